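## comparison & enrichment: inter-tumor overlap, gene-list tallies,
## truncating classification and the germline-vs-somatic 2x2 enrichment test.

#' Overlap between two variant sets at site or gene level
#'
#' @param variants_a,variants_b Variant-call data frames.
#' @param level `"site"` (key chrom:pos:ref:alt) or `"gene"` (gene symbol).
#' @return An `overlap_summary`: `level`, `n_only_a`, `n_only_b`,
#'   `n_shared`, `jaccard`, `shared_items` (sorted).
#' @export
overlap_summary <- function(variants_a, variants_b, level = c("site", "gene")) {
  level <- match.arg(level)
  items <- function(v) {
    if (level == "site") unique(variant_key(v, with_sample = FALSE))
    else unique(v$gene[!is.na(v$gene)])
  }
  a <- items(variants_a)
  b <- items(variants_b)
  shared <- sort(intersect(a, b))
  n_shared <- length(shared)
  n_only_a <- length(setdiff(a, b))
  n_only_b <- length(setdiff(b, a))
  denom <- n_only_a + n_only_b + n_shared
  out <- list(level = level, n_only_a = n_only_a, n_only_b = n_only_b,
              n_shared = n_shared,
              jaccard = if (denom > 0) n_shared / denom else NA_real_,
              shared_items = shared)
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap (%s level): %d only-A, %d only-B, %d shared (Jaccard %.3f)\n",
              x$level, x$n_only_a, x$n_only_b, x$n_shared,
              ifelse(is.na(x$jaccard), NaN, x$jaccard)))
  if (x$n_shared > 0 && x$n_shared <= 25) {
    cat("  shared:", paste(x$shared_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tally mutated genes against curated gene lists
#'
#' Intersects each sample's mutated-gene set with each gene list (e.g.
#' significantly-mutated-gene panels or signaling pathways), optionally
#' flagging genes in a recurrence set.
#'
#' @param variants_by_sample Named list (by sample) of annotated variant-call
#'   data frames.
#' @param gene_lists Named list of character vectors (see
#'   [read_gene_lists()]).
#' @param recurrent Optional character vector of recurrently mutated genes to
#'   flag.
#' @return Named list (by gene list): each element has `genes` (per-sample
#'   mutated genes in the list), `counts`, and `recurrent_flag`.
#' @export
gene_list_tally <- function(variants_by_sample, gene_lists, recurrent = NULL) {
  if (length(gene_lists) == 0) stop("no gene lists supplied")
  lapply(gene_lists, function(gl) {
    if (length(gl) == 0) stop("empty gene list")
    genes <- lapply(variants_by_sample, function(v) {
      sort(intersect(unique(v$gene[!is.na(v$gene)]), gl))
    })
    list(genes = genes,
         counts = vapply(genes, length, integer(1)),
         recurrent_flag = lapply(genes, function(g) g %in% recurrent))
  })
}

#' Classify consequence terms as truncating, missense or other
#'
#' Truncating: nonsense, nonstop, splicing and indels (frameshift and
#' inframe both; indels are grouped with truncating wholesale, flagged here
#' so a stricter definition can be rerun).
#'
#' @param consequence Character vector of controlled-vocabulary terms.
#' @return Character vector over `{"truncating", "missense", "other"}`;
#'   unknown terms map to `"other"` with a warning.
#' @export
classify_truncating <- function(consequence) {
  truncating <- c("nonsense", "nonstop", "splicing", "frameshift_indel",
                  "inframe_indel")
  out <- ifelse(consequence %in% truncating, "truncating",
                ifelse(consequence == "missense", "missense", "other"))
  unknown <- !is.na(consequence) & !(consequence %in% CONSEQUENCE_TERMS)
  if (any(unknown)) {
    warning("unknown consequence term(s) classified as 'other': ",
            paste(unique(consequence[unknown]), collapse = ", "))
  }
  out[is.na(consequence)] <- "other"
  out
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return The two-sided Fisher exact p-value as computed (not truncated to
#'   a display floor).
#' @export
fisher_p_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) == 0) stop("empty table")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Germline-vs-somatic truncating-mutation enrichment
#'
#' Classifies both variant sets as truncating/missense (dropping "other"),
#' forms the 2x2 contingency table (rows: germline, somatic; columns:
#' truncating, missense) and tests association with a two-sided Fisher exact
#' test. The odds ratio is `(a*d)/(b*c)` with a Haldane-Anscombe correction
#' (add 0.5 to every cell) when any cell is zero; a chi-square p-value is
#' reported alongside.
#'
#' @param germline_variants,somatic_variants Data frames with a
#'   `consequence` column, or bare character vectors of consequence terms.
#' @return An `enrichment_result`: `table`, `odds_ratio`, `p_value`,
#'   `test_name`, `chisq_p`.
#' @export
truncating_enrichment <- function(germline_variants, somatic_variants) {
  csq <- function(x) if (is.data.frame(x)) x$consequence else as.character(x)
  g <- classify_truncating(csq(germline_variants))
  s <- classify_truncating(csq(somatic_variants))
  g <- g[g != "other"]
  s <- s[s != "other"]
  tab <- matrix(c(sum(g == "truncating"), sum(g == "missense"),
                  sum(s == "truncating"), sum(s == "missense")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("germline", "somatic"),
                                c("truncating", "missense")))
  enrichment_test(tab)
}

#' Enrichment test on a pre-built 2x2 table
#'
#' @param tab 2x2 matrix (rows: germline, somatic; columns: truncating,
#'   missense).
#' @return An `enrichment_result` (see [truncating_enrichment()]).
#' @export
enrichment_test <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  if (sum(tab) == 0) stop("empty contingency table")
  if (any(tab < 0)) stop("negative counts")
  p <- fisher_p_2x2(tab)
  ctab <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
  chisq_p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value),
    error = function(e) NA_real_)
  out <- list(table = tab, odds_ratio = unname(or), p_value = p,
              test_name = "Fisher exact (two-sided)", chisq_p = chisq_p)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Truncating-mutation enrichment (", x$test_name, ")\n", sep = "")
  print(x$table)
  cat(sprintf("  odds ratio = %.3f\n", x$odds_ratio))
  cat(sprintf("  p = %.4g (chi-square p = %.4g)\n", x$p_value, x$chisq_p))
  invisible(x)
}

#' Per-protein-position mutation table
#'
#' Tabulates variants on one gene by protein position, truncating/missense
#' class and origin (the data behind a lollipop diagram).
#'
#' @param variants Data frame with columns `consequence`, `origin`
#'   (`"germline"`/`"somatic"`) and `protein_pos` (NA allowed).
#' @param protein_length Protein length; any annotated position beyond it is
#'   an error.
#' @return Data frame `(position, class, origin, count)`; variants without a
#'   position annotation are tallied in rows with `position = NA`.
#' @export
position_summary <- function(variants, protein_length) {
  if (nrow(variants) == 0) {
    return(data.frame(position = integer(0), class = character(0),
                      origin = character(0), count = integer(0)))
  }
  pos <- variants$protein_pos
  if (any(!is.na(pos) & pos > protein_length)) {
    stop("protein position beyond protein length ", protein_length)
  }
  cls <- classify_truncating(variants$consequence)
  key <- paste(ifelse(is.na(pos), "NA", pos), cls, variants$origin, sep = "|")
  agg <- table(key)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(
    position = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1))),
    class = vapply(parts, `[`, character(1), 2),
    origin = vapply(parts, `[`, character(1), 3),
    count = as.integer(agg), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$class, out$origin, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconstruct the germline/somatic truncating table from printed totals
#'
#' Converts reported set sizes and truncating percentages into integer
#' counts by rounding, e.g. 378 germline variants at 89.6% truncating and
#' 46 somatic mutations at 32.6%.
#'
#' @param n_germline,pct_germline_truncating Germline total and truncating
#'   percentage (0-100).
#' @param n_somatic,pct_somatic_truncating Somatic total and truncating
#'   percentage (0-100).
#' @return 2x2 integer matrix (rows germline/somatic, columns
#'   truncating/missense).
#' @export
reconstruct_enrichment_table <- function(n_germline = 378,
                                         pct_germline_truncating = 89.6,
                                         n_somatic = 46,
                                         pct_somatic_truncating = 32.6) {
  gt <- round(n_germline * pct_germline_truncating / 100)
  st <- round(n_somatic * pct_somatic_truncating / 100)
  matrix(c(gt, n_germline - gt, st, n_somatic - st), nrow = 2, byrow = TRUE,
         dimnames = list(c("germline", "somatic"),
                         c("truncating", "missense")))
}
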