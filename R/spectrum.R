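## Mutation-spectrum module: 96-context spectra, cosine signature matching,
## and non-negative least-squares mixture refitting.

#' Build a 96-context mutation spectrum
#'
#' Classifies the SNVs of one sample into the 96 pyrimidine-collapsed
#' trinucleotide contexts and counts mutations per context. Non-SNV records
#' (indels) have no substitution class and are skipped with a warning;
#' SNVs whose flank is unavailable or non-ACGT are counted in `n_skipped`.
#'
#' @param variants Data frame of variant calls (`chrom`, `pos`, `ref`, `alt`,
#'   optionally `sample`).
#' @param reference A `sim_reference` or named character vector of chromosome
#'   sequences.
#' @param sample Sample id recorded on the spectrum; when `variants` carries a
#'   `sample` column, rows are restricted to this sample.
#' @return A `mutation_spectrum` object: list with `sample`, `counts` (named
#'   integer vector of length 96), `n_snv`, `n_skipped`.
#' @export
build_spectrum <- function(variants, reference, sample = "sample") {
  if (!is.null(variants[["sample"]])) {
    keep <- is.na(variants$sample) | variants$sample == sample
    variants <- variants[keep, , drop = FALSE]
  }
  labels <- context_labels()
  counts <- stats::setNames(integer(96), labels)
  if (nrow(variants) == 0) {
    out <- list(sample = sample, counts = counts, n_snv = 0L, n_skipped = 0L)
    class(out) <- "mutation_spectrum"
    return(out)
  }
  is_snv <- nchar(as.character(variants$ref)) == 1 &
    nchar(as.character(variants$alt)) == 1 &
    variants$ref %in% .BASES & variants$alt %in% .BASES
  if (any(!is_snv)) {
    warning(sum(!is_snv), " non-SNV record(s) skipped (no trinucleotide substitution class)")
    variants <- variants[is_snv, , drop = FALSE]
  }
  if (nrow(variants) > 0) {
    ctx <- classify_context(variants, reference)
    tab <- table(factor(ctx, levels = labels))
    counts[] <- as.integer(tab)
    n_skipped <- sum(is.na(ctx))
  } else {
    n_skipped <- 0L
  }
  out <- list(sample = sample, counts = counts,
              n_snv = sum(counts), n_skipped = as.integer(n_skipped))
  class(out) <- "mutation_spectrum"
  out
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Mutation spectrum for sample '", x$sample, "'\n", sep = "")
  cat("  classified SNVs:", x$n_snv, " unclassifiable:", x$n_skipped, "\n")
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top) > 0) {
    top <- utils::head(top, 5)
    cat("  top contexts:",
        paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.mutation_spectrum <- function(x, ...) {
  cols <- rep(c("deepskyblue3", "black", "firebrick2", "grey60", "olivedrab3",
                "lightpink2"), each = 16)
  graphics::barplot(x$counts, col = cols, border = NA, las = 2,
                    cex.names = 0.35, ylab = "mutation count",
                    main = paste("Mutation spectrum:", x$sample), ...)
  invisible(x)
}

.spectrum_counts <- function(spectrum) {
  if (inherits(spectrum, "mutation_spectrum")) return(spectrum$counts)
  if (is.numeric(spectrum) && length(spectrum) == 96) return(spectrum)
  stop("spectrum must be a mutation_spectrum or a numeric vector of length 96")
}

.catalog_matrix <- function(catalog) {
  if (inherits(catalog, "signature_catalog")) return(catalog$matrix)
  if (is.matrix(catalog) && nrow(catalog) == 96) return(catalog)
  stop("catalog must be a signature_catalog or a 96-row matrix")
}

#' Cosine similarity between two non-negative vectors
#'
#' @param u,v Numeric vectors of the same length.
#' @return `sum(u*v) / (||u|| ||v||)`.
#' @export
cosine_similarity <- function(u, v) {
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

#' Match a spectrum against a signature catalog by cosine similarity
#'
#' Computes the cosine similarity between the spectrum and each catalog
#' signature and reports the best match (ties broken by catalog order, with a
#' message).
#'
#' @param spectrum A `mutation_spectrum` or numeric 96-vector; must be
#'   non-zero.
#' @param catalog A `signature_catalog` (see [read_signature_catalog()]).
#' @return A `signature_match` object: `sample`, `similarities` (named
#'   numeric), `best`, `best_similarity`.
#' @export
cosine_match <- function(spectrum, catalog) {
  u <- .spectrum_counts(spectrum)
  if (all(u == 0)) stop("all-zero spectrum: cosine similarity undefined")
  m <- .catalog_matrix(catalog)
  sims <- apply(m, 2, function(s) cosine_similarity(u, s))
  best_idx <- which.max(sims)
  ties <- which(sims == sims[best_idx])
  if (length(ties) > 1) {
    message("cosine_match: tie between ", paste(colnames(m)[ties], collapse = ", "),
            "; keeping first in catalog order")
  }
  out <- list(
    sample = if (inherits(spectrum, "mutation_spectrum")) spectrum$sample else NA_character_,
    similarities = sims,
    best = colnames(m)[best_idx],
    best_similarity = unname(sims[best_idx])
  )
  class(out) <- "signature_match"
  out
}

#' @export
print.signature_match <- function(x, ...) {
  cat("Signature match", if (!is.na(x$sample)) paste0("for '", x$sample, "'"), "\n")
  ord <- order(x$similarities, decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-16s cosine = %.4f%s\n", names(x$similarities)[i],
                x$similarities[i],
                if (names(x$similarities)[i] == x$best) "  <- best" else ""))
  }
  invisible(x)
}

#' Refit a spectrum as a non-negative signature mixture
#'
#' Estimates non-negative weights, summing to one, such that the
#' catalog-weighted mixture is closest (Euclidean distance) to the normalized
#' spectrum. Solved by non-negative least squares on a system augmented with a
#' heavily weighted sum-to-one row, followed by exact renormalization.
#'
#' @param spectrum A `mutation_spectrum` or numeric 96-vector; must be
#'   non-zero.
#' @param catalog A `signature_catalog`.
#' @return List with `weights` (named, non-negative, sums to 1) and
#'   `residual` (Euclidean distance between the normalized spectrum and the
#'   fitted mixture).
#' @export
mixture_refit <- function(spectrum, catalog) {
  u <- .spectrum_counts(spectrum)
  if (all(u == 0)) stop("all-zero spectrum: mixture refit undefined")
  m <- .catalog_matrix(catalog)
  b <- u / sum(u)
  if (ncol(m) == 1) {
    w <- stats::setNames(1, colnames(m))
    return(list(weights = w, residual = sqrt(sum((m[, 1] - b)^2))))
  }
  lambda <- 100
  A_aug <- rbind(m, rep(lambda, ncol(m)))
  b_aug <- c(b, lambda)
  fit <- pracma::lsqnonneg(A_aug, b_aug)
  w <- fit$x
  if (sum(w) <= 0) stop("degenerate refit: all weights zero")
  w <- w / sum(w)
  names(w) <- colnames(m)
  list(weights = w, residual = sqrt(sum((as.vector(m %*% w) - b)^2)))
}
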