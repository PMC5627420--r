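## variant IO: the minimal VCF dialect, annotation/catalog/gene-list TSVs,
## arm BED and reference FASTA.

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix; the prefix is restored by the writers.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector without `"chr"` prefix.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

.denorm_chrom <- function(x) paste0("chr", normalize_chrom(x))

## Controlled consequence vocabulary.
CONSEQUENCE_TERMS <- c("missense", "nonsense", "nonstop", "splicing",
                       "frameshift_indel", "inframe_indel", "synonymous",
                       "noncoding")

## Canonical variant-call columns; the data model is a plain data frame with
## these columns, keyed by (chrom, pos, ref, alt, sample).
.VC_COLS <- c("chrom", "pos", "ref", "alt", "sample", "callers", "depth",
              "alt_depth", "vaf", "pop_freq", "gene", "consequence")

#' Construct a variant-call data frame
#'
#' Fills optional columns with `NA` and validates the core invariants
#' (`alt_depth <= depth`, `ref != alt`, `pos >= 1`).
#'
#' @param chrom,pos,ref,alt,sample Required per-variant fields (`pos` 1-based).
#' @param callers Comma-separated caller names per call.
#' @param depth,alt_depth Read depths (may be `NA` when a caller omits them).
#' @param pop_freq,gene,consequence Optional annotation fields.
#' @return Data frame with the canonical variant-call columns.
#' @export
variant_calls <- function(chrom, pos, ref, alt, sample, callers = NA_character_,
                          depth = NA_integer_, alt_depth = NA_integer_,
                          pop_freq = NA_real_, gene = NA_character_,
                          consequence = NA_character_) {
  n <- length(chrom)
  rep_n <- function(x) if (length(x) == n) x else rep(x, length.out = max(n, 0))
  df <- data.frame(chrom = normalize_chrom(chrom), pos = as.integer(rep_n(pos)),
                   ref = as.character(rep_n(ref)), alt = as.character(rep_n(alt)),
                   sample = as.character(rep_n(sample)),
                   callers = as.character(rep_n(callers)),
                   depth = as.integer(rep_n(depth)),
                   alt_depth = as.integer(rep_n(alt_depth)),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1)) stop("positions must be >= 1")
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  bad <- !is.na(df$depth) & !is.na(df$alt_depth) & df$alt_depth > df$depth
  if (any(bad)) stop("alt_depth exceeds depth")
  df$vaf <- ifelse(!is.na(df$depth) & df$depth > 0, df$alt_depth / df$depth, NA_real_)
  df$pop_freq <- as.numeric(rep_n(pop_freq))
  df$gene <- as.character(rep_n(gene))
  df$consequence <- as.character(rep_n(consequence))
  df[, .VC_COLS]
}

#' Variant identity key
#'
#' @param variants Variant-call data frame.
#' @param with_sample Include the sample id in the key (the caller-independent
#'   identity used by consensus merging).
#' @return Character vector `chrom:pos:ref:alt[:sample]`.
#' @export
variant_key <- function(variants, with_sample = TRUE) {
  k <- paste(normalize_chrom(variants$chrom), variants$pos, variants$ref,
             variants$alt, sep = ":")
  if (with_sample && !is.null(variants[["sample"]])) {
    k <- paste(k, variants$sample, sep = ":")
  }
  k
}

## ---------------------------------------------------------------------------
## Minimal VCF dialect: columns CHROM POS ID REF ALT QUAL FILTER INFO with
## INFO keys DP (depth), AD (alt-supporting reads), AF, CALLER.

#' Write variant calls as a minimal VCF
#'
#' @param calls Variant-call data frame (one caller, one sample).
#' @param path Output file.
#' @param contig_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=somatrio")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          .denorm_chrom(names(contig_lengths)),
                          as.integer(contig_lengths)))
  }
  hdr <- c(hdr,
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
           '##INFO=<ID=AD,Number=1,Type=Integer,Description="Reads supporting ALT">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
           '##INFO=<ID=CALLER,Number=1,Type=String,Description="Reporting caller">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  info <- vapply(seq_len(nrow(calls)), function(i) {
    parts <- character(0)
    if (!is.na(calls$depth[i])) {
      parts <- c(parts, paste0("DP=", calls$depth[i]),
                 paste0("AD=", calls$alt_depth[i]),
                 paste0("AF=", formatC(calls$vaf[i], digits = 6, format = "g")))
    }
    if (!is.na(calls$callers[i])) parts <- c(parts, paste0("CALLER=", calls$callers[i]))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  recs <- paste(.denorm_chrom(calls$chrom), calls$pos, ".", calls$ref,
                calls$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

.parse_info <- function(info) {
  if (info == "." || info == "") return(character(0))
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else "", character(1)),
                  vapply(kv, `[`, character(1), 1))
}

#' Read a minimal-dialect VCF into variant calls
#'
#' Each record becomes one call with `callers = caller`; multi-allelic
#' records are split into one call per ALT allele. Records whose INFO lacks
#' depth fields are retained with `depth`/`alt_depth` set to `NA`.
#'
#' @param path VCF file.
#' @param caller Caller name to record on every call (when missing, the INFO
#'   `CALLER` key is used).
#' @param sample Sample id to record on every call.
#' @return Variant-call data frame.
#' @export
read_caller_vcf <- function(path, caller = NULL, sample = "sample") {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat"))
    stop("missing VCF header in ", path)
  body_idx <- which(!startsWith(lines, "#"))
  rows <- list()
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF record at line ", i, " of ", path)
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed POS at line ", i, " of ", path)
    info <- .parse_info(f[8])
    cl <- caller
    if (is.null(cl)) cl <- if ("CALLER" %in% names(info)) info[["CALLER"]] else NA_character_
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    dp <- if ("DP" %in% names(info)) as.integer(info[["DP"]]) else NA_integer_
    ad <- if ("AD" %in% names(info)) as.integer(strsplit(info[["AD"]], ",")[[1]]) else NA_integer_
    if (length(ad) < length(alts)) ad <- rep(ad[1], length(alts))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = normalize_chrom(f[1]), pos = pos, ref = f[4], alt = alts,
      sample = sample, callers = cl, depth = dp, alt_depth = ad[seq_along(alts)],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(variant_calls(character(0), integer(0), character(0), character(0),
                         character(0)))
  }
  df <- do.call(rbind, rows)
  variant_calls(df$chrom, df$pos, df$ref, df$alt, df$sample, df$callers,
                df$depth, df$alt_depth)
}

## ---------------------------------------------------------------------------
## Annotation TSV: chrom pos ref alt gene consequence pop_freq [protein_pos]

#' Read a variant annotation table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `pop_freq` (empty cells allowed) and optionally
#'   `protein_pos`.
#' @return Data frame keyed by (chrom, pos, ref, alt). Unknown consequence
#'   strings are mapped to `"noncoding"` with a warning; duplicate keys with
#'   conflicting values are an error.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pos = "integer"))
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  ann$chrom <- normalize_chrom(ann$chrom)
  if (!"pop_freq" %in% names(ann)) ann$pop_freq <- NA_real_
  ann$pop_freq <- suppressWarnings(as.numeric(ann$pop_freq))
  unknown <- !is.na(ann$consequence) & !(ann$consequence %in% CONSEQUENCE_TERMS)
  if (any(unknown)) {
    warning("unknown consequence term(s) mapped to 'noncoding': ",
            paste(unique(ann$consequence[unknown]), collapse = ", "))
    ann$consequence[unknown] <- "noncoding"
  }
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    for (k in dup) {
      sub <- ann[key == k, c("gene", "consequence", "pop_freq")]
      if (nrow(unique(sub)) > 1) stop("conflicting annotation for variant ", k)
    }
    ann <- ann[!duplicated(key), , drop = FALSE]
  }
  ann
}

#' Attach annotation to variant calls
#'
#' Left join on (chrom, pos, ref, alt); fills `gene`, `consequence`,
#' `pop_freq` (and `protein_pos` when present in the annotation).
#'
#' @param variants Variant-call data frame.
#' @param annotation Data frame from [read_annotation()] (or built in code).
#' @return `variants` with annotation columns filled.
#' @export
annotate_variants <- function(variants, annotation) {
  key_v <- variant_key(variants, with_sample = FALSE)
  key_a <- paste(normalize_chrom(annotation$chrom), annotation$pos,
                 annotation$ref, annotation$alt, sep = ":")
  idx <- match(key_v, key_a)
  variants$gene <- annotation$gene[idx]
  variants$consequence <- annotation$consequence[idx]
  variants$pop_freq <- annotation$pop_freq[idx]
  if ("protein_pos" %in% names(annotation)) {
    variants$protein_pos <- annotation$protein_pos[idx]
  }
  variants
}

## ---------------------------------------------------------------------------
## Signature catalog TSV: first column the 96 context labels, one column per
## signature.

#' Read a signature catalog
#'
#' @param path TSV whose first column holds the 96 context labels and whose
#'   remaining columns hold one probability vector per signature.
#' @return A `signature_catalog`: list with `context_labels` and `matrix`
#'   (96 x K, rows in canonical [context_labels()] order, columns summing
#'   to 1). Columns off unit sum by at most `1e-6` are renormalized; larger
#'   deviations, negative entries, wrong row counts or duplicate labels are
#'   errors.
#' @export
read_signature_catalog <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(raw[[1]])
  if (length(labels) != 96) stop("signature catalog must have 96 data rows, found ", length(labels))
  if (anyDuplicated(labels)) stop("duplicate context labels in catalog")
  canon <- context_labels()
  if (!setequal(labels, canon)) stop("catalog context labels do not match the 96 canonical labels")
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) < 1) stop("catalog contains no signature columns")
  if (any(is.na(m))) stop("missing values in catalog")
  if (any(m < 0)) stop("negative entries in catalog")
  m <- m[match(canon, labels), , drop = FALSE]
  rownames(m) <- canon
  sums <- colSums(m)
  if (any(sums == 0)) stop("all-zero signature column(s): cannot normalize")
  off <- abs(sums - 1)
  if (any(off > 1e-6)) {
    stop("signature column(s) do not sum to 1 (off by more than 1e-6): ",
         paste(colnames(m)[off > 1e-6], collapse = ", "))
  }
  m <- sweep(m, 2, sums, "/")
  out <- list(context_labels = canon, matrix = m)
  class(out) <- "signature_catalog"
  out
}

#' Write a signature catalog
#'
#' @param catalog A `signature_catalog` or 96 x K matrix with context-label
#'   rownames.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  m <- .catalog_matrix(catalog)
  df <- data.frame(context = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("Signature catalog:", ncol(x$matrix), "signature(s) over 96 contexts\n")
  cat("  names:", paste(colnames(x$matrix), collapse = ", "), "\n")
  invisible(x)
}

#' Bundled demonstration signature catalog
#'
#' A small synthetic catalog shipped with the package: a defective-MMR-like
#' profile (`MMRD_like`, mass concentrated on the `N[C>T]G` bins, as in
#' MMR-deficient hypermutation) plus four decoy processes (`Flat`,
#' `CtoA_heavy`, `TtoC_heavy`, `APOBEC_like`). Matching against a real
#' 30-signature catalog uses the same reader on a user-supplied file.
#'
#' @return A `signature_catalog` with 5 signatures.
#' @export
demo_signature_catalog <- function() {
  read_signature_catalog(system.file("extdata", "signatures_demo_synthetic.tsv",
                                     package = "somatrio", mustWork = TRUE))
}

## ---------------------------------------------------------------------------
## Chromosome-arm BED (0-based half-open) and reference FASTA.

#' Write chromosome-arm definitions as BED
#'
#' @param arms Data frame with columns `chrom`, `arm` (`"p"`/`"q"`), `start`,
#'   `end` (0-based half-open).
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_arm_bed <- function(arms, path) {
  df <- data.frame(.denorm_chrom(arms$chrom), as.integer(arms$start),
                   as.integer(arms$end),
                   paste0(normalize_chrom(arms$chrom), arms$arm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read chromosome-arm definitions from BED
#'
#' @param path BED file (0-based half-open; name column `<chrom><arm>`).
#' @return Data frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
read_arm_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("arm BED needs 4 columns (chrom, start, end, name)")
  chrom <- normalize_chrom(df[[1]])
  arm <- sub("^.*(p|q)$", "\\1", df[[4]])
  out <- data.frame(chrom = chrom, arm = arm, start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("arm intervals must satisfy start < end")
  out
}

#' Arm membership of 1-based positions
#'
#' A 1-based variant position `p` lies on an arm `[start, end)` (0-based
#' half-open) iff `start <= p - 1 < end`.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param arms Arm table from [read_arm_bed()] or [simulate_reference()].
#' @return Character vector of arm ids (`"1p"` etc.), `NA` where no arm
#'   contains the position.
#' @export
arm_of_position <- function(chrom, pos, arms) {
  chrom <- normalize_chrom(chrom)
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[i] & (pos - 1) >= arms$start[i] & (pos - 1) < arms$end[i]
    out[hit] <- paste0(arms$chrom[i], arms$arm[i])
  }
  out
}

#' Write a reference as FASTA
#'
#' @param reference A `sim_reference` or named character vector of chromosome
#'   sequences.
#' @param path Output FASTA.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  sequences <- .ref_sequences(reference)
  dna <- Biostrings::DNAStringSet(sequences)
  names(dna) <- .denorm_chrom(names(sequences))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences (names without
#'   `"chr"` prefix).
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  names(out) <- normalize_chrom(sub("\\s.*$", "", names(dna)))
  out
}

## ---------------------------------------------------------------------------
## Gene lists TSV: columns list_name, gene.

#' Read gene lists
#'
#' @param path TSV with columns `list_name` and `gene`.
#' @return Named list of character vectors (one per list).
#' @export
read_gene_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("list_name", "gene") %in% names(df)))
    stop("gene list file needs columns list_name and gene")
  split(df$gene, df$list_name)
}

#' Bundled synthetic cancer-gene lists
#'
#' Small synthetic stand-ins for curated driver-gene and pathway lists
#' (recurrently mutated genes, two signaling pathways), for demonstrations
#' and tests.
#'
#' @return Named list of character vectors.
#' @export
demo_gene_lists <- function() {
  read_gene_lists(system.file("extdata", "gene_lists_synthetic.tsv",
                              package = "somatrio", mustWork = TRUE))
}

## ---------------------------------------------------------------------------
## Germline-site table IO.

#' Write a germline-site table
#'
#' @param sites Germline-site data frame from [simulate_germline_sites()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_germline_sites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a germline-site table
#'
#' @param path TSV written by [write_germline_sites()].
#' @param normal,tumors Sample ids carried as attributes on the result.
#' @return Germline-site data frame.
#' @export
read_germline_sites <- function(path, normal, tumors) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  attr(df, "normal") <- normal
  attr(df, "tumors") <- tumors
  df
}
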