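## Trinucleotide-context machinery shared by the mutation-spectrum module and
## the synthetic-data generator.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 pyrimidine-collapsed trinucleotide context labels
#'
#' Context labels in canonical catalog order: the six substitution classes
#' `C>A, C>G, C>T, T>A, T>C, T>G` (purine-reference substitutions are
#' strand-collapsed onto these), each expanded over the 16 combinations of
#' 5' and 3' flanking bases, giving labels such as `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(context_labels())
context_labels <- function() {
  out <- character(0)
  for (sub in .SUBSTITUTIONS) {
    for (p5 in .BASES) {
      for (p3 in .BASES) {
        out <- c(out, sprintf("%s[%s]%s", p5, sub, p3))
      }
    }
  }
  out
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Map a character vector of chromosome sequences into integer base codes
## (A=0, C=1, G=2, T=3; anything else NA).
.base_codes <- function(seq) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(seq)]
}

## The 32 pyrimidine-mid trinucleotides ("ACA", "ACC", ..., "TTT") in the
## order induced by context_labels() flank expansion.
.trinuc32 <- function() {
  out <- character(0)
  for (mid in c("C", "T")) {
    for (p5 in .BASES) {
      for (p3 in .BASES) {
        out <- c(out, paste0(p5, mid, p3))
      }
    }
  }
  out
}

## Lookup tables over the 64 raw trinucleotide codes (16*b5 + 4*mid + b3):
## $class: index into .trinuc32() after pyrimidine collapse
## $flip:  TRUE when the raw trinucleotide had a purine middle base
.trinuc_tables <- function() {
  tri32 <- .trinuc32()
  raw <- character(64)
  k <- 1
  for (b5 in .BASES) for (mid in .BASES) for (b3 in .BASES) {
    raw[k] <- paste0(b5, mid, b3)
    k <- k + 1
  }
  mid <- substr(raw, 2, 2)
  flip <- mid %in% c("A", "G")
  collapsed <- ifelse(flip, revcomp(raw), raw)
  list(class = match(collapsed, tri32), flip = flip, raw = raw)
}

.TRINUC_TABLES <- .trinuc_tables()

## Per-position collapsed trinucleotide class for one chromosome sequence.
## Returns an integer vector of length nchar(seq); positions 1 and L, and any
## position whose window contains a non-ACGT base, are NA.
.position_trinuc_class <- function(seq) {
  codes <- .base_codes(seq)
  n <- length(codes)
  out <- rep(NA_integer_, n)
  if (n < 3) return(out)
  raw <- codes[1:(n - 2)] * 16L + codes[2:(n - 1)] * 4L + codes[3:n]
  out[2:(n - 1)] <- .TRINUC_TABLES$class[raw + 1L]
  out
}

## Normalize a reference argument (sim_reference object or named character
## vector of chromosome sequences) into a named character vector with
## chr-prefix-free names.
.ref_sequences <- function(reference) {
  if (inherits(reference, "sim_reference")) reference <- reference$sequences
  if (!is.character(reference) || is.null(names(reference)))
    stop("reference must be a sim_reference or a named character vector of chromosome sequences")
  names(reference) <- normalize_chrom(names(reference))
  reference
}

#' Classify SNVs into 96 trinucleotide contexts
#'
#' Assigns each single-nucleotide variant its pyrimidine-collapsed
#' trinucleotide context label. When the reference allele is a purine, the
#' substitution and its flanking bases are reverse-complemented before
#' labeling, so a variant and its reverse-complement representation map to
#' the same label.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; every row must be an SNV.
#' @param reference A `sim_reference` object or named character vector of
#'   chromosome sequences.
#' @return Character vector of context labels (one of [context_labels()]),
#'   `NA` where the flanking bases are unavailable or non-ACGT
#'   (unclassifiable).
#' @details The reference base at `pos` must equal `ref`; a mismatch is a
#'   data-integrity error and aborts.
#' @export
classify_context <- function(variants, reference) {
  sequences <- .ref_sequences(reference)
  chrom <- normalize_chrom(as.character(variants$chrom))
  pos <- as.integer(variants$pos)
  ref <- as.character(variants$ref)
  alt <- as.character(variants$alt)
  if (!all(nchar(ref) == 1 & nchar(alt) == 1 &
           ref %in% .BASES & alt %in% .BASES)) {
    stop("classify_context expects SNVs only (single-base ref and alt in A/C/G/T)")
  }
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  missing_chrom <- setdiff(unique(chrom), names(sequences))
  if (length(missing_chrom) > 0)
    stop("chromosome(s) absent from reference: ", paste(missing_chrom, collapse = ", "))

  n <- length(pos)
  out <- rep(NA_character_, n)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    s <- sequences[[cn]]
    len <- nchar(s)
    p <- pos[idx]
    if (any(p < 1 | p > len))
      stop("variant position outside chromosome ", cn)
    obs <- substring(s, p, p)
    bad <- obs != ref[idx]
    if (any(bad)) {
      stop(sprintf("reference mismatch at %s:%d (reference %s, variant ref %s)",
                   cn, p[which(bad)[1]], obs[which(bad)[1]], ref[idx][which(bad)[1]]))
    }
    interior <- p > 1 & p < len
    if (!any(interior)) next
    i2 <- idx[interior]
    p2 <- p[interior]
    l5 <- substring(s, p2 - 1, p2 - 1)
    l3 <- substring(s, p2 + 1, p2 + 1)
    ok <- l5 %in% .BASES & l3 %in% .BASES
    purine <- ref[i2] %in% c("A", "G")
    lab <- ifelse(purine,
                  sprintf("%s[%s>%s]%s", .COMP[l3], .COMP[ref[i2]], .COMP[alt[i2]], .COMP[l5]),
                  sprintf("%s[%s>%s]%s", l5, ref[i2], alt[i2], l3))
    lab[!ok] <- NA_character_
    out[i2] <- lab
  }
  out
}
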