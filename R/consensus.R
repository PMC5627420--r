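## somatic filtering: multi-caller consensus, population-frequency filter,
## non-silent classification and burden report.

#' Consensus-filter configuration
#'
#' @param min_callers Minimum number of supporting callers for a variant to
#'   be retained (default 2: "more than one" caller).
#' @param max_pop_freq Population-frequency ceiling; variants with a known
#'   frequency strictly greater than this are removed (default 0.01).
#' @param nonsilent_terms Consequence terms counted as non-silent.
#' @param keep_unannotated Retain variants lacking a consequence in
#'   [nonsilent_subset()] (default `FALSE`, dropped with a warning).
#' @return A `consensus_config` object.
#' @export
consensus_config <- function(min_callers = 2L, max_pop_freq = 0.01,
                             nonsilent_terms = c("missense", "nonsense",
                                                 "nonstop", "splicing",
                                                 "frameshift_indel",
                                                 "inframe_indel"),
                             keep_unannotated = FALSE) {
  if (min_callers < 1) stop("min_callers must be >= 1")
  if (max_pop_freq <= 0 || max_pop_freq >= 1) stop("max_pop_freq must lie in (0, 1)")
  out <- list(min_callers = as.integer(min_callers), max_pop_freq = max_pop_freq,
              nonsilent_terms = nonsilent_terms,
              keep_unannotated = isTRUE(keep_unannotated))
  class(out) <- "consensus_config"
  out
}

#' Merge per-caller call sets by consensus
#'
#' Groups calls from several callers by the caller-independent key
#' (chrom, pos, ref, alt, sample) and retains keys supported by at least
#' `min_callers` callers. The retained record carries the union of
#' supporting callers; depths come from the first caller reporting them
#' (input order).
#'
#' @param callsets List of variant-call data frames, one per caller, all
#'   from the same sample.
#' @param config A `consensus_config`.
#' @return Variant-call data frame ordered by (chrom, pos, ref, alt), with a
#'   `n_callers` column recording support.
#' @export
consensus_merge <- function(callsets, config = consensus_config()) {
  stopifnot(is.list(callsets), length(callsets) > 0)
  all_calls <- do.call(rbind, callsets)
  if (nrow(all_calls) == 0) {
    out <- all_calls
    out$n_callers <- integer(0)
    return(out)
  }
  samples <- unique(all_calls$sample)
  if (length(samples) > 1) {
    stop("consensus_merge: call sets mix samples: ", paste(samples, collapse = ", "))
  }
  key <- variant_key(all_calls)
  first <- !duplicated(key)
  support <- lapply(split(all_calls$callers, key), function(x) unique(x[!is.na(x)]))
  out <- all_calls[first, , drop = FALSE]
  out_key <- key[first]
  out$callers <- vapply(support[out_key], paste, character(1), collapse = ",")
  out$n_callers <- lengths(support[out_key])
  ## depths from the first caller reporting them
  has_depth <- !is.na(all_calls$depth)
  if (any(!has_depth)) {
    depth_first <- all_calls[has_depth, , drop = FALSE]
    dkey <- key[has_depth]
    idx <- match(out_key, dkey)
    found <- !is.na(idx)
    out$depth[found] <- depth_first$depth[idx[found]]
    out$alt_depth[found] <- depth_first$alt_depth[idx[found]]
    out$vaf[found] <- depth_first$vaf[idx[found]]
  }
  out <- out[out$n_callers >= config$min_callers, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove likely germline polymorphisms by population frequency
#'
#' Retains variants whose population frequency is unknown (`NA`) or at most
#' `max_pop_freq`; a variant is removed only when its frequency is known to
#' be strictly greater than the ceiling. Input order is preserved.
#'
#' @param variants Variant-call data frame with a `pop_freq` column.
#' @param config A `consensus_config`.
#' @return Filtered variant-call data frame.
#' @export
frequency_filter <- function(variants, config = consensus_config()) {
  keep <- is.na(variants$pop_freq) | variants$pop_freq <= config$max_pop_freq
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict to non-silent variants
#'
#' @param variants Annotated variant-call data frame.
#' @param config A `consensus_config`; `nonsilent_terms` defines the
#'   non-silent vocabulary, `keep_unannotated` governs variants with `NA`
#'   consequence.
#' @return Filtered variant-call data frame.
#' @export
nonsilent_subset <- function(variants, config = consensus_config()) {
  unann <- is.na(variants$consequence)
  if (any(unann) && !config$keep_unannotated) {
    warning(sum(unann), " unannotated variant(s) dropped from non-silent subset")
  }
  keep <- variants$consequence %in% config$nonsilent_terms |
    (unann & config$keep_unannotated)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample non-silent mutation burden
#'
#' @param variant_lists Named list (by sample) of non-silent variant-call
#'   data frames.
#' @param genome_size Genome size in bases (e.g.
#'   `sum(nchar(reference$sequences))`).
#' @return Data frame with columns `sample`, `n_nonsilent`, `per_mb`.
#' @export
burden_report <- function(variant_lists, genome_size) {
  if (is.null(genome_size) || genome_size <= 0) stop("genome size must be positive")
  data.frame(
    sample = names(variant_lists),
    n_nonsilent = vapply(variant_lists, nrow, integer(1)),
    per_mb = vapply(variant_lists, nrow, integer(1)) / (genome_size / 1e6),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Full somatic retention pipeline for one sample
#'
#' Consensus merge, annotation, population-frequency filter and non-silent
#' subset in the default order.
#'
#' @param callsets List of per-caller variant-call data frames (one sample).
#' @param annotation Annotation data frame (see [read_annotation()]).
#' @param config A `consensus_config`.
#' @return Non-silent consensus variant-call data frame.
#' @export
somatic_retention <- function(callsets, annotation, config = consensus_config()) {
  merged <- consensus_merge(callsets, config)
  merged <- annotate_variants(merged, annotation)
  merged <- frequency_filter(merged, config)
  nonsilent_subset(merged, config)
}
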