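## scna_loh: high-quality germline-site selection, sliding-window MAF curves,
## arm-level loss calls and LOH-site counting.

#' High-quality germline-site filter configuration
#'
#' @param min_coverage Coverage floor; sites must have depth strictly greater
#'   than this in every sample (default 20).
#' @param require_dbsnp Require a dbSNP entry (default `TRUE`).
#' @param require_het_normal Require a heterozygous normal genotype (default
#'   `TRUE`).
#' @param min_normal_maf Minimum minor-allele fraction in the normal sample
#'   (default 0.25, inclusive).
#' @return A `site_filter_config` object.
#' @export
site_filter_config <- function(min_coverage = 20, require_dbsnp = TRUE,
                               require_het_normal = TRUE, min_normal_maf = 0.25) {
  if (min_coverage < 0) stop("min_coverage must be >= 0")
  if (min_normal_maf < 0 || min_normal_maf > 0.5)
    stop("min_normal_maf must lie in [0, 0.5]")
  out <- list(min_coverage = min_coverage, require_dbsnp = isTRUE(require_dbsnp),
              require_het_normal = isTRUE(require_het_normal),
              min_normal_maf = min_normal_maf)
  class(out) <- "site_filter_config"
  out
}

#' Sliding-window configuration
#'
#' Windows are SNV-index based: consecutive runs of `window_size` sites with
#' starts `step` sites apart.
#'
#' @param window_size Sites per window (default 1000).
#' @param step Offset between window starts (default 500, i.e. half-window
#'   overlap).
#' @param summary Window summary statistic, `"median"` (default) or
#'   `"mean"`.
#' @return A `window_config` object.
#' @export
window_config <- function(window_size = 1000L, step = 500L,
                          summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (step <= 0 || step > window_size) stop("need 0 < step <= window_size")
  out <- list(window_size = as.integer(window_size), step = as.integer(step),
              summary = summary)
  class(out) <- "window_config"
  out
}

#' Arm-level loss-call configuration
#'
#' Decision constants for calling a one-copy arm loss from tumor-vs-normal
#' MAF curves. An arm is called `loss` when it has at least `min_windows`
#' full windows, the median tumor window summary falls below
#' `max_tumor_arm_maf`, and the median normal summary exceeds the median
#' tumor summary by at least `min_maf_drop`. Sites with tumor MAF below
#' `loh_site_max_maf` count as LOH sites.
#'
#' @param max_tumor_arm_maf Tumor MAF ceiling for a loss call (default 0.40).
#' @param min_maf_drop Minimum normal-minus-tumor median drop (default 0.05).
#' @param min_windows Minimum full windows required to call an arm (default
#'   2).
#' @param loh_site_max_maf Per-site LOH threshold on tumor MAF (default
#'   0.10, strict).
#' @return An `arm_call_config` object.
#' @export
arm_call_config <- function(max_tumor_arm_maf = 0.40, min_maf_drop = 0.05,
                            min_windows = 2L, loh_site_max_maf = 0.10) {
  for (x in c(max_tumor_arm_maf, min_maf_drop, loh_site_max_maf)) {
    if (x < 0 || x > 0.5) stop("thresholds must lie in [0, 0.5]")
  }
  if (min_windows < 1) stop("min_windows must be >= 1")
  out <- list(max_tumor_arm_maf = max_tumor_arm_maf, min_maf_drop = min_maf_drop,
              min_windows = as.integer(min_windows),
              loh_site_max_maf = loh_site_max_maf)
  class(out) <- "arm_call_config"
  out
}

.site_samples <- function(sites, normal = NULL, tumors = NULL) {
  if (is.null(normal)) normal <- attr(sites, "normal")
  if (is.null(tumors)) tumors <- attr(sites, "tumors")
  if (is.null(normal)) stop("normal sample id not given and not carried by the site table")
  if (is.null(tumors)) {
    depth_cols <- grep("^depth_", names(sites), value = TRUE)
    tumors <- setdiff(sub("^depth_", "", depth_cols), normal)
  }
  list(normal = normal, tumors = tumors)
}

#' Select high-quality germline heterozygous sites
#'
#' Applies the enabled criteria: coverage strictly greater than
#' `min_coverage` in every sample, dbSNP membership, heterozygous normal
#' genotype, and normal minor-allele fraction at least `min_normal_maf`.
#' Output is ordered by (chrom, pos).
#'
#' @param sites Germline-site data frame (see [simulate_germline_sites()]).
#' @param config A `site_filter_config`.
#' @param normal,tumors Sample ids; default taken from the site-table
#'   attributes.
#' @return Filtered, ordered germline-site data frame.
#' @export
select_hq_sites <- function(sites, config = site_filter_config(),
                            normal = NULL, tumors = NULL) {
  ss <- .site_samples(sites, normal, tumors)
  ncol_ <- paste0("depth_", ss$normal)
  if (!ncol_ %in% names(sites)) stop("site table lacks normal sample '", ss$normal, "'")
  keep <- rep(TRUE, nrow(sites))
  for (s in c(ss$normal, ss$tumors)) {
    dc <- paste0("depth_", s)
    if (!dc %in% names(sites)) stop("site table lacks sample '", s, "'")
    keep <- keep & sites[[dc]] > config$min_coverage
  }
  if (config$require_dbsnp) keep <- keep & sites$is_dbsnp
  if (config$require_het_normal) keep <- keep & sites$genotype == "het"
  keep <- keep & sites[[paste0("maf_", ss$normal)]] >= config$min_normal_maf
  out <- sites[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normal") <- ss$normal
  attr(out, "tumors") <- ss$tumors
  out
}

#' Sliding-window MAF curve for one sample on one arm
#'
#' @param sites_on_arm Site data frame sorted by position, all on one arm.
#' @param sample Sample id (`maf_<sample>` column used).
#' @param config A `window_config`.
#' @return Data frame with columns `index` and `summary` (one row per full
#'   window; zero rows when fewer sites than `window_size`, with attribute
#'   `insufficient_data = TRUE`). Trailing sites not filling a window are
#'   reported in attribute `remainder`.
#' @export
window_maf_curve <- function(sites_on_arm, sample, config = window_config()) {
  maf <- sites_on_arm[[paste0("maf_", sample)]]
  if (is.null(maf)) stop("no maf column for sample '", sample, "'")
  n <- length(maf)
  w <- config$window_size
  s <- config$step
  if (n < w) {
    out <- data.frame(index = integer(0), summary = numeric(0))
    attr(out, "insufficient_data") <- TRUE
    attr(out, "remainder") <- n
    return(out)
  }
  starts <- seq.int(1L, n - w + 1L, by = s)
  fun <- if (config$summary == "median") stats::median else mean
  summaries <- vapply(starts, function(st) fun(maf[st:(st + w - 1L)]), numeric(1))
  out <- data.frame(index = seq_along(starts), summary = summaries)
  attr(out, "insufficient_data") <- FALSE
  attr(out, "remainder") <- n - (starts[length(starts)] + w - 1L)
  out
}

#' Call an arm-level event from tumor and normal MAF curves
#'
#' @param normal_curve,tumor_curve Window curves from [window_maf_curve()]
#'   (or bare numeric vectors of window summaries) computed on the same site
#'   set.
#' @param config An `arm_call_config`.
#' @return `"loss"`, `"neutral"` or `"insufficient_data"`.
#' @export
call_arm_events <- function(normal_curve, tumor_curve,
                            config = arm_call_config()) {
  nc <- if (is.data.frame(normal_curve)) normal_curve$summary else normal_curve
  tc <- if (is.data.frame(tumor_curve)) tumor_curve$summary else tumor_curve
  if (length(nc) != length(tc)) stop("normal and tumor curves differ in length")
  if (length(tc) < config$min_windows) return("insufficient_data")
  tumor_med <- stats::median(tc)
  normal_med <- stats::median(nc)
  if (tumor_med < config$max_tumor_arm_maf &&
      (normal_med - tumor_med) >= config$min_maf_drop) "loss" else "neutral"
}

#' Count LOH sites on an arm
#'
#' Counts high-quality germline het sites whose tumor minor-allele fraction
#' falls below `loh_site_max_maf`.
#'
#' @param sites_on_arm High-quality germline-site data frame for one arm.
#' @param tumor_sample Tumor sample id.
#' @param config An `arm_call_config`.
#' @return Integer count.
#' @export
count_loh_sites <- function(sites_on_arm, tumor_sample,
                            config = arm_call_config()) {
  maf <- sites_on_arm[[paste0("maf_", tumor_sample)]]
  if (is.null(maf)) stop("no maf column for sample '", tumor_sample, "'")
  sum(maf < config$loh_site_max_maf)
}

#' Genome-wide arm-level SCNA scan
#'
#' Selects high-quality germline het sites, computes tumor and normal MAF
#' curves per chromosome arm, calls arm-level losses and counts LOH sites,
#' for every (arm, tumor) pair.
#'
#' @param sites Germline-site data frame.
#' @param arms Arm table (`chrom`, `arm`, `start`, `end`, 0-based
#'   half-open).
#' @param normal,tumors Sample ids; default from site-table attributes.
#' @param filter_config A `site_filter_config`.
#' @param window_cfg A `window_config`.
#' @param call_cfg An `arm_call_config`.
#' @return An `arm_report` data frame: one row per (arm, tumor) with
#'   `n_hq_sites`, `n_windows`, `normal_median`, `tumor_median`, `status`,
#'   `n_loh_sites`; full window curves in attribute `curves`.
#' @export
genome_scna_scan <- function(sites, arms, normal = NULL, tumors = NULL,
                             filter_config = site_filter_config(),
                             window_cfg = window_config(),
                             call_cfg = arm_call_config()) {
  ss <- .site_samples(sites, normal, tumors)
  hq <- select_hq_sites(sites, filter_config, ss$normal, ss$tumors)
  arm_ids <- arm_of_position(hq$chrom, hq$pos, arms)
  rows <- list()
  curves <- list()
  for (i in seq_len(nrow(arms))) {
    aid <- paste0(arms$chrom[i], arms$arm[i])
    on_arm <- hq[!is.na(arm_ids) & arm_ids == aid, , drop = FALSE]
    ncurve <- window_maf_curve(on_arm, ss$normal, window_cfg)
    for (t in ss$tumors) {
      tcurve <- window_maf_curve(on_arm, t, window_cfg)
      status <- call_arm_events(ncurve, tcurve, call_cfg)
      rows[[length(rows) + 1]] <- data.frame(
        arm = aid, tumor = t, n_hq_sites = nrow(on_arm),
        n_windows = nrow(tcurve),
        normal_median = if (nrow(ncurve) > 0) stats::median(ncurve$summary) else NA_real_,
        tumor_median = if (nrow(tcurve) > 0) stats::median(tcurve$summary) else NA_real_,
        status = status,
        n_loh_sites = count_loh_sites(on_arm, t, call_cfg),
        stringsAsFactors = FALSE)
      curves[[paste(aid, t, sep = ":")]] <-
        list(normal = ncurve, tumor = tcurve)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  class(out) <- c("arm_report", "data.frame")
  out
}

#' @export
print.arm_report <- function(x, ...) {
  cat("Arm-level SCNA scan:", nrow(x), "(arm, tumor) pairs\n")
  print.data.frame(x, ...)
  losses <- x[x$status == "loss", , drop = FALSE]
  if (nrow(losses) > 0) {
    cat("Called losses:",
        paste(sprintf("%s in %s (%d LOH sites)", losses$arm, losses$tumor,
                      losses$n_loh_sites), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Plot tumor vs normal MAF curves for one arm
#'
#' @param report An `arm_report` from [genome_scna_scan()].
#' @param arm Arm id (e.g. `"1p"`).
#' @param tumor Tumor sample id.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_arm_curves <- function(report, arm, tumor, ...) {
  curves <- attr(report, "curves")[[paste(arm, tumor, sep = ":")]]
  if (is.null(curves)) stop("no curves stored for ", arm, " / ", tumor)
  graphics::plot(curves$normal$index, curves$normal$summary, type = "b",
                 ylim = c(0, 0.5), xlab = "window", ylab = "window MAF",
                 main = paste("Arm", arm, "-", tumor), col = "grey40", pch = 16,
                 ...)
  graphics::lines(curves$tumor$index, curves$tumor$summary, type = "b",
                  col = "firebrick", pch = 17)
  graphics::legend("bottomleft", legend = c("normal", tumor),
                   col = c("grey40", "firebrick"), pch = c(16, 17), bty = "n")
  invisible(report)
}
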