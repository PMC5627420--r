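## Synthetic-data module: seeded tumor-normal trio generator with known
## ground truth (purity, planted arm losses, planted signature, caller error
## rates).

## Named substreams off one root seed so stages can be regenerated
## independently and deterministically.
.substream_seed <- function(seed, stream) {
  offsets <- c(reference = 101L, germline = 211L, somatic = 307L,
               callers = 401L, annotation = 503L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}

## Poisson truncated at >= 1 (depth must be positive).
.rpois_trunc <- function(n, lambda) {
  d <- stats::rpois(n, lambda)
  while (any(d == 0)) {
    z <- d == 0
    d[z] <- stats::rpois(sum(z), lambda)
  }
  d
}

#' Simulation configuration
#'
#' Defines one synthetic tumor-normal trio: genome layout, sequencing depth,
#' tumor purity, planted one-copy arm losses, the planted mutational
#' signature, and the error model of the pseudo-callers.
#'
#' @param seed Root seed; all stage streams derive from it.
#' @param n_chromosomes Number of toy chromosomes (named `1..n`, two arms
#'   each).
#' @param arm_length Bases per arm (scalar, or length-2 vector for p/q).
#' @param het_sites_per_arm Germline heterozygous SNVs simulated per arm.
#' @param mean_depth Mean sequencing depth (reads); per-site depth is
#'   Poisson(`mean_depth`) truncated at 1.
#' @param tumor_purity Fraction of tumor cells in each tumor sample, in
#'   \[0, 1\].
#' @param normal_sample,tumor_samples Sample ids.
#' @param lost_arms Named list (by tumor sample) of arm ids (e.g. `"1p"`)
#'   carrying a one-copy loss in that tumor.
#' @param n_somatic True somatic SNVs per tumor.
#' @param signature_name Catalog key of the planted signature.
#' @param signature_mixture Optional named weights over catalog signatures
#'   (must sum to 1); overrides `signature_name`.
#' @param n_callers,caller_names Number/names of pseudo-callers.
#' @param caller_sensitivity Probability each caller reports each true
#'   variant, in (0, 1\].
#' @param private_fp_rate Expected private false positives per caller
#'   (Poisson).
#' @param common_snp_fraction Fraction of somatic-candidate calls assigned a
#'   population frequency above 1%.
#' @param indel_fraction Fraction (of `n_somatic`) of additional small
#'   indels, generated only to exercise truncating classification.
#' @param dbsnp_fraction Fraction of germline sites carrying a dbSNP flag.
#' @param hom_fraction Fraction of germline sites homozygous-alt in the
#'   normal (to exercise the heterozygosity filter).
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       arm_length = 5e5,
                       het_sites_per_arm = 2000L,
                       mean_depth = 40,
                       tumor_purity = 0.6,
                       normal_sample = "blood",
                       tumor_samples = c("tumorA", "tumorB"),
                       lost_arms = list(),
                       n_somatic = 300L,
                       signature_name = "MMRD_like",
                       signature_mixture = NULL,
                       n_callers = 4L,
                       caller_names = paste0("caller", seq_len(n_callers)),
                       caller_sensitivity = 0.9,
                       private_fp_rate = 20,
                       common_snp_fraction = 0.1,
                       indel_fraction = 0,
                       dbsnp_fraction = 0.95,
                       hom_fraction = 0.02) {
  if (length(arm_length) == 1) arm_length <- rep(arm_length, 2)
  if (any(arm_length <= 0)) stop("arm lengths must be positive")
  if (tumor_purity < 0 || tumor_purity > 1) stop("tumor_purity must lie in [0, 1]")
  if (caller_sensitivity <= 0 || caller_sensitivity > 1)
    stop("caller_sensitivity must lie in (0, 1]")
  counts <- c(n_chromosomes = n_chromosomes, het_sites_per_arm = het_sites_per_arm,
              n_somatic = n_somatic, n_callers = n_callers)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_chromosomes < 1) stop("need at least one chromosome")
  if (private_fp_rate < 0) stop("private_fp_rate must be non-negative")
  for (frac in c(common_snp_fraction, indel_fraction, dbsnp_fraction, hom_fraction)) {
    if (frac < 0 || frac > 1) stop("fractions must lie in [0, 1]")
  }
  if (!is.null(signature_mixture)) {
    if (is.null(names(signature_mixture)) || any(signature_mixture < 0) ||
        abs(sum(signature_mixture) - 1) > 1e-8) {
      stop("signature_mixture must be named, non-negative and sum to 1")
    }
  }
  bad_lost <- setdiff(names(lost_arms), tumor_samples)
  if (length(bad_lost) > 0)
    stop("lost_arms names not among tumor samples: ", paste(bad_lost, collapse = ", "))
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              arm_length = arm_length, het_sites_per_arm = as.integer(het_sites_per_arm),
              mean_depth = mean_depth, tumor_purity = tumor_purity,
              normal_sample = normal_sample, tumor_samples = tumor_samples,
              lost_arms = lost_arms, n_somatic = as.integer(n_somatic),
              signature_name = signature_name, signature_mixture = signature_mixture,
              n_callers = as.integer(n_callers), caller_names = caller_names,
              caller_sensitivity = caller_sensitivity,
              private_fp_rate = private_fp_rate,
              common_snp_fraction = common_snp_fraction,
              indel_fraction = indel_fraction,
              dbsnp_fraction = dbsnp_fraction, hom_fraction = hom_fraction)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a toy reference genome with arm definitions
#'
#' Generates a deterministic (seeded) i.i.d. A/C/G/T sequence per chromosome
#' and an arm table of 0-based half-open intervals: the p arm covers the
#' first `arm_length[1]` bases, the q arm the rest; arms are non-overlapping
#' and cover each chromosome.
#'
#' @param config A `sim_config`.
#' @return A `sim_reference`: list with `sequences` (named character vector)
#'   and `arms` (data frame `chrom`, `arm`, `start`, `end`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "reference"))
  lp <- as.integer(config$arm_length[1])
  lq <- as.integer(config$arm_length[2])
  chroms <- as.character(seq_len(config$n_chromosomes))
  sequences <- vapply(chroms, function(cn) {
    intToUtf8(utf8ToInt("ACGT")[sample.int(4L, lp + lq, replace = TRUE)])
  }, character(1))
  arms <- data.frame(
    chrom = rep(chroms, each = 2),
    arm = rep(c("p", "q"), config$n_chromosomes),
    start = rep(c(0L, lp), config$n_chromosomes),
    end = rep(c(lp, lp + lq), config$n_chromosomes),
    stringsAsFactors = FALSE)
  out <- list(sequences = sequences, arms = arms)
  class(out) <- "sim_reference"
  out
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("Toy reference:", length(x$sequences), "chromosome(s),",
      sum(nchar(x$sequences)), "bases,", nrow(x$arms), "arms\n")
  invisible(x)
}

## Expected alt-read fraction at a germline het site under a one-copy loss:
## with purity rho, the retained allele is present at copy fraction
## 1/(2 - rho) and the deleted allele at (1 - rho)/(2 - rho).
.loss_alt_fraction <- function(rho, alt_deleted) {
  ifelse(alt_deleted, (1 - rho) / (2 - rho), 1 / (2 - rho))
}

#' Expected minor-allele fraction under a one-copy loss
#'
#' Closed form `(1 - rho) / (2 - rho)` for tumor purity `rho`: the deleted
#' allele is carried only by the contaminating normal cells (1 copy in a
#' fraction `1 - rho` of cells) out of a mean copy number `2 - rho`.
#'
#' @param rho Tumor purity in \[0, 1\].
#' @return Expected deleted-allele read fraction.
#' @export
expected_loss_maf <- function(rho) (1 - rho) / (2 - rho)

#' Simulate germline heterozygous sites with per-sample allele depths
#'
#' Plants `het_sites_per_arm` germline SNVs per arm. Per-site, per-sample
#' depth is Poisson(`mean_depth`) truncated at 1. The normal alt-read count
#' is Binomial(depth, 0.5) at het sites; on an arm lost in a tumor, the
#' tumor alt-read count follows Binomial(depth, f) with f the one-copy-loss
#' allele fraction at purity `rho` (deleted allele chosen uniformly per
#' site). A small fraction of sites is homozygous-alt or non-dbSNP so the
#' high-quality site filter is exercised on both sides.
#'
#' @param config A `sim_config`.
#' @param reference A `sim_reference` from [simulate_reference()].
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `arm_id`,
#'   `is_dbsnp`, `genotype` (planted normal genotype), per-sample
#'   `depth_<s>`, `alt_<s>`, `maf_<s>` (`min(vaf, 1-vaf)`), and per-tumor
#'   `lost_allele_<t>` (`"ref"`/`"alt"`/`NA`). Attributes `normal` and
#'   `tumors` carry the sample ids.
#' @export
simulate_germline_sites <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "sim_reference"))
  rho <- config$tumor_purity
  set.seed(.substream_seed(config$seed, "germline"))
  arms <- reference$arms
  pieces <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    n <- config$het_sites_per_arm
    lo <- arms$start[i] + 1L  # 1-based inclusive
    hi <- arms$end[i]
    pos <- sort(sample.int(hi - lo + 1L, n) + lo - 1L)
    pieces[[i]] <- data.frame(chrom = arms$chrom[i],
                              pos = pos,
                              arm_id = paste0(arms$chrom[i], arms$arm[i]),
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, pieces)
  n <- nrow(sites)
  ref_base <- character(n)
  for (cn in unique(sites$chrom)) {
    idx <- sites$chrom == cn
    ref_base[idx] <- substring(reference$sequences[[cn]], sites$pos[idx], sites$pos[idx])
  }
  sites$ref <- ref_base
  alt_choices <- vapply(ref_base, function(b) sample(setdiff(.BASES, b), 1), character(1))
  sites$alt <- unname(alt_choices)
  sites$is_dbsnp <- stats::runif(n) < config$dbsnp_fraction
  sites$genotype <- ifelse(stats::runif(n) < config$hom_fraction, "hom_alt", "het")
  het <- sites$genotype == "het"

  ## normal sample
  d <- .rpois_trunc(n, config$mean_depth)
  a <- stats::rbinom(n, d, ifelse(het, 0.5, 0.98))
  sites[[paste0("depth_", config$normal_sample)]] <- d
  sites[[paste0("alt_", config$normal_sample)]] <- a
  sites[[paste0("maf_", config$normal_sample)]] <- pmin(a / d, 1 - a / d)

  ## tumors
  for (t in config$tumor_samples) {
    lost_here <- sites$arm_id %in% config$lost_arms[[t]]
    deleted <- rep(NA_character_, n)
    affected <- lost_here & het
    deleted[affected] <- sample(c("ref", "alt"), sum(affected), replace = TRUE)
    p_alt <- rep(0.5, n)
    p_alt[!het] <- 0.98
    p_alt[affected] <- .loss_alt_fraction(rho, deleted[affected] == "alt")
    d <- .rpois_trunc(n, config$mean_depth)
    a <- stats::rbinom(n, d, p_alt)
    sites[[paste0("depth_", t)]] <- d
    sites[[paste0("alt_", t)]] <- a
    sites[[paste0("maf_", t)]] <- pmin(a / d, 1 - a / d)
    sites[[paste0("lost_allele_", t)]] <- deleted
  }
  rownames(sites) <- NULL
  attr(sites, "normal") <- config$normal_sample
  attr(sites, "tumors") <- config$tumor_samples
  sites
}

## Flattened position pools per collapsed trinucleotide class (1..32):
## interior usable positions over all chromosomes, excluded loci removed.
.class_pools <- function(reference, exclude = NULL) {
  sequences <- .ref_sequences(reference)
  excl <- list()
  if (!is.null(exclude) && length(exclude$pos) > 0) {
    excl <- split(as.integer(exclude$pos), normalize_chrom(exclude$chrom))
  }
  chroms <- names(sequences)
  chrom_all <- integer(0); pos_all <- integer(0); cls_all <- integer(0)
  for (ci in seq_along(chroms)) {
    cls <- .position_trinuc_class(sequences[[chroms[ci]]])
    e <- excl[[chroms[ci]]]
    if (!is.null(e)) cls[e] <- NA_integer_
    pos <- which(!is.na(cls))
    chrom_all <- c(chrom_all, rep.int(ci, length(pos)))
    pos_all <- c(pos_all, pos)
    cls_all <- c(cls_all, cls[pos])
  }
  o <- order(cls_all, method = "radix")
  counts <- tabulate(cls_all, nbins = 32L)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  pools <- vector("list", 32L)
  for (k in seq_len(32L)) {
    if (counts[k] > 0) {
      sl <- o[starts[k]:ends[k]]
      pools[[k]] <- list(chrom = chrom_all[sl], pos = pos_all[sl])
    } else {
      pools[[k]] <- list(chrom = integer(0), pos = integer(0))
    }
  }
  attr(pools, "chroms") <- chroms
  pools
}

#' Simulate per-caller somatic call sets with ground truth
#'
#' Places true somatic SNVs at reference positions whose pyrimidine-collapsed
#' trinucleotide matches contexts drawn from the planted signature (contexts
#' with no remaining positions are redrawn), assigns each variant one
#' sequencing reality (depth, alt reads at expected VAF `purity/2`), then
#' derives `n_callers` noisy views: each caller reports each true variant
#' with probability `caller_sensitivity` and adds Poisson(`private_fp_rate`)
#' private false positives never shared with another caller. A
#' `common_snp_fraction` of all candidate calls receives a population
#' frequency above 1% in the accompanying annotation.
#'
#' @param config A `sim_config`.
#' @param reference A `sim_reference`.
#' @param catalog A `signature_catalog` containing `config$signature_name`
#'   (or all names of `config$signature_mixture`).
#' @param exclude Optional data frame (`chrom`, `pos`) of loci to avoid
#'   (germline sites); guarantees somatic/germline disjointness.
#' @return List with `callsets` (per sample: per caller variant-call data
#'   frame), `annotation` (gene/consequence/pop_freq per candidate key), and
#'   `truth` (per-sample data frame of true variants with planted context and
#'   consequence, plus `planted_signature`).
#' @export
simulate_somatic_calls <- function(config, reference, catalog, exclude = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- .catalog_matrix(catalog)
  if (!is.null(config$signature_mixture)) {
    miss <- setdiff(names(config$signature_mixture), colnames(m))
    if (length(miss) > 0) stop("signature(s) not in catalog: ", paste(miss, collapse = ", "))
    sig_probs <- as.vector(m[, names(config$signature_mixture), drop = FALSE] %*%
                             config$signature_mixture)
    planted <- paste(names(config$signature_mixture), collapse = "+")
  } else {
    if (!config$signature_name %in% colnames(m))
      stop("signature not in catalog: ", config$signature_name)
    sig_probs <- m[, config$signature_name]
    planted <- config$signature_name
  }
  set.seed(.substream_seed(config$seed, "somatic"))
  pools <- .class_pools(reference, exclude = exclude)
  sequences <- .ref_sequences(reference)
  chroms <- names(sequences)
  labels <- context_labels()
  ## context -> trinucleotide class (1..32) and label alt allele
  label_tri <- match(paste0(substr(labels, 1, 1), substr(labels, 3, 3),
                            substr(labels, 7, 7)), .trinuc32())
  label_alt <- substr(labels, 5, 5)

  ## Uniform sampling without replacement from each class pool, with the
  ## permutation materialized lazily (pools are huge, demand is small).
  n_pool <- vapply(pools, function(p) length(p$pos), integer(1))
  used <- integer(32L)
  perm <- vector("list", 32L)
  take_from_class <- function(k, m) {
    m <- min(m, n_pool[k] - used[k])
    if (m <= 0) return(integer(0))
    need <- used[k] + m
    have <- length(perm[[k]])
    if (need > have) {
      new_len <- min(n_pool[k], max(need, 2L * have, 64L))
      if (have == 0L) {
        perm[[k]] <<- sample.int(n_pool[k], new_len)
      } else {
        remaining <- setdiff(seq_len(n_pool[k]), perm[[k]])
        perm[[k]] <<- c(perm[[k]],
                        remaining[sample.int(length(remaining), new_len - have)])
      }
    }
    out <- perm[[k]][(used[k] + 1L):(used[k] + m)]
    used[k] <<- used[k] + m
    out
  }

  ## place variants for contexts drawn from the signature; exhausted
  ## contexts are redrawn from the signature distribution
  place_contexts <- function(n_wanted) {
    chrom_v <- integer(0); pos_v <- integer(0); ctx_v <- integer(0)
    n_left <- n_wanted
    while (n_left > 0) {
      ctx <- sample.int(96L, n_left, replace = TRUE, prob = sig_probs)
      cls <- label_tri[ctx]
      placed <- 0L
      for (k in unique(cls)) {
        want <- which(cls == k)
        sel <- take_from_class(k, length(want))
        if (length(sel) > 0) {
          chrom_v <- c(chrom_v, pools[[k]]$chrom[sel])
          pos_v <- c(pos_v, pools[[k]]$pos[sel])
          ctx_v <- c(ctx_v, ctx[want[seq_along(sel)]])
          placed <- placed + length(sel)
        }
      }
      if (placed == 0L)
        stop("reference exhausted: cannot place ", n_left, " more somatic SNVs")
      n_left <- n_left - placed
    }
    list(chrom = chrom_v, pos = pos_v, ctx = ctx_v)
  }

  base_at <- function(chrom_idx, pos, offset = 0L) {
    out <- character(length(pos))
    for (ci in unique(chrom_idx)) {
      sel <- chrom_idx == ci
      out[sel] <- substring(sequences[[chroms[ci]]], pos[sel] + offset,
                            pos[sel] + offset)
    }
    out
  }

  nonsilent_snv_terms <- c("missense", "nonsense", "splicing", "nonstop")
  nonsilent_snv_probs <- c(0.70, 0.15, 0.10, 0.05)

  truth <- list()
  for (t in config$tumor_samples) {
    pl <- place_contexts(config$n_somatic)
    ref <- base_at(pl$chrom, pl$pos)
    alt <- ifelse(ref %in% c("C", "T"), label_alt[pl$ctx],
                  unname(.COMP[label_alt[pl$ctx]]))
    df <- data.frame(chrom = chroms[pl$chrom], pos = pl$pos, ref = ref,
                     alt = alt, context = labels[pl$ctx],
                     stringsAsFactors = FALSE)
    ## indel smoke set for truncating classification
    n_indel <- round(config$indel_fraction * config$n_somatic)
    if (n_indel > 0) {
      icls <- sample.int(32L, n_indel, replace = TRUE)
      ic <- integer(0); ip <- integer(0)
      for (k in unique(icls)) {
        sel <- take_from_class(k, sum(icls == k))
        ic <- c(ic, pools[[k]]$chrom[sel])
        ip <- c(ip, pools[[k]]$pos[sel])
      }
      if (length(ip) > 0) {
        b1 <- base_at(ic, ip)
        b2 <- base_at(ic, ip, offset = 1L)
        del <- stats::runif(length(ip)) < 0.5 & nchar(b2) == 1
        ind <- data.frame(
          chrom = chroms[ic], pos = ip,
          ref = ifelse(del, paste0(b1, b2), b1),
          alt = ifelse(del, b1, paste0(b1, sample(.BASES, length(ip), replace = TRUE))),
          context = NA_character_, stringsAsFactors = FALSE)
        df <- rbind(df, ind)
      }
    }
    df$sample <- rep(t, nrow(df))
    is_snv <- !is.na(df$context)
    df$consequence <- rep(NA_character_, nrow(df))
    df$consequence[is_snv] <- sample(nonsilent_snv_terms, sum(is_snv),
                                     replace = TRUE, prob = nonsilent_snv_probs)
    df$consequence[!is_snv] <- sample(c("frameshift_indel", "inframe_indel"),
                                      sum(!is_snv), replace = TRUE,
                                      prob = c(0.8, 0.2))
    ## one sequencing reality per true variant, shared by all callers
    df$depth <- .rpois_trunc(nrow(df), config$mean_depth)
    df$alt_depth <- stats::rbinom(nrow(df), df$depth,
                                  pmax(config$tumor_purity / 2, 0.02))
    df$alt_depth <- pmax(df$alt_depth, 1L)
    truth[[t]] <- df
  }

  ## caller views + private false positives
  set.seed(.substream_seed(config$seed, "callers"))
  callsets <- list()
  fp_rows <- list()
  for (t in config$tumor_samples) {
    df <- truth[[t]]
    per_caller <- list()
    for (cl in config$caller_names) {
      seen <- stats::runif(nrow(df)) < config$caller_sensitivity
      calls <- df[seen, c("chrom", "pos", "ref", "alt", "depth", "alt_depth"),
                  drop = FALSE]
      n_fp <- stats::rpois(1, config$private_fp_rate)
      if (n_fp > 0) {
        fcls <- sample.int(32L, n_fp, replace = TRUE)
        fc <- integer(0); fp <- integer(0)
        for (k in unique(fcls)) {
          sel <- take_from_class(k, sum(fcls == k))
          fc <- c(fc, pools[[k]]$chrom[sel])
          fp <- c(fp, pools[[k]]$pos[sel])
        }
        if (length(fp) > 0) {
          ref <- base_at(fc, fp)
          alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1),
                        character(1), USE.NAMES = FALSE)
          d <- .rpois_trunc(length(fp), config$mean_depth)
          a <- pmax(1L, stats::rbinom(length(fp), d, 0.1))
          fps <- data.frame(chrom = chroms[fc], pos = fp, ref = ref, alt = alt,
                            depth = d, alt_depth = a, stringsAsFactors = FALSE)
          calls <- rbind(calls, fps)
          fp_rows[[length(fp_rows) + 1]] <- cbind(fps, sample = t, caller = cl)
        }
      }
      per_caller[[cl]] <- variant_calls(calls$chrom, calls$pos, calls$ref,
                                        calls$alt, sample = t, callers = cl,
                                        depth = calls$depth,
                                        alt_depth = pmin(calls$alt_depth, calls$depth))
    }
    callsets[[t]] <- per_caller
  }

  ## annotation over the union of candidate keys
  set.seed(.substream_seed(config$seed, "annotation"))
  all_rows <- rbind(
    do.call(rbind, lapply(truth, function(df)
      cbind(df[, c("chrom", "pos", "ref", "alt")], consequence = df$consequence))),
    if (length(fp_rows) > 0)
      do.call(rbind, lapply(fp_rows, function(df)
        cbind(df[, c("chrom", "pos", "ref", "alt")], consequence = NA_character_)))
  )
  key <- paste(all_rows$chrom, all_rows$pos, all_rows$ref, all_rows$alt, sep = ":")
  ann <- all_rows[!duplicated(key), , drop = FALSE]
  need_csq <- is.na(ann$consequence)
  ann$consequence[need_csq] <- sample(
    c("missense", "synonymous", "noncoding"), sum(need_csq),
    replace = TRUE, prob = c(0.4, 0.3, 0.3))
  gene_pool <- c("APC", "PIK3CA", "ARID1A", "ATM", "MTOR", "MSH3", "NOTCH1",
                 "THBS1", "RIN1", "TP53", "KRAS", "MSH2", "MLH1",
                 sprintf("GENE%03d", 1:60))
  ann$gene <- sample(gene_pool, nrow(ann), replace = TRUE)
  u <- stats::runif(nrow(ann))
  ann$pop_freq <- NA_real_
  common <- u < config$common_snp_fraction
  rare <- !common & u < config$common_snp_fraction + 0.5 * (1 - config$common_snp_fraction)
  ann$pop_freq[common] <- stats::runif(sum(common), 0.011, 0.5)
  ann$pop_freq[rare] <- stats::runif(sum(rare), 0, 0.009)
  rownames(ann) <- NULL

  list(callsets = callsets, annotation = ann,
       truth = list(somatic = do.call(rbind, truth), planted_signature = planted))
}

#' Simulate a complete tumor-normal trio
#'
#' Runs [simulate_reference()], [simulate_germline_sites()] and
#' [simulate_somatic_calls()] under one root seed, with somatic loci
#' guaranteed disjoint from germline loci.
#'
#' @param config A `sim_config`.
#' @param catalog A `signature_catalog` (default the bundled demonstration
#'   catalog).
#' @return A `trio_sim`: list with `config`, `reference`, `germline`,
#'   `callsets`, `annotation`, `truth` (somatic truth, lost arms, planted
#'   signature).
#' @export
simulate_trio <- function(config, catalog = demo_signature_catalog()) {
  reference <- simulate_reference(config)
  germline <- simulate_germline_sites(config, reference)
  som <- simulate_somatic_calls(config, reference, catalog,
                                exclude = germline[, c("chrom", "pos")])
  out <- list(config = config, reference = reference, germline = germline,
              callsets = som$callsets, annotation = som$annotation,
              truth = list(somatic = som$truth$somatic,
                           lost_arms = config$lost_arms,
                           planted_signature = som$truth$planted_signature))
  class(out) <- "trio_sim"
  out
}

#' @export
print.trio_sim <- function(x, ...) {
  cat("Simulated tumor-normal trio (seed ", x$config$seed, ")\n", sep = "")
  cat("  normal:", x$config$normal_sample,
      " tumors:", paste(x$config$tumor_samples, collapse = ", "), "\n")
  cat("  germline sites:", nrow(x$germline),
      " somatic truth:", nrow(x$truth$somatic), "\n")
  if (length(x$truth$lost_arms) > 0) {
    for (t in names(x$truth$lost_arms)) {
      cat("  lost arms in ", t, ": ",
          paste(x$truth$lost_arms[[t]], collapse = ", "), "\n", sep = "")
    }
  }
  cat("  planted signature:", x$truth$planted_signature, "\n")
  invisible(x)
}

#' Write a simulated trio to disk
#'
#' Writes per-caller VCFs (`<sample>.<caller>.vcf`), the annotation TSV, the
#' reference FASTA, the arm BED, the germline-site table and the ground-truth
#' TSVs (somatic truth, lost arms).
#'
#' @param sim A `trio_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trio_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- nchar(sim$reference$sequences)
  for (t in names(sim$callsets)) {
    for (cl in names(sim$callsets[[t]])) {
      write_caller_vcf(sim$callsets[[t]][[cl]],
                       file.path(dir, paste0(t, ".", cl, ".vcf")),
                       contig_lengths = contigs)
    }
  }
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_reference_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_arm_bed(sim$reference$arms, file.path(dir, "arms.bed"))
  write_germline_sites(sim$germline, file.path(dir, "germline_sites.tsv"))
  utils::write.table(sim$truth$somatic, file.path(dir, "truth_somatic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lost <- data.frame(
    sample = rep(names(sim$truth$lost_arms), lengths(sim$truth$lost_arms)),
    arm = unlist(sim$truth$lost_arms, use.names = FALSE))
  utils::write.table(lost, file.path(dir, "truth_lost_arms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
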