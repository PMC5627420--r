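# high-quality site selection, window MAF curves, arm calls, LOH counts

make_sites <- function(n, depth = 40L, maf_normal = 0.45, maf_tumor = 0.45,
                       dbsnp = TRUE, genotype = "het") {
  df <- data.frame(
    chrom = "1", pos = seq_len(n) * 10L, ref = "C", alt = "T",
    arm_id = "1p", is_dbsnp = dbsnp, genotype = genotype,
    depth_blood = depth, alt_blood = round(depth * maf_normal),
    maf_blood = maf_normal,
    depth_tumorA = depth, alt_tumorA = round(depth * maf_tumor),
    maf_tumorA = maf_tumor, stringsAsFactors = FALSE)
  attr(df, "normal") <- "blood"
  attr(df, "tumors") <- "tumorA"
  df
}

test_that("coverage and normal-MAF boundaries follow the strict/inclusive rules", {
  s <- rbind(make_sites(1, depth = 20L),   # coverage exactly 20: dropped
             make_sites(1, depth = 21L),   # strictly greater: kept
             make_sites(1, maf_normal = 0.25),  # at least 0.25: kept
             make_sites(1, maf_normal = 0.24),  # below: dropped
             make_sites(1, dbsnp = FALSE),
             make_sites(1, genotype = "hom_alt"))
  attr(s, "normal") <- "blood"; attr(s, "tumors") <- "tumorA"
  hq <- select_hq_sites(s, site_filter_config())
  expect_equal(nrow(hq), 2)
  expect_setequal(hq$depth_blood, c(21L, 40L))
})

test_that("site selection equals the brute-force conjunction of its predicates", {
  set.seed(55)
  n <- 400
  s <- make_sites(n)
  s$depth_blood <- sample(10:60, n, replace = TRUE)
  s$depth_tumorA <- sample(10:60, n, replace = TRUE)
  s$maf_blood <- round(runif(n, 0, 0.5), 3)
  s$is_dbsnp <- runif(n) < 0.8
  s$genotype <- sample(c("het", "hom_alt"), n, replace = TRUE, prob = c(0.9, 0.1))
  cfg <- site_filter_config()
  hq <- select_hq_sites(s, cfg)
  manual <- s$depth_blood > 20 & s$depth_tumorA > 20 & s$is_dbsnp &
    s$genotype == "het" & s$maf_blood >= 0.25
  expect_equal(nrow(hq), sum(manual))
  expect_setequal(hq$pos, s$pos[manual])
  expect_false(is.unsorted(hq$pos))

  s2 <- s
  names(s2)[names(s2) == "depth_blood"] <- "depth_x"
  expect_error(select_hq_sites(s2, cfg), "normal")
})

test_that("window counts follow floor((n - size)/step) + 1", {
  wc <- window_config(window_size = 1000, step = 500)
  expect_equal(nrow(window_maf_curve(make_sites(2500), "tumorA", wc)), 4)
  expect_equal(nrow(window_maf_curve(make_sites(1000), "tumorA", wc)), 1)
  short <- window_maf_curve(make_sites(999), "tumorA", wc)
  expect_equal(nrow(short), 0)
  expect_true(attr(short, "insufficient_data"))
})

test_that("window summaries are permutation-invariant, bounded, and constant on constant input", {
  s <- make_sites(1500, maf_tumor = 0.5)
  wc <- window_config(window_size = 500, step = 250)
  curve <- window_maf_curve(s, "tumorA", wc)
  expect_true(all(curve$summary == 0.5))

  set.seed(77)
  s$maf_tumorA <- runif(1500, 0, 0.5)
  c1 <- window_maf_curve(s, "tumorA", window_config(window_size = 1500, step = 1500))
  s_perm <- s[sample(nrow(s)), ]  # same multiset inside the single window
  c2 <- window_maf_curve(s_perm, "tumorA", window_config(window_size = 1500, step = 1500))
  expect_equal(c1$summary, c2$summary)
  expect_true(all(c1$summary >= 0 & c1$summary <= 0.5))
})

test_that("arm calls separate one-copy losses from neutral arms", {
  cfg <- arm_call_config()
  expect_equal(call_arm_events(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), cfg), "neutral")
  # simulated purity-0.6 loss: tumor near (1-0.6)/(2-0.6) = 0.286
  expect_equal(call_arm_events(c(0.48, 0.47, 0.48), c(0.28, 0.29, 0.28), cfg), "loss")
  expect_equal(call_arm_events(c(0.48, 0.47), c(0.28, 0.29),
                               arm_call_config(min_windows = 3)),
               "insufficient_data")
  expect_error(call_arm_events(c(0.5, 0.5), c(0.5, 0.5, 0.5), cfg), "length")
})

test_that("LOH counting is monotone in its threshold and exact in the pure-tumor limit", {
  s <- make_sites(100, maf_tumor = 0.5)
  expect_equal(count_loh_sites(s, "tumorA", arm_call_config()), 0)

  set.seed(88)
  s$maf_tumorA <- runif(100, 0, 0.5)
  prev <- -1
  for (thr in c(0.02, 0.05, 0.1, 0.2, 0.5)) {
    cur <- count_loh_sites(s, "tumorA", arm_call_config(loh_site_max_maf = thr))
    expect_gte(cur, prev)
    prev <- cur
  }

  # purity 1: every het site on the lost arm loses the deleted allele entirely
  cfg <- sim_config(seed = 61, n_chromosomes = 1, arm_length = 2e5,
                    het_sites_per_arm = 500, tumor_purity = 1,
                    lost_arms = list(tumorA = "1p"), hom_fraction = 0)
  ref <- simulate_reference(cfg)
  g <- simulate_germline_sites(cfg, ref)
  hq <- select_hq_sites(g)
  on_p <- hq[hq$arm_id == "1p", ]
  expect_equal(count_loh_sites(on_p, "tumorA", arm_call_config()), nrow(on_p))
})

test_that("LOH counts match the closed-form binomial oracle at purity 0.8", {
  rho <- 0.8; lambda <- 40; thr <- 0.1; n_sites <- 2000
  cfg <- sim_config(seed = 62, n_chromosomes = 1, arm_length = 1e6,
                    het_sites_per_arm = n_sites, tumor_purity = rho,
                    mean_depth = lambda, lost_arms = list(tumorA = "1p"),
                    hom_fraction = 0)
  ref <- simulate_reference(cfg)
  g <- simulate_germline_sites(cfg, ref)
  lost <- g[g$arm_id == "1p", ]
  observed <- sum(lost$maf_tumorA < thr)

  # oracle: P(maf < thr) under Binomial(depth, f), depth ~ trunc-Poisson
  f <- (1 - rho) / (2 - rho)
  ds <- 1:200
  wd <- dpois(ds, lambda); wd <- wd / sum(wd)
  p_site <- sum(wd * vapply(ds, function(d) {
    ks <- 0:d
    sum(dbinom(ks, d, f)[pmin(ks / d, 1 - ks / d) < thr])
  }, numeric(1)))
  tol <- 4 * sqrt(n_sites * p_site * (1 - p_site))
  expect_lt(abs(observed - n_sites * p_site), tol)
})

test_that("the genome scan recovers planted arm losses and nothing else", {
  hits <- 0
  for (s in 1:3) {
    cfg <- sim_config(seed = 70 + s, n_chromosomes = 3, arm_length = 2e5,
                      het_sites_per_arm = 2000, tumor_purity = 0.6,
                      lost_arms = list(tumorA = "1p", tumorB = c("2p", "2q")),
                      n_somatic = 0, private_fp_rate = 0)
    ref <- simulate_reference(cfg)
    g <- simulate_germline_sites(cfg, ref)
    rep <- genome_scna_scan(g, ref$arms)
    called <- rep[rep$status == "loss", c("arm", "tumor")]
    want <- data.frame(arm = c("1p", "2p", "2q"),
                       tumor = c("tumorA", "tumorB", "tumorB"))
    ok <- nrow(called) == 3 &&
      setequal(paste(called$arm, called$tumor), paste(want$arm, want$tumor))
    hits <- hits + ok
  }
  expect_equal(hits, 3)
})

test_that("a fully neutral genome yields no loss calls", {
  cfg <- sim_config(seed = 80, n_chromosomes = 2, arm_length = 2e5,
                    het_sites_per_arm = 2000, n_somatic = 0,
                    private_fp_rate = 0)
  ref <- simulate_reference(cfg)
  g <- simulate_germline_sites(cfg, ref)
  rep <- genome_scna_scan(g, ref$arms)
  expect_true(all(rep$status == "neutral"))
})

test_that("loss detection is monotone non-decreasing in tumor purity", {
  detected <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(rho) {
    cfg <- sim_config(seed = 90, n_chromosomes = 1, arm_length = 2e5,
                      het_sites_per_arm = 2000, tumor_purity = rho,
                      lost_arms = list(tumorA = "1p"), n_somatic = 0,
                      private_fp_rate = 0)
    ref <- simulate_reference(cfg)
    g <- simulate_germline_sites(cfg, ref)
    rep <- genome_scna_scan(g, ref$arms)
    rep$status[rep$arm == "1p" & rep$tumor == "tumorA"] == "loss"
  }, logical(1))
  expect_false(is.unsorted(detected))  # FALSE..FALSE then TRUE..TRUE
})
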