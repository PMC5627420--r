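# 96-context classification, spectra, cosine matching, mixture refit

test_that("pyrimidine and purine representations map to the expected labels", {
  ref <- structure(list(sequences = c("1" = "ACGAGT"),
                        arms = data.frame(chrom = "1", arm = "p",
                                          start = 0L, end = 6L)),
                   class = "sim_reference")
  # reference trinucleotide ACG, C>T: an NCG-context transition
  v1 <- data.frame(chrom = "1", pos = 2L, ref = "C", alt = "T")
  expect_equal(classify_context(v1, ref), "A[C>T]G")
  # reference trinucleotide AGT, G>A: strand-collapses to A[C>T]T
  v2 <- data.frame(chrom = "1", pos = 5L, ref = "G", alt = "A")
  expect_equal(classify_context(v2, ref), "A[C>T]T")
})

test_that("exhaustive enumeration yields exactly 6 classes and 96 labels, all hit", {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (p5 in bases) for (mid in bases) for (p3 in bases) {
    for (alt in setdiff(bases, mid)) {
      rows[[length(rows) + 1]] <- data.frame(
        tri = paste0(p5, mid, p3), alt = alt, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)           # 64 trinucleotides x 3 alts = 192
  labels <- vapply(seq_len(nrow(df)), function(i) {
    ref <- structure(list(sequences = stats::setNames(df$tri[i], "1")),
                     class = "sim_reference")
    classify_context(data.frame(chrom = "1", pos = 2L,
                                ref = substr(df$tri[i], 2, 2), alt = df$alt[i]),
                     ref)
  }, character(1))
  expect_false(anyNA(labels))
  expect_equal(sort(unique(labels)), sort(context_labels()))  # all 96, nothing else
  classes <- unique(substr(labels, 3, 5))
  expect_equal(sort(classes), sort(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")))
  # every label hit exactly twice (once per strand representation)
  expect_true(all(table(labels) == 2))
})

test_that("a variant and its reverse-complement representation share a label", {
  set.seed(7)
  for (i in 1:25) {
    tri <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    mid <- substr(tri, 2, 2)
    alt <- sample(setdiff(c("A", "C", "G", "T"), mid), 1)
    fwd <- structure(list(sequences = c("1" = tri)), class = "sim_reference")
    rev <- structure(list(sequences = c("1" = revcomp(tri))), class = "sim_reference")
    l_fwd <- classify_context(data.frame(chrom = "1", pos = 2L, ref = mid, alt = alt), fwd)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    l_rev <- classify_context(data.frame(chrom = "1", pos = 2L,
                                         ref = comp[[mid]], alt = comp[[alt]]), rev)
    expect_equal(l_fwd, l_rev)
  }
})

test_that("reference mismatches abort and bad flanks are unclassifiable", {
  ref <- structure(list(sequences = c("1" = "ACGNT")), class = "sim_reference")
  expect_error(classify_context(data.frame(chrom = "1", pos = 2L, ref = "G", alt = "A"),
                                ref), "mismatch")
  # N flank -> NA
  expect_true(is.na(classify_context(
    data.frame(chrom = "1", pos = 3L, ref = "G", alt = "A"), ref)))
  # chromosome edge -> NA
  expect_true(is.na(classify_context(
    data.frame(chrom = "1", pos = 1L, ref = "A", alt = "C"), ref)))
  # non-SNV rejected
  expect_error(classify_context(data.frame(chrom = "1", pos = 2L, ref = "CG", alt = "C"),
                                ref), "SNV")
})

test_that("spectra conserve counts and place single variants in the right bin", {
  ref <- tiny_reference()
  empty <- build_spectrum(data.frame(chrom = character(0), pos = integer(0),
                                     ref = character(0), alt = character(0)),
                          ref, "s")
  expect_equal(empty$n_snv, 0L)
  expect_true(all(empty$counts == 0))

  # "1" = AACGTTGCAGT: position 3 has trinucleotide ACG
  one <- build_spectrum(data.frame(chrom = "1", pos = 3L, ref = "C", alt = "T"),
                        ref, "s")
  expect_equal(unname(one$counts["A[C>T]G"]), 1L)
  expect_equal(sum(one$counts), 1L)

  # non-SNV skipped with warning; conservation n_snv + skipped
  mixed <- data.frame(chrom = c("1", "1"), pos = c(3L, 4L),
                      ref = c("C", "GT"), alt = c("T", "G"))
  expect_warning(sp <- build_spectrum(mixed, ref, "s"), "non-SNV")
  expect_equal(sp$n_snv + sp$n_skipped, 1L)
})

test_that("spectrum of a planted signature approaches it in total variation", {
  catalog <- demo_signature_catalog()
  cfg <- sim_config(seed = 31, n_chromosomes = 1, arm_length = 1e6,
                    n_somatic = 300, het_sites_per_arm = 10)
  ref <- simulate_reference(cfg)
  som <- simulate_somatic_calls(cfg, ref, catalog)
  tr <- som$truth$somatic[som$truth$somatic$sample == "tumorA", ]
  sp <- build_spectrum(tr, ref, "tumorA")
  tv <- 0.5 * sum(abs(sp$counts / sp$n_snv - catalog$matrix[, "MMRD_like"]))
  expect_lt(tv, 0.15)
})

test_that("cosine matching is scale-invariant and detects orthogonality", {
  catalog <- demo_signature_catalog()
  u <- catalog$matrix[, "MMRD_like"]
  m <- cosine_match(u * 1000, catalog)
  expect_equal(m$best, "MMRD_like")
  expect_equal(m$best_similarity, 1.0, tolerance = 1e-12)
  expect_equal(cosine_match(u, catalog)$similarities, m$similarities,
               tolerance = 1e-12)

  # disjoint support
  a <- c(1, 0, 0); b <- c(0, 1, 1)
  expect_equal(cosine_similarity(a, b), 0)

  expect_error(cosine_match(rep(0, 96), catalog), "zero")
})

test_that("the MMR-deficient profile wins over decoys on simulated hypermutation", {
  catalog <- demo_signature_catalog()
  wins <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 300 + s, n_chromosomes = 1, arm_length = 1e6,
                      n_somatic = 300, het_sites_per_arm = 10)
    ref <- simulate_reference(cfg)
    som <- simulate_somatic_calls(cfg, ref, catalog)
    tr <- som$truth$somatic[som$truth$somatic$sample == "tumorA", ]
    sp <- build_spectrum(tr, ref, "tumorA")
    wins <- wins + (cosine_match(sp, catalog)$best == "MMRD_like")
  }
  expect_equal(wins, 5)
})

test_that("mixture refit recovers pure signatures and planted mixtures", {
  catalog <- demo_signature_catalog()
  # spectrum equal to a single signature -> weight 1
  fit <- mixture_refit(catalog$matrix[, "APOBEC_like"] * 500, catalog)
  expect_equal(unname(fit$weights["APOBEC_like"]), 1, tolerance = 1e-6)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)

  # 50/50 planted mixture of two well-separated signatures, 2000 SNVs
  cfg <- sim_config(seed = 41, n_chromosomes = 1, arm_length = 4e6,
                    n_somatic = 2000, het_sites_per_arm = 10,
                    signature_mixture = c(MMRD_like = 0.5, CtoA_heavy = 0.5))
  ref <- simulate_reference(cfg)
  som <- simulate_somatic_calls(cfg, ref, catalog)
  tr <- som$truth$somatic[som$truth$somatic$sample == "tumorA", ]
  sp <- build_spectrum(tr, ref, "tumorA")
  fit2 <- mixture_refit(sp, catalog)
  expect_lt(abs(fit2$weights[["MMRD_like"]] - 0.5), 0.1)
  expect_lt(abs(fit2$weights[["CtoA_heavy"]] - 0.5), 0.1)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)

  # single-signature catalog: weight trivially 1
  one <- list(context_labels = catalog$context_labels,
              matrix = catalog$matrix[, "Flat", drop = FALSE])
  class(one) <- "signature_catalog"
  expect_equal(unname(mixture_refit(rep(1, 96), one)$weights), 1)
})
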