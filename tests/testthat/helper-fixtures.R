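# shared fixtures and independent oracles

# tiny hand-written reference for context tests
tiny_reference <- function() {
  structure(list(
    sequences = c("1" = "AACGTTGCAGT", "2" = "TTACGGCA"),
    arms = data.frame(chrom = c("1", "1", "2", "2"),
                      arm = c("p", "q", "p", "q"),
                      start = c(0L, 6L, 0L, 4L),
                      end = c(6L, 11L, 4L, 8L),
                      stringsAsFactors = FALSE)),
    class = "sim_reference")
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chromosomes = 2, arm_length = 1e5,
               het_sites_per_arm = 300, n_somatic = 100)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# independent two-sided Fisher p by exhaustive hypergeometric enumeration,
# probabilities from exact log-binomials (standard two-sided rule: sum of
# outcome probabilities not exceeding the observed one, within relative
# tolerance 1e-7)
fisher_p_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); m <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, m - r2):min(r1, m)
  p <- exp(lchoose(r1, ks) + lchoose(r2, m - ks) - lchoose(n, m))
  sum(p[p <= p[ks == tab[1, 1]] * (1 + 1e-7)])
}

# brute-force consensus support count over arbitrary caller call sets
brute_force_consensus_keys <- function(callsets, min_callers) {
  keys <- lapply(callsets, function(cs) unique(variant_key(cs)))
  support <- table(unlist(keys))
  names(support)[support >= min_callers]
}
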