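#' X/autosome diversity ratio under the neutral coalescent
#'
#' Runs paired replicate loci through [simulate_population()] — the same
#' child seed drives the X and the autosomal genealogy of a locus, so the
#' ratio of mean diversities is estimated with common random numbers — and
#' summarises mean silent-site diversity per mode. With equal numbers of
#' breeding males and females the expected ratio is 3/4, emerging from the
#' copy-count bookkeeping of the simulator rather than from any hard-coded
#' constant.
#'
#' @param n_loci replicate loci per mode.
#' @param n_males,n_females breeding population sizes.
#' @param theta autosomal-scale diversity per silent site.
#' @param n_individuals diploid individuals sampled per locus.
#' @param L locus length in codons.
#' @param seed master seed (per-locus child seeds are derived from it).
#' @return list with `ratio`, `pi_x`, `pi_a`, `n_loci`.
#' @export
ploidy_diversity_ratio <- function(n_loci = 1000, n_males = 500,
                                   n_females = 500, theta = 0.01,
                                   n_individuals = 5, L = 1500, seed = 1) {
  pi_x <- pi_a <- numeric(n_loci)
  for (i in seq_len(n_loci)) {
    s <- child_seed(seed, paste0("locus", i))
    px <- simulate_population(n_males, n_females, "X", theta,
                              n_individuals, L, seed = s)
    pa <- simulate_population(n_males, n_females, "autosome", theta,
                              n_individuals, L, seed = s)
    pi_x[i] <- nucleotide_diversity(px, px$silent_sites)$pi
    pi_a[i] <- nucleotide_diversity(pa, pa$silent_sites)$pi
  }
  list(ratio = mean(pi_x) / mean(pi_a), pi_x = mean(pi_x),
       pi_a = mean(pi_a), n_loci = n_loci)
}
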