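write_fasta2 <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(rbind(paste0(">", names(seqs)), seqs)), f)
  f
}

test_that("IUPAC diploid reading expands heterozygotes case-insensitively", {
  p <- read_diploid_fasta(write_fasta2(c(i1 = "ARNy", i2 = "agc-")))
  am <- fasterx:::allele_matrix(p)
  expect_equal(am[1:2, 2], c("A", "G"))       # R -> A/G
  expect_true(all(is.na(am[1:2, 3])))          # N -> missing
  expect_equal(am[3:4, 3], c("C", "C"))        # lowercase c
  expect_equal(am[1:2, 4], c("C", "T"))        # lowercase y -> C/T
  expect_true(all(is.na(am[3:4, 4])))          # gap
  expect_error(read_diploid_fasta(write_fasta2(c(i1 = "AXG"))),
               "unknown symbol 'X' in 'i1' at position 2")
})

test_that("the silent mask is four-fold third positions of the reference", {
  # GGC (Gly, four-fold) -> position 3 masked; ATG (Met) -> nothing
  expect_equal(silent_site_mask("GGCATG"), 3)
  ref <- "GGAGCTATGCATACT"  # GGA, GCT, ATG, CAT, ACT
  m <- silent_site_mask(ref)
  expect_equal(m, c(3, 6, 15))
  gcd <- genetic_code()
  al <- codon_alignment(c(r = ref))
  expect_equal(length(m), sum(gcd$fourfold[al$codons[1, ]]))
  # the synonymous mode can only widen the mask
  expect_true(all(m %in% silent_site_mask(ref, mode = "synonymous")))
})

test_that("per-site heterozygosity follows the unbiased pairwise formula", {
  # 5 diploids: one site with allele counts 9/1 among 10 copies
  m <- matrix("A", 5, 10)
  m[1, 4] <- "R"
  panel <- structure(list(individuals = paste0("i", 1:5), seq = m),
                     class = "diploid_panel")
  nd <- nucleotide_diversity(panel, mask = 1:10)
  expect_equal(nd$S, 1L)
  expect_equal(nd$theta_pi_total, 2 * 9 * 1 / (10 * 9))
  expect_equal(nd$pi, 0.2 / 10)
  # monomorphic panel
  m0 <- matrix("A", 3, 6)
  p0 <- structure(list(individuals = paste0("i", 1:3), seq = m0),
                  class = "diploid_panel")
  expect_equal(nucleotide_diversity(p0)$pi, 0)
})

test_that("pi is invariant to duplication, ordering and phasing", {
  m <- matrix(c("A", "R", "G", "C", "C", "Y"), 2, 3, byrow = TRUE)
  panel <- structure(list(individuals = c("i1", "i2"), seq = m),
                     class = "diploid_panel")
  base <- nucleotide_diversity(panel, min_alleles = 4)$pi
  # duplicating every individual leaves the allele frequencies unchanged;
  # with the unbiased k/(k-1) estimator that is an exact factor relation
  dup <- structure(list(individuals = paste0("i", 1:4),
                        seq = m[c(1, 2, 1, 2), ]),
                   class = "diploid_panel")
  expect_equal(nucleotide_diversity(dup, min_alleles = 4)$pi,
               base * (3 / 4) * (8 / 7))
  swap <- structure(list(individuals = c("i2", "i1"), seq = m[2:1, ]),
                    class = "diploid_panel")
  expect_equal(nucleotide_diversity(swap, min_alleles = 4)$pi, base)
  # same per-site allele counts, different phasing across individuals:
  # two homozygotes A|A + G|G versus two heterozygotes A|G + A|G
  hom <- structure(list(individuals = c("i1", "i2"),
                        seq = matrix(c("A", "G"), 2, 1)),
                   class = "diploid_panel")
  het <- structure(list(individuals = c("i1", "i2"),
                        seq = matrix(c("R", "R"), 2, 1)),
                   class = "diploid_panel")
  expect_equal(nucleotide_diversity(het, min_alleles = 4)$pi,
               nucleotide_diversity(hom, min_alleles = 4)$pi)
})

test_that("Tajima's D matches its hand-evaluated constants", {
  # S = 0: undefined, flagged, never 0
  r0 <- tajimas_d(0, 10, 0)
  expect_false(r0$defined)
  expect_true(is.na(r0$D))
  # constructed equality of the two theta estimators
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(5, 10, 5 / a1)$D, 0)
  # hand-evaluated: n = 4 alleles, 3 sites each with counts 2/2
  # (theta_pi = 2), constants computed by hand
  expect_equal(tajimas_d(3, 4, 2)$D, 2.01186954041, tolerance = 1e-9)
  expect_error(tajimas_d(1, 3, 0.5), "at least 4")
})

test_that("diversity summaries tie the mask and estimators together", {
  panel <- simulate_population(200, 200, "autosome", theta = 0.02,
                               n_individuals = 5, L = 300, seed = 42)
  ds <- diversity_summary(panel, gene = "g1")
  expect_equal(ds$gene, "g1")
  expect_equal(ds$n_silent_sites, length(panel$silent_sites))
  expect_true(ds$pi >= 0)
  expect_true(ds$S == 0 || ds$d_defined)
})
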