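test_that("alignment simulation is reproducible and honours omega = 0", {
  tr <- silene_species_tree()
  a1 <- simulate_codon_alignment(tr, 60, omega = 0.3, seed = 99)
  a2 <- simulate_codon_alignment(tr, 60, omega = 0.3, seed = 99)
  expect_identical(a1$codons, a2$codons)
  a3 <- simulate_codon_alignment(tr, 60, omega = 0.3, seed = 100)
  expect_false(identical(a1$codons, a3$codons))
  # omega = 0: every between-taxon codon difference is synonymous
  gcd <- genetic_code()
  a0 <- simulate_codon_alignment(tr, 400, omega = 0, seed = 7)
  for (s in seq_len(a0$n_sites))
    expect_length(unique(gcd$aa[a0$codons[, s]]), 1)
})

test_that("gene sets carry their truth and class bookkeeping", {
  cfg <- simulation_config(n_autosomal = 10, n_x_nonhemizygous = 10,
                           n_x_hemizygous = 10, n_par = 0, L = 30,
                           seed = 3)
  out <- withr::local_tempdir()
  meta <- simulate_gene_set(cfg, out_dir = out)
  expect_length(list.files(out, pattern = "\\.fasta$"), 30)
  expect_equal(nrow(meta), 30)
  expect_true(file.exists(file.path(out, "species_tree.nwk")))
  expect_true(file.exists(file.path(out, "metadata.tsv")))
  # true foreground omega is the stored background omega times the class
  # multiplier, verbatim
  expect_equal(meta$true_omega_fore,
               meta$true_omega_back * cfg$fg_multiplier[meta$class],
               ignore_attr = TRUE)
  expect_equal(sum(meta$class == "x_hemizygous"), 10)
  # metadata truth is independent of gene order (stable hashed seeds)
  meta2 <- simulate_gene_set(cfg)
  expect_equal(meta$true_omega_back, meta2$true_omega_back)
})

test_that("default gene-class proportions mirror the study design", {
  cfg <- simulation_config()
  n_x <- cfg$n_x_nonhemizygous + cfg$n_x_hemizygous
  n_tot <- cfg$n_autosomal + n_x  # PAR excluded from the contrast
  expect_equal(n_x / n_tot, 204 / (204 + 925), tolerance = 0.05)
  expect_equal(cfg$n_x_nonhemizygous / n_x, 0.8, tolerance = 0.05)
})

test_that("population panels are seeded, ploidy-aware and bounded", {
  p1 <- simulate_population(50, 50, "X", 0.01, 4, 60, seed = 5)
  p2 <- simulate_population(50, 50, "X", 0.01, 4, 60, seed = 5)
  expect_identical(p1$seq, p2$seq)
  expect_equal(dim(p1$seq), c(4L, 180L))
  # theta = 0 -> monomorphic, pi = 0
  p0 <- simulate_population(50, 50, "autosome", 1e-12, 4, 60, seed = 5)
  expect_equal(nucleotide_diversity(p0, p0$silent_sites)$pi, 0)
  # sampling more individuals than females errors
  expect_error(simulate_population(50, 3, "X", 0.01, 4, 60), "exceeds")
  expect_error(simulate_population(0, 5, "X", 0.01, 2, 60), "each sex")
  expect_error(fasterx:::pair_coal_prob("Y", 10, 10), "mode")
})

test_that("pair-coalescence bookkeeping reflects copy numbers", {
  # with equal sex counts the X rate must exceed the autosomal rate
  # (fewer copies), and equalising copy numbers equalises the rates
  pA <- fasterx:::pair_coal_prob("autosome", 100, 100)
  pX <- fasterx:::pair_coal_prob("X", 100, 100)
  expect_gt(pX, pA)
  expect_equal(pA, 1 / 400)  # 2N copies in 2N individuals
  # female-biased sex ratio pushes the X rate towards the autosomal one
  expect_lt(abs(fasterx:::pair_coal_prob("X", 10, 1e7) /
                  fasterx:::pair_coal_prob("autosome", 10, 1e7) - 1), 0.2)
})

test_that("expression simulation is seeded with a null that stays null", {
  e1 <- simulate_expression(50, seed = 11)
  e2 <- simulate_expression(50, seed = 11)
  expect_identical(e1$expr, e2$expr)
  expect_equal(length(e1$sex), 23 + 34)
  # no biased genes: the flag stage recovers ~none at p < 0.001
  e0 <- simulate_expression(400, biased_fraction = 0, seed = 13)
  fb <- female_bias_flag(e0$expr, e0$sex)
  expect_lte(sum(fb$female_biased), 2)
})

test_that("a 4x female effect is recovered with high power", {
  ex <- simulate_expression(150, biased_fraction = 0.5, effect = 4,
                            seed = 21)
  fb <- female_bias_flag(ex$expr, ex$sex)
  expect_gte(mean(fb$female_biased[ex$truth]), 0.9)
})

test_that("child seeds are stable and order-independent", {
  s1 <- fasterx:::child_seed(42, "gene0001")
  expect_identical(s1, fasterx:::child_seed(42, "gene0001"))
  expect_false(s1 == fasterx:::child_seed(42, "gene0002"))
  expect_false(s1 == fasterx:::child_seed(43, "gene0001"))
})
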