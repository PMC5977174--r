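tree6 <- silene_species_tree()

test_that("nested fits respect the likelihood ordering", {
  al <- simulate_codon_alignment(tree6, 150, omega = 0.3, seed = 21)
  m1 <- fit_model(al, tree6, codon_model("M1a"), seed = 1, n_starts = 1)
  m2 <- fit_model(al, tree6, codon_model("M2a"), seed = 1, n_starts = 1,
                  init = list(omega0 = m1$par$omega0,
                              p0 = m1$par$p0 * 0.999,
                              p1 = (1 - m1$par$p0) * 0.99, omega2 = 1.001,
                              kappa = m1$par$kappa, scale = m1$par$scale))
  expect_gte(m2$lnL, m1$lnL - 1e-6)
  br <- fit_branch_two_ratio(al, tree6, dioecious_taxa(), seed = 1,
                             n_starts = 1)
  expect_gte(br$two$lnL, br$one$lnL - 1e-6)
})

test_that("the M7/M8 beta-law pair respects nesting", {
  al <- simulate_codon_alignment(tree6, 80,
                                 classes = data.frame(prob = c(0.7, 0.3),
                                                      w_bg = c(0.1, 1),
                                                      w_fg = c(0.1, 1)),
                                 seed = 14)
  m7 <- fit_model(al, tree6, codon_model("M7", ncat = 5), seed = 1,
                  n_starts = 1)
  m8 <- fit_model(al, tree6, codon_model("M8", ncat = 5), seed = 1,
                  n_starts = 1,
                  init = list(p = m7$par$p, q = m7$par$q, p0 = 0.999,
                              omega2 = 1.001, kappa = m7$par$kappa,
                              scale = m7$par$scale))
  expect_gte(m8$lnL, m7$lnL - 1e-6)
  # equal-probability beta discretisation preserves the distribution mean
  for (pq in list(c(0.5, 1.5), c(2, 2), c(0.2, 0.4))) {
    w <- fasterx:::beta_categories(pq[1], pq[2], 10)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(mean(w), pq[1] / sum(pq), tolerance = 1e-6)
    expect_true(all(diff(w) >= 0))
  }
})

test_that("an invariant alignment is reported as a boundary fit", {
  seq <- paste(rep(c("ATG", "GCT", "AAA", "CCG"), 25), collapse = "")
  al <- codon_alignment(setNames(rep(seq, 6), tree6$tip.label))
  f <- fit_model(al, tree6, codon_model("M0"), seed = 1, n_starts = 1)
  expect_true(f$boundary)  # branch scale collapses to its lower bound
  expect_lt(f$par$scale, 2e-4)
})

test_that("one-ratio omega is recovered from its own simulation", {
  al <- simulate_codon_alignment(tree6, 800, kappa = 2, omega = 0.2,
                                 seed = 31)
  f <- fit_model(al, tree6, codon_model("M0"), seed = 1, n_starts = 1)
  expect_true(f$convergence)
  expect_gt(f$par$omega, 0.15)
  expect_lt(f$par$omega, 0.25)
  expect_gt(f$par$kappa, 1.5)
  expect_lt(f$par$kappa, 2.6)
})

test_that("full branch-length estimation reproduces the generating tree", {
  al <- simulate_codon_alignment(tree6, 600, omega = 0.3, seed = 8)
  f <- fit_model(al, tree6, codon_model("M0"), seed = 1, n_starts = 1,
                 branch_lengths = "full")
  expect_true(f$convergence)
  expect_equal(sum(f$tree$edge.length), sum(tree6$edge.length),
               tolerance = 0.25)
})

test_that("the LRT machinery follows its contract", {
  r <- lrt(-100, -100, 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r <- lrt(-100 + 5.991 / 2, -100, 2)
  expect_equal(r$p, 0.05, tolerance = 1e-3)
  expect_warning(r <- lrt(-100.0001, -100, 1), "clamped")
  expect_equal(r$statistic, 0)
  expect_error(lrt(-1, -2, 0), "df")
})

test_that("LRT df is validated against the known nested pairs", {
  al <- simulate_codon_alignment(tree6, 60, omega = 0.3, seed = 5)
  m1 <- fit_model(al, tree6, codon_model("M1a"), seed = 1, n_starts = 1,
                  maxit = 20)
  m2 <- fit_model(al, tree6, codon_model("M2a"), seed = 1, n_starts = 1,
                  maxit = 20)
  expect_error(lrt(m2, m1, 1), "does not match")
  expect_silent(suppressWarnings(lrt(m2, m1, 2)))
})
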