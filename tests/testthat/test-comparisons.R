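test_that("gene classification builds the published strata", {
  md <- data.frame(gene = paste0("g", 1:5),
                   linkage = c("autosomal", "X", "X", "PAR", "unknown"),
                   hemizygous = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  cl <- classify_genes(md)
  expect_equal(cl$genes$stratum,
               c("autosomal", "x_nonhemizygous", "x_hemizygous"))
  expect_setequal(cl$excluded$gene, c("g4", "g5"))
  md$hemizygous[1] <- TRUE
  expect_error(classify_genes(md), "conflicting")
})

test_that("female-bias flagging is one-sided by design", {
  set.seed(8)
  expr <- rbind(equal = rep(10, 10),
                female_up = c(rep(1, 5), rep(100, 5)),
                male_up = c(rep(100, 5), rep(1, 5)),
                flat = rep(3, 10))
  sex <- rep(c("male", "female"), each = 5)
  expr[1, ] <- expr[1, ] + rnorm(10, 0, 0.1)
  expr[2, ] <- expr[2, ] * exp(rnorm(10, 0, 0.05))
  expr[3, ] <- expr[3, ] * exp(rnorm(10, 0, 0.05))
  fb <- female_bias_flag(expr, sex)
  expect_false(fb$female_biased[1])
  expect_true(fb$female_biased[2])
  expect_false(fb$female_biased[3])   # male-biased never flagged
  expect_true(fb$untestable[4])
  expect_error(female_bias_flag(expr[, 1:3], sex[1:3]), "2 individuals")
})

test_that("the 2x2 chi-squared reproduces the published example", {
  # 29 of 204 X-linked vs 128 of 925 autosomal significant genes
  r <- chi2_2x2(29, 204 - 29, 128, 925 - 128)
  expect_equal(round(r$p, 1), 0.9)
  expect_equal(r$df, 1)
  # equal proportions at large n
  expect_gt(chi2_2x2(500, 500, 500, 500)$p, 0.99)
  r0 <- chi2_2x2(10, 10, 10, 10)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  z <- chi2_2x2(0, 0, 5, 5)
  expect_equal(z$p, 1)
  expect_equal(z$note, "zero margin")
})

test_that("distribution tests follow the documented conventions", {
  r <- distribution_tests(rep(1, 5), rep(1, 5), kind = "wilcoxon")
  expect_equal(r$p, 1)
  expect_equal(r$note, "all values tied")
  # W convention: pairs where the first group exceeds the second
  w <- distribution_tests(c(1, 2, 3), c(4, 5, 6), kind = "wilcoxon")
  expect_equal(w$statistic, 0)
  w2 <- distribution_tests(c(4, 5, 6), c(1, 2, 3), kind = "wilcoxon")
  expect_equal(w2$statistic, 9)
  expect_true(is.finite(distribution_tests(rnorm(10), rnorm(10))$p))
})

test_that("a 2-sigma shift is detected in nearly every replicate", {
  set.seed(31)
  hits <- vapply(1:20, function(i) {
    a <- rnorm(50)
    b <- rnorm(50, 2)
    c(distribution_tests(a, b, "t")$p < 0.001,
      distribution_tests(a, b, "wilcoxon")$p < 0.001)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})

test_that("the scan isolates failures and keeps its books straight", {
  cfg <- simulation_config(n_autosomal = 2, n_x_nonhemizygous = 2,
                           n_x_hemizygous = 0, n_par = 1, L = 90, seed = 17)
  meta <- simulate_gene_set(cfg)
  aligns <- attr(meta, "alignments")
  names(aligns) <- meta$gene
  # sabotage one gene with an empty alignment to exercise isolation
  aligns[[2]] <- codon_alignment(setNames(rep("ATG", 2), c("a", "b")))
  sc <- run_scan(aligns, cfg$tree, meta, dioecious_taxa(),
                 models = "branch", seed = 5, n_starts = 1)
  expect_true(meta$gene[2] %in% sc$exclusions$gene)
  analysed <- unique(sc$lrt$gene)
  expect_equal(length(analysed) + nrow(sc$exclusions), nrow(meta))
  s <- sc$summary
  expect_equal(sum(s$n_genes[s$stratum %in% c("x_all", "autosomal")]),
               length(analysed))
  expect_true(all(s$sig_01 <= s$sig_05))
  # deterministic given inputs and seed
  sc2 <- run_scan(aligns, cfg$tree, meta, dioecious_taxa(),
                  models = "branch", seed = 5, n_starts = 1)
  expect_identical(sc$lrt, sc2$lrt)
  expect_identical(sc$summary, sc2$summary)
})

test_that("delta-omega ratios are guarded against vanishing denominators", {
  lrt_tab <- data.frame(gene = c("g1", "g2"), test = "branch",
                        statistic = 1, df = 1, p = 0.5,
                        omega_fore = c(0.4, 0.2),
                        omega_back = c(0.2, 1e-5), omega0 = NA,
                        p_switched = NA, omega2 = NA)
  genes <- data.frame(gene = c("g1", "g2"),
                      stratum = c("autosomal", "x_nonhemizygous"))
  dw <- fasterx:::delta_omega_table(lrt_tab, genes)
  expect_equal(dw$delta_omega[dw$gene == "g1"], 2)
  expect_false(dw$ratio_defined[dw$gene == "g2"])
  expect_true(is.na(dw$delta_omega[dw$gene == "g2"]))
})
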