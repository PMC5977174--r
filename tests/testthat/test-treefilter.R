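# GTR+Gamma likelihood at given parameters by direct enumeration over the
# internal state of a 3-taxon tree (4^1 states, mixture over gamma rates).
enum_gtr_site_lnl <- function(bases, fit) {
  bf <- fit$bf
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- fit$Q
  S <- S + t(S)
  Q <- S * rep(bf, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))
  rates <- phangorn::discrete.gamma(fit$shape, fit$k)
  el <- fit$tree$edge.length[match(1:3, fit$tree$edge[, 2])]
  ord <- match(fit$tree$tip.label, rownames(bases))
  pmat <- function(t) {
    e <- eigen(diag(sqrt(bf)) %*% Q %*% diag(1 / sqrt(bf)),
               symmetric = TRUE)
    (diag(1 / sqrt(bf)) %*% e$vectors) %*%
      (exp(e$values * t) * (t(e$vectors) %*% diag(sqrt(bf))))
  }
  vapply(seq_len(ncol(bases)), function(s) {
    tot <- 0
    for (r in rates) {
      P <- lapply(el * r, pmat)
      v <- bf
      for (i in 1:3) {
        b <- bases[ord[i], s]
        if (!is.na(b)) v <- v * P[[i]][, match(b, c("A", "C", "G", "T"))]
      }
      tot <- tot + sum(v) / fit$k
    }
    log(tot)
  }, 0)
}

test_that("four-fold column extraction follows the all-taxa rule", {
  al <- codon_alignment(c(a = "GGATTACAT", b = "GGGTTGCAT",
                          c = "GGTCTACAT"))
  # site 1: GGA/GGG/GGT all Gly (four-fold) -> kept, third positions
  # site 2: TTA (Leu, two-fold third position) -> excluded even though
  #         CTA would be four-fold
  # site 3: CAT His (two-fold) -> excluded
  nuc <- fourfold_columns(al)
  expect_equal(ncol(nuc$bases), 1)
  expect_equal(unname(nuc$bases[, 1]), c("A", "G", "T"))
})

test_that("a single non-four-fold taxon excludes the column", {
  al <- codon_alignment(c(a = "GGA", b = "GGG", c = "AAA"))
  expect_equal(ncol(fourfold_columns(al)$bases), 0)
  # but missing codons do not veto the column
  al2 <- codon_alignment(c(a = "GGA", b = "GGG", c = "---"))
  nuc2 <- fourfold_columns(al2)
  expect_equal(ncol(nuc2$bases), 1)
  expect_true(is.na(nuc2$bases[3, 1]))
})

test_that("the supermatrix missing-data rule is strictly greater than", {
  mk <- function(col) codon_alignment(setNames(
    ifelse(col, "GGA", "---"), paste0("t", 1:6)))
  four_missing <- mk(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))   # 66.7%
  three_missing <- mk(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))   # 50%
  full <- mk(rep(TRUE, 6))
  sm <- build_supermatrix(list(full, three_missing, four_missing))
  expect_equal(ncol(sm$bases), 2)  # the 66.7% column is dropped
  expect_equal(unname(attr(sm, "gene_offsets")), c(1L, 1L, 0L))
  expect_error(build_supermatrix(list(four_missing)), "max_missing")
})

test_that("per-site GTR+Gamma likelihoods match enumeration and sum", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.3,c:0.2);")
  set.seed(2)
  m <- matrix(sample(c("A", "C", "G", "T"), 30, TRUE), 3, 10,
              dimnames = list(c("a", "b", "c"), NULL))
  nuc <- structure(list(taxa = c("a", "b", "c"), bases = m),
                   class = "nuc_alignment")
  res <- gtr_gamma_site_lnl(nuc, tr, k = 4)
  expect_equal(sum(res$site_lnl), res$lnl, tolerance = 1e-9)
  expect_equal(res$site_lnl, enum_gtr_site_lnl(m, res$fit),
               tolerance = 1e-8)
})

test_that("a large gamma shape recovers the rate-homogeneous likelihood", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.3,c:0.2);")
  set.seed(5)
  m <- matrix(sample(c("A", "C", "G", "T"), 60, TRUE), 3, 20,
              dimnames = list(c("a", "b", "c"), NULL))
  nuc <- structure(list(taxa = c("a", "b", "c"), bases = m),
                   class = "nuc_alignment")
  hom <- gtr_gamma_site_lnl(nuc, tr, k = 1, optimise = FALSE)
  big <- gtr_gamma_site_lnl(nuc, tr, k = 4, optimise = FALSE, shape = 1e6)
  expect_equal(big$lnl, hom$lnl, tolerance = 1e-4)
})

test_that("the SH-test honours its trivial contracts", {
  x <- rnorm(50)
  expect_equal(sh_test(x, x), 1)
  set.seed(1)
  gene <- rnorm(100, -3)
  species <- gene - 0.5  # gene tree better at every site
  expect_lt(sh_test(gene, species, seed = 2), 0.001)
  expect_identical(sh_test(gene, species + rnorm(100, 0, 0.01), seed = 7),
                   sh_test(gene, species + rnorm(100, 0, 0.01), seed = 7))
  expect_error(sh_test(x[1:5], x[1:5]), "10 sites")
  expect_error(sh_test(x, x[1:10]), "differ")
})

test_that("BH adjustment matches the hand step-up and flags keeps", {
  r <- bh_fdr(rep(0.01, 10))
  expect_equal(r$p_adjusted, rep(0.01, 10))
  r2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r2$p_adjusted, rep(0.04, 4))
  r3 <- bh_fdr(runif(20))
  o <- order(r3$p)
  expect_true(all(diff(r3$p_adjusted[o]) >= -1e-15))
  expect_equal(nrow(bh_fdr(numeric(0))), 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the conflict filter keeps concordant genes, whatever the order", {
  tr <- silene_species_tree()
  aligns <- lapply(1:4, function(i)
    simulate_codon_alignment(tr, 250, omega = 0.2, seed = 100 + i))
  names(aligns) <- paste0("g", 1:4)
  res <- filter_gene_trees(aligns, tr, n_boot = 200, seed = 3)
  expect_true(all(res$keep[!is.na(res$p)]))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  # keep/drop decisions do not depend on gene input order
  res_rev <- filter_gene_trees(rev(aligns), tr, n_boot = 200, seed = 3)
  m <- merge(res, res_rev, by = "gene")
  expect_equal(m$p.x, m$p.y)
  expect_equal(m$keep.x, m$keep.y)
})
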