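## Comparison layer: gene classification, female-bias flagging, the
## class-wise tests, and the per-gene model scan with its LRT count tables.

#' Classify genes into analysis strata
#'
#' Builds the four analysis strata — autosomal, X hemizygous,
#' X non-hemizygous — and drops PAR and unknown-linkage genes (with counts
#' recorded), since those are excluded from every X/autosome contrast.
#'
#' @param metadata data.frame with columns `gene`, `linkage` (`autosomal`,
#'   `X`, `PAR`, `unknown`), `hemizygous` (logical; meaningful for X only)
#'   and optionally `female_biased`, `path`.
#' @return list with `genes` (kept records, plus a `stratum` column) and
#'   `excluded` (data.frame of dropped genes with reasons).
#' @export
classify_genes <- function(metadata) {
  need <- c("gene", "linkage", "hemizygous")
  if (!all(need %in% names(metadata)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  m <- metadata
  bad <- m$linkage == "autosomal" & m$hemizygous %in% TRUE
  if (any(bad))
    stop("conflicting flags (autosomal + hemizygous): ",
         paste(m$gene[bad], collapse = ", "))
  drop <- m$linkage %in% c("PAR", "unknown")
  excluded <- data.frame(gene = m$gene[drop],
                         reason = if (any(drop))
                           paste0(m$linkage[drop], " linkage")
                         else character(0),
                         stringsAsFactors = FALSE)
  kept <- m[!drop, , drop = FALSE]
  kept$stratum <- ifelse(kept$linkage == "autosomal", "autosomal",
                         ifelse(kept$hemizygous, "x_hemizygous",
                                "x_nonhemizygous"))
  if (!"female_biased" %in% names(kept)) kept$female_biased <- NA
  list(genes = kept, excluded = excluded)
}

#' Flag female-biased genes from a sexed expression matrix
#'
#' One-sided Welch t-test (female greater) on log2(x + 1) expression at
#' `p < alpha`; male-biased genes are never flagged, by design. Genes with
#' zero variance in both sexes are reported untestable.
#'
#' @param expr genes x individuals matrix.
#' @param sex factor/character of `"male"`/`"female"` per column.
#' @param alpha flag threshold (default 0.001).
#' @return data.frame: gene, p, female_biased, untestable.
#' @export
female_bias_flag <- function(expr, sex, alpha = 0.001) {
  sex <- as.character(sex)
  if (length(sex) != ncol(expr)) stop("sex labels must match columns")
  if (sum(sex == "male") < 2 || sum(sex == "female") < 2)
    stop("need at least 2 individuals per sex")
  lf <- log2(expr[, sex == "female", drop = FALSE] + 1)
  lm_ <- log2(expr[, sex == "male", drop = FALSE] + 1)
  n <- nrow(expr)
  p <- rep(NA_real_, n)
  untestable <- rep(FALSE, n)
  for (g in seq_len(n)) {
    if (stats::var(lf[g, ]) + stats::var(lm_[g, ]) == 0) {
      untestable[g] <- TRUE
      next
    }
    p[g] <- stats::t.test(lf[g, ], lm_[g, ],
                          alternative = "greater")$p.value
  }
  data.frame(gene = rownames(expr) %||% sprintf("gene%04d", seq_len(n)),
             p = p, female_biased = !untestable & !is.na(p) & p < alpha,
             untestable = untestable, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' No continuity correction (this reproduces the published contingency
#' examples); Yates' correction is available by flag. A zero margin returns
#' p = 1 with a note.
#'
#' @param a,b,c,d counts: `a` of `a + b` in group 1 versus `c` of `c + d`
#'   in group 2.
#' @param correct apply Yates' continuity correction.
#' @return list: statistic, df, p, note, group sizes.
#' @export
chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = 0, df = 1, p = 1, note = "zero margin",
                n = rowSums(m)))
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), df = 1, p = ct$p.value,
       note = NA_character_, n = rowSums(m))
}

#' Two-group distribution tests
#'
#' `kind = "t"` is Welch's unequal-variance t-test (two-sided);
#' `kind = "student"` the classic equal-variance version; `kind =
#' "wilcoxon"` the rank-sum test reporting the W statistic of the first
#' group (number of pairs where a value from `values_a` exceeds one from
#' `values_b`), with the normal approximation and tie correction for large
#' samples.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param kind `"t"`, `"student"` or `"wilcoxon"`.
#' @return list: test, statistic, p, n (group sizes), note.
#' @export
distribution_tests <- function(values_a, values_b,
                               kind = c("t", "student", "wilcoxon")) {
  kind <- match.arg(kind)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  n <- c(length(values_a), length(values_b))
  if (length(unique(c(values_a, values_b))) == 1L)
    return(list(test = kind, statistic = if (kind == "wilcoxon")
      prod(n) / 2 else 0, p = 1, n = n, note = "all values tied"))
  if (kind == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = FALSE, correct = TRUE))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value,
         n = n, note = NA_character_)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = kind == "student")
    list(test = kind, statistic = unname(tt$statistic), p = tt$p.value,
         n = n, note = NA_character_)
  }
}

# All four LRT families for one gene. Branch lengths are estimated once
# under the one-ratio model (full per-branch), then each model re-optimises
# a single scale on that tree.
gene_model_scan <- function(align, tree, foreground_taxa, seed = 1,
                            models = c("branch", "m1m2", "m7m8", "modelA"),
                            n_starts = 2) {
  m0 <- fit_model(align, tree, codon_model("M0"), seed = seed,
                  foreground_taxa = foreground_taxa, n_starts = n_starts,
                  branch_lengths = "full")
  base_tree <- m0$tree
  fits <- list(M0 = m0)
  lrts <- list()
  chain <- list(kappa = m0$par$kappa, scale = 1)
  if ("branch" %in% models) {
    two <- fit_model(align, base_tree, codon_model("BRANCH2"), seed = seed,
                     foreground_taxa = foreground_taxa, n_starts = n_starts,
                     init = c(chain, list(omega_fore = m0$par$omega,
                                          omega_back = m0$par$omega)))
    one <- fit_model(align, base_tree, codon_model("M0"), seed = seed,
                     foreground_taxa = foreground_taxa, n_starts = n_starts,
                     init = c(chain, list(omega = m0$par$omega)))
    fits$BRANCH2 <- two
    fits$M0 <- one
    lrts$branch <- c(lrt(two, one, 1),
                     list(omega_fore = two$par$omega_fore,
                          omega_back = two$par$omega_back))
  }
  if ("m1m2" %in% models) {
    m1 <- fit_model(align, base_tree, codon_model("M1a"), seed = seed,
                    n_starts = n_starts, init = chain)
    m2 <- fit_model(align, base_tree, codon_model("M2a"), seed = seed,
                    n_starts = n_starts,
                    init = c(chain, list(omega0 = m1$par$omega0,
                                         p0 = m1$par$p0 * 0.999,
                                         p1 = (1 - m1$par$p0) * 0.99,
                                         omega2 = 1.001)))
    fits$M1a <- m1; fits$M2a <- m2
    lrts$m1m2 <- c(lrt(m2, m1, 2), list(omega0 = m2$par$omega0))
  }
  if ("m7m8" %in% models) {
    m7 <- fit_model(align, base_tree, codon_model("M7"), seed = seed,
                    n_starts = n_starts, init = chain)
    m8 <- fit_model(align, base_tree, codon_model("M8"), seed = seed,
                    n_starts = n_starts,
                    init = c(chain, list(p = m7$par$p, q = m7$par$q,
                                         p0 = 0.999, omega2 = 1.001)))
    fits$M7 <- m7; fits$M8 <- m8
    lrts$m7m8 <- lrt(m8, m7, 2)
  }
  if ("modelA" %in% models) {
    a0 <- fit_model(align, base_tree, codon_model("MODEL_A_NULL"),
                    seed = seed, foreground_taxa = foreground_taxa,
                    n_starts = n_starts, init = chain)
    a1 <- fit_model(align, base_tree, codon_model("MODEL_A"), seed = seed,
                    foreground_taxa = foreground_taxa, n_starts = n_starts,
                    init = c(chain, list(omega0 = a0$par$omega0,
                                         p0 = a0$par$p0, p1 = a0$par$p1,
                                         omega2 = 1.001)))
    fits$MODEL_A_NULL <- a0; fits$MODEL_A <- a1
    cls <- model_classes(a1$spec, a1$par)
    lrts$modelA <- c(lrt(a1, a0, 1),
                     list(p_switched = sum(cls$prob[3:4]),
                          omega2 = a1$par$omega2))
  }
  list(fits = fits, lrts = lrts)
}

#' Run the full per-gene selection scan
#'
#' For every gene: the two-rate/one-rate branch LRT, the M1a/M2a and M7/M8
#' site LRTs, and the branch-site model A LRT against its fixed-omega null.
#' Produces the count table of genes significant at 5% and 1% (raw
#' p-values, no multiple-testing correction, matching the published table
#' layout) stratified as X (all), X hemizygous, X female-biased and
#' autosomal, plus per-gene parameter reports. A failing gene is isolated,
#' logged in the exclusions table, and never aborts the scan.
#'
#' @param gene_aligns named list of `codon_alignment`s (or a directory of
#'   FASTAs).
#' @param tree species tree with branch lengths.
#' @param metadata data.frame as for [classify_genes()].
#' @param foreground_taxa the dioecious clade tips.
#' @param models subset of `c("branch", "m1m2", "m7m8", "modelA")`.
#' @param seed integer seed for the optimiser restarts.
#' @param n_starts optimiser restarts per model.
#' @param out_dir optional output directory for `fits.tsv`,
#'   `lrt_summary.tsv`, `delta_omega.tsv`, `exclusions.tsv`.
#' @return list with `fits` (per gene/model rows), `lrt` (per gene/test
#'   rows), `summary` (the stratified count table), `delta_omega`,
#'   `exclusions`.
#' @export
run_scan <- function(gene_aligns, tree, metadata, foreground_taxa,
                     models = c("branch", "m1m2", "m7m8", "modelA"),
                     seed = 1, n_starts = 2, out_dir = NULL) {
  if (is.character(gene_aligns) && length(gene_aligns) == 1L) {
    files <- list.files(gene_aligns, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    gene_aligns <- lapply(files, load_codon_alignment)
    names(gene_aligns) <- sub("\\.fa(sta)?$", "", basename(files))
  }
  cl <- classify_genes(metadata)
  genes <- cl$genes[cl$genes$gene %in% names(gene_aligns), , drop = FALSE]
  fit_rows <- list(); lrt_rows <- list(); excl <- cl$excluded
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    res <- tryCatch(
      gene_model_scan(gene_aligns[[g]], tree, foreground_taxa,
                      seed = child_seed(seed, g), models = models,
                      n_starts = n_starts),
      error = function(e) e)
    if (inherits(res, "error")) {
      excl <- rbind(excl, data.frame(gene = g,
                                     reason = conditionMessage(res)))
      next
    }
    for (nm in names(res$fits)) {
      f <- res$fits[[nm]]
      core <- f$par[!names(f$par) %in% "edge_len"]
      fit_rows[[length(fit_rows) + 1]] <- data.frame(
        gene = g, model = nm, lnL = f$lnL, converged = f$convergence,
        boundary = f$boundary,
        params = paste(names(core), signif(unlist(core), 6), sep = "=",
                       collapse = ";"), stringsAsFactors = FALSE)
    }
    for (nm in names(res$lrts)) {
      l <- res$lrts[[nm]]
      lrt_rows[[length(lrt_rows) + 1]] <- data.frame(
        gene = g, test = nm, statistic = l$statistic, df = l$df, p = l$p,
        omega_fore = l$omega_fore %||% NA_real_,
        omega_back = l$omega_back %||% NA_real_,
        omega0 = l$omega0 %||% NA_real_,
        p_switched = l$p_switched %||% NA_real_,
        omega2 = l$omega2 %||% NA_real_, stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, fit_rows)
  lrt_tab <- do.call(rbind, lrt_rows)
  summary <- lrt_count_table(lrt_tab, genes)
  dw <- delta_omega_table(lrt_tab, genes)
  out <- list(fits = fits, lrt = lrt_tab, summary = summary,
              delta_omega = dw, exclusions = excl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wr(fits, "fits.tsv"); wr(lrt_tab, "lrt_summary.tsv")
    wr(summary, "lrt_counts.tsv"); wr(dw, "delta_omega.tsv")
    wr(excl, "exclusions.tsv")
  }
  out
}

# Count table in the published layout: strata x (5%, 1%) per LRT.
lrt_count_table <- function(lrt_tab, genes) {
  if (is.null(lrt_tab) || nrow(lrt_tab) == 0) return(NULL)
  strata <- list(
    x_all = genes$gene[genes$stratum != "autosomal"],
    x_hemizygous = genes$gene[genes$stratum == "x_hemizygous"],
    x_female_biased = genes$gene[genes$stratum != "autosomal" &
                                   genes$female_biased %in% TRUE],
    autosomal = genes$gene[genes$stratum == "autosomal"])
  rows <- list()
  for (tst in unique(lrt_tab$test)) {
    sub <- lrt_tab[lrt_tab$test == tst, ]
    for (s in names(strata)) {
      p <- sub$p[sub$gene %in% strata[[s]]]
      rows[[length(rows) + 1]] <- data.frame(
        test = tst, stratum = s, n_genes = length(p),
        sig_05 = sum(p < 0.05, na.rm = TRUE),
        pct_05 = if (length(p)) 100 * mean(p < 0.05, na.rm = TRUE) else NA,
        sig_01 = sum(p < 0.01, na.rm = TRUE),
        pct_01 = if (length(p)) 100 * mean(p < 0.01, na.rm = TRUE) else NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Foreground/background omega ratios from the two-ratio fits; genes with a
# background omega at the lower bound are excluded from ratio summaries.
delta_omega_table <- function(lrt_tab, genes, min_back = 1e-4) {
  if (is.null(lrt_tab)) return(NULL)
  b <- lrt_tab[lrt_tab$test == "branch", , drop = FALSE]
  if (nrow(b) == 0) return(NULL)
  b <- merge(b, genes[, c("gene", "stratum")], by = "gene")
  b$ratio_defined <- b$omega_back > min_back
  b$delta_omega <- ifelse(b$ratio_defined, b$omega_fore / b$omega_back, NA)
  b$log2_delta <- log2(b$delta_omega)
  b[, c("gene", "stratum", "omega_fore", "omega_back", "delta_omega",
        "log2_delta", "ratio_defined")]
}
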