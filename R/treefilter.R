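## Four-fold-degenerate-site supermatrix construction and the gene-tree /
## species-tree conflict filter (per-site GTR+Gamma likelihoods, SH-test
## with RELL resampling, BH-FDR).

#' Extract four-fold-degenerate third positions from a codon alignment
#'
#' Under the conservative all-taxa rule (default) a codon column contributes
#' its third position only if every non-missing codon in the column belongs
#' to a four-fold-degenerate family; `rule = "reference"` instead requires
#' only the reference taxon's codon to be four-fold.
#'
#' @param align a `codon_alignment`.
#' @param rule `"all"` or `"reference"`.
#' @param reference taxon name (first taxon by default) for the reference
#'   rule.
#' @return a `nuc_alignment`: list with `taxa` and character matrix `bases`
#'   (`NA` = missing).
#' @export
fourfold_columns <- function(align, rule = c("all", "reference"),
                             reference = align$taxa[1]) {
  rule <- match.arg(rule)
  gcd <- genetic_code()
  ff <- gcd$fourfold
  keep <- if (rule == "all") {
    apply(align$codons, 2, function(col) {
      obs <- col[!is.na(col)]
      length(obs) > 0 && all(ff[obs])
    })
  } else {
    r <- align$codons[match(reference, align$taxa), ]
    !is.na(r) & ff[r]
  }
  third <- substr(gcd$codons, 3, 3)
  bases <- matrix(NA_character_, length(align$taxa), sum(keep),
                  dimnames = list(align$taxa, NULL))
  cols <- which(keep)
  for (j in seq_along(cols)) {
    col <- align$codons[, cols[j]]
    bases[, j] <- ifelse(is.na(col), NA_character_, third[col])
  }
  structure(list(taxa = align$taxa, bases = bases), class = "nuc_alignment")
}

#' Concatenate four-fold sites into a supermatrix
#'
#' Joins four-fold columns across genes over a shared taxon set and drops
#' columns whose missing fraction is strictly greater than `max_missing`
#' (50% missing is retained).
#'
#' @param gene_aligns list of `codon_alignment`s (shared taxa).
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @param rule passed to [fourfold_columns()].
#' @return a `nuc_alignment` with attribute `gene_offsets` (per-gene column
#'   counts after filtering).
#' @export
build_supermatrix <- function(gene_aligns, max_missing = 0.5,
                              rule = c("all", "reference")) {
  rule <- match.arg(rule)
  taxa <- gene_aligns[[1]]$taxa
  for (g in gene_aligns)
    if (!setequal(g$taxa, taxa)) stop("gene alignments must share taxa")
  blocks <- lapply(gene_aligns, function(g) {
    nuc <- fourfold_columns(g, rule = rule)
    b <- nuc$bases[match(taxa, nuc$taxa), , drop = FALSE]
    if (ncol(b) == 0) return(b)
    miss <- colMeans(is.na(b))
    b[, miss <= max_missing, drop = FALSE]
  })
  bases <- do.call(cbind, blocks)
  if (is.null(bases) || ncol(bases) == 0)
    stop("no four-fold columns survive the missing-data threshold; ",
         "consider raising max_missing")
  rownames(bases) <- taxa
  structure(list(taxa = taxa, bases = bases),
            class = "nuc_alignment",
            gene_offsets = vapply(blocks, ncol, 0L))
}

as_phyDat <- function(nuc) {
  m <- nuc$bases
  m[is.na(m)] <- "-"
  phangorn::phyDat(tolower(m), type = "DNA")
}

#' Per-site log-likelihoods under GTR+Gamma on a fixed topology
#'
#' Optimises branch lengths, exchangeabilities, base frequencies and the
#' gamma shape for the given topology (via the phangorn likelihood engine)
#' and returns the per-site log-likelihood vector used by the SH-test.
#'
#' @param nuc a `nuc_alignment`.
#' @param tree fixed topology ([ape::phylo]); branch lengths are
#'   re-estimated.
#' @param k number of discrete gamma categories (default 4).
#' @param optimise logical; set `FALSE` to evaluate at the tree's current
#'   branch lengths with `shape`/`bf`/`Q` supplied.
#' @param ... passed to [phangorn::pml()] when `optimise = FALSE`.
#' @return list with `site_lnl` (length = alignment columns), `lnl` (their
#'   weighted total) and the fitted `pml` object.
#' @export
gtr_gamma_site_lnl <- function(nuc, tree, k = 4, optimise = TRUE, ...) {
  dat <- as_phyDat(nuc)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.05, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  fit <- phangorn::pml(tree, dat, k = k, ...)
  if (optimise)
    fit <- phangorn::optim.pml(fit, optEdge = TRUE, optQ = TRUE,
                               optBf = TRUE, optGamma = TRUE,
                               control = phangorn::pml.control(trace = 0))
  idx <- attr(dat, "index")
  site <- fit$siteLik[idx]
  if (any(!is.finite(site)))
    stop("non-finite site likelihood at column ",
         which(!is.finite(site))[1])
  list(site_lnl = site, lnl = sum(site), fit = fit)
}

#' Shimodaira-Hasegawa test for two fixed topologies
#'
#' Two-topology RELL version: sites are resampled with replacement, the
#' resampled total log-likelihoods are centred per topology, and the
#' one-sided p-value measures how often the centred difference exceeds the
#' observed advantage of the gene tree over the species tree. Small p means
#' the species tree is significantly worse than the gene tree.
#'
#' @param lnl_gene_tree,lnl_species_tree per-site log-likelihood vectors of
#'   equal length (>= 10 sites).
#' @param n_boot RELL replicates (default 1000).
#' @param seed integer seed; same seed, same p-value.
#' @return the p-value for rejecting the species tree.
#' @export
sh_test <- function(lnl_gene_tree, lnl_species_tree, n_boot = 1000,
                    seed = 1) {
  if (length(lnl_gene_tree) != length(lnl_species_tree))
    stop("site counts differ")
  n <- length(lnl_gene_tree)
  if (n < 10) stop("fewer than 10 sites; SH resampling is unstable")
  delta_obs <- sum(lnl_gene_tree) - sum(lnl_species_tree)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    bg <- rowSums(matrix(lnl_gene_tree[idx], n_boot, n))
    bs <- rowSums(matrix(lnl_species_tree[idx], n_boot, n))
    cg <- bg - mean(bg)
    cs <- bs - mean(bs)
    d <- pmax(cg, cs) - cs
    mean(d >= delta_obs - 1e-12)
  })
}

#' Benjamini-Hochberg adjustment with keep/drop flags
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha significance level for the drop flag (default 0.05).
#' @return data.frame with `p`, `p_adjusted`, `keep` (`TRUE` = gene passes
#'   the conflict filter).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0)
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      keep = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, keep = adj >= alpha)
}

#' Gene-tree conflict filter over a set of genes
#'
#' For each gene: builds its four-fold nucleotide alignment, obtains a gene
#' tree (supplied, or neighbour-joining internally), computes per-site
#' GTR+Gamma log-likelihoods under the gene tree and the species tree, runs
#' the SH-test, and applies BH-FDR across genes. Genes whose gene tree is
#' significantly preferred over the species tree are flagged for removal.
#'
#' @param gene_aligns named list of `codon_alignment`s.
#' @param species_tree fixed species topology.
#' @param gene_trees optional named list of gene trees; defaults to NJ trees
#'   computed from the four-fold sites.
#' @param n_boot,seed SH-test resampling controls.
#' @param alpha FDR level (default 0.05).
#' @param min_sites genes with fewer four-fold columns are kept untested.
#' @return data.frame: gene, lnl_species, lnl_gene, p, p_adjusted, keep.
#' @export
filter_gene_trees <- function(gene_aligns, species_tree, gene_trees = NULL,
                              n_boot = 1000, seed = 1, alpha = 0.05,
                              min_sites = 10) {
  genes <- names(gene_aligns)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_along(gene_aligns))
  res <- data.frame(gene = genes, lnl_species = NA_real_,
                    lnl_gene = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(gene_aligns)) {
    nuc <- fourfold_columns(gene_aligns[[i]])
    if (ncol(nuc$bases) < min_sites) next
    gt <- if (!is.null(gene_trees)) gene_trees[[genes[i]]] else {
      dat <- as_phyDat(nuc)
      ape::njs(phangorn::dist.ml(dat))
    }
    ls <- gtr_gamma_site_lnl(nuc, species_tree)
    lg <- gtr_gamma_site_lnl(nuc, gt)
    res$lnl_species[i] <- ls$lnl
    res$lnl_gene[i] <- lg$lnl
    res$p[i] <- sh_test(lg$site_lnl, ls$site_lnl, n_boot = n_boot,
                        seed = child_seed(seed, genes[i]))
  }
  tested <- !is.na(res$p)
  res$p_adjusted <- NA_real_
  res$keep <- TRUE
  if (any(tested)) {
    adj <- bh_fdr(res$p[tested], alpha = alpha)
    res$p_adjusted[tested] <- adj$p_adjusted
    res$keep[tested] <- adj$keep
  }
  res
}
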