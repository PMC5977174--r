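#' Specify a codon substitution model
#'
#' The model families follow the standard codeml naming: `M0` (one ratio),
#' `BRANCH2` (separate foreground/background ratios), `M1a`/`M2a` and
#' `M7`/`M8` site-class models, and branch-site `MODEL_A` with its
#' fixed-omega null `MODEL_A_NULL` (foreground omega2 fixed to 1).
#'
#' @param family one of `"M0"`, `"BRANCH2"`, `"M1a"`, `"M2a"`, `"M7"`,
#'   `"M8"`, `"MODEL_A"`, `"MODEL_A_NULL"`.
#' @param freq equilibrium frequency method: `"F3x4"` (default), `"F1x4"`
#'   or `"equal"`.
#' @param ncat number of equal-probability discretisation categories for the
#'   beta law of M7/M8 (default 10).
#' @return a `codon_model_spec` object.
#' @export
codon_model <- function(family = c("M0", "BRANCH2", "M1a", "M2a", "M7",
                                   "M8", "MODEL_A", "MODEL_A_NULL"),
                        freq = c("F3x4", "F1x4", "equal"), ncat = 10) {
  family <- match.arg(family)
  freq <- match.arg(freq)
  if (ncat < 2) stop("ncat must be >= 2")
  # free parameters beyond (kappa, branch scale); fixes the LRT df
  np_model <- c(M0 = 1, BRANCH2 = 2, M1a = 2, M2a = 4, M7 = 2, M8 = 4,
                MODEL_A = 4, MODEL_A_NULL = 3)[[family]]
  structure(list(family = family, freq = freq, ncat = ncat,
                 np_model = np_model),
            class = "codon_model_spec")
}

# Equal-probability discretisation of Beta(p, q): category means via the
# incomplete beta function.
beta_categories <- function(p, q, k) {
  b <- stats::qbeta(seq(0, 1, length.out = k + 1), p, q)
  means <- k * (p / (p + q)) * diff(stats::pbeta(b, p + 1, q))
  means[means < 0] <- 0
  means[means > 1] <- 1
  means
}

# Site-class structure: probabilities plus background/foreground omega per
# class. Non-branch families use identical omegas on both partitions.
model_classes <- function(spec, par) {
  f <- spec$family
  if (f == "M0") {
    list(prob = 1, w_bg = par$omega, w_fg = par$omega)
  } else if (f == "BRANCH2") {
    list(prob = 1, w_bg = par$omega_back, w_fg = par$omega_fore)
  } else if (f == "M1a") {
    list(prob = c(par$p0, 1 - par$p0), w_bg = c(par$omega0, 1),
         w_fg = c(par$omega0, 1))
  } else if (f == "M2a") {
    p <- c(par$p0, par$p1, 1 - par$p0 - par$p1)
    w <- c(par$omega0, 1, par$omega2)
    list(prob = p, w_bg = w, w_fg = w)
  } else if (f == "M7") {
    w <- beta_categories(par$p, par$q, spec$ncat)
    list(prob = rep(1 / spec$ncat, spec$ncat), w_bg = w, w_fg = w)
  } else if (f == "M8") {
    w <- c(beta_categories(par$p, par$q, spec$ncat), par$omega2)
    p <- c(rep(par$p0 / spec$ncat, spec$ncat), 1 - par$p0)
    list(prob = p, w_bg = w, w_fg = w)
  } else { # MODEL_A / MODEL_A_NULL
    p01 <- par$p0 + par$p1
    p2 <- 1 - p01
    prob <- c(par$p0, par$p1, p2 * par$p0 / p01, p2 * par$p1 / p01)
    w2 <- if (f == "MODEL_A_NULL") 1 else par$omega2
    list(prob = prob,
         w_bg = c(par$omega0, 1, par$omega0, 1),
         w_fg = c(par$omega0, 1, w2, w2))
  }
}

# Precomputed pruning inputs: postorder edges, compressed site patterns,
# tip state matrix, foreground edge labels.
pruning_data <- function(align, tree, foreground_taxa = NULL) {
  check_tree_alignment(tree, align)
  tr <- ape::reorder.phylo(tree, "postorder")
  fg <- if (is.null(foreground_taxa)) rep(0L, nrow(tr$edge)) else
    label_foreground(tr, foreground_taxa)
  states <- align$codons[match(tr$tip.label, align$taxa), , drop = FALSE]
  key <- apply(states, 2, paste, collapse = ".")
  first <- !duplicated(key)
  pat <- states[, first, drop = FALSE]
  weights <- as.numeric(table(key)[key[first]])
  pat[is.na(pat)] <- 0L
  storage.mode(pat) <- "integer"
  list(edge = tr$edge, edge_len = tr$edge.length,
       n_node = length(tr$tip.label) + tr$Nnode, tipstate = pat,
       weights = weights, fg = fg, tree = tr,
       pattern_of_site = match(key, key[first]))
}

# P matrices deduplicated over distinct (omega, scaled length) pairs.
# Returns list(P_list, edge_P (nedge x nclass index matrix)).
edge_prob_matrices <- function(prep, classes, kappa, freqs, scale) {
  omegas <- unique(c(classes$w_bg, classes$w_fg))
  eigs <- lapply(omegas, function(w)
    rev_eigen(codon_rate_matrix(kappa, w, freqs), freqs))
  tlen <- prep$edge_len * scale
  nedge <- nrow(prep$edge)
  ncls <- length(classes$prob)
  wmat <- matrix(0, nedge, ncls)
  for (c in seq_len(ncls))
    wmat[, c] <- ifelse(prep$fg == 1L, classes$w_fg[c], classes$w_bg[c])
  key <- paste(match(wmat, omegas), rep(tlen, ncls))
  ukey <- unique(key)
  P_list <- vector("list", length(ukey))
  for (i in seq_along(ukey)) {
    k1 <- match(ukey[i], key)
    e <- ((k1 - 1) %% nedge) + 1
    c <- ((k1 - 1) %/% nedge) + 1
    P_list[[i]] <- prob_matrix(eigs[[match(wmat[e, c], omegas)]], tlen[e])
  }
  edge_P <- matrix(match(key, ukey), nedge, ncls)
  list(P_list = P_list, edge_P = edge_P)
}

lnl_from_prep <- function(prep, spec, par, freqs, site = FALSE) {
  classes <- model_classes(spec, par)
  ep <- edge_prob_matrices(prep, classes, par$kappa, freqs, par$scale)
  out <- prune_mixture(prep$tipstate, prep$weights, prep$edge, prep$n_node,
                       ep$P_list, ep$edge_P, freqs, classes$prob)
  if (!is.finite(out$lnl)) {
    bad <- which(!is.finite(out$site_lnl))[1]
    stop("non-finite likelihood at site pattern ", bad)
  }
  if (site) out else out$lnl
}

#' Codon-model log-likelihood at a parameter point
#'
#' Felsenstein pruning over the tree under the mixture defined by the model
#' specification. Missing codons are marginalised over all 61 states; the
#' model is time-reversible, so the value does not depend on root placement.
#'
#' @param align a `codon_alignment`.
#' @param tree an [ape::phylo] with branch lengths in expected substitutions
#'   per codon.
#' @param spec a [codon_model()] specification.
#' @param par named list of parameters: always `kappa` and `scale`
#'   (multiplier on the tree's branch lengths), plus the family's own
#'   parameters (`omega`; `omega_fore`/`omega_back`; `omega0`, `p0`;
#'   `omega0`, `omega2`, `p0`, `p1`; `p`, `q`; ...).
#' @param foreground_taxa tips defining foreground branches (branch and
#'   branch-site families).
#' @param freqs optional explicit 61-vector of codon frequencies; default
#'   computed from the alignment by the spec's frequency method.
#' @return the log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(align, tree, spec, par, foreground_taxa = NULL,
                           freqs = NULL) {
  if (is.null(par$scale)) par$scale <- 1
  if (is.null(freqs)) freqs <- codon_frequencies(align, spec$freq)
  prep <- pruning_data(align, tree, foreground_taxa)
  lnl_from_prep(prep, spec, par, freqs)
}
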