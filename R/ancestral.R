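#' Marginal ancestral codon reconstruction
#'
#' Computes, at the fitted parameter values, the marginal posterior
#' distribution over the 61 codon states for every internal node and site,
#' then reports the argmax codon (ties broken toward the lowest codon index
#' and flagged). Uses an inside-outside pass over the same transition
#' matrices as the likelihood.
#'
#' @param align the `codon_alignment` the model was fitted to.
#' @param tree the tree used in the fit (the fit's own tree, with its fitted
#'   branch lengths, is used when `tree` is `NULL`).
#' @param fit a converged `codon_fit`.
#' @return list with `nodes` (internal node ids, ape numbering), `states`
#'   (matrix nodes x sites of codon strings), `posterior_max`, `tied`
#'   (logical matrix), and `posterior` (list per node of 61 x sites
#'   matrices).
#' @export
ancestral_reconstruct <- function(align, fit, tree = NULL) {
  if (!isTRUE(fit$convergence))
    stop("ancestral reconstruction requires a converged fit")
  if (is.null(tree)) tree <- fit$tree
  par <- fit$par
  par$scale <- 1  # fit$tree already carries fitted lengths
  prep <- pruning_data(align, tree, fit$foreground_taxa)
  gcd <- genetic_code()
  freqs <- fit$freqs
  classes <- model_classes(fit$spec, par)
  ep <- edge_prob_matrices(prep, classes, par$kappa, freqs, 1)
  npat <- ncol(prep$tipstate)
  ntip <- nrow(prep$tipstate)
  nnode <- prep$n_node
  root <- prep$edge[nrow(prep$edge), 1]
  internal <- sort(unique(prep$edge[, 1]))
  ncls <- length(classes$prob)

  sitelik <- rep(0, npat)
  post <- lapply(internal, function(n) matrix(0, 61, npat))
  names(post) <- internal

  for (cl in seq_len(ncls)) {
    Pm <- lapply(seq_len(nrow(prep$edge)),
                 function(e) ep$P_list[[ep$edge_P[e, cl]]])
    # inside (postorder): messages child -> parent, partials at internals
    msg <- vector("list", nrow(prep$edge))
    partial <- vector("list", nnode)
    for (e in seq_len(nrow(prep$edge))) {
      par_n <- prep$edge[e, 1]; ch <- prep$edge[e, 2]
      m <- if (ch <= ntip) {
        s <- prep$tipstate[ch, ]
        m0 <- matrix(1, 61, npat)
        obs <- s != 0L
        m0[, obs] <- Pm[[e]][, s[obs]]
        m0
      } else {
        Pm[[e]] %*% partial[[ch]]
      }
      msg[[e]] <- m
      partial[[par_n]] <- if (is.null(partial[[par_n]])) m else
        partial[[par_n]] * m
    }
    # outside (preorder): above-message per node
    above <- vector("list", nnode)
    above[[root]] <- matrix(freqs, 61, npat)
    for (e in rev(seq_len(nrow(prep$edge)))) {
      par_n <- prep$edge[e, 1]; ch <- prep$edge[e, 2]
      sib <- which(prep$edge[, 1] == par_n & seq_len(nrow(prep$edge)) != e)
      pr <- above[[par_n]]
      for (s2 in sib) pr <- pr * msg[[s2]]
      above[[ch]] <- crossprod(Pm[[e]], pr)
    }
    sl <- colSums(partial[[root]] * matrix(freqs, 61, npat))
    sitelik <- sitelik + classes$prob[cl] * sl
    for (n in internal) {
      joint <- if (n == root) partial[[n]] * matrix(freqs, 61, npat) else
        partial[[n]] * above[[n]]
      post[[as.character(n)]] <- post[[as.character(n)]] +
        classes$prob[cl] * joint
    }
  }

  map <- prep$pattern_of_site
  L <- align$n_sites
  states <- matrix("", length(internal), L,
                   dimnames = list(internal, NULL))
  pmax_ <- matrix(0, length(internal), L, dimnames = list(internal, NULL))
  tied <- matrix(FALSE, length(internal), L, dimnames = list(internal, NULL))
  posterior <- vector("list", length(internal))
  names(posterior) <- internal
  for (i in seq_along(internal)) {
    n <- as.character(internal[i])
    pp <- post[[n]] / rep(sitelik, each = 61)
    pp_site <- pp[, map, drop = FALSE]
    amax <- apply(pp_site, 2, which.max)  # ties: lowest codon index
    mx <- pp_site[cbind(amax, seq_len(L))]
    states[i, ] <- gcd$codons[amax]
    pmax_[i, ] <- mx
    tied[i, ] <- apply(pp_site, 2, function(v) sum(v >= max(v) - 1e-12) > 1)
    posterior[[i]] <- pp_site
  }
  list(nodes = internal, states = states, posterior_max = pmax_,
       tied = tied, posterior = posterior, tree = prep$tree)
}

#' Write reconstructed ancestors as FASTA plus an annotated newick
#'
#' @param anc result of [ancestral_reconstruct()].
#' @param fasta,newick output paths.
#' @export
write_ancestral <- function(anc, fasta, newick) {
  lines <- character(0)
  for (i in seq_along(anc$nodes)) {
    lines <- c(lines, paste0(">node", anc$nodes[i]),
               paste(anc$states[i, ], collapse = ""))
  }
  writeLines(lines, fasta)
  tr <- anc$tree
  tr$node.label <- paste0("node", sort(unique(tr$edge[, 1])))
  ape::write.tree(tr, newick)
  invisible(NULL)
}
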