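# Independent oracles used across tests: exhaustive enumeration of the
# phylogenetic likelihood over ancestral states, and a refining grid search
# for the pairwise dN/dS optimiser. These deliberately avoid the package's
# pruning path (prune_mixture) and quasi-Newton optimiser.

# Exhaustive mixture likelihood: sum over all assignments of states to the
# internal nodes, per site, per class. Feasible for trees with <= 2
# internal nodes (61^2 states).
enum_mixture_lnl <- function(align, tree, classes, kappa, freqs,
                             foreground_taxa = NULL, scale = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  fg <- if (is.null(foreground_taxa)) rep(0L, nrow(tr$edge)) else
    fasterx::label_foreground(tr, foreground_taxa)
  ntip <- length(tr$tip.label)
  internal <- sort(unique(tr$edge[, 1]))
  root <- tr$edge[nrow(tr$edge), 1]
  states <- align$codons[match(tr$tip.label, align$taxa), , drop = FALSE]
  omegas <- unique(c(classes$w_bg, classes$w_fg))
  Ps <- lapply(omegas, function(w) {
    Q <- fasterx::codon_rate_matrix(kappa, w, freqs)
    lapply(tr$edge.length * scale, function(t)
      fasterx::codon_prob_matrix(Q, freqs, t))
  })
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internal))))
  total <- rep(0, align$n_sites)
  for (cl in seq_len(nrow(classes))) {
    for (s in seq_len(align$n_sites)) {
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_ <- grid[g, ]
        node_state <- function(n) if (n <= ntip) states[n, s] else
          assign_[match(n, internal)]
        term <- freqs[node_state(root)]
        for (e in seq_len(nrow(tr$edge))) {
          w <- if (fg[e] == 1) classes$w_fg[cl] else classes$w_bg[cl]
          P <- Ps[[match(w, omegas)]][[e]]
          a <- node_state(tr$edge[e, 1])
          b <- node_state(tr$edge[e, 2])
          term <- term * if (is.na(b)) 1 else P[a, b]
        }
        lik <- lik + term
      }
      total[s] <- total[s] + classes$prob[cl] * lik
    }
  }
  sum(log(total))
}

# Marginal posterior at the single internal node of a 3-taxon tree by
# direct Bayes inversion.
enum_posterior_3taxon <- function(align, tree, kappa, omega, freqs,
                                  site) {
  tr <- ape::reorder.phylo(tree, "postorder")
  Q <- fasterx::codon_rate_matrix(kappa, omega, freqs)
  P <- lapply(tr$edge.length, function(t)
    fasterx::codon_prob_matrix(Q, freqs, t))
  ord <- match(tr$tip.label, align$taxa)
  num <- freqs
  for (e in seq_len(nrow(tr$edge))) {
    b <- align$codons[ord[tr$edge[e, 2]], site]
    num <- num * if (is.na(b)) 1 else P[[e]][, b]
  }
  num / sum(num)
}

# Refining grid search over (log t, kappa, omega) for the two-sequence
# one-ratio likelihood; three zoom stages.
grid_pairwise <- function(s1, s2, freqs) {
  u <- cbind(s1, s2)
  lik <- function(t, kap, om) {
    Q <- fasterx::codon_rate_matrix(kap, om, freqs)
    P <- fasterx::codon_prob_matrix(Q, freqs, t)
    sum(log(freqs[u[, 1]] * P[u]))
  }
  rng <- list(t = c(0.001, 2), k = c(0.5, 20), o = c(0.01, 5))
  best <- NULL
  for (stage in 1:10) {
    ts <- exp(seq(log(rng$t[1]), log(rng$t[2]), length.out = 8))
    ks <- exp(seq(log(rng$k[1]), log(rng$k[2]), length.out = 8))
    os <- exp(seq(log(rng$o[1]), log(rng$o[2]), length.out = 8))
    vals <- expand.grid(t = ts, k = ks, o = os)
    vals$ll <- mapply(lik, vals$t, vals$k, vals$o)
    best <- vals[which.max(vals$ll), ]
    shrink <- function(r, v) {
      w <- (log(r[2]) - log(r[1])) / 4
      exp(c(log(v) - w, log(v) + w))
    }
    rng <- list(t = shrink(rng$t, best$t), k = shrink(rng$k, best$k),
                o = shrink(rng$o, best$o))
  }
  best
}

toy_tree3 <- function() ape::read.tree(text = "(a:0.1,b:0.2,c:0.15);")
toy_tree4 <- function()
  ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.08);")
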