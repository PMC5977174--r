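#' Codon substitution rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of the Goldman-Yang style
#' codon model: only single-nucleotide codon changes have non-zero rate, the
#' rate to codon j is proportional to the equilibrium frequency of j,
#' multiplied by `kappa` for transitions and by `omega` for nonsynonymous
#' changes. The matrix is scaled (by default) so that the mean rate at
#' equilibrium is one substitution per codon site, giving branch lengths in
#' expected substitutions per codon.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param freqs equilibrium frequencies over the 61 sense codons (sums to 1).
#' @param scale if `TRUE` (default), normalise to mean rate 1.
#' @return 61 x 61 matrix with zero row sums.
#' @examples
#' Q <- codon_rate_matrix(2, 0.3, rep(1 / 61, 61))
#' max(abs(rowSums(Q))) < 1e-12
#' @export
codon_rate_matrix <- function(kappa, omega, freqs, scale = TRUE) {
  if (kappa <= 0 || omega < 0) stop("kappa must be > 0 and omega >= 0")
  if (length(freqs) != 61L || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 61 non-negative values summing to 1")
  pt <- codon_pair_table()
  Q <- matrix(0, 61, 61)
  Q[pt$single] <- 1
  Q <- Q * rep(freqs, each = 61)
  Q[pt$single & pt$transition] <- Q[pt$single & pt$transition] * kappa
  ns <- pt$single & !pt$synonymous
  Q[ns] <- Q[ns] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(freqs * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Eigendecomposition of a reversible rate matrix through its symmetrised
# form; returns V, Vi, values with Q = V diag(values) Vi.
rev_eigen <- function(Q, freqs) {
  sq <- sqrt(freqs)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors / sq, Vi = t(e$vectors) * rep(sq, each = length(sq)),
       values = e$values)
}

# Transition probability matrix from a cached decomposition.
prob_matrix <- function(eig, t) {
  P <- (eig$V * rep(exp(eig$values * t), each = nrow(eig$Vi))) %*% eig$Vi
  P[P < 0] <- 0
  P
}

#' Transition probabilities under a codon model
#'
#' Convenience wrapper computing `expm(Q t)` through the reversible
#' eigendecomposition.
#'
#' @param Q rate matrix from [codon_rate_matrix()].
#' @param freqs the equilibrium frequencies used to build `Q`.
#' @param t branch length (expected substitutions per codon site).
#' @return transition probability matrix (rows sum to 1).
#' @export
codon_prob_matrix <- function(Q, freqs, t) {
  if (t < 0) stop("branch length must be non-negative")
  prob_matrix(rev_eigen(Q, freqs), t)
}
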