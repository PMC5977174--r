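## Maximum-likelihood fitting of the codon model families.
##
## All optimisation runs on transformed parameters: bounded quantities via a
## scaled logit (kappa in [0.05, 50], omega in [1e-4, 999], beta shapes in
## [0.005, 99]), class proportions via stick-breaking logits, branch
## lengths / scale on the log scale. This keeps the optimiser unconstrained
## while the natural parameters respect their bounds.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.to_nat <- function(x, lo, hi) lo + (hi - lo) * .sigmoid(x)
.to_unc <- function(v, lo, hi) {
  v <- pmin(pmax(v, lo + (hi - lo) * 1e-10), hi - (hi - lo) * 1e-10)
  log((v - lo) / (hi - v))
}

.BOUNDS <- list(kappa = c(0.05, 50), omega = c(1e-4, 999),
                omega0 = c(1e-4, 1), omega2 = c(1, 999),
                shape = c(0.005, 99), scale = c(1e-4, 100))

# Parameter schema per family: bounded entries and stick-breaking entries.
param_schema <- function(family) {
  B <- .BOUNDS
  sw <- switch(family,
    M0 = list(omega = B$omega),
    BRANCH2 = list(omega_fore = B$omega, omega_back = B$omega),
    M1a = list(omega0 = B$omega0),
    M2a = list(omega0 = B$omega0, omega2 = B$omega2),
    M7 = list(p = B$shape, q = B$shape),
    M8 = list(p = B$shape, q = B$shape, omega2 = B$omega2),
    MODEL_A = list(omega0 = B$omega0, omega2 = B$omega2),
    MODEL_A_NULL = list(omega0 = B$omega0))
  sticks <- switch(family,
    M1a = "p0", M8 = "p0",
    M2a = c("p0", "p1"), MODEL_A = c("p0", "p1"),
    MODEL_A_NULL = c("p0", "p1"), character(0))
  list(bounded = c(list(kappa = B$kappa), sw), sticks = sticks)
}

pack_par <- function(par, schema, scale_mode, nedge) {
  x <- vapply(names(schema$bounded), function(nm)
    .to_unc(par[[nm]], schema$bounded[[nm]][1], schema$bounded[[nm]][2]), 0)
  if (length(schema$sticks)) {
    rem <- 1
    for (nm in schema$sticks) {
      frac <- min(max(par[[nm]] / rem, 1e-6), 1 - 1e-6)
      x <- c(x, setNames(log(frac / (1 - frac)), paste0(".s_", nm)))
      rem <- max(rem - rem * frac, 1e-8)
    }
  }
  if (scale_mode == "scale") {
    x <- c(x, .scale = .to_unc(par$scale, .BOUNDS$scale[1], .BOUNDS$scale[2]))
  } else {
    x <- c(x, setNames(log(pmax(par$edge_len, 1e-8)),
                       paste0(".b", seq_len(nedge))))
  }
  x
}

unpack_par <- function(x, schema, scale_mode, nedge) {
  par <- list()
  for (nm in names(schema$bounded))
    par[[nm]] <- .to_nat(x[[nm]], schema$bounded[[nm]][1],
                         schema$bounded[[nm]][2])
  rem <- 1
  for (nm in schema$sticks) {
    frac <- .sigmoid(x[[paste0(".s_", nm)]])
    # keep proportions away from exact 0/1 for numerical stability
    frac <- min(max(frac, 1e-8), 1 - 1e-8)
    par[[nm]] <- rem * frac
    rem <- rem - par[[nm]]
  }
  if (scale_mode == "scale") {
    par$scale <- .to_nat(x[[".scale"]], .BOUNDS$scale[1], .BOUNDS$scale[2])
  } else {
    par$scale <- 1
    par$edge_len <- pmin(pmax(exp(unname(
      x[grepl("^\\.b", names(x))])), 1e-8), 20)
  }
  par
}

default_start <- function(family) {
  list(kappa = 2, omega = 0.3, omega_fore = 0.3, omega_back = 0.3,
       omega0 = 0.1, omega2 = 2, p = 0.5, q = 1.5,
       p0 = if (family %in% c("M8")) 0.9 else 0.6,
       p1 = 0.3, scale = 1)
}

jitter_start <- function(start, schema) {
  for (nm in names(schema$bounded)) {
    b <- schema$bounded[[nm]]
    start[[nm]] <- .to_nat(.to_unc(start[[nm]], b[1], b[2]) +
                             stats::rnorm(1, 0, 0.7), b[1], b[2])
  }
  start$scale <- start$scale * exp(stats::rnorm(1, 0, 0.4))
  start
}

# boundary diagnosis on the natural scale: an MLE pressed against its box
# (e.g. the branch scale collapsing to zero on an invariant alignment)
detect_boundary <- function(par, schema, scale_mode) {
  near <- function(v, b) v <= b[1] * 1.05 + 1e-12 || v >= b[2] / 1.05
  hit <- vapply(names(schema$bounded), function(nm)
    near(par[[nm]], schema$bounded[[nm]]), logical(1))
  for (nm in schema$sticks)
    hit <- c(hit, par[[nm]] < 1e-6 || par[[nm]] > 1 - 1e-6)
  if (scale_mode == "scale") {
    hit <- c(hit, near(par$scale, .BOUNDS$scale))
  } else {
    hit <- c(hit, any(par$edge_len <= 1.05e-8) || any(par$edge_len >= 19))
  }
  any(hit)
}

# forward-difference gradient reusing a cached objective value
fd_grad <- function(fn) {
  function(x) {
    f0 <- fn(x)
    h <- 1e-6 * (1 + abs(x))
    vapply(seq_along(x), function(i) {
      xi <- x
      xi[i] <- xi[i] + h[i]
      (fn(xi) - f0) / h[i]
    }, 0)
  }
}

#' Fit a codon model by maximum likelihood
#'
#' Bounded quasi-Newton (BFGS on transformed parameters) with seeded
#' multi-start. By default branch lengths are taken from the input tree and
#' only a single multiplicative scale is re-estimated
#' (`branch_lengths = "scale"`); `branch_lengths = "full"` re-estimates every
#' branch length (intended for the one-ratio model, once per gene).
#'
#' @inheritParams log_likelihood
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of optimisation restarts (default 3).
#' @param branch_lengths `"scale"` or `"full"`.
#' @param init optional named list of starting values overriding the
#'   defaults for the first start (e.g. chain an alternative fit from its
#'   null's estimates).
#' @param maxit maximum BFGS iterations per start.
#' @return a `codon_fit`: `lnL`, `par` (MLEs on the natural scale), `spec`,
#'   `np` (free parameter count), `convergence`, `boundary`, `restarts`,
#'   `freqs`, and the tree with fitted branch lengths.
#' @export
fit_model <- function(align, tree, spec, seed = 1, foreground_taxa = NULL,
                      freqs = NULL, n_starts = 3,
                      branch_lengths = c("scale", "full"), init = NULL,
                      maxit = 300) {
  branch_lengths <- match.arg(branch_lengths)
  if (length(align$taxa) < 3) stop("alignment must have >= 3 taxa")
  if (spec$family %in% c("BRANCH2", "MODEL_A", "MODEL_A_NULL")) {
    if (is.null(foreground_taxa))
      stop("foreground_taxa required for branch / branch-site models")
  }
  if (is.null(freqs)) freqs <- codon_frequencies(align, spec$freq)
  prep <- pruning_data(align, tree, foreground_taxa)
  if (!is.null(foreground_taxa)) {
    if (all(prep$fg == 1L)) stop("all branches are foreground")
    if (all(prep$fg == 0L)) stop("no foreground branches")
  }
  schema <- param_schema(spec$family)
  nedge <- nrow(prep$edge)

  neg_lnl <- function(x) {
    par <- unpack_par(x, schema, branch_lengths, nedge)
    pp <- prep
    if (branch_lengths == "full") pp$edge_len <- par$edge_len
    v <- tryCatch(lnl_from_prep(pp, spec, par, freqs),
                  error = function(e) -Inf)
    if (!is.finite(v)) return(1e10)
    -v
  }

  start <- default_start(spec$family)
  if (!is.null(init)) start[names(init)] <- init
  if (branch_lengths == "full") start$edge_len <- prep$edge_len
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))

  best <- NULL
  conv <- FALSE
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start else jitter_start(start, schema)
    if (branch_lengths == "full") st$edge_len <- prep$edge_len
    x0 <- pack_par(st, schema, branch_lengths, nedge)
    opt <- tryCatch(
      stats::optim(x0, neg_lnl, gr = fd_grad(neg_lnl), method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) conv <- TRUE
  }
  if (is.null(best))
    return(structure(list(lnL = NA_real_, par = NULL, spec = spec,
                          convergence = FALSE, boundary = FALSE,
                          restarts = n_starts, freqs = freqs,
                          np = NA_integer_),
                     class = "codon_fit"))
  par <- unpack_par(best$par, schema, branch_lengths, nedge)
  boundary <- detect_boundary(par, schema, branch_lengths)
  tr <- prep$tree
  if (branch_lengths == "full") {
    tr$edge.length <- par$edge_len
  } else {
    tr$edge.length <- tr$edge.length * par$scale
  }
  np <- spec$np_model + 1L +
    (if (branch_lengths == "full") nedge else 1L)
  structure(list(lnL = -best$value, par = par, spec = spec,
                 convergence = conv && best$convergence == 0,
                 boundary = boundary, restarts = n_starts, freqs = freqs,
                 foreground_taxa = foreground_taxa, tree = tr, np = np,
                 branch_lengths = branch_lengths),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model", x$spec$family, " lnL =", format(x$lnL, digits = 10),
      if (!x$convergence) "(NOT converged)",
      if (x$boundary) "(boundary)", "\n")
  core <- x$par[!names(x$par) %in% "edge_len"]
  cat(paste(names(core), signif(unlist(core), 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' One-ratio and two-ratio branch model fits
#'
#' Fits the nested pair used for the "did selective pressure change in the
#' dioecious clade" question: a single dN/dS across the tree versus separate
#' foreground/background ratios (LRT df = 1).
#'
#' @inheritParams fit_model
#' @return list with elements `one` and `two` (both `codon_fit`).
#' @export
fit_branch_two_ratio <- function(align, tree, foreground_taxa, seed = 1,
                                 n_starts = 3,
                                 branch_lengths = c("scale", "full"),
                                 freqs = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  one <- fit_model(align, tree, codon_model("M0"), seed = seed,
                   foreground_taxa = foreground_taxa, n_starts = n_starts,
                   branch_lengths = branch_lengths, freqs = freqs)
  two <- fit_model(align, tree, codon_model("BRANCH2"), seed = seed,
                   foreground_taxa = foreground_taxa, n_starts = n_starts,
                   branch_lengths = branch_lengths, freqs = freqs,
                   init = list(omega_fore = one$par$omega,
                               omega_back = one$par$omega,
                               kappa = one$par$kappa,
                               scale = one$par$scale))
  list(one = one, two = two)
}

.LRT_PAIRS <- list(c("BRANCH2", "M0", 1), c("M2a", "M1a", 2),
                   c("M8", "M7", 2), c("MODEL_A", "MODEL_A_NULL", 1))

#' Likelihood ratio test between nested codon-model fits
#'
#' The statistic is `2 (lnL_alt - lnL_null)`, clamped at zero (with a
#' warning) if numerically negative, and referred to the chi-squared
#' distribution with `df` degrees of freedom.
#'
#' @param fit_alt,fit_null `codon_fit` objects (or bare log-likelihoods).
#' @param df degrees of freedom; checked against the known nested pairs when
#'   both fits carry their family.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt <- function(fit_alt, fit_null, df) {
  l1 <- if (inherits(fit_alt, "codon_fit")) fit_alt$lnL else fit_alt
  l0 <- if (inherits(fit_null, "codon_fit")) fit_null$lnL else fit_null
  if (df < 1) stop("df must be >= 1")
  if (!is.finite(l1) || !is.finite(l0))
    stop("cannot form an LRT from a failed fit (non-finite lnL)")
  if (inherits(fit_alt, "codon_fit") && inherits(fit_null, "codon_fit")) {
    for (p in .LRT_PAIRS) {
      if (fit_alt$spec$family == p[1] && fit_null$spec$family == p[2] &&
          df != as.numeric(p[3]))
        stop("df = ", df, " does not match the ", p[1], "/", p[2],
             " pair (expected ", p[3], ")")
    }
  }
  stat <- 2 * (l1 - l0)
  if (stat < 0) {
    if (stat < -1e-6)
      warning("alternative lnL below null by ", format(-stat / 2),
              "; statistic clamped to 0")
    stat <- 0
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Pairwise dN/dS between two coding sequences
#'
#' ML estimation on a two-taxon tree under the one-ratio model with F3x4
#' frequencies. `dN` and `dS` are per-site distances obtained by
#' partitioning the fitted substitution flux into synonymous and
#' nonsynonymous parts and dividing by the synonymous / nonsynonymous site
#' counts (mutational opportunity at omega = 1). When the synonymous
#' distance is zero the ratio is undefined and flagged.
#'
#' @param seqA,seqB nucleotide strings (in frame, equal length) or a
#'   2-sequence named character vector.
#' @param mask_stops passed to the codon indexing.
#' @return list with `dN`, `dS`, `omega` (`NA` and `omega_defined = FALSE`
#'   when dS = 0), `t`, `kappa`.
#' @export
pairwise_dnds <- function(seqA, seqB, mask_stops = FALSE) {
  al <- codon_alignment(c(A = unname(seqA), B = unname(seqB)),
                        mask_stops = mask_stops)
  s1 <- al$codons[1, ]; s2 <- al$codons[2, ]
  keep <- !is.na(s1) & !is.na(s2)
  if (!any(keep)) stop("no shared non-missing codons")
  s1 <- s1[keep]; s2 <- s2[keep]
  freqs <- codon_frequencies(al, "F3x4")
  key <- paste(s1, s2)
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  u1 <- s1[first]; u2 <- s2[first]

  nll <- function(x) {
    t <- exp(x[1])
    kap <- .to_nat(x[2], 0.05, 50)
    om <- .to_nat(x[3], 1e-4, 999)
    Q <- codon_rate_matrix(kap, om, freqs)
    P <- prob_matrix(rev_eigen(Q, freqs), t)
    ll <- sum(w * log(pmax(freqs[u1] * P[cbind(u1, u2)], 1e-300)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ndiff <- sum(w[u1 != u2]) / sum(w)
  if (ndiff == 0)
    return(list(dN = 0, dS = 0, omega = NA_real_, omega_defined = FALSE,
                t = 0, kappa = NA_real_))
  t0 <- max(ndiff, 1e-4)
  opt <- stats::optim(c(log(t0), .to_unc(2, 0.05, 50),
                        .to_unc(0.5, 1e-4, 999)), nll, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  t <- exp(opt$par[1]); kap <- .to_nat(opt$par[2], 0.05, 50)
  om <- .to_nat(opt$par[3], 1e-4, 999)

  flux <- function(omega) {
    Q <- codon_rate_matrix(kap, omega, freqs)
    pt <- codon_pair_table()
    syn <- sum((freqs %o% rep(1, 61)) * Q * (pt$single & pt$synonymous))
    c(syn = syn, nonsyn = 1 - syn)
  }
  a <- flux(om)     # realised flux proportions under the MLE
  a1 <- flux(1)     # site proportions (mutational opportunity)
  dS <- t * a[["syn"]] / (3 * a1[["syn"]])
  dN <- t * a[["nonsyn"]] / (3 * a1[["nonsyn"]])
  defined <- dS > 1e-8 && t > 1e-8
  list(dN = if (t > 1e-8) dN else 0, dS = if (t > 1e-8) dS else 0,
       omega = if (defined) om else NA_real_, omega_defined = defined,
       t = t, kappa = kap)
}
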