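## Codon usage bias statistics (ENC, FOP) and lineage-specific
## preferred/unpreferred synonymous change counting.

#' Effective number of codons (ENC)
#'
#' Wright's estimator: per amino acid, the codon homozygosity
#' `F = (n * sum(p^2) - 1) / (n - 1)` with `n` the codon count for that
#' amino acid; family averages over the 2-, 3-, 4- and 6-fold degenerate
#' classes; `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. Six-fold families are
#' their own class. An unobserved class is imputed from the nearest observed
#' classes by degeneracy (the 3-fold class, when absent, is the mean of the
#' 2- and 4-fold averages). Values above 61 are clamped to 61 and below 20
#' to 20.
#'
#' @param counts named codon counts over the 61 sense codons (see
#'   [codon_counts()]).
#' @param min_codons genes with fewer total codons are flagged and return
#'   `NA` (default 100).
#' @return list with `enc`, `f_bar` (per-class averages), `flagged`,
#'   `reason`.
#' @export
enc <- function(counts, min_codons = 100) {
  gcd <- genetic_code()
  total <- sum(counts)
  if (total < min_codons)
    return(list(enc = NA_real_, f_bar = NULL, flagged = TRUE,
                reason = sprintf("fewer than %d codons", min_codons)))
  deg_classes <- c(2, 3, 4, 6)
  n_aa <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  f_bar <- setNames(rep(NA_real_, 4), deg_classes)
  for (k in deg_classes) {
    aas <- names(gcd$degeneracy)[gcd$degeneracy == k]
    fs <- numeric(0)
    for (a in aas) {
      n <- sum(counts[gcd$aa == a])
      if (n < 2) next
      p <- counts[gcd$aa == a] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) fs <- c(fs, f)
    }
    if (length(fs)) f_bar[as.character(k)] <- mean(fs)
  }
  if (all(is.na(f_bar)))
    return(list(enc = NA_real_, f_bar = f_bar, flagged = TRUE,
                reason = "no degenerate family observed"))
  # impute absent classes from nearest observed degeneracies
  for (i in seq_along(deg_classes)) {
    if (is.na(f_bar[i])) {
      obs <- which(!is.na(f_bar))
      d <- abs(deg_classes[obs] - deg_classes[i])
      near <- obs[d == min(d)]
      f_bar[i] <- mean(f_bar[near])
    }
  }
  val <- 2 + sum(n_aa / f_bar)
  list(enc = min(max(val, 20), 61), f_bar = f_bar, flagged = FALSE,
       reason = NA_character_)
}

#' Frequency of optimal codons (FOP)
#'
#' Fraction of codon occurrences that are optimal, among occurrences of
#' codons whose amino acid has at least one optimal codon in `optimal_set`.
#'
#' @param counts named codon counts over the 61 sense codons.
#' @param optimal_set character vector of optimal codons.
#' @return the fraction in `[0, 1]` (`NA` if no eligible codon occurs).
#' @export
fop <- function(counts, optimal_set) {
  if (length(optimal_set) == 0) stop("optimal_set must be non-empty")
  optimal_set <- toupper(optimal_set)
  gcd <- genetic_code()
  if (!all(optimal_set %in% gcd$codons))
    stop("unknown codons in optimal set: ",
         paste(setdiff(optimal_set, gcd$codons), collapse = ", "))
  opt_aa <- unique(gcd$aa[gcd$codons %in% optimal_set])
  eligible <- gcd$aa %in% opt_aa
  denom <- sum(counts[eligible])
  if (denom == 0) return(NA_real_)
  sum(counts[gcd$codons %in% optimal_set]) / denom
}

#' Read an optimal-codon list (one codon per line)
#' @param path text file; lines starting with `#` are ignored.
#' @export
read_optimal_codons <- function(path) {
  x <- trimws(readLines(path))
  toupper(x[x != "" & !startsWith(x, "#")])
}

#' Count preferred/unpreferred synonymous codon changes on a lineage
#'
#' Compares an ancestral and a descendant codon sequence site by site. A
#' site counts when the two codons are synonymous and differ at exactly one
#' nucleotide: P to U when the ancestor codon is preferred and the
#' descendant is not, U to P for the reverse. Codons differing at more than
#' one position (ambiguous substitution path) are tallied as excluded;
#' nonsynonymous and preferred-to-preferred / unpreferred-to-unpreferred
#' changes are ignored.
#'
#' @param ancestor_seq,descendant_seq nucleotide strings of equal length
#'   (in frame), e.g. a reconstructed ancestor and a modern tip.
#' @param preferred_set character vector of preferred codons.
#' @return list with `p_to_u`, `u_to_p`, `excluded_multistep`,
#'   `synonymous_changes`.
#' @export
count_pu_changes <- function(ancestor_seq, descendant_seq, preferred_set) {
  al <- codon_alignment(c(anc = unname(ancestor_seq),
                          des = unname(descendant_seq)), mask_stops = TRUE)
  gcd <- genetic_code()
  preferred_set <- toupper(preferred_set)
  pt <- codon_pair_table()
  a <- al$codons[1, ]; d <- al$codons[2, ]
  ok <- !is.na(a) & !is.na(d) & a != d
  a <- a[ok]; d <- d[ok]
  single <- pt$single[cbind(a, d)]
  syn <- pt$synonymous[cbind(a, d)]
  multi <- sum(!single)
  a1 <- a[single & syn]; d1 <- d[single & syn]
  a_pref <- gcd$codons[a1] %in% preferred_set
  d_pref <- gcd$codons[d1] %in% preferred_set
  list(p_to_u = sum(a_pref & !d_pref), u_to_p = sum(!a_pref & d_pref),
       excluded_multistep = multi, synonymous_changes = length(a1))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric p by the probability-mass rule. A zero margin makes
#' the table degenerate; p = 1 is returned with a note.
#'
#' @param table 2x2 matrix (or 4 counts, row-wise) of non-negative
#'   integers.
#' @return list with `p`, `odds_ratio`, `note`.
#' @export
fisher_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2, 2, byrow = !is.matrix(table))
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p = 1, odds_ratio = NA_real_, note = "zero margin"))
  ft <- stats::fisher.test(m)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), note = NA_character_)
}

#' Per-gene codon usage summary
#'
#' @param align a `codon_alignment`.
#' @param optimal_set optimal codons for FOP.
#' @param min_codons ENC length threshold.
#' @return data.frame with one row per taxon: codon totals, ENC (with flag),
#'   FOP.
#' @export
codon_usage_stats <- function(align, optimal_set, min_codons = 100) {
  rows <- lapply(align$taxa, function(tx) {
    ct <- codon_counts(align, tx)
    e <- enc(ct, min_codons = min_codons)
    data.frame(taxon = tx, n_codons = sum(ct), enc = e$enc,
               enc_flagged = e$flagged, fop = fop(ct, optimal_set),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
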