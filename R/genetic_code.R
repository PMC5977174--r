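## The universal genetic code, indexed over the 61 sense codons.
## Everything downstream (rate matrices, degeneracy classes, four-fold
## site identification, ENC families) is derived from this one table.

.CODE_NT <- c("T", "C", "A", "G")

# Amino acids in TCAG order (first position slowest): TTT, TTC, TTA, ...
.CODE_AA64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]

.all_codons <- function() {
  g <- expand.grid(p3 = .CODE_NT, p2 = .CODE_NT, p1 = .CODE_NT,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' The universal genetic code over the 61 sense codons
#'
#' Returns the code table used throughout the package: the ordered sense
#' codons, their amino acids, the stop set, per-amino-acid synonymous family
#' size (degeneracy), and the set of codons that are four-fold degenerate at
#' the third position.
#'
#' @return A list with components `codons` (61 sense codons, character),
#'   `aa` (one-letter amino acid per codon), `stops` (the three stop codons),
#'   `degeneracy` (named integer, synonymous family size per amino acid),
#'   and `fourfold` (logical over the 61 codons: third position four-fold
#'   degenerate).
#' @examples
#' gc <- genetic_code()
#' length(gc$codons) # 61
#' @export
genetic_code <- function() {
  if (!is.null(.fx$code)) return(.fx$code)
  codons <- .all_codons()
  aa <- .CODE_AA64
  stops <- codons[aa == "*"]
  sense <- aa != "*"
  codons <- codons[sense]
  aa <- aa[sense]
  degeneracy <- table(aa)
  degeneracy <- setNames(as.integer(degeneracy), names(degeneracy))
  # third-position four-fold degeneracy: the codon's first two bases fix the
  # amino acid whatever the third base is
  pre <- substr(codons, 1, 2)
  fourfold <- vapply(pre, function(p) {
    length(unique(.CODE_AA64[match(paste0(p, .CODE_NT), .all_codons())])) == 1L
  }, logical(1))
  code <- list(codons = codons, aa = aa, stops = stops,
               degeneracy = degeneracy, fourfold = unname(fourfold))
  .fx$code <- code
  code
}

#' @rdname genetic_code
#' @export
sense_codons <- function() genetic_code()$codons

codon_index <- function(codon) {
  match(codon, genetic_code()$codons)
}

# Pairwise single-nucleotide-change structure over the 61 sense codons:
# for each ordered pair, whether the change is a single-nucleotide change,
# a transition, and synonymous. Cached; used by the rate matrix builder,
# the simulator and the P/U change counter.
codon_pair_table <- function() {
  if (!is.null(.fx$pairs)) return(.fx$pairs)
  gc <- genetic_code()
  n <- length(gc$codons)
  m <- do.call(rbind, strsplit(gc$codons, ""))
  diffs <- matrix(0L, n, n)
  for (p in 1:3) diffs <- diffs + outer(m[, p], m[, p], "!=")
  single <- diffs == 1L
  pur <- c("A", "G")
  is_ts <- function(a, b) (a %in% pur) == (b %in% pur)
  ts <- matrix(FALSE, n, n)
  idx <- which(single, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    p <- which(m[i, ] != m[j, ])
    ts[i, j] <- is_ts(m[i, p], m[j, p])
  }
  syn <- outer(gc$aa, gc$aa, "==")
  .fx$pairs <- list(single = single, transition = ts, synonymous = syn)
  .fx$pairs
}
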