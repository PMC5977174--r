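## Silent-site nucleotide diversity and Tajima's D from diploid sequences
## with IUPAC-coded heterozygotes.

.IUPAC_DIPLOID <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
                       T = c("T", "T"),
                       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                       W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' Read a diploid panel from IUPAC-coded FASTA
#'
#' Each individual contributes two allele copies per site: heterozygous
#' IUPAC symbols expand to their base pair, `N` and `-` are missing, and the
#' parsing is case-insensitive. Any other symbol is an error naming the
#' individual and position.
#'
#' @param path aligned FASTA of diploid consensus sequences.
#' @return a `diploid_panel` (as from [simulate_population()], without the
#'   reference).
#' @export
read_diploid_fasta <- function(path) {
  sq <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           seqtype = "AA")  # keep arbitrary symbols intact
  seqs <- toupper(vapply(sq, as.character, ""))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences must be aligned (equal length)")
  valid <- c(names(.IUPAC_DIPLOID), "N", "-", "?")
  m <- matrix("", length(seqs), len,
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!ch %in% valid)
    if (length(bad))
      stop("unknown symbol '", ch[bad[1]], "' in '", names(seqs)[i],
           "' at position ", bad[1])
    m[i, ] <- ch
  }
  structure(list(individuals = names(seqs), seq = m),
            class = "diploid_panel")
}

# 2n x sites allele matrix (NA = missing copy)
allele_matrix <- function(panel) {
  m <- panel$seq
  n <- nrow(m)
  out <- matrix(NA_character_, 2 * n, ncol(m))
  for (i in seq_len(n)) {
    ex <- .IUPAC_DIPLOID[m[i, ]]
    miss <- vapply(ex, is.null, logical(1))
    out[2 * i - 1, !miss] <- vapply(ex[!miss], `[`, "", 1)
    out[2 * i, !miss] <- vapply(ex[!miss], `[`, "", 2)
  }
  out
}

#' Silent-site mask from a reference CDS
#'
#' Third positions of reference codons that are four-fold degenerate — the
#' strict reading of "silent sites". `mode = "synonymous"` widens the mask
#' to the third position of every codon with any synonymous third-position
#' variant.
#'
#' @param reference_cds in-frame nucleotide string (no internal stops).
#' @param mode `"fourfold"` (default) or `"synonymous"`.
#' @return integer positions (1-based, nucleotide coordinates).
#' @export
silent_site_mask <- function(reference_cds, mode = c("fourfold",
                                                     "synonymous")) {
  mode <- match.arg(mode)
  al <- codon_alignment(c(ref = unname(reference_cds)))
  gcd <- genetic_code()
  idx <- al$codons[1, ]
  third_syn <- if (mode == "fourfold") gcd$fourfold else {
    # any synonymous third-position neighbour
    pt <- codon_pair_table()
    m <- do.call(rbind, strsplit(gcd$codons, ""))
    same12 <- outer(paste0(m[, 1], m[, 2]), paste0(m[, 1], m[, 2]), "==")
    rowSums(pt$single & pt$synonymous & same12) > 0
  }
  ok <- !is.na(idx) & third_syn[ifelse(is.na(idx), 1L, idx)]
  which(rep(ok, each = 3) & (seq_len(3 * al$n_sites) %% 3 == 0))
}

site_heterozygosity <- function(bases) {
  b <- bases[!is.na(bases)]
  k <- length(b)
  if (k < 2) return(c(h = NA_real_, k = k, seg = NA))
  cnt <- table(b)
  h <- (k^2 - sum(cnt^2)) / (k * (k - 1))
  c(h = h, k = k, seg = as.numeric(length(cnt) > 1))
}

#' Silent-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 sum c_i c_j / (k (k - 1))` over
#' non-missing allele copies, averaged over the usable masked sites (at
#' least `min_alleles` copies). Phase-free: everything is per-site.
#'
#' @param panel a `diploid_panel`.
#' @param mask site positions (e.g. from [silent_site_mask()]); default all
#'   sites.
#' @param min_alleles minimum non-missing allele copies per usable site
#'   (default 4).
#' @return list with `pi`, `n_sites` (usable), `S` (segregating usable
#'   sites), `theta_pi_total` (summed heterozygosity), `n_alleles_mode`,
#'   `flagged`.
#' @export
nucleotide_diversity <- function(panel, mask = NULL, min_alleles = 4) {
  if (nrow(panel$seq) < 2) stop("need at least 2 individuals")
  am <- allele_matrix(panel)
  if (is.null(mask)) mask <- seq_len(ncol(am))
  stats <- vapply(mask, function(s) site_heterozygosity(am[, s]),
                  c(h = 0, k = 0, seg = 0))
  usable <- !is.na(stats["h", ]) & stats["k", ] >= min_alleles
  if (!any(usable))
    return(list(pi = NA_real_, n_sites = 0L, S = 0L, theta_pi_total = 0,
                n_alleles_mode = NA_integer_, flagged = TRUE))
  h <- stats["h", usable]
  ks <- stats["k", usable]
  mode_k <- as.integer(names(which.max(table(ks))))
  list(pi = mean(h), n_sites = sum(usable),
       S = as.integer(sum(stats["seg", usable])),
       theta_pi_total = sum(h), n_alleles_mode = mode_k,
       flagged = diff(range(ks)) > 2)
}

#' Tajima's D
#'
#' Standard constants from the allele count `n`;
#' `D = (theta_pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Undefined (with an
#' explicit flag) when `S = 0`.
#'
#' @param S number of segregating sites.
#' @param n number of sampled allele copies (>= 4).
#' @param theta_pi total mean pairwise differences (summed site
#'   heterozygosity over the same sites as `S`).
#' @return list with `D` and `defined`.
#' @export
tajimas_d <- function(S, n, theta_pi) {
  if (n < 4) stop("Tajima's D needs at least 4 allele copies")
  if (S == 0) return(list(D = NA_real_, defined = FALSE))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, defined = TRUE)
}

#' Per-gene diversity summary
#'
#' Combines the silent mask, per-site diversity and Tajima's D for one gene.
#'
#' @param panel a `diploid_panel`.
#' @param reference_cds reference CDS defining the silent mask (for panels
#'   from [simulate_population()] the panel's own reference is used when
#'   omitted).
#' @param gene gene id for the output row.
#' @param min_alleles per-site allele threshold.
#' @param mask_mode passed to [silent_site_mask()].
#' @return one-row data.frame: gene, n_silent_sites, S, pi, theta_pi_total,
#'   n_alleles, tajimas_d, d_defined, flagged.
#' @export
diversity_summary <- function(panel, reference_cds = NULL, gene = "gene",
                              min_alleles = 4,
                              mask_mode = c("fourfold", "synonymous")) {
  mask_mode <- match.arg(mask_mode)
  if (is.null(reference_cds)) reference_cds <- panel$ref_cds
  if (is.null(reference_cds))
    stop("a reference CDS is required to define silent sites")
  mask <- silent_site_mask(reference_cds, mode = mask_mode)
  nd <- nucleotide_diversity(panel, mask, min_alleles = min_alleles)
  d <- if (!is.na(nd$pi) && nd$S > 0)
    tajimas_d(nd$S, nd$n_alleles_mode, nd$theta_pi_total)
  else list(D = NA_real_, defined = FALSE)
  data.frame(gene = gene, n_silent_sites = nd$n_sites, S = nd$S,
             pi = nd$pi, theta_pi_total = nd$theta_pi_total,
             n_alleles = nd$n_alleles_mode, tajimas_d = d$D,
             d_defined = d$defined, flagged = isTRUE(nd$flagged),
             stringsAsFactors = FALSE)
}
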