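#' Load an in-frame codon alignment from a FASTA file
#'
#' Reads an aligned FASTA of coding sequences and indexes every codon against
#' the 61 sense codons. Codons containing a gap or an ambiguous base are
#' stored as missing. An internal stop codon is a data error and aborts the
#' load with the offending taxon and codon site, unless `mask_stops = TRUE`,
#' in which case stops are converted to missing.
#'
#' @param path FASTA file of equal-length, in-frame coding sequences.
#' @param frame reading-frame offset (0, 1 or 2 bases trimmed from the
#'   start).
#' @param mask_stops convert internal stop codons to missing instead of
#'   erroring.
#' @return A `codon_alignment`: list with `taxa`, integer matrix `codons`
#'   (taxa x sites, `NA` = missing) and `n_sites`.
#' @export
load_codon_alignment <- function(path, frame = 0, mask_stops = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(seqs), paste, "", collapse = ""))
  codon_alignment(seqs, frame = frame, mask_stops = mask_stops)
}

#' Build a codon alignment from character sequences
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @inheritParams load_codon_alignment
#' @return a `codon_alignment` object.
#' @export
codon_alignment <- function(seqs, frame = 0, mask_stops = FALSE) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  if (frame > 0) seqs <- substring(seqs, frame + 1)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  if (len %% 3 != 0)
    stop("alignment length ", len, " is not divisible by 3")
  L <- len %/% 3
  if (L < 1) stop("alignment must contain at least one codon")
  gc <- genetic_code()
  codons <- matrix(NA_integer_, length(seqs), L,
                   dimnames = list(names(seqs), NULL))
  starts <- seq(1, len, by = 3)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[[i]], starts, starts + 2)
    idx <- match(cods, gc$codons)
    stop_hit <- cods %in% gc$stops
    if (any(stop_hit)) {
      if (mask_stops) {
        idx[stop_hit] <- NA_integer_
      } else {
        s <- which(stop_hit)[1]
        stop("internal stop codon ", cods[s], " in taxon '", names(seqs)[i],
             "' at codon site ", s,
             " (use mask_stops = TRUE to mask instead)")
      }
    }
    # anything not a clean sense codon (gap, N, other IUPAC) is missing
    codons[i, ] <- idx
  }
  structure(list(taxa = names(seqs), codons = codons, n_sites = L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$taxa), "taxa,", x$n_sites,
      "codon sites,", sum(is.na(x$codons)), "missing codons\n")
  invisible(x)
}

n_missing <- function(align) sum(is.na(align$codons))

#' Equilibrium codon frequencies from alignment counts
#'
#' @param align a `codon_alignment`.
#' @param method `"F3x4"` (position-specific nucleotide frequencies, the
#'   default), `"F1x4"` (overall nucleotide frequencies) or `"equal"`.
#' @return numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(align, method = c("F3x4", "F1x4", "equal")) {
  method <- match.arg(method)
  gc <- genetic_code()
  if (method == "equal") return(rep(1 / 61, 61))
  obs <- gc$codons[align$codons[!is.na(align$codons)]]
  if (length(obs) == 0) return(rep(1 / 61, 61))
  ntm <- do.call(rbind, strsplit(obs, ""))
  cm <- do.call(rbind, strsplit(gc$codons, ""))
  if (method == "F3x4") {
    f <- lapply(1:3, function(p) {
      tab <- table(factor(ntm[, p], levels = .CODE_NT))
      (tab + 0.5) / sum(tab + 0.5)  # small prior guards absent bases
    })
    w <- f[[1]][cm[, 1]] * f[[2]][cm[, 2]] * f[[3]][cm[, 3]]
  } else {
    tab <- table(factor(ntm, levels = .CODE_NT))
    f <- (tab + 0.5) / sum(tab + 0.5)
    w <- f[cm[, 1]] * f[cm[, 2]] * f[cm[, 3]]
  }
  as.numeric(w / sum(w))
}

#' Per-gene codon counts
#'
#' Counts codon occurrences over the 61 sense codons, either for one taxon
#' or pooled over all taxa.
#'
#' @param align a `codon_alignment`.
#' @param taxon optional taxon name; default pools all taxa.
#' @return named integer vector of length 61.
#' @export
codon_counts <- function(align, taxon = NULL) {
  gc <- genetic_code()
  x <- if (is.null(taxon)) align$codons else {
    if (!taxon %in% align$taxa) stop("unknown taxon: ", taxon)
    align$codons[match(taxon, align$taxa), , drop = FALSE]
  }
  tab <- tabulate(x[!is.na(x)], nbins = 61)
  setNames(tab, gc$codons)
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written as `---`.
#'
#' @param align a `codon_alignment`.
#' @param path output file.
#' @export
write_codon_fasta <- function(align, path) {
  gc <- genetic_code()
  lines <- character(0)
  for (i in seq_along(align$taxa)) {
    cods <- gc$codons[align$codons[i, ]]
    cods[is.na(cods)] <- "---"
    lines <- c(lines, paste0(">", align$taxa[i]),
               paste(cods, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
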