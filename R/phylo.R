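#' Label foreground branches by a taxon set
#'
#' Marks as foreground every branch of the tree whose descendant tips all
#' belong to `foreground_taxa` — i.e. the branches inside (and including the
#' stem of) the clade induced by that taxon set. In the study design the
#' foreground is the dioecious clade.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param foreground_taxa character vector of tip labels.
#' @return integer vector over `tree$edge` rows: 1 = foreground,
#'   0 = background.
#' @export
label_foreground <- function(tree, foreground_taxa) {
  if (!all(foreground_taxa %in% tree$tip.label))
    stop("foreground taxa not in tree: ",
         paste(setdiff(foreground_taxa, tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  fg_tip <- match(foreground_taxa, tree$tip.label)
  node_fg <- vapply(desc, function(d) all(d %in% fg_tip), logical(1))
  as.integer(node_fg[tree$edge[, 2]])
}

check_tree_alignment <- function(tree, align) {
  if (!setequal(tree$tip.label, align$taxa))
    stop("tree tips and alignment taxa differ")
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  invisible(TRUE)
}
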