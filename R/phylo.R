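# Phylogeny input and patristic distances.

#' Read a phylogeny from a Newick file
#'
#' Branch lengths are interpreted as million years. When `species` is given,
#' every cohort species must appear as a tip; extra tips are accepted and
#' noted.
#'
#' @param path Newick file path.
#' @param species Optional species labels to validate against the tips.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path, species = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_dysreg(
                     paste0("failed to parse Newick: ", conditionMessage(e)),
                     "dysregkit_format_error"))
  if (is.null(tree)) stop_dysreg("failed to parse Newick file",
                                 "dysregkit_format_error")
  validate_tree(tree, species)
}

validate_tree <- function(tree, species = NULL) {
  if (is.null(tree$edge.length)) {
    stop_dysreg("tree has no branch lengths", "dysregkit_format_error")
  }
  if (any(tree$edge.length < 0)) {
    stop_dysreg("tree has negative branch lengths", "dysregkit_format_error")
  }
  if (!is.null(species)) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss) > 0) {
      stop_dysreg(paste0("species absent from tree: ",
                         paste(miss, collapse = ", ")),
                  "dysregkit_config_error")
    }
    extra <- setdiff(tree$tip.label, species)
    if (length(extra) > 0) {
      message("tree has ", length(extra), " tip(s) not in the cohort; ignored")
    }
  }
  tree
}

#' Patristic distance matrix between species
#'
#' Tip-to-tip path lengths (sums of branch lengths, million years), ordered by
#' `species`. On an ultrametric tree each entry is twice the divergence time.
#'
#' @param tree An `ape::phylo` tree.
#' @param species Species ordering; all must be tips of `tree`.
#' @return Square symmetric numeric matrix with zero diagonal.
#' @export
patristic_distance_matrix <- function(tree, species) {
  validate_tree(tree, species)
  d <- ape::cophenetic.phylo(tree)
  d[species, species, drop = FALSE]
}
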