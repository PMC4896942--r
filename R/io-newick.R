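#' Write a tree in Newick format
#'
#' Serializes an `ape` `phylo` object, with bootstrap support values (if
#' present as `node.label`) emitted as internal node labels.  Leaf labels
#' must be unique and free of Newick syntax characters; violations are
#' errors, not silent escapes.  Output round-trips through
#' [read_newick()].
#'
#' @param tree an object of class `phylo`
#' @param path optional output path; if `NULL` the Newick string is
#'   returned
#' @return the Newick string (invisibly when `path` is given)
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  bad <- grepl("[][():;,]", labs)
  if (any(bad)) {
    stop("leaf labels contain Newick syntax characters: ",
         paste(labs[bad], collapse = ", "))
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file, or a Newick string via `text`
#' @param text Newick string (alternative to `path`)
#' @return a `phylo` object
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  tr
}
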