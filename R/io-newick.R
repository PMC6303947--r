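#' Read and write Newick trees with branch supports
#'
#' `read_newick()` parses a Newick file via [ape::read.tree()] and normalises
#' the result: missing branch lengths become 0, and numeric internal node
#' labels are interpreted as branch supports on \[0, 1\] (values in (1, 100]
#' are treated as bootstrap percentages and divided by 100). Non-numeric
#' internal labels are left untouched as clade names. Files holding several
#' trees return a list of trees.
#'
#' @param path Path to a Newick file.
#' @param simplify If `TRUE` (default) a file with a single tree returns the
#'   `phylo` object itself rather than a length-one list.
#' @return A `phylo` tree (or list of them), with supports normalised in
#'   `node.label`.
#' @export
read_newick <- function(path, simplify = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_balanced_parens(txt)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) abort(sprintf("Newick parse error in '%s': %s",
                                                      path, conditionMessage(e))))
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, normalize_tree)
  if (simplify && length(trees) == 1) trees[[1]] else trees
}

check_balanced_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    abort(sprintf("unbalanced parentheses: unexpected ')' at character %d",
                  which(depth < 0)[1]))
  }
  ends <- which(chars == ";")
  segs <- if (length(ends)) ends else length(chars)
  if (depth[length(depth)] != 0 || any(depth[segs] != 0)) {
    abort(sprintf("unbalanced parentheses: %d '(' left open at character %d",
                  depth[length(depth)], length(chars)))
  }
  invisible(TRUE)
}

normalize_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate leaf labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    pct <- !is.na(sup) & sup > 1 & sup <= 100
    sup[pct] <- sup[pct] / 100
    if (any(!is.na(sup) & (sup < 0 | sup > 1))) {
      abort("internal node support outside [0, 100]")
    }
    tree$node.label <- ifelse(is.na(sup), tree$node.label,
                              format_support(sup))
  }
  tree
}

format_support <- function(x) {
  ifelse(is.na(x), "", sub("\\.$", "", sub("0+$", "", sprintf("%.6f", x))))
}

#' Numeric branch supports of a tree
#'
#' Extracts per-internal-node supports from `node.label`, returning `NA`
#' where the label is absent or non-numeric (a clade name).
#'
#' @param tree A `phylo` object.
#' @return A numeric vector of length `tree$Nnode`.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup) & sup > 1 & sup <= 100] <- sup[!is.na(sup) & sup > 1 & sup <= 100] / 100
  sup
}

#' @rdname read_newick
#' @param tree A `phylo` object (supports, if any, in `node.label`).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
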