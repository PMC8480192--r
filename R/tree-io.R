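#' Read a phylogenetic tree from Newick
#'
#' Parses a rooted Newick tree and validates it for downstream use: exactly
#' one root, unique tip labels, non-negative branch lengths. Internal nodes
#' without labels are auto-named `N<k>` in preorder (root first), so that
#' ancestral nodes can be reported deterministically. For trees whose branch
#' lengths are in time units (`lengths_unit = "My"`) node ages are derived
#' when the tree is ultrametric.
#'
#' @param path_or_text Path to a Newick file, or a Newick string
#'   (recognised by a terminal `;`).
#' @param lengths_unit Unit of the branch lengths: `"My"` for a
#'   time-calibrated tree (millions of years) or `"subs"` for expected
#'   substitutions per site.
#' @return An [ape::phylo] object with unique, non-empty `node.label`s and
#'   attribute `lengths_unit`.
#' @examples
#' tr <- read_timetree("((A:1,B:1):1,C:2):0;")
#' node_ages(tr)
#' @seealso [node_ages()], [write_newick()]
#' @export
read_timetree <- function(path_or_text, lengths_unit = c("My", "subs")) {
  lengths_unit <- match.arg(lengths_unit)
  txt <- grepl(";", path_or_text, fixed = TRUE)
  tree <- if (txt) ape::read.tree(text = path_or_text) else ape::read.tree(path_or_text)
  if (is.null(tree)) stop("malformed Newick input")
  if (is.null(tree$edge.length)) stop("Newick input lacks branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree <- name_internal_nodes(tree)
  attr(tree, "lengths_unit") <- lengths_unit
  tree
}

#' @rdname read_timetree
#' @export
read_substtree <- function(path_or_text) {
  read_timetree(path_or_text, lengths_unit = "subs")
}

#' Name unlabelled internal nodes in preorder
#'
#' Existing internal-node labels are preserved; empty ones are replaced by
#' `N<k>` where `k` counts nodes in preorder starting at the root.
#'
#' @param tree A `phylo` object.
#' @return The tree with a complete `node.label` vector.
#' @export
name_internal_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  lab <- if (is.null(tree$node.label)) rep("", n_int) else tree$node.label
  lab[is.na(lab)] <- ""
  ord <- preorder_nodes(tree)
  ord_int <- ord[ord > n_tip] - n_tip
  k <- 0L
  for (i in ord_int) {
    k <- k + 1L
    if (!nzchar(lab[i])) lab[i] <- paste0("N", k)
  }
  tree$node.label <- lab
  if (anyDuplicated(tree$node.label)) stop("duplicate internal node labels")
  tree
}

# Node indices (ape numbering) in preorder, root first.
preorder_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, v)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  out
}

# Edge indices ordered so every parent precedes its children (preorder)
# or the reverse (postorder over edges).
postorder_edges <- function(tree) {
  ord <- preorder_nodes(tree)
  pos <- match(tree$edge[, 2], ord)
  rev(order(pos))
}

#' Node labels for every node of a tree
#'
#' Returns one label per node in ape numbering: tips first (their tip
#' labels), then internal nodes (their `node.label`s).
#'
#' @param tree A `phylo` with complete labels (see [read_timetree()]).
#' @return Character vector of length `Ntip + Nnode`.
#' @export
node_ids <- function(tree) c(tree$tip.label, tree$node.label)

#' Node ages of a time tree
#'
#' Ages in the unit of the branch lengths, measured back from the most
#' recent tip (age 0). The tree must be ultrametric within `tol` (relative
#' to the tree height) for ages to be meaningful; non-ultrametric input is
#' an error.
#'
#' @param tree A `phylo` object.
#' @param tol Relative ultrametricity tolerance.
#' @return Named numeric vector over all nodes (tips and internal).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  depth <- node_depths(tree)
  h <- max(depth[seq_along(tree$tip.label)])
  if (any(abs(depth[seq_along(tree$tip.label)] - h) > tol * max(h, 1)))
    stop("tree is not ultrametric; node ages are undefined")
  ages <- h - depth
  names(ages) <- node_ids(tree)
  ages
}

# Root-to-node path lengths for all nodes.
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- numeric(n_tip + tree$Nnode)
  ord <- preorder_nodes(tree)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(n_tip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  for (v in ord[-1L]) depth[v] <- depth[parent[v]] + elen[v]
  depth
}

#' Write a tree to Newick
#'
#' Byte-deterministic Newick writer (via ape) keeping internal node labels.
#'
#' @param tree A `phylo` object.
#' @param path Output file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
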