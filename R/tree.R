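#' Construct a tree node
#'
#' A node of a rooted phylogeny.  Leaves have a non-empty `label` and no
#' children; internal nodes may carry an (often empty) label.  The
#' `annotations` slot is an open named list used for display metadata such
#' as `!color`, `mutations` and `time`; it is empty after parsing plain
#' Newick text.
#'
#' @param label Taxon name (may be `""` for internal nodes).
#' @param branch_length Non-negative length of the branch above this node,
#'   in the tree's time units, or `NULL` when the input carried none.
#'   Zero-length and absent branch lengths are distinct states.
#' @param children List of child nodes, in input order.  Empty for leaves.
#' @param annotations Named list of annotation key/value pairs.
#' @return A list of class `tree_node`.
#' @export
tree_node <- function(label = "", branch_length = NULL, children = list(),
                      annotations = list()) {
  if (!is.null(branch_length)) {
    if (!is.numeric(branch_length) || length(branch_length) != 1L || is.na(branch_length))
      stop("branch_length must be a single number or NULL")
    if (branch_length < 0) stop("branch_length must be non-negative")
    branch_length <- as.numeric(branch_length)
  }
  if (length(children) == 0L && !nzchar(label))
    stop("a leaf must have a non-empty label")
  structure(list(label = as.character(label), branch_length = branch_length,
                 children = children, annotations = annotations),
            class = "tree_node")
}

is_leaf <- function(node) length(node$children) == 0L

#' Construct a rooted tree
#'
#' Wraps a root [tree_node()] and validates the whole-tree invariants:
#' leaf labels are unique and the leaf set is non-empty.  Trees written
#' with a basal multifurcation are accepted and treated as rooted at the
#' written root; `rooted` records whether the root is at most binary.
#'
#' @param root A [tree_node()].
#' @param rooted Logical; whether the root is a genuine (<= 2 children) root.
#' @return A list of class `mta_tree` with elements `root` and `rooted`.
#' @export
mta_tree <- function(root, rooted = length(root$children) <= 2L) {
  leaves <- leaf_set(root)
  if (length(leaves) == 0L) stop("tree has no leaves")
  dup <- leaves[duplicated(leaves)]
  if (length(dup) > 0L)
    parse_error(sprintf("duplicate leaf label '%s'", dup[[1L]]))
  structure(list(root = root, rooted = isTRUE(rooted)), class = "mta_tree")
}

#' Leaf labels descending from a node
#'
#' @param node A [tree_node()] or an [mta_tree()] (its root is used).
#' @return Character vector of leaf labels in tree traversal order; the
#'   node's own label if it is a leaf.
#' @export
leaf_set <- function(node) {
  if (inherits(node, "mta_tree")) node <- node$root
  if (is_leaf(node)) return(node$label)
  unlist(lapply(node$children, leaf_set), use.names = FALSE)
}

#' Canonical clade identifier
#'
#' Order-independent key for a set of taxon names, used to match clades
#' between trees, event logs and ground-truth tables.
#'
#' @param taxa Character vector of taxon names.
#' @return A single string; equal for equal sets.
#' @export
clade_key <- function(taxa) paste(sort(taxa), collapse = "\x1f")

clade_members <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1L]]

# Apply f to every node (preorder); returns list of results.
walk_nodes <- function(node, f) {
  c(list(f(node)), unlist(lapply(node$children, walk_nodes, f), recursive = FALSE))
}

#' Structural tree equality
#'
#' Compares topology, labels and branch lengths.  Branch lengths are
#' compared with relative tolerance `tol`; `NULL` (absent) only equals
#' `NULL`.  With `tolerant = TRUE` children are matched by leaf set
#' instead of position, so trees differing only in child order compare
#' equal.  Annotations are not compared.
#'
#' @param a,b Trees ([mta_tree()]) or nodes.
#' @param tolerant Ignore child order?
#' @param tol Relative tolerance for branch lengths.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equals <- function(a, b, tolerant = FALSE, tol = 1e-9) {
  if (inherits(a, "mta_tree")) a <- a$root
  if (inherits(b, "mta_tree")) b <- b$root
  node_equals(a, b, tolerant, tol)
}

node_equals <- function(a, b, tolerant, tol) {
  if (!identical(a$label, b$label)) return(FALSE)
  if (is.null(a$branch_length) != is.null(b$branch_length)) return(FALSE)
  if (!is.null(a$branch_length)) {
    if (abs(a$branch_length - b$branch_length) >
        tol * max(1, abs(a$branch_length), abs(b$branch_length))) return(FALSE)
  }
  if (length(a$children) != length(b$children)) return(FALSE)
  if (length(a$children) == 0L) return(TRUE)
  kids_b <- b$children
  if (tolerant) {
    sig <- function(n) clade_key(leaf_set(n))
    kids_b <- kids_b[order(vapply(kids_b, sig, ""))]
    kids_a <- a$children[order(vapply(a$children, sig, ""))]
  } else kids_a <- a$children
  all(mapply(node_equals, kids_a, kids_b,
             MoreArgs = list(tolerant = tolerant, tol = tol)))
}

#' @export
print.mta_tree <- function(x, ...) {
  leaves <- leaf_set(x$root)
  n_nodes <- length(walk_nodes(x$root, function(n) TRUE))
  cat(sprintf("Rooted phylogeny: %d leaves, %d internal nodes%s\n",
              length(leaves), n_nodes - length(leaves),
              if (x$rooted) "" else " (basal multifurcation)"))
  cat("Leaves:", paste(utils::head(leaves, 8L), collapse = ", "),
      if (length(leaves) > 8L) "..." else "", "\n")
  invisible(x)
}
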