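# Recursive-descent Newick parser and serializer.
#
# Dialect (Felsenstein-style): parenthesized topology, ':' branch lengths,
# ';' terminator, single-quoted labels with '' escaping.  Underscores in
# unquoted labels are kept as-is (not converted to spaces).  Bracketed
# comments are stripped with a warning, except that in the internal
# keep_annotations mode (used by read_nexus) comments of the form [&...]
# attached after a node's label/subtree are parsed into its annotation map.

#' Parse a Newick string into a tree
#'
#' @param text A single string holding one Newick tree terminated by `;`.
#'   If the text continues with further trees after the first `;`, only
#'   the first is read and a warning is issued; any other trailing text
#'   is a parse error.
#' @return An [mta_tree()].  Annotations of every node are empty;
#'   bracketed comments in the input are discarded with a warning.
#' @export
#' @examples
#' tr <- parse_newick("((Eu_Am6:0.0,Eu_Am22:0.0):2.0099,Eu_Am5:2.0099);")
#' leaf_set(tr)
parse_newick <- function(text) {
  parse_newick_impl(text, keep_annotations = FALSE)
}

#' Read a Newick tree from a file
#'
#' @param path Path to a Newick file.
#' @return An [mta_tree()].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  parse_newick(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

parse_newick_impl <- function(text, keep_annotations = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    parse_error("input must be a single character string")
  st <- new.env(parent = emptyenv())
  st$ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  st$n <- length(st$ch)
  st$i <- 1L
  st$stripped <- 0L
  st$leaves <- list()  # list of c(label, offset)
  st$keep <- keep_annotations

  nw_skip(st)
  if (st$i > st$n) parse_error("empty input")
  root <- nw_subtree(st)
  nw_skip(st)
  if (st$i > st$n || st$ch[st$i] != ";")
    parse_error("expected ';' terminating the tree", st$i)
  st$i <- st$i + 1L
  nw_skip(st)
  if (st$i <= st$n) {
    rest <- paste(st$ch[st$i:st$n], collapse = "")
    if (grepl(";", rest, fixed = TRUE)) {
      warning("input contains more than one tree; only the first was read")
    } else {
      parse_error("trailing garbage after ';'", st$i)
    }
  }
  if (st$stripped > 0L)
    warning(sprintf("discarded %d bracketed comment(s) from Newick input", st$stripped))
  labs <- vapply(st$leaves, `[[`, "", 1L)
  d <- which(duplicated(labs))
  if (length(d) > 0L)
    parse_error(sprintf("duplicate leaf label '%s'", labs[d[1L]]),
                as.integer(st$leaves[[d[1L]]][[2L]]))
  mta_tree(root)
}

nw_peek <- function(st) if (st$i <= st$n) st$ch[st$i] else ""

# Skip whitespace and non-annotation comments; count what was stripped.
nw_skip <- function(st) {
  repeat {
    while (st$i <= st$n && st$ch[st$i] %in% c(" ", "\t", "\n", "\r")) st$i <- st$i + 1L
    if (st$i <= st$n && st$ch[st$i] == "[" &&
        !(st$keep && st$i < st$n && st$ch[st$i + 1L] == "&")) {
      j <- st$i
      while (j <= st$n && st$ch[j] != "]") j <- j + 1L
      if (j > st$n) parse_error("unterminated '[' comment", st$i)
      st$i <- j + 1L
      st$stripped <- st$stripped + 1L
    } else break
  }
}

nw_subtree <- function(st) {
  nw_skip(st)
  start <- st$i
  if (nw_peek(st) == "(") {
    st$i <- st$i + 1L
    children <- list(nw_subtree(st))
    repeat {
      nw_skip(st)
      tok <- nw_peek(st)
      if (tok == ",") {
        st$i <- st$i + 1L
        children[[length(children) + 1L]] <- nw_subtree(st)
      } else if (tok == ")") {
        st$i <- st$i + 1L
        break
      } else {
        parse_error("expected ',' or ')' (unbalanced parentheses?)", st$i)
      }
    }
    label <- nw_label(st)
    node <- list(label = label, branch_length = NULL, children = children,
                 annotations = list())
  } else {
    label <- nw_label(st)
    if (!nzchar(label))
      parse_error("expected a taxon label or '('", st$i)
    st$leaves[[length(st$leaves) + 1L]] <- list(label, start)
    node <- list(label = label, branch_length = NULL, children = list(),
                 annotations = list())
  }
  ann <- nw_annotation(st)
  if (length(ann) > 0L) node$annotations <- ann
  nw_skip(st)
  if (nw_peek(st) == ":") {
    st$i <- st$i + 1L
    node$branch_length <- nw_number(st)
  }
  class(node) <- "tree_node"
  node
}

nw_label <- function(st) {
  nw_skip(st)
  if (nw_peek(st) == "'") {
    start <- st$i
    st$i <- st$i + 1L
    out <- character()
    repeat {
      if (st$i > st$n) parse_error("unterminated quoted label", start)
      c0 <- st$ch[st$i]
      if (c0 == "'") {
        if (st$i < st$n && st$ch[st$i + 1L] == "'") {
          out <- c(out, "'"); st$i <- st$i + 2L
        } else { st$i <- st$i + 1L; break }
      } else { out <- c(out, c0); st$i <- st$i + 1L }
    }
    return(paste(out, collapse = ""))
  }
  out <- character()
  stop_chars <- c("(", ")", "[", "]", "{", "}", ",", ":", ";", "'",
                  " ", "\t", "\n", "\r")
  while (st$i <= st$n && !(st$ch[st$i] %in% stop_chars)) {
    out <- c(out, st$ch[st$i]); st$i <- st$i + 1L
  }
  paste(out, collapse = "")
}

nw_number <- function(st) {
  nw_skip(st)
  start <- st$i
  num_chars <- c(0:9, "+", "-", ".", "e", "E")
  out <- character()
  while (st$i <= st$n && st$ch[st$i] %in% num_chars) {
    out <- c(out, st$ch[st$i]); st$i <- st$i + 1L
  }
  if (length(out) == 0L) parse_error("expected a branch length after ':'", start)
  x <- suppressWarnings(as.numeric(paste(out, collapse = "")))
  if (is.na(x)) parse_error("invalid branch length", start)
  if (x < 0) parse_error("negative branch length", start)
  x
}

# FigTree-style [&key=value,...] annotation after a label/subtree.
nw_annotation <- function(st) {
  if (!st$keep) return(list())
  # skip only whitespace here: a comment must directly follow the node
  while (st$i <= st$n && st$ch[st$i] %in% c(" ", "\t", "\n", "\r")) st$i <- st$i + 1L
  if (!(nw_peek(st) == "[" && st$i < st$n && st$ch[st$i + 1L] == "&")) return(list())
  start <- st$i
  j <- st$i
  while (j <= st$n && st$ch[j] != "]") j <- j + 1L
  if (j > st$n) parse_error("unterminated annotation comment", start)
  body <- paste(st$ch[(st$i + 2L):(j - 1L)], collapse = "")
  st$i <- j + 1L
  parse_annotation_body(body)
}

#' Serialize a tree to Newick text
#'
#' The output re-parses to an identical tree: branch lengths are written
#' with the shortest decimal representation that round-trips through
#' `as.numeric`, and labels containing Newick metacharacters are
#' single-quoted with `''` escaping.  Node annotations are not written
#' (plain Newick); see [write_nexus()] for annotated output.
#'
#' @param tree An [mta_tree()].
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "mta_tree"))
  paste0(write_node(tree$root, with_annotations = FALSE), ";")
}

write_node <- function(node, with_annotations) {
  core <- if (is_leaf(node)) {
    quote_label(node$label)
  } else {
    paste0("(", paste(vapply(node$children, write_node, "",
                             with_annotations = with_annotations),
                      collapse = ","),
           ")", quote_label(node$label))
  }
  if (with_annotations && length(node$annotations) > 0L)
    core <- paste0(core, format_annotation_comment(node$annotations))
  if (!is.null(node$branch_length))
    core <- paste0(core, ":", fmt_num(node$branch_length))
  core
}

quote_label <- function(label) {
  if (!nzchar(label)) return("")
  if (grepl("[][(){},:; \t\n\r']", label))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

# Shortest decimal representation that survives as.numeric round-trip.
fmt_num <- function(x) {
  if (x == floor(x) && abs(x) < 1e15) return(format(x, scientific = FALSE))
  for (d in 1:17) {
    s <- format(x, digits = d, scientific = FALSE)
    if (as.numeric(s) == x) return(s)
  }
  format(x, digits = 17)
}
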