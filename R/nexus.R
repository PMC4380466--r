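# FigTree-dialect Nexus serialization.
#
# Output layout is fixed for bit-exact reproducibility: LF newlines,
# lowercase keywords, single-tab indentation, one taxlabel per line,
# exactly one tree statement.  Display metadata travels in FigTree
# bracketed comments: [&!color=#rrggbb] on taxa and nodes,
# [&key=value,...] on nodes, with multi-valued keys (mutation label
# lists) as a braced, quoted, comma-separated set.

#' Assemble a Nexus document from an annotated tree
#'
#' @param tree An [mta_tree()], typically colored and/or annotated.
#' @param tree_name Name used in the tree statement.
#' @param rooted Rooted flag written as `[&R]` / `[&U]`.
#' @return A list of class `nexus_document` with fields `taxa` (leaf
#'   names in tree traversal order), `taxa_colors` (per-taxon hex color
#'   or `NA`, taken from leaf `!color` annotations), `tree_name`, `tree`
#'   and `rooted`.
#' @export
nexus_document <- function(tree, tree_name = "tree1", rooted = tree$rooted) {
  stopifnot(inherits(tree, "mta_tree"))
  attr(tree, "summary") <- NULL  # transport metadata, not document content
  tree$root <- canonicalize_annotations(tree$root)
  leaves <- list()
  collect <- function(node) {
    if (is_leaf(node)) leaves[[length(leaves) + 1L]] <<- node
    for (ch in node$children) collect(ch)
  }
  collect(tree$root)
  taxa <- vapply(leaves, `[[`, "", "label")
  colors <- vapply(leaves, function(n)
    n$annotations[["!color"]] %||% NA_character_, "")
  structure(list(taxa = taxa, taxa_colors = stats::setNames(colors, taxa),
                 tree_name = tree_name, tree = tree, rooted = isTRUE(rooted)),
            class = "nexus_document")
}

#' @export
print.nexus_document <- function(x, ...) {
  cat(sprintf("Nexus document '%s': %d taxa, %s\n", x$tree_name,
              length(x$taxa), if (x$rooted) "rooted" else "unrooted"))
  invisible(x)
}

# Fixed key order for node comments; other keys follow in insertion order.
ANN_KEY_ORDER <- c("!color", "mutations", "time")

# Reorder every node's annotation keys into serialization order, so a
# document compares equal to its own write/read round trip no matter in
# which order the pipeline installed the annotations.
canonicalize_annotations <- function(node) {
  if (length(node$annotations) > 0L) {
    keys <- c(intersect(ANN_KEY_ORDER, names(node$annotations)),
              setdiff(names(node$annotations), ANN_KEY_ORDER))
    node$annotations <- node$annotations[keys]
  }
  node$children <- lapply(node$children, canonicalize_annotations)
  node
}

format_annotation_comment <- function(ann) {
  keys <- c(intersect(ANN_KEY_ORDER, names(ann)),
            setdiff(names(ann), ANN_KEY_ORDER))
  items <- vapply(keys, function(k) {
    v <- ann[[k]]
    txt <- if (k == "mutations" || (is.character(v) && length(v) > 1L)) {
      paste0("{", paste(sprintf('"%s"', v), collapse = ","), "}")
    } else if (is.numeric(v)) {
      fmt_num(v)
    } else {
      as.character(v)
    }
    paste0(k, "=", txt)
  }, "")
  paste0("[&", paste(items, collapse = ","), "]")
}

# Parse the body of an [&...] comment (without the brackets and '&').
parse_annotation_body <- function(body) {
  items <- split_top_level(body)
  ann <- list()
  for (item in items) {
    eq <- regexpr("=", item, fixed = TRUE)
    if (eq < 0L) parse_error(sprintf("malformed annotation item '%s'", item))
    k <- trimws(substr(item, 1L, eq - 1L))
    v <- trimws(substr(item, eq + 1L, nchar(item)))
    ann[[k]] <- parse_annotation_value(v)
  }
  ann
}

split_top_level <- function(body) {
  ch <- strsplit(body, "", fixed = TRUE)[[1L]]
  depth <- 0L; in_q <- FALSE
  out <- character(); cur <- character()
  for (c0 in ch) {
    if (c0 == '"') in_q <- !in_q
    if (!in_q) {
      if (c0 == "{") depth <- depth + 1L
      if (c0 == "}") depth <- depth - 1L
      if (c0 == "," && depth == 0L) {
        out <- c(out, paste(cur, collapse = "")); cur <- character(); next
      }
    }
    cur <- c(cur, c0)
  }
  c(out, paste(cur, collapse = ""))
}

parse_annotation_value <- function(v) {
  if (startsWith(v, "{")) {
    inner <- sub("^\\{", "", sub("\\}$", "", v))
    if (!nzchar(inner)) return(character())
    parts <- split_top_level(inner)
    return(vapply(parts, function(p) gsub('^"|"$', "", trimws(p)), "",
                  USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', v)) return(substr(v, 2L, nchar(v) - 1L))
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v))
    return(as.numeric(v))
  v
}

#' Write a FigTree-dialect Nexus file
#'
#' Emits a `#NEXUS` header, a taxa block (`dimensions ntax=N;` plus one
#' taxlabel per line, each optionally suffixed `[&!color=#rrggbb]`) and a
#' trees block with exactly one statement
#' `tree <name> = [&R] <annotated newick>;`, where each annotated node
#' carries its `[&...]` comment between label/subtree and `:length`.
#' The file is written atomically (temp file + rename) with LF newlines.
#'
#' @param doc A [nexus_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(doc, path) {
  stopifnot(inherits(doc, "nexus_document"))
  tree_leaves <- leaf_set(doc$tree$root)
  if (!identical(unname(doc$taxa), unname(tree_leaves)))
    mta_abort("taxa list does not match the tree's leaves", "mta_format_error")
  taxlines <- vapply(doc$taxa, function(tx) {
    col <- doc$taxa_colors[[tx]]
    paste0("\t", quote_label(tx),
           if (!is.na(col)) paste0("[&!color=", col, "]") else "")
  }, "", USE.NAMES = FALSE)
  lines <- c(
    "#NEXUS",
    "begin taxa;",
    sprintf("\tdimensions ntax=%d;", length(doc$taxa)),
    "\ttaxlabels",
    taxlines,
    "\t;",
    "end;",
    "begin trees;",
    sprintf("\ttree %s = [&%s] %s;", doc$tree_name,
            if (doc$rooted) "R" else "U",
            write_node(doc$tree$root, with_annotations = TRUE)),
    "end;")
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a FigTree-dialect Nexus file
#'
#' Inverse of [write_nexus()] on its own output; tolerant of whitespace
#' and keyword case.  A taxa block is optional: without one, taxa are
#' inferred from the tree.  With one, `ntax` must match the number of
#' taxlabels and the tree's leaf count.
#'
#' @param path Path to the Nexus file.
#' @return A [nexus_document()].
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*#nexus", txt, ignore.case = TRUE))
    format_error("not a Nexus file (missing #NEXUS header)")

  trees_block <- block_body(txt, "trees")
  if (is.null(trees_block)) format_error("missing trees block")
  tree_re <- "(?is)\\btree\\s+(\\S+)\\s*=\\s*(\\[&([RU])\\]\\s*)?([^;]+;)"
  hits <- gregexpr(tree_re, trees_block, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) format_error("trees block holds no tree statement")
  if (length(hits) > 1L) format_error("trees block holds more than one tree statement")
  m <- regmatches(trees_block, regexec(tree_re, trees_block, perl = TRUE))[[1L]]
  tree_name <- m[2L]
  rooted_flag <- m[4L]
  tree <- parse_newick_impl(m[5L], keep_annotations = TRUE)
  rooted <- if (nzchar(rooted_flag)) toupper(rooted_flag) == "R" else tree$rooted

  taxa_block <- block_body(txt, "taxa")
  doc <- nexus_document(tree, tree_name = tree_name, rooted = rooted)
  if (!is.null(taxa_block)) {
    ntax_m <- regmatches(taxa_block,
                         regexec("(?i)dimensions\\s+ntax\\s*=\\s*([0-9]+)\\s*;",
                                 taxa_block, perl = TRUE))[[1L]]
    lbl_m <- regmatches(taxa_block,
                        regexec("(?is)taxlabels(.*?);", taxa_block, perl = TRUE))[[1L]]
    if (length(lbl_m) == 0L) format_error("taxa block has no taxlabels")
    entries <- parse_taxlabels(lbl_m[2L])
    if (length(ntax_m) > 0L && as.integer(ntax_m[2L]) != length(entries$taxa))
      format_error(sprintf("ntax=%s but %d taxlabels found",
                           ntax_m[2L], length(entries$taxa)))
    if (!setequal(entries$taxa, doc$taxa))
      format_error("taxlabels do not match the tree's leaf set")
    doc$taxa <- entries$taxa
    doc$taxa_colors <- stats::setNames(entries$colors, entries$taxa)
  }
  doc
}

block_body <- function(txt, name) {
  re <- sprintf("(?is)\\bbegin\\s+%s\\s*;(.*?)\\bend\\s*;", name)
  m <- regmatches(txt, regexec(re, txt, perl = TRUE))[[1L]]
  if (length(m) == 0L) NULL else m[2L]
}

parse_taxlabels <- function(body) {
  taxa <- character(); colors <- character()
  ch <- strsplit(body, "", fixed = TRUE)[[1L]]
  i <- 1L; n <- length(ch)
  while (i <= n) {
    while (i <= n && ch[i] %in% c(" ", "\t", "\n", "\r")) i <- i + 1L
    if (i > n) break
    if (ch[i] == "'") {
      i <- i + 1L; lab <- character()
      while (i <= n) {
        if (ch[i] == "'") {
          if (i < n && ch[i + 1L] == "'") { lab <- c(lab, "'"); i <- i + 2L }
          else { i <- i + 1L; break }
        } else { lab <- c(lab, ch[i]); i <- i + 1L }
      }
      label <- paste(lab, collapse = "")
    } else {
      lab <- character()
      while (i <= n && !(ch[i] %in% c(" ", "\t", "\n", "\r", "["))) {
        lab <- c(lab, ch[i]); i <- i + 1L
      }
      label <- paste(lab, collapse = "")
    }
    col <- NA_character_
    if (i <= n && ch[i] == "[") {
      j <- i
      while (j <= n && ch[j] != "]") j <- j + 1L
      if (j > n) format_error("unterminated comment in taxlabels")
      comment <- paste(ch[i:j], collapse = "")
      cm <- regmatches(comment, regexec("!color=(#[0-9a-fA-F]{6})", comment))[[1L]]
      if (length(cm) > 0L) col <- tolower(cm[2L])
      i <- j + 1L
    }
    if (nzchar(label)) { taxa <- c(taxa, label); colors <- c(colors, col) }
  }
  list(taxa = taxa, colors = colors)
}
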