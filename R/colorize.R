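# Taxon-group colorization.
#
# Groups come from an explicit group file when given; any leaf not
# covered falls back to name-prefix inference (strip the trailing run of
# digits, so Eu_Am5 / Eu_Am22 -> Eu_Am).  Colors come from user overrides
# plus a fixed 12-color palette assigned in sorted-group-name order, so
# identical inputs always produce identical colors.

#' Default group color palette
#'
#' Twelve visually distinct hex colors.  Groups without an explicit
#' override take palette colors in sorted group-name order, cycling if
#' there are more than twelve groups.
#'
#' @return Character vector of 12 `#rrggbb` strings.
#' @export
default_palette <- function() {
  c("#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231", "#911eb4",
    "#46f0f0", "#f032e6", "#bcf60c", "#008080", "#9a6324", "#800000")
}

DEFAULT_GROUP <- "_default"
DEFAULT_COLOR <- "#000000"

#' Infer a taxon's group from its name
#'
#' Strips the maximal trailing run of decimal digits: `"Eu_Am5"` and
#' `"Eu_Am22"` both map to `"Eu_Am"`, `"YRI7"` to `"YRI"`.  A name that
#' is all digits, or has no trailing digits, is its own group.
#'
#' @param taxon Non-empty taxon name(s).
#' @return Group name(s), vectorized over `taxon`.
#' @export
infer_group_from_name <- function(taxon) {
  stopifnot(all(nzchar(taxon)))
  stripped <- sub("[0-9]+$", "", taxon)
  ifelse(nzchar(stripped), stripped, taxon)
}

#' Assign every leaf of a tree to a group
#'
#' An explicit group definition wins for its members; all remaining
#' leaves are grouped by [infer_group_from_name()], so the assignment is
#' total.  Group-file taxa absent from the tree draw a warning listing
#' them (not fatal).
#'
#' @param tree An [mta_tree()].
#' @param groups Optional named list (group -> members) as from
#'   [read_group_file()].
#' @return Named character vector: leaf name -> group name, in tree
#'   traversal order.
#' @export
assign_groups <- function(tree, groups = NULL) {
  leaves <- leaf_set(tree$root)
  assignment <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
  if (!is.null(groups)) {
    for (g in names(groups)) {
      members <- groups[[g]]
      missing <- setdiff(members, leaves)
      if (length(missing) > 0L)
        warning(sprintf("group '%s' names taxa absent from the tree: %s",
                        g, paste(missing, collapse = ", ")))
      assignment[intersect(members, leaves)] <- g
    }
  }
  todo <- is.na(assignment)
  assignment[todo] <- infer_group_from_name(leaves[todo])
  assignment
}

valid_hex <- function(x) grepl("^#[0-9a-fA-F]{6}$", x)

#' Build the group-to-color map
#'
#' Overridden groups take their override (normalized to lowercase);
#' remaining groups take [default_palette()] colors in sorted group-name
#' order, cycling if the palette is exhausted.  The reserved group
#' `"_default"` (used for mixed-group internal branches) is always
#' present and always black.
#'
#' @param assignment Named vector from [assign_groups()].
#' @param overrides Optional named character vector, group -> `#rrggbb`.
#' @return Named character vector group -> lowercase hex color, with a
#'   `"_default"` entry.
#' @export
build_color_map <- function(assignment, overrides = NULL) {
  groups <- sort(unique(unname(assignment)))
  cmap <- stats::setNames(rep(NA_character_, length(groups)), groups)
  if (!is.null(overrides) && length(overrides) > 0L) {
    bad <- !valid_hex(overrides)
    if (any(bad))
      usage_error(sprintf("malformed hex color '%s' for group '%s'",
                          overrides[bad][1L], names(overrides)[bad][1L]))
    hit <- intersect(names(overrides), groups)
    cmap[hit] <- tolower(overrides[hit])
  }
  todo <- names(cmap)[is.na(cmap)]
  pal <- default_palette()
  if (length(todo) > 0L)
    cmap[todo] <- pal[((seq_along(todo) - 1L) %% length(pal)) + 1L]
  cmap[[DEFAULT_GROUP]] <- DEFAULT_COLOR
  cmap
}

#' Read a color configuration file
#'
#' Plain-text `group = #rrggbb` lines; `#` at line start comments.
#'
#' @param path Path to the file.
#' @return Named character vector, group -> hex color.
#' @export
read_color_file <- function(path) {
  con <- content_lines(path)
  out <- character()
  for (k in seq_along(con$text)) {
    line <- con$text[k]
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0L) format_error("expected 'group = #rrggbb'", con$lineno[k])
    g <- trimws(substr(line, 1L, eq - 1L))
    v <- trimws(substr(line, eq + 1L, nchar(line)))
    if (!nzchar(g) || !valid_hex(v))
      format_error(sprintf("malformed color assignment '%s'", line), con$lineno[k])
    out[[g]] <- tolower(v)
  }
  out
}

#' Color a tree by group
#'
#' Each leaf's annotations gain the FigTree key `"!color"` with its
#' group's color.  An internal node is colored with a group's color iff
#' every descendant leaf belongs to that single group (monophyletic
#' propagation); mixed-group internal nodes get the `"_default"` black.
#' Topology and branch lengths are unchanged, and the operation is
#' idempotent.
#'
#' @param tree An [mta_tree()].
#' @param assignment Named vector from [assign_groups()]; must cover
#'   every leaf.
#' @param color_map Named vector from [build_color_map()].
#' @return The colored [mta_tree()].
#' @export
color_tree <- function(tree, assignment, color_map) {
  leaves <- leaf_set(tree$root)
  if (!all(leaves %in% names(assignment)))
    usage_error("group assignment does not cover every leaf of the tree")
  paint <- function(node) {
    node$children <- lapply(node$children, paint)
    grps <- unique(unname(assignment[leaf_set(node)]))
    node$annotations[["!color"]] <-
      if (length(grps) == 1L) unname(color_map[[grps]])
      else unname(color_map[[DEFAULT_GROUP]])
    node
  }
  mta_tree(paint(tree$root), rooted = tree$rooted)
}
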