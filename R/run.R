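# End-to-end pipeline behind the command-line entry point.

#' Colorize and annotate a Newick tree into a FigTree Nexus file
#'
#' Behavior matrix mirrors the five input-file slots: with only a Newick
#' file the tree is colorized by name-inferred groups; a group file adds
#' explicit group membership; an event log adds mutation/merge-time
#' annotations (annotation is only meaningful for trees accompanied by a
#' MixtureTree-style log).  A sequence file, when given, is parsed and
#' validated (it feeds [reconstruct_ancestral_sequence()]); it does not
#' change the Nexus output.  The output file is written atomically.
#'
#' @param newick Path to the input Newick tree (required).
#' @param output Path for the Nexus output (required).
#' @param sequences,log,groups Optional paths to the sequence, event-log
#'   and group files.
#' @param color Add group colors? Default `TRUE`.
#' @param annotate Add event annotations? Default: `TRUE` iff `log` is
#'   given.  Requesting annotation without a log is a usage error,
#'   raised before any file is read.
#' @param color_overrides Named character vector, group -> `#rrggbb`.
#' @param tree_name Tree name in the Nexus trees block.
#' @param verbose Print the summary to standard error?
#' @return Invisibly, a list of class `mta_run_summary`: `n_leaves`,
#'   `n_groups`, `events_attached`, `events_unmatched`, `output`.
#' @export
run_annotation <- function(newick, output, sequences = NULL, log = NULL,
                           groups = NULL, color = TRUE, annotate = NULL,
                           color_overrides = NULL, tree_name = "tree1",
                           verbose = FALSE) {
  if (is.null(annotate)) annotate <- !is.null(log)
  if (annotate && is.null(log))
    usage_error("annotation requires an event-log file (--log)")
  if (!color && !annotate)
    usage_error("nothing to do: at least one of color/annotate must be enabled")
  if (missing(newick) || is.null(newick)) usage_error("a Newick input file is required")
  if (missing(output) || is.null(output)) usage_error("an output path is required")

  tree <- read_newick(newick)
  group_defs <- if (!is.null(groups)) read_group_file(groups) else NULL
  assignment <- assign_groups(tree, group_defs)

  if (!is.null(sequences)) {
    seq_recs <- read_sequence_file(sequences)
    absent <- setdiff(leaf_set(tree$root), seq_recs$name)
    if (length(absent) > 0L)
      warning(sprintf("%d tree leaves have no sequence record (e.g. %s)",
                      length(absent), absent[1L]))
  }

  if (color) {
    cmap <- build_color_map(assignment, color_overrides)
    tree <- color_tree(tree, assignment, cmap)
  }

  attached <- 0L; unmatched <- 0L
  if (annotate) {
    evlog <- read_log_file(log)
    tree <- annotate_tree(tree, evlog)
    s <- attr(tree, "summary")
    attached <- s$attached; unmatched <- s$unmatched
  }

  doc <- nexus_document(tree, tree_name = tree_name)
  write_nexus(doc, output)

  out <- structure(list(
    n_leaves = length(leaf_set(tree$root)),
    n_groups = length(unique(unname(assignment))),
    events_attached = attached,
    events_unmatched = unmatched,
    output = output), class = "mta_run_summary")
  if (verbose) {
    msg <- utils::capture.output(print(out))
    writeLines(msg, con = stderr())
  }
  invisible(out)
}

#' @export
print.mta_run_summary <- function(x, ...) {
  cat(sprintf("Wrote %s: %d leaves in %d group(s); events attached: %d, unmatched: %d\n",
              x$output, x$n_leaves, x$n_groups, x$events_attached, x$events_unmatched))
  invisible(x)
}
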