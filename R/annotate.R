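# Placing merge times and mutation events onto tree branches.
#
# Time model: reverse time, observed sequences at t = 0, ancestors at
# larger t; the root (MRCA) is the oldest node.  Events are matched to
# branches by exact leaf-set equality; exact matching fails loudly
# rather than guessing a nearby clade, because silent mis-annotation is
# worse than an error.

#' Render a mutation event as an xy### label
#'
#' `x` is the ancestral nucleotide (state at time t+eps), `y` the derived
#' nucleotide (state at time t), `###` the 1-based site, concatenated
#' without padding: A->T at site 1 renders as `"AT1"`.
#'
#' @param event A [mutation_event()].
#' @return A single string matching `[ACGT][ACGT][1-9][0-9]*`.
#' @export
render_mutation_label <- function(event) {
  stopifnot(inherits(event, "mutation_event"))
  paste0(event$from, event$to, event$site)
}

#' Infer mutation events by comparing two sequences
#'
#' Compares the state of a lineage at time t+eps (`older`) with its state
#' at time t (`newer`), site by site, and returns one [mutation_event()]
#' per differing site, sites ascending.  The event count equals the
#' Hamming distance between the sequences.  Events carry no time
#' (`time = NA`): the comparison alone cannot date them.
#'
#' @param older Sequence at time t+eps (ancestral), ACGT string.
#' @param newer Sequence at time t (derived), same length.
#' @param clade Taxon names to record on the events (default a
#'   placeholder, since the comparison is lineage-agnostic).
#' @return List of [mutation_event()]s.
#' @export
#' @examples
#' ev <- infer_mutations("ACTG", "TCTG")
#' render_mutation_label(ev[[1]])  # "AT1"
infer_mutations <- function(older, newer, clade = "lineage") {
  if (nchar(older) != nchar(newer))
    mta_abort(sprintf("sequence length mismatch: %d vs %d sites",
                      nchar(older), nchar(newer)), "mta_format_error")
  a <- strsplit(older, "", fixed = TRUE)[[1L]]
  b <- strsplit(newer, "", fixed = TRUE)[[1L]]
  if (!all(a %in% NUCLEOTIDES) || !all(b %in% NUCLEOTIDES))
    mta_abort("sequences must be over the ACGT alphabet", "mta_format_error")
  diff_sites <- which(a != b)
  lapply(diff_sites, function(s)
    mutation_event(NA, s, a[s], b[s], clade))
}

#' Find the tree node whose leaf set equals a taxon set
#'
#' Exact match only: a node is returned iff its descendant leaf set is
#' exactly `taxa` (a leaf matches its own singleton).  Proper supersets
#' or subsets never match.  Uniqueness follows from leaf-label
#' uniqueness.
#'
#' @param tree An [mta_tree()].
#' @param taxa Non-empty character vector of taxon names.
#' @return The matching [tree_node()], or `NULL` if `taxa` is not a clade
#'   of the tree (including when it names taxa absent from the tree).
#' @export
match_clade <- function(tree, taxa) {
  stopifnot(inherits(tree, "mta_tree"), length(taxa) > 0L)
  want <- clade_key(taxa)
  found <- NULL
  visit <- function(node) {
    if (clade_key(leaf_set(node)) == want) found <<- node
    for (ch in node$children) if (is.null(found)) visit(ch)
  }
  visit(tree$root)
  found
}

# Named numeric vector clade_key -> time for matched internal nodes,
# plus data.frame view; shared by compute_node_times and annotate_tree.
node_time_map <- function(tree, log) {
  keys <- unlist(walk_nodes(tree$root, function(n) clade_key(leaf_set(n))))
  times <- stats::setNames(rep(NA_real_, length(keys)), keys)
  leaf_keys <- vapply(leaf_set(tree$root), clade_key, "")
  times[leaf_keys] <- 0
  for (ev in log$merges) {
    key <- clade_key(c(ev$left, ev$right))
    if (!(key %in% keys))
      annotation_error(sprintf(
        "merge event at t=%s matches no clade of the tree: {%s}",
        fmt_num(ev$time),
        paste(sort(c(ev$left, ev$right)), collapse = ", ")))
    times[key] <- ev$time
  }
  times
}

#' Compute node times from an event log
#'
#' Leaves sit at time 0 (the present); every merge event assigns its time
#' to the internal node whose leaf set equals the union of the event's
#' two clades.  Internal nodes with no merge event keep an absent (`NA`)
#' time, with a warning.  The root-is-oldest invariant (parent time >=
#' child time wherever both are known) is enforced; a violation is an
#' error naming the offending edge.  Where a Newick branch length
#' disagrees with the log-derived time difference by more than 1e-6
#' (relative), a warning is issued; log times win for annotation while
#' branch lengths are left untouched for display.
#'
#' @param tree An [mta_tree()].
#' @param log An [event_log()].
#' @return A data frame with one row per node: `members` (list column of
#'   leaf-name vectors), `clade` (comma-joined display form), `is_leaf`,
#'   and `time` (`NA` where no event matched).
#' @export
compute_node_times <- function(tree, log) {
  times <- node_time_map(tree, log)
  check_time_monotone(tree$root, times)
  n_missing <- 0L
  rows <- walk_nodes(tree$root, function(n) {
    ls <- leaf_set(n)
    list(members = ls, is_leaf = is_leaf(n), time = times[[clade_key(ls)]])
  })
  for (r in rows) if (!r$is_leaf && is.na(r$time)) n_missing <- n_missing + 1L
  if (n_missing > 0L)
    warning(sprintf("%d internal node(s) have no merge event; their time is absent",
                    n_missing))
  data.frame(
    clade = vapply(rows, function(r) paste(r$members, collapse = ","), ""),
    members = I(lapply(rows, `[[`, "members")),
    is_leaf = vapply(rows, `[[`, TRUE, "is_leaf"),
    time = vapply(rows, `[[`, 0, "time"),
    stringsAsFactors = FALSE)
}

check_time_monotone <- function(node, times) {
  pt <- times[[clade_key(leaf_set(node))]]
  for (ch in node$children) {
    ct <- times[[clade_key(leaf_set(ch))]]
    if (!is.na(pt) && !is.na(ct)) {
      if (pt < ct)
        annotation_error(sprintf(
          "time monotonicity violated on the edge above {%s}: child t=%s > parent t=%s",
          paste(leaf_set(ch), collapse = ","), fmt_num(ct), fmt_num(pt)))
      if (!is.null(ch$branch_length)) {
        bl <- ch$branch_length
        if (abs((pt - ct) - bl) > 1e-6 * max(1, abs(bl)))
          warning(sprintf(
            "branch length above {%s} (%s) disagrees with log times (%s); log times used for annotation",
            paste(utils::head(leaf_set(ch), 3L), collapse = ","),
            fmt_num(bl), fmt_num(pt - ct)))
      }
    }
    check_time_monotone(ch, times)
  }
}

#' Annotate a tree with an event log
#'
#' Attaches every mutation event to the branch above the node whose leaf
#' set equals the event's clade, and every merge time to its node.  On a
#' node, mutation labels (see [render_mutation_label()]) are stored under
#' annotation key `"mutations"`, ordered by descending event time then
#' ascending site; matched merge times are stored under key `"time"`.
#' Topology, labels and branch lengths are never altered.
#'
#' Mutation events whose clade matches no node are collected into the
#' attached summary (attribute `"summary"`: counts of attached and
#' unmatched events plus the unmatched events themselves).  If the log
#' holds events but none can be matched, the tree/log pairing is almost
#' certainly wrong and an error is raised.  Unmatched merge events are
#' always an error (see [compute_node_times()]).
#'
#' @param tree An [mta_tree()].
#' @param log An [event_log()].
#' @return The annotated [mta_tree()], with a `"summary"` attribute.
#' @export
annotate_tree <- function(tree, log) {
  stopifnot(inherits(tree, "mta_tree"), inherits(log, "event_log"))
  times <- node_time_map(tree, log)
  check_time_monotone(tree$root, times)
  keys <- names(times)

  mut_map <- list()
  unmatched <- list()
  for (ev in log$mutations) {
    key <- clade_key(ev$clade)
    if (key %in% keys) mut_map[[key]] <- c(mut_map[[key]], list(ev))
    else unmatched[[length(unmatched) + 1L]] <- ev
  }
  n_events <- length(log$mutations) + length(log$merges)
  n_attached <- (length(log$mutations) - length(unmatched)) + length(log$merges)
  if (n_events > 0L && n_attached == 0L)
    annotation_error("no event in the log matches any clade of the tree (wrong tree/log pairing?)")

  n_timeless <- 0L
  install <- function(node) {
    key <- clade_key(leaf_set(node))
    node$children <- lapply(node$children, install)
    evs <- mut_map[[key]]
    if (!is.null(evs)) {
      ord <- order(-vapply(evs, `[[`, 0, "time"), vapply(evs, `[[`, 0L, "site"))
      node$annotations[["mutations"]] <-
        vapply(evs[ord], render_mutation_label, "")
    }
    t0 <- times[[key]]
    if (!is.na(t0) && !is_leaf(node)) node$annotations[["time"]] <- t0
    if (is.na(t0) && !is_leaf(node)) n_timeless <<- n_timeless + 1L
    node
  }
  root <- install(tree$root)
  if (n_timeless > 0L)
    warning(sprintf("%d internal node(s) have no merge event; their time is absent",
                    n_timeless))
  out <- mta_tree(root, rooted = tree$rooted)
  attr(out, "summary") <- list(
    n_mutations = length(log$mutations),
    n_merges = length(log$merges),
    attached = n_attached,
    unmatched = length(unmatched),
    unmatched_events = unmatched)
  out
}

#' Reconstruct a lineage's ancestral sequence
#'
#' Starting from a leaf's observed sequence at t = 0, walks rootward and
#' undoes every mutation event attached to the leaf-to-root path whose
#' time is at most `target_time`: in ascending time order, each event
#' resets its site from the derived to the ancestral nucleotide.  The
#' result is the lineage's state at `target_time`.  Repeat mutations at
#' one site are undone in time order.
#'
#' @param leaf Taxon name present in both the tree and `sequences`.
#' @param target_time Time (>= 0) at which to reconstruct; must not
#'   exceed the root time when the log dates the root.
#' @param tree An [mta_tree()].
#' @param log An [event_log()].
#' @param sequences Data frame as from [read_sequence_file()].
#' @return The reconstructed sequence as a single string.
#' @export
reconstruct_ancestral_sequence <- function(leaf, target_time, tree, log, sequences) {
  stopifnot(inherits(tree, "mta_tree"), inherits(log, "event_log"))
  row <- match(leaf, sequences$name)
  if (is.na(row))
    annotation_error(sprintf("leaf '%s' is missing from the sequence records", leaf))
  if (!(leaf %in% leaf_set(tree$root)))
    annotation_error(sprintf("leaf '%s' is not in the tree", leaf))
  times <- node_time_map(tree, log)
  root_time <- times[[clade_key(leaf_set(tree$root))]]
  if (!is.na(root_time) && target_time > root_time)
    annotation_error(sprintf("target time %s exceeds the root time %s",
                             fmt_num(target_time), fmt_num(root_time)))

  # clade keys on the root -> leaf path (branch above each node, root included)
  path_keys <- character()
  descend <- function(node) {
    path_keys <<- c(path_keys, clade_key(leaf_set(node)))
    if (is_leaf(node)) return(node$label == leaf)
    for (ch in node$children) {
      if (leaf %in% leaf_set(ch)) return(descend(ch))
    }
    FALSE
  }
  descend(tree$root)

  evs <- Filter(function(ev) {
    !is.na(ev$time) && ev$time <= target_time && clade_key(ev$clade) %in% path_keys
  }, log$mutations)
  evs <- evs[order(vapply(evs, `[[`, 0, "time"))]

  s <- strsplit(sequences$sequence[row], "", fixed = TRUE)[[1L]]
  for (ev in evs) {
    if (ev$site > length(s))
      annotation_error(sprintf("mutation site %d exceeds sequence length %d",
                               ev$site, length(s)))
    s[ev$site] <- ev$from
  }
  paste(s, collapse = "")
}
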