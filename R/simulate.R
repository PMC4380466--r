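# Coalescent-style simulator producing internally consistent test
# datasets with recorded ground truth: a random tree built by pairwise
# merges at cumulative-exponential times, mutations dropped on branches
# as a Poisson counting process, sequences propagated root -> leaves,
# and the four input files (tree, sequences, groups, event log) that the
# annotation pipeline consumes.

#' Simulation configuration
#'
#' Defaults emulate the shape of the demonstration dataset the tool was
#' built around: 52 sequences (34 named `Eu_Am1..34`, 18 named
#' `YRI1..18`) of 100 sites.  The mutation rate is in expected mutations
#' per unit (coalescent) time per lineage.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param n_sites Sequence length (>= 1).
#' @param groups Named list, prefix -> leaf count; counts must sum to
#'   `n_leaves`.  Leaf `k` of prefix `p` is named `pk`.
#' @param mutation_rate Expected mutations per unit time per lineage
#'   (>= 0; 0 gives a mutation-free dataset).
#' @param seed Integer seed; equal seeds give byte-identical outputs.
#' @param allow_repeat_sites If `FALSE` (default), the sites mutated on
#'   any single branch are distinct, so per-branch Hamming distance
#'   equals per-branch event count.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_leaves = 52L, n_sites = 100L,
                              groups = list(Eu_Am = 34L, YRI = 18L),
                              mutation_rate = 0.5, seed = 1L,
                              allow_repeat_sites = FALSE) {
  n_leaves <- as.integer(n_leaves); n_sites <- as.integer(n_sites)
  if (n_leaves < 2L) stop("n_leaves must be at least 2")
  if (n_sites < 1L) stop("n_sites must be at least 1")
  if (mutation_rate < 0) stop("mutation_rate must be non-negative")
  counts <- vapply(groups, as.integer, 0L)
  if (sum(counts) != n_leaves)
    stop(sprintf("group counts sum to %d but n_leaves is %d; supply matching groups",
                 sum(counts), n_leaves))
  structure(list(n_leaves = n_leaves, n_sites = n_sites,
                 groups = stats::setNames(as.list(counts), names(groups)),
                 mutation_rate = as.numeric(mutation_rate),
                 seed = as.integer(seed),
                 allow_repeat_sites = isTRUE(allow_repeat_sites)),
            class = "simulation_config")
}

#' Simulate a dataset with recorded ground truth
#'
#' Builds a random rooted binary tree by merging two uniformly chosen
#' lineages at each step, with inter-merge waiting times drawn
#' exponentially at rate k(k-1)/2 for k active lineages (so merge times
#' are strictly increasing); leaves sit at time 0.  Newick branch
#' lengths equal time differences.  Each branch receives a Poisson
#' number of mutations (rate x branch length), at uniform times within
#' the branch and uniform sites; the derived nucleotide is uniform over
#' the three alternatives.  Sequences are propagated from a uniform
#' random root sequence toward the leaves.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory: when given, writes `tree.tre`,
#'   `seqs.txt`, `groups.txt`, `events.log` and a plain-text
#'   `truth.txt` manifest there.
#' @return A list of class `mta_simulation` with fields `config`,
#'   `tree` ([mta_tree()]), `node_times` (data frame as from
#'   [compute_node_times()]), `branch_events` (named list,
#'   [clade_key()] -> list of [mutation_event()]s on the branch above
#'   that node), `node_sequences` (named character, [clade_key()] ->
#'   sequence), `root_sequence`, `sequences` (leaf data frame),
#'   `groups` (named list) and `log` ([event_log()]).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  leaf_names <- unlist(lapply(names(config$groups), function(p)
    paste0(p, seq_len(config$groups[[p]]))), use.names = FALSE)
  groups <- lapply(config$groups, function(cnt) NULL)
  for (p in names(config$groups))
    groups[[p]] <- paste0(p, seq_len(config$groups[[p]]))

  # --- coalescent topology -------------------------------------------------
  active <- lapply(leaf_names, function(nm)
    list(node = tree_node(nm), time = 0, members = nm))
  merges <- list()
  times <- list()  # clade_key -> node time
  for (nm in leaf_names) times[[clade_key(nm)]] <- 0
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pick <- sort(sample.int(k, 2L))
    left <- active[[pick[1L]]]; right <- active[[pick[2L]]]
    left$node$branch_length <- t - left$time
    right$node$branch_length <- t - right$time
    parent <- tree_node("", children = list(left$node, right$node))
    members <- c(left$members, right$members)
    merges[[length(merges) + 1L]] <- merge_event(t, left$members, right$members)
    times[[clade_key(members)]] <- t
    active[[pick[1L]]] <- list(node = parent, time = t, members = members)
    active <- active[-pick[2L]]
  }
  tree <- mta_tree(active[[1L]]$node)

  # --- mutations + sequence propagation ------------------------------------
  nts <- NUCLEOTIDES
  root_seq <- sample(nts, config$n_sites, replace = TRUE)
  branch_events <- list()
  node_seqs <- list()
  drop_mutations <- function(node, node_time, seq_chars) {
    node_seqs[[clade_key(leaf_set(node))]] <<- paste(seq_chars, collapse = "")
    for (ch in node$children) {
      ls <- leaf_set(ch)
      ct <- times[[clade_key(ls)]]
      bl <- node_time - ct
      m <- stats::rpois(1L, config$mutation_rate * bl)
      if (!config$allow_repeat_sites) m <- min(m, config$n_sites)
      sites <- if (config$allow_repeat_sites)
        sample.int(config$n_sites, m, replace = TRUE)
      else sample.int(config$n_sites, m)
      tms <- sort(stats::runif(m, min = ct, max = node_time), decreasing = TRUE)
      s <- seq_chars
      evs <- vector("list", m)
      for (idx in seq_len(m)) {
        x <- s[sites[idx]]
        y <- sample(setdiff(nts, x), 1L)
        evs[[idx]] <- mutation_event(tms[idx], sites[idx], x, y, ls)
        s[sites[idx]] <- y
      }
      if (m > 0L) branch_events[[clade_key(ls)]] <<- evs
      drop_mutations(ch, ct, s)
    }
  }
  drop_mutations(tree$root, t, root_seq)

  sequences <- data.frame(
    name = leaf_names,
    sequence = vapply(leaf_names, function(nm) node_seqs[[clade_key(nm)]], "",
                      USE.NAMES = FALSE),
    frequency = as.numeric(sample(5L, length(leaf_names), replace = TRUE)),
    stringsAsFactors = FALSE)

  log <- event_log(
    mutations = unlist(branch_events, recursive = FALSE, use.names = FALSE),
    merges = merges)

  sim <- structure(list(
    config = config, tree = tree,
    node_times = suppressWarnings(compute_node_times(tree, log)),
    branch_events = branch_events,
    node_sequences = unlist(node_seqs),
    root_sequence = paste(root_seq, collapse = ""),
    sequences = sequences, groups = groups, log = log),
    class = "mta_simulation")

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(write_newick(tree), file.path(dir, "tree.tre"))
    write_sequence_file(sequences, file.path(dir, "seqs.txt"))
    write_group_file(groups, file.path(dir, "groups.txt"))
    write_log_file(log, file.path(dir, "events.log"))
    manifest <- c(
      "# simulation ground truth",
      sprintf("seed %d", config$seed),
      sprintf("n_leaves %d", config$n_leaves),
      sprintf("n_sites %d", config$n_sites),
      sprintf("mutation_rate %s", fmt_num(config$mutation_rate)),
      sprintf("root_sequence %s", sim$root_sequence),
      sprintf("n_mutations %d", length(log$mutations)),
      sprintf("n_merges %d", length(merges)))
    writeLines(manifest, file.path(dir, "truth.txt"))
    sim$dir <- dir
  }
  sim
}

#' @export
print.mta_simulation <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d leaves, %d sites, %d mutation(s), %d merge(s) [seed %d]\n",
              x$config$n_leaves, x$config$n_sites, length(x$log$mutations),
              length(x$log$merges), x$config$seed))
  invisible(x)
}
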