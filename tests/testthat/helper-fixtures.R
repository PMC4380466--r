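# Shared fixture builders: everything is generated in code at test time.

# A small simulated dataset; single group unless told otherwise.
quick_sim <- function(seed, n_leaves = 8L, n_sites = 60L, rate = 0.5,
                      groups = list(tip = n_leaves), repeats = FALSE,
                      dir = NULL) {
  simulate_dataset(
    simulation_config(n_leaves = n_leaves, n_sites = n_sites, groups = groups,
                      mutation_rate = rate, seed = seed,
                      allow_repeat_sites = repeats),
    dir = dir)
}

# The three-taxon worked example: a cherry of two identical sequences
# plus a lineage that split at t = 2.0099 with an A->G mutation at site 54.
threetaxon_tree <- function() {
  parse_newick("((Eu_Am6:0.0,Eu_Am22:0.0):2.0099,Eu_Am5:2.0099);")
}

threetaxon_log <- function() {
  event_log(
    mutations = list(mutation_event(2.0099, 54, "A", "G", "Eu_Am5")),
    merges = list(merge_event(2.0099, "Eu_Am5", c("Eu_Am6", "Eu_Am22"))))
}

# clade_key -> annotations, for every node of a tree.
collect_node_annotations <- function(tree) {
  out <- list()
  visit <- function(node) {
    out[[clade_key(leaf_set(node))]] <<- node$annotations
    for (ch in node$children) visit(ch)
  }
  visit(tree$root)
  out
}

# Position-by-position Hamming oracle, independent of infer_mutations.
hamming_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  sum(va != vb)
}

total_tree_length <- function(tree) {
  lens <- unlist(mixtreeanno:::walk_nodes(tree$root, function(n)
    if (is.null(n$branch_length)) 0 else n$branch_length))
  sum(lens)
}

# Ground-truth per-branch labels in the order annotate_tree promises
# (descending event time, then ascending site).
truth_labels <- function(events) {
  ord <- order(-vapply(events, `[[`, 0, "time"), vapply(events, `[[`, 0L, "site"))
  vapply(events[ord], render_mutation_label, "")
}
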