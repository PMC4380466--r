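test_that("mutation labels render as ancestral + derived + site", {
  expect_equal(render_mutation_label(mutation_event(NA, 1, "A", "T", "x")), "AT1")
  expect_equal(render_mutation_label(mutation_event(2.0099, 54, "A", "G", "Eu_Am5")),
               "AG54")
  expect_match(render_mutation_label(mutation_event(0, 120, "C", "T", "x")),
               "^[ACGT][ACGT][1-9][0-9]*$")
  # a non-mutation is rejected at construction, never rendered
  expect_error(mutation_event(1, 3, "C", "C", "x"), "must differ")
})

test_that("sequence diff yields one event per differing site, ascending", {
  ev <- infer_mutations("ACTG", "TCTG")
  expect_length(ev, 1)
  expect_equal(ev[[1]]$site, 1L)
  expect_equal(ev[[1]]$from, "A")
  expect_equal(ev[[1]]$to, "T")
  expect_equal(render_mutation_label(ev[[1]]), "AT1")

  expect_length(infer_mutations("ACTG", "ACTG"), 0)
  expect_error(infer_mutations("ACTG", "ACT"), "length mismatch")

  set.seed(5)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    ev <- infer_mutations(a, b)
    expect_length(ev, hamming_oracle(a, b))
    sites <- vapply(ev, `[[`, 0L, "site")
    expect_identical(sites, sort(sites))
  }
})

test_that("clades are matched by exact leaf-set equality only", {
  tr <- threetaxon_tree()
  cherry <- match_clade(tr, c("Eu_Am6", "Eu_Am22"))
  expect_setequal(leaf_set(cherry), c("Eu_Am6", "Eu_Am22"))
  leaf <- match_clade(tr, "Eu_Am5")
  expect_identical(leaf$label, "Eu_Am5")
  expect_null(match_clade(tr, c("Eu_Am5", "Eu_Am6")))     # not a clade
  expect_null(match_clade(tr, c("Eu_Am5", "nobody")))     # absent taxon

  # exhaustive: every node's own leaf set matches exactly that node
  sim <- quick_sim(3, n_leaves = 12L, n_sites = 10L, rate = 0)
  keys <- unlist(mixtreeanno:::walk_nodes(sim$tree$root,
                                          function(n) clade_key(leaf_set(n))))
  for (k in keys) {
    hit <- match_clade(sim$tree, mixtreeanno:::clade_members(k))
    expect_equal(clade_key(leaf_set(hit)), k)
  }
})

test_that("node times come from merge events, leaves at zero", {
  expect_warning(nt <- compute_node_times(threetaxon_tree(), threetaxon_log()),
                 "no merge event")
  root_row <- which(vapply(nt$members, length, 0L) == 3)
  expect_equal(nt$time[root_row], 2.0099)
  expect_equal(nt$time[nt$is_leaf], c(0, 0, 0))

  # single-leaf tree, empty log
  nt1 <- compute_node_times(parse_newick("A;"), event_log())
  expect_equal(nrow(nt1), 1)
  expect_equal(nt1$time, 0)

  # simulated fixture: recovered times equal the simulated coalescent times
  sim <- quick_sim(21, n_leaves = 10L, n_sites = 20L, rate = 0.3)
  nt <- compute_node_times(sim$tree, sim$log)
  expect_true(all(!is.na(nt$time)))
  for (m in sim$log$merges) {
    row <- which(vapply(nt$members, function(x) setequal(x, c(m$left, m$right)), TRUE))
    expect_equal(nt$time[row], m$time)
  }
})

test_that("time-model violations fail loudly", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  bad <- event_log(merges = list(merge_event(5, "A", "B"),
                                 merge_event(2, c("A", "B"), "C")))
  expect_error(compute_node_times(tr, bad), "monotonicity",
               class = "mta_annotation_error")

  stray <- event_log(merges = list(merge_event(1, "A", "C")))
  expect_error(compute_node_times(tr, stray), "matches no clade",
               class = "mta_annotation_error")
})

test_that("branch lengths disagreeing with log times draw a warning", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  log <- event_log(merges = list(merge_event(1, "A", "B"),
                                 merge_event(5, c("A", "B"), "C")))
  w <- capture_warnings(compute_node_times(tr, log))
  expect_true(any(grepl("disagrees with log times", w)))
})

test_that("annotation attaches events to the right branches", {
  tr <- threetaxon_tree()
  at <- suppressWarnings(annotate_tree(tr, threetaxon_log()))
  ann <- collect_node_annotations(at)
  expect_identical(ann[[clade_key("Eu_Am5")]]$mutations, "AG54")
  expect_equal(ann[[clade_key(c("Eu_Am5", "Eu_Am6", "Eu_Am22"))]]$time, 2.0099)
  expect_null(ann[[clade_key(c("Eu_Am6", "Eu_Am22"))]]$mutations)
  s <- attr(at, "summary")
  expect_equal(s$attached, 2)
  expect_equal(s$unmatched, 0)
  # topology and branch lengths untouched
  expect_true(tree_equals(tr, at))

  # empty log: tree unchanged, empty summary
  at0 <- suppressWarnings(annotate_tree(tr, event_log()))
  expect_true(tree_equals(tr, at0))
  expect_equal(attr(at0, "summary")$attached, 0)

  # unmatched mutation events are reported, all-unmatched is an error
  log1 <- event_log(mutations = list(mutation_event(1, 2, "A", "C", "ghost"),
                                     mutation_event(1, 3, "A", "C", "Eu_Am5")))
  at1 <- suppressWarnings(annotate_tree(tr, log1))
  expect_equal(attr(at1, "summary")$unmatched, 1)
  log2 <- event_log(mutations = list(mutation_event(1, 2, "A", "C", "ghost")))
  expect_error(suppressWarnings(annotate_tree(tr, log2)),
               class = "mta_annotation_error")
})

test_that("multiple labels on one branch are ordered by time then site", {
  tr <- parse_newick("(A:3,B:3);")
  log <- event_log(
    mutations = list(mutation_event(1.0, 9, "A", "G", "A"),
                     mutation_event(2.5, 2, "C", "T", "A"),
                     mutation_event(2.5, 1, "G", "A", "A")),
    merges = list(merge_event(3, "A", "B")))
  at <- annotate_tree(tr, log)
  ann <- collect_node_annotations(at)
  expect_identical(ann[[clade_key("A")]]$mutations, c("GA1", "CT2", "AG9"))
})

test_that("ancestral reconstruction undoes mutations back to the target time", {
  tr <- threetaxon_tree()
  log <- threetaxon_log()
  obs <- paste(c(rep("C", 53), "G", rep("C", 46)), collapse = "")
  seqs <- data.frame(name = c("Eu_Am5", "Eu_Am6", "Eu_Am22"),
                     sequence = c(obs, gsub("G", "A", obs), gsub("G", "A", obs)),
                     frequency = c(1, 1, 1), stringsAsFactors = FALSE)
  anc <- reconstruct_ancestral_sequence("Eu_Am5", 2.0099, tr, log, seqs)
  expect_equal(substr(anc, 54, 54), "A")   # G observed, A ancestral
  expect_equal(reconstruct_ancestral_sequence("Eu_Am5", 0, tr, log, seqs), obs)
  expect_error(reconstruct_ancestral_sequence("missing", 0, tr, log, seqs),
               class = "mta_annotation_error")
  expect_error(reconstruct_ancestral_sequence("Eu_Am5", 99, tr, log, seqs),
               "exceeds the root time", class = "mta_annotation_error")
})

test_that("reconstruction is consistent across both children of every merge", {
  for (seed in c(2, 13)) {
    sim <- quick_sim(seed, n_leaves = 9L, n_sites = 50L, rate = 0.8)
    internal <- sim$node_times[!sim$node_times$is_leaf, ]
    for (r in seq_len(nrow(internal))) {
      members <- internal$members[[r]]
      t0 <- internal$time[r]
      node <- match_clade(sim$tree, members)
      picks <- vapply(node$children, function(ch) leaf_set(ch)[1L], "")
      recon <- vapply(picks, function(lf)
        reconstruct_ancestral_sequence(lf, t0, sim$tree, sim$log, sim$sequences),
        "")
      expect_equal(recon[[1]], recon[[2]])
      # and both equal the simulator's recorded ancestral sequence
      expect_equal(recon[[1]], unname(sim$node_sequences[[clade_key(members)]]))
    }
  }
})
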