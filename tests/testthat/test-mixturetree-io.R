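test_that("sequence file dialect reads one record per line", {
  p <- withr::local_tempfile(lines = c(
    "# mixturetree-dialect v1",
    "Eu_Am5 ACTG 3",
    "",
    "# a comment",
    "YRI1 GGTA 1.5"))
  recs <- read_sequence_file(p)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$name, c("Eu_Am5", "YRI1"))
  expect_equal(recs$sequence[1], "ACTG")
  expect_equal(recs$frequency, c(3, 1.5))
})

test_that("an empty sequence file yields zero records with a warning", {
  p <- withr::local_tempfile(lines = "# nothing here")
  expect_warning(recs <- read_sequence_file(p), "no records")
  expect_equal(nrow(recs), 0)
})

test_that("sequence-file format errors name the offending line", {
  cases <- list(
    list(lines = c("A ACTG 1", "B ACT 1"), line = 2, msg = "ragged"),
    list(lines = c("A ACTG 1", "A GGGG 1"), line = 2, msg = "duplicate"),
    list(lines = c("ok ACTG 1", "bad ACXG 1"), line = 2, msg = "outside ACGT"),
    list(lines = c("A ACTG -2"), line = 1, msg = "frequency"),
    list(lines = c("A ACTG"), line = 1, msg = "3 fields"))
  for (case in cases) {
    p <- withr::local_tempfile(lines = case$lines)
    err <- tryCatch(read_sequence_file(p), error = function(e) e)
    expect_s3_class(err, "mta_format_error")
    expect_match(conditionMessage(err), case$msg)
    expect_equal(err$line, case$line)
  }
})

test_that("group file reads groups in order and enforces exclusivity", {
  p <- withr::local_tempfile(lines = c("YRI: YRI1 YRI2",
                                       "Eu_Am: Eu_Am5 Eu_Am6 Eu_Am22"))
  g <- read_group_file(p)
  expect_identical(names(g), c("YRI", "Eu_Am"))
  expect_identical(g$Eu_Am, c("Eu_Am5", "Eu_Am6", "Eu_Am22"))

  p1 <- withr::local_tempfile(lines = "all: A B C D")
  expect_length(read_group_file(p1), 1)

  p2 <- withr::local_tempfile(lines = c("g1: A B", "g2: A C"))
  expect_error(read_group_file(p2), "more than one group",
               class = "mta_format_error")
  p3 <- withr::local_tempfile(lines = "g1:")
  expect_error(read_group_file(p3), "no members", class = "mta_format_error")
})

test_that("event-log lines parse into typed events, tolerantly", {
  p <- withr::local_tempfile(lines = c(
    "mutation t=2.0099 site=54 from=A to=G clade=Eu_Am5",
    "some debugging chatter",
    "merge t=2.0099 left=Eu_Am5 right=Eu_Am6,Eu_Am22",
    "mutation t=1 site=0 from=A to=G clade=X"))  # invalid site -> skipped
  expect_warning(log <- read_log_file(p), "skipped 2")
  expect_length(log$mutations, 1)
  expect_length(log$merges, 1)
  expect_length(log$skipped, 2)
  mu <- log$mutations[[1]]
  expect_equal(mu$time, 2.0099)
  expect_equal(mu$site, 54L)
  expect_equal(mu$from, "A")
  expect_equal(mu$to, "G")
  expect_equal(mu$clade, "Eu_Am5")
  expect_setequal(log$merges[[1]]$right, c("Eu_Am6", "Eu_Am22"))

  p0 <- withr::local_tempfile(lines = "nothing useful")
  expect_error(read_log_file(p0), "no parseable events",
               class = "mta_format_error")
})

test_that("merges come back sorted by time and bounded by taxon count", {
  p <- withr::local_tempfile(lines = c(
    "merge t=3.5 left=A,B right=C",
    "merge t=1.25 left=A right=B"))
  log <- read_log_file(p)
  expect_equal(vapply(log$merges, `[[`, 0, "time"), c(1.25, 3.5))
  expect_lte(length(log$merges),
             length(unique(unlist(lapply(log$merges, function(m) c(m$left, m$right))))) - 1L)
  # n taxa = 3 here, so a third merge must be rejected
  expect_error(event_log(merges = list(
    merge_event(1, "A", "B"), merge_event(2, "A", "C"),
    merge_event(3, "B", "C"))), class = "mta_format_error")
})

test_that("read after write is the identity on all three formats", {
  sim <- quick_sim(11, n_leaves = 20L, n_sites = 40L, rate = 1,
                   groups = list(Eu_Am = 12L, YRI = 8L))
  d <- withr::local_tempdir()

  write_sequence_file(sim$sequences, file.path(d, "s.txt"))
  expect_equal(read_sequence_file(file.path(d, "s.txt")), sim$sequences)

  write_group_file(sim$groups, file.path(d, "g.txt"))
  expect_equal(read_group_file(file.path(d, "g.txt")), sim$groups)

  write_log_file(sim$log, file.path(d, "l.log"))
  back <- read_log_file(file.path(d, "l.log"))
  expect_equal(back$merges, sim$log$merges)
  # mutations: same multiset of events (writer groups mutations after merges)
  key <- function(ev) paste(ev$time, ev$site, ev$from, ev$to,
                            paste(sort(ev$clade), collapse = ","))
  expect_setequal(vapply(back$mutations, key, ""),
                  vapply(sim$log$mutations, key, ""))

  # worked-example log round-trips exactly
  write_log_file(threetaxon_log(), file.path(d, "threetaxon.log"))
  expect_equal(read_log_file(file.path(d, "threetaxon.log")), threetaxon_log())
})

test_that("round-trip of many random sequence records is exact", {
  set.seed(42)
  n <- 300L
  recs <- data.frame(
    name = paste0("tx", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = ""), ""),
    frequency = as.numeric(sample(1:9, n, replace = TRUE)),
    stringsAsFactors = FALSE)
  p <- withr::local_tempfile()
  write_sequence_file(recs, p)
  expect_equal(read_sequence_file(p), recs)
})
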