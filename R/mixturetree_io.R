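# Readers and writers for the three auxiliary plain-text files that
# accompany a MixtureTree run: the sequence file, the group file and the
# event log.  All three share a minimal line grammar: whitespace-separated
# fields, '#' comment lines, one record per line.  Writers emit a
# versioned header comment ("# mixturetree-dialect v1"); readers accept
# files with or without it.

DIALECT_HEADER <- "# mixturetree-dialect v1"
NUCLEOTIDES <- c("A", "C", "G", "T")

content_lines <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(text = raw[keep], lineno = which(keep))
}

#' Read a sequence file
#'
#' One record per line: `name sequence frequency`, whitespace-separated.
#' Sequences are over the DNA alphabet ACGT and must all share one
#' length; names must be unique; frequencies (observed counts or
#' proportions) must be non-negative.
#'
#' @param path Path to the file.
#' @return A data frame with columns `name`, `sequence`, `frequency`,
#'   in file order.  An empty file yields zero rows with a warning.
#' @export
read_sequence_file <- function(path) {
  con <- content_lines(path)
  if (length(con$text) == 0L) {
    warning(sprintf("sequence file '%s' contains no records", path))
    return(data.frame(name = character(), sequence = character(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  recs <- vector("list", length(con$text))
  for (k in seq_along(con$text)) {
    ln <- con$lineno[k]
    f <- strsplit(trimws(con$text[k]), "\\s+")[[1L]]
    if (length(f) != 3L)
      format_error("expected 3 fields: name sequence frequency", ln)
    seqc <- strsplit(f[2L], "", fixed = TRUE)[[1L]]
    if (!all(seqc %in% NUCLEOTIDES))
      format_error(sprintf("sequence for '%s' has characters outside ACGT", f[1L]), ln)
    freq <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(freq) || freq < 0)
      format_error(sprintf("invalid frequency '%s'", f[3L]), ln)
    recs[[k]] <- list(name = f[1L], sequence = f[2L], frequency = freq, lineno = ln)
  }
  names_ <- vapply(recs, `[[`, "", "name")
  d <- which(duplicated(names_))
  if (length(d) > 0L)
    format_error(sprintf("duplicate sequence name '%s'", names_[d[1L]]),
                 recs[[d[1L]]]$lineno)
  lens <- nchar(vapply(recs, `[[`, "", "sequence"))
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    format_error(sprintf("ragged sequence lengths: '%s' has %d sites, expected %d",
                         names_[bad], lens[bad], lens[1L]), recs[[bad]]$lineno)
  }
  data.frame(name = names_,
             sequence = vapply(recs, `[[`, "", "sequence"),
             frequency = vapply(recs, `[[`, 0, "frequency"),
             stringsAsFactors = FALSE)
}

#' Write a sequence file
#'
#' @param records Data frame as returned by [read_sequence_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_file <- function(records, path) {
  lines <- c(DIALECT_HEADER,
             sprintf("%s %s %s", records$name, records$sequence,
                     vapply(records$frequency, fmt_num, "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a group file
#'
#' One group per line: `group_name: member member ...`.  A taxon may
#' belong to at most one group; empty groups are an error.
#'
#' @param path Path to the file.
#' @return A named list (group name -> character vector of members), in
#'   file order.
#' @export
read_group_file <- function(path) {
  con <- content_lines(path)
  groups <- list()
  seen <- character()
  for (k in seq_along(con$text)) {
    ln <- con$lineno[k]
    line <- con$text[k]
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0L) format_error("expected 'group_name: member ...'", ln)
    gname <- trimws(substr(line, 1L, colon - 1L))
    if (!nzchar(gname)) format_error("empty group name", ln)
    if (gname %in% names(groups))
      format_error(sprintf("group '%s' defined twice", gname), ln)
    members <- strsplit(trimws(substr(line, colon + 1L, nchar(line))), "\\s+")[[1L]]
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      format_error(sprintf("group '%s' has no members", gname), ln)
    clash <- members[members %in% seen]
    if (length(clash) > 0L)
      format_error(sprintf("taxon '%s' assigned to more than one group", clash[1L]), ln)
    seen <- c(seen, members)
    groups[[gname]] <- members
  }
  groups
}

#' Write a group file
#'
#' @param groups Named list, group name -> character vector of members.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_file <- function(groups, path) {
  lines <- c(DIALECT_HEADER,
             vapply(names(groups),
                    function(g) paste0(g, ": ", paste(groups[[g]], collapse = " ")),
                    ""))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a mutation event
#'
#' A nucleotide substitution on a lineage: at time `time` (reverse time,
#' 0 = present) the state at 1-based `site` changes from `from` (the
#' ancestral nucleotide, the state at time t+eps) to `to` (the derived
#' state at time t), on the branch above the clade whose leaf set is
#' `clade`.
#'
#' @param time Non-negative real, or `NA` when unknown (events inferred
#'   by sequence comparison carry no time).
#' @param site 1-based site index.
#' @param from,to Ancestral and derived nucleotides, in ACGT; must differ.
#' @param clade Character vector of taxon names carrying the event.
#' @return A list of class `mutation_event`.
#' @export
mutation_event <- function(time, site, from, to, clade) {
  if (!is.na(time) && time < 0) stop("mutation time must be non-negative")
  site <- as.integer(site)
  if (is.na(site) || site < 1L) stop("site must be a positive integer")
  if (!(from %in% NUCLEOTIDES) || !(to %in% NUCLEOTIDES))
    stop("nucleotides must be one of A, C, G, T")
  if (from == to) stop("ancestral and derived nucleotides must differ")
  if (length(clade) == 0L) stop("clade must be non-empty")
  structure(list(time = as.numeric(time), site = site, from = from, to = to,
                 clade = as.character(clade)),
            class = "mutation_event")
}

#' Construct a merge (coalescence) event
#'
#' Two lineages, identified by their leaf sets, coalesce at time `time`.
#'
#' @param time Positive real merge time.
#' @param left,right Disjoint, non-empty character vectors of taxon names.
#' @return A list of class `merge_event`.
#' @export
merge_event <- function(time, left, right) {
  if (is.na(time) || time <= 0) stop("merge time must be positive")
  if (length(left) == 0L || length(right) == 0L)
    stop("both clades of a merge must be non-empty")
  if (length(intersect(left, right)) > 0L)
    stop("merge clades must be disjoint")
  structure(list(time = as.numeric(time), left = as.character(left),
                 right = as.character(right)),
            class = "merge_event")
}

#' Construct an event log
#'
#' @param mutations List of [mutation_event()]s.
#' @param merges List of [merge_event()]s; sorted ascending by time.
#' @param skipped Character vector of unparseable input lines (tolerant
#'   log reading keeps them for reporting).
#' @return A list of class `event_log`.
#' @export
event_log <- function(mutations = list(), merges = list(), skipped = character()) {
  if (length(merges) > 0L) {
    merges <- merges[order(vapply(merges, `[[`, 0, "time"))]
    taxa <- unique(unlist(lapply(merges, function(m) c(m$left, m$right))))
    if (length(merges) > length(taxa) - 1L)
      format_error(sprintf(
        "log holds %d merges but only %d distinct taxa (at most n-1 merges possible)",
        length(merges), length(taxa)))
  }
  structure(list(mutations = mutations, merges = merges, skipped = skipped),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log: %d mutation(s), %d merge(s)%s\n",
              length(x$mutations), length(x$merges),
              if (length(x$skipped) > 0L)
                sprintf(", %d unparseable line(s) skipped", length(x$skipped))
              else ""))
  invisible(x)
}

csv_names <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]

#' Read a MixtureTree-style event log
#'
#' Tagged lines, one event per line:
#' \preformatted{
#' merge t=<real> left=<csv-names> right=<csv-names>
#' mutation t=<real> site=<int> from=<nt> to=<nt> clade=<csv-names>
#' }
#' Because the upstream source is debugging output, parsing is tolerant:
#' lines that match neither form (or violate an event invariant) are
#' skipped, counted and reported in the returned log's `skipped` field,
#' with a warning.  A file with zero parseable events is an error.
#'
#' @param path Path to the log file.
#' @return An [event_log()]; merges sorted ascending by time.
#' @export
read_log_file <- function(path) {
  con <- content_lines(path)
  mut_re <- paste0("^mutation\\s+t=([0-9.eE+-]+)\\s+site=([0-9]+)\\s+",
                   "from=([ACGT])\\s+to=([ACGT])\\s+clade=(\\S+)\\s*$")
  mrg_re <- "^merge\\s+t=([0-9.eE+-]+)\\s+left=(\\S+)\\s+right=(\\S+)\\s*$"
  mutations <- list(); merges <- list(); skipped <- character()
  for (k in seq_along(con$text)) {
    line <- trimws(con$text[k])
    if (grepl(mut_re, line)) {
      m <- regmatches(line, regexec(mut_re, line))[[1L]]
      ev <- tryCatch(mutation_event(as.numeric(m[2L]), as.integer(m[3L]),
                                    m[4L], m[5L], csv_names(m[6L])),
                     error = function(e) NULL)
      if (is.null(ev)) skipped <- c(skipped, sprintf("line %d: %s", con$lineno[k], line))
      else mutations[[length(mutations) + 1L]] <- ev
    } else if (grepl(mrg_re, line)) {
      m <- regmatches(line, regexec(mrg_re, line))[[1L]]
      ev <- tryCatch(merge_event(as.numeric(m[2L]), csv_names(m[3L]), csv_names(m[4L])),
                     error = function(e) NULL)
      if (is.null(ev)) skipped <- c(skipped, sprintf("line %d: %s", con$lineno[k], line))
      else merges[[length(merges) + 1L]] <- ev
    } else {
      skipped <- c(skipped, sprintf("line %d: %s", con$lineno[k], line))
    }
  }
  if (length(mutations) + length(merges) == 0L)
    format_error(sprintf("no parseable events in log file '%s'", path))
  if (length(skipped) > 0L)
    warning(sprintf("skipped %d unparseable log line(s)", length(skipped)))
  event_log(mutations, merges, skipped)
}

#' Write an event log
#'
#' @param log An [event_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log_file <- function(log, path) {
  mut_lines <- vapply(log$mutations, function(ev)
    sprintf("mutation t=%s site=%d from=%s to=%s clade=%s",
            fmt_num(ev$time), ev$site, ev$from, ev$to,
            paste(ev$clade, collapse = ",")), "")
  mrg_lines <- vapply(log$merges, function(ev)
    sprintf("merge t=%s left=%s right=%s", fmt_num(ev$time),
            paste(ev$left, collapse = ","), paste(ev$right, collapse = ",")), "")
  writeLines(c(DIALECT_HEADER, mrg_lines, mut_lines), path)
  invisible(path)
}
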