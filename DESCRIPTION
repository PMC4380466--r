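Package: mixtreeanno
Title: Colorize and Annotate Phylogenetic Trees for FigTree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Colorizes any Newick phylogeny by taxon groups derived from
    sequence names or an explicit group file, annotates branches with
    nucleotide mutation events (xy### labels) and coalescent merge times
    parsed from a MixtureTree-style event log, and writes a FigTree-dialect
    Nexus file that FigTree-compatible viewers render with colors and
    per-branch metadata.  Includes lossless Newick parsing and serialization,
    readers and writers for the plain-text sequence/group/event-log dialect,
    ancestral sequence reconstruction along lineages, a coalescent-style
    simulator that generates internally consistent test datasets with
    recorded ground truth, and a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
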