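---
title: "Colorizing and annotating phylogenies: the model behind mixtreeanno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorizing and annotating phylogenies: the model behind mixtreeanno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixtreeanno)
```

`mixtreeanno` turns a plain Newick phylogeny plus optional auxiliary files —
sequences, group definitions, and a coalescent event log — into a
FigTree-dialect Nexus file in which every branch carries its group color and
its inferred mutation history. This vignette explains the underlying model,
the file dialects, the tunable parameters, and the design decisions taken
where more than one reasonable choice existed.

## The time model

The package adopts the reverse-time convention of coalescent reconstruction:
observed sequences sit at time $t = 0$, ancestors at larger $t$, and the most
recent common ancestor of all leaves is the oldest node. Two kinds of events
drive annotation:

* a **merge event** $(t, L, R)$: the lineages ancestral to the leaf sets $L$
  and $R$ coalesce at time $t$. It dates the internal node whose descendant
  leaf set is exactly $L \cup R$.
* a **mutation event** $(t, s, x, y, C)$: on the branch above the clade with
  leaf set $C$, site $s$ (1-based) changed state; the lineage carried
  nucleotide $x$ at time $t + \epsilon$ (the ancestral state) and $y$ at time
  $t$ (the derived state). The event is rendered as the compact label
  $xy s$ — for example an A-to-T change at site 1 is `AT1`, an A-to-G change
  at site 54 is `AG54`.

$\epsilon$ is purely symbolic — "immediately older than $t$" — and no numeric
epsilon is ever added to a time.

Node times must be monotone: a parent is never younger than its child.
`compute_node_times()` enforces this and errors, naming the offending edge,
rather than silently accepting an inconsistent tree/log pairing. Internal
nodes for which the log holds no merge event keep an *absent* time (with a
warning); the annotated tree is still valid.

### Ancestral reconstruction

Because each mutation event records both endpoint states, the history is
invertible: starting from a leaf's observed sequence,
`reconstruct_ancestral_sequence()` walks the leaf-to-root path and, for every
event with time at most the target time, resets the event's site from the
derived to the ancestral nucleotide, in ascending time order. Repeat
mutations at one site on one lineage are legal and are undone in time order.
Two consistency properties follow and are tested: reconstructions through the
two children of any merge node agree at the merge time, and the number of
labels on a branch equals the Hamming distance between the lineage's
reconstructed sequences at the branch's two endpoint times (when the
simulator is run without repeat sites).

## Matching events to branches

The log references clades by leaf sets; the tree knows its own clades. The
package matches the two by **exact leaf-set equality** (`match_clade()`): an
event is attached only to a node whose descendant leaves are exactly the
event's clade — never to a superset or subset, never to a "nearest" clade.
This is the main open design point, since event logs do not specify the
linkage; exact matching was chosen because a silently mis-placed annotation is
worse than a loud failure. Consequences:

* an unmatched *merge* event is an error (the tree was probably re-rooted or
  ladderized after the log was written);
* unmatched *mutation* events are collected into a summary (attached count,
  unmatched count, the events themselves) attached to the returned tree;
* if the log holds events but none matches at all, the pairing is assumed
  wrong and annotation errors out.

When a Newick branch length disagrees with the log-derived time difference by
more than $10^{-6}$ (relative), a warning is issued; log times win for
annotation while the branch lengths are left untouched, since displayed
distances come from the Newick file.

Multiple labels on one branch are kept as an ordered list — descending event
time, then ascending site — and serialized as FigTree's braced multi-value
convention, `mutations={"AG54","CT12"}`.

## Colorization

Every leaf gets a group; every group gets a color; internal branches are
colored by **monophyletic propagation**: a branch takes a group's color if
and only if all its descendant leaves belong to that one group, and stays
black (`#000000`, the conventional base color of a tree) otherwise. Coloring
the mixed branches black rather than by majority group is the conservative
choice: a black backbone with colored clusters reads unambiguously, whereas a
majority rule invents signal on deep branches.

Group membership comes from, in order of precedence:

1. an explicit group file (`group_name: member member ...`) — its assignments
   always win, and members absent from the tree draw a warning;
2. name inference: the maximal trailing run of decimal digits is stripped
   from the taxon name (`Eu_Am5` → `Eu_Am`, `YRI7` → `YRI`); an all-digit
   name is its own group. This concrete rule is this package's realization of
   "color by sequence name"; it matches the common convention of numbering
   haplotypes within a population and is fully overridable by a group file.

Colors come from user overrides (`group=#rrggbb` tokens, or a `key = value`
color file) plus a fixed 12-color palette assigned to the remaining groups in
sorted group-name order, cycling if exhausted. Nothing is random, so equal
inputs give byte-identical output.

## File dialects

The upstream tool's sequence/group/log grammars are not published, so the
package defines a minimal, self-describing dialect and uses it symmetrically
in its readers, writers and simulator: whitespace-separated fields, one
record per line, `#` comments, and an optional version header
(`# mixturetree-dialect v1`).

* sequence file: `name ACGT-sequence frequency` — names unique, all
  sequences one length, frequencies non-negative (carried through, not used
  by colorization or annotation);
* group file: `group_name: member member ...` — a taxon in at most one group;
* log file: `merge t=<real> left=<csv> right=<csv>` and
  `mutation t=<real> site=<int> from=<nt> to=<nt> clade=<csv>`.

Because the log is debugging output by origin, its reader is *tolerant*:
unparseable lines are skipped, counted and reported rather than fatal; a log
with zero parseable events is an error. The other two readers are strict and
name the offending line in every format error. Exact byte-level
interoperability with the original tool's files cannot be claimed without its
grammar; the dialect here is a documented stand-in.

Newick parsing follows the standard: quoted labels with `''` escaping,
underscores in unquoted labels kept as-is, bracketed comments stripped with a
warning (the package's own annotations are authoritative on output, which
avoids conflicting dialects on re-annotation). Child order is preserved as
written. Basal multifurcations are accepted and treated as rooted at the
written root, because the Nexus output must declare a concrete root. Branch
lengths are serialized with the shortest decimal representation that
round-trips, so write–read cycles are exact; zero-length and absent lengths
are distinct states and both preserved.

## The Nexus output

The writer emits a fixed layout — LF newlines, lowercase keywords, one
tab of indentation, a taxa block (`dimensions ntax=N;`, one taxlabel per
line, each optionally suffixed `[&!color=#rrggbb]`) and a trees block with
exactly one statement `tree <name> = [&R] <annotated newick>;` — so output is
byte-reproducible and testable against golden files. Node metadata rides in
FigTree comments placed between a node's label/subtree and its `:length`,
with keys in the fixed order `!color`, `mutations`, `time`. The annotation
keys `mutations` and `time` are this package's documented choice for the
event metadata. `read_nexus()` is the exact inverse on the writer's own
output (reading arbitrary third-party Nexus is out of scope) and is used
throughout the tests for round-trip verification.

## The simulator

`simulate_dataset()` generates internally consistent datasets with recorded
ground truth, so the whole pipeline is testable without any external data:

* **topology/times**: starting from $k$ leaves at $t = 0$, two uniformly
  chosen lineages merge after an exponential waiting time with rate
  $k(k-1)/2$, repeated until one lineage remains — the standard coalescent
  waiting-time scheme, giving strictly increasing merge times. Branch lengths
  equal time differences.
* **mutations**: each branch receives a Poisson number of events with mean
  (rate × branch length), at uniform times within the branch and uniform
  sites; the derived nucleotide is uniform over the three alternatives. With
  `allow_repeat_sites = FALSE` (default) the sites on any one branch are
  distinct, which makes per-branch event counts equal per-branch Hamming
  distances — the property the test suite exploits.
* **sequences**: a uniform random root sequence is propagated root-to-leaves,
  applying each branch's events oldest-first.

Defaults describe the demonstration dataset the tool was built around: 52
leaves (34 named `Eu_Am1..34`, 18 named `YRI1..18`) and 100 sites, mirroring
a two-population human haplotype sample. The mutation rate has no published
counterpart; the default of 0.5 expected mutations per unit coalescent time
per lineage was chosen once as a realistic middle ground — on a 52-leaf
coalescent tree it yields a few dozen segregating events over 100 sites,
sparse enough that repeat-site collisions stay rare, dense enough that most
branches carry annotation.

What the simulator does **not** emulate: population-genetic realism beyond
the coalescent clock (no population structure between the named groups, no
recombination, no frequency model — frequencies are arbitrary small
integers), and no estimation noise, since events are recorded as they are
generated rather than inferred from the leaf data. Passing the
ground-truth-recovery tests therefore shows that the pipeline *transports*
event logs onto trees losslessly; it says nothing about the quality of any
upstream inference that produced a real log.

## Numerical and degenerate-input choices

* Branch lengths compare with relative tolerance $10^{-9}$ in
  `tree_equals()`; serialized numbers round-trip exactly, so file cycles are
  bit-stable and times can be compared as text.
* Ties among mutation events at one time on one branch break by ascending
  site.
* A single-leaf tree is valid (the leaf at $t = 0$, nothing to merge); an
  empty log is valid input to `annotate_tree()` (the tree passes through
  with an empty summary) but an error from `read_log_file()`, which demands
  at least one parseable event from a real file.
* Multifurcating nodes are accepted everywhere; events simply cannot match a
  clade the tree does not contain, and the exact-match rule reports them.
* The output file is written atomically (temp file + rename), so a failed
  run never leaves a truncated Nexus behind.

## Problem sizes in the test suite

The suite verifies the core recovery property on 100 simulated datasets of
3–60 leaves and 10–200 sites, round-trips 200 random annotated documents,
and checks the counting-process mean over 200 replicates of a 6-leaf
simulation; these sizes exercise every code path (including palette cycling
and multifurcation handling) while keeping a full run in the tens of
seconds.

## Known limitations

* Only the first tree of a multi-tree Newick file is read (with a warning).
* `read_nexus()` targets the package's own dialect; translate tables,
  data/characters blocks and other third-party Nexus constructs are not
  parsed.
* Trees re-rooted or rearranged after their event log was generated will
  fail annotation by design (exact clade matching).
* Quoted labels containing `;` or `]` are not supported inside the Nexus
  tree statement.
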