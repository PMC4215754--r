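---
title: "Correcting and tuning KEGG KGML pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting and tuning KEGG KGML pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgmltune)
```

## The pathway model

A KGML document is held as a `kegg_pathway`: ordered `kegg_entry` nodes
keyed by integer entry id, and ordered `kegg_relation` edges.  The model
targets the KGML v0.7.x element set.  Three invariants are enforced on
every parse and before every write: entry ids are unique; every relation
endpoint resolves to an entry; every group component resolves to an
entry (and a group has at least two components).  Attributes outside the
core set are preserved as opaque key–value maps and re-emitted, so
vocabulary drift in KEGG files does not destroy information.  Entry
`name` attributes are split on whitespace into a list of KEGG ids and
re-joined with single spaces on write; graphics coordinates are integer
node centres with a top-left origin, y growing downward.

Two pragmatic parsing decisions reflect what real KEGG files contain:
duplicate relations (same endpoints, type and subtypes) are collapsed to
one and logged rather than rejected, and `<reaction>` elements — the
compound-chemistry markup of metabolic maps — are skipped with a logged
warning, because the correction and tuning machinery here is defined on
protein-interaction relations only.  Metabolic maps that do carry
`<relation>` elements parse like signaling maps.

Serialisation is deterministic: fixed element order following the model,
fixed core-attribute order, extra attributes sorted by name.  Two writes
of the same object are byte-identical, which makes diff-based change
tracking and caching meaningful.

## Corrections

Three inconsistency classes are detected and repaired.  Every mutation
emits exactly one log record (ISO timestamp, kind, key=value fields), so
the structural diff between input and output is fully accounted for by
the log — a property the test suite checks.

**PCP motifs.**  A compound-mediated interaction drawn as `A → c → B`
lacks the direct protein edge.  Detection enumerates every triple with
`c` a compound entry and `A ≠ B` gene entries; it is exhaustive and is
tested against an independent brute-force enumeration.  Correction adds
`A → B` as `PPrel` with a `compound` subtype holding `c`'s entry id,
inheriting the other subtypes of the `A → c` relation.  Two design
choices were genuinely open and are fixed as follows: when a compound
has several upstream and downstream proteins, *all* pairs receive an
edge (this preserves every signal path); and the original
protein–compound relations are *kept*, the new edge being overlaid on
the intact map (removal would destroy information that other tools
still use).  The correction is idempotent: an edge that already exists
is not added again.

**Reversed bindings.**  Which binding/association edges are
"mis-directed" is not decidable from the KGML alone, so the detector is
a deliberately isolated, swappable predicate — the *dead-end
heuristic*: a `PPrel` binding edge is suspect when its source has no
other incoming relation while its target has at least one other
outgoing relation, i.e. the edge runs from a source-less terminal into
the cascade, the opposite of how a ligand or adapter binding feeds
signal flow.  Correction swaps the endpoints of flagged edges only (the
semi-automatic contract: passing an unflagged relation is an error),
leaves subtypes untouched, and marks the relation `cyk_reversed`.
Whether arrowhead graphics could sharpen the predicate is unknown;
keeping it a single function makes it replaceable without touching the
rest of the module.

**Group nodes.**  A complex `G` with members `e1..ek` is dissolved:
members are pairwise connected with binding/association edges
(`k(k−1)/2` of them — complex members are physically bound), each
incident relation `X → G` is fanned out to `X → ei` (and symmetrically),
`G` is removed, and each member is annotated with its former group.  So
a group with `k` members and `m` incident relations changes the relation
count by exactly `k(k−1)/2 + mk − m`, barring collisions with authored
edges, which are collapsed and logged.  Nested groups are processed
innermost-first, an outer group inheriting the members of a dissolved
inner component; cyclic component references are a validation error.
Ties are broken everywhere by ascending entry id so output is
reproducible.

`correct_all()` runs PCP → binding reversal → group expansion in that
fixed order: the first two operate on the authored topology, and group
expansion last keeps their candidate sets independent of the synthetic
pairwise-binding edges it introduces.  `report-only` mode returns every
candidate without mutating anything.  On the package's fixtures the full
pass is idempotent; this is asserted, not assumed.

## Tuning

Both tuning operations are pure functions: the input pathway is cloned
and the clone gets fresh sequential entry ids (relation endpoints, group
components and `compound` subtype values are remapped together).

**Tissue-specific tuning** (`tune_tissue()`).  The threshold is either
absolute or a percentile of expression values.  The percentile is
*nearest-rank* — the `ceiling(p/100·n)`-th smallest value — chosen over
interpolating definitions because it is deterministic, returns an actual
data value, and has unambiguous boundary behaviour (0 → minimum, 100 →
maximum).  The percentile scope defaults to the chosen tissue's column
(`per_tissue`); a `whole_table` scope is also implemented because both
readings of "percentile of the dataset" are defensible, and the choice
is surfaced rather than hidden.  Survival is `expression ≥ threshold`.
A gene absent from the table counts as below threshold and is removed
with a per-gene log record: absence of evidence must not silently count
as expression.  A `keep_missing` flag inverts this for atlases known to
be incomplete.  Entries keep their node if at least one member survives;
gene entries left empty are removed with their incident relations;
non-gene entries are always preserved, except that a group reduced below
two surviving components no longer denotes a complex and is dropped.

**PPI drill-down** (`drill_down_ppi()`).  Every gene entry is expanded
into one node per member gene.  For a parent relation between two gene
entries, the member pair `u, v` keeps a directed edge `u → v` exactly
when the unordered pair has a PPI record with score at or above the
cutoff and at least one accepted evidence source — direction is
inherited from the pathway, evidence from the undirected PPI table.
Relations touching a non-gene entry (compound, map) are fanned out to
all members *without* filtering, because physical-interaction evidence
is undefined for such endpoints.  Members of one paralog entry are not
connected to each other: paralogs are alternatives occupying the same
slot, not interaction partners.  After edge construction, nodes sharing
a gene id are merged (graphics from the lowest original entry id — a
deterministic, order-independent choice; the node label becomes the gene
id), coinciding edges are collapsed and logged, and gene nodes with no
incident relation are removed.  Drill-down refuses pathways that still
contain group entries: complex semantics under member-level expansion
are ill-defined, and `process_group_nodes()` exists precisely to resolve
them first.

PPI scores are normalised to [0, 1]; a column in the 0–999/1000
convention is detected by any value exceeding 1 and divided by 1000,
with the rescaling recorded on the table.

`tune_full()` is the composition tissue-then-PPI, producing the
"fine-tuned" variant in which every remaining gene is both expressed in
the chosen context and physically connected.

## Synthetic fixtures

The generators exist to give every detector and tuner an exact ground
truth.  `make_synthetic_pathway()` builds a signaling-style map: a chain
backbone (guaranteeing interior nodes have both incoming and outgoing
flow) with extra random edges, none of which carry binding subtypes.
Planted motifs are disjoint by construction: each PCP motif gets its own
compound with exactly one upstream and one downstream protein; each
reversed binding runs from a dedicated terminal into a distinct interior
hub, so it satisfies the dead-end heuristic and — because the hub keeps
another incoming edge — stops satisfying it once reversed; each group
gets dedicated members plus one incoming and one outgoing relation (the
incoming edge guarantees expanded members are never source-less, which
keeps the full correction idempotent); duplicated paralog entries place
one 3-gene name list at two positions, each fed by its own single-gene
neighbour.  Consequently detector output must equal the plant lists
exactly, not merely in count.

`make_expression_table()` plants per-tissue silent gene sets and shapes
values so the 25th nearest-rank percentile cleanly separates classes:
silent values lie in (0, 1), expressed values sit on a plateau at 10 up
to the percentile rank with the rest drawn above it.  This guarantees
separation under both percentile scopes provided each tissue's silent
fraction stays below 0.25, which the generator validates.
`make_ppi_table()` assigns each supported pair a score tier and a random
non-empty source subset, recording the pair set at or above every tier.

Each generator seeds a local RNG stream and restores the caller's state,
so fixtures are reproducible across platforms and do not perturb user
code.  What the fixtures deliberately do *not* emulate: realistic
expression distributions, score correlations, KEGG's drawing
conventions, or organism-specific topology.  Passing tests demonstrate
that the graph logic is exact on known ground truth; they say nothing
about the biological correctness of any particular KEGG release, which
is version-dependent by nature.

## Problem sizes and runtime choices

The test suite and the acceptance script run entirely on generated
fixtures: 100 round-trip pathways up to ~200 entries; correction
fixtures of ~30 entries planting (3, 7, 2) motifs; tissue scenarios over
20 seeds with 16-entry pathways; monotonicity sweeps of 5 thresholds ×
20 seeds on 12-entry pathways.  These sizes exercise every code path
(nesting, duplication, merging, collapse) while keeping the full suite
under half a minute; the algorithms themselves are polynomial in entries
× relations and handle real KEGG maps (tens to hundreds of entries)
comfortably.

## Known limitations

* Metabolic `<reaction>` chemistry is out of scope by design.
* Multi-organism and ko-reference pathways are not specially handled;
  the package targets single-organism maps.
* The reversed-binding heuristic is a topological proxy; it cannot see
  evidence outside the KGML file and is expected to be replaced where
  better ground truth exists.
* `fetch_kgml()` downloads single pathways only, consistent with the
  KEGG academic-use terms; no bulk retrieval is offered.
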