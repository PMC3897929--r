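---
title: "Methods: consistent entity sets, snapshot provenance and parent-child-union enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consistent entity sets, snapshot provenance and parent-child-union enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapsets)
```

## The set model and its assumptions

The unit of analysis is a species-bound entity set holding gene, transcript
and protein identifiers simultaneously. Two structural assumptions are built
in and enforced by the loaders:

* the hierarchy is functional upward — every protein has exactly one coding
  transcript and every transcript one gene — and functional downward from
  transcripts to proteins (at most one protein per transcript, so a
  transcript stands for its isoform);
* all members of a set belong to one species, and every member exists in
  that species' genome model.

On top of this the *transitive-consistency* rule is maintained after every
operation: membership of a protein implies membership of its transcript, and
membership of a transcript implies membership of its gene. The converse is
deliberately not implied — a gene can be studied without committing to any
isoform. Consistency is what lets one set carry information attached at
different biological levels (a disease association on the gene, an
interaction on the protein) without ever becoming self-contradictory.

Union and intersection take no level argument: acting element-wise on the
three id sets, they provably preserve consistency, and an element-wise
semantics is the only one that makes them commutative and associative at
every projection. Comparisons and set minus *are* level-parameterised,
because their meaning genuinely depends on the stratum of interest. Minus
cascades downward (removing a gene removes its member transcripts and their
proteins): the alternatives — refusing the removal, or keeping orphaned
transcripts — would either make gene-level curation impossible or violate
the consistency rule. Elements above the operating level are never touched,
so removing an isoform leaves its gene in place.

Cross-species operations are hard errors rather than silent coercions;
moving a set between species is an explicit, lossy, reported translation
(below). Identifier validation happens at mutation time, not lazily, so a
set can never hold an id its genome model does not know.

## Snapshots, history and the replay oracle

Analyses are organised as version trees: a container is bound to one species
and holds snapshots; a child snapshot starts as a deep copy of its parent,
so branches never write back. Snapshot removal is restricted to leaves —
with no reparenting rule that could be justified, leaf-only deletion is the
only choice that keeps the history replayable. Clearing a snapshot is an
ordinary logged action; recovery is by branching from an ancestor, not by
undo.

Every mutating operation appends exactly one history entry: actor, target,
action name, parameters, and a per-level delta summary. The entry records
the *operands' membership at call time* (for union/intersection/minus, the
other set's full three-level content). This is deliberate: if the entry only
named the operand snapshot, a later edit of that snapshot would silently
change what the entry means. With call-time operands, replaying a snapshot's
lineage — each ancestor's entries up to the point where the next child
branched off, then the snapshot's own — must reproduce its stored content
bit for bit, and this replay is used throughout the test suite as the
correctness oracle for the provenance layer.

Workspace persistence is a directory of human-diffable plain-text files
(containers and snapshot metadata as TSV, snapshot contents as level-sorted
id lists, history as an append-only TSV with JSON-encoded parameters,
collaboration state as JSON), written atomically via temp-file-and-rename.
Save → load → save is byte-identical; timestamps come from an injectable
clock so tests are reproducible.

## The parent-child-union test

For a study set of proteins, the per-term report gives (i) the description,
(ii) direct study annotations on the node, (iii) direct genome annotations,
(iv) study proteins in the node's subtree, (v) the study total at the
analysis level and (vi) a p-value. Counts use direct annotations where they
describe *this node* and true-path-propagated sets where they describe *the
subtree* — the propagated set of a term is the union of direct annotations
over the term and its descendants, traversing `is_a` and `part_of` edges by
default (configurable; other OBO relations are ignored with a warning at
load time).

The p-value conditions on the term's parents. The population for term $t$ is
$U_t = \bigcup_{q \in \mathrm{pa}(t)} \mathrm{prop}(q)$; with
$N_t = |U_t|$, $m_t = |\mathrm{prop}(t)|$ (a subset of $U_t$ by the
true-path rule), $n_t = |\mathrm{study} \cap U_t|$ and
$k_t = |\mathrm{study} \cap \mathrm{prop}(t)|$, the reported value is the
upper hypergeometric tail $P(X \ge k_t)$. Decisions taken where the
published description leaves room:

* **Root terms** have no parents; their population falls back to all
  annotated proteins of the species, i.e. the classic term-for-term test,
  which keeps the p-value defined everywhere.
* **Empty populations** ($N_t = 0$) give $p = 1$, as does $k_t = 0$
  (trivially, $P(X \ge 0) = 1$).
* **Unannotated study proteins** still count in the study total (v) but can
  never contribute hits — the universe is never silently shrunk to the
  annotated part of the study set.
* **Level.** The test counts proteins. Gene-level analysis maps each member
  gene to the union of its proteins' annotations (implemented as the
  downward closure of the gene projection), with the study total taken at
  gene level.
* **Multiple testing.** Raw p-values are the primary report; a
  Benjamini–Hochberg column is available behind `bh = TRUE`, off by
  default.
* **Determinism.** Results are sorted by p-value with ties broken by term
  id; identical inputs give bit-identical output.

The display tree renders the DAG as term browsers conventionally do: a term
with several retained parents is replicated once under each, and subtrees
without a single study match are pruned. Because propagated sets grow toward
the root, the retained set is ancestor-closed, so the number of copies of a
term equals the number of root-to-term paths — a property the tests check
against an independent memoized path count on random DAGs.

## Networks, pathways, associations, translation

Interaction-network expansion starts from the set's proteins. The default
neighbor semantics is the *union* of neighborhoods within a hop bound: in
the packaged worked example the expected node list contains a protein whose
only edge reaches a single seed, and omits an edgeless seed — both facts are
incompatible with an adjacent-to-all-seeds reading, which is nevertheless
retained as the explicit `mode = "all"` common-neighbor query (direct
neighbors only). Edgeless seeds are excluded from the network display but
never removed from the set. Interaction scores (0–1000, STRING-like) are
optional; no threshold is applied at load time, and an optional `min_score`
filter drops unscored edges when engaged, since their evidence cannot be
compared against the cutoff.

Pathway classification assigns each EC number of a pathway to exactly one of
`IN_SET` / `IN_GENOME_ONLY` / `ABSENT`. Pathway-side EC components may be
`-` wildcards, matching any value of that component; protein-side ECs are
taken literally.

Association tables (miRNA targets, disease genes, drug targets) key off
genes: the modules all resolve to genes in the end, and protein-level drug
targets are represented by their coding gene. Lookups are monotone in the
set by construction.

Orthology translation operates on the gene projection only — orthology is a
gene-level relation here, and translating isoforms through ortholog
transcripts would manufacture precision the data does not contain.
Many-to-many relations expand (every ortholog of every source gene is
included), unmapped genes are dropped from the result but listed in the
report, and the result lands in the target species as a genes-only set. For
a one-to-one orthology the translation is invertible on the mapped genes,
which the tests exercise as a round-trip identity.

## Collaboration model

Each user owns one implicit private pool of containers and stored analysis
results. Groups carry two authorization levels: NORMAL members read the
group pool, COORDINATORs additionally update it and manage membership; a
group always keeps at least one coordinator, and public groups are readable
by anyone. Publishing requires coordinator level — the published entry is an
immutable copy frozen at publish time, because the share-curate-republish
flow only makes sense with copies, not live references. Whether NORMAL
members may publish is not spelled out in the published description; it is
denied here, reading "only allowed to read the pool data" literally.
Users are plain workspace identities (`--as USER` on the command line);
authentication is a deployment concern outside the library.

## The synthetic bundle generator

The generator emulates the *relational structure* of a reference bundle:
a gene/transcript/protein hierarchy (geometric transcript counts, mean 1.5
per gene; 90 % of transcripts coding), a single-rooted acyclic GO DAG (40
terms, up to two parents drawn only from earlier-indexed terms — acyclic by
construction), direct annotations on 60 % of proteins, a sparse interaction
graph (3 % edge probability), orthology over 60 % of genes with occasional
fan-out, and small association/EC/pathway tables. These defaults are the
package's standing study conditions for property tests and calibration; a
strict one-to-one orthology mode exists for round-trip checks. One seeded
stream per file type means adding a file type never perturbs the others,
and the same spec and seed yield byte-identical files.

What the generator does **not** emulate: realistic coordinates or sequence
content, annotation evidence codes, correlated annotation patterns,
scale-free interaction topology, or database-scale sizes. Passing tests
therefore demonstrate the correctness of the algebra, propagation,
statistics and provenance — not performance or biological realism at
database scale. In the same spirit, the published use-case figures obtained
on 2013-era database snapshots (neighbor counts, target counts, specific
p-values) are not reproducible from synthetic data and are out of scope for
the checks; the packaged two-species worked example is the exact
reproducible scenario instead.

## Problem sizes and numerical checks

The test suite fixes its problem sizes as a design choice: exhaustive
hypergeometric enumeration on populations up to 12 (over 100 random
instances, agreement within 1e-12); null calibration with 10,000 uniform
study sets on the seeded default bundle, asserting the per-term rejection
rate at α ∈ {0.01, 0.05} stays below α plus three binomial standard errors
(the discrete test is conservative, so the observed rates sit well below
nominal); 1,000 random action sequences for transitivity and replay
fuzzing; 200 random DAGs for the display-tree law; 500 random one-to-one
orthologies for the round-trip identity. `scripts/acceptance.R` re-runs the
same computations at comparable sizes and reports the measured quantities.

## Known limitations

* Single-process workspaces: no concurrent write access, no merge of
  divergent snapshots (union/intersection of their contents is the intended
  mechanism).
* Identifier namespaces are taken as-is; accession conversion between
  naming systems is another tool's job.
* The OBO reader covers the subset of OBO 1.2 needed here (`is_a`,
  `part_of`, obsolescence); GAF parsing uses the object id, qualifier and
  GO id columns and skips NOT-qualified rows.
* Entity ids must be unique across a bundle, which is what lets files
  without a species column (GAF, interactions, associations, EC) resolve
  through the genome models.
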