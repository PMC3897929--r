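# snapsets

Versioned, species-bound gene/transcript/protein set analysis for
explorative biology.

Most enrichment tools take one frozen gene list and annotate it. Explorative
work looks different: a biologist starts from three disease genes, pulls in
their interaction partners, checks which of those are drug targets, keeps a
promising subset, translates it into a model organism — and needs to be able
to walk back to any earlier state of that analysis. `snapsets` provides the
data structures and operations for that workflow as an R library plus a thin
`isc` command line: entity sets under a transitive-consistency rule,
container/snapshot version trees with a replayable history, GO term
enrichment with the parent–child-union hypergeometric test,
interaction-network expansion, pathway/EC classification, miRNA/disease/drug
lookups, orthology-based cross-species translation, and group pools for
sharing sets and results between users.

Everything runs against a *reference bundle* — a directory of documented
plain-text files (genome model TSV, OBO ontology, GAF annotations,
interaction/orthology/association TSVs) — and the package ships a
deterministic generator for complete synthetic bundles, so every module is
usable and testable offline.

## The core model

An **entity set** `S` is bound to one species and may contain genes,
transcripts and proteins. It is kept *transitively consistent* at all times:

```
p ∈ S  ⇒  t(p) ∈ S        (a member protein forces its transcript in)
t ∈ S  ⇒  g(t) ∈ S        (a member transcript forces its gene in)
```

where `t(p)` is the transcript coding for protein `p` and `g(t)` the gene of
transcript `t`. The reverse is never implied: adding a gene adds nothing
below it, so isoform-level information stays isoform-specific. Comparisons
(`=`, `⊆`, `⊂`) and set minus operate on a chosen *level* (gene, transcript
or protein) via projection; union and intersection act element-wise and
preserve consistency automatically. Snapshots of sets live in version trees
inside species-bound containers, and every mutating action appends one entry
to a history whose replay reconstructs any snapshot exactly.

GO enrichment reports, for every term with a study hit in its subtree, the
six classic per-node numbers, with the p-value from the
**parent–child-union** hypergeometric test: for term `t` with parents
`pa(t)`, the population is `U_t = ⋃_{q ∈ pa(t)} prop(q)` (propagated
annotation sets; all annotated proteins for a root), and with
`N_t = |U_t|`, `m_t = |prop(t)|`, `n_t = |study ∩ U_t|`, `k_t = |study ∩
prop(t)|`,

```
p(t) = P(X ≥ k_t),   X ~ Hypergeometric(N_t, m_t, n_t)
```

— i.e. each term is judged against what its parents already explain, which
damps the cascade of trivially significant ancestors produced by
term-for-term testing.

## A worked example

The packaged two-species bundle (species A: genes `g1..g5`, seven
transcripts/proteins; species B: `g6..g9`; three interaction edges; orthology
`g1↔g6`, `g2↔g7`) ships with a replay script covering a full explorative
session:

```r
library(snapsets)

dir    <- figure1_bundle(tempfile())
bundle <- load_bundle(dir)
ws     <- workspace(bundle)
al     <- replay_script(ws, file.path(dir, "figure1.replay"))
```

The script uploads `g1,g2,g3` into snapshot `a`, branches `b` and `c`,
adds proteins `p1_1`,`p4_1` and transcripts `t1_2`,`t2_1` to `b` and removes
`g3`; extends `c`; expands `d` by the interaction network of `c`; and
translates across species into `e`, `f`, `g`. Snapshot `b` shows the
transitive rule at work — the two added proteins dragged in `t1_1`, `t4_1`
and `g4`:

```r
snapshot_content(ws, al[["b"]])
#> <entity_set> species A: 3 genes, 4 transcripts, 2 proteins
es_project(snapshot_content(ws, al[["b"]]), "transcript")
#> [1] "t1_1" "t1_2" "t2_1" "t4_1"
```

The network step finds exactly the six proteins reachable from `c`'s
members (`p2_1` has no interactions and is not displayed):

```r
interaction_network(snapshot_content(ws, al[["c"]]), bundle)$nodes
#> # A tibble: 6 × 3
#>   protein_id role   hops
#> 1 p1_1       seed      0
#> 2 p1_2       seed      0
#> 3 p3_1       seed      0
#> 4 p4_1       added     1
#> 5 p5_1       added     1
#> 6 p5_2       added     1
```

Cross-species translation is gene-level and reports its losses:

```r
tidy(translate_set(snapshot_content(ws, al[["d"]]), "B", bundle))
#> # A tibble: 5 × 2
#>   source_gene target_gene
#> 1 g1          g6
#> 2 g2          g7
#> 3 g3          NA
#> 4 g4          NA
#> 5 g5          NA
```

and the container's version tree keeps the whole session inspectable:

```r
snapshot_tree(ws, al[["I"]])
#> # A tibble: 5 × 6
#>   id    parent label n_genes n_transcripts n_proteins
#> 1 S1    <NA>   a           3             0          0
#> 2 S2    S1     b           3             4          2
#> 3 S3    S1     c           3             4          4
#> 4 S4    S3     d           5             7          7
#> 5 S7    <NA>   g           1             0          0
```

The same session is available from a shell:

```sh
inst/cli/isc workspace init --bundle DIR --workspace WS
inst/cli/isc replay --script DIR/figure1.replay --workspace WS
inst/cli/isc set show --snapshot b --level gene --workspace WS
```

with exit codes `0` (ok), `2` (unknown id), `3` (authorization), `4`
(validation).

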