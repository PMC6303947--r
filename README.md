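# subfamkit

Classification of an enzyme family into evolutionary subfamilies, built for
families like the D-2-hydroxyacid dehydrogenases (2HADHs): NAD(P)(H)-dependent
oxidoreductases whose broad and overlapping substrate ranges make annotation
by nearest-neighbour transfer unreliable. The package targets the analyst who
has a curated seed alignment, a sequence database, optionally externally
computed phylogenies, curated kinetics and structure spreadsheets — and wants
a reproducible, testable path from those inputs to a subfamily partition and
a queryable knowledgebase.

## The core inference

A **subfamily** is a group of proteins that appears as a *supported clade
consistently in every input tree*:

* On each unrooted tree, every internal edge with support s > 0.5 induces a
  bipartition; both sides are candidate leaf sets (singletons excluded).
* A candidate survives iff the identical leaf set is emitted by **all**
  trees; its provenance records min support across trees.
* Surviving candidates are selected greedily by decreasing size (ties to the
  lexicographically smallest member), skipping candidates that overlap an
  already selected subfamily or exceed half of all leaves (a cap on
  near-root bipartitions standing in for manual curation).
* Everything else — including single long branches — is left UNASSIGNED.

Around this core, the package provides the standard stages end to end:
exact Needleman–Wunsch/Smith–Waterman affine-gap alignment with
Karlin–Altschul statistics (E = K·m·n·e^(−λS)) for homolog collection
(E < 10⁻³, query coverage ≥ 90%), seed-anchored profile extension,
gap-fraction trimming (columns with gaps in ≥ 80% of rows), Poisson-corrected
distances d = −ln(1 − p) under pairwise deletion, neighbor-joining with
column-bootstrap supports, per-column conservation and subfamily logo
matrices, cofactor-specificity fingerprints (βB–αD aspartate → NAD(H);
`[ST]R[ST]X[RK]` → NADP(H)), catalytic-triad checks (Arg230/Glu259/His277 in
Q92LZ4_RHIME numbering), 5 Å heavy-atom active-site contact maps,
complex-state classification (apo / binary / ternary / true ternary by
matched redox states), and kcat/KM aggregation with best-substrate medians.

A synthetic-family simulator plants a known subfamily structure (star of
divergent stems, shallow within-subfamily trees, invariant catalytic columns,
subfamily-diagnostic fingerprint columns), plus toy kinetics tables and toy
active-site complexes, so that every stage is verified against ground truth
without any external download.

## Worked example

```r
library(subfamkit)

fam <- simulate_family(family_spec(n_subfamilies = 3, leaves_per_subfamily = 4,
                                   length = 300, seed = 1), n_replicates = 3)
trees <- lapply(1:3, function(k) {
  a <- fam$alignments[[k]]
  bootstrap_supports(a, nj_tree(distance_matrix(a)), n = 100, seed = 1 + k)
})
part <- consensus_subfamilies(trees)
part
#> <subfamily partition: 12 leaves, 3 subfamilies, 0 unassigned>
#> # A tibble: 3 × 3
#>   subfamily  size min_support
#>   <chr>     <int>       <dbl>
#> 1 SF1           4           1
#> 2 SF2           4           1
#> 3 SF3           4           1
```

All three planted subfamilies are recovered as clades with bootstrap support
1.0 in every tree; nothing is left unassigned. Kinetics aggregation on a
simulated table in the curated schema:

```r
kin <- simulate_kinetics(fam$truth, seed = 1)
glance(family_summary(kin))
#> # A tibble: 1 × 6
#>   median_best_efficiency median_best_km_uM n_pairs_with_efficiency ...
#> 1                159465.              590.                      24
```

`median_best_efficiency` is the family median kcat/KM over each enzyme's
best substrate (here ≈ 1.6 × 10⁵ M⁻¹s⁻¹ around the generator's planted
1.45 × 10⁵), and `median_best_km_uM` the corresponding median Michaelis
constant (planted 600 μM). Classifying a held-out sequence:

```r
assign_query(fam$sequences$seq[5], fam$alignment, part)
#> # A tibble: 1 × 5
#>   subfamily best_hit identity    evalue score
#> 1 SF2       SF2_02        100 3.54e-195  1717
```

`run_pipeline(pipeline_config(...))` chains the stages on files and writes
the partition, annotations, kinetics summaries and a `knowledgebase.json`
bundle; `inst/exec/subfamkit` is a thin command-line wrapper over the same
functions.

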