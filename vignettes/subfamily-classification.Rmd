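---
title: "Consensus-clade subfamily classification: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-clade subfamily classification: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(subfamkit)
```

This vignette is the package's own account of the science it implements: the
model behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic generator does and does not emulate, the
numerical choices, and the known limitations. Every number shown here is
computed by the code in this document or by the test suite; nothing is
quoted from elsewhere.

## The problem

Enzyme families such as the D-2-hydroxyacid dehydrogenases combine deep
divergence (pairwise identities below 25% between subfamilies) with broad,
overlapping substrate ranges. Transfer of a function annotation from the
nearest characterized homolog is then unreliable; the useful unit of
annotation is the *subfamily*: a clade that is robust both to resampling
noise (bootstrap support) and to the choice of inference method or data
realization (consistency across independently built trees). The package
operationalizes exactly that definition and surrounds it with the standard
stages needed to get from sequences, coordinates and kinetics spreadsheets
to a per-protein annotation bundle.

## Pairwise alignment and homolog collection

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment are computed
exactly by an affine-gap dynamic program (Rcpp). A gap of length $k$ costs
$g_o + (k-1)\,g_e$ — the first gapped residue pays the opening penalty — a
convention chosen so that a single-residue gap costs exactly $g_o$.
Traceback ties are broken deterministically (diagonal, then gap in the
second sequence, then gap in the first), so outputs are reproducible.
Defaults: BLOSUM62 (from Biostrings), $g_o = 10$, $g_e = 0.5$.

Local-alignment significance uses the Karlin–Altschul expectation
$E = K m n e^{-\lambda S}$ with the conventional gapped BLOSUM62 constants
$\lambda = 0.267$ nats per score unit and $K = 0.041$; both are fields of
the scoring scheme and can be recalibrated. Homolog collection keeps a
database sequence iff some query reaches $E < 10^{-3}$ *and* the aligned
span covers at least 90% of the query. Coverage is measured on the local
alignment span of the query, which is the natural reading when queries are
trimmed to their catalytic domains.

Percent identity is reported as identities over *all* alignment columns
(terminal gaps included), to 0.1%. Published identity figures rarely state
their denominator; the two common alternatives (shorter-sequence length and
ungapped columns) are exposed as a `denominator` argument so a reader can
reproduce any of the three conventions.

## Seed-anchored extension and trimming

New sequences are aligned one at a time to the fixed seed profile. The
score of placing residue $r$ in seed column $j$ is the mean substitution
score of $r$ against the column's residues, with gap rows contributing
$-g_e$. Insertions relative to the seed are *dropped* (and logged) rather
than opening new columns: the extension is length-preserving, which keeps
reference numbering and region definitions stable across the pipeline. The
cost is that lineage-specific insertions are invisible downstream — an
acceptable trade for a classification built on the conserved core, and the
reason the seed alignment itself is an input rather than something the
package computes.

Trimming removes a column when its gap fraction is **at least** 0.8. The
boundary is inclusive by design, matching a removal rule phrased as "gaps
in at least 80% of sequences", and is asserted by a dedicated boundary
test. Trimming is idempotent and never reorders rows.

## Conservation, logos, reference numbering

Column conservation reports the modal residue and its frequency with *all*
rows in the denominator, so gaps count against conservation; a "non-gap
rows only" mode exists because published conservation percentages are
ambiguous on this point. "Highly conserved" everywhere in the package means
*strictly greater than* 0.9. Information content is
$\log_2 20 - H(\text{residue frequencies over non-gap rows})$ bits, with no
small-sample correction (subfamily sizes vary over two orders of
magnitude; a correction is a constructor option, off by default).

Logo export includes a column iff at least one subfamily has a non-gap
fraction of at least 0.9 in it, i.e. at least 90% of that subfamily's
members possess an amino acid there; frequencies are normalized per
included column within each subfamily (they sum to 1 to machine
precision).

Reference numbering maps alignment columns to residue numbers of a chosen
reference row (the k-th non-gap reference column is residue k). Active-site
positions throughout the package are stated in the numbering of the GHRB
representative Q92LZ4_RHIME (PDB 5v7n): catalytic triad Arg230, Glu259,
His277; substrate-positioning main-chain amides Val72/Gly73; structural
sites Asp195, Asn227, Gly229, Gly231; pyrophosphate-binding GXXGXGXXG at
146–154. The packaged region boundary file (`inst/extdata/regions.csv`) is
a curator-style approximation anchored on those residues — region *names*
are well defined, their exact limits are configuration, and every test that
exercises region logic supplies an explicit synthetic region table.

## Distances, neighbor joining, bootstrap

Distances use pairwise deletion ($p$ = mismatches over columns where both
rows are non-gapped) with the Poisson correction $d = -\ln(1-p)$ as the
default model. The correction diverges as $p \to 1$; pairs with
$p \ge 0.99$ are an *error* by default, with an explicit opt-in clamp to
$d = 5$ substitutions/site. Silent clamping would hide saturation from the
user, and a saturated pair is usually a sign the input should be split.

Neighbor joining follows the classic Q-criterion agglomeration. Ties in Q
are broken by the lexicographically smallest pair of cluster labels (a
cluster is labelled by its smallest leaf), making the output deterministic;
negative branch-length estimates are clamped to zero with the total deficit
recorded on the tree. On additive matrices NJ provably recovers the
generating tree; the tests assert exact recovery (topology, and path
distances to 1e-9) on random 4–7-taxon additive matrices and cross-check
the topology against an exhaustive least-squares oracle over all unrooted
candidate topologies.

Bootstrap supports resample alignment columns with replacement (same
length), rebuild distance + NJ per replicate, and score each internal edge
of the reference tree by the fraction of replicates containing the same
unrooted bipartition. Replicates that produce a saturated pair are skipped
and counted; more than 20% skipped aborts the run. A single integer seed
makes the procedure exactly reproducible. An alignment of identical
sequences yields a star tree and supports are reported absent rather than
invented.

## Consensus subfamilies

Candidate subfamilies are leaf sets emitted as a supported bipartition side
(support strictly greater than 0.5 — an edge at exactly the threshold does
not count) by *every* input tree. "Appears consistently as a clade" is read
strictly as bipartition equality on unrooted trees, not topological
compatibility; a majority-of-trees relaxation would be easy to add but is
deliberately not the default, because the strict reading is what makes the
partition conservative. Selection is greedy by decreasing size with ties to
the lexicographically smallest member, skipping overlaps and any candidate
larger than half the leaf set. The cap exists because the complement of
every consistent clade is itself a consistent candidate: without a cap the
near-root side of a deep bipartition would absorb most of the family. Leaves
in no selected candidate — including single long branches — are
UNASSIGNED. The open design question here is how nested consistently
supported clades should resolve in general; greedy-by-size maximality is
this package's explicit, documented choice, not a claim about how any
published classification was curated.

With externally computed trees the same machinery checks a published
classification: import the Newick files with `read_newick()` (supports in
either the 0–1 or percentage dialect are normalized on read), prune all
trees to a common leaf set if necessary, and ask whether each curated
member list appears among the consistently supported candidates —
`supported_clades()` per tree, or directly `consensus_subfamilies()` with a
`names_map` to label recovered clades with their curated names.

## Structure analysis

Ligand classification splits HETATM residues into cofactors (default codes
NAD/NAI/NAJ for NAD(H) and NAP/NDP/TAP for NADP(H)), excluded compounds
(waters and common crystallization-cocktail species: SO4, PO4, GOL, EDO and
monoatomic ions), and candidate substrates (everything else). Contacts use
heavy atoms only (crystal structures at typical resolution rarely have
reliable hydrogens) with an inclusive Euclidean cutoff, default 5.0 Å, on
deposited coordinates — no symmetry expansion, which is a documented
limitation for contacts contributed by symmetry mates rather than the
deposited dimer partner. Contact sets are invariant under rigid-body motion
and monotone in the radius (both property-tested). Complex states follow
the redox-pairing rule: a ternary complex is *true* only when cofactor and
substrate redox states match (reduced with reduced, oxidized with
oxidized); unknown codes yield "redox unknown", never a silent true
ternary.

## Kinetics aggregation

Efficiency is kcat/KM in M⁻¹s⁻¹ with KM carried in μM; the missing member
of {kcat, KM, kcat/KM} is derived from the other two, and triples
inconsistent by more than 5% are flagged while keeping the reported value
(the reported efficiency is usually the directly fitted quantity).
Duplicate enzyme–substrate–cofactor measurements are reconciled to the
highest-efficiency row, logged. Best substrate per enzyme is the maximal
efficiency with ties broken by smaller KM then alphabetically; family and
per-subfamily medians are taken over best-flagged records (median of an
even-sized set is the mean of the central pair). "Accepted compound" counts
any substrate row, with or without numeric constants, which is a broader
set than "pairs with determined efficiency" — both counts are reported.

## The synthetic generator

`simulate_family()` plants: a star of subfamily stems (default 6
subfamilies × 8 leaves), each stem 0.8 substitutions/site long and carrying
a random binary subtree whose edges are all 0.05 substitutions/site;
sequences of 300 columns evolved site-wise under the 20-state symmetric
process (per-branch change probability
$\frac{19}{20}\bigl(1 - e^{-\frac{20}{19}t}\bigr)$, replacement uniform
over the 19 alternatives — the exact aggregated form of a Poisson event
process, so closed-form expectations exist for tests); four invariant
"catalytic" columns; and per-subfamily fingerprint injections (aspartate at
column 103 for odd subfamilies, the NADPH motif instance `SRSAR` at
101–105 for even ones), written at each subfamily root and held fixed below
it — fingerprints are diagnostic by construction, which is what lets the
cofactor-annotation test demand 100% accuracy. Defaults were chosen once as
a realistic strongly-separated family: stems near saturation (between-
subfamily p-distance ≈ 0.8) against shallow within-subfamily divergence,
the regime the consensus method is designed for. The default synthetic
kinetics law centres each subfamily's best substrate log-normally around a
family median efficiency of 1.45 × 10⁵ M⁻¹s⁻¹ with median KM 600 μM —
magnitudes typical of a moderately efficient dehydrogenase family.

What the generator does *not* emulate: insertions and deletions (the truth
alignment is the identity; a gap-injection mode exists solely to exercise
trimming), rate heterogeneity across sites or lineages, non-uniform
exchangeabilities (no JTT/WAG), compositional bias, and recombination or
transfer. Passing tests therefore demonstrate correctness of the
*inference machinery* under a clean model, not robustness to every
pathology of real alignments — which is also why externally computed
maximum-likelihood trees can be imported instead of inferred.

One generator design point deserves emphasis. The recovery property runs
consensus over three *independent sequence realizations* evolved along the
same planted tree (`n_replicates = 3`), not over three reseedings of the
bootstrap on a single alignment. Bootstrap supports converge to a function
of the alignment, so reseeded sets are almost perfectly correlated and
consensus over them adds no information; with a star-true tree the
arbitrary resolution of the root polytomy then reaches support 0.5–0.7
reproducibly, merging subfamilies no matter how many reseeded sets are
intersected. Independent realizations decorrelate that noise — which is
precisely the role that inferring trees from different methods and data
plays in a real analysis.

```{r recovery, eval = FALSE}
# the headline recovery check (~25 s; run by tests and scripts/acceptance.R)
fam <- simulate_family(family_spec(), n_replicates = 3)
trees <- lapply(1:3, function(k) {
  a <- fam$alignments[[k]]
  bootstrap_supports(a, nj_tree(distance_matrix(a)), n = 100,
                     seed = fam$spec$seed + k)
})
part <- consensus_subfamilies(trees)
glance(part)
```

## Numerical choices and degenerate inputs

* Alignment traceback uses an absolute tolerance of 1e-9 when matching
  predecessor states; scores themselves are exact sums of matrix entries.
* NJ branch lengths are written with 15 significant digits, preserving the
  1e-9 recovery guarantee through the Newick representation.
* Newick supports: numeric internal labels are supports; values in
  (1, 100] are read as percentages and divided by 100; non-numeric labels
  are clade names. Missing branch lengths parse as 0.
* Altloc resolution keeps the highest occupancy, ties to the
  alphabetically first altloc id; only the first model of a multi-model
  file is read.
* A fully gapped conservation column reports frequency 0 and undefined
  information; an all-zero distance matrix yields a star tree; an
  all-gap-trimmed alignment is an error rather than an empty object.
* Problem sizes in the default test and acceptance runs — 48 leaves × 300
  columns with 100 bootstrap replicates per tree set, 100 additive
  matrices, 500 aligner oracle pairs of length ≤ 12, 100 synthetic
  complexes — were chosen as the smallest sizes at which every stage is
  exercised with comfortable statistical margins.

## Limitations

* Maximum-likelihood inference, JTT/WAG-corrected distances and SH-like
  supports are out of scope; such trees are imported via Newick.
* Heuristic database search (indexing, seeding) is not implemented; the
  exact local aligner is quadratic and intended for curated databases of
  hundreds, not millions, of sequences.
* Region boundaries and the βB–αD key position are configuration with
  approximate defaults, not ground truth.
* No crystallographic symmetry expansion; other-subunit contacts are
  detected only within the deposited coordinates.
* The consensus definition requires identical leaf sets across trees;
  trees over different taxon samples must be pruned to their intersection
  by the caller.
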