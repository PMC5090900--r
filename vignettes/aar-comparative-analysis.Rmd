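---
title: "Comparative analysis of acyl-ACP reductases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of acyl-ACP reductases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aartools)
```

## The analysis problem

Cyanobacterial acyl-ACP reductases (AARs) reduce C16/C18 fatty acyl-ACP or
acyl-CoA to fatty aldehydes, which aldehyde-deformylating oxygenase (ADO)
converts to alkanes and alkenes. AAR orthologs differ widely in catalytic
activity, solubility when heterologously expressed, and substrate
chain-length preference, and those differences track the phylogeny and the
habitat (marine versus freshwater) of the host strain. `aartools`
implements the computational side of a comparative AAR screen:

1. **Sequence relatedness.** Pairwise percent identity from affine-gap
   global alignments (or directly from an input MSA), transformed to
   distances, a neighbor-joining tree, clade groups, and per-group habitat
   composition.
2. **Enzyme properties.** From hydrocarbon quantification (GC–MS) and
   western-blot densitometry tables: a soluble-protein-normalized activity
   index, percent solubility, relative expression, and product-spectrum
   specificity fractions, all with replicate statistics.
3. **Sequence determinants.** Property-versus-identity correlations with a
   leave-one-out check, and an alignment-column scan that nominates
   candidate activity and specificity residues as single-substitution
   proposals (`Q15R` style).
4. **Synthetic data.** A generator for sequence families with planted
   diagnostic columns and for noisy measurement tables, giving every stage
   a recovery test with known ground truth.

## Quantities and conventions

### Percent identity

Identity between two aligned sequences is
`100 * matches / columns where neither sequence has a gap`. The
denominator convention is not universal; excluding gap columns is the
standard choice for protein ortholog comparisons and is applied uniformly
to pairwise alignments and MSA columns, so the two routes agree exactly
when the MSA is the concatenation of a pairwise alignment. The ambiguity
code `X` never counts as a match, even against another `X`.

Pairwise alignments are global (end gaps penalized) affine-gap
Needleman–Wunsch under BLOSUM62 with gap open 11 / extend 1 — the familiar
protein-BLAST parameterization. End-gap penalization is appropriate here
because AAR orthologs are near-full-length homologs; the scheme
(`scoring_scheme()`) is configurable. The dynamic program is delegated to
`Biostrings::pairwiseAlignment()`; the test suite verifies its scores
against exhaustive enumeration of all monotone alignments for every short
sequence pair over a reduced alphabet, so the package's identity values
rest on an independently checked primitive.

### Distances, tree, and groups

Distance is the linear transform `d = 100 - identity`, a p-distance on the
percent scale. No multiple-hit correction is applied by default because
the tree is used for grouping closely related orthologs, not for
divergence dating; a Poisson correction (`-100 log(identity/100)`) is
available.

Neighbor joining follows the standard Saitou–Nei agglomeration. Ties in
the Q-criterion are broken by the first pair in row-major order, so output
is deterministic. Negative branch lengths, which NJ can produce on
non-additive input, are clamped to zero after length assignment — a
presentation choice matching common tree viewers; topology is unaffected.
On additive matrices the implementation provably recovers the generating
topology and path lengths, and the tests confirm this on random 4–8 taxon
trees plus the closed-form three-taxon solution.

Clade groups are an explicit operationalization of "the k visually
separate groups": cut the k−1 longest internal edges (ties by edge index)
and read off the leaf partition. Published AAR trees delimit their groups
by eye; longest-edge cutting is a reproducible stand-in, not a claim about
how any particular figure was drawn, which is why group membership of
specific strains is never asserted. When k−1 exceeds the number of
internal edges the longest pendant edges are cut next, and cuts that no
longer split the leaf set (possible once neighboring edges are gone) are
skipped, so any k up to the leaf count yields exactly k groups.

Habitat composition is counted per group over the four labels
`marine / freshwater / both / unknown`. Fractions are taken over leaves
with a known habitat; `both` is always its own category and can optionally
be excluded from the fraction denominator when a strict marine-versus-
freshwater contrast is wanted.

### Activity, solubility, expression

The in vivo activity index of a variant is

```
activity_index = mean(total hydrocarbons per replicate) / mean(soluble band volume)
```

reported relative to a reference enzyme. Normalizing by the *soluble*
enzyme amount is essential: a highly expressed but aggregation-prone
ortholog can out-produce a more active, poorly soluble one in raw titer.
The index is unit-free — rescaling all GC–MS amounts or all densitometry
volumes by any constant cancels — so arbitrary instrument units are fine
as long as they are consistent within a table.

Replicate aggregation forms **ratios of means**, not means of ratios;
this matches normalizing pooled quantities and avoids small-denominator
bias. Standard errors are first-order (delta-method) propagations of the
replicate standard errors of the means:
`SE(a/b)/(a/b) = sqrt((SE_a/a)^2 + (SE_b/b)^2)`, combined across the
variant and reference indices. The reference variant itself is reported
as exactly 1 with SE 0 — it is the unit of the scale, not an estimate.
Whether published error bars on such ratios include the reference's own
uncertainty is rarely stated; the convention here is explicit and tested.

Solubility is `100 * S / (S + P)` from the supernatant and pellet band
volumes. Specificity fractions divide each analyte's mean amount by the
mean total, so the triple sums to 1 exactly; their SEs are the replicate
scatter (SD/sqrt(n)) of per-replicate fractions, a descriptive choice
since a delta-method SE of a composition adds little at n = 3.

A band below the blot detection limit makes activity and solubility
**"not determined"** (`NA`), never zero or infinite — low-expression
orthologs genuinely occur and must not be ranked as inactive. A
non-detected *reference* is a configuration error. An optional
`ado_soluble` covariate column is checked for near-constancy across
cultures (warning above CV 0.25, the point where "the coupling enzyme was
constant" stops being credible); it is deliberately never used in
normalization.

### Residue scan

Two column criteria, evaluated per alignment column against a designated
in-group:

* **strict** (candidate activity determinants): all in-group rows carry
  one identical non-gap residue, and at most `max_outgroup_matches`
  out-group rows carry it. The default tolerance is 0 because every
  useful mutation proposal replaces a residue the target does not already
  have; the tolerance is configurable since the verbal criterion
  "not conserved outside" is looser. A fully conserved column is
  therefore never reported.
* **similarity** (candidate specificity determinants): all in-group
  residues fall within one similarity class while the out-group residues
  do not all fall in that class. Classes default to the Clustal "strong
  groups" (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW) — the `:`
  marks of Clustal output. Identical in-group residues count only if the
  residue belongs to some class; an invariant column of a residue outside
  every class (e.g. P or G) is the strict criterion's business, not a
  "similarity" signal.

Gaps in any in-group row disqualify a column; out-group gaps count as
non-matching residues; `X` matches nothing. Positions are reported in
reference numbering — 1-based coordinates of the ungapped reference
sequence with the initiator Met as residue 1. (Expression constructs
often insert an extra Gly after Met for cloning reasons; such construct
artifacts are *not* counted, so reported positions match the native
deposited sequence.) Columns that are gaps in the reference are still
scanned but flagged unnumberable and excluded from mutation labels.

Mutation proposals take the in-group consensus (most frequent residue,
ties to the earlier row) and emit `<wild-type><ref-position><consensus>`
labels plus `target_label` variant ids compatible with the measurement
tables. Positions where the target already matches consensus are skipped;
target gaps produce a warning record instead of a label.

### Correlations and the leverage check

`pearson()` is a validated product-moment correlation (n ≥ 3, nonzero
variance). The leave-one-out check recomputes the correlation without a
named point; its purpose is to expose correlations manufactured by a
single high-leverage observation — typically the reference enzyme itself,
which sits at identity 100 with the largest property value. For that
reason `property_identity_table()` excludes the reference's self-identity
point by default (configurable). No p-values are attached by default; a
seeded permutation p-value is available. `leverage_fixture()` builds the
canonical demonstration: ten points whose property is an exactly
symmetric function of identity (sample correlation exactly 0 by
construction) plus one leverage point, giving r ≈ 0.88 that collapses to
0 when the point is dropped.

## The synthetic-data generator

`generate_family()` draws a root sequence uniformly over the 20 canonical
residues, derives each family member by independent per-site background
substitutions (default probability 0.05, enough to scatter spurious
near-diagnostic columns without erasing family resemblance), then
overwrites the planted positions: the in-group residue in in-group rows, a
draw from a disjoint out-group set elsewhere. Defaults mirror the
AAR study scale: length 341, a 2-member high-activity in-group versus a
6-member out-group, 11 planted positions. Because planting happens after
background mutation, strict-scan recall is 1 by construction at any
background rate, while precision 1 is guaranteed only at background 0 —
exactly the properties the tests assert.

`generate_measurements()` models band volumes and hydrocarbon amounts as
truth × unit-mean lognormal noise (both are positive intensity
measurements, for which multiplicative error is the natural model),
parameterized by a CV (default 0.1, typical densitometry/GC–MS replicate
scatter). Per replicate: soluble volume = expression × solubility ×
noise; insoluble = expression × (1 − solubility) × noise; total
hydrocarbons = activity × expression × solubility × noise, split across
C15:0 / C17:1 / C17:0 by a Dirichlet draw around the variant's
habitat-specific mean. The habitat means default to (0.75, 0.20, 0.05)
for marine-like enzymes — a predominantly C16-substrate profile — and
(0.15, 0.77, 0.08) for freshwater-like ones, where pentadecane is about
20% of heptadecene; these encode the marine-C16 / freshwater-C18
dichotomy as a tunable effect. The Dirichlet concentration defaults to
100, giving replicate fraction scatter of a few percentage points,
comparable to published error bars. Variants flagged below detection emit
`soluble_detected = FALSE` rows, exercising the not-determined path.

What the generator does **not** emulate: indels and rate heterogeneity
(no realistic evolutionary model — a gap-injection option exists solely
to exercise gap handling), phylogenetic correlation among family members
beyond shared descent from one root, correlated noise across replicates
or between the hydrocarbon and blot tables, and detector saturation.
Passing recovery tests therefore demonstrate correctness of the
*computations*, not robustness to every pathology of real blots and
chromatograms.

## Numerical choices and problem sizes

* Identity values are kept at full precision internally; report files are
  written with 6 significant digits. Tests always compare numerically
  with explicit tolerances, never via string equality.
* NJ tie-breaks (row-major first minimal pair) and clade-cut tie-breaks
  (edge index) are deterministic, so identical inputs give byte-identical
  outputs; the pipeline asserts this by rerunning itself.
* All stochastic stages draw from a single seeded stream per run; the
  seed is recorded in the pipeline log.
* The validation suite runs at deliberately desk-sized scales chosen to
  finish in seconds while still being exhaustive where exhaustiveness is
  the point: all 115,600 sequence pairs of length ≤ 4 over a 4-letter
  alphabet for the alignment oracle; 200 random additive matrices of 4–8
  taxa for NJ; one 341-residue 8-sequence family for the scan; 200
  simulated variants × 3 replicates at CV 0.1 for the quantification
  error bound (median absolute relative activity error ≤ 15%, typically
  ~6%).

## Known limitations

* Identity-based p-distances underestimate divergence at low identity;
  for families below ~40% identity use the Poisson option or a proper
  substitution model (outside this package's scope).
* Longest-edge clade cutting can differ from by-eye groupings on trees
  without clear long internal edges; inspect `tree.nwk` before trusting
  `groups.tsv` boundaries.
* The strict scan's default zero-tolerance for out-group matches
  over-calls or under-calls relative to a looser "not conserved" reading;
  `max_outgroup_matches` exposes the knob.
* SEs are first-order propagations; with n = 3 replicates they are
  themselves noisy, and no distributional claims (confidence intervals,
  tests) are attached to them.
* The activity index assumes product formation is rate-limited by the
  soluble enzyme amount. When a downstream coupling enzyme saturates, the
  index compresses at the top of the scale; diagnosing that requires
  expression-titration experiments, which are inputs here, not outputs.
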