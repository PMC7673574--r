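---
title: "Methods: barcode-gap, richness and monophyly analysis of floristic surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-gap, richness and monophyly analysis of floristic surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pteridosurvey)
```

This vignette is the package's account of its methods: what each stage
computes, which assumptions it makes, why the defaults are what they are,
and where design was genuinely open, which choice we made and why.

## The analysis problem

A molecular floristic survey yields three artifacts: a pre-aligned matrix
of one barcode marker (one row per specimen), a checklist mapping specimens
to terminal taxa with their attributes (rank, genus, family, growth habits,
native status, flora label), and a taxon-by-sampling-unit incidence table
(here, collection days). The package evaluates the barcode's discriminatory
power, the survey's completeness, and the coherence of its species, plus
the conventional checklist tallies.

The scoring unit throughout is the *terminal taxon* — species or
infraspecific terminal — because survey checklists count varieties as
distinct terminals; species-level counts (varieties collapsed) are reported
alongside where tables conventionally use them. One consequence worth
knowing: in survey tables the major-clade split is tallied at species level
while percentages are taken over terminal taxa, and
`summarize_checklist()` reproduces exactly that convention.

## Distances

`build_distance_matrix()` computes the raw (uncorrected) proportion of
differing sites, with **pairwise deletion**: for each pair, only columns
where both sequences carry an unambiguous base A/C/G/T are compared.
Three decisions deserve justification:

* **Ambiguity codes are treated as missing.** An `R` carries partial
  information, but the downstream failure rule is an exact-identity call;
  counting an `R`–`A` site as either match or mismatch would inject
  arbitrary sign into distances that decide failure status. Pairwise
  deletion of all non-ACGT symbols keeps every distance a rational number
  diff/overlap, so `d == 0` is an exact test and no epsilon is needed.
* **Pairwise rather than complete deletion.** Surveys routinely contain
  partial sequences (a 5' or 3' half when one read fails); complete
  deletion would discard half the alignment for everyone because of a few
  partial specimens. Pairwise deletion preserves full resolution for
  complete pairs. This is an assumption about upstream practice, not a
  theorem; it is recorded as such.
* **`min_overlap = 100` sites.** Two opposite-half partial sequences can
  overlap on a handful of columns and produce a spurious zero distance.
  Pairs below the overlap threshold are *undefined* — carried as `NA`,
  excluded from minimum searches, and never silently zeroed. 100 sites is
  roughly 8% of a 1.3-kb marker; at typical fern *rbcL* divergence
  (p-distances of 0.01–0.1) a true non-identity has odds well under
  10^-4^ of looking identical across 100 shared sites, while thresholds
  much larger would needlessly discard genuine half-length overlaps.

A taxon whose every interspecific pair is undefined is flagged
*unscorable* and leaves the failure-rate denominator. Because published
rates are not always explicit about their denominator, `glance()` on a
report gives the rate over scored taxa and over all taxa side by side.

Parsimony-informative sites follow the standard rule (at least two
unambiguous states, each in at least two sequences); ambiguity codes do not
count as states.

## Barcode gap and cross-flora comparison

`min_interspecific_distances()` takes, per taxon, the minimum defined
distance from any of its specimens to any specimen of another taxon —
minimum semantics, not centroids, because identification failure is decided
by the closest non-conspecific haplotype. Ties for the nearest taxon are
broken lexicographically for determinism, and the full tie set is kept in a
list-column. Failure is symmetric by construction (a zero pair makes both
ends fail).

`compare_floras()` computes distances **once** on the combined alignment
and then scores each flora only among its own taxa. Since p-distances are
strictly pairwise, subsetting the matrix is mathematically identical to
recomputing on a subset alignment; computing once simply guarantees all
floras are scored on the same alignment columns. Floras with fewer than two
taxa cannot define an interspecific minimum and are skipped with a warning.

`distance_histogram()` bins scored taxa into left-closed bins (default
width 0.005) and keeps the zero-distance taxa as their own category — the
red bar of the conventional figure — rather than merging them into the
first bin.

## Species richness

Interpolation uses the exact combinatorial expectation over all subsets of
sampling units; it is evaluated through `lchoose` differences for
stability, and the test suite verifies it against exhaustive subset
enumeration for T ≤ 8 at 10^-9^. Extrapolation uses the bias-corrected
Chao2 estimate of undetected species (the (T−1)/T variant, the default of
standard rarefaction/extrapolation software); with no uniques the curve is
flat at the observed richness. Chao2 is a lower bound; treating the
asymptote as "the" richness is only defensible when the curve has visibly
flattened.

**Confidence intervals.** We use a percentile bootstrap over sampling
units: resample the T columns with replacement, drop species left with no
detections, recompute the full curve, take percentile quantiles (default
B = 1000, level 0.95, deterministic for a fixed seed). This is *not* the
analytic incidence bootstrap used by iNEXT-style software; interval widths
will differ from intervals published with that method, and the package
makes no claim to reproduce them. The unit-resampling bootstrap was chosen
because it is assumption-light, honest about between-day heterogeneity,
and trivially seedable. Its known bias: at t = T the resampled curve
cannot exceed the observed richness, so bands are asymmetric near the
observation point. A replicate that happens to draw only empty units
contributes a zero curve; this is vanishingly rare for any real matrix and
is handled rather than erroring.

Degenerate inputs: Chao2 requires T ≥ 2 (error below); t outside [0, T] is
an interpolation error; extrapolation accepts t\* = 0 (continuity) and is
monotone non-decreasing.

## The tree screen

`neighbor_joining()` implements Saitou–Nei agglomeration on the Q
criterion. Two numerical choices:

* **Tie-breaking.** Equal Q values (common when identical sequences are
  present) are resolved by merging the pair whose smallest contained leaf
  labels sort first — topologies are reproducible across runs and
  platforms. Equality is tested with a relative tolerance of 10^-12^ to
  absorb summation order.
* **Negative branches.** NJ can estimate negative lengths on non-additive
  input. They are clamped to zero with the deficit moved to the sister
  edge, preserving path lengths through the joined pair where possible.

Undefined pairs are a hard error naming the offending specimens; the
remedy — `drop_undefined_specimens()`, which greedily removes the
specimens with most undefined pairs — is what `run_pipeline()` applies
before the tree stage (and records in its manifest). The tree is then
midpoint-rooted (diameter ties broken by the lexicographically smaller
leaf pair; an all-zero-length tree roots on the first internal edge with a
warning).

`assess_monophyly()` calls a taxon monophyletic iff the smallest clade
containing all its specimens contains nothing else; single-specimen taxa
are "trivial". Zero-length internal edges from identical sequences are
*retained*, not collapsed: the screen evaluates the resolved binary tree,
which differs from support-aware practice on maximum-likelihood trees. The
screen is exactly that — a fast distance-based flag for taxa worth a
careful look, not a substitute for model-based inference with support
values; no support analogue is computed.

## What the generator emulates — and what it does not

`simulate_flora()` draws a Yule species tree (`birth_rate`, default 1;
only relative branch lengths matter since the tree is rescaled), rescales
it to `subst_rate` expected substitutions/site root-to-tip, and evolves
sequences under Jukes–Cantor. Defaults mirror the structure of a real
cloud-forest pteridophyte survey:

| parameter | default | units | rationale |
|---|---|---|---|
| `n_species` | 176 | species | survey-scale flora |
| `seq_length` | 1309 | bp | *rbcL* alignment length |
| `subst_rate` | 0.15 | subst/site | root-to-tip depth giving realistic 0.01–0.2 interspecific p-distances |
| `n_failure_pairs` | 16 | pairs | 32 failing taxa ≈ 18% failure rate, the magnitude seen in continental floras |
| `p_single` / `extra_range` | 0.8 / 2–5 | — | most taxa sequenced once; difficult groups up to 5 specimens |
| `T` | 37 | days | survey effort |
| `detection` | Beta(2, 2) | — | mean 0.5 daily detectability, wide spread |
| `habit_probs` | 0.028/0.107/0.528/0.416 | proportion | published growth-habit marginals |
| `partial_fraction` | 3/186 | — | observed frequency of half-length sequences |
| `n_nonnative` | 1 | taxa | the occasional introduced species |

Failure pairs are injected by overwriting the second taxon's haplotype
with the first's — the plastid-capture mechanism by which hybrids share
their maternal parent's barcode. Conspecific specimens get at most one
private mutation, so they form star-like clusters around the species
haplotype. The generator then audits the finished specimen matrix (after
partial-sequence masking): if any *defined* cross-taxon pair outside the
designated set has distance zero, the whole flora is redrawn (up to
`redraw_limit`). The realized failure set therefore equals the designated
truth set by construction, which is what makes truth-set comparisons in
the test suite exact rather than probabilistic.

Incidence is Bernoulli per species-day with Beta-distributed per-species
detection; species never detected are dropped from the matrix — a
checklist only contains observed species — but kept in the truth record,
so estimator recovery can be scored against true richness. The species
with barcode sequences are deliberately *not* restricted to the detected
set: the reference library and the incidence survey are treated as
separate artifacts, as they are in practice.

Growth habits are multi-label. A naive "redraw until non-empty" scheme
would inflate each habit's marginal by ~20%, so the raw Bernoulli
probabilities are calibrated (a fixed-point solve) such that the marginals
*conditional on at least one habit* equal `habit_probs` exactly; realized
proportions over many taxa track the configured ones, and the expected
habits-per-taxon ratio (~1.08) matches published tables whose habit
columns sum past the taxon total.

`simulate_three_floras()` draws one species pool and assembles floras by
subsetting: "island" takes the pool's most isolated tips (largest
nearest-neighbour distance — deep splits only, the signature of an oceanic
flora assembled by long-distance dispersal), "continental" the least
isolated (recent in-situ radiation), "mixed" at random. Here chance
haplotype identity among barely diverged sisters is *not* redrawn — recent
splits producing identical barcodes are precisely the continental signal —
and the truth record reports realized per-flora failure sets computed from
haplotype identity. The expected qualitative outcome, and the property the
tests check, is directional: island failure rates below continental ones
in the large majority of replicates.

What the generator does **not** emulate, hence what passing tests do not
establish about real data: codon structure and base-composition bias of a
real coding marker; among-site rate heterogeneity; indel evolution (gaps
appear only as partial-sequence masking, never as evolved characters);
geographically structured sampling effort; identification error in the
checklist itself. Parsimony-informative counts on synthetic alignments run
far higher than on a real single-genus-depth marker, because Jukes–Cantor
on a deep tree saturates sites evenly.

## Numerical conventions

Percentages and ratios in reports are rounded **half-up** (one decimal for
percentages, two for species-per-hectare), matching printed survey tables;
base R's round-half-to-even is deliberately not used at the presentation
layer. All internal values are full precision; rounding happens only in
reporting columns. Newick output carries six significant digits. JSON and
TSV writers are byte-stable, and `run_pipeline()` is idempotent for
identical inputs and seed, with input checksums recorded in a manifest.

## Problem sizes used by the test suite

Test and acceptance-script sizes are the package's own choices, picked so
each check has real statistical teeth while the suite stays quick to run:
oracle equivalence for distances uses 1000 random gapped fixtures;
rarefaction is checked against exhaustive enumeration for T ≤ 8; NJ
recovery on 20 random additive trees of 4–15 tips; monophyly against
clade-enumeration brute force on 50 random labeled trees; truth-set
equality on 100 simulated floras of 30 species; Chao2 recovery on 200
incidence simulations with 250 species over 37 days; the island-versus-
continental direction on 50 replicate pools (75 species, 600 bp). The
acceptance script simulates at full survey scale (176 species, 1309 bp).

## Known limitations

* The NJ screen has no support values; "non-monophyletic" on a distance
  tree is a flag, not an inference.
* Chao2 is a lower bound and the unit-resampling bootstrap differs from
  analytic incidence bootstraps; asymptote intervals are not comparable
  across methods.
* Exact-identity failure is conservative: two taxa one substitution apart
  are counted as distinguishable even though single-read error could blur
  them.
* Abundance-based estimators (Chao1), Hill numbers of order > 0 and
  coverage-standardized comparisons are out of scope, as are
  model-corrected distances (JC/K2P/GTR) — raw distances are the
  appropriate scale for exact-identity barcoding calls.
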