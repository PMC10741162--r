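---
title: "Methods: untargeted metabolomics time-course analysis of burn wound healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted metabolomics time-course analysis of burn wound healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundmetab)
```

`woundmetab` analyses longitudinal untargeted LC-MS feature tables from
burn-wound biopsies. This vignette documents the statistical model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical conventions adopted where the methodology left genuine choices
open.

## The data model

The unit of analysis is the *m/z feature*: a (mass-to-charge,
retention-time, ionization-mode) triple with one intensity per injection.
A `feature_table` couples the intensity matrix with feature metadata
(m/z within the 50–1000 Da scan range, retention time within the
10-minute HILIC gradient, mode) and sample metadata. Samples are either
pooled QC injections — aliquots of all study extracts injected every
seventh run position to track instrument drift — or study samples
carrying pig, wound type (deep partial-thickness, DPT, or full-thickness,
FT), treatment arm and biopsy day (7/14/21/28/60). Missing measurements
stay missing throughout: nothing is zero-filled or imputed at I/O time,
because downstream stages each have their own principled handling
(case-wise deletion for the tests, zero-fill on the z-scale only inside
the clustering distance).

## QC filtering and LOESS drift correction

Two filters precede normalization. The *presence* filter removes features
detected in fewer than 80% of QC injections (a feature at exactly 80% is
retained). The *RSD* filter removes features whose QC relative standard
deviation, computed with the sample (n−1) standard deviation, exceeds
25%; exact 25% is retained. The RSD threshold direction is exposed as a
parameter because the convention is occasionally stated the other way
round in write-ups; retaining the *precise* features (removing RSD > 25%)
is universal QC practice and is the default here.

Drift correction follows the QC-anchored LOESS idea (QC-RLSC): per
feature, regress QC intensity on injection order with a locally weighted
regression (degree 1, tricube weights, span 0.75), evaluate the fitted
trend at every injection, and rescale by `reference / fitted`, with the
reference the median of fitted values at the QC positions so that the
corrected scale is anchored to the middle of the run. With fewer than 7
QC points a local regression is underdetermined and the fit falls back to
an ordinary least-squares line; the worked examples in the tests use this
path deliberately because it has a closed form. A fitted trend that is
nonpositive anywhere would flip intensity signs, so such features are
dropped and counted rather than corrected. Correction is
scale-equivariant (multiplying a feature by c multiplies its corrected
values by c), and the two ionization modes are processed independently —
they are acquired as separate runs and share no drift mechanism.

Span 0.75 is the classical lowess default: with ~50 QCs in a 350-injection
run it averages over ~37 QCs, enough to track smooth monotone drift
without chasing noise. Narrower spans (0.3–0.5) are appropriate when drift
has step changes, e.g. after re-calibration.

## Differential statistics

Each feature is tested with a two-way fixed-effects ANOVA of log2
intensity on day × treatment within one wound type, including the
interaction, with Type-II sums of squares. Type II (each main effect
adjusted for the other, interaction from the full model) agrees exactly
with the textbook decomposition on balanced data but remains meaningful
under the mild unbalance produced by missing measurements. The log2
transform matches the multiplicative error structure of LC-MS intensities
and makes the fold-change scale linear in the model. Rows with missing
intensity are dropped per feature; features with fewer than 3 residual
degrees of freedom get `NA` p-values and are excluded from the
Benjamini–Hochberg family. *Features of interest* must satisfy both
BH q < 0.05 and raw p < 0.05 for the time effect — the conjunction is
deliberately conservative because the selection feeds every later stage.

Day-wise treatment contrasts use two-sided pooled-variance Student's
t-tests on log2 intensities (pooled rather than Welch because group sizes
are equal by design and the pooled test is the stated method of the
protocol this package operationalizes), with the Bonferroni family equal
to the number of features actually tested for that contrast. The fold
change is the linear-scale ratio of arithmetic group means with the graft
arm (AFSG) in the numerator. Volcano responders need p_bonf < 0.1 *and*
fold change > 1.5 or < 1/1.5. Zero-variance ties are resolved exactly:
equal constant groups give p = 1, unequal constant groups p → 0.

## Trajectory clustering

Features of interest are z-scored per feature over the study samples of
one wound type, with the population (divisor n) standard deviation;
constant rows map to zero. Clustering is agglomerative with complete
linkage on cosine distance (1 − cosine similarity) between feature
z-vectors: cosine geometry makes the grouping depend on the *shape* of a
trajectory, not its amplitude, and complete linkage keeps clusters
compact. Missing z entries are set to 0 (the z-scale mean) for the
distance computation only; zero vectors, whose cosine is undefined, are
placed at distance 1 from everything and logged.

The cluster count is selected by consensus: for each candidate k
(default 2–10, wide enough to cover the 6–7 trajectories typical of these
designs), the partition is scored with the silhouette coefficient on the
cosine distance and with the Calinski–Harabasz and Davies–Bouldin indices
on the z-vectors in Euclidean geometry — CH and DB are defined through
centroids in a vector space, so Euclidean geometry is the coherent choice
even though the clustering metric is cosine; both choices are exposed.
Candidates are ranked per metric (silhouette, CH: higher better; DB:
lower better; average ranks on ties) and the smallest mean rank wins,
ties toward smaller k (parsimony). Rank-mean was chosen over score
normalization or majority vote because it is scale-free across metrics
with very different ranges; the helper is separable and testable on
synthetic metric tables.

Cluster centroids (mean z per day) are labelled **U** when every
day-to-day step is ≥ −0.2 z and the profile rises overall, **D** when
every step is ≤ +0.2 z and it falls overall, and **P** otherwise, with
the peak at the argmax (valley-shaped centroids also map to P at the
largest absolute deviation, which is logged — a pure trough has no
separate letter in this scheme). The 0.2 z tolerance permits the small
non-monotonicities that survive averaging without letting genuine peaks
masquerade as monotone trends. Numerals order response timing: U and D
clusters by the first day their centroid crosses zero, P clusters by the
day-7 value (above +0.3 → 1, within ±0.3 → 2, below −0.3 → 3), made
consecutive within each letter. Both thresholds are parameters because
the verbal rules they encode admit nearby numerical readings.

## Annotation

Formulas over {C,H,N,O,P,S,Na,K,Cl} are summed with monoisotopic atomic
masses hard-coded to ≥ 6 decimals. Ion arithmetic uses the *proton* mass
(1.00727646 Da), not the hydrogen-atom mass: the ~0.5 mDa electron
difference matters at 4-decimal m/z. Five common adducts are supported
([M+H]+, [M+Na]+, [M+H−H2O]+, [M−H]−, [M+Cl]−), polarity-filtered against
the feature's mode. Matches within 10 ppm are level-3 hits on the
Schymanski confidence scale, sorted by ppm error with alphabetical
tie-breaks for determinism. MS/MS evidence upgrades a hit to level 2 when
at least 5 experimental fragment masses match database fragments within
0.01 Da under greedy one-to-one matching (closest pairs first, no
double-counting), and to level 1 when the database record is an
authentic-standard entry with retention time within 0.2 min. The level-1
criterion is this package's operationalization of "confirmed by
reference standard"; isotope-pattern scoring and coeluting-adduct
grouping are out of scope.

## Pathway enrichment

Compound names are mapped to KEGG IDs by case-insensitive *exact*
matching only — fuzzy matching invites silent misassignment.
Over-representation uses the exact hypergeometric upper tail
P(X ≥ overlap) with the universe defaulting to all compounds mappable
from the annotated feature set, standard ORA practice when no assay-wide
background is available. Topology impact is the sum of relative
betweenness centralities (pair-normalized, then scaled so the most
central node is 1) of the hit nodes divided by the sum over all pathway
nodes; the fraction-of-total convention keeps impact in [0, 1] and
monotone in the hit set, and the alternative (sum of raw hit
centralities) is available as a documented variant. Disconnected pathway
graphs are handled by counting shortest paths within components.

## The synthetic-data generator

`simulate_study()` generates the full design: `n_pigs = 6` animals, 4 DPT
wounds per pig (2 AFSG, 2 fetal bovine dermis) and 6 FT wounds per pig
(2 AFSG, 2 cadaver skin, 2 split-thickness-graft sandwich), one biopsy
per wound per day over days 7/14/21/28/60 (wound-level replication — the
design has no repeated biopsies of the same wound-day), giving 300 study
injections with pooled QCs at every seventh position (50 QCs, 350 total).
The per-feature intensity model is

```
intensity = baseline × 2^(E · archetype(day)) × 2^(±E at day 7, AFSG only)
            × drift(order) × lognormal(cv)
```

with `E = effect_size_log2` (default 1: a two-fold swing, typical of the
metabolites that pass selection in these studies), multiplicative
log-normal noise (default CV 0.15, mid-range for HILIC-QTOF tissue
extracts; the log-normal makes the CV independent of intensity), linear
shared drift (default amplitude 0.2, jittered ±20% per feature so that
per-feature LOESS is genuinely necessary), 2% missingness completely at
random, and 74% of features in positive mode. A quarter of features are
time-responsive, drawn from eight trajectory archetypes (U1, U2, D1–D3,
P1–P3) that are centered, unit-variance templates on the day grid, with
the default mix weighted toward the peak shapes that dominate wound
healing data. The treatment effect is planted at day 7 only — matching
the empirical finding that graft effects on the wound metabolome are
confined to early healing — so the volcano stage has exact ground truth.
QC injections carry baseline, drift and noise but no design effects, as
befits a pooled sample.

What the generator does *not* emulate: raw spectra and peak shapes,
isotope patterns and coeluting adducts, retention-time drift,
batch-to-batch jumps, pig-level random effects, intensity-dependent
missingness, and correlated features (each feature is independent given
its archetype). Passing tests therefore demonstrate that the pipeline's
inferential machinery is correct under its own assumptions — not that
those assumptions hold for any particular instrument run. In particular,
real features co-drift in correlated blocks, and real missingness is
concentrated at low intensities, both of which make real data harder than
the simulation.

## Validation and problem sizes

The test suite validates each stage against independent oracles: the
ANOVA against an explicit cell-mean sums-of-squares computation on 50
random balanced designs (agreement to 1e-10); the hypergeometric tail
against exhaustive enumeration of all draws for every universe of size
≤ 12; betweenness against a brute-force shortest-path enumerator on 100
random graphs with ≤ 8 nodes; and the printed reference masses by direct
arithmetic. End-to-end checks run the generator at 100–300 features —
large enough for stable rank statistics, small enough that the whole
suite completes in about a minute: trajectory recovery plants the six
DPT-style archetypes at noise CV 0.1 (300 features, 10 seeds, requiring
k = 6 and adjusted Rand ≥ 0.9 in at least 8); error control runs the
global null (no planted effects, 200 features, 10 seeds) requiring ≤ 1%
volcano responders and ≤ 7% BH-positive features; and drift removal
(amplitude 0.4, CV 0.05) must bring the median QC RSD under 10% and
strictly below its pre-correction value.

At the default noise level (CV 0.15) the consensus criterion typically
merges the more correlated archetypes — the day grid has only five
points, so eight centered templates cannot be mutually orthogonal — and
returns 3–7 clusters depending on the wound type and seed. This mirrors
the behaviour of consensus criteria on real data, where the reported
cluster count reflects the noise level as much as the biology.

## Known limitations

Pig is not modelled as a random effect (the two-way fixed-effects ANOVA
is the method this package operationalizes); with six animals a mixed
model would be the natural extension. The annotation stage performs no
molecular-formula generation, spectral-similarity scoring, or online
library queries. The bundled pathway file is a small synthetic toy
topology for demonstrations, not a curated KEGG export, and pathway
results on real data should use project-specific pathway definitions via
`read_pathways()`.
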