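---
title: "Methods: control-anchored organoid drug-screen analysis"
author: "orgscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-anchored organoid drug-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgscreen)
```

# Scope and data model

`orgscreen` analyses image-derived organoid drug screens in which an
AI-segmentation platform has already produced, per organoid and timepoint:
the masked brightfield area $B_i(t)$ (µm²), the overlap of that mask with a
fluorescent dead-cell reporter $G_i(t)$, the invasive-annulus area $I_i(t)$
and its dead overlap $IG_i(t)$, plus brightness and texture descriptors in
arbitrary units. The package consumes these tabular outputs; it performs no
image processing, segmentation or organoid tracking. Organoid identity over
time is taken as given by the upstream platform.

Overlap areas physically cannot exceed their mask; segmentation noise
occasionally pushes them over, so readers clip `green_area` to `bf_area`
(and `inv_green_area` to `inv_area`) and report the count. Clipping is
idempotent. Negative areas are rejected outright rather than repaired.

# Bulk response metrics

The well-level viability signal is the label-free area corrected for the
dead-reporter overlap, $S(t) = \sum_i B_i(t) - \sum_i G_i(t)$, and every
well is self-normalized to its own first measurement,
$F(t) = S(t)/S(t_0)$. Self-normalization removes seeding-density
differences between wells before any cross-well comparison.

With $\bar F_{neg}$ the mean vehicle fold change and $\bar F_{pos}$ the
mean staurosporine (2 µM, complete-kill control) fold change on the same
plate and timepoint:

* percent viability: $100\,(F - \bar F_{pos})/(\bar F_{neg} - \bar F_{pos})$,
  an affine rescaling with the vehicle at 100% and the kill control at 0%;
* growth-rate metric: $\mathrm{GR} = 2^{\log_2 F / \log_2 \bar F_{neg}} - 1$,
  i.e. the treated per-doubling growth expressed relative to the vehicle's;
* normalized drug response:
  $$\mathrm{NDR} = \frac{2^{\log_2 F/\log_2 \bar F_{neg}} - 1}
                        {1 - 2^{\log_2 \bar F_{pos}/\log_2 \bar F_{neg}}}.$$

The NDR closed form is the unique rescaling of the GR transform that meets
the published anchor scale exactly: NDR $= -1$ whenever the treated well
tracks the kill control ($F = \bar F_{pos}$), $0$ at stasis ($F = 1$), and
$\to 1$ for vehicle-like growth as the kill control's signal vanishes
($\bar F_{pos} \to 0$). Values above 1 flag a proliferative effect. Two
boundary conventions matter in practice:

* $F = 0$ (a fully killed well, all signal converted to dead overlap) is
  accepted as the complete-kill limit of the numerator ($-1$) rather than
  an error, because real kill-control wells reach exactly zero signal;
* $\bar F_{pos} = 0$ sets the denominator to its limit 1, where NDR
  coincides with GR.

Both metrics require a growing negative control, $\bar F_{neg} > 1$;
violations raise a condition of class `orgscreen_slow_growth` rather than
returning a number, because the transform is unstable for slow-growing
cultures (the metric can overestimate effects when the control barely
grows).

Control anchors are arithmetic means of the control-well fold changes by
default; a median option is available for robustness to a single failed
control well.

Dose-response AUC is the trapezoidal integral of NDR over
$\log_{10}$ concentration divided by the $\log_{10}$ span, so a constant
curve has AUC equal to that constant and regimens with different dose
ranges are comparable. The AUC ratio (combination / alternative regimen)
reads below 1 as the combination adding benefit, above 1 as antagonism.
Concentrations must be strictly positive and strictly increasing; the
integration convention is a package choice, documented because different
normalizations change AUC magnitudes but not orderings.

Response signatures combine the endpoint NDR with the percent cell death
($100\,\Sigma G/\Sigma B$): cytotoxic (NDR < −0.5 and cell death > 40%),
mixed (NDR ≥ −0.5 and cell death > 40%), cytostatic (NDR ≥ 0 and cell
death ≤ 40%), and indeterminate otherwise (deeply negative NDR with little
measured death — usually a QC flag). The mixed-response boundary is stated
inconsistently in the source literature; the rule set here was chosen so
the four labels are mutually exclusive and total. The 40% cell-death and
−0.5 NDR cut-offs are configurable (`classifySignature()` arguments,
`thresholds` in the run config).

# Single-organoid metrics

The fraction affected $fa_i = \min(G_i/B_i, 1)$ drives a three-class
response call with half-open bins: resistant $[0, 0.15)$, sensitive
$[0.15, 0.34)$, highly sensitive $[0.34, 1]$. The printed ranges in the
source literature differ by one hundredth between text and figure caption;
the half-open convention used here partitions $[0,1]$ without gaps and is
configurable (`cuts`). Organoids with zero masked area carry no information
and are excluded with a logged count, never imputed.

Class-fraction summaries report per-group fractions (summing to 1), the
percent sensitive as the complement of percent resistant (the downstream
clinical correlation treats sensitivity as a dichotomy), and the
sensitive:resistant ratio with sensitive + highly-sensitive pooled in the
numerator; a group without resistant organoids reports an infinite ratio
with an explicit flag.

Invasion metrics: survival invasive area $I_i - IG_i$ (the still-live part
of the invasive annulus), invasive fraction $I_i/B_i$, per-group sums and
the kinetic sum invasive area normalized to the group's first timepoint
(when the baseline sum is zero, normalization switches to a 1 µm²
pseudo-area and flags the group). The invasive flag defaults to invasive
fraction > 0.2: the threshold printed in the source ("< 2") contradicts its
own usage (invasiveness grows with the invasive fraction), so the package
treats the cut-off as an explicit, configurable parameter and defaults to
the most plausible reading. Quadrant labels cross the invasive flag with
the resistant/affected dichotomy at the 0.15 cut.

# Heterogeneity map

The feature matrix has one row per organoid-timepoint and six columns
(area, invasive area, fraction affected, invasive fraction, brightness,
texture), centered and scaled to unit variance; rows with missing features
are dropped and counted, constant columns excluded with a warning.

**Informative PCs.** Parallel-analysis-style permutation test: each of
`n_perm` (default 1000) null matrices independently permutes every column,
destroying inter-feature correlation while preserving marginals; the
p-value per PC is $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$
on the percentage of variance explained, Holm-adjusted in eigenvalue order,
and retention stops at the first non-significant PC so the retained set is
a leading contiguous block. Note the resolution limit: with 6 features the
smallest achievable Holm-adjusted p is $6/(n_{perm}+1)$, so at least 120
permutations are needed for significance at $\alpha = 0.05$ at all; the
package warns below 100.

**Embedding.** t-SNE (Rtsne, Barnes-Hut) with perplexity $\lfloor\sqrt n
\rfloor$ — the screen-scale heuristic that adapts neighbourhood size to the
number of organoids. When $n$ is too small for the rule (the embedder
requires $3\,\mathrm{perplexity} < n$), perplexity is lowered to
$\lfloor(n-1)/3\rfloor$ with a warning. The embedding is deterministic
given the seed, which is recorded in pipeline metadata.

**Clustering.** Each observation is connected to its $k$ nearest
neighbours in the embedding ($k = 1000$ by default, capped at $n-1$), edge
weights are the complement of the Euclidean distance rescaled by the
longest realized edge, $w = 1 - d/d_{max}$ — bounded in $[0,1]$ and
order-reversing; "complement of a distance" is undefined for unbounded
distances, so the rescaling is an explicit package choice with a linear
$d_{max} - d$ alternative available. Louvain community detection runs at
resolution 1 under the session seed.

A caveat worth knowing: modularity optimization is scale-invariant in the
edge weights, so no weighting scheme prevents Louvain from splitting a
*disconnected* dense kNN component into several communities (the
resolution-limit effect). With the default $k = 1000$ (capped at $n-1$),
well-separated groups stay connected to each other by low-weight edges and
are recovered whole; with a small $k$ relative to group size, the graph
disconnects and groups may be over-partitioned. The package keeps the
screen-scale default and resolution 1, and the tests verify planted-group
recovery under those defaults.

**Characterization.** Features are rank-normalized (average ranks over
$n$, range $(0,1]$) before cluster profiling; metadata enrichment per
cluster is the within-cluster level fraction over the overall fraction
(size-weighted mean 1 across clusters), and the trajectory root is the
cluster most enriched for the earliest timepoint.

# Pseudotime

Cluster centroids in the embedding are joined by a Euclidean minimum
spanning tree. Clusters representing discrete end states (resistant,
sensitive, invasive) are *forced* to be terminal: the MST is built over the
non-terminal centroids first and each terminal is then attached as a leaf
to its nearest non-terminal centroid. This build-then-attach mechanism is
one of several ways to enforce terminality; it was chosen because it
guarantees degree-1 terminals for any geometry, at the cost of possibly
lengthening the tree relative to the unconstrained MST when a terminal
would otherwise have been internal.

Observations are projected orthogonally onto the closest MST edge (clamped
to the endpoints; ties broken by the lowest edge id). For every
root-to-leaf path, the pseudotime of an observation on a path edge is the
arc distance from the root centroid to its projection; observations on
off-path edges are undefined for that path rather than snapped to it.
Common pseudotime averages the defined paths; every MST edge lies on at
least one root-to-leaf path, so common pseudotime is total.

Treatment-arm density along a chosen root-to-terminal path uses a Gaussian
kernel with a single bandwidth from the pooled on-path pseudotimes
(`bw.nrd0`), shared across arms so the curves are comparable, plus each
arm's mass on the path (fraction of the arm's observations whose closest
edge is on the path) — the mass, not the normalized density, is the
quantity to compare between arms.

# Clinical statistics

Spearman's $\rho$ uses ranks; for untied ranks
$\rho = 1 - 6\sum d^2/(n^3-n)$. The two-sided p-value is computed by full
enumeration of all $n!$ permutations when $n \le 8$ (40,320 permutations,
instant) — at cohort sizes around $n = 7$ the exact null matters, and
asymptotic approximations are unreliable. With ties, average ranks and the
product-moment coefficient are used with a seeded Monte-Carlo permutation
p (10,000 draws), since the untied exact null no longer applies; beyond
the exact cap the t approximation is used, and the `method` field always
states which path produced the p-value. Censored patients are excluded
from PFS correlations (no survival modelling is attempted) with the count
reported.

Signature concordance maps ex vivo labels to expected clinical categories
(default cytotoxic→good, mixed→mixed, cytostatic→bad, configurable) and
reports the concordant fraction over matched patients.

# The plate simulator

The simulator exists so every downstream stage is testable with known
ground truth; the source study's raw imaging data are not redistributable.
Per organoid, the noise-free model is

$$\frac{dA}{dt} = \bigl(k\,(1 - e(c)) - \delta(c)\bigr)\,A, \qquad
  G(t) = A(t)\,\bigl(1 - e^{-\delta(c)\,t}\bigr),$$

with growth inhibition $e(c)$ and death rate $\delta(c)$ both Hill
functions of concentration ($e = H$, $\delta = \delta_{max} H$,
$H = c^h/(c^h + EC_{50}^h)$). The dead overlap is thus a saturating
function of cumulative death, and the ground-truth death fraction
$1 - e^{-\delta t}$ matches the emitted $G/B$ exactly before noise.
Invasion is an independent annulus process: the invasive area grows
linearly to $A_0\,\varphi$ over the observation window, where
$\varphi = \text{propensity} \times \text{regimen induction} \times H(c)$,
so invasion appears only when a clone's propensity meets a positive
induction under treatment.

Default study conditions: two technical replicates per condition, ~200
organoids seeded per well (Poisson), log-normal initial areas (median
5000 µm², log-sd 0.4), imaging at 0–120 h in 24 h steps, a five-point
log-spaced dose series around the clinically relevant 400 nM
gemcitabine anchor (5:1 gemcitabine:paclitaxel molar ratio, indexed by the
anchor compound), and 5% multiplicative log-normal measurement noise per
channel. Overlap channels are nested measurements on the same mask, so
their noise factor perturbs the overlap *ratio* of the noisy mask and is
clipped to it — independent noise on nested areas would violate the mask
constraint half the time. Staurosporine wells use a 0.6 h⁻¹ death rate:
an idealization of the rapid complete kill expected of 2 µM staurosporine,
chosen so kill-control wells genuinely reach zero residual signal and the
NDR's complete-kill anchor is exercised.

What the simulator does **not** emulate: organoid birth/merging/splitting
and tracking errors, spatial well effects (edge evaporation, drift),
pharmacokinetic decay of compounds, organoid-to-organoid interaction, and
reporter kinetics beyond the saturating-death model. Passing tests
therefore demonstrate correctness of the analysis chain under the stated
generative assumptions, not robustness to every imaging artefact.

Four stock scenarios (`defaultScenarios()`) span the response taxonomy:
cytotoxic responder, cytostatic responder (zero death rate, so stasis is
exact), heterogeneous (70% sensitive + 30% resistant subclone, the
resistant clone's EC50 125× higher), and invasion-inducer (a
paclitaxel-like arm with induction 1.5 beside a non-inducing
gemcitabine-like arm).

# Problem sizes and numerical choices in the test suite

The validation suite checks planted-parameter recovery at deliberately
chosen sizes: resistant-fraction recovery uses the full 200-organoid wells
at a saturating dose over 50 seeds per planted fraction, judged against
the central 95% region of the corresponding binomial distribution over the
whole fraction grid; the invasion-trajectory comparison runs the complete
map-and-pseudotime chain on reduced plates (12 organoids/well, 500 t-SNE
iterations) over 50 seeds, since the planted effect is large and the check
targets the chain's sign, not its asymptotics. Exact-Spearman equivalence
is enumerated fully for all $n \le 6$ against an independent brute-force
oracle, and MST optimality is verified against exhaustive Prüfer-sequence
enumeration of all spanning trees for up to 7 clusters.

Tie-breaks and degeneracies are deterministic throughout: projection ties
go to the lowest edge id, duplicated embedding points yield a single
community (zero distances give unit weights), `kinetic_inv_norm` switches
to a pseudo-area denominator at zero baseline with a flag, and every error
condition carries a typed class (`orgscreen_schema_error`,
`orgscreen_slow_growth`, ...) so callers can branch on failure modes.

# Known limitations

* The NDR closed form matches the published anchor scale exactly but
  parity with the original authors' unpublished script cannot be asserted;
  the anchor scale is the tested contract.
* Whether the published "% cell death" is control-normalized is not
  stated; the package uses the raw per-well $100\,\Sigma G/\Sigma B$ and
  documents the 40% threshold against that definition.
* Pseudotime is a 2-D embedding construct: forced terminals and MST
  topology inherit any distortion t-SNE introduces, and no branch-point
  statistics are attempted.
* Clinical correlation requires observed (uncensored) PFS; the package
  deliberately stops short of survival modelling.
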