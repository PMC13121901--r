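---
title: "Consensus population identification for heterogeneous cytometry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus population identification for heterogeneous cytometry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `cytoconsensus`, the assumptions
they rest on, the parameters that matter, and the design choices made where
the method left room. It states no result that the package's test suite and
acceptance script do not themselves compute.

# The problem

A heterogeneous cultured cell line — here modeled on lymph-node stromal
cells — is profiled by flow cytometry with a five-marker panel (CD45, CD31,
PDPN, ICAM-1, VCAM-1) on two acquisition days corresponding to two culture
passages. Controls are limited: an unlabeled cell sample (autofluorescence)
and five single-stain compensation-bead samples, all run on both days.
Populations overlap heavily on every single axis, so classical sequential
gating is sensitive to where a human places each gate, and that sensitivity
compounds across gating layers. The package provides (i) a reproducible
formalization of consensus gating across several clustering algorithms, and
(ii) the statistical machinery — probability-binning chi-squared scores
adjusted for control variability — used to decide which populations are
genuinely distinct and what they are.

# Bead-anchored normalization

**Model.** For a given channel, measured intensity is assumed affine in the
number of bound antibodies within a day: `I = m·A + b`. Compensation beads
carry a day-invariant amount of antibody (negative beads ideally none), so
the negative and positive bead peaks give two anchor points per day and the
day-to-day map is the unique line through them:

```
I_ref = (I_ref_H - I_ref_L) / (I_day_H - I_day_L) * (I_day - I_day_L) + I_ref_L
```

**Assumptions.** Linearity of the intensity–antibody relation at the
titrated concentration; identical bead binding across days; sharp,
detectable bead peaks.

**Peak detection.** Kernel density on the arcsinh scale with Silverman's
rule (`stats::density`, `bw = "nrd0"`); the two highest local maxima are
the candidate modes after discarding maxima below 5 % of the peak density.
Bimodality additionally requires the valley between the candidates to drop
below 80 % of the smaller mode — otherwise the input is declared unimodal.
Modes closer than `min_separation` (default 0.5 arcsinh units) raise an
ambiguous-peaks error. Events are split at the deepest valley and the
median (default; mean available) of each side on the *linear* scale is the
anchor.

**Choices.** Normalization is applied on the linear scale (the model lives
in measured-intensity units) before the arcsinh transform; the lower-signal
day is mapped onto the higher-signal day; channels whose anchors already
agree within `tol = 1 %` (relative) keep the identity map, because the map
is a multiplier that amplifies spread (worst at low intensities) and should
not be fit to noise; the per-channel slope ratio is always reported.
Normalized values are applied to every sample of the moved day, bead
controls included.

# The arcsinh transform

All high-dimensional analysis runs on `asinh(value / cofactor)` with a
default cofactor of 150 per channel — the conventional choice for
fluorescence cytometry: linear (and finite) through zero and negative
compensated values, logarithmic at high intensity. No transform is imposed
on gating or on univariate T(x), both of which are quantile-based and
therefore invariant under any strictly monotone rescaling (for T(x) this is
exact by construction; see below).

# Sequential gating and its variation study

Layer 1 places a CD45 threshold at the smallest value retaining at least a
fraction `retention` of each unlabeled control sample (the per-sample
cutoffs are maximized so the constraint holds for every control). Layer 2
forms CD31/PDPN quadrants of the CD45-negative events (double-negative →
perivascular/double-negative path, CD31+ → BEC, PDPN+ → FRC, double
positive → LEC); layer 3 forms ICAM-1/VCAM-1 quadrants within the FRC and
double-negative populations. Each layer's thresholds come from the control
events surviving the previous layer.

The variation study re-runs the cascade under several retention criteria
(defaults 0.995, 0.999, 1.0 — the plausible range of a careful user) and
reports, per terminal population, the coefficient of variation of its count
(sample SD / mean, %), the mean CV, and the mean CV per layer. "Variance"
or "covariance" in informal descriptions of this robustness measure is read
throughout as the CV; sample (n−1) SD is used because the number of gating
variants is small. An optional multiplicative `margin` on every threshold
emulates additional hand-dragging. Oblique (diagonal) negative gates are
supported in `quadrant_gate()` via a user-supplied line, with sides decided
by the signed cross product; the automated cascade uses axis-aligned gates.

# The clustering ensemble

Three clusterers with deliberately different biases run on the transformed
full-dimensional data:

* `som_cluster` — a hand-written batch self-organizing map (no SOM package
  is available in this stack): Gaussian neighbourhood shrinking from half
  the grid diagonal to 0.5 over `rlen = 10` epochs, codebook seeded from a
  random event sample; the codebook is then agglomerated by average-linkage
  hierarchical clustering into `k_meta` metaclusters (default 7 on a 10×10
  grid). Conservative: the cluster count is capped by the user.
* `graph_community_cluster` — k-nearest-neighbour graph (Euclidean,
  `RANN`), edges weighted by the Jaccard overlap of neighbour lists,
  partitioned by Louvain modularity (`igraph`). Default k = 30.
* `density_peak_cluster` — density is the inverse mean distance to the k
  nearest neighbours; every event links to its nearest denser neighbour
  within its list; events with none are peaks and clusters are the trees
  under them. Fully deterministic; density ties break by event index
  (lower index counts as denser). This is a simplified density-ascent
  clusterer: no cross-validated neighbourhood selection or elbow-based
  model selection.

Low/default/high presets (`highdim_params`) vary grid, metacluster count
and neighbourhood size, emulating users choosing different parameters.

Embeddings (tSNE via `Rtsne`, UMAP via `uwot`, plus compact internal
implementations of triplet and pair embedding in the style of TriMap and
PaCMAP — no packages for those exist in this stack; the TriMap-style
embedder uses unit triplet weights and the PaCMAP-style embedder the
published three-phase weight schedule) serve visualization and the
island-consistency diagnostic only. They never feed the labels.

# Consensus, anchoring, merging

**Co-association.** Over the supplied clusterings, entry (i, j) is the
fraction placing events i and j in the same cluster (capped at a seeded
subsample, default 5,000 events). Average-linkage hierarchical grouping on
`1 − coassociation` is cut at height `1 − cut` (default cut 0.5: events
stay together when at least half the clusterings agree). Average-linkage
heights are clamped monotone (`cummax`) to absorb floating-point inversions
from the small rational dissimilarities. Groups with fewer than `min_size`
(5) subsampled events are dissolved to the nearest surviving centroid, and
events outside the subsample are assigned to the nearest group centroid in
transformed marker space.

**Anchoring.** A cluster whose events are at least `anchor_fraction` (0.9)
from bead samples is a bead cluster; it becomes `bead_control(channel)`
when a single stain sample dominates it *and* its median on that channel
exceeds the overall bead median (i.e., it is the positive peak), otherwise
`negative_beads`. Clusters dominated by unlabeled-cell events are
`unlabeled_cells`. Same-role clusters merge unconditionally — the controls
are known to be single populations, which is precisely why they were run.

**Merging.** Remaining labeled-cell clusters are tested pairwise, smallest
id pair first, to a fixed point. A pair merges when (a) its control-
adjusted T(x) is ≤ 0 on every channel, and (b) the robust separation — the
maximum over channels of |median difference| / pooled scaled MAD — is
below `similarity_threshold` (2). Pairs passing (a) but failing (b) are
flagged `borderline` in the audit log rather than merged, surfacing the
kind of ambiguity a marginal subpopulation (an MRC-like cluster) creates.
Pairs too small for binning (fewer than 20 events in either member) are
judged on separation alone. Every decision is recorded in the audit log.

**Defaults are package choices.** `anchor_fraction = 0.9`, `cut = 0.5`,
`similarity_threshold = 2` were fixed so the pipeline passes the synthetic
recovery suite; no published values exist for them.

**The ensemble.** By default the pipeline feeds the co-association all nine
clusterings (three algorithms × three presets) rather than three. This
mirrors the practice of generating arrays of runs at high/medium/low
parameters and looking for patterns common to all of them, and it is what
stabilizes the bulk population: individual graph/density runs carve a large
homogeneous cloud into spatially coherent pieces, and because different
presets carve it differently, the pieces co-associate above the cut and the
consensus keeps the cloud whole, while genuinely distinct populations are
separated by nearly every run. Single-preset consensus remains available
(`ensemble = FALSE`) and is what the robustness sweep varies.

**Subsampling.** Clustering runs on a hybrid subsample (default 4,000
events): half uniform, half drawn with probability proportional to inverse
local density. Uniform-only starves rare populations (tens of events at
this cap); inverse-density-only starves the extremely dense bead peaks.
The acceptance run clusters 4,000 of ~130,000 events and extends labels by
nearest centroid; this problem size keeps the full pipeline under a minute
while leaving every reference population tens to hundreds of subsampled
events.

# Probability-binning T(x)

Bins are defined on the control sample: univariate bins place edges *on*
control order statistics (bin k holds values ≤ edge k), giving equal
occupancy up to integer rounding and — because ranks are preserved — exact
invariance of the statistic under any strictly monotone transform applied
to control and test alike. Multivariate bins recursively split the
most-populated bin at the median of its highest-variance channel (used for
the overall, all-channels score; per-channel scores use univariate bins).
The bin count never exceeds `min(B_requested, floor(n/10))` for both
samples — a bin rule that keeps expected counts ≥ ~10.

The score is the two-sample chi-squared over the bins, standardized by the
chi-squared reference (`mu0 = B − 1`, `sd0 = sqrt(2(B−1))`; a seeded
Monte-Carlo alternative is available and agrees with the analytic moments),
minus a guard band of one null SD, floored at zero:

```
T(x) = max(0, (chi2 - (B-1)) / sqrt(2(B-1)) - 1)
```

The guard band is a deliberate conservative choice: a plain floored z-score
has a null expectation near 0.4 simply because the positive half of a
centred distribution survives the floor, whereas scores within one SD of
the null mean carry no evidence of a difference. With the guard band the
null expectation is ~0.08 and same-distribution comparisons read 0 — the
behaviour observed in published control tables, where most control
comparisons print exactly 0.0000. `guard = 0` restores the plain floored
z-score.

**Control adjustment.** Per channel, every control population (the positive
beads of each stain, the pooled negative beads, the unlabeled cells) is
compared day 1 vs day 2; the channel's variability level is the maximum of
those scores after excluding any control whose score exceeds the
unlabeled-cells score on that channel. The exclusion generalizes the
negative-bead case: near zero intensity, the normalization multiplier
inflates spread, so a negative-bead day difference larger than the
biological variability of actual cells reflects the transform, not biology.
A population's expression on a channel is significant when
`T(x) − variability > 0`. No multiple-testing correction is applied — the
procedure subtracts a variability level instead; this is a documented
limitation.

**Positivity and phenotypes.** A channel is called positive when it is
significant *and* the population median exceeds the unlabeled reference's
99th percentile on that channel (the difference must point upward — a
significance-only rule would call any variance change "expression").
Phenotype strings follow the marker patterns of the stromal compartment:
all five positive → hematopoietic; CD31+PDPN+ICAM1+VCAM1+ → LEC;
VCAM1-only → PvC; PDPN+ICAM1−VCAM1+ → FRC; PDPN+ICAM1+VCAM1+ → MRC-like;
anything else → unassigned. Channels missing from the panel (the
CD45-dropped dataset variant) count as negative.

**Rounding.** Percentage displays round half away from zero to two
decimals; this convention reproduces the published passage-table cells
exactly from their printed counts.

# The synthetic study generator

Each channel value is a lognormal peak plus an independent lognormal
autofluorescence floor. The reference design encodes: five single-stain
bead samples (sharp negative peak at 20, sigma 0.15; positive at 12,000,
sigma 0.18; 50/50 mixture), one unlabeled sample (floor only: location
150, sigma 0.5) and one labeled sample per day; four labeled populations
(hematopoietic, LEC-like, PvC-like, FRC-like) at the published
passage-5/passage-12 proportions, sigma 0.35 in the well-separated preset;
a day-2 ICAM-1 instrument distortion (gain 0.4, offset 15) applied to all
of that day's samples; and a modest biological drift of the cell line
between days (per-channel multipliers of 0.85–1.25 applied to cell samples
only). The drift matters conceptually: beads cannot see it, so
normalization cannot remove it, and it is exactly the variation the
control-adjusted T(x) is designed to subtract — without it the adjustment
would be vacuous (control variability ≈ 0) and any two halves of any
cluster would count as "distinct". An optional MRC-like subpopulation
(FRC with raised ICAM-1, `mrc_fraction`) exercises the
marginal-population path, and an `overlapping` preset (sigma 0.85,
positive signal pulled toward the floor) creates the gate-ambiguous regime
used for the robustness comparison.

What the generator does **not** emulate: spillover and compensation error,
doublets and debris, acquisition drift within a run, non-specific antibody
binding, and heavy-tailed instrument noise beyond lognormality. Passing
tests therefore demonstrate the pipeline's behaviour under its stated
model, not under every artifact of real list-mode data.

# Numerical details and degenerate inputs

* All seeds derive from one user seed via a seeded integer draw (kept below
  2^31); every stochastic stage is reproducible, and the RNG state of the
  caller is restored.
* Peak detection requires ≥ 200 events; binning requires ≥ 20 control
  events (B ≥ 2); clustering neighbourhoods must be smaller than the event
  count; empty test samples, degenerate (coincident) control peaks, and
  oblique gates through coincident points raise classed errors.
* Robust separation floors a collapsed pooled MAD at 5 % of the channel's
  overall MAD.
* Ties: density ties break by event index; merge candidates are scanned
  smallest-id-pair first; axis-quadrant assignment of points above an
  oblique line but below both cutoffs goes to the nearer single-positive
  quadrant.
* FCS support is a minimal 3.0/3.1 list-mode reader (float, double, or
  uniform-width integer data; `$PnE` log amplification and `$PnG` gain
  decoded to linear scale) plus a float32 fixture writer; other dialects
  are rejected with explicit errors rather than guessed.

# Problem sizes

The test suite runs the full pipeline at 6,000 events per cell sample and
1,500 per bead sample (36,000 pooled events, 2,500 clustered), the
robustness sweep at 1,500/400 over ten seeds, and unit tests at hundreds
to tens of thousands of events; the acceptance script runs the reference
20,000/5,000 design (~130,000 pooled events, 4,000 clustered). These sizes
were chosen so a complete run stays in the minutes range on a single CPU
while every population keeps enough events for the bin rule.

# Known limitations

* The consensus formalization replaces, rather than reproduces, the visual
  judgment of drawing gates along a clusterer's boundary; hand-drawn gate
  coordinates of any particular analysis are not recoverable.
* T(x) values are not comparable to FlowJo's numerically (its normalization
  constants are not published); only the qualitative contract — zero means
  indistinguishable, large means distinct, control-adjusted positivity —
  is preserved.
* The number of populations a run reports is stochastic at the margins: a
  very broad population can occasionally survive as two consensus clusters
  when its carve-up is consistent across many ensemble members and genuinely
  exceeds control variability on some channel.
* With `k_meta` below the true population count the SOM member under-splits
  by construction; the ensemble relies on the graph and density members to
  supply those separations.
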