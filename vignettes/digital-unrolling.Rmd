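---
title: "Digital unrolling and spatial program discovery with rollst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital unrolling and spatial program discovery with rollst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollst)
```

## The problem

Rolling a whole mouse colon into a "Swiss roll" before sectioning places the
entire proximal-distal axis on one Visium capture area, but the resulting
spot coordinates live in the image plane of a spiral. Questions about the
tissue's own axes - where along the colon, and how deep into the wall - need
a change of coordinates. rollst implements that change of coordinates
("digital unrolling") together with the analysis stages that consume it:
non-negative matrix factorization (NNMF) of spatial transcriptional
programs, knee-based selection of each program's top genes, footprint-based
signalling pathway activities, gene-set module scores, and preranked
gene-set enrichment in factor loadings. A seeded synthetic Swiss-roll
generator provides ground truth for every stage.

## The unrolling model

The input is a hand-traced curve along the outer edge of the muscularis (the
*base layer*), supplied as a binary mask or a pixel-coordinate list, plus
the spot positions. The algorithm:

1. **kNN graph.** Each base-layer point is linked to its `k = 5` nearest
   neighbours (kd-tree search).
2. **Endpoints.** On a uniformly sampled *open* curve, the two ends have
   one-sided neighbourhoods, which makes their mean distance to their 5
   nearest neighbours extremal. We take the two *largest* values: for
   points at arc spacing `s`, an interior point's 5-NN mean distance is
   `1.2 s` against `3 s` at an end, so one-sided neighbourhoods *increase*
   the statistic. (A `mode = "smallest"` switch is provided because the
   opposite convention also circulates; the geometric default is what the
   synthetic ground truth confirms.) If the extremal statistic is not
   separated from the bulk by a robust z-score (default 2), the curve has no
   endpoints and a closed-curve error is raised rather than an arbitrary
   cut.
3. **Ordering.** The unweighted shortest path (minimum vertex count)
   between the endpoints orders the curve. Because a kNN graph of a
   uniformly sampled curve always contains hops that skip immediate
   neighbours, the geodesic retains roughly every other traced point; the
   dropped points are reported. The retained, ordered subset *is* the base
   layer from here on - an x unit is therefore one *path vertex*, about two
   traced pixels on our defaults.
4. **Assignment.** For each base point, spots within an 80 px radius whose
   angle to the local tangent (central difference over +/- 5 ordered
   neighbours; undirected angle in [0, 180] degrees) falls in [35, 125]
   degrees are candidates; each spot keeps its minimum-distance pair, ties
   to the lower order index. An assigned spot gets `x` = order index of its
   base point and `y` = distance to it. Unmatched spots are flagged, never
   fatal. The asymmetric angle window is kept exactly as configured;
   both sides of the curve are treated identically (the distance is
   unsigned), so a base layer traced through the middle of a tissue would
   fold both sides onto the same half-plane.

## Normalization surrogate

Counts are variance-stabilized with analytic negative-binomial Pearson
residuals: expected counts `mu = n_s * pi_g` (spot depth times gene share),
per-gene method-of-moments excess-variance estimates pooled into a single
global overdispersion `alpha` (their median), residuals
`(x - mu) / sqrt(mu + alpha * mu^2)` clipped at `+/- sqrt(n_spots)`. The
pooling is essential, not cosmetic: a per-gene overdispersion estimate
absorbs biological variance and drives every gene's residual variance to
~1, destroying the "residual variance > 1.1 means variable feature"
contract that downstream stages rely on. Genes above the threshold (default
1.1) are the variable features.

## NNMF and top-gene selection

The clipped-nonnegative residual matrix over variable genes (ribosomal
`Rps`/`Rpl` symbols excluded) is factorized by HALS coordinate descent from
a deterministic non-negative double-SVD initialization; multiplicative
updates were rejected because they stall far from the 1e-6 relative error
the exact-recovery contract requires. Negative residuals are clipped at 0
by default (`shift` by the matrix minimum is available); clipping implies
every gene carries a small positive "background" for every factor, which is
why fitted loading rows have a cross-loading shelf below the true markers.

Each factor's top genes come from its loading curve: positive loadings
sorted descending, log-transformed, smoothed with a Gaussian kernel of
window length 10 (support = 10 ranks, `sigma` = 2.5, edge-renormalized; a
kernel truncated at 4 sigma would span 21 ranks and contradict the stated
window length), then cut at the unit-invariant knee: both axes min-max
scaled, knee = maximum perpendicular distance to the first-to-last chord
*on the convex side*. The sign matters: multi-level curves (markers, then
cross-loading shelf, then near-zero dust) place their plateaus *above* the
chord, and an unsigned extreme-distance estimator selects the far corner of
the shelf instead of the marker cliff. A curve that never dips below its
chord (a straight ramp, or a purely concave curve) has no knee and raises a
degenerate-curve error.

One bias is inherent to this selection and worth knowing: smoothing with
window `w` drags the knee about `w/2` ranks past a sharp cliff, because the
first smoothed rank free of marker influence is `m + w/2 + 1` for an
`m`-marker factor. A 10-marker program therefore yields ~16 selected genes
(precision ceiling 10/16 ~ 0.63) even at infinite signal-to-noise. We kept
the method as specified rather than tuning the kernel to the test.

## Scores and correlations

**Pathway activities** follow the footprint logic: per-gene z-scored
expression times a pathway-by-gene weight matrix (any `pathway, gene,
weight` CSV; the published 14-pathway mouse model can be supplied by the
user, and the generator ships a planted synthetic model), then z-scaled per
pathway across spots - fixing an order the original description leaves
open. With `per_sample` set, both z-scalings happen within each slide.

**Module scores** are set-mean minus bin-matched-control-mean on
log-normalized expression (`log1p` of depth-normalized counts, *not*
Pearson residuals - residuals have per-gene mean ~0, which makes expression
binning meaningless). Defaults: 24 equal-frequency bins, 100 seeded control
draws per set gene, drawn with replacement when a bin is small. Control
pools exclude the set genes themselves: at our bin sizes a 25-gene set
would contribute ~10% of its own controls and bias every score toward zero
by that fraction. Note what this statistic can and cannot see: a shift
applied to *every* spot also shifts the set genes' average expression, so
binning re-matches them and the score stays ~0; the module score measures
spot-specific elevation, which is what the tests assert (score response
between shifted and unshifted spots).

**Correlations** are plain Pearson with two-sided p-values and
Benjamini-Hochberg adjustment across the emitted set; zero-variance columns
surface as NA with a warning. The CMYK similarity coloring min-max rescales
a 3-D embedding into the unit cube and uses the channels as C, M, Y with
K = 0, making it invariant to per-column affine transforms.

## Enrichment analyses

Panel co-expression uses gene-gene Pearson correlation on per-gene z-scaled
residuals, diagonal zeroed, Ward (`ward.D2`) clustering of `1 - r`, and a
`cutree` at `k = 3`; the "co-expression cluster" is operationalized as the
cluster with the highest mean intra-cluster correlation (the original
choice was by inspection). Preranked GSEA is an explicit running-sum with
in-set increments proportional to `|stat|^weight` and uniform out-of-set
decrements, ES = running-sum extremum, and a seeded gene-label permutation
p-value with the +1 correction (one-sided in the observed direction);
permutations are evaluated in closed form at the set-gene positions, which
is exact because the running sum attains its maximum just after an in-set
step and its minimum just before one. The reference tool's adaptive
multilevel p-refinement is intentionally out of scope; `n_perm` bounds the
attainable p at `1/(n_perm + 1)`. Ortholog mapping, when needed, is a
user-supplied two-column table - never a live database query.

## The synthetic world

`simulate_swissroll()` generates an Archimedean spiral `r = a + b*theta`
(defaults `a = 60` px, `b = 16` px/rad, 3 turns; winding gap
`2*pi*b ~ 100` px), base-layer points at 2 px arc spacing (returned
shuffled, with the true order retained), and a spot lattice at 4 px arc
spacing on three depth layers (10, 25, 40 px inward - muscle, lamina
propria, epithelium; ~3000 spots). Depths stay below half the winding gap
so no spot is closer to the neighbouring winding than to its own; jitter is
capped at a quarter of the spot spacing; coordinates are rounded to integer
pixels to match the Visium positions dialect losslessly.

Planted programs are soft-edged regions (logistic transition of total width
~2 spot steps - the transition *width*, not the logistic s-parameter, which
would smear 15 px-apart depth layers into mush): muscle, lamina propria,
proximal and distal epithelium, follicle hotspots at three isolated arc
positions, and stem-cell zones in the distal epithelium named with the
packaged 25-gene proliferating stem-cell signature. A p53-footprint
activity `p = 1 - stem/max(stem)` is planted *outside* the factor matrices
(it is a pathway activity, near-constant over 97% of spots, and not an
NNMF-recoverable program; the planted rank of the default world is 6); its
30 footprint genes, plus TNFa-like and NFkB-like footprints riding on the
distal-damage program and a Wnt-like footprint on the lamina propria, form
the planted pathway model. Counts are negative-binomial,
`mu = size_s * (W H + baseline)`, NB size 10, log-normal spot size factors.

Two world choices deserve their rationale. First, 300 of the 1200 genes
are high-dispersion (NB size 1) but spatially unstructured: real
variable-feature sets are dominated by such noise-variable genes, and
without them every variable gene is program-loaded, fitted loading curves
have no dust tail, and no knee estimator can segment them sensibly.
Second, the stem zones are 70 px wide at amplitude 1.5: the stem/p53
anticorrelation is prescribed to be *detectable* (module score vs footprint
score r <= -0.5), and an anticorrelated signal confined to ~2% of spots is
washed out by per-spot noise regardless of effect size; at ~7% coverage the
measured correlation is ~ -0.62 across seeds. What a green test does *not*
establish: the generator has no spatial autocorrelation of noise, no
segmentation error in the base layer, no multi-sample batch structure, and
its programs are smoother and more exclusive than real histology - so
passing recovery thresholds here bounds algorithmic, not biological,
error.

## Numerical and degenerate-input policy

Ties everywhere resolve to the lowest index and are deterministic; GSEA
gene ranking breaks stat ties by gene name. All randomized stages (counts,
shuffle, jitter, NNMF init jitter, control draws, permutations) take
explicit seeds; `run_all()` derives stage seeds from one master seed and
writes a manifest with parameters and table checksums but no timestamps, so
reruns are byte-identical. Degenerate inputs raise classed errors
(`rollst_closed_curve`, `rollst_degenerate_curve`, `rollst_empty_error`,
...) rather than guesses: an all-zero mask, a closed curve, a flat loading
curve, a zero-count spot, an empty gene set after intersection.

## Known limitations

* The unrolled x unit is a path-vertex index, not calibrated arc length;
  comparisons across masks of different resolution need rescaling.
* Assignment treats both sides of the base layer identically; curves traced
  mid-tissue fold the two sides together.
* The SCTransform surrogate shares the contract, not the implementation, of
  regularized NB regression; absolute residual values differ from it.
* Permutation GSEA cannot report p below `1/(n_perm + 1)`.
* The knee selection inherits the `+window/2` smoothing bias discussed
  above.
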