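---
title: "Graph-based segmentation of retinal layer boundaries: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based segmentation of retinal layer boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlayers)
```

## The model

An OCT B-scan is an H×W intensity raster: rows are depth (vitreous at the
top), columns lateral position. A retinal layer frontier is a function of
column — one row value per column — separating two bands of different
reflectivity. octlayers extracts each frontier as the minimum-cost
left-to-right path through a weighted pixel graph, the geodesic view of
boundary tracking: if pixels on the frontier are cheap to traverse and
everything else is expensive, the cheapest path across the image *is* the
frontier.

### Cost maps

For a stage with polarity *p* and weight λ, the per-pixel cost is

$$W(x) = \exp\bigl(-\lambda\,(1 - g_h(x))\,g_v(x)\bigr),$$

renormalised to [0, 1]. Here $g_v$ is the vertical intensity derivative,
sign-flipped for bright→dark stages and clamped at zero so that only
transitions of the requested polarity score, then min–max normalised; $g_h$
is the normalised magnitude of the horizontal derivative. Both derivatives
are central differences (one-sided at the borders) of the TV-denoised scan.
A strong vertical transition of the right polarity with little lateral
variation gets cost near 0; flat or wrong-polarity tissue gets cost near 1.
The polarity clamp does most of the work of keeping stages apart: a
bright→dark search is literally blind to dark→bright frontiers, which is
why narrow regions of interest suffice.

The $(1-g_h)$ factor down-weights laterally incoherent pixels (vessel
shadows, disrupted tissue). It has a measurable side effect discussed under
*Known limitations*.

### The pixel graph

Every admissible pixel is a node joined to its 8 neighbours. With
prominence $g = 1 - W$, an edge between pixels $a$ and $b$ weighs
$(2 - g(a) - g(b)) + \varepsilon$: nearly free along a prominent frontier,
about 2 across background. The constant $\varepsilon = 10^{-5}$ keeps all
weights positive (Dijkstra's optimality precondition) and is small enough
that path length never competes with prominence (a detour of a thousand
extra edges costs 0.01 — far less than one background pixel). A fully
connected ε-weight pad column on each side, tied to a virtual source and
sink, lets the optimal path enter and leave at any row. Path rows are
averaged per column, so vertical runs collapse to one (possibly fractional)
row value. Ties between equally cheap paths are resolved deterministically
by the search's fixed scan order, though not by an anatomically meaningful
rule; on real, noisy data exact ties are measure-zero.

### Stage order and regions of interest

The IS-OS junction (B7) anchors everything. It is found first, over the
full image width, on an *enhanced* scan: pixels below their 101-px-window
local mean (minus an offset `enh`) are zeroed, which strips the dark inner
retina and vitreous and leaves the bright photoreceptor/RPE complex — whose
upper edge, the IS-OS junction, becomes the dominant dark→bright frontier.
A validity check then scores the candidate (mean prominence ≥ 0.6 along the
path, total row variation ≤ 0.5·W) and records the verdict; it never
blocks, because deciding what to do with a dubious B7 is the reviewer's
job. The remaining stages run in the order B9, B8, B6, B1, B4, B5, B3, B2,
each inside a mask anchored to earlier boundaries:

| stage | region of interest | polarity |
|---|---|---|
| B9 | 5–60 px below B7 | bright→dark |
| B8 | between B7 and B9, 1 px pads | bright→dark |
| B6 | 25 px band above B7, 3 px margin | dark→bright |
| B1 | everything above B6, 2 px margin | dark→bright |
| B4 | between B1 and B6, 1 px pads | dark→bright |
| B5 | between B4 and B6, 1 px pads | bright→dark |
| B3 | 20 px band above B4 | bright→dark |
| B2 | between B1 and B3, 1 px pads | bright→dark |

Two polarity choices deserve a note. The outer nuclear layer (between B5
and B6) is the darkest retinal band, so the frontier above it (B5, OPL→ONL)
is a bright→dark transition and the one below it (B6, ONL→IS) dark→bright;
these defaults follow that reflectivity ordering. Polarity is a per-stage
configuration value, not hard-coded, so either can be flipped for atypical
data. The B6 stage also keeps a 3 px margin below its band: B6 shares B7's
polarity, and without the margin the search would snap onto the blurred
upper shoulder of the much stronger IS-OS edge.

After all stages, the anatomical ordering B1 ≤ … ≤ B9 is enforced per
column by monotone projection (a violating boundary is clipped to the one
above it, top-down), and every adjusted column is logged rather than
silently fixed — consistent with the tool's review-first philosophy. On
clean phantoms the projection is a no-op.

### Human-in-the-loop

Interactive review maps onto files and re-runs rather than a GUI: `quality.json` and `overlay.png` support inspection,
`rerun_stage()` (CLI `rerun`) recomputes one stage and its downstream
closure after a parameter change (B7 feeds B9/B6/B1; B9 feeds B8; B4 feeds
B5/B3; B3 feeds B2), and boundary overrides replace a computed frontier
*before* downstream stages run, so a manual correction of B7 propagates to
all eight dependents. Overrides never degrade downstream accuracy in the
phantom studies — the override-monotonicity check in the test suite.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| λ (`lambda`) | 10 | – | cost-map contrast; larger values deepen the frontier's advantage |
| `smooth` | 0.05–0.08 | intensity | ROF total-variation weight before differentiation |
| `ws` | 101 | px | local-mean window of the B7 enhancement (forced odd) |
| `enh` | 0.30 | intensity | enhancement offset: pixels ≥ local mean − enh survive |
| band widths / pads | see table | px | region-of-interest geometry per stage |
| `C` | 0.01 | intensity | adaptive binarisation contrast threshold |

λ is dimensionless and deliberately modest: beyond ~50 the cost map
saturates and tie plateaus grow. `ws` at 101 px spans roughly a quarter of
a 496-row scan — wide enough that the local mean near the photoreceptors
mixes bright and dark bands, which is what makes the enhancement mask
selective. The adaptive binarisation (median-filter variant of the same
idea, `adaptive_binarise()`) is exposed with its window/threshold
parameters for preprocessing experiments; the pipeline itself uses the
mean-filter enhancement.

## The phantom generator

`default_healthy_spec()` encodes a healthy macular scan: nine boundary
curves (base depths as fixed fractions of H, jittered ±1 px per seed) with
a smooth sinusoidal undulation and a Gaussian foveal dip that attenuates
from B1 to B6; ten band intensities with the vitreous near-black, the ONL
darkest, and the outer-segment band below B7 brightest — making B7 the
strongest dark→bright frontier, the anchor assumption. Bands are rendered
with sub-pixel coverage (a boundary at row 260.3 leaves pixel 260 mostly
dark-side), blurred by a small Gaussian (σ = 0.7 px), and multiplied by
gamma speckle with mean 1 and shape k = 50 — the standard surrogate for
OCT's multiplicative speckle at a moderate signal-to-noise level.
Pathology: drusen lift B8/B9 toward the vitreous by a raised-cosine bump;
fluid pockets darken an ellipse between B4 and B6 and push B4/B5 apart.
Band crossings after perturbation are a validation error, not a silent
clip.

What the phantom does *not* emulate: depth-dependent signal roll-off,
vessel shadows, motion artefacts, the point-spread correlation structure of
real speckle, and real pathology's texture. Passing the phantom studies
therefore demonstrates the geometry of the pipeline — anchoring, ROI
construction, polarity separation, error propagation — not clinical-grade
robustness; parameters that survive the phantom may still need tuning on
device data.

## Numerical choices

* **TV denoising** is Chambolle's dual projection (30 iterations, τ =
  0.249), clipped back to [0, 1]; `smooth = 0` returns the input
  bit-identically.
* **Window filters** use reflective (symmetric) padding, so image borders
  never manufacture dark-to-bright artefacts. Even window sizes are forced
  up to the next odd value; the size check runs before odd-forcing so a
  window equal to the larger image dimension stays legal.
* **Threshold at zero** in the enhancement uses a 10⁻¹² tolerance so pixels
  analytically *at* their local mean survive the running-sum rounding.
* **Degenerate inputs**: a constant image yields an all-zero cost map
  (flagged), a boundary is still returned, and the IS-OS check reports
  score 0 and fails — the caller decides.
* **Mask construction** rounds boundary rows half-up and uses strict
  inequalities, so the reference frontier's own pixels are excluded at
  offset 0 and the next search cannot re-detect it.
* **Problem sizes** in the validation studies: 512×496 phantoms, five seeds
  per condition for the recovery and override studies, three pairs for the
  pathology study, and 100 random maps up to 5×5 for the exhaustive path
  oracle — sizes at which the full suite runs in a few minutes on one CPU.

## Known limitations

* The $(1-g_h)$ factor penalises the frontier exactly where it slopes: on a
  smooth phantom the steepest *horizontal* gradients in the image lie on
  the sloped segments of the boundaries themselves, so the path wobbles
  around the true frontier there by up to ~1 px (noise-free MAE ≈ 0.55 px
  instead of the ≈ 0.25 px rounding floor). Dropping the factor removes the
  wobble entirely on phantoms, but the factor is retained as part of the
  method's design — its purpose is robustness to lateral incoherence in
  pathological scans, which the phantom does not model.
* Errors under pathology concentrate where the anatomy is disrupted: a
  drusen degrades B8/B9 on its footprint while B1/B7 are unaffected, and a
  whole-scan average largely hides a 30-column lesion. Evaluation should be
  footprint-aware when pathology is present.
* The B8 frontier (OS–RPE) has the weakest contrast of the nine in the
  phantom's reflectivity model and carries the largest recovery error
  (~0.8 px under speckle).
* The monotone projection resolves ordering violations top-down, favouring
  the upper boundary; with a badly wrong B7 the projection can drag several
  outer frontiers with it — which is exactly the situation the IS-OS check
  is meant to flag for review.
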