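---
title: "Quantifying geometry-guided platelet spreading on striped micropatterns"
author: "plateletPattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying geometry-guided platelet spreading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletPattern)
```

## The measurement problem

On microcontact-printed substrates, protein stripes (collagen or
fibrinogen) alternate with BSA-blocked glass. Spreading platelets follow
the protein with high fidelity: above a feature scale of about 5 µm they
conform almost perfectly to stripe boundaries; below it, spreading fidelity
degrades; and platelets bridge BSA gaps only when the gap is within reach
of their filopodia. This package turns multi-channel fluorescence
micrographs of such assays — or synthetic images with known ground truth —
into per-platelet statistics and per-geometry trend curves.

Five statistics carry the analysis:

* **On-pattern area fraction**: the fraction of a platelet's mask pixels
  on protein. Its mean rises toward 1 with stripe width.
* **Aspect ratio**: greatest extent along the stripe axis over greatest
  extent perpendicular to it. Near 1 on wide stripes, large on thin ones.
* **Spanning**: a platelet touching two distinct stripes across a gap,
  counted among platelets in contact with a stripe edge.
* **Filopodia lengths**: skeleton-geodesic lengths of mask protrusions.
* **Actin edge enrichment**: boundary-band over interior mean intensity,
  with a homogeneous channel (tubulin) as the control giving ratio 1.

## Conventions

Rasters are `(row, col) = (y, x)` matrices with pixel centres at
`((i − 0.5)·px, (j − 0.5)·px)` µm; a pixel is on-pattern iff its centre
lies inside a stripe (point sampling, not area weighting), which makes
pixel counts exact and rasterization deterministic. The stripe axis angle
is measured counterclockwise from the x axis (with y up); stripe offsets
are intervals on the perpendicular coordinate measured from the field
origin. The default pixel size, 0.1 µm/px, resolves the thinnest stripes
of interest (0.6 µm = 6 px); one worked example uses 0.05 µm/px.

Extents in `aspectRatio()` are (max − min) of pixel-centre projections
plus one pixel, so a one-pixel-wide object has nonzero width and the
11.4 µm × 0.6 µm reference rectangle gives exactly 19.0. The +1 px
convention is calibrated for axis-aligned masks; under joint rotation of
mask and axis the ratio is stable to ~5% once the narrow side is resolved
by ≳20 px, and degrades on coarser rasters (a 6 px narrow side measures up
to one pixel wide of its true extent at oblique angles). Filopodial pixels
count toward the extents: a "greatest length" reading of elongation
includes the tips, and the per-group maxima are reported alongside means
so this sensitivity is visible in the output.

## The spreading simulator

The simulator is a *static end-state* generative model: the assay's
quantified results are end-state statistics, so no time-lapse dynamics are
modelled. Per platelet, with one explicit RNG seed:

1. `nFilopodia` (default 8) directions are drawn uniformly; lengths come
   from Normal(3.10, 0.8²) µm truncated to (0, 5] µm — the measured
   filopodia length distribution with a hard cap at maximal extension.
2. Probing filopodia extend from the resting body (radius 1.25 µm, a
   resting platelet) at the seed point; one anchors iff its tip pixel is
   on-pattern.
3. If none anchors and the seed is off-pattern, the platelet never
   spreads (empty mask) — platelets whose filopodia find no protein keep
   probing but do not spread.
4. Otherwise the centre relocates to the nearest on-pattern point
   (computed analytically; stripes are intervals on the perpendicular
   coordinate) and lamellipodia fill the nearest `targetAreaUm2` (default
   50 µm², a typical spread platelet; the analysis never depends on its
   absolute value) of the home stripe, never beyond `maxExtentUm`
   (default 5.7 µm, half of the largest conforming platelet length) from
   the centre. Because stripes are convex, nearest-first filling equals
   geodesic growth, and is computed in closed form.
5. Filopodia then protrude their full drawn length beyond the final body
   margin, re-anchored at the final tip. This placement — rather than
   measuring filopodia from the body centre — reflects that filopodia sit
   at the spread margin; it is also what makes skeleton-based length
   measurement on the final mask meaningful, since a 50 µm² body would
   otherwise engulf a 3 µm filopodium drawn from the centre. A filopodium
   whose tip lands on a *different* stripe creates a straight-line
   corridor plus a small lamellipodial foot on the far stripe, but only
   when the gap between the stripes is at most `maxReachUm`: spanning is
   filopodia-limited by construction, and no simulated platelet can ever
   span more than 5 µm.

Anchoring at the final tip makes retention weakly length-dependent (long
filopodia pointing off-stripe retract), biasing retained true lengths
slightly below 3.10 µm; the octile geodesic metric of the measurement
slightly overestimates oblique shaft lengths. The two effects largely
cancel: pooled measured means over 200 platelets land within ~0.05 µm of
the generator mean, inside the 2-SE acceptance band.

With `offPatternSpread` enabled and the home stripe narrower than
`fidelityScaleUm` (default 5 µm), the fill admits off-pattern pixels near
the boundary with probability `(1 − conformFidelity)` tapering linearly
over the deficit `fidelityScaleUm − width`: the sub-5 µm fidelity-loss
regime. The taper is the package's choice; only its qualitative shape
(leakage grows as stripes thin) matters to the curves built on it. With
the default `conformFidelity = 1` every mask pixel outside gap corridors
is on-pattern, exactly.

All randomness flows from one seed through counter-based splitting
(`seed_i = f(base, platelet index, stream)`), so per-platelet results are
independent of execution order and any subset of a dataset can be
regenerated bit-identically.

### What the generator does and does not emulate

It emulates: conformity above ~5 µm features, fidelity loss below, gap
spanning limited to ≤5 µm, filopodia with the measured length
distribution, actin enrichment at the pattern/BSA boundary (factor
`actinEdgeFactor` in a configurable band, default 0.5 µm), homogeneous
tubulin, and epifluorescence-like imaging (Gaussian PSF σ 0.1 µm, Poisson
shot noise at 500 counts/unit, Gaussian read noise, 8/16-bit
quantization). It does not emulate: time-lapse kinetics, receptor-level
signalling, platelet–platelet interactions or aggregation, flow,
protein-density effects (a single density is assumed, matching the
observation that density did not change spreading), or real PSF asymmetry
and debris. Passing round-trip tests therefore validates the measurement
code and its noise robustness — not performance on every artefact real
images can contain.

## Segmentation

Otsu thresholding on the [0, 1]-normalized channel (the assay gives no
reason to prefer a fixed threshold; one can be configured), hole filling
(membrane dyes ring-stain real platelets; a no-op on solid synthetic
masks), connected components at 8-connectivity so 1-px diagonal filopodia
stay attached, an area filter (default 1 µm², well below a resting
platelet), and optional border exclusion (on by default: partially imaged
platelets bias every statistic). Touching platelets merge into one label —
a documented limitation; the assay analyzes well-separated single cells
and the simulator's field layout spaces seeds accordingly.

## Numerical choices and degenerate inputs

* Empty platelet masks are an error (`undefined measurement`), not NA.
* Perpendicular width is clamped below at one pixel: no division by zero
  on the thinnest stripes.
* `detectStripes()` estimates the axis per connected component from
  second moments and takes the size-weighted circular mean on the 180°
  circle; widths are the median perpendicular extent over 1-px along-axis
  bins. Round trips recover widths and gaps within one pixel for stripes
  ≥3 px and the axis within 1°.
* The edge band used by both the renderer and `edgeIntensityRatio()` is
  the set of platelet pixels within `bandUm` of both the platelet
  boundary and the pattern boundary (Euclidean distance transforms), so
  the measured ratio is anchored to the rendered one by construction; a
  band that swallows the whole platelet, or a zero-intensity interior, is
  an error.
* Exponential fits are unweighted least squares to the group *means*
  (matching curves fitted to average data, not pooled points), with the
  asymptote fixed at 1 (fraction, aspect ratio) or 0 (spanning), b
  initialized from a log-linear regression of |y − asymptote| and
  Levenberg–Marquardt refinement. Exact model data are recovered to 1e-6.
  A curve constant at its asymptote is flagged `degenerate` (amplitude 0,
  rate NA); non-convergence is flagged, never silently replaced. A
  single exponential through a spanning curve that saturates near 1 at
  small separations underestimates the decay steepness near the
  threshold; the spanning *limit* should therefore be read from
  `spanningThreshold()` (largest observed spanned gap), not from the
  fitted tail.
* Groups with n = 1 are retained with SEM 0 and listed in
  `fitInfo$singleton_groups`.

## Design decisions that were genuinely open

* **Filopodium origin.** Probing from the resting body decides *whether
  and where* a platelet spreads; rendered filopodia protrude from the
  final margin (see above). The alternative — drawing shafts from the
  centre with total length 3.10 µm — would make filopodia invisible on
  any realistically sized body and was rejected.
* **Spanning mechanism.** Straight corridors between the body and
  anchored far-stripe tips, gated by gap ≤ maximal reach. This encodes
  the hypothesis that filopodial extension limits spanning as a hard
  model rule; the package measures the consequence (largest spanned gap
  4–5 µm across the separation series) rather than assuming it in the
  metrics.
* **Aspect ratio on mid-width stripes.** With filopodia included in the
  extents, simulated mean aspect ratios at 6–10 µm remain visibly above
  1 (≈1.5 at 10 µm) and approach 1 only on the widest stripes (1.1–1.25
  at 20 µm) — the same qualitative shape as the measured width series,
  which reaches ≈1 only at the top of its range. Tests therefore assert
  near-isotropy on 20 µm stripes and monotone decay with width, not a
  tight band at 6 µm.
* **Dataset layout.** One pattern per geometry condition (2–3 identical
  stripes plus a 12 µm perpendicular margin), rather than one stamp
  carrying all conditions: grouping is then exact by construction.
  Rendered fields place platelets on a 13 µm grid with jitter so
  segmentation sees well-separated cells; mask-only datasets simulate
  each platelet independently on a compact field.
* **Problem sizes.** Default test and acceptance runs use 40–200
  platelets per condition and 100 per separation across 0.5–20 µm —
  enough that the pooled filopodia SE is ≈0.03 µm and every separation
  bin of the spanning assay has a two-sided 95% interval narrower than
  0.1. These sizes were chosen as the smallest that make the assertions
  statistically meaningful.

## Known limitations

Touching platelets are not split; partially imaged platelets are dropped
rather than completed; filopodia measurement on *rendered* (blurred,
noisy) images is unreliable for 1-px shafts and is therefore run on
masks — the ground-truth path for simulations, the segmented-mask path for
real images, where ~0.1 µm-scale accuracy should not be expected; the
fidelity-loss taper is phenomenological; and the simulator's platelets are
internally homogeneous apart from the actin edge band, so texture-based
measurements have no synthetic test bed here.
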