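---
title: "Methods: quantifying perfused 3D angiogenic sprouting and plate-level assay performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying perfused 3D angiogenic sprouting and plate-level assay performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioscreen)
```

## The assay and what the package computes

In a perfused microfluidic angiogenesis assay, endothelial cells form a
confluent microvessel against a collagen gel that is patterned in the
central channel of each chip. Under an angiogenic growth-factor
gradient, tip cells invade the gel and sprouts extend roughly
perpendicular to the vessel; anti-angiogenic compounds suppress that
invasion dose-dependently. Each chip is imaged as a two-channel
confocal stack (nuclei and F-actin), and all quantification is done on
the maximum-intensity projection.

`angioscreen` implements the full analysis chain:

1. **imaging** — stack I/O, max projection, and stitching of the two
   vertically overlapping acquisition sites of a chip;
2. **segmentation** — a vessel mask, its skeleton, and nucleus
   centroids from the projection;
3. **metrics** — the per-chip readouts: total sprout area, migration
   distance, nuclei-in-sprouts count, total vessel length;
4. **assay performance** — signal window, Z-factor, assay variability
   ratio, CVs and the screening acceptance flags;
5. **dose response** — 4PL inhibition fits with bootstrap IC50
   confidence intervals;
6. **synthetic data** — a ground-truthed generator for chips and
   plates, so that every stage is testable without microscope data.

The coordinate convention is fixed throughout: matrices are indexed
`[y, x]`, pixel (1,1) is the top-left corner, and y increases toward
the gel (the sprouting direction). All physical outputs are in µm via
the pixel size.

## Per-chip readouts

The **migration distance** is the mean y-position of the `k = 10`
furthest nuclei beyond the monolayer baseline, minus the baseline. The
baseline defaults to 400 µm — the empirical average position at which
the monolayer abuts the gel in this chip format — and is configurable,
since it is a property of the chip geometry and imaging window rather
than a universal constant. Three edge policies are deliberate:

* only nuclei strictly beyond the baseline are eligible;
* with fewer than `k` eligible nuclei, all of them are averaged; with
  none, the distance is 0. A completely inhibited chip must map to the
  assay's minimum signal, not to a missing value — otherwise the
  min-signal control group of a well-performing inhibitor would be
  empty;
* ties at the k-th y-value are broken by (y, then x) ordering so the
  readout is deterministic.

The **total sprout area** counts vessel-mask pixels beyond the
baseline, restricted to connected components containing at least one
nucleus centroid: F-actin-positive debris without a nucleus is not a
sprout. The **nuclei-in-sprouts** count applies the same two gates to
the centroids themselves. The **total vessel length** is the
edge-weighted length of the skeleton beyond the baseline (orthogonal
steps count 1 pixel, diagonal steps √2). Branch/node topology is
deliberately not computed: on maximum projections, apparent branching
is dominated by sprout crossings, so such counts would not be
meaningful.

With two sites per chip, the migration distance is averaged across
sites (it is an intensive readout, defined per field of view) while
area, count and length are extensive and summed. Whether the "furthest
nuclei" should instead be pooled across sites before selecting the top
10 is ambiguous in principle; per-site selection followed by averaging
is the default and the alternative only changes chips whose two sites
differ grossly, which the QC statistics flag anyway.

## Segmentation choices

The reference analysis for this assay family was done with a
closed-source vendor module whose operator parameters are unpublished;
the package therefore validates against ground truth rather than
against vendor bit-parity. All parameters are exposed with defaults:

| parameter | default | unit | role |
|---|---|---|---|
| `smooth_sigma` (nuclei) | 5 | µm | pre-threshold Gaussian smoothing |
| `smooth_sigma` (vessel) | 3 | µm | pre-threshold Gaussian smoothing |
| `bg_radius` | 50 | µm | grey-opening background estimate |
| `min_diameter`, `max_diameter` | 7, 25 | µm | accepted nucleus size |
| `ws_tolerance` | 0.02 | fraction | watershed peak-merge depth |
| `min_object` | 100 | µm² | minimum vessel-mask object |
| `close_radius` | 5 | µm | vessel-mask closing disc |

Smoothing scales are specified in µm, not pixels, so segmentation
behaves identically at full acquisition resolution (0.677 µm/px) and
at the coarser scale used for fast synthetic work (2.7 µm/px).

Nucleus splitting uses a watershed on the smoothed intensity surface
rather than on the distance transform of the binary mask. In confluent
regions the binary mask of touching nuclei is nearly convex, so its
distance transform carries almost no separating signal, whereas the
intensity surface keeps one clear peak per nucleus; the intensity
watershed resolves spacing down to about twice the blob sigma.
Centroids are intensity-weighted over each watershed region, which
gives sub-pixel accuracy (well under 1 px on rendered ground truth).
Nuclei outside the vessel mask are *retained* by the segmentation and
gated only in the metrics layer, keeping the two concerns separable.

The skeleton stored in a `segmentation_result` covers the gel region
(`y > baseline`) only. The confluent monolayer band is not a linear
structure — thinning it yields an arbitrary medial line with no
biological meaning — and it is excluded from the vessel-length readout
by definition; skipping it also removes the dominant cost of
morphological thinning.

## Assay-performance statistics

For a max-signal (untreated, 0 nM) and a min-signal (fully inhibiting
dose) control group, with per-group sizes:

$$SW = \frac{\left(AVG_{max} - \tfrac{3 SD_{max}}{\sqrt{n_{max}}}\right) -
 \left(AVG_{min} + \tfrac{3 SD_{min}}{\sqrt{n_{min}}}\right)}{SD_{max}/\sqrt{n_{max}}},
\qquad
Z' = \frac{\left(AVG_{max} - \tfrac{3 SD_{max}}{\sqrt{n_{max}}}\right) -
 \left(AVG_{min} + \tfrac{3 SD_{min}}{\sqrt{n_{min}}}\right)}{AVG_{max} - AVG_{min}}$$

The published formulas write a single $n$; the package uses each
group's own size because characterisation runs of this assay use
unbalanced controls (15 vs 14 chips), and the per-group reading is the
only one consistent with that design. Sample SDs use the $n-1$
denominator, following the assay-guidance literature. Negative SW or
Z' values are returned as-is — they are diagnostic — and thresholds
are applied only by `evaluate_acceptance()` (Z' ≥ 0.4, SW ≥ 2,
CV~max~ ≤ 20%, SD~min~ ≤ SD~max~).

The **assay variability ratio** is computed as
$AVR = 3(SD_{max}+SD_{min})/(AVG_{max}-AVG_{min})$, i.e. the
complement of the classic plate-level Z-factor without the $\sqrt n$
scaling. Published tables for this assay report the AVR without its
formula; this form is adopted from the standard assay-guidance
framework and reproduces those published values within rounding of
their printed inputs, which is the strongest available check.

`reconstruct_group_params()` inverts the Z' formula at
$AVG_{max} = 1$: given a published (Z', CV~max~, CV~min~, n~max~,
n~min~) row it returns the unique normalised control-group pair
consistent with it. Recomputing SW and AVR on the reconstruction
checks a published performance table for internal consistency even
when the underlying per-chip data are not available.

```{r recon}
g <- reconstruct_group_params(0.75, 0.13, 0.20, n_max = 15, n_min = 14)
signal_window(g$gmax, g$gmin)
assay_variability_ratio(g$gmax, g$gmin)
```

## Dose-response model

Inhibition curves use the four-parameter logistic

$$R(c) = bottom + \frac{top - bottom}{1 + (c/IC_{50})^{h}}$$

fitted by Levenberg–Marquardt least squares with the IC50 parameterised
on the log10 axis. The vehicle control ($c = 0$) is handled exactly:
its inhibition fraction is identically zero, so control chips anchor
`top` without the pseudo-dose placement that plotting conventions use —
a pseudo-dose would make noise-free model data unrepresentable and
bias `top` slightly. Stability choices for 6–7-point screens: `bottom`
is constrained ≥ 0, `top` starts at the lowest-dose mean, IC50 at the
geometric mean of the nonzero doses, and the Hill slope within
[0.05, 10]. Two failure modes are flagged as `converged = FALSE`
rather than thrown: constant responses (nothing to fit) and fits whose
span `top − bottom` does not exceed twice the residual SD (no
resolvable dose dependence, as for an inactive compound).

IC50 confidence intervals are case-resampling bootstrap percentile
intervals on log10(IC50), stratified by concentration so every
resample keeps the dose design (with only a couple of chips per dose,
unstratified resampling frequently loses whole dose levels and
destroys identifiability for reasons unrelated to the data). The
default 1000 resamples are seeded and deterministic. Asymptotic Wald
intervals were rejected because screening designs of this size (down
to N = 2 per dose) violate their assumptions badly.

## The synthetic-data generator

No raw image data are published for this assay family, so the package
ships a phenomenological generator that reproduces the *statistical
structure* the downstream analysis relies on, with known ground truth:

* expected migration distance follows the 4PL inhibition model
  $E(c) = D_0(1 - I_{max}\, c^h/(c^h + IC_{50}^h))$;
* per-chip noise is multiplicative Gaussian (CV `cv_chip`) truncated
  at zero, since distances are non-negative;
* a rendered chip consists of a confluent monolayer band behind the
  baseline (uniform F-actin plus a jittered grid of nuclei), sprouts
  as jittered polylines extending in +y with Gaussian-profile F-actin
  tubes, nuclei spaced every `nuclei_spacing` µm along each sprout as
  3D Gaussian blobs, and Poisson photon noise plus Gaussian read noise
  on a constant background.

Defaults describe an untreated control chip: `D0 = 250` µm sprouting
extent, `cv_chip = 0.13` (the between-chip variability of a
well-behaved distance readout), 10 sprouts per chip, nuclei every
20 µm, baseline at 400 µm, sunitinib-like potency `IC50 = 20` nM with
full inhibition. Control sprout extent and sprout count are not
published for this assay; 250 µm and 10 sprouts are realistic
mid-range values for 2-day gradient-driven sprouting in a ~500 µm gel
window and are held fixed throughout.

The default rendering frame is 512 × 512 px at 2.7 µm/px with 8
z-planes at 5 µm — the same ~1.4 mm field of view as a full
2048 × 2048 / 0.677 µm / 80-plane acquisition, at a scale where a full
render–segment–quantify cycle takes seconds; the full geometry is one
`chip_geometry()` call away. Unit tests use a 160 px frame with a
100 µm baseline, identical physics at desk scale.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: optical anisotropy and
depth attenuation, lumen structure (sprouts are filled tubes), sprout
branching and anastomosis, uneven illumination or stitching
vignetting, staining variability, and segmentation-adversarial debris.
The generator validates the *pipeline logic and its statistics*, not
the biology of any particular dataset.

## Imaging and stitching

Stacks are written as plain multi-page 16-bit TIFF (z-major,
channel-interleaved) with a JSON sidecar holding pixel size, z-step
and channel names; on reading, OME-style `PhysicalSizeX`/`PhysicalSizeZ`
attributes embedded by other software take precedence, then the
sidecar, then explicit arguments.

The two sites of a chip overlap nominally by 10% in y. The translation
is refined by phase correlation (cross-power spectrum) of the
channel-summed projections, which is sharp for pure translations and
insensitive to the overlap fraction; the peak is accepted only within
±10% of the frame around the nominal offset, otherwise the nominal
offset is used with a warning — the stage layout is known, and an
unconstrained registration failure should never silently rearrange a
chip. Featureless (zero-variance) inputs also fall back to the nominal
offset. The overlap band is fused by linear distance-weighted
blending: the weight of the upper site ramps 1 → 0 across the seam and
the two weights always sum to 1.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and per-chip seeds
are derived deterministically from a run's master seed, so plates,
renders, tables and bootstrap intervals are bit-reproducible. The
package's own validation uses: 1000-replicate control-plate
simulations for the plate-performance medians (the median of a
200-replicate simulation is already stable to ±0.01; 1000 replicates
shrink the estimator noise well below the margins being checked),
100-run recovery sweeps for IC50, and single default-geometry renders
for the imaging chain.

## Known limitations

* Segmentation quality is validated on rendered ground truth; real
  acquisitions with strong background gradients may need the exposed
  parameters retuned (`bg_radius`, `ws_tolerance`, size limits).
* The area readout inherits the mask's sensitivity to the threshold:
  Otsu on a clean Gaussian-profile tube reproduces nominal widths to
  ~10–15%, and that scale of bias should be expected on real F-actin
  halos too.
* Stitching estimates a pure translation, matching the acquisition's
  stage layout; rotation or scale drift is out of scope.
* The 4PL fit assumes monotone inhibition; biphasic responses will be
  flagged as poor fits rather than modelled.
* 3D sprout topology (branches, nodes, lumens) is out of scope by
  design.
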