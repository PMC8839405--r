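---
title: "ABCD scoring of lesion photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ABCD scoring of lesion photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermabcd)
```

`dermabcd` scores a single-lesion photograph with the dermoscopic ABCD
rule and combines the four criteria into the total dermatoscopic value
(TDV). This vignette explains the model behind each stage, the tunable
parameters and their defaults, the numerical choices made where the method
leaves room, what the synthetic-lesion generator does and does not
emulate, and the known limitations.

## Imaging model and preprocessing

Inputs are colour rasters with channels normalised to $[0,1]$, nominally
$160 \times 120$ px covering a $20 \times 15$ mm skin field at fixed
focus, i.e. $0.125$ mm/px on both axes (the `calibration` object; custom
calibrations are supported, with a warning when the two axis ratios differ
by more than 1%). Images smaller than $8 \times 8$ px are rejected.

Preprocessing runs in the order *median filter → grayscale closing →
contrast clipping*:

* **Median filter** (`median_radius`, default 1 px): removes impulse
  noise and free-standing 1-px hair lines. Each output value is the
  median of the $(2r{+}1)^2$ neighbourhood, per channel.
* **Grayscale closing** (`close_radius`, default 2 px, disk element):
  raises thin dark structures — hairs — to the surrounding skin level.
  Closing is applied to the gray conversion only; the colour image keeps
  just the median filter, because the colour features should see the
  lesion's true pigmentation rather than morphology-flattened values.
* **Contrast clipping** (`clip_low`, `clip_high`): the piecewise-linear
  map sending levels at or below `clip_low` to 0, at or above `clip_high`
  to 255, linear in between. When unset, the clip points default to the
  0.1th and 99.9th percentiles of the closed gray image. Percentiles this
  far in the tails are deliberate: a lesion often covers several percent
  of the frame, so a more aggressive stretch (say, the 1st percentile)
  would place `clip_low` *inside* the lesion's own gray range, collapse
  the darkest-edge/body/skin structure to a two-level image, and destroy
  the three-class segmentation that follows. The mild tail stretch
  normalises brightness without touching that structure.

Gray conversion uses the standard luma weights $0.299R + 0.587G + 0.114B$
(configurable), scaled to integer levels $0..255$. Both filters use
symmetric reflection padding at the image border; this avoids the
artificial border darkening that replicate-with-zeros padding would
inject into the border-irregularity statistic.

## Segmentation

A mole photograph separates into three gray populations: the darkest
lesion edge, the lesion body, and the bright skin. `multi_otsu()`
exhaustively searches the pair of thresholds $0 < t_1 < t_2 \le 255$
maximising the between-class variance of the 256-bin histogram over the
three classes $[0,t_1)$, $[t_1,t_2)$, $[t_2,255]$. Threshold pairs that
tie (mass-free gray ranges make ties exact) resolve to the
lexicographically smallest pair, making results deterministic across
implementations; the exhaustive $O(256^2)$ search is exact, not a
heuristic. Images with fewer distinct levels than classes are rejected as
degenerate.

The lesion mask is the set of pixels *below* $t_2$ — the two darkest
classes, i.e. edge plus body. Including the edge class is a deliberate
reading: excluding it would bias the area, diameter and colour statistics
toward the lesion core (`extract_lesion_mask` keeps the rule in one
place, should a different convention be needed). The initial mask is then
reduced to its largest 8-connected component and interior holes are
filled. Hole filling is not part of the published description but is
required in practice: bright reflections inside the lesion would
otherwise puncture the mask and corrupt the area term of the asymmetry
threshold, the radial border statistic and the colour means. Background
connectivity for hole filling is 4-connected, the topological dual of the
8-connected foreground.

## The four criteria

**Alignment.** The frame is first normalised: the mask centroid is
translated to the raster centre and the frame is rotated so the mask's
major principal axis (from second-order central moments) is horizontal.
The colour image is resampled bilinearly, the mask with nearest-neighbour
lookup re-binarised at 0.5 and re-cleaned; masks with zero second moments
(degenerate) skip alignment with a warning. Area changes above 2% during
alignment are warned about.

**Asymmetry (A, range 0–2).** Two components:

* *Shape*: the non-overlap count $NOVL$ is the number of grid positions
  where the mask differs from its reflection across the centroid line —
  vertical line for the left/right comparison, horizontal for up/down.
  With $T_0 = 5\%$ of the mole area (`delta_a_frac`), the index
  $\Delta A$ is 0 if both counts are at or under $T_0$, 1 if exactly one
  is, 2 otherwise. The published description defines the "1" case with
  overlapping *or*-conditions; "exactly one comparison under threshold"
  is the only reading that partitions the outcomes and is what the
  package implements.
* *Colour*: for each channel (R, G, B) and each split of the lesion
  (left/right and top/bottom of the centroid), normalised histograms of
  the masked pixel values are compared with the chi-square distance
  $\sum_i (h_1(i)-h_2(i))^2/(h_1(i)+h_2(i))$, skipping bins empty in
  both. Histograms use 32 bins over $[0,1]$ (`acolor_bins`) and the six
  distances are averaged (`acolor_agg`, also `sum`/`max`). The method
  states neither the bin count nor the aggregation; the mean keeps
  $A_{colour}$ in $[0,2]$ — each chi-square is bounded by 2 — and
  therefore commensurate with $\Delta A$, consistent with the magnitude
  of the published worked example (0.0262594). A lesion half with no
  pixels contributes the maximal 2.0, with a warning.

$A = (\Delta A + A_{colour})/2$, clamped to $[0,2]$.

**Border (B, 0–8).** Boundary pixels (mask pixels with a non-mask
4-neighbour) are assigned to eight 45° sectors around the centroid,
sector 1 starting east, counter-clockwise. In each sector the population
standard deviation of the centroid-to-boundary radial distance (px) is
computed; sectors strictly exceeding the threshold 15
(`border_threshold`) each add 1. The method says only "the standard
deviation of each" segment with unitless threshold 15; the radial-distance
reading is the standard shape-irregularity statistic and matches the
magnitudes of the published per-sector values (1.6–13.8). An alternative
statistic — the standard deviation of boundary gray levels — is selectable
(`border_stat = "intensity"`) for users who read the criterion as
edge-abruptness. Empty sectors score 0 with a warning.

**Colour (C, 1–6).** The palette holds six clinical colours (white,
black, red, light brown, dark brown, bluish gray), each with six
reference shades normalised by 255. The default distance (`color_mode =
"mean"`) is the minimum Euclidean distance from any shade to the mean
normalised RGB of the masked pixels — one representative distance per
colour, matching a single reported $CX$ per colour; `"perpixel"` instead
takes the minimum over masked pixels and shades, detecting minority
colours. A colour counts when its distance is at or below its threshold
$T_0$; the count is floored at 1. Four thresholds follow the
first-to-last-shade distance rule (white and black 0.339655, light brown
0.588233, dark brown 0.679252, reproducing the published constants at
their printed precision). No simple pairwise rule reproduces the
published red (0.818156) and bluish-gray (0.415973) values — first/last,
maximum-pairwise and mean-centred distances were all tried — so those two
ship as fixed constants, overridable in the palette configuration.

**Diameter (D, 0.5–5).** The mask bounding-box extents $nr_X$ (columns)
and $nr_Y$ (rows) are measured on the aligned mask, so $nr_X$ is the
major-axis extent. The larger extent is converted to millimetres with the
matching axis's mm-per-px ratio; under the default calibration both
ratios are 0.125 mm/px, so the published pairing of $nr_X$ with the
15 mm/120 px ratio is numerically identical to the axis-correct pairing
implemented here (a warning is issued when a custom calibration makes the
ratios differ). The score is the millimetre value clamped to $[0.5, 5]$:
the published score table gives the range with no explicit mapping, and
the integer D values of its worked examples are consistent with direct
clamped millimetre readings.

## TDV and diagnosis

$TDV = 1.3A + 0.1B + 0.5C + 0.5D$. Bands: $TDV < 4.75$ not cancerous;
$4.75 \le TDV \le 5.45$ cancer risk; $TDV > 5.45$ cancerous. The middle
band is printed in the source table with an inconsistent inequality pair;
the closed interval is the only reading that partitions the line, and
both boundary values map to the risk band. Display rounding is two
decimals; all internal values are unrounded. Evaluation against a
specialist's three-way labels (C1 not cancerous, C2 cancerous, C3
possibly cancerous) collapses the $3\times3$ confusion matrix to binary
counts with "not cancerous" as the positive class — a cautious C3 call on
a benign mole counts as a false negative — and reports accuracy,
precision, recall and F1, with `NA` markers for 0/0 ratios.

## The synthetic-lesion generator

`generate_lesion()` renders a star-shaped blob with radial function

$$r(\theta) = \mathrm{ellipse}_{a,b}(\theta)\;[\text{left half: } a\,(1+\beta)] + \alpha \sin(k\theta + 0.7)$$

on a skin-tone background, painted with reference palette shades, with
optional 1-px hair polylines and additive Gaussian noise. Design points:

* **Skin background** is a light tone around gray level 210 with mild
  texture (σ = 2 levels), emulating LED-lit, ambient-light-free capture.
* **Egg-shaped asymmetry**: the left half uses a horizontal semi-axis
  inflated by `asymmetry_bias`. A smooth radial bias of the form
  $1 + \beta(1-\cos\theta)/2$ was tried first and rejected: to first
  order it merely *translates* the blob, and a translated near-circle is
  still reflection-symmetric about its centroid, so it produces almost no
  non-overlap. The two-semi-axis egg produces genuine left/right
  asymmetry while staying up/down symmetric, letting fixtures target
  $\Delta A = 1$ exactly.
* **Boundary irregularity** is a truncated Fourier term
  ($\alpha = $ `boundary_noise_amp` px, $k = $ `boundary_waves`), chosen
  because sector radial deviations are then predictable before
  rasterisation. The boundary geometry is fully deterministic given the
  spec fields — the seed drives only background texture, hair placement
  and pixel noise — so specs differing only in seed share a bit-identical
  ground-truth mask.
* **Dark rim**: the outer 4 px of the lesion are darkened by factor 0.55,
  giving the darkest-edge class the three-class segmentation expects.
  Real lesions show such a boundary transition; width 4 px (0.5 mm) is
  chosen to survive the radius-2 closing, which erases thinner rims and
  with them the third gray mode.
* **Colours** paint each requested palette colour's representative shade
  into angular wedges, left/right halves, or concentric rings. The
  expected colour count is computed from the clean render and exact mask
  at generation time, not assumed equal to the number of painted colours:
  the published thresholds overlap heavily — the red reference ball
  (radius 0.818156 around shades including a light tan) contains every
  dark pigment and even pure white — so a lesion painted with $k$ colours
  legitimately matches more than $k$. This mirrors the published worked
  examples, which report C = 3 for single-pigment moles.

`generate_suite(n, seed)` cycles three archetypes constructed to land in
the three diagnostic bands: a small symmetric dark-brown mole
(TDV ≈ 3.8–4.1), a 9–10 mm egg-shaped mole with $\Delta A = 1$
(TDV ≈ 5.17), and a 7 mm two-colour (black/dark-brown halves), wavy,
strongly egg-shaped mole (TDV ≈ 6.2). Each fixture carries the scores
obtained by running the feature stage on its clean render and exact mask;
the intended band is derived from that clean TDV.

What the generator does **not** emulate: real pigment texture and
gradients, specular reflection, vignetting, chromatic sensor noise,
multi-lesion scenes, and hairs wider than 1 px. Passing tests therefore
demonstrate the correctness and internal consistency of the measurement
chain under controlled geometry — not clinical performance on real
photographs.

## Numerical choices and degenerate inputs

* Otsu tie-break: smallest $(t_1, t_2)$; search is exact and exhaustive.
* Median/closing: reflection padding; medians of integer levels stay
  integer because neighbourhood sizes are odd.
* Rotation: bilinear for the image, nearest-neighbour + 0.5
  re-binarisation for the mask (keeps the mask crisp and area-stable).
* Ties at thresholds: non-overlap counts *at* $T_0$ grade as overlap;
  border deviations *at* 15 do not count ("exceeds" is strict); colour
  distances *at* $T_0$ do count ("less than or equal").
* Degenerate cases: empty initial segmentation raises a typed
  segmentation-failure error; single-pixel masks skip alignment with a
  warning; empty lesion halves contribute maximal colour asymmetry;
  empty border sectors contribute 0; 0/0 evaluation ratios return `NA`.
* All randomness in the synthetic module flows through a spec-local seed
  and the session RNG state is restored afterwards.

## Test problem sizes

The suite validates filters against brute-force oracles on 9×9–15×15
fixtures (100 seeds for the median, 50 random histograms for multi-Otsu),
feature formulas against hand-computed closed forms and the published
worked example, and the end-to-end pipeline on a 26-fixture seeded
synthetic suite at 160 × 120 px — small enough to run in well under a
minute on one CPU while exercising every stage at the method's native
resolution.

## Limitations

* The published per-image intermediates (raw non-overlap counts, sector
  deviations, per-colour distances) derive from photographs that are not
  distributed; they are not reproducible pixel-exactly, and the package
  validates the arithmetic layers above the pixels plus the full chain on
  synthetic ground truth instead.
* One published TDV column (A = 1.32, B = 0, C = 3, D = 3 → printed 4.71)
  recomputes to 4.716 ≈ 4.72 from its printed inputs; the inputs were
  themselves rounded for printing, so only its diagnosis is asserted.
* With the published colour thresholds, a minimum colour score of 1 is
  unattainable in practice (the red reference ball covers the entire
  skin-tone gamut), so C effectively starts at 2; this is a property of
  the published operating point, not of the implementation.
* The border threshold 15 px of radial deviation is large relative to the
  160 × 120 frame: only extreme outlines trigger B > 0 at the native
  resolution, which matches the published example (B = 0 on all eight
  sectors) but limits B's dynamic range at this calibration.
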