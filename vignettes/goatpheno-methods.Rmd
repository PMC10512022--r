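---
title: "Digital goat phenotyping from calibrated field photographs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital goat phenotyping from calibrated field photographs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goatpheno)
```

## The measurement problem

Smallholder goat populations are mostly phenotyped by hand: height at
withers (HW), body length (BL) and chest girth (CG) are taped on a
restrained animal, anemia is scored by holding a FAMACHA card against the
lower eyelid, and age is estimated from erupted incisor pairs. Manual
measurement is slow, needs trained staff, and stresses animals. A posed
photographic protocol replaces most of it with five photographs per
animal — rear, sign (right side with a calibration sign), side ("naked",
no sign), eye close-up, teeth close-up — taken against a blue backdrop and
blue ground tarp, with the camera at eye level and at least 3 m away.

`goatpheno` turns those photographs into phenotypes. Each stage is an
explicit, documented operator rather than a learned model, so every number
can be traced back to pixels:

1. **Chroma-key segmentation.** A pixel is background iff its HSV hue lies
   in the configured blue band (default 190–250°) with saturation ≥ 0.25
   and value ≥ 0.15. Hue is invariant to brightness scaling, which is what
   field lighting mostly changes; a ±20 % exposure shift leaves the
   classification unchanged.
2. **Subject isolation.** Among non-background 8-connected components the
   subject is the largest one satisfying the protocol's priors: area
   within 2–40 % of the frame (0.8 % minimum for the rear view, which
   subtends less area) and centroid within 25 % of the frame diagonal from
   the center. Ties on area break toward the more central component, then
   the topmost-leftmost bounding box. Interior holes are filled; regions
   connected to the outer background (e.g. between the legs) are not.
   When a calibration sign is detected, its quadrilateral is excluded from
   candidacy — the sign is a known fiducial, not a subject.
3. **Boundary refinement.** Every pixel within ±`window_px` (default 5) of
   the initial boundary is reclassified by where the strongest color step
   lies along its outward normal (estimated from the smoothed mask). The
   pixel is foreground iff the maximum forward color difference along its
   normal sits at or beyond it. On a step edge this reproduces the true
   boundary exactly — a 3-px dilated or eroded mask snaps back
   pixel-for-pixel — and on a Gaussian-blurred edge (sd 2 px) the mean
   displacement stays below one pixel. Flat neighborhoods (step magnitude
   below `min_grad`, default 8 summed channel units) keep their original
   label, and a refinement that destroys the component falls back to the
   unrefined mask with a `REFINE_FALLBACK` flag.

## Calibration from the sign

The sign is a black-bordered board carrying "pure" red, green and blue
blocks, held in the animal's plane. Detection looks for dark connected
components whose extreme points form a convex quadrilateral, scores the
fraction of the quadrilateral perimeter that is dark (`border_score`,
acceptance at ≥ 0.7, low-confidence 0.5–0.7), and requires the interior to
contain ≥ 100 px each of red-, green- and blue-dominant pixels in
left-to-right order.

**Spatial scale** is the mean of the width- and height-based ratios of
physical size (default 40 × 30 cm, configurable — the protocol does not
fix the printed dimensions) to pixel extent, using corner-to-corner edge
lengths plus one. Edge lengths are rotation-invariant, so scale survives
in-plane skews; at ±10–15° the error stays under 1 %.

**Color correction** is an affine map (3×3 matrix + offset) solved exactly
per channel from the four references: border black plus the three blocks.
With only four reference colors, anything beyond affine would overfit.
The default block references are the *measured printed-card* values
(190, 0, 0)/(0, 190, 0)/(0, 0, 190) rather than digital-pure 255: a
printed card never reaches 255 in camera, and ink-level references keep a
+30 % exposure shift on-range and therefore invertible. Real measured
card values can override the defaults in config. Corrected outputs are
clamped to [0, 255]; the reported residual is the mean per-channel error
on the references.

## Morphometry

Only the sign view and the rear view are needed for body measures; the
side "naked" view serves coat extraction. Because the final protocol
abandoned physical bone marking, landmarks are located by fractional
silhouette bands (all configurable):

- **Ground row**: the median of the two lowest leg-column extremes —
  robust to one raised foot. Columns qualify as legs when their silhouette
  reaches into the lowest 20 % of the mask.
- **Height at withers**: the topline maximum within the band 20–45 % of
  the body span behind the front of the animal, after cutting columns
  ahead of the neck inflection when the head crests above the topline
  (detected as a local topline dip behind the front-most peak).
  HW = (ground − withers row) × scale.
- **Body length**: foremost and rearmost mask pixels within the chest
  band at 45–75 % of body height; among tied extreme-column pixels the one
  nearest the band center is used, so the measure follows the horizontal
  body axis. BL is the Euclidean distance × scale.
- **Chest depth** (side): maximum vertical silhouette extent over the
  column band reaching 55 % of the span back from the foremost non-leg
  column, legs excluded ("just behind the elbows").
- **Chest width** (rear): maximum horizontal extent in the upper 70 % of
  the rear mask.
- **Chest girth**: the protocol derives girth from the side and rear
  poses but publishes no formula; this package models the chest
  cross-section as an ellipse with axes (depth, width) and reports its
  perimeter by Ramanujan's second approximation, which is accurate far
  beyond the 0.1 % we assert against adaptive quadrature. The perimeter
  bound CG ≤ π(depth + width) is enforced at construction.
- **Body weight** is a pluggable formula; the default is the classic
  girth-squared rule BW = CG²·BL / k with k = 10838 in cm/kg units.
  Weight prediction is deliberately out of the validation surface.

The right-side convention (animal faces right) is detected from the mask
itself — the muzzle end has no leg under it — and left-facing masks are
mirrored with a `MIRRORED` note.

`validate_measures()` correlates digital against manual tables by
`sample_id` with `stats::cor()`; tests hold it to the textbook two-pass
formula at 1e-12. PB and SB (pin-/shoulder-bone widths) remain
manual-only input fields: their digital marking was dropped from the
protocol.

## Health phenotypes

**FAMACHA.** The conjunctiva is the largest connected region of
color-corrected pixels within a configured RGB distance (default 60) of
any of the five reference colors; its mean corrected color is assigned to
the nearest reference in CIELAB distance, with ties breaking toward the
more anemic category (clinically conservative). The five references are a
pale-to-red ramp in config — the physical card's colors are proprietary,
so the generator and the scorer share one configured ramp, which is
exactly the self-consistency the tests need.

**Tooth age.** Tooth pixels are bright and low-chroma (min channel ≥ 180,
channel spread ≤ 40). Regions split into permanent vs deciduous by area:
permanent requires both ≥ 50 % of the largest region *and* an absolute
minimum fraction of the frame (0.8 %). The relative rule alone cannot
distinguish an all-deciduous mouth from an all-permanent one; the
protocol's fixed close-up framing keeps scale roughly constant, which is
what licenses the absolute floor. Half the permanent count, clamped to
0–4 pairs, maps through a configurable age-class table.

## Coat color and pattern

Corrected silhouette pixels from the side view are clustered with k-means
(fixed seed, 10 restarts; K capped at 3 and reduced to the number of
distinct colors). Clusters under 5 % merge into their nearest neighbor —
shadow suppression. The coat is "solid" iff the top cluster holds ≥ 90 %.
The pattern is "vectorized" as the cluster-label grid down-sampled 8×
(majority label per block) plus a run-length encoding for export.

## The synthetic-scene generator

Field data is not shipped with the package; every stage is instead
validated against a deterministic generator with exact ground truth. A
scene is built in centimeters on the subject plane and rasterized at a
configured pixels-per-cm (default 5 px/cm on an 800 × 1000 frame; the
protocol's fixed camera distance and in-plane sign make one scale valid,
so no 3-D rendering is needed). The goat is a parametric composite:
superellipse trunk (exponent 4, so the topline is flat and the chest keeps
its full depth over most of the body), neck capsule, elliptical head
(default just below the withers; a raised head exercises the neck-dip
exclusion), and four legs whose leading edge is flush with the point of
shoulder — as in the animal, the foreleg stands under the shoulder, which
is what anchors the length measure when a shallow chest leaves the band
on the legs. Renders are noiseless by default: the step-edge silhouette
is the study condition under which refinement is specified to be exact.
Eye scenes add Gaussian channel noise (default sd 4) to the conjunctiva.

Injectable defects reproduce the documented field failures: handler limbs
near the subject (skin- or scrub-blue-toned), rocks hiding the feet (the
visible silhouette stops above the ground line), a dirty tarp (a grid of
mud patches, each below the subject-size prior so dirt never impersonates
the subject), a missing ground tarp (the subject fuses with non-blue
ground and reaches the frame border), global lighting gains, and a skewed
sign. Ground truth records the exact mask, scale, landmark pixels, sign
corners and defect inventory.

What passing these tests shows — and what it does not: the pipeline
recovers its own generator's geometry essentially perfectly (correlations
≥ 0.99 on a 200-animal cohort, median relative errors well under 2 %), so
the published field correlations (0.931/0.943/0.893 for HW/BL/CG) act as
lower bounds that clean synthetic data must clear. Real goats have
texture, hair, posture variation and soft shadows that the generator does
not emulate; the synthetic surface validates the algorithmic contracts,
not field performance.

## Numerical choices and degenerate inputs

- Coordinates are 1-based (row, col), origin top-left — the native R
  matrix convention — used consistently across every module.
- Half-open rendering in cm means a W-cm feature spans exactly
  `W * ppcm` pixels; pixel extents are corner distances plus one.
- Cohort dimensions are drawn uniformly: HW 40–90, BL 50–100, chest depth
  20–40, chest width 12–30 cm. Draws with depth ≳ 0.8·HW produce
  belly-on-the-ground silhouettes whose legs cannot be resolved; these
  error out ("legs not resolved") and are reported as missing, not
  guessed.
- k-means on a solid coat would fail with more centers than distinct
  colors; K shrinks to the number of distinct colors.
- QC never raises: every check emits flags, and a scene whose priors
  reject all components is flagged from the largest foreground component.
- Problem sizes in the validation suites (200-scene cohort at 800 × 1000,
  100 mask scenes, 50 calibration scenes, 250 eyes, 30 scenes per defect)
  are the package's chosen study conditions, balancing statistical
  resolution against a few minutes of runtime.

## Known limitations

- The elliptical girth model ignores cross-section asymmetry; on real
  animals CG is systematically underestimated for slab-sided chests.
- Band-based landmarks assume a standing, roughly horizontal posture.
- The FAMACHA ramp and sign dimensions are configured stand-ins for
  physical products; deployments must measure their own card and sign.
- No lens-distortion correction; the protocol's ≥ 3 m distance keeps it
  second-order.
- One animal per scene; multi-goat separation is out of scope.
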