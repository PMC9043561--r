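---
title: "Measuring inner-wall cell morphometry and connectivity from serial-section contour stacks"
author: "vacuomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inner-wall cell morphometry and connectivity from serial-section contour stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacuomorph)
```

## The measurement problem

Aqueous humor leaves the eye through the trabecular meshwork and crosses the
inner-wall (IW) endothelium of Schlemm's canal, either through giant vacuoles
(GVs) — pressure-driven outpouchings of individual IW cells that can open
basally toward the juxtacanalicular tissue (JCT) and apically through
intracellular pores (I-pores) — or through intercellular pores (B-pores)
between adjacent IW cells. Outflow is segmental: different circumferential
sectors of the same eye carry high, low or essentially no tracer flow.
Serial block-face electron microscopy yields aligned section stacks
(0.0101 µm pixels, 0.13 µm sections) in which individual IW cells can be
traced section by section as closed contours, reconstructed in 3D, and
compared across flow-type areas.

`vacuomorph` implements the quantitative half of that workflow. Its input is
a *labeled contour stack*: per section, closed polygons in physical
micrometres tagged as the reconstructed cell envelope, its nucleus, its GVs,
adjacent IW cells, JCT cells/matrix anchors, IW–JCT connection endpoints,
and pore/opening annotations. Openings and the *structural category* of a
connection (which of the seven cell–cell/cell–matrix configurations it
represents) are explicit annotations rather than inferred from the traces:
in the original manual workflow these are qualitative calls made at the
microscope ("clear separation with smooth borders") that have no reliable
geometric signature in the contours alone. Everything quantitative —
lengths, widths, thicknesses, volumes, overlap lengths, projection heights,
contact areas, counts — is computed from the geometry by the package.

## Measurement conventions

* **Length** is the through-stack convention: (last − first section + 1) ×
  0.13 µm. The cells lie along the stack axis, so the z-trace reduces to a
  section count.
* **Width** is the length of a segmented line of at most three segments that
  spans the cell's lateral extent while following the curvature of the inner
  wall. We extract the profile's midline (below), choose the two breakpoints
  by minimising the midline's maximal deviation from the polyline, and
  report the polyline length. Nuclear width is measured once, on the section
  with the largest nuclear cross-sectional area; non-nuclear width is the
  mean over nucleus-free sections sampled every 40 sections.
* **Thickness** operationalizes the border-chord construction: the chord
  joining the two lateral cell borders is bisected, the perpendicular
  bisector fixes a locus on the midline, and thickness is the envelope
  extent perpendicular to the local midline axis at that locus. Non-nuclear
  thickness samples every 40 sections on sections free of both the nucleus
  and any GV; ineligible samples substitute the nearest eligible section
  within ±5, else they are skipped with a log message. The sampling anchor
  is the first section on which the cell appears (the source protocol does
  not state one; this choice is deterministic and reproducible).
* **Volume** is the section sum of envelope contour areas × 0.13 µm, minus
  the section-summed GV volumes, because the cell traces encompass the GV
  lumina. GV volumes use the same section-sum rule (the serial-section
  analogue of a volume tool).
* **Overlap length (OL)** between the cell and each adjacent IW cell is
  measured every 40 sections on both sides. The adjacent cell's boundary
  points lying on the envelope (within 2 pixels) are projected onto the
  envelope, split into near-straight pieces, and each piece contributes its
  extent if it lies within 45° of the local IW axis — the 45° boundary is
  counted, since the exclusion rule is stated as *greater than* 45°. Around
  each B-pore, OL is additionally measured on the nearest junction-bearing
  sections before and after the pore; this is a measurement, never an
  assertion, so a fixture with non-zero overlap around a pore reports that
  overlap (with a validation warning).
* **Connections** are grouped by object id (a connection spanning several
  sections is one countable object). Projection height is the largest
  distance from the connection's vertices to the cell envelope; contact area
  of a flat apposition is the section sum of apposition lengths × 0.13 µm.
  Types 1–6 count if the height is at least 0.3 µm, type 7 if the area is at
  least 0.5 µm² (inclusive boundaries, "at least"); measured values are
  rounded to the pixel quantum first so that rasterization noise cannot flip
  a value across the boundary.
* **Beneath-GV counting** restricts to connections whose section span
  intersects the GV's span *and* whose anchor lies within the GV's lateral
  footprint dilated by a margin (default 0.5 µm). The footprint restriction
  is the biologically coherent reading of "connections beneath the GV"; the
  alternative reading — every connection on the GV's sections — is available
  as `mode = "section"` in `connections_beneath_gv()`.
* **GV types** are the bijection on the two opening flags: neither → I,
  basal opening only → II, I-pore only → III, both → IV.

### The midline

Widths, thicknesses, and the 45° rule all need a local "axis of the inner
wall". Manual measurement draws it by eye; the reproducible analogue used
here is a medial polyline of the cell profile. The boundary is densely
resampled, the lateral axis is found by principal components and then
refined so that the basal (flatter) boundary fits a line best — a tall
nuclear bulge can otherwise tip the principal axis toward the apical–basal
direction, so the alternative axis is adopted whenever the default axis
leaves no boundary side that is even approximately straight. Profiles are
binned along the axis (0.15 µm bins); in bins whose height exceeds the
ribbon thickness (estimated from a low quantile of bin heights) the midline
is offset from the basal side by half the ribbon thickness, which keeps
nuclear and vacuolar bulges from deflecting it. The midline is smoothed over
a 2 µm window, and its endpoints are taken where the mid-height line meets
the end caps. All of this is rotation- and translation-invariant, which the
test suite checks explicitly.

## The synthetic-cell generator

No traced stacks are publicly deposited, so validation uses a parametric
generator (`generate_cell()`, `generate_dataset()`) whose ground truth is
known exactly. Each cell is a thin, gently curved ribbon — the monolayer
seen in cross-section, curvature radius 120 µm by default — extruded along
z, with an ellipsoidal nuclear bulge, ellipsoidal GVs that stay inside the
cell trace while bulging apically, finger-like connection processes and flat
appositions on the basal side, adjacent-cell ribbons overlapping the apical
surface by a prescribed OL, and explicit B-pore gaps where the borders
separate and the junction re-forms on flanking sections. Vertices are
snapped to the 0.0101 µm pixel grid, so recovery tests see genuine
quantization error. Ground truth records the analytic (pre-rasterization)
dimensions and ellipsoid volumes; overlap length is the one exception — its
recovery tolerance (±0.01 µm) is below one pixel, so truth records the
drawn, snapped junction extent.

Population defaults are the study conditions: per-area dimension means with
SD = SEM·√15 (15 cells per area), Poisson GV counts with means 7.0/4.4/4.2,
Poisson connection counts per type whose per-area means reproduce the
reported totals (18.5/15.7/33.1 cell–matrix; 8.1/29.3/26.0 cell–cell, with
unreported type-2/3/4/6 cells filled in so the rows sum correctly), per-area
GV-type proportions consistent with the overall 67/127/7/33 distribution and
the per-area pore-bearing GV counts, and mean OL 0.18/0.29/0.23 µm. GV sizes
are a modelling choice (log-normal radii, pore-bearing types drawn 1.5×
larger), since only medians/IQRs of derived ratios are reported. The
`table1_fixture` preset replaces the stochastic counts with a fixed
allocation — 105/66/63 GVs, 20/15/6 I-pores on 20/14/6 GVs (one low-flow
type-IV GV carries two), 3/2/7 B-pores on 3/2/4 cells — so the published
per-area count arithmetic is reproduced exactly.

Two published quantities are *not* jointly representable in this geometry:
the mean connections beneath a GV (2.4/4.6/5.2 per GV) and the per-cell
percentage of connections under GVs (44.6/41.2/31.6%) would require either
overlapping GV footprints or connections counted under several GVs. The
generator matches the percentage dial; the per-GV beneath means consequently
come out lower. Neither quantity is used as an acceptance check.

What the generator does *not* emulate: real section-to-section tracing
jitter beyond a smooth lateral wobble, oblique cells (the z-trace equals the
section count by construction), curved or branching cells, GVs that overlap
in z, partial-volume effects at section boundaries, or any grayscale
appearance. Passing the recovery suite therefore demonstrates that the
measurement code is correct on clean, in-tolerance traces — not that it is
robust to degraded manual tracing.

## Statistics

Per-cell metrics are compared across flow areas by one-way ANOVA with Tukey
HSD post-hocs; beneath-GV connections per unit GV volume are compared across
GV types by Kruskal–Wallis with pairwise two-sided Wilcoxon rank-sum
post-hocs (medians and IQRs reported alongside), matching the small and
skewed type-III group. SEM is sd/√n with the n−1 denominator. Wilcoxon
p-values are exact for tie-free groups of at most 20 and use the normal
approximation with continuity correction otherwise; **no multiplicity
correction is applied to the post-hoc Wilcoxon p-values** — they are
reported as unadjusted pairwise post-hocs, which callers should keep in mind
when more than a few pairs are examined. Cells with zero counted connections
have an undefined percent-under-GV and are excluded from that mean with a
log entry. The test suite checks the ANOVA/Tukey/Kruskal–Wallis/Wilcoxon
implementations against independently coded closed-form oracles
(sums of squares + `ptukey`, midrank H + `pchisq`, `pwilcox`/normal
approximation) to 1e-10, and calibrates the ANOVA type-I error rate at
5% ± 1.5% over 1000 null replicates with 15 cells per group.

## Numerical choices and degenerate inputs

* Polygon areas use the shoelace formula after orientation normalization;
  contours with fewer than 3 non-collinear vertices are rejected.
* Coordinates serialize with 6 decimal places, so a stack survives a
  write/read round trip to within 5·10⁻⁷ µm.
* Thresholds compare after rounding to the pixel quantum; generator specs
  keep heights/areas at least 2 pixels from the thresholds unless a boundary
  is deliberately tested.
* Zero-variance comparisons return `p = NaN` with a warning; empty groups
  are dropped with a warning; an area with no GVs reports a zero percentage
  flagged as undefined.
* A GV traced outside its cell's envelope makes the subtracted cell volume
  negative and raises an inconsistency error rather than clamping.

## Problem sizes

The recovery suite rasterizes the full 45-cell fixture (cells of 30–135 µm,
i.e. roughly 230–1040 sections each, ~2000 connections, 234 GVs) and runs
the complete measure/classify pipeline on it; the statistical calibration
uses 1000 null replicates. The pipeline demonstration in the tests uses one
cell per area. These sizes exercise every code path at the study's own scale
while keeping a full check run to a few minutes on a single core.

## Limitations

Pore identification quality (smooth vs. ragged openings, knife-mark
exclusion) is upstream of this package: openings are trusted annotations.
The two donor eyes of the original material are pooled, as in the source
protocol; no eye-level random effect is modelled. The segmented-line width
is capped at three segments, so strongly S-shaped profiles would be
under-measured; the midline construction assumes a ribbon-like profile and
one dominant basal surface.
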