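---
title: "Lung-side-specific adaptive-threshold airway segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung-side-specific adaptive-threshold airway segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayseg)
```

## The model

Airway lumen is air (about -1000 HU) surrounded by soft-tissue walls
(around -100 HU) inside lung parenchyma (about -850 HU with substantial
noise). Connected-threshold region growing segments the lumen from a seed:
a voxel joins the region if it is connected to the seed through voxels with
`HU < T`. The only free parameter is the threshold `T`, and it controls a
sharp trade-off: too low and peripheral branches with partial-volume-dimmed
lumina are missed; too high and the front escapes through a blurred wall
into the parenchyma, where roughly half of all voxels sit below any
threshold above the parenchyma mean - the segmentation "explodes". The
package therefore raises `T` iteratively and watches for that explosion,
and it does so *separately* for the trachea, the right lung and the left
lung, each within its own working region, so that the threshold can stop
early on a leaky side without sacrificing the other.

Leakage is recognized by three mechanisms:

* geometric guards on the trachea label (a clean trachea near the seed is a
  narrow tube; a leak fills the crop),
* the growth ratio `g = N_voxels / N_voxels_prev` between segmentations at
  consecutive thresholds, flagged when `g > g_max = 1.6`,
* a per-lung voxel budget `N_max = p * N_trachea`. The percentage `p` comes
  from a lookup keyed by reconstruction-kernel group (smooth standard /
  lung-sharp / very sharp / other), axial slice count `S` and trachea voxel
  count `N`. Band boundaries are inclusive on the upper side exactly as
  tabulated. Scaling the budget by the trachea size adapts the stopping
  rule to subject size and resolution without any absolute volume constant.

## Thresholds and schedules

| key | default | meaning |
|---|---|---|
| `start_hu` | -900 HU | first trachea threshold |
| `cap_hu` | -800 HU | hard upper bound for every region |
| `step_down_initial` | 20 HU | decrement while the initial trachea label leaks |
| `step_up_clean` / `step_up_after_leak` | 50 / 10 HU | improvement increments |
| `step_down_final` | 10 HU | recovery decrement after a rejected step |
| `floor_hu` | -1024 HU | terminates pathological decrement loops |
| `start_hu_lung` | -1100 HU | first lung threshold (below any plausible lumen HU; empty grows climb in 50 HU steps) |
| `g_max` | 1.6 | growth-ratio leak cut-off, strict comparison |
| `dilate_radius_vox` | 1 | final reconnecting dilation |

Two schedule details are deliberate design choices rather than forced by
the procedure's verbal description:

* **Strictness.** The inclusion rule is `HU < T` (a voxel exactly at the
  threshold is excluded) and the ratio rule flags only `g > 1.6`; both
  boundaries are tested.
* **Termination after recovery.** After a rejected step the threshold is
  lowered in 10 HU decrements until a clean label appears, and that label
  is final. Continuing upward in 10 HU steps from there would immediately
  re-test a threshold already rejected, oscillating forever; stopping at
  the highest clean threshold below the rejection is the fixed point of
  that process.
* **Height rule.** When the difference between consecutive trachea labels
  is shorter than 1/3 of the crop height, the addition is local and the
  loop ends as converged (`height_rule = "converge"`). The alternative
  reading - treating a short difference as a leak - is available as
  `height_rule = "leak"`; on phantoms both give the same final label, since
  the first empty difference ends the loop either way.

The trachea guard measures the label's width (along `i`) and length (along
`j`) as bounding-box extents within a 5-slice axial slab centered on the
seed slice (`guard_slab_slices`). Fixed sub-windows that clip the
measurement itself (e.g. measuring inside a 21-voxel window while the leak
cut-off sits at a quarter of a 128-voxel crop) would cap the measured
extent below the cut-off and could never fire, so the slab-based
measurement was chosen: it is local to the seed along the scan axis but
unrestricted in-plane, which is what an in-plane explosion changes.

## Masking and the opposite-bronchus plug

To segment one lung, the half of the trachea label distal to it (split at
the sagittal plane through the trachea centroid, rounded half-up) is set to
0 HU - far above any airway threshold - and growth starts from that lung's
bronchial seed. The unmasked half deliberately remains passable: the region
climbs back up the trachea, which also recovers accessory branches that
leave the trachea above the carina (present in pig anatomy, exercised by
the phantom's `supra_carinal` option). The opposite main bronchus is closed
by a spherical 0 HU plug below the opposite seed. A fixed plug radius
cannot work: any plug smaller than the bronchus lumen is simply grown
around. The plug radius therefore adapts - the equivalent-area radius of
the opposite carina-slice component plus `plug_margin_vox` (2) voxels - so
the lumen is covered with margin at every phantom scale.

## The synthetic phantom

The phantom emulates what the pipeline needs from a chest CT: a dark,
connected airway tree with walls, embedded in noisy parenchyma, with known
geometry. It is a symmetric dichotomous tree (trachea = generation 0) of
rigid tubes in one branching plane, rasterized at 0.7 mm isotropic spacing
on a 128-cube grid. Defaults: trachea lumen radius 7.5 mm (adult-like
caliber), child/parent radius ratio 0.55, branch lengths 30/20/12 mm,
half-angle 35 degrees, wall thickness 1.5 mm, lumen -1000 HU, wall
-100 HU, parenchyma -850 +/- 30 HU, body shell +40 HU, smooth-kernel
metadata ("B30f").

Design rationale, decided once:

* **Budget-compatible proportions.** One lung-side region contains half the
  trachea, the small above-seed trachea segment, and one bronchial subtree.
  The voxel budget grants a smooth-kernel scan of this trachea size
  (N under 2x10^4 voxels) 90% of the trachea count, so the subtree must
  stay below about 40% of it; the 0.55 radius ratio and the shortened
  branch lengths keep the clean side total near 80% of the budget. The
  geometry is thus deliberately not Weibel-realistic (real child/parent
  ratios are nearer 0.75); realism here means *the relations the method
  relies on*, not airway morphometry.
* **Noise on parenchyma only.** Lumen and wall HU are exact. This keeps the
  zero-noise phantom exactly four-valued, makes truth labels noise-free,
  and concentrates stochasticity where it matters for the method: in the
  parenchyma that a leak floods, and in the wall defects (which are
  converted to noisy parenchyma). Real CT noise also lives in the lumen;
  its main effect - percolation of the growth front through the lumen at
  thresholds near the air peak - is not modelled, and the threshold
  schedules on phantoms are consequently cleaner than on clinical data.
* **Defects as parenchyma, not air.** A defect sphere replaces wall voxels
  with noisy parenchyma, so whether the leak channel opens depends on the
  threshold - exactly the failure mode the leak criteria exist for. At
  -900 HU about 5% of defect voxels are passable (no connected channel);
  at -850 HU half are, the channel percolates, and the grown region jumps
  by orders of magnitude.
* **Flat terminal tips, sealed top.** Terminal branch lumina are cut flat
  at the analytic endpoint (the rounded wall capsule seals them) so that
  centerline lengths are comparable to the analytic `sum of L` without a
  per-tip correction; the trachea is cut flat at its superior end and
  closed by a wall plate, like a scan cropping the airway.
* The per-lung budget percentage itself is *not* a phantom parameter: it is
  taken from the same kernel/S/N lookup the pipeline uses on real scans.

Determinism: the only random element is the parenchyma noise field, drawn
in one pass over the full grid under `rng_seed`, so phantoms differing only
in their defect lists are voxel-identical outside the defect spheres.

## Centerline metrics

Branch count and length are computed from a one-voxel centerline obtained
by topological curve thinning (sequential deletion of simple, non-endpoint
border voxels in six directional subiterations). Skeleton voxels with a
26-neighbour count different from 2 become nodes; chains between nodes
become branches with spacing-weighted polyline lengths. Three clean-up
rules make the graph robust:

* fat junctions thin into small triangles of sub-voxel edges - internal
  edges shorter than the spur threshold are contracted;
* terminal spurs shorter than `min_spur_mm` (2 mm, never less than three
  times the coarsest voxel dimension, so one-slice stubs on thick-slice
  data are not counted) are pruned, shortest first;
* thinning retracts endpoints from tube ends by about one radius, so
  terminal branches are extended along their end tangent to the label
  surface.

Branch counting is fully automatic; a human observer counting "correctly
segmented branches" on a rendering applies anatomical judgment this
definition does not attempt to encode.

## Numerical and convention choices

* Voxel indices are 1-based with inclusive crop bounds (R convention);
  axis `i` runs right-to-left, `j` anterior-to-posterior, and `k`
  superior-to-inferior, so the carina search simply scans increasing `k`.
  External physical coordinates use DICOM LPS; NIfTI RAS headers and
  fiducial files are converted on read, and volumes whose slices are
  ordered feet-first are flipped so `k` always increases towards the feet.
* Growing connectivity is 6 (faces): it cannot slip diagonally through a
  one-voxel wall gap; 26 is available via `connectivity`.
* Minimum axial component area for the carina split and seed placement is
  5 voxels, ignoring single-voxel noise components.
* Bronchial seeds are component centroids snapped to the nearest in-label
  voxel (a concave component's centroid may fall outside it).
* The reported airway volume is measured before the final dilation: the
  dilation exists to reconnect parts and adds a one-voxel surface shell
  (about +20% on tubes of this caliber), which would bias volumetry;
  the dilated volume is reported alongside. Branch metrics use the dilated
  label, whose smoother surface thins more cleanly.

## What the tests do and do not show

The test suite runs the full pipeline on the 128-cube phantom (about 2 s
per run after a sub-second rasterization), plus an 80-cube phantom for
module-level tests and 12-cube volumes for the flood-fill oracle
comparison. Passing them shows the machinery is faithful on a geometry
where ground truth is analytic: thresholds follow the declared schedules,
leaks through a known defect are rejected and contained within the voxel
budget, the uninvolved side is bit-identical, and recovered branch count,
length, volume and carina position agree with construction. It does not
show clinical accuracy: real airways bend, taper and branch
asymmetrically, lumen HU varies with inspiration and partial volume, and
walls thin peripherally - none of which the phantom models.

## Known limitations

* No peripheral-branch rescue: once a leak criterion stops the growth, no
  morphology- or vesselness-based recovery is attempted, and a single
  threshold serves a whole lung.
* DICOM series input is not supported (NRRD/NIfTI only).
* The thinning-based branch definition differs from anatomically labelled
  counts; comparisons should be within-method.
* Oblique acquisitions (non-axis-aligned direction matrices) are rejected
  on read.
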