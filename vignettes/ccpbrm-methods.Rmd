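---
title: "Models and methods behind ccpbrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccpbrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccpbrm)
```

## The imaging model

Circular crossed-polarized birefringence microscopy (CCP-BRM) images a
tissue section between two opposite-handed circular polarizers. Myelinated
axons are strongly birefringent: light traversing a sheath of thickness $d$
(µm) with index difference $\Delta n = n_e - n_o$ accumulates a retardance

$$\delta = \frac{2\pi\, d\, \Delta n}{\lambda},$$

implemented in `retardance()` with $d$ and $\lambda$ reduced to a common
length unit. Each circular polarizer is a linear polarizer plus a
quarter-wave plate (QWP). A zero-order QWP has a fixed optical path
difference of $\lambda_0/4$, so at wavelength $\lambda$ its phase retardance
is $\Gamma = (\pi/2)\,\lambda_0/\lambda$ (`qwp_retardance()`): exact at the
design wavelength, too large for bluer light, too small for redder light.

The transmitted intensity of the full chain — polarizer, QWP at $+45^\circ$,
sample retarder of strength $\delta$ with optic axis at $\theta$, QWP at
$-45^\circ$, crossed polarizer — has the closed form used by
`ccp_intensity()`:

$$I = I_0 \sin^2\!\frac{\delta}{2}\,
      \left(1 - \cos^2\Gamma \cos^2 2\theta\right).$$

The form was derived symbolically from the 2×2 complex Jones-matrix product
and is cross-checked in the test suite against an independent numeric
Jones implementation to below $10^{-9}$. Two limits anchor the physics:

* $\Gamma = \pi/2$ (ideal plates, the camera's green band): $I = I_0
  \sin^2(\delta/2)$ for *every* orientation — fibers are bright on a dark
  background with none of the extinction crosses of linear polarizers.
* $\Gamma = 0$ (no plates): $I = I_0 \sin^2(\delta/2)\sin^2 2\theta$, the
  classic crossed-linear-polarizer result.

Because the red and blue camera bands see detuned plates
($\Gamma \ne \pi/2$), their intensity regains a $\theta$ dependence while
green does not; the R/G and B/G ratios therefore encode local fiber
orientation as color. Defaults are $\lambda_0 = 550$ nm with channel bands
610/550/470 nm. These are deliberate placeholders of the right magnitude —
the actual camera bands and plate design wavelength of any given microscope
should be set in `optical_config()`; nothing downstream depends on the
specific values.

## The synthetic phantom

`generate_phantom()` builds scenes that emulate fiber-rich cortical tissue:
anti-aliased fiber strokes (thickness ~1 µm, $\Delta n = 0.12$ by default,
chosen to place $\delta$ in the mid-contrast range of $\sin^2(\delta/2)$),
planted fiber defects (retardance gaps for breaks, local thickness bumps
for swellings/blebbings), bright vesicle rings sharp in exactly one
z-plane, and transverse-axon confounders — the same ring replicated over at
least three consecutive planes, which is precisely what the z-plane filter
must reject. Geometry defaults mirror volumetric slide-scanner acquisition:
0.226 µm/px laterally, 1.3 µm z-steps. Out-of-focus planes receive a
Gaussian blur growing at 0.6 px of sigma per µm of defocus; Gaussian read
noise (2% of $I_0$) and optional Poisson shot noise are added under the
scene seed, so rendering is bit-reproducible.

Ground truth (class, box, plane) is derived from the scene parameters, not
from the rendered pixels, so every downstream stage can be scored exactly.
What the phantom does **not** model: scattering, polarization aberrations
of the objective, tissue autofluorescence, stitching artifacts, fiber
crossings dense enough to mimic pathology, and the long-tailed morphology
of real defects. Passing tests on phantoms therefore validates the
*geometry and bookkeeping* of the pipeline (windowing, NMS, z-filtering,
matching, metrics) — they say nothing about detector accuracy on real
tissue, which is exactly why the detector itself sits behind a plugin
contract.

## Volumetric inference

`run_inference()` tiles each plane with 100×100 px windows at 50% overlap
(stride 50), upsamples each crop to 640×640 (bilinear) for the detector,
and maps boxes back by dividing by the 6.4 scale factor and adding the
window origin. The overlap desensitizes tiled detectors to small
translations; the final window on each axis is clamped to the image edge
rather than padded, so coverage is complete without invented pixels.

Pooled detections pass greedy per-plane, per-class NMS (IoU 0.5 default —
the threshold is not dictated by the workflow, so it is a parameter), then
the z-plane filter: vesicle detections are linked across consecutive planes
by best-IoU greedy matching (link IoU 0.2, the same overlap criterion used
for validation matching) and any vesicle chain spanning ≥ 3 consecutive
planes is removed in full, as those are typically transverse axons rather
than debris. Defect-class detections are never removed by the filter, and
NMS runs within a class: both scoping choices are configurable because
other conventions exist. `density_heatmap()` counts defect centers per
sliding window; with 50% overlap a center can increment up to four cells,
so the grid is a density surface rather than a partition.

## Human-in-the-loop pseudo-labeling

Each iteration of the workflow is `export_proposals()` →
`ingest_review()` → `assemble_dataset()`. Proposals are detections above a
deliberately low confidence threshold (default 0.15), because reviewers
only accept or reject — they never add boxes, so a missed detection would
go uncorrected. Review decisions are ternary: accepted proposals become
annotations attributed to `"model+review"`; challenging false positives
(`reject_background`) export their enclosing 100×100 inference window as a
background image with an empty label file, feeding the detector its own
mistakes; plain rejections are dropped. The assembler accumulates
iterations, deduplicates windows by (stack, origin, plane), clips boxes to
their windows (flagging clipped records), enforces that reserved validation
stacks never appear in training rounds, and emits a byte-stable manifest so
assembly is idempotent. Retraining itself is outside the package: any
detector honouring the plugin contract can be refit on the exported YOLO
dataset.

## Evaluation

Consensus ground truth follows the 2-of-3 protocol: same-class annotations
from distinct raters are linked when IoU ≥ 0.2 and planes differ by at most
1, clusters are formed by single linkage, and clusters supported by at
least `min_raters` raters become consensus boxes. The merged geometry is
the coordinate-wise mean box with integer median z — the protocol does not
prescribe a merge rule, and the mean is symmetric and order-independent. If
one rater contributes two boxes to a cluster, the one agreeing best with
the other raters is kept and the duplicate is logged.

Matching is greedy one-to-one in descending confidence with explicit tie
breaks (higher IoU, then smaller plane distance, then lower ground-truth
index) so results are reproducible. Two IoU regimes are kept strictly
separate: 0.2 with ±1 plane for the expert-consensus validation protocol,
0.5 for AP@50. Average precision uses all-point interpolation (the area
under the running-max precision envelope over recall); a 101-point variant
is available behind a flag for comparison with COCO-style tooling. The
summary mAP weights per-class AP by ground-truth class frequency of the
evaluated set (an override is exposed, since frequencies could also be
taken from a training set), reflecting the heavy defect/vesicle imbalance.

Reliability statistics: `icc_two_way_mixed_single()` computes both
single-measure forms from the two-way ANOVA mean squares — consistency
ICC(C,1) $= (MS_R - MS_E)/(MS_R + (k-1)MS_E)$ with its exact F-based CI,
and absolute-agreement ICC(A,1) with a Satterthwaite CI — and labels them
explicitly, because "two-way mixed, single measures" alone does not
identify which form a statistics package reported. Pairwise
Pearson tests divide the family alpha by the number of pairs (0.05/6 ≈
0.0083 for four raters), and `count_correlation()` reports $r$, the
two-tailed $p$, and $r^2$.

## Numerical choices and degenerate inputs

* Boxes are 0-based, half-open `[min, max)`; z-indices 0-based — IoU
  arithmetic needs no ±1 corrections.
* YOLO export writes nine decimals, so label round trips are exact to well
  under the half-pixel contract.
* TIFF stacks are written as 16-bit samples with the quantization scale in
  a JSON sidecar; integer stacks up to 65535 round-trip losslessly.
* `retardance()` rejects non-positive thickness/wavelength; the renderer
  clamps its thickness map away from zero before evaluating it.
* ICC on a zero-variance subject matrix, correlation of a constant vector,
  and AP with no ground truth are signalled as errors, not returned as
  NaN.
* Phantom placement uses bounded rejection sampling; infeasible requests
  raise a typed capacity error instead of looping.

## Problem sizes used in the checks

The shipped test suite exercises the full pipeline on 5-plane 512×512
phantoms (a scale at which the oracle-detector run recovers every planted
object with precision = recall = 1.0), 200-trial randomized NMS/AP oracle
comparisons, 100-seed ICC coverage simulations at 30 subjects × 4 raters,
and n = 200 count-correlation recoveries. These sizes were chosen to make
the statistical assertions stable across seeds while keeping the whole
suite comfortably under ten minutes on a single CPU; all of them are
parameters, and nothing in the package caps larger runs.

## Known limitations

The forward model treats each pixel independently (no diffraction or
partial-volume mixing beyond the defocus blur), uses a single $\Delta n$
per fiber unless per-channel values are supplied, and models QWP detuning
only as the zero-order $\lambda_0/\lambda$ law — multi-order plates with
material dispersion would need a different `qwp_retardance()`. The baseline
blob detector is a reference implementation for exercising the pipeline,
not a competitive detector. Quantitative optic-axis reconstruction (qBRM)
is out of scope.
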