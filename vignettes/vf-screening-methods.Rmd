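---
title: "Central-slab reconstruction and case-level evaluation for opportunistic vertebral fracture screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Central-slab reconstruction and case-level evaluation for opportunistic vertebral fracture screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfscreen)
library(dplyr)
```

## The screening problem

Routine chest and abdominal CT scans image much of the thoracolumbar spine
as a by-product. Vertebral fragility fractures visible on those scans are an
early marker of compromised bone strength and of sharply elevated risk of
subsequent hip fracture, yet they are very often left unreported when the
scan indication is unrelated to the spine. Opportunistic screening software
closes that gap: it reformats the axial stack into a sagittal view of the
mid-spine, runs a fracture detector over it, and reports case-level calls
with per-vertebra boxes for a radiologist to confirm.

`vfscreen` implements the non-neural computational core of such a pipeline:

1. **DICOM ingestion** — calibrated Hounsfield-unit (HU) volumes from axial
   series, with de-identification and eligibility rules;
2. **Central slab reconstruction (CSR)** — the sagittal reformat that sums a
   fixed-width stack of sagittal slices centred on the mid-spine plane;
3. **Detection post-processing** — 512×512 standardization, a pluggable
   detector backend, non-maximum suppression (NMS) and a two-step
   confidence policy producing case-level calls;
4. **Evaluation** — confusion tables, sensitivity/specificity/accuracy with
   continuity-corrected Wilson intervals, subgroup, single-fracture and
   fracture-mimic reports;
5. **Phantom simulation** — a synthetic spine generator with exactly
   computable ground truth and a stochastic oracle detector, so every stage
   is testable without patient data.

The trained detection network itself is out of scope; the detector is an
interface (`run_detector()`), with the oracle and a file-based backend as
shipped implementations.

## Central slab reconstruction

Let $\mathrm{Hu}(z, y, x)$ be the windowed HU volume, indexed slice $z$
(inferior→superior), row $y$ (anterior→posterior), column $x$ (sagittal
slice index). The pipeline is:

1. **Window clamp.** Every voxel is clamped to
   $[\ell - w/2,\; \ell + w/2]$ with width $w = 1500$ HU and level
   $\ell = 300$ HU, i.e. $[-450, 1050]$. The wide bone-type window keeps
   trabecular and cortical contrast while capping metal and contrast-agent
   extremes, and — because the clamp is applied *before* the profile — makes
   the slice-sum profile bone-dominated.
2. **Sagittal sum profile.** $P(x) = \sum_{z,y} \mathrm{Hu}(z, y, x)$. Bone
   is by far the brightest tissue in CT, so $P$ peaks at the mid-spine
   sagittal plane.
3. **Central index.** $c = \arg\max_x P(x)$, ties broken by the smallest
   index for determinism.
4. **Slab sum.** With half-width $h$ (default 20),
   $$\mathrm{HuC}(i, j) = \sum_{k = c - h}^{c + h} \mathrm{Hu}(k, i, j),$$
   inclusive bounds — 41 slices for an interior centre at the default
   half-width. At the volume border only the existing slices are summed (no
   reflection, no renormalisation); the downstream min–max map absorbs the
   scale change.
5. **Orientation and resampling.** The image is oriented head-up (rows run
   superior→inferior, columns anterior→posterior) and rows are linearly
   interpolated so mm/row equals mm/column — slice spacing rarely equals
   in-plane spacing, and an unresampled matrix would distort vertebral
   heights.
6. **8-bit conversion.** A linear min–max map onto 0..255 with half-up
   rounding (bit-reproducible across platforms); a constant slab carries no
   contrast and maps to all zeros rather than erroring.

On the inclusive-bounds choice: the slab is sometimes described as "20
slices each side, 40 in total", which conflicts with the summation bounds
$c-20$ to $c+20$ (41 slices). This package follows the summation formula and
exposes `half_width` so either convention is reachable.

Two open choices are parameterised rather than fixed: the profile may be
computed on windowed (default) or raw HU (`profile_on`), and `mode` selects
the slab operator (`csr` sum, `mip` per-pixel maximum, `mpr` single slice)
for comparison. The per-pixel maximum (MIP) and the single mid-plane slice
(MPR) are the conventional baselines the central-slab sum is compared
against: MIP is dominated by the brightest structure along the ray and MPR
by a single voxel plane, while the slab *sum* averages over the
vertebral body so endplate and trabecular changes stay visible.

## Detection post-processing

Detector input is standardized to 512×512: per axis, a centre crop when
larger (the spine is mid-frame by construction of the CSR), symmetric
zero-padding when smaller, with the odd remainder to the bottom/right so the
transform is deterministic. The transform is recorded and invertible;
`map_boxes_back()` flags boxes that lie entirely in a padded margin as
having no pre-image.

Boxes are half-open real-valued rectangles — areas are exact and two boxes
sharing an edge do not overlap — with IoU the usual Jaccard ratio. NMS is
the standard greedy scheme: keep the highest-confidence remaining box,
discard everything overlapping it above the IoU threshold (default 0.6).
Confidence ties are broken by `(top, left)` lexicographic order so results
do not depend on input order or platform.

The case decision is two-step, emphasising specificity:

* **Step 1 (flagging):** NMS over boxes with confidence ≥ `tau_high`
  (default 0.8); the case is positive iff any survive.
* **Step 2 (reporting):** only for flagged cases, NMS is re-run on the full
  set of boxes with confidence ≥ `tau_low` (default 0.5) to recover as many
  of the case's fractures as possible.

Step 2 re-runs NMS on the full low-threshold set rather than unioning with
step-1 survivors: NMS is applied independently per step, which keeps each
step's output self-consistent (pairwise IoU below threshold). With
`tau_high = tau_low` the reported set equals the step-1 survivors, and
raising `tau_high` can never convert a negative case to positive — both
properties are enforced by tests.

## Evaluation statistics

Counting is case-level: a case is a true positive if any true fracture
exists and the system flags the case, regardless of per-vertebra matching.
From the confusion table, sensitivity $= TP/(TP+FN)$, specificity
$= TN/(TN+FP)$, accuracy $= (TP+TN)/n$; an empty denominator yields `NA`
("not available"), never a silent 0 or 1.

Interval estimates use the Wilson score interval with Newcombe's continuity
correction ("efficient-score method"): with $\hat p = x/n$, $q = 1-\hat p$
and $z$ the two-sided normal quantile (1.959964 at 95 %),

$$L = \max\!\left(0,\; \frac{2n\hat p + z^2 - 1 - z\sqrt{z^2 - 2 - 1/n + 4\hat p(nq + 1)}}{2(n + z^2)}\right)$$
$$U = \min\!\left(1,\; \frac{2n\hat p + z^2 + 1 + z\sqrt{z^2 + 2 - 1/n + 4\hat p(nq - 1)}}{2(n + z^2)}\right)$$

with $L = 0$ when $x = 0$ and $U = 1$ when $x = n$. This is the same
interval `stats::prop.test(correct = TRUE)` computes; the test suite uses
`prop.test` as an independent oracle against this implementation and also
verifies ≥ 94 % empirical coverage over simulated binomials.

All reporting functions compute at full precision. Published
diagnostic-performance tables typically print proportions truncated to
three decimals (a 44/44 lower bound of 0.89999 appears as 0.899, not
0.900), so `display_metrics()` offers `truncate` (default) and `round`
modes as presentation-only transforms.

```{r evaluation-example}
records <- records_from_counts(tp = 203, tn = 722, fp = 10, fn = 21)
glance(confusion(records))
display_metrics(wilson_cc_interval(203, 224))
```

One reporting subtlety: the "fraction of fracture cases detected, counting
only moderate-or-worse misses" uses all fracture-positive cases as its
denominator — `100 (1 - FN_{\ge moderate} / (TP+FN))` — which is the
reconstruction consistent with quoting both that percentage and its
complement against the full positive set.

## The phantom: what it emulates and what it does not

The generator builds cuboid-based spines: vertebral bodies with an
elliptical axial cross-section and a 900 HU cortical shell around 250 HU
trabecular interior, stacked along $z$ with 80 HU discs, a posterior
midline element (tapering like pedicles/spinous process), embedded in 30 HU
soft tissue over air, with additive Gaussian noise (default 20 HU SD)
applied last. Geometry is exactly computable, which is the point: ground
truth (per-vertebra extents, deformity kind and grade, case label) is known
to the voxel before noise.

Deformities reduce vertebral height by a requested fraction with a
kind-specific profile along the anteroposterior axis: anterior-maximal
(wedge), centrally-maximal (biconcave), uniform (crush). Two fracture
*mimics* are label-negative by construction: OA wedging (matched anterior
wedging on two adjacent vertebrae, no endplate depression) and acquired
short vertebrae (uniform reduction with 20 % anteroposterior elongation).
Grade labels anchor to height-loss bands — minimal < 20 %, mild 20–25 %,
moderate 25–40 %, severe > 40 % — with losses at or below 5 % treated as no
deformity, since sub-voxel height changes cannot be generated (or detected)
at CT resolution. Height-loss bands double as the generator's sampling
ranges per grade.

The default cohort mix emulates a five-center external validation set:
956 cases with 224 fracture-positive (prevalence 224/956, exact under
stratified sampling), roughly 48 % of positives single-fracture, and OAw/SV
mimic rates of 137/732 and 190/732 among the negatives. Pseudo-centers and
pseudo-manufacturers rotate round-robin so subgroup reports exercise the
partition logic.

What the phantom does **not** emulate: CT physics (beam hardening,
reconstruction kernels, scanner-specific noise texture), anatomy (curved
spines beyond a sinusoidal scoliosis offset, organs, osteophytes, image
artifacts), or the visual variability that makes real minimal-grade
fractures hard. Passing phantom tests therefore demonstrates that the
*computational* pipeline — reformat geometry, box bookkeeping, policy
arithmetic, statistics — is correct and deterministic; it says nothing
about detection performance on real patients, which is entirely a property
of the detector behind the backend interface.

## The oracle detector and planted rates

The oracle emits each true fracture box with probability
$1 - \text{miss}[grade]$, at a grade-dependent confidence drawn at or above
the 0.8 flagging threshold, so the planted case-level sensitivity of a
grade is exactly $1 - \text{miss}[grade]$ (a multi-fracture case is missed
only when all its fractures are). A fracture-free case receives one
high-confidence false box with probability `fp_case_prob`, so planted
specificity is exactly `1 - fp_case_prob`. A separate Poisson stream of
low-confidence (< 0.8) nuisance boxes exercises the reporting step without
flipping case calls. Default miss probabilities fall with grade (minimal
0.25, mild 0.15, moderate 0.05, severe 0.02) and `fp_case_prob` is 0.014,
a specificity-emphasised operating point.

This design makes "recovery" checks well-defined: the acceptance suite runs
a seeded 500-case cohort end-to-end (oracle → policy → evaluation) and
requires measured sensitivity and specificity to fall within 95 % intervals
of the planted values, and recovery of the planted mid-spine plane within
±2 columns in at least 95 of 100 seeded phantoms.

## Numerical and design choices

* **Coordinates.** Array indices (slices, the central index) are 1-based R
  indices; box and crop/pad coordinates are 0-based pixel offsets with
  half-open extents. Each function documents which it uses.
* **Determinism.** One user seed fans out through a multiplicative
  sub-seeding scheme (`case seed ← f(batch seed, case id)`), so a case
  processed alone is byte-identical to the same case inside any batch, and
  two runs of a seeded batch produce byte-identical reports and PNGs.
  Batch reports reference outputs by file name only for the same reason.
* **Slice sorting.** Slices sort by the projection of the image position
  onto the slice normal (robust to reversed or tilted acquisition order),
  falling back to instance number; duplicate positions are an error naming
  the offending files. Non-axial orientations are rejected rather than
  resampled — resampling policy belongs upstream of this package.
* **De-identification.** A fixed, overridable tag list (name, identifiers,
  birth date, address, comments, institution, referring physician) is
  *blanked* (zero-length value) rather than deleted, keeping type-2
  attributes standard-conformant. Pixels, geometry and calibration are
  never touched. Missing age never blocks reconstruction — age is a cohort
  criterion, not an algorithmic requirement — it only flags eligibility.
* **Eligibility.** Slice thickness ≤ 3 mm and age ≥ 50 by default; a
  missing thickness is conservatively ineligible.
* **8-bit rounding** is half-up (not banker's), so images are bit-identical
  across platforms; constant slabs map to zero.
* **Problem sizes in tests.** Unit and acceptance tests use a 4-vertebra
  phantom at coarse spacing (2.5 × 2 × 2 mm) — large enough for an interior
  41-slice slab, small enough that the 100-phantom recovery study and the
  500-case cohort run in well under a minute each. These sizes are the
  package's chosen test conditions; the generator's clinical-scale defaults
  (12 vertebrae, 1.5 × 0.8 × 0.8 mm) are used for the worked examples.

## Known limitations

* The DICOM layer is a minimal Part-10 reader/writer (explicit/implicit VR
  little endian, defined-length elements, single-frame CT): sufficient for
  scanner-style axial series and the phantom fixtures, but not a general
  DICOM toolkit (no sequences, no compressed transfer syntaxes, no
  multi-frame enhanced CT).
* Case-level counting means a flagged case with boxes on the wrong
  vertebra still counts as a true positive; vertebra-level matching is
  deliberately out of scope.
* The CSR assumes the spine is the dominant bone along $x$; a shoulder or
  arm in the field of view of a real scan could in principle win the
  HU-sum argmax. The phantom does not model this failure mode.
* No severity grading is produced — calls are yes/no with confidences —
  and no ROC analysis is provided, matching the two-threshold operating
  point design.
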