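---
title: "Delineating hyper-signal abnormal regions across T2, FLAIR and the DTI p-map"
author: "glioseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating hyper-signal abnormal regions across T2, FLAIR and the DTI p-map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioseg)
```

## The problem

Glioblastoma infiltrates diffusely along white-matter tracts, so the
"true" tumour margin is not visible on any single MRI contrast.
Radiotherapy target volumes are conventionally drawn on the T2 or
T2-FLAIR hyper-signal abnormality (residual tumour plus vasogenic
edema). Diffusion tensor imaging offers a complementary window: the
isotropic component of the water diffusion tensor,

$$p = \sqrt{3}\, D, \qquad D = \tfrac{1}{3}(\lambda_1+\lambda_2+\lambda_3),$$

is elevated wherever the white-matter architecture is disrupted —
vasogenic edema, but also tumour-infiltrated tissue that can look normal
on structural images. `glioseg` implements the full comparison pipeline:
tensor fitting and p-map computation, semi-automatic segmentation of the
hyper-signal abnormal region on each of the three modalities, and
agreement metrics (area, Dice, Discordance Index) between the three
delineations, per patient and per cohort.

Note on the p-map convention: the formula is sometimes typeset so that it
could be read as $\sqrt{3D}$. We implement $p=\sqrt{3}\cdot D$, the
convention of the p/q tensor decomposition this metric originates from
(the magnitude of the isotropic part of the tensor,
$\lVert \tfrac{1}{3}\operatorname{tr}(T) I\rVert = \sqrt{3}D$); this is
unit-consistent (mm^2/s) and is what the map's originators compute.

## Tensor fitting

`fitTensor()` solves, per voxel, the log-linearised monoexponential
model

$$\ln(S_i/S_0) = -b_i\, g_i^{\mathsf T} \mathbf{D}\, g_i$$

by ordinary least squares over the six unique components of the
symmetric tensor $\mathbf D$, with $S_0$ the mean of the $b=0$
volumes. Choices worth knowing:

* **No weighting, no positivity constraint.** The estimator is the
  simplest faithful log-linear fit. We verified empirically that
  signal-squared weighted LS and a 7-parameter fit (intercept for
  $\ln S_0$) give practically identical mean-diffusivity accuracy on the
  12-direction scheme, so the plain OLS form is kept.
* **Voxels with any non-positive signal are excluded** from the valid
  mask rather than floored: flooring creates log-domain artifacts that
  bias the tensor.
* **Negative eigenvalues are retained**, not clipped, and their count is
  reported via `message()`. Clipping would bias mean diffusivity upward
  exactly in the low-SNR voxels where honesty matters most.

Accuracy under noise: with the acquisition used throughout (1 b0 + 12
directions at $b = 1000$ s/mm^2) and Rician noise at SNR 20, the single
$b=0$ measurement dominates the error budget — its log-noise (sd 0.05)
enters every direction as a common ADC offset of about
$5\times10^{-5}$ mm^2/s. For parenchyma-like diffusivity
($D \approx 0.8\times10^{-3}$) this puts the median relative MD error
at ~5%, irreducibly (the same for OLS, WLS and intercept fits); for the
edema-like diffusivities this pipeline targets
($D \approx 1.4\times10^{-3}$) the median error is ~4%. The package's
stochastic accuracy test therefore uses an edema-like isotropic phantom;
users fitting single-b0 protocols should expect the ~5% floor on normal
white matter.

## Preprocessing

Intensities are min-max normalized to $[0,1]$ per image
(`normalizeIntensity()`), which makes the region-growing tolerance
comparable across modalities. The p-map is additionally edge-sharpened
with an unsharp mask (`sharpenEdges()`):
$v + a\,(v - G_\sigma * v)$, clipped back to $[0,1]$, with
$\sigma = 1$ voxel and gain $a = 0.3$ by default. The gain is
deliberately mild: at larger gains ($a \gtrsim 0.8$) the boundary
over/undershoot and the clipping spike at 1 visibly reshape the
intensity histogram, which harms the four-class clustering the
enhancement is meant to assist. Both parameters are exposed.

## Four-class fuzzy C-means

`fcmCluster()` is standard Bezdek FCM on voxel intensities: memberships
$u_{ik} = 1/\sum_j (|x_k-c_i|/|x_k-c_j|)^{2/(m-1)}$ and centroids
$c_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m$, iterated until the
maximum centroid change falls below $10^{-5}$ (at most 300 iterations),
with fuzzifier $m = 2$. The recorded objective is non-increasing, and
the returned state satisfies both update equations — properties the test
suite checks with plug-in oracles on random instances.

Two practical choices:

* **Initialization at histogram peaks.** Brain images have tissue
  classes of wildly unequal voxel counts; background alone is over half
  the image. Quantile or equispaced initializations then start several
  centroids inside the heavy bands and the small bright classes never
  acquire one. We instead seed one centroid per local maximum of the
  smoothed 256-bin intensity histogram (greedy by height with an
  exclusion radius; equispaced fill-in if fewer maxima than clusters).
  Band shoulders and tails are monotone, so a heavy neighbouring band
  cannot place a spurious peak. The init is deterministic; restarts
  (only triggered by coincident converged centroids) add seeded jitter.
* **Slice-wise 2D by default.** Clustering runs on the seed's axial
  slice (see below).

`assignTissueClasses()` ranks the four clusters by centroid intensity,
descending, and maps ranks to tissue roles per modality:

| rank | T2 | T2-FLAIR | p-map |
|------|----|----------|-------|
| 0 (brightest) | necrosis / hemorrhage / cyst | necrosis / hemorrhage / cyst | hemorrhage / cyst, CSF |
| 1 | CSF + edema | edema | edema |
| 2 | WM / GM, scalp | scalp, WM / GM | WM / GM |
| 3 | skull, background | CSF, skull, background | background |

In every modality ranks 0–1 are the hyper-signal abnormal candidates.
Note where CSF sits: intermediate on T2, suppressed to the darkest class
on FLAIR, and in the brightest class on the p-map (free-water
diffusivity). Centroid ties within $10^{-12}$ and membership ties break
deterministically to the lower cluster index and are counted.

## Region growing and mask extraction

`regionGrow()` is breadth-first seeded growth with an incrementally
updated region mean: at each step the whole frontier is tested against
the current mean ($|v - \mu| \le$ tolerance, default 0.1 on normalized
intensities), accepted voxels update $\mu$, and growth stops when no
frontier voxel qualifies. Batch acceptance makes the result independent
of voxel enumeration order. Rejected frontier voxels remain candidates,
since $\mu$ drifts.

`extractAbnormalMask()` combines the fuzzy classification with the
growth step — the combination is not prescribed in detail anywhere, so
the package's reading is:

1. candidate set = voxels whose class role is hyper or edema
   (ranks 0–1), intersected with the brain mask;
2. the connected component of the candidate set containing the seed
   (8-connectivity in-plane, 26 in 3D) — connectivity is what excludes
   the ventricles, which share an intensity class with the lesion on T2
   and the p-map;
3. region growing on the *fuzzy abnormality score* (the summed
   membership of the hyper and edema clusters, `abnormalityScore()`),
   restricted to that component. Growing on the score rather than the
   raw intensity is what lets a single tolerance of 0.1 traverse the
   necrotic-core/edema intensity step: both tissues score near 1,
   normal tissue near 0;
4. interior holes up to 64 voxels (noise-flipped pixels) are filled.

The seed must land in an abnormal-role class; otherwise the function
errors and asks for a new seed — it is a semi-automatic method, and the
seed is its one manual input.

## Why slice-wise 2D is the default

The per-patient areas this analysis reports are 2D quantities (cm^2 on
the slice of maximal extent), and all pixel-level reasoning is
two-dimensional, so the pipeline segments the seed's slice by default
(`mode = "2d"`); a full-volume `mode = "3d"` exists. The 2D default is
also statistically load-bearing: over a whole volume the hyper class can
be a fraction of a percent of all voxels, and intensity FCM with
$m = 2$ then provably prefers spending a second centroid inside a heavy
band (its per-voxel cost is the harmonic mean of squared
centroid-distances, so even a *coincident* duplicate centroid halves a
band's cost) over keeping a centroid on a tiny bright class. On a
lesion-bearing slice the four classes are within about an order of
magnitude of each other and the four-band solution is a stable fixed
point. We verified both behaviours by tracing centroid trajectories
from ideal initializations.

## Agreement metrics

For comparable masks (same grid and frame of reference):

* `maskAreaCm2()` — pixel count x in-plane pixel area. Default is the
  slice of maximal extent (the single-area-per-patient convention);
  per-slice and summed-volume variants are provided because the
  convention is not stated in the source material.
* `diceScore()` $= 2|A\cap B| / (|A|+|B|)$.
* `discordanceIndex()` $= (|A\cup B| - |A\cap B|)/|A\cup B|$, i.e.
  $1 -$ Jaccard: 0 for identical regions, 1 for disjoint ones. The two
  are algebraically locked: $DS = 2(1-DI)/(2-DI)$, which the tests
  exploit as a cross-check. In the third printed DI equation the
  denominator $A_{T2}\cup A_T$ is a typo for $A_{T2}\cup A_F$; the
  verbal definition is implemented.
* `sensitivitySpecificity()` — true negatives are counted inside the
  brain mask only, so specificity is not inflated by the huge image
  background (the restriction is not stated in the source; without it
  specificity is always ~1 and meaningless).

## Cohort analysis

`loadTable3()` ships the published 25-patient table (areas on the three
modalities and the three pairwise DIs); `summarizeCohort()` recomputes
DI summaries (sample SD), size categories and percent differences from
it. Conventions:

* `percentDifference(a, b)` $= 100\,|a-b|/\max(a,b)$ — symmetric and
  bounded by 100%; the source never defines its denominator.
* Categories: `EQUAL` when all pairwise differences are below 5%
  (checked first), else p-map smallest / largest / in between.
* Re-summarizing the table reproduces the printed DI means to 3
  decimals for the T2/p and T2/FLAIR pairs; the FLAIR/p mean recomputes
  to 0.4628 where 0.462 is printed (rounding on the source side). The
  printed T2/p low of 0.266 conflicts with the table's own 0.258; the
  table wins. The printed category counts (17/4/3/1) also differ
  slightly from strict recomputation (17/5/2/1 with the EQUAL rule
  applied first): patient 5's p-map area lies between its T2 and FLAIR
  areas, and five patients, not four, have the p-map region largest.
  `summarizeCohort()` reports what the numbers say; the prose counts are
  not hard-coded anywhere.

## The synthetic phantoms

No imaging data is deposited with the source study, so validation runs
on synthetic co-registered multimodal phantoms (`generatePhantom()`):
an ellipsoidal brain with skull and scalp shells, two CSF ventricles,
white/gray matter, and a lesion = necrotic/cystic core + edema rim. Key
conditions, chosen once to emulate the cohort:

* Grid 128 x 128 x 20 at 0.9 x 0.9 x 5 mm (the FLAIR geometry), so
  max-slice lesion areas land at ~8–14 cm^2, mid-range of the cohort's
  2.5–35 cm^2.
* Per-tissue intensities follow each modality's four-class ordering
  (CSF bright on T2, suppressed on FLAIR, maximal on the p-map). The
  p-map column is derived from a mean-diffusivity table
  (WM 0.78, GM 0.82, edema 1.7, core 2.9, CSF 3.0, all x 1e-3 mm^2/s);
  the necrotic/cystic core sits near free water, as for a fluid-filled
  resection cavity, which also places core and CSF together in the
  p-map's hyper class.
* The edema rim's extent is modality-specific (`rimFactors` scale the
  core semi-axes; through-plane growth damped to 60%), so the
  per-modality truth masks are deliberately discordant — the study's
  central observable. For nested rims the truth DI has a closed form,
  $1 - V_{small}/V_{large}$, which the tests compare against.
* Rician noise (Gaussian available for analytic checks), sigma a
  fraction of the dynamic range; the p-map receives half the structural
  sigma because a parameter map pooled over 13 measurements has
  sub-structural noise at matched SNR.
* `defaultBenchmarkSuite(20, seed)` varies lesion position, size and
  noise (sigma uniform in 0.02–0.06) and fixes the mix of size
  orderings at 12 p-smallest / 4 p-largest / 3 in-between / 1 equal per
  20 phantoms, mirroring the cohort's proportions.

What the phantoms do *not* emulate: partial-volume averaging,
bias fields, anatomy beyond ellipsoids, registration error between
modalities (volumes are generated co-registered, as the pipeline's input
contract assumes), and infiltrative margins that fade gradually rather
than stopping at a rim boundary. Passing the benchmark therefore shows
the pipeline's logic is correct under the stated intensity model, not
that it reaches the same accuracy on clinical images.

## Benchmark results the package reproduces

`evaluateBenchmark(defaultBenchmarkSuite(20, rngSeed))` segments all
three channels of 20 phantoms (~10 s total) and scores them on the seed
slice. The acceptance thresholds mirror the published validation of the
semi-automatic method against expert contours: mean Dice >= 0.89, mean
sensitivity >= 0.86, mean specificity >= 0.90 per modality. On the
synthetic suite the pipeline clears these with a wide margin (mean Dice
above 0.98 on every modality); the phantoms are easier than patients,
which is exactly why the thresholds are read as floors, not targets.
`scripts/acceptance.R` recomputes the three headline numbers from
scratch.

## Numerical and degenerate-input behaviour

* Constant images cannot be normalized (degenerate-range error); FCM
  requires at least as many distinct intensities as clusters; empty
  masks, empty unions (DI), empty truth masks (sensitivity) all error
  explicitly rather than returning NaN.
* FCM restarts (seeded jitter) are only triggered by coincident
  converged centroids, at most 3 times.
* Region-growing and component operations are frontier-BFS in index
  space, so cost scales with the region, not the volume; hole filling
  works on the mask's bounding box. Singleton axes are treated as 2D
  (a region enclosed in-plane is a hole).
* All randomness (phantom noise, DWI noise, FCM restarts) is seeded;
  two runs of `runPipeline()` with the same config produce byte-identical
  masks and reports, which the test suite asserts via checksums.

## Known limitations

* The brain-mask estimator (`estimateBrainMask()`: Otsu + largest
  component + hole fill) is a stand-in for a dedicated brain-extraction
  tool and is only exercised on phantoms.
* Registration is out of scope: inputs must be co-registered (checked:
  same grid and spacing), as in the source workflow where an external
  B-spline/NMI registration preceded the analysis.
* Single-slice areas depend on the chosen slice; the max-extent
  convention is one defensible reading of an unstated protocol, so the
  per-slice and total-volume outputs are also exposed.
* The anisotropic companion metric (q) is deliberately not computed.
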