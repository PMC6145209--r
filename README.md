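# glioseg

Semi-automatic delineation and cross-modality comparison of the
postoperative hyper-signal abnormal region in glioblastoma MRI.

## The problem

Glioblastoma infiltrates along white-matter tracts, so no single MRI
contrast shows the full tumour margin. Radiotherapy targets are
conventionally drawn on the T2 or T2-FLAIR hyper-signal abnormality
(residual tumour + edema). The diffusion-tensor-derived **isotropic
p-map**,

```
p = sqrt(3) * D,    D = (lambda1 + lambda2 + lambda3) / 3
```

is elevated wherever white-matter architecture is disrupted — including
infiltrated tissue that looks normal on structural images. `glioseg`
implements the pipeline that makes the three delineations comparable,
for imaging scientists and radiotherapy-planning researchers:

- **DTI**: log-linear least-squares tensor fitting from DWI +
  bval/bvec, eigenvalue/mean-diffusivity maps, p-map computation
  (`fitTensor()`, `eigenMetrics()`, `computePMap()`).
- **Segmentation**: per modality, min-max normalization, unsharp-mask
  edge enhancement (p-map), four-class fuzzy C-means with
  modality-specific tissue semantics, and seeded region growing that
  extracts the hyper-signal abnormal region around a single manual seed
  (`segmentVolume()` and its parts).
- **Metrics**: area in cm^2, Dice score `2|A∩B|/(|A|+|B|)`,
  Discordance Index `DI = (|A∪B|-|A∩B|)/|A∪B|` (1 − Jaccard; 0 =
  identical, 1 = disjoint), sensitivity/specificity against a reference
  mask (`maskAreaCm2()`, `diceScore()`, `discordanceIndex()`, ...).
- **Cohort analysis**: the published 25-patient area/DI table is
  packaged (`loadTable3()`) and re-summarized exactly
  (`summarizeCohort()`, `categorizePatient()`).
- **Synthetic phantoms**: co-registered multimodal head phantoms with
  ground-truth lesion masks and a DWI simulator, so the whole pipeline
  is testable end to end without patient data (`generatePhantom()`,
  `simulateDWI()`, `defaultBenchmarkSuite()`, `evaluateBenchmark()`).

A thin command-line wrapper (`exec/glioseg`) exposes `phantom`,
`segment`, `compare`, `cohort` and `run` subcommands over NIfTI files
and YAML configs.

## Worked example

Generate a phantom whose per-modality edema extents differ (the
discordance is the object of study), segment all three channels from
one seed, and compare:

```r
library(glioseg)

ph <- generatePhantom(phantomSpec(rngSeed = 42))
man <- runPipeline(list(
  volumes    = list(t2 = ph$t2, flair = ph$flair, pmap = ph$pmap),
  brain_mask = ph$brainMask,
  seed       = ph$lesionSeed))

man$reports[, c("pair", "area_a_cm2", "area_b_cm2", "dice", "di")]
#>         pair area_a_cm2 area_b_cm2  dice    di
#> 1   T2-FLAIR       11.0      12.63 0.930 0.131
#> 2    T2-PMAP       11.0       8.72 0.886 0.205
#> 3 FLAIR-PMAP       12.6       8.72 0.817 0.310
```

Reading: on this phantom the p-map abnormality (8.7 cm^2) is smaller
than the T2 (11.0 cm^2) and FLAIR (12.6 cm^2) ones, and the pairwise
Discordance Indices (0.13–0.31) quantify how much the three regions
disagree in location, not just size — the pattern the method exists to
expose.

Re-summarizing the packaged 25-patient table:

```r
s <- summarizeCohort(loadTable3())
s$diSummary
#>    pair  mean    sd   min   max
#> 1 di_tp 0.468 0.135 0.258 0.794
#> 2 di_fp 0.463 0.183 0.214 0.772
#> 3 di_tf 0.423 0.204 0.123 0.776
s$categoryCounts
#> P_SMALLEST  P_LARGEST  P_BETWEEN      EQUAL
#>         17          5          2          1
```

In 17 of 25 patients the p-map region is the smallest of the three; the
mean T2/p-map discordance is 0.468 — the three contrasts carry
substantially non-overlapping information.

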