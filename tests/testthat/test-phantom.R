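test_that("noiseless phantoms are piecewise constant at the tissue table intensities", {
  ph <- generatePhantom(phantomSpec(rngSeed = 3L, noiseSigma = 0))
  tab <- glioseg:::.INTENSITY_TABLE
  for (m in c("T2", "FLAIR", "PMAP")) {
    vol <- switch(m, T2 = ph$t2, FLAIR = ph$flair, PMAP = ph$pmap)
    lab <- ph$tissueLabels[[m]]
    v <- voxelData(vol)
    for (t in seq_len(nrow(tab)))
      if (any(lab == t))
        expect_equal(unique(v[lab == t]), unname(tab[t, m]),
                     tolerance = 1e-12)
  }
})

test_that("noiseless phantom intensities respect each modality's four-class ordering", {
  ph <- generatePhantom(phantomSpec(rngSeed = 3L, noiseSigma = 0))
  tab <- glioseg:::.INTENSITY_TABLE
  # T2: hyper core > CSF/edema > WM/GM/scalp > skull/background
  expect_true(tab["core", "T2"] > max(tab[c("csf", "edema"), "T2"]))
  expect_true(min(tab[c("csf", "edema"), "T2"]) >
                max(tab[c("wm", "gm", "scalp"), "T2"]))
  expect_true(min(tab[c("wm", "gm", "scalp"), "T2"]) >
                max(tab[c("skull", "background"), "T2"]))
  # FLAIR: CSF suppressed into the lowest band
  expect_true(tab["core", "FLAIR"] > tab["edema", "FLAIR"])
  expect_true(tab["edema", "FLAIR"] > max(tab[c("wm", "gm", "scalp"), "FLAIR"]))
  expect_true(tab["csf", "FLAIR"] < min(tab[c("wm", "gm", "scalp"), "FLAIR"]))
  # p-map: CSF and necrotic/cystic core share the hyper band
  expect_true(min(tab[c("csf", "core"), "PMAP"]) > tab["edema", "PMAP"])
  expect_true(tab["edema", "PMAP"] > max(tab[c("wm", "gm"), "PMAP"]))
  expect_true(tab["background", "PMAP"] == 0)
})

test_that("phantom generation is deterministic given the seed", {
  a <- generatePhantom(phantomSpec(rngSeed = 99L))
  b <- generatePhantom(phantomSpec(rngSeed = 99L))
  expect_identical(voxelData(a$t2), voxelData(b$t2))
  expect_identical(voxelData(a$flair), voxelData(b$flair))
  expect_identical(voxelData(a$pmap), voxelData(b$pmap))
  c2 <- generatePhantom(phantomSpec(rngSeed = 100L))
  expect_false(identical(voxelData(a$t2), voxelData(c2$t2)))
})

test_that("phantom structure is well formed: truth in brain, seed in core, lesion placement checked", {
  ph <- smallPhantom()
  brain <- voxelData(ph$brainMask)
  for (m in c("T2", "FLAIR", "PMAP"))
    expect_true(all(brain[voxelData(ph$truthMasks[[m]])]))
  s <- ph$lesionSeed
  expect_equal(ph$tissueLabels$T2[s[1], s[2], s[3]], 8L)  # core
  expect_error(generatePhantom(phantomSpec(lesionCenter = c(8, 64, 10))),
               "skull|brain")
  expect_error(generatePhantom(phantomSpec(lesionCenter = c(64.5, 40, 10.5))),
               "ventricle")
})

test_that("truth-mask discordance matches the analytic nested-ellipsoid overlap", {
  spec <- phantomSpec(rngSeed = 4L, noiseSigma = 0)
  ph <- generatePhantom(spec)
  f <- spec@rimFactors
  zf <- function(x) 1 + (x - 1) * 0.6
  vol <- function(m) f[[m]]^2 * zf(f[[m]])
  anaDI <- function(m1, m2) {
    v <- sort(c(vol(m1), vol(m2)))
    1 - v[1] / v[2]
  }
  # one voxel of shell on a ~3-voxel through-plane semi-axis shifts the
  # volume ratio by a few percent, so compare with an absolute band
  expect_lt(abs(discordanceIndex(ph$truthMasks$T2, ph$truthMasks$PMAP) -
                  anaDI("T2", "PMAP")), 0.04)
  expect_lt(abs(discordanceIndex(ph$truthMasks$FLAIR, ph$truthMasks$PMAP) -
                  anaDI("FLAIR", "PMAP")), 0.04)
  expect_lt(abs(discordanceIndex(ph$truthMasks$T2, ph$truthMasks$FLAIR) -
                  anaDI("T2", "FLAIR")), 0.04)
})

test_that("DWI simulation is exact where analytic: zero tensor, log-linearity in b", {
  scheme <- defaultGradientScheme()
  z <- uniformTensorField(rep(0, 6))
  acq <- simulateDWI(z, scheme$bvals, scheme$bvecs, s0 = 700, snr = Inf)
  expect_true(all(acq@dwi == 700))

  M <- c(1.2e-3, 0.6e-3, 0.4e-3, 1e-4, 0, 0)
  tf <- uniformTensorField(M, grid = c(1L, 1L, 1L))
  g <- matrix(c(0, 0, 0, 1, 0, 0), 3)
  s1 <- simulateDWI(tf, c(0, 1000), g, s0 = 1, snr = Inf)@dwi[1, 1, 1, 2]
  s2 <- simulateDWI(tf, c(0, 2000), g, s0 = 1, snr = Inf)@dwi[1, 1, 1, 2]
  expect_equal(log(s2), 2 * log(s1), tolerance = 1e-12)
  expect_error(simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = -1), "s0")
})

test_that("simulated noise follows the requested model and seed", {
  scheme <- defaultGradientScheme()
  tf <- uniformTensorField(c(1e-3, 1e-3, 1e-3, 0, 0, 0), grid = c(5L, 5L, 2L))
  a1 <- simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = 100, snr = 10,
                    rngSeed = 2L)
  a2 <- simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = 100, snr = 10,
                    rngSeed = 2L)
  expect_identical(a1@dwi, a2@dwi)
  expect_true(all(a1@dwi >= 0))  # Rician magnitudes
  expect_gt(sd(a1@dwi[, , , 1]), 0)
})

test_that("the default benchmark suite is reproducible and spans the cohort's size orderings", {
  s1 <- defaultBenchmarkSuite(20, rngSeed = 2)
  s2 <- defaultBenchmarkSuite(20, rngSeed = 2)
  expect_equal(length(s1), 20L)
  expect_identical(lapply(s1, function(s) s@lesionCenter),
                   lapply(s2, function(s) s@lesionCenter))
  expect_identical(vapply(s1, function(s) s@noiseSigma, numeric(1)),
                   vapply(s2, function(s) s@noiseSigma, numeric(1)))
  sig <- vapply(s1, function(s) s@noiseSigma, numeric(1))
  expect_true(all(sig >= 0.02 & sig <= 0.06))

  # truth-area orderings by construction, from the analytic rim volumes
  zf <- function(x) 1 + (x - 1) * 0.6
  kinds <- vapply(s1, function(s) {
    f <- s@rimFactors
    v <- f^2 * zf(f)
    categorizePatient(v[["T2"]], v[["FLAIR"]], v[["PMAP"]], equalTol = 0.01)
  }, character(1))
  expect_true(all(c("P_SMALLEST", "P_LARGEST", "P_BETWEEN", "EQUAL") %in% kinds))

  # every suite phantom generates with the lesion inside the brain
  for (s in s1[c(1, 8, 15, 20)]) {
    ph <- generatePhantom(s)
    expect_true(all(voxelData(ph$brainMask)[voxelData(ph$truthMasks$FLAIR)]))
  }
})
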