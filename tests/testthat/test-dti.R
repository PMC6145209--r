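test_that("noiseless DWI from a known diagonal tensor is recovered to machine precision", {
  scheme <- defaultGradientScheme()
  D <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  tf <- uniformTensorField(D)
  acq <- simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = 1000, snr = Inf)
  fit <- fitTensor(acq)
  expect_lt(max(abs(tensorComponents(fit) - tensorComponents(tf))), 1e-9)
  expect_true(all(validMask(fit)@values))
})

test_that("tensor fit recovers random SPD tensors exactly at infinite SNR", {
  set.seed(11)
  scheme <- defaultGradientScheme()
  for (i in 1:100) {
    M <- randomSPDTensor()
    tf <- uniformTensorField(comp6FromMat3(M), grid = c(1L, 1L, 1L))
    acq <- simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = 800, snr = Inf)
    fit <- fitTensor(acq)
    expect_lt(max(abs(tensorComponents(fit) - tensorComponents(tf))), 1e-12)
  }
})

test_that("DWI with no attenuation fits a zero tensor; isotropic tensor gives MD = lambda", {
  scheme <- defaultGradientScheme()
  grid <- c(3L, 3L, 1L)
  acq <- diffusionAcquisition(array(500, c(grid, 13L)), scheme$bvals, scheme$bvecs)
  fit <- fitTensor(acq)
  expect_lt(max(abs(tensorComponents(fit))), 1e-12)
  expect_lt(max(abs(meanDiffusivity(fit))), 1e-12)

  lam <- 1.1e-3
  tf <- uniformTensorField(c(lam, lam, lam, 0, 0, 0))
  acq2 <- simulateDWI(tf, scheme$bvals, scheme$bvecs, snr = Inf)
  fit2 <- fitTensor(acq2)
  expect_equal(as.vector(meanDiffusivity(fit2)),
               rep(lam, prod(dim(meanDiffusivity(fit2)))), tolerance = 1e-9)
})

test_that("fit errors on rank-deficient schemes and shape mismatches", {
  # 6 repeats of a single direction cannot determine 6 components
  g <- matrix(rep(c(1, 0, 0), 7), 3)
  g[, 1] <- 0
  acq <- diffusionAcquisition(array(100, c(2, 2, 1, 7)),
                              c(0, rep(1000, 6)), g)
  expect_error(fitTensor(acq), "rank deficient")
  expect_error(diffusionAcquisition(array(100, c(2, 2, 1, 5)),
                                    c(0, rep(1000, 5)),
                                    matrix(0, 3, 6)),
               "b-values")
})

test_that("eigenvalues are sorted, rotation invariant, and match a cubic-root oracle", {
  set.seed(21)
  # brute-force characteristic polynomial roots via polyroot()
  cubicEigen <- function(M) {
    p <- c(-det(M),
           (M[1,1]*M[2,2] - M[1,2]^2) + (M[1,1]*M[3,3] - M[1,3]^2) +
             (M[2,2]*M[3,3] - M[2,3]^2),
           -(M[1,1] + M[2,2] + M[3,3]), 1)
    sort(Re(polyroot(p)), decreasing = TRUE)
  }
  for (i in 1:25) {
    cc <- rnorm(6, sd = 1e-3)
    M <- mat3FromComp(cc)
    tf <- uniformTensorField(cc, grid = c(1L, 1L, 1L))
    ev <- as.vector(eigenvalueMaps(tf))
    expect_true(ev[1] >= ev[2] && ev[2] >= ev[3])
    expect_equal(ev, cubicEigen(M), tolerance = 1e-10)
    # similarity invariance under rotation
    R <- randomRotation()
    tfR <- uniformTensorField(comp6FromMat3(R %*% M %*% t(R)),
                              grid = c(1L, 1L, 1L))
    expect_equal(as.vector(eigenvalueMaps(tfR)), ev, tolerance = 1e-12)
    expect_equal(as.vector(meanDiffusivity(tf)), mean(ev), tolerance = 1e-15)
  }
})

test_that("negative eigenvalues are retained and reported, non-finite components error", {
  tf <- uniformTensorField(c(-1e-3, -1e-3, -1e-3, 0, 0, 0), grid = c(1L, 1L, 1L))
  expect_message(eigenMetrics(tf), "negative eigenvalue")
  expect_lt(max(eigenvalueMaps(tf)), 0)

  arr <- array(c(NaN, rep(0, 5)), c(1, 1, 1, 6))
  expect_error(tensorFieldFromArray(arr), "non-finite")
})

test_that("p-map equals sqrt(3) times mean diffusivity, zero outside the valid mask", {
  grid <- c(2L, 2L, 1L)
  arr <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), each = prod(grid)), c(grid, 6L))
  vm <- array(c(TRUE, TRUE, TRUE, FALSE), grid)
  tf <- tensorFieldFromArray(arr, validMask = vm)
  p <- computePMap(tf)
  expect_equal(modality(p), "PMAP")
  expect_equal(voxelData(p)[1, 1, 1], sqrt(3) * 1e-3, tolerance = 1e-15)
  expect_equal(voxelData(p)[2, 2, 1], 0)

  # linearity: CSF/WM p ratio equals the MD ratio
  arr2 <- array(0, c(2, 1, 1, 6))
  arr2[1, 1, 1, 1:3] <- 3.0e-3
  arr2[2, 1, 1, 1:3] <- 0.7e-3
  p2 <- computePMap(tensorFieldFromArray(arr2))
  expect_equal(voxelData(p2)[1, 1, 1] / voxelData(p2)[2, 1, 1],
               3.0 / 0.7, tolerance = 1e-12)
})

test_that("p-map is invariant to rotation of the gradient scheme", {
  set.seed(31)
  scheme <- defaultGradientScheme()
  M <- randomSPDTensor()
  tf <- uniformTensorField(comp6FromMat3(M), grid = c(2L, 2L, 1L))
  p0 <- computePMap(fitTensor(simulateDWI(tf, scheme$bvals, scheme$bvecs, snr = Inf)))
  R <- randomRotation()
  rot <- scheme
  rot$bvecs[, -1] <- R %*% scheme$bvecs[, -1]
  pR <- computePMap(fitTensor(simulateDWI(tf, rot$bvals, rot$bvecs, snr = Inf)))
  expect_lt(max(abs(voxelData(p0) - voxelData(pR))), 1e-9)
})

test_that("mean diffusivity is accurate under Rician noise at SNR 20", {
  # edema-like isotropic diffusivity, the tissue class whose elevated
  # isotropic diffusion the multimodal comparison targets
  scheme <- defaultGradientScheme()
  md <- 1.4e-3
  tf <- uniformTensorField(c(md, md, md, 0, 0, 0),
                           grid = c(10L, 10L, 10L))
  acq <- simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = 1000, snr = 20,
                     rngSeed = 5L)
  fit <- fitTensor(acq)
  relErr <- abs(meanDiffusivity(fit) - md) / md
  expect_lt(median(relErr), 0.05)
})

test_that("FSL-style gradient tables round-trip through text files", {
  scheme <- defaultGradientScheme()
  bvalF <- tempfile(fileext = ".bval")
  bvecF <- tempfile(fileext = ".bvec")
  writeLines(paste(scheme$bvals, collapse = " "), bvalF)
  writeLines(apply(scheme$bvecs, 1, paste, collapse = " "), bvecF)
  gt <- readGradientTable(bvalF, bvecF)
  expect_equal(gt$bvals, scheme$bvals)
  expect_equal(gt$bvecs, scheme$bvecs, tolerance = 1e-12)
})
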