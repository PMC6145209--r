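test_that("mask area follows pixel size and matches a per-pixel summation oracle", {
  m <- binaryMask(array(c(rep(TRUE, 100), rep(FALSE, 156)), c(16, 16, 1)),
                  spacing = c(0.9, 0.9, 5))
  expect_equal(maskAreaCm2(m), 100 * 0.9 * 0.9 / 100)
  expect_equal(maskAreaCm2(binaryMask(array(FALSE, c(4, 4, 2)))), 0)

  set.seed(10)
  for (i in 1:10) {
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2), 5)  # anisotropic in-plane
    vals <- array(runif(4 * 5 * 3) < 0.4, c(4L, 5L, 3L))
    mk <- binaryMask(vals, spacing = sp)
    # naive loop oracle, per slice
    areas <- numeric(3)
    for (z in 1:3) {
      n <- 0
      for (x in 1:4) for (y in 1:5) if (vals[x, y, z]) n <- n + 1
      areas[z] <- n * sp[1] * sp[2] / 100
    }
    expect_equal(maskAreaCm2(mk), max(areas))
    expect_equal(maskAreaCm2(mk, slice = 2), areas[2])
    expect_equal(maskAreaCm2(mk, scope = "total"), sum(areas))
  }
})

test_that("discordance index matches its defining counts and bounds", {
  d <- c(4, 4, 1)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:2, 1, 1] <- TRUE          # |A| = 2
  b[2, 1, 1] <- TRUE            # |B| = 1, shared pixel
  expect_equal(discordanceIndex(binaryMask(a), binaryMask(b)), 0.5)

  m <- binaryMask(array(runif(16) < 0.5, d))
  expect_equal(discordanceIndex(m, m), 0)
  disj <- binaryMask(array(!voxelData(m), d))
  expect_equal(discordanceIndex(m, disj), 1)
  e <- binaryMask(array(FALSE, d))
  expect_error(discordanceIndex(e, e), "empty")
})

test_that("dice and DI satisfy the algebraic identity dice = 2(1 - DI)/(2 - DI)", {
  set.seed(11)
  for (i in 1:50) {
    p <- randomMaskPair()
    if (sum(voxelData(p$a) | voxelData(p$b)) == 0) next
    di <- discordanceIndex(p$a, p$b)
    dc <- diceScore(p$a, p$b)
    expect_equal(dc, 2 * (1 - di) / (2 - di), tolerance = 1e-9)
    # symmetry
    expect_equal(di, discordanceIndex(p$b, p$a))
  }
  i1 <- binaryMask(array(TRUE, c(2, 2, 1)))
  expect_equal(diceScore(i1, i1), 1)
})

test_that("1 - DI is the Jaccard index and obeys the triangle inequality", {
  set.seed(12)
  for (i in 1:30) {
    a <- randomMaskPair()$a; b <- randomMaskPair()$a; c <- randomMaskPair()$a
    if (any(c(sum(voxelData(a) | voxelData(b)) == 0,
              sum(voxelData(b) | voxelData(c)) == 0,
              sum(voxelData(a) | voxelData(c)) == 0))) next
    dab <- discordanceIndex(a, b)
    dbc <- discordanceIndex(b, c)
    dac <- discordanceIndex(a, c)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("DI strictly decreases as one mask grows toward the other", {
  d <- c(8, 8, 1)
  a <- array(FALSE, d); a[2:7, 2:7, 1] <- TRUE
  b <- array(FALSE, d); b[4, 4, 1] <- TRUE
  A <- binaryMask(a)
  prev <- discordanceIndex(A, binaryMask(b))
  missing <- which(a & !b)
  set.seed(13)
  for (idx in sample(missing)) {
    b[idx] <- TRUE
    cur <- discordanceIndex(A, binaryMask(b))
    expect_lt(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 0)
})

test_that("sensitivity and specificity match a brute-force confusion matrix inside the domain", {
  set.seed(14)
  d <- c(6, 6, 2)
  domain <- binaryMask(array(runif(prod(d)) < 0.8, d))
  for (i in 1:10) {
    pred <- binaryMask(array(runif(prod(d)) < 0.3, d) & voxelData(domain))
    truth <- binaryMask(array(runif(prod(d)) < 0.3, d) & voxelData(domain))
    if (sum(voxelData(truth)) == 0) next
    ss <- sensitivitySpecificity(pred, truth, domain)
    tp <- fn <- fp <- tn <- 0
    for (k in seq_len(prod(d))) {
      p <- voxelData(pred)[k]; t <- voxelData(truth)[k]; dm <- voxelData(domain)[k]
      if (p && t) tp <- tp + 1
      if (!p && t) fn <- fn + 1
      if (p && !t && dm) fp <- fp + 1
      if (!p && !t && dm) tn <- tn + 1
    }
    expect_equal(unname(ss["sensitivity"]), tp / (tp + fn))
    expect_equal(unname(ss["specificity"]), tn / (tn + fp))
  }
  # perfect and complementary predictions
  t0 <- binaryMask(array(c(TRUE, FALSE, FALSE, FALSE), c(2, 2, 1)))
  dom <- binaryMask(array(TRUE, c(2, 2, 1)))
  expect_equal(unname(sensitivitySpecificity(t0, t0, dom)), c(1, 1))
  compl <- binaryMask(array(!voxelData(t0), c(2, 2, 1)))
  expect_equal(unname(sensitivitySpecificity(compl, t0, dom)), c(0, 0))
  expect_error(sensitivitySpecificity(t0, binaryMask(array(FALSE, c(2, 2, 1))), dom),
               "empty truth")
})

test_that("masks with different shapes or frames are not comparable", {
  a <- binaryMask(array(TRUE, c(2, 2, 1)))
  b <- binaryMask(array(TRUE, c(3, 2, 1)))
  expect_error(discordanceIndex(a, b), "comparable")
  c2 <- binaryMask(array(TRUE, c(2, 2, 1)), frame = "other")
  expect_error(diceScore(a, c2), "comparable")
})

test_that("agreement reports collect all metrics consistently", {
  set.seed(15)
  d <- c(8, 8, 1)
  dom <- binaryMask(array(TRUE, d), spacing = c(0.9, 0.9, 5))
  a <- binaryMask(array(runif(64) < 0.4, d), spacing = c(0.9, 0.9, 5))
  b <- binaryMask(array(runif(64) < 0.4, d), spacing = c(0.9, 0.9, 5))
  rep <- agreementReport(a, b, dom, pair = "T2-PMAP")
  expect_equal(rep$pair, "T2-PMAP")
  expect_equal(rep$dice, diceScore(a, b))
  expect_equal(rep$di, discordanceIndex(a, b))
  expect_equal(rep$area_a_cm2, maskAreaCm2(a))
})
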