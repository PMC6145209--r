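test_that("FCM separates two delta-like intensity populations", {
  v <- c(rep(0.2, 500), rep(0.8, 500))
  # two exactly-equal values per population would collapse the distinct-value
  # precondition for 2 clusters, so add negligible jitter
  set.seed(3)
  v <- v + runif(1000, -1e-6, 1e-6)
  fit <- fcmCluster(v, nClusters = 2)
  expect_equal(sort(centroids(fit)), c(0.2, 0.8), tolerance = 1e-5)
  hard <- apply(memberships(fit), 1, max)
  expect_true(all(hard > 0.99))
})

test_that("converged FCM satisfies both fixed-point update equations (plug-in oracle)", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    C <- sample(2:4, 1)
    m <- sample(c(1.6, 2, 2.4), 1)
    v <- runif(n)
    fit <- fcmCluster(v, nClusters = C, fuzziness = m, tol = 1e-8,
                      maxIter = 500)
    u <- memberships(fit)
    cent <- centroids(fit)
    # membership equation from the returned centroids
    d2 <- outer(v, cent, "-")^2
    w <- d2^(-1 / (m - 1))
    uExp <- w / rowSums(w)
    expect_equal(u, uExp, tolerance = 1e-6)
    # centroid equation from the returned memberships
    um <- u^m
    centExp <- colSums(um * v) / colSums(um)
    expect_equal(cent, centExp, tolerance = 1e-5)
    # objective non-increasing
    expect_true(all(diff(objectiveTrace(fit)) <= 1e-12))
  }
})

test_that("FCM objective beats 1000 random membership matrices on a small instance", {
  set.seed(5)
  v <- runif(30)
  fit <- fcmCluster(v, nClusters = 2, tol = 1e-9, maxIter = 500)
  J <- fcmObjective(v, memberships(fit), centroids(fit))
  for (i in 1:1000) {
    u <- matrix(runif(60), 30, 2)
    u <- u / rowSums(u)
    cent <- colSums(u^2 * v) / colSums(u^2)
    expect_gte(fcmObjective(v, u, cent), J - 1e-9)
  }
})

test_that("near-crisp FCM agrees with k-means on well-separated data", {
  set.seed(6)
  v <- c(rnorm(60, 0.15, 0.02), rnorm(60, 0.55, 0.02), rnorm(60, 0.9, 0.02))
  fit <- fcmCluster(v, nClusters = 3, fuzziness = 1.05, tol = 1e-8)
  fcmLab <- max.col(memberships(fit))
  km <- kmeans(v, centers = sort(centroids(fit)))
  # map both labelings to centroid order and compare
  fcmOrd <- match(fcmLab, order(centroids(fit)))
  kmOrd <- match(km$cluster, order(km$centers))
  expect_equal(fcmOrd, kmOrd)
})

test_that("FCM is deterministic and errors on degenerate inputs", {
  set.seed(7)
  v <- runif(200)
  f1 <- fcmCluster(v, nClusters = 3, seed = 9)
  f2 <- fcmCluster(v, nClusters = 3, seed = 9)
  expect_identical(centroids(f1), centroids(f2))
  expect_identical(memberships(f1), memberships(f2))
  expect_error(fcmCluster(c(0, 1, 0, 1), nClusters = 3), "distinct")
  expect_error(fcmCluster(scalarVolume(array(runif(8), c(2, 2, 2))),
                          mask = binaryMask(array(FALSE, c(2, 2, 2))),
                          nClusters = 2), "empty")
})

test_that("tissue roles follow centroid ranks and are invariant to cluster permutation", {
  mkFcm <- function(cent, u, dim = c(length(cent), 1L, 1L),
                    idx = seq_len(nrow(u))) {
    new("FCMResult", memberships = u, centroids = cent,
        nIterations = 1L, objective = 1, voxelIndex = as.integer(idx),
        dim = as.integer(dim))
  }
  cent <- c(0.9, 0.6, 0.3, 0.05)
  u <- diag(4)  # 4 voxels, one per cluster
  tc <- assignTissueClasses(mkFcm(cent, u, dim = c(4L, 1L, 1L)), "T2")
  expect_equal(as.vector(classLabels(tc)), c(0L, 1L, 2L, 3L))
  expect_match(tc@roles[1], "hyper")
  expect_match(tc@roles[2], "CSF")
  expect_equal(tc@abnormalRanks, c(0L, 1L))

  # permuting cluster order leaves the class map unchanged
  perm <- c(3, 1, 4, 2)
  tcP <- assignTissueClasses(mkFcm(cent[perm], u[, perm], dim = c(4L, 1L, 1L)),
                             "T2")
  expect_equal(classLabels(tcP), classLabels(tc))

  # FLAIR and p-map role tables differ in where CSF sits
  expect_match(assignTissueClasses(mkFcm(cent, u, c(4L, 1L, 1L)), "FLAIR")@roles[4], "CSF")
  expect_match(assignTissueClasses(mkFcm(cent, u, c(4L, 1L, 1L)), "PMAP")@roles[1], "CSF")
})

test_that("membership ties break to the lower cluster index and are counted", {
  u <- rbind(c(0.4, 0.4, 0.1, 0.1),
             c(0.1, 0.1, 0.1, 0.7))
  fcm <- new("FCMResult", memberships = u, centroids = c(0.9, 0.6, 0.3, 0.05),
             nIterations = 1L, objective = 1, voxelIndex = 1:2,
             dim = c(2L, 1L, 1L))
  expect_message(tc <- assignTissueClasses(fcm, "T2"), "tie")
  expect_equal(tc@nTies, 1L)
  # voxel 1 tied between clusters 1 and 2 -> cluster 1 -> rank 0
  expect_equal(as.vector(classLabels(tc)), c(0L, 3L))
})

test_that("abnormality score sums hyper and edema memberships", {
  u <- rbind(c(0.7, 0.2, 0.05, 0.05),
             c(0.05, 0.1, 0.8, 0.05))
  fcm <- new("FCMResult", memberships = u, centroids = c(0.9, 0.6, 0.3, 0.05),
             nIterations = 1L, objective = 1, voxelIndex = 1:2,
             dim = c(2L, 1L, 1L))
  tc <- assignTissueClasses(fcm, "T2")
  sc <- abnormalityScore(fcm, tc)
  expect_equal(as.vector(voxelData(sc)), c(0.9, 0.15))
})
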