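# Shared fixtures built in code.

# a small but fully-featured phantom (fast to generate and segment)
smallPhantom <- function(seed = 7L, sigma = 0.03) {
  generatePhantom(phantomSpec(rngSeed = seed, noiseSigma = sigma))
}

# tensor field holding the same 6-vector at every voxel of a tiny grid
uniformTensorField <- function(comp6, grid = c(3L, 3L, 2L), spacing = c(1, 1, 1)) {
  arr <- array(rep(comp6, each = prod(grid)), c(grid, 6L))
  tensorFieldFromArray(arr, spacing = spacing)
}

# symmetric 3x3 from a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
mat3FromComp <- function(cc) {
  matrix(c(cc[1], cc[4], cc[5],
           cc[4], cc[2], cc[6],
           cc[5], cc[6], cc[3]), 3L, 3L)
}

comp6FromMat3 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])

# random rotation matrix (Gram-Schmidt of a random basis)
randomRotation <- function() {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random SPD tensor with eigenvalues in [0.2, 2.5] x 1e-3 mm^2/s
randomSPDTensor <- function() {
  ev <- sort(runif(3, 0.2e-3, 2.5e-3), decreasing = TRUE)
  R <- randomRotation()
  R %*% diag(ev) %*% t(R)
}

# independent FCM objective for given memberships/centroids
fcmObjective <- function(v, u, cent, m = 2) {
  d2 <- outer(v, cent, "-")^2
  sum(u^m * d2)
}

# independent flood fill with a static seed-value acceptance rule; on
# piecewise-constant images it matches incremental-mean region growing
floodFillOracle <- function(v, seed, tolerance) {
  d <- dim(v)
  ref <- v[seed[1], seed[2], seed[3]]
  visited <- array(FALSE, d)
  stack <- list(seed)
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (visited[p[1], p[2], p[3]]) next
    visited[p[1], p[2], p[3]] <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (!visited[q[1], q[2], q[3]] && abs(v[q[1], q[2], q[3]] - ref) <= tolerance)
        stack[[length(stack) + 1]] <- q
    }
  }
  visited
}

# random piecewise-constant blob image: k blobs of well-separated levels
randomBlobImage <- function(d = c(12L, 12L, 1L), k = 3L) {
  levels <- seq(0, 1, length.out = k)
  lab <- array(sample.int(k, prod(d), replace = TRUE), d)
  # smooth the labels a little so blobs are contiguous-ish
  for (i in 1:2) {
    sh <- lab
    sh[-1, , ] <- lab[-d[1], , ]
    lab <- ifelse(array(runif(prod(d)) < 0.5, d), lab, sh)
  }
  array(levels[lab], d)
}

randomMaskPair <- function(d = c(10L, 10L, 2L), p = 0.3) {
  a <- binaryMask(array(runif(prod(d)) < p, d))
  b <- binaryMask(array(runif(prod(d)) < p, d))
  list(a = a, b = b)
}
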