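#' Fuzzy C-means clustering of voxel intensities
#'
#' Standard (Bezdek) fuzzy C-means on the intensity values of a volume.
#' Memberships and centroids alternate through the fixed-point updates
#' \deqn{u_{ik} = 1 / \sum_j (|x_k - c_i| / |x_k - c_j|)^{2/(m-1)}, \quad
#'       c_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}
#' until the maximum centroid change falls below `tol` or `maxIter` is
#' reached. The fuzzy objective \eqn{J = \sum_{ik} u_{ik}^m |x_k - c_i|^2}
#' is recorded each iteration and is non-increasing.
#'
#' Centroids are initialized deterministically at the main peaks of the
#' smoothed intensity histogram (one per tissue band; MR tissue classes
#' have very unequal voxel counts, and a mass-blind init lets heavy bands
#' capture several centroids). If the converged centroids coincide (within
#' 1e-12 of the range) the fit restarts with seeded jitter, up to 3 times,
#' before erroring; the whole procedure is deterministic given `seed`.
#'
#' @param x A [ScalarVolume-class] or a numeric vector of intensities.
#' @param mask Optional [BinaryMask-class] restricting clustering; by
#'   default all voxels are clustered (the background/skull class is one of
#'   the four tissue classes).
#' @param nClusters Number of clusters C (default 4, the four tissue
#'   classes).
#' @param fuzziness Fuzzifier m > 1 (default 2).
#' @param tol Convergence tolerance on the maximum centroid change
#'   (default 1e-5).
#' @param maxIter Iteration cap (default 300).
#' @param seed Integer seed driving restart jitter only.
#' @return An [FCMResult-class].
#' @examples
#' x <- c(rnorm(200, 0.2, 0.01), rnorm(200, 0.8, 0.01))
#' fit <- fcmCluster(x, nClusters = 2)
#' sort(centroids(fit))
#' @export
fcmCluster <- function(x, mask = NULL, nClusters = 4L, fuzziness = 2,
                       tol = 1e-5, maxIter = 300L, seed = 1L) {
  if (is(x, "ScalarVolume")) {
    grid <- dim(x@values)
    if (is.null(mask)) {
      voxelIndex <- seq_len(prod(grid))
    } else {
      stopifnot(all(dim(mask@values) == grid))
      voxelIndex <- which(as.vector(mask@values))
    }
    v <- as.vector(x@values)[voxelIndex]
  } else {
    v <- as.numeric(x)
    grid <- c(length(v), 1L, 1L)
    voxelIndex <- seq_along(v)
  }
  if (length(v) == 0) stop("empty mask: nothing to cluster")
  stopifnot(nClusters >= 2L, fuzziness > 1, tol > 0, maxIter >= 1L)
  if (length(unique(v)) < nClusters)
    stop(sprintf("need at least %d distinct intensity values, found %d",
                 nClusters, length(unique(v))))
  rng <- max(v) - min(v)
  cent0 <- .histogramPeakInit(v, nClusters)

  for (attempt in 0:3) {
    cent <- cent0
    if (attempt > 0) {
      set.seed(as.integer(seed) + attempt)
      cent <- cent0 + stats::runif(nClusters, -0.2, 0.2) * rng / nClusters
    }
    res <- .fcmCore(v, cent, fuzziness, tol, maxIter)
    sep <- min(diff(sort(res$centroids)))
    if (is.finite(sep) && sep > 1e-12 * max(rng, 1)) {
      return(new("FCMResult", memberships = res$u, centroids = res$centroids,
                 nIterations = res$iter, objective = res$objective,
                 voxelIndex = as.integer(voxelIndex), dim = as.integer(grid)))
    }
  }
  stop("FCM centroids coincide after 3 seeded restarts")
}

# Deterministic centroid initialization at the main peaks of the smoothed
# intensity histogram. Tissue bands in MR are narrow modes of very unequal
# mass (background dwarfs any lesion class); seeding one centroid per mode
# keeps FCM in the one-centroid-per-band basin instead of letting heavy
# bands capture several centroids. Peaks are picked greedily by height
# with an exclusion radius; missing peaks fall back to equispaced values.
.histogramPeakInit <- function(v, C, nBins = 256L) {
  lo <- min(v); hi <- max(v)
  h <- tabulate(pmin.int(pmax.int(
    as.integer((v - lo) / (hi - lo) * nBins) + 1L, 1L), nBins), nbins = nBins)
  # running-mean smoothing, half-width 3
  hw <- 3L
  cs <- cumsum(c(0, h))
  iLo <- pmax(seq_len(nBins) - hw, 1L)
  iHi <- pmin(seq_len(nBins) + hw, nBins)
  hs <- (cs[iHi + 1L] - cs[iLo]) / (iHi - iLo + 1L)
  # local maxima over a +/- 8 bin window: band shoulders and tails are
  # monotone, so however heavy a neighbouring band is it cannot place a
  # spurious peak there
  w <- 8L
  isMax <- vapply(seq_len(nBins), function(j) {
    win <- hs[max(1L, j - w):min(nBins, j + w)]
    hs[j] > 0 && hs[j] >= max(win)
  }, logical(1))
  cand <- which(isMax)
  mids <- lo + (seq_len(nBins) - 0.5) / nBins * (hi - lo)
  excl <- 16L
  peaks <- numeric(0)
  avail <- rep(TRUE, length(cand))
  for (k in seq_len(C)) {
    if (!any(avail)) break
    j <- cand[avail][which.max(hs[cand[avail]])]
    peaks <- c(peaks, mids[j])
    avail <- avail & abs(cand - j) > excl
  }
  if (length(peaks) < C) {
    fill <- lo + (seq_len(C) - 0.5) / C * (hi - lo)
    fill <- fill[order(vapply(fill, function(f) min(abs(f - peaks)), numeric(1)),
                       decreasing = TRUE)]
    peaks <- c(peaks, fill[seq_len(C - length(peaks))])
  }
  sort(peaks)
}

# one FCM run; returns memberships consistent with the final centroids
.fcmCore <- function(v, cent, m, tol, maxIter) {
  em <- 2 / (m - 1)
  objective <- numeric(0)
  membershipsFor <- function(cent) {
    d2 <- outer(v, cent, "-")^2
    # |x - c|^(-2/(m-1)); m = 2 is the common case, avoid the general pow
    w <- if (m == 2) 1 / d2 else d2^(-em / 2)
    exact <- !is.finite(w)           # zero distance: hard assignment
    if (any(exact)) {
      rows <- rowSums(exact) > 0
      w[rows, ] <- 0
      w[exact] <- 1
    }
    u <- w / rowSums(w)
    list(u = u, d2 = d2)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    s <- membershipsFor(cent)
    um <- s$u^m
    objective <- c(objective, sum(um * s$d2))
    newCent <- colSums(um * v) / colSums(um)
    delta <- max(abs(newCent - cent))
    cent <- newCent
    if (delta < tol || iter >= maxIter) break
  }
  final <- membershipsFor(cent)
  list(u = final$u, centroids = cent, iter = iter, objective = objective)
}

# role tables: ranks are by centroid intensity, descending (rank 0 brightest)
.ROLE_TABLES <- list(
  T2 = c("hyper (necrosis/hemorrhage/cyst)",
         "intermediate (CSF + edema)",
         "hypo (white/gray matter, scalp)",
         "very low (skull, background)"),
  FLAIR = c("hyper (necrosis/hemorrhage/cyst)",
            "intermediate (edema)",
            "hypo (scalp, white/gray matter)",
            "zero (CSF, skull, background)"),
  PMAP = c("high hyper (hemorrhage/cyst, CSF)",
           "intermediate (edema)",
           "hypo (white/gray matter)",
           "zero (background)"))

#' Map FCM clusters to modality-specific tissue classes
#'
#' Ranks the four clusters by centroid intensity (descending) and assigns
#' each voxel the role of its maximum-membership cluster. The rank-to-role
#' mapping follows the four-class model of each modality: on T2 the two
#' brightest ranks are the hyper class (necrosis/hemorrhage/cyst) and the
#' CSF+edema class; on FLAIR, hyper and edema (CSF falls in the darkest
#' class); on the p-map, hyper (hemorrhage/cyst/CSF) and edema. In every
#' modality ranks 0 and 1 are the hyper-signal abnormal candidates.
#'
#' Centroid ties within 1e-12 are broken by cluster index; membership ties
#' assign the lower-index cluster and are counted in `nTies`.
#'
#' @param fcm An [FCMResult-class] with exactly 4 clusters.
#' @param modality `"T2"`, `"FLAIR"` or `"PMAP"`.
#' @return A [TissueClassMap-class].
#' @export
assignTissueClasses <- function(fcm, modality) {
  stopifnot(is(fcm, "FCMResult"))
  modality <- match.arg(modality, c("T2", "FLAIR", "PMAP"))
  C <- length(fcm@centroids)
  if (C != 4L) stop("tissue-class semantics are defined for exactly 4 clusters")
  # order() is stable: centroid ties resolve by cluster index
  ord <- order(fcm@centroids, decreasing = TRUE)
  if (min(abs(diff(fcm@centroids[ord]))) < 1e-12)
    message("assignTissueClasses: centroid tie broken by cluster index")
  rankOfCluster <- integer(C)
  rankOfCluster[ord] <- seq_len(C) - 1L
  best <- max.col(fcm@memberships, ties.method = "first")
  rowMax <- fcm@memberships[cbind(seq_len(nrow(fcm@memberships)), best)]
  nTies <- sum(rowSums(abs(fcm@memberships - rowMax) < 1e-12) > 1L)
  if (nTies > 0)
    message(sprintf("assignTissueClasses: %d membership tie(s) broken by cluster index", nTies))
  labels <- array(NA_integer_, fcm@dim)
  labels[fcm@voxelIndex] <- rankOfCluster[best]
  new("TissueClassMap", labels = labels, roles = .ROLE_TABLES[[modality]],
      abnormalRanks = c(0L, 1L), modality = modality, nTies = as.integer(nTies))
}

#' Fuzzy abnormality score
#'
#' The summed membership of each voxel in the abnormal-candidate clusters
#' (hyper + edema roles). Close to 1 inside the lesion regardless of
#' whether a voxel is necrotic core or edema rim, and close to 0 in normal
#' tissue, which makes it the natural image for seeded region growing
#' across the core/rim intensity step.
#'
#' @param fcm An [FCMResult-class].
#' @param classes The matching [TissueClassMap-class].
#' @param spacing Voxel spacing of the source volume.
#' @return A [ScalarVolume-class] (modality `"GENERIC"`) of scores in
#'   `[0, 1]`; 0 outside the clustered region.
#' @export
abnormalityScore <- function(fcm, classes, spacing = c(1, 1, 1)) {
  stopifnot(is(fcm, "FCMResult"), is(classes, "TissueClassMap"))
  ord <- order(fcm@centroids, decreasing = TRUE)
  abnormalClusters <- ord[classes@abnormalRanks + 1L]
  sc <- rowSums(fcm@memberships[, abnormalClusters, drop = FALSE])
  out <- array(0, fcm@dim)
  out[fcm@voxelIndex] <- sc
  scalarVolume(out, spacing = spacing)
}
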