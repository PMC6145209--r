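#' Seeded region growing with an incremental region mean
#'
#' Breadth-first growth from a seed voxel: at each step every frontier
#' voxel (neighbour of the current region) whose intensity lies within
#' `tolerance` of the current region mean is accepted, the mean is updated,
#' and growth continues until no acceptable frontier voxel remains. The
#' output is connected and contains the seed.
#'
#' Frontier voxels are accepted in whole batches against the mean of the
#' region as of the previous step, which makes the procedure deterministic
#' and independent of voxel enumeration order.
#'
#' @param vol A [ScalarVolume-class].
#' @param seed Integer voxel coordinate (1-based, length 3; a length-2
#'   coordinate addresses slice 1).
#' @param tolerance Maximum absolute intensity deviation from the region
#'   mean (> 0). Default 0.1 on normalized intensities.
#' @param connectivity 6, 18 or 26 (default 26; equals 8-connectivity
#'   in-plane for single-slice volumes).
#' @param domain Optional [BinaryMask-class] restricting growth.
#' @return A [BinaryMask-class].
#' @examples
#' v <- scalarVolume(array(rep(c(0.2, 0.8), each = 32), c(8, 8, 1)))
#' m <- regionGrow(v, c(7, 6, 1), tolerance = 0.1)
#' sum(voxelData(m))  # exactly the 0.8 half
#' @export
regionGrow <- function(vol, seed, tolerance = 0.1, connectivity = 26L,
                       domain = NULL) {
  stopifnot(is(vol, "ScalarVolume"), tolerance > 0)
  v <- vol@values
  d <- dim(v)
  seed <- as.integer(seed)
  if (length(seed) == 2L) seed <- c(seed, 1L)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed must be a voxel coordinate inside the volume")
  dom <- if (is.null(domain)) array(TRUE, d) else {
    stopifnot(all(dim(domain@values) == d))
    domain@values
  }
  if (!dom[seed[1], seed[2], seed[3]])
    stop("seed lies outside the growth domain")
  off <- .neighborOffsets(as.integer(connectivity))
  region <- array(FALSE, d)
  seedIdx <- (seed[3] - 1L) * (d[1] * d[2]) + (seed[2] - 1L) * d[1] + seed[1]
  region[seedIdx] <- TRUE
  total <- v[seedIdx]
  n <- 1L
  # pending holds every in-domain neighbour of the region seen so far;
  # voxels rejected at one step stay pending because the region mean drifts
  inPending <- array(FALSE, d)
  nb <- .neighborsOf(seedIdx, d, off)
  nb <- nb[dom[nb] & !region[nb]]
  inPending[nb] <- TRUE
  pending <- nb
  repeat {
    if (length(pending) == 0L) break
    accept <- abs(v[pending] - total / n) <= tolerance
    acc <- pending[accept]
    if (length(acc) == 0L) break
    region[acc] <- TRUE
    inPending[acc] <- FALSE
    total <- total + sum(v[acc])
    n <- n + length(acc)
    pending <- pending[!accept]
    nb <- .neighborsOf(acc, d, off)
    nb <- nb[dom[nb] & !region[nb] & !inPending[nb]]
    inPending[nb] <- TRUE
    pending <- c(pending, nb)
  }
  binaryMask(region, spacing = vol@spacing, frame = vol@frame)
}

#' Extract the hyper-signal abnormal region
#'
#' Combines the fuzzy classification with seeded region growing. The
#' candidate set is the union of voxels whose class role is abnormal
#' (hyper or edema ranks), intersected with the brain mask when given. The
#' abnormal mask is the connected component of the candidate set containing
#' the seed, refined by [regionGrow()] on `scoreVol` (normally the
#' [abnormalityScore()] image) restricted to that component; interior holes
#' up to `maxHoleSize` voxels are then filled.
#'
#' @param classes A [TissueClassMap-class].
#' @param scoreVol A [ScalarVolume-class] the refinement grows on.
#' @param seed Integer voxel coordinate (1-based); must lie in an
#'   abnormal-role class, otherwise an error prompts reseeding.
#' @param tolerance Region-growing tolerance (default 0.1).
#' @param brainMask Optional [BinaryMask-class]; the result is a subset.
#' @param maxHoleSize Fill enclosed holes up to this many voxels
#'   (default 64).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A single-component [BinaryMask-class] containing the seed.
#' @export
extractAbnormalMask <- function(classes, scoreVol, seed, tolerance = 0.1,
                                brainMask = NULL, maxHoleSize = 64L,
                                connectivity = 26L) {
  stopifnot(is(classes, "TissueClassMap"), is(scoreVol, "ScalarVolume"))
  lab <- classes@labels
  d <- dim(lab)
  stopifnot(all(dim(scoreVol@values) == d))
  seed <- as.integer(seed)
  if (length(seed) == 2L) seed <- c(seed, 1L)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed must be a voxel coordinate inside the volume")
  seedLab <- lab[seed[1], seed[2], seed[3]]
  if (is.na(seedLab) || !(seedLab %in% classes@abnormalRanks))
    stop("seed does not lie in an abnormal-role (hyper/edema) class; choose a new seed")
  candidate <- array(FALSE, d)
  candidate[which(lab %in% classes@abnormalRanks)] <- TRUE
  if (!is.null(brainMask)) {
    stopifnot(all(dim(brainMask@values) == d))
    candidate <- candidate & brainMask@values
    if (!candidate[seed[1], seed[2], seed[3]])
      stop("seed lies outside the brain mask; choose a new seed")
  }
  comp <- .connectedComponent(candidate, seed, as.integer(connectivity))
  grown <- regionGrow(scoreVol, seed, tolerance = tolerance,
                      connectivity = connectivity,
                      domain = binaryMask(comp, spacing = scoreVol@spacing))
  filled <- .fillHoles(grown@values, maxHoleSize = maxHoleSize,
                       connectivity = as.integer(connectivity))
  if (!is.null(brainMask)) filled <- filled & brainMask@values
  binaryMask(filled, spacing = scoreVol@spacing, frame = scoreVol@frame)
}

#' Brain mask by thresholding (for real acquisitions)
#'
#' Otsu threshold on the intensity histogram, largest connected component,
#' then morphological closing by hole filling. Phantoms carry their own
#' exact brain mask; this estimator stands in for a dedicated brain
#' extraction tool on real data.
#'
#' @param vol A [ScalarVolume-class].
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A [BinaryMask-class].
#' @export
estimateBrainMask <- function(vol, connectivity = 26L) {
  stopifnot(is(vol, "ScalarVolume"))
  v <- vol@values
  # Otsu's threshold on a 256-bin histogram
  breaks <- seq(min(v), max(v), length.out = 257L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-257]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[256L]
  sigmaB <- (muT * omega - mu)^2 / pmax(omega * (1 - omega), 1e-12)
  thr <- mids[which.max(sigmaB)]
  fg <- v > thr
  if (!any(fg)) stop("brain mask estimation failed: empty foreground")
  # largest component: grow from the voxel with maximal intensity, then
  # check remaining components
  remaining <- fg
  best <- NULL
  while (any(remaining)) {
    s <- arrayInd(which(remaining)[1L], dim(v))[1L, ]
    comp <- .connectedComponent(remaining, as.integer(s), as.integer(connectivity))
    if (is.null(best) || sum(comp) > sum(best)) best <- comp
    remaining <- remaining & !comp
  }
  binaryMask(.fillHoles(best, Inf, as.integer(connectivity)),
             spacing = vol@spacing, frame = vol@frame)
}
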