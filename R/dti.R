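#' Fit diffusion tensors by log-linear least squares
#'
#' Estimates, per voxel, the six unique components of the symmetric
#' diffusion tensor \eqn{D} from the monoexponential signal model
#' \deqn{\ln(S_i / S_0) = -b_i \, g_i^T D \, g_i}
#' by ordinary least squares over the diffusion-weighted measurements.
#' \eqn{S_0} is the mean of the b = 0 volumes. No positivity constraint is
#' imposed and no weighting is applied; voxels with any non-positive signal
#' (in any measurement) are excluded from the valid mask rather than
#' floored, avoiding log-domain artifacts.
#'
#' @param acq A [DiffusionAcquisition-class] with at least one b = 0 volume
#'   and at least six diffusion-weighted measurements along independent
#'   directions.
#' @param brainMask Optional [BinaryMask-class] restricting the fit.
#' @return A [TensorField-class] with `components` populated, eigenvalues
#'   and mean diffusivity computed via [eigenMetrics()].
#' @seealso [eigenMetrics()], [computePMap()], [simulateDWI()]
#' @examples
#' scheme <- defaultGradientScheme()
#' D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
#' tf <- tensorFieldFromArray(array(rep(D[c(1, 5, 9, 2, 3, 6)],
#'                            each = 8), c(2, 2, 2, 6)))
#' acq <- simulateDWI(tf, scheme$bvals, scheme$bvecs, s0 = 1000, snr = Inf)
#' fit <- fitTensor(acq)
#' range(tensorComponents(fit) - tensorComponents(tf))
#' @export
fitTensor <- function(acq, brainMask = NULL) {
  stopifnot(is(acq, "DiffusionAcquisition"))
  d <- dim(acq@dwi)
  grid <- d[1:3]
  n <- d[4L]
  if (n < 7L)
    stop("at least 7 measurements required (1 b0 + >= 6 directions)")
  b0 <- acq@bvals == 0
  dw <- !b0
  if (sum(dw) < 6L) stop("at least 6 diffusion-weighted measurements required")
  B <- t(vapply(which(dw), function(i) {
    g <- acq@bvecs[, i]
    acq@bvals[i] * c(g[1]^2, g[2]^2, g[3]^2,
                     2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
  }, numeric(6)))
  if (qr(B)$rank < 6L)
    stop("gradient scheme is rank deficient: fewer than 6 independent directions")
  sig <- matrix(acq@dwi, ncol = n)             # voxels x measurements
  mask <- if (is.null(brainMask)) rep(TRUE, prod(grid)) else {
    stopifnot(all(dim(brainMask@values) == grid))
    as.vector(brainMask@values)
  }
  positive <- rowSums(sig > 0) == n
  valid <- mask & positive
  comps <- matrix(0, nrow = prod(grid), ncol = 6L)
  if (any(valid)) {
    s0 <- rowMeans(sig[valid, b0, drop = FALSE])
    if (any(s0 <= 0)) stop("b0 intensities must be > 0 inside the mask")
    Y <- -log(sig[valid, dw, drop = FALSE] / s0)  # voxels x ndw
    # D = (B'B)^-1 B' y per voxel, all voxels at once
    Dhat <- Y %*% B %*% solve(crossprod(B))
    comps[valid, ] <- Dhat
  }
  tf <- new("TensorField",
            components = array(comps, c(grid, 6L)),
            eigenvalues = array(numeric(0)),
            md = array(numeric(0)),
            validMask = array(valid, grid),
            spacing = acq@spacing)
  eigenMetrics(tf)
}

#' Build a TensorField directly from a component array
#'
#' Convenience constructor used by the phantom generator and in tests.
#'
#' @param components 4D array (x, y, z, 6) with components ordered
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s.
#' @param spacing Voxel spacing in mm.
#' @param validMask Optional logical array; defaults to all voxels.
#' @param computeMetrics Compute eigenvalues/MD immediately (default TRUE).
#' @return A [TensorField-class].
#' @export
tensorFieldFromArray <- function(components, spacing = c(1, 1, 1),
                                 validMask = NULL, computeMetrics = TRUE) {
  grid <- dim(components)[1:3]
  if (is.null(validMask)) validMask <- array(TRUE, grid)
  tf <- new("TensorField", components = components,
            eigenvalues = array(numeric(0)), md = array(numeric(0)),
            validMask = validMask, spacing = as.numeric(spacing))
  if (computeMetrics) eigenMetrics(tf) else tf
}

#' Eigenvalues and mean diffusivity of a tensor field
#'
#' Computes, for every valid voxel, the three eigenvalues of the symmetric
#' tensor (sorted descending) and the mean diffusivity
#' \eqn{D = (\lambda_1 + \lambda_2 + \lambda_3)/3}. Negative eigenvalues are
#' retained, not clipped — clipping would bias the estimator — but their
#' count is reported via [message()].
#'
#' @param tensors A [TensorField-class] with `components` populated.
#' @return The same [TensorField-class] with `eigenvalues` and `md` filled.
#' @export
eigenMetrics <- function(tensors) {
  stopifnot(is(tensors, "TensorField"))
  grid <- dim(tensors@components)[1:3]
  comps <- matrix(tensors@components, ncol = 6L)
  valid <- as.vector(tensors@validMask)
  if (any(!is.finite(comps[valid, ]))) {
    bad <- which(valid & rowSums(!is.finite(comps)) > 0)[1L]
    stop(sprintf("non-finite tensor components at voxel (%s)",
                 paste(arrayInd(bad, grid)[1L, ], collapse = ", ")))
  }
  ev <- matrix(0, nrow = length(valid), ncol = 3L)
  idx <- which(valid)
  for (k in idx) {
    cc <- comps[k, ]
    M <- matrix(c(cc[1], cc[4], cc[5],
                  cc[4], cc[2], cc[6],
                  cc[5], cc[6], cc[3]), 3L, 3L)
    ev[k, ] <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }
  nNeg <- sum(ev[idx, ] < 0)
  if (nNeg > 0)
    message(sprintf("eigenMetrics: %d negative eigenvalue(s) across %d voxels (retained, not clipped)",
                    nNeg, length(idx)))
  md <- rowMeans(ev)
  md[!valid] <- 0
  new("TensorField", components = tensors@components,
      eigenvalues = array(ev, c(grid, 3L)),
      md = array(md, grid),
      validMask = tensors@validMask,
      spacing = tensors@spacing)
}

#' Isotropic p-map from mean diffusivity
#'
#' The isotropic component of the diffusion tensor,
#' \eqn{p = \sqrt{3}\, D}, where \eqn{D} is the mean diffusivity: the
#' magnitude of the isotropic part of the tensor in its deviatoric
#' decomposition. Elevated in vasogenic edema and tumour-infiltrated white
#' matter. Outside the valid mask p is 0.
#'
#' @param tensors A [TensorField-class] with mean diffusivity computed.
#' @return A [ScalarVolume-class] with modality `"PMAP"`, values in mm^2/s
#'   scale.
#' @export
computePMap <- function(tensors) {
  stopifnot(is(tensors, "TensorField"))
  if (length(tensors@md) == 0)
    stop("mean diffusivity not computed; call eigenMetrics() first")
  p <- sqrt(3) * tensors@md
  p[!tensors@validMask] <- 0
  scalarVolume(p, spacing = tensors@spacing, modality = "PMAP")
}

#' Default diffusion gradient scheme
#'
#' One b = 0 measurement plus 12 unique gradient directions at
#' b = 1000 s/mm^2, the acquisition scheme the cohort protocol prescribes.
#' Directions are spread over the upper hemisphere with a Fibonacci spiral.
#'
#' @param b Non-zero b-value in s/mm^2 (default 1000).
#' @param nDirections Number of diffusion-weighted directions (default 12).
#' @return A list with `bvals` (length `nDirections + 1`) and `bvecs`
#'   (3 x (`nDirections + 1`) matrix; the b = 0 column is zero).
#' @export
defaultGradientScheme <- function(b = 1000, nDirections = 12L) {
  k <- seq_len(nDirections)
  golden <- pi * (3 - sqrt(5))
  z <- (k - 0.5) / nDirections          # upper hemisphere
  r <- sqrt(1 - z^2)
  th <- golden * (k - 1)
  g <- rbind(r * cos(th), r * sin(th), z)
  g <- sweep(g, 2, sqrt(colSums(g^2)), "/")
  dimnames(g) <- NULL
  list(bvals = c(0, rep(b, nDirections)), bvecs = cbind(c(0, 0, 0), g))
}

#' Read an FSL-dialect gradient table
#'
#' bval files are a single whitespace-separated row of b-values; bvec files
#' are three rows (x, y, z) of N columns.
#'
#' @param bvalPath,bvecPath Paths to the text files.
#' @return A list with `bvals` and `bvecs` as in [defaultGradientScheme()].
#' @export
readGradientTable <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecPath))
  if (nrow(bv) != 3L) {
    if (ncol(bv) == 3L) bv <- t(bv) else stop("bvec file must have 3 rows")
  }
  if (ncol(bv) != length(bvals))
    stop("bval/bvec length mismatch")
  dimnames(bv) <- NULL
  list(bvals = bvals, bvecs = bv)
}
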