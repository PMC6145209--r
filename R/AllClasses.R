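#' @import methods
NULL

.MODALITIES <- c("T2", "FLAIR", "PMAP", "GENERIC")

#' ScalarVolume: a 3D intensity grid with voxel spacing and a modality tag
#'
#' The common currency of the pipeline: a plain 3D numeric array plus the
#' physical voxel spacing in millimetres and a modality tag identifying the
#' contrast (`"T2"`, `"FLAIR"`, `"PMAP"`, or `"GENERIC"` for derived images
#' such as membership scores).
#'
#' @slot values 3D numeric array of intensities.
#' @slot spacing Numeric length-3, millimetres per voxel along x, y, z.
#' @slot modality Character scalar, one of `"T2"`, `"FLAIR"`, `"PMAP"`,
#'   `"GENERIC"`.
#' @slot frame Character scalar identifying the frame of reference; volumes
#'   and masks are only comparable within one frame.
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(values = "array", spacing = "numeric",
                 modality = "character", frame = "character"),
  prototype(spacing = c(1, 1, 1), modality = "GENERIC", frame = "default"))

setValidity("ScalarVolume", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive numbers (mm)")
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    return(sprintf("modality must be one of %s",
                   paste(.MODALITIES, collapse = ", ")))
  if (length(object@frame) != 1L) return("frame must be a single string")
  TRUE
})

#' Construct a ScalarVolume
#'
#' @param values 3D numeric array (a 2D matrix is promoted to a single-slice
#'   volume).
#' @param spacing Voxel spacing in mm per axis (length 3).
#' @param modality Modality tag: `"T2"`, `"FLAIR"`, `"PMAP"` or `"GENERIC"`.
#' @param frame Frame-of-reference identifier.
#' @return A [ScalarVolume-class] object.
#' @examples
#' v <- scalarVolume(array(runif(8 * 8 * 2), c(8, 8, 2)), spacing = c(0.9, 0.9, 5))
#' dim(voxelData(v))
#' @export
scalarVolume <- function(values, spacing = c(1, 1, 1), modality = "GENERIC",
                         frame = "default") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  new("ScalarVolume", values = values, spacing = as.numeric(spacing),
      modality = modality, frame = frame)
}

#' BinaryMask: a boolean region on a volume grid
#'
#' The unit of all area and overlap metrics. Masks are comparable only when
#' they share grid shape and frame of reference.
#'
#' @slot values 3D logical array.
#' @slot spacing Numeric length-3, mm per voxel.
#' @slot frame Frame-of-reference identifier.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(values = "array", spacing = "numeric", frame = "character"),
  prototype(spacing = c(1, 1, 1), frame = "default"))

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (!is.logical(v)) return("values must be logical")
  if (anyNA(v)) return("mask values must not contain NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive numbers (mm)")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param values 3D logical array (a matrix is promoted to one slice;
#'   numeric input is coerced with `!= 0`).
#' @param spacing Voxel spacing in mm per axis.
#' @param frame Frame-of-reference identifier.
#' @return A [BinaryMask-class] object.
#' @export
binaryMask <- function(values, spacing = c(1, 1, 1), frame = "default") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.logical(values)) {
    d <- dim(values)
    values <- array(as.logical(values != 0), d)
  }
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      frame = frame)
}

#' DiffusionAcquisition: diffusion-weighted volumes plus gradient scheme
#'
#' @slot dwi 4D numeric array (x, y, z, measurement) of DWI signal.
#' @slot bvals Numeric b-values in s/mm^2, one per measurement.
#' @slot bvecs 3 x N numeric matrix of gradient directions (unit vectors for
#'   non-zero b, zero vectors allowed for b = 0).
#' @slot spacing Voxel spacing in mm per axis.
#' @exportClass DiffusionAcquisition
setClass("DiffusionAcquisition",
  representation(dwi = "array", bvals = "numeric", bvecs = "matrix",
                 spacing = "numeric"))

setValidity("DiffusionAcquisition", function(object) {
  d <- dim(object@dwi)
  if (length(d) != 4L) return("dwi must be a 4D array (x, y, z, measurement)")
  n <- d[4L]
  if (length(object@bvals) != n)
    return("number of b-values must equal number of volumes")
  if (!all(dim(object@bvecs) == c(3L, n)))
    return("bvecs must be a 3 x N matrix matching the number of volumes")
  if (!any(object@bvals == 0)) return("at least one b = 0 measurement required")
  if (any(object@dwi < 0)) return("all intensities must be >= 0")
  nz <- object@bvals > 0
  if (any(nz)) {
    norms <- sqrt(colSums(object@bvecs[, nz, drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-6))
      return("all non-zero-b gradient directions must have unit norm (1e-6)")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive numbers (mm)")
  TRUE
})

#' Construct a DiffusionAcquisition
#'
#' @param dwi 4D numeric array (x, y, z, measurement).
#' @param bvals Numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x N matrix of gradient directions.
#' @param spacing Voxel spacing in mm.
#' @return A [DiffusionAcquisition-class] object.
#' @export
diffusionAcquisition <- function(dwi, bvals, bvecs, spacing = c(1, 1, 1)) {
  new("DiffusionAcquisition", dwi = dwi, bvals = as.numeric(bvals),
      bvecs = as.matrix(bvecs), spacing = as.numeric(spacing))
}

#' TensorField: per-voxel diffusion tensors with derived metrics
#'
#' Tensor components are stored in the order
#' `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s. Eigenvalues, when populated,
#' are sorted descending per voxel and `md` holds their mean (mean
#' diffusivity).
#'
#' @slot components 4D array (x, y, z, 6) of tensor components.
#' @slot eigenvalues 4D array (x, y, z, 3), descending per voxel; may be
#'   empty until [eigenMetrics()] is called.
#' @slot md 3D array of mean diffusivity; may be empty.
#' @slot validMask 3D logical array of voxels where the fit was performed.
#' @slot spacing Voxel spacing in mm.
#' @exportClass TensorField
setClass("TensorField",
  representation(components = "array", eigenvalues = "array", md = "array",
                 validMask = "array", spacing = "numeric"))

setValidity("TensorField", function(object) {
  dc <- dim(object@components)
  if (length(dc) != 4L || dc[4L] != 6L)
    return("components must be a 4D array with 6 components per voxel")
  grid <- dc[1:3]
  if (!all(dim(object@validMask) == grid) || !is.logical(object@validMask))
    return("validMask must be a logical array on the tensor grid")
  if (length(object@eigenvalues) > 0) {
    de <- dim(object@eigenvalues)
    if (length(de) != 4L || de[4L] != 3L || !all(de[1:3] == grid))
      return("eigenvalues must be (x, y, z, 3) on the tensor grid")
    ev <- matrix(object@eigenvalues, ncol = 3L)[object@validMask, , drop = FALSE]
    if (nrow(ev) > 0) {
      if (any(ev[, 1] < ev[, 2] - 1e-15) || any(ev[, 2] < ev[, 3] - 1e-15))
        return("eigenvalues must be sorted descending per voxel")
      if (length(object@md) > 0) {
        mdv <- object@md[object@validMask]
        scale <- pmax(abs(mdv), .Machine$double.xmin)
        if (any(abs(mdv - rowMeans(ev)) / scale > 1e-12))
          return("md must equal the eigenvalue mean (1e-12 relative)")
      }
    }
  }
  if (length(object@md) > 0 && !all(dim(object@md) == grid))
    return("md must be a 3D array on the tensor grid")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive numbers (mm)")
  TRUE
})

#' FCMResult: fuzzy C-means memberships, centroids and convergence trace
#'
#' @slot memberships N x C matrix of memberships in `[0, 1]`, rows summing
#'   to 1; row k corresponds to voxel `voxelIndex[k]`.
#' @slot centroids Numeric length C, cluster centre intensities.
#' @slot nIterations Integer iteration count at convergence.
#' @slot objective Numeric trace of the fuzzy objective, one value per
#'   iteration (non-increasing).
#' @slot voxelIndex Integer linear indices of the clustered voxels in the
#'   source grid.
#' @slot dim Integer length-3 source grid shape.
#' @exportClass FCMResult
setClass("FCMResult",
  representation(memberships = "matrix", centroids = "numeric",
                 nIterations = "integer", objective = "numeric",
                 voxelIndex = "integer", dim = "integer"))

setValidity("FCMResult", function(object) {
  u <- object@memberships
  if (nrow(u) != length(object@voxelIndex))
    return("memberships rows must match voxelIndex")
  if (ncol(u) != length(object@centroids))
    return("memberships columns must match centroids")
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    return("memberships must lie in [0, 1]")
  if (nrow(u) > 0 && any(abs(rowSums(u) - 1) > 1e-9))
    return("memberships must sum to 1 per voxel (1e-9)")
  if (any(!is.finite(object@centroids))) return("centroids must be finite")
  if (length(object@objective) > 1) {
    d <- diff(object@objective)
    if (any(d > 1e-9 * pmax(abs(object@objective[-length(object@objective)]), 1)))
      return("objective must be non-increasing across iterations")
  }
  TRUE
})

#' TissueClassMap: per-voxel tissue class derived from FCM ranks
#'
#' Classes are ranked by centroid intensity, descending: rank 0 is the
#' brightest class. `roles` maps each rank to its modality-specific tissue
#' role; `abnormalRanks` lists the ranks treated as hyper-signal abnormal
#' candidates (hyper + edema roles).
#'
#' @slot labels 3D integer array of class ranks in `0..C-1`; `NA` outside
#'   the clustered region.
#' @slot roles Character vector, one role name per rank.
#' @slot abnormalRanks Integer ranks whose role is abnormal candidate.
#' @slot modality Modality tag the semantics belong to.
#' @slot nTies Integer count of voxels whose membership was tied and broken
#'   by cluster index.
#' @exportClass TissueClassMap
setClass("TissueClassMap",
  representation(labels = "array", roles = "character",
                 abnormalRanks = "integer", modality = "character",
                 nTies = "integer"))

setValidity("TissueClassMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) > 0 && (min(lab) < 0 || max(lab) >= length(object@roles)))
    return("labels must be ranks covered by the roles table")
  if (any(object@abnormalRanks < 0) ||
      any(object@abnormalRanks >= length(object@roles)))
    return("abnormalRanks must be valid ranks")
  TRUE
})

#' SegmentationResult: FCM state, class map, and the abnormal mask
#'
#' @slot fcm The [FCMResult-class] behind the classification.
#' @slot classes The [TissueClassMap-class].
#' @slot abnormalMask The extracted hyper-signal abnormal
#'   [BinaryMask-class] (one connected component containing the seed).
#' @slot seed Integer voxel coordinate (1-based internally) of the seed.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(fcm = "FCMResult", classes = "TissueClassMap",
                 abnormalMask = "BinaryMask", seed = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarVolume [%s] %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              object@modality, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask %d x %d x %d, spacing %s mm, %d foreground voxels\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              sum(object@values)))
})

setMethod("show", "DiffusionAcquisition", function(object) {
  d <- dim(object@dwi)
  cat(sprintf("DiffusionAcquisition %d x %d x %d, %d measurements (%d with b = 0), b up to %g s/mm^2\n",
              d[1], d[2], d[3], d[4], sum(object@bvals == 0), max(object@bvals)))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@components)
  cat(sprintf("TensorField %d x %d x %d, %d valid voxels%s\n",
              d[1], d[2], d[3], sum(object@validMask),
              if (length(object@md) > 0) ", eigenvalues/MD computed" else ""))
})

setMethod("show", "FCMResult", function(object) {
  cat(sprintf("FCMResult: %d voxels, %d clusters, %d iterations, objective %.6g\n",
              nrow(object@memberships), length(object@centroids),
              object@nIterations, utils::tail(object@objective, 1)))
  cat("  centroids:", paste(format(object@centroids, digits = 4), collapse = ", "), "\n")
})

setMethod("show", "TissueClassMap", function(object) {
  cat(sprintf("TissueClassMap [%s]: %d classes\n", object@modality,
              length(object@roles)))
  for (i in seq_along(object@roles))
    cat(sprintf("  rank %d: %s%s\n", i - 1L, object@roles[i],
                if ((i - 1L) %in% object@abnormalRanks) " [abnormal candidate]" else ""))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n")
  show(object@classes)
  cat(sprintf("  abnormal mask: %d voxels; seed (%s)\n",
              sum(object@abnormalMask@values),
              paste(object@seed, collapse = ", ")))
})
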