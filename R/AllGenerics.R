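#' Accessors for volume-like objects
#'
#' `voxelData()` returns the underlying array, `spacing()` the voxel spacing
#' in mm, `modality()` the contrast tag, and `frameOfReference()` the frame
#' identifier shared by comparable objects.
#'
#' @param x A [ScalarVolume-class], [BinaryMask-class] or related object.
#' @return `voxelData()`: an array; `spacing()`: numeric length 3;
#'   `modality()`, `frameOfReference()`: character scalars.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname volume-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname volume-accessors
#' @export
setGeneric("frameOfReference", function(x) standardGeneric("frameOfReference"))

#' @rdname volume-accessors
setMethod("voxelData", "ScalarVolume", function(x) x@values)
#' @rdname volume-accessors
setMethod("voxelData", "BinaryMask", function(x) x@values)
#' @rdname volume-accessors
setMethod("spacing", "ScalarVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("spacing", "TensorField", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("modality", "ScalarVolume", function(x) x@modality)
#' @rdname volume-accessors
setMethod("frameOfReference", "ScalarVolume", function(x) x@frame)
#' @rdname volume-accessors
setMethod("frameOfReference", "BinaryMask", function(x) x@frame)

#' Accessors for FCM results
#'
#' @param x An [FCMResult-class].
#' @return `memberships()`: the N x C membership matrix; `centroids()`: the
#'   cluster centre intensities; `objectiveTrace()`: the per-iteration
#'   objective values.
#' @name fcm-accessors
NULL

#' @rdname fcm-accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname fcm-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname fcm-accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname fcm-accessors
setMethod("memberships", "FCMResult", function(x) x@memberships)
#' @rdname fcm-accessors
setMethod("centroids", "FCMResult", function(x) x@centroids)
#' @rdname fcm-accessors
setMethod("objectiveTrace", "FCMResult", function(x) x@objective)

#' Accessors for tensor fields and segmentation results
#'
#' @param x A [TensorField-class] or [SegmentationResult-class].
#' @return `tensorComponents()`: (x, y, z, 6) array; `eigenvalueMaps()`:
#'   (x, y, z, 3) array; `meanDiffusivity()`: 3D array; `validMask()`,
#'   `abnormalMask()`: [BinaryMask-class]; `classLabels()`: 3D integer array
#'   of class ranks.
#' @name tensor-accessors
NULL

#' @rdname tensor-accessors
#' @export
setGeneric("tensorComponents", function(x) standardGeneric("tensorComponents"))
#' @rdname tensor-accessors
#' @export
setGeneric("eigenvalueMaps", function(x) standardGeneric("eigenvalueMaps"))
#' @rdname tensor-accessors
#' @export
setGeneric("meanDiffusivity", function(x) standardGeneric("meanDiffusivity"))
#' @rdname tensor-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname tensor-accessors
#' @export
setGeneric("abnormalMask", function(x) standardGeneric("abnormalMask"))
#' @rdname tensor-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname tensor-accessors
setMethod("tensorComponents", "TensorField", function(x) x@components)
#' @rdname tensor-accessors
setMethod("eigenvalueMaps", "TensorField", function(x) x@eigenvalues)
#' @rdname tensor-accessors
setMethod("meanDiffusivity", "TensorField", function(x) x@md)
#' @rdname tensor-accessors
setMethod("validMask", "TensorField",
          function(x) binaryMask(x@validMask, spacing = x@spacing))
#' @rdname tensor-accessors
setMethod("abnormalMask", "SegmentationResult", function(x) x@abnormalMask)
#' @rdname tensor-accessors
setMethod("classLabels", "TissueClassMap", function(x) x@labels)
#' @rdname tensor-accessors
setMethod("classLabels", "SegmentationResult", function(x) x@classes@labels)
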