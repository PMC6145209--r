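#' Min-max intensity normalization
#'
#' Rescales a volume to grey levels in `[0, 1]`:
#' `(v - min) / (max - min)`. All segmentation operates on normalized
#' intensities, so region-growing tolerances are comparable across
#' modalities.
#'
#' @param vol A [ScalarVolume-class].
#' @return A [ScalarVolume-class] with minimum exactly 0 and maximum
#'   exactly 1.
#' @examples
#' v <- scalarVolume(array(c(2, 4, 6, 4), c(2, 2, 1)))
#' range(voxelData(normalizeIntensity(v)))
#' @export
normalizeIntensity <- function(vol) {
  stopifnot(is(vol, "ScalarVolume"))
  v <- vol@values
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("degenerate intensity range: volume is constant")
  scalarVolume((v - lo) / (hi - lo), spacing = vol@spacing,
               modality = vol@modality, frame = vol@frame)
}

# separable 3D Gaussian blur with edge replication; sigma in voxels per axis
.gaussianBlur3 <- function(v, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(v)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0 || d[ax] == 1L) next
    hw <- max(1L, ceiling(3 * s))
    kx <- (-hw):hw
    kern <- exp(-kx^2 / (2 * s^2))
    kern <- kern / sum(kern)
    # replicate-pad along axis `ax`, then weighted sum of shifted copies
    idx <- pmin(pmax(seq_len(d[ax] + 2L * hw) - hw, 1L), d[ax])
    padded <- switch(ax,
                     v[idx, , , drop = FALSE],
                     v[, idx, , drop = FALSE],
                     v[, , idx, drop = FALSE])
    out <- array(0, d)
    for (j in seq_along(kx)) {
      sl <- seq_len(d[ax]) + (j - 1L)
      out <- out + kern[j] * switch(ax,
                                    padded[sl, , , drop = FALSE],
                                    padded[, sl, , drop = FALSE],
                                    padded[, , sl, drop = FALSE])
    }
    v <- out
  }
  v
}

#' Unsharp-mask edge sharpening
#'
#' Edge enhancement applied to the p-map before segmentation:
#' `v + amount * (v - blur(v, radius))`, where the blur is an isotropic
#' Gaussian of scale `radius` voxels, with the result clipped back to
#' `[0, 1]`. With `amount = 0` the input is returned unchanged.
#'
#' @param vol A normalized [ScalarVolume-class] (values in `[0, 1]`).
#' @param radius Gaussian scale of the unsharp mask, in voxels (> 0).
#' @param amount Dimensionless gain (>= 0); default 0.3.
#' @return A [ScalarVolume-class] with values in `[0, 1]`.
#' @export
sharpenEdges <- function(vol, radius = 1, amount = 0.3) {
  stopifnot(is(vol, "ScalarVolume"), radius > 0, amount >= 0)
  v <- vol@values
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("sharpenEdges expects a normalized volume in [0, 1]")
  if (amount == 0) return(vol)
  blur <- .gaussianBlur3(v, radius)
  out <- v + amount * (v - blur)
  out[out < 0] <- 0
  out[out > 1] <- 1
  scalarVolume(out, spacing = vol@spacing, modality = vol@modality,
               frame = vol@frame)
}
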