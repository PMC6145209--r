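.checkComparable <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  if (!all(dim(a@values) == dim(b@values)))
    stop("masks are not comparable: different grid shapes")
  if (!identical(a@frame, b@frame))
    stop("masks are not comparable: different frames of reference")
  invisible(TRUE)
}

#' Area of a binary mask in cm^2
#'
#' The 2D area convention of the cohort comparison: number of foreground
#' pixels on one slice times the in-plane pixel area (mm^2), converted to
#' cm^2. With `scope = "maxslice"` (default) the slice with the largest
#' lesion extent is used, the single-area-per-patient convention; `"slice"`
#' measures the given `slice`; `"total"` sums over all slices.
#'
#' @param mask A [BinaryMask-class] with known in-plane spacing (anisotropic
#'   in-plane spacing is allowed).
#' @param slice Slice index for `scope = "slice"`.
#' @param scope `"maxslice"`, `"slice"` or `"total"`.
#' @return Area in cm^2 (0 for an empty mask).
#' @examples
#' m <- binaryMask(array(c(rep(TRUE, 100), rep(FALSE, 156)), c(16, 16, 1)),
#'                 spacing = c(0.9, 0.9, 5))
#' maskAreaCm2(m)  # 100 * 0.81 mm^2 = 0.81 cm^2
#' @export
maskAreaCm2 <- function(mask, slice = NULL,
                        scope = c("maxslice", "slice", "total")) {
  stopifnot(is(mask, "BinaryMask"))
  scope <- if (!is.null(slice)) "slice" else match.arg(scope)
  pixArea <- mask@spacing[1] * mask@spacing[2]  # mm^2
  counts <- apply(mask@values, 3L, sum)
  n <- switch(scope,
              maxslice = max(counts),
              slice = {
                stopifnot(slice >= 1L, slice <= dim(mask@values)[3L])
                counts[slice]
              },
              total = sum(counts))
  n * pixArea / 100
}

#' Discordance Index between two regions
#'
#' A location-agreement measure: the ratio of the union of the two regions
#' minus their intersection to the union,
#' \deqn{DI = (|A \cup B| - |A \cap B|) / |A \cup B|,}
#' i.e. 1 minus the Jaccard overlap. 0 means one region is perfectly
#' similar to the other; 1 means the two regions are completely apart.
#'
#' @param a,b Comparable [BinaryMask-class] objects with non-empty union.
#' @return DI in `[0, 1]`.
#' @export
discordanceIndex <- function(a, b) {
  .checkComparable(a, b)
  un <- sum(a@values | b@values)
  if (un == 0) stop("DI undefined: both masks are empty")
  (un - sum(a@values & b@values)) / un
}

#' Dice score between two regions
#'
#' \deqn{DS = 2 |A \cap B| / (|A| + |B|)}
#'
#' @param a,b Comparable [BinaryMask-class] objects, not both empty.
#' @return Dice score in `[0, 1]`.
#' @export
diceScore <- function(a, b) {
  .checkComparable(a, b)
  sa <- sum(a@values); sb <- sum(b@values)
  if (sa + sb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a@values & b@values) / (sa + sb)
}

#' Sensitivity and specificity of a predicted mask
#'
#' Confusion-matrix rates of `pred` against `truth`. True negatives are
#' counted inside `domain` (the brain mask) only, so specificity is not
#' inflated by image background.
#'
#' @param pred,truth Comparable [BinaryMask-class] objects; `truth` must be
#'   non-empty.
#' @param domain [BinaryMask-class] containing both (the brain mask).
#' @return Named numeric: `sensitivity` = TP/(TP+FN),
#'   `specificity` = TN/(TN+FP) with TN restricted to `domain`.
#' @export
sensitivitySpecificity <- function(pred, truth, domain) {
  .checkComparable(pred, truth)
  .checkComparable(pred, domain)
  if (sum(truth@values) == 0) stop("sensitivity undefined: empty truth mask")
  p <- pred@values; t <- truth@values; d <- domain@values
  tp <- sum(p & t)
  fn <- sum(!p & t)
  fp <- sum(p & !t & d)
  tn <- sum(!p & !t & d)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Full agreement report between two abnormal masks
#'
#' @param a,b Comparable [BinaryMask-class] objects.
#' @param domain [BinaryMask-class] brain mask for the specificity
#'   restriction (`b` is treated as the reference for
#'   sensitivity/specificity).
#' @param pair Label for the mask pair (e.g. `"T2-PMAP"`).
#' @return One-row `data.frame` with columns `pair`, `area_a_cm2`,
#'   `area_b_cm2`, `dice`, `di`, `sensitivity`, `specificity`.
#' @export
agreementReport <- function(a, b, domain, pair = "A-B") {
  ss <- sensitivitySpecificity(a, b, domain)
  data.frame(pair = pair,
             area_a_cm2 = maskAreaCm2(a),
             area_b_cm2 = maskAreaCm2(b),
             dice = diceScore(a, b),
             di = discordanceIndex(a, b),
             sensitivity = unname(ss["sensitivity"]),
             specificity = unname(ss["specificity"]),
             stringsAsFactors = FALSE)
}
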