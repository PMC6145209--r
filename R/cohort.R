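#' Load the packaged 25-patient area / discordance table
#'
#' Per-patient abnormal-region areas (cm^2) on T2, T2-FLAIR and the p-map,
#' and the three pairwise Discordance Indices, as published for the
#' 25-patient glioblastoma cohort. Column sums are verified against stored
#' checksums so silent fixture corruption is a packaging error.
#'
#' @return A `data.frame` with 25 rows and columns `patient_id`, `area_t2`,
#'   `area_flair`, `area_pmap`, `di_tp`, `di_fp`, `di_tf`.
#' @examples
#' tbl <- loadTable3()
#' round(mean(tbl$di_tp), 3)
#' @export
loadTable3 <- function() {
  path <- system.file("extdata", "table3.csv", package = "glioseg",
                      mustWork = TRUE)
  d <- utils::read.csv(path)
  expected <- c(patient_id = 325, area_t2 = 322.43, area_flair = 350.27,
                area_pmap = 264.85, di_tp = 11.706, di_fp = 11.569,
                di_tf = 10.584)
  got <- round(vapply(d[names(expected)], sum, numeric(1)), 3)
  if (nrow(d) != 25L || any(abs(got - expected) > 1e-9))
    stop("packaging error: table3.csv checksum mismatch")
  d
}

#' Symmetric percent difference between two areas
#'
#' `100 * |a - b| / max(a, b)`: symmetric in its arguments and bounded by
#' 100%.
#'
#' @param a,b Areas (cm^2), vectorized; `max(a, b) > 0` required.
#' @return Percent difference.
#' @export
percentDifference <- function(a, b) {
  m <- pmax(a, b)
  if (any(m <= 0)) stop("percent difference requires max(a, b) > 0")
  100 * abs(a - b) / m
}

#' Size category of a patient's three abnormal areas
#'
#' Classifies the p-map area against the T2 and FLAIR areas:
#' `EQUAL` when all pairwise percent differences are below
#' `100 * equalTol` (the "approximately equal, mean difference < 5%" rule),
#' else `P_SMALLEST` (A_P smaller than both), `P_LARGEST` (larger than
#' both), or `P_BETWEEN`. Scale-invariant: multiplying all three areas by
#' any positive constant leaves the category unchanged.
#'
#' @param areaT2,areaFlair,areaPmap Positive areas in cm^2 (vectorized).
#' @param equalTol Fractional tolerance for `EQUAL` (default 0.05).
#' @return Character vector in
#'   `c("P_SMALLEST", "P_LARGEST", "P_BETWEEN", "EQUAL")`.
#' @export
categorizePatient <- function(areaT2, areaFlair, areaPmap, equalTol = 0.05) {
  stopifnot(all(areaT2 > 0), all(areaFlair > 0), all(areaPmap > 0))
  n <- max(length(areaT2), length(areaFlair), length(areaPmap))
  areaT2 <- rep_len(areaT2, n); areaFlair <- rep_len(areaFlair, n)
  areaPmap <- rep_len(areaPmap, n)
  out <- character(n)
  for (i in seq_len(n)) {
    t2 <- areaT2[i]; fl <- areaFlair[i]; p <- areaPmap[i]
    pds <- c(percentDifference(p, t2), percentDifference(p, fl),
             percentDifference(t2, fl))
    out[i] <- if (all(pds < 100 * equalTol)) "EQUAL"
    else if (p < t2 && p < fl) "P_SMALLEST"
    else if (p > t2 && p > fl) "P_LARGEST"
    else "P_BETWEEN"
  }
  out
}

#' Cohort-level summary of areas and discordance indices
#'
#' Per-pair DI summaries (mean, sample SD, min, max), size-category counts
#' with mean percent differences per category, and the T2 vs FLAIR size
#' comparison. Counts are recomputed strictly from the records; for the
#' published table they differ slightly from the prose counts (an internal
#' inconsistency of the source), so the recomputation is authoritative
#' here.
#'
#' @param records `data.frame` in [loadTable3()] layout (columns
#'   `area_t2`, `area_flair`, `area_pmap`, `di_tp`, `di_fp`, `di_tf`).
#' @param equalTol Fractional tolerance for the `EQUAL` category.
#' @return A list with elements:
#'   \describe{
#'     \item{diSummary}{`data.frame` of mean/sd/min/max per DI pair.}
#'     \item{categories}{per-record category vector.}
#'     \item{categoryCounts}{named counts over the four categories.}
#'     \item{categoryMeanDiff}{mean percent difference of A_P vs A_T2 and
#'       A_P vs A_F per category (plus SD).}
#'     \item{t2FlairComparison}{counts and mean percent differences for
#'       A_F > A_T2 and A_T2 > A_F.}
#'     \item{n}{cohort size.}
#'   }
#' @export
summarizeCohort <- function(records, equalTol = 0.05) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  need <- c("area_t2", "area_flair", "area_pmap", "di_tp", "di_fp", "di_tf")
  stopifnot(all(need %in% names(records)))
  single <- nrow(records) == 1L
  if (single)
    message("summarizeCohort: single-record cohort, SD reported as 0")
  sdOr0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  diCols <- c(di_tp = "di_tp", di_fp = "di_fp", di_tf = "di_tf")
  diSummary <- do.call(rbind, lapply(names(diCols), function(nm) {
    x <- records[[diCols[[nm]]]]
    data.frame(pair = nm, mean = mean(x), sd = sdOr0(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  cats <- categorizePatient(records$area_t2, records$area_flair,
                            records$area_pmap, equalTol = equalTol)
  levelsCat <- c("P_SMALLEST", "P_LARGEST", "P_BETWEEN", "EQUAL")
  counts <- table(factor(cats, levels = levelsCat))
  pdT2 <- percentDifference(records$area_pmap, records$area_t2)
  pdF <- percentDifference(records$area_pmap, records$area_flair)
  categoryMeanDiff <- do.call(rbind, lapply(levelsCat, function(cc) {
    sel <- cats == cc
    data.frame(category = cc, n = sum(sel),
               mean_pd_p_t2 = if (any(sel)) mean(pdT2[sel]) else NA_real_,
               sd_pd_p_t2 = if (any(sel)) sdOr0(pdT2[sel]) else NA_real_,
               mean_pd_p_flair = if (any(sel)) mean(pdF[sel]) else NA_real_,
               sd_pd_p_flair = if (any(sel)) sdOr0(pdF[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pdTF <- percentDifference(records$area_t2, records$area_flair)
  fLarger <- records$area_flair > records$area_t2
  t2FlairComparison <- data.frame(
    comparison = c("flair_larger", "t2_larger"),
    n = c(sum(fLarger), sum(!fLarger)),
    mean_pd = c(if (any(fLarger)) mean(pdTF[fLarger]) else NA_real_,
                if (any(!fLarger)) mean(pdTF[!fLarger]) else NA_real_),
    stringsAsFactors = FALSE)
  list(diSummary = diSummary, categories = cats,
       categoryCounts = counts, categoryMeanDiff = categoryMeanDiff,
       t2FlairComparison = t2FlairComparison, n = nrow(records))
}
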