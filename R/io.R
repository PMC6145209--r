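#' Read a NIfTI volume as a ScalarVolume
#'
#' Reads NIfTI-1/2, gzipped or plain. Voxel spacing comes from the header
#' `pixdim`; the header orientation string is recorded as the frame of
#' reference so co-registration mismatches between modalities surface as
#' frame errors at comparison time.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag to attach (`"T2"`, `"FLAIR"`, `"PMAP"`,
#'   `"GENERIC"`).
#' @return A [ScalarVolume-class].
#' @export
readVolume <- function(path, modality = "GENERIC") {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim(img))
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 1L))
  if (length(dim(v)) != 3L) stop("expected a 3D volume: ", path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- abs(sp[1:3])
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("voxel spacing missing or invalid in NIfTI header: ", path)
  frame <- paste(c(dim(v), signif(sp, 6)), collapse = "x")
  scalarVolume(v, spacing = sp, modality = modality, frame = frame)
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as uint8 (0/1), volumes as float32. Use a `.nii`
#' filename for byte-reproducible output (`.nii.gz` embeds a gzip
#' timestamp on some platforms).
#'
#' @param x A [ScalarVolume-class] or [BinaryMask-class].
#' @param path Output filename (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BinaryMask")) {
    arr <- array(as.integer(x@values), dim(x@values))
    dt <- "uint8"
  } else if (is(x, "ScalarVolume")) {
    arr <- x@values
    dt <- "float"
  } else stop("x must be a ScalarVolume or BinaryMask")
  attr(arr, "pixdim") <- spacing(x)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = dt), path, datatype = dt)
  invisible(path)
}

#' Read a BinaryMask from NIfTI
#'
#' @param path Path to the mask file (any non-zero voxel is foreground).
#' @return A [BinaryMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  binaryMask(v@values != 0, spacing = v@spacing, frame = v@frame)
}

.checkCoregistered <- function(vols) {
  dims <- lapply(vols, function(v) dim(v@values))
  sps <- lapply(vols, spacing)
  ref <- dims[[1]]
  for (i in seq_along(vols)) {
    if (!all(dims[[i]] == ref))
      stop("input volumes are not co-registered (grid mismatch); ",
           "register them externally before running the pipeline")
    if (any(abs(sps[[i]] - sps[[1]]) > 1e-3))
      stop("input volumes are not co-registered (spacing mismatch); ",
           "register them externally before running the pipeline")
  }
  invisible(TRUE)
}

#' Run the full multimodal comparison pipeline
#'
#' Per modality: normalization, sharpening (p-map), four-class FCM,
#' tissue-class assignment, and abnormal-mask extraction around the seed;
#' then all pairwise agreement reports (area, Dice, DI, sensitivity,
#' specificity) and a cohort-style row of the three areas. Deterministic
#' given the configuration.
#'
#' The configuration is a named list (or a YAML file path) with entries:
#' \describe{
#'   \item{volumes}{named list (`t2`, `flair`, `pmap`) of NIfTI paths or
#'     [ScalarVolume-class] objects; any subset of >= 1 modality.}
#'   \item{brain_mask}{optional NIfTI path or [BinaryMask-class]; when
#'     absent it is estimated from the first volume.}
#'   \item{seed}{voxel coordinate (1-based, length 3) of the seed point,
#'     or a named list of per-modality seeds.}
#'   \item{tolerance}{region-growing tolerance (default 0.1).}
#'   \item{rng_seed}{integer FCM restart seed (default 1).}
#'   \item{sharpen_radius, sharpen_amount}{unsharp-mask parameters.}
#'   \item{outdir}{output directory; when given, masks (`.nii`), a report
#'     CSV and a JSON run manifest are written.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return The run manifest: a list with the configuration echo, package
#'   version, seeds, per-stage timings, output file list, per-pair
#'   agreement reports (`data.frame`) and the per-modality areas.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$volumes))
  modTag <- c(t2 = "T2", flair = "FLAIR", pmap = "PMAP")
  present <- intersect(names(modTag), names(config$volumes))
  if (length(present) < 1L) stop("config$volumes must name t2/flair/pmap")
  omitted <- setdiff(names(modTag), present)
  vols <- lapply(present, function(m) {
    v <- config$volumes[[m]]
    if (is.character(v)) readVolume(v, modality = modTag[[m]])
    else { stopifnot(is(v, "ScalarVolume")); v }
  })
  names(vols) <- present
  .checkCoregistered(vols)
  frame <- vols[[1]]@frame
  brain <- config$brain_mask
  if (is.character(brain)) brain <- readMask(brain)
  if (is.null(brain)) brain <- estimateBrainMask(vols[[1]])
  brain@frame <- frame
  stopifnot(all(dim(brain@values) == dim(vols[[1]]@values)))
  tolerance <- config$tolerance %||% 0.1
  rngSeed <- as.integer(config$rng_seed %||% 1L)
  seeds <- config$seed
  if (is.null(seeds)) stop("config$seed (voxel coordinate) is required")
  if (!is.list(seeds)) seeds <- stats::setNames(rep(list(seeds), length(present)), present)

  timings <- c()
  segs <- list()
  for (m in present) {
    t0 <- proc.time()[["elapsed"]]
    segs[[m]] <- segmentVolume(vols[[m]], seed = unlist(seeds[[m]]),
                               modality = modTag[[m]], brainMask = brain,
                               tolerance = tolerance,
                               sharpenRadius = config$sharpen_radius %||% 1,
                               sharpenAmount = config$sharpen_amount %||% 0.3,
                               seedRng = rngSeed)
    timings[paste0("segment_", m)] <- proc.time()[["elapsed"]] - t0
  }
  masks <- lapply(segs, abnormalMask)
  for (m in present) masks[[m]]@frame <- frame

  pairs <- utils::combn(present, min(2L, length(present)), simplify = FALSE)
  reports <- NULL
  if (length(present) >= 2L) {
    reports <- do.call(rbind, lapply(pairs, function(pr) {
      agreementReport(masks[[pr[1]]], masks[[pr[2]]], brain,
                      pair = paste(modTag[pr], collapse = "-"))
    }))
  }
  areas <- vapply(masks, maskAreaCm2, numeric(1))

  outputs <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    for (m in present) {
      f <- file.path(config$outdir, paste0("mask_", m, ".nii"))
      writeVolume(masks[[m]], f)
      outputs <- c(outputs, f)
    }
    if (!is.null(reports)) {
      f <- file.path(config$outdir, "report.csv")
      fmt <- reports
      for (cc in names(fmt)) if (is.numeric(fmt[[cc]]))
        fmt[[cc]] <- sprintf("%.6f", fmt[[cc]])
      utils::write.csv(fmt, f, row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    }
  }
  # config echo keeps only serializable entries (paths, scalars, seeds)
  echo <- config[setdiff(names(config), "volumes")]
  echo <- echo[vapply(echo, function(x)
    is.atomic(x) || (is.list(x) && all(vapply(x, is.atomic, logical(1)))),
    logical(1))]
  manifest <- list(
    config = echo,
    modalities = present,
    omitted_modalities = omitted,
    package_version = as.character(utils::packageVersion("glioseg")),
    rng_seed = rngSeed,
    timings_sec = as.list(round(timings, 3)),
    outputs = outputs,
    areas_cm2 = as.list(areas),
    reports = reports)
  if (!is.null(config$outdir)) {
    mf <- file.path(config$outdir, "manifest.json")
    m2 <- manifest
    m2$reports <- if (!is.null(reports)) reports else NULL
    jsonlite::write_json(m2, mf, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    manifest$outputs <- c(outputs, mf)
  }
  manifest$segmentations <- segs
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
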