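# Tissue ids used throughout the generator
.TISSUES <- c("background", "skull", "scalp", "wm", "gm", "csf", "edema", "core")

# Normalized intensity per tissue and modality. Orderings follow the
# four-class model of each contrast: on T2 CSF/edema are intermediate and
# skull/background darkest; on FLAIR CSF is suppressed to near zero; the
# p-map column is derived from the mean-diffusivity table below
# (p = sqrt(3) * MD, normalized by the CSF maximum).
.MD_TABLE <- c(background = 0, skull = 0.07e-3, scalp = 0.78e-3,
               wm = 0.78e-3, gm = 0.82e-3, csf = 3.0e-3,
               edema = 1.7e-3, core = 2.9e-3)

.INTENSITY_TABLE <- cbind(
  T2    = c(background = 0, skull = 0.06, scalp = 0.34, wm = 0.33,
            gm = 0.355, csf = 0.68, edema = 0.64, core = 0.96),
  FLAIR = c(background = 0, skull = 0.04, scalp = 0.34, wm = 0.33,
            gm = 0.355, csf = 0.05, edema = 0.65, core = 0.96),
  PMAP  = .MD_TABLE / max(.MD_TABLE))

#' PhantomSpec: parameters of one synthetic multimodal phantom
#'
#' Describes a co-registered T2 / FLAIR / p-map phantom: an ellipsoidal
#' brain with skull and scalp shells, CSF ventricles, and a lesion made of
#' a necrotic/cystic core plus a hyper-signal edema rim whose extent is
#' modality-specific (`rimFactors` scale the core radii per modality, so
#' the per-modality truth masks are deliberately discordant).
#'
#' @slot gridShape Integer length-3 grid size in voxels.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot lesionCenter Numeric length-3 lesion centre in voxel coordinates.
#' @slot coreRadii Numeric length-3 semi-axes of the necrotic core, voxels.
#' @slot rimFactors Named numeric (`T2`, `FLAIR`, `PMAP`): in-plane rim
#'   semi-axes as multiples of the core semi-axes (through-plane growth is
#'   damped to 60% of the in-plane factor).
#' @slot noiseModel `"rician"` or `"gaussian"`.
#' @slot noiseSigma Noise SD as a fraction of the dynamic range.
#' @slot rngSeed Integer seed; generation is deterministic given it.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 lesionCenter = "numeric", coreRadii = "numeric",
                 rimFactors = "numeric", noiseModel = "character",
                 noiseSigma = "numeric", rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("gridShape must be 3 integers >= 8")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be positive")
  if (length(object@coreRadii) != 3L || any(object@coreRadii <= 0))
    return("coreRadii must be positive")
  if (!all(c("T2", "FLAIR", "PMAP") %in% names(object@rimFactors)))
    return("rimFactors must be named T2, FLAIR, PMAP")
  if (any(object@rimFactors < 1))
    return("rimFactors must be >= 1 (rim contains the core)")
  if (!object@noiseModel %in% c("rician", "gaussian"))
    return("noiseModel must be 'rician' or 'gaussian'")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults give a 128 x 128 x 20 grid at 0.9 x 0.9 x 5 mm (the FLAIR
#' acquisition geometry), which lands max-slice lesion areas in the
#' few-cm^2 range of the cohort table.
#'
#' @param gridShape,spacing,lesionCenter,coreRadii,rimFactors,noiseModel,noiseSigma,rngSeed
#'   See [PhantomSpec-class]. `lesionCenter = NULL` places the lesion
#'   anterior to the ventricles, offset from the grid centre.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(128L, 128L, 20L),
                        spacing = c(0.9, 0.9, 5),
                        lesionCenter = NULL,
                        coreRadii = NULL,
                        rimFactors = c(T2 = 1.4, FLAIR = 1.5, PMAP = 1.25),
                        noiseModel = "rician", noiseSigma = 0.04,
                        rngSeed = 1L) {
  gridShape <- as.integer(round(gridShape))
  scaleXY <- gridShape[1:2] / 128
  scaleZ <- gridShape[3] / 20
  if (is.null(lesionCenter)) {
    ctr <- (gridShape + 1) / 2
    lesionCenter <- ctr + c(8 * scaleXY[1], 17 * scaleXY[2], 0)
  }
  if (is.null(coreRadii))
    coreRadii <- c(15 * scaleXY, 2.8 * scaleZ)
  new("PhantomSpec", gridShape = gridShape, spacing = as.numeric(spacing),
      lesionCenter = as.numeric(lesionCenter),
      coreRadii = as.numeric(coreRadii), rimFactors = rimFactors,
      noiseModel = noiseModel, noiseSigma = noiseSigma,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s voxels @ %s mm, lesion at (%s), core radii (%s), rim factors T2=%.2f FLAIR=%.2f PMAP=%.2f, %s noise sigma=%.3f, seed %d\n",
              paste(object@gridShape, collapse = "x"),
              paste(format(object@spacing, digits = 3), collapse = "x"),
              paste(format(object@lesionCenter, digits = 4), collapse = ", "),
              paste(format(object@coreRadii, digits = 3), collapse = ", "),
              object@rimFactors[["T2"]], object@rimFactors[["FLAIR"]],
              object@rimFactors[["PMAP"]], object@noiseModel,
              object@noiseSigma, object@rngSeed))
})

#' PhantomBundle: one generated co-registered multimodal phantom
#'
#' @slot t2,flair,pmap [ScalarVolume-class] per modality.
#' @slot brainMask [BinaryMask-class] of the brain (inside the skull).
#' @slot truthMasks Named list of per-modality ground-truth abnormal
#'   [BinaryMask-class] objects (core + modality-specific edema rim).
#' @slot tissueLabels Named list of per-modality integer tissue-label
#'   arrays (indices into the tissue table).
#' @slot tensorField [TensorField-class] underlying the p-map.
#' @slot lesionSeed Integer voxel coordinate inside the lesion core.
#' @slot spec The generating [PhantomSpec-class].
#' @exportClass PhantomBundle
setClass("PhantomBundle",
  representation(t2 = "ScalarVolume", flair = "ScalarVolume",
                 pmap = "ScalarVolume", brainMask = "BinaryMask",
                 truthMasks = "list", tissueLabels = "list",
                 tensorField = "TensorField", lesionSeed = "integer",
                 spec = "PhantomSpec"))

#' @param name Slot name.
#' @rdname PhantomBundle-class
#' @param x A `PhantomBundle`.
#' @export
setMethod("$", "PhantomBundle", function(x, name) slot(x, name))

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle\n  ")
  show(object@spec)
  for (m in names(object@truthMasks))
    cat(sprintf("  truth %s: %d voxels\n", m, sum(object@truthMasks[[m]]@values)))
})

.ellipsoid <- function(X, Y, Z, center, radii) {
  ((X - center[1]) / radii[1])^2 + ((Y - center[2]) / radii[2])^2 +
    ((Z - center[3]) / radii[3])^2 <= 1
}

.rimRadii <- function(spec, modality) {
  f <- spec@rimFactors[[modality]]
  fz <- 1 + (f - 1) * 0.6
  spec@coreRadii * c(f, f, fz)
}

.addNoise <- function(v, sigma, model) {
  if (sigma <= 0) return(v)
  n <- length(v)
  if (model == "gaussian") {
    v + stats::rnorm(n, 0, sigma)
  } else {
    sqrt((v + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
}

#' Generate a co-registered multimodal phantom
#'
#' Builds the tissue geometry of [PhantomSpec-class], paints per-modality
#' intensities from the tissue table, adds Rician (or Gaussian) noise, and
#' derives the p-map from the underlying diffusion tensor field
#' (anisotropic in white matter, isotropic elsewhere). Deterministic given
#' `spec@rngSeed`.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [PhantomBundle-class]. The tensor field is returned without
#'   eigen-decomposition (call [eigenMetrics()] when needed).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(48, 48, 10), rngSeed = 3))
#' ph
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@gridShape
  ctr <- (d + 1) / 2
  half <- (d - 1) / 2
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)

  brainR <- c(0.72, 0.80, 0.84) * half
  skullR <- brainR + c(0.047, 0.047, 0.063) * half
  scalpR <- skullR + c(0.047, 0.047, 0.063) * half
  brain <- .ellipsoid(X, Y, Z, ctr, brainR)
  skull <- .ellipsoid(X, Y, Z, ctr, skullR) & !brain
  scalp <- .ellipsoid(X, Y, Z, ctr, scalpR) & !brain & !skull
  gmInner <- .ellipsoid(X, Y, Z, ctr, brainR * 0.85)
  ventR <- c(0.055, 0.126, 0.17) * half
  vent <- .ellipsoid(X, Y, Z, ctr + c(-0.11 * half[1], -0.3 * half[2], 0), ventR) |
          .ellipsoid(X, Y, Z, ctr + c(0.11 * half[1], -0.3 * half[2], 0), ventR)
  vent <- vent & brain

  core <- .ellipsoid(X, Y, Z, spec@lesionCenter, spec@coreRadii)
  rims <- lapply(c(T2 = "T2", FLAIR = "FLAIR", PMAP = "PMAP"), function(m)
    .ellipsoid(X, Y, Z, spec@lesionCenter, .rimRadii(spec, m)))
  maxRim <- rims[[which.max(spec@rimFactors[c("T2", "FLAIR", "PMAP")])]]
  if (any(maxRim & !brain))
    stop("invalid phantom spec: lesion overlaps the skull or leaves the brain")
  if (any(maxRim & vent))
    stop("invalid phantom spec: lesion overlaps the ventricles")

  baseLab <- array(1L, d)                       # background
  baseLab[scalp] <- 3L
  baseLab[skull] <- 2L
  baseLab[brain] <- 5L                          # gm
  baseLab[gmInner & brain] <- 4L                # wm
  baseLab[vent] <- 6L                           # csf

  labelsFor <- function(m) {
    lab <- baseLab
    lab[rims[[m]] & brain] <- 7L                # edema
    lab[core] <- 8L
    lab
  }
  labs <- lapply(c(T2 = "T2", FLAIR = "FLAIR", PMAP = "PMAP"), labelsFor)

  set.seed(spec@rngSeed)
  vols <- lapply(c(T2 = "T2", FLAIR = "FLAIR", PMAP = "PMAP"), function(m) {
    v <- array(.INTENSITY_TABLE[labs[[m]], m], d)
    # the p-map is a fitted parameter map pooled over the whole diffusion
    # acquisition (1 b0 + 12 directions), so its voxel noise is well below
    # the structural images at matched acquisition SNR
    sigma <- if (m == "PMAP") spec@noiseSigma / 2 else spec@noiseSigma
    v <- array(.addNoise(as.vector(v), sigma, spec@noiseModel), d)
    scalarVolume(v, spacing = spec@spacing, modality = m)
  })

  # diffusion tensor field behind the p-map: white matter anisotropic
  # (1.65, 0.3, 0.3) x 1e-3 mm^2/s along x, everything else isotropic at
  # the tissue mean diffusivity
  md <- .MD_TABLE[labs$PMAP]
  comps <- matrix(0, nrow = prod(d), ncol = 6L)
  comps[, 1:3] <- md
  wmIdx <- labs$PMAP == 4L
  comps[wmIdx, 1] <- 1.65e-3
  comps[wmIdx, 2] <- 0.3e-3
  comps[wmIdx, 3] <- 0.3e-3
  tf <- tensorFieldFromArray(array(comps, c(d, 6L)), spacing = spec@spacing,
                             validMask = array(baseLab != 1L, d),
                             computeMetrics = FALSE)

  truth <- lapply(c(T2 = "T2", FLAIR = "FLAIR", PMAP = "PMAP"), function(m)
    binaryMask((rims[[m]] & brain) | core, spacing = spec@spacing))

  new("PhantomBundle", t2 = vols$T2, flair = vols$FLAIR, pmap = vols$PMAP,
      brainMask = binaryMask(brain, spacing = spec@spacing),
      truthMasks = truth, tissueLabels = labs, tensorField = tf,
      lesionSeed = as.integer(round(spec@lesionCenter)), spec = spec)
}

#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Forward monoexponential model
#' \eqn{S_i = S_0 \exp(-b_i\, g_i^T D g_i)} per measurement, with Rician
#' noise at the given SNR (`snr = Inf` for noiseless).
#'
#' @param tensors A [TensorField-class] (tensors assumed SPD).
#' @param bvals,bvecs Gradient scheme as from [defaultGradientScheme()].
#' @param s0 Baseline signal (> 0).
#' @param snr Signal-to-noise ratio `s0 / sigma`; `Inf` disables noise.
#' @param rngSeed Integer seed for the noise draws.
#' @return A [DiffusionAcquisition-class].
#' @export
simulateDWI <- function(tensors, bvals, bvecs, s0 = 1000, snr = Inf,
                        rngSeed = 1L) {
  stopifnot(is(tensors, "TensorField"))
  if (s0 <= 0) stop("s0 must be positive")
  bvecs <- as.matrix(bvecs)
  n <- length(bvals)
  stopifnot(ncol(bvecs) == n)
  grid <- dim(tensors@components)[1:3]
  comps <- matrix(tensors@components, ncol = 6L)
  sig <- matrix(0, nrow = prod(grid), ncol = n)
  for (i in seq_len(n)) {
    g <- bvecs[, i]
    q <- bvals[i] * c(g[1]^2, g[2]^2, g[3]^2,
                      2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
    sig[, i] <- s0 * exp(-as.vector(comps %*% q))
  }
  if (is.finite(snr)) {
    set.seed(as.integer(rngSeed))
    sigma <- s0 / snr
    sig <- sqrt((sig + stats::rnorm(length(sig), 0, sigma))^2 +
                  stats::rnorm(length(sig), 0, sigma)^2)
  }
  diffusionAcquisition(array(sig, c(grid, n)), bvals, bvecs,
                       spacing = tensors@spacing)
}

#' Default benchmark suite of phantom specs
#'
#' `n` reproducible phantom specifications with varied lesion positions,
#' core sizes, noise levels (sigma uniform in 0.02-0.06) and per-modality
#' rim orderings. The suite covers, by construction, the three size
#' orderings observed in the cohort (p-map smallest / largest /
#' in-between) in roughly their observed proportions, plus one
#' approximately-equal case per 20 phantoms.
#'
#' @param nPhantoms Number of specs (default 20).
#' @param rngSeed Integer seed; the suite is deterministic given it.
#' @return A list of [PhantomSpec-class] objects; each carries its own
#'   derived `rngSeed`.
#' @export
defaultBenchmarkSuite <- function(nPhantoms = 20L, rngSeed = 1L) {
  stopifnot(nPhantoms >= 1L)
  set.seed(as.integer(rngSeed))
  nSmall <- max(1L, round(0.6 * nPhantoms))
  nLarge <- max(if (nPhantoms >= 4L) 1L else 0L, round(0.2 * nPhantoms))
  nEqual <- if (nPhantoms >= 10L) max(1L, round(0.05 * nPhantoms)) else 0L
  nBetween <- max(0L, nPhantoms - nSmall - nLarge - nEqual)
  kinds <- rep(c("smallest", "largest", "between", "equal"),
               c(nSmall, nLarge, nBetween, nEqual))[seq_len(nPhantoms)]
  factorsFor <- function(kind) switch(kind,
    smallest = c(T2 = 1.4, FLAIR = 1.5, PMAP = 1.25),
    largest  = c(T2 = 1.3, FLAIR = 1.4, PMAP = 1.5),
    between  = c(T2 = 1.3, FLAIR = 1.5, PMAP = 1.4),
    equal    = c(T2 = 1.4, FLAIR = 1.4, PMAP = 1.4))
  seeds <- sample.int(1e6, nPhantoms)
  lapply(seq_len(nPhantoms), function(i) {
    grid <- c(128L, 128L, 20L)
    ctr <- (grid + 1) / 2
    phantomSpec(
      gridShape = grid,
      lesionCenter = ctr + c(stats::runif(1, -9, 9),
                             stats::runif(1, 13, 17),
                             stats::runif(1, -1, 1)),
      coreRadii = c(stats::runif(1, 14, 16), stats::runif(1, 14, 16),
                    stats::runif(1, 2.6, 3.2)),
      rimFactors = factorsFor(kinds[i]),
      noiseSigma = stats::runif(1, 0.02, 0.06),
      rngSeed = seeds[i])
  })
}
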