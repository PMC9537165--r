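#' @include AllClasses.R utils.R adcm.R
NULL

# Organ-multiplier profiles: activity multipliers by organ label, emulating
# tracer-specific biodistributions. "fdg" is the base glucose-analogue
# pattern; "liver-avid" mimics hepatobiliary / somatostatin-receptor agents
# with strongly elevated hepatic (and splenic-like) uptake; "flat" mimics a
# tracer with near-uniform soft-tissue uptake.
TRACER_PROFILES <- list(
  "fdg"        = c(body = 100, lung = 30, liver = 200, heart = 250,
                   kidney = 220, spine = 50),
  "liver-avid" = c(body = 80, lung = 25, liver = 500, heart = 120,
                   kidney = 280, spine = 40),
  "flat"       = c(body = 100, lung = 40, liver = 120, heart = 120,
                   kidney = 120, spine = 80)
)

# Linear attenuation coefficients at 511 keV, per mm.
MU_SOFT <- 0.0096
MU_LUNG <- 0.0030
MU_BONE <- 0.0170

#' Default anthropomorphic phantom specification
#'
#' A desk-scale torso-like phantom: a soft-tissue body ellipsoid containing
#' two lungs, a liver, a heart, two kidneys and a spine column, plus two
#' hot spherical lesions. Activity is \code{background * multiplier}
#' inside an organ and \code{background} outside all organs, so with the
#' default background of 1 (arbitrary concentration units) the ambient
#' level sits near the epsilon = 1 threshold while soft tissue is around
#' 100. Remaining defaults: 64^3 grid at 4 mm spacing, PSF FWHM 5 mm,
#' Poisson count scale 4 counts per intensity unit, scatter fraction 0.25
#' with a 40 mm scatter kernel, 8 transaxial angles.
#'
#' @param tracerProfile one of \code{"fdg"}, \code{"liver-avid"},
#'   \code{"flat"}.
#' @param shape,spacing grid geometry.
#' @param background background activity level.
#' @param psfFwhm,noiseScale,scatterFraction,scatterFwhm scanner model.
#' @param nAngles angles for the attenuation-factor average.
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
defaultPhantomSpec <- function(tracerProfile = "fdg",
                               shape = c(64L, 64L, 64L), spacing = c(4, 4, 4),
                               background = 1, psfFwhm = 5, noiseScale = 4,
                               scatterFraction = 0.25, scatterFwhm = 40,
                               nAngles = 8L, seed = 1L) {
  if (!tracerProfile %in% names(TRACER_PROFILES))
    stop("unknown tracer profile: ", tracerProfile, call. = FALSE)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ext <- (as.integer(shape) - 1L) * spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] / 2
  mult <- TRACER_PROFILES[[tracerProfile]]
  organs <- data.frame(
    label = c("body", "lung", "lung", "liver", "heart", "kidney", "kidney",
              "spine"),
    cx = cx + c(0, -0.22, 0.22, 0.16, -0.08, -0.18, 0.18, 0) * ext[1],
    cy = cy + c(0, -0.05, -0.05, 0.02, -0.08, 0.12, 0.12, 0.26) * ext[2],
    cz = cz + c(0, 0.18, 0.18, -0.02, 0.16, -0.18, -0.18, 0) * ext[3],
    rx = c(0.40, 0.13, 0.13, 0.17, 0.10, 0.07, 0.07, 0.05) * ext[1],
    ry = c(0.34, 0.12, 0.12, 0.13, 0.09, 0.06, 0.06, 0.05) * ext[2],
    rz = c(0.46, 0.16, 0.16, 0.11, 0.09, 0.09, 0.09, 0.44) * ext[3],
    mult = unname(mult[c("body", "lung", "lung", "liver", "heart", "kidney",
                         "kidney", "spine")]),
    mu = c(MU_SOFT, MU_LUNG, MU_LUNG, 0.0098, MU_SOFT, MU_SOFT, MU_SOFT,
           MU_BONE),
    stringsAsFactors = FALSE)
  lesions <- data.frame(
    label = c("lesion1", "lesion2"),
    cx = cx + c(0.14, -0.20) * ext[1],
    cy = cy + c(-0.02, 0.00) * ext[2],
    cz = cz + c(-0.04, -0.20) * ext[3],
    r = c(0.045, 0.035) * min(ext),
    mult = c(500, 600),
    stringsAsFactors = FALSE)
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      background = background, organs = organs, lesions = lesions,
      tracerProfile = tracerProfile, psfFwhm = psfFwhm,
      noiseScale = noiseScale, scatterFraction = scatterFraction,
      scatterFwhm = scatterFwhm, nAngles = as.integer(nAngles),
      seed = as.integer(seed))
}

# Physical coordinates of voxel centres along each axis (mm).
axisCoords <- function(shape, spacing) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - 1) * spacing[ax])
}

# Boolean mask of an axis-aligned ellipsoid on the grid (voxel-centre test).
ellipsoidMask <- function(shape, spacing, center, radii) {
  co <- axisCoords(shape, spacing)
  dx2 <- ((co[[1]] - center[1]) / radii[1])^2
  dy2 <- ((co[[2]] - center[2]) / radii[2])^2
  dz2 <- ((co[[3]] - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Rasterize a phantom specification
#'
#' Paints the background activity level over the grid, then each organ
#' ellipsoid (activity = background x multiplier; attenuation = the
#' organ's mu, later organs overwriting earlier ones), then the spherical
#' lesions, and finally smooths the activity with the scanner PSF. The
#' attenuation map stays piecewise constant (air = 0 outside the body).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with elements \code{activity} and \code{muMap}, both
#'   \linkS4class{PETVolume}s.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  shape <- spec@shape
  sp <- spec@spacing
  act <- array(spec@background, shape)
  mu <- array(0, shape)
  org <- spec@organs
  for (i in seq_len(nrow(org))) {
    m <- ellipsoidMask(shape, sp, c(org$cx[i], org$cy[i], org$cz[i]),
                       c(org$rx[i], org$ry[i], org$rz[i]))
    act[m] <- spec@background * org$mult[i]
    mu[m] <- org$mu[i]
  }
  les <- spec@lesions
  for (i in seq_len(nrow(les))) {
    m <- ellipsoidMask(shape, sp, c(les$cx[i], les$cy[i], les$cz[i]),
                       rep(les$r[i], 3))
    act[m] <- spec@background * les$mult[i]
  }
  act <- gaussianBlur3d(act, sp, spec@psfFwhm)
  act[act < 0] <- 0
  list(activity = PETVolume(act, sp, "activity"),
       muMap = PETVolume(mu, sp, "mu"))
}

#' Angular-mean attenuation factor map
#'
#' For each voxel the full line integral of the attenuation coefficient
#' through the volume is accumulated along an in-plane (transaxial)
#' direction — both emission directions summed, as for a coincidence line
#' of response — by fixed-step ray marching (step = half the smallest voxel
#' spacing), and \eqn{\exp(-\int \mu)} is averaged over \code{nAngles}
#' equally spaced directions in \eqn{[0, \pi)}. The result is
#' dimensionless, in (0, 1]; a zero attenuation map yields exactly 1
#' everywhere.
#'
#' @param muMap \linkS4class{PETVolume} with unit \code{"mu"} (per mm).
#' @param nAngles number of directions, >= 1.
#' @param step ray-march step in mm; default half the smallest spacing.
#' @return \linkS4class{PETVolume} with unit \code{"ratio"}.
#' @export
attenuationFactorMap <- function(muMap, nAngles = 8L, step = NULL) {
  stopifnot(is(muMap, "PETVolume"))
  if (muMap@unit != "mu") stop("muMap must have unit 'mu'", call. = FALSE)
  if (any(!is.finite(muMap@voxels))) stop("non-finite mu", call. = FALSE)
  nAngles <- as.integer(nAngles)
  if (nAngles < 1L) stop("nAngles must be >= 1", call. = FALSE)
  if (is.null(step)) step <- min(muMap@spacing) / 2
  d <- dim(muMap@voxels)
  if (all(muMap@voxels == 0)) {
    return(PETVolume(array(1, d), muMap@spacing, "ratio"))
  }
  af <- .raymarchAF(as.numeric(muMap@voxels), as.integer(d),
                    as.numeric(muMap@spacing), nAngles, step)
  dim(af) <- d
  PETVolume(pmin(af, 1), muMap@spacing, "ratio")
}

#' Simulate one paired acquisition
#'
#' Produces a matched uncorrected/corrected volume pair from a phantom
#' specification. The noiseless attenuated image is
#' \code{trues = activity * afMap}; scatter is a Gaussian-blurred copy of
#' it scaled so that the stated scatter fraction is the scattered share of
#' total counts; Poisson noise is applied once to the measured
#' (attenuated + scattered) image on the count scale
#' \code{noiseScale}. The corrected reference is reconstructed from the
#' same noisy measurement, \code{asc = (nasc - scatter) / afMap} (clipped
#' at zero), so the noise in the two images is correlated exactly as it is
#' between two reconstructions of one acquisition — which is what makes
#' the true correction map low-frequency. With scatter fraction 0 and
#' noise 0, \code{nasc == asc * afMap} holds to machine precision and
#' \code{asc} equals the PSF-smoothed activity.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param epsilon threshold used to form the true correction map.
#' @return A \linkS4class{PhantomPair}.
#' @export
simulatePair <- function(spec, epsilon = 1) {
  stopifnot(is(spec, "PhantomSpec"))
  ph <- generatePhantom(spec)
  af <- attenuationFactorMap(ph$muMap, spec@nAngles)
  act <- ph$activity@voxels
  trues <- act * af@voxels
  sf <- spec@scatterFraction
  if (sf > 0) {
    sc0 <- gaussianBlur3d(trues, spec@spacing, spec@scatterFwhm)
    scatter <- sc0 * (sf / (1 - sf)) * sum(trues) / sum(sc0)
  } else {
    scatter <- array(0, dim(trues))
  }
  measured <- trues + scatter
  if (spec@noiseScale > 0) {
    set.seed(spec@seed)
    counts <- stats::rpois(length(measured), measured * spec@noiseScale)
    nasc <- counts / spec@noiseScale
    dim(nasc) <- dim(measured)
  } else {
    nasc <- measured
  }
  if (spec@noiseScale > 0 || sf > 0) {
    asc <- (nasc - scatter) / af@voxels
    nneg <- sum(asc < 0)
    if (nneg > 0) {
      message(sprintf("simulatePair: clipped %d negative voxels to zero", nneg))
      asc[asc < 0] <- 0
    }
  } else {
    asc <- act
  }
  nascVol <- PETVolume(nasc, spec@spacing, "activity")
  ascVol <- PETVolume(asc, spec@spacing, "activity")
  adcm <- computeADCM(nascVol, ascVol, DecompositionConfig(epsilon = epsilon))
  new("PhantomPair", asc = ascVol, nasc = nascVol, muMap = ph$muMap,
      afMap = af, trueAdcm = adcm, spec = spec, seed = spec@seed)
}

# Deterministic per-pair geometry jitter: organ centres, radii and
# multipliers perturbed a few percent so every "subject" differs.
jitterSpec <- function(spec, seed) {
  set.seed(seed)
  org <- spec@organs
  ext <- (spec@shape - 1L) * spec@spacing
  n <- nrow(org)
  jc <- matrix(stats::runif(3 * n, -0.015, 0.015), n, 3) * rep(ext, each = n)
  jr <- matrix(stats::runif(3 * n, 0.92, 1.08), n, 3)
  org$cx <- org$cx + jc[, 1]; org$cy <- org$cy + jc[, 2]; org$cz <- org$cz + jc[, 3]
  org$rx <- org$rx * jr[, 1]; org$ry <- org$ry * jr[, 2]; org$rz <- org$rz * jr[, 3]
  org$mult <- org$mult * stats::runif(n, 0.9, 1.1)
  les <- spec@lesions
  if (nrow(les)) {
    m <- nrow(les)
    jl <- matrix(stats::runif(3 * m, -0.03, 0.03), m, 3) * rep(ext, each = m)
    les$cx <- les$cx + jl[, 1]; les$cy <- les$cy + jl[, 2]; les$cz <- les$cz + jl[, 3]
    les$r <- les$r * stats::runif(m, 0.8, 1.2)
    les$mult <- les$mult * stats::runif(m, 0.85, 1.15)
  }
  # keep geometry inside the grid
  clampEll <- function(c0, r0, e) pmin(pmax(c0, r0), e - r0)
  org$cx <- clampEll(org$cx, org$rx, ext[1])
  org$cy <- clampEll(org$cy, org$ry, ext[2])
  org$cz <- clampEll(org$cz, org$rz, ext[3])
  if (nrow(les)) {
    les$cx <- clampEll(les$cx, les$r, ext[1])
    les$cy <- clampEll(les$cy, les$r, ext[2])
    les$cz <- clampEll(les$cz, les$r, ext[3])
  }
  sp <- spec
  sp@organs <- org
  sp@lesions <- les
  sp@seed <- as.integer(seed)
  sp
}

# Apply a domain-shift descriptor to a base spec.
applyShift <- function(spec, shift, tracerProfile = "liver-avid") {
  if (shift == "none") return(spec)
  if (shift == "scanner") {
    spec@psfFwhm <- spec@psfFwhm * 1.5
    spec@noiseScale <- spec@noiseScale / 2   # noisier counts
    spec@scatterFraction <- min(0.95, spec@scatterFraction + 0.10)
    return(spec)
  }
  if (shift == "tracer") {
    if (!tracerProfile %in% names(TRACER_PROFILES))
      stop("unknown tracer profile: ", tracerProfile, call. = FALSE)
    mult <- TRACER_PROFILES[[tracerProfile]]
    spec@organs$mult <- unname(mult[spec@organs$label])
    spec@tracerProfile <- tracerProfile
    return(spec)
  }
  stop("unknown shift descriptor: ", shift, call. = FALSE)
}

#' Generate a dataset of paired phantoms
#'
#' Draws \code{n} paired acquisitions from a base specification with
#' per-pair jittered organ geometry. A domain shift (\code{"scanner"}:
#' wider PSF, noisier counts, higher scatter fraction; \code{"tracer"}:
#' swapped organ-multiplier profile) is applied identically to every pair,
#' emulating a held-out scanner or tracer family. Per-pair seeds are
#' derived from \code{seed} by a named-substream scheme and recorded in
#' each pair, so any pair can be regenerated exactly.
#'
#' @param baseSpec a \linkS4class{PhantomSpec}.
#' @param n number of pairs, >= 1.
#' @param shift \code{"none"}, \code{"scanner"} or \code{"tracer"}.
#' @param seed dataset seed.
#' @param tracerProfile profile used when \code{shift == "tracer"}.
#' @param epsilon threshold for the true correction maps.
#' @return A list of \linkS4class{PhantomPair}s.
#' @export
makeDataset <- function(baseSpec, n, shift = "none", seed = 1L,
                        tracerProfile = "liver-avid", epsilon = 1) {
  stopifnot(is(baseSpec, "PhantomSpec"), n >= 1)
  if (!shift %in% c("none", "scanner", "tracer"))
    stop("unknown shift descriptor: ", shift, call. = FALSE)
  shifted <- applyShift(baseSpec, shift, tracerProfile)
  # pair 1 is the canonical (unjittered) subject of the family; later pairs
  # get jittered geometry from named sub-stream seeds
  lapply(seq_len(n), function(i) {
    if (i == 1L) return(simulatePair(shifted, epsilon = epsilon))
    si <- substreamSeed(seed, paste0("pair-", shift, "-", i))
    simulatePair(jitterSpec(shifted, si), epsilon = epsilon)
  })
}
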