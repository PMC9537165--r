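#' @useDynLib petdecomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

VOLUME_UNITS <- c("activity", "mu", "ratio")

#' PETVolume: a 3D voxel grid with physical spacing
#'
#' The elementary container of the package: a dense 3D array of voxel
#' intensities together with the per-axis voxel size in millimetres and a
#' unit tag distinguishing activity images (arbitrary concentration units),
#' linear attenuation coefficient maps (per mm) and dimensionless ratio
#' maps. Physical coordinates follow the convention
#' \code{position = (index - 1) * spacing} with 1-based R indices, i.e. the
#' first voxel centre sits at the origin.
#'
#' @slot voxels 3D numeric array of finite intensities.
#' @slot spacing numeric(3), voxel size in mm, strictly positive.
#' @slot unit one of \code{"activity"}, \code{"mu"}, \code{"ratio"}.
#' @exportClass PETVolume
setClass("PETVolume",
  slots = c(voxels = "array", spacing = "numeric", unit = "character"))

setValidity("PETVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (any(dim(v) < 1L)) return("all axis lengths must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be 3 strictly positive finite values (mm)")
  }
  if (length(object@unit) != 1L || !object@unit %in% VOLUME_UNITS) {
    return(sprintf("unit must be one of: %s", paste(VOLUME_UNITS, collapse = ", ")))
  }
  if (any(!is.finite(v))) return("voxels must be finite")
  if (object@unit %in% c("activity", "mu") && any(v < 0)) {
    return(sprintf("%s volumes must be non-negative", object@unit))
  }
  TRUE
})

#' Construct a PETVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel size in mm; scalar or length-3 vector.
#' @param unit intensity unit tag: \code{"activity"}, \code{"mu"} or
#'   \code{"ratio"}.
#' @return A \linkS4class{PETVolume}.
#' @examples
#' vol <- PETVolume(array(1, c(4, 4, 4)), spacing = 4, unit = "activity")
#' dim(voxels(vol))
#' @export
PETVolume <- function(voxels, spacing = c(1, 1, 1), unit = "activity") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PETVolume", voxels = voxels, spacing = as.numeric(spacing), unit = unit)
}

#' ADCMap: anatomy-dependent correction map
#'
#' The voxel-wise correction-factor volume obtained by dividing the
#' corrected by the uncorrected image wherever the uncorrected intensity
#' exceeds a small threshold \code{epsilon} (and storing the corrected
#' intensity itself below it). The map is dimensionless and, because
#' attenuation and scatter vary slowly in space, dominated by low spatial
#' frequencies.
#'
#' @slot ratio a \linkS4class{PETVolume} with unit \code{"ratio"}.
#' @slot epsilon the intensity threshold (in uncorrected-image units) used
#'   when the map was formed or is to be applied.
#' @slot provenance \code{"computed"} (from a paired acquisition) or
#'   \code{"predicted"} (network output).
#' @exportClass ADCMap
setClass("ADCMap",
  slots = c(ratio = "PETVolume", epsilon = "numeric", provenance = "character"))

setValidity("ADCMap", function(object) {
  if (object@ratio@unit != "ratio") return("ratio volume must have unit 'ratio'")
  if (any(object@ratio@voxels < 0)) return("ratio must be non-negative")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon < 0) {
    return("epsilon must be a single finite value >= 0")
  }
  if (!object@provenance %in% c("computed", "predicted")) {
    return("provenance must be 'computed' or 'predicted'")
  }
  TRUE
})

#' PhantomSpec: parametric description of a synthetic phantom
#'
#' Drives the image-space forward model: a background activity level, a set
#' of labelled organ ellipsoids (each with an activity multiplier and a
#' linear attenuation coefficient), spherical lesions, and a scanner model
#' (PSF, count-noise scale, scatter fraction and scatter-kernel width).
#'
#' @slot shape integer(3) grid size.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot background background activity level inside nothing-in-particular
#'   (applies to the whole grid before organs are painted).
#' @slot organs data.frame with columns label, cx, cy, cz, rx, ry, rz (mm),
#'   mult (activity multiplier), mu (attenuation per mm).
#' @slot lesions data.frame with columns label, cx, cy, cz, r (mm), mult.
#' @slot tracerProfile name of the organ-multiplier profile in use.
#' @slot psfFwhm scanner point-spread FWHM in mm.
#' @slot noiseScale expected counts per intensity unit per voxel for the
#'   Poisson noise model; 0 disables noise.
#' @slot scatterFraction scattered share of total detected counts, in [0, 1).
#' @slot scatterFwhm FWHM (mm) of the Gaussian scatter kernel.
#' @slot nAngles number of transaxial directions for the angular-mean
#'   attenuation factor.
#' @slot seed RNG seed for the noise realization.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  slots = c(shape = "integer", spacing = "numeric", background = "numeric",
            organs = "data.frame", lesions = "data.frame",
            tracerProfile = "character", psfFwhm = "numeric",
            noiseScale = "numeric", scatterFraction = "numeric",
            scatterFwhm = "numeric", nAngles = "integer", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  if (object@background < 0) return("background must be >= 0")
  ext <- (object@shape - 1L) * object@spacing
  org <- object@organs
  if (nrow(org)) {
    need <- c("label", "cx", "cy", "cz", "rx", "ry", "rz", "mult", "mu")
    if (!all(need %in% names(org))) return("organs missing required columns")
    lo <- cbind(org$cx - org$rx, org$cy - org$ry, org$cz - org$rz)
    hi <- cbind(org$cx + org$rx, org$cy + org$ry, org$cz + org$rz)
    if (any(lo < -1e-9) || any(t(t(hi) - ext) > 1e-9))
      return("organ ellipsoids must lie within the grid")
    if (any(org$mult < 0)) return("activity multipliers must be >= 0")
    if (any(org$mu < 0 | org$mu > 0.05))
      return("mu values must be in [0, 0.05] per mm")
  }
  les <- object@lesions
  if (nrow(les)) {
    need <- c("label", "cx", "cy", "cz", "r", "mult")
    if (!all(need %in% names(les))) return("lesions missing required columns")
    lo <- cbind(les$cx - les$r, les$cy - les$r, les$cz - les$r)
    hi <- cbind(les$cx + les$r, les$cy + les$r, les$cz + les$r)
    if (any(lo < -1e-9) || any(t(t(hi) - ext) > 1e-9))
      return("lesions must lie within the grid")
    if (any(les$mult < 0)) return("lesion multipliers must be >= 0")
  }
  if (object@scatterFraction < 0 || object@scatterFraction >= 1)
    return("scatterFraction must be in [0, 1)")
  if (object@psfFwhm < 0 || object@scatterFwhm < 0)
    return("kernel widths must be >= 0")
  if (object@noiseScale < 0) return("noiseScale must be >= 0")
  if (object@nAngles < 1L) return("nAngles must be >= 1")
  TRUE
})

#' PhantomPair: one simulated paired acquisition
#'
#' @slot asc reference corrected activity volume.
#' @slot nasc uncorrected (attenuated + scattered + noisy) volume.
#' @slot muMap attenuation coefficient map (per mm).
#' @slot afMap angular-mean attenuation factor map, dimensionless in (0, 1].
#' @slot trueAdcm the correction map computed from (nasc, asc).
#' @slot spec the \linkS4class{PhantomSpec} that generated the pair.
#' @slot seed the realized RNG seed.
#' @exportClass PhantomPair
setClass("PhantomPair",
  slots = c(asc = "PETVolume", nasc = "PETVolume", muMap = "PETVolume",
            afMap = "PETVolume", trueAdcm = "ADCMap", spec = "PhantomSpec",
            seed = "integer"))

setValidity("PhantomPair", function(object) {
  d <- dim(object@asc@voxels)
  for (nm in c("nasc", "muMap", "afMap")) {
    if (!identical(dim(slot(object, nm)@voxels), d))
      return("all volumes in a pair must share the grid shape")
    if (!isTRUE(all.equal(slot(object, nm)@spacing, object@asc@spacing)))
      return("all volumes in a pair must share the spacing")
  }
  af <- object@afMap@voxels
  if (any(af <= 0) || any(af > 1 + 1e-12))
    return("attenuation factors must lie in (0, 1]")
  TRUE
})

#' DecompositionConfig: parameters of the correction-map transform
#'
#' @slot epsilon intensity threshold in uncorrected-image units (default 1).
#' @slot workingShape integer(3) network-space grid (default 112^3 at full
#'   scale; desk-scale experiments use 32^3).
#' @slot interpOrder resampling order: 0 nearest, 1 trilinear.
#' @exportClass DecompositionConfig
setClass("DecompositionConfig",
  slots = c(epsilon = "numeric", workingShape = "integer",
            interpOrder = "integer"))

setValidity("DecompositionConfig", function(object) {
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (length(object@workingShape) != 3L || any(object@workingShape < 8L))
    return("workingShape axes must be >= 8")
  if (!object@interpOrder %in% c(0L, 1L)) return("interpOrder must be 0 or 1")
  TRUE
})

#' @rdname DecompositionConfig-class
#' @param epsilon,workingShape,interpOrder see slot documentation.
#' @return A \linkS4class{DecompositionConfig}.
#' @export
DecompositionConfig <- function(epsilon = 1, workingShape = c(112L, 112L, 112L),
                                interpOrder = 1L) {
  if (length(workingShape) == 1L) workingShape <- rep(workingShape, 3L)
  new("DecompositionConfig", epsilon = epsilon,
      workingShape = as.integer(workingShape), interpOrder = as.integer(interpOrder))
}

#' GANConfig: conditional-adversarial training configuration
#'
#' Houses the generator/discriminator architecture, the weight
#' \code{lambdaL2} of the regression term in the adversarial objective
#' (default 1e4), the optimizer settings, the network working resolution,
#' and the training mode: \code{"decomposition"} (predict the correction
#' map), \code{"direct3d"} or \code{"direct2d"} (predict the corrected
#' image directly, volume- or slice-wise).
#'
#' @slot mode one of decomposition, direct3d, direct2d.
#' @slot lambdaL2 weight of the mean-squared regression term (> 0).
#' @slot genDepth,genChannels U-Net levels (>= 2) and base channel count.
#' @slot discDepth,discChannels discriminator conv levels and base channels.
#' @slot lrG,lrD Adam learning rates.
#' @slot batchSize minibatch size (gradients averaged).
#' @slot epochs number of passes over the training pairs.
#' @slot workingShape integer(3) network-space grid.
#' @slot seed RNG seed controlling init and shuffling.
#' @slot pureL2 if TRUE, drop the adversarial terms (plain regression
#'   ablation).
#' @slot rMax predicted ratios are clipped to [0, rMax] before application.
#' @slot normQuantile per-volume input normalization quantile (default 0.99).
#' @slot epsilon threshold used when the prediction is applied.
#' @exportClass GANConfig
setClass("GANConfig",
  slots = c(mode = "character", lambdaL2 = "numeric", genDepth = "integer",
            genChannels = "integer", discDepth = "integer",
            discChannels = "integer", lrG = "numeric", lrD = "numeric",
            batchSize = "integer", epochs = "integer",
            workingShape = "integer", seed = "integer", pureL2 = "logical",
            rMax = "numeric", normQuantile = "numeric", epsilon = "numeric"))

setValidity("GANConfig", function(object) {
  if (!object@mode %in% c("decomposition", "direct3d", "direct2d"))
    return("mode must be decomposition, direct3d or direct2d")
  if (object@lambdaL2 <= 0) return("lambdaL2 must be > 0")
  if (object@genDepth < 2L || object@discDepth < 2L)
    return("network depths must be >= 2")
  if (object@epochs < 1L || object@batchSize < 1L)
    return("epochs and batchSize must be >= 1")
  ws <- object@workingShape
  if (length(ws) != 3L || any(ws < 1L)) return("workingShape must be 3 sizes")
  div <- 2L^(object@genDepth - 1L)
  if (any(ws > 1L & ws %% div != 0L))
    return("workingShape axes (> 1) must be divisible by 2^(genDepth-1)")
  if (object@rMax <= 0) return("rMax must be > 0")
  if (object@normQuantile <= 0 || object@normQuantile > 1)
    return("normQuantile must be in (0, 1]")
  TRUE
})

#' @rdname GANConfig-class
#' @param mode,lambdaL2,genDepth,genChannels,discDepth,discChannels see slots.
#' @param lrG,lrD,batchSize,epochs,workingShape,seed,pureL2,rMax see slots.
#' @param normQuantile,epsilon see slots.
#' @return A \linkS4class{GANConfig}.
#' @export
GANConfig <- function(mode = "decomposition", lambdaL2 = 1e4,
                      genDepth = 4L, genChannels = 8L,
                      discDepth = 3L, discChannels = 8L,
                      lrG = 1e-3, lrD = 1e-4, batchSize = 1L, epochs = 20L,
                      workingShape = c(32L, 32L, 32L), seed = 1L,
                      pureL2 = FALSE, rMax = 100, normQuantile = 0.99,
                      epsilon = 1) {
  if (length(workingShape) == 1L) workingShape <- rep(workingShape, 3L)
  new("GANConfig", mode = mode, lambdaL2 = lambdaL2,
      genDepth = as.integer(genDepth), genChannels = as.integer(genChannels),
      discDepth = as.integer(discDepth), discChannels = as.integer(discChannels),
      lrG = lrG, lrD = lrD, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), workingShape = as.integer(workingShape),
      seed = as.integer(seed), pureL2 = pureL2, rMax = rMax,
      normQuantile = normQuantile, epsilon = epsilon)
}

#' TrainedModel: trained generator/discriminator with provenance
#'
#' @slot generator parameter list of the generator network.
#' @slot discriminator parameter list of the discriminator network.
#' @slot config immutable \linkS4class{GANConfig} snapshot.
#' @slot lossTrace data.frame with one row per epoch: lossD, lossGAdv,
#'   lossGL2 (training-set means).
#' @exportClass TrainedModel
setClass("TrainedModel",
  slots = c(generator = "list", discriminator = "list", config = "GANConfig",
            lossTrace = "data.frame"))

setValidity("TrainedModel", function(object) {
  if (nrow(object@lossTrace) != object@config@epochs)
    return("loss trace must have one row per epoch")
  TRUE
})

#' VOISphere: spherical volume of interest
#'
#' @slot center numeric(3) in mm (physical coordinates).
#' @slot radius radius in mm, > 0.
#' @slot label organ label (e.g. liver, kidney, heart).
#' @exportClass VOISphere
setClass("VOISphere",
  slots = c(center = "numeric", radius = "numeric", label = "character"))

setValidity("VOISphere", function(object) {
  if (length(object@center) != 3L) return("center must be length 3 (mm)")
  if (object@radius <= 0) return("radius must be > 0")
  TRUE
})

#' @rdname VOISphere-class
#' @param center,radius,label see slot documentation.
#' @return A \linkS4class{VOISphere}.
#' @export
VOISphere <- function(center, radius, label = "voi") {
  new("VOISphere", center = as.numeric(center), radius = radius, label = label)
}

#' MetricsReport: evaluation of one predicted volume family
#'
#' @slot global data.frame of per-volume NRMSE/PSNR/SSIM.
#' @slot voi data.frame of per-VOI SUV metrics for prediction and reference.
#' @slot mape data.frame of per-feature mean absolute percentage errors.
#' @slot jointHist list with hist2d matrix, slope and intercept.
#' @slot tests data.frame of paired-comparison results (may be empty).
#' @exportClass MetricsReport
setClass("MetricsReport",
  slots = c(global = "data.frame", voi = "data.frame", mape = "data.frame",
            jointHist = "list", tests = "data.frame"))
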