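#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' \code{voxels} returns the raw 3D array of a \linkS4class{PETVolume};
#' \code{spacing} its voxel size in mm; \code{volumeUnit} its unit tag.
#' \code{ratioMap}, \code{epsilonUsed} and \code{provenance} access the
#' components of an \linkS4class{ADCMap}; \code{lossTrace} and
#' \code{modelConfig} those of a \linkS4class{TrainedModel}.
#'
#' @param object a package object.
#' @return The slot value.
#' @name accessors
#' @aliases voxels spacing volumeUnit ratioMap epsilonUsed provenance
#'   lossTrace modelConfig
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("volumeUnit", function(object) standardGeneric("volumeUnit"))
#' @rdname accessors
#' @export
setGeneric("ratioMap", function(object) standardGeneric("ratioMap"))
#' @rdname accessors
#' @export
setGeneric("epsilonUsed", function(object) standardGeneric("epsilonUsed"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

setMethod("voxels", "PETVolume", function(object) object@voxels)
setMethod("spacing", "PETVolume", function(object) object@spacing)
setMethod("volumeUnit", "PETVolume", function(object) object@unit)
setMethod("voxels", "ADCMap", function(object) object@ratio@voxels)
setMethod("spacing", "ADCMap", function(object) object@ratio@spacing)
setMethod("ratioMap", "ADCMap", function(object) object@ratio)
setMethod("epsilonUsed", "ADCMap", function(object) object@epsilon)
setMethod("provenance", "ADCMap", function(object) object@provenance)
setMethod("lossTrace", "TrainedModel", function(object) object@lossTrace)
setMethod("modelConfig", "TrainedModel", function(object) object@config)

setMethod("show", "PETVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("PETVolume %dx%dx%d [%s], spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@unit,
              paste(format(object@spacing, digits = 3), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "ADCMap", function(object) {
  d <- dim(object@ratio@voxels)
  cat(sprintf("ADCMap %dx%dx%d (%s), epsilon = %g, ratio range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@provenance, object@epsilon,
              min(object@ratio@voxels), max(object@ratio@voxels)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %dx%dx%d @ %s mm, tracer '%s', %d organs, ",
                     "%d lesions\n  PSF %.1f mm, noise scale %.3g, scatter ",
                     "fraction %.2f, %d angles, seed %d\n"),
              object@shape[1], object@shape[2], object@shape[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              object@tracerProfile, nrow(object@organs), nrow(object@lesions),
              object@psfFwhm, object@noiseScale, object@scatterFraction,
              object@nAngles, object@seed))
})

setMethod("show", "PhantomPair", function(object) {
  d <- dim(object@asc@voxels)
  cat(sprintf("PhantomPair %dx%dx%d (tracer '%s', seed %d)\n",
              d[1], d[2], d[3], object@spec@tracerProfile, object@seed))
  cat(sprintf("  total counts nasc/asc = %.4f, af range [%.3f, %.3f]\n",
              sum(object@nasc@voxels) / sum(object@asc@voxels),
              min(object@afMap@voxels), max(object@afMap@voxels)))
})

setMethod("show", "GANConfig", function(object) {
  cat(sprintf(paste0("GANConfig mode '%s': G depth %d x %dch, D depth %d x ",
                     "%dch, lambdaL2 %.3g%s\n  working shape %s, %d epochs, ",
                     "batch %d, lrG %.2g, lrD %.2g, seed %d\n"),
              object@mode, object@genDepth, object@genChannels,
              object@discDepth, object@discChannels, object@lambdaL2,
              if (object@pureL2) " (pure-L2 ablation)" else "",
              paste(object@workingShape, collapse = "x"), object@epochs,
              object@batchSize, object@lrG, object@lrD, object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  nt <- nrow(object@lossTrace)
  cat(sprintf("TrainedModel (%s), %d epochs; final lossD %.4g, adv %.4g, L2 %.4g\n",
              object@config@mode, nt, object@lossTrace$lossD[nt],
              object@lossTrace$lossGAdv[nt], object@lossTrace$lossGL2[nt]))
})

setMethod("show", "VOISphere", function(object) {
  cat(sprintf("VOISphere '%s': centre (%s) mm, radius %.1f mm\n", object@label,
              paste(format(object@center, digits = 4), collapse = ", "),
              object@radius))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d volumes, %d VOI rows, %d MAPE features\n",
              nrow(object@global), nrow(object@voi), nrow(object@mape)))
  if (nrow(object@global)) {
    cat(sprintf("  median NRMSE %.4f, PSNR %.2f dB, SSIM %.4f\n",
                stats::median(object@global$nrmse),
                stats::median(object@global$psnr),
                stats::median(object@global$ssim)))
  }
})
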