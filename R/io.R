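#' @include AllClasses.R
NULL

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI (.nii / .nii.gz) with the voxel spacing in
#' the header pixdim and the unit tag in a JSON sidecar
#' (\code{<path>.json}) next to the image. Voxels are written in double
#' precision so a write-then-read round trip is bitwise exact; spacing is
#' preserved to better than 1e-6 mm.
#'
#' @param path file path (.nii or .nii.gz).
#' @param vol a \linkS4class{PETVolume}.
#' @param unit optional unit override at read time (otherwise taken from
#'   the sidecar, falling back to \code{"activity"}).
#' @return \code{readVolume} returns a \linkS4class{PETVolume};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @name volume-io
NULL

#' @rdname volume-io
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "PETVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(list(unit = vol@unit, spacing = vol@spacing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path, unit = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(d), " dimensions",
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header has no usable voxel spacing", call. = FALSE)
  side <- paste0(path, ".json")
  if (is.null(unit)) {
    unit <- if (file.exists(side)) {
      jsonlite::read_json(side)$unit
    } else "activity"
  }
  PETVolume(array(as.numeric(img), d), as.numeric(sp), unit)
}

#' Write a phantom pair to a directory
#'
#' Stores the four volumes of a pair (asc, nasc, mu, adcm) as NIfTI files
#' plus a sidecar metadata file (seed, tracer profile, scanner settings,
#' epsilon) named \code{<prefix>_meta.json}.
#'
#' @param pair a \linkS4class{PhantomPair}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of written paths.
#' @export
writePair <- function(pair, dir, prefix = "pair") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, "_", c("asc", "nasc", "mu", "adcm"),
                                 ".nii.gz"))
  writeVolume(pair@asc, paths[1])
  writeVolume(pair@nasc, paths[2])
  writeVolume(pair@muMap, paths[3])
  writeVolume(pair@trueAdcm@ratio, paths[4])
  spec <- pair@spec
  meta <- list(seed = pair@seed, tracerProfile = spec@tracerProfile,
               psfFwhm = spec@psfFwhm, noiseScale = spec@noiseScale,
               scatterFraction = spec@scatterFraction,
               nAngles = spec@nAngles,
               epsilon = pair@trueAdcm@epsilon,
               shape = spec@shape, spacing = spec@spacing)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read or write a phantom specification as YAML
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param path YAML file path.
#' @return \code{readPhantomSpec} returns a \linkS4class{PhantomSpec}.
#' @name spec-io
NULL

#' @rdname spec-io
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  x <- list(shape = spec@shape, spacing = spec@spacing,
            background = spec@background,
            organs = lapply(seq_len(nrow(spec@organs)),
                            function(i) as.list(spec@organs[i, ])),
            lesions = lapply(seq_len(nrow(spec@lesions)),
                             function(i) as.list(spec@lesions[i, ])),
            tracerProfile = spec@tracerProfile, psfFwhm = spec@psfFwhm,
            noiseScale = spec@noiseScale,
            scatterFraction = spec@scatterFraction,
            scatterFwhm = spec@scatterFwhm, nAngles = spec@nAngles,
            seed = spec@seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname spec-io
#' @export
readPhantomSpec <- function(path) {
  x <- yaml::read_yaml(path)
  org <- do.call(rbind, lapply(x$organs, as.data.frame))
  les <- if (length(x$lesions)) {
    do.call(rbind, lapply(x$lesions, as.data.frame))
  } else {
    data.frame(label = character(), cx = numeric(), cy = numeric(),
               cz = numeric(), r = numeric(), mult = numeric())
  }
  new("PhantomSpec", shape = as.integer(x$shape),
      spacing = as.numeric(x$spacing), background = x$background,
      organs = org, lesions = les, tracerProfile = x$tracerProfile,
      psfFwhm = x$psfFwhm, noiseScale = x$noiseScale,
      scatterFraction = x$scatterFraction, scatterFwhm = x$scatterFwhm,
      nAngles = as.integer(x$nAngles), seed = as.integer(x$seed))
}
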