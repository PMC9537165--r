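#' @include AllClasses.R utils.R
NULL

#' Compute the anatomy-dependent correction map
#'
#' Forms the voxel-wise correction map from a paired uncorrected
#' (\code{nasc}) and corrected (\code{asc}) volume: wherever the
#' uncorrected intensity exceeds the threshold \eqn{\varepsilon} the map
#' stores the ratio \eqn{asc/nasc}; elsewhere it stores the corrected
#' intensity itself, giving the regression a meaningful target in
#' low-count voxels. Because photon attenuation and scatter vary slowly in
#' space the ratio map is dominated by low spatial frequencies, while the
#' tracer-dependent texture stays in the images.
#'
#' @param nasc uncorrected \linkS4class{PETVolume}.
#' @param asc corrected \linkS4class{PETVolume} on the same grid.
#' @param cfg a \linkS4class{DecompositionConfig}; only \code{epsilon} is
#'   used here.
#' @return An \linkS4class{ADCMap} with provenance \code{"computed"}.
#' @seealso \code{\link{applyADCM}} for the inverse operation.
#' @examples
#' a <- PETVolume(array(2, c(8, 8, 8)), 4, "activity")
#' n <- PETVolume(array(4, c(8, 8, 8)), 4, "activity")
#' voxels(computeADCM(n, a))[1, 1, 1]  # 0.5
#' @export
computeADCM <- function(nasc, asc, cfg = DecompositionConfig()) {
  stopifnot(is(nasc, "PETVolume"), is(asc, "PETVolume"),
            is(cfg, "DecompositionConfig"))
  stopIfNotSameGrid(nasc, asc, "nasc and asc")
  if (nasc@unit != asc@unit)
    stop("nasc and asc must share the same unit", call. = FALSE)
  nv <- nasc@voxels
  av <- asc@voxels
  if (any(!is.finite(nv)) || any(!is.finite(av)))
    stop("non-finite input intensities", call. = FALSE)
  eps <- cfg@epsilon
  ratio <- av                       # else-branch: store asc directly
  hot <- nv > eps
  ratio[hot] <- av[hot] / nv[hot]   # if-branch: asc / nasc
  new("ADCMap",
      ratio = PETVolume(ratio, nasc@spacing, "ratio"),
      epsilon = eps, provenance = "computed")
}

#' Apply a correction map to an uncorrected volume
#'
#' The inverse of \code{\link{computeADCM}}: wherever the uncorrected
#' intensity exceeds the map's \eqn{\varepsilon} the output is
#' \code{nasc * ratio}; elsewhere the uncorrected voxel passes through
#' unchanged. Multiplication by a slowly varying map preserves the
#' original image texture at full resolution.
#'
#' @param nasc uncorrected \linkS4class{PETVolume}.
#' @param adcm an \linkS4class{ADCMap} already on \code{nasc}'s grid (use
#'   \code{\link{resampleVolume}} first if it is not).
#' @param epsilon optional override; must agree with the map's recorded
#'   threshold if given.
#' @return Corrected \linkS4class{PETVolume}.
#' @export
applyADCM <- function(nasc, adcm, epsilon = NULL) {
  stopifnot(is(nasc, "PETVolume"), is(adcm, "ADCMap"))
  stopIfNotSameGrid(nasc, adcm@ratio, "nasc and the correction map")
  if (!is.null(epsilon) && abs(epsilon - adcm@epsilon) > 1e-12)
    stop("epsilon of the call (", epsilon, ") disagrees with the map (",
         adcm@epsilon, ")", call. = FALSE)
  nv <- nasc@voxels
  out <- nv                         # else-branch: pass nasc through
  hot <- nv > adcm@epsilon
  out[hot] <- nv[hot] * adcm@ratio@voxels[hot]
  PETVolume(out, nasc@spacing, nasc@unit)
}

#' Resample a volume to a target grid shape
#'
#' Grid-to-grid resampling with nearest-neighbour (order 0) or trilinear
#' (order 1, default) interpolation, performed separably per axis. The
#' voxel spacing is rescaled so the physical extent of the grid is
#' preserved (\code{newSpacing = spacing * shape / targetShape}). Under the
#' package's coordinate convention the target index \eqn{j} (0-based) maps
#' to source index \eqn{j (n_{src}/n_{tgt})}; samples beyond the last
#' source voxel are clamped. A constant volume resamples exactly to the
#' same constant, and a down-then-up round trip of a constant is exact.
#'
#' @param vol a \linkS4class{PETVolume}.
#' @param targetShape integer(3) (or scalar) target grid size, each >= 2.
#' @param order 0 or 1.
#' @return A \linkS4class{PETVolume} on the target grid.
#' @export
resampleVolume <- function(vol, targetShape, order = 1L) {
  stopifnot(is(vol, "PETVolume"))
  if (length(targetShape) == 1L) targetShape <- rep(targetShape, 3L)
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(targetShape < 2L))
    stop("targetShape must give 3 axis sizes, each >= 2", call. = FALSE)
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1", call. = FALSE)
  arr <- vol@voxels
  d <- dim(arr)
  for (ax in 1:3) {
    if (d[ax] == targetShape[ax]) next
    arr <- interpAlongAxis(arr, ax, targetShape[ax], order)
  }
  PETVolume(arr, vol@spacing * d / targetShape, vol@unit)
}

# Separable 1D resampling along one axis: target 0-based index j samples
# source position j * n_src/n_tgt (clamped to [0, n_src - 1]).
interpAlongAxis <- function(arr, ax, nt, order) {
  d <- dim(arr)
  ns <- d[ax]
  pos <- (seq_len(nt) - 1) * ns / nt
  pos <- pmin(pos, ns - 1)
  if (order == 0L) {
    i0 <- round(pos) + 1
    W <- matrix(0, nt, ns)
    W[cbind(seq_len(nt), i0)] <- 1
  } else {
    lo <- pmin(floor(pos), ns - 1)
    w <- pos - lo
    W <- matrix(0, nt, ns)
    W[cbind(seq_len(nt), lo + 1)] <- 1 - w
    idx <- cbind(seq_len(nt), pmin(lo + 2, ns))
    W[idx] <- W[idx] + w
  }
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- W %*% matrix(x, dp[1], dp[2] * dp[3])
  dim(y) <- c(nt, dp[2], dp[3])
  aperm(y, order(perm))
}

#' Resample a correction map
#'
#' Convenience wrapper resampling the ratio volume of an
#' \linkS4class{ADCMap} (trilinear by default) while carrying epsilon and
#' provenance along.
#'
#' @param adcm an \linkS4class{ADCMap}.
#' @param targetShape target grid size.
#' @param order interpolation order.
#' @return An \linkS4class{ADCMap}.
#' @export
resampleADCM <- function(adcm, targetShape, order = 1L) {
  stopifnot(is(adcm, "ADCMap"))
  new("ADCMap", ratio = resampleVolume(adcm@ratio, targetShape, order),
      epsilon = adcm@epsilon, provenance = adcm@provenance)
}
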