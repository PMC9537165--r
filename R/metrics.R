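#' @include AllClasses.R utils.R
NULL

#' Global volumetric image-quality metrics
#'
#' Computes the three global physical metrics between a predicted and a
#' reference volume on the same grid: NRMSE (RMSE divided by the reference
#' intensity range max - min), PSNR (\code{20 log10(max(ref) / RMSE)}, in
#' dB; \code{Inf} for a perfect prediction) and SSIM (mean local
#' structural similarity over a 7x7x7 uniform window with the standard
#' stabilizing constants \code{C1 = (0.01 L)^2}, \code{C2 = (0.03 L)^2}
#' scaled to the joint dynamic range \code{L} of the two inputs — so the
#' index is exactly symmetric — and computed volumetrically in 3D).
#'
#' @param pred,ref \linkS4class{PETVolume}s on the same grid and unit.
#' @param window SSIM window width (odd, default 7).
#' @return list with \code{nrmse}, \code{psnr}, \code{ssim}.
#' @export
globalMetrics <- function(pred, ref, window = 7L) {
  stopifnot(is(pred, "PETVolume"), is(ref, "PETVolume"))
  stopIfNotSameGrid(pred, ref, "pred and ref")
  if (pred@unit != ref@unit)
    stop("pred and ref must share the same unit", call. = FALSE)
  p <- pred@voxels
  r <- ref@voxels
  rng <- diff(range(r))
  if (rng == 0)
    stop("reference volume is constant: NRMSE is undefined", call. = FALSE)
  rmse <- sqrt(mean((p - r)^2))
  nrmse <- rmse / rng
  psnr <- if (rmse == 0) Inf else 20 * log10(max(r) / rmse)
  # SSIM uses the joint dynamic range so the index is exactly symmetric
  L <- diff(range(c(p, r)))
  list(nrmse = nrmse, psnr = psnr, ssim = ssim3d(p, r, L, window))
}

# Volumetric SSIM with a uniform (box) window; population moments.
ssim3d <- function(p, r, L, window = 7L) {
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  box <- function(a) boxFilter3d(a, window)
  mp <- box(p)
  mr <- box(r)
  vp <- box(p^2) - mp^2
  vr <- box(r^2) - mr^2
  cov <- box(p * r) - mp * mr
  num <- (2 * mp * mr + C1) * (2 * cov + C2)
  den <- (mp^2 + mr^2 + C1) * (vp + vr + C2)
  mean(num / den)
}

# separable moving-average filter, window renormalized at the edges
boxFilter3d <- function(arr, window) {
  kern <- rep(1, window)
  for (ax in 1:3) arr <- blurAlongAxis(arr, ax, kern)
  arr
}

#' Spherical-VOI SUV metrics
#'
#' Standardized-uptake statistics over a spherical volume of interest:
#' voxels belong to the sphere when their centre lies inside it.
#' \code{suvMean} and \code{suvMax} are the mean and maximum of the scaled
#' intensities over the members; \code{tlm} (total lesion metabolism) is
#' \code{suvMean} times the physical VOI volume in mL (member count times
#' voxel volume).
#'
#' @param vol a \linkS4class{PETVolume}.
#' @param voi a \linkS4class{VOISphere}.
#' @param suvScale factor converting stored intensity to SUV (identity for
#'   simulated data).
#' @return list with \code{suvMean}, \code{suvMax}, \code{tlm},
#'   \code{nVoxels}.
#' @export
voiMetrics <- function(vol, voi, suvScale = 1) {
  stopifnot(is(vol, "PETVolume"), is(voi, "VOISphere"))
  m <- voiMask(vol, voi)
  if (!any(m)) stop("VOI contains no voxel centres", call. = FALSE)
  v <- vol@voxels[m] * suvScale
  voxVolML <- prod(vol@spacing) / 1000  # mm^3 -> mL
  list(suvMean = mean(v), suvMax = max(v),
       tlm = mean(v) * sum(m) * voxVolML, nVoxels = sum(m))
}

voiMask <- function(vol, voi) {
  d <- dim(vol@voxels)
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * vol@spacing[ax])
  d2 <- outer(outer((co[[1]] - voi@center[1])^2, (co[[2]] - voi@center[2])^2,
                    `+`), (co[[3]] - voi@center[3])^2, `+`)
  d2 <= voi@radius^2
}

#' First-order VOI feature vector
#'
#' The configurable first-order feature set used for feature-level error
#' summaries: mean, max, entropy (of a 32-bin intensity histogram over the
#' VOI), skewness, kurtosis (non-excess) and energy (sum of squared
#' intensities).
#'
#' @param vol a \linkS4class{PETVolume}.
#' @param voi a \linkS4class{VOISphere}.
#' @param nBins histogram bins for the entropy feature.
#' @return Named numeric vector.
#' @export
voiFeatures <- function(vol, voi, nBins = 32L) {
  v <- vol@voxels[voiMask(vol, voi)]
  if (!length(v)) stop("VOI contains no voxel centres", call. = FALSE)
  mu <- mean(v)
  sdv <- if (length(v) > 1) stats::sd(v) else 0
  rng <- range(v)
  if (diff(rng) == 0) {
    ent <- 0
  } else {
    pr <- tabulate(findInterval(v, seq(rng[1], rng[2], length.out = nBins + 1L),
                                all.inside = TRUE), nBins)
    pr <- pr / sum(pr)
    pr <- pr[pr > 0]
    ent <- -sum(pr * log2(pr))
  }
  skew <- if (sdv > 0) mean((v - mu)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((v - mu)^4) / sdv^4 else 0
  c(mean = mu, max = max(v), entropy = ent, skewness = skew, kurtosis = kurt,
    energy = sum(v^2))
}

#' Mean absolute percentage error per feature
#'
#' For matched feature tables (subjects in rows, features in columns)
#' returns the mean over subjects of \code{|pred - ref| / |ref| * 100} per
#' feature. Subjects with a zero reference feature are excluded from that
#' feature's mean and counted in the \code{nExcluded} attribute.
#'
#' @param predFeatures,refFeatures numeric matrices or data.frames of equal
#'   shape.
#' @return Named numeric vector of MAPEs (percent), with attribute
#'   \code{nExcluded}.
#' @export
featureMAPE <- function(predFeatures, refFeatures) {
  p <- as.matrix(predFeatures)
  r <- as.matrix(refFeatures)
  if (!identical(dim(p), dim(r)))
    stop("feature tables must have identical shape", call. = FALSE)
  if (any(!is.finite(p)) || any(!is.finite(r)))
    stop("feature tables must be finite", call. = FALSE)
  excl <- integer(ncol(r))
  out <- numeric(ncol(r))
  for (j in seq_len(ncol(r))) {
    ok <- r[, j] != 0
    excl[j] <- sum(!ok)
    if (!any(ok)) {
      out[j] <- NA_real_
      next
    }
    out[j] <- mean(abs(p[ok, j] - r[ok, j]) / abs(r[ok, j])) * 100
  }
  names(out) <- colnames(r)
  if (any(excl > 0))
    message("featureMAPE: excluded ", sum(excl),
            " zero-reference feature values")
  attr(out, "nExcluded") <- excl
  out
}

#' Joint histogram and voxel-wise regression slope
#'
#' Builds the 2D histogram of (reference, predicted) voxel intensities
#' over the voxels where the reference exceeds \code{maskThreshold}, and
#' fits ordinary least squares of predicted on reference intensities over
#' the same voxels. A slope near 1 with intercept near 0 indicates
#' voxel-wise agreement.
#'
#' @param pred,ref \linkS4class{PETVolume}s on the same grid.
#' @param nBins number of histogram bins per axis (>= 10).
#' @param maskThreshold reference intensity threshold defining the mask.
#' @return list with \code{hist2d} (nBins x nBins counts), \code{slope},
#'   \code{intercept}, \code{nVoxels}.
#' @export
jointHistogram <- function(pred, ref, nBins = 64L, maskThreshold = 0) {
  stopifnot(is(pred, "PETVolume"), is(ref, "PETVolume"))
  stopIfNotSameGrid(pred, ref, "pred and ref")
  if (nBins < 10L) stop("nBins must be >= 10", call. = FALSE)
  m <- ref@voxels > maskThreshold
  if (sum(m) < 2L)
    stop("fewer than 2 voxels above the mask threshold", call. = FALSE)
  x <- ref@voxels[m]
  y <- pred@voxels[m]
  fit <- stats::lm.fit(cbind(1, x), y)
  lim <- range(c(x, y))
  if (diff(lim) == 0) lim <- lim + c(0, 1)
  br <- seq(lim[1], lim[2], length.out = nBins + 1L)
  ix <- findInterval(x, br, all.inside = TRUE)
  iy <- findInterval(y, br, all.inside = TRUE)
  h <- matrix(0L, nBins, nBins)
  tab <- table(factor(ix, levels = seq_len(nBins)),
               factor(iy, levels = seq_len(nBins)))
  h[] <- as.integer(tab)
  list(hist2d = h, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), nVoxels = sum(m))
}

#' Voxel-wise absolute percentage error map
#'
#' \code{|pred - ref| / max(ref, floor) * 100} per voxel, as a
#' dimensionless ratio volume. The floor guards the division in low-count
#' voxels.
#'
#' @param pred,ref \linkS4class{PETVolume}s on the same grid.
#' @param floor strictly positive divisor floor.
#' @return \linkS4class{PETVolume} with unit \code{"ratio"} (percent).
#' @export
errorMap <- function(pred, ref, floor = 1) {
  stopifnot(is(pred, "PETVolume"), is(ref, "PETVolume"))
  stopIfNotSameGrid(pred, ref, "pred and ref")
  if (floor <= 0) stop("floor must be > 0", call. = FALSE)
  e <- abs(pred@voxels - ref@voxels) / pmax(ref@voxels, floor) * 100
  PETVolume(e, ref@spacing, "ratio")
}

#' Paired two-tailed t-test with multiplicity-corrected significance
#'
#' Classical paired two-tailed t-test between matched per-subject metric
#' vectors, flagged significant when \code{p < 0.05 / nComparisons}
#' (Bonferroni); with two comparisons the threshold is 0.025. Exactly tied
#' samples (zero-variance differences) are reported as an exact tie with
#' \code{t = 0}, \code{p = 1} rather than a division error.
#'
#' @param metricA,metricB equal-length paired samples, length >= 3.
#' @param nComparisons number of simultaneous comparisons (>= 1).
#' @return list with \code{t}, \code{p}, \code{df}, \code{significant},
#'   \code{exactTie}.
#' @export
pairedComparison <- function(metricA, metricB, nComparisons = 1L) {
  stopifnot(length(metricA) == length(metricB), length(metricA) >= 3L,
            nComparisons >= 1L)
  d <- metricA - metricB
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = 1, df = length(d) - 1L, significant = FALSE,
                exactTie = TRUE))
  }
  ht <- stats::t.test(metricA, metricB, paired = TRUE,
                      alternative = "two.sided")
  alpha <- 0.05 / nComparisons
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), significant = ht$p.value < alpha,
       exactTie = FALSE)
}

#' Automatic VOI placement from a phantom specification
#'
#' Derives spherical VOIs from the organ centres of a
#' \linkS4class{PhantomSpec} (radius 40% of the organ's smallest
#' semi-axis), replacing manual delineation on clinical images. By default
#' the liver, kidney and heart are used. On coarse desk-scale grids the
#' radius is floored at half the voxel diagonal so every VOI is guaranteed
#' to contain at least one voxel centre.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param organLabels organ labels to place VOIs in.
#' @return list of \linkS4class{VOISphere}s.
#' @export
voisFromSpec <- function(spec, organLabels = c("liver", "kidney", "heart")) {
  org <- spec@organs[spec@organs$label %in% organLabels, , drop = FALSE]
  rFloor <- 0.5 * sqrt(sum(spec@spacing^2)) + 1e-9
  lapply(seq_len(nrow(org)), function(i) {
    VOISphere(center = c(org$cx[i], org$cy[i], org$cz[i]),
              radius = max(0.4 * min(org$rx[i], org$ry[i], org$rz[i]),
                           rFloor),
              label = org$label[i])
  })
}

#' Evaluate a predicted volume family against its references
#'
#' Aggregates the package's quantitative evaluation for matched lists of
#' predicted and reference volumes: per-volume global metrics, per-VOI SUV
#' metrics and first-order features with feature-level MAPE, and the
#' joint-histogram regression of the first pair.
#'
#' @param preds,refs equal-length lists of \linkS4class{PETVolume}s.
#' @param vois list of \linkS4class{VOISphere}s (possibly empty).
#' @param suvScale intensity-to-SUV factor.
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateVolumes <- function(preds, refs, vois = list(), suvScale = 1) {
  stopifnot(length(preds) == length(refs), length(preds) >= 1)
  glob <- do.call(rbind, lapply(seq_along(preds), function(i) {
    g <- globalMetrics(preds[[i]], refs[[i]])
    data.frame(volume = i, nrmse = g$nrmse, psnr = g$psnr, ssim = g$ssim)
  }))
  voiTab <- data.frame()
  mapeTab <- data.frame()
  if (length(vois)) {
    rows <- list()
    featP <- list()
    featR <- list()
    for (i in seq_along(preds)) {
      for (v in vois) {
        mp <- voiMetrics(preds[[i]], v, suvScale)
        mr <- voiMetrics(refs[[i]], v, suvScale)
        rows[[length(rows) + 1L]] <- data.frame(
          volume = i, label = v@label,
          suvMeanPred = mp$suvMean, suvMeanRef = mr$suvMean,
          suvMaxPred = mp$suvMax, suvMaxRef = mr$suvMax,
          tlmPred = mp$tlm, tlmRef = mr$tlm)
        featP[[length(featP) + 1L]] <- voiFeatures(preds[[i]], v)
        featR[[length(featR) + 1L]] <- voiFeatures(refs[[i]], v)
      }
    }
    voiTab <- do.call(rbind, rows)
    mp <- featureMAPE(do.call(rbind, featP), do.call(rbind, featR))
    mapeTab <- data.frame(feature = names(mp), mape = as.numeric(mp))
  }
  jh <- jointHistogram(preds[[1]], refs[[1]],
                       maskThreshold = stats::quantile(refs[[1]]@voxels, 0.5,
                                                       names = FALSE))
  new("MetricsReport", global = glob, voi = voiTab, mape = mapeTab,
      jointHist = list(slope = jh$slope, intercept = jh$intercept,
                       nVoxels = jh$nVoxels),
      tests = data.frame())
}
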