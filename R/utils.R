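#' @include AllClasses.R
NULL

# Deterministic sub-stream seed derived from a base seed and a name, so that
# adding phantoms/models to an experiment never perturbs existing streams.
# Simple FNV-style string hash folded with the base seed, kept < 2^31.
substreamSeed <- function(seed, name) {
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- (h * 16777619) %% 2147483647
    h <- ((h %% 2147483647) + b) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Separable Gaussian blur of a 3D array, kernel truncated at 4 sigma,
# renormalized, reflected ("replicate"-free: zero-padding avoided by
# normalizing the partial kernel mass at the edges).
gaussianBlur3d <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s <- sigma / spacing[ax]
    if (s < 1e-6) next
    half <- max(1L, ceiling(4 * s))
    kern <- stats::dnorm(seq(-half, half), sd = s)
    arr <- blurAlongAxis(arr, ax, kern)
  }
  arr
}

# Apply a 1D kernel along one axis of a 3D array via a banded matrix product;
# edge taps are renormalized so a constant volume stays exactly constant.
blurAlongAxis <- function(arr, ax, kern) {
  d <- dim(arr)
  n <- d[ax]
  half <- (length(kern) - 1L) / 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    w <- kern[ok]
    B[i, j[ok]] <- w / sum(w)
  }
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- B %*% matrix(x, dp[1], dp[2] * dp[3])
  dim(y) <- dp
  aperm(y, order(perm))
}

#' Fraction of spectral energy above a radial frequency threshold
#'
#' Computes the 3D discrete Fourier transform of a volume's voxel array and
#' returns the fraction of total spectral energy carried by radial spatial
#' frequencies above \code{frac} of the Nyquist frequency (frequencies in
#' cycles per voxel per axis). Used to quantify how low-frequency a
#' correction map is relative to the activity image it corrects.
#'
#' @param vol a \linkS4class{PETVolume} or 3D array.
#' @param frac radial threshold as a fraction of Nyquist (default 0.25,
#'   i.e. one quarter of Nyquist).
#' @return Scalar in [0, 1].
#' @export
highFreqEnergyFraction <- function(vol, frac = 0.25) {
  arr <- if (is(vol, "PETVolume")) vol@voxels else vol
  d <- dim(arr)
  F2 <- abs(fft(arr))^2
  fr <- lapply(d, function(n) {
    k <- 0:(n - 1)
    pmin(k, n - k) / n  # cycles/voxel, Nyquist = 0.5
  })
  r2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`)
  thr <- (0.5 * frac)^2
  sum(F2[r2 > thr]) / sum(F2)
}

# quantile with a guard for all-zero volumes
robustScale <- function(arr, q) {
  s <- stats::quantile(arr, q, names = FALSE)
  if (!is.finite(s) || s <= 0) s <- max(arr)
  if (s <= 0) s <- 1
  s
}

stopIfNotSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop(what, " must share the same grid shape", call. = FALSE)
  if (max(abs(a@spacing - b@spacing)) > 1e-9)
    stop(what, " must share the same spacing", call. = FALSE)
  invisible(TRUE)
}

#' @importFrom stats fft
NULL
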