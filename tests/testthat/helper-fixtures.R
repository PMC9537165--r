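# Shared fixtures, all generated in code.

# desk-scale phantom specs
tinySpec <- function(...) {
  defaultPhantomSpec(shape = 16L, spacing = 16, nAngles = 2L, ...)
}

smallSpec <- function(...) {
  defaultPhantomSpec(shape = 32L, spacing = 8, nAngles = 4L, ...)
}

noiselessSpec <- function(...) {
  smallSpec(noiseScale = 0, scatterFraction = 0, ...)
}

randomVolume <- function(d = c(8L, 8L, 8L), seed = 1L, spacing = 4,
                         unit = "activity", lo = 0, hi = 10) {
  set.seed(seed)
  PETVolume(array(runif(prod(d), lo, hi), d), spacing, unit)
}

# a bare geometric spec built by hand (no organs unless given)
bareSpec <- function(shape = c(12L, 12L, 12L), spacing = 4, background = 1,
                     organs = NULL, lesions = NULL, psfFwhm = 0,
                     noiseScale = 0, scatterFraction = 0, nAngles = 2L,
                     seed = 1L) {
  if (is.null(organs)) {
    organs <- data.frame(label = character(), cx = numeric(), cy = numeric(),
                         cz = numeric(), rx = numeric(), ry = numeric(),
                         rz = numeric(), mult = numeric(), mu = numeric())
  }
  if (is.null(lesions)) {
    lesions <- data.frame(label = character(), cx = numeric(), cy = numeric(),
                          cz = numeric(), r = numeric(), mult = numeric())
  }
  new("PhantomSpec", shape = as.integer(rep(shape, length.out = 3)),
      spacing = as.numeric(rep(spacing, length.out = 3)),
      background = background, organs = organs, lesions = lesions,
      tracerProfile = "fdg", psfFwhm = psfFwhm, noiseScale = noiseScale,
      scatterFraction = scatterFraction, scatterFwhm = 40,
      nAngles = as.integer(nAngles), seed = as.integer(seed))
}

# independent slow ray-march oracle (same defined sampling rule, written as
# a plain per-voxel loop with its own interpolator)
oracleAttenuationFactor <- function(arr, sp, nAngles, vox) {
  nx <- dim(arr)[1]; ny <- dim(arr)[2]
  step <- min(sp) / 2
  ex <- nx * sp[1]; ey <- ny * sp[2]
  nstep <- ceiling(sqrt(ex^2 + ey^2) / step)
  interp <- function(sl, qx, qy) {
    if (qx <= -1 || qy <= -1 || qx >= nx || qy >= ny) return(0)
    ix <- floor(qx); iy <- floor(qy); wx <- qx - ix; wy <- qy - iy
    g <- function(i, j) {
      if (i >= 0 && i < nx && j >= 0 && j < ny) sl[i + 1, j + 1] else 0
    }
    (1 - wy) * ((1 - wx) * g(ix, iy) + wx * g(ix + 1, iy)) +
      wy * ((1 - wx) * g(ix, iy + 1) + wx * g(ix + 1, iy + 1))
  }
  x <- vox[1] - 1; y <- vox[2] - 1; z <- vox[3]
  acc <- 0
  for (a in seq_len(nAngles) - 1) {
    th <- pi * a / nAngles
    L <- 0
    for (sgn in c(-1, 1)) {
      for (s in seq_len(nstep) - 1) {
        t <- (s + 0.5) * step
        L <- L + interp(arr[, , z], x + sgn * t * cos(th) / sp[1],
                        y + sgn * t * sin(th) / sp[2])
      }
    }
    acc <- acc + exp(-L * step)
  }
  acc / nAngles
}
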