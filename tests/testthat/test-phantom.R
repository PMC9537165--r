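test_that("rasterization handles empty geometry and exact sphere painting", {
  b <- 2.5
  spec <- bareSpec(background = b)
  ph <- generatePhantom(spec)
  expect_true(all(voxels(ph$activity) == b))
  expect_true(all(voxels(ph$muMap) == 0))

  # one centred sphere, multiplier 4, no PSF: exactly 4b inside, b outside
  ext <- (spec@shape - 1L) * spec@spacing
  org <- data.frame(label = "body", cx = ext[1] / 2, cy = ext[2] / 2,
                    cz = ext[3] / 2, rx = 12, ry = 12, rz = 12, mult = 4,
                    mu = 0.0096)
  sp2 <- bareSpec(background = b, organs = org)
  ph2 <- generatePhantom(sp2)
  co <- lapply(1:3, function(ax) (seq_len(16) - 1) * 4)
  inside <- outer(outer((co[[1]][1:12] - ext[1] / 2)^2,
                        (co[[2]][1:12] - ext[2] / 2)^2, `+`),
                  (co[[3]][1:12] - ext[3] / 2)^2, `+`) <= 12^2
  a <- voxels(ph2$activity)[1:12, 1:12, 1:12]
  expect_true(all(a[inside] == 4 * b))
  expect_true(all(a[!inside] == b))
  expect_setequal(unique(as.vector(voxels(ph2$muMap))), c(0, 0.0096))
})

test_that("default phantom matches an independent voxel-loop rasterizer", {
  spec <- defaultPhantomSpec(shape = 16L, spacing = 16, psfFwhm = 0,
                             seed = 7L)
  ph <- generatePhantom(spec)
  # independent rasterizer: plain per-voxel loop over the geometry tables
  act <- array(spec@background, spec@shape)
  mu <- array(0, spec@shape)
  for (xi in 1:16) for (yi in 1:16) for (zi in 1:16) {
    p <- (c(xi, yi, zi) - 1) * spec@spacing
    for (i in seq_len(nrow(spec@organs))) {
      o <- spec@organs[i, ]
      if (((p[1] - o$cx) / o$rx)^2 + ((p[2] - o$cy) / o$ry)^2 +
          ((p[3] - o$cz) / o$rz)^2 <= 1) {
        act[xi, yi, zi] <- spec@background * o$mult
        mu[xi, yi, zi] <- o$mu
      }
    }
    for (i in seq_len(nrow(spec@lesions))) {
      l <- spec@lesions[i, ]
      if (sum((p - c(l$cx, l$cy, l$cz))^2) <= l$r^2) {
        act[xi, yi, zi] <- spec@background * l$mult
      }
    }
  }
  expect_equal(voxels(ph$activity), act)
  expect_equal(voxels(ph$muMap), mu)
})

test_that("attenuation factors obey vacuum, analytic-chord and oracle checks", {
  # vacuum: factor exactly 1 everywhere
  z <- PETVolume(array(0, c(8, 8, 8)), 4, "mu")
  expect_true(all(voxels(attenuationFactorMap(z, 4L)) == 1))

  # uniform-mu sphere: centre factor = exp(-2 mu R) within 2% at h <= R/16
  mu0 <- 0.0096
  R <- 32
  h <- 2                      # = R/16
  n <- 41L
  ctr <- (n - 1) / 2 * h
  co <- (seq_len(n) - 1) * h
  msk <- outer(outer((co - ctr)^2, (co - ctr)^2, `+`), (co - ctr)^2, `+`) <=
    R^2
  muv <- PETVolume(array(mu0 * msk, c(n, n, n)), h, "mu")
  af <- attenuationFactorMap(muv, 2L)
  centre <- voxels(af)[(n + 1) / 2, (n + 1) / 2, (n + 1) / 2]
  expect_lt(abs(centre - exp(-2 * mu0 * R)) / exp(-2 * mu0 * R), 0.02)

  # random grid equals the independent per-voxel ray-marching loop
  set.seed(42)
  arr <- array(runif(16^3) * 0.02, c(16, 16, 16))
  sp <- c(3, 4, 5)
  af2 <- attenuationFactorMap(PETVolume(arr, sp, "mu"), 4L)
  for (vox in list(c(1L, 1L, 1L), c(8L, 9L, 3L), c(16L, 5L, 12L))) {
    o <- oracleAttenuationFactor(arr, sp, 4L, vox)
    expect_lt(abs(voxels(af2)[vox[1], vox[2], vox[3]] - o) / o, 1e-6)
  }

  # monotone: increasing mu anywhere never increases any factor
  arr2 <- arr
  arr2[5, 5, 5] <- arr2[5, 5, 5] + 0.01
  af3 <- attenuationFactorMap(PETVolume(arr2, sp, "mu"), 4L)
  expect_true(all(voxels(af3) <= voxels(af2) + 1e-12))
  expect_error(attenuationFactorMap(z, 0L), "nAngles")
})

test_that("simulated pairs satisfy the noiseless and vacuum identities", {
  spec <- noiselessSpec()
  pair <- simulatePair(spec)
  expect_equal(voxels(pair@nasc), voxels(pair@asc) * voxels(pair@afMap),
               tolerance = 1e-15)
  expect_true(all(voxels(pair@afMap) > 0 & voxels(pair@afMap) <= 1))

  # vacuum limit: mu = 0 -> nasc = asc, true map = 1 wherever nasc > eps
  spec0 <- bareSpec(shape = 12L, spacing = 8, background = 5)
  pair0 <- simulatePair(spec0)
  expect_identical(voxels(pair0@nasc), voxels(pair0@asc))
  hot <- voxels(pair0@nasc) > 1
  expect_true(all(voxels(pair0@trueAdcm)[hot] == 1))

  # true map equals 1/af on hot voxels in the noiseless scatter-free limit
  tr <- voxels(pair@trueAdcm)
  inv <- 1 / voxels(pair@afMap)
  hot <- voxels(pair@nasc) > 1
  expect_lt(max(abs(tr[hot] - inv[hot]) / inv[hot]), 1e-12)
})

test_that("count totals and determinism of the full forward model hold", {
  spec <- smallSpec(seed = 3L)
  pair <- suppressMessages(simulatePair(spec))
  # independent single-pass recomputation of the total-count ratio
  ph <- generatePhantom(spec)
  af <- attenuationFactorMap(ph$muMap, spec@nAngles)
  trues <- voxels(ph$activity) * voxels(af)
  sc0 <- petdecomp:::gaussianBlur3d(trues, spec@spacing, spec@scatterFwhm)
  sf <- spec@scatterFraction
  scatter <- sc0 * (sf / (1 - sf)) * sum(trues) / sum(sc0)
  set.seed(spec@seed)
  nasc <- rpois(length(trues), (trues + scatter) * spec@noiseScale) /
    spec@noiseScale
  asc <- pmax((nasc - as.vector(scatter)) / as.vector(voxels(af)), 0)
  expect_lt(abs(sum(voxels(pair@nasc)) / sum(voxels(pair@asc)) -
                sum(nasc) / sum(asc)), 1e-6)

  # scatter share of total counts matches the stated fraction (noiseless)
  specSc <- smallSpec(noiseScale = 0)
  pairSc <- suppressMessages(simulatePair(specSc))
  p <- voxels(pairSc@asc) * voxels(pairSc@afMap)
  expect_equal((sum(voxels(pairSc@nasc)) - sum(p)) /
                 sum(voxels(pairSc@nasc)), specSc@scatterFraction,
               tolerance = 1e-6)

  # determinism: same spec, same seed -> bitwise identical volumes
  pair2 <- suppressMessages(simulatePair(spec))
  expect_identical(voxels(pair@nasc), voxels(pair2@nasc))
  expect_identical(voxels(pair@asc), voxels(pair2@asc))
})

test_that("datasets honour the n = 1 identity, tracer shifts and determinism", {
  spec <- tinySpec(seed = 5L)
  d1 <- suppressMessages(makeDataset(spec, 1L, "none", seed = 77L))
  ref <- suppressMessages(simulatePair(spec))
  expect_identical(voxels(d1[[1]]@nasc), voxels(ref@nasc))

  # liver-avid shift: liver mean activity strictly higher in all pairs
  base <- suppressMessages(makeDataset(spec, 5L, "none", seed = 9L))
  shifted <- suppressMessages(makeDataset(spec, 5L, "tracer", seed = 9L,
                                          tracerProfile = "liver-avid"))
  liverMean <- function(p) {
    o <- p@spec@organs[p@spec@organs$label == "liver", ]
    m <- petdecomp:::ellipsoidMask(p@spec@shape, p@spec@spacing,
                                   c(o$cx, o$cy, o$cz), c(o$rx, o$ry, o$rz))
    mean(voxels(p@asc)[m])
  }
  for (i in 1:5) expect_gt(liverMean(shifted[[i]]), liverMean(base[[i]]))

  # fixed seed regenerates bitwise-identical volumes
  a <- suppressMessages(makeDataset(spec, 3L, "scanner", seed = 21L))
  b <- suppressMessages(makeDataset(spec, 3L, "scanner", seed = 21L))
  for (i in 1:3) expect_identical(voxels(a[[i]]@nasc), voxels(b[[i]]@nasc))

  expect_error(makeDataset(spec, 2L, "warp"), "shift")
})
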