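test_that("global metrics handle the perfect, shifted and degenerate cases", {
  r <- randomVolume(seed = 41, lo = 1, hi = 9)
  g <- globalMetrics(r, r)
  expect_equal(g$nrmse, 0)
  expect_identical(g$psnr, Inf)
  expect_equal(g$ssim, 1)

  # constant offset: RMSE = c exactly, NRMSE = c / range
  cshift <- PETVolume(voxels(r) + 0.5, spacing(r), volumeUnit(r))
  g2 <- globalMetrics(cshift, r)
  expect_equal(g2$nrmse, 0.5 / diff(range(voxels(r))), tolerance = 1e-12)
  expect_equal(g2$psnr, 20 * log10(max(voxels(r)) / 0.5), tolerance = 1e-12)

  expect_error(globalMetrics(r, PETVolume(array(2, c(8, 8, 8)), 4)),
               "constant")
})

test_that("global metrics match independent scalar-loop implementations", {
  p <- randomVolume(seed = 42, lo = 0, hi = 5)
  r <- randomVolume(seed = 43, lo = 0, hi = 5)
  g <- globalMetrics(p, r)
  pv <- voxels(p); rv <- voxels(r)
  # NRMSE / PSNR by explicit accumulation
  acc <- 0
  for (i in seq_along(pv)) acc <- acc + (pv[i] - rv[i])^2
  rmse <- sqrt(acc / length(pv))
  expect_equal(g$nrmse, rmse / (max(rv) - min(rv)), tolerance = 1e-10)
  expect_equal(g$psnr, 20 * log10(max(rv) / rmse), tolerance = 1e-10)
  # SSIM by a literal windowed loop (7^3 window clipped at the borders)
  L <- max(pv, rv) - min(pv, rv)   # joint dynamic range, keeps SSIM symmetric
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  n <- dim(pv)
  acc <- 0
  for (zi in 1:n[3]) for (yi in 1:n[2]) for (xi in 1:n[1]) {
    xs <- max(1, xi - 3):min(n[1], xi + 3)
    ys <- max(1, yi - 3):min(n[2], yi + 3)
    zs <- max(1, zi - 3):min(n[3], zi + 3)
    # the edge-renormalized separable box filter equals the plain mean
    # over the border-clipped window
    win <- function(a) mean(a[xs, ys, zs])
    mp <- win(pv); mr <- win(rv)
    vp <- win(pv^2) - mp^2; vr <- win(rv^2) - mr^2
    cv <- win(pv * rv) - mp * mr
    acc <- acc + ((2 * mp * mr + C1) * (2 * cv + C2)) /
      ((mp^2 + mr^2 + C1) * (vp + vr + C2))
  }
  expect_equal(g$ssim, acc / length(pv), tolerance = 1e-10)
  # symmetry
  expect_equal(globalMetrics(r, p)$ssim, g$ssim, tolerance = 1e-12)
})

test_that("VOI metrics follow voxel-centre membership exactly", {
  cst <- PETVolume(array(3, c(10, 10, 10)), 4, "activity")
  voi <- VOISphere(center = c(18, 18, 18), radius = 10, label = "liver")
  m <- voiMetrics(cst, voi)
  expect_equal(m$suvMean, 3)
  expect_equal(m$suvMax, 3)
  expect_equal(m$tlm, 3 * m$nVoxels * 64 / 1000)

  # single hot voxel dominates the max for any radius
  v <- voxels(cst); v[5, 5, 5] <- 50
  hotv <- PETVolume(v, 4, "activity")
  expect_equal(voiMetrics(hotv, voi)$suvMax, 50)

  # off-grid-centre sphere on a ramp matches a brute-force membership loop
  ramp <- PETVolume(array(rep(1:10, 100), c(10, 10, 10)), 4, "activity")
  voi2 <- VOISphere(center = c(13.7, 21.2, 9.9), radius = 9.3, label = "k")
  got <- voiMetrics(ramp, voi2, suvScale = 2)
  vals <- c()
  for (zi in 1:10) for (yi in 1:10) for (xi in 1:10) {
    p <- (c(xi, yi, zi) - 1) * 4
    if (sum((p - voi2@center)^2) <= 9.3^2) {
      vals <- c(vals, voxels(ramp)[xi, yi, zi] * 2)
    }
  }
  expect_equal(got$suvMean, mean(vals))
  expect_equal(got$suvMax, max(vals))
  expect_equal(got$nVoxels, length(vals))

  expect_error(voiMetrics(cst, VOISphere(c(-50, -50, -50), 1)), "no voxel")
})

test_that("feature MAPE reproduces closed forms and a table recomputation", {
  f <- matrix(runif(12, 1, 5), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(featureMAPE(f, f) == 0))
  expect_equal(as.numeric(featureMAPE(f[1, , drop = FALSE] * 1.1,
                                      f[1, , drop = FALSE])),
               rep(10, 3), tolerance = 1e-12)

  set.seed(50)
  p <- matrix(runif(60, 0.5, 2), 10, 6)
  r <- matrix(runif(60, 0.5, 2), 10, 6)
  got <- featureMAPE(p, r)
  want <- numeric(6)
  for (j in 1:6) {
    s <- 0
    for (i in 1:10) s <- s + abs(p[i, j] - r[i, j]) / abs(r[i, j])
    want[j] <- s / 10 * 100
  }
  expect_equal(as.numeric(got), want, tolerance = 1e-12)

  # zero references are excluded with a count, not silently dropped
  r2 <- r
  r2[3, 2] <- 0
  expect_message(out <- featureMAPE(p, r2), "excluded")
  expect_identical(attr(out, "nExcluded")[2], 1L)
})

test_that("joint histogram recovers linear relations and masks correctly", {
  r <- randomVolume(d = c(12L, 12L, 12L), seed = 61, lo = 0.5, hi = 8)
  jh <- jointHistogram(r, r, nBins = 32L)
  expect_equal(jh$slope, 1, tolerance = 1e-12)
  expect_equal(jh$intercept, 0, tolerance = 1e-10)

  # attenuated copy: slope recovered exactly (the form of a correction
  # that slightly underestimates activity)
  p94 <- PETVolume(voxels(r) * 0.94, spacing(r), "activity")
  expect_equal(jointHistogram(p94, r)$slope, 0.94, tolerance = 1e-12)

  # noisy linear relation: matches the closed-form normal equations
  set.seed(62)
  x <- runif(1e4, 1, 10)
  y <- 1.7 * x + 0.3 + rnorm(1e4, sd = 0.2)
  pr <- PETVolume(array(y, c(100, 10, 10)), 1, "activity")
  rf <- PETVolume(array(x, c(100, 10, 10)), 1, "activity")
  jh2 <- jointHistogram(pr, rf, nBins = 20L, maskThreshold = 0)
  sl <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  expect_equal(jh2$slope, sl, tolerance = 1e-10)
  expect_equal(jh2$intercept, mean(y) - sl * mean(x), tolerance = 1e-10)
  expect_equal(sum(jh2$hist2d), 1e4)

  # masking: only voxels with ref > threshold participate
  jh3 <- jointHistogram(pr, rf, nBins = 20L, maskThreshold = 5)
  expect_equal(jh3$nVoxels, sum(x > 5))
  expect_error(jointHistogram(pr, rf, nBins = 4L), "nBins")
})

test_that("error maps apply the floor branch per voxel", {
  r <- randomVolume(seed = 71, lo = 0, hi = 6)
  expect_true(all(voxels(errorMap(r, r)) == 0))

  # reference below the floor everywhere: map = 100 d / floor
  rl <- PETVolume(array(0.2, c(4, 4, 4)), 4, "activity")
  pl <- PETVolume(array(0.2 + 0.05, c(4, 4, 4)), 4, "activity")
  expect_true(all(abs(voxels(errorMap(pl, rl, floor = 1)) - 5) < 1e-12))

  p <- randomVolume(seed = 72, lo = 0, hi = 6)
  got <- voxels(errorMap(p, r, floor = 0.5))
  want <- array(0, dim(got))
  for (i in seq_along(want)) {
    want[i] <- abs(voxels(p)[i] - voxels(r)[i]) /
      max(voxels(r)[i], 0.5) * 100
  }
  expect_identical(got, want)
  expect_error(errorMap(p, r, floor = -1), "floor")
})

test_that("paired comparisons match the closed-form t statistic", {
  a <- c(2, 4, 6, 8, 10)
  b <- c(1, 2, 3, 4, 5)           # differences 1..5
  pc <- pairedComparison(a, b)
  d <- a - b
  tWant <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pc$t, tWant, tolerance = 1e-10)
  expect_equal(pc$t, 4.2426, tolerance = 1e-4)
  expect_equal(pc$p, 2 * pt(-tWant, df = 4), tolerance = 1e-10)
  expect_equal(pc$p, 0.0132, tolerance = 5e-3)

  # Bonferroni with two comparisons: threshold 0.025
  pc2 <- pairedComparison(a, b, nComparisons = 2L)
  expect_identical(pc2$significant, pc2$p < 0.025)
  # a comparison with p = 0.03 would not be significant at 2 comparisons
  expect_false(0.03 < 0.025)
  # identical samples: exact-tie report instead of a division error
  tie <- pairedComparison(b, b)
  expect_true(tie$exactTie)
  expect_equal(tie$t, 0)
  expect_equal(tie$p, 1)
})

test_that("metric invariances hold under joint rescaling", {
  p <- randomVolume(seed = 81, lo = 0.5, hi = 4)
  r <- randomVolume(seed = 82, lo = 0.5, hi = 4)
  c0 <- 11.3
  ps <- PETVolume(voxels(p) * c0, spacing(p), "activity")
  rs <- PETVolume(voxels(r) * c0, spacing(r), "activity")
  expect_equal(globalMetrics(ps, rs)$nrmse, globalMetrics(p, r)$nrmse,
               tolerance = 1e-12)
  expect_equal(voxels(errorMap(ps, rs, floor = 0.1 * c0)),
               voxels(errorMap(p, r, floor = 0.1)), tolerance = 1e-12)
})

test_that("VOIs derive from phantom organs and reports aggregate", {
  spec <- tinySpec()
  vois <- voisFromSpec(spec)
  expect_identical(sort(vapply(vois, function(v) v@label, "")),
                   c("heart", "kidney", "kidney", "liver"))
  rFloor <- 0.5 * sqrt(sum(spec@spacing^2))
  for (v in vois) {
    o <- spec@organs[which(spec@organs$label == v@label)[1], ]
    expect_equal(v@radius, max(0.4 * min(o$rx, o$ry, o$rz), rFloor + 1e-9))
  }
  pair <- suppressMessages(simulatePair(spec))
  rep <- evaluateVolumes(list(pair@nasc), list(pair@asc), vois)
  expect_s4_class(rep, "MetricsReport")
  expect_identical(nrow(rep@global), 1L)
  expect_identical(nrow(rep@voi), 4L)
  expect_true(all(rep@mape$mape >= 0))
  expect_true(is.finite(rep@jointHist$slope))
})
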