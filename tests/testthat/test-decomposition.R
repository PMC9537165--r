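test_that("correction-map formation follows the two-branch rule exactly", {
  # identity: asc = nasc everywhere above threshold -> ratio 1
  a <- PETVolume(array(5, c(4, 4, 4)), 4, "activity")
  m <- computeADCM(a, a)
  expect_true(all(voxels(m) == 1))
  expect_identical(provenance(m), "computed")

  # below-threshold voxel stores the corrected intensity itself
  nv <- array(2, c(2, 2, 2)); nv[1, 1, 1] <- 0.5
  av <- array(3, c(2, 2, 2)); av[1, 1, 1] <- 7.0
  m2 <- computeADCM(PETVolume(nv, 1), PETVolume(av, 1),
                    DecompositionConfig(epsilon = 1))
  expect_identical(voxels(m2)[1, 1, 1], 7.0)
  expect_identical(voxels(m2)[2, 2, 2], 1.5)

  # random pair matches an element-wise two-branch loop exactly
  n <- randomVolume(seed = 11, lo = 0, hi = 3)
  a <- randomVolume(seed = 12, lo = 0, hi = 3)
  got <- voxels(computeADCM(n, a))
  want <- array(0, dim(voxels(n)))
  for (i in seq_along(want)) {
    want[i] <- if (voxels(n)[i] > 1) voxels(a)[i] / voxels(n)[i] else
      voxels(a)[i]
  }
  expect_identical(got, want)

  expect_error(computeADCM(n, randomVolume(d = c(4L, 4L, 4L))), "shape")
})

test_that("map application and the round-trip conservation law hold", {
  n <- randomVolume(seed = 21, lo = 0, hi = 4)
  a <- randomVolume(seed = 22, lo = 0, hi = 4)
  m <- computeADCM(n, a)

  # unit map leaves the input untouched
  unit <- new("ADCMap", ratio = PETVolume(array(1, dim(voxels(n))),
                                          spacing(n), "ratio"),
              epsilon = 1, provenance = "computed")
  expect_identical(voxels(applyADCM(n, unit)), voxels(n))

  # round trip: asc restored above eps, nasc passed through below
  out <- voxels(applyADCM(n, m))
  hot <- voxels(n) > 1
  expect_equal(out[hot], voxels(a)[hot], tolerance = 1e-14)
  expect_identical(out[!hot], voxels(n)[!hot])

  # matches the per-voxel loop exactly
  want <- array(0, dim(voxels(n)))
  for (i in seq_along(want)) {
    want[i] <- if (voxels(n)[i] > 1) voxels(n)[i] * voxels(m)[i] else
      voxels(n)[i]
  }
  expect_identical(out, want)

  # mismatched epsilon is rejected
  expect_error(applyADCM(n, m, epsilon = 2), "disagrees")
})

test_that("application is monotone in the ratio and scale-robust", {
  n <- randomVolume(seed = 31, lo = 0, hi = 4)
  a <- randomVolume(seed = 32, lo = 0, hi = 4)
  m <- computeADCM(n, a)
  rUp <- voxels(m)
  rUp[3, 3, 3] <- rUp[3, 3, 3] + 0.5
  mUp <- new("ADCMap", ratio = PETVolume(rUp, spacing(n), "ratio"),
             epsilon = 1, provenance = "computed")
  expect_true(all(voxels(applyADCM(n, mUp)) >= voxels(applyADCM(n, m))))

  # joint rescaling with a rescaled threshold leaves the if-branch ratios
  c0 <- 3.7
  m2 <- computeADCM(PETVolume(voxels(n) * c0, spacing(n)),
                    PETVolume(voxels(a) * c0, spacing(n)),
                    DecompositionConfig(epsilon = c0))
  hot <- voxels(n) > 1
  expect_equal(voxels(m2)[hot], voxels(m)[hot], tolerance = 1e-12)
})

test_that("resampling preserves constants, extent and linear ramps", {
  cst <- PETVolume(array(3.25, c(16, 16, 16)), 4, "activity")
  down <- resampleVolume(cst, c(8L, 8L, 8L))
  expect_true(all(voxels(down) == 3.25))
  expect_equal(spacing(down), c(8, 8, 8))  # physical extent preserved
  up <- resampleVolume(down, c(16L, 16L, 16L))
  expect_true(all(voxels(up) == 3.25))
  expect_equal(spacing(up), c(4, 4, 4))

  # linear ramp down 64 -> 48 matches the closed-form interpolant at
  # fractional sample positions
  ramp <- PETVolume(array(rep(0:63, 16), c(64, 4, 4)), 2, "activity")
  d2 <- resampleVolume(ramp, c(48L, 4L, 4L))
  pos <- (0:47) * 64 / 48            # source index of each target sample
  expect_equal(voxels(d2)[, 1, 1], pmin(pos, 63), tolerance = 1e-12)

  # nearest-neighbour order picks the closest source voxel
  d0 <- resampleVolume(ramp, c(48L, 4L, 4L), order = 0L)
  expect_equal(voxels(d0)[, 1, 1], round(pmin(pos, 63)))

  expect_error(resampleVolume(cst, c(1L, 8L, 8L)), "targetShape")

  # ADCM resampling carries threshold and provenance along
  m <- computeADCM(randomVolume(seed = 5), randomVolume(seed = 6))
  mr <- resampleADCM(m, c(4L, 4L, 4L))
  expect_equal(epsilonUsed(mr), epsilonUsed(m))
  expect_identical(provenance(mr), "computed")
})
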