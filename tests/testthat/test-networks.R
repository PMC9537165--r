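pd <- asNamespace("petdecomp")

smallGANConfig <- function(...) {
  GANConfig(genDepth = 2L, genChannels = 3L, discDepth = 2L,
            discChannels = 3L, workingShape = c(8L, 8L, 8L), seed = 3L, ...)
}

test_that("generator and discriminator honour their shape contracts", {
  cfg <- smallGANConfig()
  models <- buildModels(cfg)
  x0 <- array(0, c(8, 8, 8, 1))
  y <- pd$genForward(models$generator, x0)$y
  expect_identical(dim(y), c(8L, 8L, 8L, 1L))
  expect_true(all(is.finite(y)))

  tgt <- array(rnorm(8^3), c(8, 8, 8, 1))
  sReal <- pd$discForward(models$discriminator,
                          pd$concatChannels(x0, tgt))$score
  sFake <- pd$discForward(models$discriminator,
                          pd$concatChannels(x0, y))$score
  expect_true(is.finite(sReal) && sReal > 0 && sReal < 1)
  expect_true(is.finite(sFake) && sFake > 0 && sFake < 1)

  # same seed -> identical initial parameters
  m2 <- buildModels(cfg)
  expect_identical(models$generator$final$w, m2$generator$final$w)
})

test_that("parameter count matches the layer-by-layer architecture arithmetic", {
  cfg <- smallGANConfig()
  models <- buildModels(cfg)
  # generator, depth 2, base 3 channels, single input channel:
  #   encoder L1: conv 1->3, conv 3->3; L2: conv 3->6, conv 6->6
  #   decoder L1: conv (3+6)->3, conv 3->3; final 1x1 conv 3->1
  # each conv: k^3*cin*cout weights + cout biases; each norm: 2*cout
  convN <- function(cin, cout, k = 3) k^3 * cin * cout + cout
  normN <- function(cout) 2 * cout
  genWant <- convN(1, 3) + normN(3) + convN(3, 3) + normN(3) +
    convN(3, 6) + normN(6) + convN(6, 6) + normN(6) +
    convN(9, 3) + normN(3) + convN(3, 3) + normN(3) +
    convN(3, 1, 1)
  expect_identical(pd$paramCount(models$generator), genWant)
  # discriminator: conv 2->3, conv 3->6, head 6 weights + 1 bias
  discWant <- convN(2, 3) + normN(3) + convN(3, 6) + normN(6) + 6 + 1
  expect_identical(pd$paramCount(models$discriminator), discWant)
})

test_that("convolution agrees with a direct sliding-window oracle", {
  set.seed(8)
  x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
  p <- pd$initConv(2L, 3L, 3L)
  y <- pd$convForward(x, p)
  # oracle: quadruple loop over output voxels and taps, zero padding
  want <- array(0, c(6, 5, 4, 3))
  for (co in 1:3) for (zi in 1:4) for (yi in 1:5) for (xi in 1:6) {
    acc <- p$b[co]
    for (ci in 1:2) for (kz in 0:2) for (ky in 0:2) for (kx in 0:2) {
      sx <- xi + kx - 1; sy <- yi + ky - 1; sz <- zi + kz - 1
      if (sx < 1 || sx > 6 || sy < 1 || sy > 5 || sz < 1 || sz > 4) next
      row <- ((ci - 1) * 3 + kz) * 9 + ky * 3 + kx + 1
      acc <- acc + x[sx, sy, sz, ci] * p$w[row, co]
    }
    want[xi, yi, zi, co] <- acc
  }
  expect_equal(y, want, tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- smallGANConfig(lambdaL2 = 10)
  models <- buildModels(cfg)
  G <- models$generator
  D <- models$discriminator
  set.seed(14)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  tgt <- array(rnorm(8^3), c(8, 8, 8, 1))
  lossG <- function(G) {
    gf <- pd$genForward(G, x)
    df <- pd$discForward(D, pd$concatChannels(x, gf$y))
    10 * mean((gf$y - tgt)^2) + log(max(1 - df$score, 1e-12))
  }
  gf <- pd$genForward(G, x)
  df <- pd$discForward(D, pd$concatChannels(x, gf$y))
  gI <- pd$discBackward(D, df$caches, -df$score)
  gy <- 10 * 2 * (gf$y - tgt) / length(gf$y) + gI$dx[, , , 2, drop = FALSE]
  grads <- pd$genBackward(G, gf$caches, gy)
  eps <- 1e-5
  checks <- list(
    list(get = function(g) g$enc[[1]]$b1$conv$w[5, 2],
         set = function(g, v) { g$enc[[1]]$b1$conv$w[5, 2] <- v; g },
         grad = grads$enc[[1]]$b1$conv$w[5, 2]),
    list(get = function(g) g$dec[[1]]$b2$norm$gamma[1],
         set = function(g, v) { g$dec[[1]]$b2$norm$gamma[1] <- v; g },
         grad = grads$dec[[1]]$b2$norm$gamma[1]),
    list(get = function(g) g$final$w[2, 1],
         set = function(g, v) { g$final$w[2, 1] <- v; g },
         grad = grads$final$w[2, 1]))
  for (ck in checks) {
    v0 <- ck$get(G)
    num <- (lossG(ck$set(G, v0 + eps)) - lossG(ck$set(G, v0 - eps))) /
      (2 * eps)
    expect_equal(ck$grad, num, tolerance = 1e-5)
  }
})

test_that("the adversarial objective matches a scalar-loop recomputation", {
  # perfect generator with an undecided discriminator
  out <- array(2, c(3, 3, 3))
  obj <- ganObjective(dReal = c(0.5, 0.5), dFake = c(0.5, 0.5),
                      genOut = out, target = out, lambdaL2 = 1e4)
  expect_equal(obj$l2, 0)
  expect_equal(obj$adv, 2 * log(0.5))
  expect_equal(obj$lossD, -4 * log(0.5))

  # default configuration weight is 1e4
  expect_equal(GANConfig()@lambdaL2, 1e4)

  # random tensors against an explicit scalar loop
  set.seed(9)
  dr <- runif(3, 0.05, 0.95)
  dfk <- runif(3, 0.05, 0.95)
  g <- array(rnorm(27), c(3, 3, 3))
  t0 <- array(rnorm(27), c(3, 3, 3))
  obj2 <- ganObjective(dr, dfk, g, t0, lambdaL2 = 50)
  lD <- 0; adv <- 0
  for (i in 1:3) {
    lD <- lD - (log(dr[i]) + log(1 - dfk[i]))
    adv <- adv + log(1 - dfk[i])
  }
  sq <- 0
  for (i in seq_along(g)) sq <- sq + (g[i] - t0[i])^2
  expect_equal(obj2$lossD, lD, tolerance = 1e-6)
  expect_equal(obj2$lossG, adv + 50 * sq / 27, tolerance = 1e-6)
  expect_error(ganObjective(dr, dfk, g, t0, lambdaL2 = 0), "lambdaL2")
})
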