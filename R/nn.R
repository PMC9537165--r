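#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Minimal volumetric neural-network layer library with hand-written
# backpropagation. Activations are 4D arrays (nx, ny, nz, channels); the
# convolution itself runs in compiled code (im2col + GEMM). Everything here
# is deterministic given the R RNG state.
# ---------------------------------------------------------------------------

LRELU_SLOPE <- 0.2
INORM_EPS <- 1e-5

initConv <- function(cin, cout, k) {
  n <- k^3 * cin
  list(w = matrix(stats::rnorm(n * cout, sd = sqrt(2 / n)), n, cout),
       b = numeric(cout), k = k)
}

convForward <- function(x, p) {
  .conv3dForward(x, dim(x), p$w, p$b, p$k)
}

convBackward <- function(x, p, gy) {
  .conv3dBackward(x, dim(x), p$w, p$k, gy)
}

initNorm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# instance normalization over the voxel dimension, per channel
normForward <- function(x, p) {
  d <- dim(x)
  nv <- prod(d[1:3])
  xm <- matrix(x, nv, d[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  sd <- sqrt(colMeans(xc^2) + INORM_EPS)
  xhat <- sweep(xc, 2, sd, `/`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, sd = sd)
}

normBackward <- function(cache, p, gy) {
  d <- dim(gy)
  nv <- prod(d[1:3])
  gm <- matrix(gy, nv, d[4])
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  dxhat <- sweep(gm, 2, p$gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, `*`),
              2, cache$sd, `/`)
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

lreluForward <- function(x) ifelse(x > 0, x, LRELU_SLOPE * x)

lreluBackward <- function(x, gy) gy * ifelse(x > 0, 1, LRELU_SLOPE)

# conv -> instance norm -> leaky ReLU
blockForward <- function(x, p) {
  z <- convForward(x, p$conv)
  nrm <- normForward(z, p$norm)
  a <- lreluForward(nrm$y)
  list(y = a, x = x, z = z, nrm = nrm)
}

blockBackward <- function(cache, p, gy) {
  g1 <- lreluBackward(cache$nrm$y, gy)
  nb <- normBackward(cache$nrm, p$norm, g1)
  cb <- convBackward(cache$x, p$conv, nb$dx)
  list(dx = cb$dx,
       grads = list(conv = list(w = cb$dw, b = cb$db), norm = nb$grads))
}

initBlock <- function(cin, cout, k = 3L) {
  list(conv = initConv(cin, cout, k), norm = initNorm(cout))
}

# average pooling by factor 2 along every spatial axis of size > 1
poolFactors <- function(d) ifelse(d[1:3] > 1L, 2L, 1L)

poolForward <- function(x) {
  d <- dim(x)
  f <- poolFactors(d)
  nd <- d[1:3] %/% f
  y <- array(0, c(nd, d[4]))
  for (dz in seq_len(f[3]) - 1L) for (dy in seq_len(f[2]) - 1L)
    for (dx in seq_len(f[1]) - 1L) {
      y <- y + x[seq(1L + dx, d[1], f[1]), seq(1L + dy, d[2], f[2]),
                 seq(1L + dz, d[3], f[3]), , drop = FALSE]
    }
  y / prod(f)
}

poolBackward <- function(gy, dOrig) {
  f <- poolFactors(dOrig)
  gx <- array(0, dOrig)
  g <- gy / prod(f)
  for (dz in seq_len(f[3]) - 1L) for (dy in seq_len(f[2]) - 1L)
    for (dx in seq_len(f[1]) - 1L) {
      gx[seq(1L + dx, dOrig[1], f[1]), seq(1L + dy, dOrig[2], f[2]),
         seq(1L + dz, dOrig[3], f[3]), ] <- g
    }
  gx
}

# nearest-neighbour upsampling to a stated spatial target (factor 1 or 2)
upForward <- function(x, target) {
  d <- dim(x)
  ix <- lapply(1:3, function(ax) {
    if (target[ax] == d[ax]) seq_len(d[ax]) else rep(seq_len(d[ax]), each = 2L)
  })
  x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

upBackward <- function(gy, dOrig) {
  d <- dim(gy)
  g <- gy
  for (ax in 1:3) {
    if (d[ax] == dOrig[ax]) next
    odd <- seq(1L, d[ax], 2L)
    evn <- seq(2L, d[ax], 2L)
    g <- switch(ax,
      `1` = g[odd, , , , drop = FALSE] + g[evn, , , , drop = FALSE],
      `2` = g[, odd, , , drop = FALSE] + g[, evn, , , drop = FALSE],
      `3` = g[, , odd, , drop = FALSE] + g[, , evn, , drop = FALSE])
    d <- dim(g)
  }
  g
}

concatChannels <- function(a, b) {
  da <- dim(a)
  array(c(a, b), c(da[1:3], da[4] + dim(b)[4]))
}

# ---------------------------------------------------------------------------
# Generator: U-Net style encoder-decoder with skip connections.
# ---------------------------------------------------------------------------

genChannelsPerLevel <- function(base, depth) base * 2L^(seq_len(depth) - 1L)

initGenerator <- function(cfg, inChannels = 1L) {
  ch <- genChannelsPerLevel(cfg@genChannels, cfg@genDepth)
  enc <- vector("list", cfg@genDepth)
  cin <- inChannels
  for (l in seq_len(cfg@genDepth)) {
    enc[[l]] <- list(b1 = initBlock(cin, ch[l]), b2 = initBlock(ch[l], ch[l]))
    cin <- ch[l]
  }
  dec <- vector("list", cfg@genDepth - 1L)
  for (l in rev(seq_len(cfg@genDepth - 1L))) {
    cinl <- ch[l] + ch[l + 1L]   # skip + upsampled
    dec[[l]] <- list(b1 = initBlock(cinl, ch[l]), b2 = initBlock(ch[l], ch[l]))
  }
  list(enc = enc, dec = dec, final = initConv(ch[1L], 1L, 1L))
}

genForward <- function(params, x) {
  L <- length(params$enc)
  caches <- list(enc = vector("list", L), dec = vector("list", L - 1L),
                 skipDims = vector("list", L - 1L))
  h <- x
  skips <- vector("list", L - 1L)
  for (l in seq_len(L)) {
    c1 <- blockForward(h, params$enc[[l]]$b1)
    c2 <- blockForward(c1$y, params$enc[[l]]$b2)
    caches$enc[[l]] <- list(c1 = c1, c2 = c2)
    h <- c2$y
    if (l < L) {
      skips[[l]] <- h
      caches$skipDims[[l]] <- dim(h)
      h <- poolForward(h)
    }
  }
  for (l in rev(seq_len(L - 1L))) {
    hin <- dim(h)
    hu <- upForward(h, dim(skips[[l]])[1:3])
    hc <- concatChannels(skips[[l]], hu)
    c1 <- blockForward(hc, params$dec[[l]]$b1)
    c2 <- blockForward(c1$y, params$dec[[l]]$b2)
    caches$dec[[l]] <- list(c1 = c1, c2 = c2, hinDim = hin,
                            skipCh = dim(skips[[l]])[4])
    h <- c2$y
  }
  caches$finalIn <- h
  y <- convForward(h, params$final)
  list(y = y, caches = caches)
}

genBackward <- function(params, caches, gy) {
  L <- length(params$enc)
  grads <- list(enc = vector("list", L), dec = vector("list", L - 1L))
  fb <- convBackward(caches$finalIn, params$final, gy)
  grads$final <- list(w = fb$dw, b = fb$db)
  g <- fb$dx
  skipGrads <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    cc <- caches$dec[[l]]
    b2 <- blockBackward(cc$c2, params$dec[[l]]$b2, g)
    b1 <- blockBackward(cc$c1, params$dec[[l]]$b1, b2$dx)
    grads$dec[[l]] <- list(b1 = b1$grads, b2 = b2$grads)
    sc <- cc$skipCh
    gskip <- b1$dx[, , , seq_len(sc), drop = FALSE]
    gup <- b1$dx[, , , -seq_len(sc), drop = FALSE]
    skipGrads[[l]] <- gskip
    g <- upBackward(gup, cc$hinDim)
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      g <- poolBackward(g, caches$skipDims[[l]])
      g <- g + skipGrads[[l]]
    }
    cc <- caches$enc[[l]]
    b2 <- blockBackward(cc$c2, params$enc[[l]]$b2, g)
    b1 <- blockBackward(cc$c1, params$enc[[l]]$b1, b2$dx)
    grads$enc[[l]] <- list(b1 = b1$grads, b2 = b2$grads)
    g <- b1$dx
  }
  grads
}

# ---------------------------------------------------------------------------
# Discriminator: conditional conv classifier on the channel-stacked pair
# (condition, candidate) -> sigmoid score. Global average pooling head.
# ---------------------------------------------------------------------------

initDiscriminator <- function(cfg, inChannels = 2L) {
  ch <- cfg@discChannels * 2L^(seq_len(cfg@discDepth) - 1L)
  blocks <- vector("list", cfg@discDepth)
  cin <- inChannels
  for (l in seq_len(cfg@discDepth)) {
    blocks[[l]] <- initBlock(cin, ch[l])
    cin <- ch[l]
  }
  list(blocks = blocks,
       head = list(w = stats::rnorm(cin, sd = 1 / sqrt(cin)), b = 0))
}

discForward <- function(params, x) {
  caches <- list(blocks = vector("list", length(params$blocks)),
                 inDims = vector("list", length(params$blocks)))
  h <- x
  for (l in seq_along(params$blocks)) {
    cb <- blockForward(h, params$blocks[[l]])
    caches$blocks[[l]] <- cb
    caches$inDims[[l]] <- dim(cb$y)
    h <- poolForward(cb$y)
  }
  d <- dim(h)
  v <- colMeans(matrix(h, prod(d[1:3]), d[4]))
  lin <- sum(v * params$head$w) + params$head$b
  s <- 1 / (1 + exp(-lin))
  caches$v <- v
  caches$lastDim <- d
  list(score = s, lin = lin, caches = caches)
}

# glin: d(loss)/d(pre-sigmoid linear output); returns grads and input grad
discBackward <- function(params, caches, glin) {
  grads <- list(blocks = vector("list", length(params$blocks)))
  grads$head <- list(w = glin * caches$v, b = glin)
  d <- caches$lastDim
  nv <- prod(d[1:3])
  gv <- glin * params$head$w / nv
  g <- array(rep(gv, each = nv), d)
  for (l in rev(seq_along(params$blocks))) {
    g <- poolBackward(g, caches$inDims[[l]])
    bb <- blockBackward(caches$blocks[[l]], params$blocks[[l]], g)
    grads$blocks[[l]] <- bb$grads
    g <- bb$dx
  }
  list(grads = grads, dx = g)
}

# ---------------------------------------------------------------------------
# Adam over arbitrary nested parameter lists (numeric leaves only; the
# kernel-size marker `k` is skipped).
# ---------------------------------------------------------------------------

paramMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- paramMap2(a[[nm]], b[[nm]], f)
    return(out)
  }
  f(a, b)
}

paramZeroLike <- function(p) {
  if (is.list(p)) return(lapply(p, paramZeroLike))
  p * 0
}

paramAccumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  paramMap2(acc, g, `+`)
}

paramScale <- function(p, s) {
  if (is.list(p)) return(lapply(p, paramScale, s = s))
  p * s
}

# strips the non-trainable kernel-size markers so gradient trees line up
dropKMarkers <- function(p) {
  if (is.list(p)) {
    p[["k"]] <- NULL
    return(lapply(p, dropKMarkers))
  }
  p
}

adamInit <- function(params) {
  tp <- dropKMarkers(params)
  list(m = paramZeroLike(tp), v = paramZeroLike(tp), t = 0)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- paramMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- paramMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- paramMap2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  applyUpdate <- function(p, u) {
    if (is.list(p)) {
      if (is.null(names(p))) {
        for (i in seq_along(p)) p[[i]] <- applyUpdate(p[[i]], u[[i]])
      } else {
        ui <- 0L
        for (nm in names(p)) {
          if (identical(nm, "k")) next
          ui <- ui + 1L
          p[[nm]] <- applyUpdate(p[[nm]], u[[ui]])
        }
      }
      return(p)
    }
    p - u
  }
  list(params = applyUpdate(params, upd), state = state)
}

paramCount <- function(p) {
  if (is.list(p)) {
    p[["k"]] <- NULL
    return(sum(vapply(p, paramCount, numeric(1))))
  }
  length(p)
}
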