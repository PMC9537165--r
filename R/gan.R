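#' @include AllClasses.R nn.R adcm.R utils.R
NULL

#' Build generator and discriminator networks
#'
#' Constructs the parameter sets of the conditional-adversarial pair: a
#' volumetric U-Net generator (encoder-decoder with skip connections,
#' instance normalization and leaky rectifier activations) mapping a
#' single-channel volume at the working shape to a volume of identical
#' shape, and a convolutional discriminator scoring the channel-stacked
#' pair (condition volume, candidate volume) through a sigmoid head. In
#' \code{direct2d} mode both operate on single axial slices (z extent 1);
#' pooling then only acts in-plane.
#'
#' @param cfg a \linkS4class{GANConfig}.
#' @return list with elements \code{generator} and \code{discriminator}.
#' @export
buildModels <- function(cfg) {
  stopifnot(is(cfg, "GANConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  list(generator = initGenerator(cfg, inChannels = 1L),
       discriminator = initDiscriminator(cfg, inChannels = 2L))
}

#' Conditional-adversarial objective
#'
#' The two training losses of the conditional adversarial game with an
#' L2-regression term: the discriminator loss is the negated sum over the
#' batch of \code{log D(cond, target) + log(1 - D(cond, G(cond)))}; the
#' generator loss is the adversarial term \code{sum log(1 - D(cond,
#' G(cond)))} plus \code{lambdaL2} times the mean squared error between
#' the generator output and its target. Scores are clamped away from 0
#' and 1 before taking logs.
#'
#' @param dReal,dFake discriminator scores in (0, 1) on (condition, target)
#'   and (condition, generator output); vectors over the batch.
#' @param genOut,target generator output and regression target (arrays of
#'   identical shape).
#' @param lambdaL2 weight of the regression term, > 0.
#' @return list with \code{lossD}, \code{lossG}, and the \code{adv} and
#'   \code{l2} components of the generator loss.
#' @export
ganObjective <- function(dReal, dFake, genOut, target, lambdaL2 = 1e4) {
  stopifnot(lambdaL2 > 0, length(dReal) == length(dFake),
            all(is.finite(dReal)), all(is.finite(dFake)),
            all(is.finite(genOut)), all(is.finite(target)))
  dr <- pmin(pmax(dReal, 1e-7), 1 - 1e-7)
  df <- pmin(pmax(dFake, 1e-7), 1 - 1e-7)
  lossD <- -sum(log(dr) + log(1 - df))
  adv <- sum(log(1 - df))
  l2 <- lambdaL2 * mean((genOut - target)^2)
  list(lossD = lossD, lossG = adv + l2, adv = adv, l2 = l2)
}

# Resample a PETVolume to the network working shape; in direct2d mode only
# the in-plane axes are resampled and the axial count is preserved.
toWorking <- function(vol, cfg) {
  ws <- cfg@workingShape
  tgt <- if (cfg@mode == "direct2d") c(ws[1], ws[2], dim(vol@voxels)[3]) else ws
  if (identical(dim(vol@voxels), as.integer(tgt))) return(vol)
  resampleVolume(vol, tgt, 1L)
}

# Build the (condition, target) tensors for one pair. Condition is the
# uncorrected volume normalized by its own robust upper quantile; in the
# direct modes the target shares the same scale so the correction stays a
# multiplicative field of order one. direct2d normalizes per slice, so
# every slice is a fully independent sample.
prepareSample <- function(pair, cfg) {
  xw <- toWorking(pair@nasc, cfg)
  s <- robustScale(xw@voxels, cfg@normQuantile)
  x <- xw@voxels / s
  target <- switch(cfg@mode,
    decomposition = voxels(resampleADCM(pair@trueAdcm, dim(x))),
    direct3d = toWorking(pair@asc, cfg)@voxels / s)
  list(x = x, target = target, scale = s)
}

# Per-slice samples for direct2d mode: in-plane working resolution, native
# axial count, per-slice normalization.
prepareSlices <- function(pair, cfg) {
  xw <- toWorking(pair@nasc, cfg)@voxels
  aw <- toWorking(pair@asc, cfg)@voxels
  lapply(seq_len(dim(xw)[3]), function(z) {
    xs <- xw[, , z, drop = FALSE]
    s <- robustScale(xs, cfg@normQuantile)
    list(x = xs / s, target = aw[, , z, drop = FALSE] / s, scale = s)
  })
}

asTensor <- function(a) {
  array(a, c(dim(a)[1:3], 1L))
}

#' Train the correction network
#'
#' Alternating discriminator/generator updates with Adam on prepared
#' (condition, target) samples: in \code{decomposition} mode the target is
#' the true correction map at the working shape; in the direct modes it is
#' the corrected volume (or its axial slices). All stochastic sources
#' (initialization, shuffling) are seeded from the config, so identical
#' configs give identical loss traces. Training aborts with the epoch
#' index if a loss becomes non-finite. With \code{pureL2 = TRUE} the
#' adversarial terms are dropped and training is plain L2 regression.
#'
#' @param pairs list of \linkS4class{PhantomPair}s (>= 2).
#' @param cfg a \linkS4class{GANConfig}.
#' @param verbose print per-epoch losses.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainModel <- function(pairs, cfg, verbose = FALSE) {
  stopifnot(is(cfg, "GANConfig"), length(pairs) >= 2)
  models <- buildModels(cfg)
  G <- models$generator
  D <- models$discriminator
  samples <- if (cfg@mode == "direct2d") {
    do.call(c, lapply(pairs, prepareSlices, cfg = cfg))
  } else {
    lapply(pairs, prepareSample, cfg = cfg)
  }
  stG <- adamInit(G)
  stD <- adamInit(D)
  nE <- cfg@epochs
  trace <- data.frame(epoch = seq_len(nE), lossD = NA_real_,
                      lossGAdv = NA_real_, lossGL2 = NA_real_)
  nS <- length(samples)
  for (ep in seq_len(nE)) {
    ord <- sample.int(nS)
    accD <- accAdv <- accL2 <- 0
    nBatch <- 0L
    i <- 1L
    while (i <= nS) {
      idx <- ord[i:min(i + cfg@batchSize - 1L, nS)]
      i <- i + cfg@batchSize
      nBatch <- nBatch + 1L
      gradG <- NULL
      gradD <- NULL
      bD <- bAdv <- bL2 <- 0
      fakes <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        smp <- samples[[idx[j]]]
        x <- asTensor(smp$x)
        tgt <- asTensor(smp$target)
        gf <- genForward(G, x)
        fakes[[j]] <- list(x = x, tgt = tgt, gf = gf)
        if (!cfg@pureL2) {
          dr <- discForward(D, concatChannels(x, tgt))
          df <- discForward(D, concatChannels(x, gf$y))
          # lossD = -log s_r - log(1 - s_f); d/dlin_r = s_r - 1, d/dlin_f = s_f
          gR <- discBackward(D, dr$caches, dr$score - 1)
          gF <- discBackward(D, df$caches, df$score)
          gradD <- paramAccumulate(gradD, paramMap2(gR$grads, gF$grads, `+`))
          bD <- bD - (log(pmax(dr$score, 1e-7)) + log(pmax(1 - df$score, 1e-7)))
        }
      }
      if (!cfg@pureL2) {
        upd <- adamStep(D, paramScale(gradD, 1 / length(idx)), stD, cfg@lrD)
        D <- upd$params
        stD <- upd$state
      }
      for (j in seq_along(idx)) {
        fk <- fakes[[j]]
        nvox <- length(fk$gf$y)
        gy <- cfg@lambdaL2 * 2 * (fk$gf$y - fk$tgt) / nvox
        l2 <- cfg@lambdaL2 * mean((fk$gf$y - fk$tgt)^2)
        adv <- 0
        if (!cfg@pureL2) {
          df <- discForward(D, concatChannels(fk$x, fk$gf$y))
          # generator adversarial term log(1 - s_f): d/dlin = -s_f
          gI <- discBackward(D, df$caches, -df$score)
          gy <- gy + gI$dx[, , , 2L, drop = FALSE]
          adv <- log(pmax(1 - df$score, 1e-7))
        }
        gradG <- paramAccumulate(gradG, genBackward(G, fk$gf$caches, gy))
        bAdv <- bAdv + adv
        bL2 <- bL2 + l2
      }
      upd <- adamStep(G, paramScale(gradG, 1 / length(idx)), stG, cfg@lrG)
      G <- upd$params
      stG <- upd$state
      accD <- accD + bD / length(idx)
      accAdv <- accAdv + bAdv / length(idx)
      accL2 <- accL2 + bL2 / length(idx)
    }
    trace$lossD[ep] <- accD / nBatch
    trace$lossGAdv[ep] <- accAdv / nBatch
    trace$lossGL2[ep] <- accL2 / nBatch
    if (!all(is.finite(unlist(trace[ep, -1])))) {
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    }
    if (verbose) {
      message(sprintf("epoch %d: lossD %.4f, adv %.4f, L2 %.4f", ep,
                      trace$lossD[ep], trace$lossGAdv[ep], trace$lossGL2[ep]))
    }
  }
  new("TrainedModel", generator = G, discriminator = D, config = cfg,
      lossTrace = trace)
}

#' Predict a correction from an uncorrected volume
#'
#' In \code{decomposition} mode the generator output is an
#' \linkS4class{ADCMap} (ratios clipped to [0, rMax]), upsampled back to
#' the native grid of the input — apply it with \code{\link{applyADCM}} to
#' obtain the corrected image while preserving the native texture. In the
#' direct modes the corrected activity volume is returned directly
#' (\code{direct2d} processes each axial slice independently and
#' restacks).
#'
#' @param object a \linkS4class{TrainedModel}.
#' @param nasc uncorrected \linkS4class{PETVolume}.
#' @return An \linkS4class{ADCMap} (decomposition mode) or a corrected
#'   \linkS4class{PETVolume} (direct modes).
#' @aliases predict,TrainedModel-method
#' @export
setMethod("predict", "TrainedModel", function(object, nasc) {
  cfg <- object@config
  stopifnot(is(nasc, "PETVolume"))
  d0 <- dim(nasc@voxels)
  xw <- toWorking(nasc, cfg)
  if (cfg@mode == "direct2d") {
    # each axial slice is processed independently with per-slice scaling
    xv <- xw@voxels
    nz <- dim(xv)[3]
    out <- array(0, dim(xv))
    for (z in seq_len(nz)) {
      xs <- xv[, , z, drop = FALSE]
      sz <- robustScale(xs, cfg@normQuantile)
      y <- genForward(object@generator, asTensor(xs / sz))$y
      out[, , z] <- y[, , 1L, 1L] * sz
    }
    xn <- xv
    s <- 1
  } else {
    s <- robustScale(xw@voxels, cfg@normQuantile)
    xn <- xw@voxels / s
    out <- genForward(object@generator, asTensor(xn))$y
    out <- array(out, dim(xn))
  }
  if (cfg@mode == "decomposition") {
    out <- pmin(pmax(out, 0), cfg@rMax)
    ratio <- PETVolume(array(out, dim(xn)), xw@spacing, "ratio")
    rmap <- new("ADCMap", ratio = ratio, epsilon = cfg@epsilon,
                provenance = "predicted")
    if (!identical(dim(xn), d0)) rmap <- resampleADCM(rmap, d0, 1L)
    rmap
  } else {
    vol <- PETVolume(array(pmax(out, 0) * s, dim(xn)), xw@spacing, "activity")
    if (!identical(dim(xn), d0)) vol <- resampleVolume(vol, d0, 1L)
    vol
  }
})

#' End-to-end correction of an uncorrected volume
#'
#' Convenience wrapper: in decomposition mode predicts the correction map
#' and applies it on the native grid; in direct modes returns the
#' predicted corrected volume.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param nasc uncorrected \linkS4class{PETVolume}.
#' @return Corrected \linkS4class{PETVolume}.
#' @export
correctVolume <- function(model, nasc) {
  out <- predict(model, nasc)
  if (is(out, "ADCMap")) applyADCM(nasc, out) else out
}

#' Normalized RMSE of a predicted correction map against the truth
#'
#' Working-shape NRMSE (RMSE over the reference range) of a predicted map
#' against the true map of a pair; the constant-unity map is the natural
#' no-correction baseline for this quantity.
#'
#' @param model a \linkS4class{TrainedModel} in decomposition mode.
#' @param pair a \linkS4class{PhantomPair}.
#' @return Scalar NRMSE.
#' @export
adcmPredictionNRMSE <- function(model, pair) {
  cfg <- model@config
  stopifnot(cfg@mode == "decomposition")
  predMap <- predict(model, pair@nasc)
  truth <- voxels(resampleADCM(pair@trueAdcm, cfg@workingShape))
  predW <- voxels(resampleADCM(predMap, cfg@workingShape))
  rng <- diff(range(truth))
  sqrt(mean((predW - truth)^2)) / rng
}
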