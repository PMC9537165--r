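#' @include AllClasses.R phantom.R gan.R metrics.R io.R utils.R
NULL

#' Default desk-scale experiment configuration
#'
#' Configuration of the one-command experiment reproducing the package's
#' study design at desk scale: train the three correction modes on one
#' phantom family ("one tracer on one scanner"), then test on the in-domain
#' family and on scanner-shifted and tracer-shifted held-out families.
#' Returned as a plain nested list so it can be serialized to YAML and
#' hashed into the run manifest.
#'
#' @param seed global seed; every stochastic component derives a named
#'   sub-stream seed from it.
#' @param nTrain,nTest number of training and per-family test phantoms.
#' @param modes correction modes to train.
#' @param phantom named list of \code{\link{defaultPhantomSpec}} arguments.
#' @param gan named list of \code{\link{GANConfig}} arguments shared by all
#'   modes (mode and seed are filled in per mode).
#' @return Nested configuration list.
#' @export
defaultExperimentConfig <- function(seed = 1L, nTrain = 8L, nTest = 5L,
                                    modes = c("decomposition", "direct3d",
                                              "direct2d"),
                                    phantom = list(shape = 32L, spacing = 8,
                                                   nAngles = 4L),
                                    gan = list(workingShape = 16L,
                                               genDepth = 2L, genChannels = 6L,
                                               discDepth = 2L,
                                               discChannels = 4L,
                                               epochs = 8L)) {
  list(seed = as.integer(seed), nTrain = as.integer(nTrain),
       nTest = as.integer(nTest), modes = modes, phantom = phantom,
       gan = gan, shiftTracerProfile = "liver-avid", epsilon = 1)
}

#' Read an experiment configuration from YAML
#'
#' Missing fields fall back to \code{\link{defaultExperimentConfig}}.
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
readExperimentConfig <- function(path) {
  x <- yaml::read_yaml(path)
  base <- defaultExperimentConfig()
  base[names(x)] <- x
  base
}

#' Run the full train/shift/evaluate experiment
#'
#' Simulates a training family and three test families (in-domain,
#' scanner-shifted, tracer-shifted), trains every requested mode, corrects
#' every test volume with every model, and writes per-volume global
#' metrics, VOI/MAPE summaries, paired comparisons between modes, and a
#' manifest of every seed to \code{outDir}. Re-running with the same
#' configuration reproduces every output byte-for-byte.
#'
#' @param cfg configuration list from
#'   \code{\link{defaultExperimentConfig}} or
#'   \code{\link{readExperimentConfig}}.
#' @param outDir output directory.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the trained models, the per-family
#'   metric tables and the paired-test table.
#' @export
runExperiment <- function(cfg = defaultExperimentConfig(), outDir,
                          verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  res <- tryCatch({
    phArgs <- cfg$phantom
    phArgs$seed <- substreamSeed(cfg$seed, "base-spec")
    baseSpec <- do.call(defaultPhantomSpec, phArgs)

    stage <- "simulate"
    say("simulating %d training and 3 x %d test phantoms", cfg$nTrain,
        cfg$nTest)
    train <- makeDataset(baseSpec, cfg$nTrain, "none",
                         substreamSeed(cfg$seed, "train"),
                         epsilon = cfg$epsilon)
    fams <- list(
      "test-id" = makeDataset(baseSpec, cfg$nTest, "none",
                              substreamSeed(cfg$seed, "test-id"),
                              epsilon = cfg$epsilon),
      "test-scanner" = makeDataset(baseSpec, cfg$nTest, "scanner",
                                   substreamSeed(cfg$seed, "test-scanner"),
                                   epsilon = cfg$epsilon),
      "test-tracer" = makeDataset(baseSpec, cfg$nTest, "tracer",
                                  substreamSeed(cfg$seed, "test-tracer"),
                                  tracerProfile = cfg$shiftTracerProfile,
                                  epsilon = cfg$epsilon))

    stage <- "train"
    models <- list()
    for (mode in cfg$modes) {
      say("training mode %s", mode)
      ganArgs <- cfg$gan
      ganArgs$mode <- mode
      ganArgs$seed <- substreamSeed(cfg$seed, paste0("train-", mode))
      ganArgs$epsilon <- cfg$epsilon
      models[[mode]] <- trainModel(train, do.call(GANConfig, ganArgs))
    }

    stage <- "evaluate"
    metricRows <- list()
    reports <- list()
    for (fam in names(fams)) {
      pairs <- fams[[fam]]
      refs <- lapply(pairs, function(p) p@asc)
      vois <- voisFromSpec(pairs[[1]]@spec)
      for (mode in cfg$modes) {
        say("evaluating %s on %s", mode, fam)
        preds <- lapply(pairs, function(p) correctVolume(models[[mode]],
                                                         p@nasc))
        rep <- evaluateVolumes(preds, refs, vois)
        reports[[paste(mode, fam, sep = ".")]] <- rep
        g <- rep@global
        g$mode <- mode
        g$family <- fam
        metricRows[[length(metricRows) + 1L]] <- g
      }
    }
    metrics <- do.call(rbind, metricRows)

    stage <- "compare"
    tests <- list()
    others <- setdiff(cfg$modes, "decomposition")
    nComp <- max(1L, length(others))
    if ("decomposition" %in% cfg$modes && length(others) &&
        cfg$nTest >= 3L) {
      for (fam in names(fams)) {
        a <- metrics$nrmse[metrics$mode == "decomposition" &
                           metrics$family == fam]
        for (om in others) {
          b <- metrics$nrmse[metrics$mode == om & metrics$family == fam]
          pc <- pairedComparison(a, b, nComparisons = nComp)
          tests[[length(tests) + 1L]] <- data.frame(
            family = fam, comparison = paste0("decomposition-vs-", om),
            metric = "nrmse", t = pc$t, p = pc$p, df = pc$df,
            significant = pc$significant, exactTie = pc$exactTie)
        }
      }
    }
    testTab <- if (length(tests)) do.call(rbind, tests) else data.frame()

    stage <- "write"
    utils::write.csv(metrics, file.path(outDir, "global_metrics.csv"),
                     row.names = FALSE)
    if (nrow(testTab))
      utils::write.csv(testTab, file.path(outDir, "paired_tests.csv"),
                       row.names = FALSE)
    med <- stats::aggregate(nrmse ~ mode + family, metrics, stats::median)
    utils::write.csv(med, file.path(outDir, "median_nrmse.csv"),
                     row.names = FALSE)
    losses <- do.call(rbind, lapply(names(models), function(m) {
      tr <- models[[m]]@lossTrace
      tr$mode <- m
      tr
    }))
    utils::write.csv(losses, file.path(outDir, "loss_traces.csv"),
                     row.names = FALSE)
    manifest <- list(
      seed = cfg$seed,
      configHash = digestConfig(cfg),
      packageVersion = as.character(utils::packageVersion("petdecomp")),
      rVersion = R.version.string,
      substreams = list(
        baseSpec = substreamSeed(cfg$seed, "base-spec"),
        train = substreamSeed(cfg$seed, "train"),
        testId = substreamSeed(cfg$seed, "test-id"),
        testScanner = substreamSeed(cfg$seed, "test-scanner"),
        testTracer = substreamSeed(cfg$seed, "test-tracer"),
        models = lapply(stats::setNames(cfg$modes, cfg$modes), function(m)
          substreamSeed(cfg$seed, paste0("train-", m)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(models = models, metrics = metrics, tests = testTab,
         median = med, reports = reports)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# config hash for the manifest: stable serialization -> FNV fold
digestConfig <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 16777619) %% 2147483647
    h <- (h + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
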