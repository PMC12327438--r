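# End-to-end orchestration: data -> full-data fit -> plug-in -> AXE (and/or
# manual CV) -> LRR report, with all artifacts stamped with the config hash
# and seed.

logLine <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

resolveData <- function(cfg) {
  if (!is.null(cfg$dataset) && is.character(cfg$dataset)) {
    readDataset(cfg$dataset, cfg)
  } else if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    if (identical(cfg$family, "gaussian")) {
      simulateLmm(s$J, s$cluster_sizes,
                  beta1 = if (is.null(s$beta1)) c(1, 0.5) else unlist(s$beta1),
                  sigma = if (is.null(s$sigma)) 1 else s$sigma,
                  phi = if (is.null(s$phi)) 1 else s$phi,
                  seed = cfg$seed)$data
    } else {
      simulateGlmm(s$J, s$cluster_sizes,
                   beta1 = if (is.null(s$beta1)) c(0, 0.5) else unlist(s$beta1),
                   sigma = if (is.null(s$sigma)) 1 else s$sigma,
                   family = cfg$family,
                   trials = if (is.null(s$trials)) 1 else s$trials,
                   seed = cfg$seed)$data
    }
  } else stop("config needs either a dataset path or a simulate descriptor")
}

#' Run the cross-validation pipeline described by a configuration
#'
#' Stages: resolve the data (CSV or simulation descriptor), run the full-data
#' sampler (or take fixed plug-in values), compute AXE predictions for every
#' fold, optionally run manual cross-validation (on all folds, or on the
#' AXE+ subset) and write the LRR report.
#'
#' @param cfg configuration from [readRunConfig()] (or an equivalent list).
#' @param outDir output directory (created if missing).
#' @param seed overrides the config seed when non-NULL.
#' @return invisibly, a list with the in-memory artifacts (data, plugin,
#'   axe, mcv, report, paths).
#' @export
runCv <- function(cfg, outDir, seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(cfg)
  logCon <- file(file.path(outDir, "run.log"), open = "wt")
  on.exit(close(logCon))
  logLine(logCon, "start", sprintf("config %s seed %d", hash, cfg$seed))

  data <- resolveData(cfg)
  logLine(logCon, "data", sprintf("%d rows, %d clusters, family %s",
                                  nObs(data), nClusters(data), data@family))
  prior <- priorFromConfig(cfg, data)
  plan <- foldPlan(data, kind = cfg$folds)

  sp <- cfg$sampler
  if (cfg$plugin$source == "fixed") {
    plugin <- variancePlugin(phiHat = cfg$plugin$phi, data = data,
                             sigma = setNames(rep(cfg$plugin$sigma,
                                                  nlevels(data@termId)),
                                              levels(data@termId)))
    fullFitSummary <- NULL
  } else {
    fullFitSummary <- posteriorFit(data, prior, M = sp$M, burn = sp$burn,
                                   chains = sp$chains,
                                   seed = mixSeed(cfg$seed, 11L))
    plugin <- posteriorPlugin(fullFitSummary, prior, data)
  }
  logLine(logCon, "plugin", sprintf("phiHat %.4g (%s)", plugin@phiHat,
                                    plugin@provenance))
  pluginToJson(plugin, file.path(outDir, "plugin.json"))
  if (!is.null(fullFitSummary))
    summaryToJson(fullFitSummary, file.path(outDir, "posterior.json"))

  axe <- if (data@family == "gaussian") {
    axePredictLmm(data, plan, plugin, prior)
  } else {
    fam <- linkFamily(dataLinkName(data))
    fullFit <- iwlsFit(data, penaltyFromPlugin(prior, plugin), fam)
    axePredictGlmm(data, plan, plugin, prior, fullFit,
                   refineIters = cfg$refine_iters)
  }
  logLine(logCon, "axe", sprintf("%d folds predicted", nFolds(plan)))

  mcv <- NULL; report <- NULL
  if (cfg$method %in% c("mcv", "both")) {
    if (isTRUE(cfg$axe_plus$enabled)) {
      report <- axePlus(data, plan, prior, plugin,
                        kFolds = cfg$axe_plus$k_folds,
                        delta = cfg$axe_plus$delta,
                        policy = cfg$axe_plus$policy, seed = cfg$seed,
                        M = sp$M, burn = sp$burn, chains = sp$chains,
                        refineIters = cfg$refine_iters)
      logLine(logCon, "axe+", report@decision)
    } else {
      mcv <- mcvPredict(data, plan, prior, M = sp$M, burn = sp$burn,
                        chains = sp$chains, seed = mixSeed(cfg$seed, 13L))
      lrrs <- lrr(axe, mcv, data, plan)
      report <- buildLrrReport(lrrs, sort(unique(mcv@foldId)),
                               cfg$axe_plus$delta, nFolds(plan))
      logLine(logCon, "mcv", sprintf("mean LRR %.4g", report@meanLrr))
    }
    reportToJson(report, file.path(outDir, "lrr.json"))
    utils::write.csv(report@curve, file.path(outDir, "lrr_curve.csv"),
                     row.names = FALSE)
  }

  pred <- as.data.frame(axe)
  if (!is.null(mcv)) pred <- rbind(pred, as.data.frame(mcv))
  pred$config <- hash
  pred$seed <- cfg$seed
  num <- vapply(pred, is.numeric, TRUE)
  pred[num] <- lapply(pred[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(pred, file.path(outDir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  logLine(logCon, "done", "artifacts written")
  invisible(list(data = data, prior = prior, plan = plan, plugin = plugin,
                 axe = axe, mcv = mcv, report = report, hash = hash,
                 outDir = outDir))
}
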