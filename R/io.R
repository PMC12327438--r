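# CSV / YAML / JSON surface.
#
# Datasets travel as plain CSV (comma-separated, header row, '.' decimal):
# a response column, covariate columns, a cluster column and an optional
# trials/exposure column.  Run configuration is YAML; plug-ins, posterior
# summaries and LRR reports serialize to JSON.

#' Read a run configuration from YAML
#'
#' Expected top-level fields: \code{dataset} (path, or a \code{simulate}
#' descriptor), \code{family}, \code{response}, \code{covariates} (character
#' vector; "intercept" adds a column of ones), \code{cluster},
#' \code{trials} (optional column name), \code{prior} (fields
#' \code{sigma_family}, \code{scale_prior}, \code{phi_prior}, optional
#' \code{cinv_diag}), \code{plugin} (\code{source}: "mcmc" or "fixed" with
#' \code{sigma}/\code{phi}), \code{folds} ("lco" or "loo"), \code{sampler}
#' (\code{M}, \code{burn}, \code{chains}), \code{axe_plus}
#' (\code{enabled}, \code{k_folds}, \code{delta}, \code{policy}),
#' \code{method} ("axe", "mcv" or "both"), \code{refine_iters}, \code{seed}.
#'
#' @param path YAML file path.
#' @return named list (class "axecvConfig").
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(family = "gaussian", folds = "lco", method = "both",
                   refine_iters = 0L, seed = 1L,
                   sampler = list(M = 2000L, burn = 1000L, chains = 4L),
                   plugin = list(source = "mcmc"),
                   axe_plus = list(enabled = FALSE, k_folds = 3L,
                                   delta = 0.25, policy = "largest"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$sampler))
    if (is.null(cfg$sampler[[nm]])) cfg$sampler[[nm]] <- defaults$sampler[[nm]]
  for (nm in names(defaults$axe_plus))
    if (is.null(cfg$axe_plus[[nm]])) cfg$axe_plus[[nm]] <- defaults$axe_plus[[nm]]
  if (!is.null(cfg$axe_plus$delta) && cfg$axe_plus$delta <= 0)
    stop("axe_plus delta must be positive")
  if (!cfg$plugin$source %in% c("mcmc", "fixed"))
    stop("plugin source must be 'mcmc' or 'fixed'")
  class(cfg) <- "axecvConfig"
  cfg
}

#' Semantic hash of a configuration
#'
#' Canonicalizes the parsed configuration (sorted keys, JSON encoding) so
#' that whitespace and key order do not change the hash.
#'
#' @param cfg configuration list from [readRunConfig()].
#' @return character md5 hash.
#' @export
configHash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Build a PriorSpec from a configuration
#' @param cfg configuration list.
#' @param data the [RegressionData-class] the prior must match.
#' @param adjacency optional CAR adjacency.
#' @export
priorFromConfig <- function(cfg, data, adjacency = NULL) {
  pr <- cfg$prior
  if (is.null(pr)) pr <- list()
  sigmaFamily <- if (!is.null(pr$sigma_family)) pr$sigma_family else "iid_by_term"
  p1 <- ncol(data@Xfixed)
  Cinv <- if (!is.null(pr$cinv_diag)) diag(rep(pr$cinv_diag, p1), p1) else NULL
  parsePr <- function(x, fallback) {
    if (is.null(x)) return(fallback)
    x
  }
  ht <- list(dist = "half_t", nu = 3, scale = 2.5)
  terms <- if (sigmaFamily == "car") "tau" else levels(data@termId)
  scalePriors <- setNames(rep(list(parsePr(pr$scale_prior, ht)),
                              length(terms)), terms)
  priorSpec(P1 = p1, Cinv = Cinv, sigmaFamily = sigmaFamily,
            adjacency = adjacency, scalePriors = scalePriors,
            phiPrior = parsePr(pr$phi_prior, ht), terms = terms)
}

#' Read a dataset CSV into a RegressionData
#'
#' Random-effect columns are built from the cluster column: one indicator
#' column per cluster (iid random intercepts).
#'
#' @param path CSV path.
#' @param cfg configuration list naming \code{response}, \code{covariates},
#'   \code{cluster}, optional \code{trials}, and \code{family}.
#' @return A [RegressionData-class].
#' @export
readDataset <- function(path, cfg) {
  if (!file.exists(path)) stop(sprintf("dataset '%s' not found", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(cfg$response, cfg$cluster, setdiff(cfg$covariates, "intercept"))
  if (!is.null(cfg$trials)) need <- c(need, cfg$trials)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("dataset is missing column(s): %s", paste(miss, collapse = ", ")))
  y <- df[[cfg$response]]
  if (!is.numeric(y)) stop(sprintf("response column '%s' is not numeric", cfg$response))
  cl <- df[[cfg$cluster]]
  if (anyNA(cl) || any(cl == "")) stop("empty cluster labels in cluster column")
  Xf <- NULL
  for (cv in cfg$covariates) {
    col <- if (cv == "intercept") rep(1, nrow(df)) else df[[cv]]
    Xf <- cbind(Xf, col)
  }
  colnames(Xf) <- cfg$covariates
  trials <- if (!is.null(cfg$trials)) df[[cfg$trials]] else rep(1, nrow(df))
  if (cfg$family == "binomial" && is.null(cfg$trials))
    stop("binomial family requires a trials column in the configuration")
  clusterId <- factor(cl)
  regressionData(y, Xf, clusterIndicators(clusterId), clusterId,
                 family = cfg$family, trials = trials)
}

#' Write a RegressionData to CSV
#'
#' Columns: y, the fixed covariates, cluster, trials.  Values are written at
#' 17 significant digits so a read round-trips exactly.
#'
#' @param data a [RegressionData-class].
#' @param path output CSV path.
#' @export
writeDataset <- function(data, path) {
  df <- data.frame(y = data@y, check.names = FALSE)
  if (ncol(data@Xfixed)) {
    Xf <- as.data.frame(data@Xfixed)
    names(Xf) <- colnames(data@Xfixed)
    df <- cbind(df, Xf)
  }
  df$cluster <- as.character(data@clusterId)
  df$trials <- data@trials
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pluginToJson <- function(plugin, path) {
  jsonlite::write_json(list(phi_hat = plugin@phiHat,
                            provenance = plugin@provenance,
                            params = plugin@params,
                            sigma_inv = plugin@SigmaInv),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

reportToJson <- function(report, path) {
  jsonlite::write_json(list(lrr = report@lrr, fold_id = report@foldId,
                            mean_lrr = report@meanLrr, sd_lrr = report@sdLrr,
                            auc_raw = report@aucRaw,
                            auc_normalized = report@aucNormalized,
                            delta = report@delta, decision = report@decision,
                            n_non_finite = report@nNonFinite),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Export a posterior summary to JSON
#' @param summary a [PosteriorSummary-class].
#' @param path output path.
#' @export
summaryToJson <- function(summary, path) {
  jsonlite::write_json(list(beta_mean = summary@betaMean,
                            beta_mcse = summary@betaMcse,
                            scale_mean = as.list(summary@scaleMean),
                            scale_mcse = as.list(summary@scaleMcse),
                            settings = summary@settings),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
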