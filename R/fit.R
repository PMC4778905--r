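#' Run configuration for an AIS fit
#'
#' Bundles the sampler settings; the defaults (`J = 512` temperatures,
#' `I = 32` trajectories, 5th-order schedule, step size `h = 0.5`,
#' `n_boot = 1000`) are the package's standard operating point.
#'
#' @param J Number of schedule intervals.
#' @param I Number of trajectories.
#' @param order Schedule order.
#' @param h Langevin step size.
#' @param seed Root seed.
#' @param n_boot Bootstrap resamples for evidence confidence intervals.
#' @return Object of class `run_config`.
#' @export
run_config <- function(J = 512, I = 32, order = 5, h = 0.5, seed = 1,
                       n_boot = 1000) {
  structure(list(J = J, I = I, order = order, h = h, seed = seed,
                 n_boot = n_boot),
            class = "run_config")
}

#' Fit a model by annealed importance sampling
#'
#' High-level driver: runs AIS, computes the evidence estimate with its
#' bootstrap interval, and the standard diagnostics bundle.
#'
#' @param model A [bayes_model()].
#' @param data An [ais_dataset()].
#' @param config A [run_config()].
#' @param truth Optional generating parameters for RMSE reporting
#'   (defaults to any truth stored on the dataset).
#' @return Object of class `ais_fit` with `result` (the [run_ais()]
#'   output), `evidence`, `diagnostics`, `posterior_mean` and `config`.
#' @export
fit_ais <- function(model, data, config = run_config(), truth = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(truth) && !is.null(data$truth$w) &&
      length(data$truth$w) == model$n_params) {
    truth <- data$truth$w
  }
  schedule <- make_schedule(config$J, config$order)
  result <- run_ais(model, data, schedule, I = config$I,
                    seed = config$seed, h = config$h)
  structure(
    list(result = result,
         evidence = log_evidence(result, n_boot = config$n_boot),
         diagnostics = ais_diagnostics(result, truth = truth),
         posterior_mean = posterior_mean(result),
         config = config, model_name = model$name),
    class = "ais_fit"
  )
}

#' @export
print.ais_fit <- function(x, ...) {
  cat("AIS fit of", x$model_name, " (I =", x$config$I, ", J =",
      x$config$J, ")\n")
  print(x$evidence)
  cat("posterior mean:", format(x$posterior_mean, digits = 4), "\n")
  cat("weight entropy:", format(x$diagnostics$entropy_bits, digits = 3),
      "bits; I_q =", x$diagnostics$I_q, "\n")
  cat("acceptance: a_high =", format(x$diagnostics$a_high, digits = 3),
      " a_low =", format(x$diagnostics$a_low, digits = 3), "\n")
  invisible(x)
}

#' Compare two AIS fits by their log Bayes factor
#'
#' Log Bayes factor `log_z_1 - log_z_2` with a bootstrap confidence
#' interval obtained by resampling trajectories of both runs within each
#' bootstrap iteration (paired resamples when the runs have the same
#' number of trajectories).
#'
#' @param fit1,fit2 [fit_ais()] results (or [run_ais()] results) fitted to
#'   the same dataset.
#' @param n_boot Number of bootstrap resamples.
#' @return List with `log_bf`, `ci_low`, `ci_high`.
#' @export
compare_evidence <- function(fit1, fit2, n_boot = 1000) {
  lv1 <- if (inherits(fit1, "ais_fit")) fit1$result$log_v else fit1$log_v
  lv2 <- if (inherits(fit2, "ais_fit")) fit2$result$log_v else fit2$log_v
  est <- log_mean_exp(lv1) - log_mean_exp(lv2)
  n1 <- length(lv1); n2 <- length(lv2)
  paired <- n1 == n2
  boots <- vapply(seq_len(n_boot), function(b) {
    i1 <- sample.int(n1, n1, replace = TRUE)
    i2 <- if (paired) i1 else sample.int(n2, n2, replace = TRUE)
    log_mean_exp(lv1[i1]) - log_mean_exp(lv2[i2])
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.05, 0.95), names = FALSE)
  list(log_bf = est, ci_low = ci[1], ci_high = ci[2])
}

#' Write AIS run artifacts to a directory
#'
#' Writes `samples.csv` (one row per trajectory), `weights.csv` (`log_v`,
#' `q`), `acceptance.csv` (step, inverse temperature, per-trajectory
#' acceptance rate), `evidence.json` and `diagnostics.json`.  Every JSON
#' artifact embeds the resolved run configuration for provenance.
#'
#' @param fit An [fit_ais()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ais_run <- function(fit, dir) {
  stopifnot(inherits(fit, "ais_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- fit$result
  utils::write.csv(as.data.frame(res$samples),
                   file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(data.frame(log_v = res$log_v, q = res$q),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(data.frame(step = seq_along(res$accept_beta),
                              beta = res$accept_beta,
                              rate = colMeans(res$acceptance)),
                   file.path(dir, "acceptance.csv"), row.names = FALSE)
  cfg <- unclass(fit$config)
  cfg$model <- fit$model_name
  jsonlite::write_json(
    list(log_z = fit$evidence$log_z, ci_low = fit$evidence$ci_low,
         ci_high = fit$evidence$ci_high, n_boot = fit$evidence$n_boot,
         config = cfg),
    file.path(dir, "evidence.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(fit$diagnostics, list(config = cfg)),
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
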