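#' Synthetic data: conjugate linear regression
#'
#' Generates the canonical linear-regression test problem: `p = 7`
#' orthonormal DCT regressors over `N = 20` time points, coefficients
#' drawn from the zero-mean, variance-10 prior, additive Gaussian noise
#' with SD `sigma = 0.2`.  The reduced design drops the last regressor.
#'
#' @param seed Integer seed.
#' @param N,p Design size (defaults 20 x 7).
#' @param sigma Noise SD (default 0.2).
#' @param prior_var Prior variance per coefficient (default 10).
#' @return List with `data` (an [ais_dataset()] carrying the truth),
#'   `truth` (generating coefficients), `model` (full [linear_model()]) and
#'   `model_reduced` (first `p - 1` regressors).
#' @export
gen_linear <- function(seed, N = 20, p = 7, sigma = 0.2, prior_var = 10) {
  set.seed(seed)
  X <- dct_basis(N, p)
  prior <- gaussian_prior(rep(0, p), diag(1 / prior_var, p))
  beta <- prior_sample(prior)
  y <- drop(X %*% beta) + stats::rnorm(N, sd = sigma)
  data <- ais_dataset(y = y, X = X, noise_sd = sigma, truth = list(w = beta))
  list(data = data, truth = beta,
       model = linear_model(X, sigma, prior),
       model_reduced = linear_model(X[, -p, drop = FALSE], sigma,
                                    gaussian_prior(rep(0, p - 1),
                                                   diag(1 / prior_var,
                                                        p - 1))))
}

#' Synthetic data: multimodal squared-coefficient regression
#'
#' Two DCT regressors with coefficients \eqn{\beta_i = w_i^2} at the truth
#' `w = (2, 2)` and noise SD 0.5.  By construction the data are identical
#' whichever sign combination of `w` generated them, so the posterior has
#' four symmetric modes.
#'
#' @param seed Integer seed.
#' @param N Number of time points (default 20).
#' @param sigma Noise SD (default 0.5).
#' @param w_true Generating parameters (default `c(2, 2)`).
#' @param prior_var Prior variance per parameter (default 10).
#' @return List with `data`, `truth` and `model` (a [squared_model()]).
#' @export
gen_squared <- function(seed, N = 20, sigma = 0.5, w_true = c(2, 2),
                        prior_var = 10) {
  set.seed(seed)
  X <- dct_basis(N, 2)
  y <- squared_predict(w_true, X) + stats::rnorm(N, sd = sigma)
  data <- ais_dataset(y = y, X = X, noise_sd = sigma,
                      truth = list(w = w_true))
  prior <- gaussian_prior(rep(0, 2), diag(1 / prior_var, 2))
  list(data = data, truth = w_true, model = squared_model(X, sigma, prior))
}

#' Synthetic data: exponential approach-to-limit
#'
#' Voltage ramp generated at \eqn{V_a = 30}, \eqn{\tau = 8} with unit
#' observation noise variance on a unit-step time grid.
#'
#' @param seed Integer seed.
#' @param t Time grid (default `1:20`).
#' @param Va,tau Generating physiological values.
#' @param sigma Noise SD (default 1).
#' @param from_prior If `TRUE`, draw the generating parameters from the
#'   prior instead of using `Va`/`tau`.
#' @param ... Passed to [approach_model()] (e.g. `swap_prior_mean`).
#' @return List with `data`, `truth` (on the `w = (log tau, log Va)`
#'   scale), `model` (full) and `model_reduced`.
#' @export
gen_approach <- function(seed, t = 1:20, Va = 30, tau = 8, sigma = 1,
                         from_prior = FALSE, ...) {
  set.seed(seed)
  model <- approach_model(t = t, sigma = sigma, ...)
  w_true <- if (from_prior) prior_sample(model$prior) else c(log(tau), log(Va))
  y <- approach_predict(w_true, t) + stats::rnorm(length(t), sd = sigma)
  data <- ais_dataset(y = y, t = t, noise_sd = sigma,
                      truth = list(w = w_true))
  list(data = data, truth = w_true, model = model,
       model_reduced = approach_model(t = t, sigma = sigma, reduced = TRUE,
                                      ...))
}

#' Synthetic data: two-region neural mass model
#'
#' Integrates the two-region model at the canonical generating truth
#' (strong forward and backward connections, `w1 = w2 = 1`, all other
#' parameters 0) and adds IID Gaussian observation noise to the pyramidal
#' potential of each region.  The noise SD is either given directly
#' (`sigma_s`, default 0.01) or derived from a signal-to-noise ratio:
#' `snr = sd(noise-free region-2 signal) / sigma_s`.
#'
#' @param seed Integer seed.
#' @param sigma_s Observation noise SD per region; ignored when `snr` is
#'   given.
#' @param snr Optional signal-to-noise ratio in region 2.
#' @param full If `FALSE`, generate from the reduced model (no backward
#'   connection).
#' @param config An [nmm_config()] (its `sigma_s` is overridden by the
#'   resolved noise SD).
#' @param w_true Generating parameter vector (default `c(1, 1, 0, ..., 0)`).
#' @return List with `data` (2 x N_t response matrix dataset), `truth`,
#'   `model` (full-structure [nmm_model()] with the resolved noise SD),
#'   `model_reduced`, `config`, `sigma_s` and `snr` (the realised ratio).
#' @export
gen_nmm <- function(seed, sigma_s = 0.01, snr = NULL, full = TRUE,
                    config = nmm_config(),
                    w_true = c(1, 1, rep(0, 8))) {
  set.seed(seed)
  traj <- integrate_nmm(w_true, config, backward = full)
  if (is_eval_failure(traj)) {
    stop("generating parameters failed to integrate")
  }
  signal_sd <- stats::sd(traj$yhat[config$regions, ])
  if (!is.null(snr)) {
    stopifnot(snr > 0)
    sigma_s <- signal_sd / snr
  }
  config$sigma_s <- rep(sigma_s, length.out = config$regions)
  y <- traj$yhat +
    matrix(stats::rnorm(length(traj$yhat), sd = sigma_s),
           nrow = nrow(traj$yhat))
  data <- ais_dataset(y = y, t = config$t, noise_sd = config$sigma_s,
                      truth = list(w = w_true, full = full))
  list(data = data, truth = w_true,
       model = nmm_model(config, backward = TRUE),
       model_reduced = nmm_model(config, backward = FALSE),
       config = config, sigma_s = sigma_s, snr = signal_sd / sigma_s)
}
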