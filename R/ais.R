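#' Geometric annealing schedule
#'
#' Inverse-temperature ladder \eqn{\beta_j = (j/J)^{order}}, `j = 0..J`,
#' running from the prior (\eqn{\beta_0 = 0}) to the posterior
#' (\eqn{\beta_J = 1}).  A fifth-order schedule concentrates temperatures
#' near the prior end, where the tempered density changes fastest, and is
#' the package default throughout.
#'
#' @param J Number of ladder intervals (so `J + 1` temperatures).
#' @param order Power of the schedule (default 5).
#' @return Object of class `annealing_schedule` with elements `betas`
#'   (length `J + 1`), `J` and `order`.
#' @examples
#' make_schedule(4)$betas
#' @export
make_schedule <- function(J, order = 5) {
  if (J < 1) stop("J must be at least 1")
  if (order < 1) stop("order must be at least 1")
  structure(
    list(betas = (0:J / J)^order, J = as.integer(J), order = order),
    class = "annealing_schedule"
  )
}

#' @export
print.annealing_schedule <- function(x, ...) {
  cat("<annealing_schedule> J =", x$J, "order =", x$order, "\n")
  invisible(x)
}

#' Run a single annealing trajectory
#'
#' Draws the initial point from the prior, then applies one tempered
#' Langevin transition per intermediate temperature (the kernel at
#' \eqn{\beta_{j-1}} produces the point credited to rung `j`), accumulating
#' the log importance weight
#' \eqn{\log v = \sum_{j=1}^{J} (\beta_j - \beta_{j-1}) \log p(y | w_j)}.
#' The trajectory endpoint is a draw whose weighted ensemble targets the
#' posterior.
#'
#' @param model A [bayes_model()].
#' @param data Dataset.
#' @param schedule A [make_schedule()] object.
#' @param h Langevin step size.
#' @return List with `w` (endpoint), `log_v`, `acceptance` (logical, one
#'   entry per transition), `accept_beta` (the invariant temperature of
#'   each transition) and `valid` (`FALSE` when the prior draw itself
#'   failed to evaluate).
#' @export
run_trajectory <- function(model, data, schedule, h = 0.5) {
  betas <- schedule$betas
  J <- schedule$J
  w1 <- prior_sample(model$prior)
  ev <- model_eval(model, w1, data)
  if (!is.finite(ev$log_lik)) {
    return(list(w = w1, log_v = -Inf, acceptance = rep(NA, max(J - 1, 0)),
                accept_beta = betas[seq_len(max(J - 1, 0)) + 1],
                valid = FALSE))
  }
  log_v <- (betas[2] - betas[1]) * ev$log_lik
  state <- lmc_state(w1, betas[2], ev, model)
  acceptance <- logical(max(J - 1, 0))
  if (J >= 2) {
    for (j in 2:J) {
      ## transition invariant at beta_{j-1} produces the rung-j point
      state$beta <- betas[j]
      state <- lmc_step(state, model, data, h)
      acceptance[j - 1] <- state$accepted
      log_v <- log_v + (betas[j + 1] - betas[j]) * state$log_lik
    }
  }
  list(w = state$w, log_v = log_v, acceptance = acceptance,
       accept_beta = betas[seq_len(max(J - 1, 0)) + 1], valid = TRUE)
}

#' Run annealed importance sampling
#'
#' Executes `I` independent annealing trajectories and collects endpoint
#' samples, log importance weights and acceptance traces.  Each trajectory
#' uses its own L'Ecuyer-CMRG random-number substream derived from `seed`,
#' so results are reproducible and independent of how trajectories might be
#' scheduled across workers.  Trajectories whose initial prior draw fails
#' to evaluate are dropped (with a warning); more than 20% failures abort
#' the run.
#'
#' @param model A [bayes_model()].
#' @param data Dataset.
#' @param schedule A [make_schedule()] object (default `make_schedule(512)`).
#' @param I Number of trajectories (default 32).
#' @param seed Integer seed for the trajectory substreams.
#' @param h Langevin step size (default 0.5).
#' @return Object of class `ais_result` with fields `samples`
#'   (`I` x `n_params`), `log_v`, `q` (normalised weights), `v_max`,
#'   `u_bar`, `acceptance` (`I` x `J-1` logical matrix), `accept_beta`,
#'   `schedule`, `I`, `n_dropped` and `seed`.
#' @export
run_ais <- function(model, data, schedule = make_schedule(512), I = 32,
                    seed = 1, h = 0.5) {
  stopifnot(I >= 1)
  streams <- rng_substreams(seed, I)
  ## leave the caller's RNG untouched: all draws below come from the
  ## per-trajectory substreams
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  trajs <- vector("list", I)
  for (i in seq_len(I)) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    trajs[[i]] <- run_trajectory(model, data, schedule, h)
  }
  valid <- vapply(trajs, function(tr) tr$valid, logical(1))
  n_dropped <- sum(!valid)
  if (n_dropped > 0.2 * I) {
    stop("more than 20% of trajectories failed to evaluate (",
         n_dropped, "/", I, ")")
  }
  if (n_dropped > 0) {
    warning(n_dropped, " invalid trajectories dropped")
    trajs <- trajs[valid]
  }
  samples <- do.call(rbind, lapply(trajs, function(tr) tr$w))
  log_v <- vapply(trajs, function(tr) tr$log_v, numeric(1))
  acceptance <- do.call(rbind, lapply(trajs, function(tr) tr$acceptance))
  nw <- normalize_weights(log_v)
  structure(
    list(samples = samples, log_v = log_v, q = nw$q, v_max = nw$v_max,
         u_bar = nw$u_bar, acceptance = acceptance,
         accept_beta = trajs[[1]]$accept_beta,
         schedule = schedule, I = length(trajs), n_dropped = n_dropped,
         seed = seed, h = h, model_name = model$name),
    class = "ais_result"
  )
}

#' @export
print.ais_result <- function(x, ...) {
  cat("<ais_result>", x$model_name, ": I =", x$I, ", J =", x$schedule$J,
      "\n  log evidence point estimate:",
      format(x$v_max + log(x$u_bar), digits = 6), "\n")
  invisible(x)
}

## Independent per-trajectory RNG substreams (L'Ecuyer-CMRG), so that the
## worker layout can never change results.
rng_substreams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  streams <- vector("list", n)
  streams[[1]] <- get(".Random.seed", envir = globalenv())
  if (n > 1) {
    for (i in 2:n) {
      streams[[i]] <- parallel::nextRNGStream(streams[[i - 1]])
    }
  }
  streams
}

#' Normalise log importance weights
#'
#' Overflow-safe normalisation: \eqn{u_i = \exp(\log v_i - v_{max})},
#' \eqn{q_i = u_i / \sum_i u_i}, \eqn{\bar u = mean(u)}.
#'
#' @param log_v Numeric vector of raw log importance weights (at least one
#'   finite entry).
#' @return List with `q`, `v_max` and `u_bar`.
#' @export
normalize_weights <- function(log_v) {
  if (!any(is.finite(log_v))) stop("all log weights are -Inf")
  v_max <- max(log_v)
  u <- exp(log_v - v_max)
  list(q = u / sum(u), v_max = v_max, u_bar = mean(u))
}

#' Log evidence estimate with bootstrap confidence interval
#'
#' Point estimate \eqn{v_{max} + \log \bar u} of the log marginal
#' likelihood, with 5th/95th percentile confidence limits obtained by
#' resampling the per-trajectory weights with replacement.
#'
#' @param x An [run_ais()] result, or a numeric vector of raw log
#'   importance weights.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @return Object of class `evidence_estimate` with `log_z`, `ci_low`,
#'   `ci_high`, `n_boot` and `n` (number of weights).
#' @export
log_evidence <- function(x, n_boot = 1000) {
  log_v <- if (inherits(x, "ais_result")) x$log_v else as.numeric(x)
  est <- log_mean_exp(log_v)
  n <- length(log_v)
  if (n == 1) {
    warning("single trajectory: confidence interval degenerates to the ",
            "point estimate")
    ci <- c(est, est)
  } else {
    boots <- vapply(seq_len(n_boot), function(b) {
      log_mean_exp(log_v[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.05, 0.95), names = FALSE)
  }
  structure(
    list(log_z = est, ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, n = n),
    class = "evidence_estimate"
  )
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat("log evidence:", format(x$log_z, digits = 6),
      " [", format(x$ci_low, digits = 6), ",",
      format(x$ci_high, digits = 6), "] (5th-95th pct,",
      x$n_boot, "bootstraps)\n")
  invisible(x)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Posterior mean from AIS samples
#'
#' @param result An [run_ais()] result.
#' @param weighted If `TRUE` (default), the self-normalised
#'   importance-weighted mean \eqn{\sum_i q_i w^{(i)}}; if `FALSE`, the
#'   plain mean over trajectory endpoints.
#' @return Numeric vector of length `n_params`.
#' @export
posterior_mean <- function(result, weighted = TRUE) {
  stopifnot(inherits(result, "ais_result"))
  if (weighted) {
    drop(crossprod(result$samples, result$q))
  } else {
    colMeans(result$samples)
  }
}

#' Prior arithmetic mean evidence estimator
#'
#' Log-mean-exp of the log-likelihood over independent prior draws; the
#' two-temperature special case of AIS.  Underestimates the evidence in
#' high dimensions because prior draws rarely visit the high-likelihood
#' region.
#'
#' @param model A [bayes_model()].
#' @param data Dataset.
#' @param n Number of prior draws.
#' @param seed Optional seed.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @return An `evidence_estimate`.
#' @export
pam_evidence <- function(model, data, n, seed = NULL, n_boot = 1000) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  W <- prior_sample(model$prior, n)
  if (n == 1) W <- matrix(W, nrow = 1)
  ll <- apply(W, 1, function(w) as.numeric(model$log_lik(w, data)))
  log_evidence(ll, n_boot = n_boot)
}

#' Posterior harmonic mean evidence estimator
#'
#' Minus the log-mean-exp of minus the log-likelihood over posterior
#' samples; the reverse-schedule two-temperature special case of AIS.
#' Overestimates the evidence because posterior samples rarely visit the
#' low-likelihood region.
#'
#' @param samples Matrix of posterior samples (rows) on the unconstrained
#'   scale.
#' @param model A [bayes_model()].
#' @param data Dataset.
#' @param n_boot Bootstrap resamples.
#' @return An `evidence_estimate`.
#' @export
phm_evidence <- function(samples, model, data, n_boot = 1000) {
  samples <- as.matrix(samples)
  ll <- apply(samples, 1, function(w) as.numeric(model$log_lik(w, data)))
  if (any(!is.finite(ll))) {
    stop("posterior harmonic mean undefined: sample with -Inf log-likelihood")
  }
  est <- -log_mean_exp(-ll)
  n <- length(ll)
  boots <- vapply(seq_len(n_boot), function(b) {
    -log_mean_exp(-ll[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.05, 0.95), names = FALSE)
  structure(
    list(log_z = est, ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, n = n),
    class = "evidence_estimate"
  )
}

#' Importance-sampling evidence with a Gaussian proposal
#'
#' Log-mean-exp of \eqn{\log p(y|w) + \log p(w) - \log N(w; m, C)} over
#' draws from the supplied Gaussian proposal.  With the exact posterior as
#' proposal this recovers the evidence with zero variance; with an
#' approximate posterior (e.g. from a Laplace fit) it provides a cheap but
#' potentially unreliable estimate.
#'
#' @param model A [bayes_model()].
#' @param data Dataset.
#' @param mean Proposal mean vector.
#' @param cov Proposal covariance matrix (positive definite).
#' @param n Number of proposal draws.
#' @param seed Optional seed.
#' @param n_boot Bootstrap resamples.
#' @return An `evidence_estimate`.
#' @export
gaussian_is_evidence <- function(model, data, mean, cov, n, seed = NULL,
                                 n_boot = 1000) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cholC <- chol((cov + t(cov)) / 2)
  log_w <- vapply(seq_len(n), function(i) {
    w <- rmvnorm_chol(mean, cholC)
    ll <- as.numeric(model$log_lik(w, data))
    ll + prior_logpdf(model$prior, w) - dmvnorm_chol(w, mean, cholC)
  }, numeric(1))
  log_evidence(log_w, n_boot = n_boot)
}
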