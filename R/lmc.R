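#' Evaluate log-likelihood, gradient and Fisher information together
#'
#' Uses the model's combined evaluator `eval_all` when it provides one
#' (ODE models compute all three quantities from a single integration of
#' the augmented sensitivity system); otherwise composes the three
#' callbacks.
#'
#' @param model A [bayes_model()].
#' @param w Parameter vector.
#' @param data Dataset.
#' @return List with `log_lik`, `grad` and `fisher`.
#' @keywords internal
model_eval <- function(model, w, data) {
  if (!is.null(model$eval_all)) return(model$eval_all(w, data))
  ll <- model$log_lik(w, data)
  if (!is.finite(ll)) {
    np <- model$n_params
    return(list(log_lik = ll, grad = rep(0, np), fisher = diag(0, np)))
  }
  list(log_lik = ll,
       grad = model$grad_log_lik(w, data),
       fisher = model$fisher(w, data))
}

## Tempered state: current point plus cached likelihood quantities.
lmc_state <- function(w, beta, ev, model) {
  list(w = w, beta = beta,
       log_lik = ev$log_lik, grad_ll = ev$grad, fisher = ev$fisher,
       accepted = NA)
}

tempered_logjoint <- function(state, model) {
  state$beta * state$log_lik + prior_logpdf(model$prior, state$w)
}

tempered_grad <- function(state, model) {
  state$beta * state$grad_ll + prior_grad(model$prior, state$w)
}

#' Build the Fisher-preconditioned Langevin proposal
#'
#' The proposal at a tempered state is Gaussian with covariance
#' \eqn{C = h^2 (\Lambda + \beta F)^{-1}} (prior precision plus tempered
#' Fisher information) and mean drifted half a step along the
#' preconditioned tempered gradient, \eqn{m = w + \tfrac{1}{2} C g_\beta}.
#' If \eqn{\Lambda + \beta F} is numerically non-positive-definite, an
#' escalating diagonal jitter (1e-8, 1e-6, 1e-4 times the mean diagonal
#' scale) is added, with a warning for each escalation.
#'
#' @param w Current parameter vector.
#' @param g_beta Tempered gradient at `w`.
#' @param fisher Fisher information at `w` (untempered).
#' @param beta Inverse temperature.
#' @param prior A [gaussian_prior()].
#' @param h Step-size parameter (default 0.5).
#' @return List with `m` (mean), `C` (covariance) and `cholC` (upper
#'   Cholesky factor of `C`).
#' @export
build_proposal <- function(w, g_beta, fisher, beta, prior, h = 0.5) {
  M <- prior$precision + beta * fisher
  M <- (M + t(M)) / 2
  chM <- NULL
  scale <- mean(abs(diag(M)))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (eps in c(0, 1e-8, 1e-6, 1e-4)) {
    Mj <- M + diag(eps * scale, nrow(M))
    chM <- tryCatch(chol(Mj), error = function(e) NULL)
    if (!is.null(chM)) {
      if (eps > 0) {
        warning("proposal precision regularized with jitter ", eps * scale)
      }
      break
    }
  }
  if (is.null(chM)) stop("proposal precision not positive definite")
  C <- h^2 * chol2inv(chM)
  C <- (C + t(C)) / 2
  m <- w + 0.5 * drop(C %*% g_beta)
  list(m = m, C = C, cholC = chol(C))
}

## Gaussian log-density given the upper Cholesky factor of the covariance
dmvnorm_chol <- function(x, m, cholC) {
  z <- forwardsolve(t(cholC), x - m)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(cholC))) - 0.5 * sum(z^2)
}

rmvnorm_chol <- function(m, cholC) {
  m + drop(t(cholC) %*% stats::rnorm(length(m)))
}

#' One tempered Langevin Monte Carlo transition
#'
#' A single Metropolis-adjusted Langevin (simplified manifold MALA) step
#' that leaves the tempered density
#' \eqn{f_\beta(w) \propto p(y|w)^\beta p(w)} invariant.  The reverse
#' proposal density is evaluated with mean and covariance rebuilt at the
#' proposed point (full asymmetric Metropolis–Hastings correction for the
#' position-dependent preconditioner).  Likelihood evaluation failures at
#' the proposal lead to automatic rejection.
#'
#' @param state A tempered state as produced internally by the AIS driver:
#'   list with `w`, `beta` and cached `log_lik`, `grad_ll`, `fisher`.
#' @param model A [bayes_model()].
#' @param data Dataset.
#' @param h Step size (default 0.5).
#' @return Updated state with `accepted` flag set (`TRUE` for an accepted
#'   move, `FALSE` for a rejection, in which case the point is unchanged).
#' @export
lmc_step <- function(state, model, data, h = 0.5) {
  prior <- model$prior
  g_cur <- tempered_grad(state, model)
  L_cur <- tempered_logjoint(state, model)
  prop <- build_proposal(state$w, g_cur, state$fisher, state$beta, prior, h)
  w_star <- rmvnorm_chol(prop$m, prop$cholC)
  ev_star <- model_eval(model, w_star, data)
  if (!is.finite(ev_star$log_lik)) {
    state$accepted <- FALSE
    return(state)
  }
  star <- lmc_state(w_star, state$beta, ev_star, model)
  L_star <- tempered_logjoint(star, model)
  g_star <- tempered_grad(star, model)
  prop_rev <- build_proposal(w_star, g_star, ev_star$fisher, state$beta,
                             prior, h)
  log_r <- (L_star - L_cur) +
    dmvnorm_chol(state$w, prop_rev$m, prop_rev$cholC) -
    dmvnorm_chol(w_star, prop$m, prop$cholC)
  if (is.finite(log_r) && log(stats::runif(1)) < log_r) {
    star$accepted <- TRUE
    star
  } else {
    state$accepted <- FALSE
    state
  }
}
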