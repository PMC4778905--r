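#' Bayesian model contract
#'
#' A `bayes_model` bundles everything a sampler needs to know about one
#' statistical model: a Gaussian prior, a log-likelihood, the gradient of the
#' log-likelihood, and the Fisher information of the likelihood, all as
#' functions of an unconstrained parameter vector `w`.  Constrained
#' physiological quantities (time constants, connection strengths, ...) live
#' only inside model internals; every sampler-facing quantity is on the
#' unconstrained scale.
#'
#' @param prior A [gaussian_prior()].
#' @param log_lik `function(w, data)` returning the log-likelihood
#'   \eqn{\log p(y | w)}.  Evaluation failures (ODE divergence, overflow)
#'   must be reported via [eval_failure()], not by raising an error.
#' @param grad_log_lik `function(w, data)` returning
#'   \eqn{d \log p(y|w) / dw}.
#' @param fisher `function(w, data)` returning the (expected) Fisher
#'   information matrix of the likelihood at `w`; must be symmetric positive
#'   semi-definite.
#' @param name Character label used in printing and run artifacts.
#' @param ... Further model-specific fields stored on the object.
#'
#' @return An object of class `bayes_model`.
#' @seealso [log_joint()], [grad_log_joint()]
#' @export
bayes_model <- function(prior, log_lik, grad_log_lik, fisher,
                        name = "model", ...) {
  stopifnot(inherits(prior, "gaussian_prior"),
            is.function(log_lik), is.function(grad_log_lik),
            is.function(fisher))
  structure(
    list(
      prior = prior,
      log_lik = log_lik,
      grad_log_lik = grad_log_lik,
      fisher = fisher,
      n_params = prior$n_params,
      name = name,
      ...
    ),
    class = "bayes_model"
  )
}

#' @export
print.bayes_model <- function(x, ...) {
  cat("<bayes_model>", x$name, "with", x$n_params, "parameters\n")
  invisible(x)
}

#' Flag a likelihood evaluation failure
#'
#' Models whose likelihood requires numerical integration can fail far out in
#' the parameter tails (solver divergence, overflow).  Such failures are
#' reported as a `-Inf` log-likelihood carrying a `failure` attribute, so the
#' Metropolis step rejects the move while the trajectory stays alive; they
#' remain distinguishable from an ordinary astronomically-low density.
#'
#' @param message Optional description of the failure.
#' @return `-Inf` with attribute `failure = TRUE`.
#' @export
eval_failure <- function(message = "likelihood evaluation failure") {
  structure(-Inf, failure = TRUE, message = message)
}

#' @rdname eval_failure
#' @param x A log-likelihood value.
#' @export
is_eval_failure <- function(x) {
  isTRUE(attr(x, "failure"))
}

#' Tempered log joint density
#'
#' Computes \eqn{L_\beta(w) = \beta \log p(y|w) + \log p(w)}, the log of the
#' unnormalised tempered density bridging prior (\eqn{\beta = 0}) and
#' posterior (\eqn{\beta = 1}).  At \eqn{\beta = 0} the likelihood is not
#' evaluated and the result is exactly the log prior.
#'
#' @param model A [bayes_model()].
#' @param w Unconstrained parameter vector of length `model$n_params`.
#' @param data A dataset understood by the model's likelihood.
#' @param beta Inverse temperature in `[0, 1]`.
#' @return Log joint value; `-Inf` on likelihood evaluation failure.
#' @export
log_joint <- function(model, w, data, beta = 1) {
  stopifnot(length(w) == model$n_params, beta >= 0, beta <= 1)
  lp <- prior_logpdf(model$prior, w)
  if (beta == 0) return(lp)
  ll <- model$log_lik(w, data)
  if (!is.finite(ll)) return(ll) # propagate -Inf (and any failure attribute)
  beta * ll + lp
}

#' Gradient of the tempered log joint
#'
#' Returns \eqn{g_\beta(w) = \beta \, d\log p(y|w)/dw - \Lambda (w - \mu)}.
#'
#' @inheritParams log_joint
#' @return Numeric gradient vector.
#' @export
grad_log_joint <- function(model, w, data, beta = 1) {
  stopifnot(length(w) == model$n_params, beta >= 0, beta <= 1)
  g <- prior_grad(model$prior, w)
  if (beta == 0) return(g)
  beta * model$grad_log_lik(w, data) + g
}

#' Check gradient of a model against central finite differences
#'
#' Development/testing helper: compares `grad_log_lik` with a central
#' finite-difference approximation of `log_lik` at a point.
#'
#' @inheritParams log_joint
#' @param eps Step size for the central difference.
#' @return Named list with `analytic`, `numeric` and `max_rel_err`.
#' @export
check_gradient <- function(model, w, data, eps = 1e-5) {
  g <- model$grad_log_lik(w, data)
  gn <- vapply(seq_along(w), function(i) {
    e <- rep(0, length(w)); e[i] <- eps
    (model$log_lik(w + e, data) - model$log_lik(w - e, data)) / (2 * eps)
  }, numeric(1))
  scale <- pmax(abs(g), abs(gn), 1e-8)
  list(analytic = g, numeric = gn,
       max_rel_err = max(abs(g - gn) / scale))
}
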