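#' Multivariate Gaussian prior in mean/precision form
#'
#' All models in the package use a Gaussian prior \eqn{N(w; \mu, \Lambda)}
#' parameterised by its mean vector and precision (inverse covariance)
#' matrix.  The precision parameterisation mirrors the convention used
#' throughout dynamic causal modelling software.
#'
#' @param mean Numeric vector, prior mean \eqn{\mu}.
#' @param precision Symmetric positive-definite precision matrix
#'   \eqn{\Lambda}, or a numeric vector interpreted as the diagonal of a
#'   diagonal precision matrix.
#'
#' @return An object of class `gaussian_prior` with elements `mean`,
#'   `precision`, `chol_precision` (upper-triangular Cholesky factor of
#'   \eqn{\Lambda}) and `log_det_precision`.
#' @examples
#' pr <- gaussian_prior(c(0, 0), diag(1 / 10, 2))
#' prior_logpdf(pr, c(0, 0))
#' @export
gaussian_prior <- function(mean, precision) {
  mean <- as.numeric(mean)
  p <- length(mean)
  if (is.vector(precision) && !is.matrix(precision)) {
    precision <- diag(as.numeric(precision), p)
  }
  precision <- as.matrix(precision)
  if (!all(dim(precision) == c(p, p))) {
    stop("precision must be ", p, " x ", p)
  }
  if (max(abs(precision - t(precision))) > 1e-8 * max(1, max(abs(precision)))) {
    stop("precision matrix must be symmetric")
  }
  precision <- (precision + t(precision)) / 2
  ch <- tryCatch(chol(precision), error = function(e) {
    stop("precision matrix must be positive definite: ", conditionMessage(e))
  })
  structure(
    list(
      mean = mean,
      precision = precision,
      chol_precision = ch,
      log_det_precision = 2 * sum(log(diag(ch))),
      n_params = p
    ),
    class = "gaussian_prior"
  )
}

#' Log-density of a Gaussian prior
#'
#' @param prior A [gaussian_prior()] object.
#' @param w Numeric parameter vector.
#' @return The log prior density at `w`.
#' @export
prior_logpdf <- function(prior, w) {
  d <- w - prior$mean
  q <- drop(crossprod(prior$chol_precision %*% d))
  -0.5 * length(w) * log(2 * pi) + 0.5 * prior$log_det_precision - 0.5 * q
}

#' Gradient of the log prior density
#'
#' @inheritParams prior_logpdf
#' @return Numeric vector \eqn{-\Lambda (w - \mu)}.
#' @export
prior_grad <- function(prior, w) {
  -drop(prior$precision %*% (w - prior$mean))
}

#' Draw samples from a Gaussian prior
#'
#' @inheritParams prior_logpdf
#' @param n Number of draws.
#' @return An `n` x `n_params` matrix of draws (a vector if `n = 1`).
#' @export
prior_sample <- function(prior, n = 1) {
  p <- prior$n_params
  z <- matrix(stats::rnorm(n * p), nrow = p)
  ## x = mu + R^{-1} z with R the upper Cholesky factor of the precision
  x <- backsolve(prior$chol_precision, z) + prior$mean
  if (n == 1) drop(x) else t(x)
}

#' @export
print.gaussian_prior <- function(x, ...) {
  cat("Gaussian prior over", x$n_params, "parameters\n")
  cat("  mean:", format(x$mean, digits = 4), "\n")
  cat("  precision diag:", format(diag(x$precision), digits = 4), "\n")
  invisible(x)
}
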