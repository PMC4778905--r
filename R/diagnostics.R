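#' Entropy of normalised importance weights
#'
#' Shannon entropy \eqn{-\sum_i q_i \log_2 q_i} in bits, with
#' \eqn{0 \log 0 = 0}.  Uniform weights over `I` trajectories attain the
#' maximum \eqn{\log_2 I}; a point mass has zero entropy.  Low entropy
#' signals that the evidence estimate is dominated by few trajectories.
#'
#' @param q Normalised weights (non-negative, summing to one within 1e-8).
#' @return Entropy in bits.
#' @export
weight_entropy <- function(q) {
  check_normalized(q)
  qpos <- q[q > 0]
  -sum(qpos * log2(qpos))
}

#' Count of significantly non-zero importance weights
#'
#' @inheritParams weight_entropy
#' @param threshold Weights strictly above this count as significant
#'   (default 0.01).
#' @return Integer count.
#' @export
significant_count <- function(q, threshold = 0.01) {
  check_normalized(q)
  sum(q > threshold)
}

check_normalized <- function(q) {
  if (any(q < 0) || abs(sum(q) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to one")
  }
  invisible(q)
}

#' Per-temperature acceptance-rate summary
#'
#' Averages the acceptance indicators over trajectories at each
#' temperature, and additionally over the high-temperature
#' (\eqn{\beta_j < 0.5}) and low-temperature (\eqn{\beta_j \ge 0.5}) halves
#' of the ladder.  (High temperature = small inverse temperature.)
#'
#' @param acceptance `I` x `n_steps` logical/numeric matrix of per-step
#'   acceptance flags (as in an [run_ais()] result).
#' @param betas Inverse temperature of each transition (length
#'   `n_steps`).
#' @return List with `a_j` (per-temperature means), `betas`, `a_high` and
#'   `a_low`.
#' @export
acceptance_summary <- function(acceptance, betas) {
  acceptance <- as.matrix(acceptance)
  stopifnot(ncol(acceptance) == length(betas))
  a_j <- colMeans(acceptance)
  high <- betas < 0.5
  list(a_j = a_j, betas = betas,
       a_high = mean(a_j[high]),
       a_low = mean(a_j[!high]))
}

#' Royston's test for multivariate normality
#'
#' Multivariate extension of the Shapiro–Wilk test: each margin's W
#' statistic is mapped through Royston's (1992) normalizing transformation
#' to a z-score, converted to an equivalent chi-squared variable
#' \eqn{R_j = [\Phi^{-1}(\tfrac{1}{2}\Phi(-z_j))]^2}, and the statistic
#' \eqn{H = e \, \bar R} is referred to a chi-squared distribution whose
#' equivalent degrees of freedom \eqn{e = d / (1 + (d-1)\bar c)} account
#' for the average correlation between margins.
#'
#' @param samples `n` x `d` numeric matrix, `3 <= n <= 2000`, no constant
#'   column.
#' @return List with `H` (statistic), `e` (equivalent degrees of freedom)
#'   and `p_value`.
#' @references Royston, J.P. (1992) Approximating the Shapiro-Wilk W-test
#'   for non-normality. Statistics and Computing 2, 117-119.
#' @export
royston_test <- function(samples) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  d <- ncol(samples)
  if (n < 3 || n > 2000) {
    stop("Royston's test requires 3 <= n <= 2000 (got n = ", n, ")")
  }
  if (any(apply(samples, 2, stats::sd) == 0)) {
    stop("constant column in samples")
  }
  x <- log(n)
  z <- vapply(seq_len(d), function(j) {
    W <- stats::shapiro.test(samples[, j])$statistic
    if (n <= 11) {
      g <- -2.273 + 0.459 * n
      m <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
      s <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
      (-log(g - log(1 - W)) - m) / s
    } else {
      m <- -1.5861 - 0.31082 * x - 0.083751 * x^2 + 0.0038915 * x^3
      s <- exp(-0.4803 - 0.082676 * x + 0.0030302 * x^2)
      (log(1 - W) - m) / s
    }
  }, numeric(1))
  R <- stats::qnorm(stats::pnorm(-z) / 2)^2
  if (d == 1) {
    e <- 1
    H <- R[1]
  } else {
    u <- 0.715
    v <- 0.21364 + 0.015124 * x^2 - 0.0018034 * x^3
    lam <- 5
    Cr <- stats::cor(samples)
    cij <- Cr[upper.tri(Cr)]
    cbar <- mean(cij^lam * (1 - u * (1 - cij)^u / v))
    e <- d / (1 + (d - 1) * cbar)
    H <- e * mean(R)
  }
  list(H = unname(H), e = unname(e),
       p_value = unname(stats::pchisq(H, df = e, lower.tail = FALSE)))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_tests Number of comparisons in the family.
#' @return Per-test threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Root mean squared error between two parameter vectors
#'
#' @param estimate,truth Numeric vectors of equal length.
#' @return \eqn{\sqrt{mean((estimate - truth)^2)}}.
#' @export
rmse <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth))
  sqrt(mean((estimate - truth)^2))
}

#' Diagnostics bundle for an AIS run
#'
#' Weight-distribution summaries, acceptance-rate summaries, Royston's
#' normality test on the endpoint samples, and (when the generating truth
#' is known) the RMSE of the posterior mean.
#'
#' @param result An [run_ais()] result.
#' @param truth Optional true parameter vector.
#' @param alpha,n_tests Family-wise level and family size for the
#'   Bonferroni-corrected Gaussianity flag (defaults 0.05 over 40 tests).
#' @return Named list (serialisable to JSON) with `entropy_bits`, `I_q`,
#'   `a_high`, `a_low`, `royston` (with raw p-value and Bonferroni flag)
#'   and `rmse` (or `NULL`).
#' @export
ais_diagnostics <- function(result, truth = NULL, alpha = 0.05,
                            n_tests = 40) {
  acc <- acceptance_summary(result$acceptance, result$accept_beta)
  roy <- royston_test(result$samples)
  thr <- bonferroni_threshold(alpha, n_tests)
  list(
    entropy_bits = weight_entropy(result$q),
    I_q = significant_count(result$q),
    a_high = acc$a_high,
    a_low = acc$a_low,
    royston = list(H = roy$H, e = roy$e, p = roy$p_value,
                   significant_bonferroni = roy$p_value < thr,
                   threshold = thr),
    rmse = if (is.null(truth)) NULL else {
      rmse(posterior_mean(result), truth)
    }
  )
}
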