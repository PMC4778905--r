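# Shared fixtures, all built in code.

# model with constant log-likelihood c (zero gradient/Fisher): the
# telescoping and estimator-identity tests use it because every evidence
# estimator must return exactly c.
const_lik_model <- function(c_val, n_params = 2) {
  prior <- gaussian_prior(rep(0, n_params), diag(1, n_params))
  bayes_model(
    prior = prior,
    log_lik = function(w, data) c_val,
    grad_log_lik = function(w, data) rep(0, n_params),
    fisher = function(w, data) diag(0, n_params),
    name = "const_lik"
  )
}

# brute-force 2-D quadrature posterior mean for any model with 2 parameters
quadrature_posterior_mean <- function(model, data, center, half_width,
                                      n_grid = 301) {
  g1 <- seq(center[1] - half_width, center[1] + half_width,
            length.out = n_grid)
  g2 <- seq(center[2] - half_width, center[2] + half_width,
            length.out = n_grid)
  lp <- outer(seq_along(g1), seq_along(g2), Vectorize(function(i, j) {
    log_joint(model, c(g1[i], g2[j]), data)
  }))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  c(sum(rowSums(p) * g1), sum(colSums(p) * g2))
}

# small, fast NMM configuration for unit tests (coarser grid than default)
test_nmm_config <- function(...) {
  nmm_config(t = seq(0, 0.2, by = 0.004), ...)
}
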