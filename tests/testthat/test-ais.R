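test_that("geometric schedule has the exact ladder values", {
  expect_equal(make_schedule(1)$betas, c(0, 1))
  expect_equal(make_schedule(4, 5)$betas,
               c(0, 0.0009765625, 0.03125, 0.2373046875, 1))
  expect_equal(make_schedule(2, 1)$betas, c(0, 0.5, 1))
  s <- make_schedule(512)
  expect_identical(s$betas[1], 0)
  expect_identical(s$betas[513], 1)
  expect_true(all(diff(s$betas) > 0))
  expect_error(make_schedule(0), "at least 1")
})

test_that("a constant likelihood telescopes to an exact weight", {
  m <- const_lik_model(-3.7)
  res <- run_ais(m, NULL, make_schedule(8), I = 8, seed = 1)
  expect_equal(res$log_v, rep(-3.7, 8), tolerance = 1e-12)
  ev <- log_evidence(res)
  expect_equal(ev$log_z, -3.7)
  expect_equal(ev$ci_low, ev$ci_high)
  ## all estimator baselines agree on a constant likelihood
  expect_equal(pam_evidence(m, NULL, 50, seed = 2)$log_z, -3.7)
  set.seed(2)
  expect_equal(phm_evidence(prior_sample(m$prior, 50), m, NULL)$log_z, -3.7)
  expect_equal(gaussian_is_evidence(m, NULL, c(0, 0), diag(2), 50,
                                    seed = 2)$log_z,
               -3.7 + 0, tolerance = 1e-12)
})

test_that("single-interval AIS is exactly the prior arithmetic mean", {
  gl <- gen_linear(51)
  res <- run_ais(gl$model, gl$data, make_schedule(1), I = 32, seed = 5)
  ## endpoints are untouched prior draws and weights are their likelihoods
  ll <- apply(res$samples, 1, function(w) gl$model$log_lik(w, gl$data))
  expect_equal(res$log_v, ll)
  expect_equal(log_evidence(res)$log_z, aislmc:::log_mean_exp(ll))
  one <- run_ais(gl$model, gl$data, make_schedule(1), I = 1, seed = 5)
  expect_equal(one$q, 1)
})

test_that("runs are reproducible from the seed", {
  gl <- gen_linear(52)
  a <- run_ais(gl$model, gl$data, make_schedule(32), I = 6, seed = 9)
  b <- run_ais(gl$model, gl$data, make_schedule(32), I = 6, seed = 9)
  expect_identical(a$log_v, b$log_v)
  expect_identical(a$samples, b$samples)
  c <- run_ais(gl$model, gl$data, make_schedule(32), I = 6, seed = 10)
  expect_false(identical(a$log_v, c$log_v))
})

test_that("weight normalisation is overflow-safe and shift-invariant", {
  nw <- normalize_weights(rep(2.5, 32))
  expect_equal(nw$q, rep(1 / 32, 32))
  expect_equal(normalize_weights(c(0, -Inf))$q, c(1, 0))
  lv <- c(-1000, -1001, -999.5)
  expect_equal(normalize_weights(lv)$q, normalize_weights(lv + 12345)$q)
  expect_error(normalize_weights(c(-Inf, -Inf)), "-Inf")
})

test_that("posterior mean honours weights and flags", {
  gl <- gen_linear(53)
  res <- run_ais(gl$model, gl$data, make_schedule(16), I = 4, seed = 3)
  expect_equal(posterior_mean(res, weighted = FALSE), colMeans(res$samples))
  expect_equal(posterior_mean(res, weighted = TRUE),
               drop(crossprod(res$samples, res$q)))
  one <- run_ais(gl$model, gl$data, make_schedule(16), I = 1, seed = 3)
  expect_equal(posterior_mean(one, weighted = TRUE),
               posterior_mean(one, weighted = FALSE))
  ## equal weights collapse the two estimators
  m <- const_lik_model(1, 3)
  rc <- run_ais(m, NULL, make_schedule(4), I = 8, seed = 1)
  expect_equal(posterior_mean(rc, TRUE), posterior_mean(rc, FALSE))
})

test_that("the exact posterior as Gaussian proposal recovers the evidence with zero variance", {
  gl <- gen_linear(54)
  post <- linreg_analytic_posterior(gl$model, gl$data)
  ev <- gaussian_is_evidence(gl$model, gl$data, post$mean,
                             solve(post$precision), n = 64, seed = 7)
  an <- linreg_analytic_evidence(gl$model, gl$data)
  expect_equal(ev$log_z, an, tolerance = 1e-8)
  expect_lt(ev$ci_high - ev$ci_low, 1e-8)
})

test_that("failed trajectories are dropped or abort the run", {
  prior <- gaussian_prior(0, 1)
  half_bad <- bayes_model(
    prior = prior,
    log_lik = function(w, data) if (w > 0) eval_failure() else -0.1 * w^2,
    grad_log_lik = function(w, data) -0.2 * w,
    fisher = function(w, data) matrix(0.2),
    name = "half_bad"
  )
  expect_error(
    suppressWarnings(run_ais(half_bad, NULL, make_schedule(4), I = 16,
                             seed = 1)),
    "20%"
  )
  mostly_ok <- bayes_model(
    prior = prior,
    log_lik = function(w, data) if (w > 1.8) eval_failure() else -0.1 * w^2,
    grad_log_lik = function(w, data) -0.2 * w,
    fisher = function(w, data) matrix(0.2),
    name = "mostly_ok"
  )
  expect_warning(
    res <- run_ais(mostly_ok, NULL, make_schedule(4), I = 32, seed = 4),
    "dropped"
  )
  expect_lt(res$I, 32)
  expect_equal(res$I + res$n_dropped, 32)
})
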