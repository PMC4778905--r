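test_that("analytic posterior reduces to the prior without information", {
  prior <- gaussian_prior(c(1, -1), diag(0.5, 2))
  X0 <- matrix(0, 5, 2)
  m <- linear_model(X0, sigma = 1, prior = prior)
  d <- ais_dataset(y = rnorm(5), X = X0, noise_sd = 1)
  post <- linreg_analytic_posterior(m, d)
  expect_equal(post$mean, prior$mean)
  expect_equal(post$precision, prior$precision)

  ## noise so large the data carry almost no information
  gl <- gen_linear(21)
  m_inf <- linear_model(gl$model$X, sigma = 1e8, prior = gl$model$prior)
  post_inf <- linreg_analytic_posterior(m_inf, gl$data)
  expect_equal(post_inf$mean, gl$model$prior$mean, tolerance = 1e-10)
})

test_that("analytic posterior mean matches a 2-D quadrature oracle", {
  set.seed(3)
  X <- matrix(rnorm(12), 6, 2)
  prior <- gaussian_prior(c(0, 0), diag(1 / 2, 2))
  m <- linear_model(X, sigma = 0.7, prior = prior)
  d <- ais_dataset(y = drop(X %*% c(1, -0.5)) + rnorm(6, sd = 0.7),
                   X = X, noise_sd = 0.7)
  post <- linreg_analytic_posterior(m, d)
  sds <- sqrt(diag(solve(post$precision)))
  qm <- quadrature_posterior_mean(m, d, post$mean, 7 * max(sds),
                                  n_grid = 801)
  expect_equal(qm, post$mean, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("analytic evidence has its scalar closed form and satisfies the candidate identity", {
  m <- linear_model(matrix(1, 1, 1), sigma = 1,
                    prior = gaussian_prior(0, matrix(1)))
  d <- ais_dataset(y = 0, X = matrix(1, 1, 1), noise_sd = 1)
  expect_equal(linreg_analytic_evidence(m, d), -0.5 * log(4 * pi))

  gl <- gen_linear(31)
  ev <- linreg_analytic_evidence(gl$model, gl$data)
  post <- linreg_analytic_posterior(gl$model, gl$data)
  chP <- chol(post$precision)
  set.seed(31)
  for (k in 1:3) {
    w <- rnorm(7)
    z <- chP %*% (w - post$mean)
    log_post <- -0.5 * 7 * log(2 * pi) + sum(log(diag(chP))) -
      0.5 * sum(z^2)
    expect_equal(log_joint(gl$model, w, gl$data) - log_post, ev,
                 tolerance = 1e-8)
  }
})

test_that("nested-model evidence favours the full model on noiseless full-model data", {
  X <- dct_basis(20, 7)
  beta <- c(1, 0.5, -0.5, 0.3, -0.3, 0.2, 1.5)
  d <- ais_dataset(y = drop(X %*% beta), X = X, noise_sd = 0.2)
  full <- linear_model(X, 0.2)
  red <- linear_model(X[, 1:6], 0.2)
  expect_gt(linreg_analytic_evidence(full, d),
            linreg_analytic_evidence(red, d))
})

test_that("squared-coefficient predictions are sign-symmetric with four equal posterior modes", {
  X <- dct_basis(20, 2)
  expect_equal(squared_predict(c(2, 2), X), squared_predict(c(-2, 2), X))
  expect_equal(squared_predict(c(2, 2), X), squared_predict(c(2, -2), X))
  gs <- gen_squared(4)
  base <- log_joint(gs$model, c(1.5, 2.5), gs$data)
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
    expect_equal(log_joint(gs$model, c(1.5 * s1, 2.5 * s2), gs$data), base)
  }
})

test_that("approach-to-limit predictions have the stated shape", {
  w <- c(log(8), log(30))
  expect_equal(approach_predict(w, 1e9), -60 + 30, tolerance = 1e-12)
  expect_equal(approach_predict(w, 8), -60 + 30 * (1 - exp(-1)))
  expect_equal(approach_predict(w, 0), -60)
  ## monotone non-decreasing in t
  p <- approach_predict(w, seq(0, 50, by = 0.5))
  expect_true(all(diff(p) >= 0))
  ## reduced variant: constant prediction
  expect_equal(approach_predict(log(30), 1:20, reduced = TRUE),
               rep(-30, 20))
  ## overflow guard clamps instead of overflowing (one warning per
  ## clamped parameter)
  expect_warning(expect_warning(
    p_big <- approach_predict(c(1000, 1000), 1:3), "clamped"), "clamped")
  expect_true(all(is.finite(p_big)))
})

test_that("full approach model beats the reduced one on ramp data", {
  ga <- gen_approach(12)
  sched <- make_schedule(128)
  rf <- run_ais(ga$model, ga$data, sched, I = 16, seed = 1)
  rr <- run_ais(ga$model_reduced, ga$data, sched, I = 16, seed = 1)
  expect_gt(log_evidence(rf)$log_z, log_evidence(rr)$log_z + 100)
})

test_that("prior mean pairing of the approach model is switchable", {
  m1 <- approach_model()
  m2 <- approach_model(swap_prior_mean = TRUE)
  expect_equal(m1$prior$mean, c(3, 1.6))
  expect_equal(m2$prior$mean, c(1.6, 3))
})
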