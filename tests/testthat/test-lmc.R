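test_that("proposal covariance and mean have their closed forms", {
  gl <- gen_linear(41)
  prior <- gl$model$prior
  h <- 0.5
  ## beta = 0: prior-preconditioned kernel centred at the prior mode
  p0 <- build_proposal(prior$mean, prior_grad(prior, prior$mean),
                       diag(0, 7), beta = 0, prior = prior, h = h)
  expect_equal(p0$C, h^2 * solve(prior$precision), tolerance = 1e-12)
  expect_equal(p0$m, prior$mean)
  ## beta = 1 on the conjugate model: the analytic posterior precision
  set.seed(41)
  w <- rnorm(7)
  Fw <- gl$model$fisher(w, gl$data)
  p1 <- build_proposal(w, rep(0, 7), Fw, beta = 1, prior = prior, h = h)
  post <- linreg_analytic_posterior(gl$model, gl$data)
  expect_equal(p1$C, h^2 * solve(post$precision), tolerance = 1e-10)
  ## zero tempered gradient leaves the proposal centred at w
  expect_equal(p1$m, w)
})

test_that("acceptance log-ratio is exchange-symmetric", {
  gl <- gen_linear(42)
  model <- gl$model
  log_r <- function(w_from, w_to, beta, h = 0.5) {
    ev_f <- model$fisher(w_from, gl$data)
    ev_t <- model$fisher(w_to, gl$data)
    L <- function(w) beta * model$log_lik(w, gl$data) +
      prior_logpdf(model$prior, w)
    g <- function(w) beta * model$grad_log_lik(w, gl$data) +
      prior_grad(model$prior, w)
    pf <- build_proposal(w_from, g(w_from), ev_f, beta, model$prior, h)
    pt <- build_proposal(w_to, g(w_to), ev_t, beta, model$prior, h)
    (L(w_to) - L(w_from)) +
      aislmc:::dmvnorm_chol(w_from, pt$m, pt$cholC) -
      aislmc:::dmvnorm_chol(w_to, pf$m, pf$cholC)
  }
  set.seed(42)
  for (k in 1:5) {
    a <- rnorm(7); b <- rnorm(7); beta <- runif(1)
    expect_equal(log_r(a, b, beta), -log_r(b, a, beta), tolerance = 1e-10)
  }
})

test_that("identity proposals are always accepted and failures rejected", {
  prior <- gaussian_prior(0, 1)
  flat <- bayes_model(
    prior = prior,
    log_lik = function(w, data) 0,
    grad_log_lik = function(w, data) 0,
    fisher = function(w, data) matrix(1),
    name = "flat"
  )
  st <- aislmc:::lmc_state(0.3, 1, model_eval(flat, 0.3, NULL), flat)
  set.seed(1)
  reps <- replicate(50, lmc_step(st, flat, NULL)$accepted)
  ## target is the prior itself and the preconditioner is exact, so
  ## acceptance should be essentially 1 for a Gaussian target
  expect_gt(mean(reps), 0.9)

  broken <- bayes_model(
    prior = prior,
    log_lik = function(w, data) if (abs(w - 0.3) > 1e-12) eval_failure()
      else 0,
    grad_log_lik = function(w, data) 0,
    fisher = function(w, data) matrix(1),
    name = "broken"
  )
  stb <- aislmc:::lmc_state(0.3, 1, model_eval(broken, 0.3, NULL), broken)
  out <- lmc_step(stb, broken, NULL)
  expect_false(out$accepted)
  expect_equal(out$w, 0.3)
})

test_that("a short chain at beta = 1 tracks the conjugate posterior", {
  gl <- gen_linear(43)
  post <- linreg_analytic_posterior(gl$model, gl$data)
  post_cov <- solve(post$precision)
  set.seed(43)
  ev <- model_eval(gl$model, prior_sample(gl$model$prior), gl$data)
  st <- aislmc:::lmc_state(prior_sample(gl$model$prior), 1, ev, gl$model)
  st <- aislmc:::lmc_state(st$w, 1, model_eval(gl$model, st$w, gl$data),
                           gl$model)
  n <- 4000; burn <- 500
  draws <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    st <- lmc_step(st, gl$model, gl$data)
    draws[i, ] <- st$w
  }
  kept <- draws[-seq_len(burn), ]
  sds <- sqrt(diag(post_cov))
  ## sample mean within a generous Monte-Carlo band of the analytic mean
  expect_lt(max(abs(colMeans(kept) - post$mean) / sds), 0.2)
  rel_frob <- norm(cov(kept) - post_cov, "F") / norm(post_cov, "F")
  expect_lt(rel_frob, 0.25)
})

test_that("proposal precision regularisation escalates jitter with a warning", {
  prior <- gaussian_prior(c(0, 0), diag(1, 2))
  ## precision with a tiny negative eigenvalue: only the largest jitter
  ## level restores positive definiteness
  bad_fisher <- matrix(c(0, 1 + 3e-6, 1 + 3e-6, 0), 2, 2)
  expect_warning(
    pr <- build_proposal(c(0, 0), c(0, 0), bad_fisher, beta = 1,
                         prior = prior),
    "jitter"
  )
  expect_true(all(is.finite(pr$cholC)))
})
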