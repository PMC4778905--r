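test_that("firing-rate function is zero at rest with the stated limits", {
  for (r1 in c(0.5, 2)) for (r2 in c(0.5, 2)) {
    expect_equal(sigmoid_rate(0, r1, r2), 0)
    expect_equal(sigmoid_rate(1e6, r1, r2), 1 - 1 / (1 + exp(r1 * r2)))
    expect_equal(sigmoid_rate(r2, r1, r2), 0.5 - 1 / (1 + exp(r1 * r2)))
  }
})

test_that("parameter transform maps w = 0 to defaults and round-trips", {
  cfg <- nmm_config()
  expect_equal(nmm_transform(rep(0, 10), cfg), cfg$theta0)
  set.seed(1)
  w <- rnorm(10, sd = 0.5)
  expect_equal(nmm_inverse(nmm_transform(w, cfg), cfg), w,
               tolerance = 1e-12, ignore_attr = TRUE)
  ## strong-connection generator setting scales both strengths by e
  th <- nmm_transform(c(1, 1, rep(0, 8)), cfg)
  expect_equal(th[["a12"]], exp(1) * cfg$theta0[["a12"]])
  expect_equal(th[["a21"]], exp(1) * cfg$theta0[["a21"]])
  expect_error(nmm_inverse(-cfg$theta0, cfg), "positive")
})

test_that("rest state is a fixed point and persists without input", {
  cfg <- test_nmm_config(input_amp = 0)
  d <- nmm_derivatives(rep(0, 18), 0, nmm_transform(rep(0, 10), cfg), cfg)
  expect_equal(d$f, rep(0, 18))
  tr <- integrate_nmm(rep(0, 10), cfg)
  expect_equal(max(abs(tr$X)), 0)
})

test_that("uncoupled regions behave as independent single-region units", {
  cfg2 <- test_nmm_config()
  w_dec <- c(-40, -40, rep(0, 8))  # connection strengths ~ 0
  tr2 <- integrate_nmm(w_dec, cfg2)
  expect_lt(max(abs(tr2$yhat[2, ])), 1e-12)
  cfg1 <- test_nmm_config(regions = 1)
  tr1 <- integrate_nmm(rep(0, 10), cfg1)
  scale <- max(abs(tr1$yhat[1, ]))
  expect_lt(max(abs(tr1$yhat[1, ] - tr2$yhat[1, ])) / scale, 0.05)
})

test_that("an isolated synapse reproduces the alpha-kernel impulse response", {
  cfg <- nmm_config()
  He <- cfg$H_e
  te <- cfg$tau_e
  ## impulse through the second-order realisation used by the model:
  ## v'' = (H/tau) input - (2/tau) v' - v/tau^2, impulse = v'(0) = H/tau
  out <- deSolve::ode(c(0, He / te), seq(0, 5 * te, by = te / 100),
                      function(t, y, p) {
                        list(c(y[2], -2 / te * y[2] - y[1] / te^2))
                      }, NULL, method = "bdf", rtol = 1e-8, atol = 1e-10)
  expect_equal(max(out[, 2]), He / exp(1), tolerance = 1e-4)
  expect_equal(out[which.max(out[, 2]), 1], te, tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("compiled and reference right-hand sides agree", {
  ## compared at tight tolerances so solver step-selection noise cannot
  ## mask a defect in either implementation
  cfg <- test_nmm_config(rtol = 1e-8, atol = 1e-10)
  set.seed(2)
  for (k in 1:3) {
    w <- rnorm(10, sd = 0.3)
    trC <- integrate_nmm(w, cfg)
    trR <- integrate_nmm(w, cfg, engine = "R")
    expect_false(is_eval_failure(trC))
    expect_equal(trC$yhat, trR$yhat, tolerance = 1e-6)
  }
  wS <- c(0.5, 0.5, rep(0.1, 8))
  sC <- integrate_nmm(wS, cfg, sensitivities = TRUE)
  sR <- integrate_nmm(wS, cfg, sensitivities = TRUE, engine = "R")
  expect_equal(sC$J, sR$J, tolerance = 1e-6)
})

test_that("tightening solver tolerances barely changes the trajectory", {
  w <- c(1, 1, rep(0, 8))
  loose <- integrate_nmm(w, nmm_config())
  tight <- integrate_nmm(w, nmm_config(rtol = 1e-4, atol = 1e-6))
  rel <- sqrt(mean((loose$yhat - tight$yhat)^2)) /
    sqrt(mean(tight$yhat^2))
  expect_lt(rel, 0.01)
})

test_that("log-likelihood equals independent per-point Gaussian terms", {
  cfg <- nmm_config(t = c(0, 0.05, 0.1))
  gen_y <- integrate_nmm(rep(0, 10), cfg)$yhat
  y <- gen_y + 0.005
  d <- ais_dataset(y = y, t = cfg$t, noise_sd = cfg$sigma_s)
  ll <- nmm_log_lik(rep(0, 10), d, cfg)
  by_hand <- sum(dnorm(as.vector(y), as.vector(gen_y),
                       sd = rep(cfg$sigma_s, 3), log = TRUE))
  expect_equal(ll, by_hand, tolerance = 1e-10)
  ## exact fit: N_t * sum_s -log(2 pi sigma_s^2)/2
  d0 <- ais_dataset(y = gen_y, t = cfg$t, noise_sd = cfg$sigma_s)
  expect_equal(nmm_log_lik(rep(0, 10), d0, cfg),
               3 * sum(-0.5 * log(2 * pi * cfg$sigma_s^2)))
})

test_that("sensitivity gradient matches finite differences of the log-likelihood", {
  ## tight solver tolerances: the central-difference oracle divides the
  ## integration error by a 1e-4 step, so the default tolerances would
  ## drown the comparison in solver noise
  cfg <- test_nmm_config(rtol = 1e-8, atol = 1e-10)
  gen <- gen_nmm(17, config = cfg)
  for (w in list(c(0.5, 0.5, rep(0, 8)), rep(0.1, 10))) {
    gf <- nmm_grad_fisher(w, gen$data, gen$config)
    fd <- vapply(1:10, function(k) {
      e <- rep(0, 10); e[k] <- 1e-4
      (nmm_log_lik(w + e, gen$data, gen$config) -
         nmm_log_lik(w - e, gen$data, gen$config)) / 2e-4
    }, numeric(1))
    ## norm-relative: single components whose gradient is orders of
    ## magnitude below the norm sit at the finite-difference noise floor
    expect_lt(sqrt(sum((gf$grad - fd)^2) / sum(fd^2)), 1e-3)
  }
})

test_that("Fisher information is positive semi-definite across prior draws", {
  cfg <- test_nmm_config()
  gen <- gen_nmm(18, config = cfg)
  prior <- gen$model$prior
  set.seed(18)
  for (k in 1:10) {
    w <- prior_sample(prior)
    gf <- nmm_grad_fisher(w, gen$data, gen$config)
    ev <- eigen(gf$fisher, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(gf$fisher)))
  }
})

test_that("parameters of the absent backward connection have zero gradient", {
  cfg <- test_nmm_config()
  gen <- gen_nmm(19, full = FALSE, config = cfg)
  gf <- nmm_grad_fisher(c(0.3, 0.3, rep(0.1, 8)), gen$data, gen$config,
                        backward = FALSE)
  expect_identical(gf$grad[c(1, 3)], c(0, 0))
  expect_identical(max(abs(gf$fisher[c(1, 3), ])), 0)
})
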