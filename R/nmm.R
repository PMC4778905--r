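#' Configuration of the neural mass model
#'
#' Fixed physiological constants and numerical settings for the single- or
#' two-region convolution-based neural mass model of event-related cortical
#' dynamics.  Each cortical region contains four interacting populations
#' (spiny stellate cells, excitatory and inhibitory synapses on pyramidal
#' cells, and inhibitory interneurons); postsynaptic potentials arise from
#' firing rates by convolution with an alpha-function synaptic kernel
#' \eqn{h(t) = (H/\tau) t e^{-t/\tau}}, realised as a second-order ODE.
#' In the two-region network the forward connection (region 1 to 2) targets
#' the spiny stellate population and the backward connection (region 2 to 1)
#' targets the pyramidal and inhibitory populations, following the standard
#' hierarchical construction for event-related potential modelling.  The
#' fixed constants below (synaptic gains, time constants, intrinsic
#' connectivity ratios, delays) are taken from that modelling literature.
#'
#' Signalling delays are handled by a first-order Taylor surrogate,
#' \eqn{\tilde v = v - \delta \dot v}, both within regions (fixed
#' \eqn{\delta_{11}, \delta_{22}}) and between regions (estimable
#' \eqn{\delta_{12}, \delta_{21}}).
#'
#' @param regions 1 or 2 cortical regions (9 states per region).
#' @param t Output time grid in seconds (default 0 to 0.3 s at 1 ms).
#' @param H_e,H_i Excitatory/inhibitory synaptic gains (mV).
#' @param tau_e,tau_i Excitatory/inhibitory synaptic time constants (s).
#' @param delta_intrinsic Within-region signalling delay \eqn{\delta_{11} =
#'   \delta_{22}} (s), assumed known.
#' @param input_peak,input_width Peak time and Gaussian width (SD) of the
#'   exogenous input `u(t)` to region 1, in seconds.
#' @param input_amp Amplitude of the input bump (potential units, applied
#'   before the firing-rate nonlinearity).
#' @param input_gain Fixed gain on the rate-transformed input,
#'   \eqn{g_u s(u(t))}, the analogue of the subcortical input coefficient
#'   in event-related-potential models.  Together with `input_amp` the
#'   default is calibrated so that, at the canonical generating parameters,
#'   the noise-free region-2 signal SD is about 0.16 mV (so observation
#'   noise SD 0.01 corresponds to a signal-to-noise ratio near 16).
#' @param sigma_s Observation noise SD per region (mV).
#' @param theta0 Named vector of default physiological values of the 10
#'   estimable quantities; the unconstrained parameters `w` act
#'   multiplicatively, \eqn{\theta_k = \theta_{0k} e^{w_k}}, so `w = 0`
#'   reproduces these defaults and positivity is guaranteed.
#' @param rtol,atol Relative/absolute tolerances of the stiff BDF
#'   integrator.
#' @return An object of class `nmm_config`.
#' @export
nmm_config <- function(regions = 2,
                       t = seq(0, 0.3, by = 0.001),
                       H_e = 3.25, H_i = 22,
                       tau_e = 0.010, tau_i = 0.020,
                       delta_intrinsic = 0.002,
                       input_peak = 0.064, input_width = 0.016,
                       input_amp = 8, input_gain = 75,
                       sigma_s = 0.01,
                       theta0 = c(a12 = 16, a21 = 32,
                                  d12 = 0.016, d21 = 0.016,
                                  g1 = 128, g2 = 102.4, g3 = 32, g4 = 32,
                                  r1 = 2, r2 = 2),
                       rtol = 1e-2, atol = 1e-4) {
  stopifnot(regions %in% c(1, 2), length(t) >= 2,
            tau_e > 0, tau_i > 0, delta_intrinsic > 0,
            all(theta0[c("d12", "d21")] > 0), all(sigma_s > 0))
  structure(
    list(regions = regions, t = t,
         H_e = H_e, H_i = H_i, tau_e = tau_e, tau_i = tau_i,
         delta_intrinsic = delta_intrinsic,
         input_peak = input_peak, input_width = input_width,
         input_amp = input_amp, input_gain = input_gain,
         sigma_s = rep(sigma_s, length.out = regions),
         theta0 = theta0, rtol = rtol, atol = atol,
         n_states = 9L * regions, n_params = 10L),
    class = "nmm_config"
  )
}

#' @export
print.nmm_config <- function(x, ...) {
  cat("<nmm_config>", x$regions, "region(s),", length(x$t),
      "time points,", "sigma_s =", format(x$sigma_s, digits = 3), "\n")
  invisible(x)
}

#' Population firing-rate function
#'
#' Sigmoid mapping the mean membrane potential to a population firing rate,
#' shifted so that the resting potential maps to zero rate:
#' \deqn{s(x) = \frac{1}{1 + e^{-r_1 (x - r_2)}} - \frac{1}{1 + e^{r_1 r_2}}.}
#' The offset makes the all-zero state a fixed point of the dynamics.
#'
#' @param x Membrane potential (mV); vectorised.
#' @param r1 Slope parameter (1/mV).
#' @param r2 Inflection-point potential (mV).
#' @return Firing rate(s), zero at `x = 0`.
#' @export
sigmoid_rate <- function(x, r1, r2) {
  1 / (1 + exp(-r1 * (x - r2))) - 1 / (1 + exp(r1 * r2))
}

## derivative of sigmoid_rate wrt x
sigmoid_rate_dx <- function(x, r1, r2) {
  s <- 1 / (1 + exp(-r1 * (x - r2)))
  r1 * s * (1 - s)
}

## derivatives of sigmoid_rate wrt r1 and r2
sigmoid_rate_dr <- function(x, r1, r2) {
  s <- 1 / (1 + exp(-r1 * (x - r2)))
  s0 <- 1 / (1 + exp(r1 * r2))
  ss <- s * (1 - s)
  ss0 <- s0 * (1 - s0)
  list(dr1 = (x - r2) * ss + r2 * ss0,
       dr2 = r1 * (ss0 - ss))
}

#' Map unconstrained parameters to physiological values
#'
#' The 10 estimable quantities of the two-region model (extrinsic
#' connection strengths \eqn{a_{12}, a_{21}}, extrinsic delays
#' \eqn{\delta_{12}, \delta_{21}}, intrinsic gains \eqn{\gamma_{1..4}} and
#' firing-rate parameters \eqn{r_1, r_2}) are parameterised on an
#' unconstrained log scale: \eqn{\theta_k = \theta_{0k} e^{w_k}}, with
#' defaults \eqn{\theta_0} from [nmm_config()].  `w = 0` therefore yields
#' the defaults and every constrained quantity stays positive for all
#' finite `w`.
#'
#' @param w Unconstrained parameter vector (length 10).
#' @param config An [nmm_config()].
#' @return Named numeric vector of physiological values.
#' @export
nmm_transform <- function(w, config) {
  stopifnot(length(w) == config$n_params)
  config$theta0 * exp(w)
}

#' @rdname nmm_transform
#' @param theta Named vector of strictly positive physiological values.
#' @return For `nmm_inverse`, the unconstrained vector `w` with
#'   `nmm_transform(w, config) == theta`.
#' @export
nmm_inverse <- function(theta, config) {
  if (any(theta <= 0)) stop("physiological values must be strictly positive")
  log(theta / config$theta0)
}

#' Exogenous input to region 1
#'
#' Gaussian bump peaking at `config$input_peak` (default 64 ms) with SD
#' `config$input_width` (default 16 ms), amplitude `config$input_amp`.
#'
#' @param t Time(s) in seconds; vectorised.
#' @param config An [nmm_config()].
#' @return Input potential u(t).
#' @export
nmm_input <- function(t, config) {
  config$input_amp *
    exp(-(t - config$input_peak)^2 / (2 * config$input_width^2))
}

## State layout per region (base b = 9*(r-1)):
##   b+1 v_s    b+2 dv_s     (spiny stellate, excitatory kernel)
##   b+3 v_pe   b+4 dv_pe    (pyramidal, excitatory kernel)
##   b+5 v_pi   b+6 dv_pi    (pyramidal, inhibitory kernel)
##   b+7 v_i    b+8 dv_i     (inhibitory interneurons, excitatory kernel)
##   b+9 v_p = v_pe - v_pi   (pyramidal output potential)

#' State derivatives of the neural mass model
#'
#' Evaluates the right-hand side of the convolution-form neural mass ODEs
#' at one time point, optionally together with the state Jacobian
#' \eqn{A = \partial f/\partial x} and the parameter Jacobian
#' \eqn{B = \partial f/\partial w} needed by the forward sensitivity
#' system.
#'
#' @param x State vector (9 per region).
#' @param u_val Value of the exogenous input at the current time.
#' @param theta Named physiological parameter vector (see
#'   [nmm_transform()]).
#' @param config An [nmm_config()].
#' @param backward Include the backward connection (region 2 to 1)?
#'   Ignored for a single region.
#' @param deriv If `TRUE`, also return `A` and `B` (with `B` already on the
#'   unconstrained `w` scale).
#' @return List with `f` (and `A`, `B` when `deriv = TRUE`).
#' @export
nmm_derivatives <- function(x, u_val, theta, config, backward = TRUE,
                            deriv = FALSE) {
  nr <- config$regions
  stopifnot(length(x) == 9 * nr)
  ke <- config$H_e / config$tau_e
  ki <- config$H_i / config$tau_i
  ae <- 2 / config$tau_e; be <- 1 / config$tau_e^2
  ai <- 2 / config$tau_i; bi <- 1 / config$tau_i^2
  d0 <- config$delta_intrinsic
  th <- theta
  A12 <- if (nr == 2 && backward) th[["a12"]] else 0
  A21 <- if (nr == 2) th[["a21"]] else 0
  d12 <- th[["d12"]]; d21 <- th[["d21"]]
  g1 <- th[["g1"]]; g2 <- th[["g2"]]; g3 <- th[["g3"]]; g4 <- th[["g4"]]
  r1 <- th[["r1"]]; r2 <- th[["r2"]]

  s <- function(v) sigmoid_rate(v, r1, r2)
  sp <- function(v) sigmoid_rate_dx(v, r1, r2)

  ## delayed potentials
  vp1 <- x[9] - d0 * (x[4] - x[6])
  vs1 <- x[1] - d0 * x[2]
  vi1 <- x[7] - d0 * x[8]
  if (nr == 2) {
    vp2 <- x[18] - d0 * (x[13] - x[15])
    vs2 <- x[10] - d0 * x[11]
    vi2 <- x[16] - d0 * x[17]
    c21 <- x[18] - d12 * (x[13] - x[15])  # region 2 output as seen by 1
    c12 <- x[9] - d21 * (x[4] - x[6])     # region 1 output as seen by 2
  }

  f <- numeric(9 * nr)
  f[1] <- x[2]
  f[3] <- x[4]
  f[5] <- x[6]
  f[7] <- x[8]
  gu <- config$input_gain
  f[2] <- ke * (gu * s(u_val) + g1 * s(vp1)) - ae * x[2] - be * x[1]
  bw1 <- if (nr == 2) A12 * s(c21) else 0
  f[4] <- ke * (g2 * s(vs1) + bw1) - ae * x[4] - be * x[3]
  f[6] <- ki * g4 * s(vi1) - ai * x[6] - bi * x[5]
  f[8] <- ke * (g3 * s(vp1) + bw1) - ae * x[8] - be * x[7]
  f[9] <- x[4] - x[6]
  if (nr == 2) {
    fw2 <- A21 * s(c12)
    f[10] <- x[11]
    f[12] <- x[13]
    f[14] <- x[15]
    f[16] <- x[17]
    f[11] <- ke * (g1 * s(vp2) + fw2) - ae * x[11] - be * x[10]
    f[13] <- ke * g2 * s(vs2) - ae * x[13] - be * x[12]
    f[15] <- ki * g4 * s(vi2) - ai * x[15] - bi * x[14]
    f[17] <- ke * g3 * s(vp2) - ae * x[17] - be * x[16]
    f[18] <- x[13] - x[15]
  }
  if (!deriv) return(list(f = f))

  n <- 9 * nr
  A <- matrix(0, n, n)
  for (r in seq_len(nr)) {
    b <- 9 * (r - 1)
    A[b + 1, b + 2] <- 1
    A[b + 3, b + 4] <- 1
    A[b + 5, b + 6] <- 1
    A[b + 7, b + 8] <- 1
    A[b + 2, b + 1] <- A[b + 2, b + 1] - be
    A[b + 2, b + 2] <- A[b + 2, b + 2] - ae
    A[b + 4, b + 3] <- A[b + 4, b + 3] - be
    A[b + 4, b + 4] <- A[b + 4, b + 4] - ae
    A[b + 6, b + 5] <- A[b + 6, b + 5] - bi
    A[b + 6, b + 6] <- A[b + 6, b + 6] - ai
    A[b + 8, b + 7] <- A[b + 8, b + 7] - be
    A[b + 8, b + 8] <- A[b + 8, b + 8] - ae
    A[b + 9, b + 4] <- 1
    A[b + 9, b + 6] <- -1
  }
  add_sig <- function(row, coef, spv, cols, wts) {
    A[row, cols] <<- A[row, cols] + coef * spv * wts
  }
  ## intrinsic sigmoid couplings, region 1
  spp1 <- sp(vp1)
  add_sig(2, ke * g1, spp1, c(9, 4, 6), c(1, -d0, d0))
  add_sig(8, ke * g3, spp1, c(9, 4, 6), c(1, -d0, d0))
  add_sig(4, ke * g2, sp(vs1), c(1, 2), c(1, -d0))
  add_sig(6, ki * g4, sp(vi1), c(7, 8), c(1, -d0))
  if (nr == 2) {
    spp2 <- sp(vp2)
    add_sig(11, ke * g1, spp2, c(18, 13, 15), c(1, -d0, d0))
    add_sig(17, ke * g3, spp2, c(18, 13, 15), c(1, -d0, d0))
    add_sig(13, ke * g2, sp(vs2), c(10, 11), c(1, -d0))
    add_sig(15, ki * g4, sp(vi2), c(16, 17), c(1, -d0))
    ## extrinsic couplings
    spc21 <- sp(c21)
    spc12 <- sp(c12)
    add_sig(4, ke * A12, spc21, c(18, 13, 15), c(1, -d12, d12))
    add_sig(8, ke * A12, spc21, c(18, 13, 15), c(1, -d12, d12))
    add_sig(11, ke * A21, spc12, c(9, 4, 6), c(1, -d21, d21))
  }

  B <- matrix(0, n, 10)
  colnames(B) <- names(config$theta0)
  dsr_u <- sigmoid_rate_dr(u_val, r1, r2)
  dsr_p1 <- sigmoid_rate_dr(vp1, r1, r2)
  dsr_s1 <- sigmoid_rate_dr(vs1, r1, r2)
  dsr_i1 <- sigmoid_rate_dr(vi1, r1, r2)
  B[2, "g1"] <- ke * s(vp1)
  B[4, "g2"] <- ke * s(vs1)
  B[8, "g3"] <- ke * s(vp1)
  B[6, "g4"] <- ki * s(vi1)
  B[2, "r1"] <- ke * (gu * dsr_u$dr1 + g1 * dsr_p1$dr1)
  B[2, "r2"] <- ke * (gu * dsr_u$dr2 + g1 * dsr_p1$dr2)
  B[4, "r1"] <- ke * g2 * dsr_s1$dr1
  B[4, "r2"] <- ke * g2 * dsr_s1$dr2
  B[6, "r1"] <- ki * g4 * dsr_i1$dr1
  B[6, "r2"] <- ki * g4 * dsr_i1$dr2
  B[8, "r1"] <- ke * g3 * dsr_p1$dr1
  B[8, "r2"] <- ke * g3 * dsr_p1$dr2
  if (nr == 2) {
    dsr_p2 <- sigmoid_rate_dr(vp2, r1, r2)
    dsr_s2 <- sigmoid_rate_dr(vs2, r1, r2)
    dsr_i2 <- sigmoid_rate_dr(vi2, r1, r2)
    dsr_c21 <- sigmoid_rate_dr(c21, r1, r2)
    dsr_c12 <- sigmoid_rate_dr(c12, r1, r2)
    B[11, "g1"] <- ke * s(vp2)
    B[13, "g2"] <- ke * s(vs2)
    B[17, "g3"] <- ke * s(vp2)
    B[15, "g4"] <- ki * s(vi2)
    if (backward) {
      B[4, "a12"] <- ke * s(c21)
      B[8, "a12"] <- ke * s(c21)
      B[4, "d12"] <- -ke * A12 * spc21 * (x[13] - x[15])
      B[8, "d12"] <- B[4, "d12"]
    }
    B[11, "a21"] <- ke * s(c12)
    B[11, "d21"] <- -ke * A21 * spc12 * (x[4] - x[6])
    B[11, "r1"] <- ke * (g1 * dsr_p2$dr1 + A21 * dsr_c12$dr1)
    B[11, "r2"] <- ke * (g1 * dsr_p2$dr2 + A21 * dsr_c12$dr2)
    B[13, "r1"] <- ke * g2 * dsr_s2$dr1
    B[13, "r2"] <- ke * g2 * dsr_s2$dr2
    B[15, "r1"] <- ki * g4 * dsr_i2$dr1
    B[15, "r2"] <- ki * g4 * dsr_i2$dr2
    B[17, "r1"] <- ke * g3 * dsr_p2$dr1
    B[17, "r2"] <- ke * g3 * dsr_p2$dr2
    if (backward) {
      B[4, "r1"] <- B[4, "r1"] + ke * A12 * dsr_c21$dr1
      B[4, "r2"] <- B[4, "r2"] + ke * A12 * dsr_c21$dr2
      B[8, "r1"] <- B[8, "r1"] + ke * A12 * dsr_c21$dr1
      B[8, "r2"] <- B[8, "r2"] + ke * A12 * dsr_c21$dr2
    }
  }
  ## chain rule to the unconstrained scale: theta_k = theta0_k exp(w_k)
  B <- B * rep(theta, each = n)
  list(f = f, A = A, B = B)
}

#' Integrate the neural mass model
#'
#' Integrates the stiff neural mass ODEs with backward-differentiation
#' formulas (BDF, via \pkg{deSolve}), starting from the all-zero rest
#' state, optionally together with the forward sensitivity system
#' \eqn{\dot S = (\partial f/\partial x) S + \partial f/\partial w}.
#' An analytic state Jacobian is supplied to the implicit solver.
#'
#' @param w Unconstrained parameter vector (length 10).
#' @param config An [nmm_config()].
#' @param backward Include the backward connection?
#' @param sensitivities Integrate forward sensitivities as well?
#' @param engine `"compiled"` (default) uses the C implementation of the
#'   right-hand sides; `"R"` uses the reference implementation in
#'   [nmm_derivatives()].  Both produce the same trajectories (up to solver
#'   step-selection noise) and the equivalence is enforced by the test
#'   suite.
#' @return A list of class `nmm_trajectory` with elements `t`, `X`
#'   (`n_states` x `N_t` state matrix), `yhat` (`regions` x `N_t` pyramidal
#'   potentials), and — when requested — `S`
#'   (`n_states` x 10 x `N_t` sensitivity array) and `J`
#'   (`regions` x 10 x `N_t` observation sensitivities).
#'   Returns an [eval_failure()] if the solver diverges.
#' @export
integrate_nmm <- function(w, config, backward = TRUE,
                          sensitivities = FALSE,
                          engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  nx <- config$n_states
  np <- config$n_params
  theta <- nmm_transform(w, config)
  if (!all(is.finite(theta))) return(eval_failure("non-finite parameters"))
  obs <- 9 * seq_len(config$regions)
  y0 <- numeric(if (sensitivities) nx * (np + 1) else nx)

  if (engine == "compiled") {
    pvec <- c(config$regions, as.numeric(backward),
              config$tau_e, config$tau_i, config$H_e, config$H_i,
              config$delta_intrinsic,
              config$input_amp, config$input_peak, config$input_width,
              config$input_gain, unname(theta))
    out <- tryCatch(
      suppressWarnings(
        deSolve::ode(y = y0, times = config$t,
                     func = if (sensitivities) "nmm_sens" else "nmm_deriv",
                     parms = pvec, dllname = "aislmc",
                     initfunc = "nmm_init",
                     jacfunc = if (sensitivities) "nmm_sens_jac" else
                       "nmm_jac",
                     jactype = "fullusr", method = "bdf",
                     rtol = config$rtol, atol = config$atol)
      ),
      error = function(e) NULL
    )
  } else {
    u_of_t <- function(t) nmm_input(t, config)
    if (!sensitivities) {
      func <- function(t, y, parms) {
        list(nmm_derivatives(y, u_of_t(t), theta, config, backward)$f)
      }
      jacf <- function(t, y, parms) {
        nmm_derivatives(y, u_of_t(t), theta, config, backward,
                        deriv = TRUE)$A
      }
    } else {
      func <- function(t, y, parms) {
        x <- y[seq_len(nx)]
        S <- matrix(y[-seq_len(nx)], nx, np)
        d <- nmm_derivatives(x, u_of_t(t), theta, config, backward,
                             deriv = TRUE)
        list(c(d$f, d$A %*% S + d$B))
      }
      jacf <- function(t, y, parms) {
        x <- y[seq_len(nx)]
        A <- nmm_derivatives(x, u_of_t(t), theta, config, backward,
                             deriv = TRUE)$A
        ## block-diagonal approximation: exact for the state block, and for
        ## the sensitivity blocks up to second-derivative terms (only
        ## Newton convergence, not accuracy, depends on this)
        J <- matrix(0, nx * (np + 1), nx * (np + 1))
        for (k in 0:np) {
          idx <- k * nx + seq_len(nx)
          J[idx, idx] <- A
        }
        J
      }
    }
    out <- tryCatch(
      suppressWarnings(
        deSolve::ode(y = y0, times = config$t, func = func, parms = NULL,
                     method = "bdf", jacfunc = jacf, jactype = "fullusr",
                     rtol = config$rtol, atol = config$atol)
      ),
      error = function(e) NULL
    )
  }
  if (is.null(out) || nrow(out) < length(config$t) ||
      !all(is.finite(out[, -1]))) {
    return(eval_failure("ODE solver failure"))
  }
  X <- t(out[, 1 + seq_len(nx), drop = FALSE])
  res <- list(t = config$t, X = X, yhat = X[obs, , drop = FALSE],
              regions = config$regions)
  if (sensitivities) {
    S <- array(t(out[, -(1:(1 + nx)), drop = FALSE]),
               dim = c(nx, np, length(config$t)))
    res$S <- S
    res$J <- S[obs, , , drop = FALSE]
  }
  structure(res, class = "nmm_trajectory")
}

#' Gaussian log-likelihood of the neural mass model
#'
#' Independent Gaussian observation noise on the pyramidal potential of
#' each region: \eqn{\log p(Y|w) = \sum_t \log N(y_t; \hat y_t, C_e)} with
#' \eqn{C_e = diag(\sigma_s^2)}.
#'
#' @param w Unconstrained parameter vector.
#' @param data An [ais_dataset()] whose `y` is a `regions` x `N_t` matrix on
#'   the config's time grid.
#' @param config An [nmm_config()].
#' @param backward Include the backward connection?
#' @return Log-likelihood, or [eval_failure()] on solver divergence.
#' @export
nmm_log_lik <- function(w, data, config, backward = TRUE) {
  traj <- integrate_nmm(w, config, backward)
  if (is_eval_failure(traj)) return(traj)
  nmm_gaussian_ll(data$y, traj$yhat, config$sigma_s)
}

nmm_gaussian_ll <- function(y, yhat, sigma_s) {
  nt <- ncol(yhat)
  r <- y - yhat
  sum(-0.5 * nt * log(2 * pi * sigma_s^2) -
        rowSums(r^2) / (2 * sigma_s^2))
}

#' Gradient and Fisher information via forward sensitivities
#'
#' Computes the log-likelihood, its gradient and the (Gauss–Newton / expected)
#' Fisher information from a single integration of the augmented
#' state+sensitivity system:
#' \deqn{\nabla = \sum_t J_t' C_e^{-1} (y_t - \hat y_t), \qquad
#'       F = \sum_t J_t' C_e^{-1} J_t,}
#' with \eqn{J_t = \partial \hat y_t / \partial w}.
#'
#' @inheritParams nmm_log_lik
#' @return List with `log_lik`, `grad` (length 10) and `fisher` (10 x 10
#'   PSD matrix); an [eval_failure()] in `log_lik` with zero grad/Fisher on
#'   solver divergence.
#' @export
nmm_grad_fisher <- function(w, data, config, backward = TRUE) {
  traj <- integrate_nmm(w, config, backward, sensitivities = TRUE)
  np <- config$n_params
  if (is_eval_failure(traj)) {
    return(list(log_lik = traj, grad = rep(0, np),
                fisher = diag(0, np)))
  }
  r <- data$y - traj$yhat
  grad <- numeric(np)
  Fmat <- matrix(0, np, np)
  for (s in seq_len(config$regions)) {
    Js <- t(matrix(traj$J[s, , ], np, length(config$t)))  # N_t x np
    grad <- grad + drop(crossprod(Js, r[s, ])) / config$sigma_s[s]^2
    Fmat <- Fmat + crossprod(Js) / config$sigma_s[s]^2
  }
  list(log_lik = nmm_gaussian_ll(data$y, traj$yhat, config$sigma_s),
       grad = grad, fisher = (Fmat + t(Fmat)) / 2)
}

#' Neural mass model as a `bayes_model`
#'
#' Wraps the two-region (or single-region) neural mass model into the
#' sampler-facing model contract.  The prior over the unconstrained
#' parameters has zero mean and diagonal covariance with variance 0.16 for
#' the two extrinsic connection strengths and 0.0625 for the remaining
#' eight parameters.  The reduced variant removes the backward connection
#' (its strength and delay then have no effect on the likelihood, so their
#' posterior equals their prior and the marginal likelihood is that of the
#' 8-parameter structure).
#'
#' @param config An [nmm_config()].
#' @param backward Include the backward connection (`FALSE` gives the
#'   reduced model).
#' @return A [bayes_model()] with extra fields `config` and `backward`, and
#'   a combined evaluator `eval_all` used by the Langevin kernel to obtain
#'   log-likelihood, gradient and Fisher information from one integration.
#' @export
nmm_model <- function(config = nmm_config(), backward = TRUE) {
  prior <- gaussian_prior(rep(0, 10),
                          1 / c(0.16, 0.16, rep(0.0625, 8)))
  bayes_model(
    prior = prior,
    log_lik = function(w, data) nmm_log_lik(w, data, config, backward),
    grad_log_lik = function(w, data) {
      nmm_grad_fisher(w, data, config, backward)$grad
    },
    fisher = function(w, data) {
      nmm_grad_fisher(w, data, config, backward)$fisher
    },
    name = if (backward) "nmm_full" else "nmm_reduced",
    config = config, backward = backward,
    eval_all = function(w, data) nmm_grad_fisher(w, data, config, backward)
  )
}
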