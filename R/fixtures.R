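## Bundled example models: an IVGTT sampling design, one- and two-compartment
## intravenous-bolus PK models with log-normal between-subject variability
## and proportional residual error, a paired truth/misspecification scenario,
## and the two-compartment minimal glucose kinetics ODE as a demo.

#' Standard IVGTT sampling protocol
#'
#' A 0.33 g/kg glucose bolus at time zero followed by 32 samples over
#' 240 minutes.
#'
#' @param dose_g_per_kg bolus dose (g/kg), default 0.33.
#' @param body_weight_kg assumed body weight, default 70.
#' @return a [sampling_protocol()] (dose amount in mg) of class
#'   `ivgtt_protocol` with fields `dose_g_per_kg` and `body_weight_kg`.
#' @export
make_ivgtt_protocol <- function(dose_g_per_kg = 0.33, body_weight_kg = 70) {
  times <- c(0, 2, 3, 4, 5, 6, 8, 10, 12, 15, 18, 20, 22, 24, 26, 28, 30,
             35, 40, 45, 50, 55, 60, 70, 80, 100, 120, 140, 160, 180, 210, 240)
  p <- sampling_protocol(times, dose_amt = dose_g_per_kg * body_weight_kg * 1000)
  p$dose_g_per_kg <- dose_g_per_kg
  p$body_weight_kg <- body_weight_kg
  class(p) <- c("ivgtt_protocol", class(p))
  p
}

## Bolus superposition for observation rows of one subject's design.
bolus_doses <- function(design) {
  d <- design[design$EVID == 1 & design$AMT > 0, , drop = FALSE]
  list(t = d$TIME, amt = d$AMT)
}

#' One-compartment IV bolus PK model
#'
#' `C(t) = sum_d (A_d / V) exp(-CL/V (t - t_d))` with log-normal
#' between-subject variability on `CL` and `V` and proportional residual
#' error.
#'
#' @param CL,V typical clearance (L/min) and volume (L).
#' @param omega 2x2 covariance of `eta = (eta_CL, eta_V)`.
#' @param sigma_prop proportional residual-error variance.
#' @return an [nlme_model()] with `theta = c(CL, V)`.
#' @export
pk_model_onecomp <- function(CL = 0.15, V = 12,
                             omega = diag(c(0.0225, 0.0225)),
                             sigma_prop = 0.01) {
  kernel <- function(theta, eta, tt, dose_t, dose_amt) {
    cl <- theta[1] * exp(eta[1])
    v  <- theta[2] * exp(eta[2])
    k  <- cl / v
    f <- numeric(length(tt))
    for (j in seq_along(dose_t)) {
      el <- tt >= dose_t[j]
      f[el] <- f[el] + (dose_amt[j] / v) * exp(-k * (tt[el] - dose_t[j]))
    }
    f
  }
  structural <- function(theta, eta, design) {
    dose <- bolus_doses(design)
    kernel(theta, eta, design$TIME[design$EVID == 0], dose$t, dose$amt)
  }
  nlme_model(structural, error = c(conc = "proportional"),
             theta = c(CL = CL, V = V), omega = omega,
             sigma = list(conc = c(prop = sigma_prop)),
             dv_labels = "conc", name = "one-compartment IV bolus",
             pred_fast = function(theta, eta, times, dvid, dose_t, dose_amt)
               kernel(theta, eta, times, dose_t, dose_amt))
}

#' Two-compartment IV bolus PK model
#'
#' Biexponential disposition with micro-constants `k10 = CL/V1`,
#' `k12 = Q/V1`, `k21 = Q/V2`; log-normal between-subject variability on
#' `CL` and `V1`, proportional residual error.
#'
#' @param CL,V1,Q,V2 typical clearance, central volume, inter-compartmental
#'   clearance, peripheral volume (L/min, L).
#' @param omega 2x2 covariance of `eta = (eta_CL, eta_V1)`.
#' @param sigma_prop proportional residual-error variance.
#' @return an [nlme_model()] with `theta = c(CL, V1, Q, V2)`.
#' @export
pk_model_twocomp <- function(CL = 0.12, V1 = 9, Q = 0.35, V2 = 6,
                             omega = diag(c(0.0225, 0.0225)),
                             sigma_prop = 0.01) {
  kernel <- function(theta, eta, tt, dose_t, dose_amt) {
    cl <- theta[1] * exp(eta[1])
    v1 <- theta[2] * exp(eta[2])
    q  <- theta[3]
    v2 <- theta[4]
    k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
    s <- k10 + k12 + k21
    disc <- sqrt(s^2 - 4 * k10 * k21)
    l1 <- (s + disc) / 2
    l2 <- (s - disc) / 2
    c1 <- (l1 - k21) / (l1 - l2)
    c2 <- (k21 - l2) / (l1 - l2)
    f <- numeric(length(tt))
    for (j in seq_along(dose_t)) {
      el <- tt >= dose_t[j]
      dt <- tt[el] - dose_t[j]
      f[el] <- f[el] + (dose_amt[j] / v1) *
        (c1 * exp(-l1 * dt) + c2 * exp(-l2 * dt))
    }
    f
  }
  structural <- function(theta, eta, design) {
    dose <- bolus_doses(design)
    kernel(theta, eta, design$TIME[design$EVID == 0], dose$t, dose$amt)
  }
  nlme_model(structural, error = c(conc = "proportional"),
             theta = c(CL = CL, V1 = V1, Q = Q, V2 = V2), omega = omega,
             sigma = list(conc = c(prop = sigma_prop)),
             dv_labels = "conc", name = "two-compartment IV bolus",
             pred_fast = function(theta, eta, times, dvid, dose_t, dose_amt)
               kernel(theta, eta, times, dose_t, dose_amt))
}

#' Paired truth/misspecification PK scenario
#'
#' Simulates a dataset from the two-compartment model (the truth) on the
#' IVGTT design, and pairs it with a one-compartment model (same error
#' family) as the structurally misspecified candidate. Parameter values are
#' implementation choices documented in the methods vignette.
#'
#' @param seed integer seed.
#' @param n_subjects number of simulated subjects (default 100).
#' @param protocol sampling design (default [make_ivgtt_protocol()]).
#' @return list of class `pk_scenario`: `true_model`, `mis_model` (with
#'   starting values, not fitted), `mis_inits`, `dataset`, `protocol`,
#'   `seed`, `n_subjects`.
#' @export
make_pk_scenario <- function(seed = 1L, n_subjects = 100L,
                             protocol = make_ivgtt_protocol()) {
  true_model <- pk_model_twocomp()
  dataset <- simulate_dataset(true_model, protocol, n_subjects, seed = seed)
  mis_inits <- list(theta = c(CL = 0.13, V = 13.5), omega_diag = c(0.03, 0.03),
                    sigma = list(conc = c(prop = 0.015)))
  mis_model <- pk_model_onecomp(CL = mis_inits$theta[["CL"]],
                                V = mis_inits$theta[["V"]],
                                omega = diag(mis_inits$omega_diag),
                                sigma_prop = mis_inits$sigma$conc[["prop"]])
  structure(list(true_model = true_model, mis_model = mis_model,
                 mis_inits = mis_inits, dataset = dataset,
                 protocol = protocol, seed = seed, n_subjects = n_subjects),
            class = "pk_scenario")
}

#' Minimal glucose kinetics parameters
#'
#' Two-compartment glucose sub-model with net hepatic glucose balance:
#' glucose effectiveness `S_G` is the sum of peripheral uptake `k_1` and
#' hepatic balance `k_5`. Rates in 1/min; `G_b` is the basal glucose amount.
#'
#' @param k_1 peripheral-uptake rate (default 0.016).
#' @param k_5 hepatic rate (default 0.01).
#' @param k_21,k_12 central-peripheral transfer rates.
#' @param G_b basal glucose amount (default 90).
#' @param X insulin action on glucose kinetics (1/min): a function of time
#'   or a single constant. Default is a bi-exponential pulse emulating
#'   post-bolus insulin action.
#' @return list of class `minimal_glucose_params` (including `S_G = k_1 + k_5`).
#' @export
minimal_glucose_params <- function(k_1 = 0.016, k_5 = 0.01,
                                   k_21 = 0.05, k_12 = 0.07, G_b = 90,
                                   X = function(t)
                                     0.02 * (exp(-0.02 * t) - exp(-0.15 * t))) {
  stopifnot(k_1 >= 0, k_5 >= 0, k_21 >= 0, k_12 >= 0, G_b > 0)
  if (is.numeric(X)) {
    xval <- X
    X <- function(t) rep(xval, length(t))
  }
  structure(list(S_G = k_1 + k_5, k_1 = k_1, k_5 = k_5,
                 k_21 = k_21, k_12 = k_12, G_b = G_b, X = X),
            class = "minimal_glucose_params")
}

#' Minimal glucose model right-hand side
#'
#' `dG1/dt = S_G G_b - (S_G + X(t) + k_21) G1 + k_12 G2` with the
#' mass-balance companion `dG2/dt = k_21 G1 - k_12 G2`; initial condition
#' `G1(0) = G_b`. deSolve-compatible signature.
#'
#' @param t time (min).
#' @param state named or unnamed numeric `(G1, G2)`.
#' @param params a [minimal_glucose_params()].
#' @return list holding the derivative pair, as expected by
#'   [deSolve::ode()].
#' @export
minimal_glucose_rhs <- function(t, state, params) {
  G1 <- state[[1]]; G2 <- state[[2]]
  x <- params$X(t)
  dG1 <- params$S_G * params$G_b - (params$S_G + x + params$k_21) * G1 +
    params$k_12 * G2
  dG2 <- params$k_21 * G1 - params$k_12 * G2
  list(c(dG1, dG2))
}

#' Integrate the minimal glucose model
#'
#' @param params a [minimal_glucose_params()].
#' @param times output times (min), starting at 0.
#' @param G1_0,G2_0 initial amounts; defaults `G_b` and its basal companion
#'   `(k_21 / k_12) G_b`.
#' @return data.frame with columns `time`, `G1`, `G2`.
#' @export
simulate_minimal_glucose <- function(params, times = seq(0, 240, by = 1),
                                     G1_0 = params$G_b,
                                     G2_0 = params$k_21 / params$k_12 *
                                       params$G_b) {
  out <- deSolve::ode(y = c(G1 = G1_0, G2 = G2_0), times = times,
                      func = minimal_glucose_rhs, parms = params,
                      rtol = 1e-8, atol = 1e-8)
  as.data.frame(out)
}
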