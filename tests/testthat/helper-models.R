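## Shared fixtures: a linear random-intercept model (CWRES and the bias model
## are exact on it, giving closed-form oracles) and small cached scenario
## computations reused across test files.

linear_model <- function(theta = 1, omega2 = 0.1, sigma2 = 0.05) {
  nlme_model(
    structural = function(theta, eta, design)
      rep(theta[1] + eta[1], sum(design$EVID == 0)),
    error = c(y = "additive"),
    theta = theta, omega = matrix(omega2),
    sigma = list(y = c(add = sigma2)), dv_labels = "y",
    name = "linear random intercept")
}

flat_protocol <- function(n_obs = 10) sampling_protocol(seq_len(n_obs), dose_amt = 0)

## Exact ML of the balanced compound-symmetry model y_ij = mu + eta_i + eps_ij
## (m subjects x n obs): closed-form textbook solution.
cs_ml_closed_form <- function(y_mat) {
  m <- nrow(y_mat); n <- ncol(y_mat)
  mu <- mean(y_mat)
  ybar <- rowMeans(y_mat)
  ssw <- sum((y_mat - ybar)^2)
  ssb <- n * sum((ybar - mu)^2)
  sigma2 <- ssw / (m * (n - 1))
  omega2 <- max((ssb / m - sigma2) / n, 0)
  ofv <- m * (n - 1) * log(sigma2) + m * log(sigma2 + n * omega2) +
    ssw / sigma2 + ssb / (sigma2 + n * omega2)   # no 2*pi constant
  list(mu = mu, omega2 = omega2, sigma2 = sigma2, ofv = ofv)
}

## Dense-matrix -2 log likelihood (no 2*pi term) for the bin-mean
## compound-symmetry model: independent oracle for fit_base/fit_extended.
cs_dense_ofv <- function(id, y, bin, means, omega2, sigma2) {
  tot <- 0
  for (i in unique(id)) {
    sel <- id == i
    mu <- means[bin[sel]]
    V <- omega2 + diag(sigma2, sum(sel))
    L <- chol(V)
    z <- backsolve(L, y[sel] - mu, transpose = TRUE)
    tot <- tot + 2 * sum(log(diag(L))) + sum(z^2)
  }
  tot
}

## Cache expensive scenario computations across test files (tests run in one
## process; recomputed per test run, never stored on disk).
.scenario_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scenario_cache[[key]]))
    assign(key, force(expr), envir = .scenario_cache)
  .scenario_cache[[key]]
}

## The misspecification scenario at full size with the one-compartment model
## actually fitted by FOCE; shared by the detection and bias-recovery tests.
misfit_scenario <- function() {
  cached("misfit", {
    sc <- make_pk_scenario(seed = 101, n_subjects = 100)
    fit <- fit_population(sc$mis_model, sc$dataset, inits = sc$mis_inits,
                          control = list(maxit = 400, reltol = 1e-7))
    list(sc = sc, fit = fit)
  })
}
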