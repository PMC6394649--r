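test_that("simulation is seed-reproducible and honours degenerate noise", {
  m <- pk_model_onecomp()
  prot <- make_ivgtt_protocol()
  d1 <- simulate_dataset(m, prot, 5, seed = 3)
  d2 <- simulate_dataset(m, prot, 5, seed = 3)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(m, prot, 5, seed = 4)
  expect_false(identical(d1$DV, d3$DV))

  m0 <- pk_model_onecomp(omega = diag(c(0, 0)), sigma_prop = 0)
  d0 <- simulate_dataset(m0, prot, 3, seed = 1)
  sub <- split_subjects(d0)[[1]]
  f0 <- m0$structural(m0$theta, c(0, 0), sub$design)
  expect_equal(d0$DV[d0$EVID == 0 & d0$ID == 1], f0, tolerance = 1e-12)
})

test_that("simulated between-subject variability matches omega", {
  m <- pk_model_onecomp(omega = diag(c(0.09, 0.04)), sigma_prop = 0)
  prot <- make_ivgtt_protocol()
  d <- simulate_dataset(m, prot, 400, seed = 11)
  subs <- split_subjects(d)
  ## log individual CL recovered from terminal slope and intercept:
  ## with sigma = 0, back out eta by least squares on log-concentration
  log_cl <- vapply(subs, function(s) {
    fit <- lm(log(s$obs) ~ s$times)
    k <- -coef(fit)[2]; v <- prot$dose_amt / exp(coef(fit)[1])
    log(k * v)
  }, numeric(1))
  expect_equal(var(log_cl), 0.09 + 0.04, tolerance = 0.2)
})

test_that("EBEs match the closed-form posterior mode on the linear model", {
  om2 <- 0.1; sg2 <- 0.05; th <- 1; yobs <- 1.7
  m <- linear_model(th, om2, sg2)
  d <- data.frame(ID = 1, TIME = 1, AMT = 0, DV = yobs, DVID = 1,
                  EVID = 0, MDV = 0)
  sub <- split_subjects(d)[[1]]
  eb <- estimate_ebes(m, sub)
  expect_equal(eb$eta_hat, om2 / (om2 + sg2) * (yobs - th), tolerance = 1e-6)

  ## prior dominates as omega -> 0
  m_small <- linear_model(th, 1e-8, sg2)
  expect_equal(estimate_ebes(m_small, sub)$eta_hat, 0, tolerance = 1e-3)

  ## data at the population prediction give eta = 0
  d0 <- d; d0$DV <- th
  eb0 <- estimate_ebes(m, split_subjects(d0)[[1]])
  expect_equal(eb0$eta_hat, 0, tolerance = 1e-8)
})

test_that("EBEs agree with brute-force grid minimisation on a 1-d toy", {
  m <- pk_model_onecomp(omega = matrix(0.09), sigma_prop = 0.01)
  ## one-dimensional eta: IIV on CL only
  m$structural <- local({
    base <- pk_model_onecomp()$structural
    function(theta, eta, design) base(theta, c(eta[1], 0), design)
  })
  m$pred_fast <- NULL
  prot <- make_ivgtt_protocol()
  mref <- pk_model_onecomp(omega = diag(c(0.09, 0)), sigma_prop = 0.01)
  d <- simulate_dataset(mref, prot, 1, seed = 5)
  sub <- split_subjects(d)[[1]]
  eb <- estimate_ebes(m, sub)
  grid <- seq(-1.5, 1.5, by = 1e-3)
  obj <- cwresbias:::ebe_objective(m, sub, solve(m$omega))
  vals <- vapply(grid, obj, numeric(1))
  expect_lt(abs(eb$eta_hat - grid[which.min(vals)]), 1e-3)
  expect_lte(eb$objective, min(vals) + 1e-8)
})

test_that("conditional moments reduce to hand matrix algebra on the linear model", {
  om2 <- 0.2; sg2 <- 0.3; th <- 2; n <- 4
  m <- linear_model(th, om2, sg2)
  d <- simulate_dataset(m, flat_protocol(n), 1, seed = 8)
  sub <- split_subjects(d)[[1]]
  eb <- estimate_ebes(m, sub)
  cm <- conditional_moments(m, sub, eb$eta_hat)
  J <- matrix(1, n, 1)
  expect_equal(cm$expectation, rep(th, n), tolerance = 1e-6)
  expect_equal(unname(cm$covariance), om2 * J %*% t(J) + diag(sg2, n),
               tolerance = 1e-6)
  ## eta = 0 recovers the population prediction
  cm0 <- conditional_moments(m, sub, 0)
  expect_equal(cm0$expectation, rep(th, n), tolerance = 1e-10)
})

test_that("proportional error contributes sigma^2 f^2 to the covariance diagonal", {
  m <- pk_model_onecomp(sigma_prop = 0.02)
  prot <- make_ivgtt_protocol()
  d <- simulate_dataset(m, prot, 1, seed = 2)
  sub <- split_subjects(d)[[1]]
  eb <- estimate_ebes(m, sub)
  cm <- conditional_moments(m, sub, eb$eta_hat)
  f <- cm$f_ind
  expect_equal(cm$v, 0.02 * f^2, tolerance = 1e-12)
})

test_that("CWRES whitening is exact on a diagonal toy covariance", {
  W <- cov_sqrt(diag(c(4, 1)), inverse = TRUE)
  r <- drop(W %*% c(2, -1))
  expect_equal(r, c(1, -1), tolerance = 1e-10)
})

test_that("CWRES under the data-generating model are standard normal-ish", {
  m <- linear_model(1, 0.1, 0.05)
  d <- simulate_dataset(m, flat_protocol(10), 300, seed = 17)
  cw <- compute_cwres(m, d)
  expect_lt(abs(mean(cw$CWRES)), 0.05)
  expect_gt(var(cw$CWRES), 0.9)
  expect_lt(var(cw$CWRES), 1.1)
  ## whitening property: within-subject empirical covariance near identity
  M <- matrix(cw$CWRES, ncol = 10, byrow = TRUE)
  C <- cov(M)
  expect_lt(max(abs(C[upper.tri(C)])), 0.25)
  expect_true(all(abs(diag(C) - 1) < 0.2))
})

test_that("cwres table carries population predictions and row bookkeeping", {
  m <- pk_model_onecomp()
  d <- simulate_dataset(m, make_ivgtt_protocol(), 3, seed = 6)
  cw <- compute_cwres(m, d)
  expect_named(cw, c("ID", "ROW", "DVID", "TIME", "PRED_conc", "CWRES"))
  expect_equal(nrow(cw), 3 * 32)
  sub <- split_subjects(d)[[1]]
  f_pop <- m$structural(m$theta, c(0, 0), sub$design)
  expect_equal(cw$PRED_conc[cw$ID == 1], f_pop, tolerance = 1e-12)
  expect_true(all(is.finite(cw$CWRES)))
})

test_that("FOCE OFV equals the exact marginal -2LL on the linear mixed model", {
  m <- linear_model(1.3, 0.15, 0.07)
  d <- simulate_dataset(m, flat_protocol(6), 25, seed = 21)
  ofv <- foce_ofv(m, d)
  y_mat <- matrix(d$DV[d$EVID == 0], ncol = 6, byrow = TRUE)
  V <- 0.15 + diag(0.07, 6)
  L <- chol(V)
  exact <- sum(apply(y_mat, 1, function(y) {
    z <- backsolve(L, y - 1.3, transpose = TRUE)
    2 * sum(log(diag(L))) + sum(z^2)
  }))
  expect_equal(ofv, exact, tolerance = 1e-6)

  ## additivity over subjects: doubled dataset doubles the OFV
  d2 <- d
  d2$ID <- d2$ID + 100
  expect_equal(foce_ofv(m, rbind(d, d2)), 2 * ofv, tolerance = 1e-8)

  ## moving theta off the optimum increases the OFV
  m_off <- m
  m_off$theta <- 2.5
  expect_gt(foce_ofv(m_off, d), ofv)
})

test_that("fit_population recovers linear-model parameters and the CS closed form", {
  m <- linear_model(1, 0.1, 0.05)
  d <- simulate_dataset(m, flat_protocol(10), 100, seed = 31)
  fit <- fit_population(m, d, log_theta = TRUE, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
  oracle <- cs_ml_closed_form(matrix(d$DV[d$EVID == 0], ncol = 10, byrow = TRUE))
  expect_equal(unname(fit$theta), oracle$mu, tolerance = 1e-4)
  expect_equal(unname(diag(fit$omega)), oracle$omega2, tolerance = 1e-3)
  expect_equal(unname(unlist(fit$sigma)), oracle$sigma2, tolerance = 1e-3)
  expect_equal(fit$ofv, oracle$ofv, tolerance = 1e-6)
  ## within 15% of the generating values
  expect_equal(unname(fit$theta), 1, tolerance = 0.15)
  expect_equal(unname(diag(fit$omega)), 0.1, tolerance = 0.3)
  ## descent: fitted OFV no worse than the OFV at the truth
  expect_lte(fit$ofv, foce_ofv(m, d) + 1e-6)
})

test_that("fast prediction path matches the data.frame structural path", {
  for (maker in list(pk_model_onecomp, pk_model_twocomp)) {
    m <- maker()
    d <- simulate_dataset(m, make_ivgtt_protocol(), 2, seed = 13)
    m_slow <- m; m_slow$pred_fast <- NULL
    cw_fast <- compute_cwres(m, d)
    cw_slow <- compute_cwres(m_slow, d)
    expect_equal(cw_fast$CWRES, cw_slow$CWRES, tolerance = 1e-10)
  }
})
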