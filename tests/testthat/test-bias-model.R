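make_grouped <- function(y, id, idv = NULL) {
  g <- data.frame(ID = id, Y = y,
                  IDV = if (is.null(idv)) seq_along(y) else idv)
  attr(g, "idv_name") <- "IDV"
  class(g) <- c("cwres_grouped", "data.frame")
  g
}

test_that("base fit on iid standard normal data recovers (0, 0, 1)", {
  set.seed(41)
  m <- 100; n <- 32
  g <- make_grouped(rnorm(m * n), rep(seq_len(m), each = n))
  fit <- fit_base(g)
  expect_lt(abs(fit$means), 0.05)
  expect_lte(fit$omega, 0.05)
  expect_gt(fit$sigma, 0.9)
  expect_lt(fit$sigma, 1.1)
})

test_that("degenerate all-equal data put variances on the boundary", {
  g <- make_grouped(rep(2.5, 40), rep(1:4, each = 10))
  fit <- fit_base(g)
  expect_equal(unname(fit$means), 2.5, tolerance = 1e-6)
  expect_true(fit$boundary[["sigma"]])
})

test_that("base fit matches a brute-force likelihood grid and nlme::lme", {
  set.seed(42)
  m <- 10; n <- 8
  id <- rep(seq_len(m), each = n)
  y <- 0.5 + rep(rnorm(m, sd = sqrt(0.2)), each = n) + rnorm(m * n)
  g <- make_grouped(y, id)
  fit <- fit_base(g)

  ## dense-matrix oracle at the fitted parameters agrees with the fit's OFV
  expect_equal(cs_dense_ofv(id, y, rep(1L, m * n), fit$means,
                            fit$omega, fit$sigma),
               fit$ofv, tolerance = 1e-8)
  ## grid search around the optimum finds nothing better than 1e-3
  grid <- expand.grid(om = seq(0.01, 0.8, length.out = 25),
                      sg = seq(0.5, 1.8, length.out = 25))
  grid_ofv <- mapply(function(om, sg)
    cwresbias:::bias_profile_ofv(
      cwresbias:::bias_suffstats(id, y, rep(1L, m * n)), om, sg)$ofv,
    grid$om, grid$sg)
  expect_lte(fit$ofv, min(grid_ofv) + 1e-3)

  ## independent cross-check: random-intercept ML fit in nlme
  skip_if_not_installed("nlme")
  lf <- nlme::lme(Y ~ 1, random = ~ 1 | ID, data = g, method = "ML")
  expect_equal(unname(fit$means), unname(nlme::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$sigma, lf$sigma^2, tolerance = 1e-3)
  expect_equal(fit$omega, as.numeric(nlme::VarCorr(lf)[1, "Variance"]),
               tolerance = 1e-3)
  ## OFV differs from lme's -2 logLik only by the n*log(2*pi) constant
  expect_equal(fit$ofv, -2 * as.numeric(stats::logLik(lf)) -
                 m * n * log(2 * pi), tolerance = 1e-4)
})

test_that("extended fit with one bin reproduces the base fit", {
  set.seed(43)
  g <- make_grouped(rnorm(200), rep(1:20, each = 10))
  bins <- bin_spec(numeric(0), "IDV")
  base <- fit_base(g)
  ext <- fit_extended(g, bins)
  expect_equal(ext$ofv, base$ofv, tolerance = 1e-6)
  expect_equal(ext$means, base$means, tolerance = 1e-6)
})

test_that("extended fit recovers an injected bin-specific bias", {
  set.seed(44)
  m <- 200; n <- 10
  id <- rep(seq_len(m), each = n)
  idv <- rep(seq_len(n), m)
  y <- rnorm(m * n) + ifelse(idv <= 3, 0.5, 0)
  g <- make_grouped(y, id, idv)
  bins <- bin_spec(c(3.5, 6.5), "IDV")
  ext <- fit_extended(g, bins)
  expect_equal(unname(ext$means[1]), 0.5, tolerance = 0.15)
  expect_lt(max(abs(ext$means[2:3])), 0.1)
  ## nesting: extended never fits worse than base
  base <- fit_base(g)
  expect_gte(base$ofv - ext$ofv, -1e-3)
  ## dense oracle agreement for the binned model too
  expect_equal(cs_dense_ofv(id, y, bin_assign(idv, bins), ext$means,
                            ext$omega, ext$sigma),
               ext$ofv, tolerance = 1e-8)
})

test_that("empty bins are rejected by name", {
  g <- make_grouped(rnorm(20), rep(1:2, each = 10), idv = rep(1:10, 2))
  bins <- bin_spec(c(2.5, 20), "IDV")   # third bin empty: no idv > 20
  expect_error(fit_extended(g, bins), "empty bin")
})

test_that("bias_test applies the chi-square rule and sign convention", {
  base <- structure(list(ofv = 110), class = "cwres_bias_fit")
  ext <- structure(list(ofv = 95, n_bins = 5), class = "cwres_bias_fit")
  tst <- bias_test(base, ext)
  expect_equal(tst$delta_ofv, 15)
  expect_equal(tst$df, 5)
  expect_equal(tst$critical_value, qchisq(0.95, 5), tolerance = 1e-10)
  expect_true(tst$significant)

  ## identical fits: delta 0, not significant
  tst0 <- bias_test(base, structure(list(ofv = 110, n_bins = 5),
                                    class = "cwres_bias_fit"))
  expect_equal(tst0$delta_ofv, 0)
  expect_false(tst0$significant)

  ## df = N - 1 convention available
  expect_equal(bias_test(base, ext, df = 4)$df, 4)

  ## optimizer-failure signal
  expect_warning(bias_test(structure(list(ofv = 94), class = "cwres_bias_fit"),
                           ext), "refit")
})

test_that("null dOFV distribution is roughly chi-square(N)", {
  set.seed(45)
  reps <- 120
  m <- 30; n <- 16
  dofv <- replicate(reps, {
    id <- rep(seq_len(m), each = n)
    idv <- rep(seq_len(n), m)
    g <- make_grouped(rnorm(m * n), id, idv)
    bins <- density_bins(idv, 4, 1, "IDV")
    fit_base(g)$ofv - fit_extended(g, bins)$ofv
  })
  expect_true(all(dofv > -1e-3))
  ## rejection at the chi-square(N) critical value stays near or below 5%
  rej <- mean(dofv > qchisq(0.95, 4))
  expect_lt(rej, 0.12)
  ## empirical 95th percentile within 20% of the chi-square quantile
  ## (conservative: the extension only adds N - 1 parameters)
  expect_lt(quantile(dofv, 0.95), 1.2 * qchisq(0.95, 4))
})

test_that("cwres_grouped restricts to one DV and carries the IDV", {
  m <- pk_model_onecomp()
  d <- simulate_dataset(m, make_ivgtt_protocol(), 3, seed = 9)
  cw <- compute_cwres(m, d)
  g_t <- cwres_grouped(cw, dv = "conc", idv = "TIME")
  g_p <- cwres_grouped(cw, dv = "conc", idv = "PRED_conc")
  expect_equal(nrow(g_t), nrow(cw))
  expect_equal(g_t$Y, cw$CWRES)
  expect_equal(g_p$IDV, cw$PRED_conc)
  expect_error(cwres_grouped(cw, idv = "PRED_missing"), "not found")
})
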