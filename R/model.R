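#' Construct an NLME model specification
#'
#' Bundles a structural prediction function, a residual-error model per
#' dependent variable (DV), and population parameter values: fixed effects
#' `theta`, between-subject random-effect covariance `omega` (variance of
#' eta), and residual-error variances `sigma`.
#'
#' The structural function has signature `function(theta, eta, design)` where
#' `design` is one subject's data rows (NONMEM-style columns `ID`, `TIME`,
#' `AMT`, `EVID`, `DVID`, `MDV`); it must return one finite prediction per
#' observation row (`EVID == 0`), in row order.
#'
#' @param structural prediction function (see Details).
#' @param error named character vector, one entry per DV label, each one of
#'   `"additive"`, `"proportional"`, `"combined"`.
#' @param theta numeric vector of fixed effects.
#' @param omega positive semi-definite covariance matrix of the subject-level
#'   random effects eta.
#' @param sigma named list, one entry per DV label; each entry a named numeric
#'   vector with elements `add` and/or `prop` (variances) matching the error
#'   model: `additive` needs `add`, `proportional` needs `prop`, `combined`
#'   needs both.
#' @param dv_labels character vector of DV names (e.g. `c("glucose","insulin")`).
#' @param name display name.
#' @param pred_fast optional vectorized shortcut with signature
#'   `function(theta, eta, times, dvid, dose_t, dose_amt)` returning the
#'   same predictions as `structural` for bolus designs; used by the
#'   estimation loops to avoid per-evaluation data.frame handling.
#' @return an object of class `nlme_model`.
#' @export
nlme_model <- function(structural, error, theta, omega, sigma,
                       dv_labels = "dv", name = "nlme_model",
                       pred_fast = NULL) {
  stopifnot(is.function(structural), is.numeric(theta))
  if (is.null(names(error))) names(error) <- dv_labels
  error <- vapply(error, function(e)
    match.arg(e, c("additive", "proportional", "combined")), character(1))
  if (!setequal(names(error), dv_labels))
    stop("error model must name every DV label")
  omega <- check_psd(as.matrix(omega), "omega")
  if (is.null(names(sigma))) names(sigma) <- dv_labels
  for (dv in dv_labels) {
    s <- sigma[[dv]]
    need <- switch(error[[dv]], additive = "add", proportional = "prop",
                   combined = c("prop", "add"))
    if (!all(need %in% names(s)))
      stop("sigma[['", dv, "']] must contain ", paste(need, collapse = " and "))
    if (any(s < 0)) stop("sigma variances must be >= 0")
  }
  structure(list(structural = structural, error = error, theta = theta,
                 omega = omega, sigma = sigma, dv_labels = dv_labels,
                 name = name, pred_fast = pred_fast),
            class = "nlme_model")
}

#' @export
print.nlme_model <- function(x, ...) {
  cat("<nlme_model> ", x$name, "\n", sep = "")
  cat("  DVs:   ", paste(x$dv_labels, collapse = ", "), "\n", sep = "")
  cat("  theta: ", paste(signif(x$theta, 4), collapse = ", "), "\n", sep = "")
  cat("  omega diag: ", paste(signif(diag(x$omega), 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## Residual-error variance per observation given predictions f for one DV.
resid_var <- function(model, f, dv) {
  s <- model$sigma[[dv]]
  switch(model$error[[dv]],
         additive     = rep(s[["add"]], length(f)),
         proportional = s[["prop"]] * f^2,
         combined     = s[["prop"]] * f^2 + s[["add"]])
}

## Simulate the residual-error transform y = h(f, eps) for one DV.
apply_error <- function(model, f, dv) {
  s <- model$sigma[[dv]]
  n <- length(f)
  switch(model$error[[dv]],
         additive     = f + stats::rnorm(n, sd = sqrt(s[["add"]])),
         proportional = f * (1 + stats::rnorm(n, sd = sqrt(s[["prop"]]))),
         combined     = f * (1 + stats::rnorm(n, sd = sqrt(s[["prop"]]))) +
                        stats::rnorm(n, sd = sqrt(s[["add"]])))
}

## Replace population parameters, keeping structure/error untouched.
set_params <- function(model, theta = NULL, omega = NULL, sigma = NULL) {
  if (!is.null(theta)) model$theta <- theta
  if (!is.null(omega)) model$omega <- symmetrize(as.matrix(omega))
  if (!is.null(sigma)) model$sigma <- sigma
  model
}

#' Split a NONMEM-style dataset into per-subject records
#'
#' @param data data.frame with columns `ID`, `TIME`, `AMT`, `DV`, `DVID`,
#'   `EVID`, `MDV` (`EVID` 1 = dose, 0 = observation; `MDV` 1 = missing).
#' @return list of subject records, each with `id`, `design` (all rows),
#'   `obs` (DV values for non-missing observation rows), `obs_rows` (indices
#'   of those rows within `design`), `dvid` (DV labels of those rows).
#' @export
split_subjects <- function(data) {
  req <- c("ID", "TIME", "AMT", "DV", "DVID", "EVID", "MDV")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  lapply(split(data, factor(data$ID, levels = unique(data$ID))), function(d) {
    if (is.unsorted(d$TIME)) stop("times not non-decreasing for subject ", d$ID[1])
    rows <- which(d$EVID == 0 & d$MDV == 0)
    evid0 <- which(d$EVID == 0)
    dose <- d$EVID == 1 & d$AMT > 0
    list(id = d$ID[1], design = d, obs = d$DV[rows], obs_rows = rows,
         dvid = d$DVID[rows], times = d$TIME[rows],
         # precomputed fast-path fields
         obs_in_evid0 = match(rows, evid0),
         evid0_times = d$TIME[evid0], evid0_dvid = d$DVID[evid0],
         dose_t = d$TIME[dose], dose_amt = d$AMT[dose])
  })
}

## Evaluate the structural model for one subject; returns predictions for
## non-missing observation rows.
subject_pred <- function(model, subject, eta) {
  if (!is.null(model$pred_fast)) {
    f_all <- model$pred_fast(model$theta, eta, subject$evid0_times,
                             subject$evid0_dvid, subject$dose_t,
                             subject$dose_amt)
  } else {
    f_all <- model$structural(model$theta, eta, subject$design)
  }
  f <- f_all[subject$obs_in_evid0]
  if (length(f) != length(subject$obs))
    stop("structural prediction length mismatch for subject ", subject$id)
  f
}

#' Define a sampling protocol
#'
#' A single-bolus design: one dose event followed by observation rows at the
#' given times (one row per time per DV).
#'
#' @param times observation times (non-decreasing).
#' @param dose_amt dose amount placed at `dose_time`.
#' @param dose_time time of the bolus (default 0).
#' @param dvid integer DV index for the observation rows.
#' @return object of class `sampling_protocol`.
#' @export
sampling_protocol <- function(times, dose_amt, dose_time = 0, dvid = 1L) {
  stopifnot(!is.unsorted(times), dose_amt >= 0)
  structure(list(times = times, dose_amt = dose_amt, dose_time = dose_time,
                 dvid = as.integer(dvid)),
            class = "sampling_protocol")
}

#' Simulate a dataset from an NLME model
#'
#' Draws independent subject random effects eta ~ N(0, Omega) and residual
#' errors eps ~ N(0, Sigma), and records observations `y = h(f(theta, eta),
#' eps)` on the protocol's design.
#'
#' @param model an [nlme_model()].
#' @param protocol a [sampling_protocol()].
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the simulation is reproducible given the seed.
#' @return data.frame with columns `ID, TIME, AMT, DV, DVID, EVID, MDV`.
#' @export
simulate_dataset <- function(model, protocol, n_subjects, seed = NULL) {
  stopifnot(n_subjects >= 1)
  check_psd(model$omega, "omega")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(model$omega)
  Lw <- t(chol(model$omega + diag(1e-14, k)))   # exact zeros allowed
  if (all(diag(model$omega) == 0)) Lw <- matrix(0, k, k)
  tmpl <- data.frame(
    TIME = c(protocol$dose_time, protocol$times),
    AMT  = c(protocol$dose_amt, rep(0, length(protocol$times))),
    DV   = NA_real_,
    DVID = c(protocol$dvid[1], rep_len(protocol$dvid, length(protocol$times))),
    EVID = c(1L, rep(0L, length(protocol$times))),
    MDV  = c(1L, rep(0L, length(protocol$times))))
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    d <- cbind(ID = i, tmpl)
    eta <- drop(Lw %*% stats::rnorm(k))
    obs_rows <- which(d$EVID == 0)
    f <- model$structural(model$theta, eta, d)
    for (dv_idx in unique(d$DVID[obs_rows])) {
      sel <- which(d$DVID[obs_rows] == dv_idx)
      dv <- model$dv_labels[dv_idx]
      d$DV[obs_rows[sel]] <- apply_error(model, f[sel], dv)
    }
    out[[i]] <- d
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
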