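## FOCE machinery: empirical Bayes estimation, linearization around the EBEs,
## conditional moments, CWRES, the FOCE objective and population fitting.

## -2 log individual conditional likelihood + prior penalty.
## With interaction the residual variance follows the individual predictions;
## without, it is fixed at the population predictions.
ebe_objective <- function(model, subject, Oinv, interaction = TRUE,
                          v_pop = NULL) {
  y <- subject$obs
  dv_of <- model$dv_labels[subject$dvid]
  groups <- lapply(unique(dv_of), function(dv)
    list(dv = dv, sel = which(dv_of == dv)))
  single <- length(groups) == 1L
  dv1 <- groups[[1]]$dv
  pf <- model$pred_fast
  theta <- model$theta
  if (!is.null(pf)) {
    tt <- subject$evid0_times
    dvv <- subject$evid0_dvid
    dt <- subject$dose_t
    da <- subject$dose_amt
    sel_obs <- subject$obs_in_evid0
  }
  function(eta) {
    f <- if (!is.null(pf)) pf(theta, eta, tt, dvv, dt, da)[sel_obs]
         else tryCatch(subject_pred(model, subject, eta),
                       error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(1e10)
    if (interaction) {
      if (single) {
        v <- resid_var(model, f, dv1)
      } else {
        v <- numeric(length(f))
        for (g in groups) v[g$sel] <- resid_var(model, f[g$sel], g$dv)
      }
    } else v <- v_pop
    v <- pmax(v, 1e-12)
    sum(log(v) + (y - f)^2 / v) + drop(eta %*% Oinv %*% eta)
  }
}

#' Estimate empirical Bayes estimates (EBEs) for one subject
#'
#' Minimizes the individual FOCE objective (-2 log conditional likelihood
#' plus the normal prior penalty `eta' Omega^-1 eta`) by quasi-Newton search
#' from `eta = 0` plus one alternating-sign deterministic restart at one
#' prior standard deviation, keeping the best optimum.
#'
#' @param model an [nlme_model()].
#' @param subject one record from [split_subjects()].
#' @param interaction logical; evaluate the residual variance at the
#'   individual predictions (FOCE-I, default) or at the population
#'   predictions.
#' @param start optional warm-start eta.
#' @param multistart logical; add the deterministic restart (default TRUE).
#' @return list with `eta_hat`, `objective`, `converged`.
#' @export
estimate_ebes <- function(model, subject, interaction = TRUE, start = NULL,
                          multistart = TRUE) {
  k <- nrow(model$omega)
  od <- diag(model$omega)
  if (all(od < 1e-12))
    return(list(eta_hat = rep(0, k), objective = NA_real_, converged = TRUE))
  Oinv <- solve(model$omega + diag(1e-12 * max(od), k))
  v_pop <- NULL
  if (!interaction) {
    f0 <- subject_pred(model, subject, rep(0, k))
    dv_of <- model$dv_labels[subject$dvid]
    v_pop <- numeric(length(f0))
    for (dv in unique(dv_of)) {
      sel <- dv_of == dv
      v_pop[sel] <- resid_var(model, f0[sel], dv)
    }
  }
  obj <- ebe_objective(model, subject, Oinv, interaction, v_pop)
  starts <- list(rep(0, k))
  if (!is.null(start)) starts <- c(list(start), starts)
  if (multistart)
    starts <- c(starts, list(sqrt(od) * rep_len(c(1, -1), k)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 150, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("EBE estimation failed for subject ", subject$id)
  list(eta_hat = best$par, objective = best$value,
       converged = best$convergence == 0)
}

## Jacobian df/deta by central finite differences, relative step 1e-4.
jac_eta_fd <- function(model, subject, eta) {
  k <- length(eta)
  n <- length(subject$obs)
  J <- matrix(0, n, k)
  for (j in seq_len(k)) {
    h <- 1e-4 * max(1, abs(eta[j]))
    ep <- eta; ep[j] <- ep[j] + h
    em <- eta; em[j] <- em[j] - h
    J[, j] <- (subject_pred(model, subject, ep) -
               subject_pred(model, subject, em)) / (2 * h)
  }
  J
}

#' Conditional moments of the FOCE-linearized individual model
#'
#' Linearizes the structural model around the EBEs `eta_hat`:
#' the conditional expectation is `f(theta, eta_hat) - J eta_hat` with
#' `J = df/deta` at `eta_hat`, and the conditional covariance is
#' `J Omega J' + diag(v)` where `v` is the residual-error variance
#' (evaluated at the individual predictions when `interaction = TRUE`,
#' at the population predictions otherwise). A diagonal jitter is applied
#' if the covariance is numerically singular.
#'
#' @inheritParams estimate_ebes
#' @param eta_hat EBE vector for the subject.
#' @return list of class `individual_conditional` with `eta_hat`, `jac_eta`,
#'   `expectation`, `covariance`, `f_ind` (individual predictions), `v`
#'   (residual variance diagonal) and bookkeeping fields.
#' @export
conditional_moments <- function(model, subject, eta_hat, interaction = TRUE) {
  stopifnot(all(is.finite(eta_hat)))
  f_hat <- subject_pred(model, subject, eta_hat)
  J <- jac_eta_fd(model, subject, eta_hat)
  expectation <- drop(f_hat - J %*% eta_hat)
  f_for_v <- if (interaction) f_hat else
    subject_pred(model, subject, rep(0, length(eta_hat)))
  dv_of <- model$dv_labels[subject$dvid]
  v <- numeric(length(f_hat))
  for (dv in unique(dv_of)) {
    sel <- dv_of == dv
    v[sel] <- resid_var(model, f_for_v[sel], dv)
  }
  covv <- symmetrize(J %*% model$omega %*% t(J)) + diag(v, length(v))
  covv <- jitter_spd(covv)
  jittered <- attr(covv, "jittered")
  attr(covv, "jittered") <- NULL
  structure(list(id = subject$id, eta_hat = eta_hat, jac_eta = J,
                 jittered = jittered,
                 expectation = expectation, covariance = covv,
                 f_ind = f_hat, v = v, y = subject$obs,
                 times = subject$times, dvid = subject$dvid),
            class = "individual_conditional")
}

#' FOCE conditionals for every subject in a dataset
#'
#' Runs [estimate_ebes()] and [conditional_moments()] per subject. Subjects
#' whose EBE search fails to converge are dropped with a warning.
#'
#' @param model an [nlme_model()].
#' @param data NONMEM-style dataset (see [split_subjects()]).
#' @param interaction see [estimate_ebes()].
#' @param multistart see [estimate_ebes()].
#' @return list of `individual_conditional` objects, one per retained subject.
#' @export
foce_conditionals <- function(model, data, interaction = TRUE,
                              multistart = TRUE) {
  subs <- split_subjects(data)
  out <- vector("list", length(subs))
  keep <- logical(length(subs))
  for (i in seq_along(subs)) {
    eb <- estimate_ebes(model, subs[[i]], interaction = interaction,
                        multistart = multistart)
    if (!eb$converged) next
    out[[i]] <- conditional_moments(model, subs[[i]], eb$eta_hat,
                                    interaction = interaction)
    keep[i] <- TRUE
  }
  if (!all(keep))
    warning(sum(!keep), " subject(s) dropped: EBE search did not converge")
  out[keep]
}

## Population predictions (eta = 0, per DV) for each subject, evaluated with
## the observation rows' DVID overridden so any DV's prediction is available
## on every row.
population_pred <- function(model, subject) {
  k <- nrow(model$omega)
  sapply(seq_along(model$dv_labels), function(dv_idx) {
    d <- subject$design
    d$DVID[d$EVID == 0] <- dv_idx
    s2 <- subject
    s2$design <- d
    s2$evid0_dvid <- rep(dv_idx, length(subject$evid0_dvid))
    subject_pred(model, s2, rep(0, k))
  })
}

#' Compute conditional weighted residuals (CWRES)
#'
#' For each subject, `r = COV(Y)^{-1/2} (y - E(Y))` with the conditional
#' moments from the FOCE linearization around the EBEs. The inverse square
#' root is the symmetric (eigendecomposition) root by default; Cholesky is
#' available and is used consistently by [correct_predictions()].
#'
#' @inheritParams foce_conditionals
#' @param sqrt_method `"symmetric"` (default) or `"cholesky"`.
#' @param conditionals optional precomputed result of [foce_conditionals()].
#' @return data.frame of class `cwres_table` with columns `ID`, `ROW`
#'   (within-subject observation index), `DVID` (DV label), `TIME`,
#'   `PRED_<dv>` (population predictions, one column per DV, on every row)
#'   and `CWRES`.
#' @export
compute_cwres <- function(model, data, interaction = TRUE,
                          sqrt_method = c("symmetric", "cholesky"),
                          conditionals = NULL) {
  sqrt_method <- match.arg(sqrt_method)
  if (is.null(conditionals))
    conditionals <- foce_conditionals(model, data, interaction = interaction)
  subs <- split_subjects(data)
  subs <- subs[match(vapply(conditionals, `[[`, subs[[1]]$id, "id"),
                     vapply(subs, `[[`, subs[[1]]$id, "id"))]
  rows <- lapply(seq_along(conditionals), function(i) {
    cm <- conditionals[[i]]
    W <- cov_sqrt(cm$covariance, inverse = TRUE, method = sqrt_method)
    r <- drop(W %*% (cm$y - cm$expectation))
    if (any(!is.finite(r)))
      stop("non-finite CWRES for subject ", cm$id)
    preds <- population_pred(model, subs[[i]])
    preds <- matrix(preds, ncol = length(model$dv_labels))
    out <- data.frame(ID = cm$id, ROW = seq_along(r),
                      DVID = model$dv_labels[cm$dvid], TIME = cm$times)
    for (j in seq_along(model$dv_labels))
      out[[paste0("PRED_", model$dv_labels[j])]] <- preds[, j]
    out$CWRES <- r
    out
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(tab) <- c("cwres_table", "data.frame")
  attr(tab, "dv_labels") <- model$dv_labels
  attr(tab, "sqrt_method") <- sqrt_method
  tab
}

#' FOCE objective function value of a dataset under a model
#'
#' Sum over subjects of the -2 log-likelihood of the FOCE-linearized
#' marginal model `y_i ~ N(E(Y_i), COV(Y_i))`, excluding the `n log(2 pi)`
#' constant (NONMEM convention).
#'
#' @inheritParams foce_conditionals
#' @param conditionals optional precomputed [foce_conditionals()] result.
#' @return scalar OFV.
#' @export
foce_ofv <- function(model, data, interaction = TRUE, conditionals = NULL) {
  if (is.null(conditionals))
    conditionals <- foce_conditionals(model, data, interaction = interaction)
  contrib <- vapply(conditionals, function(cm) {
    val <- tryCatch(mvn_m2ll(cm$y - cm$expectation, cm$covariance),
                    error = function(e) NaN)
    if (!is.finite(val))
      stop("non-finite OFV contribution for subject ", cm$id)
    val
  }, numeric(1))
  sum(contrib)
}

#' Fit population parameters by minimizing the FOCE objective
#'
#' Optimizes `theta` (log scale when `log_theta = TRUE`), the diagonal of
#' `omega`, and the residual variances (both log scale) over the FOCE
#' objective, re-estimating the EBEs at every evaluation with warm starts
#' carried between evaluations.
#'
#' @inheritParams foce_conditionals
#' @param inits optional list with elements `theta`, `omega_diag`, `sigma`
#'   (same shapes as the model's); defaults to the model's current values.
#' @param log_theta optimize theta on the log scale (requires positive
#'   theta; default TRUE, appropriate for PK rate/volume parameters).
#' @param method optimizer passed to [stats::optim()].
#' @param control control list for [stats::optim()].
#' @return list of class `foce_fit`: fitted `model`, `theta`, `omega`,
#'   `sigma`, final `ofv`, `convergence` code and `counts`.
#' @export
fit_population <- function(model, data, inits = NULL, interaction = TRUE,
                           log_theta = TRUE, method = "Nelder-Mead",
                           control = list(maxit = 800, reltol = 1e-8)) {
  if (is.null(inits))
    inits <- list(theta = model$theta, omega_diag = diag(model$omega),
                  sigma = model$sigma)
  sig_template <- inits$sigma
  sig_flat <- unlist(sig_template)
  if (log_theta && any(inits$theta <= 0))
    stop("log_theta = TRUE requires positive theta inits")
  if (any(inits$omega_diag <= 0) || any(sig_flat <= 0))
    stop("variance inits must be positive")
  n_th <- length(inits$theta)
  n_om <- length(inits$omega_diag)
  par0 <- c(if (log_theta) log(inits$theta) else inits$theta,
            log(inits$omega_diag), log(sig_flat))
  subs <- split_subjects(data)
  warm <- new.env(parent = emptyenv())
  warm$eta <- vector("list", length(subs))

  unpack <- function(p) {
    th <- p[seq_len(n_th)]
    if (log_theta) th <- exp(th)
    om <- exp(p[n_th + seq_len(n_om)])
    sg <- utils::relist(exp(p[(n_th + n_om + 1):length(p)]), sig_template)
    set_params(model, theta = th, omega = diag(om, n_om), sigma = sg)
  }
  objective <- function(p) {
    m <- unpack(p)
    tot <- 0
    for (i in seq_along(subs)) {
      eb <- tryCatch(
        estimate_ebes(m, subs[[i]], interaction = interaction,
                      start = warm$eta[[i]], multistart = is.null(warm$eta[[i]])),
        error = function(e) NULL)
      if (is.null(eb)) return(1e10)
      warm$eta[[i]] <- eb$eta_hat
      cm <- conditional_moments(m, subs[[i]], eb$eta_hat,
                                interaction = interaction)
      val <- tryCatch(mvn_m2ll(cm$y - cm$expectation, cm$covariance),
                      error = function(e) NaN)
      if (!is.finite(val)) return(1e10)
      tot <- tot + val
    }
    tot
  }
  opt <- stats::optim(par0, objective, method = method, control = control)
  fitted <- unpack(opt$par)
  structure(list(model = fitted, theta = fitted$theta,
                 omega = fitted$omega, sigma = fitted$sigma,
                 ofv = opt$value, convergence = opt$convergence,
                 counts = opt$counts),
            class = "foce_fit")
}

#' @export
print.foce_fit <- function(x, ...) {
  cat("<foce_fit> OFV = ", format(x$ofv, digits = 8),
      if (x$convergence != 0) "  [did not converge]", "\n", sep = "")
  cat("  theta: ", paste(signif(x$theta, 5), collapse = ", "), "\n", sep = "")
  cat("  omega diag: ", paste(signif(diag(x$omega), 4), collapse = ", "),
      "\n  sigma: ", paste(signif(unlist(x$sigma), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Conditional predictions per observation
#'
#' Returns the FOCE conditional expectation `E(Y_i)` aligned to the CWRES
#' table row order (subjects in dataset order, observations in time order).
#'
#' @inheritParams foce_conditionals
#' @param conditionals optional precomputed [foce_conditionals()] result.
#' @return numeric vector of conditional predictions.
#' @export
conditional_predictions <- function(model, data, interaction = TRUE,
                                    conditionals = NULL) {
  if (is.null(conditionals))
    conditionals <- foce_conditionals(model, data, interaction = interaction)
  unlist(lapply(conditionals, `[[`, "expectation"), use.names = FALSE)
}
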