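## Mixed-effects modeling of CWRES: base model y_ij = Theta_1 + eta_i + eps_ij
## and its bin-mean extension, fitted by exact maximum likelihood.
## Per subject the marginal covariance is V_i = Omega J + Sigma I (compound
## symmetry), whose inverse and determinant have closed forms, so the
## profiled -2 log likelihood reduces to per-subject sufficient statistics
## (bin counts, bin sums, total sum, total sum of squares) that are computed
## once per fit.

#' Group a CWRES table for bias modeling
#'
#' Restricts a [compute_cwres()] table to one DV and attaches the chosen
#' independent variable (IDV) used for binning.
#'
#' @param cwres a `cwres_table` (or data.frame with `ID`, `CWRES` and the
#'   IDV column).
#' @param dv DV label to keep; `NULL` (default) keeps all rows (valid for
#'   single-DV tables).
#' @param idv name of the IDV column: `"TIME"` or one of the `PRED_<dv>`
#'   columns.
#' @return data.frame of class `cwres_grouped` with columns `ID`, `Y`
#'   (the CWRES values), `IDV`, plus `DVID` and `ROW` carried through when
#'   present.
#' @export
cwres_grouped <- function(cwres, dv = NULL, idv = "TIME") {
  if (!idv %in% names(cwres))
    stop("IDV column '", idv, "' not found")
  if (!is.null(dv)) cwres <- cwres[cwres$DVID == dv, , drop = FALSE]
  if (nrow(cwres) == 0) stop("no observations after DV restriction")
  out <- data.frame(ID = cwres$ID, Y = cwres$CWRES, IDV = cwres[[idv]])
  for (col in intersect(c("DVID", "ROW"), names(cwres)))
    out[[col]] <- cwres[[col]]
  attr(out, "idv_name") <- idv
  attr(out, "dv") <- dv
  class(out) <- c("cwres_grouped", "data.frame")
  out
}

## Sufficient statistics for the profiled compound-symmetry likelihood.
## Returns per-subject bin counts (N x m), bin sums (N x m), totals.
bias_suffstats <- function(id, y, bin) {
  id <- factor(id, levels = unique(id))
  bin <- factor(bin, levels = seq_len(max(bin)))
  counts <- table(bin, id)                    # N x m
  sums <- tapply(y, list(bin, id), sum)
  sums[is.na(sums)] <- 0
  list(counts = unclass(counts), sums = unname(sums),
       n_i = colSums(unclass(counts)),
       ty = tapply(y, id, sum), tyy = tapply(y^2, id, sum),
       m = nlevels(id), n = length(y))
}

## Profiled -2 log likelihood (no 2*pi constant) at (omega, sigma);
## returns the OFV and the GLS bin means.
bias_profile_ofv <- function(ss, omega, sigma) {
  ci <- omega / (sigma * (sigma + ss$n_i * omega))    # Woodbury weight per subj
  A <- diag(rowSums(ss$counts) / sigma, nrow(ss$counts)) -
    (ss$counts * rep(ci, each = nrow(ss$counts))) %*% t(ss$counts)
  rhs <- rowSums(ss$sums) / sigma -
    drop(ss$counts %*% (ci * ss$ty))
  theta <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(theta)) return(list(ofv = Inf, means = NULL))
  yVy <- sum(ss$tyy) / sigma - sum(ci * ss$ty^2)
  quad <- yVy - 2 * sum(theta * rhs) + drop(theta %*% A %*% theta)
  logdet <- sum(ss$n_i) * log(sigma) + sum(log1p(ss$n_i * omega / sigma))
  list(ofv = logdet + quad, means = theta)
}

fit_bias_model <- function(grouped, bins = NULL) {
  y <- grouped$Y
  id <- grouped$ID
  if (length(unique(id)) < 2 || length(y) < 2)
    stop("need at least 2 subjects and 2 observations")
  if (is.null(bins)) {
    bin <- rep(1L, length(y))
    n_bins <- 1L
  } else {
    bin <- bin_assign(grouped$IDV, bins)
    n_bins <- bins$n_bins
    empty <- setdiff(seq_len(n_bins), unique(bin))
    if (length(empty))
      stop("empty bin(s): ", paste(empty, collapse = ", "))
  }
  ss <- bias_suffstats(id, y, bin)
  if (!is.null(bins) && nrow(ss$counts) < n_bins)
    ss$counts <- rbind(ss$counts,
                       matrix(0, n_bins - nrow(ss$counts), ss$m))
  vy <- max(stats::var(y), 1e-8)
  obj <- function(p) bias_profile_ofv(ss, p[1], p[2])$ofv
  lower <- c(1e-10, 1e-10)
  starts <- list(c(0.1 * vy, 0.9 * vy), c(1e-8, vy), c(0.5 * vy, 0.5 * vy))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmax(s, lower), obj, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("bias-model optimization failed")
  prof <- bias_profile_ofv(ss, best$par[1], best$par[2])
  boundary <- c(omega = best$par[1] <= 10 * lower[1],
                sigma = best$par[2] <= 10 * lower[2])
  structure(list(means = unname(drop(prof$means)), omega = best$par[1],
                 sigma = best$par[2], ofv = best$value,
                 converged = best$convergence == 0, boundary = boundary,
                 n_bins = n_bins, bins = bins,
                 n_obs = ss$n, n_subjects = ss$m),
            class = "cwres_bias_fit")
}

#' Fit the base CWRES model
#'
#' Exact maximum likelihood for `y_ij = Theta_1 + eta_i + eps_ij` with
#' `eta_i ~ N(0, Omega)` and `eps_ij ~ N(0, Sigma)`: the mean is profiled
#' out by GLS and `(Omega, Sigma)` are optimized within bounds. For CWRES
#' from a correctly specified model the expected estimates are
#' `Theta_1 = 0`, `Omega = 0`, `Sigma = 1`.
#'
#' @param grouped a [cwres_grouped()] data.frame.
#' @return object of class `cwres_bias_fit` with `means` (length 1),
#'   `omega`, `sigma`, `ofv` (-2 log likelihood without the 2 pi constant),
#'   `converged` and `boundary` flags.
#' @export
fit_base <- function(grouped) fit_bias_model(grouped, bins = NULL)

#' Fit the bin-mean extended CWRES model
#'
#' As [fit_base()], but with a separate mean `Theta_k` for each IDV bin
#' (the CWRES bias vector `b`), sharing a single `eta_i` and `Sigma`
#' across bins. All means are profiled jointly by GLS.
#'
#' @param grouped a [cwres_grouped()] data.frame.
#' @param bins a [bin_spec()] on the grouped IDV; every bin must be
#'   nonempty.
#' @return `cwres_bias_fit` with `means` of length `bins$n_bins`.
#' @export
fit_extended <- function(grouped, bins) {
  stopifnot(inherits(bins, "bin_spec"))
  fit_bias_model(grouped, bins = bins)
}

#' @export
print.cwres_bias_fit <- function(x, ...) {
  cat("<cwres_bias_fit> ", x$n_bins, " bin(s), ", x$n_subjects,
      " subjects, ", x$n_obs, " obs\n", sep = "")
  cat("  means: ", paste(signif(x$means, 4), collapse = ", "), "\n", sep = "")
  cat("  omega = ", signif(x$omega, 4), ", sigma = ", signif(x$sigma, 4),
      ", OFV = ", format(x$ofv, digits = 8), "\n", sep = "")
  if (any(x$boundary))
    cat("  boundary: ", paste(names(x$boundary)[x$boundary], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test for CWRES bias
#'
#' Computes `dOFV_bias = OFV_base - OFV_extended` (nonnegative improvement
#' for nested fits) and compares it with the upper `level` chi-square
#' quantile. The default degrees of freedom equal the number of bins `N`;
#' `df = N - 1` (the number of added mean parameters) is available via the
#' `df` argument.
#'
#' @param base fit from [fit_base()].
#' @param extended fit from [fit_extended()] on the same grouped data.
#' @param df degrees of freedom; default `extended$n_bins`.
#' @param level significance level (default 0.05).
#' @return object of class `cwres_bias_test` with `ofv_base`,
#'   `ofv_extended`, `delta_ofv`, `df`, `critical_value`, `significant`.
#' @export
bias_test <- function(base, extended, df = NULL, level = 0.05) {
  if (is.null(df)) df <- extended$n_bins
  delta <- base$ofv - extended$ofv
  if (delta < -1e-3)
    warning("extended OFV above base OFV (delta = ", signif(delta, 4),
            "): optimizer failure, refit advised")
  crit <- stats::qchisq(1 - level, df)
  structure(list(ofv_base = base$ofv, ofv_extended = extended$ofv,
                 delta_ofv = delta, df = df, level = level,
                 critical_value = crit, significant = delta > crit),
            class = "cwres_bias_test")
}

#' @export
print.cwres_bias_test <- function(x, ...) {
  cat("<cwres_bias_test> dOFV_bias = ", signif(x$delta_ofv, 5),
      " on df = ", x$df, " (critical ", signif(x$critical_value, 5), "): ",
      if (x$significant) "SIGNIFICANT" else "not significant", "\n", sep = "")
  invisible(x)
}
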