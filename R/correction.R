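## Back-correction of conditional-prediction bias: the bin-mean bias vector
## b estimated on CWRES is expanded to observation level and mapped back
## through the conditional covariance, delta_i = -COV(Y_i)^{1/2} %*% b`,
## inverting the whitening that defines CWRES. The corrected conditional
## prediction is E(Y_i) - delta_i.

#' Expand a bin-mean bias vector to observation level
#'
#' @param b bias vector of length `bins$n_bins` (the estimated bin means).
#' @param bins a [bin_spec()].
#' @param idv_per_obs IDV value of each observation.
#' @return numeric vector `b`` with `b`[j] = b[bin(idv[j])]`; IDV values
#'   outside the spec's range fall in the nearest edge bin with a warning.
#' @export
expand_bias <- function(b, bins, idv_per_obs) {
  stopifnot(length(b) == bins$n_bins)
  if (!is.null(bins$range) &&
      any(idv_per_obs < bins$range[1] | idv_per_obs > bins$range[2]))
    warning("IDV values outside the bin range assigned to edge bins")
  b[bin_assign(idv_per_obs, bins)]
}

#' Correct conditional predictions for estimated CWRES bias
#'
#' Per subject, `delta_i = -COV(Y_i)^{1/2} %*% b`_i` with the same matrix
#' square-root convention used by [compute_cwres()], and the corrected
#' conditional prediction is `E(Y_i) - delta_i`. The percentage bias
#' `%delta = 100 * delta / E(Y_i)` is suppressed (NA) where the prediction
#' is within `pct_threshold_rel` times the dataset-wide mean absolute
#' prediction of zero; the absolute `delta` is always retained.
#'
#' @param conditionals list of per-subject conditionals from
#'   [foce_conditionals()] (from the model whose predictions are being
#'   corrected).
#' @param b estimated bias vector (bin means) for the grouped DV.
#' @param bins the [bin_spec()] that `b` was estimated under.
#' @param grouped the [cwres_grouped()] table the bias model was fitted to;
#'   rows must correspond, subject by subject and in order, to the
#'   conditionals' observations for that DV.
#' @param sqrt_method square-root convention, matching [compute_cwres()].
#' @param weighting `"obs"` (default): binned summaries average over all
#'   observations; `"subject"`: per-subject bin means are averaged.
#' @param pct_threshold_rel near-zero suppression threshold (default 1e-6).
#' @return object of class `cwres_correction`: `per_obs` data.frame
#'   (`ID`, `IDV`, `bin`, `expected`, `delta`, `corrected`, `pct_delta`)
#'   and `binned` data.frame (`bin`, `n`, `b`, `delta`, `pct_delta`).
#' @export
correct_predictions <- function(conditionals, b, bins, grouped,
                                sqrt_method = c("symmetric", "cholesky"),
                                weighting = c("obs", "subject"),
                                pct_threshold_rel = 1e-6) {
  sqrt_method <- match.arg(sqrt_method)
  weighting <- match.arg(weighting)
  expanded <- expand_bias(b, bins, grouped$IDV)
  ids <- vapply(conditionals, `[[`, conditionals[[1]]$id, "id")
  per <- vector("list", length(conditionals))
  for (i in seq_along(conditionals)) {
    cm <- conditionals[[i]]
    rows <- which(grouped$ID == ids[i])
    # within-subject observation indices carrying the grouped DV; rows for
    # other DVs keep a zero bias entry (no estimated bias for them)
    obs_sel <- if ("ROW" %in% names(grouped)) grouped$ROW[rows]
               else seq_along(cm$y)
    if (length(obs_sel) != length(rows) || any(obs_sel > length(cm$y)))
      stop("grouped rows do not match conditionals for subject ", ids[i])
    b_full <- numeric(length(cm$y))
    b_full[obs_sel] <- expanded[rows]
    S <- cov_sqrt(cm$covariance, inverse = FALSE, method = sqrt_method)
    delta <- -drop(S %*% b_full)
    per[[i]] <- data.frame(ID = ids[i], IDV = grouped$IDV[rows],
                           bin = bin_assign(grouped$IDV[rows], bins),
                           expected = cm$expectation[obs_sel],
                           delta = delta[obs_sel])
  }
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  per$corrected <- per$expected - per$delta
  thr <- pct_threshold_rel * mean(abs(per$expected))
  per$pct_delta <- ifelse(abs(per$expected) < thr, NA_real_,
                          100 * per$delta / per$expected)
  agg <- function(v, w) {
    if (w == "obs")
      tapply(v, factor(per$bin, levels = seq_len(bins$n_bins)),
             mean, na.rm = TRUE)
    else {
      bysub <- tapply(v, list(factor(per$bin, levels = seq_len(bins$n_bins)),
                              per$ID), mean, na.rm = TRUE)
      rowMeans(bysub, na.rm = TRUE)
    }
  }
  binned <- data.frame(bin = seq_len(bins$n_bins),
                       n = as.integer(table(factor(per$bin,
                                                   levels = seq_len(bins$n_bins)))),
                       b = b,
                       delta = as.numeric(agg(per$delta, weighting)),
                       pct_delta = as.numeric(agg(per$pct_delta, weighting)))
  structure(list(per_obs = per, binned = binned, bins = bins,
                 weighting = weighting, sqrt_method = sqrt_method),
            class = "cwres_correction")
}

#' @export
print.cwres_correction <- function(x, ...) {
  cat("<cwres_correction> ", nrow(x$per_obs), " observations, ",
      x$bins$n_bins, " bins (", x$weighting, "-weighted)\n", sep = "")
  print(x$binned, digits = 4)
  invisible(x)
}

#' Reference (known) bias in conditional predictions
#'
#' Given the true-model conditional predictions `y_sim` and the fitted
#' (possibly misspecified) model conditional predictions `y_est`,
#' `percent known bias = 100 * (y_sim - y_est) / y_sim`, undefined where
#' `y_sim` is zero. Note the reference point: this is the displacement of
#' the fitted prediction relative to the truth, so a model that
#' over-predicts has negative percent known bias while the corresponding
#' correction term `%delta` from [correct_predictions()] is positive;
#' the two quantities agree in magnitude with opposite sign.
#'
#' @param y_sim true-model conditional predictions, aligned per observation.
#' @param y_est fitted-model conditional predictions.
#' @param bins optional [bin_spec()] for binned means.
#' @param idv IDV per observation (required with `bins`).
#' @return object of class `known_bias`: `percent` per observation (NA where
#'   `y_sim == 0`), `n_undefined`, and `binned` (when bins given) with
#'   per-bin mean percent and mean absolute difference `y_sim - y_est`.
#' @export
known_bias <- function(y_sim, y_est, bins = NULL, idv = NULL) {
  stopifnot(length(y_sim) == length(y_est))
  pct <- ifelse(y_sim == 0, NA_real_, 100 * (y_sim - y_est) / y_sim)
  out <- list(percent = pct, n_undefined = sum(y_sim == 0),
              diff = y_sim - y_est)
  if (!is.null(bins)) {
    stopifnot(!is.null(idv), length(idv) == length(y_sim))
    bn <- factor(bin_assign(idv, bins), levels = seq_len(bins$n_bins))
    out$binned <- data.frame(
      bin = seq_len(bins$n_bins),
      n = as.integer(table(bn)),
      pct_known = as.numeric(tapply(pct, bn, mean, na.rm = TRUE)),
      diff = as.numeric(tapply(y_sim - y_est, bn, mean, na.rm = TRUE)))
  }
  structure(out, class = "known_bias")
}

#' @export
print.known_bias <- function(x, ...) {
  cat("<known_bias> ", length(x$percent), " observations",
      if (x$n_undefined) paste0(" (", x$n_undefined, " undefined)"),
      "\n", sep = "")
  if (!is.null(x$binned)) print(x$binned, digits = 4)
  invisible(x)
}
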