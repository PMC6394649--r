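## IDV binning: quantile (data-density) bins, randomized bins, and the
## repeated random-binning study. Bins are half-open on the right,
## [min, X1), [X1, X2), ..., [X_{N-1}, max], so every observation including
## the range endpoints belongs to exactly one bin.

#' Construct a bin specification
#'
#' @param boundaries strictly increasing cutoffs `X_1 < ... < X_{N-1}`,
#'   strictly inside the observed IDV range.
#' @param idv_name name of the independent variable (`"TIME"` or a
#'   `PRED_<dv>` column).
#' @param min_per_bin the minimum observations per bin the spec was built
#'   under (bookkeeping; enforced by the constructors).
#' @param range observed IDV range the spec applies to.
#' @return object of class `bin_spec` with `n_bins = length(boundaries) + 1`.
#' @export
bin_spec <- function(boundaries, idv_name = "IDV", min_per_bin = 1L,
                     range = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) && any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  if (!is.null(range) && length(boundaries) &&
      (min(boundaries) <= range[1] || max(boundaries) >= range[2]))
    stop("boundaries must lie strictly inside the IDV range")
  structure(list(idv_name = idv_name, boundaries = boundaries,
                 n_bins = length(boundaries) + 1L,
                 min_per_bin = as.integer(min_per_bin), range = range),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat("<bin_spec> ", x$n_bins, " bins on ", x$idv_name, "\n", sep = "")
  cat("  cutoffs: ", paste(signif(x$boundaries, 5), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assign observations to bins
#'
#' @param x IDV values.
#' @param bins a [bin_spec()].
#' @return integer bin index in `1..n_bins`; values below or above the
#'   spec's range fall in the first or last bin.
#' @export
bin_assign <- function(x, bins) {
  findInterval(x, bins$boundaries) + 1L
}

#' Default bin settings per IDV
#'
#' Time uses 10 bins; prediction-based IDVs use 5 bins with at least 25
#' observations per bin.
#'
#' @param idv_name IDV column name.
#' @return list with `n_bins` and `min_per_bin`.
#' @export
default_bin_settings <- function(idv_name) {
  if (grepl("time", idv_name, ignore.case = TRUE))
    list(n_bins = 10L, min_per_bin = 10L)
  else
    list(n_bins = 5L, min_per_bin = 25L)
}

#' Data-density (quantile) bins
#'
#' Places the `N - 1` cutoffs at the empirical `k/N` quantiles of the IDV,
#' snapped to midpoints between adjacent distinct observed values so that
#' ties never straddle a boundary.
#'
#' @param idv_values observed IDV values.
#' @param n_bins number of bins `N`.
#' @param min_per_bin minimum observations required in every bin.
#' @param idv_name label stored in the spec.
#' @return a [bin_spec()].
#' @export
density_bins <- function(idv_values, n_bins, min_per_bin = 1L,
                         idv_name = "IDV") {
  stopifnot(n_bins >= 1)
  x <- idv_values[is.finite(idv_values)]
  u <- sort(unique(x))
  if (length(u) < n_bins)
    stop("only ", length(u), " distinct IDV values: use a smaller N")
  if (n_bins == 1L)
    return(bin_spec(numeric(0), idv_name, min_per_bin, range(x)))
  cumfrac <- cumsum(tabulate(match(sort(x), u))) / length(x)
  # candidate cut after distinct value j: midpoint (u[j] + u[j+1]) / 2
  idx <- vapply(seq_len(n_bins - 1) / n_bins, function(q)
    which.min(abs(cumfrac[-length(u)] - q)), integer(1))
  if (anyDuplicated(idx))
    stop("ties too heavy to form ", n_bins, " bins: use a smaller N")
  bounds <- (u[idx] + u[idx + 1]) / 2
  spec <- bin_spec(bounds, idv_name, min_per_bin, range(x))
  counts <- tabulate(bin_assign(x, spec), spec$n_bins)
  if (min(counts) < min_per_bin)
    stop("bin with ", min(counts), " < ", min_per_bin,
         " observations: use a smaller N")
  spec
}

#' Randomized bins
#'
#' Draws `N - 1` boundaries uniformly over the observed IDV range, redrawing
#' until every bin holds at least `min_per_bin` observations (at most
#' `max_tries` attempts).
#'
#' @inheritParams density_bins
#' @param seed optional integer seed for reproducible draws.
#' @param max_tries rejection cap (default 10000).
#' @return a [bin_spec()].
#' @export
random_bins <- function(idv_values, n_bins, min_per_bin = 1L,
                        idv_name = "IDV", seed = NULL, max_tries = 10000L) {
  stopifnot(n_bins >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- idv_values[is.finite(idv_values)]
  rng <- range(x)
  if (n_bins == 1L)
    return(bin_spec(numeric(0), idv_name, min_per_bin, rng))
  for (try in seq_len(max_tries)) {
    bounds <- sort(stats::runif(n_bins - 1, rng[1], rng[2]))
    if (any(diff(bounds) <= 0)) next
    spec <- bin_spec(bounds, idv_name, min_per_bin, rng)
    counts <- tabulate(bin_assign(x, spec), n_bins)
    if (min(counts) >= min_per_bin) return(spec)
  }
  stop("no feasible random binning in ", max_tries,
       " draws: reduce N or min_per_bin")
}

#' Repeated random-binning study
#'
#' Repeats: draw random bins, fit the extended CWRES model, record the bias
#' vector `b`; when `conditionals` are supplied, also back-correct to the
#' binned prediction bias. The replicate-wise results support envelope
#' plots over the bias estimates, similar to confidence intervals.
#'
#' @param grouped a [cwres_grouped()] data.frame.
#' @param n_bins,min_per_bin binning constraints per replicate.
#' @param reps number of replicates (default 500).
#' @param seed integer seed governing the whole study.
#' @param conditionals optional [foce_conditionals()] list matching the
#'   grouped table; enables the delta summaries.
#' @param max_fail_frac error if more than this fraction of replicates
#'   fails (default 0.1).
#' @return object of class `random_binning_study`: list with `replicates`
#'   (each holding `bins`, `b`, optional `delta` summary), matrix `b`
#'   (reps x N), and `failures`.
#' @export
random_binning_study <- function(grouped, n_bins, min_per_bin, reps = 500L,
                                 seed = NULL, conditionals = NULL,
                                 max_fail_frac = 0.1) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  idv_name <- attr(grouped, "idv_name")
  if (is.null(idv_name)) idv_name <- "IDV"
  replicates <- vector("list", reps)
  bmat <- matrix(NA_real_, reps, n_bins)
  failures <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      bins <- random_bins(grouped$IDV, n_bins, min_per_bin,
                          idv_name = idv_name)
      fit <- fit_extended(grouped, bins)
      rep_out <- list(bins = bins, b = fit$means, ofv = fit$ofv)
      if (!is.null(conditionals)) {
        corr <- correct_predictions(conditionals, fit$means, bins, grouped)
        rep_out$delta <- corr$binned
      }
      rep_out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      next
    }
    replicates[[r]] <- res
    bmat[r, ] <- res$b
  }
  if (failures > max_fail_frac * reps)
    stop(failures, "/", reps, " random-binning replicates failed")
  structure(list(replicates = replicates, b = bmat, failures = failures,
                 n_bins = n_bins, min_per_bin = min_per_bin, reps = reps),
            class = "random_binning_study")
}

#' @export
print.random_binning_study <- function(x, ...) {
  cat("<random_binning_study> ", x$reps, " replicates (", x$failures,
      " failed), N = ", x$n_bins, "\n", sep = "")
  cat("  pooled mean(b) = ", signif(mean(x$b, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}
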