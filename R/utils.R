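#' @keywords internal
"_PACKAGE"

## Numerical helpers shared across the FOCE engine and the correction step.
## The same square-root convention must be used to whiten residuals and to
## back-transform bin means: the correction inverts the whitening.

#' Symmetric or Cholesky square root of a covariance matrix
#'
#' Returns a factor \code{R} such that \code{R \%*\% t(R) == S} for
#' \code{method = "cholesky"} (lower-triangular) or \code{R \%*\% R == S}
#' for \code{method = "symmetric"} (eigendecomposition). With
#' \code{inverse = TRUE} the corresponding inverse square root is returned.
#' Whitening residuals with the inverse factor and mapping bin means back
#' with the forward factor are mutually consistent for either method.
#'
#' @param S symmetric positive-definite matrix.
#' @param inverse return the inverse square root.
#' @param method `"symmetric"` (default) or `"cholesky"`.
#' @return a square matrix of the same dimension as `S`.
#' @export
cov_sqrt <- function(S, inverse = FALSE, method = c("symmetric", "cholesky")) {
  method <- match.arg(method)
  S <- symmetrize(S)
  if (method == "cholesky") {
    L <- t(chol(S))                    # lower triangular, S = L L'
    if (!inverse) return(L)
    return(forwardsolve(L, diag(nrow(S))))
  }
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (inverse) {
    if (any(vals <= 0)) stop("singular covariance: cannot form inverse square root")
    d <- 1 / sqrt(vals)
  } else {
    d <- sqrt(vals)
  }
  e$vectors %*% (d * t(e$vectors))
}

symmetrize <- function(S) (S + t(S)) / 2

#' Stabilize a nearly singular covariance matrix
#'
#' Adds `1e-10 * mean(diag(S))` to the diagonal when the smallest eigenvalue
#' falls below `1e-12` times the largest. Returns the (possibly jittered)
#' matrix with attribute `"jittered"`.
#' @keywords internal
jitter_spd <- function(S) {
  S <- symmetrize(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  jittered <- FALSE
  if (min(ev) < 1e-12 * max(ev)) {
    S <- S + diag(1e-10 * mean(diag(S)), nrow(S))
    jittered <- TRUE
  }
  attr(S, "jittered") <- jittered
  S
}

## symmetry + eigenvalue check for user-supplied Omega / Sigma
check_psd <- function(M, label) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(label, " must be a square matrix")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop(label, " must be symmetric")
  ev <- eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop(label, " must be positive semi-definite (smallest eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(symmetrize(M))
}

## -2 log likelihood contribution of one multivariate normal observation,
## excluding the n*log(2*pi) constant (NONMEM convention).
mvn_m2ll <- function(resid, V) {
  L <- chol(V)
  z <- backsolve(L, resid, transpose = TRUE)
  2 * sum(log(diag(L))) + sum(z^2)
}
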