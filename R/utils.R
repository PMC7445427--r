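#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Symmetric positive-definite log-determinant + inverse via Cholesky.
## Returns NULL if the matrix is not PD (callers treat that as a penalty).
.chol_info <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  list(logdet = 2 * sum(log(diag(R))), inv = chol2inv(R))
}

## matrix square root valid for positive SEMI-definite matrices (random
## effects may legitimately have zero variance)
.psd_sqrt <- function(S) {
  r <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(r)) return(r)
  ei <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ei$values) < -1e-8 * max(abs(ei$values), 1))
    .stopf("covariance matrix is not positive semi-definite")
  t(ei$vectors %*% (t(ei$vectors) * sqrt(pmax(ei$values, 0))))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Deterministic jitter vectors for multi-start optimization (no RNG use,
## so fitting never perturbs the caller's random stream).
.jitter_start <- function(start, k, scale = 0.1) {
  start + scale * sin(seq_along(start) * (k + 1) + k)
}

## Column-wise variance with the ML (1/n) divisor.
.ml_cov <- function(X) {
  n <- nrow(X)
  xb <- colMeans(X)
  Xc <- sweep(X, 2L, xb)
  list(n = n, mean = xb, cov = crossprod(Xc) / n)
}
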