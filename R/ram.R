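## RAM (reticular action model) representation of linear path models.
##
## A model over variables v (observed + latent) is parameterized by
##   A : directed paths, A[to, from]
##   S : symmetric (co)variances of exogenous disturbances
##   M : means / intercepts
## with implied moments over all variables
##   Sigma_all = B S B',  mu_all = B m,  B = (I - A)^{-1}
## and observed moments obtained by row/column selection. Free parameters
## are labeled; entries sharing a label are constrained equal.

#' Construct a path-model specification
#'
#' Low-level constructor for a RAM path model. Most users should build
#' specifications with [build_clpm_spec()]; this constructor is exported for
#' custom models and for tests.
#'
#' @param vars character vector of all variable names (observed and latent).
#' @param obs character vector of observed variable names (subset of `vars`).
#' @param ptable data frame with columns `mat` ("A", "S" or "M"), `from`,
#'   `to`, `label`, `free` (logical), `start` (numeric starting value, used
#'   as the fixed value when `free` is `FALSE`).
#' @return An object of class `path_model_spec`.
#' @export
path_model_spec <- function(vars, obs, ptable) {
  stopifnot(all(obs %in% vars), is.data.frame(ptable))
  need <- c("mat", "from", "to", "label", "free", "start")
  if (!all(need %in% names(ptable)))
    .stopf("ptable must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(c(ptable$from[ptable$mat != "M"], ptable$to)), vars)
  if (length(bad))
    .stopf("ptable references unknown variables: %s", paste(bad, collapse = ", "))
  ## a label used by a free entry must not also be used by a fixed entry
  lab <- ptable$label[ptable$free]
  if (any(duplicated(paste(ptable$mat, ptable$from, ptable$to))))
    .stopf("duplicate ptable entries")
  spec <- structure(
    list(vars = vars, obs = obs, ptable = ptable,
         free_labels = unique(lab)),
    class = "path_model_spec")
  spec
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("path_model_spec:", length(x$obs), "observed,",
      length(x$vars) - length(x$obs), "latent variables;",
      length(x$free_labels), "free parameters\n")
  invisible(x)
}

#' Number of free parameters of a specification
#' @param spec a `path_model_spec`.
#' @return integer count of uniquely labeled free parameters.
#' @export
n_free_params <- function(spec) length(spec$free_labels)

## Default starting vector (named by free label).
.ram_start <- function(spec) {
  pt <- spec$ptable
  out <- numeric(0)
  for (lb in spec$free_labels) {
    out[lb] <- pt$start[pt$free & pt$label == lb][1L]
  }
  out
}

## Precompile a spec into integer indices for fast repeated evaluation.
.ram_compile <- function(spec) {
  v <- spec$vars
  k <- length(v)
  pt <- spec$ptable
  vi <- function(x) match(x, v)
  lin <- function(r, c) (c - 1L) * k + r     # column-major linear index
  isA <- pt$mat == "A"; isS <- pt$mat == "S"; isM <- pt$mat == "M"
  theta_pos <- ifelse(pt$free, match(pt$label, spec$free_labels), NA_integer_)
  list(
    k = k, obs_idx = vi(spec$obs),
    fixed = ifelse(pt$free, 0, pt$start),
    theta_pos = theta_pos,
    iA = lin(vi(pt$to[isA]), vi(pt$from[isA])), wA = which(isA),
    iS1 = lin(vi(pt$to[isS]), vi(pt$from[isS])),
    iS2 = lin(vi(pt$from[isS]), vi(pt$to[isS])), wS = which(isS),
    iM = vi(pt$to[isM]), wM = which(isM))
}

## Materialize A, S, M matrices for a parameter vector theta (named).
.ram_matrices <- function(spec, theta, cmp = NULL) {
  cmp <- cmp %||% .ram_compile(spec)
  k <- cmp$k
  val <- cmp$fixed
  fr <- !is.na(cmp$theta_pos)
  val[fr] <- theta[cmp$theta_pos[fr]]
  A <- matrix(0, k, k); S <- matrix(0, k, k); M <- numeric(k)
  A[cmp$iA] <- val[cmp$wA]
  S[cmp$iS1] <- val[cmp$wS]; S[cmp$iS2] <- val[cmp$wS]
  M[cmp$iM] <- val[cmp$wM]
  dimnames(A) <- dimnames(S) <- list(spec$vars, spec$vars)
  names(M) <- spec$vars
  list(A = A, S = S, M = M)
}

## Implied moments over all variables; NULL if (I - A) is singular.
.ram_implied_all <- function(spec, theta, cmp = NULL) {
  m <- .ram_matrices(spec, theta, cmp)
  k <- length(spec$vars)
  B <- tryCatch(solve(diag(k) - m$A), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  sigma <- B %*% m$S %*% t(B)
  mu <- drop(B %*% m$M)
  list(sigma = (sigma + t(sigma)) / 2, mu = mu)
}

#' Model-implied mean and covariance of the observed variables
#'
#' @param spec a `path_model_spec`.
#' @param theta named parameter vector over the free labels; defaults to the
#'   starting values.
#' @return list with `sigma` (observed covariance) and `mu` (observed means).
#' @export
implied_moments <- function(spec, theta = .ram_start(spec)) {
  imp <- .ram_implied_all(spec, theta)
  if (is.null(imp)) .stopf("implied covariance is singular at these parameters")
  list(sigma = imp$sigma[spec$obs, spec$obs, drop = FALSE],
       mu = imp$mu[spec$obs])
}
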