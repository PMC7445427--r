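## Permutation p-values and Freedman-Lane permutation inference for a
## regression coefficient under family exchangeability blocks.

#' Add-one permutation p-value
#'
#' `p = (1 + #exceedances) / (1 + B)`; never returns 0.
#'
#' @param observed observed statistic.
#' @param null_draws vector of statistics from permuted data.
#' @param sided `"two"` (compares absolute values), `"greater"` or
#'   `"less"`.
#' @return permutation p-value in (0, 1].
#' @export
perm_pvalue <- function(observed, null_draws, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (!length(null_draws)) .stopf("empty null draws")
  exc <- switch(sided,
    two = sum(abs(null_draws) >= abs(observed)),
    greater = sum(null_draws >= observed),
    less = sum(null_draws <= observed))
  (1 + exc) / (1 + length(null_draws))
}

## Orthonormal basis of the column space of X (with intercept prepended).
.design_q <- function(X, n) {
  if (is.null(X) || NCOL(X) == 0L) X <- matrix(1, n, 1L) else {
    X <- cbind(1, as.matrix(X))
  }
  qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
}

#' Freedman-Lane permutation test of a regression coefficient
#'
#' Tests the coefficient of `predictor` in the linear model
#' `outcome ~ predictor + covariates` by the Freedman-Lane scheme: the
#' outcome residuals from the nuisance-only (covariates) model are permuted
#' by legal family-block draws, the nuisance fit is added back, and the
#' full model is refit to collect the null t statistics. Permutations are
#' drawn with [draw_permutation()], so family relatedness is respected.
#'
#' @param outcome numeric response vector.
#' @param predictor numeric predictor of interest.
#' @param covariates optional numeric matrix / data frame of nuisance
#'   covariates (an intercept is always included).
#' @param blocks an `exchangeability_blocks` covering the same subjects, or
#'   `NULL` for unrestricted permutation.
#' @param n_perm number of permutations (default 5000).
#' @param sided sidedness passed to [perm_pvalue()].
#' @return list with `p_perm`, `t_obs`, `beta_obs`, `t_null` (vector),
#'   `n_perm`, `n_bad` (degenerate refits, counted as exceedances).
#' @export
permute_coefficient <- function(outcome, predictor, covariates = NULL,
                                blocks = NULL, n_perm = 5000,
                                sided = "two") {
  n <- length(outcome)
  stopifnot(length(predictor) == n)
  if (is.null(blocks)) {
    fake <- data.frame(subject_id = as.character(seq_len(n)),
                       family_id = sprintf("F%d", seq_len(n)),
                       member_type = "single", site_id = "site01",
                       stringsAsFactors = FALSE)
    blocks <- build_blocks(fake)
  }
  stopifnot(blocks$n == n)
  Qc <- .design_q(covariates, n)
  ## residualize predictor and outcome on the nuisance space
  xe <- predictor - Qc %*% crossprod(Qc, predictor)
  xnorm2 <- sum(xe^2)
  if (xnorm2 < 1e-12) .stopf("predictor is collinear with the covariates")
  fit_c <- Qc %*% crossprod(Qc, outcome)
  e <- outcome - fit_c                      # nuisance residuals
  dof <- n - ncol(Qc) - 1L

  t_of <- function(y) {
    b <- sum(xe * y) / xnorm2
    ## residual sum of squares of the full model via orthogonal decomposition
    yr <- y - Qc %*% crossprod(Qc, y)
    rss <- sum(yr^2) - b^2 * xnorm2
    if (rss <= 0 || dof <= 0) return(NA_real_)
    b / sqrt(rss / dof / xnorm2)
  }
  t_obs <- t_of(outcome)
  beta_obs <- sum(xe * outcome) / xnorm2

  t_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pe <- e[draw_permutation(blocks)]
    t_null[b] <- t_of(fit_c + pe)
  }
  n_bad <- sum(!is.finite(t_null))
  if (n_bad) t_null[!is.finite(t_null)] <- Inf   # conservative
  list(p_perm = perm_pvalue(t_obs, t_null, sided = sided),
       t_obs = t_obs, beta_obs = beta_obs, t_null = t_null,
       n_perm = n_perm, n_bad = n_bad)
}
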