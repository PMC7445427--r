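## Post-fit methods: standardized solutions, fit indices, FDR over path
## families, Wald path comparisons.

## Standardized value of every free parameter at theta: paths scaled by the
## ratio of implied SDs, covariances turned into correlations, variances
## left on the raw scale (means untouched -> NA in std column).
.std_vector <- function(spec, theta) {
  imp <- .ram_implied_all(spec, theta)
  if (is.null(imp)) return(rep(NA_real_, length(theta)))
  sdv <- sqrt(pmax(diag(imp$sigma), 0))
  names(sdv) <- spec$vars
  if (any(sdv == 0 & spec$vars %in% unlist(spec$ptable[spec$ptable$free, c("from", "to")])))
    NULL
  pt <- spec$ptable
  out <- stats::setNames(rep(NA_real_, length(theta)), names(theta))
  for (lb in names(theta)) {
    i <- which(pt$free & pt$label == lb)[1L]
    v <- theta[lb]
    if (pt$mat[i] == "A") {
      s_from <- sdv[pt$from[i]]; s_to <- sdv[pt$to[i]]
      if (s_to == 0) .stopf("zero implied variance for %s", pt$to[i])
      out[lb] <- v * s_from / s_to
    } else if (pt$mat[i] == "S" && pt$from[i] != pt$to[i]) {
      den <- sdv[pt$from[i]] * sdv[pt$to[i]]
      out[lb] <- if (den > 0) v / den else NA_real_
    } else {
      out[lb] <- NA_real_
    }
  }
  out
}

#' Standardized solution with delta-method confidence intervals
#'
#' Rescales every directed path by the ratio of model-implied standard
#' deviations (and covariances into correlations) and attaches 95%
#' delta-method confidence intervals. Calling it on an already standardized
#' fit recomputes the same quantities (idempotent).
#'
#' @param fit a converged `path_model_fit`.
#' @param level confidence level (default 0.95).
#' @return the fit with columns `std`, `std_se`, `std_lower`, `std_upper`
#'   added to `fit$estimates`.
#' @export
standardize <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "path_model_fit"))
  spec <- fit$spec; theta <- fit$theta
  std <- .std_vector(spec, theta)
  std_se <- rep(NA_real_, length(theta))
  if (!is.null(fit$vcov)) {
    ## numerical jacobian of the standardized vector
    eps <- 1e-6
    J <- matrix(0, length(theta), length(theta))
    for (j in seq_along(theta)) {
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      J[, j] <- (.std_vector(spec, tp) - .std_vector(spec, tm)) / (2 * eps)
    }
    J[is.na(J)] <- 0
    V <- J %*% fit$vcov %*% t(J)
    std_se <- sqrt(pmax(diag(V), 0))
    std_se[is.na(std)] <- NA_real_
  }
  zc <- stats::qnorm(1 - (1 - level) / 2)
  fit$estimates$std <- unname(std[fit$estimates$label])
  fit$estimates$std_se <- unname(std_se)
  fit$estimates$std_lower <- fit$estimates$std - zc * fit$estimates$std_se
  fit$estimates$std_upper <- fit$estimates$std + zc * fit$estimates$std_se
  fit$standardized <- TRUE
  fit
}

#' Chi-square based fit indices
#'
#' Computes RMSEA, CFI, TLI and SRMR against the saturated model (estimated
#' by EM under missingness) and the independence baseline. RMSEA uses the
#' (N - 1) denominator; CFI is clamped to [0, 1]; SRMR is computed from the
#' saturated-moment and implied correlation-metric covariance residuals
#' (covariance structure only).
#'
#' @param fit a `path_model_fit`.
#' @return list with `chisq`, `df`, `pvalue`, `rmsea`, `cfi`, `tli`, `srmr`,
#'   `baseline_chisq`, `baseline_df`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "path_model_fit"))
  stats_ <- fit$stats
  n <- fit$n
  p <- length(fit$spec$obs)
  f_sat <- .saturated_neg2ll(stats_)
  f_ind <- .independence_neg2ll(stats_)
  chisq <- max(fit$neg2ll - as.numeric(f_sat), 0)
  df <- p * (p + 3) / 2 - length(fit$theta)
  chisq_b <- max(f_ind - as.numeric(f_sat), 0)
  df_b <- p * (p + 3) / 2 - 2 * p

  if (df > 0) {
    rmsea <- sqrt(max((chisq - df) / (df * (n - 1)), 0))
    pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    rmsea <- 0    # df = 0: saturated target, RMSEA defined as 0
    pval <- NA_real_
  }
  num <- max(chisq - df, 0)
  den <- max(chisq - df, chisq_b - df_b, 0)
  cfi <- if (den == 0) 1 else min(max(1 - num / den, 0), 1)
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1)
    ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1) else 1

  ## SRMR: standardized residuals between saturated and implied covariances
  mu_sat <- attr(f_sat, "mu"); S_sat <- attr(f_sat, "sigma")
  if (is.null(S_sat)) {  # complete data: closed-form saturated moments
    pg <- stats_$patterns[[1L]]
    S_sat <- matrix(0, p, p); S_sat[pg$cols, pg$cols] <- pg$cov
  }
  imp <- implied_moments(fit$spec, fit$theta)
  d_sat <- sqrt(pmax(diag(S_sat), .Machine$double.eps))
  res <- (S_sat - imp$sigma) / tcrossprod(d_sat)
  lt <- lower.tri(res, diag = TRUE)
  srmr <- sqrt(mean(res[lt]^2))

  list(chisq = chisq, df = df, pvalue = pval, rmsea = rmsea, cfi = cfi,
       tli = tli, srmr = srmr, baseline_chisq = chisq_b, baseline_df = df_b,
       note = if (df == 0) "df = 0; RMSEA defined as 0" else NULL)
}

#' Benjamini-Hochberg FDR over a set of paths
#'
#' Applies the BH step-up procedure over exactly the requested parameter
#' subset (by default the lagged autoregressive + cross-lagged paths, the
#' inference family used for between-wave associations) and returns
#' monotone q-values and rejection flags.
#'
#' @param fit a `path_model_fit`.
#' @param path_subset character vector of parameter labels; defaults to
#'   `attr(fit$spec, "lagged_paths")`.
#' @param q FDR level (default 0.05).
#' @return data frame with `label`, `p`, `q`, `significant`.
#' @export
fdr_paths <- function(fit, path_subset = NULL, q = 0.05) {
  stopifnot(inherits(fit, "path_model_fit"))
  path_subset <- path_subset %||% attr(fit$spec, "lagged_paths")
  if (is.null(path_subset) || !length(path_subset))
    .stopf("empty path subset")
  est <- fit$estimates
  miss <- setdiff(path_subset, est$label)
  if (length(miss)) .stopf("paths not in fit: %s", paste(miss, collapse = ", "))
  pv <- est$p[match(path_subset, est$label)]
  qv <- stats::p.adjust(pv, method = "BH")
  data.frame(label = path_subset, p = pv, q = qv, significant = qv < q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wald test of equality of two path coefficients
#'
#' Chi-square(1) test of `theta_a = theta_b` using the observed-information
#' parameter covariance: `(theta_a - theta_b)^2 / var(theta_a - theta_b)`.
#'
#' @param fit a `path_model_fit` with `vcov` available.
#' @param path_a,path_b free-parameter labels.
#' @return list with `statistic`, `df`, `p`.
#' @export
wald_compare <- function(fit, path_a, path_b) {
  stopifnot(inherits(fit, "path_model_fit"))
  if (is.null(fit$vcov)) .stopf("fit has no parameter covariance; refit with se = TRUE")
  th <- fit$theta
  for (pp in c(path_a, path_b)) {
    if (!pp %in% names(th)) {
      if (pp %in% fit$spec$ptable$label)
        .stopf("path '%s' is fixed by constraint; Wald comparison needs free paths", pp)
      .stopf("unknown path label '%s'", pp)
    }
  }
  if (identical(path_a, path_b))
    return(list(statistic = 0, df = 1L, p = 1))
  d <- th[path_a] - th[path_b]
  v <- fit$vcov[path_a, path_a] + fit$vcov[path_b, path_b] -
    2 * fit$vcov[path_a, path_b]
  if (v <= 0) .stopf("non-positive variance of the path difference")
  stat <- unname(d^2 / v)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1, lower.tail = FALSE))
}
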