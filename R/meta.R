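## Cross-site meta-analysis of a path coefficient.

#' Pool per-site coefficients by inverse-variance meta-analysis
#'
#' Fixed-effect pooling uses inverse-variance weights; random-effects uses
#' the DerSimonian-Laird tau^2. Estimation is delegated to
#' \code{metafor::rma}.
#'
#' @param estimates data frame with columns `beta` and `se` (one row per
#'   site; optional `site` column for labels).
#' @param model `"fixed"` or `"random"`.
#' @param level confidence level (default 0.95).
#' @return An object of class `meta_result`: list with `beta` (pooled),
#'   `se`, `ci` (length 2), `weights` (normalized to sum to 1), `Q`
#'   (heterogeneity statistic), `tau2`, `model`.
#' @export
meta_sites <- function(estimates, model = c("fixed", "random"), level = 0.95) {
  model <- match.arg(model)
  stopifnot(is.data.frame(estimates), all(c("beta", "se") %in% names(estimates)))
  if (nrow(estimates) < 2L) .stopf("need at least 2 sites")
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0))
    .stopf("every site SE must be finite and positive")
  fit <- metafor::rma(yi = estimates$beta, sei = estimates$se,
                      method = if (model == "fixed") "FE" else "DL",
                      level = level * 100)
  w <- metafor::weights.rma.uni(fit)
  structure(list(beta = as.numeric(fit$beta), se = fit$se,
                 ci = c(fit$ci.lb, fit$ci.ub),
                 weights = as.numeric(w) / sum(w),
                 Q = fit$QE, Q_p = fit$QEp,
                 tau2 = if (model == "random") fit$tau2 else 0,
                 model = model, n_sites = nrow(estimates)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s effects, %d sites): beta = %.4f, 95%% CI [%.4f, %.4f], Q = %.2f\n",
              x$model, x$n_sites, x$beta, x$ci[1], x$ci[2], x$Q))
  invisible(x)
}
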