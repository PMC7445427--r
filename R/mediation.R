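## Three-variable mediation (predictor -> mediator -> outcome) with
## covariates: path estimates from the two covariate-adjusted regressions,
## bias-corrected bootstrap confidence intervals (resampling subjects, or
## whole families when a family table is supplied), and the proportion
## mediated.

.lm_coef <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  fit$coefficients
}

## a, b, c, c_prime for one resample; X columns: intercept, covariates
.med_paths <- function(x, m, y, C) {
  Xa <- cbind(1, x, C)
  a <- .lm_coef(m, Xa)[2L]
  Xb <- cbind(1, m, x, C)
  cf <- .lm_coef(y, Xb)
  b <- cf[2L]; c_prime <- cf[3L]
  cc <- .lm_coef(y, Xa)[2L]
  c(a = unname(a), b = unname(b), c = unname(cc), c_prime = unname(c_prime),
    ab = unname(a * b))
}

## bias-corrected (non-accelerated) bootstrap CI
.bc_ci <- function(est, boots, level = 0.95) {
  boots <- boots[is.finite(boots)]
  if (!length(boots)) return(c(NA_real_, NA_real_))
  prop <- mean(boots < est)
  ## guard the degenerate all-above / all-below cases
  prop <- min(max(prop, 1 / (length(boots) + 1)), length(boots) / (length(boots) + 1))
  z0 <- stats::qnorm(prop)
  zc <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  probs <- stats::pnorm(2 * z0 + zc)
  stats::quantile(boots, probs, names = FALSE, type = 6)
}

#' Bootstrap mediation analysis
#'
#' Estimates the standard mediation decomposition from two
#' covariate-adjusted linear regressions: path a (`m ~ x + C`), paths b and
#' c' (`y ~ m + x + C`), total effect c (`y ~ x + C`), mediation effect
#' `ab = a * b` (equal to `c - c'` in these linear models) and the
#' proportion mediated `ab / c`. Confidence intervals are bias-corrected
#' bootstrap intervals over subject resamples (default 10,000 draws);
#' significance means the CI excludes 0. When `families` is supplied whole
#' families are resampled (cluster bootstrap), honoring relatedness.
#'
#' @param x predictor (e.g. regional gray-matter volume).
#' @param m mediator (e.g. a symptom score).
#' @param y outcome.
#' @param covariates optional numeric matrix / data frame of covariates.
#' @param n_boot bootstrap draws (default 10000).
#' @param families optional `family_table` aligned with the subjects.
#' @param ci_type `"bc"` (bias-corrected, default) or `"percentile"`.
#' @param level confidence level.
#' @return a `mediation_result`: list with `paths` (a, b, c, c_prime, ab),
#'   `ci` (matrix of bootstrap CIs), `prop_mediated`, `n`, `n_boot`,
#'   `significant_ab`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 10000,
                    families = NULL, ci_type = c("bc", "percentile"),
                    level = 0.95) {
  ci_type <- match.arg(ci_type)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- stats::complete.cases(x, m, y, if (is.null(C)) rep(0, length(x)) else C)
  n_dropped <- sum(!keep)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  fam_id <- NULL
  if (!is.null(families)) {
    stopifnot(length(keep) == nrow(families))
    fam_id <- families$family_id[keep]
  }
  n <- length(x)
  est <- .med_paths(x, m, y, C)

  boots <- matrix(NA_real_, n_boot, 5L,
                  dimnames = list(NULL, names(est)))
  if (n_boot > 0) {
    if (is.null(fam_id)) {
      for (i in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        boots[i, ] <- .med_paths(x[idx], m[idx], y[idx],
                                 if (is.null(C)) NULL else C[idx, , drop = FALSE])
      }
    } else {
      fams <- split(seq_len(n), fam_id)
      nf <- length(fams)
      for (i in seq_len(n_boot)) {
        idx <- unlist(fams[sample.int(nf, nf, replace = TRUE)], use.names = FALSE)
        boots[i, ] <- .med_paths(x[idx], m[idx], y[idx],
                                 if (is.null(C)) NULL else C[idx, , drop = FALSE])
      }
    }
  }
  ci <- t(vapply(names(est), function(nm) {
    if (n_boot == 0) return(c(NA_real_, NA_real_))
    if (ci_type == "bc") .bc_ci(est[nm], boots[, nm], level)
    else stats::quantile(boots[, nm], c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, type = 6)
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")

  ## proportion mediated: only meaningful for consistent mediation with a
  ## non-negligible total effect
  ## the ratio ab / c is unstable when the total effect is not clearly
  ## separated from zero and meaningless under inconsistent mediation
  se_c <- if (n_boot > 0) stats::sd(boots[, "c"], na.rm = TRUE) else 0
  prop <- NA_real_
  tol_c <- max(1e-10, 2 * se_c)
  if (abs(est["c"]) > tol_c && sign(est["ab"]) == sign(est["c"])) {
    prop <- unname(est["ab"] / est["c"])
  } else {
    .warnf("proportion mediated undefined (inconsistent mediation or total effect near zero); ratio unstable")
  }

  structure(list(paths = est, ci = ci, prop_mediated = prop,
                 n = n, n_dropped = n_dropped, n_boot = n_boot,
                 ci_type = ci_type,
                 significant_ab = is.finite(ci["ab", 1L]) &&
                   (ci["ab", 1L] > 0 || ci["ab", 2L] < 0),
                 boots = boots),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result: n = %d, %d bootstraps (%s CIs)\n",
              x$n, x$n_boot, x$ci_type))
  tab <- data.frame(est = x$paths, lower = x$ci[, 1], upper = x$ci[, 2])
  print(tab, digits = 4)
  if (is.finite(x$prop_mediated))
    cat(sprintf("proportion mediated: %.3f\n", x$prop_mediated))
  invisible(x)
}

#' Prospective mediation with a later-wave outcome
#'
#' Identical to [mediate()] but the outcome comes from a follow-up wave;
#' rows with missing follow-up are dropped and counted in `n_dropped`.
#'
#' @inheritParams mediate
#' @param m_baseline mediator at baseline.
#' @param y_followup outcome at follow-up.
#' @return a `mediation_result`.
#' @export
mediate_prospective <- function(x, m_baseline, y_followup, covariates = NULL,
                                n_boot = 10000, families = NULL,
                                ci_type = "bc", level = 0.95) {
  mediate(x, m_baseline, y_followup, covariates = covariates,
          n_boot = n_boot, families = families, ci_type = ci_type,
          level = level)
}
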