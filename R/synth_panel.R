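## Synthetic bivariate longitudinal panels generated from a
## random-intercepts cross-lagged process: stable between-person intercepts
## plus a within-person lag-1 bivariate autoregressive/cross-lagged process,
## an optional family-level random effect, and missing-at-random dropout
## whose probability depends on the previous wave's observed value.

#' Ground-truth parameters for the panel generator
#'
#' Scalars are recycled across wave pairs. The within-person process is
#' lag-indexed: `cross_xy[t]` is the path from variable 1 at wave t to
#' variable 2 at wave t+1.
#'
#' @param n_waves number of waves (>= 3).
#' @param ar_x,ar_y autoregressive coefficients (length `n_waves - 1` or 1).
#' @param cross_xy,cross_yx cross-lagged coefficients.
#' @param ri_var_x,ri_var_y,ri_cov random-intercept (co)variances.
#' @param var1_x,var1_y,cov1 wave-1 within-person (co)variances.
#' @param resid_var_x,resid_var_y,resid_cov innovation (co)variances for
#'   waves 2..n_waves (length `n_waves - 1` or 1).
#' @param wave_means matrix (`n_waves` x 2) of wave means; default 0.
#' @param family_var variance of the family-level random effect added
#'   independently to each stream (default 0.1; shared by family members).
#' @param missing_rate per-wave marginal missingness target in [0, 1)
#'   (length `n_waves` or 1).
#' @param mar_strength slope of the missingness logit on the standardized
#'   previous-wave observed value of the same stream (default 1).
#' @param variables names of the two streams.
#' @return object of class `panel_truth`.
#' @export
panel_truth <- function(n_waves = 5, ar_x = 0.3, ar_y = 0.3,
                        cross_xy = 0.1, cross_yx = 0,
                        ri_var_x = 0.3, ri_var_y = 0.3, ri_cov = 0.1,
                        var1_x = 1, var1_y = 1, cov1 = 0.2,
                        resid_var_x = 0.8, resid_var_y = 0.8,
                        resid_cov = 0.1,
                        wave_means = NULL, family_var = 0.1,
                        missing_rate = 0, mar_strength = 1,
                        variables = c("x", "y")) {
  if (n_waves < 3) .stopf("the random-intercepts process requires at least 3 waves")
  L <- n_waves - 1L
  rcy <- function(v, len, nm) {
    if (length(v) == 1L) v <- rep(v, len)
    if (length(v) != len) .stopf("%s must have length 1 or %d", nm, len)
    v
  }
  tr <- list(
    n_waves = n_waves, variables = variables,
    ar_x = rcy(ar_x, L, "ar_x"), ar_y = rcy(ar_y, L, "ar_y"),
    cross_xy = rcy(cross_xy, L, "cross_xy"),
    cross_yx = rcy(cross_yx, L, "cross_yx"),
    ri_var_x = ri_var_x, ri_var_y = ri_var_y, ri_cov = ri_cov,
    var1_x = var1_x, var1_y = var1_y, cov1 = cov1,
    resid_var_x = rcy(resid_var_x, L, "resid_var_x"),
    resid_var_y = rcy(resid_var_y, L, "resid_var_y"),
    resid_cov = rcy(resid_cov, L, "resid_cov"),
    wave_means = wave_means %||% matrix(0, n_waves, 2),
    family_var = family_var,
    missing_rate = rcy(missing_rate, n_waves, "missing_rate"),
    mar_strength = mar_strength)
  if (any(tr$missing_rate < 0 | tr$missing_rate >= 1))
    .stopf("missing_rate must lie in [0, 1)")
  if (min(ri_var_x, ri_var_y, family_var) < 0) .stopf("variances must be >= 0")
  ## positive-definiteness of the within-process (co)variances, per wave
  S1 <- matrix(c(var1_x, cov1, cov1, var1_y), 2)
  if (is.null(.chol_info(S1))) .stopf("wave 1 within-person covariance not positive definite")
  for (t in seq_len(L)) {
    Rt <- matrix(c(tr$resid_var_x[t], tr$resid_cov[t],
                   tr$resid_cov[t], tr$resid_var_y[t]), 2)
    if (is.null(.chol_info(Rt)))
      .stopf("residual covariance not positive definite at wave %d", t + 1L)
  }
  structure(tr, class = "panel_truth")
}

#' Model-implied per-subject moments of a panel truth
#'
#' Closed-form marginal mean and covariance of the observed vector
#' (variable-major: `x_w1..x_wW, y_w1..y_wW`), accumulating the
#' random-intercept block, the family-effect block and the within-person
#' process covariance obtained by lag-1 recursion.
#'
#' @param truth a `panel_truth`.
#' @return list with `sigma`, `mu` and `vars`.
#' @export
implied_panel_moments <- function(truth) {
  stopifnot(inherits(truth, "panel_truth"))
  W <- truth$n_waves
  vx <- truth$variables[1L]; vy <- truth$variables[2L]
  vars <- c(paste0(vx, "_w", seq_len(W)), paste0(vy, "_w", seq_len(W)))
  p <- 2L * W
  idx <- function(v, t) (v - 1L) * W + t    # v = 1 (x) or 2 (y)

  ## within-person process: V[t] = Var(z_t), C[s,t] = Cov(z_s, z_t)
  ## z_{t+1} = Phi_t z_t + e_t with Phi [row var_to, col var_from]:
  ## row1 (x_{t+1}) gets ar_x * x_t + cross_yx * y_t
  Phi <- lapply(seq_len(W - 1L), function(t)
    matrix(c(truth$ar_x[t], truth$cross_yx[t],
             truth$cross_xy[t], truth$ar_y[t]), 2, byrow = TRUE))
  Rt <- lapply(seq_len(W - 1L), function(t)
    matrix(c(truth$resid_var_x[t], truth$resid_cov[t],
             truth$resid_cov[t], truth$resid_var_y[t]), 2))
  V <- vector("list", W)
  V[[1L]] <- matrix(c(truth$var1_x, truth$cov1, truth$cov1, truth$var1_y), 2)
  for (t in seq_len(W - 1L))
    V[[t + 1L]] <- Phi[[t]] %*% V[[t]] %*% t(Phi[[t]]) + Rt[[t]]
  Cc <- array(0, c(2, 2, W, W))   # Cov(z_s, z_t), s rows
  for (t in seq_len(W)) Cc[, , t, t] <- V[[t]]
  for (t in seq_len(W)) {
    if (t < W) for (s in (t + 1L):W) {
      Cc[, , s, t] <- Phi[[s - 1L]] %*% Cc[, , s - 1L, t]
      Cc[, , t, s] <- t(Cc[, , s, t])
    }
  }
  sigma <- matrix(0, p, p, dimnames = list(vars, vars))
  for (s in seq_len(W)) for (t in seq_len(W)) {
    blk <- Cc[, , s, t]
    sigma[idx(1L, s), idx(1L, t)] <- sigma[idx(1L, s), idx(1L, t)] + blk[1, 1]
    sigma[idx(1L, s), idx(2L, t)] <- sigma[idx(1L, s), idx(2L, t)] + blk[1, 2]
    sigma[idx(2L, s), idx(1L, t)] <- sigma[idx(2L, s), idx(1L, t)] + blk[2, 1]
    sigma[idx(2L, s), idx(2L, t)] <- sigma[idx(2L, s), idx(2L, t)] + blk[2, 2]
  }
  ## random intercepts: constant across waves
  RI <- matrix(c(truth$ri_var_x, truth$ri_cov, truth$ri_cov, truth$ri_var_y), 2)
  for (s in seq_len(W)) for (t in seq_len(W)) {
    sigma[idx(1L, s), idx(1L, t)] <- sigma[idx(1L, s), idx(1L, t)] + RI[1, 1]
    sigma[idx(1L, s), idx(2L, t)] <- sigma[idx(1L, s), idx(2L, t)] + RI[1, 2]
    sigma[idx(2L, s), idx(1L, t)] <- sigma[idx(2L, s), idx(1L, t)] + RI[2, 1]
    sigma[idx(2L, s), idx(2L, t)] <- sigma[idx(2L, s), idx(2L, t)] + RI[2, 2]
  }
  ## family effect: independent per stream, constant across waves
  for (s in seq_len(W)) for (t in seq_len(W)) {
    sigma[idx(1L, s), idx(1L, t)] <- sigma[idx(1L, s), idx(1L, t)] + truth$family_var
    sigma[idx(2L, s), idx(2L, t)] <- sigma[idx(2L, s), idx(2L, t)] + truth$family_var
  }
  mu <- stats::setNames(c(truth$wave_means[, 1L], truth$wave_means[, 2L]), vars)
  list(sigma = sigma, mu = mu, vars = vars)
}

#' Generate a longitudinal panel dataset
#'
#' Simulates, for every subject in `families`, observed scores
#' `mean + random intercept + family effect + within-person process`, then
#' applies missing-at-random masking: the probability that a cell at wave t
#' is missing follows a logistic model in the subject's observed value of
#' the same stream at wave t-1 (baseline rate only at wave 1 or when the
#' previous cell is itself missing). Masking draws are made for every cell
#' regardless of the rate, so runs that differ only in `missing_rate` share
#' all observed values.
#'
#' @param truth a `panel_truth`.
#' @param families a `family_table` from [gen_family_table()].
#' @param seed integer seed.
#' @param covariate_effects optional named list mapping covariate names to
#'   length-2 numeric vectors (effects on the two random intercepts); each
#'   named covariate is generated standard normal (or Bernoulli(0.5) for
#'   names ending in `_bin`) and shifts the subject's intercepts.
#' @return a `panel_dataset`: list with `data` (wide data frame with
#'   `<var>_w<t>` columns plus ids and covariates), `vars`, `n_waves`,
#'   `families`, `covariates`.
#' @export
gen_panel <- function(truth, families, seed = 1L, covariate_effects = NULL) {
  stopifnot(inherits(truth, "panel_truth"))
  .check_family_table(families)
  n <- nrow(families)
  W <- truth$n_waves
  vx <- truth$variables[1L]; vy <- truth$variables[2L]

  withr::with_seed(seed, {
    fam_ids <- unique(families$family_id)
    f_eff <- matrix(stats::rnorm(2L * length(fam_ids),
                                 sd = sqrt(truth$family_var)),
                    ncol = 2, dimnames = list(fam_ids, NULL))
    fi <- match(families$family_id, fam_ids)

    RI <- matrix(c(truth$ri_var_x, truth$ri_cov, truth$ri_cov, truth$ri_var_y), 2)
    ri <- matrix(stats::rnorm(2L * n), ncol = 2) %*% .psd_sqrt(RI)

    cov_tab <- NULL
    if (length(covariate_effects)) {
      cov_tab <- as.data.frame(lapply(names(covariate_effects), function(nm) {
        if (grepl("_bin$", nm)) stats::rbinom(n, 1L, 0.5) else stats::rnorm(n)
      }))
      names(cov_tab) <- names(covariate_effects)
      for (nm in names(covariate_effects))
        ri <- ri + outer(cov_tab[[nm]], covariate_effects[[nm]])
    }

    S1 <- matrix(c(truth$var1_x, truth$cov1, truth$cov1, truth$var1_y), 2)
    z <- array(0, c(n, 2, W))
    z[, , 1L] <- matrix(stats::rnorm(2L * n), ncol = 2) %*% chol(S1)
    for (t in seq_len(W - 1L)) {
      Phi <- matrix(c(truth$ar_x[t], truth$cross_yx[t],
                      truth$cross_xy[t], truth$ar_y[t]), 2, byrow = TRUE)
      Rt <- matrix(c(truth$resid_var_x[t], truth$resid_cov[t],
                     truth$resid_cov[t], truth$resid_var_y[t]), 2)
      z[, , t + 1L] <- z[, , t] %*% t(Phi) +
        matrix(stats::rnorm(2L * n), ncol = 2) %*% chol(Rt)
    }

    X <- matrix(NA_real_, n, W); Y <- matrix(NA_real_, n, W)
    for (t in seq_len(W)) {
      X[, t] <- truth$wave_means[t, 1L] + ri[, 1L] + f_eff[fi, 1L] + z[, 1L, t]
      Y[, t] <- truth$wave_means[t, 2L] + ri[, 2L] + f_eff[fi, 2L] + z[, 2L, t]
    }

    ## MAR masking: draw uniforms for every cell, compare to the
    ## value-dependent logit probability wave by wave
    Ux <- matrix(stats::runif(n * W), n, W)
    Uy <- matrix(stats::runif(n * W), n, W)
    obs_x <- matrix(TRUE, n, W); obs_y <- matrix(TRUE, n, W)
    for (t in seq_len(W)) {
      base <- stats::qlogis(truth$missing_rate[t])
      if (t == 1L) {
        px <- stats::plogis(base); py <- px
        obs_x[, t] <- Ux[, t] >= px
        obs_y[, t] <- Uy[, t] >= py
      } else {
        zx <- ifelse(obs_x[, t - 1L],
                     (X[, t - 1L] - mean(X[, t - 1L])) / stats::sd(X[, t - 1L]), 0)
        zy <- ifelse(obs_y[, t - 1L],
                     (Y[, t - 1L] - mean(Y[, t - 1L])) / stats::sd(Y[, t - 1L]), 0)
        obs_x[, t] <- Ux[, t] >= stats::plogis(base + truth$mar_strength * zx)
        obs_y[, t] <- Uy[, t] >= stats::plogis(base + truth$mar_strength * zy)
      }
    }
    X[!obs_x] <- NA_real_
    Y[!obs_y] <- NA_real_
  })

  dat <- data.frame(subject_id = families$subject_id,
                    family_id = families$family_id,
                    site_id = families$site_id,
                    stringsAsFactors = FALSE)
  for (t in seq_len(W)) dat[[paste0(vx, "_w", t)]] <- X[, t]
  for (t in seq_len(W)) dat[[paste0(vy, "_w", t)]] <- Y[, t]
  if (!is.null(cov_tab)) dat <- cbind(dat, cov_tab)

  structure(list(data = dat, vars = truth$variables, n_waves = W,
                 families = families,
                 covariates = names(covariate_effects) %||% character()),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d subjects x %d waves of (%s); %d covariates\n",
              nrow(x$data), x$n_waves, paste(x$vars, collapse = ", "),
              length(x$covariates)))
  invisible(x)
}

#' Reshape a panel dataset to tidy long format
#'
#' @param panel a `panel_dataset`.
#' @return data frame with `subject_id`, `wave`, `variable`, `value` (one
#'   row per observed or missing cell), suitable for CSV export.
#' @export
panel_long <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  out <- list()
  for (v in panel$vars) for (t in seq_len(panel$n_waves)) {
    out[[paste(v, t)]] <- data.frame(
      subject_id = panel$data$subject_id, wave = t, variable = v,
      value = panel$data[[paste0(v, "_w", t)]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id, res$wave, res$variable), ]
}
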