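## Bivariate cross-lagged panel model specifications.
##
## Observed variables are named "<var>_w<t>". In the random-intercepts
## variant (RI-CLPM) each observed score decomposes into a stable
## between-person factor (random intercept, loading fixed to 1) and a
## within-person component; autoregressive and cross-lagged paths connect
## the within-person components of adjacent waves. In the traditional CLPM
## the lagged paths connect the observed variables directly.

#' Build a bivariate (RI-)CLPM specification
#'
#' Enumerates, for two symptom streams measured at `n_waves` adjacent waves,
#' the `2 * (n_waves - 1)` autoregressive and `2 * (n_waves - 1)`
#' cross-lagged paths (so 16 lagged paths at 5 waves), wave-specific means,
#' free wave-1 (co)variances and per-wave residual (co)variances. With
#' `random_intercepts = TRUE` two between-person factors with unit loadings
#' are added, their (co)variances free, and the lagged structure moves to
#' the within-person components; at least 3 waves are then required.
#'
#' Path labels are `a_<var>_<t>` (autoregressive, wave t to t+1) and
#' `c_<from>_<to>_<t>` (cross-lagged). Time-invariant covariates enter as
#' predictors of the two random-intercept factors (the two-step covariate
#' procedure); time-variant covariates enter as wave-specific exogenous
#' regressors on the same-wave observed variables.
#'
#' @param n_waves number of measurement waves (>= 2; >= 3 with random
#'   intercepts).
#' @param variables length-2 character vector naming the two streams.
#' @param random_intercepts include between-person random intercepts.
#' @param covariates character vector of time-invariant covariate column
#'   names (regressed onto the random-intercept factors; requires
#'   `random_intercepts = TRUE`).
#' @param tv_covariates character vector of time-variant covariate base
#'   names; columns `<name>_w<t>` regress onto both same-wave observed
#'   variables.
#' @param constrain character subset of
#'   `c("ar_x", "ar_y", "cl_xy", "cl_yx")`: path families whose
#'   wave-specific coefficients are constrained equal across lags (`x`/`y`
#'   refer to `variables[1]`/`variables[2]`).
#' @return a `path_model_spec`; lagged-path labels are in
#'   `attr(spec, "lagged_paths")`.
#' @export
build_clpm_spec <- function(n_waves, variables = c("x", "y"),
                            random_intercepts = TRUE,
                            covariates = character(),
                            tv_covariates = character(),
                            constrain = character()) {
  if (length(variables) != 2L) .stopf("exactly two variables are supported")
  if (random_intercepts && n_waves < 3)
    .stopf("a random-intercepts CLPM requires at least 3 data waves (got %d)",
           n_waves)
  if (!random_intercepts && n_waves < 2) .stopf("n_waves must be >= 2")
  if (length(covariates) && !random_intercepts)
    .stopf("time-invariant covariates are modeled on the random-intercept factors; use random_intercepts = TRUE")
  bad <- setdiff(constrain, c("ar_x", "ar_y", "cl_xy", "cl_yx"))
  if (length(bad)) .stopf("unknown constrain entries: %s", paste(bad, collapse = ", "))

  vx <- variables[1L]; vy <- variables[2L]
  wn <- function(v, t) paste0(v, "_w", t)
  obs <- c(vapply(seq_len(n_waves), function(t) wn(vx, t), ""),
           vapply(seq_len(n_waves), function(t) wn(vy, t), ""))
  tvobs <- unlist(lapply(tv_covariates, function(cv)
    vapply(seq_len(n_waves), function(t) wn(cv, t), "")))
  obs_all <- c(obs, covariates, tvobs)

  rows <- list()
  add <- function(mat, from, to, label, free, start) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, from = from, to = to, label = label, free = free,
      start = start, stringsAsFactors = FALSE)
  }

  if (random_intercepts) {
    ri <- c(paste0("ri_", vx), paste0("ri_", vy))
    wi <- c(vapply(seq_len(n_waves), function(t) paste0("w_", wn(vx, t)), ""),
            vapply(seq_len(n_waves), function(t) paste0("w_", wn(vy, t)), ""))
    latent <- c(ri, wi)
    node <- function(v, t) paste0("w_", wn(v, t))  # lag structure lives here
    for (t in seq_len(n_waves)) {
      add("A", ri[1L], wn(vx, t), paste0("load_ri_", vx, "_", t), FALSE, 1)
      add("A", ri[2L], wn(vy, t), paste0("load_ri_", vy, "_", t), FALSE, 1)
      add("A", node(vx, t), wn(vx, t), paste0("load_w_", vx, "_", t), FALSE, 1)
      add("A", node(vy, t), wn(vy, t), paste0("load_w_", vy, "_", t), FALSE, 1)
    }
    if (length(covariates)) {
      ## covariates predict the between-person factors (two-step procedure)
      for (cv in covariates) {
        add("A", cv, ri[1L], paste0("g_", cv, "_", vx), TRUE, 0)
        add("A", cv, ri[2L], paste0("g_", cv, "_", vy), TRUE, 0)
      }
    }
    add("S", ri[1L], ri[1L], paste0("var_ri_", vx), TRUE, 0.5)
    add("S", ri[2L], ri[2L], paste0("var_ri_", vy), TRUE, 0.5)
    add("S", ri[1L], ri[2L], paste0("cov_ri"), TRUE, 0.1)
  } else {
    latent <- character()
    node <- wn
  }

  ## lagged paths among the within-process nodes
  lagged <- character()
  for (t in seq_len(n_waves - 1L)) {
    la <- if ("ar_x" %in% constrain) paste0("a_", vx) else paste0("a_", vx, "_", t)
    add("A", node(vx, t), node(vx, t + 1L), la, TRUE, 0.2); lagged <- c(lagged, la)
    la <- if ("ar_y" %in% constrain) paste0("a_", vy) else paste0("a_", vy, "_", t)
    add("A", node(vy, t), node(vy, t + 1L), la, TRUE, 0.2); lagged <- c(lagged, la)
    la <- if ("cl_xy" %in% constrain) paste0("c_", vx, "_", vy) else paste0("c_", vx, "_", vy, "_", t)
    add("A", node(vx, t), node(vy, t + 1L), la, TRUE, 0); lagged <- c(lagged, la)
    la <- if ("cl_yx" %in% constrain) paste0("c_", vy, "_", vx) else paste0("c_", vy, "_", vx, "_", t)
    add("A", node(vy, t), node(vx, t + 1L), la, TRUE, 0); lagged <- c(lagged, la)
  }
  lagged <- unique(lagged)

  ## wave-1 (co)variances and per-wave residual (co)variances of the process
  add("S", node(vx, 1L), node(vx, 1L), paste0("var1_", vx), TRUE, 0.5)
  add("S", node(vy, 1L), node(vy, 1L), paste0("var1_", vy), TRUE, 0.5)
  add("S", node(vx, 1L), node(vy, 1L), "cov1", TRUE, 0.1)
  for (t in 2:n_waves) {
    add("S", node(vx, t), node(vx, t), paste0("rvar_", vx, "_", t), TRUE, 0.5)
    add("S", node(vy, t), node(vy, t), paste0("rvar_", vy, "_", t), TRUE, 0.5)
    add("S", node(vx, t), node(vy, t), paste0("rcov_", t), TRUE, 0.1)
  }

  ## free means per observed wave variable (no growth structure)
  for (v in obs) add("M", "1", v, paste0("mean_", v), TRUE, 0)

  ## exogenous covariates: free means, variances, covariances
  exo <- c(covariates, tvobs)
  if (length(exo)) {
    for (i in seq_along(exo)) {
      add("S", exo[i], exo[i], paste0("var_", exo[i]), TRUE, 1)
      add("M", "1", exo[i], paste0("mean_", exo[i]), TRUE, 0)
      if (i < length(exo)) for (j in (i + 1L):length(exo))
        add("S", exo[i], exo[j], paste0("cov_", exo[i], "_", exo[j]), TRUE, 0)
    }
    for (cv in tv_covariates) for (t in seq_len(n_waves)) {
      add("A", wn(cv, t), wn(vx, t), paste0("b_", cv, "_", vx, "_", t), TRUE, 0)
      add("A", wn(cv, t), wn(vy, t), paste0("b_", cv, "_", vy, "_", t), TRUE, 0)
    }
  }

  pt <- do.call(rbind, rows)
  spec <- path_model_spec(vars = c(obs_all, latent), obs = obs_all, ptable = pt)
  nmom <- length(obs_all) * (length(obs_all) + 3) / 2
  if (n_free_params(spec) > nmom)
    .stopf("specification not identified (df < 0)")
  attr(spec, "lagged_paths") <- lagged
  attr(spec, "n_waves") <- n_waves
  attr(spec, "variables") <- variables
  attr(spec, "random_intercepts") <- random_intercepts
  spec
}
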