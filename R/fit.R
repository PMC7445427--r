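## Maximum-likelihood fitting of RAM path models, with full-information
## (casewise) likelihood for incomplete data. Cases are grouped by
## missingness pattern; each pattern contributes its Gaussian likelihood
## through pattern-level sufficient statistics, so the objective cost does
## not grow with n.

## Build pattern-wise sufficient statistics from a numeric data matrix
## (columns = observed variables; NA = missing).
.pattern_stats <- function(X) {
  p <- ncol(X)
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0L
  X <- X[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  idx <- split(seq_len(nrow(X)), key)
  pats <- lapply(idx, function(rows) {
    cols <- which(obs[rows[1L], ])
    Xi <- X[rows, cols, drop = FALSE]
    st <- .ml_cov(Xi)
    list(cols = cols, n = st$n, mean = st$mean, cov = st$cov)
  })
  structure(list(patterns = pats, n = nrow(X), p = p,
                 colnames = colnames(X)),
            class = "fiml_stats")
}

## -2 log-likelihood of (mu, sigma) given pattern statistics.
.neg2ll_patterns <- function(stats, mu, sigma) {
  f <- 0
  for (pg in stats$patterns) {
    k <- length(pg$cols)
    sg <- sigma[pg$cols, pg$cols, drop = FALSE]
    ci <- .chol_info(sg)
    if (is.null(ci)) return(NA_real_)
    d <- pg$mean - mu[pg$cols]
    f <- f + pg$n * (k * log(2 * pi) + ci$logdet +
                       sum(ci$inv * pg$cov) + drop(crossprod(d, ci$inv %*% d)))
  }
  f
}

## Objective: -2LL as a function of the free-parameter vector. Uses the
## precompiled index representation for speed under repeated evaluation.
.make_objective <- function(spec, stats) {
  cmp <- .ram_compile(spec)
  k <- cmp$k; oi <- cmp$obs_idx
  Ik <- diag(k)
  fr <- !is.na(cmp$theta_pos)
  pos <- cmp$theta_pos[fr]
  force(stats)
  function(theta) {
    val <- cmp$fixed
    val[fr] <- theta[pos]
    A <- matrix(0, k, k); S <- matrix(0, k, k); M <- numeric(k)
    A[cmp$iA] <- val[cmp$wA]
    S[cmp$iS1] <- val[cmp$wS]; S[cmp$iS2] <- val[cmp$wS]
    M[cmp$iM] <- val[cmp$wM]
    B <- tryCatch(solve(Ik - A), error = function(e) NULL)
    if (is.null(B)) return(1e12)
    Bo <- B[oi, , drop = FALSE]
    sigma <- Bo %*% S %*% t(Bo)
    sigma <- (sigma + t(sigma)) / 2
    mu <- drop(Bo %*% M)
    f <- .neg2ll_patterns(stats, mu, sigma)
    if (!is.finite(f)) return(1e12)
    f
  }
}

## Extract the observed-variable matrix from the supported input types.
.obs_matrix <- function(data, obs) {
  if (inherits(data, "panel_dataset")) data <- data$data
  if (is.data.frame(data)) {
    miss <- setdiff(obs, names(data))
    if (length(miss))
      .stopf("data is missing model variables: %s", paste(miss, collapse = ", "))
    data <- as.matrix(data[obs])
  } else {
    data <- as.matrix(data)[, obs, drop = FALSE]
  }
  storage.mode(data) <- "double"
  data
}

#' Fit a path model by maximum likelihood
#'
#' Maximizes the Gaussian likelihood of the model-implied mean vector and
#' covariance matrix. Under `estimator = "FIML"` the casewise
#' (full-information) likelihood is used, summed pattern-wise over
#' missingness patterns, which is valid under missing-at-random dropout.
#' Under `"ML"` cases with any missing value are dropped first (listwise
#' deletion); on complete data the two estimators coincide.
#'
#' Optimization is quasi-Newton (`nlminb`) from `n_starts` deterministically
#' jittered starting vectors; the best converged solution is returned.
#' Standard errors come from the observed information (numerical Hessian of
#' the -2 log-likelihood at the optimum).
#'
#' @param spec a `path_model_spec`, e.g. from [build_clpm_spec()].
#' @param data a data frame / matrix containing the observed variables, or a
#'   `panel_dataset` from [gen_panel()].
#' @param estimator `"FIML"` (default) or `"ML"` (listwise).
#' @param n_starts number of optimization starts (default 3).
#' @param se compute standard errors and the parameter covariance (default
#'   `TRUE`).
#' @param control list passed to [stats::nlminb()]'s control.
#' @return An object of class `path_model_fit` with components `estimates`
#'   (per-parameter table with `est`, `se`, `z`, `p`), `theta`, `vcov`,
#'   `loglik`, `n`, `converged`, `grad_norm`.
#' @export
fit_path_model <- function(spec, data, estimator = c("FIML", "ML"),
                           n_starts = 3, se = TRUE, control = list()) {
  estimator <- match.arg(estimator)
  X <- .obs_matrix(data, spec$obs)
  if (estimator == "ML") X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2L) .stopf("fewer than 2 usable cases")
  p <- length(spec$obs)
  nmom <- p * (p + 3) / 2
  if (n_free_params(spec) > nmom)
    .stopf("model is not identified: %d free parameters > %d observed moments",
           n_free_params(spec), nmom)
  stats <- .pattern_stats(X)
  objfn <- .make_objective(spec, stats)
  start0 <- .data_informed_start(spec, stats)

  ctl <- utils::modifyList(list(eval.max = 5000, iter.max = 2000,
                                rel.tol = 1e-11), control)
  best <- NULL
  for (k in seq_len(max(1L, n_starts))) {
    st <- if (k == 1L) start0 else .jitter_start(start0, k)
    opt <- tryCatch(stats::nlminb(st, objfn, control = ctl),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) .stopf("optimization failed from every start")

  theta <- stats::setNames(best$par, spec$free_labels)
  ## numerical gradient norm at the optimum as a convergence diagnostic
  gr <- .num_grad(objfn, best$par)
  grad_norm <- sqrt(sum(gr^2))
  converged <- best$convergence == 0 || grad_norm < 1e-3 * (1 + abs(best$objective))

  vc <- NULL; ses <- rep(NA_real_, length(theta))
  if (se) {
    H <- tryCatch(stats::optimHess(best$par, objfn), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
      if (is.null(vc)) {
        .warnf("observed information is singular; using pseudo-inverse for SEs")
        ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
        pos <- ei$values > max(ei$values) * 1e-10
        vc <- 2 * ei$vectors[, pos, drop = FALSE] %*%
          (t(ei$vectors[, pos, drop = FALSE]) / ei$values[pos])
      }
      dimnames(vc) <- list(names(theta), names(theta))
      d <- diag(vc)
      if (any(d < 0)) .warnf("negative variance estimate in parameter covariance (Heywood-adjacent); SEs set NA where negative")
      ses <- ifelse(d >= 0, sqrt(pmax(d, 0)), NA_real_)
    }
  }

  est <- data.frame(label = names(theta), est = unname(theta),
                    se = unname(ses), row.names = NULL,
                    stringsAsFactors = FALSE)
  est$z <- est$est / est$se
  est$p <- 2 * stats::pnorm(-abs(est$z))

  ## any Heywood variance? (free S diagonal gone negative)
  pt <- spec$ptable
  vlab <- unique(pt$label[pt$free & pt$mat == "S" & pt$from == pt$to])
  if (length(vlab) && any(theta[vlab] < 0))
    .warnf("Heywood case: negative variance estimate for %s",
           paste(vlab[theta[vlab] < 0], collapse = ", "))

  structure(list(spec = spec, theta = theta, vcov = vc, estimates = est,
                 loglik = -best$objective / 2, neg2ll = best$objective,
                 n = stats$n, estimator = estimator, stats = stats,
                 converged = converged, grad_norm = grad_norm),
            class = "path_model_fit")
}

## Crude data-informed starting values: variances from the data scale,
## means from observed means, paths from the spec's declared starts.
.data_informed_start <- function(spec, stats) {
  start <- .ram_start(spec)
  ## observed per-variable mean / variance pooled over patterns
  p <- stats$p
  sm <- numeric(p); sv <- numeric(p); nn <- numeric(p)
  for (pg in stats$patterns) {
    sm[pg$cols] <- sm[pg$cols] + pg$n * pg$mean
    sv[pg$cols] <- sv[pg$cols] + pg$n * (diag(pg$cov) + pg$mean^2)
    nn[pg$cols] <- nn[pg$cols] + pg$n
  }
  ok <- nn > 0
  mu <- ifelse(ok, sm / pmax(nn, 1), 0)
  vv <- ifelse(ok, sv / pmax(nn, 1) - mu^2, 1)
  names(mu) <- names(vv) <- stats$colnames
  pt <- spec$ptable
  for (i in which(pt$free)) {
    lb <- pt$label[i]
    if (pt$mat[i] == "M" && pt$to[i] %in% names(mu)) {
      start[lb] <- mu[pt$to[i]]
    } else if (pt$mat[i] == "S" && pt$from[i] == pt$to[i] &&
               pt$to[i] %in% names(vv)) {
      ## split observed variance across the variance components feeding it
      start[lb] <- max(vv[pt$to[i]] / 2, 0.05)
    }
  }
  start
}

.num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  f0 <- f(x)
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("path_model_fit (%s): n = %d, logLik = %.3f, %d free parameters%s\n",
              x$estimator, x$n, x$loglik, length(x$theta),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(utils::head(x$estimates, 12), digits = 4)
  if (nrow(x$estimates) > 12) cat("  ...", nrow(x$estimates) - 12, "more rows\n")
  invisible(x)
}

#' @export
logLik.path_model_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
coef.path_model_fit <- function(object, ...) object$theta

#' @export
vcov.path_model_fit <- function(object, ...) object$vcov

## ---- saturated & independence likelihoods (for fit indices) -------------

## EM for the unstructured MVN (mu, Sigma) under missingness, run on
## pattern statistics. Complete data converges in one step.
.saturated_neg2ll <- function(stats, max_iter = 500, tol = 1e-8) {
  p <- stats$p; n <- stats$n
  ## initialize from available-case moments
  sm <- numeric(p); nn <- numeric(p)
  for (pg in stats$patterns) { sm[pg$cols] <- sm[pg$cols] + pg$n * pg$mean; nn[pg$cols] <- nn[pg$cols] + pg$n }
  mu <- ifelse(nn > 0, sm / pmax(nn, 1), 0)
  Sg <- diag(p)
  for (pg in stats$patterns) {
    d <- pg$mean - mu[pg$cols]
    Sg[pg$cols, pg$cols] <- Sg[pg$cols, pg$cols] +
      pg$n / n * (pg$cov + tcrossprod(d))
  }
  sigma <- (Sg + t(Sg)) / 2
  complete <- length(stats$patterns) == 1L &&
    length(stats$patterns[[1L]]$cols) == p
  if (complete) {
    pg <- stats$patterns[[1L]]
    return(.neg2ll_patterns(stats, pg$mean, pg$cov))
  }
  f_old <- Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)              # sum E[x]
    T2 <- matrix(0, p, p)         # sum E[x x']
    for (pg in stats$patterns) {
      o <- pg$cols; m <- setdiff(seq_len(p), o)
      ng <- pg$n
      Exx_oo <- ng * (pg$cov + tcrossprod(pg$mean))
      T1[o] <- T1[o] + ng * pg$mean
      T2[o, o] <- T2[o, o] + Exx_oo
      if (length(m)) {
        ci <- .chol_info(sigma[o, o, drop = FALSE])
        if (is.null(ci)) break
        B <- sigma[m, o, drop = FALSE] %*% ci$inv
        mm <- mu[m] + drop(B %*% (pg$mean - mu[o]))          # E mean of missing
        Cv <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
        ## summed expected cross-products; with mm_i = mu_m + B (x_o,i - mu_o):
        ##   sum_i mm_i x_o,i' = ng (mu_m xbar' + B (S_oo + (xbar - mu_o) xbar'))
        ##   sum_i E[x_m x_m'] = ng (Cv + B S_oo B' + mm mm')
        dev_o <- pg$mean - mu[o]
        T1[m] <- T1[m] + ng * mm
        Exm_xo <- ng * (tcrossprod(mu[m], pg$mean) +
                          B %*% (pg$cov + tcrossprod(dev_o, pg$mean)))
        T2[m, o] <- T2[m, o] + Exm_xo
        T2[o, m] <- T2[o, m] + t(Exm_xo)
        BCB <- B %*% pg$cov %*% t(B)
        T2[m, m] <- T2[m, m] + ng * (Cv + BCB + tcrossprod(mm))
      }
    }
    mu_new <- T1 / n
    sigma_new <- T2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    f <- .neg2ll_patterns(stats, mu_new, sigma_new)
    if (!is.finite(f)) break
    mu <- mu_new; sigma <- sigma_new
    if (abs(f_old - f) < tol * (1 + abs(f))) { f_old <- f; break }
    f_old <- f
  }
  attr(f_old, "mu") <- mu
  attr(f_old, "sigma") <- sigma
  f_old
}

## Independence (diagonal-covariance, free means) model: the casewise
## likelihood factorizes, so the MLE is the per-variable observed-case
## mean and ML variance.
.independence_neg2ll <- function(stats) {
  p <- stats$p
  sm <- numeric(p); sv <- numeric(p); nn <- numeric(p)
  for (pg in stats$patterns) {
    sm[pg$cols] <- sm[pg$cols] + pg$n * pg$mean
    sv[pg$cols] <- sv[pg$cols] + pg$n * (diag(pg$cov) + pg$mean^2)
    nn[pg$cols] <- nn[pg$cols] + pg$n
  }
  mu <- sm / nn
  vv <- sv / nn - mu^2
  sum(nn * (log(2 * pi) + log(vv) + 1))
}
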