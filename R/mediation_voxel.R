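## Voxelwise mediation map: at each in-mask voxel, the mediation effect of
## the mediator on the voxel->outcome association, with a bootstrap-based
## t statistic (ab / bootstrap SE), BH FDR over all in-mask voxels, and a
## final constraint that the voxel-outcome association itself be
## significant (p < constraint_alpha, two-sided, uncorrected).

## Per-voxel a*b for one subject sample (vectorized over voxels).
## Xr: n x V voxel data, m, y length n, Qc orthonormal nuisance basis.
.ab_voxels <- function(Xr, m, y, Qc) {
  ## residualize everything on the nuisance space
  Xe <- Xr - Qc %*% crossprod(Qc, Xr)
  me <- drop(m - Qc %*% crossprod(Qc, m))
  ye <- drop(y - Qc %*% crossprod(Qc, y))
  sxx <- colSums(Xe^2)
  sxm <- drop(crossprod(Xe, me))
  sxy <- drop(crossprod(Xe, ye))
  smm <- sum(me^2)
  smy <- sum(me * ye)
  a <- sxm / sxx
  ## b: coefficient of m in y ~ m + x_v (+C), per voxel (2x2 solve)
  det <- smm * sxx - sxm^2
  b <- (sxx * smy - sxm * sxy) / det
  list(a = a, b = b, ab = a * b,
       ## total effect of the voxel on the outcome and its t (constraint)
       c = sxy / sxx, sxx = sxx, sxy = sxy, ye2 = sum(ye^2))
}

#' Voxelwise mediation analysis
#'
#' For every in-mask voxel: path a = voxel -> mediator, path b = mediator
#' -> outcome adjusted for the voxel, mediation effect `ab`, all with
#' covariates partialled. The per-voxel statistic is the bootstrap-based t
#' (`ab` divided by its bootstrap SE over `n_boot` subject resamples),
#' converted to p via the normal reference and FDR-corrected over all
#' in-mask voxels. A voxel is declared significant iff its FDR q <
#' `fdr_q` AND its voxel-outcome association has p < `constraint_alpha`.
#' The unthresholded t map is returned for downstream spatial analyses.
#'
#' @param study a voxel study (see [voxelwise_glm()]).
#' @param mediator,outcome column names in `study$behav` or numeric
#'   vectors.
#' @param covariates nuisance covariates (names or matrix).
#' @param n_boot bootstrap draws per voxel (default 3000; shared across
#'   voxels by resampling subjects once per draw).
#' @param fdr_q FDR level (default .05).
#' @param constraint_alpha two-sided uncorrected level for the
#'   voxel-outcome association constraint (default .005).
#' @return a `mediation_map`: list with vectors over all voxels (`NA`
#'   outside the mask): `ab`, `t_ab` (bootstrap-based t), `q`,
#'   `constraint_p`, `significant`; plus `mask`, `dims`, `n_boot`,
#'   `n_skipped` (degenerate-variance voxels).
#' @export
voxelwise_mediation <- function(study, mediator, outcome, covariates = NULL,
                                n_boot = 3000, fdr_q = 0.05,
                                constraint_alpha = 0.005) {
  .check_study(study)
  b <- study$behav
  m <- if (is.character(mediator)) b[[mediator]] else mediator
  y <- if (is.character(outcome)) b[[outcome]] else outcome
  C <- NULL
  if (length(covariates))
    C <- if (is.character(covariates)) as.matrix(b[covariates]) else as.matrix(covariates)
  n <- nrow(study$images)
  Qc <- .design_q(C, n)
  mask <- as.logical(study$gm_mask %||% rep(TRUE, prod(study$dim)))
  X <- study$images[, mask, drop = FALSE]
  V <- ncol(X)

  ## degenerate voxels (no variance after partialling) are skipped
  Xe0 <- X - Qc %*% crossprod(Qc, X)
  vvar <- colSums(Xe0^2)
  ok <- vvar > 1e-10 * max(vvar)
  n_skipped <- sum(!ok)
  Xok <- X[, ok, drop = FALSE]

  obs <- .ab_voxels(Xok, m, y, Qc)
  dof_c <- n - ncol(Qc) - 1L
  ## constraint: t of voxel -> outcome total association
  rss_c <- obs$ye2 - obs$sxy^2 / obs$sxx
  t_c <- obs$c / sqrt(rss_c / dof_c / obs$sxx)
  p_c <- 2 * stats::pt(-abs(t_c), dof_c)

  ab_boot_mean <- numeric(sum(ok)); ab_boot_m2 <- numeric(sum(ok))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ab_i <- .ab_voxels(Xok[idx, , drop = FALSE], m[idx], y[idx], Qc)$ab
    d <- ab_i - ab_boot_mean
    ab_boot_mean <- ab_boot_mean + d / i
    ab_boot_m2 <- ab_boot_m2 + d * (ab_i - ab_boot_mean)
  }
  ab_se <- sqrt(ab_boot_m2 / (n_boot - 1L))
  t_ab <- obs$ab / ab_se
  p_ab <- 2 * stats::pnorm(-abs(t_ab))
  q <- stats::p.adjust(p_ab, method = "BH")
  sig <- q < fdr_q & p_c < constraint_alpha

  full <- function(v) { out <- rep(NA_real_, prod(study$dim)); out[mask][ok] <- v; out }
  structure(list(ab = full(obs$ab), t_ab = full(t_ab), q = full(q),
                 constraint_p = full(p_c),
                 significant = { s <- rep(FALSE, prod(study$dim)); s[mask][ok] <- sig; s },
                 mask = mask, dims = study$dim, affine = study$affine,
                 n_boot = n_boot, n_skipped = n_skipped,
                 fdr_q = fdr_q, constraint_alpha = constraint_alpha),
            class = "mediation_map")
}

#' @export
print.mediation_map <- function(x, ...) {
  cat(sprintf("mediation_map: %d in-mask voxels, %d significant (q < %g & constraint p < %g), %d skipped\n",
              sum(x$mask), sum(x$significant), x$fdr_q, x$constraint_alpha,
              x$n_skipped))
  invisible(x)
}
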