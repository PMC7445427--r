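## Mass-univariate voxelwise association of gray-matter volume with a
## behavioral score: per-voxel OLS t maps, suprathreshold clustering under
## a chosen connectivity rule, family-aware permutation cluster-level FWE,
## and cluster-overlap logic.

#' Gray-matter mask from a mean image
#'
#' Retains voxels whose mean tissue fraction strictly exceeds `threshold`
#' (default 10% gray matter).
#'
#' @param mean_image 3D numeric array.
#' @param threshold fraction; strict `>` comparison.
#' @return logical array of the same dimensions.
#' @export
make_gm_mask <- function(mean_image, threshold = 0.10) {
  stopifnot(length(dim(mean_image)) == 3L)
  mask <- mean_image > threshold
  if (!any(mask)) .stopf("empty gray-matter mask at threshold %g", threshold)
  mask
}

## study: list(images = n x V matrix, dim = c(i,j,k), affine = 4x4,
##             behav = data.frame, gm_mask = logical array or NULL)
.check_study <- function(study) {
  stopifnot(is.matrix(study$images), length(study$dim) == 3L,
            ncol(study$images) == prod(study$dim))
  invisible(study)
}

## Design pieces for the partialled-predictor GLM.
.glm_parts <- function(study, predictor, covariates) {
  b <- study$behav
  x <- if (is.character(predictor)) b[[predictor]] else predictor
  C <- NULL
  if (length(covariates)) {
    C <- if (is.character(covariates)) as.matrix(b[covariates]) else as.matrix(covariates)
  }
  n <- nrow(study$images)
  stopifnot(length(x) == n)
  if (anyNA(x) || (!is.null(C) && anyNA(C)))
    .stopf("predictor and covariates must be complete for included subjects")
  Xc <- if (is.null(C)) matrix(1, n, 1L) else cbind(1, C)
  qrC <- qr(Xc)
  if (qrC$rank < ncol(Xc)) {
    cols <- colnames(Xc) %||% paste0("col", seq_len(ncol(Xc)))
    .stopf("rank-deficient design; collinear columns among: %s",
           paste(cols, collapse = ", "))
  }
  Qc <- qr.Q(qrC)
  xe <- x - Qc %*% crossprod(Qc, x)
  xnorm2 <- sum(xe^2)
  if (xnorm2 < 1e-12) .stopf("rank-deficient design; predictor collinear with covariates")
  list(Qc = Qc, xe = drop(xe), xnorm2 = xnorm2, n = n,
       dof = n - ncol(Xc) - 1L)
}

#' Voxelwise linear regression t map
#'
#' Per in-mask voxel, the OLS t statistic of `predictor` with `covariates`
#' (plus intercept) partialled out; identical to fitting the full linear
#' model voxel by voxel.
#'
#' @param study a voxel study (list with `images` n x V matrix, `dim`,
#'   `affine`, `behav`, optionally `gm_mask`), e.g. from
#'   [gen_voxel_study()].
#' @param predictor column name in `study$behav` or numeric vector.
#' @param covariates character vector of `study$behav` columns or a
#'   numeric matrix.
#' @return a `glm_result`: list with `t_map` and `coef_map` (vectors over
#'   all voxels, `NA` outside the mask), `dof`, `mask`, `dim`, `affine`.
#' @export
voxelwise_glm <- function(study, predictor, covariates = NULL) {
  .check_study(study)
  parts <- .glm_parts(study, predictor, covariates)
  mask <- as.logical(study$gm_mask %||% rep(TRUE, prod(study$dim)))
  Y <- study$images[, mask, drop = FALSE]
  bn <- drop(crossprod(parts$xe, Y))                 # x~' Y
  beta <- bn / parts$xnorm2
  QtY <- crossprod(parts$Qc, Y)
  rss <- colSums(Y^2) - colSums(QtY^2) - bn^2 / parts$xnorm2
  rss[rss < 0] <- 0
  tv <- beta / sqrt(rss / parts$dof / parts$xnorm2)
  t_map <- rep(NA_real_, prod(study$dim)); t_map[mask] <- tv
  coef_map <- rep(NA_real_, prod(study$dim)); coef_map[mask] <- beta
  structure(list(t_map = t_map, coef_map = coef_map, dof = parts$dof,
                 mask = mask, dim = study$dim, affine = study$affine),
            class = "glm_result")
}

## neighbor offsets for 6/18/26 connectivity on a 3D grid
.conn_offsets <- function(connectivity) {
  d <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  d <- d[!(d$di == 0 & d$dj == 0 & d$dk == 0), ]
  ord <- abs(d$di) + abs(d$dj) + abs(d$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(d)),
                 .stopf("connectivity must be 6, 18 or 26"))
  as.matrix(d[keep, ])
}

## Connected components of a set of voxel linear indices. Returns a list of
## integer vectors (linear indices per cluster).
.components <- function(vox, dims, offsets) {
  if (!length(vox)) return(list())
  idx <- arrayInd(vox, dims)
  inset <- new.env(hash = TRUE, size = length(vox))
  for (q in seq_along(vox)) assign(as.character(vox[q]), q, envir = inset)
  visited <- logical(length(vox))
  out <- list()
  for (s in seq_along(vox)) {
    if (visited[s]) next
    comp <- integer(0); queue <- s; visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      comp <- c(comp, cur)
      ijk <- idx[cur, ]
      for (r in seq_len(nrow(offsets))) {
        nb <- ijk + offsets[r, ]
        if (any(nb < 1L) || any(nb > dims)) next
        lk <- as.character((nb[3L] - 1L) * dims[1L] * dims[2L] +
                             (nb[2L] - 1L) * dims[1L] + nb[1L])
        q <- get0(lk, envir = inset, inherits = FALSE)
        if (!is.null(q) && !visited[q]) { visited[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    out[[length(out) + 1L]] <- vox[comp]
  }
  out
}

#' Suprathreshold clusters of a t map
#'
#' Thresholds the two-sided t map at the voxel level and labels connected
#' components; positive and negative suprathreshold voxels are clustered
#' separately.
#'
#' @param t_map numeric vector (or 3D array) of t values, `NA` outside the
#'   mask.
#' @param dims grid dimensions.
#' @param dof degrees of freedom used to convert `alpha_voxel` to a |t|
#'   threshold.
#' @param alpha_voxel two-sided voxel-level significance level (default
#'   .001).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a `cluster_set`: list with `clusters` (list of voxel index
#'   vectors), `table` (id, size, peak voxel index, peak t, sign),
#'   `threshold`, `connectivity`, `dims`.
#' @export
form_clusters <- function(t_map, dims, dof, alpha_voxel = 0.001,
                          connectivity = 26) {
  t_map <- as.numeric(t_map)
  thr <- stats::qt(1 - alpha_voxel / 2, dof)
  offsets <- .conn_offsets(connectivity)
  clusters <- list(); sign_ <- integer(0)
  for (sg in c(1, -1)) {
    vox <- which(!is.na(t_map) & sg * t_map > thr)
    cc <- .components(vox, dims, offsets)
    clusters <- c(clusters, cc)
    sign_ <- c(sign_, rep(sg, length(cc)))
  }
  tab <- if (length(clusters)) {
    do.call(rbind, lapply(seq_along(clusters), function(i) {
      vv <- clusters[[i]]
      pk <- vv[which.max(abs(t_map[vv]))]
      data.frame(id = i, size = length(vv), peak_voxel = pk,
                 peak_t = t_map[pk], sign = sign_[i])
    }))
  } else {
    data.frame(id = integer(), size = integer(), peak_voxel = integer(),
               peak_t = numeric(), sign = integer())
  }
  structure(list(clusters = clusters, table = tab, threshold = thr,
                 alpha_voxel = alpha_voxel, connectivity = connectivity,
                 dims = dims),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (|t| > %.3f, %d-connectivity)\n",
              length(x$clusters), x$threshold, x$connectivity))
  if (nrow(x$table)) print(x$table, digits = 4)
  invisible(x)
}

## Internal: max cluster size of a t vector over in-mask voxels (both signs
## clustered separately), used inside the permutation loop.
.max_cluster_size <- function(tv, mask_idx, dims, thr, offsets) {
  mx <- 0L
  for (sg in c(1, -1)) {
    vox <- mask_idx[sg * tv > thr]
    if (length(vox) <= mx) next
    cc <- .components(vox, dims, offsets)
    if (length(cc)) mx <- max(mx, max(lengths(cc)))
  }
  mx
}

#' Permutation cluster-level familywise-error correction
#'
#' Computes the observed suprathreshold clusters and, by Freedman-Lane
#' permutation of the image residuals under the family exchangeability
#' blocks, the null distribution of the maximum cluster size. Each
#' observed cluster receives an add-one FWE p value
#' `(1 + #null maxima >= size) / (1 + n_perm)`.
#'
#' @inheritParams voxelwise_glm
#' @param blocks `exchangeability_blocks` for the study subjects, or `NULL`
#'   for unrestricted permutation.
#' @param n_perm number of permutations (default 5000; < 100 warns).
#' @param alpha_voxel two-sided voxel-level threshold (default .001).
#' @param alpha_cluster cluster-level FWE level used for the `significant`
#'   flag (default .05; use .025 when two outcomes share the error budget).
#' @param connectivity 6, 18 or 26.
#' @return the observed `cluster_set` with columns `fwe_p` and
#'   `significant` added to its table, plus `null_max_size` and `glm`.
#' @export
cluster_fwe <- function(study, predictor, covariates = NULL, blocks = NULL,
                        n_perm = 5000, alpha_voxel = 0.001,
                        alpha_cluster = 0.05, connectivity = 26) {
  .check_study(study)
  if (n_perm < 100) .warnf("n_perm = %d gives coarse FWE p resolution", n_perm)
  parts <- .glm_parts(study, predictor, covariates)
  mask <- as.logical(study$gm_mask %||% rep(TRUE, prod(study$dim)))
  mask_idx <- which(mask)
  Y <- study$images[, mask, drop = FALSE]
  n <- parts$n
  if (is.null(blocks)) {
    fake <- data.frame(subject_id = as.character(seq_len(n)),
                       family_id = sprintf("F%d", seq_len(n)),
                       member_type = "single", site_id = "site01",
                       stringsAsFactors = FALSE)
    blocks <- build_blocks(fake)
  }
  stopifnot(blocks$n == n)
  thr <- stats::qt(1 - alpha_voxel / 2, parts$dof)
  offsets <- .conn_offsets(connectivity)

  glm_obs <- voxelwise_glm(study, predictor, covariates)
  obs_clusters <- form_clusters(glm_obs$t_map, study$dim, parts$dof,
                                alpha_voxel, connectivity)

  ## Freedman-Lane on the images: E = residuals of Y on the nuisance space.
  ## For permuted Y* = Qc Qc' Y + P E, the partialled statistic depends on
  ## P E alone: numerator xe' P E, and RSS = ||PE||^2 - ||Qc' PE||^2 -
  ## (xe' PE)^2 / ||xe||^2 (orthogonal decomposition), with ||PE||^2
  ## invariant under row permutation.
  QtY <- crossprod(parts$Qc, Y)
  E <- Y - parts$Qc %*% QtY
  e2 <- colSums(E^2)
  xe <- parts$xe; xn2 <- parts$xnorm2; dof <- parts$dof
  ## For permuted residuals PE, crossprod(A, PE) = crossprod(A[inv, ], E)
  ## with inv the inverse permutation, so the large image matrix is never
  ## copied inside the loop.
  D <- cbind(xe, parts$Qc)
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    p <- draw_permutation(blocks)
    inv <- integer(length(p)); inv[p] <- seq_along(p)
    ct <- crossprod(D[inv, , drop = FALSE], E)
    bn <- ct[1L, ]
    qn <- colSums(ct[-1L, , drop = FALSE]^2)
    rss <- e2 - qn - bn^2 / xn2
    rss[rss < 1e-12] <- 1e-12
    tv <- (bn / xn2) / sqrt(rss / dof / xn2)
    null_max[b] <- .max_cluster_size(tv, mask_idx, study$dim, thr, offsets)
  }
  tab <- obs_clusters$table
  if (nrow(tab)) {
    tab$fwe_p <- vapply(tab$size, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                        numeric(1))
    tab$significant <- tab$fwe_p < alpha_cluster
  } else {
    tab$fwe_p <- numeric(0); tab$significant <- logical(0)
  }
  obs_clusters$table <- tab
  obs_clusters$null_max_size <- null_max
  obs_clusters$alpha_cluster <- alpha_cluster
  obs_clusters$glm <- glm_obs
  obs_clusters
}

#' Overlap of two cluster sets
#'
#' Pairwise voxel-set intersections between the clusters of `a` and `b`;
#' an overlap region is retained iff its intersection size is strictly
#' greater than `min_voxels`. Symmetric in its arguments.
#'
#' @param a,b `cluster_set` objects on the same grid.
#' @param min_voxels retention threshold (strict `>`; default 217, the
#'   smoothing-kernel-derived overlap criterion).
#' @return list with `regions` (list of voxel index vectors) and `table`
#'   (cluster ids in `a` and `b`, overlap size).
#' @export
overlap_clusters <- function(a, b, min_voxels = 217) {
  stopifnot(inherits(a, "cluster_set"), inherits(b, "cluster_set"))
  if (!identical(a$dims, b$dims)) .stopf("cluster sets are on different grids")
  regions <- list(); rows <- list()
  for (i in seq_along(a$clusters)) for (j in seq_along(b$clusters)) {
    iv <- intersect(a$clusters[[i]], b$clusters[[j]])
    if (length(iv) > min_voxels) {
      regions[[length(regions) + 1L]] <- sort(iv)
      rows[[length(rows) + 1L]] <- data.frame(
        a_id = i, b_id = j, size = length(iv))
    }
  }
  list(regions = regions,
       table = if (length(rows)) do.call(rbind, rows) else
         data.frame(a_id = integer(), b_id = integer(), size = integer()),
       min_voxels = min_voxels, dims = a$dims)
}

#' Mean in-region image value per subject
#'
#' Average of each subject's image over a voxel-index region (e.g. an
#' overlap region), giving the per-subject regional gray-matter volume.
#'
#' @param study a voxel study.
#' @param voxels integer vector of voxel linear indices.
#' @return numeric vector, one value per subject.
#' @export
region_mean <- function(study, voxels) {
  .check_study(study)
  rowMeans(study$images[, voxels, drop = FALSE])
}
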