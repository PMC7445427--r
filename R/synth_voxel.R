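## Synthetic voxel image studies with planted spherical clusters whose
## per-subject expression drives a mediator and, through it (plus an
## optional direct path), an outcome. Images are baseline + cluster
## effects + smoothed Gaussian noise; an optional family-shared component
## in both the noise and the behavioral scores makes family blocks matter.

#' Ground truth for the voxel-study generator
#'
#' @param grid_dims voxel counts per axis (keep <= 40^3 for desk scale).
#' @param clusters list of cluster specs, each a list with `center` (voxel
#'   index triple), `radius` (voxels), `effect_mediator` (effect of the
#'   per-subject cluster score on the mediator), `effect_outcome` (direct
#'   effect on the outcome); overlapping clusters are allowed but warned
#'   about.
#' @param smoothing_fwhm Gaussian noise smoothing FWHM in mm (default 8,
#'   matching standard VBM smoothing).
#' @param voxel_size isotropic voxel edge in mm (default 1.5).
#' @param noise_sd marginal SD of the smoothed image noise.
#' @param baseline constant image baseline (gray-matter fraction scale).
#' @param amplitude image increment per unit cluster score.
#' @param med_out_coef mediator -> outcome coefficient.
#' @param family_icc intraclass correlation of cluster scores, image noise
#'   and behavioral scores within family (default 0.3).
#' @return an `image_truth` object.
#' @export
image_truth <- function(grid_dims = c(20, 20, 20), clusters = list(),
                        smoothing_fwhm = 8, voxel_size = 1.5,
                        noise_sd = 0.1, baseline = 0.5, amplitude = 0.2,
                        med_out_coef = 0.3, family_icc = 0.3) {
  stopifnot(length(grid_dims) == 3L)
  for (cl in clusters) {
    stopifnot(all(c("center", "radius") %in% names(cl)))
    if (any(cl$center < 1) || any(cl$center > grid_dims))
      .stopf("cluster center outside the grid")
  }
  structure(list(grid_dims = as.integer(grid_dims), clusters = clusters,
                 smoothing_fwhm = smoothing_fwhm, voxel_size = voxel_size,
                 noise_sd = noise_sd, baseline = baseline,
                 amplitude = amplitude, med_out_coef = med_out_coef,
                 family_icc = family_icc),
            class = "image_truth")
}

## voxel linear indices of a sphere (strictly <= radius, voxel units)
.sphere_voxels <- function(center, radius, dims) {
  rng <- lapply(1:3, function(d)
    max(1L, floor(center[d] - radius)):min(dims[d], ceiling(center[d] + radius)))
  g <- expand.grid(i = rng[[1L]], j = rng[[2L]], k = rng[[3L]])
  dd <- (g$i - center[1L])^2 + (g$j - center[2L])^2 + (g$k - center[3L])^2
  g <- g[dd <= radius^2, ]
  (g$k - 1L) * dims[1L] * dims[2L] + (g$j - 1L) * dims[1L] + g$i
}

## separable 3D Gaussian smoothing of a flat voxel vector
.smooth3d <- function(v, dims, sigma_vox) {
  if (sigma_vox <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(-r:r, sd = sigma_vox)
  kern <- kern / sum(kern)
  arr <- array(v, dims)
  for (d in 1:3) {
    K <- matrix(0, dims[d], dims[d])
    for (o in -r:r) {
      ix <- seq_len(dims[d])
      jx <- ix + o
      keep <- jx >= 1 & jx <= dims[d]
      K[cbind(ix[keep], jx[keep])] <- K[cbind(ix[keep], jx[keep])] + kern[o + r + 1L]
    }
    ## renormalize rows (edge truncation)
    K <- K / rowSums(K)
    arr <- if (d == 1L) {
      array(K %*% matrix(arr, dims[1L]), dims)
    } else if (d == 2L) {
      array(aperm(apply(arr, c(1, 3), function(s) K %*% s), c(2, 1, 3)), dims)
    } else {
      array(apply(arr, c(1, 2), function(s) K %*% s), c(dims[3L], dims[1L], dims[2L])) |>
        aperm(c(2, 3, 1))
    }
  }
  as.numeric(arr)
}

#' Generate a synthetic voxel image study
#'
#' Per subject: `image = baseline + amplitude * sum_k score_k * sphere_k +
#' smoothed noise`, with cluster scores, noise and behavioral residuals
#' carrying a family-shared component of weight `sqrt(family_icc)`. The
#' mediator is a linear function of the cluster scores; the outcome adds
#' `med_out_coef * mediator` and any direct cluster effects. The behavioral
#' table also carries a pure family-correlated `score` column (independent
#' of the images) for null calibration work, plus `age`, `sex` and `tiv`
#' nuisance columns.
#'
#' @param truth an `image_truth`.
#' @param families a `family_table`.
#' @param seed integer seed.
#' @return a voxel study: list with `images` (subjects x voxels matrix),
#'   `dim`, `affine`, `gm_mask` (logical array), `behav` (data frame with
#'   `mediator`, `outcome`, `score`, covariates), `truth`, and
#'   `cluster_voxels` (list of planted voxel index sets).
#' @export
gen_voxel_study <- function(truth, families, seed = 1L) {
  stopifnot(inherits(truth, "image_truth"))
  .check_family_table(families)
  dims <- truth$grid_dims
  V <- prod(dims)
  n <- nrow(families)
  ncl <- length(truth$clusters)
  cl_vox <- lapply(truth$clusters, function(cl)
    .sphere_voxels(cl$center, cl$radius, dims))
  if (ncl > 1L) {
    for (i in seq_len(ncl - 1L)) for (j in (i + 1L):ncl)
      if (length(intersect(cl_vox[[i]], cl_vox[[j]])))
        .warnf("clusters %d and %d overlap", i, j)
  }
  sigma_vox <- truth$smoothing_fwhm / truth$voxel_size / 2.3548
  icc <- truth$family_icc
  fam_ids <- unique(families$family_id)
  fi <- match(families$family_id, fam_ids)
  mix <- function(fam_draw, ind_draw)
    sqrt(icc) * fam_draw[fi] + sqrt(1 - icc) * ind_draw

  withr::with_seed(seed, {
    ## cluster scores (n x ncl)
    scores <- if (ncl) vapply(seq_len(ncl), function(k)
      mix(stats::rnorm(length(fam_ids)), stats::rnorm(n)), numeric(n))
      else matrix(0, n, 0)
    ## family-shared smoothed noise fields
    fam_noise <- matrix(0, length(fam_ids), V)
    if (icc > 0) {
      for (f in seq_along(fam_ids))
        fam_noise[f, ] <- .smooth3d(stats::rnorm(V), dims, sigma_vox)
    }
    images <- matrix(0, n, V)
    for (i in seq_len(n)) {
      noise <- .smooth3d(stats::rnorm(V), dims, sigma_vox)
      if (icc > 0) noise <- sqrt(1 - icc) * noise + sqrt(icc) * fam_noise[fi[i], ]
      img <- truth$baseline + noise * (truth$noise_sd / stats::sd(noise))
      if (ncl) for (k in seq_len(ncl))
        img[cl_vox[[k]]] <- img[cl_vox[[k]]] + truth$amplitude * scores[i, k]
      images[i, ] <- img
    }
    age <- stats::rnorm(n, 10, 0.6)
    sex <- stats::rbinom(n, 1L, 0.5)
    tiv <- stats::rnorm(n, 1500, 100)
    med <- stats::rnorm(n)
    out <- stats::rnorm(n)
    mediator <- mix(stats::rnorm(length(fam_ids)), med)
    outcome_res <- mix(stats::rnorm(length(fam_ids)), out)
    if (ncl) {
      em <- vapply(truth$clusters, function(cl) cl$effect_mediator %||% 0, 0)
      eo <- vapply(truth$clusters, function(cl) cl$effect_outcome %||% 0, 0)
      mediator <- mediator + drop(scores %*% em)
      outcome <- truth$med_out_coef * mediator + drop(scores %*% eo) + outcome_res
    } else {
      outcome <- truth$med_out_coef * mediator + outcome_res
    }
    score <- mix(stats::rnorm(length(fam_ids)), stats::rnorm(n))
  })

  affine <- diag(c(rep(truth$voxel_size, 3), 1))
  affine[1:3, 4] <- -truth$voxel_size * (dims + 1) / 2   # centered, x <= 0 left
  behav <- data.frame(subject_id = families$subject_id,
                      family_id = families$family_id,
                      site_id = families$site_id,
                      mediator = mediator, outcome = outcome, score = score,
                      age = age, sex = sex, tiv = tiv,
                      stringsAsFactors = FALSE)
  mean_img <- array(colMeans(images), dims)
  study <- list(images = images, dim = dims, affine = affine,
                gm_mask = make_gm_mask(mean_img, 0.10),
                behav = behav, truth = truth, cluster_voxels = cl_vox,
                families = families)
  class(study) <- "voxel_study"
  study
}

#' @export
print.voxel_study <- function(x, ...) {
  cat(sprintf("voxel_study: %d subjects, %s grid (%d in-mask voxels), %d planted clusters\n",
              nrow(x$images), paste(x$dim, collapse = "x"), sum(x$gm_mask),
              length(x$cluster_voxels)))
  invisible(x)
}

#' Write a voxel map to NIfTI-1
#'
#' @param v numeric vector or 3D array of voxel values.
#' @param dims grid dimensions (ignored when `v` is an array).
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(v, dims, affine, path) {
  arr <- if (is.array(v) && length(dim(v)) == 3L) v else array(v, dims)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map as array + affine
#'
#' @param path NIfTI file path.
#' @return list with `map` (array) and `affine` (4x4 matrix).
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(map = as.array(img), affine = structure(RNifti::xform(img), code = NULL))
}
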