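test_that("the gray-matter mask uses a strict threshold", {
  dims <- c(6, 6, 6)
  img <- array(0.5, dims)
  expect_equal(sum(make_gm_mask(img, 0.10)), prod(dims))
  img[1, 1, 1] <- 0.10                       # boundary: excluded
  img[1, 1, 2] <- 0.09
  m <- make_gm_mask(img, 0.10)
  expect_false(m[1, 1, 1])
  expect_false(m[1, 1, 2])
  ## counting oracle on a random image
  img2 <- withr::with_seed(201, array(runif(prod(dims)), dims))
  expect_equal(sum(make_gm_mask(img2, 0.10)), sum(img2 > 0.10))
  expect_error(make_gm_mask(array(0.01, dims), 0.10), "empty")
})

test_that("the voxelwise t map matches single-voxel regression fits", {
  fam <- gen_family_table(60, seed = 202)
  tr <- image_truth(grid_dims = c(10, 10, 10), family_icc = 0)
  st <- gen_voxel_study(tr, fam, seed = 203)
  g <- voxelwise_glm(st, "mediator", c("age", "sex", "tiv"))
  vox <- withr::with_seed(204, sample(which(g$mask), 100))
  for (v in vox) {
    sm <- summary(lm(st$images[, v] ~ st$behav$mediator + st$behav$age +
                       st$behav$sex + st$behav$tiv))
    expect_lt(abs(g$t_map[v] - sm$coefficients[2, "t value"]), 1e-8)
  }
  expect_equal(g$dof, 60 - 5)
  ## rank deficiency is reported
  expect_error(voxelwise_glm(st, "mediator",
                             cbind(st$behav$age, st$behav$age)), "collinear")
})

test_that("a null predictor gives calibrated suprathreshold fractions", {
  fam <- gen_family_table(80, c(single = 1), seed = 205)
  tr <- image_truth(grid_dims = c(12, 12, 12), family_icc = 0)
  fr <- vapply(1:6, function(s) {
    st <- gen_voxel_study(tr, fam, seed = 210 + s)
    g <- voxelwise_glm(st, "score", c("age", "sex"))
    thr <- qt(1 - 0.001 / 2, g$dof)
    mean(abs(g$t_map[g$mask]) > thr)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.001), 0.002)
})

test_that("connectivity semantics distinguish corner-touching voxels", {
  dims <- c(5, 5, 5)
  tm <- rep(0, prod(dims))
  v1 <- 1L + 1L * 5L + 1L * 25L + 1L      # (2,2,2) 0-based arithmetic
  ix <- function(i, j, k) (k - 1L) * 25L + (j - 1L) * 5L + i
  tm[ix(2, 2, 2)] <- 6; tm[ix(3, 3, 3)] <- 6   # touch only at a corner
  c26 <- form_clusters(tm, dims, dof = 100, connectivity = 26)
  c6 <- form_clusters(tm, dims, dof = 100, connectivity = 6)
  c18 <- form_clusters(tm, dims, dof = 100, connectivity = 18)
  expect_length(c26$clusters, 1L)
  expect_length(c18$clusters, 2L)
  expect_length(c6$clusters, 2L)
  ## signs cluster separately even when adjacent
  tm2 <- rep(0, prod(dims))
  tm2[ix(2, 2, 2)] <- 6; tm2[ix(3, 2, 2)] <- -6
  expect_length(form_clusters(tm2, dims, dof = 100)$clusters, 2L)
})

test_that("a planted sphere is recovered as one cluster of its exact voxel count", {
  dims <- c(15, 15, 15)
  sph <- neurocascade:::.sphere_voxels(c(8, 8, 8), 4, dims)
  tm <- rep(0, prod(dims)); tm[sph] <- 10
  cs <- form_clusters(tm, dims, dof = 80)
  expect_length(cs$clusters, 1L)
  expect_equal(cs$table$size, length(sph))
  expect_setequal(cs$clusters[[1]], sph)
  ## geometry oracle: voxelized-sphere count by brute-force enumeration
  cnt <- 0L
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    if ((i - 8)^2 + (j - 8)^2 + (k - 8)^2 <= 16) cnt <- cnt + 1L
  expect_equal(length(sph), cnt)
})

test_that("cluster labeling agrees with a brute-force flood fill on small grids", {
  dims <- c(8, 8, 8)
  tm <- withr::with_seed(221, { v <- rep(0, prod(dims))
    v[sample(prod(dims), 60)] <- 5; v })
  cs <- form_clusters(tm, dims, dof = 50, connectivity = 6)
  ## oracle: iterative label propagation over the suprathreshold set
  vox <- which(tm > 0)
  lab <- seq_along(vox)
  ijk <- arrayInd(vox, dims)
  repeat {
    changed <- FALSE
    for (a in seq_along(vox)) for (b in seq_along(vox)) {
      if (lab[a] != lab[b] && sum(abs(ijk[a, ] - ijk[b, ])) == 1L) {
        lab[lab == max(lab[a], lab[b])] <- min(lab[a], lab[b]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(length(cs$clusters), length(unique(lab)))
  expect_setequal(vapply(cs$clusters, length, 1L),
                  as.integer(table(lab)))
})

test_that("planted effects reach the FWE floor and alpha nesting holds", {
  fam <- gen_family_table(100, seed = 231)
  tr <- image_truth(grid_dims = c(12, 12, 12),
                    clusters = list(list(center = c(6, 6, 6), radius = 3,
                                         effect_mediator = 1)))
  st <- gen_voxel_study(tr, fam, seed = 232)
  withr::with_seed(233,
    cf <- cluster_fwe(st, "mediator", c("age", "sex", "tiv"),
                      blocks = build_blocks(fam), n_perm = 199))
  big <- which.max(cf$table$size)
  expect_equal(cf$table$fwe_p[big], 1 / 200)
  expect_true(cf$table$significant[big])
  ## recovered cluster centroid within 2 voxels of the planted center
  cen <- colMeans(arrayInd(cf$clusters[[big]], st$dim))
  expect_lt(sqrt(sum((cen - c(6, 6, 6))^2)), 2)
  ## alpha = .025 rejections are a subset of alpha = .05 on identical draws
  sig05 <- cf$table$fwe_p < 0.05
  sig025 <- cf$table$fwe_p < 0.025
  expect_true(all(!sig025 | sig05))
  expect_warning(cluster_fwe(st, "mediator", blocks = NULL, n_perm = 50),
                 "resolution")
})

test_that("cluster overlap applies the strict >217 rule and is symmetric", {
  dims <- c(12, 12, 40)
  ## an initial segment of column-major linear indices is connected
  mk <- function(vox) {
    tm <- rep(0, prod(dims)); tm[vox] <- 8
    form_clusters(tm, dims, dof = 100)
  }
  a <- mk(1:600)
  ## disjoint sets give no overlap
  expect_equal(nrow(overlap_clusters(a, mk(1001:1400))$table), 0L)
  ## intersection of exactly 217 voxels: rejected under the strict rule
  b217 <- mk(384:600)                       # 217 voxels, all inside a
  ov1 <- overlap_clusters(a, b217, min_voxels = 217)
  expect_equal(nrow(ov1$table), 0L)
  ## a constructed 419-voxel intersection is retained with its exact size
  b419 <- mk(182:900)                       # intersection with a: 182..600
  inter_oracle <- intersect(1:600, 182:900) # set-algebra oracle, 419 voxels
  expect_length(inter_oracle, 419L)
  ov2 <- overlap_clusters(a, b419, min_voxels = 217)
  ov2r <- overlap_clusters(b419, a, min_voxels = 217)
  expect_equal(ov2$table$size, 419L)
  expect_setequal(ov2$regions[[1]], inter_oracle)
  expect_equal(sort(ov2$table$size), sort(ov2r$table$size))
  expect_error(overlap_clusters(a, form_clusters(rep(0, 8), c(2, 2, 2), 10)),
               "different grids")
})

test_that("statistic maps round-trip through NIfTI with their affine", {
  dims <- c(7, 8, 9)
  affine <- diag(c(1.5, 1.5, 1.5, 1)); affine[1:3, 4] <- c(-5, -6, -7)
  v <- withr::with_seed(251, rnorm(prod(dims)))
  path <- file.path(tempdir(), "tmap.nii.gz")
  write_nifti_map(v, dims, affine, path)
  back <- read_nifti_map(path)
  expect_equal(dim(back$map), dims)
  expect_equal(as.numeric(back$map), v, tolerance = 1e-6)
  expect_equal(unname(back$affine[1:3, 1:3]), unname(affine[1:3, 1:3]),
               tolerance = 1e-5)
})
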