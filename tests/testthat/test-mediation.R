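gen_triple <- function(n, a = 0.5, b = 0.3, cp = 0.35, seed = 241,
                       with_cov = FALSE) {
  withr::with_seed(seed, {
    C <- if (with_cov) cbind(cv1 = rnorm(n), cv2 = rbinom(n, 1, 0.5)) else NULL
    x <- rnorm(n) + if (with_cov) 0.3 * C[, 1] else 0
    m <- a * x + rnorm(n) + if (with_cov) 0.2 * C[, 2] else 0
    y <- b * m + cp * x + rnorm(n) + if (with_cov) 0.2 * C[, 1] else 0
    list(x = x, m = m, y = y, C = C)
  })
}

test_that("the mediation identity ab = c - c_prime holds at machine precision", {
  for (s in 1:5) {
    d <- gen_triple(300, seed = 240 + s, with_cov = s %% 2 == 0)
    mr <- suppressWarnings(mediate(d$x, d$m, d$y, d$C, n_boot = 50))
    expect_lt(abs(mr$paths[["c"]] - mr$paths[["c_prime"]] - mr$paths[["ab"]]),
              1e-10)
    expect_true(all(mr$ci[, 1] <= mr$paths & mr$paths <= mr$ci[, 2]))
  }
})

test_that("a planted proportion mediated is recovered by generative algebra", {
  ## a = .5, b = .3, c' = .35: ab = .15, c = .5, proportion = .30
  d <- gen_triple(50000, seed = 251)
  mr <- mediate(d$x, d$m, d$y, n_boot = 300)
  expect_lt(abs(mr$paths[["ab"]] - 0.15), 0.02)
  expect_lt(abs(mr$prop_mediated - 0.30), 0.02)
  expect_true(mr$significant_ab)
})

test_that("null mediation yields CIs covering zero at roughly nominal rate", {
  cover <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- gen_triple(400, b = 0, seed = 260 + r)
    mr <- suppressWarnings(mediate(d$x, d$m, d$y, n_boot = 300))
    if (mr$ci["ab", 1] <= 0 && 0 <= mr$ci["ab", 2]) cover <- cover + 1L
  }
  expect_gte(cover, 16L)
})

test_that("proportion mediated is withheld when the total effect vanishes", {
  ## b and c' cancel: c near zero, ratio unstable
  d <- gen_triple(2000, a = 0.5, b = 0.3, cp = -0.15, seed = 271)
  expect_warning(mr <- mediate(d$x, d$m, d$y, n_boot = 100), "unstable")
  expect_true(is.na(mr$prop_mediated))
})

test_that("prospective mediation reduces to mediate on copied outcomes", {
  d <- gen_triple(500, seed = 281)
  set.seed(42); m1 <- mediate(d$x, d$m, d$y, n_boot = 200)
  set.seed(42); m2 <- mediate_prospective(d$x, d$m, d$y, n_boot = 200)
  expect_identical(m1$paths, m2$paths)
  expect_identical(m1$ci, m2$ci)
  ## missing follow-up rows are dropped with the count logged
  y2 <- d$y; y2[1:50] <- NA
  m3 <- mediate_prospective(d$x, d$m, y2, n_boot = 50)
  expect_equal(m3$n, 450)
  expect_equal(m3$n_dropped, 50)
})

test_that("family-cluster bootstrap resamples whole families", {
  fam <- gen_family_table(200, seed = 291)
  d <- gen_triple(200, seed = 292)
  mr <- mediate(d$x, d$m, d$y, n_boot = 200, families = fam)
  expect_true(is.finite(mr$ci["ab", 1]))
  expect_equal(mr$n, 200)
})

test_that("voxelwise mediation recovers the planted cluster and obeys its constraints", {
  fam <- gen_family_table(150, seed = 301)
  tr <- image_truth(grid_dims = c(12, 12, 12),
                    clusters = list(list(center = c(6, 6, 6), radius = 3,
                                         effect_mediator = 0.8,
                                         effect_outcome = 0.1)))
  st <- gen_voxel_study(tr, fam, seed = 302)
  withr::with_seed(303,
    mm <- voxelwise_mediation(st, "mediator", "outcome",
                              c("age", "sex", "tiv"), n_boot = 300))
  sig <- which(mm$significant)
  expect_gt(length(sig), 10)
  cen <- colMeans(arrayInd(sig, st$dim))
  expect_lt(sqrt(sum((cen - c(6, 6, 6))^2)), 2)
  ## significant voxels satisfy both the FDR and the constraint rule
  expect_true(all(mm$q[sig] < 0.05))
  expect_true(all(mm$constraint_p[sig] < 0.005))
  ## relaxing the constraint can only enlarge the significant set
  withr::with_seed(303,
    mm1 <- voxelwise_mediation(st, "mediator", "outcome",
                               c("age", "sex", "tiv"), n_boot = 300,
                               constraint_alpha = 1))
  expect_true(all(mm$significant <= mm1$significant))
  ## the unthresholded t map is defined over the whole mask
  expect_true(all(is.finite(mm$t_ab[mm$mask])))
})

test_that("null images yield an essentially empty mediation map", {
  fam <- gen_family_table(120, seed = 311)
  tr <- image_truth(grid_dims = c(10, 10, 10), family_icc = 0)
  st <- gen_voxel_study(tr, fam, seed = 312)
  withr::with_seed(313,
    mm <- voxelwise_mediation(st, "mediator", "outcome", c("age", "sex"),
                              n_boot = 200))
  expect_lt(mean(mm$significant[mm$mask]), 0.005)
})
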