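## a fit whose per-path p-values we can overwrite to test the FDR plumbing
fdr_fit <- function() {
  d <- withr::with_seed(151, {
    x1 <- rnorm(200); y1 <- rnorm(200)
    data.frame(x_w1 = x1, y_w1 = y1, x_w2 = 0.4 * x1 + rnorm(200),
               y_w2 = 0.4 * y1 + rnorm(200))
  })
  fit_path_model(build_clpm_spec(2, random_intercepts = FALSE), d)
}

test_that("BH over the lagged-path family matches the brute-force oracle", {
  fit <- fdr_fit()
  lag <- attr(fit$spec, "lagged_paths")
  ## inject a controlled p-value pattern over a 16-path family
  fit16 <- fit
  fit16$estimates <- data.frame(label = sprintf("pth%02d", 1:16),
                                p = seq(0.01, 0.16, by = 0.01))
  res <- fdr_paths(fit16, path_subset = fit16$estimates$label, q = 0.05)
  expect_equal(res$significant, bh_oracle(fit16$estimates$p, 0.05))
  expect_true(all(res$q >= res$p))
  ## randomized pattern, several draws
  for (s in 1:5) {
    pv <- withr::with_seed(160 + s, runif(16)^2)
    fit16$estimates$p <- pv
    res <- fdr_paths(fit16, path_subset = fit16$estimates$label, q = 0.05)
    expect_equal(res$significant, bh_oracle(pv, 0.05))
  }
})

test_that("uniformly strong and singleton p-values behave as expected", {
  fit <- fdr_fit()
  fit$estimates <- data.frame(label = sprintf("pth%02d", 1:16), p = rep(0.001, 16))
  res <- fdr_paths(fit, path_subset = fit$estimates$label, q = 0.05)
  expect_true(all(res$significant))
  fit$estimates <- data.frame(label = "only", p = 0.04)
  res1 <- fdr_paths(fit, path_subset = "only", q = 0.05)
  expect_equal(res1$q, 0.04)
  expect_error(fdr_paths(fit, path_subset = character(0)), "empty")
})

test_that("Wald self-comparison is exactly null and fixed paths are rejected", {
  fit <- fdr_fit()
  w <- wald_compare(fit, "a_x_1", "a_x_1")
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)
  expect_error(wald_compare(fit, "a_x_1", "nope"), "unknown path")
})

test_that("Wald and likelihood-ratio tests agree asymptotically", {
  tr <- plain_truth(n_waves = 3, cross_xy = 0.09, cross_yx = 0.03)
  fam <- gen_family_table(20000, c(single = 1), seed = 171)
  pan <- gen_panel(tr, fam, seed = 172)
  d <- pan$data
  ## 2-wave saturated CLPM over waves 1-2
  spec_free <- build_clpm_spec(2, random_intercepts = FALSE)
  dd <- d[c("x_w1", "y_w1", "x_w2", "y_w2")]
  free <- fit_path_model(spec_free, dd)
  w <- wald_compare(free, "c_x_y_1", "c_y_x_1")
  ## equality-constrained refit via a shared label
  spec_eq <- spec_free
  spec_eq$ptable$label[spec_eq$ptable$label %in% c("c_x_y_1", "c_y_x_1")] <- "c_eq"
  spec_eq <- path_model_spec(spec_eq$vars, spec_eq$obs, spec_eq$ptable)
  eq <- fit_path_model(spec_eq, dd, se = FALSE)
  lr <- eq$neg2ll - free$neg2ll
  expect_gt(lr, 0)
  expect_lt(abs(lr - w$statistic) / w$statistic, 0.15)
})

test_that("planted unequal paths are detected by the Wald test with high power", {
  tr <- plain_truth(n_waves = 3, cross_xy = 0.09, cross_yx = 0.03)
  spec <- build_clpm_spec(2, random_intercepts = FALSE)
  hits <- 0L; n_rep <- 25L
  for (r in seq_len(n_rep)) {
    fam <- gen_family_table(20000, c(single = 1), seed = 3000 + r)
    pan <- gen_panel(tr, fam, seed = 4000 + r)
    dd <- pan$data[c("x_w1", "y_w1", "x_w2", "y_w2")]
    fit <- fit_path_model(spec, dd, n_starts = 1)
    if (wald_compare(fit, "c_x_y_1", "c_y_x_1")$p < 0.005) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("meta-analysis pools by inverse variance", {
  ## homogeneous sites
  est <- data.frame(beta = rep(0.09, 4), se = rep(0.02, 4))
  m <- meta_sites(est, "fixed")
  expect_equal(m$beta, 0.09, tolerance = 1e-10)
  expect_equal(unname(m$ci[2] - m$beta), unname(m$beta - m$ci[1]), tolerance = 1e-10)
  expect_equal(m$weights, rep(0.25, 4), tolerance = 1e-10)
  ## two-site closed form: equal SEs average the estimates
  m2 <- meta_sites(data.frame(beta = c(0.1, 0.2), se = c(0.05, 0.05)), "fixed")
  expect_equal(m2$beta, 0.15, tolerance = 1e-10)
  ## hand-computed unequal weights: w ~ 1/se^2
  m3 <- meta_sites(data.frame(beta = c(0.1, 0.2), se = c(0.05, 0.1)), "fixed")
  expect_equal(m3$beta, (0.1 / 0.0025 + 0.2 / 0.01) / (1 / 0.0025 + 1 / 0.01),
               tolerance = 1e-10)
  ## no heterogeneity: random effects collapses to fixed
  est4 <- data.frame(beta = c(0.09, 0.091, 0.089), se = rep(0.05, 3))
  mf <- meta_sites(est4, "fixed"); mr <- meta_sites(est4, "random")
  expect_equal(mr$beta, mf$beta, tolerance = 1e-10)
  expect_equal(mr$tau2, 0, tolerance = 1e-10)
  expect_error(meta_sites(data.frame(beta = 0.1, se = 0.1)), "2 sites")
  expect_error(meta_sites(data.frame(beta = c(.1, .2), se = c(0, .1))), "positive")
})
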