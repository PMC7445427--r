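## small expression fixture with planted signal
pls_fixture <- function(n = 120, V = 300, n_drivers = 10, loading = 0.8,
                        seed = 351) {
  withr::with_seed(seed, {
    y <- rnorm(n)
    X <- matrix(rnorm(n * V), n, V,
                dimnames = list(NULL, sprintf("G%04d", seq_len(V))))
    drv <- sample(colnames(X), n_drivers)
    X[, drv] <- X[, drv] + loading * y
    list(X = X, y = y, drivers = drv)
  })
}

test_that("component-1 weights match the centered-covariance oracle", {
  fx <- pls_fixture()
  for (sc in c(TRUE, FALSE)) {
    pf <- pls_fit(fx$X, fx$y, n_components = 3, scale = sc)
    Xc <- scale(fx$X, scale = sc)
    if (!sc) Xc <- scale(fx$X, scale = FALSE)
    w_or <- drop(crossprod(Xc, fx$y - mean(fx$y)))
    w_or <- w_or / sqrt(sum(w_or^2))
    expect_gt(abs(sum(pf$weights[, 1] * w_or)), 0.999)
  }
})

test_that("PLS agrees with an independent implementation on the first direction", {
  skip_if_not_installed("mixOmics")
  fx <- pls_fixture(seed = 352)
  pf <- pls_fit(fx$X, fx$y, n_components = 2, scale = TRUE)
  mo <- mixOmics::pls(fx$X, fx$y, ncomp = 2, scale = TRUE, mode = "regression")
  w_mo <- mo$loadings$X[, 1]
  expect_gt(abs(sum(pf$weights[, 1] * w_mo) /
                  sqrt(sum(w_mo^2))), 0.999)
})

test_that("an informative gene dominates and self-prediction saturates", {
  fx <- pls_fixture(V = 200, n_drivers = 1, loading = 2, seed = 353)
  pf <- pls_fit(fx$X, fx$y)
  expect_equal(pf$genes[which.max(abs(pf$weights[, 1]))], fx$drivers)
  ## response duplicated as a column: component 1 explains ~everything
  X2 <- cbind(fx$X, ycopy = fx$y)
  pf2 <- pls_fit(X2, fx$y, n_components = 2, scale = TRUE)
  expect_gt(pf2$varexp[1], 0.5)
  expect_gt(sum(pf2$varexp), 0.95)
  expect_true(all(pf2$varexp >= 0 & pf2$varexp <= 1))
  expect_error(pls_fit(fx$X, rep(1, nrow(fx$X))), "zero variance")
})

test_that("permutation component selection is calibrated and powerful", {
  ## planted strong signal: component 1 at the permutation floor
  fx <- pls_fixture(seed = 354)
  withr::with_seed(355,
    cs <- component_significance(fx$X, fx$y, n_components = 2, n_perm = 199))
  expect_equal(cs$p[1], 1 / 200)
  ## null: rejection of component 1 at alpha = .05 is near nominal
  rej <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    fx0 <- pls_fixture(n = 60, V = 150, loading = 0, seed = 360 + r)
    withr::with_seed(380 + r,
      p0 <- suppressWarnings(component_significance(fx0$X, fx0$y,
                                                    n_components = 1,
                                                    n_perm = 99))$p[1])
    if (p0 < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 4L)       # >= 90% of null seeds non-significant
  expect_warning(component_significance(fx$X, fx$y, 1, n_perm = 50), "coarse")
})

test_that("bootstrap gene z recovers drivers and flips sign exactly", {
  fx <- pls_fixture(n = 150, V = 400, n_drivers = 10, seed = 391)
  set.seed(392)
  bz <- bootstrap_gene_z(fx$X, fx$y, n_boot = 400)
  top <- names(sort(-abs(bz$z)))[1:40]
  expect_gte(sum(fx$drivers %in% top), 8L)
  ## antisymmetry under a sign flip of one column
  flip <- fx$drivers[1]
  X2 <- fx$X; X2[, flip] <- -X2[, flip]
  set.seed(392)
  bz2 <- bootstrap_gene_z(X2, fx$y, n_boot = 400)
  expect_equal(unname(bz2$z[flip]), -unname(bz$z[flip]), tolerance = 1e-10)
  other <- setdiff(names(bz$z), flip)
  expect_equal(bz2$z[other], bz$z[other], tolerance = 1e-10)
})

test_that("leave-one-donor-out is stable with redundant donors and flags a sensitive one", {
  fx <- pls_fixture(n = 60, V = 150, loading = 1, seed = 401)
  ## duplicate donors: identical sample blocks
  X <- rbind(fx$X, fx$X, fx$X)
  y <- c(fx$y, fx$y, fx$y)
  donors <- rep(c("d1", "d2", "d3"), each = 60)
  set.seed(402)
  lo <- loo_donor_validation(X, y, donors, n_boot = 200)
  expect_gt(min(lo$rank_cor), 0.98)
  ## a donor carrying all the signal (half the genome loaded only in d1):
  ## dropping it collapses the ranking
  withr::with_seed(403, {
    n <- 90; V <- 150
    Xs <- matrix(rnorm(n * V), n, V, dimnames = list(NULL, sprintf("G%03d", 1:V)))
    ys <- rnorm(n)
    drv <- sample(colnames(Xs), 75)
    carrier <- rep(c("d1", "d2", "d3"), each = 30)
    Xs[carrier == "d1", drv] <- Xs[carrier == "d1", drv] + 2.5 * ys[carrier == "d1"]
  })
  set.seed(404)
  lo2 <- loo_donor_validation(Xs, ys, carrier, n_boot = 200)
  expect_lt(lo2$rank_cor[lo2$donor == "d1"], 0.5)
  expect_error(loo_donor_validation(fx$X, fx$y, rep("d1", 120)), "3 donors")
})

test_that("ranked export applies the 1% rule, breaks ties by name and round-trips", {
  nm <- sprintf("G%05d", 1:15408)
  z <- withr::with_seed(411, stats::setNames(rnorm(15408), nm))
  tmp <- file.path(tempdir(), "ranks.rnk")
  ex <- export_ranked(z, tmp, top_fraction = 0.01)
  expect_length(ex$top, 154L)
  expect_length(ex$bottom, 154L)
  expect_equal(ex$ranked$gene[1], names(which.max(z)))
  back <- utils::read.table(tmp, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$V1, ex$ranked$gene)
  expect_equal(back$V2, ex$ranked$z, tolerance = 1e-12)
  ## all-equal z: alphabetical ordering
  zt <- stats::setNames(rep(1, 5), c("b", "a", "e", "c", "d"))
  expect_equal(export_ranked(zt)$ranked$gene, sort(names(zt)))
})
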