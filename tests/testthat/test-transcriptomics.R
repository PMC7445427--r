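## hand-built probe matrix: 3 genes, controlled probe structure
tiny_probe_matrix <- function() {
  samples <- data.frame(sample_id = sprintf("A%02d", 1:6),
                        donor_id = rep(c("d1", "d2"), each = 3),
                        x = -(1:6), y = 0, z = 0,
                        region_class = rep(c("subcortical", "cortical"), 3),
                        stringsAsFactors = FALSE)
  probes <- rbind(
    g1_p1 = c(5, 5, 5, 5, 5, 5),
    g2_p1 = rep(5, 6) + 1:6,        # mean 8.5
    g2_p2 = rep(9, 6) + 1:6,        # mean 12.5 <- selected
    g3_p1 = 1:6)
  ann <- data.frame(probe_id = rownames(probes),
                    gene = c("g1", "g2", "g2", "g3"),
                    stringsAsFactors = FALSE)
  list(probes = probes, annotation = ann, samples = samples,
       above_bg = matrix(TRUE, 4, 6))
}

test_that("probe collapse selects the highest-mean probe (with a mean mode)", {
  pm <- tiny_probe_matrix()
  em <- preprocess_probes(pm, collapse = "select", norm = "none")
  expect_equal(unname(em$X[, "g2"]), unname(pm$probes["g2_p2", ]))
  em2 <- preprocess_probes(pm, collapse = "mean", norm = "none")
  expect_equal(unname(em2$X[, "g2"]),
               unname(colMeans(pm$probes[c("g2_p1", "g2_p2"), ])))
  ## single-probe genes collapse to identity
  expect_equal(unname(em$X[, "g3"]), unname(pm$probes["g3_p1", ]))
})

test_that("background filtering drops probes and logs empty genes", {
  pm <- tiny_probe_matrix()
  pm$above_bg[4, ] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)  # g3 below
  expect_message(em <- preprocess_probes(pm, background_fraction = 0.5,
                                         norm = "none"), "dropped")
  expect_false("g3" %in% em$genes)
  expect_equal(em$dropped_genes, "g3")
})

test_that("a fixture built to retain 15408 genes yields exactly that many", {
  n_keep <- 15408; n_drop <- 92; ns <- 4
  genes <- sprintf("G%05d", seq_len(n_keep + n_drop))
  pm <- list(
    probes = matrix(withr::with_seed(321, rnorm((n_keep + n_drop) * ns)),
                    ncol = ns),
    annotation = data.frame(probe_id = sprintf("P%05d", seq_along(genes)),
                            gene = genes, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("A%02d", 1:ns),
                         donor_id = "d1", x = -(1:ns), y = 0, z = 0,
                         region_class = "subcortical",
                         stringsAsFactors = FALSE),
    above_bg = rbind(matrix(TRUE, n_keep, ns), matrix(FALSE, n_drop, ns)))
  em <- suppressMessages(preprocess_probes(pm, norm = "none"))
  expect_equal(ncol(em$X), 15408L)
})

test_that("within-donor normalization stays inside its region class", {
  pm <- tiny_probe_matrix()
  em <- preprocess_probes(pm, norm = "srs")
  expect_true(all(em$X >= 0 & em$X <= 1))
  emz <- preprocess_probes(pm, norm = "zscore")
  ## donor d1 subcortical rows are centered within their block
  rows <- em$samples$donor_id == "d1" & em$samples$region_class == "subcortical"
  if (sum(rows) >= 2) expect_lt(abs(mean(emz$X[rows, "g2"])), 1e-10)
})

test_that("generated expression carries the 182/784 sample split and drivers", {
  mp <- toy_map(seed = 331)
  ex <- gen_expression(expression_truth(n_genes = 400, n_drivers = 10),
                       mp, seed = 332)
  expect_equal(sum(ex$samples$region_class == "subcortical"), 182L)
  expect_equal(sum(ex$samples$region_class == "cortical"), 784L)
  expect_equal(ncol(ex$probes), 966L)
  expect_length(ex$driver_genes, 10L)
  ## left hemisphere only
  expect_true(all(ex$samples$x <= 0))
  ## probe-level output carries >= 1 probe per gene
  expect_true(all(table(ex$annotation$gene) >= 1L))
  ## reproducible
  ex2 <- gen_expression(expression_truth(n_genes = 400, n_drivers = 10),
                        mp, seed = 332)
  expect_identical(ex$probes, ex2$probes)
  ## zero-variance response is unidentifiable
  aff6 <- diag(c(1.5, 1.5, 1.5, 1)); aff6[1:3, 4] <- -10
  flat <- list(map = array(1, c(6, 6, 6)), affine = aff6)
  expect_error(gen_expression(expression_truth(n_samples_subcortical = 5,
                                               n_samples_cortical = 5,
                                               n_genes = 10, n_drivers = 2),
                              flat, seed = 1), "unidentifiable")
})

test_that("spherical ROI sampling equals the exhaustive enumeration oracle", {
  dims <- c(10, 10, 10)
  affine <- diag(c(2, 2, 2, 1)); affine[1:3, 4] <- -10
  ## constant field: every response equals the constant
  const <- list(map = array(2, dims), affine = affine)
  smp <- data.frame(x = c(-4, 0, 3), y = c(-2, 0, 1), z = c(0, -6, 2))
  rs <- sample_response(const, smp, radius_mm = 4)
  expect_equal(rs$response, rep(2, 3))
  ## point sample: radius below half a voxel at a voxel center
  ## (use the same affine as the constant map so world coordinates align)
  mp <- list(map = toy_map(dims, seed = 341, voxel = 2)$map, affine = affine)
  ctr_vox <- c(5, 5, 5)
  world <- (diag(affine)[1:3]) * (ctr_vox - 1) + affine[1:3, 4]
  rs1 <- sample_response(mp, data.frame(x = world[1], y = world[2], z = world[3]),
                         radius_mm = 0.9)
  expect_equal(rs1$n_voxels, 1L)
  expect_equal(rs1$response, mp$map[5, 5, 5])
  ## sphere straddling a planted step edge: brute-force voxel enumeration
  step <- array(0, dims); step[6:10, , ] <- 1
  sp <- list(map = step, affine = affine)
  pt <- c(world[1] + 1, world[2], world[3])
  rs2 <- sample_response(sp, data.frame(x = pt[1], y = pt[2], z = pt[3]),
                         radius_mm = 5)
  acc <- c();
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    w <- 2 * (c(i, j, k) - 1) - 10
    if (sum((w - pt)^2) <= 25) acc <- c(acc, step[i, j, k])
  }
  expect_lt(abs(rs2$response - mean(acc)), 1e-10)
  expect_equal(rs2$n_voxels, length(acc))
  ## empty spheres are dropped with a log entry; all-empty errors out
  far <- data.frame(x = c(world[1], 1e3), y = c(world[2], 0), z = c(world[3], 0))
  expect_message(rs3 <- sample_response(mp, far, radius_mm = 0.9), "dropped")
  expect_equal(rs3$dropped, 2L)
  expect_true(is.na(rs3$response[2]))
  expect_error(sample_response(mp, far[2, ], radius_mm = 0.9), "empty")
})
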