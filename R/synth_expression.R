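## Synthetic probe-level expression with spatially sampled coordinates,
## donors, cortical/subcortical labels, and a planted subset of driver
## genes whose expression covaries with a response statistic map.

#' Ground truth for the expression generator
#'
#' @param n_samples_subcortical,n_samples_cortical tissue sample counts
#'   (defaults 182 and 784, a left-hemisphere subcortical/cortical split).
#' @param n_genes number of unique genes.
#' @param n_drivers number of driver genes whose expression tracks the
#'   response map.
#' @param driver_loading loading of the standardized sampled response on
#'   driver-gene expression (noise SD is 1).
#' @param probe_extra_mean mean number of extra probes per gene (Poisson).
#' @param background_rate fraction of probes that are pure background
#'   (low above-background detection).
#' @param donor_ids donor identifiers (default 6 donors).
#' @param donor_sd SD of gene-specific donor batch offsets.
#' @return an `expression_truth` object.
#' @export
expression_truth <- function(n_samples_subcortical = 182,
                             n_samples_cortical = 784,
                             n_genes = 2000, n_drivers = 20,
                             driver_loading = 0.8,
                             probe_extra_mean = 0.5,
                             background_rate = 0.1,
                             donor_ids = sprintf("donor%d", 1:6),
                             donor_sd = 0.4) {
  stopifnot(n_drivers <= n_genes)
  structure(list(n_samples_subcortical = n_samples_subcortical,
                 n_samples_cortical = n_samples_cortical,
                 n_genes = n_genes, n_drivers = n_drivers,
                 driver_loading = driver_loading,
                 probe_extra_mean = probe_extra_mean,
                 background_rate = background_rate,
                 donor_ids = donor_ids, donor_sd = donor_sd),
            class = "expression_truth")
}

#' Generate probe-level expression tied to a response map
#'
#' Sample coordinates are drawn from in-mask voxels of the response map
#' (subcortical samples from the lower third of the grid, cortical from the
#' rest). Driver genes' expression equals `driver_loading` times the
#' standardized map value at the sample plus unit noise; all other genes
#' are pure noise. Each gene yields one or more probes (probe value = gene
#' value + probe offset + noise); a `background_rate` fraction of probes
#' are pure background with low above-background detection, which the
#' preprocessing filter should remove.
#'
#' @param truth an `expression_truth`.
#' @param response_map list with `map` (3D array), `affine` (4x4), and
#'   optionally `mask` (logical array).
#' @param seed integer seed.
#' @return a `probe_matrix`: list with `probes` (probe x sample),
#'   `above_bg` (logical, probe x sample), `annotation` (probe_id, gene),
#'   `samples` (sample_id, donor_id, x, y, z, region_class), `genes`
#'   (sample x gene noiseless-collapse reference), `driver_genes`
#'   (character), `truth`.
#' @export
gen_expression <- function(truth, response_map, seed = 1L) {
  stopifnot(inherits(truth, "expression_truth"))
  map <- response_map$map
  dims <- dim(map)
  stopifnot(length(dims) == 3L)
  mask <- response_map$mask %||% array(TRUE, dims)
  affine <- response_map$affine
  n_sub <- truth$n_samples_subcortical
  n_cor <- truth$n_samples_cortical
  ns <- n_sub + n_cor

  cand <- which(as.logical(mask) & is.finite(as.numeric(map)))
  ## left hemisphere only (world x <= 0), mirroring the donor coverage
  wx <- (cbind(arrayInd(cand, dims) - 1L, 1) %*% t(affine))[, 1L]
  cand <- cand[wx <= 0]
  ijk <- arrayInd(cand, dims)
  lower <- cand[ijk[, 3L] <= ceiling(dims[3L] / 3)]
  upper <- cand[ijk[, 3L] > ceiling(dims[3L] / 3)]
  if (length(lower) < n_sub || length(upper) < n_cor)
    .stopf("response map too small for the requested sample counts")

  withr::with_seed(seed, {
    vox <- c(sample(lower, n_sub), sample(upper, n_cor))
    region <- rep(c("subcortical", "cortical"), c(n_sub, n_cor))
    donors <- sample(truth$donor_ids, ns, replace = TRUE)
    resp <- as.numeric(map)[vox]
    if (stats::sd(resp) < 1e-12 && truth$driver_loading != 0)
      .stopf("response map has zero variance over the sampled sites; driver loading unidentifiable")
    z <- if (stats::sd(resp) > 0) (resp - mean(resp)) / stats::sd(resp) else resp * 0

    genes <- sprintf("G%05d", seq_len(truth$n_genes))
    drivers <- sample(genes, truth$n_drivers)
    G <- matrix(stats::rnorm(ns * truth$n_genes), ns, truth$n_genes,
                dimnames = list(NULL, genes))
    G[, drivers] <- G[, drivers] + truth$driver_loading * z
    ## gene-specific donor batch offsets
    for (d in truth$donor_ids) {
      rows <- donors == d
      if (any(rows))
        G[rows, ] <- sweep(G[rows, , drop = FALSE], 2L,
                           stats::rnorm(truth$n_genes, sd = truth$donor_sd), "+")
    }

    n_probes <- 1L + stats::rpois(truth$n_genes, truth$probe_extra_mean)
    probe_gene <- rep(seq_len(truth$n_genes), n_probes)
    np <- length(probe_gene)
    is_bg <- stats::runif(np) < truth$background_rate
    offs <- stats::rnorm(np, sd = 0.5)
    P <- G[, probe_gene, drop = FALSE] + outer(rep(1, ns), offs) +
      matrix(stats::rnorm(ns * np, sd = 0.3), ns)
    P[, is_bg] <- matrix(stats::rnorm(ns * sum(is_bg), sd = 0.3), ns)
    above <- matrix(stats::runif(ns * np) <
                      rep(ifelse(is_bg, 0.2, 0.95), each = ns), ns)
  })

  xyz <- cbind(arrayInd(vox, dims) - 1L, 1) %*% t(affine)
  samples <- data.frame(sample_id = sprintf("A%04d", seq_len(ns)),
                        donor_id = donors,
                        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                        region_class = region, voxel = vox,
                        stringsAsFactors = FALSE)
  structure(list(probes = t(P),
                 above_bg = t(above),
                 annotation = data.frame(
                   probe_id = sprintf("P%06d", seq_len(np)),
                   gene = genes[probe_gene], stringsAsFactors = FALSE),
                 samples = samples, genes = G, driver_genes = drivers,
                 truth = truth),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes -> %d genes, %d samples (%d subcortical, %d cortical)\n",
              nrow(x$probes), length(unique(x$annotation$gene)),
              ncol(x$probes), sum(x$samples$region_class == "subcortical"),
              sum(x$samples$region_class == "cortical")))
  invisible(x)
}
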