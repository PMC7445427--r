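## Probe-to-gene preprocessing and spatial sampling of a statistic map at
## tissue coordinates.

## scaled robust sigmoid across a vector (one gene within one donor block)
.srs <- function(x) {
  md <- stats::median(x)
  iq <- stats::IQR(x) / 1.35
  if (iq < 1e-12) return(rep(0.5, length(x)))
  s <- 1 / (1 + exp(-(x - md) / iq))
  rng <- range(s)
  if (diff(rng) < 1e-12) return(rep(0.5, length(x)))
  (s - rng[1L]) / diff(rng)
}

#' Preprocess probe-level expression to a gene-by-sample matrix
#'
#' Pipeline: (1) intensity-based filtering — keep probes called above
#' background in at least `background_fraction` of samples; (2) probe
#' selection by mean — for each gene keep the retained probe with the
#' highest mean intensity (`collapse = "select"`, default) or average the
#' retained probes (`"mean"`); (3) partition samples by region class;
#' (4) within-donor normalization of every gene across each donor's
#' samples inside each region class (`"srs"`, scaled robust sigmoid,
#' default; or `"zscore"`, or `"none"`). Genes whose probes are all
#' filtered out are dropped and logged.
#'
#' @param pm a `probe_matrix` (from [gen_expression()] or built from CSVs).
#' @param background_fraction retention threshold on the above-background
#'   fraction (default 0.5).
#' @param collapse `"select"` or `"mean"`.
#' @param norm `"srs"`, `"zscore"` or `"none"`.
#' @return an `expression_matrix`: list with `X` (sample x gene), `samples`
#'   metadata, `genes`, `dropped_genes`, `normalization`.
#' @export
preprocess_probes <- function(pm, background_fraction = 0.5,
                              collapse = c("select", "mean"),
                              norm = c("srs", "zscore", "none")) {
  collapse <- match.arg(collapse)
  norm <- match.arg(norm)
  stopifnot(!is.null(pm$probes), !is.null(pm$annotation), !is.null(pm$samples))
  P <- pm$probes                       # probe x sample
  ann <- pm$annotation
  stopifnot(nrow(P) == nrow(ann))
  keep <- if (is.null(pm$above_bg)) rep(TRUE, nrow(P)) else
    rowMeans(pm$above_bg) >= background_fraction
  all_genes <- unique(ann$gene)
  Pk <- P[keep, , drop = FALSE]
  annk <- ann[keep, , drop = FALSE]
  dropped <- setdiff(all_genes, unique(annk$gene))
  if (length(dropped))
    message(sprintf("preprocess_probes: %d gene(s) dropped (no probe above background)",
                    length(dropped)))

  gsplit <- split(seq_len(nrow(Pk)), annk$gene)
  genes <- names(gsplit)
  X <- matrix(NA_real_, ncol(P), length(genes),
              dimnames = list(pm$samples$sample_id, genes))
  pmeans <- rowMeans(Pk)
  for (gi in seq_along(gsplit)) {
    rows <- gsplit[[gi]]
    X[, gi] <- if (length(rows) == 1L) Pk[rows, ] else if (collapse == "select")
      Pk[rows[which.max(pmeans[rows])], ] else colMeans(Pk[rows, , drop = FALSE])
  }

  if (norm != "none") {
    for (rc in unique(pm$samples$region_class)) {
      for (dn in unique(pm$samples$donor_id)) {
        rows <- which(pm$samples$region_class == rc & pm$samples$donor_id == dn)
        if (!length(rows)) next
        if (length(rows) == 1L) {   # degenerate block: map to the scale center
          X[rows, ] <- if (norm == "srs") 0.5 else 0
          next
        }
        X[rows, ] <- apply(X[rows, , drop = FALSE], 2L,
                           if (norm == "srs") .srs else function(v) {
                             s <- stats::sd(v)
                             if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
                           })
      }
    }
  }
  structure(list(X = X, samples = pm$samples, genes = genes,
                 dropped_genes = dropped, normalization = norm,
                 collapse = collapse),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes (%s collapse, %s normalization)\n",
              nrow(x$X), ncol(x$X), x$collapse, x$normalization))
  invisible(x)
}

#' Subset an expression matrix to one region class
#'
#' @param em an `expression_matrix`.
#' @param region `"subcortical"` or `"cortical"`.
#' @return an `expression_matrix` restricted to the region's samples.
#' @export
region_subset <- function(em, region) {
  rows <- em$samples$region_class == region
  if (!any(rows)) .stopf("no samples with region_class '%s'", region)
  em$X <- em$X[rows, , drop = FALSE]
  em$samples <- em$samples[rows, , drop = FALSE]
  em
}

#' Spherical-ROI sampling of a statistic map at tissue coordinates
#'
#' For every sample, the mean of the in-mask map voxels whose voxel-center
#' world distance to the sample coordinate is at most `radius_mm`.
#' Samples whose sphere contains no in-mask voxel are dropped and logged.
#'
#' @param stat_map list with `map` (3D array) and `affine` (4x4
#'   voxel-to-world, 0-based indices).
#' @param samples data frame with `x`, `y`, `z` world coordinates (mm).
#' @param radius_mm sphere radius in mm (default 4).
#' @param mask optional logical array; defaults to finite map voxels.
#' @return list with `response` (numeric, NA for dropped samples),
#'   `n_voxels` (sphere voxel counts) and `dropped` (indices).
#' @export
sample_response <- function(stat_map, samples, radius_mm = 4, mask = NULL) {
  map <- stat_map$map
  dims <- dim(map)
  affine <- stat_map$affine
  mask <- if (is.null(mask)) is.finite(map) else (mask & is.finite(map))
  vox <- which(as.logical(mask))
  if (!length(vox)) .stopf("empty mask")
  ijk0 <- arrayInd(vox, dims) - 1L
  world <- cbind(ijk0, 1) %*% t(affine)        # voxel centers, world mm
  vals <- as.numeric(map)[vox]

  ns <- nrow(samples)
  resp <- rep(NA_real_, ns); nv <- integer(ns)
  r2 <- radius_mm^2
  for (s in seq_len(ns)) {
    d2 <- (world[, 1L] - samples$x[s])^2 + (world[, 2L] - samples$y[s])^2 +
      (world[, 3L] - samples$z[s])^2
    inside <- d2 <= r2
    nv[s] <- sum(inside)
    if (nv[s]) resp[s] <- mean(vals[inside])
  }
  dropped <- which(nv == 0L)
  if (length(dropped) == ns) .stopf("every sample sphere is empty")
  if (length(dropped))
    message(sprintf("sample_response: %d sample(s) dropped (empty sphere)",
                    length(dropped)))
  list(response = resp, n_voxels = nv, dropped = dropped,
       radius_mm = radius_mm)
}
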