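## PLS1 (univariate-response partial least squares, NIPALS with deflation)
## relating a spatial response to gene expression, with permutation
## component selection, bootstrap gene z scores, leave-one-donor-out
## stability, and ranked-list export.

## core NIPALS PLS1 on pre-centered (optionally scaled) matrices
.pls1_core <- function(Xc, yc, n_components) {
  V <- ncol(Xc)
  K <- min(n_components, ncol(Xc), nrow(Xc) - 1L)
  W <- matrix(0, V, K); Pl <- matrix(0, V, K)
  Tm <- matrix(0, nrow(Xc), K); qv <- numeric(K)
  tss <- sum(yc^2)
  varexp <- numeric(K)
  Xd <- Xc; yd <- yc
  for (k in seq_len(K)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { K <- k - 1L; break }
    w <- w / nw
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(Xd, tt)) / t2
    q <- sum(yd * tt) / t2
    W[, k] <- w; Pl[, k] <- p; Tm[, k] <- tt; qv[k] <- q
    varexp[k] <- q^2 * t2 / tss
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - q * tt
  }
  list(weights = W[, seq_len(K), drop = FALSE],
       loadings = Pl[, seq_len(K), drop = FALSE],
       scores = Tm[, seq_len(K), drop = FALSE],
       q = qv[seq_len(K)], varexp = varexp[seq_len(K)], K = K)
}

#' Fit a PLS regression of a spatial response on gene expression
#'
#' PLS1 by NIPALS with deflation: the first component's gene weights are
#' proportional to the gene-wise covariance between (centered, optionally
#' scaled) expression and the response. Reports the response variance
#' explained per component.
#'
#' @param X sample x gene matrix or an `expression_matrix` (optionally
#'   region-restricted via [region_subset()]).
#' @param y numeric response per sample (e.g. from [sample_response()]).
#' @param n_components number of components (default 5).
#' @param scale z-score each gene before fitting (default `TRUE`).
#' @return a `pls_result`: list with `weights` (gene x component, unit
#'   norm), `varexp`, `scores`, `genes`, centering/scaling vectors.
#' @export
pls_fit <- function(X, y, n_components = 5, scale = TRUE) {
  if (inherits(X, "expression_matrix")) X <- X$X
  X <- as.matrix(X)
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) < 1e-12) .stopf("response has zero variance")
  ctr <- colMeans(X)
  scl <- if (scale) pmax(apply(X, 2L, stats::sd), 1e-12) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  yc <- y - mean(y)
  core <- .pls1_core(Xc, yc, n_components)
  structure(list(weights = core$weights, loadings = core$loadings,
                 scores = core$scores, varexp = core$varexp,
                 n_components = core$K,
                 genes = colnames(X) %||% sprintf("g%d", seq_len(ncol(X))),
                 center = ctr, scale = scl, scaled = scale, y = y),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("pls_result: %d genes, %d components; response variance explained: %s\n",
              nrow(x$weights), x$n_components,
              paste(sprintf("%.3f", x$varexp), collapse = ", ")))
  invisible(x)
}

#' Permutation test of PLS component variance explained
#'
#' Permutes the response across samples and compares, per component index,
#' the observed response variance explained with its permutation null;
#' p values use the add-one estimator.
#'
#' @inheritParams pls_fit
#' @param n_perm number of permutations (default 5000; < 100 warns).
#' @return list with `p` (per component), `observed` variance explained,
#'   and the null matrix.
#' @export
component_significance <- function(X, y, n_components = 5, n_perm = 5000,
                                   scale = TRUE) {
  if (inherits(X, "expression_matrix")) X <- X$X
  X <- as.matrix(X)
  if (n_perm < 100) .warnf("n_perm = %d gives coarse permutation resolution", n_perm)
  obs <- pls_fit(X, y, n_components, scale = scale)
  K <- obs$n_components
  null <- matrix(0, n_perm, K)
  ctr <- colMeans(X)
  scl <- if (scale) pmax(apply(X, 2L, stats::sd), 1e-12) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(length(y))]
    null[b, ] <- .pls1_core(Xc, yp - mean(yp), K)$varexp[seq_len(K)]
  }
  p <- vapply(seq_len(K), function(k)
    (1 + sum(null[, k] >= obs$varexp[k])) / (1 + n_perm), numeric(1))
  list(p = p, observed = obs$varexp, null = null, n_perm = n_perm)
}

#' Bootstrap z scores for component-1 gene weights
#'
#' Resamples samples with replacement, refits the PLS, aligns each
#' bootstrap component-1 weight vector's sign to the original (by the sign
#' of their correlation), and returns `z = original weight / bootstrap SE`
#' together with the ranked gene list (descending z; ties broken by gene
#' name).
#'
#' @inheritParams pls_fit
#' @param n_boot bootstrap draws (default 5000).
#' @return list with `z` (named per gene), `weights`, `se`, `ranked` (data
#'   frame gene/z sorted), `n_redrawn` (degenerate draws discarded).
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 5000, scale = TRUE) {
  if (inherits(X, "expression_matrix")) X <- X$X
  X <- as.matrix(X)
  obs <- pls_fit(X, y, n_components = 1L, scale = scale)
  w0 <- obs$weights[, 1L]
  n <- nrow(X)
  ## component-1 weights are the unit-normalized (scaled) covariance
  ## X_c' y_c, so each resample reduces to column moments + one crossprod
  comp1_w <- function(Xb, yb) {
    nb <- nrow(Xb)
    yc <- yb - mean(yb)
    w <- drop(crossprod(Xb, yc))             # equals Xc' yc since sum(yc)=0
    if (scale) {
      xbar <- colMeans(Xb)
      sdx <- sqrt(pmax((colSums(Xb^2) - nb * xbar^2) / (nb - 1L), 1e-24))
      w <- w / sdx
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) return(NULL)
    w / nw
  }
  mean_w <- numeric(length(w0)); m2_w <- numeric(length(w0))
  n_redrawn <- 0L; b <- 0L
  while (b < n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (n_redrawn > 100L + 10L * n_boot)
      .stopf("too many degenerate bootstrap draws (constant response)")
    if (stats::sd(yb) < 1e-12) { n_redrawn <- n_redrawn + 1L; next }
    wb <- comp1_w(X[idx, , drop = FALSE], yb)
    if (is.null(wb)) { n_redrawn <- n_redrawn + 1L; next }
    if (sum(wb * w0) < 0) wb <- -wb        # sign alignment
    b <- b + 1L
    d <- wb - mean_w
    mean_w <- mean_w + d / b
    m2_w <- m2_w + d * (wb - mean_w)
  }
  se <- sqrt(m2_w / (n_boot - 1L))
  z <- ifelse(se > 0, w0 / se, NA_real_)
  names(z) <- obs$genes
  ord <- order(-z, obs$genes)
  ranked <- data.frame(gene = obs$genes[ord], z = z[ord],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(z = z, weights = stats::setNames(w0, obs$genes), se = se,
       ranked = ranked, n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Leave-one-donor-out stability of the gene ranking
#'
#' Recomputes the bootstrap gene z leaving out one donor's samples at a
#' time and reports the Spearman rank correlation with the full-data z.
#'
#' @inheritParams bootstrap_gene_z
#' @param donor_ids donor label per sample.
#' @param n_boot bootstrap draws per left-out fit (default 500).
#' @return data frame with `donor`, `n_left_out`, `rank_cor`; the full-data
#'   z is attached as an attribute.
#' @export
loo_donor_validation <- function(X, y, donor_ids, n_boot = 500, scale = TRUE) {
  if (inherits(X, "expression_matrix")) {
    donor_ids <- donor_ids %||% X$samples$donor_id
    X <- X$X
  }
  donors <- unique(donor_ids)
  if (length(donors) < 3L) .stopf("need at least 3 donors")
  full <- bootstrap_gene_z(X, y, n_boot = n_boot, scale = scale)
  rows <- lapply(donors, function(d) {
    keep <- donor_ids != d
    if (!any(keep)) .stopf("donor %s carries all samples", d)
    zi <- bootstrap_gene_z(X[keep, , drop = FALSE], y[keep],
                           n_boot = n_boot, scale = scale)$z
    data.frame(donor = d, n_left_out = sum(!keep),
               rank_cor = stats::cor(full$z, zi, method = "spearman",
                                     use = "complete.obs"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_z") <- full$z
  out
}

#' Export a ranked gene list
#'
#' Writes a two-column tab-separated rank file (gene, z; descending, ties
#' broken by gene name) in the preranked-GSEA format, plus top/bottom
#' fraction gene lists (`floor(fraction * n)` genes each).
#'
#' @param z named numeric vector of gene z scores (or the result of
#'   [bootstrap_gene_z()]).
#' @param path output `.rnk` path; top/bottom lists are written next to it
#'   (suffixes `_top.txt`, `_bottom.txt`). Use `NULL` to skip writing.
#' @param top_fraction fraction for the extreme lists (default 0.01).
#' @return list with `ranked` (data frame), `top`, `bottom` (character
#'   vectors), and the written paths.
#' @export
export_ranked <- function(z, path = NULL, top_fraction = 0.01) {
  if (is.list(z) && !is.null(z$z)) z <- z$z
  stopifnot(!is.null(names(z)))
  ord <- order(-z, names(z))
  ranked <- data.frame(gene = names(z)[ord], z = unname(z[ord]),
                       stringsAsFactors = FALSE)
  k <- floor(top_fraction * nrow(ranked))
  top <- utils::head(ranked$gene, k)
  bottom <- utils::tail(ranked$gene, k)
  paths <- NULL
  if (!is.null(path)) {
    utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    tp <- sub("\\.rnk$", "_top.txt", path)
    bp <- sub("\\.rnk$", "_bottom.txt", path)
    writeLines(top, tp); writeLines(bottom, bp)
    paths <- c(rnk = path, top = tp, bottom = bp)
  }
  list(ranked = ranked, top = top, bottom = bottom, paths = paths,
       top_fraction = top_fraction)
}
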