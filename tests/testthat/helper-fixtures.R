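## Shared fixtures and independent oracles used across the test files.

## tiny family table built by hand
tiny_families <- function(types = c("twin", "twin", "single", "single", "single")) {
  sizes <- c(single = 1L, sibling = 2L, twin = 2L, triplet = 3L)[types]
  data.frame(
    subject_id = sprintf("S%03d", seq_len(sum(sizes))),
    family_id = rep(sprintf("F%02d", seq_along(types)), times = sizes),
    member_type = rep(types, times = sizes),
    site_id = "site01",
    stringsAsFactors = FALSE)
}

## all permutations of a vector (small n), as a list
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

## exhaustive enumeration of legal block permutations (oracle for
## n_legal_permutations and draw_permutation support)
enumerate_legal_perms <- function(blocks) {
  ## per signature class: choose a family order, then a member order per slot
  class_options <- lapply(blocks$classes, function(cl) {
    fams <- lapply(cl, function(i) blocks$families[[i]])
    slot_rows <- lapply(fams, `[[`, "rows")
    opts <- list()
    for (ford in all_perms(seq_along(cl))) {
      member_orders <- lapply(ford, function(j) all_perms(fams[[j]]$rows))
      grids <- expand.grid(lapply(member_orders, seq_along))
      for (r in seq_len(nrow(grids))) {
        assign_ <- integer(0); dest <- integer(0)
        for (j in seq_along(cl)) {
          dest <- c(dest, slot_rows[[j]])
          assign_ <- c(assign_, member_orders[[j]][[grids[r, j]]])
        }
        key <- integer(blocks$n)
        key[dest] <- assign_
        opts[[length(opts) + 1L]] <- key
      }
    }
    opts
  })
  ## combine classes: each class fills only its own slots
  combined <- list(integer(blocks$n))
  for (opts in class_options) {
    combined <- unlist(lapply(combined, function(base) {
      lapply(opts, function(k) { out <- base; out[k != 0] <- k[k != 0]; out })
    }), recursive = FALSE)
  }
  unique(combined)
}

## brute-force Benjamini-Hochberg: largest k with p_(k) <= k q / m
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rej <- logical(m)
  if (is.finite(k) && k >= 1) rej[ord[seq_len(k)]] <- TRUE
  rej
}

## small default panel truth without nuisance variance components, so OLS
## oracles apply cleanly
plain_truth <- function(...) {
  panel_truth(ri_var_x = 0, ri_var_y = 0, ri_cov = 0, family_var = 0,
              cov1 = 0, resid_cov = 0, ...)
}

## smooth random statistic map + affine on a small grid
toy_map <- function(dims = c(20, 20, 20), seed = 1, voxel = 1.5) {
  m <- withr::with_seed(seed,
    array(neurocascade:::.smooth3d(stats::rnorm(prod(dims)), dims, 2), dims))
  affine <- diag(c(rep(voxel, 3), 1))
  affine[1:3, 4] <- -voxel * (dims + 1) / 2
  list(map = m, affine = affine)
}
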