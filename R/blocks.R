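## Exchangeability blocks for family data and legal multilevel permutations.
##
## Families may swap wholesale only with families of identical composition
## signature (size x member-type); members within a multi-member family
## (siblings, twins, triplets) are exchangeable with each other. A legal
## permutation therefore factorizes as: permute family order within each
## signature class, then permute members within each family.

#' Build exchangeability blocks from a family table
#'
#' @param families a `family_table` (columns `subject_id`, `family_id`,
#'   `member_type`, `site_id`).
#' @return an `exchangeability_blocks` object: list with `families` (one
#'   entry per family: subject row indices, signature, within-family
#'   exchangeability flag), `classes` (family indices grouped by
#'   signature), `n` and `subject_id`.
#' @export
build_blocks <- function(families) {
  .check_family_table(families)
  fam_ids <- unique(families$family_id)
  fams <- lapply(fam_ids, function(fid) {
    rows <- which(families$family_id == fid)
    ty <- families$member_type[rows[1L]]
    list(family_id = fid, rows = rows, size = length(rows),
         signature = paste0(ty, ":", length(rows)),
         exchangeable = length(rows) > 1L)
  })
  sig <- vapply(fams, `[[`, "", "signature")
  classes <- split(seq_along(fams), sig)
  structure(list(families = fams, classes = classes,
                 n = nrow(families), subject_id = families$subject_id),
            class = "exchangeability_blocks")
}

#' @export
print.exchangeability_blocks <- function(x, ...) {
  cat(sprintf("exchangeability_blocks: %d subjects, %d families, %d signature classes\n",
              x$n, length(x$families), length(x$classes)))
  for (nm in names(x$classes))
    cat(sprintf("  %-12s %d families\n", nm, length(x$classes[[nm]])))
  invisible(x)
}

#' Number of legal permutations implied by the blocks
#'
#' `prod over signature classes of k! * prod over families of size!`
#' (as a double; exact only while below 2^53).
#'
#' @param blocks an `exchangeability_blocks`.
#' @return numeric count of distinct legal permutations.
#' @export
n_legal_permutations <- function(blocks) {
  out <- 1
  for (cl in blocks$classes) {
    out <- out * factorial(length(cl))
    for (i in cl) out <- out * factorial(blocks$families[[i]]$size)
  }
  out
}

#' Draw one legal permutation uniformly at random
#'
#' Shuffles family order independently within each signature class, then
#' shuffles members within each multi-member family. The returned vector
#' `perm` relabels subjects: position i receives subject `perm[i]`, and
#' family co-membership is preserved under the relabeling.
#'
#' @param blocks an `exchangeability_blocks`.
#' @return integer permutation vector of length `blocks$n`.
#' @export
draw_permutation <- function(blocks) {
  stopifnot(inherits(blocks, "exchangeability_blocks"))
  perm <- integer(blocks$n)
  for (cl in blocks$classes) {
    src <- if (length(cl) > 1L) cl[sample.int(length(cl))] else cl
    for (j in seq_along(cl)) {
      dest <- blocks$families[[cl[j]]]$rows        # slot positions
      rows <- blocks$families[[src[j]]]$rows       # donor subjects
      if (length(rows) > 1L) rows <- rows[sample.int(length(rows))]
      perm[dest] <- rows
    }
  }
  perm
}

#' Draw a matrix of legal permutations
#'
#' @param blocks an `exchangeability_blocks`.
#' @param n_perm number of draws.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return integer matrix (`n_perm` rows), one legal permutation per row.
#' @export
draw_permutations <- function(blocks, n_perm, seed = NULL) {
  draw <- function() t(vapply(seq_len(n_perm), function(i) draw_permutation(blocks),
                              integer(blocks$n)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
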