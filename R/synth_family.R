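## Synthetic family structures: singles, sibling pairs, twin pairs and
## triplet sets, assigned to data-collection sites. The mix mirrors the
## family-relationship composition typical of a large multi-site pediatric
## cohort (~76% singletons, ~18% twins, few siblings/triplets).

.family_sizes <- c(single = 1L, sibling = 2L, twin = 2L, triplet = 3L)

#' Generate a synthetic family-structure table
#'
#' Allocates `n_subjects` to families so that the fraction of subjects of
#' each member type matches `proportions` up to family-size rounding.
#' Twins always appear in pairs, triplets in threes; sibling families are
#' generated as pairs. Families are assigned uniformly to `n_sites` sites.
#'
#' @param n_subjects total number of subjects.
#' @param proportions named numeric vector over
#'   `c("single", "sibling", "twin", "triplet")` (may omit zero entries);
#'   must sum to 1.
#' @param n_sites number of data-collection sites.
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @return a `family_table`: data frame with columns `subject_id`,
#'   `family_id`, `member_type`, `site_id`.
#' @examples
#' fam <- gen_family_table(1000,
#'   c(single = .762, sibling = .056, twin = .179, triplet = .003),
#'   n_sites = 5, seed = 1)
#' table(fam$member_type)
#' @export
gen_family_table <- function(n_subjects,
                             proportions = c(single = 0.762, sibling = 0.056,
                                             twin = 0.179, triplet = 0.003),
                             n_sites = 1L, seed = 1L) {
  types <- names(.family_sizes)
  pr <- stats::setNames(numeric(4), types)
  if (is.null(names(proportions)) || !all(names(proportions) %in% types))
    .stopf("proportions must be named with: %s", paste(types, collapse = ", "))
  pr[names(proportions)] <- proportions
  if (any(pr < 0) || any(pr > 1)) .stopf("proportions must lie in [0, 1]")
  if (abs(sum(pr) - 1) > 1e-9) .stopf("proportions must sum to 1 (got %.6f)", sum(pr))

  ## family counts: round subject shares to whole families, then absorb the
  ## remainder into singleton families
  n_fam <- stats::setNames(integer(4), types)
  for (ty in c("triplet", "twin", "sibling")) {
    n_fam[ty] <- round(n_subjects * pr[ty] / .family_sizes[ty])
  }
  used <- sum(n_fam * .family_sizes)
  while (used > n_subjects) {     # shrink the largest multi-member class
    big <- which.max(n_fam * .family_sizes)
    n_fam[big] <- n_fam[big] - 1L
    used <- sum(n_fam * .family_sizes)
  }
  n_fam["single"] <- n_subjects - used
  stopifnot(sum(n_fam * .family_sizes) == n_subjects)

  withr::with_seed(seed, {
    fam_type <- rep(types, times = n_fam)
    fam_type <- sample(fam_type)              # interleave family order
    k <- length(fam_type)
    fam_id <- sprintf("F%05d", seq_len(k))
    site <- sprintf("site%02d", sample.int(n_sites, k, replace = TRUE))
    sizes <- .family_sizes[fam_type]
    out <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n_subjects)),
      family_id = rep(fam_id, times = sizes),
      member_type = rep(fam_type, times = sizes),
      site_id = rep(site, times = sizes),
      stringsAsFactors = FALSE)
  })
  class(out) <- c("family_table", "data.frame")
  out
}

.check_family_table <- function(families) {
  need <- c("subject_id", "family_id", "member_type", "site_id")
  if (!all(need %in% names(families)))
    .stopf("family table must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(families$subject_id))
    .stopf("subject appears in more than one family row")
  sz <- table(families$family_id)
  ty <- tapply(families$member_type, families$family_id, function(x) unique(x))
  if (any(lengths(ty) != 1L)) .stopf("member_type must be consistent within family")
  ty <- vapply(ty, `[`, "", 1L)
  want <- unname(.family_sizes[ty])
  if (any(as.integer(sz[names(ty)]) != want))
    .stopf("family size inconsistent with member_type (twins: 2, triplets: 3, siblings: 2, singles: 1)")
  invisible(families)
}
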