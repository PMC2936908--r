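#' Label sister pairs as niche-different or not
#'
#' Joins extracted terminal sister pairs to a niche coding and sets
#' `niche_different = 1` when the two species' niches are `"different"`
#' under [niche_overlap()] (distinct feeding habits and/or non-overlapping
#' host ranges), 0 when identical or overlapping. Pairs in which either
#' member is absent from the coding or coded unknown are dropped with a
#' warning: only ingroup species with coded niches are informative.
#'
#' @param pairs data frame from [extract_sister_pairs()].
#' @param coding a `"niche_coding"`.
#' @return a data frame (`tip_a`, `tip_b`, `split_age`, `niche_different`),
#'   one row per retained pair.
#' @export
classify_pairs <- function(pairs, coding) {
  stopifnot(is.data.frame(pairs), inherits(coding, "niche_coding"))
  keep <- logical(nrow(pairs))
  label <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$tip_a[i]; b <- pairs$tip_b[i]
    ia <- coding$assignment[a][[1L]]
    ib <- coding$assignment[b][[1L]]
    if (!a %in% names(coding$assignment) ||
        !b %in% names(coding$assignment) || is.na(ia) || is.na(ib)) {
      warning("pair (", a, ", ", b, ") dropped: unknown or uncoded niche")
      next
    }
    keep[i] <- TRUE
    label[i] <- as.integer(
      niche_overlap(coding$catalog[[ia]], coding$catalog[[ib]]) == "different")
  }
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no sister pair has both niches coded; regression impossible")
  out$niche_different <- label[keep]
  rownames(out) <- NULL
  out
}

#' Raw proportion of niche-different sister pairs
#'
#' The uncorrected estimate of the ecological-speciation fraction: the
#' share of terminal sister pairs whose niches differ, ignoring split age.
#'
#' @param dataset data frame from [classify_pairs()].
#' @return list with `n`, `n_different`, `fraction`, and `percent` (the
#'   percentage rounded to one decimal).
#' @examples
#' d <- data.frame(split_age = runif(35),
#'                 niche_different = rep(c(1, 0), c(19, 16)))
#' proportion_different(d)$percent
#' @export
proportion_different <- function(dataset) {
  stopifnot(is.data.frame(dataset), "niche_different" %in% names(dataset))
  n <- nrow(dataset)
  if (n == 0L) stop("empty pair dataset")
  nd <- sum(dataset$niche_different == 1L)
  list(n = n, n_different = nd, fraction = nd / n,
       percent = round(100 * nd / n, 1))
}
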