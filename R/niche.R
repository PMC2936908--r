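#' Construct a niche state
#'
#' A niche is the combination of a larval feeding habit (external folivory,
#' galling, leaf folding, catkin feeding, berry mining, needle feeding, ...)
#' and the nonempty set of host-plant taxa the species uses. Host labels are
#' opaque strings: the caller chooses whether they are families, genera or
#' species. A niche whose host set has more than one member is a generalist
#' (oligo-/polyphagous) state.
#'
#' @param habit feeding-habit label (length-1 character).
#' @param hosts character vector of host-plant taxon labels; duplicates are
#'   collapsed and order is irrelevant.
#' @return an object of class `"niche_state"`.
#' @examples
#' niche_state("external_folivory", c("Salix", "Betula"))
#' @export
niche_state <- function(habit, hosts) {
  stopifnot(is.character(habit), length(habit) == 1L, nzchar(habit))
  hosts <- sort(unique(as.character(hosts)))
  hosts <- hosts[nzchar(hosts)]
  if (length(hosts) == 0L) stop("a niche state needs at least one host")
  structure(list(habit = habit, hosts = hosts),
            class = "niche_state")
}

#' @export
print.niche_state <- function(x, ...) {
  cat(format_niche(x), if (is_generalist(x)) " (generalist)", "\n", sep = "")
  invisible(x)
}

format_niche <- function(s) paste(s$habit, paste(s$hosts, collapse = ";"),
                                  sep = "|")

#' Is a niche state a generalist (multi-host) state?
#' @param state a `"niche_state"`.
#' @return logical.
#' @export
is_generalist <- function(state) length(state$hosts) > 1L

#' Read a species-niche table from TSV
#'
#' Expected columns: `species`, `feeding_habit`, `hosts` (semicolon-
#' separated host taxa) and `outgroup` (0/1). Outgroup rows may leave habit
#' and hosts empty; their niche is coded as unknown.
#'
#' @param path TSV path.
#' @return a data frame with those four columns.
#' @export
read_niche_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("species", "feeding_habit", "hosts", "outgroup")
  if (!all(need %in% names(tab)))
    stop("niche table must have columns: ", paste(need, collapse = ", "))
  tab$outgroup <- as.integer(tab$outgroup)
  tab[need]
}

#' Build the distinct-niche catalog and species coding
#'
#' Enumerates every distinct ecological niche (feeding habit x host set)
#' found among the ingroup species and codes each as one state of a single
#' multistate character; each ingroup species maps to exactly one state and
#' outgroup species are coded as unknown. Catalog order is the sorted order
#' of the state labels, so the coding is deterministic for a given table.
#'
#' @param niche_table data frame as returned by [read_niche_table()].
#' @return an object of class `"niche_coding"`: a list with `catalog`
#'   (list of [niche_state()]), `labels` (state labels), `assignment`
#'   (named integer vector, species to state index, `NA` for unknown) and
#'   `unknown_species`.
#' @export
build_catalog <- function(niche_table) {
  stopifnot(is.data.frame(niche_table))
  tab <- niche_table
  tab$outgroup <- as.integer(tab$outgroup)
  if (anyDuplicated(tab$species))
    stop("duplicate species in niche table: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "))
  ingroup <- tab[tab$outgroup == 0L, , drop = FALSE]
  bad <- !nzchar(trimws(ingroup$hosts)) | !nzchar(trimws(ingroup$feeding_habit))
  if (any(bad))
    stop("ingroup species with empty habit or host set: ",
         paste(ingroup$species[bad], collapse = ", "))
  states <- lapply(seq_len(nrow(ingroup)), function(i)
    niche_state(ingroup$feeding_habit[i],
                strsplit(ingroup$hosts[i], ";", fixed = TRUE)[[1]]))
  labels <- vapply(states, format_niche, character(1))
  ulab <- sort(unique(labels))
  catalog <- states[match(ulab, labels)]
  assignment <- match(labels, ulab)
  names(assignment) <- ingroup$species
  unknown <- tab$species[tab$outgroup == 1L]
  assignment <- c(assignment,
                  stats::setNames(rep(NA_integer_, length(unknown)), unknown))
  structure(list(catalog = catalog, labels = ulab,
                 assignment = assignment, unknown_species = unknown),
            class = "niche_coding")
}

#' @export
print.niche_coding <- function(x, ...) {
  cat("Niche coding:", length(x$labels), "distinct states,",
      sum(!is.na(x$assignment)), "coded species,",
      length(x$unknown_species), "unknown (outgroup)\n")
  invisible(x)
}

#' Build a step matrix over the niche catalog
#'
#' Under `all_one` every change between distinct states costs 1 step, so
#' the parsimony length is the plain count of niche shifts. Under
#' `generalist_zero` a transition into a generalist state that subsumes the
#' source niche -- same feeding habit, source host set contained in the
#' generalist's host range -- costs 0: a clear host-range overlap between
#' states is taken as evidence against ecological speciation. All other
#' off-diagonal costs are 1. The zero applies only in the direction INTO
#' the subsuming generalist; set `symmetric = TRUE` to zero the reverse
#' direction too, for sensitivity analysis.
#'
#' @param coding a `"niche_coding"`.
#' @param rule `"generalist_zero"` or `"all_one"`.
#' @param symmetric apply the generalist zero in both directions.
#' @return a `k x k` numeric cost matrix with state labels as dimnames and
#'   a zero diagonal.
#' @export
build_step_matrix <- function(coding,
                              rule = c("generalist_zero", "all_one"),
                              symmetric = FALSE) {
  stopifnot(inherits(coding, "niche_coding"))
  rule <- match.arg(rule)
  k <- length(coding$catalog)
  C <- matrix(1, k, k, dimnames = list(coding$labels, coding$labels))
  diag(C) <- 0
  if (rule == "generalist_zero" && k > 1L) {
    for (j in seq_len(k)) {
      sj <- coding$catalog[[j]]
      if (!is_generalist(sj)) next
      for (i in seq_len(k)) {
        if (i == j) next
        si <- coding$catalog[[i]]
        if (si$habit == sj$habit && all(si$hosts %in% sj$hosts))
          C[i, j] <- 0
      }
    }
    if (symmetric) C <- pmin(C, t(C))
  }
  attr(C, "rule") <- rule
  C
}

#' Write a step matrix as TSV with state labels
#' @param matrix step matrix from [build_step_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_step_matrix <- function(matrix, path) {
  utils::write.table(cbind(state = rownames(matrix), as.data.frame(matrix)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Decide whether two niches differ
#'
#' Two species' niches are `"different"` when their feeding habits differ
#' or their host ranges do not overlap at all; a shared feeding habit with
#' at least one shared host taxon is `"same_or_overlapping"`. This is the
#' binary criterion used to label sister pairs.
#'
#' @param a,b `"niche_state"` objects.
#' @return `"different"` or `"same_or_overlapping"`.
#' @examples
#' a <- niche_state("external_folivory", c("Alnus", "Betula"))
#' b <- niche_state("external_folivory", "Betula")
#' niche_overlap(a, b)
#' @export
niche_overlap <- function(a, b) {
  stopifnot(inherits(a, "niche_state"), inherits(b, "niche_state"))
  if (a$habit != b$habit || length(intersect(a$hosts, b$hosts)) == 0L)
    "different"
  else
    "same_or_overlapping"
}
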