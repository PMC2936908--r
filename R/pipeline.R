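#' Run the full niche-shift / sister-pair analysis
#'
#' Orchestrates the whole inference: builds the distinct-niche catalog and
#' both step matrices, counts minimum niche shifts on the dated (MCC) tree
#' and optionally across a posterior tree sample under each costing rule,
#' compares shift counts with the number of speciation events the sampled
#' ingroup implies, extracts and classifies terminal sister pairs, fits
#' the logistic regression of niche difference on relative split age, and
#' extrapolates it to age zero -- the corrected estimate of the fraction of
#' ecological speciation.
#'
#' On ecologically plausible data the invariant `generalist_zero count <=
#' all_one count <= speciation events` is checked; a violation of the last
#' inequality (possible under extreme anagenetic shift rates) raises a
#' warning, not an error.
#'
#' @param mcc_tree a dated rooted `"phylo"` (relative node heights are the
#'   split ages), or a path readable by [read_trees()].
#' @param niche_table a niche table data frame or TSV path
#'   (see [read_niche_table()]).
#' @param trees optional `"multiPhylo"` (or path) of posterior topologies
#'   for the robustness summary.
#' @param symmetric_generalist_zero zero the generalist subset cost in both
#'   directions (sensitivity variant).
#' @return an object of class `"analysis_report"` (a nested list; see
#'   [write_report()] for the serialized layout).
#' @export
run_analysis <- function(mcc_tree, niche_table, trees = NULL,
                         symmetric_generalist_zero = FALSE) {
  if (is.character(mcc_tree)) mcc_tree <- read_trees(mcc_tree)[[1L]]
  if (is.character(niche_table)) niche_table <- read_niche_table(niche_table)
  if (is.character(trees)) trees <- read_trees(trees)

  coding <- build_catalog(niche_table)
  m_gz <- build_step_matrix(coding, "generalist_zero",
                            symmetric = symmetric_generalist_zero)
  m_ao <- build_step_matrix(coding, "all_one")

  ingroup_on_tree <- intersect(names(coding$assignment)[
    !is.na(coding$assignment)], mcc_tree$tip.label)
  n_ingroup <- length(ingroup_on_tree)
  if (n_ingroup < 2L) stop("fewer than 2 coded ingroup species on the tree")
  n_speciation <- required_speciation_events(n_ingroup)

  shifts <- list(
    generalist_zero = list(
      mcc = sankoff_min_cost(mcc_tree, coding, m_gz),
      sample = if (!is.null(trees))
        count_shifts_over_sample(trees, coding, m_gz)),
    all_one = list(
      mcc = sankoff_min_cost(mcc_tree, coding, m_ao),
      sample = if (!is.null(trees))
        count_shifts_over_sample(trees, coding, m_ao)))
  if (shifts$generalist_zero$mcc > shifts$all_one$mcc + 1e-9)
    warning("generalist-zero count exceeds all-one count; check the catalog")
  if (shifts$all_one$mcc > n_speciation)
    warning("niche-shift count exceeds speciation events: ",
            "more shifts than splits implies substantial anagenetic change")

  pairs <- extract_sister_pairs(mcc_tree)
  dataset <- classify_pairs(pairs, coding)
  prop <- proportion_different(dataset)

  labels <- unique(dataset$niche_different)
  if (length(labels) == 2L) {
    fit <- fit_logistic(dataset)
    p0 <- unname(predict_probability(fit, 0))
  } else {
    ## degenerate sample: every pair identical (or every pair different);
    ## the age-zero probability is the common label
    fit <- NULL
    p0 <- as.numeric(labels)
  }

  structure(list(
    n_ingroup_species = n_ingroup,
    n_speciation_events = n_speciation,
    n_niche_states = length(coding$labels),
    shift_counts = shifts,
    shift_speciation_ratio = list(
      generalist_zero = shifts$generalist_zero$mcc / n_speciation,
      all_one = shifts$all_one$mcc / n_speciation),
    pairs = list(n = prop$n, n_different = prop$n_different,
                 raw_fraction = prop$fraction, raw_percent = prop$percent,
                 dataset = dataset),
    logistic = fit,
    p_at_age0 = p0,
    provenance = list(package_version = as.character(
      utils::packageVersion("nicheshifts")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Ecological-speciation analysis\n")
  cat(sprintf("  %d ingroup species -> %d speciation events; %d niche states\n",
              x$n_ingroup_species, x$n_speciation_events, x$n_niche_states))
  cat(sprintf("  min niche shifts: %s (generalist-zero), %s (all-one)\n",
              format(x$shift_counts$generalist_zero$mcc),
              format(x$shift_counts$all_one$mcc)))
  cat(sprintf("  shift/speciation ratio: %.3f (generalist-zero), %.3f (all-one)\n",
              x$shift_speciation_ratio$generalist_zero,
              x$shift_speciation_ratio$all_one))
  cat(sprintf("  sister pairs: %d of %d niche-different (%.1f%%)\n",
              x$pairs$n_different, x$pairs$n, x$pairs$raw_percent))
  if (!is.null(x$logistic)) {
    b <- x$logistic$coefficients
    cat(sprintf("  logistic: P(diff) = 1/(1+exp(-(%.2f + %.2f*age)))\n",
                b[["intercept"]], b[["split_age"]]))
  }
  cat(sprintf("  corrected P(different) at split age 0: %.3f (%.1f%%)\n",
              x$p_at_age0, 100 * x$p_at_age0))
  invisible(x)
}

#' Serialize an analysis report to JSON and TSV
#'
#' Writes `report.json` (schema-versioned summary; percentages to one
#' decimal, probabilities to three) and `pairs.tsv` (the classified
#' sister-pair dataset) into `dir`.
#'
#' @param report an `"analysis_report"`.
#' @param dir output directory, created if needed.
#' @return path of the JSON file, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- report$logistic
  sample_summ <- function(s)
    if (is.null(s)) NULL else
      list(min = s$min, mean = s$mean, max = s$max, n_trees = s$n_trees)
  out <- list(
    schema_version = "1.0",
    n_ingroup_species = report$n_ingroup_species,
    n_speciation_events = report$n_speciation_events,
    n_niche_states = report$n_niche_states,
    shifts = list(
      generalist_zero = list(
        mcc = report$shift_counts$generalist_zero$mcc,
        sample = sample_summ(report$shift_counts$generalist_zero$sample)),
      all_one = list(
        mcc = report$shift_counts$all_one$mcc,
        sample = sample_summ(report$shift_counts$all_one$sample))),
    shift_speciation_ratio = lapply(report$shift_speciation_ratio,
                                    round, 3),
    pairs = list(n = report$pairs$n, n_different = report$pairs$n_different,
                 raw_percent = report$pairs$raw_percent),
    logistic = if (!is.null(fit)) list(
      intercept = unname(fit$coefficients[["intercept"]]),
      slope = unname(fit$coefficients[["split_age"]]),
      se = unname(fit$se), p_wald = unname(fit$p_wald),
      p_lr = unname(fit$p_lr),
      log_likelihood = fit$log_likelihood, n = fit$n,
      converged = fit$converged, separation = fit$separation),
    p_at_age0 = round(report$p_at_age0, 3),
    percent_at_age0 = round(100 * report$p_at_age0, 1),
    provenance = report$provenance)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_pairs(report$pairs$dataset, file.path(dir, "pairs.tsv"))
  invisible(json_path)
}
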