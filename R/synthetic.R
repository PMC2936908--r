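#' Configuration for the niche-evolution simulator
#'
#' Defaults emulate a Holarctic sawfly-like radiation: ~125 sampled species
#' on an ultrametric tree with root height 1, six larval feeding habits, a
#' pool of 20 woody host-plant genera, a minority of two-host generalists,
#' and a couple of outgroup species whose niches are unknown. `p_eco` is
#' the probability that a speciation event is ecological (the daughters are
#' forced into non-overlapping niches at the split); `ana_rate` is the
#' Poisson rate of anagenetic (post-speciational) niche shifts per unit
#' branch length.
#'
#' @param n_tips number of ingroup tips (>= 2).
#' @param birth_rate,death_rate per-lineage rates in relative time.
#' @param p_eco probability a split is ecological, in `[0, 1]`.
#' @param ana_rate anagenetic shift rate per unit branch length (>= 0).
#' @param host_pool character vector of host-plant taxon labels.
#' @param habit_pool character vector of feeding-habit labels.
#' @param p_generalist probability a newly drawn niche is a 2-host
#'   generalist.
#' @param n_outgroups outgroup species appended with unknown niches.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_tips = 125L,
                       birth_rate = 1,
                       death_rate = 0,
                       p_eco = 0.2,
                       ana_rate = 1.0,
                       host_pool = c("Salix", "Betula", "Alnus", "Populus",
                                     "Prunus", "Rubus", "Rosa", "Sorbus",
                                     "Crataegus", "Spiraea", "Vaccinium",
                                     "Arctostaphylos", "Picea", "Pinus",
                                     "Larix", "Quercus", "Corylus", "Ribes",
                                     "Dryas", "Geum"),
                       habit_pool = c("external_folivory", "galling",
                                      "leaf_folding", "catkin_feeding",
                                      "berry_mining", "needle_feeding"),
                       p_generalist = 0.15,
                       n_outgroups = 2L,
                       seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate >= 0, death_rate >= 0, ana_rate >= 0,
            p_eco >= 0, p_eco <= 1, p_generalist >= 0, p_generalist <= 1,
            n_outgroups >= 0, length(host_pool) >= 2,
            length(habit_pool) >= 1)
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 death_rate = death_rate, p_eco = p_eco,
                 ana_rate = ana_rate, host_pool = host_pool,
                 habit_pool = habit_pool, p_generalist = p_generalist,
                 n_outgroups = as.integer(n_outgroups), seed = seed),
            class = "sim_config")
}

set_sim_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed) + offset)
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Constant-rate birth-death tree conditioned on `n_tips` surviving
#' lineages, rescaled so the root height is exactly 1 (relative time, as in
#' a relaxed-clock chronogram). Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a rooted ultrametric `"phylo"` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$birth_rate <= config$death_rate)
    stop("birth_rate must exceed death_rate to condition on surviving tips")
  set_sim_seed(config, 0L)
  tree <- ape::rphylo(config$n_tips, birth = config$birth_rate,
                      death = config$death_rate, fossils = FALSE)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree
}

draw_niche <- function(config) {
  nh <- 1L + stats::rbinom(1L, 1L, config$p_generalist)
  niche_state(sample(config$habit_pool, 1L),
              sample(config$host_pool, nh))
}

draw_different_niche <- function(config, ref, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    cand <- draw_niche(config)
    if (niche_overlap(cand, ref) == "different") return(cand)
  }
  stop("host/habit pools too small to draw a non-overlapping niche")
}

#' Simulate niche evolution along a phylogeny
#'
#' The root receives a random niche. At each speciation node, with
#' probability `p_eco` the split is ecological: one randomly chosen
#' daughter draws a fresh niche guaranteed non-overlapping with its
#' sister's niche at that moment; otherwise both daughters inherit.
#' Along every branch, `Poisson(ana_rate x length)` anagenetic events each
#' replace the current niche with a fresh random draw. Tip niches become
#' the species-niche table; `n_outgroups` outgroup rows with unknown
#' niches are appended.
#'
#' @param tree an ultrametric `"phylo"` (from [simulate_tree()]).
#' @param config a [sim_config()].
#' @return a niche table data frame (`species`, `feeding_habit`, `hosts`,
#'   `outgroup`) accepted by [build_catalog()].
#' @export
simulate_niche_evolution <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set_sim_seed(config, 1L)
  n <- ape::Ntip(tree)
  root <- n + 1L
  state <- vector("list", n + tree$Nnode)
  state[[root]] <- draw_niche(config)
  rt <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(rt$edge)))                    # preorder
  pre <- rt$edge[ord, , drop = FALSE]
  elen <- rt$edge.length[ord]
  ## process splits node by node so the cladogenetic choice is joint over
  ## the daughters, then evolve anagenetically along each daughter branch
  nodes <- unique(pre[, 1L])
  for (v in nodes) {
    idx <- which(pre[, 1L] == v)
    kids <- pre[idx, 2L]
    start <- rep(list(state[[v]]), length(kids))
    if (length(kids) >= 2L && stats::runif(1L) < config$p_eco) {
      shifted <- sample(length(kids), 1L)
      sister <- state[[v]]
      start[[shifted]] <- draw_different_niche(config, sister)
    }
    for (j in seq_along(kids)) {
      s <- start[[j]]
      nev <- stats::rpois(1L, config$ana_rate * elen[idx[j]])
      for (e in seq_len(nev)) s <- draw_niche(config)
      state[[kids[j]]] <- s
    }
  }
  tips <- seq_len(n)
  tab <- data.frame(
    species = tree$tip.label,
    feeding_habit = vapply(state[tips], function(s) s$habit, character(1)),
    hosts = vapply(state[tips], function(s)
      paste(s$hosts, collapse = ";"), character(1)),
    outgroup = 0L, stringsAsFactors = FALSE)
  if (config$n_outgroups > 0L)
    tab <- rbind(tab, data.frame(
      species = paste0("Outgroup_", seq_len(config$n_outgroups)),
      feeding_habit = "", hosts = "", outgroup = 1L,
      stringsAsFactors = FALSE))
  tab
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes a true ("MCC") tree, an optional pseudo-posterior sample of
#' topologies obtained by random NNI perturbations of the true tree, the
#' species-niche table, and a JSON metadata file recording the
#' configuration (including the seed). The files round-trip through
#' [read_trees()] and [read_niche_table()].
#'
#' @param config a [sim_config()].
#' @param n_posterior_trees number of NNI-perturbed trees (0 for none).
#' @param dir output directory (created if needed).
#' @param nni_moves NNI moves applied per perturbed tree.
#' @return named list of file paths (`mcc`, `posterior` or `NULL`,
#'   `niches`, `meta`), invisibly; also the in-memory objects as
#'   attributes-free list elements `tree`, `trees`, `niche_table`.
#' @export
generate_dataset <- function(config, n_posterior_trees = 0L,
                             dir = tempfile("simdata"), nni_moves = 2L) {
  stopifnot(inherits(config, "sim_config"), n_posterior_trees >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(config)
  niche <- simulate_niche_evolution(tree, config)
  mcc_path <- file.path(dir, "mcc.nwk")
  ape::write.tree(tree, mcc_path)
  post_path <- NULL
  trees <- NULL
  if (n_posterior_trees > 0L) {
    set_sim_seed(config, 2L)
    trees <- structure(lapply(seq_len(n_posterior_trees), function(i)
      phangorn::rNNI(tree, moves = nni_moves)), class = "multiPhylo")
    post_path <- file.path(dir, "posterior.nwk")
    ape::write.tree(trees, post_path)
  }
  niche_path <- file.path(dir, "niches.tsv")
  utils::write.table(niche, niche_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(config), meta_path, auto_unbox = TRUE,
                       null = "null")
  invisible(list(mcc = mcc_path, posterior = post_path,
                 niches = niche_path, meta = meta_path,
                 tree = tree, trees = trees, niche_table = niche))
}
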