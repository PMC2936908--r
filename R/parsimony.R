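#' Tip state sets for a tree under a niche coding
#'
#' Coded species get a singleton admissible-state set; species coded as
#' unknown (outgroups) get the full catalog, which in Sankoff parsimony is
#' equivalent to letting the tip take any state at zero cost. A list of
#' integer vectors can also be built directly, e.g. multi-element sets for
#' polymorphic coding of oligophagous taxa with all used host families.
#'
#' @param coding a `"niche_coding"`.
#' @param tip_labels tip labels of the tree to be optimized.
#' @return named list, one nonempty integer vector of catalog indices per
#'   tip.
#' @export
tip_state_sets <- function(coding, tip_labels) {
  stopifnot(inherits(coding, "niche_coding"))
  missing <- setdiff(tip_labels, names(coding$assignment))
  if (length(missing))
    stop("tips absent from niche coding: ", paste(missing, collapse = ", "))
  k <- length(coding$catalog)
  sets <- lapply(tip_labels, function(tl) {
    s <- coding$assignment[[tl]]
    if (is.na(s)) seq_len(k) else s
  })
  names(sets) <- tip_labels
  sets
}

## bottom-up Sankoff pass: matrix of minimal subtree costs C[v, s] for every
## node; Inf marks states inadmissible at a tip. Polytomies are handled by
## summing over all children.
sankoff_down <- function(tree, tip_states, matrix) {
  stopifnot(inherits(tree, "phylo"))
  k <- ncol(matrix)
  if (nrow(matrix) != k) stop("step matrix must be square")
  if (any(matrix < 0)) stop("step-matrix costs must be nonnegative")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  tl <- tree$tip.label
  if (!all(tl %in% names(tip_states)))
    stop("tip states missing for: ",
         paste(setdiff(tl, names(tip_states)), collapse = ", "))
  C <- matrix(0, n + m, k)
  for (i in seq_len(n)) {
    adm <- tip_states[[tl[i]]]
    if (length(adm) == 0L) stop("empty state set for tip ", tl[i])
    if (any(adm < 1L | adm > k))
      stop("state index out of catalog range for tip ", tl[i])
    row <- rep(Inf, k)
    row[adm] <- 0
    C[i, ] <- row
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  ## per-edge transition vectors trans[s] = min_t cost(s,t) + C[child, t],
  ## kept for the MPR up-pass
  trans <- vector("list", nrow(po))
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]; ch <- po[e, 2L]
    M <- matrix + rep(C[ch, ], each = k)   # M[s, t] = cost(s,t) + C[ch, t]
    tr <- apply(M, 1L, min)
    trans[[e]] <- tr
    C[p, ] <- C[p, ] + tr
  }
  list(C = C, postorder = po, trans = trans, n_tip = n)
}

#' Minimum total cost of a character on a tree (Sankoff parsimony)
#'
#' Generalized-parsimony optimization of a single multistate character
#' under an arbitrary (possibly asymmetric, possibly real-valued) step
#' matrix, by the Sankoff dynamic program: subtree costs
#' `C_v(s) = sum over children of min_t [cost(s,t) + C_child(t)]`, tips
#' costing 0 for admissible states and Inf otherwise; the result is the
#' minimum root cost. Polytomies are supported.
#'
#' @param tree a rooted `"phylo"`.
#' @param tip_states named list of admissible catalog-index vectors per tip
#'   (see [tip_state_sets()]), or a `"niche_coding"`.
#' @param matrix `k x k` step matrix.
#' @return the minimum total transition cost (numeric scalar).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
#' cost <- matrix(1, 2, 2) - diag(2)
#' sankoff_min_cost(tr, list(a = 1L, b = 2L, c = 2L), cost)
#' @export
sankoff_min_cost <- function(tree, tip_states, matrix) {
  if (inherits(tip_states, "niche_coding"))
    tip_states <- tip_state_sets(tip_states, tree$tip.label)
  d <- sankoff_down(tree, tip_states, matrix)
  min(d$C[d$n_tip + 1L, ])
}

#' States attainable at each node in some most-parsimonious reconstruction
#'
#' For every node, the set of states it takes in at least one minimum-cost
#' reconstruction (the MPR set). Ambiguous nodes are reported as
#' multi-state sets, never resolved arbitrarily. Computed by the standard
#' down-pass/up-pass: a state `s` at node `v` is in the MPR set iff the
#' best cost of `v`'s subtree given `s` plus the best cost of the rest of
#' the tree given `s` equals the global minimum.
#'
#' @inheritParams sankoff_min_cost
#' @param tol numeric tolerance for cost ties (step matrices may carry
#'   real-valued costs).
#' @return a list with `min_cost` and `states`, a list over all nodes (ape
#'   numbering, tips first) of integer MPR state sets.
#' @export
ancestral_states <- function(tree, tip_states, matrix, tol = 1e-9) {
  if (inherits(tip_states, "niche_coding"))
    tip_states <- tip_state_sets(tip_states, tree$tip.label)
  d <- sankoff_down(tree, tip_states, matrix)
  k <- ncol(matrix)
  n <- d$n_tip
  root <- n + 1L
  total <- min(d$C[root, ])
  ## D[v, s]: minimal cost of the tree outside v's subtree, given v has s
  D <- matrix(Inf, nrow(d$C), k)
  D[root, ] <- 0
  po <- d$postorder
  for (e in rev(seq_len(nrow(po)))) {       # preorder over edges
    p <- po[e, 1L]; ch <- po[e, 2L]
    ## contribution of p's other children, without Inf - Inf hazards
    sib <- which(po[, 1L] == p & po[, 2L] != ch)
    others <- rep(0, k)
    for (s in sib) others <- others + d$trans[[s]]
    v <- D[p, ] + others                     # best "rest of tree" given p=s
    D[ch, ] <- apply(matrix + v, 2L, min)    # (matrix + v)[s,t] = v[s]+cost(s,t)
  }
  states <- lapply(seq_len(nrow(d$C)), function(v)
    which(d$C[v, ] + D[v, ] <= total + tol))
  list(min_cost = total, states = states)
}

#' Count niche shifts across a tree sample
#'
#' Applies [sankoff_min_cost()] to every tree of a (posterior) sample,
#' summarizing the spread of the minimum step count across topologies --
#' the robustness-to-phylogenetic-uncertainty check used with post-burnin
#' MCMC tree samples.
#'
#' @param trees a `"multiPhylo"` or list of `"phylo"`.
#' @param coding a `"niche_coding"` (or a named list of tip state sets
#'   shared by all trees).
#' @param matrix step matrix over the coding's catalog.
#' @return an object of class `"shift_summary"`: list with `counts`
#'   (per-tree vector), `min`, `max`, `mean`, `n_trees`.
#' @export
count_shifts_over_sample <- function(trees, coding, matrix) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  counts <- vapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    ts <- if (inherits(coding, "niche_coding"))
      tip_state_sets(coding, tr$tip.label) else coding
    sankoff_min_cost(tr, ts, matrix)
  }, numeric(1))
  structure(list(counts = counts, min = min(counts), max = max(counts),
                 mean = mean(counts), n_trees = length(counts)),
            class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("Niche-shift counts over %d tree(s): min %s, mean %.2f, max %s\n",
              x$n_trees, format(x$min), x$mean, format(x$max)))
  invisible(x)
}

#' Number of speciation events implied by a sampled clade
#'
#' A clade of `n` sampled species is the product of `n - 1` past speciation
#' events; the ratio of the minimum niche-shift count to this number bounds
#' the fraction of splits that can have coincided with a niche shift.
#'
#' @param n_ingroup_tips number of sampled ingroup species (>= 1).
#' @return integer, `n - 1`.
#' @examples
#' required_speciation_events(125)
#' @export
required_speciation_events <- function(n_ingroup_tips) {
  n <- n_ingroup_tips
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("n_ingroup_tips must be a single integer >= 1")
  as.integer(n) - 1L
}
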