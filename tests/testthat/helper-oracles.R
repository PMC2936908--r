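# Independent oracles used to validate the dynamic-programming and IRLS
# implementations. These deliberately share no code with the package: the
# Sankoff oracle enumerates every assignment of states to internal nodes;
# the logistic oracle maximizes the Bernoulli likelihood by nested grid
# refinement.

# exhaustive minimum parsimony cost: enumerate internal-node assignments;
# tips contribute min over their admissible states given the parent state
oracle_sankoff <- function(tree, tip_states, cost) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  k <- ncol(cost)
  edge <- tree$edge
  tipmin <- lapply(seq_len(n), function(i) {
    adm <- tip_states[[tree$tip.label[i]]]
    apply(cost[, adm, drop = FALSE], 1, min)   # per parent state s
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  tot <- numeric(nrow(grid))
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L] - n                        # internal index
    ch <- edge[e, 2L]
    ps <- grid[, p]
    tot <- tot + if (ch <= n) tipmin[[ch]][ps]
                 else cost[cbind(ps, grid[, ch - n])]
  }
  list(min = min(tot), grid = grid, tot = tot)
}

# MPR sets by enumeration: states each node takes in some optimal
# assignment (tips: admissible states achieving the per-edge minimum in
# some optimal internal assignment)
oracle_ancestral <- function(tree, tip_states, cost, tol = 1e-9) {
  o <- oracle_sankoff(tree, tip_states, cost)
  n <- ape::Ntip(tree)
  opt <- o$grid[o$tot <= o$min + tol, , drop = FALSE]
  internal_sets <- lapply(seq_len(tree$Nnode), function(j)
    sort(unique(opt[, j])))
  edge <- tree$edge
  tip_sets <- lapply(seq_len(n), function(i) {
    adm <- tip_states[[tree$tip.label[i]]]
    p <- edge[edge[, 2L] == i, 1L] - n
    res <- integer(0)
    for (r in seq_len(nrow(opt))) {
      ps <- opt[r, p]
      v <- cost[ps, adm]
      res <- union(res, adm[v <= min(v) + tol])
    }
    sort(res)
  })
  c(tip_sets, internal_sets)
}

# random Sankoff test instance: rooted random tree, random asymmetric
# nonnegative cost matrix with zero diagonal, random tip state sets
# (mostly singletons, some multi-state/unknown)
random_sankoff_instance <- function(max_tips = 7L, max_states = 5L) {
  nt <- sample(3:max_tips, 1L)
  k <- sample(2:max_states, 1L)
  tree <- ape::rtree(nt)
  sets <- lapply(seq_len(nt), function(i) {
    u <- stats::runif(1)
    if (u < 0.75) sample(k, 1L)
    else if (u < 0.9) sort(sample(k, min(2L, k)))
    else seq_len(k)
  })
  names(sets) <- tree$tip.label
  cost <- matrix(stats::runif(k * k, 0, 3), k, k)
  diag(cost) <- 0
  list(tree = tree, sets = sets, cost = cost, k = k)
}

# nested-grid maximizer of the logistic likelihood, refined to ~1e-4
grid_logistic <- function(age, y, b0_range = c(-10, 10),
                          b1_range = c(-40, 40), passes = 5L, width = 41L) {
  ll <- function(b0, b1) {
    mu <- stats::plogis(b0 + b1 * age)
    sum(stats::dbinom(y, 1, mu, log = TRUE))
  }
  for (p in seq_len(passes)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = width)
    b1s <- seq(b1_range[1], b1_range[2], length.out = width)
    vals <- outer(b0s, b1s, Vectorize(ll))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1L, ]
    best <- c(b0s[ij[1L]], b1s[ij[2L]])
    s0 <- diff(b0_range) / (width - 1)
    s1 <- diff(b1_range) / (width - 1)
    b0_range <- best[1L] + c(-2, 2) * s0
    b1_range <- best[2L] + c(-2, 2) * s1
  }
  best
}

# simulate sister-pair data from a known logistic curve
simulate_pair_data <- function(n, beta0, beta1) {
  age <- stats::runif(n)
  p <- stats::plogis(beta0 + beta1 * age)
  data.frame(split_age = age,
             niche_different = stats::rbinom(n, 1, p))
}

# small niche table used across tests
toy_niche_table <- function() {
  data.frame(
    species = c("sp1", "sp2", "sp3", "sp4", "sp5", "out1"),
    feeding_habit = c("external_folivory", "external_folivory", "galling",
                      "external_folivory", "external_folivory", ""),
    hosts = c("Salix", "Salix", "Salix", "Salix;Betula", "Betula", ""),
    outgroup = c(0L, 0L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
}
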