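test_that("Sankoff handles the hand-checkable cases", {
  cost <- matrix(1, 2, 2) - diag(2)
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(sankoff_min_cost(cherry, list(a = 1L, b = 1L), cost), 0)

  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_equal(sankoff_min_cost(tr, list(a = 1L, b = 2L, c = 2L), cost), 1)

  # polytomy: sum over all children
  poly <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  poly_sets <- list(a = 1L, b = 1L, c = 2L, d = 2L)
  expect_equal(sankoff_min_cost(poly, poly_sets, cost),
               oracle_sankoff(poly, poly_sets, cost)$min)   # = 2 on a star

  expect_error(sankoff_min_cost(tr, list(a = 1L, b = 5L, c = 2L), cost),
               "out of catalog range")
  expect_error(sankoff_min_cost(tr, list(a = 1L, b = 2L), cost), "missing")
})

test_that("Sankoff DP equals the exhaustive-enumeration oracle", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_sankoff_instance()
    dp <- sankoff_min_cost(inst$tree, inst$sets, inst$cost)
    expect_equal(dp, oracle_sankoff(inst$tree, inst$sets, inst$cost)$min,
                 tolerance = 1e-9)
  }
})

test_that("uniform-cost Sankoff equals independent Fitch parsimony", {
  set.seed(202)
  for (i in 1:25) {
    nt <- sample(4:20, 1)
    k <- sample(2:5, 1)
    tree <- ape::rtree(nt)
    states <- sample(k, nt, replace = TRUE)
    names(states) <- tree$tip.label
    sets <- lapply(states, as.integer)
    cost <- matrix(1, k, k) - diag(k)
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = seq_len(k))
    expect_equal(sankoff_min_cost(tree, sets, cost),
                 phangorn::parsimony(tree, dat, method = "fitch"))
  }
})

test_that("monotonicity and unknown-tip properties hold", {
  set.seed(303)
  for (i in 1:20) {
    inst <- random_sankoff_instance()
    base <- sankoff_min_cost(inst$tree, inst$sets, inst$cost)
    # elementwise-larger matrices never decrease the minimum cost
    bigger <- inst$cost + matrix(stats::runif(inst$k^2, 0, 1),
                                 inst$k, inst$k) * (1 - diag(inst$k))
    expect_gte(sankoff_min_cost(inst$tree, inst$sets, bigger), base - 1e-9)
    # widening one tip's set to the full catalog never increases the cost
    relaxed <- inst$sets
    relaxed[[sample(length(relaxed), 1)]] <- seq_len(inst$k)
    expect_lte(sankoff_min_cost(inst$tree, relaxed, inst$cost), base + 1e-9)
  }
})

test_that("MPR ancestral sets match the enumeration oracle", {
  cost <- matrix(1, 2, 2) - diag(2)
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  root <- ape::Ntip(cherry) + 1L
  expect_equal(ancestral_states(cherry, list(a = 1L, b = 1L),
                                cost)$states[[root]], 1L)
  amb <- ancestral_states(cherry, list(a = 1L, b = 2L), cost)
  expect_equal(amb$states[[root]], c(1L, 2L))   # ambiguous, reported as set

  set.seed(404)
  for (i in 1:25) {
    inst <- random_sankoff_instance(max_tips = 5L, max_states = 4L)
    got <- ancestral_states(inst$tree, inst$sets, inst$cost)
    expect_equal(got$states,
                 oracle_ancestral(inst$tree, inst$sets, inst$cost))
  }
})

test_that("shift counts over a tree sample are summarized correctly", {
  tab <- toy_niche_table()
  coding <- build_catalog(tab)
  gz <- build_step_matrix(coding, "generalist_zero")
  tr <- ape::read.tree(text = "(((sp1:1,sp2:1):1,(sp3:1,sp4:1):1):1,sp5:3);")

  same <- structure(rep(list(tr), 10), class = "multiPhylo")
  s <- count_shifts_over_sample(same, coding, gz)
  expect_equal(s$n_trees, 10L)
  expect_equal(s$min, s$mean)
  expect_equal(s$mean, s$max)

  # three hand-enumerable trees -> mean equals the oracle mean
  trees <- list(
    ape::read.tree(text = "((sp1:1,sp2:1):1,(sp3:1,(sp4:1,sp5:1):1):1);"),
    ape::read.tree(text = "(((sp1:1,sp3:1):1,sp2:1):1,(sp4:1,sp5:1):1);"),
    ape::read.tree(text = "((((sp1:1,sp5:1):1,sp2:1):1,sp3:1):1,sp4:1);"))
  counts <- vapply(trees, function(t)
    oracle_sankoff(t, tip_state_sets(coding, t$tip.label), gz)$min,
    numeric(1))
  s3 <- count_shifts_over_sample(trees, coding, gz)
  expect_equal(s3$counts, counts)
  expect_equal(s3$mean, mean(counts))

  missing_tree <- ape::read.tree(text = "((spX:1,sp2:1):1,sp3:2);")
  expect_error(count_shifts_over_sample(list(missing_tree), coding, gz),
               "spX")
})

test_that("unknown (outgroup) tips behave as any-state-at-zero-cost", {
  coding <- build_catalog(toy_niche_table())
  gz <- build_step_matrix(coding, "generalist_zero")
  with_out <- ape::read.tree(
    text = "((((sp1:1,sp2:1):1,(sp3:1,sp4:1):1):1,sp5:3):1,out1:4);")
  no_out <- ape::read.tree(
    text = "(((sp1:1,sp2:1):1,(sp3:1,sp4:1):1):1,sp5:3);")
  expect_lte(sankoff_min_cost(with_out, coding, gz),
             sankoff_min_cost(no_out, coding, gz) + 1e-9)
})

test_that("speciation-event counting is n - 1 with validation", {
  expect_identical(required_speciation_events(125), 124L)
  expect_identical(required_speciation_events(1), 0L)
  expect_identical(required_speciation_events(2), 1L)
  expect_error(required_speciation_events(0))
  expect_error(required_speciation_events(2.5))
})
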