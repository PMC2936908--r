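test_that("intercept-only MLE is the logit of the sample proportion", {
  d <- data.frame(split_age = seq(0, 1, length.out = 35),
                  niche_different = rep(c(1L, 0L), c(19, 16)))
  f <- fit_logistic(d, slope = FALSE)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients[["intercept"]]), log(19 / 16),
               tolerance = 1e-8)
  expect_equal(unname(predict_probability(f, 0.7)), 19 / 35,
               tolerance = 1e-8)
})

test_that("IRLS fit agrees with glm and with a grid-search maximizer", {
  set.seed(21)
  d <- simulate_pair_data(120, -1, 6)
  f <- fit_logistic(d)
  expect_true(f$converged)
  g <- stats::glm(niche_different ~ split_age, data = d, family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$se),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  expect_equal(f$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-8)

  grid <- grid_logistic(d$split_age, d$niche_different)
  expect_equal(unname(f$coefficients), grid, tolerance = 1e-3)
})

test_that("age-independent labels give a near-zero slope", {
  age <- rep(seq(0.1, 0.9, by = 0.2), each = 2)
  d <- data.frame(split_age = age,
                  niche_different = rep(c(0L, 1L), length.out = length(age)))
  f <- fit_logistic(d)
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[["split_age"]]), 1e-6)
})

test_that("degenerate inputs error and separation is flagged, not hidden", {
  expect_error(fit_logistic(data.frame(split_age = runif(5),
                                       niche_different = rep(1L, 5))),
               "one label")
  expect_error(fit_logistic(data.frame(split_age = 0.5,
                                       niche_different = 1L)), "3 pairs")
  # complete separation on split age
  d <- data.frame(split_age = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                  niche_different = c(0L, 0L, 0L, 1L, 1L, 1L))
  f <- fit_logistic(d)
  expect_true(f$separation)
  expect_false(f$converged)
  expect_true(all(is.na(f$p_wald)))
})

test_that("predicted probability is monotone, bounded and matches closed forms", {
  expect_equal(round(100 * predict_probability(c(-1.29, 15.12), 0), 1), 21.6)
  expect_equal(predict_probability(c(0, 3), 0), 0.5)
  ages <- seq(0, 1, by = 0.05)
  p <- predict_probability(c(-1.29, 15.12), ages)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("Wald and LR p-values are both reported and agree in order of magnitude", {
  set.seed(33)
  d <- simulate_pair_data(200, -1.3, 8)
  f <- fit_logistic(d)
  expect_true(all(f$p_wald > 0 & f$p_wald < 1))
  expect_true(all(f$p_lr > 0 & f$p_lr < 1))
  expect_lt(f$p_lr[["split_age"]], 0.01)
  expect_lt(f$p_wald[["split_age"]], 0.01)
})

test_that("chi-square independence test matches closed forms and is transpose-invariant", {
  flat <- matrix(10, 2, 2)
  r <- chi_square_independence(flat)
  expect_equal(r$chi2, 0)
  expect_equal(r$df, 1)

  diag2 <- matrix(c(20, 0, 0, 20), 2, 2)
  r2 <- chi_square_independence(diag2)
  expect_equal(r2$chi2, 40)
  expect_equal(r2$df, 1)

  set.seed(9)
  tab <- matrix(rpois(32, 20) + 1, 2, 16)
  a <- chi_square_independence(tab)
  b <- chi_square_independence(t(tab))
  expect_equal(a$df, 15)
  expect_equal(a$chi2, b$chi2)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2, 2)),
               "positive")
})

test_that("host tallies count oligophages once per genus with clade-wise proportions", {
  rec <- data.frame(
    clade = c("Nematini", "Nematini", "Nematini", "Pristiphorini"),
    genera = c("Alnus;Betula", "Salix", "Salix", "Picea"))
  t1 <- tally_hosts(rec)
  nem <- t1[t1$clade == "Nematini", ]
  expect_equal(nem$count[nem$genus == "Alnus"], 1L)
  expect_equal(nem$count[nem$genus == "Betula"], 1L)
  expect_equal(nem$count[nem$genus == "Salix"], 2L)
  expect_equal(sum(nem$proportion), 1)          # inflated-total normalization
  expect_equal(t1$proportion[t1$clade == "Pristiphorini"], 1)

  mono <- tally_hosts(data.frame(clade = "X", genera = "Salix"))
  expect_equal(mono$count, 1L)
  all_salix <- tally_hosts(data.frame(clade = "X",
                                      genera = rep("Salix", 3)))
  expect_equal(all_salix$proportion, 1)
})
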