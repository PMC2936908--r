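#' Logistic regression of niche difference on split age
#'
#' Fits `P(different) = 1 / (1 + exp(-(b0 + b1 * split_age)))` by maximum
#' likelihood using Newton/IRLS steps. Convergence is declared when the
#' maximum absolute score falls below `1e-8` or the parameter step below
#' `1e-10`. Wald standard errors and p-values come from the observed
#' information; likelihood-ratio p-values are reported alongside, since
#' statistics packages differ in which they print. Complete or
#' quasi-complete separation (coefficients diverging while the data are
#' perfectly classified) is detected and returned as a non-converged fit
#' with `separation = TRUE` rather than as silently huge coefficients.
#'
#' @param dataset data frame with numeric columns `split_age` in `[0, 1]`
#'   and binary `niche_different`.
#' @param slope fit the split-age slope (`TRUE`) or an intercept-only
#'   model, whose MLE is the logit of the sample proportion.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `"logistic_fit"`: coefficients, `se`, Wald
#'   `z` and `p_wald`, `p_lr`, `log_likelihood`, `n`, `converged`,
#'   `separation`.
#' @export
fit_logistic <- function(dataset, slope = TRUE, max_iter = 100L) {
  stopifnot(is.data.frame(dataset),
            all(c("split_age", "niche_different") %in% names(dataset)))
  y <- as.numeric(dataset$niche_different)
  age <- as.numeric(dataset$split_age)
  n <- length(y)
  if (n < 3L) stop("at least 3 pairs are required")
  if (!all(y %in% c(0, 1))) stop("niche_different must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("all pairs share one label; the logistic model is not estimable")
  X <- if (slope) cbind(intercept = 1, split_age = age)
       else cbind(intercept = rep(1, n))
  fit <- irls_logistic(X, y, max_iter = max_iter)
  se <- z <- pw <- rep(NA_real_, ncol(X))
  if (!fit$separation) {
    vc <- tryCatch(solve(fit$info), error = function(e) NULL)
    if (!is.null(vc)) {
      se <- sqrt(diag(vc))
      z <- fit$beta / se
      pw <- 2 * stats::pnorm(-abs(z))
    }
  }
  names(fit$beta) <- names(se) <- names(z) <- names(pw) <- colnames(X)
  p_lr <- rep(NA_real_, ncol(X))
  names(p_lr) <- colnames(X)
  if (slope && !fit$separation) {
    ## drop-one likelihood-ratio tests
    ll0 <- bernoulli_ll(rep(stats::qlogis(mean(y)), n), y)  # no slope
    fit_noint <- irls_logistic(cbind(split_age = age), y, max_iter)
    p_lr["split_age"] <- stats::pchisq(2 * (fit$ll - ll0), 1,
                                       lower.tail = FALSE)
    p_lr["intercept"] <- stats::pchisq(2 * (fit$ll - fit_noint$ll), 1,
                                       lower.tail = FALSE)
  }
  structure(list(coefficients = fit$beta, se = se, z = z, p_wald = pw,
                 p_lr = p_lr, log_likelihood = fit$ll, n = n,
                 converged = fit$converged, separation = fit$separation,
                 iterations = fit$iter),
            class = "logistic_fit")
}

bernoulli_ll <- function(eta, y) {
  mu <- stats::plogis(eta)
  sum(stats::dbinom(y, 1, mu, log = TRUE))
}

irls_logistic <- function(X, y, max_iter = 100L,
                          tol_score = 1e-8, tol_par = 1e-10) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, X * (mu * (1 - mu)))
    if (max(abs(score)) < tol_score) { converged <- TRUE; break }
    ## diverging linear predictor with perfect classification: separation
    if (max(abs(eta)) > 30 && all((eta > 0) == (y == 1))) {
      separation <- TRUE
      break
    }
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) { separation <- TRUE; break }
    beta <- beta + delta
    if (max(abs(delta)) < tol_par) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  list(beta = beta, info = crossprod(X, X * stats::plogis(eta) *
                                          (1 - stats::plogis(eta))),
       ll = bernoulli_ll(eta, y), converged = converged && !separation,
       separation = separation, iter = iter)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (n =", x$n, "pairs)\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z,
               p_wald = x$p_wald, p_lr = x$p_lr)
  print(round(tab, 4))
  cat("log-likelihood:", format(x$log_likelihood, digits = 6),
      if (!x$converged) "(NOT converged)",
      if (x$separation) "(separation detected)", "\n")
  invisible(x)
}

#' Predicted probability of niche difference at a split age
#'
#' Evaluates the fitted logistic curve; at `age = 0` this is the corrected
#' estimate of the fraction of speciation events that were ecological,
#' i.e. the probability that a sister pair already occupied non-overlapping
#' niches at the moment of splitting.
#'
#' @param fit a `"logistic_fit"`, or a numeric vector
#'   `c(intercept, slope)` to evaluate a published curve.
#' @param age split age(s), typically relative node heights in `[0, 1]`.
#' @return probability vector, elementwise `1/(1+exp(-(b0 + b1*age)))`.
#' @examples
#' predict_probability(c(-1.29, 15.12), 0)   # ~0.216
#' @export
predict_probability <- function(fit, age) {
  if (inherits(fit, "logistic_fit")) {
    b <- fit$coefficients
    b0 <- b[["intercept"]]
    b1 <- if ("split_age" %in% names(b)) b[["split_age"]] else 0
  } else {
    stopifnot(is.numeric(fit), length(fit) %in% 1:2)
    b0 <- fit[[1L]]
    b1 <- if (length(fit) == 2L) fit[[2L]] else 0
  }
  stats::plogis(b0 + b1 * age)
}

#' Pearson chi-square test of independence for a contingency table
#'
#' Compares, e.g., host-plant family distributions of species between two
#' clades. No continuity correction is applied.
#'
#' @param table an `r x c` matrix of nonnegative counts with positive row
#'   and column sums.
#' @return list with `chi2`, `df = (r-1)(c-1)`, and the upper-tail `p`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every row and column sum must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Tally species counts per host-plant genus and clade
#'
#' Oligo- and polyphagous species are counted as an additional species for
#' each plant genus on which they feed, so a species using two genera
#' contributes one count to each; proportions are normalized by the
#' inflated per-clade total and therefore sum to 1 within each clade.
#'
#' @param records data frame with columns `clade` and `genera`
#'   (semicolon-separated plant genera per species).
#' @return data frame with columns `clade`, `genus`, `count`, `proportion`.
#' @examples
#' tally_hosts(data.frame(clade = "Nematini", genera = "Alnus;Betula"))
#' @export
tally_hosts <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("clade", "genera") %in% names(records)))
  gl <- strsplit(as.character(records$genera), ";", fixed = TRUE)
  if (any(lengths(gl) == 0L) || any(!nzchar(unlist(gl))))
    stop("every species record needs at least one genus")
  long <- data.frame(clade = rep(records$clade, lengths(gl)),
                     genus = unlist(gl), stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(long))),
                          by = long[c("clade", "genus")], FUN = sum)
  totals <- tapply(agg$count, agg$clade, sum)
  agg$proportion <- agg$count / as.numeric(totals[agg$clade])
  agg <- agg[order(agg$clade, -agg$count, agg$genus), ]
  rownames(agg) <- NULL
  agg
}
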