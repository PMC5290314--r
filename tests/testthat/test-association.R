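test_that("alteration ridge matches the dense normal equations", {
  set.seed(51)
  X <- cbind(a1 = rbinom(5, 1, 0.5), a2 = c(1, 0, 1, 0, 1))
  while (any(apply(X, 2, var) == 0)) X[, 1] <- rbinom(5, 1, 0.5)
  y <- rnorm(5)
  got <- fit_alteration_regression(y, X, lambda = 2)
  # independent dense solve with centred design and outcome
  Xc <- scale(X, center = TRUE, scale = FALSE)
  b <- solve(t(Xc) %*% Xc + 2 * diag(2)) %*% t(Xc) %*% (y - mean(y))
  expect_equal(unname(got), as.numeric(b))

  # constant (centred-zero) outcome gives zero coefficients
  expect_equal(unname(fit_alteration_regression(rep(3, 5), X, 1)), c(0, 0))

  # a planted effect of 2 is recovered with a small penalty
  set.seed(52)
  a <- rbinom(200, 1, 0.4)
  act <- 2 * a + rnorm(200, sd = 0.1)
  est <- fit_alteration_regression(act, cbind(alt = a), lambda = 1e-6)
  expect_equal(unname(est), 2, tolerance = 0.05)

  expect_error(fit_alteration_regression(rnorm(5),
                                         cbind(z = rep(1, 5), X), 1),
               "zero-variance")
  expect_error(fit_alteration_regression(rnorm(5), X * 2, 1), "binary")
})

test_that("permutation coefficient p-values converge to the enumerated value", {
  # M = 6, activity 1..6, balanced predictor: only the observed split and its
  # complement attain the maximal |coefficient|, so the exhaustive two-sided
  # p over the 20 distinct assignments is 2/20 = 0.1.
  act <- 1:6
  X <- cbind(alt = c(1, 1, 1, 0, 0, 0))
  splits <- combn(6, 3)
  ridge_beta <- function(g) {
    x <- as.numeric(seq_len(6) %in% g)
    xc <- x - mean(x)
    sum(xc * (act - mean(act))) / (sum(xc^2) + 1e-9)
  }
  betas <- apply(splits, 2, ridge_beta)
  b_obs <- ridge_beta(1:3)
  p_exact <- mean(abs(betas) >= abs(b_obs) - 1e-12)
  expect_equal(p_exact, 0.1)

  res <- permutation_coefficient_pvalues(act, X, lambda = 1e-9,
                                         n_permutations = 4000, seed = 1)
  mc_sd <- sqrt(0.1 * 0.9 / 4000)
  expect_lt(abs(res$nominal_p[["alt"]] - 0.1), 3 * mc_sd + 1 / 4001)

  # determinism under the seed
  res2 <- permutation_coefficient_pvalues(act, X, lambda = 1e-9,
                                          n_permutations = 100, seed = 5)
  res3 <- permutation_coefficient_pvalues(act, X, lambda = 1e-9,
                                          n_permutations = 100, seed = 5)
  expect_identical(res2, res3)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(53)
  X <- sapply(1:4, function(i) rbinom(80, 1, 0.3))
  colnames(X) <- paste0("alt", 1:4)
  ps <- replicate(40, {
    y <- rnorm(80)
    permutation_coefficient_pvalues(y, X, lambda = 1,
                                    n_permutations = 99,
                                    seed = sample.int(1e6, 1))$nominal_p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.08)
})

test_that("association scoring adjusts within families and filters", {
  tab <- data.frame(
    regulator = rep(c("tf1", "tf2", "pr1"), times = 2),
    regulator_kind = rep(c("tf", "tf", "protein"), times = 2),
    alteration = rep(c("altA", "altB"), each = 3),
    coefficient = c(1.5, -0.2, 0.4, 0.1, 0.05, -0.3),
    nominal_p = c(0.001, 0.5, 0.01, 0.6, 0.7, 0.8),
    stringsAsFactors = FALSE)
  got <- score_associations(tab, prevalence = NULL, alteration_fdr = 0.15)
  # brute-force recomputation: BY per (alteration, family)
  for (alt in c("altA", "altB")) {
    for (fam in c("tf", "protein")) {
      idx <- tab$alteration == alt & tab$regulator_kind == fam
      want <- p.adjust(tab$nominal_p[idx], method = "BY")
      rows <- got[got$alteration == alt & got$regulator_kind == fam, ]
      if (nrow(rows) > 0) {
        expect_equal(rows$adjusted_p,
                     want[match(rows$regulator, tab$regulator[idx])])
      }
    }
  }
  # altB never reaches adjusted_p < 0.15 and is filtered out
  expect_false("altB" %in% got$alteration)
  expect_true("altA" %in% got$alteration)
  # scores agree in sign, display score is -log10 of adjusted p
  expect_equal(sign(got$score), sign(got$coefficient))
  expect_equal(sign(got$display_score), sign(got$coefficient))
  expect_equal(got$display_score,
               sign(got$coefficient) * -log10(got$adjusted_p))

  # a single-regulator family keeps its nominal p; coefficient < 0 with
  # adjusted p = 0.01 displays as -2
  tab1 <- data.frame(regulator = "pr9", regulator_kind = "protein",
                     alteration = "altC", coefficient = -3,
                     nominal_p = 0.01, stringsAsFactors = FALSE)
  got1 <- score_associations(tab1)
  expect_equal(got1$display_score, -2)
  expect_equal(got1$score, -0.01)

  # prevalence filter removes sub-threshold regulators
  got2 <- score_associations(tab, prevalence = c(tf1 = 0.5, tf2 = 0.005,
                                                 pr1 = 0.02),
                             min_prevalence = 0.01, alteration_fdr = 1)
  expect_false("tf2" %in% got2$regulator)
})

test_that("pair eligibility enforces single and co-occurrence counts", {
  n <- 60
  mk <- function(n1) c(rep(1, n1), rep(0, n - n1))
  A <- mk(25)
  B <- c(rep(1, 12), rep(0, 13), rep(1, 10), rep(0, 25))  # n=22, co=12
  C <- c(rep(0, 16), rep(1, 9), rep(1, 21), rep(0, 14))   # n=30, co=9 with A
  alt <- cbind(A = A, B = B, C = C)
  got <- select_eligible_pairs(alt, min_single = 20, min_co = 10)
  expect_true(any(got$a == "A" & got$b == "B"))     # 25/22 with co 12
  expect_false(any(got$a == "A" & got$b == "C"))    # co-occurrence 9 < 10
  # single-count bound
  small <- cbind(X = mk(19), Y = mk(30))
  expect_equal(nrow(select_eligible_pairs(small, 20, 10)), 0L)
})

test_that("pairwise interaction model matches an explicit OLS solve", {
  set.seed(54)
  a <- rbinom(60, 1, 0.5); b <- rbinom(60, 1, 0.5)
  while (qr(cbind(1, a, b, a * b))$rank < 4) b <- rbinom(60, 1, 0.5)
  y <- rnorm(60)
  got <- fit_pairwise_interaction(y, a, b)
  X <- cbind(1, a, b, a * b)
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(c(got$intercept, got$main_a, got$main_b, got$interaction),
               as.numeric(beta))

  # exactly additive activity has a zero interaction coefficient (the
  # perfect fit makes lm's inference warn; only the coefficient matters here)
  y_add <- 1 * a + 1 * b
  got_add <- suppressWarnings(fit_pairwise_interaction(y_add, a, b))
  expect_equal(got_add$interaction, 0, tolerance = 1e-10)

  # planted interaction of +2 is detected
  set.seed(55)
  a2 <- rbinom(200, 1, 0.5); b2 <- rbinom(200, 1, 0.5)
  y2 <- a2 + b2 + 2 * a2 * b2 + rnorm(200, sd = 0.5)
  got2 <- fit_pairwise_interaction(y2, a2, b2)
  expect_equal(got2$interaction, 2, tolerance = 0.35)
  expect_lt(got2$interaction_p, 0.05)

  expect_error(fit_pairwise_interaction(y, a, a), "rank-deficient")
})

test_that("interaction classification matches the brute-force rule table", {
  grid <- expand.grid(A = c(-1, -0.5, 0, 0.5, 1),
                      B = c(-1, -0.5, 0, 0.5, 1),
                      AB = c(-1, -0.5, 0, 0.5, 1),
                      p = c(0.01, 0.2))
  rule <- function(A, B, AB, p, alpha = 0.05) {
    if (p >= alpha) return("none")
    if (AB > 0 && AB > A && AB > B) return("synergistic")
    if (AB < 0 && AB < A && AB < B) return("antagonistic")
    "none"
  }
  for (i in seq_len(nrow(grid))) {
    tst <- structure(list(intercept = 0, main_a = grid$A[i],
                          main_b = grid$B[i], interaction = grid$AB[i],
                          interaction_p = grid$p[i]),
                     class = "interaction_test")
    expect_identical(classify_interaction(tst),
                     rule(grid$A[i], grid$B[i], grid$AB[i], grid$p[i]))
  }
  # spot checks of the three canonical patterns
  mk <- function(A, B, AB, p) structure(
    list(intercept = 0, main_a = A, main_b = B, interaction = AB,
         interaction_p = p), class = "interaction_test")
  expect_identical(classify_interaction(mk(0.1, 0.2, 0.5, 0.01)),
                   "synergistic")
  expect_identical(classify_interaction(mk(-0.1, -0.2, -0.5, 0.01)),
                   "antagonistic")
  expect_identical(classify_interaction(mk(0.6, 0.2, 0.5, 0.01)), "none")
})

test_that("planted alteration effects propagate to association hits", {
  ch <- make_cohort(simulation_config(
    n_genes = 300, n_samples = 120, n_tfs = 10, n_features = 8,
    n_alterations = 5, alteration_frequency = 0.3,
    planted_effects = data.frame(alteration = 1, feature = 2,
                                 magnitude = 2.5),
    seed = 61))
  fit <- affinity_regression(ch$bundle$expression, ch$bundle$motifs,
                             ch$bundle$proteins)
  act <- infer_protein_activities(fit)
  tab <- associate_alterations(act, ch$bundle$alterations,
                               n_permutations = 200, seed = 62)
  scored <- score_associations(tab, alteration_fdr = 1)
  hit <- scored[scored$regulator == "ab002" & scored$alteration == "alt001", ]
  expect_gt(hit$coefficient, 0)
  expect_lt(hit$adjusted_p, 0.15)
})
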