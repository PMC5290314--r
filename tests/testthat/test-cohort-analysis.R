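make_activity <- function(values, regulators, samples) {
  m <- matrix(values, length(regulators), length(samples),
              dimnames = list(regulators, samples))
  attr(m, "regulator_kind") <- setNames(rep("tf", length(regulators)),
                                        regulators)
  m
}

test_that("group comparison matches a hand-computed t statistic", {
  x <- c(1, 2, 3); y <- x + 10
  act <- make_activity(c(x, y), "r1", sprintf("s%d", 1:6))
  labels <- rep(c("g1", "g2"), each = 3)
  got <- compare_activity_groups(act, labels, test = "t")
  # Welch t computed from first principles
  t_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(got$statistic, t_hand)
  expect_equal(got$mean_diff, -10)
  # identical groups: statistic 0, p 1
  act0 <- make_activity(rep(1, 6), "r1", sprintf("s%d", 1:6))
  got0 <- compare_activity_groups(act0, labels)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p, 1)
  expect_error(compare_activity_groups(act, c("g1", rep("g2", 5))),
               "fewer than 2")
})

test_that("group comparison is symmetric under label swap", {
  set.seed(71)
  act <- make_activity(rnorm(40), c("r1", "r2"), sprintf("s%d", 1:20))
  labels <- rep(c("a", "b"), 10)
  g1 <- compare_activity_groups(act, factor(labels, levels = c("a", "b")))
  g2 <- compare_activity_groups(act, factor(labels, levels = c("b", "a")))
  expect_equal(g1$mean_diff, -g2$mean_diff)
  expect_equal(g1$p, g2$p)
  # wilcoxon variant runs and gives the same FDR ordering logic
  gw <- compare_activity_groups(act, labels, test = "wilcoxon")
  expect_true(all(gw$fdr_p >= gw$p))
})

test_that("planted differential regulators rank on top", {
  set.seed(72)
  n_reg <- 30; n <- 40
  act <- matrix(rnorm(n_reg * n), n_reg, n,
                dimnames = list(sprintf("r%02d", 1:n_reg),
                                sprintf("s%02d", 1:n)))
  labels <- rep(c("a", "b"), each = n / 2)
  act[1:5, labels == "a"] <- act[1:5, labels == "a"] + 2
  got <- compare_activity_groups(act, labels)
  top5 <- got$regulator[order(got$fdr_p)][1:5]
  expect_setequal(top5, sprintf("r%02d", 1:5))
})

test_that("rank-set enrichment reproduces the exact rank-sum tail", {
  ranking <- sprintf("r%d", 1:6)
  # top two of six: exact one-sided p = 1 / choose(6,2) = 1/15
  expect_equal(rank_set_enrichment(ranking, c("r1", "r2")), 1 / 15)
  # bottom-ranked query is anti-enriched
  expect_gt(rank_set_enrichment(ranking, c("r5", "r6")), 0.9)
  expect_error(rank_set_enrichment(ranking, ranking), "proper subset")
  expect_error(rank_set_enrichment(ranking, character(0)), "proper subset")
})

test_that("rank-set enrichment p is roughly uniform for random sets", {
  set.seed(73)
  ranking <- sprintf("r%d", 1:40)
  ps <- replicate(200, rank_set_enrichment(ranking, sample(ranking, 8)))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
})

test_that("survival screen recovers a planted hazard and controls errors", {
  ch <- make_cohort(simulation_config(n_genes = 30, n_samples = 300,
                                      n_tfs = 5, n_features = 4,
                                      n_alterations = 0,
                                      survival_coefficient = 1,
                                      censoring_fraction = 0.3, seed = 74))
  cl <- ch$bundle$clinical
  act <- matrix(ch$truth$risk_activity, 1, 300,
                dimnames = list("driver", cl$sample_id))
  scr <- survival_screen(act, cl)
  expect_equal(scr$table$coefficient, 1, tolerance = 0.4)
  expect_lt(scr$table$p, 1e-6)
  expect_equal(dim(scr$risk), c(1L, 300L))
  # covariate-adjusted variant runs
  scr2 <- survival_screen(act, cl, covariate = "covariate")
  expect_equal(scr2$table$coefficient, 1, tolerance = 0.4)
  # constant activity is skipped with a warning, zero events error
  act2 <- rbind(act, flat = rep(1, 300))
  expect_warning(s3 <- survival_screen(act2, cl), "constant")
  expect_equal(nrow(s3$table), 1)
  cl0 <- cl; cl0$event <- 0
  expect_error(survival_screen(act, cl0), "events")
  # prevalence filter drops low-prevalence regulators
  expect_error(survival_screen(act, cl, prevalence = c(driver = 0.01)),
               "no testable")
})

test_that("family comparison uses the one-sided paired signed-rank test", {
  p_expr <- seq(0.05, 0.5, length.out = 20)
  p_act <- p_expr / 10
  expect_lt(compare_model_families(p_act, p_expr), 0.01)
  expect_warning(p_same <- compare_model_families(p_expr, p_expr), "zero")
  expect_equal(p_same, 1)
  # 5-pair toy against exhaustive signed-rank enumeration
  pa <- c(0.01, 0.2, 0.03, 0.5, 0.04)
  pe <- c(0.05, 0.1, 0.06, 0.6, 0.2)
  d <- pa - pe
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  v_all <- as.matrix(signs) %*% r
  p_enum <- mean(v_all <= v_obs)
  expect_equal(compare_model_families(pa, pe), p_enum)
})

test_that("risk stratification fills 40/40/20 with deterministic ties", {
  set.seed(75)
  risks <- setNames(rnorm(100), sprintf("s%03d", 1:100))
  g <- stratify_risk_groups(risks, 0.40)
  expect_equal(as.vector(table(g)[c("high", "low", "excluded")]),
               c(40L, 40L, 20L))
  # high group has uniformly larger risk than low group
  expect_gt(min(risks[g == "high"]), max(risks[g == "low"]))
  # floor rule at n = 5
  g5 <- stratify_risk_groups(setNames(5:1, letters[1:5]), 0.40)
  expect_equal(as.vector(table(g5)[c("high", "low", "excluded")]),
               c(2L, 2L, 1L))
  # ties at the boundary resolve by input order, deterministically
  tied <- setNames(c(3, 2, 2, 2, 1), letters[1:5])
  expect_message(gt <- stratify_risk_groups(tied, 0.40), "tie")
  expect_identical(gt, stratify_risk_groups(tied, 0.40) |>
                     suppressMessages())
  expect_identical(unname(gt[c("a", "b")]), c("high", "high"))
  # output sizes depend only on n and fraction
  g2 <- stratify_risk_groups(setNames(runif(100), names(risks)), 0.40)
  expect_equal(as.vector(table(g2)), as.vector(table(g)))
  expect_error(stratify_risk_groups(c(a = 1), 0.4), "too few")
})

test_that("model transfer restricts to shared features and reports retention", {
  ch <- small_cohort(seed = 8)$bundle
  fit <- affinity_regression(ch$expression, ch$motifs, ch$proteins)
  # identical cohort, training centring: same activities as in-cohort
  tr <- transfer_to_external_cohort(fit, proteins = ch$proteins,
                                    center_by = "training")
  expect_equal(unname(tr), unname(infer_tf_activities(fit)),
               ignore_attr = TRUE)
  expect_equal(attr(tr, "retained_fraction"), 1)
  # half the features: retention reported
  half <- ch$proteins[, 1:3]
  expect_message(tr2 <- transfer_to_external_cohort(fit, proteins = half),
                 "60%")
  expect_equal(attr(tr2, "retained_fraction"), 3 / 5)
  expect_error(transfer_to_external_cohort(
    fit, proteins = matrix(0, 2, 1, dimnames = list(c("x1", "x2"), "zz"))),
    "shared")
  expect_error(transfer_to_external_cohort(fit), "exactly one")
  # expression route returns protein-kind activities
  tr3 <- transfer_to_external_cohort(fit, expression = ch$expression,
                                     center_by = "training")
  expect_equal(unname(tr3), unname(infer_protein_activities(fit)),
               ignore_attr = TRUE)
})

test_that("transferred activities track truth on a sibling cohort", {
  cfg <- simulation_config(n_genes = 300, n_samples = 60, n_tfs = 10,
                           n_features = 8, n_alterations = 0, seed = 76)
  train <- make_cohort(cfg)
  cfg2 <- cfg; cfg2$seed <- 77L
  ext <- make_cohort(cfg2)
  fit <- affinity_regression(train$bundle$expression, train$bundle$motifs,
                             train$bundle$proteins)
  # same generative law but a fresh draw: W differs, mapping should still
  # correlate with the external truth per sample
  tr <- transfer_to_external_cohort(fit, proteins = ext$bundle$proteins)
  truth <- fit$W %*% t(mean_center(ext$bundle$proteins, 2))
  cors <- sapply(seq_len(ncol(tr)), function(j) cor(tr[, j], truth[, j]))
  expect_gt(median(cors), 0.95)
})

test_that("concordance validation scores risk ordering against survival", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:20),
                   time_months = 20:1, event = rep(1, 20))
  risks <- 1:20   # higher risk = shorter time
  got <- concordance_validation(risks, cl)
  expect_equal(got$concordance, 1)
  expect_lt(got$p, 0.05)
  anti <- concordance_validation(rev(risks), cl)
  expect_equal(anti$concordance, 0)
  # random risks hover around 0.5
  set.seed(78)
  cs <- replicate(50, concordance_validation(rnorm(20), cl)$concordance)
  expect_lt(abs(mean(cs) - 0.5), 0.05)
  # invariance under strictly monotone transforms
  r <- rnorm(20)
  expect_equal(concordance_validation(r, cl)$concordance,
               concordance_validation(exp(3 * r), cl)$concordance)
})

test_that("Kaplan-Meier export returns per-group step data", {
  set.seed(79)
  cl <- data.frame(sample_id = sprintf("s%d", 1:50),
                   time_months = rexp(50, 0.05),
                   event = rbinom(50, 1, 0.7))
  labels <- stratify_risk_groups(setNames(rnorm(50), cl$sample_id), 0.4)
  km <- km_export(labels, cl)
  expect_setequal(unique(km$group), c("high", "low"))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_true(all(diff(km$time[km$group == "high"]) >= 0))
})
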