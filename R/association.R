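# Association of binary somatic alterations with inferred regulator
# activities: ridge regression with permutation-tested coefficients, plus
# pairwise interaction models for synergy/antagonism.

# Ridge with an unpenalized intercept: centre the outcome and the (binary,
# unscaled) predictors, solve (Xc'Xc + lambda I) b = Xc' yc.
ridge_solve <- function(X, y, lambda) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar, "-")
  yc <- y - mean(y)
  b <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, yc))
  setNames(as.numeric(b), colnames(X))
}

#' Ridge regression of one regulator's activity on alteration profiles
#'
#' Predicts a regulator's per-sample activity from the full binary alteration
#' matrix by ridge regression. Predictors stay on their 0/1 scale (presence /
#' absence); the outcome is centred and the intercept is unpenalized.
#' Alterations that are constant across the samples must be filtered before
#' calling (they carry no information and make the coefficient meaningless).
#'
#' @param activity numeric vector of one regulator's activity over samples.
#' @param alterations samples x alterations binary matrix.
#' @param lambda ridge penalty (default 1).
#' @return named coefficient vector, one per alteration.
#' @export
fit_alteration_regression <- function(activity, alterations, lambda = 1) {
  stopifnot(is.matrix(alterations), length(activity) == nrow(alterations),
            lambda >= 0)
  if (!all(alterations %in% c(0, 1))) {
    stop("alterations must be binary", call. = FALSE)
  }
  cv <- apply(alterations, 2L, var)
  if (any(cv == 0)) {
    stop("zero-variance alteration column(s): ",
         paste(colnames(alterations)[cv == 0], collapse = ", "),
         call. = FALSE)
  }
  ridge_solve(alterations, activity, lambda)
}

#' Permutation p-values for alteration regression coefficients
#'
#' Permutes the activity outcome across samples, refits the ridge regression
#' for every draw, and reports for each alteration the smoothed two-sided
#' p-value `(1 + #\{|b_null| >= |b_obs|\}) / (n + 1)`. The refits reuse the
#' factorised design, so the permutations reduce to one matrix product.
#'
#' @inheritParams fit_alteration_regression
#' @param n_permutations number of permutations (>= 1); full-scale analyses
#'   use 10000.
#' @param seed integer seed.
#' @return list with `coefficients` (observed) and `nominal_p` per alteration.
#' @export
permutation_coefficient_pvalues <- function(activity, alterations, lambda = 1,
                                            n_permutations = 1000L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  beta_obs <- fit_alteration_regression(activity, alterations, lambda)
  xbar <- colMeans(alterations)
  Xc <- sweep(alterations, 2L, xbar, "-")
  A <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)), t(Xc))  # p x M
  M <- length(activity)
  perms <- with_seed(child_seed(seed, 7L),
                     replicate(n_permutations, sample.int(M)))
  Yp <- matrix(activity[perms], nrow = M) # M x n_permutations, centred below
  Yp <- Yp - mean(activity)
  B_null <- A %*% Yp                      # p x n_permutations
  # tolerance so permutations reproducing the observed assignment tie cleanly
  thresh <- abs(beta_obs) * (1 - 1e-9) - 1e-12
  exceed <- rowSums(abs(B_null) >= thresh)
  nominal_p <- (1 + exceed) / (n_permutations + 1)
  list(coefficients = beta_obs,
       nominal_p = setNames(nominal_p, names(beta_obs)))
}

#' Association screen of all regulators against all alterations
#'
#' Runs [permutation_coefficient_pvalues()] for every regulator (fresh seeded
#' permutation draws per regulator) and assembles the long association table.
#'
#' @param activities regulators x samples matrix with a `regulator_kind`
#'   attribute.
#' @param alterations samples x alterations binary matrix.
#' @param lambda ridge penalty (default 1).
#' @param n_permutations permutations per regulator.
#' @param seed integer seed.
#' @return data frame with columns `regulator`, `regulator_kind`,
#'   `alteration`, `coefficient`, `nominal_p`.
#' @export
associate_alterations <- function(activities, alterations, lambda = 1,
                                  n_permutations = 1000L, seed = 1L) {
  kind <- regulator_kind(activities) %||%
    setNames(rep("tf", nrow(activities)), rownames(activities))
  keep <- apply(alterations, 2L, var) > 0
  if (any(!keep)) {
    warning("dropping constant alteration(s): ",
            paste(colnames(alterations)[!keep], collapse = ", "))
    alterations <- alterations[, keep, drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(activities)), function(i) {
    res <- permutation_coefficient_pvalues(
      activities[i, ], alterations, lambda = lambda,
      n_permutations = n_permutations, seed = child_seed(seed, 1000L + i))
    data.frame(regulator = rownames(activities)[i],
               regulator_kind = unname(kind[i]),
               alteration = colnames(alterations),
               coefficient = unname(res$coefficients),
               nominal_p = unname(res$nominal_p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' FDR-adjust, score and filter an association table
#'
#' Nominal permutation p-values are BY-adjusted across regulators, separately
#' within the TF family and the protein family for each alteration. Two
#' scores are emitted: `score` (the adjusted p-value carrying the sign of the
#' coefficient) and `display_score` (`sign(coefficient) * -log10(adjusted_p)`,
#' convenient for heat maps); they always agree in sign. Regulators with
#' significant-activity prevalence below `min_prevalence` are removed, and an
#' alteration is retained only if it achieves `adjusted_p < alteration_fdr`
#' for at least one remaining regulator.
#'
#' @param table association table from [associate_alterations()].
#' @param prevalence named per-regulator prevalence from
#'   [regulator_prevalence()]; NULL skips the prevalence filter.
#' @param min_prevalence minimum prevalence (default 0.01).
#' @param alteration_fdr adjusted-p cutoff qualifying an alteration (default
#'   0.15).
#' @return the filtered table with columns `adjusted_p`, `score`,
#'   `display_score` added.
#' @export
score_associations <- function(table, prevalence = NULL,
                               min_prevalence = 0.01, alteration_fdr = 0.15) {
  stopifnot(all(c("regulator", "regulator_kind", "alteration", "coefficient",
                  "nominal_p") %in% colnames(table)))
  table$adjusted_p <- NA_real_
  for (alt in unique(table$alteration)) {
    for (fam in unique(table$regulator_kind)) {
      idx <- which(table$alteration == alt & table$regulator_kind == fam)
      if (length(idx) > 0L) {
        table$adjusted_p[idx] <- adjust_by(table$nominal_p[idx])
      }
    }
  }
  sgn <- sign(table$coefficient)
  table$score <- sgn * table$adjusted_p
  table$display_score <- sgn * -log10(table$adjusted_p)
  if (!is.null(prevalence)) {
    table <- table[prevalence[table$regulator] >= min_prevalence, ,
                   drop = FALSE]
  }
  keep_alt <- unique(table$alteration[table$adjusted_p < alteration_fdr])
  out <- table[table$alteration %in% keep_alt, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Alteration pairs eligible for interaction testing
#'
#' A pair qualifies when each alteration is present in at least `min_single`
#' samples and the two co-occur in at least `min_co` samples.
#'
#' @param alterations samples x alterations binary matrix.
#' @param min_single minimum per-alteration count (default 20).
#' @param min_co minimum co-occurrence count (default 10).
#' @return data frame with columns `a`, `b`, `n_a`, `n_b`, `n_co`.
#' @export
select_eligible_pairs <- function(alterations, min_single = 20L,
                                  min_co = 10L) {
  counts <- colSums(alterations)
  co <- crossprod(alterations)
  ids <- colnames(alterations)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (counts[i] >= min_single && counts[j] >= min_single &&
          co[i, j] >= min_co) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], n_a = counts[i], n_b = counts[j],
          n_co = co[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(a = character(), b = character(), n_a = integer(),
                      n_b = integer(), n_co = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise alteration interaction model for one regulator
#'
#' Ordinary least squares of the regulator's activity on the two alteration
#' indicators and their product: `R ~ A + B + A:B`. The interaction p-value
#' is the standard two-sided t-test of the interaction coefficient from the
#' linear-model fit.
#'
#' @param activity numeric activity vector over samples.
#' @param a,b binary alteration vectors.
#' @return an object of class `interaction_test` with the four coefficients
#'   (`intercept`, `main_a`, `main_b`, `interaction`), `interaction_p`,
#'   residual degrees of freedom and the underlying `lm` fit.
#' @export
fit_pairwise_interaction <- function(activity, a, b) {
  stopifnot(all(a %in% c(0, 1)), all(b %in% c(0, 1)),
            length(a) == length(activity), length(b) == length(activity))
  X <- cbind(1, a, b, a * b)
  if (qr(X)$rank < 4L) {
    stop("rank-deficient interaction design (degenerate alteration pair)",
         call. = FALSE)
  }
  fit <- lm(activity ~ a + b + a:b)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  structure(list(intercept = unname(cf[1]), main_a = unname(cf["a"]),
                 main_b = unname(cf["b"]), interaction = unname(cf["a:b"]),
                 interaction_p = unname(sm["a:b", "Pr(>|t|)"]),
                 df_residual = fit$df.residual, fit = fit),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf(
    "Interaction test: A = %.3g, B = %.3g, AB = %.3g (p = %.3g)\n",
    x$main_a, x$main_b, x$interaction, x$interaction_p))
  invisible(x)
}

#' Classify a pairwise interaction as synergistic or antagonistic
#'
#' An interaction is `synergistic` when its p-value is below `alpha`, its
#' coefficient is positive and exceeds both main effects; `antagonistic` when
#' significant, negative and below both main effects; `none` otherwise.
#'
#' @param test an `interaction_test`.
#' @param alpha significance cutoff for the interaction term (default 0.05).
#' @return `"synergistic"`, `"antagonistic"` or `"none"`.
#' @export
classify_interaction <- function(test, alpha = 0.05) {
  ab <- test$interaction
  if (test$interaction_p >= alpha) return("none")
  if (ab > 0 && ab > test$main_a && ab > test$main_b) return("synergistic")
  if (ab < 0 && ab < test$main_a && ab < test$main_b) return("antagonistic")
  "none"
}
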