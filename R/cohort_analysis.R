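# Downstream cohort screens over inferred activities: group comparisons,
# rank-set enrichment, survival screens, risk stratification, model transfer
# and concordance validation.

#' Differential activity between sample groups
#'
#' Tests each regulator's activity between two sample groups with a two-sided
#' two-sample t-test or Wilcoxon rank-sum test, then applies BH false-
#' discovery adjustment across regulators. The mean difference is reported as
#' group1 minus group2, where group1 is the first factor level of `labels`.
#'
#' @param activities regulators x samples matrix.
#' @param labels grouping vector of length `ncol(activities)` with exactly two
#'   levels.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return data frame with columns `regulator`, `mean_diff`, `statistic`,
#'   `p`, `fdr_p`, `test`.
#' @export
compare_activity_groups <- function(activities, labels,
                                    test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  labels <- as.factor(labels)
  stopifnot(ncol(activities) == length(labels), nlevels(labels) == 2L)
  g1 <- labels == levels(labels)[1L]
  g2 <- labels == levels(labels)[2L]
  for (g in levels(labels)) {
    if (sum(labels == g) < 2L) {
      stop("group '", g, "' has fewer than 2 samples", call. = FALSE)
    }
  }
  res <- lapply(seq_len(nrow(activities)), function(i) {
    x <- activities[i, g1]
    y <- activities[i, g2]
    if (identical(sort(unname(x)), sort(unname(y))) &&
        sd(c(x, y)) == 0) {
      return(data.frame(statistic = 0, p = 1))
    }
    ht <- if (test == "t") {
      t.test(x, y)
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE))
    }
    data.frame(statistic = unname(ht$statistic), p = ht$p.value)
  })
  out <- do.call(rbind, res)
  out <- data.frame(regulator = rownames(activities),
                    mean_diff = rowMeans(activities[, g1, drop = FALSE]) -
                      rowMeans(activities[, g2, drop = FALSE]),
                    statistic = out$statistic, p = out$p,
                    stringsAsFactors = FALSE)
  out$fdr_p <- p.adjust(out$p, method = "BH")
  out$test <- test
  rownames(out) <- NULL
  out
}

#' Rank-set enrichment of a regulator set in an ordered list
#'
#' One-sided Mann-Whitney (rank-sum) test that the members of `query_set`
#' occupy higher positions (earlier, better ranks) in `ranking` than the
#' non-members. Used e.g. to ask whether regulators found in one cohort are
#' enriched near the top of another cohort's ranking.
#'
#' @param ranking character vector of regulators ordered from best to worst.
#' @param query_set non-empty proper subset of `ranking`.
#' @return one-sided p-value.
#' @export
rank_set_enrichment <- function(ranking, query_set) {
  stopifnot(all(query_set %in% ranking))
  if (length(query_set) == 0L || length(query_set) >= length(ranking)) {
    stop("query set must be a non-empty proper subset of the ranking",
         call. = FALSE)
  }
  pos <- seq_along(ranking)
  in_set <- ranking %in% query_set
  wilcox.test(pos[in_set], pos[!in_set], alternative = "less")$p.value
}

#' Cox proportional-hazards screen over regulators
#'
#' Fits one Cox model per regulator: continuous activity (or expression) plus
#' an optional categorical background covariate (reference level = most
#' frequent). Reports the activity coefficient (log hazard ratio), its Wald
#' p-value, the model's score (log-rank) p-value, a BH adjustment across
#' models, and each sample's risk (the model's linear predictor). Samples
#' with a missing covariate are excluded with a note; constant-activity
#' regulators are skipped with a warning.
#'
#' @param mat regulators x samples matrix of activities or expression.
#' @param clinical data frame with `sample_id`, `time_months`, `event`,
#'   aligned with the columns of `mat`.
#' @param covariate optional name of a column of `clinical` to adjust for.
#' @param prevalence optional named per-regulator prevalence; rows below
#'   `prevalence_min` are dropped before testing.
#' @param prevalence_min prevalence cutoff (default 0.05).
#' @return list of class `survival_screen`: `table` (regulator, coefficient,
#'   p, logrank_p, fdr_p) and `risk` (regulators x samples linear predictors).
#' @export
survival_screen <- function(mat, clinical, covariate = NULL,
                            prevalence = NULL, prevalence_min = 0.05) {
  stopifnot(ncol(mat) == nrow(clinical))
  if (sum(clinical$event) < 1L) {
    stop("no observed events; survival screen is undefined", call. = FALSE)
  }
  if (!is.null(prevalence)) {
    keep <- rownames(mat)[prevalence[rownames(mat)] >= prevalence_min]
    mat <- mat[keep, , drop = FALSE]
  }
  keep_samples <- rep(TRUE, nrow(clinical))
  covar <- NULL
  if (!is.null(covariate)) {
    covar <- clinical[[covariate]]
    keep_samples <- !is.na(covar)
    if (any(!keep_samples)) {
      message(sum(!keep_samples), " sample(s) excluded for missing ",
              covariate)
    }
    covar <- factor(covar[keep_samples])
    covar <- stats::relevel(covar, ref = names(which.max(table(covar))))
  }
  cl <- clinical[keep_samples, , drop = FALSE]
  mat_k <- mat[, keep_samples, drop = FALSE]
  surv <- survival::Surv(cl$time_months, cl$event)
  risk <- matrix(NA_real_, nrow(mat_k), ncol(mat_k), dimnames = dimnames(mat_k))
  rows <- lapply(seq_len(nrow(mat_k)), function(i) {
    act <- mat_k[i, ]
    if (sd(act) == 0) {
      warning("constant activity for ", rownames(mat_k)[i], "; skipped")
      return(NULL)
    }
    fit <- if (is.null(covar)) {
      survival::coxph(surv ~ act)
    } else {
      survival::coxph(surv ~ act + covar)
    }
    sm <- summary(fit)
    risk[i, ] <<- unname(fit$linear.predictors)
    data.frame(regulator = rownames(mat_k)[i],
               coefficient = unname(coef(fit)["act"]),
               p = unname(sm$coefficients["act", "Pr(>|z|)"]),
               logrank_p = unname(sm$sctest["pvalue"]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no testable regulators", call. = FALSE)
  tab$fdr_p <- p.adjust(tab$p, method = "BH")
  rownames(tab) <- NULL
  structure(list(table = tab, risk = risk[tab$regulator, , drop = FALSE],
                 covariate = covariate),
            class = "survival_screen")
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("Survival screen over %d regulators", nrow(x$table)))
  if (!is.null(x$covariate)) cat(" (adjusted for ", x$covariate, ")", sep = "")
  cat("\n")
  print(head(x$table[order(x$table$p), ], 5L))
  invisible(x)
}

#' Compare activity-based and expression-based survival models
#'
#' One-sided paired Wilcoxon signed-rank test that the activity models attain
#' smaller (adjusted) p-values than the expression models over the same
#' regulators. Zero differences are dropped, following the standard
#' signed-rank convention.
#'
#' @param p_activity,p_expression per-regulator p-value vectors in the same
#'   regulator order.
#' @return one-sided p-value (with a warning and p = 1 when every pair is
#'   tied).
#' @export
compare_model_families <- function(p_activity, p_expression) {
  stopifnot(length(p_activity) == length(p_expression))
  if (all(p_activity == p_expression)) {
    warning("all paired differences are zero; reported as non-significant")
    return(1)
  }
  suppressWarnings(
    wilcox.test(p_activity, p_expression, paired = TRUE,
                alternative = "less")$p.value)
}

#' Stratify samples into high- and low-risk groups
#'
#' Ranks samples by decreasing risk; the top `floor(fraction * n)` are
#' labelled `high`, the bottom `floor(fraction * n)` labelled `low`, the
#' remainder `excluded`. Ties at a boundary are broken by input (sample-id)
#' order and reported.
#'
#' @param risks named numeric vector of per-sample risks.
#' @param fraction fraction per extreme group, in (0, 0.5\] (default 0.4).
#' @return character vector of labels (`high`/`low`/`excluded`) named like
#'   `risks`.
#' @export
stratify_risk_groups <- function(risks, fraction = 0.4) {
  stopifnot(fraction > 0, fraction <= 0.5)
  n <- length(risks)
  k <- floor(fraction * n)
  if (k < 1L) stop("too few samples for the requested fraction",
                   call. = FALSE)
  ord <- order(-risks)  # stable: ties keep input (sample-id) order
  if (anyDuplicated(risks[ord][c(k, k + 1L)]) ||
      (n > 2L * k && risks[ord][n - k] == risks[ord][n - k + 1L])) {
    message("tied risks at a group boundary; broken by sample order")
  }
  labels <- rep("excluded", n)
  labels[ord[seq_len(k)]] <- "high"
  labels[ord[seq.int(n - k + 1L, n)]] <- "low"
  setNames(labels, names(risks))
}

#' Transfer a trained model to an external cohort
#'
#' Restricts the interaction matrix to the protein features (or the motif
#' matrix to the genes) shared with the external cohort, centres the external
#' data, and applies the corresponding activity mapping. By default external
#' data are centred by their own feature means (antibody batches differ
#' between cohorts); `center_by = "training"` applies the stored training
#' means instead.
#'
#' @param model an `ar_model`.
#' @param proteins external samples x features matrix (for TF activities), or
#' @param expression external genes x samples matrix (for protein activities).
#' @param center_by `"external"` (default) or `"training"`.
#' @return activity matrix with attributes `regulator_kind` and
#'   `retained_fraction` (fraction of training features found in the external
#'   cohort).
#' @export
transfer_to_external_cohort <- function(model, proteins = NULL,
                                        expression = NULL,
                                        center_by = c("external",
                                                      "training")) {
  center_by <- match.arg(center_by)
  if (is.null(proteins) == is.null(expression)) {
    stop("supply exactly one of `proteins` or `expression`", call. = FALSE)
  }
  if (!is.null(proteins)) {
    shared <- intersect(colnames(model$W), colnames(proteins))
    if (length(shared) == 0L) stop("no shared protein features",
                                   call. = FALSE)
    retained <- length(shared) / ncol(model$W)
    P <- proteins[, shared, drop = FALSE]
    P <- if (center_by == "external") {
      mean_center(P, margin = 2L)
    } else {
      mean_center(P, margin = 2L,
                  reference_means = model$feature_means[shared])
    }
    act <- model$W[, shared, drop = FALSE] %*% t(P)
    attr(act, "regulator_kind") <- setNames(rep("tf", nrow(act)),
                                            rownames(act))
  } else {
    shared <- intersect(rownames(model$D), rownames(expression))
    if (length(shared) == 0L) stop("no shared genes", call. = FALSE)
    retained <- length(shared) / nrow(model$D)
    Y <- expression[shared, , drop = FALSE]
    Y <- if (center_by == "external") {
      mean_center(Y, margin = 1L)
    } else {
      mean_center(Y, margin = 1L, reference_means = model$gene_means[shared])
    }
    act <- t(crossprod(Y, model$D[shared, , drop = FALSE] %*% model$W))
    rownames(act) <- colnames(model$W)
    attr(act, "regulator_kind") <- setNames(rep("protein", nrow(act)),
                                            rownames(act))
  }
  if (retained < 1) {
    message(sprintf("transfer retained %.0f%% of training features",
                    100 * retained))
  }
  attr(act, "retained_fraction") <- retained
  act
}

#' Concordance of externally derived risks with observed survival
#'
#' Harrell's concordance index between per-sample risk scores and observed
#' survival over all comparable pairs, with a two-sided normal test of
#' C = 0.5. Higher risk is expected to pair with earlier events.
#'
#' @param risks per-sample numeric risk scores.
#' @param clinical data frame with `time_months` and `event` aligned with
#'   `risks`.
#' @return list with `concordance`, `se` and `p`.
#' @export
concordance_validation <- function(risks, clinical) {
  stopifnot(length(risks) == nrow(clinical))
  surv <- survival::Surv(clinical$time_months, clinical$event)
  cc <- survival::concordance(surv ~ risks, reverse = TRUE)
  se <- sqrt(cc$var)
  if (is.na(se) || cc$count[["concordant"]] + cc$count[["discordant"]] == 0) {
    stop("no comparable pairs; concordance undefined", call. = FALSE)
  }
  p <- if (se == 0) {
    if (cc$concordance == 0.5) 1 else 0
  } else {
    2 * pnorm(-abs(cc$concordance - 0.5) / se)
  }
  list(concordance = unname(cc$concordance), se = se, p = p)
}

#' Kaplan-Meier export for risk groups
#'
#' Convenience wrapper around [survival::survfit()] returning the per-group
#' step-function data (time, number at risk, events, survival estimate) for
#' plotting.
#'
#' @param labels group labels from [stratify_risk_groups()].
#' @param clinical data frame with `time_months` and `event` aligned with
#'   `labels`.
#' @return data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_export <- function(labels, clinical) {
  keep <- labels != "excluded"
  fit <- survival::survfit(
    survival::Surv(clinical$time_months[keep], clinical$event[keep]) ~
      labels[keep])
  grp <- rep(sub("^labels\\[keep\\]=", "", names(fit$strata)), fit$strata)
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}
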