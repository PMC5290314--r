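# Held-out prediction assessment: k-fold cross-validation of the bilinear
# model against randomized and nearest-neighbour baselines.

cv_metric <- function(pred, obs, metric) {
  if (metric == "rmse") return(sqrt(mean((pred - obs)^2)))
  if (sd(pred) == 0 || sd(obs) == 0) {
    message("constant profile: correlation undefined, recorded as NA")
    return(NA_real_)
  }
  cor(pred, obs, method = metric)
}

cv_fold_assignment <- function(M, folds, seed) {
  with_seed(child_seed(seed, 1L), sample(rep(seq_len(folds), length.out = M)))
}

# Fit on the training part of a fold (with optional inner lambda selection)
# and predict each held-out sample's expression profile.
cv_fit_predict <- function(Y_raw, D, P_raw, train, test, lambda_grid, metric,
                           seed, top_genes, fold) {
  Y_tr_raw <- Y_raw[, train, drop = FALSE]
  genes_f <- rownames(suppressWarnings(
    select_top_variable_genes(Y_tr_raw, top_genes)))
  Y_tr <- mean_center(Y_raw[genes_f, train, drop = FALSE], margin = 1L)
  P_tr <- mean_center(P_raw[train, , drop = FALSE], margin = 2L)
  D_f <- D[genes_f, , drop = FALSE]

  lambda <- lambda_grid[1L]
  if (length(lambda_grid) > 1L) {
    n_tr <- length(train)
    n_val <- max(1L, floor(0.25 * n_tr))
    val <- with_seed(child_seed(seed, 100L + fold),
                     sample.int(n_tr, n_val))
    inner_tr <- setdiff(seq_len(n_tr), val)
    Yi <- mean_center(Y_tr_raw[genes_f, inner_tr, drop = FALSE], margin = 1L)
    Pi <- mean_center(P_raw[train, , drop = FALSE][inner_tr, , drop = FALSE],
                      margin = 2L)
    ctx <- ar_eigen_context(D_f, Pi)
    DtYP <- crossprod(D_f, Yi %*% Pi)
    Yv <- mean_center(Y_tr_raw[genes_f, val, drop = FALSE], margin = 1L,
                      reference_means = centring_means(Yi))
    Pv <- mean_center(P_raw[train, , drop = FALSE][val, , drop = FALSE],
                      margin = 2L, reference_means = centring_means(Pi))
    scores <- vapply(lambda_grid, function(l) {
      Wl <- ar_solve_ctx(ctx, DtYP, l)
      Sv <- crossprod(Yi, D_f %*% Wl %*% t(Pv))
      pred <- reconstruct_expression(Sv, Yi)
      mean(vapply(seq_along(val), function(j)
        cv_metric(pred[, j], Yv[, j], metric), numeric(1)), na.rm = TRUE)
    }, numeric(1))
    lambda <- lambda_grid[if (metric == "rmse") which.min(scores)
                          else which.max(scores)]
  }

  fit <- affinity_regression(Y_tr, D_f, P_tr, lambda = lambda, center = FALSE)
  fit$gene_means <- centring_means(Y_tr)
  fit$feature_means <- centring_means(P_tr)
  P_te <- mean_center(P_raw[test, , drop = FALSE], margin = 2L,
                      reference_means = fit$feature_means)
  S_te <- crossprod(Y_tr, D_f %*% fit$W %*% t(P_te))
  pred <- reconstruct_expression(S_te, Y_tr)
  Y_obs <- mean_center(Y_raw[genes_f, test, drop = FALSE], margin = 1L,
                       reference_means = fit$gene_means)
  list(pred = pred, obs = Y_obs, lambda = lambda, genes = genes_f,
       Y_tr = Y_tr, P_tr = P_tr)
}

#' Cross-validated held-out expression prediction
#'
#' Partitions samples into `folds` folds by a seeded shuffle. Within each
#' fold, gene selection, centring and the interaction matrix are computed on
#' the training samples only; each held-out sample's expression is predicted
#' through the similarity mapping followed by span reconstruction, and the
#' chosen metric compares predicted with measured profiles. The ridge penalty
#' is selected per fold on an inner 75/25 split over `lambda_grid`.
#'
#' `model` selects the fitted variant: the true model, negative controls with
#' motif rows and/or protein rows randomized (seeded, once per run), or the
#' nearest-neighbour baseline that copies the expression of the closest
#' training sample in protein space.
#'
#' @param bundle a `cohort_bundle`.
#' @param folds number of folds (default 10); `folds = M` gives
#'   leave-one-out.
#' @param lambda_grid candidate ridge penalties (default `10^(-2:3)`).
#' @param metric `"spearman"` (default), `"pearson"` or `"rmse"`.
#' @param seed integer seed controlling fold assignment, inner splits and any
#'   randomization.
#' @param model model variant to evaluate.
#' @param top_genes genes kept per fold by training-set variance (default
#'   5000).
#' @return a data frame with one row per held-out sample (`sample`, `fold`,
#'   `model`, `metric`, `value`, `lambda`), with the fold-mean metric in
#'   attribute `mean_value`.
#' @export
cross_validate <- function(bundle, folds = 10L,
                           lambda_grid = 10^seq(-2, 3),
                           metric = c("spearman", "pearson", "rmse"),
                           seed = 1L,
                           model = c("true", "motif", "rppa", "both", "nn"),
                           top_genes = 5000L) {
  metric <- match.arg(metric)
  model <- match.arg(model)
  M <- ncol(bundle$expression)
  stopifnot(folds >= 2L, M >= folds)
  Y_raw <- bundle$expression
  D <- bundle$motifs
  P_raw <- bundle$proteins
  if (model %in% c("motif", "both")) {
    perm <- with_seed(child_seed(seed, 11L), sample.int(nrow(D)))
    D <- D[perm, , drop = FALSE]
    rownames(D) <- rownames(bundle$motifs)
  }
  if (model %in% c("rppa", "both")) {
    perm <- with_seed(child_seed(seed, 12L), sample.int(nrow(P_raw)))
    P_raw <- P_raw[perm, , drop = FALSE]
    rownames(P_raw) <- rownames(bundle$proteins)
  }
  fold_of <- cv_fold_assignment(M, folds, seed)

  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- which(fold_of != f)
    test <- which(fold_of == f)
    if (length(test) == 0L) next
    if (model == "nn") {
      genes_f <- rownames(suppressWarnings(
        select_top_variable_genes(Y_raw[, train, drop = FALSE], top_genes)))
      Y_tr <- mean_center(Y_raw[genes_f, train, drop = FALSE], margin = 1L)
      P_tr <- mean_center(P_raw[train, , drop = FALSE], margin = 2L)
      P_te <- mean_center(P_raw[test, , drop = FALSE], margin = 2L,
                          reference_means = centring_means(P_tr))
      Y_obs <- mean_center(Y_raw[genes_f, test, drop = FALSE], margin = 1L,
                           reference_means = centring_means(Y_tr))
      vals <- vapply(seq_along(test), function(j) {
        pred <- nearest_neighbour_baseline(P_tr, Y_tr, P_te[j, ])
        cv_metric(as.numeric(pred), Y_obs[, j], metric)
      }, numeric(1))
      lam <- NA_real_
    } else {
      fp <- cv_fit_predict(Y_raw, D, P_raw, train, test, lambda_grid, metric,
                           seed, top_genes, f)
      vals <- vapply(seq_along(test), function(j)
        cv_metric(fp$pred[, j], fp$obs[, j], metric), numeric(1))
      lam <- fp$lambda
    }
    rows[[f]] <- data.frame(sample = colnames(Y_raw)[test], fold = f,
                            model = model, metric = metric, value = vals,
                            lambda = lam, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_value") <- mean(out$value, na.rm = TRUE)
  out
}

#' Compare the true model with its baselines by cross-validation
#'
#' Runs [cross_validate()] for each requested model variant under the same
#' seed (hence identical fold assignments) and reports the mean held-out
#' metric per variant.
#'
#' @inheritParams cross_validate
#' @param models variants to evaluate.
#' @return named numeric vector of mean held-out metric values, with the full
#'   per-sample table in attribute `details`.
#' @export
cv_model_comparison <- function(bundle, folds = 10L,
                                lambda_grid = 10^seq(-2, 3),
                                metric = "spearman", seed = 1L,
                                models = c("true", "nn", "motif", "both"),
                                top_genes = 5000L) {
  tabs <- lapply(models, function(m)
    cross_validate(bundle, folds = folds, lambda_grid = lambda_grid,
                   metric = metric, seed = seed, model = m,
                   top_genes = top_genes))
  means <- vapply(tabs, attr, numeric(1), which = "mean_value")
  names(means) <- models
  attr(means, "details") <- do.call(rbind, tabs)
  means
}
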