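# Bilinear ridge ("affinity regression") model linking protein profiles to
# expression through a motif-hit matrix:
#
#   minimise over W:  || Y - D W P' ||_F^2 + lambda || W ||_F^2
#
# with Y (genes x samples) the centred expression, D (genes x TFs) the binary
# motif hits and P (samples x features) the centred protein profiles. Writing
# the normal equations  D'D W P'P + lambda W = D'YP  and diagonalising
# D'D = U a U' and P'P = V b V' gives the closed form
#   W = U ( (U' D'YP V) / (a_i b_j + lambda) ) V',
# equivalent to the Kronecker system
#   vec(W) = (P'P (x) D'D + lambda I)^{-1} vec(D'YP)
# but costing O(Q^3 + S^3) instead of O(Q^3 S^3).

ar_eigen_context <- function(D, P) {
  ed <- eigen(crossprod(D), symmetric = TRUE)
  ep <- eigen(crossprod(P), symmetric = TRUE)
  list(U = ed$vectors, a = pmax(ed$values, 0),
       V = ep$vectors, b = pmax(ep$values, 0))
}

ar_solve_ctx <- function(ctx, DtYP, lambda) {
  denom <- outer(ctx$a, ctx$b) + lambda
  if (min(denom) <= max(denom) * 1e-14) {
    stop("normal equations are singular at lambda = 0; use a positive ridge ",
         "penalty", call. = FALSE)
  }
  C <- crossprod(ctx$U, DtYP %*% ctx$V)
  ctx$U %*% (C / denom) %*% t(ctx$V)
}

#' Fit an affinity-regression interaction model
#'
#' Learns the TF x protein-feature interaction matrix `W` minimising
#' `||Y - D W P'||^2 + lambda ||W||^2`, where `Y` holds centred log
#' expression (genes x samples), `D` binary motif hits (genes x TFs) and `P`
#' centred protein profiles (samples x features). The solver diagonalises
#' `D'D` and `P'P` and agrees with the dense Kronecker closed form
#' `vec(W) = (P'P \%x\% D'D + lambda I)^{-1} vec(D'YP)`.
#'
#' By default the expression rows and protein columns are mean-centred
#' in-function and the offsets stored, so held-out data can be centred
#' relative to the training set.
#'
#' @param Y genes x samples numeric matrix.
#' @param D genes x TFs binary motif-hit matrix; row names must match `Y`.
#' @param P samples x protein-features numeric matrix; row names must match
#'   `colnames(Y)`.
#' @param lambda non-negative ridge penalty (default 1). `lambda = 0` is
#'   accepted only when the normal equations are non-singular.
#' @param center logical; centre `Y` per gene and `P` per feature before
#'   fitting (default TRUE). Set FALSE when the inputs are already centred.
#' @return an object of class `ar_model` with components `W` (Q x S), `lambda`
#'   and the training context needed by the activity mappings.
#' @examples
#' set.seed(1)
#' D <- matrix(rbinom(60, 1, 0.4), 20, 3,
#'             dimnames = list(paste0("g", 1:20), paste0("tf", 1:3)))
#' P <- matrix(rnorm(10), 5, 2,
#'             dimnames = list(paste0("s", 1:5), paste0("ab", 1:2)))
#' W0 <- matrix(rnorm(6), 3, 2)
#' Y <- D %*% W0 %*% t(P)
#' dimnames(Y) <- list(rownames(D), rownames(P))
#' fit <- affinity_regression(Y, D, P, lambda = 0.01)
#' coef(fit)
#' @export
affinity_regression <- function(Y, D, P, lambda = 1, center = TRUE) {
  stopifnot(is.matrix(Y), is.matrix(D), is.matrix(P), lambda >= 0)
  stop_if_na(Y, "Y"); stop_if_na(D, "D"); stop_if_na(P, "P")
  if (nrow(Y) != nrow(D)) stop("Y and D must share gene rows", call. = FALSE)
  if (ncol(Y) != nrow(P)) stop("Y columns and P rows must be the same samples",
                               call. = FALSE)
  if (!is.null(rownames(Y)) && !is.null(rownames(D))) {
    check_aligned(rownames(Y), rownames(D), "gene ids of Y and D")
  }
  if (!is.null(colnames(Y)) && !is.null(rownames(P))) {
    check_aligned(colnames(Y), rownames(P), "sample ids of Y and P")
  }
  if (center) {
    Y <- mean_center(Y, margin = 1L)
    P <- mean_center(P, margin = 2L)
  }
  gene_means <- centring_means(Y) %||%
    setNames(rep(0, nrow(Y)), rownames(Y))
  feature_means <- centring_means(P) %||%
    setNames(rep(0, ncol(P)), colnames(P))
  ctx <- ar_eigen_context(D, P)
  W <- ar_solve_ctx(ctx, crossprod(D, Y %*% P), lambda)
  dimnames(W) <- list(colnames(D), colnames(P))
  structure(list(W = W, lambda = lambda, Y = Y, D = D, P = P,
                 gene_means = gene_means, feature_means = feature_means,
                 dims = c(N = nrow(Y), M = ncol(Y), Q = ncol(D),
                          S = ncol(P))),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  d <- x$dims
  cat("Affinity-regression model\n")
  cat(sprintf("  %d genes, %d samples, %d TFs, %d protein features\n",
              d["N"], d["M"], d["Q"], d["S"]))
  cat(sprintf("  lambda = %g, ||W||_F = %.4g\n", x$lambda,
              sqrt(sum(x$W^2))))
  invisible(x)
}

#' @export
coef.ar_model <- function(object, ...) object$W

#' @export
fitted.ar_model <- function(object, ...) {
  object$D %*% object$W %*% t(object$P)
}

#' @export
residuals.ar_model <- function(object, ...) object$Y - fitted(object)

#' @export
summary.ar_model <- function(object, ...) {
  fit <- fitted(object)
  r <- vapply(seq_len(ncol(fit)),
              function(j) cor(fit[, j], object$Y[, j], method = "spearman"),
              numeric(1))
  out <- list(dims = object$dims, lambda = object$lambda,
              train_spearman = setNames(r, colnames(object$Y)),
              frobenius_W = sqrt(sum(object$W^2)))
  class(out) <- "summary.ar_model"
  out
}

#' @export
print.summary.ar_model <- function(x, ...) {
  d <- x$dims
  cat("Affinity-regression model\n")
  cat(sprintf("  %d genes, %d samples, %d TFs, %d protein features\n",
              d["N"], d["M"], d["Q"], d["S"]))
  cat(sprintf("  lambda = %g, ||W||_F = %.4g\n", x$lambda, x$frobenius_W))
  cat(sprintf("  training per-sample Spearman: median %.3f (range %.3f-%.3f)\n",
              median(x$train_spearman), min(x$train_spearman),
              max(x$train_spearman)))
  invisible(x)
}

#' @export
plot.ar_model <- function(x, ...) {
  W <- x$W
  image(seq_len(ncol(W)), seq_len(nrow(W)), t(W[rev(seq_len(nrow(W))), ,
                                                drop = FALSE]),
        xlab = "protein feature", ylab = "TF",
        main = "Interaction matrix W", ...)
  invisible(x)
}

#' Predict from an affinity-regression model
#'
#' For a matrix of new protein profiles (samples x features, uncentred), the
#' model predicts each sample's similarity to the training samples
#' (`type = "similarity"`, the vector `Y' D W p`), reconstructs the full
#' expression profile from those similarities (`type = "expression"`), or
#' reports inferred TF activities (`type = "tf_activity"`, the mapping
#' `W P'`). With `type = "protein_activity"`, `newdata` is instead a centred
#' genes x samples expression matrix and the mapping `Y' D W` is returned.
#'
#' @param object an `ar_model`.
#' @param newdata new data matrix as described above; defaults to the
#'   training data.
#' @param type prediction type.
#' @param center centre `newdata` with the stored training means (default
#'   TRUE); ignored when `newdata` is NULL.
#' @param ... unused.
#' @return a matrix; regulators or genes in rows, samples in columns (training
#'   samples in rows for `"similarity"`).
#' @export
predict.ar_model <- function(object, newdata = NULL,
                             type = c("expression", "similarity",
                                      "tf_activity", "protein_activity"),
                             center = TRUE, ...) {
  type <- match.arg(type)
  if (type == "protein_activity") {
    return(infer_protein_activities(object, expression = newdata,
                                    center = center))
  }
  if (type == "tf_activity") {
    return(infer_tf_activities(object, proteins = newdata, center = center))
  }
  P_new <- if (is.null(newdata)) object$P else
    prepare_protein_input(object, newdata, center)
  S_mat <- crossprod(object$Y, object$D %*% object$W %*% t(P_new))
  rownames(S_mat) <- colnames(object$Y)
  colnames(S_mat) <- rownames(P_new)
  if (type == "similarity") return(S_mat)
  reconstruct_expression(S_mat, object$Y)
}

prepare_protein_input <- function(model, proteins, center) {
  stopifnot(is.matrix(proteins))
  if (!is.null(colnames(proteins))) {
    check_aligned(colnames(proteins), colnames(model$W),
                  "protein features of newdata and model")
  } else if (ncol(proteins) != ncol(model$W)) {
    stop("protein features of newdata and model are not aligned",
         call. = FALSE)
  }
  if (center) {
    proteins <- mean_center(proteins, margin = 2L,
                            reference_means = model$feature_means)
  }
  proteins
}

#' Inferred transcription-factor activities
#'
#' Maps (centred) protein profiles through the trained interaction matrix:
#' activities are the rows of `W P'`, one score per TF and sample.
#'
#' @param model an `ar_model`.
#' @param proteins optional samples x features matrix; defaults to the
#'   training profiles.
#' @param center centre new profiles with the training feature means.
#' @return TFs x samples matrix with attribute `regulator_kind = "tf"`.
#' @export
infer_tf_activities <- function(model, proteins = NULL, center = TRUE) {
  P <- if (is.null(proteins)) model$P else
    prepare_protein_input(model, proteins, center)
  act <- model$W %*% t(P)
  rownames(act) <- rownames(model$W)
  colnames(act) <- rownames(P)
  attr(act, "regulator_kind") <- setNames(rep("tf", nrow(act)), rownames(act))
  act
}

#' Inferred (phospho)protein activities
#'
#' Maps (centred) expression profiles back through the model: activities are
#' `Y' D W`, stored transposed as features x samples. These are
#' expression-informed, denoised scores of each protein feature per sample.
#'
#' @param model an `ar_model`.
#' @param expression optional genes x samples matrix; defaults to the training
#'   expression. Gene order must match the training genes.
#' @param center centre new expression rows with the training gene means.
#' @return protein-features x samples matrix with attribute
#'   `regulator_kind = "protein"`.
#' @export
infer_protein_activities <- function(model, expression = NULL, center = TRUE) {
  Y <- if (is.null(expression)) {
    model$Y
  } else {
    stopifnot(is.matrix(expression))
    if (!is.null(rownames(expression))) {
      check_aligned(rownames(expression), rownames(model$D),
                    "genes of expression and model")
    } else if (nrow(expression) != nrow(model$D)) {
      stop("genes of expression and model are not aligned", call. = FALSE)
    }
    if (center) {
      expression <- mean_center(expression, margin = 1L,
                                reference_means = model$gene_means)
    }
    expression
  }
  act <- t(crossprod(Y, model$D %*% model$W))
  rownames(act) <- colnames(model$W)
  colnames(act) <- colnames(Y)
  attr(act, "regulator_kind") <- setNames(rep("protein", nrow(act)),
                                          rownames(act))
  act
}

#' Combined regulator activity matrix
#'
#' Stacks inferred TF activities over inferred (phospho)protein activities
#' into one regulators x samples matrix tagged by regulator kind.
#'
#' @param model an `ar_model`.
#' @return regulators x samples matrix with attribute `regulator_kind`.
#' @export
infer_activities <- function(model) {
  tf <- infer_tf_activities(model)
  pr <- infer_protein_activities(model)
  out <- rbind(tf, pr)
  attr(out, "regulator_kind") <- c(attr(tf, "regulator_kind"),
                                   attr(pr, "regulator_kind"))
  out
}

#' Regulator kind labels of an activity matrix
#' @param x an activity matrix produced by the inference functions.
#' @return character vector (`"tf"` / `"protein"`) named by regulator.
#' @export
regulator_kind <- function(x) attr(x, "regulator_kind")

#' Predicted similarity of a test sample to the training samples
#'
#' Right-multiplies a single (centred) protein profile through the model:
#' `s = Y' D W p`, one entry per training sample.
#'
#' @param model an `ar_model`.
#' @param p_new numeric vector of length S (already centred with the training
#'   means) or a 1 x S matrix.
#' @return numeric vector named by training sample.
#' @export
predict_sample_similarities <- function(model, p_new) {
  p <- as.numeric(p_new)
  if (length(p) != ncol(model$W)) {
    stop("p_new length does not match the model's protein features",
         call. = FALSE)
  }
  s <- as.numeric(crossprod(model$Y, model$D %*% (model$W %*% p)))
  setNames(s, colnames(model$Y))
}

#' Reconstruct expression profiles from training-sample similarities
#'
#' Assuming a test profile lies in the linear span of the training profiles,
#' solves the regularised Gram system `(Y'Y + eps I) a = s` and returns
#' `Y a`. `eps` defaults to `1e-6 * trace(Y'Y) / M`, keeping the system
#' well-posed without noticeably biasing the reconstruction.
#'
#' @param s similarity vector over training samples, or a matrix with one
#'   column per test sample.
#' @param Y_train centred genes x samples training expression.
#' @param ridge_eps small positive regulariser; see default above.
#' @return predicted expression profile(s), genes x test-samples.
#' @export
reconstruct_expression <- function(s, Y_train, ridge_eps = NULL) {
  S_mat <- if (is.matrix(s)) s else matrix(s, ncol = 1L)
  M <- ncol(Y_train)
  if (nrow(S_mat) != M) {
    stop("similarity vector length must equal the number of training samples",
         call. = FALSE)
  }
  G <- crossprod(Y_train)
  eps <- ridge_eps %||% (1e-6 * sum(diag(G)) / M)
  A <- solve(G + diag(eps, M), S_mat)
  out <- Y_train %*% A
  colnames(out) <- colnames(S_mat)
  out
}

#' Nearest-neighbour expression prediction baseline
#'
#' Predicts a test sample's expression as the expression profile of the
#' training sample nearest in protein (RPPA) space by Euclidean distance.
#' Ties are broken by the lowest training-sample index and reported.
#'
#' @param P_train samples x features training protein matrix (centred).
#' @param Y_train genes x samples training expression (centred).
#' @param p_test protein profile of the test sample (centred with training
#'   means).
#' @return the chosen training sample's expression profile, with attribute
#'   `neighbour` naming it.
#' @export
nearest_neighbour_baseline <- function(P_train, Y_train, p_test) {
  if (nrow(P_train) == 0L) stop("empty training set", call. = FALSE)
  d2 <- colSums((t(P_train) - as.numeric(p_test))^2)
  j <- which.min(d2)
  if (sum(d2 == d2[j]) > 1L) {
    message("nearest-neighbour tie broken by lowest sample index")
  }
  out <- Y_train[, j]
  attr(out, "neighbour") <- colnames(Y_train)[j]
  out
}

#' Fit with randomized motif or protein inputs (negative control)
#'
#' Permutes the gene labels of the motif-hit matrix (`mode = "motif"`), the
#' sample labels of the protein matrix (`mode = "rppa"`), or both, with a
#' seeded shuffle, then fits the model as usual. The multiset of rows of each
#' permuted matrix is unchanged; only the pairing is destroyed.
#'
#' @param bundle a `cohort_bundle`.
#' @param mode which input to randomize.
#' @param seed integer seed for the shuffle.
#' @param lambda ridge penalty passed to [affinity_regression()].
#' @return an `ar_model` fitted to the randomized inputs.
#' @export
randomized_control_fit <- function(bundle, mode = c("motif", "rppa", "both"),
                                   seed, lambda = 1) {
  mode <- match.arg(mode)
  D <- bundle$motifs
  P <- bundle$proteins
  if (mode %in% c("motif", "both")) {
    perm <- with_seed(child_seed(seed, 11L), sample.int(nrow(D)))
    D <- D[perm, , drop = FALSE]
    rownames(D) <- rownames(bundle$motifs)
  }
  if (mode %in% c("rppa", "both")) {
    perm <- with_seed(child_seed(seed, 12L), sample.int(nrow(P)))
    P <- P[perm, , drop = FALSE]
    rownames(P) <- rownames(bundle$proteins)
  }
  affinity_regression(bundle$expression, D, P, lambda = lambda)
}
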