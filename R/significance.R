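# Permutation-based empirical null calibration of inferred activities.

#' Build a permutation null ensemble of regulator activities
#'
#' For each permutation the sample columns of the centred expression matrix
#' are shuffled as whole profiles (preserving gene-gene covariance while
#' breaking the expression-protein pairing), the interaction matrix is refit
#' with the true motif and protein matrices, and both activity mappings are
#' recomputed and stored. Because a column permutation of `Y` only permutes
#' the columns of `D'Y`, the refit reuses the eigendecompositions of `D'D`
#' and `P'P` and the ensemble is cheap even for thousands of draws.
#'
#' With `scheme = "per_gene"` each gene row is instead permuted
#' independently, which additionally destroys gene-gene covariance.
#'
#' @param bundle a `cohort_bundle`.
#' @param n_permutations number of null draws (>= 1). Full-scale analyses use
#'   5000; calibration tests are stable from a few hundred.
#' @param seed integer seed.
#' @param lambda ridge penalty used for every refit (default 1).
#' @param scheme `"columns"` (default) or `"per_gene"`.
#' @return an object of class `null_ensemble`: a 3-d array `draws` indexed
#'   (permutation, regulator, sample) plus bookkeeping fields.
#' @export
build_null_ensemble <- function(bundle, n_permutations, seed, lambda = 1,
                                scheme = c("columns", "per_gene")) {
  scheme <- match.arg(scheme)
  stopifnot(n_permutations >= 1L)
  Y <- mean_center(bundle$expression, margin = 1L)
  P <- mean_center(bundle$proteins, margin = 2L)
  D <- bundle$motifs
  M <- ncol(Y); Q <- ncol(D); S <- ncol(P)
  ctx <- ar_eigen_context(D, P)
  G <- crossprod(D, Y)                      # Q x M, recyclable across draws
  regs <- c(colnames(D), colnames(P))
  kind <- setNames(c(rep("tf", Q), rep("protein", S)), regs)
  draws <- array(NA_real_, dim = c(n_permutations, Q + S, M),
                 dimnames = list(NULL, regs, colnames(Y)))
  for (b in seq_len(n_permutations)) {
    if (scheme == "columns") {
      perm <- with_seed(child_seed(seed, b), sample.int(M))
      Gb <- G[, perm, drop = FALSE]
    } else {
      Yb <- with_seed(child_seed(seed, b),
                      t(apply(Y, 1L, sample)))
      Gb <- crossprod(D, Yb)
    }
    Wb <- ar_solve_ctx(ctx, Gb %*% P, lambda)
    draws[b, seq_len(Q), ] <- Wb %*% t(P)            # TF activities
    draws[b, Q + seq_len(S), ] <- t(crossprod(Gb, Wb))  # (Y_b' D) W_b, M x S
  }
  structure(list(draws = draws, n_permutations = n_permutations,
                 seed = seed, lambda = lambda, scheme = scheme,
                 regulator_kind = kind),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "Null ensemble: %d permutations x %d regulators x %d samples (seed %d)\n",
    d[1], d[2], d[3], x$seed))
  invisible(x)
}

#' Empirical tail p-values of observed activities against a null ensemble
#'
#' For each (regulator, sample) cell the right-tail p-value is
#' `(1 + #\{null >= observed\}) / (n + 1)` and the left tail uses `<=`; the
#' add-one smoothing keeps p-values in (0, 1]. The two-tailed p-value is
#' `min(1, 2 min(left, right))`, and Benjamini-Yekutieli adjustment is applied
#' across regulators within each sample, separately for the TF and protein
#' families.
#'
#' @param observed regulators x samples activity matrix with a
#'   `regulator_kind` attribute (see [infer_activities()]).
#' @param null a `null_ensemble` aligned with `observed`.
#' @return an object of class `activity_significance` with matrices `left_p`,
#'   `right_p`, `p_two`, `adjusted_p`, the regulator kinds and the direction
#'   of each departure (`sign`).
#' @export
empirical_tail_pvalues <- function(observed, null) {
  stopifnot(inherits(null, "null_ensemble"))
  n <- null$n_permutations
  if (n == 0L) stop("null ensemble has no permutations", call. = FALSE)
  regs <- rownames(observed)
  check_aligned(regs, dimnames(null$draws)[[2]],
                "regulators of observed activities and null ensemble")
  R <- nrow(observed); M <- ncol(observed)
  ge <- matrix(0L, R, M, dimnames = dimnames(observed))
  le <- matrix(0L, R, M, dimnames = dimnames(observed))
  for (b in seq_len(n)) {
    draw <- matrix(null$draws[b, , ], R, M)
    ge <- ge + (draw >= observed)
    le <- le + (draw <= observed)
  }
  right_p <- (1 + ge) / (n + 1)
  left_p <- (1 + le) / (n + 1)
  p_two <- pmin(2 * pmin(left_p, right_p), 1)  # keeps matrix dims
  kind <- regulator_kind(observed) %||% null$regulator_kind
  adjusted <- p_two
  for (fam in unique(kind)) {
    idx <- which(kind == fam)
    for (j in seq_len(M)) {
      adjusted[idx, j] <- adjust_by(p_two[idx, j])
    }
  }
  structure(list(left_p = left_p, right_p = right_p, p_two = p_two,
                 adjusted_p = adjusted,
                 sign = ifelse(right_p <= left_p, 1, -1),
                 regulator_kind = kind, n_permutations = n),
            class = "activity_significance")
}

#' @export
print.activity_significance <- function(x, ...) {
  cat(sprintf(
    "Activity significance: %d regulators x %d samples (%d permutations)\n",
    nrow(x$p_two), ncol(x$p_two), x$n_permutations))
  if (!is.null(x$significant)) {
    cat(sprintf("  %d significant cells at FDR %.2f\n", sum(x$significant),
                x$fdr_threshold))
  }
  invisible(x)
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' Adjusts p-values for false-discovery control under arbitrary dependence:
#' sorted `p_(i)` become `p_(i) * m * c(m) / i` with
#' `c(m) = sum_{j=1}^m 1/j`, enforced monotone and capped at 1. This is
#' `stats::p.adjust(method = "BY")` behind an input check restricting values
#' to (0, 1].
#'
#' @param pvalues numeric vector with entries in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
adjust_by <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BY")
}

#' Cohort-size dependent FDR threshold
#'
#' Larger cohorts support stricter control: 0.10 above 300 samples, 0.15 for
#' 100-300, 0.25 below 100.
#'
#' @param cohort_size number of samples.
#' @return the FDR threshold.
#' @export
cohort_fdr_threshold <- function(cohort_size) {
  stopifnot(cohort_size >= 1)
  if (cohort_size > 300) 0.10 else if (cohort_size >= 100) 0.15 else 0.25
}

#' Flag significant regulator activities
#'
#' Marks a (regulator, sample) cell significant when its BY-adjusted
#' two-tailed p-value falls below the cohort-size threshold; the direction of
#' the departure (high or low activity) is retained from the smaller tail.
#'
#' @param sig an `activity_significance`.
#' @param cohort_size number of samples, used to pick the threshold.
#' @param threshold optional explicit FDR threshold overriding the policy.
#' @return `sig` with `significant` (logical matrix) and `fdr_threshold`
#'   filled in.
#' @export
flag_significant_regulators <- function(sig, cohort_size = NULL,
                                        threshold = NULL) {
  stopifnot(inherits(sig, "activity_significance"))
  thr <- threshold %||% cohort_fdr_threshold(cohort_size)
  sig$significant <- sig$adjusted_p < thr
  sig$fdr_threshold <- thr
  sig
}

#' Per-regulator prevalence of significant activity
#'
#' Fraction of samples in which each regulator passed its significance
#' threshold; used downstream to restrict association and survival screens
#' (e.g. prevalence of at least 1% or 5%).
#'
#' @param sig a flagged `activity_significance`.
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
regulator_prevalence <- function(sig) {
  stopifnot(inherits(sig, "activity_significance"))
  if (is.null(sig$significant)) {
    stop("flags not computed; call flag_significant_regulators() first",
         call. = FALSE)
  }
  rowMeans(sig$significant)
}
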