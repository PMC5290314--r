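# Synthetic cohorts drawn from the bilinear generative model
#   Y = D W* P' + noise
# with planted alteration effects on protein features and exponential
# proportional-hazards survival, so that every pipeline stage can be tested
# against known ground truth.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a desk-scale cohort with realistic proportions: a sparse
#' binary motif matrix (10% hits), a sparse interaction matrix (20% nonzero,
#' unit-scale effects), expression noise at half the signal's standard
#' deviation, ten binary alterations at 30% carrier frequency (three of which
#' shift their target protein feature by +2 feature-sd), a unit log-hazard on
#' the standardized activity of the most variable true TF, a baseline hazard
#' of 0.02 per month
#' and 30% censoring.
#'
#' @param n_genes,n_samples,n_tfs,n_features cohort dimensions (N, M, Q, S).
#' @param motif_density fraction of 1s in the motif matrix.
#' @param w_sparsity fraction of nonzero interaction weights.
#' @param w_scale standard deviation of nonzero interaction weights.
#' @param noise_sd_ratio expression noise sd relative to the empirical signal
#'   sd of `D W* P'`.
#' @param noise_df degrees of freedom of the noise distribution: `Inf`
#'   (default) gives Gaussian noise; a finite value draws scaled Student-t
#'   noise with the same sd, for stress-testing rank-based metrics.
#' @param n_alterations number of binary alterations.
#' @param alteration_frequency carrier probability per alteration (recycled).
#' @param planted_effects data frame with columns `alteration` (index),
#'   `feature` (target protein-feature index) and `magnitude`, or NULL for
#'   the default three planted effects (+2 on features 1..3). Use a 0-row
#'   data frame for none.
#' @param survival_coefficient log hazard per sd of the designated true
#'   activity (the most variable true TF activity; named in the truth bundle
#'   as `risk_regulator`).
#' @param baseline_hazard events per month at activity 0.
#' @param censoring_fraction target fraction of censored samples.
#' @param seed mandatory integer seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L, n_samples = 100L,
                              n_tfs = 40L, n_features = 25L,
                              motif_density = 0.1, w_sparsity = 0.2,
                              w_scale = 1, noise_sd_ratio = 0.5,
                              noise_df = Inf,
                              n_alterations = 10L,
                              alteration_frequency = 0.3,
                              planted_effects = NULL,
                              survival_coefficient = 1,
                              baseline_hazard = 0.02,
                              censoring_fraction = 0.3,
                              seed) {
  stopifnot(n_genes >= 1L, n_samples >= 1L, n_tfs >= 1L, n_features >= 1L,
            motif_density > 0, motif_density < 1,
            w_sparsity > 0, w_sparsity <= 1,
            noise_sd_ratio >= 0, noise_df > 2,
            censoring_fraction >= 0, censoring_fraction < 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_alterations > 0L &&
      any(alteration_frequency * n_samples < 1)) {
    stop("infeasible config: alteration frequency x samples < 1",
         call. = FALSE)
  }
  if (is.null(planted_effects)) {
    k <- min(3L, n_alterations, n_features)
    planted_effects <- data.frame(alteration = seq_len(k),
                                  feature = seq_len(k),
                                  magnitude = rep(2, k))
  }
  stopifnot(all(planted_effects$alteration <= n_alterations),
            all(planted_effects$feature <= n_features))
  structure(list(n_genes = n_genes, n_samples = n_samples, n_tfs = n_tfs,
                 n_features = n_features, motif_density = motif_density,
                 w_sparsity = w_sparsity, w_scale = w_scale,
                 noise_sd_ratio = noise_sd_ratio, noise_df = noise_df,
                 n_alterations = n_alterations,
                 alteration_frequency = rep_len(alteration_frequency,
                                                n_alterations),
                 planted_effects = planted_effects,
                 survival_coefficient = survival_coefficient,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# Censoring rate achieving the target expected censoring fraction given
# per-sample exponential event rates.
censoring_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(rc) mean(rc / (rc + rates)) - target
  stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(rates))$root
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a cohort from the bilinear generative model. The motif matrix is
#' Bernoulli with the configured density (every TF guaranteed at least one
#' target); the interaction matrix `W*` is sparse Gaussian; base protein
#' profiles are standard normal per feature; each alteration is assigned to
#' carriers at its configured frequency and adds its planted shift to the
#' target protein features of carriers; expression is `D W* P'` plus
#' homoscedastic noise (Gaussian, or scaled Student-t when `noise_df` is
#' finite) whose sd is `noise_sd_ratio` times the empirical signal sd;
#' survival times are exponential proportional-hazards
#' draws on the standardized activity of the most variable true TF, with
#' independent exponential censoring tuned to the configured censoring
#' fraction.
#'
#' @param config a `simulation_config`.
#' @return list with elements `bundle` (a [cohort_bundle()]) and `truth`
#'   (`W_star`, `tf_activity`, `protein_activity`, `alteration_effects`,
#'   `survival_coefficient`, `signal_sd`, `noise_sd`).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sim_ids("g", cfg$n_genes)
    samples <- sim_ids("s", cfg$n_samples)
    tfs <- sim_ids("tf", cfg$n_tfs)
    feats <- sim_ids("ab", cfg$n_features)

    D <- matrix(rbinom(cfg$n_genes * cfg$n_tfs, 1, cfg$motif_density),
                cfg$n_genes, cfg$n_tfs, dimnames = list(genes, tfs))
    empty <- colSums(D) == 0
    for (j in which(empty)) D[sample.int(cfg$n_genes, 1L), j] <- 1

    W_star <- matrix(rnorm(cfg$n_tfs * cfg$n_features, sd = cfg$w_scale) *
                       rbinom(cfg$n_tfs * cfg$n_features, 1, cfg$w_sparsity),
                     cfg$n_tfs, cfg$n_features,
                     dimnames = list(tfs, feats))
    # a planted alteration effect is only observable downstream if its target
    # feature carries regulatory weight: guarantee a minimum column norm so
    # the planted shift has a transcriptional footprint
    for (f in unique(cfg$planted_effects$feature)) {
      if (sqrt(sum(W_star[, f]^2)) < 0.5 * cfg$w_scale) {
        W_star[sample.int(cfg$n_tfs, 1L), f] <-
          sample(c(-1, 1), 1L) * cfg$w_scale
      }
    }

    P <- matrix(rnorm(cfg$n_samples * cfg$n_features),
                cfg$n_samples, cfg$n_features,
                dimnames = list(samples, feats))

    alt <- NULL
    if (cfg$n_alterations > 0L) {
      alt <- sapply(cfg$alteration_frequency, function(f)
        rbinom(cfg$n_samples, 1, f))
      dimnames(alt) <- list(samples, sim_ids("alt", cfg$n_alterations))
      attr(alt, "alteration_kind") <- setNames(
        rep("mutation", ncol(alt)), colnames(alt))
      attr(alt, "alteration_gene") <- setNames(colnames(alt), colnames(alt))
      pe <- cfg$planted_effects
      if (nrow(pe) > 0L) {
        for (r in seq_len(nrow(pe))) {
          carriers <- alt[, pe$alteration[r]] == 1
          P[carriers, pe$feature[r]] <- P[carriers, pe$feature[r]] +
            pe$magnitude[r]
        }
      }
    }

    signal <- D %*% W_star %*% t(P)
    signal_sd <- sd(as.numeric(signal))
    noise_sd <- cfg$noise_sd_ratio * signal_sd
    eps <- if (is.finite(cfg$noise_df)) {
      # scaled t: same sd as the Gaussian option, heavier tails
      stats::rt(length(signal), df = cfg$noise_df) *
        noise_sd / sqrt(cfg$noise_df / (cfg$noise_df - 2))
    } else {
      rnorm(length(signal), sd = noise_sd)
    }
    Y <- signal + matrix(eps, nrow(signal), ncol(signal))
    dimnames(Y) <- list(genes, samples)

    tf_act <- W_star %*% t(P)
    # hazard is driven by the most variable true TF activity (a row of all-
    # zero weights would make the designated activity degenerate)
    risk_idx <- which.max(apply(tf_act, 1L, sd))
    risk_act <- if (sd(tf_act[risk_idx, ]) > 0) {
      as.numeric(scale(tf_act[risk_idx, ]))
    } else {
      rnorm(cfg$n_samples)
    }
    rates <- cfg$baseline_hazard * exp(cfg$survival_coefficient * risk_act)
    event_t <- rexp(cfg$n_samples, rates)
    rc <- censoring_rate(rates, cfg$censoring_fraction)
    cens_t <- if (rc > 0) rexp(cfg$n_samples, rc) else rep(Inf, cfg$n_samples)
    time <- pmin(event_t, cens_t)
    event <- as.numeric(event_t <= cens_t)

    clinical <- data.frame(
      sample_id = samples,
      time_months = time,
      event = event,
      covariate = sample(c("stage_i", "stage_ii", "stage_iii"),
                         cfg$n_samples, replace = TRUE),
      subgroup = sample(c("A", "B"), cfg$n_samples, replace = TRUE),
      stringsAsFactors = FALSE)

    bundle <- cohort_bundle(Y, D, P, alterations = alt, clinical = clinical)
    pe <- cfg$planted_effects
    truth <- list(
      W_star = W_star,
      tf_activity = tf_act,
      protein_activity = t(P),
      alteration_effects = if (cfg$n_alterations > 0L && nrow(pe) > 0L) {
        data.frame(alteration = colnames(alt)[pe$alteration],
                   feature = feats[pe$feature],
                   magnitude = pe$magnitude, stringsAsFactors = FALSE)
      } else {
        data.frame(alteration = character(), feature = character(),
                   magnitude = numeric())
      },
      survival_coefficient = cfg$survival_coefficient,
      risk_regulator = tfs[risk_idx],
      risk_activity = risk_act,
      signal_sd = signal_sd, noise_sd = noise_sd)
    list(bundle = bundle, truth = truth)
  })
}

#' Generate a fully null synthetic cohort
#'
#' Same marginal structure as [make_cohort()] but expression is generated
#' independently of the protein profiles (`W* = 0`; pure unit-variance
#' Gaussian noise) and no effects are planted. Used to calibrate every
#' p-value-producing stage.
#'
#' @param config a `simulation_config`.
#' @return a `cohort_bundle`.
#' @export
make_null_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  cfg$planted_effects <- cfg$planted_effects[0, , drop = FALSE]
  cohort <- make_cohort(cfg)
  with_seed(child_seed(cfg$seed, 99L), {
    Y <- matrix(rnorm(cfg$n_genes * cfg$n_samples),
                cfg$n_genes, cfg$n_samples,
                dimnames = dimnames(cohort$bundle$expression))
    cohort$bundle$expression <- Y
  })
  cohort$bundle
}

#' Write a graded suite of synthetic fixtures
#'
#' Emits `tiny` (N=50, M=12), `small` (N=500, M=60) and `reference`
#' (N=1000, M=100, Q=40, S=25) cohorts as the package's TSV dialect, each
#' with its ground-truth interaction matrix and a JSON manifest of seeds and
#' dimensions so the fixtures can be regenerated exactly.
#'
#' @param output_dir writable directory.
#' @param sizes subset of `c("tiny", "small", "reference")`.
#' @param seed base seed; each size derives its own child seed.
#' @return paths of the written directories, invisibly.
#' @export
write_fixture_suite <- function(output_dir,
                                sizes = c("tiny", "small", "reference"),
                                seed = 20260101) {
  sizes <- match.arg(sizes, several.ok = TRUE)
  presets <- list(
    tiny = list(n_genes = 50L, n_samples = 12L, n_tfs = 6L, n_features = 4L,
                n_alterations = 2L, alteration_frequency = 0.4),
    small = list(n_genes = 500L, n_samples = 60L, n_tfs = 20L,
                 n_features = 10L, n_alterations = 6L),
    reference = list(n_genes = 1000L, n_samples = 100L, n_tfs = 40L,
                     n_features = 25L))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (i in seq_along(sizes)) {
    sz <- sizes[i]
    args <- presets[[sz]]
    args$seed <- child_seed(seed, match(sz, names(presets)))
    cfg <- do.call(simulation_config, args)
    cohort <- make_cohort(cfg)
    d <- file.path(output_dir, sz)
    dir.create(d, showWarnings = FALSE)
    b <- cohort$bundle
    write_matrix(b$expression, file.path(d, "expression.tsv"), "gene")
    write_matrix(b$motifs, file.path(d, "motifs.tsv"), "gene")
    write_matrix(b$proteins, file.path(d, "proteins.tsv"), "sample")
    if (!is.null(b$alterations) && ncol(b$alterations) > 0L) {
      write_matrix(b$alterations, file.path(d, "alterations.tsv"), "sample")
    }
    write.table(b$clinical, file.path(d, "clinical.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix(cohort$truth$W_star, file.path(d, "truth_W.tsv"), "tf")
    manifest <- c(
      sprintf('  "size": "%s"', sz),
      sprintf('  "seed": %d', as.integer(cfg$seed)),
      sprintf('  "n_genes": %d', cfg$n_genes),
      sprintf('  "n_samples": %d', cfg$n_samples),
      sprintf('  "n_tfs": %d', cfg$n_tfs),
      sprintf('  "n_features": %d', cfg$n_features))
    writeLines(c("{", paste(manifest, collapse = ",\n"), "}"),
               file.path(d, "manifest.json"))
    written <- c(written, d)
  }
  invisible(written)
}
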