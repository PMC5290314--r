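---
title: "Methods: bilinear affinity regression for proteogenomic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilinear affinity regression for proteogenomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arpan)
```

## The model

`arpan` treats tumour gene expression as the output of a two-layer
regulatory chain: (phospho)protein signalling state, measured by RPPA,
drives transcription-factor activity, which acts on genes carrying the TF's
binding sites. With `Y` the centred log expression (genes × samples), `D` a
binary motif-hit matrix (genes × TFs) and `P` the centred protein profiles
(samples × features), the interaction matrix `W` is the unique minimiser of

$$\lVert Y - D\,W\,P^{\top}\rVert_F^2 + \lambda\,\lVert W\rVert_F^2 .$$

The normal equations $D^{\top}D\,W\,P^{\top}P + \lambda W = D^{\top}YP$ are
solved by diagonalising the two small Gram matrices: with
$D^{\top}D = U\,\mathrm{diag}(a)\,U^{\top}$ and
$P^{\top}P = V\,\mathrm{diag}(b)\,V^{\top}$,

$$W = U\left[\frac{U^{\top}(D^{\top}YP)\,V}{a_i b_j + \lambda}\right]V^{\top},$$

identical to the dense Kronecker form
$\mathrm{vec}(W) = (P^{\top}P \otimes D^{\top}D + \lambda I)^{-1}
\mathrm{vec}(D^{\top}YP)$ but at $O(Q^3 + S^3)$ cost. The test suite holds
the two routes to a relative error of $10^{-8}$ on a grid of random
instances (observed agreement is at machine precision, about $10^{-15}$).
At $\lambda = 0$ the solver refuses singular systems (any $a_i b_j = 0$,
detected at relative tolerance $10^{-14}$) and advises a positive penalty.

Three linear mappings flow through a fitted model:

* TF activities $W P^{\top}$ (TFs × samples),
* (phospho)protein activities $Y^{\top} D W$ (stored features × samples),
* similarities of a new sample to the training samples,
  $s = Y^{\top} D W p$.

Held-out expression is reconstructed from similarities under the assumption
that the test profile lies in the span of the training profiles: solve
$(Y^{\top}Y + \varepsilon I)\,a = s$ and return $Y a$. The regulariser
defaults to $\varepsilon = 10^{-6}\,\mathrm{tr}(Y^{\top}Y)/M$ — small enough
not to bias the reconstruction, large enough to keep the Gram system
well-posed when $M$ exceeds the numerical rank.

## Preprocessing conventions

* Genes are ranked by variance across samples and the top `k` retained
  (default 5,000); ties break by input order, so selection is deterministic.
* Expression is centred per gene, protein features per column. Centring
  offsets are stored so held-out or external data can be centred relative to
  the training set.
* A TF column of the motif matrix is kept when its gene is expressed —
  raw (pre-centring) abundance strictly above a configurable floor, default
  0 — in at least 40% of samples, boundary inclusive. "Expressed" is not
  fully pinned down by the data conventions this matrix emulates; abundance
  above the dataset's zero floor is the natural reading and the threshold is
  exposed.
* Near-duplicate motif columns are removed by a greedy pass in column order
  at Jaccard similarity ≥ 0.8 (both measure and threshold are configurable;
  greediness makes the result deterministic and each removal is logged with
  its retained partner).
* Alterations are binary presence/absence: non-silent mutations in driver
  genes (q < 0.05) recurring in ≥ 10 samples; copy-number events only at
  discrete calls ±2 in recurrently altered genes (q < 0.001), again with
  ≥ 10-sample recurrence; amplification and deletion of a gene are separate
  events.
* Any missing value in an input matrix is a hard validation error; no
  imputation is performed anywhere.

## Significance of inferred activities

The empirical null refits the model on expression whose **sample columns**
have been permuted as whole profiles: this preserves gene–gene covariance
and each profile's internal structure while destroying the sample-level
pairing between expression and protein data, which is exactly the
relationship the activities encode. (An option permutes each gene row
independently instead.) Because a column permutation of $Y$ only permutes
the columns of $D^{\top}Y$, the per-draw refit reuses the cached
eigendecompositions and reduces to elementwise work, so ensembles of
thousands of draws are cheap.

Per (regulator, sample) cell, tail p-values use add-one smoothing,
$p_{right} = (1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$, with the left
tail symmetric and ties counted in both tails; the two-tailed p is
$\min(1, 2\min(p_{left}, p_{right}))$. Smoothed p-values are never 0.
Benjamini–Yekutieli adjustment (valid under arbitrary dependence; delegated
to `stats::p.adjust`) is applied across regulators within each sample,
separately for the TF and protein families, mirroring how the association
stage treats the two kinds as separate test groups. Cells are flagged at a
cohort-size-dependent FDR — 0.10 above 300 samples, 0.15 for 100–300, 0.25
below 100 — and the direction of each flagged departure is taken from the
smaller tail. Where source conventions conflict on the small-cohort band
(a figure caption says < 50 samples, the procedure description < 100), the
< 100 banding is implemented, the only one consistent with a 58-sample
cohort being called small.

## Alteration associations

Each regulator's activity vector is ridge-regressed on the full binary
alteration matrix (λ default 1; predictors stay 0/1 and unstandardised —
presence/absence is the encoding, and standardising would entangle
coefficients with alteration frequency; the intercept is unpenalised via
centring). Coefficient significance comes from permuting the outcome across
samples and refitting — the refit reuses the factorised design, so all
permutations reduce to one matrix product — with the two-sided smoothed
p-value counting $|\beta_{null}| \ge |\beta_{obs}|$. The comparison uses a
$10^{-9}$ relative tolerance so permutations that exactly reproduce the
observed assignment tie cleanly; on a 6-sample worked instance with a
balanced predictor the Monte-Carlo p then converges to the exhaustively
enumerated 0.1. Fresh seeded permutation draws are used per regulator.

Nominal p-values are BY-adjusted across regulators within each
(alteration, regulator-kind) family. Two scores are emitted — the adjusted
p carrying the coefficient's sign, and $\mathrm{sign}(\beta) \times
-\log_{10}(p_{adj})$ for display — always agreeing in sign. Default filters
keep regulators significant in ≥ 1% of samples and alterations reaching
adjusted p < 0.15 for at least one regulator.

Pairwise interactions are tested for alteration pairs each present in ≥ 20
samples and co-occurring in ≥ 10: ordinary least squares of activity on
`A + B + A:B`, with the classical two-sided t-test on the interaction
coefficient (permutation is not used at this stage; single linear-model
p-values are reported). A significant (p < 0.05) interaction is synergistic
when its coefficient is positive and exceeds both main effects,
antagonistic when negative and below both, otherwise unclassified.

## Cohort screens

Group comparisons run a two-sided t or Wilcoxon rank-sum test per regulator
with BH adjustment across regulators (BH rather than BY here: these screens
are exploratory rankings, and the conservative harmonic inflation is
reserved for the activity and association families). Rank-set enrichment is
a one-sided Mann–Whitney test on list positions.

Survival screens fit one Cox model per regulator — continuous activity plus
an optional categorical background covariate whose reference level is the
most frequent — reporting the activity coefficient's Wald p, the model's
score (log-rank) p, BH adjustment across models, and each sample's risk as
the linear predictor. Samples missing the covariate are excluded with a
note; constant-activity regulators are skipped with a warning; a cohort with
no events is an error. Risk stratification ranks by decreasing risk and
labels the top and bottom `floor(0.4 n)` samples, ties at a boundary broken
by input order. Validation on an external cohort applies the trained model's
mappings to shared features — centring by the external cohort's own means by
default, since antibody batches differ between cohorts — and evaluates
Harrell's concordance with a two-sided normal test against 0.5, using the
trained linear predictor without refitting.

## The synthetic generator

`make_cohort()` draws from the same law the model assumes:
$D \sim \mathrm{Bernoulli}(0.1)$ (every TF guaranteed ≥ 1 target), sparse
Gaussian $W^{*}$ (20% nonzero, unit scale), standard-normal protein
profiles, $Y = D W^{*} P^{\top} + \varepsilon$ with noise sd defined
relative to the empirically measured signal sd (default ratio 0.5), binary
alterations at 30% frequency whose planted effects shift target protein
features of carrier samples (+2 feature-sd by default, three planted
effects), and exponential proportional-hazards survival on the most
variable standardised true TF activity (log hazard 1 per sd, baseline
0.02 events/month, independent exponential censoring whose rate is solved
numerically to hit the target 30% censoring in expectation).

Two generator guarantees are identifiability conditions, not signal
inflation: a motif column may not be all zero (a TF with no targets is not
a TF), and a planted effect's target feature must carry interaction weight
of at least half the typical scale — an alteration shifting a protein
feature with a (near-)zero $W^{*}$ column has no transcriptional footprint,
so no method could recover its sign even noiselessly. Alterations act
upstream, on protein features, so the association stage is exercised
through the full inference chain rather than on activities directly.

What the generator does **not** emulate: real marginal distributions of
RSEM or RPPA data, batch effects, antibody cross-reactivity, motif-hit
noise structure, or correlated alteration co-occurrence. Passing tests
demonstrate correctness of the machinery under the model's own assumptions,
not biological validity on real cohorts.

`make_null_cohort()` keeps all marginals but generates expression
independently of the protein layer; it calibrates every p-value-producing
stage. `write_fixture_suite()` emits tiny (N=50, M=12), small (N=500,
M=60) and reference (N=1000, M=100, Q=40, S=25) cohorts as TSV with truth
and a seed manifest.

## Problem sizes and stochastic checks

The test suite runs the solver oracle on ~20 random instances (N ≤ 20,
Q ≤ 5, M ≤ 10, S ≤ 4; λ ∈ {0.1, 1, 10}); activity recovery and the
cross-validated ordering of the true model against nearest-neighbour,
motif-randomized and fully randomized baselines (5 seeds, 10 folds) on the
reference cohort; null calibration on a 50-regulator null cohort with 500
permutations; association sign recovery and pooled false-discovery
proportion over 20 replicate cohorts (10 alterations, 3 planted, 500
permutations each); the enumerated-p worked example at 10,000 permutations;
and Cox recovery as the mean estimate over 5 replicate 300-sample cohorts
(a single cohort estimates the unit log-hazard with sd ≈ 0.15; averaging
replicates measures the same estimand more stably) plus size under the null
over 200 independent regulators.

Two calibration checks deserve a caveat: the (regulator, sample) cells of
one cohort share a single observed fit and a single null ensemble, so
uniformity statistics computed across cells have roughly twice the variance
that an independence assumption suggests. Occasional seeds therefore fall
outside tight uniformity bands without indicating miscalibration of the
per-cell procedure.

## Numerical choices and degenerate inputs

* Spearman correlations use the average-rank convention for ties
  (`stats::cor`); a constant predicted or measured profile makes the
  correlation undefined and is recorded as `NA` with a message, never as 0.
* λ is selected per cross-validation fold on an inner 75/25 split over a
  grid (default $10^{-2}\dots10^{3}$); non-CV fits default to λ = 1. Fold
  assignment is a seeded shuffle with folds as equal as possible; the seed
  is mandatory wherever randomness occurs, and every internal stream derives
  a child seed so results are reproducible end to end.
* Nearest-neighbour ties break to the lowest training index, variance-rank
  ties to input order, boundary ties in risk stratification to sample
  order — all logged.
* Zero-variance alteration columns are an error in direct regression calls
  and dropped with a warning in the screening wrapper; rank-deficient
  interaction designs (e.g. identical alteration pair) are an error.

## Limitations

The motif-hit layer is binary and context-free; inferred activities of
correlated regulators are themselves correlated, so association screens
report regulator sets rather than unique drivers; interaction tests use
classical OLS inference, which is anti-conservative for heavy-tailed
activities; and the generator's homoscedastic Gaussian noise (a
heavy-tailed stress option exists) understates the robustness gap between
Pearson- and rank-based evaluation on real data.
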