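# Shared fixture builders. Everything is generated in code; no stored data.

# A small labelled matrix with deterministic contents.
toy_matrix <- function(nr, nc, seed = 1, prefix = c("g", "s"), binary = FALSE) {
  set.seed(seed)
  vals <- if (binary) as.numeric(rbinom(nr * nc, 1, 0.5)) else rnorm(nr * nc)
  matrix(vals, nr, nc,
         dimnames = list(sprintf("%s%02d", prefix[1], seq_len(nr)),
                         sprintf("%s%02d", prefix[2], seq_len(nc))))
}

# A tiny aligned (Y, D, P) triple drawn from the bilinear model.
toy_triple <- function(N = 12, Q = 3, M = 6, S = 2, seed = 1, noise = 0) {
  set.seed(seed)
  D <- matrix(rbinom(N * Q, 1, 0.5), N, Q,
              dimnames = list(sprintf("g%02d", 1:N), sprintf("tf%d", 1:Q)))
  P <- matrix(rnorm(M * S), M, S,
              dimnames = list(sprintf("s%02d", 1:M), sprintf("ab%d", 1:S)))
  W <- matrix(rnorm(Q * S), Q, S)
  Y <- D %*% W %*% t(P) + matrix(rnorm(N * M, sd = noise), N, M)
  dimnames(Y) <- list(rownames(D), rownames(P))
  list(Y = Y, D = D, P = P, W = W)
}

# Dense Kronecker closed form, the independent oracle for the solver.
kron_oracle <- function(Y, D, P, lambda) {
  Q <- ncol(D); S <- ncol(P)
  K <- kronecker(crossprod(P), crossprod(D)) + diag(lambda, Q * S)
  matrix(solve(K, as.vector(crossprod(D, Y %*% P))), Q, S)
}

# A small full cohort for end-to-end stages.
small_cohort <- function(seed = 1, ...) {
  make_cohort(simulation_config(n_genes = 200, n_samples = 40, n_tfs = 8,
                                n_features = 5, n_alterations = 4,
                                alteration_frequency = 0.4, seed = seed, ...))
}
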