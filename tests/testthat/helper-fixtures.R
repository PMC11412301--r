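# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

fixture_ref <- function() {
  participant_reference(mvt_ef = 48.7, mvt_sabd = 54.5,
                        mvc_emg_peak = rep(4, 8), emg_scale = rep(0.6, 8))
}

# Two-participant cohort at generator defaults, with EMG.
shared_cohort <- function() {
  memo("cohort", generate_cohort(generator_config(n_participants = 2,
                                                  seed = 101)))
}

shared_features <- function() {
  memo("features", features_table(shared_cohort()))
}

# Normalized activity matrices and selected synergy models per participant.
shared_models <- function() {
  memo("models", {
    f <- shared_features()
    out <- list()
    for (pid in unique(f$participant)) {
      am <- normalize_matrix(assemble_matrix(f[f$participant == pid, ]))
      out[[pid]] <- select_synergy_count(am, seed = 7)
    }
    out
  })
}

shared_matrices <- function() {
  memo("matrices", {
    f <- shared_features()
    lapply(split(f, f$participant), function(pf) {
      normalize_matrix(assemble_matrix(pf))
    })
  })
}

# Ground-truth synergy columns as seen by the decomposition: generator W
# mapped through MVC normalization and the recorded row scaling, columns
# unit-normed.
truth_in_normalized_space <- function(ref, row_scale,
                                      W = default_ground_truth_W()) {
  Wn <- W * (100 / ref$mvc_emg_peak) * row_scale
  sweep(Wn, 2, sqrt(colSums(Wn^2)), "/")
}

# Best-cosine column matching between two unit-norm column sets.
best_cosines <- function(W_est, W_true) {
  S <- crossprod(W_est, W_true)
  apply(S, 2, max)
}

# Independent brute-force Spearman oracle: enumerate all permutations via
# expand.grid filtering, compute rho with stats::cor(method = "spearman").
brute_spearman_p <- function(x, y) {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1, function(r) length(unique(r)) == n), ,
                drop = FALSE]
  obs <- stats::cor(x, y, method = "spearman")
  rhos <- apply(perms, 1, function(p)
    stats::cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}
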