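# Synergy pipeline: matrix assembly and normalization, NMF against an
# independent oracle, VAF selection, the random-similarity threshold, and
# cross-participant matching.

test_that("a complete participant yields a deterministic 8 x 48 matrix", {
  f <- shared_features()
  pf <- f[f$participant == "P01", ]
  am1 <- assemble_matrix(pf)
  am2 <- assemble_matrix(pf[sample(nrow(pf)), ])   # row order irrelevant
  expect_identical(dim(am1$values), c(8L, 48L))
  expect_identical(am1$values, am2$values)
  expect_identical(nrow(am1$column_labels), 48L)
  # column order: load ascending, trial ascending, reference then match
  expect_identical(am1$column_labels$load[1:2], c(0.1, 0.1))
  expect_identical(am1$column_labels$phase[1:2], c("reference", "match"))
  expect_true(all(diff(order(am1$column_labels$load)) > 0) ||
                !is.unsorted(am1$column_labels$load))
  expect_true(all(am1$values >= 0))
})

test_that("strict assembly rejects incomplete load blocks, naming the cell", {
  f <- shared_features()
  pf <- f[f$participant == "P01", ]
  pf$valid[pf$load == 0.3 & pf$trial == 5] <- FALSE
  expect_error(assemble_matrix(pf), "load=0.3")
  lenient <- assemble_matrix(pf, strict = FALSE)
  expect_identical(ncol(lenient$values), 32L)   # the 0.3 block dropped
})

test_that("two-stage normalization: row max 1, then unit sample variance", {
  A <- matrix(c(2, 4, 1, 3,
                1, 1, 5, 2), 2, 4, byrow = TRUE)
  st1 <- normalize_matrix(A, variance = FALSE)
  expect_equal(unname(apply(st1$values, 1, max)), c(1, 1))
  expect_equal(st1$values[1, 1:2], c(0.5, 1))
  full <- normalize_matrix(A)
  expect_equal(unname(apply(full$values, 1, stats::sd)), c(1, 1),
               tolerance = 1e-9)
  # recorded row scales invert the normalization
  expect_equal(full$values / full$row_scale, A, tolerance = 1e-9,
               ignore_attr = TRUE)
  # full normalization is idempotent
  twice <- normalize_matrix(full$values)
  expect_equal(twice$values, full$values, tolerance = 1e-12)
  expect_error(normalize_matrix(rbind(c(0, 0, 0), c(1, 2, 3))), "all-zero")
  expect_error(normalize_matrix(rbind(c(2, 2, 2), c(1, 2, 3))),
               "zero-variance")
})

test_that("NMF factors an exact low-rank product and is seed-deterministic", {
  set.seed(1)
  w <- abs(rnorm(8)); h <- abs(rnorm(12))
  A <- outer(w, h)
  fit <- nmf_decompose(A, 1, seed = 3)
  expect_gt(compute_vaf(A, fit$W, fit$H), 1 - 1e-6)
  expect_equal(sqrt(sum(fit$W^2)), 1, tolerance = 1e-9)  # unit-norm column
  fit2 <- nmf_decompose(A, 1, seed = 3)
  expect_identical(fit, fit2)
  expect_error(nmf_decompose(A - 1, 1), "nonnegative")
  expect_error(nmf_decompose(A, 9), "between")
})

test_that("NMF matches an independent alternating-NNLS oracle", {
  skip_if_not_installed("pracma")
  als_nmf <- function(A, n, seed, iters = 200) {
    set.seed(seed)
    best <- Inf
    for (r in 1:5) {
      W <- matrix(runif(nrow(A) * n), nrow(A), n)
      for (it in seq_len(iters)) {
        H <- apply(A, 2, function(col) pracma::lsqnonneg(W, col)$x)
        H <- matrix(H, n, ncol(A))
        W <- t(apply(A, 1, function(row) pracma::lsqnonneg(t(H), row)$x))
        W <- matrix(W, nrow(A), n)
      }
      best <- min(best, sum((A - W %*% H)^2))
    }
    best
  }
  set.seed(11)
  A <- matrix(runif(24), 4, 6)
  fit <- nmf_decompose(A, 2, seed = 5, restarts = 20)
  oracle_err <- als_nmf(A, 2, seed = 99, iters = 60)
  expect_lte(fit$objective, oracle_err * 1.01 + 1e-12)
})

test_that("VAF follows its Frobenius definition", {
  A <- diag(2)
  WH_half <- list(W = matrix(c(1, 0), 2, 1), H = matrix(c(1, 0), 1, 2))
  expect_equal(compute_vaf(A, WH_half$W, WH_half$H), 0.5)
  expect_equal(compute_vaf(A, diag(2), diag(2)), 1.0)
  expect_equal(compute_vaf(A, matrix(0, 2, 1), matrix(0, 1, 2)), 0.0)
  expect_error(compute_vaf(matrix(0, 2, 2), diag(2), diag(2)), "zero norm")
  expect_error(compute_vaf(A, matrix(1, 3, 1), matrix(1, 1, 2)), "conform")
})

test_that("minimal-count selection finds the constructed synergy number", {
  set.seed(21)
  W_true <- default_ground_truth_W()
  # activation drives with the protocol's structure: near-unity elbow drive
  # with trial-to-trial gain variability and a load-biased match phase;
  # load-scaled shoulder drive in the reference phase, near zero in match
  load_pat <- rep(c(0.1, 0.3, 0.5), each = 16)
  phase_ref <- rep(rep(c(TRUE, FALSE), 8), 3)
  h1 <- rlnorm(48, 0, 0.15) *
    ifelse(phase_ref, 1, rep(c(1.01, 1.16, 1.32), each = 16))
  h2 <- ifelse(phase_ref, load_pat, 0.03) * rlnorm(48, 0, 0.15)
  # row-normalized as in the pipeline before decomposition
  A <- normalize_matrix(W_true %*% rbind(h1, h2))
  m <- select_synergy_count(A, seed = 9, restarts = 10)
  expect_identical(m$n, 2L)
  expect_gt(m$vaf, 1 - 1e-6)
  expect_lt(m$vaf_curve[1], 0.95)   # one synergy is not enough
  expect_true(m$threshold_reached)
  # degenerate threshold: one synergy always suffices
  m0 <- select_synergy_count(A, vaf_threshold = 0, seed = 9, restarts = 3)
  expect_identical(m0$n, 1L)
  # VAF curve is non-decreasing within restart tolerance
  expect_true(all(diff(m$vaf_curve) > -1e-3))
})

test_that("synergy vectors are recovered under rectified Gaussian noise", {
  set.seed(31)
  W_true <- default_ground_truth_W()
  W_true <- sweep(W_true, 2, sqrt(colSums(W_true^2)), "/")
  H_true <- matrix(runif(2 * 48, 0.2, 1), 2, 48)
  S <- W_true %*% H_true
  A <- S + abs(matrix(rnorm(8 * 48, 0, 0.05 * mean(S)), 8, 48))
  fit <- nmf_decompose(A, 2, seed = 13)
  expect_true(all(best_cosines(fit$W, W_true) >= 0.9))
})

test_that("random-synergy threshold reproduces the 10^6-pair construction", {
  th <- random_synergy_threshold(dim = 8, n_random = 1000, seed = 5)
  expect_identical(attr(th, "n_values"), 1000000L)
  expect_gt(as.numeric(th), 0)
  expect_lte(as.numeric(th), 1)
  # percentile ordering: the 95th percentile exceeds the median
  med <- random_synergy_threshold(dim = 8, n_random = 1000, percentile = 50,
                                  seed = 5)
  expect_gt(as.numeric(th), as.numeric(med))
  # stability across seeds
  ths <- vapply(1:3, function(s)
    as.numeric(random_synergy_threshold(dim = 8, n_random = 2000, seed = s)),
    numeric(1))
  expect_lt(diff(range(ths)), 0.01)
  # independent Monte Carlo oracle on freshly drawn pairs
  set.seed(123)
  u <- matrix(runif(8 * 4e4), 8); u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  v <- matrix(runif(8 * 4e4), 8); v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  mc <- unname(stats::quantile(colSums(u * v), 0.95))
  expect_lt(abs(as.numeric(th) - mc), 0.01)
  # excluding self-pairs shrinks the distribution by n_random values
  th2 <- random_synergy_threshold(dim = 8, n_random = 1000, seed = 5,
                                  include_self = FALSE)
  expect_identical(attr(th2, "n_values"), 999000L)
  expect_error(random_synergy_threshold(dim = 1), ">= 2")
})

test_that("matching is permutation-invariant and respects the threshold", {
  W <- default_ground_truth_W()
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  H <- matrix(runif(2 * 48), 2, 48)
  model <- function(W, H) {
    structure(list(W = W, H = H, n = ncol(W)), class = "synergy_model")
  }
  models <- list(P01 = model(W, H),
                 P02 = model(W[, 2:1], H[2:1, ]),   # permuted copy
                 P03 = model(W, H))
  g <- match_synergies(models, threshold = 0.9, reference = "P01")
  expect_identical(unname(g$n_matched), c(3L, 3L))
  expect_equal(g$mean_W, W, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(g$matches$P02, c(2L, 1L))

  # orthogonal synergies stay unmatched and are excluded from the means
  W_orth <- diag(8)[, 7:8]
  models$P04 <- model(W_orth, H)
  g2 <- match_synergies(models, threshold = 0.9, reference = "P01")
  expect_true(all(is.na(g2$matches$P04)))
  expect_equal(g2$mean_W, W, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(match_synergies(models, 0.9, "P99"), "not found")
  # exhaustive assignment agrees with greedy on this clean case
  g3 <- match_synergies(models, threshold = 0.9, reference = "P01",
                        method = "optimal")
  expect_identical(g3$matches$P02, g$matches$P02)
})

test_that("cohort synergies are shared and align with the generator's ground truth", {
  models <- shared_models()
  mats <- shared_matrices()
  coh <- shared_cohort()
  th <- random_synergy_threshold(seed = 42)
  g <- match_synergies(models, th, reference = "P01")
  # every participant's synergies match the reference pair one-to-one
  for (pid in setdiff(names(models), "P01")) {
    expect_identical(sort(g$matches[[pid]]), 1:2)
  }
  # matched means vs the ground truth mapped through the reference
  # participant's MVC and row scaling; the analyzed segments never contain
  # shoulder activity without concurrent elbow activity, so the shoulder
  # synergy is only partially identifiable (it carries a small elbow-muscle
  # component) while the elbow synergy, which appears nearly alone in the
  # match phase, aligns beyond the chance-similarity threshold
  truth <- truth_in_normalized_space(coh$P01$reference,
                                     mats$P01$row_scale)
  mw <- sweep(g$mean_W, 2, sqrt(colSums(g$mean_W^2)), "/")
  S <- crossprod(mw, truth)
  assign_elbow <- which.max(S[, 1])
  assign_shoulder <- which.max(S[, 2])
  expect_true(assign_elbow != assign_shoulder)   # unambiguous 1:1 assignment
  expect_gte(S[assign_elbow, 1], as.numeric(th))
  expect_gte(S[assign_shoulder, 2], 0.8)
})
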