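# Muscle-synergy pipeline: activity-matrix assembly and two-stage
# normalization, nonnegative matrix factorization by multiplicative updates,
# VAF-based selection of the synergy count, a random-synergy similarity
# threshold, and cross-participant synergy matching.

#' Assemble a participant's muscle-activity matrix
#'
#' Builds the `8 muscles x 48 data points` matrix (two phases x eight
#' analyzed trials x three loads) of mean percent-MVC envelopes from a
#' per-trial feature table. Column order is deterministic: load ascending,
#' trial ascending, phase reference-then-match.
#'
#' @param features Feature table rows for one participant (see
#'   [features_table()]); only valid trials are used.
#' @param trials_per_load Analyzed trials required per load.
#' @param strict Error when any (load, trial) cell is missing; otherwise the
#'   matrix is built from whatever complete trials exist.
#' @return Object of class `"activity_matrix"`: `values` (8 x columns),
#'   `column_labels` (`data.frame` of load, trial, phase), `row_scale`
#'   (per-row scale factors applied so far, initially 1).
#' @export
assemble_matrix <- function(features, trials_per_load = 8L, strict = TRUE) {
  if (length(unique(features$participant)) != 1L) {
    stop("`features` must contain exactly one participant", call. = FALSE)
  }
  f <- features[features$valid, , drop = FALSE]
  loads <- sort(unique(features$load))
  ref_cols <- paste0("emg_", muscle_names(), "_ref")
  match_cols <- paste0("emg_", muscle_names(), "_match")

  cols <- list()
  labels <- list()
  missing_cells <- character(0)
  for (ld in loads) {
    fl <- f[f$load == ld, , drop = FALSE]
    fl <- fl[order(fl$trial), , drop = FALSE]
    if (nrow(fl) < trials_per_load) {
      have <- fl$trial
      missing_cells <- c(missing_cells,
                         sprintf("load=%g: %d of %d valid trials (have: %s)",
                                 ld, nrow(fl), trials_per_load,
                                 paste(have, collapse = ",")))
      next
    }
    fl <- fl[seq_len(trials_per_load), , drop = FALSE]
    for (i in seq_len(trials_per_load)) {
      for (ph in c("reference", "match")) {
        v <- as.numeric(fl[i, if (ph == "reference") ref_cols else match_cols])
        cols[[length(cols) + 1L]] <- v
        labels[[length(labels) + 1L]] <-
          data.frame(load = ld, trial = fl$trial[i], phase = ph,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(missing_cells) && strict) {
    stop("incomplete activity matrix: ",
         paste(missing_cells, collapse = "; "), call. = FALSE)
  }
  if (!length(cols)) stop("no complete load blocks available", call. = FALSE)
  A <- do.call(cbind, cols)
  rownames(A) <- muscle_names()
  out <- list(values = A, column_labels = do.call(rbind, labels),
              row_scale = setNames(rep(1, 8), muscle_names()),
              participant = features$participant[1])
  class(out) <- "activity_matrix"
  out
}

#' Two-stage row normalization of an activity matrix
#'
#' Stage 1 divides each muscle's row by its maximum across all columns
#' (values then span 0 to 1); stage 2 divides each row by its sample SD so
#' every row has unit variance. The combined per-row factors are recorded in
#' `row_scale` so the scaling can be inverted.
#'
#' @param A An `"activity_matrix"` (or plain nonnegative matrix).
#' @param variance Apply the unit-variance stage (stage 2).
#' @return The normalized `"activity_matrix"`.
#' @export
normalize_matrix <- function(A, variance = TRUE) {
  am <- as_activity_matrix(A)
  vals <- am$values
  rmax <- apply(vals, 1, max)
  if (any(rmax <= 0)) {
    stop("all-zero row(s): ", paste(rownames(vals)[rmax <= 0], collapse = ", "),
         call. = FALSE)
  }
  vals <- vals / rmax
  scale <- 1 / rmax
  if (variance) {
    rsd <- apply(vals, 1, stats::sd)
    if (any(rsd <= 0)) {
      stop("zero-variance row(s): ",
           paste(rownames(vals)[rsd <= 0], collapse = ", "), call. = FALSE)
    }
    vals <- vals / rsd
    scale <- scale / rsd
  }
  am$values <- vals
  am$row_scale <- am$row_scale * scale
  am
}

as_activity_matrix <- function(A) {
  if (inherits(A, "activity_matrix")) return(A)
  if (!is.matrix(A) || any(A < 0)) {
    stop("`A` must be a nonnegative matrix", call. = FALSE)
  }
  out <- list(values = A,
              column_labels = data.frame(column = seq_len(ncol(A))),
              row_scale = rep(1, nrow(A)), participant = NA_character_)
  class(out) <- "activity_matrix"
  out
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius reconstruction error `||A - WH||_F^2`
#' under elementwise nonnegativity using the classical multiplicative update
#' rules, keeping the best of `restarts` seeded random initializations.
#' Synergy vectors (columns of `W`) are normalized to unit Euclidean norm on
#' return, with the compensating scale absorbed into `H`.
#'
#' @param A Nonnegative matrix (or `"activity_matrix"`).
#' @param n Number of synergies, between 1 and `nrow(A)`.
#' @param seed Integer seed controlling the initializations.
#' @param restarts Number of random restarts.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Convergence tolerance on the relative objective decrease.
#' @return List with `W` (`m x n`, unit-norm columns), `H` (`n x ncol(A)`),
#'   `objective` (final squared Frobenius error), `converged`, `n`, `seed`.
#' @export
nmf_decompose <- function(A, n, seed = 1L, restarts = 20L,
                          max_iter = 2000L, tol = 1e-6) {
  if (inherits(A, "activity_matrix")) A <- A$values
  if (!is.matrix(A) || any(A < 0)) {
    stop("`A` must be elementwise nonnegative", call. = FALSE)
  }
  if (n < 1 || n > nrow(A)) {
    stop("`n` must lie between 1 and nrow(A)", call. = FALSE)
  }
  eps <- .Machine$double.eps
  m <- nrow(A); p <- ncol(A)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      W <- matrix(runif(m * n, 0.1, 1), m, n) * sqrt(mean(A) / n + eps)
      H <- matrix(runif(n * p, 0.1, 1), n, p) * sqrt(mean(A) / n + eps)
      obj <- sum((A - W %*% H)^2)
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, A)) / (crossprod(W, W %*% H) + eps)
        W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
        new_obj <- sum((A - W %*% H)^2)
        if (obj - new_obj <= tol * max(obj, eps)) {
          obj <- new_obj
          converged <- TRUE
          break
        }
        obj <- new_obj
      }
      if (is.null(best) || obj < best$objective) {
        best <- list(W = W, H = H, objective = obj, converged = converged)
      }
    }
  })
  nrm <- sqrt(colSums(best$W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(best$W, 2, nrm, "/")
  H <- sweep(best$H, 1, nrm, "*")
  rownames(W) <- rownames(A)
  list(W = W, H = H, objective = best$objective,
       converged = best$converged, n = as.integer(n), seed = as.integer(seed))
}

#' Variance accounted for by a factorization
#'
#' Uncentered by default: `1 - ||A - WH||_F^2 / ||A||_F^2`, the dominant
#' convention in the synergy literature. `centered = TRUE` instead scales the
#' residual by the total variance about the grand mean, as a sensitivity
#' variant.
#'
#' @param A Nonnegative data matrix (or `"activity_matrix"`).
#' @param W,H Factor matrices with conforming shapes.
#' @param centered Use the grand-mean-centered denominator.
#' @return VAF as a fraction.
#' @export
compute_vaf <- function(A, W, H, centered = FALSE) {
  if (inherits(A, "activity_matrix")) A <- A$values
  if (ncol(W) != nrow(H) || nrow(W) != nrow(A) || ncol(H) != ncol(A)) {
    stop("shapes of `A`, `W`, `H` do not conform", call. = FALSE)
  }
  denom <- if (centered) sum((A - mean(A))^2) else sum(A^2)
  if (denom <= 0) stop("`A` has zero norm", call. = FALSE)
  1 - sum((A - W %*% H)^2) / denom
}

#' Select the synergy count by the minimal-VAF rule
#'
#' Fits factorizations with 1 to `nrow(A)` synergies and returns the model
#' with the smallest count whose VAF reaches `vaf_threshold` (95% by
#' default). If no count reaches the threshold the largest model is returned
#' with `threshold_reached = FALSE`.
#'
#' @param A Normalized activity matrix (or plain nonnegative matrix).
#' @param vaf_threshold Required VAF, fraction.
#' @param seed,restarts,max_iter,tol Passed to [nmf_decompose()].
#' @param centered Passed to [compute_vaf()].
#' @return Object of class `"synergy_model"`: the selected `W`, `H`, `n`,
#'   `vaf`, the full `vaf_curve` over all candidate counts,
#'   `threshold_reached`, `converged`, `seed`, `participant`.
#' @export
select_synergy_count <- function(A, vaf_threshold = 0.95, seed = 1L,
                                 restarts = 20L, max_iter = 2000L,
                                 tol = 1e-6, centered = FALSE) {
  am <- as_activity_matrix(A)
  m <- nrow(am$values)
  fits <- vector("list", m)
  vaf_curve <- numeric(m)
  for (n in seq_len(m)) {
    fits[[n]] <- nmf_decompose(am$values, n, seed = seed, restarts = restarts,
                               max_iter = max_iter, tol = tol)
    vaf_curve[n] <- compute_vaf(am$values, fits[[n]]$W, fits[[n]]$H,
                                centered = centered)
  }
  sel <- which(vaf_curve >= vaf_threshold)
  reached <- length(sel) > 0L
  n_sel <- if (reached) min(sel) else m
  fit <- fits[[n_sel]]
  out <- list(W = fit$W, H = fit$H, n = n_sel, vaf = vaf_curve[n_sel],
              vaf_curve = vaf_curve, threshold_reached = reached,
              converged = fit$converged, seed = as.integer(seed),
              participant = am$participant)
  class(out) <- "synergy_model"
  out
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> %s: n = %d, VAF = %.1f%%%s\n",
              if (is.na(x$participant)) "" else x$participant, x$n,
              100 * x$vaf,
              if (x$threshold_reached) "" else " (threshold not reached)"))
  cat("  VAF curve:", paste(sprintf("%.3f", x$vaf_curve), collapse = " "), "\n")
  invisible(x)
}

#' Similarity threshold from randomly generated synergies
#'
#' Draws `n_random` random nonnegative unit-norm vectors (coordinates
#' Uniform(0,1), then scaled to unit Euclidean norm), forms all
#' `n_random^2` ordered pairwise scalar products (including self-pairs, so
#' 10^6 values at the default 1000), and returns the requested percentile.
#' Two fitted synergies with a scalar product above this threshold are more
#' similar than chance at the corresponding level.
#'
#' @param dim Synergy vector dimension (number of muscles).
#' @param n_random Number of random synergies.
#' @param percentile Percentile of the scalar-product distribution, 0-100.
#' @param seed Integer seed.
#' @param include_self Include self-pairs (scalar product 1), reproducing the
#'   `n_random^2` count; set `FALSE` for sensitivity analysis.
#' @return The threshold (scalar in (0, 1]), with attribute `n_values` giving
#'   the size of the distribution used.
#' @export
random_synergy_threshold <- function(dim = 8L, n_random = 1000L,
                                     percentile = 95, seed = 1L,
                                     include_self = TRUE) {
  if (dim < 2 || n_random < 2) {
    stop("`dim` and `n_random` must both be >= 2", call. = FALSE)
  }
  with_seed(seed, {
    X <- matrix(runif(dim * n_random), dim, n_random)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    G <- crossprod(X)
    vals <- as.vector(G)
    if (!include_self) vals <- as.vector(G)[as.vector(row(G) != col(G))]
    th <- unname(stats::quantile(vals, percentile / 100))
    attr(th, "n_values") <- length(vals)
    th
  })
}

#' Match synergies across participants against a reference participant
#'
#' For each non-reference participant, pairs its synergy vectors with the
#' reference participant's by greedy best-first assignment on the scalar
#' product (cosine, since vectors are unit-norm), accepting pairs at or above
#' `threshold`; each reference synergy is used at most once per participant.
#' Group-mean synergy vectors and activation coefficients are averaged over
#' the matched sets (reference included).
#'
#' @param models Named list of `"synergy_model"` objects, one per
#'   participant.
#' @param threshold Similarity acceptance threshold, from
#'   [random_synergy_threshold()].
#' @param reference Name of the reference participant in `models`.
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive assignment
#'   maximizing total accepted similarity; feasible for <= 8 synergies).
#' @return Object of class `"group_synergy_result"`: `threshold`,
#'   `reference_participant`, `matches` (per participant, an integer vector
#'   mapping its synergy index to a reference synergy index or `NA`),
#'   `mean_W`, `mean_H`, `n_matched` per reference synergy.
#' @export
match_synergies <- function(models, threshold, reference,
                            method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!reference %in% names(models)) {
    stop("`reference` participant not found in `models`", call. = FALSE)
  }
  ref_W <- models[[reference]]$W
  n_ref <- ncol(ref_W)
  matches <- list()
  w_acc <- lapply(seq_len(n_ref), function(j) list(ref_W[, j]))
  h_acc <- lapply(seq_len(n_ref), function(j) list(models[[reference]]$H[j, ]))

  for (pid in setdiff(names(models), reference)) {
    W <- models[[pid]]$W
    S <- crossprod(W, ref_W)                      # n_p x n_ref cosines
    assign_p <- rep(NA_integer_, ncol(W))
    if (method == "greedy") {
      S_work <- S
      repeat {
        best <- which(S_work == max(S_work), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(S_work[best[1], best[2]]) ||
            S_work[best[1], best[2]] < threshold) break
        assign_p[best[1]] <- best[2]
        S_work[best[1], ] <- -Inf
        S_work[, best[2]] <- -Inf
        if (all(!is.finite(S_work))) break
      }
    } else {
      assign_p <- optimal_assignment(S, threshold)
    }
    matches[[pid]] <- assign_p
    for (i in seq_along(assign_p)) {
      j <- assign_p[i]
      if (!is.na(j)) {
        w_acc[[j]] <- c(w_acc[[j]], list(W[, i]))
        h_acc[[j]] <- c(h_acc[[j]], list(models[[pid]]$H[i, ]))
      }
    }
  }
  mean_W <- sapply(w_acc, function(v) rowMeans(do.call(cbind, v)))
  rownames(mean_W) <- rownames(ref_W)
  mean_H <- t(sapply(h_acc, function(v) colMeans(do.call(rbind, v))))
  out <- list(threshold = as.numeric(threshold),
              reference_participant = reference, matches = matches,
              mean_W = mean_W, mean_H = mean_H,
              n_matched = vapply(w_acc, length, integer(1)))
  class(out) <- "group_synergy_result"
  out
}

# Exhaustive assignment of participant synergies (rows of S) to reference
# synergies (columns), maximizing total similarity over accepted pairs.
optimal_assignment <- function(S, threshold) {
  np <- nrow(S); nr <- ncol(S)
  best_score <- -Inf
  best_assign <- rep(NA_integer_, np)
  cols <- c(seq_len(nr), rep(NA_integer_, max(0, np - nr)))
  perms <- permutations_of(length(cols))
  for (r in seq_len(nrow(perms))) {
    assign_p <- cols[perms[r, ]][seq_len(np)]
    score <- 0
    ok_assign <- assign_p
    for (i in seq_len(np)) {
      j <- assign_p[i]
      if (!is.na(j)) {
        if (S[i, j] >= threshold) score <- score + S[i, j]
        else ok_assign[i] <- NA_integer_
      }
    }
    if (score > best_score) {
      best_score <- score
      best_assign <- ok_assign
    }
  }
  best_assign
}

#' @export
print.group_synergy_result <- function(x, ...) {
  cat(sprintf("<group_synergy_result> reference %s, threshold %.3f\n",
              x$reference_participant, x$threshold))
  cat("  matched per reference synergy:",
      paste(x$n_matched, collapse = " "), "\n")
  invisible(x)
}
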