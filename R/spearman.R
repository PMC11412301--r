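# Spearman rank correlation with exact small-sample permutation p-values,
# and the per-participant, per-load correlation grid between torque-
# generation features and the matching error.

# All permutations of 1..n as an (n! x n) integer matrix; cached per n.
.perm_cache <- new.env(parent = emptyenv())
permutations_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      sub <- rec(v[-i])
      out[[i]] <- cbind(v[i], sub)
    }
    do.call(rbind, out)
  }
  res <- rec(seq_len(n))
  .perm_cache[[key]] <- res
  res
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties). The two-sided p-value is exact for `n <= exact_max`: the fraction
#' of all `n!` permutations of one variable whose |rho| reaches the observed
#' |rho|. For larger `n` the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @param exact_max Largest `n` for which the exact permutation p is
#'   computed.
#' @return List with `rho`, `p_value`, `n`, `method` (`"exact"` or
#'   `"t-approximation"`). `rho` and `p_value` are `NA` (with method
#'   `"undefined"`) when either input is constant.
#' @export
spearman <- function(x, y, exact_max = 8L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported",
                                 call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    # rho for each permutation of ry against fixed rx, via the Pearson form
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(p, 1)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Correlate torque-generation features with the matching error
#'
#' For each participant-by-load cell, Spearman correlations of the
#' force-steadiness CV, flexor-extensor coactivation, and stabilization time
#' against the per-trial matching error, over valid trials.
#'
#' @param features Feature table from [features_table()].
#' @param min_trials Minimum valid trials per cell; smaller cells are
#'   skipped.
#' @return `data.frame` with columns `participant`, `load`, `feature`,
#'   `rho`, `p_value`, `n`, `method`.
#' @export
correlate_features <- function(features, min_trials = 3L) {
  f <- features[features$valid & is.finite(features$tau_err), , drop = FALSE]
  cells <- unique(f[, c("participant", "load")])
  cells <- cells[order(cells$participant, cells$load), , drop = FALSE]
  feats <- c("cv", "coactivation", "t_ref")
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- f[f$participant == cells$participant[i] &
               f$load == cells$load[i], , drop = FALSE]
    for (fe in feats) {
      xv <- sub[[fe]]
      yv <- sub$tau_err
      keep <- is.finite(xv) & is.finite(yv)
      if (sum(keep) < min_trials) next
      res <- spearman(xv[keep], yv[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        participant = cells$participant[i], load = cells$load[i],
        feature = fe, rho = res$rho, p_value = res$p_value, n = res$n,
        method = res$method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
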