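# Perceptual outcomes of torque matching: constant error (accuracy) and
# variable error (precision) of the reproduced elbow torque.

#' Constant error of torque matching
#'
#' Mean of the signed matching errors (match minus reference torque) across
#' testing trials. Positive values indicate overestimation of the reference
#' torque when matching; negative values underestimation.
#'
#' @param errors Numeric vector of per-trial matching errors, Nm.
#' @return CE in Nm.
#' @export
compute_ce <- function(errors) {
  if (length(errors) < 1L || anyNA(errors)) {
    stop("`errors` must contain at least one non-missing value", call. = FALSE)
  }
  mean(errors)
}

#' Variable error of torque matching
#'
#' Sample standard deviation of the signed matching errors across testing
#' trials; a small VE means the participant reproduced similar torques from
#' trial to trial.
#'
#' @param errors Numeric vector of per-trial matching errors, Nm; at least 2.
#' @return VE in Nm.
#' @export
compute_ve <- function(errors) {
  if (length(errors) < 2L || anyNA(errors)) {
    stop("`errors` must contain at least two non-missing values",
         call. = FALSE)
  }
  stats::sd(errors)
}

#' Per-participant, per-load perceptual outcomes
#'
#' Computes CE and VE over the valid (non-practice, rule-passing) trials of
#' each participant-by-load cell of a feature table.
#'
#' @param features Feature table from [features_table()].
#' @return `data.frame` with columns `participant`, `load`, `ce_nm`, `ve_nm`,
#'   `n_trials` (VE is `NA` when fewer than 2 valid trials).
#' @export
perception_outcomes <- function(features) {
  f <- features[features$valid & is.finite(features$tau_err), , drop = FALSE]
  cells <- unique(f[, c("participant", "load")])
  cells <- cells[order(cells$participant, cells$load), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    e <- f$tau_err[f$participant == cells$participant[i] &
                     f$load == cells$load[i]]
    data.frame(participant = cells$participant[i], load = cells$load[i],
               ce_nm = compute_ce(e),
               ve_nm = if (length(e) >= 2) compute_ve(e) else NA_real_,
               n_trials = length(e), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
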