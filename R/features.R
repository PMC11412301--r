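# Per-trial torque-generation features and trial-validity rules.
#
# Segment conventions: half-open windows [start, end), mapped to sample
# indices by flooring start*fs; the reference window is the 0.5 s after the
# reference-phase "hold" cue, the match window is 0.25 s either side of the
# match-phase "hold" cue.

# Cue time by name, NA when the event is absent.
event_time <- function(trial, name) {
  if (name %in% names(trial$events)) trial$events[[name]] else NA_real_
}

# Half-open window [t0, t0 + width) as 1-based sample indices, or NULL if it
# does not fit inside a series of length n.
segment_indices <- function(t0, width, sample_rate, n) {
  if (is.na(t0) || t0 < 0) return(NULL)
  i0 <- floor(t0 * sample_rate)                      # 0-based first sample
  len <- as.integer(round(width * sample_rate))
  if (i0 < 0 || i0 + len > n) return(NULL)
  seq.int(i0 + 1L, i0 + len)
}

#' Extract the reference-phase analysis segment
#'
#' The 0.5 s of data starting at the reference-phase "hold" cue, during which
#' the participant holds the memorized elbow torque. Used for the reference
#' torque, the force-steadiness CV, coactivation, and the synergy matrix.
#'
#' @param trial A `trial_recording`.
#' @param width Segment width, s.
#' @return List with `idx` (sample indices), `elbow`, `shoulder` (torque
#'   segments), or `NULL` if the `hold_ref` event is missing or the data are
#'   too short.
#' @export
extract_reference_segment <- function(trial, width = 0.5) {
  t0 <- event_time(trial, "hold_ref")
  if (is.na(t0)) return(NULL)
  idx <- segment_indices(t0, width, trial$sample_rate,
                         length(trial$elbow_torque))
  if (is.null(idx)) return(NULL)
  list(idx = idx, elbow = trial$elbow_torque[idx],
       shoulder = trial$shoulder_torque[idx])
}

#' Extract the match-phase analysis segment
#'
#' The 0.5 s window centered on the match-phase "hold" cue (0.25 s before to
#' 0.25 s after the participant indicated the torque was matched).
#'
#' @inheritParams extract_reference_segment
#' @param half Half-width of the window, s.
#' @return As [extract_reference_segment()], or `NULL` on insufficient
#'   margin.
#' @export
extract_match_segment <- function(trial, half = 0.25) {
  t0 <- event_time(trial, "hold_match")
  if (is.na(t0)) return(NULL)
  idx <- segment_indices(t0 - half, 2 * half, trial$sample_rate,
                         length(trial$elbow_torque))
  if (is.null(idx)) return(NULL)
  list(idx = idx, elbow = trial$elbow_torque[idx],
       shoulder = trial$shoulder_torque[idx])
}

#' Coefficient of variation of a held torque segment
#'
#' Sample SD divided by the mean, in percent. Undefined (NA) when the mean is
#' not strictly positive.
#'
#' @param segment Numeric torque segment, Nm.
#' @return CV in percent, or `NA_real_` if undefined.
#' @export
compute_cv <- function(segment) {
  m <- mean(segment)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(segment) / m * 100
}

#' Flexor-extensor coactivation index
#'
#' Triceps share of the summed normalized biceps and triceps activity:
#' `tri / (bic + tri) * 100`, in percent. Undefined when both are zero.
#'
#' @param mean_bic,mean_tri Mean normalized EMG (percent MVC) of biceps and
#'   triceps over the reference segment.
#' @return Coactivation in percent (0-100), or `NA_real_` if undefined.
#' @export
compute_coactivation <- function(mean_bic, mean_tri) {
  s <- mean_bic + mean_tri
  if (!is.finite(s) || s <= 0) return(NA_real_)
  mean_tri / s * 100
}

#' Time to stabilize the elbow torque
#'
#' Interval between the "in" cue (begin elbow flexion) and the
#' reference-phase "hold" cue (torque stabilized and memorized).
#'
#' @param trial A `trial_recording`.
#' @return T_ref in seconds, or `NA_real_` if either event is missing or the
#'   interval is not strictly positive.
#' @export
compute_tref <- function(trial) {
  t_in <- event_time(trial, "in")
  t_hold <- event_time(trial, "hold_ref")
  if (is.na(t_in) || is.na(t_hold)) return(NA_real_)
  d <- t_hold - t_in
  if (d <= 0) NA_real_ else d
}

#' Trial validity per the acquisition rules
#'
#' A trial is excluded when it is a practice trial, when the match-phase
#' shoulder torque reaches 10% of MVT_SABD (such trials were restarted during
#' acquisition), or when a required cue event / analysis segment is missing.
#'
#' @param trial A `trial_recording`.
#' @param ref The matching [participant_reference()].
#' @return List with `valid` (flag) and `reasons` (character vector, empty
#'   when valid).
#' @export
validate_trial <- function(trial, ref) {
  reasons <- character(0)
  if (isTRUE(trial$is_practice)) reasons <- c(reasons, "practice")
  req <- c("up", "in", "hold_ref", "relax_ref", "match", "hold_match",
           "relax_end")
  missing_ev <- setdiff(req, names(trial$events))
  if (length(missing_ev)) {
    reasons <- c(reasons, paste0("missing_event:", missing_ev))
  }
  if (is.null(extract_reference_segment(trial))) {
    reasons <- c(reasons, "reference_segment")
  }
  if (is.null(extract_match_segment(trial))) {
    reasons <- c(reasons, "match_segment")
  }
  if (all(c("match", "relax_end") %in% names(trial$events))) {
    idx <- segment_indices(trial$events[["match"]],
                           trial$events[["relax_end"]] - trial$events[["match"]],
                           trial$sample_rate, length(trial$shoulder_torque))
    if (!is.null(idx) &&
        max(trial$shoulder_torque[idx]) >= 0.10 * ref$mvt_sabd) {
      reasons <- c(reasons, "shoulder_exceeded")
    }
  }
  if (is.na(compute_tref(trial))) reasons <- c(reasons, "tref_undefined")
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Per-trial feature extraction
#'
#' Computes the reference and match torques (segment means), the matching
#' error, force-steadiness CV, coactivation, stabilization time, per-muscle
#' mean normalized EMG in both phases, and the validity flag.
#'
#' @param trial A `trial_recording`.
#' @param ref The matching [participant_reference()].
#' @param envelopes Optional `n x 8` percent-MVC envelope matrix from
#'   [process_trial_emg()]; computed on the fly when `NULL` and the trial
#'   carries EMG.
#' @return One-row `data.frame` with columns `participant`, `load`, `trial`,
#'   `tau_reference`, `tau_match`, `tau_err`, `cv`, `coactivation`, `t_ref`,
#'   `shoulder_ref_mean`, `shoulder_match_max`, `valid`, `reasons`, and
#'   `emg_<muscle>_ref` / `emg_<muscle>_match` (percent MVC).
#' @export
trial_features <- function(trial, ref, envelopes = NULL) {
  val <- validate_trial(trial, ref)
  seg_r <- extract_reference_segment(trial)
  seg_m <- extract_match_segment(trial)
  tau_ref <- if (is.null(seg_r)) NA_real_ else mean(seg_r$elbow)
  tau_match <- if (is.null(seg_m)) NA_real_ else mean(seg_m$elbow)

  if (is.null(envelopes) && !is.null(trial$emg)) {
    envelopes <- process_trial_emg(trial, ref)
  }
  emg_ref <- emg_match <- rep(NA_real_, 8)
  if (!is.null(envelopes)) {
    if (!is.null(seg_r)) emg_ref <- colMeans(envelopes[seg_r$idx, , drop = FALSE])
    if (!is.null(seg_m)) emg_match <- colMeans(envelopes[seg_m$idx, , drop = FALSE])
  }

  out <- data.frame(
    participant = trial$participant_id, load = trial$load_condition,
    trial = trial$trial_index,
    tau_reference = tau_ref, tau_match = tau_match,
    tau_err = tau_match - tau_ref,
    cv = if (is.null(seg_r)) NA_real_ else compute_cv(seg_r$elbow),
    coactivation = compute_coactivation(emg_ref[1], emg_ref[2]),
    t_ref = compute_tref(trial),
    shoulder_ref_mean = if (is.null(seg_r)) NA_real_ else mean(seg_r$shoulder),
    shoulder_match_max = if (is.null(seg_m)) NA_real_ else max(seg_m$shoulder),
    valid = val$valid,
    reasons = paste(val$reasons, collapse = ";"),
    stringsAsFactors = FALSE
  )
  for (i in 1:8) {
    out[[paste0("emg_", muscle_names()[i], "_ref")]] <- emg_ref[i]
    out[[paste0("emg_", muscle_names()[i], "_match")]] <- emg_match[i]
  }
  out
}

#' Feature table for a whole cohort
#'
#' @param cohort A [generate_cohort()] result (or equivalently structured
#'   list).
#' @return `data.frame` with one row per trial, per [trial_features()].
#' @export
features_table <- function(cohort) {
  rows <- lapply(cohort, function(p) {
    do.call(rbind, lapply(p$trials, trial_features, ref = p$reference))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
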