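# Synthetic cohort generator for the two-phase torque-matching protocol.
#
# Each trial: "up" cue -> shoulder abduction ramp to the prescribed load ->
# "in" cue -> elbow flexion ramp, stabilization over T_ref -> "hold" cue,
# 1 s memorized hold -> "relax" -> 6 s gap -> "match" cue -> feedback-free
# reproduction -> "hold" -> 1 s hold -> "relax". EMG is synthesized as
# band-limited noise amplitude-modulated by a synergy-driven envelope
# W %*% h(t), plus 60 Hz line noise and a broadband noise floor.

#' Construct a participant reference record
#'
#' Holds the per-participant normalization constants: maximum voluntary
#' torques in elbow flexion (MVT_EF) and shoulder abduction (MVT_SABD), and
#' the peak processed EMG envelope per muscle from the maximum voluntary
#' contraction, used for MVC normalization.
#'
#' @param mvt_ef,mvt_sabd Maximum voluntary torques, Nm; strictly positive.
#' @param mvc_emg_peak Length-8 positive vector of peak MVC envelopes, in
#'   signal units, ordered per [muscle_names()].
#' @param emg_scale Optional length-8 positive vector of per-channel raw
#'   signal scales used by the generator (signal units per unit drive).
#' @return An object of class `"participant_reference"`.
#' @export
participant_reference <- function(mvt_ef, mvt_sabd, mvc_emg_peak,
                                  emg_scale = NULL) {
  stopifnot_scalar(mvt_ef, "mvt_ef", positive = TRUE)
  stopifnot_scalar(mvt_sabd, "mvt_sabd", positive = TRUE)
  if (length(mvc_emg_peak) != 8L || any(mvc_emg_peak <= 0)) {
    stop("`mvc_emg_peak` must be 8 strictly positive values", call. = FALSE)
  }
  out <- list(mvt_ef = mvt_ef, mvt_sabd = mvt_sabd,
              mvc_emg_peak = setNames(as.numeric(mvc_emg_peak), muscle_names()),
              emg_scale = if (is.null(emg_scale)) rep(1, 8)
                          else setNames(as.numeric(emg_scale), muscle_names()))
  class(out) <- "participant_reference"
  out
}

#' Generate one synthetic torque-matching trial
#'
#' Builds the full cue timeline, elbow and shoulder torque series, and
#' (optionally) eight channels of raw surface EMG for a single trial at a
#' given shoulder abduction load. The match-phase elbow torque level is the
#' achieved reference level plus `bias` plus Gaussian noise; the match-phase
#' shoulder torque is kept strictly below 10% MVT_SABD (trials violating that
#' bound would have been restarted during acquisition).
#'
#' @param ref A [participant_reference()].
#' @param load Shoulder abduction load as a fraction of MVT_SABD, in (0, 1).
#' @param bias Injected constant matching error, Nm.
#' @param seed Integer seed; equal seeds give identical trials.
#' @param config A [generator_config()] supplying protocol constants.
#' @param is_practice Flag the trial as practice (doubled motor noise;
#'   excluded from analysis by [validate_trial()]).
#' @param include_emg Synthesize raw EMG (set `FALSE` for torque-only
#'   simulations, e.g. large perceptual-recovery runs).
#' @param keep_truth Attach the programmed activations, envelopes and levels
#'   as `$truth` for generator-validation work.
#' @param participant_id,trial_index Labels stored in the recording.
#' @return An object of class `"trial_recording"`: torque series (Nm), an
#'   `n x 8` raw EMG matrix (or `NULL`), the cue-event map (s), and metadata.
#' @export
generate_trial <- function(ref, load, bias, seed,
                           config = generator_config(),
                           is_practice = FALSE, include_emg = TRUE,
                           keep_truth = FALSE,
                           participant_id = "P01", trial_index = 1L) {
  if (!is.numeric(load) || load <= 0 || load >= 1) {
    stop("`load` must lie in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    fs <- config$sample_rate
    li <- which.min(abs(config$loads - load))
    noise_mult <- if (is_practice) 2 else 1

    # cue timeline (s)
    t_up <- 0.5
    t_in <- t_up + 2.5
    t_ref_dur <- max(0.5, rnorm(1, config$tref_mean_per_load[li],
                                config$tref_sd_per_load[li]))
    t_hold_ref <- t_in + t_ref_dur
    t_relax_ref <- t_hold_ref + 1.0
    t_match <- t_relax_ref + 6.0
    t_match_dur <- max(1.0, rnorm(1, 3.0, 1.0))
    t_hold_match <- t_match + t_match_dur
    t_relax_end <- t_hold_match + 1.0
    duration <- t_relax_end + 0.5
    n <- as.integer(round(duration * fs))
    tt <- (seq_len(n) - 1) / fs

    # achieved torque levels: inside the +/- accept_band * MVT window
    draw_in_band <- function(target, band, sd) {
      repeat {
        x <- target + rnorm(1, 0, sd)
        if (abs(x - target) <= band) return(x)
      }
    }
    level_s <- draw_in_band(load * ref$mvt_sabd,
                            config$accept_band * ref$mvt_sabd,
                            0.015 * ref$mvt_sabd)
    target_e <- config$elbow_target * ref$mvt_ef
    level_e <- draw_in_band(target_e, config$accept_band * ref$mvt_ef,
                            0.010 * ref$mvt_ef)
    match_resid_s <- runif(1, 0.01, 0.06) * ref$mvt_sabd
    match_level <- max(0.05 * target_e,
                       level_e + bias + rnorm(1, 0, config$match_noise_sd * noise_mult))

    # noiseless torque profiles
    s_prof <- level_s * smoothstep(tt, t_up, t_up + 2.0) *
      (1 - smoothstep(tt, t_relax_ref, t_relax_ref + 1.5)) +
      match_resid_s * smoothstep(tt, t_match - 1.0, t_match) *
      (1 - smoothstep(tt, t_relax_end, t_relax_end + 0.5))
    e_prof <- level_e * smoothstep(tt, t_in, t_in + 0.8 * t_ref_dur) *
      (1 - smoothstep(tt, t_relax_ref, t_relax_ref + 1.0)) +
      match_level * smoothstep(tt, t_match, t_match + 0.7 * t_match_dur) *
      (1 - smoothstep(tt, t_relax_end, t_relax_end + 1.0))

    cv <- config$torque_hold_cv * noise_mult / 100
    shoulder <- s_prof + rnorm(n, 0, cv * s_prof)
    elbow <- e_prof + rnorm(n, 0, cv * e_prof)

    # enforce the acquisition rule: match-phase shoulder torque < 10% MVT_SABD
    in_match <- tt >= t_match & tt <= t_relax_end
    shoulder[in_match] <- pmin(shoulder[in_match], 0.095 * ref$mvt_sabd)

    events <- c(up = t_up, `in` = t_in, hold_ref = t_hold_ref,
                relax_ref = t_relax_ref, match = t_match,
                hold_match = t_hold_match, relax_end = t_relax_end)

    emg <- NULL
    truth <- NULL
    if (include_emg) {
      W <- config$ground_truth_W
      k <- ncol(W)
      # per-synergy, per-phase multiplicative neural-gain variability
      sdlog <- sqrt(log(1 + config$activation_gain_cv^2))
      gains <- matrix(rlnorm(2 * k, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = k, dimnames = list(NULL, c("ref", "match")))
      phase_col <- ifelse(tt < t_match, 1L, 2L)
      h_base <- rbind(e_prof / target_e, s_prof / ref$mvt_sabd)[seq_len(min(k, 2)), , drop = FALSE]
      if (k > 2) h_base <- rbind(h_base, matrix(0, k - 2, n))
      h <- h_base
      for (k_i in seq_len(k)) h[k_i, ] <- h_base[k_i, ] * gains[k_i, phase_col]
      env <- (W %*% h) * ref$emg_scale   # 8 x n programmed envelope

      bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
      emg <- matrix(0, n, 8, dimnames = list(NULL, muscle_names()))
      for (c_i in 1:8) {
        carrier <- signal::filter(bp, rnorm(n))
        carrier <- carrier / sqrt(mean(carrier^2))
        phi <- runif(1, 0, 2 * pi)
        emg[, c_i] <- env[c_i, ] * carrier +
          config$emg_line_noise_amp * ref$emg_scale[c_i] *
            sin(2 * pi * 60 * tt + phi) +
          config$emg_noise_floor * ref$emg_scale[c_i] * rnorm(n)
      }
      if (keep_truth) {
        truth <- list(h = h, envelope = env, gains = gains,
                      level_e = level_e, level_s = level_s,
                      match_level = match_level)
      }
    }

    out <- list(participant_id = participant_id,
                load_condition = load, trial_index = as.integer(trial_index),
                is_practice = isTRUE(is_practice), sample_rate = fs,
                elbow_torque = elbow, shoulder_torque = shoulder,
                emg = emg, events = events, duration = duration,
                truth = truth)
    class(out) <- "trial_recording"
    out
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-participant strengths (truncated normal, floored at 10 Nm) and
#' MVC normalization constants, then simulates `trials_per_block` trials at
#' each shoulder abduction load (loads in ascending block order; the first
#' two trials of each block are practice). Fully deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @param include_emg,keep_truth Passed to [generate_trial()].
#' @return An object of class `"cohort"`: a list with one element per
#'   participant, each `list(reference = participant_reference, trials =
#'   list of trial_recording)`.
#' @examples
#' coh <- generate_cohort(generator_config(n_participants = 1, seed = 42),
#'                        include_emg = FALSE)
#' length(coh[[1]]$trials)
#' @export
generate_cohort <- function(config, include_emg = TRUE, keep_truth = FALSE) {
  config <- validate_generator_config(config)
  with_seed(config$seed, {
    loads <- sort(config$loads)
    tpb <- config$trials_per_block
    n_trials <- config$n_participants * length(loads) * tpb
    refs <- vector("list", config$n_participants)
    for (i in seq_len(config$n_participants)) {
      emg_scale <- runif(8, 0.3, 1.0)
      mvc_factor <- runif(8, 5, 9)
      refs[[i]] <- participant_reference(
        mvt_ef = rtruncnorm_floor(1, config$mvt_ef_mean, config$mvt_ef_sd, 10),
        mvt_sabd = rtruncnorm_floor(1, config$mvt_sabd_mean,
                                    config$mvt_sabd_sd, 10),
        mvc_emg_peak = emg_scale * mvc_factor,
        emg_scale = emg_scale)
    }
    trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)

    out <- vector("list", config$n_participants)
    s <- 0L
    for (i in seq_len(config$n_participants)) {
      pid <- sprintf("P%02d", i)
      trials <- vector("list", length(loads) * tpb)
      ti <- 0L
      for (li in seq_along(loads)) {
        bias <- config$ce_bias_per_load[match(loads[li], config$loads)]
        for (tr in seq_len(tpb)) {
          s <- s + 1L
          ti <- ti + 1L
          trials[[ti]] <- generate_trial(
            refs[[i]], loads[li], bias, seed = trial_seeds[s],
            config = config, is_practice = tr <= 2L,
            include_emg = include_emg, keep_truth = keep_truth,
            participant_id = pid, trial_index = tr)
        }
      }
      out[[i]] <- list(reference = refs[[i]], trials = trials)
      names(out)[i] <- pid
    }
    class(out) <- "cohort"
    out
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s load %.2f trial %d%s: %.1f s @ %g Hz%s\n",
              x$participant_id, x$load_condition, x$trial_index,
              if (x$is_practice) " (practice)" else "",
              x$duration, x$sample_rate,
              if (is.null(x$emg)) ", torque only" else ", 8 EMG ch"))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d trials each\n",
              length(x), length(x[[1]]$trials)))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' One CSV per trial (`time_s`, torques, eight EMG columns when present), a
#' JSON sidecar per trial with metadata and cue events, and a cohort-level
#' JSON with the participant reference values.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- lapply(cohort, function(p)
    list(mvt_ef = p$reference$mvt_ef, mvt_sabd = p$reference$mvt_sabd,
         mvc_emg_peak = as.list(p$reference$mvc_emg_peak)))
  jsonlite::write_json(refs, file.path(dir, "participants.json"),
                       auto_unbox = TRUE, digits = NA)
  for (p in cohort) {
    for (tr in p$trials) {
      stem <- sprintf("%s_load%02.0f_trial%02d", tr$participant_id,
                      100 * tr$load_condition, tr$trial_index)
      df <- data.frame(time_s = (seq_along(tr$elbow_torque) - 1) / tr$sample_rate,
                       elbow_torque_nm = tr$elbow_torque,
                       shoulder_torque_nm = tr$shoulder_torque)
      if (!is.null(tr$emg)) {
        emg <- as.data.frame(tr$emg)
        names(emg) <- paste0("emg_", muscle_names())
        df <- cbind(df, emg)
      }
      utils::write.csv(df, file.path(dir, paste0(stem, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(participant_id = tr$participant_id, load = tr$load_condition,
             trial_index = tr$trial_index, is_practice = tr$is_practice,
             sample_rate = tr$sample_rate, events = as.list(tr$events)),
        file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}
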