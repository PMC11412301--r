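#' Configuration for the synthetic torque-matching cohort generator
#'
#' Builds and validates the parameter set that defines a simulated cohort of
#' the two-phase isometric torque-matching protocol: participants abduct the
#' shoulder to a prescribed fraction of their maximum voluntary shoulder
#' abduction torque (MVT_SABD), generate and memorize a reference elbow
#' flexion torque at 25% of maximum voluntary elbow flexion torque (MVT_EF)
#' under visual feedback, then reproduce it from memory without feedback.
#'
#' Defaults emulate the study conditions the pipeline is designed for: cohort
#' strength distributions, per-load perceptual bias (constant error), per-load
#' stabilization times, torque-hold steadiness, and a two-synergy ground truth
#' (an elbow flexion/extension synergy loading biceps and triceps, and a
#' shoulder abduction synergy loading the deltoids, pectoralis major and
#' trapezii).
#'
#' @param n_participants Number of simulated participants (default 19, the
#'   cohort size the emulated study design uses).
#' @param seed Integer master seed; equal seeds give byte-identical cohorts.
#' @param sample_rate Sampling rate in Hz for torque and EMG series.
#' @param mvt_ef_mean,mvt_ef_sd Cohort mean/SD of maximum voluntary elbow
#'   flexion torque, Nm.
#' @param mvt_sabd_mean,mvt_sabd_sd Cohort mean/SD of maximum voluntary
#'   shoulder abduction torque, Nm.
#' @param loads Shoulder abduction loads as fractions of MVT_SABD.
#' @param elbow_target Elbow torque target as a fraction of MVT_EF.
#' @param accept_band Half-width of the torque acceptance band, as a fraction
#'   of the respective MVT.
#' @param trials_per_block Trials per load block; the first two are practice
#'   trials, flagged and excluded from analysis.
#' @param ce_bias_per_load Injected constant matching error per load, Nm.
#' @param match_noise_sd SD of the trial-to-trial matching error, Nm.
#' @param torque_hold_cv Coefficient of variation of held torque, percent.
#' @param tref_mean_per_load,tref_sd_per_load Mean/SD per load of the time to
#'   stabilize the elbow torque (the "in" to "hold" cue interval), s.
#' @param ground_truth_W Nonnegative 8-by-k matrix of ground-truth synergy
#'   vectors (rows in [muscle_names()] order).
#' @param activation_gain_cv Trial- and phase-level multiplicative variability
#'   (CV, as a fraction) of each synergy's EMG drive, emulating neural-gain
#'   fluctuation at constant torque.
#' @param emg_line_noise_amp Amplitude of the additive 60 Hz mains component,
#'   relative to the per-channel signal scale.
#' @param emg_noise_floor Amplitude of the additive broadband noise floor,
#'   relative to the per-channel signal scale.
#'
#' @return An object of class `"generator_config"` (a validated named list).
#' @examples
#' cfg <- generator_config(n_participants = 2, seed = 1)
#' cfg$loads
#' @export
generator_config <- function(n_participants = 19,
                             seed = 1L,
                             sample_rate = 1000,
                             mvt_ef_mean = 48.7, mvt_ef_sd = 18.3,
                             mvt_sabd_mean = 54.5, mvt_sabd_sd = 24.0,
                             loads = c(0.10, 0.30, 0.50),
                             elbow_target = 0.25,
                             accept_band = 0.05,
                             trials_per_block = 10L,
                             ce_bias_per_load = c(0.34, 1.85, 3.77),
                             match_noise_sd = 2.0,
                             torque_hold_cv = 1.5,
                             tref_mean_per_load = c(6.44, 3.86, 3.65),
                             tref_sd_per_load = c(2.22, 1.24, 1.69),
                             ground_truth_W = default_ground_truth_W(),
                             activation_gain_cv = 0.15,
                             emg_line_noise_amp = 0.05,
                             emg_noise_floor = 0.01) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    sample_rate = sample_rate,
    mvt_ef_mean = mvt_ef_mean, mvt_ef_sd = mvt_ef_sd,
    mvt_sabd_mean = mvt_sabd_mean, mvt_sabd_sd = mvt_sabd_sd,
    loads = loads, elbow_target = elbow_target, accept_band = accept_band,
    trials_per_block = as.integer(trials_per_block),
    ce_bias_per_load = ce_bias_per_load, match_noise_sd = match_noise_sd,
    torque_hold_cv = torque_hold_cv,
    tref_mean_per_load = tref_mean_per_load,
    tref_sd_per_load = tref_sd_per_load,
    ground_truth_W = ground_truth_W,
    activation_gain_cv = activation_gain_cv,
    emg_line_noise_amp = emg_line_noise_amp,
    emg_noise_floor = emg_noise_floor
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' Default ground-truth synergy matrix
#'
#' Two synergies over the eight recorded muscles: column 1 is an elbow
#' flexion/extension synergy (biceps, triceps); column 2 a shoulder abduction
#' synergy (deltoids, pectoralis major, middle and upper trapezius).
#'
#' @return Nonnegative 8-by-2 matrix with rows named per [muscle_names()].
#' @export
default_ground_truth_W <- function() {
  W <- cbind(
    elbow    = c(1.00, 0.80, 0, 0, 0, 0, 0, 0),
    shoulder = c(0, 0, 1.00, 0.90, 0.70, 0.60, 0.50, 0.80)
  )
  rownames(W) <- muscle_names()
  W
}

validate_generator_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(cfg$n_participants >= 1, "`n_participants` must be >= 1")
  chk(is.finite(cfg$seed), "`seed` must be a finite integer")
  stopifnot_scalar(cfg$sample_rate, "sample_rate", positive = TRUE)
  for (nm in c("mvt_ef_sd", "mvt_sabd_sd", "match_noise_sd",
               "torque_hold_cv", "activation_gain_cv",
               "emg_line_noise_amp", "emg_noise_floor")) {
    chk(is.numeric(cfg[[nm]]) && all(cfg[[nm]] >= 0),
        sprintf("`%s` must be >= 0", nm))
  }
  chk(all(cfg$tref_sd_per_load >= 0), "`tref_sd_per_load` must be >= 0")
  chk(all(cfg$loads > 0 & cfg$loads < 1), "`loads` must lie in (0, 1)")
  chk(cfg$elbow_target > 0 && cfg$elbow_target < 1,
      "`elbow_target` must lie in (0, 1)")
  chk(cfg$accept_band > 0, "`accept_band` must be > 0")
  chk(cfg$trials_per_block >= 3, "`trials_per_block` must be >= 3")
  nl <- length(cfg$loads)
  chk(length(cfg$ce_bias_per_load) == nl,
      "`ce_bias_per_load` must have one value per load")
  chk(length(cfg$tref_mean_per_load) == nl &&
        length(cfg$tref_sd_per_load) == nl,
      "`tref_mean_per_load`/`tref_sd_per_load` must have one value per load")
  W <- cfg$ground_truth_W
  chk(is.matrix(W) && nrow(W) == 8, "`ground_truth_W` must be an 8-row matrix")
  chk(all(W >= 0), "`ground_truth_W` must be nonnegative")
  chk(all(colSums(W) > 0), "`ground_truth_W` columns must be nonzero")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  participants: %d, seed: %d, fs: %g Hz\n",
              x$n_participants, x$seed, x$sample_rate))
  cat(sprintf("  loads: %s of MVT_SABD; elbow target: %g MVT_EF\n",
              paste(x$loads, collapse = "/"), x$elbow_target))
  cat(sprintf("  CE bias per load (Nm): %s; match noise SD: %g Nm\n",
              paste(x$ce_bias_per_load, collapse = "/"), x$match_noise_sd))
  cat(sprintf("  ground-truth synergies: %d\n", ncol(x$ground_truth_W)))
  invisible(x)
}
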