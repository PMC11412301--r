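# Synthetic cohort generator: determinism, protocol constraints, injected
# parameters, and EMG content.

test_that("equal seeds give identical cohorts and trials", {
  cfg <- generator_config(n_participants = 2, seed = 1, trials_per_block = 4)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  ref <- fixture_ref()
  t1 <- generate_trial(ref, 0.3, 1.85, seed = 9)
  t2 <- generate_trial(ref, 0.3, 1.85, seed = 9)
  expect_identical(t1, t2)
  t3 <- generate_trial(ref, 0.3, 1.85, seed = 10)
  expect_false(identical(t1$elbow_torque, t3$elbow_torque))
})

test_that("cohort has the protocol's block structure", {
  cfg <- generator_config(n_participants = 2, seed = 3, trials_per_block = 5)
  coh <- generate_cohort(cfg, include_emg = FALSE)
  expect_length(coh, 2)
  expect_length(coh[[1]]$trials, 3 * 5)
  practice <- vapply(coh[[1]]$trials, function(t) t$is_practice, logical(1))
  expect_identical(sum(practice), 6L)   # first two per block, three blocks
  loads <- vapply(coh[[1]]$trials, function(t) t$load_condition, numeric(1))
  expect_identical(sort(unique(loads)), c(0.10, 0.30, 0.50))
  for (p in coh) {
    expect_gt(p$reference$mvt_ef, 10)
    expect_true(all(p$reference$mvc_emg_peak > 0))
  }
})

test_that("cue events are ordered and all series share one length", {
  coh <- shared_cohort()
  for (tr in coh[[1]]$trials[1:6]) {
    ev <- tr$events[c("up", "in", "hold_ref", "relax_ref", "match",
                      "hold_match", "relax_end")]
    expect_true(all(diff(ev) > 0))
    expect_true(all(ev >= 0 & ev <= tr$duration))
    n <- length(tr$elbow_torque)
    expect_length(tr$shoulder_torque, n)
    expect_identical(nrow(tr$emg), n)
    # one-second memorized hold after the reference "hold" cue
    expect_gte(ev[["relax_ref"]] - ev[["hold_ref"]], 1)
  }
})

test_that("match-phase shoulder torque stays below 10% MVT_SABD", {
  coh <- shared_cohort()
  for (p in coh) {
    for (tr in p$trials) {
      fs <- tr$sample_rate
      i0 <- floor(tr$events[["match"]] * fs) + 1
      i1 <- floor(tr$events[["relax_end"]] * fs)
      expect_lt(max(tr$shoulder_torque[i0:i1]), 0.10 * p$reference$mvt_sabd)
    }
  }
})

test_that("zero bias and zero noise give exact torque matching", {
  cfg <- generator_config(n_participants = 1, seed = 5,
                          ce_bias_per_load = c(0, 0, 0),
                          match_noise_sd = 0, torque_hold_cv = 0)
  coh <- generate_cohort(cfg, include_emg = FALSE)
  f <- features_table(coh)
  f <- f[f$valid, ]
  expect_true(all(abs(f$tau_err) < 1e-9))
})

test_that("injected bias appears as the matching error when noise is off", {
  ref <- fixture_ref()
  cfg <- generator_config(match_noise_sd = 0, torque_hold_cv = 0)
  tr <- generate_trial(ref, 0.5, bias = 3.77, seed = 2, config = cfg)
  tf <- trial_features(tr, ref)
  expect_equal(tf$tau_err, 3.77, tolerance = 1e-9)
})

test_that("zero hold CV gives an exactly constant reference hold segment", {
  ref <- fixture_ref()
  cfg <- generator_config(torque_hold_cv = 0)
  tr <- generate_trial(ref, 0.1, 0, seed = 4, config = cfg,
                       include_emg = FALSE)
  seg <- extract_reference_segment(tr)
  expect_equal(diff(range(seg$elbow)), 0, tolerance = 1e-12)
})

test_that("reference-phase torques settle inside the acceptance bands", {
  coh <- shared_cohort()
  for (p in coh) {
    for (tr in p$trials) {
      seg <- extract_reference_segment(tr)
      target_e <- 0.25 * p$reference$mvt_ef
      expect_lt(abs(mean(seg$elbow) - target_e),
                0.05 * p$reference$mvt_ef + 0.5)
      target_s <- tr$load_condition * p$reference$mvt_sabd
      expect_lt(abs(mean(seg$shoulder) - target_s),
                0.05 * p$reference$mvt_sabd + 0.5)
    }
  }
})

test_that("invalid configurations are rejected with named messages", {
  expect_error(generator_config(loads = c(0.1, 1.2, 0.5)), "loads")
  expect_error(generator_config(match_noise_sd = -1), "match_noise_sd")
  expect_error(generator_config(accept_band = 0), "accept_band")
  expect_error(generator_config(ce_bias_per_load = c(1, 2)),
               "ce_bias_per_load")
  expect_error(generator_config(ground_truth_W = matrix(-1, 8, 2)),
               "ground_truth_W")
  ref <- fixture_ref()
  expect_error(generate_trial(ref, 1.5, 0, seed = 1), "load")
  expect_error(participant_reference(0, 50, rep(1, 8)), "mvt_ef")
  expect_error(participant_reference(50, 50, rep(0, 8)), "mvc_emg_peak")
})

test_that("raw EMG carries a 60 Hz line, broadband power, and the programmed envelope", {
  ref <- fixture_ref()
  tr <- generate_trial(ref, 0.3, 1.85, seed = 21, keep_truth = TRUE)
  fs <- tr$sample_rate
  x <- tr$emg[, "antdel"]
  pxx <- Mod(stats::fft(x))^2
  freq <- (seq_along(x) - 1) / length(x) * fs
  band_60 <- sum(pxx[freq > 59 & freq < 61])
  band_rest <- sum(pxx[freq > 100 & freq < 140])
  expect_gt(band_60, 0)
  expect_gt(band_rest, 0)
  # narrowband line power density exceeds the broadband density around it
  expect_gt(band_60 / 2, band_rest / 40)

  env <- process_trial_emg(tr, ref)
  truth <- tr$truth$envelope
  for (m in c(1, 3, 8)) {
    expect_gt(stats::cor(env[, m], truth[m, ]), 0.9)
  }
})

test_that("cohort trial seeds make practice and testing trials reproducible piecewise", {
  cfg <- generator_config(n_participants = 1, seed = 77, trials_per_block = 3)
  coh <- generate_cohort(cfg, include_emg = FALSE)
  dup <- generate_cohort(cfg, include_emg = FALSE)
  expect_identical(features_table(coh), features_table(dup))
})

test_that("written cohort files round-trip the torque series", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_participants = 1, seed = 12, trials_per_block = 3)
  coh <- generate_cohort(cfg, include_emg = FALSE)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "participants.json")))
  csvs <- list.files(dir, pattern = "\\.csv$")
  expect_length(csvs, 9)
  df <- utils::read.csv(file.path(dir, csvs[1]))
  tr <- coh[[1]]$trials[[1]]
  expect_equal(df$elbow_torque_nm, tr$elbow_torque, tolerance = 1e-9)
})
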