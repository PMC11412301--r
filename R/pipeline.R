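# End-to-end pipeline: simulate (or accept) a cohort, preprocess EMG,
# extract trial features, compute perceptual outcomes, run the synergy
# pipeline, and correlate generation features with the matching error.

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> EMG envelopes -> trial features -> perception
#' (CE/VE) -> synergy extraction and cross-participant matching ->
#' feature-error correlations, and optionally writes every stage as
#' TSV/JSON. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built cohort (e.g. from [generate_cohort()]).
#' @param output_dir Optional directory for stage outputs.
#' @param vaf_threshold VAF required for synergy-count selection, fraction.
#' @param n_random Random synergies for the similarity threshold.
#' @param restarts NMF restarts per candidate count.
#' @param reference_participant Reference for synergy matching; defaults to
#'   the first participant.
#' @param strict Require complete load blocks when assembling activity
#'   matrices.
#' @return List with `features`, `perception`, `models` (per-participant
#'   `synergy_model`s), `threshold`, `group`, `correlations`, `summary`.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         output_dir = NULL, vaf_threshold = 0.95,
                         n_random = 1000L, restarts = 20L,
                         reference_participant = NULL, strict = TRUE) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  features <- features_table(cohort)
  perception <- perception_outcomes(features)

  pids <- unique(features$participant)
  models <- list()
  for (i in seq_along(pids)) {
    pf <- features[features$participant == pids[i], , drop = FALSE]
    am <- normalize_matrix(assemble_matrix(pf, strict = strict))
    models[[pids[i]]] <- select_synergy_count(
      am, vaf_threshold = vaf_threshold,
      seed = config$seed + i, restarts = restarts)
  }
  threshold <- random_synergy_threshold(dim = 8L, n_random = n_random,
                                        seed = config$seed)
  if (is.null(reference_participant)) reference_participant <- pids[1]
  group <- match_synergies(models, threshold, reference_participant)
  correlations <- correlate_features(features)
  summary <- pipeline_summary(features, perception, models)

  out <- list(features = features, perception = perception, models = models,
              threshold = as.numeric(threshold), group = group,
              correlations = correlations, summary = summary)
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# Per-load cohort summary: participant-level means first, then mean +/- SD
# across participants, matching how cohort statistics are usually reported.
pipeline_summary <- function(features, perception, models) {
  f <- features[features$valid, , drop = FALSE]
  loads <- sort(unique(features$load))
  rows <- list()
  for (ld in loads) {
    fl <- f[f$load == ld, , drop = FALSE]
    pl <- perception[perception$load == ld, , drop = FALSE]
    pmean <- function(col) {
      v <- tapply(fl[[col]], fl$participant, mean, na.rm = TRUE)
      c(mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
    }
    cv <- pmean("cv"); co <- pmean("coactivation"); tr <- pmean("t_ref")
    rows[[length(rows) + 1L]] <- data.frame(
      load = ld,
      cv_mean = cv[1], cv_sd = cv[2],
      coactivation_mean = co[1], coactivation_sd = co[2],
      t_ref_mean = tr[1], t_ref_sd = tr[2],
      ce_mean = mean(pl$ce_nm), ce_sd = stats::sd(pl$ce_nm),
      ve_mean = mean(pl$ve_nm, na.rm = TRUE),
      ve_sd = stats::sd(pl$ve_nm, na.rm = TRUE))
  }
  per_load <- do.call(rbind, rows)
  n_syn <- vapply(models, function(m) m$n, integer(1))
  vafs <- vapply(models, function(m) m$vaf, numeric(1))
  list(per_load = per_load,
       synergy_counts = table(n_syn),
       vaf_mean = mean(vafs), vaf_sd = stats::sd(vafs))
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(res$features, "features.tsv")
  tsv(res$perception, "perception.tsv")
  tsv(res$correlations, "correlations.tsv")
  tsv(res$summary$per_load, "summary_per_load.tsv")
  vaf <- do.call(rbind, lapply(names(res$models), function(pid) {
    data.frame(participant = pid, n = seq_along(res$models[[pid]]$vaf_curve),
               vaf = res$models[[pid]]$vaf_curve, stringsAsFactors = FALSE)
  }))
  tsv(vaf, "vaf_curves.tsv")
  W <- do.call(rbind, lapply(names(res$models), function(pid) {
    m <- res$models[[pid]]
    data.frame(participant = pid, muscle = rownames(m$W),
               m$W, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  tsv(W, "synergy_W.tsv")
  jsonlite::write_json(
    list(threshold = res$threshold,
         reference = res$group$reference_participant,
         matches = res$group$matches,
         n_matched = as.list(res$group$n_matched),
         mean_W = as.data.frame(res$group$mean_W),
         synergy_counts = as.list(res$summary$synergy_counts),
         vaf_mean = res$summary$vaf_mean),
    file.path(dir, "group_synergy.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
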