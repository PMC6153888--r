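#' End-to-end pipeline configuration
#'
#' @param cohort a [cohort_config] (or NULL to read trials from
#'   `input_csv`).
#' @param input_csv optional path to an existing trial table CSV; when
#'   given, simulation is skipped.
#' @param variants model variants to fit (default all five).
#' @param conditions list of orientation/frame pairs to fit, defaulting to
#'   the three columns of the reference analysis: upright (earth = body),
#'   pitched earth-centered, pitched body-centered.
#' @param pitch_deg backward pitch (degrees).
#' @param alpha_level participant-screen significance level.
#' @param noise_audit run the synthetic stimulus-noise audit too.
#' @param noise_sd_per_axis per-axis acceleration noise of the synthetic
#'   IMU recordings (m/s^2).
#' @param n_starts,gh_nodes passed to [fit_anisotropy()].
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_csv = NULL,
                            variants = model_variants(),
                            conditions = list(
                              list(orientation = "upright", frame = "earth"),
                              list(orientation = "pitch30", frame = "earth"),
                              list(orientation = "pitch30", frame = "body")),
                            pitch_deg = 30,
                            alpha_level = 0.05,
                            noise_audit = FALSE,
                            noise_sd_per_axis = 0.03,
                            n_starts = 5, gh_nodes = 15) {
  stop_if(length(variants) < 1, "request at least one model variant")
  variants <- vapply(variants, match.arg, character(1),
                     choices = model_variants())
  structure(list(cohort = cohort, input_csv = input_csv,
                 variants = unname(variants), conditions = conditions,
                 pitch_deg = pitch_deg, alpha_level = alpha_level,
                 noise_audit = noise_audit,
                 noise_sd_per_axis = noise_sd_per_axis,
                 n_starts = n_starts, gh_nodes = gh_nodes),
            class = "pipeline_config")
}

fit_summary_row <- function(f) {
  w <- unlist(f$fixed_estimates[.variant_weights[[f$variant]]])
  data.frame(orientation = f$orientation, frame = f$frame,
             variant = f$variant,
             params = paste(names(w), signif(w, 4), sep = "=",
                            collapse = ";"),
             random_effect_sd = f$random_effect_sd,
             residual_sd = f$residual_sd, loglik = f$loglik, k = f$k,
             n = f$n, aicc = f$aicc, converged = f$converged)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> screen participants -> remove outlier trials ->
#' fit all requested variants per orientation/frame condition -> AICc
#' comparison tables -> body- versus earth-frame correlations -> optional
#' synthetic stimulus-noise audit. Every stage's output is persisted under
#' `out_dir` (CSV/JSON); the run is fully reproducible from the config's
#' seed, and any stage failure halts with the stage name while earlier
#' stages' outputs remain on disk.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return the report bundle (named list), invisibly the same content as
#'   written to `report.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stop_if(!inherits(config, "pipeline_config"),
          "`config` must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  table <- stage("simulate", {
    if (!is.null(config$input_csv)) read_trials(config$input_csv)
    else simulate_cohort(config$cohort)
  })
  write_trials(table, file.path(out_dir, "cohort.csv"))
  say("simulate: %d trials, %d participants", nrow(table),
      length(unique(table$participant_id)))

  pre <- stage("preprocess", preprocess_cohort(table, config$alpha_level))
  write_trials(pre$trials, file.path(out_dir, "cleaned.csv"))
  exclusion <- list(
    excluded_participants = pre$excluded_participants,
    n_excluded = nrow(pre$excluded_participants),
    removed_trial_fraction = pre$removed_fraction)
  jsonlite::write_json(exclusion, file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("preprocess: excluded %d participant(s), removed %.2f%% of trials",
      exclusion$n_excluded, 100 * pre$removed_fraction)

  fits <- list(); comparisons <- list()
  for (cond in config$conditions) {
    key <- paste(cond$orientation, cond$frame, sep = "_")
    cfits <- stage(paste0("fit_", key), lapply(config$variants, function(v)
      fit_anisotropy(pre$trials, v, orientation = cond$orientation,
                     frame = cond$frame, pitch_deg = config$pitch_deg,
                     n_starts = config$n_starts,
                     gh_nodes = config$gh_nodes)))
    names(cfits) <- config$variants
    fits[[key]] <- cfits
    if (length(cfits) >= 2) {
      comparisons[[key]] <- compare_models(cfits)
      utils::write.csv(comparisons[[key]],
                       file.path(out_dir, paste0("comparison_", key, ".csv")),
                       row.names = FALSE)
    }
    for (f in cfits) if (!f$converged)
      warning(sprintf("fit %s (%s) did not converge", f$variant, key))
    say("fit %s: best by AICc = %s", key,
        if (length(cfits) >= 2) comparisons[[key]]$variant[1]
        else cfits[[1]]$variant)
  }
  fit_table <- do.call(rbind, lapply(unlist(fits, recursive = FALSE),
                                     fit_summary_row))
  rownames(fit_table) <- NULL
  utils::write.csv(fit_table, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)

  frames <- NULL
  if (all(c("upright", "pitch30") %in% unique(pre$trials$orientation))) {
    frames <- stage("frames", compare_frames(pre$trials, config$pitch_deg))
    jsonlite::write_json(
      list(earth = unclass(frames$earth), body = unclass(frames$body)),
      file.path(out_dir, "frames.json"), auto_unbox = TRUE, digits = NA)
    say("frames: body r = %.3f, earth r = %.3f", frames$body$r,
        frames$earth$r)
  }

  audit <- NULL
  if (isTRUE(config$noise_audit)) {
    audit <- stage("noise", {
      seed0 <- (config$cohort$seed %||% 1)
      recs <- list(); i <- 0
      for (o in config$cohort$orientations) for (dir in direction_grid()) {
        for (ph in c("target", "test")) for (rep in 1:5) {
          prof <- if (ph == "target") target_profile(1.0, 3, 400)
                  else build_test_profile(solve_test_profile(1.55, 5, 2.5), 400)
          i <- i + 1
          recs[[i]] <- preprocess_imu(synthesize_imu(
            prof, dir, config$noise_sd_per_axis,
            seed = seed0 + 7919L * i,
            label = list(orientation = o, phase = ph, rep = rep,
                         distance = 1.0)))
        }
      }
      noise_vs_threshold(recs)
    })
    utils::write.csv(audit, file.path(out_dir, "noise_audit.csv"),
                     row.names = FALSE)
    say("noise audit: %d/%d conditions sub-threshold",
        sum(audit$sub_threshold, na.rm = TRUE), nrow(audit))
  }

  report <- list(
    exclusions = exclusion,
    fits = fit_table,
    comparisons = lapply(comparisons, as.data.frame),
    frame_correlations = if (!is.null(frames))
      list(earth = unclass(frames$earth), body = unclass(frames$body)),
    noise_audit = if (!is.null(audit)) as.data.frame(audit),
    seed = if (!is.null(config$cohort)) config$cohort$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(report)
}
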