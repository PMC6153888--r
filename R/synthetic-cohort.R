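#' Configuration of a synthetic distance-reproduction cohort
#'
#' Describes a cohort of the within-subject design: each participant judges
#' 12 sagittal translation directions x 6 target distances in each requested
#' body orientation, organised in blocks of 12 trials (one per direction)
#' with the target distances assigned pseudo-randomly across blocks, and
#' the orientations run in contiguous halves.
#'
#' Normal participants reproduce the target distance with a zero-mean
#' Gaussian signed error whose scale is tied to the generative error curve:
#' sd(a) = mu(a) sqrt(pi/2), so that the expected absolute error equals
#' mu(a) (folded-normal identity). Per participant, all weights are scaled
#' by exp(participant_sd * z_i), a single multiplicative log-normal random
#' effect. Direction enters through the body-centered angle: in the
#' backward-pitch orientation the generative curve is evaluated at the
#' earth-frame direction minus the pitch, i.e. the anisotropy is body-fixed.
#'
#' A `duration_strategy_fraction` of participants instead press at a
#' characteristic time (uniform on 2-4 s, per-trial Gaussian jitter sd
#' 0.15 s), converted to a distance via the test profile's position curve,
#' yielding reproduced distances unrelated to the target distance.
#'
#' @param n_participants number of participants (default 24).
#' @param generative_variant error-model variant generating the data
#'   (see [anisotropy_params()]).
#' @param true_params generative [anisotropy_params]; defaults to the
#'   horizontal-vertical model with w_h = 0.36, w_v = 0.40.
#' @param participant_sd sd of the log-normal multiplicative participant
#'   effect (log scale, >= 0).
#' @param duration_strategy_fraction fraction of participants using the
#'   press-time strategy, in `[0, 0.5)`.
#' @param trials_per_cell repetitions of each direction x distance cell per
#'   orientation (default 1, i.e. 72 trials per orientation).
#' @param orientations body orientations to include.
#' @param pitch_deg backward pitch of the non-upright orientation (degrees).
#' @param seed integer seed; all randomness flows from it.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_participants = 24,
                          generative_variant = "hv",
                          true_params = anisotropy_params("hv", w_h = 0.36,
                                                          w_v = 0.40),
                          participant_sd = 0.2,
                          duration_strategy_fraction = 4 / 24,
                          trials_per_cell = 1,
                          orientations = c("upright", "pitch30"),
                          pitch_deg = 30,
                          seed = 1) {
  generative_variant <- match.arg(generative_variant, model_variants())
  stop_if(n_participants < 1, "need at least one participant")
  stop_if(!is.finite(participant_sd) || participant_sd < 0,
          "`participant_sd` must be non-negative")
  stop_if(duration_strategy_fraction < 0 || duration_strategy_fraction >= 0.5,
          "`duration_strategy_fraction` must lie in [0, 0.5)")
  stop_if(true_params$variant != generative_variant,
          "`true_params` variant must match `generative_variant`")
  orientations <- match.arg(orientations, c("upright", "pitch30"),
                            several.ok = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 generative_variant = generative_variant,
                 true_params = true_params,
                 participant_sd = participant_sd,
                 duration_strategy_fraction = duration_strategy_fraction,
                 trials_per_cell = as.integer(trials_per_cell),
                 orientations = orientations,
                 pitch_deg = pitch_deg,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# scale all weights of a params object by a positive factor
scale_params <- function(params, factor) {
  for (nm in .variant_weights[[params$variant]])
    params[[nm]] <- params[[nm]] * factor
  params
}

# reference test profile shared by all trials (1.55 m/s^2 peak, 2.5 m in 5 s)
reference_test_profile <- function(sample_rate = 1000) {
  build_test_profile(solve_test_profile(1.55, 5, total_distance = 2.5),
                     sample_rate)
}

#' Simulate a distance-reproduction cohort
#'
#' Generates the long-format trial table of the design described in
#' [cohort_config()]. Deterministic given the config's seed.
#'
#' @param config a [cohort_config].
#' @return a data frame of class `trial_table` with columns
#'   `participant_id`, `block`, `orientation`, `direction_deg`,
#'   `target_distance`, `reproduced_distance`, `signed_error`, `abs_error`,
#'   and the config stored as an attribute. Reproduced distances are
#'   clipped to the test profile's range `[0, 2.5]` m.
#' @examples
#' head(simulate_cohort(cohort_config(n_participants = 2, seed = 7)))
#' @export
simulate_cohort <- function(config) {
  stop_if(!inherits(config, "cohort_config"), "`config` must be a cohort_config")
  set.seed(config$seed)
  dirs <- direction_grid()
  dists <- distance_grid()
  test_prof <- reference_test_profile()
  max_dist <- measure_profile(test_prof)$total_distance
  n <- config$n_participants
  n_dur <- round(config$duration_strategy_fraction * n)
  dur_ids <- if (n_dur > 0) sample(n, n_dur) else integer(0)
  blocks_per_orient <- 6L * config$trials_per_cell

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    z_i <- stats::rnorm(1)
    params_i <- scale_params(config$true_params,
                             exp(config$participant_sd * z_i))
    press_time_i <- stats::runif(1, 2, 4)
    # orientation halves: odd participants start upright
    orients <- config$orientations
    if (length(orients) == 2 && i %% 2 == 0) orients <- rev(orients)
    tabs <- list()
    block0 <- 0L
    for (o in orients) {
      # each block holds every direction once; per direction, distances are
      # shuffled across the blocks of this orientation half
      dist_by_dir <- vapply(dirs, function(d)
        sample(rep(dists, config$trials_per_cell)),
        numeric(blocks_per_orient))
      tab <- expand.grid(block = seq_len(blocks_per_orient),
                         direction_deg = dirs)
      tab$target_distance <- dist_by_dir[cbind(tab$block,
                                               match(tab$direction_deg, dirs))]
      tab$block <- tab$block + block0
      tab$orientation <- o
      body_alpha <- if (o == "pitch30")
        wrap_angle(tab$direction_deg - config$pitch_deg) else tab$direction_deg
      m <- nrow(tab)
      if (i %in% dur_ids) {
        press <- pmin(pmax(press_time_i + stats::rnorm(m, 0, 0.15), 0), 5)
        tab$reproduced_distance <- position_at(test_prof, press)
      } else {
        mu <- predict_error(params_i, body_alpha)
        err <- stats::rnorm(m, 0, mu * sqrt(pi / 2))
        tab$reproduced_distance <- pmin(pmax(tab$target_distance + err, 0),
                                        max_dist)
      }
      tabs[[o]] <- tab
      block0 <- block0 + blocks_per_orient
    }
    tab <- do.call(rbind, tabs)
    tab$participant_id <- i
    rows[[i]] <- tab
  }
  out <- do.call(rbind, rows)
  out$signed_error <- out$reproduced_distance - out$target_distance
  out$abs_error <- abs(out$signed_error)
  out <- out[, c("participant_id", "block", "orientation", "direction_deg",
                 "target_distance", "reproduced_distance", "signed_error",
                 "abs_error")]
  rownames(out) <- NULL
  structure(out, config = config, class = c("trial_table", "data.frame"))
}

#' Write a trial table as long-format CSV with a JSON config sidecar
#'
#' @param table a trial table.
#' @param path CSV output path; the generating config (seed included) is
#'   written next to it as `<path>.config.json` when available.
#' @return the path, invisibly.
#' @export
write_trials <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  cfg <- attr(table, "config")
  if (!is.null(cfg)) {
    cfg$true_params <- unclass(cfg$true_params)
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Recomputes `signed_error`/`abs_error` if absent.
#'
#' @param path CSV file written by [write_trials()] (or with the same
#'   schema: `participant_id,block,orientation,direction_deg,
#'   target_distance,reproduced_distance`).
#' @return a `trial_table` data frame.
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "block", "orientation", "direction_deg",
            "target_distance", "reproduced_distance")
  miss <- setdiff(need, names(out))
  stop_if(length(miss) > 0,
          paste("missing columns:", paste(miss, collapse = ", ")))
  if (is.null(out$signed_error))
    out$signed_error <- out$reproduced_distance - out$target_distance
  if (is.null(out$abs_error)) out$abs_error <- abs(out$signed_error)
  structure(out, class = c("trial_table", "data.frame"))
}
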