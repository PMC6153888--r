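#' Simulator stimulus-noise audit
#'
#' Motion simulators add uncontrolled noise on top of the commanded
#' acceleration. The audit quantifies that noise per trial condition
#' (signal-to-noise ratios of commanded versus recorded 3-axis
#' acceleration), and asks whether the noise difference between the target
#' and test translations of a condition could have been perceived, by
#' comparing it against Weber-type differential thresholds for linear
#' acceleration.
#'
#' @name stimulus-noise
NULL

#' Construct an IMU recording
#'
#' @param time sample times (s), uniform grid.
#' @param commanded n x 3 matrix of commanded acceleration (m/s^2, columns
#'   x = forward, y = lateral, z = up).
#' @param recorded n x 3 matrix of recorded acceleration.
#' @param sample_rate sampling rate (Hz).
#' @param label named list of trial metadata (`direction_deg`, `distance`,
#'   `orientation`, `phase` = `"target"` or `"test"`, `rep`).
#' @return an `imu_recording`.
#' @export
imu_recording <- function(time, commanded, recorded, sample_rate,
                          label = list()) {
  commanded <- as.matrix(commanded); recorded <- as.matrix(recorded)
  stop_if(ncol(commanded) != 3 || ncol(recorded) != 3,
          "commanded and recorded must have 3 axes")
  stop_if(nrow(commanded) != length(time) ||
            nrow(recorded) != length(time),
          "commanded and recorded must share the time grid")
  colnames(commanded) <- c("x", "y", "z")
  colnames(recorded) <- c("x", "y", "z")
  structure(list(time = time, commanded = commanded, recorded = recorded,
                 sample_rate = sample_rate, label = label),
            class = "imu_recording")
}

#' Synthesize an IMU recording from a motion profile
#'
#' Projects a 1-D profile onto the 3-D unit vector of a sagittal direction
#' (x = cos alpha, y = 0, z = sin alpha) and adds seeded per-axis Gaussian
#' noise, optionally plus a constant offset (a stand-in for the gravity
#' component that preprocessing must remove). A synthetic stand-in for
#' hardware IMU recordings.
#'
#' @param profile a [motion_profile].
#' @param direction_deg sagittal translation direction (degrees).
#' @param noise_sd_per_axis sd of the additive noise on each axis
#'   (m/s^2, >= 0).
#' @param seed optional integer seed for the noise.
#' @param dc_offset length-3 constant added to the recorded axes.
#' @param label trial metadata, as in [imu_recording()].
#' @return an `imu_recording`.
#' @export
synthesize_imu <- function(profile, direction_deg, noise_sd_per_axis,
                           seed = NULL, dc_offset = c(0, 0, 0),
                           label = list()) {
  stop_if(!inherits(profile, "motion_profile"),
          "`profile` must be a motion_profile")
  stop_if(!is.finite(noise_sd_per_axis) || noise_sd_per_axis < 0,
          "`noise_sd_per_axis` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  u <- c(cosd(direction_deg), 0, sind(direction_deg))
  cmd <- outer(profile$acceleration, u)
  n <- nrow(cmd)
  rec <- cmd + matrix(stats::rnorm(3 * n, 0, noise_sd_per_axis), n, 3) +
    matrix(dc_offset, n, 3, byrow = TRUE)
  label$direction_deg <- label$direction_deg %||% direction_deg
  imu_recording(profile$time, cmd, rec, attr(profile, "sample_rate"), label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess an IMU recording
#'
#' Zero-phase low-pass filtering of the recorded axes (4th-order
#' Butterworth at 80 Hz applied forward-backward) followed by gravity
#' removal, implemented as subtraction of each recorded axis' mean over the
#' whole recording.
#'
#' @param raw an [imu_recording] with sample rate above 160 Hz.
#' @param cutoff_hz low-pass cutoff (default 80).
#' @return the preprocessed `imu_recording`.
#' @export
preprocess_imu <- function(raw, cutoff_hz = 80) {
  stop_if(!inherits(raw, "imu_recording"), "`raw` must be an imu_recording")
  stop_if(raw$sample_rate <= 2 * cutoff_hz,
          "sample rate too low for the low-pass cutoff")
  bf <- signal::butter(4, cutoff_hz / (raw$sample_rate / 2), type = "low")
  # center before filtering: a large DC (gravity) component would otherwise
  # produce edge transients in the forward-backward pass; mean removal and
  # a linear filter commute away from the edges
  rec <- sweep(raw$recorded, 2, colMeans(raw$recorded))
  rec <- apply(rec, 2, function(x) signal::filtfilt(bf, x))
  rec <- sweep(rec, 2, colMeans(rec))
  out <- raw
  out$recorded <- rec
  out$preprocessed <- TRUE
  out
}

#' Signal-to-noise ratio of a recording
#'
#' SNR = ( rms(|commanded|) / rms(|commanded - recorded|) )^2, where |.| is
#' the per-sample 3-D vector norm. A noise-free recording yields an `Inf`
#' sentinel flagged with attribute `degenerate = "noise_free"`; an all-zero
#' commanded signal yields 0.
#'
#' @param rec a preprocessed [imu_recording].
#' @return the SNR (dimensionless).
#' @export
snr <- function(rec) {
  stop_if(!inherits(rec, "imu_recording"), "`rec` must be an imu_recording")
  cmd_norm <- sqrt(rowSums(rec$commanded^2))
  noise_norm <- sqrt(rowSums((rec$commanded - rec$recorded)^2))
  num <- rms(cmd_norm); den <- rms(noise_norm)
  if (num == 0) return(0)
  if (den == 0) return(structure(Inf, degenerate = "noise_free"))
  (num / den)^2
}

# rms of the noise vector norm (stimulus intensity of the noise)
noise_rms <- function(rec) rms(sqrt(rowSums((rec$commanded - rec$recorded)^2)))

#' Weber-type differential threshold coefficients
#'
#' Literature values for the smallest perceivable difference in linear
#' acceleration: horizontal dI = 0.05 I + 0.03; upward dI = 0.19 I^0.60;
#' downward dI = 0.17 I^0.42 (I and dI in m/s^2).
#'
#' @param horizontal c(slope, offset) of the horizontal function.
#' @param upward c(coef, exponent) of the upward function.
#' @param downward c(coef, exponent) of the downward function.
#' @return a `threshold_model`.
#' @export
threshold_model <- function(horizontal = c(slope = 0.05, offset = 0.03),
                            upward = c(coef = 0.19, exponent = 0.60),
                            downward = c(coef = 0.17, exponent = 0.42)) {
  stop_if(any(c(horizontal[1], horizontal[2], upward[1], downward[1]) <= 0),
          "coefficients must be positive")
  stop_if(any(c(upward[2], downward[2]) <= 0 | c(upward[2], downward[2]) > 1),
          "exponents must lie in (0, 1]")
  structure(list(horizontal = horizontal, upward = upward,
                 downward = downward), class = "threshold_model")
}

#' Differential threshold for a translation direction
#'
#' Pure-axis directions use the axis functions directly (alpha = 0 or 180:
#' horizontal; 90: upward; -90/270: downward), treating intensity as
#' unsigned. Oblique directions combine the axis functions quadratically:
#'
#'   dI = sqrt( (cos a * 0.05 I + 0.03)^2
#'            + [sin a > 0] (sin a * 0.19 I^0.60)^2
#'            + [sin a < 0] (sin a * 0.17 I^0.42)^2 ),
#'
#' with the opposite vertical term zeroed. With `strict = TRUE` the
#' combined formula is evaluated literally at every angle, including the
#' pure axes (where the constant 0.03 then persists inside the root, and at
#' 180 degrees the horizontal term becomes (-0.05 I + 0.03)^2).
#'
#' @param I stimulus intensity (m/s^2, >= 0); vectorized.
#' @param alpha_deg translation direction (degrees, sagittal plane).
#' @param model a [threshold_model].
#' @param strict evaluate the combined formula literally at all angles.
#' @return differential threshold dI (m/s^2).
#' @examples
#' differential_threshold(1, 0)    # 0.05 + 0.03 = 0.08
#' differential_threshold(1, 90)   # 0.19
#' @export
differential_threshold <- function(I, alpha_deg, model = threshold_model(),
                                   strict = FALSE) {
  stop_if(any(!is.finite(I)) || any(I < 0), "`I` must be non-negative")
  stop_if(length(alpha_deg) != 1, "`alpha_deg` must be a single angle")
  h <- model$horizontal; u <- model$upward; d <- model$downward
  a <- wrap_angle(alpha_deg)
  if (!strict) {
    if (a == 0 || a == 180) return(h[[1]] * I + h[[2]])
    if (a == 90) return(u[[1]] * I^u[[2]])
    if (a == -90) return(d[[1]] * I^d[[2]])
  }
  ca <- cosd(a); sa <- sind(a)
  sqrt((ca * h[[1]] * I + h[[2]])^2 +
         (sa > 0) * (sa * u[[1]] * I^u[[2]])^2 +
         (sa < 0) * (sa * d[[1]] * I^d[[2]])^2)
}

#' Noise-versus-threshold audit
#'
#' For each condition (direction x orientation): average over repeats the
#' SNR of the target and of the test recordings; take the absolute
#' difference of the (repeat-averaged) noise rms between target and test;
#' compute the lowest differential threshold across that condition's
#' stimuli, plugging the target motion's noise rms in as the stimulus
#' intensity; and flag whether the noise difference is below that
#' threshold (not perceivable). Repeats are averaged on the SNR scale.
#'
#' @param recordings list of preprocessed [imu_recording]s whose labels
#'   carry `direction_deg`, `orientation`, `phase` (`"target"`/`"test"`),
#'   `distance` and `rep`.
#' @param thresholds a [threshold_model].
#' @param strict passed to [differential_threshold()].
#' @return a `noise_audit` data frame: direction_deg, orientation,
#'   snr_target, snr_test, noise_rms_target, noise_rms_test, noise_diff,
#'   lowest_threshold, sub_threshold; conditions missing a target or test
#'   recording are reported with NA and `gap = TRUE`.
#' @export
noise_vs_threshold <- function(recordings, thresholds = threshold_model(),
                               strict = FALSE) {
  lab <- function(r, f) r$label[[f]] %||% NA
  meta <- data.frame(
    direction_deg = vapply(recordings, lab, numeric(1), "direction_deg"),
    orientation = vapply(recordings, function(r)
      as.character(r$label$orientation %||% "upright"), character(1)),
    phase = vapply(recordings, function(r)
      as.character(r$label$phase %||% NA), character(1)))
  stop_if(anyNA(meta$phase), "every recording label needs a `phase`")
  meta$snr <- vapply(recordings, function(r) as.numeric(snr(r)), numeric(1))
  meta$nrms <- vapply(recordings, noise_rms, numeric(1))
  conds <- unique(meta[, c("direction_deg", "orientation")])
  out <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- meta$direction_deg == conds$direction_deg[i] &
      meta$orientation == conds$orientation[i]
    tg <- sel & meta$phase == "target"
    ts <- sel & meta$phase == "test"
    row <- data.frame(direction_deg = conds$direction_deg[i],
                      orientation = conds$orientation[i],
                      snr_target = NA_real_, snr_test = NA_real_,
                      noise_rms_target = NA_real_, noise_rms_test = NA_real_,
                      noise_diff = NA_real_, lowest_threshold = NA_real_,
                      sub_threshold = NA, gap = !any(tg) || !any(ts))
    if (row$gap) return(row)
    row$snr_target <- mean(meta$snr[tg])
    row$snr_test <- mean(meta$snr[ts])
    row$noise_rms_target <- mean(meta$nrms[tg])
    row$noise_rms_test <- mean(meta$nrms[ts])
    row$noise_diff <- abs(row$noise_rms_target - row$noise_rms_test)
    # lowest threshold across this condition's stimuli, with the target
    # motion's noise rms as the stimulus intensity
    thr <- vapply(which(tg), function(j)
      differential_threshold(meta$nrms[j], conds$direction_deg[i],
                             thresholds, strict), numeric(1))
    row$lowest_threshold <- min(thr)
    row$sub_threshold <- row$noise_diff < row$lowest_threshold
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("noise_audit", "data.frame")
  out
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Standard crossed ANOVA of a balanced factorial layout (e.g. SNR values
#' over translation direction x body orientation with repeats per cell).
#' Degenerate layouts are reported, not crashed on: effects with zero sum
#' of squares in a zero-residual-variance fit get F = 0, p = 1; nonzero
#' effects over zero residual variance get an infinite-F sentinel, p = 0.
#'
#' @param values numeric response vector.
#' @param factor_direction first factor (coerced to factor).
#' @param factor_orientation second factor (coerced to factor).
#' @return data frame with effect, df, sum_sq, F, p.
#' @export
two_way_anova <- function(values, factor_direction, factor_orientation) {
  f1 <- factor(factor_direction); f2 <- factor(factor_orientation)
  stop_if(any(table(f1, f2) == 0), "empty cells in the factorial layout")
  fit <- stats::aov(values ~ f1 * f2)
  tab <- summary(fit)[[1]]
  eff <- trimws(rownames(tab))
  res <- tab[eff == "Residuals", , drop = FALSE]
  out <- data.frame(effect = c("direction", "orientation", "interaction"),
                    df = tab$Df[1:3], sum_sq = tab$`Sum Sq`[1:3],
                    F = tab$`F value`[1:3], p = tab$`Pr(>F)`[1:3])
  if (nrow(res) == 0 || res$`Mean Sq`[1] < 1e-24) {
    zero <- out$sum_sq < 1e-24
    out$F[zero] <- 0; out$p[zero] <- 1
    out$F[!zero] <- Inf; out$p[!zero] <- 0
  }
  out
}

#' Write IMU traces as CSV with a JSON label sidecar
#'
#' Columns `time,cmd_x,cmd_y,cmd_z,rec_x,rec_y,rec_z`.
#'
#' @param rec an [imu_recording].
#' @param path CSV output path; the label is written as `<path>.json`.
#' @return the path, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  df <- data.frame(time = rec$time,
                   cmd_x = rec$commanded[, 1], cmd_y = rec$commanded[, 2],
                   cmd_z = rec$commanded[, 3],
                   rec_x = rec$recorded[, 1], rec_y = rec$recorded[, 2],
                   rec_z = rec$recorded[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(rec$label, list(sample_rate = rec$sample_rate)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
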