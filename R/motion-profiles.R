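#' Motion profiles for target and test translations
#'
#' A `motion_profile` is a data frame with columns `time`, `acceleration`,
#' `velocity` and `position` on a uniform grid starting at 0, plus a
#' `sample_rate` attribute. Translations are rest-to-rest and unidirectional
#' along the path, so velocity starts and ends at zero and position is
#' non-decreasing.
#'
#' @name motion_profile
NULL

new_motion_profile <- function(time, acceleration, velocity, position,
                               sample_rate) {
  structure(
    data.frame(time = time, acceleration = acceleration,
               velocity = velocity, position = position),
    sample_rate = sample_rate,
    class = c("motion_profile", "data.frame")
  )
}

#' @export
print.motion_profile <- function(x, ...) {
  cat(sprintf(
    "<motion_profile> %.3f s @ %g Hz, distance %.4f m, peak |a| %.4f m/s^2\n",
    max(x$time), attr(x, "sample_rate"), x$position[nrow(x)],
    max(abs(x$acceleration))))
  invisible(x)
}

#' Build the raised-cosine target translation profile
#'
#' The target translation uses a raised-cosine velocity profile,
#' v(t) = (D/T) (1 - cos(2 pi t / T)), giving a sinusoidal acceleration
#' curve with peak 2 pi D / T^2 and a rest-to-rest motion over distance D.
#'
#' @param distance total translation distance D in meters (>= 0).
#' @param duration total duration T in seconds (3 s in the reference design).
#' @param sample_rate sampling rate in Hz (>= 50).
#' @return a [motion_profile].
#' @examples
#' p <- target_profile(0.5, 3)
#' max(p$acceleration)  # ~ 2*pi*0.5/9 = 0.349 m/s^2
#' @export
target_profile <- function(distance, duration = 3, sample_rate = 1000) {
  stop_if(!is.finite(distance) || distance < 0,
          "`distance` must be finite and non-negative")
  stop_if(!is.finite(duration) || duration <= 0,
          "`duration` must be finite and positive")
  stop_if(!is.finite(sample_rate) || sample_rate < 50,
          "`sample_rate` must be at least 50 Hz")
  t <- seq(0, duration, by = 1 / sample_rate)
  w <- 2 * pi / duration
  a <- (2 * pi * distance / duration^2) * sin(w * t)
  v <- (distance / duration) * (1 - cos(w * t))
  x <- distance * (t / duration - sin(w * t) / (2 * pi))
  new_motion_profile(t, a, v, x, sample_rate)
}

#' Parameters of the test translation profile
#'
#' The test translation accelerates along the first half of a sinusoid
#' (peak `peak_accel`, phase duration `t1`) and then decelerates at the
#' constant magnitude `decel` until it halts at `total_time`, covering
#' `total_distance`. Rest-to-rest closure ties the pieces together:
#' the peak velocity v1 = 2 A t1 / pi must equal d (T - t1), and
#' S = A t1^2 / pi + v1 (T - t1) / 2.
#'
#' @param peak_accel peak acceleration A (m/s^2).
#' @param t1 acceleration-phase duration (s).
#' @param decel constant deceleration magnitude d (m/s^2, > 0).
#' @param total_time total time T to halt (s).
#' @param total_distance total distance S (m).
#' @return an object of class `test_profile_params`.
#' @export
test_profile_params <- function(peak_accel, t1, decel, total_time,
                                total_distance) {
  stop_if(any(!is.finite(c(peak_accel, t1, decel, total_time,
                           total_distance))),
          "all parameters must be finite")
  stop_if(peak_accel <= 0 || t1 <= 0 || decel <= 0 || total_time <= t1,
          "need A > 0, 0 < t1 < T, d > 0")
  v1 <- 2 * peak_accel * t1 / pi
  closure <- abs(v1 - decel * (total_time - t1))
  dist_res <- abs(peak_accel * t1^2 / pi +
                    v1 * (total_time - t1) / 2 - total_distance)
  stop_if(closure > 1e-6 * max(1, v1),
          "parameters violate rest-to-rest closure v1 = d (T - t1)")
  stop_if(dist_res > 1e-6 * max(1, total_distance),
          "parameters violate the distance constraint")
  structure(list(peak_accel = peak_accel, t1 = t1, decel = decel,
                 total_time = total_time, total_distance = total_distance,
                 peak_velocity = v1),
            class = "test_profile_params")
}

#' @export
print.test_profile_params <- function(x, ...) {
  cat(sprintf(
    "<test_profile_params> A = %.4f m/s^2, t1 = %.4f s, d = %.4f m/s^2, T = %.3f s, S = %.4f m\n",
    x$peak_accel, x$t1, x$decel, x$total_time, x$total_distance))
  invisible(x)
}

#' Solve the test-profile closure for the acceleration phase
#'
#' Given the peak acceleration A, the total time T and either the total
#' distance S or the deceleration magnitude d, solves the rest-to-rest
#' closure for the remaining quantities. Substituting v1 = 2 A t1 / pi into
#' S = A t1^2 / pi + v1 (T - t1) / 2 collapses to S = A t1 T / pi, so with S
#' given the solution is closed-form: t1 = pi S / (A T). With d given
#' instead, v1 = d (T - t1) yields t1 = d T / (2 A / pi + d).
#'
#' @param peak_accel peak acceleration A (m/s^2, > 0).
#' @param total_time total time T (s, > 0).
#' @param total_distance total distance S (m, > 0); exactly one of
#'   `total_distance` and `decel` must be supplied.
#' @param decel constant deceleration magnitude (m/s^2, > 0).
#' @return a [test_profile_params].
#' @examples
#' solve_test_profile(1.55, 5, 2.5)  # d ~ 0.251 m/s^2, t1 ~ 1.014 s
#' @export
solve_test_profile <- function(peak_accel, total_time,
                               total_distance = NULL, decel = NULL) {
  stop_if(!is.finite(peak_accel) || peak_accel <= 0,
          "`peak_accel` must be positive")
  stop_if(!is.finite(total_time) || total_time <= 0,
          "`total_time` must be positive")
  stop_if(is.null(total_distance) == is.null(decel),
          "supply exactly one of `total_distance` and `decel`")
  if (!is.null(total_distance)) {
    stop_if(!is.finite(total_distance) || total_distance <= 0,
            "`total_distance` must be positive")
    t1 <- pi * total_distance / (peak_accel * total_time)
    stop_if(t1 >= total_time,
            "infeasible: required acceleration phase exceeds the total time")
    d <- 2 * peak_accel * t1 / (pi * (total_time - t1))
    S <- total_distance
  } else {
    stop_if(!is.finite(decel) || decel <= 0, "`decel` must be positive")
    t1 <- decel * total_time / (2 * peak_accel / pi + decel)
    d <- decel
    v1 <- 2 * peak_accel * t1 / pi
    S <- peak_accel * t1^2 / pi + v1 * (total_time - t1) / 2
  }
  test_profile_params(peak_accel, t1, d, total_time, S)
}

#' Sample the test translation profile
#'
#' a(t) = A sin(pi t / t1) during the acceleration phase, then constant -d
#' until the halt at T. Velocity and position are the exact piecewise
#' integrals, so profile invariants hold to machine precision on the grid.
#'
#' @param params a [test_profile_params].
#' @param sample_rate sampling rate in Hz.
#' @return a [motion_profile].
#' @export
build_test_profile <- function(params, sample_rate = 1000) {
  stop_if(!inherits(params, "test_profile_params"),
          "`params` must be a test_profile_params")
  stop_if(!is.finite(sample_rate) || sample_rate < 50,
          "`sample_rate` must be at least 50 Hz")
  A <- params$peak_accel; t1 <- params$t1; d <- params$decel
  T <- params$total_time
  v1 <- 2 * A * t1 / pi
  x1 <- A * t1^2 / pi
  t <- seq(0, T, by = 1 / sample_rate)
  if (t[length(t)] < T) t <- c(t, T)  # always include the halt
  ph1 <- t <= t1
  a <- ifelse(ph1, A * sin(pi * t / t1), -d)
  v <- ifelse(ph1, (A * t1 / pi) * (1 - cos(pi * t / t1)),
              pmax(v1 - d * (t - t1), 0))
  x <- ifelse(ph1, (A * t1 / pi) * (t - (t1 / pi) * sin(pi * t / t1)),
              x1 + v1 * (t - t1) - d * (t - t1)^2 / 2)
  # after the halt (only possible by rounding of T) position stays put
  x <- cummax(x)
  new_motion_profile(t, a, v, x, sample_rate)
}

#' Position along a profile at an arbitrary time
#'
#' Linear interpolation of the position series; used to convert a button
#' press time during the test translation into a reproduced distance.
#'
#' @param profile a [motion_profile].
#' @param t time in seconds, within `[0, max(profile$time)]`; vectorized.
#' @return position in meters.
#' @export
position_at <- function(profile, t) {
  stop_if(!inherits(profile, "motion_profile"),
          "`profile` must be a motion_profile")
  tmax <- profile$time[nrow(profile)]
  stop_if(any(!is.finite(t)) || any(t < 0) || any(t > tmax + 1e-12),
          sprintf("`t` must lie within [0, %.6f] s", tmax))
  stats::approx(profile$time, profile$position, xout = pmin(t, tmax),
                method = "linear", ties = "ordered")$y
}

#' Summarise a profile by re-measuring its defining quantities
#'
#' @param profile a [motion_profile].
#' @return list with peak |acceleration|, total time, total distance and
#'   terminal velocity, measured from the sampled series.
#' @export
measure_profile <- function(profile) {
  n <- nrow(profile)
  list(peak_accel = max(abs(profile$acceleration)),
       total_time = profile$time[n],
       total_distance = profile$position[n],
       end_velocity = profile$velocity[n])
}

#' Write a motion profile as CSV
#'
#' Columns `time,acceleration,velocity,position` with a header row.
#'
#' @param profile a [motion_profile].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
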