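#' Wrap an angle into (-180, 180], with -180 relabelled as 180
#'
#' The sagittal direction grid runs from -150 to 180 in 30-degree steps, so
#' the wrap must land exactly on grid labels: -180 and 180 denote the same
#' (straight backward) direction and the grid uses the label 180.
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped into (-180, 180].
#' @export
wrap_angle <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Round half away from zero to a fixed number of decimals
#'
#' Comparison convention against printed two-decimal values: 0.345 rounds to
#' 0.35, unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Root mean square of a numeric vector
#' @param x numeric vector.
#' @return sqrt(mean(x^2)).
#' @export
rms <- function(x) sqrt(mean(x^2))

# cos/sin of an angle in degrees, exact at multiples of 90
cosd <- function(deg) cospi(deg / 180)
sind <- function(deg) sinpi(deg / 180)

# internal input check helper
stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Direction grid of the sagittal-plane design
#'
#' Twelve translation directions in 30-degree steps; 0 is straight forward,
#' 90 straight up (earth frame when upright).
#' @return integer vector of length 12.
#' @export
direction_grid <- function() seq(-150L, 180L, by = 30L)

#' Target distance grid of the design (meters)
#' @return numeric vector of length 6.
#' @export
distance_grid <- function() seq(0.5, 1.5, by = 0.2)
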