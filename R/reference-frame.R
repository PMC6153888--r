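#' Body- versus earth-centered reference frames
#'
#' When the trunk is pitched backward by `pitch_deg`, a direction labelled
#' in earth coordinates corresponds to a body-centered direction rotated by
#' the same pitch: body angle = earth angle - pitch, wrapped back onto the
#' (-180, 180] grid (with -180 relabelled 180 so grid directions map onto
#' grid directions). If the anisotropy of distance errors is body-fixed,
#' the per-direction error pattern of the pitched condition matches the
#' upright pattern after this relabeling; if it is earth-fixed, it matches
#' without it. The decision statistic is the Pearson correlation over the
#' 12 direction-matched bin means.
#'
#' @name reference-frame
NULL

#' Map an earth-frame direction into the body frame
#'
#' @param direction_earth_deg direction(s) in earth coordinates (degrees,
#'   sagittal plane).
#' @param pitch_deg backward pitch of the trunk (30 in the reference
#'   design; any value allowed).
#' @return body-frame direction(s) wrapped into (-180, 180].
#' @examples
#' to_body_frame(120, 30)   # 90: straight up relative to the body
#' to_body_frame(-150, 30)  # wraps to 180
#' @export
to_body_frame <- function(direction_earth_deg, pitch_deg) {
  wrap_angle(direction_earth_deg - pitch_deg)
}

#' Correlate two per-direction error patterns
#'
#' Pearson correlation over the 12 direction-matched pairs of mean absolute
#' errors, with a two-sided p-value from the t distribution with
#' `n_pairs - 2` degrees of freedom. The pitched pattern must already be
#' expressed in the requested frame (see [error_pattern()]).
#'
#' @param pattern_upright [error_pattern] of the upright condition.
#' @param pattern_pitched [error_pattern] of the pitched condition in the
#'   requested frame.
#' @param frame label of the frame being tested, `"earth"` or `"body"`.
#' @return a `frame_correlation`: frame, r, p, n_pairs (and a `note` when
#'   r is undefined because a pattern has zero variance).
#' @export
frame_correlation <- function(pattern_upright, pattern_pitched,
                              frame = c("earth", "body")) {
  frame <- match.arg(frame)
  for (pat in list(pattern_upright, pattern_pitched)) {
    stop_if(!inherits(pat, "error_pattern"),
            "patterns must be error_pattern objects")
    empty <- pat$direction_deg[pat$n == 0 | is.na(pat$mean_abs_error)]
    stop_if(length(empty) > 0,
            paste("pattern has empty bins at direction(s):",
                  paste(empty, collapse = ", ")))
  }
  i <- match(pattern_upright$direction_deg, pattern_pitched$direction_deg)
  stop_if(anyNA(i), "patterns are not on the same direction grid")
  x <- pattern_upright$mean_abs_error
  y <- pattern_pitched$mean_abs_error[i]
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(frame = frame, r = NA_real_, p = NA_real_, n_pairs = n,
                note = "undefined correlation: zero-variance pattern")
  } else {
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    out <- list(frame = frame, r = unname(ct$estimate), p = ct$p.value,
                n_pairs = n, note = NULL)
  }
  structure(out, class = "frame_correlation")
}

#' @export
print.frame_correlation <- function(x, ...) {
  if (is.null(x$note))
    cat(sprintf("<frame_correlation> %s frame: r(%d) = %.3f, p = %.3f\n",
                x$frame, x$n_pairs, x$r, x$p))
  else
    cat(sprintf("<frame_correlation> %s frame: %s\n", x$frame, x$note))
  invisible(x)
}

#' Run the body- versus earth-centered correlation test on a cohort
#'
#' Computes participant-averaged error patterns for the upright condition
#' and for the pitched condition coded both ways (earth-centered and
#' body-centered), and correlates each pitched coding with the upright
#' reference pattern.
#'
#' @param table a cleaned trial table containing both orientations.
#' @param pitch_deg backward pitch (default 30).
#' @return list with elements `earth` and `body`, each a
#'   [frame_correlation], plus the three patterns used.
#' @export
compare_frames <- function(table, pitch_deg = 30) {
  up <- error_pattern(table, "upright", "earth", pitch_deg)
  pe <- error_pattern(table, "pitch30", "earth", pitch_deg)
  pb <- error_pattern(table, "pitch30", "body", pitch_deg)
  list(earth = frame_correlation(up, pe, "earth"),
       body = frame_correlation(up, pb, "body"),
       patterns = list(upright = up, pitched_earth = pe, pitched_body = pb))
}
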