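#' (An)isotropy error models for sagittal translation directions
#'
#' Five candidate models describe the expected absolute error of a traveled
#' distance reproduction as a function of the translation direction alpha in
#' the sagittal plane (0 = forward, 90 = up):
#'
#' * `isotropy`: a constant error (intercept only).
#' * `hv`: horizontal-vertical,
#'   sqrt((w_h cos a)^2 + (w_v sin a)^2).
#' * `ud`: upward-downward refinement of the vertical component,
#'   sqrt((w_h cos a)^2 + [sin a > 0] (w_u sin a)^2 + [sin a < 0] (w_d sin a)^2).
#' * `fb`: forward-backward refinement of the horizontal component,
#'   sqrt([cos a > 0] (w_f cos a)^2 + [cos a < 0] (w_b cos a)^2 + (w_v sin a)^2).
#' * `fbud`: both refinements combined (four weights).
#'
#' The quadratic combination normalizes the weighted components so that a
#' model with all weights equal predicts the same error in every direction.
#' Indicators use strict inequalities; at the switch points the associated
#' sin/cos factor vanishes, so every model is continuous in alpha.
#'
#' @name anisotropy-models
NULL

.variant_weights <- list(
  isotropy = "intercept",
  hv   = c("w_h", "w_v"),
  ud   = c("w_h", "w_u", "w_d"),
  fb   = c("w_f", "w_b", "w_v"),
  fbud = c("w_f", "w_b", "w_u", "w_d")
)

#' Model variants
#' @return character vector of the five variant names.
#' @export
model_variants <- function() names(.variant_weights)

#' Construct anisotropy model parameters
#'
#' @param variant one of `"isotropy"`, `"hv"`, `"ud"`, `"fb"`, `"fbud"`.
#' @param ... named non-negative weights required by the variant
#'   (`intercept` for isotropy; `w_h`, `w_v` for hv; `w_h`, `w_u`, `w_d`
#'   for ud; `w_f`, `w_b`, `w_v` for fb; `w_f`, `w_b`, `w_u`, `w_d` for
#'   fbud), in meters of absolute error.
#' @return an `anisotropy_params` object.
#' @examples
#' anisotropy_params("hv", w_h = 0.36, w_v = 0.40)
#' @export
anisotropy_params <- function(variant, ...) {
  variant <- match.arg(variant, model_variants())
  w <- list(...)
  need <- .variant_weights[[variant]]
  miss <- setdiff(need, names(w))
  stop_if(length(miss) > 0,
          paste0("variant '", variant, "' needs weights: ",
                 paste(miss, collapse = ", ")))
  w <- w[need]
  vals <- unlist(w)
  stop_if(any(!is.finite(vals)) || any(vals < 0),
          "all weights must be finite and non-negative")
  structure(c(list(variant = variant), w), class = "anisotropy_params")
}

#' @export
print.anisotropy_params <- function(x, ...) {
  w <- unlist(x[.variant_weights[[x$variant]]])
  cat(sprintf("<anisotropy_params> %s: %s\n", x$variant,
              paste(names(w), round(w, 4), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Predicted absolute error for a translation direction
#'
#' Evaluates the variant's error curve at direction `alpha_deg` (degrees in
#' the sagittal plane). Vectorized over `alpha_deg`.
#'
#' @param params an [anisotropy_params].
#' @param alpha_deg translation direction(s) in degrees.
#' @return predicted mean absolute error (m), same length as `alpha_deg`.
#' @examples
#' p <- anisotropy_params("hv", w_h = 0.36, w_v = 0.40)
#' predict_error(p, c(0, 30, 90))
#' @export
predict_error <- function(params, alpha_deg) {
  stop_if(!inherits(params, "anisotropy_params"),
          "`params` must be an anisotropy_params")
  ca <- cosd(alpha_deg); sa <- sind(alpha_deg)
  switch(params$variant,
    isotropy = rep(params$intercept, length(alpha_deg)),
    hv = sqrt((params$w_h * ca)^2 + (params$w_v * sa)^2),
    ud = sqrt((params$w_h * ca)^2 +
              (sa > 0) * (params$w_u * sa)^2 +
              (sa < 0) * (params$w_d * sa)^2),
    fb = sqrt((ca > 0) * (params$w_f * ca)^2 +
              (ca < 0) * (params$w_b * ca)^2 +
              (params$w_v * sa)^2),
    fbud = sqrt((ca > 0) * (params$w_f * ca)^2 +
                (ca < 0) * (params$w_b * ca)^2 +
                (sa > 0) * (params$w_u * sa)^2 +
                (sa < 0) * (params$w_d * sa)^2))
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1). Requires n > k + 1.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects plus variance
#'   components).
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  stop_if(n <= k + 1, "AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
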