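#' Mixed-effects fitting of the (an)isotropy error models
#'
#' Each anisotropy variant is fitted to per-trial absolute errors by maximum
#' likelihood as a nonlinear mixed-effects model: for participant i and
#' trial j with direction alpha_ij,
#'
#'   abs_error_ij = exp(sigma_b z_i) * mu(alpha_ij; w) + eps_ij,
#'
#' with z_i standard normal (one multiplicative log-normal scaling per
#' participant), eps Gaussian with sd sigma, and mu the variant's error
#' curve. The participant effect is integrated out by Gauss-Hermite
#' quadrature. The isotropy variant is the linear random-intercept null
#' model, abs_error_ij = beta0 + b_i + eps_ij, whose Gaussian marginal
#' likelihood is evaluated in closed form. Direction is treated as
#' continuous through its sine/cosine projections.
#'
#' @name fit-anisotropy
NULL

# variant curve on precomputed cos/sin, weights ordered as .variant_weights
curve_eval <- function(variant, w, ca, sa) {
  switch(variant,
    isotropy = rep(w[1], length(ca)),
    hv = sqrt((w[1] * ca)^2 + (w[2] * sa)^2),
    ud = sqrt((w[1] * ca)^2 + (sa > 0) * (w[2] * sa)^2 +
                (sa < 0) * (w[3] * sa)^2),
    fb = sqrt((ca > 0) * (w[1] * ca)^2 + (ca < 0) * (w[2] * ca)^2 +
                (w[3] * sa)^2),
    fbud = sqrt((ca > 0) * (w[1] * ca)^2 + (ca < 0) * (w[2] * ca)^2 +
                  (sa > 0) * (w[3] * sa)^2 + (sa < 0) * (w[4] * sa)^2))
}

# negative marginal log-likelihood, multiplicative random effect,
# theta = (log weights, log sigma_b, log sigma)
nll_multiplicative <- function(theta, y, pid, ca, sa, variant, gh) {
  p <- length(theta) - 2
  w <- exp(theta[seq_len(p)])
  sb <- exp(theta[p + 1]); sig <- exp(theta[p + 2])
  mu <- curve_eval(variant, w, ca, sa)
  s <- exp(sb * sqrt(2) * gh$x)                       # K scale factors
  R <- (y - outer(mu, s)) / sig                       # n x K residuals
  LD <- -0.5 * R * R - log(sig) - 0.5 * log(2 * pi)   # per-trial log dens
  G <- rowsum(LD, pid, reorder = FALSE)               # participants x K
  A <- sweep(G, 2, log(gh$w) - 0.5 * log(pi), "+")
  amax <- apply(A, 1, max)
  ll <- sum(amax + log(rowSums(exp(A - amax))))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# negative marginal log-likelihood of the random-intercept LMM,
# theta = (beta0, log sigma_b, log sigma); closed form
nll_intercept <- function(theta, y, pid) {
  b0 <- theta[1]; lam <- exp(theta[2])^2; s2 <- exp(theta[3])^2
  r <- y - b0
  Sr <- rowsum(r, pid, reorder = FALSE)
  SS <- rowsum(r * r, pid, reorder = FALSE)
  ni <- rowsum(rep(1, length(y)), pid, reorder = FALSE)
  quad <- (SS - lam * Sr^2 / (s2 + ni * lam)) / s2
  logdet <- ni * log(s2) + log1p(ni * lam / s2)
  ll <- -0.5 * sum(ni * log(2 * pi) + logdet + quad)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Dennis-Schnabel scaled gradient norm via central differences
scaled_gradient_norm <- function(fn, par, fval, h = 1e-6) {
  g <- vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h * max(1, abs(par[i]))
    (fn(par + e) - fn(par - e)) / (2 * e[i])
  }, numeric(1))
  max(abs(g) * pmax(abs(par), 1)) / max(abs(fval), 1)
}

# deterministic jittered starting values (n_starts x n_par matrix)
start_matrix <- function(variant, y, n_starts) {
  p <- length(.variant_weights[[variant]])
  m <- max(mean(y), 1e-3)
  s0 <- max(stats::sd(y), 1e-3)
  fw <- rep(c(1, 0.6, 1.6, 0.85, 1.3, 0.4, 2.2), length.out = n_starts)
  fb <- rep(c(0.2, 0.05, 0.5, 0.3, 0.1, 0.7, 0.02), length.out = n_starts)
  fs <- rep(c(1, 1.5, 0.6, 1, 0.8, 1.2, 0.5), length.out = n_starts)
  tilt <- seq(-0.1, 0.1, length.out = max(p, 2))[seq_len(p)]
  t(vapply(seq_len(n_starts), function(j) {
    if (variant == "isotropy")
      c(m * fw[j], log(fb[j]* m), log(s0 * fs[j]))
    else
      c(log(m * fw[j]) + tilt * (j - 1), log(fb[j]), log(s0 * fs[j]))
  }, numeric(p + 2)))
}

#' Fit one (an)isotropy model to a trial table
#'
#' Maximum-likelihood fit for one body-orientation condition, with the
#' translation direction expressed in the requested reference frame
#' (body-frame fitting relabels directions by the backward pitch before
#' taking sine/cosine projections). Optimization uses multiple
#' deterministically jittered starts of a quasi-Newton optimizer on the
#' marginal log-likelihood; weights and variance components are kept
#' positive by a log reparameterization, and ties are broken by the best
#' likelihood. Non-convergence is flagged, never silent.
#'
#' @param table a cleaned trial table.
#' @param variant one of [model_variants()].
#' @param orientation condition to fit, `"upright"` or `"pitch30"`.
#' @param frame reference frame for direction, `"earth"` or `"body"`.
#' @param pitch_deg backward pitch used for body-frame relabeling.
#' @param n_starts number of jittered optimizer starts (>= 1, default 5).
#' @param gh_nodes Gauss-Hermite nodes for the participant integral.
#' @return an `anisotropy_fit`: variant, fitted [anisotropy_params],
#'   `random_effect_sd`, `residual_sd`, `loglik`, `k` (fixed effects plus
#'   the two variance components), `n`, `aicc`, `converged`, diagnostics.
#' @export
fit_anisotropy <- function(table, variant, orientation = "upright",
                           frame = c("earth", "body"), pitch_deg = 30,
                           n_starts = 5, gh_nodes = 15) {
  variant <- match.arg(variant, model_variants())
  frame <- match.arg(frame)
  orientation <- match.arg(orientation, c("upright", "pitch30"))
  d <- table[table$orientation == orientation, , drop = FALSE]
  stop_if(nrow(d) == 0, "no trials for the requested orientation")
  stop_if(length(unique(d$participant_id)) < 2,
          "need at least two participants")
  alpha <- d$direction_deg
  if (frame == "body" && orientation == "pitch30")
    alpha <- wrap_angle(alpha - pitch_deg)
  y <- d$abs_error
  pid <- as.integer(factor(d$participant_id))
  ca <- cosd(alpha); sa <- sind(alpha)
  gh <- pracma::gaussHermite(gh_nodes)

  if (stats::sd(y) < 1e-12) {
    # constant response: the likelihood is unbounded as both variance
    # components vanish; the ML limit has every weight equal to the
    # constant (all variants predict a flat curve there) and zero
    # variances, reported at the variance floor
    p <- length(.variant_weights[[variant]])
    wl <- as.list(rep(y[1], p))
    names(wl) <- .variant_weights[[variant]]
    est <- do.call(anisotropy_params, c(list(variant = variant), wl))
    n <- length(y)
    floor_sd <- 1e-8
    ll <- sum(stats::dnorm(y, y[1], floor_sd, log = TRUE))
    return(structure(list(variant = variant, fixed_estimates = est,
                          random_effect_sd = 0, residual_sd = floor_sd,
                          loglik = ll, k = p + 2, n = n,
                          aicc = aicc(ll, p + 2, n), converged = TRUE,
                          message = "degenerate: constant response",
                          orientation = orientation, frame = frame,
                          data_fingerprint = c(n = n, sum_y = sum(y))),
                     class = "anisotropy_fit"))
  }

  obj <- if (variant == "isotropy") {
    function(theta) nll_intercept(theta, y, pid)
  } else {
    function(theta) nll_multiplicative(theta, y, pid, ca, sa, variant, gh)
  }
  starts <- start_matrix(variant, y, n_starts)
  lower <- rep(-Inf, ncol(starts))
  lower[ncol(starts)] <- log(1e-8)          # residual sd floor
  lower[ncol(starts) - 1] <- log(1e-8)      # random-effect sd floor
  runs <- lapply(seq_len(nrow(starts)), function(j) {
    tryCatch(
      stats::nlminb(starts[j, ], obj, lower = lower,
                    control = list(rel.tol = 1e-12, iter.max = 500,
                                   eval.max = 2000)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e),
                               par = starts[j, ]))
  })
  objs <- vapply(runs, function(r) r$objective, numeric(1))
  best <- runs[[which.min(objs)]]
  # convergence judged by the scaled gradient at the selected solution:
  # quasi-Newton termination messages (e.g. singular convergence on a flat
  # ridge of an over-parameterized variant) do not distinguish failure from
  # a legitimate stationary point
  converged <- is.finite(best$objective) &&
    scaled_gradient_norm(obj, best$par, best$objective) < 1e-4

  p <- length(.variant_weights[[variant]])
  theta <- best$par
  if (variant == "isotropy") {
    est <- anisotropy_params("isotropy", intercept = theta[1])
  } else {
    wl <- as.list(exp(theta[seq_len(p)]))
    names(wl) <- .variant_weights[[variant]]
    est <- do.call(anisotropy_params, c(list(variant = variant), wl))
  }
  k <- p + 2
  n <- length(y)
  loglik <- -best$objective
  structure(list(variant = variant,
                 fixed_estimates = est,
                 random_effect_sd = exp(theta[p + 1]),
                 residual_sd = exp(theta[p + 2]),
                 loglik = loglik, k = k, n = n,
                 aicc = aicc(loglik, k, n),
                 converged = converged,
                 message = best$message,
                 orientation = orientation, frame = frame,
                 data_fingerprint = c(n = n, sum_y = sum(y))),
            class = "anisotropy_fit")
}

#' @export
print.anisotropy_fit <- function(x, ...) {
  cat(sprintf("<anisotropy_fit> %s (%s, %s frame): logLik %.2f, AICc %.2f%s\n",
              x$variant, x$orientation, x$frame, x$loglik, x$aicc,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$fixed_estimates)
  cat(sprintf("  random-effect sd %.4f, residual sd %.4f, n = %d, k = %d\n",
              x$random_effect_sd, x$residual_sd, x$n, x$k))
  invisible(x)
}

#' Compare fitted models by AICc
#'
#' Ranks fits of the same data by AICc; the best model's AICc is the
#' reference (dAICc = 0), and models within dAICc < 4 of the best are
#' flagged indistinguishable (the conventional model-selection guideline).
#' Fits on differing observation sets are refused.
#'
#' @param fits list of `anisotropy_fit` objects on identical data.
#' @return a `model_comparison` data frame sorted by AICc: variant, k,
#'   loglik, aicc, daicc, best, indistinguishable, converged.
#' @export
compare_models <- function(fits) {
  stop_if(length(fits) < 2, "need at least two fits")
  stop_if(!all(vapply(fits, inherits, logical(1), "anisotropy_fit")),
          "all elements must be anisotropy_fit objects")
  fps <- t(vapply(fits, function(f) f$data_fingerprint, numeric(2)))
  stop_if(nrow(unique(round(fps, 8))) != 1,
          "fits are not on identical observation sets")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(variant = f$variant, k = f$k, loglik = f$loglik,
               aicc = f$aicc, converged = f$converged)))
  tab$daicc <- tab$aicc - min(tab$aicc)
  tab$best <- tab$daicc == 0
  tab$indistinguishable <- tab$daicc < 4
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}
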