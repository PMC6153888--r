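test_that("predicted error hits the axis and hand-computed anchors", {
  hv <- anisotropy_params("hv", w_h = 0.36, w_v = 0.40)
  expect_equal(predict_error(hv, 0), 0.36)
  expect_equal(predict_error(hv, 180), 0.36)
  expect_equal(predict_error(hv, 90), 0.40)
  expect_equal(predict_error(hv, -90), 0.40)
  # independent hand evaluation at 30 degrees
  expect_equal(predict_error(hv, 30),
               sqrt((0.36 * sqrt(3) / 2)^2 + (0.40 * 0.5)^2),
               tolerance = 1e-12)
  expect_equal(round(predict_error(hv, 30), 4), 0.3704)
  # equal weights collapse to a direction-independent error
  eq <- anisotropy_params("hv", w_h = 0.25, w_v = 0.25)
  expect_equal(predict_error(eq, seq(-150, 180, by = 10)),
               rep(0.25, 34))
  iso <- anisotropy_params("isotropy", intercept = 0.38)
  expect_equal(predict_error(iso, c(-90, 0, 45)), rep(0.38, 3))
})

test_that("indicator terms select the right hemifield weight", {
  ud <- anisotropy_params("ud", w_h = 0.3, w_u = 0.5, w_d = 0.2)
  expect_equal(predict_error(ud, 90), 0.5)
  expect_equal(predict_error(ud, -90), 0.2)
  fb <- anisotropy_params("fb", w_f = 0.3, w_b = 0.45, w_v = 0.4)
  expect_equal(predict_error(fb, 0), 0.3)
  expect_equal(predict_error(fb, 180), 0.45)
  fbud <- anisotropy_params("fbud", w_f = 0.3, w_b = 0.45, w_u = 0.5,
                            w_d = 0.2)
  expect_equal(predict_error(fbud, c(0, 180, 90, -90)),
               c(0.3, 0.45, 0.5, 0.2))
})

test_that("refined models nest the horizontal-vertical model", {
  set.seed(42)
  grid <- seq(-179.5, 180, by = 0.5)
  for (i in 1:20) {
    w <- runif(2, 0.05, 0.6)
    hv <- anisotropy_params("hv", w_h = w[1], w_v = w[2])
    ud <- anisotropy_params("ud", w_h = w[1], w_u = w[2], w_d = w[2])
    fb <- anisotropy_params("fb", w_f = w[1], w_b = w[1], w_v = w[2])
    fbud <- anisotropy_params("fbud", w_f = w[1], w_b = w[1],
                              w_u = w[2], w_d = w[2])
    expect_equal(predict_error(ud, grid), predict_error(hv, grid))
    expect_equal(predict_error(fb, grid), predict_error(hv, grid))
    expect_equal(predict_error(fbud, grid), predict_error(hv, grid))
  }
})

test_that("all model curves are continuous at the indicator switches", {
  set.seed(7)
  eps <- 1e-7
  for (v in setdiff(model_variants(), "isotropy")) {
    nm <- c(hv = 2, ud = 3, fb = 3, fbud = 4)[[v]]
    w <- as.list(runif(nm, 0.1, 0.5))
    names(w) <- switch(v, hv = c("w_h", "w_v"),
                       ud = c("w_h", "w_u", "w_d"),
                       fb = c("w_f", "w_b", "w_v"),
                       fbud = c("w_f", "w_b", "w_u", "w_d"))
    p <- do.call(anisotropy_params, c(list(variant = v), w))
    for (a in c(-180, -90, 0, 90, 180)) {
      lo <- predict_error(p, a - eps)
      hi <- predict_error(p, a + eps)
      expect_lt(abs(hi - lo), 1e-5)
    }
  }
})

test_that("parameter constructors enforce the variant's weight set", {
  expect_error(anisotropy_params("hv", w_h = 0.3), "w_v")
  expect_error(anisotropy_params("hv", w_h = -0.1, w_v = 0.2),
               "non-negative")
  expect_error(anisotropy_params("nope", w_h = 1), "arg")
})

test_that("AICc formula and limits", {
  expect_equal(aicc(0, 1, 3), 6)
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  # approaches plain AIC for large n
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  expect_error(aicc(0, 3, 4), "n > k")
})

test_that("isotropy fit recovers a constant error exactly", {
  tab <- simulate_cohort(noiseless_config())
  tab$abs_error <- 0.27          # constant by construction
  f <- fit_anisotropy(tab, "isotropy")
  expect_equal(f$fixed_estimates$intercept, 0.27, tolerance = 1e-4)
  expect_lt(f$residual_sd, 1e-3)
  expect_equal(f$k, 3)
})

test_that("isotropy marginal likelihood agrees with nlme::lme (ML)", {
  tab <- simulate_cohort(small_upright_config(seed = 23))
  f <- fit_anisotropy(tab, "isotropy")
  ref <- nlme::lme(abs_error ~ 1, random = ~ 1 | participant_id,
                   data = as.data.frame(tab), method = "ML")
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(f$fixed_estimates$intercept,
               unname(nlme::fixef(ref)[1]), tolerance = 1e-4)
})

test_that("hv fit agrees with an nlme::nlme fit of the same model", {
  tab <- as.data.frame(simulate_cohort(small_upright_config(seed = 29,
                                                            n = 12)))
  tab$ca <- cospi(tab$direction_deg / 180)
  tab$sa <- sinpi(tab$direction_deg / 180)
  ref <- nlme::nlme(
    abs_error ~ exp(b) * sqrt((wh * ca)^2 + (wv * sa)^2),
    fixed = wh + wv ~ 1, random = b ~ 1 | participant_id,
    data = tab, start = c(wh = 0.3, wv = 0.3), method = "ML")
  f <- fit_anisotropy(structure(tab, class = c("trial_table", "data.frame")),
                      "hv", gh_nodes = 25)
  expect_equal(f$fixed_estimates$w_h, unname(nlme::fixef(ref)["wh"]),
               tolerance = 0.02)
  expect_equal(f$fixed_estimates$w_v, unname(nlme::fixef(ref)["wv"]),
               tolerance = 0.02)
  # quadrature marginal likelihood should not fall below nlme's (Laplace-
  # style) approximation by any practically relevant margin
  expect_gt(f$loglik, as.numeric(stats::logLik(ref)) - 0.5)
})

test_that("fitted likelihood is at least the likelihood at the truth", {
  tab <- simulate_cohort(small_upright_config(seed = 37))
  f <- fit_anisotropy(tab, "hv")
  gh <- pracma::gaussHermite(15)
  truth_theta <- c(log(0.36), log(0.40), log(0.2), log(f$residual_sd))
  nll_truth <- pathaniso:::nll_multiplicative(
    truth_theta, tab$abs_error,
    as.integer(factor(tab$participant_id)),
    cospi(tab$direction_deg / 180), sinpi(tab$direction_deg / 180),
    "hv", gh)
  expect_gte(f$loglik, -nll_truth)
})

test_that("weights are recovered without bias away from the clip bounds", {
  # small weights keep the response far from the generator's [0, 2.5]
  # truncation, isolating the estimator itself
  cfg <- cohort_config(n_participants = 20, duration_strategy_fraction = 0,
                       orientations = "upright",
                       true_params = anisotropy_params("hv", w_h = 0.10,
                                                       w_v = 0.12))
  st <- simulation_study(12, cfg, variants = "hv", seed = 51)
  expect_true(all(st$converged))
  expect_lt(abs(mean(st$w_h) - 0.10), 3 * sd(st$w_h) / sqrt(12))
  expect_lt(abs(mean(st$w_v) - 0.12), 3 * sd(st$w_v) / sqrt(12))
})

test_that("fitting an over-parameterized variant finds the shared truth", {
  cfg <- small_upright_config(seed = 41, n = 20)
  tab <- simulate_cohort(cfg)
  f <- fit_anisotropy(tab, "fbud")
  # data generated under hv: forward/backward and up/down pairs agree
  expect_lt(abs(f$fixed_estimates$w_f - f$fixed_estimates$w_b), 0.06)
  expect_lt(abs(f$fixed_estimates$w_u - f$fixed_estimates$w_d), 0.06)
})

test_that("model comparison ranks, flags and refuses mismatched data", {
  tab <- simulate_cohort(small_upright_config(seed = 43, n = 10))
  fits <- lapply(c("isotropy", "hv", "fbud"),
                 function(v) fit_anisotropy(tab, v))
  cmp <- compare_models(fits)
  expect_equal(cmp$daicc[1], 0)
  expect_true(cmp$best[1] && !any(cmp$best[-1]))
  expect_equal(cmp$indistinguishable, cmp$daicc < 4)
  # permutation invariance of the ranking
  cmp2 <- compare_models(fits[c(3, 1, 2)])
  expect_equal(cmp2$variant, cmp$variant)
  expect_equal(cmp2$daicc, cmp$daicc)
  # differing observation sets are refused
  other <- fit_anisotropy(simulate_cohort(small_upright_config(seed = 44,
                                                               n = 10)),
                          "hv")
  expect_error(compare_models(list(fits[[1]], other)), "identical")
})

test_that("equal-AICc fits are both flagged best-indistinguishable", {
  tab <- simulate_cohort(small_upright_config(seed = 47, n = 6))
  f <- fit_anisotropy(tab, "hv")
  g <- f
  g$variant <- "hv2"
  cmp <- compare_models(list(f, g))
  expect_equal(cmp$daicc, c(0, 0))
  expect_true(all(cmp$indistinguishable))
})

test_that("dAICc separates models beyond the indistinguishability band", {
  # AICc pair as in the reference comparison of the upright condition:
  # -63.5 (best) vs -57.9 gives dAICc 5.6, beyond the < 4 band
  stub <- function(variant, aicc_val) {
    f <- list(variant = variant, aicc = aicc_val, k = 4, loglik = 0,
              converged = TRUE, data_fingerprint = c(n = 100, sum_y = 1))
    class(f) <- "anisotropy_fit"
    f
  }
  cmp <- compare_models(list(stub("isotropy", -57.9), stub("hv", -63.5)))
  expect_equal(cmp$variant, c("hv", "isotropy"))
  expect_equal(cmp$daicc, c(0, 5.6))
  expect_equal(cmp$indistinguishable, c(TRUE, FALSE))
})
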