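make_sine_recording <- function(freq, fs = 1000, dur = 2) {
  t <- seq(0, dur, by = 1 / fs)
  sig <- sin(2 * pi * freq * t)
  imu_recording(t, matrix(0, length(t), 3), cbind(sig, 0, 0), fs)
}

test_that("preprocessing removes DC offsets entirely", {
  prof <- target_profile(1, 3, 400)
  rec <- synthesize_imu(prof, 0, 0, dc_offset = c(0.5, -9.81, 0.2))
  # commanded is along x only; recorded has pure constant offsets plus cmd
  out <- preprocess_imu(rec)
  # after filtering and mean removal, recorded x should match the
  # mean-centered commanded x; y and z should be ~0
  expect_lt(max(abs(out$recorded[, 2])), 1e-9)
  expect_lt(max(abs(out$recorded[, 3])), 1e-9)
  expect_lt(abs(mean(out$recorded[, 1])), 1e-9)
})

test_that("low-pass filter attenuates per its analytic magnitude response", {
  # 4th-order Butterworth at 80 Hz, applied forward-backward: squared
  # magnitude 1/(1 + (tan(pi f/fs)/tan(pi fc/fs))^8) per pass (bilinear
  # prewarping), so amplitude gain |H|^2 after filtfilt
  gain_at <- function(freq, fs = 1000, fc = 80) {
    ratio <- tan(pi * freq / fs) / tan(pi * fc / fs)
    1 / (1 + ratio^8)   # |H|^2 = filtfilt amplitude gain
  }
  for (freq in c(10, 100)) {
    rec <- preprocess_imu(make_sine_recording(freq))
    mid <- 500:1500   # avoid filter edge transients
    got <- rms(rec$recorded[mid, 1]) / rms(sin(2 * pi * freq *
                                                 rec$time[mid]))
    expect_equal(got, gain_at(freq), tolerance = 0.05)
  }
  expect_gt(rms(preprocess_imu(make_sine_recording(10))$recorded[, 1]),
            0.65)  # passband: nearly unattenuated
})

test_that("preprocessing refuses too-low sample rates", {
  t <- seq(0, 1, by = 1 / 150)
  rec <- imu_recording(t, cbind(t, 0, 0), cbind(t, 0, 0), 150)
  expect_error(preprocess_imu(rec), "too low")
})

test_that("SNR follows its defining ratio and degenerate sentinels", {
  t <- seq(0, 10, by = 1 / 200)
  cmd <- cbind(sin(t), 0, 0)
  # recorded identically zero: the noise equals the commanded signal, so
  # numerator and denominator rms coincide and SNR = 1 exactly
  rec <- imu_recording(t, cmd, matrix(0, length(t), 3), 200)
  expect_equal(snr(rec), 1, tolerance = 1e-12)
  # noise-free: infinite sentinel, flagged
  clean <- imu_recording(t, cmd, cmd, 200)
  expect_identical(as.numeric(snr(clean)), Inf)
  expect_equal(attr(snr(clean), "degenerate"), "noise_free")
  # all-zero command
  zero <- imu_recording(t, cbind(0, 0, 0)[rep(1, length(t)), ], cmd, 200)
  expect_equal(snr(zero), 0)
})

test_that("SNR matches the closed form for iid 3-axis Gaussian noise", {
  # E[|noise|^2] = 3 sigma^2, so SNR ~ (rms(cmd)/(sigma sqrt(3)))^2
  prof <- target_profile(1.2, 3, 4000)   # > 10^4 samples
  sigma <- 0.05
  rec <- synthesize_imu(prof, 30, sigma, seed = 97)
  cmd_rms <- rms(abs(prof$acceleration))
  expect_equal(as.numeric(snr(rec)), (cmd_rms / (sigma * sqrt(3)))^2,
               tolerance = 0.05)
})

test_that("SNR scale behavior: joint scaling invariant, command quadratic", {
  prof <- target_profile(1, 3, 500)
  rec <- synthesize_imu(prof, 0, 0.05, seed = 13)
  s <- 3.7
  joint <- rec
  joint$commanded <- s * rec$commanded
  joint$recorded <- s * rec$recorded
  expect_equal(as.numeric(snr(joint)), as.numeric(snr(rec)))
  only_cmd <- rec
  noise <- rec$recorded - rec$commanded
  only_cmd$commanded <- s * rec$commanded
  only_cmd$recorded <- s * rec$commanded + noise
  expect_equal(as.numeric(snr(only_cmd)), s^2 * as.numeric(snr(rec)))
})

test_that("differential thresholds reproduce the axis formulas", {
  expect_equal(differential_threshold(1, 0), 0.08)
  expect_equal(differential_threshold(1, 180), 0.08)
  expect_equal(differential_threshold(2, 0), 0.05 * 2 + 0.03)
  expect_equal(differential_threshold(1, 90), 0.19)
  expect_equal(differential_threshold(1, -90), 0.17)
  expect_equal(differential_threshold(0.5, 90), 0.19 * 0.5^0.6)
  expect_equal(differential_threshold(0.5, -90), 0.17 * 0.5^0.42)
  expect_error(differential_threshold(-0.1, 0), "non-negative")
})

test_that("the combined threshold formula reduces at 0 but not at 90", {
  for (I in c(0.2, 1, 3)) {
    expect_equal(differential_threshold(I, 0, strict = TRUE),
                 0.05 * I + 0.03)
    # at 90 the 0.03 offset persists inside the root when read literally
    strict90 <- sqrt(0.03^2 + (0.19 * I^0.6)^2)
    expect_equal(differential_threshold(I, 90, strict = TRUE), strict90)
    expect_gt(strict90, differential_threshold(I, 90))
  }
  # oblique angles: both modes agree (hand-evaluated combination)
  I <- 1.3; a <- 60
  byhand <- sqrt((cospi(a / 180) * 0.05 * I + 0.03)^2 +
                   (sinpi(a / 180) * 0.19 * I^0.6)^2)
  expect_equal(differential_threshold(I, a), byhand)
  expect_equal(differential_threshold(I, a, strict = TRUE), byhand)
  # downward oblique selects the downward function only
  a <- -120
  byhand <- sqrt((cospi(a / 180) * 0.05 * I + 0.03)^2 +
                   (sinpi(a / 180) * 0.17 * I^0.42)^2)
  expect_equal(differential_threshold(I, a), byhand)
})

test_that("thresholds grow monotonically with intensity at every angle", {
  I <- seq(0, 4, by = 0.25)
  for (a in seq(-150, 180, by = 30)) {
    dI <- vapply(I, differential_threshold, numeric(1), alpha_deg = a)
    expect_true(all(diff(dI) >= -1e-12))
  }
})

test_that("noise-vs-threshold audit flags as constructed", {
  prof_t <- target_profile(1, 3, 400)
  prof_s <- build_test_profile(solve_test_profile(1.55, 5, 2.5), 400)
  recs <- list()
  i <- 0
  for (dir in c(0, 90)) for (ph in c("target", "test")) for (rp in 1:2) {
    i <- i + 1
    recs[[i]] <- preprocess_imu(synthesize_imu(
      if (ph == "target") prof_t else prof_s, dir, 0.02,
      seed = 1000 + i,
      label = list(phase = ph, rep = rp, distance = 1,
                   orientation = "upright")))
  }
  audit <- noise_vs_threshold(recs)
  expect_equal(nrow(audit), 2)
  expect_false(any(audit$gap))
  # equal small injected noise on both phases: differences sub-threshold
  expect_true(all(audit$sub_threshold))
  expect_true(all(audit$lowest_threshold > 0))

  # now inject a >10x-threshold noise difference at direction 0
  big <- recs
  for (j in which(vapply(big, function(r)
    r$label$direction_deg == 0 && r$label$phase == "test", logical(1)))) {
    raw <- synthesize_imu(prof_s, 0, 0.8, seed = 2000 + j,
                          label = big[[j]]$label)
    big[[j]] <- preprocess_imu(raw)
  }
  audit2 <- noise_vs_threshold(big)
  expect_false(audit2$sub_threshold[audit2$direction_deg == 0])
  expect_true(audit2$sub_threshold[audit2$direction_deg == 90])
  # missing test recordings are reported as gaps
  audit3 <- noise_vs_threshold(recs[vapply(recs, function(r)
    !(r$label$direction_deg == 90 && r$label$phase == "test"),
    logical(1))])
  expect_true(audit3$gap[audit3$direction_deg == 90])
})

test_that("two-way ANOVA handles standard and degenerate layouts", {
  dirs <- rep(rep(c("0", "90", "180"), each = 5), 2)
  orient <- rep(c("up", "pitch"), each = 15)
  # pure direction effect, no noise: direction F infinite, orientation 0
  v <- rep(rep(c(1, 2, 3), each = 5), 2)
  out <- two_way_anova(v, dirs, orient)
  expect_equal(out$F[out$effect == "direction"], Inf)
  expect_equal(out$p[out$effect == "direction"], 0)
  expect_equal(out$F[out$effect == "orientation"], 0)
  expect_equal(out$p[out$effect == "orientation"], 1)
  # all equal: everything undefined, reported as p = 1
  flat <- two_way_anova(rep(1, 30), dirs, orient)
  expect_true(all(flat$p == 1))
  expect_error(two_way_anova(v[1:20], dirs[1:20], orient[1:20]), "empty")
})

test_that("two-way ANOVA holds its nominal type-I error under the null", {
  set.seed(31)
  reps <- 400
  dirs <- factor(rep(rep(1:4, each = 5), 2))
  orient <- factor(rep(1:2, each = 20))
  p_dir <- numeric(reps)
  for (i in seq_len(reps)) {
    out <- two_way_anova(rnorm(40), dirs, orient)
    p_dir[i] <- out$p[out$effect == "direction"]
  }
  rate <- mean(p_dir < 0.05)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("synthesized recordings project onto the direction vector", {
  prof <- target_profile(1, 3, 200)
  up <- synthesize_imu(prof, 90, 0)
  expect_true(all(up$commanded[, 1] == 0))
  expect_true(all(up$commanded[, 2] == 0))
  expect_equal(up$commanded[, 3], prof$acceleration)
  expect_identical(as.numeric(snr(up)), Inf)   # zero noise sentinel
  expect_error(synthesize_imu(prof, 0, -1), "non-negative")
})

test_that("IMU traces export as CSV with sidecar label", {
  prof <- target_profile(0.5, 3, 200)
  rec <- synthesize_imu(prof, 30, 0.01, seed = 3,
                        label = list(phase = "target", rep = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(rec, path)
  got <- utils::read.csv(path)
  expect_identical(names(got), c("time", "cmd_x", "cmd_y", "cmd_z",
                                 "rec_x", "rec_y", "rec_z"))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$phase, "target")
  expect_equal(side$sample_rate, 200)
})
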