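test_that("saccade detector finds step-like resets and nothing else", {
  # slow sinusoid far below threshold: no saccades, one ISI
  t <- seq(0, 60 - 1 / 60, by = 1 / 60)
  tr <- eye_trace(t, 2 * sin(2 * pi * 0.1 * t))
  seg <- detect_saccades(tr, vel_threshold = 50)
  expect_equal(nrow(seg$saccades), 0)
  expect_equal(length(seg$isis), 1)

  # constant trace: no saccades, single ISI spanning everything
  seg0 <- detect_saccades(eye_trace(t, rep(1, length(t))))
  expect_equal(nrow(seg0$saccades), 0)
  expect_equal(length(seg0$isis), 1)
  expect_equal(length(seg0$isis[[1]]), length(t))

  # three step-like resets at known times
  steps <- c(12.3, 24.7, 39.9)
  angle <- 2 * sin(2 * pi * 0.1 * t)
  for (ts in steps) angle <- angle - 8 * (t >= ts)
  seg3 <- detect_saccades(eye_trace(t, angle))
  expect_equal(nrow(seg3$saccades), 3)
  # each detected window covers its true reset time; the onset precedes it
  # by at most the pad plus the smoothing half-window, and by no more
  for (i in seq_along(steps)) {
    expect_lte(seg3$saccades$t_start[i], steps[i])
    expect_gte(seg3$saccades$t_end[i], steps[i])
    expect_lt(steps[i] - (seg3$saccades$t_start[i] + 0.1), 6 / 60 + 1e-9)
  }
  expect_error(detect_saccades(eye_trace(t[1:30], angle[1:30])), "2 s")
})

test_that("piecewise sinusoid fit is exact on noiseless model traces", {
  # canonical example: theta(t) = -2 cos(0.6283 t), a single ISI
  tr <- model_trace(2, 0.6283, 0, 0, c(0, 60))
  seg <- detect_saccades(tr)
  fit <- fit_piecewise_sinusoid(tr, seg, f_init = 0.1)
  expect_equal(fit$c1, 2, tolerance = 1e-6)
  expect_equal(fit$c2, 0.6283, tolerance = 1e-6)
  expect_lt(abs(fit$c3), 1e-6)
  expect_lt(fit$residual_rms, 1e-6)

  # per-ISI offsets {0, 5, -3} recovered exactly
  tr3 <- model_trace(2, 0.6283, 0.4, c(0, 5, -3), c(0, 20, 40, 60))
  seg3 <- list(isis = split(seq_len(nrow(tr3)),
                            findInterval(tr3$time_s, c(20, 40))),
               saccades = tibble::tibble(), n_samples = nrow(tr3))
  class(seg3) <- "okr_segmentation"
  fit3 <- fit_piecewise_sinusoid(tr3, seg3, f_init = 0.1)
  expect_equal(fit3$c1, 2, tolerance = 1e-6)
  expect_equal(fit3$c3, 0.4, tolerance = 1e-6)
  expect_equal(fit3$offsets, c(0, 5, -3), tolerance = 1e-5)
  expect_equal(tidy(fit3)$estimate[1], fit3$c1)
  expect_equal(glance(fit3)$n_isis, 3)
})

test_that("fit recovery holds property-style over random model parameters", {
  set.seed(21)
  for (i in 1:10) {
    c1 <- runif(1, 0.5, 10)
    c2 <- 2 * pi * 0.1 * runif(1, 0.85, 1.15)
    c3 <- runif(1, -pi, pi)
    offs <- rnorm(3, 0, 5)
    tr <- model_trace(c1, c2, c3, offs, c(0, 15, 35, 60))
    seg <- list(isis = split(seq_len(nrow(tr)),
                             findInterval(tr$time_s, c(15, 35))),
                saccades = tibble::tibble(), n_samples = nrow(tr))
    class(seg) <- "okr_segmentation"
    fit <- fit_piecewise_sinusoid(tr, seg, f_init = 0.1)
    expect_equal(fit$c1, c1, tolerance = 1e-6)
    expect_equal(fit$c2, c2, tolerance = 1e-6)
    # phase compared on the circle
    expect_lt(abs(atan2(sin(fit$c3 - c3), cos(fit$c3 - c3))), 1e-5)
  }
})

test_that("amplitude estimate is robust to noise and saccade removal", {
  spec <- stimulus_spec()
  truth0 <- okr_ground_truth(sigma_trace = 0, saccade_rate = 0)
  set.seed(4)
  tr <- simulate_trace(0.2, spec, truth0)
  fit <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
  c1_ref <- fit$c1
  # adding quick-phase resets changes the recovered amplitude by < 1e-3
  set.seed(4)
  tr_s <- simulate_trace(0.2, spec, okr_ground_truth(sigma_trace = 0,
                                                     saccade_rate = 0.3))
  fit_s <- fit_piecewise_sinusoid(tr_s, detect_saccades(tr_s), f_init = 0.1)
  expect_lt(abs(fit_s$c1 - c1_ref), 1e-3)

  # Monte-Carlo: noisy gain recovery within 5%
  set.seed(8)
  rel_err <- vapply(1:30, function(i) {
    tr <- simulate_trace(0.2, spec, okr_ground_truth(sigma_trace = 0.2,
                                                     saccade_rate = 0.25))
    f <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
    f$c1 / stimulus_position_amplitude(spec) / 0.2 - 1
  }, numeric(1))
  expect_lt(median(abs(rel_err)), 0.05)
  expect_gte(mean(abs(rel_err) < 0.05), 0.9) # occasional saccade-heavy draws
  expect_lt(abs(mean(rel_err)), 0.01) # unbiased within Monte-Carlo error
})

test_that("gain is the amplitude ratio and scales with the trace", {
  spec <- stimulus_spec()
  a_s <- stimulus_position_amplitude(spec)
  tr <- model_trace(a_s, 2 * pi * 0.1, 0, 0, c(0, 60))
  fit <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
  g <- okr_gain(fit, spec)
  expect_equal(g$gain, 1, tolerance = 1e-9)

  # c1 = 1.989 with the default stimulus gives gain 0.100
  fit$c1 <- 1.98944
  expect_equal(okr_gain(fit, spec)$gain, 0.1, tolerance = 1e-4)
  fit$c1 <- 0
  expect_equal(okr_gain(fit, spec)$gain, 0)

  # scale equivariance: scaling the trace scales the gain
  lam <- 3.7
  tr_l <- eye_trace(tr$time_s, lam * tr$angle_deg)
  fit_l <- fit_piecewise_sinusoid(tr_l, detect_saccades(tr_l), f_init = 0.1)
  expect_equal(fit_l$c1 / a_s, lam * 1, tolerance = 1e-9)
})

test_that("Bode point reports magnitude and wrapped phase", {
  spec <- stimulus_spec()
  a_s <- stimulus_position_amplitude(spec)
  # eye identical to stimulus position: magnitude 1, phase 0
  tr <- model_trace(a_s, 2 * pi * 0.1, 0, 0, c(0, 60))
  fit <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
  bp <- bode_point(fit, spec)
  expect_equal(bp$magnitude, 1, tolerance = 1e-9)
  expect_lt(abs(bp$phase_deg), 1e-6)
  # eye lagging a quarter period: phase -90 degrees
  tr_l <- model_trace(a_s, 2 * pi * 0.1, -pi / 2, 0, c(0, 60))
  fit_l <- fit_piecewise_sinusoid(tr_l, detect_saccades(tr_l), f_init = 0.1)
  expect_equal(bode_point(fit_l, spec)$phase_deg, -90, tolerance = 1e-6)

  # first-order lag: simulated response phase matches the arctan law
  f <- 0.1; tau <- 1.2
  phase_true <- -atan(2 * pi * f * tau) # radians
  tr_f <- model_trace(a_s / sqrt(1 + (2 * pi * f * tau)^2), 2 * pi * f,
                      phase_true, 0, c(0, 60))
  fit_f <- fit_piecewise_sinusoid(tr_f, detect_saccades(tr_f), f_init = 0.1)
  expect_lt(abs(bode_point(fit_f, spec)$phase_deg - phase_true * 180 / pi),
            2)
})

test_that("trial QC accepts clean fits and rejects drift and noise", {
  spec <- stimulus_spec()
  tr <- model_trace(2, 2 * pi * 0.1, 0, 0, c(0, 60))
  fit <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
  expect_true(qc_trial(fit)$accept)

  # superimposed 0.5 deg/s linear drift
  tr_d <- eye_trace(tr$time_s, tr$angle_deg + 0.5 * tr$time_s)
  fit_d <- fit_piecewise_sinusoid(tr_d, detect_saccades(tr_d), f_init = 0.1)
  qc_d <- qc_trial(fit_d)
  expect_false(qc_d$accept)
  expect_equal(qc_d$reason, "drift")

  # pure noise
  set.seed(13)
  tr_n <- eye_trace(tr$time_s, rnorm(nrow(tr), 0, 1))
  fit_n <- fit_piecewise_sinusoid(tr_n, detect_saccades(tr_n, vel_threshold = 1e6),
                                  f_init = 0.1)
  qc_n <- qc_trial(fit_n)
  expect_false(qc_n$accept)
  expect_equal(qc_n$reason, "low_r2")
})
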