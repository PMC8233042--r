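test_that("gain simulation composes surface, bias and yoking as specified", {
  truth0 <- okr_ground_truth(Y0 = 0, b1 = 0, b2 = 0, sigma_b3 = 0)
  # perfect yoking: both eyes always equal
  g <- simulate_gain(-85, 5, truth = truth0, noise = FALSE)
  expect_equal(g$g_L, g$g_R)
  # complete monocularity: unstimulated eye is silent
  truth1 <- okr_ground_truth(Y0 = 1)
  g1 <- simulate_gain(-85, 5, truth = truth1, noise = FALSE)
  expect_equal(g1$stimulated, "left")
  expect_equal(g1$g_R, 0)
  # degenerate generator: zero biases and noise at a component centre
  truth <- okr_ground_truth(Y0 = 0)
  m1 <- truth$vmf$mu1
  g2 <- simulate_gain(m1[1], m1[2], truth = truth, noise = FALSE)
  expect_equal(g2$g_L, vmf_sum_eval(truth$vmf, m1[1], m1[2]))
  # empirical yoking index converges to Y0
  truth_y <- okr_ground_truth(Y0 = 0.2, sigma_gain = 0)
  gy <- simulate_gain(-85, 5, truth = truth_y, noise = FALSE)
  expect_equal(yoking_index(gy$g_L, gy$g_R)$Y, 0.2, tolerance = 1e-12)
})

test_that("hemispheric bias enters multiplicatively with the right sign", {
  truth_b <- okr_ground_truth(Y0 = 0, b1 = 0.1, b2 = -0.05, sigma_b3 = 0)
  base <- okr_ground_truth(Y0 = 0)
  a <- 1 * 0.1 - 0.05
  gl <- simulate_gain(-85, 5, truth = truth_b, noise = FALSE)$g_L
  gl0 <- simulate_gain(-85, 5, truth = base, noise = FALSE)$g_L
  expect_equal(gl / gl0, 1 + a, tolerance = 1e-12)
  gr <- simulate_gain(85, 5, truth = truth_b, noise = FALSE)$g_R
  gr0 <- simulate_gain(85, 5, truth = base, noise = FALSE)$g_R
  expect_equal(gr / gr0, 1 - a, tolerance = 1e-12)
  # flipping the arena orientation flips the b1 contribution only
  truth_b2 <- okr_ground_truth(Y0 = 0, b1 = 0.1, b2 = -0.05, sigma_b3 = 0)
  gl_flip <- simulate_gain(-85, 5, truth = truth_b2, arena_orientation = -1,
                           noise = FALSE)$g_L
  expect_equal(gl_flip / gl0, 1 + (-0.1 - 0.05), tolerance = 1e-12)
})

test_that("trace simulation round-trips through the trace analysis", {
  spec <- stimulus_spec()
  clean <- okr_ground_truth(sigma_trace = 0, saccade_rate = 0)
  set.seed(2)
  tr <- simulate_trace(0.12, spec, clean)
  fit <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
  expect_equal(fit$c1 / stimulus_position_amplitude(spec), 0.12,
               tolerance = 1e-6)
  # zero gain: flat trace plus noise only
  set.seed(3)
  tr0 <- simulate_trace(0, spec, okr_ground_truth(sigma_trace = 0.05,
                                                  saccade_rate = 0))
  expect_lt(diff(range(tr0$angle_deg)), 1) # no oscillation beyond noise
  # noisy with saccades: gain recovered within 5% across seeds
  set.seed(14)
  rel <- vapply(1:15, function(i) {
    tr <- simulate_trace(0.12, spec,
                         okr_ground_truth(sigma_trace = 0.1,
                                          saccade_rate = 0.3))
    f <- fit_piecewise_sinusoid(tr, detect_saccades(tr), f_init = 0.1)
    f$c1 / stimulus_position_amplitude(spec) / 0.12 - 1
  }, numeric(1))
  expect_lt(median(abs(rel)), 0.05)
  expect_gte(mean(abs(rel) < 0.05), 0.85)
})

test_that("dataset generation is complete and deterministic", {
  ctr <- default_centres()
  co <- synthetic_cohort(n_fish = 7, centres = ctr, n_reps = 2, seed = 5)
  ds <- generate_dataset(co)
  # 7 fish x 38 positions x 2 reps = 532 phases -> 1064 eye records
  expect_equal(nrow(ds$records), 1064)
  expect_equal(nrow(dplyr::distinct(
    ds$records, .data$fish_id, .data$stimulus_id, .data$repetition
  )), 532)
  # same seed twice: identical tables
  ds2 <- generate_dataset(synthetic_cohort(n_fish = 7, centres = ctr,
                                           n_reps = 2, seed = 5))
  expect_identical(ds$records, ds2$records)
  # different seed: different gains
  ds3 <- generate_dataset(synthetic_cohort(n_fish = 7, centres = ctr,
                                           n_reps = 2, seed = 6))
  expect_false(identical(ds$records$gain, ds3$records$gain))
  expect_error(
    generate_dataset(synthetic_cohort(centres = ctr[0, ], seed = 1)),
    "empty"
  )
})

test_that("empirical yoking over many trials converges to Y0", {
  ctr <- default_centres()
  truth <- okr_ground_truth(Y0 = 0.25, sigma_gain = 0.005)
  co <- synthetic_cohort(n_fish = 10, centres = ctr, n_reps = 2,
                         truth = truth, seed = 8)
  ds <- generate_dataset(co)
  wide <- tidyr::pivot_wider(
    ds$records,
    id_cols = c("fish_id", "stimulus_id", "repetition", "stimulated"),
    names_from = "eye", values_from = "gain"
  )
  mono <- wide[wide$stimulated %in% c("left", "right"), ]
  y <- yoking_index(mono$left, mono$right)$Y
  # sign follows the stimulated eye; fold to the stimulated side
  y_folded <- ifelse(mono$stimulated == "left", y, -y)
  expect_equal(mean(y_folded, na.rm = TRUE), 0.25, tolerance = 0.05)
})

test_that("end-to-end generation and fitting recovers the surface centres", {
  ctr <- default_centres()
  errs <- vapply(1:3, function(sd) {
    co <- synthetic_cohort(n_fish = 7, centres = ctr, n_reps = 2, seed = sd)
    ds <- generate_dataset(co)
    direct <- ds$records[
      ds$records$stimulated == "both" |
        ds$records$stimulated == ds$records$eye, ]
    f <- fit_bimodal_vmf(direct, seed = sd)
    mean(c(
      great_circle_angle(f$model$mu1[1], f$model$mu1[2], -82.5, 5.1),
      great_circle_angle(f$model$mu2[1], f$model$mu2[2], 81.7, 1.6)
    ))
  }, numeric(1))
  expect_lt(median(errs), 5)
})
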