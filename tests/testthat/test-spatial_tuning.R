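test_that("vMF surface evaluation matches the closed form", {
  m <- vmf_model(mu1 = c(0, 0), kappa1 = 1, C1 = 1, C2 = 0, C3 = 0)
  # at the centre: kappa e^kappa / (4 pi sinh kappa)
  expect_equal(vmf_sum_eval(m, 0, 0), exp(1) / (4 * pi * sinh(1)),
               tolerance = 1e-10)
  expect_equal(round(vmf_sum_eval(m, 0, 0), 5), 0.18407)
  # antipode: kappa e^-kappa / (4 pi sinh kappa)
  expect_equal(vmf_sum_eval(m, 180, 0), exp(-1) / (4 * pi * sinh(1)),
               tolerance = 1e-10)
  expect_equal(round(vmf_sum_eval(m, 180, 0), 5), 0.02491)
  # zero masses leave only the offset
  m0 <- vmf_model(C1 = 0, C2 = 0, C3 = 0.7)
  expect_equal(vmf_sum_eval(m0, c(-120, 0, 45), c(10, -80, 0)),
               rep(0.7, 3))
  expect_error(vmf_model(kappa1 = 0), "kappa1")
})

test_that("log-domain evaluation agrees with the naive form and survives large kappa", {
  naive <- function(kappa, t) {
    kappa * exp(kappa * t) / (2 * pi * (exp(kappa) - exp(-kappa)))
  }
  set.seed(2)
  for (kappa in c(0.5, 5, 50, 100)) {
    t <- runif(20, -1, 1)
    expect_equal(exp(okrsphere:::vmf_log_kernel(kappa, t)), naive(kappa, t),
                 tolerance = 1e-10)
  }
  m_big <- vmf_model(kappa1 = 700, kappa2 = 700)
  v <- vmf_sum_eval(m_big, c(-82.5, 0), c(5.1, 0))
  expect_true(all(is.finite(v)))
})

test_that("offset-free surface integrates to the component masses", {
  m <- vmf_model(mu1 = c(-82.5, 5.1), mu2 = c(81.7, 1.6),
                 kappa1 = 8, kappa2 = 3, C1 = 0.22, C2 = 0.4, C3 = 0.05)
  expect_equal(integrate_vmf_excess(m), m$C1 + m$C2, tolerance = 1e-4)
  # and for a tighter component
  m2 <- vmf_model(kappa1 = 40, kappa2 = 8, C1 = 1.3, C2 = 0.2, C3 = 0)
  expect_equal(integrate_vmf_excess(m2), 1.5, tolerance = 1e-4)
})

test_that("bimodal vMF fit recovers a noiseless surface on the 38 centres", {
  ctr <- default_centres()
  truth <- vmf_model(mu1 = c(-82.5, 5.1), mu2 = c(81.7, 1.6),
                     kappa1 = 8, kappa2 = 8, C1 = 0.22, C2 = 0.22,
                     C3 = 0.02)
  rec <- tibble::tibble(azimuth = ctr$azimuth, elevation = ctr$elevation,
                        gain = vmf_sum_eval(truth, ctr$azimuth, ctr$elevation))
  fit <- fit_bimodal_vmf(rec)
  expect_lt(great_circle_angle(fit$model$mu1[1], fit$model$mu1[2],
                               -82.5, 5.1), 0.5)
  expect_lt(great_circle_angle(fit$model$mu2[1], fit$model$mu2[2],
                               81.7, 1.6), 0.5)
  expect_gt(fit$r_squared, 0.999)
  # mirror-symmetric input produces mirror-symmetric component centres
  sym <- vmf_model(mu1 = c(-80, 10), mu2 = c(80, 10), kappa1 = 6,
                   kappa2 = 6, C1 = 0.3, C2 = 0.3, C3 = 0.01)
  rec_s <- tibble::tibble(azimuth = ctr$azimuth, elevation = ctr$elevation,
                          gain = vmf_sum_eval(sym, ctr$azimuth, ctr$elevation))
  fit_s <- fit_bimodal_vmf(rec_s)
  expect_equal(fit_s$model$mu1[1], -fit_s$model$mu2[1], tolerance = 0.01)
  expect_equal(fit_s$model$mu1[2], fit_s$model$mu2[2], tolerance = 0.01)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_equal(td$component, c("mu1", "mu2"))
  expect_false(glance(fit)$degenerate)
  # degenerate: all-equal gains
  flat <- tibble::tibble(azimuth = ctr$azimuth, elevation = ctr$elevation,
                         gain = 0.2)
  expect_true(fit_bimodal_vmf(flat)$degenerate)
  expect_error(fit_bimodal_vmf(rec[1:8, ]), "11")
})

test_that("vMF fit tolerates noise at the cohort level", {
  ctr <- default_centres()
  truth <- okr_ground_truth()
  set.seed(31)
  errs <- vapply(1:5, function(i) {
    g <- vmf_sum_eval(truth$vmf, ctr$azimuth, ctr$elevation)
    # a cohort's worth of observations: 7 fish x 2 repetitions per position
    rec <- tidyr::expand_grid(pos = seq_len(38), fish = 1:7, rep = 1:2)
    rec$azimuth <- ctr$azimuth[rec$pos]
    rec$elevation <- ctr$elevation[rec$pos]
    rec$gain <- pmax(0, g[rec$pos] + rnorm(nrow(rec), 0, 0.2 * max(g)))
    f <- fit_bimodal_vmf(rec, seed = i)
    mean(c(
      great_circle_angle(f$model$mu1[1], f$model$mu1[2], -82.5, 5.1),
      great_circle_angle(f$model$mu2[1], f$model$mu2[2], 81.7, 1.6)
    ))
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("kernel smoothing behaves at its limits", {
  one <- tibble::tibble(azimuth = 30, elevation = 10, gain = 0.3)
  sm <- vmf_kernel_smooth(one, kappa_smooth = 5)
  expect_equal(sm$gain, rep(0.3, nrow(sm)))
  # very concentrated kernel at a sample point returns that sample's gain
  two <- tibble::tibble(azimuth = c(-60, 60), elevation = c(0, 0),
                        gain = c(0.1, 0.5))
  at <- tibble::tibble(azimuth = -60, elevation = 0)
  expect_equal(vmf_kernel_smooth(two, kappa_smooth = 500, grid = at)$gain,
               0.1, tolerance = 1e-6)
  # two antipodal records: midpoint gets the mean
  anti <- tibble::tibble(azimuth = c(90, -90), elevation = c(0, 0),
                         gain = c(0.2, 0.4))
  mid <- tibble::tibble(azimuth = 0, elevation = 0)
  expect_equal(vmf_kernel_smooth(anti, kappa_smooth = 2, grid = mid)$gain, 0.3)
  expect_error(vmf_kernel_smooth(one[0, ]), "no records")
})

test_that("arena-rotation correction averages the per-position medians", {
  orig <- tibble::tibble(azimuth = c(30, 30, -40), elevation = c(10, 10, 0),
                         gain = c(0.1, 0.3, 0.5))
  # rotated table: positions recorded in rotated-arena coordinates
  rot <- tibble::tibble(azimuth = c(-30, 40), elevation = c(-10, 0),
                        gain = c(0.4, 0.1))
  out <- correct_arena_rotation(orig, rot)
  expect_equal(nrow(out), 2)
  at30 <- out[out$azimuth == 30, ]
  expect_equal(at30$gain, (0.2 + 0.4) / 2) # mean of medians 0.2 and 0.4
  # identical tables: corrected equals the per-position medians
  both <- tibble::tibble(azimuth = c(10, 10, -10, -10),
                         elevation = 0, gain = c(0.2, 0.4, 0.1, 0.3))
  both_rot <- both
  both_rot$azimuth <- -both$azimuth # so the remap maps them back
  both_rot$elevation <- -both$elevation
  idem <- correct_arena_rotation(both, both_rot)
  expect_equal(sort(idem$gain), c(0.2, 0.3))
  # odd-in-phi additive bias cancels exactly in expectation
  set.seed(5)
  base <- tibble::tibble(azimuth = rep(c(-60, 60), each = 40),
                         elevation = 0,
                         gain = rep(c(0.2, 0.35), each = 40))
  b <- 0.07
  orig_b <- base; orig_b$gain <- orig_b$gain + b + rnorm(80, 0, 0.01)
  rot_b <- base; rot_b$gain <- rot_b$gain - b + rnorm(80, 0, 0.01)
  rot_b$azimuth <- -rot_b$azimuth; rot_b$elevation <- -rot_b$elevation
  corr <- correct_arena_rotation(orig_b, rot_b)
  expect_equal(sort(corr$gain), c(0.2, 0.35), tolerance = 0.02)
})

test_that("frequency tuning finds the log-Gaussian peak and flags edge cases", {
  freqs <- c(0.01, 0.02, 0.03, 0.05, 0.08, 0.13, 0.2)
  gains <- 0.3 * exp(-(log(freqs) - log(0.04))^2 / (2 * 0.5^2))
  rec <- tidyr::expand_grid(location_id = c("L1", "L2"),
                            spatial_frequency = freqs)
  rec$gain <- rep(gains, 2)
  fit <- frequency_tuning(rec)
  expect_equal(nrow(fit$per_location), 2)
  # peak inside the sampled interval containing 0.04
  expect_true(all(fit$per_location$peak_frequency > 0.03 &
                    fit$per_location$peak_frequency < 0.05))
  expect_true(all(fit$per_location$flag == "ok"))
  # flat profile flagged
  flat <- tibble::tibble(location_id = "L", spatial_frequency = freqs,
                         gain = 0.2)
  expect_equal(frequency_tuning(flat)$per_location$flag, "flat")
  # monotone profile flagged as boundary peak
  mono <- tibble::tibble(location_id = "L", spatial_frequency = freqs,
                         gain = seq(0.1, 0.4, length.out = 7))
  expect_equal(frequency_tuning(mono)$per_location$flag, "boundary_peak")
  expect_error(
    frequency_tuning(tibble::tibble(location_id = "L",
                                    spatial_frequency = 0.05, gain = 0.2)),
    ">= 3"
  )
})

test_that("size tuning recovers the half-maximum size", {
  sizes <- exp(seq(log(0.008), log(1), length.out = 7))
  sig <- function(s, g_max, s50, w) g_max / (1 + exp(-(log(s) - log(s50)) / w))
  rec <- tibble::tibble(location_id = "L", size = sizes,
                        gain = sig(sizes, 0.3, 0.25, 1))
  fit <- size_tuning_fit(rec)
  expect_equal(fit$per_location$s50, 0.25, tolerance = 1e-3 / 0.25)
  expect_equal(fit$per_location$g_max, 0.3, tolerance = 1e-3)
  # invariance: relabelling sizes from fractions to half-angles and back via
  # cap_fraction leaves the fitted s50 unchanged
  half_angles <- 180 / pi * acos(1 - 2 * sizes) # inverse of cap_fraction
  rec2 <- rec
  rec2$size <- cap_fraction(half_angles)
  expect_equal(size_tuning_fit(rec2)$per_location$s50,
               fit$per_location$s50, tolerance = 1e-9)
  # zero surface: flagged flat
  rec0 <- rec; rec0$gain <- 0
  expect_equal(size_tuning_fit(rec0)$per_location$flag, "flat")
  expect_error(size_tuning_fit(rec[1:3, ]), "decade|4")
  # noisy replicates at cohort scale (7 fish x 2 reps per size, 20%
  # multiplicative noise): median log-error of s50 below 0.2
  set.seed(17)
  err <- vapply(1:20, function(i) {
    r <- tidyr::expand_grid(location_id = "L", size = sizes, rep = 1:14)
    r$gain <- pmax(0, sig(r$size, 0.3, 0.25, 0.7) *
                     (1 + rnorm(nrow(r), 0, 0.2)))
    abs(log(size_tuning_fit(r)$per_location$s50) - log(0.25))
  }, numeric(1))
  expect_lt(median(err), 0.2)
})

test_that("direct visibility classifies stimuli against the eye axes", {
  expect_equal(direct_visibility(90, 0, 20, "right"), "direct")
  expect_equal(direct_visibility(-90, 0, 20, "right"), "indirect")
  expect_equal(direct_visibility(-90, 0, 20, "left"), "direct")
  # full surround field of view sees everything
  expect_equal(direct_visibility(-90, 0, 20, "right", fov = 360), "direct")
  # custom axis
  expect_equal(direct_visibility(0, 0, 5, "right", eye_axis = c(0, 0)),
               "direct")
})
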