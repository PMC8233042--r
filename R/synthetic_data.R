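#' Ground-truth parameter set for the synthetic cohort generator
#'
#' Collects every parameter of the generative model: the bimodal vMF gain
#' surface (component centres defaulting to the measured preferred locations
#' (-82.5, 5.1) and (81.7, 1.6) degrees), the yoking index `Y0` between
#' stimulated and unstimulated eye, the arena-induced (`b1`), shared (`b2`)
#' and per-fish (`sigma_b3`) hemispheric biases, additive gain noise, trace
#' measurement noise, the quick-phase (saccade) rate and amplitude
#' distribution, and the probability of injecting a slow drift into a trial.
#' Magnitudes that the experiment does not pin down (noise levels, saccade
#' statistics, peak gain) are explicit, documented defaults.
#'
#' @param vmf An `okr_vmf` gain surface; the default is scaled so the peak
#'   gain is `peak_gain`.
#' @param peak_gain Peak gain of the default surface.
#' @param Y0 Yoking index between stimulated and unstimulated eye, `[-1, 1]`.
#' @param b1,b2 Arena-induced and shared multiplicative hemisphere biases.
#' @param sigma_b3 Standard deviation of per-fish biases.
#' @param sigma_gain Additive gain noise sd, in gain units (default 20% of
#'   `peak_gain`).
#' @param sigma_trace Additive angular noise on traces, degrees.
#' @param saccade_rate Quick-phase rate, Hz.
#' @param saccade_amp_mean,saccade_amp_sd Quick-phase amplitude distribution
#'   (Normal truncated positive), degrees.
#' @param drift_prob Per-trial probability of a superimposed linear drift.
#' @param drift_slope Drift slope when injected, degree/s.
#' @return An object of class `okr_truth` (a list of the above).
#' @export
okr_ground_truth <- function(vmf = NULL, peak_gain = 0.3, Y0 = 0.2,
                             b1 = 0, b2 = 0, sigma_b3 = 0.01,
                             sigma_gain = 0.2 * peak_gain,
                             sigma_trace = 0.1, saccade_rate = 0.25,
                             saccade_amp_mean = 8, saccade_amp_sd = 2,
                             drift_prob = 0, drift_slope = 0.5) {
  stopifnot(Y0 >= -1, Y0 <= 1, sigma_b3 >= 0, sigma_gain >= 0,
            sigma_trace >= 0, saccade_rate >= 0,
            drift_prob >= 0, drift_prob <= 1)
  if (is.null(vmf)) {
    base <- vmf_model(kappa1 = 8, kappa2 = 8, C1 = 1, C2 = 1, C3 = 0.02)
    pk <- max(
      vmf_sum_eval(base, base$mu1[1], base$mu1[2]),
      vmf_sum_eval(base, base$mu2[1], base$mu2[2])
    )
    sc <- (peak_gain - base$C3) / (pk - base$C3)
    vmf <- vmf_model(
      mu1 = base$mu1, mu2 = base$mu2, kappa1 = 8, kappa2 = 8,
      C1 = sc, C2 = sc, C3 = base$C3
    )
  }
  structure(
    list(
      vmf = vmf, Y0 = Y0, b1 = b1, b2 = b2, sigma_b3 = sigma_b3,
      sigma_gain = sigma_gain, sigma_trace = sigma_trace,
      saccade_rate = saccade_rate, saccade_amp_mean = saccade_amp_mean,
      saccade_amp_sd = saccade_amp_sd, drift_prob = drift_prob,
      drift_slope = drift_slope
    ),
    class = "okr_truth"
  )
}

#' Define a synthetic cohort of fish and a stimulus protocol
#'
#' @param n_fish Number of fish.
#' @param centres Stimulus-centre tibble (`stimulus_id`, `azimuth`,
#'   `elevation`), e.g. from [place_stimulus_centres()].
#' @param crop_half_angle Crop-disk half-angle of each positioned stimulus,
#'   degrees (the position-tuning protocol uses 20, i.e. a 40-degree disk).
#' @param n_reps Stimulus repetitions per fish.
#' @param truth An `okr_truth`; per-fish biases are drawn from it.
#' @param arena_orientation `+1` or `-1` for every fish in this cohort.
#' @param embedding `"upright"` or `"inverted"`.
#' @param seed RNG seed (controls per-fish biases).
#' @return An object of class `okr_cohort`: list with tibble `fish`
#'   (`fish_id`, `b3`, `embedding`), the protocol tibble, and parameters.
#' @export
synthetic_cohort <- function(n_fish = 7, centres = NULL,
                             crop_half_angle = 20, n_reps = 2,
                             truth = okr_ground_truth(),
                             arena_orientation = 1,
                             embedding = "upright", seed = 1) {
  stopifnot(inherits(truth, "okr_truth"), n_fish >= 1, n_reps >= 1)
  if (is.null(centres)) centres <- place_stimulus_centres(seed = seed)
  set.seed(seed)
  fish <- tibble::tibble(
    fish_id = sprintf("f%02d", seq_len(n_fish)),
    b3 = stats::rnorm(n_fish, 0, truth$sigma_b3),
    embedding = embedding
  )
  structure(
    list(
      fish = fish, centres = centres, crop_half_angle = crop_half_angle,
      n_reps = n_reps, arena_orientation = arena_orientation,
      truth = truth, seed = seed
    ),
    class = "okr_cohort"
  )
}

#' @export
print.okr_cohort <- function(x, ...) {
  cat("<okr_cohort>", nrow(x$fish), "fish x", nrow(x$centres),
      "stimulus positions x", x$n_reps, "reps, arena orientation",
      x$arena_orientation, "\n")
  invisible(x)
}

#' Simulate the pair of eye gains for one stimulus presentation
#'
#' The generative model composes the pieces the analysis estimates: the base
#' gain is the vMF surface at the stimulus centre; it is modulated
#' multiplicatively by the hemispheric bias `(1 + h (phi b1 + b2 + b3_k))`
#' with `h = +1` for left-hemisphere and `h = -1` for right-hemisphere
#' stimuli (so the bias index `B` recovers `phi b1 + b2 + b3_k` to first
#' order); the stimulated eye receives this gain plus additive noise; the
#' unstimulated eye is yoked at `g (1 - Y0) / (1 + Y0)`. Gains truncate at
#' zero. A stimulus directly visible to both eyes drives both directly.
#'
#' @param azimuth,elevation Stimulus-centre direction, degrees.
#' @param b3 Individual bias of this fish.
#' @param truth An `okr_truth`.
#' @param crop_half_angle Stimulus disk half-angle, degrees.
#' @param arena_orientation phi, `+1` or `-1`.
#' @param noise Logical: add gain noise?
#' @return A one-row tibble with `g_L`, `g_R` and `stimulated`
#'   (`"left"`, `"right"` or `"both"`).
#' @export
simulate_gain <- function(azimuth, elevation, b3 = 0,
                          truth = okr_ground_truth(), crop_half_angle = 20,
                          arena_orientation = 1, noise = TRUE) {
  stopifnot(inherits(truth, "okr_truth"))
  base <- vmf_sum_eval(truth$vmf, azimuth, elevation)
  a <- arena_orientation * truth$b1 + truth$b2 + b3
  h <- dplyr::case_when(
    wrap_az(azimuth) < 0 & abs(wrap_az(azimuth)) < 180 ~ 1,
    wrap_az(azimuth) > 0 & wrap_az(azimuth) < 180 ~ -1,
    TRUE ~ 0
  )
  g_stim <- base * (1 + h * a)
  vis_l <- direct_visibility(azimuth, elevation, crop_half_angle, "left")
  vis_r <- direct_visibility(azimuth, elevation, crop_half_angle, "right")
  yoke <- (1 - truth$Y0) / (1 + truth$Y0)
  stimulated <- dplyr::case_when(
    vis_l == "direct" & vis_r == "direct" ~ "both",
    vis_l == "direct" ~ "left",
    vis_r == "direct" ~ "right",
    TRUE ~ "none"
  )
  g_L <- switch(stimulated,
    both = g_stim, left = g_stim, right = g_stim * yoke, none = g_stim * yoke
  )
  g_R <- switch(stimulated,
    both = g_stim, right = g_stim, left = g_stim * yoke, none = g_stim * yoke
  )
  if (noise) {
    g_L <- g_L + stats::rnorm(1, 0, truth$sigma_gain)
    g_R <- g_R + stats::rnorm(1, 0, truth$sigma_gain)
  }
  tibble::tibble(
    g_L = pmax(0, g_L), g_R = pmax(0, g_R), stimulated = stimulated
  )
}

#' Simulate a raw eye-position trace for a given gain
#'
#' The slow phase follows the stimulus sinusoid scaled by the gain,
#' `-g a_S cos(2 pi f t)`; quick phases occur as a Poisson process at the
#' ground-truth saccade rate, each a step directed against the current
#' stimulus velocity with amplitude drawn from a truncated normal, smeared
#' over ~50 ms as real saccades are; Gaussian measurement noise is added and
#' the trace is sampled at `sampling_rate`. With probability `drift_prob` a
#' linear drift of slope `drift_slope` is superimposed.
#'
#' @param gain Slow-phase gain g >= 0.
#' @param spec An `okr_stimulus`.
#' @param truth An `okr_truth`.
#' @param sampling_rate Sampling rate, Hz.
#' @param eye,fish_id,stimulus_id Metadata for the returned trace.
#' @return An `okr_trace` tibble; its `saccade_times` attribute carries the
#'   ground-truth quick-phase onset times.
#' @export
simulate_trace <- function(gain, spec, truth = okr_ground_truth(),
                           sampling_rate = 60, eye = "left", fish_id = "f1",
                           stimulus_id = "D1") {
  stopifnot(gain >= 0, inherits(spec, "okr_stimulus"),
            inherits(truth, "okr_truth"))
  t <- seq(0, spec$phase_duration - 1 / sampling_rate, by = 1 / sampling_rate)
  a_s <- stimulus_position_amplitude(spec)
  f <- spec$envelope_frequency
  slow <- -gain * a_s * cos(2 * pi * f * t)
  n_sac <- stats::rpois(1, truth$saccade_rate * spec$phase_duration)
  offset <- numeric(length(t))
  sac_times <- sort(stats::runif(n_sac, 1, spec$phase_duration - 1))
  for (ts in sac_times) {
    amp <- abs(stats::rnorm(1, truth$saccade_amp_mean, truth$saccade_amp_sd))
    # stimulus velocity sign at saccade time; quick phase resets against it
    v_sign <- sign(sin(2 * pi * f * ts))
    if (v_sign == 0) v_sign <- 1
    step <- -v_sign * amp
    ramp <- pmin(1, pmax(0, (t - ts) / 0.05)) # ~50 ms saccade duration
    offset <- offset + step * ramp
  }
  drift <- if (stats::runif(1) < truth$drift_prob) {
    truth$drift_slope * (t - mean(t))
  } else 0
  angle <- slow + offset + drift +
    stats::rnorm(length(t), 0, truth$sigma_trace)
  out <- eye_trace(t, angle, eye = eye, fish_id = fish_id,
                   stimulus_id = stimulus_id)
  attr(out, "saccade_times") <- sac_times
  attr(out, "true_gain") <- gain
  out
}

#' Generate a complete synthetic dataset
#'
#' One stimulus phase per (fish, stimulus, repetition) yields a pair of gain
#' records (left and right eye) and, optionally, the pair of raw traces.
#' Fully deterministic under the cohort seed.
#'
#' @param cohort An `okr_cohort`.
#' @param truth Overrides the cohort's `okr_truth` if given.
#' @param traces Logical: also simulate raw eye traces (slower)?
#' @param spec Stimulus kinematics used for all phases (positions come from
#'   the cohort's centre list).
#' @return A list with `records` (tibble: fish_id, eye, stimulus_id,
#'   repetition, azimuth, elevation, gain, stimulated, arena_orientation,
#'   embedding) and `traces` (a tibble with a list-column `trace`, or `NULL`).
#' @export
generate_dataset <- function(cohort, truth = NULL, traces = FALSE,
                             spec = stimulus_spec()) {
  stopifnot(inherits(cohort, "okr_cohort"))
  if (is.null(truth)) truth <- cohort$truth
  if (nrow(cohort$centres) == 0) stop("empty stimulus protocol", call. = FALSE)
  set.seed(cohort$seed + 1e4)
  grid <- tidyr::expand_grid(
    fish_id = cohort$fish$fish_id,
    stimulus_id = cohort$centres$stimulus_id,
    repetition = seq_len(cohort$n_reps)
  )
  grid <- dplyr::left_join(grid, cohort$fish[, c("fish_id", "b3", "embedding")],
                           by = "fish_id")
  grid <- dplyr::left_join(grid, cohort$centres, by = "stimulus_id")
  recs <- purrr::pmap_dfr(
    grid,
    function(fish_id, stimulus_id, repetition, b3, embedding,
             azimuth, elevation, ...) {
      g <- simulate_gain(
        azimuth, elevation, b3 = b3, truth = truth,
        crop_half_angle = cohort$crop_half_angle,
        arena_orientation = cohort$arena_orientation
      )
      tibble::tibble(
        fish_id = fish_id,
        eye = c("left", "right"),
        stimulus_id = stimulus_id,
        repetition = repetition,
        azimuth = azimuth, elevation = elevation,
        gain = c(g$g_L, g$g_R),
        stimulated = g$stimulated,
        direct = (g$stimulated == "both") |
          (g$stimulated == c("left", "right")),
        arena_orientation = cohort$arena_orientation,
        embedding = embedding
      )
    }
  )
  tr <- NULL
  if (traces) {
    tr <- recs
    tr$trace <- purrr::pmap(
      recs[, c("gain", "eye", "fish_id", "stimulus_id")],
      function(gain, eye, fish_id, stimulus_id) {
        simulate_trace(gain, spec, truth, eye = eye, fish_id = fish_id,
                       stimulus_id = stimulus_id)
      }
    )
  }
  list(records = recs, traces = tr, truth = truth, cohort = cohort)
}
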