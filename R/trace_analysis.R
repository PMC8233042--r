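#' Build an eye-position trace
#'
#' A trace is a tibble with one row per video frame: `time_s` (strictly
#' increasing) and `angle_deg` (horizontal eye position, degrees). Metadata
#' identifying the recording travels in ordinary columns so traces bind and
#' group naturally.
#'
#' @param time_s Time stamps, s.
#' @param angle_deg Horizontal eye position, degrees.
#' @param eye `"left"` or `"right"`.
#' @param fish_id,stimulus_id Identifiers.
#' @return A tibble of class `okr_trace`.
#' @export
eye_trace <- function(time_s, angle_deg, eye = "left", fish_id = "f1",
                      stimulus_id = "D1") {
  if (length(time_s) == 0) stop("empty trace", call. = FALSE)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing",
                                   call. = FALSE)
  if (any(!is.finite(angle_deg))) stop("angles must be finite", call. = FALSE)
  out <- tibble::tibble(
    time_s = as.numeric(time_s), angle_deg = as.numeric(angle_deg),
    eye = eye, fish_id = fish_id, stimulus_id = stimulus_id
  )
  class(out) <- c("okr_trace", class(out))
  out
}

#' Detect saccades and segment a trace into inter-saccade intervals
#'
#' Eye velocity is estimated with a Savitzky-Golay smoothed derivative
#' (`signal::sgolayfilt`); samples where `|velocity|` exceeds
#' `vel_threshold` are marked saccadic, events closer than `min_separation`
#' are merged, and each event is widened by `pad` on both sides. The
#' complementary segments are the inter-saccade intervals (ISIs) used for the
#' slow-phase fit.
#'
#' @param trace An `okr_trace` (or any tibble with `time_s`, `angle_deg`).
#' @param vel_threshold Saccade velocity threshold, degree/s.
#' @param min_separation Events closer than this are merged, s.
#' @param pad Widening applied to each saccade window, s.
#' @param sg_order,sg_length Savitzky-Golay polynomial order and (odd) window
#'   length in samples.
#' @return An object of class `okr_segmentation`: list with tibble `saccades`
#'   (`t_start`, `t_end`) and `isis`, a list of integer index ranges into the
#'   trace.
#' @export
detect_saccades <- function(trace, vel_threshold = 40, min_separation = 0.5,
                            pad = 0.1, sg_order = 3, sg_length = 9) {
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  t <- trace$time_s
  x <- trace$angle_deg
  if (max(t) - min(t) < 2) {
    stop("need at least 2 s of data to segment saccades", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  n <- length(x)
  if (n > sg_length) {
    sm <- signal::sgolayfilt(x, p = sg_order, n = sg_length)
  } else {
    sm <- x
  }
  vel <- c(diff(sm) / diff(t), 0)
  hot <- abs(vel) > vel_threshold
  # merge hot runs separated by < min_separation, then pad
  runs <- rle(hot)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  events <- data.frame(
    start = t[idx_start[runs$values]],
    end = t[idx_end[runs$values]]
  )
  if (nrow(events) > 0) {
    merged <- events[1, , drop = FALSE]
    for (i in seq_len(nrow(events))[-1]) {
      if (events$start[i] - merged$end[nrow(merged)] < min_separation) {
        merged$end[nrow(merged)] <- events$end[i]
      } else {
        merged <- rbind(merged, events[i, ])
      }
    }
    merged$start <- merged$start - pad
    merged$end <- merged$end + pad
  } else {
    merged <- events
  }
  in_saccade <- rep(FALSE, n)
  for (i in seq_len(nrow(merged))) {
    in_saccade[t >= merged$start[i] & t <= merged$end[i]] <- TRUE
  }
  isi_runs <- rle(!in_saccade)
  ie <- cumsum(isi_runs$lengths)
  is_ <- ie - isi_runs$lengths + 1
  isis <- purrr::map2(
    is_[isi_runs$values], ie[isi_runs$values],
    function(a, b) a:b
  )
  isis <- purrr::keep(isis, ~ length(.x) >= 2)
  structure(
    list(
      saccades = tibble::tibble(
        t_start = merged$start, t_end = merged$end
      ),
      isis = isis, n_samples = n
    ),
    class = "okr_segmentation"
  )
}

#' @export
print.okr_segmentation <- function(x, ...) {
  cat("<okr_segmentation>", nrow(x$saccades), "saccades,",
      length(x$isis), "ISIs over", x$n_samples, "samples\n")
  invisible(x)
}

#' Fit a shared sinusoid with per-interval offsets to the slow phase
#'
#' Fits `f(t in ISI_k) = -c1 cos(c2 t + c3) + c_{k+3}` jointly over all
#' inter-saccade intervals: one shared amplitude `c1`, angular frequency `c2`
#' and phase `c3`, plus a constant offset per ISI absorbing the position jump
#' of each saccade. For fixed `c2` the model is linear in
#' `(A, B, offsets)` with `-c1 cos(c2 t + c3) = A cos(c2 t) + B sin(c2 t)`,
#' so the fit profiles the linear parameters and optimises `c2` on
#' `[0.8, 1.2] x 2 pi f_init` (the stimulus envelope frequency is known, so
#' the frequency is fitted but softly bounded around it). The amplitude is
#' sign-normalised to `c1 >= 0`.
#'
#' @param trace An `okr_trace`.
#' @param segmentation An `okr_segmentation`, or `NULL` to run
#'   [detect_saccades()] with defaults.
#' @param f_init Initial (stimulus envelope) frequency, Hz.
#' @param c2_band Half-width of the relative search band around
#'   `2 pi f_init`.
#' @return An object of class `okr_sinusoid_fit`: list with `c1` (deg),
#'   `c2` (rad/s), `c3` (rad, in (-pi, pi]), `offsets` (deg, one per ISI),
#'   `residual_rms`, `r_squared`, `fitted`, `residuals`, and the index of
#'   samples used.
#' @export
fit_piecewise_sinusoid <- function(trace, segmentation = NULL, f_init = 0.1,
                                   c2_band = 0.2) {
  if (is.null(segmentation)) segmentation <- detect_saccades(trace)
  isis <- segmentation$isis
  if (length(isis) < 1 || sum(lengths(isis)) < 5) {
    stop("need at least one ISI with >= 5 samples in total", call. = FALSE)
  }
  t <- trace$time_s
  y <- trace$angle_deg
  used <- unlist(isis)
  k_of <- rep(seq_along(isis), lengths(isis))
  tt <- t[used]
  yy <- y[used]
  K <- length(isis)

  design <- function(c2) {
    X <- matrix(0, length(tt), 2 + K)
    X[, 1] <- cos(c2 * tt)
    X[, 2] <- sin(c2 * tt)
    X[cbind(seq_along(tt), 2 + k_of)] <- 1
    X
  }
  rss_of <- function(c2) {
    fit <- stats::lm.fit(design(c2), yy)
    sum(fit$residuals^2)
  }
  w0 <- 2 * pi * f_init
  opt <- stats::optimize(rss_of, c((1 - c2_band) * w0, (1 + c2_band) * w0),
                         tol = 1e-10)
  c2 <- opt$minimum
  fit <- stats::lm.fit(design(c2), yy)
  A <- fit$coefficients[1]
  B <- fit$coefficients[2]
  offsets <- unname(fit$coefficients[-(1:2)])
  # -c1 cos(c2 t + c3) = -c1 cos(c3) cos(c2 t) + c1 sin(c3) sin(c2 t)
  c1 <- sqrt(A^2 + B^2)
  c3 <- atan2(B, -A)
  fitted <- as.numeric(design(c2) %*% fit$coefficients)
  resid <- yy - fitted
  ss_tot <- sum((yy - mean(yy))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(
    list(
      c1 = unname(c1), c2 = unname(c2), c3 = unname(c3), offsets = offsets,
      residual_rms = sqrt(mean(resid^2)), r_squared = r2,
      fitted = fitted, residuals = resid, used_index = used,
      time_used = tt, isi_of = k_of, n_isis = K, segmentation = segmentation,
      trace = trace
    ),
    class = "okr_sinusoid_fit"
  )
}

#' @export
print.okr_sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<okr_sinusoid_fit> c1 = %.3f deg, c2 = %.4f rad/s, c3 = %.3f rad, %d ISIs, R^2 = %.3f\n",
    x$c1, x$c2, x$c3, x$n_isis, x$r_squared
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_piecewise_sinusoid
#' @param x An `okr_sinusoid_fit`.
#' @param ... Unused.
#' @export
tidy.okr_sinusoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c1", "c2", "c3", paste0("offset_", seq_along(x$offsets))),
    estimate = c(x$c1, x$c2, x$c3, x$offsets)
  )
}

#' @rdname fit_piecewise_sinusoid
#' @export
glance.okr_sinusoid_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, residual_rms = x$residual_rms,
    n_isis = x$n_isis, n_obs = length(x$residuals)
  )
}

#' OKR gain of a fitted trace
#'
#' The OKR gain is the ratio of the eye-position amplitude to the
#' stimulus-position amplitude, `g = a_E / a_S = c1 / a_S`.
#'
#' @param fit An `okr_sinusoid_fit`.
#' @param spec The `okr_stimulus` shown during the trace.
#' @param repetition Repetition index carried into the record.
#' @param arena_orientation `+1` for the default arena setup, `-1` for the
#'   horizontally rotated arena.
#' @param embedding `"upright"` or `"inverted"`.
#' @return A one-row tibble (gain record) with identification columns,
#'   `gain` and `phase_shift_rad`.
#' @export
okr_gain <- function(fit, spec, repetition = 1L, arena_orientation = 1,
                     embedding = "upright") {
  stopifnot(inherits(fit, "okr_sinusoid_fit"), inherits(spec, "okr_stimulus"))
  a_s <- stimulus_position_amplitude(spec)
  if (a_s == 0) stop("stimulus position amplitude is zero", call. = FALSE)
  tr <- fit$trace
  tibble::tibble(
    fish_id = tr$fish_id[1], eye = tr$eye[1], stimulus_id = tr$stimulus_id[1],
    repetition = repetition, gain = fit$c1 / a_s,
    phase_shift_rad = wrap_pi(fit$c3),
    arena_orientation = arena_orientation, embedding = embedding
  )
}

wrap_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, pi, w)
}

#' Bode magnitude and phase of a fitted trace
#'
#' The stimulus position reference is `s(t) = -a_S cos(2 pi f t)`, so the
#' fitted phase `c3` is directly the phase shift of the eye relative to the
#' stimulus; an eye lagging by a quarter period has phase -90 degrees.
#'
#' @inheritParams okr_gain
#' @return A one-row tibble with `magnitude` (the gain) and `phase_deg`
#'   wrapped to `(-180, 180]`.
#' @export
bode_point <- function(fit, spec) {
  g <- fit$c1 / stimulus_position_amplitude(spec)
  ph <- wrap_pi(fit$c3) * 180 / pi
  if (ph <= -180) ph <- 180
  tibble::tibble(magnitude = g, phase_deg = ph)
}

#' Quality control of a fitted trial
#'
#' Trials whose slow phase is not well described by the stimulus-locked
#' sinusoid are excluded: rejection if the fit `r_squared` falls below
#' `r2_min` (other behaviours superimposed on OKR) or if a linear drift term
#' fitted to the pooled ISI residuals exceeds `drift_threshold` in absolute
#' slope (spontaneous drift).
#'
#' @param fit An `okr_sinusoid_fit`.
#' @param r2_min Minimum acceptable coefficient of determination.
#' @param drift_threshold Maximum acceptable residual drift slope, degree/s.
#' @return A one-row tibble with `accept` (logical) and `reason`
#'   (`"ok"`, `"low_r2"` or `"drift"`).
#' @export
qc_trial <- function(fit, r2_min = 0.3, drift_threshold = 0.2) {
  stopifnot(inherits(fit, "okr_sinusoid_fit"))
  # within-ISI drift first: regress residuals on time centred per ISI, so
  # that the per-ISI offsets already absorbed by the fit do not mask a
  # steady drift (which also depresses r-squared)
  tc <- fit$time_used -
    stats::ave(fit$time_used, fit$isi_of, FUN = mean)
  dl <- stats::lm.fit(cbind(1, tc), fit$residuals)
  slope <- dl$coefficients[2]
  if (is.finite(slope) && abs(slope) > drift_threshold) {
    return(tibble::tibble(accept = FALSE, reason = "drift"))
  }
  if (is.finite(fit$r_squared) && fit$r_squared < r2_min) {
    return(tibble::tibble(accept = FALSE, reason = "low_r2"))
  }
  tibble::tibble(accept = TRUE, reason = "ok")
}
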