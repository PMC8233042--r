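#' Define a grating stimulus phase
#'
#' One stimulus phase shows horizontally moving vertical bars (meridian-bounded
#' square-wave bars, 50% duty cycle) whose angular velocity follows a
#' sinusoidal envelope `v(t) = A_v sin(2 pi f t)`, optionally cropped to a
#' disk-shaped area by a permanently dark surround. Defaults are the
#' experiment's standard parameters: 0.06 cycles/degree, 12.5 degree/s
#' velocity amplitude, 0.1 Hz envelope, 100 s per phase.
#'
#' @param spatial_frequency Grating spatial frequency, cycles/degree.
#' @param velocity_amplitude Velocity amplitude A_v, degree/s.
#' @param envelope_frequency Velocity-envelope frequency f, Hz.
#' @param phase_duration Duration of the stimulus phase, s.
#' @param crop_centre Centre of the crop disk as `c(azimuth, elevation)` in
#'   degrees, or `NULL` for whole-field stimulation.
#' @param crop_half_angle Polar half-angle of the crop disk, degrees in
#'   `(0, 180]`; 180 means no cropping.
#' @param pattern Bar luminance profile; only `"square_wave_bars"` (binary
#'   LEDs) is supported.
#' @return An object of class `okr_stimulus`.
#' @export
stimulus_spec <- function(spatial_frequency = 0.06, velocity_amplitude = 12.5,
                          envelope_frequency = 0.1, phase_duration = 100,
                          crop_centre = NULL, crop_half_angle = 180,
                          pattern = "square_wave_bars") {
  stopifnot(
    spatial_frequency > 0, envelope_frequency > 0, phase_duration > 0,
    crop_half_angle > 0, crop_half_angle <= 180,
    identical(pattern, "square_wave_bars")
  )
  if (!is.null(crop_centre)) {
    stopifnot(length(crop_centre) == 2)
    crop_centre <- as.numeric(crop_centre)
  }
  structure(
    list(
      spatial_frequency = spatial_frequency,
      velocity_amplitude = velocity_amplitude,
      envelope_frequency = envelope_frequency,
      phase_duration = phase_duration,
      crop_centre = crop_centre,
      crop_half_angle = crop_half_angle,
      pattern = pattern
    ),
    class = "okr_stimulus"
  )
}

#' @export
print.okr_stimulus <- function(x, ...) {
  crop <- if (is.null(x$crop_centre)) "whole-field" else {
    sprintf("crop (%.1f, %.1f) half-angle %.1f deg",
            x$crop_centre[1], x$crop_centre[2], x$crop_half_angle)
  }
  cat(sprintf(
    "<okr_stimulus> %.3f cpd, A_v %.1f deg/s, f %.2f Hz, %.0f s, %s\n",
    x$spatial_frequency, x$velocity_amplitude, x$envelope_frequency,
    x$phase_duration, crop
  ))
  invisible(x)
}

#' Position amplitude of the sinusoidal stimulus
#'
#' Integrating the velocity envelope `v(t) = A_v sin(2 pi f t)` gives the
#' angular position `s(t) = a_S (1 - cos(2 pi f t))` with amplitude
#' `a_S = A_v / (2 pi f)`. The OKR gain divides the fitted eye amplitude by
#' this stimulus amplitude.
#'
#' @param spec An `okr_stimulus`.
#' @return Position amplitude a_S in degrees.
#' @export
stimulus_position_amplitude <- function(spec) {
  stopifnot(inherits(spec, "okr_stimulus"))
  if (spec$envelope_frequency == 0) stop("envelope frequency must be > 0")
  spec$velocity_amplitude / (2 * pi * spec$envelope_frequency)
}

#' Stimulus angular position over time
#'
#' @param t Time in seconds from stimulus-phase onset.
#' @param spec An `okr_stimulus`.
#' @return Displacement in degrees, `s(t) = -a_S cos(2 pi f t) + a_S`.
#' @export
stimulus_position <- function(t, spec) {
  a_s <- stimulus_position_amplitude(spec)
  -a_s * cos(2 * pi * spec$envelope_frequency * t) + a_s
}

#' Default seed configuration for stimulus-centre placement
#'
#' Seven seeds populate one eighth of the sphere (positive azimuth, positive
#' elevation): one fixed at the intersection of the equator and the lateral
#' meridian (90, 0); two constrained to the lateral meridian (azimuth 90,
#' elevation free and positive); one constrained to the equator (elevation 0,
#' azimuth free in (0, 90)); and three free in the open octant. Initial free
#' values are drawn by the caller's RNG inside [place_stimulus_centres()].
#'
#' @return A tibble with columns `azimuth`, `elevation`, `constraint`
#'   (one of `"fixed"`, `"meridian"`, `"equator"`, `"free"`).
#' @export
seed_configuration <- function() {
  tibble::tibble(
    azimuth = c(90, 90, 90, 45, 30, 45, 60),
    elevation = c(0, 30, 60, 0, 30, 45, 60),
    constraint = c("fixed", "meridian", "meridian", "equator",
                   "free", "free", "free")
  )
}

# Expand the 7 fundamental-domain points to the full set under the mirror
# group {identity, sagittal, horizontal, coronal and their compositions},
# deduplicating points that lie on a mirror plane.
expand_by_reflections <- function(pts, round_digits = 6) {
  out <- pts[, c("azimuth", "elevation")]
  for (p in c("sagittal", "horizontal", "coronal")) {
    out <- rbind(out, reflect_geo(out$azimuth, out$elevation, p))
  }
  key <- paste(round(out$azimuth, round_digits), round(out$elevation, round_digits))
  out[!duplicated(key), ]
}

#' Place near-equidistant stimulus centres by constrained repulsion
#'
#' Simulates pairwise repulsion between all stimulus centres until a stable
#' pattern emerges. Only the 7 fundamental-domain seeds move; their mirror
#' images under the three symmetry planes are regenerated each step, which
#' enforces exact mirror symmetry of the final set. Constrained seeds move
#' only along their constraint set (the lateral meridian or the equator); the
#' seed at (90, 0) is fixed. Each iteration steps against the gradient of the
#' total inverse-power repulsion energy `E = sum over pairs of 1/chord^p`
#' with a backtracking line search, so the energy descends monotonically; the
#' energy and minimal-pairwise-distance trajectories are logged as
#' attributes. The default exponent `force_exponent = 6` is a short-range
#' repulsion whose equilibrium keeps the closest pairs further apart than the
#' long-range Coulomb law does, matching the near-equidistant design goal.
#' With the default seeds the expansion yields
#' 3 x 8 + 2 x 4 + 1 x 4 + 1 x 2 = 38 unique positions.
#'
#' @param seeds Seed tibble as returned by [seed_configuration()].
#' @param seed Integer RNG seed used to randomise the free initial positions.
#' @param max_iter Maximum number of repulsion iterations.
#' @param tol Convergence threshold on the maximum per-step displacement,
#'   radians.
#' @param round_to Rounding of the final coordinates, degrees.
#' @param force_exponent Exponent p of the `1/chord^p` pair energy.
#' @return A tibble of stimulus centres with columns `stimulus_id`
#'   (`"D1"`...`"D38"`, D1-D19 on the left hemisphere, D20-D38 on the right),
#'   `azimuth`, `elevation`, plus attributes `iterations`,
#'   `min_distance_trace` and `energy_trace` (one entry per accepted step).
#' @export
place_stimulus_centres <- function(seeds = seed_configuration(), seed = 1,
                                   max_iter = 2000, tol = 1e-6,
                                   round_to = 0.1, force_exponent = 6) {
  stopifnot(nrow(seeds) == 7, all(seeds$constraint %in%
    c("fixed", "meridian", "equator", "free")))
  set.seed(seed)
  # randomise initial positions of non-fixed seeds within their domains
  s <- seeds
  for (i in seq_len(nrow(s))) {
    s$azimuth[i] <- switch(s$constraint[i],
      fixed = 90, meridian = 90,
      equator = stats::runif(1, 15, 75),
      free = stats::runif(1, 15, 75)
    )
    s$elevation[i] <- switch(s$constraint[i],
      fixed = 0, equator = 0,
      meridian = stats::runif(1, 15, 75),
      free = stats::runif(1, 15, 75)
    )
  }
  # spread the two meridian seeds so they do not start on top of each other
  mer <- which(s$constraint == "meridian")
  s$elevation[mer] <- sort(stats::runif(2, c(10, 45), c(40, 80)))

  # free parameters: azimuth and/or elevation of each non-fixed seed (deg)
  par_map <- list()
  for (i in seq_len(nrow(s))) {
    cons <- s$constraint[i]
    if (cons %in% c("equator", "free")) {
      par_map[[length(par_map) + 1]] <- list(seed = i, coord = "azimuth")
    }
    if (cons %in% c("meridian", "free")) {
      par_map[[length(par_map) + 1]] <- list(seed = i, coord = "elevation")
    }
  }
  get_par <- function(s) {
    vapply(par_map, function(m) s[[m$coord]][m$seed], numeric(1))
  }
  set_par <- function(p) {
    out <- s
    for (j in seq_along(par_map)) {
      out[[par_map[[j]]$coord]][par_map[[j]]$seed] <-
        min(90 - 1e-3, max(1e-3, p[j]))
    }
    out
  }
  # In Cartesian coordinates the three mirror reflections are the sign flips
  # x -> -x (sagittal), z -> -z (horizontal), y -> -y (coronal), so the full
  # orbit of the 7 seeds is their images under all 8 sign combinations,
  # deduplicated for seeds lying on a mirror plane.
  sign_combos <- as.matrix(expand.grid(x = c(1, -1), y = c(1, -1),
                                       z = c(1, -1)))
  full_unit <- function(seeds_now) {
    fu <- geo_to_unit(seeds_now$azimuth, seeds_now$elevation)
    out <- do.call(rbind, lapply(seq_len(8), function(k) {
      fu * matrix(sign_combos[k, ], nrow(fu), 3, byrow = TRUE)
    }))
    key <- paste(round(out[, 1], 9), round(out[, 2], 9), round(out[, 3], 9))
    out[!duplicated(key), , drop = FALSE]
  }
  min_dist <- function(u) {
    d <- tcrossprod(u)
    diag(d) <- -1
    acos(pmin(1, pmax(-1, max(d[upper.tri(d) | lower.tri(d)])))) # closest pair
  }
  energy_of <- function(p) { # inverse-power chord energy over all pairs
    u <- full_unit(set_par(p))
    d2 <- 2 - 2 * tcrossprod(u)
    d2[d2 < 1e-12] <- NA
    sum(1 / d2^(force_exponent / 2), na.rm = TRUE) / 2
  }
  grad_of <- function(p, e0) { # forward differences, degrees
    h <- 1e-5
    vapply(seq_along(p), function(j) {
      pj <- p
      pj[j] <- pj[j] + h
      (energy_of(pj) - e0) / h
    }, numeric(1))
  }
  descend <- function(p0) {
    p <- p0
    e <- energy_of(p)
    dmin_trace <- min_dist(full_unit(set_par(p)))
    energy_trace <- e
    eta <- 0.01
    iterations <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- it
      g <- grad_of(p, e)
      if (sqrt(sum(g^2)) < 1e-12) {
        converged <- TRUE
        break
      }
      accepted <- FALSE
      while (eta >= 1e-12) {
        cand <- p - eta * g
        e_cand <- energy_of(cand)
        if (is.finite(e_cand) && e_cand <= e) {
          accepted <- TRUE
          break
        }
        eta <- eta / 2 # backtrack: the repulsion energy must descend
      }
      if (!accepted) {
        converged <- TRUE # stalled at a stationary point of the energy
        break
      }
      disp <- max(abs(cand - p)) * pi / 180
      p <- cand
      e <- e_cand
      dmin_trace <- c(dmin_trace, min_dist(full_unit(set_par(p))))
      energy_trace <- c(energy_trace, e)
      eta <- min(eta * 1.5, 1)
      if (disp < tol) {
        converged <- TRUE
        break
      }
    }
    list(p = p, e = e, dmin_trace = dmin_trace, energy_trace = energy_trace,
         iterations = iterations, converged = converged)
  }
  # multi-start: the first start is the seeded random configuration drawn
  # above; further starts redraw it, and the lowest-energy equilibrium wins
  n_starts <- 3
  best <- NULL
  for (k in seq_len(n_starts)) {
    if (k > 1) {
      p0 <- get_par(s) * 0 + stats::runif(length(par_map), 10, 80)
    } else {
      p0 <- get_par(s)
    }
    run <- descend(p0)
    if (!run$converged) next
    if (is.null(best) || run$e < best$e) best <- run
  }
  if (is.null(best)) {
    stop(sprintf("repulsion did not converge in %d iterations", max_iter),
         call. = FALSE)
  }
  iterations <- best$iterations
  dmin_trace <- best$dmin_trace
  energy_trace <- best$energy_trace
  g <- set_par(best$p)[, c("azimuth", "elevation")]
  g$constraint <- s$constraint
  final <- expand_by_reflections(g)
  final$azimuth <- round(final$azimuth / round_to) * round_to
  final$elevation <- round(final$elevation / round_to) * round_to
  final <- final[!duplicated(paste(final$azimuth, final$elevation)), ]
  # D1-D19: left hemisphere (azimuth < 0), D20-D38: right, each sorted
  left <- final[final$azimuth < 0, ]
  right <- final[final$azimuth > 0, ]
  zero <- final[final$azimuth == 0, ]
  ord <- function(d) d[order(d$elevation, d$azimuth), ]
  final <- rbind(ord(left), ord(right), ord(zero))
  final$stimulus_id <- paste0("D", seq_len(nrow(final)))
  out <- tibble::as_tibble(final[, c("stimulus_id", "azimuth", "elevation")])
  attr(out, "iterations") <- iterations
  attr(out, "min_distance_trace") <- dmin_trace * 180 / pi
  attr(out, "energy_trace") <- energy_trace
  out
}

#' Is the grating pattern lit at a given direction and time?
#'
#' Bars are bounded by true meridians (elevation-independent in azimuth), so
#' the pattern is a 50% duty-cycle square wave in azimuth with spatial period
#' `1 / spatial_frequency` degrees, displaced by the integrated stimulus
#' position `s(t)`. Directions outside the crop disk are permanently dark.
#'
#' @param azimuth,elevation Direction(s), degrees.
#' @param t Time since phase onset, s (scalar).
#' @param spec An `okr_stimulus`.
#' @return Logical vector: `TRUE` where the pattern is lit.
#' @export
grating_on <- function(azimuth, elevation, t, spec) {
  stopifnot(inherits(spec, "okr_stimulus"), length(t) == 1)
  period <- 1 / spec$spatial_frequency
  phase <- ((azimuth - stimulus_position(t, spec)) / period) %% 1
  on <- phase < 0.5
  if (!is.null(spec$crop_centre)) {
    ang <- great_circle_angle(
      azimuth, elevation,
      spec$crop_centre[1], spec$crop_centre[2]
    )
    on <- on & (ang <= spec$crop_half_angle)
  }
  on
}

#' Rasterise a stimulus phase onto the arena's LEDs
#'
#' Evaluates [grating_on()] for every LED direction on a regular time grid.
#'
#' @param spec An `okr_stimulus`.
#' @param arena An `okr_arena` from [arena_model()].
#' @param dt Frame interval, s (default 1/60 matching the camera rate).
#' @return An object of class `okr_led_frames`: list with `times` (s) and
#'   `states` (logical matrix, frames x LEDs), plus the arena reference.
#' @export
rasterize_stimulus <- function(spec, arena, dt = 1 / 60) {
  stopifnot(inherits(spec, "okr_stimulus"), inherits(arena, "okr_arena"),
            dt > 0)
  if (nrow(arena$leds) == 0) stop("arena has no LEDs", call. = FALSE)
  times <- seq(0, spec$phase_duration - 1e-9, by = dt)
  states <- t(vapply(
    times,
    function(tt) grating_on(arena$leds$azimuth, arena$leds$elevation, tt, spec),
    logical(nrow(arena$leds))
  ))
  structure(list(times = times, states = states, arena = arena, spec = spec),
            class = "okr_led_frames")
}

#' @export
print.okr_led_frames <- function(x, ...) {
  cat("<okr_led_frames>", length(x$times), "frames x", ncol(x$states),
      "LEDs,", sprintf("%.1f%% lit\n", 100 * mean(x$states)))
  invisible(x)
}
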