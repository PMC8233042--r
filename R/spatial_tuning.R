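#' Construct a bimodal von Mises-Fisher gain surface
#'
#' The spatial tuning of OKR gain is modelled as the sum of two independent
#' von Mises-Fisher (vMF) components plus a constant offset:
#' \deqn{F(\xi) = \sum_{j=1,2} C_j \kappa_j
#'   \exp(\kappa_j \mu_j^T \xi) / (2\pi (e^{\kappa_j} - e^{-\kappa_j})) + C_3}
#' where `xi` is a unit direction, `mu_j` are the component centres (one per
#' hemisphere because the yoked eyes each contribute a preferred location),
#' `kappa_j` the concentrations, `C_j` the component masses (so that the
#' offset-free surface integrates to `C1 + C2` over the sphere) and `C3` a
#' baseline gain.
#'
#' @param mu1,mu2 Component centres as `c(azimuth, elevation)` in degrees.
#' @param kappa1,kappa2 Concentrations, > 0.
#' @param C1,C2 Component masses (gain x steradian), >= 0.
#' @param C3 Baseline gain offset.
#' @return An object of class `okr_vmf`.
#' @export
vmf_model <- function(mu1 = c(-82.5, 5.1), mu2 = c(81.7, 1.6),
                      kappa1 = 8, kappa2 = 8, C1 = 1, C2 = 1, C3 = 0) {
  stopifnot(kappa1 > 0, kappa2 > 0, C1 >= 0, C2 >= 0,
            length(mu1) == 2, length(mu2) == 2)
  structure(
    list(mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
         kappa1 = kappa1, kappa2 = kappa2, C1 = C1, C2 = C2, C3 = C3),
    class = "okr_vmf"
  )
}

#' @export
print.okr_vmf <- function(x, ...) {
  cat(sprintf(
    "<okr_vmf> mu1 (%.1f, %.1f) kappa %.2f C %.3g | mu2 (%.1f, %.1f) kappa %.2f C %.3g | C3 %.3g\n",
    x$mu1[1], x$mu1[2], x$kappa1, x$C1,
    x$mu2[1], x$mu2[2], x$kappa2, x$C2, x$C3
  ))
  invisible(x)
}

# log of the vMF normalisation-weighted kernel:
# log[ kappa e^{kappa t} / (2 pi (e^kappa - e^{-kappa})) ]
# evaluated stably for large kappa via e^kappa - e^-kappa = e^kappa(1 - e^-2k)
vmf_log_kernel <- function(kappa, t) {
  log(kappa) - log(2 * pi) + kappa * (t - 1) - log1p(-exp(-2 * kappa))
}

#' Evaluate a bimodal vMF gain surface
#'
#' Uses log-domain evaluation of each component so that concentrations up to
#' several hundred remain finite.
#'
#' @param model An `okr_vmf`.
#' @param azimuth,elevation Evaluation direction(s), degrees.
#' @return Numeric vector of gains.
#' @export
vmf_sum_eval <- function(model, azimuth, elevation) {
  stopifnot(inherits(model, "okr_vmf"))
  xi <- geo_to_unit(azimuth, elevation)
  m1 <- geo_to_unit(model$mu1[1], model$mu1[2])[1, ]
  m2 <- geo_to_unit(model$mu2[1], model$mu2[2])[1, ]
  t1 <- as.numeric(xi %*% m1)
  t2 <- as.numeric(xi %*% m2)
  model$C1 * exp(vmf_log_kernel(model$kappa1, t1)) +
    model$C2 * exp(vmf_log_kernel(model$kappa2, t2)) +
    model$C3
}

# pack/unpack fit parameters: (az1, el1, log k1, C1, az2, el2, log k2, C2, C3)
vmf_from_par <- function(p) {
  vmf_model(
    mu1 = c(wrap_az(p[1]), clamp_el(p[2])), kappa1 = exp(p[3]), C1 = p[4]^2,
    mu2 = c(wrap_az(p[5]), clamp_el(p[6])), kappa2 = exp(p[7]), C2 = p[8]^2,
    C3 = p[9]
  )
}
wrap_az <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w <= -180, 180, w)
}
clamp_el <- function(e) pmin(89.999, pmax(-89.999, e))

#' Fit the bimodal von Mises-Fisher surface to gain data
#'
#' Aggregates gain records to one value per stimulus position (median across
#' fish and repetitions by default, mirroring the arena-rotation correction
#' pipeline; `aggregate = "none"` fits every record) and least-squares fits
#' the 9-parameter bimodal vMF surface with `minpack.lm::nls.lm`,
#' multi-starting from mirror-symmetric lateral centres at (+/-90, 0),
#' kappa = 5, plus randomised perturbations, keeping the best-loss solution.
#' Both the fitted component centres and the numerically located global
#' maxima of the surface are reported (for overlapping components they need
#' not coincide).
#'
#' @param records Tibble with columns `azimuth`, `elevation`, `gain`.
#' @param init `"symmetric_lateral"` (default) or a numeric parameter vector
#'   to use as the first start.
#' @param n_starts Number of starts (>= 1; the first is the canonical
#'   symmetric start, the rest are seeded perturbations).
#' @param aggregate `"median"` (per position) or `"none"`.
#' @param seed RNG seed for the start perturbations.
#' @return An object of class `okr_vmf_fit`: list with `model` (`okr_vmf`),
#'   `maxima` (tibble of the two local maxima of the surface), `rss`,
#'   `r_squared`, `n_positions`, `degenerate` flag, and `data` used.
#' @export
fit_bimodal_vmf <- function(records, init = "symmetric_lateral",
                            n_starts = 5, aggregate = c("median", "none"),
                            seed = 1) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("azimuth", "elevation", "gain") %in% names(records)))
  dat <- if (aggregate == "median") {
    dplyr::summarise(
      dplyr::group_by(records, .data$azimuth, .data$elevation),
      gain = stats::median(.data$gain), .groups = "drop"
    )
  } else {
    tibble::as_tibble(records[, c("azimuth", "elevation", "gain")])
  }
  n_pos <- nrow(dplyr::distinct(dat, .data$azimuth, .data$elevation))
  if (n_pos < 11) {
    stop("need at least 11 distinct stimulus positions (9 parameters)",
         call. = FALSE)
  }
  if (stats::sd(dat$gain) < 1e-12) {
    model <- vmf_model(kappa1 = 1, kappa2 = 1, C1 = 0, C2 = 0,
                       C3 = dat$gain[1])
    return(structure(
      list(model = model, maxima = NULL, rss = 0, r_squared = NA_real_,
           n_positions = n_pos, degenerate = TRUE, data = dat),
      class = "okr_vmf_fit"
    ))
  }
  resid_fun <- function(p) {
    vmf_sum_eval(vmf_from_par(p), dat$azimuth, dat$elevation) - dat$gain
  }
  peak <- max(dat$gain)
  base <- stats::median(dat$gain)
  # C scaled so a kappa=5 component roughly matches the observed peak
  c_guess <- sqrt(max(peak - base, 1e-3) / exp(vmf_log_kernel(5, 1)))
  start0 <- if (is.numeric(init)) init else {
    c(-90, 0, log(5), c_guess, 90, 0, log(5), c_guess, base)
  }
  set.seed(seed)
  starts <- list(start0)
  for (i in seq_len(max(0, n_starts - 1))) {
    jit <- start0 + c(
      stats::rnorm(2, 0, 15), stats::rnorm(1, 0, 0.5), 0,
      stats::rnorm(2, 0, 15), stats::rnorm(1, 0, 0.5), 0, 0
    )
    starts[[i + 1]] <- jit
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("vMF fit failed from all starts", call. = FALSE)
  model <- vmf_from_par(best$fit$par)
  # order components left (negative azimuth) first, for stable reporting
  if (model$mu1[1] > model$mu2[1]) {
    model <- vmf_model(model$mu2, model$mu1, model$kappa2, model$kappa1,
                       model$C2, model$C1, model$C3)
  }
  ss_tot <- sum((dat$gain - mean(dat$gain))^2)
  structure(
    list(
      model = model,
      maxima = locate_vmf_maxima(model),
      rss = best$rss,
      r_squared = 1 - best$rss / ss_tot,
      n_positions = n_pos, degenerate = FALSE, data = dat
    ),
    class = "okr_vmf_fit"
  )
}

# Numerically locate the two local maxima of the surface: coarse grid scan
# followed by Nelder-Mead polish around the best point of each hemisphere.
locate_vmf_maxima <- function(model, grid_step = 5) {
  az <- seq(-177.5, 180, by = grid_step)
  el <- seq(-87.5, 87.5, by = grid_step)
  g <- expand.grid(azimuth = az, elevation = el)
  g$gain <- vmf_sum_eval(model, g$azimuth, g$elevation)
  polish <- function(row) {
    o <- stats::optim(
      c(row$azimuth, row$elevation),
      function(p) -vmf_sum_eval(model, wrap_az(p[1]), clamp_el(p[2])),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000)
    )
    tibble::tibble(
      azimuth = wrap_az(o$par[1]), elevation = clamp_el(o$par[2]),
      gain = -o$value
    )
  }
  left <- g[g$azimuth < 0, ]
  right <- g[g$azimuth >= 0, ]
  dplyr::bind_rows(
    polish(left[which.max(left$gain), ]),
    polish(right[which.max(right$gain), ])
  )
}

#' @export
print.okr_vmf_fit <- function(x, ...) {
  print(x$model)
  if (!x$degenerate) {
    cat(sprintf("  RSS %.4g, R^2 %.3f over %d positions\n",
                x$rss, x$r_squared, x$n_positions))
  } else {
    cat("  degenerate fit (all gains equal)\n")
  }
  invisible(x)
}

#' @rdname fit_bimodal_vmf
#' @param x An `okr_vmf_fit`.
#' @param ... Unused.
#' @export
tidy.okr_vmf_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    component = c("mu1", "mu2"),
    azimuth = c(m$mu1[1], m$mu2[1]),
    elevation = c(m$mu1[2], m$mu2[2]),
    kappa = c(m$kappa1, m$kappa2),
    mass = c(m$C1, m$C2),
    offset = m$C3
  )
}

#' @rdname fit_bimodal_vmf
#' @export
glance.okr_vmf_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, r_squared = x$r_squared,
    n_positions = x$n_positions, degenerate = x$degenerate
  )
}

#' Kernel-smooth gain records on the sphere
#'
#' Nadaraya-Watson estimate with a von Mises-Fisher kernel:
#' `ghat(xi) = sum_i w_i g_i / sum_i w_i`, `w_i = exp(kappa xi^T xi_i)`
#' (computed as `exp(kappa (xi^T xi_i - 1))` for numerical stability).
#'
#' @param records Tibble with `azimuth`, `elevation`, `gain`.
#' @param kappa_smooth Kernel concentration.
#' @param grid Evaluation grid tibble with `azimuth`, `elevation`; default a
#'   regular 5-degree geographic grid.
#' @return The grid tibble with an added `gain` column.
#' @export
vmf_kernel_smooth <- function(records, kappa_smooth = 20, grid = NULL) {
  if (nrow(records) == 0) stop("no records to smooth", call. = FALSE)
  if (is.null(grid)) {
    grid <- tidyr::expand_grid(
      azimuth = seq(-180, 180, by = 5),
      elevation = seq(-90, 90, by = 5)
    )
  }
  xi_g <- geo_to_unit(grid$azimuth, grid$elevation)
  xi_r <- geo_to_unit(records$azimuth, records$elevation)
  ct <- xi_g %*% t(xi_r) # cosine similarity grid x records
  w <- exp(kappa_smooth * (ct - 1))
  grid$gain <- as.numeric((w %*% records$gain) / rowSums(w))
  grid
}

#' Combine original and rotated-arena gain tables
#'
#' To cancel environmental asymmetries, the experiment is repeated with the
#' arena rotated by 180 degrees. Rotated-arena stimulus positions are mapped
#' back into fish-centred coordinates (by default `(az, el) -> (-az, -el)`:
#' from the fish's perspective left/right and upper/lower LEDs are swapped),
#' then for each stimulus position the median gain across fish and
#' repetitions is taken within each dataset and the two medians are averaged.
#'
#' @param original,rotated Gain record tibbles with `azimuth`, `elevation`,
#'   `gain`.
#' @param remap Function mapping rotated-arena `(azimuth, elevation)` tibble
#'   rows to fish-centred coordinates.
#' @return Tibble of per-position corrected gains (`azimuth`, `elevation`,
#'   `gain`, `median_original`, `median_rotated`). Positions present in only
#'   one table are excluded and listed in the `unmatched` attribute.
#' @export
correct_arena_rotation <- function(original, rotated,
                                   remap = function(az, el) list(azimuth = -az, elevation = -el)) {
  med <- function(d) {
    dplyr::summarise(
      dplyr::group_by(d, .data$azimuth, .data$elevation),
      gain = stats::median(.data$gain), .groups = "drop"
    )
  }
  rot <- rotated
  mapped <- remap(rot$azimuth, rot$elevation)
  rot$azimuth <- mapped$azimuth
  rot$elevation <- mapped$elevation
  mo <- med(original)
  mr <- med(rot)
  joined <- dplyr::inner_join(
    mo, mr,
    by = c("azimuth", "elevation"), suffix = c("_original", "_rotated")
  )
  out <- dplyr::transmute(
    joined, .data$azimuth, .data$elevation,
    gain = (.data$gain_original + .data$gain_rotated) / 2,
    median_original = .data$gain_original,
    median_rotated = .data$gain_rotated
  )
  unmatched <- dplyr::bind_rows(
    dplyr::anti_join(mo, mr, by = c("azimuth", "elevation")),
    dplyr::anti_join(mr, mo, by = c("azimuth", "elevation"))
  )
  attr(out, "unmatched") <- unmatched
  out
}

#' Spatial-frequency tuning of OKR gain
#'
#' For each stimulus location, averages gain over repetitions at each tested
#' spatial frequency and fits a log-Gaussian bump
#' `g(f) = g_max exp(-(ln f - ln f_peak)^2 / (2 w^2))` to locate the
#' frequency optimum; the raw argmax is reported alongside. Locations with
#' flat or monotone profiles are flagged.
#'
#' @param records Tibble with `location_id`, `spatial_frequency`, `gain`.
#' @return An object of class `okr_tuning_fit` (kind `"frequency"`) whose
#'   `per_location` tibble holds `peak_frequency`, `raw_argmax`, `g_max`,
#'   `width` and a `flag` column.
#' @export
frequency_tuning <- function(records) {
  stopifnot(all(c("location_id", "spatial_frequency", "gain") %in%
    names(records)))
  per_loc <- dplyr::group_split(dplyr::group_by(records, .data$location_id))
  rows <- purrr::map_dfr(per_loc, function(d) {
    m <- dplyr::summarise(
      dplyr::group_by(d, .data$spatial_frequency),
      gain = mean(.data$gain), .groups = "drop"
    )
    m <- m[order(m$spatial_frequency), ]
    if (nrow(m) < 3) {
      stop("need >= 3 frequencies per location", call. = FALSE)
    }
    raw_arg <- m$spatial_frequency[which.max(m$gain)]
    flag <- "ok"
    if (stats::sd(m$gain) < 1e-12) flag <- "flat"
    else if (which.max(m$gain) %in% c(1L, nrow(m))) flag <- "boundary_peak"
    est <- c(g_max = max(m$gain), lf = log(raw_arg), w = 1)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = est,
        fn = function(p) {
          p["g_max"] * exp(-(log(m$spatial_frequency) - p["lf"])^2 /
            (2 * p["w"]^2)) - m$gain
        }
      ),
      error = function(e) NULL
    )
    pk <- if (!is.null(fit) && flag == "ok") exp(fit$par[["lf"]]) else raw_arg
    tibble::tibble(
      location_id = d$location_id[1], peak_frequency = pk,
      raw_argmax = raw_arg,
      g_max = if (!is.null(fit)) fit$par[["g_max"]] else max(m$gain),
      width = if (!is.null(fit)) abs(fit$par[["w"]]) else NA_real_,
      flag = flag
    )
  })
  structure(list(kind = "frequency", per_location = rows, data = records),
            class = "okr_tuning_fit")
}

#' Size tuning of OKR gain: sigmoid in log stimulus size
#'
#' OKR gain grows sigmoidally with the logarithm of stimulus size (the
#' fraction of the sphere covered by the crop disk):
#' `g(s) = g_max / (1 + exp(-(ln s - ln s50) / w))`, where `s50` is the size
#' of half-maximum performance.
#'
#' @param records Tibble with `location_id`, `size` (fraction of sphere in
#'   (0, 1]), `gain`.
#' @return An `okr_tuning_fit` (kind `"size"`) with per-location `g_max`,
#'   `s50`, `slope_w` and `flag`.
#' @export
size_tuning_fit <- function(records) {
  stopifnot(all(c("location_id", "size", "gain") %in% names(records)))
  per_loc <- dplyr::group_split(dplyr::group_by(records, .data$location_id))
  rows <- purrr::map_dfr(per_loc, function(d) {
    m <- dplyr::summarise(
      dplyr::group_by(d, .data$size),
      gain = mean(.data$gain), .groups = "drop"
    )
    m <- m[order(m$size), ]
    if (nrow(m) < 4 || max(m$size) / min(m$size) < 10) {
      stop("need >= 4 sizes spanning at least one decade", call. = FALSE)
    }
    if (max(m$gain) < 1e-12) {
      return(tibble::tibble(
        location_id = d$location_id[1], g_max = 0, s50 = NA_real_,
        slope_w = NA_real_, flag = "flat"
      ))
    }
    est <- c(g_max = max(m$gain), ls50 = mean(log(m$size)), w = 1)
    fit <- minpack.lm::nls.lm(
      par = est,
      fn = function(p) {
        p[["g_max"]] / (1 + exp(-(log(m$size) - p[["ls50"]]) / p[["w"]])) -
          m$gain
      },
      # s50 is only identified inside the sampled size range; the slope is
      # kept positive and away from degeneracy
      lower = c(0, log(min(m$size)), 0.05),
      upper = c(4 * max(m$gain), log(max(m$size)), 10),
      control = minpack.lm::nls.lm.control(maxiter = 400)
    )
    tibble::tibble(
      location_id = d$location_id[1],
      g_max = fit$par[["g_max"]], s50 = exp(fit$par[["ls50"]]),
      slope_w = fit$par[["w"]], flag = "ok"
    )
  })
  structure(list(kind = "size", per_location = rows, data = records),
            class = "okr_tuning_fit")
}

#' @export
print.okr_tuning_fit <- function(x, ...) {
  cat("<okr_tuning_fit>", x$kind, "tuning,", nrow(x$per_location),
      "locations\n")
  print(x$per_location)
  invisible(x)
}

#' @rdname frequency_tuning
#' @param x An `okr_tuning_fit`.
#' @param ... Unused.
#' @export
tidy.okr_tuning_fit <- function(x, ...) x$per_location

#' Classify a stimulus as directly visible to an eye or not
#'
#' A stimulus disk is directly visible to an eye if any part of it falls
#' inside the eye's field of view: the great-circle angle between the
#' stimulus centre and the eye's optical axis must not exceed
#' `fov / 2 + crop_half_angle`. Default axes are the measured mean eye
#' positions (left: azimuth -84.8, elevation 3.5; right: 80.1, 4.9) and the
#' literature field of view of 163 degrees per eye.
#'
#' @param azimuth,elevation Stimulus-centre direction(s), degrees.
#' @param crop_half_angle Stimulus disk half-angle, degrees.
#' @param eye `"left"` or `"right"`.
#' @param eye_axis Optional `c(azimuth, elevation)` override of the eye axis.
#' @param fov Field of view per eye, degrees in (0, 360).
#' @return Character vector, `"direct"` or `"indirect"`.
#' @export
direct_visibility <- function(azimuth, elevation, crop_half_angle = 20,
                              eye = c("left", "right"), eye_axis = NULL,
                              fov = 163) {
  eye <- match.arg(eye)
  stopifnot(fov > 0, fov <= 360)
  if (is.null(eye_axis)) {
    eye_axis <- if (eye == "left") c(-84.8, 3.5) else c(80.1, 4.9)
  }
  ang <- great_circle_angle(azimuth, elevation, eye_axis[1], eye_axis[2])
  ifelse(ang <= fov / 2 + crop_half_angle, "direct", "indirect")
}
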