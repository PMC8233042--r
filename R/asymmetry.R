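#' Yoking index of a pair of simultaneous eye gains
#'
#' `Y = (g_L - g_R) / (g_L + g_R)`: positive when the left eye responds more
#' strongly, zero for perfectly conjugate (yoked) eyes, +/-1 for fully
#' monocular movement. Antisymmetric under swapping the eyes.
#'
#' @param g_L,g_R OKR gains of the left and right eye during the same
#'   stimulus phase (vectors recycle).
#' @param condition Optional label for the stimulation condition.
#' @return A tibble with `g_L`, `g_R`, `Y` (NA with a flag when both gains
#'   are zero) and `condition`.
#' @export
yoking_index <- function(g_L, g_R, condition = "monocular") {
  if (any(g_L < 0 | g_R < 0)) stop("gains must be >= 0", call. = FALSE)
  s <- g_L + g_R
  Y <- ifelse(s > 0, (g_L - g_R) / s, NA_real_)
  tibble::tibble(
    g_L = g_L, g_R = g_R, Y = Y,
    undefined = s == 0, condition = condition
  )
}

#' Left/right bias index of one fish
#'
#' `B = (m_L - m_R) / (m_L + m_R)` where `m_L`, `m_R` are the medians of OKR
#' gain after pooling across all left-hemisphere and all right-hemisphere
#' stimulus types respectively. Hemisphere membership is decided by the sign
#' of the stimulus-centre azimuth; centres lying exactly on the sagittal
#' plane (azimuth 0 or +/-180) fall on the edge between hemispheres and are
#' excluded from both pools.
#'
#' @param records Gain records for one fish: tibble with `azimuth` (of the
#'   stimulus centre), `gain`, and optionally `fish_id` and
#'   `arena_orientation`.
#' @return A one-row tibble with `fish_id`, `m_L`, `m_R`, `B` and
#'   `arena_orientation` (NA if absent).
#' @export
bias_index <- function(records) {
  stopifnot(all(c("azimuth", "gain") %in% names(records)))
  az <- wrap_az(records$azimuth)
  left <- records$gain[az < 0 & abs(az) < 180]
  right <- records$gain[az > 0 & az < 180]
  if (length(left) == 0 || length(right) == 0) {
    stop("need at least one record per hemisphere", call. = FALSE)
  }
  m_L <- stats::median(left)
  m_R <- stats::median(right)
  tibble::tibble(
    fish_id = if ("fish_id" %in% names(records)) records$fish_id[1] else NA,
    m_L = m_L, m_R = m_R,
    B = if (m_L + m_R > 0) (m_L - m_R) / (m_L + m_R) else NA_real_,
    arena_orientation = if ("arena_orientation" %in% names(records)) {
      records$arena_orientation[1]
    } else NA_real_
  )
}

#' Two-stage regression of the linear asymmetry model
#'
#' Decomposes each fish's bias index as `B_k = phi b1 + b2 + b3_k + eta`:
#' `b1` captures environment-induced asymmetry (flipping sign with the arena
#' orientation `phi` in {+1, -1}), `b2` a shared biological bias, and `b3_k`
#' the individual bias of fish k. The system is underdetermined, so the
#' population coefficients are estimated first by least squares of `B` on
#' `[phi, 1]` under the assumption that individual biases average out, and
#' the `b3_k` are then recovered as the per-fish mean residuals.
#'
#' @param biases Tibble with one or more rows per fish: `fish_id`, `B`,
#'   `arena_orientation` (phi, +1 or -1).
#' @return An object of class `okr_asymmetry_fit`: list with `b1`, `b2`,
#'   their standard errors, tibble `b3` (per fish), residual summary and the
#'   stage-1 `lm` fit.
#' @export
fit_asymmetry_model <- function(biases) {
  stopifnot(all(c("fish_id", "B", "arena_orientation") %in% names(biases)))
  d <- biases[is.finite(biases$B), ]
  if (length(unique(d$fish_id)) < 2) {
    stop("need at least two fish", call. = FALSE)
  }
  identifiable <- length(unique(d$arena_orientation)) >= 2
  if (!identifiable) {
    warning("single arena orientation: b1 is unidentifiable and set to NA",
            call. = FALSE)
  }
  if (identifiable) {
    m <- stats::lm(B ~ arena_orientation, data = d)
    b1 <- unname(stats::coef(m)[2])
    b2 <- unname(stats::coef(m)[1])
    se <- summary(m)$coefficients[, "Std. Error"]
    b1_se <- unname(se[2])
    b2_se <- unname(se[1])
    resid <- stats::resid(m)
  } else {
    m <- stats::lm(B ~ 1, data = d)
    b1 <- NA_real_
    b1_se <- NA_real_
    b2 <- unname(stats::coef(m)[1])
    b2_se <- summary(m)$coefficients[1, "Std. Error"]
    resid <- stats::resid(m)
  }
  b3 <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(fish_id = d$fish_id, r = resid),
                    .data$fish_id),
    b3 = mean(.data$r), .groups = "drop"
  )
  structure(
    list(
      b1 = b1, b2 = b2, b1_se = b1_se, b2_se = b2_se, b3 = b3,
      eta_sd = stats::sd(resid - b3$b3[match(d$fish_id, b3$fish_id)]),
      identifiable = identifiable, stage1 = m, data = d
    ),
    class = "okr_asymmetry_fit"
  )
}

#' @export
print.okr_asymmetry_fit <- function(x, ...) {
  cat(sprintf(
    "<okr_asymmetry_fit> b1 = %.4g (se %.3g), b2 = %.4g (se %.3g), %d fish\n",
    x$b1, x$b1_se, x$b2, x$b2_se, nrow(x$b3)
  ))
  cat(sprintf("  b3: mean %.3g, sd %.3g\n", mean(x$b3$b3), stats::sd(x$b3$b3)))
  invisible(x)
}

#' @rdname fit_asymmetry_model
#' @param x An `okr_asymmetry_fit`.
#' @param ... Unused.
#' @export
tidy.okr_asymmetry_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      term = c("b1", "b2"), estimate = c(x$b1, x$b2),
      std_error = c(x$b1_se, x$b2_se)
    ),
    tibble::tibble(
      term = paste0("b3[", x$b3$fish_id, "]"), estimate = x$b3$b3,
      std_error = NA_real_
    )
  )
}

#' @rdname fit_asymmetry_model
#' @export
glance.okr_asymmetry_fit <- function(x, ...) {
  tibble::tibble(
    b3_mean = mean(x$b3$b3), b3_sd = stats::sd(x$b3$b3),
    eta_sd = x$eta_sd, n_fish = nrow(x$b3), identifiable = x$identifiable
  )
}

#' Default permutation-test statistic: vMF hemisphere-elevation difference
#'
#' Pools each group's gain records, fits the bimodal vMF surface, averages
#' the elevations of the two fitted hemisphere centres, and returns the
#' difference (group A minus group B) of these mean elevations in degrees.
#'
#' @param records_a,records_b Gain record tibbles with `azimuth`,
#'   `elevation`, `gain`.
#' @return Scalar statistic in degrees.
#' @export
elevation_difference_statistic <- function(records_a, records_b) {
  mean_el <- function(d) {
    f <- fit_bimodal_vmf(d, n_starts = 2)
    if (f$degenerate) stop("degenerate vMF fit", call. = FALSE)
    (f$model$mu1[2] + f$model$mu2[2]) / 2
  }
  mean_el(records_a) - mean_el(records_b)
}

#' Permutation test of a group difference across fish
#'
#' Tests whether a statistic computed between two groups of fish (for
#' example, upright versus upside-down embedding) exceeds what relabelling
#' would produce. Fish are the exchangeable units: all assignments of the
#' pooled fish into groups of the original sizes are enumerated exactly when
#' the total number of fish is at most `max_exact` (for a 3-vs-7 split of 10
#' fish, choose(10, 3) = 120 assignments), otherwise a seeded Monte-Carlo
#' sample of `n_mc` assignments is drawn. The p-value is the fraction of
#' assignments (including the identity, so p >= 1/P) whose statistic is
#' greater than or equal to the observed one.
#'
#' @param group_a,group_b Gain record tibbles with a `fish_id` column plus
#'   whatever columns `statistic` needs.
#' @param statistic Function of two record tibbles returning a scalar;
#'   default [elevation_difference_statistic()].
#' @param max_exact Largest total fish count for exhaustive enumeration.
#' @param n_mc Monte-Carlo sample size above `max_exact`.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return An object of class `okr_permutation_test`: list with `p_value`,
#'   `observed`, `permutation_statistics`, `n_permutations`, `n_excluded`
#'   (assignments whose statistic failed, e.g. degenerate fits) and `exact`.
#' @export
permutation_test_elevation <- function(group_a, group_b,
                                       statistic = elevation_difference_statistic,
                                       max_exact = 20, n_mc = 1000,
                                       seed = 1) {
  stopifnot("fish_id" %in% names(group_a), "fish_id" %in% names(group_b))
  fish_a <- unique(group_a$fish_id)
  fish_b <- unique(group_b$fish_id)
  if (length(intersect(fish_a, fish_b)) > 0) {
    stop("fish ids must be disjoint between groups", call. = FALSE)
  }
  pooled <- dplyr::bind_rows(group_a, group_b)
  all_fish <- c(fish_a, fish_b)
  n_a <- length(fish_a)
  n <- length(all_fish)
  exact <- n <= max_exact
  assignments <- if (exact) {
    utils::combn(n, n_a, simplify = FALSE)
  } else {
    set.seed(seed)
    c(list(seq_len(n_a)),
      purrr::map(seq_len(n_mc - 1), ~ sort(sample.int(n, n_a))))
  }
  eval_assignment <- function(idx) {
    a_ids <- all_fish[idx]
    tryCatch(
      statistic(
        pooled[pooled$fish_id %in% a_ids, , drop = FALSE],
        pooled[!pooled$fish_id %in% a_ids, , drop = FALSE]
      ),
      error = function(e) NA_real_
    )
  }
  stats_all <- purrr::map_dbl(assignments, eval_assignment)
  identity_idx <- which(purrr::map_lgl(
    assignments, ~ identical(all_fish[.x], fish_a)
  ))[1]
  observed <- stats_all[identity_idx]
  if (!is.finite(observed)) {
    stop("statistic failed on the observed grouping", call. = FALSE)
  }
  ok <- is.finite(stats_all)
  p <- mean(stats_all[ok] >= observed)
  structure(
    list(
      p_value = p, observed = observed,
      permutation_statistics = stats_all[ok],
      n_permutations = sum(ok), n_excluded = sum(!ok), exact = exact
    ),
    class = "okr_permutation_test"
  )
}

#' @export
print.okr_permutation_test <- function(x, ...) {
  cat(sprintf(
    "<okr_permutation_test> observed = %.4g, p = %.4g (%d %s permutations, %d excluded)\n",
    x$observed, x$p_value, x$n_permutations,
    if (x$exact) "exact" else "Monte-Carlo", x$n_excluded
  ))
  invisible(x)
}

#' @rdname permutation_test_elevation
#' @param x An `okr_permutation_test`.
#' @param ... Unused.
#' @export
glance.okr_permutation_test <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, observed = x$observed,
    n_permutations = x$n_permutations, n_excluded = x$n_excluded,
    exact = x$exact
  )
}
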