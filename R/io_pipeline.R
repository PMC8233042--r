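#' Write eye traces to CSV with a JSON sidecar
#'
#' The CSV holds one row per frame with columns `time_s`, `left_deg`,
#' `right_deg` (angles in degrees, rounded to 6 decimals); recording
#' metadata (fish id, stimulus id, arena orientation, embedding) goes into a
#' JSON sidecar next to it.
#'
#' @param left,right `okr_trace` tibbles for the two eyes of one recording,
#'   sampled on the same time base.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param arena_orientation,embedding Metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_eye_traces <- function(left, right, path, arena_orientation = 1,
                             embedding = "upright") {
  stopifnot(nrow(left) == nrow(right),
            max(abs(left$time_s - right$time_s)) < 1e-9)
  df <- data.frame(
    time_s = round(left$time_s, 6),
    left_deg = round(left$angle_deg, 6),
    right_deg = round(right$angle_deg, 6)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    fish_id = left$fish_id[1], stimulus_id = left$stimulus_id[1],
    arena_orientation = arena_orientation, embedding = embedding
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' Read eye traces from CSV (+ JSON sidecar)
#'
#' Validates the file structure: the required columns must be present, time
#' must be strictly increasing and all values finite; offending rows are
#' reported with their line numbers.
#'
#' @param path CSV path written by [write_eye_traces()] (sidecar optional).
#' @return A list with `okr_trace` elements `left` and `right` and the
#'   `meta` list.
#' @export
read_eye_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty trace file: ", path, call. = FALSE)
  need <- c("time_s", "left_deg", "right_deg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !apply(is.finite(as.matrix(df[need])), 1, all))
  if (length(bad) > 0) {
    stop("malformed rows (data lines ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", ")", call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar)
  } else {
    list(fish_id = "unknown", stimulus_id = "unknown",
         arena_orientation = 1, embedding = "upright")
  }
  list(
    left = eye_trace(df$time_s, df$left_deg, eye = "left",
                     fish_id = meta$fish_id, stimulus_id = meta$stimulus_id),
    right = eye_trace(df$time_s, df$right_deg, eye = "right",
                      fish_id = meta$fish_id, stimulus_id = meta$stimulus_id),
    meta = meta
  )
}

#' Pipeline configuration
#'
#' Gathers every tunable threshold of the analysis with its default, so a
#' full run is reproducible from one object. Unknown argument names are
#' rejected.
#'
#' @param seed RNG seed governing every stochastic stage.
#' @param n_fish,n_reps Cohort size for the synthetic run.
#' @param crop_half_angle Stimulus disk half-angle, degrees.
#' @param vel_threshold,min_separation,pad Saccade-detector settings.
#' @param r2_min,drift_threshold Trial QC settings.
#' @param kappa_smooth Kernel concentration of the smoothed map.
#' @param n_starts vMF fit multi-start count.
#' @param aggregate Gain aggregation mode for the vMF fit.
#' @param use_traces Simulate and analyse raw traces (`TRUE`) or work from
#'   the gain records directly (`FALSE`, faster).
#' @return A list of class `okr_config`.
#' @export
pipeline_config <- function(seed = 1, n_fish = 7, n_reps = 2,
                            crop_half_angle = 20,
                            vel_threshold = 40, min_separation = 0.5,
                            pad = 0.1, r2_min = 0.3, drift_threshold = 0.2,
                            kappa_smooth = 20, n_starts = 5,
                            aggregate = "median", use_traces = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "okr_config")
}

#' Run the full OKR analysis pipeline on a synthetic cohort
#'
#' Sequence: generate the cohort (or accept a supplied dataset), optionally
#' fit every raw trace (saccade removal, piecewise sinusoid, QC with audited
#' exclusions), aggregate gains, fit the bimodal vMF map per eye and for the
#' merged direct-stimulation records, compute yoking and bias indices and
#' the two-stage asymmetry regression. Deterministic under the config seed.
#'
#' @param config An `okr_config`.
#' @param dataset Optional dataset from [generate_dataset()]; if `NULL` one
#'   is generated from the config.
#' @return A list of class `okr_report`: `records` (post-QC gain records),
#'   `excluded` (tibble of excluded trials with reasons), `vmf_fits` (list:
#'   left, right, merged), `yoking`, `biases`, `asymmetry`, and `config`.
#' @export
run_okr_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "okr_config"))
  if (is.null(dataset)) {
    cohort <- synthetic_cohort(
      n_fish = config$n_fish, n_reps = config$n_reps,
      crop_half_angle = config$crop_half_angle, seed = config$seed
    )
    dataset <- generate_dataset(cohort, traces = config$use_traces)
  }
  records <- dataset$records
  excluded <- tibble::tibble(
    fish_id = character(), eye = character(), stimulus_id = character(),
    repetition = integer(), reason = character()
  )
  if (!is.null(dataset$traces)) {
    spec <- stimulus_spec(crop_half_angle = config$crop_half_angle)
    fitted <- purrr::pmap_dfr(
      dataset$traces[, c("fish_id", "eye", "stimulus_id", "repetition",
                         "azimuth", "elevation", "stimulated",
                         "arena_orientation", "embedding", "trace")],
      function(fish_id, eye, stimulus_id, repetition, azimuth, elevation,
               stimulated, arena_orientation, embedding, trace) {
        seg <- detect_saccades(trace, vel_threshold = config$vel_threshold,
                               min_separation = config$min_separation,
                               pad = config$pad)
        fit <- fit_piecewise_sinusoid(trace, seg,
                                      f_init = spec$envelope_frequency)
        qc <- qc_trial(fit, r2_min = config$r2_min,
                       drift_threshold = config$drift_threshold)
        tibble::tibble(
          fish_id = fish_id, eye = eye, stimulus_id = stimulus_id,
          repetition = repetition, azimuth = azimuth, elevation = elevation,
          gain = fit$c1 / stimulus_position_amplitude(spec),
          stimulated = stimulated, arena_orientation = arena_orientation,
          embedding = embedding, accept = qc$accept, reason = qc$reason
        )
      }
    )
    excluded <- dplyr::select(
      dplyr::filter(fitted, !.data$accept),
      "fish_id", "eye", "stimulus_id", "repetition", "reason"
    )
    records <- dplyr::select(
      dplyr::filter(fitted, .data$accept), -"accept", -"reason"
    )
  }
  direct_of <- function(d) {
    d[(d$stimulated == "both") |
        (d$stimulated == "left" & d$eye == "left") |
        (d$stimulated == "right" & d$eye == "right"), ]
  }
  fit_eye <- function(d) {
    fit_bimodal_vmf(d, n_starts = config$n_starts,
                    aggregate = config$aggregate, seed = config$seed)
  }
  vmf_fits <- list(
    left = fit_eye(records[records$eye == "left", ]),
    right = fit_eye(records[records$eye == "right", ]),
    merged = fit_eye(direct_of(records))
  )
  wide <- tidyr::pivot_wider(
    records,
    id_cols = c("fish_id", "stimulus_id", "repetition"),
    names_from = "eye", values_from = "gain"
  )
  # phases where QC removed one of the two eyes have no yoking index
  wide <- wide[is.finite(wide$left) & is.finite(wide$right), ]
  yoking <- yoking_index(wide$left, wide$right)
  yoking$fish_id <- wide$fish_id
  biases <- purrr::map_dfr(
    split(direct_of(records), direct_of(records)$fish_id), bias_index
  )
  asymmetry <- if (length(unique(biases$arena_orientation)) >= 2) {
    fit_asymmetry_model(biases)
  } else NULL
  structure(
    list(
      records = records, excluded = excluded, vmf_fits = vmf_fits,
      yoking = yoking, biases = biases, asymmetry = asymmetry,
      config = config
    ),
    class = "okr_report"
  )
}

#' @export
print.okr_report <- function(x, ...) {
  cat("<okr_report>", nrow(x$records), "gain records,",
      nrow(x$excluded), "excluded trials\n")
  cat("  merged map: ")
  print(x$vmf_fits$merged$model)
  cat(sprintf("  median yoking index %.3f\n",
              stats::median(x$yoking$Y, na.rm = TRUE)))
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report An `okr_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly if written).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "okr_report"))
  fits <- purrr::map(report$vmf_fits, function(f) {
    list(model = unclass(f$model), rss = f$rss, r_squared = f$r_squared,
         maxima = f$maxima)
  })
  obj <- list(
    n_records = nrow(report$records),
    n_excluded = nrow(report$excluded),
    excluded = report$excluded,
    vmf_fits = fits,
    median_yoking = stats::median(report$yoking$Y, na.rm = TRUE),
    biases = report$biases,
    asymmetry = if (!is.null(report$asymmetry)) {
      list(b1 = report$asymmetry$b1, b2 = report$asymmetry$b2,
           b3 = report$asymmetry$b3)
    },
    version = as.character(utils::packageVersion("okrsphere"))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 8, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
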