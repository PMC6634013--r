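#' Read an RR-interval series from its text format
#'
#' The on-disk format is a UTF-8 CSV with header
#' `beat_index,t_ms,rr_ms`, one row per beat, intervals in
#' milliseconds. Malformed rows are reported with their line numbers.
#'
#' @param path Path to the file.
#' @param ... Passed to [rr_series()] (e.g. `bounds`,
#'   `drop_out_of_range`).
#' @return An [rr_series()].
#' @export
read_rr <- function(path, ...) {
  df <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(
      beat_index = readr::col_double(),
      t_ms = readr::col_double(),
      rr_ms = readr::col_double()
    ), progress = FALSE)
  )
  need <- c("beat_index", "t_ms", "rr_ms")
  if (!all(need %in% names(df))) {
    abort(paste0("missing column(s): ",
                 paste(setdiff(need, names(df)), collapse = ", ")),
          class = "afrr_parse_error")
  }
  # +1 for the header line when naming offending lines
  bad <- which(!is.finite(df$rr_ms))
  if (length(bad)) {
    abort(paste0("non-numeric rr_ms at line(s): ",
                 paste(utils::head(bad + 1, 5), collapse = ", ")),
          class = "afrr_parse_error")
  }
  bad <- which(df$rr_ms <= 0)
  if (length(bad)) {
    abort(paste0("non-positive rr_ms at line(s): ",
                 paste(utils::head(bad + 1, 5), collapse = ", ")),
          class = "afrr_parse_error")
  }
  rr_series(df$rr_ms, meta = list(source = path), ...)
}

#' Write an RR-interval series to its text format
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path) {
  stopifnot(is.data.frame(series),
            all(c("beat_index", "t_ms", "rr_ms") %in% names(series)))
  readr::write_csv(series[, c("beat_index", "t_ms", "rr_ms")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write labeled beats as JSON
#'
#' Emits `{meta, params, beats: [...]}` with label strings exactly
#' `"probable_af" | "normal" | "unclassified_non_af" | "warmup"`. The
#' resolved classifier parameters are embedded so every result is
#' traceable to its configuration.
#'
#' @param labeled An `rr_labels` tibble from [classify_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_json <- function(labeled, path) {
  params <- labels_params(labeled)
  doc <- list(
    meta = attr(labeled, "meta") %||% list(),
    params = unclass(params),
    beats = labeled[, c("beat_index", "t_ms", "rr_ms", "label", "index_value")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a recording decision as JSON
#'
#' @param decision A `recording_decision`.
#' @param path Output path.
#' @param params Optional [classifier_params()] to embed.
#' @return `path`, invisibly.
#' @export
write_decision_json <- function(decision, path, params = NULL) {
  stopifnot(inherits(decision, "recording_decision"))
  doc <- unclass(decision)
  if (!is.null(params)) doc$params <- unclass(params)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a diagnostic-metrics summary as JSON
#'
#' @param metrics A `diagnostic_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "diagnostic_metrics"))
  m <- metrics$table$counts
  fe <- metrics$metrics[metrics$metrics$flutter_handling == "excluded", ]
  fn <- metrics$metrics[metrics$metrics$flutter_handling == "as_negative", ]
  row <- function(df, what) df[df$metric == what, ]
  doc <- list(
    table = list(af = unname(m["af", ]), flutter = unname(m["aflutter", ]),
                 sr = unname(m["sr", ])),
    flutter_excluded = list(
      sens = row(fe, "sensitivity")$estimate,
      sens_ci = c(row(fe, "sensitivity")$conf.low, row(fe, "sensitivity")$conf.high),
      spec = row(fe, "specificity")$estimate,
      spec_ci = c(row(fe, "specificity")$conf.low, row(fe, "specificity")$conf.high)
    ),
    flutter_as_negative = list(
      spec = row(fn, "specificity")$estimate,
      spec_ci = c(row(fn, "specificity")$conf.low, row(fn, "specificity")$conf.high),
      kappa = metrics$kappa$estimate,
      kappa_ci = c(metrics$kappa$conf.low, metrics$kappa$conf.high)
    ),
    af_prevalence_flutter_excluded = metrics$prevalence,
    n_pairs = metrics$n_pairs,
    methods = metrics$methods
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a study corpus to disk
#'
#' Writes each recording in the RR CSV format plus a `manifest.json`
#' listing per-recording truth labels, phase, seeds and the study spec.
#'
#' @param corpus An `af_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(corpus, dir) {
  stopifnot(is.data.frame(corpus), "series" %in% names(corpus))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus))) {
    write_rr(corpus$series[[i]],
             file.path(dir, paste0(corpus$recording_id[i], ".csv")))
  }
  manifest <- dplyr::select(as_tibble(corpus), -"series")
  doc <- list(recordings = manifest,
              spec = unclass(attr(corpus, "spec")))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a study manifest
#'
#' @param path Path to a `manifest.json` written by [write_study()].
#' @return A tibble of recordings (`recording_id`, `truth`, `phase`, ...).
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tibble(doc$recordings)
}

default_config <- function() {
  list(
    classifier = unclass(classifier_params()),
    decision = list(min_af_fraction = 0.90, weighting = "duration"),
    simulate = list(duration_s = 600,
                    sr = list(mean_rr_ms = 800, resp_freq_hz = 0.25,
                              resp_depth = 0.03, noise_sd_ms = 15),
                    af = list(mean_rr_ms = 600, cv = 0.20),
                    aflutter = list(atrial_cycle_ms = 220,
                                    conduction_ratios = c(2, 4),
                                    jitter_sd_ms = 5)),
    evaluate = list(ci_method = "exact", conf_level = 0.95,
                    kappa_handling = "as_negative")
  )
}

check_keys <- function(user, ref, path = "") {
  for (k in names(user)) {
    if (!k %in% names(ref)) {
      abort(paste0("unknown config key: ", path, k),
            class = "afrr_invalid_config")
    }
    if (is.list(ref[[k]]) && is.list(user[[k]])) {
      check_keys(user[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
}

#' Read a run configuration
#'
#' YAML configuration with strict schema validation: every field has a
#' default, unknown keys are rejected, and the file round-trips
#' losslessly through [write_run_config()]. The resolved classifier
#' parameters are embedded in every result the CLI writes, because the
#' shipped thresholds are declared substitutes and must stay visible.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A nested list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    check_keys(user, cfg)
    cfg <- utils::modifyList(cfg, user)
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param config A `run_config` (or the output of [read_run_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config) {
  do.call(classifier_params, config$classifier)
}
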