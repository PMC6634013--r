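#' AF burden of a labeled recording
#'
#' Fraction of the classified recording labeled probable AF. By default
#' each beat contributes its own RR interval to the duration it is
#' labeled with ("total duration" weighting); `weighting = "count"`
#' weights every beat equally. Warm-up beats are excluded from both
#' numerator and denominator, so a short warm-up cannot flip a
#' recording's call.
#'
#' @param labeled An `rr_labels` tibble from [classify_stream()].
#' @param weighting `"duration"` (default) or `"count"`.
#' @return Scalar burden in \[0,1\].
#' @examples
#' labs <- classify_stream(simulate_af(duration_s = 120, seed = 1))
#' af_burden(labs)
#' @export
af_burden <- function(labeled, weighting = c("duration", "count")) {
  weighting <- match.arg(weighting)
  if (!all(c("label", "rr_ms") %in% names(labeled))) {
    abort("labeled input needs `label` and `rr_ms` columns",
          class = "afrr_invalid_input")
  }
  classified <- labeled$label != "warmup"
  if (!any(classified)) {
    abort("recording is all warm-up: no classified beats to aggregate",
          class = "afrr_indeterminate_recording")
  }
  wgt <- if (weighting == "duration") labeled$rr_ms[classified] else
    rep(1, sum(classified))
  sum(wgt[labeled$label[classified] == "probable_af"]) / sum(wgt)
}

#' Aggregate a labeled recording into a binary AF call
#'
#' A recording is called AF when its AF burden reaches
#' `min_af_fraction` of the classified duration ("at least" -- the
#' boundary is inclusive, so a burden of exactly 0.90 is AF under the
#' default). The most prevalent non-AF label is reported for context.
#'
#' @inheritParams af_burden
#' @param min_af_fraction Burden threshold in (0, 1\]; default 0.90.
#' @return A list of class `recording_decision`: `af_burden`, `call`
#'   (`"AF"`/`"NON_AF"`), `dominant_non_af_label`, `min_af_fraction`,
#'   `weighting`, `classified_duration_ms`, `warmup_duration_ms`,
#'   `n_beats`.
#' @examples
#' labs <- classify_stream(simulate_af(duration_s = 120, seed = 1))
#' aggregate_recording(labs)
#' @export
aggregate_recording <- function(labeled, min_af_fraction = 0.90,
                                weighting = c("duration", "count")) {
  weighting <- match.arg(weighting)
  if (!(min_af_fraction > 0 && min_af_fraction <= 1)) {
    abort("min_af_fraction must lie in (0, 1]", class = "afrr_invalid_params")
  }
  burden <- af_burden(labeled, weighting)
  classified <- labeled$label != "warmup"
  non_af <- labeled$label[classified & labeled$label != "probable_af"]
  dominant <- if (length(non_af)) names(which.max(table(non_af))) else NA_character_
  structure(
    list(
      af_burden = burden,
      call = if (burden >= min_af_fraction) "AF" else "NON_AF",
      dominant_non_af_label = dominant,
      min_af_fraction = min_af_fraction,
      weighting = weighting,
      classified_duration_ms = sum(labeled$rr_ms[classified]),
      warmup_duration_ms = sum(labeled$rr_ms[!classified]),
      n_beats = nrow(labeled)
    ),
    class = "recording_decision"
  )
}

#' Collapse a recording decision to the binary app vocabulary
#'
#' Both non-AF classes (normal rhythm and unclassified non-AF
#' arrhythmia) count as an app-negative: only the AF call maps to
#' `"app_af"`.
#'
#' @param decision A `recording_decision` from [aggregate_recording()].
#' @return `"app_af"` or `"app_no_af"`.
#' @export
to_binary <- function(decision) {
  stopifnot(inherits(decision, "recording_decision"))
  if (decision$call == "AF") "app_af" else "app_no_af"
}

#' @export
print.recording_decision <- function(x, ...) {
  cat(sprintf("<recording_decision: %s, AF burden %.3f (threshold %.2f, %s-weighted)>\n",
              x$call, x$af_burden, x$min_af_fraction, x$weighting))
  if (!is.na(x$dominant_non_af_label)) {
    cat(sprintf("  dominant non-AF label: %s\n", x$dominant_non_af_label))
  }
  cat(sprintf("  classified %.1f s, warm-up %.1f s, %d beats\n",
              x$classified_duration_ms / 1000, x$warmup_duration_ms / 1000,
              x$n_beats))
  invisible(x)
}

#' @export
tidy.recording_decision <- function(x, ...) {
  tibble(
    call = x$call,
    af_burden = x$af_burden,
    dominant_non_af_label = x$dominant_non_af_label,
    min_af_fraction = x$min_af_fraction,
    weighting = x$weighting,
    classified_duration_ms = x$classified_duration_ms,
    warmup_duration_ms = x$warmup_duration_ms,
    n_beats = x$n_beats
  )
}

#' @export
glance.recording_decision <- function(x, ...) tidy(x)
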