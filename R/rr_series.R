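#' Construct an RR-interval series
#'
#' An RR series is the sole physiological input to the classifier: one
#' row per heartbeat with its beat-to-beat interval `rr_ms` and cumulative
#' onset time `t_ms` (`t_ms[i] = t_ms[i-1] + rr_ms[i]`, starting at
#' `rr_ms[1]`). Intervals outside the physiological ingestion bounds are
#' flagged and, by default, passed through: artifactual intervals
#' legitimately raise RR heterogeneity, mirroring what a chest-strap
#' sensor actually delivers. Set `drop_out_of_range = TRUE` to discard
#' them instead.
#'
#' @param rr_ms Numeric vector of beat-to-beat intervals in milliseconds;
#'   all strictly positive, length at least 1.
#' @param meta Named list of free-form recording annotations (subject id,
#'   phase, true rhythm if known).
#' @param bounds Length-2 numeric, accepted physiological range in ms
#'   (default 240-3000, i.e. 20-250 bpm).
#' @param drop_out_of_range Drop flagged intervals instead of passing
#'   them through flagged.
#'
#' @return A tibble of class `rr_series` with columns `beat_index`,
#'   `t_ms`, `rr_ms`, `flagged`, and attributes `meta` and `bounds`.
#' @examples
#' rr_series(c(800, 810, 795), meta = list(subject = "demo"))
#' @export
rr_series <- function(rr_ms, meta = list(), bounds = c(240, 3000),
                      drop_out_of_range = FALSE) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 1) {
    abort("an RR series needs at least one beat", class = "afrr_invalid_input")
  }
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    abort("all RR intervals must be finite and strictly positive",
          class = "afrr_invalid_input")
  }
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  flagged <- rr_ms < bounds[1] | rr_ms > bounds[2]
  if (drop_out_of_range && any(flagged)) {
    rr_ms <- rr_ms[!flagged]
    if (length(rr_ms) < 1) {
      abort("all intervals fell outside the ingestion bounds",
            class = "afrr_invalid_input")
    }
    flagged <- rep(FALSE, length(rr_ms))
  }
  out <- tibble(
    beat_index = seq_along(rr_ms),
    t_ms = cumsum(rr_ms),
    rr_ms = rr_ms,
    flagged = flagged
  )
  structure(out,
            class = c("rr_series", class(out)),
            meta = meta, bounds = bounds)
}

#' Recording annotations of an RR series
#'
#' @param series An `rr_series`.
#' @return The `meta` list attached at construction (possibly empty).
#' @export
rr_meta <- function(series) attr(series, "meta") %||% list()

# Pull a validated rr_ms vector out of whatever the user handed us.
rr_values <- function(series) {
  if (is.data.frame(series)) {
    if (!"rr_ms" %in% names(series)) {
      abort("input must contain an `rr_ms` column", class = "afrr_invalid_input")
    }
    rr <- series$rr_ms
  } else {
    rr <- as.numeric(series)
  }
  if (length(rr) < 1) {
    abort("empty RR series", class = "afrr_invalid_input")
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    abort("RR intervals must be finite and strictly positive",
          class = "afrr_invalid_input")
  }
  rr
}

#' @export
print.rr_series <- function(x, ...) {
  meta <- rr_meta(x)
  cat(sprintf("<rr_series: %d beats, %.1f s%s>\n",
              nrow(x), max(x$t_ms) / 1000,
              if (length(meta)) paste0(", ", paste(names(meta), unlist(lapply(meta, format)),
                                                   sep = "=", collapse = ", "))
              else ""))
  NextMethod()
}
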