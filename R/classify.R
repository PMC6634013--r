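#' Classifier parameters
#'
#' Parameters of the windowed RR-heterogeneity classifier. Each beat is
#' scored from the trailing window of `window_n` immediately prior RR
#' intervals (the beat itself included): a variability component
#' (normalized RMSSD, saturated to \[0,1\] by `v_scale`) and a randomness
#' component (first-order entropy rate of the ternary delta-RR
#' symbolization with half-width `delta_ms`) are mixed with weights
#' `w_v`/`w_r` into a combined index in \[0,1\], then cut at two
#' thresholds: index >= `theta_af` is probable AF, index < `theta_sr` is
#' normal rhythm, anything between is unclassified non-AF arrhythmia.
#'
#' The shipped thresholds and `delta_ms` were calibrated once against
#' the package's synthetic corpora (see the methods vignette); they are
#' declared substitutes for an unpublished commercial parameterization,
#' not reconstructions of it.
#'
#' @param window_n Beats per data matrix window; >= 8, default 32
#'   (roughly 20-30 s of latency at resting rates).
#' @param w_v,w_r Nonnegative weights of the variability and randomness
#'   components; must sum to 1.
#' @param theta_af Upper cutoff: combined index at or above it labels the
#'   beat probable AF.
#' @param theta_sr Lower cutoff: combined index strictly below it labels
#'   the beat normal rhythm. Must satisfy `0 <= theta_sr < theta_af <= 1`.
#' @param v_scale Saturation constant (dimensionless) of the variability
#'   transform `v = v_raw / (v_raw + v_scale)`.
#' @param delta_ms Half-width in ms of the "no change" band of the
#'   ternary delta-RR symbolization.
#'
#' @return A list of class `classifier_params`.
#' @examples
#' classifier_params()
#' classifier_params(window_n = 64, theta_af = 0.6)
#' @export
classifier_params <- function(window_n = 32, w_v = 0.5, w_r = 0.5,
                              theta_af = 0.52, theta_sr = 0.35,
                              v_scale = 0.1, delta_ms = 50) {
  window_n <- as.integer(window_n)
  if (window_n < 8) abort("window_n must be at least 8", class = "afrr_invalid_params")
  if (w_v < 0 || w_r < 0 || abs(w_v + w_r - 1) > 1e-9) {
    abort("w_v and w_r must be nonnegative and sum to 1",
          class = "afrr_invalid_params")
  }
  if (!(theta_sr >= 0 && theta_sr < theta_af && theta_af <= 1)) {
    abort("need 0 <= theta_sr < theta_af <= 1", class = "afrr_invalid_params")
  }
  if (v_scale <= 0) abort("v_scale must be positive", class = "afrr_invalid_params")
  if (delta_ms < 0) abort("delta_ms must be nonnegative", class = "afrr_invalid_params")
  structure(
    list(window_n = window_n, w_v = w_v, w_r = w_r,
         theta_af = theta_af, theta_sr = theta_sr,
         v_scale = v_scale, delta_ms = delta_ms),
    class = "classifier_params"
  )
}

#' @export
print.classifier_params <- function(x, ...) {
  cat("<classifier_params>\n")
  cat(sprintf("  window_n: %d beats\n", x$window_n))
  cat(sprintf("  weights:  variability %.2f / randomness %.2f\n", x$w_v, x$w_r))
  cat(sprintf("  cutoffs:  normal < %.2f <= unclassified < %.2f <= probable AF\n",
              x$theta_sr, x$theta_af))
  cat(sprintf("  v_scale:  %.3f   delta_ms: %.0f\n", x$v_scale, x$delta_ms))
  invisible(x)
}

#' RR variability index of one window
#'
#' Normalized RMSSD: the root mean square of successive RR differences
#' divided by the window's mean RR. Dimensionless, nonnegative, and
#' invariant to multiplying every interval by a positive constant.
#'
#' @param window Numeric vector of RR intervals in ms, length >= 2, all
#'   positive.
#' @return Nonnegative scalar.
#' @examples
#' variability_index(rep(800, 32))          # 0: no successive change
#' variability_index(c(800, 800, 1600))     # 0.5303
#' @export
variability_index <- function(window) {
  window <- rr_values(window)
  if (length(window) < 2) {
    abort("variability_index needs a window of at least 2 beats",
          class = "afrr_invalid_window")
  }
  d <- diff(window)
  sqrt(mean(d^2)) / mean(window)
}

# Ternary symbolization of successive RR differences:
# 0 = within +/- delta, 1 = increase beyond delta, 2 = decrease beyond delta.
symbolize_drr <- function(d, delta_ms) {
  s <- integer(length(d))
  s[d > delta_ms] <- 1L
  s[d < -delta_ms] <- 2L
  s
}

#' First-order entropy rate of a symbol sequence
#'
#' Plug-in conditional Shannon entropy H(next | current) estimated from
#' symbol-pair counts, normalized by log(alphabet size) so the result
#' lies in \[0,1\]. Zero for any deterministic first-order pattern
#' (constant, strict alternation); near 1 for long i.i.d. equiprobable
#' sequences. `0 * log 0` is taken as 0 and no bias correction is
#' applied: the window is short and the quantity is a feature, not an
#' estimator of a population entropy.
#'
#' @param symbols Integer vector with values in `0:(alphabet - 1)`,
#'   length >= 3 (at least two pairs).
#' @param alphabet Alphabet size (default 3, the delta-RR ternary code).
#' @return Scalar in \[0,1\].
#' @export
symbol_entropy_rate <- function(symbols, alphabet = 3L) {
  symbols <- as.integer(symbols)
  if (length(symbols) < 3) {
    abort("need at least 3 symbols (two pairs)", class = "afrr_invalid_window")
  }
  if (any(symbols < 0L | symbols >= alphabet)) {
    abort("symbols out of alphabet range", class = "afrr_invalid_window")
  }
  a <- symbols[-length(symbols)]
  b <- symbols[-1]
  counts <- tabulate(alphabet * a + b + 1L, nbins = alphabet^2)
  n_pairs <- sum(counts)
  row_marg <- rowSums(matrix(counts, nrow = alphabet, byrow = TRUE))
  marg_per_cell <- rep(row_marg, each = alphabet)
  nz <- counts > 0
  h <- sum(counts[nz] / n_pairs * log(marg_per_cell[nz] / counts[nz]))
  h / log(alphabet)
}

#' RR randomness index of one window
#'
#' Serial randomness of the RR stream: successive RR differences are
#' symbolized into decrease / steady / increase (half-width `delta_ms`)
#' and the first-order entropy rate of that ternary symbol stream is
#' returned, normalized to \[0,1\]. Regularly irregular rhythms such as
#' atrial flutter with patterned AV conduction produce deterministic
#' symbol patterns and score exactly 0, which is what keeps them out of
#' the AF class however variable their RR intervals are.
#'
#' @param window Numeric vector of RR intervals in ms, length >= 8.
#' @param delta_ms Symbolization half-width in ms (default 50).
#' @return Scalar in \[0,1\].
#' @examples
#' randomness_index(rep(800, 32))                       # 0
#' randomness_index(rep(c(600, 900), 16))               # 0: strict alternation
#' @export
randomness_index <- function(window, delta_ms = 50) {
  window <- rr_values(window)
  if (length(window) < 8) {
    abort("randomness_index needs a window of at least 8 beats",
          class = "afrr_invalid_window")
  }
  symbol_entropy_rate(symbolize_drr(diff(window), delta_ms), alphabet = 3L)
}

#' Combine variability and randomness into the heterogeneity index
#'
#' Saturates the raw variability `v = v_raw / (v_raw + v_scale)` into
#' \[0,1\] and mixes it with the randomness index: `index = w_v * v +
#' w_r * rn`. Monotone nondecreasing in both components.
#'
#' @param v_raw Nonnegative raw variability (normalized RMSSD).
#' @param rn Randomness index in \[0,1\].
#' @param params A [classifier_params()] object.
#' @return A one-row tibble with columns `v_raw`, `v`, `rn`, `index`.
#' @examples
#' heterogeneity_index(0.28, 0.8)
#' @export
heterogeneity_index <- function(v_raw, rn, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  if (any(v_raw < 0)) abort("v_raw must be nonnegative", class = "afrr_invalid_input")
  if (any(rn < 0 | rn > 1)) abort("rn must lie in [0,1]", class = "afrr_invalid_input")
  v <- v_raw / (v_raw + params$v_scale)
  tibble(v_raw = v_raw, v = v, rn = rn,
         index = params$w_v * v + params$w_r * rn)
}

#' Label one beat from its heterogeneity index
#'
#' `index >= theta_af` is probable AF; `index < theta_sr` is normal
#' rhythm; the band between (ties at `theta_sr` included) is
#' unclassified non-AF arrhythmia. Raising the index never moves the
#' label away from probable AF.
#'
#' @param index Combined heterogeneity index in \[0,1\] (vectorized).
#' @param params A [classifier_params()] object.
#' @return Character vector of labels `"probable_af"`, `"normal"`,
#'   `"unclassified_non_af"`.
#' @export
classify_beat <- function(index, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  if (any(index < -1e-12 | index > 1 + 1e-12, na.rm = TRUE)) {
    abort("index must lie in [0,1]", class = "afrr_invalid_input")
  }
  out <- rep("unclassified_non_af", length(index))
  out[index >= params$theta_af] <- "probable_af"
  out[index < params$theta_sr] <- "normal"
  out[is.na(index)] <- NA_character_
  out
}

#' Classify every beat of an RR series
#'
#' Streaming, causal, single-pass labeling: the label of beat `i` is
#' computed from the trailing window of `window_n` beats ending at `i`.
#' The first `window_n - 1` beats carry the `"warmup"` sentinel and no
#' index. The computation is deterministic: identical series and
#' parameters give identical labels.
#'
#' @param series An [rr_series()] (or any data frame with an `rr_ms`
#'   column).
#' @param params A [classifier_params()] object.
#' @return A tibble of class `rr_labels`, one row per beat:
#'   `beat_index`, `t_ms`, `rr_ms`, `label`, `index_value`, `v`, `rn`.
#'   The parameters used are attached as attribute `params`.
#' @examples
#' af <- simulate_af(duration_s = 120, seed = 1)
#' labs <- classify_stream(af)
#' table(labs$label)
#' @export
classify_stream <- function(series, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  rr <- rr_values(series)
  n <- length(rr)
  w <- params$window_n

  index <- v <- rn <- rep(NA_real_, n)
  label <- rep("warmup", n)

  if (n >= w) {
    i <- w:n
    d <- diff(rr)
    # rolling RMSSD / mean over the trailing window of w beats
    d2 <- c(0, cumsum(d^2))
    sum_d2 <- d2[i] - d2[i - w + 1]
    rms <- sqrt(sum_d2 / (w - 1))
    rc <- c(0, cumsum(rr))
    mean_rr <- (rc[i + 1] - rc[i - w + 1]) / w
    v_raw <- rms / mean_rr

    # rolling symbol-pair counts; code in 1..9 indexes (first, next) symbol
    s <- symbolize_drr(d, params$delta_ms)
    code <- 3L * s[-(n - 1)] + s[-1] + 1L
    cc <- matrix(0L, nrow = length(code) + 1L, ncol = 9L)
    for (k in 1:9) cc[, k] <- c(0L, cumsum(code == k))
    counts <- cc[i - 1, , drop = FALSE] - cc[i - w + 1, , drop = FALSE]
    n_pairs <- w - 2
    row_marg <- cbind(rowSums(counts[, 1:3, drop = FALSE]),
                      rowSums(counts[, 4:6, drop = FALSE]),
                      rowSums(counts[, 7:9, drop = FALSE]))
    # columns are codes 3*a+b+1, so cell (a,b) takes the marginal of first symbol a
    marg_per_cell <- row_marg[, rep(1:3, each = 3), drop = FALSE]
    term <- counts / n_pairs * log(marg_per_cell / counts)
    term[counts == 0] <- 0
    rn_i <- rowSums(term) / log(3)

    feats <- heterogeneity_index(v_raw, rn_i, params)
    index[i] <- feats$index
    v[i] <- feats$v
    rn[i] <- rn_i
    label[i] <- classify_beat(feats$index, params)
  }

  out <- tibble(
    beat_index = seq_len(n),
    t_ms = cumsum(rr),
    rr_ms = rr,
    label = label,
    index_value = index,
    v = v,
    rn = rn
  )
  structure(out,
            class = c("rr_labels", class(out)),
            params = params, meta = rr_meta(series))
}

#' Parameters attached to a labeled stream
#' @param labeled An `rr_labels` tibble from [classify_stream()].
#' @return The [classifier_params()] used.
#' @export
labels_params <- function(labeled) attr(labeled, "params")
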