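# Seeded synthetic RR-series generators for the rhythm types a
# cardioversion cohort exhibits. Every generator is a pure function of
# its arguments and seed; series stop at the first beat whose cumulative
# time reaches the requested duration.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

cut_to_duration <- function(rr, duration_ms) {
  keep <- which(cumsum(rr) >= duration_ms)
  if (length(keep) == 0) rr else rr[seq_len(keep[1])]
}

#' Simulate sinus rhythm with respiratory modulation
#'
#' `rr_i = mu * (1 + a * sin(2 pi f t_i)) + sigma * eps_i`: a steady
#' rate modulated by respiration (respiratory sinus arrhythmia) plus
#' Gaussian beat-to-beat noise. Defaults give a coefficient of variation
#' of roughly 0.03-0.05, typical of resting sinus rhythm.
#'
#' @param duration_s Recording length in seconds (default 600, a
#'   10-minute recording).
#' @param mean_rr_ms Mean RR interval mu in ms (default 800, 75 bpm).
#' @param resp_freq_hz Respiratory frequency f (default 0.25 Hz, 15
#'   breaths/min).
#' @param resp_depth Fractional modulation depth a (default 0.03).
#' @param noise_sd_ms Gaussian noise SD sigma in ms (default 15).
#' @param seed Integer seed; identical seeds give identical series.
#' @param meta Extra annotations merged into the series meta.
#' @return An [rr_series()].
#' @examples
#' simulate_sr(duration_s = 60, seed = 1)
#' @export
simulate_sr <- function(duration_s = 600, mean_rr_ms = 800,
                        resp_freq_hz = 0.25, resp_depth = 0.03,
                        noise_sd_ms = 15, seed = NULL, meta = list()) {
  stopifnot(duration_s > 0, mean_rr_ms > 0, resp_depth >= 0, noise_sd_ms >= 0)
  duration_ms <- duration_s * 1000
  n_max <- ceiling(duration_ms / (mean_rr_ms * (1 - resp_depth) * 0.5)) + 16L
  rr <- with_seed_if(seed, {
    eps <- rnorm(n_max)
    out <- numeric(n_max)
    t <- 0
    i <- 0L
    while (t < duration_ms && i < n_max) {
      i <- i + 1L
      r <- mean_rr_ms * (1 + resp_depth * sin(2 * pi * resp_freq_hz * t / 1000)) +
        noise_sd_ms * eps[i]
      r <- max(r, 1)
      out[i] <- r
      t <- t + r
    }
    out[seq_len(i)]
  })
  rr_series(rr, meta = utils::modifyList(
    list(rhythm = "sr", mean_rr_ms = mean_rr_ms, seed = seed), meta))
}

#' Simulate atrial fibrillation
#'
#' The irregularly irregular ventricular response of AF: i.i.d. Gamma
#' RR intervals with mean `mean_rr_ms` and coefficient of variation
#' `cv`, truncated by rejection to \[300, 1800\] ms (the range an
#' untreated ventricular response in AF realistically spans), with no
#' serial correlation.
#'
#' @inheritParams simulate_sr
#' @param mean_rr_ms Mean RR in ms (default 600, 100 bpm).
#' @param cv Coefficient of variation (default 0.20). `cv = 0` gives a
#'   degenerate constant series.
#' @param rr_range Truncation bounds in ms.
#' @return An [rr_series()].
#' @examples
#' simulate_af(duration_s = 60, seed = 1)
#' @export
simulate_af <- function(duration_s = 600, mean_rr_ms = 600, cv = 0.20,
                        rr_range = c(300, 1800), seed = NULL, meta = list()) {
  stopifnot(duration_s > 0, mean_rr_ms > 0, cv >= 0)
  duration_ms <- duration_s * 1000
  rr <- with_seed_if(seed, {
    if (cv == 0) {
      rep(mean_rr_ms, ceiling(duration_ms / mean_rr_ms))
    } else {
      shape <- 1 / cv^2
      scale <- mean_rr_ms * cv^2
      acc <- numeric(0)
      while (sum(acc) < duration_ms) {
        draw <- rgamma(256, shape = shape, scale = scale)
        acc <- c(acc, draw[draw >= rr_range[1] & draw <= rr_range[2]])
      }
      acc
    }
  })
  rr_series(cut_to_duration(rr, duration_ms), meta = utils::modifyList(
    list(rhythm = "af", mean_rr_ms = mean_rr_ms, cv = cv, seed = seed), meta))
}

#' Simulate atrial flutter
#'
#' A regularly irregular rhythm: the atria cycle at `atrial_cycle_ms`
#' and the ventricles follow at a repeating pattern of AV conduction
#' ratios, so `rr = ratio * atrial_cycle_ms` plus a little Gaussian
#' jitter. A single ratio gives fixed conduction (constant RR); the
#' default alternating 2:1/4:1 pattern gives a strictly alternating RR
#' sequence whose first-order randomness is exactly zero -- the
#' signature that keeps flutter out of the AF class.
#'
#' @inheritParams simulate_sr
#' @param atrial_cycle_ms Atrial cycle length in ms (default 220,
#'   ~270 bpm flutter waves).
#' @param conduction_ratios Integer vector of AV conduction ratios,
#'   recycled as a repeating pattern (default `c(2, 4)`).
#' @param jitter_sd_ms Gaussian jitter SD in ms (default 5).
#' @return An [rr_series()].
#' @examples
#' simulate_aflutter(duration_s = 60, conduction_ratios = 2, seed = 1)
#' @export
simulate_aflutter <- function(duration_s = 600, atrial_cycle_ms = 220,
                              conduction_ratios = c(2, 4), jitter_sd_ms = 5,
                              seed = NULL, meta = list()) {
  stopifnot(duration_s > 0, atrial_cycle_ms > 0, all(conduction_ratios >= 1),
            jitter_sd_ms >= 0)
  duration_ms <- duration_s * 1000
  min_rr <- min(conduction_ratios) * atrial_cycle_ms
  n_max <- ceiling(duration_ms / (min_rr * 0.5)) + 16L
  base <- rep_len(conduction_ratios, n_max) * atrial_cycle_ms
  rr <- with_seed_if(seed, pmax(base + rnorm(n_max, sd = jitter_sd_ms), 1))
  rr_series(cut_to_duration(rr, duration_ms), meta = utils::modifyList(
    list(rhythm = "aflutter", atrial_cycle_ms = atrial_cycle_ms,
         conduction_ratios = conduction_ratios, seed = seed), meta))
}

#' Inject premature (ectopic) beats into an RR series
#'
#' At each beat, with probability `rate_per_beat`, the interval `rr_i`
#' is replaced by an early ectopic coupling interval plus a pause:
#' `(c * rr_i, (1 - c) * rr_i)` in compensatory mode (the following
#' beat lands back on the underlying schedule, so total duration is
#' conserved to the millisecond), or `(c * rr_i, rr_i)` in
#' non-compensatory mode (the rhythm resets from the ectopic, PAC-like,
#' and the recording lengthens). Beat count grows by one per ectopic.
#' Frequent non-compensatory ectopy after cardioversion is the classic
#' false-positive mechanism for RR-only AF detectors.
#'
#' @param series An [rr_series()].
#' @param rate_per_beat Ectopic probability per beat, in \[0, 0.5\].
#' @param coupling_fraction Coupling interval as a fraction of the
#'   underlying RR (default 0.7).
#' @param compensatory Logical; see above.
#' @param seed Integer seed.
#' @return An [rr_series()] with ectopics inserted.
#' @examples
#' sr <- simulate_sr(duration_s = 60, seed = 1)
#' inject_ectopy(sr, rate_per_beat = 0.1, seed = 2)
#' @export
inject_ectopy <- function(series, rate_per_beat, coupling_fraction = 0.7,
                          compensatory = FALSE, seed = NULL) {
  if (rate_per_beat < 0 || rate_per_beat > 0.5) {
    abort("rate_per_beat must lie in [0, 0.5]", class = "afrr_invalid_params")
  }
  stopifnot(coupling_fraction > 0, coupling_fraction < 1)
  rr <- rr_values(series)
  out <- with_seed_if(seed, {
    ect <- runif(length(rr)) < rate_per_beat
    pieces <- lapply(seq_along(rr), function(i) {
      if (!ect[i]) return(rr[i])
      e1 <- coupling_fraction * rr[i]
      if (compensatory) c(e1, rr[i] - e1) else c(e1, rr[i])
    })
    unlist(pieces)
  })
  rr_series(out, meta = utils::modifyList(
    rr_meta(series),
    list(ectopy_rate = rate_per_beat, ectopy_compensatory = compensatory)))
}

#' Inject sensor artifacts (missed and split detections)
#'
#' A missed R-peak merges two adjacent intervals into their sum; a
#' spurious detection splits one interval into two halves. Both
#' operators conserve total duration exactly.
#'
#' @param series An [rr_series()].
#' @param drop_prob Per-beat probability of a missed detection, in
#'   \[0, 0.2\].
#' @param split_prob Per-beat probability of a split detection, in
#'   \[0, 0.2\].
#' @param seed Integer seed.
#' @return An [rr_series()].
#' @export
inject_artifacts <- function(series, drop_prob = 0, split_prob = 0,
                             seed = NULL) {
  if (drop_prob < 0 || drop_prob > 0.2 || split_prob < 0 || split_prob > 0.2) {
    abort("artifact probabilities must lie in [0, 0.2]",
          class = "afrr_invalid_params")
  }
  rr <- rr_values(series)
  n <- length(rr)
  out <- with_seed_if(seed, {
    u_drop <- runif(n)
    u_split <- runif(n)
    res <- numeric(0)
    i <- 1L
    while (i <= n) {
      if (i < n && u_drop[i] < drop_prob) {
        res <- c(res, rr[i] + rr[i + 1])
        i <- i + 2L
      } else if (u_split[i] < split_prob) {
        res <- c(res, rr[i] / 2, rr[i] / 2)
        i <- i + 1L
      } else {
        res <- c(res, rr[i])
        i <- i + 1L
      }
    }
    res
  })
  rr_series(out, meta = utils::modifyList(
    rr_meta(series),
    list(drop_prob = drop_prob, split_prob = split_prob)))
}
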