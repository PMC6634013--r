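#' Specification of a paired pre/post-cardioversion validation study
#'
#' Fixes the design of the synthetic validation cohort: patients
#' enrolled for elective electrical cardioversion (ECV) of AF, a few
#' excluded for spontaneous conversion to sinus rhythm, the rest
#' recorded for `duration_s` immediately before and after the shock.
#' Defaults reproduce a 100-patient cohort: 5 spontaneous conversions,
#' 95 included (87 AF + 8 flutter at the moment of ECV), 83 successful
#' cardioversions, and 4 post-ECV sinus-rhythm patients with very
#' frequent supraventricular ectopy. Counts are fixed deterministically
#' (not resampled) so pipeline fixtures are exact.
#'
#' With these margins every flutter ECV succeeds and all 12 failures
#' are AF patients, so the truth totals over the 190 recordings are
#' 99 AF, 8 flutter and 83 sinus rhythm.
#'
#' @param n_enrolled Patients screened and enrolled (default 100).
#' @param n_spontaneous_conversion Excluded before ECV (default 5).
#' @param n_aflutter Included patients found in flutter (default 8).
#' @param n_success Successful cardioversions (default 83).
#' @param n_post_ectopy Post-ECV sinus patients with frequent ectopy
#'   (default 4).
#' @param duration_s Recording length per phase (default 600 s).
#' @param ectopy_rate Per-beat ectopic rate for the frequent-ectopy
#'   patients (default 0.2, non-compensatory).
#' @param seed Master seed; all per-recording seeds derive from it.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(n_enrolled = 100, n_spontaneous_conversion = 5,
                       n_aflutter = 8, n_success = 83, n_post_ectopy = 4,
                       duration_s = 600, ectopy_rate = 0.2, seed = 1) {
  n_included <- n_enrolled - n_spontaneous_conversion
  n_af <- n_included - n_aflutter
  n_fail <- n_included - n_success
  if (n_included < 1 || n_aflutter < 0 || n_aflutter > n_included ||
      n_success < 0 || n_success > n_included || n_fail > n_af ||
      n_post_ectopy < 0 || n_post_ectopy > n_success) {
    abort("inconsistent study counts", class = "afrr_invalid_spec")
  }
  structure(
    list(n_enrolled = n_enrolled,
         n_spontaneous_conversion = n_spontaneous_conversion,
         n_included = n_included, n_aflutter = n_aflutter, n_af = n_af,
         n_success = n_success, n_fail = n_fail,
         n_post_ectopy = n_post_ectopy,
         duration_s = duration_s, ectopy_rate = ectopy_rate, seed = seed),
    class = "study_spec"
  )
}

#' @export
print.study_spec <- function(x, ...) {
  cat(sprintf(paste0("<study_spec: %d enrolled, %d excluded, %d included ",
                     "(%d AF + %d flutter), %d successful ECV, %d with ",
                     "post-ECV ectopy, %d s recordings, seed %d>\n"),
              x$n_enrolled, x$n_spontaneous_conversion, x$n_included,
              x$n_af, x$n_aflutter, x$n_success, x$n_post_ectopy,
              x$duration_s, x$seed))
  invisible(x)
}

#' Emulate the paired-recording validation study
#'
#' Generates the full synthetic corpus: one pre-ECV and one post-ECV
#' RR recording per included patient, with ground-truth rhythm labels.
#' Pre-ECV, AF patients are in AF and flutter patients in flutter
#' (alternating between fixed 2:1 and patterned 2:1/4:1 conduction
#' across patients). Post-ECV, successfully cardioverted patients are
#' in sinus rhythm -- the designated frequent-ectopy patients with
#' non-compensatory ectopics injected -- and failures remain in their
#' pre-ECV rhythm. Fully seeded: the master seed determines every beat.
#'
#' @param spec A [study_spec()].
#' @return A tibble of class `af_study`, one row per recording:
#'   `recording_id`, `patient_id`, `phase` (`"pre"`/`"post"`), `truth`
#'   (`"af"`/`"aflutter"`/`"sr"`), `ectopy` (logical), `seed`, and a
#'   `series` list-column of [rr_series()] objects.
#' @examples
#' \donttest{
#' corpus <- simulate_study(study_spec(duration_s = 120))
#' dplyr::count(corpus, phase, truth)
#' }
#' @export
simulate_study <- function(spec = study_spec()) {
  stopifnot(inherits(spec, "study_spec"))
  n_rec <- 2L * spec$n_included
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max - 1L, n_rec))

  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(spec$n_included)),
    pre_rhythm = rep(c("af", "aflutter"), c(spec$n_af, spec$n_aflutter)),
    # all failures are AF patients (flutter cardioversions all succeed)
    converts = c(rep(TRUE, spec$n_af - spec$n_fail),
                 rep(FALSE, spec$n_fail),
                 rep(TRUE, spec$n_aflutter))
  )
  patients$post_rhythm <- ifelse(patients$converts, "sr", patients$pre_rhythm)
  ect <- rep(FALSE, spec$n_included)
  ect[which(patients$post_rhythm == "sr")[seq_len(spec$n_post_ectopy)]] <- TRUE
  patients$post_ectopy <- ect
  # flutter conduction alternates fixed 2:1 / patterned 2:1-4:1
  flutter_pattern <- function(k) if (k %% 2 == 0) c(2, 4) else 2

  manifest <- tidyr::expand_grid(patient_id = patients$patient_id,
                                 phase = c("pre", "post"))
  manifest <- dplyr::left_join(manifest, patients, by = "patient_id")
  manifest$truth <- ifelse(manifest$phase == "pre",
                           manifest$pre_rhythm, manifest$post_rhythm)
  manifest$ectopy <- manifest$phase == "post" & manifest$post_ectopy
  manifest$recording_id <- paste0(manifest$patient_id, "_", manifest$phase)
  manifest$seed <- seeds[seq_len(nrow(manifest))]

  flutter_idx <- cumsum(manifest$truth == "aflutter")
  gen_one <- function(truth, seed, ectopy, fl_k, id) {
    s <- switch(
      truth,
      af = simulate_af(duration_s = spec$duration_s, seed = seed),
      sr = simulate_sr(duration_s = spec$duration_s, seed = seed),
      aflutter = simulate_aflutter(duration_s = spec$duration_s,
                                   conduction_ratios = flutter_pattern(fl_k),
                                   seed = seed)
    )
    if (ectopy) {
      s <- inject_ectopy(s, rate_per_beat = spec$ectopy_rate,
                         compensatory = FALSE, seed = seed + 1L)
    }
    attr(s, "meta") <- utils::modifyList(rr_meta(s), list(recording_id = id))
    s
  }
  manifest$series <- purrr::pmap(
    list(manifest$truth, manifest$seed, manifest$ectopy, flutter_idx,
         manifest$recording_id),
    gen_one
  )

  out <- manifest[, c("recording_id", "patient_id", "phase", "truth",
                      "ectopy", "seed", "series")]
  structure(out, class = c("af_study", class(out)), spec = spec)
}

#' Classify every recording of a study corpus
#'
#' Runs [classify_stream()] and [aggregate_recording()] over each
#' recording of a corpus from [simulate_study()] and returns the
#' manifest with the recording-level decision columns appended.
#'
#' @param corpus An `af_study` tibble.
#' @param params A [classifier_params()].
#' @param min_af_fraction Burden threshold passed to
#'   [aggregate_recording()].
#' @return The corpus tibble (without the `series` column) plus
#'   `af_burden`, `call` and `prediction` (`"app_af"`/`"app_no_af"`).
#' @export
classify_study <- function(corpus, params = classifier_params(),
                           min_af_fraction = 0.90) {
  stopifnot(is.data.frame(corpus), "series" %in% names(corpus))
  decisions <- purrr::map(corpus$series, function(s) {
    aggregate_recording(classify_stream(s, params), min_af_fraction)
  })
  out <- dplyr::select(as_tibble(corpus), -"series")
  out$af_burden <- purrr::map_dbl(decisions, "af_burden")
  out$call <- purrr::map_chr(decisions, "call")
  out$prediction <- purrr::map_chr(decisions, to_binary)
  out
}
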