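truth_levels <- c("af", "aflutter", "sr")
pred_levels <- c("app_af", "app_no_af")

#' Build a truth-by-prediction contingency table
#'
#' Cross-tabulates reference rhythm diagnoses (12-lead ECG style truth:
#' `"af"`, `"aflutter"`, `"sr"`) against the app's binary prediction
#' (`"app_af"`, `"app_no_af"`). Order-independent; counts sum to the
#' number of rows.
#'
#' @param data Data frame with one row per recording.
#' @param truth,prediction Columns of `data` holding the labels
#'   (tidy-evaluated; defaults `truth` and `prediction`).
#' @return An object of class `af_contingency` wrapping the 3 x 2 count
#'   matrix.
#' @examples
#' df <- data.frame(truth = c("af", "af", "sr"),
#'                  prediction = c("app_af", "app_no_af", "app_no_af"))
#' build_contingency(df)
#' @export
build_contingency <- function(data, truth = truth, prediction = prediction) {
  stopifnot(is.data.frame(data))
  tr <- as.character(dplyr::pull(data, {{ truth }}))
  pr <- as.character(dplyr::pull(data, {{ prediction }}))
  if (length(tr) != length(pr)) {
    abort("truth and prediction must be aligned", class = "afrr_invalid_label")
  }
  bad <- setdiff(unique(tr), truth_levels)
  if (length(bad)) {
    abort(paste0("unknown truth label(s): ", paste(bad, collapse = ", ")),
          class = "afrr_invalid_label")
  }
  bad <- setdiff(unique(pr), pred_levels)
  if (length(bad)) {
    abort(paste0("unknown prediction label(s): ", paste(bad, collapse = ", ")),
          class = "afrr_invalid_label")
  }
  counts <- table(factor(tr, truth_levels), factor(pr, pred_levels))
  new_contingency(unclass(counts))
}

new_contingency <- function(m) {
  m <- matrix(as.integer(m), nrow = 3, ncol = 2,
              dimnames = list(truth = truth_levels, prediction = pred_levels))
  structure(list(counts = m, n = sum(m)), class = "af_contingency")
}

#' Contingency table from the six printed counts
#'
#' Convenience constructor taking the counts the way a published table
#' prints them: each truth row with its app-AF and app-no-AF counts.
#'
#' @param af True-AF row, `c(app_af, app_no_af)`.
#' @param flutter Flutter row, `c(app_af, app_no_af)`.
#' @param sr Sinus-rhythm row, `c(app_af, app_no_af)`.
#' @return An `af_contingency`.
#' @examples
#' contingency_from_counts(af = c(96, 3), flutter = c(0, 8), sr = c(4, 79))
#' @export
contingency_from_counts <- function(af, flutter = c(0, 0), sr = c(0, 0)) {
  stopifnot(length(af) == 2, length(flutter) == 2, length(sr) == 2,
            all(c(af, flutter, sr) >= 0))
  new_contingency(rbind(af, flutter, sr))
}

#' @export
print.af_contingency <- function(x, ...) {
  cat(sprintf("<af_contingency: %d pairs>\n", x$n))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.af_contingency <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    dplyr::rename(count = "Freq")
}

# Collapse to a 2x2 (positive = AF) under a flutter-handling policy.
collapse_binary <- function(tbl, flutter_handling = c("excluded", "as_negative")) {
  flutter_handling <- match.arg(flutter_handling)
  m <- tbl$counts
  neg_rows <- if (flutter_handling == "excluded") "sr" else c("aflutter", "sr")
  rbind(pos = m["af", ], neg = colSums(m[neg_rows, , drop = FALSE]))
}

#' Exact and Wilson binomial confidence intervals
#'
#' Default is the exact (Clopper-Pearson) interval obtained by
#' inverting binomial tail probabilities via the beta quantile
#' identity; it guarantees at least nominal coverage. `"wilson"` gives
#' the Wilson score interval.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, positive.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"exact"` or `"wilson"`.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `method`.
#' @examples
#' binomial_ci(96, 99)
#' @export
binomial_ci <- function(x, n, conf_level = 0.95,
                        method = c("exact", "wilson")) {
  method <- match.arg(method)
  if (n <= 0 || x < 0 || x > n) {
    abort("need 0 <= x <= n with n > 0", class = "afrr_invalid_input")
  }
  alpha <- 1 - conf_level
  if (method == "exact") {
    lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- qnorm(1 - alpha / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw)
    hi <- min(1, ctr + hw)
  }
  tibble(estimate = x / n, conf.low = lo, conf.high = hi, method = method)
}

metric_row <- function(metric, x, n, flutter_handling, ci_method, conf_level) {
  ci <- binomial_ci(x, n, conf_level, ci_method)
  tibble(metric = metric, estimate = ci$estimate,
         conf.low = ci$conf.low, conf.high = ci$conf.high,
         x = as.integer(x), n = as.integer(n),
         flutter_handling = flutter_handling, method = ci_method)
}

#' Sensitivity of the AF call
#'
#' True-positive rate among truth-AF recordings, `TP / (TP + FN)`.
#' Flutter handling cannot change it (flutter only populates the
#' negative margin) but is carried for labeling.
#'
#' @param tbl An `af_contingency`.
#' @param flutter_handling `"excluded"` (drop the flutter row) or
#'   `"as_negative"` (count flutter as truth-negative).
#' @param ci_method,conf_level Passed to [binomial_ci()].
#' @return A one-row tibble with estimate and CI.
#' @export
sensitivity <- function(tbl, flutter_handling = c("excluded", "as_negative"),
                        ci_method = "exact", conf_level = 0.95) {
  flutter_handling <- match.arg(flutter_handling)
  b <- collapse_binary(tbl, flutter_handling)
  if (sum(b["pos", ]) == 0) {
    abort("no truth-positive recordings: sensitivity undefined",
          class = "afrr_undefined_metric")
  }
  metric_row("sensitivity", b["pos", "app_af"], sum(b["pos", ]),
             flutter_handling, ci_method, conf_level)
}

#' Specificity of the AF call
#'
#' True-negative rate among truth-negative recordings,
#' `TN / (TN + FP)`, under the declared flutter handling: with flutter
#' excluded only sinus-rhythm recordings count as negatives; with
#' flutter as negative the flutter row joins the negative margin.
#'
#' @inheritParams sensitivity
#' @return A one-row tibble with estimate and CI.
#' @export
specificity <- function(tbl, flutter_handling = c("excluded", "as_negative"),
                        ci_method = "exact", conf_level = 0.95) {
  flutter_handling <- match.arg(flutter_handling)
  b <- collapse_binary(tbl, flutter_handling)
  if (sum(b["neg", ]) == 0) {
    abort("no truth-negative recordings: specificity undefined",
          class = "afrr_undefined_metric")
  }
  metric_row("specificity", b["neg", "app_no_af"], sum(b["neg", ]),
             flutter_handling, ci_method, conf_level)
}

#' Cohen's kappa for intermethod agreement
#'
#' Chance-corrected agreement between the reference diagnosis and the
#' app's binary call after collapsing to AF / non-AF:
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' from the row and column marginals. The CI uses the large-sample
#' standard error `sqrt(p_o (1 - p_o)) / ((1 - p_e) sqrt(n))` with
#' normal quantiles.
#'
#' @inheritParams sensitivity
#' @param flutter_handling Default `"as_negative"`: agreement over all
#'   pairs, flutter counted as a true negative.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `p_o`,
#'   `p_e`, `n`, `flutter_handling`.
#' @export
cohens_kappa <- function(tbl, flutter_handling = c("as_negative", "excluded"),
                         conf_level = 0.95) {
  flutter_handling <- match.arg(flutter_handling)
  b <- collapse_binary(tbl, flutter_handling)
  n <- sum(b)
  if (n == 0) abort("empty table", class = "afrr_undefined_metric")
  p_o <- (b["pos", "app_af"] + b["neg", "app_no_af"]) / n
  # p_e = P(both say AF) + P(both say non-AF) from independent margins
  p_e <- (rowSums(b)["pos"] * colSums(b)["app_af"] +
            rowSums(b)["neg"] * colSums(b)["app_no_af"]) / n^2
  p_e <- unname(p_e)
  if (1 - p_e < .Machine$double.eps) {
    abort("degenerate marginals: kappa undefined", class = "afrr_undefined_metric")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o)) / ((1 - p_e) * sqrt(n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(metric = "kappa", estimate = kappa,
         conf.low = max(-1, kappa - z * se),
         conf.high = min(1, kappa + z * se),
         p_o = p_o, p_e = p_e, n = as.integer(n),
         flutter_handling = flutter_handling)
}

#' AF prevalence in the evaluated pairs
#'
#' Fraction of truth-AF recordings among the pairs retained under the
#' declared flutter handling (with flutter excluded, the denominator
#' drops the flutter row).
#'
#' @inheritParams sensitivity
#' @return Scalar proportion.
#' @export
af_prevalence <- function(tbl, flutter_handling = c("excluded", "as_negative")) {
  flutter_handling <- match.arg(flutter_handling)
  b <- collapse_binary(tbl, flutter_handling)
  sum(b["pos", ]) / sum(b)
}

#' Full diagnostic-accuracy summary of a contingency table
#'
#' Computes sensitivity and specificity under both flutter handlings
#' (excluded and as-negative), Cohen's kappa over all pairs, and AF
#' prevalence among the flutter-excluded pairs.
#'
#' @inheritParams sensitivity
#' @param kappa_handling Flutter handling for kappa (default
#'   `"as_negative"`, i.e. all pairs).
#' @return An object of class `diagnostic_metrics`.
#' @examples
#' tbl <- contingency_from_counts(af = c(96, 3), flutter = c(0, 8),
#'                                sr = c(4, 79))
#' diagnostic_metrics(tbl)
#' @export
diagnostic_metrics <- function(tbl, ci_method = "exact", conf_level = 0.95,
                               kappa_handling = "as_negative") {
  stopifnot(inherits(tbl, "af_contingency"))
  metrics <- dplyr::bind_rows(
    sensitivity(tbl, "excluded", ci_method, conf_level),
    specificity(tbl, "excluded", ci_method, conf_level),
    sensitivity(tbl, "as_negative", ci_method, conf_level),
    specificity(tbl, "as_negative", ci_method, conf_level)
  )
  structure(
    list(table = tbl, metrics = metrics,
         kappa = cohens_kappa(tbl, kappa_handling, conf_level),
         prevalence = af_prevalence(tbl, "excluded"),
         n_pairs = tbl$n,
         methods = list(ci = ci_method, kappa_ci = "large-sample normal",
                        conf_level = conf_level)),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fe <- dplyr::filter(x$metrics, .data$flutter_handling == "excluded")
  fn <- dplyr::filter(x$metrics, .data$flutter_handling == "as_negative")
  pick <- function(df, m) df$estimate[df$metric == m]
  cat(sprintf("<diagnostic_metrics: %d pairs>\n", x$n_pairs))
  cat(sprintf("  sensitivity: %.1f%%   (flutter excluded and as-negative agree)\n",
              100 * pick(fe, "sensitivity")))
  cat(sprintf("  specificity: %.1f%% flutter-excluded / %.1f%% flutter-as-negative\n",
              100 * pick(fe, "specificity"), 100 * pick(fn, "specificity")))
  cat(sprintf("  kappa: %.3f (%s)\n", x$kappa$estimate,
              x$kappa$flutter_handling))
  cat(sprintf("  AF prevalence (flutter excluded): %.1f%%\n",
              100 * x$prevalence))
  invisible(x)
}

#' @export
tidy.diagnostic_metrics <- function(x, ...) {
  dplyr::bind_rows(
    x$metrics,
    dplyr::select(x$kappa, "metric", "estimate", "conf.low", "conf.high",
                  "n", "flutter_handling")
  )
}

#' @export
glance.diagnostic_metrics <- function(x, ...) {
  pick <- function(m, h) {
    x$metrics$estimate[x$metrics$metric == m & x$metrics$flutter_handling == h]
  }
  tibble(
    sensitivity = pick("sensitivity", "excluded"),
    specificity_flutter_excluded = pick("specificity", "excluded"),
    specificity_flutter_as_negative = pick("specificity", "as_negative"),
    kappa = x$kappa$estimate,
    af_prevalence = x$prevalence,
    n_pairs = x$n_pairs
  )
}

#' Evaluate a corpus of decisions against its manifest
#'
#' Joins per-recording truth labels with per-recording app decisions,
#' checks the two cover exactly the same recordings, and returns the
#' full [diagnostic_metrics()] summary.
#'
#' @param manifest Data frame with `recording_id` and `truth`
#'   (`"af"`/`"aflutter"`/`"sr"`).
#' @param decisions Data frame with `recording_id` and either a
#'   `prediction` column (`"app_af"`/`"app_no_af"`) or a `call` column
#'   (`"AF"`/`"NON_AF"`).
#' @inheritParams sensitivity
#' @return A `diagnostic_metrics` object.
#' @export
evaluate_corpus <- function(manifest, decisions, ci_method = "exact",
                            conf_level = 0.95) {
  stopifnot(is.data.frame(manifest), is.data.frame(decisions))
  if (!all(c("recording_id", "truth") %in% names(manifest))) {
    abort("manifest needs recording_id and truth columns",
          class = "afrr_invalid_input")
  }
  if (!"prediction" %in% names(decisions)) {
    if (!"call" %in% names(decisions)) {
      abort("decisions need a prediction or call column",
            class = "afrr_invalid_input")
    }
    decisions$prediction <- ifelse(decisions$call == "AF",
                                   "app_af", "app_no_af")
  }
  missing <- setdiff(manifest$recording_id, decisions$recording_id)
  extra <- setdiff(decisions$recording_id, manifest$recording_id)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "manifest/decision mismatch",
      if (length(missing)) paste0("; missing decisions for: ",
                                  paste(utils::head(missing, 5), collapse = ", ")),
      if (length(extra)) paste0("; decisions for unknown recordings: ",
                                paste(utils::head(extra, 5), collapse = ", "))
    ), class = "afrr_corpus_mismatch")
  }
  joined <- dplyr::inner_join(
    as_tibble(manifest)[, c("recording_id", "truth")],
    as_tibble(decisions)[, c("recording_id", "prediction")],
    by = "recording_id"
  )
  diagnostic_metrics(build_contingency(joined), ci_method, conf_level)
}
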