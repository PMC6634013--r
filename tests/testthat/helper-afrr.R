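# Shared fixture builders: everything is generated in code, no stored data.

# A labeled-beat tibble with uniform 1000 ms beats, given label strings.
make_labels <- function(labels, rr_ms = 1000) {
  tibble::tibble(
    beat_index = seq_along(labels),
    t_ms = cumsum(rep_len(rr_ms, length(labels))),
    rr_ms = rep_len(rr_ms, length(labels)),
    label = labels,
    index_value = ifelse(labels == "warmup", NA_real_, 0.5)
  )
}

# Independent brute-force Clopper-Pearson oracle: invert the binomial
# tail probabilities numerically instead of using the beta identity.
brute_force_exact_ci <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

# The published validation counts, used across evaluation tests:
# truth AF 96/3, flutter 0/8, sinus 4/79 against the app's binary call.
study_table <- function() {
  contingency_from_counts(af = c(96, 3), flutter = c(0, 8), sr = c(4, 79))
}

# Expand a contingency table into aligned truth/prediction label vectors.
expand_table_labels <- function(af, flutter, sr) {
  tibble::tibble(
    truth = rep(c("af", "aflutter", "sr"), c(sum(af), sum(flutter), sum(sr))),
    prediction = c(rep(c("app_af", "app_no_af"), af),
                   rep(c("app_af", "app_no_af"), flutter),
                   rep(c("app_af", "app_no_af"), sr))
  )
}
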