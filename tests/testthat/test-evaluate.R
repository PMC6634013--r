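test_that("contingency tables count pairs correctly and order-independently", {
  df <- expand_table_labels(af = c(96, 3), flutter = c(0, 8), sr = c(4, 79))
  tbl <- build_contingency(df)
  expect_equal(tbl$n, 190)
  expect_equal(tbl$counts["af", ], c(app_af = 96L, app_no_af = 3L))
  expect_equal(tbl$counts["aflutter", ], c(app_af = 0L, app_no_af = 8L))
  expect_equal(tbl$counts["sr", ], c(app_af = 4L, app_no_af = 79L))

  # permutation invariance
  withr::with_seed(3, {
    perm <- df[sample(nrow(df)), ]
  })
  expect_equal(build_contingency(perm)$counts, tbl$counts)

  empty <- build_contingency(data.frame(truth = character(0),
                                        prediction = character(0)))
  expect_equal(empty$n, 0)
  expect_true(all(empty$counts == 0))

  single <- build_contingency(data.frame(truth = "af", prediction = "app_af"))
  expect_equal(single$counts["af", "app_af"], 1L)
  expect_equal(single$n, 1)

  expect_error(build_contingency(data.frame(truth = "vt",
                                            prediction = "app_af")),
               class = "afrr_invalid_label")
  expect_error(build_contingency(data.frame(truth = "af",
                                            prediction = "maybe")),
               class = "afrr_invalid_label")
})

test_that("sensitivity and specificity reproduce the validation-study values", {
  tbl <- study_table()

  sens <- sensitivity(tbl)
  expect_equal(sens$estimate, 96 / 99)
  expect_equal(round(100 * sens$estimate, 1), 97.0)

  spec_ex <- specificity(tbl, "excluded")
  expect_equal(spec_ex$estimate, 79 / 83)
  expect_equal(round(100 * spec_ex$estimate, 1), 95.2)

  spec_neg <- specificity(tbl, "as_negative")
  expect_equal(spec_neg$estimate, 87 / 91)
  expect_equal(round(100 * spec_neg$estimate, 1), 95.6)

  # flutter only populates the negative margin, so sensitivity is
  # identical under both handlings -- on any table
  withr::with_seed(21, {
    for (i in 1:20) {
      t2 <- contingency_from_counts(af = sample(0:50, 2),
                                    flutter = sample(0:50, 2),
                                    sr = c(sample(0:50, 1), sample(1:50, 1)))
      if (sum(t2$counts["af", ]) == 0) next
      expect_equal(sensitivity(t2, "excluded")$estimate,
                   sensitivity(t2, "as_negative")$estimate)
    }
  })

  expect_equal(sensitivity(contingency_from_counts(af = c(0, 10)))$estimate, 0)
  expect_equal(sensitivity(contingency_from_counts(af = c(10, 0)))$estimate, 1)
  expect_equal(specificity(contingency_from_counts(
    af = c(1, 0), sr = c(0, 12)))$estimate, 1)
  expect_error(sensitivity(contingency_from_counts(af = c(0, 0),
                                                   sr = c(1, 1))),
               class = "afrr_undefined_metric")
})

test_that("Cohen's kappa matches the plug-in formula and its edge cases", {
  tbl <- study_table()
  k <- cohens_kappa(tbl)  # all 190 pairs, flutter as negative
  # hand plug-in: p_o = 183/190, p_e = (99*100 + 91*90)/190^2
  p_o <- 183 / 190
  p_e <- (99 * 100 + 91 * 90) / 190^2
  expect_equal(k$estimate, (p_o - p_e) / (1 - p_e))
  expect_equal(round(k$estimate, 3), 0.926)
  expect_equal(round(k$estimate, 2), 0.93)

  # perfect agreement
  expect_equal(cohens_kappa(contingency_from_counts(
    af = c(10, 0), sr = c(0, 15)))$estimate, 1)

  # statistically independent margins (25/25/25/25) give kappa 0
  expect_equal(cohens_kappa(contingency_from_counts(
    af = c(25, 25), sr = c(25, 25)))$estimate, 0)

  # kappa never exceeds observed agreement; kappa = 1 iff off-diagonals 0
  withr::with_seed(33, {
    for (i in 1:20) {
      t2 <- contingency_from_counts(af = sample(1:50, 2),
                                    flutter = sample(0:10, 2),
                                    sr = sample(1:50, 2))
      kk <- cohens_kappa(t2)
      expect_lte(kk$estimate, kk$p_o + 1e-12)
      off <- t2$counts["af", "app_no_af"] +
        t2$counts["aflutter", "app_af"] + t2$counts["sr", "app_af"]
      if (off > 0) expect_lt(kk$estimate, 1)
    }
  })

  expect_error(cohens_kappa(contingency_from_counts(af = c(0, 0))),
               class = "afrr_undefined_metric")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  tbl <- study_table()
  b <- rbind(pos = tbl$counts["af", ],
             neg = colSums(tbl$counts[c("aflutter", "sr"), ]))
  expect_equal(cohens_kappa(tbl)$estimate,
               e1071::classAgreement(b)$kappa, tolerance = 1e-12)
})

test_that("exact binomial intervals invert the tail probabilities", {
  expect_equal(binomial_ci(99, 99)$conf.high, 1)
  expect_equal(binomial_ci(0, 50)$conf.low, 0)

  # brute-force inversion oracle at the study's sensitivity counts
  ci <- binomial_ci(96, 99)
  oracle <- brute_force_exact_ci(96, 99)
  expect_equal(ci$conf.low, oracle[1], tolerance = 1e-4)
  expect_equal(ci$conf.high, oracle[2], tolerance = 1e-4)
  expect_true(ci$conf.low <= 96 / 99 && 96 / 99 <= ci$conf.high)

  # a few more points against the oracle
  for (x in c(1, 25, 79)) {
    ci <- binomial_ci(x, 83)
    oracle <- brute_force_exact_ci(x, 83)
    expect_equal(ci$conf.low, oracle[1], tolerance = 1e-4)
    expect_equal(ci$conf.high, oracle[2], tolerance = 1e-4)
  }

  w <- binomial_ci(96, 99, method = "wilson")
  expect_true(w$conf.low <= 96 / 99 && 96 / 99 <= w$conf.high)
  expect_error(binomial_ci(5, 0), class = "afrr_invalid_input")
  expect_error(binomial_ci(10, 5), class = "afrr_invalid_input")
})

test_that("corpus evaluation replays the full metrics trio", {
  df <- expand_table_labels(af = c(96, 3), flutter = c(0, 8), sr = c(4, 79))
  manifest <- tibble::tibble(recording_id = sprintf("R%03d", seq_len(nrow(df))),
                             truth = df$truth)
  decisions <- tibble::tibble(recording_id = manifest$recording_id,
                              prediction = df$prediction)
  m <- evaluate_corpus(manifest, decisions)
  g <- glance(m)
  expect_equal(g$sensitivity, 96 / 99)
  expect_equal(g$specificity_flutter_excluded, 79 / 83)
  expect_equal(g$specificity_flutter_as_negative, 87 / 91)
  expect_equal(round(g$kappa, 4), 0.9262)
  expect_equal(g$af_prevalence, 99 / 182)
  expect_equal(g$n_pairs, 190L)

  # all correct -> everything 1
  perfect <- decisions
  perfect$prediction <- ifelse(df$truth == "af", "app_af", "app_no_af")
  gp <- glance(evaluate_corpus(manifest, perfect))
  expect_equal(gp$sensitivity, 1)
  expect_equal(gp$specificity_flutter_excluded, 1)
  expect_equal(gp$kappa, 1)

  # all negative -> sensitivity 0, specificity 1
  none <- decisions
  none$prediction <- "app_no_af"
  gn <- glance(evaluate_corpus(manifest, none))
  expect_equal(gn$sensitivity, 0)
  expect_equal(gn$specificity_flutter_excluded, 1)

  # mismatches are named
  expect_error(evaluate_corpus(manifest, decisions[-1, ]),
               class = "afrr_corpus_mismatch")
  expect_error(evaluate_corpus(manifest[-1, ], decisions),
               class = "afrr_corpus_mismatch")
  err <- tryCatch(evaluate_corpus(manifest, decisions[-1, ]),
                  error = conditionMessage)
  expect_match(err, "R001")
})

test_that("decisions with a call column are accepted too", {
  manifest <- tibble::tibble(recording_id = c("a", "b"),
                             truth = c("af", "sr"))
  decisions <- tibble::tibble(recording_id = c("a", "b"),
                              call = c("AF", "NON_AF"))
  g <- glance(evaluate_corpus(manifest, decisions))
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity_flutter_excluded, 1)
})
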