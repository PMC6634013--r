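test_that("variability index is normalized RMSSD with scale invariance", {
  expect_equal(variability_index(rep(800, 32)), 0)

  # hand evaluation: diffs (0, 800), RMSSD = sqrt(800^2 / 2) = 565.685,
  # mean RR = 3200/3 = 1066.667, ratio = 0.530330
  expect_equal(variability_index(c(800, 800, 1600)),
               sqrt((0^2 + 800^2) / 2) / (3200 / 3))
  expect_equal(variability_index(c(800, 800, 1600)), 0.5303301, tolerance = 1e-6)

  withr::with_seed(11, {
    for (i in 1:50) {
      w <- runif(32, 400, 1200)
      k <- runif(1, 0.1, 10)
      expect_equal(variability_index(k * w), variability_index(w))
      expect_gte(variability_index(w), 0)
    }
  })

  expect_error(variability_index(800), class = "afrr_invalid_window")
  expect_error(variability_index(c(800, -5, 700)), class = "afrr_invalid_input")
})

test_that("randomness index vanishes on deterministic first-order patterns", {
  expect_equal(randomness_index(rep(800, 32)), 0)
  # strict alternation: each symbol deterministically follows the other,
  # the signature that keeps patterned AV conduction out of the AF class
  expect_equal(randomness_index(rep(c(600, 900), 16)), 0)
  expect_equal(randomness_index(rep(c(440, 880), 32)), 0)
  expect_error(randomness_index(c(800, 900)), class = "afrr_invalid_window")
})

test_that("entropy rate of iid uniform ternary symbols approaches 1", {
  # Monte-Carlo oracle on the stated symbol process: 1000 seeded draws of
  # 512 iid uniform symbols; the plug-in entropy rate must average
  # within 0.05 of the maximum.
  vals <- withr::with_seed(42, {
    vapply(1:1000, function(i) {
      symbol_entropy_rate(sample(0:2, 512, replace = TRUE))
    }, numeric(1))
  })
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(abs(mean(vals) - 1), 0.05)
})

test_that("heterogeneity index combines components with saturation and bounds", {
  p <- classifier_params()
  expect_equal(heterogeneity_index(0, 0, p)$index, 0)

  # v = 0.4 needs v_raw = v_scale * 0.4 / 0.6; with rn = 0.8 and equal
  # weights the combined index is 0.6
  h <- heterogeneity_index(p$v_scale * 0.4 / 0.6, 0.8, p)
  expect_equal(h$v, 0.4)
  expect_equal(h$index, 0.6)

  # saturating transform approaches 1, so index approaches 1 at rn = 1
  expect_equal(heterogeneity_index(1e9, 1, p)$index, 1, tolerance = 1e-6)

  # monotone nondecreasing in both arguments
  withr::with_seed(7, {
    v1 <- runif(100, 0, 2); v2 <- v1 + runif(100, 0, 1)
    r1 <- runif(100, 0, 0.9); r2 <- pmin(1, r1 + runif(100, 0, 0.1))
    expect_true(all(heterogeneity_index(v2, r1, p)$index >=
                      heterogeneity_index(v1, r1, p)$index))
    expect_true(all(heterogeneity_index(v1, r2, p)$index >=
                      heterogeneity_index(v1, r1, p)$index))
  })
})

test_that("beat labels follow the two-threshold rule with inclusive AF boundary", {
  p <- classifier_params()
  expect_equal(classify_beat(p$theta_af, p), "probable_af")
  expect_equal(classify_beat(0, p), "normal")
  expect_equal(classify_beat(p$theta_sr, p), "unclassified_non_af")
  expect_equal(classify_beat((p$theta_sr + p$theta_af) / 2, p),
               "unclassified_non_af")
  expect_equal(classify_beat(1, p), "probable_af")

  # monotone: raising the index never moves the label away from AF
  ord <- c(normal = 1, unclassified_non_af = 2, probable_af = 3)
  labs <- classify_beat(seq(0, 1, by = 0.01), p)
  expect_true(all(diff(ord[labs]) >= 0))
})

test_that("classifier parameter invariants are enforced", {
  expect_error(classifier_params(window_n = 4), class = "afrr_invalid_params")
  expect_error(classifier_params(w_v = 0.7, w_r = 0.5),
               class = "afrr_invalid_params")
  expect_error(classifier_params(theta_af = 0.3, theta_sr = 0.5),
               class = "afrr_invalid_params")
})

test_that("streaming labels match brute-force window recomputation", {
  p <- classifier_params()
  n_checked <- 0
  withr::with_seed(101, {
    for (s in 1:4) {
      rhythm <- list(
        simulate_af(200, seed = s),
        simulate_sr(200, seed = s + 10),
        simulate_aflutter(200, seed = s + 20)
      )[[1 + (s %% 3)]]
      labs <- classify_stream(rhythm, p)
      rr <- rhythm$rr_ms
      for (i in p$window_n:nrow(labs)) {
        win <- rr[(i - p$window_n + 1):i]
        v_raw <- variability_index(win)
        rn <- randomness_index(win, p$delta_ms)
        expected <- heterogeneity_index(v_raw, rn, p)
        expect_equal(labs$index_value[i], expected$index, tolerance = 1e-12)
        expect_equal(labs$rn[i], rn, tolerance = 1e-12)
        n_checked <- n_checked + 1
      }
    }
  })
  expect_gt(n_checked, 1000)
})

test_that("streaming output has warm-up prefix, full length, and determinism", {
  p <- classifier_params()
  af <- simulate_af(duration_s = 60, seed = 3)
  labs <- classify_stream(af, p)
  expect_equal(nrow(labs), nrow(af))
  expect_equal(labs$label[seq_len(p$window_n - 1)],
               rep("warmup", p$window_n - 1))
  expect_false(any(labs$label[-seq_len(p$window_n - 1)] == "warmup"))
  expect_true(all(is.na(labs$index_value[seq_len(p$window_n - 1)])))
  idx <- labs$index_value[!is.na(labs$index_value)]
  expect_true(all(idx >= 0 & idx <= 1))

  # exactly window_n - 1 beats: everything is warm-up
  short <- rr_series(rep(800, p$window_n - 1))
  expect_true(all(classify_stream(short, p)$label == "warmup"))

  # determinism: identical inputs, identical labels
  expect_identical(labs, classify_stream(af, p))

  expect_error(classify_stream(rr_series(numeric(0))),
               class = "afrr_invalid_input")
})

test_that("classification is invariant to joint rescaling of RR and delta", {
  p <- classifier_params()
  af <- simulate_af(duration_s = 120, seed = 9)
  labs1 <- classify_stream(af, p)
  for (k in c(0.5, 2)) {
    p2 <- classifier_params(delta_ms = p$delta_ms * k)
    labs2 <- classify_stream(rr_series(af$rr_ms * k), p2)
    expect_identical(labs1$label, labs2$label)
    expect_equal(labs1$index_value, labs2$index_value, tolerance = 1e-9)
  }
})

test_that("strictly alternating sequences can never reach the AF class", {
  # randomness is exactly 0, so the index is capped at w_v and stays
  # below the AF cutoff under defaults (theta_af > w_v would be needed)
  p <- classifier_params()
  alt <- rr_series(rep(c(440, 880), 64))
  labs <- classify_stream(alt, p)
  classified <- labs$label != "warmup"
  expect_true(all(labs$rn[classified] == 0))
  expect_true(all(labs$index_value[classified] <= p$w_v))
  expect_false(any(labs$label[classified] == "probable_af"))
})

test_that("a sustained synthetic AF episode is labeled AF nearly throughout", {
  labs <- classify_stream(simulate_af(duration_s = 600, seed = 77))
  classified <- labs$label[labs$label != "warmup"]
  expect_gt(mean(classified == "probable_af"), 0.90)
})
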