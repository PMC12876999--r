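test_that("trials are bit-reproducible and respect the requested size", {
  cfg <- cohort_config(n_fixations = 30, seed = 5)
  a <- generate_trial(cfg, "part_based", seed = 42)
  b <- generate_trial(cfg, "part_based", seed = 42)
  expect_identical(a$fixations, b$fixations)
  expect_equal(n_fixations(a), 30)
  fx <- a$fixations
  expect_true(all(fx$x_px >= 0 & fx$x_px < 1920))
  expect_true(all(fx$y_px >= 0 & fx$y_px < 1080))
  expect_true(all(fx$duration_ms >= 100 & fx$duration_ms <= 5000))
  expect_true(all(diff(fx$onset_ms) > 0))

  c1 <- generate_cohort(cohort_config(n_participants = 2, n_trials = 3, seed = 9))
  c2 <- generate_cohort(cohort_config(n_participants = 2, n_trials = 3, seed = 9))
  expect_identical(lapply(c1$scanpaths, `[[`, "fixations"),
                   lapply(c2$scanpaths, `[[`, "fixations"))
  expect_identical(c1$truth, c2$truth)
})

test_that("cohort seeds are substreamed: extending the cohort never reshuffles", {
  small <- generate_cohort(cohort_config(n_participants = 2, n_trials = 2, seed = 77))
  big <- generate_cohort(cohort_config(n_participants = 3, n_trials = 2, seed = 77))
  expect_identical(small$scanpaths[[1]]$fixations, big$scanpaths[[1]]$fixations)
  expect_identical(small$scanpaths[[8]]$fixations, big$scanpaths[[8]]$fixations)
})

test_that("a perfectly ordered double tour is fully deterministic", {
  cfg <- cohort_config(n_fixations = 10, n_anchors = 5, revisit_prob = 1,
                       order_fidelity = 1, cluster_dwell = 1, jitter_sd = 0,
                       seed = 3)
  sp <- generate_trial(cfg, "free", seed = 11, use_preset = FALSE)
  r <- rqa(sp)
  expect_equal(r$determinism, 100)
  expect_equal(r$laminarity, 0)
  expect_equal(r$rec_count, 5)
})

test_that("full coupling with zero jitter replays encoding exactly", {
  cfg <- cohort_config(n_fixations = 15, n_anchors = 15, encoding_coupling = 1,
                       jitter_sd = 0, order_fidelity = 1, cluster_dwell = 1,
                       anchor_min_sep_px = 180, seed = 5)
  enc <- generate_trial(cfg, "free", seed = 9, use_preset = FALSE)
  img <- generate_trial(cfg, "imagery", encoding = enc, seed = 10,
                        use_preset = FALSE)
  expect_equal(img$fixations$x_px, enc$fixations$x_px)
  expect_equal(img$fixations$y_px, enc$fixations$y_px)
  expect_equal(aoi_profile(img)$proportions, aoi_profile(enc)$proportions)
  expect_equal(img$phase, "imagery")
  expect_equal(img$condition, "FP")  # inherited from encoding
})

test_that("impossible anchor packing raises a configuration error", {
  cfg <- cohort_config(n_anchors = 60, seed = 1)
  expect_error(generate_trial(cfg, "free", seed = 1), "configuration error")
  expect_error(generate_trial(cohort_config(), "imagery", seed = 1),
               "encoding scanpath")
})

test_that("generator levers move their recurrence measures monotonically", {
  # order fidelity is probed under a high revisit rate: it only governs
  # revisits that actually happen
  mean_measure <- function(field, lever, values, extra = list(),
                           n_trials = 120) {
    vapply(values, function(v) {
      args <- c(list(n_fixations = 30, seed = 13), extra)
      args[[lever]] <- v
      cfg <- do.call(cohort_config, args)
      mean(vapply(seq_len(n_trials), function(t)
        rqa(generate_trial(cfg, "free", seed = 20000 + t,
                           use_preset = FALSE))[[field]],
        numeric(1)))
    }, numeric(1))
  }
  rec <- mean_measure("recurrence_rate", "revisit_prob", c(0.1, 0.5, 0.9))
  expect_true(all(diff(rec) > 0))
  det <- mean_measure("determinism", "order_fidelity", c(0.1, 0.5, 0.9),
                      list(revisit_prob = 0.7))
  expect_true(all(diff(det) > 0))
  lam <- mean_measure("laminarity", "cluster_dwell", c(1, 2, 3.5))
  expect_true(all(diff(lam) > 0))
})

test_that("truth table and behaviour table describe every generated trial", {
  cohort <- generate_cohort(cohort_config(n_participants = 3, n_trials = 6,
                                          seed = 21))
  expect_equal(length(cohort$scanpaths), 3 * 6 * 2)  # encoding + imagery
  expect_equal(nrow(cohort$truth), 3 * 6 * 2)
  expect_setequal(unique(cohort$truth$mode),
                  c("free", "part_based", "holistic", "imagery"))
  expect_equal(nrow(cohort$behaviour), 3 * 6)
  expect_true(all(cohort$behaviour$vividness %in% 1:7))
  expect_true(all(cohort$behaviour$accuracy %in% 0:1))
  # conditions rotate over trials
  expect_setequal(unique(cohort$truth$condition), c("FP", "GCW", "AS"))
})

test_that("config validation rejects out-of-range knobs", {
  expect_error(cohort_config(revisit_prob = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(n_trials = 0), "positive")
  expect_error(cohort_config(cluster_dwell = 0.5), "cluster_dwell")
})
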