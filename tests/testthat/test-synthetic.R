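test_that("degenerate category masses pin all scores to one segment", {
  m <- calibrate_score_model(c(1, 0, 0), 1, 30.44)
  set.seed(1)
  expect_true(all(sample_scores(m, 500) <= 1))
  m <- calibrate_score_model(c(0, 0, 1), 1, 30.44)
  expect_true(all(sample_scores(m, 500) >= 30.44))
})

test_that("invalid cuts or masses are configuration errors", {
  expect_error(calibrate_score_model(c(0.5, 0.5, 0.5), 1, 30),
               class = "screentriage_config_error")
  expect_error(calibrate_score_model(c(1, 0, 0), 0, 30),
               class = "screentriage_config_error")
  expect_error(calibrate_score_model(c(1, 0, 0), 30, 30),
               class = "screentriage_config_error")
})

test_that("sampled category shares recover the calibrated masses at n = 100,000", {
  probs <- c(1928, 2616, 349) / 4893
  m <- calibrate_score_model(probs, 1, 30.44)
  set.seed(42)
  n <- 100000
  shares <- prop.table(table(triage_category(sample_scores(m, n), 1, 30.44)))
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(as.numeric(shares) - probs) < 3 * se))
})

test_that("identical config and seed give identical cohorts", {
  cfg <- synthetic_config(n_women = 400, rounds = 3, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a different seed gives a different cohort
  c2 <- generate_cohort(synthetic_config(n_women = 400, rounds = 3,
                                         seed = 10))
  expect_false(identical(as.data.frame(a)$ai_score,
                         as.data.frame(c2)$ai_score))
})

test_that("a zero cancer rate yields zero cancer visits", {
  cfg <- synthetic_config(n_women = 300, rounds = 2, cancer_rate = 0,
                          prior_positive_fraction = 0, seed = 1)
  expect_equal(sum(generate_cohort(cfg)$is_cancer_visit), 0)
})

test_that("prior positives require at least two rounds", {
  expect_error(synthetic_config(rounds = 1),
               class = "screentriage_config_error")
  expect_silent(synthetic_config(rounds = 1, prior_positive_fraction = 0))
})

test_that("cancer-visit count matches the configured rate within 3 SE", {
  cfg <- synthetic_config(n_women = 10000, rounds = 5, seed = 123,
                          prior_positive_fraction = 0)
  co <- generate_cohort(cfg)
  n <- nrow(co)
  expected <- 0.0057 * n
  se <- sqrt(n * 0.0057 * (1 - 0.0057))
  expect_lt(abs(sum(co$is_cancer_visit) - expected), 3 * se)
})

test_that("detection-mode shares match 68/29/8 of 105 within 3 SE", {
  cfg <- synthetic_config(n_women = 80000, rounds = 5, cancer_rate = 0.005,
                          prior_positive_fraction = 0, seed = 77)
  co <- generate_cohort(cfg)
  modes <- co$detection_mode[co$is_cancer_visit]
  n <- length(modes)
  expect_gt(n, 1000)
  probs <- c(68, 29, 8) / 105
  obs <- c(mean(modes == "screen_detected"), mean(modes == "interval"),
           mean(modes == "missed"))
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(obs - probs) < 3 * se))
})

test_that("visits are chronologically ordered and biennially spaced per woman", {
  cfg <- synthetic_config(n_women = 300, rounds = 4, cancer_rate = 0.05,
                          seed = 5)
  co <- generate_cohort(cfg)
  by_woman <- split(seq_len(nrow(co)), co$woman_id)
  on_grid <- function(idx) {
    d <- co$visit_date[idx]
    expect_true(all(diff(d) > 0))   # strictly increasing
    gaps <- months_between(d[-1], d[-length(d)])
    # regular screening visits sit 24 months apart; inserted AI-positive
    # priors may fall between rounds, so gaps are at most one interval
    expect_true(all(gaps <= 24))
  }
  invisible(lapply(by_woman, on_grid))
})

test_that("triage of a large cohort recovers the configured class proportions", {
  cfg <- synthetic_config(n_women = 50000, rounds = 2,
                          prior_positive_fraction = 0, seed = 21)
  co <- generate_cohort(cfg)
  nc <- co$ai_score[!co$is_cancer_visit]
  shares <- prop.table(table(triage_category(nc, 1, 30.44)))
  probs <- c(1928, 2616, 349) / 4893
  se <- sqrt(probs * (1 - probs) / length(nc))
  expect_true(all(abs(as.numeric(shares) - probs) < 3 * se))
})

test_that("the designated prior-positive mechanism produces qualifying priors", {
  # remove background red mass among non-cancers so every positive prior
  # comes from the mechanism itself
  cfg <- synthetic_config(
    n_women = 20000, rounds = 5, cancer_rate = 0.01,
    category_probs_noncancer = c(0.5, 0.5, 0),
    prior_positive_fraction = 24 / 105, seed = 31)
  co <- generate_cohort(cfg)
  lt <- lead_time_summary(co, high_cut = 30.44)
  # eligible patients: cancers after round 1
  # all women enter at the same first round, so a cancer visit after that
  # date implies at least one earlier screening visit
  ca_rows <- co[co$is_cancer_visit, ]
  eligible <- sum(ca_rows$visit_date > min(co$visit_date))
  p <- 24 / 105
  se <- sqrt(eligible * p * (1 - p))
  expect_lt(abs(lt$n_patients_earlier - eligible * p), 3 * se)
  # lead times are positive whole months drawn from the configured bins
  expect_true(all(lt$lead_times$months > 0))
  expect_true(all(lt$lead_times$months %in% c(6, 12, 24, 36, 48, 72)))
})
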