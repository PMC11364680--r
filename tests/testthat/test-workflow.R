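# Scenario accounting on the expanded in-study fixture, whose 105 cancers
# carry the published triage categories and detection modes.

fixture <- expand_table2_visits()

test_that("double reading reads every mammogram twice and detects the recorded 68", {
  o <- run_scenario(fixture, "bmsp")
  expect_equal(o$workload, 2 * 4998)
  expect_equal(o$detected, 68)
  expect_equal(o$missed_or_interval, 37)
})

test_that("AI-second-reader halves the reads; detection is human union AI-red", {
  o <- run_scenario(fixture, "s1")
  expect_equal(o$workload, 4998)
  # union of 68 recorded detections and 76 red cancers: 57 overlap
  expect_equal(o$detected, 87)
  b <- run_scenario(fixture, "bmsp")
  expect_equal(workload_reduction(o, b), 50)
})

test_that("hybrid flagged review detects 101 with one extra read per yellow", {
  o <- run_scenario(fixture, "s2")
  yellow <- sum(fixture$ai_score > 1 & fixture$ai_score < 30.44)
  expect_equal(o$workload, 4998 + yellow)
  expect_equal(o$detected, 101)   # 76 red + 24 yellow + 1 green recorded
  expect_equal(o$missed_or_interval, 4)
})

test_that("AI triage with a flag-perfect reader detects 100 with 5 missed", {
  o <- run_scenario(fixture, "s3", reader = "flag_perfect")
  expect_equal(o$detected, 100)
  expect_equal(o$missed_or_interval, 5)
  yr <- sum(fixture$ai_score > 1)
  expect_equal(o$workload, yr)
  # the conservative observed-reader variant detects fewer
  oc <- run_scenario(fixture, "s3", reader = "observed")
  expect_equal(oc$detected, 67)   # recorded detections minus the green one
})

test_that("accuracy increase of triage over double reading is 30.5%", {
  s3 <- run_scenario(fixture, "s3")
  b <- run_scenario(fixture, "bmsp")
  expect_equal(round(accuracy_increase(s3, b, 105), 1), 30.5)
  expect_equal(accuracy_increase(b, b, 105), 0)
  s2 <- run_scenario(fixture, "s2")
  expect_equal(round(accuracy_increase(s2, b, 105), 1), 31.4)
})

test_that("detected plus missed equals the 105 fixture cancers in every scenario", {
  for (s in c("bmsp", "s1", "s2", "s3")) {
    for (r in c("flag_perfect", "observed")) {
      o <- run_scenario(fixture, s, reader = r)
      expect_equal(o$detected + o$missed_or_interval, 105)
    }
  }
})

test_that("adding the second reading stage never loses cancers or reads", {
  for (seed in 1:5) {
    v <- random_visits(300, seed = seed)
    s1 <- run_scenario(v, "s1")
    s2 <- run_scenario(v, "s2")
    expect_gte(s2$detected, s1$detected)
    expect_gte(s2$workload, s1$workload)
  }
})

test_that("unknown scenarios and zero baselines are errors", {
  expect_error(run_scenario(fixture, "s9"),
               class = "screentriage_config_error")
  expect_error(workload_reduction(list(workload = 1), list(workload = 0)),
               class = "screentriage_metric_error")
})

test_that("predictive values: all-cancer recalls give PPV1 1, no FN gives NPV 1", {
  v <- random_visits(50, seed = 12)
  # make every red visit a cancer and every cancer red, no recorded recalls
  v$reader_detected <- FALSE
  v$detection_mode <- ifelse(v$is_cancer_visit, "interval", "none")
  v$ai_score <- ifelse(v$is_cancer_visit, 90, 10)
  o <- run_scenario(v, "s3", reader = "flag_perfect")
  pv <- predictive_values(o)
  expect_equal(pv$ppv1, 1)
  expect_equal(pv$npv, 1)
})

test_that("bootstrap scenario means match the closed-form workload oracle", {
  n_iter <- 400
  res <- simulate_scenarios(fixture, rate = 0.0057, n_iter = n_iter,
                            seed = 6)
  n_draw <- 18421 - 105
  p_yellow <- 2616 / 4893
  p_yr <- (2616 + 349) / 4893
  # expected workloads: s2 = N + E[yellow]; s3 = E[yellow + red]
  e_s2 <- 18421 + n_draw * p_yellow + 24
  e_s3 <- n_draw * p_yr + 100
  se_s2 <- sqrt(n_draw * p_yellow * (1 - p_yellow) / n_iter)
  se_s3 <- sqrt(n_draw * p_yr * (1 - p_yr) / n_iter)
  get <- function(s, col) res[[col]][res$scenario == s]
  expect_equal(get("bmsp", "workload_mean"), 36842)
  expect_equal(get("s1", "workload_mean"), 18421)
  expect_lt(abs(get("s2", "workload_mean") - e_s2), 3 * se_s2)
  expect_lt(abs(get("s3", "workload_mean") - e_s3), 3 * se_s3)
  # detection is fixed by the cancer visits
  expect_equal(res$detected[match(c("bmsp", "s1", "s2", "s3"),
                                  res$scenario)],
               c(68, 87, 101, 100))
  expect_true(all(res$detected + res$missed_or_interval == 105))
})

test_that("scenario streams are reproducible and respect the scenario subset", {
  a <- simulate_scenarios(fixture, scenarios = c("bmsp", "s3"),
                          n_iter = 50, seed = 9)
  b <- simulate_scenarios(fixture, scenarios = c("bmsp", "s3"),
                          n_iter = 50, seed = 9)
  expect_equal(as.data.frame(a), as.data.frame(b))
  no_base <- simulate_scenarios(fixture, scenarios = "s3", n_iter = 20,
                                seed = 1)
  expect_true(is.na(no_base$workload_reduction_vs_bmsp))
})
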