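# Independent oracles and small random-cohort builders used across tests.

# All-pairs Mann-Whitney concordance (ties counted half): the AUC oracle.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Brute-force Youden search over every observed score plus a sentinel.
brute_force_youden <- function(scores, labels) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  j <- vapply(thr, function(t) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    sens + spec - 1
  }, numeric(1))
  list(threshold = thr[which.max(j)], j = max(j))
}

# Exhaustive per-threshold sensitivity/specificity recount.
brute_force_roc <- function(scores, labels, thresholds) {
  data.frame(
    threshold = thresholds,
    sensitivity = vapply(thresholds,
                         function(t) mean(scores[labels] >= t), numeric(1)),
    specificity = vapply(thresholds,
                         function(t) mean(scores[!labels] < t), numeric(1))
  )
}

# Small random visit table for property tests (independent of the
# package's own generator).
random_visits <- function(n, seed, p_cancer = 0.3) {
  set.seed(seed)
  cancer <- runif(n) < p_cancer
  mode <- ifelse(cancer,
                 sample(c("screen_detected", "interval", "missed"), n,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                 "none")
  tibble::tibble(
    visit_id = sprintf("r%04d", seq_len(n)),
    woman_id = sprintf("rw%04d", seq_len(n)),
    visit_date = as.Date("2014-06-01"),
    ai_score = round(runif(n, 0, 100), 1),
    birads = ifelse(mode == "screen_detected", 5L, 2L),
    reader_detected = mode == "screen_detected",
    is_cancer_visit = cancer,
    detection_mode = mode
  )
}
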