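# Synthetic screening cohort generator. Emulates the statistical structure
# the analysis assumes: biennial rounds, a per-mammogram cancer rate,
# AI-score category masses per class, detection-mode composition, and
# AI-positive prior visits with a configured lead-time distribution.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions: 5.7 cancers per 1000 mammograms,
#' category masses equal to the published contingency-table proportions,
#' detection-mode composition 68/29/8 of 105, prior-positive fraction
#' 24/105 with the published lead-time bins, biennial (24-month) rounds.
#' The non-cancer recall rate (reader false positives) is not reported by
#' the study; the default 0.05 is a typical population-screening recall
#' figure.
#'
#' @param n_women Number of women.
#' @param rounds Number of biennial screening rounds per woman.
#' @param cancer_rate Per-mammogram cancer probability in (0, 1).
#' @param category_probs_noncancer,category_probs_cancer Probability triples
#'   over (green, yellow, red).
#' @param detection_mode_probs Probability triple over (screen_detected,
#'   interval, missed).
#' @param prior_positive_fraction Fraction of cancer patients whose earlier
#'   visit is AI-positive.
#' @param lead_time_distribution Named probability vector (names = months).
#' @param noncancer_recall_rate Probability a non-cancer visit is recalled
#'   by the readers.
#' @param low_cut,high_cut Triage cut points the score model is calibrated
#'   to.
#' @param interval_months Spacing of screening rounds in months.
#' @param seed Integer root seed.
#' @return An object of class `synthetic_config` (validated list).
#' @export
synthetic_config <- function(n_women = 10000L,
                             rounds = 5L,
                             cancer_rate = 0.0057,
                             category_probs_noncancer =
                               c(1928, 2616, 349) / 4893,
                             category_probs_cancer = c(5, 24, 76) / 105,
                             detection_mode_probs = c(68, 29, 8) / 105,
                             prior_positive_fraction = 24 / 105,
                             lead_time_distribution =
                               load_leadtime_bins() / 24,
                             noncancer_recall_rate = 0.05,
                             low_cut = 1,
                             high_cut = 30.44,
                             interval_months = 24L,
                             seed = 1L) {
  chk_probs <- function(p, name, len) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_config(sprintf("%s must be %d nonnegative values summing to 1",
                          name, len))
    }
  }
  if (n_women < 1 || rounds < 1) {
    stop_config("n_women and rounds must be positive")
  }
  if (!(cancer_rate >= 0 && cancer_rate < 1)) {
    stop_config("cancer_rate must lie in [0, 1)")
  }
  chk_probs(category_probs_noncancer, "category_probs_noncancer", 3)
  chk_probs(category_probs_cancer, "category_probs_cancer", 3)
  chk_probs(detection_mode_probs, "detection_mode_probs", 3)
  chk_probs(lead_time_distribution, "lead_time_distribution",
            length(lead_time_distribution))
  if (prior_positive_fraction < 0 || prior_positive_fraction > 1) {
    stop_config("prior_positive_fraction must lie in [0, 1]")
  }
  if (rounds < 2 && prior_positive_fraction > 0) {
    stop_config("prior_positive_fraction > 0 requires at least 2 rounds (no prior visit exists otherwise)")
  }
  structure(list(
    n_women = as.integer(n_women), rounds = as.integer(rounds),
    cancer_rate = cancer_rate,
    category_probs_noncancer = unname(category_probs_noncancer),
    category_probs_cancer = unname(category_probs_cancer),
    detection_mode_probs = unname(detection_mode_probs),
    prior_positive_fraction = prior_positive_fraction,
    lead_time_distribution = lead_time_distribution,
    noncancer_recall_rate = noncancer_recall_rate,
    low_cut = low_cut, high_cut = high_cut,
    interval_months = as.integer(interval_months),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Deterministic sub-seed per named component so each sampling stage draws
# from its own stream and stages can be tested independently.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Calibrate a piecewise score model to category masses
#'
#' Builds a sampling model for AI scores whose mass in the three triage
#' segments (at or below `low_cut`; strictly between the cuts; at or above
#' `high_cut`) equals the given category probabilities. Within each segment
#' the density is uniform — the least-informative choice consistent with
#' category masses.
#'
#' @param category_probs Probability triple over (green, yellow, red).
#' @param low_cut,high_cut Cut points with `0 < low_cut < high_cut < 100`.
#' @return An object of class `score_model`.
#' @export
#' @examples
#' m <- calibrate_score_model(c(0.3941, 0.5346, 0.0713), 1, 30.44)
#' summary(triage_category(sample_scores(m, 1000)))
calibrate_score_model <- function(category_probs, low_cut = 1,
                                  high_cut = 30.44) {
  if (length(category_probs) != 3 || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-9) {
    stop_config("category_probs must be 3 nonnegative values summing to 1")
  }
  if (!(0 < low_cut && low_cut < high_cut && high_cut < 100)) {
    stop_config("cuts must satisfy 0 < low_cut < high_cut < 100 (zero-width segment otherwise)")
  }
  structure(list(probs = unname(category_probs),
                 breaks = c(0, low_cut, high_cut, 100)),
            class = "score_model")
}

#' Sample AI scores from a calibrated score model
#'
#' @param model A `score_model` from [calibrate_score_model()].
#' @param n Number of scores to draw.
#' @return Numeric vector of scores in \[0, 100\].
#' @export
sample_scores <- function(model, n) {
  stopifnot(inherits(model, "score_model"))
  seg <- sample.int(3L, n, replace = TRUE, prob = model$probs)
  lo <- model$breaks[seg]
  hi <- model$breaks[seg + 1L]
  stats::runif(n, lo, hi)
}

#' Generate a synthetic screening cohort
#'
#' Simulates per-woman biennial visit sequences. Cancer strikes at most
#' once per woman, at the configured per-mammogram rate; the cancer visit
#' carries a detection mode drawn from the configured composition, with
#' `reader_detected` true exactly for screen-detected cancers. Interval
#' cancers receive a diagnosis date within 24 months of the (negative)
#' cancer visit; missed cancers within 1 month; a diagnosed woman leaves
#' the program. A configured fraction of cancer patients with at least one
#' earlier visit receives an AI-positive prior at a lead time drawn from
#' the lead-time distribution: when the lead falls on the screening grid
#' the existing visit's score is elevated, otherwise an extra visit row is
#' inserted at that month.
#'
#' @param config A `synthetic_config`.
#' @return A validated visit tibble (with a `diagnosis_date` column), with
#'   the config attached as attribute `"config"`.
#' @export
#' @examples
#' v <- generate_cohort(synthetic_config(n_women = 500, rounds = 3, seed = 7))
#' mean(v$is_cancer_visit)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  nw <- config$n_women
  rounds <- config$rounds
  base_date <- as.Date("2009-01-01")

  # Per-woman first cancer round (0 = never), via per-visit Bernoulli.
  hit <- matrix(stats::runif(nw * rounds) < config$cancer_rate,
                nrow = nw, ncol = rounds)
  any_hit <- rowSums(hit) > 0
  cancer_round <- ifelse(any_hit, max.col(hit, ties.method = "first"), 0L)

  # A diagnosed woman leaves screening: visits run to the cancer round.
  last_round <- ifelse(cancer_round > 0, cancer_round, rounds)
  woman <- rep.int(seq_len(nw), last_round)
  round_no <- sequence(last_round)
  n_visit <- length(woman)
  is_cancer <- cancer_round[woman] > 0 & round_no == cancer_round[woman]

  visit_month <- (round_no - 1L) * config$interval_months
  visit_date <- add_months(base_date, visit_month)

  set.seed(substream_seed(config$seed, "scores"))
  nc_model <- calibrate_score_model(config$category_probs_noncancer,
                                    config$low_cut, config$high_cut)
  ca_model <- calibrate_score_model(config$category_probs_cancer,
                                    config$low_cut, config$high_cut)
  score <- numeric(n_visit)
  score[!is_cancer] <- sample_scores(nc_model, sum(!is_cancer))
  score[is_cancer] <- sample_scores(ca_model, sum(is_cancer))

  set.seed(substream_seed(config$seed, "detection"))
  mode <- rep("none", n_visit)
  n_ca <- sum(is_cancer)
  if (n_ca > 0) {
    mode[is_cancer] <- sample(c("screen_detected", "interval", "missed"),
                              n_ca, replace = TRUE,
                              prob = config$detection_mode_probs)
  }
  reader_detected <- mode == "screen_detected"
  recall_nc <- !is_cancer &
    stats::runif(n_visit) < config$noncancer_recall_rate
  reader_detected[recall_nc] <- TRUE

  diagnosis_date <- as.Date(rep(NA, n_visit))
  diagnosis_date[mode == "screen_detected"] <-
    visit_date[mode == "screen_detected"]
  diagnosis_date[mode == "missed"] <-
    add_months(visit_date[mode == "missed"], 1L)
  n_int <- sum(mode == "interval")
  if (n_int > 0) {
    diagnosis_date[mode == "interval"] <-
      add_months(visit_date[mode == "interval"],
                 sample.int(24L, n_int, replace = TRUE))
  }

  birads <- integer(n_visit)
  birads[reader_detected] <- sample(c(0L, 4L, 5L), sum(reader_detected),
                                    replace = TRUE, prob = c(0.3, 0.4, 0.3))
  birads[mode == "screen_detected"] <- 5L
  birads[!reader_detected] <- sample(1:2, sum(!reader_detected),
                                     replace = TRUE)

  visits <- tibble::tibble(
    woman_id = sprintf("sw%06d", woman),
    visit_date = visit_date,
    ai_score = score,
    birads = birads,
    reader_detected = reader_detected,
    is_cancer_visit = is_cancer,
    detection_mode = mode,
    diagnosis_date = diagnosis_date
  )

  # AI-positive priors for a fraction of cancer patients with >= 1 earlier
  # visit: elevate the grid visit at the drawn lead, or insert an off-grid
  # visit (e.g. a 6- or 12-month lead between biennial rounds).
  set.seed(substream_seed(config$seed, "priors"))
  ca_rows <- which(is_cancer & round_no > 1L)
  pick <- ca_rows[stats::runif(length(ca_rows)) <
                    config$prior_positive_fraction]
  if (length(pick) > 0) {
    lead_months <- as.integer(names(config$lead_time_distribution))
    extra <- list()
    red_lo <- config$high_cut
    for (i in pick) {
      avail <- visit_month[i]   # months since entry; lead must not precede it
      ok <- lead_months <= avail
      if (!any(ok)) next
      p <- config$lead_time_distribution[ok]
      lead <- lead_months[ok][sample.int(sum(ok), 1L, prob = p / sum(p))]
      prior_month <- visit_month[i] - lead
      pos_score <- stats::runif(1, red_lo, 100)
      if (prior_month %% config$interval_months == 0L) {
        j <- which(woman == woman[i] & visit_month == prior_month)
        visits$ai_score[j] <- pos_score
      } else {
        extra[[length(extra) + 1L]] <- tibble::tibble(
          woman_id = visits$woman_id[i],
          visit_date = add_months(base_date, prior_month),
          ai_score = pos_score,
          birads = 2L,
          reader_detected = FALSE,
          is_cancer_visit = FALSE,
          detection_mode = "none",
          diagnosis_date = as.Date(NA)
        )
      }
    }
    if (length(extra) > 0) {
      visits <- rbind(visits, do.call(rbind, extra))
    }
  }

  visits <- visits[order(visits$woman_id, visits$visit_date), ]
  visits <- tibble::tibble(
    visit_id = sprintf("sv%07d", seq_len(nrow(visits))),
    visits
  )
  visits <- validate_visits(visits)
  attr(visits, "config") <- config
  visits
}
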