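# In-study fixtures: the published triage contingency counts and the
# lead-time bin counts, plus expansion into synthetic row-level visit tables.

#' Load the published triage contingency counts
#'
#' Returns the study's contingency table of AI triage categories
#' (green / yellow / red at cuts 1 and 30.44) against radiologist
#' evaluations: 4893 non-cancer and 105 histopathology-proven cancer
#' mammograms, with the cancers further split by detection mode
#' (68 screen-detected, 29 interval, 8 missed).
#'
#' @return An object of class `table2_fixture`: a list with integer matrices
#'   `truth` (non_cancer/cancer x green/yellow/red) and `mode`
#'   (screen_detected/interval/missed x green/yellow/red), plus `cuts`.
#' @export
#' @examples
#' fx <- load_table2_fixture()
#' fx$truth["cancer", "red"]  # 76
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_counts.csv",
                      package = utils::packageName())
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, c("green", "yellow", "red")])
  storage.mode(m) <- "integer"
  rownames(m) <- raw$row
  fx <- structure(list(
    truth = m[c("non_cancer", "cancer"), , drop = FALSE],
    mode  = m[c("screen_detected", "interval", "missed"), , drop = FALSE],
    cuts  = c(low = 1, high = 30.44)
  ), class = "table2_fixture")
  stopifnot(
    sum(fx$truth["non_cancer", ]) == 4893L,
    sum(fx$truth["cancer", ]) == 105L,
    rowSums(fx$mode) == c(68L, 29L, 8L),
    colSums(fx$mode) == fx$truth["cancer", ]
  )
  fx
}

#' @export
print.table2_fixture <- function(x, ...) {
  cat("Triage contingency fixture (cuts: <=", x$cuts["low"], "green, >=",
      x$cuts["high"], "red)\n\n", sep = " ")
  print(rbind(x$truth, x$mode))
  invisible(x)
}

#' Expand the triage fixture into a row-level visit table
#'
#' Expands the published category counts into one synthetic visit row per
#' mammogram (4893 non-cancer + 105 cancer = 4998 rows). Each row receives a
#' representative AI score at the midpoint of its category's score interval
#' — downstream stages consume scores, and only the category matters for
#' every in-study computation. Cancer rows carry their detection mode;
#' screen-detected cancers are `reader_detected` with BI-RADS 5, interval
#' and missed cancers are reader-negative with BI-RADS 2, as are all
#' non-cancer rows (the published table carries no non-cancer recall
#' information).
#'
#' @param low_cut,high_cut Triage cut points (defaults: the study's 1 and
#'   30.44).
#' @return A validated visit tibble with 4998 rows.
#' @export
#' @examples
#' v <- expand_table2_visits()
#' table(v$is_cancer_visit)
expand_table2_visits <- function(low_cut = 1, high_cut = 30.44) {
  fx <- load_table2_fixture()
  rep_score <- c(green = low_cut / 2,
                 yellow = (low_cut + high_cut) / 2,
                 red = (high_cut + 100) / 2)
  cats <- colnames(fx$truth)

  nc_n <- fx$truth["non_cancer", ]
  nc <- tibble::tibble(
    ai_score = rep(rep_score[cats], nc_n),
    detection_mode = "none",
    is_cancer_visit = FALSE,
    reader_detected = FALSE,
    birads = 2L
  )

  modes <- rownames(fx$mode)
  ca <- do.call(rbind, lapply(modes, function(m) {
    n <- fx$mode[m, ]
    tibble::tibble(
      ai_score = rep(rep_score[cats], n),
      detection_mode = m,
      is_cancer_visit = TRUE,
      reader_detected = m == "screen_detected",
      birads = if (m == "screen_detected") 5L else 2L
    )
  }))

  all <- rbind(nc, ca)
  n <- nrow(all)
  visits <- tibble::tibble(
    visit_id = sprintf("v%04d", seq_len(n)),
    woman_id = sprintf("w%04d", seq_len(n)),
    visit_date = as.Date("2015-01-01"),
    ai_score = all$ai_score,
    birads = all$birads,
    reader_detected = all$reader_detected,
    is_cancer_visit = all$is_cancer_visit,
    detection_mode = all$detection_mode
  )
  validate_visits(visits)
}

#' Load the published lead-time bin counts
#'
#' Counts of cancer patients whose earliest AI-positive prior mammogram
#' preceded diagnosis by 6, 12, 24, 36, 48 or 72 months (24 patients in
#' total).
#'
#' @return A named integer vector (names = months, values = patients).
#' @export
load_leadtime_bins <- function() {
  path <- system.file("extdata", "leadtime_bins.csv",
                      package = utils::packageName())
  raw <- utils::read.csv(path)
  bins <- stats::setNames(as.integer(raw$patients), raw$months)
  stopifnot(sum(bins) == 24L)
  bins
}

#' Build a synthetic longitudinal fixture cohort
#'
#' Constructs per-patient screening histories for the 105 cancer patients
#' that reproduce the published longitudinal margins: 138 prior mammograms
#' in total, 35 of them AI-positive, belonging to 24 patients whose
#' *earliest* positive prior matches the published lead-time bins. Visit
#' dates are synthetic (the study reports only the bins); everything beyond
#' the printed margins — which patients carry the extra positive or negative
#' priors — is an arbitrary but deterministic allocation.
#'
#' @param low_cut,high_cut Triage cut points used for representative scores.
#' @return A validated visit tibble: 105 diagnosis visits plus 138 priors.
#' @export
leadtime_fixture_cohort <- function(low_cut = 1, high_cut = 30.44) {
  bins <- load_leadtime_bins()
  pos_score <- (high_cut + 100) / 2
  neg_score <- (low_cut + high_cut) / 2   # flagged but below threshold
  dx_date <- as.Date("2018-01-01")

  lead <- rep(as.integer(names(bins)), bins)   # 24 earliest-positive leads
  n_pos_patients <- length(lead)               # 24
  n_patients <- 105L

  rows <- list()
  add <- function(woman, months_before, score, cancer = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      woman_id = sprintf("p%03d", woman),
      visit_date = add_months(dx_date, -months_before),
      ai_score = score,
      birads = if (cancer) 5L else 2L,
      reader_detected = cancer,
      is_cancer_visit = cancer,
      detection_mode = if (cancer) "screen_detected" else "none"
    )
  }

  # Diagnosis visit for every cancer patient.
  for (w in seq_len(n_patients)) add(w, 0L, pos_score, cancer = TRUE)
  # Earliest positive prior at the binned lead time.
  for (w in seq_len(n_pos_patients)) add(w, lead[w], pos_score)
  # 11 additional positive priors (35 total) go to patients with lead > 6
  # months, placed 6 months before diagnosis so the earliest is unchanged.
  extra_pos <- utils::head(which(lead > 6L), 11L)
  for (w in extra_pos) add(w, 6L, pos_score)
  # Negative priors: one for each of the 81 patients with no positive prior,
  # plus 22 more spread over the first positive-prior patients, for 138
  # priors in total.
  for (w in seq(n_pos_patients + 1L, n_patients)) add(w, 24L, neg_score)
  for (w in utils::head(seq_len(n_pos_patients), 22L)) {
    add(w, lead[w] + 24L, neg_score)
  }

  visits <- do.call(rbind, rows)
  visits <- visits[order(visits$woman_id, visits$visit_date), ]
  visits <- tibble::tibble(
    visit_id = sprintf("lv%03d", seq_len(nrow(visits))),
    visits
  )
  validate_visits(visits)
}
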