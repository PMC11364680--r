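# Green/yellow/red triage of AI scores and contingency summaries.

triage_levels <- c("green", "yellow", "red")

#' Triage an AI score into green / yellow / red
#'
#' Scores at or below `low_cut` are green (auto-negative), scores at or
#' above `high_cut` are red (positive), and scores strictly between the two
#' cuts are yellow (flagged for human review). The boundary conventions
#' match the scoring software: scores below the low-risk cut are reported as
#' low risk, and scores above or equal to the selected threshold are
#' positive.
#'
#' @param ai_score Numeric vector of scores in \[0, 100\].
#' @param low_cut Green/yellow boundary (default 1).
#' @param high_cut Yellow/red boundary (default 30.44, the study's
#'   Youden-selected threshold).
#' @return Factor with levels `green`, `yellow`, `red`.
#' @export
#' @examples
#' triage_category(c(0.5, 15, 30.44))
triage_category <- function(ai_score, low_cut = 1, high_cut = 30.44) {
  if (!(low_cut < high_cut)) {
    stop_config("low_cut must be strictly below high_cut")
  }
  bad <- which(!is.finite(ai_score) | ai_score < 0 | ai_score > 100)
  if (length(bad) > 0) {
    stop_validation(sprintf("ai_score out of [0, 100] at position %d",
                            bad[1L]))
  }
  out <- ifelse(ai_score <= low_cut, "green",
                ifelse(ai_score >= high_cut, "red", "yellow"))
  factor(out, levels = triage_levels)
}

#' Build a triage contingency table from a visit table
#'
#' Tallies visits by truth class (non-cancer / cancer) and triage category,
#' and cancer visits additionally by detection mode, mirroring the study's
#' published layout.
#'
#' @param visits Visit table (see [visit_columns]).
#' @param low_cut,high_cut Triage cut points passed to [triage_category()].
#' @return An object of class `triage_table`: list with integer matrices
#'   `truth` and `mode`, row-wise `proportions`, and the `cuts` used.
#' @export
#' @examples
#' tt <- build_triage_table(expand_table2_visits())
#' tt$truth
build_triage_table <- function(visits, low_cut = 1, high_cut = 30.44) {
  visits <- validate_visits(visits)
  cat <- triage_category(visits$ai_score, low_cut, high_cut)
  truth_f <- factor(ifelse(visits$is_cancer_visit, "cancer", "non_cancer"),
                    levels = c("non_cancer", "cancer"))
  truth <- table(truth_f, cat)
  truth <- matrix(as.integer(truth), nrow = 2,
                  dimnames = list(c("non_cancer", "cancer"), triage_levels))
  ca <- visits$is_cancer_visit
  mode_f <- factor(visits$detection_mode[ca],
                   levels = c("screen_detected", "interval", "missed"))
  mode <- table(mode_f, cat[ca])
  mode <- matrix(as.integer(mode), nrow = 3,
                 dimnames = list(c("screen_detected", "interval", "missed"),
                                 triage_levels))
  props <- rbind(truth, mode)
  props <- props / ifelse(rowSums(props) > 0, rowSums(props), NA_real_)
  structure(list(truth = truth, mode = mode, proportions = props,
                 cuts = c(low = low_cut, high = high_cut)),
            class = "triage_table")
}

#' @export
print.triage_table <- function(x, digits = 2, ...) {
  cat(sprintf("Triage table at cuts (green <= %s, red >= %s)\n\n",
              format(x$cuts["low"]), format(x$cuts["high"])))
  m <- rbind(x$truth, x$mode)
  p <- x$proportions * 100
  disp <- matrix(sprintf("%d (%.*f%%)", m, digits, p), nrow = nrow(m),
                 dimnames = dimnames(m))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Convert a triage table to a tidy tibble
#'
#' @param x A `triage_table`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `category`, `count`, `proportion`.
#' @export
as_tibble.triage_table <- function(x, ...) {
  m <- rbind(x$truth, x$mode)
  tibble::tibble(
    row = rep(rownames(m), times = ncol(m)),
    category = rep(colnames(m), each = nrow(m)),
    count = as.integer(m),
    proportion = as.numeric(x$proportions)
  )
}

#' Operating metrics of AI triage against histology truth
#'
#' Treating red (score at or above the threshold) as test-positive:
#' sensitivity is the red share of cancer visits; specificity is one minus
#' the red share of non-cancer visits; `fp_rate_noncancer` is the
#' false-positive share among non-cancer visits; `fn_rate_cancer` is the
#' share of cancers *not* called red (green plus yellow — flagged cancers
#' count as false negatives of the positive call). Per-mode detection rates
#' are the red shares within screen-detected, interval and missed cancers.
#'
#' @param table A `triage_table` from [build_triage_table()].
#' @return List with `sensitivity`, `specificity`, `fp_rate_noncancer`,
#'   `fn_rate_cancer`, and `detection_rate_by_mode` (named numeric vector).
#' @export
#' @examples
#' operating_metrics(build_triage_table(expand_table2_visits()))
operating_metrics <- function(table) {
  stopifnot(inherits(table, "triage_table"))
  n_nc <- sum(table$truth["non_cancer", ])
  n_ca <- sum(table$truth["cancer", ])
  if (n_nc == 0 || n_ca == 0) {
    stop_metric("operating metrics undefined: empty truth class")
  }
  mode_tot <- rowSums(table$mode)
  list(
    sensitivity = table$truth["cancer", "red"] / n_ca,
    specificity = 1 - table$truth["non_cancer", "red"] / n_nc,
    fp_rate_noncancer = table$truth["non_cancer", "red"] / n_nc,
    fn_rate_cancer = (table$truth["cancer", "green"] +
                        table$truth["cancer", "yellow"]) / n_ca,
    detection_rate_by_mode = ifelse(mode_tot > 0,
                                    table$mode[, "red"] / mode_tot, NA_real_)
  )
}
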