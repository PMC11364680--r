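# Reading-workflow simulation: double reading (bmsp) and three AI-assisted
# scenarios, with workload, detection, recall, PPV1 and NPV accounting.
#
# Scenario definitions (reads per visit; cancer-detection rule):
#   bmsp  2 reads/visit; detection = recorded double-reading outcome.
#   s1    1 read/visit, AI is the second reader; detection = recorded
#         human outcome OR AI red.
#   s2    s1 plus a second human read of every yellow (flagged) visit;
#         detection additionally credits the second reader on yellows.
#   s3    AI triage: green eliminated unread; yellow and red read by a
#         single radiologist; detection = that reader's calls on
#         yellow/red, with red escalated for assessment.
#
# Reader models govern the AI-era human stages (the second reader on
# yellows in s2, the single triage reader in s3):
#   flag_perfect  the human detects every cancer the AI flagged yellow or
#                 red; non-cancer recalls follow the recorded labels.
#   observed      the human repeats the recorded double-reading outcome.

scenario_names <- c("bmsp", "s1", "s2", "s3")
reader_models <- c("flag_perfect", "observed")

#' Describe a reading-workflow scenario
#'
#' @param name One of `"bmsp"`, `"s1"`, `"s2"`, `"s3"`.
#' @return An object of class `scenario_spec` with `name` and
#'   `description`.
#' @export
scenario_spec <- function(name) {
  name <- as.character(name)
  if (!name %in% scenario_names) {
    stop_config(sprintf("unknown scenario %s (expected one of %s)",
                        dQuote(name),
                        paste(scenario_names, collapse = ", ")))
  }
  desc <- c(
    bmsp = "Double reading: two radiologists read every mammogram",
    s1 = "Single radiologist with AI as second reader",
    s2 = "Scenario 1 plus a second radiologist on AI-flagged (yellow) visits",
    s3 = "AI triage: green auto-negative, yellow/red read by one radiologist"
  )[[name]]
  structure(list(name = name, description = desc), class = "scenario_spec")
}

# Per-visit detection/recall/read indicators for one scenario. Returns
# logical vectors over the cohort.
scenario_flags <- function(cat, cancer, recorded, spec_name, reader) {
  red <- cat == 3L
  yellow <- cat == 2L
  # AI-era human stage outcome per visit: detection call on cancers and
  # recall call on non-cancers.
  stage_call <- switch(reader,
    flag_perfect = (cancer & (yellow | red)) | (!cancer & recorded),
    observed = recorded
  )
  switch(spec_name,
    bmsp = list(reads = rep(2L, length(cat)),
                detected = cancer & recorded,
                recalled = recorded),
    s1 = list(reads = rep(1L, length(cat)),
              detected = cancer & (recorded | red),
              recalled = recorded | red),
    s2 = list(reads = 1L + as.integer(yellow),
              detected = cancer & (recorded | red | (yellow & stage_call)),
              recalled = recorded | red | (yellow & stage_call)),
    s3 = list(reads = as.integer(yellow | red),
              detected = cancer & (yellow | red) & stage_call,
              recalled = red | (yellow & stage_call))
  )
}

#' Run one reading-workflow scenario on a cohort
#'
#' Computes total human reads (workload), detected cancers, missed or
#' interval cancers (cancers the workflow does not detect), recalls, PPV1
#' (cancers among recalled visits / recalls) and NPV (non-cancers among
#' final negatives / negatives). Recalls are the visits called positive by
#' the final workflow decision: human recalls on read visits plus AI-red
#' escalation where the scenario eliminates or triages reads.
#'
#' @param cohort A visit table or a `simulated_cohort` from
#'   [bootstrap_cohorts()].
#' @param spec A `scenario_spec` or scenario name.
#' @param reader Reader model for the AI-era human stages:
#'   `"flag_perfect"` (default; the human detects every AI-flagged cancer)
#'   or `"observed"` (the human repeats the recorded outcome — the
#'   conservative variant).
#' @param cuts Numeric `(low, high)` triage cut points.
#' @param seed Unused by the built-in deterministic readers; accepted for
#'   forward compatibility with stochastic reader models.
#' @return An object of class `scenario_outcome`: list with `scenario`,
#'   `reader`, `n_visits`, `n_cancers`, `workload`, `detected`,
#'   `missed_or_interval`, `recalls`, `ppv1`, `npv`.
#' @export
#' @examples
#' run_scenario(expand_table2_visits(), "s3")
run_scenario <- function(cohort, spec, reader = c("flag_perfect", "observed"),
                         cuts = c(1, 30.44), seed = NULL) {
  if (inherits(cohort, "simulated_cohort")) cohort <- cohort$visits
  cohort <- validate_visits(cohort)
  if (inherits(spec, "scenario_spec")) spec <- spec$name
  spec <- scenario_spec(spec)$name
  reader <- match.arg(reader)
  cat <- as.integer(triage_category(cohort$ai_score, cuts[1], cuts[2]))
  fl <- scenario_flags(cat, cohort$is_cancer_visit, cohort$reader_detected,
                       spec, reader)
  n_ca <- sum(cohort$is_cancer_visit)
  detected <- sum(fl$detected)
  recalls <- sum(fl$recalled)
  negatives <- nrow(cohort) - recalls
  structure(list(
    scenario = spec,
    reader = reader,
    n_visits = nrow(cohort),
    n_cancers = n_ca,
    workload = sum(fl$reads),
    detected = detected,
    missed_or_interval = n_ca - detected,
    recalls = recalls,
    ppv1 = if (recalls > 0) {
      sum(cohort$is_cancer_visit & fl$recalled) / recalls
    } else NA_real_,
    npv = if (negatives > 0) {
      sum(!cohort$is_cancer_visit & !fl$recalled) / negatives
    } else NA_real_
  ), class = "scenario_outcome")
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf(
    "%s (%s reader): workload %d, detected %d/%d, missed/interval %d, recalls %d\n",
    x$scenario, x$reader, x$workload, x$detected, x$n_cancers,
    x$missed_or_interval, x$recalls))
  if (!is.na(x$ppv1)) cat(sprintf("  PPV1 %.2f%%", 100 * x$ppv1))
  if (!is.na(x$npv)) cat(sprintf("  NPV %.2f%%", 100 * x$npv))
  cat("\n")
  invisible(x)
}

#' Percent workload reduction relative to a baseline scenario
#'
#' @param outcome,baseline `scenario_outcome` objects (or anything with a
#'   `workload` element).
#' @return Percentage, `100 * (1 - outcome / baseline)`.
#' @export
#' @examples
#' v <- expand_table2_visits()
#' workload_reduction(run_scenario(v, "s3"), run_scenario(v, "bmsp"))
workload_reduction <- function(outcome, baseline) {
  if (is.null(baseline$workload) || baseline$workload <= 0) {
    stop_metric("baseline workload must be positive")
  }
  100 * (1 - outcome$workload / baseline$workload)
}

#' Percent accuracy increase relative to a baseline scenario
#'
#' Measured as additionally detected cancers as a share of all cancers.
#'
#' @param outcome,baseline `scenario_outcome` objects.
#' @param n_cancers Total cancers in the cohort.
#' @return Percentage, `100 * (detected - baseline detected) / n_cancers`.
#' @export
accuracy_increase <- function(outcome, baseline, n_cancers) {
  if (n_cancers <= 0) stop_metric("n_cancers must be positive")
  100 * (outcome$detected - baseline$detected) / n_cancers
}

#' Predictive values of a scenario outcome
#'
#' @param outcome A `scenario_outcome`.
#' @return List with `ppv1` and `npv`.
#' @export
predictive_values <- function(outcome) {
  if (is.na(outcome$ppv1)) stop_metric("PPV1 undefined: no recalls")
  if (is.na(outcome$npv)) stop_metric("NPV undefined: no negatives")
  list(ppv1 = outcome$ppv1, npv = outcome$npv)
}

#' Simulate scenarios over a prevalence-matched bootstrap
#'
#' Runs the requested scenarios on `n_iter` prevalence-matched bootstrap
#' cohorts (cancer visits fixed, non-cancer visits resampled with
#' replacement to the target rate) and aggregates workload, recalls, PPV1,
#' NPV and — when `bmsp` is included — the per-iteration workload reduction
#' of each scenario against the double-reading baseline. Detection counts
#' depend only on the fixed cancer visits and are therefore constant across
#' iterations. Uses an index-resampling fast path: per-iteration cohorts
#' are never materialised, so 10,000 iterations run in seconds with
#' constant memory.
#'
#' @param visits Source visit table.
#' @param scenarios Character vector of scenario names (default all four).
#' @param rate Target cancer rate per mammogram (default 0.0057).
#' @param n_iter Bootstrap iterations (default 10,000).
#' @param seed Optional integer seed.
#' @param cuts Triage cut points.
#' @param reader Reader model for the AI-era human stages.
#' @param level Confidence level for percentile intervals (default 0.95).
#' @return A tibble with one row per scenario: detection counts, mean / sd
#'   / percentile-interval workload and recalls, mean PPV1 and NPV, and
#'   mean workload reduction vs `bmsp` (NA when `bmsp` is absent).
#' @export
#' @examples
#' simulate_scenarios(expand_table2_visits(), n_iter = 50, seed = 1)
simulate_scenarios <- function(visits, scenarios = scenario_names,
                               rate = 0.0057, n_iter = 10000L, seed = NULL,
                               cuts = c(1, 30.44),
                               reader = c("flag_perfect", "observed"),
                               level = 0.95) {
  visits <- validate_visits(visits)
  reader <- match.arg(reader)
  scenarios <- vapply(scenarios, function(s) scenario_spec(s)$name, "")
  cancer <- visits$is_cancer_visit
  if (!any(cancer) || all(cancer)) {
    stop_degenerate("bootstrap requires at least one visit of each class")
  }
  cat <- as.integer(triage_category(visits$ai_score, cuts[1], cuts[2]))
  rec <- visits$reader_detected

  size <- simulated_cohort_size(sum(cancer), rate)
  n_draw <- size - sum(cancer)

  # Cancer-side contributions are fixed across iterations.
  ca_fl <- lapply(scenarios, function(s) {
    f <- scenario_flags(cat[cancer], rep(TRUE, sum(cancer)), rec[cancer],
                        s, reader)
    list(reads = sum(f$reads), detected = sum(f$detected),
         recalls = sum(f$recalled))
  })
  names(ca_fl) <- scenarios

  # Non-cancer visits collapse to 6 cells: triage category x recorded
  # recall. Per-scenario per-cell reads and recall indicators.
  nc_cat <- cat[!cancer]
  nc_rec <- rec[!cancer]
  cell <- nc_cat + 3L * as.integer(nc_rec)        # 1..6
  cell_reads <- function(s) {
    g <- expand.grid(cat = 1:3, rec = c(FALSE, TRUE))
    f <- scenario_flags(g$cat, rep(FALSE, 6), g$rec, s, reader)
    list(reads = f$reads, recalled = f$recalled)
  }
  cells <- lapply(scenarios, cell_reads)
  names(cells) <- scenarios

  if (!is.null(seed)) set.seed(seed)
  nc_n <- length(cell)
  work <- matrix(0, nrow = n_iter, ncol = length(scenarios),
                 dimnames = list(NULL, scenarios))
  recalls <- work
  for (it in seq_len(n_iter)) {
    idx <- sample.int(nc_n, n_draw, replace = TRUE)
    counts <- tabulate(cell[idx], nbins = 6L)
    for (s in scenarios) {
      work[it, s] <- ca_fl[[s]]$reads + sum(counts * cells[[s]]$reads)
      recalls[it, s] <- ca_fl[[s]]$recalls +
        sum(counts * cells[[s]]$recalled)
    }
  }

  alpha <- (1 - level) / 2
  has_bmsp <- "bmsp" %in% scenarios
  rows <- lapply(scenarios, function(s) {
    w <- work[, s]
    r <- recalls[, s]
    negatives <- size - r
    ppv1 <- ifelse(r > 0, ca_fl[[s]]$recalls / r, NA_real_)
    nc_neg <- (size - sum(cancer)) - (r - ca_fl[[s]]$recalls)
    npv <- ifelse(negatives > 0, nc_neg / negatives, NA_real_)
    tibble::tibble(
      scenario = s,
      reader = reader,
      n_visits = size,
      n_cancers = sum(cancer),
      detected = ca_fl[[s]]$detected,
      missed_or_interval = sum(cancer) - ca_fl[[s]]$detected,
      workload_mean = mean(w),
      workload_sd = stats::sd(w),
      workload_lo = unname(stats::quantile(w, alpha)),
      workload_hi = unname(stats::quantile(w, 1 - alpha)),
      recalls_mean = mean(r),
      ppv1_mean = mean(ppv1),
      npv_mean = mean(npv),
      workload_reduction_vs_bmsp = if (has_bmsp) {
        mean(100 * (1 - w / work[, "bmsp"]))
      } else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  out
}
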