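# Prevalence-matched bootstrap: resample non-cancer visits with replacement
# so the combined cohort attains a target cancer rate per mammogram.

#' Size of a prevalence-matched simulated cohort
#'
#' The simulated cohort keeps every cancer visit and resamples non-cancer
#' visits so that `n_cancer / size = rate`; the size is rounded to the
#' nearest integer (105 cancers at 5.7 per 1000 gives 18,421 mammograms).
#'
#' @param n_cancer Number of cancer visits (kept fixed).
#' @param rate Target cancer rate per mammogram, in (0, 1\].
#' @return Integer cohort size; the non-cancer draw count is
#'   `size - n_cancer`.
#' @export
#' @examples
#' simulated_cohort_size(105, 0.0057)  # 18421
simulated_cohort_size <- function(n_cancer, rate) {
  if (n_cancer < 1) stop_config("n_cancer must be positive")
  if (!(rate > 0 && rate <= 1)) {
    stop_config("rate must lie in (0, 1]")
  }
  as.integer(round(n_cancer / rate))
}

#' Stream prevalence-matched bootstrap cohorts
#'
#' For each of `n_iter` iterations, draws `size - n_cancer` non-cancer
#' visits uniformly with replacement from the source table, combines them
#' with the (never-resampled) cancer visits, and applies `fun` to the
#' resulting cohort. Only the `n_iter` return values of `fun` are retained,
#' so memory use is constant in `n_iter`.
#'
#' @param visits Source visit table with at least one visit of each class.
#' @param fun Function applied to each cohort; receives an object of class
#'   `simulated_cohort` — a list with `visits` (tibble; omitted when
#'   `materialize = FALSE`), `source_rows` (row indices into `visits`,
#'   cancers first), `iteration` and `seed`.
#' @param rate Target cancer rate (default 0.0057, i.e. 5.7 per 1000).
#' @param n_iter Number of bootstrap iterations (default 10,000).
#' @param seed Optional integer seed; iterations are reproducible given it.
#' @param woman_level If `TRUE`, resample non-cancer *women* with
#'   replacement (all their visits), trimming the final woman's visits to
#'   hit the target draw count; the default resamples at the visit level.
#' @param materialize If `FALSE`, `fun` receives indices only (faster).
#' @return List of `fun` results, length `n_iter`.
#' @export
#' @examples
#' v <- expand_table2_visits()
#' sizes <- bootstrap_cohorts(v, function(co) nrow(co$visits),
#'                            n_iter = 3, seed = 1)
bootstrap_cohorts <- function(visits, fun, rate = 0.0057, n_iter = 10000L,
                              seed = NULL, woman_level = FALSE,
                              materialize = TRUE) {
  visits <- validate_visits(visits)
  if (n_iter < 1) stop_config("n_iter must be positive")
  cancer_rows <- which(visits$is_cancer_visit)
  noncancer_rows <- which(!visits$is_cancer_visit)
  if (length(cancer_rows) == 0 || length(noncancer_rows) == 0) {
    stop_degenerate("bootstrap requires at least one visit of each class")
  }
  size <- simulated_cohort_size(length(cancer_rows), rate)
  n_draw <- size - length(cancer_rows)
  if (n_draw < 0) {
    stop_config("target rate implies fewer visits than there are cancers")
  }
  if (!is.null(seed)) set.seed(seed)

  nc_women <- NULL
  if (woman_level) {
    nc_women <- split(noncancer_rows, visits$woman_id[noncancer_rows])
  }

  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    if (woman_level) {
      drawn <- integer(0)
      while (length(drawn) < n_draw) {
        w <- sample.int(length(nc_women), 1L)
        drawn <- c(drawn, nc_women[[w]])
      }
      idx <- drawn[seq_len(n_draw)]
    } else {
      idx <- noncancer_rows[sample.int(length(noncancer_rows), n_draw,
                                       replace = TRUE)]
    }
    src <- c(cancer_rows, idx)
    cohort <- structure(list(
      visits = if (materialize) visits[src, ] else NULL,
      source_rows = src,
      iteration = it,
      seed = seed
    ), class = "simulated_cohort")
    out[[it]] <- fun(cohort)
  }
  out
}
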