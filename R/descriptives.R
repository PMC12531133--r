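#' Half-up rounding
#'
#' Rounds halves away from zero (ties-to-even is the base default), matching
#' the one-decimal percentage formatting used in the reported tables.
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

OUTCOME_PRECEDENCE <- c("death", "life_threatening", "disability",
                        "hospitalization", "other_serious", "non_serious")

#' Collapse outcome codes to one category per report
#'
#' Spontaneous reports can carry several outcome codes while descriptive
#' tables need a partition; the most severe code wins (death >
#' life-threatening > disability > hospitalization > other serious >
#' non-serious). Reports with no outcome code count as non-serious.
#'
#' @param db an [icsr_db()].
#' @return tibble `case_id`, `outcome` (one row per case).
#' @export
outcome_partition <- function(db) {
  sev <- match(db$outcomes$outcome, OUTCOME_PRECEDENCE)
  ranked <- db$outcomes |>
    dplyr::mutate(rank = sev) |>
    dplyr::filter(!is.na(.data$rank)) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      # suppressWarnings: dplyr probes the empty prototype when no rows match
      outcome = OUTCOME_PRECEDENCE[suppressWarnings(min(.data$rank))],
      .groups = "drop")
  out <- dplyr::left_join(db$demo["case_id"], ranked, by = "case_id")
  out$outcome[is.na(out$outcome)] <- "non_serious"
  out
}

#' Fraction of reports meeting serious-outcome criteria
#'
#' Share of reports whose collapsed outcome is anything other than
#' non-serious.
#'
#' @param db an [icsr_db()].
#' @return list `pct` (one decimal) and `pct_int` (integer-rounded).
#' @export
serious_fraction <- function(db) {
  oc <- outcome_partition(db)
  p <- 100 * mean(oc$outcome != "non_serious")
  list(pct = round_half_up(p, 1), pct_int = round_half_up(p, 0))
}

#' Map free-text indications to organ-system buckets
#'
#' @param indication character vector of free-text indications.
#' @param map optional custom mapping table (`indication`, `bucket`);
#'   defaults to the shipped editable table. Indications already equal to a
#'   bucket name pass through; anything unmapped or missing becomes
#'   `"Unknown or missing"`.
#' @export
map_indication_bucket <- function(indication, map = NULL) {
  map <- map %||% readr::read_csv(pv_extdata("indication_buckets.csv"),
                                  show_col_types = FALSE, progress = FALSE)
  x <- tolower(trimws(indication))
  hit <- match(x, tolower(map$indication))
  out <- map$bucket[hit]
  known_buckets <- unique(map$bucket)
  direct <- match(x, tolower(known_buckets))
  out[is.na(out) & !is.na(direct)] <- known_buckets[direct[is.na(out) & !is.na(direct)]]
  out[is.na(out)] <- "Unknown or missing"
  out
}

count_block <- function(values, categories, n_total) {
  cnt <- table(factor(values, levels = categories))
  tibble::tibble(category = categories,
                 n = as.integer(cnt),
                 pct = if (n_total > 0)
                   round_half_up(100 * as.integer(cnt) / n_total, 1) else NA_real_)
}

summarize_stratum <- function(db, asg, label, indication_map = NULL,
                              exclude_imputed_tto = TRUE,
                              indication_levels = NULL) {
  n <- n_cases(db)
  demo <- db$demo
  oc <- outcome_partition(db)
  sex <- ifelse(demo$sex == "unknown", "not_reported", demo$sex)
  blocks <- dplyr::bind_rows(
    dplyr::mutate(count_block(sex, c("male", "female", "not_reported"), n),
                  block = "sex"),
    dplyr::mutate(count_block(demo$reporter_type, REPORTER_LEVELS, n),
                  block = "reporter"),
    dplyr::mutate(count_block(
      oc$outcome,
      c("non_serious", "hospitalization", "disability", "life_threatening",
        "death", "other_serious"), n), block = "outcome"),
    dplyr::mutate(count_block(demo$region, REGION_LEVELS, n), block = "region"),
    dplyr::mutate(count_block(
      map_indication_bucket(demo$indication, indication_map),
      indication_levels %||%
        sort(unique(map_indication_bucket(demo$indication, indication_map))), n),
      block = "indication")
  )
  blocks$stratum <- label
  age <- demo$age_years[!is.na(demo$age_years)]
  tto <- asg$time_to_onset_days[
    !is.na(asg$time_to_onset_days) &
      (!exclude_imputed_tto | !asg$tto_imputed)]
  list(
    counts = blocks[, c("stratum", "block", "category", "n", "pct")],
    scalars = tibble::tibble(
      stratum = label, n_reports = n,
      age_median = if (length(age)) median(age) else NA_real_,
      age_min = if (length(age)) min(age) else NA_real_,
      age_max = if (length(age)) max(age) else NA_real_,
      age_n = length(age),
      tto_median = if (length(tto)) median(tto) else NA_real_,
      tto_min = if (length(tto)) min(tto) else NA_real_,
      tto_max = if (length(tto)) max(tto) else NA_real_,
      tto_n = length(tto)))
}

#' Stratified descriptive summary of selected cases
#'
#' One summary per regimen stratum plus a pooled Total: report counts,
#' age median/range over reports with known age, sex / reporter / outcome /
#' region / indication-bucket blocks as counts with one-decimal percentages
#' of the stratum size, and the time-to-onset median/range over reports
#' where onset could be computed from non-imputed dates. Medians use the
#' mean-of-middle-two convention for even n.
#'
#' @param db an [icsr_db()] of selected cases.
#' @param assignments [classify_regimen()] output for the same cases.
#' @param indication_map optional custom indication-bucket table.
#' @param exclude_imputed_tto drop onset gaps built on imputed partial dates
#'   (default TRUE).
#' @return list `counts` (tidy tibble: stratum, block, category, n, pct) and
#'   `scalars` (tibble with n_reports, age and onset summaries per stratum).
#' @export
summarize_cases <- function(db, assignments, indication_map = NULL,
                            exclude_imputed_tto = TRUE) {
  strata <- split(assignments$case_id,
                  factor(assignments$regimen, levels = ANALYSIS_REGIMENS))
  ind_levels <- sort(unique(map_indication_bucket(
    db$demo$indication[db$demo$case_id %in% assignments$case_id],
    indication_map)))
  pieces <- lapply(names(strata), function(lab) {
    ids <- strata[[lab]]
    summarize_stratum(filter_cases(db, ids),
                      assignments[assignments$case_id %in% ids, ],
                      lab, indication_map, exclude_imputed_tto, ind_levels)
  })
  total <- summarize_stratum(filter_cases(db, assignments$case_id),
                             assignments, "Total", indication_map,
                             exclude_imputed_tto, ind_levels)
  pieces <- c(pieces, list(total))
  list(counts = dplyr::bind_rows(lapply(pieces, `[[`, "counts")),
       scalars = dplyr::bind_rows(lapply(pieces, `[[`, "scalars")))
}

#' Per-stratum time-to-onset summary
#'
#' Median, range and n over the reports whose onset delay is known (both
#' dates present; gaps built on imputed partial dates excluded by default).
#'
#' @param assignments [classify_regimen()] output.
#' @param exclude_imputed drop imputed-date gaps (default TRUE).
#' @return tibble `stratum`, `median`, `min`, `max`, `n` (regimen strata
#'   plus Total).
#' @export
tto_summary <- function(assignments, exclude_imputed = TRUE) {
  usable <- assignments[!is.na(assignments$time_to_onset_days) &
                          (!exclude_imputed | !assignments$tto_imputed), ]
  one <- function(tto, label) tibble::tibble(
    stratum = label,
    median = if (length(tto)) median(tto) else NA_real_,
    min = if (length(tto)) min(tto) else NA_real_,
    max = if (length(tto)) max(tto) else NA_real_,
    n = length(tto))
  dplyr::bind_rows(
    lapply(ANALYSIS_REGIMENS, function(r)
      one(usable$time_to_onset_days[usable$regimen == r], r)),
    one(usable$time_to_onset_days, "Total"))
}

#' Fraction of onsets within an early window
#'
#' Share of reports with known time to onset whose onset delay is at most
#' `window_days` (default 90: the first three months of therapy).
#'
#' @inheritParams tto_summary
#' @param window_days window length in days.
#' @return percentage to one decimal, or `NA` with attribute
#'   `reason = "no_tto"` when no report has a known onset delay.
#' @export
early_onset_fraction <- function(assignments, window_days = 90,
                                 exclude_imputed = TRUE) {
  tto <- assignments$time_to_onset_days[
    !is.na(assignments$time_to_onset_days) &
      (!exclude_imputed | !assignments$tto_imputed)]
  if (!length(tto)) return(structure(NA_real_, reason = "no_tto"))
  round_half_up(100 * mean(tto <= window_days), 1)
}

#' Annual report counts
#'
#' Counts reports by receipt year, zero-filled over the configured span.
#'
#' @param db an [icsr_db()].
#' @param year_range inclusive two-element year span; defaults to the
#'   observed range.
#' @return tibble `year`, `n`.
#' @export
annual_counts <- function(db, year_range = NULL) {
  yrs <- db$demo$receipt_year
  if (is.null(year_range)) {
    if (all(is.na(yrs))) return(tibble::tibble(year = integer(0), n = integer(0)))
    year_range <- range(yrs, na.rm = TRUE)
  }
  span <- seq(year_range[1], year_range[2])
  cnt <- table(factor(yrs[!is.na(yrs)], levels = span))
  tibble::tibble(year = span, n = as.integer(cnt))
}

#' Annual-trend bar chart
#'
#' @param counts output of [annual_counts()].
#' @return a ggplot object.
#' @export
plot_annual_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$year), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Receipt year", y = "Reports") +
    ggplot2::theme_minimal()
}

#' Table-2-shaped wide descriptive table
#'
#' Pivots the tidy summary into the reported layout: strata as columns,
#' variable blocks as row groups, cells formatted `n (pct)`.
#'
#' @param summary output of [summarize_cases()].
#' @return tibble with `block`, `category` and one column per stratum.
#' @export
descriptives_wide <- function(summary) {
  summary$counts |>
    dplyr::mutate(cell = sprintf("%d (%.1f)", .data$n, .data$pct)) |>
    dplyr::select("block", "category", "stratum", "cell") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "cell")
}
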