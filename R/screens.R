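MONOTHERAPY_REGIMENS <- c("ipilimumab", "nivolumab", "pembrolizumab",
                          "cemiplimab", "durvalumab", "atezolizumab",
                          "avelumab")
ANALYSIS_REGIMENS <- c(MONOTHERAPY_REGIMENS, "ipilimumab_nivolumab")

#' Regimen analysis strata over a database
#'
#' Builds the case-id sets for every analysis stratum: the seven
#' monotherapies, the ipilimumab+nivolumab combination, the drug classes
#' (Anti-PD-1, Anti-PD-L1) and the pooled Total over all checkpoint
#' inhibitors. A class stratum contains the reports whose suspect ICI set
#' is non-empty and lies wholly within the class's drugs, so a report
#' contributes once per class however many same-class suspects it carries,
#' and the cross-class combination belongs to neither class (its class Ns
#' therefore add up over member monotherapies when no report carries two
#' same-class suspects). Total covers any report with at least one ICI
#' suspect.
#'
#' @param db an [icsr_db()].
#' @param catalog ICI catalog.
#' @param assignments optional precomputed [classify_regimen()] output.
#' @return named list of case-id character vectors.
#' @export
regimen_strata <- function(db, catalog = ici_catalog(), assignments = NULL) {
  asg <- assignments %||% classify_regimen(db, catalog)
  class_drugs <- split(catalog$drug_name, catalog$drug_class)
  in_class <- function(drugs) {
    vapply(asg$ici_suspects, function(s)
      length(s) > 0 && all(s %in% drugs), logical(1))
  }
  strata <- c(
    setNames(lapply(MONOTHERAPY_REGIMENS, function(r)
      asg$case_id[asg$regimen == r]), MONOTHERAPY_REGIMENS),
    list(ipilimumab_nivolumab =
           asg$case_id[asg$regimen == "ipilimumab_nivolumab"],
         `Anti-PD-1` = asg$case_id[in_class(class_drugs[["PD1"]] %||% character(0))],
         `Anti-PD-L1` = asg$case_id[in_class(class_drugs[["PDL1"]] %||% character(0))],
         Total = asg$case_id[lengths(asg$ici_suspects) > 0]))
  strata
}

#' Regimen-level disproportionality screen
#'
#' One signal evaluation per analysis stratum against the full-database
#' background: the event cases are the preferred-term query hits, the
#' exposure is the stratum's case set, and every other report in the
#' database forms the comparator cells. Strata with no event reports give
#' an N = 0 result with all flags false.
#'
#' @param db an [icsr_db()] (the full background database).
#' @param query a [term_query()].
#' @param criteria a [signal_criteria()].
#' @param catalog ICI catalog.
#' @param formula_variant `"printed"` or `"canonical"` interval formulas.
#' @param strata optional named list of case-id sets; defaults to
#'   [regimen_strata()].
#' @return named list of `signal_result` objects, one per stratum.
#' @export
regimen_screen <- function(db, query = term_query(),
                           criteria = signal_criteria(),
                           catalog = ici_catalog(),
                           formula_variant = "printed", strata = NULL) {
  strata <- strata %||% regimen_strata(db, catalog)
  event_ids <- flag_event_cases(db, query)$case_ids
  lapply(setNames(names(strata), names(strata)), function(lab) {
    tab <- build_table(db, strata[[lab]], event_ids,
                       background = "full_database",
                       exposure_label = lab, event_label = query$query_id)
    evaluate_signal(signal_statistics(tab, formula_variant), criteria)
  })
}

#' Head-to-head comparison of two regimens
#'
#' Restricted-background design: the 2x2 table opposes the exposure
#' regimen's reports to the comparator regimen's reports only, so the
#' reporting odds ratio contrasts the two regimens directly (e.g. the
#' ipilimumab+nivolumab combination against nivolumab monotherapy). The
#' full statistic set is computed but the reported contract is the ROR with
#' its interval.
#'
#' @inheritParams regimen_screen
#' @param exposure_regimen,comparator_regimen stratum names as in
#'   [regimen_strata()].
#' @return a `signal_result`.
#' @export
head_to_head <- function(db, exposure_regimen = "ipilimumab_nivolumab",
                         comparator_regimen = "nivolumab",
                         query = term_query(), criteria = signal_criteria(),
                         catalog = ici_catalog(),
                         formula_variant = "printed") {
  strata <- regimen_strata(db, catalog)
  event_ids <- flag_event_cases(db, query)$case_ids
  tab <- build_table(db, strata[[exposure_regimen]], event_ids,
                     background = "comparator_restricted",
                     comparator = strata[[comparator_regimen]],
                     exposure_label = paste0(exposure_regimen, " vs ",
                                             comparator_regimen),
                     event_label = query$query_id)
  evaluate_signal(signal_statistics(tab, formula_variant), criteria)
}

#' Preferred-term-level disproportionality screen
#'
#' For every (preferred term, regimen stratum) pair with at least `min_n`
#' co-occurring reports, evaluates a signal with the event defined by that
#' single term against the full-database background. A report carrying k
#' matching terms contributes to k term rows (once per row), so the
#' per-regimen Total — defined as the sum of its term-row Ns — can differ
#' from the stratum's distinct-report count.
#'
#' @inheritParams regimen_screen
#' @param min_n minimum co-occurrence count for a row to be reported.
#' @return list with `results` (tibble: `pt`, `regimen`, statistics, flags)
#'   and `totals` (tibble: `regimen`, `total_n` = sum of term-row Ns).
#' @export
pt_level_screen <- function(db, query = term_query(),
                            criteria = signal_criteria(),
                            catalog = ici_catalog(), min_n = 2,
                            formula_variant = "printed", strata = NULL) {
  strata <- strata %||% regimen_strata(db, catalog)
  strata <- strata[intersect(names(strata), ANALYSIS_REGIMENS)]
  pt_index <- flag_event_cases(db, query)$pt_index
  rows <- list()
  for (pt in query$terms) {
    pt_ids <- pt_index$case_id[pt_index$pt == pt]
    for (lab in names(strata)) {
      a <- length(intersect(strata[[lab]], pt_ids))
      if (a < min_n) next
      tab <- build_table(db, strata[[lab]], pt_ids,
                         background = "full_database",
                         exposure_label = lab, event_label = pt)
      res <- evaluate_signal(signal_statistics(tab, formula_variant), criteria)
      row <- tidy_signal_results(res)
      row$pt <- pt
      row$regimen <- lab
      rows[[length(rows) + 1]] <- row
    }
  }
  results <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pt = character(0), regimen = character(0), n = integer(0))
  totals <- results |>
    dplyr::group_by(regimen = factor(.data$regimen, levels = names(strata))) |>
    dplyr::summarise(total_n = sum(.data$n), .groups = "drop") |>
    tidyr::complete(.data$regimen, fill = list(total_n = 0L)) |>
    dplyr::mutate(regimen = as.character(.data$regimen))
  list(results = results, totals = totals)
}
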