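#' Preferred-term query for event-case retrieval
#'
#' A flat preferred-term set standing in for a standardized MedDRA query
#' (the noninfectious-meningitis query, code 20000134, in the shipped
#' default). MedDRA itself is licensed, so the term set is an editable
#' surrogate reverse-engineered from the preferred terms reported for this
#' event; scope is configurable.
#'
#' @param terms character vector of preferred terms (non-empty).
#' @param query_id identifier carried through logs and outputs.
#' @param match_mode `"case_insensitive"` (default) or `"exact"`.
#' @return object of class `term_query`.
#' @export
term_query <- function(terms = NULL, query_id = "SMQ-20000134-surrogate",
                       match_mode = c("case_insensitive", "exact")) {
  mode_given <- !missing(match_mode)
  match_mode <- match.arg(match_mode)
  if (is.null(terms)) {
    spec <- yaml::read_yaml(pv_extdata("meningitis_terms.yaml"))
    terms <- unlist(spec$terms)
    query_id <- spec$query_id %||% query_id
    if (!mode_given) match_mode <- spec$match_mode %||% match_mode
  }
  terms <- unique(as.character(terms))
  stopifnot(length(terms) > 0)
  structure(list(query_id = query_id, terms = terms, match_mode = match_mode),
            class = "term_query")
}

#' Read a term query from a YAML file
#' @param path YAML file with `query_id`, `terms`, `match_mode` keys.
#' @export
read_term_query <- function(path) {
  spec <- yaml::read_yaml(path)
  term_query(unlist(spec$terms), spec$query_id %||% "custom-query",
             spec$match_mode %||% "case_insensitive")
}

#' Flag event cases by preferred-term query
#'
#' A report is flagged when at least one of its reactions matches a query
#' term under the query's match mode. The per-term match index is returned
#' alongside: a report carrying several matching terms appears under each,
#' so index totals may exceed the number of distinct flagged reports (as in
#' PT-level signal tables).
#'
#' @param db an [icsr_db()].
#' @param query a [term_query()].
#' @return list with `case_ids` (distinct flagged ids), `pt_index` (tibble
#'   `pt`, `case_id`, one row per match) and `n_flagged`.
#' @export
flag_event_cases <- function(db, query = term_query()) {
  pt_obs <- db$reactions$pt
  if (query$match_mode == "case_insensitive") {
    hit <- match(tolower(pt_obs), tolower(query$terms))
  } else {
    hit <- match(pt_obs, query$terms)
  }
  idx <- tibble::tibble(pt = query$terms[hit[!is.na(hit)]],
                        case_id = db$reactions$case_id[!is.na(hit)])
  idx <- dplyr::distinct(idx)
  list(case_ids = unique(idx$case_id), pt_index = idx,
       n_flagged = length(unique(idx$case_id)))
}

DEDUP_FIELDS <- c("event_date", "age_years", "sex", "reporter_country")

dedup_key_matrix <- function(demo) {
  cbind(as.character(demo$event_date),
        as.character(demo$age_years),
        ifelse(demo$sex == "unknown", NA_character_, demo$sex),
        demo$reporter_country)
}

#' Remove near-duplicate reports
#'
#' Two reports are duplicates when they agree on at least `min_match` of the
#' four linkage fields: event date, age, sex, reporter country. A field with
#' a missing value on either side never counts as agreement (shared
#' missingness is not identity). Reports are swept in `(receipt_year,
#' case_id)` order and a report is dropped when it matches any already
#' retained report, so the first of each duplicate cluster survives and the
#' operation is idempotent.
#'
#' @param db an [icsr_db()].
#' @param min_match minimum number of agreeing fields (default 3 of 4).
#' @return list with `db` (retained reports), `removed_pairs` (tibble
#'   `kept_id`, `dropped_id`, `n_fields_matched`) and `n_removed`.
#' @export
deduplicate <- function(db, min_match = 3) {
  demo <- db$demo
  # radix order = C-locale byte order, deterministic across platforms
  ord <- order(demo$receipt_year, demo$case_id, na.last = TRUE,
               method = "radix")
  demo <- demo[ord, ]
  keys <- dedup_key_matrix(demo)
  n <- nrow(demo)
  keep <- logical(n)
  kept_rows <- integer(0)
  pairs <- list()
  for (i in seq_len(n)) {
    dup_against <- NA_integer_
    if (length(kept_rows)) {
      # agreement count vs each retained report; missing never matches
      agree <- rowSums(
        keys[kept_rows, , drop = FALSE] ==
          matrix(keys[i, ], nrow = length(kept_rows), ncol = 4, byrow = TRUE),
        na.rm = TRUE)
      hit <- which(agree >= min_match)
      if (length(hit)) dup_against <- kept_rows[hit[[1]]]
    }
    if (is.na(dup_against)) {
      keep[i] <- TRUE
      kept_rows <- c(kept_rows, i)
    } else {
      m <- sum(keys[dup_against, ] == keys[i, ], na.rm = TRUE)
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        kept_id = demo$case_id[dup_against],
        dropped_id = demo$case_id[i],
        n_fields_matched = m)
    }
  }
  removed <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(kept_id = character(0), dropped_id = character(0),
                   n_fields_matched = integer(0))
  list(db = filter_cases(db, demo$case_id[keep]),
       removed_pairs = removed, n_removed = sum(!keep))
}

#' Temporal plausibility filter
#'
#' Removes reports whose earliest suspect checkpoint-inhibitor start date is
#' strictly after the reaction onset date: the drug cannot have caused an
#' event that preceded it. Day-0 onsets (start equal to onset) are
#' plausible and retained. Reports where either date is missing cannot be
#' shown implausible and are retained.
#'
#' @param db an [icsr_db()] of event-flagged reports.
#' @param catalog ICI catalog defining which suspects count.
#' @return list with `db` (retained), `removed_ids`, `n_removed`.
#' @export
temporal_filter <- function(db, catalog = ici_catalog()) {
  ici_starts <- db$drugs |>
    dplyr::filter(.data$role == "suspect",
                  .data$drug_name %in% catalog$drug_name,
                  !is.na(.data$start_date)) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      # suppress the spurious empty-prototype warning dplyr emits when the
      # filtered frame has no rows
      first_start = suppressWarnings(min(.data$start_date)),
      .groups = "drop")
  joined <- dplyr::left_join(db$demo, ici_starts, by = "case_id")
  implausible <- !is.na(joined$event_date) & !is.na(joined$first_start) &
    joined$first_start > joined$event_date
  list(db = filter_cases(db, joined$case_id[!implausible]),
       removed_ids = joined$case_id[implausible],
       n_removed = sum(implausible))
}

#' Classify each report's checkpoint-inhibitor regimen
#'
#' The suspect-drug set intersected with the ICI catalog determines the
#' regimen: exactly one ICI gives that monotherapy; exactly
#' {ipilimumab, nivolumab} gives the combination stratum; any other
#' multi-ICI set is `other_ici_combination` (counted but excluded from the
#' per-regimen analysis strata); no ICI suspect gives `non_ici`. Time to
#' onset is the whole-day gap from the earliest suspect ICI start date to
#' the reaction onset date; gaps involving an imputed partial date are
#' flagged so summaries can exclude them.
#'
#' @param db an [icsr_db()].
#' @param catalog ICI catalog.
#' @return tibble: `case_id`, `regimen`, `ici_suspects` (list column),
#'   `time_to_onset_days`, `tto_imputed`.
#' @export
classify_regimen <- function(db, catalog = ici_catalog()) {
  ici <- db$drugs |>
    dplyr::filter(.data$role == "suspect",
                  .data$drug_name %in% catalog$drug_name)
  per_case <- ici |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      ici_suspects = list(sort(unique(.data$drug_name))),
      first_start = if (all(is.na(.data$start_date))) as.Date(NA) else
        min(.data$start_date, na.rm = TRUE),
      start_imputed = {
        ok <- !is.na(.data$start_date)
        if (!any(ok)) NA else {
          first <- min(.data$start_date[ok])
          any(date_is_imputed(.data$start_date_prec[ok & .data$start_date == first]))
        }
      },
      .groups = "drop")
  out <- dplyr::left_join(
    db$demo[, c("case_id", "event_date", "event_date_prec")], per_case,
    by = "case_id")
  out$ici_suspects[vapply(out$ici_suspects, is.null, logical(1))] <-
    list(character(0))
  out$regimen <- vapply(out$ici_suspects, function(s) {
    if (length(s) == 0) "non_ici"
    else if (length(s) == 1) s
    else if (setequal(s, c("ipilimumab", "nivolumab"))) "ipilimumab_nivolumab"
    else "other_ici_combination"
  }, character(1))
  tto <- as.integer(floor(as.numeric(out$event_date - out$first_start)))
  tto[!is.na(tto) & tto < 0] <- NA_integer_
  out$time_to_onset_days <- tto
  out$tto_imputed <- !is.na(tto) &
    (date_is_imputed(out$event_date_prec) | out$start_imputed %in% TRUE)
  out[, c("case_id", "regimen", "ici_suspects", "time_to_onset_days",
          "tto_imputed")]
}

#' Run the full case-selection stage
#'
#' Sequences the selection exactly as the analysis defines it: restrict to
#' reports with a suspect checkpoint inhibitor, flag event cases by
#' preferred-term query, remove near-duplicates, apply the temporal
#' plausibility filter, then classify regimens. Per-stage counts are
#' returned so the count algebra (input = retained + removed) can be
#' audited at every step.
#'
#' @param db an [icsr_db()].
#' @param query a [term_query()].
#' @param catalog ICI catalog.
#' @return list with `db` (selected cases), `assignments` (regimen tibble,
#'   analysis strata only), `assignments_all` (including excluded regimens),
#'   `pt_index`, `stage_counts`, `removed_pairs`.
#' @export
select_cases <- function(db, query = term_query(), catalog = ici_catalog()) {
  counts <- list(input = n_cases(db))
  ici_ids <- unique(db$drugs$case_id[db$drugs$role == "suspect" &
                                       db$drugs$drug_name %in% catalog$drug_name])
  db_ici <- filter_cases(db, ici_ids)
  counts$ici_suspect <- n_cases(db_ici)

  flags <- flag_event_cases(db_ici, query)
  db_event <- filter_cases(db_ici, flags$case_ids)
  counts$event_flagged <- n_cases(db_event)

  dd <- deduplicate(db_event)
  counts$after_dedup <- n_cases(dd$db)
  counts$duplicates_removed <- dd$n_removed

  tf <- temporal_filter(dd$db, catalog)
  counts$after_temporal <- n_cases(tf$db)
  counts$temporal_removed <- tf$n_removed

  assignments <- classify_regimen(tf$db, catalog)
  excluded <- assignments$regimen %in% c("other_ici_combination", "non_ici")
  counts$excluded_regimen <- sum(excluded)
  counts$analyzed <- sum(!excluded)

  pt_index <- dplyr::filter(flags$pt_index,
                            .data$case_id %in% tf$db$demo$case_id)
  list(db = tf$db,
       assignments = assignments[!excluded, ],
       assignments_all = assignments,
       pt_index = pt_index,
       stage_counts = counts,
       removed_pairs = dd$removed_pairs)
}
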