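#' @importFrom rlang .data
#' @importFrom stats median rbinom rlnorm runif setNames
#' @importFrom utils head
NULL

SEX_LEVELS <- c("male", "female", "unknown")
REGION_LEVELS <- c("Africa", "Asia", "Europe", "NorthAmerica", "Oceania",
                   "SouthAmerica", "unknown")
REPORTER_LEVELS <- c("healthcare_professional", "consumer")
OUTCOME_LEVELS <- c("death", "life_threatening", "hospitalization",
                    "disability", "other_serious", "non_serious")
DRUG_CLASS_LEVELS <- c("CTLA4", "PD1", "PDL1", "other")
REGIMEN_LEVELS <- c("ipilimumab", "nivolumab", "pembrolizumab", "cemiplimab",
                    "durvalumab", "atezolizumab", "avelumab",
                    "ipilimumab_nivolumab", "other_ici_combination", "non_ici")

#' Individual case safety report database
#'
#' An `icsr_db` mirrors the relational layout of spontaneous-report archives:
#' one demographics row per case, plus drug, reaction and outcome tables
#' linked by `case_id`. All pipeline stages operate on this container.
#'
#' @param demo tibble with one row per case: `case_id`, `event_date` (Date),
#'   `event_date_prec`, `age_years`, `sex`, `reporter_country`, `region`,
#'   `reporter_type`, `indication`, `receipt_year`. `region` is derived from
#'   `reporter_country` when absent.
#' @param drugs tibble: `case_id`, `drug_name` (normalized lowercase),
#'   `role` (`suspect`/`concomitant`), `drug_class`, `start_date`,
#'   `start_date_prec`.
#' @param reactions tibble: `case_id`, `pt` (preferred term).
#' @param outcomes tibble: `case_id`, `outcome`.
#' @return an object of class `icsr_db`.
#' @export
icsr_db <- function(demo, drugs = NULL, reactions = NULL, outcomes = NULL) {
  demo <- tibble::as_tibble(demo)
  stopifnot(!anyDuplicated(demo$case_id))
  if (!"region" %in% names(demo) || all(is.na(demo$region))) {
    demo$region <- map_country_region(demo$reporter_country)
  }
  if (!"event_date_prec" %in% names(demo)) demo$event_date_prec <- NA_character_
  demo$sex[is.na(demo$sex) | !demo$sex %in% SEX_LEVELS] <- "unknown"
  empty <- function(cols) tibble::as_tibble(setNames(
    lapply(cols, function(x) character(0)), cols))
  drugs <- if (is.null(drugs)) {
    tibble::tibble(case_id = character(0), drug_name = character(0),
                   role = character(0), drug_class = character(0),
                   start_date = as.Date(character(0)),
                   start_date_prec = character(0))
  } else tibble::as_tibble(drugs)
  if (!"start_date_prec" %in% names(drugs)) drugs$start_date_prec <- NA_character_
  reactions <- if (is.null(reactions)) empty(c("case_id", "pt")) else
    tibble::as_tibble(reactions)
  outcomes <- if (is.null(outcomes)) empty(c("case_id", "outcome")) else
    tibble::as_tibble(outcomes)
  bad_age <- !is.na(demo$age_years) & (demo$age_years < 0 | !is.finite(demo$age_years))
  demo$age_years[bad_age] <- NA_real_
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes),
            class = "icsr_db")
}

#' @export
print.icsr_db <- function(x, ...) {
  cat(sprintf(
    "<icsr_db> %d cases, %d drug rows, %d reaction rows, %d outcome rows\n",
    nrow(x$demo), nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  invisible(x)
}

#' Number of cases in an icsr_db
#' @param db an `icsr_db`.
#' @export
n_cases <- function(db) nrow(db$demo)

#' Restrict a database to a set of case ids
#' @param db an `icsr_db`.
#' @param case_ids character vector of ids to keep.
#' @return the filtered `icsr_db` (demographics order preserved).
#' @export
filter_cases <- function(db, case_ids) {
  icsr_db(
    demo = dplyr::filter(db$demo, .data$case_id %in% case_ids),
    drugs = dplyr::filter(db$drugs, .data$case_id %in% case_ids),
    reactions = dplyr::filter(db$reactions, .data$case_id %in% case_ids),
    outcomes = dplyr::filter(db$outcomes, .data$case_id %in% case_ids)
  )
}

pv_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pvsignal")
  if (!nzchar(path)) stop("reference file not found: ", file, call. = FALSE)
  path
}

#' Checkpoint-inhibitor catalog
#'
#' The active moieties treated as immune checkpoint inhibitors with their
#' target class (`CTLA4`, `PD1`, `PDL1`). Shipped as an editable CSV.
#'
#' @param path optional path to a custom catalog CSV (`drug_name`,
#'   `drug_class`).
#' @return tibble with columns `drug_name`, `drug_class`.
#' @export
ici_catalog <- function(path = NULL) {
  readr::read_csv(path %||% pv_extdata("ici_catalog.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @keywords internal
drug_synonyms <- function(path = NULL) {
  readr::read_csv(path %||% pv_extdata("drug_synonyms.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @keywords internal
country_region_table <- function(path = NULL) {
  readr::read_csv(path %||% pv_extdata("country_regions.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Normalize drug names to active moieties
#'
#' Lowercases, trims, and maps brand names / sponsor codes to active
#' moieties via the shipped synonym table, so that e.g. `"OPDIVO"` and
#' `"nivolumab"` pool into one exposure.
#'
#' @param x character vector of verbatim drug names.
#' @param synonyms optional custom synonym table (`synonym`, `active_moiety`).
#' @export
normalize_drug_name <- function(x, synonyms = NULL) {
  syn <- synonyms %||% drug_synonyms()
  x <- tolower(trimws(as.character(x)))
  hit <- match(x, syn$synonym)
  x[!is.na(hit)] <- syn$active_moiety[hit[!is.na(hit)]]
  x
}

#' Assign checkpoint-inhibitor class to drug names
#'
#' @param drug_name normalized drug names.
#' @param catalog ICI catalog as from [ici_catalog()].
#' @return `"CTLA4"`, `"PD1"`, `"PDL1"` or `"other"`.
#' @export
classify_drug <- function(drug_name, catalog = ici_catalog()) {
  hit <- match(drug_name, catalog$drug_name)
  ifelse(is.na(hit), "other", catalog$drug_class[hit])
}

#' Map ISO country codes to continents
#'
#' @param country character vector of ISO-3166 alpha-2 codes.
#' @return region labels; unmapped or missing countries give `"unknown"`.
#' @export
map_country_region <- function(country) {
  tab <- country_region_table()
  hit <- match(toupper(trimws(country)), tab$country)
  out <- ifelse(is.na(hit), "unknown", tab$region[hit])
  out[is.na(country)] <- "unknown"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
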