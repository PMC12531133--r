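FILE_ROLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER")

locate_role_files <- function(paths, dialect) {
  if (length(paths) == 1 && dir.exists(paths)) {
    files <- list.files(paths, full.names = TRUE)
    found <- setNames(vector("list", length(FILE_ROLES)), FILE_ROLES)
    for (role in FILE_ROLES) {
      pattern <- paste0("^", tolower(role))
      hit <- files[grepl(pattern, tolower(basename(files)))]
      found[[role]] <- if (length(hit)) hit[[1]] else NA_character_
    }
    unlist(found)
  } else {
    if (is.null(names(paths)) || !all(FILE_ROLES %in% toupper(names(paths))))
      stop("supply a directory or a named vector with entries ",
           paste(FILE_ROLES, collapse = ", "), call. = FALSE)
    setNames(paths[match(FILE_ROLES, toupper(names(paths)))], FILE_ROLES)
  }
}

read_role <- function(path, dialect) {
  if (dialect == "faers_ascii") {
    readr::read_delim(path, delim = "$", col_types = readr::cols(
      .default = readr::col_character()), na = c("", "NA"),
      progress = FALSE, show_col_types = FALSE)
  } else {
    readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), na = c("", "NA"),
      progress = FALSE, show_col_types = FALSE)
  }
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))
int_or_na <- function(x) suppressWarnings(as.integer(x))

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  out
}

#' Read an ICSR database from disk
#'
#' Loads the five report tables (demographics, drugs, reactions, outcomes,
#' therapy dates) linked by `case_id`. Two dialects are supported:
#' `faers_ascii` (`'$'`-delimited text with one header row, quarterly-archive
#' style, file names starting with `DEMO`/`DRUG`/`REAC`/`OUTC`/`THER`) and
#' `csv` (RFC-4180, same column vocabulary, lowercase file names).
#'
#' The loader is total over rows: unparseable ages, dates and sex codes
#' become missing values, never errors. Drug or reaction rows whose
#' `case_id` has no demographics row are attached to a skeleton report with
#' a warning. A load summary (rows read per table, missing-field counts,
#' skeleton count) is attached as the `"load_summary"` attribute; see
#' [load_summary()].
#'
#' @param paths a directory containing the five files, or a named character
#'   vector with entries `DEMO`, `DRUG`, `REAC`, `OUTC`, `THER`.
#' @param dialect `"faers_ascii"` or `"csv"`.
#' @param catalog ICI catalog used to derive `drug_class`.
#' @param synonyms optional drug-name synonym table.
#' @return an [icsr_db()].
#' @export
read_icsr_database <- function(paths, dialect = c("faers_ascii", "csv"),
                               catalog = ici_catalog(), synonyms = NULL) {
  dialect <- match.arg(dialect)
  files <- locate_role_files(paths, dialect)
  missing_files <- FILE_ROLES[is.na(files) | !file.exists(files)]
  if (length(missing_files))
    stop("missing mandatory file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  raw <- lapply(setNames(files, FILE_ROLES), read_role, dialect = dialect)

  ed <- parse_faers_date(raw$DEMO$event_dt)
  demo <- tibble::tibble(
    case_id = as.character(raw$DEMO$case_id),
    event_date = ed$date, event_date_prec = ed$prec,
    age_years = num_or_na(raw$DEMO$age_yrs),
    sex = parse_sex(raw$DEMO$sex),
    reporter_country = dplyr::na_if(toupper(trimws(
      as.character(raw$DEMO$reporter_country %||% NA_character_))), ""),
    reporter_type = ifelse(
      tolower(as.character(raw$DEMO$reporter_type)) %in%
        c("consumer", "cn", "cs"), "consumer", "healthcare_professional"),
    indication = as.character(raw$DEMO$indication),
    receipt_year = int_or_na(raw$DEMO$receipt_year)
  )

  sd <- parse_faers_date(raw$THER$start_dt)
  ther <- tibble::tibble(case_id = as.character(raw$THER$case_id),
                         drug_name = normalize_drug_name(raw$THER$drug_name,
                                                         synonyms),
                         start_date = sd$date, start_date_prec = sd$prec)
  drugs <- tibble::tibble(
    case_id = as.character(raw$DRUG$case_id),
    drug_name = normalize_drug_name(raw$DRUG$drug_name, synonyms),
    role = ifelse(tolower(as.character(raw$DRUG$role)) %in%
                    c("c", "concomitant", "i", "interacting"),
                  "concomitant", "suspect")
  )
  drugs$drug_class <- classify_drug(drugs$drug_name, catalog)
  drugs <- dplyr::left_join(
    drugs,
    dplyr::distinct(ther, .data$case_id, .data$drug_name, .keep_all = TRUE),
    by = c("case_id", "drug_name"))

  reactions <- tibble::tibble(case_id = as.character(raw$REAC$case_id),
                              pt = as.character(raw$REAC$pt))
  outcomes <- tibble::tibble(
    case_id = as.character(raw$OUTC$case_id),
    outcome = ifelse(as.character(raw$OUTC$outcome) %in% OUTCOME_LEVELS,
                     as.character(raw$OUTC$outcome), "other_serious"))

  orphan <- setdiff(c(drugs$case_id, reactions$case_id, outcomes$case_id),
                    demo$case_id)
  if (length(orphan)) {
    warning(length(orphan),
            " case id(s) without demographics row; skeleton reports created",
            call. = FALSE)
    demo <- dplyr::bind_rows(demo, tibble::tibble(
      case_id = orphan, event_date = as.Date(NA),
      event_date_prec = NA_character_, age_years = NA_real_, sex = "unknown",
      reporter_country = NA_character_, reporter_type = "healthcare_professional",
      indication = NA_character_, receipt_year = NA_integer_))
  }

  db <- icsr_db(demo, drugs, reactions, outcomes)
  attr(db, "load_summary") <- list(
    rows_read = vapply(raw, nrow, integer(1)),
    n_cases = nrow(demo),
    n_skeleton = length(orphan),
    missing_fields = c(
      age = sum(is.na(demo$age_years)),
      sex = sum(parse_sex(raw$DEMO$sex) == "unknown"),
      event_date = sum(is.na(ed$date)),
      country = sum(is.na(demo$reporter_country))
    ))
  db
}

#' Retrieve the load summary of a freshly read database
#' @param db an `icsr_db` returned by [read_icsr_database()].
#' @export
load_summary <- function(db) attr(db, "load_summary")

#' Write an ICSR database to disk
#'
#' Serializes the five linked tables in the requested dialect. Missing
#' values are written as the dialect's null token (empty field) and partial
#' dates at their recorded precision, so [read_icsr_database()] round-trips
#' the database field-for-field.
#'
#' @param db an [icsr_db()].
#' @param dir output directory (created if needed).
#' @inheritParams read_icsr_database
#' @return invisibly, the named vector of files written.
#' @export
write_icsr_database <- function(db, dir, dialect = c("faers_ascii", "csv")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  ext <- if (dialect == "faers_ascii") ".txt" else ".csv"
  base <- if (dialect == "faers_ascii") FILE_ROLES else tolower(FILE_ROLES)
  files <- setNames(file.path(dir, paste0(base, ext)), FILE_ROLES)

  demo_out <- tibble::tibble(
    case_id = db$demo$case_id,
    event_dt = format_faers_date(db$demo$event_date, db$demo$event_date_prec),
    age_yrs = ifelse(is.na(db$demo$age_years), "",
                     format(db$demo$age_years, trim = TRUE, scientific = FALSE)),
    sex = ifelse(db$demo$sex == "unknown", "", db$demo$sex),
    reporter_country = db$demo$reporter_country,
    reporter_type = db$demo$reporter_type,
    indication = db$demo$indication,
    receipt_year = db$demo$receipt_year)
  drug_out <- tibble::tibble(case_id = db$drugs$case_id,
                             drug_name = db$drugs$drug_name,
                             role = db$drugs$role)
  ther_rows <- !is.na(db$drugs$start_date)
  ther_out <- tibble::tibble(
    case_id = db$drugs$case_id[ther_rows],
    drug_name = db$drugs$drug_name[ther_rows],
    start_dt = format_faers_date(db$drugs$start_date[ther_rows],
                                 db$drugs$start_date_prec[ther_rows]))
  reac_out <- db$reactions
  outc_out <- db$outcomes

  tables <- list(DEMO = demo_out, DRUG = drug_out, REAC = reac_out,
                 OUTC = outc_out, THER = ther_out)
  for (role in FILE_ROLES) {
    if (dialect == "faers_ascii") {
      readr::write_delim(tables[[role]], files[[role]], delim = "$", na = "")
    } else {
      readr::write_csv(tables[[role]], files[[role]], na = "")
    }
  }
  invisible(files)
}
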