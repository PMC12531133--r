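default_drug_catalog <- function() {
  tibble::tibble(
    drug_name = c("ipilimumab", "nivolumab", "pembrolizumab", "cemiplimab",
                  "durvalumab", "atezolizumab", "avelumab",
                  "carboplatin", "paclitaxel", "ondansetron", "levothyroxine"),
    drug_class = classify_drug(c("ipilimumab", "nivolumab", "pembrolizumab",
                                 "cemiplimab", "durvalumab", "atezolizumab",
                                 "avelumab", "carboplatin", "paclitaxel",
                                 "ondansetron", "levothyroxine")),
    p_exposure = c(0.015, 0.05, 0.06, 0.003, 0.01, 0.03, 0.003,
                   0.25, 0.20, 0.30, 0.35))
}

default_event_catalog <- function() {
  tibble::tibble(
    term = c("Meningitis", "Meningitis aseptic", "Meningitis noninfective",
             "Meningeal disorder", "Meningism", "Arachnoiditis",
             "Meningoradiculitis", "Pachymeningitis",
             "Headache", "Pyrexia", "Nausea", "Fatigue", "Rash",
             "Diarrhoea", "Drug ineffective"),
    p_event = c(0.004, 0.003, 0.0008, 0.0008, 0.001, 0.0005, 0.0003, 0.0005,
                0.06, 0.05, 0.06, 0.05, 0.04, 0.04, 0.03))
}

default_tto_days <- function() {
  list(ipilimumab = c(36.5, 1.2), nivolumab = c(81, 1.5),
       pembrolizumab = c(43, 1.4), cemiplimab = c(52, 0.8),
       durvalumab = c(7.5, 1.0), atezolizumab = c(10, 1.5),
       avelumab = c(14, 0.8), ipilimumab_nivolumab = c(32, 1.3),
       default = c(34, 1.4))
}

#' Configuration for the synthetic report generator
#'
#' Defines the statistical structure of a generated spontaneous-report
#' database: a drug catalog with marginal exposure probabilities, an event
#' catalog with baseline reporting probabilities, planted drug–event
#' association strengths expressed as true reporting odds ratios, a
#' combination-therapy rate, near-duplicate injection, per-field
#' missingness, regimen-specific log-normal onset-delay distributions,
#' outcome category probabilities and the receipt-year span.
#'
#' @param n_reports number of base reports (before duplicate injection).
#' @param drug_catalog tibble `drug_name`, `drug_class`, `p_exposure`.
#' @param event_catalog tibble `term`, `p_event` (baseline probability).
#' @param planted_or nested named list `exposure -> term -> odds ratio`;
#'   an exposure key is a drug name or `"ipilimumab_nivolumab"`. Omitted
#'   pairs default to 1 (no association).
#' @param combo_rate probability a report carries both ipilimumab and
#'   nivolumab as suspects.
#' @param duplicate_rate fraction of reports cloned into near-duplicates.
#' @param duplicate_perturb probability a clone has one linkage field
#'   perturbed; see [inject_duplicates()].
#' @param missingness named list of per-field missing probabilities
#'   (`age`, `sex`, `country`, `event_date`, `start_date`, `indication`).
#' @param tto_days named list `regimen -> c(median_days, sdlog)` for the
#'   log-normal onset delay; a `default` entry covers unlisted regimens.
#' @param outcome_probs named probability vector over outcome categories.
#' @param year_range inclusive receipt-year span.
#' @param seed integer RNG seed; the generated database is a deterministic
#'   function of the config.
#' @return validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_reports = 5000,
                             drug_catalog = default_drug_catalog(),
                             event_catalog = default_event_catalog(),
                             planted_or = list(),
                             combo_rate = 0.04,
                             duplicate_rate = 0.02,
                             duplicate_perturb = 0.5,
                             missingness = list(age = 0.2, sex = 0.12,
                                                country = 0.05,
                                                event_date = 0.3,
                                                start_date = 0.35,
                                                indication = 0.15),
                             tto_days = default_tto_days(),
                             outcome_probs = c(non_serious = 0.02,
                                               hospitalization = 0.458,
                                               disability = 0.022,
                                               life_threatening = 0.064,
                                               death = 0.114,
                                               other_serious = 0.322),
                             year_range = c(2011, 2024),
                             seed = 1) {
  stopifnot(n_reports >= 1,
            all(drug_catalog$p_exposure >= 0 & drug_catalog$p_exposure <= 1),
            all(event_catalog$p_event >= 0 & event_catalog$p_event <= 1),
            combo_rate >= 0, combo_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            all(unlist(missingness) >= 0 & unlist(missingness) <= 1))
  for (key in names(planted_or)) {
    ors <- planted_or[[key]]
    if (any(unlist(ors) <= 0)) stop("planted odds ratios must be > 0",
                                    call. = FALSE)
    absent <- setdiff(names(ors), event_catalog$term)
    if (length(absent))
      stop("planted event term(s) absent from event catalog: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog, event_catalog = event_catalog,
                 planted_or = planted_or, combo_rate = combo_rate,
                 duplicate_rate = duplicate_rate,
                 duplicate_perturb = duplicate_perturb,
                 missingness = missingness,
                 tto_days = tto_days,
                 outcome_probs = outcome_probs / sum(outcome_probs),
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a generator config from YAML
#' @param path YAML file mirroring [synthetic_config()] field names.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_reports", "combo_rate", "duplicate_rate", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$drug_catalog))
    args$drug_catalog <- dplyr::bind_rows(y$drug_catalog)
  if (!is.null(y$event_catalog))
    args$event_catalog <- dplyr::bind_rows(y$event_catalog)
  if (!is.null(y$planted_or)) args$planted_or <- y$planted_or
  if (!is.null(y$missingness)) args$missingness <- y$missingness
  if (!is.null(y$tto_days))
    args$tto_days <- lapply(y$tto_days, unlist)
  if (!is.null(y$outcome_probs)) args$outcome_probs <- unlist(y$outcome_probs)
  if (!is.null(y$year_range)) args$year_range <- unlist(y$year_range)
  do.call(synthetic_config, args)
}

exposure_indicator <- function(expo, key) {
  if (key == "ipilimumab_nivolumab") {
    if (!all(c("ipilimumab", "nivolumab") %in% colnames(expo)))
      stop("combination exposure requires ipilimumab and nivolumab in catalog",
           call. = FALSE)
    expo[, "ipilimumab"] & expo[, "nivolumab"]
  } else {
    if (!key %in% colnames(expo))
      stop("planted exposure not in drug catalog: ", key, call. = FALSE)
    expo[, key] == 1
  }
}

SYN_COUNTRIES <- c(JP = 0.25, US = 0.20, DE = 0.08, FR = 0.08, GB = 0.06,
                   CN = 0.05, KR = 0.04, IT = 0.04, ES = 0.03, CA = 0.03,
                   AU = 0.02, BR = 0.02, NL = 0.02, SE = 0.02, CH = 0.02,
                   ZA = 0.01, IN = 0.03)

#' Generate a synthetic ICSR database with known ground truth
#'
#' Draws `n_reports` independent reports: drug exposures from the catalog's
#' marginal probabilities (with the ipilimumab+nivolumab combination forced
#' at `combo_rate`), reaction terms from baseline probabilities tilted per
#' exposed report so the population odds ratio of each planted pair equals
#' its configured value (odds multiplied by the planted OR), regimen-specific
#' log-normal onset delays realized as therapy-start to event-date gaps,
#' demographics with configured missingness, and one outcome category per
#' report. Near-duplicates are then injected with [inject_duplicates()].
#'
#' The returned ground truth records, for every planted pair, the realized
#' 2x2 cells counted over the base reports before duplicate injection —
#' the oracle against which [build_table()] is validated.
#'
#' @param config a [synthetic_config()].
#' @return list `db` (an [icsr_db()]), `ground_truth` (tibble `exposure`,
#'   `event`, `or_planted`, `a`, `b`, `c`, `d`), `clone_ids`, `config`.
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dc <- config$drug_catalog
  ec <- config$event_catalog
  miss <- config$missingness

  # exposures ---------------------------------------------------------------
  expo <- vapply(dc$p_exposure, function(p) rbinom(n, 1, p), integer(n))
  if (n == 1) expo <- matrix(expo, nrow = 1)
  colnames(expo) <- dc$drug_name
  if (config$combo_rate > 0 &&
      all(c("ipilimumab", "nivolumab") %in% dc$drug_name)) {
    combo <- runif(n) < config$combo_rate
    expo[combo, "ipilimumab"] <- 1L
    expo[combo, "nivolumab"] <- 1L
  }
  none <- rowSums(expo) == 0
  expo[none, ncol(expo)] <- 1L  # every report carries at least one suspect

  # regimen of each report (drives the onset-delay distribution) ------------
  ici_names <- dc$drug_name[dc$drug_class != "other"]
  ici_mat <- expo[, ici_names, drop = FALSE]
  n_ici <- rowSums(ici_mat)
  regimen <- rep("non_ici", n)
  one <- n_ici == 1
  regimen[one] <- ici_names[max.col(ici_mat[one, , drop = FALSE])]
  multi <- n_ici > 1
  if (any(multi)) {
    is_combo <- rep(FALSE, n)
    if (all(c("ipilimumab", "nivolumab") %in% ici_names)) {
      is_combo <- multi & n_ici == 2 &
        ici_mat[, "ipilimumab"] == 1 & ici_mat[, "nivolumab"] == 1
    }
    regimen[is_combo] <- "ipilimumab_nivolumab"
    regimen[multi & !is_combo] <- "other_ici_combination"
  }

  # reactions: logistic tilting of event odds per exposed report ------------
  react <- matrix(0L, n, nrow(ec), dimnames = list(NULL, ec$term))
  or_mult <- matrix(1, n, nrow(ec), dimnames = list(NULL, ec$term))
  for (key in names(config$planted_or)) {
    ind <- exposure_indicator(expo, key)
    for (term in names(config$planted_or[[key]])) {
      or_mult[ind, term] <- or_mult[ind, term] * config$planted_or[[key]][[term]]
    }
  }
  for (j in seq_len(nrow(ec))) {
    p0 <- ec$p_event[j]
    m <- or_mult[, j]
    p <- (p0 * m) / (1 - p0 + p0 * m)
    react[, j] <- rbinom(n, 1, p)
  }
  empty <- rowSums(react) == 0
  react[empty, ncol(react)] <- 1L  # last catalog term doubles as filler

  # ground truth cells before duplicate injection ---------------------------
  gt <- list()
  for (key in names(config$planted_or)) {
    ind <- exposure_indicator(expo, key)
    for (term in names(config$planted_or[[key]])) {
      ev <- react[, term] == 1
      gt[[length(gt) + 1]] <- tibble::tibble(
        exposure = key, event = term,
        or_planted = config$planted_or[[key]][[term]],
        a = sum(ind & ev), b = sum(ind & !ev),
        c = sum(!ind & ev), d = sum(!ind & !ev))
    }
  }
  ground_truth <- if (length(gt)) dplyr::bind_rows(gt) else
    tibble::tibble(exposure = character(0), event = character(0),
                   or_planted = numeric(0), a = integer(0), b = integer(0),
                   c = integer(0), d = integer(0))

  # dates, demographics, outcomes -------------------------------------------
  year <- sample(seq(config$year_range[1], config$year_range[2]), n,
                 replace = TRUE)
  start <- as.Date(sprintf("%d-01-01", year)) + sample(0:364, n, replace = TRUE)
  tto_par <- t(vapply(regimen, function(r)
    config$tto_days[[r]] %||% config$tto_days[["default"]] %||% c(34, 1.4),
    numeric(2)))
  gap <- round(rlnorm(n, meanlog = log(tto_par[, 1]), sdlog = tto_par[, 2]))
  event_date <- start + gap

  age <- pmin(90, pmax(20, round(stats::rnorm(n, 64, 12))))
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.48, 0.52))
  country <- sample(names(SYN_COUNTRIES), n, replace = TRUE,
                    prob = SYN_COUNTRIES)
  buckets <- c("Skin cancer", "Tumors of respiratory system",
               "Head and neck cancer", "Haematopoietic and lymphoid tissues",
               "Tumors of urinary system", "Breast cancer",
               "Gastrointestinal cancer", "Mesothelioma")
  indication <- sample(buckets, n, replace = TRUE)
  reporter <- sample(REPORTER_LEVELS, n, replace = TRUE, prob = c(0.9, 0.1))
  outcome <- sample(names(config$outcome_probs), n, replace = TRUE,
                    prob = config$outcome_probs)

  drop <- function(x, p) { x[runif(length(x)) < p] <- NA; x }
  age <- drop(age, miss$age %||% 0)
  sex[runif(n) < (miss$sex %||% 0)] <- "unknown"
  country <- drop(country, miss$country %||% 0)
  event_date[runif(n) < (miss$event_date %||% 0)] <- NA
  start[runif(n) < (miss$start_date %||% 0)] <- NA
  indication <- drop(indication, miss$indication %||% 0)

  case_id <- sprintf("SYN%07d", seq_len(n))
  demo <- tibble::tibble(
    case_id = case_id, event_date = event_date,
    event_date_prec = ifelse(is.na(event_date), NA_character_, "day"),
    age_years = as.numeric(age), sex = sex, reporter_country = country,
    reporter_type = reporter, indication = indication, receipt_year = year)

  idx <- which(expo == 1L, arr.ind = TRUE)
  drugs <- tibble::tibble(
    case_id = case_id[idx[, 1]],
    drug_name = dc$drug_name[idx[, 2]],
    role = "suspect",
    drug_class = dc$drug_class[idx[, 2]],
    start_date = dplyr::if_else(dc$drug_class[idx[, 2]] != "other",
                                start[idx[, 1]], as.Date(NA)),
    start_date_prec = ifelse(dc$drug_class[idx[, 2]] != "other" &
                               !is.na(start[idx[, 1]]), "day", NA_character_))
  ridx <- which(react == 1L, arr.ind = TRUE)
  reactions <- tibble::tibble(case_id = case_id[ridx[, 1]],
                              pt = ec$term[ridx[, 2]])
  outcomes <- tibble::tibble(case_id = case_id, outcome = outcome)

  db <- icsr_db(demo, drugs, reactions, outcomes)
  dup <- inject_duplicates(db, config$duplicate_rate,
                           p_perturb = config$duplicate_perturb %||% 0.5)
  list(db = dup$db, ground_truth = ground_truth,
       clone_ids = dup$clone_ids, config = config)
}

#' Inject near-duplicate reports
#'
#' Clones `floor(rate * n)` reports under fresh case ids. Each clone
#' preserves at least three of the four deduplication linkage fields (event
#' date, age, sex, reporter country) with both values present, and perturbs
#' at most one of them — exactly the structure the rule-based deduplication
#' removes. Sources with all four fields present are preferred (those may
#' have one field perturbed); sources with exactly three present are used
#' unperturbed when needed. Clone ids sort after their source within the
#' same receipt year, so deduplication retains the original.
#'
#' @param db an [icsr_db()].
#' @param rate fraction of reports to clone, in `[0, 1]`.
#' @param seed optional seed; by default the call continues the current RNG
#'   stream (as inside [generate_database()]).
#' @param p_perturb probability that a fully-matching clone has one linkage
#'   field perturbed (0 gives exact clones on all four fields).
#' @return list `db` (augmented), `clone_ids`, `source_ids`.
#' @export
inject_duplicates <- function(db, rate, seed = NULL, p_perturb = 0.5) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_cases(db)
  n_clones <- floor(rate * n)
  if (n_clones == 0)
    return(list(db = db, clone_ids = character(0), source_ids = character(0)))
  keys <- dedup_key_matrix(db$demo)
  present <- rowSums(!is.na(keys))
  four <- which(present == 4)
  three <- which(present == 3)
  pool <- c(sample(four), sample(three))
  if (length(pool) < n_clones)
    stop("not enough reports with >=3 linkage fields present to clone",
         call. = FALSE)
  src_rows <- pool[seq_len(n_clones)]

  clone_demo <- db$demo[src_rows, ]
  source_ids <- clone_demo$case_id
  clone_ids <- paste0(source_ids, "-D", seq_len(n_clones))
  clone_demo$case_id <- clone_ids
  perturb <- present[src_rows] == 4 & runif(n_clones) < p_perturb
  which_field <- sample(4, n_clones, replace = TRUE)
  for (i in which(perturb)) {
    f <- which_field[i]
    if (f == 1) clone_demo$event_date[i] <- clone_demo$event_date[i] + 1
    if (f == 2) clone_demo$age_years[i] <- clone_demo$age_years[i] + 1
    if (f == 3) clone_demo$sex[i] <-
        if (clone_demo$sex[i] == "male") "female" else "male"
    if (f == 4) clone_demo$reporter_country[i] <-
        if (identical(clone_demo$reporter_country[i], "US")) "CA" else "US"
  }
  relabel <- function(tab) {
    rows <- tab[tab$case_id %in% source_ids, ]
    rows$case_id <- clone_ids[match(rows$case_id, source_ids)]
    rows
  }
  out <- icsr_db(
    demo = dplyr::bind_rows(db$demo, clone_demo),
    drugs = dplyr::bind_rows(db$drugs, relabel(db$drugs)),
    reactions = dplyr::bind_rows(db$reactions, relabel(db$reactions)),
    outcomes = dplyr::bind_rows(db$outcomes, relabel(db$outcomes)))
  list(db = out, clone_ids = clone_ids, source_ids = source_ids)
}
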