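# shared builders and independent oracles

# contingency table object without going through a database
make_table <- function(a, b, c, d, background = "full_database") {
  structure(list(a = a, b = b, c = c, d = d,
                 exposure_label = "x", event_label = "y",
                 background = background),
            class = "contingency_table")
}

# independent single-expression re-evaluations of the printed formulas;
# deliberately written as one-liners so they share no code with the package
oracle_ror <- function(a, b, c, d) (a * d) / (b * c)
oracle_ror_ci <- function(a, b, c, d)
  exp(log((a * d) / (b * c)) + c(-1, 1) * 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))
oracle_prr <- function(a, b, c, d) a * (c + d) / c / (a + b)
oracle_chi2 <- function(a, b, c, d)
  ((a * d - b * c)^2) * (a + b + c + d) / ((a + b) * (c + d) * (a + c) * (b + d))
oracle_ic <- function(a, b, c, d) log2(a * (a + b + c + d) / ((a + c) * (a + b)))
oracle_ic025 <- function(a, b, c, d) {
  ic <- log2(a * (a + b + c + d) / ((a + c) * (a + b)))
  if (ic <= 0) NA_real_ else exp(log(ic) - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))
}
oracle_ebgm <- function(a, b, c, d) a * (a + b + c + d) / (a + c) / (a + b)
oracle_ebgm05 <- function(a, b, c, d)
  exp(log(a * (a + b + c + d) / (a + c) / (a + b)) -
        1.64 * sqrt(1/a + 1/b + 1/c + 1/d))

# compact report-database builder: one row per case, drugs/reactions given as
# per-case lists
tiny_db <- function(case_id,
                    drugs = NULL, reactions = NULL, outcomes = NULL,
                    event_date = as.Date(NA), age = NA_real_, sex = "unknown",
                    country = NA_character_, reporter = "healthcare_professional",
                    indication = NA_character_, year = 2020L,
                    start_date = as.Date(NA)) {
  n <- length(case_id)
  rec <- function(x) rep(x, length.out = n)
  demo <- tibble::tibble(
    case_id = case_id, event_date = rec(event_date),
    event_date_prec = ifelse(is.na(rec(event_date)), NA_character_, "day"),
    age_years = rec(age), sex = rec(sex), reporter_country = rec(country),
    reporter_type = rec(reporter), indication = rec(indication),
    receipt_year = rec(year))
  drug_tab <- NULL
  if (!is.null(drugs)) {
    drugs <- rep(drugs, length.out = n)
    start <- rec(start_date)
    drug_tab <- purrr::map_dfr(seq_len(n), function(i) {
      if (length(drugs[[i]]) == 0) return(NULL)
      tibble::tibble(case_id = case_id[i], drug_name = drugs[[i]],
                     role = "suspect",
                     drug_class = pvsignal::classify_drug(drugs[[i]]),
                     start_date = start[i],
                     start_date_prec = ifelse(is.na(start[i]), NA_character_,
                                              "day"))
    })
  }
  reac_tab <- NULL
  if (!is.null(reactions)) {
    reactions <- rep(reactions, length.out = n)
    reac_tab <- purrr::map_dfr(seq_len(n), function(i)
      tibble::tibble(case_id = case_id[i], pt = reactions[[i]]))
  }
  outc_tab <- NULL
  if (!is.null(outcomes)) {
    outc_tab <- tibble::tibble(case_id = case_id, outcome = rec(outcomes))
  }
  icsr_db(demo, drug_tab, reac_tab, outc_tab)
}

# randomized report collection exercising every field combination, for
# round-trip properties
random_db <- function(n, seed) {
  set.seed(seed)
  maybe <- function(x, p = 0.3) ifelse(runif(length(x)) < p,
                                       NA, x)
  ev <- as.Date("2019-01-01") + sample(0:900, n, TRUE)
  ev[runif(n) < 0.3] <- NA
  prec <- sample(c("day", "month", "year"), n, TRUE)
  prec[is.na(ev)] <- NA
  # truncate to the precision so format/parse agree
  ev[prec %in% "month"] <- as.Date(format(ev[prec %in% "month"], "%Y-%m-01"))
  ev[prec %in% "year"] <- as.Date(format(ev[prec %in% "year"], "%Y-01-01"))
  demo <- tibble::tibble(
    case_id = sprintf("R%04d", seq_len(n)),
    event_date = ev, event_date_prec = prec,
    age_years = as.numeric(maybe(sample(20:90, n, TRUE))),
    sex = sample(c("male", "female", "unknown"), n, TRUE),
    reporter_country = ifelse(runif(n) < 0.2, NA_character_,
                              sample(c("US", "JP", "DE", "XX"), n, TRUE)),
    reporter_type = sample(c("healthcare_professional", "consumer"), n, TRUE),
    indication = ifelse(runif(n) < 0.3, NA_character_,
                        sample(c("melanoma", "breast cancer"), n, TRUE)),
    receipt_year = sample(2011:2024, n, TRUE))
  drugs <- purrr::map_dfr(seq_len(n), function(i) {
    nm <- sample(c("nivolumab", "ipilimumab", "carboplatin"),
                 sample(1:2, 1))
    sd <- as.Date("2018-06-01") + sample(0:400, length(nm), TRUE)
    sd[runif(length(nm)) < 0.4] <- NA
    tibble::tibble(case_id = demo$case_id[i], drug_name = nm,
                   role = sample(c("suspect", "concomitant"), length(nm), TRUE),
                   drug_class = pvsignal::classify_drug(nm),
                   start_date = sd,
                   start_date_prec = ifelse(is.na(sd), NA_character_, "day"))
  })
  reactions <- purrr::map_dfr(seq_len(n), function(i)
    tibble::tibble(case_id = demo$case_id[i],
                   pt = sample(c("Meningitis", "Headache", "Pyrexia"),
                               sample(1:2, 1))))
  outcomes <- tibble::tibble(
    case_id = demo$case_id,
    outcome = sample(c("death", "hospitalization", "non_serious",
                       "other_serious"), n, TRUE))
  icsr_db(demo, drugs, reactions, outcomes)
}

# field-for-field database comparison helper (order-insensitive)
expect_db_equal <- function(x, y) {
  ord <- function(t, cols) dplyr::arrange(t, dplyr::across(dplyr::all_of(cols)))
  expect_equal(ord(x$demo, "case_id"), ord(y$demo, "case_id"))
  expect_equal(ord(x$drugs, c("case_id", "drug_name", "role")),
               ord(y$drugs, c("case_id", "drug_name", "role")))
  expect_equal(ord(x$reactions, c("case_id", "pt")),
               ord(y$reactions, c("case_id", "pt")))
  expect_equal(ord(x$outcomes, c("case_id", "outcome")),
               ord(y$outcomes, c("case_id", "outcome")))
}
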