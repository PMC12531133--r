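REGIMEN_NS <- c(ipilimumab = 37, nivolumab = 85, pembrolizumab = 174,
                cemiplimab = 5, durvalumab = 9, atezolizumab = 79,
                avelumab = 3, ipilimumab_nivolumab = 106)

fixture_block <- function(...) {
  m <- rbind(...)
  colnames(m) <- names(REGIMEN_NS)
  m
}

fixture_counts <- function() {
  list(
    sex = fixture_block(
      male = c(13, 42, 85, 0, 1, 32, 1, 56),
      female = c(13, 31, 80, 5, 7, 35, 1, 35),
      unknown = c(11, 12, 9, 0, 1, 12, 1, 15)),
    reporter = fixture_block(
      healthcare_professional = c(33, 82, 163, 3, 8, 77, 3, 102),
      consumer = c(4, 3, 11, 2, 1, 2, 0, 4)),
    outcome = fixture_block(
      non_serious = c(0, 1, 7, 1, 0, 0, 0, 1),
      hospitalization = c(18, 44, 88, 1, 6, 25, 1, 45),
      disability = c(1, 3, 5, 0, 0, 2, 0, 0),
      life_threatening = c(2, 3, 11, 0, 0, 4, 0, 12),
      death = c(4, 7, 16, 1, 0, 18, 1, 10),
      other_serious = c(12, 27, 47, 2, 3, 30, 1, 38)),
    region = fixture_block(
      ZA = c(0, 0, 0, 0, 0, 3, 0, 0),        # Africa
      JP = c(2, 29, 82, 2, 2, 59, 0, 44),    # Asia
      DE = c(16, 38, 64, 1, 6, 11, 2, 48),   # Europe
      US = c(18, 18, 26, 2, 1, 5, 1, 12),    # North America
      AU = c(1, 0, 1, 0, 0, 0, 0, 0),        # Oceania
      BR = c(0, 0, 1, 0, 0, 1, 0, 1)),       # South America
    indication = fixture_block(
      `Bone tumor` = c(0, 0, 3, 0, 0, 23, 0, 2),
      `Breast cancer` = c(0, 0, 20, 2, 0, 1, 0, 0),
      `Gastrointestinal cancer` = c(0, 4, 1, 0, 0, 0, 1, 0),
      `Haematopoietic and lymphoid tissues` = c(0, 12, 5, 1, 0, 3, 1, 58),
      `Head and neck cancer` = c(0, 3, 63, 1, 9, 42, 0, 5),
      Mesothelioma = c(0, 0, 27, 0, 0, 3, 1, 29),
      `Neuroendocrine neoplasm` = c(0, 0, 31, 0, 0, 0, 0, 0),
      `Skin cancer` = c(24, 22, 1, 0, 0, 0, 0, 0),
      `Tumors of female reproductive organs` = c(0, 0, 1, 0, 0, 0, 0, 3),
      `Tumors of respiratory system` = c(0, 26, 0, 0, 0, 0, 0, 2),
      `Tumors of urinary system` = c(4, 11, 1, 0, 0, 0, 0, 0),
      `Unknown or missing` = c(9, 7, 21, 1, 0, 7, 0, 7))
  )
}

expand_counts <- function(counts_col) rep(rownames(counts_col),
                                          times = counts_col)

#' Synthetic case series with the reported stratified counts
#'
#' Builds a 498-report event-case database whose per-regimen report, sex,
#' reporter, outcome, region and indication counts equal the published
#' stratified clinical-characteristics table for checkpoint-inhibitor
#' aseptic meningitis (eight regimen strata; the blocks are filled
#' independently within each stratum, so only the published marginals are
#' reproduced, not any joint structure). Every report carries the regimen's
#' suspect drug(s) and one aseptic-meningitis preferred term. This is a
#' synthetic stand-in constructed from printed counts — not source data.
#'
#' @return an [icsr_db()] of 498 reports.
#' @export
paper_case_series <- function() {
  cnt <- fixture_counts()
  demos <- list(); drugs <- list()
  for (reg in names(REGIMEN_NS)) {
    n <- REGIMEN_NS[[reg]]
    ids <- sprintf("AM-%s-%03d", toupper(substr(reg, 1, 3 +
                     4 * (reg == "ipilimumab_nivolumab"))), seq_len(n))
    demos[[reg]] <- tibble::tibble(
      case_id = ids,
      event_date = as.Date(NA), event_date_prec = NA_character_,
      age_years = NA_real_,
      sex = expand_counts(cnt$sex[, reg, drop = FALSE]),
      # the printed region block sums to 497 of 498 (one combination-stratum
      # report has no region); the remainder is padded as unknown
      reporter_country = {
        vals <- expand_counts(cnt$region[, reg, drop = FALSE])
        c(vals, rep(NA_character_, n - length(vals)))
      },
      reporter_type = expand_counts(cnt$reporter[, reg, drop = FALSE]),
      indication = expand_counts(cnt$indication[, reg, drop = FALSE]),
      receipt_year = 2018L,
      outcome = expand_counts(cnt$outcome[, reg, drop = FALSE]))
    suspects <- if (reg == "ipilimumab_nivolumab")
      c("ipilimumab", "nivolumab") else reg
    drugs[[reg]] <- tidyr::expand_grid(case_id = ids, drug_name = suspects)
  }
  demo <- dplyr::bind_rows(demos)
  drug_tab <- dplyr::bind_rows(drugs)
  drug_tab$role <- "suspect"
  drug_tab$drug_class <- classify_drug(drug_tab$drug_name)
  drug_tab$start_date <- as.Date(NA)
  drug_tab$start_date_prec <- NA_character_
  outcomes <- demo[, c("case_id", "outcome")]
  reactions <- tibble::tibble(case_id = demo$case_id, pt = "Meningitis aseptic")
  demo$outcome <- NULL
  icsr_db(demo, drug_tab, reactions, outcomes)
}

#' Combine two ICSR databases
#' @param a,b `icsr_db` objects with disjoint case ids.
#' @export
bind_dbs <- function(a, b) {
  icsr_db(dplyr::bind_rows(a$demo, b$demo),
          dplyr::bind_rows(a$drugs, b$drugs),
          dplyr::bind_rows(a$reactions, b$reactions),
          dplyr::bind_rows(a$outcomes, b$outcomes))
}

#' Embed the reported case series in a synthetic reporting background
#'
#' Binds [paper_case_series()] to a generated multi-drug background whose
#' event catalog contains only non-meningitis noise terms, so every
#' meningitis event case in the combined database comes from the fixture
#' and the regimen strata keep their published Ns, while the background
#' supplies the exposed-non-event and non-exposed cells needed by the
#' disproportionality screens.
#'
#' @param n_background number of background reports.
#' @param seed RNG seed for the background generator.
#' @param p_background_event probability that a background report without a
#'   checkpoint-inhibitor suspect additionally carries a meningitis term
#'   (populates the non-exposed event cell without touching stratum Ns).
#' @return list `db`, `fixture`, `background`.
#' @export
paper_embedded_database <- function(n_background = 20000, seed = 1,
                                    p_background_event = 0.007) {
  noise_catalog <- default_event_catalog()
  noise_catalog <- noise_catalog[noise_catalog$p_event >= 0.01, ]
  bg <- generate_database(synthetic_config(
    n_reports = n_background, event_catalog = noise_catalog,
    duplicate_rate = 0, combo_rate = 0.02,
    missingness = list(age = 0.2, sex = 0.12, country = 0.05,
                       event_date = 0.3, start_date = 0.35,
                       indication = 0.15),
    seed = seed))
  bg_db <- bg$db
  ici <- ici_catalog()
  non_ici_ids <- setdiff(
    bg_db$demo$case_id,
    bg_db$drugs$case_id[bg_db$drugs$drug_name %in% ici$drug_name])
  hit <- non_ici_ids[runif(length(non_ici_ids)) < p_background_event]
  if (length(hit)) {
    terms <- sample(c("Meningitis", "Meningitis aseptic"), length(hit),
                    replace = TRUE)
    bg_db$reactions <- dplyr::bind_rows(
      bg_db$reactions, tibble::tibble(case_id = hit, pt = terms))
  }
  fixture <- paper_case_series()
  list(db = bind_dbs(fixture, bg_db), fixture = fixture, background = bg_db)
}
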