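test_that("term matching flags reports and indexes them per preferred term", {
  db <- tiny_db(
    c("C1", "C2", "C3", "C4", "C5"),
    drugs = list("nivolumab"),
    reactions = list(c("meningitis ASEPTIC"),            # case-insensitive hit
                     c("Headache", "Pyrexia"),           # no hit
                     c("Meningitis", "Meningism"),       # two hits, one report
                     c("Pachymeningitis"),
                     c("Arachnoiditis", "Nausea")))
  fl <- flag_event_cases(db, term_query())
  expect_setequal(fl$case_ids, c("C1", "C3", "C4", "C5"))
  expect_equal(fl$n_flagged, 4)
  expect_equal(nrow(fl$pt_index), 5)  # C3 counted under two terms
  expect_equal(sort(fl$pt_index$pt[fl$pt_index$case_id == "C3"]),
               c("Meningism", "Meningitis"))
})

test_that("exact match mode distinguishes case", {
  db <- tiny_db("C1", drugs = list("nivolumab"),
                reactions = list("MENINGITIS"))
  expect_equal(flag_event_cases(db, term_query(match_mode = "exact"))$n_flagged, 0)
  expect_equal(flag_event_cases(db, term_query())$n_flagged, 1)
})

test_that("duplicates need >=3 present identical fields; missing never matches", {
  base <- list(event_date = as.Date("2020-06-01"), age = 64, sex = "male",
               country = "US")
  # identical on all four -> one retained
  db4 <- tiny_db(c("A", "B"), event_date = base$event_date, age = base$age,
                 sex = base$sex, country = base$country)
  dd <- deduplicate(db4)
  expect_equal(dd$db$demo$case_id, "A")
  expect_equal(dd$removed_pairs$n_fields_matched, 4)
  # agreement on exactly two fields -> both retained
  db2 <- tiny_db(c("A", "B"), event_date = c(base$event_date, base$event_date + 1),
                 age = c(64, 65), sex = "male", country = "US")
  expect_equal(deduplicate(db2)$n_removed, 0)
  # three agreeing fields but one of the three missing on one side -> retained
  dbm <- tiny_db(c("A", "B"), event_date = base$event_date, age = c(64, NA),
                 sex = "male", country = c(NA, NA))
  expect_equal(deduplicate(dbm)$n_removed, 0)
})

test_that("a triple-clone cluster collapses to its first report (brute-force oracle)", {
  db <- tiny_db(c("R1", "R2", "R3", "R4", "R5", "R6"),
                event_date = as.Date("2020-01-01") + c(0, 0, 0, 50, 60, 70),
                age = c(70, 70, 71, 30, 31, 32),
                sex = c("male", "male", "male", "female", "female", "male"),
                country = c("JP", "JP", "JP", "US", "DE", "FR"))
  # R1/R2 agree on 4, R1/R3 and R2/R3 on 3 -> cluster of three; R4-R6 distinct
  dd <- deduplicate(db)
  expect_equal(n_cases(dd$db), 4)
  expect_setequal(dd$db$demo$case_id, c("R1", "R4", "R5", "R6"))
  # brute-force all-pairs check: no retained pair matches >=3 fields
  keys <- pvsignal:::dedup_key_matrix(dd$db$demo)
  for (i in seq_len(nrow(keys))) for (j in seq_len(i - 1)) {
    expect_lt(sum(keys[i, ] == keys[j, ], na.rm = TRUE), 3)
  }
})

test_that("deduplication is idempotent and monotone", {
  for (seed in c(1, 8)) {
    db <- random_db(60, seed)
    once <- deduplicate(db)
    twice <- deduplicate(once$db)
    expect_equal(twice$n_removed, 0)
    expect_db_equal(twice$db, once$db)
    expect_lte(n_cases(once$db), n_cases(db))
    expect_equal(n_cases(once$db) + once$n_removed, n_cases(db))
  }
})

test_that("dedup removes exactly the injected clones on generator output", {
  # reporter country is fully missing here so agreement requires the sharp
  # event-date field; that makes coincidental >=3-field base pairs improbable
  g <- generate_database(synthetic_config(
    n_reports = 150, duplicate_rate = 0.2, duplicate_perturb = 0,
    missingness = list(age = 0, sex = 0, country = 1, event_date = 0,
                       start_date = 0, indication = 0), seed = 31))
  # with exact clones, "no coincidental base pair" (checked first) implies
  # every clone is dropped against exactly its source and nothing else
  base <- filter_cases(g$db, setdiff(g$db$demo$case_id, g$clone_ids))
  expect_equal(deduplicate(base)$n_removed, 0)
  dd <- deduplicate(g$db)
  expect_setequal(dd$removed_pairs$dropped_id, g$clone_ids)
  expect_equal(dd$removed_pairs$kept_id, sub("-D.*", "", dd$removed_pairs$dropped_id))
})

test_that("temporal filter removes only start-after-onset reports", {
  db <- tiny_db(c("T1", "T2", "T3"),
                drugs = list("nivolumab"),
                reactions = list("Meningitis"),
                event_date = as.Date(c("2020-02-01", "2020-03-01", "2020-02-01")),
                start_date = as.Date(c("2020-03-01", "2020-03-01", NA)))
  tf <- temporal_filter(db)
  expect_equal(tf$removed_ids, "T1")           # start strictly after onset
  expect_setequal(tf$db$demo$case_id, c("T2", "T3"))  # day-0 and missing kept
})

test_that("regimens classify from the suspect ICI set", {
  db <- tiny_db(c("M1", "M2", "M3", "M4"),
                drugs = list("pembrolizumab",
                             c("ipilimumab", "nivolumab"),
                             c("ipilimumab", "pembrolizumab"),
                             "carboplatin"),
                reactions = list("Meningitis"))
  asg <- classify_regimen(db)
  expect_equal(asg$regimen[match(c("M1", "M2", "M3", "M4"), asg$case_id)],
               c("pembrolizumab", "ipilimumab_nivolumab",
                 "other_ici_combination", "non_ici"))
})

test_that("time to onset is the floored day gap, flagged when imputed", {
  db <- tiny_db("K1", drugs = list("nivolumab"), reactions = list("Meningitis"),
                event_date = as.Date("2020-03-15"),
                start_date = as.Date("2020-02-10"))
  asg <- classify_regimen(db)
  expect_equal(asg$time_to_onset_days, 34L)
  expect_false(asg$tto_imputed)
  # month-precision start date -> imputed flag set
  db$drugs$start_date_prec <- "month"
  asg2 <- classify_regimen(db)
  expect_true(asg2$tto_imputed)
})

test_that("the selection pipeline conserves counts at every stage", {
  g <- generate_database(synthetic_config(n_reports = 3000, seed = 17))
  sel <- select_cases(g$db)
  sc <- sel$stage_counts
  expect_equal(sc$after_dedup + sc$duplicates_removed, sc$event_flagged)
  expect_equal(sc$after_temporal + sc$temporal_removed, sc$after_dedup)
  expect_equal(sc$analyzed + sc$excluded_regimen, sc$after_temporal)
  expect_lte(sc$event_flagged, sc$ici_suspect)
  expect_lte(sc$ici_suspect, sc$input)
  expect_equal(nrow(sel$assignments), sc$analyzed)
})

test_that("term queries load from YAML files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("query_id: custom", "match_mode: exact", "terms:",
               "  - Meningitis", "  - Meningism"), path)
  q <- read_term_query(path)
  expect_equal(q$query_id, "custom")
  expect_equal(q$match_mode, "exact")
  expect_setequal(q$terms, c("Meningitis", "Meningism"))
})
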