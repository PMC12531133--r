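test_that("the worked 2x2 table reproduces all four statistics", {
  t <- make_table(10, 20, 30, 240)
  s <- signal_statistics(t)
  expect_equal(s$ror, 4.0)
  expect_equal(s$ror_lo, 1.712, tolerance = 1e-3)
  expect_equal(s$ror_hi, 9.347, tolerance = 1e-3)
  expect_equal(s$prr, 3.0)
  expect_equal(s$chi2, 11.538, tolerance = 1e-3)
  expect_equal(s$ic, log2(2.5))
  expect_equal(s$ic025, 0.566, tolerance = 1e-3)
  expect_equal(s$ebgm, 2.5)
  expect_equal(s$ebgm05, 1.229, tolerance = 1e-3)
})

test_that("a uniform table is null under every algorithm", {
  s <- signal_statistics(make_table(25, 25, 25, 25))
  expect_equal(s$ror, 1)
  expect_lt(s$ror_lo, 1); expect_gt(s$ror_hi, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$chi2, 0)
  expect_equal(s$ic, 0)
  expect_true(is.na(s$ic025))  # printed bound undefined at IC <= 0
  expect_equal(s$ebgm, 1)
  expect_lt(s$ebgm05, 1)
  r <- evaluate_signal(s)
  expect_false(any(r$flags))
  expect_false(r$validated)
})

test_that("each statistic matches an independent re-evaluation on 1000 random tables", {
  set.seed(2024)
  rel_ok <- function(x, y) {
    expect_equal(x, y, tolerance = 1e-12)
  }
  for (i in 1:1000) {
    k <- as.numeric(sample(1:500, 4, replace = TRUE))
    t <- make_table(k[1], k[2], k[3], k[4])
    s <- signal_statistics(t)
    rel_ok(s$ror, oracle_ror(k[1], k[2], k[3], k[4]))
    rel_ok(c(s$ror_lo, s$ror_hi), oracle_ror_ci(k[1], k[2], k[3], k[4]))
    rel_ok(s$prr, oracle_prr(k[1], k[2], k[3], k[4]))
    rel_ok(s$chi2, oracle_chi2(k[1], k[2], k[3], k[4]))
    rel_ok(s$ic, oracle_ic(k[1], k[2], k[3], k[4]))
    rel_ok(s$ic025, oracle_ic025(k[1], k[2], k[3], k[4]))
    rel_ok(s$ebgm, oracle_ebgm(k[1], k[2], k[3], k[4]))
    rel_ok(s$ebgm05, oracle_ebgm05(k[1], k[2], k[3], k[4]))
  }
})

test_that("algebraic identities hold across random positive tables", {
  set.seed(7)
  for (i in 1:200) {
    k <- as.numeric(sample(1:300, 4, replace = TRUE))
    s <- signal_statistics(make_table(k[1], k[2], k[3], k[4]))
    # IC and EBGM share the observed/expected kernel
    expect_identical(s$ic, log2(s$ebgm))
    # ROR and PRR sit on the same side of 1
    expect_equal(sign(round(s$ror - s$prr, 9)), sign(round(s$ror - 1, 9)))
    # exchanging exposure rows inverts the ROR, chi2 invariant
    sw <- signal_statistics(make_table(k[3], k[4], k[1], k[2]))
    expect_equal(sw$ror, 1 / s$ror, tolerance = 1e-12)
    expect_equal(sw$chi2, s$chi2, tolerance = 1e-12)
    # chi2 = 0 iff ad = bc
    expect_identical(s$chi2 == 0, k[1] * k[4] == k[2] * k[3])
  }
  # independence case: ad = bc forces chi2 to exactly 0
  expect_equal(signal_statistics(make_table(6, 9, 10, 15))$chi2, 0)
})

test_that("zero cells yield undefined statistics unless the 0.5 correction is on", {
  t0 <- make_table(0, 10, 5, 100)
  expect_equal(compute_ror(t0)$reason, "zero_cell")
  expect_true(is.na(compute_ror(t0)$ror))
  expect_true(is.na(compute_ic(t0)$ic))
  expect_true(is.na(compute_ebgm(t0)$ebgm))
  r <- evaluate_signal(signal_statistics(t0))
  expect_false(any(r$flags))
  corrected <- compute_ror(t0, zero_correction = TRUE)
  expect_false(is.na(corrected$ror))
  expect_equal(corrected$ror, (0.5 * 100.5) / (10.5 * 5.5))
})

test_that("scaling all cells leaves EBGM fixed while its lower bound tightens", {
  s1 <- signal_statistics(make_table(10, 20, 30, 240))
  s10 <- signal_statistics(make_table(100, 200, 300, 2400))
  expect_equal(s10$ebgm, s1$ebgm)
  expect_gt(s10$ebgm05, s1$ebgm05)
  expect_lt(s10$ebgm05, s10$ebgm)
})

test_that("the canonical interval variant differs only where documented", {
  t <- make_table(10, 20, 30, 240)
  printed <- signal_statistics(t, "printed")
  canonical <- signal_statistics(t, "canonical")
  expect_equal(printed$ic, canonical$ic)
  expect_equal(printed$ebgm05, canonical$ebgm05)
  se <- sqrt(1/10 + 1/20 + 1/30 + 1/240)
  expect_equal(canonical$ic025, printed$ic - 1.96 * se / log(2))
  # canonical bound stays defined at IC <= 0 where the printed one cannot
  u <- make_table(25, 25, 25, 25)
  expect_true(is.na(compute_ic(u, "printed")$ic025))
  expect_false(is.na(compute_ic(u, "canonical")$ic025))
})

test_that("signal flags follow the per-algorithm thresholds and concordance", {
  r <- evaluate_signal(signal_statistics(make_table(10, 20, 30, 240)))
  expect_equal(unname(r$flags), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(r$validated)  # 3 of 4 >= 2
  # N = 1 with a huge ROR: ROR blocked by N>=2, PRR by N>=3
  r1 <- evaluate_signal(signal_statistics(make_table(1, 1, 1, 10000)))
  expect_false(r1$flags[["ror"]])
  expect_false(r1$flags[["prr"]])
  expect_lte(r1$n_positive, 2)
  # concordance threshold is configurable
  r4 <- evaluate_signal(signal_statistics(make_table(10, 20, 30, 240)),
                        signal_criteria(concordance_min = 4))
  expect_false(r4$validated)
})

test_that("build_table assigns each report to exactly one cell", {
  db <- tiny_db(c("E1", "E2", "N1", "N2"),
                drugs = list("nivolumab", "nivolumab", "carboplatin",
                             "carboplatin"),
                reactions = list("Meningitis", "Headache", "Meningitis",
                                 "Headache"))
  exposed <- unique(db$drugs$case_id[db$drugs$drug_name == "nivolumab"])
  event <- unique(db$reactions$case_id[db$reactions$pt == "Meningitis"])
  t <- build_table(db, exposed, event)
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  expect_error(build_table(filter_cases(db, character(0)), exposed, event),
               "empty background")
})

test_that("comparator-restricted tables count only the two strata", {
  ids_combo <- sprintf("CB%02d", 1:10)
  ids_nivo <- sprintf("NV%02d", 1:10)
  db <- tiny_db(c(ids_combo, ids_nivo),
                drugs = c(rep(list(c("ipilimumab", "nivolumab")), 10),
                          rep(list("nivolumab"), 10)),
                reactions = c(rep(list("Meningitis"), 3),
                              rep(list("Headache"), 7),
                              rep(list("Meningitis"), 2),
                              rep(list("Headache"), 8)))
  t <- build_table(db, ids_combo,
                   unique(db$reactions$case_id[db$reactions$pt == "Meningitis"]),
                   background = "comparator_restricted", comparator = ids_nivo)
  expect_equal(t$a + t$b, 10)
  expect_equal(t$c + t$d, 10)
  expect_error(build_table(db, ids_combo, ids_combo[1],
                           background = "comparator_restricted",
                           comparator = c(ids_nivo, ids_combo[1])),
               "disjoint")
})

test_that("head-to-head ROR matches hand arithmetic and is reciprocal", {
  n_combo_ev <- 20; n_combo_non <- 80; n_nivo_ev <- 10; n_nivo_non <- 160
  ids <- c(sprintf("CE%03d", seq_len(n_combo_ev)),
           sprintf("CN%03d", seq_len(n_combo_non)),
           sprintf("NE%03d", seq_len(n_nivo_ev)),
           sprintf("NN%03d", seq_len(n_nivo_non)))
  db <- tiny_db(ids,
                drugs = c(rep(list(c("ipilimumab", "nivolumab")), 100),
                          rep(list("nivolumab"), 170)),
                reactions = c(rep(list("Meningitis"), n_combo_ev),
                              rep(list("Headache"), n_combo_non),
                              rep(list("Meningitis"), n_nivo_ev),
                              rep(list("Headache"), n_nivo_non)))
  h <- head_to_head(db, "ipilimumab_nivolumab", "nivolumab")
  expect_equal(h$statistics$ror, (20 * 160) / (80 * 10))
  rev <- head_to_head(db, "nivolumab", "ipilimumab_nivolumab")
  expect_equal(rev$statistics$ror, 1 / h$statistics$ror)
  # identical event rates give ROR 1
  db_eq <- tiny_db(ids[1:200],
                   drugs = c(rep(list(c("ipilimumab", "nivolumab")), 100),
                             rep(list("nivolumab"), 100)),
                   reactions = rep(c(rep(list("Meningitis"), 20),
                                     rep(list("Headache"), 80)), 2))
  expect_equal(head_to_head(db_eq)$statistics$ror, 1)
})

test_that("class stratum N adds over member monotherapies; combo joins neither class", {
  db <- tiny_db(sprintf("S%02d", 1:8),
                drugs = list("nivolumab", "pembrolizumab", "cemiplimab",
                             c("ipilimumab", "nivolumab"), "atezolizumab",
                             "durvalumab", "ipilimumab", "carboplatin"),
                reactions = list("Meningitis"))
  strata <- regimen_strata(db)
  expect_setequal(strata[["Anti-PD-1"]], c("S01", "S02", "S03"))
  expect_setequal(strata[["Anti-PD-L1"]], c("S05", "S06"))
  expect_false("S04" %in% c(strata[["Anti-PD-1"]], strata[["Anti-PD-L1"]]))
  expect_setequal(strata[["Total"]], sprintf("S%02d", 1:7))
  # a report with two same-class suspects joins the class once
  db2 <- tiny_db("D1", drugs = list(c("nivolumab", "pembrolizumab")),
                 reactions = list("Meningitis"))
  s2 <- regimen_strata(db2)
  expect_equal(s2[["Anti-PD-1"]], "D1")
  expect_equal(length(s2[["nivolumab"]]), 0)
})

test_that("an empty stratum yields an N=0 result with all flags false", {
  g <- generate_database(synthetic_config(n_reports = 400, seed = 3))
  scr <- regimen_screen(g$db)
  ns <- vapply(scr, function(r) r$statistics$n, numeric(1))
  empty <- names(ns)[ns == 0]
  expect_gt(length(empty), 0)  # rare drugs have no event case at this size
  for (lab in empty) expect_false(any(scr[[lab]]$flags))
})

test_that("the regimen screen recovers a planted association and only it", {
  validated <- matrix(NA, 15, 2,
                      dimnames = list(NULL, c("atezolizumab", "durvalumab")))
  for (i in 1:15) {
    g <- generate_database(synthetic_config(
      n_reports = 6000, duplicate_rate = 0,
      planted_or = list(atezolizumab = list(Meningitis = 6,
                                            `Meningitis aseptic` = 6)),
      seed = 100 + i))
    scr <- regimen_screen(g$db,
                          strata = regimen_strata(g$db)[c("atezolizumab",
                                                          "durvalumab")])
    validated[i, ] <- c(scr[["atezolizumab"]]$validated,
                        scr[["durvalumab"]]$validated)
  }
  expect_gte(mean(validated[, "atezolizumab"]), 0.9)
  expect_lte(mean(validated[, "durvalumab"]), 0.1)
})

test_that("PT-level screen counts a report once per matching term row", {
  db <- tiny_db(c(sprintf("P%02d", 1:6)),
                drugs = list("nivolumab"),
                reactions = list(c("Meningitis", "Meningism"), "Meningitis",
                                 "Meningitis", "Meningism", "Headache",
                                 "Headache"))
  # background so cells are positive
  bg <- tiny_db(sprintf("B%03d", 1:50), drugs = list("carboplatin"),
                reactions = c(rep(list("Meningitis"), 3),
                              rep(list("Meningism"), 2),
                              rep(list("Headache"), 45)))
  full <- bind_dbs(db, bg)
  pts <- pt_level_screen(full, min_n = 2)
  res <- pts$results
  n_meningitis <- res$n[res$pt == "Meningitis" & res$regimen == "nivolumab"]
  n_meningism <- res$n[res$pt == "Meningism" & res$regimen == "nivolumab"]
  expect_equal(n_meningitis, 3)
  expect_equal(n_meningism, 2)
  # PT-row N sum exceeds distinct flagged reports by one (P01 double-counted)
  tot <- pts$totals$total_n[pts$totals$regimen == "nivolumab"]
  expect_equal(tot, 5)
  expect_equal(flag_event_cases(db)$n_flagged, 4)
})

test_that("PT rows below min_n are suppressed; single-PT databases collapse", {
  db <- tiny_db(c("Q1", "Q2", "Q3"),
                drugs = list("nivolumab", "nivolumab", "carboplatin"),
                reactions = list("Meningitis", "Pachymeningitis", "Headache"))
  bg <- tiny_db(sprintf("G%03d", 1:40), drugs = list("carboplatin"),
                reactions = c(rep(list("Meningitis"), 2),
                              rep(list("Headache"), 38)))
  full <- bind_dbs(db, bg)
  res2 <- pt_level_screen(full, min_n = 2)$results
  expect_equal(nrow(res2), 0)  # a=1 everywhere at min_n=2
  res1 <- pt_level_screen(full, min_n = 1)$results
  expect_setequal(res1$pt, c("Meningitis", "Pachymeningitis"))
  # single-PT database: PT-level N equals the regimen-screen N
  scr <- regimen_screen(full)
  expect_equal(sum(res1$n[res1$regimen == "nivolumab"]), 2)
  expect_equal(scr[["nivolumab"]]$statistics$n, 2)
})
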