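#' 2x2 contingency table for one exposure x event pair
#'
#' Cross-classifies every unique report in the chosen background into the
#' four disproportionality cells: `a` exposed with the suspect event, `b`
#' exposed with other events, `c` event under other exposures, `d` neither.
#' Under the `full_database` background, `c`/`d` run over all non-exposed
#' reports; under `comparator_restricted` they run over the comparator's
#' reports only (head-to-head design).
#'
#' @param db an [icsr_db()].
#' @param exposure case ids of exposed reports, or a function `db ->` ids.
#' @param event case ids of event reports, or a function `db ->` ids.
#' @param background `"full_database"` or `"comparator_restricted"`.
#' @param comparator case ids (or function) of the comparator stratum;
#'   required under `comparator_restricted`, must be disjoint from exposure.
#' @param exposure_label,event_label labels carried into results.
#' @return object of class `contingency_table`: `a`,`b`,`c`,`d`, labels,
#'   `background`.
#' @export
build_table <- function(db, exposure, event,
                        background = c("full_database", "comparator_restricted"),
                        comparator = NULL,
                        exposure_label = "exposure", event_label = "event") {
  background <- match.arg(background)
  resolve <- function(x) if (is.function(x)) x(db) else x
  all_ids <- db$demo$case_id
  if (length(all_ids) == 0) stop("empty background database", call. = FALSE)
  exp_ids <- intersect(resolve(exposure), all_ids)
  ev_ids <- intersect(resolve(event), all_ids)
  if (background == "comparator_restricted") {
    if (is.null(comparator))
      stop("comparator_restricted background requires a comparator",
           call. = FALSE)
    comp_ids <- intersect(resolve(comparator), all_ids)
    if (length(intersect(comp_ids, exp_ids)))
      stop("exposure and comparator strata must be disjoint", call. = FALSE)
    non_exp <- comp_ids
  } else {
    non_exp <- setdiff(all_ids, exp_ids)
  }
  a <- length(intersect(exp_ids, ev_ids))
  b <- length(exp_ids) - a
  c_ <- length(intersect(non_exp, ev_ids))
  d <- length(non_exp) - c_
  structure(list(a = a, b = b, c = c_, d = d,
                 exposure_label = exposure_label, event_label = event_label,
                 background = background),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2 table> %s x %s (%s)\n  a=%d b=%d c=%d d=%d\n",
              x$exposure_label, x$event_label, x$background,
              x$a, x$b, x$c, x$d))
  invisible(x)
}

cells_of <- function(table, zero_correction = FALSE) {
  cells <- c(a = as.numeric(table$a), b = as.numeric(table$b),
             c = as.numeric(table$c), d = as.numeric(table$d))
  if (zero_correction && any(cells == 0)) cells <- cells + 0.5
  cells
}

#' Reporting odds ratio with Woolf 95% interval
#'
#' ROR = ad/bc; the confidence bounds are
#' exp(ln ROR -/+ 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). With any zero cell the
#' statistic is undefined and returned as `NA` with a reason code; an
#' optional Haldane–Anscombe 0.5 correction can be switched on.
#'
#' @param table a [build_table()] result.
#' @param zero_correction add 0.5 to every cell when any cell is zero
#'   (default off).
#' @return list `ror`, `ci95` (lower, upper), `reason` (`NA` or
#'   `"zero_cell"`).
#' @export
compute_ror <- function(table, zero_correction = FALSE) {
  k <- cells_of(table, zero_correction)
  if (any(k == 0))
    return(list(ror = NA_real_, ci95 = c(NA_real_, NA_real_),
                reason = "zero_cell"))
  ror <- (k["a"] * k["d"]) / (k["b"] * k["c"])
  se <- sqrt(sum(1 / k))
  list(ror = unname(ror),
       ci95 = unname(exp(log(ror) + c(-1, 1) * 1.96 * se)),
       reason = NA_character_)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' PRR = a(c+d) / (c(a+b)); the support statistic is the Pearson
#' chi-squared of the 2x2 table without continuity correction,
#' (ad-bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @inheritParams compute_ror
#' @return list `prr`, `chi2`, `reason`.
#' @export
compute_prr <- function(table, zero_correction = FALSE) {
  k <- cells_of(table, zero_correction)
  if (k["c"] == 0 || (k["a"] + k["b"]) == 0)
    return(list(prr = NA_real_, chi2 = NA_real_, reason = "zero_cell"))
  prr <- (k["a"] * (k["c"] + k["d"])) / (k["c"] * (k["a"] + k["b"]))
  n <- sum(k)
  chi2 <- ((k["a"] * k["d"] - k["b"] * k["c"])^2 * n) /
    ((k["a"] + k["b"]) * (k["c"] + k["d"]) * (k["a"] + k["c"]) * (k["b"] + k["d"]))
  list(prr = unname(prr), chi2 = unname(chi2), reason = NA_character_)
}

#' Information component (BCPNN family)
#'
#' IC = log2( a N / ((a+c)(a+b)) ), the log2 observed-over-expected
#' co-reporting ratio. Two interval variants are provided. `"printed"`
#' follows the source formula literally: IC025 = exp(ln(IC) - 1.96 sqrt(1/a
#' + 1/b + 1/c + 1/d)), which applies exp/ln to the statistic itself and is
#' undefined for IC <= 0 (then the signal can never be positive and IC025 is
#' returned `NA`). `"canonical"` uses the conventional delta-method bound on
#' the log2 scale: IC025 = IC - 1.96 sqrt(1/a+1/b+1/c+1/d)/ln 2.
#'
#' @inheritParams compute_ror
#' @param formula_variant `"printed"` (default) or `"canonical"`.
#' @return list `ic`, `ic025`, `reason`.
#' @export
compute_ic <- function(table, formula_variant = c("printed", "canonical"),
                       zero_correction = FALSE) {
  formula_variant <- match.arg(formula_variant)
  k <- cells_of(table, zero_correction)
  if (any(k == 0))
    return(list(ic = NA_real_, ic025 = NA_real_, reason = "zero_cell"))
  n <- sum(k)
  ic <- log2(k["a"] * n / ((k["a"] + k["c"]) * (k["a"] + k["b"])))
  se <- sqrt(sum(1 / k))
  ic025 <- if (formula_variant == "printed") {
    if (ic > 0) exp(log(ic) - 1.96 * se) else NA_real_
  } else {
    ic - 1.96 * se / log(2)
  }
  list(ic = unname(ic), ic025 = unname(ic025), reason = NA_character_)
}

#' Empirical Bayes geometric mean (non-shrunk observed/expected form)
#'
#' EBGM = a N / ((a+c)(a+b)), the relative reporting ratio; EBGM05 =
#' exp(ln(EBGM) - 1.64 sqrt(1/a+1/b+1/c+1/d)) is its one-sided 5% lower
#' bound. No gamma-Poisson mixture shrinkage is applied: this is the
#' closed-form ratio as used for the thresholds here, not the full MGPS
#' posterior mean.
#'
#' @inheritParams compute_ic
#' @return list `ebgm`, `ebgm05`, `reason`.
#' @export
compute_ebgm <- function(table, formula_variant = c("printed", "canonical"),
                         zero_correction = FALSE) {
  formula_variant <- match.arg(formula_variant)
  k <- cells_of(table, zero_correction)
  if (any(k == 0))
    return(list(ebgm = NA_real_, ebgm05 = NA_real_, reason = "zero_cell"))
  n <- sum(k)
  ebgm <- k["a"] * n / ((k["a"] + k["c"]) * (k["a"] + k["b"]))
  se <- sqrt(sum(1 / k))
  # printed and canonical coincide for this bound (log-scale lower limit)
  ebgm05 <- exp(log(ebgm) - 1.64 * se)
  list(ebgm = unname(ebgm), ebgm05 = unname(ebgm05), reason = NA_character_)
}

#' All four disproportionality statistics for one table
#'
#' @inheritParams compute_ic
#' @return a `signal_statistics` list: `n` (= a), `ror`, `ror_lo`, `ror_hi`,
#'   `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`, `reason`.
#' @export
signal_statistics <- function(table, formula_variant = c("printed", "canonical"),
                              zero_correction = FALSE) {
  formula_variant <- match.arg(formula_variant)
  ror <- compute_ror(table, zero_correction)
  prr <- compute_prr(table, zero_correction)
  ic <- compute_ic(table, formula_variant, zero_correction)
  ebgm <- compute_ebgm(table, formula_variant, zero_correction)
  structure(list(
    n = table$a,
    ror = ror$ror, ror_lo = ror$ci95[1], ror_hi = ror$ci95[2],
    prr = prr$prr, chi2 = prr$chi2,
    ic = ic$ic, ic025 = ic$ic025,
    ebgm = ebgm$ebgm, ebgm05 = ebgm$ebgm05,
    reason = ror$reason,
    exposure_label = table$exposure_label, event_label = table$event_label,
    formula_variant = formula_variant), class = "signal_statistics")
}

#' Signal-positivity thresholds for the four algorithms
#'
#' Defaults are the standard criteria: ROR lower 95% bound > 1 with N >= 2;
#' PRR >= 2 with chi-squared >= 4 and N >= 3; IC025 > 0; EBGM05 > 2 with
#' N > 0. A validated association requires at least `concordance_min`
#' algorithms positive simultaneously.
#'
#' @param ror_n,prr_min,chi2_min,prr_n,ebgm05_min,mgps_n algorithm
#'   thresholds.
#' @param concordance_min number of concordant methods required (1..4).
#' @export
signal_criteria <- function(ror_n = 2, prr_min = 2, chi2_min = 4, prr_n = 3,
                            ebgm05_min = 2, mgps_n = 1, concordance_min = 2) {
  stopifnot(concordance_min >= 1, concordance_min <= 4,
            prr_min > 0, chi2_min > 0, ebgm05_min > 0)
  structure(list(ror_n = ror_n, prr_min = prr_min, chi2_min = chi2_min,
                 prr_n = prr_n, ebgm05_min = ebgm05_min, mgps_n = mgps_n,
                 concordance_min = concordance_min),
            class = "signal_criteria")
}

#' Apply signal criteria to one set of statistics
#'
#' Undefined statistics (zero cells, or the printed IC025 when IC <= 0)
#' count as flag-negative. The verdict `validated` is true when at least
#' `concordance_min` algorithm flags are true.
#'
#' @param stats a [signal_statistics()] result.
#' @param criteria a [signal_criteria()].
#' @return a `signal_result` list: `statistics`, `flags` (named logical:
#'   ror, prr, bcpnn, mgps), `n_positive`, `validated`, labels.
#' @export
evaluate_signal <- function(stats, criteria = signal_criteria()) {
  tf <- function(x) isTRUE(x)
  flags <- c(
    ror = tf(!is.na(stats$ror_lo) && stats$ror_lo > 1 && stats$n >= criteria$ror_n),
    prr = tf(!is.na(stats$prr) && stats$prr >= criteria$prr_min &&
               stats$chi2 >= criteria$chi2_min && stats$n >= criteria$prr_n),
    bcpnn = tf(!is.na(stats$ic025) && stats$ic025 > 0),
    mgps = tf(!is.na(stats$ebgm05) && stats$ebgm05 > criteria$ebgm05_min &&
                stats$n >= criteria$mgps_n)
  )
  structure(list(statistics = stats, flags = flags,
                 n_positive = sum(flags),
                 validated = sum(flags) >= criteria$concordance_min,
                 exposure_label = stats$exposure_label,
                 event_label = stats$event_label),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  s <- x$statistics
  cat(sprintf(
    "<signal> %s x %s: N=%d ROR=%.2f (%.2f, %.2f) PRR=%.2f chi2=%.1f IC=%.2f EBGM=%.2f\n  flags: %s -> %s\n",
    x$exposure_label, x$event_label, s$n, s$ror, s$ror_lo, s$ror_hi,
    s$prr, s$chi2, s$ic, s$ebgm,
    paste(names(x$flags)[x$flags], collapse = "+"),
    if (x$validated) "VALIDATED" else "not validated"))
  invisible(x)
}

#' Tidy one or more signal results
#' @param results a `signal_result` or list of them.
#' @return tibble with one row per result.
#' @export
tidy_signal_results <- function(results) {
  if (inherits(results, "signal_result")) results <- list(results)
  purrr::map_dfr(results, function(r) {
    s <- r$statistics
    tibble::tibble(
      exposure = r$exposure_label, event = r$event_label, n = s$n,
      ror = s$ror, ror_lo = s$ror_lo, ror_hi = s$ror_hi,
      prr = s$prr, chi2 = s$chi2, ic = s$ic, ic025 = s$ic025,
      ebgm = s$ebgm, ebgm05 = s$ebgm05,
      flag_ror = unname(r$flags["ror"]), flag_prr = unname(r$flags["prr"]),
      flag_bcpnn = unname(r$flags["bcpnn"]), flag_mgps = unname(r$flags["mgps"]),
      validated = r$validated)
  })
}
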