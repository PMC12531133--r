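#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: where the report tables live
#' (or an in-memory database), the preferred-term query, the ICI catalog,
#' signal criteria overrides, the interval-formula variant, the early-onset
#' window, the receipt-year span and the output directory.
#'
#' @param input directory of report tables, or an [icsr_db()].
#' @param dialect `"faers_ascii"` or `"csv"` (ignored for in-memory input).
#' @param out_dir output directory for artifacts.
#' @param query a [term_query()] or path to a query YAML.
#' @param catalog ICI catalog or path to a catalog CSV.
#' @param criteria a [signal_criteria()].
#' @param formula_variant `"printed"` or `"canonical"`.
#' @param early_window_days early-onset window (days).
#' @param year_range receipt-year span for annual counts.
#' @param seed seed recorded in the manifest (reserved for resampling
#'   extensions; the core pipeline is deterministic).
#' @export
pipeline_config <- function(input, dialect = "csv", out_dir = tempfile("pv"),
                            query = term_query(), catalog = ici_catalog(),
                            criteria = signal_criteria(),
                            formula_variant = c("printed", "canonical"),
                            early_window_days = 90,
                            year_range = c(2011, 2024), seed = 1L) {
  if (is.character(query)) query <- read_term_query(query)
  if (is.character(catalog)) catalog <- ici_catalog(catalog)
  structure(list(input = input, dialect = dialect, out_dir = out_dir,
                 query = query, catalog = catalog, criteria = criteria,
                 formula_variant = match.arg(formula_variant),
                 early_window_days = early_window_days,
                 year_range = year_range, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Sequences read -> event flagging -> deduplication -> temporal filter ->
#' regimen classification -> descriptive summaries -> regimen-, term- and
#' head-to-head disproportionality screens, writing every artifact as CSV
#' plus a JSON manifest with per-stage counts. Deterministic: identical
#' input and config give byte-identical artifacts.
#'
#' Artifacts written under `out_dir`: `table2.csv` (wide descriptives),
#' `table2_tidy.csv`, `table3.csv` (regimen screen), `table4.csv`
#' (term-level screen), `head_to_head.csv`, `annual_counts.csv`,
#' `tto_summary.csv`, `removed_pairs.csv`, `stage_counts.json`,
#' `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  db <- if (inherits(config$input, "icsr_db")) config$input else
    read_icsr_database(config$input, config$dialect, config$catalog)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  sel <- select_cases(db, config$query, config$catalog)

  summ <- summarize_cases(sel$db |> filter_cases(sel$assignments$case_id),
                          sel$assignments)
  readr::write_csv(descriptives_wide(summ), file.path(out, "table2.csv"),
                   na = "")
  readr::write_csv(summ$counts, file.path(out, "table2_tidy.csv"), na = "")
  readr::write_csv(tto_summary(sel$assignments),
                   file.path(out, "tto_summary.csv"), na = "")
  readr::write_csv(annual_counts(filter_cases(sel$db, sel$assignments$case_id),
                                 config$year_range),
                   file.path(out, "annual_counts.csv"), na = "")
  readr::write_csv(sel$removed_pairs, file.path(out, "removed_pairs.csv"),
                   na = "")

  screen <- regimen_screen(db, config$query, config$criteria, config$catalog,
                           config$formula_variant)
  readr::write_csv(tidy_signal_results(screen), file.path(out, "table3.csv"),
                   na = "")
  pts <- pt_level_screen(db, config$query, config$criteria, config$catalog,
                         formula_variant = config$formula_variant)
  readr::write_csv(pts$results, file.path(out, "table4.csv"), na = "")
  h2h <- tryCatch(
    head_to_head(db, "ipilimumab_nivolumab", "nivolumab", config$query,
                 config$criteria, config$catalog, config$formula_variant),
    error = function(e) NULL)
  if (!is.null(h2h))
    readr::write_csv(tidy_signal_results(h2h),
                     file.path(out, "head_to_head.csv"), na = "")

  early <- early_onset_fraction(sel$assignments, config$early_window_days)
  serious <- serious_fraction(filter_cases(sel$db, sel$assignments$case_id))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsignal")),
    stage_counts = sel$stage_counts,
    n_strata_analyzed = length(unique(sel$assignments$regimen)),
    serious_pct = serious$pct,
    early_onset_pct = if (is.na(early)) NULL else as.numeric(early),
    query_id = config$query$query_id,
    formula_variant = config$formula_variant,
    criteria = unclass(config$criteria),
    year_range = config$year_range,
    seed = config$seed)
  jsonlite::write_json(sel$stage_counts, file.path(out, "stage_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
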