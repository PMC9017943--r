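#' Pipeline run configuration
#'
#' @param extract_path path to the extract CSV.
#' @param reference_path optional path to a national reference CSV
#'   (columns cancer, category, region, n).
#' @param truth_path optional path to a ground-truth JSON (enables the QC
#'   stage on synthetic data).
#' @param catalog a [drug_catalog()].
#' @param out_dir output directory for reports.
#' @param gap_days regimen segmentation threshold (days).
#' @param flag_threshold_pp representativeness flag threshold (percentage
#'   points).
#' @param qc a [qc_params()].
#' @param seed integer seed (QC sampling).
#' @return list of class `run_config`.
#' @export
run_config <- function(extract_path, reference_path = NULL, truth_path = NULL,
                       catalog = default_drug_catalog(), out_dir = tempfile("eprflow_run_"),
                       gap_days = 60, flag_threshold_pp = 4, qc = qc_params(),
                       seed = 1L) {
  stopifnot(gap_days >= 1, flag_threshold_pp >= 0, inherits(qc, "qc_params"))
  structure(list(
    extract_path = extract_path, reference_path = reference_path,
    truth_path = truth_path, catalog = catalog, out_dir = out_dir,
    gap_days = gap_days, flag_threshold_pp = flag_threshold_pp,
    qc = qc, seed = as.integer(seed)
  ), class = "run_config")
}

stage_log <- function(log_path, stage, detail) {
  line <- jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                stage = stage, detail = detail),
                           auto_unbox = TRUE)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  message("[eprflow] ", stage, ": ", detail)
}

#' Run the full data-management pipeline
#'
#' Executes the fixed stage order codify, exclusions, inference, assessment,
#' QC, and writes all reports (JSON plus markdown tables) and a per-center
#' dashboard under `config$out_dir`. Identical config and seed give identical
#' outputs. A stage failure aborts with a stage-named error and removes the
#' partial output directory.
#'
#' @param config a [run_config()].
#' @return run summary list, invisibly: `flowchart`, `completion`, `coverage`,
#'   `representativeness`, `qc`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- config$out_dir
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(created, recursive = TRUE)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  extract <- run_stage("load", {
    x <- read_extract(config$extract_path)
    stage_log(log_path, "load", sprintf("%d records, %d load errors",
                                        nrow(x$records), load_report(x)$n_errors))
    x
  })
  cod <- run_stage("codify", {
    x <- codify_extract(extract, config$catalog)
    stage_log(log_path, "codify", sprintf("matched %d / %d records",
                                          x$report$drug_status$matched, x$report$n_records))
    x
  })
  excl <- run_stage("exclusions", {
    x <- apply_exclusions(cod$extract, config$catalog, config$gap_days)
    stage_log(log_path, "exclusions", sprintf("%d patients excluded (rules R1-R5)",
                                              sum(x$flowchart$excluded$n)))
    x
  })
  inf <- run_stage("inference", {
    x <- run_inference(excl$extract, excl$flowchart, config$gap_days)
    stage_log(log_path, "inference", sprintf("%d field values changed; %d analyzable patients",
                                             nrow(x$audit), sum(x$flowchart$analyzable$n)))
    x
  })

  analyzable_empty <- nrow(inf$extract$records) == 0
  assessment <- NULL
  if (analyzable_empty) {
    warning("analyzable population is empty: assessment skipped", call. = FALSE)
    stage_log(log_path, "assessment", "skipped (empty analyzable population)")
  } else {
    assessment <- run_stage("assessment", {
      completion <- completion_rates(inf$extract)
      counts <- patient_counts_by_stratum(inf$extract)
      coverage <- NULL
      repres <- NULL
      if (!is.null(config$reference_path)) {
        ref_tbl <- readr::read_csv(config$reference_path, show_col_types = FALSE,
                                   progress = FALSE)
        ref <- national_reference(ref_tbl)
        coverage <- coverage_rates(counts, ref)
        repres <- representativeness(counts, ref, config$flag_threshold_pp)
      }
      stage_log(log_path, "assessment", sprintf("%d variables assessed", nrow(completion)))
      list(completion = completion, counts = counts, coverage = coverage,
           representativeness = repres)
    })
  }

  qc_results <- NULL
  if (!is.null(config$truth_path) && nrow(inf$audit) > 0) {
    qc_results <- run_stage("qc", {
      truth <- read_truth(config$truth_path)
      x <- qc_all_algorithms(inf$audit, truth, config$qc, config$seed)
      stage_log(log_path, "qc", sprintf("%d algorithms reviewed", nrow(x)))
      x
    })
  }

  run_stage("reports", {
    write_reports(config$out_dir, inf, assessment, qc_results)
    stage_log(log_path, "reports", paste("written to", config$out_dir))
  })

  invisible(list(
    flowchart = inf$flowchart,
    completion = if (!is.null(assessment)) assessment$completion,
    coverage = if (!is.null(assessment)) assessment$coverage,
    representativeness = if (!is.null(assessment)) assessment$representativeness,
    qc = qc_results,
    audit = inf$audit,
    extract = inf$extract,
    out_dir = config$out_dir
  ))
}

write_reports <- function(out_dir, inf, assessment, qc_results) {
  fc <- inf$flowchart
  write_json_report(list(
    extracted = fc$extracted, excluded = fc$excluded, analyzable = fc$analyzable,
    retention = retention_summary(fc)$overall
  ), file.path(out_dir, "flowchart.json"))
  writeLines(format_flowchart(fc), file.path(out_dir, "flowchart.md"))
  jsonlite::write_json(inf$audit, file.path(out_dir, "inference_audit.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  if (!is.null(assessment)) {
    write_json_report(assessment$completion, file.path(out_dir, "completion.json"))
    writeLines(render_markdown_table(assessment$completion),
               file.path(out_dir, "completion.md"))
    if (!is.null(assessment$coverage)) {
      write_json_report(assessment$coverage, file.path(out_dir, "coverage.json"))
      writeLines(render_markdown_table(assessment$coverage),
                 file.path(out_dir, "coverage.md"))
      write_json_report(assessment$representativeness$by_stratum,
                        file.path(out_dir, "representativeness.json"))
      writeLines(render_markdown_table(assessment$representativeness$by_stratum),
                 file.path(out_dir, "representativeness.md"))
    }
    dashboard <- center_dashboard(inf$extract)
    write_json_report(dashboard, file.path(out_dir, "center_dashboard.json"))
    writeLines(render_markdown_table(dashboard), file.path(out_dir, "center_dashboard.md"))
  }
  if (!is.null(qc_results)) {
    write_json_report(qc_results, file.path(out_dir, "qc.json"))
    writeLines(render_markdown_table(qc_results), file.path(out_dir, "qc.md"))
  }
  invisible(out_dir)
}

#' Per-center activity dashboard
#'
#' The feedback a platform returns to each participating center: patient and
#' administration volumes and completion of the key clinician-entered fields.
#'
#' @param extract an analyzable `epr_extract`.
#' @return tibble, one row per center.
#' @export
center_dashboard <- function(extract) {
  rec <- extract$records
  rec |>
    group_by(.data$center_id) |>
    summarise(
      patients = n_distinct(.data$patient_id),
      administrations = n(),
      stage_completion = mean(!is.na(.data$disease_stage)),
      line_completion = mean(!is.na(.data$treatment_line)),
      cycle_completion = mean(!is.na(.data$cycle_number)),
      .groups = "drop"
    ) |>
    left_join(extract$centers, by = "center_id") |>
    select("center_id", "category", "region", "patients", "administrations",
           dplyr::ends_with("completion"))
}
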