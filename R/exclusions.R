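#' Detect a truncated treatment start
#'
#' A patient's drug history is flagged as truncated (unknown treatment start,
#' typically after an EPR software change) when the earliest regimen block's
#' recorded cycle numbers exist but do not start at 1: the minimum observed
#' `cycle_number` in the first block is present and greater than 1. When no
#' cycle number is recorded in the first block, truncation cannot be asserted
#' and the patient is conservatively kept.
#'
#' @param patient_records one patient's records, canonical order.
#' @param gap_days regimen segmentation gap threshold (see
#'   [segment_regimens()]).
#' @return logical scalar.
#' @export
detect_truncated_start <- function(patient_records, gap_days = 60) {
  if (nrow(patient_records) == 0) return(FALSE)
  seg <- segment_regimens(patient_records, gap_days)
  cyc <- patient_records$cycle_number[seg == 1L]
  cyc <- cyc[!is.na(cyc)]
  length(cyc) > 0 && min(cyc) > 1
}

#' Detect treatment of another concomitant cancer
#'
#' TRUE when any administered INN belongs to the catalog's list of drugs
#' specific to cancers other than the cohort cancers.
#'
#' @param patient_records one patient's codified records.
#' @param catalog a [drug_catalog()].
#' @return logical scalar.
#' @export
detect_other_cancer_treatment <- function(patient_records, catalog) {
  any(norm_text(patient_records$drug_inn) %in% catalog$other_cancer_drugs)
}

new_flowchart <- function(extracted, excluded, analyzable) {
  structure(
    list(extracted = extracted, excluded = excluded, analyzable = analyzable),
    class = "epr_flowchart"
  )
}

#' Build a flow chart from explicit counts
#'
#' Useful for reporting on populations whose per-rule accounting is already
#' known (e.g. published cohort descriptions).
#'
#' @param extracted named integer vector: patients extracted, by cancer.
#' @param excluded tibble with columns `rule`, `cancer`, `n`.
#' @param analyzable named integer vector: analyzable patients, by cancer. If
#'   omitted, computed as extracted minus exclusions.
#' @return an `epr_flowchart`.
#' @export
flowchart <- function(extracted, excluded, analyzable = NULL) {
  extracted_tbl <- tibble(cancer = names(extracted), n = as.integer(extracted))
  excluded <- tibble::as_tibble(excluded)
  stopifnot(all(excluded$rule %in% EXCLUSION_RULES))
  if (is.null(analyzable)) {
    excl_by_cancer <- excluded |>
      group_by(.data$cancer) |>
      summarise(n_excl = sum(.data$n), .groups = "drop")
    analyzable_tbl <- left_join(extracted_tbl, excl_by_cancer, by = "cancer") |>
      mutate(n = .data$n - dplyr::coalesce(.data$n_excl, 0L)) |>
      select("cancer", "n")
  } else {
    analyzable_tbl <- tibble(cancer = names(analyzable), n = as.integer(analyzable))
  }
  fc <- new_flowchart(extracted_tbl, excluded, analyzable_tbl)
  stopifnot(flowchart_conserved(fc))
  fc
}

#' Flow-chart conservation invariant
#'
#' Checks that extracted = analyzable + sum of exclusions, per cancer and
#' overall.
#'
#' @param fc an `epr_flowchart`.
#' @return logical scalar.
#' @export
flowchart_conserved <- function(fc) {
  per_cancer <- fc$extracted |>
    left_join(
      fc$excluded |> group_by(.data$cancer) |> summarise(n_excl = sum(.data$n), .groups = "drop"),
      by = "cancer"
    ) |>
    left_join(fc$analyzable |> dplyr::rename(n_ana = "n"), by = "cancer") |>
    mutate(
      n_excl = dplyr::coalesce(.data$n_excl, 0L),
      n_ana = dplyr::coalesce(.data$n_ana, 0L)
    )
  all(per_cancer$n == per_cancer$n_excl + per_cancer$n_ana)
}

#' Retention and exclusion summary of a flow chart
#'
#' @param fc an `epr_flowchart`.
#' @return list with `per_cancer` (tibble: cancer, extracted, analyzable,
#'   retention_rate, retention_pct displayed as whole percent) and `overall`
#'   (extracted, excluded, analyzable, exclusion_share_pct displayed with one
#'   decimal). Display rounding is half-away-from-zero.
#' @export
retention_summary <- function(fc) {
  per_cancer <- fc$extracted |>
    dplyr::rename(extracted = "n") |>
    left_join(fc$analyzable |> dplyr::rename(analyzable = "n"), by = "cancer") |>
    mutate(
      analyzable = dplyr::coalesce(.data$analyzable, 0L),
      retention_rate = .data$analyzable / .data$extracted,
      retention_pct = round_half_up(100 * .data$retention_rate)
    )
  extracted_total <- sum(fc$extracted$n)
  excluded_total <- sum(fc$excluded$n)
  list(
    per_cancer = per_cancer,
    overall = list(
      extracted = extracted_total,
      excluded = excluded_total,
      analyzable = sum(fc$analyzable$n),
      exclusion_share = excluded_total / extracted_total,
      exclusion_share_pct = round_half_up(100 * excluded_total / extracted_total, 1)
    )
  )
}

#' @export
print.epr_flowchart <- function(x, ...) {
  cat(format_flowchart(x), sep = "\n")
  invisible(x)
}

#' Render a flow chart as text
#' @param fc an `epr_flowchart`.
#' @return character vector of lines.
#' @export
format_flowchart <- function(fc) {
  fmt_counts <- function(tbl) {
    paste(sprintf("%s: %d", tbl$cancer, tbl$n), collapse = ", ")
  }
  by_rule <- fc$excluded |>
    group_by(.data$rule) |>
    summarise(n = sum(.data$n), .groups = "drop")
  lines <- c(
    sprintf("Extracted population   (%d): %s", sum(fc$extracted$n), fmt_counts(fc$extracted))
  )
  for (r in EXCLUSION_RULES) {
    nr <- by_rule$n[by_rule$rule == r]
    if (length(nr) && nr > 0) lines <- c(lines, sprintf("  - excluded %-24s %d", r, nr))
  }
  c(lines, sprintf("Analyzable population  (%d): %s", sum(fc$analyzable$n), fmt_counts(fc$analyzable)))
}

#' Apply the five patient-removal rules
#'
#' Data-management step two. Patients are removed (all of their records) when
#' they trigger any of:
#' * `R1_truncated` - treatment sequence with unknown start
#'   ([detect_truncated_start()]);
#' * `R2_name_mismatch` - at least one record whose brand does not match the
#'   recorded drug name (`match_status == "brand_conflict"`);
#' * `R3_duplicate_injection` - two administrations of the same INN on the same
#'   day (coding-error suspicion);
#' * `R4_multi_primary` - two or more distinct primary cancer diagnoses
#'   recorded across the patient's records;
#' * `R5_other_cancer_drug` - administration of a drug specific to another
#'   cancer ([detect_other_cancer_treatment()]).
#'
#' Rule precedence is the listing order R1 > R2 > R3 > R4 > R5: each excluded
#' patient is counted once, under the first rule triggered, so flow-chart
#' counts are disjoint.
#'
#' @param extract a codified `epr_extract` (see [codify_extract()]).
#' @param catalog a [drug_catalog()].
#' @param gap_days regimen segmentation threshold for R1.
#' @return list with `extract` (retained patients only) and `flowchart`
#'   (an `epr_flowchart`; the post-inference rule `R6_stage_unresolved` is
#'   added later by [run_inference()]).
#' @export
apply_exclusions <- function(extract, catalog, gap_days = 60) {
  rec <- extract$records
  if (!"match_status" %in% names(rec)) {
    stop("extract must be codified before exclusions (run codify_extract)", call. = FALSE)
  }
  rec <- sort_canonical(rec)
  pkey <- patient_key(rec$center_id, rec$patient_id)

  # vectorized record-level signals
  dup_key <- paste(pkey, rec$drug_inn, rec$administration_date, sep = "\x1f")
  dup_key[is.na(rec$drug_inn)] <- NA
  is_dup <- !is.na(dup_key) & (duplicated(dup_key) | duplicated(dup_key, fromLast = TRUE))
  other_drug <- norm_text(rec$drug_inn) %in% catalog$other_cancer_drugs
  conflict <- rec$match_status == "brand_conflict"

  patients <- split(seq_len(nrow(rec)), factor(pkey, levels = unique(pkey)))
  rules <- vapply(patients, function(idx) {
    pr <- rec[idx, , drop = FALSE]
    if (detect_truncated_start(pr, gap_days)) return("R1_truncated")
    if (any(conflict[idx])) return("R2_name_mismatch")
    if (any(is_dup[idx])) return("R3_duplicate_injection")
    if (n_distinct(pr$diagnosis, na.rm = TRUE) >= 2) return("R4_multi_primary")
    if (any(other_drug[idx])) return("R5_other_cancer_drug")
    NA_character_
  }, character(1))

  rules <- unname(rules)
  cancers <- unname(vapply(patients, function(idx) patient_cancer(rec[idx, , drop = FALSE]),
                           character(1)))

  extracted <- tibble(cancer = cancers) |> count(.data$cancer, name = "n")
  excluded <- tibble(rule = rules, cancer = cancers) |>
    filter(!is.na(.data$rule)) |>
    count(.data$rule, .data$cancer, name = "n")
  analyzable <- tibble(cancer = cancers[is.na(rules)]) |> count(.data$cancer, name = "n")
  # keep every extracted cancer class in the analyzable margin (possibly 0)
  analyzable <- left_join(extracted["cancer"], analyzable, by = "cancer") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))

  keep_idx <- unlist(patients[is.na(rules)], use.names = FALSE)
  extract$records <- rec[sort(keep_idx), , drop = FALSE]
  fc <- new_flowchart(extracted, excluded, analyzable)
  stopifnot(flowchart_conserved(fc))
  list(extract = extract, flowchart = fc)
}
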