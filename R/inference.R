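#' Regimen-label keyword map
#'
#' Plain CSV (`keyword`, `stage`) mapping normalized substrings of regimen
#' labels to disease stages, used by the `S2_regimen_keyword` rule. Editable
#' without code changes.
#'
#' @param path optional replacement table.
#' @return tibble with columns `keyword`, `stage`.
#' @export
regimen_keyword_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "regimen_keywords.csv", package = "eprflow")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

label_stage <- function(labels, keywords) {
  lab <- norm_text(labels)
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) return(NA_character_)
  hits <- keywords$stage[vapply(keywords$keyword, function(k) any(grepl(k, lab, fixed = TRUE)), logical(1))]
  if (length(hits) == 0) return(NA_character_)
  # several keywords: keep the highest severity mentioned
  STAGE_LEVELS[max(stage_severity(hits))]
}

audit_entry <- function(records, idx, algorithm_id, field, before, after) {
  tibble(
    center_id = records$center_id[idx],
    patient_id = records$patient_id[idx],
    row_id = records$.row_id[idx],
    algorithm_id = algorithm_id,
    field = field,
    before = as.character(before),
    after = as.character(after)
  )
}

#' Infer disease stage for one patient
#'
#' Three pluggable rules, applied in order, each identified in the audit trail
#' so alternative rule sets can replace them:
#' * `S1_fill_within_regimen` - a missing stage is copied from the nearest
#'   record of the same regimen block carrying a recorded stage (looking
#'   backward first, then forward);
#' * `S2_regimen_keyword` - a regimen block still entirely missing gets the
#'   stage implied by its regimen label, via [regimen_keyword_map()];
#' * `S3_severity_ratchet` - consistency over time: a recorded stage strictly
#'   below the running maximum severity is corrected up to it (a cancer's
#'   stage does not regress).
#'
#' @param patient_records one patient's codified records, canonical order.
#' @param gap_days regimen segmentation threshold.
#' @param keywords keyword map for S2.
#' @return list with `records` (stages completed where possible), `audit`
#'   (tibble of changes) and `resolved` (TRUE when no record is left with a
#'   missing stage).
#' @export
infer_stage <- function(patient_records, gap_days = 60, keywords = regimen_keyword_map()) {
  rec <- patient_records
  n <- nrow(rec)
  audit <- list()
  if (n > 0) {
    seg <- segment_regimens(rec, gap_days)
    s <- rec$disease_stage
    orig_known <- which(!is.na(s))
    # S1: nearest same-regimen fill, backward preferred
    for (i in which(is.na(s))) {
      cand <- orig_known[seg[orig_known] == seg[i]]
      if (length(cand) == 0) next
      back <- cand[cand < i]
      src <- if (length(back)) max(back) else min(cand)
      audit[[length(audit) + 1]] <- audit_entry(rec, i, "S1_fill_within_regimen",
                                                "disease_stage", NA, s[src])
      s[i] <- s[src]
    }
    # S2: regimen-label keyword for blocks still fully missing
    for (b in unique(seg)) {
      idx <- which(seg == b)
      if (!all(is.na(s[idx]))) next
      st <- label_stage(rec$regimen_label[idx], keywords)
      if (is.na(st)) next
      for (i in idx) {
        audit[[length(audit) + 1]] <- audit_entry(rec, i, "S2_regimen_keyword",
                                                  "disease_stage", NA, st)
      }
      s[idx] <- st
    }
    # S3: severity ratchet
    runmax <- -Inf
    for (i in seq_len(n)) {
      sev <- stage_severity(s[i])
      if (is.na(s[i])) next
      if (sev < runmax) {
        corrected <- STAGE_LEVELS[runmax]
        audit[[length(audit) + 1]] <- audit_entry(rec, i, "S3_severity_ratchet",
                                                  "disease_stage", s[i], corrected)
        s[i] <- corrected
      } else {
        runmax <- max(runmax, sev)
      }
    }
    rec$disease_stage <- s
  }
  audit <- if (length(audit)) bind_rows(audit) else empty_audit()
  list(records = rec, audit = audit, resolved = n == 0 || !anyNA(rec$disease_stage))
}

empty_audit <- function() {
  tibble(center_id = character(0), patient_id = character(0), row_id = integer(0),
         algorithm_id = character(0), field = character(0),
         before = character(0), after = character(0))
}

#' Infer treatment line for one patient
#'
#' Runs after stage inference. Lines are numbered within a disease phase
#' (pre-metastatic vs metastatic; numbering restarts at the metastatic
#' transition, the standard oncology convention). Rules, in order:
#' * `L1_fill_within_regimen` - a missing line within a regimen block that has
#'   a recorded line takes that block's recorded line;
#' * `L2_regimen_change_increment` - a block with no recorded line at all is
#'   numbered by continuing from the last known line of the phase (1 at phase
#'   start), incrementing by one at each block boundary (regimen-composition
#'   change or treatment-free gap longer than `gap_days`);
#' * `L3_monotonic_correction` - within a phase, lines are forced
#'   non-decreasing (violations raised to the running maximum).
#'
#' @param patient_records one patient's records with stages already inferred.
#' @param gap_days regimen segmentation threshold.
#' @return list with `records` and `audit`.
#' @export
infer_line <- function(patient_records, gap_days = 60) {
  rec <- patient_records
  n <- nrow(rec)
  audit <- list()
  if (n > 0) {
    seg <- segment_regimens(rec, gap_days)
    phase <- ifelse(!is.na(rec$disease_stage) & rec$disease_stage == "metastatic", 2L, 1L)
    # a block spanning the phase transition is split at the boundary
    block <- cumsum(c(1L, diff(seg) != 0L | diff(phase) != 0L))
    ln <- as.integer(rec$treatment_line)

    # L1: within-block fill from the block's recorded line
    for (b in unique(block)) {
      idx <- which(block == b)
      known <- ln[idx][!is.na(ln[idx])]
      if (length(known) == 0 || !anyNA(ln[idx])) next
      fill <- known[[1]]
      for (i in idx[is.na(ln[idx])]) {
        audit[[length(audit) + 1]] <- audit_entry(rec, i, "L1_fill_within_regimen",
                                                  "treatment_line", NA, fill)
        ln[i] <- fill
      }
    }
    # L2: number the still-unlabelled blocks phase by phase
    for (ph in unique(phase)) {
      blocks <- unique(block[phase == ph])
      last_line <- NA_integer_
      for (b in blocks) {
        idx <- which(block == b)
        if (all(is.na(ln[idx]))) {
          new_line <- if (is.na(last_line)) 1L else last_line + 1L
          for (i in idx) {
            audit[[length(audit) + 1]] <- audit_entry(rec, i, "L2_regimen_change_increment",
                                                      "treatment_line", NA, new_line)
          }
          ln[idx] <- new_line
        }
        last_line <- max(ln[idx])
      }
    }
    # L3: non-decreasing within a phase
    for (ph in unique(phase)) {
      idx <- which(phase == ph)
      runmax <- -Inf
      for (i in idx) {
        if (is.na(ln[i])) next
        if (ln[i] < runmax) {
          audit[[length(audit) + 1]] <- audit_entry(rec, i, "L3_monotonic_correction",
                                                    "treatment_line", ln[i], runmax)
          ln[i] <- as.integer(runmax)
        } else {
          runmax <- max(runmax, ln[i])
        }
      }
    }
    rec$treatment_line <- as.integer(ln)
  }
  audit <- if (length(audit)) bind_rows(audit) else empty_audit()
  list(records = rec, audit = audit)
}

#' Run stage and line inference over an extract
#'
#' Data-management step three. Applies [infer_stage()] to every patient;
#' patients whose disease stage is still missing on any record afterwards are
#' removed and counted under `R6_stage_unresolved` in the flow chart, and
#' [infer_line()] completes treatment lines for the stage-resolved patients.
#' Among retained patients, disease stage and treatment line are 100% complete
#' by construction.
#'
#' @param extract an `epr_extract` with exclusions already applied.
#' @param flowchart the `epr_flowchart` from [apply_exclusions()].
#' @param gap_days regimen segmentation threshold.
#' @param keywords keyword map for S2.
#' @return list with `extract` (retained, inferred), `flowchart` (with the R6
#'   row added), and `audit` (tibble of every field change, one entry per
#'   modified value).
#' @export
run_inference <- function(extract, flowchart, gap_days = 60,
                          keywords = regimen_keyword_map()) {
  patients <- split_patients(extract$records)
  audits <- vector("list", length(patients))
  resolved <- logical(length(patients))
  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    st <- infer_stage(patients[[i]], gap_days, keywords)
    resolved[i] <- st$resolved
    if (st$resolved) {
      # line numbering depends on the stage phases, so it is only meaningful
      # (and only audited) for stage-resolved patients; the others are about
      # to be excluded under R6
      li <- infer_line(st$records, gap_days)
      out[[i]] <- li$records
      audits[[i]] <- bind_rows(st$audit, li$audit)
    } else {
      out[[i]] <- st$records
      audits[[i]] <- st$audit
    }
  }
  audit <- if (length(audits)) bind_rows(audits) else empty_audit()

  unresolved <- out[!resolved]
  if (length(unresolved) > 0) {
    r6_cancers <- vapply(unresolved, patient_cancer, character(1))
    r6 <- tibble(cancer = r6_cancers) |>
      count(.data$cancer, name = "n") |>
      mutate(rule = "R6_stage_unresolved", .before = 1)
    flowchart$excluded <- bind_rows(flowchart$excluded, r6)
    flowchart$analyzable <- flowchart$analyzable |>
      left_join(r6 |> select("cancer", n_r6 = "n"), by = "cancer") |>
      mutate(n = .data$n - dplyr::coalesce(.data$n_r6, 0L)) |>
      select("cancer", "n")
  }
  stopifnot(flowchart_conserved(flowchart))

  kept <- out[resolved]
  extract$records <- if (length(kept)) bind_rows(kept) else empty_records()
  list(extract = extract, flowchart = flowchart, audit = audit)
}

#' Text timeline of one patient's history
#'
#' Renders administrations with stage and line before/after inference, a
#' lightweight stand-in for an interactive review interface.
#'
#' @param before,after one patient's records pre/post inference (same rows).
#' @return character vector of lines.
#' @export
render_timeline <- function(before, after) {
  stopifnot(nrow(before) == nrow(after))
  header <- sprintf("patient %s @ %s", before$patient_id[1], before$center_id[1])
  body <- sprintf(
    "%s  %-24s stage: %-16s -> %-16s line: %s -> %s",
    format(after$administration_date), substr(after$drug_inn, 1, 24),
    ifelse(is.na(before$disease_stage), "?", before$disease_stage),
    ifelse(is.na(after$disease_stage), "?", after$disease_stage),
    ifelse(is.na(before$treatment_line), "?", before$treatment_line),
    ifelse(is.na(after$treatment_line), "?", after$treatment_line)
  )
  c(header, body)
}
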