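#' @importFrom rlang %||% .data
#' @importFrom dplyr group_by ungroup summarise mutate filter select arrange
#'   bind_rows left_join n n_distinct distinct across all_of first count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats qbeta chisq.test setNames
NULL

# Canonical stage vocabulary, ordered by severity.
STAGE_LEVELS <- c("early", "locally_advanced", "metastatic")

EXCLUSION_RULES <- c(
  "R1_truncated", "R2_name_mismatch", "R3_duplicate_injection",
  "R4_multi_primary", "R5_other_cancer_drug", "R6_stage_unresolved"
)

STAGE_ALGOS <- c("S1_fill_within_regimen", "S2_regimen_keyword", "S3_severity_ratchet")
LINE_ALGOS <- c("L1_fill_within_regimen", "L2_regimen_change_increment", "L3_monotonic_correction")

stage_severity <- function(stage) {
  match(stage, STAGE_LEVELS)
}

#' Normalize free text for dictionary lookup
#'
#' Lower-cases, strips diacritics, collapses internal whitespace and trims.
#' Used for all drug-name and synonym matching; matching is exact after this
#' normalization (no fuzzy distance).
#'
#' @param x character vector.
#' @return normalized character vector, `NA` preserved.
#' @keywords internal
norm_text <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- iconv(out, from = "UTF-8", to = "ASCII//TRANSLIT")
  # glibc transliteration marks accents with ' ` ^ " ~ ; drop the marks
  out <- gsub("['`^\"~]", "", out)
  out <- gsub("[^a-z0-9]+", " ", out)
  out <- trimws(gsub("\\s+", " ", out))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

# Round half away from zero (display convention for printed percentages;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Composite patient key: patient_id is only unique within a center.
patient_key <- function(center_id, patient_id) {
  paste(center_id, patient_id, sep = "\x1f")
}

# Canonical within-patient order: administration_date, INN (lexical, NA last),
# cycle_number (NA last), then input row order. Deterministic by construction.
canonical_order <- function(records) {
  order(
    patient_key(records$center_id, records$patient_id),
    records$administration_date,
    xtfrm(records$drug_inn),
    records$cycle_number,
    records$.row_id,
    na.last = TRUE,
    method = "radix"
  )
}

sort_canonical <- function(records) {
  records[canonical_order(records), , drop = FALSE]
}

#' Segment one patient's timeline into regimen blocks
#'
#' A regimen is a maximal run of administration dates sharing the same set of
#' standardized drug names (INN-set equality), with a new block opened whenever
#' the drug set changes or a treatment-free gap longer than `gap_days` occurs.
#' Records on the same calendar day always belong to the same block.
#'
#' @param records one patient's records in canonical order.
#' @param gap_days gap threshold in days (default 60, about one cycle
#'   frequency of slack over typical 21-28 day cycles).
#' @return integer vector of block ids (1, 2, ...), one per record.
#' @keywords internal
segment_regimens <- function(records, gap_days = 60) {
  n <- nrow(records)
  if (n == 0L) return(integer(0))
  dates <- records$administration_date
  inns <- ifelse(is.na(records$drug_inn), paste0("?", norm_text(records$drug_raw)), records$drug_inn)
  udates <- sort(unique(dates))
  sets <- vapply(
    udates,
    function(d) paste(sort(unique(inns[dates == d])), collapse = "|"),
    character(1)
  )
  block <- integer(length(udates))
  block[1] <- 1L
  if (length(udates) > 1) {
    for (i in 2:length(udates)) {
      new_block <- !identical(sets[i], sets[i - 1]) ||
        as.numeric(udates[i] - udates[i - 1]) > gap_days
      block[i] <- block[i - 1] + as.integer(new_block)
    }
  }
  block[match(dates, udates)]
}

# Split a records tibble into a list of per-patient tibbles in canonical order.
split_patients <- function(records) {
  records <- sort_canonical(records)
  key <- patient_key(records$center_id, records$patient_id)
  split(records, factor(key, levels = unique(key)))
}

# Dominant cancer class of one patient: first non-missing diagnosis in
# canonical order, else "unknown".
patient_cancer <- function(records) {
  dx <- records$diagnosis[!is.na(records$diagnosis)]
  if (length(dx) == 0) "unknown" else dx[[1]]
}

# Per-patient cancer lookup table for a whole extract.
patient_cancer_table <- function(records) {
  records <- sort_canonical(records)
  records |>
    mutate(.pkey = patient_key(.data$center_id, .data$patient_id)) |>
    group_by(.data$.pkey, .data$center_id, .data$patient_id) |>
    summarise(
      cancer = {
        dx <- .data$diagnosis[!is.na(.data$diagnosis)]
        if (length(dx) == 0) "unknown" else dx[[1]]
      },
      .groups = "drop"
    )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# Render a tibble as a GitHub-style markdown table (for reports/dashboards).
render_markdown_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}
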