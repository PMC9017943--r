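#' @title EPR extract schema
#' @description Column names and types for a flat administration-level extract,
#'   one row per injectable-drug administration. The same dictionary is shipped
#'   as `inst/extdata/data_dictionary.csv`.
#' @keywords internal
epr_schema <- function() {
  tibble::tribble(
    ~column, ~type, ~mandatory,
    "center_id", "character", TRUE,
    "center_category", "character", FALSE,
    "center_region", "character", FALSE,
    "patient_id", "character", TRUE,
    "birth_year", "integer", FALSE,
    "gender", "character", FALSE,
    "weight", "double", FALSE,
    "height", "double", FALSE,
    "ecog", "integer", FALSE,
    "diagnosis", "character", FALSE,
    "disease_stage", "character", FALSE,
    "metastasis_sites", "character", FALSE,
    "oncogenic_driver", "character", FALSE,
    "drug_raw", "character", TRUE,
    "drug_inn", "character", FALSE,
    "drug_brand", "character", FALSE,
    "dose", "double", TRUE,
    "administration_date", "date", TRUE,
    "treatment_line", "integer", FALSE,
    "cycle_number", "integer", FALSE,
    "frequency_days", "integer", FALSE,
    "regimen_label", "character", FALSE,
    "estimated_duration_days", "integer", FALSE,
    "response", "character", FALSE,
    "response_date", "date", FALSE,
    "discontinuation_motive", "character", FALSE,
    "discontinuation_date", "date", FALSE,
    "trial_name", "character", FALSE
  )
}

CENTER_CATEGORIES <- c("GH_NFPH", "UH", "CCC", "PH")
CENTER_REGIONS <- c("North", "East", "SouthEast", "SouthWest", "West", "ParisArea")

record_columns <- function() {
  setdiff(epr_schema()$column, c("center_category", "center_region"))
}

empty_records <- function() {
  sch <- epr_schema()
  sch <- sch[sch$column %in% record_columns(), ]
  cols <- lapply(seq_len(nrow(sch)), function(i) {
    switch(sch$type[i],
      character = character(0),
      integer = integer(0),
      double = double(0),
      date = as.Date(character(0))
    )
  })
  names(cols) <- sch$column
  out <- tibble::as_tibble(cols)
  out$.row_id <- integer(0)
  out
}

#' Construct an EPR extract
#'
#' An extract is the pipeline's working set: an administration-level record
#' table plus center metadata.
#'
#' @param records tibble with the columns of [epr_schema()] (center category and
#'   region live in `centers`); a `.row_id` column is added if absent.
#' @param centers tibble with columns `center_id`, `category`, `region`.
#' @param extraction_date date of extraction.
#' @return object of class `epr_extract` with elements `records`, `centers`,
#'   `extraction_date`.
#' @export
epr_extract <- function(records = empty_records(),
                        centers = tibble(center_id = character(0),
                                         category = character(0),
                                         region = character(0)),
                        extraction_date = Sys.Date()) {
  records <- tibble::as_tibble(records)
  if (!".row_id" %in% names(records)) {
    records$.row_id <- seq_len(nrow(records))
  }
  centers <- tibble::as_tibble(centers)
  if (anyDuplicated(centers$center_id)) {
    stop("duplicate center_id in centers table", call. = FALSE)
  }
  missing_centers <- setdiff(unique(records$center_id), centers$center_id)
  if (length(missing_centers) > 0) {
    centers <- bind_rows(centers, tibble(
      center_id = missing_centers,
      category = NA_character_, region = NA_character_
    ))
  }
  structure(
    list(records = records, centers = centers,
         extraction_date = as.Date(extraction_date)),
    class = "epr_extract"
  )
}

#' @export
print.epr_extract <- function(x, ...) {
  np <- n_distinct(patient_key(x$records$center_id, x$records$patient_id))
  cat(sprintf(
    "<epr_extract> %d administrations, %d patients, %d centers (extracted %s)\n",
    nrow(x$records), np, nrow(x$centers), format(x$extraction_date)
  ))
  invisible(x)
}

#' Number of distinct patients in an extract
#' @param extract an `epr_extract`.
#' @return integer count of distinct (center, patient) pairs.
#' @export
n_patients <- function(extract) {
  n_distinct(patient_key(extract$records$center_id, extract$records$patient_id))
}

parse_typed_column <- function(x, type, column) {
  n <- length(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  ok_idx <- !is.na(x)
  if (type == "character") {
    return(list(values = x, bad = logical(n)))
  }
  if (type == "date") {
    suppressWarnings(v <- as.Date(x, format = "%Y-%m-%d"))
    bad <- ok_idx & is.na(v)
    return(list(values = v, bad = bad))
  }
  suppressWarnings(num <- as.numeric(x))
  bad <- ok_idx & is.na(num)
  if (column == "dose") {
    bad <- bad | (!is.na(num) & num <= 0)
    num[!is.na(num) & num <= 0] <- NA_real_
  }
  if (type == "integer") {
    bad <- bad | (!is.na(num) & num != floor(num))
    num[!is.na(num) & num != floor(num)] <- NA_real_
    v <- as.integer(num)
  } else {
    v <- num
  }
  v[bad] <- NA
  list(values = v, bad = bad)
}

#' Read a delimited EPR extract
#'
#' Reads a UTF-8, comma-delimited extract (one row per administration,
#' ISO-8601 dates, empty cell = missing). Rows with unparseable typed fields
#' are retained with the field set missing, and the problem is recorded in the
#' load report; no row is ever silently dropped. Extra columns are tolerated;
#' a missing mandatory column is a fatal schema error.
#'
#' @param path path to the CSV file.
#' @param extraction_date extraction date to stamp on the result.
#' @return an [epr_extract()] with a `load_report` attribute: a list with
#'   `n_rows`, `n_errors` and an `errors` tibble (`row`, `column`, `value`,
#'   `message`).
#' @export
read_extract <- function(path, extraction_date = Sys.Date()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  sch <- epr_schema()
  mandatory <- sch$column[sch$mandatory]
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  errors <- list()
  rec <- empty_records()[, setdiff(names(empty_records()), ".row_id")]
  rec_sch <- sch[sch$column %in% record_columns(), ]
  cols <- list()
  for (i in seq_len(nrow(rec_sch))) {
    cn <- rec_sch$column[i]
    x <- if (cn %in% names(raw)) raw[[cn]] else rep(NA_character_, n)
    parsed <- parse_typed_column(x, rec_sch$type[i], cn)
    cols[[cn]] <- parsed$values
    if (any(parsed$bad)) {
      errors[[length(errors) + 1]] <- tibble(
        row = which(parsed$bad), column = cn,
        value = x[parsed$bad],
        message = sprintf("unparseable or invalid %s; set to missing", rec_sch$type[i])
      )
    }
  }
  records <- tibble::as_tibble(cols)
  records$.row_id <- seq_len(n)
  centers <- tibble(
    center_id = records$center_id,
    category = if ("center_category" %in% names(raw)) raw$center_category else NA_character_,
    region = if ("center_region" %in% names(raw)) raw$center_region else NA_character_
  )
  centers <- distinct(centers[!is.na(centers$center_id), ], .data$center_id, .keep_all = TRUE)
  bad_cat <- !is.na(centers$category) & !centers$category %in% CENTER_CATEGORIES
  bad_reg <- !is.na(centers$region) & !centers$region %in% CENTER_REGIONS
  if (any(bad_cat)) {
    errors[[length(errors) + 1]] <- tibble(
      row = NA_integer_, column = "center_category", value = centers$category[bad_cat],
      message = "unknown center category; set to missing"
    )
    centers$category[bad_cat] <- NA_character_
  }
  if (any(bad_reg)) {
    errors[[length(errors) + 1]] <- tibble(
      row = NA_integer_, column = "center_region", value = centers$region[bad_reg],
      message = "unknown center region; set to missing"
    )
    centers$region[bad_reg] <- NA_character_
  }
  errors <- if (length(errors)) bind_rows(errors) else
    tibble(row = integer(0), column = character(0), value = character(0), message = character(0))
  out <- epr_extract(records, centers, extraction_date)
  attr(out, "load_report") <- list(n_rows = n, n_errors = nrow(errors), errors = errors)
  out
}

#' Load report of a read extract
#' @param extract an extract produced by [read_extract()].
#' @return list with `n_rows`, `n_errors`, `errors`, or `NULL` when the extract
#'   was built in memory.
#' @export
load_report <- function(extract) {
  attr(extract, "load_report")
}

#' Write an EPR extract to a delimited file
#'
#' Inverse of [read_extract()]: UTF-8 CSV, ISO-8601 dates, empty cells for
#' missing values; center category and region are denormalized onto each row so
#' a single file round-trips the full extract.
#'
#' @param extract an `epr_extract`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extract <- function(extract, path) {
  rec <- extract$records
  rec <- left_join(rec, extract$centers, by = "center_id")
  names(rec)[names(rec) == "category"] <- "center_category"
  names(rec)[names(rec) == "region"] <- "center_region"
  ord <- intersect(epr_schema()$column, names(rec))
  rec <- rec[, ord]
  readr::write_csv(rec, path, na = "")
  invisible(path)
}

#' Build a drug catalog
#'
#' The catalog drives drug-name standardization and the other-cancer exclusion
#' rule: a brand-to-INN map, the set of INNs specific to cancers other than the
#' cohort cancers (their administration flags a concomitant other cancer), and
#' the cohort-defining drugs of interest.
#'
#' @param inn_by_brand tibble with columns `brand`, `inn`.
#' @param other_cancer_drugs character vector of INNs.
#' @param drugs_of_interest character vector of INNs; every cohort patient must
#'   have received at least one of these.
#' @return object of class `drug_catalog`.
#' @export
drug_catalog <- function(inn_by_brand, other_cancer_drugs, drugs_of_interest) {
  inn_by_brand <- tibble::as_tibble(inn_by_brand)
  stopifnot(all(c("brand", "inn") %in% names(inn_by_brand)))
  inn_by_brand$brand_norm <- norm_text(inn_by_brand$brand)
  if (anyDuplicated(inn_by_brand$brand_norm)) {
    stop("each brand must map to exactly one INN", call. = FALSE)
  }
  other_cancer_drugs <- unique(norm_text(other_cancer_drugs))
  drugs_of_interest <- unique(norm_text(drugs_of_interest))
  if (length(intersect(drugs_of_interest, other_cancer_drugs)) > 0) {
    stop("drugs_of_interest and other_cancer_drugs must be disjoint", call. = FALSE)
  }
  structure(
    list(inn_by_brand = inn_by_brand,
         other_cancer_drugs = other_cancer_drugs,
         drugs_of_interest = drugs_of_interest),
    class = "drug_catalog"
  )
}

#' Default drug catalog shipped with the package
#'
#' Built from the plain-text tables under `inst/extdata/`: `drug_brands.csv`
#' (brand-to-INN) and `other_cancer_drugs.csv`. The other-cancer list is a
#' synthetic seed assembled for testing (drugs essentially specific to
#' hematologic and other non-breast, non-lung cancers), not a reproduction of
#' any program's validated list; it is editable without code changes.
#'
#' @return a [drug_catalog()].
#' @export
default_drug_catalog <- function() {
  brands <- readr::read_csv(
    system.file("extdata", "drug_brands.csv", package = "eprflow"),
    show_col_types = FALSE, progress = FALSE
  )
  other <- readr::read_csv(
    system.file("extdata", "other_cancer_drugs.csv", package = "eprflow"),
    show_col_types = FALSE, progress = FALSE
  )
  drug_catalog(
    inn_by_brand = brands,
    other_cancer_drugs = other$inn,
    drugs_of_interest = c("trastuzumab", "trastuzumab emtansine", "pertuzumab",
                          "bevacizumab", "atezolizumab")
  )
}

#' Validate extract invariants
#'
#' Checks structural invariants: positive doses, administration dates present,
#' cycle numbers >= 1, consistent per-patient demographics, known centers.
#'
#' @param extract an `epr_extract`.
#' @return tibble of violations (`check`, `n`); zero rows when valid.
#' @export
validate_extract <- function(extract) {
  rec <- extract$records
  out <- list()
  add <- function(check, n) {
    if (n > 0) out[[length(out) + 1]] <<- tibble(check = check, n = as.integer(n))
  }
  add("dose_nonpositive", sum(!is.na(rec$dose) & rec$dose <= 0))
  add("administration_date_missing", sum(is.na(rec$administration_date)))
  add("cycle_number_below_1", sum(!is.na(rec$cycle_number) & rec$cycle_number < 1))
  add("treatment_line_below_1", sum(!is.na(rec$treatment_line) & rec$treatment_line < 1))
  add("unknown_center", sum(!rec$center_id %in% extract$centers$center_id))
  demo <- rec |>
    mutate(.pkey = patient_key(.data$center_id, .data$patient_id)) |>
    group_by(.data$.pkey) |>
    summarise(
      bad = n_distinct(.data$birth_year, na.rm = TRUE) > 1 |
        n_distinct(.data$gender, na.rm = TRUE) > 1,
      .groups = "drop"
    )
  add("inconsistent_demographics", sum(demo$bad))
  if (length(out)) bind_rows(out) else
    tibble(check = character(0), n = integer(0))
}
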