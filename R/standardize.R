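#' Read a shipped synonym table
#'
#' Synonym tables (stage, gender, response) are plain CSV data files with
#' columns `raw`, `canonical`; they can be edited or replaced without touching
#' code. French and English synonyms are shipped. Lookup keys are normalized
#' with the same rules as drug names, and every canonical value maps to itself,
#' which makes codification idempotent.
#'
#' @param which one of `"stage"`, `"gender"`, `"response"`.
#' @param path optional path to a replacement table.
#' @return named character vector: normalized raw value -> canonical value.
#' @export
synonym_table <- function(which = c("stage", "gender", "response"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    path <- system.file("extdata", paste0(which, "_synonyms.csv"), package = "eprflow")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  keys <- norm_text(tab$raw)
  vals <- tab$canonical
  # canonical values map to themselves so re-codification is a no-op
  extra <- setdiff(norm_text(unique(vals)), keys)
  if (length(extra) > 0) {
    keys <- c(keys, extra)
    vals <- c(vals, unique(vals)[match(extra, norm_text(unique(vals)))])
  }
  setNames(vals, keys)
}

lookup_synonym <- function(x, table) {
  unname(table[norm_text(x)])
}

# Name -> INN lookup map for a catalog: brands plus INN identity entries.
catalog_lookup <- function(catalog) {
  inns <- unique(c(catalog$inn_by_brand$inn, catalog$other_cancer_drugs,
                   catalog$drugs_of_interest))
  keys <- c(catalog$inn_by_brand$brand_norm, norm_text(inns))
  vals <- c(catalog$inn_by_brand$inn, inns)
  keep <- !duplicated(keys)
  setNames(vals[keep], keys[keep])
}

#' Standardize a drug name against the catalog
#'
#' Resolves a free-text drug name (and, when present, a separately recorded
#' brand) to an INN by exact lookup after text normalization (case,
#' whitespace, diacritics). No fuzzy matching is attempted: unknown names are
#' surfaced, never guessed.
#'
#' The match status encodes the agreement between the two fields:
#' * `matched` - name resolved, and any brand information agrees;
#' * `inn_only` - name resolved directly to an INN, no usable brand to check;
#' * `brand_conflict` - a brand is present and maps to a *different* INN than
#'   the recorded name (the name-mismatch exclusion signal);
#' * `unknown_drug` - nothing resolved.
#'
#' @param raw_name character vector of recorded drug names (brand or INN).
#' @param brand_field optional character vector of recorded brand names.
#' @param catalog a [drug_catalog()].
#' @return tibble with columns `inn` (character, `NA` when unresolved) and
#'   `status` (factor over the four statuses).
#' @export
normalize_drug <- function(raw_name, brand_field = NA_character_, catalog) {
  map <- catalog_lookup(catalog)
  n <- length(raw_name)
  brand_field <- rep_len(brand_field, n)
  raw_norm <- norm_text(raw_name)
  brand_norm <- norm_text(brand_field)
  inn_raw <- unname(map[raw_norm])
  inn_brand <- unname(map[brand_norm])
  # was the raw name itself a brand (as opposed to an INN)?
  raw_is_brand <- raw_norm %in% catalog$inn_by_brand$brand_norm

  inn <- ifelse(!is.na(inn_raw), inn_raw, inn_brand)
  status <- rep("unknown_drug", n)
  status[!is.na(inn)] <- "inn_only"
  both <- !is.na(inn_raw) & !is.na(inn_brand)
  status[both & inn_raw == inn_brand] <- "matched"
  status[both & inn_raw != inn_brand] <- "brand_conflict"
  # resolved through brand information alone (raw was a brand, or only the
  # brand field resolved): brand and INN agree by construction
  status[!both & !is.na(inn) & (raw_is_brand | is.na(inn_raw))] <- "matched"
  tibble(inn = inn, status = factor(status, levels = MATCH_STATUSES))
}

MATCH_STATUSES <- c("matched", "inn_only", "brand_conflict", "unknown_drug")

#' Codify an extract
#'
#' Data-management step one: map free-text fields from heterogeneous pharmacy
#' record dialects onto fixed vocabularies. Fills `drug_inn` (and a
#' `match_status` working column) from the catalog, and maps `disease_stage`,
#' `gender` and `response` through the shipped synonym tables. No record is
#' ever dropped here; unresolvable values are left missing and counted in the
#' report. The operation is idempotent.
#'
#' @param extract an `epr_extract`.
#' @param catalog a [drug_catalog()].
#' @return list with elements `extract` (codified) and `report` (list with
#'   per-status drug counts and per-field unmapped counts).
#' @export
codify_extract <- function(extract, catalog) {
  rec <- extract$records
  nd <- normalize_drug(rec$drug_raw, rec$drug_brand, catalog)
  rec$drug_inn <- nd$inn
  rec$match_status <- as.character(nd$status)

  map_field <- function(values, table) {
    mapped <- lookup_synonym(values, table)
    unmappable <- !is.na(values) & is.na(mapped)
    list(values = mapped, n_unmapped = sum(unmappable))
  }
  st <- map_field(rec$disease_stage, synonym_table("stage"))
  ge <- map_field(rec$gender, synonym_table("gender"))
  re <- map_field(rec$response, synonym_table("response"))
  rec$disease_stage <- st$values
  rec$gender <- ge$values
  rec$response <- re$values

  extract$records <- rec
  report <- list(
    n_records = nrow(rec),
    drug_status = as.list(table(factor(rec$match_status, levels = MATCH_STATUSES))),
    unmapped = list(disease_stage = st$n_unmapped, gender = ge$n_unmapped,
                    response = re$n_unmapped)
  )
  list(extract = extract, report = report)
}
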