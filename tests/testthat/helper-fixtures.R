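# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  drug_catalog(
    inn_by_brand = tibble::tribble(
      ~brand, ~inn,
      "Herceptin", "trastuzumab",
      "Avastin", "bevacizumab",
      "Perjeta", "pertuzumab",
      "Taxol", "paclitaxel",
      "Mabthera", "rituximab"
    ),
    other_cancer_drugs = c("rituximab", "bortezomib"),
    drugs_of_interest = c("trastuzumab", "trastuzumab emtansine", "pertuzumab",
                          "bevacizumab", "atezolizumab")
  )
}

# one patient's records: minimal columns filled, the rest missing
make_patient <- function(patient_id, dates, inns, center_id = "C001",
                         cycles = seq_along(dates), stages = NA_character_,
                         lines = NA_integer_, labels = NA_character_,
                         diagnosis = "breast_cancer", brands = NA_character_) {
  n <- length(dates)
  rec <- eprflow:::empty_records()[0, ]
  out <- tibble::tibble(
    center_id = center_id,
    patient_id = patient_id,
    birth_year = 1960L, gender = "F", weight = 70, height = 165,
    ecog = NA_integer_,
    diagnosis = rep_len(diagnosis, n),
    disease_stage = rep_len(stages, n),
    metastasis_sites = NA_character_, oncogenic_driver = NA_character_,
    drug_raw = inns,
    drug_inn = NA_character_,
    drug_brand = rep_len(brands, n),
    dose = 300,
    administration_date = as.Date(dates),
    treatment_line = as.integer(rep_len(lines, n)),
    cycle_number = as.integer(rep_len(cycles, n)),
    frequency_days = 21L,
    regimen_label = rep_len(labels, n),
    estimated_duration_days = NA_integer_,
    response = NA_character_, response_date = as.Date(NA),
    discontinuation_motive = NA_character_, discontinuation_date = as.Date(NA),
    trial_name = NA_character_
  )
  out
}

make_extract <- function(..., centers = NULL) {
  records <- dplyr::bind_rows(...)
  if (is.null(centers)) {
    centers <- tibble::tibble(center_id = unique(records$center_id),
                              category = "CCC", region = "West")
  }
  epr_extract(records, centers)
}

codified <- function(extract, catalog = tiny_catalog()) {
  codify_extract(extract, catalog)$extract
}

# small fast generator config for property loops
small_config <- function(seed, n_strata = 2, patients = 4, ...) {
  strata <- tidyr::expand_grid(category = c("CCC", "UH"), region = c("West", "East"))
  strata <- strata[seq_len(n_strata), ]
  strata$n_centers <- 1L
  synthetic_config(n_centers_by_stratum = strata, patients_per_center = patients,
                   seed = seed, ...)
}
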