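#' Synthetic extract configuration
#'
#' Defines the study conditions the generator emulates. Defaults mirror the
#' structure of a large multi-center platform assessment: pre-inference stage
#' completion of 93% (breast) and 77% (lung), line completion of 80% and 70%,
#' a breast/lung mix of about 5:1, truncated treatment starts at 3.7% of
#' patients and the four other injectable-record error modes at 0.6% each.
#'
#' @param n_centers_by_stratum tibble with columns `category`, `region`,
#'   `n_centers`; default one center in each of the 24 category-by-region
#'   strata.
#' @param patients_per_center patients generated per center.
#' @param cancer_mix probability a patient is a breast-cancer patient (the
#'   complement is lung cancer).
#' @param stage_missing_rate_bc,stage_missing_rate_lc probability a patient's
#'   recorded disease stage is masked.
#' @param line_missing_rate_bc,line_missing_rate_lc probability a patient's
#'   recorded treatment line is masked.
#' @param partial_stage_share,partial_line_share among masked patients, share
#'   whose masking hits isolated records inside regimens (recoverable by
#'   within-regimen fill) rather than the whole history.
#' @param stage_in_label_rate probability a regimen label carries a stage
#'   keyword (the recovery route for fully masked stages).
#' @param truncation_rate probability a patient's history start is cut
#'   (first regimen starts at a cycle number above 1).
#' @param duplicate_injection_rate probability of a same-day duplicate
#'   administration of the same drug.
#' @param brand_mismatch_rate probability of a record whose brand contradicts
#'   its drug name.
#' @param multi_primary_rate probability of a second primary diagnosis
#'   appearing in the patient's records.
#' @param other_drug_contamination_rate probability of an administration of a
#'   drug specific to another cancer.
#' @param response_rate_bc,response_rate_lc probability a disease-assessment
#'   result is recorded for a patient.
#' @param exclusive_errors when TRUE (default) at most one error mode is
#'   injected per patient, so per-rule exclusion counts are unambiguous;
#'   FALSE draws error modes independently (for rule-precedence testing).
#' @param seed integer RNG seed; generation is deterministic given the config.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_centers_by_stratum = NULL,
                             patients_per_center = 25,
                             cancer_mix = 0.835,
                             stage_missing_rate_bc = 0.07,
                             stage_missing_rate_lc = 0.23,
                             line_missing_rate_bc = 0.20,
                             line_missing_rate_lc = 0.30,
                             partial_stage_share = 0.5,
                             partial_line_share = 0.5,
                             stage_in_label_rate = 0.8,
                             truncation_rate = 0.037,
                             duplicate_injection_rate = 0.006,
                             brand_mismatch_rate = 0.006,
                             multi_primary_rate = 0.006,
                             other_drug_contamination_rate = 0.006,
                             response_rate_bc = 0.07,
                             response_rate_lc = 0.04,
                             exclusive_errors = TRUE,
                             seed = 1L) {
  if (is.null(n_centers_by_stratum)) {
    n_centers_by_stratum <- tidyr::expand_grid(
      category = CENTER_CATEGORIES, region = CENTER_REGIONS
    )
    n_centers_by_stratum$n_centers <- 1L
  }
  cfg <- list(
    n_centers_by_stratum = tibble::as_tibble(n_centers_by_stratum),
    patients_per_center = as.integer(patients_per_center),
    cancer_mix = cancer_mix,
    stage_missing_rate_bc = stage_missing_rate_bc,
    stage_missing_rate_lc = stage_missing_rate_lc,
    line_missing_rate_bc = line_missing_rate_bc,
    line_missing_rate_lc = line_missing_rate_lc,
    partial_stage_share = partial_stage_share,
    partial_line_share = partial_line_share,
    stage_in_label_rate = stage_in_label_rate,
    truncation_rate = truncation_rate,
    duplicate_injection_rate = duplicate_injection_rate,
    brand_mismatch_rate = brand_mismatch_rate,
    multi_primary_rate = multi_primary_rate,
    other_drug_contamination_rate = other_drug_contamination_rate,
    response_rate_bc = response_rate_bc,
    response_rate_lc = response_rate_lc,
    exclusive_errors = isTRUE(exclusive_errors),
    seed = as.integer(seed)
  )
  probs <- cfg[grepl("rate|share|mix$", names(cfg))]
  bad <- vapply(probs, function(p) !is.numeric(p) || is.na(p) || p < 0 || p > 1, logical(1))
  if (any(bad)) stop("probabilities must lie in [0, 1]: ",
                     paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  if (cfg$patients_per_center < 0 || any(cfg$n_centers_by_stratum$n_centers < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

BC_BACKBONES <- list("trastuzumab", c("trastuzumab", "pertuzumab"), "trastuzumab emtansine")
LC_BACKBONES <- list("bevacizumab", "atezolizumab")
BC_PARTNERS <- c("paclitaxel", "docetaxel", "vinorelbine", "capecitabine",
                 "epirubicin", "cyclophosphamide")
LC_PARTNERS <- c("carboplatin", "cisplatin", "pemetrexed", "gemcitabine", "paclitaxel")
STAGE_TAGS <- c(early = "ADJUVANT", locally_advanced = "LOCALLY ADVANCED",
                metastatic = "METASTATIC")
ERROR_RULES <- c("R1_truncated", "R2_name_mismatch", "R3_duplicate_injection",
                 "R4_multi_primary", "R5_other_cancer_drug")

# one patient's record frame with true stage/line carried in extra columns
build_patient <- function(center_id, patient_id, cancer, cfg, brand_of) {
  is_bc <- cancer == "breast_cancer"
  n_reg <- sample(1:4, 1)
  backbones <- if (is_bc) BC_BACKBONES else LC_BACKBONES
  partners <- if (is_bc) BC_PARTNERS else LC_PARTNERS
  sets <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    repeat {
      set <- sort(unique(c(backbones[[sample(length(backbones), 1)]],
                           if (stats::runif(1) < 0.6) sample(partners, 1))))
      if (r == 1 || !identical(set, sets[[r - 1]])) break
    }
    sets[[r]] <- set
  }
  # stage trajectory: de novo metastatic, or an early phase with optional
  # transition to metastatic at a regimen boundary
  de_novo <- stats::runif(1) < (if (is_bc) 0.30 else 0.80)
  if (de_novo) {
    stages <- rep("metastatic", n_reg)
  } else {
    first_stage <- if (stats::runif(1) < 0.7) "early" else "locally_advanced"
    stages <- rep(first_stage, n_reg)
    if (n_reg >= 2 && stats::runif(1) < 0.6) {
      t <- sample(2:n_reg, 1)
      stages[t:n_reg] <- "metastatic"
    }
  }
  # true line: sequence number within phase, restarting at metastatic onset
  phase <- ifelse(stages == "metastatic", 2L, 1L)
  lines <- stats::ave(seq_len(n_reg), phase, FUN = seq_along)

  cycles <- sample(4:8, n_reg, replace = TRUE)
  freq <- 21L
  start <- as.Date("2016-01-01") + sample(0:1200, 1)
  demo <- list(
    birth_year = sample(1935:1985, 1),
    gender = if (is_bc) (if (stats::runif(1) < 0.99) "F" else "M")
             else (if (stats::runif(1) < 0.6) "M" else "F"),
    weight = round(stats::rnorm(1, 70, 12), 1),
    height = round(stats::rnorm(1, 167, 9)),
    ecog = if (!is_bc && stats::runif(1) < 0.12) sample(0:2, 1) else NA_integer_,
    driver = if (is_bc) {
      if (stats::runif(1) < 0.31) "HER2" else NA_character_
    } else {
      if (stats::runif(1) < 0.10) sample(c("EGFR", "ALK", "PD-L1"), 1) else NA_character_
    },
    trial = if (stats::runif(1) < 0.98) "none" else NA_character_
  )

  reg_frames <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    set <- sets[[r]]
    nd <- length(set)
    label <- paste(toupper(set), collapse = " + ")
    if (stats::runif(1) < cfg$stage_in_label_rate) {
      label <- paste0(label, " - ", STAGE_TAGS[[stages[r]]])
    }
    dates <- start + (seq_len(cycles[r]) - 1L) * freq
    doses <- setNames(sample(100:600, nd, replace = TRUE), set)
    reg_frames[[r]] <- tibble(
      regimen = r,
      drug_inn_true = rep(set, times = cycles[r]),
      administration_date = rep(dates, each = nd),
      cycle_number = rep(seq_len(cycles[r]), each = nd),
      dose = as.numeric(doses[rep(set, times = cycles[r])]),
      frequency_days = freq,
      regimen_label = label,
      estimated_duration_days = as.integer(cycles[r] * freq),
      true_stage = stages[r],
      true_line = as.integer(lines[r])
    )
    start <- dates[length(dates)] + sample(7:45, 1)
  }
  rec <- bind_rows(reg_frames)

  # recorded drug fields: raw name is the INN or the brand, mixed case;
  # brand field, when filled, is the consistent brand
  n <- nrow(rec)
  brand <- unname(brand_of[rec$drug_inn_true])
  use_brand <- !is.na(brand) & stats::runif(n) < 0.5
  raw <- ifelse(use_brand, brand, rec$drug_inn_true)
  upper <- stats::runif(n) < 0.3
  raw[upper] <- toupper(raw[upper])
  rec$drug_raw <- raw
  rec$drug_brand <- ifelse(!is.na(brand) & stats::runif(n) < 0.5, brand, NA_character_)

  rec$center_id <- center_id
  rec$patient_id <- patient_id
  rec$birth_year <- demo$birth_year
  rec$gender <- demo$gender
  rec$weight <- demo$weight
  rec$height <- demo$height
  rec$ecog <- demo$ecog
  rec$diagnosis <- cancer
  rec$disease_stage <- rec$true_stage
  rec$treatment_line <- rec$true_line
  rec$metastasis_sites <- ifelse(rec$true_stage == "metastatic" & stats::runif(n) < 0.10,
                                 "liver", NA_character_)
  rec$oncogenic_driver <- demo$driver
  rec$drug_inn <- NA_character_
  rec$response <- NA_character_
  rec$response_date <- as.Date(NA)
  rec$discontinuation_motive <- NA_character_
  rec$discontinuation_date <- as.Date(NA)
  rec$trial_name <- demo$trial

  resp_rate <- if (is_bc) cfg$response_rate_bc else cfg$response_rate_lc
  if (stats::runif(1) < resp_rate) {
    i <- which(rec$regimen == sample(n_reg, 1))
    i <- i[length(i)]
    rec$response[i] <- sample(c("PR", "SD", "PD", "CR"), 1)
    rec$response_date[i] <- rec$administration_date[i] + 7
  }
  rec
}

mask_one_per_regimen <- function(rec, field) {
  # mask one isolated record inside each regimen (leaves >= 1 recorded value
  # per regimen, so within-regimen fill can recover it exactly)
  for (r in unique(rec$regimen)) {
    idx <- which(rec$regimen == r)
    if (length(idx) < 2) next
    rec[[field]][sample(idx, 1)] <- NA
  }
  rec
}

inject_error <- function(rec, rule, cancer, brand_of, other_inns) {
  switch(rule,
    R1_truncated = {
      first <- which(rec$regimen == 1L)
      kmax <- max(rec$cycle_number[first]) - 1L
      k <- if (kmax >= 1) sample(seq_len(kmax), 1) else 0L
      if (k > 0) rec <- rec[!(rec$regimen == 1L & rec$cycle_number <= k), , drop = FALSE]
      rec
    },
    R2_name_mismatch = {
      i <- sample(nrow(rec), 1)
      # brand_of maps inn -> brand; pick the brand of a different INN
      other_inn <- sample(setdiff(names(brand_of), rec$drug_inn_true[i]), 1)
      rec$drug_brand[i] <- unname(brand_of[[other_inn]])
      rec$drug_raw[i] <- rec$drug_inn_true[i]
      rec
    },
    R3_duplicate_injection = {
      i <- sample(nrow(rec), 1)
      bind_rows(rec, rec[i, , drop = FALSE])
    },
    R4_multi_primary = {
      i <- sample(nrow(rec), 1)
      rec$diagnosis[i] <- "other"
      rec
    },
    R5_other_cancer_drug = {
      extra <- rec[nrow(rec), , drop = FALSE]
      inn <- sample(other_inns, 1)
      extra$drug_inn_true <- inn
      extra$drug_raw <- inn
      extra$drug_brand <- NA_character_
      extra$administration_date <- extra$administration_date + 3
      extra$cycle_number <- NA_integer_
      extra$dose <- 375
      bind_rows(rec, extra)
    }
  )
}

#' Generate a synthetic multi-center EPR extract with ground truth
#'
#' Every generated patient receives at least one administration of a cohort
#' drug of interest (each regimen contains one). Missingness and error modes
#' are realized as independent per-patient draws at the configured rates;
#' the true stage/line trajectory and the injected error labels are recorded
#' before masking, so downstream cleaning and inference can be scored against
#' truth.
#'
#' @param config a [synthetic_config()].
#' @param catalog a [drug_catalog()]; brand names and the other-cancer drug
#'   list are drawn from it.
#' @return list with `extract` (an `epr_extract`, uncodified: `drug_inn` left
#'   for [codify_extract()] to fill) and `truth` (class `epr_truth`: `patients`
#'   tibble with masking modes and injected `error_rule`, `records` tibble with
#'   `row_id`, `true_stage`, `true_line`).
#' @export
generate_extract <- function(config, catalog = default_drug_catalog()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_extract_impl(config, catalog))
}

generate_extract_impl <- function(cfg, catalog) {
  strata <- cfg$n_centers_by_stratum[rep(seq_len(nrow(cfg$n_centers_by_stratum)),
                                         cfg$n_centers_by_stratum$n_centers), ]
  n_centers <- nrow(strata)
  centers <- tibble(
    center_id = sprintf("C%03d", seq_len(max(n_centers, 0))),
    category = strata$category,
    region = strata$region
  )
  if (n_centers == 0 || cfg$patients_per_center == 0) {
    return(list(
      extract = epr_extract(empty_records(), centers),
      truth = structure(list(
        patients = tibble(center_id = character(0), patient_id = character(0),
                          cancer = character(0), stage_mask = character(0),
                          line_mask = character(0), error_rule = character(0)),
        records = tibble(row_id = integer(0), center_id = character(0),
                         patient_id = character(0), true_stage = character(0),
                         true_line = integer(0))
      ), class = "epr_truth")
    ))
  }
  brand_of <- setNames(catalog$inn_by_brand$inn, catalog$inn_by_brand$brand)
  brand_of <- setNames(names(brand_of), unname(brand_of)) # inn -> brand
  other_inns <- intersect(catalog$other_cancer_drugs,
                          norm_text(catalog$inn_by_brand$inn))

  n_pat <- n_centers * cfg$patients_per_center
  pat_center <- rep(centers$center_id, each = cfg$patients_per_center)
  pat_id <- sprintf("P%04d", unlist(lapply(
    rep(cfg$patients_per_center, n_centers), seq_len
  )))
  cancer <- ifelse(stats::runif(n_pat) < cfg$cancer_mix, "breast_cancer", "lung_cancer")
  is_bc <- cancer == "breast_cancer"

  stage_rate <- ifelse(is_bc, cfg$stage_missing_rate_bc, cfg$stage_missing_rate_lc)
  line_rate <- ifelse(is_bc, cfg$line_missing_rate_bc, cfg$line_missing_rate_lc)
  stage_mask <- ifelse(stats::runif(n_pat) < stage_rate,
                       ifelse(stats::runif(n_pat) < cfg$partial_stage_share, "partial", "full"),
                       "none")
  line_mask <- ifelse(stats::runif(n_pat) < line_rate,
                      ifelse(stats::runif(n_pat) < cfg$partial_line_share, "partial", "full"),
                      "none")

  err_p <- c(cfg$truncation_rate, cfg$brand_mismatch_rate, cfg$duplicate_injection_rate,
             cfg$multi_primary_rate, cfg$other_drug_contamination_rate)
  err_rules <- c("R1_truncated", "R2_name_mismatch", "R3_duplicate_injection",
                 "R4_multi_primary", "R5_other_cancer_drug")
  if (cfg$exclusive_errors) {
    if (sum(err_p) > 1) stop("error rates sum above 1 with exclusive_errors = TRUE", call. = FALSE)
    draw <- stats::runif(n_pat)
    cum <- cumsum(err_p)
    error_rule <- rep(NA_character_, n_pat)
    for (j in rev(seq_along(err_rules))) {
      error_rule[draw < cum[j]] <- err_rules[j]
    }
    error_list <- lapply(error_rule, function(e) if (is.na(e)) character(0) else e)
  } else {
    hits <- matrix(stats::runif(n_pat * 5) < rep(err_p, each = n_pat), nrow = n_pat)
    error_list <- lapply(seq_len(n_pat), function(i) err_rules[hits[i, ]])
    error_rule <- vapply(error_list, function(e) if (length(e)) e[[1]] else NA_character_,
                         character(1))
  }

  frames <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    rec <- build_patient(pat_center[i], pat_id[i], cancer[i], cfg, brand_of)
    for (rule in error_list[[i]]) {
      rec <- inject_error(rec, rule, cancer[i], brand_of, other_inns)
    }
    # truth is fixed at this point; masking only hides values
    if (stage_mask[i] == "full") {
      rec$disease_stage <- NA_character_
    } else if (stage_mask[i] == "partial") {
      rec <- mask_one_per_regimen(rec, "disease_stage")
    }
    if (line_mask[i] == "full") {
      rec$treatment_line <- NA_integer_
    } else if (line_mask[i] == "partial") {
      rec <- mask_one_per_regimen(rec, "treatment_line")
    }
    frames[[i]] <- rec
  }
  all <- bind_rows(frames)
  all$.row_id <- seq_len(nrow(all))

  truth <- structure(list(
    patients = tibble(center_id = pat_center, patient_id = pat_id, cancer = cancer,
                      stage_mask = stage_mask, line_mask = line_mask,
                      error_rule = error_rule),
    records = tibble(row_id = all$.row_id, center_id = all$center_id,
                     patient_id = all$patient_id, true_stage = all$true_stage,
                     true_line = all$true_line)
  ), class = "epr_truth")

  keep <- setdiff(record_columns(), character(0))
  records <- all[, c(keep, ".row_id")]
  list(extract = epr_extract(records, centers), truth = truth)
}

#' Generate a synthetic national reference table
#'
#' Builds per-stratum national patient counts as an inflation of the counts
#' the configuration implies for the platform itself, so the platform's
#' expected coverage rate is about `1 / inflation` in every stratum and the
#' distribution shape across strata is preserved.
#'
#' @param config a [synthetic_config()].
#' @param inflation factor > 1 by which national counts exceed platform counts.
#' @param reference_year year stamped on the reference.
#' @return a [national_reference()] tibble (cancer, category, region, n).
#' @export
generate_national_reference <- function(config, inflation = 3, reference_year = 2018L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("inflation must be > 1", call. = FALSE)
  }
  base <- config$n_centers_by_stratum |>
    mutate(n_platform = .data$n_centers * config$patients_per_center)
  counts <- bind_rows(
    base |> mutate(cancer = "breast_cancer",
                   n = ceiling(.data$n_platform * config$cancer_mix * inflation)),
    base |> mutate(cancer = "lung_cancer",
                   n = ceiling(.data$n_platform * (1 - config$cancer_mix) * inflation))
  ) |>
    select("cancer", "category", "region", "n") |>
    mutate(n = as.integer(.data$n))
  national_reference(counts, reference_year)
}

#' Write / read ground truth as JSON
#' @param truth an `epr_truth`.
#' @param path file path.
#' @return `path` (write) or an `epr_truth` (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(patients = truth$patients, records = truth$records),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(patients = tibble::as_tibble(x$patients),
                 records = tibble::as_tibble(x$records)), class = "epr_truth")
}
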