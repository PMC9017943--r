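#' National reference table
#'
#' Patient counts by cancer and center stratum for the whole country, the
#' denominator for coverage and the comparator for representativeness.
#'
#' @param counts tibble with a `cancer` column, an `n` count column, and any
#'   subset of the stratum columns `category`, `region`.
#' @param reference_year year of the reference counts.
#' @return tibble of class `national_reference` with a `reference_year`
#'   attribute.
#' @export
national_reference <- function(counts, reference_year = NA_integer_) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("cancer", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("reference counts must be >= 0", call. = FALSE)
  structure(counts, reference_year = as.integer(reference_year),
            class = c("national_reference", class(counts)))
}

#' Default variable specification for completeness reporting
#'
#' `patient`-level variables count a patient as complete when any of their
#' records carries a value; `record`-level variables are counted per record.
#'
#' @return tibble with columns `variable`, `level`.
#' @export
default_variable_spec <- function() {
  tibble::tribble(
    ~variable, ~level,
    "birth_year", "patient",
    "gender", "patient",
    "weight", "patient",
    "height", "patient",
    "ecog", "patient",
    "diagnosis", "patient",
    "metastasis_sites", "patient",
    "oncogenic_driver", "patient",
    "response", "patient",
    "response_date", "patient",
    "discontinuation_motive", "patient",
    "discontinuation_date", "patient",
    "trial_name", "patient",
    "drug_inn", "record",
    "dose", "record",
    "administration_date", "record",
    "disease_stage", "record",
    "treatment_line", "record",
    "cycle_number", "record",
    "frequency_days", "record",
    "regimen_label", "record",
    "estimated_duration_days", "record"
  )
}

#' Completion rates of extract variables
#'
#' Completeness is the proportion of available data for each variable in the
#' analyzable population. Variables below 70% completion are flagged as not
#' usable for analysis (no imputation is ever attempted on them).
#'
#' @param extract an `epr_extract`.
#' @param variable_spec tibble (`variable`, `level`), see
#'   [default_variable_spec()].
#' @param usable_threshold completion rate below which a variable is unusable.
#' @return tibble: `variable`, `level`, `n`, `n_complete`, `completion_rate`,
#'   `usable`.
#' @export
completion_rates <- function(extract, variable_spec = default_variable_spec(),
                             usable_threshold = 0.70) {
  rec <- extract$records
  if (nrow(rec) == 0) {
    warning("empty population: completion rates undefined", call. = FALSE)
    return(variable_spec |>
             mutate(n = 0L, n_complete = 0L, completion_rate = NA_real_, usable = NA))
  }
  pkey <- patient_key(rec$center_id, rec$patient_id)
  n_pat <- n_distinct(pkey)
  rows <- lapply(seq_len(nrow(variable_spec)), function(i) {
    v <- variable_spec$variable[i]
    lvl <- variable_spec$level[i]
    x <- rec[[v]]
    if (lvl == "patient") {
      present <- tapply(!is.na(x), pkey, any)
      n <- n_pat
      k <- sum(present)
    } else {
      n <- nrow(rec)
      k <- sum(!is.na(x))
    }
    tibble(variable = v, level = lvl, n = as.integer(n), n_complete = as.integer(k),
           completion_rate = k / n)
  })
  bind_rows(rows) |>
    mutate(usable = .data$completion_rate >= usable_threshold)
}

#' Patient counts by cancer and center stratum
#'
#' Each patient is counted once per cancer, attributed to the center of their
#' first administration (canonical order). Unknown centers fall into an
#' explicit `"unknown"` stratum.
#'
#' @param extract an `epr_extract`.
#' @return tibble: `cancer`, `category`, `region`, `n`.
#' @export
patient_counts_by_stratum <- function(extract) {
  rec <- sort_canonical(extract$records)
  if (nrow(rec) == 0) {
    return(tibble(cancer = character(0), category = character(0),
                  region = character(0), n = integer(0)))
  }
  pkey <- patient_key(rec$center_id, rec$patient_id)
  firsts <- rec[!duplicated(pkey), c("center_id", "patient_id")]
  firsts$cancer <- vapply(split_patients(rec), patient_cancer, character(1))
  firsts <- left_join(firsts, extract$centers, by = "center_id")
  firsts |>
    mutate(
      category = ifelse(is.na(.data$category), "unknown", .data$category),
      region = ifelse(is.na(.data$region), "unknown", .data$region)
    ) |>
    count(.data$cancer, .data$category, .data$region, name = "n")
}

join_strata <- function(prm_counts, reference) {
  strata <- intersect(intersect(names(prm_counts), names(reference)),
                      c("cancer", "category", "region"))
  if (!"cancer" %in% strata) stop("counts must share a cancer column", call. = FALSE)
  prm <- prm_counts |>
    group_by(across(all_of(strata))) |>
    summarise(prm_count = sum(.data$n), .groups = "drop")
  nat <- tibble::as_tibble(reference) |>
    group_by(across(all_of(strata))) |>
    summarise(national_count = sum(.data$n), .groups = "drop")
  list(joined = dplyr::full_join(prm, nat, by = strata) |>
         mutate(prm_count = dplyr::coalesce(.data$prm_count, 0L),
                national_count = dplyr::coalesce(.data$national_count, 0L)),
       strata = strata)
}

#' Coverage rates against a national reference
#'
#' Coverage is the fraction of nationally treated patients captured by the
#' platform's centers: `prm_count / national_count` per stratum, plus a Total
#' row per cancer. Displayed percentages are rounded to the nearest integer,
#' half away from zero; the underlying rate keeps full precision.
#'
#' @param prm_counts tibble from [patient_counts_by_stratum()] (or any counts
#'   sharing stratum columns with the reference).
#' @param reference a [national_reference()].
#' @return tibble with `prm_count`, `national_count`, `coverage_rate`,
#'   `coverage_pct`.
#' @export
coverage_rates <- function(prm_counts, reference) {
  js <- join_strata(prm_counts, reference)
  joined <- js$joined
  totals <- joined |>
    group_by(.data$cancer) |>
    summarise(prm_count = sum(.data$prm_count),
              national_count = sum(.data$national_count), .groups = "drop")
  for (s in setdiff(js$strata, "cancer")) totals[[s]] <- "Total"
  out <- bind_rows(joined, totals[, names(joined)]) |>
    mutate(
      coverage_rate = ifelse(.data$national_count > 0,
                             .data$prm_count / .data$national_count, NA_real_),
      coverage_pct = round_half_up(100 * .data$coverage_rate)
    )
  undef <- is.na(out$coverage_rate) & out$prm_count > 0
  if (any(undef)) {
    warning(sum(undef), " stratum/strata with platform patients but a zero national count: ",
            "coverage undefined", call. = FALSE)
  }
  out
}

#' Representativeness of the platform against the national distribution
#'
#' Compares the distribution of patients across strata in the platform to the
#' national distribution: per-stratum shares, absolute differences in
#' percentage points (flagged above `flag_threshold_pp`), and a supplementary
#' chi-square goodness-of-fit of platform counts against the national share
#' vector (descriptive; it gates nothing).
#'
#' @param prm_counts,reference as in [coverage_rates()].
#' @param flag_threshold_pp flag threshold in percentage points.
#' @param share_digits decimals for displayed shares (1 by default; use 0 to
#'   mimic whole-percent reporting). `abs_diff_display` is the difference of
#'   the displayed (rounded) shares, as a reader of the printed table would
#'   compute it; `abs_diff_pp` keeps full precision and drives the flag.
#' @return list with `by_stratum` (tibble per cancer and stratum) and
#'   `chi_square` (tibble per cancer: statistic, df, p_value).
#' @export
representativeness <- function(prm_counts, reference, flag_threshold_pp = 4,
                               share_digits = 1) {
  js <- join_strata(prm_counts, reference)
  joined <- js$joined
  if (sum(joined$national_count) == 0) stop("zero national total", call. = FALSE)
  by_stratum <- joined |>
    group_by(.data$cancer) |>
    mutate(
      prm_share = .data$prm_count / sum(.data$prm_count),
      national_share = .data$national_count / sum(.data$national_count),
      abs_diff_pp = abs(100 * (.data$prm_share - .data$national_share)),
      prm_share_pct = round_half_up(100 * .data$prm_share, share_digits),
      national_share_pct = round_half_up(100 * .data$national_share, share_digits),
      abs_diff_display = round_half_up(abs(.data$prm_share_pct - .data$national_share_pct),
                                       share_digits),
      flagged = .data$abs_diff_pp > flag_threshold_pp
    ) |>
    ungroup()
  chi <- by_stratum |>
    group_by(.data$cancer) |>
    summarise(
      statistic = {
        exp_p <- .data$national_share
        if (length(exp_p) < 2 || any(exp_p == 0)) NA_real_ else
          suppressWarnings(unname(chisq.test(.data$prm_count, p = exp_p)$statistic))
      },
      df = dplyr::n() - 1L,
      p_value = {
        exp_p <- .data$national_share
        if (length(exp_p) < 2 || any(exp_p == 0)) NA_real_ else
          suppressWarnings(chisq.test(.data$prm_count, p = exp_p)$p.value)
      },
      .groups = "drop"
    )
  list(by_stratum = by_stratum, chi_square = chi)
}
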