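# Category-level patient counts of a large multi-center platform and the
# matching national reference (reported national assessment, reference year
# 2018), used as a worked example throughout.
platform_counts <- function() {
  tibble::tribble(
    ~cancer, ~category, ~n,
    "breast_cancer", "GH_NFPH", 7058L,
    "breast_cancer", "UH", 1420L,
    "breast_cancer", "CCC", 8793L,
    "breast_cancer", "PH", 9712L,
    "lung_cancer", "GH_NFPH", 8406L,
    "lung_cancer", "UH", 2553L,
    "lung_cancer", "CCC", 1933L,
    "lung_cancer", "PH", 4129L
  )
}

national_counts <- function() {
  national_reference(tibble::tribble(
    ~cancer, ~category, ~n,
    "breast_cancer", "GH_NFPH", 17784L,
    "breast_cancer", "UH", 5757L,
    "breast_cancer", "CCC", 17372L,
    "breast_cancer", "PH", 20036L,
    "lung_cancer", "GH_NFPH", 23441L,
    "lung_cancer", "UH", 11193L,
    "lung_cancer", "CCC", 5090L,
    "lung_cancer", "PH", 11184L
  ), reference_year = 2018)
}

test_that("completion rates honor patient/record levels and the 70% usability bar", {
  ext <- make_extract(
    make_patient("P1", c("2018-01-01", "2018-01-22"), "Herceptin",
                 stages = c("early", NA)),
    make_patient("P2", "2018-02-01", "Herceptin", stages = NA)
  )
  spec <- tibble::tibble(variable = c("disease_stage", "disease_stage", "gender"),
                         level = c("patient", "record", "patient"))
  out <- completion_rates(ext, spec)
  expect_equal(out$completion_rate, c(1 / 2, 1 / 3, 1))
  # threshold edge: 69/100 is not usable, 70/100 is
  expect_false(completion_rates(ext, spec)$usable[2])
  big <- make_extract(make_patient("P1", sprintf("2018-01-%02d", 1:25), "Herceptin",
                                   stages = c(rep("early", 17), rep(NA, 8))))
  out <- completion_rates(big, tibble::tibble(variable = "disease_stage", level = "record"))
  expect_equal(out$completion_rate, 0.68)
  expect_false(out$usable)
  out <- completion_rates(
    make_extract(make_patient("P1", sprintf("2018-01-%02d", 1:20), "Herceptin",
                              stages = c(rep("early", 14), rep(NA, 6)))),
    tibble::tibble(variable = "disease_stage", level = "record")
  )
  expect_equal(out$completion_rate, 0.70)
  expect_true(out$usable)
})

test_that("empty population reports missing rates with a warning", {
  expect_warning(out <- completion_rates(epr_extract()), "empty")
  expect_true(all(is.na(out$completion_rate)))
})

test_that("patients are counted once, at their first-administration center", {
  centers <- tibble::tibble(center_id = c("C001", "C002"),
                            category = c("CCC", "UH"),
                            region = c("West", "East"))
  recs <- dplyr::bind_rows(
    make_patient("P1", c("2018-01-01", "2018-02-01"), "Herceptin"),
    make_patient("P2", "2018-03-01", "Herceptin", center_id = "C002"),
    # same patient id at the second center counts as a different patient
    make_patient("P1", "2018-04-01", "Herceptin", center_id = "C002")
  )
  ext <- epr_extract(recs, centers)
  counts <- patient_counts_by_stratum(ext)
  expect_equal(sum(counts$n), 3)
  expect_equal(counts$n[counts$category == "UH"], 2)
  # unknown center falls into an explicit stratum
  ext2 <- make_extract(make_patient("P3", "2018-01-01", "Herceptin", center_id = "C099"))
  ext2$centers$category <- NA_character_
  counts2 <- patient_counts_by_stratum(ext2)
  expect_equal(counts2$category, "unknown")
})

test_that("coverage reproduces the reported per-category and total percentages", {
  cov <- coverage_rates(platform_counts(), national_counts())
  pick <- function(cancer, cat) cov$coverage_pct[cov$cancer == cancer & cov$category == cat]
  expect_equal(vapply(c("GH_NFPH", "UH", "CCC", "PH"), function(cc)
    pick("breast_cancer", cc), numeric(1)), c(GH_NFPH = 40, UH = 25, CCC = 51, PH = 48))
  expect_equal(vapply(c("GH_NFPH", "UH", "CCC", "PH"), function(cc)
    pick("lung_cancer", cc), numeric(1)), c(GH_NFPH = 36, UH = 23, CCC = 38, PH = 37))
  expect_equal(pick("lung_cancer", "Total"), 33)
})

test_that("coverage is scale-equivariant and warns on zero national counts", {
  prm <- platform_counts()
  ref <- national_counts()
  scaled <- coverage_rates(dplyr::mutate(prm, n = n * 7L),
                           national_reference(dplyr::mutate(as.data.frame(ref), n = n * 7L)))
  base <- coverage_rates(prm, ref)
  expect_equal(scaled$coverage_rate, base$coverage_rate)
  ref0 <- national_reference(tibble::tibble(cancer = "breast_cancer",
                                            category = "UH", n = 0L))
  expect_warning(out <- coverage_rates(prm[prm$cancer == "breast_cancer" &
                                             prm$category == "UH", ], ref0),
                 "zero national count")
  expect_true(all(is.na(out$coverage_rate)))
})

test_that("representativeness reproduces the reported shares and gap structure", {
  rep <- representativeness(platform_counts(), national_counts(), share_digits = 1)
  bc <- rep$by_stratum[rep$by_stratum$cancer == "breast_cancer", ]
  expect_equal(bc$prm_share_pct[match(c("GH_NFPH", "UH", "CCC", "PH"), bc$category)],
               c(26.2, 5.3, 32.6, 36.0))
  expect_equal(bc$national_share_pct[match(c("GH_NFPH", "UH", "CCC", "PH"), bc$category)],
               c(29.2, 9.4, 28.5, 32.9))
  # university hospitals show the largest discrepancy: 4.1 points as printed
  expect_equal(bc$abs_diff_display[bc$category == "UH"], 4.1)
  expect_equal(bc$category[which.max(bc$abs_diff_pp)], "UH")
  # whole-percent convention for the lung-cancer distribution
  rep0 <- representativeness(platform_counts(), national_counts(), share_digits = 0)
  lc <- rep0$by_stratum[rep0$by_stratum$cancer == "lung_cancer", ]
  expect_equal(lc$prm_share_pct[match(c("GH_NFPH", "UH", "CCC", "PH"), lc$category)],
               c(49, 15, 11, 24))
  expect_equal(lc$national_share_pct[match(c("GH_NFPH", "UH", "CCC", "PH"), lc$category)],
               c(46, 22, 10, 22))
  # shares sum to one before rounding
  sums <- tapply(rep$by_stratum$prm_share, rep$by_stratum$cancer, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("identical distributions give zero chi-square and no flags", {
  prm <- platform_counts()
  same <- representativeness(prm, national_reference(prm))
  expect_true(all(same$by_stratum$abs_diff_pp == 0))
  expect_false(any(same$by_stratum$flagged))
  expect_equal(same$chi_square$statistic, c(0, 0))
  half <- representativeness(
    tibble::tibble(cancer = "x", category = c("a", "b"), n = c(50L, 50L)),
    national_reference(tibble::tibble(cancer = "x", category = c("a", "b"),
                                      n = c(500L, 500L)))
  )
  expect_equal(half$chi_square$statistic, 0)
  expect_equal(half$chi_square$p_value, 1)
  expect_error(
    representativeness(prm, national_reference(dplyr::mutate(platform_counts(), n = 0L))),
    "zero national total"
  )
})
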