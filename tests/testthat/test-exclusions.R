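dates3 <- c("2018-01-01", "2018-01-22", "2018-02-12")

test_that("truncated-start detection follows the first-regimen cycle rule", {
  # earliest regimen observed at cycles 4,5,6: truncated
  p <- codified(make_extract(make_patient("P1", dates3, "Herceptin", cycles = 4:6)))
  expect_true(detect_truncated_start(p$records))
  # cycles 1,2,3: complete start
  p <- codified(make_extract(make_patient("P1", dates3, "Herceptin", cycles = 1:3)))
  expect_false(detect_truncated_start(p$records))
  # all cycle numbers missing: truncation cannot be asserted
  p <- codified(make_extract(make_patient("P1", dates3, "Herceptin", cycles = NA)))
  expect_false(detect_truncated_start(p$records))
  # a later regimen starting above 1 does not matter, only the earliest one
  p <- codified(make_extract(make_patient(
    "P1", c(dates3, "2018-03-05"), c(rep("Herceptin", 3), "Taxol"), cycles = c(1:3, 5)
  )))
  expect_false(detect_truncated_start(p$records))
})

test_that("other-cancer treatment detection uses the catalog list", {
  cat <- tiny_catalog()
  p <- codified(make_extract(make_patient("P1", dates3, c("Herceptin", "Taxol", "Mabthera"))))
  expect_true(detect_other_cancer_treatment(p$records, cat))
  p <- codified(make_extract(make_patient("P1", dates3[1:2], c("Herceptin", "Taxol"))))
  expect_false(detect_other_cancer_treatment(p$records, cat))
  # vacuous list: never triggers
  cat0 <- drug_catalog(cat$inn_by_brand[, c("brand", "inn")], character(0),
                       cat$drugs_of_interest)
  p <- codified(make_extract(make_patient("P1", dates3, "Mabthera")))
  expect_false(detect_other_cancer_treatment(p$records, cat0))
})

six_patient_fixture <- function() {
  make_extract(
    make_patient("P_ok", dates3, "Herceptin", cycles = 1:3),
    make_patient("P_r1", dates3, "Herceptin", cycles = 4:6),
    make_patient("P_r2", dates3, "trastuzumab", brands = c("Avastin", NA, NA), cycles = 1:3),
    make_patient("P_r3", c(dates3[1], dates3[1], dates3[2]), "Herceptin", cycles = c(1, 1, 2)),
    make_patient("P_r4", dates3, "Herceptin", cycles = 1:3,
                 diagnosis = c("breast_cancer", "other", "breast_cancer")),
    make_patient("P_r5", dates3, c("Herceptin", "Herceptin", "Mabthera"), cycles = c(1, 2, NA))
  )
}

test_that("each of the five rules removes exactly its constructed violator", {
  res <- apply_exclusions(codified(six_patient_fixture()), tiny_catalog())
  fc <- res$flowchart
  by_rule <- tapply(fc$excluded$n, fc$excluded$rule, sum)
  expect_equal(as.vector(by_rule[c("R1_truncated", "R2_name_mismatch",
                                   "R3_duplicate_injection", "R4_multi_primary",
                                   "R5_other_cancer_drug")]),
               rep(1L, 5))
  expect_equal(sum(fc$analyzable$n), 1)
  expect_equal(unique(res$extract$records$patient_id), "P_ok")
  expect_true(flowchart_conserved(fc))
})

test_that("a patient violating several rules is counted once, under the first", {
  # truncated start AND same-day duplicate: counted under R1 only
  p <- make_patient("P_both", c(dates3[1], dates3[1], dates3[2]), "Herceptin",
                    cycles = c(4, 4, 5))
  res <- apply_exclusions(codified(make_extract(p)), tiny_catalog())
  expect_equal(res$flowchart$excluded$rule, "R1_truncated")
  expect_equal(sum(res$flowchart$excluded$n), 1)
})

test_that("adding a clean patient changes no exclusion count", {
  base <- apply_exclusions(codified(six_patient_fixture()), tiny_catalog())
  more <- apply_exclusions(
    codified(make_extract(six_patient_fixture()$records,
                          make_patient("P_new", dates3, "Herceptin", cycles = 1:3))),
    tiny_catalog()
  )
  expect_equal(
    dplyr::arrange(more$flowchart$excluded, rule, cancer),
    dplyr::arrange(base$flowchart$excluded, rule, cancer)
  )
  expect_equal(sum(more$flowchart$analyzable$n), sum(base$flowchart$analyzable$n) + 1)
})

test_that("exclusions require a codified extract", {
  expect_error(apply_exclusions(six_patient_fixture(), tiny_catalog()), "codified")
})

test_that("per-rule counts equal injected counts on synthetic data", {
  cfg <- small_config(101, n_strata = 2, patients = 150,
                      truncation_rate = 0.05, duplicate_injection_rate = 0.04,
                      brand_mismatch_rate = 0.04, multi_primary_rate = 0.04,
                      other_drug_contamination_rate = 0.04)
  gen <- generate_extract(cfg)
  res <- apply_exclusions(codified(gen$extract, default_drug_catalog()),
                          default_drug_catalog())
  injected <- table(gen$truth$patients$error_rule)
  observed <- tapply(res$flowchart$excluded$n, res$flowchart$excluded$rule, sum)
  expect_equal(as.integer(observed[names(injected)]), as.integer(injected))
  # sensitivity 1.0: every injected violator is excluded
  expect_equal(sum(observed), sum(injected))
})

test_that("flow chart built from explicit counts enforces conservation", {
  fc <- flowchart(
    extracted = c(breast_cancer = 100L, lung_cancer = 50L),
    excluded = tibble::tibble(rule = c("R1_truncated", "R6_stage_unresolved"),
                              cancer = c("breast_cancer", "lung_cancer"),
                              n = c(10L, 5L))
  )
  expect_true(flowchart_conserved(fc))
  expect_equal(fc$analyzable$n, c(90L, 45L))
  rs <- retention_summary(fc)
  expect_equal(rs$overall$analyzable, 135)
  expect_error(
    flowchart(c(breast_cancer = 100L),
              tibble::tibble(rule = "R1_truncated", cancer = "breast_cancer", n = 10L),
              analyzable = c(breast_cancer = 80L))
  )
})
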