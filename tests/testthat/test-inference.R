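d <- function(...) as.Date(c(...))
w3 <- c("2018-01-01", "2018-01-22", "2018-02-12")

one_patient <- function(...) {
  ext <- codified(make_extract(make_patient(...)))
  eprflow:::sort_canonical(ext$records)
}

test_that("S1 fills missing stages from the nearest same-regimen record", {
  rec <- one_patient("P1", w3, "Herceptin", stages = c("metastatic", NA, NA))
  out <- infer_stage(rec)
  expect_equal(out$records$disease_stage, rep("metastatic", 3))
  expect_equal(out$audit$algorithm_id, rep("S1_fill_within_regimen", 2))
  expect_true(out$resolved)
  # backward preferred over forward
  rec <- one_patient("P1", w3, "Herceptin", stages = c("early", NA, "metastatic"))
  out <- infer_stage(rec)
  expect_equal(out$records$disease_stage[2], "early")
})

test_that("S2 assigns a stage from regimen-label keywords when a block is empty", {
  rec <- one_patient("P1", w3, "Herceptin", labels = "HERCEPTIN - METASTATIQUE")
  out <- infer_stage(rec)
  expect_equal(out$records$disease_stage, rep("metastatic", 3))
  expect_setequal(out$audit$algorithm_id, "S2_regimen_keyword")
  # uninformative label: unresolved, not dropped
  rec <- one_patient("P1", w3, "Herceptin", labels = "PROTOCOL 7")
  out <- infer_stage(rec)
  expect_false(out$resolved)
  expect_true(all(is.na(out$records$disease_stage)))
})

test_that("S3 ratchets stage severity upward over time", {
  rec <- one_patient("P1", w3, "Herceptin", stages = c("early", "metastatic", "early"))
  out <- infer_stage(rec)
  expect_equal(out$records$disease_stage, c("early", "metastatic", "metastatic"))
  expect_equal(out$audit$algorithm_id, "S3_severity_ratchet")
  expect_equal(out$audit$before, "early")
})

test_that("L1 fills a missing line from its regimen's recorded line", {
  rec <- one_patient("P1", c(w3, "2018-03-05"), c(rep("Herceptin", 3), "Taxol"),
                     stages = "metastatic", lines = c(1L, NA, 1L, 2L),
                     cycles = c(1:3, 1))
  out <- infer_line(rec)
  expect_equal(out$records$treatment_line, c(1L, 1L, 1L, 2L))
  expect_equal(out$audit$algorithm_id, "L1_fill_within_regimen")
})

test_that("L2 numbers unlabelled regimen blocks sequentially within a phase", {
  rec <- one_patient("P1", c(w3, "2018-03-05", "2018-03-26"),
                     c(rep("Herceptin", 3), "Taxol", "Taxol"),
                     stages = "metastatic", cycles = c(1:3, 1:2))
  out <- infer_line(rec)
  expect_equal(out$records$treatment_line, c(1L, 1L, 1L, 2L, 2L))
  expect_setequal(out$audit$algorithm_id, "L2_regimen_change_increment")
  # a treatment-free gap above gap_days also increments the line
  rec <- one_patient("P1", c("2018-01-01", "2018-06-01"), "Herceptin",
                     stages = "metastatic", cycles = c(1, 1))
  out <- infer_line(rec, gap_days = 60)
  expect_equal(out$records$treatment_line, c(1L, 2L))
})

test_that("line numbering restarts at the metastatic transition", {
  rec <- one_patient("P1", c(w3, "2018-03-05"), c(rep("Herceptin", 3), "Taxol"),
                     stages = c(rep("early", 3), rep("metastatic", 1)),
                     cycles = c(1:3, 1))
  out <- infer_line(rec)
  expect_equal(out$records$treatment_line, c(1L, 1L, 1L, 1L))
})

test_that("L3 forces lines non-decreasing within a phase", {
  rec <- one_patient("P1", c("2018-01-01", "2018-01-22"), c("Herceptin", "Taxol"),
                     stages = "metastatic", lines = c(2L, 1L), cycles = c(1, 1))
  out <- infer_line(rec)
  expect_equal(out$records$treatment_line, c(2L, 2L))
  expect_equal(out$audit$algorithm_id, "L3_monotonic_correction")
})

test_that("run_inference resolves or excludes every patient and audits every change", {
  ext <- codified(make_extract(
    make_patient("P_fill", w3, "Herceptin", stages = c("metastatic", NA, NA)),
    make_patient("P_label", w3, "Herceptin", labels = "X - METASTATIC"),
    make_patient("P_lost", w3, "Herceptin", labels = "PROTOCOL 7")
  ))
  fc0 <- apply_exclusions(ext, tiny_catalog())
  res <- run_inference(fc0$extract, fc0$flowchart)
  rec <- res$extract$records
  expect_equal(sort(unique(rec$patient_id)), c("P_fill", "P_label"))
  expect_false(anyNA(rec$disease_stage))
  expect_false(anyNA(rec$treatment_line))
  r6 <- res$flowchart$excluded[res$flowchart$excluded$rule == "R6_stage_unresolved", ]
  expect_equal(sum(r6$n), 1)
  expect_true(flowchart_conserved(res$flowchart))
  # every changed value has exactly one audit entry
  changed_stage <- sum(is.na(ext$records$disease_stage[
    ext$records$patient_id %in% c("P_fill", "P_label")]))
  expect_equal(sum(res$audit$field == "disease_stage" &
                     res$audit$patient_id != "P_lost"), changed_stage)
})

test_that("inference is idempotent and stages end up non-decreasing", {
  gen <- generate_extract(small_config(31, patients = 25))
  cod <- codified(gen$extract, default_drug_catalog())
  fc0 <- apply_exclusions(cod, default_drug_catalog())
  res1 <- run_inference(fc0$extract, fc0$flowchart)
  res2 <- run_inference(res1$extract, res1$flowchart)
  expect_equal(as.data.frame(res2$extract$records), as.data.frame(res1$extract$records))
  expect_equal(nrow(res2$audit), 0)
  # stage severity monotone and lines monotone within phase, per patient
  for (p in eprflow:::split_patients(res1$extract$records)) {
    sev <- eprflow:::stage_severity(p$disease_stage)
    expect_true(all(diff(sev) >= 0))
    for (ph in split(p$treatment_line, sev == 3)) {
      expect_true(all(diff(ph) >= 0))
    }
    expect_true(all(p$treatment_line >= 1))
  }
})

test_that("masked stages and lines are recovered to ground truth when recoverable", {
  gen <- generate_extract(small_config(41, patients = 40))
  cod <- codified(gen$extract, default_drug_catalog())
  fc0 <- apply_exclusions(cod, default_drug_catalog())
  res <- run_inference(fc0$extract, fc0$flowchart)
  rec <- res$extract$records
  tr <- gen$truth$records
  i <- match(rec$.row_id, tr$row_id)
  expect_equal(rec$disease_stage, tr$true_stage[i])
  expect_equal(rec$treatment_line, as.integer(tr$true_line[i]))
})

test_that("timeline rendering shows before/after values", {
  rec <- one_patient("P1", w3, "Herceptin", stages = c("metastatic", NA, NA))
  out <- infer_stage(rec)
  lines <- render_timeline(rec, out$records)
  expect_length(lines, 4)
  expect_match(lines[3], "\\? +-> metastatic")
})
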