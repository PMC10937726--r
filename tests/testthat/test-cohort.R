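test_that("initial diagnosis is the earliest PD-coded encounter", {
  d <- mk_diagnoses(day0 + c(100, 400), c("G20", "G20"))
  expect_equal(find_initial_diagnosis(d), day0 + 100)
  d2 <- mk_diagnoses(day0 + c(1, 2), c("I10", "E11.9"))
  expect_true(is.na(find_initial_diagnosis(d2)))
  d3 <- mk_diagnoses(day0 + 50, "332.0", vocab = "ICD9")
  expect_equal(find_initial_diagnosis(d3), day0 + 50)
  d4 <- mk_diagnoses(day0 + c(400, 100), c("G20", "G20"))
  expect_error(find_initial_diagnosis(d4), "sorted")
})

test_that("code matching honors vocabulary, normalization and prefix mode", {
  pd <- pd_code_set()
  expect_true(matches_code_set("332.0", "ICD9", pd))
  expect_true(matches_code_set("3320", "ICD9", pd))
  expect_true(matches_code_set("G20", "ICD10", pd))
  expect_false(matches_code_set("G20", "ICD9", pd))   # wrong vocabulary
  expect_false(matches_code_set("G21.9", "ICD10", pd))
  ex <- code_set("x", icd10 = "G30.9", match_mode = "exact")
  expect_true(matches_code_set("G309", "ICD10", ex))
  expect_false(matches_code_set("G30", "ICD10", ex))
  expect_error(code_set("empty"), "at least one code")
})

test_that("quiescence boundary is inclusive at exactly 730 days", {
  dx <- day0 + 1000
  pat <- list(encounters = mk_encounters(dx - 730))
  expect_true(passes_quiescence(pat, dx, "encounter"))
  pat2 <- list(encounters = mk_encounters(dx - 729))
  expect_false(passes_quiescence(pat2, dx, "encounter"))
  pat3 <- list(encounters = mk_encounters(dx + 10))
  expect_false(passes_quiescence(pat3, dx, "encounter"))
  expect_error(passes_quiescence(pat, dx, "telepathy"))
})

test_that("coverage quiescence requires full window containment", {
  dx <- day0 + 2000
  cov <- function(...) list(coverage = data.frame(
    patient_id = "p1",
    start = as.Date(sapply(list(...), `[[`, 1), origin = "1970-01-01"),
    end = as.Date(sapply(list(...), `[[`, 2), origin = "1970-01-01")))
  expect_false(passes_quiescence(cov(c(dx - 900, dx - 10)), dx, "coverage"))
  expect_true(passes_quiescence(cov(c(dx - 900, dx + 5)), dx, "coverage"))
  # split coverage: a gap breaks containment unless within tolerance
  split_cov <- cov(c(dx - 900, dx - 400), c(dx - 390, dx + 5))
  expect_false(passes_quiescence(split_cov, dx, "coverage"))
  expect_true(passes_quiescence(split_cov, dx, "coverage",
                                gap_tolerance = 10))
})

test_that("confirmatory diagnosis needs a PD code at least 30 days later", {
  dx <- day0
  d29 <- mk_diagnoses(day0 + c(0, 29), c("G20", "G20"))
  expect_false(has_confirmatory_diagnosis(d29, initial_dx = dx))
  d30 <- mk_diagnoses(day0 + c(0, 30), c("G20", "G20"))
  expect_true(has_confirmatory_diagnosis(d30, initial_dx = dx))
  d1 <- mk_diagnoses(day0, "G20")
  expect_false(has_confirmatory_diagnosis(d1, initial_dx = dx))
})

test_that("mimic exclusions apply only inside the quiescence window", {
  dx <- day0 + 1500
  d <- mk_diagnoses(dx - 60, "G30.9")  # Alzheimer's-like mimic
  expect_equal(apply_exclusions(d, initial_dx = dx), "mimic_dementia")
  d_old <- mk_diagnoses(dx - 3 * 365, "G30.9")
  expect_true(is.na(apply_exclusions(d_old, initial_dx = dx)))
  d_none <- mk_diagnoses(dx - 60, "I10")
  expect_true(is.na(apply_exclusions(d_none, initial_dx = dx)))
})

test_that("build_cohort applies filters in order with attrition accounting", {
  # p_q fails quiescence; p_c fails confirmation; p_x is mimic-excluded;
  # p_ok passes everything.
  mk_pat <- function(pid, enc_dates, dx_dates, dx_codes) {
    enc <- data.frame(patient_id = pid,
                      encounter_id = paste0(pid, "_e", seq_along(enc_dates)),
                      date = as.Date(enc_dates), setting = "outpatient",
                      has_treatment = FALSE, study_visit = FALSE,
                      stringsAsFactors = FALSE)
    dg <- data.frame(patient_id = pid,
                     encounter_id = paste0(pid, "_d", seq_along(dx_dates)),
                     date = as.Date(dx_dates), code = dx_codes,
                     vocabulary = "ICD10", code_type = "primary",
                     stringsAsFactors = FALSE)
    list(enc = enc, dg = dg)
  }
  dx <- day0 + 1000
  p_q <- mk_pat("p_q", dx - 100, c(dx, dx + 60), c("G20", "G20"))
  p_c <- mk_pat("p_c", dx - 800, c(dx, dx + 10), c("G20", "G20"))
  p_x <- mk_pat("p_x", dx - 800, c(dx - 50, dx, dx + 60),
                c("F03", "G20", "G20"))
  p_ok <- mk_pat("p_ok", dx - 800, c(dx, dx + 60), c("G20", "G20"))
  ds <- list(
    patients = data.frame(patient_id = c("p_q", "p_c", "p_x", "p_ok"),
                          sex = "M", birth_date = day0 - 20000,
                          stringsAsFactors = FALSE),
    encounters = rbind(p_q$enc, p_c$enc, p_x$enc, p_ok$enc),
    diagnoses = rbind(p_q$dg, p_c$dg, p_x$dg, p_ok$dg),
    coverage = data.frame(patient_id = character(),
                          start = as.Date(character()),
                          end = as.Date(character())),
    config = NULL, ground_truth = NULL)
  coh <- build_cohort(ds, quiescence_mode = "encounter")
  expect_equal(unname(coh$attrition[c("quiescence_fail", "no_confirmation",
                                      "mimic_excluded", "included")]),
               c(1, 1, 1, 1))
  expect_equal(coh$cohort$included,
               coh$cohort$patient_id == "p_ok")
  expect_equal(coh$cohort$excluded_reason[coh$cohort$patient_id == "p_x"],
               "mimic_dementia")
  expect_equal(sum(coh$attrition[-1]), coh$attrition[["input"]])
  expect_error(build_cohort(list(patients = ds$patients[0, ])), "empty")
})

test_that("build_cohort matches a naive per-patient re-evaluation", {
  ds <- generate_dataset(make_archetype_config("rwd_emr"), 1000, 2)
  coh <- build_cohort(ds)
  pdc <- pd_code_set()
  excl <- mimic_exclusion_sets()
  naive_included <- vapply(ds$patients$patient_id, function(p) {
    d <- ds$diagnoses[ds$diagnoses$patient_id == p, ]
    d <- d[order(d$date), ]
    hit <- matches_code_set(d$code, d$vocabulary, pdc)
    if (!any(hit)) return(FALSE)
    idx <- min(d$date[hit])
    enc <- ds$encounters[ds$encounters$patient_id == p, ]
    if (!any(enc$date <= idx - 730)) return(FALSE)
    if (!any(hit & d$date >= idx + 30)) return(FALSE)
    win <- d[d$date >= idx - 730 & d$date <= idx, ]
    for (s in excl)
      if (any(matches_code_set(win$code, win$vocabulary, s))) return(FALSE)
    TRUE
  }, logical(1))
  expect_equal(coh$cohort$included, unname(naive_included))
})

test_that("shrinking the quiescence window never decreases the pass count", {
  ds <- generate_dataset(make_archetype_config("rwd_emr"), 300, 4)
  counts <- vapply(c(730, 365, 180, 30), function(w)
    sum(build_cohort(ds, window = w)$cohort$quiescence_pass), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("included set is order-invariant (filters are conjunctive)", {
  ds <- generate_dataset(make_archetype_config("rwd_emr"), 300, 6)
  coh <- build_cohort(ds)
  pdc <- pd_code_set()
  # evaluate each filter independently and intersect
  per_filter <- lapply(ds$patients$patient_id, function(p) {
    d <- ds$diagnoses[ds$diagnoses$patient_id == p, ]
    d <- d[order(d$date), ]
    idx <- find_initial_diagnosis(d, pdc)
    if (is.na(idx)) return(FALSE)
    enc <- ds$encounters[ds$encounters$patient_id == p, ]
    all(passes_quiescence(list(encounters = enc), idx, "encounter"),
        has_confirmatory_diagnosis(d, pdc, idx),
        is.na(apply_exclusions(d, initial_dx = idx)))
  })
  expect_equal(coh$cohort$included, unlist(per_filter))
})

test_that("research archetype bypasses quiescence and exclusions", {
  ds <- generate_dataset(make_archetype_config("research"), 100, 3)
  coh <- build_cohort(ds)
  expect_equal(coh$attrition[["included"]], 100)
  expect_equal(coh$quiescence_mode, "none")
})
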