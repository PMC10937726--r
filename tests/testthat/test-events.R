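pd_enc <- data.frame(encounter_id = "pd1", date = day0,
                     stringsAsFactors = FALSE)

test_that("therapy initiation episode rule on hand-built fill sequences", {
  # 30 + 30 + 31 = 91 days of supply, third fill at offset 100 in (90, 180]
  f <- mk_fills(c(0, 40, 100), c(30, 30, 31),
                linked = c("pd1", NA, NA))
  expect_equal(detect_therapy_initiation(f, pd_enc), day0)
  # a single 90-day fill never qualifies
  f1 <- mk_fills(0, 90, linked = "pd1")
  expect_true(is.na(detect_therapy_initiation(f1, pd_enc)))
  # no companion fill inside the 180-day window
  f2 <- mk_fills(c(0, 200), c(60, 60), linked = c("pd1", NA))
  expect_true(is.na(detect_therapy_initiation(f2, pd_enc)))
  # 91 days over two fills but the second at offset 40 (not > 90)
  f3 <- mk_fills(c(0, 40), c(60, 31), linked = c("pd1", NA))
  expect_true(is.na(detect_therapy_initiation(f3, pd_enc)))
  # unlinked first fill fails unless linkage is waived or same-day PD visit
  f4 <- mk_fills(c(0, 40, 100), c(30, 30, 31))
  expect_true(is.na(detect_therapy_initiation(
    f4, data.frame(encounter_id = "pd1", date = day0 + 999))))
  expect_equal(detect_therapy_initiation(f4, pd_enc), day0)  # same-day PD
  rule0 <- therapy_rule(require_pd_linked_first_fill = FALSE)
  expect_equal(detect_therapy_initiation(
    f4, pd_enc[0, ], rule = rule0), day0)
  # drug class filter
  expect_true(is.na(detect_therapy_initiation(f, pd_enc,
                                              drug_classes = "other_pd")))
  expect_error(detect_therapy_initiation(mk_fills(c(10, 0), c(30, 30)),
                                         pd_enc), "sorted")
})

test_that("relaxing min_total_days never removes a detection", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    f <- mk_fills(sort(sample(0:200, k)), sample(10:90, k, replace = TRUE),
                  linked = c("pd1", rep(NA, k - 1)))
    strict <- detect_therapy_initiation(f, pd_enc,
                                        rule = therapy_rule(min_total_days = 90))
    lax <- detect_therapy_initiation(f, pd_enc,
                                     rule = therapy_rule(min_total_days = 50))
    if (!is.na(strict)) expect_false(is.na(lax))
    if (!is.na(strict) && !is.na(lax)) expect_lte(as.numeric(lax - strict), 0)
  }
})

test_that("real-world cognitive decline proxy follows the and/or grouping", {
  enc <- mk_encounters(day0 + c(400, 500), ids = c("e1", "e2"))
  # MCI code day 400; cognitive fill at a PD-coded encounter day 500
  pat <- list(
    encounters = enc,
    diagnoses = mk_diagnoses(day0 + c(400, 500), c("G31.84", "G20"),
                             enc_ids = c("e1", "e2")),
    fills = mk_fills(500, 30, classes = "cognitive", linked = "e2"),
    referrals = data.frame(patient_id = character(),
                           date = as.Date(character()), code = character()))
  expect_equal(detect_cognitive_decline_rwd(pat), day0 + 500)
  # referral alone qualifies at its date
  pat2 <- list(encounters = enc, diagnoses = mk_diagnoses(day0, "G20"),
               fills = mk_fills(0, 0)[0, ],
               referrals = data.frame(patient_id = "p1", date = day0 + 300,
                                      code = "REF_NEURO_COGNITIVE"))
  expect_equal(detect_cognitive_decline_rwd(pat2), day0 + 300)
  # cognitive fill at a non-PD encounter, no MCI, no referral: nothing
  pat3 <- list(
    encounters = enc,
    diagnoses = mk_diagnoses(day0 + 400, "I10", enc_ids = "e1"),
    fills = mk_fills(400, 30, classes = "cognitive", linked = "e1"),
    referrals = pat$referrals)
  expect_true(is.na(detect_cognitive_decline_rwd(pat3)))
  # the any-of-three reading fires on the earliest signal
  expect_equal(detect_cognitive_decline_rwd(pat, grouping = "any"),
               day0 + 400)
})

test_that("MMSE cognitive-decline cutoff is inclusive at 25", {
  expect_true(is.na(detect_cognitive_decline_mmse(
    mk_scores(c(0, 100, 200), c(28, 26, 27), "mmse"))))
  s <- mk_scores(c(0, 100), c(28, 25), "mmse")
  expect_equal(detect_cognitive_decline_mmse(s), day0 + 100)
  s2 <- mk_scores(0, 24, "mmse")
  expect_equal(detect_cognitive_decline_mmse(s2), day0)
})

test_that("score threshold events fire at the first value >= threshold", {
  s <- mk_scores(c(0, 100, 200), c(2, 2.5, 3))
  expect_equal(detect_score_threshold_event(s), day0 + 200)
  expect_true(is.na(detect_score_threshold_event(
    mk_scores(c(0, 100), c(2, 2.5)))))
  expect_equal(detect_score_threshold_event(mk_scores(0, 3.5)), day0)
})

test_that("adverse events need primary/admitting code plus inpatient or treatment", {
  codes <- adverse_event_code_sets()$falls_fractures
  dx <- day0
  # secondary code, outpatient, no treatment: no event
  pat <- list(
    encounters = mk_encounters(dx + 100, ids = "e1"),
    diagnoses = mk_diagnoses(dx + 100, "S72.00", code_type = "secondary",
                             enc_ids = "e1"))
  expect_true(is.na(detect_adverse_event(pat, codes, dx)$date))
  # primary at outpatient without treatment still fails
  pat$diagnoses$code_type <- "primary"
  expect_true(is.na(detect_adverse_event(pat, codes, dx)$date))
  # admitting code at an inpatient stay qualifies
  pat2 <- list(
    encounters = mk_encounters(dx + 600, setting = "inpatient", ids = "e1"),
    diagnoses = mk_diagnoses(dx + 600, "W19", code_type = "admitting",
                             enc_ids = "e1"))
  a <- detect_adverse_event(pat2, codes, dx)
  expect_equal(a$date, dx + 600)
  expect_true(a$eligible)
  # outpatient with recorded treatment qualifies
  pat3 <- list(
    encounters = mk_encounters(dx + 50, has_treatment = TRUE, ids = "e1"),
    diagnoses = mk_diagnoses(dx + 50, "W19", enc_ids = "e1"))
  expect_equal(detect_adverse_event(pat3, codes, dx)$date, dx + 50)
  # any event code in the quiescence window voids eligibility
  pat4 <- list(
    encounters = mk_encounters(c(dx - 100, dx + 600),
                               setting = c("outpatient", "inpatient"),
                               ids = c("e0", "e1")),
    diagnoses = mk_diagnoses(c(dx - 100, dx + 600), c("W19", "W19"),
                             code_type = c("secondary", "admitting"),
                             enc_ids = c("e0", "e1")))
  expect_false(detect_adverse_event(pat4, codes, dx)$eligible)
})

test_that("phi coefficient matches the closed-form 2x2 computation", {
  a <- c(1, 1, 0, 0, 1, 0)
  expect_equal(phi_coefficient(a, a), 1.0)
  expect_equal(phi_coefficient(a, 1 - a), -1.0)
  expect_equal(phi_coefficient(c(1, 1, 0, 0), c(1, 0, 0, 0)), 2 / sqrt(12))
  expect_error(phi_coefficient(c(1, 1), c(1, 0, 0)), "equal length")
  expect_error(phi_coefficient(c(1, 1, 1), c(1, 0, 1)), "constant")
  # matches cor() on binary vectors wherever defined
  set.seed(5)
  for (i in 1:10) {
    x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(phi_coefficient(x, y), unname(cor(x, y)), tolerance = 1e-12)
  }
})

test_that("detected event times equal ground truth at the observation grid", {
  ds <- generate_dataset(make_archetype_config("rwd_emr"), 300, 21)
  coh <- build_cohort(ds)
  sc <- analysis_scores(ds, scales = "hy")
  ev <- detect_events(ds, coh, events = c("pd_therapy", "hy3"), scores = sc)
  gt <- ds$ground_truth

  th <- ev[ev$event_type == "pd_therapy" & ev$observed %in% TRUE, ]
  j <- match(th$patient_id, gt$patient_id)
  # detected initiation is the true start date (first fill of the sequence)
  expect_lt(max(abs(th$time_years - gt$t_therapy[j])), 3 / 365.25)

  hy <- ev[ev$event_type == "hy3" & ev$observed %in% TRUE, ]
  j2 <- match(hy$patient_id, gt$patient_id)
  # with zero H&Y noise the crossing is seen at the first encounter at or
  # after the true crossing time: never before, within one encounter gap after
  expect_true(all(hy$time_years >= gt$t_hy3[j2] - 1e-6))
  expect_lt(mean(hy$time_years - gt$t_hy3[j2]), 0.6)
})
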