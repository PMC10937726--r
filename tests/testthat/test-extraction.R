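test_that("reference extractor parses templates, absence and conflicts", {
  expect_equal(reference_extractor("Hoehn and Yahr stage: 2.5.", "hy"), "2.5")
  expect_equal(reference_extractor("MMSE: 27/30.", "mmse"), "27")
  expect_equal(reference_extractor("UPDRS total: 41.5.", "updrs_total"),
               "41.5")
  expect_true(is.na(reference_extractor(
    "Blood pressure 128/76. Gait assessed over 10 meters.", "hy")))
  two <- "Hoehn and Yahr stage: 2. Later note: Hoehn and Yahr stage: 3."
  expect_equal(reference_extractor(two, "hy"), "ambiguous")
  # repeated identical mention is not a conflict
  same <- "Hoehn and Yahr stage: 3. Confirmed Hoehn and Yahr stage: 3."
  expect_equal(reference_extractor(same, "hy"), "3")
})

test_that("score token normalization handles the documented dialects", {
  expect_equal(normalize_score_value("2,5"), "2.5")
  expect_equal(normalize_score_value("II.5"), "2.5")
  expect_equal(normalize_score_value("III"), "3")
  expect_equal(normalize_score_value("28/30"), "28")
  expect_equal(normalize_score_value("3.0"), "3")
  expect_equal(normalize_score_value(" 4 "), "4")
  expect_true(is.na(normalize_score_value("NA")))
  expect_true(is.na(normalize_score_value("unknown")))
})

test_that("unanimous runs are accepted with the modal value", {
  be <- scripted_backend(rep("3", 10), rep("3", 10))
  res <- run_consensus("x", "hy", be)
  expect_false(res$flagged)
  expect_equal(res$final_value, 3)
  expect_equal(unname(res$agreement), c(10L, 10L))
  expect_equal(res$provenance, "consensus")
})

test_that("the 4/10 and 5/10 agreement pattern is flagged", {
  pos <- c(rep("2", 4), c("3", "1", "4", "2.5", "5", "1.5"))
  neg <- c(rep("2", 5), c("3", "1", "4", "2.5", "5"))
  res <- run_consensus("x", "hy", scripted_backend(pos, neg))
  expect_true(res$flagged)
  expect_true(is.na(res$final_value))
})

test_that("9/10 with 10/10 on the same value passes the threshold", {
  pos <- c(rep("3", 9), "2")
  neg <- rep("3", 10)
  res <- run_consensus("x", "hy", scripted_backend(pos, neg))
  expect_false(res$flagged)
  expect_equal(res$final_value, 3)
  # 8/10 fails
  pos8 <- c(rep("3", 8), "2", "4")
  expect_true(run_consensus("x", "hy", scripted_backend(pos8, neg))$flagged)
  # polarity modal disagreement fails even with high counts
  resx <- run_consensus("x", "hy", scripted_backend(rep("3", 10),
                                                    rep("2", 10)))
  expect_true(resx$flagged)
})

test_that("modal ties flag the note and errors mark error provenance", {
  pos <- c(rep("2", 5), rep("3", 5))
  res <- run_consensus("x", "hy", scripted_backend(pos, rep("2", 10)))
  expect_true(res$flagged)
  err_be <- function(text, scale, polarity, run_index) stop("backend down")
  res2 <- run_consensus("x", "hy", err_be)
  expect_true(res2$flagged)
  expect_equal(res2$provenance, "error")
  expect_error(run_consensus("x", "hy", scripted_backend(rep("3", 10),
                                                         rep("3", 10)),
                             threshold = 11), "threshold")
})

test_that("consensus agrees on absent scores via the none token", {
  be <- scripted_backend(rep(NA_character_, 10), rep(NA_character_, 10))
  res <- run_consensus("x", "hy", be)
  expect_false(res$flagged)
  expect_true(is.na(res$final_value))
})

test_that("pooled variant applies a single 18-of-20 rule", {
  pos <- c(rep("3", 9), "2"); neg <- c(rep("3", 9), "2")
  per <- run_consensus("x", "hy", scripted_backend(pos, neg),
                       pooling = "per_polarity")
  pooled <- run_consensus("x", "hy", scripted_backend(pos, neg),
                          pooling = "pooled")
  expect_false(per$flagged)
  expect_equal(unname(pooled$agreement), 18L)
  expect_false(pooled$flagged)
  pos2 <- c(rep("3", 9), "2"); neg2 <- c(rep("3", 8), "2", "2")
  expect_true(run_consensus("x", "hy", scripted_backend(pos2, neg2),
                            pooling = "pooled")$flagged)
})

test_that("raising the threshold never unflags a note", {
  set.seed(42)
  for (i in 1:25) {
    pos <- as.character(sample(1:4, 10, replace = TRUE, prob = c(6, 1, 1, 1)))
    neg <- as.character(sample(1:4, 10, replace = TRUE, prob = c(6, 1, 1, 1)))
    be <- scripted_backend(pos, neg)
    flags <- vapply(5:10, function(th)
      run_consensus("x", "hy", be, threshold = th)$flagged, logical(1))
    expect_true(all(diff(as.integer(flags)) >= 0))
  }
})

test_that("deterministic backend round-trip is exact and unflagged", {
  ds <- generate_dataset(make_archetype_config("rwd_emr"), 400, 8)
  truth <- ds$note_truth
  for (sc in c("hy", "mmse")) {
    ex <- extract_scores(ds$notes, sc, reference_backend())
    expect_false(any(ex$flagged))
    g <- truth$value[truth$scale == sc][match(ex$note_id,
                                              truth$note_id[truth$scale == sc])]
    acc <- score_accuracy(ex, data.frame(note_id = ex$note_id, value = g))
    expect_equal(acc$accuracy, 1.0)
  }
})

test_that("noisy-backend flag rates match the binomial expectation", {
  ds <- generate_dataset(make_archetype_config("rwd_emr"), 260, 12)
  notes <- ds$notes[seq_len(min(250, nrow(ds$notes))), ]
  for (p in c(0.05, 0.2)) {
    ex <- extract_scores(notes, "hy", mock_noisy_backend(p, seed = 3))
    p_ok <- sum(dbinom(9:10, 10, 1 - p))  # P(>= 9 uncorrupted runs per set)
    expected_flag <- 1 - p_ok^2
    se <- sqrt(expected_flag * (1 - expected_flag) / nrow(notes))
    expect_lt(abs(mean(ex$flagged) - expected_flag), 4 * se + 0.02)
  }
})

test_that("audit sampling draws the requested strata without replacement", {
  res <- data.frame(note_id = sprintf("n%04d", 1:1000),
                    final_value = c(rep(3, 500), rep(NA, 500)),
                    flagged = FALSE, provenance = "consensus",
                    stringsAsFactors = FALSE)
  gold <- data.frame(note_id = res$note_id,
                     value = c(rep(3, 480), rep(NA, 520)))
  s <- audit_sample(res, gold, sizes = c(200, 200, 200, 200), seed = 1)
  expect_equal(unname(s$sizes), c(200L, 200L, 200L, 200L))
  expect_equal(sum(s$sizes), 800)
  for (st in s$strata) expect_false(any(duplicated(st)))
  s2 <- audit_sample(res, gold, sizes = 100, seed = 1)
  expect_equal(sum(s2$sizes), 400)
  # exhaustion: take all with a warning
  small <- res[1:40, ]
  w <- capture_warnings(s3 <- audit_sample(small, gold, sizes = 200,
                                           seed = 1))
  expect_true(any(grepl("taking all", w)))
  expect_lte(max(s3$sizes), 40)
  # seeded: reproducible
  expect_identical(audit_sample(res, gold, 50, seed = 9)$strata,
                   audit_sample(res, gold, 50, seed = 9)$strata)
})

test_that("accuracy counts value matches and none-none agreement", {
  res <- data.frame(note_id = sprintf("n%03d", 1:800),
                    final_value = c(rep(3, 798), 2, 2))
  gold <- data.frame(note_id = res$note_id, value = rep(3, 800))
  acc <- score_accuracy(res, gold)
  expect_equal(acc$accuracy, 0.9975)
  expect_equal(nrow(acc$errors), 2)
  acc2 <- score_accuracy(res[1:798, ], gold[1:798, ])
  expect_equal(acc2$accuracy, 1.0)
  res3 <- data.frame(note_id = c("a", "b"), final_value = c(NA, NA))
  gold3 <- data.frame(note_id = c("a", "b"), value = c(3, NA))
  expect_equal(score_accuracy(res3, gold3)$accuracy, 0.5)
})

test_that("corrections only overwrite flagged notes", {
  res <- data.frame(note_id = c("a", "b"), final_value = c(NA, 3),
                    flagged = c(TRUE, FALSE),
                    provenance = c("consensus", "consensus"),
                    stringsAsFactors = FALSE)
  out <- apply_corrections(res, c(a = 2.5))
  expect_equal(out$final_value[1], 2.5)
  expect_equal(out$provenance[1], "manual_correction")
  expect_error(apply_corrections(res, c(b = 4)), "flagged")
  expect_error(apply_corrections(res, c(zz = 4)), "unknown note")
  expect_identical(apply_corrections(res, list()), res)
})
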