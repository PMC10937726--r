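# Small hand-built fixtures used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

day0 <- as.Date("2015-06-01")

mk_encounters <- function(dates, setting = "outpatient",
                          has_treatment = FALSE, ids = NULL) {
  n <- length(dates)
  data.frame(patient_id = rep("p1", n),
             encounter_id = ids %||% sprintf("e%03d", seq_len(n)),
             date = as.Date(dates), setting = rep_len(setting, n),
             has_treatment = rep_len(has_treatment, n),
             study_visit = FALSE, stringsAsFactors = FALSE)
}

mk_diagnoses <- function(dates, codes, vocab = "ICD10",
                         code_type = "primary", enc_ids = NULL) {
  n <- length(dates)
  data.frame(patient_id = rep("p1", n),
             encounter_id = enc_ids %||% sprintf("e%03d", seq_len(n)),
             date = as.Date(dates), code = codes,
             vocabulary = rep_len(vocab, n),
             code_type = rep_len(code_type, n), stringsAsFactors = FALSE)
}

mk_fills <- function(offsets, supplies, classes = "levodopa",
                     linked = NULL, start = day0) {
  n <- length(offsets)
  data.frame(patient_id = rep("p1", n), date = start + offsets,
             drug_code = "LEVODOPA_CARBIDOPA",
             drug_class = rep_len(classes, n),
             days_supply = supplies,
             linked_encounter_id = linked %||% rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

mk_scores <- function(offsets, values, scale = "hy", start = day0) {
  data.frame(patient_id = "p1", date = start + offsets, scale = scale,
              value = values, stringsAsFactors = FALSE)
}

# Independent brute-force product-limit estimator (oracle for km_fit).
naive_product_limit <- function(time, observed) {
  ut <- sort(unique(time[observed]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & observed)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ut, surv = surv,
       median = if (any(surv <= 0.5 + 1e-12)) ut[min(which(surv <= 0.5 + 1e-12))]
       else NA_real_)
}

# Backend whose outputs are scripted per (polarity, run_index).
scripted_backend <- function(pos_outputs, neg_outputs) {
  function(text, scale, polarity, run_index) {
    if (identical(polarity, "positive")) pos_outputs[[run_index]]
    else neg_outputs[[run_index]]
  }
}
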