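#' Generate a synthetic longitudinal EHR/claims dataset
#'
#' Draws a population of Parkinson's disease patients under a source archetype
#' (see [make_archetype_config()]) and emits the observable tables an
#' EHR/claims analysis would see — patients, encounters, diagnoses,
#' prescription fills, referrals, coverage intervals (claims archetype),
#' clinical notes and/or structured scores — together with the hidden ground
#' truth (true event times and trajectory parameters) that parameter-recovery
#' tests compare against.
#'
#' The generative model: age at diagnosis is truncated normal; follow-up is
#' exponential with the configured mean; encounters arrive as a homogeneous
#' Poisson process (research archetypes add annual structured study visits);
#' score trajectories are linear per patient (population intercept plus a
#' patient-level random intercept, plus observation noise, clamped to the
#' scale range, H&Y floor-quantized to half stages); event times (H&Y stage 3,
#' cognitive decline) are Weibull with shape `event_shape` and scale solved
#' from the configured median; therapy-initiation delays are truncated normal;
#' adverse events are exponential. Therapy starts materialize as prescription
#' fill sequences that satisfy the initiation episode rule whenever the whole
#' sequence fits inside follow-up.
#'
#' @param config An [make_archetype_config()] object.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; identical `(config, n, seed)` give identical
#'   datasets.
#' @return A list of class `ehr_dataset` with data-frame elements `patients`,
#'   `encounters`, `diagnoses`, `fills`, `referrals`, `coverage`, `notes`,
#'   `note_truth`, `scores`, `ground_truth`, plus `archetype` and `seed`.
#' @export
generate_dataset <- function(config, n, seed) {
  stopifnot(inherits(config, "archetype_config"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  cfg <- config

  base_date <- as.Date("2012-01-01")
  dx_date <- base_date + sample.int(4L * 365L, n, replace = TRUE)
  ## truncation shifts the mean of a plain normal; centre the location so the
  ## truncated distribution's mean equals the configured mean
  age_mu <- trunc_norm_mu_for_mean(cfg$age_at_dx_mean, cfg$age_at_dx_sd,
                                   cfg$age_at_dx_range[1],
                                   cfg$age_at_dx_range[2])
  age_at_dx <- rnorm_trunc(n, age_mu, cfg$age_at_dx_sd,
                           cfg$age_at_dx_range[1], cfg$age_at_dx_range[2])
  sex <- ifelse(runif(n) < cfg$pct_male, "M", "F")
  birth_date <- dx_date - round(age_at_dx * DAYS_PER_YEAR)
  ## follow-up: exponential truncated at a records-era cap, with the rate
  ## solved so the truncated mean equals the configured follow-up mean
  fu_scale <- exp_mean_for_capped(cfg$followup_mean, cfg$followup_cap)
  followup <- pmax(pmin(rexp(n, 1 / fu_scale), cfg$followup_cap), 0.15)
  censor_date <- add_years(dx_date, followup)
  has_hist <- runif(n) < cfg$pre_dx_prob
  hist_years <- ifelse(has_hist,
                       2 + rexp(n, 1 / cfg$pre_dx_extra_years_mean),
                       runif(n, 0.2, 1.9))
  history_start <- dx_date - round(hist_years * DAYS_PER_YEAR)
  recorded_dx_date <- if (cfg$dx_resolution == "year")
    as.Date(paste0(format(dx_date, "%Y"), "-01-01")) else dx_date
  pid <- sprintf("%s_%05d", cfg$name, seq_len(n))

  ## --- true event times (years since true diagnosis) ---
  t_hy3 <- rweibull(n, cfg$event_shape,
                    weibull_scale_for_median(cfg$hy3_median_years,
                                             cfg$event_shape))
  t_cog <- rweibull(n, cfg$event_shape,
                    weibull_scale_for_median(cfg$cogdecline_median_years,
                                             cfg$event_shape))
  t_therapy <- pmax(rnorm(n, cfg$therapy_delay_mean, cfg$therapy_delay_sd),
                    0.05)
  t_lev_raw <- pmax(rnorm(n, cfg$levodopa_delay_mean, cfg$therapy_delay_sd),
                    0.05)
  first_line_levodopa <- t_lev_raw <= t_therapy
  t_levodopa <- ifelse(first_line_levodopa, t_therapy, t_lev_raw)
  t_falls <- rexp(n, cfg$adverse_event_rates[["falls_fractures"]])
  t_depression <- rexp(n, cfg$adverse_event_rates[["depression"]])

  ## --- trajectory parameters ---
  updrs_int_i <- cfg$updrs_intercept +
    rnorm(n, 0, cfg$random_intercept_sd[["updrs_total"]])
  mmse_int_i <- cfg$mmse_intercept +
    rnorm(n, 0, cfg$random_intercept_sd[["mmse"]])
  hy_slope_i <- (3 - cfg$hy_intercept) / t_hy3

  ## couple the utilization-based cognitive-decline event to the latent MMSE
  ## trajectory: comonotone (rank) coupling with the trajectory's crossing
  ## time of the MMSE <= 25 impairment cutoff, keeping the configured Weibull
  ## marginal — patients whose cognition declines early also hit the
  ## utilization definition early.
  if (cfg$mmse_slope < 0) {
    t_cross <- (25 - mmse_int_i) / cfg$mmse_slope
    t_cog <- sort(t_cog)[rank(t_cross, ties.method = "first")]
  }

  ## --- score recording: marginal probability score_recording_prob, with a
  ## weak specialist-visit signal (odds ratio specialist_or) ---
  specialist <- runif(n) < cfg$specialist_prob
  p0 <- solve_base_recording_prob(cfg$score_recording_prob,
                                  cfg$specialist_prob, cfg$specialist_or)
  p_rec <- ifelse(specialist, plogis(qlogis_safe(p0) + log(cfg$specialist_or)),
                  p0)
  recorder <- runif(n) < p_rec

  mimic <- runif(n) < cfg$mimic_code_prob
  falls_history <- runif(n) < cfg$adverse_history_prob
  depression_history <- runif(n) < cfg$adverse_history_prob

  ground_truth <- data.frame(
    patient_id = pid, sex = sex, age_at_dx = age_at_dx,
    dx_date = dx_date, recorded_dx_date = recorded_dx_date,
    followup_years = followup, censor_date = censor_date,
    history_start = history_start, has_history = has_hist,
    t_hy3 = t_hy3, t_cog = t_cog, t_therapy = t_therapy,
    t_levodopa = t_levodopa, first_line_levodopa = first_line_levodopa,
    t_falls = t_falls, t_depression = t_depression,
    updrs_intercept_i = updrs_int_i, updrs_slope = cfg$updrs_slope,
    mmse_intercept_i = mmse_int_i, mmse_slope = cfg$mmse_slope,
    hy_intercept = cfg$hy_intercept, hy_slope_i = hy_slope_i,
    recorder = recorder, specialist = specialist, mimic = mimic,
    falls_history = falls_history, depression_history = depression_history,
    stringsAsFactors = FALSE)

  ## --- encounters -----------------------------------------------------------
  enc <- build_encounters(cfg, ground_truth)
  encounters <- enc$encounters
  diagnoses <- enc$diagnoses

  ## event encounters (therapy first fill, cognitive decline, adverse events)
  extra <- build_event_records(cfg, ground_truth)
  encounters <- rbind(encounters, extra$encounters)
  diagnoses <- rbind(diagnoses, extra$diagnoses)
  fills <- extra$fills
  referrals <- extra$referrals

  ord <- order(encounters$patient_id, encounters$date, encounters$encounter_id)
  encounters <- encounters[ord, , drop = FALSE]
  rownames(encounters) <- NULL
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date), ,
                         drop = FALSE]
  rownames(diagnoses) <- NULL

  ## --- coverage intervals (claims archetype) --------------------------------
  coverage <- build_coverage(cfg, ground_truth)

  ## --- score observations, structured or as notes ---------------------------
  obs <- build_score_observations(cfg, ground_truth, encounters)
  scores <- obs$scores
  notes <- obs$notes
  note_truth <- obs$note_truth

  structure(list(
    patients = data.frame(patient_id = pid, sex = sex,
                          birth_date = birth_date, stringsAsFactors = FALSE),
    encounters = encounters, diagnoses = diagnoses, fills = fills,
    referrals = referrals, coverage = coverage,
    notes = notes, note_truth = note_truth, scores = scores,
    ground_truth = ground_truth,
    archetype = cfg$name, config = cfg, seed = as.integer(seed)),
    class = "ehr_dataset")
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>", x$archetype, "-", nrow(x$patients), "patients,",
      nrow(x$encounters), "encounters,", nrow(x$notes), "notes\n")
  invisible(x)
}

qlogis_safe <- function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))

## Base recording probability p0 such that the marginal probability of score
## recording equals `target` when a `spec_prob` fraction of patients carry a
## specialist flag shifting the log-odds by log(or).
solve_base_recording_prob <- function(target, spec_prob, or) {
  if (target <= 0) return(0)
  if (target >= 1) return(1)
  f <- function(p0) {
    (1 - spec_prob) * p0 + spec_prob * plogis(qlogis_safe(p0) + log(or)) -
      target
  }
  uniroot(f, c(1e-10, target))$root
}

## ---------------------------------------------------------------------------

build_encounters <- function(cfg, gt) {
  n <- nrow(gt)
  ## guaranteed first encounter at history start + Poisson pre-diagnosis
  ## encounters, the diagnosis-day encounter, Poisson post-diagnosis
  ## encounters, and (research) annual study visits.
  n_pre <- rpois(n, cfg$encounter_rate * as.numeric(gt$dx_date - gt$history_start) / DAYS_PER_YEAR)
  n_post <- rpois(n, cfg$encounter_rate * gt$followup_years)

  pre_pid <- rep(gt$patient_id, n_pre)
  pre_span <- rep(as.numeric(gt$dx_date - gt$history_start), n_pre)
  pre_date <- rep(gt$history_start, n_pre) + floor(runif(sum(n_pre)) * pre_span)

  post_pid <- rep(gt$patient_id, n_post)
  post_t <- runif(sum(n_post)) * rep(gt$followup_years, n_post)
  post_date <- rep(gt$dx_date, n_post) + pmax(1, round(post_t * DAYS_PER_YEAR))

  visit_pid <- character(0); visit_date <- as.Date(character(0))
  visit_flag <- logical(0)
  if (isTRUE(cfg$study_visits)) {
    u0 <- runif(n, 0, 0.5)
    n_vis <- pmax(0L, floor(gt$followup_years - u0) + 1L)
    visit_pid <- rep(gt$patient_id, n_vis)
    visit_t <- rep(u0, n_vis) + (sequence(n_vis) - 1L)
    visit_date <- rep(gt$dx_date, n_vis) + round(visit_t * DAYS_PER_YEAR)
    visit_flag <- rep(TRUE, length(visit_pid))
  }

  pid_all <- c(gt$patient_id, gt$patient_id, pre_pid, post_pid, visit_pid)
  date_all <- c(gt$history_start, gt$dx_date, pre_date, post_date, visit_date)
  study_visit <- c(rep(FALSE, 2L * n + length(pre_pid) + length(post_pid)),
                   visit_flag)
  is_dx_day <- c(rep(FALSE, n), rep(TRUE, n),
                 rep(FALSE, length(pre_pid) + length(post_pid) + length(visit_pid)))

  m <- length(pid_all)
  encounters <- data.frame(
    patient_id = pid_all,
    encounter_id = sprintf("E%08d", seq_len(m)),
    date = date_all,
    setting = rep("outpatient", m),
    has_treatment = rep(FALSE, m),
    study_visit = study_visit,
    stringsAsFactors = FALSE)

  ## diagnoses: PD code on the diagnosis-day encounter; PD code with
  ## probability pd_code_prob on post-diagnosis encounters; background codes
  ## on pre-diagnosis encounters; mimic codes inside the quiescence window for
  ## flagged patients.
  dx_idx <- which(is_dx_day)
  pd_icd9 <- runif(length(dx_idx)) < 0.2
  d_dx <- data.frame(
    patient_id = encounters$patient_id[dx_idx],
    encounter_id = encounters$encounter_id[dx_idx],
    date = encounters$date[dx_idx],
    code = ifelse(pd_icd9, "332.0", "G20"),
    vocabulary = ifelse(pd_icd9, "ICD9", "ICD10"),
    code_type = "primary", stringsAsFactors = FALSE)

  dx_by_pid <- stats::setNames(gt$dx_date, gt$patient_id)
  is_post <- !is_dx_day & encounters$date > dx_by_pid[encounters$patient_id]
  post_idx <- which(is_post & runif(m) < cfg$pd_code_prob)
  pd9 <- runif(length(post_idx)) < 0.2
  d_post <- data.frame(
    patient_id = encounters$patient_id[post_idx],
    encounter_id = encounters$encounter_id[post_idx],
    date = encounters$date[post_idx],
    code = ifelse(pd9, "332.0", "G20"),
    vocabulary = ifelse(pd9, "ICD9", "ICD10"),
    code_type = "primary", stringsAsFactors = FALSE)

  bg_pool <- c("I10", "E11.9", "M54.5", "J06.9", "K21.9")
  pre_idx <- which(!is_dx_day & !is_post)
  keep <- pre_idx[runif(length(pre_idx)) < 0.8]
  d_bg <- data.frame(
    patient_id = encounters$patient_id[keep],
    encounter_id = encounters$encounter_id[keep],
    date = encounters$date[keep],
    code = sample(bg_pool, length(keep), replace = TRUE),
    vocabulary = "ICD10",
    code_type = "secondary", stringsAsFactors = FALSE)

  mim <- which(gt$mimic)
  if (length(mim)) {
    mim_date <- gt$dx_date[mim] - sample(30:700, length(mim), replace = TRUE)
    eid <- sprintf("EM%07d", seq_along(mim))
    encounters <- rbind(encounters, data.frame(
      patient_id = gt$patient_id[mim], encounter_id = eid, date = mim_date,
      setting = "outpatient", has_treatment = FALSE, study_visit = FALSE,
      stringsAsFactors = FALSE))
    d_mim <- data.frame(
      patient_id = gt$patient_id[mim], encounter_id = eid, date = mim_date,
      code = sample(c("G30.9", "F03", "G23.1", "G21.9", "F20.9"),
                    length(mim), replace = TRUE),
      vocabulary = "ICD10", code_type = "secondary", stringsAsFactors = FALSE)
  } else {
    d_mim <- d_dx[0, ]
  }

  list(encounters = encounters,
       diagnoses = rbind(d_dx, d_post, d_bg, d_mim))
}

build_event_records <- function(cfg, gt) {
  n <- nrow(gt)
  empty_enc <- data.frame(patient_id = character(), encounter_id = character(),
                          date = as.Date(character()), setting = character(),
                          has_treatment = logical(), study_visit = logical(),
                          stringsAsFactors = FALSE)
  empty_dx <- data.frame(patient_id = character(), encounter_id = character(),
                         date = as.Date(character()), code = character(),
                         vocabulary = character(), code_type = character(),
                         stringsAsFactors = FALSE)
  enc_out <- list(); dx_out <- list(); fill_out <- list(); ref_out <- list()
  drugs <- drug_vocabulary()

  ## --- therapy initiation fill sequences ---
  seq_fits <- function(t0) t0 + 111 / DAYS_PER_YEAR <= gt$followup_years
  mk_sequence <- function(idx, t0, class_of, tag) {
    if (!length(idx)) return(NULL)
    start_date <- add_years(gt$dx_date[idx], t0[idx])
    eid <- sprintf("ET%s%06d", tag, seq_along(idx))
    enc <- data.frame(patient_id = gt$patient_id[idx], encounter_id = eid,
                      date = start_date, setting = "outpatient",
                      has_treatment = TRUE, study_visit = FALSE,
                      stringsAsFactors = FALSE)
    dx <- data.frame(patient_id = gt$patient_id[idx], encounter_id = eid,
                     date = start_date, code = "G20", vocabulary = "ICD10",
                     code_type = "primary", stringsAsFactors = FALSE)
    fits <- seq_fits(t0)[idx]
    core_off <- c(0L, 40L, 110L); core_sup <- c(30L, 30L, 40L)
    fl <- do.call(rbind, lapply(seq_along(idx), function(k) {
      i <- idx[k]
      code <- sample(drugs[[class_of[i]]], 1L)
      if (fits[k]) {
        horizon <- as.numeric(gt$censor_date[i] - start_date[k])
        maint <- seq.int(200L, by = 90L,
                         length.out = max(0L, (floor(horizon) - 200L) %/% 90L + 1L))
        off <- c(core_off, maint)
        sup <- c(core_sup, rep(90L, length(maint)))
      } else {
        off <- 0L; sup <- 30L
      }
      data.frame(patient_id = gt$patient_id[i],
                 date = start_date[k] + off,
                 drug_code = code, drug_class = class_of[i],
                 days_supply = sup,
                 linked_encounter_id = c(eid[k], rep(NA, length(off) - 1L)),
                 stringsAsFactors = FALSE)
    }))
    list(enc = enc, dx = dx, fills = fl)
  }

  first_class <- ifelse(gt$first_line_levodopa, "levodopa", "other_pd")
  ther_idx <- which(gt$t_therapy < gt$followup_years)
  s1 <- mk_sequence(ther_idx, gt$t_therapy, first_class, "A")
  lev_idx <- which(!gt$first_line_levodopa &
                     gt$t_levodopa < gt$followup_years)
  s2 <- mk_sequence(lev_idx, gt$t_levodopa,
                    rep("levodopa", n), "B")
  for (s in list(s1, s2)) if (!is.null(s)) {
    enc_out <- c(enc_out, list(s$enc)); dx_out <- c(dx_out, list(s$dx))
    fill_out <- c(fill_out, list(s$fills))
  }

  ## --- cognitive decline proxy: MCI code + cognitive-class fill at a
  ## PD-coded encounter at the true event time ---
  cog_idx <- which(gt$t_cog < gt$followup_years)
  if (length(cog_idx)) {
    cdate <- add_years(gt$dx_date[cog_idx], gt$t_cog[cog_idx])
    eid <- sprintf("EC%07d", seq_along(cog_idx))
    enc_out <- c(enc_out, list(data.frame(
      patient_id = gt$patient_id[cog_idx], encounter_id = eid, date = cdate,
      setting = "outpatient", has_treatment = TRUE, study_visit = FALSE,
      stringsAsFactors = FALSE)))
    dx_out <- c(dx_out, list(
      data.frame(patient_id = rep(gt$patient_id[cog_idx], 2L),
                 encounter_id = rep(eid, 2L), date = rep(cdate, 2L),
                 code = rep(c("G20", "G31.84"), each = length(cog_idx)),
                 vocabulary = "ICD10",
                 code_type = rep(c("primary", "secondary"),
                                 each = length(cog_idx)),
                 stringsAsFactors = FALSE)))
    fill_out <- c(fill_out, list(data.frame(
      patient_id = gt$patient_id[cog_idx], date = cdate,
      drug_code = sample(drugs$cognitive, length(cog_idx), replace = TRUE),
      drug_class = "cognitive", days_supply = 30L,
      linked_encounter_id = eid, stringsAsFactors = FALSE)))
    ## a minority also get a cognitive referral
    refd <- runif(length(cog_idx)) < 0.3
    if (any(refd)) ref_out <- c(ref_out, list(data.frame(
      patient_id = gt$patient_id[cog_idx][refd], date = cdate[refd],
      code = COG_REFERRAL_CODE, stringsAsFactors = FALSE)))
  }

  ## --- adverse events: inpatient encounter with the event code primary ---
  mk_adverse <- function(t_ev, hist, codes10, tag) {
    idx <- which(t_ev < gt$followup_years)
    out <- list()
    if (length(idx)) {
      adate <- add_years(gt$dx_date[idx], t_ev[idx])
      eid <- sprintf("EA%s%06d", tag, seq_along(idx))
      out$enc <- data.frame(
        patient_id = gt$patient_id[idx], encounter_id = eid, date = adate,
        setting = "inpatient", has_treatment = TRUE, study_visit = FALSE,
        stringsAsFactors = FALSE)
      out$dx <- data.frame(
        patient_id = gt$patient_id[idx], encounter_id = eid, date = adate,
        code = sample(codes10, length(idx), replace = TRUE),
        vocabulary = "ICD10", code_type = "primary", stringsAsFactors = FALSE)
    }
    hidx <- which(hist)
    if (length(hidx)) {
      hdate <- gt$dx_date[hidx] - sample(30:700, length(hidx), replace = TRUE)
      eidh <- sprintf("EH%s%06d", tag, seq_along(hidx))
      out$enc <- rbind(out$enc, data.frame(
        patient_id = gt$patient_id[hidx], encounter_id = eidh, date = hdate,
        setting = "outpatient", has_treatment = FALSE, study_visit = FALSE,
        stringsAsFactors = FALSE))
      out$dx <- rbind(out$dx, data.frame(
        patient_id = gt$patient_id[hidx], encounter_id = eidh, date = hdate,
        code = sample(codes10, length(hidx), replace = TRUE),
        vocabulary = "ICD10", code_type = "secondary",
        stringsAsFactors = FALSE))
    }
    out
  }
  av <- adverse_event_code_sets()
  a1 <- mk_adverse(gt$t_falls, gt$falls_history,
                   c("W19", "S72.00", "S32.000"), "F")
  a2 <- mk_adverse(gt$t_depression, gt$depression_history,
                   c("F32.9", "F33.9"), "D")
  for (a in list(a1, a2)) {
    if (!is.null(a$enc)) enc_out <- c(enc_out, list(a$enc))
    if (!is.null(a$dx)) dx_out <- c(dx_out, list(a$dx))
  }

  fills <- if (length(fill_out)) do.call(rbind, fill_out) else
    data.frame(patient_id = character(), date = as.Date(character()),
               drug_code = character(), drug_class = character(),
               days_supply = integer(), linked_encounter_id = character(),
               stringsAsFactors = FALSE)
  fills <- fills[order(fills$patient_id, fills$date), , drop = FALSE]
  rownames(fills) <- NULL
  referrals <- if (length(ref_out)) do.call(rbind, ref_out) else
    data.frame(patient_id = character(), date = as.Date(character()),
               code = character(), stringsAsFactors = FALSE)

  list(encounters = if (length(enc_out)) do.call(rbind, enc_out) else empty_enc,
       diagnoses = if (length(dx_out)) do.call(rbind, dx_out) else empty_dx,
       fills = fills, referrals = referrals)
}

build_coverage <- function(cfg, gt) {
  empty <- data.frame(patient_id = character(), start = as.Date(character()),
                      end = as.Date(character()), stringsAsFactors = FALSE)
  if (cfg$quiescence_mode != "coverage") return(empty)
  n <- nrow(gt)
  gap <- runif(n) < cfg$coverage_gap_prob
  span <- as.numeric(gt$censor_date - gt$history_start)
  gap_start <- gt$history_start + floor(runif(n) * pmax(span - 130, 1))
  gap_len <- sample(30:120, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    if (!gap[i] || span[i] < 200) {
      data.frame(patient_id = gt$patient_id[i], start = gt$history_start[i],
                 end = gt$censor_date[i], stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = rep(gt$patient_id[i], 2L),
                 start = c(gt$history_start[i], gap_start[i] + gap_len[i]),
                 end = c(gap_start[i], gt$censor_date[i]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

build_score_observations <- function(cfg, gt, encounters) {
  empty_scores <- data.frame(patient_id = character(),
                             date = as.Date(character()), scale = character(),
                             value = numeric(), stringsAsFactors = FALSE)
  empty_notes <- data.frame(note_id = character(), patient_id = character(),
                            date = as.Date(character()), text = character(),
                            stringsAsFactors = FALSE)
  empty_truth <- data.frame(note_id = character(), scale = character(),
                            value = numeric(), stringsAsFactors = FALSE)

  rec_ids <- gt$patient_id[gt$recorder]
  if (!length(rec_ids))
    return(list(scores = empty_scores, notes = empty_notes,
                note_truth = empty_truth))

  dx_by_pid <- stats::setNames(gt$dx_date, gt$patient_id)
  if (isTRUE(cfg$study_visits)) {
    obs_enc <- encounters[encounters$study_visit &
                            encounters$patient_id %in% rec_ids, ]
  } else {
    obs_enc <- encounters[encounters$patient_id %in% rec_ids &
                            encounters$date >= dx_by_pid[encounters$patient_id] &
                            encounters$setting == "outpatient" &
                            !startsWith(encounters$encounter_id, "EH"), ]
  }
  if (!nrow(obs_enc))
    return(list(scores = empty_scores, notes = empty_notes,
                note_truth = empty_truth))

  i <- match(obs_enc$patient_id, gt$patient_id)
  t_obs <- years_between(gt$dx_date[i], obs_enc$date)
  noise <- cfg$score_noise_sd
  m <- nrow(obs_enc)
  updrs <- clamp(gt$updrs_intercept_i[i] + gt$updrs_slope[i] * t_obs +
                   rnorm(m, 0, noise[["updrs_total"]]), 0, 199)
  mmse <- clamp(gt$mmse_intercept_i[i] + gt$mmse_slope[i] * t_obs +
                  rnorm(m, 0, noise[["mmse"]]), 0, 30)
  hy <- quantize_hy(gt$hy_intercept[i] + gt$hy_slope_i[i] * t_obs +
                      if (noise[["hy"]] > 0) rnorm(m, 0, noise[["hy"]]) else 0)

  if (isTRUE(cfg$structured_scores)) {
    scores <- data.frame(
      patient_id = rep(obs_enc$patient_id, 3L),
      date = rep(obs_enc$date, 3L),
      scale = rep(c("updrs_total", "mmse", "hy"), each = m),
      value = c(updrs, mmse, hy), stringsAsFactors = FALSE)
    return(list(scores = scores, notes = empty_notes,
                note_truth = empty_truth))
  }

  ## notes archetype: rendered values are rounded to 2 decimals; the note
  ## ground truth records exactly what was rendered.
  updrs_r <- round(updrs, 2); mmse_r <- round(mmse, 2)
  note_id <- sprintf("N%08d", seq_len(m))
  dseed <- sample.int(.Machine$integer.max, m)
  text <- vapply(seq_len(m), function(k)
    render_note(list(hy = hy[k], updrs_total = updrs_r[k], mmse = mmse_r[k]),
                dseed[k]), character(1))
  notes <- data.frame(note_id = note_id, patient_id = obs_enc$patient_id,
                      date = obs_enc$date, text = text,
                      stringsAsFactors = FALSE)
  note_truth <- data.frame(
    note_id = rep(note_id, 3L),
    scale = rep(c("hy", "updrs_total", "mmse"), each = m),
    value = c(hy, updrs_r, mmse_r), stringsAsFactors = FALSE)

  ## distractor-only notes from non-recorder encounters (negative examples
  ## for the extraction audit strata)
  nonrec <- encounters[!(encounters$patient_id %in% rec_ids) &
                         encounters$date >= dx_by_pid[encounters$patient_id], ]
  if (nrow(nonrec)) {
    keep <- which(runif(nrow(nonrec)) < 0.1)
    if (length(keep)) {
      nid <- sprintf("N9%07d", seq_along(keep))
      ds2 <- sample.int(.Machine$integer.max, length(keep))
      txt2 <- vapply(seq_along(keep), function(k)
        render_note(list(), ds2[k]), character(1))
      notes <- rbind(notes, data.frame(
        note_id = nid, patient_id = nonrec$patient_id[keep],
        date = nonrec$date[keep], text = txt2, stringsAsFactors = FALSE))
      note_truth <- rbind(note_truth, data.frame(
        note_id = rep(nid, 3L),
        scale = rep(c("hy", "updrs_total", "mmse"), each = length(keep)),
        value = NA_real_, stringsAsFactors = FALSE))
    }
  }
  list(scores = empty_scores, notes = notes, note_truth = note_truth)
}

#' Evaluate a patient's true score trajectory
#'
#' Linear trajectory `intercept + slope * t` from a ground-truth entry,
#' clamped to the scale's valid range; H&Y is floor-quantized to half stages.
#'
#' @param patient One row of the generator's `ground_truth` table (or any list
#'   with the trajectory fields `updrs_intercept_i`/`updrs_slope`,
#'   `mmse_intercept_i`/`mmse_slope`, `hy_intercept`/`hy_slope_i`).
#' @param scale `"updrs_total"`, `"mmse"` or `"hy"`.
#' @param t Years since diagnosis (>= 0), vectorized.
#' @return Numeric score value(s).
#' @export
trajectory_value <- function(patient, scale, t) {
  assert_scale(scale)
  stopifnot(all(t >= 0))
  r <- scale_ranges()[[scale]]
  if (scale == "updrs_total") {
    clamp(patient$updrs_intercept_i + patient$updrs_slope * t, r[1], r[2])
  } else if (scale == "mmse") {
    clamp(patient$mmse_intercept_i + patient$mmse_slope * t, r[1], r[2])
  } else {
    quantize_hy(patient$hy_intercept + patient$hy_slope_i * t)
  }
}

#' Render a synthetic clinical note
#'
#' Emits one template sentence per present score — "Hoehn and Yahr stage: X.",
#' "UPDRS total: X.", "MMSE: X/30." — interleaved with distractor sentences
#' containing other numbers. A score given as a length-2 vector produces an
#' ambiguous note carrying both conflicting values (used to exercise the
#' consensus flagging protocol). Deterministic given its arguments: the
#' distractor selection is a pure function of `distractor_seed` and does not
#' touch the global RNG stream.
#'
#' @param scores Named list; names among `hy`, `updrs_total`, `mmse`. Missing
#'   names render a note without that scale's template.
#' @param distractor_seed Integer choosing the distractor sentences.
#' @return A single string.
#' @export
render_note <- function(scores = list(), distractor_seed = 0L) {
  ranges <- scale_ranges()
  tmpl <- list(
    hy = function(v) sprintf("Hoehn and Yahr stage: %s.", format_score(v)),
    updrs_total = function(v) sprintf("UPDRS total: %s.", format_score(v)),
    mmse = function(v) sprintf("MMSE: %s/30.", format_score(v)))
  bad <- setdiff(names(scores), names(tmpl))
  if (length(bad)) stop("unknown scale in scores: ", bad[1], call. = FALSE)
  for (s in names(scores)) {
    v <- scores[[s]]
    if (any(v < ranges[[s]][1] | v > ranges[[s]][2]))
      stop("score out of range for scale ", s, call. = FALSE)
  }
  pool <- c(
    "Patient is a %d year old presenting for routine follow up.",
    "Blood pressure 128/76, heart rate 72.",
    "Seen in clinic for a 30 minute visit.",
    "Gait assessed over 10 meters in the hallway.",
    "Reports 2 episodes of dizziness in the last month.",
    "Medication list reviewed, 4 active prescriptions.",
    "Sleep averages 6 hours per night.")
  seed <- abs(as.integer(distractor_seed)) %% 10000L
  k <- 2L + seed %% 3L
  idx <- ((seed + seq_len(k) * 3L) %% length(pool)) + 1L
  age <- 55L + seed %% 35L
  distract <- vapply(pool[idx], function(s)
    if (grepl("%d", s, fixed = TRUE)) sprintf(s, age) else s, character(1),
    USE.NAMES = FALSE)
  body <- unlist(lapply(names(scores), function(s)
    vapply(scores[[s]], tmpl[[s]], character(1))))
  ## interleave deterministically: distractor, scores..., distractors
  paste(c(distract[1], body, distract[-1]), collapse = " ")
}

format_score <- function(v) {
  out <- trimws(formatC(v, format = "fg", digits = 8))
  ifelse(grepl("\\.", out), sub("\\.?0+$", "", out), out)
}
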