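#' Therapy-initiation episode rule configuration
#'
#' The default criteria for calling a sequence of prescription fills a true
#' therapy initiation: the first fill is linked to an encounter carrying a PD
#' diagnosis; more than `min_total_days` (90) total days of pills are supplied
#' within `span_max_days` (180) of the first fill; and at least one further
#' fill falls more than `span_min_days` (90) but at most `span_max_days` days
#' after the first. A single 90-day fill therefore never qualifies.
#'
#' @param min_total_days Total days-supply that must be exceeded (strict).
#' @param span_min_days Lower bound (exclusive) on the later fill's offset.
#' @param span_max_days Upper bound (inclusive) on the window.
#' @param require_pd_linked_first_fill Require PD linkage of the first fill.
#' @return A list of class `therapy_rule`.
#' @export
therapy_rule <- function(min_total_days = 90, span_min_days = 90,
                         span_max_days = 180,
                         require_pd_linked_first_fill = TRUE) {
  structure(list(min_total_days = min_total_days,
                 span_min_days = span_min_days, span_max_days = span_max_days,
                 require_pd_linked_first_fill = require_pd_linked_first_fill),
            class = "therapy_rule")
}

#' Detect therapy initiation from prescription fills
#'
#' Scans candidate first fills in date order and returns the earliest fill
#' date whose sequence meets all criteria of [therapy_rule()]. Linkage to a PD
#' diagnosis is satisfied when the fill's `linked_encounter_id` is a PD-coded
#' encounter, or (when no link is recorded) a PD-coded encounter occurs the
#' same day.
#'
#' @param fills Data frame with `date`, `drug_class`, `days_supply`,
#'   `linked_encounter_id`, sorted by date.
#' @param pd_encounters Data frame of PD-coded encounters with
#'   `encounter_id`, `date` (e.g. diagnoses rows restricted to PD codes).
#' @param drug_classes Character vector of qualifying drug classes, e.g.
#'   `c("levodopa", "other_pd")` for any PD therapeutic or `"levodopa"` alone.
#' @param rule A [therapy_rule()].
#' @return The initiation `Date`, or `NA` when no sequence qualifies.
#' @export
detect_therapy_initiation <- function(fills, pd_encounters,
                                      drug_classes = c("levodopa", "other_pd"),
                                      rule = therapy_rule()) {
  f <- fills[fills$drug_class %in% drug_classes, , drop = FALSE]
  if (!nrow(f)) return(as.Date(NA))
  if (is.unsorted(f$date)) stop("fills must be date-sorted", call. = FALSE)
  pd_ids <- unique(pd_encounters$encounter_id)
  pd_dates <- unique(pd_encounters$date)
  for (i in seq_len(nrow(f))) {
    d0 <- f$date[i]
    if (rule$require_pd_linked_first_fill) {
      link <- f$linked_encounter_id[i]
      linked <- (!is.na(link) && link %in% pd_ids) || (d0 %in% pd_dates)
      if (!linked) next
    }
    off <- as.numeric(f$date - d0)
    in_win <- off >= 0 & off <= rule$span_max_days
    if (sum(f$days_supply[in_win]) <= rule$min_total_days) next
    if (sum(in_win) < 2) next
    if (!any(off > rule$span_min_days & off <= rule$span_max_days)) next
    return(d0)
  }
  as.Date(NA)
}

#' Detect cognitive decline from real-world utilization (proxy definition)
#'
#' Qualifies at the earlier of (i) the later of the first mild-cognitive-
#' impairment diagnosis date and the first cognitive-medication fill at a
#' PD-coded encounter (both must exist), or (ii) the first referral to
#' neurology for cognitive decline. `grouping = "any"` gives the alternate
#' reading where any one of the three signals alone qualifies at its first
#' date.
#'
#' @param patient List with `diagnoses`, `fills`, `referrals`, `encounters`
#'   data frames.
#' @param mci_codes [code_set()] for mild cognitive impairment.
#' @param pd_codes [code_set()] for PD.
#' @param cognitive_class Drug class label for cognition medications.
#' @param referral_code Referral code for cognitive-decline neurology
#'   referrals.
#' @param grouping `"and_or"` (default) or `"any"`.
#' @return Event `Date` or `NA`.
#' @export
detect_cognitive_decline_rwd <- function(patient,
                                         mci_codes = mci_code_set(),
                                         pd_codes = pd_code_set(),
                                         cognitive_class = "cognitive",
                                         referral_code = COG_REFERRAL_CODE,
                                         grouping = c("and_or", "any")) {
  grouping <- match.arg(grouping)
  d <- patient$diagnoses
  mci_dates <- if (!is.null(d) && nrow(d))
    d$date[matches_code_set(d$code, d$vocabulary, mci_codes)] else
      as.Date(character())
  pd_enc <- if (!is.null(d) && nrow(d))
    unique(d$encounter_id[matches_code_set(d$code, d$vocabulary, pd_codes)])
  else character()
  f <- patient$fills
  cog_fill_dates <- if (!is.null(f) && nrow(f))
    f$date[f$drug_class == cognitive_class &
             !is.na(f$linked_encounter_id) &
             f$linked_encounter_id %in% pd_enc] else as.Date(character())
  r <- patient$referrals
  ref_dates <- if (!is.null(r) && nrow(r))
    r$date[r$code == referral_code] else as.Date(character())

  if (grouping == "any") {
    all_d <- c(mci_dates, cog_fill_dates, ref_dates)
    return(if (length(all_d)) min(all_d) else as.Date(NA))
  }
  pair <- if (length(mci_dates) && length(cog_fill_dates))
    max(min(mci_dates), min(cog_fill_dates)) else as.Date(NA)
  ref <- if (length(ref_dates)) min(ref_dates) else as.Date(NA)
  cand <- c(pair, ref)
  if (all(is.na(cand))) as.Date(NA) else min(cand, na.rm = TRUE)
}

#' Detect cognitive decline from MMSE scores
#'
#' First date at which the MMSE falls to the cutoff or below (default <= 25,
#' the global cognitive impairment indicator).
#'
#' @param scores Data frame with `date`, `value` (MMSE).
#' @param cutoff Threshold, inclusive (default 25).
#' @return Event `Date` or `NA`.
#' @export
detect_cognitive_decline_mmse <- function(scores, cutoff = 25) {
  if (is.null(scores) || !nrow(scores)) return(as.Date(NA))
  hit <- scores$value <= cutoff
  if (!any(hit)) return(as.Date(NA))
  min(scores$date[hit])
}

#' Detect a score-threshold crossing event
#'
#' First date at which a recorded score reaches the threshold or more;
#' default threshold 3 for Hoehn & Yahr stage 3 ("3 or more").
#'
#' @param scores Data frame with `date`, `value`.
#' @param threshold Inclusive threshold (default 3).
#' @return Event `Date` or `NA`.
#' @export
detect_score_threshold_event <- function(scores, threshold = 3) {
  if (is.null(scores) || !nrow(scores)) return(as.Date(NA))
  hit <- scores$value >= threshold
  if (!any(hit)) return(as.Date(NA))
  min(scores$date[hit])
}

#' Detect an adverse clinical event with utilization criteria
#'
#' A qualifying event carries the event code as the primary or admitting code
#' of an encounter with an inpatient stay or a recorded treatment, at or
#' after the initial diagnosis. Patients with any event code during the
#' pre-diagnosis quiescence window are ineligible for the analysis of that
#' event.
#'
#' @param patient List with `diagnoses` (columns `date`, `code`,
#'   `vocabulary`, `code_type`, `encounter_id`) and `encounters` (columns
#'   `encounter_id`, `setting`, `has_treatment`).
#' @param event_codes [code_set()] for the event.
#' @param initial_dx Initial diagnosis date.
#' @param window Quiescence window in days (default 730).
#' @return List with `date` (`NA` when none) and `eligible` (logical).
#' @export
detect_adverse_event <- function(patient, event_codes, initial_dx,
                                 window = 730) {
  d <- patient$diagnoses
  if (is.null(d) || !nrow(d))
    return(list(date = as.Date(NA), eligible = TRUE))
  hit <- matches_code_set(d$code, d$vocabulary, event_codes)
  in_quiescence <- hit & d$date >= initial_dx - window & d$date < initial_dx
  if (any(in_quiescence))
    return(list(date = as.Date(NA), eligible = FALSE))
  enc <- patient$encounters
  qual_enc <- enc$encounter_id[enc$setting == "inpatient" |
                                 isTRUE_vec(enc$has_treatment)]
  qual <- hit & d$date >= initial_dx &
    d$code_type %in% c("primary", "admitting") &
    d$encounter_id %in% qual_enc
  if (!any(qual)) return(list(date = as.Date(NA), eligible = TRUE))
  list(date = min(d$date[qual]), eligible = TRUE)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Phi coefficient of two binary vectors
#'
#' Pearson correlation of two binary variables computed from their 2x2 table:
#' `(n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`.
#'
#' @param a,b Logical or 0/1 vectors of equal length >= 2; both must vary.
#' @return Value in `[-1, 1]`.
#' @export
phi_coefficient <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  if (length(a) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("phi coefficient undefined for a constant vector", call. = FALSE)
  n11 <- sum(a == 1 & b == 1); n00 <- sum(a == 0 & b == 0)
  n10 <- sum(a == 1 & b == 0); n01 <- sum(a == 0 & b == 1)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

#' Build per-patient time-to-event records for a dataset
#'
#' Runs the event detectors over an `ehr_dataset` restricted to an included
#' cohort, converting event dates to years since the (recorded) initial
#' diagnosis with censoring at the last encounter (EMR/research archetypes)
#' or coverage end (claims archetype). For year-resolution diagnosis dates
#' the time origin is mid-year (recorded date + 182 days), which is
#' mean-unbiased when diagnoses are uniform within the year.
#'
#' @param dataset An `ehr_dataset`.
#' @param cohort A `cohort_table` from [build_cohort()] (only included
#'   patients are analyzed).
#' @param events Character vector among `pd_therapy`, `levodopa`, `hy3`,
#'   `cognitive_decline`, `falls_fractures`, `depression`.
#' @param scores Optional data frame of recorded scores (`patient_id`,
#'   `date`, `scale`, `value`) for score-based events; defaults to the
#'   dataset's structured scores.
#' @return Data frame: `patient_id`, `event_type`, `time_years`, `observed`,
#'   `eligible`.
#' @export
detect_events <- function(dataset, cohort,
                          events = c("pd_therapy", "levodopa", "hy3",
                                     "cognitive_decline", "falls_fractures",
                                     "depression"),
                          scores = NULL) {
  tab <- cohort$cohort
  tab <- tab[tab$included, , drop = FALSE]
  if (!nrow(tab)) return(empty_event_records())
  scores <- scores %||% dataset$scores
  year_res <- !is.null(dataset$config) &&
    identical(dataset$config$dx_resolution, "year")
  origin <- tab$initial_dx_date + if (year_res) 182L else 0L

  enc_split <- split(dataset$encounters, dataset$encounters$patient_id)
  diag_split <- split(dataset$diagnoses, dataset$diagnoses$patient_id)
  fill_split <- split(dataset$fills, dataset$fills$patient_id)
  ref_split <- split(dataset$referrals, dataset$referrals$patient_id)
  cov_split <- if (nrow(dataset$coverage))
    split(dataset$coverage, dataset$coverage$patient_id) else list()
  score_split <- if (!is.null(scores) && nrow(scores))
    split(scores, scores$patient_id) else list()
  pdc <- pd_code_set()
  adv <- adverse_event_code_sets()

  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$patient_id[i]
    enc <- enc_split[[p]]
    d <- diag_split[[p]]; if (is.null(d)) d <- dataset$diagnoses[0, ]
    f <- fill_split[[p]]; if (is.null(f)) f <- dataset$fills[0, ]
    r <- ref_split[[p]]; if (is.null(r)) r <- dataset$referrals[0, ]
    cv <- cov_split[[p]]
    sc <- score_split[[p]]
    pat <- list(encounters = enc, diagnoses = d, fills = f, referrals = r)
    censor_date <- if (!is.null(cv) && nrow(cv)) max(cv$end) else
      max(enc$date)
    censor_t <- max(years_between(origin[i], censor_date), 0)
    pd_enc_rows <- d[matches_code_set(d$code, d$vocabulary, pdc), ,
                     drop = FALSE]

    rec <- list()
    one <- function(type, date, eligible = TRUE) {
      if (!eligible)
        data.frame(patient_id = p, event_type = type, time_years = NA_real_,
                   observed = NA, eligible = FALSE, stringsAsFactors = FALSE)
      else if (is.na(date))
        data.frame(patient_id = p, event_type = type, time_years = censor_t,
                   observed = FALSE, eligible = TRUE, stringsAsFactors = FALSE)
      else
        data.frame(patient_id = p, event_type = type,
                   time_years = max(years_between(origin[i], date), 0),
                   observed = TRUE, eligible = TRUE, stringsAsFactors = FALSE)
    }
    if ("pd_therapy" %in% events)
      rec$pd_therapy <- one("pd_therapy",
                            detect_therapy_initiation(f, pd_enc_rows))
    if ("levodopa" %in% events)
      rec$levodopa <- one("levodopa",
                          detect_therapy_initiation(f, pd_enc_rows,
                                                    drug_classes = "levodopa"))
    if ("hy3" %in% events) {
      hy <- if (!is.null(sc)) sc[sc$scale == "hy", , drop = FALSE] else NULL
      rec$hy3 <- one("hy3", detect_score_threshold_event(hy))
    }
    if ("cognitive_decline" %in% events)
      rec$cognitive_decline <- one("cognitive_decline",
                                   detect_cognitive_decline_rwd(pat))
    if ("falls_fractures" %in% events) {
      a <- detect_adverse_event(pat, adv$falls_fractures,
                                tab$initial_dx_date[i])
      rec$falls_fractures <- one("falls_fractures", a$date, a$eligible)
    }
    if ("depression" %in% events) {
      a <- detect_adverse_event(pat, adv$depression, tab$initial_dx_date[i])
      rec$depression <- one("depression", a$date, a$eligible)
    }
    out[[i]] <- do.call(rbind, rec)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_event_records <- function() {
  data.frame(patient_id = character(), event_type = character(),
             time_years = numeric(), observed = logical(),
             eligible = logical(), stringsAsFactors = FALSE)
}
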