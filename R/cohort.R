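#' Find the initial Parkinson's disease diagnosis date
#'
#' The earliest encounter date carrying any PD code (first observed PD
#' diagnosis), honoring both ICD-9 and ICD-10 vocabularies.
#'
#' @param diagnoses Data frame with columns `date`, `code`, `vocabulary`,
#'   sorted by date.
#' @param pd_codes A [code_set()]; defaults to [pd_code_set()].
#' @return A `Date`, or `NA` if no PD code is present.
#' @export
find_initial_diagnosis <- function(diagnoses, pd_codes = pd_code_set()) {
  if (!nrow(diagnoses)) return(as.Date(NA))
  if (is.unsorted(diagnoses$date)) stop("diagnoses must be date-sorted",
                                        call. = FALSE)
  hit <- matches_code_set(diagnoses$code, diagnoses$vocabulary, pd_codes)
  if (!any(hit)) return(as.Date(NA))
  min(diagnoses$date[hit])
}

#' Pre-diagnosis quiescence filter
#'
#' Enriches for incident (de novo) diagnoses by requiring prior presence in
#' the data for a window (default 730 days) before the initial diagnosis:
#' in `encounter` mode, some encounter at least `window` days before the
#' diagnosis; in `coverage` mode, continuous coverage (merged intervals,
#' allowing gaps up to `gap_tolerance` days) over the whole
#' `[initial_dx - window, initial_dx]` interval. Both boundaries are
#' inclusive ("at least" readings).
#'
#' @param patient List with `encounters` (data frame with `date`) and/or
#'   `coverage` (data frame with `start`, `end`).
#' @param initial_dx Initial diagnosis `Date`.
#' @param mode `"encounter"` or `"coverage"`.
#' @param window Window length in days (default 730).
#' @param gap_tolerance Maximum coverage gap, in days, still treated as
#'   continuous (default 0).
#' @return Logical.
#' @export
passes_quiescence <- function(patient, initial_dx,
                              mode = c("encounter", "coverage"),
                              window = 730, gap_tolerance = 0) {
  mode <- match.arg(mode)
  if (is.na(initial_dx)) return(FALSE)
  if (mode == "encounter") {
    enc <- patient$encounters
    if (is.null(enc) || !nrow(enc)) return(FALSE)
    any(enc$date <= initial_dx - window)
  } else {
    cov <- patient$coverage
    if (is.null(cov) || !nrow(cov)) return(FALSE)
    iv <- merge_intervals(cov$start, cov$end, gap_tolerance)
    any(iv$start <= initial_dx - window & iv$end >= initial_dx)
  }
}

## Merge sorted-or-not [start, end] intervals, fusing gaps <= tol days.
merge_intervals <- function(start, end, tol = 0) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (as.numeric(start[i] - me) <= tol) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = as.Date(c(out_s, ms), origin = "1970-01-01"),
       end = as.Date(c(out_e, me), origin = "1970-01-01"))
}

#' Confirmatory diagnosis filter
#'
#' A second PD diagnosis at least `min_gap` days (inclusive) after the initial
#' one, filtering out referral/rule-out codes.
#'
#' @inheritParams find_initial_diagnosis
#' @param initial_dx Initial diagnosis date.
#' @param min_gap Minimum gap in days (default 30).
#' @return Logical.
#' @export
has_confirmatory_diagnosis <- function(diagnoses, pd_codes = pd_code_set(),
                                       initial_dx, min_gap = 30) {
  if (!nrow(diagnoses) || is.na(initial_dx)) return(FALSE)
  hit <- matches_code_set(diagnoses$code, diagnoses$vocabulary, pd_codes)
  any(hit & diagnoses$date >= initial_dx + min_gap)
}

#' Parkinsonism-mimic exclusions
#'
#' Checks the patient's diagnoses in the quiescence window
#' `[initial_dx - window, initial_dx]` (inclusive) against each exclusion code
#' set in order, returning the first matching set's name.
#'
#' @param diagnoses Data frame with `date`, `code`, `vocabulary`.
#' @param exclusion_sets List of [code_set()]s, evaluated in order; defaults
#'   to [mimic_exclusion_sets()].
#' @param initial_dx Initial diagnosis date.
#' @param window Window length in days (default 730).
#' @return The matching set's name, or `NA` if none match.
#' @export
apply_exclusions <- function(diagnoses, exclusion_sets = mimic_exclusion_sets(),
                             initial_dx, window = 730) {
  if (!nrow(diagnoses) || is.na(initial_dx)) return(NA_character_)
  in_win <- diagnoses$date >= initial_dx - window & diagnoses$date <= initial_dx
  if (!any(in_win)) return(NA_character_)
  d <- diagnoses[in_win, , drop = FALSE]
  for (set in exclusion_sets) {
    if (any(matches_code_set(d$code, d$vocabulary, set))) return(set$name)
  }
  NA_character_
}

#' Build an incident PD cohort with attrition accounting
#'
#' Applies, in order: initial diagnosis identification, the quiescence rule,
#' the confirmatory-diagnosis rule, and mimic-condition exclusions. Research
#' archetypes (quiescence mode `"none"`) bypass quiescence and exclusions —
#' actively recruited participants are screened at enrollment — and use the
#' recorded diagnosis date directly.
#'
#' @param dataset An `ehr_dataset` from [generate_dataset()] (or a list with
#'   the same tables).
#' @param quiescence_mode `"encounter"`, `"coverage"` or `"none"`; defaults to
#'   the dataset's archetype configuration.
#' @param window Quiescence window in days.
#' @param confirm_gap Confirmatory-diagnosis gap in days.
#' @param gap_tolerance Coverage gap tolerance in days.
#' @param pd_codes,exclusion_sets Code sets to use.
#' @return A list of class `cohort_table` with elements `cohort` (data frame:
#'   `patient_id`, `initial_dx_date`, `quiescence_pass`, `confirmation_pass`,
#'   `excluded_reason`, `included`) and `attrition` (named counts removed at
#'   each stage; stage counts plus the included count sum to the input count).
#' @export
build_cohort <- function(dataset, quiescence_mode = NULL, window = 730,
                         confirm_gap = 30, gap_tolerance = 0,
                         pd_codes = pd_code_set(),
                         exclusion_sets = mimic_exclusion_sets()) {
  if (!nrow(dataset$patients)) stop("empty dataset", call. = FALSE)
  mode <- quiescence_mode %||% (dataset$config$quiescence_mode %||% "encounter")
  pids <- dataset$patients$patient_id
  n <- length(pids)

  diag_split <- split(dataset$diagnoses, dataset$diagnoses$patient_id)
  enc_split <- split(dataset$encounters, dataset$encounters$patient_id)
  cov_split <- if (nrow(dataset$coverage))
    split(dataset$coverage, dataset$coverage$patient_id) else list()
  rec_dx <- if (!is.null(dataset$ground_truth))
    stats::setNames(dataset$ground_truth$recorded_dx_date,
                    dataset$ground_truth$patient_id) else NULL

  initial <- rep(as.Date(NA), n)
  q_pass <- c_pass <- logical(n)
  excl <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    p <- pids[i]
    d <- diag_split[[p]]
    if (is.null(d)) d <- dataset$diagnoses[0, ]
    d <- d[order(d$date), , drop = FALSE]
    if (mode == "none") {
      ## explicit diagnosis date from enrollment records
      initial[i] <- if (!is.null(rec_dx)) rec_dx[[p]] else
        find_initial_diagnosis(d, pd_codes)
      q_pass[i] <- !is.na(initial[i])
      c_pass[i] <- q_pass[i]
      next
    }
    initial[i] <- find_initial_diagnosis(d, pd_codes)
    if (is.na(initial[i])) next
    pat <- list(encounters = enc_split[[p]], coverage = cov_split[[p]])
    q_pass[i] <- passes_quiescence(pat, initial[i], mode, window,
                                   gap_tolerance)
    if (!q_pass[i]) next
    c_pass[i] <- has_confirmatory_diagnosis(d, pd_codes, initial[i],
                                            confirm_gap)
    if (!c_pass[i]) next
    excl[i] <- apply_exclusions(d, exclusion_sets, initial[i], window)
  }

  included <- !is.na(initial) & q_pass & c_pass & is.na(excl)
  cohort <- data.frame(patient_id = pids, initial_dx_date = initial,
                       quiescence_pass = q_pass, confirmation_pass = c_pass,
                       excluded_reason = excl, included = included,
                       stringsAsFactors = FALSE)
  attrition <- c(
    input = n,
    no_pd_diagnosis = sum(is.na(initial)),
    quiescence_fail = sum(!is.na(initial) & !q_pass),
    no_confirmation = sum(!is.na(initial) & q_pass & !c_pass),
    mimic_excluded = sum(!is.na(initial) & q_pass & c_pass & !is.na(excl)),
    included = sum(included))
  structure(list(cohort = cohort, attrition = attrition,
                 quiescence_mode = mode), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table>", x$attrition[["included"]], "of",
      x$attrition[["input"]], "patients included (mode:",
      paste0(x$quiescence_mode, ")"), "\n")
  a <- x$attrition[c("no_pd_diagnosis", "quiescence_fail", "no_confirmation",
                     "mimic_excluded")]
  for (k in names(a)) cat("  removed at", k, ":", a[[k]], "\n")
  invisible(x)
}
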