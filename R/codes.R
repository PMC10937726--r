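#' Diagnosis code sets
#'
#' A code set bundles ICD-9 and ICD-10 codes under a name with a matching
#' mode. Codes are normalized (uppercase, dots removed) so "332.0" and "3320"
#' are equivalent; `prefix` matching lets "332" capture "332.0".
#'
#' @param name Label for the set (used as the exclusion reason).
#' @param icd9,icd10 Character vectors of codes (either may be empty, not both).
#' @param match_mode `"exact"` or `"prefix"`.
#' @return An object of class `code_set`.
#' @export
code_set <- function(name, icd9 = character(), icd10 = character(),
                     match_mode = c("exact", "prefix")) {
  match_mode <- match.arg(match_mode)
  if (length(icd9) + length(icd10) == 0L)
    stop("code_set needs at least one code", call. = FALSE)
  structure(
    list(name = name,
         icd9 = normalize_code(icd9),
         icd10 = normalize_code(icd10),
         match_mode = match_mode),
    class = "code_set")
}

normalize_code <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

#' Match diagnosis codes against a code set
#'
#' @param codes Character vector of diagnosis codes.
#' @param vocab Character vector (recycled) of vocabularies, `"ICD9"`/`"ICD10"`.
#' @param set A [code_set()].
#' @return Logical vector, one element per code.
#' @export
matches_code_set <- function(codes, vocab, set) {
  stopifnot(inherits(set, "code_set"))
  codes <- normalize_code(codes)
  vocab <- rep_len(toupper(vocab), length(codes))
  hit <- function(code, targets) {
    if (!length(targets)) return(FALSE)
    if (set$match_mode == "exact") code %in% targets
    else any(startsWith(code, targets))
  }
  vapply(seq_along(codes), function(i) {
    targets <- if (vocab[i] == "ICD9") set$icd9 else set$icd10
    hit(codes[i], targets)
  }, logical(1))
}

#' Parkinson's disease diagnosis code set
#'
#' ICD-9 332 / 332.0 (prefix-matched so 332.0 falls under 332) and ICD-10 G20.
#' @return A [code_set()].
#' @export
pd_code_set <- function() {
  code_set("parkinsons_disease", icd9 = "332", icd10 = "G20",
           match_mode = "prefix")
}

#' Mild cognitive impairment code set (ICD-9 331.83, ICD-10 G31.84)
#' @return A [code_set()].
#' @export
mci_code_set <- function() {
  code_set("mild_cognitive_impairment", icd9 = "331.83", icd10 = "G31.84")
}

#' Parkinsonism-mimic exclusion code sets
#'
#' Synthetic stand-in vocabulary for conditions that commonly produce clinical
#' parkinsonism (dementias, psychotic disorders, atypical parkinsonian
#' syndromes, metabolic neurogenic anomalies); a diagnosis from any of these
#' sets during the pre-diagnosis quiescence window excludes the patient.
#'
#' @return List of [code_set()] objects, in evaluation order.
#' @export
mimic_exclusion_sets <- function() {
  list(
    code_set("mimic_dementia", icd9 = c("331.0", "323.9"),
             icd10 = c("G30.9", "F03", "G04.90")),
    code_set("mimic_psychiatric", icd9 = "295.90", icd10 = "F20.9"),
    code_set("mimic_atypical_parkinsonism", icd9 = c("333.0", "332.1"),
             icd10 = c("G23.1", "G23.2", "G90.3", "G21.9")),
    code_set("mimic_metabolic", icd9 = "275.1", icd10 = "E83.01"))
}

#' Adverse clinical event code sets (synthetic vocabulary)
#'
#' Falls and fractures, and depression, as used for the utilization-based
#' adverse event definitions.
#' @return Named list of [code_set()] objects.
#' @export
adverse_event_code_sets <- function() {
  list(
    falls_fractures = code_set("falls_fractures",
                               icd9 = c("E888.9", "820.8"),
                               icd10 = c("W19", "S72.00", "S32.000")),
    depression = code_set("depression", icd9 = "296.20",
                          icd10 = c("F32.9", "F33.9")))
}

#' Drug classes in the synthetic prescription vocabulary
#'
#' `levodopa` and `other_pd` are the PD-therapeutic classes; `cognitive` covers
#' the four cognition drugs used by the real-world cognitive-decline proxy
#' (donepezil, rivastigmine, memantine, galantamine equivalents).
#' @return Named list of character vectors of drug codes per class.
#' @export
drug_vocabulary <- function() {
  list(levodopa = c("LEVODOPA_CARBIDOPA", "LEVODOPA_BENSERAZIDE"),
       other_pd = c("PRAMIPEXOLE", "ROPINIROLE", "RASAGILINE", "AMANTADINE"),
       cognitive = c("DONEPEZIL", "RIVASTIGMINE", "MEMANTINE", "GALANTAMINE"),
       other = c("LISINOPRIL", "ATORVASTATIN", "METFORMIN", "OMEPRAZOLE"))
}

## Referral code used by the cognitive-decline proxy (synthetic vocabulary).
COG_REFERRAL_CODE <- "REF_NEURO_COGNITIVE"
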