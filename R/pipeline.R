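#' Pipeline run configuration
#'
#' Bundles the archetypes to simulate, the per-archetype sample size, the
#' master seed (every stage derives its own seed from it via a documented
#' stable hash, so runs are reproducible end to end), the extraction backend
#' and an optional output directory.
#'
#' @param archetypes Character vector of archetype names.
#' @param n Patients per archetype.
#' @param seed Master seed.
#' @param backend `"reference"` or a backend function (see
#'   [reference_backend()]).
#' @param out_dir Optional output directory for [write_report()].
#' @param overrides Named list (by archetype) of config override lists.
#' @return A list of class `run_config`.
#' @export
run_config <- function(archetypes = c("research", "rwd_emr"), n = 500,
                       seed = 1L, backend = "reference", out_dir = NULL,
                       overrides = list()) {
  structure(list(archetypes = archetypes, n = n, seed = as.integer(seed),
                 backend = backend, out_dir = out_dir, overrides = overrides),
            class = "run_config")
}

#' Recorded scores for analysis
#'
#' Research archetypes carry structured scores; note-based archetypes get
#' their scores from consensus extraction over the notes (flagged notes are
#' dropped pending correction; extracted "no score" notes contribute
#' nothing).
#'
#' @param dataset An `ehr_dataset`.
#' @param backend Extraction backend (default [reference_backend()]).
#' @param scales Scales to extract.
#' @return Data frame `patient_id`, `date`, `scale`, `value`.
#' @export
analysis_scores <- function(dataset, backend = reference_backend(),
                            scales = c("hy", "updrs_total", "mmse")) {
  if (nrow(dataset$scores)) return(dataset$scores)
  if (!nrow(dataset$notes))
    return(data.frame(patient_id = character(), date = as.Date(character()),
                      scale = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(scales, function(sc) {
    ex <- extract_scores(dataset$notes, sc, backend)
    keep <- !ex$flagged & !is.na(ex$final_value)
    i <- match(ex$note_id[keep], dataset$notes$note_id)
    data.frame(patient_id = dataset$notes$patient_id[i],
               date = dataset$notes$date[i], scale = sc,
               value = ex$final_value[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Analysis time origin per included patient
#'
#' The recorded initial diagnosis date, shifted to mid-year (+182 days) for
#' year-resolution archetypes so that times since diagnosis are mean-unbiased
#' under a uniform within-year diagnosis phase.
#'
#' @param dataset An `ehr_dataset`.
#' @param cohort A `cohort_table`.
#' @return Named `Date` vector over included patients.
#' @export
dx_time_origin <- function(dataset, cohort) {
  tab <- cohort$cohort[cohort$cohort$included, , drop = FALSE]
  year_res <- !is.null(dataset$config) &&
    identical(dataset$config$dx_resolution, "year")
  stats::setNames(tab$initial_dx_date + if (year_res) 182L else 0L,
                  tab$patient_id)
}

#' Build the per-visit progression regression table
#'
#' One row per recorded score observation of an included patient: the score
#' value, years since diagnosis, age at diagnosis, sex, and patient id.
#'
#' @param dataset An `ehr_dataset`.
#' @param cohort A `cohort_table`.
#' @param scores Recorded scores (see [analysis_scores()]).
#' @param scale Scale to extract rows for.
#' @return Data frame with columns `patient_id`, `value`, `years_since_dx`,
#'   `age_at_dx`, `sex`.
#' @export
progression_table <- function(dataset, cohort, scores, scale) {
  origin <- dx_time_origin(dataset, cohort)
  s <- scores[scores$scale == scale & scores$patient_id %in% names(origin), ,
              drop = FALSE]
  if (!nrow(s)) return(data.frame(patient_id = character(), value = numeric(),
                                  years_since_dx = numeric(),
                                  age_at_dx = numeric(), sex = character(),
                                  stringsAsFactors = FALSE))
  org <- origin[s$patient_id]
  i <- match(s$patient_id, dataset$patients$patient_id)
  ## NB: years_since_dx may be slightly negative for year-resolution
  ## diagnosis dates (mid-year origin); truncating would bias the fit.
  data.frame(patient_id = s$patient_id, value = s$value,
             years_since_dx = years_between(org, s$date),
             age_at_dx = years_between(dataset$patients$birth_date[i], org),
             sex = dataset$patients$sex[i], stringsAsFactors = FALSE)
}

#' Visit-level agreement between the two cognitive-decline definitions
#'
#' For patients with recorded MMSE values, compares at each MMSE visit the
#' binary MMSE definition (score <= cutoff) with the binary real-world proxy
#' definition (proxy event on or before the visit date), returning the phi
#' coefficient over visits (and the patient-level variant).
#'
#' @param dataset An `ehr_dataset`.
#' @param cohort A `cohort_table`.
#' @param scores Recorded scores.
#' @param cutoff MMSE cutoff (default 25).
#' @return List: `phi_visit`, `phi_patient`, `n_visits`, `n_patients`.
#' @export
phi_validation <- function(dataset, cohort, scores, cutoff = 25) {
  tab <- cohort$cohort[cohort$cohort$included, , drop = FALSE]
  mmse <- scores[scores$scale == "mmse" &
                   scores$patient_id %in% tab$patient_id, , drop = FALSE]
  if (!nrow(mmse)) return(list(phi_visit = NA_real_, phi_patient = NA_real_,
                               n_visits = 0L, n_patients = 0L))
  pids <- unique(mmse$patient_id)
  diag_split <- split(dataset$diagnoses, dataset$diagnoses$patient_id)
  fill_split <- split(dataset$fills, dataset$fills$patient_id)
  ref_split <- split(dataset$referrals, dataset$referrals$patient_id)
  proxy_date <- stats::setNames(rep(as.Date(NA), length(pids)), pids)
  for (p in pids) {
    pat <- list(diagnoses = diag_split[[p]], fills = fill_split[[p]],
                referrals = ref_split[[p]])
    proxy_date[p] <- detect_cognitive_decline_rwd(pat)
  }
  a_visit <- mmse$value <= cutoff
  pd <- proxy_date[mmse$patient_id]
  b_visit <- !is.na(pd) & mmse$date >= pd
  phi_v <- tryCatch(phi_coefficient(a_visit, b_visit),
                    error = function(e) NA_real_)
  a_pat <- tapply(a_visit, mmse$patient_id, any)
  b_pat <- tapply(b_visit, mmse$patient_id, any)
  phi_p <- tryCatch(phi_coefficient(as.logical(a_pat), as.logical(b_pat)),
                    error = function(e) NA_real_)
  list(phi_visit = phi_v, phi_patient = phi_p,
       n_visits = nrow(mmse), n_patients = length(pids))
}

#' Run the full comparison pipeline
#'
#' For each archetype: generate -> phenotype the cohort -> obtain recorded
#' scores (structured or via consensus extraction) -> detect clinical events
#' -> per-source summaries (cohort characteristics, Kaplan-Meier medians,
#' progression fits). Then cross-source comparisons: age-at-diagnosis test
#' routing, therapy-delay difference, log-rank on time to Hoehn & Yahr 3,
#' UPDRS/MMSE slope comparisons, plus the cognitive-definition phi validation
#' and the score-presence missingness audit on the EMR archetype.
#' Deterministic for a fixed configuration under the reference backend.
#'
#' @param config A [run_config()].
#' @return A list of class `results_bundle`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  backend <- if (is.function(config$backend)) config$backend else
    reference_backend()
  per_source <- list()
  log <- character()
  for (arch in config$archetypes) {
    seed <- derive_seed(config$seed, paste0("generate_", arch))
    cfg <- make_archetype_config(arch, config$overrides[[arch]] %||% list())
    ds <- generate_dataset(cfg, config$n, seed)
    coh <- build_cohort(ds)
    scores <- analysis_scores(ds, backend)
    ev <- detect_events(ds, coh)
    log <- c(log, sprintf("source=%s seed=%d n=%d included=%d", arch, seed,
                          config$n, coh$attrition[["included"]]))
    per_source[[arch]] <- summarize_source(ds, coh, scores, ev)
    per_source[[arch]]$dataset <- ds
    per_source[[arch]]$cohort <- coh
    per_source[[arch]]$scores <- scores
    per_source[[arch]]$events <- ev
  }

  comparisons <- list()
  if (all(c("research", "rwd_emr") %in% names(per_source))) {
    comparisons <- compare_sources(per_source$research, per_source$rwd_emr)
  }
  if ("rwd_emr" %in% names(per_source)) {
    r <- per_source$rwd_emr
    comparisons$phi_validation <- phi_validation(r$dataset, r$cohort, r$scores)
    comparisons$missingness <- missingness_for(r$dataset, r$cohort,
                                               seed = derive_seed(config$seed,
                                                                  "missingness"))
  }
  structure(list(per_source = per_source, comparisons = comparisons,
                 config = config, log = log, schema_version = "1.0"),
            class = "results_bundle")
}

summarize_source <- function(ds, coh, scores, ev) {
  inc <- coh$cohort[coh$cohort$included, , drop = FALSE]
  origin <- dx_time_origin(ds, coh)
  i <- match(inc$patient_id, ds$patients$patient_id)
  age <- years_between(ds$patients$birth_date[i], origin[inc$patient_id])
  enc_split <- split(ds$encounters$date, ds$encounters$patient_id)
  fup <- vapply(inc$patient_id, function(p)
    max(years_between(origin[[p]], max(enc_split[[p]])), 0), numeric(1))
  with_score <- mean(inc$patient_id %in% unique(scores$patient_id))
  km <- lapply(split(ev, ev$event_type), function(e) {
    e <- e[e$eligible, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    km_fit(e)
  })
  fits <- list(); prog_tables <- list()
  tev <- if (!is.null(ds$config) &&
               identical(ds$config$dx_resolution, "year")) 1 / 12 else 0
  for (sc in c("updrs_total", "mmse")) {
    tabsc <- progression_table(ds, coh, scores, sc)
    if (length(unique(tabsc$patient_id)) >= 10) {
      prog_tables[[sc]] <- tabsc
      fits[[sc]] <- fit_progression_model(tabsc, "value",
                                          c("age_at_dx", "sex"),
                                          time_error_var = tev)
    }
  }
  list(characteristics = list(
    n_included = nrow(inc), attrition = as.list(coh$attrition),
    pct_male = mean(ds$patients$sex[i] == "M"),
    mean_age_at_dx = mean(age), mean_followup_years = mean(fup),
    pct_with_score = with_score),
    km = km, progression = fits, prog_tables = prog_tables, age_at_dx = age)
}

compare_sources <- function(res, rwd) {
  out <- list()
  out$age_test <- group_difference_test(rwd$age_at_dx, res$age_at_dx)
  out$age_diff <- mean(rwd$age_at_dx) - mean(res$age_at_dx)

  delay_of <- function(s) {
    e <- s$events
    e <- e[e$event_type == "pd_therapy" & e$observed %in% TRUE, , drop = FALSE]
    e$time_years
  }
  d_r <- delay_of(res); d_w <- delay_of(rwd)
  out$therapy_delay <- list(
    mean_research = mean(d_r), mean_rwd = mean(d_w),
    difference = mean(d_w) - mean(d_r))

  ev_of <- function(s, type) {
    e <- s$events
    e[e$event_type == type & e$eligible, , drop = FALSE]
  }
  hy_r <- ev_of(res, "hy3"); hy_w <- ev_of(rwd, "hy3")
  if (nrow(hy_r) && nrow(hy_w)) {
    out$hy3_logrank <- logrank_test(hy_w, hy_r)
    out$hy3_median <- list(
      research = km_fit(hy_r)$median_label,
      rwd = km_fit(hy_w)$median_label)
  }
  for (sc in c("updrs_total", "mmse")) {
    ta <- res$prog_tables[[sc]]; tb <- rwd$prog_tables[[sc]]
    if (!is.null(ta) && !is.null(tb)) {
      ta$source <- "research"; tb$source <- "rwd_emr"
      pool <- rbind(ta, tb)
      out[[paste0(sc, "_slope_comparison")]] <-
        compare_progression_slopes(pool, "value", c("age_at_dx", "sex"))
    }
  }
  out
}

missingness_for <- function(ds, coh, seed = 1L) {
  inc <- coh$cohort[coh$cohort$included, , drop = FALSE]
  gt <- ds$ground_truth
  i <- match(inc$patient_id, gt$patient_id)
  features <- data.frame(
    age_at_dx = gt$age_at_dx[i],
    sex = factor(gt$sex[i]),
    specialist = as.integer(gt$specialist[i]),
    followup = gt$followup_years[i])
  has_score <- gt$recorder[i]
  if (length(unique(has_score)) < 2)
    return(list(auc = NA_real_, n = nrow(inc)))
  missingness_audit(features, has_score, seed = seed)
}

#' Write a machine-readable results bundle to disk
#'
#' Emits `results.json` (schema-versioned summary), a Table-1-style
#' `characteristics.csv`, per-event Kaplan-Meier curves as
#' `km_<source>_<event>.csv` and the run log. Sections without content (e.g.
#' no events) are omitted with a log notice.
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  rows <- lapply(names(bundle$per_source), function(a) {
    ch <- bundle$per_source[[a]]$characteristics
    data.frame(source = a, n_included = ch$n_included,
               pct_male = ch$pct_male, mean_age_at_dx = ch$mean_age_at_dx,
               mean_followup_years = ch$mean_followup_years,
               pct_with_score = ch$pct_with_score)
  })
  chpath <- file.path(out_dir, "characteristics.csv")
  utils::write.csv(do.call(rbind, rows), chpath, row.names = FALSE)
  written <- c(written, chpath)

  notices <- character()
  for (a in names(bundle$per_source)) {
    km <- bundle$per_source[[a]]$km
    if (!length(km)) {
      notices <- c(notices, paste0("no events for source ", a,
                                   "; KM section omitted"))
      next
    }
    for (ev in names(km)) {
      k <- km[[ev]]
      if (is.null(k)) next
      p <- file.path(out_dir, sprintf("km_%s_%s.csv", a, ev))
      utils::write.csv(data.frame(time = k$time, survival = k$surv,
                                  ci_low = k$lower, ci_high = k$upper,
                                  n_at_risk = k$n_risk), p, row.names = FALSE)
      written <- c(written, p)
    }
  }

  js <- bundle_to_json_list(bundle)
  js$notices <- notices
  jpath <- file.path(out_dir, "results.json")
  jsonlite::write_json(js, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, jpath)
  logpath <- file.path(out_dir, "run.log")
  writeLines(bundle$log, logpath)
  invisible(c(written, logpath))
}

bundle_to_json_list <- function(bundle) {
  src <- lapply(bundle$per_source, function(s) {
    list(characteristics = s$characteristics,
         km_medians = lapply(s$km, function(k)
           if (is.null(k)) NULL else
             list(median = k$median, median_label = k$median_label,
                  n = k$n)),
         progression = lapply(s$progression, function(f)
           list(slope = f$slope, slope_se = f$slope_se,
                intercept_at_dx = f$intercept_at_dx,
                intercept_at_dx_se = f$intercept_at_dx_se,
                n_obs = f$n_obs, n_patients = f$n_patients,
                vif_flag = f$vif_flag)))
  })
  comp <- bundle$comparisons
  comp_js <- list()
  if (!is.null(comp$age_test))
    comp_js$age_test <- list(route = comp$age_test$route,
                             p_value = comp$age_test$p_value,
                             difference = comp$age_diff)
  if (!is.null(comp$therapy_delay)) comp_js$therapy_delay <- comp$therapy_delay
  if (!is.null(comp$hy3_logrank))
    comp_js$hy3 <- list(logrank_p = comp$hy3_logrank$p_value,
                        medians = comp$hy3_median)
  for (sc in c("updrs_total", "mmse")) {
    key <- paste0(sc, "_slope_comparison")
    if (!is.null(comp[[key]]))
      comp_js[[key]] <- comp[[key]][c("slope_diff", "se", "p_value",
                                      "separate_fit_diff")]
  }
  if (!is.null(comp$phi_validation))
    comp_js$phi_validation <- comp$phi_validation
  if (!is.null(comp$missingness))
    comp_js$missingness_auc <- comp$missingness$auc
  ## multiple-testing note: raw p-values are reported, no correction applied
  list(schema_version = bundle$schema_version, sources = src,
       comparisons = comp_js,
       notes = "p-values are reported uncorrected for multiple testing")
}
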