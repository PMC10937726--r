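#' Write a synthetic dataset to disk
#'
#' Emits the observable tables as CSV (`patients.csv`, `encounters.csv`,
#' `diagnoses.csv`, `fills.csv`, `referrals.csv`, `coverage.csv`,
#' `scores.csv`), notes as JSON lines (`notes.jsonl`, fields `note_id`,
#' `patient_id`, `date`, `text`) and the generator ground truth as
#' `ground_truth.csv`. Dates are ISO-8601; files are UTF-8.
#'
#' @param dataset An `ehr_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("patients", "encounters", "diagnoses", "fills", "referrals",
            "coverage", "scores", "ground_truth", "note_truth")
  for (t in tabs) {
    utils::write.csv(dataset[[t]], file.path(dir, paste0(t, ".csv")),
                     row.names = FALSE)
  }
  write_notes_jsonl(dataset$notes, file.path(dir, "notes.jsonl"))
  invisible(dir)
}

write_notes_jsonl <- function(notes, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(notes)) {
    lines <- vapply(seq_len(nrow(notes)), function(i)
      as.character(jsonlite::toJSON(list(
        note_id = notes$note_id[i], patient_id = notes$patient_id[i],
        date = as.character(notes$date[i]), text = notes$text[i]),
        auto_unbox = TRUE)), character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory holding the CSV/JSONL files.
#' @param archetype Optional archetype name to attach a config.
#' @return An `ehr_dataset` list.
#' @export
read_dataset <- function(dir, archetype = NULL) {
  rd <- function(name, date_cols = "date") {
    p <- file.path(dir, paste0(name, ".csv"))
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    for (dc in intersect(date_cols, names(df))) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  notes_path <- file.path(dir, "notes.jsonl")
  notes <- if (file.exists(notes_path) && file.size(notes_path) > 0) {
    rows <- lapply(readLines(notes_path, encoding = "UTF-8"),
                   jsonlite::fromJSON)
    data.frame(note_id = vapply(rows, `[[`, character(1), "note_id"),
               patient_id = vapply(rows, `[[`, character(1), "patient_id"),
               date = as.Date(vapply(rows, `[[`, character(1), "date")),
               text = vapply(rows, `[[`, character(1), "text"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(note_id = character(), patient_id = character(),
               date = as.Date(character()), text = character(),
               stringsAsFactors = FALSE)
  }
  cfg <- if (!is.null(archetype)) make_archetype_config(archetype) else NULL
  structure(list(
    patients = rd("patients", "birth_date"),
    encounters = rd("encounters"), diagnoses = rd("diagnoses"),
    fills = rd("fills"), referrals = rd("referrals"),
    coverage = rd("coverage", c("start", "end")),
    notes = notes, note_truth = rd("note_truth", character()),
    scores = rd("scores"),
    ground_truth = rd("ground_truth",
                      c("dx_date", "recorded_dx_date", "censor_date",
                        "history_start")),
    archetype = archetype %||% NA_character_, config = cfg),
    class = "ehr_dataset")
}

#' Read a pipeline run configuration from YAML
#'
#' Expected shape: `archetypes` (list of names or name -> overrides blocks),
#' `n_per_archetype` (the bare key `n` is a YAML 1.1 boolean and cannot be
#' used), `seed`, `backend`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A `run_config` list (see [run_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  archetypes <- y$archetypes %||% c("research", "rwd_emr")
  overrides <- list()
  if (is.list(archetypes) && !is.null(names(archetypes))) {
    overrides <- archetypes
    archetypes <- names(archetypes)
  }
  run_config(archetypes = unlist(archetypes),
             n = y$n_per_archetype %||% y$n %||% 500, seed = y$seed %||% 1,
             backend = y$backend %||% "reference",
             out_dir = y$out_dir, overrides = overrides)
}
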