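#' Deterministic reference extractor for synthetic note templates
#'
#' Parses the scale's template phrase out of a synthetic note. Returns the
#' canonical value token, `NA` when the phrase is absent, and the sentinel
#' `"ambiguous"` when the phrase occurs more than once with conflicting
#' values.
#'
#' @param text Note text.
#' @param scale `"hy"`, `"updrs_total"` or `"mmse"`.
#' @return A character token: a number, `NA_character_`, or `"ambiguous"`.
#' @export
reference_extractor <- function(text, scale) {
  assert_scale(scale)
  pat <- switch(scale,
                hy = "Hoehn and Yahr stage:\\s*([0-9]+(?:[.,][0-9]+)?)",
                updrs_total = "UPDRS total:\\s*([0-9]+(?:[.,][0-9]+)?)",
                mmse = "MMSE:\\s*([0-9]+(?:[.,][0-9]+)?)/30")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NA_character_)
  starts <- attr(m, "capture.start")[, 1]
  lens <- attr(m, "capture.length")[, 1]
  vals <- unique(normalize_score_value(substring(text, starts,
                                                 starts + lens - 1)))
  if (length(vals) > 1) "ambiguous" else vals
}

#' Normalize a score token to a canonical numeric string
#'
#' Handles dialect variants seen in extractor outputs: decimal commas
#' ("2,5"), Roman numerals I-V with optional fraction ("II.5"), a "/30"
#' denominator suffix, surrounding whitespace, and trailing zeros ("3.0").
#' Non-numeric / NA-like tokens normalize to `NA_character_`.
#'
#' @param x Character vector of raw tokens.
#' @return Character vector of canonical tokens (or `NA_character_`).
#' @export
normalize_score_value <- function(x) {
  out <- trimws(as.character(x))
  out[out %in% c("", "NA", "N/A", "na", "none", "None")] <- NA_character_
  out <- sub("/30$", "", out)
  out <- gsub(",", ".", out, fixed = TRUE)
  roman <- c(I = "1", II = "2", III = "3", IV = "4", V = "5")
  rm <- regmatches(out, regexec("^(I{1,3}|IV|V)(\\.[0-9]+)?$", out))
  for (i in seq_along(out)) {
    if (!is.na(out[i]) && length(rm[[i]]) > 0)
      out[i] <- paste0(roman[[rm[[i]][2]]], rm[[i]][3])
  }
  num <- suppressWarnings(as.numeric(out))
  ifelse(is.na(num), NA_character_, format_score(num))
}

#' Extractor backends
#'
#' A backend is a function `(text, scale, polarity, run_index) -> token`
#' standing in for one exemplar-conditioned model inference. All backends here
#' are pure given their arguments.
#'
#' `reference_backend()` wraps [reference_extractor()]; on ambiguous notes
#' (two conflicting values in the text) it deterministically returns one of
#' the conflicting values depending on `(polarity, run_index)`, emulating a
#' model that latches onto different mentions on different prompt runs — such
#' notes end up flagged by the consensus protocol.
#'
#' `mock_noisy_backend(p, seed)` corrupts each run independently with
#' probability `p`, replacing the truth with a different value on the scale
#' (used to check flag rates against their binomial expectation).
#'
#' @param p Per-run corruption probability.
#' @param seed Integer; corruption is a pure hash of (note text, scale,
#'   polarity, run, seed).
#' @return A backend function.
#' @export
reference_backend <- function() {
  ## one-entry memo: consensus runs call the backend repeatedly with the same
  ## (text, scale); the parse is deterministic, so cache the last result.
  last_text <- NULL; last_scale <- NULL; last_val <- NULL
  function(text, scale, polarity, run_index) {
    if (identical(text, last_text) && identical(scale, last_scale)) {
      v <- last_val
    } else {
      v <- reference_extractor(text, scale)
      last_text <<- text; last_scale <<- scale; last_val <<- v
    }
    if (identical(v, "ambiguous")) {
      vals <- extract_all_values(text, scale)
      pick <- (ifelse(identical(polarity, "positive"), 0L, 1L) +
                 as.integer(run_index)) %% length(vals) + 1L
      vals[pick]
    } else v
  }
}

extract_all_values <- function(text, scale) {
  pat <- switch(scale,
                hy = "Hoehn and Yahr stage:\\s*([0-9]+(?:[.,][0-9]+)?)",
                updrs_total = "UPDRS total:\\s*([0-9]+(?:[.,][0-9]+)?)",
                mmse = "MMSE:\\s*([0-9]+(?:[.,][0-9]+)?)/30")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NA_character_)
  starts <- attr(m, "capture.start")[, 1]
  lens <- attr(m, "capture.length")[, 1]
  unique(normalize_score_value(substring(text, starts, starts + lens - 1)))
}

#' @rdname reference_backend
#' @export
mock_noisy_backend <- function(p, seed = 1L) {
  force(p); force(seed)
  ref <- reference_backend()
  function(text, scale, polarity, run_index) {
    truth <- ref(text, scale, polarity, run_index)
    h <- string_hash(paste(text, scale, polarity, run_index, seed,
                           sep = "|"))
    ## draw from a locally seeded RNG (set.seed scrambles the raw hash into a
    ## uniform stream); the global RNG state is preserved, so the backend is
    ## pure given its arguments and invisible to callers
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old))
      suppressWarnings(rm(".Random.seed", envir = globalenv())) else
        assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(h %% 2147483646))
    u <- runif(1)
    if (u >= p) return(truth)
    r <- scale_ranges()[[scale]]
    cand <- setdiff(as.character(seq(r[1] + 1, r[2])), truth)
    sample(cand, 1)
  }
}

string_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  h
}

#' Run the self-consistency voting protocol on one note
#'
#' Executes `n_pos` positive-exemplar and `n_neg` negative-exemplar backend
#' runs and votes: within each polarity set the modal output must occur at
#' least `threshold` times (default 9 of 10) with no modal tie, and the two
#' polarity modes must agree; otherwise the note is flagged and its value is
#' left pending manual correction. With `pooling = "pooled"` the rule is
#' instead applied once to all `n_pos + n_neg` runs with threshold
#' `2 * threshold`.
#'
#' @param text Note text.
#' @param scale Scale label.
#' @param backend A backend function (see [reference_backend()]).
#' @param n_pos,n_neg Runs per polarity (default 10 each).
#' @param threshold Minimum modal count per polarity set (default 9).
#' @param pooling `"per_polarity"` (default) or `"pooled"`.
#' @param note_id Optional identifier carried into the result.
#' @return A list of class `consensus_result`: `note_id`, `scale`, `runs`,
#'   `modal_value`, `agreement` (counts per polarity), `flagged`,
#'   `final_value` (numeric, `NA` when absent or flagged), `provenance`.
#' @export
run_consensus <- function(text, scale, backend, n_pos = 10, n_neg = 10,
                          threshold = 9, pooling = c("per_polarity", "pooled"),
                          note_id = NA_character_) {
  pooling <- match.arg(pooling)
  assert_scale(scale)
  if (threshold > min(n_pos, n_neg))
    stop("threshold must be <= min(n_pos, n_neg)", call. = FALSE)
  run_one <- function(polarity, k) {
    tryCatch(normalize_token(backend(text, scale, polarity, k)),
             error = function(e) structure("ERROR", error = TRUE))
  }
  pos <- vapply(seq_len(n_pos), function(k) run_one("positive", k),
                character(1))
  neg <- vapply(seq_len(n_neg), function(k) run_one("negative", k),
                character(1))
  runs <- c(pos, neg)
  if (any(runs == "ERROR", na.rm = TRUE)) {
    return(structure(list(note_id = note_id, scale = scale, runs = runs,
                          modal_value = NA_character_,
                          agreement = c(positive = 0L, negative = 0L),
                          flagged = TRUE, final_value = NA_real_,
                          provenance = "error"),
                     class = "consensus_result"))
  }
  tok <- function(x) ifelse(is.na(x), "<none>", x)
  if (pooling == "pooled") {
    mv <- modal_value(tok(runs))
    flagged <- mv$tie || mv$count < 2 * threshold
    agreement <- c(pooled = mv$count)
    modal <- mv$value
  } else {
    mp <- modal_value(tok(pos)); mn <- modal_value(tok(neg))
    flagged <- mp$tie || mn$tie || mp$count < threshold ||
      mn$count < threshold || !identical(mp$value, mn$value)
    agreement <- c(positive = mp$count, negative = mn$count)
    modal <- mp$value
  }
  final <- if (flagged || identical(modal, "<none>")) NA_real_ else
    as.numeric(modal)
  structure(list(note_id = note_id, scale = scale, runs = runs,
                 modal_value = if (identical(modal, "<none>")) NA_character_
                 else modal,
                 agreement = agreement, flagged = flagged,
                 final_value = final, provenance = "consensus"),
            class = "consensus_result")
}

normalize_token <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_character_)
  normalize_score_value(as.character(x))
}

#' Consensus extraction over a notes table
#'
#' Vectorized driver of [run_consensus()] over a `notes` data frame.
#'
#' @param notes Data frame with `note_id`, `text`.
#' @param scale Scale label.
#' @inheritParams run_consensus
#' @return Data frame: `note_id`, `scale`, `final_value`, `flagged`,
#'   `modal_value`, `agreement_pos`, `agreement_neg`, `provenance`.
#' @export
extract_scores <- function(notes, scale, backend = reference_backend(),
                           n_pos = 10, n_neg = 10, threshold = 9,
                           pooling = "per_polarity") {
  res <- lapply(seq_len(nrow(notes)), function(i)
    run_consensus(notes$text[i], scale, backend, n_pos, n_neg, threshold,
                  pooling, note_id = notes$note_id[i]))
  data.frame(
    note_id = notes$note_id,
    scale = scale,
    final_value = vapply(res, `[[`, numeric(1), "final_value"),
    flagged = vapply(res, `[[`, logical(1), "flagged"),
    modal_value = vapply(res, function(r) r$modal_value %||% NA_character_,
                         character(1)),
    agreement_pos = vapply(res, function(r)
      as.integer(r$agreement[[1]]), integer(1)),
    agreement_neg = vapply(res, function(r)
      as.integer(r$agreement[[length(r$agreement)]]), integer(1)),
    provenance = vapply(res, `[[`, character(1), "provenance"),
    stringsAsFactors = FALSE)
}

#' Stratified audit sample for manual chart review
#'
#' Seeded sampling without replacement from the four review strata:
#' notes where the (gold) reviewer identified a score, notes where the model
#' identified a score, notes where the model found none, and notes where the
#' reviewer found none. If a stratum holds fewer notes than requested, all of
#' them are taken with a warning.
#'
#' @param results Extraction results (from [extract_scores()]), with
#'   `note_id`, `final_value`.
#' @param gold Data frame with `note_id`, `value` (`NA` = no score present).
#' @param sizes Named or unnamed vector of 4 stratum sizes
#'   (gold-positive, model-positive, model-negative, gold-negative), or a
#'   single size used for all four.
#' @param seed Integer sampling seed.
#' @return List of class `audit_sample` with `strata` (named list of note_id
#'   vectors) and `sizes`.
#' @export
audit_sample <- function(results, gold, sizes, seed = 1L) {
  if (length(sizes) == 1) sizes <- rep(sizes, 4)
  stopifnot(length(sizes) == 4)
  g <- gold$value[match(results$note_id, gold$note_id)]
  strata_pop <- list(
    gold_positive = results$note_id[!is.na(g)],
    model_positive = results$note_id[!is.na(results$final_value)],
    model_negative = results$note_id[is.na(results$final_value)],
    gold_negative = results$note_id[is.na(g)])
  set.seed(as.integer(seed))
  out <- vector("list", 4); names(out) <- names(strata_pop)
  for (i in seq_along(strata_pop)) {
    pop <- strata_pop[[i]]
    if (length(pop) < sizes[i]) {
      warning("stratum ", names(strata_pop)[i], " has only ", length(pop),
              " notes (requested ", sizes[i], "); taking all", call. = FALSE)
      out[[i]] <- pop
    } else {
      out[[i]] <- sample(pop, sizes[i])
    }
  }
  structure(list(strata = out, sizes = vapply(out, length, integer(1))),
            class = "audit_sample")
}

#' Extraction accuracy against gold labels
#'
#' Value-for-value accuracy over an audited set; an absent score matched by an
#' absent extraction (`NA` vs `NA`) counts as correct.
#'
#' @param results Extraction results with `note_id`, `final_value`.
#' @param gold Data frame with `note_id`, `value`.
#' @param note_ids Optional subset of note ids (e.g. an audit sample).
#' @return List with `accuracy`, `n`, and `errors` (data frame of
#'   mismatches).
#' @export
score_accuracy <- function(results, gold, note_ids = NULL) {
  if (!is.null(note_ids)) results <- results[results$note_id %in% note_ids, ]
  g <- gold$value[match(results$note_id, gold$note_id)]
  v <- results$final_value
  ok <- (is.na(g) & is.na(v)) | (!is.na(g) & !is.na(v) & g == v)
  errors <- data.frame(note_id = results$note_id[!ok],
                       extracted = v[!ok], gold = g[!ok],
                       stringsAsFactors = FALSE)
  list(accuracy = mean(ok), n = length(ok), errors = errors)
}

#' Merge manual corrections into extraction results
#'
#' Only flagged notes may be overwritten; correcting an unflagged note is an
#' error (consensus-accepted values are never silently replaced). Corrected
#' notes get provenance `"manual_correction"`.
#'
#' @param results Extraction results data frame.
#' @param corrections Named numeric vector or list, `note_id -> value`.
#' @return Updated results data frame.
#' @export
apply_corrections <- function(results, corrections) {
  if (!length(corrections)) return(results)
  ids <- names(corrections)
  missing <- setdiff(ids, results$note_id)
  if (length(missing))
    stop("corrections refer to unknown note(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(ids, results$note_id)
  if (any(!results$flagged[idx]))
    stop("corrections may only be applied to flagged notes: ",
         paste(ids[!results$flagged[idx]], collapse = ", "), call. = FALSE)
  results$final_value[idx] <- as.numeric(unlist(corrections))
  results$provenance[idx] <- "manual_correction"
  results
}
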