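#' Default ICD-10 code prefixes for substance use
#'
#' Category-level ICD-10 prefixes commonly used to identify drug use in
#' published phenotyping work: drug use and dependence categories F11-F16,
#' F18, F19 (opioids, cannabis, sedatives, cocaine, other stimulants,
#' hallucinogens, inhalants, other psychoactive substances; alcohol F10 and
#' nicotine F17 excluded) and narcotic/psychostimulant poisoning T40.0-T40.6
#' and T43.6. Comparison is prefix-based on canonical (dot-stripped,
#' upper-case) codes, so the entry `"F11"` matches `"F11.20"`.
#'
#' @return Character vector of canonical code prefixes.
#' @export
default_code_list <- function() {
  c("F11", "F12", "F13", "F14", "F15", "F16", "F18", "F19",
    "T400", "T401", "T402", "T403", "T404", "T405", "T406", "T436")
}

#' Flag an encounter on ICD-10 codes
#'
#' TRUE iff any code in the selected scope has a canonical form with a
#' prefix in `code_list`. `"visit"` consults the (top 5) codes attached to
#' the hospital encounter; `"history"` consults all codes on the patient's
#' chart.
#'
#' @param encounter A one-row slice of a corpus `codes` table, or a list
#'   with `visit_codes` and `history_codes` character vectors.
#' @param code_list Character vector of canonical code prefixes.
#' @param scope `"visit"` or `"history"`.
#' @return Logical scalar.
#' @examples
#' flag_icd(list(visit_codes = "F1120", history_codes = character()),
#'          default_code_list(), "visit")
#' @export
flag_icd <- function(encounter, code_list, scope = c("visit", "history")) {
  if (length(code_list) == 0L) stop_pwud("`code_list` must be non-empty")
  scope <- match.arg(scope)
  codes <- if (scope == "visit") encounter$visit_codes else
    encounter$history_codes
  if (is.list(codes)) codes <- unlist(codes)
  codes_hit(codes, code_list)
}

codes_hit <- function(codes, code_list) {
  if (length(codes) == 0L) return(FALSE)
  codes <- canonicalize_code(codes)
  prefixes <- canonicalize_code(code_list)
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), TRUE))
}

#' Aggregate note flags to a partial encounter signal
#'
#' Computes the flagged-note fraction against the total number of notes
#' linked to the encounter and applies the 10/25/50 percent thresholds with
#' inclusive comparison ("present in at least 10 percent of notes").
#' Encounters with zero linked notes get fraction 0 and all flags FALSE.
#'
#' @param note_flags Tibble of note flags for one encounter (from
#'   [classify_note()]); may have zero rows.
#' @param n_notes_linked Total number of notes linked to the encounter
#'   (must be at least `nrow(note_flags)`).
#' @return A one-row tibble: `n_notes`, `n_flagged`, `fraction`, `any`,
#'   `ge10`, `ge25`, `ge50`.
#' @export
aggregate_encounter <- function(note_flags, n_notes_linked) {
  if (!is_count(n_notes_linked)) {
    stop_pwud("`n_notes_linked` must be a non-negative integer")
  }
  n_flagged <- if (nrow(note_flags)) sum(note_flags$flagged) else 0L
  if (n_notes_linked == 0L && nrow(note_flags) > 0L) {
    stop_pwud("n_notes_linked is 0 but %d note flag(s) supplied",
              nrow(note_flags))
  }
  if (nrow(note_flags) > n_notes_linked) {
    stop_pwud("more note flags (%d) than linked notes (%d)",
              nrow(note_flags), n_notes_linked)
  }
  fraction <- if (n_notes_linked > 0L) n_flagged / n_notes_linked else 0
  tibble::tibble(n_notes = as.integer(n_notes_linked),
                 n_flagged = as.integer(n_flagged),
                 fraction = fraction,
                 any = n_flagged >= 1L,
                 ge10 = n_notes_linked > 0L & fraction >= 0.10,
                 ge25 = n_notes_linked > 0L & fraction >= 0.25,
                 ge50 = n_notes_linked > 0L & fraction >= 0.50)
}

#' Build the encounter-level signal table for a corpus
#'
#' Runs both annotators over every note, aggregates to encounters, applies
#' the note-fraction thresholds, and computes the ICD-10 visit and history
#' flags. One row per encounter; encounters with zero notes are retained
#' with all text flags FALSE.
#'
#' @param corpus A [assemble_corpus()] object.
#' @param lex A [lexicon()] (default [default_lexicon()]).
#' @param code_list ICD-10 prefixes (default [default_code_list()]).
#' @param note_types Note types entering both the numerator and the
#'   denominator of the note fraction. Default all four types (every note
#'   linked to the admission); set to
#'   `c("emergency", "hpi", "discharge")` to restrict to the reviewed types.
#' @param count_historical Count historical-only ConText hits as positive
#'   (default TRUE).
#' @return A tibble with columns `encounter_id`, `n_notes`,
#'   `n_flagged_regex`, `n_flagged_context`, `fraction_regex`, `regex_any`,
#'   `regex_ge10`, `regex_ge25`, `regex_ge50`, `context_any`, `icd_visit`,
#'   `icd_history`.
#' @export
build_signals <- function(corpus, lex = default_lexicon(),
                          code_list = default_code_list(),
                          note_types = NOTE_TYPES,
                          count_historical = TRUE) {
  stopifnot(inherits(corpus, "pwud_corpus"))
  notes <- corpus$notes[corpus$notes$note_type %in% note_types, , drop = FALSE]
  rx <- classify_notes(notes, lex, system = "regex")
  cx <- classify_notes(notes, lex, system = "context",
                       count_historical = count_historical)
  ids <- corpus$encounter_ids
  enc_of_note <- factor(notes$encounter_id, levels = ids)
  n_notes <- as.integer(table(enc_of_note))
  n_rx <- as.integer(tapply(rx$flagged, enc_of_note, sum, default = 0L))
  n_cx <- as.integer(tapply(cx$flagged, enc_of_note, sum, default = 0L))
  n_rx[is.na(n_rx)] <- 0L
  n_cx[is.na(n_cx)] <- 0L
  fraction <- ifelse(n_notes > 0L, n_rx / n_notes, 0)
  icd_visit <- vapply(corpus$codes$visit_codes, codes_hit, TRUE,
                      code_list = code_list)
  icd_history <- vapply(corpus$codes$history_codes, codes_hit, TRUE,
                        code_list = code_list)
  tibble::tibble(
    encounter_id = ids,
    n_notes = n_notes,
    n_flagged_regex = n_rx,
    n_flagged_context = n_cx,
    fraction_regex = fraction,
    regex_any = n_rx >= 1L,
    regex_ge10 = n_notes > 0L & fraction >= 0.10,
    regex_ge25 = n_notes > 0L & fraction >= 0.25,
    regex_ge50 = n_notes > 0L & fraction >= 0.50,
    context_any = n_cx >= 1L,
    icd_visit = icd_visit,
    icd_history = icd_history
  )
}

#' Write an encounter signal table to CSV
#'
#' Booleans are serialized as 0/1.
#'
#' @param signals Tibble from [build_signals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  out <- as.data.frame(signals)
  for (cl in names(out)) {
    if (is.logical(out[[cl]])) out[[cl]] <- as.integer(out[[cl]])
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an encounter signal table from CSV
#'
#' @param path Path written by [write_signals()].
#' @return A tibble in [build_signals()] layout.
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop_pwud("signals file does not exist: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("regex_any", "regex_ge10", "regex_ge25", "regex_ge50",
               "context_any", "icd_visit", "icd_history")) {
    if (cl %in% names(df)) df[[cl]] <- df[[cl]] != 0
  }
  df$encounter_id <- as.character(df$encounter_id)
  tibble::as_tibble(df)
}
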