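#' Canonicalize ICD-10 code strings
#'
#' Codes are compared throughout the package in a canonical form: upper case
#' with the dot removed, so `"F11.20"` and `"f1120"` both canonicalize to
#' `"F1120"`. Canonicalization is idempotent.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector of canonical codes.
#' @examples
#' canonicalize_code(c("F11.20", "b18.2"))
#' @export
canonicalize_code <- function(code) {
  if (!is.character(code)) stop_pwud("`code` must be a character vector")
  out <- toupper(gsub(".", "", code, fixed = TRUE))
  out <- gsub("\\s+", "", out)
  if (any(!nzchar(out) & !is.na(out))) {
    stop_pwud("empty ICD-10 code after canonicalization")
  }
  out
}

#' Read clinical notes from a JSONL file
#'
#' One JSON object per line with fields `note_id`, `encounter_id`,
#' `note_type` and `text`. Unknown note types are coerced to `"other"` with
#' a warning; text is preserved byte-for-byte after UTF-8 decoding.
#'
#' @param path Path to a `.jsonl` file.
#' @return A tibble with columns `note_id`, `encounter_id`, `note_type`
#'   (one of `emergency`, `hpi`, `discharge`, `other`) and `text`.
#' @seealso [write_notes()] for the inverse, [assemble_corpus()].
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) stop_pwud("notes file does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(note_id = character(), encounter_id = character(),
                          note_type = character(), text = character()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) {
      stop_pwud("malformed JSONL record at line %d of %s", i, path)
    }
    need <- c("note_id", "encounter_id", "note_type", "text")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop_pwud("line %d of %s is missing field(s): %s", i, path,
                paste(miss, collapse = ", "))
    }
    recs[[i]] <- rec[need]
  }
  notes <- tibble::tibble(
    note_id = vapply(recs, function(r) as.character(r$note_id), ""),
    encounter_id = vapply(recs, function(r) as.character(r$encounter_id), ""),
    note_type = vapply(recs, function(r) as.character(r$note_type), ""),
    text = vapply(recs, function(r) as.character(r$text), "")
  )
  dup <- notes$note_id[duplicated(notes$note_id)]
  if (length(dup)) {
    stop_pwud("duplicate note_id(s): %s", paste(unique(dup), collapse = ", "))
  }
  unknown <- !(notes$note_type %in% NOTE_TYPES)
  if (any(unknown)) {
    warn_pwud("%d note(s) with unknown note_type (%s) coerced to \"other\"",
              sum(unknown),
              paste(unique(notes$note_type[unknown]), collapse = ", "))
    notes$note_type[unknown] <- "other"
  }
  notes
}

#' Write clinical notes to a JSONL file
#'
#' @param notes A tibble as returned by [read_notes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  need <- c("note_id", "encounter_id", "note_type", "text")
  if (!all(need %in% names(notes))) {
    stop_pwud("`notes` must have columns %s", paste(need, collapse = ", "))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    line <- jsonlite::toJSON(
      list(note_id = notes$note_id[i], encounter_id = notes$encounter_id[i],
           note_type = notes$note_type[i], text = notes$text[i]),
      auto_unbox = TRUE)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read ICD-10 codes from a CSV file
#'
#' Expects columns `encounter_id`, `code`, `scope` with scope either
#' `"visit"` (top 5 discharge codes attached to the hospital encounter) or
#' `"history"` (all codes on the patient's chart). Codes are canonicalized
#' on read.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `encounter_id`, `visit_codes` and
#'   `history_codes` (list columns of canonical code strings), one row per
#'   encounter present in the file.
#' @export
read_codes <- function(path) {
  if (!file.exists(path)) stop_pwud("codes file does not exist: %s", path)
  df <- read.csv(path, colClasses = "character")
  need <- c("encounter_id", "code", "scope")
  if (!all(need %in% names(df))) {
    stop_pwud("codes CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(tibble::tibble(encounter_id = character(),
                          visit_codes = list(), history_codes = list()))
  }
  bad <- !(df$scope %in% c("visit", "history"))
  if (any(bad)) {
    stop_pwud("unknown scope value(s): %s",
              paste(unique(df$scope[bad]), collapse = ", "))
  }
  if (any(!nzchar(trimws(df$code)))) stop_pwud("empty code in %s", path)
  df$code <- canonicalize_code(df$code)
  ids <- unique(df$encounter_id)
  visit <- lapply(ids, function(id) {
    df$code[df$encounter_id == id & df$scope == "visit"]
  })
  history <- lapply(ids, function(id) {
    df$code[df$encounter_id == id & df$scope == "history"]
  })
  tibble::tibble(encounter_id = ids, visit_codes = visit,
                 history_codes = history)
}

#' Read gold-standard labels from a CSV file
#'
#' Expects columns `encounter_id` and `label` (`"pwud"` or `"not_pwud"`),
#' plus optional boolean columns `emergency`, `hpi`, `discharge` carrying
#' per-chart-type review results.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `encounter_id`, `label`, and any per-chart columns
#'   present (as logical).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_pwud("labels file does not exist: %s", path)
  df <- read.csv(path, colClasses = "character")
  if (!all(c("encounter_id", "label") %in% names(df))) {
    stop_pwud("labels CSV must have columns encounter_id, label")
  }
  bad <- !(df$label %in% c("pwud", "not_pwud"))
  if (any(bad)) {
    stop_pwud("unknown label value(s): %s",
              paste(unique(df$label[bad]), collapse = ", "))
  }
  out <- tibble::tibble(encounter_id = df$encounter_id, label = df$label)
  for (ct in intersect(REVIEW_TYPES, names(df))) {
    out[[ct]] <- df[[ct]] %in% c("1", "TRUE", "true", "T")
  }
  out
}

#' Assemble a corpus from notes, codes and optional labels
#'
#' An encounter exists for every distinct `encounter_id` seen in the notes
#' or the codes table; encounters with zero notes are retained (their
#' note-fraction is defined as 0 downstream). Encounters absent from the
#' codes table get empty code lists, with a warning.
#'
#' @param notes Tibble from [read_notes()].
#' @param codes Tibble from [read_codes()], or `NULL`.
#' @param labels Tibble from [read_labels()], or `NULL`. Every labelled
#'   encounter must exist in the corpus.
#' @return An object of class `pwud_corpus`: a list with elements `notes`,
#'   `codes` (one row per encounter), `labels` and `encounter_ids`.
#' @export
assemble_corpus <- function(notes, codes = NULL, labels = NULL) {
  if (is.null(codes)) {
    codes <- tibble::tibble(encounter_id = character(),
                            visit_codes = list(), history_codes = list())
  }
  ids <- unique(c(notes$encounter_id, codes$encounter_id))
  missing_codes <- setdiff(unique(notes$encounter_id), codes$encounter_id)
  if (length(missing_codes)) {
    warn_pwud("%d encounter(s) have no ICD-10 codes; empty code lists used",
              length(missing_codes))
  }
  idx <- match(ids, codes$encounter_id)
  full_codes <- tibble::tibble(
    encounter_id = ids,
    visit_codes = lapply(idx, function(i) {
      if (is.na(i)) character() else codes$visit_codes[[i]]
    }),
    history_codes = lapply(idx, function(i) {
      if (is.na(i)) character() else codes$history_codes[[i]]
    })
  )
  n_visit <- vapply(full_codes$visit_codes, length, 0L)
  if (any(n_visit > 5L)) {
    warn_pwud("%d encounter(s) carry more than 5 visit codes",
              sum(n_visit > 5L))
  }
  if (!is.null(labels)) {
    stray <- setdiff(labels$encounter_id, ids)
    if (length(stray)) {
      stop_pwud("label(s) for unknown encounter(s): %s",
                paste(stray, collapse = ", "))
    }
  }
  structure(list(notes = notes, codes = full_codes, labels = labels,
                 encounter_ids = ids),
            class = "pwud_corpus")
}

#' @export
print.pwud_corpus <- function(x, ...) {
  cat(sprintf("<pwud_corpus> %d encounters, %d notes%s\n",
              length(x$encounter_ids), nrow(x$notes),
              if (is.null(x$labels)) "" else
                sprintf(", %d labelled", nrow(x$labels))))
  invisible(x)
}
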