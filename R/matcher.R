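#' Find lexicon term matches in note text
#'
#' Case-insensitive, word-boundary-anchored matching of every lexicon term
#' against `text`. Matches of one term are non-overlapping (leftmost
#' scanning); overlapping matches of different terms are all reported.
#' Offsets are 0-based, half-open, counted in Unicode code points.
#'
#' @param text A single note text (character scalar; may be empty).
#' @param lex A [lexicon()].
#' @return A tibble with columns `term_id`, `start`, `end`, `matched_text`,
#'   sorted by `start` (ties broken by lexicon term order).
#' @examples
#' find_matches("patient injects drugs daily", default_lexicon())
#' @export
find_matches <- function(text, lex) {
  stopifnot(inherits(lex, "pwud_lexicon"))
  if (length(text) != 1L || !is.character(text)) {
    stop_pwud("`text` must be a single character string")
  }
  m <- match_texts(text, lex)
  tibble::as_tibble(m[, c("term_id", "start", "end", "matched_text")])
}

# Vectorized raw matching over a character vector of texts.
# Returns a data.frame: text_idx, term_id, start, end (0-based half-open),
# matched_text, ordered by (text_idx, start, lexicon term order).
match_texts <- function(texts, lex) {
  texts <- enc2utf8(texts)
  out <- list()
  for (t in seq_len(nrow(lex$terms))) {
    rx <- term_regex(lex$terms$pattern[t])
    hits <- gregexpr(rx, texts, perl = TRUE, ignore.case = TRUE)
    for (i in seq_along(texts)) {
      st <- hits[[i]]
      if (st[1] == -1L) next
      len <- attr(st, "match.length")
      out[[length(out) + 1L]] <- data.frame(
        text_idx = i, term_rank = t,
        term_id = lex$terms$term_id[t],
        start = as.integer(st) - 1L,
        end = as.integer(st) - 1L + len,
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(text_idx = integer(), term_rank = integer(),
                      term_id = character(), start = integer(),
                      end = integer(), matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  m <- m[order(m$text_idx, m$start, m$term_rank), , drop = FALSE]
  m$matched_text <- substr(texts[m$text_idx], m$start + 1L, m$end)
  rownames(m) <- NULL
  m
}

#' Extract a review snippet around a match
#'
#' Returns the matched span plus up to `context_chars` characters of context
#' on each side, truncated at the text boundaries (no padding). Offsets are
#' 0-based, half-open, in Unicode code points.
#'
#' @param text The note text the match came from.
#' @param start,end Match offsets (0-based, half-open).
#' @param context_chars Context width on each side (default 100).
#' @return The snippet (character scalar).
#' @export
extract_snippet <- function(text, start, end, context_chars = 100L) {
  if (!is.numeric(context_chars) || context_chars < 0) {
    stop_pwud("`context_chars` must be non-negative")
  }
  n <- nchar(text)
  if (start < 0 || end > n || start >= end) {
    stop_pwud("match offsets [%d,%d) out of bounds for text of length %d",
              start, end, n)
  }
  substr(text, max(0L, start - context_chars) + 1L,
         min(n, end + context_chars))
}

# Does any cue fire in scope of the match? `cues` has pattern/window/
# direction. Scope for "before" cues is the `window` characters preceding
# the match, truncated at the last sentence boundary ([.;!?\n]); "after"
# cues mirror this. Vectorized over parallel vectors (texts, start, end).
cue_in_scope <- function(texts, start, end, cues) {
  hit <- rep(FALSE, length(texts))
  if (nrow(cues) == 0L || length(texts) == 0L) return(hit)
  for (k in seq_len(nrow(cues))) {
    w <- as.integer(cues$window[k])
    rx <- cue_regex(cues$pattern[k])
    if (cues$direction[k] == "before") {
      ctx <- substr(texts, pmax(0L, start - w) + 1L, start)
      ctx <- sub(".*[.;!?\n]", "", ctx)
    } else {
      ctx <- substr(texts, end + 1L, end + w)
      ctx <- sub("[.;!?\n].*", "", ctx)
    }
    hit <- hit | grepl(rx, ctx, perl = TRUE, ignore.case = TRUE)
  }
  hit
}

# False-trigger rules are term-specific adjacency patterns (not sentence
# truncated: "adjacent text" within the rule window).
false_trigger_hits <- function(texts, start, end, term_id, rules) {
  hit <- rep(FALSE, length(texts))
  if (nrow(rules) == 0L || length(texts) == 0L) return(hit)
  for (k in seq_len(nrow(rules))) {
    sel <- term_id == rules$term_id[k]
    if (!any(sel)) next
    w <- as.integer(rules$window[k])
    rx <- cue_regex(rules$pattern[k])
    if (rules$direction[k] == "after") {
      ctx <- substr(texts[sel], end[sel] + 1L, end[sel] + w)
    } else {
      ctx <- substr(texts[sel], pmax(0L, start[sel] - w) + 1L, start[sel])
    }
    hit[sel] <- hit[sel] | grepl(rx, ctx, perl = TRUE, ignore.case = TRUE)
  }
  hit
}

# Vectorized assertion over a raw-match table from match_texts().
assert_texts <- function(texts, m, lex, system = "regex",
                         context_chars = 100L) {
  tx <- texts[m$text_idx]
  m$negated <- cue_in_scope(tx, m$start, m$end, lex$negation_cues)
  m$historical <- if (identical(system, "context")) {
    cue_in_scope(tx, m$start, m$end, lex$history_cues)
  } else {
    rep(FALSE, nrow(m))
  }
  m$false_trigger <- false_trigger_hits(tx, m$start, m$end, m$term_id,
                                        lex$false_triggers)
  m$is_true_hit <- !m$negated & !m$false_trigger
  m$snippet <- substr(tx, pmax(0L, m$start - context_chars) + 1L,
                      pmin(nchar(tx), m$end + context_chars))
  m
}

#' Attach assertion attributes to a raw match
#'
#' Determines whether a match is negated (a negation cue within the cue's
#' scope window, not crossing a sentence boundary), a false trigger (a
#' term-specific adjacency rule fires, e.g. "gtt" just after a drug name),
#' or historical (history cue in scope; computed by the ConText-style
#' `"context"` system only). A match is a *true hit* iff it is neither
#' negated nor a false trigger.
#'
#' @param text The note text the match came from.
#' @param match One row of [find_matches()] output (or a list with
#'   `term_id`, `start`, `end`).
#' @param lex The same [lexicon()] used for matching.
#' @param system `"regex"` or `"context"`.
#' @param context_chars Snippet context width (default 100).
#' @return A one-row tibble: `term_id`, `start`, `end`, `matched_text`,
#'   `negated`, `historical`, `false_trigger`, `is_true_hit`, `snippet`.
#' @examples
#' lex <- default_lexicon()
#' m <- find_matches("no IVDU", lex)
#' assert_match("no IVDU", m[1, ], lex)
#' @export
assert_match <- function(text, match, lex, system = c("regex", "context"),
                         context_chars = 100L) {
  system <- match.arg(system)
  start <- as.integer(match$start)
  end <- as.integer(match$end)
  if (is.na(start) || is.na(end) || start < 0 || end > nchar(text) ||
      start >= end) {
    stop_pwud("match offsets [%s,%s) out of bounds for text of length %d",
              start, end, nchar(text))
  }
  m <- data.frame(text_idx = 1L, term_rank = NA_integer_,
                  term_id = as.character(match$term_id),
                  start = start, end = end,
                  matched_text = substr(text, start + 1L, end),
                  stringsAsFactors = FALSE)
  out <- assert_texts(enc2utf8(text), m, lex, system = system,
                      context_chars = context_chars)
  tibble::as_tibble(out[, c("term_id", "start", "end", "matched_text",
                            "negated", "historical", "false_trigger",
                            "is_true_hit", "snippet")])
}

#' Classify a single note
#'
#' Runs matching and assertion on one note and reduces to the note-level
#' flag: a note is flagged iff it contains at least one true hit (positive
#' hits minus negated and false-trigger hits). Historical-only hits still
#' count as true hits by default (the history attribute is carried through
#' as a separate output of the `"context"` system); set
#' `count_historical = FALSE` to exclude them.
#'
#' @param note A list or one-row data frame with `note_id` and `text`.
#' @param lex A [lexicon()].
#' @param system `"regex"` or `"context"`.
#' @param count_historical Count historical-only hits as true (default TRUE).
#' @return A one-row tibble: `note_id`, `system`, `n_matches_total`,
#'   `n_matches_true`, `flagged`.
#' @export
classify_note <- function(note, lex, system = c("regex", "context"),
                          count_historical = TRUE) {
  system <- match.arg(system)
  text <- as.character(note$text)
  m <- match_texts(text, lex)
  a <- assert_texts(enc2utf8(text), m, lex, system = system)
  true_hits <- a$is_true_hit
  if (!count_historical) true_hits <- true_hits & !a$historical
  tibble::tibble(note_id = as.character(note$note_id), system = system,
                 n_matches_total = nrow(a),
                 n_matches_true = sum(true_hits),
                 flagged = sum(true_hits) >= 1L)
}

#' Annotate a notes table with asserted matches
#'
#' Corpus-scale equivalent of [find_matches()] + [assert_match()]: returns
#' one row per match across all notes, with assertion attributes and
#' 100-character review snippets.
#'
#' @param notes Tibble from [read_notes()] (columns `note_id`,
#'   `encounter_id`, `text`).
#' @param lex A [lexicon()].
#' @param system `"regex"` or `"context"`.
#' @param context_chars Snippet context width (default 100).
#' @return A tibble: `note_id`, `encounter_id`, `system`, `term_id`,
#'   `start`, `end`, `matched_text`, `negated`, `historical`,
#'   `false_trigger`, `is_true_hit`, `snippet`.
#' @export
annotate_notes <- function(notes, lex, system = c("regex", "context"),
                           context_chars = 100L) {
  system <- match.arg(system)
  m <- match_texts(notes$text, lex)
  a <- assert_texts(enc2utf8(notes$text), m, lex, system = system,
                    context_chars = context_chars)
  tibble::tibble(note_id = notes$note_id[a$text_idx],
                 encounter_id = notes$encounter_id[a$text_idx],
                 system = system,
                 term_id = a$term_id, start = a$start, end = a$end,
                 matched_text = a$matched_text, negated = a$negated,
                 historical = a$historical, false_trigger = a$false_trigger,
                 is_true_hit = a$is_true_hit, snippet = a$snippet)
}

# Per-note flag table for a whole notes table (vectorized classify_note).
classify_notes <- function(notes, lex, system = "regex",
                           count_historical = TRUE) {
  m <- match_texts(notes$text, lex)
  a <- assert_texts(enc2utf8(notes$text), m, lex, system = system)
  true_hits <- a$is_true_hit
  if (!count_historical) true_hits <- true_hits & !a$historical
  n_total <- tabulate(a$text_idx, nbins = nrow(notes))
  n_true <- tabulate(a$text_idx[true_hits], nbins = nrow(notes))
  tibble::tibble(note_id = notes$note_id, system = system,
                 n_matches_total = n_total, n_matches_true = n_true,
                 flagged = n_true >= 1L)
}
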