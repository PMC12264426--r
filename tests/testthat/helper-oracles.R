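# Independent oracles and fixture builders used across the suite.

# Brute-force sliding-window scan for a literal phrase pattern.
# Case-insensitive, word-boundary semantics, internal whitespace in the
# pattern matches one-or-more whitespace/hyphen characters, matches of one
# pattern do not overlap (scan resumes past each accepted match).
# Returns a data.frame with 0-based half-open offsets. Written as a
# character-by-character scan, independent of any regex machinery.
brute_find <- function(text, pattern) {
  chars <- strsplit(tolower(text), "")[[1]]
  n <- length(chars)
  toks <- strsplit(tolower(pattern), "[ \t\n]+")[[1]]
  is_word <- function(ch) length(ch) == 1 && grepl("[a-z0-9_]", ch)
  sep_chars <- c(" ", "\t", "\n", "\r", "-")
  starts <- integer(0); ends <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i; ok <- TRUE
    for (t in seq_along(toks)) {
      tok <- strsplit(toks[t], "")[[1]]
      if (j + length(tok) - 1 > n ||
          !identical(chars[j:(j + length(tok) - 1)], tok)) {
        ok <- FALSE; break
      }
      j <- j + length(tok)
      if (t < length(toks)) {
        k0 <- j
        while (j <= n && chars[j] %in% sep_chars) j <- j + 1
        if (j == k0) { ok <- FALSE; break }
      }
    }
    if (ok) {
      pre_ok <- i == 1 || !is_word(chars[i - 1])
      post_ok <- j > n || !is_word(chars[j])
      if (pre_ok && post_ok) {
        starts <- c(starts, i - 1)
        ends <- c(ends, j - 1)
        i <- j
        next
      }
    }
    i <- i + 1
  }
  data.frame(start = starts, end = ends)
}

# Random boolean encounter-signal table with the nesting constraint
# (ge50 => ge25 => ge10 => any) built in, plus a gold vector with at least
# one event and one nonevent.
random_toy_cohort <- function(n = 30) {
  frac <- ifelse(runif(n) < 0.3, 0, runif(n))
  sig <- tibble::tibble(
    encounter_id = sprintf("E%03d", seq_len(n)),
    n_notes = rep(10L, n),
    fraction_regex = frac,
    regex_any = frac > 0,
    regex_ge10 = frac >= 0.10,
    regex_ge25 = frac >= 0.25,
    regex_ge50 = frac >= 0.50,
    context_any = runif(n) < 0.4,
    icd_visit = runif(n) < 0.3,
    icd_history = NA
  )
  sig$icd_history <- sig$icd_visit | (runif(n) < 0.15)
  gold <- runif(n) < 0.4
  gold[1] <- TRUE; gold[2] <- FALSE
  names(gold) <- sig$encounter_id
  list(signals = sig, gold = gold)
}

# Per-subject recount of a confusion matrix (independent of confusion()).
brute_confusion <- function(pred, gold) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (id in names(pred)) {
    if (pred[[id]] && gold[[id]]) tp <- tp + 1
    else if (pred[[id]] && !gold[[id]]) fp <- fp + 1
    else if (!pred[[id]] && gold[[id]]) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Shared small lexicon for matcher tests: literal phrases only.
toy_lexicon <- function() {
  lexicon(
    terms = data.frame(
      term_id = c("injects_drugs", "ivdu", "heroin", "fentanyl"),
      pattern = c("injects drugs", "IVDU", "heroin", "fentanyl"),
      category = c("action", "person", "drug", "drug")),
    negation_cues = data.frame(pattern = c("no", "denies"),
                               window = 30L, direction = "before"),
    false_triggers = data.frame(term_id = "fentanyl", pattern = "gtt",
                                window = 15L, direction = "after"),
    history_cues = data.frame(pattern = "history of", window = 30L,
                              direction = "before"))
}
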