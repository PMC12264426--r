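lex <- toy_lexicon()

test_that("find_matches reports word-bounded, case-insensitive offsets", {
  m <- find_matches("patient injects drugs daily", lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 8L)
  expect_equal(m$end, 21L)
  expect_equal(m$matched_text, "injects drugs")

  # raw matching reports the hit; exclusion happens at assertion time
  m2 <- find_matches("fentanyl gtt started", lex)
  expect_equal(m2$term_id, "fentanyl")

  expect_equal(nrow(find_matches("", lex)), 0L)
  # word boundaries: no match inside a longer token
  expect_equal(nrow(find_matches("heroine is a noun", lex)), 0L)
  # hyphen/whitespace variants collapse to the same phrase pattern
  expect_equal(nrow(find_matches("injects-drugs", lex)), 1L)
  expect_equal(nrow(find_matches("INJECTS   DRUGS", lex)), 1L)
})

test_that("matcher agrees with the brute-force substring oracle", {
  vocab <- c("patient", "injects", "drugs", "IVDU", "heroin", "fentanyl",
             "stable", "plan", "no", "gtt", "daily", "the", "history")
  seps <- c(" ", " ", " ", "-", ". ", "\n")
  set.seed(42)
  for (rep in 1:50) {
    words <- sample(vocab, sample(3:12, 1), replace = TRUE)
    text <- paste0(paste(words, collapse = sample(seps, 1)), ".")
    got <- find_matches(text, lex)
    for (t in seq_len(nrow(lex$terms))) {
      want <- brute_find(text, lex$terms$pattern[t])
      have <- got[got$term_id == lex$terms$term_id[t], , drop = FALSE]
      expect_equal(have$start, want$start, info = text)
      expect_equal(have$end, want$end, info = text)
    }
  }
})

test_that("matching is deterministic and monotone in the lexicon", {
  text <- "IVDU; injects drugs. no heroin-fentanyl gtt"
  expect_identical(find_matches(text, lex), find_matches(text, lex))
  bigger <- lexicon(
    terms = rbind(lex$terms,
                  data.frame(term_id = "cocaine", pattern = "cocaine",
                             category = "drug")),
    negation_cues = lex$negation_cues,
    false_triggers = lex$false_triggers,
    history_cues = lex$history_cues)
  set.seed(7)
  for (rep in 1:20) {
    txt <- paste(sample(c("IVDU", "heroin", "cocaine", "word", "no"),
                        sample(2:8, 1), replace = TRUE), collapse = " ")
    expect_gte(nrow(find_matches(txt, bigger)), nrow(find_matches(txt, lex)))
  }
})

test_that("negation assertion respects cue scope and sentence boundaries", {
  m <- find_matches("no IVDU", lex)
  a <- assert_match("no IVDU", m[1, ], lex)
  expect_true(a$negated)
  expect_false(a$is_true_hit)

  # cue in a previous sentence does not negate
  txt <- "no history today. IVDU reported"
  a2 <- assert_match(txt, find_matches(txt, lex)[1, ], lex)
  expect_false(a2$negated)

  # cue beyond the 30-character window does not negate
  txt3 <- paste0("no ", strrep("x", 35), " IVDU")
  a3 <- assert_match(txt3, find_matches(txt3, lex)[1, ], lex)
  expect_false(a3$negated)

  # plain hit with no cue in scope
  a4 <- assert_match("injects drugs", find_matches("injects drugs", lex)[1, ],
                     lex)
  expect_false(a4$negated)
  expect_true(a4$is_true_hit)
})

test_that("false-trigger rules exclude adjacent administration vocabulary", {
  m <- find_matches("fentanyl gtt", lex)
  a <- assert_match("fentanyl gtt", m[1, ], lex)
  expect_true(a$false_trigger)
  expect_false(a$is_true_hit)
  # the rule is term-specific: heroin has no gtt rule
  b <- assert_match("heroin gtt", find_matches("heroin gtt", lex)[1, ], lex)
  expect_false(b$false_trigger)
  # and distance-bounded
  txt <- paste0("fentanyl ", strrep("y", 20), " gtt")
  c1 <- assert_match(txt, find_matches(txt, lex)[1, ], lex)
  expect_false(c1$false_trigger)
})

test_that("history cues mark matches for the context system only", {
  txt <- "history of IVDU"
  m <- find_matches(txt, lex)
  rx <- assert_match(txt, m[1, ], lex, system = "regex")
  cx <- assert_match(txt, m[1, ], lex, system = "context")
  expect_false(rx$historical)
  expect_true(cx$historical)
  expect_true(cx$is_true_hit)  # history does not cancel a hit
  fl <- classify_note(list(note_id = "n", text = txt), lex,
                      system = "context", count_historical = FALSE)
  expect_false(fl$flagged)
})

test_that("assert_match rejects out-of-bounds offsets", {
  expect_error(assert_match("abc", list(term_id = "x", start = 1, end = 9),
                            lex), "out of bounds")
})

test_that("snippets carry at most 100 characters of context each side", {
  left <- strrep("a", 150)
  right <- strrep("b", 150)
  text <- paste0(left, " heroin ", right)
  m <- find_matches(text, lex)
  sn <- extract_snippet(text, m$start[1], m$end[1])
  expect_equal(nchar(sn), 100 + 6 + 100)
  expect_equal(sn, substr(text, m$start[1] + 1 - 100, m$end[1] + 100))
  expect_equal(sn, paste0(strrep("a", 99), " heroin ", strrep("b", 99)))

  # truncation at text boundaries, no padding
  text2 <- paste0("heroin ", right)
  m2 <- find_matches(text2, lex)
  expect_equal(extract_snippet(text2, m2$start[1], m2$end[1]),
               paste0("heroin ", strrep("b", 99)))
  expect_equal(extract_snippet("see heroin", 4, 10), "see heroin")
  expect_error(extract_snippet("see heroin", 4, 10, context_chars = -1),
               "non-negative")
})

test_that("note classification subtracts negated and false-trigger hits", {
  fl <- classify_note(
    list(note_id = "n1", text = "pt injects drugs; no IVDU per partner"),
    lex)
  expect_equal(fl$n_matches_total, 2L)
  expect_equal(fl$n_matches_true, 1L)
  expect_true(fl$flagged)

  fl2 <- classify_note(list(note_id = "n2", text = "no IVDU"), lex)
  expect_equal(fl2$n_matches_total, 1L)
  expect_equal(fl2$n_matches_true, 0L)
  expect_false(fl2$flagged)

  fl3 <- classify_note(list(note_id = "n3", text = ""), lex)
  expect_equal(fl3$n_matches_total, 0L)
  expect_false(fl3$flagged)
})

test_that("negation flip: prepending a cue to a true hit unflags the note", {
  set.seed(11)
  phrases <- c("IVDU", "heroin", "injects drugs", "fentanyl")
  for (p in phrases) {
    base <- classify_note(list(note_id = "n", text = p), lex)
    expect_true(base$flagged)
    flipped <- classify_note(list(note_id = "n", text = paste("no", p)), lex)
    expect_false(flipped$flagged)
  }
})

test_that("annotate_notes matches per-note classification", {
  notes <- tibble::tibble(
    note_id = c("N1", "N2"), encounter_id = c("E1", "E1"),
    note_type = "hpi",
    text = c("uses heroin daily. no IVDU.", "fentanyl gtt running"))
  ann <- annotate_notes(notes, lex)
  expect_equal(nrow(ann), 3L)
  expect_equal(sum(ann$is_true_hit), 1L)
  expect_true(all(mapply(grepl, ann$matched_text, ann$snippet,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("lexicon YAML round trip preserves matching behaviour", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  txt <- "no IVDU; injects drugs; fentanyl gtt"
  expect_equal(as.data.frame(find_matches(txt, lex2)),
               as.data.frame(find_matches(txt, lex)))
  fl1 <- classify_note(list(note_id = "n", text = txt), lex)
  fl2 <- classify_note(list(note_id = "n", text = txt), lex2)
  expect_equal(fl1$n_matches_true, fl2$n_matches_true)
})

test_that("lexicon validation catches inconsistent rules", {
  expect_error(
    lexicon(terms = data.frame(term_id = "a", pattern = "abc",
                               category = "drug"),
            negation_cues = data.frame(pattern = "no"),
            false_triggers = data.frame(term_id = "zzz", pattern = "gtt",
                                        window = 15, direction = "after"),
            history_cues = data.frame()),
    "unknown term")
  expect_error(
    lexicon(terms = data.frame(term_id = "a", pattern = "abc",
                               category = "narcotic"),
            negation_cues = data.frame(), false_triggers = data.frame(),
            history_cues = data.frame()),
    "category")
})
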