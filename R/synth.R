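#' Configuration for the synthetic corpus generator
#'
#' Specifies the full statistical structure of a synthetic encounter
#' corpus: cohort size and PWUD prevalence, the notes-per-encounter
#' distribution, the note-type mix, per-note phrase-injection rates, and
#' the accuracy of ICD-10 code assignment against the true label.
#'
#' The defaults are a stylized emulation of the chart-review cohort shape:
#' 790 encounters, prevalence 0.067, a median of 3 notes per encounter
#' (Poisson mean 3, minimum 1), visit-code assignment with sensitivity
#' 0.434 and specificity 0.995, and a per-note mention probability of 0.30
#' (which puts the closed-form encounter-level text sensitivity near 0.61).
#'
#' @param n_encounters Number of encounters (>= 1).
#' @param prevalence Probability an encounter is truly PWUD.
#' @param notes_per_encounter List: `list(dist = "poisson", lambda, min)`
#'   or `list(dist = "fixed", k)`.
#' @param note_type_mix Named probability vector over
#'   `emergency`, `hpi`, `discharge`, `other` (sums to 1).
#' @param p_mention Per-note probability that a PWUD encounter's note
#'   contains a true drug-use phrase.
#' @param p_negated_mention Per-note probability (any encounter) of a
#'   negated phrase ("no IVDU"-style).
#' @param p_false_trigger Per-note probability (any encounter) of a
#'   clinical false trigger ("fentanyl gtt"-style).
#' @param icd_sensitivity Probability a PWUD encounter receives a drug-use
#'   visit code.
#' @param icd_specificity Probability a non-PWUD encounter receives no
#'   drug-use visit code.
#' @param history_extra_rate Probability an extra non-visit history code is
#'   added (a drug-use code for PWUD encounters, a neutral chronic-disease
#'   code otherwise), so history flags fire at least as often as visit
#'   flags.
#' @param seed Integer seed driving all sampling.
#' @return A validated list of class `pwud_genconfig`.
#' @export
generator_config <- function(n_encounters = 790,
                             prevalence = 0.067,
                             notes_per_encounter = list(dist = "poisson",
                                                        lambda = 3, min = 1),
                             note_type_mix = c(emergency = 0.20, hpi = 0.25,
                                               discharge = 0.20,
                                               other = 0.35),
                             p_mention = 0.30,
                             p_negated_mention = 0.10,
                             p_false_trigger = 0.05,
                             icd_sensitivity = 0.434,
                             icd_specificity = 0.995,
                             history_extra_rate = 0.15,
                             seed = 1L) {
  if (!is_count(n_encounters) || n_encounters < 1) {
    stop_pwud("`n_encounters` must be a positive integer")
  }
  for (p in c("prevalence", "p_mention", "p_negated_mention",
              "p_false_trigger", "icd_sensitivity", "icd_specificity",
              "history_extra_rate")) {
    if (!is_prob(get(p))) stop_pwud("`%s` must be a probability", p)
  }
  if (!setequal(names(note_type_mix), NOTE_TYPES)) {
    stop_pwud("`note_type_mix` must be named over: %s",
              paste(NOTE_TYPES, collapse = ", "))
  }
  if (abs(sum(note_type_mix) - 1) > 1e-8 || any(note_type_mix < 0)) {
    stop_pwud("`note_type_mix` must be non-negative and sum to 1")
  }
  if (!is.list(notes_per_encounter) ||
      !notes_per_encounter$dist %in% c("poisson", "fixed")) {
    stop_pwud("`notes_per_encounter$dist` must be \"poisson\" or \"fixed\"")
  }
  if (notes_per_encounter$dist == "poisson") {
    if (is.null(notes_per_encounter$min)) notes_per_encounter$min <- 1L
    if (!is.numeric(notes_per_encounter$lambda) ||
        notes_per_encounter$lambda <= 0) {
      stop_pwud("poisson `lambda` must be positive")
    }
  } else if (!is_count(notes_per_encounter$k) || notes_per_encounter$k < 0) {
    stop_pwud("fixed `k` must be a non-negative integer")
  }
  if (!is_count(abs(seed))) stop_pwud("`seed` must be an integer")
  structure(list(n_encounters = as.integer(n_encounters),
                 prevalence = prevalence,
                 notes_per_encounter = notes_per_encounter,
                 note_type_mix = note_type_mix[NOTE_TYPES],
                 p_mention = p_mention,
                 p_negated_mention = p_negated_mention,
                 p_false_trigger = p_false_trigger,
                 icd_sensitivity = icd_sensitivity,
                 icd_specificity = icd_specificity,
                 history_extra_rate = history_extra_rate,
                 seed = as.integer(seed)),
            class = "pwud_genconfig")
}

#' Read a generator configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [generator_config()]
#'   arguments.
#' @return A `pwud_genconfig`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$note_type_mix)) y$note_type_mix <- unlist(y$note_type_mix)
  do.call(generator_config, y)
}

# Code pools used by the generator. Drug codes all fall under
# default_code_list() prefixes; neutral codes never do (validated in tests).
DRUG_CODES <- c("F1120", "F1410", "F1520", "F1220", "F1920", "F1320",
                "T40601A", "T40411A")
NEUTRAL_CODES <- c("I10", "E119", "N179", "J189", "K219", "Z23", "M545",
                   "E785", "D649", "I4891")

#' Default phrase bank for note synthesis
#'
#' Sentence templates instantiated with lexicon terms: positive mentions
#' ("Patient reports use of {term} at home."), negated mentions
#' ("Denies {term}."), false triggers ("{term} gtt titrated overnight.",
#' drug-category terms only), and neutral clinical filler sentences that
#' match no lexicon term. The bank is validated against the lexicon at
#' build time: every positive template must produce a true hit, negated
#' templates a negated hit, false-trigger templates an excluded hit, and
#' fillers no match at all.
#'
#' @param lex Lexicon to validate against (default [default_lexicon()]).
#' @return A list of class `pwud_phrasebank`.
#' @export
default_phrase_bank <- function(lex = default_lexicon()) {
  bank <- structure(list(
    positive_templates = c(
      "Patient reports use of {term} at home.",
      "Social work consulted regarding {term}.",
      "Patient admits to {term} this week.",
      "Documented {term} in social context."
    ),
    negated_templates = c(
      "Denies {term}.",
      "No {term} reported by patient.",
      "Negative for {term} on screening."
    ),
    false_trigger_templates = c(
      "{term} gtt titrated overnight.",
      "Continued {term} drip for sedation.",
      "{term} patch applied to upper arm."
    ),
    filler_sentences = c(
      "Vital signs stable overnight.",
      "Patient resting comfortably this morning.",
      "Plan to continue current antibiotics.",
      "Follow up with primary care after discharge.",
      "Chest radiograph shows clear lung fields.",
      "Diet advanced as tolerated without issue.",
      "Ambulating in hallway with physical therapy.",
      "Electrolytes repleted per protocol."
    )), class = "pwud_phrasebank")
  validate_phrase_bank(bank, lex)
  bank
}

#' Validate a phrase bank against a lexicon
#'
#' Checks the bank invariants: every positive template instantiation yields
#' at least one true hit, negated instantiations yield matches but no true
#' hit, false-trigger instantiations are excluded by a false-trigger rule,
#' and filler sentences match no term at all.
#'
#' @param bank A phrase bank (see [default_phrase_bank()]).
#' @param lex The lexicon the bank will be used with.
#' @return `TRUE` invisibly; errors describe the offending entry.
#' @export
validate_phrase_bank <- function(bank, lex) {
  ft_terms <- ft_capable_terms(lex)
  for (tpl in bank$positive_templates) {
    for (i in seq_len(nrow(lex$terms))) {
      txt <- sub("{term}", lex$terms$pattern[i], tpl, fixed = TRUE)
      fl <- classify_note(list(note_id = "x", text = txt), lex)
      if (!fl$flagged) {
        stop_pwud("positive template \"%s\" fails to flag term %s", tpl,
                  lex$terms$term_id[i])
      }
    }
  }
  for (tpl in bank$negated_templates) {
    for (i in seq_len(nrow(lex$terms))) {
      txt <- sub("{term}", lex$terms$pattern[i], tpl, fixed = TRUE)
      fl <- classify_note(list(note_id = "x", text = txt), lex)
      if (fl$n_matches_total < 1L || fl$flagged) {
        stop_pwud("negated template \"%s\" not negated for term %s", tpl,
                  lex$terms$term_id[i])
      }
    }
  }
  if (length(ft_terms)) {
    for (tpl in bank$false_trigger_templates) {
      for (tid in ft_terms) {
        pat <- lex$terms$pattern[lex$terms$term_id == tid]
        txt <- sub("{term}", pat, tpl, fixed = TRUE)
        fl <- classify_note(list(note_id = "x", text = txt), lex)
        if (fl$n_matches_total < 1L || fl$flagged) {
          stop_pwud("false-trigger template \"%s\" not excluded for term %s",
                    tpl, tid)
        }
      }
    }
  }
  for (s in bank$filler_sentences) {
    if (nrow(find_matches(s, lex)) > 0L) {
      stop_pwud("filler sentence matches a lexicon term: \"%s\"", s)
    }
  }
  invisible(TRUE)
}

# Terms for which at least one false-trigger rule exists and every
# false-trigger template pattern applies (the default bank pairs drug terms
# with administration vocabulary).
ft_capable_terms <- function(lex) {
  intersect(lex$terms$term_id[lex$terms$category == "drug"],
            unique(lex$false_triggers$term_id))
}

# Compose a note text from independent injection events. Each injected
# phrase occupies its own sentence; fillers surround them so phrases sit
# away from text boundaries often enough to exercise snippet truncation
# both ways.
compose_note_text <- function(mention, negated, false_trigger, bank, lex) {
  sentences <- sample(bank$filler_sentences,
                      size = sample(2:4, 1), replace = TRUE)
  inject <- character(0)
  if (mention) {
    tpl <- sample(bank$positive_templates, 1)
    term <- sample(lex$terms$pattern, 1)
    inject <- c(inject, sub("{term}", term, tpl, fixed = TRUE))
  }
  if (negated) {
    tpl <- sample(bank$negated_templates, 1)
    term <- sample(lex$terms$pattern, 1)
    inject <- c(inject, sub("{term}", term, tpl, fixed = TRUE))
  }
  if (false_trigger) {
    ft_terms <- ft_capable_terms(lex)
    if (length(ft_terms)) {
      tpl <- sample(bank$false_trigger_templates, 1)
      tid <- sample(ft_terms, 1)
      pat <- lex$terms$pattern[lex$terms$term_id == tid]
      inject <- c(inject, sub("{term}", pat, tpl, fixed = TRUE))
    }
  }
  all_s <- c(sentences, inject)
  paste(all_s[sample.int(length(all_s))], collapse = " ")
}

#' Generate a single synthetic note
#'
#' @param role One of `"pwud_mention"` (contains at least one true
#'   drug-use phrase), `"negated_only"` (a negated phrase, no true hit),
#'   `"false_trigger_only"` (an excluded clinical false trigger), or
#'   `"neutral"` (matches no lexicon term).
#' @param note_type One of `emergency`, `hpi`, `discharge`, `other`.
#' @param bank Phrase bank (default [default_phrase_bank()] over `lex`).
#' @param lex Lexicon (default [default_lexicon()]).
#' @param note_id,encounter_id Identifiers for the emitted note.
#' @return A one-row tibble in [read_notes()] layout.
#' @export
generate_note <- function(role = c("neutral", "pwud_mention", "negated_only",
                                   "false_trigger_only"),
                          note_type = "other", lex = default_lexicon(),
                          bank = default_phrase_bank(lex),
                          note_id = "N1", encounter_id = "E1") {
  role <- match.arg(role)
  text <- compose_note_text(mention = role == "pwud_mention",
                            negated = role == "negated_only",
                            false_trigger = role == "false_trigger_only",
                            bank, lex)
  tibble::tibble(note_id = note_id, encounter_id = encounter_id,
                 note_type = note_type, text = text)
}

#' Generate a synthetic encounter corpus with known ground truth
#'
#' Samples a cohort under a [generator_config()]: true PWUD status per
#' encounter, notes with independently injected positive/negated/
#' false-trigger phrases, and ICD-10 visit and history codes assigned with
#' the configured sensitivity and specificity. All sampling is driven by
#' `config$seed`, so identical configurations reproduce identical corpora.
#'
#' The truth sidecar is for validation only; no pipeline stage reads it.
#'
#' @param config A [generator_config()].
#' @param lex Lexicon (default [default_lexicon()]).
#' @param bank Phrase bank (default [default_phrase_bank()] over `lex`).
#' @return A list of class `pwud_syncorpus`: `corpus` (a `pwud_corpus`
#'   with labels attached), `truth` (per-note event tibble with the true
#'   label and code-assignment indicators), and `config`.
#' @export
generate_corpus <- function(config = generator_config(),
                            lex = default_lexicon(),
                            bank = default_phrase_bank(lex)) {
  stopifnot(inherits(config, "pwud_genconfig"))
  set.seed(config$seed)
  n <- config$n_encounters
  enc_ids <- sprintf("E%05d", seq_len(n))
  pwud <- runif(n) < config$prevalence
  npe <- config$notes_per_encounter
  k <- if (npe$dist == "fixed") rep(npe$k, n) else
    pmax(npe$min, rpois(n, npe$lambda))

  visit_drug <- ifelse(pwud, runif(n) < config$icd_sensitivity,
                       runif(n) > config$icd_specificity)
  hist_extra <- runif(n) < config$history_extra_rate

  visit_codes <- vector("list", n)
  history_codes <- vector("list", n)
  for (i in seq_len(n)) {
    vc <- sample(NEUTRAL_CODES, sample(1:4, 1))
    if (visit_drug[i]) vc <- c(sample(DRUG_CODES, 1), vc)
    vc <- head(vc, 5L)
    hc <- c(vc, sample(NEUTRAL_CODES, sample(0:3, 1)))
    if (hist_extra[i]) {
      hc <- c(hc, if (pwud[i]) sample(DRUG_CODES, 1) else
        sample(NEUTRAL_CODES, 1))
    }
    visit_codes[[i]] <- vc
    history_codes[[i]] <- unique(hc)
  }

  note_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  note_counter <- 0L
  for (i in seq_len(n)) {
    if (k[i] == 0L) next  # preallocated slots stay NULL
    types <- sample(NOTE_TYPES, k[i], replace = TRUE,
                    prob = config$note_type_mix)
    mention <- pwud[i] & runif(k[i]) < config$p_mention
    negated <- runif(k[i]) < config$p_negated_mention
    ftrig <- runif(k[i]) < config$p_false_trigger
    texts <- character(k[i])
    for (j in seq_len(k[i])) {
      texts[j] <- compose_note_text(mention[j], negated[j], ftrig[j],
                                    bank, lex)
    }
    ids <- sprintf("N%07d", note_counter + seq_len(k[i]))
    note_counter <- note_counter + k[i]
    note_rows[[i]] <- tibble::tibble(note_id = ids, encounter_id = enc_ids[i],
                                     note_type = types, text = texts)
    truth_rows[[i]] <- tibble::tibble(
      encounter_id = enc_ids[i], note_id = ids,
      true_label = if (pwud[i]) "pwud" else "not_pwud",
      mention = mention, negated_phrase = negated, false_trigger = ftrig,
      icd_visit_drug = visit_drug[i],
      icd_history_drug = visit_drug[i] |
        (hist_extra[i] & pwud[i]))
  }
  notes <- do.call(rbind, note_rows[!vapply(note_rows, is.null, TRUE)])
  if (is.null(notes)) {
    notes <- tibble::tibble(note_id = character(), encounter_id = character(),
                            note_type = character(), text = character())
  }
  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, TRUE)])
  codes <- tibble::tibble(encounter_id = enc_ids, visit_codes = visit_codes,
                          history_codes = history_codes)
  labels <- tibble::tibble(encounter_id = enc_ids,
                           label = ifelse(pwud, "pwud", "not_pwud"))
  corpus <- suppressWarnings(assemble_corpus(notes, codes, labels))
  structure(list(corpus = corpus, truth = truth, config = config),
            class = "pwud_syncorpus")
}

#' @export
print.pwud_syncorpus <- function(x, ...) {
  cat(sprintf("<pwud_syncorpus> %d encounters (%d PWUD), %d notes, seed %d\n",
              length(x$corpus$encounter_ids),
              sum(x$corpus$labels$label == "pwud"), nrow(x$corpus$notes),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits `notes.jsonl`, `codes.csv`, `labels.csv` in the package's input
#' formats, plus `truth.csv` (the validation sidecar, never read by the
#' pipeline).
#'
#' @param syn A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(syn, dir) {
  stopifnot(inherits(syn, "pwud_syncorpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_notes(syn$corpus$notes, file.path(dir, "notes.jsonl"))
  codes <- syn$corpus$codes
  long <- do.call(rbind, lapply(seq_len(nrow(codes)), function(i) {
    rbind(
      if (length(codes$visit_codes[[i]])) {
        data.frame(encounter_id = codes$encounter_id[i],
                   code = codes$visit_codes[[i]], scope = "visit")
      },
      if (length(codes$history_codes[[i]])) {
        data.frame(encounter_id = codes$encounter_id[i],
                   code = codes$history_codes[[i]], scope = "history")
      })
  }))
  write.csv(long, file.path(dir, "codes.csv"), row.names = FALSE)
  write.csv(as.data.frame(syn$corpus$labels), file.path(dir, "labels.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(syn$truth), file.path(dir, "truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Closed-form expected encounter-level text sensitivity
#'
#' Probability that a PWUD encounter has at least one flagged note under a
#' generator configuration: `1 - E[(1 - p_mention)^K]` with `K` the number
#' of notes. Available for the fixed distribution
#' (`1 - (1 - p)^k`) and the Poisson distribution with minimum 0 or 1
#' (for minimum 1, `E[q^K] = exp(-lambda) * (q - 1 + exp(lambda * q))`).
#'
#' @param config A [generator_config()].
#' @return Expected sensitivity of the `regex_any` encounter flag.
#' @export
expected_encounter_sensitivity <- function(config) {
  stopifnot(inherits(config, "pwud_genconfig"))
  p <- config$p_mention
  q <- 1 - p
  npe <- config$notes_per_encounter
  if (npe$dist == "fixed") {
    return(1 - q^npe$k)
  }
  lam <- npe$lambda
  if (npe$min == 0L) {
    1 - exp(-lam * (1 - q))
  } else if (npe$min == 1L) {
    1 - exp(-lam) * (q - 1 + exp(lam * q))
  } else {
    stop_pwud("unsupported notes-per-encounter minimum: %d", npe$min)
  }
}
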