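#' Construct a PWUD lexicon
#'
#' A lexicon bundles the term patterns to search for, the negation cues that
#' convert a hit into a negated (non-true) hit, false-trigger rules that
#' exclude clinically irrelevant matches (a drug name adjacent to
#' infusion/administration vocabulary such as "gtt"), and history cues used
#' by the ConText-style annotator.
#'
#' Term patterns are matched case-insensitively on word boundaries; internal
#' whitespace in a pattern matches any run of whitespace or hyphens, so
#' `"intravenous drug user"` also matches `"intravenous-drug user"`.
#'
#' @param terms Data frame with columns `term_id`, `pattern`, `category`
#'   (one of `"action"`, `"person"`, `"drug"`).
#' @param negation_cues Data frame with columns `pattern`, `window`
#'   (characters), `direction` (`"before"` or `"after"` the term).
#' @param false_triggers Data frame with columns `term_id`, `pattern`,
#'   `window`, `direction`; each `term_id` must exist in `terms`.
#' @param history_cues Data frame with columns `pattern`, `window`,
#'   `direction`.
#' @param version Free-text version string.
#' @return An object of class `pwud_lexicon`.
#' @seealso [default_lexicon()], [read_lexicon()], [find_matches()]
#' @export
lexicon <- function(terms, negation_cues, false_triggers, history_cues,
                    version = "custom") {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  need <- c("term_id", "pattern", "category")
  if (!all(need %in% names(terms)) || nrow(terms) == 0L) {
    stop_pwud("`terms` must be a non-empty data frame with columns %s",
              paste(need, collapse = ", "))
  }
  if (any(!nzchar(terms$pattern))) stop_pwud("term patterns must be non-empty")
  if (any(duplicated(terms$term_id))) stop_pwud("duplicate term_id in lexicon")
  bad <- !(terms$category %in% c("action", "person", "drug"))
  if (any(bad)) {
    stop_pwud("unknown term category: %s",
              paste(unique(terms$category[bad]), collapse = ", "))
  }
  negation_cues <- normalize_cues(negation_cues, "negation_cues")
  history_cues <- normalize_cues(history_cues, "history_cues")
  false_triggers <- as.data.frame(false_triggers, stringsAsFactors = FALSE)
  if (nrow(false_triggers)) {
    needft <- c("term_id", "pattern", "window", "direction")
    if (!all(needft %in% names(false_triggers))) {
      stop_pwud("`false_triggers` must have columns %s",
                paste(needft, collapse = ", "))
    }
    stray <- setdiff(false_triggers$term_id, terms$term_id)
    if (length(stray)) {
      stop_pwud("false-trigger rule(s) reference unknown term(s): %s",
                paste(unique(stray), collapse = ", "))
    }
  } else {
    false_triggers <- data.frame(term_id = character(), pattern = character(),
                                 window = integer(), direction = character(),
                                 stringsAsFactors = FALSE)
  }
  structure(list(terms = terms, negation_cues = negation_cues,
                 false_triggers = false_triggers, history_cues = history_cues,
                 version = version),
            class = "pwud_lexicon")
}

normalize_cues <- function(cues, what) {
  cues <- as.data.frame(cues, stringsAsFactors = FALSE)
  if (nrow(cues) == 0L) {
    return(data.frame(pattern = character(), window = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  if (!("pattern" %in% names(cues))) {
    stop_pwud("`%s` must have a `pattern` column", what)
  }
  if (is.null(cues$window)) cues$window <- 30L
  if (is.null(cues$direction)) cues$direction <- "before"
  bad <- !(cues$direction %in% c("before", "after"))
  if (any(bad)) stop_pwud("cue direction must be \"before\" or \"after\"")
  cues[, c("pattern", "window", "direction")]
}

#' Default PWUD lexicon
#'
#' A starter lexicon covering the three categories used to describe drug
#' use in clinical notes: the action ("injects drugs"), the person
#' ("intravenous drug user", "IVDU"), and drug names (heroin, cocaine,
#' fentanyl, methamphetamine, crack). Negation cues ("no", "denies", ...)
#' use a 30-character preceding scope bounded by sentence breaks;
#' false-trigger rules exclude drug names followed within 15 characters by
#' medication-administration vocabulary ("gtt", "drip", "patch", "mcg").
#'
#' Institutions are expected to substitute their own curated term list; the
#' default is data, not a fixed algorithmic choice.
#'
#' @return A `pwud_lexicon`.
#' @export
default_lexicon <- function() {
  terms <- data.frame(
    term_id = c("injects_drugs", "injection_drug_use", "smoked_crack",
                "snorts_drugs", "sniffs_drugs",
                "ivdu", "idu", "intravenous_drug_user", "pwid",
                "heroin", "cocaine", "crack_cocaine", "fentanyl",
                "methamphetamine", "speedball"),
    pattern = c("injects drugs", "injection drug use", "smoked crack",
                "snorts drugs", "sniffs drugs",
                "IVDU", "IDU", "intravenous drug user", "PWID",
                "heroin", "cocaine", "crack cocaine", "fentanyl",
                "methamphetamine", "speedball"),
    category = c("action", "action", "action", "action", "action",
                 "person", "person", "person", "person",
                 "drug", "drug", "drug", "drug", "drug", "drug"),
    stringsAsFactors = FALSE
  )
  negation_cues <- data.frame(
    pattern = c("no", "denies", "denied", "negative for", "not", "without",
                "ruled out"),
    window = 30L, direction = "before", stringsAsFactors = FALSE
  )
  drug_terms <- terms$term_id[terms$category == "drug"]
  false_triggers <- expand.grid(
    term_id = drug_terms,
    pattern = c("gtt", "drip", "patch", "mcg", "infusion"),
    stringsAsFactors = FALSE
  )
  false_triggers$window <- 15L
  false_triggers$direction <- "after"
  history_cues <- data.frame(
    pattern = c("history of", "hx of", "prior", "remote", "past"),
    window = 30L, direction = "before", stringsAsFactors = FALSE
  )
  lexicon(terms, negation_cues, false_triggers, history_cues,
          version = "default-1")
}

#' Read a lexicon from a YAML file
#'
#' The YAML layout mirrors the lexicon components: `terms` (list of `id`,
#' `pattern`, `category`), `negation_cues`, `false_triggers` (with
#' `term_id`), `history_cues`, and an optional `version` string.
#'
#' @param path Path to a YAML file.
#' @return A `pwud_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop_pwud("lexicon file does not exist: %s", path)
  y <- yaml::read_yaml(path)
  as_df <- function(x, id_field = NULL) {
    if (is.null(x) || length(x) == 0L) return(data.frame())
    do.call(rbind, lapply(x, function(e) {
      as.data.frame(e, stringsAsFactors = FALSE)
    }))
  }
  terms <- as_df(y$terms)
  if ("id" %in% names(terms) && !("term_id" %in% names(terms))) {
    names(terms)[names(terms) == "id"] <- "term_id"
  }
  lexicon(terms = terms,
          negation_cues = as_df(y$negation_cues),
          false_triggers = as_df(y$false_triggers),
          history_cues = as_df(y$history_cues),
          version = if (is.null(y$version)) "yaml" else y$version)
}

#' Write a lexicon to a YAML file
#'
#' @param lex A `pwud_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "pwud_lexicon"))
  rows <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  yaml::write_yaml(list(version = lex$version, terms = rows(lex$terms),
                        negation_cues = rows(lex$negation_cues),
                        false_triggers = rows(lex$false_triggers),
                        history_cues = rows(lex$history_cues)),
                   path)
  invisible(path)
}

#' @export
print.pwud_lexicon <- function(x, ...) {
  cat(sprintf(
    "<pwud_lexicon %s> %d terms (%s), %d negation cues, %d false-trigger rules\n",
    x$version, nrow(x$terms),
    paste(sprintf("%d %s", table(x$terms$category),
                  names(table(x$terms$category))), collapse = ", "),
    nrow(x$negation_cues), nrow(x$false_triggers)))
  invisible(x)
}

# Compile a term pattern to a PCRE: escape regex metacharacters, let internal
# whitespace match whitespace-or-hyphen runs, anchor on word boundaries.
term_regex <- function(pattern) {
  esc <- gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", pattern, perl = TRUE)
  esc <- gsub("\\s+", "[\\\\s-]+", esc)
  paste0("\\b", esc, "\\b")
}

# Cue patterns are matched the same way as terms (word-bounded, whitespace
# flexible) but are data supplied by the lexicon.
cue_regex <- term_regex
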