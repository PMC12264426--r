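#' Define a boolean encounter classifier
#'
#' A model is a boolean expression over the encounter signal names
#' `icd`, `regex_any`, `regex_ge10`, `regex_ge25`, `regex_ge50`,
#' `context_any`, combined with `&` and `|`. The `icd` signal resolves to
#' the visit flag, the history flag, or their disjunction according to
#' `icd_scope`.
#'
#' @param model_id Stable identifier (snake_case).
#' @param expression Boolean expression string, e.g. `"icd | regex_any"`.
#' @param label Human-readable row label for reports.
#' @param icd_scope `"visit"`, `"history"` or `"visit_or_history"`.
#' @return An object of class `pwud_model`.
#' @seealso [builtin_registry()], [predict.pwud_model()]
#' @export
model_spec <- function(model_id, expression, label = model_id,
                       icd_scope = c("visit", "history", "visit_or_history")) {
  icd_scope <- match.arg(icd_scope)
  expr <- tryCatch(str2lang(expression),
                   error = function(e) stop_pwud(
                     "cannot parse expression for model %s: %s",
                     model_id, expression))
  used <- all.vars(expr)
  unknown <- setdiff(used, SIGNAL_NAMES)
  if (length(unknown)) {
    stop_pwud("model %s references unknown signal(s): %s",
              model_id, paste(unknown, collapse = ", "))
  }
  ops <- setdiff(all.names(expr), used)
  bad_ops <- setdiff(ops, c("&", "|", "(", "&&", "||"))
  if (length(bad_ops)) {
    stop_pwud("model %s uses unsupported operator(s): %s",
              model_id, paste(bad_ops, collapse = ", "))
  }
  structure(list(model_id = model_id, expression = expression,
                 expr = expr, label = label, icd_scope = icd_scope),
            class = "pwud_model")
}

#' @export
print.pwud_model <- function(x, ...) {
  cat(sprintf("<pwud_model %s> %s  [icd scope: %s]\n",
              x$model_id, x$expression, x$icd_scope))
  invisible(x)
}

#' Built-in registry of the 15 evaluated classifiers
#'
#' The single-signal models (ICD-10 only, RegEx only, OHNLP-style only),
#' their OR/AND pairings, the three-way combinations, and the OR/AND
#' variants of the 10/25/50 percent RegEx note-fraction thresholds --
#' 15 models in all.
#'
#' @param icd_scope ICD-10 scope applied to every model (default
#'   `"visit"`).
#' @return A list of [model_spec()] objects, named by `model_id`.
#' @export
builtin_registry <- function(icd_scope = "visit") {
  defs <- list(
    c("icd_only", "icd", "ICD-10 only"),
    c("regex_only", "regex_any", "RegEx only"),
    c("ohnlp_only", "context_any", "OHNLP only"),
    c("icd_or_regex", "icd | regex_any", "ICD-10 or RegEx"),
    c("icd_and_regex", "icd & regex_any", "ICD-10 and RegEx"),
    c("icd_or_ohnlp", "icd | context_any", "ICD-10 or OHNLP"),
    c("icd_and_ohnlp", "icd & context_any", "ICD-10 and OHNLP"),
    c("icd_or_regex_or_ohnlp", "icd | regex_any | context_any",
      "ICD-10 or RegEx or OHNLP"),
    c("icd_and_regex_or_ohnlp", "icd & (regex_any | context_any)",
      "ICD-10 and (RegEx or OHNLP)"),
    c("icd_or_regex_ge10", "icd | regex_ge10",
      "ICD-10 or RegEx 10% threshold"),
    c("icd_and_regex_ge10", "icd & regex_ge10",
      "ICD-10 and RegEx 10% threshold"),
    c("icd_or_regex_ge25", "icd | regex_ge25",
      "ICD-10 or RegEx 25% threshold"),
    c("icd_and_regex_ge25", "icd & regex_ge25",
      "ICD-10 and RegEx 25% threshold"),
    c("icd_or_regex_ge50", "icd | regex_ge50",
      "ICD-10 or RegEx 50% threshold"),
    c("icd_and_regex_ge50", "icd & regex_ge50",
      "ICD-10 and RegEx 50% threshold")
  )
  models <- lapply(defs, function(d) {
    model_spec(d[1], d[2], label = d[3], icd_scope = icd_scope)
  })
  names(models) <- vapply(models, function(m) m$model_id, "")
  models
}

#' Read a model registry from a YAML file
#'
#' The YAML maps model ids to expression strings, or to lists with
#' `expression`, optional `label` and `icd_scope`.
#'
#' @param path Path to a YAML file.
#' @param icd_scope Default ICD scope for entries that do not set one.
#' @return A named list of [model_spec()] objects.
#' @export
read_registry <- function(path, icd_scope = "visit") {
  y <- yaml::read_yaml(path)
  models <- lapply(names(y), function(id) {
    e <- y[[id]]
    if (is.character(e)) {
      model_spec(id, e, icd_scope = icd_scope)
    } else {
      model_spec(id, e$expression,
                 label = if (is.null(e$label)) id else e$label,
                 icd_scope = if (is.null(e$icd_scope)) icd_scope else
                   e$icd_scope)
    }
  })
  names(models) <- names(y)
  models
}

#' Apply a classifier to encounter signals
#'
#' Pure boolean evaluation of the model expression over each row of the
#' signal table.
#'
#' @param object A [model_spec()].
#' @param signals One or more rows of a [build_signals()] table.
#' @param ... Unused.
#' @return Logical vector named by `encounter_id` (when present).
#' @examples
#' reg <- builtin_registry()
#' sig <- tibble::tibble(icd_visit = FALSE, icd_history = FALSE,
#'                       regex_any = TRUE, regex_ge10 = TRUE,
#'                       regex_ge25 = FALSE, regex_ge50 = FALSE,
#'                       context_any = FALSE)
#' predict(reg$icd_or_regex, sig)
#' @export
predict.pwud_model <- function(object, signals, ...) {
  used <- all.vars(object$expr)
  env <- list()
  if ("icd" %in% used) {
    icd <- switch(object$icd_scope,
                  visit = signals[["icd_visit"]],
                  history = signals[["icd_history"]],
                  visit_or_history = signals[["icd_visit"]] |
                    signals[["icd_history"]])
    if (is.null(icd)) {
      stop_pwud("model %s needs signal field icd_%s", object$model_id,
                sub("_or_history", "", object$icd_scope))
    }
    env$icd <- icd
  }
  for (v in setdiff(used, "icd")) {
    if (is.null(signals[[v]])) {
      stop_pwud("model %s needs missing signal field %s", object$model_id, v)
    }
    env[[v]] <- signals[[v]]
  }
  out <- eval(object$expr, envir = env, enclos = baseenv())
  if (!is.null(signals[["encounter_id"]])) {
    names(out) <- signals[["encounter_id"]]
  }
  out
}
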