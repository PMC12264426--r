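#' Adjudicate a gold-standard label from chart review
#'
#' An encounter is gold-positive when at least 2 of the 3 reviewed chart
#' types (emergency, admission/HPI, discharge) describe the person as
#' someone who uses drugs. When two independent reviewer labels are
#' supplied and disagree, the tiebreaker label decides; a disagreement with
#' no tiebreaker is an error.
#'
#' @param per_chart_labels Named logical vector/list with entries among
#'   `emergency`, `hpi`, `discharge`, or `NULL` when adjudicating from
#'   reviewer labels alone.
#' @param reviewer_labels Optional list with logicals `reviewer1`,
#'   `reviewer2` and optional `tiebreaker`.
#' @return `"pwud"` or `"not_pwud"`.
#' @examples
#' adjudicate_gold(c(emergency = TRUE, hpi = TRUE, discharge = FALSE))
#' @export
adjudicate_gold <- function(per_chart_labels = NULL, reviewer_labels = NULL) {
  if (!is.null(reviewer_labels)) {
    r1 <- isTRUE(reviewer_labels$reviewer1)
    r2 <- isTRUE(reviewer_labels$reviewer2)
    if (r1 != r2) {
      if (is.null(reviewer_labels$tiebreaker)) {
        stop_pwud("reviewers disagree and no tiebreaker label was supplied")
      }
      return(if (isTRUE(reviewer_labels$tiebreaker)) "pwud" else "not_pwud")
    }
    return(if (r1) "pwud" else "not_pwud")
  }
  if (is.null(per_chart_labels)) {
    stop_pwud("supply per_chart_labels and/or reviewer_labels")
  }
  keys <- names(per_chart_labels)
  if (is.null(keys) || !all(keys %in% REVIEW_TYPES)) {
    stop_pwud("per_chart_labels keys must be among: %s",
              paste(REVIEW_TYPES, collapse = ", "))
  }
  n_pos <- sum(vapply(per_chart_labels, isTRUE, TRUE))
  if (n_pos >= 2L) "pwud" else "not_pwud"
}

#' Confusion matrix of predictions against gold labels
#'
#' @param predictions Named logical vector (names are encounter ids).
#' @param gold Named vector of `"pwud"`/`"not_pwud"` labels (or logicals)
#'   over the same encounter ids.
#' @return A list of class `pwud_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(predictions, gold) {
  if (is.character(gold) || is.factor(gold)) gold <- as.character(gold) == "pwud"
  if (is.null(names(predictions)) || is.null(names(gold))) {
    if (length(predictions) != length(gold)) {
      stop_pwud("predictions and gold have different lengths and no names")
    }
  } else {
    if (!setequal(names(predictions), names(gold))) {
      stop_pwud("predictions and gold cover different encounter ids")
    }
    gold <- gold[names(predictions)]
  }
  structure(list(tp = sum(predictions & gold),
                 fp = sum(predictions & !gold),
                 fn = sum(!predictions & gold),
                 tn = sum(!predictions & !gold)),
            class = "pwud_confusion")
}

#' @export
print.pwud_confusion <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and per-class F1 from a confusion matrix
#'
#' `f1_pos` is the F1 for the drug-use class, `2tp / (2tp + fp + fn)`;
#' `f1_neg` is the F1 of the complement-labelled problem,
#' `2tn / (2tn + fn + fp)`. An F1 with zero denominator is reported as 0
#' (convention); an undefined sensitivity or specificity (no gold positives
#' or no gold negatives) is an error rather than a silent NaN.
#'
#' @param cm A [confusion()] object (or list with `tp`, `fp`, `fn`, `tn`).
#' @return A tibble with `sensitivity`, `specificity`, `f1_pos`, `f1_neg`.
#' @export
metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop_pwud("negative confusion counts")
  if (tp + fn == 0L) stop_pwud("sensitivity undefined: no gold positives")
  if (tn + fp == 0L) stop_pwud("specificity undefined: no gold negatives")
  f1 <- function(a, b, c) if (2 * a + b + c == 0) 0 else 2 * a / (2 * a + b + c)
  tibble::tibble(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 f1_pos = f1(tp, fp, fn),
                 f1_neg = f1(tn, fn, fp))
}

#' Net reclassification index between two classifiers
#'
#' Compares a new classifier against an old one. A subject moves *up* when
#' reclassified old-negative to new-positive, and *down* for the reverse.
#' The event NRI is `P(up | drug use) - P(down | drug use)`, the nonevent
#' NRI is `P(down | no drug use) - P(up | no drug use)`, and the
#' population-weighted NRI is `wnri = rho * nri_e + (1 - rho) * nri_ne`,
#' with `rho` the prevalence of drug use.
#'
#' @param pred_old,pred_new Named logical prediction vectors over the same
#'   encounter ids.
#' @param gold Named gold labels (`"pwud"`/`"not_pwud"` or logical).
#' @param rho Prevalence weight; default the observed prevalence of gold
#'   positives.
#' @return A tibble of class `pwud_nri`: `p_up_event`, `p_down_event`,
#'   `p_up_nonevent`, `p_down_nonevent`, `nri_e`, `nri_ne`, `rho`, `wnri`.
#' @export
compute_nri <- function(pred_old, pred_new, gold, rho = NULL) {
  if (is.character(gold) || is.factor(gold)) gold <- as.character(gold) == "pwud"
  if (!is.null(names(pred_old)) && !is.null(names(pred_new)) &&
      !is.null(names(gold))) {
    if (!setequal(names(pred_old), names(gold)) ||
        !setequal(names(pred_new), names(gold))) {
      stop_pwud("prediction and gold encounter ids differ")
    }
    pred_new <- pred_new[names(pred_old)]
    gold <- gold[names(pred_old)]
  } else if (length(pred_old) != length(gold) ||
             length(pred_new) != length(gold)) {
    stop_pwud("prediction and gold lengths differ and no names given")
  }
  n_event <- sum(gold)
  n_nonevent <- sum(!gold)
  if (n_event == 0L) stop_pwud("no gold-positive encounters: NRI_e undefined")
  if (n_nonevent == 0L) stop_pwud("no gold-negative encounters: NRI_ne undefined")
  up <- !pred_old & pred_new
  down <- pred_old & !pred_new
  p_up_event <- sum(up & gold) / n_event
  p_down_event <- sum(down & gold) / n_event
  p_up_nonevent <- sum(up & !gold) / n_nonevent
  p_down_nonevent <- sum(down & !gold) / n_nonevent
  if (is.null(rho)) rho <- n_event / (n_event + n_nonevent)
  if (!is_prob(rho)) stop_pwud("`rho` must be a probability")
  nri_e <- p_up_event - p_down_event
  nri_ne <- p_down_nonevent - p_up_nonevent
  out <- tibble::tibble(p_up_event = p_up_event, p_down_event = p_down_event,
                        p_up_nonevent = p_up_nonevent,
                        p_down_nonevent = p_down_nonevent,
                        nri_e = nri_e, nri_ne = nri_ne, rho = rho,
                        wnri = rho * nri_e + (1 - rho) * nri_ne)
  class(out) <- c("pwud_nri", class(out))
  out
}

#' Evaluate a model registry against gold labels
#'
#' Produces the two report tables of a model-comparison study: per-model
#' sensitivity/specificity/F1, and per-model NRI against the ICD-10
#' visit-codes-only baseline.
#'
#' @param signals Tibble from [build_signals()].
#' @param gold Named gold labels over the signal encounter ids, or a labels
#'   tibble from [read_labels()].
#' @param registry Named list of models (default [builtin_registry()]).
#' @param rho NRI prevalence weight; default observed prevalence.
#' @param baseline Model id used as the NRI baseline (default
#'   `"icd_only"`, i.e. visit ICD-10 codes only).
#' @return A list of class `pwud_study` with tibbles `metrics` (model_id,
#'   label, sensitivity, specificity, f1_pos, f1_neg) and `nri` (model_id,
#'   label, nri_e, nri_ne, wnri, rho), plus the prediction matrix. Values
#'   are kept at full precision; round for display only.
#' @export
run_study <- function(signals, gold, registry = builtin_registry(),
                      rho = NULL, baseline = "icd_only") {
  if (is.data.frame(gold)) {
    gold <- setNames(gold$label, gold$encounter_id)
  }
  if (is.character(gold) || is.factor(gold)) {
    gold <- setNames(as.character(gold) == "pwud", names(gold))
  }
  if (!setequal(names(gold), signals$encounter_id)) {
    stop_pwud("gold labels and signals cover different encounter ids")
  }
  gold <- gold[signals$encounter_id]
  preds <- lapply(registry, predict, signals = signals)
  mets <- do.call(rbind, lapply(names(registry), function(id) {
    m <- metrics(confusion(preds[[id]], gold))
    tibble::tibble(model_id = id, label = registry[[id]]$label, m)
  }))
  if (!baseline %in% names(registry)) {
    stop_pwud("baseline model %s is not in the registry", baseline)
  }
  base_pred <- preds[[baseline]]
  nri <- do.call(rbind, lapply(names(registry), function(id) {
    r <- compute_nri(base_pred, preds[[id]], gold, rho = rho)
    tibble::tibble(model_id = id, label = registry[[id]]$label,
                   nri_e = r$nri_e, nri_ne = r$nri_ne, wnri = r$wnri,
                   rho = r$rho)
  }))
  structure(list(metrics = mets, nri = nri,
                 predictions = do.call(cbind, preds), baseline = baseline),
            class = "pwud_study")
}

#' @export
print.pwud_study <- function(x, digits = 3, ...) {
  cat("Model performance (rounded for display):\n")
  m <- x$metrics
  m[3:6] <- lapply(m[3:6], round, digits = digits)
  print(as.data.frame(m), row.names = FALSE)
  cat(sprintf("\nNet reclassification vs baseline \"%s\":\n", x$baseline))
  n <- x$nri
  n[3:6] <- lapply(n[3:6], round, digits = digits)
  print(as.data.frame(n), row.names = FALSE)
  invisible(x)
}
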