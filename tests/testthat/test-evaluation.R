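test_that("gold adjudication follows the 2-of-3 chart rule", {
  expect_equal(adjudicate_gold(c(emergency = TRUE, hpi = TRUE,
                                 discharge = FALSE)), "pwud")
  expect_equal(adjudicate_gold(c(emergency = TRUE, hpi = FALSE,
                                 discharge = FALSE)), "not_pwud")
  expect_equal(adjudicate_gold(c(emergency = TRUE, hpi = TRUE,
                                 discharge = TRUE)), "pwud")
  expect_error(adjudicate_gold(c(admission = TRUE)), "keys")
})

test_that("reviewer disagreement is settled by the tiebreaker", {
  expect_equal(adjudicate_gold(reviewer_labels = list(
    reviewer1 = TRUE, reviewer2 = FALSE, tiebreaker = TRUE)), "pwud")
  expect_equal(adjudicate_gold(reviewer_labels = list(
    reviewer1 = TRUE, reviewer2 = FALSE, tiebreaker = FALSE)), "not_pwud")
  expect_equal(adjudicate_gold(reviewer_labels = list(
    reviewer1 = FALSE, reviewer2 = FALSE)), "not_pwud")
  expect_error(adjudicate_gold(reviewer_labels = list(
    reviewer1 = TRUE, reviewer2 = FALSE)), "tiebreaker")
})

test_that("confusion counts partition the cohort and swap under complement", {
  ids <- sprintf("E%d", 1:10)
  gold <- setNames(rep(c(TRUE, FALSE), each = 5), ids)
  perfect <- gold
  cm <- confusion(perfect, gold)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(5, 5, 0, 0))

  none <- setNames(rep(FALSE, 10), ids)
  cm0 <- confusion(none, gold)
  expect_equal(cm0$tp, 0)
  expect_equal(cm0$fn, 5)

  set.seed(3)
  pred <- setNames(runif(10) < 0.5, ids)
  a <- confusion(pred, gold)
  b <- confusion(!pred, gold)
  expect_equal(a$tp, b$fn)
  expect_equal(a$tn, b$fp)
  # against the per-subject recount oracle
  brute <- brute_confusion(pred, gold)
  expect_equal(list(tp = a$tp, fp = a$fp, fn = a$fn, tn = a$tn), brute)
  expect_error(confusion(pred[1:9], gold), "different")
})

test_that("metrics match their defining formulas", {
  m <- metrics(list(tp = 9, fn = 1, fp = 0, tn = 10))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 1.0)

  perfect <- metrics(list(tp = 4, fn = 0, fp = 0, tn = 6))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  f1_pos = 1, f1_neg = 1))

  # F1 via the independent precision/recall route
  m2 <- metrics(list(tp = 3, fp = 1, fn = 1, tn = 5))
  prec <- 3 / (3 + 1); rec <- 3 / (3 + 1)
  expect_equal(m2$f1_pos, 2 * prec * rec / (prec + rec))
  expect_equal(m2$f1_pos, 0.75)
  # f1_neg is the F1 of the complement-labelled problem
  swapped <- metrics(list(tp = 5, fp = 1, fn = 1, tn = 3))
  expect_equal(m2$f1_neg, swapped$f1_pos)

  expect_error(metrics(list(tp = 0, fn = 0, fp = 1, tn = 9)), "sensitivity")
  # all-positive predictions: F1 for the negative class is 0, not NaN
  m3 <- metrics(list(tp = 5, fp = 5, fn = 0, tn = 0))
  expect_equal(m3$f1_neg, 0)
})

test_that("NRI components follow the up/down definitions exactly", {
  ids <- sprintf("E%d", 1:10)
  gold <- setNames(rep(c(TRUE, FALSE), c(4, 6)), ids)
  pred_old <- setNames(rep(FALSE, 10), ids)
  # identical models: everything zero
  r0 <- compute_nri(pred_old, pred_old, gold)
  expect_equal(r0$wnri, 0)
  expect_equal(r0$nri_e, 0)

  # 10-subject toy: new model upgrades 2 events and 1 nonevent
  pred_new <- pred_old
  pred_new[c("E1", "E2", "E5")] <- TRUE
  r <- compute_nri(pred_old, pred_new, gold)
  # brute-force enumeration of the up/down moves
  up_e <- 0; down_e <- 0; up_ne <- 0; down_ne <- 0
  for (id in ids) {
    up <- !pred_old[[id]] && pred_new[[id]]
    down <- pred_old[[id]] && !pred_new[[id]]
    if (gold[[id]]) { up_e <- up_e + up; down_e <- down_e + down }
    else { up_ne <- up_ne + up; down_ne <- down_ne + down }
  }
  expect_equal(r$nri_e, (up_e - down_e) / 4)
  expect_equal(r$nri_ne, (down_ne - up_ne) / 6)
  expect_equal(r$nri_e, 0.5)
  expect_equal(r$nri_ne, -1 / 6)
  expect_equal(r$rho, 0.4)
  expect_equal(r$wnri, 0.4 * 0.5 + 0.6 * (-1 / 6))
  expect_equal(r$wnri, 0.1)

  # direct substitution into the weighting formula with an override rho
  r2 <- compute_nri(pred_old, pred_new, gold, rho = 0.5)
  expect_equal(r2$wnri, 0.5 * r2$nri_e + 0.5 * r2$nri_ne)

  expect_error(compute_nri(pred_old, pred_new,
                           setNames(rep(TRUE, 10), ids)), "nonevent|negative")
})

test_that("wNRI identity holds exactly for random model pairs", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    ids <- sprintf("E%d", seq_len(n))
    gold <- setNames(runif(n) < 0.3, ids)
    gold[1] <- TRUE; gold[2] <- FALSE
    old <- setNames(runif(n) < 0.5, ids)
    new <- setNames(runif(n) < 0.5, ids)
    r <- compute_nri(old, new, gold)
    expect_identical(r$wnri, r$rho * r$nri_e + (1 - r$rho) * r$nri_ne)
  }
})

test_that("McNemar test handles symmetric, degenerate and exact cases", {
  ids <- sprintf("E%d", 1:20)
  a <- setNames(rep(c(TRUE, FALSE), 10), ids)
  r_same <- mcnemar_test(a, a)
  expect_equal(r_same$statistic, 0)
  expect_equal(r_same$p_value, 1)
  expect_equal(r_same$method, "degenerate")

  # b = c = 4: statistic 0, p = 1
  b <- a
  flip_to_false <- names(which(a))[1:4]
  flip_to_true <- names(which(!a))[1:4]
  b[flip_to_false] <- FALSE
  b[flip_to_true] <- TRUE
  r_sym <- mcnemar_test(a, b)
  expect_equal(r_sym$b, 4)
  expect_equal(r_sym$c, 4)
  expect_equal(r_sym$statistic, 0)
  expect_equal(r_sym$p_value, 1)

  # b = 10, c = 2: closed-form statistic and exact binomial p
  ids2 <- sprintf("F%d", 1:30)
  p <- setNames(rep(FALSE, 30), ids2)
  q <- p
  p[1:10] <- TRUE          # first-only positives
  q[11:12] <- TRUE         # second-only positives
  r <- mcnemar_test(p, q)
  expect_equal(r$b, 10)
  expect_equal(r$c, 2)
  expect_equal(r$statistic, (10 - 2)^2 / 12)
  expect_equal(r$p_value, 2 * pbinom(2, 12, 0.5))
  expect_equal(r$method, "exact")
  # cross-check against the stock exact binomial test
  expect_equal(r$p_value, binom.test(2, 12, 0.5)$p.value, tolerance = 1e-12)
})

test_that("large-sample McNemar agrees with the stock chi-square test", {
  set.seed(8)
  n <- 400
  ids <- sprintf("E%d", seq_len(n))
  a <- setNames(runif(n) < 0.5, ids)
  b <- setNames(ifelse(runif(n) < 0.8, a, runif(n) < 0.6), ids)
  r <- mcnemar_test(a, b)
  expect_equal(r$method, "asymptotic")
  ref <- stats::mcnemar.test(table(a, b), correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("restriction to gold positives compares sensitivities", {
  ids <- sprintf("E%d", 1:12)
  gold_pos <- ids[1:6]
  a <- setNames(c(rep(TRUE, 6), rep(TRUE, 6)), ids)
  b <- setNames(c(rep(c(TRUE, FALSE), 3), rep(FALSE, 6)), ids)
  r <- mcnemar_test(a, b, restrict_to = gold_pos)
  expect_equal(r$b + r$c, 3)  # only discordance among gold positives counted
})

test_that("analytic power reproduces the published design and is monotone", {
  pow <- mcnemar_power(790, 0.10, 0.15, 0.22, 0.05)
  expect_gte(pow, 0.80)
  expect_lt(pow, 0.90)
  # null case: power collapses to the test size
  expect_equal(mcnemar_power(790, 0.10, 0, 0.22, 0.05), 0.05,
               tolerance = 0.01)
  # doubling the cohort strictly increases power
  expect_gt(mcnemar_power(1580, 0.10, 0.15, 0.22, 0.05), pow)
  # infeasible designs are rejected
  expect_error(mcnemar_power(790, 0.10, 0.30, 0.22, 0.05), "discordant")
  expect_error(mcnemar_power(790, 0.10, 1, 1, 0.05), "variance")
})

test_that("run_study on a perfectly separable corpus saturates OR models", {
  config <- generator_config(n_encounters = 120, prevalence = 0.3,
                             p_mention = 1, p_negated_mention = 0,
                             p_false_trigger = 0, icd_sensitivity = 1,
                             icd_specificity = 1, seed = 21)
  syn <- generate_corpus(config)
  sig <- build_signals(syn$corpus)
  study <- run_study(sig, syn$corpus$labels)
  or_models <- c("icd_only", "regex_only", "icd_or_regex",
                 "icd_or_regex_or_ohnlp")
  for (id in or_models) {
    expect_equal(study$metrics$sensitivity[study$metrics$model_id == id], 1)
  }
  expect_equal(study$metrics$specificity[
    study$metrics$model_id == "regex_only"], 1)
  # baseline against itself: the all-zero NRI row
  base_row <- study$nri[study$nri$model_id == "icd_only", ]
  expect_equal(base_row$nri_e, 0)
  expect_equal(base_row$nri_ne, 0)
  expect_equal(base_row$wnri, 0)
})

test_that("OR-augmentation never reclassifies downward; AND never upward", {
  reg <- builtin_registry()
  set.seed(99)
  for (rep in 1:20) {
    toy <- random_toy_cohort(40)
    base <- predict(reg$icd_only, toy$signals)
    for (id in c("icd_or_regex", "icd_or_ohnlp", "icd_or_regex_ge25")) {
      r <- compute_nri(base, predict(reg[[id]], toy$signals), toy$gold)
      expect_equal(r$p_down_event, 0)
      expect_gte(r$nri_e, 0)
      expect_lte(r$nri_ne, 0)
    }
    for (id in c("icd_and_regex", "icd_and_ohnlp")) {
      r <- compute_nri(base, predict(reg[[id]], toy$signals), toy$gold)
      expect_equal(r$p_up_event, 0)
      expect_lte(r$nri_e, 0)
      expect_gte(r$nri_ne, 0)
    }
  }
})
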