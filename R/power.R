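#' McNemar paired test between two classifiers
#'
#' Counts the discordant pairs between two prediction vectors over the same
#' encounters (`b`: first-only positive, `c`: second-only positive) and
#' tests marginal homogeneity. For small discordant counts
#' (`b + c < exact_below`) the exact two-sided binomial p-value is used;
#' otherwise the asymptotic chi-square statistic `(b - c)^2 / (b + c)`
#' without continuity correction. `b + c = 0` is reported as statistic 0,
#' p = 1 by convention.
#'
#' Restricting to gold-positive encounters turns the test into a paired
#' comparison of sensitivities, the design used for the study's sample-size
#' calculation.
#'
#' @param pred_a,pred_b Named logical prediction vectors over the same ids.
#' @param restrict_to Optional character vector of encounter ids (for
#'   example the gold positives) to restrict the comparison to.
#' @param exact_below Use the exact binomial p-value when `b + c` is below
#'   this count (default 25).
#' @return A list of class `pwud_mcnemar`: `b`, `c`, `statistic`,
#'   `p_value`, `method`.
#' @export
mcnemar_test <- function(pred_a, pred_b, restrict_to = NULL,
                         exact_below = 25L) {
  if (!is.null(names(pred_a)) && !is.null(names(pred_b))) {
    if (!setequal(names(pred_a), names(pred_b))) {
      stop_pwud("prediction vectors cover different encounter ids")
    }
    pred_b <- pred_b[names(pred_a)]
    if (!is.null(restrict_to)) {
      keep <- names(pred_a) %in% restrict_to
      pred_a <- pred_a[keep]
      pred_b <- pred_b[keep]
    }
  } else if (length(pred_a) != length(pred_b)) {
    stop_pwud("prediction vectors differ in length and have no names")
  }
  b <- sum(pred_a & !pred_b)
  cc <- sum(!pred_a & pred_b)
  res <- mcnemar_decide(b, cc, exact_below = exact_below)
  structure(c(list(b = b, c = cc), res), class = "pwud_mcnemar")
}

# Shared decision core: statistic and p-value from discordant counts.
mcnemar_decide <- function(b, cc, exact_below = 25L) {
  nd <- b + cc
  if (nd == 0L) {
    return(list(statistic = 0, p_value = 1, method = "degenerate"))
  }
  statistic <- (b - cc)^2 / nd
  if (nd < exact_below) {
    p <- min(1, 2 * pbinom(min(b, cc), nd, 0.5))
    list(statistic = statistic, p_value = p, method = "exact")
  } else {
    list(statistic = statistic,
         p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
         method = "asymptotic")
  }
}

#' @export
print.pwud_mcnemar <- function(x, ...) {
  cat(sprintf("McNemar test (%s): b=%d c=%d statistic=%.4g p=%.4g\n",
              x$method, x$b, x$c, x$statistic, x$p_value))
  invisible(x)
}

check_power_spec <- function(n_total, prevalence, delta, discordant, alpha) {
  if (!is_count(n_total) || n_total < 1) {
    stop_pwud("`n_total` must be a positive integer")
  }
  if (!is_prob(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_pwud("`prevalence` must be in (0, 1)")
  }
  if (!is_prob(alpha) || alpha <= 0 || alpha >= 1) {
    stop_pwud("`alpha` must be in (0, 1)")
  }
  if (!is_prob(discordant)) stop_pwud("`discordant` must be in [0, 1]")
  if (!is.numeric(delta) || delta < 0 || delta > 1) {
    stop_pwud("`delta` must be in [0, 1]")
  }
  if (discordant < delta) {
    stop_pwud("infeasible design: discordant proportion (%g) < delta (%g)",
              discordant, delta)
  }
  if (discordant <= delta^2) {
    stop_pwud("variance term nonpositive: discordant (%g) <= delta^2 (%g)",
              discordant, delta^2)
  }
  invisible(TRUE)
}

#' Analytic power of the paired McNemar sensitivity comparison
#'
#' Power to detect a difference `delta` in sensitivity between two search
#' methods with a two-sided McNemar test at level `alpha`, when a cohort of
#' `n_total` encounters contains a fraction `prevalence` of true PWUD
#' hospitalizations and a proportion `discordant` of the PWUD encounters
#' are classified discordantly by the two methods.
#'
#' The effective paired sample size is `n_eff = round(n_total * prevalence)`
#' (the comparison is conditional on the gold positives). Power follows the
#' conditional normal-approximation formula
#' `Phi((delta * sqrt(n_eff) - z * sqrt(psi)) / sqrt(psi - delta^2))`
#' with `psi = discordant` and `z` the upper `alpha/2` normal quantile,
#' plus the (negligible) opposite tail.
#'
#' @param n_total Total cohort size.
#' @param prevalence Design prevalence of PWUD hospitalizations.
#' @param delta Difference in sensitivities to detect.
#' @param discordant Proportion of discordant classifications among PWUD.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power (scalar in `[0, 1]`).
#' @examples
#' mcnemar_power(790, 0.10, 0.15, 0.22)
#' @seealso [simulate_mcnemar_power()] for the Monte-Carlo cross-check.
#' @export
mcnemar_power <- function(n_total, prevalence, delta, discordant,
                          alpha = 0.05) {
  check_power_spec(n_total, prevalence, delta, discordant, alpha)
  n_eff <- round(n_total * prevalence)
  if (n_eff < 1) stop_pwud("effective paired sample size is zero")
  z <- qnorm(1 - alpha / 2)
  s <- sqrt(discordant - delta^2)
  pnorm((delta * sqrt(n_eff) - z * sqrt(discordant)) / s) +
    pnorm((-delta * sqrt(n_eff) - z * sqrt(discordant)) / s)
}

#' Simulated power of the paired McNemar sensitivity comparison
#'
#' Monte-Carlo companion to [mcnemar_power()]: simulates the discordant
#' classifications of the `n_eff = round(n_total * prevalence)` gold-positive
#' encounters (`n_d ~ Binomial(n_eff, discordant)` discordant pairs, of
#' which `b ~ Binomial(n_d, (discordant + delta) / (2 * discordant))` favor
#' the first method) and applies the same test decision rule as
#' [mcnemar_test()] to each replicate. Because the test is applied to
#' discrete counts, the estimate reflects the test's true (discrete) power
#' rather than the normal approximation; at small `n_eff` the two can
#' differ by a few percentage points.
#'
#' @inheritParams mcnemar_power
#' @param reps Number of Monte-Carlo replicates (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @param exact_below Passed to the test decision rule (default 25).
#' @return Estimated power (scalar).
#' @export
simulate_mcnemar_power <- function(n_total, prevalence, delta, discordant,
                                   alpha = 0.05, reps = 1e5, seed = NULL,
                                   exact_below = 25L) {
  check_power_spec(n_total, prevalence, delta, discordant, alpha)
  if (!is.null(seed)) set.seed(seed)
  n_eff <- round(n_total * prevalence)
  p_b <- (discordant + delta) / (2 * discordant)
  nd <- rbinom(reps, n_eff, discordant)
  b <- rbinom(reps, nd, p_b)
  cc <- nd - b
  m <- pmin(b, cc)
  reject <- logical(reps)
  small <- nd > 0L & nd < exact_below
  reject[small] <- 2 * pbinom(m[small], nd[small], 0.5) < alpha
  big <- nd >= exact_below
  reject[big] <- (b[big] - cc[big])^2 / nd[big] > qchisq(1 - alpha, df = 1)
  mean(reject)
}
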