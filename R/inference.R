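#' Pooled two-proportion z test for the priming effect
#'
#' Tests whether the observed difference in identification proportions
#' between the studied and non-studied arms is significant. The statistic
#' uses the pooled success proportion in its variance, with no continuity
#' correction:
#' \deqn{z = \frac{\hat p_1 - \hat p_0}
#'   {\sqrt{\hat p (1 - \hat p) (1/N_1 + 1/N_0)}},}
#' where \eqn{\hat p} pools successes over both arms. Trials are treated as
#' exchangeable independent units (subject-word trials pooled within arm);
#' with subject or word heterogeneity the nominal level is approximate — a
#' documented simplification of the trial-pooling convention. The statistic
#' is the signed square root of the Pearson chi-square of the underlying
#' 2x2 table; see [chisq_from_table()].
#'
#' @param successes1,n1 successes and trials in the studied (`z = 1`) arm.
#' @param successes0,n0 successes and trials in the non-studied arm.
#' @param sided `"two_sided"` (default) or `"one_sided_greater"` (alternative
#'   that the priming effect exceeds zero).
#' @return An object of class `priming_test`: `z_value`, `p_value`, `sided`,
#'   `pooled_p`, `dpe`, `n1`, `n0`.
#' @export
pooled_ztest <- function(successes1, n1, successes0, n0,
                         sided = c("two_sided", "one_sided_greater")) {
  sided <- match.arg(sided)
  check_counts(successes1, n1, successes0, n0)
  p1 <- successes1 / n1
  p0 <- successes0 / n0
  pooled <- (successes1 + successes0) / (n1 + n0)
  if (pooled <= 0 || pooled >= 1) {
    stop("degenerate pooled proportion (all failures or all successes)",
         call. = FALSE)
  }
  z <- (p1 - p0) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n0))
  p_value <- switch(sided,
                    two_sided = 2 * pnorm(-abs(z)),
                    one_sided_greater = pnorm(z, lower.tail = FALSE))
  structure(list(z_value = z, p_value = p_value, sided = sided,
                 pooled_p = pooled, dpe = p1 - p0,
                 p1_hat = p1, p0_hat = p0,
                 n1 = as.integer(n1), n0 = as.integer(n0)),
            class = "priming_test")
}

check_counts <- function(successes1, n1, successes0, n0) {
  if (n1 < 1 || n0 < 1) stop("trial counts must be >= 1", call. = FALSE)
  if (successes1 < 0 || successes1 > n1 || successes0 < 0 || successes0 > n0) {
    stop("success counts must lie in [0, n]", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.priming_test <- function(x, ...) {
  cat(sprintf("Pooled two-proportion z test (%s)\n", x$sided))
  cat(sprintf("  DPE = %.4f   z = %.3f   p = %.4g   pooled p = %.4f\n",
              x$dpe, x$z_value, x$p_value, x$pooled_p))
  invisible(x)
}

#' Wald confidence interval for the priming effect
#'
#' The 100(1 - alpha)% interval for the difference in proportions, using the
#' unpooled arm variances:
#' \deqn{\hat p_1 - \hat p_0 \mp z_{1-\alpha/2}
#'   \sqrt{\hat p_1 (1-\hat p_1)/N_1 + \hat p_0 (1-\hat p_0)/N_0}.}
#' Note the deliberate asymmetry with [pooled_ztest()]: the test pools the
#' variance under the null of no effect, the interval does not — the two
#' formulas are kept exactly as conventionally printed.
#'
#' @param p1_hat,n1 success proportion and trial count, studied arm.
#' @param p0_hat,n0 success proportion and trial count, non-studied arm.
#' @param level confidence level in (0, 1); default 0.95.
#' @return An object of class `priming_ci`: `lower`, `upper`, `level`,
#'   `estimate`.
#' @export
wald_ci <- function(p1_hat, n1, p0_hat, n0, level = 0.95) {
  if (level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p1_hat < 0 || p1_hat > 1 || p0_hat < 0 || p0_hat > 1) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (n1 < 1 || n0 < 1) stop("trial counts must be >= 1", call. = FALSE)
  est <- p1_hat - p0_hat
  se <- sqrt(p1_hat * (1 - p1_hat) / n1 + p0_hat * (1 - p0_hat) / n0)
  q <- qnorm(1 - (1 - level) / 2)
  structure(list(lower = est - q * se, upper = est + q * se,
                 level = level, estimate = est, se = se),
            class = "priming_ci")
}

#' @export
print.priming_ci <- function(x, ...) {
  cat(sprintf("%.0f%% Wald CI for the priming effect: (%.4f, %.4f)\n",
              100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Pearson chi-square statistic of the 2x2 arm-by-outcome table
#'
#' The chi-square statistic (no continuity correction) of the
#' success/failure table underlying the priming contrast. It equals the
#' square of the pooled z statistic, and the two tests' two-sided p-values
#' coincide. Computed via [stats::chisq.test()], which serves as the
#' independent route against the hand-built z statistic.
#'
#' @inheritParams pooled_ztest
#' @return The chi-square statistic (1 df), a single number.
#' @export
chisq_from_table <- function(successes1, n1, successes0, n0) {
  check_counts(successes1, n1, successes0, n0)
  tab <- matrix(c(successes1, n1 - successes1,
                  successes0, n0 - successes0),
                nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    stop("degenerate margins (all failures or all successes)", call. = FALSE)
  }
  unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic))
}

#' Reconstruct arm proportions from a printed (DPE, z, N) summary
#'
#' Inverts the pooled z statistic to recover the success proportions behind
#' a published summary. With equal arm sizes `n_per_arm`, the pooled
#' proportion \eqn{\hat p} satisfies the quadratic
#' \deqn{\hat p (1 - \hat p) = (DPE / z)^2 \, n_\mathrm{per\,arm} / 2,}
#' whose two roots sum to 1. The selected root (by default the one below
#' 0.5, since word-fragment-completion accuracies in this literature sit
#' below one half) is split into arm proportions as
#' \eqn{\hat p_1 = \hat p + DPE/2}, \eqn{\hat p_0 = \hat p - DPE/2}, which is
#' exact when the arms are equally sized. Substituting the result back into
#' [pooled_ztest()] reproduces the input `z_value`.
#'
#' @param dpe printed difference in proportions, in \[-1, 1\].
#' @param z_value printed z statistic (nonzero).
#' @param n_per_arm trials per arm.
#' @param root `"low"` (default, pooled proportion < 0.5) or `"high"`.
#' @return An object of class `pooled_solve`: `pooled_p_low`,
#'   `pooled_p_high`, `pooled_p` (selected), `p1_hat`, `p0_hat`.
#' @export
solve_pooled_proportion <- function(dpe, z_value, n_per_arm,
                                    root = c("low", "high")) {
  root <- match.arg(root)
  if (z_value == 0) stop("underdetermined: z_value must be nonzero",
                         call. = FALSE)
  if (abs(dpe) > 1) stop("|dpe| must be <= 1", call. = FALSE)
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  cc <- (dpe / z_value)^2 * n_per_arm / 2
  disc <- 1 - 4 * cc
  if (disc < 0) {
    stop("inconsistent summary: implied pooled variance is impossible ",
         "(negative discriminant)", call. = FALSE)
  }
  p_low <- (1 - sqrt(disc)) / 2
  p_high <- (1 + sqrt(disc)) / 2
  pooled <- if (root == "low") p_low else p_high
  structure(list(pooled_p_low = p_low, pooled_p_high = p_high,
                 pooled_p = pooled,
                 p1_hat = pooled + dpe / 2,
                 p0_hat = pooled - dpe / 2),
            class = "pooled_solve")
}

#' @export
print.pooled_solve <- function(x, ...) {
  cat(sprintf(
    "Reconstructed proportions: p1_hat = %.4f, p0_hat = %.4f (pooled %.4f; roots %.4f / %.4f)\n",
    x$p1_hat, x$p0_hat, x$pooled_p, x$pooled_p_low, x$pooled_p_high))
  invisible(x)
}

#' Test the priming effect of a trial table
#'
#' Convenience wrapper: counts successes per arm at the given test index and
#' runs [pooled_ztest()] and [wald_ci()].
#'
#' @param table a [trial_table()].
#' @param test_index which test's trials to use (default 1).
#' @param level confidence level for the interval.
#' @inheritParams pooled_ztest
#' @return A list with elements `test` (a `priming_test`) and `ci`
#'   (a `priming_ci`).
#' @export
test_priming <- function(table, test_index = 1L, level = 0.95,
                         sided = c("two_sided", "one_sided_greater")) {
  sided <- match.arg(sided)
  a <- arm_counts(table, test_index)
  tst <- pooled_ztest(a$s1, a$n1, a$s0, a$n0, sided = sided)
  ci <- wald_ci(tst$p1_hat, a$n1, tst$p0_hat, a$n0, level = level)
  list(test = tst, ci = ci)
}
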