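#' Effect-estimate container
#'
#' Result of the difference-in-proportions priming estimators: the point
#' estimate, the two arm proportions and trial counts, and (when available)
#' per-word detail. The invariant `estimate == p1_hat - p0_hat` holds
#' exactly.
#'
#' @param p1_hat,p0_hat success proportions in the studied / non-studied arm.
#' @param n1,n0 trial counts per arm.
#' @param per_word optional tibble of word-level detail
#'   (`word_id, dpe, n1, n0`).
#' @param estimator label of the producing estimator.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(p1_hat, p0_hat, n1, n0, per_word = NULL,
                            estimator = "dpe") {
  stopifnot(n1 >= 1, n0 >= 1)
  structure(list(estimate = p1_hat - p0_hat,
                 p1_hat = p1_hat, p0_hat = p0_hat,
                 n1 = as.integer(n1), n0 = as.integer(n0),
                 per_word = per_word, estimator = estimator),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Priming effect (%s): %.4f\n", x$estimator, x$estimate))
  cat(sprintf("  p1_hat = %.4f (n1 = %d)   p0_hat = %.4f (n0 = %d)\n",
              x$p1_hat, x$n1, x$p0_hat, x$n0))
  if (!is.null(x$per_word)) {
    cat("  per-word effects for", nrow(x$per_word), "words\n")
  }
  invisible(x)
}

arm_counts <- function(table, test_index = NULL) {
  df <- tibble::as_tibble(table)
  if (!is.null(test_index)) df <- df[df$test_index == test_index, ]
  list(s1 = sum(df$y[df$z == 1L]), n1 = sum(df$z == 1L),
       s0 = sum(df$y[df$z == 0L]), n0 = sum(df$z == 0L), df = df)
}

#' Difference in priming effect (DPE), pooled over trials
#'
#' The observable estimator of the average priming effect in a
#' between-subjects study: the difference between the success proportion of
#' the studied arm and that of the non-studied arm, pooling all subject-word
#' trials within each arm,
#' \deqn{\widehat{DPE} = \hat p_1 - \hat p_0.}
#' With perfectly matched arms this equals the sample average priming effect
#' exactly; under randomization it is unbiased for it. Trials are pooled as
#' exchangeable units (no within-subject clustering correction), the
#' convention under which the companion z test ([pooled_ztest()]) is exact.
#'
#' @param table a [trial_table()].
#' @param test_index which test's trials to use (default 1).
#' @return An [effect_estimate()]; `per_word` is populated when every word
#'   appears in both arms.
#' @export
estimate_dpe <- function(table, test_index = 1L) {
  a <- arm_counts(table, test_index)
  if (a$n1 == 0) stop("no trials in the z=1 arm", call. = FALSE)
  if (a$n0 == 0) stop("no trials in the z=0 arm", call. = FALSE)
  per_word <- word_level_dpe(a$df)
  if (any(per_word$n1 == 0 | per_word$n0 == 0)) per_word <- NULL
  effect_estimate(p1_hat = a$s1 / a$n1, p0_hat = a$s0 / a$n0,
                  n1 = a$n1, n0 = a$n0, per_word = per_word,
                  estimator = "dpe")
}

word_level_dpe <- function(df) {
  df |>
    dplyr::group_by(.data$word_id) |>
    dplyr::summarise(
      n1 = sum(.data$z == 1L),
      n0 = sum(.data$z == 0L),
      p1 = ifelse(.data$n1 > 0, sum(.data$y[.data$z == 1L]) / .data$n1, NA_real_),
      p0 = ifelse(.data$n0 > 0, sum(.data$y[.data$z == 0L]) / .data$n0, NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(dpe = .data$p1 - .data$p0) |>
    dplyr::select("word_id", "dpe", "n1", "n0", "p1", "p0")
}

#' Word-averaged expected priming effect
#'
#' The word-averaged version of the priming estimator: the unweighted mean
#' over words of the word-level differences in success proportions. It equals
#' [estimate_dpe()] exactly whenever the per-word arm sizes are balanced, and
#' differs from it under imbalance (the pooled estimator then weights words
#' by their trial counts).
#'
#' @param table a [trial_table()].
#' @param test_index which test's trials to use (default 1).
#' @return An [effect_estimate()] with `per_word` always populated;
#'   `p1_hat` / `p0_hat` are the unweighted word means of the arm
#'   proportions.
#' @export
estimate_per_word_epe <- function(table, test_index = 1L) {
  a <- arm_counts(table, test_index)
  pw <- word_level_dpe(a$df)
  missing <- pw$word_id[pw$n1 == 0 | pw$n0 == 0]
  if (length(missing) > 0) {
    stop("word(s) missing from an arm: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  effect_estimate(p1_hat = mean(pw$p1), p0_hat = mean(pw$p0),
                  n1 = a$n1, n0 = a$n0, per_word = pw,
                  estimator = "per_word_epe")
}

#' True average priming effect of a simulated experiment
#'
#' The causal estimand itself: the mean of the individual potential-outcome
#' differences `y1 - y0` over all (subject, word) rows. Computable only for
#' simulated data, where both potential outcomes are realised; in a real
#' experiment only one of the two is ever observed.
#'
#' @param potential a `potential_table` from [simulate_experiment()].
#' @return The sample average priming effect, a number in \[-1, 1\].
#' @export
true_ape <- function(potential) {
  stopifnot(inherits(potential, "potential_table"))
  if (nrow(potential) == 0) stop("empty potential table", call. = FALSE)
  mean(potential$y1 - potential$y0)
}

#' Second-test priming effect conditional on first-test failure
#'
#' Restricts to (subject, word) pairs whose first-test identification failed
#' (`y = 0` at `test_index` 1) and contrasts the arms' second-test success
#' proportions among them. This measures whether the initial word study still
#' primes the second attempt after a failed first attempt. Counting pools
#' conditioning pairs across subjects within each arm.
#'
#' @param table a [trial_table()] containing `test_index` 1 and 2 rows.
#' @return An [effect_estimate()].
#' @export
conditional_second_test_dpe <- function(table) {
  df <- tibble::as_tibble(table)
  if (!all(c(1L, 2L) %in% df$test_index)) {
    stop("table must contain test_index 1 and 2 rows", call. = FALSE)
  }
  t1 <- df[df$test_index == 1L, c("subject_id", "word_id", "y")]
  failures <- t1[t1$y == 0L, c("subject_id", "word_id")]
  t2 <- dplyr::inner_join(df[df$test_index == 2L, ], failures,
                          by = c("subject_id", "word_id"))
  n1 <- sum(t2$z == 1L); n0 <- sum(t2$z == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("conditioning set empty in the z=",
         if (n1 == 0) "1" else "0", " arm", call. = FALSE)
  }
  effect_estimate(p1_hat = sum(t2$y[t2$z == 1L]) / n1,
                  p0_hat = sum(t2$y[t2$z == 0L]) / n0,
                  n1 = n1, n0 = n0, estimator = "conditional_second_test")
}

#' Inclusion/exclusion recollection contrast
#'
#' For a three-phase design, the difference between the proportion of
#' Phase-1 items called "old" under the inclusion instruction and under the
#' exclusion instruction,
#' \deqn{\hat p_i - \hat p_e,}
#' which estimates the probability of consciously recollecting a Phase-1
#' item: recollected items are called old under inclusion but withheld under
#' exclusion, while familiarity-driven responses contribute equally to both
#' instructions.
#'
#' @param table a [trial_table()] with inclusion and exclusion instruction
#'   groups and Phase-1 items.
#' @return An object of class `inclusion_exclusion_estimate` with fields
#'   `p_inclusion`, `p_exclusion`, `contrast` and the per-group Phase-1 trial
#'   counts.
#' @export
inclusion_exclusion_contrast <- function(table) {
  df <- tibble::as_tibble(table)
  p1 <- df[df$phase_origin == "phase1", ]
  for (instr in c("inclusion", "exclusion")) {
    if (!any(p1$instruction == instr)) {
      stop("no Phase-1 trials under the ", instr, " instruction",
           call. = FALSE)
    }
  }
  inc <- p1[p1$instruction == "inclusion", ]
  exc <- p1[p1$instruction == "exclusion", ]
  structure(list(p_inclusion = mean(inc$y),
                 p_exclusion = mean(exc$y),
                 contrast = mean(inc$y) - mean(exc$y),
                 n_inclusion = nrow(inc), n_exclusion = nrow(exc)),
            class = "inclusion_exclusion_estimate")
}

#' @export
print.inclusion_exclusion_estimate <- function(x, ...) {
  cat(sprintf(
    "Recollection contrast p_i - p_e = %.4f (p_i = %.4f, p_e = %.4f)\n",
    x$contrast, x$p_inclusion, x$p_exclusion))
  invisible(x)
}
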