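#' Covariate-adjusted priming effect by logistic regression
#'
#' Randomization balances covariates only in expectation; chance imbalance
#' in a finite sample (or outright confounded uptake of the word study) can
#' bias the raw difference in proportions. Adjustment fits the trial-level
#' logistic model
#' \deqn{\mathrm{logit}\, P(Y = 1) = \beta_0 + \beta_z z + \beta_w^\top w,}
#' where `z` is the word-study indicator and `w` the subject covariates. The
#' treatment coefficient `beta_z` is the covariate-adjusted priming effect on
#' the log-odds scale. Two probability-scale summaries are reported:
#' `transformed_effect = exp(beta_z) / (1 + exp(beta_z))`, the conventional
#' logistic transform of the treatment coefficient, and `marginal_effect`,
#' the standardization (g-computation) estimate — the average over all trials
#' of the fitted success probability with `z` set to 1 minus that with `z`
#' set to 0, which is directly comparable to [estimate_dpe()] and to the
#' simulator's true average priming effect. The fit is by maximum likelihood
#' via [stats::glm()] (relative deviance change below 1e-8 or 100
#' iterations); rows are trials, so within-subject correlation is ignored —
#' the same simplification the unadjusted estimator makes.
#'
#' @param table a [trial_table()] whose covariates are complete.
#' @param covariate_names covariate names without the `cov_` prefix,
#'   e.g. `"iq"`; must exist as `cov_<name>` columns.
#' @param test_index which test's trials to use (default 1).
#' @return An object of class `adjusted_effect`: `beta0`, `beta_z`, `beta_w`
#'   (named), `standard_errors`, `transformed_effect`, `marginal_effect`,
#'   `converged`, `n_used`.
#' @export
fit_logistic_adjustment <- function(table, covariate_names,
                                    test_index = 1L) {
  df <- tibble::as_tibble(table)
  df <- df[df$test_index == test_index, ]
  cols <- paste0("cov_", covariate_names)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("covariate column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (sum(df$z == 1L) == 0 || sum(df$z == 0L) == 0) {
    stop("both arms must be nonempty", call. = FALSE)
  }
  fml <- as.formula(paste("y ~ z +", paste(cols, collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, family = binomial(), data = df,
        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  cf <- coef(fit)
  if (anyNA(cf)) stop("rank-deficient design", call. = FALSE)
  # divergent slopes flag separation; the intercept tracks covariate scale
  if (any(abs(cf[-1]) > 15) || !fit$converged) {
    stop("separation: a coefficient diverged (|beta| > 15)", call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))
  beta_z <- unname(cf["z"])
  # g-computation: average predicted risk difference over the observed
  # covariate distribution
  d1 <- df; d1$z <- 1L
  d0 <- df; d0$z <- 0L
  marginal <- mean(stats::predict(fit, newdata = d1, type = "response") -
                     stats::predict(fit, newdata = d0, type = "response"))
  structure(list(beta0 = unname(cf["(Intercept)"]),
                 beta_z = beta_z,
                 beta_w = cf[cols],
                 standard_errors = se,
                 transformed_effect = plogis(beta_z),
                 marginal_effect = marginal,
                 converged = fit$converged,
                 n_used = nrow(df)),
            class = "adjusted_effect")
}

#' @export
print.adjusted_effect <- function(x, ...) {
  cat("Covariate-adjusted priming effect (trial-level logistic model)\n")
  cat(sprintf("  beta_z = %.4f (SE %.4f); transformed exp(b)/(1+exp(b)) = %.4f\n",
              x$beta_z, x$standard_errors["z"], x$transformed_effect))
  cat(sprintf("  standardized marginal risk difference = %.4f  (n = %d trials)\n",
              x$marginal_effect, x$n_used))
  invisible(x)
}

#' Propensity-score matching of exposed to unexposed subjects
#'
#' For exposures that cannot be randomized (e.g. medication), estimates each
#' subject's propensity score — the probability of exposure given covariates
#' — by maximum-likelihood logistic regression, then pairs each exposed
#' subject with the unexposed subject of closest score. Matching is greedy:
#' exposed subjects are processed in descending score order (ties broken by
#' subject id), each taking the nearest available control by absolute score
#' distance (ties again by subject id); by default controls are used without
#' replacement. With a caliper, pairs farther apart than `caliper` are
#' refused and the exposed subject counted as unmatched.
#'
#' @param subject_covariates one row per subject: `subject_id`, `exposure`
#'   (0/1) and one column per matching covariate.
#' @param caliper maximum admissible score distance, or `NULL` (default) for
#'   none.
#' @param with_replacement if `TRUE` a control may serve several exposed
#'   subjects.
#' @return An object of class `matched_sample`: `pairs` (tibble of
#'   `treated`, `control`, `distance`), `caliper`, `n_unmatched`,
#'   `propensity_scores` (tibble of `subject_id`, `exposure`, `score`).
#' @export
propensity_match <- function(subject_covariates, caliper = NULL,
                             with_replacement = FALSE) {
  df <- tibble::as_tibble(subject_covariates)
  stopifnot(all(c("subject_id", "exposure") %in% names(df)))
  if (sum(df$exposure == 1) < 1 || sum(df$exposure == 0) < 1) {
    stop("need at least one exposed and one unexposed subject",
         call. = FALSE)
  }
  covs <- setdiff(names(df), c("subject_id", "exposure"))
  if (length(covs) == 0) stop("no covariates to match on", call. = FALSE)
  fml <- as.formula(paste("exposure ~", paste(covs, collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, family = binomial(), data = df,
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- coef(fit)
  if (anyNA(cf) || any(abs(cf[-1]) > 15) || !fit$converged) {
    stop("separation in the propensity model", call. = FALSE)
  }
  score <- stats::predict(fit, type = "response")
  scores <- tibble::tibble(subject_id = as.character(df$subject_id),
                           exposure = as.integer(df$exposure),
                           score = unname(score))

  exposed <- scores[scores$exposure == 1L, ]
  controls <- scores[scores$exposure == 0L, ]
  exposed <- exposed[order(-exposed$score, exposed$subject_id), ]

  pairs <- list()
  available <- rep(TRUE, nrow(controls))
  n_unmatched <- 0L
  for (i in seq_len(nrow(exposed))) {
    idx <- if (with_replacement) seq_len(nrow(controls)) else which(available)
    if (length(idx) == 0) { n_unmatched <- n_unmatched + 1L; next }
    dist <- abs(controls$score[idx] - exposed$score[i])
    ord <- order(dist, controls$subject_id[idx])
    best <- idx[ord[1]]
    d_best <- abs(controls$score[best] - exposed$score[i])
    if (!is.null(caliper) && d_best > caliper) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      treated = exposed$subject_id[i],
      control = controls$subject_id[best],
      distance = d_best)
    if (!with_replacement) available[best] <- FALSE
  }
  pairs <- if (length(pairs) > 0) dplyr::bind_rows(pairs) else
    tibble::tibble(treated = character(), control = character(),
                   distance = numeric())
  structure(list(pairs = pairs, caliper = caliper,
                 n_unmatched = n_unmatched,
                 propensity_scores = scores),
            class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("Propensity-matched sample: %d pairs, %d exposed unmatched\n",
              nrow(x$pairs), x$n_unmatched))
  if (!is.null(x$caliper)) cat("  caliper:", x$caliper, "\n")
  invisible(x)
}

#' Exposure effect on priming via matched strata
#'
#' After propensity matching on an exposure that cannot be randomized (such
#' as medication), the word-study priming effect is estimated separately
#' among matched exposed subjects and matched unexposed subjects, and the
#' exposure's effect on priming is their difference:
#' \deqn{DPE_{\mathrm{exposed}} - DPE_{\mathrm{unexposed}}.}
#' In the minimal four-subject scheme (one exposed studier A, one exposed
#' non-studier B, one unexposed studier C, one unexposed non-studier D over
#' M words) this is exactly
#' \eqn{(\bar Y_A - \bar Y_B) - (\bar Y_C - \bar Y_D)}.
#'
#' @param table a [trial_table()] carrying a per-subject exposure flag in
#'   column `cov_<exposure>`.
#' @param matched a [propensity_match()] result whose treated/control ids
#'   refer to subjects of `table`.
#' @param exposure name of the exposure covariate (default `"med"`).
#' @return An object of class `psm_contrast`: `dpe_exposed`,
#'   `dpe_unexposed` (both [effect_estimate()]s) and `contrast`.
#' @export
psm_priming_contrast <- function(table, matched, exposure = "med") {
  stopifnot(inherits(matched, "matched_sample"))
  df <- tibble::as_tibble(table)
  col <- paste0("cov_", exposure)
  if (!col %in% names(df)) {
    stop("exposure column not found: ", col, call. = FALSE)
  }
  subset_dpe <- function(ids, label) {
    sub <- df[df$subject_id %in% ids, ]
    if (sum(sub$z == 1L) == 0 || sum(sub$z == 0L) == 0) {
      stop("empty word-study arm among matched ", label, " subjects",
           call. = FALSE)
    }
    estimate_dpe(new_trial_table(sub, design = attr(table, "design"),
                                 crossed_words = TRUE))
  }
  dpe_exp <- subset_dpe(matched$pairs$treated, "exposed")
  dpe_unexp <- subset_dpe(matched$pairs$control, "unexposed")
  structure(list(dpe_exposed = dpe_exp, dpe_unexposed = dpe_unexp,
                 contrast = dpe_exp$estimate - dpe_unexp$estimate),
            class = "psm_contrast")
}

#' @export
print.psm_contrast <- function(x, ...) {
  cat(sprintf(
    "Exposure effect on priming: %.4f (exposed DPE %.4f, unexposed DPE %.4f)\n",
    x$contrast, x$dpe_exposed$estimate, x$dpe_unexposed$estimate))
  invisible(x)
}
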