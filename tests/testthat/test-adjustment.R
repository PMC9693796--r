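test_that("logistic fit matches an independent Newton-Raphson oracle", {
  set.seed(501)
  for (rep in 1:10) {
    n <- 400
    z <- rep(c(1L, 0L), each = n / 2)
    iq <- rnorm(n)
    p <- plogis(-0.5 + 0.6 * z + 0.8 * iq)
    y <- rbinom(n, 1, p)
    df <- make_trials(subject_id = sprintf("s%03d", seq_len(n)),
                      word_id = "w1", z = z, y = y, cov_iq = iq)
    fit <- fit_logistic_adjustment(trial_table(df), "iq")
    X <- cbind(1, z, iq)
    oracle <- logistic_ml_oracle(X, y)
    expect_equal(fit$beta0, oracle[1], tolerance = 1e-6)
    expect_equal(fit$beta_z, oracle[2], tolerance = 1e-6)
    expect_equal(unname(fit$beta_w["cov_iq"]), oracle[3], tolerance = 1e-6)
    expect_true(fit$converged)
    expect_equal(fit$n_used, n)
  }
})

test_that("transformed effect is the logistic transform and increases in beta_z", {
  set.seed(502)
  z <- rep(c(1L, 0L), each = 100)
  y <- rbinom(200, 1, plogis(-0.2 + 0.5 * z))
  df <- make_trials(sprintf("s%03d", 1:200), "w1", z, y, cov_iq = rnorm(200))
  fit <- fit_logistic_adjustment(trial_table(df), "iq")
  expect_equal(fit$transformed_effect, plogis(fit$beta_z))
  expect_gt(fit$transformed_effect, 0)
  expect_lt(fit$transformed_effect, 1)
  betas <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(plogis(betas)) > 0))
})

test_that("null and collapsible cases recover the proportion-scale answer", {
  # tau = 0: treatment coefficient within 3 SEs of zero
  sim0 <- simulate_experiment(sim_config(k_per_arm = 110, m_words = 24,
                                         tau = 0, covariate_effect = 0.5,
                                         sigma_subject = 0, sigma_word = 0,
                                         seed = 61))
  fit0 <- fit_logistic_adjustment(sim0$trials, "w")
  expect_lt(abs(fit0$beta_z), 3 * fit0$standard_errors["z"])

  # no covariate effect, balanced arms: beta_z close to the logit difference
  sim1 <- simulate_experiment(sim_config(k_per_arm = 110, m_words = 24,
                                         tau = 0.6, covariate_effect = 0,
                                         sigma_subject = 0, sigma_word = 0,
                                         seed = 62))
  fit1 <- fit_logistic_adjustment(sim1$trials, "w")
  est <- estimate_dpe(sim1$trials)
  logit_diff <- qlogis(est$p1_hat) - qlogis(est$p0_hat)
  expect_lt(abs(fit1$beta_z - logit_diff), 3 * fit1$standard_errors["z"])
})

test_that("separation and rank deficiency raise hard errors", {
  z <- rep(c(1L, 0L), each = 20)
  df <- make_trials(sprintf("s%03d", 1:40), "w1", z, y = z,
                    cov_iq = rnorm(40))
  expect_error(fit_logistic_adjustment(trial_table(df), "iq"), "separation")

  df2 <- make_trials(sprintf("s%03d", 1:40), "w1", z,
                     y = rbinom(40, 1, 0.5),
                     cov_a = rnorm(40))
  df2$cov_b <- df2$cov_a  # perfectly collinear copy
  expect_error(fit_logistic_adjustment(trial_table(df2), c("a", "b")),
               "rank-deficient")

  expect_error(fit_logistic_adjustment(trial_table(df2), "missing"),
               "cov_missing")
})

test_that("matching pairs duplicated covariate vectors at distance zero", {
  covs <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12),
    exposure = rep(c(1L, 0L), 6),
    age = rep(c(40, 45, 50, 55, 60, 65), each = 2),
    iq = rep(c(95, 108, 99, 120, 104, 111), each = 2))
  ms <- propensity_match(covs)
  expect_equal(nrow(ms$pairs), 6L)
  expect_equal(ms$n_unmatched, 0L)
  expect_true(all(ms$pairs$distance < 1e-12))
  # each exposed subject got its exact duplicate
  dup <- merge(ms$pairs, covs, by.x = "treated", by.y = "subject_id")
  dup <- merge(dup, covs, by.x = "control", by.y = "subject_id",
               suffixes = c("_t", "_c"))
  expect_equal(dup$age_t, dup$age_c)
})

test_that("a zero caliper with distinct scores leaves everyone unmatched", {
  set.seed(77)
  covs <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                         exposure = rep(c(1L, 0L), each = 10),
                         age = rnorm(20, mean = c(52, 48)))
  ms <- propensity_match(covs, caliper = 0)
  expect_equal(nrow(ms$pairs), 0L)
  expect_equal(ms$n_unmatched, 10L)
})

test_that("matching equals the brute-force greedy oracle and ignores row order", {
  set.seed(88)
  covs <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                         exposure = rep(c(1L, 0L), each = 10),
                         age = rnorm(20, mean = rep(c(51, 49), each = 10)),
                         iq = rnorm(20))
  ms <- propensity_match(covs)
  oracle <- greedy_match_oracle(ms$propensity_scores)
  expect_equal(as.data.frame(ms$pairs[, c("treated", "control")]), oracle)

  shuffled <- covs[sample(20), ]
  ms2 <- propensity_match(shuffled)
  expect_equal(ms$pairs, ms2$pairs)
})

test_that("matched exposure strata give the documented priming contrast", {
  # minimal four-subject scheme: one subject per (exposure, study) cell
  y_a <- c(1L, 1L, 0L, 1L); y_b <- c(0L, 1L, 0L, 0L)
  y_c <- c(1L, 0L, 0L, 0L); y_d <- c(0L, 0L, 1L, 0L)
  df <- dplyr::bind_rows(
    make_trials("A", sprintf("w%d", 1:4), 1L, y_a, cov_med = 1),
    make_trials("B", sprintf("w%d", 1:4), 0L, y_b, cov_med = 1),
    make_trials("C", sprintf("w%d", 1:4), 1L, y_c, cov_med = 0),
    make_trials("D", sprintf("w%d", 1:4), 0L, y_d, cov_med = 0))
  tab <- trial_table(df)
  matched <- structure(list(
    pairs = tibble::tibble(treated = c("A", "B"), control = c("C", "D"),
                           distance = c(0, 0)),
    caliper = NULL, n_unmatched = 0L, propensity_scores = NULL),
    class = "matched_sample")
  ctr <- psm_priming_contrast(tab, matched)
  expected <- (mean(y_a) - mean(y_b)) - (mean(y_c) - mean(y_d))
  expect_equal(ctr$contrast, expected)
  expect_equal(ctr$contrast,
               ctr$dpe_exposed$estimate - ctr$dpe_unexposed$estimate)

  # identical outcome patterns in both strata: contrast exactly zero
  df0 <- df
  df0$y <- rep(c(y_a, y_b), 2)
  expect_equal(psm_priming_contrast(trial_table(df0), matched)$contrast, 0)
})

test_that("a drug-by-study interaction yields a mostly positive contrast", {
  wins <- vapply(1:40, function(r) {
    sim <- simulate_drug_priming(k_per_stratum = 100, interaction = 0.5,
                                 seed = 9000 + r)
    ms <- propensity_match(sim$subjects[, c("subject_id", "exposure", "age")])
    psm_priming_contrast(sim$trials, ms)$contrast > 0
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("matched and unmatched estimates agree without confounding", {
  set.seed(404)
  sim <- simulate_drug_priming(k_per_stratum = 150, interaction = 0,
                               seed = 11)
  # exposure affects neither outcome nor covariate balance materially
  ms <- propensity_match(sim$subjects[, c("subject_id", "exposure", "age")])
  ctr <- psm_priming_contrast(sim$trials, ms)
  dpe_all <- estimate_dpe(sim$trials)
  se <- sqrt(1 / dpe_all$n1 + 1 / dpe_all$n0)  # conservative binomial bound
  expect_lt(abs(ctr$contrast), 4 * se)
})
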