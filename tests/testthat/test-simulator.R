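test_that("observed outcomes obey consistency and the monotone contract", {
  for (mono in c(TRUE, FALSE)) {
    sim <- simulate_experiment(sim_config(k_per_arm = 15, m_words = 8,
                                          covariate_effect = 0.7,
                                          monotone = mono, seed = 91))
    joined <- dplyr::inner_join(
      tibble::as_tibble(sim$trials),
      tibble::as_tibble(sim$potential),
      by = c("subject_id", "word_id"))
    expect_equal(joined$y, joined$z * joined$y1 + (1 - joined$z) * joined$y0)
    if (mono) expect_true(all(joined$y1 >= joined$y0))
    expect_equal(attr(sim$potential, "true_ape"),
                 mean(sim$potential$y1 - sim$potential$y0))
  }
})

test_that("identical seeds give byte-identical output; seeds differ otherwise", {
  cfg <- sim_config(k_per_arm = 8, m_words = 6, seed = 123)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(tibble::as_tibble(s1$trials), tibble::as_tibble(s2$trials))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_trials(s1$trials, p1); write_trials(s2$trials, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  s3 <- simulate_experiment(sim_config(k_per_arm = 8, m_words = 6, seed = 124))
  expect_false(identical(s1$trials$y, s3$trials$y))
})

test_that("enlarging the design leaves existing units' draws unchanged", {
  small <- simulate_experiment(sim_config(k_per_arm = 5, m_words = 4,
                                          assignment = "matched", seed = 6))
  large <- simulate_experiment(sim_config(k_per_arm = 5, m_words = 7,
                                          assignment = "matched", seed = 6))
  shared <- dplyr::inner_join(
    tibble::as_tibble(small$potential),
    tibble::as_tibble(large$potential),
    by = c("subject_id", "word_id"), suffix = c("_s", "_l"))
  expect_equal(nrow(shared), nrow(small$potential))
  expect_equal(shared$y1_s, shared$y1_l)
  expect_equal(shared$y0_s, shared$y0_l)
})

test_that("the flat null yields Bernoulli(0.5) trials and near-zero APE", {
  sim <- simulate_experiment(sim_config(k_per_arm = 250, m_words = 20,
                                        mu = 0, tau = 0, sigma_subject = 0,
                                        sigma_word = 0, monotone = FALSE,
                                        seed = 17))
  n <- nrow(sim$potential)
  expect_equal(n, 10000L)
  # mean success near 0.5 and true_ape within 4 Monte-Carlo SEs of 0
  expect_lt(abs(mean(sim$trials$y) - 0.5), 4 * sqrt(0.25 / n))
  se_ape <- stats::sd(sim$potential$y1 - sim$potential$y0) / sqrt(n)
  expect_lt(abs(true_ape(sim$potential)), 4 * se_ape)
})

test_that("an overwhelming priming effect gives a positive DPE every time", {
  positive <- vapply(1:100, function(r) {
    sim <- simulate_experiment(sim_config(k_per_arm = 50, m_words = 24,
                                          tau = 50, mu = -1.1,
                                          seed = 5000 + r))
    estimate_dpe(sim$trials)$estimate > 0
  }, logical(1))
  expect_true(all(positive))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(k_per_arm = 0), "k_per_arm")
  expect_error(sim_config(sigma_subject = -1), "nonnegative")
  expect_error(sim_config(assignment = "haphazard"))
  expect_error(mpt_params(0.5, 1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("MPT generator collapses to its branch probabilities", {
  rate1 <- function(params, k, m, seed = 3) {
    tab <- simulate_mpt_experiment(params, k, m, seed = seed)
    mean(tab$y[tab$z == 1L])
  }
  # 10^4 treated trials; binomial SE ~ 0.005
  expect_lt(abs(rate1(mpt_params(0.2, 0, 0.9, 0.3), 100, 100) - 0.3), 0.015)
  expect_lt(abs(rate1(mpt_params(0.2, 1, 0.9, 0.3), 100, 100) - 0.9), 0.010)
  expect_lt(abs(rate1(mpt_params(0.25, 0.5, 0.8, 0.25), 100, 100) - 0.525),
            0.016)
  tab <- simulate_mpt_experiment(mpt_params(0.25, 0.5, 0.8, 0.25), 100, 100)
  expect_lt(abs(mean(tab$y[tab$z == 0L]) - 0.25), 0.014)
})

test_that("two-test generator handles carryover and cue modes", {
  cfg0 <- sim_config(k_per_arm = 40, m_words = 24, carryover = 0, seed = 21)
  t0 <- simulate_two_test(cfg0)
  m1 <- mean(t0$y[t0$test_index == 1L])
  m2 <- mean(t0$y[t0$test_index == 2L])
  expect_lt(abs(m1 - m2), 4 * sqrt(0.5 / sum(t0$test_index == 1L)))

  # carryover raises conditional second-test success among first-test
  # failures in (nearly) every replicate
  cond2 <- function(carry, seed) {
    cfg <- sim_config(k_per_arm = 30, m_words = 24, carryover = carry,
                      seed = seed)
    est <- conditional_second_test_dpe(simulate_two_test(cfg))
    (est$p1_hat * est$n1 + est$p0_hat * est$n0) / (est$n1 + est$n0)
  }
  wins <- vapply(1:60, function(r) {
    cond2(2, 7000 + r) > cond2(0, 7000 + r)
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  same <- simulate_two_test(cfg0, cue_mode = "same")
  expect_identical(t0$y, same$y)
  expect_identical(t0$subject_id, same$subject_id)
  expect_false(identical(t0$cue_id, same$cue_id))
})

test_that("inclusion/exclusion generator matches its closed forms", {
  # recollection 0: both instructions converge to the same phase-1 rate
  t0 <- simulate_inclusion_exclusion(40, 10, 10, recollection = 0,
                                     familiarity = 0.4, k_per_group = 60,
                                     seed = 8)
  c0 <- inclusion_exclusion_contrast(t0)
  expect_lt(abs(c0$contrast), 4 * sqrt(2 * 0.4 * 0.6 / 2400))

  # recollection 1: inclusion rate 1, exclusion rate 0, exactly
  t1 <- simulate_inclusion_exclusion(20, 5, 5, recollection = 1,
                                     familiarity = 0.4, k_per_group = 10,
                                     seed = 9)
  c1 <- inclusion_exclusion_contrast(t1)
  expect_equal(c1$p_inclusion, 1)
  expect_equal(c1$p_exclusion, 0)

  expect_error(simulate_inclusion_exclusion(10, 5, 5, 1.2, 0.4, 5),
               "probabilities")
})

test_that("YAML configs round-trip into sim_config", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("k_per_arm: 7", "m_words: 3", "tau: 0.8",
               "assignment: matched", "seed: 99"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$k_per_arm, 7L)
  expect_equal(cfg$tau, 0.8)
  expect_equal(cfg$assignment, "matched")
  expect_equal(cfg$sigma_word, 0.5)  # default preserved
  writeLines("k_per_word: 7", path)
  expect_error(read_sim_config(path), "unknown config key")
})
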