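# Builders for tiny hand-written trial tables and independent oracles used
# across the test files. Everything here is constructed in code; nothing is
# read from disk.

make_trials <- function(subject_id, word_id, z, y,
                        test_index = 1L,
                        cue_id = paste0("cue_", word_id),
                        instruction = "completion",
                        phase_origin = "none", ...) {
  tibble::tibble(subject_id = subject_id, word_id = word_id, cue_id = cue_id,
                 test_index = test_index, z = z, y = y,
                 instruction = instruction, phase_origin = phase_origin, ...)
}

# Two disjoint arms with fixed success counts: n subjects per arm, one word
# per trial, s1 / s0 successes.
two_arm_table <- function(s1, n1, s0, n0) {
  trial_table(make_trials(
    subject_id = c(sprintf("t%02d", seq_len(n1)), sprintf("c%02d", seq_len(n0))),
    word_id = "w1",
    z = rep(c(1L, 0L), c(n1, n0)),
    y = c(rep(1:0, c(s1, n1 - s1)), rep(1:0, c(s0, n0 - s0)))
  ))
}

# Eight-row two-test fixture with a hand-counted conditional second-test
# effect. Test-1 failures: (s1, w1) in the z=1 arm with test-2 success 1/1;
# (s2, w1) and (s2, w2) in the z=0 arm with test-2 successes 1/2. Expected
# conditional DPE = 1 - 0.5 = 0.5.
conditional_fixture <- function() {
  trial_table(make_trials(
    subject_id = rep(c("s1", "s2"), each = 4),
    word_id = rep(c("w1", "w2"), 4),
    test_index = rep(rep(1:2, each = 2), 2),
    z = rep(c(1L, 0L), each = 4),
    y = c(0L, 1L, 1L, 0L,   # s1 (z=1): t1 w1 fail, w2 success; t2 w1=1, w2=0
          0L, 0L, 0L, 1L)   # s2 (z=0): t1 both fail; t2 w1=0, w2=1
  ))
}

# Independent maximum-likelihood logistic oracle: direct Newton-Raphson on
# the log-likelihood, no glm machinery.
logistic_ml_oracle <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - p))
    W <- p * (1 - p)
    H <- crossprod(X * W, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

# Independent greedy matching oracle mirroring the documented rule with
# plain loops over a distance matrix.
greedy_match_oracle <- function(scores) {
  ex <- scores[scores$exposure == 1L, ]
  co <- scores[scores$exposure == 0L, ]
  ex <- ex[order(-ex$score, ex$subject_id), ]
  co_avail <- rep(TRUE, nrow(co))
  out <- NULL
  for (i in seq_len(nrow(ex))) {
    if (!any(co_avail)) break
    cand <- which(co_avail)
    d <- abs(co$score[cand] - ex$score[i])
    best <- cand[order(d, co$subject_id[cand])[1]]
    out <- rbind(out, data.frame(treated = ex$subject_id[i],
                                 control = co$subject_id[best],
                                 stringsAsFactors = FALSE))
    co_avail[best] <- FALSE
  }
  out
}

# Generator for a drug-effect-on-priming scenario: per-subject exposure
# (med) driven by a covariate, word-study arm randomized within exposure
# strata, and an optional drug-by-study interaction on the log-odds scale.
simulate_drug_priming <- function(k_per_stratum = 50, m_words = 24,
                                  mu = -1, tau = 0.5, interaction = 0,
                                  seed = 1) {
  set.seed(seed)
  n <- 4L * k_per_stratum
  med <- rep(c(1L, 0L), each = 2L * k_per_stratum)
  z <- rep(c(1L, 0L, 1L, 0L), each = k_per_stratum)
  age <- stats::rnorm(n, mean = 50 + 2 * med, sd = 3)
  ids <- sprintf("s%03d", seq_len(n))
  words <- sprintf("w%03d", seq_len(m_words))
  lin <- mu + tau * z + interaction * z * med
  p <- stats::plogis(lin)
  y <- matrix(stats::rbinom(n * m_words, 1, rep(p, each = m_words)),
              nrow = m_words)
  trials <- make_trials(
    subject_id = rep(ids, each = m_words),
    word_id = rep(words, n),
    z = rep(z, each = m_words),
    y = as.integer(y),
    cov_med = rep(med, each = m_words),
    cov_age = rep(age, each = m_words)
  )
  list(trials = trial_table(trials),
       subjects = tibble::tibble(subject_id = ids, exposure = med, age = age))
}
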