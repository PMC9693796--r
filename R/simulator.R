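#' Simulator configuration
#'
#' Settings for the potential-outcomes word-fragment-completion simulator.
#' The generative model is a logistic random-intercept model: subject ability,
#' word difficulty and an optional subject covariate enter the success
#' log-odds additively, and a word study shifts the log-odds by `tau`. This is
#' the simplest structure exhibiting the two sources of heterogeneity that
#' motivate averaging over subjects and over words — individual memory
#' variability and word variability.
#'
#' Defaults emulate the canonical between-subjects experiment this package
#' targets: 22 subjects per arm and 24 target words per list, a baseline
#' completion probability near 0.25 (`mu = -1.1` log-odds) and a priming
#' effect of about 0.10 on the probability scale (`tau = 0.5` log-odds),
#' with moderate subject and word heterogeneity (SD 0.5 each).
#'
#' @param k_per_arm subjects per arm (matched/randomized) or half the subject
#'   pool (confounded); >= 1.
#' @param m_words number of target words; >= 1.
#' @param mu baseline log-odds of correct identification.
#' @param tau priming effect of the word study on the log-odds scale.
#' @param sigma_subject SD of subject random intercepts (ability); >= 0.
#' @param sigma_word SD of word random intercepts (difficulty); >= 0.
#' @param covariate_effect log-odds effect of a standard-normal subject
#'   covariate (e.g. IQ) on identification.
#' @param assignment `"randomized"` (arms of exactly `k_per_arm` drawn at
#'   random), `"matched"` (every treated subject has a control clone sharing
#'   ability, covariate and all per-word draws — the perfectly matched
#'   design), or `"confounded"` (each subject self-selects with probability
#'   `plogis(confounding_strength * w)`).
#' @param confounding_strength log-odds effect of the covariate on treatment
#'   uptake; used only under `"confounded"` assignment.
#' @param carryover log-odds bonus applied to second-test trials of words
#'   attempted at the first test (see [simulate_two_test()]).
#' @param monotone if `TRUE` (default) both potential outcomes share one
#'   uniform draw per (subject, word), so a positive `tau` can never make
#'   studying hurt (`y1 >= y0` rowwise); if `FALSE` the two potential
#'   outcomes are drawn independently.
#' @param seed integer root seed. Sub-streams per subject and per word are
#'   derived deterministically from it, so enlarging `k_per_arm` or `m_words`
#'   leaves already-generated units unchanged.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(k_per_arm = 22L, m_words = 24L,
                       mu = -1.1, tau = 0.5,
                       sigma_subject = 0.5, sigma_word = 0.5,
                       covariate_effect = 0,
                       assignment = c("randomized", "matched", "confounded"),
                       confounding_strength = 1,
                       carryover = 0,
                       monotone = TRUE,
                       seed = 1L) {
  assignment <- match.arg(assignment)
  if (k_per_arm < 1 || m_words < 1) {
    stop("k_per_arm and m_words must be >= 1", call. = FALSE)
  }
  if (sigma_subject < 0 || sigma_word < 0) {
    stop("random-intercept SDs must be nonnegative", call. = FALSE)
  }
  structure(list(k_per_arm = as.integer(k_per_arm),
                 m_words = as.integer(m_words),
                 mu = mu, tau = tau,
                 sigma_subject = sigma_subject, sigma_word = sigma_word,
                 covariate_effect = covariate_effect,
                 assignment = assignment,
                 confounding_strength = confounding_strength,
                 carryover = carryover,
                 monotone = isTRUE(monotone),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' All keys are optional; absent keys take the [sim_config()] defaults.
#'
#' @param path a YAML file of `key: value` pairs matching [sim_config()]
#'   argument names.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

# Deterministic sub-stream seed: one root seed, disjoint streams for
# subjects (1), words (2), assignment (3). Keeps every derived seed in
# [0, 2^31 - 1) and stable under changes of k or m.
sub_seed <- function(seed, stream, index = 0L) {
  (abs(seed) * 1e6 + stream * 1e5 + index) %% 2147483647
}

# Per-subject draws in a fixed layout so every generator sees the same
# stream: ability, covariate, then four uniform blocks of length m
# (test-1 shared, test-1 independent, test-2 shared, test-2 independent).
subject_draws <- function(seed, i, m, sigma_subject) {
  set.seed(sub_seed(seed, 1, i))
  list(a = rnorm(1, 0, sigma_subject),
       w = rnorm(1),
       u1 = runif(m), u1b = runif(m),
       u2 = runif(m), u2b = runif(m))
}

# Column-per-subject matrices of the per-subject draws for n subjects.
subject_draw_matrix <- function(seed, n, m, sigma_subject) {
  a <- numeric(n); w <- numeric(n)
  u1 <- matrix(0, m, n); u1b <- matrix(0, m, n)
  u2 <- matrix(0, m, n); u2b <- matrix(0, m, n)
  for (i in seq_len(n)) {
    d <- subject_draws(seed, i, m, sigma_subject)
    a[i] <- d$a; w[i] <- d$w
    u1[, i] <- d$u1; u1b[, i] <- d$u1b
    u2[, i] <- d$u2; u2b[, i] <- d$u2b
  }
  list(a = a, w = w, u1 = u1, u1b = u1b, u2 = u2, u2b = u2b)
}

word_effects <- function(seed, m, sigma_word) {
  vapply(seq_len(m), function(j) {
    set.seed(sub_seed(seed, 2, j))
    rnorm(1, 0, sigma_word)
  }, numeric(1))
}

subject_labels <- function(n, prefix = "s") {
  sprintf("%s%03d", prefix, seq_len(n))
}

word_labels <- function(m) sprintf("w%03d", seq_len(m))

#' Simulate a between-subjects priming experiment with potential outcomes
#'
#' Generates one word-fragment-completion experiment under the logistic
#' random-intercept model of [sim_config()]. For every subject \eqn{i} and
#' word \eqn{j} the success probability under study status \eqn{z} is
#' \deqn{P(Y(z) = 1) = \mathrm{logit}^{-1}(\mu + a_i + b_j + \gamma w_i +
#'   \tau z),}
#' with \eqn{a_i \sim N(0, \sigma_s^2)}, \eqn{b_j \sim N(0, \sigma_w^2)} and
#' \eqn{w_i \sim N(0, 1)}. Both potential outcomes are realised for every
#' pair, so the sample average priming effect — unobservable in a real
#' experiment — is an exact quantity here, returned as `true_ape`. The
#' observed outcome obeys consistency: `y = z * y1 + (1 - z) * y0`.
#'
#' Under `"matched"` assignment each treated subject is cloned into a control
#' subject sharing its ability, covariate and per-word uniform draws; the
#' observed difference in proportions then equals the sample average priming
#' effect exactly. Under `"randomized"` the two arms are an exact random
#' split, making the difference in proportions unbiased. Under `"confounded"`
#' treatment uptake depends on the covariate, biasing the unadjusted
#' difference when `covariate_effect != 0`.
#'
#' @param config a [sim_config()].
#' @return A list with `potential` (a `potential_table`: one row per
#'   (subject, word) with both potential outcomes `y1`, `y0` and attribute
#'   `true_ape`) and `trials` (a [trial_table()] of the observed experiment,
#'   covariate in column `cov_w`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k_per_arm; m <- config$m_words
  n_subj <- 2L * k

  b <- word_effects(config$seed, m, config$sigma_word)
  words <- word_labels(m)

  if (config$assignment == "matched") {
    # k treated subjects, each cloned into a control sharing all draws
    d <- subject_draw_matrix(config$seed, k, m, config$sigma_subject)
    d <- list(a = c(d$a, d$a), w = c(d$w, d$w),
              u1 = cbind(d$u1, d$u1), u1b = cbind(d$u1b, d$u1b))
    ids <- c(subject_labels(k, "t"), subject_labels(k, "c"))
    z_subj <- rep(c(1L, 0L), each = k)
  } else {
    d <- subject_draw_matrix(config$seed, n_subj, m, config$sigma_subject)
    ids <- subject_labels(n_subj)
    set.seed(sub_seed(config$seed, 3, 0))
    if (config$assignment == "randomized") {
      treated <- sample(n_subj, k)
      z_subj <- as.integer(seq_len(n_subj) %in% treated)
    } else {
      p_take <- plogis(config$confounding_strength * d$w)
      z_subj <- as.integer(runif(n_subj) < p_take)
    }
  }
  n_all <- length(ids)

  # m x n matrices: words index rows, subjects index columns
  lin <- outer(b, config$mu + d$a + config$covariate_effect * d$w, `+`)
  p1 <- plogis(lin + config$tau)
  p0 <- plogis(lin)
  y1 <- (d$u1 < p1) + 0L
  u0 <- if (config$monotone) d$u1 else d$u1b
  y0 <- (u0 < p0) + 0L
  z_mat <- matrix(z_subj, m, n_all, byrow = TRUE)

  po <- tibble::tibble(
    subject_id = rep(ids, each = m),
    word_id = rep(words, n_all),
    y1 = as.integer(y1), y0 = as.integer(y0),
    z = as.integer(z_mat), cov_w = rep(d$w, each = m))

  potential <- new_potential_table(po[, c("subject_id", "word_id", "y1", "y0")])
  trials <- tibble::tibble(
    subject_id = po$subject_id,
    word_id = po$word_id,
    cue_id = paste0("cue_", po$word_id),
    test_index = 1L,
    z = po$z,
    y = po$z * po$y1 + (1L - po$z) * po$y0,
    instruction = "completion",
    phase_origin = "none",
    cov_w = po$cov_w
  )
  list(potential = potential,
       trials = new_trial_table(trials, design = "between_subjects",
                                crossed_words = FALSE))
}

new_potential_table <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("potential_table", class(tibble::tibble())),
            true_ape = mean(df$y1 - df$y0))
}

#' Simulate a two-test priming experiment
#'
#' As [simulate_experiment()], but every (subject, word) pair is tested
#' twice. Second-test success log-odds gain the `carryover` bonus of the
#' configuration, modelling learning from the first attempt (all words are
#' attempted at test 1). Cue identifiers differ between tests under
#' `cue_mode = "different"` and repeat under `"same"`; cue labels never enter
#' the outcome model, so the two modes yield identical outcomes for the same
#' seed.
#'
#' @param config a [sim_config()].
#' @param cue_mode `"different"` (default) or `"same"`: whether the second
#'   test re-uses the first test's fragment cue.
#' @return A [trial_table()] with `test_index` 1 and 2 rows.
#' @export
simulate_two_test <- function(config, cue_mode = c("different", "same")) {
  cue_mode <- match.arg(cue_mode)
  stopifnot(inherits(config, "sim_config"))
  k <- config$k_per_arm; m <- config$m_words
  n_subj <- 2L * k

  b <- word_effects(config$seed, m, config$sigma_word)
  words <- word_labels(m)
  draws <- lapply(seq_len(n_subj), subject_draws, seed = config$seed, m = m,
                  sigma_subject = config$sigma_subject)
  ids <- subject_labels(n_subj)
  set.seed(sub_seed(config$seed, 3, 0))
  treated <- sample(n_subj, k)
  z_subj <- as.integer(seq_len(n_subj) %in% treated)

  rows <- lapply(seq_len(n_subj), function(i) {
    d <- draws[[i]]
    z <- z_subj[i]
    lin <- config$mu + d$a + b + config$covariate_effect * d$w +
      config$tau * z
    p_t1 <- plogis(lin)
    p_t2 <- plogis(lin + config$carryover)
    y_t1 <- as.integer(d$u1 < p_t1)
    y_t2 <- as.integer(d$u2 < p_t2)
    cue1 <- paste0("cue_", words, "_1")
    cue2 <- if (cue_mode == "same") cue1 else paste0("cue_", words, "_2")
    tibble::tibble(
      subject_id = ids[i],
      word_id = rep(words, 2L),
      cue_id = c(cue1, cue2),
      test_index = rep(c(1L, 2L), each = m),
      z = z,
      y = c(y_t1, y_t2),
      instruction = "completion",
      phase_origin = "none",
      cov_w = d$w
    )
  })
  new_trial_table(dplyr::bind_rows(rows), design = "between_subjects",
                  crossed_words = FALSE,
                  time_labels = c(`1` = "t1", `2` = "t2"))
}

#' Simulate a priming experiment from multinomial-processing-tree parameters
#'
#' Control-arm (`z = 0`) trials succeed with probability `A`. Treated-arm
#' (`z = 1`) trials follow the storage tree: with probability `B` the studied
#' word was stored and the trial succeeds with probability `C`; otherwise it
#' succeeds with probability `D`. The treated marginal success probability is
#' therefore `B*C + D*(1 - B)`; see [mpt_forward()].
#'
#' @param params an [mpt_params()].
#' @param k_per_arm subjects per arm.
#' @param m_words words per subject.
#' @param seed integer root seed.
#' @return A [trial_table()].
#' @export
simulate_mpt_experiment <- function(params, k_per_arm, m_words, seed = 1L) {
  stopifnot(inherits(params, "mpt_params"))
  if (k_per_arm < 1 || m_words < 1) {
    stop("k_per_arm and m_words must be >= 1", call. = FALSE)
  }
  n_subj <- 2L * k_per_arm
  z_subj <- rep(c(1L, 0L), each = k_per_arm)
  ids <- subject_labels(n_subj)
  words <- word_labels(m_words)

  rows <- lapply(seq_len(n_subj), function(i) {
    set.seed(sub_seed(seed, 1, i))
    u_store <- runif(m_words)
    u_succ <- runif(m_words)
    if (z_subj[i] == 1L) {
      stored <- u_store < params$B
      p <- ifelse(stored, params$C, params$D)
    } else {
      p <- params$A
    }
    tibble::tibble(
      subject_id = ids[i], word_id = words,
      cue_id = paste0("cue_", words),
      test_index = 1L, z = z_subj[i],
      y = as.integer(u_succ < p),
      instruction = "completion", phase_origin = "none"
    )
  })
  new_trial_table(dplyr::bind_rows(rows), design = "between_subjects",
                  crossed_words = FALSE)
}

#' Simulate a three-phase inclusion/exclusion experiment
#'
#' Two disjoint subject groups judge the same item list as "old" or "new",
#' one group under the inclusion instruction (call an item old if it appeared
#' in Phase 1 or Phase 2) and one under the exclusion instruction (call an
#' item old only if it appeared in Phase 2). Responses follow the standard
#' independence model of process dissociation, with recollection of Phase-1
#' items independent of their familiarity:
#' \deqn{P(\mathrm{old} \mid \mathrm{inclusion}) = r + (1 - r) f, \quad
#'       P(\mathrm{old} \mid \mathrm{exclusion}) = (1 - r) f}
#' for Phase-1 items, so the inclusion-minus-exclusion contrast of Phase-1
#' "old" rates identifies the recollection probability `r` exactly; see
#' [inclusion_exclusion_contrast()]. Phase-2 items are called old with a
#' fixed high probability (0.9, both instructions) and distractors with
#' probability `familiarity`.
#'
#' @param phase1_items,phase2_items,distractors item counts per phase.
#' @param recollection probability of consciously recollecting a Phase-1
#'   item.
#' @param familiarity probability that an unrecollected item still feels
#'   familiar enough to be called old.
#' @param k_per_group subjects per instruction group.
#' @param seed integer root seed.
#' @return A [trial_table()] with `design = "three_phase"`; `y = 1` encodes
#'   an "old" response, `z = 1` marks studied (Phase 1 or 2) items.
#' @export
simulate_inclusion_exclusion <- function(phase1_items, phase2_items,
                                         distractors, recollection,
                                         familiarity, k_per_group,
                                         seed = 1L) {
  if (phase1_items < 0 || phase2_items < 0 || distractors < 0 ||
      k_per_group < 1) {
    stop("item counts must be nonnegative and k_per_group >= 1",
         call. = FALSE)
  }
  if (recollection < 0 || recollection > 1 ||
      familiarity < 0 || familiarity > 1) {
    stop("recollection and familiarity must be probabilities in [0, 1]",
         call. = FALSE)
  }
  p2_old <- 0.9  # Phase-2 items are recent and well learned

  items <- tibble::tibble(
    word_id = c(sprintf("p1_%03d", seq_len(phase1_items)),
                sprintf("p2_%03d", seq_len(phase2_items)),
                sprintf("d_%03d", seq_len(distractors))),
    phase_origin = rep(c("phase1", "phase2", "distractor"),
                       c(phase1_items, phase2_items, distractors)),
    z = rep(c(1L, 1L, 0L), c(phase1_items, phase2_items, distractors))
  )
  n_items <- nrow(items)
  if (n_items == 0) stop("no items to simulate", call. = FALSE)

  p_old <- function(instruction) {
    base <- (1 - recollection) * familiarity
    dplyr::case_when(
      items$phase_origin == "phase2" ~ p2_old,
      items$phase_origin == "distractor" ~ familiarity,
      instruction == "inclusion" ~ recollection + base,
      TRUE ~ base
    )
  }

  groups <- list(inclusion = subject_labels(k_per_group, "i"),
                 exclusion = subject_labels(k_per_group, "e"))
  rows <- list()
  idx <- 0L
  for (instr in names(groups)) {
    p <- p_old(instr)
    for (s in groups[[instr]]) {
      idx <- idx + 1L
      set.seed(sub_seed(seed, 1, idx))
      rows[[idx]] <- tibble::tibble(
        subject_id = s, word_id = items$word_id,
        cue_id = items$word_id, test_index = 1L,
        z = items$z, y = as.integer(runif(n_items) < p),
        instruction = instr, phase_origin = items$phase_origin
      )
    }
  }
  new_trial_table(dplyr::bind_rows(rows), design = "three_phase",
                  crossed_words = TRUE)
}
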