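#' Trial-level data model for between-subjects priming experiments
#'
#' A `trial_table` is a tibble holding one observed binary word-identification
#' outcome per (subject, word, test) with its arm assignment, instruction
#' condition and optional subject-level covariates. It is the common currency
#' of the package: the simulator emits one, the file readers return one, and
#' every estimator consumes one.
#'
#' Mandatory columns:
#' \describe{
#'   \item{subject_id}{opaque subject identifier (character)}
#'   \item{word_id}{opaque target-word identifier (character)}
#'   \item{cue_id}{opaque fragment-cue identifier; in two-test designs the
#'     cue of the given test}
#'   \item{test_index}{1 or 2}
#'   \item{z}{treatment indicator, 1 = word study contained the target}
#'   \item{y}{binary identification outcome (pre-scored; answers with several
#'     correct completions are scored upstream)}
#'   \item{instruction}{one of `"completion"`, `"recall"`, `"inclusion"`,
#'     `"exclusion"`, `"none"`}
#'   \item{phase_origin}{one of `"phase1"`, `"phase2"`, `"distractor"`,
#'     `"none"`; meaningful only for three-phase designs}
#' }
#' Subject-level covariates are carried in columns named `cov_<name>` and must
#' be constant within a subject.
#'
#' @param trials a data frame with the columns above (covariates optional).
#' @param design `"between_subjects"` (default) or `"three_phase"`.
#' @param crossed_words set `TRUE` for crossed designs in which every subject
#'   contributes both studied (`z = 1`) and non-studied (`z = 0`) words, as in
#'   counterbalanced two-wordlist experiments; this relaxes the requirement
#'   that the treated and control subject sets be disjoint. Estimators pool
#'   word-level trials either way.
#' @param time_labels optional named character vector mapping test index to a
#'   nominal time label (descriptive metadata only).
#'
#' @return A `trial_table` (tibble subclass) with attributes `design`,
#'   `crossed_words` and `time_labels`.
#' @seealso [read_trials()], [write_trials()], [validate_design()]
#' @export
trial_table <- function(trials,
                        design = c("between_subjects", "three_phase"),
                        crossed_words = FALSE,
                        time_labels = NULL) {
  design <- match.arg(design)
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_mandatory_cols(), names(trials))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) stop("empty table", call. = FALSE)

  trials <- dplyr::mutate(
    trials,
    subject_id = as.character(.data$subject_id),
    word_id = as.character(.data$word_id),
    cue_id = as.character(.data$cue_id),
    test_index = as.integer(.data$test_index),
    z = as.integer(.data$z),
    y = as.integer(.data$y)
  )

  check <- check_trial_invariants(trials)
  if (any(check != "ok")) {
    bad <- table(check[check != "ok"])
    stop("invalid trial rows: ",
         paste(sprintf("%s (%d)", names(bad), bad), collapse = "; "),
         call. = FALSE)
  }
  if (design == "between_subjects" && !crossed_words) {
    overlap <- arm_subject_overlap(trials)
    if (length(overlap) > 0) {
      stop("subjects appear in both arms of a between-subjects design ",
           "(set crossed_words = TRUE for counterbalanced designs): ",
           paste(head(overlap, 5), collapse = ", "), call. = FALSE)
    }
  }

  new_trial_table(trials, design = design, crossed_words = crossed_words,
                  time_labels = time_labels)
}

new_trial_table <- function(trials, design, crossed_words, time_labels = NULL) {
  structure(trials,
            class = c("trial_table", class(tibble::tibble())),
            design = design,
            crossed_words = crossed_words,
            time_labels = time_labels)
}

trial_mandatory_cols <- function() {
  c("subject_id", "word_id", "cue_id", "test_index", "z", "y",
    "instruction", "phase_origin")
}

instruction_levels <- function() {
  c("completion", "recall", "inclusion", "exclusion", "none")
}

phase_levels <- function() c("phase1", "phase2", "distractor", "none")

covariate_cols <- function(trials) {
  grep("^cov_", names(trials), value = TRUE)
}

arm_subject_overlap <- function(trials) {
  intersect(unique(trials$subject_id[trials$z == 1L]),
            unique(trials$subject_id[trials$z == 0L]))
}

# Per-row invariant check; returns "ok" or a drop reason per row.
check_trial_invariants <- function(trials) {
  reason <- rep("ok", nrow(trials))
  flag <- function(cond, why) {
    hit <- which(cond & reason == "ok")
    reason[hit] <<- why
  }
  flag(!(trials$y %in% c(0L, 1L)) | is.na(trials$y), "outcome not binary")
  flag(!(trials$z %in% c(0L, 1L)) | is.na(trials$z), "treatment not binary")
  flag(!(trials$test_index %in% c(1L, 2L)) | is.na(trials$test_index),
       "test_index not in {1, 2}")
  flag(!(trials$instruction %in% instruction_levels()) |
         is.na(trials$instruction), "unknown instruction")
  flag(!(trials$phase_origin %in% phase_levels()) |
         is.na(trials$phase_origin), "unknown phase_origin")
  flag(duplicated(trials[, c("subject_id", "word_id", "test_index")]),
       "duplicate (subject, word, test)")
  covs <- covariate_cols(trials)
  if (length(covs) > 0) {
    has_na <- Reduce(`|`, lapply(trials[covs], is.na))
    bad_subj <- unique(trials$subject_id[has_na])
    # a subject's covariates must be complete and constant across trials
    for (cv in covs) {
      n_vals <- tapply(trials[[cv]], trials$subject_id,
                       function(x) length(unique(x)))
      bad_subj <- union(bad_subj, names(n_vals)[n_vals > 1])
    }
    flag(trials$subject_id %in% bad_subj, "incomplete or inconsistent covariates")
  }
  reason
}

#' Count subjects and words in a trial table
#'
#' @param table a [trial_table()].
#' @return `k_treated()` / `k_control()`: the number of distinct subjects with
#'   any `z = 1` (resp. `z = 0`) trial; `m_words()`: distinct words.
#' @export
k_treated <- function(table) length(unique(table$subject_id[table$z == 1L]))

#' @rdname k_treated
#' @export
k_control <- function(table) length(unique(table$subject_id[table$z == 0L]))

#' @rdname k_treated
#' @export
m_words <- function(table) length(unique(table$word_id))

#' Read a trial file
#'
#' Reads a delimited text file (header row required, column order free) into a
#' validated [trial_table()]. Rows violating the trial invariants — non-binary
#' `y` or `z`, test index outside \{1, 2\}, unknown instruction or phase
#' labels, duplicated (subject, word, test) keys, or subjects with missing or
#' inconsistent covariate values — are dropped and tallied per reason in the
#' accompanying validation report. The file schema is this package's own
#' interchange convention (no standard exists for trial-level priming data):
#' columns `subject_id, word_id, cue_id, test_index, z, y, instruction,
#' phase_origin` plus `cov_<name>` covariate columns, comma-delimited UTF-8
#' with `.` as the decimal mark.
#'
#' @param path file to read.
#' @param delim field delimiter (default `","`).
#' @param col_map optional named character vector renaming file columns to
#'   schema names, e.g. `c(subject = "subject_id")`.
#' @inheritParams trial_table
#' @return A list with elements `table` (a `trial_table`) and `report` (a
#'   [validation_report()]).
#' @export
read_trials <- function(path, delim = ",", col_map = NULL,
                        design = c("between_subjects", "three_phase"),
                        crossed_words = FALSE) {
  design <- match.arg(design)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(col_map)) {
    idx <- match(unname(col_map), names(raw))
    names(raw)[idx[!is.na(idx)]] <- names(col_map)[!is.na(idx)]
  }
  missing_cols <- setdiff(trial_mandatory_cols(), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("empty table", call. = FALSE)

  raw <- dplyr::mutate(
    raw,
    subject_id = as.character(.data$subject_id),
    word_id = as.character(.data$word_id),
    cue_id = as.character(.data$cue_id),
    test_index = suppressWarnings(as.integer(.data$test_index)),
    z = suppressWarnings(as.integer(.data$z)),
    y = suppressWarnings(as.integer(.data$y))
  )
  reason <- check_trial_invariants(raw)
  keep <- raw[reason == "ok", , drop = FALSE]
  dropped <- reason[reason != "ok"]
  if (nrow(keep) == 0) stop("empty table after filtering", call. = FALSE)

  warnings <- character()
  if (design == "between_subjects" && !crossed_words &&
      length(arm_subject_overlap(keep)) > 0) {
    warnings <- c(warnings,
                  "subjects appear in both arms; treating as crossed design")
    crossed_words <- TRUE
  }
  report <- validation_report(
    n_rows_read = nrow(raw),
    n_rows_dropped = length(dropped),
    drop_reasons = as.list(table(dropped)),
    warnings = warnings
  )
  list(table = new_trial_table(keep, design = design,
                               crossed_words = crossed_words),
       report = report)
}

#' Write a trial table to a delimited text file
#'
#' Emits the interchange format read by [read_trials()]; reading the result
#' back yields a field-identical table with zero dropped rows. Covariate
#' columns are written only when present.
#'
#' @param table a [trial_table()].
#' @param path destination file.
#' @param delim field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "trial_table"))
  cols <- c(trial_mandatory_cols(), covariate_cols(table))
  out <- tibble::as_tibble(table)[, cols]
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Validation report
#'
#' Bookkeeping record returned by [read_trials()] and [validate_design()]:
#' rows read, rows dropped with per-reason counts, and free-text warnings.
#'
#' @param n_rows_read rows present in the source.
#' @param n_rows_dropped rows removed for invariant violations.
#' @param drop_reasons named list of per-reason counts.
#' @param warnings character vector of advisory messages.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(n_rows_read = 0L, n_rows_dropped = 0L,
                              drop_reasons = list(), warnings = character()) {
  stopifnot(n_rows_read >= n_rows_dropped, n_rows_dropped >= 0)
  structure(list(n_rows_read = as.integer(n_rows_read),
                 n_rows_dropped = as.integer(n_rows_dropped),
                 drop_reasons = lapply(drop_reasons, as.integer),
                 warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:", x$n_rows_read, "rows read,",
      x$n_rows_dropped, "dropped\n")
  if (length(x$drop_reasons) > 0) {
    for (r in names(x$drop_reasons)) {
      cat("  -", r, ":", x$drop_reasons[[r]], "\n")
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
format.validation_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE)
}

#' Check design balance of a trial table
#'
#' Advisory checks on an experiment's balance; problems are reported as
#' warnings in the returned report, never as errors. Flags (a) arms whose
#' subject counts differ by more than `size_ratio`, (b) covariates whose
#' standardized arm-mean difference exceeds `std_diff_threshold` (difference
#' in arm means over the pooled subject-level SD), and (c) (word, arm) cells
#' with no trials. Randomization balances covariates only in expectation, so
#' finite samples can show chance imbalance worth adjusting for; see
#' [fit_logistic_adjustment()].
#'
#' @param table a [trial_table()].
#' @param std_diff_threshold standardized-difference threshold for covariate
#'   imbalance warnings (default 0.25).
#' @param size_ratio maximum tolerated ratio of larger to smaller arm subject
#'   count (default 1.2).
#' @return A [validation_report()] whose `warnings` describe any imbalance.
#' @export
validate_design <- function(table, std_diff_threshold = 0.25,
                            size_ratio = 1.2) {
  stopifnot(inherits(table, "trial_table"), nrow(table) > 0)
  warnings <- character()

  k1 <- k_treated(table); k0 <- k_control(table)
  if (min(k1, k0) == 0 || max(k1, k0) / min(k1, k0) > size_ratio) {
    warnings <- c(warnings, sprintf(
      "unbalanced arm sizes: %d treated vs %d control subjects", k1, k0))
  }

  covs <- covariate_cols(table)
  if (length(covs) > 0) {
    subj <- dplyr::distinct(
      tibble::as_tibble(table),
      .data$subject_id, .keep_all = TRUE)[, c("subject_id", "z", covs)]
    # crossed designs: a subject belongs to both arms, skip covariate check
    if (!isTRUE(attr(table, "crossed_words"))) {
      for (cv in covs) {
        x1 <- subj[[cv]][subj$z == 1L]; x0 <- subj[[cv]][subj$z == 0L]
        s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
        if (is.na(s) || s == 0) s <- 1
        d <- abs(mean(x1) - mean(x0)) / s
        if (isTRUE(d > std_diff_threshold)) {
          warnings <- c(warnings, sprintf(
            "covariate %s imbalanced between arms (standardized difference %.2f)",
            sub("^cov_", "", cv), d))
        }
      }
    }
  }

  cells <- tidyr::expand_grid(word_id = unique(table$word_id), z = c(0L, 1L))
  seen <- dplyr::distinct(tibble::as_tibble(table), .data$word_id, .data$z)
  empty <- dplyr::anti_join(cells, seen, by = c("word_id", "z"))
  for (i in seq_len(nrow(empty))) {
    warnings <- c(warnings, sprintf(
      "word %s has no trials in the z=%d arm", empty$word_id[i], empty$z[i]))
  }

  validation_report(n_rows_read = nrow(table), n_rows_dropped = 0L,
                    warnings = warnings)
}
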