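#' Multinomial-processing-tree parameters for a priming study
#'
#' Four branch probabilities of the storage tree: `A`, success without a
#' word study; `B`, probability that a studied word is stored (consciously
#' or not); `C`, success when the word is stored; `D`, success when it is
#' not.
#'
#' @param A,B,C,D probabilities in \[0, 1\].
#' @return An object of class `mpt_params`.
#' @export
mpt_params <- function(A, B, C, D) {
  vals <- c(A = A, B = B, C = C, D = D)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("MPT parameters must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "mpt_params")
}

#' Forward map from tree parameters to arm probabilities
#'
#' Computes the two arm success probabilities implied by the storage tree
#' and the decomposition of the priming effect:
#' \deqn{p_1 = BC + D(1 - B), \qquad p_0 = A,}
#' \deqn{p_1 - p_0 = B(C - D) + (D - A).}
#' The first term is the storage route — the probability of storing the
#' studied word times the accuracy improvement the stored trace buys; the
#' second is a baseline shift between unstored-word accuracy and no-study
#' accuracy. When `A = D` the priming effect reduces to the storage term
#' alone.
#'
#' Only the forward map is provided: recovering all four parameters from the
#' two observable proportions is not identifiable (two observables, four
#' parameters), so estimation targets the reduced `A = D` form via
#' [estimate_storage_effect()].
#'
#' @param params an [mpt_params()].
#' @return An object of class `mpt_decomposition`: `p1`, `p0`,
#'   `storage_term` (`B(C - D)`), `baseline_term` (`D - A`), `priming`
#'   (`p1 - p0`).
#' @export
mpt_forward <- function(params) {
  stopifnot(inherits(params, "mpt_params"))
  p1 <- params$B * params$C + params$D * (1 - params$B)
  p0 <- params$A
  structure(list(p1 = p1, p0 = p0,
                 storage_term = params$B * (params$C - params$D),
                 baseline_term = params$D - params$A,
                 priming = p1 - p0),
            class = "mpt_decomposition")
}

#' @export
print.mpt_decomposition <- function(x, ...) {
  cat(sprintf("MPT decomposition: p1 = %.4f, p0 = %.4f, priming = %.4f\n",
              x$p1, x$p0, x$priming))
  cat(sprintf("  storage term B(C-D) = %.4f, baseline term D-A = %.4f\n",
              x$storage_term, x$baseline_term))
  invisible(x)
}

#' Estimate the storage component of the priming effect
#'
#' Under the reduced tree with `A = D` (no-study accuracy equal to
#' unstored-word accuracy), the observable difference in arm proportions
#' estimates the storage term `B(C - D)` directly. This function returns
#' `p1_hat - p0_hat` under that interpretation.
#'
#' @param p1_hat,p0_hat observed arm success proportions in \[0, 1\].
#' @return The estimated storage effect, a single number.
#' @export
estimate_storage_effect <- function(p1_hat, p0_hat) {
  if (p1_hat < 0 || p1_hat > 1 || p0_hat < 0 || p0_hat > 1) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  p1_hat - p0_hat
}

#' Sensitivity of the storage interpretation to A != D
#'
#' The reduced estimand `B(C - D)` assumes `A = D`; when the assumption
#' fails, the observed priming effect over- or under-states the storage term
#' by exactly the baseline gap `D - A`. This utility tabulates that bias
#' over a grid of `D - A` values for fixed `B`, `C`.
#'
#' @param params an [mpt_params()] supplying `B`, `C` and the central `D`.
#' @param delta_grid grid of baseline gaps `D - A` to sweep (default
#'   `seq(-0.2, 0.2, by = 0.05)`).
#' @return A tibble with columns `baseline_gap`, `priming`, `storage_term`,
#'   `bias` (`priming - storage_term`, equal to the gap).
#' @export
storage_sensitivity <- function(params,
                                delta_grid = seq(-0.2, 0.2, by = 0.05)) {
  stopifnot(inherits(params, "mpt_params"))
  rows <- lapply(delta_grid, function(d) {
    A <- min(max(params$D - d, 0), 1)
    dec <- mpt_forward(mpt_params(A, params$B, params$C, params$D))
    tibble::tibble(baseline_gap = params$D - A, priming = dec$priming,
                   storage_term = dec$storage_term,
                   bias = dec$priming - dec$storage_term)
  })
  dplyr::bind_rows(rows)
}
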