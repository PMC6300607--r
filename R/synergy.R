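new_dose_matrix <- function(dose_a, dose_b, viability, effect,
                            stimulated = NULL, n_replicates = 1L) {
  stopifnot(length(dose_a) >= 2L, length(dose_b) >= 2L,
            nrow(viability) == length(dose_a),
            ncol(viability) == length(dose_b))
  dimnames(viability) <- dimnames(effect) <- list(dose_a, dose_b)
  structure(
    list(dose_a = dose_a, dose_b = dose_b, viability = viability,
         effect = effect,
         stimulated = stimulated %||% (viability > 1),
         n_replicates = as.integer(n_replicates)),
    class = "dose_matrix"
  )
}

#' Normalise a raw viability grid to its untreated control
#'
#' Divides a raw (replicate-averaged) readout grid by the untreated
#' control value and converts to effect `E = clip(1 - viability, 0, 1)`.
#' Cells with viability above 1 (growth stimulation) are clipped to
#' effect 0 and flagged.
#'
#' @param raw Numeric matrix of raw readouts, rows indexed by drug-A
#'   dose, columns by drug-B dose.
#' @param dose_a,dose_b Dose vectors (each of length >= 2, including 0
#'   for the single-agent margins).
#' @param control Positive control (untreated) readout; defaults to the
#'   `(0, 0)` cell of `raw`.
#' @param n_replicates Number of replicates averaged into `raw` (metadata).
#' @return A `dose_matrix` object with `viability`, `effect` and a
#'   logical `stimulated` flag grid.
#' @export
normalize_to_control <- function(raw, dose_a, dose_b, control = NULL,
                                 n_replicates = 1L) {
  raw <- as.matrix(raw)
  if (is.null(control)) {
    ia <- which(dose_a == 0); ib <- which(dose_b == 0)
    if (length(ia) != 1L || length(ib) != 1L) {
      abort("control not supplied and no unique zero-dose cell found")
    }
    control <- raw[ia, ib]
  }
  if (!is.finite(control) || control <= 0) {
    abort("control value must be positive")
  }
  viability <- raw / control
  if (any(viability < 0)) abort("negative viability after normalisation")
  effect <- pmin(pmax(1 - viability, 0), 1)
  dim(effect) <- dim(viability)
  new_dose_matrix(dose_a, dose_b, viability, effect,
                  stimulated = viability > 1, n_replicates = n_replicates)
}

#' Read a dose-matrix CSV
#'
#' Expects a CSV whose first row holds the drug-B doses, first column the
#' drug-A doses, and body the raw viability readouts; cell `(0, 0)` is
#' the untreated control.
#'
#' @param path CSV path.
#' @param normalize Normalise to the `(0,0)` control (default `TRUE`).
#' @return A `dose_matrix` (normalised) or the raw pieces when
#'   `normalize = FALSE`.
#' @export
read_dose_matrix <- function(path, normalize = TRUE) {
  tbl <- readr::read_csv(path, col_names = FALSE, show_col_types = FALSE)
  mat <- as.matrix(tbl)
  dose_b <- as.numeric(mat[1, -1])
  dose_a <- as.numeric(mat[-1, 1])
  raw <- matrix(as.numeric(mat[-1, -1]), nrow = length(dose_a))
  if (!normalize) {
    return(list(dose_a = dose_a, dose_b = dose_b, raw = raw))
  }
  normalize_to_control(raw, dose_a, dose_b)
}

#' Bliss-independence expected effect
#'
#' Under Bliss independence two agents act as independent probabilistic
#' events, so the expected combined effect of single-agent effects
#' `Ea`, `Eb` in `[0, 1]` is `Ea + Eb - Ea * Eb`. Vectorised.
#'
#' @param ea,eb Effects in `[0, 1]`.
#' @return Expected combination effect(s).
#' @export
bliss_expected <- function(ea, eb) {
  if (any(ea < 0 | ea > 1 | eb < 0 | eb > 1, na.rm = FALSE) ||
      anyNA(ea) || anyNA(eb)) {
    abort("effects must lie in [0, 1]")
  }
  ea + eb - ea * eb
}

#' Bliss-independence analysis of a dose matrix
#'
#' Reads the single-agent effects off the zero-dose margins, computes
#' the Bliss expectation for every combination cell and the excess
#' `E_obs - E_exp`. The summary score is the mean excess over cells where
#' both doses are positive (positive = synergy, negative = antagonism);
#' the maximum excess and its cell are reported as well.
#'
#' @param m A `dose_matrix` with zero-dose row and column present.
#' @return A `bliss_result`: list with `effect_a`, `effect_b`,
#'   `observed`, `expected`, `excess` grids, `mean_excess`, `max_excess`
#'   and `max_cell` (doses of the maximal-excess combination). Use
#'   [tidy()] for a long tibble and [glance()] for the one-row summary.
#' @export
bliss_matrix <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  ia <- which(m$dose_a == 0); ib <- which(m$dose_b == 0)
  if (length(ia) != 1L || length(ib) != 1L) {
    abort("zero-dose margins are required to read single-agent effects")
  }
  effect_a <- m$effect[, ib]
  effect_b <- m$effect[ia, ]
  expected <- outer(effect_a, effect_b, bliss_expected)
  excess <- m$effect - expected
  comb <- outer(m$dose_a > 0, m$dose_b > 0, `&`)
  mean_excess <- mean(excess[comb])
  imax <- which(excess == max(excess[comb]) & comb, arr.ind = TRUE)[1, ]
  structure(
    list(dose_a = m$dose_a, dose_b = m$dose_b,
         effect_a = effect_a, effect_b = effect_b,
         observed = m$effect, expected = expected, excess = excess,
         mean_excess = mean_excess,
         max_excess = excess[imax[1], imax[2]],
         max_cell = c(dose_a = m$dose_a[imax[1]], dose_b = m$dose_b[imax[2]])),
    class = "bliss_result"
  )
}

#' @export
print.bliss_result <- function(x, ...) {
  cat("<bliss_result> ", length(x$dose_a), "x", length(x$dose_b),
      " dose grid; mean excess over combinations = ",
      signif(x$mean_excess, 4), ", max excess = ",
      signif(x$max_excess, 4), " at (", x$max_cell[1], ", ",
      x$max_cell[2], ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.bliss_result <- function(x, ...) {
  grid <- tidyr::expand_grid(dose_a = x$dose_a, dose_b = x$dose_b)
  ii <- cbind(match(grid$dose_a, x$dose_a), match(grid$dose_b, x$dose_b))
  grid$observed <- x$observed[ii]
  grid$expected <- x$expected[ii]
  grid$excess <- x$excess[ii]
  grid$combination <- grid$dose_a > 0 & grid$dose_b > 0
  grid
}

#' @export
glance.bliss_result <- function(x, ...) {
  tibble(mean_excess = x$mean_excess, max_excess = x$max_excess,
         max_dose_a = unname(x$max_cell[1]),
         max_dose_b = unname(x$max_cell[2]),
         n_combinations = sum(outer(x$dose_a > 0, x$dose_b > 0, `&`)))
}
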