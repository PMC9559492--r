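#' Relative inhibition of viability or proliferation
#'
#' `100 * (1 - treated / control)`, elementwise for vector input.
#'
#' @param treated treated-well readout(s).
#' @param control matched control readout(s), strictly positive.
#' @return % inhibition (negative values indicate stimulation).
#' @export
relative_inhibition <- function(treated, control) {
  stop_if_not(all(is.finite(control)) && all(control > 0),
              "control values must be positive")
  100 * (1 - treated / control)
}

#' Highest-single-agent (HSA) synergy delta scores
#'
#' For every combination well (both doses > 0) the HSA null expects the better
#' of the two monotherapies at the same doses; the delta score is the observed
#' excess: \eqn{\delta_{ij} = y_{ij} - \max(y_{i0}, y_{0j})}. The summary
#' score is the arithmetic mean of the per-well deltas over combination wells
#' only (monotherapy and vehicle wells excluded).
#'
#' @param response % inhibition grid, rows indexed by `doses_a`, columns by
#'   `doses_b` (replicate-averaged). Row/column names are set from the doses.
#' @param doses_a,doses_b dose vectors, each containing 0 (the monotherapy
#'   column/row of the other drug).
#' @return object of class `synergy_result`: list with `delta_grid` (NA on
#'   monotherapy wells), `summary_delta`, `model = "HSA"`, `doses_a`,
#'   `doses_b`, and `wells` (number of combination wells).
#' @export
#' @examples
#' resp <- rbind(c(0, 10, 30), c(20, 25, 42), c(40, 45, 70))
#' hsa_delta(resp, doses_a = c(0, 1, 2), doses_b = c(0, 1, 2))
hsa_delta <- function(response, doses_a, doses_b) {
  stop_if_not(is.matrix(response) &&
                nrow(response) == length(doses_a) &&
                ncol(response) == length(doses_b),
              "response grid must be doses_a x doses_b")
  stop_if_not(any(doses_a == 0) && any(doses_b == 0),
              "both dose vectors must include the zero dose")
  stop_if_not(all(is.finite(response)), "response grid must be complete")
  ia0 <- which(doses_a == 0)[1]
  ib0 <- which(doses_b == 0)[1]
  mono_a <- response[, ib0]   # drug A alone, indexed by doses_a
  mono_b <- response[ia0, ]   # drug B alone, indexed by doses_b
  delta <- matrix(NA_real_, nrow(response), ncol(response),
                  dimnames = list(doses_a, doses_b))
  for (i in seq_along(doses_a)) {
    for (j in seq_along(doses_b)) {
      if (doses_a[i] > 0 && doses_b[j] > 0) {
        delta[i, j] <- response[i, j] - max(mono_a[i], mono_b[j])
      }
    }
  }
  wells <- sum(!is.na(delta))
  stop_if_not(wells > 0, "no combination wells in the grid")
  out <- list(
    delta_grid = delta,
    summary_delta = mean(delta, na.rm = TRUE),
    model = "HSA",
    doses_a = doses_a, doses_b = doses_b,
    wells = wells,
    note = "summary is the mean over combination wells only"
  )
  class(out) <- "synergy_result"
  out
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("HSA synergy: summary delta = %.3f over %d combination wells\n",
              x$summary_delta, x$wells))
  invisible(x)
}

#' Build a dose grid from a long-format combination table
#'
#' @param df data frame with columns `dose_a`, `dose_b`, `response`
#'   (replicates at the same dose pair are averaged).
#' @return list with `response` matrix, `doses_a`, `doses_b` ready for
#'   [hsa_delta()].
#' @export
long_to_grid <- function(df) {
  need <- c("dose_a", "dose_b", "response")
  stop_if_not(all(need %in% names(df)), "need columns dose_a, dose_b, response")
  da <- sort(unique(df$dose_a))
  db <- sort(unique(df$dose_b))
  resp <- matrix(NA_real_, length(da), length(db), dimnames = list(da, db))
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      v <- df$response[df$dose_a == da[i] & df$dose_b == db[j]]
      if (length(v)) resp[i, j] <- mean(v)
    }
  }
  list(response = resp, doses_a = da, doses_b = db)
}
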