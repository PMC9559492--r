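#' Four-parameter logistic inhibition model
#'
#' Evaluates the sigmoidal dose-response model
#' \deqn{Inhibition\% = Bottom + \frac{Top - Bottom}{1 + 10^{(logEC50 - x)\,HillSlope}}}
#' at log10 concentrations `x`. With a positive Hill slope inhibition
#' increases with concentration; `bottom` and `top` are the lower and upper
#' asymptotes in percent.
#'
#' @param x numeric vector of log10 concentrations.
#' @param bottom,top asymptotes (% inhibition).
#' @param log_ec50 log10 of the relative EC50, same units as `x`.
#' @param hill_slope Hill slope (unitless).
#' @return numeric vector of % inhibition.
#' @export
#' @examples
#' four_pl(0:4, bottom = 0, top = 100, log_ec50 = 2, hill_slope = 1)
four_pl <- function(x, bottom, top, log_ec50, hill_slope) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - x) * hill_slope))
}

#' Replicate-averaged inhibition from raw plate signals
#'
#' Converts raw viability signals (e.g. luminescence) to percent inhibition
#' relative to the vehicle control: `100 * (1 - treated / control)`.
#' Replicates at the same dose are averaged after conversion. An optional T0
#' (time-zero) signal is carried through as metadata only; it does not enter
#' the endpoint.
#'
#' @param doses concentrations (nM) parallel to `signals`; replicates repeat
#'   the dose value.
#' @param signals raw treated-well signals.
#' @param control_signals raw vehicle-control signals (must be positive).
#' @param cell_line,drug identifiers attached to the result.
#' @param t0_signals optional raw T0 signals, stored as an attribute.
#' @return an object of class `inhibition_curve`: a data frame with one row
#'   per distinct dose (`dose_nM`, `x` = log10 dose, `inhibition`,
#'   `n_replicates`) plus `cell_line`/`drug` attributes.
#' @export
compute_inhibition <- function(doses, signals, control_signals,
                               cell_line = NA_character_, drug = NA_character_,
                               t0_signals = NULL) {
  stop_if_not(length(doses) == length(signals),
              "`doses` and `signals` must have equal length")
  stop_if_not(all(is.finite(control_signals)) && all(control_signals > 0),
              "vehicle control signals must be positive and finite")
  stop_if_not(all(is.finite(signals)), "treated signals must be finite")
  ctrl <- mean(control_signals)
  inh <- 100 * (1 - signals / ctrl)
  ud <- sort(unique(doses))
  curve <- data.frame(
    dose_nM = ud,
    x = log10(ud),
    inhibition = vapply(ud, function(d) mean(inh[doses == d]), numeric(1)),
    n_replicates = vapply(ud, function(d) sum(doses == d), integer(1))
  )
  attr(curve, "cell_line") <- cell_line
  attr(curve, "drug") <- drug
  attr(curve, "control_mean") <- ctrl
  if (!is.null(t0_signals)) attr(curve, "t0_mean") <- mean(t0_signals)
  class(curve) <- c("inhibition_curve", "data.frame")
  curve
}

# residual function used by the bounded Levenberg-Marquardt fit
.fpl_resid <- function(par, x, y) {
  y - four_pl(x, par[1], par[2], par[3], par[4])
}

# analytic Jacobian of the 4PL mean function (rows = doses, cols = params)
.fpl_jacobian <- function(par, x) {
  b <- par[1]; t <- par[2]; e <- par[3]; h <- par[4]
  u <- 10^((e - x) * h)
  d <- 1 + u
  cbind(
    bottom = 1 - 1 / d,
    top = 1 / d,
    log_ec50 = -(t - b) * u * log(10) * h / d^2,
    hill_slope = -(t - b) * u * log(10) * (e - x) / d^2
  )
}

#' Fitting-error acceptability rule for a 4PL fit
#'
#' A fit is acceptable when it converged and the relative standard error of
#' EC50 (`se_ec50_ratio` = \eqn{\sigma_{EC50}/EC50}) is below `max_se_ratio`
#' (default 40%).
#'
#' @param se_ec50_ratio relative EC50 standard error (fraction).
#' @param converged logical optimizer status.
#' @param max_se_ratio acceptability threshold (default 0.4).
#' @return logical.
#' @export
fit_acceptable <- function(se_ec50_ratio, converged = TRUE, max_se_ratio = 0.4) {
  isTRUE(converged) & is.finite(se_ec50_ratio) & se_ec50_ratio < max_se_ratio
}

#' Fit the constrained four-parameter logistic model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) with multi-start initial values. Bottom is allowed
#' down to -20% and Top up to 120% to accommodate experimental error. The
#' fitting error is \eqn{\sigma_{EC50}/EC50}, obtained by the delta method
#' from the standard error of log10 EC50 (`se_ec50_ratio = ln(10) * se(logEC50)`);
#' fits with `se_ec50_ratio >= 40%` are flagged unacceptable but still
#' reported.
#'
#' @param curve an `inhibition_curve` (or any data frame with `x` and
#'   `inhibition` columns); at least 5 distinct doses are required.
#' @param lower_bottom,upper_top asymptote constraints (%).
#' @param max_se_ratio acceptability threshold on the EC50 fitting error.
#' @return an object of class `four_pl_fit`: list with `bottom`, `top`,
#'   `log_ec50`, `hill_slope`, `se_ec50_ratio`, `converged`, `acceptable`,
#'   `rss`, `n`, and the identifiers from `curve`.
#' @export
fit_4pl <- function(curve, lower_bottom = -20, upper_top = 120,
                    max_se_ratio = 0.4) {
  x <- curve$x
  y <- curve$inhibition
  stop_if_not(length(unique(x)) >= 5, "need at least 5 distinct doses to fit")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "doses and inhibition values must be finite")

  lower <- c(lower_bottom, lower_bottom, min(x) - 3, -10)
  upper <- c(upper_top, upper_top, max(x) + 3, 10)
  qs <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  starts <- list()
  for (e0 in qs) {
    for (s0 in c(1, -1)) {
      starts[[length(starts) + 1]] <- c(min(y), max(y), e0, s0)
    }
  }

  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper,
        fn = .fpl_resid, x = x, y = y,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-14, ptol = 1e-14, gtol = 0, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = res$par, rss = rss, info = res$info)
    }
  }
  stop_if_not(!is.null(best), "4PL optimization failed for every start")

  par <- best$par
  # bottom > top with the opposite slope sign describes the same curve;
  # canonicalize so bottom <= top
  if (par[1] > par[2]) {
    par <- c(par[2], par[1], par[3], -par[4])
  }
  # info 1-3: tolerance-based convergence; 4: residual orthogonal to the
  # Jacobian, reached at exact (zero-residual) minima
  converged <- best$info %in% 1:4

  n <- length(y)
  se_log_ec50 <- Inf
  if (n > 4 && best$rss >= 0) {
    J <- .fpl_jacobian(par, x)
    sigma2 <- best$rss / (n - 4)
    cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv) && is.finite(cv[3, 3]) && cv[3, 3] >= 0) {
      se_log_ec50 <- sqrt(cv[3, 3])
    }
  }
  # delta method: EC50 = 10^logEC50 => se(EC50)/EC50 = ln(10) * se(logEC50)
  se_ratio <- log(10) * se_log_ec50

  fit <- list(
    cell_line = attr(curve, "cell_line"),
    drug = attr(curve, "drug"),
    bottom = par[1], top = par[2], log_ec50 = par[3], hill_slope = par[4],
    se_ec50_ratio = se_ratio,
    converged = converged,
    acceptable = fit_acceptable(se_ratio, converged, max_se_ratio),
    rss = best$rss, n = n
  )
  class(fit) <- "four_pl_fit"
  fit
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit%s: bottom=%.3f top=%.3f logEC50=%.4f hill=%.3f seEC50/EC50=%.3f %s\n",
    if (is.na(x$cell_line)) "" else paste0(" [", x$cell_line, "]"),
    x$bottom, x$top, x$log_ec50, x$hill_slope, x$se_ec50_ratio,
    if (x$acceptable) "(acceptable)" else "(NOT acceptable)"
  ))
  invisible(x)
}

#' Closed-form area under the 4PL inhibition curve
#'
#' Integral of [four_pl()] over the log10-concentration window `[a, b]`:
#' \deqn{AUC = Bottom (b-a) + \frac{Top - Bottom}{HillSlope \ln 10}
#'   \ln\frac{1 + 10^{HillSlope (b - logEC50)}}{1 + 10^{HillSlope (a - logEC50)}}}
#' The default window \eqn{[log10(1), log10(10000)] = [0, 4]} spans 1-10,000 nM.
#' A zero Hill slope degenerates to the flat-curve value
#' `(top + bottom)/2 * (b - a)`.
#'
#' @param bottom,top,log_ec50,hill_slope 4PL parameters.
#' @param a,b integration bounds on the log10 concentration axis.
#' @return AUC in % x log10-concentration units.
#' @export
auc_4pl <- function(bottom, top, log_ec50, hill_slope, a = 0, b = 4) {
  stop_if_not(a < b, "integration bounds must satisfy a < b")
  if (hill_slope == 0) {
    return((top + bottom) / 2 * (b - a))
  }
  bottom * (b - a) + (top - bottom) / (hill_slope * log(10)) *
    (log1p10(hill_slope * (b - log_ec50)) - log1p10(hill_slope * (a - log_ec50)))
}

#' AUC endpoint from a fitted 4PL model
#'
#' Computes the closed-form AUC for a [fit_4pl()] result. The AUC is reported
#' for unacceptable fits too (flagged via `from_acceptable_fit`), since panel
#' analyses use AUC precisely where EC50 is unreliable.
#'
#' @param fit a `four_pl_fit`.
#' @param a,b integration bounds (log10 concentration); defaults 0 and 4.
#' @return list of class `auc_endpoint` with `auc`, `a`, `b`,
#'   `from_acceptable_fit`, `degenerate` (zero Hill slope) and identifiers.
#' @export
compute_auc <- function(fit, a = 0, b = 4) {
  stopifnot(inherits(fit, "four_pl_fit"))
  out <- list(
    cell_line = fit$cell_line, drug = fit$drug,
    auc = auc_4pl(fit$bottom, fit$top, fit$log_ec50, fit$hill_slope, a, b),
    a = a, b = b,
    from_acceptable_fit = isTRUE(fit$acceptable),
    degenerate = fit$hill_slope == 0
  )
  class(out) <- "auc_endpoint"
  out
}

#' Fit every cell line x drug curve in a long plate table
#'
#' Convenience wrapper grouping a long-format plate table (as produced by
#' [generate_panel()] or read from TSV) into per-curve fits and AUC endpoints.
#'
#' @param plates data frame with columns `cell_line`, `drug`,
#'   `concentration_nM`, `signal`, `well_type` (`"treated"`, `"vehicle"` or
#'   `"t0"`).
#' @param a,b AUC integration bounds.
#' @return data frame with one row per cell line x drug: fitted parameters,
#'   `se_ec50_ratio`, `converged`, `acceptable`, `auc`.
#' @export
fit_panel <- function(plates, a = 0, b = 4) {
  need <- c("cell_line", "drug", "concentration_nM", "signal", "well_type")
  stop_if_not(all(need %in% names(plates)),
              paste("plate table must have columns:", paste(need, collapse = ", ")))
  keys <- unique(plates[plates$well_type == "treated", c("cell_line", "drug")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- plates[plates$cell_line == keys$cell_line[i] &
                    plates$drug == keys$drug[i], ]
    tr <- sub[sub$well_type == "treated", ]
    ve <- sub[sub$well_type == "vehicle", ]
    t0 <- sub[sub$well_type == "t0", ]
    curve <- compute_inhibition(
      tr$concentration_nM, tr$signal, ve$signal,
      cell_line = keys$cell_line[i], drug = keys$drug[i],
      t0_signals = if (nrow(t0)) t0$signal else NULL
    )
    fit <- fit_4pl(curve)
    end <- compute_auc(fit, a, b)
    data.frame(
      cell_line = keys$cell_line[i], drug = keys$drug[i],
      bottom = fit$bottom, top = fit$top, log_ec50 = fit$log_ec50,
      hill_slope = fit$hill_slope, se_ec50_ratio = fit$se_ec50_ratio,
      converged = fit$converged, acceptable = fit$acceptable,
      auc = end$auc
    )
  })
  do.call(rbind, rows)
}
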