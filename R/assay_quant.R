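#' Relative expression by the delta-delta Ct method
#'
#' Replicate Cts are averaged per sample; `dCt = Ct_target - Ct_reference`
#' (reference = housekeeping gene, e.g. GAPDH); `ddCt = dCt - mean dCt of the
#' control group`; fold change `= 2^(-ddCt)`. The per-group fold change is
#' `2^(-mean ddCt)`, so the control group is exactly 1 against itself.
#'
#' @param qpcr data frame with columns `sample`, `group`, `target_ct`,
#'   `reference_ct` (and optionally `replicate`). Ct values must lie in
#'   (0, 45) and every sample needs a reference Ct.
#' @param control_group label of the calibrator group.
#' @return list with `samples` (per-sample `dct`, `ddct`, `fold_change`) and
#'   `groups` (per-group mean `ddct` and `fold_change`).
#' @export
ddct_relative_expression <- function(qpcr, control_group) {
  need <- c("sample", "group", "target_ct", "reference_ct")
  stop_if_not(all(need %in% names(qpcr)),
              paste("qPCR table needs columns:", paste(need, collapse = ", ")))
  stop_if_not(!anyNA(qpcr$reference_ct), "missing reference Ct")
  stop_if_not(all(qpcr$target_ct > 0 & qpcr$target_ct < 45 &
                    qpcr$reference_ct > 0 & qpcr$reference_ct < 45),
              "Ct values must lie in (0, 45)")
  stop_if_not(control_group %in% qpcr$group, "control group not present")

  agg <- stats::aggregate(
    cbind(target_ct, reference_ct) ~ sample + group, data = qpcr, FUN = mean
  )
  agg$dct <- agg$target_ct - agg$reference_ct
  ctrl_mean <- mean(agg$dct[agg$group == control_group])
  agg$ddct <- agg$dct - ctrl_mean
  agg$fold_change <- 2^(-agg$ddct)

  groups <- stats::aggregate(ddct ~ group, data = agg, FUN = mean)
  groups$fold_change <- 2^(-groups$ddct)
  list(samples = agg[, c("sample", "group", "dct", "ddct", "fold_change")],
       groups = groups)
}

#' Percent DNA crosslinks from olive tail moments
#'
#' Crosslinks reduce DNA migration after an H2O2 challenge, so the treated
#' condition's mean olive tail moment (OTM) shrinks relative to the
#' drug-free challenged control:
#' `%CL = 100 * (1 - mean(OTM_treated) / mean(OTM_control))`, capped at 100.
#' Both conditions should be measured at the same timepoint after the same
#' challenge; a median-based variant is available since OTM distributions are
#' right-skewed.
#'
#' @param treated,control numeric per-nucleus OTM vectors (>= 0).
#' @param location `"mean"` (default) or `"median"`.
#' @return percent crosslinks (can be negative if the treated tails exceed
#'   the control's).
#' @export
percent_crosslinks <- function(treated, control, location = c("mean", "median")) {
  location <- match.arg(location)
  stop_if_not(all(treated >= 0) && all(control >= 0), "OTM values must be >= 0")
  loc <- if (location == "mean") mean else stats::median
  mc <- loc(control)
  stop_if_not(mc > 0, "control mean OTM is zero")
  min(100, 100 * (1 - loc(treated) / mc))
}
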