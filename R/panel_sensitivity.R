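#' z-score sensitivity classification of panel AUCs
#'
#' Normalizes a panel's AUC endpoints to z-scores (mean 0, sample sd 1,
#' n-1 denominator) and assigns sensitivity classes by the strict-threshold
#' rule: `sensitive` iff z < -0.5, `insensitive` iff z > 0.5, `intermediate`
#' otherwise (boundary values land in `intermediate`).
#'
#' @param aucs numeric AUC vector for the panel (>= 3 lines, non-zero sd).
#' @param cell_lines optional identifiers (defaults to names of `aucs` or an
#'   index).
#' @param tumour_type optional per-line labels carried through.
#' @param threshold z cut-off magnitude (default 0.5).
#' @return data frame with `cell_line`, `tumour_type` (if given), `auc`,
#'   `z_auc`, `sens_class` (factor: sensitive/intermediate/insensitive).
#' @export
#' @examples
#' zscore_classify(c(1, 2, 3, 4, 5))
zscore_classify <- function(aucs, cell_lines = NULL, tumour_type = NULL,
                            threshold = 0.5) {
  stop_if_not(length(aucs) >= 3, "need at least 3 cell lines")
  stop_if_not(all(is.finite(aucs)), "AUCs must be finite")
  s <- stats::sd(aucs)
  stop_if_not(s > 0, "zero AUC variance: sensitivity classes are undefined")
  z <- (aucs - mean(aucs)) / s
  cls <- ifelse(z < -threshold, "sensitive",
                ifelse(z > threshold, "insensitive", "intermediate"))
  if (is.null(cell_lines)) {
    cell_lines <- if (!is.null(names(aucs))) names(aucs) else
      paste0("line_", seq_along(aucs))
  }
  out <- data.frame(
    cell_line = cell_lines,
    auc = unname(aucs),
    z_auc = unname(z),
    sens_class = factor(cls, levels = c("sensitive", "intermediate", "insensitive"))
  )
  if (!is.null(tumour_type)) out$tumour_type <- tumour_type
  out[, c("cell_line", intersect("tumour_type", names(out)), "auc", "z_auc",
          "sens_class")]
}
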