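#' Remove genes expressed in too few cell lines
#'
#' Drops a gene when more than `frac_threshold` of the samples have expression
#' below `level` (both comparisons strict). With the defaults a gene is removed
#' iff >85% of cell lines have log2(FPKM) < 1. The sample set is unchanged.
#'
#' @param expr numeric gene x sample matrix (log2 FPKM), with row and column
#'   names.
#' @param frac_threshold fraction of low-expression samples above which a gene
#'   is removed (strict `>`).
#' @param level expression level below which a sample counts as low (strict `<`).
#' @return the filtered matrix (possibly zero rows).
#' @export
filter_low_expression <- function(expr, frac_threshold = 0.85, level = 1.0) {
  stop_if_not(is.matrix(expr) && nrow(expr) > 0 && ncol(expr) > 0,
              "expression matrix must be a non-empty matrix")
  stop_if_not(!anyDuplicated(rownames(expr)) && !anyDuplicated(colnames(expr)),
              "gene and sample ids must be unique")
  low_frac <- rowMeans(expr < level)
  expr[low_frac <= frac_threshold, , drop = FALSE]
}

# Spearman rho with average-rank ties plus two-sided p from the t
# approximation on n - 2 df (the screen's working p-value at panel n).
.spearman_t <- function(xr, yr, n) {
  r <- stats::cor(xr, yr)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  c(rho = r, p = min(p, 1))
}

#' Spearman screen of genes against a panel endpoint
#'
#' Per-gene Spearman correlation (average-rank tie handling) between
#' expression and the endpoint (e.g. AUC), with a two-sided p-value from the
#' t approximation on n - 2 degrees of freedom. A gene is selected iff
#' `p < alpha`; no multiple-testing correction is applied (raw-p screen).
#' Genes with zero rank variance have undefined rho and are excluded with a
#' warning (reported with `rho = NA`, not selected).
#'
#' @param expr gene x sample matrix; column names must match `names(endpoint)`
#'   when both are named.
#' @param endpoint numeric endpoint vector aligned to the matrix columns
#'   (n >= 5).
#' @param alpha selection threshold on the raw p-value (default 0.001).
#' @return data frame `gene`, `rho`, `p_value`, `selected`, ordered as the
#'   input genes.
#' @export
spearman_screen <- function(expr, endpoint, alpha = 0.001) {
  stop_if_not(is.matrix(expr) && nrow(expr) > 0, "empty expression matrix")
  n <- ncol(expr)
  stop_if_not(length(endpoint) == n, "endpoint length must match sample count")
  stop_if_not(n >= 5, "need at least 5 samples for the screen")
  if (!is.null(colnames(expr)) && !is.null(names(endpoint))) {
    stop_if_not(identical(colnames(expr), names(endpoint)),
                "sample ids of matrix and endpoint do not align")
  }
  yr <- rank(endpoint)
  xr <- t(apply(expr, 1, rank))      # average ranks per gene
  const <- apply(xr, 1, function(r) stats::var(r) == 0)
  if (any(const)) {
    warning(sum(const), " constant gene(s) excluded from the Spearman screen")
  }
  rho <- rep(NA_real_, nrow(expr))
  p <- rep(NA_real_, nrow(expr))
  if (any(!const)) {
    res <- t(apply(xr[!const, , drop = FALSE], 1, .spearman_t, yr = yr, n = n))
    rho[!const] <- res[, "rho"]
    p[!const] <- res[, "p"]
  }
  data.frame(
    gene = if (is.null(rownames(expr))) paste0("g", seq_len(nrow(expr))) else rownames(expr),
    rho = rho,
    p_value = p,
    selected = !const & !is.na(p) & p < alpha
  )
}

#' Pearson correlation between gene expression and a drug-sensitivity endpoint
#'
#' Pearson r with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom, e.g. cyclophilin expression against cisplatin IC50.
#'
#' @param expression numeric vector (one gene across cell lines).
#' @param ic50 numeric sensitivity endpoint aligned to `expression` (n >= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_drug_correlation <- function(expression, ic50) {
  stop_if_not(length(expression) == length(ic50), "vectors must align")
  stop_if_not(length(expression) >= 3, "need at least 3 samples")
  stop_if_not(stats::var(expression) > 0 && stats::var(ic50) > 0,
              "zero variance in expression or endpoint")
  ct <- stats::cor.test(expression, ic50, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(ic50))
}
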