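# End-to-end pipeline and plain-text I/O.

#' Write/read tab-separated tables with headers
#'
#' Thin wrappers fixing the conventions used by every pipeline artifact
#' (tab separator, header row, no quoting, no row names, full double
#' precision).
#'
#' @param df data frame.
#' @param path file path.
#' @return `read_tsv_table` returns a data frame.
#' @export
write_tsv_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write/read a gene x sample expression matrix as TSV
#'
#' Genes as rows (first column `gene`), header row = sample ids.
#'
#' @param expr numeric matrix with dimnames.
#' @param path file path.
#' @return `read_expression_tsv` returns a numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Run the full panel analysis on synthetic data
#'
#' Generates a seeded panel, fits every dose-response curve, computes AUC
#' endpoints and z-score sensitivity classes, filters and screens the
#' expression matrix against AUC, selects signature genes on the grouped
#' (non-intermediate) lines, trains the LPS/Bayes classifier, estimates
#' accuracy by repeated stratified cross-validation, and scores a seeded
#' drug-combination matrix with the HSA delta model. All outputs are written
#' as tab-separated text and JSON under `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic step.
#' @param spec optional [panel_spec()]; defaults to `panel_spec(seed = seed)`.
#' @param syn_spec optional [synergy_spec()]; defaults to a planted delta of 8
#'   with 2% noise.
#' @param cv_repeats,cv_folds cross-validation design.
#' @param screen_alpha Spearman screen threshold.
#' @param max_signature_candidates cap on screened genes passed to the
#'   selector (strongest correlations first).
#' @return invisibly, a list with `endpoints`, `screen`, `signature`,
#'   `cv`, `predictions`, `synergy`, and the output file paths.
#' @export
run_panel_pipeline <- function(out_dir, seed = 1, spec = NULL, syn_spec = NULL,
                               cv_repeats = 20, cv_folds = 10,
                               screen_alpha = 0.001,
                               max_signature_candidates = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- panel_spec(seed = seed)
  if (is.null(syn_spec)) {
    syn_spec <- synergy_spec(planted_delta = 8, noise_sd = 2, seed = seed)
  }

  panel <- generate_panel(spec)
  fits <- fit_panel(panel$plates)
  endpoints <- zscore_classify(
    fits$auc, cell_lines = fits$cell_line,
    tumour_type = panel$truth$tumour_type[match(fits$cell_line,
                                                panel$truth$cell_line)]
  )
  endpoints$se_ec50_ratio <- fits$se_ec50_ratio
  endpoints$acceptable_fit <- fits$acceptable

  expr <- filter_low_expression(panel$expression)
  auc_vec <- endpoints$auc[match(colnames(expr), endpoints$cell_line)]
  screen <- spearman_screen(expr, stats::setNames(auc_vec, colnames(expr)),
                            alpha = screen_alpha)
  candidates <- screen$gene[screen$selected]
  if (length(candidates) > max_signature_candidates) {
    ord <- order(screen$p_value[screen$selected])
    candidates <- candidates[ord][seq_len(max_signature_candidates)]
  }

  grouped <- endpoints$sens_class != "intermediate"
  grouped_ids <- endpoints$cell_line[grouped]
  labels <- as.character(endpoints$sens_class[grouped])
  expr_grp <- expr[, grouped_ids, drop = FALSE]

  signature <- if (length(candidates) >= 2) {
    boruta_select(expr_grp[candidates, , drop = FALSE], labels, seed = seed)
  } else {
    candidates
  }
  if (length(signature) == 0) signature <- candidates  # fall back to screen

  weights <- t_weights(expr_grp[signature, , drop = FALSE], labels)
  model <- fit_lps_groups(expr_grp[signature, , drop = FALSE], labels, weights)
  preds <- posterior_sensitive(lps_score(expr_grp[signature, , drop = FALSE],
                                         weights),
                               model, cell_line = grouped_ids)
  cv <- repeated_cv(expr_grp, labels, signature,
                    n_repeats = cv_repeats, n_folds = cv_folds, seed = seed)

  syn <- generate_synergy_matrix(syn_spec)
  hsa <- hsa_delta(syn$response, syn$doses_a, syn$doses_b)

  paths <- list(
    endpoints = file.path(out_dir, "endpoints.tsv"),
    screen = file.path(out_dir, "screen.tsv"),
    signature = file.path(out_dir, "signature.json"),
    predictions = file.path(out_dir, "predictions.tsv"),
    cv = file.path(out_dir, "cv_report.json"),
    synergy = file.path(out_dir, "synergy.json")
  )
  write_tsv_table(endpoints, paths$endpoints)
  write_tsv_table(screen, paths$screen)
  jsonlite::write_json(
    list(genes = signature, weights = as.list(weights),
         mu1 = model$mu1, var1 = model$var1,
         mu2 = model$mu2, var2 = model$var2),
    paths$signature, auto_unbox = TRUE, digits = NA
  )
  write_tsv_table(preds, paths$predictions)
  jsonlite::write_json(
    list(n_repeats = cv$n_repeats, n_folds = cv$n_folds,
         mean_accuracy = cv$accuracy, per_repeat = cv$per_repeat,
         selection_outside_cv = cv$selection_outside_cv),
    paths$cv, auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(model = hsa$model, summary_delta = hsa$summary_delta,
         wells = hsa$wells,
         delta_grid = apply(hsa$delta_grid, 1, as.list),
         note = hsa$note),
    paths$synergy, auto_unbox = TRUE, digits = NA
  )

  invisible(list(endpoints = endpoints, screen = screen, signature = signature,
                 cv = cv, predictions = preds, synergy = hsa, paths = paths))
}
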