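#' Shadow-feature (Boruta-style) all-relevant gene selection
#'
#' Iteratively compares each candidate gene's importance in a randomized-tree
#' ensemble against "shadow" features (column-permuted copies of the
#' candidates). A gene scores a hit in an iteration when its permutation
#' importance exceeds the maximum shadow importance. Genes are confirmed or
#' rejected by two one-sided binomial tests on their hit counts at level
#' `alpha`, Bonferroni-corrected over the candidates; rejected genes are
#' dropped from later iterations, confirmed genes stay in the ensemble.
#' Genes still undecided after `max_iter` iterations are tentative; by
#' default they are not selected (the reference procedure's default
#' selection). `tentative = "median"` instead applies the rough-fix
#' resolution: a tentative gene is confirmed when its median importance over
#' the run exceeds the median of the per-iteration shadow maxima. The
#' rough-fix is lenient in small-sample, many-gene settings (it inherits the
#' low late-run shadow bar), so the strict default is recommended for
#' selection.
#'
#' @param expr gene x sample matrix restricted to the candidate genes
#'   (typically the Spearman screen's selection).
#' @param labels two-level factor/character vector over samples (each class
#'   >= 3 samples).
#' @param max_iter maximum ensemble iterations (default 100).
#' @param alpha decision-test level before Bonferroni correction (default 0.05).
#' @param num_trees trees per ensemble (default 500, permutation importance).
#' @param seed integer seed controlling permutations and ensembles.
#' @param tentative how to resolve genes undecided at `max_iter`: `"reject"`
#'   (default) or `"median"` (rough-fix comparison described above).
#' @return character vector of selected genes, with attributes `decision`
#'   (data frame: gene, hits, iterations, decision) and `n_iter`.
#' @export
boruta_select <- function(expr, labels, max_iter = 100, alpha = 0.05,
                          num_trees = 500, seed = 1,
                          tentative = c("reject", "median")) {
  tentative <- match.arg(tentative)
  stop_if_not(is.matrix(expr) && nrow(expr) > 0, "no candidate features")
  labels <- as.factor(labels)
  stop_if_not(nlevels(droplevels(labels)) == 2, "exactly two classes required")
  stop_if_not(all(table(droplevels(labels)) >= 3),
              "each class needs at least 3 samples")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(expr)))
  m <- length(genes)
  x <- t(expr)                           # samples x genes
  colnames(x) <- genes

  with_local_seed(seed, {
    status <- setNames(rep("tentative", m), genes)
    hits <- setNames(integer(m), genes)
    iters <- setNames(integer(m), genes)
    imp_hist <- vector("list", m)
    names(imp_hist) <- genes
    shadow_max_hist <- numeric(0)
    thr <- alpha / (2 * m)               # Bonferroni over candidates, two-sided

    for (it in seq_len(max_iter)) {
      active <- genes[status != "rejected"]
      undecided <- genes[status == "tentative"]
      if (length(undecided) == 0) break
      xa <- x[, active, drop = FALSE]
      # shadows: permuted copy of every active gene, padded so at least 5
      # shadow features always anchor the importance bar
      shadow_src <- active
      while (length(shadow_src) < 5) {
        shadow_src <- c(shadow_src, active[seq_len(min(length(active),
                                                       5 - length(shadow_src)))])
      }
      shadow <- apply(x[, shadow_src, drop = FALSE], 2, sample)
      colnames(shadow) <- paste0(".shadow.", seq_along(shadow_src))
      dat <- data.frame(cbind(xa, shadow), check.names = FALSE)
      dat$.class <- droplevels(labels)
      rf <- ranger::ranger(
        dependent.variable.name = ".class", data = dat,
        num.trees = num_trees, importance = "permutation",
        scale.permutation.importance = TRUE,   # z-scored importance
        num.threads = 1, seed = seed * 1000L + it
      )
      imp <- rf$variable.importance
      smax <- max(imp[startsWith(names(imp), ".shadow.")])
      shadow_max_hist <- c(shadow_max_hist, smax)
      real_imp <- imp[active]
      for (g in active) imp_hist[[g]] <- c(imp_hist[[g]], real_imp[[g]])
      hit <- active[real_imp > smax]
      hits[intersect(hit, undecided)] <- hits[intersect(hit, undecided)] + 1L
      iters[undecided] <- iters[undecided] + 1L

      k <- hits[undecided]
      n_it <- iters[undecided]
      p_acc <- stats::pbinom(k - 1L, n_it, 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(k, n_it, 0.5)
      status[undecided[p_acc < thr]] <- "confirmed"
      status[undecided[p_rej < thr & p_acc >= thr]] <- "rejected"
    }

    if (tentative == "median") {
      # rough-fix: median importance over the run vs median shadow max
      med_shadow <- stats::median(shadow_max_hist)
      for (g in genes[status == "tentative"]) {
        if (length(imp_hist[[g]]) && stats::median(imp_hist[[g]]) > med_shadow) {
          status[g] <- "confirmed"
        } else {
          status[g] <- "rejected"
        }
      }
    } else {
      status[status == "tentative"] <- "rejected"
    }

    selected <- genes[status == "confirmed"]
    attr(selected, "decision") <- data.frame(
      gene = genes, hits = unname(hits), iterations = unname(iters),
      decision = unname(status)
    )
    attr(selected, "n_iter") <- length(shadow_max_hist)
    selected
  })
}

#' Two-sample t-statistic weights for signature genes
#'
#' Per-gene pooled-variance (Student) t-statistics between the sensitive and
#' insensitive groups, the weights \eqn{a_j} of the linear predictor score.
#' Positive weight means higher mean expression in the sensitive group. Genes
#' with zero pooled variance get weight 0 with a warning.
#'
#' @param expr gene x sample matrix restricted to the signature genes.
#' @param labels two-level vector over samples; `sensitive_level` names the
#'   group whose higher expression yields positive weights.
#' @param sensitive_level label of the sensitive group (default `"sensitive"`).
#' @param welch use Welch (unpooled) t instead of Student (default FALSE).
#' @return named numeric vector of weights, one per gene.
#' @export
t_weights <- function(expr, labels, sensitive_level = "sensitive",
                      welch = FALSE) {
  stop_if_not(is.matrix(expr), "expr must be a gene x sample matrix")
  labels <- as.character(labels)
  g1 <- labels == sensitive_level
  g2 <- !g1
  stop_if_not(sum(g1) >= 2 && sum(g2) >= 2,
              "both groups need at least 2 samples")
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  v1 <- apply(expr[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(expr[, g2, drop = FALSE], 1, stats::var)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  w <- (m1 - m2) / se
  degen <- !is.finite(w)
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero variance get weight 0")
    w[degen] <- 0
  }
  names(w) <- rownames(expr)
  w
}

#' Linear predictor score
#'
#' `LPS(X) = sum_j a_j X_j`: the dot product of t-statistic weights and a cell
#' line's expression over the signature genes. For a matrix, one score per
#' column (sample). Missing values are an error: no imputation.
#'
#' @param expression numeric vector aligned to `names(weights)`, or a
#'   gene x sample matrix whose rows cover the signature genes.
#' @param weights named weight vector from [t_weights()].
#' @return numeric score (or vector of per-sample scores).
#' @export
lps_score <- function(expression, weights) {
  if (is.matrix(expression)) {
    stop_if_not(all(names(weights) %in% rownames(expression)),
                "expression matrix is missing signature genes")
    expression <- expression[names(weights), , drop = FALSE]
    stop_if_not(all(is.finite(expression)), "missing expression values")
    return(drop(crossprod(expression, weights))[seq_len(ncol(expression))])
  }
  stop_if_not(length(expression) == length(weights),
              "expression vector must align with the signature")
  if (!is.null(names(expression)) && !is.null(names(weights))) {
    stop_if_not(all(names(weights) %in% names(expression)),
                "missing gene values in expression vector")
    expression <- expression[names(weights)]
  }
  stop_if_not(all(is.finite(expression)), "missing expression values")
  sum(weights * expression)
}

#' Fit the group-wise LPS Gaussians of the Bayes classifier
#'
#' Estimates the mean and (sample) variance of the linear predictor score in
#' the sensitive (group 1) and insensitive (group 2) training lines.
#'
#' @param expr gene x sample training matrix (must contain the signature).
#' @param labels two-level vector over training samples.
#' @param weights named t-statistic weights defining the LPS.
#' @param sensitive_level label mapped to group 1 (default `"sensitive"`).
#' @return object of class `signature_model`: list with `genes`, `weights`,
#'   `mu1`, `var1`, `mu2`, `var2`, `sensitive_level`.
#' @export
fit_lps_groups <- function(expr, labels, weights,
                           sensitive_level = "sensitive") {
  labels <- as.character(labels)
  g1 <- labels == sensitive_level
  stop_if_not(sum(g1) >= 2 && sum(!g1) >= 2,
              "both groups need at least 2 samples")
  lps <- lps_score(expr, weights)
  v1 <- stats::var(lps[g1]); v2 <- stats::var(lps[!g1])
  stop_if_not(v1 > 0 && v2 > 0,
              "zero within-group LPS variance: degenerate Gaussian")
  model <- list(
    genes = names(weights), weights = weights,
    mu1 = mean(lps[g1]), var1 = v1,
    mu2 = mean(lps[!g1]), var2 = v2,
    sensitive_level = sensitive_level
  )
  class(model) <- "signature_model"
  model
}

#' Posterior probability of sensitivity from an LPS value
#'
#' Bayes' rule with the two fitted normal densities and implicit equal priors:
#' \deqn{P(sensitive) = \frac{\phi(LPS; \mu_1, \sigma_1^2)}
#'   {\phi(LPS; \mu_1, \sigma_1^2) + \phi(LPS; \mu_2, \sigma_2^2)}}
#' The predicted class is the posterior argmax; an exact tie is flagged
#' `undecided`.
#'
#' @param lps numeric LPS value(s).
#' @param model a `signature_model` from [fit_lps_groups()].
#' @param cell_line optional identifier(s).
#' @return data frame `cell_line`, `lps`, `p_sensitive`, `p_insensitive`,
#'   `predicted_class`.
#' @export
posterior_sensitive <- function(lps, model, cell_line = NULL) {
  stopifnot(inherits(model, "signature_model"))
  stop_if_not(all(is.finite(lps)), "non-finite LPS")
  # work with log densities for numerical stability far from both means
  l1 <- stats::dnorm(lps, model$mu1, sqrt(model$var1), log = TRUE)
  l2 <- stats::dnorm(lps, model$mu2, sqrt(model$var2), log = TRUE)
  p1 <- 1 / (1 + exp(l2 - l1))
  cls <- ifelse(p1 > 0.5, "sensitive",
                ifelse(p1 < 0.5, "insensitive", "undecided"))
  if (is.null(cell_line)) cell_line <- rep(NA_character_, length(lps))
  data.frame(
    cell_line = cell_line, lps = lps,
    p_sensitive = p1, p_insensitive = 1 - p1,
    predicted_class = cls
  )
}

# Stratified fold assignment: within each class, shuffle and deal round-robin
# so every fold keeps both classes wherever sizes allow.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the LPS/Bayes classifier
#'
#' For each repeat, samples are dealt into stratified folds (reseeded as
#' `seed + repeat index`); within each fold the t-statistic weights and
#' group Gaussians are fitted on the training lines only and posteriors are
#' computed for the held-out lines. Accuracy is the fraction of correct
#' predictions pooled over folds; the report averages over repeats.
#'
#' By default the signature genes are fixed inputs, i.e. selection happened
#' outside the CV (the report carries a leakage note); `nested = TRUE`
#' re-runs the selector inside every training fold instead.
#'
#' @param expr gene x sample matrix (full panel; grouped lines only).
#' @param labels two-level vector over samples.
#' @param genes signature gene ids (rows of `expr`).
#' @param n_repeats,n_folds CV design (defaults 20 and 10).
#' @param seed integer base seed.
#' @param sensitive_level label mapped to group 1.
#' @param nested re-select genes within each training fold.
#' @param selector function `(expr, labels) -> genes` used when `nested`.
#' @return object of class `cv_report`: list with `accuracy` (mean over
#'   repeats), `per_repeat` accuracies, `tally` (per-line correct counts),
#'   `n_repeats`, `n_folds`, `selection_outside_cv`.
#' @export
repeated_cv <- function(expr, labels, genes, n_repeats = 20, n_folds = 10,
                        seed = 1, sensitive_level = "sensitive",
                        nested = FALSE,
                        selector = function(e, l) boruta_select(e, l, seed = seed)) {
  labels <- as.character(labels)
  stop_if_not(length(unique(labels)) == 2, "two classes required")
  stop_if_not(all(genes %in% rownames(expr)),
              "signature genes missing from the matrix")
  n <- ncol(expr)
  ids <- colnames(expr)
  if (is.null(ids)) ids <- paste0("line_", seq_len(n))

  per_repeat <- numeric(n_repeats)
  tally <- setNames(integer(n), ids)
  for (r in seq_len(n_repeats)) {
    correct <- logical(n)
    with_local_seed(seed + r, {
      fold <- .stratified_folds(labels, n_folds)
      for (k in sort(unique(fold))) {
        tr <- fold != k
        te <- !tr
        sig <- if (nested) {
          selector(expr[, tr, drop = FALSE], labels[tr])
        } else {
          genes
        }
        w <- t_weights(expr[sig, tr, drop = FALSE], labels[tr],
                       sensitive_level = sensitive_level)
        model <- fit_lps_groups(expr[sig, tr, drop = FALSE], labels[tr], w,
                                sensitive_level = sensitive_level)
        lps_te <- lps_score(expr[sig, te, drop = FALSE], w)
        pred <- posterior_sensitive(lps_te, model)
        truth1 <- labels[te] == sensitive_level
        correct[te] <- ifelse(truth1, pred$predicted_class == "sensitive",
                              pred$predicted_class == "insensitive")
      }
    })
    per_repeat[r] <- mean(correct)
    tally <- tally + as.integer(correct)
  }
  out <- list(
    accuracy = mean(per_repeat),
    per_repeat = per_repeat,
    tally = tally,
    n_repeats = n_repeats, n_folds = n_folds,
    selection_outside_cv = !nested
  )
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated CV: %d x %d-fold, mean accuracy %.3f\n",
              x$n_repeats, x$n_folds, x$accuracy))
  if (x$selection_outside_cv) {
    cat("note: signature selected outside CV (as-described procedure);",
        "accuracy may be optimistic. Use nested = TRUE for unbiased folds.\n")
  }
  invisible(x)
}
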