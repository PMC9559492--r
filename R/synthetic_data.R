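#' Specification of a synthetic cell-line panel
#'
#' Describes the study conditions the generator emulates: a 50-line panel of
#' three tumour types treated with 3.16-fold serial dilutions spanning
#' 1-10,000 nM, sigmoidal inhibition plus Gaussian noise on the % scale, and a
#' log2(FPKM) expression matrix in which a small set of genes is linearly
#' (hence monotonically) associated with the true AUC among many null genes.
#'
#' @param n_cell_lines panel size (default 50).
#' @param tumour_types named proportions of tumour-type labels (default
#'   10 colorectal / 31 liver / 9 pancreatic out of 50).
#' @param dose_series concentrations in nM, strictly increasing (default nine
#'   3.16-fold steps from 1 nM).
#' @param param_ranges list of `c(min, max)` ranges from which each line's
#'   true 4PL parameters (`bottom`, `top`, `log_ec50`, `hill_slope`) are drawn
#'   uniformly.
#' @param noise_sd sd of additive Gaussian noise on % inhibition, truncated to
#'   `[-20, 120]` to mirror the fit constraints (default 2).
#' @param n_replicates treated replicates per dose (default 2).
#' @param n_genes,n_informative expression matrix size and number of
#'   AUC-linked genes (defaults 1000 and 20).
#' @param effect_size slope of informative-gene expression vs true AUC
#'   (log2-FPKM per AUC unit, default 0.01).
#' @param expression_noise_sd residual sd on the log2-FPKM scale (default 1).
#' @param seed integer seed.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(n_cell_lines = 50,
                       tumour_types = c(colorectal = 10 / 50, liver = 31 / 50,
                                        pancreatic = 9 / 50),
                       dose_series = 3.16^(0:8),
                       param_ranges = list(bottom = c(-10, 10),
                                           top = c(60, 110),
                                           log_ec50 = c(1, 4.5),
                                           hill_slope = c(0.7, 2)),
                       noise_sd = 2, n_replicates = 2,
                       n_genes = 1000, n_informative = 20,
                       effect_size = 0.01, expression_noise_sd = 1,
                       seed = 1) {
  stop_if_not(n_cell_lines >= 3, "n_cell_lines must be at least 3")
  stop_if_not(length(dose_series) >= 5 && all(diff(dose_series) > 0) &&
                all(dose_series > 0),
              "dose_series must be >= 5 strictly increasing positive doses")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(n_genes >= 1 && n_informative >= 0 && n_informative <= n_genes,
              "need 0 <= n_informative <= n_genes and n_genes >= 1")
  stop_if_not(abs(sum(tumour_types) - 1) < 1e-8,
              "tumour_type proportions must sum to 1")
  out <- list(
    n_cell_lines = n_cell_lines, tumour_types = tumour_types,
    dose_series = dose_series, param_ranges = param_ranges,
    noise_sd = noise_sd, n_replicates = n_replicates,
    n_genes = n_genes, n_informative = n_informative,
    effect_size = effect_size, expression_noise_sd = expression_noise_sd,
    seed = seed
  )
  class(out) <- "panel_spec"
  out
}

#' Generate a synthetic cell-line panel
#'
#' Produces everything the pipeline consumes, plus the planted truth needed by
#' recovery tests: a long-format viability plate table (vehicle, T0 and
#' treated wells; treated signal = vehicle mean x (1 - inhibition/100) with
#' truncated-Gaussian noise on the % scale), the true per-line 4PL parameters
#' and closed-form AUCs, the true z-score sensitivity labels, and a
#' gene x cell-line log2(FPKM) matrix in which exactly `n_informative` genes
#' follow `intercept + effect_size * AUC_true + noise` while the remaining
#' genes are independent noise around gene-specific baselines.
#'
#' @param spec a [panel_spec()].
#' @return list with `plates` (data frame), `truth` (per-line data frame:
#'   true 4PL parameters, `auc_true`, `z_auc_true`, `sens_class_true`,
#'   `tumour_type`), `expression` (matrix), `informative_genes` (character).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_cell_lines
    ids <- sprintf("CL%02d", seq_len(n))
    ttype <- rep(names(spec$tumour_types),
                 times = round(spec$tumour_types * n))
    ttype <- ttype[seq_len(n)]
    if (length(ttype) < n) ttype <- c(ttype, rep(names(spec$tumour_types)[1],
                                                 n - length(ttype)))

    pr <- spec$param_ranges
    truth <- data.frame(
      cell_line = ids, tumour_type = ttype,
      bottom = stats::runif(n, pr$bottom[1], pr$bottom[2]),
      top = stats::runif(n, pr$top[1], pr$top[2]),
      log_ec50 = stats::runif(n, pr$log_ec50[1], pr$log_ec50[2]),
      hill_slope = stats::runif(n, pr$hill_slope[1], pr$hill_slope[2])
    )
    truth$auc_true <- mapply(auc_4pl, truth$bottom, truth$top,
                             truth$log_ec50, truth$hill_slope)
    zc <- zscore_classify(truth$auc_true, cell_lines = ids,
                          tumour_type = ttype)
    truth$z_auc_true <- zc$z_auc
    truth$sens_class_true <- zc$sens_class

    x <- log10(spec$dose_series)
    vehicle_signal <- 10000
    plates <- vector("list", n)
    for (i in seq_len(n)) {
      inh_true <- four_pl(x, truth$bottom[i], truth$top[i],
                          truth$log_ec50[i], truth$hill_slope[i])
      rows <- list(
        data.frame(cell_line = ids[i], drug = "drug", concentration_nM = 0,
                   replicate = seq_len(spec$n_replicates),
                   signal = vehicle_signal, well_type = "vehicle"),
        data.frame(cell_line = ids[i], drug = "drug", concentration_nM = 0,
                   replicate = seq_len(spec$n_replicates),
                   signal = vehicle_signal * 0.25, well_type = "t0")
      )
      for (r in seq_len(spec$n_replicates)) {
        inh_obs <- inh_true
        if (spec$noise_sd > 0) {
          inh_obs <- inh_obs + stats::rnorm(length(x), 0, spec$noise_sd)
        }
        inh_obs <- pmin(pmax(inh_obs, -20), 120)
        rows[[length(rows) + 1]] <- data.frame(
          cell_line = ids[i], drug = "drug",
          concentration_nM = spec$dose_series,
          replicate = r,
          signal = vehicle_signal * (1 - inh_obs / 100),
          well_type = "treated"
        )
      }
      plates[[i]] <- do.call(rbind, rows)
    }
    plates <- do.call(rbind, plates)
    rownames(plates) <- NULL

    g <- spec$n_genes
    genes <- sprintf("GENE%04d", seq_len(g))
    expr <- matrix(NA_real_, g, n, dimnames = list(genes, ids))
    k <- spec$n_informative
    info <- if (k > 0) genes[seq_len(k)] else character(0)
    if (k > 0) {
      intercepts <- stats::runif(k, 3, 6)
      for (j in seq_len(k)) {
        expr[j, ] <- intercepts[j] + spec$effect_size * truth$auc_true +
          stats::rnorm(n, 0, spec$expression_noise_sd)
      }
    }
    if (g > k) {
      baselines <- stats::runif(g - k, 0, 8)
      expr[(k + 1):g, ] <- baselines +
        matrix(stats::rnorm((g - k) * n, 0, spec$expression_noise_sd), g - k, n)
    }

    list(plates = plates, truth = truth, expression = expr,
         informative_genes = info)
  })
}

#' Two-class expression matrix with planted discriminative genes
#'
#' Calibration construct for the signature selector and classifier: two
#' balanced groups, `n_informative` genes shifted by `shift` standard
#' deviations between classes (unit within-class sd), remaining genes pure
#' noise. With k informative genes at shift s the linear predictor score has
#' Mahalanobis separation `s * sqrt(k)` between classes.
#'
#' @param n_per_class samples per class.
#' @param n_genes total genes; `n_informative` of them discriminative.
#' @param n_informative number of planted genes.
#' @param shift standardized between-class mean shift of the planted genes.
#' @param seed integer seed.
#' @return list with `expression` (gene x sample), `labels`
#'   (sensitive/insensitive), `informative_genes`.
#' @export
generate_two_class_expression <- function(n_per_class, n_genes, n_informative,
                                          shift = 2, seed = 1) {
  stop_if_not(n_informative <= n_genes, "n_informative must be <= n_genes")
  stop_if_not(n_per_class >= 2, "need at least 2 samples per class")
  with_local_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("sensitive", "insensitive"), each = n_per_class)
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    ids <- sprintf("S%03d", seq_len(n))
    expr <- matrix(stats::rnorm(n_genes * n), n_genes, n,
                   dimnames = list(genes, ids))
    if (n_informative > 0) {
      expr[seq_len(n_informative), labels == "sensitive"] <-
        expr[seq_len(n_informative), labels == "sensitive"] + shift
    }
    list(expression = expr, labels = labels,
         informative_genes = genes[seq_len(n_informative)])
  })
}

#' Specification of a synthetic drug-combination matrix
#'
#' @param doses_a,doses_b dose vectors, each including 0 (defaults mirror a
#'   combination design of 0-0.1 uM of one drug against 0-10 uM of the other).
#' @param params_a,params_b monotherapy 4PL parameters
#'   (`bottom`, `top`, `log_ec50` on log10 of the dose unit, `hill_slope`).
#' @param planted_delta % inhibition added to every combination well on top of
#'   the HSA null surface.
#' @param noise_sd Gaussian noise sd (% inhibition) on non-vehicle wells.
#' @param seed integer seed.
#' @return list of class `synergy_spec`.
#' @export
synergy_spec <- function(doses_a = c(0, 0.01, 0.02, 0.05, 0.1),
                         doses_b = c(0, 1, 2, 5, 10),
                         params_a = list(bottom = 0, top = 90,
                                         log_ec50 = log10(0.03), hill_slope = 1.2),
                         params_b = list(bottom = 0, top = 95,
                                         log_ec50 = log10(3), hill_slope = 1),
                         planted_delta = 0, noise_sd = 0, seed = 1) {
  stop_if_not(any(doses_a == 0) && any(doses_b == 0),
              "each dose grid must include the zero dose")
  stop_if_not(is.finite(planted_delta), "planted_delta must be finite")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  out <- list(doses_a = doses_a, doses_b = doses_b,
              params_a = params_a, params_b = params_b,
              planted_delta = planted_delta, noise_sd = noise_sd, seed = seed)
  class(out) <- "synergy_spec"
  out
}

# monotherapy response with the zero-dose convention f(0) = 0
.mono_response <- function(dose, p) {
  ifelse(dose == 0, 0,
         four_pl(log10(dose), p$bottom, p$top, p$log_ec50, p$hill_slope))
}

#' Generate a dose-combination inhibition grid
#'
#' Monotherapy rows/columns follow each drug's 4PL; combination wells equal
#' the HSA null `max(monotherapy responses)` plus `planted_delta` plus noise.
#' The vehicle well (0, 0) is exactly 0.
#'
#' @param spec a [synergy_spec()].
#' @return list with `response` (matrix doses_a x doses_b), `doses_a`,
#'   `doses_b`, `true_delta` (the planted value).
#' @export
generate_synergy_matrix <- function(spec) {
  stopifnot(inherits(spec, "synergy_spec"))
  with_local_seed(spec$seed, {
    da <- spec$doses_a
    db <- spec$doses_b
    ra <- .mono_response(da, spec$params_a)
    rb <- .mono_response(db, spec$params_b)
    resp <- matrix(NA_real_, length(da), length(db),
                   dimnames = list(da, db))
    for (i in seq_along(da)) {
      for (j in seq_along(db)) {
        if (da[i] == 0 && db[j] == 0) {
          resp[i, j] <- 0
        } else if (da[i] == 0) {
          resp[i, j] <- rb[j]
        } else if (db[j] == 0) {
          resp[i, j] <- ra[i]
        } else {
          resp[i, j] <- max(ra[i], rb[j]) + spec$planted_delta
        }
      }
    }
    if (spec$noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(resp), 0, spec$noise_sd),
                      nrow(resp), ncol(resp))
      noise[da == 0, db == 0] <- 0   # vehicle well stays normalized
      resp <- resp + noise
    }
    list(response = resp, doses_a = da, doses_b = db,
         true_delta = spec$planted_delta)
  })
}

#' Generate per-nucleus olive-tail-moment tables
#'
#' OTM values are drawn from a gamma distribution with the requested mean and
#' shape (right-skewed, positive). `shape = Inf` yields noise-free constant
#' values equal to the mean.
#'
#' @param otm_means named numeric vector: mean OTM per condition (> 0).
#' @param n_comets nuclei per condition (>= 1; protocols score at least 50).
#' @param shape gamma shape parameter (default 3).
#' @param seed integer seed.
#' @return data frame with `condition` and `otm`.
#' @export
generate_comet_samples <- function(otm_means, n_comets = 50, shape = 3,
                                   seed = 1) {
  stop_if_not(all(otm_means > 0), "OTM means must be positive")
  stop_if_not(n_comets >= 1, "n_comets must be >= 1")
  stop_if_not(shape > 0, "gamma shape must be positive")
  conds <- names(otm_means)
  if (is.null(conds)) conds <- paste0("cond_", seq_along(otm_means))
  with_local_seed(seed, {
    do.call(rbind, lapply(seq_along(otm_means), function(i) {
      otm <- if (is.infinite(shape)) {
        rep(otm_means[[i]], n_comets)
      } else {
        stats::rgamma(n_comets, shape = shape, scale = otm_means[[i]] / shape)
      }
      data.frame(condition = conds[i], otm = otm)
    }))
  })
}

#' Generate a qPCR Ct table with a stable reference gene
#'
#' Reference (housekeeping) Cts are drawn around `reference_ct`; target Cts
#' encode the requested per-group fold changes relative to the control group
#' (`Ct_target = baseline - log2(fold)` plus noise).
#'
#' @param fold_changes named numeric vector of true fold changes per group;
#'   the control group should have value 1.
#' @param n_samples samples per group.
#' @param n_replicates technical replicates per sample.
#' @param target_baseline_ct,reference_ct mean Cts (defaults 25 and 18).
#' @param noise_sd technical Ct noise (default 0.1).
#' @param seed integer seed.
#' @return data frame with `sample`, `group`, `replicate`, `target_ct`,
#'   `reference_ct`.
#' @export
generate_qpcr_table <- function(fold_changes, n_samples = 3, n_replicates = 3,
                                target_baseline_ct = 25, reference_ct = 18,
                                noise_sd = 0.1, seed = 1) {
  stop_if_not(!is.null(names(fold_changes)), "fold_changes must be named")
  stop_if_not(all(fold_changes > 0), "fold changes must be positive")
  with_local_seed(seed, {
    rows <- list()
    for (grp in names(fold_changes)) {
      for (s in seq_len(n_samples)) {
        sid <- paste0(grp, "_s", s)
        rows[[length(rows) + 1]] <- data.frame(
          sample = sid, group = grp, replicate = seq_len(n_replicates),
          target_ct = target_baseline_ct - log2(fold_changes[[grp]]) +
            stats::rnorm(n_replicates, 0, noise_sd),
          reference_ct = reference_ct + stats::rnorm(n_replicates, 0, noise_sd)
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
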