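test_that("generators are byte-deterministic under a fixed seed", {
  spec <- panel_spec(n_cell_lines = 10, n_genes = 50, n_informative = 5, seed = 5)
  expect_identical(generate_panel(spec), generate_panel(spec))

  ss <- synergy_spec(planted_delta = 5, noise_sd = 2, seed = 7)
  expect_identical(generate_synergy_matrix(ss), generate_synergy_matrix(ss))

  expect_identical(generate_comet_samples(c(a = 4, b = 2), seed = 3),
                   generate_comet_samples(c(a = 4, b = 2), seed = 3))

  expect_identical(generate_qpcr_table(c(control = 1, treated = 0.5), seed = 2),
                   generate_qpcr_table(c(control = 1, treated = 0.5), seed = 2))
})

test_that("noise-free plates refit to the planted 4PL parameters", {
  spec <- panel_spec(n_cell_lines = 4, n_genes = 5, n_informative = 0,
                     noise_sd = 0, seed = 13)
  panel <- generate_panel(spec)
  fits <- fit_panel(panel$plates)
  fits <- fits[match(panel$truth$cell_line, fits$cell_line), ]
  for (col in c("bottom", "top", "log_ec50", "hill_slope")) {
    expect_lt(max(abs(fits[[col]] - panel$truth[[col]]) /
                    pmax(abs(panel$truth[[col]]), 1)), 1e-6)
  }
  expect_equal(fits$auc, panel$truth$auc_true, tolerance = 1e-6)
})

test_that("panel structure matches the spec: plates, truth, expression", {
  spec <- panel_spec(n_cell_lines = 12, n_genes = 40, n_informative = 4,
                     seed = 21)
  panel <- generate_panel(spec)
  expect_equal(nrow(panel$truth), 12)
  expect_equal(dim(panel$expression), c(40, 12))
  expect_equal(length(panel$informative_genes), 4)
  expect_setequal(unique(panel$plates$well_type), c("vehicle", "t0", "treated"))
  # replicate count per dose per line
  tr <- panel$plates[panel$plates$well_type == "treated" &
                       panel$plates$cell_line == "CL01", ]
  expect_equal(nrow(tr), length(spec$dose_series) * spec$n_replicates)
  # truth labels follow the z rule on the true AUCs
  zc <- zscore_classify(panel$truth$auc_true)
  expect_equal(as.character(panel$truth$sens_class_true),
               as.character(zc$sens_class))
})

test_that("with zero effect size the Spearman screen runs at its null level", {
  sel <- 0; tot <- 0
  for (s in 1:10) {
    spec <- panel_spec(n_cell_lines = 50, n_genes = 2000, n_informative = 0,
                       noise_sd = 0, effect_size = 0, seed = 300 + s)
    panel <- generate_panel(spec)
    scr <- spearman_screen(panel$expression,
                           setNames(panel$truth$auc_true,
                                    colnames(panel$expression)))
    sel <- sel + sum(scr$selected); tot <- tot + nrow(scr)
  }
  # 20,000 null genes at alpha = 0.001: expect ~20 selections
  expect_gte(sel, qbinom(0.005, tot, 0.001))
  expect_lte(sel, qbinom(0.995, tot, 0.001))
})

test_that("informative genes are linear in the true AUC", {
  spec <- panel_spec(n_cell_lines = 40, n_genes = 30, n_informative = 3,
                     effect_size = 0.05, expression_noise_sd = 1e-9, seed = 31)
  panel <- generate_panel(spec)
  for (g in panel$informative_genes) {
    fit <- lm(panel$expression[g, ] ~ panel$truth$auc_true)
    expect_equal(unname(coef(fit)[2]), 0.05, tolerance = 1e-6)
  }
})

test_that("synergy matrices carry the planted HSA structure", {
  null_ss <- synergy_spec(planted_delta = 0, noise_sd = 0, seed = 1)
  m0 <- generate_synergy_matrix(null_ss)
  expect_equal(hsa_delta(m0$response, m0$doses_a, m0$doses_b)$summary_delta, 0)

  ss10 <- synergy_spec(planted_delta = 10, noise_sd = 0, seed = 1)
  m10 <- generate_synergy_matrix(ss10)
  expect_equal(hsa_delta(m10$response, m10$doses_a, m10$doses_b)$summary_delta, 10)
  expect_equal(m10$response[1, 1], 0)   # vehicle well normalized

  expect_error(synergy_spec(doses_a = c(1, 2)), "zero dose")
})

test_that("comet tables have the requested size and noise-free ratio", {
  tab <- generate_comet_samples(c(control = 6, treated = 3), n_comets = 50,
                                seed = 2)
  expect_equal(as.integer(table(tab$condition)), c(50L, 50L))
  expect_true(all(tab$otm >= 0))

  exact <- generate_comet_samples(c(control = 6, treated = 3), n_comets = 50,
                                  shape = Inf, seed = 2)
  expect_equal(percent_crosslinks(exact$otm[exact$condition == "treated"],
                                  exact$otm[exact$condition == "control"]), 50)
  expect_error(generate_comet_samples(c(a = -1)), "positive")
})

test_that("invalid panel specifications are rejected", {
  expect_error(panel_spec(n_genes = 10, n_informative = 20), "n_informative")
  expect_error(panel_spec(dose_series = c(10, 5, 1)), "increasing")
  expect_error(panel_spec(noise_sd = -1), "noise_sd")
})
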