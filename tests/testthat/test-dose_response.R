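test_that("inhibition is computed relative to the vehicle control", {
  doses <- rep(3.16^(0:5), each = 2)
  ctrl <- c(10000, 10000)

  same <- compute_inhibition(doses, rep(10000, length(doses)), ctrl)
  expect_equal(same$inhibition, rep(0, 6))
  expect_equal(same$n_replicates, rep(2L, 6))

  dead <- compute_inhibition(doses, rep(0, length(doses)), ctrl)
  expect_equal(dead$inhibition, rep(100, 6))

  stim <- compute_inhibition(doses, rep(12000, length(doses)), ctrl)
  expect_equal(stim$inhibition, rep(-20, 6))

  expect_error(compute_inhibition(doses, rep(1, length(doses)), c(0, 1)),
               "positive")
})

test_that("closed-form AUC matches its limits and the quadrature oracle", {
  # flat curve: AUC = 4c over [0, 4]
  expect_equal(auc_4pl(30, 30, 2, 1), 120)
  # zero Hill slope degenerates to the flat-curve average
  expect_equal(auc_4pl(0, 100, 2, 0), 50 * 4)
  # step-function limit: 100 * (4 - logEC50)
  expect_equal(auc_4pl(0, 100, 2, 1000), 200, tolerance = 1e-6)
  expect_equal(auc_4pl(0, 100, 0.5, 1000), 350, tolerance = 1e-6)

  # spec'd quadrature case at high panel count
  q <- simpson(function(x) fpl_oracle(x, 0, 100, 2, 1), 0, 4, n = 1e5)
  expect_lt(abs(auc_4pl(0, 100, 2, 1) - q) / abs(q), 1e-8)

  # randomized draws within the constraint box
  set.seed(41)
  for (i in 1:50) {
    b <- runif(1, -20, 100); t <- runif(1, b + 1, 120)
    e <- runif(1, -1, 5); h <- runif(1, 0.2, 3) * sample(c(-1, 1), 1)
    cf <- auc_4pl(b, t, e, h)
    q <- simpson(function(x) fpl_oracle(x, b, t, e, h), 0, 4, n = 2e4)
    expect_lt(abs(cf - q) / max(abs(q), 1), 1e-8)
  }
})

test_that("AUC is strictly increasing in both asymptotes", {
  set.seed(7)
  for (i in 1:20) {
    b <- runif(1, -20, 50); t <- runif(1, b + 5, 120)
    e <- runif(1, 0, 4); h <- runif(1, 0.3, 3)
    expect_gt(auc_4pl(b, t + 1, e, h), auc_4pl(b, t, e, h))
    expect_gt(auc_4pl(b + 1, t, e, h), auc_4pl(b, t, e, h))
  }
})

test_that("noise-free curves are recovered to high precision", {
  x <- log10(3.16^(0:8))
  for (pars in list(c(0, 100, 3, 1), c(-5, 90, 1.8, 2), c(10, 110, 2.5, 0.8))) {
    curve <- data.frame(x = x,
                        inhibition = fpl_oracle(x, pars[1], pars[2], pars[3], pars[4]))
    fit <- fit_4pl(curve)
    est <- c(fit$bottom, fit$top, fit$log_ec50, fit$hill_slope)
    expect_lt(max(abs(est - pars) / pmax(abs(pars), 1)), 1e-6)
    expect_true(fit$acceptable)
  }
})

test_that("flat curves are flagged unacceptable with unidentifiable EC50", {
  flat <- compute_inhibition(3.16^(0:8), rep(10000, 9), rep(10000, 2))
  fit <- fit_4pl(flat)
  expect_equal(fit$bottom, 0, tolerance = 1e-8)
  expect_equal(fit$top, 0, tolerance = 1e-8)
  expect_false(fit$acceptable)
  expect_gt(fit$se_ec50_ratio, 0.4)
})

test_that("the 40% EC50 fitting-error rule is a strict threshold", {
  expect_true(fit_acceptable(0.39))
  expect_false(fit_acceptable(0.41))
  expect_false(fit_acceptable(0.39, converged = FALSE))
})

test_that("fits are invariant to dose-unit rescaling up to a logEC50 shift", {
  x <- log10(3.16^(0:8))
  y <- fpl_oracle(x, 2, 95, 2.2, 1.3) + c(0.5, -0.3, 0.2, 0, -0.4, 0.1, 0.3, -0.2, 0)
  f1 <- fit_4pl(data.frame(x = x, inhibition = y))
  f2 <- fit_4pl(data.frame(x = x + 3, inhibition = y))  # doses x 1000
  expect_equal(f2$log_ec50 - f1$log_ec50, 3, tolerance = 1e-6)
  expect_equal(f2$bottom, f1$bottom, tolerance = 1e-6)
  expect_equal(f2$top, f1$top, tolerance = 1e-6)
  expect_equal(f2$hill_slope, f1$hill_slope, tolerance = 1e-6)
})

test_that("compute_auc reports flags alongside the endpoint", {
  x <- log10(3.16^(0:8))
  curve <- data.frame(x = x, inhibition = fpl_oracle(x, 0, 100, 2, 1))
  fit <- fit_4pl(curve)
  end <- compute_auc(fit)
  expect_equal(end$auc, auc_4pl(0, 100, 2, 1), tolerance = 1e-6)
  expect_true(end$from_acceptable_fit)
  expect_false(end$degenerate)
  expect_equal(c(end$a, end$b), c(0, 4))
})
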