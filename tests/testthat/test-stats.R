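test_that("covariance of a linear-response fit matches closed-form least squares", {
  setup <- linear_signal_setup(seed = 3)
  fit <- fit_gmma(setup$model, list(setup$exp), setup$params)
  V <- linear_analytic_cov(setup)
  # undo the reduced-chisq scaling to compare against the sigma-based formula
  V_fit <- fit$covariance / fit$chisq_r
  expect_equal(unname(V_fit), unname(V), tolerance = 1e-6)
  expect_equal(unname(diag(fit$correlation)), c(1, 1))
  expect_true(all(abs(fit$correlation) <= 1 + 1e-12))
})

test_that("orthogonal-by-design parameters show near-zero cross-correlation", {
  # two components measured in disjoint blocks: their signal coefficients
  # cannot correlate
  m <- binding_model(c("A", "B"), list())
  d <- data.frame(tot.A = c(1e-6, 2e-6, 3e-6, 0, 0, 0),
                  tot.B = c(0, 0, 0, 1e-6, 2e-6, 3e-6))
  e <- simulate_experiment(m, "signal", d,
                           locals = list(`coeff.A` = 1e5, `coeff.B` = 2e5),
                           sigma = 0.02, seed = 9, name = "s1")
  p <- default_parameters(m, list(e))
  p$free <- p$name %in% c("s1:coeff.A", "s1:coeff.B")
  fit <- fit_gmma(m, list(e), p)
  expect_lt(abs(fit$correlation[1, 2]), 0.05)
})

test_that("1-D profile of a quadratic surface matches the analytic width", {
  setup <- linear_signal_setup(seed = 13)
  fit <- fit_gmma(setup$model, list(setup$exp), setup$params)
  pr <- profile_projection(fit, "lin1:baseline", levels = 0.95,
                           n = 41, span = 4 * fit$stderr[["lin1:baseline"]])
  # profiled chisq never dips below the global minimum; minimum at best fit
  expect_true(all(pr$chisq >= pr$chisq_min - 1e-9))
  i0 <- which.min(abs(pr$grid[[1]] - fit$value[["lin1:baseline"]]))
  expect_equal(pr$chisq[i0], pr$chisq_min, tolerance = 1e-6)
  # analytic half-width of the F contour for a linear model: the profiled
  # chisq rises as chisq_min + (delta)^2 / V_jj with V the sigma-based
  # least-squares covariance
  V <- linear_analytic_cov(setup)
  crit_delta <- pr$crit[["95%"]] - pr$chisq_min
  half_analytic <- sqrt(crit_delta * V[1, 1])
  # find the crossing by interpolation on the grid
  g <- pr$grid[[1]]
  above <- which(pr$chisq > pr$crit[["95%"]] & g > fit$value[["lin1:baseline"]])
  i <- above[1]
  x1 <- g[i - 1]; x2 <- g[i]
  y1 <- pr$chisq[i - 1]; y2 <- pr$chisq[i]
  crossing <- x1 + (pr$crit[["95%"]] - y1) / (y2 - y1) * (x2 - x1)
  half_measured <- crossing - fit$value[["lin1:baseline"]]
  expect_equal(half_measured, half_analytic, tolerance = 0.02)
})

test_that("2-D profile contour area matches the analytic ellipse within a few %", {
  setup <- linear_signal_setup(seed = 17)
  fit <- fit_gmma(setup$model, list(setup$exp), setup$params)
  se <- fit$stderr
  grid <- list(`lin1:baseline` = seq(fit$value[1] - 4 * se[1],
                                     fit$value[1] + 4 * se[1], length.out = 61),
               `lin1:coeff.A` = seq(fit$value[2] - 4 * se[2],
                                    fit$value[2] + 4 * se[2], length.out = 61))
  pr <- profile_projection(fit, c("lin1:baseline", "lin1:coeff.A"),
                           grid = grid, levels = 0.95)
  area <- contour_area(pr, 0.95)
  # analytic: {d' V^-1 d <= crit_delta} has area pi*crit_delta*sqrt(det V)
  V <- linear_analytic_cov(setup)
  crit_delta <- pr$crit[["95%"]] - pr$chisq_min
  area_analytic <- pi * crit_delta * sqrt(det(V))
  expect_equal(area, area_analytic, tolerance = 0.05)
  # best-fit node lies inside every contour
  expect_lte(min(pr$chisq, na.rm = TRUE), pr$crit[["95%"]])
})

test_that("Monte-Carlo intervals are reproducible and match analytic errors", {
  setup <- linear_signal_setup(seed = 23)
  fit <- fit_gmma(setup$model, list(setup$exp), setup$params)
  mc1 <- monte_carlo_intervals(fit, n_replicates = 500, seed = 77)
  mc2 <- monte_carlo_intervals(fit, n_replicates = 500, seed = 77)
  expect_identical(mc1$intervals, mc2$intervals)
  V <- linear_analytic_cov(setup)
  se_analytic <- sqrt(diag(V))
  half <- (mc1$intervals$upper - mc1$intervals$lower) / 2
  # 68% percentile half-width estimates one standard error
  expect_equal(unname(half), unname(se_analytic), tolerance = 0.15)
  expect_equal(mc1$intervals$sd, unname(se_analytic), tolerance = 0.15)
})

test_that("Monte-Carlo interval width collapses as noise goes to zero", {
  widths <- sapply(c(0.05, 5e-5), function(sg) {
    setup <- linear_signal_setup(sigma = sg, seed = 29)
    fit <- fit_gmma(setup$model, list(setup$exp), setup$params)
    mc <- monte_carlo_intervals(fit, n_replicates = 100, seed = 5)
    mc$intervals$upper - mc$intervals$lower
  })
  # widths scale down with sigma: three orders of magnitude here
  expect_true(all(widths[, 2] < 2e-3 * widths[, 1]))
})

test_that("weight scan: identical weight sets give the single interval envelope", {
  setup <- linear_signal_setup(seed = 31)
  fit <- fit_gmma(setup$model, list(setup$exp), setup$params)
  ws <- weight_scan(fit, list(1, 1), level = 0.68)
  d1 <- ws$per_set[ws$per_set$set == 1, c("lower", "upper")]
  expect_equal(ws$envelope$lower, d1$lower)
  expect_equal(ws$envelope$upper, d1$upper)
  expect_false(any(ws$envelope$flagged))
  expect_error(weight_scan(fit, list(c(0), c(1))), "all-zero")
})

test_that("weight scan flags an experiment simulated from a different Kd", {
  m <- model_1to1(log10beta = 6)
  d <- data.frame(tot.A = 1e-6, tot.B = 10^seq(-7, -4.5, length.out = 10))
  e1 <- simulate_experiment(m, "sw", d, sigma = 0.01, seed = 51, name = "sv1")
  e2 <- simulate_experiment(m, "sw", d, sigma = 0.01, seed = 52, name = "sv2")
  m_shift <- model_1to1(log10beta = 6.8)   # inconsistent truth
  e3 <- simulate_experiment(m_shift, "sw", d, sigma = 0.01, seed = 53,
                            name = "sv3")
  p <- default_parameters(m, list(e1, e2, e3))
  p$free <- p$name == "log10beta.AB"
  fit <- fit_gmma(m, list(e1, e2, e3), p)
  ws <- weight_scan(fit, list(c(1, 1, 1), c(0.2, 0.2, 5)), level = 0.68)
  expect_true(ws$envelope$flagged[ws$envelope$parameter == "log10beta.AB"])
  # consistent data under the same scan: no flag
  e3b <- simulate_experiment(m, "sw", d, sigma = 0.01, seed = 54, name = "sv3")
  fitc <- fit_gmma(m, list(e1, e2, e3b), p)
  wsc <- weight_scan(fitc, list(c(1, 1, 1), c(0.2, 0.2, 5)), level = 0.68)
  expect_false(wsc$envelope$flagged[wsc$envelope$parameter == "log10beta.AB"])
})

test_that("consistency test rejects a single subgroup and flags a shifted one", {
  m <- model_1to1(log10beta = 6)
  d <- data.frame(tot.A = 1e-6, tot.B = 10^seq(-7, -4.5, length.out = 8))
  mk <- function(model, seed, name, sg)
    simulate_experiment(model, "sw", d, sigma = 0.005, seed = seed,
                        name = name, subgroup = sg)
  e1 <- mk(m, 61, "sv1", "g1")
  p1 <- default_parameters(m, list(e1)); p1$free <- p1$name == "log10beta.AB"
  expect_error(consistency_test(m, list(e1), p1), ">= 2 subgroups")
  # one subgroup generated from a 10x shifted Kd at low noise is flagged
  m_shift <- model_1to1(log10beta = 7)
  e2 <- mk(m, 62, "sv2", "g2")
  e3 <- mk(m_shift, 63, "sv3", "g3")
  p <- default_parameters(m, list(e1, e2, e3))
  p$free <- p$name == "log10beta.AB"
  ct <- consistency_test(m, list(e1, e2, e3), p, confidence = 0.95)
  expect_true(ct$flagged[ct$subgroup == "g3"])
})

test_that("information report ranks techniques by their parameter sensitivity", {
  suite <- make_fixture_suite(5)
  fit <- fit_gmma(suite$model, suite$experiments, suite$params)
  # enthalpy is probed calorimetrically: only ITC experiments respond,
  # every other technique's forward model is exactly insensitive
  ir <- information_report(fit, "dH.AB")
  other_dchi <- ir$delta_chisq[ir$technique != "itc"]
  expect_true(all(abs(other_dchi) < 1e-9))
  expect_equal(ir$technique[1], "itc")
  expect_gt(max(abs(ir$delta_chisq)), 0.1)
  expect_gt(sum(ir$delta_chisq), 0)
  # sedimentation coefficients are probed only by s_w isotherms
  ir_s <- information_report(fit, "s.AB")
  expect_true(all(abs(ir_s$delta_chisq[ir_s$technique != "sw"]) < 1e-9))
  expect_equal(ir_s$technique[1], "sw")
  # the binding constant is informed by more than one technique
  ir_k <- information_report(fit, "log10beta.AB")
  informative <- unique(ir_k$technique[abs(ir_k$delta_chisq) > 0.1])
  expect_gt(length(informative), 2)
  expect_gt(sum(ir_k$delta_chisq), 0)
})
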