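test_that("effective totals combine gamma and incompetent fraction", {
  expect_equal(effective_totals(c(A = 1e-5), list()), c(A = 1e-5))
  expect_equal(
    effective_totals(c(A = 1e-5),
                     list(gamma.A = 0.9, incompetent.A = 0.1)),
    c(A = 8.1e-6))
  expect_equal(effective_totals(c(A = 1e-5), list(incompetent.A = 1)),
               c(A = 0))
  expect_error(effective_totals(c(A = 1e-5), list(incompetent.A = 1.2)),
               "\\[0, 1\\]")
  expect_error(
    effective_totals(c(A = 1e-5),
                     list(gamma.A = 3, gamma_bounds.A = c(0.5, 2))),
    "outside declared bounds")
})

test_that("ITC heats vanish for an athermal model", {
  m <- model_1to1(dH = 0)
  pr <- itc_protocol(cell_volume = 1.4e-3, cell = c(A = 1e-5, B = 0),
                     syringe = c(A = 0, B = 2e-4),
                     injection_volumes = rep(8e-6, 12))
  expect_equal(itc_heats(m, pr), rep(0, 12))
})

test_that("high-c titration heats integrate to V0*dH*A_tot within 2%", {
  # Kd = 1 nM, cell A = 10 uM in 200 uL, dH = -10 kcal/mol, titrated to
  # 2:1 B:A; complete saturation of 2e-9 mol gives ~ -2e-8 kcal total
  m <- model_1to1(log10beta = 9, dH = -10)
  vols <- rep(5e-7, 20)
  pr <- itc_protocol(cell_volume = 2e-4, cell = c(A = 1e-5, B = 0),
                     syringe = c(A = 0, B = 8e-4),
                     injection_volumes = vols)
  q <- itc_heats(m, pr)
  total_heat <- sum(q * vols * 8e-4)       # un-normalize
  expect_equal(total_heat, 2e-4 * (-10) * 1e-5, tolerance = 0.02)
  # early injections at high c deliver full molar heat per mole injected
  expect_equal(q[1], -10, tolerance = 0.02)
})

test_that("displacement titration heats match brute-force enthalpy bookkeeping", {
  # three-component cell: A pre-saturated with B, titrated with a
  # stronger binder C that displaces B
  m <- binding_model(
    c("A", "B", "C"),
    list(AB = list(stoich = c(A = 1, B = 1), log10beta = 6, dH = -5),
         AC = list(stoich = c(A = 1, C = 1), log10beta = 8.5, dH = -12)))
  vols <- rep(6e-6, 15)
  pr <- itc_protocol(cell_volume = 1.4e-3,
                     cell = c(A = 1e-5, B = 3e-5, C = 0),
                     syringe = c(A = 0, B = 0, C = 3e-4),
                     injection_volumes = vols, injectant = "C")
  q <- itc_heats(m, pr)
  # independent recursion: track compositions, solve each, finite-difference
  # the enthalpy content with the displacement mean-value term
  V0 <- 1.4e-3
  tot <- c(A = 1e-5, B = 3e-5, C = 0)
  H <- function(tot) {
    st <- solve_concentrations(m, tot)
    V0 * (-5 * st$species[["AB"]] + -12 * st$species[["AC"]])
  }
  Hp <- H(tot)
  q_oracle <- numeric(length(vols))
  for (i in seq_along(vols)) {
    f <- vols[i] / V0
    tot <- tot * (1 - f) + c(A = 0, B = 0, C = 3e-4) * f
    Hi <- H(tot)
    q_oracle[i] <- (Hi - Hp + f * (Hi + Hp) / 2) / (vols[i] * 3e-4)
    Hp <- Hi
  }
  expect_equal(q, q_oracle, tolerance = 1e-6)
  # displacement signature: exothermic first (C binds, B leaves: net
  # -12 + 5), decaying as B is displaced
  expect_lt(q[1], 0)
  expect_gt(q[15], q[1])
})

test_that("ITC raw heats telescope to the enthalpy-content difference", {
  m <- model_2to1()
  vols <- rep(8e-6, 10)
  pr <- itc_protocol(cell_volume = 1.4e-3, cell = c(A = 2e-5, B = 0),
                     syringe = c(A = 0, B = 5e-4),
                     injection_volumes = vols)
  q <- itc_heats(m, pr)
  V0 <- 1.4e-3
  H <- function(tot) {
    st <- solve_concentrations(m, tot)
    V0 * sum(m$dH * st$species)
  }
  tots <- matrix(0, 11, 2, dimnames = list(NULL, c("A", "B")))
  tots[1, ] <- c(2e-5, 0)
  for (i in 1:10) {
    f <- vols[i] / V0
    tots[i + 1, ] <- tots[i, ] * (1 - f) + c(0, 5e-4) * f
  }
  Hs <- apply(tots, 1, function(t) H(c(A = unname(t[1]), B = unname(t[2]))))
  disp <- sum((vols / V0) * (Hs[-1] + Hs[-11]) / 2)
  expect_equal(sum(q * vols * 5e-4), Hs[11] - Hs[1] + disp, tolerance = 1e-10)
})

test_that("SPR steady-state isotherm follows the calibrated Langmuir", {
  m <- model_1to1(log10beta = 6)
  locals <- list(analyte = "B", rmax = 100, kd_surf = 1e-6, baseline = 5)
  # B alone: free B = total B; half-saturation at kd_surf
  d <- data.frame(tot.A = 0, tot.B = 1e-6)
  expect_equal(spr_steady_isotherm(m, d, locals), 55)
  d0 <- data.frame(tot.A = 0, tot.B = 0)
  expect_equal(spr_steady_isotherm(m, d0, locals), 5)
  # solution partner depletes free B; response reads the residual free B
  dm <- data.frame(tot.A = 2e-5, tot.B = 1e-6)
  st <- solve_concentrations(m, c(A = 2e-5, B = 1e-6))
  expect_equal(spr_steady_isotherm(m, dm, locals),
               100 * st$free[["B"]] / (1e-6 + st$free[["B"]]) + 5)
  expect_lt(st$free[["B"]] / 1e-6, 0.1)   # >90% depleted here
  expect_error(spr_steady_isotherm(m, d, list(analyte = "Z", rmax = 1,
                                              kd_surf = 1)), "component")
})

test_that("SPR competition isotherm uses the direct-series calibration", {
  m <- model_1to1(log10beta = 6)
  truth <- list(analyte = "B", rmax = 120, kd_surf = 8e-7, baseline = 0)
  direct <- data.frame(tot.A = 0, tot.B = 10^seq(-8, -5, length.out = 12))
  resp <- spr_steady_isotherm(m, direct, truth)
  cal <- spr_calibrate(m, direct, resp, analyte = "B")
  expect_equal(cal$rmax, 120, tolerance = 1e-4)
  expect_equal(cal$kd_surf, 8e-7, tolerance = 1e-4)
  # zero competitor: equals the direct-series prediction
  mix0 <- data.frame(tot.A = 0, tot.B = 1e-6)
  expect_equal(spr_competition_isotherm(m, mix0, list(calibration = cal)),
               spr_steady_isotherm(m, mix0, truth), tolerance = 1e-4)
  # saturating competitor: response collapses toward baseline (0)
  sat <- data.frame(tot.A = 1e-2, tot.B = 1e-6)
  expect_lt(
    suppressWarnings(spr_competition_isotherm(m, sat, list(calibration = cal))),
    0.05 * 120)
  expect_warning(spr_competition_isotherm(m, sat, list(calibration = cal)),
                 "calibrated range")
  # competition point at Kd = A_tot = B_tot agrees with a grid-search oracle
  mix <- data.frame(tot.A = 1e-6, tot.B = 1e-6)
  or <- grid_oracle_1to1(1e-6, 1e-6, 6)
  expect_equal(spr_competition_isotherm(m, mix, list(calibration = cal)),
               120 * or[["B"]] / (8e-7 + or[["B"]]), tolerance = 1e-3)
  expect_error(spr_competition_isotherm(m, mix, list(analyte = "B")),
               "calibration")
  # multivalent surface models are rejected
  expect_error(
    spr_steady_isotherm(m, mix, c(truth, list(surface_valency = 2))),
    "multivalent|1:1 Langmuir")
})

test_that("s_w isotherm is the signal-weighted mean over species", {
  m <- model_1to1(log10beta = 6, s_AB = 6, s_A = 3, s_B = 4)
  # worked composition: A = B = Kd = 1 uM; free 0.618 uM each, AB 0.382 uM
  d <- data.frame(tot.A = 1e-6, tot.B = 1e-6)
  sw <- sw_isotherm(m, d, list(eps.A = 1, eps.B = 1))
  expect_equal(sw,
               (0.618 * 3 + 0.618 * 4 + 0.382 * 2 * 6) /
                 (0.618 + 0.618 + 0.382 * 2),
               tolerance = 1e-3)
  # single free species: s_w = its s at any concentration
  expect_equal(sw_isotherm(m, data.frame(tot.A = 1e-5, tot.B = 0), list()), 3)
  # saturating B with detection only on A: s_w -> s_AB
  dsat <- data.frame(tot.A = 1e-7, tot.B = 1e-2)
  expect_equal(sw_isotherm(m, dsat, list(eps.A = 1, eps.B = 0)), 6,
               tolerance = 1e-3)
  expect_error(sw_isotherm(m, d, list(eps.A = 0, eps.B = 0)), "signal")
})

test_that("s_w stays within the s range of signal-carrying species", {
  m <- model_2to1()
  d <- expand.grid(tot.A = 10^seq(-8, -4, length.out = 7),
                   tot.B = 10^seq(-8, -4, length.out = 7))
  sw <- sw_isotherm(m, d, list(eps.A = 1, eps.B = 0.8))
  expect_true(all(sw >= 2.3 - 1e-9 & sw <= 5.6 + 1e-9))
})

test_that("anisotropy is the population-weighted mean over probe species", {
  m <- model_1to1(log10beta = 6, r_AB = 0.25, r_B = 0.05)
  loc <- list(probe = "B")
  expect_equal(anisotropy_isotherm(m, data.frame(tot.A = 0, tot.B = 1e-6), loc),
               0.05)
  expect_equal(anisotropy_isotherm(m, data.frame(tot.A = 1e-2, tot.B = 1e-8), loc),
               0.25, tolerance = 1e-4)
  # 50% bound: r = (r_free + r_bound)/2 = 0.15; construct 50% binding by
  # strong binding with A_tot = B_tot/2
  m2 <- model_1to1(log10beta = 12, r_AB = 0.25, r_B = 0.05)
  r <- anisotropy_isotherm(m2, data.frame(tot.A = 5e-7, tot.B = 1e-6), loc)
  expect_equal(r, 0.15, tolerance = 1e-4)
  expect_error(anisotropy_isotherm(m, data.frame(tot.A = 0, tot.B = 1e-6),
                                   list(probe = "X")), "probe")
})

test_that("generic linear signal sums species contributions on a baseline", {
  m <- model_1to1(log10beta = 6)
  d <- data.frame(tot.A = 1e-6, tot.B = 1e-6)
  expect_equal(signal_isotherm(m, d, list(baseline = 2)), 2)
  # 1:1 quenching: free probe coefficient 1, bound 0.4
  sig <- signal_isotherm(m, d, list(baseline = 0.1, coeff.A = 1, coeff.AB = 0.4))
  st <- solve_concentrations(m, c(A = 1e-6, B = 1e-6))
  expect_equal(sig, 0.1 + st$free[["A"]] + 0.4 * st$species[["AB"]])
})

test_that("forward models are invariant under species order relabeling", {
  m1 <- binding_model(
    c("A", "B"),
    list(AB = list(stoich = c(A = 1, B = 1), log10beta = 6.5, dH = -8,
                   s = 4.1, r = 0.18),
         ABB = list(stoich = c(A = 1, B = 2), log10beta = 12, dH = -20,
                    s = 5.6, r = 0.22)),
    component_properties = list(A = list(s = 2.6), B = list(s = 2.3, r = 0.06)))
  m2 <- binding_model(
    c("A", "B"),
    list(ABB = list(stoich = c(A = 1, B = 2), log10beta = 12, dH = -20,
                    s = 5.6, r = 0.22),
         AB = list(stoich = c(A = 1, B = 1), log10beta = 6.5, dH = -8,
                   s = 4.1, r = 0.18)),
    component_properties = list(A = list(s = 2.6), B = list(s = 2.3, r = 0.06)))
  d <- data.frame(tot.A = 10^seq(-7, -5, length.out = 5),
                  tot.B = 10^seq(-6, -4, length.out = 5))
  expect_equal(sw_isotherm(m1, d, list(eps.A = 1, eps.B = 0.8)),
               sw_isotherm(m2, d, list(eps.A = 1, eps.B = 0.8)))
  expect_equal(anisotropy_isotherm(m1, d, list(probe = "B")),
               anisotropy_isotherm(m2, d, list(probe = "B")))
  pr <- itc_protocol(cell_volume = 1.4e-3, cell = c(A = 2e-5, B = 0),
                     syringe = c(A = 0, B = 5e-4),
                     injection_volumes = rep(8e-6, 8))
  expect_equal(itc_heats(m1, pr), itc_heats(m2, pr))
})

test_that("isotherms are continuous in log-totals under grid refinement", {
  m <- model_2to1()
  coarse <- data.frame(tot.A = 1e-6, tot.B = 10^seq(-7, -4, length.out = 31))
  fine <- data.frame(tot.A = 1e-6, tot.B = 10^seq(-7, -4, length.out = 61))
  swc <- sw_isotherm(m, coarse, list())
  swf <- sw_isotherm(m, fine, list())
  # coincident nodes agree exactly; neighbors differ smoothly
  expect_equal(swf[seq(1, 61, 2)], swc, tolerance = 1e-6)
  expect_true(max(abs(diff(swf))) < 2 * max(abs(diff(swc))))
})
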