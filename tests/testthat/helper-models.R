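# Shared model builders and independent oracles used across test files.

model_1to1 <- function(log10beta = 6, dH = -10, s_AB = 6, s_A = 3, s_B = 4,
                       r_AB = 0.25, r_B = 0.05) {
  binding_model(
    c("A", "B"),
    list(AB = list(stoich = c(A = 1, B = 1), log10beta = log10beta,
                   dH = dH, s = s_AB, r = r_AB)),
    component_properties = list(A = list(s = s_A, r = 0),
                                B = list(s = s_B, r = r_B)))
}

model_2to1 <- function(log10b1 = 6.5, log10b2 = 12, dH1 = -8, dH2 = -20) {
  binding_model(
    c("A", "B"),
    list(AB = list(stoich = c(A = 1, B = 1), log10beta = log10b1,
                   dH = dH1, s = 4.1, r = 0.18),
         ABB = list(stoich = c(A = 1, B = 2), log10beta = log10b2,
                    dH = dH2, s = 5.6, r = 0.22)),
    component_properties = list(A = list(s = 2.6, r = 0),
                                B = list(s = 2.3, r = 0.06)))
}

# Closed-form 1:1 complex concentration (quadratic root).
ab_closed_form <- function(Atot, Btot, Kd) {
  s <- Atot + Btot + Kd
  (s - sqrt(s^2 - 4 * Atot * Btot)) / 2
}

# Dense grid-search oracle: minimize the mass-balance error over free
# concentrations. For 1:1 models search free A in [0, Atot]; for 1:2
# (A + 2B) models search the 2-D grid. Accuracy is limited by the grid
# resolution, which the tests account for.
grid_oracle_1to1 <- function(Atot, Btot, log10beta, n = 4001) {
  beta <- 10^log10beta
  fa <- seq(0, Atot, length.out = n)
  # with free A fixed, free B follows from B mass balance: Btot = fb + beta fa fb
  fb <- Btot / (1 + beta * fa)
  err <- abs(fa + beta * fa * fb - Atot)
  i <- which.min(err)
  c(A = fa[i], B = fb[i], AB = beta * fa[i] * fb[i])
}

# 2-D refining grid search on log10 free concentrations: at each stage an
# n x n grid is scanned for the minimal mass-balance error and the window
# zooms onto the best node (kept clamped below the totals). Resolution after
# `stages` stages is (10/(n-1)) * (16/(n-1))^(stages-1) decades -- about
# 5e-5 decades for the defaults.
grid_oracle_2to1 <- function(Atot, Btot, log10b1, log10b2, n = 81,
                             stages = 6) {
  b1 <- 10^log10b1; b2 <- 10^log10b2
  la <- c(log10(Atot) - 10, log10(Atot))
  lb <- c(log10(Btot) - 10, log10(Btot))
  ca <- cb <- NA_real_
  for (s in seq_len(stages)) {
    fa <- 10^seq(la[1], la[2], length.out = n)
    fb <- 10^seq(lb[1], lb[2], length.out = n)
    best <- c(Inf, 1, 1)
    for (i in seq_len(n)) {
      ab <- b1 * fa[i] * fb
      abb <- b2 * fa[i] * fb^2
      err <- pmax(abs(fa[i] + ab + abb - Atot) / Atot,
                  abs(fb + ab + 2 * abb - Btot) / Btot)
      j <- which.min(err)
      if (err[j] < best[1]) best <- c(err[j], i, j)
    }
    sa <- diff(la) / (n - 1); sb <- diff(lb) / (n - 1)
    ca <- la[1] + (best[2] - 1) * sa
    cb <- lb[1] + (best[3] - 1) * sb
    la <- c(ca - 8 * sa, min(ca + 8 * sa, log10(Atot)))
    lb <- c(cb - 8 * sb, min(cb + 8 * sb, log10(Btot)))
  }
  fa <- 10^ca; fb <- 10^cb
  c(A = fa, B = fb, AB = b1 * fa * fb, ABB = b2 * fa * fb^2)
}

# A small linear-response problem: signal = baseline + coeff * [A] for a
# single inert component, so the global fit is an ordinary linear model
# with closed-form least-squares solution.
linear_signal_setup <- function(x = seq(1, 10) * 1e-6, baseline = 0.5,
                                coeff = 2e5, sigma = 0.05, seed = 1) {
  m <- binding_model("A", list())
  locals <- list(baseline = baseline)
  locals[["coeff.A"]] <- coeff
  e <- simulate_experiment(m, "signal", data.frame(tot.A = x),
                           locals = locals, sigma = sigma, seed = seed,
                           name = "lin1")
  p <- default_parameters(m, list(e))
  p$free <- p$name %in% c("lin1:baseline", "lin1:coeff.A")
  list(model = m, exp = e, params = p, x = x, sigma = sigma,
       truth = c(baseline = baseline, coeff = coeff))
}

# Closed-form least-squares covariance for the linear setup.
linear_analytic_cov <- function(setup) {
  X <- cbind(1, setup$x)
  solve(crossprod(X)) * setup$sigma^2
}
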