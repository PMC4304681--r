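## --- local (per-experiment nuisance) parameter helpers -------------------
##
## Locals are stored as a flat named list, e.g. list(`gamma.A` = 0.95,
## `incompetent.A` = 0.05, baseline = 0, `eps.A` = 1). Flat dotted names make
## the mapping from the fit parameter table onto locals trivial.

local_value <- function(locals, key, default) {
  v <- locals[[key]]
  if (is.null(v)) default else v
}

local_comp_vec <- function(locals, prefix, components, default) {
  out <- stats::setNames(rep(default, length(components)), components)
  for (cn in components) {
    v <- locals[[paste0(prefix, ".", cn)]]
    if (!is.null(v)) out[cn] <- v
  }
  out
}

#' Effective total concentrations under concentration-error and
#' incompetent-fraction nuisance parameters
#'
#' In a global analysis the reaction stoichiometry is fixed in the model;
#' instead of a fractional "n" value, each experiment carries per-component
#' nuisance parameters: a concentration-error factor `gamma.<comp>`
#' (dimensionless, optionally bounded via `gamma_bounds.<comp>` =
#' c(lower, upper)) and an incompetent fraction `incompetent.<comp>` in
#' [0, 1]. The effective concentration entering the equilibrium is
#' `nominal * gamma * (1 - incompetent)`.
#'
#' @param nominal named numeric vector of nominal totals (M), >= 0.
#' @param locals flat named list of local parameters.
#' @return named numeric vector of effective totals (M).
#' @export
effective_totals <- function(nominal, locals = list()) {
  comps <- names(nominal)
  gam <- local_comp_vec(locals, "gamma", comps, 1)
  inc <- local_comp_vec(locals, "incompetent", comps, 0)
  if (any(inc < 0 | inc > 1)) stop("incompetent fraction must be in [0, 1]")
  for (cn in comps) {
    b <- locals[[paste0("gamma_bounds.", cn)]]
    if (!is.null(b) && (gam[cn] < b[1] || gam[cn] > b[2])) {
      stop("gamma.", cn, " = ", gam[cn], " outside declared bounds [",
           b[1], ", ", b[2], "]")
    }
  }
  if (any(!is.finite(nominal)) || any(nominal < 0)) stop("nominal totals must be >= 0")
  nominal * gam * (1 - inc)
}

## --- ITC ------------------------------------------------------------------

#' ITC titration protocol
#'
#' Describes a perfusion-cell titration: fixed-volume cell with initial
#' composition, syringe composition, and a schedule of injection volumes.
#'
#' @param cell_volume cell volume V0 in liters.
#' @param cell named vector, initial cell concentrations (M) per component.
#' @param syringe named vector, syringe concentrations (M) per component.
#' @param injection_volumes numeric vector of injection volumes (L), > 0.
#' @param temperature K.
#' @param injectant component whose moles normalize the heats; defaults to
#'   the syringe component at highest concentration.
#' @return object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume, cell, syringe, injection_volumes,
                         temperature = 298.15, injectant = NULL) {
  stopifnot(cell_volume > 0, all(injection_volumes > 0),
            all(cell >= 0), all(syringe >= 0))
  if (is.null(injectant)) injectant <- names(syringe)[which.max(syringe)]
  if (!injectant %in% names(syringe) || syringe[[injectant]] <= 0) {
    stop("injectant must name a syringe component with positive concentration")
  }
  structure(list(cell_volume = cell_volume, cell = cell, syringe = syringe,
                 injection_volumes = injection_volumes,
                 temperature = temperature, injectant = injectant),
            class = "itc_protocol")
}

#' Normalized ITC injection heats
#'
#' Forward model for a titration series: after each injection `v_i` the
#' pre-injection cell contents are diluted by `(1 - v_i/V0)` and injectant
#' enters at `v_i/V0` of the syringe concentration (perfusion-displacement
#' bookkeeping). With the cell enthalpy content
#' `H(i) = V0 * sum_S dH_S [S](i)` the raw heat of injection i is
#' `q_i = H(i) - H(i-1) + (v_i/V0) * (H(i) + H(i-1)) / 2` — the mean-value
#' correction accounts for reacted material carried out of the sensed
#' volume by displacement — plus a heat of dilution proportional to moles
#' injected. Heats are normalized by the nominal moles of injectant per
#' injection (kcal per mol of injectant). Concentration-error and
#' incompetent-fraction locals apply to both cell and syringe; a
#' `dH_dilution` local (kcal/mol injectant) and `q_offset` local
#' (kcal/mol, baseline on the normalized heats) default to 0. Cells with
#' two or three components (displacement/competition titrations) are
#' supported through the general equilibrium solve.
#'
#' @param model a [binding_model()].
#' @param protocol an [itc_protocol()].
#' @param locals flat named list of local parameters.
#' @return numeric vector of normalized heats, one per injection.
#' @export
itc_heats <- function(model, protocol, locals = list()) {
  stopifnot(inherits(protocol, "itc_protocol"))
  V0 <- protocol$cell_volume
  vols <- protocol$injection_volumes
  comps <- model$components
  cell0 <- stats::setNames(numeric(length(comps)), comps)
  syr <- stats::setNames(numeric(length(comps)), comps)
  cell0[names(protocol$cell)] <- protocol$cell
  syr[names(protocol$syringe)] <- protocol$syringe
  cell_eff <- effective_totals(cell0, locals)
  syr_eff <- effective_totals(syr, locals)

  dH_dil <- local_value(locals, "dH_dilution", 0)
  q_off <- local_value(locals, "q_offset", 0)
  n_syr_nominal <- syr[[protocol$injectant]]

  ## cell compositions: initial, then after each perfusion-displacement step
  n <- length(vols)
  comp_tab <- matrix(0, n + 1, length(comps),
                     dimnames = list(NULL, paste0("tot.", comps)))
  tot <- cell_eff
  comp_tab[1, ] <- tot
  for (i in seq_len(n)) {
    f <- vols[i] / V0
    tot <- tot * (1 - f) + syr_eff * f
    comp_tab[i + 1, ] <- tot
  }
  conc <- solve_series(model, as.data.frame(comp_tab))
  ## enthalpy content of the cell; free components carry dH = 0
  csp <- conc[, model$species_names, drop = FALSE]
  H <- V0 * drop(csp %*% model$dH)
  f <- vols / V0
  H_i <- H[-1]; H_prev <- H[-(n + 1)]
  q_raw <- (H_i - H_prev) + f * (H_i + H_prev) / 2
  q_raw / (vols * n_syr_nominal) + dH_dil + q_off
}

## --- SPR ------------------------------------------------------------------

#' Steady-state SPR surface-binding isotherm
#'
#' Langmuir response of a calibrated surface to the free concentration of a
#' designated analyte in the injected mixture,
#' `R = Rmax * [free] / (Kd_surf + [free]) + baseline`, where `[free]` is
#' obtained from the solution equilibrium of the full mixture. Locals:
#' `analyte` (component name, required), `rmax` (RU), `kd_surf` (M),
#' `baseline` (RU, default 0), plus concentration-error locals.
#'
#' @param model a [binding_model()].
#' @param design data.frame with `tot.<component>` columns (M).
#' @param locals flat named list of local parameters.
#' @return numeric vector of response units per design point.
#' @export
spr_steady_isotherm <- function(model, design, locals = list()) {
  analyte <- locals$analyte
  if (is.null(analyte) || !analyte %in% model$components) {
    stop("locals$analyte must name a model component")
  }
  rmax <- local_value(locals, "rmax", NULL)
  kds <- local_value(locals, "kd_surf", NULL)
  if (is.null(rmax) || is.null(kds)) stop("locals rmax and kd_surf are required")
  if (!is.null(locals$surface_valency) && locals$surface_valency != 1) {
    stop("multivalent surface binding is not supported; ",
         "the surface model is restricted to a 1:1 Langmuir calibration")
  }
  base <- local_value(locals, "baseline", 0)
  conc <- solve_series(model, apply_conc_errors(model, design, locals))
  fr <- unname(conc[, analyte])
  rmax * fr / (kds + fr) + base
}

#' Calibrate an SPR surface from a direct binding series
#'
#' Fits the 1:1 Langmuir `R = Rmax [free]/(Kd + [free]) + baseline` to a
#' direct series (analyte alone, or any mixture series with the model's
#' solution equilibrium supplying the free concentration). The returned
#' calibration carries `rmax`, `kd_surf`, `baseline` and the calibrated
#' free-concentration range.
#'
#' @param model a [binding_model()].
#' @param design data.frame of `tot.<component>` columns for the direct series.
#' @param response observed response units.
#' @param analyte the surface-binding component.
#' @param fit_baseline logical; fit a baseline offset (default FALSE).
#' @return list of class `spr_calibration`.
#' @export
spr_calibrate <- function(model, design, response, analyte,
                          fit_baseline = FALSE) {
  conc <- solve_series(model, design)
  fr <- unname(conc[, analyte])
  start <- c(log_rmax = log(max(response) * 1.2 + 1e-12),
             log_kd = log(stats::median(fr) + 1e-15))
  if (fit_baseline) start <- c(start, baseline = 0)
  fn <- function(p) {
    base <- if (fit_baseline) p[["baseline"]] else 0
    exp(p[["log_rmax"]]) * fr / (exp(p[["log_kd"]]) + fr) + base - response
  }
  res <- minpack.lm::nls.lm(par = start, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- res$par
  structure(list(
    analyte = analyte,
    rmax = exp(p[["log_rmax"]]),
    kd_surf = exp(p[["log_kd"]]),
    baseline = if (fit_baseline) p[["baseline"]] else 0,
    free_range = range(fr)
  ), class = "spr_calibration")
}

#' SPR solution-competition isotherm through a calibrated surface
#'
#' The surface is used solely as a probe of the free concentration of the
#' surface-binding partner in injected reaction mixtures: each mixture is
#' solved for solution equilibrium, and the free analyte concentration is
#' mapped to a response through a previously fitted direct-series
#' calibration. Mixtures whose free analyte falls outside the calibrated
#' range trigger a warning (extrapolation). Locals may supply the
#' calibration either as an `spr_calibration` object under `calibration`,
#' or as fixed `rmax`/`kd_surf`/`baseline` values.
#'
#' @inheritParams spr_steady_isotherm
#' @return numeric vector of response units per mixture.
#' @export
spr_competition_isotherm <- function(model, design, locals = list()) {
  cal <- locals$calibration
  if (!is.null(cal)) {
    if (!inherits(cal, "spr_calibration")) stop("locals$calibration must come from spr_calibrate()")
    locals$analyte <- cal$analyte
    locals$rmax <- cal$rmax
    locals$kd_surf <- cal$kd_surf
    locals$baseline <- local_value(locals, "baseline", cal$baseline)
  } else if (is.null(locals$rmax) || is.null(locals$kd_surf)) {
    stop("competition isotherm requires a surface calibration ",
         "(locals$calibration from spr_calibrate(), or fixed rmax/kd_surf)")
  }
  resp <- spr_steady_isotherm(model, design, locals)
  if (!is.null(cal)) {
    conc <- solve_series(model, apply_conc_errors(model, design, locals))
    fr <- unname(conc[, cal$analyte])
    if (any(fr < cal$free_range[1] - 1e-15) || any(fr > cal$free_range[2] + 1e-15)) {
      warning("free analyte concentration outside calibrated range; response extrapolated")
    }
  }
  resp
}

## --- sedimentation velocity s_w ------------------------------------------

#' Signal-weighted average sedimentation coefficient isotherm
#'
#' The s_w binding isotherm: at each composition the equilibrium species
#' mixture is formed and `s_w = sum_S eps_S c_S s_S / sum_S eps_S c_S`,
#' where the molar signal coefficient of a species is additive over its
#' composition, `eps_S = sum_j eps_j * nu_jS` with per-component signal
#' increments `eps.<comp>` from the locals (default 1; an optical
#' pathlength local `pathlength` scales the total signal but cancels in
#' s_w).
#'
#' @inheritParams spr_steady_isotherm
#' @return numeric vector of s_w values (Svedberg) per composition.
#' @export
sw_isotherm <- function(model, design, locals = list()) {
  sp <- all_species(model)
  eps_c <- local_comp_vec(locals, "eps", model$components, 1)
  eps_s <- drop(sp$stoich %*% eps_c)
  conc <- solve_series(model, apply_conc_errors(model, design, locals))
  num <- drop(conc %*% (eps_s * sp$s))
  den <- drop(conc %*% eps_s)
  if (any(den <= 0)) stop("total signal is zero at some compositions; s_w undefined")
  num / den
}

## Total optical signal of an s_w experiment (for design maps / cropping).
sw_total_signal <- function(model, design, locals = list()) {
  sp <- all_species(model)
  eps_c <- local_comp_vec(locals, "eps", model$components, 1)
  eps_s <- drop(sp$stoich %*% eps_c)
  d <- local_value(locals, "pathlength", 1)
  conc <- solve_series(model, apply_conc_errors(model, design, locals))
  d * drop(conc %*% eps_s)
}

## --- fluorescence anisotropy ---------------------------------------------

#' Fluorescence anisotropy isotherm
#'
#' Population-weighted anisotropy of a designated fluorescent probe
#' component: `r = sum_S nu_probe,S c_S r_S / sum_S nu_probe,S c_S` over
#' all species containing the probe (including the free probe). Equal
#' quantum yields across bound states are assumed by default, so intensity
#' weighting degenerates to population weighting; per-species yield ratios
#' can be supplied as locals `yield.<species>` (default 1).
#'
#' @inheritParams spr_steady_isotherm
#' @return numeric vector of anisotropies per composition.
#' @export
anisotropy_isotherm <- function(model, design, locals = list()) {
  probe <- locals$probe
  if (is.null(probe) || !probe %in% model$components) {
    stop("locals$probe must name a model component (the fluorescent probe)")
  }
  sp <- all_species(model)
  nu <- sp$stoich[, probe]
  yield <- vapply(sp$names, function(nm)
    local_value(locals, paste0("yield.", nm), 1), numeric(1))
  w <- nu * yield
  conc <- solve_series(model, apply_conc_errors(model, design, locals))
  num <- drop(conc %*% (w * sp$r))
  den <- drop(conc %*% w)
  if (any(den <= 0)) stop("probe absent at some compositions; anisotropy undefined")
  num / den
}

## --- generic linear spectroscopy -----------------------------------------

#' Generic linear-signal isotherm
#'
#' Any observable that is linear in species concentrations (steady-state
#' fluorescence quenching, absorbance, NMR chemical shift in fast
#' exchange, ...): `signal = baseline + sum_S coeff_S c_S` with per-species
#' molar signal coefficients from locals `coeff.<species>` (free components
#' are species too; default coefficient 0) and a `baseline` local
#' (default 0).
#'
#' @inheritParams spr_steady_isotherm
#' @return numeric vector of signals per composition.
#' @export
signal_isotherm <- function(model, design, locals = list()) {
  sp <- all_species(model)
  coeff <- vapply(sp$names, function(nm)
    local_value(locals, paste0("coeff.", nm), 0), numeric(1))
  base <- local_value(locals, "baseline", 0)
  conc <- solve_series(model, apply_conc_errors(model, design, locals))
  base + drop(conc %*% coeff)
}

## Apply concentration-error/incompetent-fraction locals to the tot.*
## columns of a design table.
apply_conc_errors <- function(model, design, locals) {
  design_columns(model, design)   # validates columns
  if (!any(grepl("^(gamma|incompetent)\\.", names(locals)))) return(design)
  gam <- local_comp_vec(locals, "gamma", model$components, 1)
  inc <- local_comp_vec(locals, "incompetent", model$components, 0)
  if (any(inc < 0 | inc > 1)) stop("incompetent fraction must be in [0, 1]")
  for (cn in model$components) {
    b <- locals[[paste0("gamma_bounds.", cn)]]
    if (!is.null(b) && (gam[cn] < b[1] || gam[cn] > b[2])) {
      stop("gamma.", cn, " outside declared bounds")
    }
    col <- paste0("tot.", cn)
    design[[col]] <- design[[col]] * gam[cn] * (1 - inc[cn])
  }
  design
}
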