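#' Construct an experiment (one technique's data set)
#'
#' An `experiment` bundles one data set for the global analysis: a
#' technique tag, the design (a composition table with `tot.<component>`
#' columns in molar, or an [itc_protocol()] for ITC), observations,
#' per-point standard deviations, a statistical weight `w_e`, the
#' experiment's local (nuisance) parameters, and an optional subgroup
#' label used by the statistical consistency tools.
#'
#' Supported technique tags: `"itc"`, `"spr"`, `"spr_competition"`,
#' `"sw"` (sedimentation-velocity s_w isotherm), `"anisotropy"`,
#' `"signal"`. Tags `"se"` and `"sv"` (sedimentation-equilibrium /
#' full sedimentation-boundary data) are recognized names of the wider
#' ecosystem but are rejected here: boundary-level modeling is outside
#' this package's scope.
#'
#' @param technique technique tag (see Details).
#' @param design data.frame of `tot.<component>` columns (M); `NULL` for ITC.
#' @param y numeric observations.
#' @param sigma per-point standard deviations, > 0 (scalar recycled).
#' @param locals flat named list of local parameters.
#' @param weight statistical weight w_e >= 0 in the global chi-square.
#' @param name experiment name (unique within a fit).
#' @param subgroup optional subgroup label for consistency testing.
#' @param protocol an [itc_protocol()] (ITC only).
#' @return object of class `gmma_experiment`.
#' @export
experiment <- function(technique, design = NULL, y, sigma,
                       locals = list(), weight = 1, name = technique,
                       subgroup = NULL, protocol = NULL) {
  known <- c("itc", "spr", "spr_competition", "sw", "anisotropy", "signal")
  rejected <- c("se", "sv")
  if (technique %in% rejected) {
    stop("technique '", technique, "' (boundary/equilibrium profile data) is ",
         "unsupported in this package; use isotherm-level techniques: ",
         paste(known, collapse = ", "))
  }
  if (!technique %in% known) {
    stop("unknown technique tag '", technique, "'; supported: ",
         paste(known, collapse = ", "))
  }
  y <- as.numeric(y)
  n <- length(y)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  if (weight < 0) stop("weight w_e must be >= 0")
  if (technique == "itc") {
    if (is.null(protocol) || !inherits(protocol, "itc_protocol")) {
      stop("ITC experiments need an itc_protocol")
    }
    if (length(protocol$injection_volumes) != n) {
      stop("number of observations must match number of injections")
    }
  } else {
    if (is.null(design) || !is.data.frame(design) || nrow(design) != n) {
      stop("design must be a data.frame with one row per observation")
    }
  }
  structure(list(technique = technique, design = design, y = y,
                 sigma = sigma, locals = locals, weight = weight,
                 name = name, subgroup = subgroup, protocol = protocol,
                 n = n),
            class = "gmma_experiment")
}

#' @export
print.gmma_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%s): %d points, w_e = %g%s\n",
              x$name, x$technique, x$n, x$weight,
              if (!is.null(x$subgroup)) paste0(", subgroup ", x$subgroup) else ""))
  invisible(x)
}

#' Evaluate the forward model of an experiment
#'
#' Projects an interaction model into the experiment's observable space
#' f_(e,i), dispatching on the technique tag.
#'
#' @param model a [binding_model()].
#' @param exp a [experiment()].
#' @param locals optional local-parameter override (defaults to the
#'   experiment's own locals).
#' @return numeric vector of model observations.
#' @export
predict_experiment <- function(model, exp, locals = NULL) {
  if (is.null(locals)) locals <- exp$locals
  switch(exp$technique,
    itc = itc_heats(model, exp$protocol, locals),
    spr = spr_steady_isotherm(model, exp$design, locals),
    spr_competition = spr_competition_isotherm(model, exp$design, locals),
    sw = sw_isotherm(model, exp$design, locals),
    anisotropy = anisotropy_isotherm(model, exp$design, locals),
    signal = signal_isotherm(model, exp$design, locals),
    stop("no forward model for technique '", exp$technique, "'")
  )
}

## Technique signal used by the design maps (single scalar signal per
## composition point, given as a design data.frame).
technique_signal <- function(model, technique, design, locals) {
  switch(technique,
    sw = sw_isotherm(model, design, locals),
    sw_signal = sw_total_signal(model, design, locals),
    spr = spr_steady_isotherm(model, design, locals),
    spr_competition = spr_competition_isotherm(model, design, locals),
    anisotropy = anisotropy_isotherm(model, design, locals),
    signal = signal_isotherm(model, design, locals),
    stop("design maps are not available for technique '", technique, "'")
  )
}
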