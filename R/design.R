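#' Two-dimensional concentration-space map for experiment planning
#'
#' Evaluates, over a log10-spaced grid of total concentrations of two
#' components (all other components held at a fixed background), either
#' the predicted total signal of a chosen technique (`mode = "signal"`),
#' the fractional signal contribution of each complex
#' (`"fractional_signal"`), or the fractional population of a reference
#' component across all species (`"population"`, technique-independent).
#' These maps guide where in concentration space isotherms are
#' informative before any sample is spent.
#'
#' @param model a [binding_model()].
#' @param technique technique tag for signal modes (see
#'   [experiment()]); ignored for `"population"`.
#' @param locals technique locals for the signal evaluation.
#' @param comp_x,comp_y the two varied components.
#' @param xlim,ylim log10 total-concentration bounds, e.g. `c(-8, -4)`.
#' @param n nodes per axis (scalar or length 2).
#' @param background named vector of fixed totals (M) for the remaining
#'   components (default 0).
#' @param mode `"signal"`, `"fractional_signal"` or `"population"`.
#' @param ref_component reference component for `"population"` mode
#'   (default `comp_x`).
#' @return object of class `design_map`: `x`, `y` (log10 M axes),
#'   `value` (matrix, signal mode) or `fractions` (named list of
#'   matrices), `mask` (feasibility, all TRUE initially), plus the
#'   defining metadata.
#' @export
concentration_map <- function(model, technique = "sw", locals = list(),
                              comp_x, comp_y, xlim, ylim, n = 25,
                              background = NULL,
                              mode = c("signal", "fractional_signal",
                                       "population"),
                              ref_component = comp_x) {
  mode <- match.arg(mode)
  stopifnot(comp_x %in% model$components, comp_y %in% model$components,
            comp_x != comp_y)
  n <- rep_len(n, 2)
  x <- seq(xlim[1], xlim[2], length.out = n[1])
  y <- seq(ylim[1], ylim[2], length.out = n[2])
  grid <- expand.grid(ix = seq_along(x), iy = seq_along(y))
  design <- data.frame(matrix(0, nrow(grid), length(model$components)))
  names(design) <- paste0("tot.", model$components)
  for (cn in names(background)) design[[paste0("tot.", cn)]] <- background[[cn]]
  design[[paste0("tot.", comp_x)]] <- 10^x[grid$ix]
  design[[paste0("tot.", comp_y)]] <- 10^y[grid$iy]

  mk <- function(v) matrix(v, length(x), length(y))
  out <- list(comp_x = comp_x, comp_y = comp_y, x = x, y = y,
              background = background, mode = mode, technique = technique,
              locals = locals, model = model,
              mask = mk(TRUE))
  if (mode == "signal") {
    val <- tryCatch(technique_signal(model, technique, design, locals),
                    error = function(e) stop("signal evaluation failed: ",
                                             conditionMessage(e)))
    out$value <- mk(val)
  } else {
    conc <- solve_series(model, design)
    sp <- all_species(model)
    if (mode == "population") {
      nu <- sp$stoich[, ref_component]
      tot_ref <- design[[paste0("tot.", ref_component)]]
      fr <- lapply(seq_along(sp$names), function(k) {
        v <- nu[k] * conc[, k] / tot_ref
        v[tot_ref == 0] <- 0
        mk(v)
      })
      names(fr) <- sp$names
      out$fractions <- fr[nu > 0]
      out$ref_component <- ref_component
    } else {
      eps_c <- local_comp_vec(locals, "eps", model$components, 1)
      eps_s <- drop(sp$stoich %*% eps_c)
      tot_sig <- drop(conc %*% eps_s)
      fr <- lapply(seq_along(sp$names), function(k) mk(eps_s[k] * conc[, k] / tot_sig))
      names(fr) <- sp$names
      out$fractions <- fr
      out$value <- mk(tot_sig)
    }
  }
  structure(out, class = "design_map")
}

#' Crop a design map to experimentally feasible nodes
#'
#' Restricts the feasibility mask of a map to nodes that can actually be
#' mixed from available stocks and whose signal lies in a usable window:
#' a node is feasible iff the one-step mixing volume fractions satisfy
#' `c_x/stock_x + c_y/stock_y + sum_fixed c_f/stock_f <= 1` and
#' `min_signal <= signal <= max_signal` (signal bounds apply to the
#' mapped signal and require a signal-mode map). The mask only ever
#' restricts: cropping never adds nodes, and larger stocks never remove
#' feasible nodes.
#'
#' @param map a [concentration_map()].
#' @param stocks named vector of stock concentrations (M), > 0; missing
#'   components are treated as unconstrained (infinite stock).
#' @param min_signal,max_signal signal window (defaults unbounded).
#' @return the map with an updated `mask`.
#' @export
crop_map <- function(map, stocks = NULL, min_signal = -Inf,
                     max_signal = Inf) {
  stopifnot(inherits(map, "design_map"))
  if (!is.null(stocks) && any(stocks <= 0)) stop("stocks must be > 0")
  mask <- map$mask
  stock_of <- function(cn) {
    if (is.null(stocks) || !cn %in% names(stocks)) return(Inf)
    v <- stocks[[cn]]
    if (is.na(v)) Inf else v
  }
  cx <- 10^map$x; cy <- 10^map$y
  vf_fixed <- 0
  for (cn in names(map$background)) {
    vf_fixed <- vf_fixed + map$background[[cn]] / stock_of(cn)
  }
  vf <- outer(cx / stock_of(map$comp_x), cy / stock_of(map$comp_y), `+`) + vf_fixed
  mask <- mask & (vf <= 1 + 1e-12)
  if (is.finite(min_signal) || is.finite(max_signal)) {
    if (is.null(map$value)) {
      stop("signal bounds require a map carrying a signal matrix")
    }
    mask <- mask & (map$value >= min_signal) & (map$value <= max_signal)
  }
  if (!any(mask)) {
    stop("no feasible nodes: stock/volume constraint and signal window [",
         min_signal, ", ", max_signal, "] exclude the whole map")
  }
  map$mask <- mask
  map$stocks <- stocks
  map
}

#' Parameter-sensitivity (differential) map
#'
#' Switches the concentration map into differential mode: at each node
#' the technique signal's sensitivity to one model parameter,
#' `|dS / d(log parameter)|`, is evaluated by central finite differences.
#' Parameters already on a log scale (`log10beta.*`, `log10k`,
#' `log10alpha`) are stepped additively by `rel_step`; linear-scale
#' parameters (dH, s, r) are stepped multiplicatively by a relative
#' `rel_step`. Regions of high sensitivity are where experiments best
#' constrain that parameter.
#'
#' @inheritParams concentration_map
#' @param parameter global parameter name (as in [parameter_table()]).
#' @param rel_step finite-difference step (default 0.01).
#' @return a `design_map` with mode `"differential"`.
#' @export
differential_map <- function(model, technique = "sw", locals = list(),
                             comp_x, comp_y, xlim, ylim, n = 25,
                             background = NULL, parameter,
                             rel_step = 0.01) {
  if (rel_step <= 0 || rel_step < 1e-10) stop("rel_step too small (underflow)")
  value_at <- function(delta_sign) {
    p <- global_parameter_value(model, parameter)
    is_log <- grepl("^log10", parameter)
    newv <- if (is_log) p + delta_sign * rel_step else p * (1 + delta_sign * rel_step)
    pt <- parameter_table(parameter, newv)
    m2 <- apply_parameters(model, list(), pt)$model
    concentration_map(m2, technique, locals, comp_x, comp_y, xlim, ylim,
                      n, background, mode = "signal")$value
  }
  hi <- value_at(+1)
  lo <- value_at(-1)
  h <- if (grepl("^log10", parameter)) rel_step else
    abs(log(1 + rel_step) - log(1 - rel_step)) / 2
  base <- concentration_map(model, technique, locals, comp_x, comp_y,
                            xlim, ylim, n, background, mode = "signal")
  base$value <- abs(hi - lo) / (2 * h)
  base$mode <- "differential"
  base$parameter <- parameter
  base$rel_step <- rel_step
  base
}

global_parameter_value <- function(model, name) {
  if (name == "log10k") return(model$microscopic$log10k)
  if (name == "log10alpha") return(model$microscopic$log10alpha)
  dot <- regexpr(".", name, fixed = TRUE)
  field <- substr(name, 1, dot - 1)
  target <- substr(name, dot + 1, nchar(name))
  tab <- switch(field, log10beta = model$log10beta, dH = model$dH,
                s = c(model$s, model$comp_s), r = c(model$r, model$comp_r),
                stop("unknown parameter field: ", field))
  v <- tab[[target]]
  if (is.null(v)) stop("unknown parameter target: ", name)
  v
}

#' Log-equidistant compositions along a line in concentration space
#'
#' Interpolates `n` mixture compositions log-equidistantly along the
#' segment from `start` to `end` in log10-total-concentration
#' coordinates (endpoints included) — the concentrations a titration
#' should probe along a chosen trajectory of a design map. A component
#' with equal start and end values (including 0) stays constant.
#'
#' @param start,end named vectors of total concentrations (M).
#' @param n number of points (>= 2).
#' @param map optional [concentration_map()]; when given, the varied
#'   endpoints must lie within the map axes.
#' @return data.frame of `tot.<component>` columns, one row per point.
#' @export
trajectory_points <- function(start, end, n, map = NULL) {
  stopifnot(n >= 2, identical(sort(names(start)), sort(names(end))))
  end <- end[names(start)]
  if (!is.null(map)) {
    for (cn in c(map$comp_x, map$comp_y)) {
      ax <- if (cn == map$comp_x) range(map$x) else range(map$y)
      for (v in c(start[[cn]], end[[cn]])) {
        lv <- log10(v)
        if (lv < ax[1] - 1e-9 || lv > ax[2] + 1e-9) {
          stop("trajectory endpoint for ", cn, " outside the map axes")
        }
      }
    }
  }
  t <- seq(0, 1, length.out = n)
  out <- lapply(names(start), function(cn) {
    a <- start[[cn]]; b <- end[[cn]]
    if (a == b) rep(a, n)
    else {
      if (a <= 0 || b <= 0) {
        stop("log-equidistant interpolation needs positive endpoints for ", cn)
      }
      10^(log10(a) + t * (log10(b) - log10(a)))
    }
  })
  names(out) <- paste0("tot.", names(start))
  as.data.frame(out)
}

#' Mixing recipes from stock solutions
#'
#' For each target composition, the volume of each component stock and
#' of buffer needed to prepare `total_volume` of the mixture in one
#' step: `v_comp = c * V / stock`, `v_buffer = V - sum(v_comp)`. A
#' composition whose stock volumes exceed the total volume is infeasible
#' and raises an error naming the binding constraint.
#'
#' @param compositions data.frame of `tot.<component>` columns (M).
#' @param stocks named vector of stock concentrations (M), > 0 for every
#'   component with a nonzero target.
#' @param total_volume volume per mixture (any volume unit; outputs are
#'   in the same unit).
#' @return object of class `titration_plan`: data.frame with one row per
#'   mixture, columns `v.<component>`, `v.buffer`, `v.total`, plus the
#'   target compositions.
#' @export
mixing_recipes <- function(compositions, stocks, total_volume) {
  stopifnot(total_volume > 0)
  comps <- sub("^tot\\.", "", grep("^tot\\.", names(compositions), value = TRUE))
  vols <- list()
  v_sum <- 0
  for (cn in comps) {
    target <- compositions[[paste0("tot.", cn)]]
    st <- stocks[[cn]]
    v <- numeric(length(target))
    nz <- target > 0
    if (any(nz)) {
      if (is.null(st) || is.na(st) || st <= 0) {
        stop("no stock concentration given for component ", cn)
      }
      v[nz] <- target[nz] * total_volume / st
    }
    vols[[paste0("v.", cn)]] <- v
    v_sum <- v_sum + v
  }
  v_buffer <- total_volume - v_sum
  if (any(v_buffer < -1e-12 * total_volume)) {
    i <- which.min(v_buffer)
    worst <- comps[which.max(vapply(comps, function(cn)
      vols[[paste0("v.", cn)]][i], 0))]
    stop("mixture ", i, " infeasible from the given stocks (largest volume ",
         "demand from component ", worst, "); raise its stock concentration")
  }
  v_buffer[abs(v_buffer) < 1e-12 * total_volume] <- 0
  plan <- cbind(compositions,
                as.data.frame(vols),
                v.buffer = v_buffer,
                v.total = rep(total_volume, nrow(compositions)))
  structure(plan, class = c("titration_plan", "data.frame"))
}

#' Simulate an experimental data set in silico
#'
#' Generates a synthetic [experiment()] from the forward model of a
#' technique: observations are the model prediction plus i.i.d. Gaussian
#' noise of standard deviation `sigma` (recorded per point), reproducible
#' under a fixed seed. The result is a valid experiment that can be added
#' directly to a global multi-method analysis — the basis of the
#' experimental-design workflow, where candidate designs are simulated,
#' fitted and compared before any measurement.
#'
#' @param model a [binding_model()].
#' @param technique technique tag (see [experiment()]).
#' @param design composition data.frame (`tot.<component>` columns, M);
#'   for ITC an [itc_protocol()].
#' @param locals technique locals (likely values must be provided for
#'   the technique's nuisance parameters).
#' @param sigma noise standard deviation: scalar or per point. The
#'   special form `sigma_fraction` scales to the clean signal range.
#' @param seed integer seed (required when sigma > 0).
#' @param sigma_fraction if non-NULL, sigma = sigma_fraction * range of
#'   the noise-free signal (overrides `sigma`).
#' @param name,weight,subgroup passed to [experiment()].
#' @return a `gmma_experiment`.
#' @export
simulate_experiment <- function(model, technique, design, locals = list(),
                                sigma = 0, seed = NULL,
                                sigma_fraction = NULL,
                                name = technique, weight = 1,
                                subgroup = NULL) {
  if (technique == "itc") {
    stopifnot(inherits(design, "itc_protocol"))
    f <- itc_heats(model, design, locals)
    protocol <- design
    design_df <- NULL
  } else {
    e_probe <- experiment(technique, design,
                          y = rep(0, nrow(design)), sigma = 1,
                          locals = locals, name = name)
    f <- predict_experiment(model, e_probe)
    protocol <- NULL
    design_df <- design
  }
  if (!is.null(sigma_fraction)) {
    rng <- diff(range(f))
    if (rng == 0) rng <- max(abs(f), 1)
    sigma <- sigma_fraction * rng
  }
  sigma <- rep_len(sigma, length(f))
  y <- f
  if (any(sigma > 0)) {
    if (is.null(seed)) stop("a seed is required to simulate noisy data")
    set.seed(seed)
    y <- f + stats::rnorm(length(f), 0, sigma)
  }
  sigma_rec <- ifelse(sigma > 0, sigma, pmax(1e-12, abs(f) * 1e-6 + 1e-12))
  experiment(technique, design_df, y, sigma_rec, locals = locals,
             weight = weight, name = name, subgroup = subgroup,
             protocol = protocol)
}
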