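## Restrict the free set of a parameter table to parameters that can be
## informed by the given experiments: global parameters stay as they are,
## local parameters (name contains ":") of other experiments are fixed.
restrict_params <- function(params, experiments) {
  keep <- vapply(experiments, `[[`, "", "name")
  is_local <- grepl(":", params$name, fixed = TRUE)
  owner <- sub(":.*$", "", params$name)
  params$free <- params$free & (!is_local | owner %in% keep)
  params
}

#' Profile (error-surface) projection with F-statistics contours
#'
#' Profiles the global chi-square over one or two selected free
#' parameters: at each grid node the selected parameters are fixed and
#' all remaining free parameters are re-optimized, giving the projected
#' error surface. Confidence contours follow the F-statistics threshold
#' `chisq_crit = chisq_min * (1 + p/(N_eff - P) * qF(CL; p, N_eff - P))`
#' with p the number of projected parameters and P the total number of
#' free parameters of the fit. Nodes whose re-optimization fails are
#' marked invalid (NA), never interpolated. Grids for K-type (log10)
#' parameters should be supplied log-spaced; the profiling itself is
#' agnostic to the spacing.
#'
#' @param fit a [fit_gmma()] result.
#' @param par_names character(1 or 2): free parameters to project.
#' @param grid list of numeric grid vectors, named by parameter; or for
#'   convenience `n` and `span` to build grids around the best fit.
#' @param levels confidence levels for the contour thresholds.
#' @param n,span used when `grid` is NULL: `n` nodes per axis spanning
#'   best-fit value +/- `span`.
#' @return object of class `gmma_profile`: grids, `chisq` (vector or
#'   matrix over nodes), `chisq_min`, `crit` (named by level), best-fit
#'   values.
#' @export
profile_projection <- function(fit, par_names, grid = NULL,
                               levels = c(0.68, 0.95), n = 21, span = 1) {
  stopifnot(length(par_names) %in% 1:2)
  if (!all(par_names %in% fit$free_names)) {
    stop("par_names must be free parameters of the fit")
  }
  if (is.null(grid)) {
    grid <- lapply(par_names, function(p) {
      v <- fit$value[[p]]
      seq(v - span, v + span, length.out = n)
    })
    names(grid) <- par_names
  }
  stopifnot(all(par_names %in% names(grid)))

  base <- fit$params
  sel <- match(par_names, base$name)
  base$free[sel] <- FALSE

  links_rest <- resolve_links(base)
  has_rest <- links_rest$n_free > 0
  warm <- if (has_rest) links_rest$pack(base) else numeric(0)

  eval_node <- function(vals, start) {
    p <- base
    p$value[sel] <- vals
    if (!has_rest) {
      gc <- global_chisq(fit$experiments, fit$model, params = p)
      return(list(chisq = gc$chisq, v = start))
    }
    links <- resolve_links(p)
    resid_fun <- make_residual_fun(fit$model, fit$experiments, p, links)
    lo <- links$lower; up <- links$upper
    t0 <- transform_to_unconstrained(start, lo, up)
    res <- tryCatch(
      minpack.lm::nls.lm(par = t0,
                         fn = function(t) resid_fun(transform_from_unconstrained(t, lo, up)),
                         control = minpack.lm::nls.lm.control(maxiter = 40,
                                                              ftol = 1e-9)),
      error = function(e) NULL)
    if (is.null(res)) return(list(chisq = NA_real_, v = start))
    v <- transform_from_unconstrained(res$par, lo, up)
    list(chisq = res$deviance, v = v)
  }

  if (length(par_names) == 1) {
    g <- grid[[1]]
    chisq <- rep(NA_real_, length(g))
    ## sweep outward from the node nearest the best fit, warm-starting
    i0 <- which.min(abs(g - fit$value[[par_names]]))
    for (dir in list(i0:length(g), rev(seq_len(i0)))) {
      v <- warm
      for (i in dir) {
        nd <- eval_node(g[i], v)
        chisq[i] <- nd$chisq
        v <- nd$v
      }
    }
  } else {
    gx <- grid[[1]]; gy <- grid[[2]]
    chisq <- matrix(NA_real_, length(gx), length(gy),
                    dimnames = list(NULL, NULL))
    v_row_start <- warm
    for (ix in seq_along(gx)) {
      v <- v_row_start
      jy <- if (ix %% 2 == 1) seq_along(gy) else rev(seq_along(gy))
      first <- TRUE
      for (iy in jy) {
        nd <- eval_node(c(gx[ix], gy[iy]), v)
        chisq[ix, iy] <- nd$chisq
        v <- nd$v
        if (first) { v_row_start <- nd$v; first <- FALSE }
      }
    }
  }
  chisq_min_grid <- min(chisq, na.rm = TRUE)
  chisq_min <- min(fit$chisq, chisq_min_grid)
  p <- length(par_names)
  dof <- fit$n_eff - fit$n_free
  crit <- stats::setNames(
    chisq_min * (1 + p / dof * stats::qf(levels, p, dof)),
    paste0(levels * 100, "%"))
  structure(list(par_names = par_names, grid = grid, chisq = chisq,
                 chisq_min = chisq_min, crit = crit, levels = levels,
                 best = fit$value[par_names], n_eff = fit$n_eff,
                 n_free = fit$n_free),
            class = "gmma_profile")
}

#' Area of a confidence region on a 2-D error-surface projection
#'
#' Counts grid nodes with profiled chi-square at or below the
#' F-statistics threshold of the requested level and multiplies by the
#' grid cell area (in the projected parameter coordinates). Invalid
#' nodes count as outside.
#'
#' @param profile a 2-D [profile_projection()].
#' @param level confidence level (must be one of the profile's levels).
#' @return area in grid coordinate units.
#' @export
contour_area <- function(profile, level = 0.95) {
  stopifnot(inherits(profile, "gmma_profile"),
            length(profile$par_names) == 2)
  i <- match(level, profile$levels)
  if (is.na(i)) stop("level not among the profile's computed levels")
  crit <- profile$crit[i]
  gx <- profile$grid[[1]]; gy <- profile$grid[[2]]
  cell <- mean(diff(gx)) * mean(diff(gy))
  sum(profile$chisq <= crit, na.rm = TRUE) * cell
}

#' Monte-Carlo confidence intervals
#'
#' Generates synthetic replicate data sets as best-fit model plus i.i.d.
#' Gaussian noise at the experimental sigma_(e,i), refits each replicate
#' from the best-fit starting point, and reports percentile intervals of
#' the free parameters. Reproducible under a fixed seed. Replicates whose
#' refit fails are dropped; more than 10 percent failures aborts.
#'
#' @param fit a [fit_gmma()] result.
#' @param n_replicates number of replicates (>= 100 recommended).
#' @param seed integer seed (required).
#' @param level confidence level for the percentile interval.
#' @return list with `intervals` (data.frame: parameter, estimate,
#'   lower, upper, sd), `samples` (replicates x parameters matrix),
#'   `n_failed`.
#' @export
monte_carlo_intervals <- function(fit, n_replicates = 500, seed,
                                  level = 0.68) {
  if (missing(seed)) stop("a seed is required for reproducible Monte-Carlo")
  set.seed(seed)
  f_best <- lapply(fit$experiments, function(e) predict_experiment(fit$model, e))
  samples <- matrix(NA_real_, n_replicates, fit$n_free,
                    dimnames = list(NULL, fit$free_names))
  n_failed <- 0
  for (k in seq_len(n_replicates)) {
    exps <- fit$experiments
    for (i in seq_along(exps)) {
      exps[[i]]$y <- f_best[[i]] + stats::rnorm(exps[[i]]$n, 0, exps[[i]]$sigma)
    }
    links <- fit$links
    resid_fun <- make_residual_fun(fit$model, exps, fit$params, links)
    lo <- links$lower; up <- links$upper
    t0 <- transform_to_unconstrained(unname(fit$value), lo, up)
    res <- tryCatch(
      minpack.lm::nls.lm(par = t0,
        fn = function(t) resid_fun(transform_from_unconstrained(t, lo, up)),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res$par))) {
      n_failed <- n_failed + 1
      next
    }
    samples[k, ] <- transform_from_unconstrained(res$par, lo, up)
  }
  if (n_failed > 0.1 * n_replicates) {
    stop(n_failed, " of ", n_replicates, " replicate fits failed")
  }
  ok <- stats::complete.cases(samples)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  intervals <- data.frame(
    parameter = fit$free_names,
    estimate = unname(fit$value),
    lower = apply(samples[ok, , drop = FALSE], 2, stats::quantile, qs[1]),
    upper = apply(samples[ok, , drop = FALSE], 2, stats::quantile, qs[2]),
    sd = apply(samples[ok, , drop = FALSE], 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  list(intervals = intervals, samples = samples[ok, , drop = FALSE],
       n_failed = n_failed)
}

#' Scan parameter errors over sets of experiment weights
#'
#' Refits the global analysis under each supplied set of weights {w_e}
#' and reports, per free parameter, the union envelope of the confidence
#' intervals across all weight sets, flagging parameters whose best-fit
#' estimate moves by more than its baseline standard error — an alert
#' that the analysis is sensitive to the weighting choice.
#'
#' @param fit a [fit_gmma()] result (defines the baseline weights).
#' @param weight_sets list of numeric weight vectors (one w_e per
#'   experiment; >= 2 sets including the baseline comparison).
#' @param level confidence level for the per-set intervals (curvature
#'   based, value +/- z*stderr).
#' @return list with `per_set` (data.frame), `envelope` (data.frame:
#'   parameter, lower, upper, max_shift_sigma, flagged).
#' @export
weight_scan <- function(fit, weight_sets, level = 0.68) {
  stopifnot(length(weight_sets) >= 2)
  nexp <- length(fit$experiments)
  z <- stats::qnorm(1 - (1 - level) / 2)
  base_se <- fit$stderr
  if (is.null(base_se)) base_se <- fit_covariance(fit)$stderr
  rows <- list()
  for (k in seq_along(weight_sets)) {
    w <- rep_len(weight_sets[[k]], nexp)
    if (all(w == 0)) stop("weight set ", k, " has all-zero weights")
    fk <- fit_gmma(fit$model, fit$experiments, fit$params,
                   method = "marquardt", weights = w)
    se <- fk$stderr
    if (is.null(se)) se <- rep(NA_real_, fk$n_free)
    rows[[k]] <- data.frame(
      set = k, parameter = fk$free_names, estimate = unname(fk$value),
      lower = unname(fk$value) - z * se, upper = unname(fk$value) + z * se,
      stringsAsFactors = FALSE)
  }
  per_set <- do.call(rbind, rows)
  env <- do.call(rbind, lapply(fit$free_names, function(p) {
    d <- per_set[per_set$parameter == p, ]
    shift <- max(abs(d$estimate - fit$value[[p]])) / base_se[[p]]
    data.frame(parameter = p, lower = min(d$lower), upper = max(d$upper),
               max_shift_sigma = shift, flagged = shift > 1,
               stringsAsFactors = FALSE)
  }))
  list(per_set = per_set, envelope = env)
}

#' Cross-validation consistency test across experiment subgroups
#'
#' Flags subgroups of experiments that do not appear mutually consistent
#' with the rest under the shared interaction model. For each subgroup g
#' the analysis is cross-validated: the model is fitted without g
#' (leave-out parameters), g is fitted alone (its own best fit, with only
#' the parameters g can inform left free), and the jointly constrained
#' fit of everything is compared against the split description
#' `chisq_split = chisq_leaveout + chisq_own` by an F-ratio on the extra
#' degrees of freedom released by the split. A subgroup whose own
#' description improves on the shared fit beyond the critical F at the
#' stated confidence is flagged. The chi-square of g's data under the
#' leave-out parameters is reported alongside.
#'
#' @param model a [binding_model()].
#' @param experiments list of [experiment()]s carrying subgroup labels.
#' @param params a [parameter_table()] (starting values).
#' @param confidence confidence level of the F test.
#' @return data.frame: subgroup, chisq_own, chisq_leaveout_eval, F,
#'   F_crit, p_extra, flagged (logical; NA when the subgroup was too
#'   small to fit alone).
#' @export
consistency_test <- function(model, experiments, params = NULL,
                             confidence = 0.95) {
  sg <- vapply(experiments, function(e)
    if (is.null(e$subgroup)) NA_character_ else e$subgroup, "")
  if (any(is.na(sg))) stop("every experiment needs a subgroup label")
  groups <- unique(sg)
  if (length(groups) < 2) stop("need >= 2 subgroups to cross-validate")
  if (is.null(params)) params <- default_parameters(model, experiments)

  fit_all <- fit_gmma(model, experiments, restrict_params(params, experiments),
                      method = "marquardt", covariance = FALSE)
  n_eff <- fit_all$n_eff
  out <- list()
  for (g in groups) {
    in_g <- sg == g
    exps_g <- experiments[in_g]
    exps_rest <- experiments[!in_g]
    pg <- restrict_params(params, exps_g)
    n_free_g <- resolve_links(pg)$n_free
    n_g <- sum(vapply(exps_g, `[[`, 0, "n"))
    if (n_g <= n_free_g) {
      warning("subgroup '", g, "' too small to fit alone; skipped")
      out[[g]] <- data.frame(subgroup = g, chisq_own = NA, chisq_leaveout_eval = NA,
                             F = NA, F_crit = NA, p_extra = NA, flagged = NA)
      next
    }
    fit_rest <- fit_gmma(model, exps_rest,
                         restrict_params(params, exps_rest),
                         method = "marquardt", covariance = FALSE)
    fit_own <- fit_gmma(model, exps_g, pg,
                        method = "marquardt", covariance = FALSE)
    ## chi-square of g's data under the leave-out (cross-validated) global
    ## parameters, with g's own-fit locals
    glob_rows <- !grepl(":", fit_rest$params$name, fixed = TRUE)
    ap <- apply_parameters(fit_rest$model, fit_own$experiments,
                           fit_rest$params[glob_rows, , drop = FALSE])
    loo_eval <- global_chisq(ap$experiments, ap$model)$chisq

    chisq_split <- fit_rest$chisq + fit_own$chisq
    p_extra <- (fit_rest$n_free + fit_own$n_free) - fit_all$n_free
    dof2 <- n_eff - (fit_rest$n_free + fit_own$n_free)
    if (p_extra <= 0 || dof2 <= 0) {
      out[[g]] <- data.frame(subgroup = g, chisq_own = fit_own$chisq,
                             chisq_leaveout_eval = loo_eval,
                             F = NA, F_crit = NA, p_extra = p_extra,
                             flagged = NA)
      next
    }
    Fval <- ((fit_all$chisq - chisq_split) / p_extra) / (chisq_split / dof2)
    Fcrit <- stats::qf(confidence, p_extra, dof2)
    out[[g]] <- data.frame(subgroup = g, chisq_own = fit_own$chisq,
                           chisq_leaveout_eval = loo_eval,
                           F = Fval, F_crit = Fcrit, p_extra = p_extra,
                           flagged = is.finite(Fval) && Fval > Fcrit,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Which experiments carry information on a parameter
#'
#' Perturbs one fitted parameter by its 1-sigma standard error and
#' reports, per experiment, the chi-square increase with that
#' experiment's own free local parameters re-optimized (global parameters
#' held at the perturbed values). Experiments insensitive to the
#' parameter show a near-zero increase; the ranked table identifies
#' where the information on the parameter resides.
#'
#' @param fit a [fit_gmma()] result with covariance.
#' @param par_name one of the fit's free parameters.
#' @return data.frame ranked by decreasing `delta_chisq`:
#'   name, technique, delta_chisq.
#' @export
information_report <- function(fit, par_name) {
  stopifnot(par_name %in% fit$free_names)
  se <- fit$stderr
  if (is.null(se)) se <- fit_covariance(fit)$stderr
  delta <- se[[par_name]]
  if (!is.finite(delta) || delta == 0) delta <- abs(fit$value[[par_name]]) * 1e-3 + 1e-6
  p <- fit$params
  i <- match(par_name, p$name)
  p$value[i] <- p$value[i] + delta
  p$free[i] <- FALSE
  rows <- lapply(fit$experiments, function(e) {
    pe <- restrict_params(p, list(e))
    pe$free <- pe$free & grepl(":", pe$name, fixed = TRUE)  # locals only
    base_chisq <- fit$per_experiment$chisq[fit$per_experiment$name == e$name]
    n_loc <- resolve_links(pe)$n_free
    chisq_pert <- if (n_loc > 0) {
      fe <- fit_gmma(fit$model, list(e), pe, method = "marquardt",
                     covariance = FALSE)
      fe$chisq
    } else {
      global_chisq(list(e), fit$model, params = pe)$chisq
    }
    data.frame(name = e$name, technique = e$technique,
               delta_chisq = chisq_pert - base_chisq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$delta_chisq), , drop = FALSE]
}
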