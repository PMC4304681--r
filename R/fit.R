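#' Weighted global chi-square over a set of experiments
#'
#' The global objective of the multi-method analysis:
#' `chisq_glob = sum_e w_e sum_i ((f_ei - y_ei)/sigma_ei)^2` over all
#' experiments e and points i, with per-experiment statistical weights
#' w_e. The reduced form divides by the effective number of degrees of
#' freedom `N_eff - P` with `N_eff = sum_e w_e N_e` and P the number of
#' free parameters after link resolution (each linked group counts once).
#'
#' @param experiments list of [experiment()]s.
#' @param model a [binding_model()].
#' @param params optional [parameter_table()]; when given, its values are
#'   applied to model and locals before evaluation (and P is taken from
#'   it; otherwise P = 0).
#' @return list with `chisq`, `chisq_r`, `n_eff`, `n_free` and a
#'   `per_experiment` data.frame (name, technique, n, weight, chisq, rmsd).
#' @export
global_chisq <- function(experiments, model, params = NULL) {
  n_free <- 0
  if (!is.null(params)) {
    params <- filter_params_to_experiments(params, experiments)
    ap <- apply_parameters(model, experiments, params)
    model <- ap$model; experiments <- ap$experiments
    n_free <- resolve_links(params)$n_free
  }
  per <- lapply(experiments, function(e) {
    f <- predict_experiment(model, e)
    res <- (f - e$y) / e$sigma
    data.frame(name = e$name, technique = e$technique, n = e$n,
               weight = e$weight, chisq = e$weight * sum(res^2),
               rmsd = sqrt(mean((f - e$y)^2)), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  chisq <- sum(per$chisq)
  n_eff <- sum(per$weight * per$n)
  dof <- n_eff - n_free
  list(chisq = chisq,
       chisq_r = if (dof > 0) chisq / dof else NA_real_,
       n_eff = n_eff, n_free = n_free, per_experiment = per)
}

## A parameter table may cover a superset of experiments (e.g. when fitting
## a single-technique subset of a session); local rows of absent
## experiments are dropped before fitting.
filter_params_to_experiments <- function(params, experiments) {
  exp_names <- vapply(experiments, `[[`, "", "name")
  is_local <- grepl(":", params$name, fixed = TRUE)
  owner <- sub(":.*$", "", params$name)
  params[!is_local | owner %in% exp_names, , drop = FALSE]
}

## Weighted residual vector sqrt(w_e) * (f - y)/sigma for a free vector on
## the natural scale. Returns a big vector over all experiments.
make_residual_fun <- function(model, experiments, params, links) {
  function(vfree) {
    p <- links$unpack(vfree, params)
    ap <- apply_parameters(model, experiments, p)
    unlist(lapply(ap$experiments, function(e) {
      f <- predict_experiment(ap$model, e)
      sqrt(e$weight) * (f - e$y) / e$sigma
    }), use.names = FALSE)
  }
}

#' Fit an interaction model globally to multiple experiments
#'
#' Minimizes the weighted global chi-square of [global_chisq()] over the
#' free parameters of `params` (linked locals move jointly; bounds are
#' enforced by logit/log transformation of the free vector). Optimizers:
#' `"marquardt"` (Marquardt-Levenberg via [minpack.lm::nls.lm()], the
#' default), `"simplex"` (Nelder-Mead, restarted once from its converged
#' point), and `"anneal"` (simulated annealing with exponential cooling
#' followed by a local polish; a seed is mandatory for reproducibility).
#'
#' @param model a [binding_model()].
#' @param experiments list of [experiment()]s.
#' @param params a [parameter_table()]; defaults to
#'   [default_parameters()] of the model and experiments.
#' @param method one of `"marquardt"`, `"simplex"`, `"anneal"`.
#' @param seed integer seed (required for `"anneal"`).
#' @param weights optional numeric vector overriding the experiments'
#'   w_e (recycled; `"equal_experiment"` gives w_e = mean(N)/N_e so every
#'   data set contributes equally regardless of size).
#' @param control list: `maxiter` (default 200), `ftol`, `ptol`.
#' @param covariance compute the covariance matrix at the optimum
#'   (default TRUE).
#' @return object of class `gmma_fit`: optimized `params`, `chisq`,
#'   `chisq_r`, `per_experiment` breakdown, `covariance`, `correlation`,
#'   `free_names`, `n_eff`, `n_free`, `convergence`, plus the model and
#'   experiments carrying best-fit values.
#' @export
fit_gmma <- function(model, experiments, params = NULL,
                     method = c("marquardt", "simplex", "anneal"),
                     seed = NULL, weights = NULL, control = list(),
                     covariance = TRUE) {
  method <- match.arg(method)
  if (inherits(experiments, "gmma_experiment")) experiments <- list(experiments)
  if (is.null(params)) params <- default_parameters(model, experiments)
  params <- filter_params_to_experiments(params, experiments)
  if (!is.null(weights)) {
    if (identical(weights, "equal_experiment")) {
      ns <- vapply(experiments, `[[`, 0, "n")
      weights <- mean(ns) / ns
    }
    weights <- rep_len(weights, length(experiments))
    for (i in seq_along(experiments)) experiments[[i]]$weight <- weights[i]
  }
  links <- resolve_links(params)
  if (links$n_free == 0) stop("all parameters fixed; nothing to fit")
  resid_fun <- make_residual_fun(model, experiments, params, links)
  v0 <- links$pack(params)
  r0 <- resid_fun(v0)
  if (any(!is.finite(r0))) stop("objective is not finite at the starting values")
  chisq0 <- sum(r0^2)

  lo <- links$lower; up <- links$upper
  t0 <- transform_to_unconstrained(v0, lo, up)
  resid_t <- function(t) resid_fun(transform_from_unconstrained(t, lo, up))
  chisq_t <- function(t) {
    r <- resid_t(t)
    if (any(!is.finite(r))) return(1e300)
    sum(r^2)
  }
  maxiter <- if (is.null(control$maxiter)) 200L else control$maxiter

  conv <- list(method = method, start_chisq = chisq0)
  t_best <- t0
  if (method == "marquardt") {
    res <- minpack.lm::nls.lm(
      par = t0, fn = resid_t,
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter,
        ftol = if (is.null(control$ftol)) 1e-10 else control$ftol,
        ptol = if (is.null(control$ptol)) 1e-10 else control$ptol))
    t_best <- res$par
    conv$message <- res$message
    conv$iterations <- res$niter
  } else if (method == "simplex") {
    res <- stats::optim(t0, chisq_t, method = "Nelder-Mead",
                        control = list(maxit = 500 * maxiter))
    res2 <- stats::optim(res$par, chisq_t, method = "Nelder-Mead",
                         control = list(maxit = 500 * maxiter))
    t_best <- res2$par
    conv$message <- "Nelder-Mead with one restart"
    conv$iterations <- res$counts[1] + res2$counts[1]
  } else {
    if (is.null(seed)) stop("simulated annealing requires a seed for reproducibility")
    set.seed(seed)
    res <- stats::optim(t0, chisq_t, method = "SANN",
                        control = list(maxit = if (is.null(control$sann_maxit))
                          5000 else control$sann_maxit,
                          temp = 10, tmax = 10))
    polish <- stats::optim(res$par, chisq_t, method = "Nelder-Mead",
                           control = list(maxit = 500 * maxiter))
    t_best <- polish$par
    conv$message <- "simulated annealing (exponential cooling) + simplex polish"
    conv$iterations <- res$counts[1] + polish$counts[1]
  }
  ## single-free-parameter Nelder-Mead is unreliable; guard with a 1-D polish
  if (links$n_free == 1 && method != "marquardt") {
    opt1 <- stats::optimize(function(t) chisq_t(t),
                            interval = c(t_best - 2, t_best + 2))
    if (opt1$objective < chisq_t(t_best)) t_best <- opt1$minimum
  }

  v_best <- transform_from_unconstrained(t_best, lo, up)
  r_best <- resid_fun(v_best)
  chisq_best <- sum(r_best^2)
  if (chisq_best > chisq0) {        # never step uphill from the start
    v_best <- v0; r_best <- r0; chisq_best <- chisq0
  }
  conv$chisq <- chisq_best

  params <- links$unpack(v_best, params)
  ap <- apply_parameters(model, experiments, params)
  gc <- global_chisq(ap$experiments, ap$model, params = NULL)
  n_eff <- gc$n_eff
  dof <- n_eff - links$n_free
  chisq_r <- if (dof > 0) chisq_best / dof else NA_real_

  fit <- structure(list(
    params = params, links = links, free_names = links$free_names,
    value = stats::setNames(v_best, links$free_names),
    chisq = chisq_best, chisq_r = chisq_r,
    n_eff = n_eff, n_free = links$n_free, dof = dof,
    per_experiment = gc$per_experiment,
    residuals = r_best,
    model = ap$model, experiments = ap$experiments,
    method = method, seed = seed, convergence = conv,
    covariance = NULL, correlation = NULL
  ), class = "gmma_fit")
  if (covariance) {
    cv <- try(fit_covariance(fit), silent = TRUE)
    if (!inherits(cv, "try-error")) {
      fit$covariance <- cv$covariance
      fit$correlation <- cv$correlation
      fit$stderr <- cv$stderr
    }
  }
  fit
}

## Numerical Jacobian of the weighted residual vector w.r.t. the free
## vector on the natural scale (forward differences, relative step 1e-6).
fit_jacobian <- function(fit, rel_step = 1e-6) {
  resid_fun <- make_residual_fun(fit$model, fit$experiments, fit$params,
                                 fit$links)
  v <- unname(fit$value)
  r0 <- resid_fun(v)
  J <- matrix(0, nrow = length(r0), ncol = length(v))
  for (j in seq_along(v)) {
    h <- rel_step * max(abs(v[j]), 1e-8)
    vj <- v; vj[j] <- vj[j] + h
    J[, j] <- (resid_fun(vj) - r0) / h
  }
  colnames(J) <- fit$free_names
  J
}

#' Covariance and cross-correlation matrix of a converged fit
#'
#' Curvature-based error estimates: with J the Jacobian of the weighted
#' residual vector at the optimum, `cov = chisq_r * (J'J)^-1`, scaled by
#' the reduced chi-square so that sigma estimates remain calibrated when
#' the per-point sigmas are off by a common factor. A singular curvature
#' matrix is flagged with a warning and handled by pseudo-inverse.
#'
#' @param fit a [fit_gmma()] result.
#' @return list with `covariance`, `correlation`, `stderr`.
#' @export
fit_covariance <- function(fit) {
  J <- fit_jacobian(fit)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ), error = function(e) {
    warning("singular curvature matrix; using pseudo-inverse")
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  scale <- if (is.finite(fit$chisq_r) && fit$chisq_r > 0) fit$chisq_r else 1
  cov <- cov * scale
  se <- sqrt(pmax(diag(cov), 0))
  cor <- cov / outer(se, se)
  diag(cor) <- 1
  dimnames(cov) <- dimnames(cor) <- list(fit$free_names, fit$free_names)
  list(covariance = cov, correlation = cor,
       stderr = stats::setNames(se, fit$free_names))
}

#' @export
print.gmma_fit <- function(x, ...) {
  cat(sprintf("Global multi-method fit (%s): %d experiments, %d free parameters\n",
              x$method, nrow(x$per_experiment), x$n_free))
  cat(sprintf("  global chisq = %.6g, reduced chisq = %.4g (N_eff = %g)\n",
              x$chisq, x$chisq_r, x$n_eff))
  se <- if (!is.null(x$stderr)) x$stderr else rep(NA_real_, x$n_free)
  for (i in seq_along(x$free_names)) {
    cat(sprintf("  %-24s %12.6g +/- %.3g\n", x$free_names[i],
                x$value[i], se[i]))
  }
  cat("  per experiment:\n")
  pe <- x$per_experiment
  for (i in seq_len(nrow(pe))) {
    cat(sprintf("    %-16s (%s, n=%d, w=%g): chisq %.4g, rmsd %.4g\n",
                pe$name[i], pe$technique[i], pe$n[i], pe$weight[i],
                pe$chisq[i], pe$rmsd[i]))
  }
  invisible(x)
}

#' @export
vcov.gmma_fit <- function(object, ...) {
  if (is.null(object$covariance)) fit_covariance(object)$covariance
  else object$covariance
}
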