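#' Solve mass-action equilibrium for free and complex concentrations
#'
#' Given total molar concentrations per component, finds the unique
#' composition satisfying the law of mass action
#' `[S] = beta_S * prod_j [free_j]^nu_jS` for every complex species and the
#' mass balance `total_j = free_j + sum_S nu_jS [S]`. The solve is a damped
#' Newton iteration on log free concentrations (unconditionally positive,
#' robust over many orders of magnitude of beta), initialized at
#' `free = totals`, with step backtracking on overshoot and convergence at
#' maximum relative mass-balance error < `tol`.
#'
#' @param model a [binding_model()].
#' @param totals named numeric vector of total concentrations (M), one per
#'   component (missing components are taken as 0). All must be >= 0.
#' @param tol relative mass-balance convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `solution_state`: list with `totals`, `free`
#'   (per component, M) and `species` (per complex species, M).
#' @examples
#' m <- binding_model(c("A", "B"),
#'   list(AB = list(stoich = c(A = 1, B = 1), log10beta = 6)))
#' st <- solve_concentrations(m, c(A = 1e-6, B = 1e-6))
#' st$species[["AB"]]  # 3.8197e-7 M at Kd = 1 uM
#' @export
solve_concentrations <- function(model, totals, tol = 1e-12, max_iter = 200L) {
  comps <- model$components
  if (is.null(names(totals)) || !all(names(totals) %in% comps)) {
    stop("totals must be named by model components")
  }
  tot <- stats::setNames(numeric(length(comps)), comps)
  tot[names(totals)] <- unname(totals)
  if (any(!is.finite(tot)) || any(tot < 0)) stop("totals must be finite and >= 0")

  nsp <- length(model$species_names)
  species <- stats::setNames(numeric(nsp), model$species_names)
  free <- stats::setNames(numeric(length(comps)), comps)

  active <- tot > 0
  if (any(active)) {
    if (nsp > 0) {
      sp_active <- rowSums(model$stoich[, !active, drop = FALSE] != 0) == 0
    } else {
      sp_active <- logical(0)
    }
    S <- model$stoich[sp_active, active, drop = FALSE]
    lnb <- model$log10beta[sp_active] * .LN10
    sol <- solve_core(S, lnb, tot[active], tol, max_iter)
    free[active] <- sol$x
    species[rownames(S)] <- sol$csp
  }
  new_solution_state(model, tot, free, species)
}

## Lean Newton core on log free concentrations. S: species x components
## stoichiometry (complexes only), lnb: natural-log cumulative association
## constants, Ta: positive totals. Returns x (free) and csp (complexes).
solve_core <- function(S, lnb, Ta, tol = 1e-12, max_iter = 200L, x0 = NULL) {
  na <- length(Ta)
  nS <- nrow(S)
  if (nS == 0L) return(list(x = Ta, csp = numeric(0)))
  x <- if (is.null(x0)) Ta else pmin(pmax(x0, Ta * 1e-14), Ta)
  u <- log(x)
  csp <- exp(pmin(lnb + drop(S %*% u), 700))
  R <- x + drop(csp %*% S) - Ta
  err <- max(abs(R) / Ta)
  iter <- 0L
  two <- na == 2L
  one <- na == 1L
  while (err > tol && iter < max_iter) {
    iter <- iter + 1L
    ## J_jk = x_j delta_jk + sum_S nu_jS nu_kS [S]
    if (one) {
      J11 <- x + sum(S[, 1]^2 * csp)
      du <- -R / J11
    } else if (two) {
      a <- x[1] + sum(S[, 1]^2 * csp)
      d <- x[2] + sum(S[, 2]^2 * csp)
      b <- sum(S[, 1] * S[, 2] * csp)
      det <- a * d - b * b
      if (det <= 0 || !is.finite(det)) {
        du <- -R / c(a, d)
      } else {
        du <- c(-(d * R[1] - b * R[2]), -(a * R[2] - b * R[1])) / det
      }
    } else {
      J <- crossprod(S * sqrt(csp))
      diag(J) <- diag(J) + x
      du <- tryCatch(-solve(J, R), error = function(e) -R / (x + diag(J)))
    }
    cap <- max(abs(du))
    if (cap > 4) du <- du * (4 / cap)
    lambda <- 1
    repeat {
      u_new <- u + lambda * du
      x_new <- exp(u_new)
      c_new <- exp(pmin(lnb + drop(S %*% u_new), 700))
      R_new <- x_new + drop(c_new %*% S) - Ta
      e_new <- max(abs(R_new) / Ta)
      if (e_new < err || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    u <- u_new; x <- x_new; csp <- c_new; R <- R_new; err <- e_new
  }
  if (err > tol) {
    if (!is.null(x0)) return(solve_core(S, lnb, Ta, tol, max_iter))  # cold restart
    stop(sprintf(
      "equilibrium solver did not converge (relative mass-balance error %.3g after %d iterations)",
      err, iter))
  }
  list(x = x, csp = csp)
}

new_solution_state <- function(model, totals, free, species) {
  structure(list(totals = totals, free = free, species = species),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat("Equilibrium solution state (M):\n")
  for (nm in names(x$free)) {
    cat(sprintf("  free %-6s %.6e  (total %.6e)\n", nm, x$free[nm], x$totals[nm]))
  }
  for (nm in names(x$species)) {
    cat(sprintf("  %-10s %.6e\n", nm, x$species[nm]))
  }
  invisible(x)
}

## Concentrations of every species (free components first, then complexes)
## at one composition; used by the forward models.
state_species_conc <- function(state) {
  c(state$free, state$species)
}

## Solve a series of compositions given as a data.frame with columns
## "tot.<component>"; returns a matrix (points x all species), free
## components first. Hot path of every isotherm: uses the lean core
## directly, re-deriving the active-component pattern only when it
## changes between consecutive points.
solve_series <- function(model, design) {
  cols <- design_columns(model, design)
  totm <- as.matrix(design[, cols, drop = FALSE])
  colnames(totm) <- model$components
  nc <- length(model$components)
  nsp <- length(model$species_names)
  out <- matrix(0, nrow = nrow(totm), ncol = nc + nsp,
                dimnames = list(NULL, c(model$components, model$species_names)))
  if (any(!is.finite(totm)) || any(totm < 0)) stop("totals must be finite and >= 0")

  pat_prev <- NULL
  S <- NULL; lnb <- NULL; sp_active <- NULL
  x_prev <- NULL
  for (i in seq_len(nrow(totm))) {
    tot <- totm[i, ]
    active <- tot > 0
    if (!any(active)) next
    if (is.null(pat_prev) || !identical(active, pat_prev)) {
      pat_prev <- active
      if (nsp > 0) {
        sp_active <- rowSums(model$stoich[, !active, drop = FALSE] != 0) == 0
      } else sp_active <- logical(0)
      S <- model$stoich[sp_active, active, drop = FALSE]
      lnb <- model$log10beta[sp_active] * .LN10
      x_prev <- NULL
    }
    sol <- solve_core(S, lnb, tot[active], x0 = x_prev)
    x_prev <- sol$x
    out[i, which(active)] <- sol$x
    out[i, nc + which(sp_active)] <- sol$csp
  }
  out
}

design_columns <- function(model, design) {
  cols <- paste0("tot.", model$components)
  missing <- setdiff(cols, names(design))
  if (length(missing)) {
    stop("design is missing total-concentration column(s): ",
         paste(missing, collapse = ", "))
  }
  cols
}
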