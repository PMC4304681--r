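#' @keywords internal
"_PACKAGE"

## Gas constant in kcal mol^-1 K^-1; all energies in the package are kcal/mol,
## all concentrations molar, association constants stored as log10(beta)
## against a 1 M standard state.
.R_KCAL <- 1.987e-3
.LN10 <- log(10)

#' Define a multi-site interaction model
#'
#' A `binding_model` holds the named components of an interacting system and
#' the complex species they form. Each complex carries an integer
#' stoichiometry vector over the components, a cumulative association
#' constant `log10beta` (dimensionless against a 1 M standard state), a
#' cumulative molar enthalpy `dH` relative to the free components
#' (kcal/mol), a sedimentation coefficient `s` (Svedberg) and an anisotropy
#' `r`. Free components are implicit species with `log10beta = 0` and
#' `dH = 0`; their `s` and `r` values are supplied through
#' `component_properties`.
#'
#' In `mode = "microscopic"` the model describes a component with two
#' identical, possibly cooperative sites: instead of macroscopic constants
#' the user supplies a per-site constant `log10k` and a cooperativity factor
#' `log10alpha` for a designated pair of 1:1 and 1:2 species. These are
#' converted to the stored macroscopic constants through the statistical
#' factors for two identical sites, K1 = 2k and K2 = alpha*k/2 (so
#' beta2 = alpha*k^2).
#'
#' @param components character vector of component names (e.g. `c("A","B")`).
#' @param species named list of complexes. Each element is a list with
#'   `stoich` (named integer vector over components), `log10beta`, and
#'   optionally `dH`, `s`, `r` (defaults 0).
#' @param mode `"macroscopic"` (default) or `"microscopic"`.
#' @param temperature temperature in K used for thermodynamic transforms.
#' @param component_properties optional named list giving, per component,
#'   a list with `s` and/or `r` for the free species (defaults 0).
#' @param microscopic for `mode = "microscopic"`: a list with `pair`
#'   (character(2): the names of the 1:1 and 1:2 species), `log10k` and
#'   `log10alpha`. The two pair species must share the same single-site
#'   component and the site component must appear once resp. twice.
#' @return an object of class `binding_model`.
#' @examples
#' m <- binding_model(
#'   components = c("A", "B"),
#'   species = list(AB = list(stoich = c(A = 1, B = 1), log10beta = 6))
#' )
#' @export
binding_model <- function(components, species = list(),
                          mode = c("macroscopic", "microscopic"),
                          temperature = 298.15,
                          component_properties = NULL,
                          microscopic = NULL) {
  mode <- match.arg(mode)
  if (!is.character(components) || length(components) < 1 ||
      anyDuplicated(components)) {
    stop("components must be unique non-empty names")
  }
  if (length(species) && (is.null(names(species)) ||
                          anyDuplicated(names(species)) ||
                          any(!nzchar(names(species))))) {
    stop("duplicate or unnamed species")
  }
  if (any(names(species) %in% components)) {
    stop("species name collides with a component name: ",
         paste(intersect(names(species), components), collapse = ", "))
  }
  nsp <- length(species)
  stoich <- matrix(0L, nrow = nsp, ncol = length(components),
                   dimnames = list(names(species), components))
  log10beta <- dH <- s <- r <- stats::setNames(numeric(nsp), names(species))
  for (nm in names(species)) {
    sp <- species[[nm]]
    st <- sp$stoich
    if (is.null(st) || is.null(names(st))) {
      stop("species '", nm, "' needs a named stoichiometry vector")
    }
    unknown <- setdiff(names(st), components)
    if (length(unknown)) {
      stop("species '", nm, "' references unknown component(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(st < 0) || any(st != round(st))) {
      stop("species '", nm, "' has non-integer or negative stoichiometry")
    }
    if (all(st == 0)) stop("species '", nm, "' has all-zero stoichiometry")
    stoich[nm, names(st)] <- as.integer(st)
    log10beta[nm] <- if (is.null(sp[["log10beta"]])) NA_real_ else sp[["log10beta"]]
    dH[nm] <- if (is.null(sp[["dH"]])) 0 else sp[["dH"]]
    s[nm] <- if (is.null(sp[["s"]])) 0 else sp[["s"]]
    r[nm] <- if (is.null(sp[["r"]])) 0 else sp[["r"]]
  }

  micro <- NULL
  if (mode == "microscopic") {
    if (is.null(microscopic) ||
        is.null(microscopic$pair) || length(microscopic$pair) != 2 ||
        is.null(microscopic$log10k) || is.null(microscopic$log10alpha)) {
      stop("microscopic mode needs a 'microscopic' list with pair, log10k, log10alpha")
    }
    pair <- microscopic$pair
    if (!all(pair %in% rownames(stoich))) {
      stop("microscopic pair species not found: ",
           paste(setdiff(pair, rownames(stoich)), collapse = ", "))
    }
    d <- stoich[pair[2], ] - stoich[pair[1], ]
    if (sum(stoich[pair[1], ] != 0) != 2 || any(d < 0) || sum(d) != 1) {
      stop("microscopic pair must be a 1:1 species and its 1:2 extension ",
           "over the same two components")
    }
    k <- microscopic$log10k
    a <- microscopic$log10alpha
    ## two identical sites: K1 = 2k, K2 = alpha*k/2 -> beta2 = alpha*k^2
    log10beta[pair[1]] <- log10(2) + k
    log10beta[pair[2]] <- a + 2 * k
    micro <- list(pair = pair, log10k = k, log10alpha = a)
  }
  if (any(!is.finite(log10beta))) {
    stop("every species needs a finite log10beta (or microscopic constants)")
  }

  cs <- cr <- stats::setNames(numeric(length(components)), components)
  for (cn in names(component_properties)) {
    if (!cn %in% components) stop("component_properties for unknown component: ", cn)
    cp <- component_properties[[cn]]
    if (!is.null(cp[["s"]])) cs[cn] <- cp[["s"]]
    if (!is.null(cp[["r"]])) cr[cn] <- cp[["r"]]
  }

  structure(list(
    components = components,
    species_names = names(species),
    stoich = stoich,
    log10beta = log10beta,
    dH = dH,
    s = s,
    r = r,
    comp_s = cs,
    comp_r = cr,
    mode = mode,
    microscopic = micro,
    temperature = temperature
  ), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Interaction model (", x$mode, "), ",
      length(x$components), " components, ",
      length(x$species_names), " complex species, T = ",
      x$temperature, " K\n", sep = "")
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  for (nm in x$species_names) {
    st <- x$stoich[nm, ]
    comp <- paste(rep(names(st), st), collapse = "")
    cat(sprintf("  %-8s [%s]  log10beta=%.4g  dH=%.4g kcal/mol  s=%.3g S\n",
                nm, comp, x$log10beta[nm], x$dH[nm], x$s[nm]))
  }
  invisible(x)
}

## Full species table including the implicit free components (unit
## stoichiometries, log10beta = 0, dH = 0). Used by all forward models.
all_species <- function(model) {
  nc <- length(model$components)
  free_stoich <- diag(nc)
  dimnames(free_stoich) <- list(model$components, model$components)
  stoich <- rbind(free_stoich, model$stoich)
  list(
    names = c(model$components, model$species_names),
    stoich = stoich,
    log10beta = c(stats::setNames(numeric(nc), model$components),
                  model$log10beta),
    dH = c(stats::setNames(numeric(nc), model$components), model$dH),
    s = c(model$comp_s, model$s),
    r = c(model$comp_r, model$r),
    is_complex = c(rep(FALSE, nc), rep(TRUE, length(model$species_names)))
  )
}

#' Thermodynamic transforms between log10(beta) and free energy
#'
#' `dG_from_log10beta` converts association constants to standard binding
#' free energies, dG = -RT ln(10) log10beta (kcal/mol, R = 1.987e-3
#' kcal/(mol K)); `log10beta_from_dG` is its inverse.
#'
#' @param log10beta,dG numeric vectors.
#' @param temperature temperature in K (> 0).
#' @return numeric vector.
#' @export
dG_from_log10beta <- function(log10beta, temperature = 298.15) {
  stopifnot(temperature > 0)
  -.R_KCAL * temperature * .LN10 * log10beta
}

#' @rdname dG_from_log10beta
#' @export
log10beta_from_dG <- function(dG, temperature = 298.15) {
  stopifnot(temperature > 0)
  -dG / (.R_KCAL * temperature * .LN10)
}

#' Cooperativity of a two-site model
#'
#' For a model with a 1:1 species and its 1:2 extension the macroscopic
#' stepwise constants are K1 = beta1 and K2 = beta2/beta1. Two
#' cooperativity conventions are reported side by side: the raw
#' macroscopic ddG = dG(step 2) - dG(step 1), and the
#' statistical-factor-corrected ddG derived from the microscopic
#' cooperativity factor alpha = 4 K2 / K1 (for two identical sites,
#' K1 = 2k and K2 = alpha k / 2), ddG_corrected = -RT ln(10) log10(alpha).
#' For independent identical sites (alpha = 1) the corrected ddG is 0
#' while the macroscopic convention gives -RT ln(4).
#'
#' @param model a `binding_model` with at least a 1:1/1:2 species pair.
#' @param pair character(2) naming the 1:1 and 1:2 species; defaults to the
#'   microscopic pair if the model has one, else the first such pair found.
#' @return list with `log10K1`, `log10K2`, `log10alpha`,
#'   `ddG_macroscopic`, `ddG_corrected` (kcal/mol).
#' @export
cooperativity <- function(model, pair = NULL) {
  if (is.null(pair)) {
    if (!is.null(model$microscopic)) {
      pair <- model$microscopic$pair
    } else {
      pair <- find_site_pair(model)
    }
  }
  stopifnot(all(pair %in% model$species_names))
  b1 <- model$log10beta[pair[1]]
  b2 <- model$log10beta[pair[2]]
  log10K1 <- b1
  log10K2 <- b2 - b1
  log10alpha <- log10(4) + log10K2 - log10K1
  T <- model$temperature
  list(
    log10K1 = unname(log10K1),
    log10K2 = unname(log10K2),
    log10alpha = unname(log10alpha),
    ddG_macroscopic = unname(dG_from_log10beta(log10K2, T) -
                             dG_from_log10beta(log10K1, T)),
    ddG_corrected = unname(dG_from_log10beta(log10alpha, T))
  )
}

find_site_pair <- function(model) {
  st <- model$stoich
  for (i in seq_along(model$species_names)) {
    for (j in seq_along(model$species_names)) {
      d <- st[j, ] - st[i, ]
      if (sum(st[i, ] != 0) == 2 && all(st[i, ] <= 1) &&
          all(d >= 0) && sum(d) == 1 && all(st[j, ] <= 2)) {
        return(c(model$species_names[i], model$species_names[j]))
      }
    }
  }
  stop("no 1:1/1:2 species pair found in model")
}
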