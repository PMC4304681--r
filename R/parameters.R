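#' Parameter table for a global fit
#'
#' The parameter space of a GMMA fit is a data.frame with one row per
#' parameter slot and columns `name`, `value`, `free`, `lower`, `upper`,
#' `link`. Global parameters address model quantities by name:
#' `log10beta.<species>`, `dH.<species>`, `s.<species-or-component>`,
#' `r.<species-or-component>`, and (for microscopic-mode models)
#' `log10k` / `log10alpha`. Local parameters are prefixed with the
#' experiment name, `"<experiment>:<local>"`, e.g. `"itc1:gamma.A"` or
#' `"spr1:baseline"`. Parameters sharing a non-NA `link` id are linked
#' local parameters: they are fitted as a single free value.
#'
#' @param name character vector of parameter names.
#' @param value numeric starting values.
#' @param free logical, is the parameter adjusted by the fit.
#' @param lower,upper bounds (default unbounded). Bounds are enforced by
#'   a logit/log transformation of the free vector, not by penalties.
#' @param link character link-group ids (NA = unlinked).
#' @return data.frame of class `gmma_parameters`.
#' @export
parameter_table <- function(name, value, free = TRUE,
                            lower = -Inf, upper = Inf, link = NA_character_) {
  df <- data.frame(name = as.character(name), value = as.numeric(value),
                   free = rep_len(free, length(name)),
                   lower = rep_len(as.numeric(lower), length(name)),
                   upper = rep_len(as.numeric(upper), length(name)),
                   link = rep_len(as.character(link), length(name)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("duplicate parameter names")
  bad <- df$value < df$lower | df$value > df$upper
  if (any(bad)) stop("starting value outside bounds for: ",
                     paste(df$name[bad], collapse = ", "))
  class(df) <- c("gmma_parameters", "data.frame")
  df
}

rbind_parameters <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  parameter_table(df$name, df$value, df$free, df$lower, df$upper, df$link)
}

#' Default parameter registry for a model and a set of experiments
#'
#' Auto-populates the parameter table the way a global-analysis session
#' expects: all `log10beta` free; `dH` of every species free if any ITC
#' experiment is present (fixed otherwise — no other technique probes
#' enthalpy); complex-species `s` free if any s_w experiment is present;
#' complex-species `r` free if any anisotropy experiment is present; and
#' the locals each technique needs, registered per experiment with
#' technique-appropriate defaults and bounds (all fixed by default —
#' baselines at 0, concentration-error factors gamma at 1 in [0.5, 2],
#' incompetent fractions at 0 in [0, 1]). The caller frees, links or
#' re-bounds entries as the design warrants.
#'
#' @param model a [binding_model()].
#' @param experiments list of [experiment()] objects.
#' @return a [parameter_table()].
#' @export
default_parameters <- function(model, experiments = list()) {
  techs <- vapply(experiments, `[[`, "", "technique")
  rows <- list()
  add <- function(name, value, free = FALSE, lower = -Inf, upper = Inf) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, value = value, free = free, lower = lower, upper = upper,
      link = NA_character_, stringsAsFactors = FALSE)
  }
  if (model$mode == "microscopic") {
    add("log10k", model$microscopic$log10k, free = TRUE)
    add("log10alpha", model$microscopic$log10alpha, free = TRUE)
    other <- setdiff(model$species_names, model$microscopic$pair)
    for (nm in other) add(paste0("log10beta.", nm), model$log10beta[nm], free = TRUE)
  } else {
    for (nm in model$species_names) {
      add(paste0("log10beta.", nm), model$log10beta[nm], free = TRUE)
    }
  }
  for (nm in model$species_names) {
    add(paste0("dH.", nm), model$dH[nm], free = "itc" %in% techs)
    add(paste0("s.", nm), model$s[nm], free = "sw" %in% techs)
    add(paste0("r.", nm), model$r[nm], free = "anisotropy" %in% techs)
  }
  for (e in experiments) {
    p <- function(local) paste0(e$name, ":", local)
    for (cn in model$components) {
      add(p(paste0("gamma.", cn)),
          local_value(e$locals, paste0("gamma.", cn), 1), lower = 0.5, upper = 2)
      add(p(paste0("incompetent.", cn)),
          local_value(e$locals, paste0("incompetent.", cn), 0),
          lower = 0, upper = 1)
    }
    switch(e$technique,
      itc = {
        add(p("dH_dilution"), local_value(e$locals, "dH_dilution", 0))
        add(p("q_offset"), local_value(e$locals, "q_offset", 0))
      },
      spr = ,
      spr_competition = {
        add(p("rmax"), local_value(e$locals, "rmax", 1), lower = 0)
        add(p("kd_surf"), local_value(e$locals, "kd_surf", 1e-6), lower = 0)
        add(p("baseline"), local_value(e$locals, "baseline", 0))
      },
      sw = {
        for (cn in model$components) {
          add(p(paste0("eps.", cn)),
              local_value(e$locals, paste0("eps.", cn), 1), lower = 0)
        }
      },
      anisotropy = NULL,
      signal = {
        add(p("baseline"), local_value(e$locals, "baseline", 0))
        sp <- all_species(model)
        for (nm in sp$names) {
          add(p(paste0("coeff.", nm)),
              local_value(e$locals, paste0("coeff.", nm), 0))
        }
      })
  }
  df <- do.call(rbind, rows)
  parameter_table(df$name, df$value, df$free, df$lower, df$upper, df$link)
}

#' Resolve linked parameters into a free-parameter vector
#'
#' Builds the bijection between the parameter table and the flattened
#' vector of independently fitted values: fixed parameters are excluded;
#' parameters sharing a link id collapse to a single slot (all members
#' must agree on free status — a group mixing fixed and free members is
#' contradictory and rejected). `pack` extracts the free vector from a
#' table; `unpack` writes a free vector back (link members move jointly);
#' the round trip is the identity.
#'
#' @param params a [parameter_table()].
#' @return list with `free_names` (representative name per free slot),
#'   `lower`, `upper`, `pack(params)` and `unpack(values, params)`.
#' @export
resolve_links <- function(params) {
  stopifnot(is.data.frame(params))
  groups <- split(seq_len(nrow(params)),
                  ifelse(is.na(params$link),
                         paste0(".row", seq_len(nrow(params))), params$link))
  slots <- list()
  for (g in groups) {
    fr <- params$free[g]
    if (length(unique(fr)) > 1) {
      stop("contradictory link group (mixes fixed and free): ",
           paste(params$name[g], collapse = ", "))
    }
    if (!fr[1]) next
    slots[[length(slots) + 1]] <- g
  }
  ## deterministic order: by first row index
  ord <- order(vapply(slots, min, 0L))
  slots <- slots[ord]
  free_names <- vapply(slots, function(g) params$name[g[1]], "")
  lower <- vapply(slots, function(g) max(params$lower[g]), 0)
  upper <- vapply(slots, function(g) min(params$upper[g]), 0)
  list(
    free_names = free_names,
    lower = lower,
    upper = upper,
    n_free = length(slots),
    pack = function(p) {
      vapply(slots, function(g) p$value[g[1]], 0)
    },
    unpack = function(values, p) {
      stopifnot(length(values) == length(slots))
      for (i in seq_along(slots)) p$value[slots[[i]]] <- values[i]
      p
    }
  )
}

## --- bound-enforcing transforms ------------------------------------------
## Free values are optimized on an unconstrained scale: identity when
## unbounded, log-offset for one-sided bounds, logit for two-sided.

transform_to_unconstrained <- function(v, lower, upper) {
  out <- v
  for (i in seq_along(v)) {
    l <- lower[i]; u <- upper[i]
    out[i] <- if (is.finite(l) && is.finite(u)) {
      p <- (v[i] - l) / (u - l)
      p <- min(max(p, 1e-12), 1 - 1e-12)
      log(p / (1 - p))
    } else if (is.finite(l)) log(max(v[i] - l, 1e-300))
    else if (is.finite(u)) -log(max(u - v[i], 1e-300))
    else v[i]
  }
  out
}

transform_from_unconstrained <- function(t, lower, upper) {
  out <- t
  for (i in seq_along(t)) {
    l <- lower[i]; u <- upper[i]
    out[i] <- if (is.finite(l) && is.finite(u)) {
      l + (u - l) / (1 + exp(-t[i]))
    } else if (is.finite(l)) l + exp(t[i])
    else if (is.finite(u)) u - exp(-t[i])
    else t[i]
  }
  out
}

#' Apply a parameter table to a model and experiments
#'
#' Writes the current values of a parameter table into a copy of the
#' model (global parameters) and of the experiments' locals (prefixed
#' parameters), returning the updated objects.
#'
#' @param model a [binding_model()].
#' @param experiments list of [experiment()]s.
#' @param params a [parameter_table()].
#' @return list(model, experiments).
#' @export
apply_parameters <- function(model, experiments, params) {
  exp_names <- vapply(experiments, `[[`, "", "name")
  micro_touched <- FALSE
  for (i in seq_len(nrow(params))) {
    nm <- params$name[i]
    val <- params$value[i]
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      j <- match(parts[1], exp_names)
      if (is.na(j)) stop("parameter '", nm, "' references unknown experiment")
      experiments[[j]]$locals[[parts[2]]] <- val
    } else if (nm == "log10k") {
      model$microscopic$log10k <- val; micro_touched <- TRUE
    } else if (nm == "log10alpha") {
      model$microscopic$log10alpha <- val; micro_touched <- TRUE
    } else {
      dot <- regexpr(".", nm, fixed = TRUE)
      if (dot < 0) stop("unrecognized parameter name '", nm, "'")
      field <- substr(nm, 1, dot - 1)
      target <- substr(nm, dot + 1, nchar(nm))
      is_sp <- target %in% model$species_names
      is_comp <- target %in% model$components
      if (!is_sp && !is_comp) {
        stop("parameter '", nm, "' references unknown species/component")
      }
      model <- switch(field,
        log10beta = { if (!is_sp) stop("log10beta applies to species: ", nm)
          model$log10beta[target] <- val; model },
        dH = { if (!is_sp) stop("dH applies to species: ", nm)
          model$dH[target] <- val; model },
        s = { if (is_sp) model$s[target] <- val else model$comp_s[target] <- val
          model },
        r = { if (is_sp) model$r[target] <- val else model$comp_r[target] <- val
          model },
        stop("unrecognized parameter field '", field, "' in '", nm, "'"))
    }
  }
  if (micro_touched && model$mode == "microscopic") {
    pair <- model$microscopic$pair
    model$log10beta[pair[1]] <- log10(2) + model$microscopic$log10k
    model$log10beta[pair[2]] <- model$microscopic$log10alpha +
      2 * model$microscopic$log10k
  }
  list(model = model, experiments = experiments)
}
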