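## Full-precision number formatting for lossless text round trips.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 17, scientific = NA, trim = TRUE)
    s
  }, "")
}

#' Read and write interaction models as YAML
#'
#' The model configuration is a small YAML tree: `components`, `mode`,
#' `temperature`, optional `component_properties` (per-component `s`,
#' `r`), `species` (per complex: `stoich`, `log10beta`, `dH`, `s`, `r`)
#' and, for microscopic mode, a `microscopic` block (`pair`, `log10k`,
#' `log10alpha`). Numbers are written with 17 significant digits so the
#' round trip through `write_model`/`read_model` is exact.
#'
#' @param path file path.
#' @param model a [binding_model()].
#' @return `read_model` returns a `binding_model`; `write_model` its
#'   path, invisibly.
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components)) stop("model file lacks 'components'")
  species <- lapply(cfg$species, function(sp) {
    list(stoich = unlist(sp[["stoich"]]), log10beta = sp[["log10beta"]],
         dH = sp[["dH"]], s = sp[["s"]], r = sp[["r"]])
  })
  binding_model(
    components = unlist(cfg$components),
    species = species,
    mode = if (is.null(cfg$mode)) "macroscopic" else cfg$mode,
    temperature = if (is.null(cfg$temperature)) 298.15 else cfg$temperature,
    component_properties = cfg$component_properties,
    microscopic = if (!is.null(cfg$microscopic)) {
      list(pair = unlist(cfg$microscopic$pair),
           log10k = cfg$microscopic$log10k,
           log10alpha = cfg$microscopic$log10alpha)
    } else NULL
  )
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  species <- list()
  for (nm in model$species_names) {
    st <- model$stoich[nm, ]
    sp <- list(stoich = as.list(st[st != 0]))
    if (is.null(model$microscopic) ||
        !(nm %in% model$microscopic$pair)) {
      sp$log10beta <- model$log10beta[[nm]]
    }
    sp$dH <- model$dH[[nm]]
    sp$s <- model$s[[nm]]
    sp$r <- model$r[[nm]]
    species[[nm]] <- sp
  }
  cfg <- list(
    components = as.list(model$components),
    mode = model$mode,
    temperature = model$temperature,
    component_properties = stats::setNames(lapply(model$components, function(cn)
      list(s = model$comp_s[[cn]], r = model$comp_r[[cn]])), model$components),
    species = species
  )
  if (!is.null(model$microscopic)) cfg$microscopic <- model$microscopic
  txt <- yaml::as.yaml(cfg, precision = 17)
  writeLines(txt, path)
  invisible(path)
}

#' Read and write experiment data files
#'
#' Experiments are stored as tab-separated text: comment lines starting
#' with `#` carry a typed header (`technique`, `name`, `weight`,
#' `subgroup`, `local <name>: <value>` declarations and, for ITC, a
#' `protocol <field>: <value>` block), followed by a column header and
#' one observation per row. Composition columns are `tot.<component>` in
#' molar; every file must have `y` and `sigma` columns. Values are
#' written with 17 significant digits, so write/read round trips are
#' lossless.
#'
#' @param path file path.
#' @param exp a [experiment()].
#' @return `read_experiment` returns a `gmma_experiment`;
#'   `write_experiment` its path, invisibly.
#' @export
read_experiment <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(); locals <- list(); proto <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(local|protocol)?\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) < 4) next
    kind <- m[2]; key <- trimws(m[3]); val <- trimws(m[4])
    if (kind == "local") {
      num <- suppressWarnings(as.numeric(val))
      locals[[key]] <- if (is.na(num)) val else num
    } else if (kind == "protocol") {
      proto[[key]] <- val
    } else {
      meta[[key]] <- val
    }
  }
  if (is.null(meta$technique)) stop("experiment file lacks a '# technique:' header")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  if (!"y" %in% names(tab)) stop("experiment file lacks the 'y' column")
  if (!"sigma" %in% names(tab)) stop("experiment file lacks the 'sigma' column")
  for (cl in names(tab)) {
    if (!is.numeric(tab[[cl]])) stop("malformed number in column '", cl, "'")
  }
  tech <- meta$technique
  protocol <- NULL
  design <- NULL
  if (tech == "itc") {
    if (!"inj_volume" %in% names(tab)) stop("ITC file lacks the 'inj_volume' column")
    cellv <- as.numeric(proto$cell_volume)
    temp <- if (is.null(proto$temperature)) 298.15 else as.numeric(proto$temperature)
    cell_keys <- grep("^cell\\.", names(proto), value = TRUE)
    syr_keys <- grep("^syringe\\.", names(proto), value = TRUE)
    cell <- stats::setNames(as.numeric(unlist(proto[cell_keys])),
                            sub("^cell\\.", "", cell_keys))
    syr <- stats::setNames(as.numeric(unlist(proto[syr_keys])),
                           sub("^syringe\\.", "", syr_keys))
    protocol <- itc_protocol(cell_volume = cellv, cell = cell, syringe = syr,
                             injection_volumes = tab$inj_volume,
                             temperature = temp,
                             injectant = proto$injectant)
  } else {
    design <- tab[, grep("^tot\\.", names(tab)), drop = FALSE]
  }
  experiment(technique = tech, design = design, y = tab$y, sigma = tab$sigma,
             locals = locals,
             weight = if (is.null(meta$weight)) 1 else as.numeric(meta$weight),
             name = if (is.null(meta$name)) tech else meta$name,
             subgroup = meta$subgroup, protocol = protocol)
}

#' @rdname read_experiment
#' @export
write_experiment <- function(exp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# gmma experiment v1")
  w("# technique: ", exp$technique)
  w("# name: ", exp$name)
  w("# weight: ", fmt_num(exp$weight))
  if (!is.null(exp$subgroup)) w("# subgroup: ", exp$subgroup)
  for (nm in names(exp$locals)) {
    v <- exp$locals[[nm]]
    if (is.numeric(v) && length(v) == 1) {
      w("# local ", nm, ": ", fmt_num(v))
    } else if (is.character(v) && length(v) == 1) {
      w("# local ", nm, ": ", v)
    }
  }
  if (exp$technique == "itc") {
    p <- exp$protocol
    w("# protocol cell_volume: ", fmt_num(p$cell_volume))
    w("# protocol temperature: ", fmt_num(p$temperature))
    w("# protocol injectant: ", p$injectant)
    for (cn in names(p$cell)) w("# protocol cell.", cn, ": ", fmt_num(p$cell[[cn]]))
    for (cn in names(p$syringe)) w("# protocol syringe.", cn, ": ", fmt_num(p$syringe[[cn]]))
    tab <- data.frame(inj_volume = p$injection_volumes, y = exp$y,
                      sigma = exp$sigma)
  } else {
    tab <- cbind(exp$design, data.frame(y = exp$y, sigma = exp$sigma))
  }
  w(paste(names(tab), collapse = "\t"))
  for (i in seq_len(nrow(tab))) {
    w(paste(fmt_num(as.numeric(tab[i, ])), collapse = "\t"))
  }
  invisible(path)
}

#' Read a fit-session configuration
#'
#' A session file is a YAML document tying a model file to experiment
#' files with weights and subgroups, optional parameter overrides
#' (value/fixed/bounds/links), and an optimizer block. Paths are
#' resolved relative to the session file.
#'
#' @param path session YAML path.
#' @return list with `model`, `experiments`, `params`, `optimizer`,
#'   `output`, `seed`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  rel <- function(p) if (file.exists(p)) p else file.path(dir, p)
  mpath <- rel(cfg$model)
  if (!file.exists(mpath)) stop("model file not found: ", cfg$model)
  model <- read_model(mpath)
  experiments <- lapply(cfg$experiments, function(e) {
    epath <- rel(e$file)
    if (!file.exists(epath)) stop("experiment file not found: ", e$file)
    ex <- read_experiment(epath)
    if (!is.null(e$weight)) ex$weight <- e$weight
    if (!is.null(e$subgroup)) ex$subgroup <- e$subgroup
    ex
  })
  params <- default_parameters(model, experiments)
  for (ov in cfg$parameters) {
    i <- match(ov$name, params$name)
    if (is.na(i)) stop("parameter override for unknown parameter: ", ov$name)
    if (!is.null(ov$value)) params$value[i] <- ov$value
    if (!is.null(ov$free)) params$free[i] <- ov$free
    if (!is.null(ov$lower)) params$lower[i] <- ov$lower
    if (!is.null(ov$upper)) params$upper[i] <- ov$upper
    if (!is.null(ov$link)) params$link[i] <- ov$link
  }
  list(model = model, experiments = experiments, params = params,
       optimizer = cfg$optimizer, output = cfg$output, seed = cfg$seed)
}
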