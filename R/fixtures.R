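#' Bundled synthetic two-site GMMA demo suite
#'
#' Generates a complete synthetic global multi-method study of a
#' two-site system A + B = AB = ABB (component A carries two sites for
#' B): 11 data sets across four techniques — one SPR solution-competition
#' isotherm, four ITC titrations at different cell concentrations, five
#' sedimentation-velocity s_w isotherms (a 1:2 and a 1:1 dilution series
#' and three titration series at fixed A), and one fluorescence
#' anisotropy titration of a labeled B probe. Noise is Gaussian at 1
#' percent of each data set's clean signal range; everything is
#' deterministic under the seed. The generating ("truth") parameters are
#' returned alongside, so simulate-and-refit studies can score parameter
#' recovery.
#'
#' @param seed integer seed.
#' @param noise_fraction Gaussian noise as a fraction of each clean
#'   signal range (default 0.01).
#' @param dir optional directory; when given, the model, the 11
#'   experiment files and a session file are written there.
#' @return list with `model` (truth [binding_model()]), `experiments`
#'   (list of 11), `params` (the fit's [parameter_table()] with free
#'   global parameters started at perturbed values), `truth` (named
#'   vector of the generating values of the free parameters), and
#'   `files` (paths, when `dir` was given).
#' @export
make_fixture_suite <- function(seed = 42, noise_fraction = 0.01, dir = NULL) {
  ## truth: K1 = 10^6.5 /M (Kd 0.32 uM), K2 = 10^5.5 /M (Kd 3.2 uM);
  ## step enthalpies -8 and -12 kcal/mol (cumulative ABB: -20)
  model <- binding_model(
    components = c("A", "B"),
    species = list(
      AB = list(stoich = c(A = 1, B = 1), log10beta = 6.5, dH = -8,
                s = 4.1, r = 0.18),
      ABB = list(stoich = c(A = 1, B = 2), log10beta = 12.0, dH = -20,
                 s = 5.6, r = 0.22)
    ),
    component_properties = list(A = list(s = 2.6, r = 0),
                                B = list(s = 2.3, r = 0.06)),
    temperature = 298.15
  )

  exps <- list()
  sd_seed <- function(k) (seed * 97 + k) %% .Machine$integer.max

  ## 1 SPR solution-competition isotherm: surface reads free B; mixtures
  ## at fixed B with increasing A deplete free B
  spr_design <- data.frame(
    tot.A = c(0, 10^seq(-7.5, -4.5, length.out = 11)),
    tot.B = 1e-6)
  exps$spr1 <- simulate_experiment(
    model, "spr_competition", spr_design,
    locals = list(analyte = "B", rmax = 500, kd_surf = 5e-7, baseline = 0),
    sigma_fraction = noise_fraction, seed = sd_seed(1),
    name = "spr1", subgroup = "spr")

  ## 4 ITC titrations, B into A, at different cell concentrations
  cellA <- c(5e-6, 1e-5, 2e-5, 4e-5)
  for (k in seq_along(cellA)) {
    proto <- itc_protocol(
      cell_volume = 1.4e-3,
      cell = c(A = cellA[k], B = 0),
      syringe = c(A = 0, B = 25 * cellA[k]),
      injection_volumes = rep(8e-6, 18),
      temperature = 298.15, injectant = "B")
    exps[[paste0("itc", k)]] <- simulate_experiment(
      model, "itc", proto, locals = list(),
      sigma_fraction = noise_fraction, seed = sd_seed(1 + k),
      name = paste0("itc", k), subgroup = "itc")
  }

  ## 5 SV s_w isotherms: two dilution series (fixed molar ratio) and
  ## three titrations of B at fixed A
  sv_locals <- list(eps.A = 1.0, eps.B = 0.8, pathlength = 1.2)
  dil12 <- data.frame(tot.A = 10^seq(-7, -4.7, length.out = 10))
  dil12$tot.B <- 2 * dil12$tot.A
  dil11 <- data.frame(tot.A = 10^seq(-7, -4.7, length.out = 10))
  dil11$tot.B <- dil11$tot.A
  sv_designs <- list(sv_dil12 = dil12, sv_dil11 = dil11)
  fixedA <- c(1e-6, 3e-6, 1e-5)
  for (k in seq_along(fixedA)) {
    sv_designs[[paste0("sv_titr", k)]] <- data.frame(
      tot.A = fixedA[k],
      tot.B = 10^seq(-7.3, -4.3, length.out = 10))
  }
  for (k in seq_along(sv_designs)) {
    nm <- names(sv_designs)[k]
    exps[[nm]] <- simulate_experiment(
      model, "sw", sv_designs[[k]], locals = sv_locals,
      sigma_fraction = noise_fraction, seed = sd_seed(10 + k),
      name = nm, subgroup = "sv")
  }

  ## 1 anisotropy titration of the labeled B probe with A
  fa_design <- data.frame(
    tot.A = c(0, 10^seq(-7.5, -4.5, length.out = 11)),
    tot.B = 2e-7)
  exps$fa1 <- simulate_experiment(
    model, "anisotropy", fa_design, locals = list(probe = "B"),
    sigma_fraction = noise_fraction, seed = sd_seed(20),
    name = "fa1", subgroup = "fa")

  ## fit parameter table: the six global parameters the suite can inform,
  ## started away from the truth; all locals fixed at their true values
  params <- default_parameters(model, exps)
  free_set <- c("log10beta.AB", "log10beta.ABB", "dH.AB", "dH.ABB",
                "s.AB", "s.ABB")
  params$free <- params$name %in% free_set
  truth <- stats::setNames(params$value[match(free_set, params$name)], free_set)
  start <- truth + c(0.35, -0.4, 1.5, -2.0, 0.25, -0.3)
  params$value[match(free_set, params$name)] <- start

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mpath <- file.path(dir, "model.yaml")
    write_model(model, mpath)
    epaths <- character(0)
    for (nm in names(exps)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write_experiment(exps[[nm]], p)
      epaths <- c(epaths, p)
    }
    session <- list(
      model = "model.yaml",
      experiments = lapply(names(exps), function(nm)
        list(file = paste0(nm, ".tsv"), weight = 1,
             subgroup = exps[[nm]]$subgroup)),
      parameters = lapply(free_set, function(p)
        list(name = p, value = unname(start[p]), free = TRUE)),
      optimizer = list(method = "marquardt"),
      seed = seed)
    spath <- file.path(dir, "session.yaml")
    writeLines(yaml::as.yaml(session, precision = 17), spath)
    files <- list(model = mpath, experiments = epaths, session = spath)
  }

  list(model = model, experiments = unname(exps), params = params,
       truth = truth, start = stats::setNames(start, free_set),
       noise_fraction = noise_fraction, seed = seed, files = files)
}
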