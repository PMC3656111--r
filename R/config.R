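# Configuration handling and the shipped MscL model library. All physical
# constants live in the packaged YAML defaults (inst/extdata/mscl_params.yaml)
# or in a user-supplied config; library code carries no hard-wired values.

#' Load a model configuration
#'
#' Reads a YAML (or JSON) configuration; with `path = NULL` the packaged
#' MscL defaults are returned. The configuration carries the bilayer
#' material constants, the cylinder-model radii and hydrophobic
#' thicknesses of the closed and open states, the lipid tail-length
#' calibration and the boundary-shape amplitudes of the shipped channel
#' models; every numeric key is unit-suffixed.
#'
#' @param path path to a YAML/JSON config, or NULL for the defaults.
#' @return a named list.
#' @export
load_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mscl_params.yaml", package = "memdef")
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("[.]json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
  cfg$config_path <- path
  cfg
}

validate_config <- function(cfg) {
  need <- function(x, name) {
    if (is.null(x) || !is.numeric(x) || !is.finite(x))
      stop("config error: missing or non-numeric field '", name, "'")
    x
  }
  pos <- function(x, name) {
    if (need(x, name) <= 0) stop("config error: '", name, "' must be > 0")
    x
  }
  pos(cfg$material$Kb_kt, "material.Kb_kt")
  pos(cfg$material$Kt_kt_per_nm2, "material.Kt_kt_per_nm2")
  if (need(cfg$material$tau_kt_per_nm2, "material.tau_kt_per_nm2") < 0)
    stop("config error: 'material.tau_kt_per_nm2' must be >= 0")
  pos(cfg$states$r_closed_nm, "states.r_closed_nm")
  pos(cfg$states$r_open_nm, "states.r_open_nm")
  pos(cfg$thickness$W_equal_nm, "thickness.W_equal_nm")
  pos(cfg$tail_map$slope_nm_per_carbon, "tail_map.slope_nm_per_carbon")
  invisible(cfg)
}

#' Material parameters from a configuration
#'
#' @param cfg a configuration list from [load_params()].
#' @param n_carbons PC tail length setting the bilayer hydrophobic
#'   thickness; defaults to the config's reference lipid.
#' @param tau tension override (kBT/nm^2), or NULL for the config value.
#' @return a [material_params()].
#' @export
params_from_config <- function(cfg, n_carbons = NULL, tau = NULL) {
  if (is.null(n_carbons)) n_carbons <- cfg$reference_lipid_n_carbons
  th <- tail_to_thickness(n_carbons, cfg$tail_map$slope_nm_per_carbon,
                          cfg$tail_map$intercept_nm)
  material_params(Kb = cfg$material$Kb_kt,
                  Kt = cfg$material$Kt_kt_per_nm2,
                  tau = if (is.null(tau)) cfg$material$tau_kt_per_nm2 else tau,
                  leaflet_l = th / 2)
}

#' Shipped MscL channel-state models
#'
#' Builds one conformational state of the shipped structural models of
#' MscL: the cylinder reference, polygonal cross sections (tetragonal and
#' pentagonal, truncated regular-polygon Fourier series), and clover-leaf
#' cross sections (pentameric and hexameric single-harmonic lobes), each
#' normalized to the cross-sectional area (or, on request, the
#' circumference) of the cylinder model in the corresponding state.
#'
#' @param model one of `"cylinder"`, `"tetragonal"`, `"pentagonal"`,
#'   `"cloverleaf_pentamer"`, `"cloverleaf_hexamer"`.
#' @param state `"closed"` or `"open"`.
#' @param cfg configuration list from [load_params()].
#' @param thickness_mode `"equal"` (one protein thickness for all states)
#'   or `"distinct"` (state-specific thicknesses).
#' @param reference `"area"` or `"circumference"` matching convention.
#' @param systematic use the equal-perturbation-amplitude model-scan
#'   amplitudes instead of the structure-fitted clover-leaf amplitudes.
#' @return a [channel_state()].
#' @export
mscl_state <- function(model = c("cylinder", "tetragonal", "pentagonal",
                                 "cloverleaf_pentamer", "cloverleaf_hexamer"),
                       state = c("closed", "open"), cfg = load_params(),
                       thickness_mode = c("equal", "distinct"),
                       reference = c("area", "circumference"),
                       systematic = FALSE) {
  model <- match.arg(model)
  state <- match.arg(state)
  thickness_mode <- match.arg(thickness_mode)
  reference <- match.arg(reference)
  r_cyl <- if (state == "closed") cfg$states$r_closed_nm else cfg$states$r_open_nm
  mm <- cfg$shapes$polygon_max_multiple
  clv <- cfg$shapes$cloverleaf
  sys_eps <- function(st) {
    e <- cfg$shapes$systematic$closed_eps
    if (st == "open") e * cfg$states$r_closed_nm / cfg$states$r_open_nm else e
  }
  shape <- switch(model,
    cylinder = make_circle(r_cyl),
    tetragonal = make_ngon(4L, mm),
    pentagonal = make_ngon(5L, mm),
    cloverleaf_pentamer = make_cloverleaf(5L,
      if (systematic) sys_eps(state)
      else if (state == "closed") clv$closed_pentamer_eps else clv$open_pentamer_eps),
    cloverleaf_hexamer = make_cloverleaf(6L,
      if (systematic) sys_eps(state) else clv$hexamer_eps))
  W <- if (thickness_mode == "equal") cfg$thickness$W_equal_nm
       else if (state == "closed") cfg$thickness$W_closed_nm
       else cfg$thickness$W_open_nm
  tgt_area <- pi * r_cyl^2
  if (reference == "area")
    channel_state(shape, W = W, area = tgt_area,
                  label = paste(model, state, sep = "/"))
  else
    channel_state(shape, W = W, circumference = 2 * pi * r_cyl,
                  label = paste(model, state, sep = "/"))
}

#' Shipped MscL gating pairs
#'
#' Closed/open [gating_pair()]s for the shipped structural models,
#' including the two hybrid transitions between boundary-curve families.
#'
#' @param model one of the [mscl_state()] models or the hybrids
#'   `"pentagon_to_cloverleaf"` (closed pentagon, open pentameric
#'   clover-leaf) and `"cloverleaf_to_pentagon"` (the reverse).
#' @inheritParams mscl_state
#' @return a [gating_pair()].
#' @export
mscl_pair <- function(model = c("cylinder", "tetragonal", "pentagonal",
                                "cloverleaf_pentamer", "cloverleaf_hexamer",
                                "pentagon_to_cloverleaf", "cloverleaf_to_pentagon"),
                      cfg = load_params(),
                      thickness_mode = c("equal", "distinct"),
                      reference = c("area", "circumference"),
                      systematic = FALSE) {
  model <- match.arg(model)
  cl_model <- switch(model,
    pentagon_to_cloverleaf = "pentagonal",
    cloverleaf_to_pentagon = "cloverleaf_pentamer",
    model)
  op_model <- switch(model,
    pentagon_to_cloverleaf = "cloverleaf_pentamer",
    cloverleaf_to_pentagon = "pentagonal",
    model)
  gating_pair(
    mscl_state(cl_model, "closed", cfg, thickness_mode, reference, systematic),
    mscl_state(op_model, "open", cfg, thickness_mode, reference, systematic))
}
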