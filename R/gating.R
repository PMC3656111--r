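#' Channel conformational state
#'
#' Bundles the cross-section shape, the mismatch source and the size
#' normalization of one conformational state of a membrane channel.
#' Exactly one of `U` (explicit half-mismatch, nm) or `W` (protein
#' hydrophobic thickness, nm, from which `U = (W - 2l)/2` at solve time)
#' must be given; the normalization target (`area` in nm^2 or
#' `circumference` in nm) is applied to the shape before solving.
#'
#' @param shape a [boundary_shape()].
#' @param U explicit half hydrophobic mismatch (nm), or NULL.
#' @param W protein hydrophobic thickness (nm), or NULL.
#' @param Uprime contact slope (default 0).
#' @param area target cross-sectional area (nm^2), or NULL.
#' @param circumference target circumference (nm), or NULL.
#' @param label optional state label.
#' @return an object of class `channel_state`.
#' @export
channel_state <- function(shape, U = NULL, W = NULL, Uprime = 0,
                          area = NULL, circumference = NULL, label = "") {
  stopifnot(inherits(shape, "boundary_shape"))
  if (is.null(U) == is.null(W))
    stop("specify exactly one mismatch source: U or W")
  if (!is.null(area) && !is.null(circumference))
    stop("specify at most one normalization target: area or circumference")
  structure(list(shape = shape, U = U, W = W, Uprime = Uprime,
                 area = area, circumference = circumference, label = label),
            class = "channel_state")
}

# Shape after applying the state's normalization target.
resolved_shape <- function(state) {
  sh <- state$shape
  if (!is.null(state$area)) sh <- scale_to_area(sh, state$area)
  if (!is.null(state$circumference)) sh <- scale_to_circumference(sh, state$circumference)
  sh
}

# Boundary data of a state at given material params (resolves W -> U).
state_bdata <- function(state, params) {
  U <- if (!is.null(state$U)) state$U else (state$W - 2 * params$leaflet_l) / 2
  boundary_data(U, state$Uprime)
}

#' Membrane deformation energy of a channel state
#'
#' Normalizes the state's shape, resolves its mismatch against the bilayer
#' thickness in `params`, solves the elastic problem and returns the
#' closed-form energy breakdown.
#'
#' @param state a [channel_state()].
#' @param params a [material_params()].
#' @param reference comparison convention for the cylinder reference, see
#'   [shape_decomposition()].
#' @return an `energy_breakdown`.
#' @export
state_energy <- function(state, params, reference = c("area", "circumference")) {
  shape_decomposition(resolved_shape(state), state_bdata(state, params),
                      params, match.arg(reference))
}

#' Membrane contribution to the gating energy
#'
#' Difference in thickness-deformation energy between the open and closed
#' conformations under identical material parameters,
#' `dG = G_def(open) - G_def(closed)`. Thickness conventions are carried by
#' the states themselves: give both states the same `W` (or `U`) for the
#' equal-thickness comparison, or distinct values for the
#' distinct-thickness model.
#'
#' @param closed,open [channel_state()] objects.
#' @param params a [material_params()].
#' @return gating energy in kBT.
#' @export
gating_energy <- function(closed, open, params) {
  state_energy(open, params)$g_total - state_energy(closed, params)$g_total
}

#' Two-state Boltzmann opening probability
#'
#' \deqn{P_{open} = \frac{1}{1 + e^{\beta(\Delta G - \tau \Delta A)}}}
#' with all energies in kBT (beta = 1). The exponent is clamped so the
#' limits 0 and 1 are returned without overflow.
#'
#' @param dG_total total open-closed free energy difference (kBT).
#' @param tau membrane tension (kBT/nm^2).
#' @param dA open-closed in-plane area difference (nm^2), >= 0.
#' @return opening probability in (0, 1), vectorized over `tau`.
#' @export
open_probability <- function(dG_total, tau, dA) {
  if (any(dA < 0)) stop("dA must be >= 0")
  # clamp far enough out that exp() saturates to Inf/0 and the probability
  # reaches its exact 0/1 limits without intermediate overflow surprises
  x <- pmin(pmax(dG_total - tau * dA, -750), 750)
  1 / (1 + exp(x))
}

#' Closed/open gating pair
#'
#' @param closed,open [channel_state()] objects.
#' @param dA in-plane area difference (nm^2); defaults to the difference of
#'   the normalized shape areas. A warning is given when `dA <= 0` (the
#'   standard mechanosensitive setup opens to a larger area).
#' @return an object of class `gating_pair`.
#' @export
gating_pair <- function(closed, open, dA = NULL) {
  stopifnot(inherits(closed, "channel_state"), inherits(open, "channel_state"))
  if (is.null(dA))
    dA <- shape_area(resolved_shape(open)) - shape_area(resolved_shape(closed))
  if (dA <= 0)
    warning("dA <= 0: tension will not favor the open state")
  structure(list(closed = closed, open = open, dA = dA), class = "gating_pair")
}

#' @export
print.gating_pair <- function(x, ...) {
  cat(sprintf("<gating_pair> dA = %.4f nm^2\n", x$dA))
  invisible(x)
}

# Membrane gating energy of a pair at tension tau.
pair_dG <- function(pair, params, tau) {
  p <- params; p$tau <- tau
  gating_energy(pair$closed, pair$open, p)
}

#' Gating curve P_open(tau)
#'
#' In `"tension_dependent"` mode (default) the membrane deformation energy
#' difference is recomputed at every tension of the grid before applying
#' the Boltzmann factor; in `"fixed_dG"` mode it is evaluated once at zero
#' tension.
#'
#' @param pair a [gating_pair()].
#' @param params a [material_params()] (its `tau` is overridden by the grid).
#' @param tau_grid nonnegative ascending tensions (kBT/nm^2).
#' @param mode `"tension_dependent"` or `"fixed_dG"`.
#' @return data.frame with columns `tau_kt_per_nm2`, `dg_mem_kt`, `p_open`.
#' @export
gating_curve <- function(pair, params, tau_grid,
                         mode = c("tension_dependent", "fixed_dG")) {
  mode <- match.arg(mode)
  tau_grid <- as.numeric(tau_grid)
  if (any(tau_grid < 0) || is.unsorted(tau_grid))
    stop("tau_grid must be nonnegative and ascending")
  dg <- if (mode == "fixed_dG") rep(pair_dG(pair, params, 0), length(tau_grid))
        else vapply(tau_grid, function(t) pair_dG(pair, params, t), numeric(1))
  data.frame(tau_kt_per_nm2 = tau_grid, dg_mem_kt = dg,
             p_open = open_probability(dg, tau_grid, pair$dA))
}

#' Critical gating tension
#'
#' Tension at which the opening probability crosses one-half, i.e. the
#' root of \eqn{\Delta G(\tau) - \tau \Delta A = 0}. In
#' `"tension_dependent"` mode the root is self-consistent (the membrane
#' energy difference is re-evaluated at each candidate tension).
#'
#' @param pair a [gating_pair()] with `dA > 0`.
#' @param params a [material_params()].
#' @param mode `"tension_dependent"` or `"fixed_dG"`.
#' @param tau_max upper end of the search bracket (kBT/nm^2).
#' @param tol absolute tolerance on the root (kBT/nm^2).
#' @return gating tension tau* (kBT/nm^2).
#' @export
gating_tension <- function(pair, params, mode = c("tension_dependent", "fixed_dG"),
                           tau_max = 8, tol = 1e-9) {
  mode <- match.arg(mode)
  if (pair$dA <= 0) stop("gating tension requires dA > 0")
  f <- if (mode == "fixed_dG") {
    dg0 <- pair_dG(pair, params, 0)
    function(tau) dg0 - tau * pair$dA
  } else {
    function(tau) pair_dG(pair, params, tau) - tau * pair$dA
  }
  f0 <- f(0); f1 <- f(tau_max)
  if (sign(f0) == sign(f1))
    stop(sprintf(paste("no gating-tension root in [0, %g] kBT/nm^2:",
                       "dG - tau*dA = %.4g at 0 and %.4g at the bracket end"),
                 tau_max, f0, f1))
  stats::uniroot(f, c(0, tau_max), tol = tol)$root
}

#' PC lipid tail length to bilayer hydrophobic thickness
#'
#' Linear interpolation `2l = slope * n_carbons + intercept` calibrated for
#' fluid phosphatidylcholine bilayers. The shipped defaults use the
#' classic fluid-chain estimate of 0.175 nm of bilayer hydrophobic
#' thickness per tail carbon beyond the first
#' (`2l = 0.175 (n - 1)` nm).
#'
#' @param n_carbons acyl tail length (number of carbons).
#' @param slope nm of bilayer hydrophobic thickness per carbon.
#' @param intercept nm.
#' @return bilayer hydrophobic thickness 2l (nm), vectorized.
#' @export
tail_to_thickness <- function(n_carbons, slope = 0.175, intercept = -0.175) {
  out_of_range <- n_carbons < 8 | n_carbons > 24
  if (any(out_of_range))
    warning("tail length outside the calibrated PC8-PC24 range; extrapolating")
  slope * n_carbons + intercept
}

#' Inverse of [tail_to_thickness()]
#'
#' @param thickness bilayer hydrophobic thickness 2l (nm).
#' @inheritParams tail_to_thickness
#' @return (fractional) tail carbon number.
#' @export
thickness_to_tail <- function(thickness, slope = 0.175, intercept = -0.175) {
  (thickness - intercept) / slope
}

#' Energy versus lipid tail length
#'
#' Recomputes the state energy (single state) or gating energy (pair) over
#' a series of PC tail lengths, updating the bilayer thickness (and hence
#' the hydrophobic mismatch of `W`-specified states) at each step.
#'
#' @param states a [channel_state()] or a [gating_pair()].
#' @param params_base a [material_params()]; `leaflet_l` is overridden per
#'   tail length.
#' @param tail_lengths integer vector of tail carbon numbers.
#' @param slope,intercept calibration of [tail_to_thickness()].
#' @return data.frame with columns `n_carbons`, `thickness_nm`, and
#'   `g_kt` (single state) or `dg_kt` (pair).
#' @export
energy_vs_tail_length <- function(states, params_base, tail_lengths,
                                  slope = 0.175, intercept = -0.175) {
  tail_lengths <- as.integer(tail_lengths)
  th <- tail_to_thickness(tail_lengths, slope, intercept)
  vals <- vapply(seq_along(tail_lengths), function(i) {
    p <- params_base; p$leaflet_l <- th[i] / 2
    if (inherits(states, "gating_pair"))
      gating_energy(states$closed, states$open, p)
    else state_energy(states, p)$g_total
  }, numeric(1))
  out <- data.frame(n_carbons = tail_lengths, thickness_nm = th)
  if (inherits(states, "gating_pair")) out$dg_kt <- vals else out$g_kt <- vals
  out
}

#' Tension unit conversion
#'
#' Converts membrane tension between the model's internal kBT/nm^2 and
#' mN/m at temperature `T_K` (default 298 K): 1 kBT/nm^2 = kB*T * 1e21 mN/m.
#'
#' @param tau tension value(s).
#' @param from,to `"kt_per_nm2"` or `"mN_per_m"`.
#' @param T_K absolute temperature (K).
#' @return converted tension.
#' @export
convert_tension <- function(tau, from = "kt_per_nm2", to = "mN_per_m", T_K = 298) {
  from <- match.arg(from, c("kt_per_nm2", "mN_per_m"))
  to <- match.arg(to, c("kt_per_nm2", "mN_per_m"))
  fac <- 1.380649e-23 * T_K * 1e21   # mN/m per kBT/nm^2
  if (from == to) tau
  else if (from == "kt_per_nm2") tau * fac
  else tau / fac
}
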