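# Shared fixtures: one standard bilayer parameterization and boundary data,
# matching the shipped MscL defaults at a PC18 bilayer.
std_params <- function(tau = 0) material_params(Kb = 20, Kt = 60, tau = tau,
                                                leaflet_l = 1.4875)
std_bd <- function(U = -0.525, Uprime = 0) boundary_data(U, Uprime)

# brute-force trapezoid quadrature of (1/2) integral r^2 dtheta
area_quadrature <- function(shape, n = 20000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  sum(radius_profile(shape, th)^2) * (2 * pi / n) / 2
}

scale_harmonics <- function(shape, f) {
  shape$harmonics$c <- shape$harmonics$c * f
  shape$harmonics$s <- shape$harmonics$s * f
  shape
}
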