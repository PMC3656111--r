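#' Boundary shapes of membrane inclusions
#'
#' A `boundary_shape` describes the transmembrane cross-section outline of a
#' membrane inclusion as a star-shaped curve in polar coordinates,
#' \deqn{r(\theta) = R_0\,[1 + \epsilon(\theta)], \qquad
#'   \epsilon(\theta) = \sum_{n\ge 1} (c_n \cos n\theta + s_n \sin n\theta),}
#' where `R0` is the reference radius (nm) and the dimensionless harmonics
#' `(n, c_n, s_n)` encode the relative radial deviation from the circle.
#' Any constant (n = 0) content of the deviation is absorbed into `R0`, so
#' the circle of radius `R0` is the reference state of every shape. The
#' elastic solver treats `eps` perturbatively to leading order; shapes whose
#' maximum |eps| exceeds `validity_threshold` are accepted but flagged with
#' a warning.
#'
#' @param R0 reference radius in nm (> 0).
#' @param harmonics data.frame (or NULL) with columns `n` (distinct positive
#'   integers), `c` (cosine coefficient) and `s` (sine coefficient).
#' @param family one of `"circle"`, `"ngon"`, `"cloverleaf"`, `"custom"`.
#' @param symmetry_order rotational symmetry order, or NA.
#' @param meta optional list of provenance metadata.
#' @param validity_threshold maximum |eps| beyond which the leading-order
#'   treatment is flagged (default 0.35).
#' @return an object of class `boundary_shape`.
#' @export
boundary_shape <- function(R0, harmonics = NULL, family = "custom",
                           symmetry_order = NA_integer_, meta = list(),
                           validity_threshold = 0.35) {
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("R0 must be a single positive number (nm)")
  family <- match.arg(family, c("circle", "ngon", "cloverleaf", "custom"))
  if (is.null(harmonics) || nrow(harmonics) == 0L) {
    harmonics <- data.frame(n = integer(0), c = numeric(0), s = numeric(0))
  } else {
    harmonics <- data.frame(n = as.integer(harmonics$n),
                            c = as.numeric(harmonics$c),
                            s = as.numeric(harmonics$s))
    if (any(harmonics$n < 1L)) stop("harmonic indices must be >= 1")
    if (anyDuplicated(harmonics$n)) stop("harmonic indices must be distinct")
    if (any(!is.finite(harmonics$c)) || any(!is.finite(harmonics$s)))
      stop("harmonic coefficients must be finite")
    harmonics <- harmonics[order(harmonics$n), , drop = FALSE]
    rownames(harmonics) <- NULL
  }
  obj <- structure(list(R0 = R0, harmonics = harmonics, family = family,
                        symmetry_order = symmetry_order, meta = meta),
                   class = "boundary_shape")
  th <- seq(0, 2 * pi, length.out = 2048L)
  eps <- eps_profile(obj, th)
  if (any(1 + eps <= 0))
    stop("invalid shape: r(theta) = R0*(1 + eps) must stay positive")
  if (max(abs(eps)) > validity_threshold)
    warning(sprintf(paste("max |eps| = %.3f exceeds the leading-order",
                          "validity threshold %.2f; energies are only",
                          "perturbatively accurate"),
                    max(abs(eps)), validity_threshold))
  obj
}

#' @export
print.boundary_shape <- function(x, ...) {
  cat(sprintf("<boundary_shape: %s>  R0 = %.4f nm", x$family, x$R0))
  if (!is.na(x$symmetry_order)) cat(sprintf(", symmetry order %d", x$symmetry_order))
  cat("\n")
  if (nrow(x$harmonics)) {
    cat("  harmonics:\n")
    for (i in seq_len(nrow(x$harmonics)))
      cat(sprintf("    n = %2d   c = %+.5f   s = %+.5f\n",
                  x$harmonics$n[i], x$harmonics$c[i], x$harmonics$s[i]))
  } else cat("  (circular: no harmonics)\n")
  cat(sprintf("  area = %.5f nm^2, circumference = %.5f nm\n",
              shape_area(x), shape_circumference(x)))
  invisible(x)
}

#' Relative radial deviation eps(theta)
#'
#' @param shape a [boundary_shape()].
#' @param theta numeric vector of polar angles (rad).
#' @return numeric vector of the dimensionless deviation.
#' @export
eps_profile <- function(shape, theta) {
  out <- numeric(length(theta))
  h <- shape$harmonics
  for (i in seq_len(nrow(h)))
    out <- out + h$c[i] * cos(h$n[i] * theta) + h$s[i] * sin(h$n[i] * theta)
  out
}

#' Boundary radius r(theta) = R0 (1 + eps(theta))
#'
#' @inheritParams eps_profile
#' @return numeric vector of radii (nm).
#' @export
radius_profile <- function(shape, theta) {
  shape$R0 * (1 + eps_profile(shape, theta))
}

#' Circular inclusion cross section
#'
#' @param R radius in nm (> 0).
#' @return a [boundary_shape()] of family `"circle"`.
#' @export
make_circle <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a single positive radius (nm)")
  boundary_shape(R, family = "circle", symmetry_order = NA_integer_)
}

#' Clover-leaf inclusion cross section
#'
#' A single cosine harmonic at the oligomeric symmetry order,
#' \eqn{r(\theta) = R0 (1 + \epsilon \cos s\theta)}: the propeller-like
#' cross sections of pentameric and hexameric channel models.
#'
#' @param s symmetry order (integer >= 2).
#' @param eps dimensionless lobe amplitude, |eps| < 1.
#' @param R0 reference radius (nm), default 1 (rescale with
#'   [scale_to_area()]).
#' @return a [boundary_shape()] of family `"cloverleaf"`.
#' @export
make_cloverleaf <- function(s, eps, R0 = 1) {
  s <- as.integer(s)
  if (is.na(s) || s < 2L) stop("clover-leaf symmetry order s must be >= 2")
  if (!is.finite(eps) || abs(eps) >= 1)
    stop("|eps| must be < 1: the boundary radius would touch zero")
  if (eps == 0) return(make_circle(R0))
  boundary_shape(R0, data.frame(n = s, c = eps, s = 0),
                 family = "cloverleaf", symmetry_order = s)
}

# Fourier cosine coefficients of the exact regular-P-gon radial function
# r_gon(theta) = cos(pi/P) / cos((theta mod 2pi/P) - pi/P)  (unit circumradius,
# vertices at theta = 0 mod 2pi/P). Returns a0 (mean) and the coefficients
# a_{kP} of cos(kP theta) for k = 1..kmax, by adaptive quadrature over one
# period (the integrand is analytic inside each period).
ngon_fourier <- function(P, kmax) {
  period <- 2 * pi / P
  f <- function(th) cos(pi / P) / cos(th - pi / P)
  a0 <- stats::integrate(f, 0, period, rel.tol = 1e-12)$value / period
  ak <- vapply(seq_len(kmax), function(k) {
    g <- function(th) f(th) * cos(k * P * th)
    2 * P * stats::integrate(g, 0, period, rel.tol = 1e-12,
                             subdivisions = 400L)$value / (2 * pi)
  }, numeric(1))
  list(a0 = a0, ak = ak)
}

#' Regular polygon inclusion cross section
#'
#' Truncated Fourier representation of the radial function of a regular
#' P-gon. The exact polygon radius (unit circumradius, one vertex at
#' theta = 0) is \eqn{r_{gon}(\theta) = \cos(\pi/P)/\cos((\theta \bmod
#' 2\pi/P) - \pi/P)}; its Fourier series contains cosines only at multiples
#' of P. The constant term is absorbed into `R0` so the returned shape has
#' harmonics exactly at `n = k P`, `k = 1..max_multiple`.
#'
#' @param P number of polygon sides (integer >= 3).
#' @param max_multiple number of harmonic multiples of P retained
#'   (integer >= 1; default 3).
#' @param R0 circumradius of the underlying exact polygon (nm), default 1.
#' @return a [boundary_shape()] of family `"ngon"` with
#'   `meta$orientation = "vertex at theta = 0 (mod 2*pi/P)"`.
#' @export
make_ngon <- function(P, max_multiple = 3L, R0 = 1) {
  P <- as.integer(P)
  if (is.na(P) || P < 3L) stop("a polygon needs P >= 3 sides")
  max_multiple <- as.integer(max_multiple)
  if (is.na(max_multiple) || max_multiple < 1L) stop("max_multiple must be >= 1")
  fc <- ngon_fourier(P, max_multiple)
  boundary_shape(R0 * fc$a0,
                 data.frame(n = P * seq_len(max_multiple),
                            c = fc$ak / fc$a0, s = 0),
                 family = "ngon", symmetry_order = P,
                 meta = list(orientation = "vertex at theta = 0 (mod 2*pi/P)",
                             circumradius_nm = R0))
}

#' Enclosed area of a boundary shape
#'
#' Closed form from Parseval's identity applied to
#' \eqn{A = \frac12 \oint r^2 d\theta}:
#' \eqn{A = \pi R_0^2 [1 + \frac12 \sum_n (c_n^2 + s_n^2)]}.
#'
#' @param shape a [boundary_shape()].
#' @return area in nm^2.
#' @export
shape_area <- function(shape) {
  h <- shape$harmonics
  pi * shape$R0^2 * (1 + 0.5 * sum(h$c^2 + h$s^2))
}

#' Circumference of a boundary shape
#'
#' Adaptive quadrature of \eqn{\oint \sqrt{r^2 + (dr/d\theta)^2}\, d\theta}
#' to relative tolerance 1e-8.
#'
#' @param shape a [boundary_shape()].
#' @return circumference in nm.
#' @export
shape_circumference <- function(shape) {
  h <- shape$harmonics
  dr <- function(th) {
    out <- numeric(length(th))
    for (i in seq_len(nrow(h)))
      out <- out + h$n[i] * (-h$c[i] * sin(h$n[i] * th) + h$s[i] * cos(h$n[i] * th))
    shape$R0 * out
  }
  f <- function(th) sqrt(radius_profile(shape, th)^2 + dr(th)^2)
  stats::integrate(f, 0, 2 * pi, rel.tol = 1e-10, subdivisions = 600L)$value
}

#' Rescale a shape to a target area
#'
#' Rescales `R0` (harmonics unchanged) using the exact closed-form area of
#' the truncated Fourier curve, so that compared shapes do not pick up a
#' spurious O(eps^2) area mismatch.
#'
#' @param shape a [boundary_shape()].
#' @param A_target target area in nm^2 (> 0).
#' @return rescaled [boundary_shape()].
#' @export
scale_to_area <- function(shape, A_target) {
  if (!is.finite(A_target) || A_target <= 0) stop("A_target must be > 0")
  shape$R0 <- shape$R0 * sqrt(A_target / shape_area(shape))
  shape
}

#' Rescale a shape to a target circumference
#'
#' Circumference is homogeneous of degree 1 in `R0` at fixed harmonics, so a
#' single division suffices.
#'
#' @param shape a [boundary_shape()].
#' @param C_target target circumference in nm (> 0).
#' @return rescaled [boundary_shape()].
#' @export
scale_to_circumference <- function(shape, C_target) {
  if (!is.finite(C_target) || C_target <= 0) stop("C_target must be > 0")
  shape$R0 <- shape$R0 * C_target / shape_circumference(shape)
  shape
}

#' Rotate a shape by a common phase
#'
#' Applies \eqn{\theta \to \theta - \phi} to every harmonic. Physical
#' observables (area, circumference, deformation energy) are invariant.
#'
#' @param shape a [boundary_shape()].
#' @param phase rotation angle (rad).
#' @return rotated [boundary_shape()].
#' @export
rotate_shape <- function(shape, phase) {
  h <- shape$harmonics
  if (nrow(h)) {
    cn <- h$c * cos(h$n * phase) + h$s * sin(h$n * phase)
    sn <- -h$c * sin(h$n * phase) + h$s * cos(h$n * phase)
    shape$harmonics$c <- cn
    shape$harmonics$s <- sn
  }
  shape
}

#' Least-squares Fourier fit of sampled boundary points
#'
#' Fits \eqn{r(\theta) = a_0 + \sum_{n=1}^{n_{max}} (a_n \cos n\theta + b_n
#' \sin n\theta)} by linear least squares and converts to a
#' [boundary_shape()] with `R0 = a0` and relative harmonics `a_n/a0`,
#' `b_n/a0` (so the fitted deviation has no constant component by
#' construction).
#'
#' @param theta numeric vector of sample angles (rad).
#' @param r numeric vector of sampled radii (nm, > 0).
#' @param n_max highest harmonic fitted.
#' @param drop_tol harmonics with |c_n| and |s_n| below this are dropped
#'   from the result (default 0, keep all).
#' @return a [boundary_shape()] of family `"custom"` with fit residual RMS
#'   in `meta$fit_rms_nm`.
#' @export
fit_fourier <- function(theta, r, n_max, drop_tol = 0) {
  theta <- as.numeric(theta); r <- as.numeric(r)
  if (length(theta) != length(r)) stop("theta and r must have equal length")
  if (any(!is.finite(r)) || any(r <= 0)) stop("all radii must be positive and finite")
  n_max <- as.integer(n_max)
  if (length(theta) < 2L * n_max + 1L)
    stop("need at least 2*n_max + 1 samples for the Fourier fit")
  span <- diff(range(theta %% (2 * pi)))
  if (span < pi)
    stop("samples must span the full circle; got angular span < pi")
  X <- matrix(1, length(theta), 2L * n_max + 1L)
  for (n in seq_len(n_max)) {
    X[, 2L * n] <- cos(n * theta)
    X[, 2L * n + 1L] <- sin(n * theta)
  }
  fit <- stats::lm.fit(X, r)
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  a0 <- cf[1L]
  if (a0 <= 0) stop("fitted mean radius is non-positive; samples are degenerate")
  an <- cf[2L * seq_len(n_max)]
  bn <- cf[2L * seq_len(n_max) + 1L]
  keep <- pmax(abs(an), abs(bn)) / a0 > drop_tol
  h <- data.frame(n = seq_len(n_max)[keep], c = (an / a0)[keep], s = (bn / a0)[keep])
  rms <- sqrt(mean(fit$residuals^2))
  boundary_shape(a0, h, family = "custom",
                 meta = list(fit_rms_nm = rms, fit_n_max = n_max))
}
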