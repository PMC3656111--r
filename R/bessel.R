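#' Modified Bessel function of the second kind for complex argument
#'
#' Evaluates \eqn{K_n(z)} for integer order `n` and complex `z` with
#' `Re(z) > 0`, the regime in which the exterior Fourier-Bessel solution of
#' the thickness-deformation problem lives (the Helmholtz roots are complex
#' at physiological tensions, so base R's real-argument [besselK()] does not
#' suffice). Uses the integral representation
#' \deqn{K_n(z) = \int_0^\infty e^{-z\cosh t}\cosh(nt)\,dt,}
#' discretized by the trapezoid rule. The integrand is even in `t` and
#' decays double-exponentially, so the trapezoid rule converges at spectral
#' rate; the fixed step below gives relative errors near machine precision
#' for `|arg z| <= pi/4` and `n <= 40` (verified against the real-axis
#' [besselK()] and by the Wronskian identity in the test suite).
#'
#' @param n integer order (n >= 0).
#' @param z complex (or numeric) vector with positive real part.
#' @return complex vector of the same length as `z`.
#' @export
cbesselK <- function(n, z) {
  z <- as.complex(z)
  if (length(z) == 0L) return(complex(0))
  if (any(!is.finite(z)) || any(Re(z) <= 0))
    stop("cbesselK() requires finite z with Re(z) > 0")
  n <- as.integer(abs(n))
  rezmin <- min(Re(z))
  # upper limit: envelope exp(-Re(z)(cosh T - 1) + nT) below 1e-20
  Tmax <- 1
  while (rezmin * (cosh(Tmax) - 1) - n * Tmax < 46 && Tmax < 25) {
    Tmax <- Tmax + 0.25
  }
  h <- 0.01
  t <- seq(0, Tmax, by = h)
  w <- rep(h, length(t))
  w[1] <- h / 2
  ch <- cosh(t)
  lc <- log(cosh(n * t))
  out <- complex(length(z))
  chunk <- 512L
  for (i0 in seq(1L, length(z), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(z))
    E <- exp(-outer(z[ii], ch) + rep(lc, each = length(ii)))
    out[ii] <- drop(E %*% w)
  }
  out
}

#' First derivative of K_n
#'
#' Uses the recurrence \eqn{K_n'(z) = -(K_{n-1}(z) + K_{n+1}(z))/2}
#' (with \eqn{K_{-1} = K_1}).
#'
#' @inheritParams cbesselK
#' @return complex vector, \eqn{dK_n/dz}.
#' @export
cbesselK_d1 <- function(n, z) {
  n <- as.integer(abs(n))
  -(cbesselK(abs(n - 1L), z) + cbesselK(n + 1L, z)) / 2
}

#' Second derivative of K_n
#'
#' From applying the first-derivative recurrence twice:
#' \eqn{K_n''(z) = (K_{n-2} + 2K_n + K_{n+2})/4}.
#'
#' @inheritParams cbesselK
#' @return complex vector, \eqn{d^2K_n/dz^2}.
#' @export
cbesselK_d2 <- function(n, z) {
  n <- as.integer(abs(n))
  (cbesselK(abs(n - 2L), z) + 2 * cbesselK(n, z) + cbesselK(n + 2L, z)) / 4
}

#' Modified Bessel function of the first kind for complex argument
#'
#' Power series \eqn{I_n(z) = \sum_k (z/2)^{n+2k} / (k! (n+k)!)}, adequate
#' for the moderate `|z|` arising at inclusion boundaries. Used only as an
#' independent cross-check of [cbesselK()] through the Wronskian identity
#' \eqn{I_n(z) K_{n+1}(z) + I_{n+1}(z) K_n(z) = 1/z}.
#'
#' @inheritParams cbesselK
#' @return complex vector.
#' @export
cbesselI <- function(n, z) {
  z <- as.complex(z)
  n <- as.integer(abs(n))
  half <- z / 2
  term <- half^n / factorial(n)
  out <- term
  for (k in 1:200) {
    term <- term * half * half / (k * (n + k))
    out <- out + term
    if (all(abs(term) <= 1e-17 * abs(out))) break
  }
  out
}
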