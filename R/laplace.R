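#' Laplace-space first-passage-time flux into the nucleus
#'
#' Laplace transform of the first-passage-time density of a Brownian
#' particle released at radius `r0` between an absorbing sphere of radius
#' `ra` and a reflecting sphere of radius `R`:
#' \deqn{\hat P(\lambda) = \frac{r_a}{r_0}\;
#'   \frac{qR\cosh((R-r_0)q) - \sinh((R-r_0)q)}
#'        {qR\cosh((R-r_a)q) - \sinh((R-r_a)q)}, \quad q=\sqrt{\lambda/D}.}
#' The limit \eqn{\lambda \to 0} equals 1 (absorption is certain in the
#' closed domain) and is handled analytically, as is the boundary case
#' `r0 = ra`.  Internally the hyperbolic functions are evaluated in a
#' scaled form that is stable for large `Re(q)` (no overflow on the Talbot
#' contour at small times).
#'
#' @param lambda Laplace variable, 1/s; a nonnegative numeric vector (the
#'   inversion routines also pass complex values, for which the principal
#'   square root keeps `Re(q)` nonnegative).
#' @param r0 starting radius in um, within `[ra, R]`.
#' @param D diffusion coefficient in um^2/s.
#' @param geometry a [cell_geometry()].
#' @return The transform value(s); dimensionless, 1 at `lambda = 0`.
#' @examples
#' laplace_flux(0.01, r0 = 17, D = 2.5)  # 0.26591...
#' @export
laplace_flux <- function(lambda, r0, D, geometry = cell_geometry()) {
  check_r0(r0, geometry)
  if (is.numeric(lambda) && any(lambda < 0))
    stop("lambda must be nonnegative", call. = FALSE)
  R <- geometry$R; ra <- geometry$ra
  if (r0 == ra) return(rep(1, length(lambda)) + 0 * lambda)
  q <- sqrt(lambda / D)
  # scaled numerator/denominator: e^{-c} (qR cosh c - sinh c)
  g <- function(cc, q) {
    e <- exp(-2 * cc)
    q * R * (1 + e) / 2 - (1 - e) / 2
  }
  a <- (R - r0) * q
  b <- (R - ra) * q
  out <- (ra / r0) * exp(a - b) * g(a, q) / g(b, q)
  # lambda -> 0 limit: certain absorption
  zero <- (Mod(lambda) == 0)
  out[zero] <- 1
  out
}

#' Bessel-function route to the Laplace flux
#'
#' Evaluates the same transform as [laplace_flux()] through the
#' Green's-function combination
#' \eqn{D_{-1/2}(x, x_R) = I_{-1/2}(x)K_{-3/2}(x_R) + K_{-1/2}(x)I_{-3/2}(x_R)}
#' of modified Bessel functions of orders -1/2 and -3/2, in the scaled radii
#' \eqn{x = r\sqrt{\lambda/D}}:
#' \deqn{\hat P(\lambda) = \frac{r_a}{r_0}\sqrt{\frac{x_0}{x_a}}
#'   \frac{D_{-1/2}(x_0, x_R)}{D_{-1/2}(x_a, x_R)}.}
#' The half-integer Bessel functions reduce to hyperbolics, so the two
#' routes agree to near machine precision; this one is kept as an
#' independent check.  Singular at `lambda = 0`.
#'
#' @inheritParams laplace_flux
#' @return Transform value(s).
#' @export
laplace_flux_bessel <- function(lambda, r0, D, geometry = cell_geometry()) {
  check_r0(r0, geometry)
  if (!is.numeric(lambda) || any(lambda <= 0))
    stop("Bessel route requires lambda > 0; use laplace_flux() at lambda = 0",
         call. = FALSE)
  R <- geometry$R; ra <- geometry$ra
  if (r0 == ra) return(rep(1, length(lambda)))
  q <- sqrt(lambda / D)
  x0 <- r0 * q; xa <- ra * q; xR <- R * q
  # exponentially scaled Bessel products keep everything in range
  dm <- function(x, xR) {
    exp(x - xR) * besselI(x, -0.5, expon.scaled = TRUE) *
      besselK(xR, -1.5, expon.scaled = TRUE) +
      exp(xR - x) * besselK(x, -0.5, expon.scaled = TRUE) *
      besselI(xR, -1.5, expon.scaled = TRUE)
  }
  (ra / r0) * sqrt(x0 / xa) * dm(x0, xR) / dm(xa, xR)
}

check_r0 <- function(r0, geometry, strict_lower = FALSE, strict_upper = FALSE) {
  stopifnot(is.numeric(r0), length(r0) == 1L, is.finite(r0))
  lo_ok <- if (strict_lower) r0 > geometry$ra else r0 >= geometry$ra
  hi_ok <- if (strict_upper) r0 < geometry$R else r0 <= geometry$R
  if (!lo_ok || !hi_ok)
    stop("starting radius r0 = ", r0, " um outside the allowed range [",
         geometry$ra, ", ", geometry$R, "]", call. = FALSE)
  invisible(TRUE)
}

#' Reduced long-time rate polynomial
#'
#' The long-time (slow-diffusion) decay rate of the first-passage-time
#' density is `k = 6 D r0 ra / |Q(r0)|` with the quartic-free cubic
#' \deqn{Q(r_0) = -4R^4 + 10R^3 r_0 - 2R r_0^3 + 2R^3 r_a - 12R^2 r_0 r_a
#'   + r_0^3 r_a + 6R r_0 r_a^2 - r_0 r_a^3.}
#' Dividing numerator and denominator by `6 ra` normalises the numerator to
#' `D r0`; this function returns the coefficients of the reduced
#' denominator polynomial in `r0`.  With R = 25 um, ra = 5 um the constant
#' term is -46875, the linear coefficient 122375/30 = 4079.1667 and the
#' cubic coefficient -1.5 (all exact; stored at full precision).
#'
#' @param geometry a [cell_geometry()].
#' @return Named numeric vector `c(constant, linear, quadratic, cubic)` of
#'   the reduced polynomial `Q(r0) / (6 ra)`.
#' @examples
#' slow_rate_poly()
#' @export
slow_rate_poly <- function(geometry = cell_geometry()) {
  R <- geometry$R; ra <- geometry$ra
  c(constant  = (-4 * R^4 + 2 * R^3 * ra) / (6 * ra),
    linear    = (10 * R^3 - 12 * R^2 * ra + 6 * R * ra^2 - ra^3) / (6 * ra),
    quadratic = 0,
    cubic     = (-2 * R + ra) / (6 * ra))
}

#' Long-time (slow-diffusion) decay rate
#'
#' Rate constant of the exponential tail of the first-passage-time density,
#' obtained from the small-`lambda` expansion of the Laplace flux:
#' `k = 6 D r0 ra / |Q(r0)|` (see [slow_rate_poly()]).  Note this expansion
#' rate differs from the exact mean first-passage time: `1/k = 355.33 s` at
#' r0 = 17 um, D = 2.5 um^2/s, whereas [mfpt()] gives 276.52 s; both
#' quantities are exposed.
#'
#' @inheritParams laplace_flux
#' @return Decay rate in 1/s.
#' @export
slow_rate <- function(r0, D, geometry = cell_geometry()) {
  check_r0(r0, geometry, strict_lower = TRUE, strict_upper = TRUE)
  p <- slow_rate_poly(geometry)
  denom <- p[["constant"]] + p[["linear"]] * r0 + p[["cubic"]] * r0^3
  if (abs(denom) < 1e-9 * abs(p[["constant"]]))
    stop("degenerate parameters: rate polynomial vanishes at r0 = ", r0,
         call. = FALSE)
  # numerator reduced to D * r0 by the same division by 6 ra
  D * r0 / abs(denom)
}

#' Long-time (slow-diffusion) first-passage-time density
#'
#' Exponential density `k exp(-k t)` with `k = slow_rate(...)`; describes
#' the tail (t beyond a few hundred seconds at cellular parameters) of the
#' recruitment-time distribution.
#'
#' @param t time(s) in seconds, `>= 0`.
#' @inheritParams laplace_flux
#' @return Density value(s) in 1/s.
#' @export
slow_pdf <- function(t, r0, D, geometry = cell_geometry()) {
  stopifnot(all(t >= 0))
  k <- slow_rate(r0, D, geometry)
  k * exp(-k * t)
}

#' Short-time (Levy) first-passage-time density
#'
#' In the short-time regime the particle has not yet felt the outer
#' membrane and the first-arrival density to the absorbing sphere is the
#' Levy-type law
#' \deqn{P_{FD}(t) = \frac{r_a}{r_0}\,\frac{r_0-r_a}{\sqrt{4\pi D t^3}}
#'   \exp\!\left(-\frac{(r_0-r_a)^2}{4Dt}\right),}
#' with total mass `ra/r0` (the transient hitting probability without the
#' confining wall).  Its mode is at `(r0-ra)^2/(6D)`.
#'
#' @param t time(s) in seconds, `> 0` (the value at `t = 0` is the limit 0).
#' @inheritParams laplace_flux
#' @return Density value(s) in 1/s.
#' @export
fast_pdf <- function(t, r0, D, geometry = cell_geometry()) {
  ra <- geometry$ra
  if (r0 <= ra)
    stop("fast-diffusion density requires r0 > ra", call. = FALSE)
  check_r0(r0, geometry)
  stopifnot(all(t >= 0))
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- (ra / r0) * (r0 - ra) / sqrt(4 * pi * D * tp^3) *
    exp(-(r0 - ra)^2 / (4 * D * tp))
  out
}

#' Accumulated recruitment, slow-diffusion regime
#'
#' Integral of [slow_pdf()]: `N_SD(t) = 1 - exp(-k t)`, rising from 0 to 1.
#'
#' @inheritParams slow_pdf
#' @return Recruited fraction(s) in `[0, 1]`.
#' @export
nsd_curve <- function(t, r0, D, geometry = cell_geometry()) {
  stopifnot(all(t >= 0))
  k <- slow_rate(r0, D, geometry)
  -expm1(-k * t)
}

#' Accumulated recruitment, fast-diffusion regime
#'
#' Integral of [fast_pdf()]:
#' `N_FD(t) = (ra/r0) erfc((r0-ra) / (2 sqrt(D t)))`, rising from 0 at
#' `t = 0` to the transient plateau `ra/r0` as `t` grows.
#'
#' @inheritParams fast_pdf
#' @return Recruited fraction(s).
#' @export
nfd_curve <- function(t, r0, D, geometry = cell_geometry()) {
  ra <- geometry$ra
  if (r0 <= ra)
    stop("fast-diffusion curve requires r0 > ra", call. = FALSE)
  check_r0(r0, geometry)
  stopifnot(all(t >= 0))
  out <- numeric(length(t))
  pos <- t > 0
  arg <- (r0 - ra) / (2 * sqrt(D * t[pos]))
  # erfc(x) = 2 pnorm(-x sqrt(2))
  out[pos] <- (ra / r0) * 2 * pnorm(-arg * sqrt(2))
  out
}

#' Exact mean first-passage time
#'
#' Closed-form mean of the first-passage time for radial diffusion from
#' `r0` to the absorbing sphere `ra` with a reflecting wall at `R`:
#' \deqn{\tau(r_0) = \frac{1}{3D}\left[R^3\left(\frac{1}{r_a} -
#'   \frac{1}{r_0}\right) - \frac{r_0^2 - r_a^2}{2}\right].}
#' Equals `-d\hat P/d\lambda` at `lambda = 0`.  At r0 = 17 um,
#' D = 2.5 um^2/s and default geometry: 276.52 s.
#'
#' @inheritParams laplace_flux
#' @return Mean first-passage time in seconds.
#' @export
mfpt <- function(r0, D, geometry = cell_geometry()) {
  check_r0(r0, geometry)
  R <- geometry$R; ra <- geometry$ra
  (R^3 * (1 / ra - 1 / r0) - (r0^2 - ra^2) / 2) / (3 * D)
}
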