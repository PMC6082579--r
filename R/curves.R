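#' Recruitment curve container
#'
#' A recruitment curve is the fraction of proteins that have reached the
#' nucleus as a function of time since release, on an increasing time grid.
#' Provenance is tracked: `analytic` and `simulated` curves must be monotone
#' nondecreasing in `[0, 1]`; `synthetic` and `observed` curves carry
#' observation noise and are only required to stay within `[0, 1.05]`
#' (normalised fluorescence may overshoot slightly).
#'
#' @param time_s increasing numeric vector of times, seconds, `>= 0`.
#' @param fraction recruited fraction at each time.
#' @param kind provenance: `"analytic"`, `"simulated"`, `"synthetic"` or
#'   `"observed"`.
#' @param protein optional protein label.
#' @param r0 optional starting radius (um) or a [start_distribution()]
#'   describing the mixture of starting radii.
#' @param D optional diffusion coefficient (um^2/s).
#' @param normalization `"fraction"` (of all particles) or `"plateau"`
#'   (curve rescaled so its final value is 1).
#' @return An object of class `recruitment_curve`: a data frame with columns
#'   `time_s` and `fraction` plus metadata attributes.
#' @export
recruitment_curve <- function(time_s, fraction,
                              kind = c("analytic", "simulated", "synthetic",
                                       "observed"),
                              protein = NULL, r0 = NULL, D = NULL,
                              normalization = c("fraction", "plateau")) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(time_s), is.numeric(fraction),
            length(time_s) == length(fraction), length(time_s) >= 1L)
  if (any(diff(time_s) <= 0) || any(time_s < 0))
    stop("time grid must be nonnegative and strictly increasing",
         call. = FALSE)
  if (kind %in% c("analytic", "simulated")) {
    if (any(fraction < -1e-12) || any(fraction > 1 + 1e-9))
      stop(kind, " curve fractions must lie in [0, 1]", call. = FALSE)
    if (any(diff(fraction) < -1e-9))
      stop(kind, " curve must be monotone nondecreasing", call. = FALSE)
    fraction <- pmin(pmax(fraction, 0), 1)
  } else {
    if (any(fraction < -1e-12) || any(fraction > 1.05 + 1e-9))
      stop(kind, " curve fractions must lie in [0, 1.05]", call. = FALSE)
  }
  structure(data.frame(time_s = time_s, fraction = fraction),
            kind = kind, protein = protein, r0 = r0, D = D,
            normalization = normalization,
            class = c("recruitment_curve", "data.frame"))
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("Recruitment curve (%s): %d points, t in [%g, %g] s, final fraction %.4g\n",
              attr(x, "kind"), nrow(x), x$time_s[1], x$time_s[nrow(x)],
              x$fraction[nrow(x)]))
  invisible(x)
}

#' @export
plot.recruitment_curve <- function(x, ...,
                                   xlab = "time (s)",
                                   ylab = "recruited fraction") {
  plot(x$time_s, x$fraction, type = if (attr(x, "kind") %in%
                                        c("synthetic", "observed")) "p" else "l",
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Truncated-Gaussian starting-radius distribution
#'
#' Ribosomes producing the protein are spread over a range of radii; the
#' model uses a Gaussian centred at `mean`, truncated to `[lower, upper]`.
#' The stated ranges (e.g. 14-20 um for NBS1 around a 17 um mean) are taken
#' as mean +/- 3 sigma, hence the default `sd = 1` um.  The distribution is
#' discretised on `n_nodes` equispaced radii with renormalised Gaussian
#' weights, which is how curve averaging and sampling consume it.
#'
#' @param mean mean starting radius, um.
#' @param sd Gaussian standard deviation, um (default 1).
#' @param lower,upper truncation bounds, um (defaults `mean - 3`, `mean + 3`).
#' @param n_nodes number of discretisation nodes (>= 1).
#' @param geometry a [cell_geometry()]; the support must lie inside
#'   `(ra, R)`.
#' @return An object of class `start_distribution` with fields `nodes`,
#'   `weights` (summing to 1), `mean`, `sd`, `lower`, `upper`.
#' @export
start_distribution <- function(mean, sd = 1, lower = mean - 3,
                               upper = mean + 3, n_nodes = 25L,
                               geometry = cell_geometry()) {
  stopifnot(is.numeric(mean), length(mean) == 1L, sd >= 0, lower <= upper,
            n_nodes >= 1L)
  if (lower <= geometry$ra || upper >= geometry$R)
    stop("starting-radius support [", lower, ", ", upper,
         "] must lie strictly inside (ra, R)", call. = FALSE)
  if (sd == 0 || lower == upper) {
    nodes <- mean
    weights <- 1
  } else {
    nodes <- seq(lower, upper, length.out = n_nodes)
    weights <- dnorm(nodes, mean, sd)
    if (sum(weights) <= 0) stop("empty support: all weights vanish",
                                call. = FALSE)
    weights <- weights / sum(weights)
  }
  structure(list(nodes = nodes, weights = weights, mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "start_distribution")
}

#' @export
print.start_distribution <- function(x, ...) {
  cat(sprintf(
    "Truncated Gaussian start distribution: mean %g um, sd %g um, support [%g, %g] um (%d nodes)\n",
    x$mean, x$sd, x$lower, x$upper, length(x$nodes)))
  invisible(x)
}

# Draw starting radii from a start_distribution (continuous, rejection
# sampling against the truncation window).
sample_start <- function(dist, n) {
  if (dist$sd == 0) return(rep(dist$mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, dist$mean, dist$sd)
    out <- c(out, x[x >= dist$lower & x <= dist$upper])
  }
  out[seq_len(n)]
}

#' Single-start analytic recruitment curve
#'
#' Evaluates one analytic curve family at fixed starting radius:
#' `"exact"` (numerical inversion of the Laplace flux, valid at all times),
#' `"nsd"` (long-time exponential form) or `"nfd"` (short-time Levy form).
#'
#' @param time_s time grid, seconds.
#' @param r0 starting radius, um.
#' @inheritParams laplace_flux
#' @param family `"exact"`, `"nsd"` or `"nfd"`.
#' @param degree Talbot contour nodes for `family = "exact"`.
#' @return Numeric vector of recruited fractions.
#' @export
curve_family <- function(time_s, r0, D, geometry = cell_geometry(),
                         family = c("exact", "nsd", "nfd"), degree = 32L) {
  family <- match.arg(family)
  switch(family,
         exact = invert_flux_numeric(time_s, r0, D, geometry, what = "cdf",
                                     degree = degree),
         nsd = nsd_curve(time_s, r0, D, geometry),
         nfd = nfd_curve(time_s, r0, D, geometry))
}

#' Analytic curves tabulated over a starting-radius grid
#'
#' Precomputes the matrix `[time x r0]` of single-start curves used by
#' [averaged_curve()] and by the grid search in [fit_start_mean()], so that
#' any mixture over starting radii is a cheap weighted column sum.
#'
#' @param r0_grid starting radii, um.
#' @inheritParams curve_family
#' @return An object of class `model_family`: the matrix with attributes
#'   `time_s`, `r0_grid`, `D`, `family`, `geometry`.
#' @export
model_family <- function(r0_grid, time_s, D, geometry = cell_geometry(),
                         family = c("exact", "nsd", "nfd"), degree = 32L) {
  family <- match.arg(family)
  m <- vapply(r0_grid, function(r0)
    curve_family(time_s, r0, D, geometry, family, degree),
    numeric(length(time_s)))
  m <- matrix(m, nrow = length(time_s))
  structure(m, time_s = time_s, r0_grid = r0_grid, D = D,
            family = family, geometry = geometry, class = "model_family")
}

# Weighted mixture of family columns for a start_distribution whose nodes
# need not coincide with the tabulated grid (linear interpolation in r0).
mix_family <- function(fam, dist) {
  grid <- attr(fam, "r0_grid")
  if (min(dist$nodes) < min(grid) - 1e-9 ||
      max(dist$nodes) > max(grid) + 1e-9)
    stop("distribution support not covered by the tabulated r0 grid",
         call. = FALSE)
  w <- numeric(length(grid))
  for (i in seq_along(dist$nodes)) {
    # spread each node weight onto the two bracketing grid columns
    j <- findInterval(dist$nodes[i], grid, all.inside = TRUE)
    frac <- (dist$nodes[i] - grid[j]) / (grid[j + 1] - grid[j])
    frac <- min(max(frac, 0), 1)
    w[j] <- w[j] + dist$weights[i] * (1 - frac)
    w[j + 1] <- w[j + 1] + dist$weights[i] * frac
  }
  as.numeric(unclass(fam) %*% w)
}

#' Recruitment curve averaged over starting radii
#'
#' Weighted mixture of single-start analytic curves over a
#' [start_distribution()]: the model of a cell population whose ribosomes
#' sit at varying distances from the nucleus.
#'
#' @param time_s time grid, seconds.
#' @param distribution a [start_distribution()] (or a single numeric radius,
#'   treated as a point mass).
#' @inheritParams curve_family
#' @param fam optional precomputed [model_family()] covering the
#'   distribution support (saves recomputation in fitting loops).
#' @return A `recruitment_curve` of kind `"analytic"`.
#' @export
averaged_curve <- function(time_s, distribution, D,
                           geometry = cell_geometry(),
                           family = c("exact", "nsd", "nfd"), degree = 32L,
                           fam = NULL) {
  family <- match.arg(family)
  if (is.numeric(distribution) && length(distribution) == 1L)
    distribution <- start_distribution(distribution, sd = 0,
                                       lower = distribution,
                                       upper = distribution,
                                       geometry = geometry)
  stopifnot(inherits(distribution, "start_distribution"))
  if (is.null(fam)) {
    frac <- rowSums(matrix(vapply(seq_along(distribution$nodes), function(i)
      distribution$weights[i] *
        curve_family(time_s, distribution$nodes[i], D, geometry, family,
                     degree), numeric(length(time_s))),
      nrow = length(time_s)))
  } else {
    stopifnot(inherits(fam, "model_family"))
    if (!isTRUE(all.equal(attr(fam, "time_s"), time_s)))
      stop("time grid mismatch between fam and time_s", call. = FALSE)
    frac <- mix_family(fam, distribution)
  }
  recruitment_curve(time_s, frac, kind = "analytic", r0 = distribution, D = D)
}

#' Default logarithmic time grid
#'
#' Log-spaced grid resolving both the short-time (seconds) and long-time
#' (hundreds of seconds) recruitment regimes.
#'
#' @param t_min,t_max grid limits, seconds.
#' @param n number of points.
#' @return Numeric vector.
#' @export
log_time_grid <- function(t_min = 1e-2, t_max = 1800, n = 200L) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}
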