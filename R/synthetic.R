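#' Synthetic recruitment-curve specification
#'
#' Describes a surrogate "experimental" curve with known ground truth,
#' emulating the statistical structure of fluorescence accumulation
#' measurements at a DNA damage site: a recruitment fraction sampled on a
#' uniform time grid (default 0-600 s every 5 s), with independent additive
#' Gaussian observation noise on the normalised fraction scale (default
#' sigma = 0.02) and values clipped to `[0, 1.05]`.
#'
#' @param protein a [protein_spec()].
#' @param true_mean true mean starting radius, um.
#' @param half_range truncation half-width, um (default 3).
#' @param sd Gaussian width of the starting distribution, um (default 1).
#' @param time_s sampling grid, seconds.
#' @param noise_sd observation noise standard deviation (fraction scale).
#' @param normalization `"fraction"` (of all particles) or `"plateau"`
#'   (rescaled so the final noiseless value is 1, as plateau-normalised
#'   fluorescence traces are).
#' @param seed integer seed (required: every stochastic stage is seeded).
#' @param geometry a [cell_geometry()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(protein, true_mean = protein$r0_mean,
                           half_range = 3, sd = 1,
                           time_s = seq(0, 600, by = 5), noise_sd = 0.02,
                           normalization = c("fraction", "plateau"),
                           seed, geometry = cell_geometry()) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(protein, "protein_spec"), noise_sd >= 0)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (any(diff(time_s) <= 0)) stop("time grid must be increasing",
                                   call. = FALSE)
  # validates truth parameters against the geometry
  dist <- start_distribution(true_mean, sd, true_mean - half_range,
                             true_mean + half_range, geometry = geometry)
  structure(list(protein = protein, true_mean = true_mean,
                 half_range = half_range, sd = sd, distribution = dist,
                 time_s = time_s, noise_sd = noise_sd,
                 normalization = normalization, seed = as.integer(seed),
                 geometry = geometry),
            class = "synthetic_spec")
}

#' Generate a synthetic recruitment curve with ground truth
#'
#' Builds the noiseless analytic mixture curve for the true starting
#' distribution, applies the normalisation mode, adds independent Gaussian
#' noise per grid point and clips to `[0, 1.05]`.  The ground-truth record
#' always travels with the curve.
#'
#' @param spec a [synthetic_spec()].
#' @param fam optional precomputed [model_family()] covering the truth
#'   support on the spec's grid.
#' @return List with `curve` (a `recruitment_curve`, kind `"synthetic"`) and
#'   `truth` (true mean, range, sd, noise, seed, protein, normalization).
#' @export
generate_curve <- function(spec, fam = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  clean <- averaged_curve(spec$time_s, spec$distribution, spec$protein$D,
                          spec$geometry, family = "exact", fam = fam)$fraction
  if (spec$normalization == "plateau")
    clean <- clean / clean[length(clean)]
  set.seed(spec$seed)
  noisy <- clean + rnorm(length(clean), 0, spec$noise_sd)
  noisy <- pmin(pmax(noisy, 0), 1.05)
  curve <- recruitment_curve(spec$time_s, noisy, kind = "synthetic",
                             protein = spec$protein$name,
                             r0 = spec$distribution, D = spec$protein$D,
                             normalization = spec$normalization)
  truth <- list(protein = spec$protein$name, D_um2_s = spec$protein$D,
                true_mean_um = spec$true_mean,
                lower_um = spec$distribution$lower,
                upper_um = spec$distribution$upper,
                sd_um = spec$sd, noise_sd = spec$noise_sd,
                normalization = spec$normalization, seed = spec$seed)
  list(curve = curve, truth = truth)
}

#' Draw synthetic first-passage times from the exact law
#'
#' Fast surrogate for the kinetic Monte Carlo simulator: samples
#' first-passage times by inverse-transform sampling from the numerically
#' inverted exact distribution function (Talbot inversion of the Laplace
#' flux over lambda, tabulated on a log time grid, with the analytic
#' exponential tail extension at rate [slow_rate()] beyond the grid).
#' Starting radii are drawn from the spec's truth distribution (node
#' resampling).  Times beyond `horizon` are censored.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of draws (>= 1).
#' @param horizon censoring horizon, seconds.
#' @param grid_n points in the tabulated distribution function.
#' @return An `fpt_ensemble`.
#' @export
generate_fpt_samples <- function(spec, n, horizon = 1800, grid_n = 400L) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1)
  dist <- spec$distribution
  D <- spec$protein$D
  geometry <- spec$geometry
  set.seed(spec$seed)
  node_idx <- sample.int(length(dist$nodes), n, replace = TRUE,
                         prob = dist$weights)
  u <- runif(n)
  times <- numeric(n)
  for (j in unique(node_idx)) {
    r0 <- dist$nodes[j]
    t_max <- max(horizon, 40 * mfpt(r0, D, geometry))
    tg <- c(0, exp(seq(log(1e-2), log(t_max), length.out = grid_n)))
    Fg <- invert_flux_numeric(tg, r0, D, geometry, what = "cdf")
    Fg <- cummax(pmax(pmin(Fg, 1), 0))   # guard vanishing inversion noise
    keep <- c(TRUE, diff(Fg) > 0)        # strictly increasing for inversion
    Fk <- Fg[keep]; tk <- tg[keep]
    sel <- node_idx == j
    uu <- u[sel]
    tt <- approx(Fk, tk, xout = uu, rule = 1)$y
    beyond <- uu > Fk[length(Fk)]
    if (any(beyond)) {
      k <- slow_rate(r0, D, geometry)
      tt[beyond] <- tk[length(tk)] +
        (log1p(-Fk[length(Fk)]) - log1p(-uu[beyond])) / k
    }
    tt[uu <= Fk[1]] <- 0
    times[sel] <- tt
  }
  cens <- times > horizon
  times[cens] <- horizon
  fpt_ensemble(times, cens, horizon,
               r0 = dist$nodes[node_idx], protein = spec$protein$name,
               D = D, base_seed = spec$seed)
}
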