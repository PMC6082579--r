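#' Concentric-sphere cell geometry
#'
#' The cell is modelled as two concentric spheres: a reflecting outer
#' membrane of radius `R_um` and an absorbing nuclear surface of radius
#' `ra_um` (absorption models passage through the nuclear pore complexes,
#' assumed uniform over the nuclear surface).  Defaults correspond to a
#' human bone-marrow cell: R = 25 um, ra = 5 um.
#'
#' @param R_um outer (cell membrane) radius in micrometres.
#' @param ra_um nucleus radius in micrometres.
#' @return An object of class `cell_geometry` with fields `R` and `ra` (um).
#' @examples
#' cell_geometry()
#' @export
cell_geometry <- function(R_um = 25, ra_um = 5) {
  if (!is.numeric(R_um) || !is.numeric(ra_um) ||
      length(R_um) != 1L || length(ra_um) != 1L ||
      !is.finite(R_um) || !is.finite(ra_um) || ra_um <= 0 || ra_um >= R_um)
    stop("invalid geometry: need 0 < ra_um < R_um", call. = FALSE)
  structure(list(R = as.numeric(R_um), ra = as.numeric(ra_um)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell geometry: R = %g um (reflecting), ra = %g um (absorbing)\n",
              x$R, x$ra))
  invisible(x)
}

#' Diffusing repair-protein specification
#'
#' A protein is characterised by its cytoplasmic diffusion coefficient and
#' the range of radial starting positions (distance of the producing
#' ribosome from the cell centre).  The starting positions are modelled as
#' a Gaussian centred at `r0_mean_um`, truncated to
#' `[r0_lower_um, r0_upper_um]`.
#'
#' @param name protein label, e.g. `"NBS1"`.
#' @param D_um2_s diffusion coefficient in um^2/s (must be > 0).
#' @param r0_mean_um mean starting radius in um.
#' @param r0_lower_um,r0_upper_um support of the starting-radius
#'   distribution in um.
#' @param geometry a [cell_geometry()]; starting radii must lie strictly
#'   between `ra` and `R`.
#' @return An object of class `protein_spec`.
#' @examples
#' protein_defaults("NBS1")
#' @export
protein_spec <- function(name, D_um2_s, r0_mean_um,
                         r0_lower_um = r0_mean_um - 3,
                         r0_upper_um = r0_mean_um + 3,
                         geometry = cell_geometry()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(D_um2_s) || length(D_um2_s) != 1L || !is.finite(D_um2_s) ||
      D_um2_s <= 0)
    stop("invalid parameter: diffusion coefficient must be a positive number",
         call. = FALSE)
  ok <- geometry$ra < r0_lower_um && r0_lower_um <= r0_mean_um &&
    r0_mean_um <= r0_upper_um && r0_upper_um < geometry$R
  if (!ok)
    stop("invalid parameter: need ra < r0_lower <= r0_mean <= r0_upper < R",
         call. = FALSE)
  structure(list(name = name, D = as.numeric(D_um2_s),
                 r0_mean = as.numeric(r0_mean_um),
                 r0_lower = as.numeric(r0_lower_um),
                 r0_upper = as.numeric(r0_upper_um)),
            class = "protein_spec")
}

#' Default protein parameter sets
#'
#' NBS1 (85 kDa): D = 2.5 um^2/s, starting radii 14-20 um (mean 17).
#' MRE11 (80 kDa): D = 2.0 um^2/s, starting radii 11-17 um (mean 14).
#'
#' @param name `"NBS1"` or `"MRE11"`.
#' @inheritParams protein_spec
#' @return A `protein_spec`.
#' @export
protein_defaults <- function(name = c("NBS1", "MRE11"),
                             geometry = cell_geometry()) {
  name <- match.arg(name)
  switch(name,
    NBS1  = protein_spec("NBS1", 2.5, 17, 14, 20, geometry),
    MRE11 = protein_spec("MRE11", 2.0, 14, 11, 17, geometry))
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("Protein %s: D = %g um^2/s, start radius %g um (range %g-%g um)\n",
              x$name, x$D, x$r0_mean, x$r0_lower, x$r0_upper))
  invisible(x)
}

#' Diffusive step time
#'
#' Time for a three-dimensional Brownian particle with diffusion coefficient
#' `D` to cover a mean-squared displacement `L^2`:  `dt = L^2 / (6 D)`.
#' This sets the physical clock of one kinetic Monte Carlo lattice step,
#' and, with `L` identified with the starting radius, the upper time bound
#' of the short-time (Levy) recruitment regime.
#'
#' @param L step length; a length in `L_unit`. Vectorised.
#' @param D diffusion coefficient in um^2/s (> 0).
#' @param L_unit unit of `L`: `"nm"` or `"um"`.
#' @return Step time in seconds.
#' @examples
#' step_time(38.5, 2.5)            # 9.88e-5 s
#' step_time(38.5, 2.0)            # 1.23e-4 s
#' @export
step_time <- function(L, D, L_unit = c("nm", "um")) {
  L_unit <- match.arg(L_unit)
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0))
    stop("invalid parameter: diffusion coefficient must be positive",
         call. = FALSE)
  if (!is.numeric(L) || any(L < 0))
    stop("invalid parameter: step length must be nonnegative", call. = FALSE)
  L_um <- if (L_unit == "nm") L / 1000 else L
  L_um^2 / (6 * D)
}

#' Upper time bound of the fast-diffusion regime
#'
#' Identifies the mean-squared displacement with the squared starting radius
#' `r0^2` in the diffusive clock `dt = <L^2>/(6D)`: the short-time (Levy)
#' asymptotics are expected to hold for times below `r0^2/(6 D)`.
#' At r0 = 20 um this gives about 27 s for NBS1 (D = 2.5) and 33 s for
#' MRE11 (D = 2.0).
#'
#' @param r0 starting radius in um.
#' @param D diffusion coefficient in um^2/s.
#' @return Time bound in seconds.
#' @export
fast_regime_bound <- function(r0, D) {
  step_time(r0, D, L_unit = "um")
}
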