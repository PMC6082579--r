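#' Kinetic Monte Carlo lattice specification
#'
#' Discretises a rectangular simulation box on a regular grid.  The walker
#' hops between neighbouring grid sites; one hop along axis i covers one
#' lattice constant, and the physical time per hop follows the diffusive
#' clock [step_time()].  The nucleus (absorbing sphere of radius `ra`) sits
#' at the box centre -- the only placement that accommodates starting radii
#' up to 20 um inside a 45 um-tall box.
#'
#' The effective step length entering the clock is, by default, the x/y
#' lattice constant (`effective_step = "xy"`); the paper-grid step times
#' 9.88e-5 s (D = 2.5) and 1.23e-4 s (D = 2.0) follow from L = 38.5 nm.
#' `effective_step = "rms"` uses the root mean square of the three axis
#' constants instead.
#'
#' @param geometry a [cell_geometry()].
#' @param unit_nm lattice constants per axis, nm (length 1 or 3).
#' @param box_um box extents per axis, um (length 1 or 3).
#' @param D diffusion coefficient in um^2/s (sets the step time).
#' @param effective_step `"xy"` or `"rms"`; see Details.
#' @param confine `"sphere"` (default): the cell membrane is a reflecting
#'   sphere of radius `R` about the nucleus centre, clipped by the box (the
#'   paper-scale 45 um z-extent does clip the R = 25 um sphere); `"box"`:
#'   reflection at the box faces only.  Only the spherical membrane matches
#'   the concentric-sphere first-passage theory.
#' @return An object of class `lattice_spec` with fields `unit_um` (lattice
#'   constants, um), `n_units` (integer grid counts per axis, from
#'   `round(extent/unit)`), `center` (nucleus centre in lattice coordinates),
#'   `dt` (step time, s), `box_um` (realised box extents `n_units * unit_um`),
#'   `R` (membrane radius when `confine = "sphere"`).
#' @examples
#' make_lattice(cell_geometry(), unit_nm = c(38.5, 38.5, 37.5),
#'              box_um = c(50, 50, 45), D = 2.5)
#' @export
make_lattice <- function(geometry, unit_nm = c(38.5, 38.5, 37.5),
                         box_um = c(50, 50, 45), D,
                         effective_step = c("xy", "rms"),
                         confine = c("sphere", "box")) {
  effective_step <- match.arg(effective_step)
  confine <- match.arg(confine)
  stopifnot(inherits(geometry, "cell_geometry"))
  unit_nm <- rep_len(as.numeric(unit_nm), 3L)
  box_um <- rep_len(as.numeric(box_um), 3L)
  if (any(!is.finite(unit_nm)) || any(unit_nm <= 0))
    stop("invalid parameter: lattice constants must be positive", call. = FALSE)
  if (any(!is.finite(box_um)) || any(box_um <= 0))
    stop("invalid parameter: box extents must be positive", call. = FALSE)
  if (any(box_um < 2 * geometry$ra))
    stop("invalid geometry: nucleus sphere (radius ", geometry$ra,
         " um) does not fit inside the box", call. = FALSE)
  unit_um <- unit_nm / 1000
  # round half up, so 1298.7 -> 1299; lattice_preset("paper") pins its counts
  n_units <- as.integer(floor(box_um / unit_um + 0.5))
  L_eff <- switch(effective_step,
                  xy  = unit_nm[1],
                  rms = sqrt(mean(unit_nm^2)))
  structure(list(
    unit_um = unit_um,
    n_units = n_units,
    center = (n_units - 1) / 2,   # lattice coordinates of the nucleus centre
    dt = step_time(L_eff, D, "nm"),
    D = as.numeric(D),
    ra = geometry$ra,
    R = geometry$R,
    confine = confine,
    effective_step = effective_step,
    box_um = n_units * unit_um
  ), class = "lattice_spec")
}

#' Lattice presets
#'
#' `"paper"`: 38.5 x 38.5 x 37.5 nm units with the production counts
#' 1300 x 1300 x 1200 pinned (box 50.05 x 50.05 x 45 um).
#' `"fine"`: cubic 20 nm units in the same 50 x 50 x 45 um box (short-time
#' accuracy).  `"coarse"`: cubic 100 nm units (test-scale runs; first-passage
#' statistics at these radii are insensitive to lattice resolution).
#'
#' @param preset one of `"paper"`, `"fine"`, `"coarse"`.
#' @inheritParams make_lattice
#' @return A `lattice_spec`.
#' @export
lattice_preset <- function(preset = c("coarse", "paper", "fine"),
                           geometry = cell_geometry(), D,
                           effective_step = c("xy", "rms"),
                           confine = c("sphere", "box")) {
  preset <- match.arg(preset)
  effective_step <- match.arg(effective_step)
  confine <- match.arg(confine)
  spec <- switch(preset,
    paper  = make_lattice(geometry, c(38.5, 38.5, 37.5), c(50, 50, 45), D,
                          effective_step, confine),
    fine   = make_lattice(geometry, 20, c(50, 50, 45), D, effective_step,
                          confine),
    coarse = make_lattice(geometry, 100, c(50, 50, 45), D, effective_step,
                          confine))
  if (preset == "paper") {
    spec$n_units <- c(1300L, 1300L, 1200L)
    spec$center <- (spec$n_units - 1) / 2
    spec$box_um <- spec$n_units * spec$unit_um
  }
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "kMC lattice: %d x %d x %d units of %g x %g x %g nm, dt = %.4g s (D = %g um^2/s)\n",
    x$n_units[1], x$n_units[2], x$n_units[3],
    x$unit_um[1] * 1000, x$unit_um[2] * 1000, x$unit_um[3] * 1000,
    x$dt, x$D))
  invisible(x)
}
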