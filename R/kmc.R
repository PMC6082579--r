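#' Initialise a lattice walker on the starting sphere
#'
#' Places a walker at the lattice site nearest to a point drawn uniformly on
#' the sphere of radius `r0` around the nucleus centre.  The realised radius
#' deviates from `r0` by at most one lattice diagonal.  Uses the current R
#' random number stream (call `set.seed()` for reproducibility).
#'
#' @param r0 starting radius, um.
#' @param lattice a `lattice_spec` from [make_lattice()].
#' @return A walker state: list with integer `pos` (lattice coordinates),
#'   `steps = 0` and `absorbed = FALSE`.
#' @export
init_walker <- function(r0, lattice) {
  stopifnot(inherits(lattice, "lattice_spec"))
  if (r0 <= lattice$ra)
    stop("starting radius must exceed the nucleus radius", call. = FALSE)
  half <- lattice$box_um / 2
  if (r0 >= min(half))
    stop("starting sphere of radius ", r0, " um exits the box", call. = FALSE)
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  p_um <- r0 * c(s * cos(phi), s * sin(phi), z)
  pos <- as.integer(round(lattice$center + p_um / lattice$unit_um))
  list(pos = pos, steps = 0L, absorbed = FALSE)
}

#' Advance a walker by one kinetic Monte Carlo step
#'
#' One of the six axis moves is chosen with probability 1/6; a move that
#' would exit the box -- or, for `confine = "sphere"` lattices, the
#' reflecting spherical membrane of radius `R` -- is rejected (the walker
#' stays put for that step, the lattice version of a reflecting wall).  The
#' step counter always advances.  Absorption is the caller's concern
#' ([run_replica()]).
#'
#' @param state a walker state from [init_walker()].
#' @param lattice a `lattice_spec`.
#' @return The updated walker state.
#' @export
walker_step <- function(state, lattice) {
  if (isTRUE(state$absorbed))
    stop("cannot step an absorbed walker", call. = FALSE)
  p <- kmc_path_cpp(state$pos, lattice$n_units, lattice$unit_um,
                    lattice$center, lat_confine_radius(lattice), 1L)
  state$pos <- as.integer(p[1, ])
  state$steps <- state$steps + 1L
  state
}

walker_radius <- function(state, lattice) {
  sqrt(sum(((state$pos - lattice$center) * lattice$unit_um)^2))
}

#' Simulate one first-passage replica
#'
#' Runs a single walker from radius `r0` until its site centre lies within
#' the nucleus (Euclidean distance <= `ra`; returns the elapsed time
#' `steps * dt`, uncensored) or until the time horizon is reached (returns
#' the horizon, censored).
#'
#' @param r0 starting radius, um.
#' @param lattice a `lattice_spec`.
#' @param horizon simulation horizon, seconds (> 0).
#' @param seed integer seed for this replica (required; every stochastic
#'   stage is explicitly seeded).
#' @return List with `time` (s), `censored` (logical), `steps`.
#' @export
run_replica <- function(r0, lattice, horizon, seed) {
  stopifnot(inherits(lattice, "lattice_spec"), horizon > 0)
  set.seed(seed)
  w <- init_walker(r0, lattice)
  max_steps <- floor(horizon / lattice$dt)
  res <- kmc_run_cpp(w$pos, lattice$n_units, lattice$unit_um, lattice$center,
                     lattice$ra, lat_confine_radius(lattice), max_steps, TRUE)
  if (res$absorbed)
    list(time = res$steps * lattice$dt, censored = FALSE, steps = res$steps)
  else
    list(time = horizon, censored = TRUE, steps = res$steps)
}

lat_confine_radius <- function(lattice) {
  if (identical(lattice$confine, "box")) -1 else lattice$R
}

#' Simulate an ensemble of independent first-passage replicas
#'
#' Each replica places a single particle (no concentration gradient) and is
#' seeded deterministically as `base_seed + replica index`, so ensembles are
#' bit-reproducible.  Starting radii are either fixed (`start_mode =
#' "fixed"`) or drawn per replica from the protein's truncated-Gaussian
#' starting distribution (`start_mode = "sampled"`).
#'
#' @param protein a [protein_spec()].
#' @param lattice a `lattice_spec` built with the protein's `D`.
#' @param n_replicas number of independent replicas (>= 1).
#' @param horizon simulation horizon, seconds.
#' @param base_seed integer base seed (replica i uses `base_seed + i - 1`;
#'   keep `base_seed + n_replicas` below 2^31).
#' @param start_mode `"fixed"` (all replicas start at `r0`) or `"sampled"`.
#' @param r0 starting radius for `start_mode = "fixed"` (defaults to the
#'   protein's mean).
#' @param sd Gaussian width for `start_mode = "sampled"` (um).
#' @return An object of class `fpt_ensemble`: list with `times` (s),
#'   `censored` (logical), `r0` (per replica), `horizon`, `n`, `base_seed`,
#'   `protein`, `D`, `dt`.
#' @export
run_ensemble <- function(protein, lattice, n_replicas, horizon, base_seed,
                         start_mode = c("fixed", "sampled"),
                         r0 = protein$r0_mean, sd = 1) {
  start_mode <- match.arg(start_mode)
  stopifnot(inherits(protein, "protein_spec"), n_replicas >= 1)
  if (missing(base_seed)) stop("an explicit base_seed is required",
                               call. = FALSE)
  if (base_seed + n_replicas >= 2^31)
    stop("base_seed + n_replicas must stay below 2^31", call. = FALSE)
  times <- numeric(n_replicas)
  cens <- logical(n_replicas)
  r0s <- numeric(n_replicas)
  dist <- if (start_mode == "sampled")
    start_distribution(protein$r0_mean, sd, protein$r0_lower,
                       protein$r0_upper)
  for (i in seq_len(n_replicas)) {
    seed_i <- base_seed + i - 1
    if (start_mode == "sampled") {
      set.seed(seed_i)
      r0_i <- sample_start(dist, 1)
      rep_i <- run_replica_current_rng(r0_i, lattice, horizon)
    } else {
      r0_i <- r0
      rep_i <- run_replica(r0_i, lattice, horizon, seed_i)
    }
    times[i] <- rep_i$time
    cens[i] <- rep_i$censored
    r0s[i] <- r0_i
  }
  structure(list(times = times, censored = cens, r0 = r0s,
                 horizon = horizon, n = n_replicas, base_seed = base_seed,
                 start_mode = start_mode, protein = protein$name,
                 D = protein$D, dt = lattice$dt),
            class = "fpt_ensemble")
}

# As run_replica() but continues the current RNG stream (used when the
# starting radius was just drawn from the same per-replica stream).
run_replica_current_rng <- function(r0, lattice, horizon) {
  w <- init_walker(r0, lattice)
  max_steps <- floor(horizon / lattice$dt)
  res <- kmc_run_cpp(w$pos, lattice$n_units, lattice$unit_um, lattice$center,
                     lattice$ra, lat_confine_radius(lattice), max_steps, TRUE)
  if (res$absorbed)
    list(time = res$steps * lattice$dt, censored = FALSE, steps = res$steps)
  else
    list(time = horizon, censored = TRUE, steps = res$steps)
}

#' Construct a first-passage-time ensemble from raw values
#'
#' Low-level constructor used by the synthetic sampler and the I/O layer.
#'
#' @param times first-passage times, seconds (censored replicas carry the
#'   horizon).
#' @param censored logical vector, same length.
#' @param horizon simulation horizon, seconds.
#' @param r0 starting radius (scalar or per replica).
#' @param protein,D,base_seed provenance fields.
#' @return An `fpt_ensemble`.
#' @export
fpt_ensemble <- function(times, censored, horizon, r0 = NA_real_,
                         protein = NA_character_, D = NA_real_,
                         base_seed = NA_integer_) {
  stopifnot(length(times) == length(censored))
  if (any(times[!censored] > horizon + 1e-9))
    stop("uncensored times must not exceed the horizon", call. = FALSE)
  structure(list(times = as.numeric(times), censored = as.logical(censored),
                 r0 = r0, horizon = horizon, n = length(times),
                 base_seed = base_seed, start_mode = NA_character_,
                 protein = protein, D = D, dt = NA_real_),
            class = "fpt_ensemble")
}

#' @export
print.fpt_ensemble <- function(x, ...) {
  cat(sprintf(
    "FPT ensemble: %d replicas (%s), horizon %g s, censored %.2f%%\n",
    x$n, x$protein, x$horizon, 100 * mean(x$censored)))
  if (any(!x$censored))
    cat(sprintf("  mean uncensored FPT: %.1f s\n", mean(x$times[!x$censored])))
  invisible(x)
}

#' @export
summary.fpt_ensemble <- function(object, ...) {
  u <- object$times[!object$censored]
  structure(list(n = object$n, censored_fraction = mean(object$censored),
                 mean = mean(u), sd = sd(u),
                 quantiles = quantile(u, c(0.05, 0.25, 0.5, 0.75, 0.95)),
                 horizon = object$horizon, protein = object$protein),
            class = "summary.fpt_ensemble")
}

#' @export
print.summary.fpt_ensemble <- function(x, ...) {
  cat(sprintf("FPT ensemble summary (%s): n = %d, censored %.2f%%\n",
              x$protein, x$n, 100 * x$censored_fraction))
  cat(sprintf("  mean %.1f s, sd %.1f s\n", x$mean, x$sd))
  print(round(x$quantiles, 1))
  invisible(x)
}
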