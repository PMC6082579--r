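#' First-passage-time histogram
#'
#' Empirical density of the uncensored first-passage times, normalised so
#' that the histogram integrates to the uncensored fraction of the ensemble
#' (histogram mass + censored fraction = 1).  Censored replicas are excluded
#' from the bins and reported separately.
#'
#' @param ensemble an `fpt_ensemble`.
#' @param breaks increasing bin edges, seconds; defaults to 2 s bins on
#'   `[0, 100]` when the horizon is short (fast regime) and 25 s bins on
#'   `[0, horizon]` otherwise.
#' @return An object of class `fpt_histogram`: list with `breaks`, `density`
#'   (1/s), `counts`, `censored_fraction`, `n`.
#' @export
fpt_histogram <- function(ensemble, breaks = NULL) {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  u <- ensemble$times[!ensemble$censored]
  if (length(u) == 0L)
    stop("empty histogram: all replicas are censored", call. = FALSE)
  if (is.null(breaks)) {
    breaks <- if (ensemble$horizon <= 150) seq(0, ensemble$horizon, by = 2)
              else seq(0, ensemble$horizon, by = 25)
  }
  if (any(diff(breaks) <= 0)) stop("bin edges must be increasing",
                                   call. = FALSE)
  counts <- as.numeric(table(cut(u, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  widths <- diff(breaks)
  density <- counts / (ensemble$n * widths)
  structure(list(breaks = breaks, density = density, counts = counts,
                 censored_fraction = mean(ensemble$censored),
                 n = ensemble$n),
            class = "fpt_histogram")
}

#' @export
print.fpt_histogram <- function(x, ...) {
  cat(sprintf(
    "FPT histogram: %d bins on [%g, %g] s, total mass %.4f, censored %.4f\n",
    length(x$counts), x$breaks[1], x$breaks[length(x$breaks)],
    sum(x$density * diff(x$breaks)), x$censored_fraction))
  invisible(x)
}

#' @export
plot.fpt_histogram <- function(x, ..., xlab = "first-passage time (s)",
                               ylab = "density (1/s)") {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  plot(mids, x$density, type = "h", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Accumulated recruitment curve from an ensemble
#'
#' Empirical recruitment fraction: at each grid time, the number of
#' uncensored first-passage times at or below that time, divided by the
#' total number of replicas (censored replicas never enter the numerator).
#'
#' @param ensemble an `fpt_ensemble`.
#' @param time_s increasing time grid, seconds.
#' @return A `recruitment_curve` of kind `"simulated"`.
#' @export
accumulate <- function(ensemble, time_s = seq(0, ensemble$horizon,
                                              length.out = 201L)) {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  u <- sort(ensemble$times[!ensemble$censored])
  frac <- findInterval(time_s, u, left.open = FALSE) / ensemble$n
  recruitment_curve(time_s, frac, kind = "simulated",
                    protein = ensemble$protein,
                    r0 = if (length(unique(ensemble$r0)) == 1L)
                      ensemble$r0[1] else NULL,
                    D = ensemble$D)
}

#' Average recruitment curves over a starting-radius distribution
#'
#' Pointwise weighted mean of a family of curves indexed by starting radius
#' (all sharing one time grid), with weights from a truncated-Gaussian
#' [start_distribution()] evaluated at the family's radii and renormalised.
#'
#' @param curves named list of `recruitment_curve`s; names (or the `r0`
#'   attribute of each curve) give the starting radius in um.
#' @param distribution a [start_distribution()], or `NULL` for equal
#'   weights.
#' @return A `recruitment_curve` whose `r0` attribute records the mixing
#'   distribution.
#' @export
average_over_start <- function(curves, distribution = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  r0s <- vapply(seq_along(curves), function(i) {
    r0 <- attr(curves[[i]], "r0")
    if (is.numeric(r0) && length(r0) == 1L) r0
    else if (!is.null(names(curves))) as.numeric(names(curves)[i])
    else NA_real_
  }, numeric(1))
  grid <- curves[[1]]$time_s
  for (cv in curves)
    if (!isTRUE(all.equal(cv$time_s, grid)))
      stop("alignment error: curves do not share a time grid", call. = FALSE)
  if (is.null(distribution)) {
    w <- rep(1 / length(curves), length(curves))
  } else {
    stopifnot(inherits(distribution, "start_distribution"))
    if (any(is.na(r0s)))
      stop("curves must carry starting radii to be averaged over a ",
           "distribution", call. = FALSE)
    w <- dnorm(r0s, distribution$mean, max(distribution$sd, 1e-12))
    w[r0s < distribution$lower | r0s > distribution$upper] <- 0
    if (sum(w) <= 0) stop("empty support: no curve has positive weight",
                          call. = FALSE)
    w <- w / sum(w)
  }
  frac <- Reduce(`+`, Map(function(wi, cv) wi * cv$fraction, w, curves))
  kind <- attr(curves[[1]], "kind")
  if (!kind %in% c("analytic", "simulated")) kind <- "analytic"
  recruitment_curve(grid, frac, kind = kind,
                    protein = attr(curves[[1]], "protein"),
                    r0 = distribution, D = attr(curves[[1]], "D"))
}
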