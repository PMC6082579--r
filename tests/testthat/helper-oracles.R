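# Shared test oracles.
#
# pde_cdf(): independent oracle for the first-passage-time distribution via
# the backward Kolmogorov equation.  For radial diffusion between the
# absorbing sphere ra and the reflecting sphere R, the survival probability
# S(r, t) obeys dS/dt = D (S'' + 2 S'/r) with S(ra, t) = 0 and S'(R, t) = 0.
# Substituting u = r S reduces it to the 1-D heat equation du/dt = D u''
# with u(ra) = 0 and the Robin condition u'(R) = u(R)/R, solved here by the
# method of lines (deSolve).  The FPT distribution function is 1 - S(r0, t).
pde_cdf <- function(t_out, r0, D, geometry = cell_geometry(), n = 601L) {
  ra <- geometry$ra
  R <- geometry$R
  r <- seq(ra, R, length.out = n)
  h <- r[2] - r[1]
  rhs <- function(t, u, parms) {
    full <- c(0, u)                     # u(ra) = 0 pinned
    m <- length(full)
    d2 <- numeric(m - 1)
    i <- 2:(m - 1)
    d2[i - 1] <- full[i - 1] - 2 * full[i] + full[i + 1]
    # reflecting wall: ghost node u[m+1] = u[m-1] + 2 h u[m]/R
    d2[m - 1] <- 2 * full[m - 1] - 2 * full[m] + 2 * h * full[m] / R
    list(D * d2 / h^2)
  }
  u0 <- r[-1]                           # S = 1 everywhere at t = 0
  times <- sort(unique(c(0, t_out)))
  sol <- deSolve::ode.1D(y = u0, times = times, func = rhs, parms = NULL,
                         nspec = 1L, method = "lsoda",
                         atol = 1e-10, rtol = 1e-10)
  i0 <- which.min(abs(r - r0))
  stopifnot(abs(r[i0] - r0) < 1e-9)     # keep r0 on-grid
  S <- sol[match(t_out, times), 1 + (i0 - 1)] / r0   # column i0-1 of u
  as.numeric(1 - S)
}

# Wrapper around invert_flux_numeric usable inside stats::integrate
# (vector-safe, zero below t = 0).
inv_pdf_fun <- function(r0, D, geometry = cell_geometry()) {
  function(t) {
    out <- numeric(length(t))
    pos <- t > 0
    if (any(pos))
      out[pos] <- invert_flux_numeric(t[pos], r0, D, geometry, what = "pdf")
    out
  }
}
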