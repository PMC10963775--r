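#' Simulate Langevin state-transition dynamics
#'
#' Euler--Maruyama integration of
#' `dX_t = -U_p'(X_t) dt + sqrt(2 beta_inv) dB_t`. With `beta_inv = 0` the
#' motion is deterministic gradient descent into the nearest well. A
#' stability guard rejects time steps for which `dt * max |U_p''|` (over
#' the span of the wells and the initial conditions, with a margin)
#' reaches 0.5, since explicit integration of the drift is then unstable.
#'
#' @param m A [potential_model()] (its `beta_inv` is the diffusion
#'   coefficient unless overridden).
#' @param x0 Initial coordinate; a vector simulates that many independent
#'   walkers with the same noise schedule length.
#' @param t_end Final time.
#' @param dt Time step (> 0).
#' @param seed Seed for the Brownian increments.
#' @param beta_inv Optional override of the model's diffusion coefficient.
#' @return A matrix of coordinates, `(steps + 1) x length(x0)`, with the
#'   time grid in attribute `time`; a plain vector when `x0` is scalar.
#' @export
simulate_langevin <- function(m, x0, t_end, dt, seed = 1L, beta_inv = NULL) {
  stopifnot(inherits(m, "potential_model"))
  if (dt <= 0) stop("dt must be positive")
  beta_inv <- beta_inv %||% m$beta_inv
  span <- range(c(m$c1, m$c3, x0))
  pad <- 0.2 * (span[2] - span[1]) + 1e-9
  xs <- seq(span[1] - pad, span[2] + pad, length.out = 512L)
  curv <- m$scale * (3 * xs^2 - 2 * (m$c1 + m$c2 + m$c3) * xs +
                       (m$c1 * m$c2 + m$c1 * m$c3 + m$c2 * m$c3))
  if (dt * max(abs(curv)) >= 0.5)
    stop(sprintf("unstable: dt * max|U''| = %.3g >= 0.5; use dt < %.3g",
                 dt * max(abs(curv)), 0.5 / max(abs(curv))))
  n_steps <- ceiling(t_end / dt)
  nw <- length(x0)
  out <- matrix(NA_real_, n_steps + 1L, nw)
  out[1L, ] <- x0
  x <- x0
  noise_amp <- sqrt(2 * beta_inv * dt)
  with_seed(seed, {
    for (it in seq_len(n_steps)) {
      x <- x - potential_gradient(m, x) * dt +
        if (noise_amp > 0) noise_amp * stats::rnorm(nw) else 0
      out[it + 1L, ] <- x
    }
  })
  attr(out, "time") <- dt * (0:n_steps)
  if (nw == 1L) {
    tm <- attr(out, "time"); out <- as.vector(out); attr(out, "time") <- tm
  }
  out
}

#' Solve the 1-D Fokker--Planck equation on a bounded grid
#'
#' Conservative finite-volume scheme with Chang--Cooper exponential
#' fitting and reflecting (zero-flux) boundaries for
#' `dP/dt = -d/dx( -U_p'(x) P ) + beta_inv d2P/dx2`. The discrete
#' stationary solution is the Boltzmann density exactly (up to float
#' round-off), and total mass is conserved to machine precision. Explicit
#' time stepping under a CFL-like bound; a user-supplied `dt` above the
#' bound is an error.
#'
#' @param m A [potential_model()] supplying drift `-U_p'` and diffusion
#'   `beta_inv`, or `NULL` when `drift` and `beta_inv` are given directly
#'   (e.g. a quadratic-potential override for the Ornstein--Uhlenbeck
#'   limit).
#' @param p0 Initial density on `grid` (nonnegative, unit trapezoidal
#'   mass).
#' @param grid Uniform increasing coordinate grid covering the support;
#'   should extend past `[c1, c3]` so that boundary densities are
#'   negligible.
#' @param t_end Final time.
#' @param dt Time step; `NULL` picks 90% of the stability bound.
#' @param times Output snapshot times (default `c(0, t_end)`).
#' @param drift Optional drift function `A(x)` overriding the model's
#'   `-U_p'(x)`.
#' @param beta_inv Optional diffusion override (> 0).
#' @return Object of class `density_solution`: `grid`, `times`, `density`
#'   (times x grid matrix).
#' @export
solve_fokker_planck <- function(m, p0, grid, t_end, dt = NULL, times = NULL,
                                drift = NULL, beta_inv = NULL) {
  n <- length(grid)
  if (n < 10L) stop("grid too coarse")
  h <- diff(grid)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) stop("grid must be uniform")
  h <- h[1]
  if (length(p0) != n || any(p0 < 0)) stop("p0 must be a nonnegative density on the grid")
  mass0 <- trapz(grid, p0)
  if (abs(mass0 - 1) > 1e-6) stop("p0 must have unit (trapezoidal) mass")
  if (is.null(drift)) {
    stopifnot(inherits(m, "potential_model"))
    drift <- function(x) -potential_gradient(m, x)
  }
  D <- beta_inv %||% (if (!is.null(m)) m$beta_inv else NULL)
  if (is.null(D) || D <= 0) stop("need a positive diffusion coefficient")
  xe <- (grid[-1L] + grid[-n]) / 2
  Ae <- drift(xe)
  dt_max <- 1 / (2 * D / h^2 + max(abs(Ae)) / h)
  if (is.null(dt)) dt <- 0.9 * dt_max
  if (dt > dt_max) stop(sprintf("dt = %.3g violates the stability bound %.3g", dt, dt_max))
  w <- Ae * h / D
  delta <- ifelse(abs(w) < 1e-8, 0.5 - w / 12, 1 / w - 1 / expm1(w))
  times <- sort(unique(c(0, times %||% t_end)))
  if (max(times) > t_end + 1e-12) stop("snapshot times exceed t_end")
  dens <- matrix(NA_real_, length(times), n)
  P <- p0
  t_now <- 0
  for (j in seq_along(times)) {
    t_target <- times[j]
    if (t_target > t_now) {
      nt <- ceiling((t_target - t_now) / dt)
      step <- (t_target - t_now) / nt
      for (it in seq_len(nt)) {
        Pl <- P[-n]; Pr <- P[-1L]
        Fe <- Ae * ((1 - delta) * Pl + delta * Pr) - D * (Pr - Pl) / h
        P <- P - step / h * (c(Fe, 0) - c(0, Fe))
      }
      t_now <- t_target
    }
    dens[j, ] <- P
  }
  structure(list(grid = grid, times = times, density = dens),
            class = "density_solution")
}

#' Boltzmann stationary density of a potential model
#'
#' `p(x) propto exp(-U_p(x) / beta_inv)`, normalized by trapezoidal
#' quadrature on the supplied grid. This is the long-time limit of both
#' dynamics engines.
#'
#' @param m A [potential_model()] with `beta_inv > 0`.
#' @param grid Coordinate grid.
#' @param beta_inv Optional diffusion override.
#' @return Density values on the grid (unit trapezoidal mass).
#' @export
boltzmann_density <- function(m, grid, beta_inv = NULL) {
  D <- beta_inv %||% m$beta_inv
  if (D <= 0) stop("beta_inv must be positive")
  u <- potential_value(m, grid)
  p <- exp(-(u - min(u)) / D)
  p / trapz(grid, p)
}
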