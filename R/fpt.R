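#' Solve the cumulative Fokker-Planck equation for the LIF membrane
#'
#' Crank-Nicolson integration of
#' \eqn{\partial_t F = -b(x,t)\partial_x F + (\sigma^2/2)\partial^2_x F}
#' on \eqn{[x^-, x_{th}]} with absorbing-in-CDF lower boundary
#' \eqn{F(x^-, t) = 0}, reflecting upper boundary
#' \eqn{\partial_x F(x_{th}, t) = 0} and Heaviside initial condition at
#' `x_start`.  \eqn{F(x_{th}, t)} is the ISI survival function; the ISI
#' density is \eqn{g(t) = -\partial_t F(x_{th}, t)}, obtained by central
#' differences in t (one-sided at the ends) with negative round-off
#' clipped at zero.
#'
#' @param lif a [lif_params()].
#' @param drive stimulus-plus-history current: a single number, a numeric
#'   vector with one value per PDE step (evaluated at half-steps), or a
#'   function of time.
#' @param grid a [pde_grid()].
#' @param t_max solve horizon, s (defaults to the grid's cap).
#' @param x_start initial membrane value (defaults to the reset `x0`).
#' @param kernel,history optional [response_kernel()] and past spike
#'   times (all non-positive relative to the solve origin at 0); their
#'   post-spike current is added to `drive`.
#' @param full_surface keep the full surface F(x, t)?
#' @return An object of class `isi_solution`: time grid `t`, survival
#'   `survival` = F(x_th, t), density `g`, cumulative `G`, the fraction
#'   of clipped negative density mass `clipped_mass`, and optionally the
#'   surface `F` (x in rows) with node positions `x`.
#' @export
solve_fpt_cdf <- function(lif, drive, grid = pde_grid(),
                          t_max = grid$t_max, x_start = lif$x0,
                          kernel = NULL, history = numeric(0),
                          full_surface = FALSE) {
  stopifnot(inherits(lif, "lif_params"), inherits(grid, "pde_grid"),
            x_start >= lif$x_minus, x_start < lif$x_th, t_max > 0)
  nsteps <- max(3L, as.integer(ceiling(t_max / grid$dt)))
  th <- (seq_len(nsteps) - 0.5) * grid$dt
  off <- if (is.function(drive)) drive(th)
         else if (length(drive) == 1) rep(drive, nsteps)
         else if (length(drive) == nsteps) as.numeric(drive)
         else stop("drive must be scalar, a function, or one value per step")
  if (!is.null(kernel) && length(history)) {
    stopifnot(all(history <= 0))
    e <- kernel$eta
    A0 <- sum(exp(e[2] * history)); B0 <- sum(exp(e[4] * history))
    off <- off + e[1] * A0 * exp(-e[2] * th) - e[3] * B0 * exp(-e[4] * th)
  }
  # advection-dominance check: cell Peclet number of the scheme
  bmax <- max(abs(-lif$a * (c(lif$x_minus, lif$x_th) - lif$mu)) +
              max(abs(off)))
  if (bmax * grid$dx / (0.5 * lif$sigma^2) > 50)
    warning("strongly advection-dominated grid; central differences may ",
            "oscillate (consider a finer dx)")
  sol <- cpp_fpt_solve(off, lif$a, lif$mu, lif$sigma, grid$dt, grid$dx,
                       lif$x_minus, lif$x_th, x_start, full_surface)
  Fth <- sol$Fth
  tgrid <- seq(0, by = grid$dt, length.out = nsteps + 1)
  g <- numeric(nsteps + 1)
  g[1] <- -(Fth[2] - Fth[1]) / grid$dt
  g[nsteps + 1] <- -(Fth[nsteps + 1] - Fth[nsteps]) / grid$dt
  if (nsteps > 1)
    g[2:nsteps] <- -(Fth[3:(nsteps + 1)] - Fth[1:(nsteps - 1)]) /
      (2 * grid$dt)
  neg <- pmin(g, 0)
  clipped <- if (any(g > 0)) sum(-neg) / sum(pmax(g, 0)) else 0
  g <- pmax(g, 0)
  G <- cumsum(c(0, (g[-1] + g[-length(g)]) / 2 * grid$dt))
  out <- list(t = tgrid, survival = Fth, g = g, G = pmin(G, 1),
              clipped_mass = clipped, grid = grid, t_max = t_max)
  if (full_surface) {
    out$F <- sol$F
    out$x <- seq(lif$x_minus, by = grid$dx, length.out = sol$nx)
  }
  class(out) <- "isi_solution"
  out
}

#' Interpolate the ISI density of a solved first-passage problem
#'
#' @param solution an `isi_solution` from [solve_fpt_cdf()].
#' @param t time(s) within the solved horizon.
#' @return Linearly interpolated density value(s).
#' @export
isi_density_at <- function(solution, t) {
  stopifnot(inherits(solution, "isi_solution"))
  if (any(t < 0) || any(t > max(solution$t) + 1e-12))
    stop("t outside the solved horizon")
  stats::approx(solution$t, solution$g, xout = pmin(t, max(solution$t)),
                rule = 2)$y
}

#' Interval log-likelihood of an observed spike segment
#'
#' Log-probability of the spikes falling in the half-open decoding
#' interval `[Tb, Te)`, conditional on the spike history before `Tb`:
#' the product of first-passage densities for the complete ISIs inside
#' the interval, the density of the first spike (solved from the last
#' pre-interval spike, with the previous interval's stimulus value before
#' `Tb` and the current one after, conditioned on survival up to `Tb`)
#' and the survival probability from the last spike to `Te`.  With no
#' spikes in the interval the conditional survival over `[Tb, Te)` is
#' returned.  The conditioning convention makes log-likelihoods add
#' exactly over a partition of the window.
#'
#' @param spikes numeric vector of the spike times inside `[Tb, Te)`.
#' @param Tb,Te interval boundaries, s.
#' @param s_curr stimulus value(s) attended during the interval; a vector
#'   evaluates a batch of particles in one call.
#' @param s_prev stimulus value(s) attended before `Tb` (same length as
#'   `s_curr`); defaults to `s_curr`.
#' @param history spike times before the interval (may be empty).
#' @param window_start start of the observation window, used as the
#'   solve origin when the history is empty (the membrane is taken to
#'   start at the reset there).
#' @param lif,kernel,grid model components.
#' @return Numeric vector of log-likelihoods (`-Inf` on underflow, never
#'   an error).
#' @export
interval_loglik <- function(spikes, Tb, Te, s_curr, s_prev = s_curr,
                            history = numeric(0), window_start = Tb,
                            lif = lif_params(), kernel = kernel_bursting(),
                            grid = pde_grid()) {
  stopifnot(Tb < Te, length(s_prev) == length(s_curr))
  if (length(spikes)) stopifnot(all(spikes >= Tb), all(spikes < Te + 1e-12))
  if (length(history)) stopifnot(max(history) < min(c(spikes, Te)))
  cpp_interval_loglik(Tb, Te, as.numeric(spikes), as.numeric(history),
                      window_start, as.numeric(s_prev), as.numeric(s_curr),
                      lif$a, lif$mu, lif$sigma, lif$x0, lif$x_th,
                      lif$x_minus, kernel$eta, grid$dt, grid$dx, grid$t_max)
}

#' Whole-train log-likelihood under a single stimulus trajectory
#'
#' Sum of log first-passage densities over successive ISIs, each solved
#' with the (possibly time-varying) stimulus and the accumulated spike
#' history, plus the final survival term.  An empty train yields the log
#' survival over the window.
#'
#' @param train a [spike_train()].
#' @param stim stimulus: a number or a function of absolute time.
#' @param lif,kernel,grid model components.
#' @return Log-likelihood (scalar; `-Inf` on underflow).
#' @export
spiketrain_loglik <- function(train, stim, lif = lif_params(),
                              kernel = kernel_bursting(),
                              grid = pde_grid()) {
  stopifnot(inherits(train, "spike_train"))
  sfun <- if (is.function(stim)) stim else function(t) rep(stim, length(t))
  w <- train$window
  events <- c(w[1], train$times)
  ends <- c(train$times, w[2])
  e <- kernel$eta
  hist <- numeric(0)
  ll <- 0
  for (i in seq_along(events)) {
    t0 <- events[i]
    horizon <- min(ends[i] - t0, grid$t_max)
    if (horizon <= 0 && i <= length(train$times)) next
    nsteps <- max(3L, as.integer(ceiling(horizon / grid$dt)) + 2L)
    th <- (seq_len(nsteps) - 0.5) * grid$dt
    off <- sfun(t0 + th)
    if (length(hist)) {
      A0 <- sum(exp(-e[2] * (t0 - hist))); B0 <- sum(exp(-e[4] * (t0 - hist)))
      off <- off + e[1] * A0 * exp(-e[2] * th) - e[3] * B0 * exp(-e[4] * th)
    }
    sol <- cpp_fpt_solve(off, lif$a, lif$mu, lif$sigma, grid$dt, grid$dx,
                         lif$x_minus, lif$x_th, lif$x0, FALSE)
    Fth <- sol$Fth
    tg <- seq(0, by = grid$dt, length.out = nsteps + 1)
    target <- min(ends[i] - t0, grid$t_max)
    if (i <= length(train$times)) {        # ends at a spike: density term
      g <- c(-(Fth[2] - Fth[1]) / grid$dt,
             -(Fth[-c(1, 2)] - Fth[-c(nsteps, nsteps + 1)]) / (2 * grid$dt),
             -(Fth[nsteps + 1] - Fth[nsteps]) / grid$dt)
      g <- pmax(g, 0)
      gv <- stats::approx(tg, g, xout = target, rule = 2)$y
      ll <- ll + if (gv > 0) log(gv) else -Inf
      hist <- c(hist, ends[i])
    } else {                               # ends at window edge: survival
      sv <- min(stats::approx(tg, Fth, xout = target, rule = 2)$y, 1)
      ll <- ll + if (sv > 0) log(sv) else -Inf
    }
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Sample first-passage times of the LIF membrane by Euler-Maruyama
#'
#' Direct stochastic simulation of the membrane SDE from the reset to the
#' threshold under a constant input current: the Monte Carlo route to the
#' ISI distribution, independent of the PDE solver.
#'
#' @param n number of paths.
#' @param drive constant input current.
#' @param lif a [lif_params()].
#' @param sim_dt Euler-Maruyama step, s.
#' @param t_max censoring horizon, s.
#' @param bridge use the within-step Brownian-bridge crossing test,
#'   which removes the O(sqrt(dt)) bias of end-of-step threshold
#'   detection (recommended for oracle-grade comparisons; plain
#'   end-of-step detection matches the spike-train simulator).
#' @return Numeric vector of first-passage times (censored values equal
#'   `t_max`).
#' @export
sample_first_passage <- function(n, drive, lif = lif_params(),
                                 sim_dt = 1e-4, t_max = 2,
                                 bridge = FALSE) {
  cpp_fpt_sample(as.integer(n), drive, lif$a, lif$mu, lif$sigma,
                 lif$x0, lif$x_th, sim_dt, t_max, bridge)
}
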