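#' Evaluate the spike-response kernel
#'
#' @param kernel a [response_kernel()].
#' @param t non-negative time(s) since the spike, s.
#' @return Kernel value(s) \eqn{\eta_1 e^{-\eta_2 t} - \eta_3 e^{-\eta_4 t}}.
#' @export
evaluate_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "response_kernel"))
  if (any(t < 0)) stop("kernel is causal: t must be non-negative")
  e <- kernel$eta
  e[1] * exp(-e[2] * t) - e[3] * exp(-e[4] * t)
}

#' Post-spike current from a spike history
#'
#' Sums the response kernel over all past spikes,
#' \eqn{H(t) = \sum_j k_h(t - t_j)} for \eqn{t_j < t}.
#'
#' @param kernel a [response_kernel()].
#' @param spikes numeric vector of past spike times (may be empty), or a
#'   [spike_train()].
#' @param t evaluation time; all spikes must precede `t`.
#' @return The post-spike current H(t).
#' @export
post_spike_current <- function(kernel, spikes, t) {
  if (inherits(spikes, "spike_train")) spikes <- spikes$times
  if (!length(spikes)) return(0)
  if (any(spikes >= t)) stop("all history spikes must precede t")
  sum(evaluate_kernel(kernel, t - spikes))
}

#' Simulate one Ornstein-Uhlenbeck stimulus component
#'
#' Uses the exact Gaussian transition of the OU process
#' \eqn{dS = (\beta - S)dt + \gamma dW}: over a step of length `dt` the
#' mean is \eqn{(s-\beta)e^{-dt}+\beta} and the variance
#' \eqn{\gamma^2(1 - e^{-2 dt})/2}.
#'
#' @param params a [stimulus_params()].
#' @param k component index.
#' @param s_init initial value; default: a draw from the stationary law
#'   \eqn{N(\beta^k, \gamma^2/2)}.
#' @param duration total simulated time, s.
#' @param dt simulation step, s.
#' @return Numeric vector of length `duration/dt + 1` (value at each grid
#'   time starting at 0).
#' @export
simulate_ou_path <- function(params, k = 1, s_init = NULL,
                             duration = 6, dt = 0.01) {
  stopifnot(inherits(params, "stimulus_params"), duration > 0, dt > 0,
            k >= 1, k <= params$K)
  beta <- params$beta[k]; gam <- params$gamma
  if (is.null(s_init)) s_init <- stats::rnorm(1, beta, gam / sqrt(2))
  n <- round(duration / dt)
  e <- exp(-dt)
  sdv <- gam * sqrt((1 - exp(-2 * dt)) / 2)
  noise <- stats::rnorm(n, 0, sdv)
  dev <- as.numeric(stats::filter(noise, e, method = "recursive"))
  c(s_init, beta + (s_init - beta) * e^(seq_len(n)) + dev)
}

#' Simulate an attention index path
#'
#' In discrete mode one index is drawn per decoding interval from the TPM
#' row of the previous index.  In poisson mode inter-switch times are
#' exponential with the model's rate; at each switch the new index is
#' drawn from the TPM row of the current one.
#'
#' @param model an [attention_model()].
#' @param n_intervals number of decoding intervals to cover.
#' @param c_init initial index; default a uniform draw.
#' @return An object of class `attention_path` with elements `index`
#'   (attended component per interval, defined at interval start for the
#'   poisson mode), and in poisson mode `switches`, a data frame of
#'   switch times and indices.
#' @export
simulate_attention <- function(model, n_intervals, c_init = NULL) {
  stopifnot(inherits(model, "attention_model"), n_intervals >= 1)
  K <- model$K
  if (is.null(c_init)) {
    c_init <- if (K == 1) 1L else sample.int(K, 1)
  }
  stopifnot(c_init >= 1, c_init <= K)
  if (model$switching == "discrete") {
    idx <- integer(n_intervals)
    idx[1] <- c_init
    if (n_intervals > 1 && K > 1) {
      for (n in 2:n_intervals)
        idx[n] <- sample.int(K, 1, prob = model$tpm[idx[n - 1], ])
    } else if (n_intervals > 1) idx[] <- 1L
    out <- list(index = idx, switches = NULL)
  } else {
    t_total <- n_intervals * model$v
    tcur <- 0; ccur <- c_init
    st <- numeric(0); si <- integer(0)
    repeat {
      tcur <- tcur + stats::rexp(1, model$poisson_rate)
      if (tcur >= t_total) break
      ccur <- if (K == 1) 1L else sample.int(K, 1, prob = model$tpm[ccur, ])
      st <- c(st, tcur); si <- c(si, ccur)
    }
    starts <- (seq_len(n_intervals) - 1) * model$v
    idx <- vapply(starts, function(ts) {
      j <- findInterval(ts, st)
      if (j == 0) c_init else si[j]
    }, integer(1))
    out <- list(index = idx,
                switches = data.frame(time = st, index = si))
  }
  out$v <- model$v; out$K <- K; out$switching <- model$switching
  out$c_init <- c_init
  class(out) <- "attention_path"
  out
}

#' Attended component index at arbitrary times
#'
#' @param path an `attention_path`.
#' @param t numeric vector of times (relative to the path's start).
#' @return Integer vector of attended component indices.
#' @export
attended_index <- function(path, t) {
  stopifnot(inherits(path, "attention_path"))
  if (path$switching == "discrete" || is.null(path$switches)) {
    n <- pmin(pmax(floor(t / path$v) + 1L, 1L), length(path$index))
    path$index[n]
  } else {
    j <- findInterval(t, path$switches$time)
    ifelse(j == 0, path$c_init, path$switches$index[pmax(j, 1L)])
  }
}

#' Simulate a mixture of OU stimuli with an attention path
#'
#' Generates the K stimulus component trajectories on a fine grid (0.01 s
#' by default) together with one attention path covering burn-in plus the
#' observation period.
#'
#' @param params a [stimulus_params()].
#' @param model an [attention_model()].
#' @param duration observation period after burn-in, s.
#' @param burn_in burn-in period, s.
#' @param dt fine stimulus grid step, s.
#' @param s_init optional length-K vector of initial stimulus values.
#' @param attention optional pre-simulated `attention_path`; simulated if
#'   missing.
#' @return An object of class `stimulus_mixture_path` with fields `times`
#'   (absolute, starting at 0), `values` (matrix, one column per
#'   component), `attention`, `burn_in`, `duration`, `v`.
#' @export
simulate_stimulus_mixture <- function(params, model, duration = 5,
                                      burn_in = 1, dt = 0.01,
                                      s_init = NULL, attention = NULL) {
  stopifnot(inherits(params, "stimulus_params"),
            inherits(model, "attention_model"),
            params$K == model$K)
  total <- burn_in + duration
  n_int <- ceiling(round(total / model$v, 9))
  if (is.null(attention)) attention <- simulate_attention(model, n_int)
  vals <- sapply(seq_len(params$K), function(k)
    simulate_ou_path(params, k,
                     s_init = if (is.null(s_init)) NULL else s_init[k],
                     duration = total, dt = dt))
  vals <- matrix(vals, ncol = params$K)
  structure(list(times = seq(0, by = dt, length.out = nrow(vals)),
                 values = vals, attention = attention,
                 burn_in = burn_in, duration = duration,
                 dt = dt, v = model$v, K = params$K),
            class = "stimulus_mixture_path")
}

#' Attended stimulus drive on the fine grid
#' @param path a `stimulus_mixture_path`.
#' @return Numeric vector: the value of the attended component at each
#'   fine grid time.
#' @keywords internal
attended_drive <- function(path) {
  idx <- attended_index(path$attention, path$times)
  path$values[cbind(seq_along(idx), idx)]
}

#' Simulate a spike train from the LIF encoding model
#'
#' Euler-Maruyama integration of the membrane SDE with the attended
#' stimulus as input current; a threshold crossing detected at the end of
#' a step records a spike at the step's right endpoint and resets the
#' membrane.  Spikes fired during burn-in feed the post-spike current but
#' are not part of the returned train; they are attached as attribute
#' `"burnin_spikes"`.
#'
#' @param lif a [lif_params()].
#' @param kernel a [response_kernel()].
#' @param path a `stimulus_mixture_path` (from
#'   [simulate_stimulus_mixture()]).
#' @param sim_dt Euler-Maruyama step, s.
#' @return A [spike_train()] on the window
#'   `[burn_in, burn_in + duration]`.
#' @export
simulate_spike_train <- function(lif, kernel, path, sim_dt = 1e-4) {
  stopifnot(inherits(lif, "lif_params"), inherits(kernel, "response_kernel"),
            inherits(path, "stimulus_mixture_path"))
  total <- path$burn_in + path$duration
  drive <- attended_drive(path)
  sp <- cpp_sim_lif(drive, path$dt, lif$a, lif$mu, lif$sigma,
                    lif$x0, lif$x_th, kernel$eta, sim_dt, total)
  keep <- sp >= path$burn_in
  train <- spike_train(sp[keep], c(path$burn_in, total))
  attr(train, "burnin_spikes") <- sp[!keep]
  train
}

#' Simulate a population of spike trains
#'
#' Serial processing: all M neurons share one attention path (they attend
#' the same component and switch together).  Parallel processing: each
#' neuron carries its own independent attention path.  The K physical
#' stimulus trajectories are shared in both modes; membrane noise is
#' independent across neurons.
#'
#' @param M number of neurons.
#' @param mode `"serial"` or `"parallel"`.
#' @param lif,kernel,params,model,duration,burn_in,dt,sim_dt as in
#'   [simulate_stimulus_mixture()] and [simulate_spike_train()].
#' @return A list with `trains` (list of [spike_train()]), `paths` (list
#'   of `stimulus_mixture_path`, one per neuron, sharing `values`),
#'   `values`, `times` and `mode`.
#' @export
simulate_population <- function(M, mode = c("serial", "parallel"),
                                lif, kernel, params, model,
                                duration = 5, burn_in = 1, dt = 0.01,
                                sim_dt = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(M >= 1)
  base <- simulate_stimulus_mixture(params, model, duration, burn_in, dt)
  n_int <- length(base$attention$index)
  paths <- vector("list", M)
  for (m in seq_len(M)) {
    p <- base
    if (mode == "parallel" && m > 1)
      p$attention <- simulate_attention(model, n_int)
    paths[[m]] <- p
  }
  trains <- lapply(paths, function(p) simulate_spike_train(lif, kernel, p,
                                                           sim_dt = sim_dt))
  list(trains = trains, paths = paths, values = base$values,
       times = base$times, mode = mode)
}

#' Static probability-mixing log-likelihood of spike trains
#'
#' Whole-trial likelihood under the static mixing model: each train is
#' generated by exactly one component, component k with probability
#' `alpha[k]`, so
#' \eqn{p(y) = \prod_m \sum_k \alpha_k p(y^m | s^k)}.
#'
#' @param trains a [spike_train()] or list of them.
#' @param path a `stimulus_mixture_path` carrying the K component
#'   trajectories.
#' @param alpha a [mixture_weights()].
#' @param lif,kernel,grid model components for the first-passage
#'   likelihood.
#' @return Log-likelihood (log scale; the per-train mixture is a convex
#'   combination of single-component likelihoods).
#' @export
mixture_spiketrain_loglik <- function(trains, path, alpha, lif, kernel,
                                      grid = pde_grid()) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  stopifnot(inherits(alpha, "mixture_weights"), alpha$K == path$K)
  total <- 0
  for (tr in trains) {
    ll <- vapply(seq_len(path$K), function(k)
      spiketrain_loglik(tr, stimulus_fun(path, k), lif, kernel, grid),
      numeric(1))
    la <- log(alpha$alpha)
    v <- la + ll
    m <- max(v)
    total <- total + if (is.finite(m)) m + log(sum(exp(v - m))) else -Inf
  }
  total
}

#' Component trajectory as a step function of time
#' @param path a `stimulus_mixture_path`.
#' @param k component index.
#' @return A function of absolute time returning the component value
#'   (piecewise constant on the fine grid).
#' @export
stimulus_fun <- function(path, k) {
  times <- path$times; vals <- path$values[, k]
  function(t) vals[pmin(pmax(findInterval(t, times), 1L), length(vals))]
}
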