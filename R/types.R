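#' LIF model parameters
#'
#' Parameters of the leaky integrate-and-fire membrane model
#' \eqn{dX = (-a(X-\mu) + I(t) + H(t))\,dt + \sigma\,dW}.  The membrane
#' potential is dimensionless: it is measured in units of the distance
#' between the reset potential and the spike threshold, so the defaults
#' place the reset at 0.4 and the threshold at 1.
#'
#' @param a decay (leak) rate, 1/s.
#' @param mu resting potential.
#' @param sigma membrane diffusion coefficient.
#' @param x0 reset potential.
#' @param x_th firing threshold.
#' @param x_minus lower reflecting boundary used by the numerical
#'   Fokker-Planck solver.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(a = 100, mu = 0.5, sigma = 1, x0 = 0.4,
                       x_th = 1, x_minus = 0) {
  stopifnot(a > 0, sigma > 0, x_minus <= x0, x0 < x_th)
  structure(list(a = a, mu = mu, sigma = sigma, x0 = x0,
                 x_th = x_th, x_minus = x_minus),
            class = "lif_params")
}

#' Spike-response kernel
#'
#' Difference-of-exponentials post-spike kernel
#' \eqn{k_h(t) = \eta_1 e^{-\eta_2 t} - \eta_3 e^{-\eta_4 t}}.  Depending
#' on the coefficients the kernel produces bursting (excitation followed
#' by inhibition), decaying (slow adaptation) or delaying (refractory)
#' spiking behaviour.
#'
#' @param eta numeric vector of the four non-negative coefficients.
#' @param label descriptive label.
#' @return An object of class `response_kernel`.
#' @export
response_kernel <- function(eta, label = "custom") {
  eta <- as.numeric(eta)
  stopifnot(length(eta) == 4, all(is.finite(eta)), all(eta >= 0))
  structure(list(eta = eta, label = label), class = "response_kernel")
}

#' @rdname response_kernel
#' @export
kernel_bursting <- function() response_kernel(c(50, 25, 40, 15), "bursting")

#' @rdname response_kernel
#' @export
kernel_decaying <- function() response_kernel(c(0, 0, 2, 0.5), "decaying")

#' @rdname response_kernel
#' @export
kernel_delaying <- function() response_kernel(c(20, 8, 50, 15), "delaying")

#' @rdname response_kernel
#' @export
kernel_none <- function() response_kernel(c(0, 1, 0, 1), "none")

#' Ornstein-Uhlenbeck stimulus parameters
#'
#' Each of the K stimulus components follows
#' \eqn{dS^k = (\beta^k - S^k)\,dt + \gamma\,dW}; the mean-reversion
#' levels `beta` are component specific while the diffusion `gamma` is
#' shared.
#'
#' @param beta numeric vector of K drift levels.
#' @param gamma common diffusion coefficient, > 0.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(beta, gamma) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) >= 1, all(is.finite(beta)), gamma > 0)
  structure(list(beta = beta, gamma = gamma, K = length(beta)),
            class = "stimulus_params")
}

#' Markov attention-switching model
#'
#' Attention switches between the K stimulus components following a
#' Markov chain with a row-stochastic transition probability matrix.  In
#' `discrete` mode switches can only occur at the boundaries of decoding
#' intervals of length `v`; in `poisson` mode switch times follow a
#' Poisson process and the new component is drawn from the TPM row of the
#' current one (self-transitions allowed).
#'
#' @param tpm K x K row-stochastic matrix.
#' @param v decoding interval length in seconds.
#' @param switching `"discrete"` or `"poisson"`.
#' @param poisson_rate switch rate (1/s), used only in poisson mode.
#' @return An object of class `attention_model`.
#' @export
attention_model <- function(tpm, v = 0.1,
                            switching = c("discrete", "poisson"),
                            poisson_rate = 2) {
  switching <- match.arg(switching)
  tpm <- as.matrix(tpm)
  stopifnot(nrow(tpm) == ncol(tpm), all(tpm >= 0),
            all(abs(rowSums(tpm) - 1) < 1e-12), v > 0)
  if (switching == "poisson") stopifnot(poisson_rate > 0)
  structure(list(tpm = tpm, v = v, switching = switching,
                 poisson_rate = poisson_rate, K = nrow(tpm)),
            class = "attention_model")
}

#' Study transition probability matrices
#'
#' The two- and three-component attention TPMs used throughout the
#' simulation study.
#' @param K number of stimulus components (1, 2 or 3).
#' @return A K x K row-stochastic matrix.
#' @export
study_tpm <- function(K) {
  switch(as.character(K),
         "1" = matrix(1, 1, 1),
         "2" = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE),
         "3" = matrix(c(0.5, 0.2, 0.3,
                        0.3, 0.5, 0.2,
                        0.2, 0.3, 0.5), 3, 3, byrow = TRUE),
         stop("no study TPM for K = ", K))
}

#' Spike train
#'
#' Ordered spike times of one neuron in one trial.  Only the spike times
#' are observed; the membrane potential is latent.
#'
#' @param times strictly increasing spike times in seconds.
#' @param window numeric length-2 observation window (start, end).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, window) {
  times <- as.numeric(times)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (length(times)) {
    stopifnot(all(diff(times) > 0),
              all(times >= window[1]), all(times <= window[2]))
  }
  structure(list(times = times, window = as.numeric(window)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in [%.3f, %.3f] s\n",
              length(x$times), x$window[1], x$window[2]))
  invisible(x)
}

#' Numerical grid of the Fokker-Planck solver
#'
#' @param dt time step of the Crank-Nicolson scheme, s.
#' @param dx potential step.
#' @param t_max horizon cap per solve, s; a solve whose natural horizon
#'   (interval length plus time elapsed since the last spike) exceeds the
#'   cap is clamped to it.
#' @return An object of class `pde_grid`.
#' @export
pde_grid <- function(dt = 0.002, dx = 0.02, t_max = 2) {
  stopifnot(dt > 0, dx > 0, t_max > 0)
  structure(list(dt = dt, dx = dx, t_max = t_max), class = "pde_grid")
}

#' Mixture weights of the static probability-mixing model
#'
#' @param alpha non-negative probabilities summing to one.
#' @return An object of class `mixture_weights`.
#' @export
mixture_weights <- function(alpha) {
  alpha <- as.numeric(alpha)
  stopifnot(all(alpha >= 0), abs(sum(alpha) - 1) < 1e-8)
  structure(list(alpha = alpha, K = length(alpha)),
            class = "mixture_weights")
}
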