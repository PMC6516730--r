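#' Uniform initialization ranges of the particle ensemble
#'
#' @param max_gamma,max_beta,max_S upper bounds of the uniform
#'   initializers of the stimulus diffusion, the drift levels and the
#'   stimulus values.
#' @return An object of class `init_ranges`.
#' @export
init_ranges <- function(max_gamma = 40, max_beta = 200, max_S = 200) {
  stopifnot(max_gamma > 0, max_beta > 0, max_S > 0)
  structure(list(max_gamma = max_gamma, max_beta = max_beta,
                 max_S = max_S), class = "init_ranges")
}

#' State-propagation configuration
#'
#' Variances of the artificial parameter dynamics, the Liu-West discount
#' and the decoding interval length used as the OU transition step.
#'
#' @param V_lambda Dirichlet concentration scale of the TPM propagation.
#' @param V_gamma,V_beta random-walk variances of the diffusion and drift
#'   parameters.
#' @param delta Liu-West discount factor in (0, 1].
#' @param v decoding interval length, s.
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(V_lambda = 0.02, V_gamma = 1, V_beta = 4,
                               delta = 0.95, v = 0.1) {
  stopifnot(V_lambda > 0, V_gamma > 0, V_beta > 0,
            delta > 0, delta <= 1, v > 0)
  structure(list(V_lambda = V_lambda, V_gamma = V_gamma, V_beta = V_beta,
                 delta = delta, v = v), class = "propagation_config")
}

#' Liu-West shrinkage constants
#' @param delta discount factor in (0, 1].
#' @return List with shrinkage `psi = (3*delta - 1) / (2*delta)` and
#'   jitter variance factor `h2 = 1 - psi^2`.
#' @export
liu_west_constants <- function(delta) {
  stopifnot(delta > 0, delta <= 1)
  psi <- (3 * delta - 1) / (2 * delta)
  list(psi = psi, h2 = 1 - psi^2)
}

#' Positive-truncated normal draws
#'
#' Rejection sampling from the untruncated normal, falling back to the
#' inverse-CDF method for elements whose acceptance probability is below
#' 10 percent.
#'
#' @param n number of draws.
#' @param mean,sd pre-truncation mean(s) and standard deviation(s).
#' @return Positive draws.
#' @export
rtnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- numeric(n)
  zero_sd <- sd <= 0
  out[zero_sd] <- mean[zero_sd]
  todo <- which(!zero_sd)
  acc <- 1 - stats::pnorm(0, mean[todo], sd[todo])
  hard <- todo[acc < 0.1]
  easy <- todo[acc >= 0.1]
  if (length(easy)) {
    pending <- easy
    for (it in 1:100) {
      if (!length(pending)) break
      draw <- stats::rnorm(length(pending), mean[pending], sd[pending])
      ok <- draw > 0
      out[pending[ok]] <- draw[ok]
      pending <- pending[!ok]
    }
    hard <- c(hard, pending)
  }
  if (length(hard)) {
    p0 <- stats::pnorm(0, mean[hard], sd[hard])
    u <- p0 + stats::runif(length(hard)) * (1 - p0)
    q <- stats::qnorm(pmin(u, 1 - 1e-16), mean[hard], sd[hard])
    out[hard] <- pmax(q, .Machine$double.xmin)
  }
  out
}

#' Initialize a particle ensemble
#'
#' TPM rows are symmetric Dirichlet(1, ..., 1) draws, the attention index
#' uniform on the K components, and the diffusion, drift and stimulus
#' values uniform on their initialization ranges.  With `K = 1` the TPM
#' and attention are degenerate and no random numbers are consumed for
#' them, so single-component runs of different filters share RNG streams.
#'
#' @param K number of stimulus components.
#' @param I number of particles.
#' @param ranges an [init_ranges()].
#' @return An object of class `particle_ensemble`: `tpm` (I x K x K
#'   array), `C` (integer I), `gam` (numeric I), `beta`, `S` (I x K
#'   matrices), `logw`/`w` (weights).
#' @export
init_ensemble <- function(K, I, ranges = init_ranges()) {
  stopifnot(K >= 1, I >= 2, inherits(ranges, "init_ranges"))
  tpm <- array(1, dim = c(I, K, K))
  C <- rep(1L, I)
  if (K > 1) {
    g <- array(stats::rgamma(I * K * K, shape = 1), dim = c(I, K, K))
    tpm <- g / array(rep(apply(g, c(1, 2), sum), K), dim = c(I, K, K))
    C <- sample.int(K, I, replace = TRUE)
  }
  structure(list(
    K = K, I = I,
    tpm = tpm, C = C,
    gam = stats::runif(I, 0, ranges$max_gamma),
    beta = matrix(stats::runif(I * K, 0, ranges$max_beta), I, K),
    S = matrix(stats::runif(I * K, 0, ranges$max_S), I, K),
    logw = rep(0, I), w = rep(1 / I, I)),
    class = "particle_ensemble")
}

#' Propagate the transition probability matrices
#'
#' Each row of each particle's TPM is redrawn from a Dirichlet
#' distribution with parameter vector `row / V_lambda`, so the expected
#' new row equals the old one and `V_lambda` scales the jitter.  Zero
#' entries are floored at 1e-8 before sampling.
#'
#' @param tpm I x K x K array of row-stochastic matrices.
#' @param V_lambda concentration scale.
#' @return Propagated array (rows remain stochastic).
#' @export
propagate_tpm <- function(tpm, V_lambda) {
  d <- dim(tpm); K <- d[2]
  if (K == 1) return(tpm)
  shape <- pmax(tpm / V_lambda, 1e-8)
  g <- array(stats::rgamma(length(shape), shape = shape), dim = d)
  rs <- apply(g, c(1, 2), sum)
  bad <- rs < 1e-300
  if (any(bad)) {           # extreme underflow: keep the previous row
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      g[idx[r, 1], idx[r, 2], ] <- tpm[idx[r, 1], idx[r, 2], ]
    rs <- apply(g, c(1, 2), sum)
  }
  g / array(rep(rs, K), dim = d)
}

#' Propagate the attention indices
#'
#' Draws each particle's new index from the row of its own TPM given by
#' the previous index.  With `K = 1` no randomness is consumed.
#'
#' @param C integer vector of current indices.
#' @param tpm I x K x K array.
#' @return Integer vector of new indices.
#' @export
propagate_attention <- function(C, tpm) {
  K <- dim(tpm)[2]
  if (K == 1) return(rep(1L, length(C)))
  I <- length(C)
  P <- sapply(seq_len(K), function(l) tpm[cbind(seq_len(I), C, l)])
  P <- matrix(P, I, K)
  cs <- P %*% upper.tri(diag(K), diag = TRUE)
  u <- stats::runif(I)
  max.col(cs >= u, ties.method = "first")
}

#' Random-walk propagation of the stimulus diffusion parameter
#' @param gam positive current values.
#' @param V_gamma random-walk variance.
#' @return Positive-truncated normal draws centred at `gam`.
#' @export
propagate_gamma_rw <- function(gam, V_gamma) {
  rtnorm_pos(length(gam), gam, sqrt(V_gamma))
}

#' Liu-West kernel-smoothed propagation of the diffusion parameter
#'
#' Shrinks each particle's value towards the weighted posterior mean with
#' factor `psi` and jitters with variance `h2 * v_n`, where `v_n` is the
#' weighted posterior variance; positive-truncated.  With `delta = 1`
#' (or a degenerate posterior) this is the identity map.
#'
#' @param gam particle values.
#' @param weights normalized weights used to form the posterior moments.
#' @param delta discount factor.
#' @return Propagated values.
#' @export
propagate_gamma_liu_west <- function(gam, weights, delta) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  lw <- liu_west_constants(delta)
  gbar <- sum(weights * gam)
  vn <- sum(weights * (gam - gbar)^2)
  m <- lw$psi * gam + (1 - lw$psi) * gbar
  if (lw$h2 * vn <= 0) return(m)
  rtnorm_pos(length(gam), m, sqrt(lw$h2 * vn))
}

#' Random-walk propagation of the drift levels
#' @param beta I x K matrix.
#' @param V_beta variance of the independent componentwise jitter.
#' @return Propagated matrix (unconstrained in sign).
#' @export
propagate_beta <- function(beta, V_beta) {
  beta + matrix(stats::rnorm(length(beta), 0, sqrt(V_beta)),
                nrow(beta), ncol(beta))
}

#' Exact OU propagation of the stimulus values
#'
#' One exact Ornstein-Uhlenbeck transition of step `v` per component:
#' mean \eqn{(S - \beta)e^{-v} + \beta}, variance
#' \eqn{\gamma^2 (1 - e^{-2v})/2}.
#'
#' @param S I x K matrix of current values.
#' @param beta I x K matrix of drift levels.
#' @param gam length-I diffusion parameters.
#' @param v transition step (the decoding interval length), s.
#' @return Propagated I x K matrix.
#' @export
propagate_stimulus <- function(S, beta, gam, v) {
  e <- exp(-v)
  M <- (S - beta) * e + beta
  sdv <- gam * sqrt((1 - exp(-2 * v)) / 2)
  M + matrix(stats::rnorm(length(S)), nrow(S), ncol(S)) * sdv
}
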