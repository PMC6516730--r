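#' Relative root-mean-square deviation of interval-constant estimates
#'
#' The decoder reports one constant per 0.1 s interval while the true
#' stimulus moves on a 0.01 s grid, so even a perfect interval-constant
#' decoder has positive RMSD.  The rRMSD therefore normalizes the RMSD
#' of the estimates by the RMSD of the best interval-constant oracle,
#' the per-interval mean of the fine-grid truth:
#' \deqn{\mathrm{rRMSD} = \sqrt{\sum_{n,l} (\hat S_n - S_{n,l})^2} \Big/
#'       \sqrt{\sum_{n,l} (\hat S^*_n - S_{n,l})^2},
#'       \quad \hat S^*_n = \tfrac1{10}\sum_{l=1}^{10} S_{n,l}.}
#' Its best achievable value is 1.
#'
#' @param estimates length-N vector of per-interval estimates.
#' @param truth N x L matrix of fine-grid true values (L sub-steps per
#'   interval, 10 for the 0.1 s / 0.01 s grids).
#' @return The rRMSD ratio.  If the truth is constant within every
#'   interval the oracle RMSD vanishes; the value is then 1 when the
#'   numerator also vanishes and `Inf` (with a warning) otherwise.
#' @export
rrmsd <- function(estimates, truth) {
  truth <- as.matrix(truth)
  N <- nrow(truth)
  stopifnot(length(estimates) == N)
  oracle <- rowMeans(truth)
  num <- sum((estimates - truth)^2)
  den <- sum((oracle - truth)^2)
  if (den == 0) {
    if (num == 0) return(1)
    warning("interval-constant truth: rRMSD undefined, returning Inf")
    return(Inf)
  }
  sqrt(num / den)
}

#' Per-component rRMSD for multi-component estimates
#'
#' For the marginal filters all K sorted components are reported; each
#' estimate column is compared against the true components after sorting
#' the latter per interval by their interval means, the same ordering
#' convention the estimates use.
#'
#' @param estimates N x K matrix of sorted component estimates.
#' @param truth N x L x K array of fine-grid true component values.
#' @return Length-K vector of rRMSD values.
#' @export
rrmsd_components <- function(estimates, truth) {
  stopifnot(length(dim(truth)) == 3, ncol(estimates) == dim(truth)[3])
  N <- dim(truth)[1]; K <- dim(truth)[3]
  means <- apply(truth, c(1, 3), mean)
  sorted <- truth
  for (n in seq_len(N)) {
    ord <- order(means[n, ])
    sorted[n, , ] <- truth[n, , ord]
  }
  vapply(seq_len(K), function(k) rrmsd(estimates[, k], sorted[, , k]),
         numeric(1))
}

#' Effective sample size of normalized particle weights
#'
#' \eqn{N_{eff} = 1 / \sum_i \bar w_i^2}: equals the particle count for
#' uniform weights and 1 for a degenerate ensemble.
#'
#' @param weights normalized weights.
#' @return ESS in `[1, length(weights)]`.
#' @export
ess <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  1 / sum(weights^2)
}

#' Fine-grid truth of the attended stimulus, per interval
#'
#' Builds the N x L truth matrix consumed by [rrmsd()] from a simulated
#' stimulus path: the attended component value at each fine sub-step of
#' each decoding interval of the observation window.
#'
#' @param path a `stimulus_mixture_path`.
#' @param attention optional `attention_path` overriding the one stored
#'   in the path (e.g. a specific neuron's path under parallel
#'   processing).
#' @return N x L matrix (L = `v / dt` sub-steps).
#' @export
attended_truth <- function(path, attention = NULL) {
  att <- if (is.null(attention)) path$attention else attention
  L <- round(path$v / path$dt)
  N <- round(path$duration / path$v)
  t0 <- path$burn_in
  out <- matrix(NA_real_, N, L)
  for (n in seq_len(N)) {
    tt <- t0 + (n - 1) * path$v + (seq_len(L) - 1) * path$dt
    idx <- attended_index(att, tt)
    ti <- pmin(pmax(round(tt / path$dt) + 1L, 1L), nrow(path$values))
    out[n, ] <- path$values[cbind(ti, idx)]
  }
  out
}

#' Fine-grid truth of all stimulus components, per interval
#' @param path a `stimulus_mixture_path`.
#' @return N x L x K array consumed by [rrmsd_components()].
#' @export
component_truth <- function(path) {
  L <- round(path$v / path$dt)
  N <- round(path$duration / path$v)
  K <- path$K
  t0 <- path$burn_in
  out <- array(NA_real_, c(N, L, K))
  for (n in seq_len(N)) {
    tt <- t0 + (n - 1) * path$v + (seq_len(L) - 1) * path$dt
    ti <- pmin(pmax(round(tt / path$dt) + 1L, 1L), nrow(path$values))
    out[n, , ] <- path$values[ti, ]
  }
  out
}
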