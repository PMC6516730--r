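#' Fixed-lag smoothed estimate from stored values and ancestry
#'
#' Applies the current filtering weights to each particle's ancestral
#' state at the target step, traced backwards through the resampling
#' ancestry.  With an empty ancestor list this reduces to the filtering
#' estimate.
#'
#' @param values I x K matrix of per-particle reported values at the
#'   target step (a vector is treated as one column).
#' @param ancestors list of ancestor index vectors
#'   \eqn{A_{r+1}, \dots, A_n} (each maps particles of one step to their
#'   ancestors at the previous step), newest last.
#' @param weights normalized filtering weights at the current step n.
#' @return Weighted estimate (length K) with attribute `"index"`, the
#'   traced ancestor index of each current particle.
#' @export
fixed_lag_estimate <- function(values, ancestors, weights) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  idx <- seq_along(weights)
  for (Am in rev(ancestors)) idx <- Am[idx]
  est <- colSums(weights * values[idx, , drop = FALSE])
  attr(est, "index") <- idx
  est
}

smooth_fixed_lag <- function(res, lag) {
  N <- res$N
  out <- matrix(NA_real_, N, res$Kout)
  for (r in seq_len(N)) {
    n_use <- min(r + lag, N)
    ancs <- if (n_use > r) res$ancestry[(r + 1):n_use] else list()
    out[r, ] <- fixed_lag_estimate(res$val_hist[r, , , drop = TRUE],
                                   ancs, res$weights[n_use, ])
  }
  out
}

#' Pairwise particle transition log-densities between two steps
#'
#' Log of the state-transition density \eqn{p(z_{n+1,j} | z_{n,i})}
#' under the propagation laws of the filters: Dirichlet for the TPM
#' rows, categorical for the attention index (using particle j's own
#' TPM), truncated normal (or Liu-West shrinkage normal) for the
#' diffusion parameter, independent normals for the drift levels and the
#' exact OU transition for the stimulus components.
#'
#' @param snap_n,snap_np1 particle snapshots (lists with `tpm`, `C`,
#'   `gam`, `beta`, `S`, and for `snap_np1` optionally `lw` with the
#'   Liu-West moments used at that step).
#' @param prop a [propagation_config()].
#' @param gamma_model `"rw"` for the random-walk propagation of the
#'   bootstrap filters, `"liu_west"` for the auxiliary filters.
#' @param include_C include the attention-index factor (FALSE for the
#'   marginal filters, whose state carries no attention index).
#' @return I x I matrix; rows index particles at step n, columns at
#'   step n+1.
#' @export
particle_transition_logdens <- function(snap_n, snap_np1, prop,
                                        gamma_model = c("rw", "liu_west"),
                                        include_C = TRUE) {
  gamma_model <- match.arg(gamma_model)
  I <- length(snap_n$gam)
  K <- ncol(snap_n$S)
  logP <- matrix(0, I, I)

  if (K > 1) {
    ## Dirichlet factor for all TPM rows:
    ## log f = sum_rows [ lgamma(1/Vl) - sum_l lgamma(shape) +
    ##                    sum_l (shape - 1) log lambda' ]
    Vl <- prop$V_lambda
    shp <- matrix(pmax(aperm(snap_n$tpm, c(1, 2, 3)), 1e-8) / Vl, I)
    lt <- matrix(log(pmax(snap_np1$tpm, 1e-300)), I)
    normc <- K * lgamma(1 / Vl) - rowSums(lgamma(shp))
    logP <- logP + normc + (shp - 1) %*% t(lt)
    if (include_C) {
      MC <- matrix(0, I, I)
      for (k in seq_len(K)) {
        Tk <- snap_np1$tpm[cbind(seq_len(I), k, snap_np1$C)]
        MC[snap_n$C == k, ] <- rep(log(pmax(Tk, 1e-300)),
                                   each = sum(snap_n$C == k))
      }
      logP <- logP + MC
    }
  }

  if (gamma_model == "rw") {
    sd <- sqrt(prop$V_gamma)
    logP <- logP +
      outer(snap_n$gam, snap_np1$gam,
            function(g, gp) stats::dnorm(gp, g, sd, log = TRUE) -
              stats::pnorm(0, g, sd, lower.tail = FALSE, log.p = TRUE))
  } else {
    lw <- liu_west_constants(prop$delta)
    st <- snap_np1$lw
    if (!is.null(st) && lw$h2 * st$vn > 1e-12) {
      sd <- sqrt(lw$h2 * st$vn)
      mns <- lw$psi * snap_n$gam + (1 - lw$psi) * st$gbar
      logP <- logP +
        outer(mns, snap_np1$gam,
              function(m, gp) stats::dnorm(gp, m, sd, log = TRUE) -
                stats::pnorm(0, m, sd, lower.tail = FALSE, log.p = TRUE))
    }
    # degenerate jitter (vn ~ 0): the map is deterministic; the factor
    # is dropped rather than approximated by a spike
  }

  sdb <- sqrt(prop$V_beta)
  for (k in seq_len(K))
    logP <- logP + outer(snap_n$beta[, k], snap_np1$beta[, k],
                         function(b, bp) stats::dnorm(bp, b, sdb,
                                                      log = TRUE))

  e <- exp(-prop$v)
  sds <- snap_np1$gam * sqrt((1 - exp(-2 * prop$v)) / 2)
  for (k in seq_len(K)) {
    mean_ij <- e * outer(snap_n$S[, k], rep(1, I)) +
      (1 - e) * matrix(snap_np1$beta[, k], I, I, byrow = TRUE)
    sp <- matrix(snap_np1$S[, k], I, I, byrow = TRUE)
    sdm <- matrix(pmax(sds, 1e-12), I, I, byrow = TRUE)
    logP <- logP - 0.5 * ((sp - mean_ij) / sdm)^2 - log(sdm) -
      0.5 * log(2 * pi)
  }
  logP
}

#' Backward smoothing weights by forward-filtering backward-smoothing
#'
#' One backward recursion over a window of particle snapshots: starting
#' from the filtering weights at the last snapshot, the smoothed weights
#' at each earlier step are
#' \deqn{\bar w^*_{n,i} = \bar w_{n,i} \sum_j
#'   \frac{p(z_{n+1,j} | z_{n,i}) \bar w^*_{n+1,j}}
#'        {\sum_l p(z_{n+1,j} | z_{n,l}) \bar w_{n,l}},}
#' normalized at every step.  If a column denominator vanishes (no
#' particle reaches a successor) the recursion falls back to the
#' filtering weights for that step with a warning.
#'
#' @param filter_weights list of normalized filtering weight vectors,
#'   oldest first.
#' @param trans_logdens list of pairwise transition log-density matrices
#'   (`length(filter_weights) - 1` of them; element m links snapshot m to
#'   m+1).
#' @param warn emit a warning when a backward step falls back to the
#'   filtering weights.
#' @return List of smoothed weight vectors (same length/order as
#'   `filter_weights`; the last equals its filtering weights).
#' @export
ffbs_smoothing_weights <- function(filter_weights, trans_logdens,
                                   warn = TRUE) {
  L <- length(filter_weights)
  stopifnot(length(trans_logdens) == L - 1)
  out <- vector("list", L)
  out[[L]] <- filter_weights[[L]]
  if (L == 1) return(out)
  fallback <- function(m, wn) {
    if (warn)
      warning("FFBS denominator vanished; falling back to filtering ",
              "weights for one step")
    wn
  }
  for (m in (L - 1):1) {
    wn <- filter_weights[[m]]
    wstar <- out[[m + 1]]
    lp <- trans_logdens[[m]]
    fin <- is.finite(lp)
    if (!any(fin)) { out[[m]] <- fallback(m, wn); next }
    P <- exp(lp - max(lp[fin]))       # overall scale cancels below
    denom <- as.numeric(crossprod(P, wn))
    if (any(denom <= 0 & wstar > 0)) { out[[m]] <- fallback(m, wn); next }
    ratio <- ifelse(denom > 0, wstar / denom, 0)
    ws <- wn * as.numeric(P %*% ratio)
    s <- sum(ws)
    out[[m]] <- if (is.finite(s) && s > 0) ws / s else fallback(m, wn)
  }
  out
}

smooth_ffbs <- function(res, lag, gamma_model, include_C) {
  N <- res$N
  snaps <- res$snapshots
  # pairwise transition matrices between consecutive snapshots, cached
  trans <- vector("list", N - 1)
  for (m in seq_len(N - 1))
    trans[[m]] <- particle_transition_logdens(snaps[[m]], snaps[[m + 1]],
                                              res$prop, gamma_model,
                                              include_C)
  out <- matrix(NA_real_, N, res$Kout)
  for (r in seq_len(N)) {
    n_use <- min(r + lag, N)
    fw <- lapply(r:n_use, function(m) res$weights[m, ])
    td <- if (n_use > r) trans[r:(n_use - 1)] else list()
    ws <- ffbs_smoothing_weights(fw, td, warn = FALSE)[[1]]
    vals <- res$val_hist[r, , , drop = TRUE]
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
    out[r, ] <- colSums(ws * vals)
  }
  out
}

#' Semi-online smoothed decoding
#'
#' Re-reports the estimates of a completed filter run with a smoothing
#' delay: at each interval n the estimate for interval n - lag is formed
#' from the posterior given data up to n (fixed-lag by ancestry
#' marginalization, or forward-filtering backward-smoothing).  The final
#' `lag` intervals are reported with the shorter lags available at the
#' end of the run; equivalently, a lag at least the run length gives
#' full offline smoothing.
#'
#' @param result an `smc_decoding` run with `keep_particles = TRUE` (for
#'   `type = "fb"`) or any run (for `type = "lag"`).
#' @param lag delay in intervals.
#' @param type `"lag"` or `"fb"`.
#' @return Matrix of smoothed estimates (intervals x components).
#' @export
semi_online_smoother <- function(result, lag = 10,
                                 type = c("lag", "fb")) {
  type <- match.arg(type)
  stopifnot(inherits(result, "smc_decoding"), lag >= 1)
  if (type == "lag") return(smooth_fixed_lag(result, lag))
  if (is.null(result$snapshots))
    stop("fb smoothing needs a run with keep_particles = TRUE")
  gamma_model <- if (result$method %in% c("apf", "mapf"))
    "liu_west" else "rw"
  smooth_ffbs(result, lag, gamma_model,
              include_C = !result$method %in% c("mbf", "mapf"))
}
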