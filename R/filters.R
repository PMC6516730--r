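#' Systematic resampling
#'
#' Draws one uniform offset, places I equally spaced grid points on
#' (0, 1] and counts how many fall in each increment of the cumulative
#' weights.  The duplicate counts sum to I and are unbiased,
#' E(W_i) = I * w_i; resampled particles carry weight 1/I.
#'
#' @param weights normalized weights.
#' @return Integer vector of ancestor indices of length `length(weights)`
#'   (particle i appears `W_i` times), with attribute `"counts"`.
#' @export
systematic_resample <- function(weights) {
  I <- length(weights)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  u <- stats::runif(1)
  grid <- (seq_len(I) - 1 + u) / I
  cw <- pmin(cumsum(weights), 1)
  cw[I] <- 1
  anc <- findInterval(grid, c(0, cw), left.open = TRUE)
  anc <- pmin(pmax(anc, 1L), I)
  counts <- tabulate(anc, nbins = I)
  structure(anc, counts = counts)
}

#' Marginalize the attention state of the interval likelihood
#'
#' One step of the forward recursion integrating the attended component
#' out of the likelihood: given the filtered attention posterior of the
#' previous interval, the transition matrix and the per-component
#' interval log-likelihoods, returns the attention-marginal interval
#' log-likelihood and the updated posterior.
#'
#' @param post_prev filtered posterior over components (vector of K
#'   probabilities, or an I x K matrix for a particle batch).
#' @param tpm K x K matrix, or I x K x K array for a batch.
#' @param comp_loglik per-component interval log-likelihoods (length K or
#'   I x K).
#' @return List with `loglik` (length I) and `post` (I x K filtered
#'   posterior for the current interval).
#' @export
marginal_attention_update <- function(post_prev, tpm, comp_loglik) {
  if (is.null(dim(post_prev))) post_prev <- matrix(post_prev, 1)
  if (is.null(dim(comp_loglik))) comp_loglik <- matrix(comp_loglik, 1)
  K <- ncol(post_prev)
  I <- nrow(post_prev)
  if (length(dim(tpm)) == 2) tpm <- array(rep(tpm, each = I), c(I, K, K))
  pred <- matrix(0, I, K)
  for (j in seq_len(K))
    for (i in seq_len(K))
      pred[, j] <- pred[, j] + post_prev[, i] * tpm[, i, j]
  m <- apply(comp_loglik, 1, max)
  m[!is.finite(m)] <- 0
  joint <- pred * exp(comp_loglik - m)
  tot <- rowSums(joint)
  loglik <- ifelse(tot > 0, m + log(tot), -Inf)
  post <- joint / ifelse(tot > 0, tot, 1)
  post[tot <= 0, ] <- 1 / K
  list(loglik = as.numeric(loglik), post = post)
}

#' Serial-processing population log-likelihood of one interval
#'
#' Under serial processing all trains attend the same component, so the
#' interval likelihood is the product over trains of single-train
#' interval likelihoods, each conditioned on its own spike history.
#'
#' @param segments list of per-train spike vectors inside the interval.
#' @param histories list of per-train spike histories before it.
#' @param Tb,Te,s_curr,s_prev,window_start,lif,kernel,grid as in
#'   [interval_loglik()].
#' @return Per-particle summed log-likelihoods.
#' @export
serial_population_loglik <- function(segments, histories, Tb, Te,
                                     s_curr, s_prev = s_curr,
                                     window_start = Tb,
                                     lif = lif_params(),
                                     kernel = kernel_bursting(),
                                     grid = pde_grid()) {
  stopifnot(length(segments) == length(histories))
  ll <- numeric(length(s_curr))
  for (m in seq_along(segments))
    ll <- ll + interval_loglik(segments[[m]], Tb, Te, s_curr, s_prev,
                               histories[[m]], window_start,
                               lif, kernel, grid)
  ll
}

#' Parallel-processing marginal population log-likelihood of one interval
#'
#' Each train carries its own attention posterior; the interval
#' likelihood is the product over trains of attention-marginalized
#' single-train likelihoods.
#'
#' @param segments,histories per-train spikes and histories.
#' @param posts list of per-train I x K attention posteriors.
#' @param tpm I x K x K array.
#' @param S,S_prev I x K stimulus matrices (current and previous).
#' @param Tb,Te,window_start,lif,kernel,grid as in [interval_loglik()].
#' @return List with `loglik` (length I) and `posts` (updated list).
#' @export
parallel_marginal_loglik <- function(segments, histories, posts, tpm,
                                     S, S_prev, Tb, Te, window_start = Tb,
                                     lif = lif_params(),
                                     kernel = kernel_bursting(),
                                     grid = pde_grid()) {
  K <- ncol(S)
  ll <- numeric(nrow(S))
  for (m in seq_along(segments)) {
    cll <- sapply(seq_len(K), function(k)
      interval_loglik(segments[[m]], Tb, Te, S[, k], S_prev[, k],
                      histories[[m]], window_start, lif, kernel, grid))
    cll <- matrix(cll, nrow(S), K)
    upd <- marginal_attention_update(posts[[m]], tpm, cll)
    ll <- ll + upd$loglik
    posts[[m]] <- upd$post
  }
  list(loglik = ll, posts = posts)
}

#' Geometric-mean adjustment of auxiliary weights
#'
#' Tempering used in the first resampling stage of the auxiliary filters
#' for population data: the per-train log-likelihoods are averaged rather
#' than summed (geometric mean on the probability scale), which keeps the
#' auxiliary weights from becoming extreme when many trains contribute.
#' Second-stage ratio weights always use the untempered likelihood.
#'
#' @param train_logliks I x M matrix (or length-I vector when M = 1) of
#'   per-train first-stage log-likelihoods.
#' @return Length-I adjusted auxiliary log-weights.
#' @export
geometric_mean_aux <- function(train_logliks) {
  if (is.null(dim(train_logliks))) return(as.numeric(train_logliks))
  rowMeans(train_logliks)
}

normalize_logw <- function(logw) {
  finite <- is.finite(logw)
  if (!any(finite))
    stop(errorCondition(
      "all particle log-weights are -Inf: likelihood breakdown",
      class = c("smc_degeneracy_error", "error", "condition")))
  m <- max(logw[finite])
  w <- exp(logw - m)
  w[!finite] <- 0
  w / sum(w)
}

sort_components <- function(S, beta) {
  I <- nrow(S); K <- ncol(S)
  if (K == 1) return(S)
  out <- S
  for (i in seq_len(I)) out[i, ] <- S[i, order(S[i, ], beta[i, ])]
  out
}

#' Decode stochastic stimuli from spike trains by particle filtering
#'
#' Runs one of the four sequential Monte Carlo decoders over the decoding
#' intervals of the observation window.
#'
#' * `bf` — bootstrap filter: resample, propagate the full state (TPM,
#'   attention, diffusion, drift, stimulus), weight by the attended
#'   component's interval likelihood.
#' * `apf` — auxiliary filter: the attention is propagated first, a
#'   first resampling stage uses the likelihood at the predicted
#'   (expected) stimulus, the diffusion parameter is propagated by
#'   Liu-West kernel shrinkage, and second-stage weights are the
#'   likelihood ratio at the sampled versus predicted stimulus.
#' * `mbf` / `mapf` — the same with the attention state integrated out of
#'   the likelihood; all K components are estimated, reported on
#'   ascending-sorted components to tame label switching.
#'
#' Population modes: `serial` multiplies the per-train likelihoods of a
#' shared attended component; `parallel_marginal` multiplies per-train
#' attention-marginal likelihoods (each train keeps its own attention
#' posterior); `parallel_individual` decodes each train separately and
#' combines the estimates by k-medoids clustering
#' ([combine_parallel_estimates()]).
#'
#' @param trains a [spike_train()] or a list of them (all sharing one
#'   observation window).
#' @param scenario a [scenario_config()] or any list with fields `K`,
#'   `v`, `lif`, `kernel`, `grid`, `prop`, `ranges`.
#' @param method filter type.
#' @param mode population mode.
#' @param n_particles number of particles I.
#' @param smoother `"filter"` for online estimates only, `"lag"` for
#'   fixed-lag smoothing by ancestry marginalization, `"fb"` for
#'   forward-filtering backward-smoothing; both smoothers also return the
#'   filtered estimates.
#' @param lag smoothing delay in intervals.
#' @param geometric_mean_aux temper first-stage auxiliary weights with
#'   the geometric mean over trains (apf/mapf only).
#' @param resample_ess_frac optional fraction of I below which the
#'   bootstrap filters resample; `NULL` (default) resamples every
#'   interval.
#' @param loglik_fun optional likelihood backend
#'   `function(n, m, s_curr, s_prev)` returning per-particle interval
#'   log-likelihoods; defaults to the Fokker-Planck first-passage
#'   likelihood.  Intended for testing.
#' @param use_burnin_history condition the first intervals on pre-window
#'   spikes when the trains carry them (attribute `"burnin_spikes"`, as
#'   attached by [simulate_spike_train()]).  Without a history the
#'   window start is treated as a membrane reset.
#' @param keep_particles keep per-interval particle snapshots in the
#'   result.
#' @return An object of class `smc_decoding`; see Details.  Fields
#'   include the filtered (and, with a smoother, smoothed) stimulus
#'   estimates per interval, ESS and parameter traces.
#' @export
smc_decode <- function(trains, scenario,
                       method = c("bf", "apf", "mbf", "mapf"),
                       mode = c("single", "serial", "parallel_marginal",
                                "parallel_individual"),
                       n_particles = 500,
                       smoother = c("filter", "lag", "fb"), lag = 10,
                       geometric_mean_aux = FALSE,
                       resample_ess_frac = NULL,
                       loglik_fun = NULL, keep_particles = FALSE,
                       use_burnin_history = TRUE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  smoother <- match.arg(smoother)
  if (inherits(trains, "spike_train")) trains <- list(trains)
  M <- length(trains)
  if (mode == "single" && M != 1) stop("single mode expects one train")
  if (mode == "serial" && !method %in% c("bf", "apf"))
    stop("serial mode marginalises nothing: use bf or apf")
  if (mode == "parallel_marginal" && !method %in% c("mbf", "mapf"))
    stop("parallel_marginal mode requires mbf or mapf")
  if (geometric_mean_aux && !method %in% c("apf", "mapf"))
    stop("geometric-mean auxiliary weights apply to apf/mapf only")
  if (smoother != "filter" && lag < 1) stop("lag must be >= 1")

  if (mode == "parallel_individual") {
    runs <- lapply(trains, function(tr)
      smc_decode(tr, scenario, method = method, mode = "single",
                 n_particles = n_particles, smoother = smoother,
                 lag = lag, loglik_fun = loglik_fun))
    est <- sapply(runs, function(r) r$estimates[, 1])
    sm <- if (smoother != "filter")
      sapply(runs, function(r) r$smoothed[, 1]) else NULL
    comb <- combine_parallel_estimates(est, scenario$K)
    comb_sm <- if (!is.null(sm))
      combine_parallel_estimates(sm, scenario$K) else NULL
    return(structure(list(method = method, mode = mode,
                          smoother = smoother, lag = lag,
                          runs = runs, clusters = comb,
                          clusters_smoothed = comb_sm,
                          estimates = comb$estimates,
                          smoothed = if (!is.null(comb_sm))
                            comb_sm$estimates else NULL,
                          K = scenario$K, N = runs[[1]]$N, v = scenario$v,
                          window = runs[[1]]$window),
                     class = c("smc_population_decoding", "smc_decoding")))
  }

  K <- scenario$K; v <- scenario$v
  lif <- scenario$lif; kernel <- scenario$kernel; grid <- scenario$grid
  prop <- scenario$prop; ranges <- scenario$ranges
  I <- n_particles
  w <- trains[[1]]$window
  for (tr in trains) stopifnot(all(abs(tr$window - w) < 1e-9))
  N <- round((w[2] - w[1]) / v)
  stopifnot(N >= 1)
  breaks <- w[1] + v * (0:N)

  # per-train interval spike segments and pre-interval histories
  seg <- vector("list", M); hist <- vector("list", M)
  for (m in seq_len(M)) {
    tt <- trains[[m]]$times
    bin <- pmin(pmax(findInterval(tt, breaks), 1L), N)
    hb <- if (use_burnin_history) attr(trains[[m]], "burnin_spikes")
          else NULL
    if (is.null(hb)) hb <- numeric(0)
    seg[[m]] <- lapply(seq_len(N), function(n) tt[bin == n])
    hist[[m]] <- lapply(seq_len(N), function(n) c(hb, tt[tt < breaks[n]]))
  }
  if (is.null(loglik_fun))
    loglik_fun <- function(n, m, s_curr, s_prev)
      cpp_interval_loglik(breaks[n], breaks[n + 1], seg[[m]][[n]],
                          hist[[m]][[n]], w[1],
                          as.numeric(s_prev), as.numeric(s_curr),
                          lif$a, lif$mu, lif$sigma, lif$x0, lif$x_th,
                          lif$x_minus, kernel$eta, grid$dt, grid$dx,
                          grid$t_max)

  marginal <- method %in% c("mbf", "mapf")
  auxiliary <- method %in% c("apf", "mapf")
  Kout <- if (marginal) K else 1L

  ens <- init_ensemble(K, I, ranges)
  posts <- if (marginal)
    replicate(M, matrix(1 / K, I, K), simplify = FALSE) else NULL

  # likelihood of interval n given current/previous states
  eval_loglik <- function(n, S, S_prev, C, C_prev, tpm_arr) {
    if (!marginal) {
      sc <- S[cbind(seq_len(I), C)]
      sp <- S_prev[cbind(seq_len(I), C_prev)]
      ll <- 0
      llm <- matrix(0, I, M)
      for (m in seq_len(M)) {
        llm[, m] <- loglik_fun(n, m, sc, sp)
        ll <- ll + llm[, m]
      }
      list(loglik = ll, train_logliks = llm, posts = NULL)
    } else {
      ll <- 0
      llm <- matrix(0, I, M)
      new_posts <- posts
      for (m in seq_len(M)) {
        cll <- sapply(seq_len(K), function(k)
          loglik_fun(n, m, S[, k], S_prev[, k]))
        cll <- matrix(cll, I, K)
        upd <- marginal_attention_update(posts[[m]], tpm_arr, cll)
        llm[, m] <- upd$loglik
        ll <- ll + upd$loglik
        new_posts[[m]] <- upd$post
      }
      list(loglik = ll, train_logliks = llm, posts = new_posts)
    }
  }

  est <- matrix(NA_real_, N, Kout)
  ess_tr <- numeric(N)
  gamma_mean <- gamma_sd <- numeric(N)
  beta_mean <- matrix(NA_real_, N, K)
  att_post <- if (marginal) matrix(NA_real_, N, K) else NULL
  w_hist <- matrix(NA_real_, N, I)
  val_hist <- array(NA_real_, c(N, I, Kout))
  ancestry <- vector("list", N)
  snapshots <- if (smoother == "fb" || keep_particles)
    vector("list", N) else NULL
  temper <- isTRUE(geometric_mean_aux)

  reorder <- function(anc) {
    ens$tpm <<- ens$tpm[anc, , , drop = FALSE]
    ens$C <<- ens$C[anc]
    ens$gam <<- ens$gam[anc]
    ens$beta <<- ens$beta[anc, , drop = FALSE]
    ens$S <<- ens$S[anc, , drop = FALSE]
    if (marginal)
      posts <<- lapply(posts, function(p) p[anc, , drop = FALSE])
  }

  record <- function(n, wts, S_report, lw_stats = NULL) {
    est[n, ] <<- colSums(wts * S_report)
    ess_tr[n] <<- 1 / sum(wts^2)
    gamma_mean[n] <<- sum(wts * ens$gam)
    gamma_sd[n] <<- sqrt(max(sum(wts * (ens$gam - gamma_mean[n])^2), 0))
    beta_mean[n, ] <<- colSums(wts * ens$beta)
    if (marginal)
      att_post[n, ] <<- colSums(wts * posts[[1]])
    w_hist[n, ] <<- wts
    val_hist[n, , ] <<- S_report
    if (!is.null(snapshots))
      snapshots[[n]] <<- list(tpm = ens$tpm, C = ens$C, gam = ens$gam,
                              beta = ens$beta, S = ens$S, w = wts,
                              lw = lw_stats)
  }

  lw_warned <- FALSE
  for (n in seq_len(N)) {
    if (n == 1) {
      # uniform prior on the first attention index: feed the marginal
      # update an identity TPM so the predicted attention is uniform
      id_tpm <- array(rep(diag(K), each = I), c(I, K, K))
      ev <- eval_loglik(1, ens$S, ens$S, ens$C, ens$C, id_tpm)
      if (marginal) posts <- ev$posts
      wts <- normalize_logw(ev$loglik)
      ens$w <- wts
      ancestry[[1]] <- seq_len(I)
      S_report <- if (marginal) sort_components(ens$S, ens$beta)
                  else matrix(ens$S[cbind(seq_len(I), ens$C)], I, 1)
      record(1, wts, S_report)
      next
    }

    S_prev_raw <- ens$S; C_prev_raw <- ens$C
    if (!auxiliary) {
      ## ---- bootstrap step: resample, propagate, weight --------------
      do_rs <- is.null(resample_ess_frac) ||
        (1 / sum(ens$w^2)) < resample_ess_frac * I
      if (do_rs) {
        anc <- systematic_resample(ens$w)
        reorder(anc)
        ens$w <- rep(1 / I, I)
        prev_logw <- rep(0, I)
      } else {
        anc <- seq_len(I)
        prev_logw <- log(ens$w) + log(I)
      }
      ancestry[[n]] <- as.integer(anc)
      S_prev <- S_prev_raw[anc, , drop = FALSE]
      C_prev <- C_prev_raw[anc]
      ens$tpm <- propagate_tpm(ens$tpm, prop$V_lambda)
      if (!marginal) ens$C <- propagate_attention(ens$C, ens$tpm)
      ens$gam <- propagate_gamma_rw(ens$gam, prop$V_gamma)
      ens$beta <- propagate_beta(ens$beta, prop$V_beta)
      ens$S <- propagate_stimulus(ens$S, ens$beta, ens$gam, prop$v)
      ev <- eval_loglik(n, ens$S, S_prev, ens$C, C_prev, ens$tpm)
      if (marginal) posts <- ev$posts
      logw <- prev_logw + ev$loglik
      wts <- normalize_logw(logw)
      ens$w <- wts
      lw_stats <- NULL
    } else {
      ## ---- auxiliary step -------------------------------------------
      if (!marginal) {
        ens$tpm <- propagate_tpm(ens$tpm, prop$V_lambda)
        ens$C <- propagate_attention(ens$C, ens$tpm)
      }
      e <- exp(-prop$v)
      mu <- (ens$S - ens$beta) * e + ens$beta   # E(S_n | S_{n-1}, theta_{n-1})
      ev1 <- eval_loglik(n, mu, S_prev_raw, ens$C, C_prev_raw, ens$tpm)
      ll1 <- ev1$loglik
      ll1_aux <- if (temper) geometric_mean_aux(ev1$train_logliks) else ll1
      logu <- log(pmax(ens$w, .Machine$double.xmin)) + ll1_aux
      uw <- normalize_logw(logu)
      if (1 / sum(uw^2) < 2)
        warning("first-stage auxiliary weights nearly degenerate ",
                "(ESS < 2) at interval ", n)
      anc <- systematic_resample(uw)
      ancestry[[n]] <- as.integer(anc)
      reorder(anc)
      ll1 <- ll1[anc]
      S_prev <- S_prev_raw[anc, , drop = FALSE]
      C_prev <- C_prev_raw[anc]
      ens$w <- rep(1 / I, I)
      # Liu-West shrinkage of the diffusion parameter from the
      # post-resample (equally weighted) cloud
      uni <- rep(1 / I, I)
      lw_stats <- list(gbar = mean(ens$gam),
                       vn = mean((ens$gam - mean(ens$gam))^2))
      ens$gam <- propagate_gamma_liu_west(ens$gam, uni, prop$delta)
      ens$beta <- propagate_beta(ens$beta, prop$V_beta)
      if (marginal) ens$tpm <- propagate_tpm(ens$tpm, prop$V_lambda)
      ens$S <- propagate_stimulus(ens$S, ens$beta, ens$gam, prop$v)
      ev2 <- eval_loglik(n, ens$S, S_prev, ens$C, C_prev, ens$tpm)
      if (marginal) posts <- ev2$posts
      logw <- ev2$loglik - ll1
      logw[!is.finite(ll1)] <- -Inf
      wts <- normalize_logw(logw)
      ens$w <- wts
    }
    S_report <- if (marginal) sort_components(ens$S, ens$beta)
                else matrix(ens$S[cbind(seq_len(I), ens$C)], I, 1)
    record(n, wts, S_report, lw_stats)
  }

  out <- list(method = method, mode = mode, smoother = smoother,
              lag = lag, K = K, Kout = Kout, N = N, v = v, window = w,
              M = M,
              intervals = data.frame(interval = seq_len(N),
                                     t_start = breaks[-(N + 1)],
                                     t_end = breaks[-1]),
              estimates = est, ess = ess_tr,
              gamma_mean = gamma_mean, gamma_sd = gamma_sd,
              beta_mean = beta_mean, att_posterior = att_post,
              weights = w_hist, ancestry = ancestry,
              val_hist = val_hist, snapshots = snapshots,
              prop = prop, geometric_mean_aux = geometric_mean_aux)
  class(out) <- "smc_decoding"

  if (smoother == "lag") {
    out$smoothed <- smooth_fixed_lag(out, lag)
  } else if (smoother == "fb") {
    gamma_model <- if (auxiliary) "liu_west" else "rw"
    out$smoothed <- smooth_ffbs(out, lag, gamma_model,
                                include_C = !marginal)
    if (!keep_particles) out$snapshots <- NULL
  }
  out
}

#' @export
print.smc_decoding <- function(x, ...) {
  cat(sprintf("<smc_decoding> %s / %s / %s, %d intervals of %.3f s, K=%d\n",
              x$method, x$mode, x$smoother, x$N, x$v, x$K))
  cat(sprintf("  mean ESS %.1f, final gamma %.2f +/- %.2f\n",
              mean(x$ess), x$gamma_mean[x$N], x$gamma_sd[x$N]))
  invisible(x)
}

#' Named filter front-ends
#'
#' Convenience wrappers around [smc_decode()] for the four filter types:
#' bootstrap (`bootstrap_filter`), auxiliary with Liu-West parameter
#' learning (`auxiliary_filter`), and their attention-marginalized
#' counterparts (`marginal_bootstrap_filter`,
#' `marginal_auxiliary_filter`).
#'
#' @param trains,scenario,... forwarded to [smc_decode()].
#' @return An `smc_decoding` object.
#' @export
bootstrap_filter <- function(trains, scenario, ...)
  smc_decode(trains, scenario, method = "bf", ...)

#' @rdname bootstrap_filter
#' @export
auxiliary_filter <- function(trains, scenario, ...)
  smc_decode(trains, scenario, method = "apf", ...)

#' @rdname bootstrap_filter
#' @export
marginal_bootstrap_filter <- function(trains, scenario, ...)
  smc_decode(trains, scenario, method = "mbf", ...)

#' @rdname bootstrap_filter
#' @export
marginal_auxiliary_filter <- function(trains, scenario, ...)
  smc_decode(trains, scenario, method = "mapf", ...)
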