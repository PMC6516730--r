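#' Read and write spike trains as CSV
#'
#' Plain-text interchange format: columns `train_id, spike_time_s`
#' (header required, times written with six decimals).
#'
#' @param trains list of [spike_train()] objects (or one).
#' @param path file path.
#' @return `write_spike_trains` invisibly returns `path`;
#'   `read_spike_trains` returns a list of spike trains.
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(seq_along(trains), function(m)
    data.frame(train_id = m,
               spike_time_s = sprintf("%.6f", trains[[m]]$times))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  w <- trains[[1]]$window
  cat(sprintf("# window,%.6f,%.6f\n", w[1], w[2]),
      file = path, append = TRUE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param window observation window; if `NULL`, recovered from the
#'   trailing comment line written by `write_spike_trains` (or spanned
#'   by the data).
#' @export
read_spike_trains <- function(path, window = NULL) {
  lines <- readLines(path)
  wline <- grep("^# window,", lines, value = TRUE)
  if (is.null(window)) {
    window <- if (length(wline)) {
      as.numeric(strsplit(wline[1], ",")[[1]][2:3])
    } else NULL
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  stopifnot(all(c("train_id", "spike_time_s") %in% names(df)))
  if (is.null(window))
    window <- range(df$spike_time_s)
  lapply(split(df$spike_time_s, df$train_id), function(tt)
    spike_train(sort(tt), window))
}

#' Read and write stimulus component paths as CSV
#'
#' Long format with columns `time_s, component, value`.
#'
#' @param times fine time grid.
#' @param values matrix with one column per component.
#' @param path file path.
#' @export
write_stimulus_paths <- function(times, values, path) {
  values <- as.matrix(values)
  df <- do.call(rbind, lapply(seq_len(ncol(values)), function(k)
    data.frame(time_s = sprintf("%.6f", times), component = k,
               value = sprintf("%.6f", values[, k]))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_paths
#' @return `read_stimulus_paths` returns a list with `times` and
#'   `values`.
#' @export
read_stimulus_paths <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "component", "value") %in% names(df)))
  ks <- sort(unique(df$component))
  times <- sort(unique(df$time_s))
  values <- sapply(ks, function(k) {
    sub <- df[df$component == k, ]
    sub$value[order(sub$time_s)]
  })
  list(times = times, values = matrix(values, ncol = length(ks)))
}

#' Read and write attention paths as CSV
#'
#' Columns `train_id, interval_index, attended_component` with 1-based
#' component indices; intervals are the half-open decoding intervals.
#'
#' @param paths list of `attention_path` objects.
#' @param path file path.
#' @export
write_attention_paths <- function(paths, path) {
  df <- do.call(rbind, lapply(seq_along(paths), function(m)
    data.frame(train_id = m,
               interval_index = seq_along(paths[[m]]$index),
               attended_component = paths[[m]]$index)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_attention_paths
#' @return `read_attention_paths` returns a list of integer index
#'   vectors, one per train.
#' @export
read_attention_paths <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$train_id), function(sub)
    as.integer(sub$attended_component[order(sub$interval_index)]))
}

#' Serialize a scenario configuration to YAML
#'
#' Writes the scalar and matrix fields of a [scenario_config()] in a
#' plain mapping mirroring the model parameter tables
#' (`a, mu, sigma, x0, xth, xminus, eta, beta, gamma, tpm, v, duration,
#' burn_in, ...`); `read_scenario` reconstructs an equivalent config.
#'
#' @param scenario a [scenario_config()].
#' @param path file path.
#' @export
write_scenario <- function(scenario, path) {
  s <- scenario
  obj <- list(
    K = s$K, M = s$M, preset = s$preset,
    a = s$lif$a, mu = s$lif$mu, sigma = s$lif$sigma,
    x0 = s$lif$x0, xth = s$lif$x_th, xminus = s$lif$x_minus,
    eta = s$kernel$eta, kernel_label = s$kernel$label,
    beta = s$stim$beta, gamma = s$stim$gamma,
    tpm = apply(s$attention$tpm, 1, function(r) as.numeric(r),
                simplify = FALSE),
    switching = s$attention$switching,
    poisson_rate = s$attention$poisson_rate,
    v = s$v, duration = s$duration, burn_in = s$burn_in,
    dt_stim = s$dt_stim, sim_dt = s$sim_dt,
    pde = list(dt = s$grid$dt, dx = s$grid$dx, t_max = s$grid$t_max),
    propagation = list(V_lambda = s$prop$V_lambda,
                       V_gamma = s$prop$V_gamma,
                       V_beta = s$prop$V_beta,
                       delta = s$prop$delta, v = s$prop$v),
    init = list(max_gamma = s$ranges$max_gamma,
                max_beta = s$ranges$max_beta, max_S = s$ranges$max_S),
    n_particles = s$n_particles, n_repetitions = s$n_repetitions,
    lag = s$lag)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  o <- yaml::read_yaml(path)
  tpm <- do.call(rbind, o$tpm)
  scenario_config(K = o$K, kernel_label = o$kernel_label,
                  switching = o$switching, preset = o$preset,
                  M = o$M, beta = o$beta, gamma = o$gamma, tpm = tpm,
                  stim_scale = 1,
                  v = o$v, duration = o$duration, burn_in = o$burn_in,
                  dt_stim = o$dt_stim, sim_dt = o$sim_dt,
                  n_particles = o$n_particles,
                  n_repetitions = o$n_repetitions, lag = o$lag,
                  lif = lif_params(o$a, o$mu, o$sigma, o$x0, o$xth,
                                   o$xminus),
                  kernel = response_kernel(o$eta, o$kernel_label),
                  grid = pde_grid(o$pde$dt, o$pde$dx, o$pde$t_max),
                  prop = propagation_config(o$propagation$V_lambda,
                                            o$propagation$V_gamma,
                                            o$propagation$V_beta,
                                            o$propagation$delta,
                                            o$propagation$v),
                  ranges = init_ranges(o$init$max_gamma, o$init$max_beta,
                                       o$init$max_S))
}

#' Write decoding results as tidy CSV
#'
#' One row per interval and component:
#' `interval, component, estimate, smoothed_estimate, ess, gamma_mean,
#' gamma_sd`.
#'
#' @param result an `smc_decoding`.
#' @param path file path.
#' @export
write_decoding_result <- function(result, path) {
  Kout <- ncol(result$estimates)
  df <- do.call(rbind, lapply(seq_len(Kout), function(k)
    data.frame(interval = seq_len(result$N), component = k,
               estimate = result$estimates[, k],
               smoothed_estimate = if (!is.null(result$smoothed))
                 result$smoothed[, k] else NA_real_,
               ess = if (!is.null(result$ess)) result$ess else NA_real_,
               gamma_mean = if (!is.null(result$gamma_mean))
                 result$gamma_mean else NA_real_,
               gamma_sd = if (!is.null(result$gamma_sd))
                 result$gamma_sd else NA_real_)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
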