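#' Scenario configuration for simulation experiments
#'
#' Bundles the encoding, stimulus, attention and decoding parameters of
#' one simulation scenario.  The `study` preset reproduces the full
#' study conditions (500 particles, 5 s observation after 1 s burn-in,
#' 50 repetitions, 0.02 potential grid); the `desk` preset is a reduced
#' configuration for interactive work and testing (100 particles, 2 s
#' observation, 10 repetitions, 0.04 potential grid).
#'
#' @param K number of stimulus components (1, 2 or 3 select the study
#'   drift levels and TPM automatically).
#' @param kernel_label `"bursting"`, `"decaying"`, `"delaying"` or
#'   `"none"`.
#' @param switching `"discrete"` or `"poisson"`.
#' @param preset `"study"` (full-scale study conditions) or `"desk"`.
#' @param M number of neurons (population scenarios).
#' @param beta,gamma,tpm optional overrides of the stimulus drift
#'   levels, diffusion and attention TPM.
#' @param stim_scale multiplier applied to `beta` (the decaying-kernel
#'   scenario uses a stronger stimulus to sustain firing).
#' @param ... further overrides of any config field.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(K = 1, kernel_label = "bursting",
                            switching = "discrete",
                            preset = c("desk", "study"), M = 1,
                            beta = NULL, gamma = 20, tpm = NULL,
                            stim_scale = if (kernel_label == "decaying")
                              2 else 1,
                            ...) {
  preset <- match.arg(preset)
  if (is.null(beta))
    beta <- switch(as.character(K),
                   "1" = 70, "2" = c(65, 75), "3" = c(60, 70, 80),
                   stop("supply beta explicitly for K = ", K))
  beta <- beta * stim_scale
  if (is.null(tpm)) tpm <- study_tpm(K)
  kern <- switch(kernel_label,
                 bursting = kernel_bursting(), decaying = kernel_decaying(),
                 delaying = kernel_delaying(), none = kernel_none(),
                 stop("unknown kernel label"))
  base <- list(
    K = K, M = M, preset = preset,
    v = 0.1, burn_in = 1,
    duration = if (preset == "study") 5 else 2,
    n_particles = if (preset == "study") 500 else 100,
    n_repetitions = if (preset == "study") 50 else 10,
    lag = 10,
    dt_stim = 0.01, sim_dt = 1e-4,
    lif = lif_params(),
    kernel = kern,
    stim = stimulus_params(beta, gamma),
    attention = attention_model(tpm, v = 0.1, switching = switching),
    grid = pde_grid(dt = 0.002,
                    dx = if (preset == "study") 0.02 else 0.04,
                    t_max = 2),
    prop = propagation_config(),
    ranges = init_ranges())
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "scenario_config")
}

#' Simulate one decoding trial of a scenario
#'
#' Generates fresh stimuli, attention and spike trains for a scenario
#' (every decoding trial uses new stimulus realizations).
#'
#' @param scenario a [scenario_config()].
#' @param mode `"single"`, `"serial"` or `"parallel"` attention scheme
#'   for population data.
#' @return As [simulate_population()].
#' @export
simulate_trial <- function(scenario,
                           mode = c("single", "serial", "parallel")) {
  mode <- match.arg(mode)
  M <- if (mode == "single") 1L else scenario$M
  simulate_population(M, if (mode == "parallel") "parallel" else "serial",
                      scenario$lif, scenario$kernel, scenario$stim,
                      scenario$attention,
                      duration = scenario$duration,
                      burn_in = scenario$burn_in,
                      dt = scenario$dt_stim, sim_dt = scenario$sim_dt)
}

#' Run a repeated decoding experiment
#'
#' Repeats trials of a scenario: each repetition simulates new stimuli
#' and spike trains with a deterministically derived sub-seed, decodes
#' them with the requested method and evaluates rRMSD, mean ESS and the
#' final diffusion-parameter estimate.  A failed repetition is recorded
#' with its error message and does not abort the sweep.
#'
#' @param scenario a [scenario_config()].
#' @param method,mode,smoother,lag,geometric_mean_aux forwarded to
#'   [smc_decode()].
#' @param n_repetitions number of repetitions (defaults to the
#'   scenario's).
#' @param seed master seed; sub-seeds are derived from it.
#' @return A data frame with one row per repetition: `rep, seed, method,
#'   mode, smoother, rrmsd, rrmsd_smoothed, mean_ess, gamma_final,
#'   error`.
#' @export
run_experiment <- function(scenario, method = "bf", mode = "single",
                           smoother = "filter", lag = scenario$lag,
                           geometric_mean_aux = FALSE,
                           n_repetitions = scenario$n_repetitions,
                           seed = 1) {
  set.seed(seed)
  sub_seeds <- sample.int(2^30, n_repetitions)
  rows <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    rows[[r]] <- tryCatch({
      set.seed(sub_seeds[r])
      sim_mode <- switch(mode, single = "single", serial = "serial",
                         parallel_marginal = , parallel_individual =
                           "parallel")
      sim <- simulate_trial(scenario, sim_mode)
      dec_mode <- if (mode == "single") "single" else mode
      res <- smc_decode(sim$trains, scenario, method = method,
                        mode = dec_mode,
                        n_particles = scenario$n_particles,
                        smoother = smoother, lag = lag,
                        geometric_mean_aux = geometric_mean_aux)
      ev <- evaluate_decoding(res, sim)
      data.frame(rep = r, seed = sub_seeds[r], method = method,
                 mode = mode, smoother = smoother,
                 rrmsd = ev$rrmsd,
                 rrmsd_smoothed = ev$rrmsd_smoothed,
                 mean_ess = if (!is.null(res$ess)) mean(res$ess)
                            else NA_real_,
                 gamma_final = if (!is.null(res$gamma_mean))
                   res$gamma_mean[res$N] else NA_real_,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(rep = r, seed = sub_seeds[r], method = method,
                 mode = mode, smoother = smoother,
                 rrmsd = NA_real_, rrmsd_smoothed = NA_real_,
                 mean_ess = NA_real_, gamma_final = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Evaluate a decoding result against the simulated truth
#'
#' @param result an `smc_decoding` (or population) result.
#' @param sim the matching simulation from [simulate_trial()] /
#'   [simulate_population()].
#' @return List with `rrmsd` (mean over components for multi-component
#'   output) and `rrmsd_smoothed` (NA without a smoother).
#' @export
evaluate_decoding <- function(result, sim) {
  smoothed <- result$smoothed
  if (inherits(result, "smc_population_decoding") ||
      result$method %in% c("mbf", "mapf")) {
    truth <- component_truth(sim$paths[[1]])
    K <- dim(truth)[3]
    val <- mean(rrmsd_components(result$estimates, truth))
    vs <- if (!is.null(smoothed))
      mean(rrmsd_components(smoothed, truth)) else NA_real_
  } else {
    truth <- attended_truth(sim$paths[[1]])
    val <- rrmsd(result$estimates[, 1], truth)
    vs <- if (!is.null(smoothed)) rrmsd(smoothed[, 1], truth)
          else NA_real_
  }
  list(rrmsd = val, rrmsd_smoothed = vs)
}

#' Write small deterministic fixture data sets
#'
#' Generates a bundle of small simulated data sets (spike trains,
#' stimulus paths, attention paths and a scenario file) for examples and
#' tests.  Byte-identical across runs with the same seed.
#'
#' @param seed RNG seed.
#' @param dir output directory.
#' @param duration observation window length, s.
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(seed = 42, dir = tempdir(), duration = 1) {
  set.seed(seed)
  sc <- scenario_config(K = 2, preset = "desk", M = 2,
                        duration = duration)
  sim <- simulate_trial(sc, "parallel")
  paths <- character(0)
  f <- file.path(dir, "spike_trains.csv")
  write_spike_trains(sim$trains, f); paths <- c(paths, f)
  f <- file.path(dir, "stimulus.csv")
  write_stimulus_paths(sim$times, sim$values, f); paths <- c(paths, f)
  f <- file.path(dir, "attention.csv")
  write_attention_paths(lapply(sim$paths, function(p) p$attention), f)
  paths <- c(paths, f)
  f <- file.path(dir, "scenario.yaml")
  write_scenario(sc, f); paths <- c(paths, f)
  invisible(paths)
}
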