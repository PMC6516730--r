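# shared fixtures for the test suite; everything is generated in code

# oracle-grade solver grid: monotone regime (cell Peclet ~1) and small
# discretization error, used where absolute first-passage accuracy is
# asserted
accuracy_grid <- function() pde_grid(dt = 2e-4, dx = 0.0025)

# small scenario helpers
desk1 <- function(...) scenario_config(K = 1, preset = "desk", ...)
desk2 <- function(...) scenario_config(K = 2, preset = "desk", ...)

# a constant-stimulus mixture path built by hand (no OU noise), useful
# for likelihood cross-checks
constant_path <- function(value = 70, duration = 5, burn_in = 1,
                          dt = 0.01, v = 0.1) {
  nt <- round((duration + burn_in) / dt) + 1
  att <- structure(list(index = rep(1L, ceiling((duration + burn_in) / v)),
                        switches = NULL, v = v, K = 1L,
                        switching = "discrete", c_init = 1L),
                   class = "attention_path")
  structure(list(times = seq(0, by = dt, length.out = nt),
                 values = matrix(value, nt, 1), attention = att,
                 burn_in = burn_in, duration = duration, dt = dt,
                 v = v, K = 1L),
            class = "stimulus_mixture_path")
}

# empirical KS distance between samples and a CDF given on a grid
ks_distance <- function(samples, t, cdf) {
  Gf <- stats::approxfun(t, cdf, rule = 2)
  xs <- sort(samples)
  emp <- seq_along(xs) / length(xs)
  max(abs(emp - Gf(xs)), abs(c(0, emp[-length(emp)]) - Gf(xs)))
}
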