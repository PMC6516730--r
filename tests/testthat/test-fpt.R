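test_that("CDF solve satisfies initial and boundary conditions", {
  lif <- lif_params()
  sol <- solve_fpt_cdf(lif, 70, accuracy_grid(), t_max = 0.05,
                       full_surface = TRUE)
  # Heaviside initial condition at the reset (cell-average at the node)
  ic <- sol$F[, 1]
  expect_true(all(ic[sol$x < lif$x0 - 1e-9] == 0))
  expect_true(all(ic[sol$x > lif$x0 + 1e-9] == 1))
  # lower boundary pinned at zero on every slice
  expect_true(all(abs(sol$F[1, ]) < 1e-10))
  # reflecting upper boundary: vanishing one-sided gradient at x_th
  nx <- nrow(sol$F)
  grad <- abs(sol$F[nx, -1] - sol$F[nx - 1, -1]) / accuracy_grid()$dx
  interior <- abs(sol$F[nx - 1, -1] - sol$F[nx - 2, -1]) / accuracy_grid()$dx
  expect_lt(stats::median(grad / pmax(interior, 1e-12)), 0.5)
})

test_that("CDF solve is monotone with sub-unit mass and positive density", {
  lif <- lif_params()
  for (drive in c(40, 70, 160)) {
    sol <- solve_fpt_cdf(lif, drive, accuracy_grid(), t_max = 0.2,
                         full_surface = TRUE)
    worst <- min(apply(sol$F, 2, function(col) min(diff(col))))
    expect_gt(worst, -1e-6)                 # non-decreasing in x
    expect_true(all(sol$F >= -1e-12 & sol$F <= 1 + 1e-9))
    expect_true(all(sol$g >= 0))
    expect_lt(sol$clipped_mass, 1e-6)
    expect_lte(max(sol$G), 1 + 1e-6)        # sub-distribution
  }
  # the coarse default grid keeps positivity too (M-matrix scheme),
  # with a documented looser clipping bound
  solc <- solve_fpt_cdf(lif, 70, pde_grid(), t_max = 0.2,
                        full_surface = TRUE)
  expect_true(all(solc$F >= 0))
  expect_lt(solc$clipped_mass, 1e-3)
})

test_that("ISI density interpolation is linear on the grid", {
  sol <- solve_fpt_cdf(lif_params(), 70, pde_grid(), t_max = 0.1)
  # instantaneous crossing from below threshold is impossible; on the
  # coarse grid "zero" means small relative to the density peak
  expect_lt(isi_density_at(sol, 0), 0.01 * max(sol$g))
  # node values are reproduced exactly
  j <- 11
  expect_equal(isi_density_at(sol, sol$t[j]), sol$g[j])
  # midpoints average the neighbouring nodes
  tm <- (sol$t[j] + sol$t[j + 1]) / 2
  expect_equal(isi_density_at(sol, tm), (sol$g[j] + sol$g[j + 1]) / 2)
  expect_error(isi_density_at(sol, 1), "horizon")
})

test_that("solved ISI law matches Euler-Maruyama first passages", {
  lif <- lif_params()
  sol <- solve_fpt_cdf(lif, 70, accuracy_grid(), t_max = 0.3)
  set.seed(99)
  fpt <- sample_first_passage(2e4, 70, lif, sim_dt = 1e-4, t_max = 2,
                              bridge = TRUE)
  expect_lt(ks_distance(fpt, sol$t, 1 - sol$survival), 0.03)
})

test_that("empty-interval likelihood is conditional survival", {
  lif <- lif_params(); kern <- kernel_bursting(); grid <- pde_grid()
  # strongly hyperpolarizing input: no spike is almost sure
  ll <- interval_loglik(numeric(0), 1, 1.1, s_curr = -1000,
                        history = 0.99, lif = lif, kernel = kern,
                        grid = grid)
  expect_lte(ll, 0)
  expect_gt(ll, -1e-4)
  # strong depolarization makes silence nearly impossible
  ll2 <- interval_loglik(numeric(0), 1, 1.1, s_curr = 200,
                         history = 0.99, lif = lif, kernel = kern,
                         grid = grid)
  expect_lt(ll2, -50)
})

test_that("interval log-likelihoods add over any partition of the window", {
  sc <- desk1(duration = 1)
  set.seed(50)
  sim <- simulate_trial(sc, "single")
  tr <- sim$trains[[1]]
  w <- tr$window
  lif <- sc$lif; kern <- sc$kernel; grid <- sc$grid
  whole <- interval_loglik(tr$times, w[1], w[2], 70, lif = lif,
                           kernel = kern, grid = grid,
                           window_start = w[1])
  set.seed(51)
  for (rep in 1:5) {
    cuts <- sort(c(w, runif(sample(1:8, 1), w[1], w[2])))
    pieces <- vapply(seq_len(length(cuts) - 1), function(i) {
      Tb <- cuts[i]; Te <- cuts[i + 1]
      interval_loglik(tr$times[tr$times >= Tb & tr$times < Te],
                      Tb, Te, 70, history = tr$times[tr$times < Tb],
                      window_start = w[1], lif = lif, kernel = kern,
                      grid = grid)
    }, numeric(1))
    expect_equal(sum(pieces), whole, tolerance = 1e-9)
  }
})

test_that("a spike at the interval start is handled as a density term", {
  lif <- lif_params(); kern <- kernel_bursting(); grid <- pde_grid()
  hist <- 0.95
  # one spike exactly at Tb: density of that spike (conditional on
  # survival to Tb) times survival to Te
  Tb <- 1; Te <- 1.1
  ll <- interval_loglik(Tb, Tb, Te, 70, history = hist,
                        lif = lif, kernel = kern, grid = grid)
  # manual composition from a fresh solve anchored at the history spike
  # (relative history time 0 = a spike at the solve origin)
  sol1 <- solve_fpt_cdf(lif, 70, grid, t_max = 0.2, kernel = kern,
                        history = 0)
  g1 <- isi_density_at(sol1, Tb - hist)
  s1 <- stats::approx(sol1$t, sol1$survival, xout = Tb - hist)$y
  sol2 <- solve_fpt_cdf(lif, 70, grid, t_max = 0.2, kernel = kern,
                        history = c(hist, Tb) - Tb)
  s2 <- stats::approx(sol2$t, sol2$survival, xout = Te - Tb)$y
  expect_equal(ll, log(g1) - log(s1) + log(s2), tolerance = 1e-6)
})

test_that("whole-train likelihood decomposes over decoding intervals", {
  sc <- desk1(duration = 1)
  set.seed(60)
  sim <- simulate_trial(sc, "single")
  tr <- sim$trains[[1]]
  w <- tr$window
  ll_train <- spiketrain_loglik(tr, 70, sc$lif, sc$kernel, sc$grid)
  breaks <- seq(w[1], w[2], by = 0.1)
  pieces <- vapply(seq_len(length(breaks) - 1), function(i) {
    Tb <- breaks[i]; Te <- breaks[i + 1]
    interval_loglik(tr$times[tr$times >= Tb & tr$times < Te], Tb, Te,
                    70, history = tr$times[tr$times < Tb],
                    window_start = w[1], lif = sc$lif,
                    kernel = sc$kernel, grid = sc$grid)
  }, numeric(1))
  expect_equal(sum(pieces), ll_train, tolerance = 1e-3)
  # empty train: log survival over the window
  empty <- spike_train(numeric(0), c(0, 0.3))
  lle <- spiketrain_loglik(empty, -500, sc$lif, sc$kernel, sc$grid)
  expect_gt(lle, -1e-3); expect_lte(lle, 1e-12)
  # non-degeneracy in the diffusion parameter
  lif2 <- lif_params(sigma = 2)
  ll2 <- spiketrain_loglik(tr, 70, lif2, sc$kernel, sc$grid)
  expect_true(is.finite(ll2))
  expect_false(isTRUE(all.equal(ll2, ll_train)))
})
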