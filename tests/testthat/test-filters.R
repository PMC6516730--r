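test_that("systematic resampling counts are valid and unbiased", {
  set.seed(1)
  I <- 8
  # uniform weights: perfect grid alignment, one copy each
  for (r in 1:5) {
    anc <- systematic_resample(rep(1 / I, I))
    expect_equal(attr(anc, "counts"), rep(1L, I))
  }
  # a one-hot weight vector copies that particle I times
  w1 <- c(0, 0, 1, 0, 0, 0, 0, 0)
  anc <- systematic_resample(w1)
  expect_true(all(anc == 3L))
  expect_equal(sum(attr(anc, "counts")), I)
  # unbiasedness: E[W_i] = I * w_i
  w <- c(0.4, 0.25, 0.2, 0.1, 0.05, 0, 0, 0)
  set.seed(2)
  nrep <- 1e4
  tot <- numeric(I)
  for (r in seq_len(nrep))
    tot <- tot + attr(systematic_resample(w), "counts")
  mhat <- tot / nrep
  se <- sqrt(I * w * pmax(1 - w, 0.01)) / sqrt(nrep) + 1e-3
  expect_true(all(abs(mhat - I * w) < 4 * se))
  expect_error(systematic_resample(c(0.5, 0.2)), "normalized")
})

test_that("marginal attention update matches exhaustive enumeration", {
  tpm <- study_tpm(2)
  # hand case: uniform posterior, likelihoods (0.2, 0.1)
  upd <- marginal_attention_update(c(0.5, 0.5), tpm, log(c(0.2, 0.1)))
  pred <- as.numeric(c(0.5, 0.5) %*% tpm)
  expect_equal(exp(upd$loglik), sum(pred * c(0.2, 0.1)), tolerance = 1e-12)
  expect_equal(as.numeric(upd$post),
               pred * c(0.2, 0.1) / sum(pred * c(0.2, 0.1)),
               tolerance = 1e-12)
  # three intervals, enumeration over all 2^3 attention paths
  set.seed(3)
  lik <- matrix(runif(6, 0.05, 1), 3, 2)   # interval x component
  prior <- c(0.5, 0.5)
  total_enum <- 0
  for (c1 in 1:2) for (c2 in 1:2) for (c3 in 1:2)
    total_enum <- total_enum + prior[c1] * tpm[c1, c2] * tpm[c2, c3] *
      lik[1, c1] * lik[2, c2] * lik[3, c3]
  post <- prior                # interval 1 has no transition before it
  u1 <- marginal_attention_update(post, diag(2), log(lik[1, ]))
  u2 <- marginal_attention_update(u1$post, tpm, log(lik[2, ]))
  u3 <- marginal_attention_update(u2$post, tpm, log(lik[3, ]))
  expect_equal(exp(u1$loglik + u2$loglik + u3$loglik), total_enum,
               tolerance = 1e-12)
  # K = 1 passes the single likelihood through with a unit posterior
  u0 <- marginal_attention_update(1, matrix(1, 1, 1), log(0.3))
  expect_equal(u0$loglik, log(0.3))
  expect_equal(as.numeric(u0$post), 1)
  # identity TPM and equal likelihoods leave the posterior unchanged
  ui <- marginal_attention_update(c(0.3, 0.7), diag(2), log(c(0.2, 0.2)))
  expect_equal(as.numeric(ui$post), c(0.3, 0.7))
})

test_that("population likelihood helpers compose per-train terms", {
  sc <- desk2(duration = 0.5, M = 2)
  set.seed(4)
  sim <- simulate_trial(sc, "serial")
  Tb <- 1.1; Te <- 1.2
  segs <- lapply(sim$trains, function(tr)
    tr$times[tr$times >= Tb & tr$times < Te])
  hists <- lapply(sim$trains, function(tr) tr$times[tr$times < Tb])
  sv <- c(60, 75, 90)
  ser <- serial_population_loglik(segs, hists, Tb, Te, sv,
                                  window_start = 1, lif = sc$lif,
                                  kernel = sc$kernel, grid = sc$grid)
  by_hand <- interval_loglik(segs[[1]], Tb, Te, sv, history = hists[[1]],
                             window_start = 1, lif = sc$lif,
                             kernel = sc$kernel, grid = sc$grid) +
    interval_loglik(segs[[2]], Tb, Te, sv, history = hists[[2]],
                    window_start = 1, lif = sc$lif, kernel = sc$kernel,
                    grid = sc$grid)
  expect_equal(ser, by_hand, tolerance = 1e-12)
  # M = 1 serial reduces to the single-train likelihood
  one <- serial_population_loglik(segs[1], hists[1], Tb, Te, sv,
                                  window_start = 1, lif = sc$lif,
                                  kernel = sc$kernel, grid = sc$grid)
  single <- interval_loglik(segs[[1]], Tb, Te, sv, history = hists[[1]],
                            window_start = 1, lif = sc$lif,
                            kernel = sc$kernel, grid = sc$grid)
  expect_equal(one, single, tolerance = 1e-12)
  # parallel marginal with K = 1 TPM reduces to the serial value
  I <- 3
  S <- matrix(sv, I, 1); Sp <- S
  posts <- list(matrix(1, I, 1), matrix(1, I, 1))
  tpm1 <- array(1, c(I, 1, 1))
  pm <- parallel_marginal_loglik(segs, hists, posts, tpm1, S, Sp,
                                 Tb, Te, window_start = 1, lif = sc$lif,
                                 kernel = sc$kernel, grid = sc$grid)
  expect_equal(pm$loglik, ser, tolerance = 1e-12)
})

test_that("geometric-mean tempering averages per-train log-likelihoods", {
  m <- matrix(c(-10, -20, -30, -40), 2, 2)
  expect_equal(geometric_mean_aux(m), c(-20, -30))
  expect_equal(geometric_mean_aux(c(-5, -6)), c(-5, -6))  # M = 1
  # equal trains: unchanged up to the 1/M scale, so the ESS of the
  # tempered first-stage weights can only go up for unequal trains
  set.seed(5)
  ll <- matrix(rnorm(20 * 50, sd = 8), 50, 20)
  full <- rowSums(ll); temp <- rowMeans(ll)
  wf <- exp(full - max(full)); wf <- wf / sum(wf)
  wt <- exp(temp - max(temp)); wt <- wt / sum(wt)
  expect_gte(ess(wt), ess(wf))
})

test_that("decoding runs are reproducible and estimates stay in hull", {
  sc <- desk1(duration = 1)
  set.seed(6)
  sim <- simulate_trial(sc, "single")
  set.seed(7)
  r1 <- smc_decode(sim$trains, sc, "bf", "single", n_particles = 50,
                   keep_particles = TRUE)
  set.seed(7)
  r2 <- smc_decode(sim$trains, sc, "bf", "single", n_particles = 50)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$gamma_mean, r2$gamma_mean)
  # ESS within [1, I]; weights normalized
  expect_true(all(r1$ess >= 1 - 1e-9 & r1$ess <= 50 + 1e-9))
  expect_equal(rowSums(r1$weights), rep(1, r1$N), tolerance = 1e-9)
  # the attended-stimulus estimate lies in the convex hull of particles
  for (n in seq_len(r1$N)) {
    vals <- r1$val_hist[n, , 1]
    expect_gte(r1$estimates[n, 1], min(vals) - 1e-9)
    expect_lte(r1$estimates[n, 1], max(vals) + 1e-9)
  }
})

test_that("K = 1 marginal filters reproduce their attended counterparts", {
  sc <- desk1(duration = 1)
  set.seed(8)
  sim <- simulate_trial(sc, "single")
  set.seed(9)
  rb <- smc_decode(sim$trains, sc, "bf", "single", n_particles = 40)
  set.seed(9)
  rm <- smc_decode(sim$trains, sc, "mbf", "single", n_particles = 40)
  expect_equal(rm$estimates, rb$estimates, tolerance = 1e-12)
  expect_equal(rm$ess, rb$ess, tolerance = 1e-12)
  set.seed(10)
  ra <- suppressWarnings(
    smc_decode(sim$trains, sc, "apf", "single", n_particles = 40))
  set.seed(10)
  rma <- suppressWarnings(
    smc_decode(sim$trains, sc, "mapf", "single", n_particles = 40))
  expect_equal(rma$estimates, ra$estimates, tolerance = 1e-12)
})

test_that("sorted-component reporting is label-invariant", {
  S <- matrix(c(5, 1, 2, 9), 2, 2)
  B <- matrix(c(0, 0, 0, 0), 2, 2)
  s1 <- smcdecode:::sort_components(S, B)
  # permute the component labels inside each particle
  s2 <- smcdecode:::sort_components(S[, 2:1], B[, 2:1])
  expect_identical(s1, s2)
  expect_true(all(apply(s1, 1, function(r) !is.unsorted(r))))
})

test_that("degenerate-model recovery: the filter finds a noiseless level", {
  # gamma ~ 0 and beta pinned at the truth: the posterior-mean stimulus
  # must converge to beta
  sc <- desk1(duration = 1)
  sc$prop <- propagation_config(V_gamma = 1e-8, V_beta = 1e-8)
  sc$ranges <- init_ranges(max_gamma = 1e-3, max_beta = 200, max_S = 200)
  path <- constant_path(70, duration = 1)
  set.seed(11)
  tr <- simulate_spike_train(sc$lif, sc$kernel, path)
  # pin beta by initializing all particles at 70: emulate via tiny
  # jitter around the truth using the init range trick is not possible,
  # so instead check stimulus tracking: posterior mean near 70 by the end
  set.seed(12)
  res <- smc_decode(tr, sc, "bf", "single", n_particles = 200)
  final <- res$estimates[res$N, 1]
  expect_lt(abs(final - 70), 15)
})

test_that("a baseline-level prior mean decodes worse than the filter", {
  sc <- desk1()
  ok <- 0
  for (s in 1:6) {
    set.seed(20 + s)
    sim <- simulate_trial(sc, "single")
    res <- smc_decode(sim$trains, sc, "bf", "single", n_particles = 100)
    truth <- attended_truth(sim$paths[[1]])
    r_f <- rrmsd(res$estimates[, 1], truth)
    r_base <- rrmsd(rep(100, res$N), truth)   # prior-mean baseline
    ok <- ok + (r_f < r_base)
  }
  expect_gte(ok, 5)
})

test_that("likelihood breakdown aborts with a structured error", {
  sc <- desk1(duration = 0.3)
  set.seed(30)
  sim <- simulate_trial(sc, "single")
  bad_backend <- function(n, m, s_curr, s_prev) rep(-Inf, length(s_curr))
  expect_error(
    smc_decode(sim$trains, sc, "bf", "single", n_particles = 20,
               loglik_fun = bad_backend),
    class = "smc_degeneracy_error")
})

test_that("flat likelihoods make auxiliary stages uninformative", {
  sc <- desk1(duration = 0.5)
  set.seed(31)
  sim <- simulate_trial(sc, "single")
  flat <- function(n, m, s_curr, s_prev) rep(-1, length(s_curr))
  res <- smc_decode(sim$trains, sc, "apf", "single", n_particles = 30,
                    loglik_fun = flat)
  # first-stage weights are uniform, second-stage ratios are 1: the
  # final weights stay uniform at every interval
  expect_equal(res$ess, rep(30, res$N), tolerance = 1e-9)
})
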