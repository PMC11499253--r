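test_that("sim_config enforces its invariants", {
  expect_error(sim_config(tau_slow = 5, tau_fast = 10))
  expect_error(sim_config(emission_noise_sd = -1))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical (config, seed) gives bit-identical sessions", {
  s1 <- simulate_session(sim_config(seed = 9, duration_frames = 1500,
                                    n_neurons = 20))
  s2 <- simulate_session(sim_config(seed = 9, duration_frames = 1500,
                                    n_neurons = 20))
  expect_identical(s1$latents$x, s2$latents$x)
  expect_identical(unclass(s1$raster), unclass(s2$raster))
  expect_identical(s1$male_bouts$start, s2$male_bouts$start)
  expect_identical(s1$female_bouts$start, s2$female_bouts$start)
})

test_that("male bout process: escalation order, degenerate input, IBI", {
  b <- simulate_male_bouts(sim_config(seed = 3))
  sn <- b[b$behavior == "sniff", ]
  mt <- b[b$behavior == "mount", ]
  it <- b[b$behavior == "intromission", ]
  expect_lt(min(sn$start), min(mt$start))
  expect_lt(min(mt$start), min(it$start))
  # non-overlap across all bouts (sequential process)
  bo <- b[order(b$start), ]
  expect_true(all(bo$start[-1] >= bo$stop[-nrow(bo)]))
  # zero-length session
  b0 <- simulate_male_bouts(sim_config(duration_frames = 0))
  expect_equal(nrow(b0), 0)
  expect_true(attr(b0, "warning_flag"))
})

test_that("mean copulation IBI matches the 13.7-s target over 50 seeds", {
  ibis <- vapply(1:50, function(s)
    bout_ibi_stats(simulate_male_bouts(sim_config(seed = s)))$mean_ibi,
    numeric(1))
  expect_equal(mean(ibis), 13.7, tolerance = 0.2)
})

test_that("latent dynamics: fixed point, impulse decay, ramp accumulation", {
  cfg <- sim_config(duration_frames = 3000, seed = 1)
  empty <- bout_table(frame_rate = 10)
  # zero input, zero noise, x0 = 0 stays at 0
  lat0 <- simulate_latents(cfg, empty, noise_sd = 0)
  expect_true(all(lat0$x == 0))
  # a unit impulse into the slow dimension decays as exp(-t/tau_slow)
  one_sniff <- bt("male", "sniff", 10, 20)
  cfg2 <- sim_config(duration_frames = 3000,
                     input_gain = c(sniff = 1, mount = 0,
                                    intromission = 0),
                     fast_kick = 0, sustained_gain = 0, seed = 1)
  lat1 <- simulate_latents(cfg2, one_sniff, noise_sd = 0)
  peak_t <- 11                       # onset frame (1-based)
  peak <- lat1$x[1, peak_t]
  k <- cfg2$tau_slow * cfg2$frame_rate   # frames per tau_slow
  expect_equal(lat1$x[1, peak_t + k] / peak, exp(-1), tolerance = 1e-6)
  # 20 spaced impulses: slow-dim value after pulse k strictly increasing
  starts <- seq(50, 2900, length.out = 20)
  pulses <- bt(rep("male", 20), rep("sniff", 20), starts, starts + 5)
  latp <- simulate_latents(cfg2, pulses, noise_sd = 0)
  after <- latp$x[1, round(starts) + 3]
  expect_true(all(diff(after) > 0))
  # unstable dynamics are rejected
  cfg_bad <- sim_config()
  cfg_bad$tau_slow <- -100   # bypasses constructor checks on purpose
  expect_error(simulate_latents(cfg_bad, empty), "unstable")
})

test_that("emissions: identity case, z-scoring contract, SNR monotonicity", {
  cfg <- sim_config(duration_frames = 800, n_neurons = 2, D = 2, seed = 4)
  ses_lat <- simulate_latents(cfg, simulate_male_bouts(cfg))
  cfg0 <- cfg; cfg0$emission_noise_sd <- 0
  r <- simulate_emissions(ses_lat, cfg0, C = diag(2), d = rep(0, 2))
  zlat <- t(scale(t(ses_lat$x)))
  expect_equal(unclass(r), zlat, tolerance = 1e-12,
               ignore_attr = TRUE)
  # z-scoring: every row mean 0, sd 1
  cfgN <- sim_config(duration_frames = 800, n_neurons = 30, seed = 4)
  r2 <- simulate_emissions(ses_lat, cfgN)
  expect_true(all(abs(rowMeans(r2)) < 1e-9))
  expect_true(all(abs(apply(r2, 1, sd) - 1) < 1e-9))
  # n_neurons < D rejected
  cfg_small <- sim_config(duration_frames = 800, n_neurons = 1, D = 2)
  expect_error(simulate_emissions(ses_lat, cfg_small), ">=")
  # readout quality of the slow latent degrades monotonically with noise
  cors <- vapply(c(0.1, 1, 4), function(nsd) {
    cc <- sim_config(duration_frames = 800, n_neurons = 30, seed = 4,
                     emission_noise_sd = nsd)
    mean(vapply(1:10, function(s) {
      cc$seed <- s
      lat <- simulate_latents(cc, simulate_male_bouts(cc))
      rr <- simulate_emissions(lat, cc)
      # best linear readout via least squares
      w <- qr.solve(t(unclass(rr)), lat$x[1, ])
      cor(as.numeric(t(w) %*% unclass(rr)), lat$x[1, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("female behaviour link couples acceptance to the slow latent", {
  # strong gain: rank correlation of slow-latent AUC vs acceptance > 0.7
  stats_for <- function(gain) {
    vapply(1:50, function(s) {
      cfg <- sim_config(seed = s, duration_frames = 3000, n_neurons = 5)
      male <- simulate_male_bouts(cfg)
      lat <- simulate_latents(cfg, male)
      fem <- simulate_female_behavior(lat, male,
                                      link_params = list(gain = gain,
                                                         midpoint = 2),
                                      seed = s)
      c(auc = mean(lat$x[1, ]),
        acc = acceptance_fraction(fem, male, cfg$duration_frames))
    }, numeric(2))
  }
  strong <- stats_for(3)
  keep <- is.finite(strong["acc", ])
  expect_gt(cor(strong["auc", keep], strong["acc", keep],
                method = "spearman"), 0.7)
  # null link: correlation ~ 0
  null <- stats_for(0)
  keep0 <- is.finite(null["acc", ])
  expect_lt(abs(cor(null["auc", keep0], null["acc", keep0],
                    method = "spearman")), 0.3)
  # no male bouts -> no female bouts
  cfg <- sim_config(duration_frames = 100, seed = 1)
  lat <- simulate_latents(cfg, bout_table(frame_rate = 10))
  fem0 <- simulate_female_behavior(lat, bout_table(frame_rate = 10))
  expect_equal(nrow(fem0), 0)
})

test_that("perturbations: identity, orthogonal relaxation, slow persistence", {
  cfg <- sim_config(duration_frames = 2000, seed = 5)
  male <- simulate_male_bouts(cfg)
  lat <- simulate_latents(cfg, male, noise_sd = 0)
  win <- list(c(800, 900))
  # zero kick leaves the trajectory untouched
  p0 <- simulate_perturbation(lat, win, kick = c(0, 0))
  expect_identical(p0$x, lat$x)
  # orthogonal kick relaxes back with tau_fast
  pk <- simulate_perturbation(lat, win, kick = c(0, 1))
  delta <- attr(pk, "delta")
  d_end <- delta[2, 900]
  tfast_frames <- cfg$tau_fast * cfg$frame_rate
  expect_equal(delta[2, 900 + tfast_frames] / d_end, exp(-1),
               tolerance = 1e-9)
  # slow-dim value at window end close to its pre-window value
  expect_equal(pk$x[1, 900], lat$x[1, 900], tolerance = 1e-9)
  # kick along the slow dimension persists far beyond tau_fast
  ps <- simulate_perturbation(lat, win, kick = c(1, 0))
  ds <- attr(ps, "delta")
  ratio_slow <- ds[1, 900 + 3 * tfast_frames] / ds[1, 900]
  ratio_fast <- delta[2, 900 + 3 * tfast_frames] / d_end
  # slow-dim displacement decays with tau_slow (closed form), far slower
  # than the orthogonal displacement (exp(-3) after 3 tau_fast)
  expect_equal(ratio_slow,
               exp(-3 * tfast_frames / (cfg$tau_slow * cfg$frame_rate)),
               tolerance = 1e-9)
  expect_gt(ratio_slow, 10 * ratio_fast)
  # overlapping windows rejected
  expect_error(simulate_perturbation(lat, list(c(100, 200), c(150, 300))),
               "overlap")
})

test_that("generative line-attractor score separates the regimes", {
  fr <- 10
  for (s in 1:5) {
    cr <- sim_config(seed = s)
    Ar <- true_dynamics(cr)
    taus_r <- sort(lineattractor:::tau_from_lambda(
      Mod(eigen(Ar, only.values = TRUE)$values)), decreasing = TRUE)
    score_r <- log2(taus_r[1] / taus_r[2])
    expect_equal(score_r, log2(cr$tau_slow / cr$tau_fast),
                 tolerance = 1e-9)
    cu <- sim_config(seed = s, regime = "unreceptive")
    Au <- true_dynamics(cu)
    taus_u <- sort(lineattractor:::tau_from_lambda(
      Mod(eigen(Au, only.values = TRUE)$values)), decreasing = TRUE)
    expect_lt(log2(taus_u[1] / taus_u[2]), 1)
    # unreceptive: no eigenvalue slower than 2 * tau_fast
    expect_true(all(taus_u / fr < 2 * cu$tau_fast))
  }
})
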