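test_that("K=1 EM recovers a noise-free LDS nearly exactly", {
  set.seed(10)
  D <- 2; N <- 12; T_ <- 800
  # damped rotation: deterministic transient explores both dimensions
  rho <- 0.995; th <- 0.2
  A <- rho * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  x <- matrix(0, D, T_); xp <- c(3, 0)
  for (t in 1:T_) { xp <- A %*% xp; x[, t] <- xp }
  C <- matrix(rnorm(N * D), N, D)
  Y <- C %*% x + rnorm(N * T_, 0, 1e-3)
  r <- population_raster(Y, frame_rate = 10)
  fit <- fit_rslds(r, K = 1, D = 2, seed = 1)
  ev_hat <- eigen(fit$model$A[[1]], only.values = TRUE)$values
  expect_equal(sort(Mod(ev_hat)), rep(rho, 2), tolerance = 0.01)
  fsa <- forward_sim_accuracy(fit)
  expect_gt(fsa$var_explained, 0.99)
  # log-likelihood non-decreasing over EM iterations (within tolerance)
  tr <- fit$diagnostics$elbo_trace
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-length(tr)])))
})

test_that("time constants follow the eigenvalue formula", {
  mk <- function(A) rslds_model(A, rep(0, 2), diag(1e-4, 2),
                                C = diag(2), frame_rate = 10)
  # lambda = e^{-0.01} -> tau = 100 frames = 10 s at 10 Hz
  tc <- time_constants(mk(diag(c(exp(-0.01), 0))))
  expect_equal(tc$tau_frames[1], 100, tolerance = 1e-9)
  expect_equal(tc$tau_s[1], 10, tolerance = 1e-9)
  # lambda = 0 -> tau = 0
  expect_equal(tc$tau_frames[2], 0)
  # |lambda| >= 1 capped and flagged
  tc2 <- time_constants(mk(diag(c(1.05, 0.5))), cap_frames = 1e6)
  expect_true(tc2$capped[tc2$modulus > 1])
  expect_equal(max(tc2$tau_frames), 1e6)
  # complex conjugate pair shares one pair_id and equal taus
  rot <- 0.95 * matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2)
  tc3 <- time_constants(mk(rot))
  expect_equal(length(unique(tc3$pair_id)), 1)
  expect_equal(diff(tc3$tau_frames), 0)
})

test_that("line-attractor score contrasts slow/fast spectra", {
  mk <- function(taus, fr = 10) {
    lams <- exp(-1 / (taus * fr))
    rslds_model(diag(lams), rep(0, 2), diag(1e-4, 2), C = diag(2),
                frame_rate = fr)
  }
  expect_equal(line_attractor_score(time_constants(mk(c(100, 5)))),
               log2(20), tolerance = 1e-9)
  expect_equal(line_attractor_score(time_constants(mk(c(5, 5)))), 0,
               tolerance = 1e-9)
  # zero second time constant -> flagged NA
  m0 <- rslds_model(diag(c(0.9, 0)), rep(0, 2), diag(1e-4, 2),
                    C = diag(2))
  expect_true(is.na(line_attractor_score(time_constants(m0))))
})

test_that("forward simulation: exact model gives accuracy 1; bounds hold", {
  set.seed(2)
  A <- diag(c(0.95, 0.8)); b <- c(0.1, 0)
  x <- matrix(0, 2, 400); xp <- c(1, 1)
  for (t in 1:400) { xp <- A %*% xp + b; x[, t] <- xp }
  m <- rslds_model(A, b, diag(1e-6, 2), C = diag(2))
  lat <- structure(list(x = x, z = rep(1L, 400),
                        credences = matrix(1, 400, 1), frame_rate = 10),
                   class = "latent_trajectory")
  fsa <- forward_sim_accuracy(m, lat, dt_s = 1)
  expect_true(all(abs(fsa$mse) < 1e-20))
  expect_true(all(fsa$accuracy >= 0 & fsa$accuracy <= 1))
  expect_equal(fsa$var_explained, 1, tolerance = 1e-9)
  # time-shuffled latents are predicted far worse than intact ones
  ses <- cached_session(seed = 4, duration_frames = 2000, n_neurons = 30)
  fit <- fit_rslds(ses$raster, K = 1, D = 2, seed = 1)
  fsa_fit <- forward_sim_accuracy(fit)
  lat_sh <- fit$latents
  set.seed(9); lat_sh$x <- lat_sh$x[, sample(ncol(lat_sh$x))]
  fsa_sh <- forward_sim_accuracy(fit$model, lat_sh)
  expect_gt(fsa_fit$var_explained, fsa_sh$var_explained + 0.2)
})

test_that("integration dimension tracks the true slow latent", {
  ses <- cached_session(seed = 4, duration_frames = 2000, n_neurons = 30)
  fit <- fit_rslds(ses$raster, K = 1, D = 2,
                   inputs = male_inputs(ses$male_bouts, 2000), seed = 1)
  idim <- integration_dimension(fit)
  expect_true(idim$has_integration_dim)
  expect_gt(abs(cor(idim$raw, ses$latents$x[1, ])), 0.9)
  expect_true(all(idim$series >= 0 & idim$series <= 1))  # minmax
  # persistence: each IBI's mean matches the preceding bout's mean
  # (activity in the integration dimension survives the pause)
  cop <- filter_bouts(ses$male_bouts, actor = "male", group = "copulation")
  iv <- lineattractor:::interval_union(cop$start, cop$stop)
  ratios <- vapply(seq_len(nrow(iv) - 1), function(i) {
    b_idx <- (iv$start[i] + 1):iv$stop[i]
    i_idx <- (iv$stop[i] + 1):iv$start[i + 1]
    mean(idim$series[i_idx]) / mean(idim$series[b_idx])
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  med <- stats::median(ratios[seq(ceiling(length(ratios) / 2),
                                  length(ratios))])  # past the early ramp
  expect_gt(med, 0.8)
  expect_lt(med, 1.25)
  # unreceptive session: no integration dimension
  sesu <- cached_session(seed = 4, regime = "unreceptive",
                         duration_frames = 2000, n_neurons = 30)
  fitu <- fit_rslds(sesu$raster, K = 1, D = 2,
                    inputs = male_inputs(sesu$male_bouts, 2000), seed = 1)
  expect_false(integration_dimension(fitu)$has_integration_dim)
})

test_that("flow field geometry: fixed points, slow regions", {
  # point attractor: A x* + b = x* at x* = (2, 1)
  A <- diag(c(0.8, 0.7)); xstar <- c(2, 1)
  b <- as.numeric((diag(2) - A) %*% xstar)
  m <- rslds_model(A, b, diag(1e-4, 2), C = diag(2))
  set.seed(3)
  x <- matrix(0, 2, 500); xp <- c(0, 0)
  for (t in 1:500) { xp <- A %*% xp + b + rnorm(2, 0, 0.3); x[, t] <- xp }
  lat <- structure(list(x = x, z = rep(1L, 500),
                        credences = matrix(1, 500, 1), frame_rate = 10),
                   class = "latent_trajectory")
  ff <- flow_field_2d(m, lat, n_grid = 21)
  # velocity at the true fixed point is ~0
  gstar <- as.numeric(t(ff$basis) %*% (xstar - ff$center))
  d2 <- (ff$grid[, 1] - gstar[1])^2 + (ff$grid[, 2] - gstar[2])^2
  expect_true(ff$slow_mask[which.min(d2)])
  v_at_star <- (A %*% xstar + b) - xstar
  expect_lt(sqrt(sum(v_at_star^2)), 1e-9)
  # line attractor: slow region is elongated
  A2 <- diag(c(0.9995, 0.75))
  m2 <- rslds_model(A2, c(0, 0), diag(1e-4, 2), C = diag(2))
  set.seed(4)
  x2 <- matrix(0, 2, 800); xp <- c(0, 0)
  for (t in 1:800) {
    xp <- A2 %*% xp + c(abs(rnorm(1, 0, 0.05)), rnorm(1, 0, 0.3))
    x2[, t] <- xp
  }
  lat2 <- structure(list(x = x2, z = rep(1L, 800),
                         credences = matrix(1, 800, 1), frame_rate = 10),
                    class = "latent_trajectory")
  ff2 <- flow_field_2d(m2, lat2, n_grid = 25, slow_quantile = 0.05)
  slow_pts <- ff2$grid[ff2$slow_mask, , drop = FALSE]
  sv <- svd(scale(slow_pts, scale = FALSE))$d
  expect_gt(sv[1] / max(sv[2], 1e-9), 5)   # aspect ratio of slow band
})

test_that("projection into a frozen model is self-consistent and guarded", {
  ses <- cached_session(seed = 4, duration_frames = 2000, n_neurons = 30)
  fit <- fit_rslds(ses$raster, K = 1, D = 2, seed = 1)
  lat2 <- project_into_model(fit$model, ses$raster)
  for (dd in 1:2)
    expect_gt(abs(cor(lat2$x[dd, ], fit$latents$x[dd, ])), 0.99)
  # neuron count mismatch rejected
  expect_error(project_into_model(fit$model,
                                  population_raster(ses$raster[1:10, ],
                                                    frame_rate = 10)),
               "mismatch")
  # neuron identity mismatch rejected when ids are carried
  Y <- unclass(ses$raster); rownames(Y) <- paste0("n", seq_len(nrow(Y)))
  rid <- population_raster(Y, frame_rate = 10)
  fit2 <- fit_rslds(rid, K = 1, D = 2, seed = 1, max_iter = 5)
  Yp <- Y[rev(seq_len(nrow(Y))), ]
  expect_error(project_into_model(fit2$model,
                                  population_raster(Yp, frame_rate = 10)),
               "identities")
  # unreceptive data projected into a receptive-day model: no net ramp
  sesu <- cached_session(seed = 4, regime = "unreceptive",
                         duration_frames = 2000, n_neurons = 30)
  latu <- project_into_model(fit$model, sesu$raster)
  idir <- integration_dimension(fit)$direction
  proj_r <- as.numeric(t(idir) %*% fit$latents$x)
  proj_u <- as.numeric(t(idir) %*% latu$x)
  ramp_r <- mean(tail(proj_r, 100)) - mean(head(proj_r, 100))
  ramp_u <- mean(tail(proj_u, 100)) - mean(head(proj_u, 100))
  expect_lt(abs(ramp_u), 0.2 * abs(ramp_r))
})

test_that("PLS finds the integration dimension and respects nulls", {
  # a neuron identical to the target dominates the weights
  set.seed(5)
  target <- cumsum(abs(rnorm(600, 0.1)))
  Y <- rbind(target, matrix(rnorm(5 * 600), 5))
  r <- population_raster(Y, frame_rate = 10)
  pls <- pls_integration_dimension(r, target)
  expect_gt(abs(pls$weights[1]), 0.9)
  # white-noise raster: held-out correlation near 0
  rn <- population_raster(matrix(rnorm(6 * 600), 6), frame_rate = 10)
  pls0 <- pls_integration_dimension(rn, target)
  expect_lt(abs(pls0$r_holdout), 0.45)
  expect_error(pls_integration_dimension(rn, rep(1, 600)),
               "zero-variance")
  # method agreement on a receptive session
  ses <- cached_session(seed = 4, duration_frames = 2000, n_neurons = 30)
  fit <- fit_rslds(ses$raster, K = 1, D = 2, seed = 1)
  idim <- integration_dimension(fit)
  pls2 <- pls_integration_dimension(ses$raster, ses$latents$x[1, ])
  expect_gt(abs(cor(pls2$projection, idim$raw)), 0.8)
})

test_that("model order selection recovers D = 2 and honours trivial grids", {
  ses <- cached_session(seed = 7, duration_frames = 1500, n_neurons = 20)
  sel <- select_model_order(ses$raster, K_grid = 1, D_grid = 1:3,
                            folds = 3, max_iter = 15, seed = 1)
  expect_equal(sel$K, 1)
  expect_equal(sel$D, 2)
  # held-out score improves sharply from D=1 to D=2, then plateaus
  ms <- sel$mean_scores
  expect_gt(ms[2] - ms[1], abs(ms[3] - ms[2]))
})

test_that("excluding perturbation windows still recovers the dynamics", {
  cfg <- sim_config(seed = 11, duration_frames = 2000, n_neurons = 30)
  male <- simulate_male_bouts(cfg)
  lat <- simulate_latents(cfg, male)
  windows <- list(c(700, 800), c(1300, 1400))
  pert <- simulate_perturbation(lat, windows, kick = c(0, 0.8))
  raster <- simulate_emissions(pert, cfg)
  res <- fit_excluding_windows(raster, windows, K = 1, D = 2, seed = 1)
  expect_gt(res$cvR2, 0.5)
  ev <- sort(Mod(eigen(res$fit$model$A[[1]], only.values = TRUE)$values),
             decreasing = TRUE)
  taus <- lineattractor:::tau_from_lambda(ev) / 10
  expect_gt(log2(taus[1] / taus[2]), 1.5)
  # empty window set behaves like a plain fit
  plain <- fit_excluding_windows(raster, list(), K = 1, D = 2, seed = 1)
  expect_s3_class(plain$model, "rslds_model")
})
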