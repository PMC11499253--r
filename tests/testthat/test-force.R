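test_that("FORCE training drives readouts to zero targets", {
  set.seed(20)
  targets <- population_raster(matrix(0, 4, 200), frame_rate = 10)
  rnn <- train_force(targets, n_passes = 3, seed = 2)
  # after the initial-state transient has decayed, readouts are ~0
  resid <- sqrt(mean(rnn$readout_eval[, -(1:60)]^2))
  expect_lt(resid, 1e-3)
  # training error decreases across passes
  expect_lt(rnn$train_error[3], rnn$train_error[1])
})

test_that("fixed-point search solves the linear network exactly", {
  J <- 0.5 * diag(6)
  rnn <- force_rnn(J, g = 1)
  set.seed(1)
  inits <- matrix(rnorm(6 * 10, 0, 2), 6)
  fp <- find_fixed_points(rnn, inits = inits, tol = 1e-6)
  expect_gte(fp$n_converged, 1)
  expect_lt(sqrt(sum(fp$points[, 1]^2)), 1e-6)
  # stable: Jacobian eigenvalues negative
  expect_true(all(fp$max_re_eig < 0))
  # empty point set when the tolerance excludes everything
  fp0 <- find_fixed_points(rnn, inits = inits, tol = 1e-300)
  if (fp0$n_converged == 0) expect_match(fp0$flag, "no converged")
})

test_that("planted line-attractor network yields collinear slow points", {
  # rank-one J = u u^T / ||u||^2 with unit gain: along u the dynamics are
  # a = tanh(a), whose slow manifold near the origin is a 1-D continuum
  set.seed(22)
  N <- 20
  u <- rnorm(N); u <- u / sqrt(sum(u^2))
  J <- tcrossprod(u)
  rnn <- force_rnn(J, g = 1)
  inits <- u %o% seq(-1, 1, length.out = 24) +
    matrix(rnorm(N * 24, 0, 0.2), N)
  fp <- find_fixed_points(rnn, inits = inits, tol = 2e-2,
                          dedup_radius = 1e-4)
  expect_gte(fp$n_converged, 5)
  # PCA line fit of the slow points: near-perfect collinearity
  P <- t(fp$points)
  P <- sweep(P, 2, colMeans(P))
  sv <- svd(P)$d
  expect_gt(sv[1]^2 / sum(sv^2), 0.95)
})

test_that("FORCE reproduces the signal component of synthetic traces", {
  ses <- cached_session(seed = 19)   # full-scale session, 100 units
  inputs <- male_input_series(
    ses$male_bouts, ncol(ses$raster))$indicator
  rnn <- train_force(ses$raster, inputs = inputs, n_passes = 4, seed = 3)
  # training error decreases over passes
  expect_lt(rnn$train_error[4], rnn$train_error[1])
  # reconstruction of the generator's noiseless trace (the observation
  # noise itself is irreproducible by construction)
  clean <- attr(ses$raster, "true_C") %*% ses$latents$x +
    attr(ses$raster, "true_d")
  clean <- t(scale(t(clean)))
  t_sim <- rnn$t_sim
  clean_s <- t(apply(clean, 1, function(v)
    approx((seq_len(ncol(clean)) - 1) / 10, v, t_sim, rule = 2)$y))
  keep <- vapply(seq_len(rnn$N), function(i) sd(clean_s[i, ]) > 0,
                 logical(1))
  r2_sig <- vapply(which(keep), function(i)
    cor(rnn$readout_eval[i, ], clean_s[i, ])^2, numeric(1))
  expect_gt(median(r2_sig), 0.8)
})

test_that("untrained network is chaotic; training fixes the readout", {
  set.seed(23)
  divergence <- function(J, g, x0, steps = 400, dt = 0.05, tau = 0.5) {
    x1 <- x0; x2 <- x0 + rnorm(length(x0), 0, 1e-6)
    for (t in seq_len(steps)) {
      x1 <- x1 + dt / tau * (-x1 + g * as.numeric(J %*% tanh(x1)))
      x2 <- x2 + dt / tau * (-x2 + g * as.numeric(J %*% tanh(x2)))
    }
    sqrt(sum((x1 - x2)^2)) / 1e-6
  }
  ses <- cached_session(seed = 19, duration_frames = 1200, n_neurons = 40)
  rnn <- train_force(ses$raster, n_passes = 3, seed = 4)
  # chaotic amplification of a tiny perturbation at g = 1.5 pre-training
  expect_gt(divergence(rnn$J0, g = 1.5, x0 = rnorm(40, 0, 0.5)), 1)
  # training moves the readout from chaos-level error to target-level:
  # the untrained matrix reconstructs nothing of the data trajectory
  err_trained <- mean((rnn$readout_eval - rnn$targets_sim)^2)
  # readout of the untrained J along the same (data-driven) trajectory
  x <- rnorm(40, 0, 0.5); adt <- rnn$dt / rnn$tau
  err0 <- 0
  for (t in seq_len(ncol(rnn$targets_sim))) {
    z0 <- as.numeric(rnn$J0 %*% tanh(x))
    err0 <- err0 + mean((z0 - rnn$targets_sim[, t])^2)
    x <- x + adt * (-x + rnn$g * rnn$targets_sim[, t])
  }
  err0 <- err0 / ncol(rnn$targets_sim)
  expect_lt(err_trained, 0.5 * err0)
})

test_that("projection into the rSLDS plane localises RNN fixed points", {
  ses <- cached_session(seed = 19, duration_frames = 1200, n_neurons = 40)
  fit <- fit_rslds(ses$raster, K = 1, D = 2, seed = 1)
  flow <- flow_field_2d(fit, n_grid = 21, slow_quantile = 0.2)
  rnn <- train_force(ses$raster, n_passes = 4, seed = 3)
  fp <- find_fixed_points(rnn, n_inits = 12, tol = 1, seed = 5)
  pr <- project_points(fp, rnn, flow, fit)
  expect_equal(nrow(pr$coords), fp$n_converged)
  # mapped coordinates are finite and the overlap statistic well-defined
  expect_true(all(is.finite(pr$coords)))
  expect_true(pr$overlap >= 0 && pr$overlap <= 1)
  # slow states of the network readout project inside (or just beyond)
  # the latent data region spanned by the flow field
  rng1 <- range(flow$traj[, 1]); rng2 <- range(flow$traj[, 2])
  pad1 <- diff(rng1); pad2 <- diff(rng2)
  expect_true(all(pr$coords[, 1] > rng1[1] - pad1 &
                    pr$coords[, 1] < rng1[2] + pad1))
  expect_true(all(pr$coords[, 2] > rng2[1] - pad2 &
                    pr$coords[, 2] < rng2[2] + pad2))
  # empty set projects to empty output
  fp_empty <- structure(list(points = matrix(0, 40, 0), speed = numeric(0),
                             max_re_eig = numeric(0), n_converged = 0),
                        class = "fixed_point_set")
  expect_equal(nrow(project_points(fp_empty, rnn, flow, fit)$coords), 0)
  # dimension mismatch rejected
  expect_error(project_points(fp, force_rnn(diag(5)), flow, fit),
               "mismatch")
})
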