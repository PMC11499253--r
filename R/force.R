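#' Train a rate RNN to reproduce target traces with FORCE
#'
#' Recursive-least-squares (FORCE) training of a tanh rate network whose
#' units correspond one-to-one to target traces. Unit dynamics follow
#' `tau dx_i/dt = -x_i + g z_i + H_i(t)` with readouts
#' `z_i = sum_j J_ij r(x_j)` (`r = tanh`) and external input
#' `H = J_in u(t)`; the full recurrent matrix `J` and the input weights
#' (appended to the RLS regressor) are updated against the error
#' `e_i = z_i - f_i` every `learn_every` steps.
#'
#' During training passes the network is teacher-driven: the recurrent
#' drive is the target `g f(t)` rather than the imperfect readout, so the
#' unit states traverse the trajectory the trained network is meant to
#' visit while RLS makes the readout of that trajectory reproduce the
#' targets. Reconstruction R^2 per unit is then measured on a final pass
#' with learning frozen. (Fully autonomous replay of input-driven ramping
#' targets is generally unstable for networks this small; see the methods
#' vignette. `free_run = TRUE` runs the closed loop instead, for
#' diagnostics.)
#'
#' Targets sampled at the raster frame rate are linearly interpolated to
#' the integration step (default 0.05 s).
#'
#' @param targets a [population_raster()] (or plain matrix) of target
#'   traces `f_i(t)`, units x frames.
#' @param inputs optional m x frames matrix of input time series (e.g.
#'   male behaviour indicators); input weights are learned.
#' @param g chaotic gain scaling the recurrent drive (default 1.5).
#' @param tau unit time constant, seconds (default 0.5).
#' @param dt Euler step, seconds (default 0.05).
#' @param n_passes training passes (default 4).
#' @param learn_every RLS update interval in steps (default 2).
#' @param alpha RLS regularisation (P initialised to `I/alpha`).
#' @param train_noise s.d. of state noise injected during training
#'   (default 0; robustness knob).
#' @param free_run evaluate the closed loop (readout feedback) instead of
#'   the data-driven pass.
#' @param frame_rate frames/s of the targets (default from raster).
#' @param seed integer seed.
#' @return a `force_rnn`: list with `J` (learned), `J0` (initial),
#'   `J_in`, `g`, `tau`, `dt`, `r2` (per unit, evaluation pass),
#'   `train_error` (per-pass mean squared readout error, decreasing),
#'   `readout_eval`, `targets_sim`, `state_samples` (visited states for
#'   fixed-point seeding).
#' @export
train_force <- function(targets, inputs = NULL, g = 1.5, tau = 0.5,
                        dt = 0.05, n_passes = 4, learn_every = 2,
                        alpha = 1, train_noise = 0, free_run = FALSE,
                        frame_rate = NULL, seed = 1) {
  F_ <- unclass(targets)
  if (is.null(frame_rate)) frame_rate <- attr(targets, "frame_rate")
  if (is.null(frame_rate)) stop("frame_rate required")
  N <- nrow(F_)
  if (N < 2) stop("need at least 2 target traces")
  if (!all(is.finite(F_))) stop("targets must be finite")
  t_frames <- (seq_len(ncol(F_)) - 1) / frame_rate
  t_sim <- seq(0, max(t_frames), by = dt)
  Fs <- t(apply(F_, 1, function(v)
    stats::approx(t_frames, v, t_sim, rule = 2)$y))
  m_in <- if (is.null(inputs)) 0L else nrow(inputs)
  Us <- if (m_in > 0)
    t(apply(inputs, 1, function(v)
      stats::approx(t_frames, v, t_sim, rule = 2)$y))
  else NULL
  Tn <- ncol(Fs)

  set.seed(derive_seed(seed, 11))
  J0 <- matrix(stats::rnorm(N * N, 0, 1 / sqrt(N)), N, N)
  J <- J0
  J_in <- if (m_in > 0) matrix(stats::runif(N * m_in, -1, 1), N, m_in)
          else NULL
  P <- diag(1 / alpha, N + m_in)
  x <- stats::rnorm(N, 0, 0.5)
  adt <- dt / tau
  sqdt <- sqrt(adt)
  train_error <- numeric(n_passes)
  n_samp <- 200
  samp_at <- unique(pmax(1, round(seq(1, Tn, length.out = n_samp))))

  input_at <- function(t) {
    if (m_in > 0) as.numeric(J_in %*% Us[, t]) else 0
  }

  # teacher-forced pass with RLS updates (closes over J, J_in, P)
  for (pass in seq_len(n_passes)) {
    err_acc <- 0; n_err <- 0
    for (t in seq_len(Tn)) {
      r <- tanh(x)
      z <- as.numeric(J %*% r) + input_at(t)
      x <- x + adt * (-x + g * Fs[, t] + input_at(t))
      if (train_noise > 0)
        x <- x + stats::rnorm(N, 0, train_noise) * sqdt
      if (t %% learn_every == 0) {
        e <- z - Fs[, t]
        reg <- if (m_in > 0) c(r, Us[, t]) else r
        Pr <- as.numeric(P %*% reg)
        k <- 1 / (1 + sum(reg * Pr))
        P <- P - k * tcrossprod(Pr)
        upd <- (k * e) %o% Pr
        J <- J - upd[, seq_len(N), drop = FALSE]
        if (m_in > 0)
          J_in <- J_in - upd[, N + seq_len(m_in), drop = FALSE]
        err_acc <- err_acc + mean(e^2); n_err <- n_err + 1
      }
      if (any(!is.finite(x))) stop("FORCE training diverged at step ", t)
    }
    train_error[pass] <- err_acc / n_err
  }

  # frozen evaluation pass
  Z <- matrix(0, N, Tn)
  samples <- matrix(0, N, length(samp_at)); si <- 1
  x <- stats::rnorm(N, 0, 0.5)
  for (t in seq_len(Tn)) {
    r <- tanh(x)
    z <- as.numeric(J %*% r) + input_at(t)
    drive <- if (free_run) g * z else g * Fs[, t]
    x <- x + adt * (-x + drive + input_at(t))
    Z[, t] <- z
    if (si <= length(samp_at) && t == samp_at[si]) {
      samples[, si] <- x; si <- si + 1
    }
    if (any(!is.finite(x))) stop("FORCE evaluation diverged at step ", t)
  }
  r2 <- vapply(seq_len(N), function(i) {
    if (stats::sd(Z[i, ]) == 0 || stats::sd(Fs[i, ]) == 0) return(0)
    stats::cor(Z[i, ], Fs[i, ])^2
  }, numeric(1))

  out <- list(J = J, J0 = J0, J_in = J_in, g = g, tau = tau, dt = dt,
              N = N, r2 = r2, train_error = train_error,
              readout_eval = Z, targets_sim = Fs, inputs_sim = Us,
              t_sim = t_sim, state_samples = samples,
              free_run = free_run)
  class(out) <- "force_rnn"
  out
}

#' Build a force_rnn object from explicit weights
#'
#' For constructing reference networks (e.g. planted line attractors)
#' without training.
#'
#' @param J recurrent matrix.
#' @param g gain.
#' @param tau,dt dynamics constants (s).
#' @return a `force_rnn`.
#' @export
force_rnn <- function(J, g = 1, tau = 0.5, dt = 0.05) {
  out <- list(J = J, J0 = J, J_in = NULL, g = g, tau = tau, dt = dt,
              N = nrow(J), r2 = NULL, train_error = NULL,
              state_samples = matrix(0, nrow(J), 0))
  class(out) <- "force_rnn"
  out
}

# speed q(x) = 0.5 ||dx/dt||^2 and its gradient for the autonomous network
rnn_speed <- function(x, J, g, tau, H = 0) {
  f <- (-x + g * as.numeric(J %*% tanh(x)) + H) / tau
  0.5 * sum(f^2)
}
rnn_speed_grad <- function(x, J, g, tau, H = 0) {
  f <- (-x + g * as.numeric(J %*% tanh(x)) + H) / tau
  Jac <- (-diag(length(x)) + g * J * rep(1 - tanh(x)^2,
                                         each = length(x))) / tau
  as.numeric(crossprod(Jac, f))
}

#' Find fixed and slow points of a trained RNN
#'
#' Minimises the kinetic energy `q(x) = 0.5 ||dx/dt||^2` of the autonomous
#' network by gradient-based optimisation (BFGS with analytic gradient)
#' from many initial conditions sampled from visited states (plus optional
#' explicit inits), deduplicates converged points within a radius, and
#' classifies each accepted point by the eigenvalues of the Jacobian.
#' Points with residual speed `||dx/dt||` below `tol` are accepted.
#'
#' @param rnn a `force_rnn`.
#' @param n_inits number of optimisation starts.
#' @param tol residual speed tolerance (default 1e-6).
#' @param inits optional explicit matrix of initial states (N x n).
#' @param H constant external input during the search (default 0).
#' @param dedup_radius distance below which two points are merged.
#' @param seed integer seed.
#' @return a `fixed_point_set`: list with `points` (N x n_pts), `speed`,
#'   `max_re_eig` (stability), `n_converged`; empty and flagged when
#'   nothing converges.
#' @export
find_fixed_points <- function(rnn, n_inits = 30, tol = 1e-6, inits = NULL,
                              H = 0, dedup_radius = NULL, seed = 1) {
  N <- rnn$N
  set.seed(derive_seed(seed, 13))
  if (is.null(inits)) {
    pool <- rnn$state_samples
    if (is.null(pool) || ncol(pool) == 0)
      pool <- matrix(stats::rnorm(N * n_inits, 0, 1), N)
    pick <- sample(ncol(pool), n_inits, replace = ncol(pool) < n_inits)
    inits <- pool[, pick, drop = FALSE] +
      matrix(stats::rnorm(N * n_inits, 0, 0.05), N)
  }
  fn <- function(x) rnn_speed(x, rnn$J, rnn$g, rnn$tau, H)
  gr <- function(x) rnn_speed_grad(x, rnn$J, rnn$g, rnn$tau, H)
  pts <- list(); speeds <- numeric(0)
  for (i in seq_len(ncol(inits))) {
    opt <- tryCatch(
      stats::optim(inits[, i], fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) next
    sp <- sqrt(2 * opt$value)
    if (sp < tol) {
      pts[[length(pts) + 1]] <- opt$par
      speeds <- c(speeds, sp)
    }
  }
  if (length(pts) == 0) {
    return(structure(list(points = matrix(0, N, 0), speed = numeric(0),
                          max_re_eig = numeric(0), n_converged = 0,
                          flag = "no converged points"),
                     class = "fixed_point_set"))
  }
  P <- do.call(cbind, pts)
  if (is.null(dedup_radius))
    dedup_radius <- 1e-3 * max(1, sqrt(mean(P^2)))
  keep <- rep(TRUE, ncol(P))
  for (i in seq_len(ncol(P))) {
    if (!keep[i]) next
    if (i < ncol(P)) {
      later <- (i + 1):ncol(P)
      d <- sqrt(colSums((P[, later, drop = FALSE] - P[, i])^2))
      keep[later][d < dedup_radius] <- FALSE
    }
  }
  P <- P[, keep, drop = FALSE]; speeds <- speeds[keep]
  stab <- vapply(seq_len(ncol(P)), function(i) {
    x <- P[, i]
    Jac <- (-diag(N) + rnn$g * rnn$J * rep(1 - tanh(x)^2, each = N)) /
      rnn$tau
    max(Re(eigen(Jac, only.values = TRUE)$values))
  }, numeric(1))
  structure(list(points = P, speed = speeds, max_re_eig = stab,
                 n_converged = ncol(P), flag = NULL),
            class = "fixed_point_set")
}

#' Project RNN fixed points into an rSLDS state-space plane
#'
#' Maps each point's readout (`g J r(x*)`, the network's reconstruction of
#' neural activity) through the rSLDS emission pseudo-inverse into latent
#' space and then into the model's 2-D principal-component plane, and
#' reports the fraction of points that land inside the flow field's slow
#' region.
#'
#' @param points a `fixed_point_set`.
#' @param rnn the `force_rnn` that produced them.
#' @param flow a [flow_field_2d()] result.
#' @param model the `rslds_model`/fit whose emissions define the mapping
#'   (neuron count must equal the RNN size).
#' @return list with `coords` (n_pts x 2), `in_slow_region` (logical),
#'   `overlap` (fraction).
#' @export
project_points <- function(points, rnn, flow, model) {
  m <- as_rslds_model(model)
  if (rnn$N != nrow(m$C)) stop("dimension mismatch between RNN and model")
  if (ncol(points$points) == 0)
    return(list(coords = matrix(0, 0, 2), in_slow_region = logical(0),
                overlap = NA_real_))
  Cpinv <- solve(crossprod(m$C) + 1e-10 * diag(m$D), t(m$C))
  coords <- matrix(0, ncol(points$points), 2)
  for (i in seq_len(ncol(points$points))) {
    y <- rnn$g * as.numeric(rnn$J %*% tanh(points$points[, i]))
    xl <- as.numeric(Cpinv %*% (y - m$d))
    coords[i, ] <- as.numeric(t(flow$basis) %*% (xl - flow$center))
  }
  inslow <- vapply(seq_len(nrow(coords)), function(i) {
    d2 <- (flow$grid[, 1] - coords[i, 1])^2 +
      (flow$grid[, 2] - coords[i, 2])^2
    flow$slow_mask[which.min(d2)]
  }, logical(1))
  list(coords = coords, in_slow_region = inslow, overlap = mean(inslow))
}
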