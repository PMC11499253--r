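#' Time constants of the fitted dynamics
#'
#' For each discrete state, the eigenvalues `lambda_a` of the dynamics
#' matrix give one time constant each, `tau_a = |1 / log(|lambda_a|)|`
#' frames, converted to seconds by the frame rate. `|lambda| = 0` gives
#' `tau = 0`; `|lambda| >= 1` is capped at `cap_frames` and flagged
#' unstable. Complex conjugate pairs share a magnitude; they are tagged
#' with a common `pair_id` so reports can list each pair once.
#'
#' @param model an `rslds_model` or `rslds_fit`.
#' @param cap_frames cap for non-decaying modes (default 1e7 frames).
#' @return data.frame with columns `state`, `dim`, `eigenvalue` (complex),
#'   `modulus`, `tau_frames`, `tau_s`, `pair_id`, `capped`; attribute
#'   `occupancy` copies the model's state occupancy.
#' @export
time_constants <- function(model, cap_frames = 1e7) {
  m <- as_rslds_model(model)
  fr <- m$frame_rate
  rows <- list()
  for (k in seq_len(m$K)) {
    ev <- eigen(m$A[[k]], only.values = TRUE)$values
    mod <- Mod(ev)
    tau <- tau_from_lambda(mod, cap_frames)
    pair <- integer(length(ev))
    nextid <- 1L
    for (i in seq_along(ev)) {
      if (pair[i] != 0) next
      pair[i] <- nextid
      if (Im(ev[i]) != 0) {
        j <- which(pair == 0 & abs(ev - Conj(ev[i])) < 1e-10)
        if (length(j) > 0) pair[j[1]] <- nextid
      }
      nextid <- nextid + 1L
    }
    rows[[k]] <- data.frame(state = k, dim = seq_along(ev),
                            eigenvalue = ev, modulus = mod,
                            tau_frames = tau, tau_s = tau / fr,
                            pair_id = pair, capped = mod >= 1)
  }
  out <- do.call(rbind, rows)
  attr(out, "occupancy") <- m$occupancy
  attr(out, "frame_rate") <- fr
  out
}

tau_from_lambda <- function(mod, cap_frames = 1e7) {
  tau <- ifelse(mod == 0, 0,
                ifelse(mod >= 1, cap_frames, abs(1 / log(mod))))
  pmin(tau, cap_frames)
}

#' Line-attractor score
#'
#' `log2` ratio of the two longest time constants of the state housing the
#' slowest dimension (eigenvalue multiplicity counted, so a complex pair
#' contributes two equal time constants). Large values indicate a single
#' dominant slow mode — an approximate line attractor; values near 0 mean
#' no time-scale separation.
#'
#' @param tcs a [time_constants()] data.frame (or a model/fit, converted
#'   automatically).
#' @param state optional state index; default = state containing the
#'   globally slowest dimension.
#' @return scalar score; NA with attribute `flag` when the second time
#'   constant is 0.
#' @export
line_attractor_score <- function(tcs, state = NULL) {
  if (!is.data.frame(tcs)) tcs <- time_constants(tcs)
  if (is.null(state)) state <- tcs$state[which.max(tcs$tau_frames)]
  tk <- sort(tcs$tau_frames[tcs$state == state], decreasing = TRUE)
  if (length(tk) < 2) stop("line-attractor score needs >= 2 dimensions")
  if (tk[2] <= 0) {
    out <- NA_real_
    attr(out, "flag") <- "second time constant is zero"
    return(out)
  }
  log2(tk[1] / tk[2])
}

#' Forward-simulation accuracy
#'
#' From every frame's posterior latent state, simulates the fitted
#' dynamics forward `dt_s` seconds and compares against the inferred
#' latents at the target frame. The per-frame MSE (across latent
#' dimensions) is min-max normalised to `[0, 1]` over the session and
#' reported as accuracy `1 - normalised MSE`; variance explained is the
#' per-dimension squared Pearson correlation between predicted and
#' observed latents, averaged over dimensions.
#'
#' @param model an `rslds_model` or `rslds_fit`.
#' @param latents a `latent_trajectory` (defaults to the fit's own).
#' @param dt_s forward horizon in seconds (default 1).
#' @param inputs optional input matrix if the model has input loadings.
#' @return list with `accuracy` (per-frame, in `[0,1]`), `mse`,
#'   `var_explained`, `r2_per_dim`, `dt_frames`.
#' @export
forward_sim_accuracy <- function(model, latents = NULL, dt_s = 1,
                                 inputs = NULL) {
  m <- as_rslds_model(model)
  if (is.null(latents)) {
    if (is.list(model) && !is.null(model$latents)) latents <- model$latents
    else stop("latents required")
  }
  dt <- max(1L, round(dt_s * m$frame_rate))
  X <- latents$x; T_ <- ncol(X)
  if (dt >= T_) stop("horizon longer than session")
  # state-resolved step matrices per frame
  zt <- latents$z
  Xp <- X[, 1:(T_ - dt), drop = FALSE]
  for (j in seq_len(dt)) {
    tcur <- (1 + j):(T_ - dt + j)   # time index of the step being applied
    if (m$K == 1) {
      Xp <- m$A[[1]] %*% Xp + m$b[[1]]
      if (!is.null(m$W) && !is.null(inputs))
        Xp <- Xp + m$W[[1]] %*% inputs[, tcur, drop = FALSE]
    } else {
      Xnew <- matrix(0, m$D, ncol(Xp))
      for (k in seq_len(m$K)) {
        sel <- zt[tcur] == k
        if (!any(sel)) next
        Xk <- m$A[[k]] %*% Xp[, sel, drop = FALSE] + m$b[[k]]
        if (!is.null(m$W) && !is.null(inputs))
          Xk <- Xk + m$W[[k]] %*% inputs[, tcur[sel], drop = FALSE]
        Xnew[, sel] <- Xk
      }
      Xp <- Xnew
    }
  }
  target <- X[, (1 + dt):T_, drop = FALSE]
  mse <- colMeans((Xp - target)^2)
  rng <- range(mse)
  norm <- if (diff(rng) > 0) (mse - rng[1]) / diff(rng) else rep(0, length(mse))
  r2 <- vapply(seq_len(m$D), function(dd) {
    if (stats::sd(Xp[dd, ]) == 0 || stats::sd(target[dd, ]) == 0) return(0)
    stats::cor(Xp[dd, ], target[dd, ])^2
  }, numeric(1))
  list(accuracy = 1 - norm, mse = mse, var_explained = mean(r2),
       r2_per_dim = r2, dt_frames = dt)
}

#' Extract the integration dimension
#'
#' Projects the latent trajectory onto the slowest eigen-direction of the
#' dynamics (the state housing the slowest dimension), returning a
#' normalised time series and the per-neuron weights `C v`. When the
#' slowest time constant does not exceed `ratio_flag` times the next one,
#' the session is flagged as lacking an integration dimension.
#'
#' @param model an `rslds_model` or `rslds_fit`.
#' @param latents a `latent_trajectory` (defaults to the fit's own).
#' @param normalize `"minmax"`, `"zscore"` or `"none"`.
#' @param ratio_flag separation ratio below which absence is flagged
#'   (default 3).
#' @return list with `series` (normalised), `raw`, `weights` (per
#'   neuron), `direction` (latent-space unit vector), `state`, `tau_s`
#'   (two longest), `has_integration_dim`.
#' @export
integration_dimension <- function(model, latents = NULL,
                                  normalize = c("minmax", "zscore", "none"),
                                  ratio_flag = 3) {
  normalize <- match.arg(normalize)
  m <- as_rslds_model(model)
  if (is.null(latents)) {
    if (is.list(model) && !is.null(model$latents)) latents <- model$latents
    else stop("latents required")
  }
  tcs <- time_constants(m)
  state <- tcs$state[which.max(tcs$tau_frames)]
  tk <- sort(tcs$tau_frames[tcs$state == state], decreasing = TRUE)
  has_dim <- tk[1] > ratio_flag * max(tk[2], 1e-12)
  eg <- eigen(m$A[[state]])
  i_slow <- which.max(Mod(eg$values))
  v <- Re(eg$vectors[, i_slow])
  v <- v / sqrt(sum(v^2))
  raw <- as.numeric(t(v) %*% latents$x)
  series <- switch(normalize,
    minmax = {
      rng <- range(raw)
      if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw * 0
    },
    zscore = as.numeric(scale(raw)),
    none = raw)
  list(series = series, raw = raw, weights = as.numeric(m$C %*% v),
       direction = v, state = state,
       tau_s = tk[1:2] / m$frame_rate,
       has_integration_dim = has_dim)
}

#' 2-D flow field of the fitted dynamical system
#'
#' Projects the latents onto their top two principal components, evaluates
#' the one-step velocity of the locally active state's dynamics on a grid
#' in that plane, and masks the slow region where speed falls below a
#' quantile (default the 5th percentile).
#'
#' @param model an `rslds_model` or `rslds_fit`.
#' @param latents a `latent_trajectory` (defaults to the fit's own).
#' @param n_grid grid resolution per axis.
#' @param slow_quantile speed quantile defining the slow region.
#' @param expand fractional margin beyond the data range.
#' @return list with `basis` (D x 2, orthonormal), `center`, `grid`,
#'   `velocity` (projected), `speed`, `slow_mask`, `extrapolated` (grid
#'   points outside the data's bounding box), `traj` (projected latents).
#' @export
flow_field_2d <- function(model, latents = NULL, n_grid = 25,
                          slow_quantile = 0.05, expand = 0.1) {
  m <- as_rslds_model(model)
  if (is.null(latents)) {
    if (is.list(model) && !is.null(model$latents)) latents <- model$latents
    else stop("latents required")
  }
  if (m$D < 2) stop("flow field needs D >= 2")
  X <- latents$x
  mu <- rowMeans(X)
  eg <- eigen(stats::cov(t(X)), symmetric = TRUE)
  E <- eg$vectors[, 1:2, drop = FALSE]
  proj <- t(E) %*% (X - mu)          # 2 x T
  rg1 <- range(proj[1, ]); rg2 <- range(proj[2, ])
  pad1 <- expand * diff(rg1); pad2 <- expand * diff(rg2)
  g1 <- seq(rg1[1] - pad1, rg1[2] + pad1, length.out = n_grid)
  g2 <- seq(rg2[1] - pad2, rg2[2] + pad2, length.out = n_grid)
  grid <- as.matrix(expand.grid(pc1 = g1, pc2 = g2))
  vel <- matrix(0, nrow(grid), 2)
  speed <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x <- mu + E %*% grid[i, ]
    if (m$K == 1) k <- 1
    else k <- which.max(as.numeric(m$R %*% x + m$r) +
                          diag(m$logPi) * 0)   # recurrent logits
    v <- (m$A[[k]] %*% x + m$b[[k]]) - x
    pv <- t(E) %*% v
    vel[i, ] <- pv
    speed[i] <- sqrt(sum(pv^2))
  }
  thr <- stats::quantile(speed, slow_quantile)
  extrap <- grid[, 1] < rg1[1] | grid[, 1] > rg1[2] |
    grid[, 2] < rg2[1] | grid[, 2] > rg2[2]
  list(basis = E, center = mu, grid = grid, velocity = vel, speed = speed,
       slow_mask = speed <= thr, speed_threshold = thr,
       extrapolated = extrap, traj = t(proj))
}

#' Select model order by cross-validation
#'
#' Fits each (K, D) candidate with one contiguous block of frames held out
#' per fold and scores the held-out frames by their predictive
#' log-likelihood under the frozen fitted model (the filter updates only on
#' training frames). Ties are broken toward the smallest D, then K.
#'
#' @param raster a [population_raster()].
#' @param K_grid,D_grid candidate grids.
#' @param folds CV folds (default 5).
#' @param ... passed to [fit_rslds()].
#' @return list with `K`, `D`, and the `scores` matrix (candidates x
#'   folds, mean per-frame held-out log-likelihood).
#' @export
select_model_order <- function(raster, K_grid = 1:2, D_grid = 1:3,
                               folds = 5, ...) {
  Y <- unclass(raster)
  T_ <- ncol(Y)
  fold_id <- cut(seq_len(T_), folds, labels = FALSE)
  cand <- expand.grid(K = K_grid, D = D_grid)
  cand <- cand[order(cand$D, cand$K), , drop = FALSE]
  scores <- matrix(NA_real_, nrow(cand), folds)
  any_ok <- FALSE
  for (i in seq_len(nrow(cand))) {
    for (f in seq_len(folds)) {
      obs <- fold_id != f
      fit <- tryCatch(
        fit_rslds(raster, K = cand$K[i], D = cand$D[i], obs = obs, ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      m <- fit$model
      gamma <- fit$latents$credences
      if (m$K == 1) {
        Ac <- as_cube(m$A[[1]], m$D); bc <- matrix(m$b[[1]], m$D, 1)
        Qc <- as_cube(m$Q[[1]], m$D)
      } else {
        Amat <- matrix(vapply(m$A, identity, matrix(0, m$D, m$D)),
                       m$D^2, m$K)
        Ac <- array(Amat %*% t(gamma), c(m$D, m$D, T_))
        bc <- matrix(vapply(m$b, identity, numeric(m$D)), m$D, m$K) %*%
          t(gamma)
        Qmat <- matrix(vapply(m$Q, identity, matrix(0, m$D, m$D)),
                       m$D^2, m$K)
        Qc <- array(Qmat %*% t(gamma), c(m$D, m$D, T_))
      }
      ll <- kalman_predictive_ll_cpp(Y, m$C, m$d, m$Sdiag, Ac, bc, Qc,
                                     matrix(0, m$D, 1), m$x0, m$V0,
                                     as.integer(obs))
      scores[i, f] <- mean(ll[!obs])
      any_ok <- TRUE
    }
  }
  if (!any_ok) stop("all model fits failed")
  ms <- rowMeans(scores, na.rm = TRUE)
  best <- which(ms >= max(ms, na.rm = TRUE) - 1e-9)[1]  # cand sorted by D, K
  list(K = cand$K[best], D = cand$D[best],
       candidates = cand, scores = scores, mean_scores = ms)
}

#' Integration dimension by partial least squares
#'
#' Supervised counterpart to the rSLDS integration dimension: the first
#' PLS component of the population raster regressed on a ramping target
#' vector. Weights are the (unit-norm) covariance direction `X' y`; the
#' held-out correlation between projection and target is reported from a
#' temporal split.
#'
#' @param raster a [population_raster()].
#' @param ramp_target numeric vector, length = frames.
#' @param train_frac fraction of frames (from the start) used to fit the
#'   weights; the rest scores the held-out correlation.
#' @return list with `weights` (per neuron, unit norm), `projection`,
#'   `r_holdout`, `r_insample`.
#' @export
pls_integration_dimension <- function(raster, ramp_target,
                                      train_frac = 0.7) {
  X <- t(unclass(raster))            # T x N
  y <- as.numeric(ramp_target)
  if (length(y) != nrow(X)) stop("target length must equal frame count")
  if (stats::sd(y) == 0) stop("zero-variance ramp target")
  T_ <- nrow(X)
  tr <- seq_len(floor(train_frac * T_))
  te <- setdiff(seq_len(T_), tr)
  fitw <- function(idx) {
    Xc <- sweep(X[idx, , drop = FALSE], 2, colMeans(X[idx, , drop = FALSE]))
    yc <- y[idx] - mean(y[idx])
    w <- as.numeric(crossprod(Xc, yc))
    w / sqrt(sum(w^2))
  }
  w_tr <- fitw(tr)
  proj_te <- as.numeric(X[te, , drop = FALSE] %*% w_tr)
  r_holdout <- if (stats::sd(proj_te) == 0) 0 else
    stats::cor(proj_te, y[te])
  w <- fitw(seq_len(T_))
  proj <- as.numeric(X %*% w)
  r_in <- stats::cor(proj, y)
  list(weights = w, projection = proj, r_holdout = r_holdout,
       r_insample = r_in)
}
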