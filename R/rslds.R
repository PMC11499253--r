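#' @useDynLib lineattractor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_cube <- function(x, D) {
  if (is.list(x)) array(unlist(x), c(D, D, length(x))) else array(x, c(D, D, 1))
}

logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }

# Floor the eigenvalues of a symmetric matrix (keeps covariances PSD).
psd_floor <- function(M, floor = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  d <- pmax(e$values, floor)
  e$vectors %*% (d * t(e$vectors))
}

#' Fit a recurrent switching linear dynamical system
#'
#' Approximate EM for the generative model: discrete state `z_t` with
#' recurrent softmax transitions driven by the continuous latent, per-state
#' linear-Gaussian latent dynamics `x_t = A_k x_{t-1} + b_k (+ W u_t) +
#' eps_t`, and linear-Gaussian emissions `y_t = C x_t + d + delta_t` with
#' diagonal observation covariance. Inference alternates structured
#' updates: a Kalman smoother over the continuous latents (with per-frame
#' dynamics averaged under the current state posteriors), forward-backward
#' over discrete states with transition logits `logPi[j,k] + R[k,] x + r_k`,
#' closed-form M-steps for dynamics and emissions, and a multinomial
#' logistic fit for the recurrent transition parameters. For `K = 1` this
#' reduces to exact EM for a linear dynamical system, and the data
#' log-likelihood is non-decreasing over iterations.
#'
#' Initialisation is PCA emissions plus (for `K > 1`) k-means on latent
#' position/velocity; `n_restarts` reseeds the k-means. States that end
#' with negligible occupancy are pruned with a warning.
#'
#' @param raster a [population_raster()] (z-scored).
#' @param K number of discrete states.
#' @param D latent dimensionality.
#' @param inputs optional m x T input matrix `u_t` (adds an input-loading
#'   matrix W to the dynamics).
#' @param obs optional logical vector (length T): FALSE frames are treated
#'   as missing by the smoother and excluded from the emission M-step.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param n_restarts random restarts (K > 1).
#' @param stickiness additive self-transition log-bonus.
#' @param seed integer seed.
#' @return an `rslds_fit`: list with `model` (parameters), `latents`
#'   (posterior means `x`, state path `z`, state `credences`), and
#'   `diagnostics` (`elbo_trace`, `loglik`, `converged`, `n_iter`).
#' @export
fit_rslds <- function(raster, K = 1, D = 2, inputs = NULL, obs = NULL,
                      max_iter = 50, tol = 1e-5, n_restarts = 3,
                      stickiness = 3, seed = 1) {
  Y <- unclass(raster)
  fr <- attr(raster, "frame_rate")
  N <- nrow(Y); T_ <- ncol(Y)
  if (T_ < 5 * K * D) stop("too few frames for the requested model order")
  if (is.null(obs)) obs <- rep(TRUE, T_)
  obs <- as.logical(obs)
  m_in <- if (is.null(inputs)) 0L else nrow(inputs)
  if (!is.null(inputs) && ncol(inputs) != T_)
    stop("inputs must have one column per frame")

  restarts <- if (K == 1) 1 else n_restarts
  best <- NULL
  for (rs in seq_len(restarts)) {
    fit <- rslds_em(Y, fr, K, D, inputs, obs, max_iter, tol,
                    stickiness, seed = seed + 101 * (rs - 1))
    if (is.null(best) || fit$diagnostics$loglik > best$diagnostics$loglik)
      best <- fit
  }
  # prune never-occupied states
  occ <- colMeans(best$latents$credences)
  dead <- which(occ < 0.005)
  if (length(dead) > 0 && length(dead) < K) {
    warning(length(dead), " unoccupied state(s) pruned")
    best <- prune_states(best, setdiff(seq_len(K), dead))
  }
  if (!is.null(rownames(Y))) best$model$neuron_ids <- rownames(Y)
  best
}

rslds_em <- function(Y, fr, K, D, inputs, obs, max_iter, tol,
                     stickiness, seed) {
  set.seed(seed)
  N <- nrow(Y); T_ <- ncol(Y)
  m_in <- if (is.null(inputs)) 0L else nrow(inputs)
  Yobs <- Y[, obs, drop = FALSE]

  # ---- init: PCA emissions ----
  d <- rowMeans(Yobs)
  sv <- svd(Yobs - d, nu = D, nv = 0)
  C <- sv$u %*% diag(sv$d[1:D] / sqrt(sum(obs)), D)
  Sdiag <- pmax(rowMeans((Yobs - d)^2) - rowSums(C^2), 1e-3)
  # initial latents by least squares projection
  X0 <- solve(crossprod(C) + 1e-8 * diag(D), t(C) %*% (Y - d))
  gamma <- init_states(X0, K)
  A <- vector("list", K); b <- vector("list", K); Q <- vector("list", K)
  W <- if (m_in > 0) vector("list", K) else NULL
  Rmat <- matrix(0, K, D); rvec <- rep(0, K)
  logPi <- matrix(0, K, K); diag(logPi) <- stickiness
  x0 <- X0[, 1, drop = TRUE]; V0 <- diag(1, D)
  xs <- X0
  Ps <- array(0, c(D, D, T_)); Pcross <- array(0, c(D, D, T_))

  elbo_trace <- numeric(0); prev <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    # ---- M-step: dynamics per state ----
    dyn <- mstep_dynamics(xs, Ps, Pcross, gamma, inputs, K, D, m_in)
    A <- dyn$A; b <- dyn$b; Q <- dyn$Q; W <- dyn$W
    # ---- M-step: emissions ----
    em <- mstep_emissions(Y, xs, Ps, obs, D)
    C <- em$C; d <- em$d; Sdiag <- em$Sdiag
    # ---- transitions ----
    if (K > 1) {
      tr <- mstep_transitions(gamma, xs, stickiness)
      Rmat <- tr$R; rvec <- tr$r; logPi <- tr$logPi
    }
    # ---- E-step: continuous latents under soft dynamics ----
    sm <- smooth_soft(Y, C, d, Sdiag, A, b, Q, W, inputs, gamma,
                      x0, V0, obs, K, D)
    xs <- sm$xs; Ps <- sm$Ps; Pcross <- sm$Pcross
    x0 <- xs[, 1]; V0 <- psd_floor(Ps[, , 1], 1e-8)
    # ---- E-step: discrete states ----
    if (K > 1) {
      fb <- states_forward_backward(xs, A, b, Q, W, inputs, Rmat, rvec,
                                    logPi)
      gamma <- fb$gamma
    }
    elbo_trace <- c(elbo_trace, sm$loglik)
    if (is.finite(prev) &&
        abs(sm$loglik - prev) < tol * (abs(prev) + 1e-8)) {
      converged <- TRUE
      break
    }
    prev <- sm$loglik
  }

  z <- max.col(gamma)
  model <- list(K = K, D = D, A = A, b = b, Q = Q, W = W,
                R = Rmat, r = rvec, logPi = logPi,
                C = C, d = d, Sdiag = Sdiag, x0 = x0, V0 = V0,
                frame_rate = fr, occupancy = colMeans(gamma))
  class(model) <- "rslds_model"
  latents <- list(x = xs, z = z, credences = gamma, frame_rate = fr)
  class(latents) <- "latent_trajectory"
  list(model = model, latents = latents,
       diagnostics = list(elbo_trace = elbo_trace,
                          loglik = elbo_trace[length(elbo_trace)],
                          converged = converged, n_iter = it))
}

init_states <- function(X0, K) {
  T_ <- ncol(X0)
  if (K == 1) return(matrix(1, T_, 1))
  dx <- cbind(X0[, 1, drop = FALSE] * 0, X0[, -1, drop = FALSE] -
                X0[, -T_, drop = FALSE])
  feats <- scale(cbind(t(X0), t(dx)))
  km <- stats::kmeans(feats, K, nstart = 3)
  gamma <- matrix(1e-3, T_, K)
  gamma[cbind(seq_len(T_), km$cluster)] <- 1
  gamma / rowSums(gamma)
}

mstep_dynamics <- function(xs, Ps, Pcross, gamma, inputs, K, D, m_in) {
  T_ <- ncol(xs)
  Ps_mat <- matrix(Ps, D * D, T_)
  Pc_mat <- matrix(Pcross, D * D, T_)
  idx <- 2:T_
  A <- vector("list", K); b <- vector("list", K); Q <- vector("list", K)
  W <- if (m_in > 0) vector("list", K) else NULL
  p <- D + m_in + 1
  for (k in seq_len(K)) {
    w <- gamma[idx, k]
    sw <- sum(w)
    xw_prev <- sweep(xs[, idx - 1, drop = FALSE], 2, w, `*`)
    # regressor second moments
    S00 <- xw_prev %*% t(xs[, idx - 1, drop = FALSE]) +
      matrix(Ps_mat[, idx - 1, drop = FALSE] %*% w, D, D)
    S01 <- rowSums(xw_prev)
    Szz <- sweep(xs[, idx, drop = FALSE], 2, w, `*`) %*%
      t(xs[, idx, drop = FALSE]) +
      matrix(Ps_mat[, idx, drop = FALSE] %*% w, D, D)
    Sz0 <- sweep(xs[, idx, drop = FALSE], 2, w, `*`) %*%
      t(xs[, idx - 1, drop = FALSE]) +
      matrix(Pc_mat[, idx, drop = FALSE] %*% w, D, D)
    Sz1 <- rowSums(sweep(xs[, idx, drop = FALSE], 2, w, `*`))
    if (m_in > 0) {
      U <- inputs[, idx, drop = FALSE]
      Uw <- sweep(U, 2, w, `*`)
      S0u <- xw_prev %*% t(U)
      Suu <- Uw %*% t(U)
      Su1 <- rowSums(Uw)
      Szu <- sweep(xs[, idx, drop = FALSE], 2, w, `*`) %*% t(U)
      Srr <- rbind(cbind(S00, S0u, S01),
                   cbind(t(S0u), Suu, Su1),
                   c(S01, Su1, sw))
      Szr <- cbind(Sz0, Szu, Sz1)
    } else {
      Srr <- rbind(cbind(S00, S01), c(S01, sw))
      Szr <- cbind(Sz0, Sz1)
    }
    AWb <- Szr %*% solve(Srr + 1e-6 * diag(p))
    A[[k]] <- AWb[, 1:D, drop = FALSE]
    if (m_in > 0) W[[k]] <- AWb[, D + seq_len(m_in), drop = FALSE]
    b[[k]] <- AWb[, p]
    Qk <- (Szz - AWb %*% t(Szr)) / max(sw, 1e-6)
    Q[[k]] <- psd_floor(Qk, 1e-8)
  }
  list(A = A, b = b, Q = Q, W = W)
}

mstep_emissions <- function(Y, xs, Ps, obs, D) {
  T_ <- ncol(xs)
  Ps_mat <- matrix(Ps, D * D, T_)
  o <- which(obs); no <- length(o)
  Xo <- xs[, o, drop = FALSE]
  Sxx <- Xo %*% t(Xo) + matrix(rowSums(Ps_mat[, o, drop = FALSE]), D, D)
  Sx1 <- rowSums(Xo)
  M <- rbind(cbind(Sxx, Sx1), c(Sx1, no))
  Yo <- Y[, o, drop = FALSE]
  Syx <- Yo %*% t(Xo)
  Sy1 <- rowSums(Yo)
  Cd <- cbind(Syx, Sy1) %*% solve(M + 1e-8 * diag(D + 1))
  C <- Cd[, 1:D, drop = FALSE]; d <- Cd[, D + 1]
  yy <- rowSums(Yo^2)
  cross <- rowSums(Cd * cbind(Syx, Sy1))
  quad <- rowSums((Cd %*% M) * Cd)
  Sdiag <- pmax((yy - 2 * cross + quad) / no, 1e-6)
  list(C = C, d = d, Sdiag = Sdiag)
}

mstep_transitions <- function(gamma, xs, stickiness) {
  T_ <- nrow(gamma); K <- ncol(gamma)
  xprev <- t(xs[, -T_, drop = FALSE])
  gnext <- gamma[-1, , drop = FALSE]
  fit <- tryCatch(
    nnet::multinom(gnext ~ xprev, trace = FALSE, maxit = 200),
    error = function(e) NULL)
  D <- ncol(xprev)
  Rmat <- matrix(0, K, D); rvec <- rep(0, K)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1)
    rvec[2:K] <- co[, 1]
    Rmat[2:K, ] <- co[, -1, drop = FALSE]
  }
  logPi <- matrix(0, K, K); diag(logPi) <- stickiness
  list(R = Rmat, r = rvec, logPi = logPi)
}

smooth_soft <- function(Y, C, d, Sdiag, A, b, Q, W, inputs, gamma,
                        x0, V0, obs, K, D) {
  T_ <- ncol(Y)
  if (K == 1) {
    Ac <- as_cube(A[[1]], D)
    bc <- matrix(b[[1]], D, 1)
    Qc <- as_cube(Q[[1]], D)
  } else {
    # per-frame dynamics as posterior-weighted mixtures
    Amat <- vapply(A, identity, matrix(0, D, D))
    Amat <- matrix(Amat, D * D, K)
    Ac <- array(Amat %*% t(gamma), c(D, D, T_))
    bmat <- vapply(b, identity, numeric(D))
    bc <- matrix(bmat, D, K) %*% t(gamma)
    Qmat <- vapply(Q, identity, matrix(0, D, D))
    Qmat <- matrix(Qmat, D * D, K)
    Qc <- array(Qmat %*% t(gamma), c(D, D, T_))
  }
  U <- matrix(0, D, 1)
  if (!is.null(W)) {
    if (K == 1) U <- W[[1]] %*% inputs
    else {
      U <- matrix(0, D, T_)
      for (k in seq_len(K))
        U <- U + sweep(W[[k]] %*% inputs, 2, gamma[, k], `*`)
    }
  }
  out <- kalman_smooth_cpp(Y, C, d, Sdiag, Ac, bc, Qc, U, x0, V0,
                           as.integer(obs))
  list(xs = out$xs, Ps = out$Ps, Pcross = out$Pcross, loglik = out$loglik)
}

states_forward_backward <- function(xs, A, b, Q, W, inputs, Rmat, rvec,
                                    logPi) {
  D <- nrow(xs); T_ <- ncol(xs); K <- length(A)
  # per-frame, per-state transition log-density of the smoothed latents
  ld <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    mu <- A[[k]] %*% xs[, -T_, drop = FALSE] + b[[k]]
    if (!is.null(W)) mu <- mu + W[[k]] %*% inputs[, -1, drop = FALSE]
    Qi <- solve(Q[[k]])
    Rt <- chol(Qi)
    resid <- Rt %*% (xs[, -1, drop = FALSE] - mu)
    ld[2:T_, k] <- -0.5 * (D * log(2 * pi) +
                             as.numeric(determinant(Q[[k]])$modulus) +
                             colSums(resid^2))
  }
  # recurrent transition logits
  V <- t(Rmat %*% xs + rvec)          # T x K (row t used for t -> t+1)
  la <- matrix(-Inf, T_, K)
  la[1, ] <- ld[1, ] - log(K)
  for (t in 2:T_) {
    lt <- logPi + matrix(V[t - 1, ], K, K, byrow = TRUE)
    lt <- lt - apply(lt, 1, logsumexp)
    la[t, ] <- ld[t, ] +
      vapply(seq_len(K), function(k) logsumexp(la[t - 1, ] + lt[, k]),
             numeric(1))
  }
  lb <- matrix(0, T_, K)
  for (t in (T_ - 1):1) {
    lt <- logPi + matrix(V[t, ], K, K, byrow = TRUE)
    lt <- lt - apply(lt, 1, logsumexp)
    lb[t, ] <- vapply(seq_len(K), function(j)
      logsumexp(lt[j, ] + ld[t + 1, ] + lb[t + 1, ]), numeric(1))
  }
  lg <- la + lb
  lg <- lg - apply(lg, 1, logsumexp)
  gamma <- exp(lg)
  gamma <- pmax(gamma, 1e-10)
  gamma / rowSums(gamma)
}

prune_states <- function(fit, keep) {
  m <- fit$model
  map <- match(seq_len(m$K), keep)
  m$A <- m$A[keep]; m$b <- m$b[keep]; m$Q <- m$Q[keep]
  if (!is.null(m$W)) m$W <- m$W[keep]
  m$R <- m$R[keep, , drop = FALSE]; m$r <- m$r[keep]
  m$logPi <- m$logPi[keep, keep, drop = FALSE]
  m$occupancy <- m$occupancy[keep]
  m$K <- length(keep)
  fit$model <- m
  g <- fit$latents$credences[, keep, drop = FALSE]
  fit$latents$credences <- g / rowSums(g)
  fit$latents$z <- max.col(fit$latents$credences)
  fit
}

#' Construct an rSLDS model from explicit parameters
#'
#' For building reference dynamical systems by hand (tests, theory
#' checks); [fit_rslds()] is the estimation entry point.
#'
#' @param A,b,Q lists (length K) of dynamics matrices, bias vectors and
#'   innovation covariances (single matrices/vectors accepted for K = 1).
#' @param C,d,Sdiag emission parameters.
#' @param R,r,logPi recurrent transition parameters (defaults: none).
#' @param W optional list of input loadings.
#' @param x0,V0 initial state mean/covariance.
#' @param frame_rate Hz.
#' @return an `rslds_model`.
#' @export
rslds_model <- function(A, b, Q, C, d = NULL, Sdiag = NULL, R = NULL,
                        r = NULL, logPi = NULL, W = NULL, x0 = NULL,
                        V0 = NULL, frame_rate = 10) {
  if (!is.list(A)) A <- list(A)
  if (!is.list(b)) b <- list(b)
  if (!is.list(Q)) Q <- list(Q)
  K <- length(A); D <- ncol(A[[1]])
  if (is.null(d)) d <- rep(0, nrow(C))
  if (is.null(Sdiag)) Sdiag <- rep(1e-2, nrow(C))
  if (is.null(R)) R <- matrix(0, K, D)
  if (is.null(r)) r <- rep(0, K)
  if (is.null(logPi)) { logPi <- matrix(0, K, K); diag(logPi) <- 3 }
  if (is.null(x0)) x0 <- rep(0, D)
  if (is.null(V0)) V0 <- diag(1, D)
  m <- list(K = K, D = D, A = A, b = b, Q = Q, W = W, R = R, r = r,
            logPi = logPi, C = C, d = d, Sdiag = Sdiag, x0 = x0, V0 = V0,
            frame_rate = frame_rate, occupancy = rep(1 / K, K))
  class(m) <- "rslds_model"
  m
}

as_rslds_model <- function(x) {
  if (inherits(x, "rslds_model")) return(x)
  if (is.list(x) && !is.null(x$model) && inherits(x$model, "rslds_model"))
    return(x$model)
  stop("not an rslds model or fit")
}

#' Infer latents for new data under a frozen model
#'
#' Runs posterior inference (Kalman smoothing, plus discrete-state updates
#' when K > 1) with all model parameters fixed — e.g. to project activity
#' recorded on a different day, with the same registered neurons, into a
#' previously fit dynamical system. The neuron count (and identities, when
#' both sides carry them as rownames) must match the training raster.
#'
#' @param model an `rslds_model` or `rslds_fit`.
#' @param raster a [population_raster()] with the same neurons.
#' @param inputs optional input matrix matching the model's input loading.
#' @return a `latent_trajectory`.
#' @export
project_into_model <- function(model, raster, inputs = NULL) {
  m <- as_rslds_model(model)
  Y <- unclass(raster)
  if (nrow(Y) != nrow(m$C))
    stop("neuron count mismatch: model has ", nrow(m$C), ", raster has ",
         nrow(Y))
  if (!is.null(m$neuron_ids) && !is.null(rownames(Y)) &&
      !identical(m$neuron_ids, rownames(Y)))
    stop("neuron identities do not match the training raster")
  T_ <- ncol(Y)
  obs <- rep(TRUE, T_)
  gamma <- matrix(1 / m$K, T_, m$K)
  for (pass in seq_len(if (m$K == 1) 1 else 3)) {
    sm <- smooth_soft(Y, m$C, m$d, m$Sdiag, m$A, m$b, m$Q, m$W, inputs,
                      gamma, m$x0, m$V0, obs, m$K, m$D)
    if (m$K > 1)
      gamma <- states_forward_backward(sm$xs, m$A, m$b, m$Q, m$W, inputs,
                                       m$R, m$r, m$logPi)
  }
  out <- list(x = sm$xs, z = max.col(gamma), credences = gamma,
              frame_rate = m$frame_rate)
  class(out) <- "latent_trajectory"
  out
}

#' Fit excluding perturbation windows, then predict through them
#'
#' Fits the model on unperturbed frames only (each window plus `post_s`
#' seconds after it is held out), then forward-simulates the fitted
#' dynamics through every held-out window and reports prediction accuracy
#' against latents inferred from the full recording under the frozen model.
#'
#' @param raster a [population_raster()].
#' @param windows list of `c(start, stop)` frame intervals (half-open).
#' @param K,D model order.
#' @param post_s post-window exclusion, seconds (default 20).
#' @param ... passed to [fit_rslds()].
#' @return list with `fit`, `full_latents`, `windows`, and per-window
#'   `predictions` (list with `frames`, `predicted`, `observed`, `R2`),
#'   plus `cvR2` (mean across windows and dimensions).
#' @export
fit_excluding_windows <- function(raster, windows, K = 1, D = 2,
                                  post_s = 20, ...) {
  fr <- attr(raster, "frame_rate")
  T_ <- ncol(raster)
  obs <- rep(TRUE, T_)
  post <- round(post_s * fr)
  for (w in windows) {
    a <- w[1] + 1; z <- min(T_, w[2] + post)
    if (a <= T_) obs[a:min(z, T_)] <- FALSE
  }
  if (sum(obs) < 10 * K * D)
    stop("too little unperturbed data to fit")
  if (length(windows) == 0)
    return(fit_rslds(raster, K = K, D = D, ...))
  fit <- fit_rslds(raster, K = K, D = D, obs = obs, ...)
  m <- fit$model
  full <- project_into_model(m, raster)
  simulate_from <- function(start, frames) {
    xsim <- matrix(0, m$D, length(frames))
    xcur <- full$x[, start]
    zcur <- full$z[start]
    for (i in seq_along(frames)) {
      xcur <- m$A[[zcur]] %*% xcur + m$b[[zcur]]
      xsim[, i] <- xcur
      if (m$K > 1) {
        logits <- m$logPi[zcur, ] + as.numeric(m$R %*% xcur + m$r)
        zcur <- which.max(logits)
      }
    }
    xsim
  }
  preds <- list()
  r2s <- numeric(0)
  for (w in windows) {
    a <- w[1]; z <- min(T_, w[2] + post)
    if (a < 1 || w[2] >= T_) next
    in_frames <- (a + 1):w[2]
    post_frames <- (w[2] + 1):z
    xsim_in <- simulate_from(a, in_frames)
    # post-stimulus prediction: free-run the fitted dynamics from the
    # inferred state at stimulation offset and score it against the
    # latents inferred from the full recording (pooled R^2 across dims)
    xsim_post <- simulate_from(w[2], post_frames)
    obs_post <- full$x[, post_frames, drop = FALSE]
    sse <- sum((xsim_post - obs_post)^2)
    sst <- sum((obs_post - rowMeans(obs_post))^2)
    r2 <- if (sst > 0) 1 - sse / sst else 0
    preds[[length(preds) + 1]] <- list(
      window = w, frames_in = in_frames, frames_post = post_frames,
      predicted_in = xsim_in, predicted_post = xsim_post,
      observed_post = obs_post, R2_post = r2)
    r2s <- c(r2s, r2)
  }
  list(fit = fit, full_latents = full, windows = windows,
       predictions = preds, cvR2 = max(-1, min(1, mean(r2s))))
}
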