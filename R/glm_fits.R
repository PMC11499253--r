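#' Lagged behaviour design matrix
#'
#' Binary indicators of the three male behaviours (sniff, mount,
#' intromission) at lags 0..`lag_s` seconds, so each neuron's fitted filter
#' describes how it integrates behaviour over a 10-s window by default.
#'
#' @param male_bouts male [bout_table()].
#' @param n_frames frames in session.
#' @param frame_rate Hz.
#' @param lag_s filter length in seconds (default 10).
#' @return T x (3 * (lag_s*frame_rate + 1)) matrix with column metadata in
#'   attributes `behaviour` and `lag`.
#' @export
behavior_design <- function(male_bouts, n_frames, frame_rate, lag_s = 10) {
  u <- male_input_series(male_bouts, n_frames)$indicator
  L <- round(lag_s * frame_rate)
  behs <- rownames(u)
  X <- matrix(0, n_frames, 3 * (L + 1))
  beh_id <- character(ncol(X)); lag_id <- integer(ncol(X))
  col <- 0
  for (b in seq_len(3)) {
    ub <- u[b, ]
    for (lag in 0:L) {
      col <- col + 1
      if (lag == 0) X[, col] <- ub
      else X[(lag + 1):n_frames, col] <- ub[1:(n_frames - lag)]
      beh_id[col] <- behs[b]; lag_id[col] <- lag
    }
  }
  attr(X, "behaviour") <- beh_id
  attr(X, "lag") <- lag_id
  X
}

# Ridge solution paths and cross-validated R^2 from per-fold crossproducts.
# Folds are contiguous blocks (time series). Lambda is chosen per outer
# training set by inner cross-validation over a log grid.
ridge_cv <- function(X, y, folds = 10,
                     lambda_grid = 10^seq(-1, 3, length.out = 5),
                     G_blocks = NULL, fold_id = NULL) {
  T_ <- nrow(X); p <- ncol(X)
  if (is.null(fold_id))
    fold_id <- cut(seq_len(T_), folds, labels = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  if (is.null(G_blocks)) {
    G_blocks <- lapply(seq_len(folds), function(f)
      crossprod(Xc[fold_id == f, , drop = FALSE]))
  }
  g_blocks <- lapply(seq_len(folds), function(f)
    crossprod(Xc[fold_id == f, , drop = FALSE], yc[fold_id == f]))
  G_all <- Reduce(`+`, G_blocks); g_all <- Reduce(`+`, g_blocks)

  solve_ridge <- function(G, g, lam) {
    tryCatch(solve(G + diag(lam, p), g),
             error = function(e) solve(G + diag(lam * 10, p), g))
  }
  r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    Gtr <- G_all - G_blocks[[f]]; gtr <- g_all - g_blocks[[f]]
    inner <- setdiff(seq_len(folds), f)
    # inner CV: leave one training block out
    sc <- vapply(lambda_grid, function(lam) {
      err <- 0
      for (fi in inner) {
        b <- solve_ridge(Gtr - G_blocks[[fi]], gtr - g_blocks[[fi]], lam)
        idx <- fold_id == fi
        err <- err + sum((yc[idx] - Xc[idx, , drop = FALSE] %*% b)^2)
      }
      err
    }, numeric(1))
    lam <- lambda_grid[which.min(sc)]
    b <- solve_ridge(Gtr, gtr, lam)
    idx <- fold_id == f
    pred <- Xc[idx, , drop = FALSE] %*% b
    sse <- sum((yc[idx] - pred)^2)
    sst <- sum((yc[idx] - mean(yc[idx]))^2)
    r2[f] <- if (sst > 0) 1 - sse / sst else 0
  }
  # final coefficients: lambda by leave-block-out CV on all data
  sc <- vapply(lambda_grid, function(lam) {
    err <- 0
    for (f in seq_len(folds)) {
      b <- solve_ridge(G_all - G_blocks[[f]], g_all - g_blocks[[f]], lam)
      idx <- fold_id == f
      err <- err + sum((yc[idx] - Xc[idx, , drop = FALSE] %*% b)^2)
    }
    err
  }, numeric(1))
  lambda <- lambda_grid[which.min(sc)]
  beta <- solve_ridge(G_all, g_all, lambda)
  cvr2 <- max(-1, min(1, mean(r2)))
  list(cvR2 = cvr2, beta = as.numeric(beta), lambda = lambda,
       intercept = ym - sum(xm * beta))
}

#' Behaviour-only GLM per neuron
#'
#' Ridge regression of each neuron's trace on lagged male-behaviour
#' indicators, with cross-validated variance explained (cvR^2, contiguous
#' 10-fold split) and ridge strength chosen by nested cross-validation over
#' a log grid. Constant design columns are dropped with a warning.
#'
#' @param raster a [population_raster()].
#' @param male_bouts male [bout_table()].
#' @param lag_s filter window in seconds (default 10).
#' @param folds outer CV folds (default 10).
#' @param lambda_grid ridge strengths searched.
#' @param neurons optional subset of neuron indices.
#' @return list with `cvR2` (per neuron), `filters` (list of
#'   (lag+1) x 3 matrices), `lambda`, `design_meta`.
#' @export
fit_behavior_glm <- function(raster, male_bouts, lag_s = 10, folds = 10,
                             lambda_grid = 10^seq(-1, 3, length.out = 5),
                             neurons = NULL) {
  fr <- attr(raster, "frame_rate")
  Y <- unclass(raster); T_ <- ncol(Y)
  if (is.null(neurons)) neurons <- seq_len(nrow(Y))
  X <- behavior_design(male_bouts, T_, fr, lag_s)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant design column(s) dropped")
  }
  meta <- list(behaviour = attr(X, "behaviour")[keep],
               lag = attr(X, "lag")[keep])
  X <- X[, keep, drop = FALSE]
  fold_id <- cut(seq_len(T_), folds, labels = FALSE)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  G_blocks <- lapply(seq_len(folds), function(f)
    crossprod(Xc[fold_id == f, , drop = FALSE]))
  res <- lapply(neurons, function(k)
    ridge_cv(X, Y[k, ], folds, lambda_grid, G_blocks, fold_id))
  filters <- lapply(res, function(r) {
    m <- matrix(0, max(meta$lag) + 1, 3,
                dimnames = list(NULL, c("sniff", "mount", "intromission")))
    for (j in seq_along(r$beta))
      m[meta$lag[j] + 1, meta$behaviour[j]] <- r$beta[j]
    m
  })
  list(cvR2 = vapply(res, `[[`, numeric(1), "cvR2"),
       filters = filters,
       lambda = vapply(res, `[[`, numeric(1), "lambda"),
       design_meta = meta, neurons = neurons)
}

#' Coupled GLM: behaviour plus simultaneous neuronal activity
#'
#' Adds the same-frame activity of all other neurons as regressors on top
#' of the lagged behaviour design (self-coupling excluded) and reports the
#' per-neuron cvR^2 and the fitted coupling weight matrix.
#'
#' @inheritParams fit_behavior_glm
#' @return list with `cvR2`, `coupling` (N x N, `coupling[k, j]` = weight
#'   of neuron j in the prediction of neuron k, zero diagonal), `lambda`.
#' @export
fit_coupled_glm <- function(raster, male_bouts, lag_s = 10, folds = 10,
                            lambda_grid = 10^seq(-1, 3, length.out = 5),
                            neurons = NULL) {
  fr <- attr(raster, "frame_rate")
  Y <- unclass(raster); N <- nrow(Y); T_ <- ncol(Y)
  if (N < 2) stop("coupled GLM requires at least 2 neurons")
  if (is.null(neurons)) neurons <- seq_len(N)
  Xb <- behavior_design(male_bouts, T_, fr, lag_s)
  keep <- apply(Xb, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) warning(sum(!keep), " constant design column(s) dropped")
  Xb <- Xb[, keep, drop = FALSE]
  pb <- ncol(Xb)
  Xfull <- cbind(Xb, t(Y))   # behaviour cols then all neurons
  fold_id <- cut(seq_len(T_), folds, labels = FALSE)
  xm <- colMeans(Xfull)
  Xc <- sweep(Xfull, 2, xm)
  G_blocks_full <- lapply(seq_len(folds), function(f)
    crossprod(Xc[fold_id == f, , drop = FALSE]))
  coupling <- matrix(0, N, N)
  cvr2 <- numeric(length(neurons)); lambda <- numeric(length(neurons))
  for (i in seq_along(neurons)) {
    k <- neurons[i]
    cols <- c(seq_len(pb), pb + setdiff(seq_len(N), k))
    Gb <- lapply(G_blocks_full, function(G) G[cols, cols, drop = FALSE])
    r <- ridge_cv(Xfull[, cols, drop = FALSE], Y[k, ], folds, lambda_grid,
                  Gb, fold_id)
    cvr2[i] <- r$cvR2; lambda[i] <- r$lambda
    coupling[k, setdiff(seq_len(N), k)] <- r$beta[(pb + 1):length(r$beta)]
  }
  list(cvR2 = cvr2, coupling = coupling, lambda = lambda,
       neurons = neurons)
}
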