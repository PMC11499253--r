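#' Input-driven integrator model of the slow dimension
#'
#' Single-state linear dynamical system for the integration-dimension time
#' series: `x_t = a x_{t-1} + b + W u_t + eps_t`, where `u_t` are binary
#' per-frame indicators of the three male behaviours (sniff, mount,
#' intromission). Fit by least squares; cross-validated variance explained
#' (contiguous folds) and the intrinsic time constant `|1/log|a||`
#' (seconds) are reported. With all-zero inputs the model reduces to an
#' AR(1) and is flagged.
#'
#' @param x_slow numeric vector, the integration-dimension series.
#' @param male_bouts male [bout_table()] aligned to the series.
#' @param frame_rate Hz (default: taken from the bout table).
#' @param folds CV folds (default 10).
#' @param smooth_boxcar optional causal boxcar width (seconds) applied to
#'   the input indicators (0 = raw binary, the default).
#' @return an `integrator_model`: list with `a`, `b`, `W` (named, per
#'   behaviour), `W_se` (standard errors), `tau_s`, `cvR2`, `sigma`,
#'   `ar1_only` flag.
#' @export
fit_input_driven_integrator <- function(x_slow, male_bouts,
                                        frame_rate = NULL, folds = 10,
                                        smooth_boxcar = 0) {
  if (is.null(frame_rate)) frame_rate <- frame_rate_of(male_bouts)
  T_ <- length(x_slow)
  u <- male_input_series(male_bouts, T_)$indicator
  if (smooth_boxcar > 0) {
    w <- max(1L, round(smooth_boxcar * frame_rate))
    k <- rep(1 / w, w)
    u <- t(apply(u, 1, function(v)
      stats::filter(v, k, method = "convolution", sides = 1)))
    u[is.na(u)] <- 0
  }
  ar1_only <- all(u == 0)
  yt <- x_slow[-1]
  Xd <- cbind(xprev = x_slow[-T_], t(u[, -1, drop = FALSE]))
  keep <- c(TRUE, apply(Xd[, -1, drop = FALSE], 2, stats::sd) > 0)
  Xk <- Xd[, keep, drop = FALSE]
  fit <- stats::lm(yt ~ Xk)
  co <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  a <- unname(co[2])
  W <- stats::setNames(rep(0, 3), rownames(u))
  W_se <- stats::setNames(rep(NA_real_, 3), rownames(u))
  if (sum(keep) > 1) {
    nm <- colnames(Xd)[keep][-1]
    W[nm] <- unname(co[-(1:2)])
    W_se[nm] <- unname(se[-(1:2)])
  }
  # contiguous-fold cross-validated variance explained
  fold_id <- cut(seq_along(yt), folds, labels = FALSE)
  r2 <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    cf <- stats::coef(stats::lm(yt[tr] ~ Xk[tr, , drop = FALSE]))
    cf[is.na(cf)] <- 0
    pred <- cbind(1, Xk[!tr, , drop = FALSE]) %*% cf
    sse <- sum((yt[!tr] - pred)^2)
    sst <- sum((yt[!tr] - mean(yt[!tr]))^2)
    if (sst > 0) 1 - sse / sst else 0
  }, numeric(1))
  out <- list(a = a, b = unname(co[1]), W = W, W_se = W_se,
              tau_s = tau_from_lambda(abs(a)) / frame_rate,
              cvR2 = max(-1, min(1, mean(r2))),
              sigma = stats::sigma(fit),
              frame_rate = frame_rate, ar1_only = ar1_only)
  if (ar1_only) out$flag <- "all-zero inputs; reduced to AR(1)"
  class(out) <- "integrator_model"
  out
}

#' Transformed input of a fitted integrator
#'
#' The model's per-frame input drive `W u_t`: the weighted combination of
#' male-behaviour indicators that moves activity along the integrator.
#' Peaks of this series mark the male-contact events the dimension
#' integrates.
#'
#' @param model an `integrator_model`.
#' @param male_bouts male [bout_table()].
#' @param n_frames length of the output series.
#' @return numeric vector of length `n_frames`.
#' @export
transformed_input <- function(model, male_bouts, n_frames) {
  u <- male_input_series(male_bouts, n_frames)$indicator
  as.numeric(model$W[rownames(u)] %*% u)
}
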