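#' Choice probability of a neuron for a behaviour pair
#'
#' ROC-based discriminability of two behaviours from one neuron's binned
#' activity: responses are averaged in 1-s bins inside each behaviour's
#' bouts and the choice probability (CP) is the area under the ROC curve of
#' the two binned-response distributions, computed by the rank (Mann-Whitney)
#' formula with tie correction, so CP in [0, 1] and CP = 0.5 for identical
#' distributions. A shuffle null permutes bout labels between the two
#' behaviours; a neuron is "tuned" when CP > 0.7 or CP < 0.3 and CP deviates
#' from the shuffle mean by more than 2 shuffle s.d.
#'
#' @param trace numeric vector, one neuron's activity.
#' @param bouts_a,bouts_b [bout_table()]s for the two behaviours (all rows
#'   used, labels ignored).
#' @param frame_rate Hz.
#' @param bin bin width in seconds (default 1).
#' @param n_shuffles shuffle repetitions for the null (default 1000).
#' @return list with `cp`, `shuffle_mean`, `shuffle_sd`, `tuned`, `n_a`,
#'   `n_b`; `cp` is NA with a `flag` when a behaviour has no frames.
#' @export
choice_probability <- function(trace, bouts_a, bouts_b, frame_rate,
                               bin = 1, n_shuffles = 1000) {
  bins_a <- binned_responses(trace, bouts_a, frame_rate, bin)
  bins_b <- binned_responses(trace, bouts_b, frame_rate, bin)
  if (length(bins_a) == 0 || length(bins_b) == 0) {
    return(list(cp = NA_real_, shuffle_mean = NA_real_,
                shuffle_sd = NA_real_, tuned = NA,
                n_a = length(bins_a), n_b = length(bins_b),
                flag = "behaviour with zero frames"))
  }
  cp <- roc_auc(bins_a, bins_b)
  pooled <- c(bins_a, bins_b)
  na <- length(bins_a)
  sh <- vapply(seq_len(n_shuffles), function(i) {
    idx <- sample.int(length(pooled), na)
    roc_auc(pooled[idx], pooled[-idx])
  }, numeric(1))
  sm <- mean(sh); ss <- stats::sd(sh)
  tuned <- (cp > 0.7 || cp < 0.3) && abs(cp - sm) > 2 * ss
  list(cp = cp, shuffle_mean = sm, shuffle_sd = ss, tuned = tuned,
       n_a = na, n_b = length(bins_b), flag = NULL)
}

# mean response in consecutive 1-s bins inside each bout
binned_responses <- function(trace, bouts, frame_rate, bin = 1) {
  bw <- max(1L, round(bin * frame_rate))
  out <- numeric(0)
  for (i in seq_len(nrow(bouts))) {
    a <- bouts$start[i] + 1; z <- min(bouts$stop[i], length(trace))
    if (a > z) next
    idx <- a:z
    nb <- floor(length(idx) / bw)
    if (nb == 0) {            # short bout: one bin covering it
      out <- c(out, mean(trace[idx]))
    } else {
      for (k in seq_len(nb))
        out <- c(out, mean(trace[idx[((k - 1) * bw + 1):(k * bw)]]))
    }
  }
  out
}

# Mann-Whitney AUC with tie correction: P(a > b) + 0.5 P(a = b)
roc_auc <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); nb <- length(b)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

#' Autocorrelation half-width (ACHW)
#'
#' Autocorrelation `r_k = c_k / c_0` with `c_k = (1/T) sum (y_t - ybar)
#' (y_{t+k} - ybar)` (the convention of [stats::acf()]), and the half-width
#' as the first lag where the autocorrelation crosses 0.5, linearly
#' interpolated between the bracketing lags and converted to seconds. If the
#' autocorrelation never reaches 0.5 within `max_lag_s`, the ACHW is
#' censored at `max_lag_s` and flagged.
#'
#' @param trace numeric vector.
#' @param frame_rate Hz.
#' @param max_lag_s maximum lag searched, seconds (default 100).
#' @return list with `achw` (seconds), `lags` (seconds), `acf`, `censored`,
#'   `flag` (zero-variance traces give NA with a flag).
#' @export
autocorr_halfwidth <- function(trace, frame_rate, max_lag_s = 100) {
  if (stats::sd(trace) == 0 || !is.finite(stats::sd(trace))) {
    return(list(achw = NA_real_, lags = NULL, acf = NULL, censored = NA,
                flag = "zero-variance trace"))
  }
  max_lag <- min(length(trace) - 1, round(max_lag_s * frame_rate))
  r <- as.numeric(stats::acf(trace, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  below <- which(r < 0.5)
  if (length(below) == 0) {
    return(list(achw = max_lag_s, lags = seq_len(max_lag) / frame_rate,
                acf = r, censored = TRUE, flag = "censored at max lag"))
  }
  k <- below[1] - 1   # lag index (0-based) of first r < 0.5
  if (k == 0) {
    achw_frames <- 0
  } else {
    r_hi <- r[k]; r_lo <- r[k + 1]   # r at lags k-1 and k
    achw_frames <- (k - 1) + (r_hi - 0.5) / (r_hi - r_lo)
  }
  list(achw = achw_frames / frame_rate,
       lags = (seq_along(r) - 1) / frame_rate, acf = r, censored = FALSE,
       flag = NULL)
}

#' ACHW for every neuron of a raster
#'
#' @param raster a [population_raster()].
#' @param max_lag_s maximum lag in seconds.
#' @return numeric vector of ACHWs (seconds), NA for flat traces.
#' @export
achw_population <- function(raster, max_lag_s = 100) {
  fr <- attr(raster, "frame_rate")
  apply(unclass(raster), 1, function(tr)
    autocorr_halfwidth(tr, fr, max_lag_s)$achw)
}

#' Photometry isosbestic normalisation
#'
#' `Fn(t) = 100 * (F470(t) - F405fit(t)) / F405fit(t)` where `F405fit` is
#' the 405-nm control channel scaled to the 470-nm signal channel by linear
#' least squares (`fit = "linear"`: slope and intercept; `fit = "scale"`:
#' slope only; `fit = "none"`: `f405` is used as-is, i.e. it is already the
#' fitted control).
#'
#' @param f470 signal channel.
#' @param f405 isosbestic control channel.
#' @param fit fitting mode, see above.
#' @return percent-change series.
#' @export
photometry_normalize <- function(f470, f405,
                                 fit = c("linear", "scale", "none")) {
  fit <- match.arg(fit)
  f405fit <- switch(fit,
    linear = {
      co <- stats::coef(stats::lm(f470 ~ f405))
      co[1] + co[2] * f405
    },
    scale = as.numeric(sum(f470 * f405) / sum(f405^2)) * f405,
    none = f405)
  if (any(f405fit <= 0)) stop("fitted control channel must be positive")
  100 * (f470 - f405fit) / f405fit
}
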