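#' Event-triggered average (peri-event time histogram)
#'
#' Aligns a signal to a set of event frames, z-scores each snippet against
#' its own pre-event baseline window (baseline mean F0 and s.d., default
#' window -5 s to -3 s), and averages across events. Events whose window
#' falls outside the session, or whose baseline window contains another
#' event, are excluded. A constant baseline (s.d. 0) is guarded with a
#' floor of 1e-6 and the event flagged.
#'
#' @param signal numeric vector (one trace).
#' @param events event frame indices (1-based, alignment point).
#' @param frame_rate Hz.
#' @param window c(before, after) seconds around the event.
#' @param baseline c(from, to) seconds relative to the event (negative =
#'   before); default c(-5, -3).
#' @return list with `time` (seconds), `mean`, `sem`, `n_events`,
#'   `excluded` (indices of dropped events), `flagged` (events that hit the
#'   s.d. floor). Empty PETH (all events excluded) has `n_events = 0` and
#'   a `flag` noting it.
#' @export
event_triggered_average <- function(signal, events, frame_rate,
                                    window = c(5, 5), baseline = c(-5, -3)) {
  if (baseline[1] >= baseline[2] || baseline[2] > 0)
    stop("baseline window must precede the event")
  T_ <- length(signal)
  pre <- round(window[1] * frame_rate); post <- round(window[2] * frame_rate)
  b0 <- round(baseline[1] * frame_rate); b1 <- round(baseline[2] * frame_rate)
  keep <- logical(length(events)); flagged <- integer(0)
  for (i in seq_along(events)) {
    e <- events[i]
    full <- (e - pre) >= 1 && (e + post) <= T_ && (e + b0) >= 1
    other <- events[events != e]
    clean <- !any(other >= e + b0 & other <= e + b1)
    keep[i] <- full && clean
  }
  excluded <- which(!keep)
  ev <- events[keep]
  if (length(ev) == 0) {
    return(list(time = seq(-pre, post) / frame_rate, mean = NULL, sem = NULL,
                n_events = 0, excluded = excluded, flagged = flagged,
                flag = "no valid events"))
  }
  snips <- matrix(NA_real_, length(ev), pre + post + 1)
  for (i in seq_along(ev)) {
    e <- ev[i]
    base <- signal[(e + b0):(e + b1)]
    f0 <- mean(base); s0 <- stats::sd(base)
    if (!is.finite(s0) || s0 < 1e-6) { s0 <- 1e-6; flagged <- c(flagged, i) }
    snips[i, ] <- (signal[(e - pre):(e + post)] - f0) / s0
  }
  m <- colMeans(snips)
  sem <- apply(snips, 2, stats::sd) / sqrt(nrow(snips))
  list(time = seq(-pre, post) / frame_rate, mean = m, sem = sem,
       n_events = length(ev), excluded = excluded, flagged = flagged,
       flag = NULL)
}
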