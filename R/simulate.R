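#' Synthetic-session configuration
#'
#' Parameters of the generative model used to exercise the whole pipeline:
#' a male bout point process with log-normal durations and inter-bout
#' intervals, a latent linear dynamical system with one slow
#' input-integrating dimension (receptive regime) or only fast dimensions
#' (unreceptive regime), linear-Gaussian calcium emissions, and a logistic
#' link from the slow latent to female acceptance.
#'
#' Defaults correspond to the study conditions the generator emulates:
#' 10-minute sessions at 10 Hz, ~100 imaged neurons, a slow time constant
#' of 100 s against fast dynamics of ~5 s, and a mean copulation IBI of
#' 13.7 s.
#'
#' @param duration_frames session length in frames.
#' @param frame_rate Hz.
#' @param n_neurons number of emitted neurons.
#' @param D latent dimensionality (2 = one slow + one fast).
#' @param tau_slow,tau_fast time constants in seconds; requires
#'   `tau_slow > tau_fast > 0`.
#' @param rotation_unreceptive rotation (radians/frame) of the unreceptive
#'   dynamics; fast conjugate-pair dynamics with no slow mode.
#' @param input_gain named onset-kick amplitudes into the slow dimension per
#'   male behaviour (sniff, mount, intromission).
#' @param sustained_gain per-frame drive into the slow dimension during
#'   intromission.
#' @param fast_kick onset-kick amplitude into the fast dimension(s).
#' @param innovation_sd innovation noise s.d. per latent dimension
#'   (recycled).
#' @param emission_noise_sd observation noise s.d.
#' @param loading_sparsity fraction of zero entries in the emission matrix.
#' @param mean_ibi,ibi_sdlog log-normal IBI parameters (seconds).
#' @param regime `"receptive"` or `"unreceptive"`.
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   sessions.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_frames = 6000, frame_rate = 10,
                       n_neurons = 100, D = 2,
                       tau_slow = 100, tau_fast = 5,
                       rotation_unreceptive = 0.08,
                       input_gain = c(sniff = 0.04, mount = 0.08,
                                      intromission = 0.12),
                       sustained_gain = 0.010,
                       fast_kick = 0.5,
                       innovation_sd = c(0.02, 0.05),
                       emission_noise_sd = 0.5,
                       loading_sparsity = 0.5,
                       mean_ibi = 13.7, ibi_sdlog = 0.8,
                       regime = c("receptive", "unreceptive"),
                       seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(duration_frames >= 0, frame_rate > 0, n_neurons >= 1, D >= 1,
            tau_slow > tau_fast, tau_fast > 0,
            all(innovation_sd >= 0), emission_noise_sd >= 0,
            loading_sparsity >= 0, loading_sparsity <= 1)
  cfg <- list(duration_frames = as.integer(duration_frames),
              frame_rate = frame_rate, n_neurons = as.integer(n_neurons),
              D = as.integer(D), tau_slow = tau_slow, tau_fast = tau_fast,
              rotation_unreceptive = rotation_unreceptive,
              input_gain = input_gain, sustained_gain = sustained_gain,
              fast_kick = fast_kick,
              innovation_sd = rep_len(innovation_sd, D),
              emission_noise_sd = emission_noise_sd,
              loading_sparsity = loading_sparsity,
              mean_ibi = mean_ibi, ibi_sdlog = ibi_sdlog,
              regime = regime, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-stream seeds so components can be re-run
# independently. Mixed multiplicatively so that distinct (seed, offset)
# pairs do not produce structured collisions when derivations nest.
derive_seed <- function(seed, offset) {
  s <- as.numeric(seed) %% 65521
  o <- as.numeric(offset) %% 65521
  as.integer(((s * 40503 + o) * 69069 + 12345) %% 2147483629)
}

#' Ground-truth dynamics matrix for a configuration
#'
#' Receptive regime: diagonal with eigenvalues `exp(-1/(tau*fr))` for the
#' slow and fast time constants. Unreceptive regime: a fast decaying
#' rotation (complex conjugate pair at magnitude `exp(-1/(tau_fast*fr))`),
#' giving time-locked excursions that relax to a point attractor and a
#' generative line-attractor score of 0.
#'
#' @param config a [sim_config()].
#' @return D x D dynamics matrix.
#' @export
true_dynamics <- function(config) {
  fr <- config$frame_rate
  lam_fast <- exp(-1 / (config$tau_fast * fr))
  if (config$regime == "receptive") {
    lams <- c(exp(-1 / (config$tau_slow * fr)),
              rep(lam_fast, config$D - 1))
    A <- diag(lams, config$D)
  } else {
    A <- diag(rep(lam_fast, config$D), config$D)
    if (config$D >= 2) {
      w <- config$rotation_unreceptive
      R <- diag(config$D)
      R[1:2, 1:2] <- matrix(c(cos(w), sin(w), -sin(w), cos(w)), 2)
      A <- lam_fast * R[1:config$D, 1:config$D, drop = FALSE]
      if (config$D > 2) diag(A)[3:config$D] <- lam_fast
    }
  }
  if (any(Mod(eigen(A, only.values = TRUE)$values) > 1))
    stop("requested dynamics are unstable")
  A
}

#' Simulate the male bout point process
#'
#' Produces a sequence of non-overlapping male behaviour bouts with an
#' escalation structure (sniffing precedes the first mount, which precedes
#' the first intromission) and log-normal bout durations and inter-bout
#' intervals; the copulation IBI distribution has configurable mean
#' (default 13.7 s).
#'
#' @param config a [sim_config()].
#' @return male [bout_table()]; attribute `warning_flag` is TRUE when the
#'   session was too short to place any bout.
#' @export
simulate_male_bouts <- function(config) {
  fr <- config$frame_rate
  T_ <- config$duration_frames
  set.seed(derive_seed(config$seed, 1))
  rows <- list()
  # log-normal draw with target arithmetic mean `m` and log-sd `s`
  rln <- function(m, s) stats::rlnorm(1, log(m) - s^2 / 2, s)
  t <- round(rln(8, 0.5) * fr)  # latency to first sniff
  phase <- 1L; n_sniff <- 0L; n_mount <- 0L
  while (TRUE) {
    if (phase == 1L) {
      beh <- "sniff"; dur <- rln(5, 0.5); gap <- rln(5, 0.6)
      n_sniff <- n_sniff + 1L
      if (n_sniff >= 2L) phase <- 2L
    } else if (phase == 2L) {
      beh <- "mount"; dur <- rln(8, 0.5)
      gap <- rln(config$mean_ibi, config$ibi_sdlog)
      n_mount <- n_mount + 1L
      if (n_mount >= 2L) phase <- 3L
    } else {
      beh <- if (stats::runif(1) < 0.75) "intromission" else "mount"
      dur <- if (beh == "intromission") rln(12, 0.5) else rln(8, 0.5)
      gap <- rln(config$mean_ibi, config$ibi_sdlog)
    }
    dur_f <- max(1, round(dur * fr))
    if (t + dur_f > T_) break
    rows[[length(rows) + 1]] <- data.frame(behavior = beh, start = t,
                                           stop = t + dur_f)
    t <- t + dur_f + max(1, round(gap * fr))
  }
  if (length(rows) == 0) {
    out <- bout_table(frame_rate = fr)
    attr(out, "warning_flag") <- TRUE
    return(out)
  }
  df <- do.call(rbind, rows)
  out <- bout_table(rep("male", nrow(df)), df$behavior, df$start, df$stop,
                    frame_rate = fr)
  attr(out, "warning_flag") <- FALSE
  out
}

#' Male-behaviour input series
#'
#' Binary per-frame indicator matrices (3 x T, rows sniff/mount/
#' intromission) for the male behaviours, plus onset impulses (1 only on
#' each bout's first frame) — the input representation consumed by the
#' dynamical-system fits and the integrator model.
#'
#' @param male_bouts male [bout_table()].
#' @param n_frames session length in frames.
#' @return list with `indicator` and `onset`, each 3 x `n_frames`.
#' @export
male_input_series <- function(male_bouts, n_frames) {
  behs <- c("sniff", "mount", "intromission")
  ind <- matrix(0, 3, n_frames, dimnames = list(behs, NULL))
  ons <- matrix(0, 3, n_frames, dimnames = list(behs, NULL))
  mb <- male_bouts[male_bouts$actor == "male", , drop = FALSE]
  for (i in seq_len(nrow(mb))) {
    b <- mb$behavior[i]
    if (!b %in% behs) next
    a <- mb$start[i] + 1; z <- min(mb$stop[i], n_frames)
    if (a <= n_frames) {
      ind[b, a:z] <- 1
      ons[b, a] <- 1
    }
  }
  list(indicator = ind, onset = ons)
}

#' Simulate ground-truth latent dynamics
#'
#' Evolves `x_t = A x_{t-1} + W_kick u_onset + W_sus u_sustained + eps_t`
#' with onset kicks at male bout starts and sustained drive during
#' intromission. In the receptive regime all contact input feeds the slow
#' dimension (plus a fast transient), so the slow dimension integrates male
#' contact and ramps across bouts.
#'
#' @param config a [sim_config()].
#' @param male_bouts male [bout_table()].
#' @param noise_sd override innovation s.d. (e.g. 0 for noise-free tests).
#' @return a `latent_trajectory`: list with `x` (D x T), `z` (all 1),
#'   `credences`, `frame_rate`; attributes `A`, `W_kick`, `W_sus`.
#' @export
simulate_latents <- function(config, male_bouts, noise_sd = NULL) {
  fr <- config$frame_rate
  T_ <- config$duration_frames
  D <- config$D
  A <- true_dynamics(config)
  if (is.null(noise_sd)) noise_sd <- config$innovation_sd
  noise_sd <- rep_len(noise_sd, D)
  W_kick <- matrix(0, D, 3, dimnames = list(NULL, c("sniff", "mount",
                                                    "intromission")))
  W_kick[1, ] <- config$input_gain[c("sniff", "mount", "intromission")]
  if (D >= 2) W_kick[2, ] <- config$fast_kick
  W_sus <- matrix(0, D, 3, dimnames = dimnames(W_kick))
  W_sus[1, "intromission"] <- config$sustained_gain
  u <- male_input_series(male_bouts, T_)
  drive <- W_kick %*% u$onset + W_sus %*% u$indicator

  set.seed(derive_seed(config$seed, 2))
  eps <- matrix(stats::rnorm(D * T_), D, T_) * noise_sd
  x <- matrix(0, D, T_)
  xprev <- rep(0, D)
  for (t in seq_len(T_)) {
    xprev <- A %*% xprev + drive[, t] + eps[, t]
    x[, t] <- xprev
  }
  traj <- list(x = x, z = rep(1L, T_),
               credences = matrix(1, T_, 1), frame_rate = fr)
  attr(traj, "A") <- A
  attr(traj, "W_kick") <- W_kick
  attr(traj, "W_sus") <- W_sus
  attr(traj, "u") <- u
  class(traj) <- "latent_trajectory"
  traj
}

#' Simulate calcium emissions from latents
#'
#' `y_t = C x_t + d + delta_t`, then z-scored per neuron.
#'
#' @param latents a `latent_trajectory`.
#' @param config a [sim_config()].
#' @param C,d optional explicit emission parameters (sampled when NULL).
#' @return z-scored [population_raster()] with attributes `true_C`,
#'   `true_d`.
#' @export
simulate_emissions <- function(latents, config, C = NULL, d = NULL) {
  D <- nrow(latents$x); N <- config$n_neurons
  if (N < D) stop("n_neurons must be >= latent dimension")
  set.seed(derive_seed(config$seed, 3))
  if (is.null(C)) {
    C <- matrix(stats::rnorm(N * D), N, D)
    mask <- matrix(stats::runif(N * D) >= config$loading_sparsity, N, D)
    # every neuron keeps at least one loading
    none <- rowSums(mask) == 0
    mask[cbind(which(none), sample.int(D, sum(none), replace = TRUE))] <- TRUE
    C <- C * mask
  }
  if (is.null(d)) d <- stats::rnorm(N, 0, 0.5)
  noise <- matrix(stats::rnorm(N * ncol(latents$x)), N) *
    config$emission_noise_sd
  y <- C %*% latents$x + d + noise
  r <- zscore_raster(population_raster(y, frame_rate = latents$frame_rate))
  attr(r, "true_C") <- C
  attr(r, "true_d") <- d
  r
}

#' Simulate female behaviour from the slow latent
#'
#' For each male copulation bout the female accepts (lordose/wiggle
#' covering the bout) with probability given by a logistic link on the mean
#' slow-latent value during the bout, otherwise resists (short dart/kick
#' bout); appetitive approach/sniff bouts accompany male sniffing. With
#' `gain = 0` acceptance is independent of the latent.
#'
#' @param latents a `latent_trajectory`.
#' @param male_bouts male [bout_table()].
#' @param link_params list with `gain` and `midpoint` of the logistic link.
#' @param seed integer seed.
#' @return female [bout_table()].
#' @export
simulate_female_behavior <- function(latents, male_bouts,
                                     link_params = list(gain = 1,
                                                        midpoint = 2),
                                     seed = 1L) {
  set.seed(derive_seed(seed, 4))
  fr <- latents$frame_rate
  T_ <- ncol(latents$x)
  xs <- latents$x[1, ]
  rows <- list()
  cop <- filter_bouts(male_bouts, actor = "male", group = "copulation")
  for (i in seq_len(nrow(cop))) {
    a <- cop$start[i] + 1; z <- min(cop$stop[i], T_)
    if (a > T_) next
    xbar <- mean(xs[a:z])
    p <- stats::plogis(link_params$gain * (xbar - link_params$midpoint))
    if (stats::runif(1) < p) {
      beh <- sample(c("lordose", "wiggle"), 1)
      rows[[length(rows) + 1]] <- data.frame(behavior = beh,
                                             start = cop$start[i],
                                             stop = cop$stop[i])
    } else {
      beh <- sample(c("dart", "kick", "top_up", "turn"), 1)
      dur <- max(1, round((cop$stop[i] - cop$start[i]) / 3))
      rows[[length(rows) + 1]] <- data.frame(behavior = beh,
                                             start = cop$start[i],
                                             stop = cop$start[i] + dur)
    }
  }
  sn <- filter_bouts(male_bouts, actor = "male", group = "sniff")
  for (i in seq_len(nrow(sn))) {
    if (stats::runif(1) < 0.5) {
      beh <- sample(c("approach", "sniff"), 1)
      rows[[length(rows) + 1]] <- data.frame(behavior = beh,
                                             start = sn$start[i],
                                             stop = sn$stop[i])
    }
  }
  if (length(rows) == 0) return(bout_table(frame_rate = fr))
  df <- do.call(rbind, rows)
  # same-label overlaps can arise from overlapping male bouts; drop overlaps
  df <- df[order(df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (b in unique(df$behavior)) {
    idx <- which(df$behavior == b)
    if (length(idx) > 1) {
      last_stop <- df$stop[idx[1]]
      for (j in idx[-1]) {
        if (df$start[j] < last_stop) keep[j] <- FALSE
        else last_stop <- df$stop[j]
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  bout_table(rep("female", nrow(df)), df$behavior, df$start, df$stop,
             frame_rate = fr)
}

#' Fraction of male copulation time covered by female acceptance
#' @param female,male [bout_table()]s.
#' @param n_frames session length.
#' @return scalar in `[0, 1]` (NA when there is no copulation time).
#' @export
acceptance_fraction <- function(female, male, n_frames) {
  cop <- occupancy(filter_bouts(male, actor = "male", group = "copulation"),
                   n_frames)
  acc <- occupancy(filter_bouts(female, actor = "female", group = "accept"),
                   n_frames)
  if (!any(cop)) return(NA_real_)
  mean(acc[cop])
}

#' Add an off-manifold perturbation to a latent trajectory
#'
#' Superimposes the linear response to a sustained kick applied during each
#' window: `delta_t = A delta_{t-1} + kick * 1[t in window]`, added to the
#' unperturbed trajectory. For linear dynamics this is the exact perturbed
#' trajectory. A kick orthogonal to the slow dimension relaxes back with
#' the fast time constant; a kick along the slow dimension persists.
#'
#' @param latents a `latent_trajectory` (from [simulate_latents()]).
#' @param windows list of `c(start, stop)` frame intervals (half-open).
#' @param kick length-D vector (default: unit kick in dimension 2,
#'   orthogonal to the slow dimension).
#' @return perturbed `latent_trajectory`; attribute `delta` holds the
#'   displacement.
#' @export
simulate_perturbation <- function(latents, windows, kick = NULL) {
  D <- nrow(latents$x); T_ <- ncol(latents$x)
  A <- attr(latents, "A")
  if (is.null(A)) stop("latents carry no dynamics matrix")
  if (is.null(kick)) {
    kick <- rep(0, D); if (D >= 2) kick[2] <- 1
  }
  if (length(windows) > 1) {
    m <- do.call(rbind, windows)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2])) stop("overlapping windows")
  }
  for (w in windows)
    if (w[1] < 0 || w[2] > T_) stop("window outside session")
  inwin <- logical(T_)
  for (w in windows) if (w[2] > w[1]) inwin[(w[1] + 1):w[2]] <- TRUE
  delta <- matrix(0, D, T_)
  dprev <- rep(0, D)
  for (t in seq_len(T_)) {
    dprev <- A %*% dprev + if (inwin[t]) kick else 0
    delta[, t] <- dprev
  }
  out <- latents
  out$x <- latents$x + delta
  attr(out, "delta") <- delta
  attr(out, "windows") <- windows
  out
}

#' Simulate a complete synthetic session
#'
#' Runs the male bout process, latent dynamics, emissions and female
#' behaviour under one seed, returning ground truth alongside the data.
#'
#' @param config a [sim_config()].
#' @param link_params passed to [simulate_female_behavior()].
#' @return list with `raster`, `latents`, `male_bouts`, `female_bouts`,
#'   `true_params` (A, C, d, W_kick, W_sus, innovation_sd), `config`.
#' @export
simulate_session <- function(config,
                             link_params = list(gain = 1, midpoint = 2)) {
  male <- simulate_male_bouts(config)
  lat <- simulate_latents(config, male)
  raster <- simulate_emissions(lat, config)
  female <- simulate_female_behavior(lat, male, link_params,
                                     seed = config$seed)
  list(raster = raster, latents = lat, male_bouts = male,
       female_bouts = female,
       true_params = list(A = attr(lat, "A"), C = attr(raster, "true_C"),
                          d = attr(raster, "true_d"),
                          W_kick = attr(lat, "W_kick"),
                          W_sus = attr(lat, "W_sus"),
                          innovation_sd = config$innovation_sd),
       config = config)
}
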