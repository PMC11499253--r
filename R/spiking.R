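#' Configuration of the mechanistic spiking network
#'
#' A current-based excitatory LIF network with graded feedback inhibition
#' and a designated integration subnetwork whose synaptic conductance time
#' constant is long (20 s) while the remaining units decay in 100 ms. The
#' subnetwork is also more densely connected (12% versus 1%), with weights
#' scaled to its own size. Defaults: 1,000 units, membrane time constant
#' 20 ms, threshold 0.1 with reset to 0, recurrent gain 2.5, inhibitory
#' gain 4.25, inhibitory time constant 50 ms, Euler step 1 ms, and
#' per-step Gaussian current noise N(0,1)/5.
#'
#' @param N network size.
#' @param N_p integration subnetwork size (first `N_p` units).
#' @param tau_m,tau_I membrane and inhibitory time constants (s).
#' @param tau_s_subnet,tau_s_rest synaptic time constants (s).
#' @param g,g_inh recurrent and inhibitory gains.
#' @param theta spike threshold.
#' @param density_subnet,density_rest connection densities.
#' @param dt Euler step (s).
#' @param noise_sd per-step current noise s.d.
#' @param input_amplitude pulse height of the external step input.
#' @param input_gain_subnet,input_gain_rest multipliers on the input
#'   weights of each subpopulation (hypothesis manipulations rescale
#'   these).
#' @param target_fraction fraction of each subpopulation receiving input.
#' @param seed integer seed.
#' @return a `spiking_config` list.
#' @export
spiking_config <- function(N = 1000, N_p = 200,
                           tau_m = 0.020, tau_I = 0.050,
                           tau_s_subnet = 20, tau_s_rest = 0.100,
                           g = 2.5, g_inh = 4.25, theta = 0.1,
                           density_subnet = 0.12, density_rest = 0.01,
                           dt = 0.001, noise_sd = 0.2,
                           input_amplitude = 0.6,
                           input_gain_subnet = 1, input_gain_rest = 1,
                           target_fraction = 0.25, seed = 1L) {
  stopifnot(tau_m > 0, tau_I > 0, tau_s_subnet > 0, tau_s_rest > 0,
            density_subnet >= 0, density_subnet <= 1,
            density_rest >= 0, density_rest <= 1, N_p <= N, dt > 0)
  cfg <- list(N = as.integer(N), N_p = as.integer(N_p), tau_m = tau_m,
              tau_I = tau_I, tau_s_subnet = tau_s_subnet,
              tau_s_rest = tau_s_rest, g = g, g_inh = g_inh,
              theta = theta, density_subnet = density_subnet,
              density_rest = density_rest, dt = dt, noise_sd = noise_sd,
              input_amplitude = input_amplitude,
              input_gain_subnet = input_gain_subnet,
              input_gain_rest = input_gain_rest,
              target_fraction = target_fraction, seed = as.integer(seed))
  class(cfg) <- "spiking_config"
  cfg
}

#' Build the synaptic weight matrix
#'
#' Non-negative sparse weights: within the integration subnetwork (the
#' first `N_p` units) connections are drawn at `density_subnet` with
#' magnitudes U(0, 1/sqrt(N_p)); all other connections at `density_rest`
#' with magnitudes U(0, 1/sqrt(N)). Deterministic under the config seed.
#'
#' @param config a [spiking_config()].
#' @return list with `W` (N x N sparse matrix, `W[i, j]` = weight of
#'   j onto i, no autapses), `subnet` (unit indices), and the realised
#'   densities of each block.
#' @export
build_network <- function(config) {
  N <- config$N; Np <- config$N_p
  set.seed(derive_seed(config$seed, 21))
  if (config$density_subnet * Np^2 < 1 && config$density_rest * N^2 < 1) {
    warning("densities too low to place any connection")
  }
  # sample connections block-wise
  sub <- seq_len(Np)
  idx_sub <- which(matrix(stats::runif(Np * Np) < config$density_subnet,
                          Np, Np), arr.ind = TRUE)
  w_sub <- stats::runif(nrow(idx_sub), 0, 1 / sqrt(Np))
  mask_rest <- matrix(stats::runif(N * N) < config$density_rest, N, N)
  mask_rest[sub, sub] <- FALSE
  idx_rest <- which(mask_rest, arr.ind = TRUE)
  w_rest <- stats::runif(nrow(idx_rest), 0, 1 / sqrt(N))
  i <- c(idx_sub[, 1], idx_rest[, 1])
  j <- c(idx_sub[, 2], idx_rest[, 2])
  wv <- c(w_sub, w_rest)
  keep <- i != j    # no autapses
  i <- i[keep]; j <- j[keep]; wv <- wv[keep]
  W <- Matrix::sparseMatrix(i = i, j = j, x = wv, dims = c(N, N))
  dens_sub <- length(w_sub) / (Np * Np)
  dens_rest <- length(w_rest) / (N * N - Np * Np)
  list(W = W, subnet = sub,
       density_subnet_realized = dens_sub,
       density_rest_realized = dens_rest)
}

#' Pulsed step-input stimulus
#'
#' A step function of `n_pulses` pulses separated by `isi` seconds (pulse
#' width `width` s), delivered to a random `target_fraction` of units in
#' the integration subnetwork and of the remaining units. Input weights on
#' targeted units are U(0, 1), scaled by the per-subpopulation input
#' gains.
#'
#' The default interstimulus interval (5 s) is shorter than the
#' integration subnetwork's 20-s synaptic time constant, so successive
#' pulses accumulate in the slow synaptic variable instead of
#' equilibrating between pulses; both the interval and pulse width are
#' configuration knobs.
#'
#' @param config a [spiking_config()].
#' @param n_pulses number of pulses (default 20).
#' @param isi interstimulus interval, seconds (default 5).
#' @param width pulse width, seconds (default 1).
#' @param onset latency of the first pulse, seconds (default 10, so the
#'   network's noise-driven baseline settles before the first pulse).
#' @param duration total simulated time (default: covers all pulses plus
#'   one trailing ISI).
#' @return list with `s` (per-step input series), `w_in` (per-unit input
#'   weights), `targets_subnet`, `targets_rest`, `pulse_onsets_s`,
#'   `duration_s`.
#' @export
pulse_stimulus <- function(config, n_pulses = 20, isi = 5, width = 1,
                           onset = 10, duration = NULL) {
  dt <- config$dt
  if (is.null(duration))
    duration <- onset + max(0, n_pulses - 1) * isi + width + isi
  steps <- round(duration / dt)
  s <- numeric(steps)
  onsets <- onset + (seq_len(n_pulses) - 1) * isi
  if (n_pulses > 0 && max(onsets) + width > duration)
    stop("stimulus does not fit in the simulation")
  for (o in onsets) {
    a <- round(o / dt) + 1; z <- min(steps, round((o + width) / dt))
    if (a <= steps) s[a:z] <- config$input_amplitude
  }
  set.seed(derive_seed(config$seed, 22))
  N <- config$N; Np <- config$N_p
  n_t_sub <- round(config$target_fraction * Np)
  n_t_rest <- round(config$target_fraction * (N - Np))
  t_sub <- sample(seq_len(Np), n_t_sub)
  t_rest <- sample(Np + seq_len(N - Np), n_t_rest)
  w_in <- numeric(N)
  w_in[t_sub] <- stats::runif(n_t_sub) * config$input_gain_subnet
  w_in[t_rest] <- stats::runif(n_t_rest) * config$input_gain_rest
  list(s = s, w_in = w_in, targets_subnet = t_sub, targets_rest = t_rest,
       pulse_onsets_s = onsets, duration_s = duration)
}

#' Simulate the spiking network
#'
#' Euler integration at `dt` (default 1 ms) of the LIF network with
#' feedback inhibition and slow/fast synaptic variables (compiled core).
#' Threshold crossing resets the membrane to zero and emits a unit spike
#' indicator that drives inhibition and the synaptic low-pass.
#'
#' @param config a [spiking_config()].
#' @param stimulus a [pulse_stimulus()] result (or compatible list with
#'   `s` and `w_in`).
#' @param network optional prebuilt [build_network()] result.
#' @param record_every recording interval in steps (default 100 = 0.1 s).
#' @return a `spiking_state`: list with `p`, `x` (units x recorded
#'   steps), `spikes` (counts per record bin), `I_inh`, `time_s`,
#'   `subnet`, `config`, `stimulus`.
#' @export
simulate_spiking <- function(config, stimulus, network = NULL,
                             record_every = 100) {
  if (is.null(network)) network <- build_network(config)
  tau_s <- c(rep(config$tau_s_subnet, config$N_p),
             rep(config$tau_s_rest, config$N - config$N_p))
  out <- lif_simulate_cpp(network$W, stimulus$w_in, stimulus$s, tau_s,
                          config$tau_m, config$tau_I, config$g,
                          config$g_inh, config$theta, config$dt,
                          config$noise_sd, as.integer(record_every),
                          derive_seed(config$seed, 23))
  nrec <- ncol(out$p)
  res <- list(p = out$p, x = out$x, spikes = out$spikes,
              I_inh = as.numeric(out$I_inh),
              time_s = (seq_len(nrec)) * record_every * config$dt,
              subnet = network$subnet, config = config,
              stimulus = stimulus, record_every = record_every)
  class(res) <- "spiking_state"
  res
}

#' Apply a hypothesis manipulation to a spiking configuration
#'
#' `"h1"`: the integration subnetwork loses its slow synapses (synaptic
#' time constant set to 100 ms, like the rest) — tests whether slow
#' synaptic integration is required for ramping. `"h2"`: input gain is
#' reduced by 50% for the subnetwork and increased by 50% for the rest —
#' tests whether differential input drive alone could produce the ramp.
#' Everything else is untouched.
#'
#' @param config a [spiking_config()].
#' @param which `"h1"` or `"h2"`.
#' @return modified `spiking_config`.
#' @export
apply_hypothesis <- function(config, which) {
  if (!which %in% c("h1", "h2")) stop("unknown hypothesis label: ", which)
  if (which == "h1") {
    config$tau_s_subnet <- 0.100
  } else {
    config$input_gain_subnet <- config$input_gain_subnet * 0.5
    config$input_gain_rest <- config$input_gain_rest * 1.5
  }
  config
}

#' Ramping metrics of a simulated spiking run
#'
#' Per-pulse mean synaptic activation and spike rate for the integration
#' subnetwork and the remaining units, measured in a window at the end of
#' each inter-pulse interval (just before the next pulse), plus the
#' Spearman rank correlation of the per-pulse values against pulse index
#' (the ramp statistic) and the between-pulse decay fraction of the
#' non-subnetwork units.
#'
#' @param state a `spiking_state`.
#' @param window_s width of the pre-pulse measurement window (default 3).
#' @return list with `per_pulse` (data.frame), `rho_subnet`, `rho_rest`,
#'   `rest_decay_fraction`.
#' @export
subnetwork_summary <- function(state, window_s = 3) {
  cfg <- state$config
  onsets <- state$stimulus$pulse_onsets_s
  if (length(onsets) == 0 || all(state$spikes == 0)) {
    return(list(per_pulse = data.frame(), rho_subnet = 0, rho_rest = 0,
                rest_decay_fraction = 0))
  }
  sub <- state$subnet
  rest <- setdiff(seq_len(cfg$N), sub)
  tm <- state$time_s
  isi <- if (length(onsets) > 1) onsets[2] - onsets[1] else window_s
  rows <- list()
  for (k in seq_along(onsets)) {
    # end-of-interval window just before the next pulse
    hi <- onsets[k] + isi
    lo <- hi - window_s
    idx <- which(tm >= lo & tm < hi)
    if (length(idx) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      pulse = k,
      p_subnet = mean(state$p[sub, idx]),
      p_rest = mean(state$p[rest, idx]),
      rate_subnet = mean(state$spikes[sub, idx]),
      rate_rest = mean(state$spikes[rest, idx]))
    # peak within the interval for the decay fraction
  }
  pp <- do.call(rbind, rows)
  rho_s <- if (nrow(pp) > 2 && stats::sd(pp$p_subnet) > 0)
    stats::cor(pp$pulse, pp$p_subnet, method = "spearman") else 0
  rho_r <- if (nrow(pp) > 2 && stats::sd(pp$p_rest) > 0)
    stats::cor(pp$pulse, pp$p_rest, method = "spearman") else 0
  # rest decay: trough-before-next-pulse over peak-within-interval
  decay <- vapply(seq_along(onsets), function(k) {
    hi <- onsets[k] + isi
    idx_all <- which(tm >= onsets[k] & tm < hi)
    idx_end <- which(tm >= hi - window_s & tm < hi)
    if (length(idx_all) == 0 || length(idx_end) == 0) return(NA_real_)
    pk <- max(colMeans(state$p[rest, idx_all, drop = FALSE]))
    tr <- mean(state$p[rest, idx_end])
    if (pk <= 0) NA_real_ else tr / pk
  }, numeric(1))
  list(per_pulse = pp, rho_subnet = rho_s, rho_rest = rho_r,
       rest_decay_fraction = mean(decay, na.rm = TRUE))
}
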