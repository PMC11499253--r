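#' Recompute the package's benchmark quantities from scratch
#'
#' Runs the full battery of property benchmarks on freshly generated
#' synthetic data: rSLDS time-constant recovery and line-attractor-score
#' regime separation, the eigenvalue/time-constant closed form, the ACHW
#' estimator against the AR(1) closed form, choice-probability agreement
#' with exhaustive pair counting, GLM filter recovery and the
#' coupling-gain contrast, integrator parameter recovery, perturbation
#' relaxation prediction, FORCE fixed-point geometry and reconstruction,
#' the spiking-network ramp contrast, and decoder performance with its
#' shuffle control. Every random draw derives from `seed`.
#'
#' @param seed master seed.
#' @param n_sessions rSLDS recovery sessions per regime (default 20).
#' @param n_seeds_glm seeds for the coupled-GLM contrast (default 20).
#' @param n_seeds_spiking seeds for the spiking contrast (default 20).
#' @param n_achw AR(1) realizations (default 50).
#' @param verbose print progress.
#' @return named list of measured quantities (see source for fields).
#' @export
acceptance_metrics <- function(seed = 1, n_sessions = 20,
                               n_seeds_glm = 20, n_seeds_spiking = 20,
                               n_achw = 50, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  base <- derive_seed(seed, 0)
  out <- list(seed = seed)

  ## --- rSLDS parameter recovery and regime separation -----------------
  say("rSLDS recovery (", 2 * n_sessions, " fits)")
  tau_err <- numeric(n_sessions)
  score_r <- numeric(n_sessions); score_u <- numeric(n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- sim_config(seed = derive_seed(base, 100 + i))
    ses <- simulate_session(cfg)
    u <- male_input_series(ses$male_bouts, cfg$duration_frames)
    fit <- fit_rslds(ses$raster, K = 1, D = 2,
                     inputs = rbind(u$onset, u$indicator), seed = 1)
    tcs <- time_constants(fit)
    tau_err[i] <- abs(max(tcs$tau_s) - cfg$tau_slow) / cfg$tau_slow
    score_r[i] <- line_attractor_score(tcs)
    cfgu <- sim_config(seed = derive_seed(base, 100 + i),
                       regime = "unreceptive")
    sesu <- simulate_session(cfgu)
    uu <- male_input_series(sesu$male_bouts, cfgu$duration_frames)
    fitu <- fit_rslds(sesu$raster, K = 1, D = 2,
                      inputs = rbind(uu$onset, uu$indicator), seed = 1)
    score_u[i] <- line_attractor_score(time_constants(fitu))
  }
  out$rslds <- list(median_tau_rel_err = stats::median(tau_err),
                    tau_rel_err = tau_err,
                    score_receptive = score_r,
                    score_unreceptive = score_u,
                    min_score_receptive = min(score_r),
                    max_score_unreceptive = max(score_u),
                    n = n_sessions)

  ## --- eigenvalue time-constant closed form ---------------------------
  out$eq5 <- list(tau_k = tau_from_lambda(exp(-1 / c(1, 10, 100))),
                  tau_zero = tau_from_lambda(0))

  ## --- ACHW estimator vs AR(1) closed form ----------------------------
  say("ACHW oracle")
  set.seed(derive_seed(base, 300))
  ach <- replicate(n_achw, autocorr_halfwidth(
    as.numeric(stats::arima.sim(list(ar = 0.995), 6000)), 10, 100)$achw)
  wn <- replicate(10, autocorr_halfwidth(stats::rnorm(6000), 10)$achw)
  out$achw <- list(mean_achw_s = mean(ach), target_s = 13.82,
                   white_noise_max_s = max(wn), n = n_achw)

  ## --- choice probability vs exhaustive pair counting -----------------
  set.seed(derive_seed(base, 400))
  auc_brute <- function(a, b) {
    w <- 0
    for (x in a) for (y in b) w <- w + (x > y) + 0.5 * (x == y)
    w / (length(a) * length(b))
  }
  max_dev <- 0
  for (i in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    va <- round(stats::rnorm(na), 2); vb <- round(stats::rnorm(nb), 2)
    sa <- (seq_len(na) - 1) * 40
    sb <- na * 40 + (seq_len(nb) - 1) * 40 + 400
    trace <- numeric(max(c(sa, sb)) + 100)
    for (k in seq_len(na)) trace[sa[k] + (1:10)] <- va[k]
    for (k in seq_len(nb)) trace[sb[k] + (1:10)] <- vb[k]
    ba <- bout_table(rep("female", na), rep("lordose", na), sa, sa + 10)
    bb <- bout_table(rep("female", nb), rep("dart", nb), sb, sb + 10)
    cp <- choice_probability(trace, ba, bb, 10, n_shuffles = 5)$cp
    max_dev <- max(max_dev, abs(cp - auc_brute(va, vb)))
  }
  flat <- rep(1, 400)
  ba <- bout_table(rep("female", 5), rep("lordose", 5), seq(0, 80, 20),
                   seq(10, 90, 20))
  bb <- bout_table(rep("female", 5), rep("dart", 5),
                   100 + seq(0, 80, 20), 100 + seq(10, 90, 20))
  cp_eq <- choice_probability(flat, ba, bb, 10, n_shuffles = 5)$cp
  out$cp <- list(max_abs_dev = max_dev, cp_equal = cp_eq, n = 10)

  ## --- GLM filter recovery and coupling contrast ----------------------
  say("GLM recovery (", n_seeds_glm, " seeds)")
  set.seed(derive_seed(base, 500))
  cfgg <- sim_config(seed = derive_seed(base, 500),
                     duration_frames = 6000, n_neurons = 5)
  maleg <- simulate_male_bouts(cfgg)
  Xd <- behavior_design(maleg, 6000, 10, lag_s = 10)
  true_f <- exp(-(0:100) / 25)
  beta <- numeric(ncol(Xd))
  beta[attr(Xd, "behaviour") == "mount"] <- true_f
  sig <- as.numeric(Xd %*% beta)
  y <- sig + stats::rnorm(6000, 0, stats::sd(sig) / 5)   # SNR 5
  rg <- population_raster(rbind(y, stats::rnorm(6000)), frame_rate = 10)
  g1 <- fit_behavior_glm(rg, maleg, neurons = 1)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  filt_cos <- cosine(g1$filters[[1]][, "mount"], true_f)
  wins <- logical(n_seeds_glm)
  gain <- numeric(n_seeds_glm)
  for (i in seq_len(n_seeds_glm)) {
    cfg <- sim_config(seed = derive_seed(base, 600 + i),
                      duration_frames = 2000, n_neurons = 6,
                      emission_noise_sd = 0.7)
    ses <- simulate_session(cfg)
    grid <- 10^seq(-1, 2, length.out = 4)
    bh <- fit_behavior_glm(ses$raster, ses$male_bouts, folds = 5,
                           lambda_grid = grid)
    cp2 <- fit_coupled_glm(ses$raster, ses$male_bouts, folds = 5,
                           lambda_grid = grid)
    wins[i] <- mean(cp2$cvR2) > mean(bh$cvR2)
    gain[i] <- mean(cp2$cvR2) - mean(bh$cvR2)
  }
  out$glm <- list(filter_cosine = filt_cos, coupled_wins = sum(wins),
                  mean_coupling_gain = mean(gain), n = n_seeds_glm)

  ## --- integrator model -----------------------------------------------
  say("integrator recovery")
  cfgi <- sim_config(seed = derive_seed(base, 700))
  malei <- simulate_male_bouts(cfgi)
  u_ind <- male_input_series(malei, cfgi$duration_frames)$indicator
  W_true <- c(sniff = 0.01, mount = 0.03, intromission = 0.06)
  a_true <- exp(-1 / (cfgi$tau_slow * cfgi$frame_rate))
  set.seed(derive_seed(base, 701))
  xs <- numeric(cfgi$duration_frames); xp <- 0
  drv <- as.numeric(W_true %*% u_ind)
  for (t in seq_len(cfgi$duration_frames)) {
    xp <- a_true * xp + drv[t] + stats::rnorm(1, 0, 0.02)
    xs[t] <- xp
  }
  mi <- fit_input_driven_integrator(xs, malei)
  w_cos <- sum(mi$W * W_true) / sqrt(sum(mi$W^2) * sum(W_true^2))
  ses_r <- simulate_session(sim_config(seed = derive_seed(base, 702)))
  ses_u <- simulate_session(sim_config(seed = derive_seed(base, 702),
                                       regime = "unreceptive"))
  m_r <- fit_input_driven_integrator(ses_r$latents$x[1, ],
                                     ses_r$male_bouts)
  m_u <- fit_input_driven_integrator(ses_u$latents$x[1, ],
                                     ses_u$male_bouts)
  out$integrator <- list(w_cosine = w_cos, cvR2 = m_r$cvR2,
                         tau_receptive_s = m_r$tau_s,
                         tau_unreceptive_s = m_u$tau_s,
                         tau_ratio = m_r$tau_s / m_u$tau_s)

  ## --- perturbation relaxation ----------------------------------------
  say("perturbation relaxation")
  cfgp <- sim_config(seed = derive_seed(base, 800))
  malep <- simulate_male_bouts(cfgp)
  latp <- simulate_latents(cfgp, malep)
  windows <- list(c(1000, 1100), c(2000, 2100), c(3000, 3100),
                  c(4000, 4100), c(5000, 5100))
  pert <- simulate_perturbation(latp, windows, kick = c(0, 0.05))
  rasterp <- simulate_emissions(pert, cfgp)
  resp <- fit_excluding_windows(rasterp, windows, K = 1, D = 2, seed = 1)
  # return-to-attractor: off-line displacement at 3 tau_fast after offset,
  # in units of the fast dimension's stationary innovation sd
  delta <- attr(pert, "delta")
  lam_f <- exp(-1 / (cfgp$tau_fast * cfgp$frame_rate))
  sd_fast <- cfgp$innovation_sd[2] / sqrt(1 - lam_f^2)
  t3 <- round(3 * cfgp$tau_fast * cfgp$frame_rate)
  ret <- vapply(windows, function(w)
    abs(delta[2, w[2] + t3]) / sd_fast, numeric(1))
  out$perturbation <- list(post_kick_cvR2 = resp$cvR2,
                           return_dist_sd = max(ret),
                           n_windows = length(windows))

  ## --- FORCE and fixed points -----------------------------------------
  say("FORCE training and fixed points")
  J <- 0.5 * diag(6)
  set.seed(derive_seed(base, 900))
  fp_lin <- find_fixed_points(force_rnn(J, g = 1),
                              inits = matrix(stats::rnorm(60, 0, 2), 6),
                              tol = 1e-6)
  fp_norm <- if (fp_lin$n_converged > 0)
    min(sqrt(colSums(fp_lin$points^2))) else NA_real_
  N <- 20
  u <- stats::rnorm(N); u <- u / sqrt(sum(u^2))
  inits <- u %o% seq(-1, 1, length.out = 24) +
    matrix(stats::rnorm(N * 24, 0, 0.2), N)
  fp_line <- find_fixed_points(force_rnn(tcrossprod(u), g = 1),
                               inits = inits, tol = 2e-2,
                               dedup_radius = 1e-4)
  line_r2 <- NA_real_
  if (fp_line$n_converged >= 2) {
    P <- t(fp_line$points); P <- sweep(P, 2, colMeans(P))
    sv <- svd(P)$d
    line_r2 <- sv[1]^2 / sum(sv^2)
  }
  cfgf <- sim_config(seed = derive_seed(base, 901))
  sesf <- simulate_session(cfgf)
  uf <- male_input_series(sesf$male_bouts, cfgf$duration_frames)$indicator
  rnn <- train_force(sesf$raster, inputs = uf, n_passes = 4, seed = 3)
  clean <- attr(sesf$raster, "true_C") %*% sesf$latents$x +
    attr(sesf$raster, "true_d")
  clean <- t(scale(t(clean)))
  clean_s <- t(apply(clean, 1, function(v)
    stats::approx((seq_len(ncol(clean)) - 1) / 10, v, rnn$t_sim,
                  rule = 2)$y))
  keep <- apply(clean_s, 1, stats::sd) > 0
  r2_sig <- vapply(which(keep), function(i)
    stats::cor(rnn$readout_eval[i, ], clean_s[i, ])^2, numeric(1))
  out$force <- list(linear_fp_norm = fp_norm,
                    n_slow_points = fp_line$n_converged,
                    line_fit_r2 = line_r2,
                    recon_r2_median = stats::median(r2_sig),
                    train_error_first = rnn$train_error[1],
                    train_error_last = rnn$train_error[length(rnn$train_error)])

  ## --- spiking-network ramp contrast ----------------------------------
  say("spiking contrast (", 2 * n_seeds_spiking, " simulations)")
  rho_def <- numeric(n_seeds_spiking); rho_h1 <- numeric(n_seeds_spiking)
  decay_rest <- numeric(n_seeds_spiking)
  for (i in seq_len(n_seeds_spiking)) {
    cfg <- spiking_config(seed = derive_seed(base, 1000 + i))
    sm <- subnetwork_summary(simulate_spiking(cfg, pulse_stimulus(cfg)))
    rho_def[i] <- sm$rho_subnet
    decay_rest[i] <- sm$rest_decay_fraction
    h1 <- apply_hypothesis(cfg, "h1")
    sm1 <- subnetwork_summary(simulate_spiking(h1, pulse_stimulus(h1)))
    rho_h1[i] <- sm1$rho_subnet
  }
  # single-neuron subthreshold closed form
  cfg1 <- spiking_config(N = 2, N_p = 1, density_subnet = 0,
                         density_rest = 0, noise_sd = 0,
                         seed = derive_seed(base, 1050))
  stim1 <- list(s = rep(1, 200), w_in = c(0.05, 0),
                targets_subnet = 1L, targets_rest = integer(0),
                pulse_onsets_s = numeric(0), duration_s = 0.2)
  st1 <- suppressWarnings(simulate_spiking(cfg1, stim1, record_every = 1))
  closed <- 0.05 * (1 - exp(-st1$time_s / cfg1$tau_m))
  ode_err <- max(abs(as.numeric(st1$x[1, ]) - closed))
  out$spiking <- list(rho_default = rho_def, rho_h1 = rho_h1,
                      frac_default_ramping = mean(rho_def > 0.9),
                      frac_h1_abolished = mean(rho_h1 < 0.3),
                      rest_decay_mean = mean(decay_rest),
                      ode_max_abs_err = ode_err,
                      n = n_seeds_spiking)

  ## --- decoder ---------------------------------------------------------
  say("decoder")
  mk2 <- function(sep, sd_seed) {
    set.seed(derive_seed(base, sd_seed))
    n_trials <- 10; trial_len <- 30; n_neurons <- 8
    T_ <- 2 * n_trials * (trial_len + 20)
    Y <- matrix(stats::rnorm(n_neurons * T_), n_neurons)
    ax <- stats::rnorm(n_neurons); ax <- ax / sqrt(sum(ax^2))
    starts <- seq(0, by = trial_len + 20, length.out = 2 * n_trials)
    lab <- rep(c("a", "b"), n_trials)
    for (i in seq_along(starts)) {
      idx <- (starts[i] + 1):(starts[i] + trial_len)
      Y[, idx] <- Y[, idx] + ax * (if (lab[i] == "a") sep / 2 else -sep / 2)
    }
    list(r = population_raster(Y, frame_rate = 10),
         a = bout_table(rep("female", n_trials), rep("lordose", n_trials),
                        starts[lab == "a"], starts[lab == "a"] + trial_len),
         b = bout_table(rep("female", n_trials), rep("dart", n_trials),
                        starts[lab == "b"], starts[lab == "b"] + trial_len))
  }
  dsep <- mk2(6, 1100)
  res_sep <- framewise_svm_decoder(dsep$r, dsep$a, dsep$b,
                                   n_shuffles = 50, seed = seed)
  dnull <- mk2(0, 1101)
  res_null <- framewise_svm_decoder(dnull$r, dnull$a, dnull$b,
                                    n_shuffles = 50, seed = seed)
  out$decoder <- list(f1_separable = res_sep$f1,
                      shuffle_mean = res_sep$shuffle_mean,
                      shuffle_sd = res_sep$shuffle_sd,
                      f1_null = res_null$f1,
                      null_shuffle_mean = res_null$shuffle_mean,
                      null_shuffle_sd = res_null$shuffle_sd,
                      n_shuffles = 50)
  out
}
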