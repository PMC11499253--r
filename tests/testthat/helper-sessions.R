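# Shared fixtures: synthetic sessions are generated once per test run and
# cached, so several test files can reuse the same (seeded) data.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(seed = 1, regime = "receptive", ...) {
  key <- paste0(regime, "_", seed, "_",
                paste(deparse(list(...)), collapse = ""))
  if (!exists(key, envir = .session_cache)) {
    cfg <- sim_config(seed = seed, regime = regime, ...)
    assign(key, simulate_session(cfg), envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# small hand-built bout table helper
bt <- function(actor, behavior, start, stop, frame_rate = 10) {
  bout_table(actor, behavior, start, stop, frame_rate = frame_rate)
}

# male behaviour input design (onset impulses + sustained indicators) used
# by the input-driven rSLDS fits
male_inputs <- function(male_bouts, n_frames) {
  u <- male_input_series(male_bouts, n_frames)
  rbind(u$onset, u$indicator)
}
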