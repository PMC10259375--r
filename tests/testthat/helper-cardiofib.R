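# Shared fixtures, computed lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# steady-state young/aged condition summaries (used by several files)
young_result <- function() fixture("young", run_condition_traces("young"))
aged_result <- function() fixture("aged", run_condition_traces("aged"))

# a small noiseless planar-wave movie with ground truth
clean_movie <- function() {
  fixture("clean_movie",
          gen_wave_movie(rows = 32, cols = 32, apd_ms = 180, cv_mps = 0.5,
                         noise_sd = 0, seed = 11))
}

# uncoupled paced run at default stimulus (fixed amplitude for determinism)
uncoupled_beat <- function() {
  fixture("uncoupled_beat", {
    cfg <- coupled_config(myocyte_params())
    integrate_coupled(cfg, stim_times = c(0, 400), t_end = 800,
                      stim_amp = 60)
  })
}
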