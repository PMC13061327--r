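# Shared simulation fixtures, computed once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# a small tumoroid grown without signaling, reused by several tests
small_run <- function() {
  cached("small_run", run_simulation(
    simulation_config(stop_count = 1200, scenario = "none",
                      fate = fate_config(differentiation_threshold = 0.003)),
    seed = 42))
}

# the three desk-scale study conditions, 5 replicate seeds each
acceptance_cfg <- function(case) {
  switch(case,
    contact = simulation_config(
      stop_count = 10000, scenario = "contact", gamma = 0.3,
      fate = fate_config(differentiation_threshold = 0.004)),
    diffusive = simulation_config(
      stop_count = 10000, scenario = "diffusive",
      diffusion = diffusion_config(q = 0.3, delta = 2),
      fate = fate_config(differentiation_threshold = 0.004)),
    none = simulation_config(
      stop_count = 10000, scenario = "none",
      fate = fate_config(differentiation_threshold = 0.003)),
    stop("unknown case"))
}

acceptance_runs <- function(case, seeds = 1:5) {
  cached(paste0("acc_", case), {
    cfg <- acceptance_cfg(case)
    lapply(seeds, function(s) run_simulation(cfg, seed = s))
  })
}
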