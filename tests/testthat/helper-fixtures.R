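# Shared simulation helpers. Tests run the filter on reduced grids (the
# model is grid-size configurable); the vignette records the sizes used.

test_grid <- function(m = 12) make_grid(m, m, m)

# One simulated participant: counterbalanced session + flexible agent.
sim_participant <- function(id, seed, grid = test_grid(), ...) {
  sess <- make_session(id, seed = seed)
  ag <- agent_spec("flexible", grid = grid, ...)
  run_agent(sess, ag, seed = seed + 7919)
}

# Tiny deterministic run table for unit tests.
toy_run <- function(s, r, run = 1L) {
  tibble::tibble(run = run, trial = seq_along(s),
                 condition = "easy", s = as.integer(s), r = as.integer(r))
}
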