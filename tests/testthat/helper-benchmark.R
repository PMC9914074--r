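# The default synthetic benchmark shared by the acceptance checks:
# 500 sessions per class, seed 1, simulator and detector at their defaults.
# Computed once per test run.
benchmark_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulate_dataset(500, sim_config(), seed = 1)
      cache <<- detect_sessions(d, detection_basis())
    }
    cache
  }
})
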