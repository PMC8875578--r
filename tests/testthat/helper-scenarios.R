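# shared fixtures: reduced-resolution solver settings for unit tests, and a
# lazily computed, memoized reference-protocol result for the acceptance suite

quick_solver <- function(t_end = 1200, dt = 5, n_theta = 16, dr_max = 2e-4) {
  solver_settings(n_theta = n_theta, dr_max = dr_max, dt = dt, t_end = t_end)
}

quick_conventional <- function(...) {
  conventional_scenario(solver = quick_solver(), ...)
}

quick_magnetic <- function(mobility_scale = 124, t_end = 1200, ...) {
  magnetic_baseline_scenario(
    particle = nanoparticle_spec(mobility_scale = mobility_scale),
    solver = quick_solver(t_end = t_end), ...)
}

# the full study protocol at default resolution, computed once per test run
.protocol_cache <- new.env(parent = emptyenv())
reference_protocol <- function() {
  if (is.null(.protocol_cache$prot)) {
    .protocol_cache$prot <- run_reference_protocol()
  }
  .protocol_cache$prot
}
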