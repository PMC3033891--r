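# Shared fixtures for the test suite.

# Reduced-unit test set: energies in kBT, lengths in units of r_e.
reduced_params <- function(...) {
  args <- utils::modifyList(
    list(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3.0, H_B = 1),
    list(...)
  )
  do.call(model_params, args)
}

# Stationary points of the reduced test set, frozen from an independent
# dense-grid oracle (step 1e-6 over [0.5, 2.5], local extrema of sampled
# potential values; no derivative information). Positions accurate to the
# grid step, energies to ~1e-10.
oracle_reduced <- list(
  r_dim  = 1.004240,
  r_ts   = 1.385502,
  r_diss = 1.792792,
  v_dim  = -0.681659624689414,
  v_ts   = 0.0440062398621,
  v_diss = -0.000694963477117,
  barrier = 0.7256658646,
  distance = 0.3812620,
  force = 0.7957600
)

# Thickness sweep of the reduced test set (d = 2.9..3.4, the double-well
# rows of the 2.6..3.4 sweep), frozen from the same grid oracle.
oracle_thickness <- data.frame(
  d = seq(2.9, 3.4, by = 0.1),
  barrier = c(0.76576238, 0.72566586, 0.68901971, 0.65481004, 0.62252812,
              0.59186004),
  distance = c(0.424927, 0.381262, 0.353184, 0.331820, 0.314328, 0.299386)
)

expect_close <- function(actual, expected, tol) {
  expect_true(
    all(abs(actual - expected) <= tol),
    label = sprintf("max |diff| = %g (tol %g)",
                    max(abs(actual - expected)), tol)
  )
}
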