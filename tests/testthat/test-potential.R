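test_that("hydrophobic length couples one-to-one with axial separation", {
  p <- reduced_params()
  expect_equal(hydrophobic_length(p$r_e, p), p$l0)
  expect_equal(hydrophobic_length(p$r_e + 0.5, p), p$l0 + 0.5)
  # mismatch exactly relieved when the subunits separate by d - l0
  expect_equal(hydrophobic_length(p$r_e + (p$d - p$l0), p), p$d)
  expect_error(hydrophobic_length(0, p), class = "memtug_domain_error")
  expect_error(hydrophobic_length(-1, p), class = "memtug_domain_error")
})

test_that("Morse term has depth -D_e at r_e and plateaus at zero", {
  p <- reduced_params(D_e = 5)
  expect_equal(morse_energy(p$r_e, p), -p$D_e)
  expect_lt(abs(morse_energy(p$r_e + 30 / p$beta, p)), 1e-12 * p$D_e)
  # curvature at the minimum: central second difference vs closed form
  h <- 1e-5
  fd <- (morse_energy(p$r_e + h, p) - 2 * morse_energy(p$r_e, p) +
           morse_energy(p$r_e - h, p)) / h^2
  expect_equal(fd, 2 * p$D_e * p$beta^2, tolerance = 1e-4)
})

test_that("mismatch term is a two-sided harmonic, zero where relieved", {
  p <- reduced_params()
  expect_equal(mismatch_energy(p$r_e + (p$d - p$l0), p), 0)
  p0 <- reduced_params(H_B = 0)
  r <- seq(0.5, 3, length.out = 11)
  expect_equal(mismatch_energy(r, p0), rep(0, 11))
  # (1/2) * 1 * 0.8^2 at r_e for mismatch 0.8
  expect_equal(mismatch_energy(p$r_e, p), 0.32)
  # symmetric under the sign of the residual mismatch
  relief <- p$r_e + (p$d - p$l0)
  expect_equal(mismatch_energy(relief + 0.3, p), mismatch_energy(relief - 0.3, p))
})

test_that("total potential decomposes exactly and hits -0.68 on the test set", {
  p <- reduced_params()
  r <- seq(0.5, 2.5, length.out = 101)
  expect_equal(total_potential(r, p), morse_energy(r, p) + mismatch_energy(r, p))
  expect_equal(total_potential(p$r_e, p), -0.68) # -1 + 0.32
  # both terms at their minima when d = l0
  q <- reduced_params(d = 2.2)
  expect_equal(total_potential(q$r_e, q), -q$D_e)
  # H_B = 0: total potential is the Morse term everywhere
  p0 <- reduced_params(H_B = 0)
  expect_equal(total_potential(r, p0), morse_energy(r, p0))
})

test_that("analytic derivatives match central finite differences", {
  for (p in list(reduced_params(),
                 reduced_params(D_e = 7, beta = 4, H_B = 3, d = 2.5),
                 reduced_params(H_B = 0),
                 reduced_params(d = 1.9, coupling_slope = 0.8))) {
    r <- seq(0.6, 2.4, length.out = 100)
    h <- 1e-6
    fd_g <- (total_potential(r + h, p) - total_potential(r - h, p)) / (2 * h)
    g <- potential_gradient(r, p)
    expect_close(g, fd_g, tol = 1e-5 * max(1, max(abs(fd_g))))
    fd_c <- (total_potential(r + h, p) - 2 * total_potential(r, p) +
               total_potential(r - h, p)) / h^2
    expect_close(potential_curvature(r, p), fd_c,
                 tol = 1e-3 * max(1, max(abs(fd_c))))
  }
})

test_that("gradient vanishes where both terms are stationary", {
  p0 <- reduced_params(H_B = 0)
  expect_equal(potential_gradient(p0$r_e, p0), 0)
  expect_equal(potential_curvature(p0$r_e, p0), 2 * p0$D_e * p0$beta^2)
  aligned <- reduced_params(d = 2.2, H_B = 5)
  expect_equal(potential_gradient(aligned$r_e, aligned), 0)
})

test_that("beta_from_hooke inverts the Morse curvature at the minimum", {
  expect_equal(beta_from_hooke(2, 1), 1)
  expect_equal(beta_from_hooke(8, 1), 2)
  # round trip: curvature of the Morse term at r_e recovers k
  for (k in c(0.5, 3, 40)) {
    for (D_e in c(1, 6, 20)) {
      b <- beta_from_hooke(k, D_e)
      p <- reduced_params(D_e = D_e, beta = b, H_B = 0)
      expect_equal(potential_curvature(p$r_e, p), k, tolerance = 1e-10)
    }
  }
  expect_error(beta_from_hooke(-1, 1), class = "memtug_domain_error")
  expect_error(beta_from_hooke(1, 0), class = "memtug_domain_error")
})

test_that("parameter validation names the offending field", {
  expect_error(model_params(D_e = -1, r_e = 1, beta = 1, l0 = 2, d = 3, H_B = 1),
               "D_e", class = "memtug_config_error")
  expect_error(model_params(D_e = 1, r_e = 1, beta = 1, l0 = 2, d = 3, H_B = -1),
               "H_B", class = "memtug_config_error")
  expect_error(model_params(D_e = 1, r_e = 1, beta = 1, l0 = 2, d = 0, H_B = 1),
               "'d'", class = "memtug_config_error")
  # negative mismatch is a valid input
  expect_s3_class(reduced_params(d = 1.9), "memtug_params")
})

test_that("reduced/physical unit round trip is the identity", {
  p <- model_params(D_e = 20, r_e = 1.1, beta = 10, l0 = 2.2, d = 3, H_B = 20)
  pr <- to_reduced(p)
  expect_equal(pr$r_e, 1)
  expect_equal(pr$beta, p$beta * p$r_e)
  u <- attr(pr, "units")
  back <- to_physical(pr, u)
  for (f in names(unclass(p))) {
    expect_equal(back[[f]], p[[f]], tolerance = 1e-12)
  }
  # identity unit system leaves parameters unchanged
  same <- to_physical(p, unit_system())
  expect_equal(unclass(same), unclass(p), tolerance = 1e-15)
  expect_error(unit_system(energy_to_kBT = 0), class = "memtug_domain_error")
})

test_that("barriers are invariant under the reduced/physical round trip", {
  p <- model_params(D_e = 20, r_e = 1.1, beta = 10, l0 = 2.2, d = 3, H_B = 20)
  b_phys <- activation_barrier(analyze_landscape(p))
  pr <- to_reduced(p)
  b_red <- activation_barrier(analyze_landscape(pr))
  # energies already in kBT in both systems: barriers agree directly
  expect_equal(b_red, b_phys, tolerance = 1e-10)
  # and distances map back through the length scale
  d_phys <- distance_to_transition(analyze_landscape(p))
  d_red <- distance_to_transition(analyze_landscape(pr))
  expect_equal(d_red * attr(pr, "units")$length_to_nm, d_phys,
               tolerance = 1e-8)
})
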