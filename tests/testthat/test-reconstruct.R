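test_that("Funk-Radon multipliers match the Legendre closed form", {
  expect_equal(frt_multiplier(0), 2 * pi)
  expect_equal(frt_multiplier(2), -pi)
  expect_equal(frt_multiplier(4), 3 * pi / 4)
  expect_error(frt_multiplier(3), "even")
})

test_that("QBI and CSA transforms are linear in coefficient space", {
  scheme <- default_scheme()
  ph <- fix_phantoms()
  s1 <- simulate_signal(ph$fib1, scheme)
  s2 <- simulate_signal(ph$fib2, scheme)
  q1 <- qbi_odf(s1, scheme)$coeffs
  q2 <- qbi_odf(s2, scheme)$coeffs
  qm <- qbi_odf(0.3 * s1 + 0.7 * s2, scheme)$coeffs
  expect_equal(qm, 0.3 * q1 + 0.7 * q2, tolerance = 1e-10)
})

test_that("noiseless single-fiber QBI peaks at the fiber axis", {
  scheme <- default_scheme()
  sig <- simulate_signal(fix_phantoms()$fib1, scheme)
  cs <- qbi_odf(sig, scheme)
  m <- fix_mesh(2562)
  v <- evaluate_sh(cs, m$vertices)
  expect_lte(arc_angle(m$vertices[which.max(v), ], c(1, 0, 0)), 3)
  # even-order representation: antipodally symmetric by construction
  set.seed(51)
  U <- sph_to_unit(cbind(runif(20, 0, 2 * pi), asin(runif(20, -1, 1))))
  expect_equal(evaluate_sh(cs, U), evaluate_sh(cs, -U), tolerance = 1e-12)
})

test_that("isotropic QBI signal yields a degenerate (constant) ODF", {
  scheme <- default_scheme()
  iso <- phantom(list(tensor_compartment(1, c(0, 0), c(7e-4, 7e-4, 7e-4))))
  cs <- qbi_odf(simulate_signal(iso, scheme), scheme)
  expect_error(objective_from(cs, fix_mesh(724)), "degenerate")
})

test_that("CSA of an isotropic signal is exactly the uniform ODF", {
  scheme <- default_scheme()
  iso <- phantom(list(tensor_compartment(1, c(0, 0), c(7e-4, 7e-4, 7e-4))))
  cs <- csa_odf(simulate_signal(iso, scheme), scheme)
  v <- evaluate_sh(cs, fix_mesh(724)$vertices)
  expect_equal(v, rep(1 / (4 * pi), 724), tolerance = 1e-6)
  expect_error(csa_odf(simulate_signal(iso, scheme), scheme, delta = 0.7),
               "delta")
})

test_that("CSA clamps out-of-range attenuations to finite output", {
  scheme <- default_scheme()
  sig <- simulate_signal(fix_phantoms()$fib2, scheme)
  noisy <- add_rician(sig, 1, 5, seed = 3) # strong noise: E can exceed 1
  cs <- csa_odf(noisy, scheme)
  expect_true(all(is.finite(cs$coeffs)))
  expect_true(all(is.finite(evaluate_sh(cs, fix_mesh(724)$vertices))))
})

test_that("noiseless two-fiber CSA recovers both crossing directions", {
  scheme <- default_scheme()
  sig <- simulate_signal(fix_phantoms()$fib2, scheme)
  cs <- csa_odf(sig, scheme)
  m <- fix_mesh(2562)
  samp <- spherical_samples(m, pmax(0, evaluate_sh(cs, m$vertices)))
  pk <- filter_peaks(grid_peaks(samp), samp)
  expect_equal(nrow(pk), 2)
  truth <- fix_truth(fix_phantoms()$fib2)
  for (i in 1:2) {
    expect_lte(min(arc_angle(truth, matrix(unlist(pk[i, c("x", "y", "z")]), 1))),
               5)
  }
})

test_that("single-shell contract is enforced", {
  bad <- acq_scheme(c(0, 1000, 3000),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_error(qbi_odf(c(1, 0.5, 0.4), bad), "single-shell")
  nob0 <- acq_scheme(c(3000, 3000), rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_error(qbi_odf(c(0.5, 0.4), nob0), "b = 0")
})

test_that("tensor fit recovers FA and principal direction", {
  scheme <- default_scheme()
  sig <- simulate_signal(fix_phantoms()$fib1, scheme)
  tf <- fit_tensor(sig, scheme)
  # closed-form FA of eigenvalues (1.7, 0.3, 0.3) is 0.799
  expect_equal(tf$fa, 0.7990222, tolerance = 1e-3)
  expect_lte(arc_angle(tf$principal, c(1, 0, 0)), 0.5)
  iso <- phantom(list(tensor_compartment(1, c(0, 0), c(7e-4, 7e-4, 7e-4))))
  expect_equal(fit_tensor(simulate_signal(iso, scheme), scheme)$fa, 0,
               tolerance = 1e-6)
  # non-positive signals are clamped with a warning
  sig_bad <- sig; sig_bad[10] <- -0.01
  expect_warning(fit_tensor(sig_bad, scheme), "clamped")
})
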