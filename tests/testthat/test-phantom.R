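test_that("standard crossing-fiber phantoms have the published layout", {
  ph <- fix_phantoms()
  expect_length(ph, 3)
  expect_length(ph$fib1$compartments, 1)
  expect_length(ph$fib2$compartments, 2)
  expect_length(ph$fib3$compartments, 3)
  expect_equal(unname(ph$fib2$compartments[[2]]$angles), c(1.22, 0))
  expect_equal(unname(ph$fib3$compartments[[3]]$angles), c(0.52, 1.05))
  for (p in ph) {
    f <- vapply(p$compartments, `[[`, 0, "fraction")
    expect_equal(sum(f), 1, tolerance = 1e-12) # renormalized 0.33s included
  }
  f3 <- vapply(ph$fib3$compartments, `[[`, 0, "fraction")
  expect_equal(f3, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("tensor compartments validate eigenvalues and fractions", {
  expect_error(tensor_compartment(1, c(0, 0), c(1.7e-3, 3e-4, 0)))
  expect_error(tensor_compartment(1.5, c(0, 0)), "fraction")
  expect_error(phantom(list(tensor_compartment(0.5, c(0, 0)))), "sum")
})

test_that("multi-tensor signal decay matches scalar arithmetic", {
  scheme <- acq_scheme(c(0, 3000, 3000),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  ph <- phantom(list(tensor_compartment(1, c(0, 0))), s0 = 2)
  s <- simulate_signal(ph, scheme)
  expect_equal(s[1], 2) # b = 0 returns S0 exactly
  expect_equal(s[2] / 2, exp(-3000 * 1.7e-3), tolerance = 1e-12) # parallel
  expect_equal(s[3] / 2, exp(-3000 * 3e-4), tolerance = 1e-12)   # perpendicular
  # mixture is the fraction-weighted sum
  ph2 <- fix_phantoms()$fib2
  s2 <- simulate_signal(ph2, scheme)
  s_a <- simulate_signal(phantom(list(tensor_compartment(1, c(0, 0)))), scheme)
  s_b <- simulate_signal(phantom(list(tensor_compartment(1, c(1.22, 0)))), scheme)
  expect_equal(s2, 0.5 * s_a + 0.5 * s_b, tolerance = 1e-12)
})

test_that("rician noise honors its seed, SNR and zero-noise limit", {
  s <- seq(0.1, 1, length.out = 50)
  expect_identical(add_rician(s, 1, 20, seed = 4), add_rician(s, 1, 20, seed = 4))
  expect_false(identical(add_rician(s, 1, 20, seed = 4),
                         add_rician(s, 1, 20, seed = 5)))
  expect_identical(add_rician(s, 1, Inf, seed = 4), s)
  # Rayleigh mean at S = 0: sigma * sqrt(pi/2)
  x <- add_rician(rep(0, 1e5), 1, 20, seed = 6)
  expect_equal(mean(x), (1 / 20) * sqrt(pi / 2), tolerance = 0.01)
})

test_that("analytic ODF has the Gaussian closed-form shape", {
  iso <- phantom(list(tensor_compartment(1, c(0, 0), c(7e-4, 7e-4, 7e-4))))
  fn <- analytic_odf_fun(iso)
  expect_equal(fn(c(1, 0, 0)), 1 / (4 * pi), tolerance = 1e-12)
  ph <- fix_phantoms()$fib1
  f1 <- analytic_odf_fun(ph)
  expect_equal(f1(c(1, 0, 0)) / f1(c(0, 0, 1)), (1.7 / 0.3)^1.5,
               tolerance = 1e-9)
})

test_that("analytic ODF is antipodally symmetric and integrates to one", {
  ph <- fix_phantoms()$fib3
  fn <- analytic_odf_fun(ph)
  set.seed(31)
  U <- sph_to_unit(cbind(runif(100, 0, 2 * pi), asin(runif(100, -1, 1))))
  expect_equal(fn(U), fn(-U), tolerance = 1e-14)
  expect_equal(sphere_integral(analytic_odf(ph, fix_mesh(724))), 1,
               tolerance = 1e-3)
  expect_equal(sphere_integral(analytic_odf(ph, fix_mesh(2562))), 1,
               tolerance = 1e-4)
})

test_that("analytic ODF maxima sit at the fiber axes", {
  ph <- fix_phantoms()
  m <- fix_mesh(2562)
  # one edge length on this mesh, degrees
  edge <- max(acos(pmin(1, rowSums(m$vertices[m$triangles[, 1], ] *
                                     m$vertices[m$triangles[, 2], ]))) *
                180 / pi)
  pk1 <- grid_peaks(analytic_odf(ph$fib1, m))
  expect_equal(nrow(pk1), 1)
  expect_lte(arc_angle(unlist(pk1[1, c("x", "y", "z")]), c(1, 0, 0)), edge)
  pk2 <- grid_peaks(analytic_odf(ph$fib2, m))
  expect_equal(nrow(pk2), 2)
})

test_that("random phantoms keep the requested separation and determinism", {
  for (seed in 1:5) {
    ph <- random_phantom(3, seed = seed)
    tr <- fix_truth(ph)
    seps <- c(arc_angle(tr[1, ], tr[2, ]), arc_angle(tr[1, ], tr[3, ]),
              arc_angle(tr[2, ], tr[3, ]))
    expect_true(all(seps >= 40))
  }
  expect_equal(random_phantom(2, seed = 9), random_phantom(2, seed = 9))
})
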