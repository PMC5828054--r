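test_that("inertia weight decays linearly between its bounds", {
  p <- hybrid_params()
  expect_equal(inertia_weight(0, p), 0.2)
  expect_equal(inertia_weight(p$t_max, p), 0.1)
  expect_equal(inertia_weight(p$t_max / 2, p), 0.15)
  expect_error(inertia_weight(p$t_max + 1, p))
})

test_that("hybrid_params exposes the documented defaults", {
  p <- hybrid_params()
  expect_equal(p$n_particles, 100L)
  expect_equal(p$t_max, 120L)
  expect_equal(p$m_rounds, 20L)
  expect_equal(p$p_threshold, 0.02)
  expect_equal(p$c1, 0.5)
  expect_equal(p$c2, 0)
  expect_equal(c(p$omega_min, p$omega_max), c(0.1, 0.2))
  expect_error(hybrid_params(c2 = 0.5)) # social term is fixed at zero
})

test_that("objective_from normalizes and flags degenerate input", {
  m <- fix_mesh(724)
  ph <- fix_phantoms()$fib1
  obj <- objective_from(ph, m)
  # a mesh vertex evaluates to its stored normalized sample
  samples <- attr(obj, "samples")
  rng <- attr(obj, "range")
  a <- unit_to_sph(m$vertices[17, ])
  expect_equal(obj(matrix(a, 1)),
               (samples$values[17] - rng[1]) / diff(rng), tolerance = 1e-9)
  expect_error(objective_from(spherical_samples(m, rep(2, 724)), m),
               "degenerate")
})

test_that("sampled-mode objectives stay within the normalized bound", {
  m <- fix_mesh(724)
  set.seed(61)
  s <- spherical_samples(m, runif(724))
  obj <- objective_from(s, interp = "nearest")
  a <- cbind(runif(2000, 0, 2 * pi), asin(runif(2000, -1, 1)))
  v <- obj(a)
  expect_lte(max(v), 1 + 1e-9)
  expect_gte(min(v), -1e-9)
})

test_that("derandomized swarm updates are exact arithmetic", {
  m <- fix_mesh(724)
  obj <- objective_from(fix_phantoms()$fib1, m)
  p <- hybrid_params(n_particles = 2)
  sw <- init_swarm(obj, p, seed = 1)
  # fixed point: zero velocity at the personal best stays put
  sw$velocities[] <- 0
  sw2 <- pso_step(sw, obj, p)
  expect_equal(sw2$positions, wrap_angles(sw$positions))
  expect_equal(sw2$velocities, matrix(0, 2, 2), ignore_attr = TRUE)
  # velocity update: omega(0) = 0.2, c1 = 0.5, V = 0, P - X = (0.1, 0)
  sw$pbest <- sw$positions + rep(c(0.1, 0), each = 2)
  sw3 <- pso_step(sw, obj, p)
  expect_equal(sw3$velocities, matrix(rep(c(0.05, 0), each = 2), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # no random draws anywhere: identical swarms evolve identically
  swa <- init_swarm(obj, p, seed = 5)
  expect_equal(pso_step(swa, obj, p), pso_step(swa, obj, p))
})

test_that("pso_run covers the maxima and respects its seed", {
  m <- fix_mesh(724)
  obj <- objective_from(fix_phantoms()$fib1, m)
  p <- hybrid_params()
  sw <- pso_run(obj, p, seed = 2)
  best_arc <- min(arc_angle(sph_to_unit(sw$pbest), c(1, 0, 0)))
  expect_lte(best_arc, 5)
  expect_equal(pso_run(obj, p, seed = 2), pso_run(obj, p, seed = 2))
  # a flat objective cannot improve: terminates at the first check
  flat <- function(a) rep(0.5, nrow(a))
  swf <- pso_run(flat, p, seed = 3)
  expect_equal(swf$k, 1L)
})

test_that("line search solves the quadratic axis case and ties to zero", {
  quad <- function(a) -(a[, 1] - 1)^2
  ls <- line_search(quad, c(0, 0), c(1, 0))
  expect_equal(ls$alpha, 1, tolerance = 1e-5)
  expect_equal(ls$x_new, c(1, 0), tolerance = 1e-5)
  flat <- function(a) rep(1, nrow(a))
  expect_equal(line_search(flat, c(0.3, 0.2), c(1, 0))$alpha, 0)
  expect_error(line_search(quad, c(0, 0), c(0, 0)), "zero direction")
  # single-fiber ODF slice through the true peak
  obj <- objective_from(fix_phantoms()$fib1, fix_mesh(724))
  ls2 <- line_search(obj, c(0.3, 0), c(1, 0))
  expect_equal(ls2$x_new[1], 0, tolerance = 1e-3)
})

test_that("powell converges on quadratics and ODF peaks monotonically", {
  p <- hybrid_params()
  quad <- function(a) -((a[, 1] - 1)^2 + (a[, 2] - 0.3)^2)
  res <- powell_search(quad, c(0, 0), p)
  expect_equal(unname(res$x), c(1, 0.3), tolerance = 1e-4)
  expect_true(all(diff(res$trace) >= -1e-12))
  # starting at the optimum returns immediately
  res0 <- powell_search(quad, c(1, 0.3), p)
  expect_equal(unname(res0$x), c(1, 0.3), tolerance = 1e-6)
  expect_lte(res0$cycles, 2)
  # analytic single-fiber ODF from a tilted start
  obj <- objective_from(fix_phantoms()$fib1, fix_mesh(724))
  resf <- powell_search(obj, c(0.3, 0.2), p)
  expect_lte(arc_angle(sph_to_unit(resf$x), c(1, 0, 0)), 0.5)
  expect_true(all(diff(resf$trace) >= -1e-12))
})

test_that("hybrid extraction finds the single fiber for any seed", {
  m <- fix_mesh(724)
  obj <- objective_from(fix_phantoms()$fib1, m)
  for (seed in 1:8) {
    pk <- hybrid_find_peaks(obj, fix_quick_params(seed))
    expect_equal(nrow(pk), 1)
    expect_lte(arc_angle(unlist(pk[1, c("x", "y", "z")]), c(1, 0, 0)), 1)
  }
})

test_that("the hybrid is a pure function of objective, params and seed", {
  m <- fix_mesh(724)
  obj <- objective_from(fix_phantoms()$fib2, m)
  p1 <- hybrid_find_peaks(obj, fix_quick_params(3))
  p2 <- hybrid_find_peaks(obj, fix_quick_params(3))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("peak sets enforce hemisphere and separation invariants", {
  d <- rbind(c(0, 0, -1), c(1, 0, 0))
  pk <- peak_set(d, c(2, 1), c(1, 0.5))
  expect_equal(pk$z[1], 1) # flipped to the canonical hemisphere
  expect_error(peak_set(rbind(c(0, 0, 1), c(0, sin(0.05), cos(0.05))),
                        c(2, 1), c(1, 0.5)),
               "separation")
})

test_that("filter_peaks applies the mean-value and threshold rules", {
  m <- fix_mesh(724)
  vals <- rep(0.3, 724)
  vals[1] <- 1 # mean just above 0.3
  s <- spherical_samples(m, vals)
  pk <- peak_set(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
                 c(1.0, 0.9, 0.1), c(1.0, 0.9, 0.05))
  out <- filter_peaks(pk, s)
  expect_equal(nrow(out), 2) # the sub-mean 0.1 peak is discarded
  expect_equal(out$odf_value, c(1.0, 0.9))
  # all peaks above mean and threshold: identity
  s2 <- spherical_samples(m, rep(0.05, 723) |> c(1))
  expect_equal(nrow(filter_peaks(pk, s2)), 3)
  # normalized floor removes noise-level peaks
  pk2 <- peak_set(rbind(c(0, 0, 1), c(1, 0, 0)), c(1.0, 0.9), c(1.0, 0.01))
  expect_equal(nrow(filter_peaks(pk2, s2)), 1)
})
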