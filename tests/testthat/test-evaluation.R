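test_that("grid oracle finds exactly the mesh-local maxima", {
  m <- fix_mesh(2562)
  ph <- fix_phantoms()
  pk1 <- grid_peaks(analytic_odf(ph$fib1, m))
  expect_equal(nrow(pk1), 1)
  pk2 <- grid_peaks(analytic_odf(ph$fib2, m))
  expect_equal(nrow(pk2), 2)
  # a constant field has no strict maxima, only a flagged plateau
  flat <- grid_peaks(spherical_samples(fix_mesh(724), rep(1, 724)))
  expect_equal(nrow(flat), 0)
  expect_true(attr(flat, "plateau"))
})

test_that("matching is exact against an independent exhaustive oracle", {
  # identity and antipodes match at zero cost
  truth <- fix_truth(fix_phantoms()$fib3)
  m0 <- match_peaks(truth, truth)
  expect_equal(nrow(m0), 3)
  expect_equal(m0$arc_deg, rep(0, 3))
  expect_equal(attr(m0, "total_arc"), 0)
  ma <- match_peaks(-truth, truth)
  expect_equal(ma$arc_deg, rep(0, 3))
  # random unbalanced instances agree with brute-force enumeration
  set.seed(71)
  for (trial in 1:20) {
    k <- sample(1:4, 1)
    m_ <- sample(1:4, 1)
    F_ <- sph_to_unit(cbind(runif(k, 0, 2 * pi), asin(runif(k, -1, 1))))
    T_ <- sph_to_unit(cbind(runif(m_, 0, 2 * pi), asin(runif(m_, -1, 1))))
    got <- attr(match_peaks(F_, T_, max_arc = 180), "total_arc")
    expect_equal(got, oracle_match(F_, T_), tolerance = 1e-9)
  }
})

test_that("pairs beyond the matching gate are dropped", {
  truth <- rbind(c(1, 0, 0), c(0, 1, 0))
  found <- rbind(c(1, 0, 0), c(0, cos(pi / 4), sin(pi / 4))) # 45 deg off
  mp <- match_peaks(found, truth, max_arc = 20)
  expect_equal(nrow(mp), 1)
  expect_equal(mp$found, 1)
})

test_that("deviation reports decompose azimuth and elevation errors", {
  truth <- rbind(sph_to_unit(c(0, 0)))
  found <- rbind(sph_to_unit(c(0.02, 0)))
  rp <- deviation_report(match_peaks(found, truth), found, truth)
  expect_equal(rp$pairs$azimuth_dev, 0.02, tolerance = 1e-9)
  expect_equal(rp$pairs$elevation_dev, 0, tolerance = 1e-9)
  expect_equal(rp$pairs$arc_deg, 0.02 * 180 / pi, tolerance = 1e-6)
  expect_true(rp$success)
  # the antipodal representation has zero deviation
  t2 <- rbind(sph_to_unit(c(1.22, 0)))
  f2 <- rbind(sph_to_unit(c(1.22 + pi, 0)))
  rp2 <- deviation_report(match_peaks(f2, t2), f2, t2)
  expect_equal(rp2$pairs$azimuth_dev, 0, tolerance = 1e-9)
  expect_equal(rp2$pairs$arc_deg, 0, tolerance = 1e-9)
  # missing fiber: counts reported, success false
  rp3 <- deviation_report(match_peaks(found, rbind(truth, c(0, 0, 1))),
                          found, rbind(truth, c(0, 0, 1)))
  expect_false(rp3$success)
  expect_equal(rp3$n_matched, 1)
})

test_that("deviation symmetry: swapping found and truth preserves arcs", {
  set.seed(72)
  A <- sph_to_unit(cbind(runif(3, 0, 2 * pi), asin(runif(3, -1, 1))))
  B <- sph_to_unit(cbind(runif(3, 0, 2 * pi), asin(runif(3, -1, 1))))
  r1 <- deviation_report(match_peaks(A, B, 180), A, B, 180)
  r2 <- deviation_report(match_peaks(B, A, 180), B, A, 180)
  expect_equal(sort(r1$pairs$arc_deg), sort(r2$pairs$arc_deg),
               tolerance = 1e-9)
})

test_that("the experiment harness is deterministic and well-formed", {
  p <- fix_quick_params()
  res1 <- run_experiment(phantoms = fix_phantoms()["fib1"],
                         reconstructions = "analytic", snr = Inf,
                         n_reps = 1, seed = 4, params = p)
  res2 <- run_experiment(phantoms = fix_phantoms()["fib1"],
                         reconstructions = "analytic", snr = Inf,
                         n_reps = 1, seed = 4, params = p)
  expect_identical(res1, res2)
  expect_true(all(res1$success))
  expect_equal(nrow(res1), 1) # one matched fiber row
  expect_true(all(c("phantom", "recon", "snr", "rep", "truth_fiber",
                    "azimuth_dev", "elevation_dev", "arc_deg") %in%
                    names(res1)))
})
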