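#' Single-shell HARDI acquisition scheme
#'
#' @param bvals numeric vector of b-values in s/mm^2 (zeros mark b0 volumes).
#' @param bvecs n x 3 matrix of gradient directions; rows for `b > 0` must be
#'   unit vectors, b0 rows may be zero.
#' @return object of class `acq_scheme`.
#' @export
acq_scheme <- function(bvals, bvecs) {
  bvecs <- .as_direction_matrix_or_zero(bvecs)
  bvals <- as.numeric(bvals)
  if (length(bvals) != nrow(bvecs)) stop("acq_scheme: bvals/bvecs length mismatch")
  if (any(bvals < 0)) stop("acq_scheme: negative b-value")
  dwi <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[dwi] - 1) > 1e-6)) {
    stop("acq_scheme: non-unit gradient for a diffusion-weighted volume")
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "acq_scheme")
}

.as_direction_matrix_or_zero <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 3L) stop("expected an n x 3 matrix of directions")
  v
}

#' Default 64-direction b = 3000 scheme
#'
#' One b = 0 volume plus `n_dirs` deterministic quasi-uniform gradient
#' directions (spherical Fibonacci lattice) at a single shell, the typical
#' HARDI protocol the phantom experiments emulate.
#'
#' @param n_dirs number of diffusion-weighted directions (default 64).
#' @param b shell b-value in s/mm^2 (default 3000).
#' @param n_b0 number of unweighted volumes prepended (default 1).
#' @return an [acq_scheme()].
#' @export
default_scheme <- function(n_dirs = 64, b = 3000, n_b0 = 1) {
  dirs <- fibonacci_directions(n_dirs)
  acq_scheme(
    bvals = c(rep(0, n_b0), rep(b, n_dirs)),
    bvecs = rbind(matrix(0, n_b0, 3), dirs)
  )
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("acq_scheme:", sum(x$bvals == 0), "b0 +", sum(x$bvals > 0),
      "DWI volumes, shell b =", paste(unique(x$bvals[x$bvals > 0]), collapse = ", "),
      "s/mm^2\n")
  invisible(x)
}

#' Gaussian diffusion-tensor compartment
#'
#' @param fraction volume fraction in `[0, 1]`.
#' @param angles `c(theta, phi)` azimuth/elevation (radians) of the principal
#'   (largest-eigenvalue) axis.
#' @param lambda eigenvalues `c(l1, l2, l3)` in mm^2/s, `l1 >= l2 >= l3 > 0`.
#'   Defaults to typical coherent white-matter diffusivities
#'   `(1.7, 0.3, 0.3) * 1e-3`.
#' @return object of class `tensor_compartment` with the rotated 3 x 3 tensor
#'   precomputed.
#' @export
tensor_compartment <- function(fraction, angles,
                               lambda = c(1.7e-3, 3e-4, 3e-4)) {
  stopifnot(length(lambda) == 3L, all(diff(lambda) <= 0), lambda[3] > 0)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  angles <- wrap_angles(angles)
  mu <- sph_to_unit(angles)
  # orthonormal complement; the choice only matters when l2 != l3
  ref <- if (abs(mu[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e2 <- .cross3(ref, mu); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- .cross3(mu, e2)
  D <- lambda[1] * tcrossprod(mu) + lambda[2] * tcrossprod(e2) +
    lambda[3] * tcrossprod(e3)
  structure(list(fraction = fraction, angles = angles, lambda = lambda,
                 principal = mu, D = D),
            class = "tensor_compartment")
}

#' Multi-tensor phantom configuration
#'
#' A mixture of Gaussian diffusion compartments whose volume fractions sum
#' to 1 (renormalized if they are off by rounding, e.g. 0.33 + 0.33 + 0.33).
#'
#' @param compartments list of [tensor_compartment()] objects.
#' @param s0 unweighted signal amplitude (arbitrary units, default 1).
#' @return object of class `phantom`.
#' @export
phantom <- function(compartments, s0 = 1) {
  if (length(compartments) < 1L) stop("phantom: need at least one compartment")
  stopifnot(all(vapply(compartments, inherits, TRUE, "tensor_compartment")))
  fsum <- sum(vapply(compartments, `[[`, 0, "fraction"))
  if (abs(fsum - 1) > 0.05) {
    stop("phantom: volume fractions sum to ", format(fsum), ", expected ~1")
  }
  if (abs(fsum - 1) > 1e-9) {
    compartments <- lapply(compartments, function(cp) {
      cp$fraction <- cp$fraction / fsum
      cp
    })
  }
  structure(list(compartments = compartments, s0 = s0), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom:", length(x$compartments), "tensor compartment(s), S0 =", x$s0, "\n")
  for (cp in x$compartments) {
    cat(sprintf("  f = %.3f at (theta, phi) = (%.3f, %.3f) rad\n",
                cp$fraction, cp$angles[1], cp$angles[2]))
  }
  invisible(x)
}

#' Standard one-, two-, and three-crossing-fiber phantoms
#'
#' The canonical simulation test bed: one fiber along `(0, 0)`; two crossing
#' fibers at `(0, 0)` and `(1.22, 0)` with equal fractions; three crossing
#' fibers at `(0, 0)`, `(1.22, 0)` and `(0.52, 1.05)` with fractions
#' 0.33/0.33/0.33 renormalized to sum to 1. Angles are (azimuth, elevation)
#' in radians.
#'
#' @param lambda per-compartment eigenvalues, see [tensor_compartment()].
#' @return list of three [phantom()] objects named `fib1`, `fib2`, `fib3`.
#' @export
fiber_phantoms <- function(lambda = c(1.7e-3, 3e-4, 3e-4)) {
  list(
    fib1 = phantom(list(
      tensor_compartment(1, c(0, 0), lambda)
    )),
    fib2 = phantom(list(
      tensor_compartment(0.5, c(0, 0), lambda),
      tensor_compartment(0.5, c(1.22, 0), lambda)
    )),
    fib3 = phantom(list(
      tensor_compartment(0.33, c(0, 0), lambda),
      tensor_compartment(0.33, c(1.22, 0), lambda),
      tensor_compartment(0.33, c(0.52, 1.05), lambda)
    ))
  )
}

#' Random multi-tensor phantom with separated orientations
#'
#' Draws `n_fibers` orientations uniformly on the sphere, rejecting draws
#' whose pairwise antipodal arc is below `min_sep_deg`, with equal volume
#' fractions. Used for property-style stress tests of the peak extractor.
#'
#' @param n_fibers 1, 2 or 3 compartments.
#' @param seed integer RNG seed (the draw is a pure function of it).
#' @param min_sep_deg minimum pairwise separation in degrees (default 40).
#' @param lambda per-compartment eigenvalues.
#' @return a [phantom()].
#' @export
random_phantom <- function(n_fibers, seed, min_sep_deg = 40,
                           lambda = c(1.7e-3, 3e-4, 3e-4)) {
  stopifnot(n_fibers >= 1, n_fibers <= 3)
  dirs <- .with_seed(seed, {
    out <- matrix(0, 0, 3)
    while (nrow(out) < n_fibers) {
      cand <- sph_to_unit(c(stats::runif(1, 0, 2 * pi),
                            asin(stats::runif(1, -1, 1))))
      if (nrow(out) == 0L ||
          min(arc_angle(out, matrix(cand, 1), antipodal = TRUE)) >= min_sep_deg) {
        out <- rbind(out, cand)
      }
    }
    out
  })
  phantom(lapply(seq_len(n_fibers), function(i) {
    tensor_compartment(1 / n_fibers, unit_to_sph(dirs[i, ]), lambda)
  }))
}

# run code with a local, restored RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate multi-tensor HARDI signals
#'
#' Gaussian mixture signal decay:
#' `S(g, b) = S0 * sum_i f_i * exp(-b * g' D_i g)`.
#'
#' @param phantom a [phantom()].
#' @param scheme an [acq_scheme()].
#' @return numeric vector of signals, one per scheme volume (b = 0 volumes
#'   give exactly `S0`).
#' @export
simulate_signal <- function(phantom, scheme) {
  stopifnot(inherits(phantom, "phantom"), inherits(scheme, "acq_scheme"))
  G <- scheme$bvecs
  b <- scheme$bvals
  S <- numeric(length(b))
  for (cp in phantom$compartments) {
    q <- rowSums((G %*% cp$D) * G) # g' D g
    S <- S + cp$fraction * exp(-b * q)
  }
  S[b == 0] <- 1 # unit gradients are zero rows there; decay is exactly 1
  phantom$s0 * S
}

#' Add Rician magnitude noise
#'
#' Standard MRI noise model: `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma = S0 / snr`
#' on each channel. The draw is a pure function of the seed.
#'
#' @param signals numeric vector of noiseless magnitudes.
#' @param s0 unweighted signal amplitude defining the SNR scale.
#' @param snr signal-to-noise ratio `S0 / sigma`; `Inf` returns the input
#'   unchanged.
#' @param seed integer RNG seed.
#' @return noisy magnitudes, same length as `signals`.
#' @export
add_rician <- function(signals, s0, snr, seed) {
  stopifnot(snr > 0)
  if (!is.finite(snr)) return(signals)
  sigma <- s0 / snr
  .with_seed(seed, {
    n1 <- stats::rnorm(length(signals), 0, sigma)
    n2 <- stats::rnorm(length(signals), 0, sigma)
    sqrt((signals + n1)^2 + n2^2)
  })
}

#' Closed-form mixture ODF as a function of direction
#'
#' The solid-angle ODF of a Gaussian mixture propagator — the radial
#' projection with the `r^2` Jacobian — has the exact closed form
#' `psi(u) = sum_i f_i / (4*pi*sqrt(det(D_i)) * (u' D_i^{-1} u)^{3/2})`,
#' which integrates to 1 over the sphere analytically.
#'
#' @param phantom a [phantom()].
#' @return a vectorized function mapping an n x 3 matrix of unit directions
#'   (or a single direction) to ODF values.
#' @export
analytic_odf_fun <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  comps <- lapply(phantom$compartments, function(cp) {
    det_d <- prod(cp$lambda)
    if (det_d <= 0) stop("singular tensor in phantom")
    list(f = cp$fraction, Dinv = solve(cp$D), c0 = 1 / (4 * pi * sqrt(det_d)))
  })
  function(u) {
    U <- .as_direction_matrix(u)
    val <- numeric(nrow(U))
    for (cp in comps) {
      q <- rowSums((U %*% cp$Dinv) * U)
      val <- val + cp$f * cp$c0 * q^(-1.5)
    }
    if (is.null(dim(u)) && length(u) == 3L) val[1L] else val
  }
}

#' Exact analytic ODF sampled on a mesh
#'
#' @param phantom a [phantom()].
#' @param mesh a [even_sphere()] mesh.
#' @return a [spherical_samples()] object; the mesh-quadrature integral of
#'   the samples approximates 1 (exactly 1 in the continuum).
#' @export
analytic_odf <- function(phantom, mesh) {
  fn <- analytic_odf_fun(phantom)
  spherical_samples(mesh, fn(mesh$vertices))
}
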