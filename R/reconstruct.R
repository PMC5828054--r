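#' Funk-Radon transform multiplier for degree l
#'
#' In the SH basis the Funk-Radon transform is diagonal with eigenvalue
#' `2 * pi * P_l(0)`; `P_l(0) = (-1)^(l/2) (l-1)!! / l!!` for even `l`.
#'
#' @param l even degree(s).
#' @return multiplier(s): `2*pi` for l = 0, `-pi` for l = 2, `3*pi/4` for
#'   l = 4, ...
#' @export
frt_multiplier <- function(l) {
  vapply(l, function(li) {
    if (li %% 2 != 0) stop("frt_multiplier: l must be even")
    if (li == 0) return(2 * pi)
    k <- seq(2, li, by = 2)
    pl0 <- (-1)^(li / 2) * prod((k - 1) / k)
    2 * pi * pl0
  }, 0)
}

# split signals into S0 estimate and single-shell attenuation E = S/S0
.shell_attenuation <- function(signals, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"), length(signals) == length(scheme$bvals))
  b0 <- scheme$bvals == 0
  if (!any(b0)) stop("scheme has no b = 0 volume to estimate S0")
  shells <- unique(scheme$bvals[!b0])
  if (length(shells) != 1L) stop("single-shell scheme required (one nonzero b)")
  s0 <- mean(signals[b0])
  if (s0 <= 0) stop("non-positive S0 estimate")
  list(E = signals[!b0] / s0, dirs = scheme$bvecs[!b0, , drop = FALSE],
       b = shells, s0 = s0)
}

#' Q-ball imaging ODF (analytic Funk-Radon transform)
#'
#' Fits even-order spherical harmonics to the single-shell attenuation
#' `S/S0` and applies the Funk-Radon transform coefficient-wise
#' (`c'_lm = 2*pi*P_l(0)*c_lm`). The result is the (unnormalized) Tuch ODF
#' in SH form; downstream peak extraction min-max normalizes its samples.
#'
#' @param signals vector of signals, one per scheme volume.
#' @param scheme single-shell [acq_scheme()] with at least one b0.
#' @param lmax even SH order (default 8).
#' @param lambda_reg Laplace-Beltrami regularization weight (default 0.006).
#' @return an [sh_coeffs()] object.
#' @export
qbi_odf <- function(signals, scheme, lmax = 8, lambda_reg = 0.006) {
  sa <- .shell_attenuation(signals, scheme)
  B <- sh_basis(lmax, sa$dirs)
  cs <- fit_sh(sa$E, B, lambda_reg)
  cs$coeffs <- cs$coeffs * frt_multiplier(cs$degree)
  cs
}

#' Constant-solid-angle q-ball ODF
#'
#' Clamps the attenuation `E = S/S0` into `[delta, 1 - delta]`, fits SH to
#' `log(-log(E))` and forms
#' `ODF = 1/(4*pi) + 1/(16*pi^2) * FRT( Laplace-Beltrami( log(-log E) ) )`,
#' i.e. coefficient-wise `c'_lm = -(1/(16*pi^2)) * 2*pi*P_l(0) * l(l+1) *
#' c_lm` for `l >= 2` plus the constant `1/(4*pi)` term. This is the
#' solid-angle (r^2-weighted) ODF, properly normalized in the continuum.
#'
#' @inheritParams qbi_odf
#' @param delta clamp width in `(0, 0.5)` guarding the double logarithm
#'   against noise-driven attenuations outside `(0, 1)` (default 1e-3).
#' @return an [sh_coeffs()] object.
#' @export
csa_odf <- function(signals, scheme, lmax = 8, lambda_reg = 0.006,
                    delta = 1e-3) {
  if (delta <= 0 || delta >= 0.5) stop("csa_odf: delta must be in (0, 0.5)")
  sa <- .shell_attenuation(signals, scheme)
  E <- pmin(1 - delta, pmax(delta, sa$E))
  B <- sh_basis(lmax, sa$dirs)
  cs <- fit_sh(log(-log(E)), B, lambda_reg)
  l <- cs$degree
  cs$coeffs <- -(1 / (16 * pi^2)) * frt_multiplier(l) * l * (l + 1) * cs$coeffs
  cs$coeffs[1] <- 1 / sqrt(4 * pi) # constant term: 1/(4*pi) * Y00^{-1}
  cs
}

#' Log-linear diffusion tensor fit with fractional anisotropy
#'
#' Ordinary least squares on `log(S) = log(S0) - b g' D g` (at least six
#' noncollinear gradients plus a b0 required). Non-positive signals are
#' clamped to a small fraction of S0 with a warning. FA is computed from the
#' tensor eigenvalues by the standard formula; thresholding FA (typically at
#' 0.20) segments coherent white matter before peak extraction.
#'
#' @param signals vector of signals, one per scheme volume.
#' @param scheme an [acq_scheme()].
#' @return object of class `tensor_fit`: list with the 3 x 3 tensor `D`,
#'   `fa`, `md` (mean diffusivity), eigenvalues `evals` (decreasing),
#'   eigenvectors `evecs`, and `principal` (unit vector of the largest
#'   eigenvalue).
#' @export
fit_tensor <- function(signals, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"), length(signals) == length(scheme$bvals))
  if (sum(scheme$bvals > 0) < 6) stop("fit_tensor: need >= 6 gradient directions")
  s0ref <- mean(signals[scheme$bvals == 0])
  if (!is.finite(s0ref) || s0ref <= 0) s0ref <- max(signals)
  bad <- signals <= 0
  if (any(bad)) {
    warning("fit_tensor: ", sum(bad), " non-positive signal(s) clamped")
    signals[bad] <- 1e-6 * s0ref
  }
  g <- scheme$bvecs
  b <- scheme$bvals
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  beta <- stats::lm.fit(X, log(signals))$coefficients
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE)
  lam <- ev$values
  md <- mean(lam)
  fa <- sqrt(1.5 * sum((lam - md)^2) / sum(lam^2))
  fa <- min(1, max(0, fa))
  structure(list(D = D, fa = fa, md = md, evals = lam, evecs = ev$vectors,
                 principal = ev$vectors[, 1]),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("tensor_fit: FA = %.3f, MD = %.3e mm^2/s\n", x$fa, x$md))
  invisible(x)
}
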