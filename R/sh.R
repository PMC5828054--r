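# Real symmetric spherical-harmonic basis (even orders only).
#
# Ordering: (l, m) with l = 0, 2, ..., lmax and m = -l..l; for m < 0 the
# basis function is sqrt(2) * N_l|m| * P_l^|m|(sin(phi)) * sin(|m| theta),
# for m = 0 it is N_l0 * P_l^0, and for m > 0
# sqrt(2) * N_lm * P_l^m * cos(m theta), with N_lm the full orthonormalizing
# constant. P_l^m carries the Condon-Shortley phase; the basis is
# orthonormal over the sphere either way.
#
# The associated Legendre values come from the standard stable recurrences
# (diagonal P_m^m, then upward in l), vectorized over directions: the
# optimizer evaluates the basis at single query points inside line searches,
# so this path has to be cheap.

# list of matrices P[[l+1]]: (l+1) x n, rows m = 0..l (only even l filled)
.assoc_legendre_even <- function(lmax, z) {
  n <- length(z)
  s <- sqrt(pmax(0, 1 - z^2)) # sin(polar)
  # full table up to lmax (odd l needed as recurrence intermediates)
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- matrix(0, l + 1L, n)
  P[[1L]][1L, ] <- 1
  if (lmax >= 1) {
    for (m in 1:lmax) { # diagonal: P_m^m = -(2m-1) s P_{m-1}^{m-1}
      P[[m + 1L]][m + 1L, ] <- -(2 * m - 1) * s * P[[m]][m, ]
    }
    for (m in 0:(lmax - 1)) { # P_{m+1}^m = (2m+1) z P_m^m
      P[[m + 2L]][m + 1L, ] <- (2 * m + 1) * z * P[[m + 1L]][m + 1L, ]
    }
    if (lmax >= 2) {
      for (l in 2:lmax) {
        for (m in 0:(l - 2)) {
          P[[l + 1L]][m + 1L, ] <-
            ((2 * l - 1) * z * P[[l]][m + 1L, ] -
               (l + m - 1) * P[[l - 1L]][m + 1L, ]) / (l - m)
        }
      }
    }
  }
  P
}

.sh_index_table <- function(lmax) {
  ls <- seq(0, lmax, by = 2)
  do.call(rbind, lapply(ls, function(l) cbind(l = l, m = seq(-l, l))))
}

#' Number of even-order SH coefficients up to `lmax`
#' @param lmax maximum (even) order.
#' @return `(lmax + 1) * (lmax + 2) / 2`.
#' @export
sh_ncoef <- function(lmax) (lmax + 1) * (lmax + 2) / 2

#' Real symmetric spherical-harmonic design matrix
#'
#' One row per direction, one column per even-order basis function
#' `(l, m)`, `l = 0, 2, ..., lmax`, `m = -l..l`. The basis is orthonormal
#' over the sphere in the continuum and antipodally symmetric (even `l`
#' only), the natural representation for ODFs. `lmax = 8` (45 coefficients)
#' resolves fibers crossing at small angles.
#'
#' @param lmax maximum order, even and `>= 0`.
#' @param directions n x 3 matrix of unit directions (or one direction).
#' @return n x `sh_ncoef(lmax)` matrix with attributes `degree` and `order`
#'   (the per-column `l` and `m`).
#' @export
sh_basis <- function(lmax, directions) {
  if (lmax < 0 || lmax %% 2 != 0) stop("sh_basis: lmax must be even and >= 0")
  U <- .as_direction_matrix(directions)
  theta <- atan2(U[, 2], U[, 1])
  z <- pmin(1, pmax(-1, U[, 3])) # sin(elevation)
  tab <- .sh_index_table(lmax)
  B <- matrix(0, nrow(U), nrow(tab))
  P <- .assoc_legendre_even(lmax, z)
  j <- 0L
  for (l in seq(0, lmax, by = 2)) {
    for (m in seq(-l, l)) {
      j <- j + 1L
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      col <- nlm * P[[l + 1L]][am + 1L, ]
      if (m < 0) {
        col <- sqrt(2) * col * sin(am * theta)
      } else if (m > 0) {
        col <- sqrt(2) * col * cos(m * theta)
      }
      B[, j] <- col
    }
  }
  attr(B, "degree") <- tab[, "l"]
  attr(B, "order") <- tab[, "m"]
  attr(B, "lmax") <- lmax
  B
}

#' SH coefficient container
#'
#' @param coeffs numeric vector of length `sh_ncoef(lmax)` in the
#'   `(l, m)` ordering of [sh_basis()].
#' @param lmax the maximum even order.
#' @return object of class `sh_coeffs`.
#' @export
sh_coeffs <- function(coeffs, lmax) {
  if (length(coeffs) != sh_ncoef(lmax)) {
    stop("sh_coeffs: expected ", sh_ncoef(lmax), " coefficients for lmax = ", lmax)
  }
  structure(list(coeffs = as.numeric(coeffs), lmax = lmax,
                 degree = .sh_index_table(lmax)[, "l"]),
            class = "sh_coeffs")
}

#' @export
print.sh_coeffs <- function(x, ...) {
  cat("sh_coeffs: lmax =", x$lmax, "(", length(x$coeffs), "coefficients )\n")
  invisible(x)
}

#' Fit spherical-harmonic coefficients by regularized least squares
#'
#' Solves `argmin ||B c - s||^2 + lambda ||L c||^2` with
#' `L = diag(l (l + 1))`, the Laplace-Beltrami regularizer that damps
#' high-order terms (default weight 0.006, standard for analytic q-ball
#' fits).
#'
#' @param values signal value per direction.
#' @param basis design matrix from [sh_basis()] evaluated at those
#'   directions.
#' @param lambda_reg Laplace-Beltrami weight, `>= 0`.
#' @return an [sh_coeffs()] object.
#' @export
fit_sh <- function(values, basis, lambda_reg = 0.006) {
  stopifnot(length(values) == nrow(basis), lambda_reg >= 0)
  deg <- attr(basis, "degree")
  if (is.null(deg)) stop("fit_sh: basis must come from sh_basis()")
  L2 <- (deg * (deg + 1))^2
  A <- crossprod(basis) + lambda_reg * diag(L2, length(deg))
  ok <- tryCatch({
    ch <- chol(A)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("fit_sh: rank-deficient system (too few directions for lmax ",
                "with lambda_reg = 0)")
  co <- backsolve(ch, forwardsolve(t(ch), crossprod(basis, values)))
  sh_coeffs(as.vector(co), attr(basis, "lmax"))
}

#' Evaluate SH coefficients at arbitrary directions
#'
#' @param coeffs an [sh_coeffs()] object.
#' @param directions n x 3 matrix of unit directions (or one direction).
#' @return numeric value(s) of the band-limited function.
#' @export
evaluate_sh <- function(coeffs, directions) {
  stopifnot(inherits(coeffs, "sh_coeffs"))
  B <- sh_basis(coeffs$lmax, directions)
  v <- as.vector(B %*% coeffs$coeffs)
  if (is.null(dim(directions)) && length(directions) == 3L) v[1L] else v
}

# Polynomial coefficient vectors (ascending powers of z) of Q_{l,m}, where
# P_l^m(z) = s^m Q_{l,m}(z), s = sqrt(1 - z^2), via the standard recurrences.
.legendre_poly_table <- function(lmax) {
  key <- paste0("Q", lmax)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  padd <- function(a, b) {
    n <- max(length(a), length(b))
    c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  }
  zshift <- function(a) c(0, a) # multiply by z
  Q <- vector("list", lmax + 1L)
  for (l in 0:lmax) Q[[l + 1L]] <- vector("list", l + 1L)
  Q[[1L]][[1L]] <- 1
  if (lmax >= 1) {
    for (m in 1:lmax) Q[[m + 1L]][[m + 1L]] <- (-(2 * m - 1)) * Q[[m]][[m]]
    for (m in 0:(lmax - 1)) {
      Q[[m + 2L]][[m + 1L]] <- (2 * m + 1) * zshift(Q[[m + 1L]][[m + 1L]])
    }
    if (lmax >= 2) {
      for (l in 2:lmax) {
        for (m in 0:(l - 2)) {
          Q[[l + 1L]][[m + 1L]] <- padd(
            (2 * l - 1) / (l - m) * zshift(Q[[l]][[m + 1L]]),
            -(l + m - 1) / (l - m) * Q[[l - 1L]][[m + 1L]]
          )
        }
      }
    }
  }
  .sh_cache[[key]] <- Q
  Q
}

.sh_cache <- new.env(parent = emptyenv())

# Fast evaluator for a fixed coefficient vector: collapses the expansion to
# sum_m s^m (A_m(z) cos(m theta) + B_m(z) sin(m theta)) with A_m, B_m
# polynomials in z precomputed once into coefficient matrices, so a query
# costs one small matrix product plus trig recurrences. Exactly equal to
# evaluate_sh (up to roundoff); this is the optimizer's hot path.
.sh_fast_eval <- function(cs) {
  lmax <- cs$lmax
  tab <- .sh_index_table(lmax)
  Q <- .legendre_poly_table(lmax)
  d <- lmax + 1L
  CA <- matrix(0, d, d) # rows m, cols z-power (ascending)
  CB <- matrix(0, d, d)
  for (j in seq_len(nrow(tab))) {
    l <- tab[j, "l"]
    m <- tab[j, "m"]
    am <- abs(m)
    nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    k <- nlm * cs$coeffs[j] * if (m != 0) sqrt(2) else 1
    qc <- k * Q[[l + 1L]][[am + 1L]]
    idx <- seq_along(qc)
    if (m >= 0) CA[am + 1L, idx] <- CA[am + 1L, idx] + qc
    else CB[am + 1L, idx] <- CB[am + 1L, idx] + qc
  }
  tCA <- t(CA)
  tCB <- t(CB)
  function(U) {
    z <- U[, 3]
    n <- length(z)
    s2 <- 1 - z * z
    s2[s2 < 0] <- 0
    s <- sqrt(s2)
    Zp <- matrix(1, n, d)
    for (k in 2:d) Zp[, k] <- Zp[, k - 1L] * z
    PA <- Zp %*% tCA # n x d: A_m(z)
    PB <- Zp %*% tCB
    r <- s
    r[r < 1e-300] <- 1e-300
    c1 <- U[, 1] / r
    s1 <- U[, 2] / r
    out <- PA[, 1L]
    cm <- c1
    sm_ <- s1
    spow <- s
    for (m in 1:lmax) {
      out <- out + spow * (PA[, m + 1L] * cm + PB[, m + 1L] * sm_)
      tmp <- cm * c1 - sm_ * s1
      sm_ <- sm_ * c1 + cm * s1
      cm <- tmp
      spow <- spow * s
    }
    out
  }
}
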