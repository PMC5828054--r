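#' Parameters of the PSO-Powell hybrid peak search
#'
#' Defaults are the published operating point of the method: swarm size
#' `N = 100`, inertia weight decaying linearly from 0.2 to 0.1, acceleration
#' factor `c1 = 0.5` with the social term `c2` fixed at 0, at most
#' `t_max = 120` swarm iterations per round, transfer threshold `P = 0.02`,
#' and at most `M = 20` hybrid (PSO then Powell) rounds.
#'
#' @param n_particles swarm size N.
#' @param t_max maximum PSO iterations per round.
#' @param m_rounds maximum hybrid rounds M.
#' @param epsilon Powell convergence tolerance on the per-cycle displacement
#'   `||x^D - x^0||` (radians).
#' @param p_threshold transfer tolerance P: when the mean per-iteration
#'   improvement of the particles' personal bests (normalized ODF units)
#'   drops below it, the swarm hands over to Powell. The same value also
#'   discards peaks whose normalized ODF value is below it.
#' @param c1 cognitive acceleration factor.
#' @param c2 social factor, fixed at 0 in the derandomized update.
#' @param omega_max,omega_min inertia-weight bounds (linear decay over
#'   `t_max`).
#' @param merge_angle antipodal arc (degrees) under which two extrema are
#'   considered the same peak; the higher-valued one is kept.
#' @param seed integer seed; the entire hybrid is a pure function of
#'   (objective, params, seed).
#' @param start_dedup_angle antipodal arc (degrees) under which near-equal
#'   Powell start points (personal bests) are collapsed before the local
#'   searches; 0 starts Powell from every personal best.
#' @param early_exit stop before `m_rounds` when three consecutive rounds
#'   add no new extremum; set `FALSE` for the strict fixed-round schedule.
#' @param powell_criterion direction-retention rule: `"paper"` keeps the
#'   direction set when the printed extrapolation inequality holds and
#'   otherwise replaces the max-drop direction; `"classical"` uses the
#'   textbook Powell criterion.
#' @param max_cycles hard cap on Powell cycles.
#' @param line_tol line-search tolerance (radians).
#' @return object of class `hybrid_params`.
#' @export
hybrid_params <- function(n_particles = 100, t_max = 120, m_rounds = 20,
                          epsilon = 1e-4, p_threshold = 0.02,
                          c1 = 0.5, c2 = 0,
                          omega_max = 0.2, omega_min = 0.1,
                          merge_angle = 10, seed = 1,
                          start_dedup_angle = 2, early_exit = TRUE,
                          powell_criterion = c("paper", "classical"),
                          max_cycles = 100, line_tol = 1e-6) {
  stopifnot(n_particles >= 1, t_max >= 1, m_rounds >= 1, epsilon > 0,
            p_threshold > 0, c1 > 0, c2 == 0, omega_min > 0,
            omega_min <= omega_max, merge_angle > 0, start_dedup_angle >= 0,
            max_cycles >= 1, line_tol > 0)
  structure(list(
    n_particles = as.integer(n_particles), t_max = as.integer(t_max),
    m_rounds = as.integer(m_rounds), epsilon = epsilon,
    p_threshold = p_threshold, c1 = c1, c2 = c2,
    omega_max = omega_max, omega_min = omega_min,
    merge_angle = merge_angle, seed = as.integer(seed),
    start_dedup_angle = start_dedup_angle, early_exit = isTRUE(early_exit),
    powell_criterion = match.arg(powell_criterion),
    max_cycles = as.integer(max_cycles), line_tol = line_tol
  ), class = "hybrid_params")
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat(sprintf(
    "hybrid_params: N=%d, t_max=%d, P=%.3g, M=%d, c1=%.3g, c2=%g, omega=[%.3g, %.3g],\n  epsilon=%.3g, merge_angle=%.3g deg, seed=%d\n",
    x$n_particles, x$t_max, x$p_threshold, x$m_rounds, x$c1, x$c2,
    x$omega_min, x$omega_max, x$epsilon, x$merge_angle, x$seed))
  invisible(x)
}

#' Inertia weight at iteration k
#'
#' Linear decay from `omega_max` at `k = 0` to `omega_min` at `k = t_max`.
#'
#' @param k iteration counter, `0 <= k <= t_max`.
#' @param params a [hybrid_params()].
#' @return scalar inertia weight.
#' @export
inertia_weight <- function(k, params) {
  stopifnot(k >= 0, k <= params$t_max)
  params$omega_max - (params$omega_max - params$omega_min) * k / params$t_max
}

#' Build a continuous objective on the sphere from an ODF representation
#'
#' Adapter feeding the optimizer: wraps mesh samples (nearest-neighbor or
#' barycentric interpolation), SH coefficients (exact band-limited
#' evaluation), or a phantom's analytic mixture ODF into a single vectorized
#' function of (theta, phi), min-max normalized to `[0, 1]` over the mesh
#' samples. Nearest-neighbor interpolation gives a piecewise-constant
#' surface on which line searches stall at plateau edges, so the smooth
#' modes (`sh`, `analytic`, or barycentric samples) are preferred whenever
#' available; nearest mode reproduces sample-snapped peak extraction.
#'
#' @param x a [spherical_samples()], [sh_coeffs()], or [phantom()] object.
#' @param mesh mesh on which normalization samples are evaluated (required
#'   for `sh_coeffs`/`phantom` input; taken from `x` for samples input).
#' @param interp interpolation mode for samples input, `"barycentric"` or
#'   `"nearest"`.
#' @return a function `f(angles)` on `c(theta, phi)` rows returning
#'   normalized values in `[0, 1]`, with attributes `samples` (the raw mesh
#'   samples) and `range` (raw min/max used for normalization).
#' @export
objective_from <- function(x, mesh = NULL, interp = c("barycentric", "nearest")) {
  interp <- match.arg(interp)
  if (inherits(x, "spherical_samples")) {
    samples <- x
    raw_fn <- function(U) sph_interpolate(samples, U, mode = interp)
  } else if (inherits(x, "sh_coeffs")) {
    if (is.null(mesh)) stop("objective_from: mesh required for sh_coeffs input")
    raw_fn <- .sh_fast_eval(x)
    samples <- spherical_samples(mesh, pmax(0, raw_fn(mesh$vertices)))
    samples$values <- raw_fn(mesh$vertices) # keep raw (possibly negative) scale
  } else if (inherits(x, "phantom")) {
    if (is.null(mesh)) stop("objective_from: mesh required for phantom input")
    fn <- analytic_odf_fun(x)
    raw_fn <- function(U) fn(U)
    samples <- spherical_samples(mesh, raw_fn(mesh$vertices))
  } else {
    stop("objective_from: unsupported input of class ", class(x)[1])
  }
  rng <- range(samples$values)
  if (!all(is.finite(rng)) || diff(rng) < 1e-12) {
    stop("degenerate objective: all mesh samples are (numerically) equal")
  }
  scale <- rng[2] - rng[1]
  f <- function(angles) {
    a <- if (is.matrix(angles)) angles else matrix(angles, ncol = 2L,
                                                   byrow = length(angles) == 2L)
    cphi <- cos(a[, 2L])
    U <- cbind(cphi * cos(a[, 1L]), cphi * sin(a[, 1L]), sin(a[, 2L]))
    (raw_fn(U) - rng[1]) / scale
  }
  attr(f, "samples") <- samples
  attr(f, "range") <- rng
  f
}

#' Initialize a particle swarm
#'
#' Positions are drawn area-uniformly on the sphere (seeded). Initial
#' velocities are drawn uniformly within plus/minus the mean inter-particle
#' spacing `sqrt(4*pi/N)` per angular component: because the derandomized
#' velocity update contains no random factors, a swarm started at rest at
#' its own personal bests would never move, so the initial velocities are
#' what makes the swarm sweep its neighborhoods before handing over to the
#' local search. Personal bests start at the initial positions.
#'
#' @param objective function from [objective_from()].
#' @param params a [hybrid_params()].
#' @param seed integer seed for the position draw.
#' @return object of class `swarm`.
#' @export
init_swarm <- function(objective, params, seed = params$seed) {
  n <- params$n_particles
  v0 <- sqrt(4 * pi / n) # mean inter-particle spacing, radians
  draw <- .with_seed(seed, list(
    X = cbind(theta = stats::runif(n, 0, 2 * pi),
              phi = asin(stats::runif(n, -1, 1))),
    V = cbind(stats::runif(n, -v0, v0), stats::runif(n, -v0, v0))
  ))
  fit <- objective(draw$X)
  structure(list(
    positions = draw$X, velocities = draw$V,
    pbest = draw$X, pbest_val = fit,
    gbest = draw$X[which.max(fit), ], gbest_val = max(fit),
    k = 0L
  ), class = "swarm")
}

#' One derandomized PSO iteration
#'
#' The velocity update is the derandomized rule
#' `V' = omega(k) V + c1 (P_id - X)` — no random factors and no social term
#' (`c2 = 0`) — so every particle hill-climbs toward its own personal best
#' and the swarm as a whole converges to all basins rather than to the
#' single global optimum. Positions advance by `X' = X + V'` and are wrapped
#' back into canonical angle ranges; personal and global bests are updated
#' together. Azimuth differences are taken as shortest wrapped differences.
#'
#' @param swarm a `swarm` from [init_swarm()].
#' @param objective function from [objective_from()].
#' @param params a [hybrid_params()].
#' @return the updated swarm, with `tolerance` set to the mean personal-best
#'   improvement of this iteration.
#' @export
pso_step <- function(swarm, objective, params) {
  w <- inertia_weight(min(swarm$k, params$t_max), params)
  dtheta <- .wrap_diff(swarm$pbest[, 1] - swarm$positions[, 1])
  dphi <- swarm$pbest[, 2] - swarm$positions[, 2]
  V <- w * swarm$velocities + params$c1 * cbind(dtheta, dphi)
  X <- wrap_angles(swarm$positions + V)
  fit <- objective(X)
  improved <- fit > swarm$pbest_val
  gain <- mean(pmax(fit - swarm$pbest_val, 0))
  swarm$pbest[improved, ] <- X[improved, , drop = FALSE]
  swarm$pbest_val[improved] <- fit[improved]
  if (max(swarm$pbest_val) > swarm$gbest_val) {
    swarm$gbest <- swarm$pbest[which.max(swarm$pbest_val), ]
    swarm$gbest_val <- max(swarm$pbest_val)
  }
  swarm$positions <- X
  swarm$velocities <- V
  swarm$k <- swarm$k + 1L
  swarm$tolerance <- gain
  swarm
}

#' Run one PSO stage to its transfer condition
#'
#' Iterates [pso_step()] until the swarm tolerance (mean per-iteration
#' personal-best improvement) drops below the transfer threshold `P` or
#' `t_max` iterations have run.
#'
#' @inheritParams init_swarm
#' @return the final `swarm`, with a `tol_trace` attribute recording the
#'   tolerance after each iteration.
#' @export
pso_run <- function(objective, params, seed = params$seed) {
  swarm <- init_swarm(objective, params, seed)
  trace <- numeric(0)
  repeat {
    swarm <- pso_step(swarm, objective, params)
    trace <- c(trace, swarm$tolerance)
    if (swarm$tolerance < params$p_threshold || swarm$k >= params$t_max) break
  }
  attr(swarm, "tol_trace") <- trace
  swarm
}

#' Bounded derivative-free line search
#'
#' Maximizes `t -> f(x + t d)` for `t` in `[-bound, bound]` by outward
#' (geometric) bracketing of the local maximum nearest the current point,
#' followed by Brent golden-section/parabolic refinement
#' ([stats::optimize()]). The bracketing is deliberately local: an ODF slice
#' is multimodal, and the local stage of the hybrid must converge to the
#' basin it was started in (sphere-wide coverage is the swarm's job). If no
#' probe improves on `t = 0` the step is 0 (tie-break toward the smallest
#' step), so the search never decreases the objective.
#'
#' @param f vectorized objective on `c(theta, phi)` rows.
#' @param x starting point (length-2 numeric, unwrapped angle plane).
#' @param d search direction (length-2, nonzero).
#' @param bound step-magnitude bound (default `pi`).
#' @param tol refinement tolerance on the step (default 1e-6).
#' @param h0 initial probe step (default 0.05 rad).
#' @return list with `alpha` (optimal step), `x_new = x + alpha d`, and
#'   `value = f(x_new)`.
#' @export
line_search <- function(f, x, d, bound = pi, tol = 1e-6, h0 = 0.05) {
  if (sum(d^2) == 0) stop("line_search: zero direction")
  g <- function(t) f(matrix(x + t * d, 1))
  f0 <- g(0)
  if (!is.finite(f0)) stop("line_search: non-finite objective value")
  finish <- function(lo, hi) {
    opt <- stats::optimize(g, interval = c(lo, hi), maximum = TRUE, tol = tol)
    if (!is.finite(opt$objective)) stop("line_search: non-finite objective value")
    if (opt$objective <= f0 + 1e-15) {
      list(alpha = 0, x_new = x, value = f0)
    } else {
      list(alpha = opt$maximum, x_new = x + opt$maximum * d,
           value = opt$objective)
    }
  }
  for (sgn in c(1, -1)) {
    a <- 0
    b <- sgn * h0
    fb <- g(b)
    if (!is.finite(fb)) stop("line_search: non-finite objective value")
    if (fb > f0) {
      fa <- f0
      repeat {
        cc <- if (abs(b) >= bound) NA else sgn * min(bound, 2 * abs(b))
        if (is.na(cc)) return(finish(min(a, b), max(a, b)))
        fc <- g(cc)
        if (!is.finite(fc)) stop("line_search: non-finite objective value")
        if (fc < fb) return(finish(min(a, cc), max(a, cc)))
        a <- b; fa <- fb
        b <- cc; fb <- fc
      }
    }
  }
  # no probe improved: any local optimum is within the first probes
  finish(-h0, h0)
}

#' Modified Powell direction-set local maximization
#'
#' Starting from `x0`, repeatedly performs sequential line searches along a
#' direction set initialized to the theta- and phi-axes. After each cycle:
#' if the total displacement `||x^D - x^0||` is within `epsilon` the point
#' is returned; otherwise an extra line search runs along the cycle
#' displacement `d^D = x^D - x^0`, the maximum-drop direction index `tl` is
#' identified, and the extrapolated point `2 x^D - x^0` decides (via the
#' printed retention inequality, or the classical Powell rule) whether the
#' direction set is kept or `d^tl` is discarded in favor of `d^D`. All
#' formulas are applied to the negated objective so that the minimization
#' inequalities hold verbatim while the task is maximization. The search
#' operates in the unwrapped angle plane (the map to the sphere is smooth
#' and periodic); the result is canonicalized by the caller.
#'
#' @param f vectorized objective on `c(theta, phi)` rows (maximized).
#' @param x0 starting angles `c(theta, phi)`.
#' @param params a [hybrid_params()] (uses `epsilon`, `max_cycles`,
#'   `line_tol`, `powell_criterion`).
#' @return list with `x` (the located maximum, canonical angles), `value`
#'   (objective there), `cycles`, and `trace` (objective value at the start
#'   of each cycle; non-decreasing).
#' @export
powell_search <- function(f, x0, params = hybrid_params()) {
  D <- 2L
  dirs <- diag(1, D)
  x_cur <- as.numeric(x0)
  f_cur <- f(matrix(x_cur, 1))
  if (!is.finite(f_cur)) stop("powell_search: non-finite objective at start")
  trace <- numeric(0)
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    trace <- c(trace, f_cur)
    xs <- vector("list", D + 2L)
    fs <- numeric(D + 2L)
    xs[[1]] <- x_cur
    fs[1] <- f_cur
    for (i in seq_len(D)) {
      ls <- line_search(f, xs[[i]], dirs[, i], tol = params$line_tol)
      xs[[i + 1L]] <- ls$x_new
      fs[i + 1L] <- ls$value
    }
    dD <- xs[[D + 1L]] - xs[[1L]]
    if (sqrt(sum(dD^2)) <= params$epsilon) {
      x_cur <- xs[[D + 1L]]
      f_cur <- fs[D + 1L]
      # guard against stalling on a ridge with a degenerate direction set:
      # only accept convergence certified along the coordinate axes
      if (!isTRUE(all.equal(dirs, diag(1, D)))) {
        dirs <- diag(1, D)
        if (cycles < params$max_cycles) next
      }
      break
    }
    ls <- line_search(f, xs[[D + 1L]], dD, tol = params$line_tol)
    xs[[D + 2L]] <- ls$x_new
    fs[D + 2L] <- ls$value
    # minimization bookkeeping on g = -f
    g <- -fs
    drops <- g[seq_len(D + 1L)] - g[seq_len(D + 1L) + 1L] # i = 0..D
    tl <- which.max(drops)
    xE <- 2 * xs[[D + 1L]] - xs[[1L]] # extrapolated point
    gE <- -f(matrix(xE, 1))
    if (!is.finite(gE)) stop("powell_search: non-finite objective value")
    g0 <- g[1L]
    gN <- g[D + 1L]
    dmax <- drops[tl]
    keep <- if (params$powell_criterion == "paper") {
      (g0 - 2 * gN + gE) >= 2 * dmax
    } else {
      gE >= g0 ||
        2 * (g0 - 2 * gN + gE) * (g0 - gN - dmax)^2 >= dmax * (g0 - gE)^2
    }
    if (!keep && tl <= D) {
      if (tl < D) dirs[, tl:(D - 1L)] <- dirs[, (tl + 1L):D, drop = FALSE]
      dirs[, D] <- dD / sqrt(sum(dD^2))
    }
    x_cur <- xs[[D + 2L]]
    f_cur <- fs[D + 2L]
    if (cycles >= params$max_cycles) break
  }
  list(x = wrap_angles(x_cur), value = f_cur, cycles = cycles, trace = trace)
}

# greedy antipodal dedup of candidate directions; keeps higher values
.merge_extrema <- function(dirs, vals, merge_angle) {
  if (length(vals) == 0L) return(list(dirs = matrix(0, 0, 3), vals = numeric(0)))
  ord <- order(vals, decreasing = TRUE)
  dirs <- dirs[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(length(vals))
  for (i in seq_along(vals)) {
    if (!any(keep)) {
      keep[i] <- TRUE
    } else {
      sep <- arc_angle(dirs[keep, , drop = FALSE], matrix(dirs[i, ], 1),
                       antipodal = TRUE)
      keep[i] <- min(sep) >= merge_angle
    }
  }
  list(dirs = dirs[keep, , drop = FALSE], vals = vals[keep])
}

#' Extracted peak set
#'
#' @param dirs k x 3 matrix of unit peak directions (any hemisphere).
#' @param odf_value raw ODF values at the peaks.
#' @param normalized_value min-max normalized values in `[0, 1]`.
#' @param merge_angle the pairwise-separation invariant (degrees).
#' @return a `data.frame` of class `peak_set` with columns `x, y, z,
#'   odf_value, normalized_value`, rows sorted by decreasing `odf_value`,
#'   directions mapped to the canonical hemisphere ([hemisphere()]), and
#'   pairwise antipodal separation `>= merge_angle` asserted.
#' @export
peak_set <- function(dirs, odf_value, normalized_value, merge_angle = 10) {
  dirs <- .as_direction_matrix(if (length(odf_value)) dirs else matrix(0, 0, 3))
  stopifnot(nrow(dirs) == length(odf_value),
            length(odf_value) == length(normalized_value))
  if (nrow(dirs) > 0) {
    dirs <- hemisphere(dirs)
    ord <- order(odf_value, decreasing = TRUE)
    dirs <- dirs[ord, , drop = FALSE]
    odf_value <- odf_value[ord]
    normalized_value <- normalized_value[ord]
    if (nrow(dirs) > 1) {
      for (i in 2:nrow(dirs)) {
        sep <- arc_angle(dirs[seq_len(i - 1), , drop = FALSE],
                         matrix(dirs[i, ], 1), antipodal = TRUE)
        if (min(sep) < merge_angle - 1e-9) {
          stop("peak_set: pairwise separation below merge_angle")
        }
      }
    }
  }
  structure(
    data.frame(x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
               odf_value = odf_value, normalized_value = normalized_value),
    class = c("peak_set", "data.frame"),
    merge_angle = merge_angle
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set with", nrow(x), "peak(s)\n")
  if (nrow(x)) print.data.frame(round(as.data.frame(x), 5))
  invisible(x)
}

#' Discard sub-threshold peaks
#'
#' Applies the two published filtering rules: peaks whose raw ODF value is
#' below the mean of the mesh samples are discarded, as are peaks whose
#' normalized value falls below the threshold `P` (guarding against small
#' noise-driven maxima). Order is preserved.
#'
#' @param peaks a [peak_set()].
#' @param samples the raw [spherical_samples()] the peaks came from.
#' @param p_threshold normalized-value floor (default 0.02).
#' @return the filtered `peak_set`.
#' @export
filter_peaks <- function(peaks, samples, p_threshold = 0.02) {
  stopifnot(inherits(peaks, "peak_set"), inherits(samples, "spherical_samples"))
  if (nrow(peaks) == 0L) return(peaks)
  keep <- peaks$odf_value >= mean(samples$values) &
    peaks$normalized_value >= p_threshold
  out <- peaks[keep, , drop = FALSE]
  attr(out, "merge_angle") <- attr(peaks, "merge_angle")
  class(out) <- c("peak_set", "data.frame")
  out
}

#' PSO-Powell hybrid extraction of all ODF maxima
#'
#' The full hybrid driver: up to `M` rounds of (i) a derandomized PSO stage
#' covering the sphere until its transfer tolerance falls below `P`,
#' (ii) modified Powell local maximization started from the particles'
#' personal bests (deduplicated at `start_dedup_angle`), and (iii) merging
#' of converged extrema into the extreme set with antipodal deduplication at
#' `merge_angle`, after which the swarm is reinitialized with a fresh seeded
#' draw. Rounds stop early when three consecutive rounds add nothing (unless
#' `early_exit = FALSE`). The accumulated extrema are then filtered by
#' [filter_peaks()] (mean-value rule plus normalized floor `P`).
#'
#' @param objective function from [objective_from()] (must carry its
#'   `samples` attribute). A degenerate (constant) objective yields an empty
#'   peak set with a warning.
#' @param params a [hybrid_params()].
#' @return a [peak_set()], sorted by decreasing ODF value, with attributes
#'   `rounds` (hybrid rounds executed) and `n_candidates` (extreme-set size
#'   before filtering).
#' @export
hybrid_find_peaks <- function(objective, params = hybrid_params()) {
  samples <- attr(objective, "samples")
  rng <- attr(objective, "range")
  if (is.null(samples) || is.null(rng)) {
    stop("hybrid_find_peaks: objective must come from objective_from()")
  }
  if (diff(rng) < 1e-12) {
    warning("degenerate objective: returning empty peak set")
    return(structure(peak_set(matrix(0, 0, 3), numeric(0), numeric(0),
                              params$merge_angle),
                     rounds = 0L, n_candidates = 0L))
  }
  ext_dirs <- matrix(0, 0, 3)
  ext_vals <- numeric(0)
  stale <- 0L
  rounds <- 0L
  for (m in seq_len(params$m_rounds)) {
    rounds <- m
    swarm <- pso_run(objective, params, seed = params$seed + m - 1L)
    starts <- .merge_extrema(sph_to_unit(swarm$pbest), swarm$pbest_val,
                             max(params$start_dedup_angle, 1e-9))
    cand_dirs <- matrix(0, 0, 3)
    cand_vals <- numeric(0)
    for (i in seq_along(starts$vals)) {
      res <- powell_search(objective, unit_to_sph(starts$dirs[i, ]), params)
      cand_dirs <- rbind(cand_dirs, sph_to_unit(res$x))
      cand_vals <- c(cand_vals, res$value)
    }
    prev_vals <- ext_vals
    merged <- .merge_extrema(rbind(ext_dirs, cand_dirs),
                             c(ext_vals, cand_vals), params$merge_angle)
    ext_dirs <- merged$dirs
    ext_vals <- merged$vals
    # staleness counts only extrema that would survive the final filtering
    # rules; sub-threshold ripples keep being collected but do not prolong
    # the round schedule
    retain <- function(v) {
      raw <- rng[1] + v * diff(rng)
      sort(v[raw >= mean(samples$values) & v >= params$p_threshold])
    }
    new_kept <- retain(ext_vals)
    old_kept <- retain(prev_vals)
    added <- length(new_kept) != length(old_kept) ||
      (length(new_kept) > 0 && max(abs(new_kept - old_kept)) > 1e-9)
    stale <- if (added) 0L else stale + 1L
    if (params$early_exit && stale >= 3L) break
  }
  raw_vals <- rng[1] + ext_vals * diff(rng)
  # a continuous optimum can top the discrete mesh samples slightly; the
  # normalized report is capped at 1
  peaks <- peak_set(ext_dirs, raw_vals, pmin(1, ext_vals), params$merge_angle)
  peaks <- filter_peaks(peaks, samples, params$p_threshold)
  attr(peaks, "rounds") <- rounds
  attr(peaks, "n_candidates") <- length(ext_vals)
  peaks
}
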