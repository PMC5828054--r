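#' Brute-force local maxima on a sphere mesh
#'
#' Independent grid oracle for peak extraction: returns every vertex whose
#' value strictly exceeds all of its 1-ring neighbors and exceeds
#' `relative_floor` times the maximum sample, antipodally deduplicated
#' (keeping the higher value). Plateaus (a vertex tying a neighbor) produce
#' no strict maximum; the lowest-index plateau vertex convention applies to
#' exact ties around distinct maxima, and the result carries a `plateau`
#' attribute when any tie was seen.
#'
#' @param samples a [spherical_samples()] object.
#' @param relative_floor fraction of the maximum value below which maxima
#'   are ignored (default 0).
#' @param dedup_angle antipodal arc (degrees) for deduplication (default 10).
#' @return a [peak_set()].
#' @export
grid_peaks <- function(samples, relative_floor = 0, dedup_angle = 10) {
  stopifnot(inherits(samples, "spherical_samples"))
  mesh <- samples$mesh
  v <- samples$values
  floorv <- relative_floor * max(v)
  plateau <- FALSE
  is_max <- vapply(seq_along(v), function(i) {
    nb <- v[mesh$adjacency[[i]]]
    if (any(nb == v[i])) plateau <<- TRUE
    v[i] > max(nb) && v[i] >= floorv
  }, TRUE)
  idx <- which(is_max)
  rng <- range(v)
  norm <- if (diff(rng) > 0) (v[idx] - rng[1]) / diff(rng) else rep(0, length(idx))
  merged <- .merge_extrema(mesh$vertices[idx, , drop = FALSE], norm, dedup_angle)
  raw <- rng[1] + merged$vals * diff(rng)
  out <- peak_set(merged$dirs, raw, merged$vals, dedup_angle)
  attr(out, "plateau") <- plateau
  out
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Optimal one-to-one matching of found peaks to ground-truth directions
#'
#' Exhaustive assignment (all injections of the smaller set into the larger)
#' minimizing the total antipodal arc; exact for up to 7 peaks a side, which
#' covers any realistic voxel. Matched pairs whose arc exceeds `max_arc`
#' are dropped (they count as a spurious or missed fiber).
#'
#' @param found a [peak_set()] or k x 3 matrix of unit directions.
#' @param truth m x 3 matrix of true unit directions.
#' @param max_arc matching gate in degrees (default 20).
#' @return `data.frame` with columns `found`, `truth` (indices) and
#'   `arc_deg`, one row per retained pair; attribute `total_arc` holds the
#'   assignment cost before gating.
#' @export
match_peaks <- function(found, truth, max_arc = 20) {
  F_ <- if (inherits(found, "peak_set")) {
    as.matrix(as.data.frame(found)[, c("x", "y", "z"), drop = FALSE])
  } else {
    .as_direction_matrix(found)
  }
  T_ <- .as_direction_matrix(truth)
  k <- nrow(F_)
  m <- nrow(T_)
  empty <- data.frame(found = integer(0), truth = integer(0),
                      arc_deg = numeric(0))
  if (k == 0L || m == 0L) {
    attr(empty, "total_arc") <- 0
    return(empty)
  }
  if (max(k, m) > 7L) stop("match_peaks: exhaustive matching capped at 7 peaks")
  cost <- matrix(0, k, m)
  for (i in seq_len(k)) cost[i, ] <- arc_angle(T_, matrix(F_[i, ], 1))
  # enumerate injections of the smaller side into the larger
  swap <- k > m
  if (swap) cost <- t(cost)
  a <- nrow(cost); b <- ncol(cost) # a <= b
  best <- NULL; best_cost <- Inf
  for (sub in utils::combn(b, a, simplify = FALSE)) {
    for (perm in .permutations(a)) {
      cols <- sub[perm]
      tot <- sum(cost[cbind(seq_len(a), cols)])
      if (tot < best_cost) {
        best_cost <- tot
        best <- cols
      }
    }
  }
  rows <- seq_len(a)
  pairs <- if (swap) {
    data.frame(found = best, truth = rows,
               arc_deg = cost[cbind(rows, best)])
  } else {
    data.frame(found = rows, truth = best,
               arc_deg = cost[cbind(rows, best)])
  }
  out <- pairs[pairs$arc_deg <= max_arc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_arc") <- best_cost
  out
}

#' Angular deviation report for one voxel
#'
#' For each matched found/truth pair, reports the azimuth deviation
#' (wrapped to the shortest difference after mapping the found direction to
#' the antipodal representative closest to the truth), the elevation
#' deviation under the same representative, and the antipodal arc.
#'
#' @param pairing output of [match_peaks()].
#' @param found a [peak_set()] or k x 3 direction matrix.
#' @param truth m x 3 matrix of true unit directions.
#' @param max_arc the success gate in degrees (default 20): success means
#'   the peak count equals the truth count and every matched arc is within
#'   the gate.
#' @return object of class `deviation_report`: list with `pairs` (data
#'   frame: `found`, `truth`, `azimuth_dev`, `elevation_dev`, `arc_deg`),
#'   counts `n_true`, `n_found`, `n_matched`, `success`, and summary
#'   `mean_arc` / `max_arc_found` over matched pairs.
#' @export
deviation_report <- function(pairing, found, truth, max_arc = 20) {
  F_ <- if (inherits(found, "peak_set")) {
    as.matrix(as.data.frame(found)[, c("x", "y", "z"), drop = FALSE])
  } else {
    .as_direction_matrix(found)
  }
  T_ <- .as_direction_matrix(truth)
  n <- nrow(pairing)
  az <- el <- arc <- numeric(n)
  for (r in seq_len(n)) {
    fv <- F_[pairing$found[r], ]
    tv <- T_[pairing$truth[r], ]
    if (sum(fv * tv) < 0) fv <- -fv # antipodal representative nearest truth
    fa <- unit_to_sph(fv)
    ta <- unit_to_sph(tv)
    az[r] <- abs(.wrap_diff(fa[1] - ta[1]))
    el[r] <- abs(fa[2] - ta[2])
    arc[r] <- arc_angle(fv, tv, antipodal = TRUE)
  }
  pairs <- data.frame(found = pairing$found, truth = pairing$truth,
                      azimuth_dev = az, elevation_dev = el, arc_deg = arc)
  success <- nrow(F_) == nrow(T_) && nrow(pairs) == nrow(T_) &&
    (nrow(pairs) == 0L || all(pairs$arc_deg <= max_arc))
  structure(list(
    pairs = pairs,
    n_true = nrow(T_), n_found = nrow(F_), n_matched = nrow(pairs),
    success = success,
    mean_arc = if (n) mean(arc) else NA_real_,
    max_arc_found = if (n) max(arc) else NA_real_
  ), class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("deviation_report: %d/%d matched (found %d), success = %s\n",
              x$n_matched, x$n_true, x$n_found, x$success))
  if (nrow(x$pairs)) print.data.frame(round(x$pairs, 4))
  invisible(x)
}

# true principal directions of a phantom, one row per compartment
phantom_truth <- function(phantom) {
  do.call(rbind, lapply(phantom$compartments, `[[`, "principal"))
}

#' Factorial crossing-fiber extraction experiment
#'
#' Runs the hybrid peak extractor over phantoms x reconstruction methods x
#' noise conditions x repetitions and tabulates angular deviations against
#' the known fiber directions. Reconstruction `"analytic"` evaluates the
#' exact mixture ODF; `"qbi"` and `"csa"` simulate DWI signals on `scheme`
#' (Rician noise at the requested SNR, seeded per repetition) and
#' reconstruct the ODF in spherical harmonics first.
#'
#' @param phantoms named list of [phantom()] objects (default
#'   [fiber_phantoms()]).
#' @param scheme an [acq_scheme()] for the signal-based reconstructions.
#' @param reconstructions subset of `c("analytic", "qbi", "csa")`.
#' @param snr numeric vector of SNR conditions; `Inf` means noiseless.
#' @param n_reps repetitions per cell (noise re-drawn each rep).
#' @param seed base seed; every cell derives its own deterministic seed.
#' @param mesh evaluation mesh (default `even_sphere(724)`).
#' @param params a [hybrid_params()]; the per-cell seed overrides its seed.
#' @param max_arc matching gate in degrees.
#' @param lmax,lambda_reg SH reconstruction settings.
#' @return `data.frame`, one row per matched fiber (plus one count-only row
#'   for cells with no matches), with columns `phantom`, `recon`, `snr`,
#'   `rep`, `truth_fiber`, `azimuth_dev`, `elevation_dev`, `arc_deg`,
#'   `n_true`, `n_found`, `n_matched`, `success`.
#' @export
run_experiment <- function(phantoms = fiber_phantoms(),
                           scheme = default_scheme(),
                           reconstructions = c("analytic", "qbi", "csa"),
                           snr = c(Inf, 20),
                           n_reps = 1, seed = 1,
                           mesh = even_sphere(724),
                           params = hybrid_params(),
                           max_arc = 20, lmax = 8, lambda_reg = 0.006) {
  reconstructions <- match.arg(reconstructions, several.ok = TRUE)
  rows <- list()
  cell <- 0L
  for (pi_ in seq_along(phantoms)) {
    pname <- names(phantoms)[pi_] %||% as.character(pi_)
    ph <- phantoms[[pi_]]
    truth <- phantom_truth(ph)
    for (rc in reconstructions) {
      for (sn in snr) {
        if (rc == "analytic" && is.finite(sn)) next # noise enters via signals
        for (rep_ in seq_len(n_reps)) {
          cell <- cell + 1L
          cell_seed <- seed + 7919L * (cell - 1L)
          obj <- tryCatch({
            if (rc == "analytic") {
              objective_from(ph, mesh)
            } else {
              sig <- simulate_signal(ph, scheme)
              if (is.finite(sn)) {
                sig <- add_rician(sig, ph$s0, sn, seed = cell_seed)
              }
              cs <- if (rc == "qbi") {
                qbi_odf(sig, scheme, lmax, lambda_reg)
              } else {
                csa_odf(sig, scheme, lmax, lambda_reg)
              }
              objective_from(cs, mesh)
            }
          }, error = function(e) NULL)
          p2 <- params
          p2$seed <- cell_seed
          peaks <- if (is.null(obj)) {
            peak_set(matrix(0, 0, 3), numeric(0), numeric(0))
          } else {
            hybrid_find_peaks(obj, p2)
          }
          pairing <- match_peaks(peaks, truth, max_arc)
          rep_report <- deviation_report(pairing, peaks, truth, max_arc)
          base <- data.frame(phantom = pname, recon = rc, snr = sn, rep = rep_,
                             n_true = rep_report$n_true,
                             n_found = rep_report$n_found,
                             n_matched = rep_report$n_matched,
                             success = rep_report$success)
          if (nrow(rep_report$pairs)) {
            rows[[length(rows) + 1L]] <- cbind(
              base[rep(1L, nrow(rep_report$pairs)), , drop = FALSE],
              truth_fiber = rep_report$pairs$truth,
              azimuth_dev = rep_report$pairs$azimuth_dev,
              elevation_dev = rep_report$pairs$elevation_dev,
              arc_deg = rep_report$pairs$arc_deg
            )
          } else {
            rows[[length(rows) + 1L]] <- cbind(
              base, truth_fiber = NA_integer_, azimuth_dev = NA_real_,
              elevation_dev = NA_real_, arc_deg = NA_real_
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
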