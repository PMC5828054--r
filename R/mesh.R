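#' Quasi-uniform directions by the spherical Fibonacci lattice
#'
#' Deterministic construction: point i (i = 0..n-1) has
#' `z = 1 - (2i + 1)/n` and azimuth `2*pi*i/golden_ratio`.
#'
#' @param n number of directions, `n >= 1`.
#' @return n x 3 matrix of unit row vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  golden <- (1 + sqrt(5)) / 2
  theta <- (2 * pi * i / golden) %% (2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# Incremental 3-D convex hull of points on (or near) the unit sphere.
# Returns an f x 3 integer matrix of triangles with outward orientation.
# For points on a sphere the hull is exactly the Delaunay triangulation of
# the sphere, so every input point must end up a hull vertex.
.convex_hull_sphere <- function(V, tol = 1e-12) {
  n <- nrow(V)
  stopifnot(n >= 4)

  # initial tetrahedron from spread-out extreme points
  i1 <- which.min(V[, 3])
  d1 <- rowSums(sweep(V, 2, V[i1, ])^2)
  i2 <- which.max(d1)
  e1 <- V[i2, ] - V[i1, ]
  w <- sweep(V, 2, V[i1, ])
  proj <- as.vector(w %*% e1) / sum(e1^2)
  i3 <- which.max(rowSums((w - outer(proj, e1))^2))
  nrm0 <- .cross3(V[i2, ] - V[i1, ], V[i3, ] - V[i1, ])
  i4 <- which.max(abs(as.vector(w %*% nrm0)))
  init <- c(i1, i2, i3, i4)
  if (length(unique(init)) < 4L) stop("degenerate point set: no tetrahedron")
  interior <- colMeans(V[init, ])

  cap <- max(64L, 8L * n)
  faces <- matrix(0L, cap, 3)
  normals <- matrix(0, cap, 3)
  offs <- numeric(cap)
  alive <- logical(cap)
  nf <- 0L

  add_face <- function(a, b, c) {
    nrm <- .cross3(V[b, ] - V[a, ], V[c, ] - V[a, ])
    len <- sqrt(sum(nrm^2))
    if (len < tol) stop("degenerate (collinear) hull face")
    nrm <- nrm / len
    if (sum(nrm * (V[a, ] - interior)) < 0) {
      tmp <- b; b <- c; c <- tmp
      nrm <- -nrm
    }
    nf <<- nf + 1L
    if (nf > nrow(faces)) {
      faces <<- rbind(faces, matrix(0L, cap, 3))
      normals <<- rbind(normals, matrix(0, cap, 3))
      offs <<- c(offs, numeric(cap))
      alive <<- c(alive, logical(cap))
    }
    faces[nf, ] <<- c(a, b, c)
    normals[nf, ] <<- nrm
    offs[nf] <<- sum(nrm * V[a, ])
    alive[nf] <<- TRUE
  }

  combos <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (cm in combos) add_face(init[cm[1]], init[cm[2]], init[cm[3]])

  eps <- 1e-10
  for (p in setdiff(seq_len(n), init)) {
    vp <- V[p, ]
    act <- which(alive[seq_len(nf)])
    vis <- act[as.vector(normals[act, , drop = FALSE] %*% vp) > offs[act] + eps]
    if (length(vis) == 0L) {
      stop("point ", p, " fell inside the hull; directions are not in general ",
           "position on the sphere")
    }
    ed <- rbind(faces[vis, c(1, 2), drop = FALSE],
                faces[vis, c(2, 3), drop = FALSE],
                faces[vis, c(3, 1), drop = FALSE])
    key <- ed[, 1] * (n + 1) + ed[, 2]
    rkey <- ed[, 2] * (n + 1) + ed[, 1]
    horizon <- ed[!(rkey %in% key), , drop = FALSE]
    alive[vis] <- FALSE
    for (j in seq_len(nrow(horizon))) {
      add_face(horizon[j, 1], horizon[j, 2], p)
    }
  }

  faces[seq_len(nf), , drop = FALSE][alive[seq_len(nf)], , drop = FALSE]
}

# Solid angles of the spherical triangles of a mesh (Van Oosterom-Strackee).
.triangle_solid_angles <- function(V, tri) {
  A <- V[tri[, 1], , drop = FALSE]
  B <- V[tri[, 2], , drop = FALSE]
  C <- V[tri[, 3], , drop = FALSE]
  num <- abs(A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
             A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
             A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1]))
  den <- 1 + rowSums(A * B) + rowSums(B * C) + rowSums(C * A)
  2 * atan2(num, den)
}

.mesh_cache <- new.env(parent = emptyenv())

#' Triangulated quasi-uniform sphere mesh
#'
#' Builds `n` deterministic quasi-uniform directions (spherical Fibonacci
#' lattice, see [fibonacci_directions()]) and triangulates them by their 3-D
#' convex hull, which for points on a sphere is the spherical Delaunay
#' triangulation. The mesh is a closed surface: with `n` vertices in general
#' position it has `2n - 4` triangles and satisfies Euler's formula
#' `V - E + F = 2`.
#'
#' @param n number of vertices (default 724, a typical evaluation set size
#'   for HARDI ODF fields); must be at least 4.
#' @return an object of class `sphere_mesh`: a list with `vertices` (n x 3),
#'   `triangles` (f x 3 integer), `adjacency` (list of 1-ring neighbor index
#'   vectors), `weights` (per-vertex quadrature weights summing to `4*pi`),
#'   and precomputed barycentric solve matrices used by [sph_interpolate()].
#' @export
even_sphere <- function(n = 724) {
  if (n < 4) stop("even_sphere: n must be >= 4 (no closed triangulation)")
  key <- as.character(n)
  if (!is.null(.mesh_cache[[key]])) return(.mesh_cache[[key]])
  V <- fibonacci_directions(n)
  tri <- .convex_hull_sphere(V)

  # 1-ring adjacency
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  adj <- split(edges[, 2], edges[, 1])
  adjacency <- lapply(seq_len(n), function(i) {
    sort(unique(adj[[as.character(i)]]))
  })

  # per-vertex quadrature weights: a third of each incident spherical
  # triangle area, then corrected by least squares so that the rule
  # integrates spherical harmonics exactly up to a mesh-dependent order
  # (the raw vertex rule converges too slowly for sharply peaked ODFs)
  areas <- .triangle_solid_angles(V, tri)
  wts <- numeric(n)
  for (k in 1:3) {
    acc <- rowsum(areas / 3, tri[, k])
    idx <- as.integer(rownames(acc))
    wts[idx] <- wts[idx] + acc[, 1]
  }
  lmax_w <- 0
  while (lmax_w + 2 <= 16 && sh_ncoef(lmax_w + 2) <= n / 4) {
    lmax_w <- lmax_w + 2
  }
  if (lmax_w >= 2) {
    B <- sh_basis(lmax_w, V)
    e <- numeric(ncol(B))
    e[1] <- sqrt(4 * pi) # the only basis function with nonzero integral
    wts <- wts + as.vector(B %*% solve(crossprod(B), e - crossprod(B, wts)))
  }

  # barycentric solve rows: w = solve(t(cbind(A,B,C))) applied to a query
  f <- nrow(tri)
  R1 <- matrix(0, f, 3); R2 <- matrix(0, f, 3); R3 <- matrix(0, f, 3)
  for (t in seq_len(f)) {
    M <- t(V[tri[t, ], ]) # columns are the three vertices
    Minv <- solve(M)
    R1[t, ] <- Minv[1, ]; R2[t, ] <- Minv[2, ]; R3[t, ] <- Minv[3, ]
  }

  mesh <- structure(
    list(vertices = V, triangles = tri, adjacency = adjacency,
         weights = wts, bary = list(R1, R2, R3), n = n),
    class = "sphere_mesh"
  )
  .mesh_cache[[key]] <- mesh
  mesh
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("sphere_mesh:", x$n, "vertices,", nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Scalar samples on a sphere mesh
#'
#' Container pairing a [even_sphere()] mesh with one nonnegative value per
#' vertex (typically an ODF evaluated on the mesh directions).
#'
#' @param mesh a `sphere_mesh`.
#' @param values numeric vector, one value per vertex, all finite and `>= 0`.
#' @return an object of class `spherical_samples`.
#' @export
spherical_samples <- function(mesh, values) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  values <- as.numeric(values)
  if (length(values) != nrow(mesh$vertices)) {
    stop("spherical_samples: need one value per mesh vertex")
  }
  if (any(!is.finite(values))) stop("spherical_samples: non-finite values")
  if (any(values < 0)) stop("spherical_samples: negative values")
  structure(list(mesh = mesh, values = values), class = "spherical_samples")
}

#' @export
print.spherical_samples <- function(x, ...) {
  cat("spherical_samples on", x$mesh$n, "vertices; range [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Quadrature integral of sampled values over the sphere
#'
#' @param samples a [spherical_samples()] object.
#' @return scalar, `sum(weights * values)`.
#' @export
sphere_integral <- function(samples) {
  stopifnot(inherits(samples, "spherical_samples"))
  sum(samples$mesh$weights * samples$values)
}

# index of the triangle whose central-projection cone encloses the query
.enclosing_triangle <- function(mesh, q, tol = 1e-12) {
  w1 <- as.vector(mesh$bary[[1]] %*% q)
  w2 <- as.vector(mesh$bary[[2]] %*% q)
  w3 <- as.vector(mesh$bary[[3]] %*% q)
  ok <- which(w1 >= -tol & w2 >= -tol & w3 >= -tol & (w1 + w2 + w3) > 0)
  if (length(ok) == 0L) stop("no enclosing triangle found (degenerate mesh?)")
  t <- ok[1L]
  list(triangle = t, w = c(w1[t], w2[t], w3[t]))
}

#' Interpolate sampled spherical values at arbitrary directions
#'
#' Locates the mesh triangle whose central-projection cone encloses the
#' query direction. `mode = "nearest"` returns the value at the nearest of
#' the three triangle vertices; `mode = "barycentric"` returns the
#' barycentric-weighted average of the three vertex values (exact for
#' functions linear in Cartesian coordinates on the triangle's plane
#' projection).
#'
#' @param samples a [spherical_samples()] object.
#' @param query unit vector `c(x, y, z)` or n x 3 matrix of unit rows.
#' @param mode `"nearest"` or `"barycentric"`.
#' @return interpolated value(s).
#' @export
sph_interpolate <- function(samples, query, mode = c("barycentric", "nearest")) {
  stopifnot(inherits(samples, "spherical_samples"))
  mode <- match.arg(mode)
  Q <- .as_direction_matrix(query)
  mesh <- samples$mesh
  out <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    enc <- .enclosing_triangle(mesh, Q[i, ])
    vid <- mesh$triangles[enc$triangle, ]
    if (mode == "nearest") {
      dots <- as.vector(mesh$vertices[vid, , drop = FALSE] %*% Q[i, ])
      out[i] <- samples$values[vid[which.max(dots)]]
    } else {
      w <- enc$w / sum(enc$w)
      out[i] <- sum(w * samples$values[vid])
    }
  }
  if (is.null(dim(query)) && length(query) == 3L) out[1L] else out
}
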