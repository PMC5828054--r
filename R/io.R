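#' Read an FSL-dialect gradient table
#'
#' `bval` holds one whitespace-separated row of b-values; `bvec` holds three
#' rows (x, y, z components), one column per volume. Nonzero gradient
#' columns whose norm is off unit by more than 1e-3 are renormalized with a
#' warning.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return a `gradient_table`: list with `bvals` (vector) and `bvecs`
#'   (n x 3 matrix, rows = volumes).
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L) {
    stop("bvec file must have exactly 3 rows (x, y, z), found ", length(lines))
  }
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v))) stop("non-numeric entry in bvec row")
    v
  })
  lens <- vapply(rows, length, 0L)
  if (length(unique(c(lens, length(bvals)))) != 1L) {
    stop("gradient table length mismatch: bvals has ", length(bvals),
         " columns, bvec rows have ", paste(lens, collapse = "/"))
  }
  bvecs <- cbind(rows[[1]], rows[[2]], rows[[3]])
  nrm <- sqrt(rowSums(bvecs^2))
  fix <- which(bvals > 0 & abs(nrm - 1) > 1e-3)
  if (length(fix)) {
    warning("renormalized ", length(fix), " bvec column(s) with non-unit norm")
    bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' Write an FSL-dialect gradient table
#'
#' @param gtab a `gradient_table` or [acq_scheme()].
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Convert a gradient table to an acquisition scheme
#' @param gtab a `gradient_table`.
#' @return an [acq_scheme()].
#' @export
as_acq_scheme <- function(gtab) acq_scheme(gtab$bvals, gtab$bvecs)

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving the data array and affine (sform)
#' within float precision; the 4th axis carries channel semantics (DWI
#' volumes, SH coefficients, or flattened peaks).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: list with `data` (array) and `affine` (4 x 4).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = structure(RNifti::xform(img), class = NULL))
}

#' @rdname read_volume
#' @param data numeric array (3-D or 4-D).
#' @param affine 4 x 4 voxel-to-world matrix (default identity spacing).
#' @export
write_volume <- function(data, path, affine = diag(4)) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write direction lists
#'
#' Plain whitespace-delimited text, one unit vector per row (`x y z`).
#'
#' @param path file path.
#' @return n x 3 matrix of unit rows.
#' @export
read_directions <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-3)) stop("non-unit direction in ", path)
  m / nrm
}

#' @rdname read_directions
#' @param dirs n x 3 matrix of unit directions.
#' @export
write_directions <- function(dirs, path) {
  utils::write.table(format(dirs, digits = 15), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write phantom configurations
#'
#' YAML schema: top-level `s0` plus a `compartments` list, each entry with
#' `fraction`, `theta`, `phi` (radians) and `lambda` (three eigenvalues,
#' mm^2/s).
#'
#' @param path file path.
#' @return a [phantom()].
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  comps <- lapply(cfg$compartments, function(cp) {
    tensor_compartment(cp$fraction, c(cp$theta, cp$phi),
                       as.numeric(cp$lambda))
  })
  phantom(comps, s0 = cfg$s0 %||% 1)
}

#' @rdname read_phantom_config
#' @param ph a [phantom()].
#' @export
write_phantom_config <- function(ph, path) {
  cfg <- list(
    s0 = ph$s0,
    compartments = lapply(ph$compartments, function(cp) {
      list(fraction = cp$fraction, theta = cp$angles[[1]],
           phi = cp$angles[[2]], lambda = as.numeric(cp$lambda))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a peak table as CSV
#'
#' One row per peak: `voxel`, `rank`, `x`, `y`, `z`, `odf_value`,
#' `normalized_value`.
#'
#' @param peaks a [peak_set()] or list of them (one per voxel).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_peaks_table <- function(peaks, path) {
  if (inherits(peaks, "peak_set")) peaks <- list(peaks)
  rows <- lapply(seq_along(peaks), function(v) {
    pk <- as.data.frame(peaks[[v]])
    if (nrow(pk) == 0L) return(NULL)
    cbind(voxel = v, rank = seq_len(nrow(pk)), pk)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(tab)) {
    tab <- data.frame(voxel = integer(0), rank = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), odf_value = numeric(0),
                      normalized_value = numeric(0))
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Flatten per-voxel peaks into a 4-D array
#'
#' Channel layout `3 * K`: peaks are stacked as consecutive xyz triples in
#' rank order, zero-padded up to `K = max_peaks`.
#'
#' @param peaks_list list of [peak_set()] objects, one per voxel (in array
#'   order).
#' @param dim3 integer 3-vector of spatial dimensions.
#' @param max_peaks channel capacity K (default 5).
#' @return 4-D array `dim3 x (3 * max_peaks)`.
#' @export
peaks_to_array <- function(peaks_list, dim3, max_peaks = 5) {
  stopifnot(length(peaks_list) == prod(dim3))
  arr <- array(0, c(dim3, 3 * max_peaks))
  flat <- matrix(0, prod(dim3), 3 * max_peaks)
  for (v in seq_along(peaks_list)) {
    pk <- as.data.frame(peaks_list[[v]])
    k <- min(nrow(pk), max_peaks)
    if (k > 0) {
      flat[v, seq_len(3 * k)] <- as.vector(t(as.matrix(pk[seq_len(k),
                                                          c("x", "y", "z")])))
    }
  }
  arr[] <- flat
  arr
}
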