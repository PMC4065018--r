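#' Construct a 3-D volume map
#'
#' A `volume_map` is the basic spatial container used throughout the package:
#' a 3-D lattice of real values together with its voxel geometry. Out-of-brain
#' voxels carry the sentinel `NaN`.
#'
#' @param values Numeric 3-D array (`nx x ny x nz`).
#' @param voxel_size_mm Positive numeric triple, edge length of a voxel in mm.
#' @param origin Numeric triple, world coordinates (mm) of voxel `(1,1,1)`.
#' @return An object of class `volume_map` with fields `values`,
#'   `voxel_size_mm` and `origin`.
#' @examples
#' v <- volume_map(array(rnorm(8^3), c(8, 8, 8)))
#' dim(v$values)
#' @export
volume_map <- function(values, voxel_size_mm = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    amy_stop("`values` must be a 3-D array", "amynet_dim_error")
  if (any(dim(values) < 1L))
    amy_stop("all dimensions must be >= 1", "amynet_dim_error")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    amy_stop("`voxel_size_mm` must be strictly positive", "amynet_domain_error")
  origin <- rep_len(as.numeric(origin), 3L)
  storage.mode(values) <- "double"
  bad <- is.infinite(values)
  if (any(bad, na.rm = TRUE))
    amy_stop("non-sentinel values must be finite (use NaN as sentinel)",
             "amynet_domain_error")
  structure(list(values = values,
                 voxel_size_mm = voxel_size_mm,
                 origin = origin),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  n_ok <- sum(is.finite(x$values))
  cat(sprintf("<volume_map> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  finite voxels: %d / %d; origin (%.1f, %.1f, %.1f) mm\n",
              n_ok, prod(d), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_volume_map <- function(x) inherits(x, "volume_map")

#' Read a single 3-D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding one 3-D image.
#' @return A [volume_map]. Voxel sizes come from the NIfTI pixdim, the origin
#'   from the stored affine translation.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    amy_stop(sprintf("file not found: %s", path), "amynet_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    amy_stop(sprintf("cannot read volume '%s': %s",
                                     path, conditionMessage(e)),
                             "amynet_io_error"))
  d <- dim(img)
  if (length(d) != 3L)
    amy_stop(sprintf("expected a 3-D volume, got %d-D: %s", length(d), path),
             "amynet_dim_error")
  vals <- as.array(img)
  attributes(vals) <- list(dim = d)
  aff <- RNifti::xform(img)
  volume_map(vals,
             voxel_size_mm = RNifti::pixdim(img)[1:3],
             origin = as.numeric(aff[1:3, 4]))
}

#' Write a volume map to a NIfTI-1 file
#'
#' Values are stored as 64-bit doubles so that [read_volume()] recovers them
#' bitwise, sentinel `NaN` included.
#'
#' @param map A [volume_map].
#' @param path Destination file path (`.nii` or `.nii.gz`); the parent
#'   directory must already exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path) {
  stopifnot(is_volume_map(map))
  if (!dir.exists(dirname(path)))
    amy_stop(sprintf("directory does not exist: %s", dirname(path)),
             "amynet_io_error")
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size_mm
  aff <- diag(c(map$voxel_size_mm, 1))
  aff[1:3, 4] <- map$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e)
             amy_stop(sprintf("cannot write volume '%s': %s",
                              path, conditionMessage(e)),
                      "amynet_io_error"))
  invisible(path)
}

#' Integer lattice offsets covering a sphere
#'
#' Enumerates every integer voxel offset whose world-space distance to the
#' centre is at most `radius_mm`, the neighbourhood stencil of the searchlight.
#' The closed ball is used (offsets at exactly the radius are kept) and the
#' central offset `(0,0,0)` is always present. At the default 2-mm isotropic
#' lattice a 6-mm radius gives 123 offsets, the "~100 voxels" scale of a
#' searchlight neighbourhood.
#'
#' @param radius_mm Sphere radius in mm (>= 0).
#' @param voxel_size_mm Positive numeric triple.
#' @return An object of class `sphere_offsets`: list with `radius_mm`,
#'   `voxel_size_mm` and `offsets`, an `n x 3` integer matrix.
#' @examples
#' nrow(sphere_offsets(6, c(2, 2, 2))$offsets)  # 123
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm = c(2, 2, 2)) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0) || any(!is.finite(voxel_size_mm)))
    amy_stop("voxel sizes must be strictly positive", "amynet_domain_error")
  if (!is.finite(radius_mm) || radius_mm < 0)
    amy_stop("`radius_mm` must be >= 0", "amynet_domain_error")
  half <- floor(radius_mm / voxel_size_mm + 1e-9)
  g <- expand.grid(i = -half[1]:half[1],
                   j = -half[2]:half[2],
                   k = -half[3]:half[3])
  d2 <- (g$i * voxel_size_mm[1])^2 + (g$j * voxel_size_mm[2])^2 +
    (g$k * voxel_size_mm[3])^2
  keep <- d2 <= radius_mm^2 * (1 + 1e-12)
  offs <- as.matrix(g[keep, , drop = FALSE])
  dimnames(offs) <- NULL
  storage.mode(offs) <- "integer"
  structure(list(radius_mm = radius_mm,
                 voxel_size_mm = voxel_size_mm,
                 offsets = offs),
            class = "sphere_offsets")
}

# 1-D Gaussian smoothing matrix with half-sample symmetric (reflect) boundary.
# Rows and columns both sum to 1, so constants and total mass are preserved.
smoothing_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  h <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(-h:h, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (t in seq_along(w)) {
    off <- t - h - 1L
    j <- seq_len(n) + off
    # reflect about the half-sample boundary: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
    repeat {
      below <- j < 1L
      above <- j > n
      if (!any(below) && !any(above)) break
      j[below] <- 1L - j[below]
      j[above] <- 2L * n + 1L - j[above]
    }
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[t]
  }
  K
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian smoothing of a volume map
#'
#' Separable Gaussian filter specified by its full width at half maximum in
#' mm, converted per axis to lattice units via the voxel size (anisotropic
#' voxels are handled per axis). Boundaries are treated by half-sample
#' reflection, which preserves both constants and the total sum. Sentinel
#' (`NaN`) voxels are excluded by normalized convolution and restored in the
#' output.
#'
#' @param map A [volume_map].
#' @param fwhm_mm Kernel FWHM in mm; `0` returns the input unchanged.
#' @return A smoothed [volume_map] on the same grid.
#' @export
smooth_volume <- function(map, fwhm_mm) {
  stopifnot(is_volume_map(map))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    amy_stop("`fwhm_mm` must be >= 0", "amynet_domain_error")
  if (fwhm_mm == 0) return(map)
  x <- map$values
  ok <- is.finite(x)
  all_ok <- all(ok)
  x0 <- x
  if (!all_ok) x0[!ok] <- 0
  sig <- fwhm_to_sigma(fwhm_mm) / map$voxel_size_mm
  sm <- smooth_array3d(x0, sig)
  if (!all_ok) {
    m <- smooth_array3d(array(as.numeric(ok), dim(x)), sig)
    sm <- sm / m
    sm[!ok] <- NaN
  }
  volume_map(sm, map$voxel_size_mm, map$origin)
}

# apply 1-D smoothing along each axis of a 3-D array (no NA handling)
smooth_array3d <- function(x, sigma_vox) {
  d <- dim(x)
  sigma_vox <- rep_len(sigma_vox, 3L)
  # axis 1
  if (sigma_vox[1] > 0) {
    K <- smoothing_matrix_1d(d[1], sigma_vox[1])
    x <- array(K %*% matrix(x, d[1]), d)
  }
  # axis 2
  if (sigma_vox[2] > 0) {
    K <- smoothing_matrix_1d(d[2], sigma_vox[2])
    x <- aperm(array(K %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  # axis 3
  if (sigma_vox[3] > 0) {
    K <- smoothing_matrix_1d(d[3], sigma_vox[3])
    x <- aperm(array(K %*% matrix(aperm(x, c(3, 1, 2)), d[3]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  x
}

# classed error helper used across the package
amy_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "amynet_error")))
}
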