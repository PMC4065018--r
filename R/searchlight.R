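#' Gram-Schmidt decorrelation of one vector with respect to another
#'
#' Demeans both vectors and removes from `a` its projection onto `b`:
#' `a' = a - (<a,b> / <b,b>) b`. The returned vector has exactly zero Pearson
#' correlation with `b` (to numerical precision), which is the contract the
#' local searchlight analysis relies on: whatever whole-network coupling
#' exists between PiB uptake and connectivity is removed before neighbourhood
#' correlations are measured, so r_LOCAL reflects purely local structure.
#'
#' @param a Numeric vector to be decorrelated.
#' @param b Reference vector (nonzero variance).
#' @return Residual vector `a'`, same length, mean zero.
#' @examples
#' a <- c(1, 2, 3, 5); b <- c(1, 1, 2, 2)
#' cor(gram_schmidt(a, b), b)  # 0 to machine precision
#' @export
gram_schmidt <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    amy_stop("`a` and `b` must have equal length >= 3", "amynet_domain_error")
  b0 <- b - mean(b)
  if (sum(b0^2) == 0)
    amy_stop("reference vector has zero variance", "amynet_degeneracy_error")
  a0 <- a - mean(a)
  a0 - (sum(a0 * b0) / sum(b0^2)) * b0
}

#' Orthogonalized PiB / connectivity pair for one network voxel set
#'
#' Prepares the vector pair entering the searchlight. `direction`
#' `"pib_wrt_ifc"` decorrelates PiB uptake with respect to (log) connectivity;
#' `"ifc_wrt_pib"` decorrelates connectivity with respect to PiB. The
#' unmodified member of the pair is demeaned only.
#'
#' @param nvs A `network_voxel_set`.
#' @param direction Which vector is orthogonalized.
#' @param log_transform Log-transform connectivity first (default), matching
#'   the whole-network r_GLOBAL convention.
#' @return Object of class `orthogonalized_set` carrying the base voxel set
#'   and the aligned vector pair `x` (connectivity side) and `y` (PiB side).
#' @export
orthogonalize_set <- function(nvs,
                              direction = c("pib_wrt_ifc", "ifc_wrt_pib"),
                              log_transform = TRUE) {
  direction <- match.arg(direction)
  ifc <- if (log_transform) log_transform_ifc(nvs$ifc_values) else nvs$ifc_values
  pib <- nvs$pib_values
  if (direction == "pib_wrt_ifc") {
    y <- gram_schmidt(pib, ifc)
    x <- ifc - mean(ifc)
  } else {
    x <- gram_schmidt(ifc, pib)
    y <- pib - mean(pib)
  }
  structure(list(base = nvs, x = x, y = y, direction = direction),
            class = "orthogonalized_set")
}

# linear indices of neighbours for each centre under each offset; NA when the
# neighbour falls outside the lattice
neighbor_index_matrix <- function(idx, offsets, dims) {
  n <- nrow(idx)
  m <- nrow(offsets)
  out <- matrix(NA_integer_, n, m)
  for (t in seq_len(m)) {
    ni <- idx[, 1] + offsets[t, 1]
    nj <- idx[, 2] + offsets[t, 2]
    nk <- idx[, 3] + offsets[t, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
      nk >= 1L & nk <= dims[3]
    out[ok, t] <- ni[ok] + (nj[ok] - 1L) * dims[1] +
      (nk[ok] - 1L) * dims[1] * dims[2]
  }
  out
}

#' Searchlight map of local correlations r_LOCAL
#'
#' Steps through every network voxel; its neighbourhood is the set of
#' *network* voxels (same subject, same network, out-of-network voxels inside
#' the sphere are ignored) reachable by the sphere offsets, the central voxel
#' included. Voxels with fewer than `min_neighbors` neighbours are skipped to
#' avoid unreliable boundary estimates. Otherwise the Pearson correlation
#' between the orthogonalized pair over the neighbourhood is Fisher
#' transformed and recorded at the centre. Neighbourhoods with zero variance
#' in either vector are skipped and tallied, not an error.
#'
#' @param oset An [orthogonalize_set()] result.
#' @param offsets A [sphere_offsets] stencil (6-mm radius by convention).
#' @param min_neighbors Minimum neighbourhood cardinality (default 25).
#' @return Object of class `searchlight_map`: `r_local` ([volume_map] of
#'   Fisher-z values, sentinel `NaN`), `valid_mask`, `n_neighbors` (counts at
#'   network voxels), `radius_mm`, `min_neighbors`, `n_skipped_small`,
#'   `n_skipped_variance`, plus subject/network ids.
#' @export
searchlight_rlocal <- function(oset, offsets, min_neighbors = 25L) {
  stopifnot(inherits(oset, "orthogonalized_set"),
            inherits(offsets, "sphere_offsets"))
  nvs <- oset$base
  d <- nvs$dim
  A <- array(NaN, d); A[nvs$voxel_indices] <- oset$x
  B <- array(NaN, d); B[nvs$voxel_indices] <- oset$y
  nbr <- neighbor_index_matrix(nvs$voxel_indices, offsets$offsets, d)
  Am <- matrix(A[nbr], nrow(nbr))
  Bm <- matrix(B[nbr], nrow(nbr))
  fin <- is.finite(Am)            # same pattern for Am and Bm by construction
  n <- rowSums(fin)
  Am[!fin] <- 0; Bm[!fin] <- 0
  sa <- rowSums(Am);  sb <- rowSums(Bm)
  saa <- rowSums(Am^2); sbb <- rowSums(Bm^2); sab <- rowSums(Am * Bm)
  va <- n * saa - sa^2
  vb <- n * sbb - sb^2
  big_enough <- n >= min_neighbors
  # relative tolerance guards against catastrophic cancellation on flat patches
  has_var <- va > 1e-12 * pmax(saa * n, 1) & vb > 1e-12 * pmax(sbb * n, 1)
  valid <- big_enough & has_var
  r <- rep(NaN, length(n))
  r[valid] <- (n[valid] * sab[valid] - sa[valid] * sb[valid]) /
    sqrt(va[valid] * vb[valid])
  zmap <- array(NaN, d)
  zmap[nvs$voxel_indices[valid, , drop = FALSE]] <- fisher_z(r[valid])
  vmask <- array(0, d)
  vmask[nvs$voxel_indices[valid, , drop = FALSE]] <- 1
  nmap <- array(NaN, d)
  nmap[nvs$voxel_indices] <- n
  structure(list(subject_id = nvs$subject_id,
                 network_name = nvs$network_name,
                 r_local = volume_map(zmap, nvs$voxel_size_mm),
                 valid_mask = volume_map(vmask, nvs$voxel_size_mm),
                 n_neighbors = volume_map(nmap, nvs$voxel_size_mm),
                 radius_mm = offsets$radius_mm,
                 min_neighbors = min_neighbors,
                 n_skipped_small = sum(!big_enough),
                 n_skipped_variance = sum(big_enough & !has_var)),
            class = "searchlight_map")
}

#' Bidirectionally averaged searchlight map
#'
#' Orthogonalization is asymmetric, so the searchlight is run twice - PiB
#' decorrelated with respect to connectivity, then connectivity with respect
#' to PiB - and the two Fisher-z maps are averaged voxel-wise. Only voxels
#' recorded in both directions are kept.
#'
#' @param nvs A `network_voxel_set`.
#' @param offsets A [sphere_offsets] stencil.
#' @param min_neighbors Minimum neighbourhood cardinality.
#' @param log_transform Log-transform connectivity (default).
#' @return A `searchlight_map` whose `r_local` holds the mean Fisher-z of the
#'   two directions and whose `valid_mask` is the intersection of theirs.
#' @export
symmetric_rlocal <- function(nvs, offsets, min_neighbors = 25L,
                             log_transform = TRUE) {
  m1 <- searchlight_rlocal(orthogonalize_set(nvs, "pib_wrt_ifc", log_transform),
                           offsets, min_neighbors)
  m2 <- searchlight_rlocal(orthogonalize_set(nvs, "ifc_wrt_pib", log_transform),
                           offsets, min_neighbors)
  both <- m1$valid_mask$values == 1 & m2$valid_mask$values == 1
  z <- array(NaN, dim(both))
  z[both] <- (m1$r_local$values[both] + m2$r_local$values[both]) / 2
  vmask <- array(0, dim(both)); vmask[both] <- 1
  out <- m1
  out$r_local <- volume_map(z, nvs$voxel_size_mm)
  out$valid_mask <- volume_map(vmask, nvs$voxel_size_mm)
  out$n_skipped_small <- max(m1$n_skipped_small, m2$n_skipped_small)
  out$n_skipped_variance <- max(m1$n_skipped_variance, m2$n_skipped_variance)
  out
}

#' Median r_LOCAL over recorded voxels
#'
#' @param map A `searchlight_map`.
#' @return Median Fisher-z value across voxels in the valid mask.
#' @export
median_rlocal <- function(map) {
  v <- map$r_local$values[map$valid_mask$values == 1]
  if (length(v) == 0)
    amy_stop(sprintf("subject %s, network %s: no recorded searchlight voxels",
                     map$subject_id, map$network_name),
             "amynet_degenerate_network_error")
  stats::median(v)
}
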