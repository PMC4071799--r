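#' Label connected cavity components
#'
#' Partitions the set points of a cavity field into maximal 26-connected
#' components: two points belong to the same cavity when every grid index
#' coordinate differs by at most one (faces, edges and corners all connect).
#' Implemented iteratively with an explicit stack; recursion depth is
#' unbounded on large cavities.
#'
#' @param cavity Logical 3D cavity field.
#' @param grid Matching `grid_spec`.
#' @return List of integer matrices (n x 3, 1-based grid indices), one per
#'   component, in scan-encounter order.
#' @export
label_components <- function(cavity, grid) {
  check_same_grid(cavity, grid)
  lab <- cpp_label26(as.logical(cavity), grid$dims)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  set <- which(lab > 0L)
  idx <- arrayInd(set, grid$dims)
  unname(lapply(split(seq_along(set), factor(lab[set], levels = seq_len(nlab))),
                function(rows) {
    idx[rows, , drop = FALSE]
  }))
}

#' Cavity volume from voxel count
#'
#' Volume is the sum of grid-sized cubes: `|points| * h^3` exactly.
#'
#' @param points Integer matrix (n x 3) of grid indices.
#' @param h Grid spacing in angstroms.
#' @return Volume in cubic angstroms.
#' @export
cavity_volume <- function(points, h) {
  stopifnot(h > 0)
  nrow(points) * h^3
}

#' Cavity surface area from exposed voxel faces
#'
#' Area is `h^2` times the number of voxel faces whose 6-neighbor across the
#' face is not in the same point set. Faces shared with other cavities count
#' for each side, keeping per-cavity areas separable. Voxelized area
#' overestimates a smooth surface by a bounded orientation factor (up to
#' 1.5 for a sphere); reported areas carry that convention.
#'
#' @inheritParams cavity_volume
#' @return Area in square angstroms.
#' @export
cavity_area <- function(points, h) {
  stopifnot(h > 0)
  n <- nrow(points)
  if (n == 0L) return(0)
  lo <- apply(points, 2, min)
  dims <- apply(points, 2, max) - lo + 1L
  # membership array padded with one empty layer so every face has a neighbor
  m <- array(FALSE, dim = dims + 2L)
  m[cbind(points[, 1] - lo[1] + 2L, points[, 2] - lo[2] + 2L,
          points[, 3] - lo[3] + 2L)] <- TRUE
  ix <- seq(2L, dims[1] + 1L); iy <- seq(2L, dims[2] + 1L)
  iz <- seq(2L, dims[3] + 1L)
  core <- m[ix, iy, iz, drop = FALSE]
  faces <- sum(core & !m[ix + 1L, iy, iz, drop = FALSE]) +
    sum(core & !m[ix - 1L, iy, iz, drop = FALSE]) +
    sum(core & !m[ix, iy + 1L, iz, drop = FALSE]) +
    sum(core & !m[ix, iy - 1L, iz, drop = FALSE]) +
    sum(core & !m[ix, iy, iz + 1L, drop = FALSE]) +
    sum(core & !m[ix, iy, iz - 1L, drop = FALSE])
  faces * h^2
}

#' Cavity center of mass
#'
#' Unweighted arithmetic mean of the cavity points' coordinates (all voxels
#' are identical, so no occupancy weighting).
#'
#' @inheritParams cavity_volume
#' @param grid The `grid_spec` the indices refer to.
#' @return Numeric 3-vector, angstroms.
#' @export
cavity_center_of_mass <- function(points, grid) {
  if (nrow(points) == 0L) stop("center of mass of an empty point set")
  colMeans(grid_coords(points, grid))
}

#' Residues lining a cavity
#'
#' A residue contributes when any of its atoms lies within
#' `vdw + probe_in + contact_margin` of some cavity point (inclusive
#' threshold). Ordered by chain then residue number.
#'
#' @inheritParams cavity_center_of_mass
#' @param atoms Atom tibble with radii assigned.
#' @param probe_in Small probe radius (angstroms).
#' @param contact_margin Extra margin; defaults to one grid spacing.
#' @return Tibble with `chain_id`, `residue_number`, `residue_name`.
#' @export
contributing_residues <- function(points, grid, atoms, probe_in = 1.4,
                                  contact_margin = grid$spacing) {
  if (nrow(points) == 0L) {
    return(tibble(chain_id = character(), residue_number = numeric(),
                  residue_name = character()))
  }
  d2 <- cpp_min_dist2(atom_matrix(atoms), grid_coords(points, grid))
  thr <- atoms$vdw_radius + probe_in + contact_margin
  atoms[d2 <= thr^2, c("chain_id", "residue_number", "residue_name")] |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chain_id, .data$residue_number)
}

#' Filter cavities by volume and rank by size
#'
#' Cavities below the volume threshold are suppressed; survivors are sorted
#' by volume descending. Ties break deterministically on the minimal
#' `(i, j, k)` grid index of each cavity's point set. Tags (KAA, KAB, ...)
#' are assigned in rank order.
#'
#' @param cavities Cavity tibble (one row per component, `points` list
#'   column plus `volume`).
#' @param volume_threshold Minimum volume retained, cubic angstroms.
#' @return Filtered, ranked, tagged cavity tibble.
#' @export
filter_and_rank <- function(cavities, volume_threshold = 5.0) {
  kept <- dplyr::filter(cavities, .data$volume >= volume_threshold)
  if (nrow(kept) == 0L) {
    kept$tag <- character(0)
    return(kept)
  }
  key <- t(vapply(kept$points, function(p) {
    c(min(p[, 1]), min(p[, 2]), min(p[, 3]))
  }, numeric(3)))
  ord <- order(-kept$volume, key[, 1], key[, 2], key[, 3])
  kept <- kept[ord, , drop = FALSE]
  kept$tag <- cavity_tags(nrow(kept))
  dplyr::relocate(kept, "tag")
}
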