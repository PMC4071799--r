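#' Regular 3D grid specification
#'
#' @param origin Coordinate (angstroms) of grid index `(1,1,1)`.
#' @param spacing Grid spacing h in angstroms (> 0).
#' @param dims Integer vector `(nx, ny, nz)`.
#' @return A `grid_spec` object. The point at index `(i,j,k)` (1-based) has
#'   coordinate `origin + spacing * (i-1, j-1, k-1)`; axes are aligned with
#'   the input coordinate frame.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3L, length(dims) == 3L, spacing > 0,
            all(dims >= 1))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d points, h = %g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Cartesian coordinates of grid indices
#'
#' @param idx Integer matrix (n x 3) of 1-based grid indices.
#' @param grid A `grid_spec`.
#' @return Numeric matrix (n x 3) of coordinates in angstroms.
#' @export
grid_coords <- function(idx, grid) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  cbind(grid$origin[1] + grid$spacing * (idx[, 1] - 1),
        grid$origin[2] + grid$spacing * (idx[, 2] - 1),
        grid$origin[3] + grid$spacing * (idx[, 3] - 1))
}

new_bitfield <- function(values, grid, role) {
  arr <- array(values, dim = grid$dims)
  attr(arr, "role") <- role
  arr
}

atom_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

search_region <- function(atoms, space) {
  switch(space$mode,
    whole_protein = {
      r <- if ("vdw_radius" %in% names(atoms)) atoms$vdw_radius else 0
      list(lo = c(min(atoms$x - r), min(atoms$y - r), min(atoms$z - r)),
           hi = c(max(atoms$x + r), max(atoms$y + r), max(atoms$z + r)))
    },
    box = list(lo = space$box_min, hi = space$box_max),
    ligand_adjacent = {
      lp <- atom_matrix(space$ligand_atoms)
      list(lo = apply(lp, 2, min) - space$ligand_cutoff,
           hi = apply(lp, 2, max) + space$ligand_cutoff)
    },
    stop("unknown search space mode: ", space$mode)
  )
}

#' Build the detection grid around a search region
#'
#' The grid covers the search region expanded on every side by
#' `probe_out + probe_in + spacing`, guaranteeing a full shell of bulk
#' solvent around the region of interest; out-of-grid neighbors therefore
#' never need special treatment. Dimensions are the minimal ones covering
#' that padded region.
#'
#' @param atoms Atom tibble with radii assigned (whole-protein mode uses the
#'   vdW-inflated bounding box of the atoms).
#' @param space A `search_space`; defaults to [whole_protein()].
#' @param spacing Grid spacing h in angstroms (default 0.6).
#' @param probe_out,probe_in Probe radii in angstroms.
#' @return A `grid_spec`.
#' @export
build_grid <- function(atoms, space = whole_protein(), spacing = 0.6,
                       probe_out = 4.0, probe_in = 1.4) {
  stopifnot(nrow(atoms) > 0L, spacing > 0)
  reg <- search_region(atoms, space)
  if (any(reg$hi < reg$lo)) stop("degenerate (zero-extent) search region")
  pad <- probe_out + probe_in + spacing
  origin <- reg$lo - pad
  extent <- (reg$hi + pad) - origin
  dims <- as.integer(ceiling(extent / spacing)) + 1L
  grid_spec(origin, spacing, dims)
}

#' Mark grid points occupied by the protein
#'
#' A point is occupied when it lies within (\eqn{\le}) the van der Waals
#' radius of any atom.
#'
#' @param atoms Atom tibble with `vdw_radius` assigned.
#' @param grid A `grid_spec`.
#' @return Logical 3D array (role `occupancy`).
#' @export
mark_occupancy <- function(atoms, grid) {
  stopifnot("vdw_radius" %in% names(atoms), all(atoms$vdw_radius > 0))
  v <- cpp_mark_spheres(grid$dims, grid$origin, grid$spacing,
                        atom_matrix(atoms), atoms$vdw_radius)
  new_bitfield(v, grid, "occupancy")
}

#' Compute the probe-center field
#'
#' A grid point is a valid probe center when the probe placed there overlaps
#' no atom: strictly farther than `vdw + probe_radius` from every atom. This
#' is the solvent-accessible surface interior at that probe radius.
#'
#' @inheritParams mark_occupancy
#' @param probe_radius Probe radius in angstroms.
#' @return Logical 3D array (role `centers`).
#' @export
compute_center_field <- function(atoms, grid, probe_radius) {
  stopifnot("vdw_radius" %in% names(atoms), probe_radius > 0)
  blocked <- cpp_mark_spheres(grid$dims, grid$origin, grid$spacing,
                              atom_matrix(atoms),
                              atoms$vdw_radius + probe_radius)
  new_bitfield(!blocked, grid, "centers")
}

#' Dilate probe centers by the probe ball
#'
#' Morphological dilation of the center set by the discretized ball of the
#' probe radius: a point is covered iff some set center lies within
#' (\eqn{\le}) `probe_radius`. Computed with an exact squared Euclidean
#' distance transform, which is bit-identical to the union-of-balls
#' definition on the lattice.
#'
#' @param centers Logical 3D array of probe centers.
#' @param grid Matching `grid_spec`.
#' @param probe_radius Probe radius in angstroms.
#' @return Logical 3D array (role `covered`).
#' @export
dilate_centers <- function(centers, grid, probe_radius) {
  check_same_grid(centers, grid)
  d2 <- cpp_edt_sq(as.logical(centers), grid$dims)
  covered <- d2 * (grid$spacing * grid$spacing) <= probe_radius * probe_radius
  new_bitfield(covered, grid, "covered")
}

# Grid used by the detection pipeline: the lattice is anchored to the
# protein (origin at the vdW-inflated bounding box minus padding) and only
# *extended by whole steps* to cover a box/ligand region reaching beyond the
# protein. Anchoring makes segmentation a pure restriction of the
# whole-protein solution: a box containing the protein reproduces the
# whole-protein lattice point-for-point, and translating the atoms by whole
# grid steps translates every field exactly.
detection_grid <- function(atoms, space, spacing, probe_out, probe_in) {
  stopifnot(nrow(atoms) > 0L, spacing > 0)
  pad <- probe_out + probe_in + spacing
  prot <- search_region(atoms, whole_protein())
  origin0 <- prot$lo - pad
  far0 <- prot$hi + pad
  if (space$mode != "whole_protein") {
    reg <- search_region(atoms, space)
    if (any(reg$hi < reg$lo)) stop("degenerate (zero-extent) search region")
    glo <- pmin(origin0, reg$lo - pad)
    ghi <- pmax(far0, reg$hi + pad)
  } else {
    glo <- origin0
    ghi <- far0
  }
  origin <- origin0 - spacing * ceiling(pmax(0, origin0 - glo) / spacing)
  dims <- as.integer(ceiling((ghi - origin) / spacing)) + 1L
  grid_spec(origin, spacing, dims)
}

#' Restrict probe centers to the bulk-connected component
#'
#' Keeps only the center points 26-connected to the grid boundary. The
#' padding contract of [build_grid()] guarantees the boundary lies in bulk
#' solvent, so this selects the placements a probe can reach by rolling in
#' from outside. Applied to the large probe, it implements its role as the
#' border between cavity and bulk: a placement inside a sealed void cannot
#' bound the bulk, so sealed voids larger than the probe remain reportable
#' cavities.
#'
#' @param centers Logical 3D array of valid probe centers.
#' @param grid Matching `grid_spec`.
#' @return Logical 3D array (role `centers`).
#' @export
bulk_centers <- function(centers, grid) {
  check_same_grid(centers, grid)
  lab <- array(cpp_label26(as.logical(centers), grid$dims), dim = grid$dims)
  d <- grid$dims
  boundary_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                              lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  boundary_labels <- boundary_labels[boundary_labels > 0L]
  new_bitfield(lab %in% boundary_labels & centers, grid, "centers")
}

check_same_grid <- function(field, grid) {
  if (!identical(dim(field), NULL) && !all(dim(field) == grid$dims)) {
    stop("bit field dimensions ", paste(dim(field), collapse = "x"),
         " do not match grid ", paste(grid$dims, collapse = "x"))
  }
  invisible(TRUE)
}

#' Extract the raw cavity point set
#'
#' Cavity points are those reachable by the small probe but not by the large
#' one. In `molecular_surface` mode the inner limit is the van der Waals
#' surface: `covered_in & !covered_out & !occupancy`. In `sas` mode it is the
#' solvent-accessible surface traced by the small probe's center:
#' `centers_in & !covered_out`. Points outside the search space are cleared
#' (membership clipping only; the morphology has already seen all atoms).
#'
#' @param covered_in,centers_in,covered_out,occupancy Bit fields on one grid.
#' @param grid The shared `grid_spec`.
#' @param surface_mode `"molecular_surface"` (default) or `"sas"`.
#' @param space Optional `search_space` to clip membership to.
#' @return Logical 3D array (role `cavity`).
#' @export
extract_cavity_field <- function(covered_in, centers_in, covered_out,
                                 occupancy, grid,
                                 surface_mode = c("molecular_surface", "sas"),
                                 space = NULL) {
  surface_mode <- match.arg(surface_mode)
  for (f in list(covered_in, centers_in, covered_out, occupancy)) {
    check_same_grid(f, grid)
  }
  cavity <- if (surface_mode == "molecular_surface") {
    covered_in & !covered_out & !occupancy
  } else {
    centers_in & !covered_out
  }
  if (!is.null(space) && space$mode != "whole_protein") {
    cavity <- clip_cavity_to_space(cavity, grid, space)
  }
  new_bitfield(cavity, grid, "cavity")
}

#' Coarsen the grid when it exceeds a point budget
#'
#' Step re-dimension: when `nx*ny*nz` exceeds `max_points`, the spacing is
#' scaled up by the smallest factor (quantized to 0.05 angstrom steps)
#' bringing the count within budget, and a notice reports the new spacing.
#' The covered region is unchanged.
#'
#' @param grid A `grid_spec`.
#' @param max_points Maximum allowed number of grid points (default 8e6).
#' @return A `grid_spec`, possibly with coarser spacing.
#' @export
apply_step_redimension <- function(grid, max_points = 8e6) {
  stopifnot(max_points > 0)
  if (prod(as.numeric(grid$dims)) <= max_points) return(grid)
  extent <- grid$spacing * (grid$dims - 1L)
  q <- floor(grid$spacing / 0.05 + 1e-9) + 1  # next 0.05-quantized spacing up
  repeat {
    h <- q * 0.05
    dims <- as.integer(ceiling(extent / h)) + 1L
    if (prod(as.numeric(dims)) <= max_points) break
    q <- q + 1
  }
  message(sprintf("step re-dimension: grid spacing coarsened %.3g -> %.3g A",
                  grid$spacing, h))
  grid_spec(grid$origin, h, dims)
}
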