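#' Search spaces for steered cavity prospection
#'
#' The prospection region can be the whole protein, an explicit axis-aligned
#' box, or the zone around a ligand. Restricting the region segments
#' cavities into sub-pockets: morphology still sees all atoms on the full
#' padded grid, only cavity membership is clipped, so segmentation is a pure
#' restriction of the whole-protein solution.
#'
#' @return A `search_space` object.
#' @name search_space
NULL

#' @rdname search_space
#' @export
whole_protein <- function() {
  structure(list(mode = "whole_protein"), class = "search_space")
}

#' @rdname search_space
#' @param box_min,box_max Numeric 3-vectors (angstroms); must satisfy
#'   `box_min < box_max` componentwise. Box faces are closed (ties belong to
#'   the box).
#' @export
box_space <- function(box_min, box_max) {
  stopifnot(length(box_min) == 3L, length(box_max) == 3L)
  if (!all(box_min < box_max)) {
    stop("degenerate box: box_min must be strictly below box_max on every axis")
  }
  structure(list(mode = "box", box_min = as.numeric(box_min),
                 box_max = as.numeric(box_max)),
            class = "search_space")
}

#' @rdname search_space
#' @param ligand_atoms Atom tibble of the ligand.
#' @param ligand_cutoff Distance cutoff in angstroms (default 5).
#' @export
ligand_space <- function(ligand_atoms, ligand_cutoff = 5) {
  stopifnot(nrow(ligand_atoms) > 0L, ligand_cutoff > 0)
  structure(list(mode = "ligand_adjacent", ligand_atoms = ligand_atoms,
                 ligand_cutoff = as.numeric(ligand_cutoff)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space>", x$mode, "\n")
  invisible(x)
}

#' Axis-aligned box around a set of points
#'
#' @param points Numeric matrix (n x 3) of coordinates.
#' @param padding Expansion on each side, angstroms (>= 0).
#' @return A box-mode `search_space`.
#' @export
box_from_points <- function(points, padding = 0) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) == 0L || anyNA(points)) stop("points must be nonempty")
  stopifnot(padding >= 0)
  box_space(apply(points, 2, min) - padding, apply(points, 2, max) + padding)
}

#' Test points for search-space membership
#'
#' @param p Numeric 3-vector or n x 3 matrix of coordinates.
#' @param space A `search_space`.
#' @return Logical vector.
#' @export
point_in_space <- function(p, space) {
  p <- matrix(as.numeric(p), ncol = 3L)
  switch(space$mode,
    whole_protein = rep(TRUE, nrow(p)),
    box = p[, 1] >= space$box_min[1] & p[, 1] <= space$box_max[1] &
      p[, 2] >= space$box_min[2] & p[, 2] <= space$box_max[2] &
      p[, 3] >= space$box_min[3] & p[, 3] <= space$box_max[3],
    ligand_adjacent = {
      lp <- atom_matrix(space$ligand_atoms)
      d2 <- cpp_min_dist2(p, lp)
      d2 <= space$ligand_cutoff^2
    }
  )
}

space_mask <- function(grid, space) {
  if (space$mode == "whole_protein") {
    return(new_bitfield(TRUE, grid, "space"))
  }
  if (space$mode == "ligand_adjacent") {
    lp <- atom_matrix(space$ligand_atoms)
    v <- cpp_mark_spheres(grid$dims, grid$origin, grid$spacing, lp,
                          rep(space$ligand_cutoff, nrow(lp)))
    return(new_bitfield(v, grid, "space"))
  }
  ax <- grid$origin[1] + grid$spacing * (seq_len(grid$dims[1]) - 1)
  ay <- grid$origin[2] + grid$spacing * (seq_len(grid$dims[2]) - 1)
  az <- grid$origin[3] + grid$spacing * (seq_len(grid$dims[3]) - 1)
  inx <- ax >= space$box_min[1] & ax <= space$box_max[1]
  iny <- ay >= space$box_min[2] & ay <= space$box_max[2]
  inz <- az >= space$box_min[3] & az <= space$box_max[3]
  new_bitfield(outer(outer(inx, iny, `&`), inz, `&`), grid, "space")
}

#' Clip a cavity field to a search space
#'
#' Cavity points outside the space are cleared. Clipping happens after
#' morphology and before connectivity labeling, so a cavity cut by a box
#' splits into separately labeled sub-pockets.
#'
#' @param cavity Logical 3D cavity field.
#' @param grid Matching `grid_spec`.
#' @param space A `search_space`.
#' @return Clipped logical 3D array.
#' @export
clip_cavity_to_space <- function(cavity, grid, space) {
  check_same_grid(cavity, grid)
  if (space$mode == "whole_protein") return(cavity)
  new_bitfield(cavity & space_mask(grid, space), grid, "cavity")
}
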