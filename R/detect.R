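#' Detect and characterize protein cavities
#'
#' Runs the full dual-probe pipeline on one structure: build the padded grid,
#' mark van der Waals occupancy, compute probe-accessible regions for the
#' small (Probe In) and large (Probe Out) probes, take their difference as
#' the raw cavity set, clip to the search space, label 26-connected
#' components, characterize each cavity (volume, area, center of mass,
#' lining residues), then filter by volume and rank.
#'
#' The small probe (default 1.40 A, a water radius) delineates the interior
#' of cavities; the large probe (default 4.0 A) cannot descend into them and
#' so defines the cavity ceiling — the boundary between cavity and bulk
#' solvent. Larger `probe_out` values give deeper ceilings and larger
#' cavities; larger `probe_in` values shrink them.
#'
#' @param atoms Receptor atom tibble (see [read_pdb_atoms()]); radii are
#'   assigned from `vdw_table` if not already present.
#' @param probe_in Small probe radius, angstroms (default 1.40).
#' @param probe_out Large probe radius, angstroms (default 4.00); must
#'   exceed `probe_in`.
#' @param spacing Grid spacing h, angstroms (default 0.6).
#' @param volume_threshold Suppress cavities below this volume, cubic
#'   angstroms (default 5).
#' @param surface_mode `"molecular_surface"` (inner limit at the van der
#'   Waals surface) or `"sas"` (inner limit at the solvent-accessible
#'   surface traced by the small probe's center).
#' @param space A `search_space` ([whole_protein()], [box_space()],
#'   [ligand_space()]).
#' @param contact_margin Residue-contact margin, angstroms; defaults to one
#'   grid spacing.
#' @param vdw_table vdW dictionary used when `atoms` lacks radii.
#' @param max_points Step re-dimension budget; `Inf` disables coarsening.
#' @param keep_fields Keep the intermediate bit fields on the result (large;
#'   off by default).
#' @param grid Optional `grid_spec` to run on (advanced; used to share one
#'   lattice across a probe scan). Defaults to a lattice anchored to the
#'   protein's vdW bounding box and padded by `probe_out + probe_in +
#'   spacing` so the boundary is guaranteed bulk solvent.
#' @return A `cavity_result`: list with `cavities` (ranked tibble: `tag`,
#'   `n_points`, `volume`, `area`, `com_x/y/z`, `residues` and `points` list
#'   columns), `grid`, `parameters`, `field_counts`, `atoms`.
#' @examples
#' atoms <- make_hollow_sphere(void_radius = 5)
#' res <- detect_cavities(atoms, spacing = 0.6)
#' res$cavities$volume
#' @export
detect_cavities <- function(atoms, probe_in = 1.4, probe_out = 4.0,
                            spacing = 0.6, volume_threshold = 5.0,
                            surface_mode = c("molecular_surface", "sas"),
                            space = whole_protein(),
                            contact_margin = spacing,
                            vdw_table = load_vdw_table(),
                            max_points = 8e6, keep_fields = FALSE,
                            grid = NULL) {
  surface_mode <- match.arg(surface_mode)
  stopifnot(nrow(atoms) > 0L, probe_in > 0, probe_out > probe_in,
            spacing > 0)
  if (!"vdw_radius" %in% names(atoms)) {
    atoms <- assign_radii(atoms, vdw_table, quiet = TRUE)
  }
  if (is.null(grid)) {
    grid <- detection_grid(atoms, space, spacing, probe_out, probe_in)
    if (is.finite(max_points)) grid <- apply_step_redimension(grid, max_points)
  }

  occupancy <- mark_occupancy(atoms, grid)
  centers_in <- compute_center_field(atoms, grid, probe_in)
  covered_in <- dilate_centers(centers_in, grid, probe_in)
  centers_out <- bulk_centers(compute_center_field(atoms, grid, probe_out),
                              grid)
  covered_out <- dilate_centers(centers_out, grid, probe_out)
  cavity <- extract_cavity_field(covered_in, centers_in, covered_out,
                                 occupancy, grid, surface_mode, space)

  comps <- label_components(cavity, grid)
  h <- grid$spacing
  cav <- tibble(
    points = comps,
    n_points = vapply(comps, nrow, integer(1)),
    volume = vapply(comps, cavity_volume, numeric(1), h = h),
    area = vapply(comps, cavity_area, numeric(1), h = h)
  )
  com <- t(vapply(comps, cavity_center_of_mass, numeric(3), grid = grid))
  if (nrow(cav)) {
    cav$com_x <- com[, 1]; cav$com_y <- com[, 2]; cav$com_z <- com[, 3]
  } else {
    cav$com_x <- cav$com_y <- cav$com_z <- numeric(0)
  }
  cav$residues <- lapply(comps, contributing_residues, grid = grid,
                         atoms = atoms, probe_in = probe_in,
                         contact_margin = contact_margin)
  ranked <- filter_and_rank(cav, volume_threshold)

  structure(list(
    cavities = ranked,
    grid = grid,
    parameters = list(probe_in = probe_in, probe_out = probe_out,
                      spacing = grid$spacing, requested_spacing = spacing,
                      volume_threshold = volume_threshold,
                      surface_mode = surface_mode, search_mode = space$mode,
                      contact_margin = contact_margin),
    field_counts = c(grid_points = prod(as.numeric(grid$dims)),
                     occupancy = sum(occupancy),
                     centers_in = sum(centers_in),
                     covered_in = sum(covered_in),
                     centers_out = sum(centers_out),
                     covered_out = sum(covered_out),
                     cavity = sum(cavity),
                     cavities_prefilter = nrow(cav),
                     cavities = nrow(ranked)),
    fields = if (keep_fields) {
      list(occupancy = occupancy, centers_in = centers_in,
           covered_in = covered_in, centers_out = centers_out,
           covered_out = covered_out, cavity = cavity)
    },
    atoms = atoms
  ), class = "cavity_result")
}

#' @export
print.cavity_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<cavity_result> %d cavit%s (probe_in %.2f, probe_out %.2f, h %.2f A, %s)\n",
              nrow(x$cavities), if (nrow(x$cavities) == 1) "y" else "ies",
              p$probe_in, p$probe_out, p$spacing, p$surface_mode))
  if (nrow(x$cavities)) {
    print(tidy_cavities(x$cavities), ...)
  }
  invisible(x)
}

tidy_cavities <- function(cavities) {
  tibble(
    tag = cavities$tag,
    n_points = cavities$n_points,
    volume = cavities$volume,
    area = cavities$area,
    com_x = cavities$com_x, com_y = cavities$com_y, com_z = cavities$com_z,
    n_residues = vapply(cavities$residues, nrow, integer(1))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cavity detection result
#'
#' One row per reported cavity, ranked by volume: tag, voxel count, volume
#' (cubic angstroms), area (square angstroms), center of mass and number of
#' lining residues.
#'
#' @param x A `cavity_result`.
#' @param ... Unused.
#' @export
tidy.cavity_result <- function(x, ...) {
  tidy_cavities(x$cavities)
}

#' One-row summary of a cavity detection run
#'
#' @param x A `cavity_result`.
#' @param ... Unused.
#' @export
glance.cavity_result <- function(x, ...) {
  tibble(
    n_cavities = nrow(x$cavities),
    total_volume = sum(x$cavities$volume),
    largest_volume = if (nrow(x$cavities)) max(x$cavities$volume) else NA_real_,
    grid_points = unname(x$field_counts["grid_points"]),
    spacing = x$grid$spacing,
    probe_in = x$parameters$probe_in,
    probe_out = x$parameters$probe_out,
    surface_mode = x$parameters$surface_mode
  )
}
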