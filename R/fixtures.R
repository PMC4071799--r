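#' Synthetic PDB fixtures with analytically known cavity geometry
#'
#' Toy structures built from carbon-like pseudo-atoms (radius 1.7 A, wall
#' lattice spacing 1.0 A by default) whose cavity volumes are known in
#' closed form, so every pipeline stage is testable without downloading
#' real structures. Walls are dense enough that a water-sized probe cannot
#' leak through them: atom spacing must satisfy
#' `spacing <= sqrt(3) * (atom_radius + probe_in_ref)` (the three-atom
#' circumradius bound), with `probe_in_ref = 1.4` A.
#'
#' @name fixtures
NULL

check_wall_spacing <- function(atom_spacing, atom_radius,
                               probe_in_ref = 1.4) {
  bound <- sqrt(3) * (atom_radius + probe_in_ref)
  if (atom_spacing >= bound) {
    stop(sprintf(paste0("leaky wall: atom_spacing %.3f >= sqrt(3)*(atom_radius",
                        " + %.2f) = %.3f; probes could pass between atoms"),
                 atom_spacing, probe_in_ref, bound))
  }
  invisible(TRUE)
}

fixture_atoms <- function(xyz, residue_name = "FIX", chain_id = "A") {
  n <- nrow(xyz)
  tibble(
    record = "ATOM",
    serial = seq_len(n),
    atom_name = "C",
    alt_loc = " ",
    residue_name = residue_name,
    chain_id = chain_id,
    residue_number = seq_len(n),
    insertion_code = " ",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy_value = 1.0,
    element = "C"
  )
}

# deterministic, seedless near-uniform layout of n points on a sphere
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @describeIn fixtures Spherical shell enclosing an empty interior ball of
#'   `void_radius`; the innermost atom layer is tangent to that ball, so the
#'   detected molecular-surface cavity approaches the analytic ball volume
#'   `4/3 * pi * void_radius^3` as the grid is refined. Returns an atom
#'   tibble.
#' @param void_radius Radius of the enclosed empty ball, angstroms.
#' @param shell_thickness Radial thickness of the atom wall, angstroms.
#' @param atom_spacing Target spacing between wall atom centers, angstroms.
#' @param atom_radius van der Waals radius given to every wall atom.
#' @export
make_hollow_sphere <- function(void_radius = 5, shell_thickness = 2,
                               atom_spacing = 1.0, atom_radius = 1.7) {
  stopifnot(void_radius > 0, shell_thickness > 0, atom_spacing > 0,
            atom_radius > 0)
  check_wall_spacing(atom_spacing, atom_radius)
  layers <- seq(void_radius + atom_radius,
                void_radius + atom_radius + shell_thickness,
                by = atom_spacing)
  xyz <- do.call(rbind, lapply(layers, function(r) {
    n <- max(12L, ceiling(4 * pi * r^2 / atom_spacing^2))
    fibonacci_sphere(n, r)
  }))
  atoms <- fixture_atoms(xyz, residue_name = "SHL")
  atoms$vdw_radius <- atom_radius
  atoms$radius_source <- "fixture"
  atoms
}

slab_lattice <- function(slab_dims, atom_spacing) {
  sx <- slab_dims[1] / 2; sy <- slab_dims[2] / 2
  xs <- seq(-sx, sx, by = atom_spacing)
  ys <- seq(-sy, sy, by = atom_spacing)
  zs <- seq(-slab_dims[3], 0, by = atom_spacing)
  as.matrix(expand.grid(x = xs, y = ys, z = zs))
}

#' @describeIn fixtures Dense rectangular atom slab (top face at z = 0,
#'   i.e. van der Waals surface at `z = atom_radius`) with a hemispherical
#'   pocket of `pocket_radius` opening upward through the top face. Lattice
#'   atoms intruding into the pocket sphere are removed and the wall is
#'   lined with atoms placed exactly tangent to the analytic sphere, so the
#'   van der Waals pocket surface coincides with the stated geometry and
#'   the open-pocket volume approaches `2/3 * pi * pocket_radius^3` (up to
#'   the ceiling set by the large probe bridging the mouth).
#' @param slab_dims Numeric 3-vector `(x, y, thickness)`, angstroms.
#' @param pocket_radius Hemispherical pocket radius, angstroms; must be
#'   smaller than `slab_dims[3] + atom_radius`.
#' @export
make_slab_pocket <- function(slab_dims = c(16, 16, 8), pocket_radius = 4,
                             atom_spacing = 1.0, atom_radius = 1.7) {
  stopifnot(length(slab_dims) == 3L, all(slab_dims > 0), pocket_radius >= 0)
  if (pocket_radius >= slab_dims[3] + atom_radius) {
    stop("pocket_radius must be smaller than the slab thickness")
  }
  check_wall_spacing(atom_spacing, atom_radius)
  xyz <- slab_lattice(slab_dims, atom_spacing)
  if (pocket_radius > 0) {
    center <- slab_pocket_center(atom_radius)
    rr <- pocket_radius + atom_radius
    d <- sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
                (xyz[, 3] - center[3])^2)
    xyz <- xyz[d >= rr, , drop = FALSE]
    # tangent lining: wall atoms exactly on the pocket sphere (kept flush
    # with the slab, z <= 0) so the vdW wall is the analytic sphere
    lining <- fibonacci_sphere(max(12L, ceiling(4 * pi * rr^2 /
                                                  atom_spacing^2)), rr)
    lining <- sweep(lining, 2, center, `+`)
    xyz <- rbind(xyz, lining[lining[, 3] <= 0, , drop = FALSE])
  }
  atoms <- fixture_atoms(xyz, residue_name = "SLB")
  atoms$vdw_radius <- atom_radius
  atoms$radius_source <- "fixture"
  atoms
}

# pocket sphere center sits on the slab's top atom-lattice plane, so the
# tangent lining's rim ring is flush with the top layer and the analytic
# void below z = 0 is exactly the lower half of the pocket sphere
slab_pocket_center <- function(atom_radius = 1.7) {
  c(0, 0, 0)
}

#' @describeIn fixtures Rectangular block with a cylindrical through-tunnel
#'   along x, optionally widened into `chambers` spherical bulbs for
#'   sub-pocket segmentation tests. The tunnel bore must admit the small
#'   probe (`bore_radius > 1.4`).
#' @param length Tunnel length (block x extent), angstroms.
#' @param bore_radius Tunnel bore radius, angstroms.
#' @param chambers Number of spherical bulbs widened along the tunnel.
#' @param chamber_radius Bulb radius, angstroms.
#' @export
make_channel <- function(length = 20, bore_radius = 2.5, atom_spacing = 1.0,
                         atom_radius = 1.7, chambers = 0,
                         chamber_radius = 4) {
  stopifnot(length > 0, bore_radius > 0, chambers >= 0)
  check_wall_spacing(atom_spacing, atom_radius)
  half_sec <- max(bore_radius, if (chambers > 0) chamber_radius else 0) + 3
  xs <- seq(-length / 2, length / 2, by = atom_spacing)
  ys <- seq(-half_sec, half_sec, by = atom_spacing)
  xyz <- as.matrix(expand.grid(x = xs, y = ys, z = ys))
  keep <- sqrt(xyz[, 2]^2 + xyz[, 3]^2) >= bore_radius + atom_radius
  if (chambers > 0) {
    cx <- channel_chamber_centers(length, chambers)
    for (c0 in cx) {
      d <- sqrt((xyz[, 1] - c0)^2 + xyz[, 2]^2 + xyz[, 3]^2)
      keep <- keep & d >= chamber_radius + atom_radius
    }
  }
  atoms <- fixture_atoms(xyz[keep, , drop = FALSE], residue_name = "CHN")
  atoms$vdw_radius <- atom_radius
  atoms$radius_source <- "fixture"
  atoms
}

# chamber centers evenly spaced along the tunnel axis, away from the ends
channel_chamber_centers <- function(length, chambers) {
  if (chambers == 0L) return(numeric(0))
  seq(-length / 2, length / 2,
      length.out = chambers + 2L)[seq_len(chambers) + 1L]
}

#' @describeIn fixtures Receptor-ligand pair for the benchmark protocol: a
#'   slab-pocket receptor plus `ligand_atom_count` HETATM ligand atoms placed
#'   within `ligand_jitter` angstroms of the pocket void's centroid
#'   (deterministic under `seed`). `displacement` shifts the whole ligand,
#'   e.g. `c(0, 0, 10)` to construct a failing case. Returns
#'   `list(receptor, ligand)`.
#' @param ligand_atom_count Number of ligand atoms.
#' @param seed Integer seed for ligand placement.
#' @param ligand_jitter Maximum ligand-atom distance from the pocket
#'   centroid, angstroms.
#' @param displacement Numeric 3-vector added to all ligand coordinates.
#' @export
make_receptor_ligand <- function(pocket_radius = 4, slab_dims = c(16, 16, 8),
                                 atom_spacing = 1.0, atom_radius = 1.7,
                                 ligand_atom_count = 3, seed = 1,
                                 ligand_jitter = 2,
                                 displacement = c(0, 0, 0)) {
  receptor <- make_slab_pocket(slab_dims, pocket_radius, atom_spacing,
                               atom_radius)
  # centroid of the hemispherical void (z in [-r, 0] below the mouth plane)
  center <- slab_pocket_center(atom_radius) - c(0, 0, 3 * pocket_radius / 8)
  xyz <- withr::with_seed(seed, {
    u <- matrix(stats::rnorm(3 * ligand_atom_count), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- stats::runif(ligand_atom_count, 0, ligand_jitter)
    u * r
  })
  xyz <- sweep(xyz, 2, center + displacement, `+`)
  ligand <- fixture_atoms(xyz, residue_name = "LIG", chain_id = "L")
  ligand$record <- "HETATM"
  ligand$residue_number <- 1L
  list(receptor = receptor, ligand = ligand)
}

#' Write a fixture structure as a PDB file
#'
#' Receptor atoms become ATOM records, ligand atoms HETATM records, in
#' standard fixed columns; output is deterministic (byte-identical for equal
#' inputs) and round-trips through [read_pdb_atoms()].
#'
#' @param receptor,ligand Atom tibbles (ligand may be `NULL`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(receptor, path, ligand = NULL) {
  fmt <- function(a, record) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, a$serial %% 100000L, a$atom_name, " ", a$residue_name,
            a$chain_id, a$residue_number %% 10000L, " ", a$x, a$y, a$z,
            a$occupancy_value, 0, a$element)
  }
  lines <- fmt(receptor, "ATOM")
  if (!is.null(ligand) && nrow(ligand)) lines <- c(lines, fmt(ligand, "HETATM"))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a set of benchmark fixture cases and their manifest
#'
#' Builds `n_cases` receptor-ligand slab-pocket fixtures (pocket radii cycle
#' over 3.5-5 A), writes each as a PDB file plus a tab-separated manifest
#' (`case_id`, `pdb_path`, `ligand_names`) consumable by [run_benchmark()].
#'
#' @param dir Output directory (created if needed).
#' @param n_cases Number of cases.
#' @param seed Base seed; case i uses `seed + i`.
#' @param displacement Ligand displacement applied to every case (for
#'   constructing failing sets).
#' @return Manifest path, invisibly.
#' @export
write_benchmark_fixtures <- function(dir, n_cases = 4, seed = 1,
                                     displacement = c(0, 0, 0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # pockets sized below the default 4 A Probe Out so its ceiling bridges
  # the mouth and the pocket is the dominant detected cavity
  radii <- rep(c(3.5, 3.0, 3.2, 3.8), length.out = n_cases)
  rows <- purrr::map(seq_len(n_cases), function(i) {
    rl <- make_receptor_ligand(pocket_radius = radii[i], seed = seed + i,
                               displacement = displacement)
    p <- file.path(dir, sprintf("case_%02d.pdb", i))
    write_structure_pdb(rl$receptor, p, ligand = rl$ligand)
    tibble(case_id = sprintf("case_%02d", i), pdb_path = p,
           ligand_names = "LIG")
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(dplyr::bind_rows(rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
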