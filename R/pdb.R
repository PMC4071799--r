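#' Read atoms from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (wwPDB v3.3 layout), first model
#' only. Alternate locations other than blank or `A` are dropped (first
#' conformer policy). Waters (`HOH`, `WAT`, `DOD`) and hydrogens are excluded
#' from the receptor by default; records whose residue name is listed in
#' `ligand_names` are routed to the ligand table instead (waters never count
#' as ligand).
#'
#' @param path PDB file path.
#' @param include_hetero Keep HETATM records in the receptor (ions, cofactors).
#' @param exclude_waters Drop water residues.
#' @param exclude_hydrogens Drop hydrogen/deuterium atoms.
#' @param ligand_names Character vector of residue names to split out as the
#'   ligand.
#' @return A list with tibbles `receptor` and `ligand`; columns `serial`,
#'   `record`, `atom_name`, `alt_loc`, `residue_name`, `chain_id`,
#'   `residue_number`, `insertion_code`, `x`, `y`, `z`, `occupancy_value`,
#'   `element`.
#' @export
read_pdb_atoms <- function(path, include_hetero = TRUE, exclude_waters = TRUE,
                           exclude_hydrogens = TRUE,
                           ligand_names = character()) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no ATOM/HETATM records in ", path)
  lines <- lines[keep]

  num <- function(s) suppressWarnings(as.numeric(s))
  field <- function(a, b) trimws(substr(lines, a, b))
  atoms <- tibble(
    record = trimws(substr(lines, 1, 6)),
    serial = num(substr(lines, 7, 11)),
    atom_name = field(13, 16),
    alt_loc = substr(lines, 17, 17),
    residue_name = field(18, 20),
    chain_id = substr(lines, 22, 22),
    residue_number = num(substr(lines, 23, 26)),
    insertion_code = substr(lines, 27, 27),
    x = num(substr(lines, 31, 38)),
    y = num(substr(lines, 39, 46)),
    z = num(substr(lines, 47, 54)),
    occupancy_value = num(substr(lines, 55, 60)),
    element = toupper(field(77, 78))
  )
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("unreadable coordinates at PDB record(s): ",
         paste(utils::head(atoms$serial[bad], 5), collapse = ", "))
  }
  atoms <- dplyr::filter(atoms, .data$alt_loc %in% c(" ", "", "A"))

  is_water <- atoms$residue_name %in% c("HOH", "WAT", "DOD")
  is_lig <- atoms$residue_name %in% toupper(ligand_names) & !is_water
  ligand <- atoms[is_lig, , drop = FALSE]
  receptor <- atoms[!is_lig, , drop = FALSE]

  if (exclude_waters) receptor <- receptor[!receptor$residue_name %in%
                                             c("HOH", "WAT", "DOD"), ]
  if (!include_hetero) receptor <- receptor[receptor$record == "ATOM", ]
  if (exclude_hydrogens) {
    elem <- receptor$element
    noelem <- !nzchar(elem)
    nm <- gsub("[^A-Za-z]", "", toupper(receptor$atom_name))
    elem[noelem] <- substr(nm[noelem], 1, 1)
    receptor <- receptor[!elem %in% c("H", "D"), ]
  }
  if (nrow(receptor) == 0L) stop("empty receptor after filtering: ", path)
  list(receptor = as_tibble(receptor), ligand = as_tibble(ligand))
}

cavity_tags <- function(n) {
  if (n > 676L) {
    stop("cavity tag space exhausted: at most 676 cavities (KAA..KZZ), got ",
         n)
  }
  idx <- seq_len(n) - 1L
  paste0("K", LETTERS[idx %/% 26L + 1L], LETTERS[idx %% 26L + 1L])
}

fmt_pdb_hetatm <- function(serial, atom_name, residue_name, chain_id,
                           residue_number, x, y, z, occ, bfac, element) {
  sprintf("HETATM%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atom_name, " ", residue_name, chain_id, residue_number, " ",
          x, y, z, occ, bfac, element)
}

#' Write cavity points as a PDB file
#'
#' One HETATM pseudo-atom per cavity grid point, for inspection in any
#' molecular viewer. The residue name encodes the cavity tag (KAA, KAB, ...),
#' the occupancy column is fixed at 0.00 and the B-factor column carries the
#' cavity rank index so viewers can color by cavity. Pseudo-atoms are written
#' as element C so the file round-trips through [read_pdb_atoms()] under
#' default filters.
#'
#' @param cavities Cavity tibble from [detect_cavities()] (or a
#'   `cavity_result`), with `tag` and `points` columns.
#' @param grid The `grid_spec` the point indices refer to.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cavity_pdb <- function(cavities, grid, path) {
  if (inherits(cavities, "cavity_result")) {
    grid <- cavities$grid
    cavities <- cavities$cavities
  }
  n <- nrow(cavities)
  cavity_tags(max(n, 0L))  # validates tag space
  out <- character(0)
  serial <- 0L
  for (ci in seq_len(n)) {
    xyz <- grid_coords(cavities$points[[ci]], grid)
    for (p in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      out <- c(out, fmt_pdb_hetatm(serial %% 100000L, "C",
                                   cavities$tag[[ci]], "A",
                                   ci %% 10000L, xyz[p, 1], xyz[p, 2],
                                   xyz[p, 3], 0, ci, "C"))
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write the plain-text results report
#'
#' Deterministic, machine-parseable key/value layout: a parameter echo block
#' followed by one block per reported cavity with its volume (cubic
#' angstroms), area (square angstroms), center of mass and lining residues,
#' in ranked (tag) order.
#'
#' @param result A `cavity_result` from [detect_cavities()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_report <- function(result, path) {
  stopifnot(inherits(result, "cavity_result"))
  p <- result$parameters
  lines <- c(
    "# pocketgrid results",
    "> PARAMETERS",
    sprintf("probe_in %.3f", p$probe_in),
    sprintf("probe_out %.3f", p$probe_out),
    sprintf("grid_spacing %.3f", result$grid$spacing),
    sprintf("volume_threshold %.3f", p$volume_threshold),
    sprintf("surface_mode %s", p$surface_mode),
    sprintf("search_mode %s", p$search_mode),
    sprintf("grid_dims %d %d %d", result$grid$dims[1], result$grid$dims[2],
            result$grid$dims[3]),
    sprintf("n_cavities %d", nrow(result$cavities))
  )
  for (ci in seq_len(nrow(result$cavities))) {
    cv <- result$cavities[ci, ]
    res <- cv$residues[[1]]
    lines <- c(
      lines,
      sprintf("> CAVITY %s", cv$tag),
      sprintf("volume %.3f", cv$volume),
      sprintf("area %.3f", cv$area),
      sprintf("center_of_mass %.3f %.3f %.3f", cv$com_x, cv$com_y, cv$com_z),
      sprintf("points %d", cv$n_points),
      paste("residues",
            if (nrow(res)) {
              paste(sprintf("%s_%d_%s", res$chain_id, res$residue_number,
                            res$residue_name), collapse = " ")
            } else "")
    )
  }
  writeLines(lines, path)
  invisible(path)
}
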