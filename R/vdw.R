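#' Load a van der Waals radii dictionary
#'
#' The dictionary is a plain-text file of whitespace-separated
#' `RESIDUE ATOM RADIUS` lines; `#` starts a comment. The special residue
#' `GENERIC` declares fallbacks: `GENERIC <ELEMENT> <radius>` is the
#' per-element fallback and `GENERIC * <radius>` the last-resort generic
#' default. Radii are in angstroms and must be positive; a generic default
#' must be present so that radius assignment is total.
#'
#' @param path Path to the dictionary file. The packaged default table
#'   (Bondi-style element radii) is used when `path` is `NULL`.
#' @return A tibble with columns `residue_name`, `atom_name`, `radius` and
#'   class `vdw_table`.
#' @examples
#' tab <- load_vdw_table()
#' @export
load_vdw_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.dat", package = "pocketgrid")
  }
  if (!file.exists(path)) stop("vdW dictionary not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(stripped)))
  rows <- purrr::map(keep, function(ln) {
    tok <- strsplit(trimws(stripped[ln]), "\\s+")[[1]]
    if (length(tok) != 3L) {
      stop("malformed vdW dictionary line ", ln, ": ", trimws(lines[ln]))
    }
    r <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(r)) {
      stop("malformed vdW dictionary line ", ln, ": radius not numeric")
    }
    if (r <= 0) {
      stop("invalid vdW radius on line ", ln, ": radii must be > 0")
    }
    tibble(residue_name = toupper(tok[1]), atom_name = toupper(tok[2]),
           radius = r)
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) stop("empty vdW dictionary: ", path)
  generic <- tab$residue_name == "GENERIC" & tab$atom_name == "*"
  if (!any(generic)) {
    stop("vdW dictionary must contain a `GENERIC * <radius>` default line")
  }
  structure(tab, class = c("vdw_table", class(tab)))
}

#' Look up one radius in a vdW table
#'
#' Resolution order: residue-specific entry, then per-element fallback
#' (`GENERIC <element>`), then the generic default (`GENERIC *`).
#'
#' @param table A `vdw_table`.
#' @param residue_name,atom_name,element Atom identity (element may be "").
#' @return Radius in angstroms (always positive).
#' @export
vdw_lookup <- function(table, residue_name, atom_name, element = "") {
  hit <- table$radius[table$residue_name == toupper(residue_name) &
                        table$atom_name == toupper(atom_name)]
  if (length(hit)) return(hit[[1]])
  if (nzchar(element)) {
    hit <- table$radius[table$residue_name == "GENERIC" &
                          table$atom_name == toupper(element)]
    if (length(hit)) return(hit[[1]])
  }
  table$radius[table$residue_name == "GENERIC" & table$atom_name == "*"][[1]]
}

#' Assign van der Waals radii to atoms
#'
#' Every atom leaves with a positive `vdw_radius`; the generic default
#' guarantees coverage. The assignment source is recorded in `radius_source`
#' (`"residue"`, `"element"` or `"generic"`), and the number of fallback
#' assignments is reported with a warning-level message.
#'
#' @param atoms Atom tibble (see [read_pdb_atoms()]).
#' @param table A `vdw_table` from [load_vdw_table()].
#' @param quiet Suppress the fallback-count message.
#' @return `atoms` with `vdw_radius` and `radius_source` columns.
#' @export
assign_radii <- function(atoms, table = load_vdw_table(), quiet = FALSE) {
  stopifnot(inherits(table, "vdw_table"))
  key <- paste(toupper(atoms$residue_name), toupper(atoms$atom_name))
  tab_key <- paste(table$residue_name, table$atom_name)
  res_idx <- match(key, tab_key)

  elem <- toupper(atoms$element)
  blank <- !nzchar(elem)
  # derive element from the atom name when the PDB element column is empty
  elem[blank] <- sub("^([A-Z]).*$", "\\1",
                     gsub("[^A-Za-z]", "", toupper(atoms$atom_name[blank])))
  elem_idx <- match(paste("GENERIC", elem), tab_key)
  gen_idx <- match("GENERIC *", tab_key)

  idx <- dplyr::coalesce(res_idx, elem_idx, gen_idx)
  source <- dplyr::case_when(
    !is.na(res_idx) ~ "residue",
    !is.na(elem_idx) ~ "element",
    TRUE ~ "generic"
  )
  n_fallback <- sum(source != "residue")
  if (n_fallback > 0L && !quiet) {
    message(n_fallback, " atom(s) assigned by element/generic fallback")
  }
  atoms$vdw_radius <- table$radius[idx]
  atoms$radius_source <- source
  atoms
}
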