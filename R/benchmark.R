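#' Evaluate a top-k binding-site prediction
#'
#' A prediction is correct when any of the k largest cavities (by volume
#' rank) has its center of mass within `cutoff` (default 4 A, inclusive) of
#' any ligand atom.
#'
#' @param cavities Ranked cavity tibble (from [detect_cavities()] or a
#'   `cavity_result`).
#' @param ligand Ligand atom tibble (nonempty).
#' @param k Rank cutoff (>= 1).
#' @param cutoff Center-of-mass distance criterion, angstroms.
#' @return Logical scalar.
#' @export
evaluate_prediction <- function(cavities, ligand, k = 3, cutoff = 4.0) {
  if (inherits(cavities, "cavity_result")) cavities <- cavities$cavities
  stopifnot(k >= 1)
  if (nrow(ligand) == 0L) stop("empty ligand: nothing to evaluate against")
  n <- min(k, nrow(cavities))
  if (n == 0L) return(FALSE)
  com <- cbind(cavities$com_x, cavities$com_y, cavities$com_z)[seq_len(n), ,
                                                              drop = FALSE]
  d2 <- cpp_min_dist2(com, atom_matrix(ligand))
  any(d2 <= cutoff^2)
}

#' Whole-protein detection across a scan of Probe Out radii
#'
#' Runs one full whole-protein detection per radius with all other
#' parameters identical. The default scan is 2 to 8 A in 0.5 A steps
#' (13 runs), the protocol used to choose the 4.0 A preset. All runs share
#' one lattice (padded for the largest radius) so cavity point sets are
#' directly comparable across the scan.
#'
#' @param receptor Receptor atom tibble.
#' @param radii Probe Out radii to scan, angstroms; all must exceed
#'   `probe_in`.
#' @param probe_in Small probe radius.
#' @param spacing Grid spacing, angstroms.
#' @param ... Further arguments passed to [detect_cavities()].
#' @return Named list (names = formatted radii) of `cavity_result` objects.
#' @export
probe_out_scan <- function(receptor, radii = seq(2, 8, by = 0.5),
                           probe_in = 1.4, spacing = 0.6, ...) {
  stopifnot(length(radii) > 0)
  if (any(radii <= probe_in)) {
    stop("every scanned probe_out must exceed probe_in = ", probe_in)
  }
  if (!"vdw_radius" %in% names(receptor)) {
    receptor <- assign_radii(receptor, quiet = TRUE)
  }
  grid <- detection_grid(receptor, whole_protein(), spacing, max(radii),
                         probe_in)
  results <- purrr::map(radii, function(r) {
    detect_cavities(receptor, probe_in = probe_in, probe_out = r,
                    spacing = spacing, grid = grid, ...)
  })
  names(results) <- sprintf("%.1f", radii)
  results
}

#' Combine predictions across a Probe Out scan
#'
#' `"union"` (default): success iff any scanned radius succeeds at rank k —
#' the weakest rule consistent with a combined rate at least as high as the
#' best single radius. `"pooled"`: pool all cavities across the scan,
#' re-rank by volume, and evaluate the pooled top k.
#'
#' @param scan Named list of `cavity_result` objects from
#'   [probe_out_scan()].
#' @param ligand Ligand atom tibble.
#' @param k Rank cutoff.
#' @param rule Combination rule.
#' @param cutoff Center-of-mass distance criterion, angstroms.
#' @return Logical scalar.
#' @export
combine_predictions <- function(scan, ligand, k = 3,
                                rule = c("union", "pooled"), cutoff = 4.0) {
  rule <- match.arg(rule)
  stopifnot(length(scan) > 0)
  if (rule == "union") {
    return(any(vapply(scan, evaluate_prediction, logical(1), ligand = ligand,
                      k = k, cutoff = cutoff)))
  }
  pooled <- dplyr::bind_rows(lapply(scan, function(r) {
    cv <- if (inherits(r, "cavity_result")) r$cavities else r
    cv[, c("tag", "volume", "com_x", "com_y", "com_z")]
  }))
  pooled <- dplyr::arrange(pooled, dplyr::desc(.data$volume))
  evaluate_prediction(pooled, ligand, k = k, cutoff = cutoff)
}

#' Success-rate summary over benchmark cases
#'
#' @param per_case Tibble with one row per (case, condition) and logical
#'   columns `top1`, `top2`, ... as produced by [run_benchmark()].
#' @param k_values Integer ranks summarized.
#' @return Tibble with one row per condition and success-rate columns
#'   `top<k>` as fractions in `[0, 1]`.
#' @export
success_rate_summary <- function(per_case, k_values = 1:3) {
  if (nrow(per_case) == 0L) stop("no benchmark cases to summarize")
  cols <- paste0("top", k_values)
  stopifnot(all(cols %in% names(per_case)))
  per_case |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_cases = dplyr::n(),
                     dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
}

#' Run the benchmark protocol over a case manifest
#'
#' For each case the receptor is read (ligand residues split out by name),
#' cavities are detected and ranked by volume, and top-k success is scored
#' with the center-of-mass criterion. With `scan = TRUE` the Probe Out scan
#' and the combined prediction are added. Cases whose files are missing are
#' recorded as errors and skipped with a warning.
#'
#' @param manifest Path to a tab-separated manifest (`case_id`, `pdb_path`,
#'   `ligand_names`; comma-separated names) or an equivalent data frame.
#' @param k_values Ranks to score.
#' @param scan Also run the 13-radius Probe Out scan and combined rule.
#' @param radii Scan radii.
#' @param cutoff Center-of-mass criterion, angstroms.
#' @param ... Further arguments passed to [detect_cavities()].
#' @return A `benchmark_summary`: list with `per_case` (logical top-k flags
#'   per case and condition), `summary` (success-rate table), `errors`.
#' @export
run_benchmark <- function(manifest, k_values = 1:3, scan = FALSE,
                          radii = seq(2, 8, by = 0.5), cutoff = 4.0, ...) {
  cases <- if (is.data.frame(manifest)) {
    as_tibble(manifest)
  } else {
    as_tibble(utils::read.table(manifest, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
  }
  if (nrow(cases) == 0L) stop("empty benchmark manifest")
  stopifnot(all(c("case_id", "pdb_path", "ligand_names") %in% names(cases)))

  errors <- character(0)
  rows <- list()
  score_row <- function(case_id, condition, pred) {
    out <- tibble(case_id = case_id, condition = condition)
    for (k in k_values) out[[paste0("top", k)]] <- pred(k)
    out
  }
  for (ci in seq_len(nrow(cases))) {
    id <- cases$case_id[ci]
    path <- cases$pdb_path[ci]
    if (!file.exists(path)) {
      errors <- c(errors, sprintf("%s: missing file %s", id, path))
      next
    }
    lig_names <- toupper(trimws(strsplit(cases$ligand_names[ci], ",")[[1]]))
    st <- read_pdb_atoms(path, ligand_names = lig_names)
    if (nrow(st$ligand) == 0L) {
      errors <- c(errors, sprintf("%s: no ligand atoms named %s", id,
                                  paste(lig_names, collapse = ",")))
      next
    }
    base <- detect_cavities(st$receptor, ...)
    rows[[length(rows) + 1L]] <-
      score_row(id, "default", function(k) {
        evaluate_prediction(base, st$ligand, k = k, cutoff = cutoff)
      })
    if (scan) {
      sc <- probe_out_scan(st$receptor, radii = radii, ...)
      for (rn in names(sc)) {
        rows[[length(rows) + 1L]] <-
          score_row(id, paste0("probe_out_", rn), function(k) {
            evaluate_prediction(sc[[rn]], st$ligand, k = k, cutoff = cutoff)
          })
      }
      rows[[length(rows) + 1L]] <-
        score_row(id, "combined", function(k) {
          combine_predictions(sc, st$ligand, k = k, cutoff = cutoff)
        })
    }
  }
  if (length(errors)) {
    warning("benchmark skipped ", length(errors), " case(s): ",
            paste(errors, collapse = "; "))
  }
  per_case <- dplyr::bind_rows(rows)
  if (nrow(per_case) == 0L) stop("no benchmark cases could be evaluated")
  structure(list(per_case = per_case,
                 summary = success_rate_summary(per_case, k_values),
                 errors = errors),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary>", dplyr::n_distinct(x$per_case$case_id),
      "case(s)\n")
  print(x$summary, ...)
  invisible(x)
}

#' Tidy per-case benchmark results
#' @param x A `benchmark_summary`.
#' @param ... Unused.
#' @export
tidy.benchmark_summary <- function(x, ...) x$per_case

#' Success-rate table of a benchmark run
#' @param x A `benchmark_summary`.
#' @param ... Unused.
#' @export
glance.benchmark_summary <- function(x, ...) x$summary
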