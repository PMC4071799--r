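#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ranked cavity volumes
#'
#' Bar chart of cavity volumes in rank order, the graphical companion of the
#' results report.
#'
#' @param object A `cavity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cavity_result <- function(object, ...) {
  dat <- tidy(object)
  if (nrow(dat) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no cavities above threshold") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$tag,
                                                       -.data$volume),
                                    y = .data$volume)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cavity (volume rank)",
                  y = expression(volume ~ (ring(A)^3)),
                  title = "Detected cavities") +
    ggplot2::theme_minimal()
}

#' Plot a grid slice through the detection fields
#'
#' Tile map of one z-slice showing protein occupancy, cavity points and free
#' space — the didactic cross-section view of the dual-probe construction.
#' Requires a result built with `keep_fields = TRUE`.
#'
#' @param result A `cavity_result` with kept fields.
#' @param z Slice coordinate, angstroms (nearest grid plane is used;
#'   defaults to the grid mid-plane).
#' @return A ggplot object.
#' @export
plot_cavity_slice <- function(result, z = NULL) {
  stopifnot(inherits(result, "cavity_result"))
  if (is.null(result$fields)) {
    stop("run detect_cavities(..., keep_fields = TRUE) to plot slices")
  }
  grid <- result$grid
  if (is.null(z)) z <- grid$origin[3] + grid$spacing * (grid$dims[3] - 1) / 2
  k <- round((z - grid$origin[3]) / grid$spacing) + 1
  k <- max(1L, min(grid$dims[3], as.integer(k)))
  occ <- result$fields$occupancy[, , k]
  cav <- result$fields$cavity[, , k]
  dat <- tidyr::expand_grid(i = seq_len(grid$dims[1]),
                            j = seq_len(grid$dims[2])) |>
    dplyr::mutate(
      x = grid$origin[1] + grid$spacing * (.data$i - 1),
      y = grid$origin[2] + grid$spacing * (.data$j - 1),
      what = dplyr::case_when(
        cav[cbind(i, j)] ~ "cavity",
        occ[cbind(i, j)] ~ "protein",
        TRUE ~ "free"
      )
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y,
                                    fill = .data$what)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(protein = "darkorange",
                                          cavity = "steelblue",
                                          free = "grey92")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = sprintf("grid slice at z = %.2f Å",
                                  grid$origin[3] + grid$spacing * (k - 1))) +
    ggplot2::theme_minimal()
}

#' Plot success rate against Probe Out radius
#'
#' Line plot of top-k success rates across the Probe Out scan conditions of
#' a benchmark run (the probe-size calibration curve).
#'
#' @param object A `benchmark_summary` from [run_benchmark()] with
#'   `scan = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_summary <- function(object, ...) {
  dat <- object$summary |>
    dplyr::filter(startsWith(.data$condition, "probe_out_")) |>
    dplyr::mutate(probe_out = as.numeric(sub("probe_out_", "",
                                             .data$condition))) |>
    tidyr::pivot_longer(dplyr::starts_with("top"), names_to = "rank",
                        values_to = "rate")
  if (nrow(dat) == 0L) stop("no probe-out scan conditions in this summary")
  ggplot2::ggplot(dat, ggplot2::aes(.data$probe_out, .data$rate,
                                    color = .data$rank)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Probe Out radius (Å)", y = "success rate",
                  title = "Binding-site prediction vs. probe size") +
    ggplot2::theme_minimal()
}
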