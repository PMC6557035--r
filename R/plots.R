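#' Raster plot of binarized activity
#'
#' Frames on the x axis, cells on the y axis; spikes belonging to a detected
#' network ensemble are highlighted when an `ensemble_set` is supplied.
#'
#' @param raster A `binary_raster` (frames x cells, 0/1).
#' @param ensembles Optional `ensemble_set` used to highlight ensemble spikes.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster, ensembles = NULL) {
  m <- trace_matrix(raster)
  df <- tibble::as_tibble(m) |>
    dplyr::mutate(frame = dplyr::row_number()) |>
    tidyr::pivot_longer(-"frame", names_to = "cell", values_to = "active") |>
    dplyr::filter(.data$active == 1) |>
    dplyr::mutate(in_ensemble = FALSE)
  if (!is.null(ensembles) && nrow(ensembles$ensembles)) {
    for (i in seq_len(nrow(ensembles$ensembles))) {
      e <- ensembles$ensembles[i, ]
      hit <- df$frame >= e$frame_start & df$frame <= e$frame_end &
        df$cell %in% e$members[[1]]
      df$in_ensemble[hit] <- TRUE
    }
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame,
                                   y = factor(.data$cell, levels = colnames(m)),
                                   colour = .data$in_ensemble)) +
    ggplot2::geom_point(shape = 3, size = 1, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "frame", y = "cell") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Per-frame co-activity with the significance threshold
#'
#' @param x An `ensemble_set`.
#' @param ... Unused.
#' @return A ggplot object: percent of co-active cells per frame with the
#'   null-derived threshold as a horizontal line.
#' @export
autoplot.ensemble_set <- function(x, ...) {
  co <- rowSums(x$raster) / x$n_cells * 100
  df <- tibble::tibble(frame = seq_along(co), coactive_pct = co)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$coactive_pct)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "frame", y = "% co-active cells") +
    ggplot2::theme_minimal()
  if (!is.na(x$coactivity_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = x$coactivity_threshold / x$n_cells * 100,
                                 colour = "red", linetype = 2)
  }
  p
}

#' Bar chart of a relative frequency distribution
#'
#' @param object A `rel_freq` tibble from [relative_frequency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rel_freq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$midpoint, .data$proportion)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "value", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Per-animal spine densities by group
#'
#' Jittered per-animal means with group mean +/- SEM overlaid.
#'
#' @param summaries Output of [summarize_spine_groups()].
#' @return A ggplot object.
#' @export
plot_spine_densities <- function(summaries) {
  ggplot2::ggplot(summaries$animals,
                  ggplot2::aes(.data[[names(summaries$animals)[1]]], .data$density)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = summaries$groups,
      ggplot2::aes(y = .data$mean_density,
                   ymin = .data$mean_density - .data$sem_density,
                   ymax = .data$mean_density + .data$sem_density),
      colour = "red") +
    ggplot2::labs(x = NULL, y = "spines per 10 µm") +
    ggplot2::theme_minimal()
}
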