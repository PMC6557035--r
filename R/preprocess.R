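#' Subtract a background signal from all traces
#'
#' The background is measured in areas of the field of view without cells and
#' removed from every ROI trace. Results that would go negative are clipped to
#' zero (fluorescence is non-negative); the number of clipped entries is
#' recorded in the `n_clipped` attribute.
#'
#' @param traces A [trace_tbl()].
#' @param background A scalar, or one value per frame.
#' @return A [trace_tbl()] with attribute `n_clipped`.
#' @export
subtract_background <- function(traces, background) {
  m <- trace_matrix(traces)
  if (!all(is.finite(background))) abort("`background` must be finite")
  if (length(background) != 1 && length(background) != nrow(m)) {
    abort(sprintf("`background` must be length 1 or %d (one per frame), got %d",
                  nrow(m), length(background)))
  }
  out <- m - background   # scalar, or per-frame vector recycled down columns
  n_clipped <- sum(out < 0)
  out[out < 0] <- 0
  new_trace_tbl(tibble::as_tibble(out), frame_period = frame_period(traces),
                fov_id = attr(traces, "fov_id"), extra = list(n_clipped = n_clipped))
}

#' Exclude cells saturating the indicator
#'
#' A cell whose fluorescence never leaves the top band of its own dynamic
#' range - `min(F) >= (1 - exclusion_fraction) * max(F)`, i.e. the whole
#' recording sits at 90% of maximum or above for the default 0.10 - carries no
#' usable transient information and is removed before any further analysis.
#' Constant traces satisfy the rule and are excluded.
#'
#' @param traces A [trace_tbl()].
#' @param exclusion_fraction Width of the admissible band below the maximum.
#' @return The kept cells as a [trace_tbl()]; the dropped cells are available
#'   via [excluded_cells()] (attribute `exclusions`: `cell_id`, `reason`,
#'   `min`, `max`).
#' @export
exclude_saturated_cells <- function(traces, exclusion_fraction = 0.10) {
  m <- trace_matrix(traces)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  drop <- mins >= (1 - exclusion_fraction) * maxs
  exclusions <- tibble::tibble(cell_id = colnames(m)[drop],
                               reason = "saturated-range",
                               min = mins[drop], max = maxs[drop])
  if (all(drop)) abort("all cells excluded as saturated; nothing left to analyze")
  kept <- m[, !drop, drop = FALSE]
  new_trace_tbl(tibble::as_tibble(kept), frame_period = frame_period(traces),
                fov_id = attr(traces, "fov_id"),
                extra = list(exclusions = exclusions))
}

#' @rdname exclude_saturated_cells
#' @param x A trace table returned by [exclude_saturated_cells()].
#' @export
excluded_cells <- function(x) {
  ex <- attr(x, "exclusions")
  if (is.null(ex)) {
    tibble::tibble(cell_id = character(), reason = character(),
                   min = numeric(), max = numeric())
  } else ex
}

#' Convert traces to dF/F with a sliding lower-half baseline
#'
#' For frame `t` the baseline is the mean of the lower `lower_fraction` of the
#' values in the previous `window` frames (the `floor(w * lower_fraction)`
#' smallest values of the `w = min(window, t - 1)` preceding frames, at least
#' one value), and `dff = (F_t - baseline) / baseline`. The first frame has no
#' preceding window and is set to 0; early frames use the shortened window so
#' no frames are discarded from a 120-frame recording.
#'
#' @param traces A background-subtracted [trace_tbl()].
#' @param window Sliding window length in frames (default 10).
#' @param lower_fraction Fraction of window values forming the baseline
#'   (default 0.5).
#' @return A [trace_tbl()]-shaped tibble of dF/F values (class `dff_tbl`).
#' @export
compute_dff <- function(traces, window = 10, lower_fraction = 0.5) {
  stopifnot(window >= 1, lower_fraction > 0, lower_fraction <= 1)
  m <- trace_matrix(traces)
  nf <- nrow(m)
  out <- matrix(0, nf, ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    f <- m[, j]
    for (t in seq_len(nf)[-1]) {
      w <- min(window, t - 1)
      prev <- f[(t - w):(t - 1)]
      k <- max(1L, floor(w * lower_fraction))
      baseline <- mean(sort(prev, partial = k)[seq_len(k)])
      if (baseline == 0) {
        abort(sprintf("zero baseline for cell '%s' at frame %d (add an offset before dF/F)",
                      colnames(m)[j], t))
      }
      out[t, j] <- (f[t] - baseline) / baseline
    }
  }
  res <- new_trace_tbl(tibble::as_tibble(out), frame_period = frame_period(traces),
                       fov_id = attr(traces, "fov_id"))
  class(res) <- unique(c("dff_tbl", class(res)))
  res
}

#' Per-cell distribution summaries of raw fluorescence
#'
#' The median raw intensity across frames ("baseline fluorescence") and the
#' difference between the maximum and minimum intensity ("dF, fluorescence
#' intensity range"), computed per cell on the (background-subtracted) traces
#' of kept cells.
#'
#' @param traces A [trace_tbl()].
#' @return A tibble: `cell_id`, `baseline_median`, `intensity_range`.
#' @export
summarize_cells <- function(traces) {
  m <- trace_matrix(traces)
  tibble::tibble(
    cell_id = colnames(m),
    baseline_median = unname(apply(m, 2, median)),
    intensity_range = unname(apply(m, 2, max) - apply(m, 2, min))
  )
}
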