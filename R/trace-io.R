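#' Build a fluorescence trace table
#'
#' A trace table is the pipeline's entry object: one row per imaging frame,
#' one numeric column per ROI (cell soma), holding raw fluorescence intensity
#' in arbitrary units. Acquisition metadata (seconds per frame, a field-of-view
#' label) travel as attributes so downstream stages can reach them without
#' extra arguments.
#'
#' @param values A numeric matrix or data frame, frames x cells.
#' @param frame_period Seconds per frame (default 5, one frame every 5 s).
#' @param cell_ids Optional ROI labels; defaults to existing column names or
#'   `cell_1`, `cell_2`, ...
#' @param fov_id Field-of-view label.
#' @return A tibble of class `trace_tbl` with attributes `frame_period` and
#'   `fov_id`.
#' @export
trace_tbl <- function(values, frame_period = 5, cell_ids = NULL, fov_id = "fov") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1) abort("trace table needs at least 1 frame and 1 cell")
  if (!all(is.finite(values))) abort("trace values must be finite")
  if (!is.numeric(frame_period) || length(frame_period) != 1 || frame_period <= 0) {
    abort("`frame_period` must be a single positive number (seconds per frame)")
  }
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != ncol(values)) abort("`cell_ids` length must match the number of columns")
  if (anyDuplicated(cell_ids)) abort("duplicate ROI labels in `cell_ids`")
  colnames(values) <- cell_ids
  out <- tibble::as_tibble(values)
  new_trace_tbl(out, frame_period = frame_period, fov_id = fov_id)
}

new_trace_tbl <- function(x, frame_period, fov_id, extra = list()) {
  attr(x, "frame_period") <- frame_period
  attr(x, "fov_id") <- fov_id
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  class(x) <- unique(c("trace_tbl", class(x)))
  x
}

#' Extract the numeric frames-by-cells matrix from a trace-like table
#' @param x A `trace_tbl` or any all-numeric data frame.
#' @return A numeric matrix, frames x cells.
#' @export
trace_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  ok <- vapply(x, is.numeric, logical(1))
  if (!all(ok)) abort(paste0("non-numeric column(s): ", paste(names(x)[!ok], collapse = ", ")))
  as.matrix(x)
}

#' @rdname trace_tbl
#' @param x A `trace_tbl`.
#' @export
frame_period <- function(x) {
  fp <- attr(x, "frame_period")
  if (is.null(fp)) 5 else fp
}

#' Read an exported ROI trace table
#'
#' Reads a delimited text file as exported from microscope software: a header
#' row of ROI labels followed by one numeric row per frame. Orientation is
#' rows = frames, columns = ROIs; pass `transpose = TRUE` for the other layout.
#'
#' @param path Path to a comma-separated file.
#' @param frame_period Seconds per frame carried as metadata (default 5).
#' @param fov_id Field-of-view label (defaults to the file name).
#' @param transpose If `TRUE`, the file has one row per ROI.
#' @return A [trace_tbl()].
#' @export
read_trace_table <- function(path, frame_period = 5, fov_id = NULL, transpose = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0) abort("empty table: no data rows below the header")
  if (ncol(raw) == 0) abort("empty table: no columns")
  if (anyDuplicated(names(raw))) abort("duplicate ROI labels in header")
  values <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(NULL, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) & nzchar(trimws(raw[[j]])))
    if (length(bad) || anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      abort(sprintf("non-numeric value at row %d, column '%s'", row, names(raw)[j]))
    }
    values[, j] <- v
  }
  if (transpose) {
    ids <- rownames(values)
    values <- t(values)
    colnames(values) <- if (!is.null(ids)) ids else paste0("cell_", seq_len(ncol(values)))
  }
  if (is.null(fov_id)) fov_id <- sub("\\.[^.]*$", "", basename(path))
  trace_tbl(values, frame_period = frame_period, fov_id = fov_id)
}

#' Write a trace table to delimited text
#'
#' Inverse of [read_trace_table()]: header of ROI labels, one row per frame,
#' full double precision so a round trip is lossless.
#'
#' @param traces A [trace_tbl()] (or frames x cells data frame).
#' @param path Output path.
#' @export
write_trace_table <- function(traces, path) {
  m <- trace_matrix(traces)
  # 17 significant digits keeps doubles bit-reproducible through text
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  lines <- c(paste(colnames(m), collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
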