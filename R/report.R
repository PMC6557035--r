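#' Write an ensemble analysis report to JSON
#'
#' Serializes the ensemble count, per-ensemble frame range and member list,
#' core ensembles, the thresholds that produced them and the shuffle-null
#' summary into a machine-checkable JSON report. [read_ensemble_report()]
#' reproduces the counts.
#'
#' @param result An `ensemble_set`.
#' @param path Output path.
#' @export
write_ensemble_report <- function(result, path) {
  stopifnot(inherits(result, "ensemble_set"))
  s <- summarize_ensembles(result)
  cores <- if (is.null(result$cores)) find_core_ensembles(result) else result$cores
  report <- list(
    n_ensembles = nrow(result$ensembles),
    mean_cells_per_ensemble = s$mean_cells_per_ensemble,
    n_core_ensembles = nrow(cores),
    mean_cells_per_core = s$mean_cells_per_core,
    coactivity_threshold = result$coactivity_threshold,
    binarize_threshold_value = result$threshold_value,
    sd_multiplier = result$sd_multiplier,
    ensembles = lapply(seq_len(nrow(result$ensembles)), function(i) {
      e <- result$ensembles[i, ]
      list(ensemble_id = e$ensemble_id, frame_start = e$frame_start,
           frame_end = e$frame_end, members = e$members[[1]])
    }),
    core_ensembles = lapply(seq_len(nrow(cores)), function(i) {
      cc <- cores[i, ]
      list(core_id = cc$core_id, members = cc$members[[1]],
           parents = cc$parents[[1]])
    }),
    null_summary = if (!is.null(result$null)) {
      n <- result$null
      list(alpha = n$alpha, n_shuffles = n$n_shuffles,
           shuffle_mode = n$shuffle_mode, null_mode = n$null_mode,
           seed = n$seed,
           coactivity = n$null$coactivity,
           p_pooled = n$null$p_pooled, p_max = n$null$p_max)
    } else NULL
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ensemble_report
#' @return `read_ensemble_report()`: the report as a list.
#' @export
read_ensemble_report <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
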