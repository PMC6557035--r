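#' Analysis run configuration
#'
#' Bundles every tunable parameter of the trace-to-ensembles pipeline with the
#' conventional defaults: a 10-frame sliding window whose lower 50% of values
#' forms the dF/F baseline, exclusion of cells whose whole-recording intensity
#' range stays within 10% of their maximum, a population threshold of 3 SD
#' above zero on spike probabilities, and a 1000-shuffle permutation null at
#' p < 0.05.
#'
#' @param dff_window Frames in the sliding baseline window.
#' @param dff_lower_fraction Fraction of window values averaged as baseline.
#' @param exclusion_fraction Saturation band as a fraction of the maximum:
#'   a cell is dropped when `min(F) >= (1 - exclusion_fraction) * max(F)`.
#' @param sd_multiplier Multiplier on the population SD for binarization.
#' @param n_shuffles Number of per-cell permutations for the co-activity null.
#' @param alpha Significance level of the null.
#' @param gamma Per-frame AR(1) calcium decay in (0,1); `NULL` derives
#'   `exp(-frame_period / tau_decay)` at run time.
#' @param tau_decay Indicator decay time constant in seconds used when
#'   `gamma` is `NULL` (default 2 s).
#' @param sparsity_weight Non-negative weight on total inferred spiking;
#'   `NULL` uses `1 / sigma` per cell.
#' @param shuffle_mode `"permute"` (full per-cell permutation) or
#'   `"circular"` (per-cell circular shift, preserves autocorrelation).
#' @param null_mode `"max"` (per-recording maximum-statistic null, the
#'   default) or `"pooled"` (per-frame pooled null).
#' @param binarize_center `"zero"` (threshold = multiplier x RMS about zero)
#'   or `"mean"` (mean + multiplier x SD).
#' @param seed RNG seed for the stochastic stages (`NULL` = caller's stream).
#' @return A list of class `run_config`.
#' @export
run_config <- function(dff_window = 10,
                       dff_lower_fraction = 0.5,
                       exclusion_fraction = 0.10,
                       sd_multiplier = 3,
                       n_shuffles = 1000,
                       alpha = 0.05,
                       gamma = NULL,
                       tau_decay = 2,
                       sparsity_weight = NULL,
                       shuffle_mode = c("permute", "circular"),
                       null_mode = c("max", "pooled"),
                       binarize_center = c("zero", "mean"),
                       seed = NULL) {
  stopifnot(dff_window >= 1,
            dff_lower_fraction > 0, dff_lower_fraction <= 1,
            exclusion_fraction > 0, exclusion_fraction < 1,
            sd_multiplier > 0,
            n_shuffles >= 1,
            alpha > 0, alpha < 1,
            is.null(gamma) || (gamma > 0 && gamma < 1),
            tau_decay > 0,
            is.null(sparsity_weight) || sparsity_weight >= 0)
  structure(list(
    dff_window = dff_window,
    dff_lower_fraction = dff_lower_fraction,
    exclusion_fraction = exclusion_fraction,
    sd_multiplier = sd_multiplier,
    n_shuffles = n_shuffles,
    alpha = alpha,
    gamma = gamma,
    tau_decay = tau_decay,
    sparsity_weight = sparsity_weight,
    shuffle_mode = match.arg(shuffle_mode),
    null_mode = match.arg(null_mode),
    binarize_center = match.arg(binarize_center),
    seed = seed
  ), class = "run_config")
}

#' Read a run configuration from JSON or YAML-like key: value text
#'
#' @param path Path to a JSON file of `run_config` fields.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}
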