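#' Binarize spike probabilities at a population threshold
#'
#' The threshold is `sd_multiplier` times the population SD of all pooled
#' spike-probability values in the field of view. "SD above zero" is taken
#' literally as the root-mean-square about zero (`center = "zero"`, the
#' default); `center = "mean"` instead uses `mean + sd_multiplier * SD`.
#' Values strictly above the threshold become 1.
#'
#' @param spikes A `spike_prob_tbl` from [infer_spikes()] (values in `[0, 1]`).
#' @param sd_multiplier Threshold multiplier (default 3).
#' @param center `"zero"` or `"mean"`.
#' @return A 0/1 tibble of class `binary_raster` with attributes
#'   `threshold_value`, `sd_multiplier` and `center`.
#' @export
binarize <- function(spikes, sd_multiplier = 3, center = c("zero", "mean")) {
  center <- match.arg(center)
  m <- trace_matrix(spikes)
  if (any(m < 0) || any(m > 1)) abort("spike probabilities must lie in [0, 1]")
  v <- as.vector(m)
  threshold <- if (center == "zero") {
    sd_multiplier * sqrt(mean(v^2))
  } else {
    mean(v) + sd_multiplier * sd(v)
  }
  as_binary_raster((m > threshold) * 1L, threshold_value = threshold,
                   sd_multiplier = sd_multiplier, center = center)
}

#' @rdname binarize
#' @param active A 0/1 matrix or data frame, frames x cells (e.g. a
#'   ground-truth spike raster used directly as thresholded activity).
#' @param threshold_value,center Threshold metadata to record.
#' @export
as_binary_raster <- function(active, threshold_value = NA_real_,
                             sd_multiplier = NA_real_, center = NA_character_) {
  m <- trace_matrix(active)
  if (!all(m %in% c(0, 1))) abort("raster values must be 0/1")
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- paste0("cell_", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  attr(out, "threshold_value") <- threshold_value
  attr(out, "sd_multiplier") <- sd_multiplier
  attr(out, "center") <- center
  class(out) <- unique(c("binary_raster", class(out)))
  out
}

#' Shuffle null for per-frame co-activity
#'
#' Estimates how many cells must be co-active in one frame before the count is
#' statistically surprising, by destroying all cross-cell correlation while
#' preserving each cell's total activity: each of `n_shuffles` surrogates
#' independently permutes every cell's activity across frames
#' (`shuffle_mode = "permute"`) or circularly shifts it
#' (`shuffle_mode = "circular"`, preserving autocorrelation).
#'
#' Two significance conventions are available. `null_mode = "max"` (default)
#' compares candidate counts against the distribution of each surrogate's
#' maximum per-frame co-activity, controlling the probability of any false
#' high-activity frame per recording at `alpha`. `null_mode = "pooled"` uses
#' the pooled per-frame co-activity distribution across all surrogate frames,
#' an uncorrected per-frame test (anti-conservative over a whole recording;
#' see the package vignette).
#'
#' @param raster A [binarize()] raster (or any 0/1 frames x cells table).
#' @param n_shuffles Number of surrogates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed for the surrogate draws.
#' @param shuffle_mode `"permute"` or `"circular"`.
#' @param null_mode `"max"` or `"pooled"`.
#' @return A list of class `coactivity_null`: `coactivity_threshold` (the
#'   smallest count `c >= 2` with null `p(c) < alpha`; `NA` if the raster has
#'   no activity or no count is significant), `null` (tibble of candidate
#'   `coactivity` counts and their null `p`), plus the parameters. The pooled
#'   and max p-value curves are both retained (`p_pooled`, `p_max`).
#' @export
shuffle_null <- function(raster, n_shuffles = 1000, alpha = 0.05, seed = NULL,
                         shuffle_mode = c("permute", "circular"),
                         null_mode = c("max", "pooled")) {
  shuffle_mode <- match.arg(shuffle_mode)
  null_mode <- match.arg(null_mode)
  stopifnot(n_shuffles >= 1, alpha > 0, alpha < 1)
  m <- trace_matrix(raster)
  nf <- nrow(m); nc <- ncol(m)
  k <- colSums(m)
  base <- list(alpha = alpha, n_shuffles = n_shuffles, seed = seed,
               shuffle_mode = shuffle_mode, null_mode = null_mode,
               n_frames = nf, n_cells = nc)
  if (sum(k) == 0) {
    out <- c(base, list(coactivity_threshold = NA_integer_, no_activity = TRUE,
                        null = tibble::tibble(coactivity = integer(),
                                              p_pooled = numeric(), p_max = numeric())))
    class(out) <- "coactivity_null"
    return(out)
  }
  active_frames <- lapply(seq_len(nc), function(j) which(m[, j] == 1L))
  counts <- with_seed(seed, {
    cnt <- matrix(0L, nf, n_shuffles)
    for (s in seq_len(n_shuffles)) {
      idx <- if (shuffle_mode == "permute") {
        # a full per-cell permutation moves each cell's k_j active entries to
        # k_j uniformly drawn distinct frames; only frame counts are needed
        unlist(lapply(k, function(kj) if (kj > 0) sample.int(nf, kj) else integer(0)),
               use.names = FALSE)
      } else {
        shifts <- sample.int(nf, nc, replace = TRUE) - 1L
        unlist(lapply(seq_len(nc), function(j) {
          if (k[j] > 0) ((active_frames[[j]] + shifts[j] - 1L) %% nf) + 1L else integer(0)
        }), use.names = FALSE)
      }
      cnt[, s] <- tabulate(idx, nbins = nf)
    }
    cnt
  })
  cmax <- max(counts, max(rowSums(m)))
  cand <- 2:max(2, cmax)
  pooled_tail <- vapply(cand, function(c) mean(counts >= c), numeric(1))
  shuffle_max <- apply(counts, 2, max)
  max_tail <- vapply(cand, function(c) mean(shuffle_max >= c), numeric(1))
  p <- if (null_mode == "pooled") pooled_tail else max_tail
  hit <- which(p < alpha)
  threshold <- if (length(hit)) cand[hit[1]] else NA_integer_
  out <- c(base, list(
    coactivity_threshold = threshold, no_activity = FALSE,
    null = tibble::tibble(coactivity = cand, p_pooled = pooled_tail, p_max = max_tail)))
  class(out) <- "coactivity_null"
  out
}

#' Materialize one shuffled surrogate raster
#'
#' Companion to [shuffle_null()] for inspection and testing: applies the same
#' per-cell permutation (or circular shift) scheme and returns the full
#' surrogate raster, whose column sums always equal the original's.
#'
#' @inheritParams shuffle_null
#' @return A `binary_raster` of the same shape as `raster`.
#' @export
shuffle_raster <- function(raster, seed = NULL,
                           shuffle_mode = c("permute", "circular")) {
  shuffle_mode <- match.arg(shuffle_mode)
  m <- trace_matrix(raster)
  nf <- nrow(m)
  out <- with_seed(seed, {
    apply(m, 2, function(col) {
      if (shuffle_mode == "permute") {
        col[sample.int(nf)]
      } else {
        shift <- sample.int(nf, 1) - 1L
        col[((seq_len(nf) - 1L - shift) %% nf) + 1L]
      }
    })
  })
  colnames(out) <- colnames(m)
  as_binary_raster(out)
}

#' Detect network ensembles (significant high-activity frames)
#'
#' Every frame whose co-active cell count reaches the null-derived threshold
#' is a high-activity frame, and the cells active in it form one network
#' ensemble. Consecutive significant frames with identical member sets are
#' merged into a single event. The threshold is floored at 2: a single active
#' cell is never an ensemble.
#'
#' @param raster A `binary_raster`.
#' @param null A `coactivity_null` from [shuffle_null()], or a bare integer
#'   threshold.
#' @return An object of class `ensemble_set`; see [summarize_ensembles()],
#'   [find_core_ensembles()], [tidy.ensemble_set()].
#' @export
detect_ensembles <- function(raster, null) {
  m <- trace_matrix(raster)
  if (inherits(null, "coactivity_null")) {
    threshold <- null$coactivity_threshold
    null_info <- null
  } else {
    threshold <- null
    null_info <- NULL
  }
  ensembles <- tibble::tibble(ensemble_id = integer(), frame_start = integer(),
                              frame_end = integer(), n_cells = integer(),
                              members = list())
  if (!is.na(threshold)) {
    threshold <- max(2L, as.integer(threshold))
    co <- rowSums(m)
    sig <- which(co >= threshold)
    if (length(sig)) {
      sets <- lapply(sig, function(f) colnames(m)[m[f, ] == 1L])
      keep <- rep(TRUE, length(sig))
      ends <- sig
      for (i in seq_along(sig)[-1]) {
        prev <- max(which(keep[seq_len(i - 1)]))
        if (sig[i] == ends[prev] + 1L && identical(sets[[i]], sets[[prev]])) {
          keep[i] <- FALSE
          ends[prev] <- sig[i]
        }
      }
      idx <- which(keep)
      ensembles <- tibble::tibble(
        ensemble_id = seq_along(idx),
        frame_start = sig[idx],
        frame_end = ends[idx],
        n_cells = lengths(sets[idx]),
        members = sets[idx])
    }
  }
  out <- list(ensembles = ensembles,
              cores = NULL,
              coactivity_threshold = if (is.na(threshold)) NA_integer_ else threshold,
              threshold_value = attr(raster, "threshold_value"),
              sd_multiplier = attr(raster, "sd_multiplier"),
              null = null_info,
              n_frames = nrow(m), n_cells = ncol(m),
              raster = m)
  class(out) <- "ensemble_set"
  out$cores <- find_core_ensembles(out)
  out
}

#' Extract core ensembles
#'
#' A core ensemble is a group of cells co-activated in more than one network
#' ensemble: every pairwise intersection of ensemble member sets with at least
#' 2 cells is a candidate, candidates that are subsets of another candidate
#' are dropped (maximal sets kept), and each core records all ensembles whose
#' member sets contain it.
#'
#' @param x An `ensemble_set`.
#' @return A tibble: `core_id`, `n_cells`, `members` (list), `parents` (list
#'   of ensemble ids), `n_parents`.
#' @export
find_core_ensembles <- function(x) {
  stopifnot(inherits(x, "ensemble_set"))
  ens <- x$ensembles$members
  empty <- tibble::tibble(core_id = integer(), n_cells = integer(),
                          members = list(), parents = list(), n_parents = integer())
  if (length(ens) < 2) return(empty)
  cand <- list()
  for (i in seq_along(ens)[-length(ens)]) {
    for (j in (i + 1):length(ens)) {
      int <- sort(intersect(ens[[i]], ens[[j]]))
      if (length(int) >= 2) cand[[length(cand) + 1]] <- int
    }
  }
  if (!length(cand)) return(empty)
  cand <- unique(cand)
  maximal <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      i != j && length(cand[[i]]) < length(cand[[j]]) && all(cand[[i]] %in% cand[[j]])
    }, logical(1)))
  }, logical(1))
  cores <- cand[maximal]
  parents <- lapply(cores, function(cc) {
    which(vapply(ens, function(e) all(cc %in% e), logical(1)))
  })
  tibble::tibble(core_id = seq_along(cores), n_cells = lengths(cores),
                 members = cores, parents = parents, n_parents = lengths(parents))
}

#' Summary counts for an ensemble set
#'
#' @param x An `ensemble_set`.
#' @return A one-row tibble: `n_ensembles`, `mean_cells_per_ensemble`,
#'   `n_core_ensembles`, `mean_cells_per_core`, `coactivity_threshold`.
#' @export
summarize_ensembles <- function(x) {
  stopifnot(inherits(x, "ensemble_set"))
  cores <- if (is.null(x$cores)) find_core_ensembles(x) else x$cores
  tibble::tibble(
    n_ensembles = nrow(x$ensembles),
    mean_cells_per_ensemble = if (nrow(x$ensembles)) mean(x$ensembles$n_cells) else 0,
    n_core_ensembles = nrow(cores),
    mean_cells_per_core = if (nrow(cores)) mean(cores$n_cells) else 0,
    coactivity_threshold = x$coactivity_threshold
  )
}

#' Run the spike-probability-to-ensembles stage in one call
#'
#' [binarize()], [shuffle_null()], [detect_ensembles()] and
#' [find_core_ensembles()] chained under one [run_config()].
#'
#' @param spikes A `spike_prob_tbl` (or a 0/1 raster, which skips
#'   binarization).
#' @param config A [run_config()].
#' @return An `ensemble_set`.
#' @export
run_ensemble_analysis <- function(spikes, config = run_config()) {
  raster <- if (inherits(spikes, "binary_raster")) {
    spikes
  } else {
    binarize(spikes, sd_multiplier = config$sd_multiplier,
             center = config$binarize_center)
  }
  null <- shuffle_null(raster, n_shuffles = config$n_shuffles,
                       alpha = config$alpha, seed = config$seed,
                       shuffle_mode = config$shuffle_mode,
                       null_mode = config$null_mode)
  detect_ensembles(raster, null)
}

#' @export
print.ensemble_set <- function(x, ...) {
  s <- summarize_ensembles(x)
  cat(sprintf("<ensemble_set> %d ensembles (mean %.2f cells), %d core ensembles, co-activity threshold %s\n",
              s$n_ensembles, s$mean_cells_per_ensemble, s$n_core_ensembles,
              format(s$coactivity_threshold)))
  invisible(x)
}

#' Tidy an ensemble set into one row per ensemble
#'
#' @param x An `ensemble_set`.
#' @param ... Unused.
#' @return A tibble with `ensemble_id`, `frame_start`, `frame_end`,
#'   `n_cells`, `members`.
#' @export
tidy.ensemble_set <- function(x, ...) x$ensembles

#' One-row model summary of an ensemble set
#'
#' @inheritParams tidy.ensemble_set
#' @export
glance.ensemble_set <- function(x, ...) summarize_ensembles(x)
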