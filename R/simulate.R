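#' Simulation configuration for a synthetic recording
#'
#' Describes one synthetic field of view the way the analysis assumes real
#' recordings look: `n_cells` somata imaged for `n_frames` frames at one frame
#' per `frame_period` seconds, Poisson-like background firing, scheduled
#' multi-cell co-activation events ("planted ensembles"), AR(1) calcium
#' kinetics, a per-cell baseline with optional linear drift, and additive
#' Gaussian noise. Defaults emulate a 10-minute, 120-frame recording at 0.2 Hz
#' of ~120 cells, with sparse spontaneous firing.
#'
#' @param n_cells Number of cells (ROIs).
#' @param n_frames Number of frames (default 120).
#' @param frame_period Seconds per frame (default 5).
#' @param background_rate Probability a cell fires in a frame outside any
#'   scheduled event (independent Bernoulli per cell per frame).
#' @param ensembles A list of planted ensembles, each a list or named vector
#'   with `member_count`, `n_events` and `participation_prob` (see
#'   [planted_ensemble()]).
#' @param calcium_amplitude Fractional fluorescence change (dF/F units) added
#'   per spike.
#' @param gamma_true Per-frame AR(1) calcium decay in (0,1); default
#'   `exp(-frame_period / 2)` (a 2 s indicator decay constant).
#' @param baseline_f0 Per-cell resting fluorescence, arbitrary units; a scalar
#'   or length-`n_cells` vector.
#' @param noise_sd SD of additive Gaussian noise, arbitrary units.
#' @param drift_slope Baseline drift in arbitrary units per frame.
#' @param seed RNG seed; fixed seed makes every output bit-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 120,
                       n_frames = 120,
                       frame_period = 5,
                       background_rate = 0.02,
                       ensembles = list(),
                       calcium_amplitude = 1,
                       gamma_true = NULL,
                       baseline_f0 = 50,
                       noise_sd = 2,
                       drift_slope = 0,
                       seed = NULL) {
  if (is.null(gamma_true)) gamma_true <- exp(-frame_period / 2)
  stopifnot(n_cells >= 1, n_frames >= 1, frame_period > 0,
            background_rate >= 0, background_rate <= 1,
            calcium_amplitude >= 0,
            gamma_true > 0, gamma_true < 1,
            all(baseline_f0 > 0), noise_sd >= 0)
  ensembles <- lapply(ensembles, function(e) {
    e <- as.list(e)
    do.call(planted_ensemble, e[c("member_count", "n_events", "participation_prob")])
  })
  n_events_total <- sum(vapply(ensembles, `[[`, numeric(1), "n_events"))
  if (n_events_total > n_frames) abort("more scheduled ensemble events than frames")
  for (e in ensembles) {
    if (e$member_count > n_cells) abort("ensemble member_count exceeds n_cells")
  }
  structure(list(n_cells = n_cells, n_frames = n_frames,
                 frame_period = frame_period,
                 background_rate = background_rate, ensembles = ensembles,
                 calcium_amplitude = calcium_amplitude, gamma_true = gamma_true,
                 baseline_f0 = rep_len(baseline_f0, n_cells),
                 noise_sd = noise_sd, drift_slope = drift_slope, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @param member_count Cells recruited by the ensemble.
#' @param n_events Number of scheduled co-activation events.
#' @param participation_prob Probability each member actually spikes at an
#'   event.
#' @export
planted_ensemble <- function(member_count, n_events = 1, participation_prob = 1) {
  stopifnot(member_count >= 1, n_events >= 1,
            participation_prob > 0, participation_prob <= 1)
  list(member_count = member_count, n_events = n_events,
       participation_prob = participation_prob)
}

#' Generate a ground-truth spike raster with planted ensembles
#'
#' Background spikes are independent Bernoulli(`background_rate`) draws per
#' cell per frame. Each planted ensemble is assigned a fixed random member set
#' and `n_events` distinct event frames (drawn without replacement across all
#' ensembles); at an event frame each member spikes with
#' `participation_prob`. The schedule is returned alongside the raster so
#' detection can be scored against a known answer.
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth`: `spikes` (0/1 matrix, frames x
#'   cells), `schedule` (tibble with `frame`, `ensemble`, `members` list
#'   column of the scheduled member cells, and `spiking` list column of the
#'   members that actually spiked).
#' @export
generate_spike_trains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nf <- config$n_frames; nc <- config$n_cells
    spikes <- matrix(rbinom(nf * nc, 1L, config$background_rate), nf, nc)
    colnames(spikes) <- paste0("cell_", seq_len(nc))
    n_events <- vapply(config$ensembles, `[[`, numeric(1), "n_events")
    schedule <- tibble::tibble(frame = integer(), ensemble = integer(),
                               members = list(), spiking = list())
    if (length(config$ensembles)) {
      frames <- sample.int(nf, sum(n_events))
      k <- 0L
      for (i in seq_along(config$ensembles)) {
        e <- config$ensembles[[i]]
        members <- sort(sample.int(nc, e$member_count))
        for (j in seq_len(e$n_events)) {
          k <- k + 1L
          f <- frames[k]
          hit <- members[runif(length(members)) <= e$participation_prob]
          spikes[f, hit] <- 1L
          schedule <- dplyr::bind_rows(schedule, tibble::tibble(
            frame = f, ensemble = i, members = list(members),
            spiking = list(sort(which(spikes[f, ] == 1L)))))
        }
      }
      schedule <- dplyr::arrange(schedule, .data$frame)
    }
    structure(list(spikes = spikes, schedule = schedule, config = config),
              class = "ground_truth")
  })
}

#' Render a spike raster into noisy fluorescence traces
#'
#' Forward model inverted by the deconvolution stage. Per cell, calcium
#' follows `C_t = gamma_true * C_{t-1} + spike_t` with `C_1` set by the first
#' frame's spikes, and fluorescence is
#' `F_t = baseline_f0 * (1 + calcium_amplitude * C_t) + drift_slope * t +
#' N(0, noise_sd)`, clipped at zero. The multiplicative form makes the
#' ground-truth dF/F amplitude independent of the cell's baseline brightness.
#'
#' @param truth A `ground_truth` from [generate_spike_trains()].
#' @param config A [sim_config()]; defaults to the one stored in `truth`.
#' @return A [trace_tbl()] of noisy fluorescence, frames x cells.
#' @export
render_fluorescence <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  spikes <- truth$spikes
  nf <- nrow(spikes); nc <- ncol(spikes)
  calcium <- apply(spikes, 2, function(s) {
    as.numeric(stats::filter(s, config$gamma_true, method = "recursive"))
  })
  calcium <- matrix(calcium, nf, nc)
  f0 <- matrix(config$baseline_f0, nf, nc, byrow = TRUE)
  drift <- matrix(config$drift_slope * seq_len(nf), nf, nc)
  seed <- if (is.null(config$seed)) NULL else config$seed + 1
  noise <- with_seed(seed, matrix(rnorm(nf * nc, 0, config$noise_sd), nf, nc))
  f <- f0 * (1 + config$calcium_amplitude * calcium) + drift + noise
  f <- pmax(f, 0)
  colnames(f) <- colnames(spikes)
  trace_tbl(f, frame_period = config$frame_period, fov_id = "simulated")
}

#' Simulate a full synthetic recording
#'
#' Convenience wrapper: [generate_spike_trains()] then [render_fluorescence()].
#'
#' @param config A [sim_config()].
#' @return A list with `traces` (a [trace_tbl()]) and `truth` (the
#'   `ground_truth`).
#' @export
simulate_recording <- function(config) {
  truth <- generate_spike_trains(config)
  list(traces = render_fluorescence(truth, config), truth = truth)
}

#' Generate a synthetic dendritic spine record table
#'
#' One row per spine (plus one placeholder row for spineless dendrites so the
#' dendrite is preserved for density computation). Spine counts per dendrite
#' are Poisson with mean `mean_density * segment_length / 10`; spine lengths
#' are log-normal with median ~1.5 um, truncated to the admissible range of
#' the context (at least 0.4 um; at most 10 um in vitro).
#'
#' @param n_dendrites Number of dendrite segments.
#' @param mean_density Expected spines per 10 um.
#' @param segment_length Analyzed shaft length in um (default 100 ex vivo,
#'   use 20 for the in vitro distal-segment convention).
#' @param context `"ex-vivo"` or `"in-vitro"`.
#' @param marker_prob Probability a spine is scored positive for the
#'   postsynaptic marker (e.g. PSD-95).
#' @param length_sdlog SD of log spine length.
#' @param length_median Median spine length in um.
#' @param shaft_width_range Range for ex vivo shaft widths (um).
#' @param animal Animal label(s) recycled across dendrites.
#' @param seed RNG seed.
#' @return A tibble: `dendrite_id`, `animal`, `context`, `segment_length`,
#'   `shaft_width`, `well_separated`, `spine_id`, `spine_length`,
#'   `marker_positive`. Placeholder rows for spineless dendrites carry
#'   `spine_id = NA`.
#' @export
generate_spine_records <- function(n_dendrites,
                                   mean_density,
                                   segment_length = 100,
                                   context = c("ex-vivo", "in-vitro"),
                                   marker_prob = 0.15,
                                   length_sdlog = 0.35,
                                   length_median = 1.5,
                                   shaft_width_range = c(2, 4),
                                   animal = "animal_1",
                                   seed = NULL) {
  context <- match.arg(context)
  if (segment_length <= 0) abort("`segment_length` must be positive")
  if (mean_density < 0) abort("`mean_density` must be non-negative")
  lo <- 0.4
  hi <- if (context == "in-vitro") 10 else Inf
  with_seed(seed, {
    animal <- rep_len(animal, n_dendrites)
    counts <- rpois(n_dendrites, mean_density * segment_length / 10)
    widths <- if (context == "ex-vivo") {
      runif(n_dendrites, shaft_width_range[1], shaft_width_range[2])
    } else rep(NA_real_, n_dendrites)
    # spineless dendrites keep one placeholder row so density sees them
    rows_per <- pmax(counts, 1L)
    idx <- rep.int(seq_len(n_dendrites), rows_per)
    has_spine <- rep.int(counts > 0, rows_per)
    n_spines <- sum(counts)
    lengths <- rtrunc_lnorm(n_spines, meanlog = log(length_median),
                            sdlog = length_sdlog, lo = lo, hi = hi)
    tibble::tibble(
      dendrite_id = sprintf("dend_%05d", idx),
      animal = animal[idx],
      context = context,
      segment_length = segment_length,
      shaft_width = widths[idx],
      well_separated = TRUE,
      spine_id = ifelse(has_spine, stats::ave(idx, idx, FUN = seq_along), NA_integer_),
      spine_length = replace(rep(NA_real_, length(idx)), has_spine, lengths),
      marker_positive = replace(rep(NA, length(idx)), has_spine,
                                runif(n_spines) < marker_prob))
  })
}

# Truncated log-normal via rejection; the admissible ranges keep the
# acceptance probability near 1 for the defaults used here.
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a two-level spine experiment (animals then dendrites)
#'
#' Each animal draws its own mean density from
#' `Normal(mean_density, sd_between)` (floored at 0), then contributes
#' `dendrites_per_animal` dendrites via [generate_spine_records()]. This
#' mirrors study designs in which the animal, not the dendrite, is the
#' statistical unit.
#'
#' @param n_animals Number of animals.
#' @param dendrites_per_animal Dendrites analyzed per animal.
#' @param mean_density Group mean density, spines per 10 um.
#' @param sd_between Between-animal SD of the mean density.
#' @param group Group label stored on every row.
#' @param seed RNG seed.
#' @inheritParams generate_spine_records
#' @return A tibble as in [generate_spine_records()], plus `group`.
#' @export
simulate_spine_experiment <- function(n_animals,
                                      dendrites_per_animal,
                                      mean_density,
                                      sd_between = 0,
                                      segment_length = 100,
                                      context = "ex-vivo",
                                      group = "group",
                                      marker_prob = 0.15,
                                      seed = NULL) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_animals), function(a) {
      dens <- max(0, rnorm(1, mean_density, sd_between))
      rec <- generate_spine_records(dendrites_per_animal, dens,
                                    segment_length = segment_length,
                                    context = context, marker_prob = marker_prob,
                                    animal = sprintf("%s_animal_%02d", group, a))
      rec$dendrite_id <- paste0(rec$animal, "_", rec$dendrite_id)
      rec
    })
    dplyr::mutate(dplyr::bind_rows(rows), group = group, .before = 1)
  })
}
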