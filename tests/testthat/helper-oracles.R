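# Independent oracles used across the suite. Each deliberately takes the
# slow, literal route (explicit loops, full sorts, generic first-order
# optimization, exhaustive enumeration) so it shares no code path with the
# implementation it checks.

# Per-frame dF/F by explicit loop and full sort: baseline at frame t is the
# mean of the floor(w * lower_fraction) smallest of the w = min(window, t-1)
# previous values (at least one), dff_1 = 0.
oracle_dff <- function(f, window = 10, lower_fraction = 0.5) {
  n <- length(f)
  out <- numeric(n)
  for (t in seq_len(n)) {
    if (t == 1) next
    w <- min(window, t - 1)
    prev <- sort(f[(t - w):(t - 1)])
    k <- max(1, floor(w * lower_fraction))
    baseline <- sum(prev[1:k]) / k
    out[t] <- (f[t] - baseline) / baseline
  }
  out
}

# Generic constrained-QP solve of the deconvolution program by accelerated
# projected gradient (FISTA) on the spike-amplitude parameterization
# s >= 0, C = Dinv s. First-order, dense in iterations, no barrier, no
# tridiagonal structure: independent of the interior-point implementation.
oracle_deconvolve_qp <- function(y, gamma, lambda, sigma, iters = 10000) {
  n <- length(y)
  dinv <- function(s) as.numeric(stats::filter(s, gamma, method = "recursive"))
  dinv_t <- function(v) rev(as.numeric(stats::filter(rev(v), gamma, method = "recursive")))
  lip <- (1 / (1 - gamma))^2 / sigma^2
  s <- pmax(y, 0)
  z <- s
  tk <- 1
  for (i in seq_len(iters)) {
    grad <- dinv_t(dinv(z) - y) / sigma^2 + lambda
    s_new <- pmax(z - grad / lip, 0)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- s_new + (tk - 1) / t_new * (s_new - s)
    s <- s_new
    tk <- t_new
  }
  C <- dinv(s)
  list(spikes = s, calcium = C,
       objective = sum((y - C)^2) / (2 * sigma^2) + lambda * sum(s))
}

# Exhaustive per-cell permutation null for a small raster: each cell's k_j
# active frames land uniformly on one of the choose(nf, k_j) frame subsets;
# enumerate every combination and accumulate the exact pooled per-frame
# co-activity distribution.
oracle_exact_coactivity <- function(raster) {
  m <- as.matrix(raster)
  nf <- nrow(m)
  k <- colSums(m)
  subsets <- lapply(k, function(kj) {
    if (kj == 0) return(list(integer(0)))
    cmb <- utils::combn(nf, kj)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  })
  grid <- expand.grid(lapply(subsets, seq_along))
  counts <- integer(nf + 1)  # counts[c + 1] = number of (config, frame) at co-activity c
  for (r in seq_len(nrow(grid))) {
    co <- integer(nf)
    for (j in seq_along(subsets)) {
      sel <- subsets[[j]][[grid[r, j]]]
      co[sel] <- co[sel] + 1L
    }
    tb <- tabulate(co + 1L, nbins = nf + 1)
    counts <- counts + tb
  }
  counts / sum(counts)  # exact P(frame co-activity = c), c = 0..nf
}

# Core-ensemble extraction by literal re-enumeration: all pairs, intersections
# of size >= 2, subset-maximal filtering, parent lookup.
oracle_core_ensembles <- function(member_sets) {
  cand <- list()
  n <- length(member_sets)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- sort(intersect(member_sets[[i]], member_sets[[j]]))
      if (length(v) >= 2 && !any(vapply(cand, identical, logical(1), y = v))) {
        cand[[length(cand) + 1]] <- v
      }
    }
  }
  keep <- list()
  for (i in seq_along(cand)) {
    dominated <- FALSE
    for (j in seq_along(cand)) {
      if (i != j && length(cand[[i]]) < length(cand[[j]]) &&
          all(cand[[i]] %in% cand[[j]])) dominated <- TRUE
    }
    if (!dominated) keep[[length(keep) + 1]] <- cand[[i]]
  }
  lapply(keep, function(v) {
    list(members = v,
         parents = which(vapply(member_sets, function(e) all(v %in% e), logical(1))))
  })
}

# Jaccard similarity of two label sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best-match mean Jaccard of detected ensembles against the truly co-active
# cell sets at the scheduled frames.
recovery_jaccard <- function(es, truth) {
  sched <- truth$schedule
  vapply(seq_len(nrow(sched)), function(i) {
    truth_set <- colnames(truth$spikes)[truth$spikes[sched$frame[i], ] == 1]
    if (!nrow(es$ensembles)) return(0)
    max(vapply(es$ensembles$members, jaccard, numeric(1), b = truth_set))
  }, numeric(1))
}

# Single planted-event trace at a given dF/F signal-to-noise ratio.
make_single_spike_trace <- function(n_frames, spike_frame, gamma, snr, seed) {
  amplitude <- 1
  noise_sd <- amplitude / snr
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr
  }
  withr_seed(seed, {
    s <- numeric(n_frames)
    s[spike_frame] <- amplitude
    calcium <- as.numeric(stats::filter(s, gamma, method = "recursive"))
    calcium + rnorm(n_frames, 0, noise_sd)
  })
}

# Fresh temp file path cleaned up with the test process's tempdir.
withr_tempfile <- function(ext = ".csv") {
  tempfile("coactive-test-", fileext = ext)
}
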