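#' Robust high-frequency noise estimate for a dF/F trace
#'
#' MAD-based estimator on first differences: the median absolute first
#' difference divided by `sqrt(2) * 0.6745`. Differencing removes slow trends
#' and calcium transients contribute little to the median at realistic firing
#' rates, so the estimate tracks the additive noise SD. Floored at 1e-6 so a
#' constant trace never produces a zero noise level.
#'
#' @param dff_trace Numeric vector, one cell's dF/F series (>= 4 frames).
#' @return The estimated noise SD (dF/F units).
#' @export
estimate_noise_sd <- function(dff_trace) {
  stopifnot(is.numeric(dff_trace), length(dff_trace) >= 4, all(is.finite(dff_trace)))
  max(median(abs(diff(dff_trace))) / (sqrt(2) * 0.6745), 1e-6)
}

#' Fast non-negative deconvolution of one calcium trace
#'
#' Infers a non-negative spike amplitude series `s` from a dF/F trace `y`
#' under the AR(1) calcium model `C_t = gamma * C_{t-1} + s_t`: it solves the
#' convex program
#'
#' \deqn{\min_C \; \frac{1}{2\sigma^2}\sum_t (y_t - C_t)^2 +
#'       \lambda \sum_t s_t, \quad s_t = C_t - \gamma C_{t-1} \ge 0}
#'
#' (with `s_1 = C_1`) by a log-barrier interior-point method. Because the
#' constraint matrix is bidiagonal, the Newton systems are tridiagonal and
#' each step costs O(n) (Thomas algorithm), which is what makes the method
#' "fast". The sparsity weight `lambda` acts as an exponential prior on total
#' spiking: larger values shrink `s` toward zero.
#'
#' @param dff_trace Numeric dF/F vector for one cell.
#' @param gamma AR(1) decay per frame, in (0,1).
#' @param sparsity_weight Non-negative weight `lambda`; default `1 / sigma`.
#' @param noise_sd Noise SD `sigma`; default [estimate_noise_sd()] of the
#'   trace.
#' @param tolerance Relative duality-gap target (default 1e-9 of the
#'   objective magnitude).
#' @param max_newton Iteration cap across all barrier stages.
#' @return A list: `spikes` (s, >= 0), `calcium` (fitted C), `objective`,
#'   `objective_path` (objective after each barrier stage), `gap` (final
#'   duality-gap bound), `iterations`, `converged`, and the model parameters.
#' @export
deconvolve <- function(dff_trace, gamma,
                       sparsity_weight = NULL, noise_sd = NULL,
                       tolerance = 1e-9, max_newton = 500) {
  y <- as.numeric(dff_trace)
  if (!all(is.finite(y))) abort("non-finite values in trace")
  stopifnot(gamma > 0, gamma < 1)
  n <- length(y)
  if (is.null(noise_sd)) noise_sd <- if (n >= 4) estimate_noise_sd(y) else max(sd(y), 1e-6)
  if (is.null(sparsity_weight)) sparsity_weight <- 1 / noise_sd
  stopifnot(noise_sd > 0, sparsity_weight >= 0)
  lam <- sparsity_weight; sig2 <- noise_sd^2

  if (all(y == 0)) {
    return(list(spikes = numeric(n), calcium = numeric(n), objective = 0,
                objective_path = 0, gap = 0, iterations = 0L, converged = TRUE,
                gamma = gamma, sparsity_weight = lam, noise_sd = noise_sd))
  }

  Dmul <- function(C) c(C[1], C[-1] - gamma * C[-n])          # s = D C
  Dtmul <- function(v) v - gamma * c(v[-1], 0)                # D^T v
  Dinv <- function(s) as.numeric(stats::filter(s, gamma, method = "recursive"))
  fobj <- function(C, s) sum((y - C)^2) / (2 * sig2) + lam * sum(s)

  # strictly feasible start: positive spikes roughly matched to the data scale
  s <- pmax(Dmul(pmax(y, 0)), 0) + 0.1 * max(abs(y))
  C <- Dinv(s)
  obj <- fobj(C, s)
  obj_scale <- max(1, abs(obj))
  mu <- obj_scale / n
  iters <- 0L
  obj_path <- numeric(0)
  converged <- FALSE

  while (TRUE) {
    # Newton minimization of the barrier objective at this mu
    repeat {
      g <- (C - y) / sig2 + Dtmul(lam - mu / s)
      w <- mu / s^2
      dmain <- 1 / sig2 + w + gamma^2 * c(w[-1], 0)
      doff <- -gamma * w[-1]
      d <- solve_tridiag(dmain, doff, -g)
      decr <- -sum(g * d) / 2                      # Newton decrement^2 / 2
      if (!is.finite(decr) || decr <= 1e-12 * obj_scale || iters >= max_newton) break
      sd_ <- Dmul(d)
      step <- 1
      neg <- sd_ < 0
      if (any(neg)) step <- min(1, 0.99 * min(-s[neg] / sd_[neg]))
      phi0 <- obj - mu * sum(log(s))
      repeat {
        s_new <- s + step * sd_
        C_new <- C + step * d
        phi <- fobj(C_new, s_new) - mu * sum(log(s_new))
        if (is.finite(phi) && phi <= phi0 - 1e-4 * step * 2 * decr) break
        step <- step / 2
        if (step < 1e-12) break
      }
      if (step < 1e-12) break
      s <- s_new; C <- C_new; obj <- fobj(C, s)
      iters <- iters + 1L
    }
    obj_path <- c(obj_path, obj)
    if (n * mu <= tolerance * max(1, abs(obj))) { converged <- TRUE; break }
    if (iters >= max_newton) break
    mu <- mu / 10
  }

  list(spikes = s, calcium = C, objective = obj, objective_path = obj_path,
       gap = n * mu, iterations = iters, converged = converged,
       gamma = gamma, sparsity_weight = lam, noise_sd = noise_sd)
}

# Thomas algorithm for a symmetric tridiagonal system (main, off) x = b.
solve_tridiag <- function(main, off, b) {
  n <- length(main)
  if (n == 1) return(b / main)
  cp <- numeric(n - 1); dp <- numeric(n)
  cp[1] <- off[1] / main[1]
  dp[1] <- b[1] / main[1]
  for (i in 2:n) {
    m <- main[i] - off[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- off[i] / m
    dp[i] <- (b[i] - off[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Infer spike probabilities for every cell of a dF/F table
#'
#' Runs [deconvolve()] per cell and rescales the inferred amplitudes with
#' [to_spike_probability()] so each active cell peaks at 1.
#'
#' @param dff A dF/F table from [compute_dff()] (frames x cells).
#' @param gamma AR(1) decay per frame; default `exp(-frame_period /
#'   tau_decay)` using the table's frame period.
#' @param tau_decay Indicator decay constant in seconds (default 2).
#' @param sparsity_weight,noise_sd,tolerance Passed to [deconvolve()]
#'   (`NULL` = per-cell defaults).
#' @return A tibble of class `spike_prob_tbl`, frames x cells, values in
#'   `[0, 1]`; attributes `amplitudes` and `calcium` (matrices), `gamma`,
#'   `noise_sd` and `normalization` (per-cell vectors).
#' @export
infer_spikes <- function(dff, gamma = NULL, tau_decay = 2,
                         sparsity_weight = NULL, noise_sd = NULL,
                         tolerance = 1e-9) {
  m <- trace_matrix(dff)
  if (is.null(gamma)) gamma <- exp(-frame_period(dff) / tau_decay)
  fits <- lapply(seq_len(ncol(m)), function(j) {
    deconvolve(m[, j], gamma = gamma, sparsity_weight = sparsity_weight,
               noise_sd = noise_sd, tolerance = tolerance)
  })
  amps <- vapply(fits, `[[`, numeric(nrow(m)), "spikes")
  amps <- matrix(amps, nrow(m), ncol(m), dimnames = dimnames(m))
  calcium <- vapply(fits, `[[`, numeric(nrow(m)), "calcium")
  calcium <- matrix(calcium, nrow(m), ncol(m), dimnames = dimnames(m))
  out <- to_spike_probability(amps)
  attr(out, "calcium") <- calcium
  attr(out, "gamma") <- gamma
  attr(out, "noise_sd") <- vapply(fits, `[[`, numeric(1), "noise_sd")
  attr(out, "frame_period") <- frame_period(dff)
  out
}

#' Rescale deconvolved amplitudes to bounded spike probabilities
#'
#' Divides each cell's amplitude series by that cell's maximum, so values lie
#' in `[0, 1]` with the strongest inferred event at exactly 1; all-zero cells
#' stay all-zero. This max-normalization is a declared convention bridging
#' unbounded deconvolution amplitudes to a bounded per-frame activity measure,
#' and is isolated here so it can be swapped.
#'
#' @param amplitudes Non-negative matrix (or data frame), frames x cells.
#' @return A tibble of class `spike_prob_tbl` with attributes `amplitudes`
#'   (the input) and `normalization` (per-cell maxima).
#' @export
to_spike_probability <- function(amplitudes) {
  m <- trace_matrix(amplitudes)
  if (any(m < 0)) abort("negative amplitudes")
  if (is.null(colnames(m))) colnames(m) <- paste0("cell_", seq_len(ncol(m)))
  mx <- apply(m, 2, max)
  scale <- ifelse(mx > 0, mx, 1)
  out <- sweep(m, 2, scale, "/")
  res <- tibble::as_tibble(out)
  attr(res, "amplitudes") <- m
  attr(res, "normalization") <- mx
  class(res) <- unique(c("spike_prob_tbl", class(res)))
  res
}
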