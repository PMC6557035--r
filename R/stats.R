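#' Unpaired two-tailed Student t-test (pooled variance)
#'
#' Classical pooled-variance t with `df = n_a + n_b - 2` and a two-tailed p
#' from the t distribution. Degenerate inputs follow the natural limits: zero
#' pooled variance with equal means gives p = 1, with different means p = 0.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2, finite).
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`.
#' @export
unpaired_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(is.finite(group_a)), all(is.finite(group_b)))
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  if (sp2 == 0) {
    t_stat <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
  } else {
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(t_stat), df)
  }
  tibble::tibble(test = "unpaired two-tailed t", statistic = t_stat, df = df,
                 p_value = p, mean_a = ma, mean_b = mb,
                 sem_a = sd(group_a) / sqrt(na), sem_b = sd(group_b) / sqrt(nb),
                 n_a = na, n_b = nb)
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. With at most
#' `exact_max` observations in each group the two-tailed p-value comes from
#' exact enumeration of all group assignments of the pooled values (so ties
#' are handled exactly); for larger groups the normal approximation with
#' tie-corrected variance and a continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors (each n >= 1).
#' @param exact_max Largest per-group n for exact enumeration (default 8).
#' @return A one-row tibble: `test`, `statistic` (U of `group_a`),
#'   `u_prime` (U of `group_b`; `statistic + u_prime = n_a * n_b`), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 8) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1,
            all(is.finite(group_a)), all(is.finite(group_b)))
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  u_obs <- u_from_ranks(pooled, seq_len(na))
  u_prime <- na * nb - u_obs
  if (length(unique(pooled)) == 1) {
    p <- 1
    method <- "degenerate"
  } else if (na <= exact_max && nb <= exact_max) {
    method <- "exact"
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2, function(idx) u_from_ranks(pooled, idx))
    # two-tailed: double the smaller tail (with >= / <= at the observed U)
    p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  } else {
    method <- "normal"
    n <- na + nb
    ties <- table(pooled)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble::tibble(test = "Mann-Whitney U (two-tailed)", statistic = u_obs,
                 u_prime = u_prime, p_value = p, method = method,
                 median_a = median(group_a), median_b = median(group_b),
                 n_a = na, n_b = nb)
}

# U statistic of the subset `idx_a` of the pooled sample, via midranks:
# U_a = R_a - n_a (n_a + 1) / 2.
u_from_ranks <- function(pooled, idx_a) {
  r <- rank(pooled)
  na <- length(idx_a)
  sum(r[idx_a]) - na * (na + 1) / 2
}

#' Relative frequency distribution
#'
#' Histogram of proportions over half-open bins `[lo, hi)`; proportions sum
#' to 1 (the topmost edge is extended past the maximum so no value is lost).
#'
#' @param values Numeric vector (>= 1 value).
#' @param breaks Explicit bin edges (ascending). When `NULL`, edges are built
#'   from `binwidth` starting at `origin`.
#' @param binwidth Bin width used when `breaks` is `NULL` (default 1).
#' @param origin Left edge of the first bin (default `floor(min(values))`).
#' @return A tibble of class `rel_freq`: `bin_lo`, `bin_hi`, `midpoint`,
#'   `count`, `proportion`.
#' @export
relative_frequency <- function(values, breaks = NULL, binwidth = 1, origin = NULL) {
  if (length(values) < 1) abort("empty input")
  stopifnot(all(is.finite(values)))
  if (is.null(breaks)) {
    if (is.null(origin)) origin <- floor(min(values))
    n_bins <- max(1, ceiling((max(values) - origin) / binwidth + 1e-9))
    breaks <- origin + binwidth * (0:n_bins)
    if (max(values) >= breaks[length(breaks)]) {
      breaks <- c(breaks, breaks[length(breaks)] + binwidth)
    }
  } else {
    stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
    if (min(values) < breaks[1] || max(values) >= breaks[length(breaks)]) {
      abort("`breaks` must cover [min(values), max(values)] with half-open bins")
    }
  }
  idx <- findInterval(values, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  out <- tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    midpoint = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts,
    proportion = counts / length(values))
  class(out) <- unique(c("rel_freq", class(out)))
  out
}
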