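test_that("binarization thresholds at multiplier x RMS about zero", {
  # 100 pooled values engineered to RMS exactly 0.1
  rest <- sqrt((100 * 0.1^2 - 0.35^2 - 0.2^2) / 98)
  v <- c(0.35, 0.2, rep(rest, 98))
  m <- matrix(v, 10, 10)
  ras <- binarize(m, sd_multiplier = 3)
  expect_equal(attr(ras, "threshold_value"), 0.3, tolerance = 1e-12)
  expect_equal(trace_matrix(ras)[1, 1], 1L, ignore_attr = TRUE)  # 0.35 > 0.3
  expect_equal(trace_matrix(ras)[2, 1], 0L, ignore_attr = TRUE)  # 0.20 < 0.3
  expect_equal(sum(trace_matrix(ras)), 1)                        # rest < 0.3

  # all-zero matrix: threshold 0, strict inequality keeps everything 0
  zeros <- binarize(matrix(0, 5, 4))
  expect_equal(attr(zeros, "threshold_value"), 0)
  expect_true(all(trace_matrix(zeros) == 0))

  # brute-force elementwise comparison equals the vectorized raster
  set.seed(12)
  r <- matrix(runif(30 * 8), 30, 8)
  ras_r <- binarize(r)
  thr <- attr(ras_r, "threshold_value")
  manual <- matrix(0L, 30, 8)
  for (i in 1:30) for (j in 1:8) if (r[i, j] > thr) manual[i, j] <- 1L
  expect_equal(unname(trace_matrix(ras_r)), manual)

  # mean-centered variant uses mean + k * SD
  ras_m <- binarize(r, sd_multiplier = 2, center = "mean")
  expect_equal(attr(ras_m, "threshold_value"), mean(r) + 2 * sd(r))
})

test_that("shuffles preserve per-cell totals in both modes", {
  set.seed(30)
  m <- matrix(rbinom(120 * 100, 1, 0.01), 120, 100)
  # the conservation example: one spike per cell stays one spike per cell
  one_each <- diag(1L, 100)[rep(1:100, length.out = 100), ]
  for (mode in c("permute", "circular")) {
    for (seed in 1:5) {
      sh <- shuffle_raster(as_binary_raster(m), seed = seed, shuffle_mode = mode)
      expect_identical(unname(colSums(trace_matrix(sh))), unname(colSums(m)))
    }
    sh1 <- shuffle_raster(as_binary_raster(one_each), seed = 7, shuffle_mode = mode)
    expect_equal(sum(trace_matrix(sh1)), 100)
  }
})

test_that("the 1000-shuffle null matches exhaustive enumeration on a toy raster", {
  toy <- matrix(c(1, 0, 1, 0,
                  0, 1, 0, 0,
                  1, 1, 0, 1), 4, 3)
  exact <- oracle_exact_coactivity(toy)            # P(co-activity = c), c = 0..4
  exact_tail <- rev(cumsum(rev(exact)))            # P(co-activity >= c)
  nl <- shuffle_null(as_binary_raster(toy), n_shuffles = 1000, seed = 99,
                     null_mode = "pooled")
  for (c in 2:3) {
    p_hat <- nl$null$p_pooled[nl$null$coactivity == c]
    p_true <- exact_tail[c + 1]
    # conservative MC error: one dependent draw of 4 frames per shuffle
    se <- sqrt(p_true * (1 - p_true) / 1000)
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-12)
  }
})

test_that("the co-activity threshold moves with alpha and activity as expected", {
  set.seed(55)
  ras_lo <- as_binary_raster(matrix(rbinom(120 * 80, 1, 0.02), 120, 80))
  ras_hi <- as_binary_raster(matrix(rbinom(120 * 80, 1, 0.08), 120, 80))
  thr <- function(r, a) shuffle_null(r, n_shuffles = 300, alpha = a, seed = 4)$coactivity_threshold
  # non-increasing in alpha
  expect_true(thr(ras_lo, 0.01) >= thr(ras_lo, 0.05))
  expect_true(thr(ras_lo, 0.05) >= thr(ras_lo, 0.20))
  # non-decreasing in overall rate
  expect_true(thr(ras_hi, 0.05) >= thr(ras_lo, 0.05))
})

test_that("ensemble detection reports high-activity frames and merges runs", {
  m <- matrix(0L, 60, 12, dimnames = list(NULL, paste0("c", 1:12)))
  m[10, 1:8] <- 1L
  m[50, 1:8] <- 1L
  es <- detect_ensembles(as_binary_raster(m), 3)
  expect_equal(nrow(es$ensembles), 2)
  expect_equal(es$ensembles$n_cells, c(8L, 8L))
  expect_equal(es$ensembles$frame_start, c(10L, 50L))

  # nothing reaches threshold: empty set, zero summaries
  empty <- detect_ensembles(as_binary_raster(m), 9)
  expect_equal(nrow(empty$ensembles), 0)
  s <- summarize_ensembles(empty)
  expect_equal(s$n_ensembles, 0)
  expect_equal(s$mean_cells_per_ensemble, 0)

  # identical consecutive member sets merge into one event
  m2 <- matrix(0L, 20, 6, dimnames = list(NULL, paste0("c", 1:6)))
  m2[7:9, 1:4] <- 1L      # same 4 cells across 3 consecutive frames
  m2[15, 2:5] <- 1L
  es2 <- detect_ensembles(as_binary_raster(m2), 3)
  expect_equal(nrow(es2$ensembles), 2)
  expect_equal(es2$ensembles$frame_start[1], 7L)
  expect_equal(es2$ensembles$frame_end[1], 9L)

  # a different member set in between breaks the merge
  m2[8, 5] <- 1L
  es3 <- detect_ensembles(as_binary_raster(m2), 3)
  expect_equal(nrow(es3$ensembles), 4)
})

test_that("core ensembles are maximal multi-parent intersections", {
  m <- matrix(0L, 10, 5, dimnames = list(NULL, LETTERS[1:5]))
  m[2, 1:4] <- 1L            # {A, B, C, D}
  m[6, 3:5] <- 1L            # {C, D, E}
  es <- detect_ensembles(as_binary_raster(m), 3)
  expect_equal(nrow(es$cores), 1)
  expect_equal(es$cores$members[[1]], c("C", "D"))
  expect_equal(es$cores$parents[[1]], c(1L, 2L))

  # disjoint ensembles share no core
  m2 <- matrix(0L, 10, 8, dimnames = list(NULL, LETTERS[1:8]))
  m2[2, 1:4] <- 1L
  m2[6, 5:8] <- 1L
  expect_equal(nrow(detect_ensembles(as_binary_raster(m2), 3)$cores), 0)
})

test_that("core extraction agrees with brute-force enumeration on random ensembles", {
  set.seed(64)
  cells <- paste0("cell_", 1:30)
  for (rep in 1:10) {
    sets <- lapply(1:5, function(i) sort(sample(cells, sample(4:10, 1))))
    es <- list(ensembles = tibble::tibble(
      ensemble_id = 1:5, frame_start = 1:5 * 2, frame_end = 1:5 * 2,
      n_cells = lengths(sets), members = sets))
    class(es) <- "ensemble_set"
    got <- find_core_ensembles(es)
    ref <- oracle_core_ensembles(sets)
    expect_equal(nrow(got), length(ref))
    got_sets <- lapply(got$members, sort)
    ref_sets <- lapply(ref, `[[`, "members")
    perm <- match(sapply(got_sets, paste, collapse = "|"),
                  sapply(ref_sets, paste, collapse = "|"))
    expect_false(anyNA(perm))
    for (i in seq_along(perm)) {
      expect_equal(got$parents[[i]], ref[[perm[i]]]$parents)
    }
  }
})

test_that("ensemble summaries average member counts", {
  m <- matrix(0L, 30, 12, dimnames = list(NULL, paste0("c", 1:12)))
  m[4, 1:8] <- 1L
  m[20, 5:8] <- 1L
  s <- summarize_ensembles(detect_ensembles(as_binary_raster(m), 3))
  expect_equal(s$n_ensembles, 2)
  expect_equal(s$mean_cells_per_ensemble, 6)
})

test_that("the whole ensemble stage is deterministic under one seed", {
  cfg <- sim_config(n_cells = 50, n_frames = 120, background_rate = 0.02,
                    ensembles = list(planted_ensemble(8, 2)), seed = 77)
  ras <- as_binary_raster(generate_spike_trains(cfg)$spikes)
  rc <- run_config(n_shuffles = 200, seed = 5)
  a <- run_ensemble_analysis(ras, rc)
  b <- run_ensemble_analysis(ras, rc)
  expect_identical(a$ensembles, b$ensembles)
  expect_identical(a$cores, b$cores)
  expect_identical(a$coactivity_threshold, b$coactivity_threshold)
  expect_identical(a$null$null, b$null$null)
})

test_that("planted ensembles are recovered from their raster", {
  for (seed in 1:5) {
    cfg <- sim_config(n_cells = 100, n_frames = 120, background_rate = 0.005,
                      ensembles = rep(list(planted_ensemble(8, 1)), 3), seed = seed)
    truth <- generate_spike_trains(cfg)
    es <- run_ensemble_analysis(as_binary_raster(truth$spikes),
                                run_config(n_shuffles = 400, seed = seed + 1000))
    expect_equal(nrow(es$ensembles), 3)
    expect_true(all(recovery_jaccard(es, truth) >= 0.9))
  }
})

test_that("a silent raster yields the no-activity marker and an empty set", {
  nl <- shuffle_null(as_binary_raster(matrix(0L, 10, 5)), n_shuffles = 50, seed = 1)
  expect_true(nl$no_activity)
  expect_true(is.na(nl$coactivity_threshold))
  es <- detect_ensembles(as_binary_raster(matrix(0L, 10, 5)), nl)
  expect_equal(nrow(es$ensembles), 0)
})
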