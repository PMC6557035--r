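make_spines <- function(lengths, context = "ex-vivo", shaft = 3, seg = 120,
                        dendrite = "d1", marker = FALSE, animal = "a1") {
  tibble::tibble(dendrite_id = dendrite, animal = animal, context = context,
                 segment_length = seg, shaft_width = shaft,
                 well_separated = TRUE, spine_id = seq_along(lengths),
                 spine_length = lengths,
                 marker_positive = rep_len(marker, length(lengths)))
}

test_that("inclusion criteria partition spines and dendrites with reason codes", {
  tbl <- filter_spines(make_spines(c(0.3, 0.5, 1.2)))
  expect_equal(sum(tbl$spine_valid), 2)
  expect_equal(tbl$spine_reject_reason[1], "below-0.4")

  wide <- filter_spines(make_spines(c(1, 2), shaft = 5))
  expect_true(all(!wide$dendrite_ok))
  expect_true(all(wide$dendrite_reject_reason == "shaft-width-out-of-range"))
  expect_true(all(!wide$spine_valid))

  short <- filter_spines(make_spines(c(1, 2), seg = 80))
  expect_true(all(short$dendrite_reject_reason == "segment-too-short"))

  iv <- filter_spines(make_spines(c(0.5, 12, 5), context = "in-vitro",
                                  shaft = NA, seg = 20))
  expect_equal(iv$spine_reject_reason[2], "above-10")
  expect_equal(sum(iv$spine_valid), 2)
  # ex vivo has no upper length bound
  ev <- filter_spines(make_spines(c(0.5, 12)))
  expect_equal(sum(ev$spine_valid), 2)

  expect_error(filter_spines(make_spines(c(1), shaft = NA)), "shaft_width")

  sep <- make_spines(c(1, 2))
  sep$well_separated <- c(TRUE, FALSE)
  expect_equal(filter_spines(sep)$spine_reject_reason[2], "not-separated")
})

test_that("density is count per 10 um and matches the in vitro x0.5 shortcut", {
  expect_equal(spine_density(30, 100), 3.0)
  expect_equal(spine_density(8, 20), 4.0)
  expect_equal(spine_density(8, 20), 8 * 0.5)
  expect_equal(spine_density(0, 50), 0)
  expect_error(spine_density(3, 0), "positive")
})

test_that("per-dendrite summaries respect the partition and marker ordering", {
  tbl <- dplyr::bind_rows(
    make_spines(c(0.3, 0.5, 1.2, 2.0), dendrite = "d1", marker = c(FALSE, TRUE, TRUE, FALSE)),
    make_spines(c(1, 1.5), dendrite = "d2", shaft = 5))
  dens <- spine_densities(tbl)
  expect_equal(nrow(dens), 1)   # d2 rejected wholly
  expect_equal(dens$n_valid, 3)
  expect_equal(dens$n_rejected, 1)
  expect_equal(dens$density, 3 / 120 * 10)
  expect_equal(dens$marker_density, 2 / 120 * 10)
  expect_lte(dens$marker_density, dens$density)
  expect_equal(dens$mean_length, mean(c(0.5, 1.2, 2.0)))

  # filtering never increases counts; marker density never exceeds density
  rec <- generate_spine_records(40, 12, 100, context = "ex-vivo", seed = 2,
                                marker_prob = 0.3)
  d <- spine_densities(rec)
  expect_true(all(d$marker_density <= d$density))
  expect_true(all(d$n_valid + d$n_rejected <=
                    tapply(!is.na(rec$spine_length), rec$dendrite_id, sum)[d$dendrite_id]))
})

test_that("group summaries average animals first", {
  dens <- tibble::tibble(
    group = "wt", animal = c("a1", "a1", "a2"),
    dendrite_id = c("d1", "d2", "d3"), segment_length = 100,
    n_valid = c(100, 200, 200), n_rejected = 0,
    mean_length = c(1.4, 1.6, 1.5),
    density = c(10, 20, 20), marker_density = 0)
  s <- summarize_spine_groups(dens)
  expect_equal(s$animals$density, c(15, 20))
  expect_equal(s$groups$mean_density, 17.5)

  two <- dplyr::mutate(dens[c(1, 3), ], density = c(10, 20))
  s2 <- summarize_spine_groups(two)
  expect_equal(s2$groups$mean_density, 15)
  expect_equal(s2$groups$sem_density, 5)

  # balanced designs: per-animal-first equals pooled averaging
  bal <- tibble::tibble(group = "g", animal = rep(c("a1", "a2"), each = 3),
                        dendrite_id = paste0("d", 1:6), segment_length = 100,
                        n_valid = 1, n_rejected = 0, mean_length = 1.5,
                        density = c(10, 12, 14, 20, 22, 24), marker_density = 0)
  s3 <- summarize_spine_groups(bal)
  expect_equal(s3$groups$mean_density, mean(bal$density))

  expect_error(summarize_spine_groups(dens[0, ]), "empty group")
})

test_that("a two-group spine experiment separates the group means", {
  wt <- simulate_spine_experiment(8, 6, 13.7, sd_between = 0.7 * sqrt(8),
                                  group = "wt", seed = 101)
  ko <- simulate_spine_experiment(8, 6, 17.2, sd_between = 0.5 * sqrt(8),
                                  group = "ko", seed = 202)
  s <- summarize_spine_groups(dplyr::bind_rows(spine_densities(wt), spine_densities(ko)))
  means <- s$groups$mean_density[match(c("wt", "ko"), s$groups$group)]
  expect_lt(abs(means[1] - 13.7), 3)
  expect_lt(abs(means[2] - 17.2), 3)
  res <- unpaired_t_test(s$animals$density[s$animals$group == "ko"],
                         s$animals$density[s$animals$group == "wt"])
  expect_equal(res$df, 14)
})
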