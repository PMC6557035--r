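# coactive

Network-ensemble detection and dendritic-spine quantification for
calcium-imaging studies of developing cortical networks.

Cultured cortical neurons fire spontaneously, and during the first weeks of
development subsets of them begin to fire *together*. Such co-active groups —
**network ensembles** — are the functional readout of the synaptic
connectivity being built, and changes in ensemble number or size are a
sensitive signature of altered synapse development (for example after
knockout of a synaptic regulator). `coactive` is a tidyverse-native R
implementation of the full analysis chain used in such studies:

1. **Preprocessing** — background subtraction, exclusion of cells whose
   fluorescence range stays within 10% of their maximum (saturated
   indicator), and ΔF/F conversion with a sliding lower-half baseline:
   `dff_t = (F_t − b_t)/b_t`, where `b_t` is the mean of the lower 50% of
   values in the previous 10 frames.
2. **Spike inference** — fast non-negative deconvolution under an AR(1)
   calcium model, solving the convex program

   ```
   min_C  1/(2σ²) Σ_t (y_t − C_t)²  +  λ Σ_t s_t,    s_t = C_t − γ C_{t−1} ≥ 0
   ```

   by an interior-point method with O(n) tridiagonal Newton steps, followed
   by per-cell max normalization to a bounded "spike probability".
3. **Ensemble detection** — binarization at 3 SD (RMS about zero) of the
   population's spike probabilities; a 1000-fold per-cell shuffle null for
   per-frame co-activity (`p < 0.05`); every significant high-activity frame
   becomes one ensemble, and **core ensembles** (cells co-activated in more
   than one ensemble) are extracted as maximal multi-parent intersections.
4. **Spine metrics** — inclusion criteria (ex vivo: 2–4 µm shafts, ≥ 100 µm
   segments, spines ≥ 0.4 µm; in vitro: 0.4–10 µm spines on 20 µm distal
   segments) and densities in spines per 10 µm, averaged animal-first.
5. **Group statistics** — pooled-variance unpaired t and exact/tie-corrected
   Mann–Whitney U tests, plus relative-frequency distributions.
6. **Synthetic data** — a generator that plants ground-truth co-activation
   ensembles in Poisson background firing and renders them into noisy
   fluorescence, so every stage above is verifiable against a known answer.

Every user-facing function takes a data frame first and returns a tibble (or
an object with `tidy()`/`glance()`/`autoplot()` methods), so stages chain
with the pipe.

## Worked example

Simulate a 120-frame, 100-cell recording with one planted 12-cell ensemble
firing three times, then run the full chain:

```r
library(coactive)

cfg <- sim_config(n_cells = 100, n_frames = 120, frame_period = 5,
                  background_rate = 0.02,
                  ensembles = list(planted_ensemble(member_count = 12, n_events = 3)),
                  seed = 7)
sim <- simulate_recording(cfg)

es <- sim$traces |>
  subtract_background(background = 2) |>
  exclude_saturated_cells() |>
  compute_dff(window = 10, lower_fraction = 0.5) |>
  infer_spikes() |>
  run_ensemble_analysis(run_config(n_shuffles = 1000, seed = 8))

es
#> <ensemble_set> 3 ensembles (mean 13.33 cells), 1 core ensembles, co-activity threshold 11
tidy(es)
#> # A tibble: 3 × 5
#>   ensemble_id frame_start frame_end n_cells members
#>         <int>       <int>     <int>   <int> <list>
#> 1           1          12        12      12 <chr [12]>
#> 2           2          73        73      14 <chr [14]>
#> 3           3         115       115      14 <chr [14]>
sim$truth$schedule$frame
#> [1]  12  73 115
```

The three planted events are recovered at exactly their scheduled frames
(12, 73, 115); the shuffle null put the significance threshold at 11
co-active cells, so only the planted frames qualify. Member counts of 12–14
are the 12 planted cells plus background spikes coincidentally landing in a
high-activity frame — genuinely co-active cells a frame-based detector
reports by construction. The recurring 12-cell intersection across all three
events is reported as one core ensemble.

Comparing per-coverslip ensemble counts between two groups:

```r
unpaired_t_test(c(4.2, 3.1, 5.0, 4.4, 3.6, 4.0, 3.9),
                c(7.9, 6.8, 8.4, 7.2, 8.0, 6.9, 7.7, 8.1))
#> # A tibble: 1 × 10
#>   test             statistic    df p_value mean_a mean_b sem_a sem_b   n_a   n_b
#>   <chr>                <dbl> <dbl>   <dbl>  <dbl>  <dbl> <dbl> <dbl> <int> <int>
#> 1 unpaired two-ta…     -11.7    13 2.92e-8   4.03   7.62 0.228 0.209     7     8
```

A thin command-line wrapper over the same functions ships in
`inst/cli/coactive` (subcommands `simulate`, `preprocess`, `infer`,
`ensembles`, `spines`, `compare`); see `?coactive_cli`.

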