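#' Apply spine and dendrite inclusion criteria
#'
#' Annotates a long spine record table (one row per spine; spineless
#' dendrites keep one placeholder row with `spine_id = NA`) with the study's
#' inclusion rules. Ex vivo, a dendrite is rejected wholly unless its shaft is
#' 2-4 um wide and at least 100 um of it was analyzed, and a spine must
#' protrude at least 0.4 um; in vitro, spines must be 0.4-10 um long. A
#' `well_separated` column (at least 4 um from a neighboring apical dendrite,
#' measured upstream) is honored when present. Every rejection carries a
#' reason code.
#'
#' @param table A tibble with columns `dendrite_id`, `context` (`"ex-vivo"`
#'   or `"in-vitro"`), `segment_length`, `spine_length`, and for ex vivo
#'   records `shaft_width`; optionally `well_separated`, `marker_positive`,
#'   `animal`, `group`.
#' @param shaft_width_range,min_segment_length Ex vivo dendrite criteria.
#' @param length_range Admissible spine length range in um; the upper bound
#'   applies in vitro only.
#' @return The input with `dendrite_ok`, `dendrite_reject_reason`,
#'   `spine_valid` and `spine_reject_reason` columns added.
#' @export
filter_spines <- function(table,
                          shaft_width_range = c(2, 4),
                          min_segment_length = 100,
                          length_range = c(0.4, 10)) {
  req <- c("dendrite_id", "context", "segment_length", "spine_length")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(table$context %in% c("ex-vivo", "in-vitro"))) {
    abort("`context` must be 'ex-vivo' or 'in-vitro'")
  }
  ex <- table$context == "ex-vivo"
  if (any(ex)) {
    if (!"shaft_width" %in% names(table) || anyNA(table$shaft_width[ex])) {
      abort("ex-vivo records require `shaft_width`")
    }
  }
  if (!"well_separated" %in% names(table)) table$well_separated <- TRUE
  shaft_bad <- ex & (table$shaft_width < shaft_width_range[1] |
                     table$shaft_width > shaft_width_range[2])
  seg_bad <- ex & table$segment_length < min_segment_length
  table$dendrite_ok <- !(shaft_bad | seg_bad)
  table$dendrite_reject_reason <- dplyr::case_when(
    shaft_bad ~ "shaft-width-out-of-range",
    seg_bad ~ "segment-too-short",
    TRUE ~ NA_character_)
  is_spine <- !is.na(table$spine_length)
  too_short <- is_spine & table$spine_length < length_range[1]
  too_long <- is_spine & table$context == "in-vitro" &
    table$spine_length > length_range[2]
  not_sep <- is_spine & !table$well_separated
  table$spine_valid <- is_spine & table$dendrite_ok &
    !too_short & !too_long & !not_sep
  table$spine_reject_reason <- dplyr::case_when(
    !is_spine ~ NA_character_,
    !table$dendrite_ok ~ "dendrite-rejected",
    too_short ~ sprintf("below-%g", length_range[1]),
    too_long ~ sprintf("above-%g", length_range[2]),
    not_sep ~ "not-separated",
    TRUE ~ NA_character_)
  table
}

#' Spine density per 10 micrometres
#'
#' `density = n_valid / segment_length * 10`. For the fixed 20 um in vitro
#' distal segment this reduces to `n_valid * 0.5`.
#'
#' @param n_valid Number of spines passing the inclusion criteria.
#' @param segment_length Analyzed shaft length in um.
#' @return Spines per 10 um.
#' @export
spine_density <- function(n_valid, segment_length) {
  if (any(segment_length <= 0)) abort("`segment_length` must be positive")
  n_valid / segment_length * 10
}

#' Per-dendrite density and length summaries
#'
#' Applies [filter_spines()] (unless the table is already annotated) and
#' reduces to one row per admissible dendrite.
#'
#' @inheritParams filter_spines
#' @param ... Passed to [filter_spines()].
#' @return A tibble: `dendrite_id` (plus `animal`/`group`/`context` when
#'   present), `segment_length`, `n_valid`, `n_rejected`, `density`,
#'   `marker_density`, `mean_length`.
#' @export
spine_densities <- function(table, ...) {
  if (!"spine_valid" %in% names(table)) table <- filter_spines(table, ...)
  if (!"marker_positive" %in% names(table)) table$marker_positive <- NA
  keep_cols <- intersect(c("group", "animal", "context"), names(table))
  table |>
    dplyr::filter(.data$dendrite_ok) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keep_cols, "dendrite_id", "segment_length")))) |>
    dplyr::summarise(
      n_valid = sum(.data$spine_valid),
      n_rejected = sum(!is.na(.data$spine_length) & !.data$spine_valid),
      marker_valid = sum(.data$spine_valid & .data$marker_positive %in% TRUE),
      mean_length = if (any(.data$spine_valid))
        mean(.data$spine_length[.data$spine_valid]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      density = spine_density(.data$n_valid, .data$segment_length),
      marker_density = spine_density(.data$marker_valid, .data$segment_length)) |>
    dplyr::select(-"marker_valid")
}

#' Per-animal then per-group spine summaries
#'
#' Densities are averaged within animal first and then across animals, so the
#' animal is the statistical unit (matching designs where n = animals, each
#' contributing several dendrites).
#'
#' @param densities A per-dendrite table from [spine_densities()].
#' @param group,animal Column names (strings) holding group and animal labels.
#' @return A list of tibbles: `animals` (per-animal means) and `groups`
#'   (per-group mean, SD, SEM, n).
#' @export
summarize_spine_groups <- function(densities, group = "group", animal = "animal") {
  for (col in c(group, animal)) {
    if (!col %in% names(densities)) abort(paste0("missing grouping column: ", col))
  }
  if (nrow(densities) == 0) abort("empty group: no admissible dendrites")
  animals <- densities |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, animal)))) |>
    dplyr::summarise(
      n_dendrites = dplyr::n(),
      density = mean(.data$density),
      marker_density = mean(.data$marker_density),
      mean_length = mean(.data$mean_length, na.rm = TRUE),
      .groups = "drop")
  groups <- animals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      mean_density = mean(.data$density),
      sd_density = sd(.data$density),
      sem_density = sd(.data$density) / sqrt(dplyr::n()),
      mean_length = mean(.data$mean_length, na.rm = TRUE),
      sem_length = sd(.data$mean_length) / sqrt(dplyr::n()),
      .groups = "drop")
  list(animals = animals, groups = groups)
}
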