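#' Fraction of cells per hemisphere
#'
#' For each animal, the fraction of labeled cortical cells detected in each
#' hemisphere. The ipsilateral injection target is always excluded (it is the
#' injection site); the contralateral homotopic area is retained.
#'
#' @param counts Count tibble or [cohort] (filtered; see
#'   [apply_min_cell_filter()]).
#' @param target Injected area acronym. Defaults to the cohort's target.
#' @return A tibble with columns `animal_id`, `hemisphere`, `share`. Shares
#'   sum to 1 per animal; `NA` when the animal has no cells at all.
#' @export
hemisphere_share <- function(counts, target = NULL) {
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  if (is.null(target)) abort("`target` is required when counts is not a cohort")
  all_ids <- unique(counts$animal_id)
  counts |>
    filter(!(.data$hemisphere == "ipsi" & .data$area == target)) |>
    group_by(.data$animal_id, .data$hemisphere) |>
    summarise(cells = sum(.data$count), .groups = "drop") |>
    tidyr::complete(animal_id = all_ids, hemisphere = .hemispheres,
                    fill = list(cells = 0L)) |>
    group_by(.data$animal_id) |>
    mutate(share = if (sum(.data$cells) > 0) .data$cells / sum(.data$cells)
           else NA_real_) |>
    ungroup() |>
    select("animal_id", "hemisphere", "share")
}

apply_exclusions <- function(counts, target, exclude_target_ipsi = TRUE,
                             exclude_homotopic_contra = TRUE) {
  if (exclude_target_ipsi) {
    counts <- filter(counts,
                     !(.data$hemisphere == "ipsi" & .data$area == target))
  }
  if (exclude_homotopic_contra) {
    counts <- filter(counts,
                     !(.data$hemisphere == "contra" & .data$area == target))
  }
  counts
}

#' Areal fractional counts
#'
#' The relative projection weight of each cortical area: its labeled-cell
#' count divided by the total labeled cells in its hemisphere, after the
#' stated exclusions. Fractions over included areas sum to 1 per
#' (animal, hemisphere).
#'
#' @inheritParams hemisphere_share
#' @param exclude_target_ipsi Exclude the injected area from the ipsilateral
#'   hemisphere (default `TRUE`; it is the injection site).
#' @param exclude_homotopic_contra Exclude the homotopic counterpart of the
#'   target from the contralateral hemisphere (default `TRUE`, the setting
#'   used for flat-map and module summaries).
#' @param inclusion Optional inclusion mask from [area_inclusion_mask()];
#'   areas outside the mask are dropped before normalization.
#' @return A tibble `animal_id`, `hemisphere`, `area`, `fraction` (`NA` for an
#'   empty hemisphere).
#' @export
areal_fraction <- function(counts, target = NULL, exclude_target_ipsi = TRUE,
                           exclude_homotopic_contra = TRUE, inclusion = NULL) {
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  if (is.null(target)) abort("`target` is required when counts is not a cohort")
  counts <- apply_exclusions(counts, target, exclude_target_ipsi,
                             exclude_homotopic_contra)
  if (!is.null(inclusion)) {
    counts <- semi_join(counts, inclusion, by = c("hemisphere", "area"))
  }
  counts |>
    group_by(.data$animal_id, .data$hemisphere, .data$area) |>
    summarise(cells = sum(.data$count), .groups = "drop_last") |>
    mutate(fraction = if (sum(.data$cells) > 0) .data$cells / sum(.data$cells)
           else NA_real_) |>
    ungroup() |>
    select("animal_id", "hemisphere", "area", "fraction")
}

#' Number of labeled areas per hemisphere
#'
#' Counts, per animal and hemisphere, the cortical areas with a nonzero cell
#' count after filtering, excluding the ipsilateral injection target.
#'
#' @inheritParams hemisphere_share
#' @return A tibble `animal_id`, `hemisphere`, `n_areas`.
#' @export
count_labeled_areas <- function(counts, target = NULL) {
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  if (is.null(target)) abort("`target` is required when counts is not a cohort")
  all_ids <- unique(counts$animal_id)
  counts |>
    filter(!(.data$hemisphere == "ipsi" & .data$area == target)) |>
    group_by(.data$animal_id, .data$hemisphere, .data$area) |>
    summarise(cells = sum(.data$count), .groups = "drop") |>
    group_by(.data$animal_id, .data$hemisphere) |>
    summarise(n_areas = sum(.data$cells > 0), .groups = "drop") |>
    tidyr::complete(animal_id = all_ids, hemisphere = .hemispheres,
                    fill = list(n_areas = 0L))
}

#' Homotopic share of the contralateral projection
#'
#' The fraction of all contralateral cells located in the homotopic
#' counterpart of the injected area (versus all other contralateral areas).
#'
#' @inheritParams hemisphere_share
#' @return A tibble `animal_id`, `share` (`NA` when the animal has no
#'   contralateral cells).
#' @export
homotopic_share <- function(counts, target = NULL) {
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  if (is.null(target)) abort("`target` is required when counts is not a cohort")
  all_ids <- unique(counts$animal_id)
  counts |>
    filter(.data$hemisphere == "contra") |>
    group_by(.data$animal_id) |>
    summarise(share = if (sum(.data$count) > 0) {
      sum(.data$count[.data$area == target]) / sum(.data$count)
    } else NA_real_) |>
    tidyr::complete(animal_id = all_ids, fill = list(share = NA_real_))
}

#' Laminar profile of each area
#'
#' Normalizes counts within each (animal, hemisphere, area) to the total over
#' a stated layer universe, giving the fraction of that area's projection
#' neurons in each layer.
#'
#' @inheritParams hemisphere_share
#' @param layer_universe Layers over which to normalize (default all five
#'   count-carrying layers; hierarchy analyses use `c("L2/3", "L5", "L6a")`).
#' @return A tibble `animal_id`, `hemisphere`, `area`, `layer`, `fraction`.
#'   Areas with zero cells over the universe get `NA` fractions (undefined,
#'   never silently zero).
#' @export
laminar_fraction <- function(counts,
                             layer_universe = .analysis_layers) {
  counts <- as_counts(counts)
  bad <- setdiff(layer_universe, .analysis_layers)
  if (length(bad) > 0) {
    abort(paste0("unknown layer(s) in layer_universe: ",
                 paste(bad, collapse = ", ")))
  }
  counts |>
    filter(.data$layer %in% layer_universe) |>
    group_by(.data$animal_id, .data$hemisphere, .data$area, .data$layer) |>
    summarise(cells = sum(.data$count), .groups = "drop_last") |>
    mutate(fraction = if (sum(.data$cells) > 0) .data$cells / sum(.data$cells)
           else NA_real_) |>
    ungroup() |>
    select("animal_id", "hemisphere", "area", "layer", "fraction")
}

#' Module-level fractional counts
#'
#' Aggregates areal fractional counts into the six cortical modules by summing
#' member-area fractions; module fractions sum to 1 per (animal, hemisphere).
#'
#' @param fractions Output of [areal_fraction()] (computed under the
#'   exclusions the analysis calls for).
#' @param atlas Atlas tibble.
#' @return A tibble `animal_id`, `hemisphere`, `module`, `fraction`.
#' @export
module_fraction <- function(fractions, atlas = load_atlas()) {
  if (nrow(fractions) == 0) {
    return(tibble(animal_id = character(), hemisphere = character(),
                  module = character(), fraction = double()))
  }
  fractions |>
    mutate(module = module_of(.data$area, atlas)) |>
    group_by(.data$animal_id, .data$hemisphere, .data$module) |>
    summarise(fraction = if (all(is.na(.data$fraction))) NA_real_
              else sum(.data$fraction, na.rm = TRUE),
              .groups = "drop_last") |>
    tidyr::complete(module = sort(unique(atlas$module)),
                    fill = list(fraction = 0)) |>
    ungroup()
}
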