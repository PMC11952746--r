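#' Fraction of infragranular labeled neurons (fILN)
#'
#' The anatomical hierarchy statistic: the fraction of an area's projection
#' neurons located in the infragranular layers,
#' \deqn{fILN = (L5 + L6) / (L2/3 + L5 + L6),}
#' computed on laminar fractions (or, equivalently, raw counts) over the
#' universe \{L2/3, L5, L6\}. Values near 0 indicate a feedforward-like
#' (supragranular) projection, values near 1 a feedback-like (infragranular)
#' one. Layer-ablation variants drop L5 or L6 from both numerator and
#' denominator: `excl_L5` gives L6/(L2/3+L6) and `excl_L6` gives
#' L5/(L2/3+L5).
#'
#' @param l23,l5,l6 Non-negative numeric vectors of laminar fractions or
#'   counts (recycled to a common length).
#' @param variant `"default"`, `"excl_L5"` or `"excl_L6"`.
#' @return Numeric vector of fILN values in \[0, 1\]; `NA` where the
#'   denominator is zero (undefined, never coerced to 0).
#' @examples
#' filn(0.30, 0.30, 0.40)                  # 0.7
#' filn(20, 30, 50, variant = "excl_L6")   # 0.6
#' @export
filn <- function(l23, l5, l6, variant = c("default", "excl_L5", "excl_L6")) {
  variant <- match.arg(variant)
  if (any(l23 < -1e-9, na.rm = TRUE) || any(l5 < -1e-9, na.rm = TRUE) ||
      any(l6 < -1e-9, na.rm = TRUE)) {
    abort("laminar fractions must be non-negative")
  }
  # tolerate floating-point dust from simplex arithmetic
  l23 <- pmax(l23, 0)
  l5 <- pmax(l5, 0)
  l6 <- pmax(l6, 0)
  num <- switch(variant, default = l5 + l6, excl_L5 = l6, excl_L6 = l5)
  den <- switch(variant,
                default = l23 + l5 + l6,
                excl_L5 = l23 + l6,
                excl_L6 = l23 + l5)
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

# Collapse counts to the {L2/3, L5, L6} universe used by fILN.
filn_layer_counts <- function(counts, include_l6b = FALSE) {
  l6_layers <- if (include_l6b) c("L6a", "L6b") else "L6a"
  out <- counts |>
    mutate(class = case_when(
      .data$layer == "L2/3" ~ "l23",
      .data$layer == "L5" ~ "l5",
      .data$layer %in% l6_layers ~ "l6",
      TRUE ~ NA_character_
    )) |>
    group_by(.data$animal_id, .data$hemisphere, .data$area) |>
    summarise(l23 = sum(.data$count[.data$class == "l23"], na.rm = TRUE),
              l5 = sum(.data$count[.data$class == "l5"], na.rm = TRUE),
              l6 = sum(.data$count[.data$class == "l6"], na.rm = TRUE),
              .groups = "drop")
  out
}

#' Per-area fILN table
#'
#' Computes fILN for every (animal, hemisphere, area). The ipsilateral
#' injection target is set to `NA` (it is the injection site); the
#' contralateral homotopic area is retained as a valid contralateral input.
#' Areas outside the inclusion mask, and areas with no cells in the
#' denominator layers, are `NA`.
#'
#' @param counts Count tibble or [cohort] (filtered).
#' @param target Injected area acronym (cohort default).
#' @param variant fILN variant; see [filn()].
#' @param include_l6b Count L6b together with L6a as "L6" (default `FALSE`:
#'   the L6 term means L6a, and L4/L6b are excluded from the universe).
#' @param inclusion Optional mask from [area_inclusion_mask()].
#' @return A tibble `animal_id`, `hemisphere`, `area`, `filn`, `variant`.
#' @export
filn_table <- function(counts, target = NULL,
                       variant = c("default", "excl_L5", "excl_L6"),
                       include_l6b = FALSE, inclusion = NULL) {
  variant <- match.arg(variant)
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  out <- filn_layer_counts(counts, include_l6b) |>
    mutate(filn = filn(.data$l23, .data$l5, .data$l6, variant))
  if (!is.null(inclusion)) {
    out <- out |>
      left_join(mutate(inclusion[c("hemisphere", "area")], .inc = TRUE),
                by = c("hemisphere", "area")) |>
      mutate(filn = if_else(is.na(.data$.inc), NA_real_, .data$filn)) |>
      select(-".inc")
  }
  if (!is.null(target)) {
    out <- mutate(out, filn = if_else(
      .data$hemisphere == "ipsi" & .data$area == target, NA_real_, .data$filn))
  }
  out |>
    mutate(variant = .env$variant) |>
    select("animal_id", "hemisphere", "area", "filn", "variant")
}

#' Pooled-hemisphere fILN
#'
#' fILN computed from all cells in a hemisphere, blind to individual cortical
#' areas (cell-weighted: the summed counts enter the formula directly). The
#' ipsilateral injection target is excluded.
#'
#' @inheritParams filn_table
#' @return A tibble `animal_id`, `hemisphere`, `filn`, `variant`.
#' @export
pooled_filn <- function(counts, target = NULL,
                        variant = c("default", "excl_L5", "excl_L6"),
                        include_l6b = FALSE) {
  variant <- match.arg(variant)
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  if (!is.null(target)) {
    counts <- filter(counts,
                     !(.data$hemisphere == "ipsi" & .data$area == target))
  }
  filn_layer_counts(counts, include_l6b) |>
    group_by(.data$animal_id, .data$hemisphere) |>
    summarise(across(c("l23", "l5", "l6"), sum), .groups = "drop") |>
    mutate(filn = filn(.data$l23, .data$l5, .data$l6, variant),
           variant = .env$variant) |>
    select("animal_id", "hemisphere", "filn", "variant")
}

#' Laminar dominance
#'
#' Labels each cortical area by the layer contributing the largest fraction of
#' its projection neurons, over \{L2/3, L5, L6\} with L6 = L6a + L6b. Ties are
#' broken toward the deeper layer. With `basis = "per_animal"` each animal is
#' labelled separately (tally with [dominance_tally()]); with
#' `basis = "cohort_average"` the across-animal mean laminar profile is
#' labelled.
#'
#' @param counts Count tibble or [cohort] (filtered).
#' @param basis `"per_animal"` or `"cohort_average"`.
#' @return A tibble with `hemisphere`, `area`, `label` (`"L2/3"`, `"L5"`,
#'   `"L6"`, or `NA` when undefined), `basis`, and `animal_id` when
#'   `basis = "per_animal"`.
#' @export
dominance <- function(counts, basis = c("per_animal", "cohort_average")) {
  basis <- match.arg(basis)
  counts <- as_counts(counts)
  prof <- filn_layer_counts(counts, include_l6b = TRUE) |>
    mutate(total = .data$l23 + .data$l5 + .data$l6)
  if (basis == "cohort_average") {
    prof <- prof |>
      mutate(across(c("l23", "l5", "l6"),
                    ~ if_else(.data$total > 0, .x / .data$total, NA_real_))) |>
      group_by(.data$hemisphere, .data$area) |>
      summarise(l23 = mean_na(.data$l23), l5 = mean_na(.data$l5),
                l6 = mean_na(.data$l6), .groups = "drop") |>
      mutate(total = .data$l23 + .data$l5 + .data$l6)
  }
  labels <- c("L2/3", "L5", "L6")
  out <- prof |>
    mutate(label = pmap_chr_dominance(.data$l23, .data$l5, .data$l6,
                                      .data$total, labels),
           basis = .env$basis)
  keep <- c(if (basis == "per_animal") "animal_id", "hemisphere", "area",
            "label", "basis")
  select(out, dplyr::all_of(keep))
}

# argmax with ties broken toward the deeper layer (L6 > L5 > L2/3).
pmap_chr_dominance <- function(l23, l5, l6, total, labels) {
  m <- cbind(l23, l5, l6)
  idx <- max.col(m, ties.method = "last")
  out <- labels[idx]
  out[is.na(total) | total == 0] <- NA_character_
  out
}

#' Tally laminar dominance
#'
#' Converts per-animal dominance labels into the percentage of areas dominated
#' by each layer, per animal and hemisphere (areas with undefined labels are
#' excluded from the denominator).
#'
#' @param labels Output of [dominance()] with `basis = "per_animal"`.
#' @return A tibble `animal_id`, `hemisphere`, `label`, `percent`.
#' @export
dominance_tally <- function(labels) {
  if (!"animal_id" %in% names(labels)) {
    abort("dominance_tally needs per-animal labels (basis = \"per_animal\")")
  }
  labels |>
    filter(!is.na(.data$label)) |>
    group_by(.data$animal_id, .data$hemisphere, .data$label) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    tidyr::complete(label = c("L2/3", "L5", "L6"),
                    fill = list(n = 0L, percent = 0)) |>
    ungroup() |>
    select("animal_id", "hemisphere", "label", "percent")
}

#' Rank areas by mean fILN
#'
#' NaN-aware across-animal mean fILN per area, ordered from lowest (most
#' feedforward) to highest (most feedback). Ties are broken by atlas area
#' index. Animals from several targets can be pooled by row-binding their
#' fILN tables first; injection-site entries are already `NA` in
#' [filn_table()] output and do not contribute.
#'
#' @param filn_tbl Output of [filn_table()] (possibly row-bound across
#'   cohorts).
#' @param hemisphere Hemisphere to rank (`"ipsi"` by default).
#' @param atlas Atlas tibble (for tie-breaking indices).
#' @return A `filn_ranking` tibble: `rank`, `area`, `index`, `mean_filn`,
#'   `sem`, `n` (defined values contributing). Areas with no defined values
#'   are dropped with a warning.
#' @export
rank_areas <- function(filn_tbl, hemisphere = "ipsi", atlas = load_atlas()) {
  hemi <- hemisphere
  out <- filn_tbl |>
    filter(.data$hemisphere == hemi) |>
    group_by(.data$area) |>
    summarise(mean_filn = mean_na(.data$filn), sem = sem_na(.data$filn),
              n = sum(!is.na(.data$filn)), .groups = "drop") |>
    mutate(index = atlas$index[match(.data$area, atlas$acronym)])
  dropped <- out$area[out$n == 0]
  if (length(dropped) > 0) {
    warn(paste0("dropping area(s) with no defined fILN values: ",
                paste(dropped, collapse = ", ")))
    out <- filter(out, .data$n > 0)
  }
  out <- out |>
    arrange(.data$mean_filn, .data$index) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "area", "index", "mean_filn", "sem", "n")
  class(out) <- c("filn_ranking", class(out))
  attr(out, "hemisphere") <- hemi
  out
}

#' Interhemispheric fILN difference
#'
#' Per (animal, area) signed difference contra − ipsi. Undefined values
#' propagate: the difference is `NA` unless both hemispheres are defined.
#'
#' @param filn_tbl Output of [filn_table()].
#' @return A tibble `animal_id`, `area`, `ipsi`, `contra`, `delta`.
#' @export
interhemispheric_delta <- function(filn_tbl) {
  wide <- filn_tbl |>
    select("animal_id", "hemisphere", "area", "filn") |>
    pivot_wider(names_from = "hemisphere", values_from = "filn")
  for (h in .hemispheres) if (!h %in% names(wide)) wide[[h]] <- NA_real_
  mutate(wide, delta = .data$contra - .data$ipsi)
}

#' Module-level fILN
#'
#' Unweighted NaN-aware mean of member-area fILN values per animal and
#' hemisphere, at the level of the six modules or of the two module groups
#' (`"v-a-sm"` vs `"pf-m-l"`). Group means average over all member areas
#' directly (equal to the mean of the concatenated member-area values, not the
#' mean of module means).
#'
#' @param filn_tbl Output of [filn_table()].
#' @param atlas Atlas tibble.
#' @param grouping `"six-modules"` or `"two-groups"`.
#' @return A tibble `animal_id`, `hemisphere`, `module` (or `group`), `filn`
#'   (`NA` when no member area is defined).
#' @export
module_filn <- function(filn_tbl, atlas = load_atlas(),
                        grouping = c("six-modules", "two-groups")) {
  grouping <- match.arg(grouping)
  x <- mutate(filn_tbl, module = module_of(.data$area, atlas))
  if (grouping == "two-groups") {
    x <- x |>
      left_join(module_groupings(), by = "module") |>
      group_by(.data$animal_id, .data$hemisphere, .data$group)
  } else {
    x <- group_by(x, .data$animal_id, .data$hemisphere, .data$module)
  }
  summarise(x, filn = mean_na(.data$filn), .groups = "drop")
}

#' Interhemispheric laminar change within the sensory-motor modules
#'
#' For the 24 areas of the visual, auditory, and somatomotor modules, compares
#' each area's laminar fractions (over \{L2/3, L5, L6a\}) between the
#' hemispheres: per-area per-layer mean change (contra − ipsi) across animals,
#' a per-area paired test with Bonferroni correction over the areas tested
#' within each layer, and a tally of the percentage of areas that
#' significantly increase or decrease per layer. The homotopic counterpart of
#' the injection target is excluded.
#'
#' @param counts Count tibble or [cohort] (filtered).
#' @param target Injected area acronym (cohort default).
#' @param atlas Atlas tibble.
#' @param layers Layers compared (default `c("L2/3", "L5", "L6a")`).
#' @param alpha Significance level after correction (default 0.05).
#' @param test Paired test routed through [compare_samples()]
#'   (default `"paired-t"`).
#' @return A list with `changes` (tibble `area`, `layer`, `mean_change`, `n`,
#'   `p`, `p_adj`, `direction`) and `tally` (tibble `layer`, `direction`,
#'   `n_areas`, `percent`); areas missing in one hemisphere are reported in
#'   `excluded`.
#' @export
laminar_change <- function(counts, target = NULL, atlas = load_atlas(),
                           layers = c("L2/3", "L5", "L6a"), alpha = 0.05,
                           test = "paired-t") {
  target <- target %||% if (inherits(counts, "cohort")) counts$target
  counts <- as_counts(counts)
  if (is.null(target)) abort("`target` is required when counts is not a cohort")
  vasm <- atlas$acronym[atlas$module %in% module_groupings("v-a-sm")]
  lam <- laminar_fraction(filter(counts, .data$area %in% vasm),
                          layer_universe = layers) |>
    filter(!(.data$area == target & .data$hemisphere == "contra"),
           !(.data$area == target & .data$hemisphere == "ipsi"))
  wide <- lam |>
    pivot_wider(names_from = "hemisphere", values_from = "fraction") |>
    filter(!is.na(.data$ipsi) & !is.na(.data$contra))
  tested <- wide |>
    group_by(.data$area, .data$layer) |>
    summarise(n = n(), mean_change = mean(.data$contra - .data$ipsi),
              p = if (n() >= 2 && sd(.data$contra - .data$ipsi) > 0) {
                compare_samples(.data$contra, .data$ipsi, paired = TRUE,
                                test = .env$test)$p
              } else NA_real_,
              .groups = "drop")
  all_pairs <- tidyr::expand_grid(area = setdiff(vasm, target), layer = layers)
  excluded <- anti_join(all_pairs, tested, by = c("area", "layer"))
  changes <- tested |>
    group_by(.data$layer) |>
    mutate(p_adj = bonferroni_adjust(.data$p, m = sum(!is.na(.data$p)))) |>
    ungroup() |>
    mutate(direction = case_when(
      !is.na(.data$p_adj) & .data$p_adj < alpha & .data$mean_change > 0 ~ "increase",
      !is.na(.data$p_adj) & .data$p_adj < alpha & .data$mean_change < 0 ~ "decrease",
      TRUE ~ "ns"
    )) |>
    arrange(.data$layer, .data$area)
  tally <- changes |>
    group_by(.data$layer) |>
    summarise(n_tested = n(),
              increase = sum(.data$direction == "increase"),
              decrease = sum(.data$direction == "decrease"),
              .groups = "drop") |>
    pivot_longer(c("increase", "decrease"), names_to = "direction",
                 values_to = "n_areas") |>
    mutate(percent = 100 * .data$n_areas / .data$n_tested) |>
    select("layer", "direction", "n_areas", "percent")
  list(changes = changes, tally = tally, excluded = excluded)
}
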