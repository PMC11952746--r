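#' Read a per-animal laminar count table
#'
#' Reads one animal's cellfinder-style count table: a tidy CSV with columns
#' `animal_id`, `hemisphere`, `area`, `layer`, `count`, one row per
#' (hemisphere, area, layer) with the number of detected projection-neuron
#' nuclei. Hemisphere labels may be anatomical (`left`/`right`) or already
#' injection-relative (`ipsi`/`contra`); anatomical labels are converted with
#' [flip_to_injection_frame()] when metadata is available. Missing
#' (hemisphere, area, layer) combinations are imputed as zero; unknown areas or
#' layers, negative or non-integer counts, and L4 counts in agranular areas are
#' rejected.
#'
#' @param file Path to the CSV. A sidecar JSON with the same path plus
#'   `.json` (e.g. `animal1.csv.json`), holding `animal_id`, `target_area`,
#'   `injection_hemisphere`, `frac_bolus_outside_target` and
#'   `frac_whitematter_bolus`, is read when present.
#' @param atlas Atlas tibble from [load_atlas()].
#' @param meta Optional metadata as a one-row tibble/list overriding any
#'   sidecar.
#' @return A tibble of validated counts with an attached `meta` attribute
#'   (a one-row tibble, or `NULL` when no metadata was found).
#' @export
read_count_table <- function(file, atlas = load_atlas(), meta = NULL) {
  x <- readr::read_csv(file, show_col_types = FALSE,
                       col_types = readr::cols(
                         animal_id = readr::col_character(),
                         hemisphere = readr::col_character(),
                         area = readr::col_character(),
                         layer = readr::col_character(),
                         count = readr::col_double()
                       ))
  if (is.null(meta)) {
    sidecar <- paste0(file, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    }
  }
  if (!is.null(meta)) meta <- as_tibble(as.list(meta))
  anatomical <- all(x$hemisphere %in% c("left", "right"))
  if (anatomical) {
    if (is.null(meta) || is.null(meta$injection_hemisphere)) {
      abort("hemispheres are labelled left/right but injection_hemisphere metadata is missing")
    }
    x <- flip_to_injection_frame(x, meta$injection_hemisphere)
  }
  check_counts(x, atlas)
  x <- complete_counts(x, atlas)
  attr(x, "meta") <- meta
  x
}

# Impute absent (hemisphere, area, layer) combinations as zero, respecting
# has_L4 flags so agranular areas never gain an L4 row.
complete_counts <- function(x, atlas) {
  grid <- tidyr::expand_grid(
    animal_id = unique(x$animal_id),
    hemisphere = .hemispheres,
    area = atlas$acronym,
    layer = setdiff(.analysis_layers, character(0))
  )
  grid <- anti_join(grid,
                    tibble(area = atlas$acronym[!atlas$has_L4], layer = "L4"),
                    by = c("area", "layer"))
  out <- left_join(grid, x, by = c("animal_id", "hemisphere", "area", "layer"))
  out$count <- as.integer(replace_na(out$count, 0))
  as_tibble(out)
}

#' Injection quality control
#'
#' Applies the two injection-level exclusion rules: an animal fails when more
#' than 30% of the viral bolus lies outside the target area, or when white
#' matter transduction reaches 0.1% of the total bolus volume (inclusion
#' requires it to be strictly below 0.1%).
#'
#' @param meta Metadata tibble with one row per animal and columns
#'   `animal_id`, `frac_bolus_outside_target`, `frac_whitematter_bolus`.
#' @param max_outside_target Maximum tolerated fraction of the bolus outside
#'   the target area (default 0.30; fail when strictly greater).
#' @param max_whitematter White-matter fraction at or above which the animal
#'   fails (default 0.001).
#' @return A tibble with columns `animal_id`, `pass` (logical) and `reasons`
#'   (character; `""` when the animal passes).
#' @examples
#' qc_injection(tibble::tibble(animal_id = "m1",
#'                             frac_bolus_outside_target = 0.35,
#'                             frac_whitematter_bolus = 0))
#' @export
qc_injection <- function(meta, max_outside_target = 0.30,
                         max_whitematter = 0.001) {
  meta <- as_tibble(meta)
  frac_cols <- c("frac_bolus_outside_target", "frac_whitematter_bolus")
  for (col in frac_cols) {
    if (!col %in% names(meta)) abort(paste0("metadata is missing column ", col))
    if (any(meta[[col]] < 0 | meta[[col]] > 1, na.rm = TRUE)) {
      abort(paste0(col, " must lie in [0, 1]"))
    }
  }
  meta |>
    mutate(
      .fail_bolus = .data$frac_bolus_outside_target > max_outside_target,
      .fail_wm = .data$frac_whitematter_bolus >= max_whitematter,
      pass = !.data$.fail_bolus & !.data$.fail_wm,
      reasons = paste0(
        if_else(.data$.fail_bolus,
                paste0("bolus outside target > ", max_outside_target), ""),
        if_else(.data$.fail_bolus & .data$.fail_wm, "; ", ""),
        if_else(.data$.fail_wm,
                paste0("white-matter bolus >= ", max_whitematter), "")
      )
    ) |>
    select("animal_id", "pass", "reasons")
}

#' Zero out sparsely labeled areas
#'
#' The minimum-cell rule: a cortical area in a given hemisphere must contain at
#' least `threshold` cells (summed across layers) for a given animal;
#' otherwise all of its layer counts are set to zero. Idempotent and never
#' increases any count.
#'
#' @param counts Long count tibble (or a [cohort] object, in which case its
#'   counts are filtered and the cohort returned).
#' @param threshold Minimum number of cells per (hemisphere, area); default 10.
#' @return The same type as `counts`, filtered.
#' @export
apply_min_cell_filter <- function(counts, threshold = 10) {
  if (threshold < 1) abort("threshold must be >= 1")
  if (inherits(counts, "cohort")) {
    counts$counts <- apply_min_cell_filter(counts$counts, threshold)
    return(counts)
  }
  counts |>
    group_by(.data$animal_id, .data$hemisphere, .data$area) |>
    mutate(count = if (sum(.data$count) < threshold) 0L
           else as.integer(.data$count)) |>
    ungroup()
}

#' Cohort-level area inclusion mask
#'
#' The cohort inclusion rule: a (hemisphere, area) pair enters cohort-level
#' analyses only when at least `min_animals` distinct animals carry at least
#' `min_cells` cells there, counted in the same hemisphere. The minimum-cell
#' filter ([apply_min_cell_filter()]) is applied first.
#'
#' @param counts Multi-animal count tibble or [cohort].
#' @param min_cells Per-animal cell threshold (default 10).
#' @param min_animals Number of qualifying animals required (default 3).
#' @return A tibble with columns `hemisphere`, `area` listing included pairs,
#'   plus `n_animals` (how many animals qualified).
#' @export
area_inclusion_mask <- function(counts, min_cells = 10, min_animals = 3) {
  counts <- as_counts(counts)
  counts <- apply_min_cell_filter(counts, min_cells)
  counts |>
    group_by(.data$animal_id, .data$hemisphere, .data$area) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    filter(.data$total >= min_cells) |>
    group_by(.data$hemisphere, .data$area) |>
    summarise(n_animals = n_distinct(.data$animal_id), .groups = "drop") |>
    filter(.data$n_animals >= min_animals)
}

#' Relabel hemispheres relative to the injection
#'
#' Converts anatomical `left`/`right` hemisphere labels to injection-relative
#' `ipsi`/`contra` labels (ipsi = injection side). Counts are unchanged;
#' applying the function to already injection-relative data is a no-op.
#'
#' @param counts Long count tibble with `hemisphere` in `left`/`right` (or
#'   already `ipsi`/`contra`).
#' @param injection_hemisphere `"left"` or `"right"`.
#' @return The count tibble with `hemisphere` in `ipsi`/`contra`.
#' @export
flip_to_injection_frame <- function(counts, injection_hemisphere) {
  counts <- as_tibble(counts)
  if (all(counts$hemisphere %in% .hemispheres)) return(counts)
  if (is.null(injection_hemisphere) ||
      !injection_hemisphere %in% c("left", "right")) {
    abort("injection_hemisphere must be \"left\" or \"right\"")
  }
  if (any(!counts$hemisphere %in% c("left", "right"))) {
    abort("hemisphere labels must all be left/right or all ipsi/contra")
  }
  mutate(counts, hemisphere = if_else(
    .data$hemisphere == injection_hemisphere, "ipsi", "contra"))
}

#' Assemble a cohort
#'
#' Bundles multi-animal counts with per-animal injection metadata and the
#' shared target area. All package analyses accept either a plain count
#' tibble or a cohort.
#'
#' @param counts Long count tibble covering all animals.
#' @param meta Metadata tibble, one row per animal (see [read_count_table()]).
#' @param target Target (injected) area acronym shared by all animals.
#' @param events Optional per-cell event list (one row per detected cell), as
#'   emitted by [simulate_cohort()].
#' @param truth Optional [ground_truth()] the cohort was simulated from.
#' @return An object of class `cohort`.
#' @export
cohort <- function(counts, meta, target, events = NULL, truth = NULL) {
  counts <- as_tibble(counts)
  meta <- as_tibble(meta)
  if (!all(counts$animal_id %in% meta$animal_id)) {
    abort("every animal in `counts` needs a metadata row")
  }
  structure(list(counts = counts, meta = meta, target = target,
                 events = events, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> target:", x$target,
      "| animals:", n_distinct(x$counts$animal_id),
      "| cells:", format(sum(x$counts$count), big.mark = ","), "\n")
  invisible(x)
}

#' Read a cohort from a directory
#'
#' Reads every `*.csv` count table (with `*.csv.json` sidecars) in `dir`, as
#' written by [write_cohort()], and assembles a [cohort()].
#'
#' @param dir Directory containing per-animal CSVs and JSON sidecars.
#' @param atlas Atlas tibble.
#' @return A [cohort] object.
#' @export
read_cohort <- function(dir, atlas = load_atlas()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("ground_truth", files)]
  files <- files[!grepl("events", files)]
  if (length(files) == 0) abort(paste0("no count CSVs found in ", dir))
  tables <- map(files, read_count_table, atlas = atlas)
  metas <- map(tables, ~ attr(.x, "meta"))
  if (any(vapply(metas, is.null, logical(1)))) {
    abort("every animal CSV needs a .csv.json metadata sidecar")
  }
  meta <- list_rbind(metas)
  counts <- list_rbind(map(tables, as_tibble))
  target <- unique(meta$target_area)
  if (length(target) != 1) {
    abort("animals in a cohort must share a single target area")
  }
  cohort(counts, meta, target)
}

#' Write a cohort to a directory
#'
#' Writes one CSV (+ JSON metadata sidecar) per animal in the ingest schema,
#' plus the ground truth (JSON) and per-cell event list (CSV) when present.
#'
#' @param x A [cohort].
#' @param dir Output directory (created if needed).
#' @param events Write the per-cell event list too (default `FALSE`; the file
#'   is large).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir, events = FALSE) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in sort(unique(x$counts$animal_id))) {
    sub <- filter(x$counts, .data$animal_id == id, .data$count > 0)
    path <- file.path(dir, paste0(id, ".csv"))
    readr::write_csv(sub, path)
    meta <- filter(x$meta, .data$animal_id == id)
    jsonlite::write_json(as.list(meta), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(x$truth)) {
    write_ground_truth(x$truth, file.path(dir, "ground_truth.json"))
  }
  if (events && !is.null(x$events)) {
    readr::write_csv(x$events, file.path(dir, "events.csv"))
  }
  invisible(dir)
}
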