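# Internal vocabulary shared by all modules.

# All layers the imaging pipeline can report; L1 never carries counts.
.all_layers <- c("L1", "L2/3", "L4", "L5", "L6a", "L6b")

# Layers that carry counts in analysis tables.
.analysis_layers <- c("L2/3", "L4", "L5", "L6a", "L6b")

.hemispheres <- c("ipsi", "contra")

.targets <- c("VISp", "SSp-bfd", "MOp")

# Columns every long count table must have.
.count_cols <- c("animal_id", "hemisphere", "area", "layer", "count")

`%||%` <- rlang::`%||%`

# Validate a long count table against the atlas; returns the tibble invisibly.
check_counts <- function(x, atlas = NULL, hemispheres = .hemispheres,
                         call = rlang::caller_env()) {
  x <- as_tibble(x)
  missing_cols <- setdiff(.count_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (any(!x$hemisphere %in% hemispheres)) {
    bad <- unique(x$hemisphere[!x$hemisphere %in% hemispheres])
    abort(paste0("unknown hemisphere label(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(hemispheres, collapse = "/"), ")"),
          call = call)
  }
  if (any(!x$layer %in% .analysis_layers)) {
    bad <- unique(x$layer[!x$layer %in% .analysis_layers])
    abort(paste0("unknown layer label(s): ", paste(bad, collapse = ", ")),
          call = call)
  }
  if (any(is.na(x$count)) || any(x$count < 0) || any(x$count != round(x$count))) {
    i <- which(is.na(x$count) | x$count < 0 | x$count != round(x$count))[1]
    abort(paste0("counts must be non-negative integers (first offending row: ",
                 i, ")"), call = call)
  }
  if (!is.null(atlas)) {
    unknown <- setdiff(unique(x$area), atlas$acronym)
    if (length(unknown) > 0) {
      i <- which(x$area %in% unknown)[1]
      abort(paste0("unknown area acronym(s): ", paste(unknown, collapse = ", "),
                   " (first at row ", i, ")"), call = call)
    }
    agranular <- atlas$acronym[!atlas$has_L4]
    bad <- x$count > 0 & x$layer == "L4" & x$area %in% agranular
    if (any(bad)) {
      abort(paste0("L4 counts reported for agranular area(s): ",
                   paste(unique(x$area[bad]), collapse = ", ")), call = call)
    }
  }
  invisible(x)
}

# Extract the multi-animal count tibble from a cohort or pass a tibble through.
as_counts <- function(x) {
  if (inherits(x, "cohort")) x$counts else as_tibble(x)
}

cohort_meta <- function(x) {
  if (inherits(x, "cohort")) x$meta else NULL
}

# NaN-aware mean/sem used throughout; all-NA in -> NA out (no NaN warnings).
mean_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

sem_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
}
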