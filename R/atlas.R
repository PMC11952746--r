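#' Load the cortical area ontology
#'
#' Returns the 45-area cortical parcellation used throughout the package: the
#' CCFv3 isocortex summary structures (plus lateral and medial entorhinal
#' cortex), each assigned to one of six connectivity-defined modules
#' (prefrontal, lateral, somatomotor, visual, medial, auditory) and flagged for
#' the presence of a cytoarchitectonic layer 4. The packaged table is a
#' reconstruction from the public CCFv3 ontology and the standard module
#' assignment of the mouse cortical connectivity literature; supply `path` to
#' override it with your own parcellation.
#'
#' @param path Optional path to a CSV with columns `acronym`, `index`,
#'   `module`, `has_L4`. When `NULL` (default) the packaged table is used.
#' @return A tibble with one row per cortical area and columns `acronym`
#'   (character), `index` (integer, unique), `module` (character, one of the
#'   six module names) and `has_L4` (logical).
#' @examples
#' atlas <- load_atlas()
#' nrow(atlas)            # 45 areas
#' table(atlas$module)
#' @export
load_atlas <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ccf_isocortex_modules.csv",
                                package = "projectome", mustWork = TRUE)
  atlas <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("acronym", "index", "module", "has_L4")
  missing_cols <- setdiff(required, names(atlas))
  if (length(missing_cols) > 0) {
    abort(paste0("atlas table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  atlas <- mutate(atlas, acronym = as.character(.data$acronym),
                  index = as.integer(.data$index),
                  module = as.character(.data$module),
                  has_L4 = as.logical(.data$has_L4))
  if (anyDuplicated(atlas$acronym)) {
    dup <- atlas$acronym[duplicated(atlas$acronym)][1]
    abort(paste0("duplicate area acronym in atlas table: ", dup))
  }
  if (anyDuplicated(atlas$index)) {
    abort("area indices in atlas table are not unique")
  }
  bad_mod <- setdiff(unique(atlas$module), names(module_groupings_all()))
  if (length(bad_mod) > 0) {
    i <- which(atlas$module %in% bad_mod)[1]
    abort(paste0("unknown module name '", atlas$module[i], "' at atlas row ", i))
  }
  if (any(is.na(atlas$has_L4)) || any(is.na(atlas$index)) ||
      any(is.na(atlas$acronym))) {
    i <- which(!complete.cases(atlas[required]))[1]
    abort(paste0("missing value in atlas table at row ", i))
  }
  arrange(atlas, .data$index)
}

module_groupings_all <- function() {
  list(
    prefrontal = "pf-m-l", medial = "pf-m-l", lateral = "pf-m-l",
    visual = "v-a-sm", auditory = "v-a-sm", somatomotor = "v-a-sm"
  )
}

#' Module group membership
#'
#' The two module groupings compared throughout the hierarchy analyses:
#' `"v-a-sm"` (visual, auditory, somatomotor -- the sensory and motor modules)
#' and `"pf-m-l"` (prefrontal, medial, lateral).
#'
#' @param group `"v-a-sm"`, `"pf-m-l"`, or `NULL` for a lookup table of all
#'   modules.
#' @return A character vector of module names, or a tibble mapping `module` to
#'   `group` when `group` is `NULL`.
#' @examples
#' module_groupings("v-a-sm")
#' @export
module_groupings <- function(group = NULL) {
  map <- module_groupings_all()
  tbl <- tibble(module = names(map), group = unlist(map, use.names = FALSE))
  if (is.null(group)) return(tbl)
  if (!group %in% tbl$group) {
    abort(paste0("unknown module group '", group, "'; use \"v-a-sm\" or \"pf-m-l\""))
  }
  tbl$module[tbl$group == group]
}

#' Look up the module of cortical areas
#'
#' @param area Character vector of area acronyms.
#' @param atlas Atlas tibble from [load_atlas()].
#' @return Character vector of module names, same length as `area`.
#' @examples
#' module_of(c("VISp", "MOp"), load_atlas())
#' @export
module_of <- function(area, atlas = load_atlas()) {
  idx <- match(area, atlas$acronym)
  if (anyNA(idx)) {
    abort(paste0("unknown area acronym(s): ",
                 paste(unique(area[is.na(idx)]), collapse = ", ")))
  }
  atlas$module[idx]
}

#' Homotopic counterpart of an area
#'
#' The homotopic counterpart of a cortical area is the same area in the other
#' hemisphere; applying the map twice returns the input.
#'
#' @param area Character vector of area acronyms.
#' @param hemisphere Character vector (`"ipsi"`/`"contra"`), recycled against
#'   `area`.
#' @return A tibble with columns `area` and `hemisphere`.
#' @examples
#' homotopic_of("VISp", "ipsi")
#' @export
homotopic_of <- function(area, hemisphere) {
  if (any(!hemisphere %in% .hemispheres)) {
    abort("hemisphere must be \"ipsi\" or \"contra\"")
  }
  tibble(area = area,
         hemisphere = if_else(hemisphere == "ipsi", "contra", "ipsi"))
}
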