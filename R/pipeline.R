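#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' `min_cells` (minimum cells per area and hemisphere, 10), `min_animals`
#' (qualifying animals for cohort inclusion, 3), `max_outside_target` (QC
#' bolus rule, 0.30), `max_whitematter` (QC white-matter rule, 0.001),
#' `include_l6b` (count L6b as L6 in fILN, `FALSE`), `alpha` (significance
#' level, 0.05), and `seed` (for any randomness, 1).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(min_cells = 10, min_animals = 3, max_outside_target = 0.30,
              max_whitematter = 0.001, include_l6b = FALSE, alpha = 0.05,
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(cfg, dots), class = "analysis_config")
}

#' Read/write analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns an [analysis_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config An [analysis_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full projectome analysis on a cohort
#'
#' Orchestrates the pipeline on one cohort: injection QC, the minimum-cell
#' filter, the cohort inclusion mask, and every figure-equivalent table --
#' hemisphere shares, labeled-area counts, homotopic share, areal and module
#' fractional counts, laminar profiles, laminar dominance (both bases), fILN
#' tables (default and both layer-ablation variants), pooled-hemisphere fILN,
#' the ipsilateral hierarchy ranking, interhemispheric fILN differences,
#' module and module-group fILN with the group comparisons, per-area symmetry
#' tests, interhemispheric correlations, and the sensory-motor laminar-change
#' analysis.
#'
#' @param coh A [cohort].
#' @param atlas Atlas tibble.
#' @param config An [analysis_config()].
#' @return A list of class `projectome_analysis`: `tables` (named list of
#'   tibbles), `manifest` (config, animals kept/excluded with reasons, config
#'   hash).
#' @export
run_analysis <- function(coh, atlas = load_atlas(), config = analysis_config()) {
  stopifnot(inherits(coh, "cohort"))
  qc <- qc_injection(coh$meta, config$max_outside_target,
                     config$max_whitematter)
  if (!any(qc$pass)) {
    abort(paste0("all animals fail injection QC:\n",
                 paste0("  ", qc$animal_id, ": ", qc$reasons, collapse = "\n")))
  }
  keep <- qc$animal_id[qc$pass]
  counts <- filter(coh$counts, .data$animal_id %in% keep)
  target <- coh$target
  filtered <- apply_min_cell_filter(counts, config$min_cells)
  mask <- area_inclusion_mask(filtered, config$min_cells, config$min_animals)

  t <- list()
  t$qc <- qc
  t$inclusion_mask <- mask
  t$hemisphere_share <- hemisphere_share(filtered, target)
  t$labeled_areas <- count_labeled_areas(filtered, target)
  t$homotopic_share <- homotopic_share(filtered, target)
  t$areal_fraction <- areal_fraction(filtered, target, inclusion = mask)
  t$module_fraction <- module_fraction(t$areal_fraction, atlas)
  t$laminar_profile <- laminar_fraction(filtered)
  dom <- dominance(filtered, basis = "per_animal")
  t$dominance_labels <- dom
  t$dominance_tally <- dominance_tally(dom)
  t$dominance_cohort <- dominance(filtered, basis = "cohort_average")

  variants <- c("default", "excl_L5", "excl_L6")
  t$filn <- list_rbind(map(variants, function(v) {
    filn_table(filtered, target, variant = v,
               include_l6b = config$include_l6b, inclusion = mask)
  }))
  filn_default <- filter(t$filn, .data$variant == "default")
  t$pooled_filn <- pooled_filn(filtered, target,
                               include_l6b = config$include_l6b)
  t$ranking <- as_tibble(rank_areas(filn_default, "ipsi", atlas))
  t$interhemispheric_delta <- interhemispheric_delta(filn_default)
  t$module_filn <- module_filn(filn_default, atlas, "six-modules")
  t$group_filn <- module_filn(filn_default, atlas, "two-groups")

  # v-a-sm ipsi vs contra, and interhemispheric delta of v-a-sm vs pf-m-l
  gw <- t$group_filn |>
    pivot_wider(names_from = "hemisphere", values_from = "filn") |>
    arrange(.data$animal_id)
  for (h in .hemispheres) if (!h %in% names(gw)) gw[[h]] <- NA_real_
  vasm <- filter(gw, .data$group == "v-a-sm")
  pfml <- filter(gw, .data$group == "pf-m-l")
  pfml <- pfml[match(vasm$animal_id, pfml$animal_id), ]
  pf <- pivot_wider(t$pooled_filn, names_from = "hemisphere",
                    values_from = "filn", id_cols = "animal_id")
  for (h in .hemispheres) if (!h %in% names(pf)) pf[[h]] <- NA_real_
  safe_test <- function(a, b, analysis, ...) {
    ok <- sum(!is.na(a) & !is.na(b)) >= 2
    res <- if (ok) compare_samples(a, b, paired = TRUE, ...) else {
      tibble(test_name = NA_character_, sidedness = NA_character_,
             alternative = NA_character_, statistic = NA_real_, p = NA_real_,
             n_a = sum(!is.na(a)), n_b = sum(!is.na(b)), routed = FALSE)
    }
    mutate(res, analysis = analysis)
  }
  t$group_tests <- list_rbind(list(
    safe_test(vasm$ipsi, vasm$contra, "vasm_ipsi_vs_contra_filn",
              test = "paired-t"),
    safe_test(vasm$contra - vasm$ipsi, pfml$contra - pfml$ipsi,
              "vasm_vs_pfml_filn_delta", test = "paired-t",
              alternative = "greater"),
    safe_test(pf$contra, pf$ipsi, "pooled_filn_contra_gt_ipsi",
              test = "paired-t", alternative = "greater")
  ))

  t$symmetry_tests <- symmetry_tests(t$areal_fraction, alpha = config$alpha)

  safe_corr <- function(df, x, y, method, analysis) {
    if (nrow(df) == 0 || !all(c(x, y) %in% names(df))) {
      return(tibble(method = method, mean = NA_real_, sem = NA_real_,
                    n_animals = 0L, analysis = analysis))
    }
    mutate(glance(correlate(df, x, y, method = method)), analysis = analysis)
  }
  fr_wide <- t$areal_fraction |>
    pivot_wider(names_from = "hemisphere", values_from = "fraction")
  t$fraction_correlation <- safe_corr(fr_wide, "ipsi", "contra", "pearson-R2",
                                      "ipsi_vs_contra_fraction")
  dl <- t$interhemispheric_delta
  t$filn_correlations <- bind_rows(
    safe_corr(dl, "ipsi", "contra", "spearman", "ipsi_vs_contra_filn"),
    safe_corr(dl, "ipsi", "delta", "spearman", "ipsi_filn_vs_delta")
  )

  lc <- laminar_change(filtered, target, atlas, alpha = config$alpha)
  t$laminar_change <- lc$changes
  t$laminar_change_tally <- lc$tally

  manifest <- list(
    package_version = as.character(utils::packageVersion("projectome")),
    target = target,
    config = unclass(config),
    animals_kept = keep,
    animals_excluded = qc$animal_id[!qc$pass],
    exclusion_reasons = setNames(qc$reasons[!qc$pass],
                                 qc$animal_id[!qc$pass]),
    config_hash = rlang::hash(unclass(config))
  )
  structure(list(tables = t, manifest = manifest),
            class = "projectome_analysis")
}

# Per-area interhemispheric symmetry: one-sample t on contra - ipsi fractional
# counts, Bonferroni-corrected over the areas tested.
symmetry_tests <- function(areal_fractions, alpha = 0.05) {
  empty <- tibble(area = character(), mean_delta = double(), n = integer(),
                  statistic = double(), p = double(), m = integer(),
                  p_adj = double(), symmetric = logical(), bias = character())
  if (nrow(areal_fractions) == 0) return(empty)
  wide <- areal_fractions |>
    pivot_wider(names_from = "hemisphere", values_from = "fraction")
  if (!all(.hemispheres %in% names(wide))) return(empty)
  wide <- filter(wide, !is.na(.data$ipsi) & !is.na(.data$contra))
  res <- wide |>
    group_by(.data$area) |>
    filter(n() >= 2, sd(.data$contra - .data$ipsi) > 0) |>
    summarise(res = list(compare_samples(.data$contra - .data$ipsi,
                                         test = "one-sample-t")),
              mean_delta = mean(.data$contra - .data$ipsi),
              n = n(), .groups = "drop") |>
    tidyr::unnest("res")
  if (nrow(res) == 0) return(empty)
  m <- nrow(res)
  res |>
    mutate(m = .env$m, p_adj = bonferroni_adjust(.data$p, .env$m),
           symmetric = .data$p_adj >= alpha,
           bias = case_when(
             .data$p_adj >= alpha ~ "none",
             .data$mean_delta > 0 ~ "contra",
             TRUE ~ "ipsi"
           )) |>
    select("area", "mean_delta", "n", "statistic", "p", "m", "p_adj",
           "symmetric", "bias")
}

#' @export
print.projectome_analysis <- function(x, ...) {
  cat("<projectome_analysis> target:", x$manifest$target,
      "| animals:", length(x$manifest$animals_kept),
      "| tables:", length(x$tables), "\n")
  invisible(x)
}

#' Write analysis tables to a directory
#'
#' One CSV per table plus a JSON manifest recording the configuration, the
#' animals kept and excluded (with the triggering rule), and a config hash.
#'
#' @param res A `projectome_analysis` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(res, dir) {
  stopifnot(inherits(res, "projectome_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(res$tables)) {
    readr::write_csv(as_tibble(res$tables[[name]]),
                     file.path(dir, paste0(name, ".csv")))
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Summarize an analysis as markdown
#'
#' A human-readable summary of the headline quantities: hemisphere shares,
#' labeled areas, homotopic share, module weights, dominance tallies, pooled
#' and group-level fILN with the associated tests, and the laminar-change
#' tallies. Missing tables are listed as absent rather than failing.
#'
#' @param res A `projectome_analysis`, or a directory written by
#'   [write_analysis()].
#' @param path Optional file to write the markdown to.
#' @return The markdown text, invisibly when `path` is given.
#' @export
summarize_analysis <- function(res, path = NULL) {
  tables <- if (inherits(res, "projectome_analysis")) {
    res$tables
  } else {
    files <- list.files(res, pattern = "\\.csv$")
    setNames(map(file.path(res, files),
                 ~ readr::read_csv(.x, show_col_types = FALSE)),
             sub("\\.csv$", "", files))
  }
  target <- if (inherits(res, "projectome_analysis")) {
    res$manifest$target
  } else {
    mf <- file.path(res, "manifest.json")
    if (file.exists(mf)) jsonlite::read_json(mf)$target else "?"
  }
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(paste0("# Projectome analysis summary (target: ", target, ")"), "")
  absent <- function(name) !name %in% names(tables)
  section <- function(title, name, body) {
    if (absent(name)) {
      c(paste0("## ", title), "", paste0("*table `", name, "` absent*"), "")
    } else {
      c(paste0("## ", title), "", body(tables[[name]]), "")
    }
  }
  lines <- c(
    lines,
    section("Hemisphere shares", "hemisphere_share", function(tb) {
      tb |>
        group_by(.data$hemisphere) |>
        summarise(m = mean_na(.data$share), s = sem_na(.data$share)) |>
        (\(d) paste0("- ", d$hemisphere, ": ", fmt(d$m), " +/- ", fmt(d$s),
                     " SEM"))()
    }),
    section("Labeled areas per hemisphere", "labeled_areas", function(tb) {
      tb |>
        group_by(.data$hemisphere) |>
        summarise(m = mean_na(.data$n_areas), lo = min(.data$n_areas),
                  hi = max(.data$n_areas)) |>
        (\(d) paste0("- ", d$hemisphere, ": mean ", fmt(d$m, 1), " (range ",
                     d$lo, "-", d$hi, ")"))()
    }),
    section("Homotopic share of contralateral cells", "homotopic_share",
            function(tb) {
      paste0("- ", fmt(mean_na(tb$share)), " +/- ", fmt(sem_na(tb$share)),
             " SEM")
    }),
    section("Module fractional counts", "module_fraction", function(tb) {
      tb |>
        group_by(.data$hemisphere, .data$module) |>
        summarise(m = mean_na(.data$fraction), .groups = "drop") |>
        arrange(.data$hemisphere, desc(.data$m)) |>
        (\(d) paste0("- ", d$hemisphere, " ", d$module, ": ", fmt(d$m)))()
    }),
    section("Laminar dominance (% of areas, per animal)", "dominance_tally",
            function(tb) {
      tb |>
        group_by(.data$hemisphere, .data$label) |>
        summarise(m = mean_na(.data$percent), .groups = "drop") |>
        (\(d) paste0("- ", d$hemisphere, " ", d$label, ": ", fmt(d$m, 1),
                     "%"))()
    }),
    section("Pooled-hemisphere fILN", "pooled_filn", function(tb) {
      tb |>
        group_by(.data$hemisphere) |>
        summarise(m = mean_na(.data$filn), s = sem_na(.data$filn)) |>
        (\(d) paste0("- ", d$hemisphere, ": ", fmt(d$m), " +/- ", fmt(d$s),
                     " SEM"))()
    }),
    section("Module-group fILN", "group_filn", function(tb) {
      tb |>
        group_by(.data$group, .data$hemisphere) |>
        summarise(m = mean_na(.data$filn), .groups = "drop") |>
        (\(d) paste0("- ", d$group, " ", d$hemisphere, ": ", fmt(d$m)))()
    }),
    section("Group tests", "group_tests", function(tb) {
      paste0("- ", tb$analysis, ": ", tb$test_name, " (", tb$sidedness,
             "-sided), p = ", fmt(tb$p, 4))
    }),
    section("Laminar change tally (v-a-sm areas)", "laminar_change_tally",
            function(tb) {
      paste0("- ", tb$layer, " ", tb$direction, ": ", tb$n_areas, " areas (",
             fmt(tb$percent, 1), "%)")
    })
  )
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
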