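#' Construct a generative ground truth
#'
#' Bundles the generative parameters of a synthetic projectome: the target
#' area, the expected ipsilateral share of cells, per-hemisphere area weights,
#' per-area laminar profiles, a Dirichlet concentration controlling
#' animal-to-animal overdispersion, and cohort dimensions. [simulate_cohort()]
#' draws cohorts from it; [recovery_report()] compares pipeline estimates
#' against it.
#'
#' @param target Target area acronym.
#' @param ipsi_share Expected fraction of cells in the ipsilateral hemisphere
#'   (in (0, 1)).
#' @param area_weights Tibble `hemisphere`, `area`, `weight`; weights must sum
#'   to 1 within each hemisphere. The ipsilateral target (the injection site)
#'   must carry weight 0.
#' @param laminar_profiles Tibble `hemisphere`, `area`, `layer`, `prob`;
#'   probabilities sum to 1 within each (hemisphere, area); agranular areas
#'   must carry zero L4 mass.
#' @param overdispersion Dirichlet concentration of per-animal perturbations
#'   (larger = less animal-to-animal variability; `Inf` = every animal uses
#'   the truth exactly).
#' @param cells_per_animal,n_animals Cohort size.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows from
#'   it.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(target, ipsi_share, area_weights, laminar_profiles,
                         overdispersion = 300, cells_per_animal = 2e5,
                         n_animals = 6, seed = 1L) {
  area_weights <- as_tibble(area_weights)
  laminar_profiles <- as_tibble(laminar_profiles)
  if (ipsi_share <= 0 || ipsi_share >= 1) abort("ipsi_share must lie in (0, 1)")
  if (overdispersion <= 0) abort("overdispersion must be positive")
  sums <- area_weights |>
    group_by(.data$hemisphere) |>
    summarise(s = sum(.data$weight))
  if (any(abs(sums$s - 1) > 1e-8)) {
    abort("area weights must sum to 1 within each hemisphere")
  }
  tgt_w <- area_weights$weight[area_weights$hemisphere == "ipsi" &
                                 area_weights$area == target]
  if (length(tgt_w) > 0 && any(tgt_w > 0)) {
    abort("the ipsilateral target (injection site) must have weight 0")
  }
  lsums <- laminar_profiles |>
    group_by(.data$hemisphere, .data$area) |>
    summarise(s = sum(.data$prob), .groups = "drop")
  if (any(abs(lsums$s - 1) > 1e-8)) {
    abort("laminar profiles must sum to 1 within each (hemisphere, area)")
  }
  structure(list(target = target, ipsi_share = ipsi_share,
                 area_weights = area_weights,
                 laminar_profiles = laminar_profiles,
                 overdispersion = overdispersion,
                 cells_per_animal = as.integer(cells_per_animal),
                 n_animals = as.integer(n_animals), seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> target:", x$target,
      "| ipsi share:", x$ipsi_share,
      "| animals:", x$n_animals, "x", x$cells_per_animal, "cells",
      "| overdispersion:", x$overdispersion, "| seed:", x$seed, "\n")
  invisible(x)
}

# Deterministic within-module spread: geometrically decreasing weights over
# member areas in atlas index order.
spread_module_weight <- function(areas, total, ratio = 0.8) {
  k <- length(areas)
  w <- ratio^(seq_len(k) - 1)
  tibble(area = areas, weight = total * w / sum(w))
}

#' Default ground truth for a study target
#'
#' A calibrated generative profile for one of the three study targets (VISp,
#' SSp-bfd, MOp): roughly 80% of cells ipsilateral; module-structured area
#' weights dominated by the home module (visual for VISp, somatomotor for the
#' others) with a strong contralateral homotopic component; laminar profiles
#' that shift mass from L2/3 to L6a contralaterally for every
#' sensory-motor-module area (generative fILN 0.65 ipsilateral vs 0.79
#' contralateral for those areas, higher for prefrontal/medial/lateral areas
#' in both hemispheres). A deterministic per-area offset spreads generative
#' fILN values across areas so rankings and correlations are non-trivial.
#'
#' @param target `"VISp"`, `"SSp-bfd"` or `"MOp"`.
#' @param atlas Atlas tibble.
#' @param ... Overrides passed to [ground_truth()] (e.g. `cells_per_animal`,
#'   `n_animals`, `overdispersion`, `seed`).
#' @return A `ground_truth`.
#' @examples
#' default_profile("VISp")$ipsi_share
#' @export
default_profile <- function(target = c("VISp", "SSp-bfd", "MOp"),
                            atlas = load_atlas(), ...) {
  target <- match.arg(target)
  module_w <- switch(
    target,
    "VISp" = c(visual = 0.42, lateral = 0.19, somatomotor = 0.15,
               medial = 0.12, auditory = 0.07, prefrontal = 0.05),
    "SSp-bfd" = c(somatomotor = 0.62, visual = 0.16, lateral = 0.10,
                  medial = 0.05, prefrontal = 0.04, auditory = 0.03),
    "MOp" = c(somatomotor = 0.83, lateral = 0.08, prefrontal = 0.06,
              medial = 0.01, visual = 0.01, auditory = 0.01)
  )
  ipsi_w <- purrr::imap(module_w, function(total, mod) {
    areas <- atlas$acronym[atlas$module == mod]
    spread_module_weight(areas, total)
  }) |> list_rbind()
  # injection site never contributes ipsilateral cells
  ipsi_w$weight[ipsi_w$area == target] <- 0
  ipsi_w$weight <- ipsi_w$weight / sum(ipsi_w$weight)
  # contralateral: homotopic target takes a large share, the rest mirrors the
  # ipsilateral structure with the lateral module strengthened
  homotopic_share <- 0.35
  contra_rest <- ipsi_w |>
    mutate(weight = .data$weight *
             if_else(module_of(.data$area, atlas) == "lateral", 1.5, 1)) |>
    mutate(weight = .data$weight / sum(.data$weight) * (1 - homotopic_share))
  contra_w <- contra_rest
  contra_w$weight[contra_w$area == target] <- homotopic_share
  contra_w$weight <- contra_w$weight / sum(contra_w$weight)
  area_weights <- bind_rows(
    mutate(ipsi_w, hemisphere = "ipsi"),
    mutate(contra_w, hemisphere = "contra")
  ) |> select("hemisphere", "area", "weight")

  groups <- module_groupings()
  laminar_profiles <- tidyr::expand_grid(hemisphere = .hemispheres,
                                         area = atlas$acronym) |>
    mutate(
      module = module_of(.data$area, atlas),
      group = groups$group[match(.data$module, groups$module)],
      index = atlas$index[match(.data$area, atlas$acronym)],
      has_L4 = atlas$has_L4[match(.data$area, atlas$acronym)]
    ) |>
    pmap(function(hemisphere, area, module, group, index, has_L4) {
      base <- if (group == "v-a-sm") {
        if (hemisphere == "ipsi") c(`L2/3` = 0.35, L5 = 0.25, L6a = 0.40)
        else c(`L2/3` = 0.21, L5 = 0.28, L6a = 0.51)
      } else {
        if (hemisphere == "ipsi") c(`L2/3` = 0.15, L5 = 0.30, L6a = 0.55)
        else c(`L2/3` = 0.12, L5 = 0.30, L6a = 0.58)
      }
      # deterministic per-area offset moving mass between L2/3 and L6a;
      # halved contralaterally so the two hemispheres stay correlated while
      # the contralateral distribution is more compressed
      d <- (((index * 7) %% 11) - 5) / 50
      if (hemisphere == "contra") d <- d / 2
      d <- max(min(d, base[["L2/3"]] - 0.02), -(base[["L6a"]] - 0.02))
      base[["L2/3"]] <- base[["L2/3"]] - d
      base[["L6a"]] <- base[["L6a"]] + d
      extra <- if (has_L4) c(L4 = 0.06, L6b = 0.02) else c(L6b = 0.02)
      p <- c(base * (1 - sum(extra)), extra)
      tibble(hemisphere = hemisphere, area = area,
             layer = names(p), prob = unname(p))
    }) |>
    list_rbind()

  args <- modifyList(
    list(target = target, ipsi_share = 0.8, area_weights = area_weights,
         laminar_profiles = laminar_profiles),
    list(...)
  )
  do.call(ground_truth, args)
}

#' Toy ground truth for quick examples
#'
#' A three-area, two-animal, 100-cell preset that runs in milliseconds, for
#' examples and fast tests.
#'
#' @param ... Overrides passed to [ground_truth()].
#' @return A `ground_truth`.
#' @export
toy_profile <- function(...) {
  areas <- c("VISp", "VISal", "MOp")
  aw <- bind_rows(
    tibble(hemisphere = "ipsi", area = areas, weight = c(0, 0.7, 0.3)),
    tibble(hemisphere = "contra", area = areas, weight = c(0.5, 0.3, 0.2))
  )
  lp <- tidyr::expand_grid(hemisphere = .hemispheres, area = areas) |>
    pmap(function(hemisphere, area) {
      p <- if (hemisphere == "ipsi") c(`L2/3` = 0.35, L5 = 0.25, L6a = 0.40)
           else c(`L2/3` = 0.20, L5 = 0.28, L6a = 0.52)
      if (area != "MOp") {                      # MOp is agranular: no L4
        p <- c(p * 0.92, L4 = 0.06, L6b = 0.02)
      } else {
        p <- c(p * 0.98, L6b = 0.02)
      }
      tibble(hemisphere = hemisphere, area = area, layer = names(p),
             prob = unname(p))
    }) |>
    list_rbind()
  args <- modifyList(
    list(target = "VISp", ipsi_share = 0.8, area_weights = aw,
         laminar_profiles = lp, overdispersion = 300,
         cells_per_animal = 100L, n_animals = 2L, seed = 1L),
    list(...)
  )
  do.call(ground_truth, args)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {                      # numerically degenerate draw
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Simulate a cohort from a ground truth
#'
#' Draws a cohort of animals from a `ground_truth`. For each animal, the
#' hemisphere split, per-hemisphere area weights, and per-area laminar
#' profiles are perturbed with Dirichlet noise of concentration
#' `overdispersion * truth`, then `cells_per_animal` cells are drawn
#' categorically from the resulting joint distribution over
#' (hemisphere, area, layer). Both the per-cell event list (one row per
#' detected cell -- the brute-force oracle substrate) and the aggregated count
#' table are returned; the whole draw is reproducible from the seed stored in
#' the truth.
#'
#' @param gt A [ground_truth()].
#' @param events Keep the per-cell event list (default `TRUE`).
#' @return A [cohort] whose `counts`/`events`/`truth` fields are filled in and
#'   whose metadata records a clean injection for every animal.
#' @examples
#' coh <- simulate_cohort(toy_profile())
#' sum(coh$counts$count)   # 2 animals x 100 cells
#' @export
simulate_cohort <- function(gt, events = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  joint_truth <- inner_join(gt$area_weights, gt$laminar_profiles,
                            by = c("hemisphere", "area")) |>
    mutate(hemi_w = if_else(.data$hemisphere == "ipsi", gt$ipsi_share,
                            1 - gt$ipsi_share),
           prob_joint = .data$hemi_w * .data$weight * .data$prob)

  sim_one <- function(id) {
    if (is.infinite(gt$overdispersion)) {
      p <- joint_truth$prob_joint
    } else {
      c0 <- gt$overdispersion
      s <- rdirichlet1(c0 * c(gt$ipsi_share, 1 - gt$ipsi_share))
      aw <- gt$area_weights |>
        group_by(.data$hemisphere) |>
        mutate(w_animal = rdirichlet1(c0 * .data$weight)) |>
        ungroup()
      lp <- gt$laminar_profiles |>
        group_by(.data$hemisphere, .data$area) |>
        mutate(p_animal = rdirichlet1(c0 * .data$prob)) |>
        ungroup()
      p <- inner_join(aw, lp, by = c("hemisphere", "area")) |>
        mutate(hemi_w = if_else(.data$hemisphere == "ipsi", s[1], s[2]),
               pj = .data$hemi_w * .data$w_animal * .data$p_animal) |>
        pull("pj")
    }
    idx <- sample.int(nrow(joint_truth), size = gt$cells_per_animal,
                      replace = TRUE, prob = p)
    tibble(animal_id = id,
           hemisphere = joint_truth$hemisphere[idx],
           area = joint_truth$area[idx],
           layer = joint_truth$layer[idx])
  }

  ids <- sprintf("sim%02d", seq_len(gt$n_animals))
  ev <- withr::with_seed(gt$seed, list_rbind(map(ids, sim_one)))
  counts <- ev |>
    group_by(.data$animal_id, .data$hemisphere, .data$area, .data$layer) |>
    summarise(count = n(), .groups = "drop")
  # impute unobserved (hemisphere, area, layer) cells of the truth support as 0
  grid <- tidyr::expand_grid(
    animal_id = ids,
    distinct(gt$laminar_profiles, .data$hemisphere, .data$area, .data$layer))
  counts <- left_join(grid, counts,
                      by = c("animal_id", "hemisphere", "area", "layer")) |>
    mutate(count = as.integer(replace_na(.data$count, 0L)))
  meta <- tibble(animal_id = ids, target_area = gt$target,
                 injection_hemisphere = "left",
                 frac_bolus_outside_target = 0.05,
                 frac_whitematter_bolus = 5e-4)
  cohort(counts, meta, gt$target,
         events = if (events) ev else NULL, truth = gt)
}

#' Compare pipeline estimates against the generative truth
#'
#' Runs the estimation side of the pipeline on a simulated cohort and tabulates
#' generative versus estimated values for the ipsilateral share, per-area
#' fractional counts, per-area fILN, and sensory-motor group fILN per
#' hemisphere.
#'
#' @param coh A [cohort] produced by [simulate_cohort()] (its `truth` field is
#'   used), or any cohort plus an explicit `gt`.
#' @param gt Ground truth (defaults to `coh$truth`).
#' @param atlas Atlas tibble.
#' @param min_cells Minimum-cell filter threshold applied before estimation.
#' @return A tibble `quantity`, `hemisphere`, `area`, `truth`, `estimate`,
#'   `abs_error`.
#' @export
recovery_report <- function(coh, gt = coh$truth, atlas = load_atlas(),
                            min_cells = 10) {
  stopifnot(inherits(coh, "cohort"), inherits(gt, "ground_truth"))
  filtered <- apply_min_cell_filter(coh, min_cells)

  hs <- hemisphere_share(filtered) |>
    filter(.data$hemisphere == "ipsi") |>
    summarise(estimate = mean_na(.data$share))
  out <- tibble(quantity = "ipsi_share", hemisphere = "ipsi",
                area = NA_character_, truth = gt$ipsi_share,
                estimate = hs$estimate)

  af <- areal_fraction(filtered, exclude_homotopic_contra = FALSE) |>
    group_by(.data$hemisphere, .data$area) |>
    summarise(estimate = mean_na(.data$fraction), .groups = "drop") |>
    inner_join(gt$area_weights, by = c("hemisphere", "area")) |>
    filter(!(.data$hemisphere == "ipsi" & .data$area == gt$target)) |>
    mutate(quantity = "area_fraction") |>
    select("quantity", "hemisphere", "area", truth = "weight", "estimate")

  truth_filn <- gt$laminar_profiles |>
    filter(.data$layer %in% c("L2/3", "L5", "L6a")) |>
    pivot_wider(names_from = "layer", values_from = "prob") |>
    mutate(truth = filn(.data$`L2/3`, .data$L5, .data$L6a)) |>
    select("hemisphere", "area", "truth")
  ft <- filn_table(filtered)
  est_filn <- ft |>
    group_by(.data$hemisphere, .data$area) |>
    summarise(estimate = mean_na(.data$filn), .groups = "drop") |>
    inner_join(truth_filn, by = c("hemisphere", "area")) |>
    filter(!is.na(.data$estimate)) |>
    mutate(quantity = "area_filn") |>
    select("quantity", "hemisphere", "area", "truth", "estimate")

  vasm <- atlas$acronym[atlas$module %in% module_groupings("v-a-sm")]
  truth_group <- truth_filn |>
    filter(.data$area %in% vasm,
           !(.data$hemisphere == "ipsi" & .data$area == gt$target)) |>
    group_by(.data$hemisphere) |>
    summarise(truth = mean(.data$truth))
  est_group <- module_filn(ft, atlas, grouping = "two-groups") |>
    filter(.data$group == "v-a-sm") |>
    group_by(.data$hemisphere) |>
    summarise(estimate = mean_na(.data$filn))
  grp <- inner_join(truth_group, est_group, by = "hemisphere") |>
    mutate(quantity = "vasm_filn", area = NA_character_) |>
    select("quantity", "hemisphere", "area", "truth", "estimate")

  bind_rows(out, af, est_filn, grp) |>
    mutate(abs_error = abs(.data$estimate - .data$truth))
}

#' Serialize a ground truth to JSON
#'
#' @param gt A [ground_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  x <- unclass(gt)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground truth from JSON
#'
#' @param path Path written by [write_ground_truth()].
#' @return A [ground_truth()].
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(target = x$target, ipsi_share = x$ipsi_share,
               area_weights = as_tibble(x$area_weights),
               laminar_profiles = as_tibble(x$laminar_profiles),
               overdispersion = x$overdispersion,
               cells_per_animal = x$cells_per_animal,
               n_animals = x$n_animals, seed = x$seed)
}
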