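atlas <- load_atlas()

test_that("count tables are parsed, zero-imputed and validated", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_counts(
    list("m1", "ipsi", "VISl", "L2/3", 50),
    list("m1", "ipsi", "VISl", "L5", 30),
    list("m1", "contra", "MOp", "L6a", 20)
  ), tmp)
  x <- read_count_table(tmp, atlas)
  expect_equal(sum(x$count > 0), 3)
  expect_equal(sum(x$count), 100)
  # zero-imputed grid covers both hemispheres and all atlas areas
  expect_setequal(unique(x$hemisphere), c("ipsi", "contra"))
  expect_setequal(unique(x$area), atlas$acronym)
  # agranular areas get no L4 row even after imputation
  expect_equal(nrow(dplyr::filter(x, area == "MOp", layer == "L4")), 0)

  readr::write_csv(make_counts(list("m1", "ipsi", "VISl", "L5", -1)), tmp)
  expect_error(read_count_table(tmp, atlas), "non-negative")

  readr::write_csv(make_counts(list("m1", "ipsi", "MOp", "L4", 5)), tmp)
  expect_error(read_count_table(tmp, atlas), "agranular")

  readr::write_csv(make_counts(list("m1", "ipsi", "XYZ", "L5", 5)), tmp)
  expect_error(read_count_table(tmp, atlas), "unknown area")
})

test_that("left/right tables are flipped via sidecar metadata", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(animal_id = "m1",
                                  hemisphere = c("right", "left"),
                                  area = "VISl", layer = "L5",
                                  count = c(80L, 20L)), tmp)
  expect_error(read_count_table(tmp, atlas), "injection_hemisphere")
  jsonlite::write_json(list(animal_id = "m1", target_area = "VISp",
                            injection_hemisphere = "right",
                            frac_bolus_outside_target = 0.1,
                            frac_whitematter_bolus = 0),
                       paste0(tmp, ".json"), auto_unbox = TRUE)
  x <- read_count_table(tmp, atlas)
  expect_equal(sum(x$count[x$hemisphere == "ipsi"]), 80)
  expect_equal(sum(x$count[x$hemisphere == "contra"]), 20)
})

test_that("injection QC applies the bolus and white-matter rules", {
  meta <- tibble::tibble(
    animal_id = c("a", "b", "c", "d", "e"),
    frac_bolus_outside_target = c(0.35, 0.0, 0.0, 0.30, 0.0),
    frac_whitematter_bolus = c(0.0, 0.0012, 0.0, 0.0, 0.001)
  )
  qc <- qc_injection(meta)
  expect_equal(qc$pass, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_match(qc$reasons[1], "bolus outside target")
  expect_match(qc$reasons[2], "white-matter")
  expect_equal(qc$reasons[3], "")
  # boundary semantics: fail only strictly above 30%; fail at exactly 0.1%
  expect_true(qc$pass[4])
  expect_false(qc$pass[5])
  expect_error(qc_injection(dplyr::mutate(meta,
                                          frac_whitematter_bolus = 1.2)),
               "\\[0, 1\\]")
})

test_that("minimum-cell filter zeroes sparse areas per hemisphere", {
  x <- make_counts(
    list("m1", "ipsi", "VISl", "L2/3", 4),
    list("m1", "ipsi", "VISl", "L5", 5),      # VISl ipsi total 9 -> zeroed
    list("m1", "ipsi", "VISal", "L5", 10),    # exactly 10 -> retained
    list("m1", "contra", "VISl", "L5", 50)    # other hemisphere untouched
  )
  f <- apply_min_cell_filter(x)
  expect_equal(sum(f$count[f$area == "VISl" & f$hemisphere == "ipsi"]), 0)
  expect_equal(sum(f$count[f$area == "VISal"]), 10)
  expect_equal(sum(f$count[f$hemisphere == "contra"]), 50)
  # idempotent and monotone (never increases a count)
  expect_identical(apply_min_cell_filter(f), f)
  expect_true(all(f$count <= x$count))
  # identity on the empty table
  empty <- x[0, ]
  expect_identical(apply_min_cell_filter(empty), empty)
  expect_error(apply_min_cell_filter(x, threshold = 0), ">= 1")
})

test_that("cohort inclusion mask needs three qualifying animals in the same hemisphere", {
  base <- function(ids, hemisphere, area, n) {
    purrr::list_rbind(purrr::map(ids, ~ one_cell_block(.x, hemisphere, area,
                                                       "L5", n)))
  }
  x <- dplyr::bind_rows(
    base(c("m1", "m2", "m3"), "ipsi", "VISl", 15),    # 3 mice -> in
    base(c("m1", "m2"), "ipsi", "VISal", 20),         # 2 mice -> out
    base(c("m1", "m2"), "ipsi", "AUDp", 12),          # 2 ipsi + 1 contra
    base("m3", "contra", "AUDp", 12),                 #   -> out both
    base(c("m4", "m5", "m6"), "ipsi", "TEa", 3)       # < 10 cells -> out
  )
  mask <- area_inclusion_mask(x)
  expect_equal(nrow(mask), 1)
  expect_equal(mask$area, "VISl")
  expect_equal(mask$hemisphere, "ipsi")
  expect_equal(mask$n_animals, 3L)
  # mask shrinks (or stays equal) as thresholds rise
  lax <- area_inclusion_mask(x, min_cells = 10, min_animals = 2)
  strict <- area_inclusion_mask(x, min_cells = 16, min_animals = 2)
  expect_true(nrow(strict) <= nrow(lax))
  expect_true(nrow(mask) <= nrow(lax))
})

test_that("hemisphere flipping is injection-relative, conservative and idempotent", {
  x <- tibble::tibble(animal_id = "m1", hemisphere = c("right", "left"),
                      area = "VISl", layer = "L5", count = c(7L, 3L))
  f <- flip_to_injection_frame(x, "right")
  expect_equal(f$hemisphere, c("ipsi", "contra"))
  f2 <- flip_to_injection_frame(x, "left")
  expect_equal(f2$hemisphere, c("contra", "ipsi"))
  expect_equal(sum(f$count), sum(x$count))
  # idempotent on already-flipped data
  expect_identical(flip_to_injection_frame(f, "right"), f)
  expect_error(flip_to_injection_frame(x, NULL), "injection_hemisphere")
})

test_that("cohorts round-trip through a directory", {
  gt <- toy_profile(seed = 11L)
  coh <- simulate_cohort(gt)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, atlas)
  expect_equal(back$target, "VISp")
  expect_equal(sort(unique(back$counts$animal_id)),
               sort(unique(coh$counts$animal_id)))
  # identical nonzero cells (read_cohort zero-imputes the full atlas grid)
  orig <- dplyr::arrange(dplyr::filter(coh$counts, count > 0),
                         animal_id, hemisphere, area, layer)
  got <- dplyr::arrange(dplyr::filter(back$counts, count > 0),
                        animal_id, hemisphere, area, layer)
  expect_equal(got, orig)
  expect_equal(read_ground_truth(file.path(dir, "ground_truth.json"))$seed,
               11L)
})
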