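atlas <- load_atlas()

test_that("fILN formula and ablation variants match hand arithmetic", {
  expect_equal(filn(0.30, 0.30, 0.40), 0.7)
  # no supragranular input -> 1 regardless of the infragranular split
  expect_equal(filn(0, 0.4, 0.6), 1)
  expect_equal(filn(0, 5, 0), 1)
  # counts work identically to fractions
  expect_equal(filn(20, 30, 50), 0.8)
  expect_equal(filn(20, 30, 50, variant = "excl_L6"), 30 / 50)
  expect_equal(filn(20, 30, 50, variant = "excl_L5"), 50 / 70)
  # undefined when the denominator is empty
  expect_true(is.na(filn(0, 0, 0)))
  expect_true(is.na(filn(0, 5, 0, variant = "excl_L5")))
  expect_error(filn(-0.1, 0.5, 0.6), "non-negative")
})

test_that("fILN bounds and ablation monotonicity hold on a profile grid", {
  g <- seq(0, 1, by = 0.05)
  grid <- expand.grid(l23 = g, l5 = g)
  grid <- grid[grid$l23 + grid$l5 <= 1, ]
  grid$l6 <- 1 - grid$l23 - grid$l5
  d <- filn(grid$l23, grid$l5, grid$l6)
  e5 <- filn(grid$l23, grid$l5, grid$l6, variant = "excl_L5")
  e6 <- filn(grid$l23, grid$l5, grid$l6, variant = "excl_L6")
  defined <- !is.na(d)
  expect_true(all(d[defined] >= 0 & d[defined] <= 1))
  expect_true(all(d[defined & !is.na(e5)] >= e5[defined & !is.na(e5)]))
  expect_true(all(d[defined & !is.na(e6)] >= e6[defined & !is.na(e6)]))
  # boundary characterization
  expect_true(all((d[defined] == 0) ==
                    (grid$l5[defined] == 0 & grid$l6[defined] == 0)))
  expect_true(all((d[defined] == 1) == (grid$l23[defined] == 0)))
})

test_that("fILN tables handle injection site, pooling and L6b switch", {
  x <- dplyr::bind_rows(
    make_counts(list("m1", "ipsi", "VISl", "L5", 30),
                list("m1", "ipsi", "VISl", "L6a", 50),
                list("m1", "ipsi", "VISl", "L2/3", 20),
                list("m1", "ipsi", "VISal", "L5", 40),
                list("m1", "ipsi", "VISal", "L2/3", 60),
                list("m1", "ipsi", "VISp", "L2/3", 999))
  )
  ft <- filn_table(x, target = "VISp")
  expect_equal(ft$filn[ft$area == "VISl"], 0.8)
  expect_equal(ft$filn[ft$area == "VISal"], 0.4)
  # the injection site is undefined by construction
  expect_true(is.na(ft$filn[ft$area == "VISp" & ft$hemisphere == "ipsi"]))
  # pooled fILN equals the formula on summed counts (injection site excluded)
  pf <- pooled_filn(x, target = "VISp")
  expect_equal(pf$filn[pf$hemisphere == "ipsi"],
               (30 + 50 + 40) / (20 + 60 + 30 + 50 + 40))
  # L6b counts enter only when requested
  y <- make_counts(list("m1", "ipsi", "VISl", "L2/3", 50),
                   list("m1", "ipsi", "VISl", "L6a", 30),
                   list("m1", "ipsi", "VISl", "L6b", 20))
  expect_equal(filn_table(y)$filn, 30 / 80)
  expect_equal(filn_table(y, include_l6b = TRUE)$filn, 50 / 100)
  # a cohort where every area lacks L2/3 input is all-feedback
  z <- dplyr::bind_rows(one_cell_block(area = "VISl", layer = "L5"),
                        one_cell_block(area = "VISal", layer = "L6a"))
  expect_equal(filn_table(z)$filn, c(1, 1))
})

test_that("inclusion mask turns excluded areas into NA fILN", {
  x <- dplyr::bind_rows(
    make_counts(list("m1", "ipsi", "VISl", "L5", 30),
                list("m1", "ipsi", "VISal", "L5", 40))
  )
  mask <- tibble::tibble(hemisphere = "ipsi", area = "VISl")
  ft <- filn_table(x, inclusion = mask)
  expect_false(is.na(ft$filn[ft$area == "VISl"]))
  expect_true(is.na(ft$filn[ft$area == "VISal"]))
})

test_that("dominance is the argmax with ties toward the deeper layer", {
  x <- make_counts(list("m1", "ipsi", "VISl", "L2/3", 50),
                   list("m1", "ipsi", "VISl", "L5", 30),
                   list("m1", "ipsi", "VISl", "L6a", 20))
  expect_equal(dominance(x)$label, "L2/3")
  # L6 = L6a + L6b for dominance
  y <- make_counts(list("m1", "ipsi", "VISl", "L2/3", 40),
                   list("m1", "ipsi", "VISl", "L6a", 25),
                   list("m1", "ipsi", "VISl", "L6b", 20))
  expect_equal(dominance(y)$label, "L6")
  # tie between L5 and L6 -> deeper layer wins
  z <- make_counts(list("m1", "ipsi", "VISl", "L2/3", 20),
                   list("m1", "ipsi", "VISl", "L5", 40),
                   list("m1", "ipsi", "VISl", "L6a", 40))
  expect_equal(dominance(z)$label, "L6")
  # undefined profile -> NA label
  w <- one_cell_block(layer = "L4")
  expect_true(is.na(dominance(w)$label))
})

test_that("per-animal dominance tallies recount a constructed cohort", {
  # 6 L6-dominant and 4 L2/3-dominant areas for each of 2 animals -> 60/40
  areas6 <- c("VISl", "VISal", "VISam", "VISpm", "AUDp", "AUDd")
  areas23 <- c("SSp-bfd", "SSs", "MOs", "TEa")
  mk <- function(id) {
    dplyr::bind_rows(
      purrr::list_rbind(purrr::map(areas6, ~ make_counts(
        list(id, "ipsi", .x, "L6a", 60), list(id, "ipsi", .x, "L2/3", 40)))),
      purrr::list_rbind(purrr::map(areas23, ~ make_counts(
        list(id, "ipsi", .x, "L6a", 40), list(id, "ipsi", .x, "L2/3", 60))))
    )
  }
  x <- dplyr::bind_rows(mk("m1"), mk("m2"))
  tally <- dominance_tally(dominance(x, basis = "per_animal"))
  expect_equal(tally$percent[tally$label == "L6"], c(60, 60))
  expect_equal(tally$percent[tally$label == "L2/3"], c(40, 40))
  expect_equal(tally$percent[tally$label == "L5"], c(0, 0))
  # cohort-average basis labels the mean profile once per area
  lab <- dominance(x, basis = "cohort_average")
  expect_false("animal_id" %in% names(lab))
  expect_equal(sum(lab$label == "L6"), 6)
})

test_that("ranking is ascending, NaN-aware and index-tie-broken", {
  ft <- tibble::tibble(
    animal_id = rep(c("m1", "m2"), each = 3),
    hemisphere = "ipsi",
    area = rep(c("VISl", "AUDp", "TEa"), 2),
    filn = c(0.9, 0.6, 0.4, 0.9, NA, 0.4),
    variant = "default"
  )
  rk <- rank_areas(ft, "ipsi", atlas)
  expect_equal(rk$area, c("TEa", "AUDp", "VISl"))
  expect_equal(rk$mean_filn, c(0.4, 0.6, 0.9))
  # the NA animal does not contribute to AUDp's mean or n
  expect_equal(rk$n[rk$area == "AUDp"], 1L)
  expect_equal(rk$n[rk$area == "TEa"], 2L)
  # equal means -> lower atlas index first (VISal index 28 < VISrl index 35)
  ft2 <- tibble::tibble(animal_id = "m1", hemisphere = "ipsi",
                        area = c("VISrl", "VISal"), filn = c(0.5, 0.5),
                        variant = "default")
  expect_equal(rank_areas(ft2, "ipsi", atlas)$area, c("VISal", "VISrl"))
  # areas with no defined values are dropped with a warning
  ft3 <- dplyr::bind_rows(ft2, tibble::tibble(
    animal_id = "m1", hemisphere = "ipsi", area = "AUDd",
    filn = NA_real_, variant = "default"))
  expect_warning(rk3 <- rank_areas(ft3, "ipsi", atlas), "AUDd")
  expect_equal(nrow(rk3), 2)
})

test_that("interhemispheric differences propagate undefined values", {
  ft <- tibble::tibble(
    animal_id = "m1", hemisphere = rep(c("ipsi", "contra"), 3),
    area = rep(c("VISl", "AUDp", "TEa"), each = 2),
    filn = c(0.5, 0.5, 0.42, 0.66, NA, 0.7),
    variant = "default"
  )
  d <- interhemispheric_delta(ft)
  expect_equal(d$delta[d$area == "VISl"], 0)
  expect_equal(d$delta[d$area == "AUDp"], 0.24)
  expect_true(is.na(d$delta[d$area == "TEa"]))
})

test_that("module and group fILN are unweighted NaN-aware means over areas", {
  vis <- atlas$acronym[atlas$module == "visual"]
  ft <- tibble::tibble(animal_id = "m1", hemisphere = "ipsi",
                       area = vis, filn = 0.8, variant = "default")
  mf <- module_filn(ft, atlas, "six-modules")
  expect_equal(mf$filn[mf$module == "visual"], 0.8)
  # group mean equals the mean of concatenated member-area values
  aud <- atlas$acronym[atlas$module == "auditory"]
  ft2 <- dplyr::bind_rows(ft, tibble::tibble(
    animal_id = "m1", hemisphere = "ipsi", area = aud, filn = 0.4,
    variant = "default"))
  gf <- module_filn(ft2, atlas, "two-groups")
  expect_equal(gf$filn[gf$group == "v-a-sm"],
               mean(c(rep(0.8, length(vis)), rep(0.4, length(aud)))))
  # a module with no defined member areas is NA
  ft3 <- tibble::tibble(animal_id = "m1", hemisphere = "ipsi",
                        area = c(vis, "AUDp"), filn = c(rep(0.5, length(vis)),
                                                        NA),
                        variant = "default")
  mf3 <- module_filn(ft3, atlas, "six-modules")
  expect_true(is.na(mf3$filn[mf3$module == "auditory"]))
})

test_that("laminar-change analysis detects constructed contralateral shifts", {
  vasm <- atlas$acronym[atlas$module %in% module_groupings("v-a-sm")]
  vasm <- setdiff(vasm, "VISp")
  shifted <- vasm[seq(1, length(vasm), by = 2)]   # half the areas shift
  mk <- function(id) {
    purrr::list_rbind(purrr::map(vasm, function(a) {
      up <- a %in% shifted
      jit <- (match(id, c("m1", "m2", "m3", "m4")) - 2.5)  # animal noise
      ipsi <- c(40 + jit, 30, 30 - jit)
      contra <- if (up) c(25 + jit / 2, 30, 45 - jit / 2) else ipsi
      make_counts(list(id, "ipsi", a, "L2/3", round(ipsi[1] * 10)),
                  list(id, "ipsi", a, "L5", round(ipsi[2] * 10)),
                  list(id, "ipsi", a, "L6a", round(ipsi[3] * 10)),
                  list(id, "contra", a, "L2/3", round(contra[1] * 10)),
                  list(id, "contra", a, "L5", round(contra[2] * 10)),
                  list(id, "contra", a, "L6a", round(contra[3] * 10)))
    }))
  }
  x <- dplyr::bind_rows(mk("m1"), mk("m2"), mk("m3"), mk("m4"))
  lc <- laminar_change(x, target = "VISp", atlas)
  tal <- lc$tally
  frac_up_l6a <- tal$percent[tal$layer == "L6a" & tal$direction == "increase"]
  frac_dn_l23 <- tal$percent[tal$layer == "L2/3" & tal$direction == "decrease"]
  expect_equal(frac_up_l6a, 100 * length(shifted) / length(vasm))
  expect_equal(frac_dn_l23, 100 * length(shifted) / length(vasm))
  expect_equal(tal$n_areas[tal$layer == "L5" & tal$direction == "increase"], 0)
  # identical hemispheres -> zero change, nothing significant
  y <- purrr::list_rbind(purrr::map(c("m1", "m2", "m3"), mk))
  y_sym <- dplyr::bind_rows(
    dplyr::filter(y, hemisphere == "ipsi"),
    dplyr::mutate(dplyr::filter(y, hemisphere == "ipsi"),
                  hemisphere = "contra"))
  lc2 <- laminar_change(y_sym, target = "VISp", atlas)
  expect_true(all(lc2$changes$mean_change == 0))
  expect_true(all(lc2$changes$direction == "ns"))
  # the homotopic target never appears
  expect_false("VISp" %in% lc$changes$area)
})
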