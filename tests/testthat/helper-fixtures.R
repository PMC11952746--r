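# Shared fixtures: tiny count tables built in code.

# One row per (animal, hemisphere, area, layer); `...` are rows as lists.
make_counts <- function(...) {
  rows <- list(...)
  purrr::list_rbind(purrr::map(rows, function(r) {
    tibble::tibble(animal_id = r[[1]], hemisphere = r[[2]], area = r[[3]],
                   layer = r[[4]], count = as.integer(r[[5]]))
  }))
}

# A single-animal table with `n` cells in one (hemisphere, area, layer) cell.
one_cell_block <- function(animal = "m1", hemisphere = "ipsi", area = "VISl",
                           layer = "L5", n = 100) {
  make_counts(list(animal, hemisphere, area, layer, n))
}

# Brute-force recount of an event list into fractions/fILN, used as the
# independent oracle against the package's vectorized implementations.
oracle_from_events <- function(events) {
  ev <- events
  list(
    hemisphere_share = function(animal, target) {
      e <- ev[ev$animal_id == animal &
                !(ev$hemisphere == "ipsi" & ev$area == target), ]
      c(ipsi = sum(e$hemisphere == "ipsi") / nrow(e),
        contra = sum(e$hemisphere == "contra") / nrow(e))
    },
    areal_fraction = function(animal, hemisphere, area, target,
                              drop_contra_homotopic = FALSE) {
      e <- ev[ev$animal_id == animal & ev$hemisphere == hemisphere, ]
      e <- e[!(e$hemisphere == "ipsi" & e$area == target), ]
      if (drop_contra_homotopic) {
        e <- e[!(e$hemisphere == "contra" & e$area == target), ]
      }
      sum(e$area == area) / nrow(e)
    },
    laminar_fraction = function(animal, hemisphere, area, layer, universe) {
      e <- ev[ev$animal_id == animal & ev$hemisphere == hemisphere &
                ev$area == area & ev$layer %in% universe, ]
      if (nrow(e) == 0) return(NA_real_)
      sum(e$layer == layer) / nrow(e)
    },
    filn = function(animal, hemisphere, area) {
      e <- ev[ev$animal_id == animal & ev$hemisphere == hemisphere &
                ev$area == area, ]
      l23 <- sum(e$layer == "L2/3")
      l5 <- sum(e$layer == "L5")
      l6 <- sum(e$layer == "L6a")
      if (l23 + l5 + l6 == 0) return(NA_real_)
      (l5 + l6) / (l23 + l5 + l6)
    },
    dominance = function(animal, hemisphere, area) {
      e <- ev[ev$animal_id == animal & ev$hemisphere == hemisphere &
                ev$area == area, ]
      v <- c(`L2/3` = sum(e$layer == "L2/3"), L5 = sum(e$layer == "L5"),
             L6 = sum(e$layer %in% c("L6a", "L6b")))
      if (sum(v) == 0) return(NA_character_)
      names(v)[max(which(v == max(v)))]   # tie -> deeper layer
    }
  )
}
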