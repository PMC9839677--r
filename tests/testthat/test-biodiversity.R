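test_that("desert mask requires a desert habitat and under 500 mm rain", {
  land <- toy_landscape(2, 3)
  land$habitat <- matrix(c(1L, 1L, 10L, 2L, 1L, 11L), 2, 3)
  prec <- matrix(c(400, 600, 100, 499, 500, 200), 2, 3)
  m <- build_desert_mask(land, prec)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(build_desert_mask(land, matrix(100, 3, 3)), "aligned")
})

test_that("AOH refinement intersects range, habitat and elevation", {
  land <- toy_landscape(2, 5) # 10 cells
  land$habitat <- matrix(c(1L, 1L, 1L, 1L, 10L, 10L, 10L, 10L, 10L, 10L), 2)
  land$elev <- matrix(c(100, 100, 900, 100, 100, 100, 100, 100, 100, 100), 2)
  sp <- toy_species("a", 1:10, habitat = 1L, elev = c(0, 500))
  a <- refine_aoh(sp, land)
  # brute-force set intersection
  want <- intersect(intersect(1:10, which(land$habitat == 1L)),
                    which(land$elev >= 0 & land$elev <= 500))
  expect_identical(a$cells, want)
  expect_identical(a$area_cells, 3L)
  expect_equal(a$area_km2, 3 * 50^2)
  # everything suitable: AOH = range
  all_ok <- refine_aoh(toy_species("b", 3:7), toy_landscape(2, 5))
  expect_identical(all_ok$cells, 3:7)
  # nothing suitable: dropped with a log entry
  none <- toy_species("c", 1:4, elev = c(5000, 6000))
  expect_null(refine_aoh(none, land))
  res <- refine_aoh_all(list(sp, none), land)
  expect_length(res$aohs, 1)
  expect_identical(res$log$retained, c(TRUE, FALSE))
  expect_error(refine_aoh(toy_species("d", 1:99), land), "extent")
})

test_that("desert birds are kept at >= 90% of AOH in desert", {
  land <- toy_landscape(2, 5)
  desert <- matrix(TRUE, 2, 5)
  desert[1:2] <- FALSE # cells 1, 2 are not desert
  mk <- function(cells) structure(list(id = "x", cells = cells,
    area_cells = length(cells), area_km2 = 1, mass_g = 30), class = "aoh")
  expect_length(select_desert_birds(list(mk(3:10)), desert), 1)    # 100%
  expect_length(select_desert_birds(list(mk(1:10)), desert), 0)    # 80%
  desert9 <- matrix(TRUE, 2, 5); desert9[1] <- FALSE
  expect_length(select_desert_birds(list(mk(1:10)), desert9), 1)   # 90.0%
  # monotone under mask growth
  bigger <- desert; bigger[1] <- TRUE
  kept <- select_desert_birds(list(mk(1:10), mk(3:10)), desert)
  kept2 <- select_desert_birds(list(mk(1:10), mk(3:10)), bigger)
  expect_gte(length(kept2), length(kept))
})

test_that("rarity-weighted richness sums to the species count", {
  land <- toy_landscape(4, 5)
  mk <- function(id, cells) structure(list(id = id, cells = cells,
    area_cells = length(cells), area_km2 = 1, mass_g = 30), class = "aoh")
  one <- rarity_weighted_richness(list(mk("a", 1:10)), land)
  expect_equal(one[1:10], rep(0.1, 10))
  expect_equal(sum(one), 1)
  set.seed(8)
  aohs <- lapply(1:12, function(i)
    mk(paste0("s", i), sample.int(20, sample(1:20, 1))))
  rwr <- rarity_weighted_richness(aohs, land)
  expect_equal(sum(rwr), 12, tolerance = 1e-9)
  # halving an AOH doubles its per-cell contribution
  a <- rarity_weighted_richness(list(mk("a", 1:10)), land)
  b <- rarity_weighted_richness(list(mk("a", 1:5)), land)
  expect_equal(b[1], 2 * a[1])
})

test_that("mass tertiles split species into small/medium/large", {
  sc <- size_classes(1:9)
  expect_identical(as.character(sc$class),
                   rep(c("small", "medium", "large"), each = 3))
  expect_identical(sc$model_masses, c(13, 39, 185))
  expect_warning(size_classes(rep(10, 5)), "degenerate")
  expect_error(size_classes(c(1, 2)), "at least 3")
})

test_that("community weighting averages class maps by species counts", {
  maps <- list(small = matrix(0.2, 2, 2), medium = matrix(0.8, 2, 2),
               large = matrix(0.5, 2, 2))
  all_medium <- list(small = matrix(0L, 2, 2), medium = matrix(3L, 2, 2),
                     large = matrix(0L, 2, 2))
  expect_equal(community_weighted_overlap(maps, all_medium), maps$medium)
  counts <- list(small = matrix(1L, 2, 2), medium = matrix(1L, 2, 2),
                 large = matrix(0L, 2, 2))
  expect_equal(community_weighted_overlap(maps, counts),
               matrix(0.5, 2, 2))
  none <- list(small = matrix(0L, 2, 2), medium = matrix(0L, 2, 2),
               large = matrix(0L, 2, 2))
  expect_true(all(is.na(community_weighted_overlap(maps, none))))
  # bounded by the per-class extremes
  set.seed(9)
  rmaps <- lapply(maps, function(m) matrix(runif(4), 2, 2))
  rcounts <- lapply(maps, function(m) matrix(sample(0:5, 4, TRUE), 2, 2))
  cw <- community_weighted_overlap(rmaps, rcounts)
  lo <- pmin(rmaps[[1]], rmaps[[2]], rmaps[[3]])
  hi <- pmax(rmaps[[1]], rmaps[[2]], rmaps[[3]])
  ok <- !is.na(cw)
  expect_true(all(cw[ok] >= lo[ok] - 1e-12 & cw[ok] <= hi[ok] + 1e-12))
})
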