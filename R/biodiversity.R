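# Desert delineation, Area-of-Habitat refinement, desert-bird selection,
# rarity-weighted richness and body-mass community weighting.

#' Warm-desert mask
#'
#' A pixel is desert iff its habitat code is a desert type and annual
#' precipitation is below 500 mm.
#'
#' @param landscape A `landscape` (supplies habitat raster + desert codes).
#' @param annual_precip Matrix of annual precipitation (mm), same shape.
#' @return Logical matrix.
#' @export
build_desert_mask <- function(landscape, annual_precip) {
  if (!all(dim(annual_precip) == dim(landscape$habitat)))
    stop("rasters are not aligned")
  matrix(landscape$habitat %in% landscape$desert_codes, landscape$rows,
         landscape$cols) & annual_precip < 500
}

#' Refine a species range to its Area of Habitat
#'
#' AOH = range cells with a suitable habitat code and elevation within the
#' species' limits. Species whose AOH is empty are dropped (`NULL` returned).
#'
#' @param species A `species_record`.
#' @param landscape A `landscape`.
#' @return List of class `aoh` (`id`, `cells`, `area_cells`, `area_km2`,
#'   `mass_g`) or `NULL` if the refined range is empty.
#' @export
refine_aoh <- function(species, landscape) {
  cells <- species$cells
  if (any(cells < 1 | cells > length(landscape$habitat)))
    stop("species range outside the landscape extent")
  ok <- landscape$habitat[cells] %in% species$habitat &
    landscape$elev[cells] >= species$elev[1] &
    landscape$elev[cells] <= species$elev[2]
  cells <- cells[ok]
  if (!length(cells)) return(NULL)
  structure(list(id = species$id, cells = cells, area_cells = length(cells),
                 area_km2 = length(cells) * landscape$cell_km^2,
                 mass_g = species$mass_g),
            class = "aoh")
}

#' Refine all species, with a retention log
#'
#' @param species_list List of `species_record`s.
#' @param landscape A `landscape`.
#' @return List with `aohs` (retained) and `log` (data.frame: id, range and
#'   AOH cell counts, retained flag).
#' @export
refine_aoh_all <- function(species_list, landscape) {
  aohs <- lapply(species_list, refine_aoh, landscape = landscape)
  log <- data.frame(
    id = vapply(species_list, `[[`, character(1), "id"),
    range_cells = vapply(species_list, function(s) length(s$cells), integer(1)),
    aoh_cells = vapply(aohs, function(a) if (is.null(a)) 0L else a$area_cells,
                       integer(1)))
  log$retained <- log$aoh_cells > 0
  list(aohs = aohs[!vapply(aohs, is.null, logical(1))], log = log)
}

#' Select desert birds
#'
#' Retains species with at least `threshold` (default 90%) of their AOH
#' inside the warm-desert mask.
#'
#' @param aohs List of `aoh` objects.
#' @param desert Logical desert mask.
#' @param threshold Minimum desert fraction (default 0.9, inclusive).
#' @return The retained subset of `aohs`.
#' @export
select_desert_birds <- function(aohs, desert, threshold = 0.9) {
  keep <- vapply(aohs, function(a) mean(desert[a$cells]) >= threshold,
                 logical(1))
  aohs[keep]
}

#' Rarity-weighted richness
#'
#' RWR(pixel) = sum over species present of 1/AOH area, with area measured
#' in equal-area cells; summed over the map it equals the species count.
#'
#' @param aohs List of `aoh` objects.
#' @param landscape A `landscape` (supplies the grid shape).
#' @return Matrix of RWR values (0 where no species occurs).
#' @export
rarity_weighted_richness <- function(aohs, landscape) {
  rwr <- matrix(0, landscape$rows, landscape$cols)
  for (a in aohs) {
    stopifnot(a$area_cells > 0)
    rwr[a$cells] <- rwr[a$cells] + 1 / a$area_cells
  }
  rwr
}

#' Body-mass size classes by tertiles
#'
#' Splits species masses into small/medium/large at the 33rd and 66th
#' percentiles of the mass distribution.
#'
#' @param masses Numeric vector of body masses (g), length >= 3.
#' @param model_masses Representative masses simulated for the three classes
#'   (defaults 13, 39, 185 g).
#' @return List with `breaks` (two percentile cut points), `class` (factor
#'   small/medium/large per species) and `model_masses`.
#' @export
size_classes <- function(masses, model_masses = c(13, 39, 185)) {
  if (length(masses) < 3) stop("need at least 3 species")
  breaks <- stats::quantile(masses, c(1, 2) / 3, names = FALSE)
  if (breaks[1] == breaks[2]) {
    warning("degenerate mass distribution: tertile breaks coincide")
    cls <- factor(rep("medium", length(masses)),
                  levels = c("small", "medium", "large"))
  } else {
    cls <- cut(masses, c(-Inf, breaks, Inf),
               labels = c("small", "medium", "large"))
  }
  list(breaks = breaks, class = cls, model_masses = model_masses)
}

#' Per-pixel species counts by size class
#'
#' @param aohs List of `aoh` objects.
#' @param classes Factor from [size_classes()] aligned with `aohs`.
#' @param landscape A `landscape`.
#' @return Named list of three count matrices (small, medium, large).
#' @export
size_class_counts <- function(aohs, classes, landscape) {
  stopifnot(length(aohs) == length(classes))
  counts <- lapply(levels(classes), function(lv) {
    m <- matrix(0L, landscape$rows, landscape$cols)
    for (a in aohs[classes == lv]) m[a$cells] <- m[a$cells] + 1L
    m
  })
  names(counts) <- levels(classes)
  counts
}

#' Community-weighted mean of per-class maps
#'
#' Per pixel, the mean of the three size-class maps weighted by the number
#' of species in each class; pixels with no species are `NA`.
#'
#' @param class_maps Named list of 3 matrices (values per size class).
#' @param class_counts Named list of 3 count matrices (same names/shapes).
#' @return Matrix of weighted means.
#' @export
community_weighted_overlap <- function(class_maps, class_counts) {
  nm <- names(class_maps)
  stopifnot(setequal(nm, names(class_counts)))
  dims <- dim(class_maps[[1]])
  num <- den <- matrix(0, dims[1], dims[2])
  for (k in nm) {
    stopifnot(all(dim(class_maps[[k]]) == dims),
              all(dim(class_counts[[k]]) == dims))
    w <- class_counts[[k]]
    v <- class_maps[[k]]
    contrib <- w * v
    contrib[w == 0] <- 0 # NA map values are irrelevant where count is 0
    num <- num + contrib
    den <- den + w
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
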