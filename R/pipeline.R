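# Orchestration: synth -> microclimate -> endotherm -> metrics ->
# biodiversity -> refugia, with seeded determinism and text outputs.

#' Configuration for a full pipeline run
#'
#' @param scenario Global-mean warming scenario (+2 or +4 C).
#' @param behavior `"shade"` (shade-shifting between 0% and 90% shade) or
#'   `"open"` (always in the open).
#' @param shade_fraction Shade level of the shaded habitat (default 0.9).
#' @param refugia_rule `"or"` or `"and"` over the two impact metrics.
#' @param threshold Fixed refugia percentile threshold (default 75).
#' @param target Floating refugia area target (default 0.05).
#' @param bird_masses Masses (g) of the three model birds.
#' @param n_years Years per period for the toy run (default 10).
#' @param rows,cols,n_species,pa_fraction,n_realms Passed to
#'   [synth_config()].
#' @param tol Heat-balance solver tolerance (W).
#' @param seed Integer seed controlling every random draw.
#' @param out_dir Output directory (`NULL` for no file output).
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = 2, behavior = c("shade", "open"),
                       shade_fraction = 0.9, refugia_rule = c("or", "and"),
                       threshold = 75, target = 0.05,
                       bird_masses = c(13, 39, 185), n_years = 10,
                       rows = 40, cols = 25, n_species = 150,
                       pa_fraction = 0.1, n_realms = 6, tol = 1e-5,
                       seed = 1, out_dir = NULL) {
  if (!scenario %in% c(2, 4)) stop("'scenario' must be 2 or 4")
  cfg <- list(scenario = scenario, behavior = match.arg(behavior),
              shade_fraction = shade_fraction,
              refugia_rule = match.arg(refugia_rule), threshold = threshold,
              target = target, bird_masses = bird_masses, n_years = n_years,
              rows = rows, cols = cols, n_species = n_species,
              pa_fraction = pa_fraction, n_realms = n_realms, tol = tol,
              seed = as.integer(seed), out_dir = out_dir)
  cfg$synth <- synth_config(rows = rows, cols = cols, n_years = n_years,
                            delta = scenario, n_species = n_species,
                            pa_fraction = pa_fraction, n_realms = n_realms,
                            seed = cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

# hottest-month site record for one cell and year
.site_record <- function(clim, cell, year, month) {
  list(latitude = clim$lat[cell], longitude = clim$lon[cell], year = year,
       month = month, tmax = clim$tmax[cell, year, month],
       tmin = clim$tmin[cell, year, month],
       vapor_pressure = clim$vp[cell, year, month],
       shortwave = clim$srad[cell, year, month],
       wind = clim$wind[cell, year, month])
}

#' Hottest-month physiology for a set of pixels
#'
#' For every pixel and year, builds the hourly microclimate of the
#' representative day of the pixel's hottest month (July north of and at
#' the equator, January south of it) and solves the water balance of each
#' model bird under the configured behaviour.
#'
#' @param climate A `monthly_climate` (one period).
#' @param pixels Integer cell indices to simulate.
#' @param birds List of `bird_model`s.
#' @param behavior `"shade"` or `"open"`.
#' @param shade_fraction Shade level of the shaded habitat.
#' @param tol Solver tolerance (W).
#' @return List of class `physio_sample`: arrays `tewl`, `adr`
#'   `[pixel, year, bird]`, `tair` `[pixel, year]` (daily-mean air
#'   temperature of the representative day), `flagged` (count of unmet-load
#'   hours), and `pixels`.
#' @export
run_physiology <- function(climate, pixels, birds,
                           behavior = c("shade", "open"),
                           shade_fraction = 0.9, tol = 1e-5) {
  behavior <- match.arg(behavior)
  np <- length(pixels)
  ny <- dim(climate$tmax)[2]
  nb <- length(birds)
  tewl_a <- adr_a <- array(NA_real_, c(np, ny, nb))
  tair_a <- matrix(NA_real_, np, ny)
  flagged <- 0L
  for (i in seq_len(np)) {
    cell <- pixels[i]
    month <- hottest_month(climate$lat[cell])
    for (y in seq_len(ny)) {
      site <- .site_record(climate, cell, y, month)
      open <- build_microclimate(site, 0)
      shade <- if (behavior == "shade")
        build_microclimate(site, shade_fraction) else NULL
      tair_a[i, y] <- mean(open$tair)
      for (bi in seq_len(nb)) {
        day <- hourly_water_loss(open, shade, birds[[bi]], tol = tol)
        tewl_a[i, y, bi] <- tewl(day)
        adr_a[i, y, bi] <- adr(day)
        flagged <- flagged + sum(day$flag != 0L)
      }
    }
  }
  structure(list(tewl = tewl_a, adr = adr_a, tair = tair_a,
                 flagged = flagged, pixels = pixels),
            class = "physio_sample")
}

# long-format per-pixel maps back onto the grid
.to_map <- function(values, pixels, rows, cols) {
  m <- matrix(NA_real_, rows, cols)
  m[pixels] <- values
  m
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic inputs, simulates hottest-month physiology for
#' the three model birds over both periods on all desert pixels, computes
#' impact surfaces (KDE overlap and mean change of TEWL, ADR, Tair),
#' community-weights them by size-class species counts, maps rarity-weighted
#' richness of desert birds, identifies fixed- and floating-threshold
#' refugia (physiology- and air-temperature-based), overlays protected
#' areas, and computes the comparison statistics. With `out_dir` set, writes
#' deterministic CSV tables and a manifest JSON with file checksums.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with all intermediate and final objects
#'   (landscape, climate, aohs, impact tables, maps, refugia results,
#'   statistics, manifest).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  land <- generate_landscape(config$synth)
  clim <- generate_climate(config$synth, land)
  species <- generate_species(config$synth, land)

  annual_prec <- matrix(rowSums(clim$current$prec[, 1, ]), land$rows)
  desert <- build_desert_mask(land, annual_prec)
  ref <- refine_aoh_all(species, land)
  desert_birds <- select_desert_birds(ref$aohs, desert)
  if (length(desert_birds) < 3)
    stop("stage biodiversity: fewer than 3 desert birds generated")
  masses <- vapply(desert_birds, `[[`, numeric(1), "mass_g")
  sc <- size_classes(masses, model_masses = config$bird_masses)
  counts <- size_class_counts(desert_birds, sc$class, land)
  rwr <- rarity_weighted_richness(desert_birds, land)

  birds <- lapply(config$bird_masses, make_model_bird)
  pixels <- which(desert)
  phys_cur <- run_physiology(clim$current, pixels, birds,
                             behavior = config$behavior,
                             shade_fraction = config$shade_fraction,
                             tol = config$tol)
  phys_fut <- run_physiology(clim$future, pixels, birds,
                             behavior = config$behavior,
                             shade_fraction = config$shade_fraction,
                             tol = config$tol)

  # per size class impact surfaces + the bird-independent Tair surface
  class_names <- levels(sc$class)
  imp_by_class <- lapply(seq_along(birds), function(bi) {
    impact_surface(
      list(tewl = phys_cur$tewl[, , bi], adr = phys_cur$adr[, , bi]),
      list(tewl = phys_fut$tewl[, , bi], adr = phys_fut$adr[, , bi]))
  })
  names(imp_by_class) <- class_names
  imp_tair <- impact_surface(list(tair = phys_cur$tair),
                             list(tair = phys_fut$tair))

  map_of <- function(col, bi)
    .to_map(imp_by_class[[bi]][[col]], pixels, land$rows, land$cols)
  cw <- function(col) community_weighted_overlap(
    setNames(lapply(class_names, function(k) map_of(col, k)), class_names),
    counts)
  tewl_ov <- cw("tewl_overlap"); adr_ov <- cw("adr_overlap")
  tewl_de <- cw("tewl_delta");   adr_de <- cw("adr_delta")
  tair_ov <- .to_map(imp_tair$tair_overlap, pixels, land$rows, land$cols)
  tair_de <- .to_map(imp_tair$tair_delta, pixels, land$rows, land$cols)

  biv <- bivariate_classes(tewl_ov, rwr, land$realm, mask = desert)
  fixed <- refugia_fixed(tewl_ov, adr_ov, rwr, land$realm, mask = desert,
                         threshold = config$threshold,
                         rule = config$refugia_rule)
  floating <- refugia_floating(tewl_ov, adr_ov, rwr, land$realm,
                               mask = desert, target = config$target,
                               rule = config$refugia_rule)
  fixed_tair <- refugia_fixed(tair_ov, tair_ov, rwr, land$realm,
                              mask = desert, threshold = config$threshold,
                              rule = config$refugia_rule)
  mismatch <- protection_mismatch(fixed, fixed_tair)
  pa_fixed <- pa_coverage(fixed, land$pa, land$realm)
  pa_floating <- pa_coverage(floating, land$pa, land$realm)

  groups <- split(tewl_ov[desert & is.finite(tewl_ov)],
                  land$realm[desert & is.finite(tewl_ov)])
  stats_tbl <- data.frame(
    statistic = c("kw_H", "kw_p", "kw_epsilon_sq",
                  "pearson_tewl_adr", "pearson_tewl_tair",
                  "jaccard_tewl_adr", "jaccard_tewl_tair",
                  "under_protection_pct", "over_protection_pct"),
    value = c(unlist(kruskal_wallis_epsilon(groups)[c("H", "p", "epsilon_sq")]),
              pearson_r(tewl_ov, adr_ov), pearson_r(tewl_ov, tair_ov),
              weighted_jaccard(as.vector(tewl_ov), as.vector(adr_ov)),
              weighted_jaccard(as.vector(tewl_ov), as.vector(tair_ov)),
              mismatch["under"], mismatch["over"]))

  result <- list(config = config, landscape = land, climate = clim,
                 desert = desert, retention_log = ref$log,
                 desert_birds = desert_birds, size_classes = sc,
                 class_counts = counts, rwr = rwr,
                 physiology = list(current = phys_cur, future = phys_fut),
                 impact = list(by_class = imp_by_class, tair = imp_tair,
                               tewl_overlap = tewl_ov, adr_overlap = adr_ov,
                               tair_overlap = tair_ov, tewl_delta = tewl_de,
                               adr_delta = adr_de, tair_delta = tair_de),
                 bivariate = biv,
                 refugia = list(fixed = fixed, floating = floating,
                                fixed_tair = fixed_tair,
                                pa_fixed = pa_fixed,
                                pa_floating = pa_floating,
                                mismatch = mismatch),
                 stats = stats_tbl)
  if (!is.null(config$out_dir)) result$manifest <- .write_run(result)
  invisible(result)
}

# deterministic CSV/JSON outputs + checksum manifest
.write_run <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(res$config$out_dir, name)
  w <- function(df, name) {
    write.csv(df, out(name), row.names = FALSE)
    name
  }
  land <- res$landscape
  pix <- which(res$desert)
  files <- c(
    w(data.frame(id = vapply(res$desert_birds, `[[`, character(1), "id"),
                 mass_g = vapply(res$desert_birds, `[[`, numeric(1), "mass_g"),
                 aoh_cells = vapply(res$desert_birds, `[[`, numeric(1),
                                    "area_cells"),
                 size_class = as.character(res$size_classes$class)),
      "desert_birds.csv"),
    w(res$retention_log, "retention_log.csv"),
    w(data.frame(pixel = pix, realm = land$realm[pix],
                 rwr = res$rwr[pix],
                 tewl_overlap = res$impact$tewl_overlap[pix],
                 adr_overlap = res$impact$adr_overlap[pix],
                 tair_overlap = res$impact$tair_overlap[pix],
                 tewl_delta = res$impact$tewl_delta[pix],
                 adr_delta = res$impact$adr_delta[pix],
                 tair_delta = res$impact$tair_delta[pix],
                 bivariate = res$bivariate$class[pix],
                 refugium_fixed = res$refugia$fixed$mask[pix],
                 refugium_floating = res$refugia$floating$mask[pix],
                 protected = land$pa[pix]),
      "impact_surface.csv"),
    w(res$bivariate$area_table, "bivariate_area.csv"),
    w(data.frame(realm = names(res$refugia$fixed$area_fraction),
                 fixed_threshold = res$refugia$fixed$threshold,
                 fixed_fraction = res$refugia$fixed$area_fraction,
                 floating_threshold = res$refugia$floating$threshold,
                 floating_fraction = res$refugia$floating$area_fraction,
                 pa_fixed_pct = res$refugia$pa_fixed,
                 pa_floating_pct = res$refugia$pa_floating),
      "refugia_realms.csv"),
    w(res$stats, "stats.csv"))
  cfg <- res$config
  cfg$out_dir <- NULL
  manifest <- list(
    config = cfg[!vapply(cfg, is.list, logical(1))],
    n_desert_birds = length(res$desert_birds),
    n_desert_pixels = length(pix),
    flagged_hours = res$physiology$current$flagged +
      res$physiology$future$flagged,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(res$config$out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(res$config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Apply a named parameter perturbation to a bird model
#'
#' Understood names: any scalar `bird_model` field (e.g. `alpha_solar`,
#' `wet_baseline`, `bmr_c1`, `tb_norm`, `k_plume`), plus `plumage_depth_mm`
#' (sets both depths) and `mass_g` (rescales size traits via
#' [make_model_bird()]).
#'
#' @param bird A `bird_model`.
#' @param param Parameter name.
#' @param value New value.
#' @return Perturbed `bird_model`.
#' @export
perturb_bird <- function(bird, param, value) {
  if (!is.finite(value)) stop("perturbation value must be finite")
  if (param == "plumage_depth_mm") {
    if (value <= 0) stop("plumage depth must be positive")
    bird$depth_dorsal_mm <- bird$depth_ventral_mm <- value
  } else if (param == "mass_g") {
    bird <- make_model_bird(value, bird)
  } else if (param %in% names(bird) && length(bird[[param]]) == 1) {
    if (param %in% c("wet_baseline", "alpha_solar") &&
        (value < 0 || value > 1))
      stop("'", param, "' must stay in [0, 1]")
    if (param %in% c("bmr_c1", "k_plume", "density") && value <= 0)
      stop("'", param, "' must be positive")
    bird[[param]] <- value
    if (param %in% c("bmr_c1", "bmr_c2"))
      bird$qbasal <- bird$bmr_c1 * bird$mass_g^bird$bmr_c2
  } else {
    stop("unknown or non-scalar parameter: ", param)
  }
  bird
}

#' Parameter-perturbation sensitivity of identified safe sites
#'
#' Re-runs the hottest-month physiology of the reference bird at a sample
#' of desert sites under perturbed parameter values and reports how
#' consistently the top-25% safe sites (largest TEWL overlap, largest ADR
#' overlap) are re-identified.
#'
#' @param config A `run_config`.
#' @param perturbations List of perturbation specs: each a list with
#'   `param`, `low`, `high` (low != high). Combinations minimizing and
#'   maximizing water loss are added automatically from the listed extremes
#'   when `combos = TRUE`.
#' @param n_sites Number of desert sites sampled (default 60).
#' @param fraction Safe-site fraction (default 0.25).
#' @param combos Add min-water / max-water parameter combinations.
#' @return `data.frame`: perturbation label and safe-site consistency (%)
#'   for TEWL and ADR overlap.
#' @export
sensitivity_suite <- function(config, perturbations, n_sites = 60,
                              fraction = 0.25, combos = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!length(perturbations))
    return(data.frame(label = character(0), tewl_consistency = numeric(0),
                      adr_consistency = numeric(0)))
  for (p in perturbations)
    if (identical(p$low, p$high)) stop("perturbation with low == high")
  land <- generate_landscape(config$synth)
  clim <- generate_climate(config$synth, land)
  annual_prec <- matrix(rowSums(clim$current$prec[, 1, ]), land$rows)
  desert_cells <- which(build_desert_mask(land, annual_prec))
  set.seed(config$seed + 101L)
  sites <- sort(sample(desert_cells, min(n_sites, length(desert_cells))))
  base_bird <- make_model_bird(config$bird_masses[2])

  site_overlaps <- function(bird) {
    cur <- run_physiology(clim$current, sites, list(bird),
                          behavior = config$behavior,
                          shade_fraction = config$shade_fraction,
                          tol = config$tol)
    fut <- run_physiology(clim$future, sites, list(bird),
                          behavior = config$behavior,
                          shade_fraction = config$shade_fraction,
                          tol = config$tol)
    list(
      tewl = vapply(seq_along(sites), function(i)
        density_overlap(cur$tewl[i, , 1], fut$tewl[i, , 1]), numeric(1)),
      adr = vapply(seq_along(sites), function(i)
        density_overlap(cur$adr[i, , 1], fut$adr[i, , 1]), numeric(1)))
  }
  base <- site_overlaps(base_bird)

  runs <- list()
  for (p in perturbations)
    for (side in c("low", "high"))
      runs[[paste0(p$param, "_", side)]] <-
        list(label = paste0(p$param, "_", side),
             birds = list(perturb_bird(base_bird, p$param, p[[side]])))
  if (combos && length(perturbations) > 1) {
    mkcombo <- function(pick) {
      b <- base_bird
      # pick, per parameter, the extreme that moves hot-day water loss in
      # the requested direction (probed at a 42 C reference condition)
      probe <- function(bb) respirometry_curve(bb, 42)$water_gph
      for (p in perturbations) {
        hi_up <- probe(perturb_bird(base_bird, p$param, p$high)) >
          probe(perturb_bird(base_bird, p$param, p$low))
        b <- perturb_bird(b, p$param,
                          if (xor(hi_up, pick == "max")) p$low else p$high)
      }
      b
    }
    runs[["combo_min_water"]] <- list(label = "combo_min_water",
                                      birds = list(mkcombo("min")))
    runs[["combo_max_water"]] <- list(label = "combo_max_water",
                                      birds = list(mkcombo("max")))
  }

  rows <- lapply(runs, function(r) {
    ov <- site_overlaps(r$birds[[1]])
    data.frame(label = r$label,
               tewl_consistency = safe_site_consistency(base$tewl, ov$tewl,
                                                        fraction),
               adr_consistency = safe_site_consistency(base$adr, ov$adr,
                                                       fraction))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
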