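# Seeded synthetic inputs: landscape, monthly climate grids, species.
#
# Rasters are plain matrices (rows = latitude bands, north at row 1, cols =
# longitude); cells are equal-area squares of cell_km on a side, so cell
# counts double as areas.

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the study conditions of the analysis: a 40 x 25 grid of
#' 50-km equal-area cells, 30-year periods, a +2 C global-mean warming
#' scenario amplified with distance from the coast, shared annual temperature
#' anomalies of sd 0.8 C, ~150 species with log-normal masses (median 39 g)
#' and heavy-tailed range sizes, six longitudinal desert realms, and ~10%
#' protected-area coverage.
#'
#' @param rows,cols Grid shape.
#' @param cell_km Cell size (km).
#' @param n_years Years per period (>= 2).
#' @param lat_range Latitude span c(min, max) in degrees.
#' @param delta Global-mean warming (C, >= 0).
#' @param warm_amp_a Continentality amplification slope of the warming
#'   pattern: pattern is proportional to `1 + warm_amp_a * normalized coast
#'   distance`, renormalized to mean `warm_amp_global`.
#' @param warm_amp_global Area-mean amplification factor (default 1).
#' @param interannual_sd Sd (C) of the shared annual anomaly added to
#'   tmax/tmin.
#' @param n_species Number of species to generate.
#' @param mass_meanlog,mass_sdlog Log-normal body-mass parameters (g).
#' @param range_meanlog,range_sdlog Log-normal range-size parameters (cells).
#' @param pa_fraction Target protected-area fraction in `[0, 1]`.
#' @param n_realms Number of longitudinal realm bands.
#' @param seed Integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(rows = 40, cols = 25, cell_km = 50, n_years = 30,
                         lat_range = c(-9, 9), delta = 2, warm_amp_a = 0.3,
                         warm_amp_global = 1, interannual_sd = 0.8,
                         n_species = 150, mass_meanlog = log(39),
                         mass_sdlog = 0.8, range_meanlog = log(60),
                         range_sdlog = 1.3, pa_fraction = 0.1, n_realms = 6,
                         seed = 1) {
  cfg <- list(rows = rows, cols = cols, cell_km = cell_km, n_years = n_years,
              lat_range = lat_range, delta = delta, warm_amp_a = warm_amp_a,
              warm_amp_global = warm_amp_global,
              interannual_sd = interannual_sd, n_species = n_species,
              mass_meanlog = mass_meanlog, mass_sdlog = mass_sdlog,
              range_meanlog = range_meanlog, range_sdlog = range_sdlog,
              pa_fraction = pa_fraction, n_realms = n_realms,
              seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "lat_range")])
  if (!all(is.finite(c(num, lat_range))))
    stop("all configuration parameters must be finite")
  if (rows < 1 || cols < 1 || n_realms < 1 || cell_km <= 0)
    stop("all counts must be positive")
  if (delta < 0) stop("'delta' must be >= 0")
  if (n_years < 2) stop("'n_years' must be >= 2")
  if (interannual_sd < 0) stop("'interannual_sd' must be >= 0")
  if (pa_fraction < 0 || pa_fraction > 1)
    stop("'pa_fraction' must be in [0, 1]")
  if (diff(lat_range) <= 0) stop("'lat_range' must be increasing")
  class(cfg) <- "synth_config"
  cfg
}

# smooth seeded random surface in [0, 1] from a few 2-D cosine modes
.smooth_field <- function(rows, cols, n_modes = 4) {
  r <- row(matrix(0, rows, cols)) / rows
  c_ <- col(matrix(0, rows, cols)) / cols
  f <- matrix(0, rows, cols)
  for (k in seq_len(n_modes)) {
    f <- f + runif(1, 0.5, 1) *
      cos(2 * pi * (runif(1, 0.5, 2) * r + runif(1, 0.5, 2) * c_ + runif(1)))
  }
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

#' Generate the synthetic landscape
#'
#' Habitat codes (1, 2 desert types; 10, 11 non-desert), an elevation raster,
#' contiguous longitudinal realm bands, a patchy protected-area mask near the
#' configured fraction, coast distance (coast at the west edge, with a
#' seeded meander) and the aridity surface the climate generator reuses.
#'
#' @param config A `synth_config`.
#' @return List of class `landscape` with matrices `habitat`, `elev`,
#'   `realm`, `pa`, `coast_km`, `aridity`, vectors `lat` (per row), `lon`
#'   (per column), and `cell_km`, `desert_codes`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 11L)
  rows <- config$rows; cols <- config$cols
  lat <- seq(config$lat_range[2], config$lat_range[1], length.out = rows)
  lon_step <- config$cell_km / 111.32
  lon <- seq(0, by = lon_step, length.out = cols)
  meander <- pmax(0, 1.2 * sin(seq_len(rows) / 4) + rnorm(rows, 0, 0.3))
  coast_km <- (matrix(rep(seq_len(cols), each = rows), rows, cols) - 0.5 +
                 meander) * config$cell_km
  dist_norm <- coast_km / max(coast_km)
  elev <- 200 + 1600 * .smooth_field(rows, cols)
  aridity <- pmin(1, pmax(0, 0.55 * dist_norm + 0.45 * .smooth_field(rows, cols)))
  desert <- aridity > 0.45
  if (!any(desert)) desert[aridity >= quantile(aridity, 0.75)] <- TRUE
  if (all(desert)) desert[aridity <= quantile(aridity, 0.1)] <- FALSE
  habitat <- matrix(0L, rows, cols)
  habitat[desert] <- sample(c(1L, 2L), sum(desert), replace = TRUE)
  habitat[!desert] <- sample(c(10L, 11L), sum(!desert), replace = TRUE)
  realm <- matrix(rep(ceiling(seq_len(cols) * config$n_realms / cols),
                      each = rows), rows, cols)
  pa <- matrix(FALSE, rows, cols)
  target <- round(config$pa_fraction * rows * cols)
  guard <- 0
  while (sum(pa) < target && guard < 10000) {
    guard <- guard + 1
    cr <- sample.int(rows, 1); cc <- sample.int(cols, 1)
    rad <- sample(0:2, 1)
    pa[max(1, cr - rad):min(rows, cr + rad),
       max(1, cc - rad):min(cols, cc + rad)] <- TRUE
  }
  out <- list(habitat = habitat, elev = elev, realm = realm, pa = pa,
              coast_km = coast_km, aridity = aridity, lat = lat, lon = lon,
              cell_km = config$cell_km, desert_codes = c(1L, 2L),
              rows = rows, cols = cols)
  class(out) <- "landscape"
  out
}

# monthly climatology arrays [cell, month] for one landscape
.climatology <- function(config, land) {
  rows <- config$rows; cols <- config$cols
  ncell <- rows * cols
  latm <- matrix(rep(land$lat, cols), rows, cols)
  dn <- land$coast_km / max(land$coast_km)
  alat <- abs(latm) / max(abs(land$lat), 1)
  tmean_ann <- 26 + 6 * dn + 2 * (1 - alat)
  amp <- 3 + 6 * dn + 4 * alat
  drange <- 8 + 8 * dn
  peak <- ifelse(latm >= 0, 7, 1)
  m <- 1:12
  tmax <- tmin <- vp <- srad <- wind <- prec <- matrix(0, ncell, 12)
  # clear-sky monthly means per row latitude
  csm <- sapply(m, function(mm) {
    doy <- as.integer(round(.month_mid[mm]))
    vapply(land$lat, function(la)
      mean(clear_sky_radiation(la, doy, 0:23)), numeric(1))
  }) # rows x 12
  wind_base <- matrix(rlnorm(ncell, log(2.5), 0.3), rows, cols)
  prec_ann <- 800 * (1 - land$aridity)^2 + matrix(runif(ncell, 0, 40), rows, cols)
  for (mm in m) {
    s <- amp * cos(2 * pi * (mm - peak) / 12)
    tmid <- tmean_ann + s
    tmax[, mm] <- as.vector(tmid + drange / 2)
    tmin[, mm] <- as.vector(tmid - drange / 2)
    rh_tmin <- 0.55 - 0.35 * land$aridity
    vp[, mm] <- as.vector(pmax(0.05, rh_tmin * esat_kpa(tmid - drange / 2)))
    cf <- pmin(0.92, 0.55 + 0.35 * land$aridity)
    srad[, mm] <- as.vector(cf * matrix(rep(csm[, mm], cols), rows, cols))
    wind[, mm] <- as.vector(pmax(0.2, wind_base))
    seasonal_w <- 1 + 0.3 * cos(2 * pi * (mm - peak) / 12)
    prec[, mm] <- as.vector(prec_ann / 12 * seasonal_w)
  }
  list(tmax = tmax, tmin = tmin, vp = vp, srad = srad, wind = wind,
       prec = prec, lat = as.vector(latm), lon = rep(land$lon, each = rows),
       dist_norm = as.vector(dn))
}

# expand [cell, month] climatology + per-cell yearly anomalies (vector of
# length ncell per year, or 0) to [cell, year, month]
.expand_years <- function(clim_cm, anom, ncell, n_years, warm = 0) {
  a <- array(0, dim = c(ncell, n_years, 12))
  for (y in seq_len(n_years)) {
    shift <- if (is.matrix(anom)) anom[, y] else anom[y]
    a[, y, ] <- clim_cm + shift + warm
  }
  a
}

#' Generate current and future monthly climate grids
#'
#' The future grid equals the current climatology plus a spatially varying
#' warming field `delta * (1 + a * coast distance) / mean(...) *
#' warm_amp_global` (area mean exactly `delta * warm_amp_global`), applied
#' to tmax and tmin. Interannual variability is an annual anomaly
#' (sd `interannual_sd`) shared by tmax and tmin and by all months of a
#' year, drawn independently per pixel, year and period. Vapour
#' pressure rises by 3% per degree of warming; radiation, wind and
#' precipitation keep their climatology.
#'
#' @param config A `synth_config`.
#' @param landscape Optional `landscape` (generated from `config` if absent).
#' @return List with elements `current` and `future`, each of class
#'   `monthly_climate`: arrays `tmax`, `tmin`, `vp`, `srad`, `wind`, `prec`
#'   with dim `[cell, year, month]`, plus `lat`, `lon` per cell and the
#'   warming field (`warming`, future only has it non-zero).
#' @export
generate_climate <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(landscape)) landscape <- generate_landscape(config)
  set.seed(config$seed + 23L)
  cl <- .climatology(config, landscape)
  ncell <- config$rows * config$cols
  ny <- config$n_years
  amp <- 1 + config$warm_amp_a * cl$dist_norm
  amp <- amp / mean(amp) * config$warm_amp_global
  warming <- config$delta * amp
  anom_cur <- matrix(rnorm(ncell * ny, 0, config$interannual_sd), ncell, ny)
  anom_fut <- matrix(rnorm(ncell * ny, 0, config$interannual_sd), ncell, ny)
  period <- function(anom, warm, vp_fac) {
    p <- list(
      tmax = .expand_years(cl$tmax, anom, ncell, ny, warm),
      tmin = .expand_years(cl$tmin, anom, ncell, ny, warm),
      vp   = .expand_years(cl$vp * vp_fac, numeric(ny), ncell, ny),
      srad = .expand_years(cl$srad, rep(0, ny), ncell, ny),
      wind = .expand_years(cl$wind, rep(0, ny), ncell, ny),
      prec = .expand_years(cl$prec, rep(0, ny), ncell, ny),
      lat = cl$lat, lon = cl$lon)
    class(p) <- "monthly_climate"
    p
  }
  cur <- period(anom_cur, 0, 1)
  cur$warming <- rep(0, ncell)
  fut <- period(anom_fut, warming, 1 + 0.03 * config$delta)
  fut$warming <- warming
  list(current = cur, future = fut)
}

# grow a contiguous range of about `size` cells from a seed cell
.grow_range <- function(seed_cell, size, rows, cols) {
  in_range <- logical(rows * cols)
  in_range[seed_cell] <- TRUE
  frontier <- seed_cell
  while (sum(in_range) < size && length(frontier) > 0) {
    cell <- frontier[[1]]
    frontier <- frontier[-1]
    r <- (cell - 1) %% rows + 1
    c_ <- (cell - 1) %/% rows + 1
    nb <- c(if (r > 1) cell - 1, if (r < rows) cell + 1,
            if (c_ > 1) cell - rows, if (c_ < cols) cell + rows)
    nb <- nb[!in_range[nb]]
    if (length(nb)) {
      nb <- nb[sample.int(length(nb))]
      take <- head(nb, size - sum(in_range))
      in_range[take] <- TRUE
      frontier <- c(frontier, take)
    }
  }
  which(in_range)
}

#' Generate synthetic species records
#'
#' Masses are log-normal; range sizes follow a heavy-tailed log-normal
#' (capped at the grid size); ranges are contiguous blobs grown from seeds
#' biased toward desert habitat; habitat preferences favour desert codes;
#' elevation limits are ordered.
#'
#' @param config A `synth_config`.
#' @param landscape A `landscape` for placement (generated if absent).
#' @return List of `species_record` lists: `id`, `cells` (pixel indices),
#'   `habitat` (suitable codes), `elev` (c(min, max), m), `mass_g`.
#' @export
generate_species <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_species < 1) stop("'n_species' must be >= 1")
  if (is.null(landscape)) landscape <- generate_landscape(config)
  set.seed(config$seed + 37L)
  rows <- config$rows; cols <- config$cols
  ncell <- rows * cols
  desert_cells <- which(landscape$habitat %in% landscape$desert_codes)
  lapply(seq_len(config$n_species), function(i) {
    mass <- rlnorm(1, config$mass_meanlog, config$mass_sdlog)
    size <- min(ncell, max(1, round(rlnorm(1, config$range_meanlog,
                                           config$range_sdlog))))
    seed_cell <- if (length(desert_cells) && runif(1) < 0.8)
      sample(desert_cells, 1) else sample.int(ncell, 1)
    cells <- .grow_range(seed_cell, size, rows, cols)
    habitat <- if (runif(1) < 0.85) landscape$desert_codes else
      sort(sample(c(landscape$desert_codes, 10L, 11L), sample(2:3, 1)))
    emin <- if (runif(1) < 0.7) 0 else runif(1, 0, 400)
    emax <- emin + runif(1, 800, 2400)
    structure(list(id = sprintf("sp%03d", i), cells = cells,
                   habitat = habitat, elev = c(emin, emax), mass_g = mass),
              class = "species_record")
  })
}
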