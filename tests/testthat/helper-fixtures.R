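# Small shared fixtures for the test suite.

tiny_config <- function(seed = 1, ...) {
  args <- modifyList(list(rows = 12, cols = 10, n_years = 4,
                          n_species = 30, n_realms = 3, seed = seed),
                     list(...))
  do.call(synth_config, args)
}

tiny_run_config <- function(seed = 1, ...) {
  args <- modifyList(list(rows = 12, cols = 10, n_years = 3,
                          n_species = 30, n_realms = 3, seed = seed),
                     list(...))
  do.call(run_config, args)
}

# a plain landscape with known structure for biodiversity/refugia tests
toy_landscape <- function(rows = 4, cols = 5, cell_km = 50) {
  structure(list(
    habitat = matrix(1L, rows, cols),
    elev = matrix(500, rows, cols),
    realm = matrix(1L, rows, cols),
    pa = matrix(FALSE, rows, cols),
    coast_km = matrix(cell_km, rows, cols),
    aridity = matrix(0.8, rows, cols),
    lat = seq(30, 20, length.out = rows),
    lon = seq(0, 2, length.out = cols),
    cell_km = cell_km, desert_codes = c(1L, 2L),
    rows = rows, cols = cols), class = "landscape")
}

toy_species <- function(id, cells, habitat = c(1L, 2L),
                        elev = c(0, 3000), mass = 39) {
  structure(list(id = id, cells = cells, habitat = habitat, elev = elev,
                 mass_g = mass), class = "species_record")
}

toy_site <- function(latitude = 25, tmax = 42, tmin = 26, vp = 1.2,
                     srad = 320, wind = 2, month = 7) {
  list(latitude = latitude, month = month, tmax = tmax, tmin = tmin,
       vapor_pressure = vp, shortwave = srad, wind = wind)
}
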