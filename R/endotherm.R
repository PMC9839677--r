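# Bird model construction and the thermoregulation solver interface.

#' Reference 39-g bird parameter set
#'
#' Morphological and physiological template modelled on a 39-g desert
#' passerine. All values are configurable; plumage depths and feather
#' lengths are the size-scaled traits, the thermoregulatory limits encode
#' the cascade: ptiloerection multiplier down to `ptilo_range[1]`, body
#' stretching over `shape_range`, flesh conductivity over `k_flesh_range`,
#' then core temperature up to `tb_max` (44 C) coupled with respiratory rate
#' up to `p_max` (7.5x resting), and finally skin wetness up to 1. Basal
#' metabolism follows a passerine allometry `bmr_c1 * M^bmr_c2` (W, M in g).
#'
#' @param mass_g Body mass in grams.
#' @return A list of class `bird_model`.
#' @export
bird_template <- function(mass_g = 39) {
  b <- list(
    mass_g = mass_g,
    density = 1000,             # kg/m^3
    depth_dorsal_mm = 6,
    depth_ventral_mm = 6,
    feather_len_dorsal_mm = 22,
    feather_len_ventral_mm = 18,
    k_plume = 0.028,            # W/m/K
    k_flesh_range = c(0.412, 2.8),
    tb_norm = 41,
    tb_max = 44,
    p_max = 7.5,
    shape_range = c(1.1, 3.0),  # prolate semi-axis ratio
    ptilo_range = c(0.5, 1),
    wet_baseline = 0.02,        # baseline skin wetness fraction
    alpha_solar = 0.85,
    emissivity = 0.95,
    bmr_c1 = 0.045,             # W g^-bmr_c2
    bmr_c2 = 0.684,
    tf_frac = 0.5,              # flesh shell thickness / semi-minor axis
    qgen_max_mult = 10,         # cold-side ceiling on Q_gen / basal
    perch_height_m = 1.5
  )
  b$qbasal <- b$bmr_c1 * b$mass_g^b$bmr_c2
  class(b) <- "bird_model"
  b
}

#' Scale the reference bird to another body mass
#'
#' Plumage depths and feather lengths are multiplied by
#' `(mass / reference mass)^(1/3)`; basal metabolism is re-evaluated from the
#' allometry; all other parameters are copied unchanged.
#'
#' @param mass Target body mass (g, > 0).
#' @param reference Template `bird_model` (default the 39-g reference).
#' @return A `bird_model` for the new mass.
#' @export
make_model_bird <- function(mass, reference = bird_template()) {
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass <= 0)
    stop("'mass' must be a single positive number")
  b <- reference
  k <- (mass / reference$mass_g)^(1 / 3)
  b$mass_g <- mass
  for (f in c("depth_dorsal_mm", "depth_ventral_mm",
              "feather_len_dorsal_mm", "feather_len_ventral_mm"))
    b[[f]] <- reference[[f]] * k
  b$qbasal <- b$bmr_c1 * mass^b$bmr_c2
  b
}

#' Body geometry at a given shape ratio
#'
#' The bird is a prolate ellipsoid (semi-axes a >= b = c, ratio a/b) of
#' volume mass/density; surface area is the exact prolate-spheroid closed
#' form and the characteristic dimension for convection is V^(1/3).
#'
#' @param bird A `bird_model`.
#' @param shape_ratio Semi-axis ratio a/b (>= 1).
#' @return List with `volume_m3`, `area_m2`, `char_dim_m`, `semi_minor_m`.
#' @export
body_geometry <- function(bird, shape_ratio) {
  stopifnot(shape_ratio >= 1)
  v <- bird$mass_g / 1000 / bird$density
  bs <- (3 * v / (4 * pi * shape_ratio))^(1 / 3)
  a <- shape_ratio * bs
  if (shape_ratio <= 1 + 1e-9) {
    area <- 4 * pi * bs^2
  } else {
    e <- sqrt(1 - bs^2 / a^2)
    area <- 2 * pi * bs^2 * (1 + a / (bs * e) * asin(e))
  }
  list(volume_m3 = v, area_m2 = area, char_dim_m = v^(1 / 3),
       semi_minor_m = bs)
}

# pack a bird_model into the parameter vector the C++ solver expects
.bird_vec <- function(bird) {
  depth_m <- mean(c(bird$depth_dorsal_mm, bird$depth_ventral_mm)) / 1000
  c(bird$mass_g, bird$density, depth_m, bird$k_plume,
    bird$k_flesh_range[1], bird$k_flesh_range[2], bird$tb_norm, bird$tb_max,
    bird$p_max, bird$shape_range[1], bird$shape_range[2],
    bird$ptilo_range[1], bird$wet_baseline, bird$alpha_solar, bird$qbasal,
    bird$tf_frac, bird$emissivity, bird$qgen_max_mult)
}

.env_vec <- function(env) {
  v <- c(env$tair, env$rh, env$solar, env$wind, env$tsky, env$tground)
  if (length(v) != 6 || !all(is.finite(v)))
    stop("environment record needs finite tair, rh, solar, wind, tsky, tground")
  v
}

#' Solve the thermoregulatory cascade for one hourly environment
#'
#' Finds the minimal-water-loss steady state at basal metabolic rate (hot
#' side) satisfying the heat balance, with the cascade controls engaged in
#' order: (1) reduce ptiloerection, (2) stretch the body, (3) raise flesh
#' conductivity, (4) raise core temperature (up to 44 C) and respiratory
#' rate (up to 7.5x) together as one normalized control, (5) raise skin
#' wetness. Every admissible state has at most one partially engaged stage;
#' stages below it are saturated or skipped, stages above it rest. A stage
#' is skipped when engaging it would not pay: typically when the air is
#' hotter than the body surface, so that sleeking, stretching or flushing
#' the skin would add heat instead of dissipating it. Below thermoneutrality
#' baseline skin wetness is shed first, then metabolic heat rises above
#' basal.
#'
#' @param env One hourly record: list or one-row data.frame with `tair`,
#'   `rh`, `solar`, `wind`, `tsky`, `tground`.
#' @param bird A `bird_model`.
#' @param tol Heat-balance tolerance in W (default 1e-5).
#' @return A list of class `thermal_state`: engaged `stage` (0-5), `flag`
#'   (0 ok, 1 unmet heat load, 2 unmet cold load), node temperatures `tb`,
#'   `ts`, `tsurf`, controls `ptilo`, `shape`, `kflesh`, `pmult`, `wet`,
#'   fluxes `qgen`, `qsol`, `qconv`, `qlw`, `qresp`, `qcut` (W), water loss
#'   `water_gph` (g/h), heat-balance `resid` (W), and `stage_status`
#'   (per stage: 0 skipped, 1 saturated, 2 partial, 3 at rest).
#' @export
solve_thermoregulation <- function(env, bird, tol = 1e-5) {
  s <- .solve_env_cpp(.env_vec(env), .bird_vec(bird), tol)
  out <- as.list(s)
  out$stage <- as.integer(out$stage)
  out$flag <- as.integer(out$flag)
  out$stage_status <- as.integer(attr(s, "stage_status"))
  class(out) <- "thermal_state"
  out
}

#' Heat-balance residual of a thermal state
#'
#' Recomputes every flux term at the state's recorded node temperatures and
#' controls: `residual = Q_gen + absorbed solar - (convection + net longwave
#' + evaporation)`; positive means net heat gain. At a solver-returned,
#' non-flagged state the magnitude is below the solver tolerance.
#'
#' @param state A `thermal_state` (or list with the same fields).
#' @param env The hourly environment record used.
#' @param bird The `bird_model` used.
#' @return Residual in W, with flux components as attribute `components`.
#' @export
heat_balance_residual <- function(state, env, bird) {
  temps <- c(state$tb, state$ts, state$tsurf, env$tair)
  if (any(!is.finite(temps)) || any(temps < -80) || any(temps > 80))
    stop("non-physical temperatures (outside [-80, 80] C)")
  g <- body_geometry(bird, state$shape)
  depth_m <- mean(c(bird$depth_dorsal_mm, bird$depth_ventral_mm)) / 1000
  sigma <- 5.670374419e-8; rv <- 461.5; lambda <- 2.406e6
  kair <- 0.0263; nuair <- 1.6e-5; rhoair <- 1.13; cpair <- 1006
  rho_v <- function(e_kpa, t) e_kpa * 1000 / (rv * (t + 273.15))
  re <- max(env$wind, 0.05) * g$char_dim_m / nuair
  hc <- max(2, 0.35 * re^0.6) * kair / g$char_dim_m
  hm <- hc / (rhoair * cpair)
  # silhouette area is posture-independent: half the rest-shape surface
  asil <- body_geometry(bird, bird$shape_range[1])$area_m2 / 2
  qsol <- bird$alpha_solar * asil * env$solar
  qconv <- hc * g$area_m2 * (state$tsurf - env$tair)
  tk <- state$tsurf + 273.15
  qlw <- bird$emissivity * sigma * g$area_m2 *
    (tk^4 - 0.5 * (env$tsky + 273.15)^4 - 0.5 * (env$tground + 273.15)^4)
  rva <- rho_v(env$rh / 100 * esat_kpa(env$tair), env$tair)
  vent <- state$qgen / 20.1 * 1e-6 / (0.2094 * 0.2) * state$pmult
  mresp <- vent * max(0, rho_v(esat_kpa(state$tb), state$tb) - rva)
  # cutaneous vapour conductance: plumage air layer + boundary layer in series
  gv <- 1 / (1 / hm + depth_m * state$ptilo / 2.5e-5)
  mcut <- gv * g$area_m2 * state$wet *
    max(0, rho_v(esat_kpa(state$ts), state$ts) - rva)
  qevap <- (mresp + mcut) * lambda
  res <- state$qgen + qsol - (qconv + qlw + qevap)
  attr(res, "components") <- c(qgen = state$qgen, qsol = qsol, qconv = qconv,
                               qlw = qlw, qresp = mresp * lambda,
                               qcut = mcut * lambda,
                               water_gph = (mresp + mcut) * 3.6e6)
  res
}

.env_matrix <- function(mc) {
  as.matrix(mc[, c("tair", "rh", "solar", "wind", "tsky", "tground")])
}

#' Hourly water loss with shade-shifting behaviour
#'
#' Solves the cascade for each hour in the open and (unless `open_env` only
#' is given) in the shade, and takes per hour the habitat minimizing water
#' loss.
#'
#' @param open_env `hourly_microclimate` for the open (0% shade).
#' @param shade_env `hourly_microclimate` for the shade, or `NULL` for
#'   open-only behaviour.
#' @param bird A `bird_model`.
#' @param tol Heat-balance tolerance (W).
#' @return A `data.frame` of class `hourly_water_loss` with columns `hour`,
#'   `water_gph`, `habitat` ("open"/"shade"), `tb`, `stage`, `flag`,
#'   `water_open`, `water_shade`; attribute `mass_g`.
#' @export
hourly_water_loss <- function(open_env, shade_env = NULL, bird, tol = 1e-5) {
  open_only <- is.null(shade_env)
  mo <- .env_matrix(open_env)
  ms <- if (open_only) mo else .env_matrix(shade_env)
  if (nrow(mo) != nrow(ms)) stop("open and shade environments must share hours")
  day <- .solve_day_cpp(mo, ms, .bird_vec(bird), tol, open_only)
  out <- data.frame(hour = seq_len(nrow(mo)) - 1L,
                    water_gph = day[, "water_gph"],
                    habitat = ifelse(day[, "habitat"] > 0, "shade", "open"),
                    tb = day[, "tb"], stage = as.integer(day[, "stage"]),
                    flag = as.integer(day[, "flag"]),
                    water_open = day[, "water_open"],
                    water_shade = day[, "water_shade"])
  attr(out, "mass_g") <- bird$mass_g
  class(out) <- c("hourly_water_loss", "data.frame")
  out
}

#' Simulated respirometry: Tb and water loss across air temperatures
#'
#' Runs the cascade solver at chamber conditions (wind 0.1 m/s, relative
#' humidity 5%, zero radiation; radiant temperatures equal to air
#' temperature) across a sweep of air temperatures.
#'
#' @param bird A `bird_model`.
#' @param ta_values Air temperatures (C).
#' @param wind,rh Chamber wind (m/s) and relative humidity (%).
#' @param tol Heat-balance tolerance (W).
#' @return `data.frame` with `ta`, `tb`, `water_gph`, `stage`, `flag`.
#' @export
respirometry_curve <- function(bird, ta_values, wind = 0.1, rh = 5,
                               tol = 1e-5) {
  stopifnot(all(is.finite(ta_values)))
  rows <- lapply(ta_values, function(ta) {
    st <- solve_thermoregulation(
      list(tair = ta, rh = rh, solar = 0, wind = wind,
           tsky = ta, tground = ta), bird, tol = tol)
    data.frame(ta = ta, tb = st$tb, water_gph = st$water_gph,
               stage = st$stage, flag = st$flag)
  })
  do.call(rbind, rows)
}
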