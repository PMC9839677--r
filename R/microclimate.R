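# Monthly -> hourly microclimate downscaling for the hottest month.

#' Saturation vapour pressure (Magnus form over water)
#'
#' @param t_c Air temperature (degrees C).
#' @return Saturation vapour pressure in kPa.
#' @export
esat_kpa <- function(t_c) {
  0.61094 * exp(17.625 * t_c / (t_c + 243.04))
}

#' Hottest calendar month for a latitude
#'
#' July for the Northern Hemisphere, January for the Southern; latitude 0 is
#' assigned to the Northern rule.
#'
#' @param latitude Latitude in degrees (finite).
#' @return Month index (7 or 1), vectorised over `latitude`.
#' @export
hottest_month <- function(latitude) {
  stopifnot(all(is.finite(latitude)))
  ifelse(latitude >= 0, 7L, 1L)
}

# mid-month day-of-year anchors (365-day year)
.month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.month_mid <- cumsum(.month_days) - .month_days / 2

#' Interpolate 12 monthly values to 365 daily values
#'
#' Periodic cubic spline through the monthly values anchored at mid-month
#' day-of-year, continuous across the year boundary.
#'
#' @param values Numeric vector of 12 finite monthly values.
#' @return Numeric vector of 365 daily values.
#' @export
monthly_to_daily <- function(values) {
  if (length(values) != 12L || !all(is.finite(values)))
    stop("'values' must be 12 finite monthly values")
  x <- c(.month_mid, .month_mid[1] + 365)
  y <- c(values, values[1])
  f <- stats::splinefun(x, y, method = "periodic")
  f(1:365)
}

# solar declination (degrees) for a day of year
.declination <- function(doy) {
  -23.44 * cos(2 * pi * (doy + 10) / 365)
}

# sunrise/sunset solar hour, clamped away from polar day/night
.sun_hours <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dec <- .declination(doy) * pi / 180
  cosH <- pmin(1, pmax(-1, -tan(phi) * tan(dec)))
  H <- acos(cosH)
  half <- H * 12 / pi
  list(sunrise = 12 - half, sunset = 12 + half, daylen = 2 * half)
}

#' Hourly air temperatures from daily extremes
#'
#' Parton-Logan style diurnal curve: half-sine rise from `tmin` at sunrise to
#' `tmax` at solar noon plus a lag, sinusoidal decline to sunset, exponential
#' decay overnight back to `tmin` at the next sunrise. Sunrise, sunset and
#' peak are snapped to whole hours so the 24-value series attains `tmin` and
#' `tmax` exactly.
#'
#' @param tmin,tmax Daily minimum/maximum air temperature (C), `tmin <= tmax`.
#' @param latitude Latitude (degrees), sets day length.
#' @param day_of_year Day of year (1-365).
#' @param peak_lag Hours after solar noon at which `tmax` occurs (default 1).
#' @param tau Nocturnal decay time constant (hours, default 4).
#' @return 24 hourly temperatures for hours 0-23.
#' @export
diurnal_cycle <- function(tmin, tmax, latitude, day_of_year,
                          peak_lag = 1, tau = 4) {
  if (!is.finite(tmin) || !is.finite(tmax) || tmin > tmax)
    stop("need finite tmin <= tmax")
  if (tmax == tmin) return(rep(tmin, 24))
  sun <- .sun_hours(latitude, day_of_year)
  h_peak <- as.integer(round(12 + peak_lag))
  h_sr <- min(max(as.integer(round(sun$sunrise)), 1L), h_peak - 2L)
  h_ss <- min(max(as.integer(round(sun$sunset)), h_peak + 1L), 23L)
  span <- 2 * (h_peak - h_sr)
  hours <- 0:23
  temp <- numeric(24)
  day <- hours >= h_sr & hours <= h_ss
  temp[day] <- tmin + (tmax - tmin) * sin(pi * (hours[day] - h_sr) / span)
  t_ss <- tmin + (tmax - tmin) * sin(pi * (h_ss - h_sr) / span)
  nl <- 24 - (h_ss - h_sr)
  n_night <- ifelse(hours > h_ss, hours - h_ss, hours + 24 - h_ss)
  decay <- (exp(-n_night / tau) - exp(-nl / tau)) / (1 - exp(-nl / tau))
  temp[!day] <- tmin + (t_ss - tmin) * decay[!day]
  temp
}

#' Hourly relative humidity from a fixed vapour pressure
#'
#' @param vapor_pressure Ambient vapour pressure (kPa, >= 0), held constant
#'   over the day.
#' @param hourly_t 24 hourly air temperatures (C).
#' @return 24 relative humidities in percent, capped at 100.
#' @export
hourly_humidity <- function(vapor_pressure, hourly_t) {
  if (!is.finite(vapor_pressure) || vapor_pressure < 0)
    stop("'vapor_pressure' must be >= 0")
  pmin(100, pmax(0, 100 * vapor_pressure / esat_kpa(hourly_t)))
}

#' Clear-sky solar radiation on a horizontal surface
#'
#' S = S0 * tau^(1/cos z) * cos z while the sun is above the horizon, else 0.
#'
#' @param latitude Latitude (degrees).
#' @param day_of_year Day of year (1-365).
#' @param hour Hour(s) of solar time, 0-23.
#' @param s0 Solar constant (W/m^2, default 1361).
#' @param tau Atmospheric transmittance (default 0.7).
#' @return Clear-sky flux (W/m^2), vectorised over `hour`.
#' @export
clear_sky_radiation <- function(latitude, day_of_year, hour,
                                s0 = 1361, tau = 0.7) {
  stopifnot(all(hour >= 0 & hour <= 23))
  phi <- latitude * pi / 180
  dec <- .declination(day_of_year) * pi / 180
  cosz <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(pi * (hour - 12) / 12)
  ifelse(cosz > 1e-6, s0 * tau^(1 / cosz) * cosz, 0)
}

#' Hourly solar radiation matching a monthly mean
#'
#' The hourly clear-sky profile of the representative day is scaled by the
#' clear-sky fraction f = observed monthly mean / modelled clear-sky mean,
#' capped at 1.
#'
#' @param monthly_mean_shortwave Observed monthly-mean downward shortwave
#'   (W/m^2, 24-h average).
#' @param latitude Latitude (degrees).
#' @param day_of_year Representative day of year.
#' @inheritParams clear_sky_radiation
#' @return 24 hourly fluxes (W/m^2).
#' @export
hourly_radiation <- function(monthly_mean_shortwave, latitude, day_of_year,
                             s0 = 1361, tau = 0.7) {
  if (!is.finite(monthly_mean_shortwave) || monthly_mean_shortwave < 0)
    stop("'monthly_mean_shortwave' must be >= 0")
  cs <- clear_sky_radiation(latitude, day_of_year, 0:23, s0 = s0, tau = tau)
  csm <- mean(cs)
  if (csm <= 0) return(rep(0, 24))
  f <- min(1, monthly_mean_shortwave / csm)
  cs * f
}

#' Hourly microclimate for one site-month at a given shade level
#'
#' Builds the 24-hour environment a perched bird (1.5 m, near screen height)
#' experiences on the representative (mean-climate) day of a month. Shade
#' attenuates solar radiation on the animal and the solar heating of the
#' ground; air temperature, humidity and wind are unchanged by shade. Sky
#' radiant temperature follows Swinbank clear-sky emissivity; ground radiant
#' temperature is air temperature plus 0.02 C per W/m^2 of (attenuated)
#' incident solar.
#'
#' @param site List with `latitude`, `tmax`, `tmin`, `vapor_pressure` (kPa),
#'   `shortwave` (monthly-mean W/m^2), `wind` (m/s) and `month` (1-12);
#'   optionally `year` and `longitude` (carried through).
#' @param shade_fraction Shade in `[0, 1]` (0 = open, 0.9 = deep shade).
#' @return A `data.frame` of 24 rows (class `hourly_microclimate`) with
#'   columns `hour`, `tair`, `rh`, `solar` (on the animal), `wind`, `tsky`,
#'   `tground`, and attributes `shade` and `height_m`.
#' @export
build_microclimate <- function(site, shade_fraction = 0) {
  if (!is.numeric(shade_fraction) || length(shade_fraction) != 1 ||
      !is.finite(shade_fraction) || shade_fraction < 0 || shade_fraction > 1)
    stop("'shade_fraction' must be a single value in [0, 1]")
  stopifnot(site$month %in% 1:12, site$tmin <= site$tmax,
            site$vapor_pressure >= 0, site$wind >= 0)
  doy <- as.integer(round(.month_mid[site$month]))
  tair <- diurnal_cycle(site$tmin, site$tmax, site$latitude, doy)
  rh <- hourly_humidity(site$vapor_pressure, tair)
  sol_open <- hourly_radiation(site$shortwave, site$latitude, doy)
  sol_animal <- (1 - shade_fraction) * sol_open
  tk <- tair + 273.15
  eps_sky <- pmin(1, 9.37e-6 * tk^2) # Swinbank clear-sky emissivity
  tsky <- tk * eps_sky^0.25 - 273.15
  tground <- tair + 0.02 * sol_animal
  out <- data.frame(hour = 0:23, tair = tair, rh = rh, solar = sol_animal,
                    wind = rep(site$wind, 24), tsky = tsky, tground = tground)
  attr(out, "shade") <- shade_fraction
  attr(out, "height_m") <- 1.5
  class(out) <- c("hourly_microclimate", "data.frame")
  out
}
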