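# ---------------------------------------------------------------------------
# Surface heat budget.
#
# Two modes: (1) Fick conduction, all heat into the surface layer;
# (2) bulk fluxes: clear-sky shortwave from solar geometry, longwave,
# sensible and latent heat from standard bulk formulas.  Non-solar fluxes
# and shortwave are absorbed exponentially with depth (e-folding scale =
# penetration depth, ~ the Secchi depth); whatever reaches the bottom is
# reflected and absorbed exponentially upward, and any residual reaching
# the surface is spread uniformly over the column, so the discrete budget
# closes exactly.
# ---------------------------------------------------------------------------

#' Heat-model parameters
#'
#' @param mode \code{"flux"} (bulk formulas) or \code{"fick"}.
#' @param solar_constant W/m2.
#' @param latitude degrees north.
#' @param penetration_depth e-folding absorption depth (m), roughly the
#'   Secchi disk depth.
#' @param sw_reflectivity shortwave surface reflectivity (albedo, 0-1).
#' @param bottom_reflectivity fraction of bottom-reaching shortwave
#'   reflected upward; the rest heats the bottom layer.
#' @param conduction_coefficient Fick-mode coefficient k (W/m2/K).
#' @param atm_transmission clear-sky atmospheric transmission factor.
#' @param rho_cp volumetric heat capacity of seawater (J/m3/K).
#' @export
heat_params <- function(mode = c("flux", "fick"), solar_constant = 1361,
                        latitude = 55, penetration_depth = 5,
                        sw_reflectivity = 0.06, bottom_reflectivity = 1,
                        conduction_coefficient = 50,
                        atm_transmission = 0.7, rho_cp = 4.09e6) {
  mode <- match.arg(mode)
  stopifnot(penetration_depth > 0,
            sw_reflectivity >= 0, sw_reflectivity <= 1,
            bottom_reflectivity >= 0, bottom_reflectivity <= 1)
  structure(list(mode = mode, solar_constant = solar_constant,
                 latitude = latitude, penetration_depth = penetration_depth,
                 sw_reflectivity = sw_reflectivity,
                 bottom_reflectivity = bottom_reflectivity,
                 conduction_coefficient = conduction_coefficient,
                 atm_transmission = atm_transmission, rho_cp = rho_cp),
            class = "flex_heat_params")
}

#' Clear-sky incoming shortwave radiation
#'
#' Solar declination and hour-angle geometry: zero when the sun is below
#' the horizon, otherwise the solar constant scaled by the sine of the
#' solar elevation and a bulk atmospheric transmission.
#'
#' @param latitude degrees north, in [-90, 90].
#' @param day_of_year 1-365.
#' @param hour local solar time (h, 12 = solar noon).
#' @param solar_constant W/m2.
#' @param transmission atmospheric transmission factor.
#' @return W/m2 at the (flat, unreflecting) surface.
#' @export
clear_sky_shortwave <- function(latitude, day_of_year, hour,
                                solar_constant = 1361, transmission = 0.7) {
  stopifnot(latitude >= -90, latitude <= 90)
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude * pi / 180
  h <- (hour - 12) * pi / 12
  sinel <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h)
  solar_constant * transmission * pmax(sinel, 0)
}

magnus_esat <- function(T) 6.112 * exp(17.67 * T / (T + 243.5))  # hPa

#' Relative humidity from dew point (Magnus formula)
#' @param dew_point,air_temp deg C.
#' @export
dewpoint_to_rh <- function(dew_point, air_temp) {
  pmin(magnus_esat(dew_point) / magnus_esat(air_temp), 1)
}

#' Bulk surface heat fluxes
#'
#' Sensible and latent heat scale with wind speed and the air-sea
#' temperature / humidity gradients; net longwave follows a
#' Stefan-Boltzmann formula with vapour-pressure and cloud corrections
#' (full cloud cover suppresses most of the longwave loss).  All fluxes are
#' W/m2, positive into the water.
#'
#' @param meteo list with \code{wind_speed} (m/s), \code{air_temp} (deg C),
#'   \code{cloud_cover} (0-1), and either \code{rel_humidity} (0-1) or
#'   \code{dew_point} (deg C).
#' @param water_temp sea-surface temperature (deg C).
#' @param Q_sw_clear clear-sky shortwave (W/m2), e.g. from
#'   \code{\link{clear_sky_shortwave}}; reduced here for cloud and surface
#'   reflectivity.
#' @param params a \code{flex_heat_params}.
#' @return list \code{Q_sw}, \code{Q_lw}, \code{Q_sensible}, \code{Q_latent}
#'   (W/m2, positive into the water).
#' @export
surface_flux_bulk <- function(meteo, water_temp, Q_sw_clear = 0,
                              params = heat_params()) {
  W <- meteo$wind_speed
  Ta <- meteo$air_temp
  C <- meteo$cloud_cover
  stopifnot(C >= 0, C <= 1)
  rh <- if (!is.null(meteo$rel_humidity)) {
    meteo$rel_humidity
  } else if (!is.null(meteo$dew_point)) {
    dewpoint_to_rh(meteo$dew_point, Ta)
  } else {
    stop("meteo needs rel_humidity or dew_point")
  }
  stopifnot(rh >= 0, rh <= 1)
  Tw <- water_temp
  rho_air <- 1.25; cp_air <- 1004; Lv <- 2.5e6
  C_H <- 1.3e-3; C_E <- 1.5e-3; p_atm <- 1013
  emiss <- 0.97; sigma <- 5.67e-8

  e_air <- rh * magnus_esat(Ta)
  e_sat_w <- magnus_esat(Tw)
  q_air <- 0.622 * e_air / p_atm
  q_sat <- 0.622 * e_sat_w / p_atm

  Q_sens <- rho_air * cp_air * C_H * W * (Ta - Tw)
  Q_lat <- rho_air * Lv * C_E * W * (q_air - q_sat)
  TwK <- Tw + 273.15
  Q_lw <- -(emiss * sigma * TwK^4 * (0.39 - 0.05 * sqrt(e_air)) *
              (1 - 0.75 * C^2) +
            4 * emiss * sigma * TwK^3 * (Tw - Ta))
  Q_sw <- Q_sw_clear * (1 - 0.62 * C) * (1 - params$sw_reflectivity)
  list(Q_sw = Q_sw, Q_lw = Q_lw, Q_sensible = Q_sens, Q_latent = Q_lat)
}

# Shared absorption kernel: exponential down, (partial) bottom reflection,
# exponential back up, residual spread uniformly.  Returns per-layer W/m2
# summing exactly to Q.
absorb_column <- function(Q, thick, penetration_depth, bottom_reflectivity) {
  n <- length(thick)
  if (Q == 0 || n == 0L) return(numeric(n))
  lam <- 1 / penetration_depth
  abs_ <- numeric(n)
  # downward pass
  Iin <- Q
  for (k in seq_len(n)) {
    Iout <- Iin * exp(-lam * thick[k])
    abs_[k] <- abs_[k] + (Iin - Iout)
    Iin <- Iout
  }
  # bottom: reflected part travels back up; the rest heats the bottom layer
  refl <- Iin * bottom_reflectivity
  abs_[n] <- abs_[n] + Iin - refl
  Iin <- refl
  if (Iin != 0) {
    for (k in n:1) {
      Iout <- Iin * exp(-lam * thick[k])
      abs_[k] <- abs_[k] + (Iin - Iout)
      Iin <- Iout
    }
    # residual reaching the surface: distributed uniformly (per area-depth)
    abs_ <- abs_ + Iin * thick / sum(thick)
  }
  abs_
}

#' Vertical absorption profile of net shortwave radiation
#'
#' @param Q_sw_net net shortwave entering the water (W/m2, >= 0).
#' @param thicknesses layer thicknesses of the column, surface first (m).
#' @param penetration_depth e-folding depth (m).
#' @param bottom_reflectivity fraction reflected at the bottom.
#' @return per-layer heating (W/m2) summing exactly to \code{Q_sw_net}.
#' @export
absorb_shortwave_profile <- function(Q_sw_net, thicknesses,
                                     penetration_depth,
                                     bottom_reflectivity = 1) {
  stopifnot(Q_sw_net >= 0)
  absorb_column(Q_sw_net, thicknesses, penetration_depth,
                bottom_reflectivity)
}

#' Vertical absorption profile of non-solar surface fluxes
#'
#' Longwave, sensible and latent heat (possibly negative = cooling) are
#' absorbed exponentially with depth; in water shallower than the
#' penetration depth the remainder is reflected at the bottom and any
#' residual distributed uniformly, closing the budget exactly.
#'
#' @param Q_nonsolar summed non-solar flux (W/m2, any sign).
#' @inheritParams absorb_shortwave_profile
#' @export
absorb_surface_fluxes <- function(Q_nonsolar, thicknesses,
                                  penetration_depth) {
  absorb_column(Q_nonsolar, thicknesses, penetration_depth, 1)
}

#' Fick-mode surface conduction
#'
#' \code{Q = k (T_air - T_surface)}, applied wholly to the surface layer.
#'
#' @param air_temp,surface_temp deg C.
#' @param conduction_coefficient k (W/m2/K).
#' @return surface heat flux (W/m2, positive into the water).
#' @export
fick_surface_conduction <- function(air_temp, surface_temp,
                                    conduction_coefficient) {
  conduction_coefficient * (air_temp - surface_temp)
}

#' Apply a heating step to the temperature field
#'
#' Computes the per-layer heating of every water column and updates the
#' temperature by \code{dt * Q / (rho_cp * h)}.  In flux mode the shortwave
#' absorption profile is also returned as the \code{light} environment
#' field for the equation solver.
#'
#' @param temp temperature field (polygon x layer, deg C).
#' @param mesh3d a \code{flex_mesh3d}.
#' @param params a \code{flex_heat_params}.
#' @param meteo meteo list (see \code{\link{surface_flux_bulk}}).
#' @param time_days simulation time in days (fractional; drives the solar
#'   cycle: day of year and hour).
#' @param dt time step (s).
#' @return list \code{temp} (updated), \code{light} (per-cell shortwave
#'   W/m2), \code{budget} (total W into the water).
#' @export
step_heat <- function(temp, mesh3d, params, meteo, time_days, dt) {
  np <- mesh3d$n_poly
  light <- matrix(0, np, mesh3d$n_layers)
  total <- 0
  doy <- floor(time_days %% 365) + 1
  hour <- (time_days %% 1) * 24
  for (i in seq_len(np)) {
    kb <- mesh3d$bottom_layer[i]
    th <- mesh3d$thickness[i, seq_len(kb)]
    if (params$mode == "fick") {
      Q <- fick_surface_conduction(meteo$air_temp, temp[i, 1],
                                   params$conduction_coefficient)
      heating <- c(Q, numeric(kb - 1L))
    } else {
      Qcs <- clear_sky_shortwave(params$latitude, doy, hour,
                                 params$solar_constant,
                                 params$atm_transmission)
      fl <- surface_flux_bulk(meteo, temp[i, 1], Qcs, params)
      sw <- absorb_shortwave_profile(fl$Q_sw, th, params$penetration_depth,
                                     params$bottom_reflectivity)
      ns <- absorb_surface_fluxes(fl$Q_lw + fl$Q_sensible + fl$Q_latent,
                                  th, params$penetration_depth)
      heating <- sw + ns
      light[i, seq_len(kb)] <- sw
    }
    temp[i, seq_len(kb)] <- temp[i, seq_len(kb)] +
      dt * heating / (params$rho_cp * th)
    total <- total + sum(heating) * mesh3d$mesh2d$area[i]
  }
  list(temp = temp, light = light, budget = total)
}

#' Column heat content (J) relative to 0 deg C
#' @inheritParams step_heat
#' @export
heat_content <- function(temp, mesh3d, params) {
  sum(temp[mesh3d$active] * mesh3d$volume[mesh3d$active]) * params$rho_cp
}
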