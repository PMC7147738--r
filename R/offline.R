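# ---------------------------------------------------------------------------
# Offline hydrodynamics: velocities (full face fields or uniform profiles),
# surface elevation and diffusivities read from a series of snapshots and
# interpolated linearly in time to the model's time stepping.
# ---------------------------------------------------------------------------

#' Create an offline field series
#'
#' @param times strictly increasing snapshot times (s).
#' @param u list of face-velocity matrices (face x layer), one per snapshot;
#'   or \code{NULL} when using profiles.
#' @param profiles list of per-snapshot \code{list(speed=, direction=)}
#'   (per-layer speed m/s, direction degrees clockwise from north, i.e.
#'   oceanographic "towards" convention), broadcast to faces on demand.
#' @param eta optional list of elevation vectors.
#' @param K_v optional list of per-layer vertical diffusivities.
#' @export
offline_series <- function(times, u = NULL, profiles = NULL, eta = NULL,
                           K_v = NULL) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("offline time axis must be strictly increasing")
  for (fld in list(u, profiles, eta, K_v)) {
    if (!is.null(fld) && length(fld) != length(times)) {
      stop("every offline field needs one snapshot per time")
    }
  }
  structure(list(times = times, u = u, profiles = profiles, eta = eta,
                 K_v = K_v),
            class = "flex_offline")
}

lin_combine <- function(a, b, w) {
  if (is.list(a) && !is.null(names(a))) {
    out <- a
    for (nm in names(a)) out[[nm]] <- (1 - w) * a[[nm]] + w * b[[nm]]
    out
  } else {
    (1 - w) * a + w * b
  }
}

#' Interpolate the offline series to an instant
#'
#' Linear interpolation between the bracketing snapshots; exact at snapshot
#' times; no extrapolation outside the covered window.
#'
#' @param series a \code{flex_offline}.
#' @param t time (s).
#' @return list with the interpolated components present in the series.
#' @export
fields_at <- function(series, t) {
  tt <- series$times
  if (t < tt[1] || t > tt[length(tt)]) {
    stop(sprintf("time %.6g outside offline coverage [%.6g, %.6g]",
                 t, tt[1], tt[length(tt)]))
  }
  j <- findInterval(t, tt, rightmost.closed = TRUE)
  j2 <- min(j + 1L, length(tt))
  w <- if (j2 == j) 0 else (t - tt[j]) / (tt[j2] - tt[j])
  out <- list(time = t)
  for (nm in c("u", "profiles", "eta", "K_v")) {
    if (!is.null(series[[nm]])) {
      out[[nm]] <- lin_combine(series[[nm]][[j]], series[[nm]][[j2]], w)
    }
  }
  out
}

#' Broadcast a uniform velocity profile onto face normals
#'
#' A horizontally uniform velocity vector per layer (speed + direction) is
#' projected onto every face normal; open/solid boundary faces keep their
#' projected value or zero respectively via \code{solid_walls}.
#'
#' @param speed per-layer current speed (m/s), or scalar.
#' @param direction per-layer direction (degrees clockwise from north,
#'   "towards"), or scalar.
#' @param mesh3d a \code{flex_mesh3d}.
#' @param solid_walls zero the velocity on solid boundary faces (default
#'   TRUE; the interior projection is unaffected).
#' @return face-normal velocity matrix (face x layer).
#' @export
broadcast_profile <- function(speed, direction, mesh3d, solid_walls = TRUE) {
  nl <- mesh3d$n_layers
  if (!length(speed) %in% c(1L, nl) || !length(direction) %in% c(1L, nl)) {
    stop(sprintf(
      "profile layer count mismatch: %d values for %d layers",
      max(length(speed), length(direction)), nl))
  }
  speed <- rep_len(speed, nl)
  direction <- rep_len(direction, nl)
  th <- direction * pi / 180
  vx <- speed * sin(th)      # east component
  vy <- speed * cos(th)      # north component
  f <- mesh3d$mesh2d$faces
  u <- outer(f$nx, vx) + outer(f$ny, vy)
  if (solid_walls) u[f$type == "solid", ] <- 0
  u[!mesh3d$face_active] <- 0
  u
}

#' Wind-dependent vertical diffusivity
#'
#' \code{K_v = a * wind_speed^b + K_background}, either uniform over the
#' column or weighted toward the surface with an exponential decay scale.
#'
#' @param wind_speed m/s (>= 0).
#' @param a,b power-law coefficients (m2/s per (m/s)^b, dimensionless).
#' @param K_background floor diffusivity (m2/s).
#' @param mesh3d optional mesh for a per-layer profile.
#' @param surface_scale e-folding depth (m) of a surface-weighted profile;
#'   \code{Inf} (default) gives a uniform value.
#' @return scalar, or per-layer vector when a mesh is given.
#' @export
wind_vertical_diffusivity <- function(wind_speed, a = 1e-4, b = 1.5,
                                      K_background = 1e-5, mesh3d = NULL,
                                      surface_scale = Inf) {
  stopifnot(wind_speed >= 0)
  K0 <- a * wind_speed^b
  if (is.null(mesh3d)) return(K0 + K_background)
  nl <- mesh3d$n_layers
  zc <- (mesh3d$interfaces[-1] + mesh3d$interfaces[-(nl + 1)]) / 2
  wgt <- if (is.finite(surface_scale)) exp(-zc / surface_scale) else rep(1, nl)
  K0 * wgt + K_background
}

#' Record the hydro state into an offline snapshot list
#'
#' Helper for writing out an online run for later offline re-use (the
#' self-consistency round trip: transport driven by recorded fields should
#' reproduce the online-coupled evolution up to temporal interpolation).
#'
#' @param state a \code{flex_hydro_state} after a step (its diagnostics
#'   carry the theta-weighted transport velocities).
#' @export
offline_snapshot <- function(state) {
  list(u = state$diag$u_transport %||% state$u, eta = state$eta,
       time = state$time)
}
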