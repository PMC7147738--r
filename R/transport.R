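# ---------------------------------------------------------------------------
# Finite-volume advection-diffusion of pelagic scalars on the C-grid.
#
# Horizontal advection is first-order upwind on face-normal velocities;
# horizontal diffusion is a centred two-point flux along the Voronoi segment
# (this is where mesh orthogonality pays off).  Vertical transport is either
# explicit (upwind + centred) or fully implicit (tridiagonal per column,
# unconditionally stable, M-matrix so no new extrema).  All fluxes are
# antisymmetric between the two sides of a face, so a closed basin conserves
# tracer mass to round-off.
#
# Open boundaries are clamped: an inflow face carries the prescribed
# boundary concentration in its upwind flux, an outflow face the interior
# value.  Solid faces carry no flux (face-normal velocity must be zero).
# ---------------------------------------------------------------------------

# Vertical volume fluxes (m3/s, positive upward) at the interface below each
# layer k (k = 1..nl-1 rows used), from horizontal-divergence continuity,
# integrating from the bottom up.  The surface absorbs the residual
# (free-surface motion when coupled; reported for diagnostics).
diagnose_vertical_flux <- function(mesh3d, u) {
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  f <- mesh3d$mesh2d$faces
  divH <- matrix(0, np, nl)    # net horizontal volume outflow per cell (m3/s)
  for (k in seq_len(nl)) {
    flux <- mesh3d$face_area[, k] * u[, k]
    divH[, k] <- rowsum_vec(mesh3d$fc_sign * flux[mesh3d$fc_face],
                            mesh3d$fc_cell, np)
  }
  wA <- matrix(0, np, nl)      # wA[, k]: upward flux through interface below k
  if (nl > 1L) {
    for (k in nl:2L) {
      below <- if (k < nl) wA[, k] else 0
      # interface above layer k is interface below layer k-1
      wA[, k - 1L] <- below - divH[, k]
    }
  }
  surf_residual <- (if (nl > 1L) wA[, 1L] else 0) - divH[, 1L]
  attr(wA, "surface_residual") <- surf_residual   # = dV/dt of the column
  wA
}

# Horizontal mass-flux divergence (units/s per cell): upwind advection +
# centred diffusion.  Returns np x nl matrix of dM/dt contributions.
horizontal_divergence <- function(C, u, mesh3d, D_h = 0,
                                  boundary_value = NULL) {
  f <- mesh3d$mesh2d$faces
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers; nf <- mesh3d$n_face
  li <- f$left; ri <- pmax(f$right, 1L)
  interior <- f$right > 0L
  open <- f$type == "open"
  cl <- C[li, , drop = FALSE]
  cr <- C[ri, , drop = FALSE]
  cr[!interior, ] <- 0
  if (any(open)) {
    if (is.null(boundary_value)) {
      stop("open boundary present but no boundary values supplied")
    }
    bv <- if (is.matrix(boundary_value)) {
      boundary_value
    } else {
      matrix(boundary_value, nf, nl)
    }
    cr[open, ] <- bv[open, , drop = FALSE]
  }
  cup <- ifelse(u > 0, cl, ifelse(u < 0, cr, 0.5 * (cl + cr)))
  flux <- mesh3d$face_area * u * cup          # out of left when positive
  flux[f$type == "solid", ] <- 0
  if (D_h > 0) {
    dgrad <- (cr - cl) / f$dist
    dflux <- -D_h * mesh3d$face_area * dgrad
    dflux[!interior, ] <- 0                   # no diffusive boundary flux
    flux <- flux + dflux
  }
  flux[!mesh3d$face_active] <- 0
  dM <- matrix(0, np, nl)
  for (k in seq_len(nl)) {
    dM[, k] <- -rowsum_vec(mesh3d$fc_sign * flux[mesh3d$fc_face, k],
                           mesh3d$fc_cell, np)
  }
  dM
}

check_courant <- function(C, u, mesh3d, dt, wA) {
  # outflow-volume Courant number per cell
  f <- mesh3d$mesh2d$faces
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  out <- matrix(0, np, nl)
  for (k in seq_len(nl)) {
    flux <- mesh3d$face_area[, k] * u[, k]
    sflux <- mesh3d$fc_sign * flux[mesh3d$fc_face]
    out[, k] <- rowsum_vec(pmax(sflux, 0), mesh3d$fc_cell, np)
  }
  if (!is.null(wA) && nl > 1L) {
    for (k in seq_len(nl)) {
      up <- if (k > 1L) pmax(-wA[, k - 1L], 0) else 0   # downward out the top? no: upward out
      if (k > 1L) out[, k] <- out[, k] + pmax(wA[, k - 1L], 0)
      if (k < nl) out[, k] <- out[, k] + pmax(-wA[, k], 0)
    }
  }
  co <- dt * out / pmax(mesh3d$volume, 1e-300)
  co[!mesh3d$active] <- 0
  max(co)
}

#' Explicit advection-diffusion step for one tracer field
#'
#' @param C tracer concentration, (polygon x layer) matrix.
#' @param u face-normal velocities, (face x layer) matrix (m/s).
#' @param mesh3d a \code{flex_mesh3d}.
#' @param dt time step (s).
#' @param D_h,D_v horizontal / vertical diffusivity (m2/s).
#' @param boundary_value clamped concentration used on inflowing open faces:
#'   scalar or (face x layer) matrix.
#' @param wA vertical volume fluxes as returned by the continuity diagnosis
#'   (computed from \code{u} when \code{NULL}).
#' @param V_old,V_new cell volumes before/after the step (default: static
#'   mesh volumes); supply these when coupled to a moving free surface.
#' @return updated concentration matrix.
#' @export
advect_diffuse_explicit <- function(C, u, mesh3d, dt, D_h = 0, D_v = 0,
                                    boundary_value = NULL, wA = NULL,
                                    V_old = NULL, V_new = NULL) {
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  if (is.null(wA)) wA <- diagnose_vertical_flux(mesh3d, u)
  co <- check_courant(C, u, mesh3d, dt, wA)
  if (co > 1) {
    stop(sprintf(
      "explicit advection CFL violated: max Courant %.3f; reduce dt to <= %.3g s",
      co, dt / co))
  }
  dM <- horizontal_divergence(C, u, mesh3d, D_h, boundary_value)
  A <- mesh3d$mesh2d$area
  if (nl > 1L) {
    for (k in seq_len(nl - 1L)) {
      both <- mesh3d$active[, k] & mesh3d$active[, k + 1L]
      w <- wA[, k] * both
      cup <- ifelse(w > 0, C[, k + 1L], C[, k])
      Fv <- w * cup
      if (D_v > 0) {
        dzc <- (mesh3d$thickness[, k] + mesh3d$thickness[, k + 1L]) / 2
        Fv <- Fv + D_v * A * (C[, k + 1L] - C[, k]) / pmax(dzc, 1e-300) * both
      }
      dM[, k] <- dM[, k] + Fv
      dM[, k + 1L] <- dM[, k + 1L] - Fv
    }
  }
  V0 <- if (is.null(V_old)) mesh3d$volume else V_old
  V1 <- if (is.null(V_new)) mesh3d$volume else V_new
  Cn <- C
  act <- mesh3d$active
  Cn[act] <- (V0[act] * C[act] + dt * dM[act]) / pmax(V1[act], 1e-300)
  Cn
}

#' Vertically semi-implicit advection-diffusion step
#'
#' Horizontal transport explicit (upwind), vertical transport fully implicit
#' (upwind advection + centred diffusion, tridiagonal solve per column):
#' unconditionally stable in the vertical and free of vertical CFL limits,
#' e.g. for strong settling-like velocities.
#'
#' @inheritParams advect_diffuse_explicit
#' @export
advect_diffuse_semi_implicit <- function(C, u, mesh3d, dt, D_h = 0, D_v = 0,
                                         boundary_value = NULL, wA = NULL,
                                         V_old = NULL, V_new = NULL) {
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  if (is.null(wA)) wA <- diagnose_vertical_flux(mesh3d, u)
  dM <- horizontal_divergence(C, u, mesh3d, D_h, boundary_value)
  V0 <- if (is.null(V_old)) mesh3d$volume else V_old
  V1 <- if (is.null(V_new)) mesh3d$volume else V_new
  A <- mesh3d$mesh2d$area
  Cs <- C
  act <- mesh3d$active
  Cs[act] <- (V0[act] * C[act] + dt * dM[act]) / pmax(V1[act], 1e-300)
  if (nl == 1L) return(Cs)
  Cn <- Cs
  for (i in seq_len(np)) {
    kb <- mesh3d$bottom_layer[i]
    if (!mesh3d$active[i, 1L] || kb == 1L) next
    ks <- seq_len(kb)
    V <- V1[i, ks]
    w <- wA[i, ks[-kb]]                        # interfaces below layers 1..kb-1
    dzc <- (mesh3d$thickness[i, ks[-kb]] + mesh3d$thickness[i, ks[-1]]) / 2
    dcoef <- if (D_v > 0) D_v * A[i] / pmax(dzc, 1e-300) else numeric(kb - 1L)
    wp <- pmax(w, 0); wm <- pmax(-w, 0)
    lower <- numeric(kb); diag_ <- numeric(kb); upper <- numeric(kb)
    # interface j couples layers j and j+1
    diag_ <- V
    for (j in seq_len(kb - 1L)) {
      dj <- if (D_v > 0) dcoef[j] else 0
      diag_[j] <- diag_[j] + dt * (wm[j] + dj)
      upper[j] <- -dt * (wp[j] + dj)
      diag_[j + 1L] <- diag_[j + 1L] + dt * (wp[j] + dj)
      lower[j + 1L] <- -dt * (wm[j] + dj)
    }
    Cn[i, ks] <- solve_tridiag(lower, diag_, upper, V * Cs[i, ks])
  }
  Cn
}

#' Volume or tracer flux through a section
#'
#' Signed sum over the section's faces and layers of
#' \code{face_area * u * (upwind tracer | 1)}.
#'
#' @param section a \code{flex_section} from \code{\link{define_section}}.
#' @param u face-normal velocities (face x layer).
#' @param mesh3d a \code{flex_mesh3d}.
#' @param C optional tracer field; when omitted the volume flux (m3/s) is
#'   returned, otherwise the tracer flux (units/s).
#' @export
section_flux <- function(section, u, mesh3d, C = NULL) {
  f <- mesh3d$mesh2d$faces
  j <- section$faces
  A <- mesh3d$face_area[j, , drop = FALSE]
  uj <- u[j, , drop = FALSE]
  if (is.null(C)) {
    val <- A * uj
  } else {
    cl <- C[f$left[j], , drop = FALSE]
    cr <- C[pmax(f$right[j], 1L), , drop = FALSE]
    cup <- ifelse(uj > 0, cl, ifelse(uj < 0, cr, 0.5 * (cl + cr)))
    val <- A * uj * cup
  }
  sum(section$sign * rowSums(val))
}

#' Add source loads to a tracer field
#'
#' Sources add mass (load, units/s) to their target cell; a moving source is
#' re-located to the polygon containing its position each step.  The vertical
#' distribution rule places the load in the surface layer, the bottom layer,
#' uniformly over the column, or in a stated layer.
#'
#' @param C tracer field (polygon x layer).
#' @param mesh3d a \code{flex_mesh3d}.
#' @param sources list of source specs: \code{list(polygon=} or
#'   \code{x=, y=, load=, distribute = "surface"|"bottom"|"uniform"|layer)}.
#' @param dt time step (s).
#' @param time current time (s), passed to time-varying source positions
#'   (\code{x}/\code{y} may be functions of time).
#' @export
apply_sources <- function(C, mesh3d, sources, dt, time = 0) {
  for (s in sources) {
    if (!is.null(s$polygon)) {
      ip <- s$polygon
    } else {
      sx <- if (is.function(s$x)) s$x(time) else s$x
      sy <- if (is.function(s$y)) s$y(time) else s$y
      ip <- locate_element(mesh3d, sx, sy)
      if (is.na(ip)) next                      # source outside mesh: skipped
    }
    load <- if (is.function(s$load)) s$load(time) else s$load
    dist <- if (is.null(s$distribute)) "surface" else s$distribute
    kb <- mesh3d$bottom_layer[ip]
    if (identical(dist, "surface")) {
      kk <- 1L; wgt <- 1
    } else if (identical(dist, "bottom")) {
      kk <- kb; wgt <- 1
    } else if (identical(dist, "uniform")) {
      kk <- seq_len(kb)
      wgt <- mesh3d$volume[ip, kk] / sum(mesh3d$volume[ip, kk])
    } else {
      kk <- min(as.integer(dist), kb); wgt <- 1
    }
    C[ip, kk] <- C[ip, kk] + load * wgt * dt / mesh3d$volume[ip, kk]
  }
  C
}
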