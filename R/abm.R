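# ---------------------------------------------------------------------------
# Lagrangian agent-based module.
#
# Agents carry a position (x, y, z), an active flag, a release-region tag
# and user-named trait variables evolved by the same expression DSL as the
# pelagic equations.  Velocities are interpolated to agent positions from
# the face-normal field via a cell-centred least-squares reconstruction
# plus its linear gradient (exact for uniform and linear velocity fields).
# Advection is explicit RK2 (midpoint); diffusion is a random displacement
# of uniform direction.  Boundary handling follows an end-point test: an
# agent stepping outside the wet domain is returned to the Voronoi point of
# its last wet element at unchanged depth (solid mode) or deactivated when
# its last wet element touches an open boundary (sink mode).
# ---------------------------------------------------------------------------

#' Create an agent population
#'
#' @param x,y,z initial positions (m; z positive down).
#' @param region release-region tag per agent (integer).
#' @param traits named list of initial trait values (scalar or per agent).
#' @param substeps ABM sub-steps per global time step (integer >= 1).
#' @export
agent_population <- function(x, y, z = 0, region = 1L, traits = list(),
                             substeps = 1L) {
  n <- length(x)
  tr <- lapply(traits, rep_len, n)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 z = rep_len(as.numeric(z), n),
                 active = rep(TRUE, n),
                 region = rep_len(as.integer(region), n),
                 traits = tr, substeps = as.integer(substeps), n = n),
            class = "flex_agents")
}

#' @export
print.flex_agents <- function(x, ...) {
  cat(sprintf("flex_agents: %d agents (%d active), traits: %s\n",
              x$n, sum(x$active),
              if (length(x$traits)) paste(names(x$traits), collapse = ", ")
              else "none"))
  invisible(x)
}

# interpolation context: cell-centred velocities + linear gradients
velocity_context <- function(mesh3d, u) {
  uc <- reconstruct_cell_velocity(mesh3d, u)
  list(ux = uc$ux, uy = uc$uy,
       gxx = cell_gradients(mesh3d, uc$ux),
       gyy = cell_gradients(mesh3d, uc$uy))
}

#' Interpolate the velocity field to arbitrary positions
#'
#' Linear reconstruction around the containing cell's Voronoi point:
#' exact for spatially uniform flow (consistency) and for linear fields
#' such as solid-body rotation away from boundaries.  Vertical: values of
#' the layer containing z, interpolated linearly between layer centres.
#'
#' @param mesh3d a \code{flex_mesh3d}.
#' @param u face-normal velocities (face x layer) or a precomputed context
#'   from \code{velocity_context}.
#' @param x,y,z positions (z positive down, defaults to mid-surface-layer).
#' @param cells optional pre-located containing polygons.
#' @return list \code{vx}, \code{vy} (m/s) per position (NA outside mesh).
#' @export
interpolate_velocity <- function(mesh3d, u, x, y, z = NULL, cells = NULL) {
  ctx <- if (is.matrix(u)) velocity_context(mesh3d, u) else u
  if (is.null(cells)) cells <- locate_element(mesh3d, x, y)
  n <- length(x)
  vx <- rep(NA_real_, n); vy <- rep(NA_real_, n)
  nl <- mesh3d$n_layers
  zc_nominal <- (mesh3d$interfaces[-1] + mesh3d$interfaces[-(nl + 1)]) / 2
  ok <- which(!is.na(cells))
  for (q in ok) {
    i <- cells[q]
    zz <- if (is.null(z)) zc_nominal[1] else z[q]
    # containing layer
    k <- findInterval(zz, mesh3d$interfaces, all.inside = TRUE)
    k <- min(k, mesh3d$bottom_layer[i])
    if (!mesh3d$active[i, k]) { vx[q] <- 0; vy[q] <- 0; next }
    dxq <- x[q] - mesh3d$mesh2d$voronoi[i, 1]
    dyq <- y[q] - mesh3d$mesh2d$voronoi[i, 2]
    lin <- function(k) c(
      ctx$ux[i, k] + ctx$gxx$gx[i, k] * dxq + ctx$gxx$gy[i, k] * dyq,
      ctx$uy[i, k] + ctx$gyy$gx[i, k] * dxq + ctx$gyy$gy[i, k] * dyq)
    v <- lin(k)
    # vertical linear interpolation between layer centres
    kb <- mesh3d$bottom_layer[i]
    if (nl > 1L) {
      if (zz > zc_nominal[k] && k < kb) {
        v2 <- lin(k + 1L)
        wgt <- (zz - zc_nominal[k]) / (zc_nominal[k + 1L] - zc_nominal[k])
        v <- (1 - wgt) * v + wgt * v2
      } else if (zz < zc_nominal[k] && k > 1L) {
        v2 <- lin(k - 1L)
        wgt <- (zc_nominal[k] - zz) / (zc_nominal[k] - zc_nominal[k - 1L])
        v <- (1 - wgt) * v + wgt * v2
      }
    }
    vx[q] <- v[1]; vy[q] <- v[2]
  }
  list(vx = vx, vy = vy)
}

# cells touching an open boundary face
open_boundary_cells <- function(mesh3d) {
  f <- mesh3d$mesh2d$faces
  unique(f$left[f$type == "open"])
}

#' Advance the agent population one (sub-stepped) time step
#'
#' Per sub-step: trait equations (same DSL engine as the pelagic solver),
#' RK2 midpoint advection in the interpolated velocity field, a uniform-
#' direction random-walk displacement, then boundary handling and the
#' optional deactivation criterion.
#'
#' @param pop a \code{flex_agents}.
#' @param mesh3d a \code{flex_mesh3d}.
#' @param u face-normal velocities (face x layer); \code{NULL} for no flow.
#' @param dt global time step (s); each sub-step advances
#'   \code{dt / substeps}.
#' @param diffusivity_h,diffusivity_v horizontal/vertical agent diffusivity
#'   (m2/s): random displacements of magnitude \code{sqrt(4 Kh dt)}
#'   (uniform direction) and \code{sqrt(2 Kv dt)} (random sign).
#' @param system optional \code{flex_eqsys} whose pelagic equations act on
#'   the agent traits (cell-local, so traits evolve per agent).
#' @param env environment fields passed to the trait equations.
#' @param w_agent vertical agent velocity (m/s, positive down; e.g. a
#'   buoyancy or settling term), scalar or per agent.
#' @param boundary \code{"solid"} (open boundaries act like walls) or
#'   \code{"sink"} (agents crossing an open boundary are deactivated).
#' @param deactivate optional DSL expression of traits/environment: agents
#'   where it evaluates > 0 are deactivated (e.g. settlement criteria).
#' @param scheme \code{"rk2"} (midpoint) or \code{"euler"}.
#' @return updated population.
#' @export
step_agents <- function(pop, mesh3d, u = NULL, dt,
                        diffusivity_h = 0, diffusivity_v = 0,
                        system = NULL, env = list(), w_agent = 0,
                        boundary = c("solid", "sink"),
                        deactivate = NULL, scheme = c("rk2", "euler")) {
  boundary <- match.arg(boundary)
  scheme <- match.arg(scheme)
  nsub <- pop$substeps
  h <- dt / nsub
  ctx <- if (!is.null(u)) velocity_context(mesh3d, u) else NULL
  obc <- open_boundary_cells(mesh3d)
  deact_fn <- if (!is.null(deactivate)) {
    dsl_compile(deactivate, c(names(pop$traits), ENV_NAMES))
  } else {
    NULL
  }
  for (ss in seq_len(nsub)) {
    act <- which(pop$active)
    if (length(act) == 0L) break
    # trait equations (cell-local DSL, applied per agent)
    if (!is.null(system) && length(system$eq_fun) > 0) {
      flds <- lapply(pop$traits, function(tr) tr[act])
      envA <- env
      envA$z <- pop$z[act]
      upd <- evaluate_timestep(system, flds, envA, h)
      for (v in names(system$eq_fun)) pop$traits[[v]][act] <- upd[[v]]
    }
    cells <- locate_element(mesh3d, pop$x[act], pop$y[act])
    vx <- numeric(length(act)); vy <- numeric(length(act))
    if (!is.null(ctx)) {
      v1 <- interpolate_velocity(mesh3d, ctx, pop$x[act], pop$y[act],
                                 pop$z[act], cells)
      v1$vx[is.na(v1$vx)] <- 0; v1$vy[is.na(v1$vy)] <- 0
      if (scheme == "rk2") {
        xm <- pop$x[act] + 0.5 * h * v1$vx
        ym <- pop$y[act] + 0.5 * h * v1$vy
        vm <- interpolate_velocity(mesh3d, ctx, xm, ym, pop$z[act])
        vx <- ifelse(is.na(vm$vx), v1$vx, vm$vx)
        vy <- ifelse(is.na(vm$vy), v1$vy, vm$vy)
      } else {
        vx <- v1$vx; vy <- v1$vy
      }
    }
    xn <- pop$x[act] + h * vx
    yn <- pop$y[act] + h * vy
    zn <- pop$z[act] + h * rep_len(w_agent, length(act))
    if (diffusivity_h > 0) {
      ang <- runif(length(act), 0, 2 * pi)
      step_len <- sqrt(4 * diffusivity_h * h)
      xn <- xn + step_len * cos(ang)
      yn <- yn + step_len * sin(ang)
    }
    if (diffusivity_v > 0) {
      zn <- zn + sqrt(2 * diffusivity_v * h) *
        sign(runif(length(act)) - 0.5)
    }
    # end-point boundary test
    new_cells <- locate_element(mesh3d, xn, yn)
    lost <- is.na(new_cells)
    if (any(lost)) {
      last_wet <- cells[lost]
      last_wet[is.na(last_wet)] <- 1L
      if (boundary == "sink") {
        sink_hit <- last_wet %in% obc
        pop$active[act[lost][sink_hit]] <- FALSE
        ret <- which(lost)[!sink_hit]
      } else {
        ret <- which(lost)
      }
      # return to the centre (Voronoi point) of the last wet element,
      # depth unchanged
      if (length(ret) > 0) {
        lw <- cells[ret]; lw[is.na(lw)] <- 1L
        xn[ret] <- mesh3d$mesh2d$voronoi[lw, 1]
        yn[ret] <- mesh3d$mesh2d$voronoi[lw, 2]
        new_cells[ret] <- lw
      }
    }
    # reflect depth at the surface and the local bottom (a reflecting wall
    # keeps a uniform vertical distribution uniform; clamping would not)
    loc_depth <- mesh3d$bathymetry[ifelse(is.na(new_cells), 1L, new_cells)]
    zn <- abs(zn)
    over <- !is.na(new_cells) & zn > loc_depth
    zn[over] <- 2 * loc_depth[over] - zn[over]
    zn <- pmin(pmax(zn, 0), ifelse(is.na(new_cells), zn, loc_depth))
    pop$x[act] <- xn; pop$y[act] <- yn; pop$z[act] <- zn
    if (!is.null(deact_fn)) {
      vals <- c(lapply(pop$traits, function(tr) tr[act]), list(z = pop$z[act]))
      for (nm in setdiff(ENV_NAMES, names(vals))) vals[[nm]] <- 0
      crit <- deact_fn(vals)
      pop$active[act[crit > 0]] <- FALSE
    }
  }
  pop
}

#' Downstream connectivity matrix
#'
#' \code{P[i, j]} = fraction of the agents released in region i censused in
#' region j; the final \code{"lost"} column collects agents that are
#' inactive or outside every region, so rows sum to 1.
#'
#' @param pop a \code{flex_agents} at census time.
#' @param mesh3d a \code{flex_mesh3d}.
#' @param regions integer vector mapping each polygon to a region id (NA =
#'   not part of any region).
#' @param release_regions the region ids that released agents (defaults to
#'   those present in the population); a listed region with zero releases
#'   yields a NaN row with a warning.
#' @return matrix with one row per release region.
#' @export
downstream_connectivity <- function(pop, mesh3d, regions,
                                    release_regions = NULL) {
  rel <- if (is.null(release_regions)) {
    sort(unique(pop$region))
  } else {
    sort(release_regions)
  }
  reg_ids <- sort(unique(regions[!is.na(regions)]))
  P <- matrix(0, length(rel), length(reg_ids) + 1L,
              dimnames = list(from = rel, to = c(reg_ids, "lost")))
  cells <- locate_element(mesh3d, pop$x, pop$y)
  final_reg <- ifelse(is.na(cells), NA_integer_, regions[cells])
  final_reg[!pop$active] <- NA_integer_
  for (r in seq_along(rel)) {
    sel <- pop$region == rel[r]
    n_rel <- sum(sel)
    if (n_rel == 0L) {
      warning(sprintf("region %s released no agents", rel[r]))
      P[r, ] <- NaN
      next
    }
    for (j in seq_along(reg_ids)) {
      P[r, j] <- sum(sel & !is.na(final_reg) & final_reg == reg_ids[j]) / n_rel
    }
    P[r, length(reg_ids) + 1L] <- 1 - sum(P[r, seq_along(reg_ids)])
  }
  P
}
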