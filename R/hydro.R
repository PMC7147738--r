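# ---------------------------------------------------------------------------
# Hydrostatic semi-implicit free-surface solver on the C-grid.
#
# Face-normal momentum carries an explicit AB2 tendency (advection,
# horizontal/vertical diffusion, Coriolis, baroclinic pressure, wind and
# bottom drag) plus a theta-weighted free-surface gradient.  Substituting
# the momentum update into depth-integrated continuity yields a symmetric
# positive-definite system for the new surface elevation, solved by
# Jacobi-preconditioned conjugate gradients.  theta = 0.5 is second-order
# accurate and energy-neutral for the linear seiche; theta = 1 is fully
# implicit and strongly damped but unconditionally stable.
#
# Degenerate 0D setups (a mesh with no interior faces) evolve a
# cell-centred velocity vector under Coriolis, wind and drag with the same
# AB2 machinery: that is the 0D/box-model limit of the framework.
# ---------------------------------------------------------------------------

#' Hydrodynamic parameters
#'
#' @param dt time step (s).
#' @param theta implicitness of the free-surface terms, in [0, 1]; 0.5 is
#'   second-order accurate, 1 fully implicit.
#' @param g gravity (m/s2).
#' @param f Coriolis parameter (1/s), scalar or per polygon.
#' @param rho0 reference density (kg/m3).
#' @param nu_h,nu_v laminar horizontal/vertical viscosity (m2/s).
#' @param C_smag Smagorinsky coefficient (dimensionless, 0 disables).
#' @param C_bottom quadratic bottom-drag coefficient (dimensionless).
#' @param wind \code{NULL}, or \code{list(taux=, tauy=)} (N/m2), or a
#'   function of time returning that list.
#' @param advect_momentum include momentum advection (upwind flux form on
#'   the cell-centred reconstruction).
#' @param eos equation of state: \code{list(mode="linear", rho0=, alpha_T=,
#'   beta_S=, T0=, S0=)}; density rho0*(1 - alpha_T (T-T0) + beta_S (S-S0)).
#' @param pcg_tol,pcg_maxiter conjugate-gradient controls.
#' @param eta_limit sanity bound on |eta| (m); exceeded => abort.
#' @export
hydro_params <- function(dt, theta = 0.5, g = 9.81, f = 0, rho0 = 1025,
                         nu_h = 0, nu_v = 0, C_smag = 0, C_bottom = 0,
                         wind = NULL, advect_momentum = FALSE,
                         eos = list(mode = "linear", rho0 = 1025,
                                    alpha_T = 2e-4, beta_S = 8e-4,
                                    T0 = 10, S0 = 35),
                         pcg_tol = 1e-12, pcg_maxiter = 5000L,
                         eta_limit = 50) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  if (C_smag < 0) stop("C_smag must be >= 0")
  structure(list(dt = dt, theta = theta, g = g, f = f, rho0 = rho0,
                 nu_h = nu_h, nu_v = nu_v, C_smag = C_smag,
                 C_bottom = C_bottom, wind = wind,
                 advect_momentum = advect_momentum, eos = eos,
                 pcg_tol = pcg_tol, pcg_maxiter = pcg_maxiter,
                 eta_limit = eta_limit),
            class = "flex_hydro_params")
}

#' Density from the equation of state
#' @param eos see \code{\link{hydro_params}}.
#' @param temp,salt temperature (deg C) and salinity (PSU) fields.
#' @export
eos_density <- function(eos, temp, salt) {
  if (identical(eos$mode, "linear")) {
    eos$rho0 * (1 - eos$alpha_T * (temp - eos$T0) +
                  eos$beta_S * (salt - eos$S0))
  } else {
    stop(sprintf("unknown EOS mode '%s'", eos$mode))
  }
}

#' Initialise a hydrodynamic state
#'
#' @param mesh3d a \code{flex_mesh3d}.
#' @param params a \code{flex_hydro_params}.
#' @param eta,temp,salt initial fields (scalars recycled).
#' @export
hydro_state <- function(mesh3d, params, eta = 0, temp = 10, salt = 35) {
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers; nf <- mesh3d$n_face
  temp <- matrix(temp, np, nl)
  salt <- matrix(salt, np, nl)
  structure(list(u = matrix(0, nf, nl),
                 eta = rep_len(eta, np),
                 temp = temp, salt = salt,
                 rho = eos_density(params$eos, temp, salt),
                 nu_h = matrix(params$nu_h, np, nl),
                 prev_tend = NULL,
                 uc = NULL,          # 0D mode cell velocities (ux, uy)
                 prev_tend0 = NULL,
                 time = 0,
                 diag = list()),
            class = "flex_hydro_state")
}

#' Cell volumes including the free-surface contribution
#' @param mesh3d a \code{flex_mesh3d}.
#' @param eta free-surface elevation per polygon (m).
#' @export
cell_volumes <- function(mesh3d, eta) {
  V <- mesh3d$volume
  V[, 1] <- (mesh3d$thickness[, 1] + eta) * mesh3d$mesh2d$area
  V
}

#' Smagorinsky eddy viscosity
#'
#' \code{nu_h = (C_smag * L)^2 |S|} per cell with \code{L = sqrt(area)} and
#' \code{|S|} the magnitude of the discrete strain rate of the cell-centred
#' velocity reconstruction.
#'
#' @param u face-normal velocities (face x layer).
#' @param mesh3d a \code{flex_mesh3d}.
#' @param C_smag Smagorinsky coefficient.
#' @export
smagorinsky_viscosity <- function(u, mesh3d, C_smag) {
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  if (C_smag == 0) return(matrix(0, np, nl))
  uc <- reconstruct_cell_velocity(mesh3d, u)
  gx <- cell_gradients(mesh3d, uc$ux)
  gy <- cell_gradients(mesh3d, uc$uy)
  S <- sqrt(2 * gx$gx^2 + 2 * gy$gy^2 + (gx$gy + gy$gx)^2)
  (C_smag * sqrt(mesh3d$mesh2d$area))^2 * S
}

# diffusive divergence of a cell field with per-cell viscosity (units*m3/s)
diffuse_cell_field <- function(C, mesh3d, nu_cell) {
  f <- mesh3d$mesh2d$faces
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  int <- f$right > 0L
  li <- f$left; ri <- pmax(f$right, 1L)
  nu_face <- 0.5 * (nu_cell[li, , drop = FALSE] + nu_cell[ri, , drop = FALSE])
  flux <- -nu_face * mesh3d$face_area * (C[ri, , drop = FALSE] -
                                         C[li, , drop = FALSE]) / f$dist
  flux[!int, ] <- 0
  flux[!mesh3d$face_active] <- 0
  dM <- matrix(0, np, nl)
  for (k in seq_len(nl)) {
    dM[, k] <- -rowsum_vec(mesh3d$fc_sign * flux[mesh3d$fc_face, k],
                           mesh3d$fc_cell, np)
  }
  dM
}

# Explicit momentum tendency F(t) on faces (m/s2), before AB2 combination.
momentum_tendency <- function(state, mesh3d, params, time = 0) {
  f <- mesh3d$mesh2d$faces
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers; nf <- mesh3d$n_face
  u <- state$u
  int <- f$right > 0L
  li <- f$left; ri <- pmax(f$right, 1L)
  tend <- matrix(0, nf, nl)
  V <- pmax(cell_volumes(mesh3d, state$eta), 1e-300)

  uc <- NULL
  need_uc <- params$advect_momentum || any(params$f != 0) ||
    params$C_smag > 0
  if (need_uc) uc <- reconstruct_cell_velocity(mesh3d, u)

  cell_ax <- matrix(0, np, nl)
  cell_ay <- matrix(0, np, nl)

  if (params$advect_momentum) {
    # flux-form upwind advection of the reconstructed components, corrected
    # to advective form so a uniform flow has zero tendency
    bvx <- matrix(uc$ux[li, ], nf, nl)
    bvy <- matrix(uc$uy[li, ], nf, nl)
    one <- matrix(1, np, nl)
    d1 <- horizontal_divergence(one, u, mesh3d, boundary_value = matrix(1, nf, nl))
    dx_ <- horizontal_divergence(uc$ux, u, mesh3d, boundary_value = bvx)
    dy_ <- horizontal_divergence(uc$uy, u, mesh3d, boundary_value = bvy)
    cell_ax <- cell_ax + (dx_ - uc$ux * d1) / V
    cell_ay <- cell_ay + (dy_ - uc$uy * d1) / V
  }

  nu <- state$nu_h
  if (any(nu > 0)) {
    if (is.null(uc)) uc <- reconstruct_cell_velocity(mesh3d, u)
    cell_ax <- cell_ax + diffuse_cell_field(uc$ux, mesh3d, nu) / V
    cell_ay <- cell_ay + diffuse_cell_field(uc$uy, mesh3d, nu) / V
  }

  # project cell accelerations onto interior face normals
  if (any(cell_ax != 0) || any(cell_ay != 0)) {
    axf <- 0.5 * (cell_ax[li, , drop = FALSE] + cell_ax[ri, , drop = FALSE])
    ayf <- 0.5 * (cell_ay[li, , drop = FALSE] + cell_ay[ri, , drop = FALSE])
    tend <- tend + (axf * f$nx + ayf * f$ny)
  }

  # Coriolis: du_n/dt = -f u_t with tangent t = (n_y, -n_x)
  if (any(params$f != 0)) {
    fc <- rep_len(params$f, np)
    utx <- 0.5 * (uc$ux[li, , drop = FALSE] + uc$ux[ri, , drop = FALSE])
    uty <- 0.5 * (uc$uy[li, , drop = FALSE] + uc$uy[ri, , drop = FALSE])
    ffc <- 0.5 * (fc[li] + fc[ri])
    ut <- utx * f$ny - uty * f$nx
    tend <- tend - ffc * ut
  }

  # baroclinic pressure gradient (hydrostatic, layer-centre pressures)
  rhop <- state$rho - params$rho0
  if (any(rhop != 0)) {
    p <- matrix(0, np, nl)
    cum <- numeric(np)
    for (k in seq_len(nl)) {
      hk <- mesh3d$thickness[, k]
      p[, k] <- params$g * (cum + rhop[, k] * hk / 2)
      cum <- cum + rhop[, k] * hk
    }
    dp <- (p[ri, , drop = FALSE] - p[li, , drop = FALSE]) /
      (params$rho0 * f$dist)
    dp[!int, ] <- 0
    tend <- tend - dp
  }

  # vertical viscosity (explicit), wind stress on top, bottom drag
  if (params$nu_v > 0 && nl > 1L) {
    hface <- mesh3d$face_thickness
    for (k in seq_len(nl - 1L)) {
      both <- mesh3d$face_active[, k] & mesh3d$face_active[, k + 1L]
      dzc <- pmax((hface[, k] + hface[, k + 1L]) / 2, 1e-300)
      s <- params$nu_v * (u[, k + 1L] - u[, k]) / dzc * both
      tend[, k] <- tend[, k] + s / pmax(hface[, k], 1e-300)
      tend[, k + 1L] <- tend[, k + 1L] - s / pmax(hface[, k + 1L], 1e-300)
    }
  }
  wind <- params$wind
  if (!is.null(wind)) {
    if (is.function(wind)) wind <- wind(time)
    taun <- wind$taux * f$nx + wind$tauy * f$ny
    tend[, 1] <- tend[, 1] +
      taun / (params$rho0 * pmax(mesh3d$face_thickness[, 1], 1e-300))
  }
  if (params$C_bottom > 0) {
    # quadratic drag on the bottom wet layer of each face column
    fb <- apply(mesh3d$face_active, 1, function(a) {
      w <- which(a); if (length(w)) max(w) else NA_integer_
    })
    ok <- which(!is.na(fb))
    ib <- cbind(ok, fb[ok])
    ub <- u[ib]
    tend[ib] <- tend[ib] - params$C_bottom * abs(ub) * ub /
      pmax(mesh3d$face_thickness[ib], 1e-300)
  }

  tend[!mesh3d$face_active] <- 0
  tend[f$type != "interior", ] <- 0
  tend
}

# cached SPD free-surface matrix: A_i + g theta^2 dt^2 sum_j Lambda_j/delta_j
build_fs_matrix <- function(mesh3d, params, clamped) {
  f <- mesh3d$mesh2d$faces
  np <- mesh3d$n_poly
  int <- which(f$right > 0L)
  Lam <- rowSums(mesh3d$face_area[int, , drop = FALSE])
  li <- f$left[int]; ri <- f$right[int]
  coef <- params$g * params$theta^2 * params$dt^2 * Lam / f$dist[int]
  ii <- c(seq_len(np), li, ri, li, ri)
  jj <- c(seq_len(np), li, ri, ri, li)
  xx <- c(mesh3d$mesh2d$area, coef, coef, -coef, -coef)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(np, np))
  if (length(clamped) > 0) {
    # Dirichlet rows/columns; off-diagonal couplings to clamped cells move
    # to the RHS at solve time
    A[clamped, ] <- 0
    A[, clamped] <- 0
    diag(A)[clamped] <- mesh3d$mesh2d$area[clamped]
  }
  list(A = A, int = int, Lam = Lam, li = li, ri = ri, coef = coef)
}

#' One semi-implicit hydrodynamic step
#'
#' Viscosity update, AB2 momentum tendency, theta-method free-surface solve
#' (PCG), velocity update, optional temperature/salinity transport and EOS
#' update.  Clamped open boundaries: \code{forcings$eta_bc =
#' list(cells=, value=)} prescribes the elevation of boundary cells and
#' \code{forcings$u_bc = list(faces=, value=)} the normal velocity of open
#' faces (values may be functions of time).  \code{forcings$sources} is a
#' list of \code{list(polygon=, Q=)} volume sources (m3/s).
#'
#' @param state a \code{flex_hydro_state}.
#' @param mesh3d a \code{flex_mesh3d}.
#' @param params a \code{flex_hydro_params}.
#' @param forcings list of boundary/forcing specs (see details).
#' @param advect_ts also advect temperature and salinity (explicit upwind)
#'   with the theta-weighted transport velocities.
#' @return updated state; \code{state$diag} carries PCG iterations, Courant
#'   number and the volume budget of the step.
#' @export
step_hydro <- function(state, mesh3d, params, forcings = list(),
                       advect_ts = FALSE) {
  f <- mesh3d$mesh2d$faces
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  t0 <- state$time
  dt <- params$dt; theta <- params$theta; g <- params$g

  if (!any(f$right > 0L)) {
    return(step_hydro_0d(state, mesh3d, params, t0, forcings))
  }

  # dynamic viscosity
  state$nu_h <- matrix(params$nu_h, np, nl) +
    smagorinsky_viscosity(state$u, mesh3d, params$C_smag)

  Fexp <- momentum_tendency(state, mesh3d, params, t0)
  Fab <- ab2_combine(Fexp, state$prev_tend)
  state$prev_tend <- Fexp

  co <- max(abs(state$u) * dt / f$dist)
  if (co > 1) {
    warning(sprintf("momentum CFL exceeded: max Courant %.2f", co))
  }

  eta_bc <- forcings$eta_bc
  clamped <- if (is.null(eta_bc)) integer(0) else eta_bc$cells
  u_bc <- forcings$u_bc

  key <- sprintf("%.12g_%.12g_%s", theta, dt, paste(clamped, collapse = ","))
  if (is.null(state$fs_cache) || !identical(state$fs_cache$key, key)) {
    fs <- build_fs_matrix(mesh3d, params, clamped)
    fs$key <- key
    state$fs_cache <- fs
  }
  fs <- state$fs_cache

  # provisional face velocity G (explicit part + (1-theta) surface gradient)
  G <- state$u + dt * Fab
  deta <- state$eta[pmax(f$right, 1L)] - state$eta[f$left]
  deta[f$right == 0L] <- 0
  G <- G - (1 - theta) * g * dt * outer(deta / f$dist, rep(1, nl))
  G[!mesh3d$face_active] <- 0
  G[f$type != "interior", ] <- 0

  # RHS of the eta system: old volume minus the explicit part of the
  # theta-weighted face fluxes, accumulated into both adjacent cells
  Gbar <- rowSums(mesh3d$face_area * (theta * G + (1 - theta) * state$u))
  rhs <- mesh3d$mesh2d$area * state$eta
  int <- fs$int
  sflux <- dt * Gbar[int]
  acc <- rowsum_vec(c(sflux, -sflux), c(fs$li, fs$ri), np)
  rhs <- rhs - acc

  Q <- numeric(np)
  for (s in forcings$sources %||% list()) {
    qv <- if (is.function(s$Q)) s$Q(t0) else s$Q
    Q[s$polygon] <- Q[s$polygon] + qv
  }
  rhs <- rhs + dt * Q

  # prescribed open-face velocities enter the RHS explicitly
  if (!is.null(u_bc)) {
    ub <- if (is.function(u_bc$value)) u_bc$value(t0 + dt) else u_bc$value
    ub <- rep_len(ub, length(u_bc$faces))
    for (q in seq_along(u_bc$faces)) {
      j <- u_bc$faces[q]
      Abar <- sum(mesh3d$face_area[j, ])
      rhs[f$left[j]] <- rhs[f$left[j]] - dt * Abar * ub[q]
    }
  }

  eta_bc_val <- NULL
  if (length(clamped) > 0) {
    eta_bc_val <- if (is.function(eta_bc$value)) {
      eta_bc$value(t0 + dt)
    } else {
      eta_bc$value
    }
    eta_bc_val <- rep_len(eta_bc_val, length(clamped))
    # move couplings to clamped cells into the RHS
    known <- numeric(np)
    known[clamped] <- eta_bc_val
    coef <- fs$coef
    li <- fs$li; ri <- fs$ri
    # contribution -(-coef)*eta_known for free cells adjacent to clamped ones
    addl <- rowsum_vec(coef * known[ri], li, np)
    addr <- rowsum_vec(coef * known[li], ri, np)
    rhs <- rhs + addl + addr
    rhs[clamped] <- mesh3d$mesh2d$area[clamped] * eta_bc_val
  }

  sol <- pcg_solve(fs$A, rhs, x0 = state$eta, tol = params$pcg_tol,
                   maxiter = params$pcg_maxiter)
  eta_new <- sol$x
  if (length(clamped) > 0) eta_new[clamped] <- eta_bc_val

  # velocity update with the new surface gradient
  u_new <- matrix(0, mesh3d$n_face, nl)
  detan <- eta_new[pmax(f$right, 1L)] - eta_new[f$left]
  upd <- G - theta * g * dt * outer(detan / f$dist, rep(1, nl))
  isint <- f$right > 0L
  u_new[isint, ] <- upd[isint, ]
  u_new[!mesh3d$face_active] <- 0
  if (!is.null(u_bc)) {
    ub <- if (is.function(u_bc$value)) u_bc$value(t0 + dt) else u_bc$value
    u_new[u_bc$faces, ] <- rep_len(ub, length(u_bc$faces))
    u_new[u_bc$faces, ][!mesh3d$face_active[u_bc$faces, ]] <- 0
  }

  # conservative eta recomputation from the theta-weighted fluxes: identical
  # to the PCG solution in exact arithmetic, conserves volume to round-off
  u_trans <- theta * u_new + (1 - theta) * state$u
  fl <- rowSums(mesh3d$face_area * u_trans)
  div <- rowsum_vec(c(fl[int], -fl[int]), c(fs$li, fs$ri), np)
  if (!is.null(u_bc)) {
    for (q in seq_along(u_bc$faces)) {
      j <- u_bc$faces[q]
      div[f$left[j]] <- div[f$left[j]] + fl[j]
    }
  }
  eta_cons <- state$eta - dt * div / mesh3d$mesh2d$area +
    dt * Q / mesh3d$mesh2d$area
  free <- setdiff(seq_len(np), clamped)
  eta_new[free] <- eta_cons[free]

  if (any(!is.finite(eta_new)) || max(abs(eta_new)) > params$eta_limit) {
    stop(sprintf(
      "hydro solver diverged at t=%.1f s: max |eta| = %.3g m (limit %.3g)",
      t0 + dt, max(abs(eta_new)), params$eta_limit))
  }
  if (any(!is.finite(u_new))) {
    bad <- which(!is.finite(u_new), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN velocity at t=%.1f s, face %d layer %d",
                 t0 + dt, bad[1], bad[2]))
  }

  if (advect_ts) {
    V0 <- cell_volumes(mesh3d, state$eta)
    V1 <- cell_volumes(mesh3d, eta_new)
    wA <- diagnose_vertical_flux(mesh3d, u_trans)
    bvT <- forcings$temp_bc %||% 10
    bvS <- forcings$salt_bc %||% 35
    state$temp <- advect_diffuse_explicit(state$temp, u_trans, mesh3d, dt,
                                          boundary_value = bvT, wA = wA,
                                          V_old = V0, V_new = V1)
    state$salt <- advect_diffuse_explicit(state$salt, u_trans, mesh3d, dt,
                                          boundary_value = bvS, wA = wA,
                                          V_old = V0, V_new = V1)
  }
  state$rho <- eos_density(params$eos, state$temp, state$salt)

  state$diag <- list(pcg_iterations = sol$iterations,
                     pcg_residual = sol$residual,
                     courant = co,
                     u_transport = u_trans)
  state$u <- u_new
  state$eta <- eta_new
  state$time <- t0 + dt
  state
}

# 0D degenerate mode: cell-centred velocity under Coriolis / wind / drag;
# with no faces the free surface responds to volume sources only.
step_hydro_0d <- function(state, mesh3d, params, t0, forcings = list()) {
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  for (s in forcings$sources %||% list()) {
    qv <- if (is.function(s$Q)) s$Q(t0) else s$Q
    state$eta[s$polygon] <- state$eta[s$polygon] +
      params$dt * qv / mesh3d$mesh2d$area[s$polygon]
  }
  if (is.null(state$uc)) {
    state$uc <- list(ux = matrix(0, np, nl), uy = matrix(0, np, nl))
  }
  ux <- state$uc$ux; uy <- state$uc$uy
  fc <- rep_len(params$f, np)
  ax <- fc * uy
  ay <- -fc * ux
  wind <- params$wind
  if (!is.null(wind)) {
    if (is.function(wind)) wind <- wind(t0)
    h1 <- pmax(mesh3d$thickness[, 1], 1e-300)
    ax[, 1] <- ax[, 1] + wind$taux / (params$rho0 * h1)
    ay[, 1] <- ay[, 1] + wind$tauy / (params$rho0 * h1)
  }
  if (params$C_bottom > 0) {
    ib <- cbind(seq_len(np), mesh3d$bottom_layer)
    sp <- sqrt(ux[ib]^2 + uy[ib]^2)
    hb <- pmax(mesh3d$thickness[ib], 1e-300)
    ax[ib] <- ax[ib] - params$C_bottom * sp * ux[ib] / hb
    ay[ib] <- ay[ib] - params$C_bottom * sp * uy[ib] / hb
  }
  Fc <- list(ax = ax, ay = ay)
  Fab <- if (is.null(state$prev_tend0)) {
    Fc
  } else {
    list(ax = 1.5 * Fc$ax - 0.5 * state$prev_tend0$ax,
         ay = 1.5 * Fc$ay - 0.5 * state$prev_tend0$ay)
  }
  state$prev_tend0 <- Fc
  state$uc$ux <- ux + params$dt * Fab$ax
  state$uc$uy <- uy + params$dt * Fab$ay
  state$time <- t0 + params$dt
  state
}

#' Basin-integrated energy of the hydro state
#'
#' Potential energy of the displaced free surface plus kinetic energy of the
#' cell-centred velocity reconstruction (J).
#'
#' @inheritParams step_hydro
#' @export
hydro_energy <- function(state, mesh3d, params) {
  A <- mesh3d$mesh2d$area
  pe <- 0.5 * params$rho0 * params$g * sum(A * state$eta^2)
  uc <- reconstruct_cell_velocity(mesh3d, state$u)
  ke <- 0.5 * params$rho0 *
    sum(cell_volumes(mesh3d, state$eta) * (uc$ux^2 + uc$uy^2))
  pe + ke
}

#' Total water volume
#' @inheritParams hydro_energy
#' @export
hydro_volume <- function(state, mesh3d) {
  sum(cell_volumes(mesh3d, state$eta)[mesh3d$active])
}

#' Quadratic-drag bed shear stress per polygon (N/m2)
#' @inheritParams hydro_energy
#' @export
bottom_stress <- function(state, mesh3d, params) {
  uc <- reconstruct_cell_velocity(mesh3d, state$u)
  ib <- cbind(seq_len(mesh3d$n_poly), mesh3d$bottom_layer)
  sp2 <- uc$ux[ib]^2 + uc$uy[ib]^2
  params$rho0 * params$C_bottom * sp2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
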