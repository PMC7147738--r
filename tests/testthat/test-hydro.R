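test_that("a resting basin stays exactly at rest", {
  m <- rect_mesh(6, 3, 100, 10, interfaces = c(0, 5, 10))
  p <- hydro_params(dt = 10)
  st <- hydro_state(m, p)
  st2 <- step_hydro(st, m, p)
  expect_equal(st2$eta, st$eta)
  expect_equal(max(abs(st2$u)), 0)
})

test_that("Smagorinsky viscosity vanishes for uniform flow, is zero at
           C_smag = 0, and recovers (C L)^2 gamma for pure shear", {
  m <- rect_mesh(10, 10, 100, 10)
  f <- m$mesh2d$faces
  # sample the analytic fields on every face, walls included, so the
  # reconstruction sees the pure flow rather than wall effects
  u <- matrix(0.3 * f$nx + 0.1 * f$ny, m$n_face, 1)
  expect_equal(max(smagorinsky_viscosity(u, m, 0.2)), 0)
  expect_equal(max(smagorinsky_viscosity(u, m, 0)), 0)

  # u = (gamma * y, 0): face-normal samples of a linear shear
  gamma <- 1e-3
  ush <- matrix(gamma * f$cy * f$nx, m$n_face, 1)
  nu <- smagorinsky_viscosity(ush, m, 0.2)
  core <- locate_element(m, 450, 450)
  expect_equal(nu[core, 1], (0.2 * 100)^2 * gamma, tolerance = 1e-6)
})

test_that("a single step of uniform wind from rest accelerates the
           surface layer by dt*tau/(rho0*h)", {
  m <- rect_mesh(2, 1, 100, 10, interfaces = c(0, 2, 10))
  p <- hydro_params(dt = 1, wind = list(taux = 0.1, tauy = 0))
  st <- hydro_state(m, p)
  st <- step_hydro(st, m, p)
  j <- which(m$mesh2d$faces$type == "interior")
  expect_equal(st$u[j, 1], 1 * 0.1 / (1025 * 2), tolerance = 1e-2)
  expect_lt(abs(st$u[j, 2]), 1e-6)
})

test_that("the free seiche of a closed basin has period 2L/sqrt(gH)
           within 2% and conserves volume", {
  m <- seiche_mesh()
  p <- hydro_params(dt = 5, theta = 0.5)
  st <- seiche_state(m, p)
  v0 <- hydro_volume(st, m)
  eta1 <- numeric(1500)
  for (i in seq_len(1500)) {
    st <- step_hydro(st, m, p)
    eta1[i] <- st$eta[1]
  }
  expect_equal(hydro_volume(st, m), v0, tolerance = 1e-12)
  Tth <- 2 * 5000 / sqrt(9.81 * 10)
  expect_equal(period_from_series(eta1, 5), Tth, tolerance = 0.02)
})

test_that("theta = 1 with a large time step is stable and strongly
           damped", {
  m <- seiche_mesh()
  p <- hydro_params(dt = 100, theta = 1)
  st <- seiche_state(m, p)
  e0 <- hydro_energy(st, m, p)
  for (i in 1:200) st <- step_hydro(st, m, p)
  e1 <- hydro_energy(st, m, p)
  expect_true(is.finite(e1))
  expect_lt(e1, 0.1 * e0)
})

test_that("energy never grows beyond its initial value without forcing
           for theta >= 0.5, and theta > 0.5 dissipates monotonically
           across periods", {
  m <- seiche_mesh()
  for (th in c(0.5, 0.75)) {
    p <- hydro_params(dt = 5, theta = th)
    st <- seiche_state(m, p)
    e0 <- hydro_energy(st, m, p)
    period_steps <- 202            # ~ one seiche period at dt = 5
    e_at_period <- numeric(4)
    emax <- -Inf
    for (pp in 1:4) {
      for (i in seq_len(period_steps)) {
        st <- step_hydro(st, m, p)
        emax <- max(emax, hydro_energy(st, m, p))
      }
      e_at_period[pp] <- hydro_energy(st, m, p)
    }
    expect_lt((emax - e0) / e0, 1e-9)
    if (th > 0.5) expect_true(all(diff(e_at_period) < 0))
  }
})

test_that("mirror-symmetric initial conditions stay mirror-symmetric", {
  m <- seiche_mesh()
  p <- hydro_params(dt = 5, theta = 0.5)
  st <- seiche_state(m, p)          # cos profile: symmetric under x -> L-x
  for (i in 1:200) st <- step_hydro(st, m, p)
  expect_equal(st$eta, -rev(st$eta), tolerance = 1e-12)
})

test_that("the 0D inertial oscillation has period 2*pi/f within 1%", {
  m <- rect_mesh(1, 1, 100, 10)
  fcor <- 1e-4
  p <- hydro_params(dt = 60, f = fcor)
  st <- hydro_state(m, p)
  st$uc <- list(ux = matrix(0.1, 1, 1), uy = matrix(0, 1, 1))
  prev <- 0; tot <- 0
  n <- 2000
  for (i in seq_len(n)) {
    st <- step_hydro(st, m, p)
    a <- atan2(st$uc$uy[1, 1], st$uc$ux[1, 1])
    d <- a - prev
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    tot <- tot + d; prev <- a
  }
  period <- 2 * pi / (abs(tot) / n) * 60
  expect_equal(period, 2 * pi / fcor, tolerance = 0.01)
  # speed is preserved by the rotation (AB2 amplitude error is tiny)
  expect_equal(sqrt(st$uc$ux[1, 1]^2 + st$uc$uy[1, 1]^2), 0.1,
               tolerance = 1e-3)
})

test_that("a 0D cell's surface responds only to volume sources", {
  m <- rect_mesh(1, 1, 100, 10)
  p <- hydro_params(dt = 10, wind = list(taux = 1, tauy = 0))
  st <- hydro_state(m, p)
  st <- step_hydro(st, m, p, forcings = list(
    sources = list(list(polygon = 1, Q = 5))))
  expect_equal(st$eta[1], 10 * 5 / 1e4)
})

test_that("clamped open-boundary throughflow reaches a steady state with a
           flat interior surface", {
  m <- rect_mesh(20, 1, 100, 10, open = c("west", "east"))
  f <- m$mesh2d$faces
  open_faces <- which(f$type == "open")
  # fully implicit time stepping damps the start-up transient (there is no
  # other dissipation in the configuration), leaving the steady throughflow
  p <- hydro_params(dt = 20, theta = 1)
  st <- hydro_state(m, p)
  forc <- list(u_bc = list(faces = open_faces,
                           value = 0.1 * f$nx[open_faces]))
  for (i in 1:800) st <- step_hydro(st, m, p, forcings = forc)
  j <- which(f$type == "interior")
  expect_equal(unname(st$u[j, 1]), rep(0.1, length(j)) * sign(f$nx[j]),
               tolerance = 1e-6)
  expect_lt(diff(range(st$eta)), 1e-6)
})

test_that("a uniform tracer stays uniform under the velocities and volume
           changes produced by the free-surface solver", {
  m <- seiche_mesh()
  p <- hydro_params(dt = 5, theta = 0.5)
  st <- seiche_state(m, p)
  C <- matrix(1, m$n_poly, 1)
  for (i in 1:300) {
    eta_prev <- st$eta
    st <- step_hydro(st, m, p)
    C <- advect_diffuse_explicit(C, st$diag$u_transport, m, 5,
                                 V_old = cell_volumes(m, eta_prev),
                                 V_new = cell_volumes(m, st$eta))
  }
  expect_lt(max(abs(C - 1)), 1e-12)
})

test_that("the nonlinear terms leave a uniform advected flow unchanged
           (momentum advection consistency)", {
  m <- rect_mesh(10, 3, 100, 10)
  p <- hydro_params(dt = 5, advect_momentum = TRUE)
  st <- hydro_state(m, p)
  f <- m$mesh2d$faces
  st$u <- matrix(0.2 * f$nx, m$n_face, 1)   # uniform flow on every face
  tend <- flexmarine:::momentum_tendency(st, m, p)
  expect_lt(max(abs(tend)), 1e-14)
})
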