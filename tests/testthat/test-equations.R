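logistic_system <- function() {
  equation_system(
    constants = list(r = 0.1, K = 1),
    variables = list(P = list(domain = "pelagic", initial = 0.01)),
    equations = list(P = "r*P*(1-P/K)"))
}

test_that("0D logistic growth matches the closed form within 0.1%", {
  sys <- logistic_system()
  f <- init_fields(sys)
  dt <- 0.01                           # days; r in 1/d
  for (i in seq_len(10000)) f <- evaluate_timestep(sys, f, dt = dt)
  exact <- 1 / (1 + (1 / 0.01 - 1) * exp(-0.1 * 100))
  expect_equal(f$P[1, 1], exact, tolerance = 1e-3)
})

test_that("an all-zero RHS leaves fields exactly unchanged", {
  sys <- equation_system(
    variables = list(A = list(initial = 0.37)),
    equations = list(A = "0*A"))
  f <- init_fields(sys)
  f2 <- evaluate_timestep(sys, f, dt = 5)
  expect_identical(f2$A, f$A)
})

test_that("the linear oscillator reproduces the exact forward-Euler
           recurrence to 1e-12", {
  sys <- equation_system(
    variables = list(A = list(initial = 1), B = list(initial = 0)),
    equations = list(A = "B", B = "-A"))
  f <- init_fields(sys)
  dt <- 0.05
  ab <- c(1, 0)
  M <- rbind(c(1, dt), c(-dt, 1))      # scalar Euler oracle
  for (i in 1:400) {
    f <- evaluate_timestep(sys, f, dt = dt)
    ab <- as.numeric(M %*% ab)
  }
  expect_equal(f$A[1, 1], ab[1], tolerance = 1e-12)
  expect_equal(f$B[1, 1], ab[2], tolerance = 1e-12)
  # energy grows per Euler theory: (1 + dt^2)^(n/2)
  expect_equal(f$A[1, 1]^2 + f$B[1, 1]^2, (1 + dt^2)^400,
               tolerance = 1e-10)
})

test_that("rk4 integration is far more accurate than euler on the
           oscillator", {
  sys <- equation_system(
    variables = list(A = list(initial = 1), B = list(initial = 0)),
    equations = list(A = "B", B = "-A"))
  fe <- init_fields(sys); f4 <- init_fields(sys)
  for (i in 1:200) {
    fe <- evaluate_timestep(sys, fe, dt = 0.05)
    f4 <- evaluate_timestep(sys, f4, dt = 0.05, integrator = "rk4")
  }
  expect_lt(abs(f4$A[1, 1] - cos(10)), 1e-6)
  expect_gt(abs(fe$A[1, 1] - cos(10)), 1e-3)
})

settling_system <- function(ws = 0.001) {
  equation_system(variables = list(
    C = list(domain = "pelagic", initial = 1, settling = ws,
             settle_into = "B"),
    B = list(domain = "benthic", initial = 0)))
}

test_that("settling moves >=95% of a uniform column into the benthic pool
           after H/w_s and conserves the summed inventory", {
  m <- rect_mesh(1, 1, 10, depth = 10, interfaces = 0:10)
  sys <- settling_system(0.001)
  f <- init_fields(sys, m)
  inv0 <- sum(system_inventory(sys, f, m))
  dt <- 500
  n <- ceiling(10 / 0.001 / dt)        # H / w_s
  for (i in seq_len(n)) f <- apply_settling(sys, f, m, dt = dt)
  inv <- system_inventory(sys, f, m)
  expect_equal(sum(inv), inv0, tolerance = 1e-12)
  expect_gt(inv[["B"]] / inv0, 0.95)
})

test_that("zero settling velocity changes nothing", {
  m <- rect_mesh(1, 1, 10, depth = 10, interfaces = 0:10)
  sys <- settling_system(0)
  f <- init_fields(sys, m)
  f2 <- apply_settling(sys, f, m, dt = 1000)
  expect_identical(f2$C, f$C)
  expect_identical(f2$B, f$B)
})

test_that("resuspension: below-critical stress is inert; the one-step
           erosion equals E*(tau/tau_crit - 1)*dt; settling-resuspension
           equilibrium balances fluxes", {
  m <- rect_mesh(1, 1, 10, depth = 2, interfaces = c(0, 2))
  sys <- equation_system(variables = list(
    C = list(domain = "pelagic", initial = 0, settling = 1e-4,
             settle_into = "B"),
    B = list(domain = "benthic", initial = 50, resuspend_into = "C",
             tau_crit = 0.1, erosion_rate = 1e-3)))
  f <- init_fields(sys, m)
  f1 <- resuspend(sys, f, bottom_stress = 0.05, m, dt = 100)
  expect_identical(f1$B, f$B)

  f2 <- resuspend(sys, f, bottom_stress = 0.2, m, dt = 100)
  expect_equal(f$B[1, 1] - f2$B[1, 1], 1e-3 * (0.2 / 0.1 - 1) * 100)
  expect_equal(sum(system_inventory(sys, f2, m)),
               sum(system_inventory(sys, f, m)), tolerance = 1e-12)

  # drive to equilibrium: w_s c* = E (tau/tau_crit - 1)
  dt <- 200
  for (i in 1:2000) {
    f <- apply_settling(sys, f, m, dt = dt)
    f <- resuspend(sys, f, bottom_stress = 0.2, m, dt = dt)
  }
  c_star <- 1e-3 * (0.2 / 0.1 - 1) / 1e-4
  expect_equal(f$C[1, 1], c_star, tolerance = 1e-3)
})

test_that("interface exchange is inert at equal effective concentrations
           or zero coefficient, and relaxes a two-box contrast at rate
           k_ex (1/h_p + 1/h_b)", {
  m <- rect_mesh(1, 1, 1, depth = 2, interfaces = c(0, 2))
  mk <- function(k_ex) equation_system(
    variables = list(C = list(domain = "pelagic", initial = 1),
                     B = list(domain = "benthic", initial = 0)),
    exchanges = list(list(pelagic = "C", benthic = "B",
                          k_ex = k_ex, h_b = 0.5)))
  sys0 <- mk(0)
  f <- init_fields(sys0, m)
  expect_identical(interface_exchange(sys0, f, m, dt = 100)$C, f$C)

  sys <- mk(1e-4)
  feq <- list(C = matrix(2, 1, 1), B = matrix(1, 1, 1))  # B/h_b = 2 = C
  f2 <- interface_exchange(sys, feq, m, dt = 100)
  expect_equal(f2$C[1, 1], 2)
  expect_equal(f2$B[1, 1], 1)

  f <- init_fields(sys, m)
  dt <- 10
  d0 <- f$C[1, 1] - f$B[1, 1] / 0.5
  inv0 <- sum(system_inventory(sys, f, m))
  for (i in 1:500) f <- interface_exchange(sys, f, m, dt = dt)
  d1 <- f$C[1, 1] - f$B[1, 1] / 0.5
  rate <- 1e-4 * (1 / 2 + 1 / 0.5)
  expect_equal(-log(d1 / d0) / (500 * dt), rate, tolerance = 5e-3)
  expect_equal(sum(system_inventory(sys, f, m)), inv0, tolerance = 1e-12)
})

test_that("cell-local equations give identical trajectories in 0D and in
           a quiescent 3D run", {
  sys <- logistic_system()
  f0 <- init_fields(sys)
  m <- rect_mesh(3, 2, 100, depth = 6, interfaces = c(0, 2, 4, 6))
  f3 <- init_fields(sys, m)
  for (i in 1:200) {
    f0 <- evaluate_timestep(sys, f0, dt = 0.05)
    f3 <- evaluate_timestep(sys, f3, dt = 0.05)
  }
  expect_equal(max(abs(f3$P[m$active] - f0$P[1, 1])), 0)
})

test_that("a closed transfer chain conserves its total over 1e4 steps", {
  sys <- equation_system(
    constants = list(k1 = 0.01, k2 = 0.003),
    variables = list(A = list(initial = 1), B = list(initial = 0.2),
                     C = list(initial = 0)),
    equations = list(A = "-k1*A + k2*C", B = "k1*A - k1*B",
                     C = "k1*B - k2*C"))
  f <- init_fields(sys)
  tot0 <- f$A + f$B + f$C
  for (i in seq_len(10000)) f <- evaluate_timestep(sys, f, dt = 0.1)
  expect_equal(f$A + f$B + f$C, tot0, tolerance = 1e-10)
})

test_that("the stiffness diagnostic warns on large relative steps", {
  sys <- equation_system(
    constants = list(k = 10),
    variables = list(A = list(initial = 1)),
    equations = list(A = "-k*A"))
  f <- init_fields(sys)
  expect_warning(evaluate_timestep(sys, f, dt = 0.1, warn_stiff = TRUE),
                 "stiff")
})

test_that("the XML equation-system block parses and runs", {
  xml <- '
  <equationsystem>
    <constants><constant name="r" value="0.1"/>
               <constant name="K" value="1"/></constants>
    <variables>
      <variable name="P" initial="0.01" advected="false"
                nonnegative="true"/>
    </variables>
    <equations><equation variable="P" expr="r*P*(1-P/K)"/></equations>
  </equationsystem>'
  sys <- parse_equation_system(xml)
  f <- init_fields(sys)
  for (i in 1:1000) f <- evaluate_timestep(sys, f, dt = 0.1)
  exact <- 1 / (1 + 99 * exp(-0.1 * 100))
  expect_equal(f$P[1, 1], exact, tolerance = 1e-2)
  expect_error(parse_equation_system(
    '<equationsystem><variables>
       <variable name="N"/></variables>
     <equations><equation variable="N" expr="-Z"/></equations>
     </equationsystem>'), "Z")
})

test_that("nonnegative clipping is accounted as a mass error", {
  sys <- equation_system(
    constants = list(k = 1),
    variables = list(A = list(initial = 0.01, nonnegative = TRUE)),
    equations = list(A = "-k"))
  f <- init_fields(sys)
  f <- evaluate_timestep(sys, f, dt = 1)
  expect_equal(f$A[1, 1], 0)
  expect_equal(attr(f, "clip_error")[["A"]], 0.99)
})
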