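# solid-body rotation sampled onto the faces of a fine rectangular mesh
rotation_field <- function(mesh, cx, cy, Om) {
  f <- mesh$mesh2d$faces
  u <- matrix(-Om * (f$cy - cy) * f$nx + Om * (f$cx - cx) * f$ny,
              mesh$n_face, mesh$n_layers)
  u[f$type != "interior", ] <- 0
  u
}

test_that("velocity interpolation is exact for uniform flow, recovers
           solid-body speed within 2%, and collapses to the cell value at
           a Voronoi point", {
  m <- rect_mesh(40, 40, 50, 10)
  u <- uniform_u(m, 0.2, -0.1)
  iv <- interpolate_velocity(m, u, c(333, 1017, 1500), c(512, 1693, 980))
  expect_equal(iv$vx, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(iv$vy, rep(-0.1, 3), tolerance = 1e-12)

  Om <- 1e-3
  ur <- rotation_field(m, 1000, 1000, Om)
  iv2 <- interpolate_velocity(m, ur, 1000 + 500, 1000)
  expect_equal(iv2$vy, Om * 500, tolerance = 0.02)
  expect_equal(iv2$vx, 0, tolerance = 1e-6 * Om * 500)

  i <- locate_element(m, 775, 1225)
  vp <- m$mesh2d$voronoi[i, ]
  uc <- flexmarine:::reconstruct_cell_velocity(m, ur)
  iv3 <- interpolate_velocity(m, ur, vp[1], vp[2])
  expect_equal(iv3$vx, uc$ux[i, 1], tolerance = 1e-12)
  expect_equal(iv3$vy, uc$uy[i, 1], tolerance = 1e-12)
})

test_that("agents at rest stay put; a full rotation returns within 1% of
           the orbit radius; all-solid boundaries conserve the count", {
  m <- rect_mesh(40, 40, 50, 10)
  pop0 <- agent_population(c(700, 1300), c(900, 1100), z = 5)
  popz <- step_agents(pop0, m, NULL, dt = 100)
  expect_equal(popz$x, pop0$x)
  expect_equal(popz$y, pop0$y)

  Om <- 1e-3
  u <- rotation_field(m, 1000, 1000, Om)
  pop <- agent_population(1500, 1000, z = 5)
  dt <- 20
  n <- round(2 * pi / Om / dt)
  for (i in seq_len(n)) pop <- step_agents(pop, m, u, dt)
  ret <- sqrt((pop$x - 1500)^2 + (pop$y - 1000)^2)
  expect_lt(ret / 500, 0.01)
  expect_equal(sum(pop$active), 1L)
})

test_that("pure diffusion: mean-square displacement grows linearly at 4K
           and directions are isotropic (chi-squared test)", {
  set.seed(99)
  m <- rect_mesh(40, 40, 100, 10)
  n_ag <- 10000
  pop <- agent_population(rep(2000, n_ag), rep(2000, n_ag), z = 5)
  K <- 1; dt <- 30; nstep <- 20
  msd <- numeric(nstep)
  for (i in seq_len(nstep)) {
    pop <- step_agents(pop, m, NULL, dt, diffusivity_h = K)
    msd[i] <- mean((pop$x - 2000)^2 + (pop$y - 2000)^2)
  }
  slope <- coef(lm(msd ~ I(dt * seq_len(nstep))))[[2]]
  expect_equal(slope, 4 * K, tolerance = 0.05)

  ang <- atan2(pop$y - 2000, pop$x - 2000)
  counts <- table(cut(ang, breaks = seq(-pi, pi, length.out = 9)))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("an agent pushed through a solid wall is returned to the last
           wet element's centre at unchanged depth", {
  m <- rect_mesh(5, 5, 100, 10)
  # strong westward flow slams the agent into the west wall
  u <- uniform_u(m, -5)
  pop <- agent_population(60, 250, z = 7.3)
  pop <- step_agents(pop, m, u, dt = 100)
  i <- locate_element(m, 60, 250)
  expect_equal(pop$x, m$mesh2d$voronoi[i, 1])
  expect_equal(pop$y, m$mesh2d$voronoi[i, 2])
  expect_equal(pop$z, 7.3)
  expect_true(pop$active)
})

test_that("open boundaries as sinks deactivate exactly the crossing
           agents; as walls they conserve the count", {
  m <- rect_mesh(5, 1, 100, 10, open = "east")
  u <- uniform_u(m, 0.5)
  f <- m$mesh2d$faces
  u[f$type == "open", ] <- 0.5 * f$nx[f$type == "open"]
  pop <- agent_population(c(460, 260, 60), rep(50, 3), z = 5)
  pop <- step_agents(pop, m, u, dt = 100, boundary = "sink")
  expect_equal(sum(pop$active), 2L)     # only the cell at the open end left
  pop2 <- agent_population(c(460, 260, 60), rep(50, 3), z = 5)
  for (i in 1:10) pop2 <- step_agents(pop2, m, u, dt = 100,
                                      boundary = "solid")
  expect_equal(sum(pop2$active), 3L)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- rect_mesh(10, 10, 100, 10)
  u <- rotation_field(m, 500, 500, 5e-4)
  run <- function() {
    set.seed(1729)
    pop <- agent_population(runif(50, 100, 900), runif(50, 100, 900), z = 5)
    for (i in 1:20) pop <- step_agents(pop, m, u, 60, diffusivity_h = 0.5)
    pop
  }
  a <- run(); b <- run()
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$z, b$z)
})

test_that("vertical random walk in a closed basin stays well mixed
           (Kolmogorov-Smirnov test against uniform)", {
  set.seed(21)
  m <- rect_mesh(3, 3, 100, 10)
  n_ag <- 2000
  pop <- agent_population(runif(n_ag, 50, 250), runif(n_ag, 50, 250),
                          z = runif(n_ag, 0, 10))
  for (i in 1:60) {
    pop <- step_agents(pop, m, NULL, dt = 100, diffusivity_v = 1e-3)
  }
  ks <- suppressWarnings(stats::ks.test(pop$z, "punif", 0, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("an agent trait equation reproduces the identical 0D pelagic
           trajectory (shared DSL engine)", {
  sys <- equation_system(
    constants = list(r = 0.1, K = 1),
    variables = list(P = list(domain = "pelagic", initial = 0.01)),
    equations = list(P = "r*P*(1-P/K)"))
  m <- rect_mesh(3, 3, 100, 10)
  pop <- agent_population(150, 150, z = 5, traits = list(P = 0.01))
  f0 <- init_fields(sys)
  for (i in 1:500) {
    pop <- step_agents(pop, m, NULL, dt = 0.1, system = sys)
    f0 <- evaluate_timestep(sys, f0, dt = 0.1)
  }
  expect_equal(pop$traits$P, f0$P[1, 1], tolerance = 1e-14)
})

test_that("connectivity: identity under no flow, full transfer under a
           constructed drift, rows always sum to 1 over regions + lost", {
  m <- rect_mesh(10, 2, 100, 10)
  regions <- rep(NA_integer_, m$n_poly)
  regions[m$mesh2d$voronoi[, 1] < 300] <- 1L
  regions[m$mesh2d$voronoi[, 1] > 700] <- 2L

  pop <- agent_population(c(150, 150, 850), c(50, 150, 150),
                          region = c(1L, 1L, 2L))
  P0 <- downstream_connectivity(pop, m, regions)
  expect_equal(unname(P0[, c("1", "2")]), diag(2))
  expect_equal(unname(rowSums(P0)), c(1, 1))

  # uniform eastward drift carries region-1 agents into region 2
  u <- uniform_u(m, 0.5)
  pop2 <- agent_population(rep(150, 10), seq(15, 185, length.out = 10),
                           region = 1L)
  for (i in 1:16) pop2 <- step_agents(pop2, m, u, dt = 100)
  P1 <- downstream_connectivity(pop2, m, regions)
  expect_equal(unname(P1[1, "2"]), 1)

  expect_warning(
    P2 <- downstream_connectivity(pop, m, regions,
                                  release_regions = c(1L, 2L, 9L)),
    "released no agents")
  expect_true(all(is.nan(P2["9", ])))
})

test_that("two-region symmetric diffusion yields a symmetric connectivity
           matrix within 3 binomial standard errors", {
  set.seed(2024)
  m <- rect_mesh(8, 4, 100, 10)
  regions <- rep(NA_integer_, m$n_poly)
  regions[m$mesh2d$voronoi[, 1] < 400] <- 1L
  regions[m$mesh2d$voronoi[, 1] > 400] <- 2L
  n_side <- 3000
  pop <- agent_population(
    c(runif(n_side, 0, 400), runif(n_side, 400, 800)),
    runif(2 * n_side, 0, 400),
    region = rep(c(1L, 2L), each = n_side))
  for (i in 1:30) pop <- step_agents(pop, m, NULL, 100, diffusivity_h = 5)
  P <- downstream_connectivity(pop, m, regions)
  p12 <- P["1", "2"]; p21 <- P["2", "1"]
  se <- sqrt(p12 * (1 - p12) / n_side + p21 * (1 - p21) / n_side)
  expect_lt(abs(p12 - p21), 3 * se + 1e-9)
})
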