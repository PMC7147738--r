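# Shared test fixtures, all built in code.

rect_mesh <- function(nx, ny, dx = 100, depth = 10, interfaces = NULL,
                      open = character(0)) {
  generate_fixture_mesh("rect", nx, ny, dx, depth = depth,
                        interfaces = interfaces, open_sides = open)
}

hex_mesh <- function(rings = 2, dx = 100, depth = 5) {
  generate_fixture_mesh("hex", rings, dx = dx, depth = depth)
}

# spatially uniform eastward face-normal velocity field
uniform_u <- function(mesh, vx, vy = 0) {
  f <- mesh$mesh2d$faces
  u <- matrix(vx * f$nx + vy * f$ny, mesh$n_face, mesh$n_layers)
  u[f$type == "solid", ] <- 0
  u[!mesh$face_active] <- 0
  u
}

# exactly divergence-free discrete field from a node streamfunction:
# u_face = (psi[n2] - psi[n1]) / face_length telescopes to zero divergence
# around every polygon (flat bathymetry, full layers).  psi is forced to
# zero on boundary nodes so the closed walls carry no flux and boundary
# cells stay divergence free too.
streamfunction_u <- function(mesh, psi) {
  m2 <- mesh$mesh2d
  psi[m2$boundary_mark != "interior"] <- 0
  f <- m2$faces
  u <- matrix((psi[f$n2] - psi[f$n1]) / f$length, mesh$n_face,
              mesh$n_layers)
  u[f$type != "interior", ] <- 0
  u
}

# seiche basin used by several hydro tests: 50 x 1 cells, 100 m, 10 m deep
seiche_mesh <- function() rect_mesh(50, 1, 100, 10)

seiche_state <- function(mesh, params, amplitude = 0.01) {
  st <- hydro_state(mesh, params)
  st$eta <- amplitude * cos(pi * mesh$mesh2d$voronoi[, 1] / 5000)
  st
}

# estimate the oscillation period of a series from its sign changes
period_from_series <- function(x, dt) {
  s <- sign(x)
  cross <- which(diff(s) != 0 & s[-1] != 0)
  2 * mean(diff(cross)) * dt
}
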