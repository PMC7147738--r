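# ---------------------------------------------------------------------------
# Self-contained runnable fixture setups.  Each recipe writes a complete
# setup directory (setup.xml + forcing/field text files) that runs in well
# under a minute on one CPU, and doubles as a documented example of the
# setup schema.
# ---------------------------------------------------------------------------

#' Generate a complete runnable fixture setup
#'
#' Recipes:
#' \describe{
#'   \item{box_npzd}{0D nutrient-phytoplankton box model (DSL demo).}
#'   \item{seiche}{closed 50x1 basin, initial surface tilt, free seiche.}
#'   \item{channel}{open channel with a prescribed current and a clamped
#'     inflow tracer front.}
#'   \item{gyre_abm}{closed basin with a prescribed solid-body gyre, agent
#'     releases in 3 angular regions and a connectivity census.}
#'   \item{farm_depletion}{rectangular 1500 x 1050 m domain (50 m cells)
#'     with a mid-domain farm block filtering a boundary-supplied food
#'     tracer out of the passing current.}
#'   \item{sediment_plume}{point release of two grain-size fractions
#'     (coarse and fine, Stokes settling velocities) in a uniform current,
#'     depositing to the seabed.}
#' }
#'
#' @param recipe one of the names above.
#' @param dir output directory (created).
#' @return path to the written \code{setup.xml}.
#' @export
generate_fixtures <- function(recipe = c("box_npzd", "seiche", "channel",
                                         "gyre_abm", "farm_depletion",
                                         "sediment_plume"),
                              dir = tempfile("fixture_")) {
  recipe <- match.arg(recipe)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "setup.xml")
  w <- function(...) writeLines(c(...), path)

  if (recipe == "box_npzd") {
    w('<flexmarine>',
      '  <simulation dt="3600" n_steps="2400" seed="1"/>',
      '  <mesh kind="rect" nx="1" ny="1" dx="10" depth="10" interfaces="0,10"/>',
      '  <equationsystem>',
      '    <constants>',
      '      <constant name="mu" value="1.1574e-5"/>',   # 1.0 / d
      '      <constant name="kN" value="0.5"/>',
      '      <constant name="mort" value="1.1574e-6"/>', # 0.1 / d
      '    </constants>',
      '    <auxiliaries>',
      '      <aux name="uptake" expr="mu*P*N/(N+kN)"/>',
      '    </auxiliaries>',
      '    <variables>',
      '      <variable name="N" initial="8" nonnegative="true" advected="false"/>',
      '      <variable name="P" initial="0.1" nonnegative="true" advected="false"/>',
      '    </variables>',
      '    <equations>',
      '      <equation variable="N" expr="-uptake + mort*P"/>',
      '      <equation variable="P" expr="uptake - mort*P"/>',
      '    </equations>',
      '  </equationsystem>',
      '  <output every_steps="24"/>',
      '</flexmarine>')
  } else if (recipe == "seiche") {
    m <- generate_fixture_mesh("rect", 50, 1, 100, depth = 10)
    eta0 <- 0.01 * cos(pi * m$mesh2d$voronoi[, 1] / 5000)
    write_field_text(eta0, file.path(dir, "eta0.txt"))
    w('<flexmarine>',
      '  <simulation dt="5" n_steps="1200" seed="1"/>',
      '  <mesh kind="rect" nx="50" ny="1" dx="100" depth="10" interfaces="0,10"/>',
      '  <hydro theta="0.5" eta0_file="eta0.txt"/>',
      '  <section name="mid" polyline="2500,-10;2500,110"/>',
      '  <output every_steps="1"/>',
      '</flexmarine>')
  } else if (recipe == "channel") {
    write_series(data.frame(time = c(0, 1e7), speed = 0.05,
                            direction = 90), file.path(dir, "profile.csv"))
    w('<flexmarine>',
      '  <simulation dt="500" n_steps="400" seed="1"/>',
      '  <mesh kind="rect" nx="30" ny="4" dx="100" depth="5" interfaces="0,5" open="west,east"/>',
      '  <offline profile_file="profile.csv" K_h="0.1"/>',
      '  <equationsystem>',
      '    <variables>',
      '      <variable name="trc" initial="0" boundary="1" nonnegative="true"/>',
      '    </variables>',
      '  </equationsystem>',
      '  <output every_steps="40"/>',
      '</flexmarine>')
  } else if (recipe == "gyre_abm") {
    m <- generate_fixture_mesh("rect", 20, 20, 100, depth = 10)
    f <- m$mesh2d$faces
    cx <- 1000; cy <- 1000; Om <- 1e-3
    u <- matrix(-Om * (f$cy - cy) * f$nx + Om * (f$cx - cx) * f$ny,
                m$n_face, m$n_layers)
    u[f$type != "interior", ] <- 0
    write_offline_u(offline_series(c(0, 1e7), u = list(u, u)),
                    file.path(dir, "gyre_u.txt"))
    ang <- atan2(m$mesh2d$voronoi[, 2] - cy, m$mesh2d$voronoi[, 1] - cx)
    rad <- sqrt((m$mesh2d$voronoi[, 1] - cx)^2 +
                (m$mesh2d$voronoi[, 2] - cy)^2)
    reg <- ifelse(rad < 300 | rad > 900, 0L,
                  1L + floor(3 * (ang + pi) / (2 * pi + 1e-9)))
    write_field_text(reg, file.path(dir, "regions.txt"))
    w('<flexmarine>',
      '  <simulation dt="60" n_steps="100" seed="7"/>',
      '  <mesh kind="rect" nx="20" ny="20" dx="100" depth="10" interfaces="0,10"/>',
      '  <offline u_file="gyre_u.txt"/>',
      '  <abm region_file="regions.txt" n_per_polygon="2" diffusivity_h="0.5" z0="5"/>',
      '  <output every_steps="30"/>',
      '</flexmarine>')
  } else if (recipe == "farm_depletion") {
    # 1500 x 1050 m, 50 m cells; farm block 250 x 200 m in the middle
    m <- generate_fixture_mesh("rect", 30, 21, 50, depth = 5,
                               interfaces = 0:5,
                               open_sides = c("west", "east"))
    vx <- m$mesh2d$voronoi[, 1]; vy <- m$mesh2d$voronoi[, 2]
    farm <- as.numeric(vx > 625 & vx < 875 & vy > 425 & vy < 625)
    write_field_text(farm, file.path(dir, "farm.txt"))
    write_series(data.frame(time = c(0, 1e7), speed = 0.05,
                            direction = 90), file.path(dir, "profile.csv"))
    w('<flexmarine>',
      '  <simulation dt="250" n_steps="600" seed="1"/>',
      '  <mesh kind="rect" nx="30" ny="21" dx="50" depth="5" interfaces="0,1,2,3,4,5" open="west,east"/>',
      '  <offline profile_file="profile.csv" K_h="1"/>',
      '  <field name="farm" file="farm.txt"/>',
      '  <equationsystem>',
      '    <constants>',
      '      <constant name="filtration" value="2e-4"/>',  # 1/s inside the farm
      '    </constants>',
      '    <variables>',
      '      <variable name="chl" initial="5" boundary="5" nonnegative="true"/>',
      '    </variables>',
      '    <equations>',
      '      <equation variable="chl" expr="-filtration*farm*chl"/>',
      '    </equations>',
      '  </equationsystem>',
      '  <output every_steps="100"/>',
      '</flexmarine>')
  } else {                              # sediment_plume
    write_series(data.frame(time = c(0, 1e7), speed = 0.05,
                            direction = 90), file.path(dir, "profile.csv"))
    w('<flexmarine>',
      '  <simulation dt="500" n_steps="800" seed="1"/>',
      '  <mesh kind="rect" nx="21" ny="21" dx="200" depth="50" interfaces="0,5,10,15,20,25,30,35,40,45,50" open="west,east"/>',
      '  <offline profile_file="profile.csv" K_h="0.1"/>',
      '  <equationsystem>',
      '    <variables>',
      # Stokes fall velocities for 66 um and 9 um grains (excess density
      # 1650 kg/m3, molecular viscosity): 3.9e-3 and 7.3e-5 m/s
      '      <variable name="coarse" initial="0" boundary="0" settling="3.9e-3" settle_into="dep_coarse" nonnegative="true"/>',
      '      <variable name="fine" initial="0" boundary="0" settling="7.3e-5" settle_into="dep_fine" nonnegative="true"/>',
      '      <variable name="dep_coarse" domain="benthic" initial="0"/>',
      '      <variable name="dep_fine" domain="benthic" initial="0"/>',
      '    </variables>',
      '  </equationsystem>',
      '  <source polygon="221" variable="coarse" load="1" distribute="5"/>',
      '  <source polygon="221" variable="fine" load="1" distribute="5"/>',
      '  <output every_steps="100"/>',
      '</flexmarine>')
  }
  path
}
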