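# ---------------------------------------------------------------------------
# Setup-file parsing, the simulation driver and the fixture generator.
#
# A simulation is described by one XML file.  Module call order within a
# step is fixed and part of the package contract:
#   forcings -> hydro/offline -> heat -> tracer transport -> equation
#   systems (timestep, settling, resuspension, exchange) -> ABM -> output.
# All file formats are documented delimited text (plain, diffable and
# dependency-free): mesh tables, time series, per-snapshot field dumps.
# ---------------------------------------------------------------------------

#' Write / read the mesh text format
#'
#' Format: a `nodes` block (`id x y mark`), a `polygons` block
#' (`id n1 n2 ...`), and a `bathymetry` block (`id depth`), whitespace
#' separated, with `#` comments.
#'
#' @param mesh3d a \code{flex_mesh3d}.
#' @param path output file.
#' @export
write_mesh_text <- function(mesh3d, path) {
  m2 <- mesh3d$mesh2d
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# flexmarine mesh (text format)", con)
  writeLines(sprintf("interfaces %s",
                     paste(mesh3d$interfaces, collapse = " ")), con)
  writeLines(sprintf("nodes %d", nrow(m2$nodes)), con)
  for (i in seq_len(nrow(m2$nodes))) {
    writeLines(sprintf("%d %.10g %.10g %s", i, m2$nodes[i, 1],
                       m2$nodes[i, 2], m2$boundary_mark[i]), con)
  }
  writeLines(sprintf("polygons %d", m2$n_poly), con)
  for (i in seq_len(m2$n_poly)) {
    writeLines(paste(c(i, m2$polygons[[i]]), collapse = " "), con)
  }
  writeLines(sprintf("bathymetry %d", m2$n_poly), con)
  for (i in seq_len(m2$n_poly)) {
    writeLines(sprintf("%d %.10g", i, mesh3d$bathymetry[i]), con)
  }
  invisible(path)
}

#' @rdname write_mesh_text
#' @export
read_mesh_text <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  i <- 1L
  expect_block <- function(name) {
    parts <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    if (parts[1] != name) stop(sprintf("mesh file: expected '%s' block", name))
    i <<- i + 1L
    parts[-1]
  }
  interfaces <- as.numeric(expect_block("interfaces"))
  nn <- as.integer(expect_block("nodes"))
  nodes <- matrix(0, nn, 2)
  mark <- character(nn)
  for (q in seq_len(nn)) {
    p <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    nodes[as.integer(p[1]), ] <- as.numeric(p[2:3])
    mark[as.integer(p[1])] <- p[4]
    i <- i + 1L
  }
  np <- as.integer(expect_block("polygons"))
  polys <- vector("list", np)
  for (q in seq_len(np)) {
    p <- as.integer(strsplit(trimws(ln[i]), "\\s+")[[1]])
    polys[[p[1]]] <- p[-1]
    i <- i + 1L
  }
  nb <- as.integer(expect_block("bathymetry"))
  bathy <- numeric(np)
  for (q in seq_len(nb)) {
    p <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    bathy[as.integer(p[1])] <- as.numeric(p[2])
    i <- i + 1L
  }
  build_mesh(nodes, polys, mark, bathy, interfaces)
}

#' Read / write a (time, value...) delimited series
#' @param path CSV file with a header line; first column \code{time}
#'   (seconds, or ISO 8601 converted relative to the first entry).
#' @export
read_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(d$time)) {
    tt <- as.POSIXct(d$time, tz = "UTC")
    d$time <- as.numeric(tt - tt[1], units = "secs")
  }
  d
}

#' @rdname read_series
#' @param d data frame whose first column is \code{time}.
#' @export
write_series <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# per-polygon value table (id value)
read_field_text <- function(path) {
  d <- utils::read.table(path, header = FALSE)
  v <- numeric(max(d[[1]]))
  v[d[[1]]] <- d[[2]]
  v
}

write_field_text <- function(v, path) {
  utils::write.table(data.frame(id = seq_along(v), value = v), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load and validate a simulation setup
#'
#' Parses the XML setup file and performs full validation, reporting all
#' configuration errors at once.  Relative file references are resolved
#' against the setup file's directory.
#'
#' @param path setup XML file.
#' @return a \code{flex_setup}; or an error listing every problem found.
#' @export
load_setup <- function(path) {
  doc <- xml2::read_xml(path)
  dir <- dirname(normalizePath(path))
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  sim <- xml2::xml_find_first(doc, "./simulation")
  if (inherits(sim, "xml_missing")) {
    note("missing <simulation> element")
    dt <- 1; n_steps <- 0; seed <- 1
  } else {
    dt <- xml_num(sim, "dt")
    n_steps <- xml_num(sim, "n_steps")
    seed <- xml_num(sim, "seed", 1)
    if (is.null(dt) || dt <= 0) note("<simulation> needs dt > 0")
    if (is.null(n_steps) || n_steps < 1) note("<simulation> needs n_steps >= 1")
  }

  mesh <- NULL
  mn <- xml2::xml_find_first(doc, "./mesh")
  if (inherits(mn, "xml_missing")) {
    note("missing <mesh> element")
  } else if (!is.null(xml_chr(mn, "file"))) {
    mesh <- tryCatch(read_mesh_text(file.path(dir, xml_chr(mn, "file"))),
                     error = function(e) {
                       note(sprintf("mesh file: %s", conditionMessage(e)))
                       NULL
                     })
  } else {
    ifc <- as.numeric(strsplit(xml_chr(mn, "interfaces", "0"), ",")[[1]])
    open <- strsplit(xml_chr(mn, "open", ""), ",")[[1]]
    mesh <- tryCatch(
      generate_fixture_mesh(xml_chr(mn, "kind", "rect"),
                            as.integer(xml_num(mn, "nx", 1)),
                            as.integer(xml_num(mn, "ny", 1)),
                            xml_num(mn, "dx", 100),
                            depth = xml_num(mn, "depth", 10),
                            interfaces = if (length(ifc) > 1) ifc else NULL,
                            open_sides = open[nzchar(open)]),
      error = function(e) {
        note(sprintf("mesh: %s", conditionMessage(e)))
        NULL
      })
  }

  hyd <- xml2::xml_find_first(doc, "./hydro")
  off <- xml2::xml_find_first(doc, "./offline")
  n_hd <- sum(!inherits(hyd, "xml_missing"), !inherits(off, "xml_missing"))
  if (n_hd > 1) {
    note("the hydrodynamic providers (hydro, offline) are alternatives: enable at most one")
  }

  hydro <- NULL
  if (!inherits(hyd, "xml_missing") && !is.null(mesh)) {
    hydro <- list(
      params = hydro_params(
        dt = dt %||% 1,
        theta = xml_num(hyd, "theta", 0.5),
        f = xml_num(hyd, "f", 0),
        nu_h = xml_num(hyd, "nu_h", 0),
        nu_v = xml_num(hyd, "nu_v", 0),
        C_smag = xml_num(hyd, "C_smag", 0),
        C_bottom = xml_num(hyd, "C_bottom", 0)),
      eta0_file = xml_chr(hyd, "eta0_file"),
      advect_ts = xml_lgl(hyd, "advect_ts", FALSE))
    if (!is.null(hydro$eta0_file)) {
      hydro$eta0 <- tryCatch(
        read_field_text(file.path(dir, hydro$eta0_file)),
        error = function(e) {
          note(sprintf("eta0_file: %s", conditionMessage(e)))
          NULL
        })
    }
  }

  offline <- NULL
  if (!inherits(off, "xml_missing") && !is.null(mesh)) {
    offline <- list(K_h = xml_num(off, "K_h", 0),
                    K_v = xml_num(off, "K_v", 0))
    pf <- xml_chr(off, "profile_file")
    uf <- xml_chr(off, "u_file")
    if (!is.null(pf)) {
      prof <- tryCatch(read_series(file.path(dir, pf)), error = function(e) {
        note(sprintf("profile_file: %s", conditionMessage(e)))
        NULL
      })
      if (!is.null(prof)) {
        offline$series <- offline_series(
          times = prof$time,
          profiles = lapply(seq_len(nrow(prof)), function(r) {
            list(speed = prof$speed[r], direction = prof$direction[r])
          }))
      }
    } else if (!is.null(uf)) {
      offline$series <- tryCatch(
        read_offline_u(file.path(dir, uf)), error = function(e) {
          note(sprintf("u_file: %s", conditionMessage(e)))
          NULL
        })
    } else {
      note("<offline> needs profile_file or u_file")
    }
  }

  heat <- NULL
  hn <- xml2::xml_find_first(doc, "./heat")
  if (!inherits(hn, "xml_missing")) {
    heat <- list(
      params = heat_params(
        mode = xml_chr(hn, "mode", "flux"),
        latitude = xml_num(hn, "latitude", 55),
        penetration_depth = xml_num(hn, "penetration_depth", 5),
        conduction_coefficient = xml_num(hn, "conduction", 50)),
      meteo = list(wind_speed = xml_num(hn, "wind_speed", 5),
                   air_temp = xml_num(hn, "air_temp", 10),
                   cloud_cover = xml_num(hn, "cloud_cover", 0.5),
                   rel_humidity = xml_num(hn, "rel_humidity", 0.8)))
  }

  # spatial fields usable as extra environment names in the DSL
  env_fields <- list()
  for (fn in xml2::xml_find_all(doc, "./field")) {
    nm <- xml2::xml_attr(fn, "name")
    env_fields[[nm]] <- tryCatch(
      read_field_text(file.path(dir, xml2::xml_attr(fn, "file"))),
      error = function(e) {
        note(sprintf("field %s: %s", nm, conditionMessage(e)))
        NULL
      })
  }

  system <- NULL
  en <- xml2::xml_find_first(doc, "./equationsystem")
  if (!inherits(en, "xml_missing")) {
    system <- tryCatch(
      parse_equation_system(en, env_extra = names(env_fields)),
      error = function(e) {
        note(sprintf("equationsystem: %s", conditionMessage(e)))
        NULL
      })
  }

  # tracer transport config for advected pelagic variables
  scheme <- "explicit"
  tn <- xml2::xml_find_first(doc, "./transport")
  if (!inherits(tn, "xml_missing")) {
    scheme <- xml_chr(tn, "scheme", "explicit")
    if (!scheme %in% c("explicit", "semi_implicit")) {
      note("transport scheme must be 'explicit' or 'semi_implicit'")
    }
  }

  sources <- list()
  for (sn in xml2::xml_find_all(doc, "./source")) {
    sources[[length(sources) + 1L]] <- list(
      polygon = as.integer(xml_num(sn, "polygon")),
      x = xml_num(sn, "x"), y = xml_num(sn, "y"),
      variable = xml_chr(sn, "variable"),
      load = xml_num(sn, "load", 0),
      Q = xml_num(sn, "Q", 0),
      distribute = xml_chr(sn, "distribute", "surface"))
  }

  abm <- NULL
  an <- xml2::xml_find_first(doc, "./abm")
  if (!inherits(an, "xml_missing")) {
    abm <- list(
      n_per_polygon = as.integer(xml_num(an, "n_per_polygon", 10)),
      region_file = xml_chr(an, "region_file"),
      diffusivity_h = xml_num(an, "diffusivity_h", 0),
      diffusivity_v = xml_num(an, "diffusivity_v", 0),
      substeps = as.integer(xml_num(an, "substeps", 1)),
      boundary = xml_chr(an, "boundary", "solid"),
      z0 = xml_num(an, "z0", 0.5))
    if (!is.null(abm$region_file)) {
      abm$regions <- tryCatch(
        read_field_text(file.path(dir, abm$region_file)),
        error = function(e) {
          note(sprintf("region_file: %s", conditionMessage(e)))
          NULL
        })
    } else {
      note("<abm> needs region_file")
    }
  }

  sections <- list()
  for (sn in xml2::xml_find_all(doc, "./section")) {
    pl <- do.call(rbind, lapply(
      strsplit(strsplit(xml2::xml_attr(sn, "polyline"), ";")[[1]], ","),
      as.numeric))
    if (!is.null(mesh)) {
      sec <- tryCatch(
        define_section(mesh, pl, xml_chr(sn, "name", "section")),
        error = function(e) {
          note(sprintf("section: %s", conditionMessage(e)))
          NULL
        })
      if (!is.null(sec)) sections[[length(sections) + 1L]] <- sec
    }
  }

  on <- xml2::xml_find_first(doc, "./output")
  interval <- if (inherits(on, "xml_missing")) 1L else {
    as.integer(xml_num(on, "every_steps", 1))
  }
  if (interval < 1) note("<output every_steps> must be >= 1")

  # cross-cutting validation
  if (!is.null(mesh) && !is.null(system)) {
    has_open <- any(mesh$mesh2d$faces$type == "open")
    if (has_open && n_hd > 0) {
      for (v in names(system$variables)) {
        spec <- system$variables[[v]]
        if (spec$domain == "pelagic" && isTRUE(spec$advected) &&
            is.null(spec$boundary)) {
          note(sprintf(
            "open boundary present: advected variable '%s' needs a boundary value",
            v))
        }
      }
    }
  }

  if (length(errs) > 0) {
    stop(sprintf("invalid setup '%s':\n  - %s", path,
                 paste(errs, collapse = "\n  - ")))
  }

  structure(list(dt = dt, n_steps = as.integer(n_steps), seed = seed,
                 mesh = mesh, hydro = hydro, offline = offline, heat = heat,
                 system = system, scheme = scheme, sources = sources,
                 abm = abm, sections = sections, env_fields = env_fields,
                 interval = interval, dir = dir),
            class = "flex_setup")
}

#' Run a simulation
#'
#' Executes the fixed module order per step and records snapshots every
#' output interval.  Deterministic given the setup's seed.
#'
#' @param setup a \code{flex_setup} from \code{\link{load_setup}}.
#' @param outdir optional directory: recorded series and final fields are
#'   written there as delimited text.
#' @return list with \code{times}, \code{fields} (per-snapshot variable
#'   list), \code{eta} (matrix snapshot x polygon when hydro is active),
#'   \code{section_flux} (per section), \code{agents} (final population),
#'   \code{connectivity} (when ABM regions exist), \code{inventory}.
#' @export
run_setup <- function(setup, outdir = NULL) {
  set.seed(setup$seed)
  mesh <- setup$mesh
  dt <- setup$dt
  np <- mesh$n_poly; nl <- mesh$n_layers

  hstate <- NULL
  if (!is.null(setup$hydro)) {
    hstate <- hydro_state(mesh, setup$hydro$params)
    if (!is.null(setup$hydro$eta0)) hstate$eta <- setup$hydro$eta0
  }
  fields <- if (!is.null(setup$system)) init_fields(setup$system, mesh)
            else list()
  adv_vars <- if (!is.null(setup$system)) {
    names(Filter(function(v) v$domain == "pelagic" && isTRUE(v$advected),
                 setup$system$variables))
  } else {
    character(0)
  }

  pop <- NULL
  if (!is.null(setup$abm)) {
    regs <- setup$abm$regions
    rel <- which(!is.na(regs) & regs > 0)
    xs <- rep(mesh$mesh2d$voronoi[rel, 1], each = setup$abm$n_per_polygon)
    ys <- rep(mesh$mesh2d$voronoi[rel, 2], each = setup$abm$n_per_polygon)
    rg <- rep(regs[rel], each = setup$abm$n_per_polygon)
    pop <- agent_population(xs, ys, z = setup$abm$z0, region = rg,
                            substeps = setup$abm$substeps)
  }

  env <- setup$env_fields
  env$depth <- matrix(mesh$bathymetry, np, nl)
  zc <- (mesh$interfaces[-1] + mesh$interfaces[-(nl + 1)]) / 2
  env$z <- matrix(zc, np, nl, byrow = TRUE)

  u_now <- matrix(0, mesh$n_face, nl)
  rec_times <- c()
  rec_fields <- list()
  rec_eta <- list()
  rec_secflux <- matrix(0, 0, length(setup$sections))

  for (istep in seq_len(setup$n_steps)) {
    t_now <- (istep - 1) * dt
    env$time <- t_now

    V_old <- V_new <- NULL
    if (!is.null(hstate)) {
      eta_prev <- hstate$eta
      hstate <- step_hydro(hstate, mesh, setup$hydro$params,
                           advect_ts = setup$hydro$advect_ts)
      u_now <- hstate$diag$u_transport %||% hstate$u
      V_old <- cell_volumes(mesh, eta_prev)
      V_new <- cell_volumes(mesh, hstate$eta)
      env$temp <- hstate$temp
      env$salt <- hstate$salt
      env$bottom_stress <- bottom_stress(hstate, mesh, setup$hydro$params)
    } else if (!is.null(setup$offline)) {
      snap <- fields_at(setup$offline$series, t_now)
      u_now <- if (!is.null(snap$u)) {
        snap$u
      } else {
        broadcast_profile(snap$profiles$speed, snap$profiles$direction, mesh)
      }
    }

    if (!is.null(setup$heat)) {
      temp0 <- if (!is.null(hstate)) hstate$temp else
        (env$temp %||% matrix(10, np, nl))
      hres <- step_heat(temp0, mesh, setup$heat$params, setup$heat$meteo,
                        t_now / 86400, dt)
      if (!is.null(hstate)) hstate$temp <- hres$temp else env$temp <- hres$temp
      env$light <- hres$light
    }

    if (!is.null(setup$system)) {
      K_h <- if (!is.null(setup$offline)) setup$offline$K_h else 0
      K_v <- if (!is.null(setup$offline)) setup$offline$K_v else 0
      for (v in adv_vars) {
        spec <- setup$system$variables[[v]]
        stepfn <- if (setup$scheme == "explicit") advect_diffuse_explicit
                  else advect_diffuse_semi_implicit
        fields[[v]] <- stepfn(fields[[v]], u_now, mesh, dt,
                              D_h = max(K_h, spec$diffusivity_h),
                              D_v = max(K_v, spec$diffusivity_v),
                              boundary_value = spec$boundary %||% 0,
                              V_old = V_old, V_new = V_new)
      }
      for (s in setup$sources) {
        if (!is.null(s$variable) && s$load != 0) {
          fields[[s$variable]] <- apply_sources(
            fields[[s$variable]], mesh, list(s), dt, t_now)
        }
      }
      fields <- evaluate_timestep(setup$system, fields, env, dt)
      fields <- apply_settling(setup$system, fields, mesh, env, dt)
      if (!is.null(env$bottom_stress)) {
        fields <- resuspend(setup$system, fields, env$bottom_stress, mesh, dt)
      }
      fields <- interface_exchange(setup$system, fields, mesh, dt)
    }

    if (!is.null(pop)) {
      pop <- step_agents(pop, mesh, u_now, dt,
                         diffusivity_h = setup$abm$diffusivity_h,
                         diffusivity_v = setup$abm$diffusivity_v,
                         boundary = setup$abm$boundary)
    }

    if (istep %% setup$interval == 0L) {
      rec_times <- c(rec_times, istep * dt)
      rec_fields[[length(rec_fields) + 1L]] <- fields
      if (!is.null(hstate)) rec_eta[[length(rec_eta) + 1L]] <- hstate$eta
      if (length(setup$sections) > 0) {
        rec_secflux <- rbind(rec_secflux, vapply(
          setup$sections, function(s) section_flux(s, u_now, mesh),
          numeric(1)))
      }
    }
  }

  out <- list(times = rec_times, fields = rec_fields,
              eta = if (length(rec_eta)) do.call(rbind, rec_eta) else NULL,
              section_flux = rec_secflux,
              agents = pop,
              final_fields = fields,
              hydro_state = hstate)
  if (!is.null(pop) && !is.null(setup$abm$regions)) {
    regs <- setup$abm$regions
    regs[regs == 0] <- NA
    out$connectivity <- downstream_connectivity(pop, mesh, regs)
  }
  if (!is.null(setup$system)) {
    out$inventory <- system_inventory(setup$system, fields, mesh)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (length(rec_times) > 0 && !is.null(setup$system)) {
      for (v in names(fields)) {
        d <- data.frame(time = rec_times, value = vapply(
          rec_fields, function(ff) mean(ff[[v]][, 1]), numeric(1)))
        write_series(d, file.path(outdir, sprintf("series_%s.csv", v)))
        utils::write.table(
          fields[[v]], file.path(outdir, sprintf("final_%s.txt", v)),
          row.names = FALSE, col.names = FALSE)
      }
    }
    if (!is.null(out$eta)) {
      utils::write.table(out$eta, file.path(outdir, "eta.txt"),
                         row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(out$connectivity)) {
      utils::write.table(out$connectivity,
                         file.path(outdir, "connectivity.txt"))
    }
  }
  out
}

#' Offline face-velocity file round trip
#'
#' Text layout: a header `offline_u <n_times> <n_faces> <n_layers>`, the
#' time axis, then one `<n_faces> x <n_layers>` block per snapshot.
#'
#' @param series a \code{flex_offline} with full face-velocity snapshots.
#' @param path file path.
#' @export
write_offline_u <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nt <- length(series$times)
  nf <- nrow(series$u[[1]]); nl <- ncol(series$u[[1]])
  writeLines(sprintf("offline_u %d %d %d", nt, nf, nl), con)
  writeLines(paste(sprintf("%.10g", series$times), collapse = " "), con)
  for (s in seq_len(nt)) {
    utils::write.table(series$u[[s]], con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_offline_u
#' @export
read_offline_u <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hd <- strsplit(trimws(readLines(con, 1)), "\\s+")[[1]]
  if (hd[1] != "offline_u") stop("not an offline_u file")
  nt <- as.integer(hd[2]); nf <- as.integer(hd[3]); nl <- as.integer(hd[4])
  times <- as.numeric(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
  u <- vector("list", nt)
  for (s in seq_len(nt)) {
    u[[s]] <- as.matrix(utils::read.table(con, nrows = nf))
    dimnames(u[[s]]) <- NULL
  }
  offline_series(times, u = u)
}
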