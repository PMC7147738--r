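# ---------------------------------------------------------------------------
# User-defined equation systems: constants, pelagic/benthic variables and
# per-variable differential equations dC/dt = RHS, parsed from text and
# solved every time step.  Evaluation is cell-local; spatial coupling is the
# transport module's job.  Settling, bottom-stress resuspension and
# pelagic-benthic diffusive exchange are conservative transfer operators.
# ---------------------------------------------------------------------------

ENV_NAMES <- c("temp", "salt", "light", "depth", "bottom_stress", "time", "z")

#' Construct an equation system
#'
#' @param constants named list/vector of numeric constants.
#' @param variables named list; each element a list with fields
#'   \code{domain} ("pelagic" or "benthic"), \code{initial} (default 0),
#'   \code{advected} (pelagic only, default TRUE), \code{settling}
#'   (m/s downward, number or DSL expression, default 0),
#'   \code{settle_into} (name of the benthic variable receiving pelagic
#'   settling flux), \code{nonnegative} (default FALSE), and for benthic
#'   variables optionally \code{resuspend_into}, \code{tau_crit} (N/m2) and
#'   \code{erosion_rate} (units/m2/s per unit excess stress ratio).
#' @param equations named list of DSL right-hand-side strings, one per
#'   prognostic variable (variables without an equation are diagnostic).
#' @param auxiliaries named list of DSL expressions evaluated per cell
#'   before the equations, in dependency order.
#' @param exchanges list of pelagic-benthic diffusive links, each
#'   \code{list(pelagic=, benthic=, k_ex=, h_b=)} with \code{k_ex} the
#'   piston velocity (m/s) and \code{h_b} the benthic mixing thickness (m)
#'   converting the per-area benthic pool to a porewater-equivalent
#'   concentration.
#' @param env_extra additional environment-field names (beyond temp, salt,
#'   light, depth, bottom_stress, time, z) the expressions may reference,
#'   e.g. a spatial mask supplied by the setup.
#' @return object of class \code{flex_eqsys}.
#' @export
equation_system <- function(constants = list(), variables = list(),
                            equations = list(), auxiliaries = list(),
                            exchanges = list(), env_extra = character(0)) {
  constants <- as.list(constants)
  vn <- names(variables)
  if (length(variables) > 0 && (is.null(vn) || any(vn == ""))) {
    stop("all variables must be named")
  }
  defaults <- list(domain = "pelagic", initial = 0, advected = TRUE,
                   settling = 0, settle_into = NULL, nonnegative = FALSE,
                   resuspend_into = NULL, tau_crit = Inf, erosion_rate = 0,
                   diffusivity_h = 0, diffusivity_v = 0, boundary = NULL)
  variables <- lapply(variables, function(v) {
    v <- utils::modifyList(defaults, as.list(v))
    if (!v$domain %in% c("pelagic", "benthic")) {
      stop("variable domain must be 'pelagic' or 'benthic'")
    }
    v
  })
  names(variables) <- vn

  declared <- c(names(constants), vn, names(auxiliaries), ENV_NAMES,
                env_extra)
  if (anyDuplicated(declared)) {
    stop(sprintf("duplicate declaration: %s",
                 paste(unique(declared[duplicated(declared)]), collapse = ", ")))
  }

  # auxiliaries: validate + topological order (cycle detection)
  aux_ast <- lapply(auxiliaries, dsl_parse)
  for (a in names(auxiliaries)) {
    dsl_validate(aux_ast[[a]], declared, auxiliaries[[a]])
  }
  aux_order <- character(0)
  state <- setNames(rep(0L, length(auxiliaries)), names(auxiliaries))
  visit <- function(a, stack) {
    if (state[[a]] == 2L) return(invisible(NULL))
    if (state[[a]] == 1L) {
      stop(sprintf("cyclic auxiliary definitions: %s",
                   paste(c(stack, a), collapse = " -> ")))
    }
    state[[a]] <<- 1L
    for (dep in intersect(dsl_names(aux_ast[[a]]), names(auxiliaries))) {
      visit(dep, c(stack, a))
    }
    state[[a]] <<- 2L
    aux_order <<- c(aux_order, a)
  }
  for (a in names(auxiliaries)) visit(a, character(0))

  for (e in names(equations)) {
    if (!(e %in% vn)) {
      stop(sprintf("equation for undeclared variable '%s'", e))
    }
  }
  eq_fun <- lapply(equations, dsl_compile, declared = declared)
  aux_fun <- lapply(auxiliaries, dsl_compile, declared = declared)

  settle_fun <- lapply(variables, function(v) {
    if (is.character(v$settling)) dsl_compile(v$settling, declared) else NULL
  })
  for (v in vn) {
    tgt <- variables[[v]]$settle_into
    if (!is.null(tgt) && nzchar(tgt)) {
      if (!(tgt %in% vn) || variables[[tgt]]$domain != "benthic") {
        stop(sprintf(
          "settling target '%s' of '%s' is not a declared benthic variable",
          tgt, v))
      }
    }
    tgt <- variables[[v]]$resuspend_into
    if (!is.null(tgt) && nzchar(tgt)) {
      if (!(tgt %in% vn) || variables[[tgt]]$domain != "pelagic") {
        stop(sprintf(
          "resuspension target '%s' of '%s' is not a declared pelagic variable",
          tgt, v))
      }
    }
  }
  for (x in exchanges) {
    if (!(x$pelagic %in% vn) || variables[[x$pelagic]]$domain != "pelagic") {
      stop("exchange 'pelagic' member must be a declared pelagic variable")
    }
    if (!(x$benthic %in% vn) || variables[[x$benthic]]$domain != "benthic") {
      stop("exchange 'benthic' member must be a declared benthic variable")
    }
    if (x$k_ex < 0) stop("exchange coefficient k_ex must be >= 0")
  }

  structure(list(constants = constants, variables = variables,
                 equations = equations, eq_fun = eq_fun,
                 auxiliaries = auxiliaries, aux_fun = aux_fun,
                 aux_order = aux_order, settle_fun = settle_fun,
                 exchanges = exchanges, declared = declared,
                 env_extra = env_extra),
            class = "flex_eqsys")
}

#' @export
print.flex_eqsys <- function(x, ...) {
  dom <- vapply(x$variables, `[[`, "", "domain")
  cat(sprintf(
    "flex_eqsys: %d constants, %d pelagic + %d benthic variables, %d equations\n",
    length(x$constants), sum(dom == "pelagic"), sum(dom == "benthic"),
    length(x$equations)))
  invisible(x)
}

#' Initialise fields for an equation system
#'
#' Pelagic fields are (polygon x layer) matrices masked by the wet cells;
#' benthic fields are (polygon x benthic-layer) matrices (per-area units).
#'
#' @param system a \code{flex_eqsys}.
#' @param mesh3d a \code{flex_mesh3d}; omit for a 0D (1x1) configuration.
#' @param n_benthic_layers benthic stack depth (default 1).
#' @export
init_fields <- function(system, mesh3d = NULL, n_benthic_layers = 1L) {
  np <- if (is.null(mesh3d)) 1L else mesh3d$n_poly
  nl <- if (is.null(mesh3d)) 1L else mesh3d$n_layers
  out <- list()
  for (v in names(system$variables)) {
    spec <- system$variables[[v]]
    if (spec$domain == "pelagic") {
      f <- matrix(spec$initial, np, nl)
      if (!is.null(mesh3d)) f[!mesh3d$active] <- 0
    } else {
      f <- matrix(spec$initial, np, n_benthic_layers)
    }
    out[[v]] <- f
  }
  out
}

build_eval_env <- function(system, fields, env) {
  vals <- c(system$constants, fields)
  for (nm in c(ENV_NAMES, system$env_extra)) {
    vals[[nm]] <- if (!is.null(env[[nm]])) env[[nm]] else 0
  }
  for (a in system$aux_order) {
    vals[[a]] <- system$aux_fun[[a]](vals)
  }
  vals
}

#' Advance the equation system one time step
#'
#' Cell-local integration of every prognostic variable: forward Euler
#' (default) or classic RK4 at the module's sub-step.  Auxiliaries are
#' (re)evaluated in dependency order at each stage.
#'
#' @param system a \code{flex_eqsys}.
#' @param fields named list of state matrices (see \code{\link{init_fields}}).
#' @param env named list of environment fields (\code{temp}, \code{salt},
#'   \code{light}, \code{depth}, \code{bottom_stress}, \code{time}, \code{z});
#'   missing entries default to 0.
#' @param dt time step (s, or any unit consistent with the equations).
#' @param integrator \code{"euler"} or \code{"rk4"}.
#' @param warn_stiff warn when \code{|dt * RHS / C| > 0.5} somewhere.
#' @return updated fields; clipped negative mass (for variables flagged
#'   nonnegative) is accumulated in attribute \code{"clip_error"}.
#' @export
evaluate_timestep <- function(system, fields, env = list(), dt,
                              integrator = c("euler", "rk4"),
                              warn_stiff = FALSE) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0)
  prognostic <- names(system$eq_fun)
  rhs_at <- function(flds) {
    vals <- build_eval_env(system, flds, env)
    out <- lapply(prognostic, function(v) {
      r <- system$eq_fun[[v]](vals)
      if (any(!is.finite(r) & is.finite(flds[[v]]))) {
        bad <- which(!is.finite(r))[1]
        stop(sprintf(
          "non-finite RHS for variable '%s' (expression \"%s\") at cell %d",
          v, system$equations[[v]], bad))
      }
      r
    })
    names(out) <- prognostic
    out
  }
  if (integrator == "euler") {
    k1 <- rhs_at(fields)
    upd <- lapply(prognostic, function(v) fields[[v]] + dt * k1[[v]])
  } else {
    k1 <- rhs_at(fields)
    s2 <- fields; for (v in prognostic) s2[[v]] <- fields[[v]] + dt / 2 * k1[[v]]
    k2 <- rhs_at(s2)
    s3 <- fields; for (v in prognostic) s3[[v]] <- fields[[v]] + dt / 2 * k2[[v]]
    k3 <- rhs_at(s3)
    s4 <- fields; for (v in prognostic) s4[[v]] <- fields[[v]] + dt * k3[[v]]
    k4 <- rhs_at(s4)
    upd <- lapply(prognostic, function(v) {
      fields[[v]] + dt / 6 * (k1[[v]] + 2 * k2[[v]] + 2 * k3[[v]] + k4[[v]])
    })
  }
  names(upd) <- prognostic
  if (warn_stiff) {
    ratios <- vapply(prognostic, function(v) {
      c0 <- fields[[v]]
      ok <- abs(c0) > 1e-12
      if (!any(ok)) return(0)
      max(abs(dt * k1[[v]][ok] / c0[ok]))
    }, numeric(1))
    if (any(ratios > 0.5)) {
      warning(sprintf(
        "stiff equation step: |dt*RHS/C| = %.2f for '%s'; halve the sub-step",
        max(ratios), prognostic[which.max(ratios)]))
    }
  }
  clip <- attr(fields, "clip_error")
  if (is.null(clip)) clip <- setNames(numeric(length(fields)), names(fields))
  for (v in prognostic) {
    fields[[v]] <- upd[[v]]
    if (isTRUE(system$variables[[v]]$nonnegative)) {
      neg <- fields[[v]] < 0
      if (any(neg)) {
        clip[v] <- clip[v] - sum(fields[[v]][neg])
        fields[[v]][neg] <- 0
      }
    }
  }
  attr(fields, "clip_error") <- clip
  fields
}

# thickness helper: 0D systems run without a mesh (unit cell, unit depth)
eff_thickness <- function(mesh3d, fields) {
  if (!is.null(mesh3d)) return(mesh3d$thickness)
  matrix(1, 1, 1)
}

#' Apply vertical settling and pelagic-to-benthic deposition
#'
#' First-order upwind settling flux between vertically adjacent wet cells;
#' the flux leaving each bottom cell is deposited (per area) into the top
#' benthic layer of the variable's \code{settle_into} target.  The summed
#' pelagic + benthic inventory is conserved to round-off.
#'
#' @inheritParams evaluate_timestep
#' @param mesh3d a \code{flex_mesh3d}; \code{NULL} for 0D (unit-depth cell).
#' @export
apply_settling <- function(system, fields, mesh3d = NULL, env = list(), dt) {
  h <- eff_thickness(mesh3d, fields)
  np <- nrow(h); nl <- ncol(h)
  active <- if (is.null(mesh3d)) matrix(TRUE, 1, 1) else mesh3d$active
  for (v in names(system$variables)) {
    spec <- system$variables[[v]]
    if (spec$domain != "pelagic") next
    ws <- spec$settling
    if (is.character(ws)) {
      vals <- build_eval_env(system, fields, env)
      ws <- system$settle_fun[[v]](vals)
    }
    if (all(ws == 0)) next
    if (any(ws < 0)) stop(sprintf("settling velocity of '%s' must be >= 0", v))
    W <- matrix(ws, np, nl)
    C <- fields[[v]]
    if (max(W * dt / pmax(h, 1e-300) * active) > 1) {
      stop(sprintf("settling CFL violated for '%s': w_s*dt exceeds layer thickness", v))
    }
    # interface flux below layer k (per area): w * C_k, into k+1 when wet
    if (nl > 1L) {
      for (k in seq_len(nl - 1L)) {
        below <- active[, k] & active[, k + 1L]
        flx <- W[, k] * C[, k] * dt * below
        C[, k] <- C[, k] - flx / pmax(h[, k], 1e-300)
        C[, k + 1L] <- C[, k + 1L] + flx / pmax(h[, k + 1L], 1e-300)
      }
    }
    tgt <- spec$settle_into
    if (!is.null(tgt) && nzchar(tgt)) {
      bl <- if (is.null(mesh3d)) rep(1L, np) else mesh3d$bottom_layer
      ib <- cbind(seq_len(np), bl)
      dep <- W[ib] * C[ib] * dt            # per-area deposit
      C[ib] <- C[ib] - dep / pmax(h[ib], 1e-300)
      fields[[tgt]][, 1] <- fields[[tgt]][, 1] + dep
    }
    fields[[v]] <- C
  }
  fields
}

#' Bottom-stress-driven resuspension of benthic pools
#'
#' Where the bed shear stress exceeds a benthic variable's critical stress,
#' mass erodes at rate \code{erosion_rate * (tau/tau_crit - 1)} (per area,
#' capped by the available pool) into the bottom pelagic cell of the
#' variable's \code{resuspend_into} target.
#'
#' @inheritParams apply_settling
#' @param bottom_stress per-polygon bed shear stress (N/m2).
#' @export
resuspend <- function(system, fields, bottom_stress, mesh3d = NULL, dt) {
  h <- eff_thickness(mesh3d, fields)
  np <- nrow(h)
  bl <- if (is.null(mesh3d)) rep(1L, np) else mesh3d$bottom_layer
  tau <- rep_len(bottom_stress, np)
  for (v in names(system$variables)) {
    spec <- system$variables[[v]]
    if (spec$domain != "benthic") next
    tgt <- spec$resuspend_into
    if (is.null(tgt) || !nzchar(tgt)) next
    excess <- pmax(tau / spec$tau_crit - 1, 0)
    if (all(excess == 0)) next
    erode <- pmin(fields[[v]][, 1], spec$erosion_rate * excess * dt)
    fields[[v]][, 1] <- fields[[v]][, 1] - erode
    ib <- cbind(seq_len(np), bl)
    fields[[tgt]][ib] <- fields[[tgt]][ib] + erode / pmax(h[ib], 1e-300)
  }
  fields
}

#' Diffusive exchange across the pelagic-benthic interface
#'
#' For each configured link, flux (per area) =
#' \code{k_ex * (C_pelagic_bottom - B/h_b)}, applied over \code{dt}; the
#' summed inventory of each pair is conserved.
#'
#' @inheritParams apply_settling
#' @export
interface_exchange <- function(system, fields, mesh3d = NULL, dt) {
  h <- eff_thickness(mesh3d, fields)
  np <- nrow(h)
  bl <- if (is.null(mesh3d)) rep(1L, np) else mesh3d$bottom_layer
  ib <- cbind(seq_len(np), bl)
  for (x in system$exchanges) {
    if (x$k_ex == 0) next
    cp <- fields[[x$pelagic]][ib]
    cb <- fields[[x$benthic]][, 1] / x$h_b
    flux <- x$k_ex * (cp - cb) * dt       # per-area mass, pelagic -> benthic
    fields[[x$pelagic]][ib] <- cp - flux / pmax(h[ib], 1e-300)
    fields[[x$benthic]][, 1] <- fields[[x$benthic]][, 1] + flux
  }
  fields
}

#' Total inventory per variable
#'
#' Pelagic: concentration integrated over wet cell volumes; benthic:
#' per-area pool integrated over polygon areas.  0D systems use a unit cell.
#'
#' @inheritParams apply_settling
#' @export
system_inventory <- function(system, fields, mesh3d = NULL) {
  vol <- if (is.null(mesh3d)) matrix(1, 1, 1) else mesh3d$volume
  area <- if (is.null(mesh3d)) 1 else mesh3d$mesh2d$area
  vapply(names(system$variables), function(v) {
    if (system$variables[[v]]$domain == "pelagic") {
      sum(fields[[v]] * vol)
    } else {
      sum(fields[[v]] * area)
    }
  }, numeric(1))
}

xml_num <- function(node, attr, default = NULL) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v) || v == "") return(default)
  as.numeric(v)
}

xml_chr <- function(node, attr, default = NULL) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v) || v == "") default else v
}

xml_lgl <- function(node, attr, default = NULL) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v) || v == "") return(default)
  tolower(v) %in% c("true", "1", "yes")
}

#' Parse an equation system from its XML block
#'
#' Schema: an \code{<equationsystem>} element with children
#' \code{<constants>} (\code{<constant name= value=>}),
#' \code{<auxiliaries>} (\code{<aux name= expr=>}),
#' \code{<variables>} (\code{<variable name= domain= initial= advected=
#' settling= settle_into= nonnegative= resuspend_into= tau_crit=
#' erosion_rate= diffusivity_h= diffusivity_v= boundary=>}),
#' \code{<equations>} (\code{<equation variable= expr=>}) and
#' \code{<exchanges>} (\code{<exchange pelagic= benthic= k_ex= h_b=>}).
#'
#' @param xml an \code{xml2} node, document, file path or XML string
#'   containing the \code{<equationsystem>} element.
#' @param env_extra extra environment names (see
#'   \code{\link{equation_system}}).
#' @return a \code{flex_eqsys}.
#' @export
parse_equation_system <- function(xml, env_extra = character(0)) {
  node <- if (inherits(xml, "xml_node") || inherits(xml, "xml_document")) {
    xml
  } else {
    xml2::read_xml(xml)
  }
  if (xml2::xml_name(node) != "equationsystem") {
    found <- xml2::xml_find_first(node, ".//equationsystem")
    if (inherits(found, "xml_missing")) {
      stop("no <equationsystem> element found")
    }
    node <- found
  }
  constants <- list()
  for (cn in xml2::xml_find_all(node, "./constants/constant")) {
    constants[[xml2::xml_attr(cn, "name")]] <- as.numeric(xml2::xml_attr(cn, "value"))
  }
  auxiliaries <- list()
  for (an in xml2::xml_find_all(node, "./auxiliaries/aux")) {
    auxiliaries[[xml2::xml_attr(an, "name")]] <- xml2::xml_attr(an, "expr")
  }
  variables <- list()
  for (vn in xml2::xml_find_all(node, "./variables/variable")) {
    settl <- xml_chr(vn, "settling", "0")
    settl_num <- suppressWarnings(as.numeric(settl))
    variables[[xml2::xml_attr(vn, "name")]] <- list(
      domain = xml_chr(vn, "domain", "pelagic"),
      initial = xml_num(vn, "initial", 0),
      advected = xml_lgl(vn, "advected", TRUE),
      settling = if (is.na(settl_num)) settl else settl_num,
      settle_into = xml_chr(vn, "settle_into"),
      nonnegative = xml_lgl(vn, "nonnegative", FALSE),
      resuspend_into = xml_chr(vn, "resuspend_into"),
      tau_crit = xml_num(vn, "tau_crit", Inf),
      erosion_rate = xml_num(vn, "erosion_rate", 0),
      diffusivity_h = xml_num(vn, "diffusivity_h", 0),
      diffusivity_v = xml_num(vn, "diffusivity_v", 0),
      boundary = xml_num(vn, "boundary"))
  }
  equations <- list()
  for (en in xml2::xml_find_all(node, "./equations/equation")) {
    equations[[xml2::xml_attr(en, "variable")]] <- xml2::xml_attr(en, "expr")
  }
  exchanges <- list()
  for (xn in xml2::xml_find_all(node, "./exchanges/exchange")) {
    exchanges[[length(exchanges) + 1L]] <- list(
      pelagic = xml2::xml_attr(xn, "pelagic"),
      benthic = xml2::xml_attr(xn, "benthic"),
      k_ex = as.numeric(xml2::xml_attr(xn, "k_ex")),
      h_b = as.numeric(xml2::xml_attr(xn, "h_b")))
  }
  equation_system(constants, variables, equations, auxiliaries, exchanges,
                  env_extra = env_extra)
}
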