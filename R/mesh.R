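#' @importFrom stats runif setNames coef lm
NULL

# ---------------------------------------------------------------------------
# 2D orthogonal unstructured mesh, its Voronoi dual, z-layering, bathymetry.
#
# Conventions:
#   * coordinates are local Cartesian metres;
#   * polygons are stored counter-clockwise (input is reoriented if needed);
#   * depth is positive down, layer 1 is the surface layer;
#   * every face carries a fixed unit normal; for interior faces it points
#     from the "left" (owner) polygon to the "right" polygon, for boundary
#     faces outward.  Face-normal velocities are signed by this normal.
# ---------------------------------------------------------------------------

polygon_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Least-squares circumcenter: the point minimising the variance of squared
# distances to the vertices.  Exact circumcenter for triangles, rectangles
# and regular polygons; for general orthogonal polygons this is the natural
# Voronoi-point estimate (the orthogonality check will flag a bad mesh).
ls_circumcenter <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1L)
  A <- cbind(2 * (xy[i2, 1] - xy[, 1]), 2 * (xy[i2, 2] - xy[, 2]))
  b <- (xy[i2, 1]^2 + xy[i2, 2]^2) - (xy[, 1]^2 + xy[, 2]^2)
  AtA <- crossprod(A)
  if (abs(det(AtA)) < 1e-12 * (sum(AtA^2) + 1e-300)) {
    stop("degenerate polygon: vertices are collinear")
  }
  as.numeric(solve(AtA, crossprod(A, b)))
}

#' Build the 2D mesh, faces and Voronoi dual
#'
#' @param nodes two-column matrix of node coordinates (m).
#' @param polygons list of integer vectors, each the node indices of one
#'   polygon (any consistent orientation; reoriented counter-clockwise).
#' @param boundary_mark character vector per node: \code{"interior"},
#'   \code{"solid"} or \code{"open"}.
#' @param orth_tol orthogonality tolerance in degrees; the mesh is rejected
#'   if the worst interior face deviates more than this from perpendicular.
#' @return an object of class \code{flex_mesh2d}.
#' @export
build_mesh2d <- function(nodes, polygons, boundary_mark = NULL,
                         orth_tol = 0.5) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  np <- length(polygons)
  if (np < 1L) stop("mesh needs at least one polygon")
  if (is.null(boundary_mark)) boundary_mark <- rep("interior", nrow(nodes))
  if (!all(boundary_mark %in% c("interior", "solid", "open"))) {
    stop("boundary_mark must be 'interior', 'solid' or 'open'")
  }

  area <- numeric(np)
  voronoi <- matrix(0, np, 2)
  centroid <- matrix(0, np, 2)
  for (i in seq_len(np)) {
    ids <- as.integer(polygons[[i]])
    if (length(ids) < 3L || anyDuplicated(ids)) {
      stop(sprintf("polygon %d must have >= 3 distinct nodes", i))
    }
    xy <- nodes[ids, , drop = FALSE]
    a <- polygon_area_signed(xy)
    if (abs(a) < 1e-12) stop(sprintf("polygon %d is degenerate (zero area)", i))
    if (a < 0) {                       # reorient clockwise input
      ids <- rev(ids)
      xy <- nodes[ids, , drop = FALSE]
      a <- -a
      polygons[[i]] <- ids
    }
    area[i] <- a
    voronoi[i, ] <- ls_circumcenter(xy)
    centroid[i, ] <- colMeans(xy)
  }

  # Face table: edges keyed by sorted node pair; first polygon met is "left".
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  fkey <- character(0)
  left <- integer(0); right <- integer(0)
  n1 <- integer(0); n2 <- integer(0)
  idx <- new.env(hash = TRUE)
  for (i in seq_len(np)) {
    ids <- polygons[[i]]
    nv <- length(ids)
    for (e in seq_len(nv)) {
      a <- ids[e]; b <- ids[if (e == nv) 1L else e + 1L]
      k <- edge_key(a, b)
      j <- idx[[k]]
      if (is.null(j)) {
        fkey <- c(fkey, k)
        left <- c(left, i); right <- c(right, 0L)
        n1 <- c(n1, a); n2 <- c(n2, b)
        idx[[k]] <- length(fkey)
      } else {
        if (right[j] != 0L) stop(sprintf("edge %s shared by > 2 polygons", k))
        right[j] <- i
      }
    }
  }
  nf <- length(fkey)
  p1 <- nodes[n1, , drop = FALSE]
  p2 <- nodes[n2, , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  len <- sqrt(dx^2 + dy^2)
  # CCW edge n1->n2 of the left polygon: outward normal is (dy, -dx)/len
  nx <- dy / len; ny <- -dx / len
  cx <- (p1[, 1] + p2[, 1]) / 2; cy <- (p1[, 2] + p2[, 2]) / 2

  dist <- numeric(nf)
  interior <- right > 0L
  dist[interior] <- sqrt((voronoi[right[interior], 1] - voronoi[left[interior], 1])^2 +
                         (voronoi[right[interior], 2] - voronoi[left[interior], 2])^2)
  dist[!interior] <- sqrt((cx[!interior] - voronoi[left[!interior], 1])^2 +
                          (cy[!interior] - voronoi[left[!interior], 2])^2)
  if (any(dist <= 0)) stop("coincident Voronoi points: face distance is zero")

  type <- ifelse(interior, "interior",
                 ifelse(boundary_mark[n1] == "open" & boundary_mark[n2] == "open",
                        "open", "solid"))

  faces <- data.frame(left = left, right = right, n1 = n1, n2 = n2,
                      length = len, cx = cx, cy = cy, nx = nx, ny = ny,
                      dist = dist, type = type, stringsAsFactors = FALSE)

  m <- structure(list(nodes = nodes, polygons = polygons,
                      boundary_mark = boundary_mark, area = area,
                      voronoi = voronoi, centroid = centroid, faces = faces,
                      n_poly = np, n_face = nf),
                 class = "flex_mesh2d")

  rep_ <- check_orthogonality(m, tol_deg = orth_tol)
  if (length(rep_$offending_faces) > 0) {
    worst <- rep_$offending_faces[1]
    stop(sprintf(
      "mesh is not orthogonal: face %d (nodes %d-%d) deviates %.3f deg (tolerance %.3f)",
      worst, faces$n1[worst], faces$n2[worst], rep_$max_deviation_deg, orth_tol))
  }

  # polygons whose Voronoi point falls outside themselves (flagged, per docs)
  out <- which(!vapply(seq_len(np), function(i) {
    point_in_polygon(voronoi[i, 1], voronoi[i, 2],
                     nodes[polygons[[i]], , drop = FALSE])
  }, logical(1)))
  if (length(out) > 0) {
    warning(sprintf("Voronoi point outside polygon for %d polygon(s): %s",
                    length(out), paste(utils::head(out, 5), collapse = ", ")))
  }
  m$locate_cache <- mesh_locate_index(m)
  m
}

#' Orthogonality diagnostic
#'
#' For every interior face, measures the deviation from perpendicularity
#' between the face and the segment joining the adjacent Voronoi points.
#'
#' @param mesh2d a \code{flex_mesh2d}.
#' @param tol_deg tolerance in degrees used to flag offending faces.
#' @return list with \code{max_deviation_deg} and \code{offending_faces}
#'   (face indices sorted by decreasing deviation).
#' @export
check_orthogonality <- function(mesh2d, tol_deg = 0.5) {
  f <- mesh2d$faces
  int <- which(f$right > 0L)
  if (length(int) == 0L) {
    return(list(max_deviation_deg = 0, offending_faces = integer(0),
                deviation_deg = numeric(0)))
  }
  tvx <- mesh2d$nodes[f$n2[int], 1] - mesh2d$nodes[f$n1[int], 1]
  tvy <- mesh2d$nodes[f$n2[int], 2] - mesh2d$nodes[f$n1[int], 2]
  dvx <- mesh2d$voronoi[f$right[int], 1] - mesh2d$voronoi[f$left[int], 1]
  dvy <- mesh2d$voronoi[f$right[int], 2] - mesh2d$voronoi[f$left[int], 2]
  cosang <- (tvx * dvx + tvy * dvy) /
    (sqrt(tvx^2 + tvy^2) * sqrt(dvx^2 + dvy^2))
  dev <- abs(90 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  ord <- order(dev, decreasing = TRUE)
  off <- int[ord][dev[ord] > tol_deg]
  list(max_deviation_deg = max(dev), offending_faces = off,
       deviation_deg = setNames(dev, int))
}

#' Attach z-layering and bathymetry to a 2D mesh
#'
#' A cell (polygon, layer) is wet iff the layer's top interface lies above
#' the polygon's bathymetry.  The bottom wet cell is clipped to the
#' bathymetry (partial bottom cell); if the bathymetry exceeds the deepest
#' interface, the bottom layer is extended down to it.
#'
#' @param mesh2d a \code{flex_mesh2d}.
#' @param interfaces strictly increasing layer interface depths, starting at
#'   0 (m, positive down).
#' @param bathymetry per-polygon depth (m, positive down), or a scalar, or a
#'   function of (x, y) evaluated at the Voronoi points.
#' @return an object of class \code{flex_mesh3d}.
#' @export
build_mesh3d <- function(mesh2d, interfaces, bathymetry) {
  stopifnot(inherits(mesh2d, "flex_mesh2d"))
  interfaces <- as.numeric(interfaces)
  if (interfaces[1] != 0) stop("first layer interface must be 0")
  if (any(diff(interfaces) <= 0)) stop("interfaces must be strictly increasing")
  nl <- length(interfaces) - 1L
  np <- mesh2d$n_poly
  if (is.function(bathymetry)) {
    bathymetry <- vapply(seq_len(np), function(i) {
      bathymetry(mesh2d$voronoi[i, 1], mesh2d$voronoi[i, 2])
    }, numeric(1))
  }
  bathymetry <- rep_len(as.numeric(bathymetry), np)
  if (any(bathymetry <= 0)) stop("bathymetry must be positive everywhere")

  top <- interfaces[seq_len(nl)]
  bot <- interfaces[-1]
  thick <- matrix(0, np, nl)
  for (k in seq_len(nl)) {
    b_eff <- if (k == nl) pmax(bot[k], bathymetry) else bot[k]
    thick[, k] <- pmax(0, pmin(b_eff, bathymetry) - top[k])
    thick[bathymetry <= top[k], k] <- 0
  }
  active <- thick > 0
  bottom_layer <- apply(active, 1, function(a) max(which(a)))
  volume <- thick * mesh2d$area

  f <- mesh2d$faces
  nf <- nrow(f)
  face_thick <- matrix(0, nf, nl)
  li <- f$left; ri <- f$right
  for (k in seq_len(nl)) {
    tl <- thick[li, k]
    tr <- ifelse(ri > 0L, thick[ifelse(ri > 0L, ri, 1L), k], tl)
    face_thick[, k] <- pmin(tl, tr)
  }
  face_active <- face_thick > 0
  face_area <- face_thick * f$length

  # stacked (face, cell, sign) table: every face paired with each adjacent
  # polygon; sign = +1 when the face normal points out of that polygon.
  int <- ri > 0L
  fc_face <- c(seq_len(nf), which(int))
  fc_cell <- c(li, ri[int])
  fc_sign <- c(rep(1, nf), rep(-1, sum(int)))

  structure(list(mesh2d = mesh2d, interfaces = interfaces, n_layers = nl,
                 bathymetry = bathymetry, thickness = thick, active = active,
                 bottom_layer = bottom_layer, volume = volume,
                 face_thickness = face_thick, face_active = face_active,
                 face_area = face_area,
                 fc_face = fc_face, fc_cell = fc_cell, fc_sign = fc_sign,
                 n_poly = np, n_face = nf),
            class = "flex_mesh3d")
}

#' Build a complete 3D mesh from raw tables
#'
#' Convenience constructor chaining \code{\link{build_mesh2d}} and
#' \code{\link{build_mesh3d}}.
#'
#' @inheritParams build_mesh2d
#' @inheritParams build_mesh3d
#' @export
build_mesh <- function(nodes, polygons, boundary_mark = NULL,
                       bathymetry, interfaces, orth_tol = 0.5) {
  build_mesh3d(build_mesh2d(nodes, polygons, boundary_mark, orth_tol),
               interfaces, bathymetry)
}

point_in_polygon <- function(px, py, xy) {
  # ray casting with boundary counted as inside
  n <- nrow(xy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    # on-edge test
    d <- abs((xj - xi) * (py - yi) - (px - xi) * (yj - yi))
    if (d <= 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1) &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# uniform-grid spatial index over polygon bounding boxes; built lazily and
# cached in the mesh environment so repeated point location is cheap
mesh_locate_index <- function(m2) {
  np <- m2$n_poly
  bb <- matrix(0, np, 4)
  for (i in seq_len(np)) {
    xy <- m2$nodes[m2$polygons[[i]], , drop = FALSE]
    bb[i, ] <- c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
  }
  x0 <- min(bb[, 1]); x1 <- max(bb[, 2])
  y0 <- min(bb[, 3]); y1 <- max(bb[, 4])
  h <- max(mean(bb[, 2] - bb[, 1]), mean(bb[, 4] - bb[, 3]), 1e-12)
  nx <- max(1L, ceiling((x1 - x0) / h))
  ny <- max(1L, ceiling((y1 - y0) / h))
  buckets <- vector("list", nx * ny)
  for (i in seq_len(np)) {
    ix <- max(1L, floor((bb[i, 1] - x0) / h) + 1L):
          min(nx, floor((bb[i, 2] - x0) / h) + 1L)
    iy <- max(1L, floor((bb[i, 3] - y0) / h) + 1L):
          min(ny, floor((bb[i, 4] - y0) / h) + 1L)
    for (b in as.vector(outer(ix, (iy - 1L) * nx, `+`))) {
      buckets[[b]] <- c(buckets[[b]], i)
    }
  }
  list(cells = buckets, bb = bb, x0 = x0, y0 = y0, h = h, nx = nx, ny = ny)
}

#' Locate the polygon containing a point
#'
#' Boundary ties are resolved deterministically to the lowest polygon index.
#'
#' @param mesh3d a \code{flex_mesh3d} (or \code{flex_mesh2d}).
#' @param x,y point coordinates (vectors allowed).
#' @return integer polygon index per point, \code{NA} when outside the mesh.
#' @export
locate_element <- function(mesh3d, x, y) {
  m2 <- if (inherits(mesh3d, "flex_mesh3d")) mesh3d$mesh2d else mesh3d
  idx <- m2$locate_cache
  if (is.null(idx)) idx <- mesh_locate_index(m2)
  out <- rep(NA_integer_, length(x))
  for (q in seq_along(x)) {
    ix <- floor((x[q] - idx$x0) / idx$h) + 1L
    iy <- floor((y[q] - idx$y0) / idx$h) + 1L
    if (ix < 1L || ix > idx$nx || iy < 1L || iy > idx$ny) next
    cand <- idx$cells[[(iy - 1L) * idx$nx + ix]]
    if (is.null(cand)) next
    for (i in sort(cand)) {
      b <- idx$bb[i, ]
      if (x[q] < b[1] - 1e-12 || x[q] > b[2] + 1e-12 ||
          y[q] < b[3] - 1e-12 || y[q] > b[4] + 1e-12) next
      if (point_in_polygon(x[q], y[q],
                           m2$nodes[m2$polygons[[i]], , drop = FALSE])) {
        out[q] <- i
        break
      }
    }
  }
  out
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  l1 <- sqrt(sum(d1^2)); l2 <- sqrt(sum(d2^2))
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12 * l1 * l2) {
    # parallel; a collinear overlap means the polyline traces the face
    cr <- (q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]
    if (abs(cr) > 1e-9 * l1 * l2) return(NULL)
    t1 <- sum((q1 - p1) * d1) / (l1 * l1)
    t2 <- sum((q2 - p1) * d1) / (l1 * l1)
    lo <- max(0, min(t1, t2)); hi <- min(1, max(t1, t2))
    if (hi - lo > 1e-9) return("overlap")
    return(NULL)
  }
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  s <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  if (t < 0 || t > 1 || s < 0 || s > 1) return(NULL)
  t
}

#' Define a flux section from a polyline
#'
#' Collects the interior faces crossed by the polyline.  The positive flux
#' direction is to the right of the polyline's direction of travel; a face
#' crossed twice in opposite senses cancels out of the section.
#'
#' @param mesh3d a \code{flex_mesh3d}.
#' @param polyline two-column matrix of waypoints (m).
#' @param name section label.
#' @return object of class \code{flex_section}: data frame of (face, sign).
#' @export
define_section <- function(mesh3d, polyline, name = "section") {
  m2 <- mesh3d$mesh2d
  f <- m2$faces
  int <- which(f$right > 0L)
  polyline <- as.matrix(polyline)
  acc <- numeric(length(int))
  for (s in seq_len(nrow(polyline) - 1L)) {
    p1 <- polyline[s, ]; p2 <- polyline[s + 1L, ]
    d <- p2 - p1
    # right-hand normal of the travel direction
    rn <- c(d[2], -d[1])
    for (jj in seq_along(int)) {
      j <- int[jj]
      q1 <- m2$nodes[f$n1[j], ]; q2 <- m2$nodes[f$n2[j], ]
      hit <- segments_intersect(p1, p2, q1, q2)
      if (!is.null(hit)) {
        sgn <- sign(f$nx[j] * rn[1] + f$ny[j] * rn[2])
        acc[jj] <- acc[jj] + sgn
      }
    }
  }
  keep <- which(acc != 0)
  if (length(keep) == 0L) {
    stop("polyline does not cross any interior face of the mesh")
  }
  structure(list(name = name,
                 faces = int[keep],
                 sign = sign(acc[keep])),
            class = "flex_section")
}

#' Generate an orthogonal fixture mesh
#'
#' Builds synthetic meshes that are orthogonal by construction: a regular
#' rectangular grid or a honeycomb of regular hexagons.  These are the test
#' substrates for every module and a convenient way to set up idealized
#' domains.
#'
#' @param kind \code{"rect"} or \code{"hex"}.
#' @param nx,ny number of cells in x and y (\code{rect}); for \code{hex},
#'   \code{nx} is the ring count (1 = single hexagon, 2 = 7 cells, ...).
#' @param dx cell size (m): rectangle edge, or hexagon centre-to-centre
#'   distance.
#' @param depth bathymetry: scalar, per-polygon vector, or function (x, y).
#' @param interfaces layer interface depths; default a single layer to the
#'   maximum depth.
#' @param open_sides for \code{rect}: character subset of
#'   \code{c("west","east","south","north")} whose boundary nodes are marked
#'   open (the rest are solid walls).
#' @return a \code{flex_mesh3d}.
#' @export
generate_fixture_mesh <- function(kind = c("rect", "hex"), nx = 1L, ny = 1L,
                                  dx = 100, depth = 10,
                                  interfaces = NULL,
                                  open_sides = character(0)) {
  kind <- match.arg(kind)
  if (kind == "rect") {
    stopifnot(nx >= 1L, ny >= 1L, dx > 0)
    xs <- (0:nx) * dx; ys <- (0:ny) * dx
    nodes <- as.matrix(expand.grid(x = xs, y = ys))
    nid <- function(i, j) (j - 1L) * (nx + 1L) + i   # i in 1..nx+1
    polys <- vector("list", nx * ny)
    p <- 0L
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      p <- p + 1L
      polys[[p]] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L),
                      nid(i, j + 1L))
    }
    mark <- rep("interior", nrow(nodes))
    onb <- nodes[, 1] == 0 & "west" %in% open_sides |
           nodes[, 1] == nx * dx & "east" %in% open_sides |
           nodes[, 2] == 0 & "south" %in% open_sides |
           nodes[, 2] == ny * dx & "north" %in% open_sides
    bnd <- nodes[, 1] == 0 | nodes[, 1] == nx * dx |
           nodes[, 2] == 0 | nodes[, 2] == ny * dx
    mark[bnd] <- "solid"
    mark[onb] <- "open"
  } else {
    rings <- as.integer(nx)
    stopifnot(rings >= 1L, dx > 0)
    # hexagon centres on a triangular lattice (axial coordinates)
    centers <- list()
    for (q in -(rings - 1L):(rings - 1L)) {
      for (r in max(-(rings - 1L), -q - (rings - 1L)):
                min(rings - 1L, -q + (rings - 1L))) {
        centers[[length(centers) + 1L]] <-
          c(dx * (q + r / 2), dx * r * sqrt(3) / 2)
      }
    }
    rad <- dx / sqrt(3)
    ang <- pi / 6 + (0:5) * pi / 3
    key_env <- new.env(hash = TRUE)
    nodes <- matrix(0, 0, 2)
    polys <- vector("list", length(centers))
    for (i in seq_along(centers)) {
      vx <- centers[[i]][1] + rad * cos(ang)
      vy <- centers[[i]][2] + rad * sin(ang)
      ids <- integer(6)
      for (v in 1:6) {
        k <- sprintf("%.6f_%.6f", round(vx[v] / dx, 9) + 0,
                     round(vy[v] / dx, 9) + 0)
        j <- key_env[[k]]
        if (is.null(j)) {
          nodes <- rbind(nodes, c(vx[v], vy[v]))
          j <- nrow(nodes)
          key_env[[k]] <- j
        }
        ids[v] <- j
      }
      polys[[i]] <- ids
    }
    # boundary nodes: those not shared by 3 hexagons
    cnt <- integer(nrow(nodes))
    for (pp in polys) cnt[pp] <- cnt[pp] + 1L
    mark <- ifelse(cnt < 3L, "solid", "interior")
  }

  m2 <- build_mesh2d(nodes, polys, mark, orth_tol = 1e-9 + 0.5)
  if (is.null(interfaces)) {
    dmax <- if (is.function(depth)) {
      max(vapply(seq_len(m2$n_poly),
                 function(i) depth(m2$voronoi[i, 1], m2$voronoi[i, 2]),
                 numeric(1)))
    } else max(depth)
    interfaces <- c(0, dmax)
  }
  build_mesh3d(m2, interfaces, depth)
}

#' Total wet volume of the mesh
#' @param mesh3d a \code{flex_mesh3d}.
#' @export
mesh_volume <- function(mesh3d) sum(mesh3d$volume)

#' @export
print.flex_mesh2d <- function(x, ...) {
  cat(sprintf("flex_mesh2d: %d polygons, %d nodes, %d faces (%d interior)\n",
              x$n_poly, nrow(x$nodes), x$n_face, sum(x$faces$right > 0)))
  invisible(x)
}

#' @export
print.flex_mesh3d <- function(x, ...) {
  cat(sprintf(
    "flex_mesh3d: %d polygons x %d layers, %d wet cells, volume %.4g m^3\n",
    x$n_poly, x$n_layers, sum(x$active), sum(x$volume)))
  invisible(x)
}

# --- cell-centred velocity reconstruction -----------------------------------
# Per active cell and layer, least-squares fit of a velocity vector to the
# face-normal components on the cell's faces (weights = face length).
# Returns list(ux, uy): n_poly x n_layers matrices.
reconstruct_cell_velocity <- function(mesh3d, u) {
  m2 <- mesh3d$mesh2d
  f <- m2$faces
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  fc_f <- mesh3d$fc_face; fc_c <- mesh3d$fc_cell
  wx <- f$nx[fc_f]; wy <- f$ny[fc_f]; wl <- f$length[fc_f]
  ux <- matrix(0, np, nl); uy <- matrix(0, np, nl)
  for (k in seq_len(nl)) {
    act <- mesh3d$face_active[fc_f, k]
    w <- wl * act
    sxx <- rowsum_vec(w * wx * wx, fc_c, np)
    sxy <- rowsum_vec(w * wx * wy, fc_c, np)
    syy <- rowsum_vec(w * wy * wy, fc_c, np)
    bx <- rowsum_vec(w * wx * u[fc_f, k], fc_c, np)
    by <- rowsum_vec(w * wy * u[fc_f, k], fc_c, np)
    det <- sxx * syy - sxy * sxy
    ok <- det > 1e-12 * (sxx + syy + 1e-300)^2
    ux[ok, k] <- (syy[ok] * bx[ok] - sxy[ok] * by[ok]) / det[ok]
    uy[ok, k] <- (sxx[ok] * by[ok] - sxy[ok] * bx[ok]) / det[ok]
  }
  list(ux = ux, uy = uy)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Least-squares gradient of a cell field from neighbouring cell centres.
# Returns list(gx, gy) matrices (np x nl); zero where fewer than 2 wet
# neighbours constrain the fit.
cell_gradients <- function(mesh3d, phi) {
  m2 <- mesh3d$mesh2d
  f <- m2$faces
  int <- which(f$right > 0L)
  np <- mesh3d$n_poly; nl <- mesh3d$n_layers
  li <- f$left[int]; ri <- f$right[int]
  dxv <- m2$voronoi[ri, 1] - m2$voronoi[li, 1]
  dyv <- m2$voronoi[ri, 2] - m2$voronoi[li, 2]
  gx <- matrix(0, np, nl); gy <- matrix(0, np, nl)
  cells <- c(li, ri)
  ddx <- c(dxv, -dxv); ddy <- c(dyv, -dyv)
  for (k in seq_len(nl)) {
    act <- mesh3d$active[li, k] & mesh3d$active[ri, k]
    w <- rep(as.numeric(act), 2)
    dphi <- c(phi[ri, k] - phi[li, k], phi[li, k] - phi[ri, k])
    sxx <- rowsum_vec(w * ddx * ddx, cells, np)
    sxy <- rowsum_vec(w * ddx * ddy, cells, np)
    syy <- rowsum_vec(w * ddy * ddy, cells, np)
    bx <- rowsum_vec(w * ddx * dphi, cells, np)
    by <- rowsum_vec(w * ddy * dphi, cells, np)
    det <- sxx * syy - sxy * sxy
    ok <- det > 1e-10 * (sxx + syy + 1e-300)^2
    gx[ok, k] <- (syy[ok] * bx[ok] - sxy[ok] * by[ok]) / det[ok]
    gy[ok, k] <- (sxx[ok] * by[ok] - sxy[ok] * bx[ok]) / det[ok]
    # 1D meshes: fall back to the single well-constrained direction
    one <- !ok & (sxx > 0 | syy > 0)
    gx[one & sxx > 0, k] <- bx[one & sxx > 0] / sxx[one & sxx > 0]
    gy[one & syy > 0, k] <- by[one & syy > 0] / syy[one & syy > 0]
  }
  list(gx = gx, gy = gy)
}
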