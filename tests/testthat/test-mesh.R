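test_that("a unit square with unit depth gives one active cell of 1 m^3", {
  m <- build_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                  list(1:4), rep("solid", 4),
                  bathymetry = 1, interfaces = c(0, 1))
  expect_equal(sum(m$active), 1L)
  expect_equal(sum(m$volume), 1)
  expect_equal(m$bottom_layer, 1L)
})

test_that("hexagonal fixture has exact circumcenters and orthogonal faces", {
  h <- hex_mesh(2, dx = 100)
  expect_equal(h$n_poly, 7L)
  # oracle: circumcenter of a regular polygon by brute force - the point
  # equidistant from all vertices, found from two perpendicular bisectors
  for (i in seq_len(h$n_poly)) {
    xy <- h$mesh2d$nodes[h$mesh2d$polygons[[i]], ]
    a <- xy[1, ]; b <- xy[2, ]; c <- xy[3, ]
    A <- rbind(2 * (b - a), 2 * (c - b))
    rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(b^2))
    cc <- solve(A, rhs)
    expect_equal(unname(h$mesh2d$voronoi[i, ]), unname(cc), tolerance = 1e-9)
    # all vertices equidistant from it
    expect_lt(diff(range(sqrt(colSums((t(xy) - cc)^2)))), 1e-9)
  }
  expect_lt(check_orthogonality(h$mesh2d)$max_deviation_deg, 1e-9)
})

test_that("partial bottom cells clip to the bathymetry", {
  m <- rect_mesh(2, 2, 1, depth = c(1, 1, 1, 3), interfaces = c(0, 2, 4))
  expect_equal(sum(m$active), 5L)
  expect_equal(m$thickness[4, 2], 1)      # deep cell: 3 m - 2 m interface
  expect_equal(m$thickness[1, 1], 1)      # shallow cells clipped to 1 m
  expect_equal(sum(m$volume), 3 * 1 + 3)  # integral of depth over area
})

test_that("orthogonality check is zero for rectangles and reports the
           displaced-node deviation computed by direct trigonometry", {
  r <- rect_mesh(4, 3, 50)
  expect_equal(check_orthogonality(r$mesh2d)$max_deviation_deg, 0)

  nodes <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(2, 1))
  nodes[5, 1] <- 1.1                      # displaced by 10% of edge length
  m2 <- suppressWarnings(
    build_mesh2d(nodes, list(c(1, 2, 5, 4), c(2, 3, 6, 5)),
                 rep("solid", 6), orth_tol = 45))
  rep_ <- check_orthogonality(m2, tol_deg = 0.5)
  f <- m2$faces
  j <- which(f$right > 0)
  tv <- nodes[f$n2[j], ] - nodes[f$n1[j], ]
  dv <- m2$voronoi[f$right[j], ] - m2$voronoi[f$left[j], ]
  oracle <- abs(90 - acos(sum(tv * dv) /
                          sqrt(sum(tv^2) * sum(dv^2))) * 180 / pi)
  expect_gt(rep_$max_deviation_deg, 0)
  expect_equal(rep_$max_deviation_deg, oracle, tolerance = 1e-12)
  expect_true(j %in% rep_$offending_faces)
})

test_that("degenerate and invalid meshes are rejected", {
  expect_error(build_mesh2d(rbind(c(0, 0), c(1, 0), c(2, 0)), list(1:3),
                            rep("solid", 3)),
               "degenerate|collinear")
  expect_error(build_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                          list(1:4), rep("solid", 4),
                          bathymetry = -1, interfaces = c(0, 1)),
               "bathymetry")
})

test_that("sections: splitting line, closed loop and hex oracle", {
  m2x1 <- rect_mesh(2, 1, 100, 5)
  s <- define_section(m2x1, rbind(c(100, -10), c(100, 110)))
  expect_length(s$faces, 1L)

  # closed CCW loop around one interior cell: its faces, signed outward,
  # so a uniform flow has zero net flux (discrete divergence theorem)
  m <- rect_mesh(4, 4, 100, 10)
  loop <- rbind(c(100, 100), c(200, 100), c(200, 200), c(100, 200),
                c(100, 100))
  sc <- define_section(m, loop)
  expect_length(sc$faces, 4L)
  u <- uniform_u(m, 1, 0.3)
  expect_lt(abs(section_flux(sc, u, m)), 1e-12)

  # diagonal across the hex fixture vs a brute-force intersection scan
  h <- hex_mesh(2, dx = 100)
  pl <- rbind(c(-130, -80), c(130, 80))
  sh <- define_section(h, pl)
  f <- h$mesh2d$faces
  brute <- integer(0)
  for (j in which(f$right > 0)) {
    q1 <- h$mesh2d$nodes[f$n1[j], ]; q2 <- h$mesh2d$nodes[f$n2[j], ]
    d1 <- pl[2, ] - pl[1, ]; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) next
    tt <- ((q1[1] - pl[1, 1]) * d2[2] - (q1[2] - pl[1, 2]) * d2[1]) / den
    ss <- ((q1[1] - pl[1, 1]) * d1[2] - (q1[2] - pl[1, 2]) * d1[1]) / den
    if (tt >= 0 && tt <= 1 && ss >= 0 && ss <= 1) brute <- c(brute, j)
  }
  expect_setequal(sh$faces, brute)
  expect_error(define_section(m, rbind(c(-5000, 0), c(-4000, 0))), "cross")
})

test_that("fixture meshes have the advertised cell counts", {
  r <- rect_mesh(10, 10, 100, 10, interfaces = seq(0, 10, 2))
  expect_equal(sum(r$active), 500L)
  expect_equal(hex_mesh(2)$n_poly, 7L)
  expect_equal(hex_mesh(3)$n_poly, 19L)
  m0 <- rect_mesh(1, 1, 10, 5)           # 0D substrate
  expect_equal(sum(m0$active), 1L)
  expect_equal(sum(m0$mesh2d$faces$right > 0), 0L)
})

test_that("mesh construction is idempotent and volume matches the depth
           integral", {
  depth_fn <- function(x, y) 5 + 3 * sin(x / 300) * cos(y / 400)
  m1 <- rect_mesh(6, 5, 100, depth_fn, interfaces = seq(0, 10, 1))
  m2 <- rect_mesh(6, 5, 100, depth_fn, interfaces = seq(0, 10, 1))
  expect_identical(m1$mesh2d$voronoi, m2$mesh2d$voronoi)
  expect_identical(m1$mesh2d$faces, m2$mesh2d$faces)
  expect_identical(m1$volume, m2$volume)
  analytic <- sum(m1$bathymetry * m1$mesh2d$area)
  expect_equal(sum(m1$volume), analytic, tolerance = 1e-10)
})

test_that("locate_element agrees with an exhaustive scan and handles
           outside points", {
  set.seed(11)
  h <- hex_mesh(3, dx = 80)
  expect_identical(locate_element(h, h$mesh2d$voronoi[, 1],
                                  h$mesh2d$voronoi[, 2]),
                   seq_len(h$n_poly))
  xs <- runif(500, -250, 250); ys <- runif(500, -250, 250)
  got <- locate_element(h, xs, ys)
  for (q in seq_along(xs)) {
    hits <- which(vapply(seq_len(h$n_poly), function(i) {
      flexmarine:::point_in_polygon(
        xs[q], ys[q], h$mesh2d$nodes[h$mesh2d$polygons[[i]], ])
    }, logical(1)))
    expect_equal(got[q],
                 if (length(hits)) min(hits) else NA_integer_)
  }
  expect_true(is.na(locate_element(h, 1e6, 1e6)))
})
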