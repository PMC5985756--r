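test_that("element quality is normalized, flags degeneracy, and is invariant", {
  # regular tetrahedron scores exactly 1 / rescaled 0
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  m <- labeled_mesh(reg, matrix(1:4, 1))
  q <- element_quality(m)
  expect_equal(q$raw, 1, tolerance = 1e-9)
  expect_equal(q$rescaled, 0, tolerance = 1e-9)

  # right-corner tetrahedron: oracle evaluated from the formula directly
  rc <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ssq <- 3 * 1 + 3 * 2                       # edge lengths^2
  c3 <- 6 * (6 * sqrt(2))^(2 / 3)
  kappa_oracle <- ssq / (c3 * (1 / 6)^(2 / 3))
  mrc <- labeled_mesh(rc, matrix(1:4, 1))
  expect_equal(element_quality(mrc)$raw, kappa_oracle, tolerance = 1e-12)

  # flattened tetrahedron degenerates toward rescaled 1
  flat <- rc; flat[4, 3] <- 1e-6
  qf <- element_quality(mrc, flat)
  expect_gt(qf$rescaled, 0.99)

  # inverted element: flagged, Inf/1, no error
  inv <- rc; inv[4, 3] <- -1
  qi <- element_quality(mrc, inv)
  expect_true(qi$inverted)
  expect_equal(qi$raw, Inf)
  expect_equal(qi$rescaled, 1)

  # invariance under rigid rotation and uniform scaling
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  q0 <- element_quality(mrc)$raw
  expect_equal(element_quality(mrc, rc %*% t(R))$raw, q0, tolerance = 1e-12)
  expect_equal(element_quality(mrc, rc * 3.7)$raw, q0, tolerance = 1e-12)
})

test_that("point location returns exact barycentric data and projects outside", {
  m <- cube_mesh(4)
  # a mesh vertex: one weight 1 at that vertex
  v7 <- m$vertices[7, , drop = FALSE]
  loc <- locate_points(m, v7)
  expect_false(loc$exterior)
  w <- loc$weights[1, ]
  expect_equal(sort(w, decreasing = TRUE)[1], 1, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # element centroid: equal weights 1/4
  el1 <- m$elements[5, ]
  cen <- colMeans(m$vertices[el1, ])
  loc2 <- locate_points(m, matrix(cen, 1))
  expect_equal(as.numeric(loc2$weights), rep(0.25, 4), tolerance = 1e-10)
  # far exterior point: flagged, clipped weights still sum to 1
  loc3 <- locate_points(m, matrix(c(3, 3, 3), 1))
  expect_true(loc3$exterior)
  expect_equal(sum(loc3$weights), 1, tolerance = 1e-12)
  # empty query
  loc4 <- locate_points(m, matrix(0, 0, 3))
  expect_length(loc4$element, 0)
})

test_that("barycentric interpolation reproduces a global linear field exactly", {
  m <- cube_mesh(4)
  f <- 2.5 * m$vertices[, 1] - 1.25 * m$vertices[, 2] + 0.75 * m$vertices[, 3] + 3
  set.seed(42)
  pts <- matrix(runif(30), 10, 3)
  loc <- locate_points(m, pts)
  vals <- interpolate_at(m, loc, f)
  expect_equal(vals, 2.5 * pts[, 1] - 1.25 * pts[, 2] + 0.75 * pts[, 3] + 3,
               tolerance = 1e-12)
})

test_that("surface extraction: areas, interfaces, and volume identity", {
  m <- cube_mesh(4)
  s <- surface_of(m, "lv")
  expect_equal(sum(s$areas), 6, tolerance = 1e-12)   # unit cube boundary
  # divergence theorem: signed element volumes match the enclosed volume
  expect_equal(sum(element_volumes(m)),
               abs(enclosed_volume(m$vertices, s$facets)),
               tolerance = 1e-10)
  # label absent
  expect_error(surface_of(m, "aobp"), "label not present")

  # two-label mesh: interface facets equal the brute-force shared-facet scan
  m2 <- m
  cen_z <- sapply(seq_len(nrow(m2$elements)), function(e)
    mean(m2$vertices[m2$elements[e, ], 3]))
  m2$element_labels <- ifelse(cen_z < 1 / 3, "lv", "lvbp")  # planar interface
  int <- surface_of(m2, "lv", interface_with = "lvbp")
  af <- cardioemf:::all_facets(m2)
  key <- cardioemf:::facet_key(af$facets)
  lv_keys <- key[m2$element_labels[af$owner] == "lv"]
  bp_keys <- key[m2$element_labels[af$owner] == "lvbp"]
  brute <- intersect(lv_keys, bp_keys)
  expect_setequal(cardioemf:::facet_key(int$facets), brute)
  # normals point out of the first label set (upward here)
  expect_true(all(int$normals[, 3] > 0))
})

test_that("ellipsoid surface area approaches the analytic value", {
  # sphere via the octant helper (radius known): area -> 4 pi r^2 / 8
  m <- sphere_octant_mesh(Ri = 10, Ro = 12, nr = 2, nt = 10, np = 10)
  s <- surface_of(m, "ao")
  bf <- s$facets
  ctr <- (m$vertices[bf[, 1], ] + m$vertices[bf[, 2], ] + m$vertices[bf[, 3], ]) / 3
  rr <- sqrt(rowSums(ctr^2))
  outer_f <- rr > 11.5 & rowSums(s$normals * ctr / rr) > 0.9
  a_outer <- sum(s$areas[outer_f])
  expect_equal(a_outer, 4 * pi * 12^2 / 8, tolerance = 0.02)
})

test_that("VTK mesh I/O round-trips and rejects malformed input", {
  m <- coarse_tube()
  path <- tempfile(fileext = ".vtk")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-12)
  expect_identical(m2$elements, m$elements)
  expect_identical(m2$element_labels, m$element_labels)
  expect_identical(m2$facet_tags, m$facet_tags)

  # two-element round trip
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  el <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  small <- labeled_mesh(v, el, c("lv", "aobp"))
  p2 <- tempfile(fileext = ".vtk")
  write_mesh(small, p2)
  s2 <- read_mesh(p2)
  expect_identical(s2$elements, small$elements)
  expect_identical(s2$element_labels, small$element_labels)

  # missing label array: single-region default with a warning
  lines <- readLines(p2)
  i0 <- grep("^CELL_DATA", lines)
  writeLines(lines[seq_len(i0 - 1)], p2)
  file.remove(paste0(p2, ".facets.csv"))
  expect_warning(m3 <- read_mesh(p2), "single")
  expect_true(all(m3$element_labels == m3$element_labels[1]))

  # malformed file: named parse error
  bad <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "x", "ASCII",
               "DATASET UNSTRUCTURED_GRID", "POINTS 4 double",
               "0 0 zero"), bad)
  expect_error(read_mesh(bad), "malformed")
  # unknown cell type
  lines <- readLines(path)
  lines[grep("^CELL_TYPES", lines) + 1L] <- "42"
  bad2 <- tempfile(fileext = ".vtk")
  writeLines(lines, bad2)
  expect_error(read_mesh(bad2), "cell type")
})

test_that("time-series CSV round-trips with time_ms first", {
  tr <- data.frame(p_lv = c(1, 2), time_ms = c(0, 1), V = c(5, 6))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f)
  expect_identical(names(tr2)[1], "time_ms")
  expect_equal(tr2$p_lv, tr$p_lv)
  expect_error(read_trace_csv({
    f2 <- tempfile(); writeLines("a,b\n1,2", f2); f2
  }), "time_ms")
})
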