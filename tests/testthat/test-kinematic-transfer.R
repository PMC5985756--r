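test_that("pseudo-elastic motion reproduces rigid and affine boundary data", {
  m <- cube_mesh(4, L = 10)
  nv <- nrow(m$vertices)
  # rigid translation everywhere
  d_tr <- matrix(rep(c(1, -2, 0.5), each = nv), ncol = 3)
  sol <- solve_pseudo_elastic(m, d_tr)
  expect_equal(sol, d_tr, tolerance = 1e-10)
  # affine boundary map gives the exact affine interior field (patch test)
  A <- rbind(c(0.02, 0.01, 0), c(-0.01, 0.03, 0.005), c(0, 0.01, -0.02))
  d_af <- m$vertices %*% t(A)
  sol2 <- solve_pseudo_elastic(m, d_af)
  expect_equal(sol2, d_af, tolerance = 1e-9)
  # singular system when data misses part of the boundary of a split mesh
  v2 <- m$vertices; v2[, 1] <- v2[, 1] + 100
  disc <- labeled_mesh(rbind(m$vertices, v2),
                       rbind(m$elements, m$elements + nv))
  only_first <- list(vertices = tagged_vertices(m, "homogeneous"),
                     values = matrix(0, length(tagged_vertices(m, "homogeneous")), 3))
  expect_error(solve_pseudo_elastic(disc, only_first), "singular")
})

test_that("one-face displacement converges toward a refined reference", {
  # 2D patch: left edge displaced inward, others fixed
  drive <- function(n) {
    m <- rect_mesh(n, n, Lx = 10, Ly = 10)
    bidx <- sort(unique(as.vector(m$boundary_facets)))
    bv <- matrix(0, length(bidx), 2)
    left <- m$vertices[bidx, 1] < 1e-9
    bv[left, 1] <- 2 * sin(pi * m$vertices[bidx[left], 2] / 10)
    list(mesh = m, d = solve_pseudo_elastic(m, list(vertices = bidx, values = bv)))
  }
  coarse <- drive(7)
  fine <- drive(41)
  # compare on the coarse vertices via interpolation from the fine solve
  loc <- locate_points(fine$mesh, coarse$mesh$vertices)
  d_ref <- interpolate_at(fine$mesh, loc, fine$d)
  num <- sqrt(sum((coarse$d - d_ref)^2))
  den <- sqrt(sum(d_ref^2))
  expect_lt(num / den, 0.02)
})

test_that("quality stiffening multiplies E by kappa and caps inversions", {
  m <- cube_mesh(3, L = 6)
  # undeformed: E = E0 * kappa with kappa equal to the reference quality
  qs <- quality_stiffen(m, NULL, E0 = 100)
  q0 <- element_quality(m)$raw
  expect_equal(qs$E, 100 * q0)
  expect_false(any(qs$inverted))
  # uniform scaling leaves quality (hence E) unchanged
  qs2 <- quality_stiffen(m, 0.7 * m$vertices, E0 = 100)   # scale by 1.7
  expect_equal(qs2$E, qs$E, tolerance = 1e-9)
  # progressively squashing one vertex raises only nearby elements' E
  v_top <- which.max(m$vertices[, 3])
  E_hist <- sapply(c(0.3, 0.6, 0.8), function(s) {
    d <- matrix(0, nrow(m$vertices), 3)
    d[v_top, 3] <- -s * 6 / 2
    quality_stiffen(m, d, E0 = 100)$E
  })
  touched <- apply(m$elements, 1, function(e) v_top %in% e)
  expect_true(all(diff(t(E_hist[touched, , drop = FALSE])[, 1]) > 0))
  expect_equal(E_hist[!touched, 1], E_hist[!touched, 3], tolerance = 1e-9)
  # inverted element: capped stiffness, flagged
  d_inv <- matrix(0, nrow(m$vertices), 3)
  d_inv[v_top, 3] <- -7
  qs3 <- quality_stiffen(m, d_inv, E0 = 100)
  expect_true(any(qs3$inverted))
  expect_equal(max(qs3$E), 1e6 * 100)
})

test_that("volume-ratio rule switches nu only below the threshold", {
  m <- cube_mesh(3)
  ne <- nrow(m$elements)
  ref <- rep(1, ne)
  par <- pseudo_elastic_params(volume_ratio_threshold = 0.2, nu_stiff = 0.49)
  expect_equal(nu_volume_stiffen(m, ref, ref, par), rep(0.3, ne))
  cur <- ref; cur[5] <- 0.1
  nu <- nu_volume_stiffen(m, cur, ref, par)
  expect_equal(nu[5], 0.49)
  expect_equal(nu[-5], rep(0.3, ne - 1))
  # threshold 0 disables the rule entirely
  par0 <- pseudo_elastic_params(volume_ratio_threshold = 0)
  expect_equal(nu_volume_stiffen(m, cur, ref, par0), rep(0.3, ne))
})

test_that("surface transfer is exact for coincident targets and linear fields", {
  bg <- cube_mesh(4, L = 10)
  disp <- cbind(0.1 * bg$vertices[, 1] - 0.05 * bg$vertices[, 2] + 0.3,
                0.02 * bg$vertices[, 3] + 1,
                -0.04 * bg$vertices[, 1] + 0.01 * bg$vertices[, 3])
  # background surface vertices transfer exactly
  sv <- sort(unique(as.vector(bg$boundary_facets)))
  out <- transfer_surface_displacement(bg, disp, bg$vertices[sv, ])
  expect_equal(out, disp[sv, ], tolerance = 1e-12)
  # any target reproduces a globally linear field to 1e-12
  set.seed(5)
  tp <- matrix(runif(45, 0, 10), 15, 3)
  out2 <- transfer_surface_displacement(bg, disp, tp)
  ref <- cbind(0.1 * tp[, 1] - 0.05 * tp[, 2] + 0.3,
               0.02 * tp[, 3] + 1,
               -0.04 * tp[, 1] + 0.01 * tp[, 3])
  expect_equal(out2, ref, tolerance = 1e-12)
  # distant targets warn with a count
  expect_warning(transfer_surface_displacement(bg, disp, matrix(c(50, 50, 50), 1)),
                 "farther")
})

test_that("smooth-field transfer error shrinks near quadratically", {
  f <- function(x) cbind(-0.1 * x[, 1] * sqrt(1 + x[, 3] / 20),
                         -0.1 * x[, 2] * sqrt(1 + x[, 3] / 20),
                         0 * x[, 3])
  errs <- sapply(c(3, 5, 9), function(n) {
    bg <- cube_mesh(n, L = 10)
    set.seed(1)
    tp <- matrix(runif(60, 0.5, 9.5), 20, 3)
    out <- transfer_surface_displacement(bg, f(bg$vertices), tp)
    max(abs(out - f(tp)))
  })
  # halving h should give about a quarter of the error
  expect_lt(errs[2] / errs[1], 0.45)
  expect_lt(errs[3] / errs[2], 0.45)
})

test_that("mesh velocity is the exact first-order difference", {
  d0 <- matrix(1:12, 4, 3)
  d1 <- d0 + 2
  expect_equal(mesh_velocity(d0, d0, 0.5), matrix(0, 4, 3))
  expect_equal(mesh_velocity(d0, d1, 0.5), matrix(4, 4, 3))
  expect_equal(mesh_velocity(d0, d1, 0.25), 2 * mesh_velocity(d0, d1, 0.5))
})

test_that("ejection-scale contraction keeps the stiffened mesh valid", {
  fx <- fx_motion60()
  expect_lt(fx$with$V_ratio, 0.45)        # a 55%+ volume reduction is probed
  expect_equal(sum(fx$with$ninv), 0)      # no inverted elements at any step
  expect_lt(max(fx$with$worst), 1)        # never fully degenerate
  # regression guard: without stiffening the worst quality is no better
  expect_gte(max(fx$without$worst) + 1e-12, max(fx$with$worst))
})
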