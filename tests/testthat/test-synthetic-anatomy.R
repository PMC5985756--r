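test_that("LV generator produces a valid labeled anatomy with the right cavity", {
  lv <- coarse_lv()
  expect_s3_class(lv, "emf_mesh")
  expect_true(all(element_volumes(lv) > 0))
  expect_setequal(unique(lv$element_labels), c("lv", "lvbp", "av", "mv", "cushion"))
  expect_true(all(c("dirichlet", "homogeneous", "rim") %in% lv$facet_tags))

  # cavity volume vs the analytic truncated ellipsoid (default resolution)
  lvd <- make_lv_ellipsoid()
  mand <- attr(lvd, "manifest")
  V_an <- pi * mand$short_axis^2 * mand$long_axis *
    (mand$base_cut - mand$base_cut^3 / 3 + 2 / 3)
  V_num <- sum(element_volumes(submesh(lvd, "lvbp")))
  expect_lt(abs(V_num - V_an) / V_an, 0.03)

  # determinism: same parameters and seed give identical meshes
  man <- attr(lv, "manifest")
  lv2 <- make_lv_ellipsoid(wall_thickness = man$wall_thickness,
                           long_axis = man$long_axis,
                           short_axis = man$short_axis,
                           base_cut = man$base_cut,
                           resolution = man$resolution, seed = man$seed)
  expect_identical(lv2$vertices, lv$vertices)
  expect_identical(lv2$elements, lv$elements)

  # full ellipsoid (no valve plane) is rejected
  expect_error(make_lv_ellipsoid(base_cut = 0), "base_cut")
  # wall too thin for the resolution
  expect_error(make_lv_ellipsoid(wall_thickness = 3, resolution = 8), "coarse")
})

test_that("aorta tube honors the stenosis area relation and grading", {
  severity <- 0.5
  ao <- make_aorta_tube(length = 60, radius = 8, stenosis_severity = severity,
                        resolution = 2.5)
  man <- attr(ao, "manifest")
  rr <- aorta_radius_profile(man, seq(0, 60, by = 0.05))
  expect_equal(min(rr), 8 * sqrt(1 - severity), tolerance = 1e-6)
  # severity 0: constant-radius tube
  m0 <- attr(coarse_tube(), "manifest")
  expect_equal(diff(range(aorta_radius_profile(m0, seq(0, 40, 1)))), 0)
  # lumen volume vs 1-D quadrature of the analytic radius profile
  V_lum <- sum(element_volumes(submesh(ao, "aobp")))
  V_q <- stats::integrate(function(z) pi * aorta_radius_profile(man, z)^2,
                          0, 60)$value
  expect_lt(abs(V_lum - V_q) / V_q, 0.02)
  # outlets must not overlap the stenosis
  expect_error(make_aorta_tube(stenosis_severity = 0.4, stenosis_position = 0.95),
               "overlap")
  # outlet sector tags
  ao3 <- make_aorta_tube(length = 40, radius = 6, n_outlets = 3, resolution = 3)
  expect_setequal(grep("^outlet", unique(ao3$facet_tags), value = TRUE),
                  c("outlet_1", "outlet_2", "outlet_3"))
})

test_that("fiber frames are orthonormal with a linear transmural helix", {
  sol <- solid_submesh(coarse_lv())
  fib <- assign_fibers(sol, endo_angle = -60, epi_angle = 60)
  lvv <- which(sol$element_labels == "lv")
  # orthonormality to 1e-10
  expect_lt(max(abs(rowSums(fib$f0^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(fib$s0^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(fib$n0^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(fib$f0 * fib$s0))), 1e-10)
  expect_lt(max(abs(rowSums(fib$f0 * fib$n0))), 1e-10)
  # helix angle is linear in the transmural coordinate: regression over the
  # wall recovers the endo/epi angles; the midwall value sits at the mean
  fit <- stats::lm(fib$helix_deg[lvv] ~ fib$xi[lvv])
  expect_equal(unname(stats::coef(fit)[1]), -60, tolerance = 1)
  expect_equal(unname(stats::coef(fit)[1] + stats::coef(fit)[2]), 60,
               tolerance = 1)
  # mid-wall value follows the linear rule at the sampled depths
  mid <- lvv[abs(fib$xi[lvv] - 0.5) < 0.25]
  expect_equal(mean(fib$helix_deg[mid]),
               -60 + 120 * mean(fib$xi[mid]), tolerance = 2)
  # constant case: zero angles give circumferential fibers
  fib0 <- assign_fibers(sol, 0, 0)
  expect_lt(max(abs(fib0$helix_deg[lvv])), 1e-8)
  zcomp <- abs(fib0$f0[lvv, 3])
  expect_lt(stats::median(zcomp), 0.15)
})

test_that("CFD cavity is a finer, mildly smoothed, non-conformal copy", {
  lv <- coarse_lv()
  cav <- make_cfd_cavity(lv, refinement = 1.6)
  expect_true(all(element_volumes(cav) > 0))
  expect_setequal(unique(cav$facet_tags), c("wall", "outlet_1"))
  # volume change from smoothing below 2% (against the unsmoothed fine cavity)
  man <- attr(lv, "manifest")
  fine <- make_lv_ellipsoid(wall_thickness = man$wall_thickness,
                            long_axis = man$long_axis,
                            short_axis = man$short_axis,
                            base_cut = man$base_cut,
                            resolution = man$resolution / 1.6)
  V_ref <- sum(element_volumes(submesh(fine, c("av", "lvbp"))))
  V_cav <- sum(element_volumes(cav))
  expect_lt(abs(V_cav - V_ref) / V_ref, 0.02)
  # refinement about 1.6: mean edge length scales accordingly (within 20%)
  em_cavity <- submesh(lv, c("av", "lvbp"))
  ratio <- mean_edge_length(em_cavity) / mean_edge_length(cav)
  expect_gt(ratio, 1.6 * 0.8)
  expect_lt(ratio, 1.6 * 1.2)
  # every CFD surface vertex lies within one EM-element diameter of the EM
  # blood-pool surface (nearest-facet-centroid scan)
  s_em <- surface_of(lv, c("lv", "av", "mv", "cushion"),
                     interface_with = c("lvbp"))
  cen <- (lv$vertices[s_em$facets[, 1], ] + lv$vertices[s_em$facets[, 2], ] +
            lv$vertices[s_em$facets[, 3], ]) / 3
  surfv <- cav$vertices[tagged_vertices(cav, "wall"), ]
  h_em <- mean_edge_length(lv) * 2
  dmax <- max(vapply(seq_len(nrow(surfv)), function(q)
    sqrt(min(rowSums(sweep(cen, 2, surfv[q, ])^2))), numeric(1)))
  expect_lt(dmax, h_em)
  # meshes are non-conformal by construction
  expect_false(nrow(cav$vertices) == nrow(em_cavity$vertices))
})

test_that("Laplacian smoothing is mild and detects inversion", {
  m <- cube_mesh(6)
  sm <- smooth_mesh(m, iterations = 1, factor = 0.15)
  V0 <- sum(element_volumes(m)); V1 <- sum(element_volumes(sm))
  expect_lt(abs(V1 - V0) / V0, 0.05)
  expect_true(all(element_volumes(sm) > 0))
})
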