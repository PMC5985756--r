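test_that("eikonal solver is exact for a planar wave and scales with speed", {
  strip <- rect_mesh(21, 3, Lx = 20, Ly = 2)
  src <- list(vertices = which(strip$vertices[, 1] == 0), t0 = rep(0, 3))
  am <- solve_eikonal(strip, v = conduction_velocities(2, 2, 2), sources = src)
  expect_equal(am$t_a, strip$vertices[, 1] / 2, tolerance = 1e-9)
  # speed scaling: multiplying all speeds by c divides arrival times by c
  am2 <- solve_eikonal(strip, v = conduction_velocities(4, 4, 4), sources = src)
  expect_equal(am2$t_a, am$t_a / 2, tolerance = 1e-9)
  # nonzero initial time shifts the map rigidly
  src5 <- list(vertices = src$vertices, t0 = rep(5, 3))
  am3 <- solve_eikonal(strip, v = conduction_velocities(2, 2, 2), sources = src5)
  expect_equal(am3$t_a, am$t_a + 5, tolerance = 1e-9)
})

test_that("center-source arrival approaches r/v under refinement", {
  err <- sapply(c(11, 21), function(n) {
    sq <- rect_mesh(n, n, Lx = 20, Ly = 20)
    ic <- which.min(rowSums(sweep(sq$vertices, 2, c(10, 10))^2))
    am <- solve_eikonal(sq, v = conduction_velocities(1, 1, 1),
                        sources = list(vertices = ic, t0 = 0))
    r <- sqrt(rowSums(sweep(sq$vertices, 2, sq$vertices[ic, ])^2))
    max(abs(am$t_a - r))
  })
  expect_lt(err[2], err[1])          # refinement reduces the L-infinity error
  expect_lt(err[2], 1.2)             # O(h) accuracy at h = 1 mm
})

test_that("anisotropic arrival times agree with a refined-graph Dijkstra oracle", {
  skip_if_not_installed("igraph")
  expect_lt(fx_eikonal_slab(), 0.05)
})

test_that("reaction model rests at equilibrium and fires on the foot current", {
  par <- monodomain_params(dt_ep = 0.05)
  # no foot, no stimulus: resting potential is constant to 1e-9
  x <- seq(0, 10, by = 1)
  quiet <- simulate_reaction_eikonal(x, t_a = rep(0, 11), params = par,
                                     duration = 40, use_foot = FALSE)
  expect_lt(max(abs(quiet$V - ionic_model()$rest)), 1e-9)
  expect_true(all(is.na(quiet$t_depol)))

  # single cell: foot timed at t_a = 10 ms triggers the upstroke within
  # [t_a - foot duration, t_a + 2]
  cell <- simulate_reaction_eikonal(0, t_a = 10, params = par, duration = 40)
  expect_false(is.na(cell$t_depol))
  expect_gte(cell$t_depol, 10 - par$foot$duration)
  expect_lte(cell$t_depol, 12)

  # blow-up guard: an absurd foot amplitude aborts with a diagnostic
  par_bad <- monodomain_params(dt_ep = 0.05,
                               foot = list(amplitude = 1e9, tau = 2,
                                           duration = 10))
  expect_error(simulate_reaction_eikonal(0, t_a = 5, params = par_bad,
                                         duration = 20), "blow-up")
  # the ten Tusscher interface is declared but not shipped
  expect_error(ionic_model("ten_tusscher"), "not implemented")
})

test_that("reaction-eikonal reproduces the prescribed activation sequence", {
  par <- monodomain_params(dt_ep = 0.05)
  x <- seq(0, 20, by = 1)           # 1 mm cable
  vset <- 0.6                        # mm/ms
  # offset so every node sees its full foot window (the map origin is
  # arbitrary; a clipped foot would delay the first nodes)
  t_a <- x / vset + 15
  re <- simulate_reaction_eikonal(x, t_a = t_a, params = par, duration = 95)
  # depolarization times track t_a within 2 ms at 1 mm resolution
  expect_lt(max(abs(re$t_depol - t_a)), 2)
  # isochrones are linear in x with slope 1/v within 5% (the first few
  # nodes carry a truncated foot window and are excluded as start-up)
  sel <- x >= 5
  fit <- stats::lm(re$t_depol[sel] ~ x[sel])
  expect_equal(unname(stats::coef(fit)[2]), 1 / vset, tolerance = 0.05)
})

test_that("reaction-eikonal beats plain reaction-diffusion on a coarse cable", {
  par <- monodomain_params(dt_ep = 0.05)
  x <- seq(0, 20, by = 1)
  vset <- 0.6
  t_a <- x / vset + 15
  re <- simulate_reaction_eikonal(x, t_a = t_a, params = par, duration = 115)
  rd <- simulate_reaction_eikonal(x, t_a = t_a, params = par, duration = 115,
                                  use_foot = FALSE,
                                  stimulus = list(nodes = 1:2, t0 = 15,
                                                  amplitude = 80000,
                                                  duration = 2))
  err_re <- max(abs(re$t_depol - t_a))
  ok <- !is.na(rd$t_depol)
  expect_true(sum(ok) > 5)           # the R-D wave does propagate
  err_rd <- max(abs(rd$t_depol[ok] - t_a[ok]))
  expect_lt(err_re, err_rd)          # coarse-mesh R-D propagates too slowly
})

test_that("unreachable regions are flagged and bad tensors rejected", {
  strip <- rect_mesh(5, 3, Lx = 4, Ly = 2)
  # second disconnected component
  v2 <- strip$vertices; v2[, 1] <- v2[, 1] + 100
  both <- labeled_mesh(rbind(strip$vertices, v2),
                       rbind(strip$elements, strip$elements + nrow(v2)))
  am <- solve_eikonal(both, v = conduction_velocities(1, 1, 1),
                      sources = list(vertices = 1L, t0 = 0))
  expect_true(any(am$unreached))
  expect_true(all(is.finite(am$t_a[seq_len(nrow(strip$vertices))])))
  expect_error(conduction_velocities(-1, 1, 1), "SPD|positive")
  expect_error(solve_eikonal(strip, sources = list(vertices = integer(0), t0 = numeric(0))),
               "source")
})
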