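test_that("stress-free state is an exact equilibrium", {
  ctx <- coarse_ctx()
  s0 <- solve_quasistatic(ctx, p = 0, Sa = 0)
  expect_equal(s0$iterations, 0L)
  expect_equal(max(abs(s0$d)), 0)
  expect_gt(s0$V, 0)
})

test_that("hydrostatic load on a symmetric block deforms volumetrically only", {
  m <- cube_mesh(3, L = 10)
  m$element_labels[] <- "ao"
  bf <- m$boundary_facets
  ctr <- (m$vertices[bf[, 1], ] + m$vertices[bf[, 2], ] + m$vertices[bf[, 3], ]) / 3
  outer <- ctr[, 1] > 10 - 1e-9 | ctr[, 2] > 10 - 1e-9 | ctr[, 3] > 10 - 1e-9
  m$facet_tags <- ifelse(outer, "pressure_endo", "homogeneous")
  # symmetry rollers on the three coordinate planes
  fx <- which(m$vertices[, 1] < 1e-9); fy <- which(m$vertices[, 2] < 1e-9)
  fz <- which(m$vertices[, 3] < 1e-9)
  fixed <- c(3 * (fx - 1) + 1, 3 * (fy - 1) + 2, 3 * (fz - 1) + 3)
  mats <- list(ao = list(law = "demiray",
                         params = demiray_params(C_tilde = 30, kappa = 100)))
  ctx <- em_context(m, materials = mats, fixed_dofs = fixed)
  sol <- solve_quasistatic(ctx, p = 2, Sa = 0)
  Fv <- cardioemf:::ctx_F(ctx, sol$d)
  # deformation gradient is alpha * I everywhere: deviatoric part vanishes
  alpha <- mean(Fv[, 1])
  expect_false(isTRUE(all.equal(alpha, 1)))
  dev <- Fv - alpha * cardioemf:::t3_eye(nrow(Fv))
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("pressurized thick sphere matches the radial ODE oracle", {
  Ri <- 10; Ro <- 15
  pars <- demiray_params(C_tilde = 30, kappa = 100)
  p_load <- 6  # kPa
  # --- oracle: compressible spherically-symmetric equilibrium by shooting ---
  sigma_rt <- function(lr, lt) {
    F <- diag(c(lr, lt, lt))
    S <- pk2_passive(deformation_state(F), "demiray", pars)
    J <- lr * lt^2
    c(r = lr^2 * S[1, 1] / J, t = lt^2 * S[2, 2] / J)
  }
  lr_of <- function(sr, lt) {
    stats::uniroot(function(lr) sigma_rt(lr, lt)["r"] - sr,
                   c(0.2, 5), tol = 1e-12)$root
  }
  shoot <- function(ri) {
    n <- 400
    Rs <- seq(Ri, Ro, length.out = n + 1)
    h <- Rs[2] - Rs[1]
    y <- c(ri, -p_load)
    deriv <- function(R, y) {
      lt <- y[1] / R
      lr <- lr_of(y[2], lt)
      st <- sigma_rt(lr, lt)
      c(lr, -2 * (y[2] - st["t"]) / y[1] * lr)
    }
    for (k in seq_len(n)) {  # RK4
      k1 <- deriv(Rs[k], y)
      k2 <- deriv(Rs[k] + h / 2, y + h / 2 * k1)
      k3 <- deriv(Rs[k] + h / 2, y + h / 2 * k2)
      k4 <- deriv(Rs[k] + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  ri_star <- stats::uniroot(function(ri) shoot(ri)[2], c(Ri, 1.35 * Ri),
                            tol = 1e-8)$root
  u_oracle <- ri_star - Ri

  # --- FE: octant with symmetry rollers, inner follower pressure ---
  m <- sphere_octant_mesh(Ri, Ro, nr = 4, nt = 11, np = 11)
  fx <- which(abs(m$vertices[, 1]) < 1e-6)
  fy <- which(abs(m$vertices[, 2]) < 1e-6)
  fz <- which(abs(m$vertices[, 3]) < 1e-6)
  fixed <- c(3 * (fx - 1) + 1, 3 * (fy - 1) + 2, 3 * (fz - 1) + 3)
  ctx <- em_context(m, materials = list(ao = list(law = "demiray", params = pars)),
                    fixed_dofs = fixed)
  sol <- inflate_to(ctx, p_load, step_kPa = 1)
  inner_v <- which(abs(sqrt(rowSums(m$vertices^2)) - Ri) < 1e-6)
  r_new <- sqrt(rowSums((m$vertices[inner_v, ] + sol$d[inner_v, ])^2))
  u_fe <- mean(r_new) - Ri
  expect_gt(u_oracle, 0.3)           # an appreciable expansion is probed
  expect_lt(abs(u_fe - u_oracle) / u_oracle, 0.03)
})

test_that("cavity volume: analytic value, rigid-motion invariance, scaling", {
  # closed tagged surface of the coarse LV solid
  sol <- solid_submesh(coarse_lv())
  V0 <- cavity_volume(sol)
  man <- attr(coarse_lv(), "manifest")
  a <- man$long_axis; b <- man$short_axis; f <- man$base_cut
  V_an <- pi * b^2 * a * (f - f^3 / 3 + 2 / 3) / 1000
  expect_lt(abs(V0 - V_an) / V_an, 0.05)  # includes the thin valve layer lid
  # rigid translation leaves the volume unchanged to 1e-10
  d_tr <- matrix(rep(c(3, -2, 5), each = nrow(sol$vertices)), ncol = 3)
  expect_equal(cavity_volume(sol, d_tr), V0, tolerance = 1e-10)
  # uniform scaling by alpha scales the volume by alpha^3 exactly
  alpha <- 1.23
  d_sc <- (alpha - 1) * sol$vertices
  expect_equal(cavity_volume(sol, d_sc), alpha^3 * V0, tolerance = 1e-10)
  # open surface with a single ring is closed by the fan lid
  cav <- make_cfd_cavity(coarse_lv(), refinement = 1.3)
  V_wall_lid <- cavity_volume(cav, tag = "wall")
  V_cells <- sum(element_volumes(cav)) / 1000
  expect_lt(abs(V_wall_lid - V_cells) / V_cells, 1e-6)
  # two open rings cannot be closed by one lid
  tube <- coarse_tube()
  lum <- submesh(tube, "aobp", interface_tag = "wall")
  expect_error(cavity_volume(lum, tag = "wall"), "boundary edges")
})

test_that("Klotz relation: limits, derived value, monotonicity", {
  expect_equal(klotz_v0(100, 10)$V_0, 54)          # direct evaluation
  expect_equal(klotz_v0(100, 1e-9)$V_0, 60, tolerance = 1e-6)
  v0s <- sapply(c(5, 10, 20, 40), function(pm) klotz_v0(90, pm)$V_0)
  expect_true(all(diff(v0s) < 0))
  expect_error(klotz_v0(100, 120), "100 mmHg")
  # normalized curve passes through the measured point
  kl <- klotz_v0(100, 10)
  expect_equal(kl$P_of_V(100), 10, tolerance = 1e-9)
})

test_that("backward-displacement unloading inverts inflation", {
  lv <- coarse_lv()
  sol <- solid_submesh(lv)
  # p = 0: the reference equals the input after one iteration
  un0 <- unload_backward_displacement(sol, 0)
  expect_equal(un0$iterations, 1L)
  expect_equal(un0$mesh$vertices, sol$vertices)
  # moderate pressure: the round trip reproduces the input geometry
  p_ED <- mmHg_to_kPa(6)
  un <- unload_backward_displacement(sol, p_ED, tol = 1e-3)
  expect_lt(un$V0, cavity_volume(sol))
  reinf <- un$check   # final inflation of the returned reference
  expect_lt(max(row_norm(un$mesh$vertices + reinf$d - sol$vertices)), 2e-3)
  # small pressure: the relaxed fixed point contracts to within 10x the
  # tolerance within a few iterations
  un_small <- unload_backward_displacement(sol, 0.05, tol = 1e-4,
                                           max_iter = 8)
  expect_lt(un_small$updates[min(5L, length(un_small$updates))], 1e-3)
  expect_lt(un_small$updates[length(un_small$updates)],
            un_small$updates[1])
})

test_that("stiffness fitting sweeps the grid and reports the best trial", {
  sol <- solid_submesh(coarse_lv())
  # degenerate one-value grid returns that value with its error
  fit1 <- suppressWarnings(
    fit_cguc(sol, p_ED = mmHg_to_kPa(8), trial_grid = 1.0))
  expect_equal(fit1$C_Guc, 1.0)
  expect_true(is.finite(fit1$rel_error))
  # stiffer material inflates less, so its unloaded volume is larger
  fit3 <- suppressWarnings(
    fit_cguc(sol, p_ED = mmHg_to_kPa(8), trial_grid = c(0.3, 3.0),
             max_refine = 0L, unload_tol = 5e-3))
  tab <- fit3$table[order(fit3$table$C_Guc), ]
  expect_true(all(diff(tab$V0_model) > 0))
})

test_that("a heartbeat walks through all phases with consistent bookkeeping", {
  hb <- coarse_heartbeat()
  ph <- rle(as.character(hb$trace$phase))$values
  expect_equal(ph, c("IVC", "ejection", "IVR"))
  m <- hb$metrics
  # ejection fraction identity from the volume-trace extremes
  expect_equal(m$SV, m$EDV - m$ESV)
  expect_equal(m$EF, 100 * (m$EDV - min(hb$trace$V_lv_ml)) / m$EDV)
  expect_gt(m$EF, 20)
  # during IVC the cavity volume is held within 0.1%
  ivc <- hb$trace[hb$trace$phase == "IVC", ]
  expect_lt(max(abs(ivc$V_lv_ml - m$EDV)) / m$EDV, 1e-3)
  # valve events ordered
  expect_lt(m$valve_open_t, m$valve_close_t)
})

test_that("zero active stress never opens the valve", {
  hb0 <- run_heartbeat(coarse_ctx(), coarse_activation(),
                       act = active_params(S_peak = 0), dt = 8, t_end = 120,
                       wk = windkessel_lv(R_av = 1),
                       store_displacements = FALSE)
  expect_true(all(hb0$trace$phase == "IVC"))
  expect_true(is.na(hb0$metrics$valve_open_t))
  expect_lt(max(abs(hb0$trace$V_lv_ml - hb0$metrics$EDV)) / hb0$metrics$EDV,
            1e-3)
})

test_that("ejection work matches the Windkessel-side energy bookkeeping", {
  bal <- wk_energy_balance(coarse_heartbeat())
  expect_gt(bal$lv_work, 0)
  expect_lt(bal$rel_gap, 0.02)
})

test_that("halving the mechanics step barely moves the end-systolic volume", {
  fx <- fx_dt_invariance()
  expect_lt(abs(fx$esv4 - fx$esv8) / fx$esv8, 0.005)
})

test_that("active-stress fitting recovers forward-model parameters", {
  fx <- fx_fit_active()
  expect_equal(fx$fit$params$S_peak, fx$truth$S_peak)
  expect_equal(fx$fit$params$tau_c0, fx$truth$tau_c0)
  # zero budget returns the starting parameters untouched
  f0 <- fit_active(coarse_ctx(), coarse_activation(),
                   params0 = active_params(S_peak = 77), targets = fx$targets,
                   budget = 0)
  expect_equal(f0$params$S_peak, 77)
  expect_equal(f0$evaluations, 0L)
})
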