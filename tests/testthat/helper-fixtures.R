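# Shared fixtures, built lazily and cached for the whole test run.

fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# structured 2D rectangle mesh of right triangles
rect_mesh <- function(nx, ny, Lx = 10, Ly = 2, tag_fun = NULL) {
  xs <- seq(0, Lx, length.out = nx)
  ys <- seq(0, Ly, length.out = ny)
  vg <- as.matrix(expand.grid(x = xs, y = ys))
  idx <- function(i, j) (j - 1) * nx + i
  tri <- matrix(0L, 2 * (nx - 1) * (ny - 1), 3)
  k <- 0L
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    tri[k + 1L, ] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
    tri[k + 2L, ] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    k <- k + 2L
  }
  m <- labeled_mesh(vg, tri, rep("aobp", nrow(tri)))
  if (!is.null(tag_fun)) {
    bf <- m$boundary_facets
    ctr <- (vg[bf[, 1], , drop = FALSE] + vg[bf[, 2], , drop = FALSE]) / 2
    m$facet_tags <- tag_fun(ctr)
  }
  m
}

channel_mesh <- function(nx = 21, ny = 9, Lx = 10, Ly = 2) {
  rect_mesh(nx, ny, Lx, Ly, tag_fun = function(ctr) {
    tags <- rep("wall", nrow(ctr))
    tags[ctr[, 1] < 1e-9] <- "inlet"
    tags[ctr[, 1] > Lx - 1e-9] <- "outlet_1"
    tags
  })
}

# structured cube mesh of tetrahedra (n points per edge), unit cube scaled
cube_mesh <- function(n = 4, L = 1) {
  xs <- seq(0, L, length.out = n)
  g <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  idx <- function(i, j, k) (k - 1) * n * n + (j - 1) * n + i
  hexes <- list()
  for (k in 1:(n - 1)) for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    hexes[[length(hexes) + 1L]] <- c(
      idx(i, j, k), idx(i + 1, j, k), idx(i, j + 1, k), idx(i + 1, j + 1, k),
      idx(i, j, k + 1), idx(i + 1, j, k + 1), idx(i, j + 1, k + 1),
      idx(i + 1, j + 1, k + 1))
  }
  parts <- cardioemf:::build_tet_mesh(g, do.call(rbind, hexes),
                                      rep("lv", length(hexes)))
  labeled_mesh(parts$vertices, parts$elements, parts$labels)
}

# octant of a thick spherical shell (Ri..Ro), symmetry planes on x=0, y=0,
# z=0; inner surface tagged pressure_endo
sphere_octant_mesh <- function(Ri = 10, Ro = 15, nr = 3, nt = 6, np = 6) {
  pts <- list(); hexes <- list(); cnt <- 0L
  id_of <- function(k, t, p) ((k) * (nt + 1) + t) * (np + 1) + p + 1L
  for (k in 0:nr) for (t in 0:nt) for (p in 0:np) {
    r <- Ri + (Ro - Ri) * k / nr
    th <- (pi / 2) * t / nt       # 0 = +z pole, pi/2 = equator
    ph <- (pi / 2) * p / np
    pts[[id_of(k, t, p)]] <- c(r * sin(th) * cos(ph), r * sin(th) * sin(ph),
                               r * cos(th))
  }
  for (k in 1:nr) for (t in 1:nt) for (p in 1:np) {
    hexes[[length(hexes) + 1L]] <- c(
      id_of(k - 1, t - 1, p - 1), id_of(k, t - 1, p - 1),
      id_of(k - 1, t, p - 1), id_of(k, t, p - 1),
      id_of(k - 1, t - 1, p), id_of(k, t - 1, p),
      id_of(k - 1, t, p), id_of(k, t, p))
  }
  parts <- cardioemf:::build_tet_mesh(do.call(rbind, pts),
                                      do.call(rbind, hexes),
                                      rep("ao", length(hexes)))
  m <- labeled_mesh(parts$vertices, parts$elements, parts$labels)
  bf <- m$boundary_facets
  ctr <- (m$vertices[bf[, 1], ] + m$vertices[bf[, 2], ] +
            m$vertices[bf[, 3], ]) / 3
  rr <- sqrt(rowSums(ctr^2))
  tags <- rep("homogeneous", nrow(bf))
  tags[rr < Ri + 0.25 * (Ro - Ri)] <- "pressure_endo"
  m$facet_tags <- tags
  m
}

# coarse LV used across the mechanics tests (cheap but full-featured)
coarse_lv <- function() fixture("coarse_lv", function() {
  make_lv_ellipsoid(wall_thickness = 12, long_axis = 45, short_axis = 26,
                    base_cut = 0.3, resolution = 12)
})

coarse_ctx <- function() fixture("coarse_ctx", function() {
  # the beating simulations clamp the basal ring: the surrogate for the
  # atrial/aortic tether that the isolated-LV anatomy lacks
  em_context(solid_submesh(coarse_lv()), dirichlet_tags = c("dirichlet", "rim"))
})

coarse_activation <- function() fixture("coarse_activation", function() {
  ctx <- coarse_ctx()
  solve_eikonal(ctx$mesh, ctx$fibers, conduction_velocities(),
                apical_source(ctx$mesh), region = "lv")
})

# one shared heartbeat run (coarse mesh, 10 ms steps)
coarse_heartbeat <- function() fixture("coarse_heartbeat", function() {
  run_heartbeat(coarse_ctx(), coarse_activation(), dt = 10, t_end = 600,
                wk = windkessel_lv(R_av = 1),
                act = active_params(S_peak = 60), store_stride = 2L)
})

coarse_tube <- function() fixture("coarse_tube", function() {
  make_aorta_tube(length = 40, radius = 6, resolution = 3, n_outlets = 1)
})

# ---- heavy shared computations (built once, asserted from several tests) ----

fx_poiseuille <- function() fixture("fx_poiseuille", function() {
  m <- channel_mesh(41, 17)
  props <- fluid_props()
  dp <- 0.4
  state <- new_flow_state(m)
  for (k in 1:150) {
    state <- step_ale_ns(state, m, dt = 4, props = props, wall_tags = "wall",
                         traction_tags = list(inlet = dp, outlet_1 = 0))
  }
  umax_an <- dp * (2e-3)^2 / (8 * props$mu * 1e-2)
  sel <- abs(m$vertices[, 1] - 5) < 1e-9
  list(mesh = m, state = state, umax_an = umax_an,
       prof = state$u[sel, 1], uy = state$u[sel, 2],
       y = m$vertices[sel, 2] * 1e-3)
})

fx_taylor_green <- function() fixture("fx_taylor_green", function() {
  n <- 41
  xs <- seq(0, 10, length.out = n)
  vg <- as.matrix(expand.grid(x = xs, y = xs))
  idx <- function(i, j) (j - 1) * n + i
  tri <- matrix(0L, 2 * (n - 1)^2, 3); k <- 0L
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    tri[k + 1L, ] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
    tri[k + 2L, ] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    k <- k + 2L
  }
  m <- labeled_mesh(vg, tri, rep("aobp", nrow(tri)))
  props <- fluid_props()
  nu <- props$mu / props$rho
  kw <- 2 * pi / 0.01; U0 <- 0.05
  uex <- function(t) {
    xy <- m$vertices * 1e-3
    dec <- exp(-2 * nu * kw^2 * t)
    cbind(U0 * sin(kw * xy[, 1]) * cos(kw * xy[, 2]),
          -U0 * cos(kw * xy[, 1]) * sin(kw * xy[, 2])) * dec
  }
  bv <- sort(unique(as.vector(m$boundary_facets)))
  state <- new_flow_state(m, u0 = uex(0))
  dt <- 5; ns <- 20
  for (k in 1:ns) {
    state <- step_ale_ns(state, m, dt = dt, props = props,
                         wall_tags = character(0),
                         dirichlet = list(vertices = bv,
                                          values = uex(k * dt * 1e-3)[bv, ]))
  }
  M <- assemble_mass(m)
  ke <- function(u) sum(u[, 1] * (M %*% u[, 1])) + sum(u[, 2] * (M %*% u[, 2]))
  rate_num <- -log(ke(state$u) / ke(uex(0))) / (ns * dt * 1e-3)
  list(rate_num = rate_num, rate_ex = 4 * nu * kw^2)
})

fx_freestream <- function() fixture("fx_freestream", function() {
  m <- cube_mesh(4, L = 8)
  m$element_labels[] <- "aobp"
  U <- c(0.3, 0.1, -0.2)
  bv <- sort(unique(as.vector(m$boundary_facets)))
  state <- new_flow_state(m, u0 = matrix(U, nrow(m$vertices), 3, byrow = TRUE))
  wvel <- c(0.25, -0.1, 0.05)
  for (k in 1:8) {
    dnew <- matrix(wvel * k, nrow(m$vertices), 3, byrow = TRUE)
    state <- step_ale_ns(state, m, d_new = dnew, dt = 1,
                         wall_tags = character(0),
                         dirichlet = list(vertices = bv,
                                          values = matrix(U, length(bv), 3,
                                                          byrow = TRUE)))
  }
  max(abs(sweep(state$u, 2, U)))
})

fx_tube_balance <- function() fixture("fx_tube_balance", function() {
  ao <- make_aorta_tube(length = 40, radius = 6, resolution = 3)
  lum <- submesh(ao, "aobp", interface_tag = "wall")
  lum$facet_tags[lum$facet_tags == "interface"] <- "wall"
  X <- lum$vertices
  motion <- function(t) {
    s <- 0.12 * sin(pi * min(t, 80) / 160)^2
    d <- X * 0
    d[, 1] <- -X[, 1] * s
    d[, 2] <- -X[, 2] * s
    d
  }
  vol_of <- function(t) sum(abs(element_volumes(lum, X + motion(t)))) / 1000
  wk <- outlet_windkessel(R_i = 100, Z_i = 5, C_i = 1)
  state <- new_flow_state(lum)
  state$d_mesh <- motion(0)
  dt <- 0.5
  rels <- c()
  for (k in 1:80) {
    t_new <- k * dt
    state <- step_ale_ns(state, lum, d_new = motion(t_new),
                         outlets = list(outlet_1 = wk), dt = dt)
    wk <- state$outlets$outlet_1
    if (t_new >= 15) {
      qnow <- flux_through(lum, state$u, tag = "outlet_1",
                           d_mesh = motion(t_new)) / 1000
      dVdt <- -(vol_of(t_new + dt) - vol_of(t_new - dt)) / (2 * dt)
      rels <- c(rels, abs(qnow - dVdt) / abs(dVdt))
    }
  }
  max(rels)
})

fx_motion60 <- function() fixture("fx_motion60", function() {
  lv <- coarse_lv()
  cav <- make_cfd_cavity(lv, refinement = 1.2)
  X <- cav$vertices
  zc <- max(X[, 3])
  # apex-weighted squeeze with a partially mobile basal ring (a hard-fixed
  # ring is harsher than any real annulus and shears the mesh apart)
  weight <- 0.35 + 0.65 * pmin(pmax((zc - X[, 3]) / (zc - min(X[, 3])), 0), 1)
  contract <- function(s) {
    d <- matrix(0, nrow(X), 3)
    shrink <- 1 - s * 0.5 * weight
    d[, 1] <- X[, 1] * (shrink - 1)
    d[, 2] <- X[, 2] * (shrink - 1)
    d[, 3] <- s * 0.3 * weight * (zc - X[, 3])
    d
  }
  V0 <- sum(abs(element_volumes(cav)))
  run_quality <- function(stiffen) {
    d_prev <- NULL
    worst <- c(); ninv <- c()
    bidx <- sort(unique(as.vector(cav$boundary_facets)))
    for (s in seq(0.1, 1, by = 0.1)) {
      dfull <- contract(s)
      bval <- dfull[bidx, ]
      E_el <- NULL; nu_el <- NULL
      if (stiffen) {
        qs <- quality_stiffen(cav, d_prev, E0 = 100)
        E_el <- qs$E
        nu_el <- nu_volume_stiffen(cav,
                                   abs(element_volumes(cav, X + (d_prev %||% 0))),
                                   abs(element_volumes(cav)),
                                   pseudo_elastic_params())
      }
      d_new <- solve_pseudo_elastic(cav, list(vertices = bidx, values = bval),
                                    E_elem = E_el, nu_elem = nu_el)
      q <- element_quality(cav, X + d_new)
      worst <- c(worst, max(q$rescaled))
      ninv <- c(ninv, sum(q$inverted))
      d_prev <- d_new
    }
    Vend <- sum(abs(element_volumes(cav, X + d_prev)))
    list(worst = worst, ninv = ninv, V_ratio = Vend / V0)
  }
  list(with = run_quality(TRUE), without = run_quality(FALSE))
})

fx_eikonal_slab <- function() fixture("fx_eikonal_slab", function() {
  lx <- 16; ly <- 8; lz <- 4
  mk_box <- function(h) {
    nx <- lx / h + 1; ny <- ly / h + 1; nz <- lz / h + 1
    g <- as.matrix(expand.grid(x = seq(0, lx, by = h), y = seq(0, ly, by = h),
                               z = seq(0, lz, by = h)))
    idx <- function(i, j, k) (k - 1) * nx * ny + (j - 1) * nx + i
    hexes <- list()
    for (k in 1:(nz - 1)) for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
      hexes[[length(hexes) + 1L]] <- c(
        idx(i, j, k), idx(i + 1, j, k), idx(i, j + 1, k), idx(i + 1, j + 1, k),
        idx(i, j, k + 1), idx(i + 1, j, k + 1), idx(i, j + 1, k + 1),
        idx(i + 1, j + 1, k + 1))
    }
    parts <- cardioemf:::build_tet_mesh(g, do.call(rbind, hexes),
                                        rep("lv", length(hexes)))
    labeled_mesh(parts$vertices, parts$elements, parts$labels)
  }
  box <- mk_box(0.5)
  v <- conduction_velocities(v_f = 0.8, v_s = 0.4, v_n = 0.4)
  src_pt <- c(0, 0, 0)
  isrc <- which(rowSums(sweep(box$vertices, 2, src_pt)^2) < 1e-9)
  am <- solve_eikonal(box, fibers = NULL, v = v,
                      sources = list(vertices = isrc, t0 = 0))
  # oracle: Dijkstra on a 4x refined lattice graph with chords up to two
  # cells long (a rich direction set keeps the graph-metric bias small),
  # edge weights from the anisotropic metric sqrt(d' V^-1 d)
  hf <- 0.5
  nx <- lx / hf + 1; ny <- ly / hf + 1; nz <- lz / hf + 1
  gf <- as.matrix(expand.grid(x = seq(0, lx, by = hf), y = seq(0, ly, by = hf),
                              z = seq(0, lz, by = hf)))
  idx <- function(i, j, k) (k - 1) * nx * ny + (j - 1) * nx + i
  offs <- as.matrix(expand.grid(di = -3:3, dj = -3:3, dk = 0:3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                 (offs[, 2] == 0 & offs[, 1] > 0))), ]  # one per direction pair
  g3 <- function(a, b, c) {  # primitive directions only (chords compose)
    out <- integer(length(a))
    for (q in seq_along(a)) {
      v <- abs(c(a[q], b[q], c[q])); v <- v[v > 0]
      out[q] <- Reduce(function(x, y) {
        while (y) { t <- x %% y; x <- y; y <- t }; x
      }, v)
    }
    out
  }
  offs <- offs[g3(offs[, 1], offs[, 2], offs[, 3]) == 1L, ]
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  base <- as.matrix(expand.grid(i = 1:nx, j = 1:ny, k = 1:nz))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- base[, 1] + o[1] >= 1 & base[, 1] + o[1] <= nx &
      base[, 2] + o[2] >= 1 & base[, 2] + o[2] <= ny &
      base[, 3] + o[3] >= 1 & base[, 3] + o[3] <= nz
    b <- base[ok, , drop = FALSE]
    from <- idx(b[, 1], b[, 2], b[, 3])
    to <- idx(b[, 1] + o[1], b[, 2] + o[2], b[, 3] + o[3])
    dvec <- hf * o
    wlen <- sqrt(dvec[1]^2 / v$v_f^2 + (dvec[2]^2 + dvec[3]^2) / v$v_s^2)
    ii <- c(ii, from); jj <- c(jj, to); ww <- c(ww, rep(wlen, length(from)))
  }
  gr <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  ifine <- which(rowSums(sweep(gf, 2, src_pt)^2) < 1e-9)
  dist_fine <- igraph::distances(gr, v = ifine, weights = ww)[1, ]
  key_c <- apply(round(box$vertices, 6), 1, paste, collapse = "_")
  key_f <- apply(round(gf, 6), 1, paste, collapse = "_")
  t_oracle <- dist_fine[match(key_c, key_f)]
  # compare in the far field: the point-source cone carries an O(h/r)
  # error that is a property of first-arrival discretizations, not of the
  # anisotropy handling under test
  sel <- t_oracle > 9
  max(abs(am$t_a[sel] - t_oracle[sel]) / t_oracle[sel])
})

fx_klotz_fit <- function() fixture("fx_klotz_fit", function() {
  suppressWarnings(fit_cguc(solid_submesh(coarse_lv()), p_ED = mmHg_to_kPa(10),
                            trial_grid = c(0.25, 0.7), max_refine = 2L))
})

fx_fit_active <- function() fixture("fx_fit_active", function() {
  ctx <- coarse_ctx()
  am <- coarse_activation()
  truth <- active_params(S_peak = 60, tau_c0 = 30)
  fwd <- run_heartbeat(ctx, am, act = truth, wk = windkessel_lv(R_av = 1),
                       dt = 10, t_end = 360, store_displacements = FALSE)
  targets <- list(p_peak = fwd$metrics$p_peak, dpdt_max = fwd$metrics$dpdt_max)
  fit <- suppressWarnings(
    fit_active(ctx, am, params0 = truth, targets = targets,
               S_peak_grid = c(45, 60), tau_c0_grid = c(30, 42),
               wk = windkessel_lv(R_av = 1), dt = 10, t_end = 360,
               store_displacements = FALSE))
  list(truth = truth, fit = fit, targets = targets)
})

fx_dt_invariance <- function() fixture("fx_dt_invariance", function() {
  hb5 <- run_heartbeat(coarse_ctx(), coarse_activation(), dt = 5, t_end = 600,
                       wk = windkessel_lv(R_av = 1),
                       act = active_params(S_peak = 60),
                       store_displacements = FALSE)
  hb2 <- run_heartbeat(coarse_ctx(), coarse_activation(), dt = 2.5,
                       t_end = 600, wk = windkessel_lv(R_av = 1),
                       act = active_params(S_peak = 60),
                       store_displacements = FALSE)
  list(esv8 = hb5$metrics$ESV, esv4 = hb2$metrics$ESV)
})

fx_tg_convergence <- function() fixture("fx_tg_convergence", function() {
  props <- fluid_props()
  nu <- props$mu / props$rho
  one <- function(n, dt, Ttot = 20) {
    xs <- seq(0, 10, length.out = n)
    vg <- as.matrix(expand.grid(x = xs, y = xs))
    idx <- function(i, j) (j - 1) * n + i
    tri <- matrix(0L, 2 * (n - 1)^2, 3); k <- 0L
    for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
      tri[k + 1L, ] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      tri[k + 2L, ] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
      k <- k + 2L
    }
    m <- labeled_mesh(vg, tri, rep("aobp", nrow(tri)))
    kw <- 2 * pi / 0.01; U0 <- 0.05
    uex <- function(t) {
      xy <- m$vertices * 1e-3; dec <- exp(-2 * nu * kw^2 * t)
      cbind(U0 * sin(kw * xy[, 1]) * cos(kw * xy[, 2]),
            -U0 * cos(kw * xy[, 1]) * sin(kw * xy[, 2])) * dec
    }
    bv <- sort(unique(as.vector(m$boundary_facets)))
    st <- new_flow_state(m, u0 = uex(0))
    ns <- round(Ttot / dt)
    for (k in 1:ns) {
      st <- step_ale_ns(st, m, dt = dt, props = props,
                        wall_tags = character(0),
                        dirichlet = list(vertices = bv,
                                         values = uex(k * dt * 1e-3)[bv, ]))
    }
    sqrt(mean((st$u - uex(ns * dt * 1e-3))^2))
  }
  # dt scaled with h^2 so the first-order time error refines faster
  list(errs = c(one(11, 4), one(21, 1), one(41, 0.25)))
})
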