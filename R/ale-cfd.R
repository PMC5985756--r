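#' Stabilized finite-element flow solver on moving meshes
#'
#' Equal-order (P1-P1) incompressible Navier-Stokes with residual-based
#' variational multiscale (RBVMS) stabilization in arbitrary
#' Lagrangian-Eulerian form: the mesh velocity w is subtracted from the
#' convective velocity, wall velocities are imposed strongly, outlets carry
#' Windkessel tractions with backflow stabilization, and time stepping is a
#' cheap semi-implicit scheme (BDF1 with extrapolated convection) so each
#' step costs one linear solve. Internally the solver works in SI units
#' (m, s, Pa); meshes stay in mm and are converted on entry.
#'
#' @name ale_cfd
NULL

#' Fluid properties
#' @param rho_f blood density (kg/m^3).
#' @param mu_f dynamic viscosity (Pa s).
#' @param beta_backflow backflow stabilization parameter.
#' @return list of class \code{fluid_props}.
#' @export
fluid_props <- function(rho_f = 1060, mu_f = 0.004, beta_backflow = 0.2) {
  stopifnot(rho_f > 0, mu_f > 0, beta_backflow >= 0)
  structure(list(rho = rho_f, mu = mu_f, beta = beta_backflow),
            class = "fluid_props")
}

#' VMS stabilization parameters
#' @param C_M constant of the viscous branch of tau_MOM.
#' @param dt time step (ms).
#' @return list of class \code{vms_params}.
#' @export
vms_params <- function(C_M = 0.0285, dt = 0.5) {
  structure(list(C_M = C_M, dt = dt), class = "vms_params")
}

# simplex covariant metric G = J^-T K J^-1 and vector g per element, from
# the P1 gradients (which are the rows of d xi/d x up to the affine map).
# Returns per-element G (n x d^2 column-major) and g (n x d), plus G:G.
element_metric <- function(gp) {
  d <- gp$dim
  # d xi_k / d x_i = grads[[k+1]][, i] for the reference simplex with
  # vertices (0, e_1, ..., e_d)
  n <- nrow(gp$grads[[1]])
  Kc <- 2^(2 / 3) / 2 * (diag(d) * 4 - matrix(1, d, d)) # 3 on diag, -1 off
  G <- matrix(0, n, d * d)
  g <- matrix(0, n, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    acc <- 0
    for (k in seq_len(d)) for (l in seq_len(d)) {
      acc <- acc + gp$grads[[k + 1L]][, i] * Kc[k, l] * gp$grads[[l + 1L]][, j]
    }
    G[, i + d * (j - 1L)] <- acc
  }
  for (i in seq_len(d)) {
    gi <- 0
    for (k in seq_len(d)) gi <- gi + gp$grads[[k + 1L]][, i]
    g[, i] <- gi
  }
  list(G = G, g = g, GG = rowSums(G^2), gg = rowSums(g^2))
}

#' VMS stabilization parameters tau_MOM and tau_CONT
#'
#' tau_MOM is the minimum of the transient-advective branch
#' (4/dt^2 + u_rel . G u_rel)^(-1/2) and the diffusive-limit branch
#' rho / (C_M mu sqrt(G:G)); tau_CONT = 1 / (tau_MOM g.g).
#'
#' @param u_rel relative (convective) velocity per element (n x d, m/s).
#' @param metric the per-element metric from \code{element_metric}.
#' @param props \code{\link{fluid_props}}.
#' @param dt time step (s).
#' @param C_M stabilization constant.
#' @return list with \code{tau_mom} (s) and \code{tau_cont}.
#' @export
vms_tau <- function(u_rel, metric, props, dt, C_M = 0.0285) {
  d <- ncol(u_rel)
  uGu <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) {
    uGu <- uGu + u_rel[, i] * metric$G[, i + d * (j - 1L)] * u_rel[, j]
  }
  tr_branch <- (4 / dt^2 + uGu)^(-1 / 2)
  visc_branch <- props$rho / (C_M * props$mu * sqrt(metric$GG))
  tau_mom <- pmin(tr_branch, visc_branch)
  list(tau_mom = tau_mom, tau_cont = 1 / (tau_mom * metric$gg))
}

new_flow_state <- function(mesh, u0 = NULL, p0 = NULL) {
  nv <- nrow(mesh$vertices)
  d <- mesh$dim
  list(u = u0 %||% matrix(0, nv, d), p = p0 %||% numeric(nv),
       d_mesh = matrix(0, nv, d), t = 0,
       u_prev = NULL)
}

# moving least-squares gradient recovery: per vertex, fit a linear model to
# the incident element-centroid gradient samples (volume weighted); exact
# whenever the underlying gradient field is (piecewise sampled from) linear
recover_gradient_ls <- function(mesh, Gu, coords, vol) {
  d <- mesh$dim
  el <- mesh$elements
  nv <- nrow(coords)
  nn <- d + 1L
  cen <- 0
  for (a in seq_len(nn)) cen <- cen + coords[el[, a], , drop = FALSE] / nn
  inc <- split(rep(seq_len(nrow(el)), nn), as.vector(el))
  out <- matrix(0, nv, d * d)
  for (v in seq_len(nv)) {
    ids <- inc[[as.character(v)]]
    if (is.null(ids)) next
    X <- cbind(1, sweep(cen[ids, , drop = FALSE], 2, coords[v, ]))
    w <- vol[ids]
    A <- crossprod(X * sqrt(w))
    ok <- length(ids) > d && rcond(A) > 1e-10
    for (cc in seq_len(d * d)) {
      y <- Gu[ids, cc]
      out[v, cc] <- if (ok) {
        solve(A, crossprod(X * w, y))[1]
      } else sum(w * y) / sum(w)
    }
  }
  out
}

# facet data for a tag selection on displaced coordinates
facet_data <- function(mesh, coords, tags) {
  sel <- mesh$facet_tags %in% tags
  fac <- mesh$boundary_facets[sel, , drop = FALSE]
  geo <- facet_geometry(coords, fac, mesh$dim)
  list(facets = fac, normals = geo$normals, areas = geo$areas)
}

#' One semi-implicit step of the ALE Navier-Stokes system
#'
#' Assembles and solves the P1-P1 RBVMS system on the displaced mesh:
#' implicit viscous/pressure/SUPG-PSPG/grad-div terms, convection with the
#' previous step's velocity relative to the mesh, backflow-stabilized
#' outlet tractions from Windkessel pressures driven by the previous step's
#' flux, and strongly imposed wall velocity equal to the mesh velocity.
#' The third and fourth VMS terms (cross and fine-scale Reynolds stress)
#' are assembled explicitly from the previous step's residual.
#'
#' @param state flow state (see \code{\link{new_flow_state}}).
#' @param mesh the fluid \code{emf_mesh} (reference, mm).
#' @param d_new mesh displacement at the new time level (mm; zero matrix
#'   for a static mesh).
#' @param outlets named list tag -> \code{\link{outlet_windkessel}} (states
#'   are advanced and returned), or NULL.
#' @param props \code{\link{fluid_props}}.
#' @param dt time step (ms).
#' @param wall_tags facet tags with strongly imposed (mesh) velocity.
#' @param dirichlet optional extra velocity conditions:
#'   list(vertices, values (m/s)).
#' @param traction_tags named numeric: tag -> applied normal traction
#'   pressure (Pa), e.g. an inlet driving pressure.
#' @param C_M stabilization constant.
#' @param pin_pressure vertex index whose pressure is pinned when no
#'   outlet/traction boundary fixes the pressure level (NULL = auto).
#' @return updated state; fields \code{outlets} (advanced states),
#'   \code{iterations} (solver diagnostic), \code{flux} (per-outlet m^3/s).
#' @export
step_ale_ns <- function(state, mesh, d_new = NULL, outlets = NULL,
                        props = fluid_props(), dt = 0.5,
                        wall_tags = c("wall", "noslip"),
                        dirichlet = NULL, traction_tags = NULL,
                        C_M = 0.0285, pin_pressure = NULL,
                        explicit_vms = TRUE, supg_scale = 1) {
  d <- mesh$dim
  nv <- nrow(mesh$vertices)
  ne <- nrow(mesh$elements)
  el <- mesh$elements
  nn <- d + 1L
  if (is.null(d_new)) d_new <- matrix(0, nv, d)
  dts <- dt * 1e-3                      # s
  coords <- (mesh$vertices + d_new) * 1e-3   # m
  w <- (d_new - state$d_mesh) / dt      # mm/ms = m/s
  gp <- p1_gradients(mesh, coords)
  vol <- abs(gp$vol)
  if (any(gp$vol <= 0)) stop_emf("inverted element in CFD mesh")
  met <- element_metric(gp)

  u_n <- state$u
  # element-mean quantities (one-point quadrature at the centroid)
  emean <- function(f) {
    acc <- 0
    for (a in seq_len(nn)) acc <- acc + f[el[, a], , drop = FALSE]
    acc / nn
  }
  a_el <- emean(u_n - w)                 # convective velocity per element
  tau <- vms_tau(a_el, met, props, dts, C_M)
  rho <- props$rho; mu <- props$mu

  # gradients of u^n per element: Gu[, i + d*(j-1)] = d u_i / d x_j
  Gu_n <- matrix(0, ne, d * d)
  for (a in seq_len(nn)) {
    ua <- u_n[el[, a], , drop = FALSE]
    ga <- gp$grads[[a]]
    for (i in seq_len(d)) for (j in seq_len(d))
      Gu_n[, i + d * (j - 1L)] <- Gu_n[, i + d * (j - 1L)] + ua[, i] * ga[, j]
  }
  # previous-step element residual r^n (for the explicit VMS terms)
  gradp_n <- matrix(0, ne, d)
  for (a in seq_len(nn)) {
    pa <- state$p[el[, a]]
    ga <- gp$grads[[a]]
    for (j in seq_len(d)) gradp_n[, j] <- gradp_n[, j] + pa * ga[, j]
  }
  adv_n <- matrix(0, ne, d)
  for (i in seq_len(d)) {
    acc <- 0
    for (j in seq_len(d)) acc <- acc + a_el[, j] * Gu_n[, i + d * (j - 1L)]
    adv_n[, i] <- acc
  }
  # recovered-gradient viscous term: P1 elements have no local Laplacian,
  # so project the velocity gradient to the vertices and take its
  # divergence per element; without it the stabilization residual sees the
  # pressure gradient as an unbalanced force (first-order consistency loss)
  gnod <- vertex_average(mesh, Gu_n, coords)
  lap_n <- matrix(0, ne, d)
  for (a in seq_len(nn)) {
    ga <- gp$grads[[a]]
    gn <- gnod[el[, a], , drop = FALSE]
    for (i in seq_len(d)) for (j in seq_len(d))
      lap_n[, i] <- lap_n[, i] + gn[, i + d * (j - 1L)] * ga[, j]
  }
  # quasi-static subscales: the transient term is excluded from the
  # stabilization residual (with tau ~ dt/2 it otherwise overwhelms the
  # pressure equation at small steps)
  r_n <- rho * adv_n + gradp_n

  nu_dof <- d * nv
  ntot <- nu_dof + nv
  udof <- function(vtx, i) d * (vtx - 1L) + i
  pdof <- function(vtx) nu_dof + vtx

  ii <- jj <- xx <- list(); slot <- 0L
  rhs <- numeric(ntot)
  add <- function(i, j, x) {
    slot <<- slot + 1L
    ii[[slot]] <<- i; jj[[slot]] <<- j; xx[[slot]] <<- x
  }
  # advective weight a.grad(phi_b) per local node (exact for P1)
  adv_b <- lapply(seq_len(nn), function(b) {
    acc <- 0
    for (j in seq_len(d)) acc <- acc + a_el[, j] * gp$grads[[b]][, j]
    acc
  })
  un_mean <- emean(u_n)
  rhs_add <- function(idx, val) {
    racc <- rowsum(val, idx)
    tgt <- as.integer(rownames(racc))
    rhs[tgt] <<- rhs[tgt] + racc[, 1]
  }
  Mcoef <- rho / dts
  tm <- tau$tau_mom
  for (a in seq_len(nn)) {
    ga <- gp$grads[[a]]
    supg_a <- supg_scale * rho * adv_b[[a]]  # rho a.grad(phi_a), SUPG test weight
    for (b in seq_len(nn)) {
      gb <- gp$grads[[b]]
      gagb <- rowSums(ga * gb)
      mass_ab <- vol / (nn * (nn + 1L)) * (1L + (a == b))
      for (i in seq_len(d)) {
        # Galerkin mass + convection + viscous (grad u part)
        # + SUPG acting on the BDF1 residual terms of u_b,i
        kcc <- Mcoef * mass_ab +
          rho * vol / nn * adv_b[[b]] +
          mu * vol * gagb +
          tm * supg_a * vol * adv_b[[b]]
        add(udof(el[, a], i), udof(el[, b], i), kcc)
        for (j in seq_len(d)) {
          # viscous transpose + grad-div (tau_CONT) blocks
          kij <- mu * vol * gb[, i] * ga[, j] +
            rho * tau$tau_cont * vol * ga[, i] * gb[, j]
          add(udof(el[, a], i), udof(el[, b], j), kij)
        }
        # pressure gradient (-p div v) + SUPG pressure coupling
        add(udof(el[, a], i), pdof(el[, b]),
            -vol / nn * ga[, i] + tm / rho * supg_a * vol * gb[, i])
        # continuity (q div u) + PSPG on the velocity residual
        add(pdof(el[, a]), udof(el[, b], i),
            vol / nn * gb[, i] + tm * vol * ga[, i] * adv_b[[b]])
      }
      # PSPG pressure Laplacian (1/rho prefactor of the VMS form)
      add(pdof(el[, a]), pdof(el[, b]), tm / rho * vol * gagb)
    }
    # ---- right-hand side ----
    for (i in seq_len(d)) {
      acc <- 0
      for (b in seq_len(nn)) {
        mass_ab <- vol / (nn * (nn + 1L)) * (1L + (a == b))
        acc <- acc + Mcoef * mass_ab * u_n[el[, b], i]
      }
      # explicit VMS cross and fine-scale Reynolds terms (residual at t^n);
      # they enter S_VMS with a minus sign, hence plus on the RHS
      if (explicit_vms) {
        cross_i <- 0
        for (j in seq_len(d))
          cross_i <- cross_i + Gu_n[, i + d * (j - 1L)] * r_n[, j]
        acc <- acc + tm * vol / nn * cross_i
        reyn <- 0
        for (j in seq_len(d)) reyn <- reyn + ga[, j] * r_n[, i] * r_n[, j]
        acc <- acc + tm^2 / rho * 2 * vol * reyn
      }
      rhs_add(udof(el[, a], i), acc)
    }
  }

  # outlet terms: Windkessel traction (previous-step flux) + backflow
  outlet_flux <- list()
  if (!is.null(outlets)) {
    for (tag in names(outlets)) {
      fd <- facet_data(mesh, coords, tag)
      if (nrow(fd$facets) == 0) stop_emf("no facets tagged ", tag)
      # previous-step flux through this outlet (m^3/s)
      umean <- matrix(0, nrow(fd$facets), d)
      wmean <- matrix(0, nrow(fd$facets), d)
      for (k in seq_len(d)) {
        for (c2 in seq_len(d)) {
          umean[, c2] <- umean[, c2] + u_n[fd$facets[, k], c2] / d
          wmean[, c2] <- wmean[, c2] + w[fd$facets[, k], c2] / d
        }
      }
      q_prev <- sum(rowSums(umean * fd$normals) * fd$areas)     # m^3/s
      q_ml_ms <- q_prev * 1e3                                   # ml/ms
      wk <- outlet_wk_step(outlets[[tag]], q_ml_ms, dt)
      outlets[[tag]] <- wk
      p_wk_Pa <- wk$p_wk * 1000                                 # kPa -> Pa
      an_rel <- rowSums((umean - wmean) * fd$normals)
      an_neg <- pmin(an_rel, 0)
      for (k in seq_len(d)) {
        nodes <- fd$facets[, k]
        for (i in seq_len(d)) {
          # traction RHS: -p_wk n
          idx <- udof(nodes, i)
          racc <- rowsum(-p_wk_Pa * fd$normals[, i] * fd$areas / d, idx)
          tgt <- as.integer(rownames(racc))
          rhs[tgt] <- rhs[tgt] + racc[, 1]
          # backflow: + rho beta (an)_- u . v  moved to LHS with sign -
          add(udof(nodes, i), udof(nodes, i),
              -rho * props$beta * an_neg * fd$areas / d)
        }
      }
      outlet_flux[[tag]] <- q_prev
    }
  }
  # plain traction boundaries (directional do-nothing: prescribed normal
  # traction plus backflow stabilization against incoming convection)
  if (!is.null(traction_tags)) {
    for (tag in names(traction_tags)) {
      fd <- facet_data(mesh, coords, tag)
      pt <- traction_tags[[tag]]
      umean <- matrix(0, nrow(fd$facets), d)
      wmean <- matrix(0, nrow(fd$facets), d)
      for (k in seq_len(d)) for (c2 in seq_len(d)) {
        umean[, c2] <- umean[, c2] + u_n[fd$facets[, k], c2] / d
        wmean[, c2] <- wmean[, c2] + w[fd$facets[, k], c2] / d
      }
      an_neg <- pmin(rowSums((umean - wmean) * fd$normals), 0)
      for (k in seq_len(d)) {
        nodes <- fd$facets[, k]
        for (i in seq_len(d)) {
          idx <- udof(nodes, i)
          racc <- rowsum(-pt * fd$normals[, i] * fd$areas / d, idx)
          tgt <- as.integer(rownames(racc))
          rhs[tgt] <- rhs[tgt] + racc[, 1]
          add(udof(nodes, i), udof(nodes, i),
              -rho * max(props$beta, 0.5) * an_neg * fd$areas / d)
        }
      }
    }
  }

  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ntot, ntot))
  # strong Dirichlet: wall velocity = mesh velocity; extra conditions
  wall_v <- tagged_vertices(mesh, wall_tags)
  dofs <- c(); vals <- c()
  if (length(wall_v)) {
    for (i in seq_len(d)) {
      dofs <- c(dofs, udof(wall_v, i)); vals <- c(vals, w[wall_v, i])
    }
  }
  if (!is.null(dirichlet)) {
    bv <- dirichlet$vertices
    bm <- as.matrix(dirichlet$values)
    for (i in seq_len(d)) {
      dofs <- c(dofs, udof(bv, i)); vals <- c(vals, bm[, i])
    }
  }
  if (is.null(outlets) && is.null(traction_tags)) {
    pin <- pin_pressure %||% 1L
    dofs <- c(dofs, pdof(pin)); vals <- c(vals, 0)
  }
  dup <- duplicated(dofs)
  dofs <- dofs[!dup]; vals <- vals[!dup]
  bc <- apply_dirichlet(K, rhs, dofs, vals)
  sol <- solve_sparse(bc$K, bc$f)
  u_new <- matrix(sol[seq_len(nu_dof)], nv, d, byrow = TRUE)
  p_new <- sol[pdof(seq_len(nv))]
  state$u_prev <- state$u
  state$u <- u_new
  state$p <- p_new
  state$d_mesh <- d_new
  state$w <- w
  state$t <- state$t + dt
  state$outlets <- outlets
  state$flux <- outlet_flux
  state
}

#' Flux through a tagged surface or internal plane
#'
#' For a facet tag, the exact P1 surface integral of u . n. For an internal
#' plane (list with \code{point}, \code{normal}, \code{radius}), the
#' integral is evaluated by dense grid quadrature over the plane with
#' point location in the mesh.
#'
#' @param mesh the fluid mesh (mm).
#' @param u nodal velocity (m/s).
#' @param tag facet tag, or NULL.
#' @param plane internal plane description, or NULL.
#' @param d_mesh mesh displacement (mm) to evaluate on the moved mesh.
#' @param n_grid quadrature grid resolution per direction.
#' @return flux in ml/s.
#' @export
flux_through <- function(mesh, u, tag = NULL, plane = NULL, d_mesh = NULL,
                         n_grid = 60) {
  coords <- mesh$vertices + (d_mesh %||% 0)
  if (!is.null(tag)) {
    fd <- facet_data(mesh, coords * 1e-3, tag)
    if (nrow(fd$facets) == 0) stop_emf("no facets tagged ", tag)
    d <- mesh$dim
    umean <- matrix(0, nrow(fd$facets), d)
    for (k in seq_len(d)) umean <- umean + u[fd$facets[, k], , drop = FALSE] / d
    return(sum(rowSums(umean * fd$normals) * fd$areas) * 1e9 / 1e3) # m^3/s -> ml/s
  }
  if (is.null(plane)) stop_emf("give either a tag or a plane")
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  # orthonormal in-plane basis
  t1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- t1 - sum(t1 * nrm) * nrm; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
          nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  r <- plane$radius
  s <- seq(-r, r, length.out = n_grid)
  dA <- (s[2] - s[1])^2                        # mm^2
  gridp <- as.matrix(expand.grid(a = s, b = s))
  pts <- matrix(plane$point, nrow(gridp), 3, byrow = TRUE) +
    gridp[, 1] %o% t1 + gridp[, 2] %o% t2
  # displaced-mesh location
  mesh2 <- mesh; mesh2$vertices <- coords
  loc <- locate_points(mesh2, pts)
  inside <- !loc$exterior
  if (!any(inside)) stop_emf("section does not intersect the mesh")
  un <- interpolate_at(mesh2, loc, u %*% nrm)
  sum(un[inside]) * dA                 # (m/s) * mm^2 = 1e-6 m^3/s = 1 ml/s
}

#' Pressure-Poisson mapping from a velocity field to relative pressure
#'
#' Solves div(grad p) = div(b) with b = -rho (du/dt + (u . grad) u)
#' + mu Lap(u) in weak form with homogeneous Neumann walls, on a mask
#' eroded by a fraction of the domain depth (to avoid inconsistencies near
#' the wall), and reports pressure relative to a reference point. The
#' viscous term uses a recovered-gradient Laplacian (nodal projection of
#' the P1 gradients).
#'
#' @param mesh the fluid mesh (mm).
#' @param u nodal velocity (m/s), or a list of two fields \code{(prev,
#'   cur)} for the transient term.
#' @param props \code{\link{fluid_props}}.
#' @param reference_point coordinates (mm) of the zero-pressure location.
#' @param mask_erosion fraction of the maximal wall distance to erode.
#' @param dt time between the two fields (ms), if transient.
#' @return list with \code{mesh} (eroded submesh), \code{p} (Pa, relative),
#'   \code{vertex_map} into the input mesh.
#' @export
pressure_poisson <- function(mesh, u, props = fluid_props(),
                             reference_point = NULL, mask_erosion = 0.05,
                             dt = NULL) {
  d <- mesh$dim
  if (is.list(u) && !is.matrix(u)) {
    stopifnot(!is.null(dt))
    dudt <- (as.matrix(u$cur) - as.matrix(u$prev)) / (dt * 1e-3)
    u <- as.matrix(u$cur)
  } else {
    u <- as.matrix(u)
    dudt <- matrix(0, nrow(u), d)
  }
  # erode the domain: drop elements near the boundary
  wallv <- sort(unique(as.vector(mesh$boundary_facets)))
  dist <- rep(Inf, nrow(mesh$vertices))
  dist[wallv] <- 0
  # graph-distance sweep (edge lengths) as a cheap wall distance
  el <- mesh$elements
  pairs <- utils::combn(d + 1L, 2L)
  ei <- c(); ej <- c()
  for (k in seq_len(ncol(pairs))) {
    ei <- c(ei, el[, pairs[1, k]], el[, pairs[2, k]])
    ej <- c(ej, el[, pairs[2, k]], el[, pairs[1, k]])
  }
  elen <- row_norm(mesh$vertices[ej, , drop = FALSE] -
                     mesh$vertices[ei, , drop = FALSE])
  for (it in 1:60) {
    nd <- dist[ei] + elen
    o <- order(ej, nd)
    eo <- ej[o]
    newmin <- nd[o][!duplicated(eo)]
    vidx <- eo[!duplicated(eo)]
    dn <- dist
    dn[vidx] <- pmin(dn[vidx], newmin)
    if (max(abs(dn - dist)[is.finite(dn) & is.finite(dist)]) < 1e-12 &&
        !any(is.finite(dn) & !is.finite(dist))) { dist <- dn; break }
    dist <- dn
  }
  dmax <- max(dist[is.finite(dist)])
  cut <- mask_erosion * dmax
  keep_el <- apply(matrix(dist[el], nrow(el)), 1, min) >= cut
  if (!any(keep_el)) stop_emf("mask erosion removed the whole domain")
  mesh$element_labels[keep_el] <- "aobp"
  mesh$element_labels[!keep_el] <- "ao"
  # recover nodal velocity gradients on the FULL mesh first (consistent-mass
  # L2 projection), so the eroded domain sees well-centred recovery data
  nn2 <- d + 1L
  gpf <- p1_gradients(mesh, mesh$vertices * 1e-3)
  volf <- abs(gpf$vol)
  elf <- mesh$elements
  Guf <- matrix(0, nrow(elf), d * d)
  for (a in seq_len(nn2)) {
    ua <- u[elf[, a], , drop = FALSE]
    ga <- gpf$grads[[a]]
    for (i in seq_len(d)) for (j in seq_len(d))
      Guf[, i + d * (j - 1L)] <- Guf[, i + d * (j - 1L)] + ua[, i] * ga[, j]
  }
  gnod_full <- recover_gradient_ls(mesh, Guf, mesh$vertices * 1e-3, volf)

  ermesh <- submesh(mesh, "aobp")
  vmap <- attr(ermesh, "vertex_map")
  ue <- u[vmap, , drop = FALSE]
  dudte <- dudt[vmap, , drop = FALSE]
  gnod <- gnod_full[vmap, , drop = FALSE]
  gp <- p1_gradients(ermesh, ermesh$vertices * 1e-3)  # SI
  vol <- abs(gp$vol)
  ele <- ermesh$elements
  emean2 <- function(f) {
    acc <- 0
    for (a in seq_len(nn2)) acc <- acc + f[ele[, a], , drop = FALSE]
    acc / nn2
  }
  Gu <- matrix(0, nrow(ele), d * d)
  for (a in seq_len(nn2)) {
    ua <- ue[ele[, a], , drop = FALSE]
    ga <- gp$grads[[a]]
    for (i in seq_len(d)) for (j in seq_len(d))
      Gu[, i + d * (j - 1L)] <- Gu[, i + d * (j - 1L)] + ua[, i] * ga[, j]
  }
  lap <- matrix(0, nrow(ele), d)         # Lap(u_i) per element
  for (a in seq_len(nn2)) {
    ga <- gp$grads[[a]]
    gn <- gnod[ele[, a], , drop = FALSE]
    for (i in seq_len(d)) for (j in seq_len(d))
      lap[, i] <- lap[, i] + gn[, i + d * (j - 1L)] * ga[, j]
  }
  u_el <- emean2(ue)
  conv <- matrix(0, nrow(ele), d)
  for (i in seq_len(d)) {
    acc <- 0
    for (j in seq_len(d)) acc <- acc + u_el[, j] * Gu[, i + d * (j - 1L)]
    conv[, i] <- acc
  }
  b <- -props$rho * (emean2(dudte) + conv) + props$mu * lap
  # weak form: (grad p, grad q) = (b, grad q)
  K <- assemble_scalar_stiffness(ermesh, coords = ermesh$vertices * 1e-3)
  f <- numeric(nrow(ermesh$vertices))
  for (a in seq_len(nn2)) {
    ga <- gp$grads[[a]]
    val <- vol * rowSums(ga * b)
    racc <- rowsum(val, ele[, a])
    tgt <- as.integer(rownames(racc))
    f[tgt] <- f[tgt] + racc[, 1]
  }
  bc <- apply_dirichlet(K, f, 1L, 0)     # pin, then shift to the reference
  p <- solve_sparse(bc$K, bc$f)
  if (!is.null(reference_point)) {
    loc <- locate_points(ermesh, matrix(reference_point, 1))
    p <- p - interpolate_at(ermesh, loc, p)
  } else p <- p - mean(p)
  list(mesh = ermesh, p = p, vertex_map = vmap)
}

#' Pressure along a centerline polyline
#'
#' Interpolates nodal pressure at sample points along a polyline; samples
#' outside the mesh are flagged and skipped.
#'
#' @param mesh fluid mesh (mm).
#' @param p nodal pressure.
#' @param polyline matrix of polyline vertices (mm).
#' @param n_samples samples along the polyline.
#' @param d_mesh optional mesh displacement.
#' @return data.frame with \code{s_mm} (arclength), \code{p}, and
#'   \code{inside}.
#' @export
centerline_pressure <- function(mesh, p, polyline, n_samples = 100,
                                d_mesh = NULL) {
  polyline <- as.matrix(polyline)
  seg <- diff(polyline)
  slen <- row_norm(seg)
  stot <- sum(slen)
  svals <- seq(0, stot, length.out = n_samples)
  cums <- c(0, cumsum(slen))
  pts <- t(vapply(svals, function(s) {
    k <- max(1L, findInterval(s, cums, rightmost.closed = TRUE))
    k <- min(k, nrow(seg))
    frac <- (s - cums[k]) / slen[k]
    polyline[k, ] + frac * seg[k, ]
  }, numeric(ncol(polyline))))
  mesh2 <- mesh
  if (!is.null(d_mesh)) mesh2$vertices <- mesh2$vertices + d_mesh
  loc <- locate_points(mesh2, pts)
  vals <- interpolate_at(mesh2, loc, p)
  vals[loc$exterior] <- NA_real_
  data.frame(s_mm = svals, p = vals, inside = !loc$exterior)
}

#' Pressure drop between two cross-sections
#'
#' Reported both as the difference of centerline point values and as the
#' difference of plane-averaged pressures (grid quadrature).
#'
#' @param mesh fluid mesh (mm).
#' @param p nodal pressure.
#' @param plane1,plane2 plane lists (\code{point}, \code{normal},
#'   \code{radius}), upstream first.
#' @param d_mesh optional mesh displacement.
#' @param n_grid quadrature resolution.
#' @return list with \code{point_drop} and \code{plane_drop} (units of p).
#' @export
pressure_drop <- function(mesh, p, plane1, plane2, d_mesh = NULL,
                          n_grid = 40) {
  mesh2 <- mesh
  if (!is.null(d_mesh)) mesh2$vertices <- mesh2$vertices + d_mesh
  point_at <- function(pl) {
    loc <- locate_points(mesh2, matrix(pl$point, 1))
    interpolate_at(mesh2, loc, p)
  }
  avg_at <- function(pl) {
    nrm <- pl$normal / sqrt(sum(pl$normal^2))
    t1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * nrm) * nrm; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
            nrm[3] * t1[1] - nrm[1] * t1[3],
            nrm[1] * t1[2] - nrm[2] * t1[1])
    s <- seq(-pl$radius, pl$radius, length.out = n_grid)
    gridp <- as.matrix(expand.grid(a = s, b = s))
    pts <- matrix(pl$point, nrow(gridp), 3, byrow = TRUE) +
      gridp[, 1] %o% t1 + gridp[, 2] %o% t2
    loc <- locate_points(mesh2, pts)
    mean(interpolate_at(mesh2, loc, p)[!loc$exterior])
  }
  list(point_drop = point_at(plane1) - point_at(plane2),
       plane_drop = avg_at(plane1) - avg_at(plane2))
}

#' Run the ALE flow solver over a time window
#'
#' Advances \code{\link{step_ale_ns}} from \code{t_start} to \code{t_end},
#' obtaining the mesh displacement at each step from \code{motion} (a
#' function of time returning an nv x d matrix in mm, or NULL for a static
#' mesh), and records outlet fluxes and Windkessel pressures.
#'
#' @param mesh fluid mesh (mm).
#' @param motion function(t_ms) -> displacement, or NULL.
#' @param outlets named list tag -> \code{\link{outlet_windkessel}}.
#' @param props \code{\link{fluid_props}}.
#' @param dt step (ms).
#' @param t_start,t_end window (ms).
#' @param state0 initial state (defaults to rest).
#' @param ... passed to \code{\link{step_ale_ns}}.
#' @return list with final \code{state}, \code{trace} (data.frame of time,
#'   per-outlet flux ml/s and p_wk kPa, domain volume ml), and
#'   \code{n_steps}.
#' @export
ale_cfd_run <- function(mesh, motion = NULL, outlets = NULL,
                        props = fluid_props(), dt = 0.5, t_start = 0,
                        t_end = 100, state0 = NULL, ...) {
  state <- state0 %||% new_flow_state(mesh)
  state$t <- t_start
  if (!is.null(motion)) state$d_mesh <- motion(t_start)
  n_steps <- cfd_step_count(t_start, t_end, dt)
  rows <- list()
  for (k in seq_len(n_steps)) {
    t_new <- t_start + k * dt
    d_new <- if (is.null(motion)) NULL else motion(t_new)
    state <- step_ale_ns(state, mesh, d_new = d_new, outlets = outlets,
                         props = props, dt = dt, ...)
    outlets <- state$outlets %||% outlets
    vol_ml <- sum(abs(element_volumes(mesh, mesh$vertices +
                                        (d_new %||% 0)))) / 1000
    row <- data.frame(time_ms = t_new, volume_ml = vol_ml)
    if (!is.null(state$flux) && length(state$flux)) {
      for (tag in names(state$flux)) {
        row[[paste0("q_", tag, "_ml_s")]] <- state$flux[[tag]] * 1e6
        row[[paste0("p_wk_", tag, "_kPa")]] <- state$outlets[[tag]]$p_wk
      }
    }
    rows[[k]] <- row
  }
  list(state = state, trace = do.call(rbind, rows), n_steps = n_steps)
}

#' Number of CFD steps for a time window
#' @param t_start,t_end window bounds (ms).
#' @param dt step (ms).
#' @return integer step count.
#' @export
cfd_step_count <- function(t_start, t_end, dt = 0.5) {
  as.integer(round((t_end - t_start) / dt))
}

#' Degree-of-freedom bookkeeping for an equal-order mesh
#' @param n_vertices vertex count (or an \code{emf_mesh}).
#' @param dim spatial dimension.
#' @return list with \code{dof_u}, \code{dof_p}, \code{dof_total}.
#' @export
dof_count <- function(n_vertices, dim = 3L) {
  if (inherits(n_vertices, "emf_mesh")) {
    dim <- n_vertices$dim
    n_vertices <- nrow(n_vertices$vertices)
  }
  list(dof_u = dim * n_vertices, dof_p = n_vertices,
       dof_total = (dim + 1L) * n_vertices)
}
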