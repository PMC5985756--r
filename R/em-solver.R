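#' Quasi-static electromechanics of the LV
#'
#' Total-Lagrangian finite elasticity on P1 tetrahedra: the equilibrium
#' -Div(F S) = 0 with S = S_pas + S_act, homogeneous Dirichlet conditions on
#' the anchoring surfaces, a follower pressure on the endocardium, Newton
#' iterations with an analytic stress and a finite-difference consistent
#' material tangent, and a scalar pressure Lagrange multiplier enforcing the
#' cavity volume during the isovolumetric phases.
#'
#' @name em_solver
NULL

#' Default material assignment per region label
#'
#' Guccione myocardium; Demiray elsewhere with the stiffness scales
#' C-tilde = 3000 kPa (aorta), 30000 kPa (valves), 300 kPa (cushion, with
#' bulk modulus 100 kPa).
#'
#' @param C_Guc myocardial stiffness scale (kPa).
#' @return named list label -> list(law, params).
#' @export
default_materials <- function(C_Guc = 0.48) {
  list(lv = list(law = "guccione", params = guccione_params(C_Guc = C_Guc)),
       ao = list(law = "demiray", params = demiray_params(C_tilde = 3000)),
       av = list(law = "demiray", params = demiray_params(C_tilde = 30000)),
       mv = list(law = "demiray", params = demiray_params(C_tilde = 30000)),
       cushion = list(law = "demiray",
                      params = demiray_params(C_tilde = 300, kappa = 100)))
}

#' Build a mechanics context
#'
#' Precomputes shape-function gradients, fiber frames, material groups and
#' boundary data for repeated solves on the same mesh. Blood-pool labels
#' are stripped automatically.
#'
#' @param mesh a labeled mesh (full or solid).
#' @param fibers optional \code{emf_fibers} on the solid mesh; computed by
#'   \code{\link{assign_fibers}} when absent.
#' @param materials per-label material map (see
#'   \code{\link{default_materials}}).
#' @param dirichlet_tags facet tags clamped to zero displacement.
#' @param pressure_tag facet tag carrying the cavity follower pressure.
#' @return an \code{em_context}.
#' @export
em_context <- function(mesh, fibers = NULL, materials = default_materials(),
                       dirichlet_tags = "dirichlet",
                       pressure_tag = "pressure_endo", fixed_dofs = NULL) {
  if (any(mesh$element_labels %in% c("lvbp", "aobp"))) mesh <- solid_submesh(mesh)
  if (mesh$dim != 3L) stop_emf("mechanics context requires a 3D mesh")
  if (is.null(fibers)) {
    fibers <- if ("lv" %in% mesh$element_labels) assign_fibers(mesh) else {
      ne <- nrow(mesh$elements)
      list(f0 = matrix(rep(c(1, 0, 0), each = ne), ne, 3),
           s0 = matrix(rep(c(0, 1, 0), each = ne), ne, 3),
           n0 = matrix(rep(c(0, 0, 1), each = ne), ne, 3))
    }
  }
  gp <- p1_gradients(mesh)
  labs <- unique(mesh$element_labels)
  missing <- setdiff(labs, names(materials))
  if (length(missing) > 0)
    stop_emf("no material for labels: ", paste(missing, collapse = ", "))
  groups <- lapply(labs, function(l) which(mesh$element_labels == l))
  names(groups) <- labs
  psel <- mesh$facet_tags == pressure_tag
  pfac <- mesh$boundary_facets[psel, , drop = FALSE]
  dir_v <- tagged_vertices(mesh, dirichlet_tags)
  dof <- function(v) c(3 * (v - 1) + 1, 3 * (v - 1) + 2, 3 * (v - 1) + 3)
  structure(list(mesh = mesh, fibers = fibers, materials = materials,
                 ff_outer = t3_outer(fibers$f0, fibers$f0),
                 gp = gp, groups = groups, pressure_facets = pfac,
                 dirichlet_vertices = dir_v,
                 dirichlet_dofs = sort(unique(c(dof(dir_v), fixed_dofs))),
                 nv = nrow(mesh$vertices), ne = nrow(mesh$elements)),
            class = "em_context")
}

# total PK2 stress field (and energy) at the element level given C (ne x 9);
# Sa: per-element active stress scalar (kPa) or NULL
ctx_stress_C <- function(ctx, Cv, Sa = NULL, want_psi = FALSE, visc = NULL) {
  ne <- ctx$ne
  S <- matrix(0, ne, 9)
  psi <- if (want_psi) numeric(ne) else NULL
  for (lab in names(ctx$groups)) {
    idx <- ctx$groups[[lab]]
    mat <- ctx$materials[[lab]]
    res <- if (mat$law == "guccione") {
      guccione_psi_S_C(Cv[idx, , drop = FALSE],
                       ctx$fibers$f0[idx, , drop = FALSE],
                       ctx$fibers$s0[idx, , drop = FALSE],
                       ctx$fibers$n0[idx, , drop = FALSE], mat$params)
    } else {
      demiray_psi_S_C(Cv[idx, , drop = FALSE], mat$params)
    }
    S[idx, ] <- res$S
    if (want_psi) psi[idx] <- res$psi
  }
  if (!is.null(Sa) && any(Sa != 0)) {
    f0 <- ctx$fibers$f0
    lam2 <- t3_quad(Cv, f0)
    S <- S + (Sa / lam2) * ctx$ff_outer
  }
  if (!is.null(visc)) {
    # Kelvin-Voigt damping of the quasi-static path: S_visc = (eta/dt)(E - E_prev)
    S <- S + visc$eta_dt / 2 * (Cv - visc$C_prev)
  }
  if (want_psi) list(S = S, psi = psi) else list(S = S)
}

# deformation gradient field from nodal displacement (nv x 3)
ctx_F <- function(ctx, d) {
  el <- ctx$mesh$elements
  Fv <- t3_eye(ctx$ne)
  for (a in 1:4) {
    da <- d[el[, a], , drop = FALSE]
    ga <- ctx$gp$grads[[a]]
    Fv <- Fv + t3_outer(da, ga)
  }
  Fv
}

# nodal area vectors (dV/dx) of the closed cavity surface, on displaced
# coordinates; also the signed enclosed volume
cavity_volume_gradient <- function(ctx, coords) {
  fac <- ctx$pressure_facets
  Vs <- enclosed_volume(coords, fac, 3L)
  a <- coords[fac[, 1], , drop = FALSE]
  b <- coords[fac[, 2], , drop = FALSE]
  cc <- coords[fac[, 3], , drop = FALSE]
  g1 <- row_cross(b, cc) / 6
  g2 <- row_cross(cc, a) / 6
  g3 <- row_cross(a, b) / 6
  G <- matrix(0, nrow(coords), 3)
  for (k in 1:3) {
    gk <- list(g1, g2, g3)[[k]]
    for (c in 1:3)
      G[, c] <- G[, c] + tabulate_weighted(fac[, k], gk[, c], nrow(coords))
  }
  sgn <- if (Vs < 0) -1 else 1
  list(V = sgn * Vs, G = sgn * G)
}

#' Cavity volume from a closed (or lid-closable) tagged surface
#'
#' Divergence-theorem volume over the deformed surface. If the tagged facet
#' set is open along a single ring (for example a cavity cut at the valve
#' plane), a lid is added by fan triangulation from the ring centroid; an
#' open surface that cannot be closed this way raises an error listing the
#' boundary edges.
#'
#' @param mesh an \code{emf_mesh}.
#' @param d nodal displacement (or NULL for the reference configuration).
#' @param tag facet tag of the cavity surface.
#' @return volume in ml (1000 mm^3 = 1 ml).
#' @export
cavity_volume <- function(mesh, d = NULL, tag = "pressure_endo") {
  coords <- mesh$vertices
  if (!is.null(d)) coords <- coords + d
  fac <- mesh$boundary_facets[mesh$facet_tags %in% tag, , drop = FALSE]
  if (nrow(fac) == 0) stop_emf("no facets tagged ", paste(tag, collapse = "/"))
  closed <- close_surface(coords, fac)
  abs(enclosed_volume(closed$coords, closed$facets, 3L)) / 1000
}

# close an open triangulated surface with a centroid fan over its boundary
# ring; returns possibly augmented coords/facets
close_surface <- function(coords, fac) {
  ed <- rbind(fac[, 1:2], fac[, 2:3], fac[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  open_ed <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  if (nrow(open_ed) == 0) return(list(coords = coords, facets = fac))
  ring_v <- unique(as.vector(open_ed))
  # single-ring check: every ring vertex has exactly two open edges and the
  # ring is connected (walk it)
  cnt <- table(as.vector(open_ed))
  single <- !any(cnt != 2L)
  if (single) {
    adj <- split(c(open_ed[, 2], open_ed[, 1]), c(open_ed[, 1], open_ed[, 2]))
    seen <- ring_v[1]; frontier <- ring_v[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[as.character(frontier)])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    single <- length(seen) == length(ring_v)
  }
  if (!single)
    stop_emf("open surface cannot be closed by one lid; boundary edges: ",
             paste(utils::head(apply(open_ed, 1, paste, collapse = "-"), 10),
                   collapse = ", "))
  ctr <- colMeans(coords[ring_v, , drop = FALSE])
  coords2 <- rbind(coords, ctr)
  cidx <- nrow(coords2)
  lid <- cbind(open_ed[, 2], open_ed[, 1], cidx)
  list(coords = coords2, facets = rbind(fac, lid))
}

# assemble residual (3 nv) and optionally tangent for the current state
em_assemble <- function(ctx, d, p, Sa, want_K = TRUE, fd_h = 1e-6,
                        visc = NULL) {
  el <- ctx$mesh$elements
  nv <- ctx$nv; ne <- ctx$ne
  vol <- abs(ctx$gp$vol)
  Fv <- ctx_F(ctx, d)
  J <- t3_det(Fv)
  if (any(J <= 0)) stop_emf("inverted deformation during solve")
  Cv <- t3_mm(t3_t(Fv), Fv)
  S <- ctx_stress_C(ctx, Cv, Sa, visc = visc)$S
  P <- t3_mm(Fv, S)
  # internal forces
  R <- matrix(0, nv, 3)
  for (a in 1:4) {
    fa <- t3_mv(P, ctx$gp$grads[[a]]) * vol
    for (c in 1:3) R[, c] <- R[, c] + tabulate_weighted(el[, a], fa[, c], nv)
  }
  # follower cavity pressure: f_ext = p * dV/dx
  cg <- NULL
  if (p != 0 || TRUE) {
    cg <- cavity_volume_gradient(ctx, ctx$mesh$vertices + d)
    R <- R - p * cg$G
  }
  out <- list(R = as.numeric(t(R)), V = cg$V, G = as.numeric(t(cg$G)))
  if (!want_K) return(out)

  # 6x6 material tangent per element by central differences in C-space
  voigt_i <- c(1, 5, 9, 8, 7, 4)  # 11,22,33,23,13,12 in column-major
  Svgt <- function(Cp) ctx_stress_C(ctx, Cp, Sa, visc = visc)$S[, voigt_i, drop = FALSE]
  D <- array(0, c(ne, 6, 6))
  for (q in 1:6) {
    dC <- matrix(0, ne, 9)
    if (q <= 3) {
      dC[, voigt_i[q]] <- 2 * fd_h
    } else {
      dC[, voigt_i[q]] <- fd_h
      sym_i <- c(6, 3, 2)[q - 3]  # mirror entries of 23,13,12
      dC[, sym_i] <- fd_h
    }
    D[, , q] <- (Svgt(Cv + dC) - Svgt(Cv - dC)) / (2 * fd_h)
  }
  # B matrices: B[[a]][p, i] per element (list over voigt p of ne x 3)
  Fcol <- function(j) Fv[, (3 * (j - 1) + 1):(3 * j), drop = FALSE] # F[, j] col
  Bmat <- function(ga) {
    list(Fcol(1) * ga[, 1],
         Fcol(2) * ga[, 2],
         Fcol(3) * ga[, 3],
         Fcol(2) * ga[, 3] + Fcol(3) * ga[, 2],
         Fcol(1) * ga[, 3] + Fcol(3) * ga[, 1],
         Fcol(1) * ga[, 2] + Fcol(2) * ga[, 1])
  }
  Bs <- lapply(1:4, function(a) Bmat(ctx$gp$grads[[a]]))
  ii <- jj <- xx <- vector("list", 16L * 9L)
  slot <- 0L
  for (a in 1:4) for (b in 1:4) {
    ga <- ctx$gp$grads[[a]]; gb <- ctx$gp$grads[[b]]
    kgeo <- vol * rowSums(ga * t3_mv(S, gb))
    # DB[p][j] = sum_q D[,p,q] B_b[q][ , j]
    DB <- vector("list", 6)
    for (pq in 1:6) {
      acc <- matrix(0, ne, 3)
      for (q in 1:6) acc <- acc + D[, pq, q] * Bs[[b]][[q]]
      DB[[pq]] <- acc
    }
    for (i in 1:3) for (j in 1:3) {
      kij <- numeric(ne)
      for (pq in 1:6) kij <- kij + Bs[[a]][[pq]][, i] * DB[[pq]][, j]
      kij <- kij * vol
      if (i == j) kij <- kij + kgeo
      slot <- slot + 1L
      ii[[slot]] <- 3 * (el[, a] - 1) + i
      jj[[slot]] <- 3 * (el[, b] - 1) + j
      xx[[slot]] <- kij
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * nv, 3 * nv))
  if (p != 0) K <- K - p * follower_load_stiffness(ctx, ctx$mesh$vertices + d)
  out$K <- K
  out
}

# d(dV/dx)/dx of the closed cavity surface: skew-symmetric facet blocks.
# Keeping this in the tangent restores fast Newton convergence under the
# follower pressure.
follower_load_stiffness <- function(ctx, coords) {
  fac <- ctx$pressure_facets
  nf <- nrow(fac)
  a <- coords[fac[, 1], , drop = FALSE]
  b <- coords[fac[, 2], , drop = FALSE]
  cc <- coords[fac[, 3], , drop = FALSE]
  Vs <- enclosed_volume(coords, fac, 3L)
  sgn <- if (Vs < 0) -1 else 1
  # dG_a/db = -skew(c)/6, dG_a/dc = skew(b)/6, and cyclic
  pairs <- list(list(1L, 2L, cc, -1), list(1L, 3L, b, +1),
                list(2L, 3L, a, -1), list(2L, 1L, cc, +1),
                list(3L, 1L, b, -1), list(3L, 2L, a, +1))
  skew_idx <- rbind(c(1, 2, 3, -1), c(1, 3, 2, +1), c(2, 1, 3, +1),
                    c(2, 3, 1, -1), c(3, 1, 2, -1), c(3, 2, 1, +1))
  ii <- jj <- xx <- vector("list", length(pairs) * 6L)
  slot <- 0L
  nv <- nrow(coords)
  for (pr in pairs) {
    na <- fac[, pr[[1]]]; nb <- fac[, pr[[2]]]
    v <- pr[[3]]; s <- pr[[4]] * sgn / 6
    for (r in seq_len(nrow(skew_idx))) {
      i <- skew_idx[r, 1]; j <- skew_idx[r, 2]; comp <- skew_idx[r, 3]
      slot <- slot + 1L
      ii[[slot]] <- 3 * (na - 1) + i
      jj[[slot]] <- 3 * (nb - 1) + j
      xx[[slot]] <- s * skew_idx[r, 4] * v[, comp]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(3 * nv, 3 * nv))
}

#' Solve the quasi-static equilibrium at a given load
#'
#' Newton's method with backtracking line search. The cavity pressure acts
#' as a follower load on the \code{pressure_endo} surface; with
#' \code{constraint_volume} set, the pressure becomes a scalar Lagrange
#' multiplier chosen so the cavity volume matches (the saddle-point form of
#' the isovolumetric phases), solved via a bordered Newton system.
#'
#' @param ctx an \code{\link{em_context}}.
#' @param p cavity pressure (kPa); ignored when a volume constraint is set
#'   (used as the multiplier's initial guess).
#' @param Sa per-element active stress (kPa) or a single number.
#' @param d0 initial nodal displacement guess.
#' @param constraint_volume target cavity volume (ml) or NULL.
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap.
#' @return list with \code{d} (nv x 3), \code{p} (kPa; the multiplier if
#'   constrained), \code{V} (ml), \code{residual}, \code{iterations},
#'   \code{history}.
#' @export
solve_quasistatic <- function(ctx, p = 0, Sa = 0, d0 = NULL,
                              constraint_volume = NULL, tol = 1e-8,
                              max_iter = 60L,
                              verbose = getOption("cardioemf.newton_verbose", FALSE),
                              visc = NULL, cache = NULL) {
  if (!is.null(constraint_volume)) {
    # large one-shot volume corrections exceed the Newton basin of the
    # exponential material: split them into sub-targets (continuation),
    # with a finer fallback level if a sub-target still fails
    Sa <- rep_len(Sa, ctx$ne)
    d_cur <- d0 %||% matrix(0, ctx$nv, 3)
    V0 <- cavity_volume_gradient(ctx, ctx$mesh$vertices + d_cur)$V / 1000
    run_chain <- function(d_cur, p_cur, V_from, dV_max, depth) {
      nsub <- max(1L, ceiling(abs(V_from - constraint_volume) / dV_max))
      res <- NULL
      for (k in seq_len(nsub)) {
        tgt <- V_from + (constraint_volume - V_from) * k / nsub
        res <- tryCatch(
          solve_quasistatic_inner(ctx, p_cur, Sa, d_cur, tgt, tol,
                                  max_iter, verbose, visc, cache),
          error = function(e) e)
        if (inherits(res, "error")) {
          if (depth >= 2L) stop(res)
          Vc <- cavity_volume_gradient(ctx, ctx$mesh$vertices + d_cur)$V / 1000
          res <- run_chain(d_cur, p_cur, Vc, dV_max / 6, depth + 1L)
        }
        d_cur <- res$d
        p_cur <- res$p
      }
      res
    }
    dV_big <- max(0.015 * constraint_volume, 0.1)
    if (is.null(cache)) cache <- new.env(parent = emptyenv())
    return(run_chain(d_cur, p, V0, dV_big, 1L))
  }
  solve_quasistatic_inner(ctx, p, Sa, d0, NULL, tol, max_iter, verbose, visc,
                          cache)
}

solve_quasistatic_inner <- function(ctx, p = 0, Sa = 0, d0 = NULL,
                                    constraint_volume = NULL, tol = 1e-8,
                                    max_iter = 40L, verbose = FALSE,
                                    visc = NULL, cache = NULL) {
  nv <- ctx$nv
  Sa <- rep_len(Sa, ctx$ne)
  d <- d0 %||% matrix(0, nv, 3)
  fixed <- ctx$dirichlet_dofs
  constrained <- !is.null(constraint_volume)
  p_cur <- p
  hist <- numeric(0)
  scale0 <- NULL
  kc <- 1  # the merit is the norm of the exact augmented residual,
  # which the bordered Newton direction is guaranteed to descend
  merit_of <- function(rn, V) {
    if (!constrained) return(rn)
    sqrt(rn^2 + (kc * (V - constraint_volume * 1000))^2)
  }
  # modified Newton: the factorized tangent is reused (also across the
  # sub-targets of a continuation chain via `cache`) while convergence
  # stays fast, and rebuilt when it slows
  lu_cur <- if (!is.null(cache)) cache$lu else NULL
  refresh <- is.null(lu_cur)
  merit_prev <- Inf
  for (it in seq_len(max_iter)) {
    fresh_now <- refresh
    asm <- em_assemble(ctx, d, p_cur, Sa, want_K = refresh, visc = visc)
    res <- asm$R
    res[fixed] <- 0
    rn <- sqrt(sum(res^2))
    if (it <= 2L) {
      cterm <- if (constrained) kc * abs(asm$V - constraint_volume * 1000) else 0
      scale0 <- max(scale0 %||% 0, rn, abs(p_cur) * sum(abs(asm$G)) / 3,
                    cterm, 1e-4)
    }
    hist <- c(hist, rn)
    if (rn / scale0 < tol &&
        (!constrained || abs(asm$V / 1000 - constraint_volume) <
           1e-4 * constraint_volume)) {
      return(list(d = d, p = p_cur, V = asm$V / 1000, residual = rn / scale0,
                  iterations = it - 1L, history = hist))
    }
    n <- length(res)
    f <- -res
    if (refresh) {
      bc <- apply_dirichlet(asm$K, f, fixed)
      if (constrained) {
        G <- asm$G; G[fixed] <- 0
        Gsp <- Matrix::sparseMatrix(i = which(G != 0), j = rep(1L, sum(G != 0)),
                                    x = G[G != 0], dims = c(n, 1))
        # full bordered system [K, -G; G', 0]: well-posed even when K alone
        # is singular at a limit point
        Kaug <- rbind(cbind(bc$K, -Gsp),
                      cbind(Matrix::t(Gsp),
                            Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                 dims = c(1, 1))))
        lu_cur <- Matrix::lu(Kaug)
      } else {
        lu_cur <- Matrix::lu(bc$K)
      }
      if (!is.null(cache)) cache$lu <- lu_cur
    }
    f[fixed] <- 0
    if (constrained) {
      faug <- c(f, -(asm$V - constraint_volume * 1000))
      sol_aug <- as.numeric(Matrix::solve(lu_cur, faug))
      ddisp <- sol_aug[seq_len(n)]
      dp <- sol_aug[n + 1L]
    } else {
      ddisp <- as.numeric(Matrix::solve(lu_cur, f))
      dp <- 0
    }
    step <- matrix(ddisp, nv, 3, byrow = TRUE)
    merit0 <- merit_of(rn, asm$V)
    alpha <- 1
    best <- NULL
    for (ls in 1:10) {
      d_try <- d + alpha * step
      p_try <- p_cur + alpha * dp
      ok <- TRUE
      m_new <- tryCatch({
        a2 <- em_assemble(ctx, d_try, p_try, Sa, want_K = FALSE, visc = visc)
        r2 <- a2$R; r2[fixed] <- 0
        merit_of(sqrt(sum(r2^2)), a2$V)
      }, error = function(e) { ok <<- FALSE; Inf })
      if (ok && is.finite(m_new)) {
        if (is.null(best) || m_new < best$m) best <- list(m = m_new, alpha = alpha)
        if (m_new < (1 - 1e-4 * alpha) * merit0) break
      }
      alpha <- alpha / 2
    }
    m_reached <- if (!is.null(best)) best$m else Inf
    if (m_reached >= merit0 && !fresh_now) {
      # a stale tangent found no descent: rebuild it and retry in place
      refresh <- TRUE
      emf_log(verbose, "  newton it=%d stale tangent, refreshing", it)
      next
    }
    alpha <- if (!is.null(best)) best$alpha else alpha
    # reuse the tangent only while the step contracts the merit briskly
    refresh <- !(alpha >= 0.99 && m_reached < 0.35 * merit0)
    merit_prev <- merit0
    d <- d + alpha * step
    p_cur <- p_cur + alpha * dp
    emf_log(verbose, "  newton it=%d rn=%.3g c=%.3g alpha=%.4g dp=%.3g refresh=%d",
            it, rn, if (constrained) asm$V - constraint_volume * 1000 else 0,
            alpha, dp, as.integer(refresh))
  }
  stop_emf("Newton divergence after line-search fallback; residual history: ",
           paste(signif(hist, 3), collapse = ", "))
}

#' Inflate the cavity to a target pressure by load continuation
#'
#' Ramps the follower pressure in increments with warm starts, which keeps
#' every Newton solve in its fast-convergence regime.
#'
#' @param ctx an \code{\link{em_context}}.
#' @param p_target cavity pressure (kPa).
#' @param Sa active stress per element (kPa).
#' @param d0 initial displacement.
#' @param step_kPa maximum pressure increment per continuation step.
#' @param ... passed to \code{\link{solve_quasistatic}}.
#' @return the final \code{\link{solve_quasistatic}} result.
#' @export
inflate_to <- function(ctx, p_target, Sa = 0, d0 = NULL, step_kPa = 0.35,
                       visc_eta = 0, ...) {
  mk_visc <- function(d, eta) {
    if (eta <= 0) return(NULL)
    Fp <- ctx_F(ctx, d %||% matrix(0, ctx$nv, 3))
    list(eta_dt = eta, C_prev = t3_mm(t3_t(Fp), Fp))
  }
  polish <- function(res) {
    if (visc_eta <= 0) return(res)
    # (almost) undamped equilibrium from the warm start
    solve_quasistatic(ctx, p = p_target, Sa = Sa, d0 = res$d,
                      visc = mk_visc(res$d, visc_eta / 50), ...)
  }
  # warm-started call: one damped solve at the target usually suffices
  if (!is.null(d0)) {
    direct <- tryCatch(
      solve_quasistatic(ctx, p = p_target, Sa = Sa, d0 = d0,
                        visc = mk_visc(d0, visc_eta), ...),
      error = function(e) e)
    if (!inherits(direct, "error")) return(polish(direct))
  }
  # pressure ramp with adaptive step halving and damping boost on failure
  d <- d0
  p_cur <- 0
  dp <- step_kPa
  eta <- visc_eta
  res <- NULL
  fails <- 0L
  while (p_cur < abs(p_target)) {
    p_next <- min(p_cur + dp, abs(p_target))
    att <- tryCatch(
      solve_quasistatic(ctx, p = sign(p_target) * p_next, Sa = Sa, d0 = d,
                        visc = mk_visc(d, eta), ...),
      error = function(e) e)
    if (inherits(att, "error")) {
      fails <- fails + 1L
      if (fails > 12L) stop(att)
      dp <- dp / 2
      eta <- max(eta * 2, 2)
      next
    }
    res <- att
    d <- res$d
    p_cur <- p_next
    dp <- min(dp * 1.3, step_kPa)
  }
  polish(res)
}

# volume-controlled inflation to a target pressure: the cavity volume is
# ramped with the constrained (multiplier) solver until the multiplier
# reaches p_target, then refined by a secant. Robust where the
# pressure-controlled ramp hits instabilities in soft-wall regimes.
inflate_vc <- function(ctx, p_target, d0 = NULL, dV_frac = 0.02,
                       visc_eta = 10, tol_frac = 1e-3, ...) {
  d <- d0 %||% matrix(0, ctx$nv, 3)
  mk_visc <- function(d) {
    if (visc_eta <= 0) return(NULL)
    Fp <- ctx_F(ctx, d)
    list(eta_dt = visc_eta, C_prev = t3_mm(t3_t(Fp), Fp))
  }
  V0 <- cavity_volume_gradient(ctx, ctx$mesh$vertices + d)$V / 1000
  chain_cache <- new.env(parent = emptyenv())
  at_V <- function(Vt, dw) solve_quasistatic(ctx, p = 0, Sa = 0, d0 = dw,
                                             constraint_volume = Vt,
                                             visc = mk_visc(dw),
                                             cache = chain_cache, ...)
  V_prev <- V0
  res_prev <- at_V(V0, d)
  if (res_prev$p >= p_target) return(res_prev)
  V_cur <- V0
  res <- res_prev
  for (k in 1:120) {
    V_next <- V_cur * (1 + dV_frac)
    res_new <- at_V(V_next, res$d)
    if (res_new$p >= p_target) {
      # secant refinement on the multiplier-pressure curve
      a <- list(V = V_cur, p = res$p, d = res$d)
      b <- list(V = V_next, p = res_new$p, d = res_new$d)
      res <- res_new
      for (it in 1:10) {
        if (abs(res$p - p_target) < tol_frac * p_target) break
        Vc <- b$V + (p_target - b$p) * (b$V - a$V) / (b$p - a$p)
        Vc <- min(max(Vc, min(a$V, b$V)), max(a$V, b$V) * 1.001)
        res <- at_V(Vc, res$d)
        a <- b
        b <- list(V = Vc, p = res$p, d = res$d)
      }
      # near-undamped polish at the found volume
      if (visc_eta > 0) {
        Fp <- ctx_F(ctx, res$d)
        res <- solve_quasistatic(ctx, p = res$p, Sa = 0, d0 = res$d,
                                 constraint_volume = res$V,
                                 visc = list(eta_dt = visc_eta / 50,
                                             C_prev = t3_mm(t3_t(Fp), Fp)),
                                 ...)
      }
      return(res)
    }
    V_cur <- V_next
    res <- res_new
  }
  stop_emf("volume-controlled inflation did not reach the target pressure ",
           "(multiplier ", signif(res$p, 4), " kPa at V = ", signif(V_cur, 5),
           " ml)")
}

#' Klotz end-diastolic pressure-volume relation
#'
#' Single-beat empiric EDPVR: the unloaded volume prediction
#' V_0 = V_m (0.6 - 0.006 P_m) from one measured end-diastolic point, and
#' the normalized curve P = A_n V_n^(B_n) for plotting and fitting
#' (constants from the source study of the relation; configurable).
#'
#' @param V_m measured end-diastolic volume (ml).
#' @param P_m measured end-diastolic pressure (mmHg).
#' @param A_n,B_n normalized-curve constants (mmHg, -).
#' @return object of class \code{klotz_curve}: V_0 (ml), V_30, and
#'   \code{P_of_V} (function, ml -> mmHg).
#' @export
klotz_v0 <- function(V_m, P_m, A_n = 28.2, B_n = 2.79) {
  stopifnot(V_m > 0, P_m > 0)
  if (P_m >= 100)
    stop_emf("P_m >= 100 mmHg puts the predicted unloaded volume at zero ",
             "or below; the empiric relation does not apply")
  V_0 <- V_m * (0.6 - 0.006 * P_m)
  V_30 <- V_0 + (V_m - V_0) / (P_m / A_n)^(1 / B_n)
  P_of_V <- function(V) {
    Vn <- (V - V_0) / (V_30 - V_0)
    ifelse(Vn > 0, A_n * Vn^B_n, 0)
  }
  structure(list(V_m = V_m, P_m = P_m, V_0 = V_0, V_30 = V_30,
                 A_n = A_n, B_n = B_n, P_of_V = P_of_V),
            class = "klotz_curve")
}

#' Unload a pressurized configuration by backward displacement
#'
#' Fixed-point iteration X_ref <- X_ED - d(X_ref; p_ED): the reference
#' coordinates are corrected by the displacement obtained from re-inflating
#' the current reference guess to the end-diastolic pressure, until the
#' largest vertex update drops below \code{tol}. Re-inflating the returned
#' reference reproduces the input geometry to the same tolerance.
#'
#' @param mesh solid mesh in the end-diastolic (pressurized) configuration.
#' @param p_ED end-diastolic cavity pressure (kPa).
#' @param materials material map.
#' @param fibers optional fiber frame (recomputed per iterate otherwise).
#' @param max_iter fixed-point iteration cap.
#' @param tol vertex-update tolerance (mm).
#' @return list with \code{mesh} (reference configuration), \code{V0} (its
#'   cavity volume, ml), \code{iterations}, \code{updates} (max update per
#'   iteration) and the final inflation result \code{check}.
#' @export
unload_backward_displacement <- function(mesh, p_ED,
                                         materials = default_materials(),
                                         fibers = NULL, max_iter = 25L,
                                         tol = 1e-3, ref0 = NULL) {
  if (any(mesh$element_labels %in% c("lvbp", "aobp"))) mesh <- solid_submesh(mesh)
  X_ED <- mesh$vertices
  ref <- mesh
  if (!is.null(ref0)) ref$vertices <- ref0   # warm-started reference guess
  fib <- fibers %||% assign_fibers(mesh)
  updates <- numeric(0)
  res <- NULL
  d_warm <- NULL
  step_prev <- NULL
  converged <- FALSE
  omega <- 0.8   # Aitken relaxation
  for (it in seq_len(max_iter)) {
    ctx <- em_context(ref, fibers = fib, materials = materials)
    res <- tryCatch(inflate_vc(ctx, p_ED, d0 = d_warm),
                    error = function(e) e)
    if (inherits(res, "error"))   # stale warm start: redo the ramp cold
      res <- inflate_vc(ctx, p_ED, d0 = NULL)
    step <- (X_ED - res$d) - ref$vertices
    upd <- max(row_norm(step))
    updates <- c(updates, upd)
    # the re-inflation carries its own tolerance, which puts a floor under
    # the attainable update; accept a stalled plateau near that floor
    stalled <- it >= 8L && upd < 0.02 && upd > 0.6 * updates[it - 1L]
    if (upd < tol || stalled) {
      ref$vertices <- ref$vertices + step
      converged <- TRUE
      break
    }
    if (!is.null(step_prev)) {
      dstep <- step - step_prev
      denom <- sum(dstep^2)
      if (denom > 0) omega <- min(max(-omega * sum(step_prev * dstep) / denom,
                                      0.1), 1.5)
    }
    # keep the updated reference geometrically valid
    om <- omega
    for (g in 1:8) {
      cand <- ref$vertices + om * step
      if (all(element_volumes(ref, cand) > 0)) break
      om <- om / 2
    }
    ref$vertices <- ref$vertices + om * step
    step_prev <- step
    d_warm <- res$d
    if (p_ED == 0) break
  }
  if (!converged && updates[length(updates)] >= tol && p_ED != 0)
    stop_emf("backward displacement did not converge; updates: ",
             paste(signif(updates, 3), collapse = ", "))
  ctx <- em_context(ref, fibers = fib, materials = materials)
  list(mesh = ref, V0 = cavity_volume(ref), iterations = length(updates),
       updates = updates, check = res)
}

#' Fit the myocardial stiffness scale against the Klotz relation
#'
#' Sweeps a trial grid of C_Guc values; for each, the end-diastolic mesh is
#' unloaded by backward displacement and the unloaded cavity volume is
#' compared with the Klotz prediction. Returns the trial with the smallest
#' absolute relative error (the acceptance criterion for the fit is a
#' mismatch below 5\%).
#'
#' @param mesh solid mesh at end diastole.
#' @param p_ED end-diastolic pressure (kPa).
#' @param V_m,P_m measured end-diastolic volume (ml) and pressure (mmHg)
#'   defining the Klotz prediction (defaults: the mesh's own cavity volume
#'   and \code{p_ED} converted to mmHg).
#' @param trial_grid candidate C_Guc values (kPa).
#' @param ... passed to \code{\link{unload_backward_displacement}}.
#' @return list with \code{C_Guc}, \code{rel_error} (fraction),
#'   \code{within_5pct}, \code{table} (per-trial results) and the winning
#'   \code{unloaded} result.
#' @export
fit_cguc <- function(mesh, p_ED, V_m = NULL, P_m = NULL,
                     trial_grid = c(0.2, 0.4, 0.8), max_refine = 4L,
                     unload_tol = 8e-3, ...) {
  if (any(mesh$element_labels %in% c("lvbp", "aobp"))) mesh <- solid_submesh(mesh)
  V_m <- V_m %||% cavity_volume(mesh)
  P_m <- P_m %||% kPa_to_mmHg(p_ED)
  kl <- klotz_v0(V_m, P_m)
  rows <- list(); best <- NULL
  ref_warm <- NULL
  try_one <- function(cg) {
    un <- tryCatch(
      unload_backward_displacement(mesh, p_ED,
                                   materials = default_materials(C_Guc = cg),
                                   ref0 = ref_warm, tol = unload_tol, ...),
      error = function(e) e)
    if (inherits(un, "error")) {
      rows[[length(rows) + 1L]] <<- data.frame(C_Guc = cg, V0_model = NA_real_,
                                               V0_klotz = kl$V_0,
                                               rel_error = NA_real_)
      return(NA_real_)
    }
    ref_warm <<- un$mesh$vertices
    err <- (un$V0 - kl$V_0) / kl$V_0
    rows[[length(rows) + 1L]] <<- data.frame(C_Guc = cg, V0_model = un$V0,
                                             V0_klotz = kl$V_0, rel_error = err)
    if (is.null(best) || abs(err) < abs(best$rel_error)) {
      best <<- list(C_Guc = cg, rel_error = err, unloaded = un)
    }
    err
  }
  exec_grid <- sort(trial_grid, decreasing = TRUE)  # stiff first: each
  errs <- numeric(0)                                # softer trial warm-starts
  for (cg in exec_grid) {
    errs <- c(errs, try_one(cg))
    if (isTRUE(any(errs < 0, na.rm = TRUE)) &&
        isTRUE(any(errs > 0, na.rm = TRUE))) break  # bracketed already
  }
  exec_grid <- exec_grid[seq_along(errs)]
  # unloaded volume grows with stiffness: when the sweep brackets the Klotz
  # prediction, bisect the bracketing pair until within the 5% criterion
  ord <- order(exec_grid)
  g_sorted <- exec_grid[ord]; e_sorted <- errs[ord]
  if (is.null(best)) stop_emf("no stiffness trial could be unloaded")
  e_sorted[is.na(e_sorted)] <- Inf
  if (abs(best$rel_error) > 0.045 && any(e_sorted < 0) &&
      any(is.finite(e_sorted) & e_sorted > 0)) {
    i_lo <- max(which(e_sorted < 0))
    lo <- g_sorted[i_lo]; hi <- g_sorted[min(i_lo + 1L, length(g_sorted))]
    for (r in seq_len(max_refine)) {
      if (abs(best$rel_error) <= 0.045) break
      mid <- sqrt(lo * hi)
      e_mid <- try_one(mid)
      if (e_mid < 0) lo <- mid else hi <- mid
    }
  }
  tab <- do.call(rbind, rows)
  if (abs(best$rel_error) > 0.05)
    warning(sprintf("no trial stiffness meets the 5%% Klotz criterion (best %.1f%%)",
                    100 * abs(best$rel_error)))
  list(C_Guc = best$C_Guc, rel_error = best$rel_error,
       within_5pct = abs(best$rel_error) <= 0.05, table = tab,
       unloaded = best$unloaded, klotz = kl)
}

#' Run one heartbeat: filling, IVC, ejection, IVR
#'
#' Phase machine driving the quasi-static mechanics with the activation map
#' and the active stress transient against the LV Windkessel afterload:
#' pressure-ramp filling to the end-diastolic pressure, isovolumetric
#' contraction with the cavity volume held by the pressure multiplier,
#' ejection coupled to the Windkessel (valve opens when p_lv exceeds p_ao,
#' closes when the flow reverses, with a chattering guard), and
#' isovolumetric relaxation. The flux fed to the Windkessel is the previous
#' step's volume change (semi-implicit coupling).
#'
#' @param ctx an \code{\link{em_context}}.
#' @param activation an \code{activation_map} on the context mesh (or a
#'   per-element activation-time vector).
#' @param act \code{\link{active_params}}.
#' @param wk \code{\link{windkessel_lv}} (valve resistance included).
#' @param p_ED end-diastolic pressure (kPa).
#' @param p_ao0 initial aortic pressure (kPa).
#' @param p_la constant left-atrial filling pressure (kPa); IVR ends when
#'   p_lv falls below it.
#' @param dt mechanics time step (ms).
#' @param t_end simulation end (ms).
#' @param n_fill filling continuation steps.
#' @param store_displacements keep the displacement snapshot of every
#'   \code{store_stride}-th step (for the CFD kinematic transfer).
#' @param store_stride snapshot stride.
#' @param verbose print per-step progress.
#' @return object of class \code{emf_heartbeat}: \code{trace} (data.frame:
#'   time_ms, phase, p_lv_kPa, p_ao_kPa, V_lv_ml, q_lv_ml_s),
#'   \code{metrics} (EDV, ESV, SV, EF, p_peak, dpdt_max, valve times),
#'   \code{snapshots} (list of displacement matrices), \code{snapshot_times}.
#' @export
run_heartbeat <- function(ctx, activation, act = active_params(),
                          wk = windkessel_lv(R_av = 1),
                          p_ED = mmHg_to_kPa(10), p_ao0 = mmHg_to_kPa(71.1),
                          p_la = mmHg_to_kPa(8), dt = 0.5, t_end = 600,
                          n_fill = 6, store_displacements = TRUE,
                          store_stride = 1L, visc_eta = 10, verbose = FALSE) {
  el <- ctx$mesh$elements
  if (inherits(activation, "activation_map")) {
    tv <- activation$t_a
    t_a_el <- rowMeans(matrix(tv[el], nrow(el), 4L))
  } else t_a_el <- rep_len(activation, ctx$ne)
  is_lv <- ctx$mesh$element_labels == "lv"
  t_a_el[!is_lv] <- Inf  # only myocardium contracts
  if (!is.null(ctx$fibers$apex_degenerate))
    t_a_el[ctx$fibers$apex_degenerate] <- Inf  # no tension on degenerate frames

  # ---- filling (volume-controlled ramp: robust for a compliant base) ----
  fill <- inflate_vc(ctx, p_ED)
  d <- fill$d
  EDV <- fill$V
  phase <- "IVC"
  p_lv <- fill$p
  p_ao <- p_ao0
  wk_noav <- wk; wk_noav$R_av <- 0
  V <- EDV
  q <- 0; q_prev <- 0
  rows <- list(); snaps <- list(); snap_t <- c()
  valve_open_t <- NA_real_; valve_close_t <- NA_real_
  sec_slope <- NULL
  eject_steps <- 0L
  Sa_prev <- rep(0, ctx$ne)
  neg_q_run <- 0L
  chatter <- 0L
  t <- 0
  step_i <- 0L
  while (t < t_end) {
    t <- t + dt
    step_i <- step_i + 1L
    Sa <- active_stress_scalar(t, t_a_el, p = act)
    Sa[!is_lv] <- 0
    visc <- NULL
    if (visc_eta > 0) {
      Fp <- ctx_F(ctx, d)
      visc <- list(eta_dt = visc_eta / dt, C_prev = t3_mm(t3_t(Fp), Fp))
    }
    Sa_prev_step <- Sa
    if (phase == "IVC") {
      sol <- solve_substep(ctx, p_lv, Sa, Sa_prev, d, EDV, visc)
      d <- sol$d; p_lv <- sol$p; V <- sol$V
      p_ao <- wk3_lv_step(p_ao, 0, 0, wk_noav, dt)
      q <- 0
      if (p_lv > p_ao) {
        phase <- "ejection"; valve_open_t <- t
        q <- 0; q_prev <- 0; eject_steps <- 0L
      }
    } else if (phase == "ejection") {
      # balance the mechanics multiplier against the Windkessel pressure:
      # find V* with p_mech(V*) = p_wk(q), q = (V_n - V*)/dt (secant on the
      # scalar gap; each evaluation is a volume-constrained saddle solve)
      p_wk_of <- function(qq) wk3_lv_step(p_lv, qq, (qq - q) / dt, wk, dt)
      eval_gap <- function(Vt, d_init) {
        sol <- solve_substep(ctx, p_lv, Sa, Sa_prev, d_init, Vt, visc)
        list(sol = sol, gap = sol$p - p_wk_of((V - Vt) / dt))
      }
      # flow-continuation prediction, then secant with the slope carried
      # over from the previous step (the gap is nearly linear in V)
      Va <- min(max(V - q * dt, 0.9 * V), V * 1.02)
      ea <- eval_gap(Va, d)
      Vb <- if (!is.null(sec_slope) && is.finite(sec_slope) && sec_slope > 0) {
        Va - ea$gap / sec_slope
      } else Va - max(q * dt, 0.005 * V) / 4
      Vb <- min(max(Vb, 0.9 * V), V * 1.02)
      if (abs(Vb - Va) < 1e-6) Vb <- Va - 1e-3 * V
      eb <- eval_gap(Vb, ea$sol$d)
      for (sec in 1:4) {
        if (abs(eb$gap) < 0.05 || abs(Vb - Va) < 1e-4) break
        Vc <- Vb - eb$gap * (Vb - Va) / (eb$gap - ea$gap)
        Va <- Vb; ea <- eb
        Vc <- min(max(Vc, 0.9 * V), V * 1.02)
        eb <- eval_gap(Vc, eb$sol$d)
        Vb <- Vc
      }
      if (abs(Vb - Va) > 1e-9) sec_slope <- (eb$gap - ea$gap) / (Vb - Va)
      sol <- eb$sol
      q_prev <- q
      q <- (V - Vb) / dt   # ml/ms, positive while ejecting
      d <- sol$d; V <- Vb; p_lv <- sol$p
      p_ao <- p_lv - (wk$Z_c + wk$R_av) * q
      eject_steps <- eject_steps + 1L
      if (q < 0) neg_q_run <- neg_q_run + 1L else {
        if (neg_q_run > 0) chatter <- chatter + 1L
        neg_q_run <- 0L
      }
      if (eject_steps > 5L && neg_q_run >= 2L) {
        phase <- "IVR"; valve_close_t <- t
      }
    } else { # IVR
      sol <- solve_substep(ctx, p_lv, Sa, Sa_prev, d, V, visc)
      d <- sol$d; p_lv <- sol$p
      q <- 0
      p_ao <- wk3_lv_step(p_ao, 0, 0, wk_noav, dt)
      if (p_lv < p_la || all(Sa == 0)) {
        rows[[step_i]] <- data.frame(time_ms = t, phase = phase,
                                     p_lv_kPa = p_lv, p_ao_kPa = p_ao,
                                     V_lv_ml = V, q_lv_ml_s = 1000 * q)
        break
      }
    }
    Sa_prev <- Sa_prev_step
    rows[[step_i]] <- data.frame(time_ms = t, phase = phase, p_lv_kPa = p_lv,
                                 p_ao_kPa = p_ao, V_lv_ml = V,
                                 q_lv_ml_s = 1000 * q)
    if (store_displacements && step_i %% store_stride == 0L) {
      snaps[[length(snaps) + 1L]] <- d
      snap_t <- c(snap_t, t)
    }
    emf_log(verbose, "t=%6.1f ms phase=%s p_lv=%.1f mmHg V=%.1f ml",
            t, phase, kPa_to_mmHg(p_lv), V)
  }
  if (chatter > 0) message("valve chattering guard engaged ", chatter, " time(s)")
  trace <- do.call(rbind, rows)
  ESV <- min(trace$V_lv_ml)
  dpdt <- diff(trace$p_lv_kPa) / dt
  metrics <- list(EDV = EDV, ESV = ESV, SV = EDV - ESV,
                  EF = 100 * (EDV - ESV) / EDV,
                  p_peak = max(trace$p_lv_kPa),
                  dpdt_max = max(dpdt),
                  valve_open_t = valve_open_t, valve_close_t = valve_close_t,
                  chatter = chatter)
  structure(list(trace = trace, metrics = metrics, snapshots = snaps,
                 snapshot_times = snap_t, d_ED = fill$d, dt = dt,
                 wk = wk, p_ED = p_ED),
            class = "emf_heartbeat")
}

# constrained solve with adaptive sub-stepping of the active stress: if the
# solve fails, the step's Sa change is split and applied in halves
solve_substep <- function(ctx, p, Sa, Sa_prev, d0, V_target, visc,
                          depth = 0L) {
  res <- tryCatch(
    solve_quasistatic(ctx, p = p, Sa = Sa, d0 = d0,
                      constraint_volume = V_target, visc = visc),
    error = function(e) e)
  if (!inherits(res, "error")) return(res)
  if (depth >= 3L) stop(res)
  Sa_mid <- (Sa + Sa_prev) / 2
  mid <- solve_substep(ctx, p, Sa_mid, Sa_prev, d0, V_target, visc,
                       depth + 1L)
  solve_substep(ctx, mid$p, Sa, Sa_mid, mid$d, V_target, visc, depth + 1L)
}

#' Energy bookkeeping across the Windkessel coupling
#'
#' Splits the ejection-phase PV work into Windkessel-side terms: dissipation
#' in the proximal (Z_c + R_av) and peripheral (R) resistances and the
#' change of energy stored in the compliance.
#'
#' @param hb an \code{emf_heartbeat}.
#' @return list with \code{lv_work} (kPa ml = mJ), \code{wk_absorbed}, and
#'   the relative mismatch \code{rel_gap}.
#' @export
wk_energy_balance <- function(hb) {
  tr <- hb$trace
  ej <- which(tr$phase == "ejection")
  if (length(ej) < 3) stop_emf("no ejection phase in trace")
  dt <- hb$dt
  wk <- hb$wk
  Zt <- wk$Z_c + wk$R_av
  q <- tr$q_lv_ml_s[ej] / 1000       # ml/ms
  p <- tr$p_lv_kPa[ej]
  Vd <- tr$V_lv_ml[ej]
  lv_work <- sum(p[-1] * (-diff(Vd)))
  p_c <- p - Zt * q
  diss <- sum((Zt * q^2 + p_c^2 / wk$R) * dt)
  cap <- 0.5 * wk$C * (p_c[length(p_c)]^2 - p_c[1]^2)
  wk_absorbed <- diss + cap
  list(lv_work = lv_work, wk_absorbed = wk_absorbed,
       rel_gap = abs(lv_work - wk_absorbed) / abs(lv_work))
}

#' Fit active stress parameters to pressure targets
#'
#' Deterministic coordinate/grid search over (S_peak, tau_c0) minimizing the
#' summed squared relative error against the peak LV pressure and the
#' maximum rate of pressure rise.
#'
#' @param ctx an \code{\link{em_context}}.
#' @param activation activation map or per-element times.
#' @param params0 starting \code{\link{active_params}}.
#' @param targets list with \code{p_peak} (kPa) and \code{dpdt_max}
#'   (kPa/ms).
#' @param S_peak_grid,tau_c0_grid candidate values; the bounds are the grid
#'   extremes.
#' @param budget maximum heartbeat evaluations (0 returns \code{params0}).
#' @param ... passed to \code{\link{run_heartbeat}}.
#' @return list with \code{params}, \code{error}, \code{at_bound},
#'   \code{evaluations}, \code{table}.
#' @export
fit_active <- function(ctx, activation, params0 = active_params(), targets,
                       S_peak_grid = c(40, 60, 80),
                       tau_c0_grid = c(20, 30, 45), budget = 25L, ...) {
  if (budget <= 0)
    return(list(params = params0, error = NA_real_, at_bound = FALSE,
                evaluations = 0L, table = NULL))
  rows <- list(); best <- NULL; nev <- 0L
  for (sp in S_peak_grid) for (tc in tau_c0_grid) {
    if (nev >= budget) break
    pa <- params0; pa$S_peak <- sp; pa$tau_c0 <- tc
    hb <- run_heartbeat(ctx, activation, act = pa, ...)
    nev <- nev + 1L
    err <- ((hb$metrics$p_peak - targets$p_peak) / targets$p_peak)^2 +
      ((hb$metrics$dpdt_max - targets$dpdt_max) / targets$dpdt_max)^2
    rows[[nev]] <- data.frame(S_peak = sp, tau_c0 = tc, error = err,
                              p_peak = hb$metrics$p_peak,
                              dpdt_max = hb$metrics$dpdt_max)
    if (is.null(best) || err < best$error)
      best <- list(S_peak = sp, tau_c0 = tc, error = err)
  }
  pa <- params0; pa$S_peak <- best$S_peak; pa$tau_c0 <- best$tau_c0
  at_bound <- best$S_peak %in% range(S_peak_grid) ||
    best$tau_c0 %in% range(tau_c0_grid)
  if (at_bound) warning("fit_active: best point lies on a grid bound")
  list(params = pa, error = best$error, at_bound = at_bound,
       evaluations = nev, table = do.call(rbind, rows))
}
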