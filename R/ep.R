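#' Cardiac electrophysiology: eikonal activation and reaction-eikonal
#'
#' The activation sequence is the first-arrival-time solution of the
#' anisotropic eikonal equation grad(t_a)' V grad(t_a) = 1, where the
#' symmetric positive definite tensor V carries the squared conduction
#' velocities along the fiber, sheet and sheet-normal axes. The arrival
#' times then drive a monodomain reaction model through an
#' arrival-time-gated foot current, which lets coarse meshes reproduce the
#' eikonal sequence that a plain reaction-diffusion model would propagate
#' too slowly.
#'
#' @name electrophysiology
NULL

#' Conduction velocities along the tissue eigenaxes
#'
#' @param v_f,v_s,v_n wavefront speeds along fiber / sheet / sheet-normal
#'   (m/s; numerically identical to mm/ms, the internal unit).
#' @return list of class \code{conduction_velocities}.
#' @export
conduction_velocities <- function(v_f = 0.6, v_s = 0.4, v_n = 0.2) {
  if (any(c(v_f, v_s, v_n) <= 0))
    stop_emf("conduction velocities must be positive (V must be SPD)")
  structure(list(v_f = v_f, v_s = v_s, v_n = v_n),
            class = "conduction_velocities")
}

# inverse velocity-squared metric M = V^{-1} per element (n x 9), 3D
eikonal_metric <- function(fibers, v, ne) {
  vf <- rep_len(v$v_f, ne); vs <- rep_len(v$v_s, ne); vn <- rep_len(v$v_n, ne)
  t3_outer(fibers$f0, fibers$f0) / vf^2 +
    t3_outer(fibers$s0, fibers$s0) / vs^2 +
    t3_outer(fibers$n0, fibers$n0) / vn^2
}

#' Solve the anisotropic eikonal equation
#'
#' Fixed-point (fast-iterative, Jacobi-sweep) solver on a simplicial mesh.
#' Every vertex is repeatedly updated from the faces opposite to it in each
#' incident element, taking the minimum over face-interior, edge and vertex
#' characteristic paths under the metric sqrt(d' V^{-1} d); sweeps stop when
#' the largest update falls below \code{tol}. Deterministic. Vertices
#' unreachable from the sources keep \code{Inf} and are flagged.
#'
#' @param mesh an \code{emf_mesh} (2D or 3D).
#' @param fibers an \code{emf_fibers} frame (ignored for isotropic 2D runs).
#' @param v \code{\link{conduction_velocities}} (a single speed may be given
#'   as \code{v_f} with \code{v_s = v_n = v_f} for isotropy).
#' @param sources list with \code{vertices} (indices) and \code{t0} (ms).
#' @param region optional label set restricting the solve (default: all).
#' @param tol convergence tolerance (ms).
#' @param max_sweeps safety cap on Jacobi sweeps.
#' @return object of class \code{activation_map}: list with per-vertex
#'   \code{t_a} (ms, \code{Inf} if unreachable), \code{sources},
#'   \code{unreached} flags.
#' @export
solve_eikonal <- function(mesh, fibers = NULL, v = conduction_velocities(),
                          sources, region = NULL, tol = 1e-3,
                          max_sweeps = 2000L) {
  if (length(sources$vertices) == 0) stop_emf("at least one source required")
  el <- mesh$elements
  keep <- if (is.null(region)) seq_len(nrow(el)) else which(mesh$element_labels %in% region)
  el <- el[keep, , drop = FALSE]
  d <- mesh$dim
  ne <- nrow(el)
  nv <- nrow(mesh$vertices)
  if (d == 3L) {
    if (is.null(fibers))
      fibers <- list(f0 = matrix(rep(c(1, 0, 0), each = ne), ne, 3),
                     s0 = matrix(rep(c(0, 1, 0), each = ne), ne, 3),
                     n0 = matrix(rep(c(0, 0, 1), each = ne), ne, 3))
    M <- eikonal_metric(list(f0 = fibers$f0[keep, , drop = FALSE],
                             s0 = fibers$s0[keep, , drop = FALSE],
                             n0 = fibers$n0[keep, , drop = FALSE]), v, ne)
  } else {
    # 2D: isotropic (v_f) or metric from in-plane fiber via first two axes
    M <- NULL
  }
  co <- mesh$vertices
  nn <- d + 1L
  # one update stencil per (element, target local vertex)
  tgt <- c(); I <- c(); J <- c(); K <- c()
  for (a in seq_len(nn)) {
    oth <- setdiff(seq_len(nn), a)
    tgt <- c(tgt, el[, a])
    I <- c(I, el[, oth[1]])
    J <- c(J, el[, oth[2]])
    K <- c(K, if (d == 3L) el[, oth[3]] else rep(NA_integer_, ne))
  }
  mdot <- function(u, w, rows) {
    if (d == 3L) rowSums(u * t3_mv(M[rows, , drop = FALSE], w))
    else rowSums(u * w) / v$v_f^2
  }
  rows <- rep(seq_len(ne), nn)
  e1 <- co[J, , drop = FALSE] - co[I, , drop = FALSE]
  vv_ <- co[tgt, , drop = FALSE] - co[I, , drop = FALSE]
  g11 <- mdot(e1, e1, rows)
  b1 <- mdot(e1, vv_, rows)
  vMv <- mdot(vv_, vv_, rows)
  if (d == 3L) {
    e2 <- co[K, , drop = FALSE] - co[I, , drop = FALSE]
    g22 <- mdot(e2, e2, rows)
    g12 <- mdot(e1, e2, rows)
    b2 <- mdot(e2, vv_, rows)
    detG <- g11 * g22 - g12^2
  }
  line_update <- function(tI, tJ, g, b, vMvloc) {
    # minimize over a in [0,1]: tI + a (tJ - tI) + ||v - a e||_M
    dt <- tJ - tI
    cand <- rep(Inf, length(tI))
    denom <- 1 - dt^2 / g
    ok <- is.finite(dt) & denom > 1e-14
    w0 <- pmax(vMvloc - b^2 / g, 0)
    s <- sqrt(w0[ok] / denom[ok])
    aa <- (b[ok] - s * dt[ok]) / g[ok]
    feas <- aa >= 0 & aa <= 1
    val <- tI[ok] + aa * dt[ok] + s
    val[!feas] <- Inf
    cand[ok] <- val
    cand
  }
  t_a <- rep(Inf, nv)
  t_a[sources$vertices] <- sources$t0
  src <- sources$vertices
  for (sweep in seq_len(max_sweeps)) {
    tI <- t_a[I]; tJ <- t_a[J]
    # vertex candidates
    cand <- pmin(tI + sqrt(vMv),
                 tJ + sqrt(pmax(vMv - 2 * b1 + g11, 0)))
    # edge I-J
    cand <- pmin(cand, line_update(tI, tJ, g11, b1, vMv))
    if (d == 3L) {
      tK <- t_a[K]
      cand <- pmin(cand, tK + sqrt(pmax(vMv - 2 * b2 + g22, 0)))
      cand <- pmin(cand, line_update(tI, tK, g22, b2, vMv))
      # edge J-K (base J)
      gJK <- g11 + g22 - 2 * g12
      bJK <- b2 - b1 - g12 + g11
      vJ <- vMv - 2 * b1 + g11
      cand <- pmin(cand, line_update(tJ, tK, pmax(gJK, 1e-300), bJK, vJ))
      # face interior
      d1 <- tJ - tI; d2 <- tK - tI
      Gi11 <- g22 / detG; Gi22 <- g11 / detG; Gi12 <- -g12 / detG
      dGd <- d1 * (Gi11 * d1 + Gi12 * d2) + d2 * (Gi12 * d1 + Gi22 * d2)
      c01 <- Gi11 * b1 + Gi12 * b2
      c02 <- Gi12 * b1 + Gi22 * b2
      w0M <- pmax(vMv - (b1 * c01 + b2 * c02), 0)
      denom <- 1 - dGd
      ok <- is.finite(d1) & is.finite(d2) & denom > 1e-14
      s <- sqrt(w0M[ok] / denom[ok])
      a1 <- c01[ok] - s * (Gi11[ok] * d1[ok] + Gi12[ok] * d2[ok])
      a2 <- c02[ok] - s * (Gi12[ok] * d1[ok] + Gi22[ok] * d2[ok])
      feas <- a1 >= 0 & a2 >= 0 & (a1 + a2) <= 1
      val <- tI[ok] + a1 * d1[ok] + a2 * d2[ok] + s
      val[!feas] <- Inf
      face_cand <- rep(Inf, length(tI))
      face_cand[ok] <- val
      cand <- pmin(cand, face_cand)
    }
    fin <- is.finite(cand)
    if (!any(fin)) break
    # min candidate per target vertex: sort then take the first per group
    o <- order(tgt[fin], cand[fin])
    tg_o <- tgt[fin][o]
    first <- !duplicated(tg_o)
    new_t <- cand[fin][o][first]
    vidx <- tg_o[first]
    t_new <- t_a
    t_new[vidx] <- pmin(t_new[vidx], new_t)
    t_new[src] <- sources$t0
    delta <- max(abs(t_new - t_a)[is.finite(t_new) & is.finite(t_a)],
                 if (any(is.finite(t_new) & !is.finite(t_a))) Inf else 0)
    t_a <- t_new
    if (delta < tol) break
  }
  structure(list(t_a = t_a, sources = sources,
                 unreached = !is.finite(t_a), sweeps = sweep),
            class = "activation_map")
}

#' Monodomain / reaction-eikonal parameters
#'
#' @param beta_sv surface-to-volume ratio (1/cm).
#' @param C_m membrane capacitance (uF/cm^2).
#' @param sigma_i intracellular conductivity along the fiber (S/m).
#' @param foot list with \code{amplitude} (uA/cm^2; \code{NULL} =
#'   auto-calibrated so rest reaches threshold at t_a), \code{tau} (ms) and
#'   \code{duration} (ms) of the exponential foot current.
#' @param dt_ep reaction time step (ms; 0.025 ms = 25 us).
#' @param ionic_model name of the ionic model plug-in; the built-in default
#'   is a two-variable cubic activation / slow recovery model
#'   (\code{"two_variable"}). A ten Tusscher-class interface is accepted by
#'   name but ships without an implementation.
#' @return list of class \code{monodomain_params}.
#' @export
monodomain_params <- function(beta_sv = 1400, C_m = 1, sigma_i = 0.174,
                              foot = list(amplitude = NULL, tau = 2,
                                          duration = 10),
                              dt_ep = 0.025, ionic_model = "two_variable") {
  stopifnot(dt_ep > 0, beta_sv > 0, C_m > 0, sigma_i > 0)
  structure(list(beta_sv = beta_sv, C_m = C_m, sigma_i = sigma_i,
                 foot = utils::modifyList(list(amplitude = NULL, tau = 2,
                                               duration = 10), foot),
                 dt_ep = dt_ep, ionic_model = ionic_model),
            class = "monodomain_params")
}

#' Ionic model plug-ins
#'
#' Returns an ionic model by name. The default \code{"two_variable"} model
#' is a phenomenological cubic-activation / slow-recovery model resting at
#' -85 mV with an action-potential amplitude of about 120 mV; its
#' activation threshold sits near -67 mV.
#'
#' @param name model name.
#' @return list with \code{rest}, \code{threshold}, \code{init},
#'   \code{I_ion} (uA/cm^2) and \code{step_state}.
#' @export
ionic_model <- function(name = "two_variable") {
  if (name == "two_variable") {
    V_rest <- -85; amp <- 120; k <- 8; a <- 0.15; tau <- 3
    eps0 <- 0.002; mu1 <- 0.2; mu2 <- 0.3
    list(name = name, rest = V_rest, threshold = V_rest + a * amp,
         init = function(n) list(w = numeric(n)),
         I_ion = function(V, state, C_m = 1) {
           u <- (V - V_rest) / amp
           -C_m * amp / tau * (k * u * (1 - u) * (u - a) - u * state$w)
         },
         step_state = function(V, state, dt) {
           u <- (V - V_rest) / amp
           eps <- eps0 + mu1 * state$w / (u + mu2)
           state$w <- state$w + dt / tau *
             eps * (-state$w - k * u * (u - a - 1))
           state
         })
  } else if (name == "ten_tusscher") {
    stop_emf("the ten Tusscher ionic interface is declared but not implemented; ",
             "use 'two_variable'")
  } else stop_emf("unknown ionic model: ", name)
}

foot_amplitude <- function(params, ion) {
  # calibrated so the foot alone lifts the resting potential well past
  # threshold (to about -25 mV) by t = t_a: near threshold the cubic
  # kinetics sit close to an unstable equilibrium and the upstroke would
  # otherwise take off tens of milliseconds late
  dV <- -25 - ion$rest
  dV * params$beta_sv * params$C_m /
    (params$foot$tau * (1 - exp(-params$foot$duration / params$foot$tau)))
}

#' Simulate the (reaction-eikonal) monodomain on a cable or mesh
#'
#' Operator splitting: explicit ionic update and arrival-time-gated foot
#' current at \code{dt_ep}, implicit P1 diffusion. On a cable, pass the
#' node positions \code{x} (mm); on a mesh, diffusion uses the fiber-frame
#' conductivity along f0. With \code{use_foot = FALSE} and a
#' \code{stimulus}, the plain reaction-diffusion monodomain is recovered.
#'
#' @param x cable node positions (mm), or an \code{emf_mesh}.
#' @param t_a per-node activation times (ms; finite where simulated), or
#'   an \code{activation_map}.
#' @param params \code{\link{monodomain_params}}.
#' @param duration simulated time (ms).
#' @param fibers fiber frame (mesh input only).
#' @param use_foot apply the foot current (reaction-eikonal mode).
#' @param stimulus optional list(\code{nodes}, \code{t0}, \code{amplitude},
#'   \code{duration}) transmembrane stimulus (reaction-diffusion mode).
#' @param dt_out output sampling interval (ms).
#' @return list with \code{time_ms}, voltage matrix \code{V} (nodes x
#'   samples), per-node depolarization times \code{t_depol} (V crossing
#'   -20 mV) and the parameters used.
#' @export
simulate_reaction_eikonal <- function(x, t_a, params = monodomain_params(),
                                      duration = 100, fibers = NULL,
                                      use_foot = TRUE, stimulus = NULL,
                                      dt_out = 0.5) {
  ion <- ionic_model(params$ionic_model)
  if (inherits(t_a, "activation_map")) t_a <- t_a$t_a
  if (use_foot && any(!is.finite(t_a)))
    stop_emf("t_a must be finite on the simulated region")
  # diffusion coefficient sigma/(beta C_m) in mm^2/ms
  D <- 1000 * params$sigma_i / (params$beta_sv * params$C_m)
  if (inherits(x, "emf_mesh")) {
    mesh <- x
    n <- nrow(mesh$vertices)
    tensor <- if (!is.null(fibers) && mesh$dim == 3L) {
      ne <- nrow(mesh$elements)
      D * (t3_outer(fibers$f0, fibers$f0) +
             (params$sigma_i_ratio %||% 0.25) *
             (t3_outer(fibers$s0, fibers$s0) + t3_outer(fibers$n0, fibers$n0)))
    } else NULL
    Kd <- assemble_scalar_stiffness(mesh, coef = if (is.null(tensor)) D else 1,
                                    tensor = tensor)
    Mm <- assemble_mass(mesh, lumped = TRUE)
  } else {
    x <- as.numeric(x)
    n <- length(x)
    if (n > 1L) {
      h <- diff(x)
      iK <- c(); jK <- c(); xK <- c()
      for (e in seq_len(n - 1L)) {
        k <- D / h[e]
        iK <- c(iK, e, e, e + 1L, e + 1L)
        jK <- c(jK, e, e + 1L, e, e + 1L)
        xK <- c(xK, k, -k, -k, k)
      }
      Kd <- Matrix::sparseMatrix(i = iK, j = jK, x = xK, dims = c(n, n))
      lump <- c(h / 2, 0) + c(0, h / 2)
      Mm <- Matrix::Diagonal(n, lump)
    } else {
      Kd <- Matrix::Matrix(0, 1, 1, sparse = TRUE)
      Mm <- Matrix::Diagonal(1, 1)
    }
  }
  dt <- params$dt_ep
  A <- Mm + dt * Kd
  A_fac <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  amp <- params$foot$amplitude %||% foot_amplitude(params, ion)
  V <- rep(ion$rest, n)
  st <- ion$init(n)
  nt <- ceiling(duration / dt)
  out_every <- max(1L, round(dt_out / dt))
  times <- c(); Vout <- list(); oi <- 0L
  t_depol <- rep(NA_real_, n)
  Vprev <- V
  bCm <- params$beta_sv * params$C_m
  for (it in seq_len(nt)) {
    t <- it * dt
    I_f <- if (use_foot) {
      on <- t >= (t_a - params$foot$duration) & t <= t_a
      ifelse(on, amp * exp((t - t_a) / params$foot$tau), 0)
    } else 0
    I_s <- 0
    if (!is.null(stimulus)) {
      I_s <- numeric(n)
      if (t >= stimulus$t0 && t <= stimulus$t0 + stimulus$duration)
        I_s[stimulus$nodes] <- stimulus$amplitude
    }
    I_i <- ion$I_ion(V, st, params$C_m)
    V <- V + dt * ((I_f + I_s) / bCm - I_i / params$C_m)
    st <- ion$step_state(V, st, dt)
    if (n > 1L) {
      V <- as.numeric(Matrix::solve(A_fac, Mm %*% V))
    }
    if (any(abs(V) > 500))
      stop_emf("ionic model state blow-up: |V_m| > 500 mV at t = ", round(t, 2), " ms")
    cross <- is.na(t_depol) & Vprev < -20 & V >= -20
    if (any(cross)) {
      frac <- (-20 - Vprev[cross]) / (V[cross] - Vprev[cross])
      t_depol[cross] <- t - dt + frac * dt
    }
    Vprev <- V
    if (it %% out_every == 0L) {
      oi <- oi + 1L
      times[oi] <- t
      Vout[[oi]] <- V
    }
  }
  list(time_ms = times, V = do.call(cbind, Vout), t_depol = t_depol,
       params = params)
}

#' Default apical activation source
#'
#' Picks the myocardial vertices nearest the apex (lowest long-axis
#' coordinate among vertices of \code{label} elements) as the initial
#' activation site at t_0 = 0: the default source location used when no
#' conduction-system personalization is attempted.
#'
#' @param mesh a labeled mesh with an \code{lv} region.
#' @param label region carrying the source.
#' @param radius capture radius (mm) around the apex point.
#' @return a source list for \code{\link{solve_eikonal}}.
#' @export
apical_source <- function(mesh, label = "lv", radius = 5) {
  lv_v <- sort(unique(as.vector(mesh$elements[mesh$element_labels == label, ])))
  z <- mesh$vertices[lv_v, 3]
  apex <- lv_v[which.min(z)]
  d <- row_norm(mesh$vertices[lv_v, , drop = FALSE] -
                  matrix(mesh$vertices[apex, ], length(lv_v), 3, byrow = TRUE))
  picks <- lv_v[d <= radius]
  list(vertices = picks, t0 = rep(0, length(picks)))
}
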