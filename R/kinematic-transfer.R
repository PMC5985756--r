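#' Kinematic transfer: moving the CFD mesh with EM wall motion
#'
#' The electromechanics displacement is interpolated onto the (non-conformal)
#' CFD cavity surface through the background mesh, and extended into the
#' volume by a pseudo-elastic solve: linear elasticity whose per-element
#' Young's modulus is multiplied by the shape-quality indicator of the
#' previous step (quality-based stiffening) and whose Poisson ratio is
#' switched to a near-incompressible value for elements compressed below a
#' volume-ratio threshold (nu-volume stiffening). This keeps the mesh valid
#' through ejection-scale deformation without remeshing.
#'
#' @name kinematic_transfer
NULL

#' Pseudo-elastic mesh-motion parameters
#'
#' @param E0 baseline Young's modulus (kPa; the scale is arbitrary for pure
#'   Dirichlet motion but kept in familiar units).
#' @param nu0 baseline Poisson ratio.
#' @param volume_ratio_threshold elements compressed below this fraction of
#'   their reference volume become nearly incompressible.
#' @param nu_stiff Poisson ratio used for such elements (close to 0.5).
#' @return list of class \code{pseudo_elastic_params}.
#' @export
pseudo_elastic_params <- function(E0 = 100, nu0 = 0.3,
                                  volume_ratio_threshold = 0.2,
                                  nu_stiff = 0.49) {
  stopifnot(E0 > 0, nu0 > -1, nu0 < 0.5, nu_stiff < 0.5)
  structure(list(E0 = E0, nu0 = nu0,
                 volume_ratio_threshold = volume_ratio_threshold,
                 nu_stiff = nu_stiff), class = "pseudo_elastic_params")
}

#' Solve the pseudo-elastic mesh-motion problem
#'
#' Linear elastic FE solve -Div(sigma(d)) = 0 with Dirichlet data on the
#' full boundary and per-element stiffness overrides.
#'
#' @param mesh an \code{emf_mesh} (2D or 3D).
#' @param boundary_disp displacement prescribed on the boundary: a matrix
#'   for all vertices (only boundary rows are used) or a list
#'   \code{(vertices, values)}.
#' @param params \code{\link{pseudo_elastic_params}}.
#' @param E_elem,nu_elem optional per-element overrides of E and nu.
#' @return displacement matrix (nv x d); boundary rows reproduce the data
#'   exactly.
#' @export
solve_pseudo_elastic <- function(mesh, boundary_disp,
                                 params = pseudo_elastic_params(),
                                 E_elem = NULL, nu_elem = NULL) {
  d <- mesh$dim
  nv <- nrow(mesh$vertices)
  if (is.list(boundary_disp) && !is.data.frame(boundary_disp) &&
      !is.matrix(boundary_disp)) {
    bidx <- boundary_disp$vertices
    bval <- as.matrix(boundary_disp$values)
  } else {
    bidx <- sort(unique(as.vector(mesh$boundary_facets)))
    bval <- as.matrix(boundary_disp)[bidx, , drop = FALSE]
  }
  E <- rep_len(E_elem %||% params$E0, nrow(mesh$elements))
  nu <- rep_len(nu_elem %||% params$nu0, nrow(mesh$elements))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  gp <- p1_gradients(mesh)
  vol <- abs(gp$vol)
  el <- mesh$elements
  nn <- d + 1L
  ii <- jj <- xx <- vector("list", nn * nn * d * d)
  slot <- 0L
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    ga <- gp$grads[[a]]; gb <- gp$grads[[b]]
    gagb <- rowSums(ga * gb)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      val <- vol * (mu * ((i == j) * gagb + gb[, i] * ga[, j]) +
                      lam * ga[, i] * gb[, j])
      slot <- slot + 1L
      ii[[slot]] <- d * (el[, a] - 1L) + i
      jj[[slot]] <- d * (el[, b] - 1L) + j
      xx[[slot]] <- val
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(d * nv, d * nv))
  # components without any prescribed vertex render the system singular
  reach <- rep(FALSE, nv)
  reach[bidx] <- TRUE
  repeat {
    touched <- reach[el[, 1]]
    for (a in 2:nn) touched <- touched | reach[el[, a]]
    newly <- unique(as.vector(el[touched, , drop = FALSE]))
    if (all(reach[newly])) break
    reach[newly] <- TRUE
  }
  if (!all(reach))
    stop_emf("singular mesh-motion system (isolated components): ",
             sum(!reach), " vertices unreachable from the boundary data")
  f <- numeric(d * nv)
  dofs <- as.vector(t(outer(bidx, seq_len(d), function(v, i) d * (v - 1L) + i)))
  vals <- as.vector(t(bval))
  bc <- apply_dirichlet(K, f, dofs, vals)
  x <- tryCatch(solve_sparse(bc$K, bc$f), error = function(e)
    stop_emf("singular mesh-motion system (isolated components?): ",
             conditionMessage(e)))
  if (!all(is.finite(x)))
    stop_emf("singular mesh-motion system (isolated components?)")
  out <- matrix(x, nv, d, byrow = TRUE)
  out[bidx, ] <- bval  # exact boundary interpolation
  out
}

#' Quality-based stiffening
#'
#' Per-element Young's modulus E0 multiplied by the raw shape quality
#' kappa evaluated on the previous step's displaced coordinates: elements
#' already distorted become stiffer and resist further distortion.
#' Inverted elements get a large capped modulus and are flagged.
#'
#' @param mesh the CFD mesh (reference configuration).
#' @param prev_disp previous-step displacement (nv x d), or NULL.
#' @param E0 baseline modulus (kPa).
#' @param cap multiple of E0 used for inverted elements.
#' @return list with per-element \code{E} and logical \code{inverted}.
#' @export
quality_stiffen <- function(mesh, prev_disp = NULL, E0 = 100, cap = 1e6) {
  coords <- mesh$vertices
  if (!is.null(prev_disp)) coords <- coords + prev_disp
  q <- element_quality(mesh, coords)
  E <- E0 * q$raw
  E[q$inverted] <- cap * E0
  list(E = E, inverted = q$inverted)
}

#' Volume-ratio based Poisson stiffening
#'
#' Elements whose current volume has fallen below
#' \code{volume_ratio_threshold} times the reference volume are made nearly
#' incompressible.
#'
#' @param mesh the CFD mesh.
#' @param current_volumes,reference_volumes per-element volumes.
#' @param params \code{\link{pseudo_elastic_params}}.
#' @return per-element Poisson ratio.
#' @export
nu_volume_stiffen <- function(mesh, current_volumes, reference_volumes,
                              params = pseudo_elastic_params()) {
  stopifnot(all(reference_volumes > 0))
  ratio <- current_volumes / reference_volumes
  ifelse(ratio < params$volume_ratio_threshold, params$nu_stiff, params$nu0)
}

#' Interpolate background displacement onto target surface vertices
#'
#' Barycentric interpolation through the hanging background mesh; exterior
#' targets (the smoothed CFD surface is non-conformal and may poke out)
#' use clipped projected weights. Targets farther than one background
#' element diameter trigger a warning with the count.
#'
#' @param background an \code{emf_mesh} carrying the displacement.
#' @param displacement nodal displacement on the background mesh.
#' @param target_points coordinates to interpolate at.
#' @return displacement matrix at the targets.
#' @export
transfer_surface_displacement <- function(background, displacement,
                                          target_points) {
  loc <- locate_points(background, target_points)
  if (any(loc$exterior)) {
    h <- mean_edge_length(background) * (background$dim + 1)
    far <- 0L
    ext <- which(loc$exterior)
    for (q in ext) {
      elv <- background$elements[loc$element[q], ]
      dmin <- min(row_norm(background$vertices[elv, , drop = FALSE] -
                             matrix(target_points[q, ], length(elv),
                                    background$dim, byrow = TRUE)))
      if (dmin > h) far <- far + 1L
    }
    if (far > 0)
      warning(far, " target vertices lie farther than one background ",
              "element diameter from the mesh")
  }
  interpolate_at(background, loc, displacement)
}

#' Mesh velocity by first-order backward difference
#'
#' @param d_prev,d_next displacement at the two time levels (mm).
#' @param dt step (ms).
#' @return velocity (mm/ms = m/s).
#' @export
mesh_velocity <- function(d_prev, d_next, dt) {
  stopifnot(dt > 0)
  (d_next - d_prev) / dt
}

#' One kinematic-transfer step
#'
#' The two-stage transfer: interpolate the background (EM) displacement onto
#' the CFD surface vertices only, then fill the interior with the
#' pseudo-elastic solve using quality and volume-ratio stiffening based on
#' the previous step.
#'
#' @param cfd_mesh the fluid mesh (reference configuration).
#' @param background background mesh carrying \code{displacement}.
#' @param displacement nodal displacement on the background mesh (mm).
#' @param d_prev previous-step CFD mesh displacement (for stiffening and
#'   velocity), or NULL.
#' @param dt step (ms) for the mesh velocity.
#' @param params \code{\link{pseudo_elastic_params}}.
#' @param stiffen apply the two stiffening strategies.
#' @param fixed_tags facet tags whose vertices stay fixed (e.g. outlet
#'   planes), displacement zero there.
#' @return list with \code{d} (nv x d mm), \code{w} (mesh velocity, mm/ms),
#'   \code{E}, \code{nu}, \code{inverted} diagnostics.
#' @export
transfer_step <- function(cfd_mesh, background, displacement, d_prev = NULL,
                          dt = 0.5, params = pseudo_elastic_params(),
                          stiffen = TRUE, fixed_tags = character(0)) {
  surf_v <- sort(unique(as.vector(cfd_mesh$boundary_facets)))
  fix_v <- if (length(fixed_tags)) tagged_vertices(cfd_mesh, fixed_tags) else integer(0)
  mov_v <- setdiff(surf_v, fix_v)
  dsurf <- transfer_surface_displacement(background, displacement,
                                         cfd_mesh$vertices[mov_v, , drop = FALSE])
  bidx <- c(mov_v, fix_v)
  bval <- rbind(as.matrix(dsurf),
                matrix(0, length(fix_v), cfd_mesh$dim))
  E_el <- NULL; nu_el <- NULL; inverted <- rep(FALSE, nrow(cfd_mesh$elements))
  if (stiffen) {
    qs <- quality_stiffen(cfd_mesh, d_prev, E0 = params$E0)
    E_el <- qs$E; inverted <- qs$inverted
    refv <- abs(element_volumes(cfd_mesh))
    curv <- abs(element_volumes(cfd_mesh, cfd_mesh$vertices +
                                  (d_prev %||% 0)))
    nu_el <- nu_volume_stiffen(cfd_mesh, curv, refv, params)
  }
  d_new <- solve_pseudo_elastic(cfd_mesh, list(vertices = bidx, values = bval),
                                params, E_elem = E_el, nu_elem = nu_el)
  w <- mesh_velocity(d_prev %||% matrix(0, nrow(d_new), ncol(d_new)),
                     d_new, dt)
  list(d = d_new, w = w, E = E_el, nu = nu_el, inverted = inverted)
}

# prefactored constant-coefficient pseudo-elastic solve: returns a closure
# mapping boundary values (on the fixed vertex set bidx) to the full field
pe_factor <- function(mesh, bidx, params = pseudo_elastic_params()) {
  d <- mesh$dim
  nv <- nrow(mesh$vertices)
  E <- rep_len(params$E0, nrow(mesh$elements))
  nu <- rep_len(params$nu0, nrow(mesh$elements))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  gp <- p1_gradients(mesh)
  vol <- abs(gp$vol)
  el <- mesh$elements
  nn <- d + 1L
  ii <- jj <- xx <- vector("list", nn * nn * d * d)
  slot <- 0L
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    ga <- gp$grads[[a]]; gb <- gp$grads[[b]]
    gagb <- rowSums(ga * gb)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      slot <- slot + 1L
      ii[[slot]] <- d * (el[, a] - 1L) + i
      jj[[slot]] <- d * (el[, b] - 1L) + j
      xx[[slot]] <- vol * (mu * ((i == j) * gagb + gb[, i] * ga[, j]) +
                             lam * ga[, i] * gb[, j])
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(d * nv, d * nv))
  dofs <- as.vector(t(outer(bidx, seq_len(d), function(v, i) d * (v - 1L) + i)))
  n <- nrow(K)
  Dm <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% dofs)))
  K2 <- Dm %*% K %*% Dm + Matrix::Diagonal(n, x = as.numeric(seq_len(n) %in% dofs))
  lu <- Matrix::lu(K2)
  function(bval) {
    vals <- as.vector(t(as.matrix(bval)))
    f <- numeric(n)
    f <- f - as.numeric(K[, dofs, drop = FALSE] %*% vals)
    f <- as.numeric(Dm %*% f)
    f[dofs] <- vals
    out <- matrix(as.numeric(Matrix::solve(lu, f)), nv, d, byrow = TRUE)
    out[bidx, ] <- as.matrix(bval)
    out
  }
}
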