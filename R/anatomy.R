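# Synthetic idealized anatomies: truncated-ellipsoid LV with cavity, valves
# and apical cushion, and a cylindrical aorta with an optional Gaussian
# coarctation. Structured hexahedral parameter grids are mapped to physical
# space, duplicate vertices merged (parametric degeneracies at the apex and
# on the axis collapse there by construction), and each hexahedron is split
# into six tetrahedra sharing its main diagonal, which is a conforming
# template on a structured grid.

hex_corner_offsets <- matrix(c(
  0L, 0L, 0L,
  1L, 0L, 0L,
  0L, 1L, 0L,
  1L, 1L, 0L,
  0L, 0L, 1L,
  1L, 0L, 1L,
  0L, 1L, 1L,
  1L, 1L, 1L), ncol = 3, byrow = TRUE)

hex_tet_template <- matrix(c(
  1L, 2L, 4L, 8L,
  1L, 4L, 3L, 8L,
  1L, 3L, 7L, 8L,
  1L, 7L, 5L, 8L,
  1L, 5L, 6L, 8L,
  1L, 6L, 2L, 8L), ncol = 4, byrow = TRUE)

# points: N x 3 with duplicates allowed; hexes: nh x 8 (template corner order);
# labels: nh. Collapsed hex corners produce degenerate tets that are dropped.
build_tet_mesh <- function(points, hexes, labels, merge_tol = 1e-8) {
  scale <- max(apply(points, 2, function(x) diff(range(x))), 1)
  key <- apply(round(points / (scale * merge_tol)), 1, paste, collapse = "_")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  verts <- points[uid, , drop = FALSE]
  tets <- matrix(0L, 6L * nrow(hexes), 4L)
  tlab <- character(6L * nrow(hexes))
  for (t in 1:6) {
    idx <- seq((t - 1L) * nrow(hexes) + 1L, t * nrow(hexes))
    tets[idx, ] <- matrix(map[hexes[, hex_tet_template[t, ]]], nrow(hexes), 4L)
    tlab[idx] <- labels
  }
  # drop collapsed tets, fix orientation
  distinct <- tets[, 1] != tets[, 2] & tets[, 1] != tets[, 3] &
    tets[, 1] != tets[, 4] & tets[, 2] != tets[, 3] &
    tets[, 2] != tets[, 4] & tets[, 3] != tets[, 4]
  tets <- tets[distinct, , drop = FALSE]; tlab <- tlab[distinct]
  a <- verts[tets[, 2], ] - verts[tets[, 1], ]
  b <- verts[tets[, 3], ] - verts[tets[, 1], ]
  cc <- verts[tets[, 4], ] - verts[tets[, 1], ]
  vol <- rowSums(row_cross(a, b) * cc) / 6
  hmin <- (max(abs(vol)))^(1 / 3)
  keep <- abs(vol) > 1e-9 * hmin^3
  tets <- tets[keep, , drop = FALSE]; tlab <- tlab[keep]; vol <- vol[keep]
  flip <- vol < 0
  tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp
  used <- sort(unique(as.vector(tets)))
  vmap <- integer(nrow(verts)); vmap[used] <- seq_along(used)
  list(vertices = verts[used, , drop = FALSE],
       elements = matrix(vmap[tets], nrow(tets), 4L), labels = tlab)
}

#' Generate an idealized truncated-ellipsoid left ventricle
#'
#' Builds a labeled tetrahedral mesh of an LV: an ellipsoidal shell
#' (label \code{lv}) around a blood-pool cavity (\code{lvbp}), truncated at
#' the base; the basal cross-section is closed by a one-element-thick valve
#' layer split into an aortic (\code{av}) and a mitral (\code{mv}) azimuthal
#' sector, and the apex rests on an elastic \code{cushion} cap. Boundary
#' facets are tagged \code{dirichlet} on the cushion outside, the wall rim at
#' the base cut and the valve tops, and \code{homogeneous} on the remaining
#' epicardium. The endocardial pressure surface appears when the solid
#' submesh is extracted (see \code{\link{solid_submesh}}).
#'
#' @param wall_thickness wall thickness (mm).
#' @param long_axis endocardial long (apex-base) semi-axis (mm).
#' @param short_axis endocardial short semi-axis (mm).
#' @param base_cut truncation height as a fraction of \code{long_axis}
#'   above the equator; must lie in (0, 0.9].
#' @param resolution target edge length (mm); must not exceed
#'   \code{wall_thickness} (at least two element layers across the wall).
#' @param seed integer recorded in the manifest; generation is fully
#'   deterministic.
#' @param av_fraction azimuthal fraction of the basal disk labeled \code{av}.
#' @return an \code{emf_mesh} with a generation manifest attached as
#'   attribute \code{manifest}.
#' @export
make_lv_ellipsoid <- function(wall_thickness = 10, long_axis = 45,
                              short_axis = 26, base_cut = 0.3,
                              resolution = 8, seed = 1L,
                              av_fraction = 1 / 3) {
  if (wall_thickness <= 0 || resolution <= 0)
    stop_emf("wall_thickness and resolution must be positive")
  if (base_cut <= 0 || base_cut > 0.9)
    stop_emf("base_cut must lie in (0, 0.9]: a full ellipsoid has no valve plane")
  if (resolution > wall_thickness)
    stop_emf("resolution too coarse: fewer than 2 elements across the wall")
  a <- long_axis; b <- short_axis; th <- wall_thickness
  theta_cut <- acos(base_cut)
  n_w <- max(2L, round(th / resolution))
  n_c <- max(2L, ceiling(b / resolution))
  arc <- a * (pi - theta_cut)
  n_v <- max(6L, ceiling(arc / resolution))
  n_phi <- max(8L, ceiling(2 * pi * b / resolution))
  v_cush <- 0.8  # meridional fraction beyond which the cushion cap sits

  theta_of <- function(v) theta_cut + v * (pi - theta_cut)
  # radial stations: 0..n_c cavity, n_c..n_c+n_w wall, +1 cushion layer
  n_k <- n_c + n_w
  point_at <- function(k, v, j) {
    th_ang <- theta_of(v)
    phi <- 2 * pi * j / n_phi
    en <- c(b * sin(th_ang) * cos(phi), b * sin(th_ang) * sin(phi),
            a * cos(th_ang))
    if (k <= n_c) {
      ax <- c(0, 0, a * cos(th_ang))
      ax + (k / n_c) * (en - ax)
    } else {
      ep <- c((b + th) * sin(th_ang) * cos(phi),
              (b + th) * sin(th_ang) * sin(phi), (a + th) * cos(th_ang))
      en + ((k - n_c) / n_w) * (ep - en)
    }
  }
  cushion_point <- function(v, j) {
    th_ang <- theta_of(v)
    phi <- 2 * pi * j / n_phi
    tc <- th
    c((b + th + tc) * sin(th_ang) * cos(phi),
      (b + th + tc) * sin(th_ang) * sin(phi), (a + th + tc) * cos(th_ang))
  }

  pts <- list(); hexes <- list(); labs <- list()
  vid <- function(k, v, j) sprintf("%d_%d_%d", k, v, j %% n_phi)
  # enumerate unique grid ids lazily
  id_env <- new.env(parent = emptyenv())
  coords <- list(); cnt <- 0L
  get_id <- function(key, coord) {
    if (!is.null(id_env[[key]])) return(id_env[[key]])
    cnt <<- cnt + 1L
    id_env[[key]] <- cnt
    coords[[cnt]] <<- coord
    cnt
  }
  hex_list <- list(); lab_list <- list(); hn <- 0L
  add_hex <- function(ids, label) {
    hn <<- hn + 1L
    hex_list[[hn]] <<- ids
    lab_list[[hn]] <<- label
  }
  for (ki in seq_len(n_k)) for (vi in seq_len(n_v)) for (ji in seq_len(n_phi)) {
    corner <- integer(8)
    for (c8 in 1:8) {
      o <- hex_corner_offsets[c8, ]
      k <- ki - 1L + o[1]; v <- vi - 1L + o[2]; j <- ji - 1L + o[3]
      corner[c8] <- get_id(vid(k, v, j),
                           point_at(k, v / n_v, j))
    }
    lab <- if (ki <= n_c) "lvbp" else "lv"
    add_hex(corner, lab)
  }
  # valve layer above the basal cavity disk (one layer thick)
  th_v <- th / 2
  zc <- a * base_cut
  valve_top <- function(k, j) {
    p <- point_at(min(k, n_c), 0, j)  # basal disk point
    c(p[1], p[2], zc + th_v)
  }
  for (ki in seq_len(n_c)) for (ji in seq_len(n_phi)) {
    corner <- integer(8)
    for (c8 in 1:8) {
      o <- hex_corner_offsets[c8, ]
      k <- ki - 1L + o[1]; j <- ji - 1L + o[3]
      if (o[2] == 1L) { # bottom of valve layer = basal cavity disk (v = 0)
        corner[c8] <- get_id(vid(k, 0L, j), point_at(k, 0, j))
      } else {
        corner[c8] <- get_id(sprintf("vt_%d_%d", k, j %% n_phi), valve_top(k, j))
      }
    }
    phi_mid <- 2 * pi * (ji - 0.5) / n_phi
    lab <- if (phi_mid < 2 * pi * av_fraction) "av" else "mv"
    add_hex(corner, lab)
  }
  # cushion cap beyond the epicardium near the apex
  v_lo <- ceiling(v_cush * n_v)
  for (vi in seq(v_lo + 1L, n_v)) for (ji in seq_len(n_phi)) {
    corner <- integer(8)
    for (c8 in 1:8) {
      o <- hex_corner_offsets[c8, ]
      v <- vi - 1L + o[2]; j <- ji - 1L + o[3]
      if (o[1] == 0L) {
        corner[c8] <- get_id(vid(n_k, v, j), point_at(n_k, v / n_v, j))
      } else {
        corner[c8] <- get_id(sprintf("cu_%d_%d", v, j %% n_phi),
                             cushion_point(v / n_v, j))
      }
    }
    add_hex(corner, "cushion")
  }

  points <- do.call(rbind, coords)
  hexes <- do.call(rbind, hex_list)
  labels <- unlist(lab_list)
  parts <- build_tet_mesh(points, hexes, labels)
  mesh <- labeled_mesh(parts$vertices, parts$elements, parts$labels,
                       validate = TRUE)
  mesh <- tag_lv_boundary(mesh, zc, th_v)
  attr(mesh, "manifest") <- list(
    generator = "make_lv_ellipsoid", wall_thickness = wall_thickness,
    long_axis = long_axis, short_axis = short_axis, base_cut = base_cut,
    resolution = resolution, seed = as.integer(seed),
    av_fraction = av_fraction)
  mesh
}

tag_lv_boundary <- function(mesh, zc, th_v) {
  bf <- mesh$boundary_facets
  geo <- facet_geometry(mesh$vertices, bf, 3L)
  cz <- (mesh$vertices[bf[, 1], 3] + mesh$vertices[bf[, 2], 3] +
           mesh$vertices[bf[, 3], 3]) / 3
  # owning element labels
  af <- all_facets(mesh)
  key_all <- facet_key(af$facets)
  key_bf <- facet_key(bf)
  owner_lab <- mesh$element_labels[af$owner[match(key_bf, key_all)]]
  tags <- rep("homogeneous", nrow(bf))
  # only the cushion bottom is anchored: the ventricular base must stay
  # free to move (the full anatomy anchors at remote artery rims instead)
  tags[owner_lab == "cushion"] <- "dirichlet"
  tags[owner_lab %in% c("av", "mv") & cz > zc + th_v * 0.45 &
         geo$normals[, 3] > 0.9] <- "rim"
  tags[owner_lab == "lv" & geo$normals[, 3] > 0.8 & cz > zc * 0.98] <- "rim"
  mesh$facet_tags <- tags
  mesh
}

#' Extract the solid (myocardium + aorta + valves + cushion) submesh
#'
#' Removes the blood-pool labels; the newly exposed endocardial interface is
#' tagged \code{pressure_endo} (the surface carrying the cavity follower
#' pressure).
#'
#' @param mesh a labeled mesh including blood-pool labels.
#' @return an \code{emf_mesh}.
#' @export
solid_submesh <- function(mesh) {
  solid <- intersect(unique(mesh$element_labels), c("lv", "ao", "cushion", "av", "mv"))
  submesh(mesh, solid, interface_tag = "pressure_endo")
}

#' Generate a cylindrical aorta with an optional coarctation
#'
#' Straight tube along z with lumen label \code{aobp} and wall label
#' \code{ao}. A Gaussian-profile radius reduction emulates an aortic
#' coarctation: the minimal cross-sectional area is
#' \code{(1 - stenosis_severity)} times the nominal area (so the minimal
#' radius is \code{radius * sqrt(1 - severity)}). The distal disk is split
#' azimuthally into \code{n_outlets} facet sets tagged \code{outlet_1..n};
#' the proximal disk is tagged \code{interface}; the outer wall is
#' \code{homogeneous} with \code{dirichlet} end rims. Radial vertex spacing
#' is graded toward the wall.
#'
#' @param length tube length (mm).
#' @param radius nominal lumen radius (mm).
#' @param stenosis_severity area reduction fraction in [0, 1); 0 means a
#'   straight (post-treatment) tube.
#' @param stenosis_position axial position of the throat as a fraction of
#'   the length.
#' @param n_outlets number of outlet sectors on the distal disk.
#' @param resolution target edge length (mm).
#' @param seed integer recorded in the manifest.
#' @param wall_thickness wall thickness (mm); defaults to 15\% of the radius.
#' @param stenosis_width Gaussian width (mm); defaults to the radius.
#' @return an \code{emf_mesh} with a \code{manifest} attribute.
#' @export
make_aorta_tube <- function(length = 80, radius = 9, stenosis_severity = 0,
                            stenosis_position = 0.5, n_outlets = 1L,
                            resolution = 3, seed = 1L,
                            wall_thickness = NULL, stenosis_width = NULL) {
  if (stenosis_severity < 0 || stenosis_severity >= 1)
    stop_emf("stenosis_severity must lie in [0, 1)")
  if (resolution <= 0 || radius <= 0 || length <= 0)
    stop_emf("length, radius and resolution must be positive")
  tw <- wall_thickness %||% (0.15 * radius)
  sw <- stenosis_width %||% radius
  zs <- stenosis_position * length
  if (stenosis_severity > 0 && (zs - 2 * sw < 0.05 * length ||
                                zs + 2 * sw > 0.95 * length))
    stop_emf("outlets overlapping stenosis: move stenosis_position or shrink its width")
  r_of <- function(z) {
    radius - (radius - radius * sqrt(1 - stenosis_severity)) *
      exp(-((z - zs) / sw)^2)
  }
  n_z <- max(4L, ceiling(length / resolution))
  n_r <- max(2L, ceiling(radius / resolution))
  n_w <- max(1L, round(tw / resolution))
  n_phi <- max(8L, ceiling(2 * pi * radius / resolution))
  grade <- function(s) s^0.75  # finer spacing toward the wall

  coords <- list(); cnt <- 0L
  id_env <- new.env(parent = emptyenv())
  get_id <- function(key, coord) {
    if (!is.null(id_env[[key]])) return(id_env[[key]])
    cnt <<- cnt + 1L; id_env[[key]] <- cnt; coords[[cnt]] <<- coord; cnt
  }
  point_at <- function(k, i, j) {
    z <- length * i / n_z
    phi <- 2 * pi * j / n_phi
    if (k <= n_r) r <- r_of(z) * grade(k / n_r)
    else r <- r_of(z) + tw * (k - n_r) / n_w
    c(r * cos(phi), r * sin(phi), z)
  }
  hex_list <- list(); lab_list <- list(); hn <- 0L
  for (ki in seq_len(n_r + n_w)) for (ii in seq_len(n_z)) for (ji in seq_len(n_phi)) {
    corner <- integer(8)
    for (c8 in 1:8) {
      o <- hex_corner_offsets[c8, ]
      k <- ki - 1L + o[1]; i <- ii - 1L + o[2]; j <- (ji - 1L + o[3]) %% n_phi
      corner[c8] <- get_id(sprintf("%d_%d_%d", k, i, j), point_at(k, i, j))
    }
    hn <- hn + 1L
    hex_list[[hn]] <- corner
    lab_list[[hn]] <- if (ki <= n_r) "aobp" else "ao"
  }
  parts <- build_tet_mesh(do.call(rbind, coords), do.call(rbind, hex_list),
                          unlist(lab_list))
  mesh <- labeled_mesh(parts$vertices, parts$elements, parts$labels)
  # tag boundary
  bf <- mesh$boundary_facets
  ctr <- (mesh$vertices[bf[, 1], ] + mesh$vertices[bf[, 2], ] +
            mesh$vertices[bf[, 3], ]) / 3
  af <- all_facets(mesh)
  owner_lab <- mesh$element_labels[af$owner[match(facet_key(bf), facet_key(af$facets))]]
  tol <- 1e-6 * length
  tags <- rep("homogeneous", nrow(bf))
  at_top <- ctr[, 3] > length - tol
  at_bot <- ctr[, 3] < tol
  tags[owner_lab == "ao" & (at_top | at_bot)] <- "dirichlet"
  tags[owner_lab == "aobp" & at_bot] <- "interface"
  if (n_outlets == 1L) {
    tags[owner_lab == "aobp" & at_top] <- "outlet_1"
  } else {
    phi <- atan2(ctr[, 2], ctr[, 1]) %% (2 * pi)
    sector <- pmin(floor(phi / (2 * pi / n_outlets)) + 1L, n_outlets)
    sel <- owner_lab == "aobp" & at_top
    tags[sel] <- paste0("outlet_", sector[sel])
  }
  mesh$facet_tags <- tags
  attr(mesh, "manifest") <- list(
    generator = "make_aorta_tube", length = length, radius = radius,
    stenosis_severity = stenosis_severity,
    stenosis_position = stenosis_position, n_outlets = as.integer(n_outlets),
    resolution = resolution, seed = as.integer(seed),
    wall_thickness = tw, stenosis_width = sw)
  mesh
}

#' Analytic lumen radius profile of a generated aorta
#' @param manifest the \code{manifest} attribute of a tube mesh.
#' @param z axial positions (mm).
#' @return lumen radius (mm) at \code{z}.
#' @export
aorta_radius_profile <- function(manifest, z) {
  m <- manifest
  zs <- m$stenosis_position * m$length
  m$radius - (m$radius - m$radius * sqrt(1 - m$stenosis_severity)) *
    exp(-((z - zs) / m$stenosis_width)^2)
}

#' Rule-based transmural fiber architecture
#'
#' Assigns an orthonormal frame (fiber \code{f0}, sheet \code{s0}, sheet
#' normal \code{n0}) to every element. In the myocardium the helix angle
#' rotates linearly with transmural depth from \code{endo_angle} at the
#' endocardium to \code{epi_angle} at the epicardium (the feature the
#' transversely isotropic material law consumes); the sheet direction is
#' transmural. Non-myocardial elements receive a fixed frame, which the
#' isotropic laws ignore.
#'
#' @param mesh a labeled mesh containing an \code{lv} region.
#' @param endo_angle,epi_angle helix angles (degrees).
#' @return an object of class \code{emf_fibers}: list of n x 3 matrices
#'   \code{f0}, \code{s0}, \code{n0} plus the transmural depth \code{xi}.
#' @export
assign_fibers <- function(mesh, endo_angle = -60, epi_angle = 60) {
  if (!"lv" %in% mesh$element_labels) stop_emf("mesh has no lv region")
  ne <- nrow(mesh$elements)
  f0 <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)
  s0 <- matrix(rep(c(0, 1, 0), each = ne), ne, 3)
  n0 <- matrix(rep(c(0, 0, 1), each = ne), ne, 3)
  xi <- rep(NA_real_, ne)

  endo <- tryCatch(surface_of(mesh, "lv", interface_with = c("lvbp", "av", "mv")),
                   error = function(e) NULL)
  if (is.null(endo) || nrow(endo$facets) == 0) {
    sel <- mesh$facet_tags == "pressure_endo"
    if (!any(sel)) stop_emf("unresolvable transmural direction: no endocardial surface")
    fac <- mesh$boundary_facets[sel, , drop = FALSE]
    geo <- facet_geometry(mesh$vertices, fac, 3L)
    endo <- list(facets = fac, normals = -geo$normals)
  }
  epi_sel <- mesh$facet_tags == "homogeneous"
  af <- all_facets(mesh)
  key_all <- facet_key(af$facets)
  bf_lab <- mesh$element_labels[af$owner[match(facet_key(mesh$boundary_facets), key_all)]]
  epi_fac <- mesh$boundary_facets[epi_sel & bf_lab == "lv", , drop = FALSE]
  if (nrow(epi_fac) == 0) stop_emf("unresolvable transmural direction: no epicardial surface")

  fcen <- function(fac) (mesh$vertices[fac[, 1], , drop = FALSE] +
                           mesh$vertices[fac[, 2], , drop = FALSE] +
                           mesh$vertices[fac[, 3], , drop = FALSE]) / 3
  cen_endo <- fcen(endo$facets)
  cen_epi <- fcen(epi_fac)
  lv_el <- which(mesh$element_labels == "lv")
  el <- mesh$elements[lv_el, , drop = FALSE]
  cen <- (mesh$vertices[el[, 1], ] + mesh$vertices[el[, 2], ] +
            mesh$vertices[el[, 3], ] + mesh$vertices[el[, 4], ]) / 4
  near_idx <- function(cen, ref) {
    # nearest reference row per row of cen (brute force, blocked)
    out_i <- integer(nrow(cen)); out_d <- numeric(nrow(cen))
    for (q in seq_len(nrow(cen))) {
      d2 <- (ref[, 1] - cen[q, 1])^2 + (ref[, 2] - cen[q, 2])^2 +
        (ref[, 3] - cen[q, 3])^2
      out_i[q] <- which.min(d2); out_d[q] <- sqrt(min(d2))
    }
    list(i = out_i, d = out_d)
  }
  ne_endo <- near_idx(cen, cen_endo)
  ne_epi <- near_idx(cen, cen_epi)
  denom <- ne_endo$d + ne_epi$d
  if (any(denom <= 0)) stop_emf("unresolvable transmural direction: degenerate wall")
  xi_lv <- ne_endo$d / denom
  # transmural direction: from the nearest endocardial facet outward
  et <- -endo$normals[ne_endo$i, , drop = FALSE]  # surface_of points out of lv
  et <- row_unit(et)
  zhat <- matrix(rep(c(0, 0, 1), each = nrow(et)), ncol = 3)
  circ <- row_cross(zhat, et)
  circ_norm <- row_norm(circ)
  degen <- circ_norm < 1e-6
  if (any(degen)) {
    xhat <- matrix(rep(c(1, 0, 0), each = sum(degen)), ncol = 3)
    circ[degen, ] <- row_cross(xhat, et[degen, , drop = FALSE])
  }
  circ <- row_unit(circ)
  long <- row_cross(et, circ)
  alpha <- (endo_angle + xi_lv * (epi_angle - endo_angle)) * pi / 180
  f <- cos(alpha) * circ + sin(alpha) * long
  s <- et
  nn <- row_cross(f, s)
  f0[lv_el, ] <- f; s0[lv_el, ] <- s; n0[lv_el, ] <- nn
  xi[lv_el] <- xi_lv
  # near the apex pole the circumferential direction is ill-defined; flag
  # these elements so active stress can be tapered off there (their frame
  # is an arbitrary continuation, not a physiological fiber direction)
  apex <- rep(FALSE, ne)
  apex[lv_el] <- circ_norm < 0.35
  structure(list(f0 = f0, s0 = s0, n0 = n0, xi = xi,
                 apex_degenerate = apex,
                 helix_deg = replace(rep(NA_real_, ne), lv_el, alpha * 180 / pi)),
            class = "emf_fibers")
}

#' Laplacian-smooth mesh vertices
#'
#' Fixed-iteration umbrella-operator smoothing; vertices listed in
#' \code{fixed} do not move. Errors if smoothing inverts any element.
#'
#' @param mesh an \code{emf_mesh}.
#' @param iterations number of smoothing sweeps.
#' @param factor relaxation factor in (0, 1].
#' @param fixed integer vertex indices to keep in place.
#' @return the smoothed \code{emf_mesh}.
#' @export
smooth_mesh <- function(mesh, iterations = 3L, factor = 0.3, fixed = integer(0)) {
  el <- mesh$elements
  pairs <- utils::combn(mesh$dim + 1L, 2L)
  ei <- c(); ej <- c()
  for (k in seq_len(ncol(pairs))) {
    ei <- c(ei, el[, pairs[1, k]], el[, pairs[2, k]])
    ej <- c(ej, el[, pairs[2, k]], el[, pairs[1, k]])
  }
  nv <- nrow(mesh$vertices)
  adj <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(nv, nv))
  adj@x[] <- 1  # dedupe repeated edges to weight 1
  deg <- Matrix::rowSums(adj)
  # surface vertices are averaged over surface neighbours only, so the
  # boundary shrinks mildly instead of being pulled inward by the volume
  surfv <- sort(unique(as.vector(mesh$boundary_facets)))
  sadj <- NULL
  if (length(surfv) > 0) {
    bf <- mesh$boundary_facets
    spairs <- utils::combn(ncol(bf), 2L)
    si <- c(); sj <- c()
    for (k in seq_len(ncol(spairs))) {
      si <- c(si, bf[, spairs[1, k]], bf[, spairs[2, k]])
      sj <- c(sj, bf[, spairs[2, k]], bf[, spairs[1, k]])
    }
    sadj <- Matrix::sparseMatrix(i = si, j = sj, x = 1, dims = c(nv, nv))
    sadj@x[] <- 1
    sdeg <- Matrix::rowSums(sadj)
  }
  coords <- mesh$vertices
  movable <- setdiff(seq_len(nv), fixed)
  for (it in seq_len(iterations)) {
    avg <- as.matrix(adj %*% coords) / deg
    if (!is.null(sadj)) {
      savg <- as.matrix(sadj %*% coords)
      savg[surfv, ] <- savg[surfv, , drop = FALSE] / sdeg[surfv]
      avg[surfv, ] <- savg[surfv, , drop = FALSE]
    }
    coords[movable, ] <- coords[movable, , drop = FALSE] +
      factor * (avg[movable, , drop = FALSE] - coords[movable, , drop = FALSE])
  }
  out <- mesh
  out$vertices <- coords
  if (any(element_volumes(out) <= 0))
    stop_emf("smoothing produced inverted/self-intersecting elements")
  out
}

#' Build the finer, non-conformal CFD cavity mesh
#'
#' Regenerates the blood-pool cavity of a generated anatomy at
#' \code{refinement} times finer resolution from its manifest, extracts the
#' cavity submesh (valve + blood pool), and applies mild fixed-iteration
#' Laplacian smoothing to its surface. The result is deliberately
#' non-conformal with the electromechanics mesh. Lateral/apical facets are
#' tagged \code{wall}; the valve-orifice disk becomes \code{outlet_1} (LV)
#' or keeps the tube outlet tags (aorta).
#'
#' @param mesh a mesh produced by \code{\link{make_lv_ellipsoid}} or
#'   \code{\link{make_aorta_tube}} (its manifest is required).
#' @param refinement linear refinement factor (> 1 gives finer elements).
#' @param seed integer recorded in the manifest.
#' @param smooth_iterations,smooth_factor smoothing controls.
#' @return an \code{emf_mesh} of the cavity.
#' @export
make_cfd_cavity <- function(mesh, refinement = 1.5, seed = 1L,
                            smooth_iterations = 2L, smooth_factor = 0.1) {
  man <- attr(mesh, "manifest")
  if (is.null(man))
    stop_emf("mesh carries no generation manifest; make_cfd_cavity needs one")
  if (!any(mesh$element_labels %in% c("lvbp", "aobp")))
    stop_emf("label not present: no blood-pool labels in mesh")
  if (man$generator == "make_lv_ellipsoid") {
    fine <- make_lv_ellipsoid(wall_thickness = man$wall_thickness,
                              long_axis = man$long_axis,
                              short_axis = man$short_axis,
                              base_cut = man$base_cut,
                              resolution = man$resolution / refinement,
                              seed = seed, av_fraction = man$av_fraction)
    cav <- submesh(fine, c("av", "lvbp"), interface_tag = "wall")
    # valve-orifice disk (top of the av layer) becomes the outlet
    zc <- man$long_axis * man$base_cut + man$wall_thickness / 2
    cz <- (cav$vertices[cav$boundary_facets[, 1], 3] +
             cav$vertices[cav$boundary_facets[, 2], 3] +
             cav$vertices[cav$boundary_facets[, 3], 3]) / 3
    geo <- facet_geometry(cav$vertices, cav$boundary_facets, 3L)
    top <- cz > zc - 1e-6 * man$long_axis & geo$normals[, 3] > 0.9
    cav$facet_tags <- ifelse(top, "outlet_1", "wall")
  } else if (man$generator == "make_aorta_tube") {
    fine <- make_aorta_tube(length = man$length, radius = man$radius,
                            stenosis_severity = man$stenosis_severity,
                            stenosis_position = man$stenosis_position,
                            n_outlets = man$n_outlets,
                            resolution = man$resolution / refinement,
                            seed = seed, wall_thickness = man$wall_thickness,
                            stenosis_width = man$stenosis_width)
    cav <- submesh(fine, "aobp", interface_tag = "wall")
  } else stop_emf("unknown generator in manifest: ", man$generator)
  fixed <- tagged_vertices(cav, grep("^outlet|^interface", unique(cav$facet_tags),
                                     value = TRUE))
  cav <- smooth_mesh(cav, iterations = smooth_iterations,
                     factor = smooth_factor, fixed = fixed)
  man_out <- man
  man_out$cfd_refinement <- refinement
  man_out$seed <- as.integer(seed)
  attr(cav, "manifest") <- man_out
  cav
}
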