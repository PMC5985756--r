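#' Labeled simplicial meshes
#'
#' The central mesh container used throughout the package: a simplicial mesh
#' (tetrahedra in 3D, triangles in 2D) whose elements carry region labels from
#' the anatomical index set \{lv, ao, cushion, av, mv, lvbp, aobp\} and whose
#' boundary facets carry surface tags (\code{dirichlet},
#' \code{pressure_endo}, \code{homogeneous}, \code{interface},
#' \code{outlet_k}, \code{wall}). Coordinates are millimetres. Vertex indices
#' are 1-based in memory (the R convention); the VTK files written by
#' \code{\link{write_mesh}} use the format's 0-based indices.
#'
#' @param vertices numeric matrix, one row per vertex (mm).
#' @param elements integer matrix, one row per simplex, \code{d + 1} columns.
#' @param element_labels character vector, one region label per element.
#' @param boundary_facets integer matrix of facet vertex indices (rows), or
#'   \code{NULL} to compute the mesh boundary automatically.
#' @param facet_tags character vector of surface tags, one per boundary facet.
#' @param validate check invariants (positive volumes, index bounds).
#' @return an object of class \code{emf_mesh}.
#' @export
labeled_mesh <- function(vertices, elements, element_labels = NULL,
                         boundary_facets = NULL, facet_tags = NULL,
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  d <- ncol(vertices)
  if (!d %in% c(2L, 3L)) stop_emf("only 2D or 3D meshes are supported")
  if (ncol(elements) != d + 1L)
    stop_emf("elements must have ", d + 1L, " vertices per simplex")
  if (is.null(element_labels)) element_labels <- rep("lv", nrow(elements))
  element_labels <- as.character(element_labels)
  if (length(element_labels) != nrow(elements))
    stop_emf("one label per element required")

  mesh <- structure(list(vertices = vertices, elements = elements,
                         element_labels = element_labels,
                         boundary_facets = NULL, facet_tags = NULL,
                         dim = d),
                    class = "emf_mesh")
  if (is.null(boundary_facets)) {
    bf <- compute_boundary_facets(mesh)
    mesh$boundary_facets <- bf
    mesh$facet_tags <- rep("homogeneous", nrow(bf))
  } else {
    boundary_facets <- as.matrix(boundary_facets)
    storage.mode(boundary_facets) <- "integer"
    mesh$boundary_facets <- boundary_facets
    mesh$facet_tags <- if (is.null(facet_tags))
      rep("homogeneous", nrow(boundary_facets)) else as.character(facet_tags)
    if (length(mesh$facet_tags) != nrow(boundary_facets))
      stop_emf("one tag per boundary facet required")
  }
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.emf_mesh <- function(x, ...) {
  cat(sprintf("<emf_mesh> %dD, %d vertices, %d elements\n",
              x$dim, nrow(x$vertices), nrow(x$elements)))
  cat("  labels:", paste(sprintf("%s(%d)", names(table(x$element_labels)),
                                 table(x$element_labels)), collapse = " "), "\n")
  if (!is.null(x$facet_tags))
    cat("  facet tags:", paste(unique(x$facet_tags), collapse = " "), "\n")
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks index bounds, strictly positive signed volumes in the reference
#' configuration, and facet index bounds.
#'
#' @param mesh an \code{emf_mesh}.
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (max(mesh$elements) > nv || min(mesh$elements) < 1L)
    stop_emf("element vertex index out of range")
  v <- element_volumes(mesh)
  if (any(v <= 0))
    stop_emf(sum(v <= 0), " elements with non-positive volume")
  if (!is.null(mesh$boundary_facets) && nrow(mesh$boundary_facets) > 0 &&
      (max(mesh$boundary_facets) > nv || min(mesh$boundary_facets) < 1L))
    stop_emf("facet vertex index out of range")
  invisible(TRUE)
}

#' Signed element volumes (areas in 2D)
#'
#' @param mesh an \code{emf_mesh}.
#' @param coords optional displaced vertex coordinates (defaults to the
#'   reference configuration).
#' @return numeric vector of signed volumes (mm^3) or areas (mm^2).
#' @export
element_volumes <- function(mesh, coords = NULL) {
  if (is.null(coords)) coords <- mesh$vertices
  el <- mesh$elements
  if (mesh$dim == 3L) {
    a <- coords[el[, 2], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    b <- coords[el[, 3], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    cc <- coords[el[, 4], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    rowSums(row_cross(a, b) * cc) / 6
  } else {
    a <- coords[el[, 2], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    b <- coords[el[, 3], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / 2
  }
}

facet_rows_per_element <- function(d) {
  # local vertex indices of the facet opposite each local vertex, oriented
  # so the facet normal points away from the opposite vertex
  if (d == 3L) list(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  else list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
}

all_facets <- function(mesh) {
  el <- mesh$elements
  d <- mesh$dim
  loc <- facet_rows_per_element(d)
  fac <- do.call(rbind, lapply(loc, function(ix) el[, ix, drop = FALSE]))
  owner <- rep(seq_len(nrow(el)), times = d + 1L)
  list(facets = fac, owner = owner)
}

facet_key <- function(fac) {
  sorted <- t(apply(fac, 1, sort))
  do.call(paste, c(as.data.frame(sorted), sep = "_"))
}

#' Compute the boundary facets of a mesh
#'
#' A facet is on the boundary iff it belongs to exactly one element. The
#' returned facets are oriented with outward normals.
#'
#' @param mesh an \code{emf_mesh}.
#' @return integer matrix of facet vertex indices.
#' @export
compute_boundary_facets <- function(mesh) {
  af <- all_facets(mesh)
  key <- facet_key(af$facets)
  tab <- table(key)
  on_boundary <- tab[key] == 1L
  af$facets[on_boundary, , drop = FALSE]
}

#' Element shape quality
#'
#' Raw quality kappa is the ratio of the sum of squared edge lengths to the
#' (normalized) volume power, scaled so a regular simplex scores exactly 1;
#' degenerating elements send kappa to infinity. The rescaled quality
#' \code{1 - 1/kappa} maps this to [0, 1) with 0 best. Inverted elements
#' (signed volume <= 0) report \code{Inf} / 1 and are flagged rather than
#' raising an error, because the mesh-motion stage must keep going and
#' stiffen them away.
#'
#' @param mesh an \code{emf_mesh}.
#' @param displaced_coords optional coordinates to evaluate on (one row per
#'   vertex); defaults to the reference configuration.
#' @return a list of class \code{emf_quality} with \code{raw},
#'   \code{rescaled} and logical \code{inverted} per element.
#' @export
element_quality <- function(mesh, displaced_coords = NULL) {
  coords <- displaced_coords %||% mesh$vertices
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(mesh$vertices))
    stop_emf("displaced_coords must have one row per vertex")
  el <- mesh$elements
  d <- mesh$dim
  pairs <- utils::combn(d + 1L, 2L)
  ssq <- 0
  for (k in seq_len(ncol(pairs))) {
    e <- coords[el[, pairs[2, k]], , drop = FALSE] -
      coords[el[, pairs[1, k]], , drop = FALSE]
    ssq <- ssq + rowSums(e^2)
  }
  vol <- element_volumes(mesh, coords)
  inverted <- vol <= 0
  if (d == 3L) {
    c_d <- 6 * (6 * sqrt(2))^(2 / 3)   # regular tetrahedron scores 1
    denom <- c_d * abs(vol)^(2 / 3)
  } else {
    c_d <- 4 * sqrt(3)                 # regular triangle scores 1
    denom <- c_d * abs(vol)
  }
  raw <- ssq / denom
  raw[inverted] <- Inf
  rescaled <- 1 - 1 / raw
  rescaled[inverted] <- 1
  structure(list(raw = raw, rescaled = rescaled, inverted = inverted),
            class = "emf_quality")
}

#' Locate points in a background mesh
#'
#' Brute-force barycentric point location with a bounding-box prefilter.
#' Points outside the mesh are assigned their nearest element with clipped,
#' renormalized weights and flagged \code{exterior}; the mesh-motion transfer
#' relies on this projection because the smoothed CFD surface is
#' non-conformal by construction.
#'
#' @param background an \code{emf_mesh}.
#' @param points numeric matrix of query points (rows).
#' @param tol barycentric tolerance for the inside test.
#' @return list with integer \code{element}, weight matrix \code{weights}
#'   (\code{d + 1} columns), and logical \code{exterior}.
#' @export
locate_points <- function(background, points, tol = 1e-10) {
  mesh <- background
  points <- as.matrix(points)
  d <- mesh$dim
  np <- nrow(points)
  if (np == 0L)
    return(list(element = integer(0),
                weights = matrix(0, 0, d + 1L), exterior = logical(0)))
  el <- mesh$elements
  ne <- nrow(el)
  v0 <- mesh$vertices[el[, 1], , drop = FALSE]
  # inverse of the edge matrix per element, stored row-wise
  if (d == 3L) {
    # column-major tensor whose columns are the edge vectors e1, e2, e3
    E <- cbind(mesh$vertices[el[, 2], ] - v0,
               mesh$vertices[el[, 3], ] - v0,
               mesh$vertices[el[, 4], ] - v0)
    Einv <- t3_inv(E)
  } else {
    det <- (mesh$vertices[el[, 2], 1] - v0[, 1]) * (mesh$vertices[el[, 3], 2] - v0[, 2]) -
      (mesh$vertices[el[, 3], 1] - v0[, 1]) * (mesh$vertices[el[, 2], 2] - v0[, 2])
  }
  lo <- apply(mesh$vertices, 2, function(x) tapply(x[t(el)], rep(seq_len(ne), each = d + 1), min))
  hi <- apply(mesh$vertices, 2, function(x) tapply(x[t(el)], rep(seq_len(ne), each = d + 1), max))
  h <- max(hi - lo)
  element <- integer(np); exterior <- logical(np)
  weights <- matrix(0, np, d + 1L)
  for (q in seq_len(np)) {
    p <- points[q, ]
    cand <- which(p[1] >= lo[, 1] - tol * h & p[1] <= hi[, 1] + tol * h &
                    p[2] >= lo[, 2] - tol * h & p[2] <= hi[, 2] + tol * h)
    if (d == 3L)
      cand <- cand[p[3] >= lo[cand, 3] - tol * h & p[3] <= hi[cand, 3] + tol * h]
    lam_best <- -Inf; best <- NA_integer_; wbest <- NULL
    search_sets <- list(cand, seq_len(ne))
    for (s in seq_along(search_sets)) {
      idx <- search_sets[[s]]
      if (length(idx) == 0L) next
      rel <- matrix(p, length(idx), d, byrow = TRUE) - v0[idx, , drop = FALSE]
      if (d == 3L) {
        lam <- t3_mv(Einv[idx, , drop = FALSE], rel)
      } else {
        e1 <- mesh$vertices[el[idx, 2], , drop = FALSE] - v0[idx, , drop = FALSE]
        e2 <- mesh$vertices[el[idx, 3], , drop = FALSE] - v0[idx, , drop = FALSE]
        dd <- det[idx]
        lam <- cbind((rel[, 1] * e2[, 2] - rel[, 2] * e2[, 1]) / dd,
                     (e1[, 1] * rel[, 2] - e1[, 2] * rel[, 1]) / dd)
      }
      lam0 <- 1 - rowSums(lam)
      lam_full <- cbind(lam0, lam)
      minw <- apply(lam_full, 1, min)
      k <- which.max(minw)
      if (minw[k] > lam_best) {
        lam_best <- minw[k]; best <- idx[k]; wbest <- lam_full[k, ]
      }
      if (lam_best >= -tol) break  # found containing element, skip full scan
    }
    element[q] <- best
    if (lam_best >= -tol) {
      exterior[q] <- FALSE
      weights[q, ] <- wbest / sum(wbest)
    } else {
      exterior[q] <- TRUE
      w <- pmax(wbest, 0)
      weights[q, ] <- w / sum(w)
    }
  }
  list(element = element, weights = weights, exterior = exterior)
}

#' Interpolate a nodal field at located points
#'
#' @param mesh background mesh used in \code{\link{locate_points}}.
#' @param loc result of \code{\link{locate_points}}.
#' @param field nodal values (vector or matrix with one row per vertex).
#' @return interpolated values at the query points.
#' @export
interpolate_at <- function(mesh, loc, field) {
  field <- as.matrix(field)
  el <- mesh$elements
  out <- matrix(0, length(loc$element), ncol(field))
  for (a in seq_len(mesh$dim + 1L)) {
    out <- out + loc$weights[, a] *
      field[el[cbind(loc$element, rep(a, length(loc$element)))], , drop = FALSE]
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' Extract a tagged or label-bounded surface
#'
#' Returns the oriented facets bounding the union of the given labels; with
#' \code{interface_with}, only facets shared between the two label sets.
#' Normals point out of the first label set.
#'
#' @param mesh an \code{emf_mesh}.
#' @param label_set character vector of region labels.
#' @param interface_with optional second label set.
#' @return list with \code{facets} (vertex-index rows), \code{normals}
#'   (unit outward), \code{areas} and owning \code{element} indices.
#' @export
surface_of <- function(mesh, label_set, interface_with = NULL) {
  if (length(label_set) == 0L) stop_emf("label_set must be nonempty")
  missing_lab <- setdiff(label_set, unique(mesh$element_labels))
  if (length(missing_lab) > 0)
    stop_emf("label not present: ", paste(missing_lab, collapse = ", "))
  af <- all_facets(mesh)
  key <- facet_key(af$facets)
  in_set <- mesh$element_labels[af$owner] %in% label_set
  if (is.null(interface_with)) {
    # facets of in-set elements not shared with another in-set element
    keys_in <- key[in_set]
    cnt <- table(keys_in)
    pick <- in_set & cnt[key] == 1L
    pick[is.na(pick)] <- FALSE
  } else {
    in_other <- mesh$element_labels[af$owner] %in% interface_with
    keys_other <- unique(key[in_other])
    pick <- in_set & key %in% keys_other
  }
  fac <- af$facets[pick, , drop = FALSE]
  owner <- af$owner[pick]
  geo <- facet_geometry(mesh$vertices, fac, mesh$dim)
  list(facets = fac, normals = geo$normals, areas = geo$areas,
       element = owner)
}

facet_geometry <- function(coords, fac, d) {
  if (d == 3L) {
    a <- coords[fac[, 2], , drop = FALSE] - coords[fac[, 1], , drop = FALSE]
    b <- coords[fac[, 3], , drop = FALSE] - coords[fac[, 1], , drop = FALSE]
    n2 <- row_cross(a, b)
    areas <- row_norm(n2) / 2
    normals <- row_unit(n2)
  } else {
    e <- coords[fac[, 2], , drop = FALSE] - coords[fac[, 1], , drop = FALSE]
    areas <- row_norm(e)
    normals <- row_unit(cbind(e[, 2], -e[, 1]))
  }
  list(normals = normals, areas = areas)
}

#' Volume enclosed by a closed oriented surface
#'
#' Divergence-theorem volume of a closed triangulated (3D) or polygonal (2D)
#' surface with outward normals.
#'
#' @param coords vertex coordinates.
#' @param facets oriented facet rows.
#' @param d spatial dimension.
#' @return enclosed volume (mm^3) or area (mm^2).
#' @export
enclosed_volume <- function(coords, facets, d = 3L) {
  if (d == 3L) {
    a <- coords[facets[, 1], , drop = FALSE]
    b <- coords[facets[, 2], , drop = FALSE]
    cc <- coords[facets[, 3], , drop = FALSE]
    sum(rowSums(a * row_cross(b, cc))) / 6
  } else {
    a <- coords[facets[, 1], , drop = FALSE]
    b <- coords[facets[, 2], , drop = FALSE]
    sum(a[, 1] * b[, 2] - b[, 1] * a[, 2]) / 2
  }
}

#' Mean edge length of a mesh
#' @param mesh an \code{emf_mesh}.
#' @return mean over the unique edges (mm).
#' @export
mean_edge_length <- function(mesh) {
  el <- mesh$elements
  d <- mesh$dim
  pairs <- utils::combn(d + 1L, 2L)
  ed <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    cbind(el[, pairs[1, k]], el[, pairs[2, k]])))
  ed <- unique(t(apply(ed, 1, sort)))
  mean(row_norm(mesh$vertices[ed[, 2], , drop = FALSE] -
                  mesh$vertices[ed[, 1], , drop = FALSE]))
}

#' Extract the submesh carrying the given labels
#'
#' Vertices are renumbered; facets on the old interface with removed labels
#' are tagged per \code{interface_tag}. Existing boundary tags are carried
#' over where the facet survives.
#'
#' @param mesh an \code{emf_mesh}.
#' @param labels labels to keep.
#' @param interface_tag tag given to newly exposed interface facets.
#' @return an \code{emf_mesh}; the vertex map is attached as attribute
#'   \code{vertex_map} (old index per new vertex).
#' @export
submesh <- function(mesh, labels, interface_tag = "interface") {
  keep <- mesh$element_labels %in% labels
  if (!any(keep)) stop_emf("label not present: ", paste(labels, collapse = ", "))
  el <- mesh$elements[keep, , drop = FALSE]
  used <- sort(unique(as.vector(el)))
  map <- integer(nrow(mesh$vertices)); map[used] <- seq_along(used)
  newel <- matrix(map[el], nrow(el), ncol(el))
  sub <- labeled_mesh(mesh$vertices[used, , drop = FALSE], newel,
                      mesh$element_labels[keep], validate = FALSE)
  # carry over tags from the parent mesh where facets coincide
  old_bf_key <- facet_key(mesh$boundary_facets)
  sub_in_old <- matrix(used[sub$boundary_facets], nrow(sub$boundary_facets))
  sub_key <- facet_key(sub_in_old)
  hit <- match(sub_key, old_bf_key)
  tags <- ifelse(is.na(hit), interface_tag, mesh$facet_tags[hit])
  sub$facet_tags <- tags
  attr(sub, "vertex_map") <- used
  attr(sub, "manifest") <- attr(mesh, "manifest")
  sub
}

#' Vertex indices carrying a facet tag
#' @param mesh an \code{emf_mesh}.
#' @param tags character vector of facet tags.
#' @return sorted unique vertex indices.
#' @export
tagged_vertices <- function(mesh, tags) {
  sel <- mesh$facet_tags %in% tags
  sort(unique(as.vector(mesh$boundary_facets[sel, , drop = FALSE])))
}
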