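# Shared P1 finite-element machinery on simplicial meshes: hat-function
# gradients, vectorized sparse assembly of scalar operators, and Dirichlet
# elimination. Element loops are replaced by per-(node-pair) vectorized
# triplet construction.

#' P1 shape-function gradients
#'
#' Constant per element; returned as a list \code{grads[[a]]} (one
#' \code{ne x d} matrix per local node) plus element volumes.
#'
#' @param mesh an \code{emf_mesh}.
#' @param coords optional displaced coordinates.
#' @return list with \code{grads}, \code{vol}, and \code{dim}.
#' @export
p1_gradients <- function(mesh, coords = NULL) {
  coords <- coords %||% mesh$vertices
  el <- mesh$elements
  d <- mesh$dim
  ne <- nrow(el)
  if (d == 3L) {
    E <- cbind(coords[el[, 2], ] - coords[el[, 1], ],
               coords[el[, 3], ] - coords[el[, 1], ],
               coords[el[, 4], ] - coords[el[, 1], ])
    Einv <- t3_inv(E)  # rows of Einv (as matrix) are grad(lambda_{2,3,4})
    g2 <- cbind(Einv[, 1], Einv[, 4], Einv[, 7])
    g3 <- cbind(Einv[, 2], Einv[, 5], Einv[, 8])
    g4 <- cbind(Einv[, 3], Einv[, 6], Einv[, 9])
    g1 <- -(g2 + g3 + g4)
    vol <- t3_det(E) / 6
    grads <- list(g1, g2, g3, g4)
  } else {
    e1 <- coords[el[, 2], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    e2 <- coords[el[, 3], , drop = FALSE] - coords[el[, 1], , drop = FALSE]
    det <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    g2 <- cbind(e2[, 2], -e2[, 1]) / det
    g3 <- cbind(-e1[, 2], e1[, 1]) / det
    g1 <- -(g2 + g3)
    vol <- det / 2
    grads <- list(g1, g2, g3)
  }
  list(grads = grads, vol = vol, dim = d)
}

# assemble sum_e coef_e * (grad_a . K grad_b) over a scalar unknown.
# coef: per-element scalar; K: NULL (identity) or per-element tensor
# (ne x 9 in 3D / function applying it).
assemble_scalar_stiffness <- function(mesh, coef = 1, coords = NULL,
                                      tensor = NULL) {
  gp <- p1_gradients(mesh, coords)
  el <- mesh$elements
  nv <- nrow(mesh$vertices)
  nn <- mesh$dim + 1L
  coef <- rep_len(coef, nrow(el)) * abs(gp$vol)
  ii <- jj <- xx <- vector("list", nn * nn)
  k <- 0L
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    ga <- gp$grads[[a]]
    gb <- gp$grads[[b]]
    gb_eff <- if (is.null(tensor)) gb else {
      if (mesh$dim == 3L) t3_mv(tensor, gb) else gb # 2D tensor unused
    }
    k <- k + 1L
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]
    xx[[k]] <- coef * rowSums(ga * gb_eff)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

# consistent or lumped P1 mass matrix (scalar field)
assemble_mass <- function(mesh, coef = 1, coords = NULL, lumped = FALSE) {
  el <- mesh$elements
  nv <- nrow(mesh$vertices)
  nn <- mesh$dim + 1L
  vol <- abs(element_volumes(mesh, coords)) * rep_len(coef, nrow(el))
  if (lumped) {
    x <- rep(vol / nn, nn)
    i <- as.vector(el)
    return(Matrix::sparseMatrix(i = i, j = i, x = x, dims = c(nv, nv)))
  }
  ii <- jj <- xx <- vector("list", nn * nn)
  k <- 0L
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    k <- k + 1L
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]
    xx[[k]] <- vol / (nn * (nn + 1L)) * (1L + (a == b))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

# Apply Dirichlet conditions to a sparse system: rows/cols of constrained
# dofs are eliminated symmetrically; returns modified K, f.
apply_dirichlet <- function(K, f, dofs, values = 0) {
  if (length(dofs) == 0L) return(list(K = K, f = f))
  values <- rep_len(values, length(dofs))
  n <- nrow(K)
  free <- setdiff(seq_len(n), dofs)
  f2 <- f
  if (any(values != 0)) {
    f2 <- f - as.numeric(K[, dofs, drop = FALSE] %*% values)
  }
  f2[dofs] <- values
  # zero rows/cols, unit diagonal
  D <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% dofs)))
  K2 <- D %*% K %*% D + Matrix::Diagonal(n, x = as.numeric(seq_len(n) %in% dofs))
  list(K = K2, f = f2)
}

solve_sparse <- function(K, f) {
  as.numeric(Matrix::solve(K, f))
}

# volume-weighted element-to-vertex averaging
vertex_average <- function(mesh, evals, coords = NULL) {
  vol <- abs(element_volumes(mesh, coords))
  el <- mesh$elements
  nv <- nrow(mesh$vertices)
  evals <- as.matrix(evals)
  num <- matrix(0, nv, ncol(evals))
  den <- numeric(nv)
  nn <- mesh$dim + 1L
  for (a in seq_len(nn)) {
    idx <- el[, a]
    den <- den + tabulate_weighted(idx, vol, nv)
    for (c in seq_len(ncol(evals)))
      num[, c] <- num[, c] + tabulate_weighted(idx, vol * evals[, c], nv)
  }
  num / pmax(den, .Machine$double.xmin)
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  acc <- rowsum(w, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}
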