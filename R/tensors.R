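# Vectorized 3x3 tensor algebra.
#
# A field of n tensors is stored as an n x 9 matrix in column-major order
# (a11, a21, a31, a12, a22, a32, a13, a23, a33). Vector fields are n x 3.
# These kernels back the per-element constitutive and kinematic evaluations.

t3_eye <- function(n) {
  out <- matrix(0, n, 9)
  out[, c(1, 5, 9)] <- 1
  out
}

t3_from_matrix <- function(A) matrix(as.numeric(A), 1, 9)

t3_mm <- function(A, B) {
  # C = A %*% B, row-wise
  C <- matrix(0, nrow(A), 9)
  for (j in 1:3) for (i in 1:3) {
    C[, i + 3 * (j - 1)] <-
      A[, i] * B[, 1 + 3 * (j - 1)] +
      A[, i + 3] * B[, 2 + 3 * (j - 1)] +
      A[, i + 6] * B[, 3 + 3 * (j - 1)]
  }
  C
}

t3_t <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

t3_tr <- function(A) A[, 1] + A[, 5] + A[, 9]

t3_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 8] * A[, 6]) -
    A[, 4] * (A[, 2] * A[, 9] - A[, 8] * A[, 3]) +
    A[, 7] * (A[, 2] * A[, 6] - A[, 5] * A[, 3])
}

t3_inv <- function(A) {
  d <- t3_det(A)
  inv <- matrix(0, nrow(A), 9)
  inv[, 1] <- (A[, 5] * A[, 9] - A[, 8] * A[, 6]) / d
  inv[, 2] <- -(A[, 2] * A[, 9] - A[, 8] * A[, 3]) / d
  inv[, 3] <- (A[, 2] * A[, 6] - A[, 5] * A[, 3]) / d
  inv[, 4] <- -(A[, 4] * A[, 9] - A[, 7] * A[, 6]) / d
  inv[, 5] <- (A[, 1] * A[, 9] - A[, 7] * A[, 3]) / d
  inv[, 6] <- -(A[, 1] * A[, 6] - A[, 4] * A[, 3]) / d
  inv[, 7] <- (A[, 4] * A[, 8] - A[, 7] * A[, 5]) / d
  inv[, 8] <- -(A[, 1] * A[, 8] - A[, 7] * A[, 2]) / d
  inv[, 9] <- (A[, 1] * A[, 5] - A[, 4] * A[, 2]) / d
  inv
}

t3_scale <- function(A, s) A * s

t3_add <- function(A, B) A + B

t3_sym <- function(A) (A + t3_t(A)) / 2

t3_ddot <- function(A, B) rowSums(A * B)

# y = A v (row-wise 3-vectors); preallocated fill (hot path)
t3_mv <- function(A, v) {
  out <- matrix(0, nrow(A), 3)
  out[, 1] <- A[, 1] * v[, 1] + A[, 4] * v[, 2] + A[, 7] * v[, 3]
  out[, 2] <- A[, 2] * v[, 1] + A[, 5] * v[, 2] + A[, 8] * v[, 3]
  out[, 3] <- A[, 3] * v[, 1] + A[, 6] * v[, 2] + A[, 9] * v[, 3]
  out
}

# outer product u (x) v; preallocated fill (hot path)
t3_outer <- function(u, v) {
  out <- matrix(0, nrow(u), 9)
  out[, 1] <- u[, 1] * v[, 1]; out[, 2] <- u[, 2] * v[, 1]
  out[, 3] <- u[, 3] * v[, 1]; out[, 4] <- u[, 1] * v[, 2]
  out[, 5] <- u[, 2] * v[, 2]; out[, 6] <- u[, 3] * v[, 2]
  out[, 7] <- u[, 1] * v[, 3]; out[, 8] <- u[, 2] * v[, 3]
  out[, 9] <- u[, 3] * v[, 3]
  out
}

# quadratic form v . A v
t3_quad <- function(A, v) rowSums(v * t3_mv(A, v))

row_norm <- function(v) sqrt(rowSums(v^2))

row_unit <- function(v) {
  n <- row_norm(v)
  n[n == 0] <- 1
  v / n
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
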