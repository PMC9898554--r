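# Rotation operators, Wigner D matrices, and real-basis Wigner 3j coupling
# tensors. D matrices are constructed directly from the package's own real
# spherical harmonics, and the 3j tensors are solved from the equivariance
# constraint, so every coupling coefficient is exactly consistent with the
# harmonic convention in R/spherical.R.

#' Rotation (and optional inversion) operator
#'
#' An element of O(3): a proper rotation matrix `R` (det = +1) plus an
#' optional inversion flag; the represented operation is `(-1)^inversion * R`.
#'
#' @param R 3x3 proper rotation matrix.
#' @param inversion Logical; compose with spatial inversion.
#' @return An object of class `"rotation_op"`.
#' @export
rotation_op <- function(R, inversion = FALSE) {
  R <- matrix(as.numeric(R), 3L, 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) .stopf("R is not orthogonal")
  if (det(R) < 0) .stopf("R must be proper (det +1); use inversion = TRUE")
  structure(list(R = R, inversion = isTRUE(inversion)), class = "rotation_op")
}

#' @rdname rotation_op
#' @param angles Length-3 numeric; extrinsic rotations about z, y, z.
#' @export
rotation_from_euler <- function(angles) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L)
  rotation_op(rz(angles[3L]) %*% ry(angles[2L]) %*% rz(angles[1L]))
}

#' @rdname rotation_op
#' @param inversion_prob Probability of adding an inversion.
#' @export
random_rotation <- function(inversion_prob = 0) {
  # uniform over SO(3) via QR of a Gaussian matrix
  q <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  rotation_op(R, inversion = stats::runif(1L) < inversion_prob)
}

# Cartesian action on points/vectors
rot_apply_vec <- function(rot, v) {
  s <- if (rot$inversion) -1 else 1
  s * (matrix(v, ncol = 3L) %*% t(rot$R))
}

#' Wigner D matrix in the real harmonic basis
#'
#' The `(2*ell+1) x (2*ell+1)` orthogonal matrix `D(ell, R)` satisfying
#' `Y_ell(R u) = D(ell, R) Y_ell(u)` in the package's real-harmonic
#' convention. It is recovered by evaluating the harmonics on a fixed,
#' well-conditioned set of sample directions. Inversion acts on an irrep with
#' parity `p` as multiplication by `p` (for the harmonics, `(-1)^ell`); the
#' proper-rotation part returned here is parity-independent.
#'
#' @param ell Rotation order.
#' @param rot A [rotation_op()] (its inversion flag is ignored here; see
#'   [apply_rotation()] for the parity-aware action on features).
#' @return Orthogonal matrix of dim `2*ell+1`.
#' @export
wigner_D <- function(ell, rot) {
  if (ell == 0L) return(matrix(1, 1L, 1L))
  pts <- .sph_points(2L * (2L * ell + 1L) + 5L)
  Y0 <- .rsh_eval(ell, pts)[[ell + 1L]]          # K x (2l+1)
  Y1 <- .rsh_eval(ell, pts %*% t(rot$R))[[ell + 1L]]
  # Y1 = Y0 %*% t(D)  =>  t(D) = lstsq(Y0, Y1)
  t(qr.solve(Y0, Y1))
}

#' Apply a rotation (optionally with inversion) to a block array
#'
#' Acts blockwise with the Wigner D matrix of each block's rotation order;
#' blocks with odd parity additionally flip sign under inversion. Blocks with
#' unset parity (SE(3) mode) are unaffected by inversion.
#'
#' @param x A [block_array()].
#' @param rot A [rotation_op()].
#' @return A transformed [block_array()].
#' @export
apply_rotation <- function(x, rot) {
  blocks <- vector("list", nrow(x$layout))
  for (b in seq_len(nrow(x$layout))) {
    D <- wigner_D(x$layout$ell[b], rot)
    blk <- x$blocks[[b]] %*% t(D)
    if (rot$inversion && x$layout$parity[b] == -1L) blk <- -blk
    blocks[[b]] <- blk
  }
  block_array(x$layout, blocks)
}

# ---- real-basis Wigner 3j --------------------------------------------------

.w3j_fixed_rotations <- function() {
  list(rotation_from_euler(c(0.3, 0.0, 0.0)),
       rotation_from_euler(c(0.0, 0.7, 0.0)),
       rotation_from_euler(c(0.9, 1.2, 0.4)))
}

#' Real-basis Wigner 3j coupling tensor
#'
#' The coupling tensor `C` of shape `(2*l1+1) x (2*l2+1) x (2*l3+1)` such that
#' `z[m3] = sum_{m1,m2} C[m1,m2,m3] x[m1] y[m2]` maps two equivariant inputs
#' of orders `l1`, `l2` to an equivariant output of order `l3`, in the real
#' harmonic basis of this package. `C` is the (one-dimensional) solution of
#' the rotational equivariance constraint over a fixed set of generic
#' rotations, normalized so that `sum_{m1,m2} C[m1,m2,m]^2 = 1` for each `m`
#' (by Schur orthogonality the slices are automatically orthogonal), with the
#' sign fixed by making the first nonzero entry positive. Tensors are cached.
#'
#' @param l1,l2,l3 Rotation orders; must satisfy the triangle selection rule
#'   `|l1 - l2| <= l3 <= l1 + l2`, otherwise an invalid-path error is raised.
#' @return 3-dimensional array.
#' @examples
#' wigner_3j(1, 1, 0)  # proportional to the Euclidean dot product
#' @export
wigner_3j <- function(l1, l2, l3) {
  if (l3 < abs(l1 - l2) || l3 > l1 + l2)
    .stopf("invalid path: (%d, %d, %d) violates |l1-l2| <= l3 <= l1+l2", l1, l2, l3)
  .cache_get(sprintf("w3j_%d_%d_%d", l1, l2, l3), function() {
    d1 <- 2L * l1 + 1L; d2 <- 2L * l2 + 1L; d3 <- 2L * l3 + 1L
    rows <- lapply(.w3j_fixed_rotations(), function(rot) {
      D1 <- wigner_D(l1, rot); D2 <- wigner_D(l2, rot); D3 <- wigner_D(l3, rot)
      # constraint on vec(C) (index m1 fastest, then m2, then m3):
      # kron(I_d3, kron(t(D2), t(D1))) - kron(D3, I_{d1*d2})
      kronecker(diag(d3), kronecker(t(D2), t(D1))) -
        kronecker(D3, diag(d1 * d2))
    })
    K <- do.call(rbind, rows)
    sv <- svd(K)
    null_dim <- sum(sv$d < 1e-8 * max(sv$d[1L], 1))
    if (null_dim != 1L)
      .stopf("unexpected null-space dimension %d for (%d,%d,%d)", null_dim, l1, l2, l3)
    v <- sv$v[, ncol(sv$v)]
    C <- array(v, dim = c(d1, d2, d3))
    # per-output-slice unit norm; slices share a common norm by Schur
    C <- C / sqrt(sum(C^2) / d3)
    nz <- which(abs(C) > 1e-8)[1L]
    if (C[nz] < 0) C <- -C
    C
  })
}

# Sparse triplet form (m1, m2, m3, coeff) of a 3j tensor, cached; used by the
# batched tensor-product kernels.
w3j_triplets <- function(l1, l2, l3) {
  .cache_get(sprintf("w3jtrip_%d_%d_%d", l1, l2, l3), function() {
    C <- wigner_3j(l1, l2, l3)
    idx <- which(abs(C) > 1e-12, arr.ind = TRUE)
    cbind(idx, coef = C[idx])
  })
}
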