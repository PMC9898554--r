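# Real spherical harmonics.
#
# Convention used throughout the package:
#   * components ordered m = -ell, ..., 0, ..., +ell
#     (m < 0 -> sin(|m| phi) components, m > 0 -> cos(m phi) components),
#   * no Condon-Shortley phase,
#   * "component normalization": each ell-block evaluated on a unit vector has
#     squared Euclidean norm 2*ell + 1 (i.e. sqrt(4*pi) times the orthonormal
#     real harmonics), so that individual components are O(1).
# Under this convention the ell = 1 block is sqrt(3) * (y, z, x).

# Associated Legendre P_l^m(x) WITHOUT the Condon-Shortley phase, for one m
# and all l = m..l_max, given x = cos(theta) and s = sin(theta) >= 0.
.legendre_m <- function(l_max, m, x, s) {
  out <- vector("list", l_max - m + 1L)
  pmm <- rep(1, length(x))
  if (m > 0) pmm <- prod(seq(1, 2 * m - 1, by = 2)) * s^m
  out[[1L]] <- pmm
  if (l_max > m) {
    pm1 <- (2 * m + 1) * x * pmm
    out[[2L]] <- pm1
    if (l_max > m + 1L) {
      for (l in (m + 2L):l_max) {
        p <- ((2 * l - 1) * x * pm1 - (l + m - 1) * pmm) / (l - m)
        out[[l - m + 1L]] <- p
        pmm <- pm1; pm1 <- p
      }
    }
  }
  out
}

# Evaluate real spherical harmonics for unit vectors. u: n x 3 matrix.
# Returns a list over ell = 0..ell_max of n x (2*ell+1) matrices.
.rsh_eval <- function(ell_max, u) {
  u <- matrix(u, ncol = 3L)
  x <- u[, 1L]; y <- u[, 2L]; z <- u[, 3L]
  ct <- z
  st <- sqrt(pmax(x^2 + y^2, 0))
  phi <- atan2(y, x)  # arbitrary at poles; m > 0 terms vanish there anyway
  out <- lapply(0:ell_max, function(l) matrix(0, length(ct), 2L * l + 1L))
  for (m in 0:ell_max) {
    pl <- .legendre_m(ell_max, m, ct, st)
    for (l in m:ell_max) {
      # norm: sqrt(2l+1) * sqrt((l-m)!/(l+m)!), times sqrt(2) for m > 0
      nrm <- sqrt((2 * l + 1) * exp(lfactorial(l - m) - lfactorial(l + m)))
      p <- pl[[l - m + 1L]]
      if (m == 0L) {
        out[[l + 1L]][, l + 1L] <- nrm * p
      } else {
        out[[l + 1L]][, l + 1L + m] <- sqrt(2) * nrm * p * cos(m * phi)
        out[[l + 1L]][, l + 1L - m] <- sqrt(2) * nrm * p * sin(m * phi)
      }
    }
  }
  out
}

#' Real spherical harmonics of a direction
#'
#' Projects a direction onto the real spherical harmonics
#' \eqn{Y_\ell}{Y_l} for \eqn{\ell = 0, \dots, \ell_{max}}, the angular basis
#' used for all equivariant atomic-environment embeddings. Components are
#' ordered \eqn{m = -\ell..\ell}, carry no Condon-Shortley phase, and each
#' \eqn{\ell}-block has squared norm \eqn{2\ell+1} on unit input
#' ("component normalization"); the \eqn{\ell}-block has parity
#' \eqn{(-1)^\ell}.
#'
#' Non-unit input policy: the input is normalized internally; a (near-)zero
#' vector is an error.
#'
#' @param ell_max Maximum rotation order.
#' @param u Numeric length-3 direction vector.
#' @param parity If `TRUE` (default) blocks are tagged with parity
#'   `(-1)^ell`; if `FALSE` parity is left unset (SE(3) mode).
#' @return A [block_array()] with one channel per `ell = 0..ell_max`.
#' @examples
#' y <- sph_harmonics(1, c(0, 0, 1))
#' y$blocks[[2]]  # sqrt(3) * (y, z, x) = (0, sqrt(3), 0)
#' @export
sph_harmonics <- function(ell_max, u, parity = TRUE) {
  u <- as.numeric(u)
  if (length(u) != 3L) .stopf("u must be a length-3 vector")
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) .stopf("cannot take spherical harmonics of a zero vector")
  u <- u / nu
  vals <- .rsh_eval(ell_max, matrix(u, 1L, 3L))
  p <- if (parity) (-1L)^(0:ell_max) else rep(0L, ell_max + 1L)
  block_array(irrep_layout(rep(1L, ell_max + 1L), 0:ell_max, p),
              lapply(vals, function(v) v))
}

# ---- Homogeneous-polynomial (monomial) form -------------------------------
# Each component of Y_ell restricted to the unit sphere is a homogeneous
# polynomial of degree ell in (x, y, z). The monomial coefficients are
# recovered once per ell by exact least squares against .rsh_eval on a fixed
# deterministic point set, then cached. They drive both the closed-form
# derivative of the harmonics (needed for forces) and the polynomial-form
# tests.

.sph_points <- function(n) {
  # deterministic, well-spread unit vectors (Fibonacci sphere)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# exponents (a,b,c), a+b+c = ell
.monomial_exponents <- function(ell) {
  ex <- expand.grid(a = 0:ell, b = 0:ell)
  ex <- ex[ex$a + ex$b <= ell, , drop = FALSE]
  cbind(a = ex$a, b = ex$b, c = ell - ex$a - ex$b)
}

sph_monomials <- function(ell) {
  .cache_get(paste0("sphmono_", ell), function() {
    ex <- .monomial_exponents(ell)
    pts <- .sph_points(4L * nrow(ex) + 16L)
    M <- sapply(seq_len(nrow(ex)), function(k)
      pts[, 1L]^ex[k, 1L] * pts[, 2L]^ex[k, 2L] * pts[, 3L]^ex[k, 3L])
    Y <- .rsh_eval(ell, pts)[[ell + 1L]]
    coef <- qr.solve(M, Y)  # nrow(ex) x (2*ell+1)
    coef[abs(coef) < 1e-10] <- 0
    list(exponents = ex, coef = coef)
  })
}

# Evaluate Y_ell and its Jacobian w.r.t. the *unnormalized* vectors.
# v: n x 3 (not necessarily unit). Returns list(Y = n x (2l+1),
# dY = list over m of n x 3). Complex-step safe (no abs/max on v).
.sph_poly_eval <- function(ell, v, want_grad = FALSE) {
  mono <- sph_monomials(ell)
  ex <- mono$exponents; coef <- mono$coef
  n <- nrow(v)
  r2 <- v[, 1L]^2 + v[, 2L]^2 + v[, 3L]^2
  r <- sqrt(r2)
  # P(v) homogeneous degree ell; Y = P(v) / r^ell
  pows <- function(col, maxe) {
    out <- vector("list", maxe + 1L)
    out[[1L]] <- rep(1 + 0 * r[1L], n) * (if (is.complex(v)) 1 + 0i else 1)
    if (maxe >= 1L) for (e in 1:maxe) out[[e + 1L]] <- out[[e]] * v[, col]
    out
  }
  px <- pows(1L, ell); py <- pows(2L, ell); pz <- pows(3L, ell)
  nm <- nrow(ex)
  monos <- matrix(if (is.complex(v)) 0i else 0, n, nm)
  for (k in seq_len(nm))
    monos[, k] <- px[[ex[k, 1L] + 1L]] * py[[ex[k, 2L] + 1L]] * pz[[ex[k, 3L] + 1L]]
  P <- monos %*% coef
  rl <- if (ell == 0L) rep(1, n) else r^ell
  Y <- P / rl
  if (!want_grad) return(list(Y = Y))
  # dY/dv = grad(P)/r^l - l * P * v / r^(l+2)
  dY <- vector("list", 3L)
  for (d in 1:3) {
    gm <- matrix(if (is.complex(v)) 0i else 0, n, nm)
    for (k in seq_len(nm)) {
      e <- ex[k, d]
      if (e > 0L) {
        ee <- ex[k, ]; ee[d] <- ee[d] - 1L
        gm[, k] <- e * px[[ee[1L] + 1L]] * py[[ee[2L] + 1L]] * pz[[ee[3L] + 1L]]
      }
    }
    dP <- gm %*% coef
    dY[[d]] <- dP / rl - ell * P * v[, d] / (rl * r2)
  }
  list(Y = Y, dY = dY)
}
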