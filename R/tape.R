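# Minimal reverse-mode automatic differentiation on a tape.
#
# Values are plain numeric (or complex) matrices/vectors; nodes are
# environments recording parents and a backward closure. The engine is
# complex-safe: running a forward+backward pass at complex input yields the
# complex-step directional derivative of the gradient, which the training
# module uses to differentiate force residuals with respect to parameters
# without a second-order tape.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

.nd_record <- function(tape, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$bw <- bw
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

is_nd <- function(x) is.environment(x) && !is.null(x$val)
nd_val <- function(x) if (is_nd(x)) x$val else x

nd_leaf <- function(tape, val) .nd_record(tape, val)

.acc <- function(nd, g) {
  if (is.null(nd)) return(invisible())
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible()
}

# run backward from `out` with seed gradient `seed` (same shape as out$val)
tape_backward <- function(tape, out, seed = 1) {
  for (k in seq_len(tape$n)) tape$nodes[[k]]$grad <- NULL
  out$grad <- seed + 0 * out$val
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    nd$bw(nd$grad)
  }
  invisible()
}

# group-sum of rows (complex-safe rowsum)
.rowsum_by <- function(x, group, ngroups) {
  x <- as.matrix(x)
  if (is.complex(x)) {
    out <- .rowsum_by(Re(x), group, ngroups) + 1i * .rowsum_by(Im(x), group, ngroups)
    return(out)
  }
  out <- matrix(0, ngroups, ncol(x))
  rs <- rowsum(x, group = group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- ops -------------------------------------------------------------------

nd_matmul <- function(tape, x, w) {
  xv <- nd_val(x); wv <- nd_val(w)
  .nd_record(tape, xv %*% wv, bw = function(g) {
    if (is_nd(x)) .acc(x, g %*% t(wv))
    if (is_nd(w)) .acc(w, t(xv) %*% g)
  })
}

nd_add <- function(tape, x, y) {
  .nd_record(tape, nd_val(x) + nd_val(y), bw = function(g) {
    if (is_nd(x)) .acc(x, g)
    if (is_nd(y)) .acc(y, g)
  })
}

nd_scale <- function(tape, x, a) {  # a: plain scalar constant
  .nd_record(tape, a * nd_val(x), bw = function(g) if (is_nd(x)) .acc(x, a * g))
}

nd_mul <- function(tape, x, y) {  # elementwise, same shape
  xv <- nd_val(x); yv <- nd_val(y)
  .nd_record(tape, xv * yv, bw = function(g) {
    if (is_nd(x)) .acc(x, g * yv)
    if (is_nd(y)) .acc(y, g * xv)
  })
}

nd_mulvec <- function(tape, x, v) {  # each column of x times vector v
  xv <- nd_val(x); vv <- as.vector(nd_val(v))
  .nd_record(tape, xv * vv, bw = function(g) {
    if (is_nd(x)) .acc(x, g * vv)
    if (is_nd(v)) .acc(v, rowSums(g * xv))
  })
}

nd_silu <- function(tape, x) {
  xv <- nd_val(x)
  sig <- 1 / (1 + exp(-xv))
  .nd_record(tape, xv * sig, bw = function(g)
    .acc(x, g * (sig + xv * sig * (1 - sig))))
}

nd_cbind <- function(tape, ...) {
  xs <- list(...)
  vals <- lapply(xs, nd_val)
  widths <- vapply(vals, ncol, 0L)
  .nd_record(tape, do.call(cbind, vals), bw = function(g) {
    at <- 0L
    for (k in seq_along(xs)) {
      if (is_nd(xs[[k]]))
        .acc(xs[[k]], g[, (at + 1L):(at + widths[k]), drop = FALSE])
      at <- at + widths[k]
    }
  })
}

nd_rows <- function(tape, x, idx) {  # gather rows
  xv <- nd_val(x)
  .nd_record(tape, xv[idx, , drop = FALSE], bw = function(g) {
    if (is_nd(x)) .acc(x, .rowsum_by(g, idx, nrow(xv)))
  })
}

nd_rowsum_by <- function(tape, x, group, ngroups) {  # scatter-add rows
  xv <- nd_val(x)
  .nd_record(tape, .rowsum_by(xv, group, ngroups), bw = function(g) {
    if (is_nd(x)) .acc(x, g[group, , drop = FALSE])
  })
}

nd_sum <- function(tape, x) {
  xv <- nd_val(x)
  .nd_record(tape, sum(xv), bw = function(g) .acc(x, g + 0 * xv))
}

# Euclidean norm of rows of an E x 3 matrix (analytic, complex-step safe)
nd_norm3 <- function(tape, rvec) {
  v <- nd_val(rvec)
  r <- sqrt(v[, 1L]^2 + v[, 2L]^2 + v[, 3L]^2)
  .nd_record(tape, r, bw = function(g) .acc(rvec, (g / r) * v))
}

# spherical harmonics block Y_l of edge vectors; E x (2l+1)
nd_sph <- function(tape, rvec, ell) {
  v <- nd_val(rvec)
  pe <- .sph_poly_eval(ell, v, want_grad = TRUE)
  .nd_record(tape, pe$Y, bw = function(g) {
    dd <- cbind(rowSums(g * pe$dY[[1L]]), rowSums(g * pe$dY[[2L]]),
                rowSums(g * pe$dY[[3L]]))
    .acc(rvec, dd)
  })
}

# normalized enveloped radial basis of distances; E x n_basis
nd_radial <- function(tape, r, spec, freq = NULL) {
  rv <- nd_val(r)
  fv <- if (is_nd(freq)) nd_val(freq) else freq
  g <- .normalized_basis_grad(rv, spec, fv)
  .nd_record(tape, g$val, bw = function(gg) {
    .acc(r, rowSums(gg * g$dr))
    if (is_nd(freq)) .acc(freq, colSums(gg * g$dfreq))
  })
}

# cutoff envelope u(r); vector
nd_envelope <- function(tape, r, spec) {
  rv <- nd_val(r)
  du <- .envelope_grad(rv, spec)
  .nd_record(tape, envelope(rv, spec), bw = function(g) .acc(r, g * du))
}

# channelwise Wigner coupling of two blocks in channel-fastest layout:
# x: E x ((2*l1+1)*neq), y: E x ((2*l2+1)*neq); out: E x ((2*lo+1)*neq)
# out[, (mo-1)*neq + n] = sum_trip c * x[, (m1-1)*neq + n] * y[, (m2-1)*neq + n]
nd_tp <- function(tape, x, y, l1, l2, lo, neq) {
  trip <- w3j_triplets(l1, l2, lo)
  xv <- nd_val(x); yv <- nd_val(y)
  cols <- function(m) ((m - 1L) * neq + 1L):(m * neq)
  out <- matrix(if (is.complex(xv) || is.complex(yv)) 0i else 0,
                nrow(xv), (2L * lo + 1L) * neq)
  for (t in seq_len(nrow(trip))) {
    out[, cols(trip[t, 3L])] <- out[, cols(trip[t, 3L])] +
      trip[t, 4L] * xv[, cols(trip[t, 1L]), drop = FALSE] *
      yv[, cols(trip[t, 2L]), drop = FALSE]
  }
  .nd_record(tape, out, bw = function(g) {
    if (is_nd(x)) {
      gx <- 0 * xv
      for (t in seq_len(nrow(trip)))
        gx[, cols(trip[t, 1L])] <- gx[, cols(trip[t, 1L])] +
          trip[t, 4L] * g[, cols(trip[t, 3L]), drop = FALSE] *
          yv[, cols(trip[t, 2L]), drop = FALSE]
      .acc(x, gx)
    }
    if (is_nd(y)) {
      gy <- 0 * yv
      for (t in seq_len(nrow(trip)))
        gy[, cols(trip[t, 2L])] <- gy[, cols(trip[t, 2L])] +
          trip[t, 4L] * g[, cols(trip[t, 3L]), drop = FALSE] *
          xv[, cols(trip[t, 1L]), drop = FALSE]
      .acc(y, gy)
    }
  })
}

# per-channel outer product: w (E x neq) with Y (E x (2l+1)) ->
# E x ((2l+1)*neq), channel-fastest
nd_chanouter <- function(tape, w, y, neq) {
  wv <- nd_val(w); yv <- nd_val(y)
  dm <- ncol(yv)
  out <- matrix(if (is.complex(wv) || is.complex(yv)) 0i else 0,
                nrow(wv), dm * neq)
  for (m in seq_len(dm))
    out[, ((m - 1L) * neq + 1L):(m * neq)] <- wv * yv[, m]
  .nd_record(tape, out, bw = function(g) {
    if (is_nd(w)) {
      gw <- 0 * wv
      for (m in seq_len(dm))
        gw <- gw + g[, ((m - 1L) * neq + 1L):(m * neq), drop = FALSE] * yv[, m]
      .acc(w, gw)
    }
    if (is_nd(y)) {
      gy <- 0 * yv
      for (m in seq_len(dm))
        gy[, m] <- rowSums(g[, ((m - 1L) * neq + 1L):(m * neq), drop = FALSE] * wv)
      .acc(y, gy)
    }
  })
}

# block-diagonal matmul: x (E x (nb*win)) -> (E x (nb*wout)) applying the same
# W (win x wout) to each of nb contiguous column blocks (used for per-m
# channel mixing with channel-fastest layout)
nd_blockmm <- function(tape, x, w, nblocks) {
  xv <- nd_val(x); wv <- nd_val(w)
  win <- nrow(wv); wout <- ncol(wv)
  out <- matrix(if (is.complex(xv) || is.complex(wv)) 0i else 0,
                nrow(xv), nblocks * wout)
  for (b in seq_len(nblocks))
    out[, ((b - 1L) * wout + 1L):(b * wout)] <-
      xv[, ((b - 1L) * win + 1L):(b * win), drop = FALSE] %*% wv
  .nd_record(tape, out, bw = function(g) {
    if (is_nd(x)) {
      gx <- 0 * xv
      for (b in seq_len(nblocks))
        gx[, ((b - 1L) * win + 1L):(b * win)] <-
          g[, ((b - 1L) * wout + 1L):(b * wout), drop = FALSE] %*% t(wv)
      .acc(x, gx)
    }
    if (is_nd(w)) {
      gw <- 0 * wv
      for (b in seq_len(nblocks))
        gw <- gw + t(xv[, ((b - 1L) * win + 1L):(b * win), drop = FALSE]) %*%
          g[, ((b - 1L) * wout + 1L):(b * wout), drop = FALSE]
      .acc(w, gw)
    }
  })
}

nd_cols <- function(tape, x, idx) {  # select columns
  xv <- nd_val(x)
  .nd_record(tape, xv[, idx, drop = FALSE], bw = function(g) {
    if (is_nd(x)) {
      gx <- 0 * xv
      gx[, idx] <- gx[, idx, drop = FALSE] + g
      .acc(x, gx)
    }
  })
}
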