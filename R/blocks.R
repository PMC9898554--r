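# Tensor products of block arrays and enumeration of coupling paths.

#' Enumerate tensor-product paths between two layouts
#'
#' A path is an admissible triple of irreps `(l1,p1) x (l2,p2) -> (lo,po)`
#' satisfying the selection rules `|l1-l2| <= lo <= l1+l2`, `po = p1*p2`
#' (parity is propagated as "unset" if either input parity is unset), and
#' `lo <= ell_max`. With `mode = "all_allowed"` every such path is emitted;
#' with `mode = "restricted"` only paths whose output irrep already occurs in
#' `layout1`. Paths are returned in lexicographic order of
#' `(l1, p1, l2, p2, l_out, p_out)`, the canonical order used for every
#' path-dependent sum in the package.
#'
#' @param layout1,layout2 [irrep_layout()]s of the two factors.
#' @param ell_max Cap on the output rotation order.
#' @param mode `"all_allowed"` (default) or `"restricted"`.
#' @return A data.frame with columns `i1`, `i2` (block indices into the two
#'   layouts), `l1`, `p1`, `l2`, `p2`, `l_out`, `p_out`.
#' @export
enumerate_paths <- function(layout1, layout2, ell_max,
                            mode = c("all_allowed", "restricted")) {
  mode <- match.arg(mode)
  out <- list()
  for (i1 in seq_len(nrow(layout1))) for (i2 in seq_len(nrow(layout2))) {
    l1 <- layout1$ell[i1]; p1 <- layout1$parity[i1]
    l2 <- layout2$ell[i2]; p2 <- layout2$parity[i2]
    po <- if (p1 == 0L || p2 == 0L) 0L else p1 * p2
    los <- seq.int(abs(l1 - l2), min(l1 + l2, ell_max))
    for (lo in los) {
      if (mode == "restricted" &&
          !any(layout1$ell == lo & layout1$parity == po)) next
      out[[length(out) + 1L]] <-
        data.frame(i1 = i1, i2 = i2, l1 = l1, p1 = p1, l2 = l2, p2 = p2,
                   l_out = lo, p_out = po)
    }
  }
  if (!length(out))
    return(data.frame(i1 = integer(), i2 = integer(), l1 = integer(),
                      p1 = integer(), l2 = integer(), p2 = integer(),
                      l_out = integer(), p_out = integer()))
  paths <- do.call(rbind, out)
  paths[order(paths$l1, paths$p1, paths$l2, paths$p2, paths$l_out, paths$p_out,
              paths$i1, paths$i2), , drop = FALSE]
}

#' Tensor product of two block arrays
#'
#' The equivariant bilinear product: for each path, contracts the two input
#' blocks with the real-basis Wigner 3j tensor,
#' `out[n, mo] = sum_{m1,m2} C[m1,m2,mo] x[n,m1] y[n,m2]`,
#' channel-wise (`n` runs over channels; a single-channel factor is broadcast
#' against a multi-channel one). The output has one block per path.
#'
#' @param x,y [block_array()]s.
#' @param paths Path table from [enumerate_paths()]; defaults to all allowed
#'   paths with `ell_max = max(ell)` of the two layouts summed.
#' @return A [block_array()] with one block per path.
#' @export
tensor_product <- function(x, y, paths = NULL) {
  if (is.null(paths))
    paths <- enumerate_paths(x$layout, y$layout, max(x$layout$ell) + max(y$layout$ell))
  blocks <- vector("list", nrow(paths))
  ns <- integer(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    i1 <- paths$i1[r]; i2 <- paths$i2[r]
    if (i1 > nrow(x$layout) || i2 > nrow(y$layout))
      .stopf("path refers to block outside layout")
    if (x$layout$ell[i1] != paths$l1[r] || y$layout$ell[i2] != paths$l2[r])
      .stopf("path/layout mismatch on rotation orders")
    bx <- x$blocks[[i1]]; by <- y$blocks[[i2]]
    n1 <- nrow(bx); n2 <- nrow(by)
    if (n1 != n2) {
      if (n1 == 1L) bx <- bx[rep(1L, n2), , drop = FALSE]
      else if (n2 == 1L) by <- by[rep(1L, n1), , drop = FALSE]
      else .stopf("incompatible channel counts %d and %d", n1, n2)
    }
    n <- max(n1, n2)
    trip <- w3j_triplets(paths$l1[r], paths$l2[r], paths$l_out[r])
    out <- matrix(0, n, 2L * paths$l_out[r] + 1L)
    for (t in seq_len(nrow(trip)))
      out[, trip[t, 3L]] <- out[, trip[t, 3L]] +
        trip[t, 4L] * bx[, trip[t, 1L]] * by[, trip[t, 2L]]
    blocks[[r]] <- out
    ns[r] <- n
  }
  block_array(irrep_layout(ns, paths$l_out, paths$p_out), blocks)
}
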