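#' Irreducible representation of O(3) / SO(3)
#'
#' An irrep is indexed by a rotation order `ell >= 0` and, when working with
#' the full orthogonal group O(3), a parity `p = +1` (even) or `p = -1` (odd).
#' Setting `parity = 0` leaves the parity index unset, which corresponds to
#' SO(3)/SE(3)-mode features where inversion is not tracked. The irrep has
#' dimension `2*ell + 1`; components are indexed by `m = -ell, ..., ell`.
#'
#' @param ell Non-negative integer rotation order.
#' @param parity One of `1`, `-1`, or `0` (unset).
#' @return An object of class `"irrep"` with fields `ell` and `parity`.
#' @examples
#' irrep(1, -1)          # a vector (parity-odd l = 1)
#' irrep_dim(irrep(2, 1))  # 5
#' @export
irrep <- function(ell, parity = 0L) {
  ell <- as.integer(ell)
  parity <- as.integer(parity)
  if (length(ell) != 1L || is.na(ell) || ell < 0L) .stopf("ell must be a single integer >= 0")
  if (!parity %in% c(-1L, 0L, 1L)) .stopf("parity must be +1, -1, or 0 (unset)")
  structure(list(ell = ell, parity = parity), class = "irrep")
}

#' @rdname irrep
#' @param x An `irrep`.
#' @export
irrep_dim <- function(x) 2L * x$ell + 1L

#' @export
format.irrep <- function(x, ...) {
  p <- c(`-1` = "o", `0` = "", `1` = "e")[as.character(x$parity)]
  paste0(x$ell, p)
}

#' @export
print.irrep <- function(x, ...) {
  cat("<irrep ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Irrep layout of a block array
#'
#' A layout is an ordered list of `(n, irrep)` entries: `n` channels of the
#' given irrep. It fixes the block structure (and total component count
#' `sum(n * (2*ell+1))`) of an [block_array()].
#'
#' @param n Integer vector of channel counts.
#' @param ell Integer vector of rotation orders.
#' @param parity Integer vector of parities (`1`, `-1`, or `0` = unset).
#' @return A data.frame of class `"irrep_layout"` with columns `n`, `ell`,
#'   `parity`.
#' @examples
#' irrep_layout(n = c(4, 4), ell = c(0, 1), parity = c(1, -1))
#' @export
irrep_layout <- function(n, ell, parity = rep(0L, length(ell))) {
  n <- as.integer(n); ell <- as.integer(ell); parity <- as.integer(parity)
  if (length(n) != length(ell) || length(ell) != length(parity))
    .stopf("n, ell, parity must have equal length")
  if (any(n < 1L)) .stopf("channel counts must be >= 1")
  if (any(ell < 0L)) .stopf("ell must be >= 0")
  if (!all(parity %in% c(-1L, 0L, 1L))) .stopf("parity must be +1, -1, or 0")
  structure(data.frame(n = n, ell = ell, parity = parity),
            class = c("irrep_layout", "data.frame"))
}

layout_dim <- function(layout) sum(layout$n * (2L * layout$ell + 1L))

#' Block array of equivariant features
#'
#' The carrier of all equivariant math in the package: feature components
#' grouped into blocks, one block per layout entry, each block an
#' `n x (2*ell+1)` matrix (channels in rows, `m = -ell..ell` in columns).
#'
#' @param layout An [irrep_layout()].
#' @param blocks List of matrices, `blocks[[b]]` of dim `n[b] x (2*ell[b]+1)`.
#' @return An object of class `"block_array"`.
#' @export
block_array <- function(layout, blocks) {
  if (!inherits(layout, "irrep_layout")) .stopf("layout must be an irrep_layout")
  if (length(blocks) != nrow(layout)) .stopf("need one block per layout entry")
  for (b in seq_len(nrow(layout))) {
    blk <- as.matrix(blocks[[b]])
    if (nrow(blk) != layout$n[b] || ncol(blk) != 2L * layout$ell[b] + 1L)
      .stopf("block %d has dim %dx%d, expected %dx%d", b, nrow(blk), ncol(blk),
             layout$n[b], 2L * layout$ell[b] + 1L)
    blocks[[b]] <- blk
  }
  structure(list(layout = layout, blocks = blocks), class = "block_array")
}

#' @rdname block_array
#' @param x A `block_array`.
#' @export
ba_components <- function(x) unlist(lapply(x$blocks, function(b) as.vector(t(b))))

ba_zero <- function(layout) {
  block_array(layout, lapply(seq_len(nrow(layout)), function(b)
    matrix(0, layout$n[b], 2L * layout$ell[b] + 1L)))
}

#' @export
print.block_array <- function(x, ...) {
  lab <- paste0(x$layout$n, "x", x$layout$ell,
                c(`-1` = "o", `0` = "", `1` = "e")[as.character(x$layout$parity)])
  cat("<block_array ", paste(lab, collapse = " + "),
      " (", layout_dim(x$layout), " components)>\n", sep = "")
  invisible(x)
}
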