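# Brute-force reference implementations: the atomic cluster expansion (ACE)
# density projection and body-ordered descriptors (computed both through the
# "density trick" and through explicit neighbor-tuple sums), a neighbor-tuple
# expansion of the model's equivariant features for verifying the layer
# recursion, and a polynomial probe of the model's body order.

#' ACE density projection A_{z,n,l}
#'
#' Projects the local atomic density around one center onto a radial-chemical
#' x spherical-harmonic basis: for each species z, radial index n and rotation
#' order l, `A = sum_{j in N(i), z_j = z} R_n(r_ij) Y_l(rhat_ij)`. The radial
#' basis is the enveloped Bessel basis of [cutoff_basis()] (shared with the
#' tuple route, which is all the correspondence tests require).
#'
#' @param system An [atomic_system()].
#' @param center Center atom index.
#' @param basis A [radial_basis_spec()] (its `r_cut` defines the
#'   neighborhood).
#' @param ell_max Maximum rotation order.
#' @param species Character vector fixing the species-channel order
#'   (default: the system's unique species).
#' @return Object of class `"ace_density"`: list `A` over `l = 0..ell_max` of
#'   `(S*n_basis) x (2l+1)` matrices (channel index runs species-major), plus
#'   the channel bookkeeping.
#' @export
ace_A <- function(system, center, basis, ell_max, species = NULL) {
  species <- species %||% unique(system$species)
  smap <- species_map(species)
  nl <- build_neighbor_list(system, basis$r_cut)
  sel <- which(nl$i == center)
  S <- length(species); nb <- basis$n_basis
  chan <- expand.grid(n = seq_len(nb), z = seq_len(S))[, c(2L, 1L)]
  A <- lapply(0:ell_max, function(l) matrix(0, S * nb, 2L * l + 1L))
  if (length(sel)) {
    r <- nl$r[sel]
    rhat <- nl$rvec[sel, , drop = FALSE] / r
    R <- cutoff_basis(r, basis)              # k x nb
    zc <- species_codes(smap, system$species[nl$j[sel]])
    Y <- .rsh_eval(ell_max, rhat)            # list over l: k x (2l+1)
    for (l in 0:ell_max) for (k in seq_along(sel)) {
      rows <- (zc[k] - 1L) * nb + seq_len(nb)
      A[[l + 1L]][rows, ] <- A[[l + 1L]][rows, ] + outer(R[k, ], Y[[l + 1L]][k, ])
    }
  }
  structure(list(A = A, species = species, n_basis = nb, ell_max = ell_max,
                 chan = chan), class = "ace_density")
}

# contract a (2l1+1) vector with a (2l2+1) vector into (2lo+1)
.couple <- function(v1, v2, l1, l2, lo) {
  trip <- w3j_triplets(l1, l2, lo)
  out <- numeric(2L * lo + 1L)
  for (t in seq_len(nrow(trip)))
    out[trip[t, 3L]] <- out[trip[t, 3L]] + trip[t, 4L] * v1[trip[t, 1L]] * v2[trip[t, 2L]]
  out
}

.ace_chan_label <- function(dens, c, l) {
  sprintf("%s.n%d.l%d", dens$species[dens$chan$z[c]], dens$chan$n[c], l)
}

#' ACE body-ordered scalar descriptors
#'
#' `ace_B_density()` builds the descriptors `B^(nu)` of body order `nu + 1`
#' by iterated Wigner-coupled tensor products of the density projection `A`
#' (the "density trick" route); only scalar-output coupling paths are
#' retained. `ace_B_tuples()` computes the identical quantities by the
#' explicit sum over neighbor `nu`-tuples; the two agree by bilinearity and
#' serve as mutual oracles. Couplings are performed left-to-right;
#' descriptor names record the channel sequence and intermediate orders.
#'
#' @param dens An [ace_A()] result.
#' @param nu Correlation order (body order is `nu + 1`); `nu >= 1`.
#' @param ell_inter_max Cap on intermediate coupling orders (defaults to the
#'   density's `ell_max`).
#' @return Named numeric vector of scalar descriptors.
#' @export
ace_B_density <- function(dens, nu, ell_inter_max = dens$ell_max) {
  if (nu < 1L) .stopf("nu must be >= 1")
  nchan <- nrow(dens$chan)
  state <- list()
  for (c in seq_len(nchan)) for (l in 0:dens$ell_max) {
    state[[length(state) + 1L]] <-
      list(label = .ace_chan_label(dens, c, l), l = l,
           vec = dens$A[[l + 1L]][c, ])
  }
  for (alpha in seq_len(nu)[-1L]) {
    new_state <- list()
    for (st in state) for (c in seq_len(nchan)) for (l in 0:dens$ell_max) {
      hi <- if (alpha == nu) 0L else ell_inter_max
      if (abs(st$l - l) > hi) next
      for (lo in abs(st$l - l):min(st$l + l, hi)) {
        new_state[[length(new_state) + 1L]] <- list(
          label = sprintf("%s|%s>%d", st$label, .ace_chan_label(dens, c, l), lo),
          l = lo,
          vec = .couple(st$vec, dens$A[[l + 1L]][c, ], st$l, l, lo))
      }
    }
    state <- new_state
  }
  keep <- Filter(function(st) st$l == 0L, state)
  stats::setNames(vapply(keep, function(st) st$vec[1L], 0),
                  vapply(keep, `[[`, "", "label"))
}

#' @rdname ace_B_density
#' @param system,center,basis,ell_max,species As in [ace_A()].
#' @param budget Maximum number of neighbor tuples (error beyond).
#' @export
ace_B_tuples <- function(system, center, basis, ell_max, nu,
                         species = NULL, ell_inter_max = ell_max,
                         budget = 4096L) {
  if (nu < 1L) .stopf("nu must be >= 1")
  species <- species %||% unique(system$species)
  smap <- species_map(species)
  nl <- build_neighbor_list(system, basis$r_cut)
  sel <- which(nl$i == center)
  K <- length(sel)
  if (K^nu > budget)
    .stopf("tuple budget exceeded: %d^%d > %d", K, nu, budget)
  dens0 <- ace_A(system, center, basis, ell_max, species)  # for channel labels
  nchan <- nrow(dens0$chan); nb <- basis$n_basis
  r <- nl$r[sel]
  R <- cutoff_basis(r, basis)
  zc <- species_codes(smap, system$species[nl$j[sel]])
  Y <- .rsh_eval(ell_max, nl$rvec[sel, , drop = FALSE] / r)
  # single-neighbor term for channel c, order l, neighbor k
  term <- function(c, l, k) {
    if (dens0$chan$z[c] != zc[k]) return(numeric(2L * l + 1L))
    R[k, dens0$chan$n[c]] * Y[[l + 1L]][k, ]
  }
  acc <- new.env(parent = emptyenv())
  add <- function(label, val) {
    cur <- if (!is.null(acc[[label]])) acc[[label]] else 0
    acc[[label]] <- cur + val
  }
  recurse <- function(alpha, label, lcur, vec) {
    if (alpha > nu) {
      if (lcur == 0L) add(label, vec[1L])
      return(invisible())
    }
    for (c in seq_len(nchan)) for (l in 0:ell_max) for (k in seq_len(K)) {
      tv <- term(c, l, k)
      if (alpha == 1L) {
        recurse(alpha + 1L, .ace_chan_label(dens0, c, l), l, tv)
      } else {
        hi <- if (alpha == nu) 0L else ell_inter_max
        if (abs(lcur - l) > hi) next
        for (lo in abs(lcur - l):min(lcur + l, hi)) {
          recurse(alpha + 1L,
                  sprintf("%s|%s>%d", label, .ace_chan_label(dens0, c, l), lo),
                  lo, .couple(vec, tv, lcur, l, lo))
        }
      }
    }
  }
  if (K > 0L) recurse(1L, "", 0L, 1) else return(stats::setNames(numeric(0), character(0)))
  nm <- ls(acc)
  stats::setNames(vapply(nm, function(x) acc[[x]], 0), nm)
}

# ---- expansion of the model's layer recursion ------------------------------

# plain-vector helpers on channel-fastest blocks (single edge)
.vec_tp <- function(v1, v2, l1, l2, lo, neq) {
  trip <- w3j_triplets(l1, l2, lo)
  out <- numeric((2L * lo + 1L) * neq)
  cols <- function(m) ((m - 1L) * neq + 1L):(m * neq)
  for (t in seq_len(nrow(trip)))
    out[cols(trip[t, 3L])] <- out[cols(trip[t, 3L])] +
      trip[t, 4L] * v1[cols(trip[t, 1L])] * v2[cols(trip[t, 2L])]
  out
}

#' Explicit neighbor-tuple expansion of the equivariant features
#'
#' Evaluates the layer recursion's equivariant output `V^{ij,L}` as the
#' explicit sum over neighbor tuples `(k_1, ..., k_L)` of iterated tensor
#' products of spherical harmonics, using the environment-embedding weights
#' and mixing matrices the model itself computes. This is the brute-force
#' oracle for the recursion: the result must match the recursively computed
#' features. Budgeted: requires `L <= 2` and at most `max_neighbors`
#' neighbors.
#'
#' @param model An [allegro_model()].
#' @param system An [atomic_system()].
#' @param i,j Center and neighbor atom index of the ordered pair.
#' @param L Layer whose output to expand (`1 <= L <= n_layers - 1`, since
#'   the recursion only materializes mixed equivariant features below the
#'   final layer).
#' @param max_neighbors Tuple budget (error beyond).
#' @return List with `expanded` (list of per-irrep numeric vectors,
#'   channel-fastest) and `recursive` (the model's own features for the same
#'   pair, same layout).
#' @export
allegro_expand <- function(model, system, i, j, L, max_neighbors = 4L) {
  cfg <- model$config
  if (L > 2L) .stopf("expansion budget: L <= 2")
  if (L >= cfg$n_layers)
    .stopf("L must be < n_layers (mixed equivariant features)")
  neq <- cfg$n_equivariant
  smap <- species_map(cfg$species)
  codes <- species_codes(smap, system$species)
  nl <- build_neighbor_list(system, cfg$r_cut)
  n <- n_atoms(system)
  fw <- .forward(model, codes, rep(1L, n), 1L, nl$i, nl$j, nl$rvec, keep = TRUE)
  inter <- fw$intermediates
  env_edges <- which(nl$i == i)
  if (length(env_edges) > max_neighbors)
    .stopf("tuple budget: %d neighbors > %d", length(env_edges), max_neighbors)
  e0 <- which(nl$i == i & nl$j == j)[1L]
  if (is.na(e0)) .stopf("(%d, %d) is not a pair within the cutoff", i, j)
  plan <- model$plan
  lmax <- cfg$ell_max
  Y <- lapply(0:lmax, function(l) .sph_poly_eval(l, nl$rvec)$Y)
  inv_sqrt_nn <- 1 / sqrt(max(cfg$avg_num_neighbors, 1e-12))
  # single-edge environment term for layer Lyr, edge e, harmonic block b:
  # w_{n,b} Y_b(e) / sqrt(<N>), with the first layer's channel mixing folded in
  env_term <- function(Lyr, e, b) {
    w <- inter$layers[[Lyr]]$w[e, ((b - 1L) * neq + 1L):(b * neq)]
    out <- as.vector(outer(w, Y[[b]][e, ]))  # channel-fastest
    out <- out * inv_sqrt_nn
    if (Lyr == 1L) {
      W <- model$params[[sprintf("env_linear.%d", b)]]
      m <- matrix(out, neq)                  # neq x (2l+1)
      out <- as.vector(t(W) %*% m) / sqrt(neq)
    }
    out
  }
  v0 <- lapply(seq_len(plan$nY), function(b) {
    w <- inter$w0[e0, ((b - 1L) * neq + 1L):(b * neq)]
    as.vector(outer(w, Y[[b]][e0, ]))
  })
  # one recursion step on a single tuple: V_in (blocks over vin irreps) with
  # env term of edge ek at layer Lyr; mixing applied
  step <- function(Lyr, Vin, ek) {
    lay <- plan$layers[[Lyr]]
    paths <- lay$paths
    Tp <- vector("list", nrow(paths))
    for (p in seq_len(nrow(paths))) {
      if (!paths$retained[p]) next
      Tp[[p]] <- .vec_tp(Vin[[paths$i1[p]]], env_term(Lyr, ek, paths$i2[p]),
                         paths$l1[p], paths$l2[p], paths$l_out[p], neq)
    }
    oi <- lay$out_irreps
    lapply(seq_len(nrow(oi)), function(r2) {
      sel <- which(paths$retained & paths$l_out == oi$l_out[r2] &
                     paths$p_out == oi$p_out[r2])
      W <- model$params[[sprintf("mix.L%d.%d", Lyr, r2)]]
      dm <- 2L * oi$l_out[r2] + 1L
      out <- numeric(dm * neq)
      for (m in seq_len(dm)) {
        stacked <- unlist(lapply(Tp[sel], function(t)
          t[((m - 1L) * neq + 1L):(m * neq)]))
        out[((m - 1L) * neq + 1L):(m * neq)] <-
          as.vector(stacked %*% W) / sqrt(length(sel) * neq)
      }
      out
    })
  }
  zero_like <- function(blocks) lapply(blocks, function(b) 0 * b)
  sum_blocks <- function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE)
  expand_rec <- function(Lyr, Vin) {
    # sum over the layer-Lyr tuple index
    acc <- NULL
    for (ek in env_edges) {
      contrib <- step(Lyr, Vin, ek)
      contrib <- if (Lyr == L) contrib else expand_rec(Lyr + 1L, contrib)
      acc <- if (is.null(acc)) contrib else sum_blocks(acc, contrib)
    }
    acc
  }
  expanded <- expand_rec(1L, v0)
  recursive <- lapply(inter$layers[[L]]$V, function(m) m[e0, ])
  list(expanded = expanded, recursive = recursive)
}

#' Polynomial body-order probe
#'
#' Scales the contribution of every environment atom other than the paired
#' neighbor by a factor `t` and examines the pair energy `E_ij(t)`. If the
#' embedding and latent MLPs are linear, the expanded features — and hence
#' `E_ij(t)` — are polynomials in `t` of bounded degree (`2^L - 1` for `L`
#' layers under this probe), evidencing finite body order; a nonlinear
#' latent MLP leaves a non-polynomial residual at every tested degree.
#' Nonlinearities in the two-body MLP do not affect the body order and are
#' allowed.
#'
#' @param model An [allegro_model()].
#' @param system An [atomic_system()].
#' @param i,j Ordered pair to probe.
#' @param degrees Polynomial degrees to try.
#' @param t_grid Scaling factors at which `E_ij(t)` is evaluated. The default
#'   extends well beyond 1 because a wide scaling range is what separates an
#'   exact polynomial (residual at machine precision for some degree) from a
#'   merely well-approximated smooth response.
#' @param tol Relative RMS residual below which a degree counts as an exact
#'   polynomial fit.
#' @return List with `values` (data.frame `t`, `e_pair`), `fits`
#'   (data.frame `degree`, `residual` — relative RMS), `degree` (smallest
#'   adequate degree, or `NA` if none fits), and `polynomial` (logical).
#' @export
body_order_probe <- function(model, system, i, j, degrees = 0:6,
                             t_grid = seq(0, 4, length.out = 40L),
                             tol = 1e-11) {
  cfg <- model$config
  smap <- species_map(cfg$species)
  codes <- species_codes(smap, system$species)
  nl <- build_neighbor_list(system, cfg$r_cut)
  n <- n_atoms(system)
  e0 <- which(nl$i == i & nl$j == j)[1L]
  if (is.na(e0)) .stopf("(%d, %d) is not a pair within the cutoff", i, j)
  ep <- vapply(t_grid, function(t) {
    fw <- .forward(model, codes, rep(1L, n), 1L, nl$i, nl$j, nl$rvec,
                   env_scale = t)
    as.numeric(nd_val(fw$e_pair))[e0]
  }, 0)
  sdy <- stats::sd(ep)
  fits <- data.frame(degree = degrees, residual = NA_real_)
  for (k in seq_along(degrees)) {
    d <- degrees[k]
    X <- outer(t_grid / max(t_grid), 0:d, `^`)  # scaled for conditioning
    res <- ep - X %*% qr.solve(X, ep)
    fits$residual[k] <- sqrt(mean(res^2)) / max(sdy, 1e-300)
  }
  ok <- fits$degree[fits$residual < tol]
  list(values = data.frame(t = t_grid, e_pair = ep), fits = fits,
       degree = if (length(ok)) min(ok) else NA_integer_,
       polynomial = length(ok) > 0L)
}
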