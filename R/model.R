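# The strictly local equivariant pair-energy model.
#
# Architecture per ordered pair (i, j) within the cutoff:
#   x0  = MLP_two_body(1Hot(Zi) || 1Hot(Zj) || B(r_ij)) * u(r_ij)
#   V0  = (W_embed0 x0)_{n,l,p} * Y_{l,p}(rhat_ij)
#   per layer L = 1..N:
#     w_ik = W_embedL x^{ik,L-1}                      (environment weights)
#     A_i  = sum_k w_ik Y(rhat_ik) / sqrt(<N>)        (embedded environment;
#            channel-mixed by a per-irrep linear at the first layer)
#     T    = V^{ij,L-1} (x) A_i  over all allowed paths with l_out <= l_max
#     x^L  = (x^{L-1} + MLP_latentL(x^{L-1} || T_scalars) * u(r_ij)) / sqrt(2)
#     V^L  = per-irrep learned linear mix over (path, channel)   [not at last layer]
#   E_ij = MLP_output(x^N)
#   E_i  = sum_j sigma_{ZiZj} E_ij / sqrt(<N>);  E = sum_i sigma_Zi E_i + mu_Zi
# All linear maps are bias-free and scale by 1/sqrt(fan-in); weights are
# initialized from a uniform distribution of unit variance. Forces are exact
# reverse-mode gradients: F_a = -dE/dr_a.

#' Model configuration
#'
#' Complete architectural hyperparameters of the pair-energy network;
#' sufficient (with a seed) to reconstruct the model and its parameter count
#' exactly.
#'
#' @param species Character vector of chemical symbols (fixes the one-hot
#'   encoding order).
#' @param r_cut Radial cutoff (Angstrom).
#' @param n_layers Number of tensor-product layers (>= 1).
#' @param ell_max Maximum rotation order of internal features.
#' @param n_equivariant Channels per irrep in the equivariant track.
#' @param two_body_hidden Hidden widths of the two-body MLP; the last entry
#'   is the scalar latent width.
#' @param latent_hidden Hidden widths of the per-layer latent MLP; the last
#'   entry must equal the scalar latent width (residual update).
#' @param output_hidden Hidden widths of the output MLP (final output is 1).
#' @param parity `"E3"` (track parities) or `"SE3"` (parity index unset).
#' @param latent_nonlin `"silu"` or `"linear"` (the two-body MLP always uses
#'   SiLU on hidden outputs; embedding projections are always linear).
#' @param output_nonlin `"linear"` (default) or `"silu"`.
#' @param n_basis,envelope_p Radial basis size and envelope exponent.
#' @param trainable_basis Whether Bessel frequencies are trainable.
#' @param avg_num_neighbors Neighbor-sum normalization constant `<N>`
#'   (set from the training data via [average_neighbor_count()]).
#' @param mu,sigma Per-species energy shift/scale (eV); recycled to the
#'   number of species.
#' @param sigma_pair Optional S x S per-species-pair scale (default all 1,
#'   non-trainable).
#' @param trainable_shift Whether `mu` is a trainable parameter (used by the
#'   variable-composition presets).
#' @param path_mode `"all_allowed"` (default) or `"restricted"`.
#' @return An object of class `"allegro_config"`.
#' @export
allegro_config <- function(species, r_cut, n_layers = 1L, ell_max = 1L,
                           n_equivariant = 1L,
                           two_body_hidden = c(32L, 64L),
                           latent_hidden = 64L,
                           output_hidden = 32L,
                           parity = c("E3", "SE3"),
                           latent_nonlin = c("silu", "linear"),
                           output_nonlin = c("linear", "silu"),
                           n_basis = 8L, envelope_p = 6,
                           trainable_basis = FALSE,
                           avg_num_neighbors = 1,
                           mu = 0, sigma = 1, sigma_pair = NULL,
                           trainable_shift = FALSE,
                           path_mode = c("all_allowed", "restricted")) {
  parity <- match.arg(parity)
  latent_nonlin <- match.arg(latent_nonlin)
  output_nonlin <- match.arg(output_nonlin)
  path_mode <- match.arg(path_mode)
  species <- as.character(species)
  S <- length(species)
  if (S < 1L) .stopf("need at least one species")
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) .stopf("n_layers must be >= 1")
  if (ell_max < 0L) .stopf("ell_max must be >= 0")
  two_body_hidden <- as.integer(two_body_hidden)
  latent_hidden <- as.integer(latent_hidden)
  output_hidden <- as.integer(output_hidden)
  if (any(c(two_body_hidden, latent_hidden, output_hidden, n_equivariant) < 1L))
    .stopf("all widths must be >= 1")
  latent <- two_body_hidden[length(two_body_hidden)]
  if (latent_hidden[length(latent_hidden)] != latent)
    .stopf("latent MLP output width must equal the scalar latent width (%d)", latent)
  mu <- rep(as.numeric(mu), length.out = S)
  sigma <- rep(as.numeric(sigma), length.out = S)
  if (any(sigma <= 0)) .stopf("sigma must be > 0")
  if (is.null(sigma_pair)) sigma_pair <- matrix(1, S, S)
  sigma_pair <- matrix(as.numeric(sigma_pair), S, S)
  structure(list(
    species = species, r_cut = as.numeric(r_cut),
    n_layers = n_layers, ell_max = as.integer(ell_max),
    n_equivariant = as.integer(n_equivariant),
    two_body_hidden = two_body_hidden, latent_hidden = latent_hidden,
    output_hidden = output_hidden, parity = parity,
    latent_nonlin = latent_nonlin, output_nonlin = output_nonlin,
    radial = radial_basis_spec(n_basis, r_cut, envelope_p, trainable_basis),
    avg_num_neighbors = as.numeric(avg_num_neighbors),
    mu = mu, sigma = sigma, sigma_pair = sigma_pair,
    trainable_shift = isTRUE(trainable_shift),
    path_mode = path_mode), class = "allegro_config")
}

# irreps reachable from (0, even) by k inverse couplings with the harmonic
# irreps (used to prune layer outputs that cannot contribute to the energy)
.reachable <- function(ell_max, parity_mode, k) {
  if (k == 0L) return(data.frame(ell = 0L, parity = if (parity_mode == "E3") 1L else 0L))
  prev <- .reachable(ell_max, parity_mode, k - 1L)
  ps <- if (parity_mode == "E3") c(1L, -1L) else 0L
  out <- expand.grid(ell = 0:ell_max, parity = ps)
  keep <- logical(nrow(out))
  for (r in seq_len(nrow(out))) {
    for (l2 in 0:ell_max) {
      p2 <- if (parity_mode == "E3") (-1L)^l2 else 0L
      lo <- abs(out$ell[r] - l2):min(out$ell[r] + l2, ell_max)
      po <- if (parity_mode == "E3") out$parity[r] * p2 else 0L
      if (any(mapply(function(l) any(prev$ell == l & prev$parity == po), lo)))
        keep[r] <- TRUE
    }
  }
  out[keep, , drop = FALSE]
}

# Full architectural plan: per-layer irreps, paths, and parameter shapes.
.model_plan <- function(cfg) {
  lmax <- cfg$ell_max
  neq <- cfg$n_equivariant
  S <- length(cfg$species)
  latent <- cfg$two_body_hidden[length(cfg$two_body_hidden)]
  pY <- if (cfg$parity == "E3") (-1L)^(0:lmax) else rep(0L, lmax + 1L)
  layY <- irrep_layout(rep(neq, lmax + 1L), 0:lmax, pY)
  nY <- lmax + 1L
  shapes <- list()
  dims <- c(2L * S + cfg$radial$n_basis, cfg$two_body_hidden)
  for (k in seq_len(length(dims) - 1L))
    shapes[[sprintf("two_body.W%d", k)]] <- c(dims[k], dims[k + 1L])
  for (L in 0:cfg$n_layers)
    shapes[[sprintf("embed.L%d", L)]] <- c(latent, neq * nY)
  for (b in seq_len(nY))
    shapes[[sprintf("env_linear.%d", b)]] <- c(neq, neq)
  layers <- vector("list", cfg$n_layers)
  vin <- layY
  for (L in seq_len(cfg$n_layers)) {
    paths <- enumerate_paths(vin, layY, lmax, cfg$path_mode)
    paths$scalar <- paths$l_out == 0L & paths$p_out %in% c(0L, 1L)
    if (L < cfg$n_layers) {
      reach <- .reachable(lmax, cfg$parity, cfg$n_layers - L)
      paths$retained <- mapply(function(l, p) any(reach$ell == l & reach$parity == p),
                               paths$l_out, paths$p_out)
    } else {
      paths$retained <- paths$scalar
    }
    n_scalar <- sum(paths$scalar)
    dims <- c(latent + n_scalar * neq, cfg$latent_hidden)
    for (k in seq_len(length(dims) - 1L))
      shapes[[sprintf("latent.L%d.W%d", L, k)]] <- c(dims[k], dims[k + 1L])
    out_irreps <- NULL
    if (L < cfg$n_layers) {
      kept <- paths[paths$retained, , drop = FALSE]
      out_irreps <- unique(kept[, c("l_out", "p_out")])
      out_irreps <- out_irreps[order(out_irreps$l_out, out_irreps$p_out), , drop = FALSE]
      for (r in seq_len(nrow(out_irreps))) {
        np <- sum(kept$l_out == out_irreps$l_out[r] & kept$p_out == out_irreps$p_out[r])
        shapes[[sprintf("mix.L%d.%d", L, r)]] <- c(np * neq, neq)
      }
    }
    layers[[L]] <- list(vin = vin, paths = paths, n_scalar = n_scalar,
                        out_irreps = out_irreps)
    if (L < cfg$n_layers)
      vin <- irrep_layout(rep(neq, nrow(out_irreps)), out_irreps$l_out,
                          out_irreps$p_out)
  }
  dims <- c(latent, cfg$output_hidden, 1L)
  for (k in seq_len(length(dims) - 1L))
    shapes[[sprintf("output.W%d", k)]] <- c(dims[k], dims[k + 1L])
  if (cfg$radial$trainable)
    shapes[["basis.freq"]] <- c(cfg$radial$n_basis, 1L)
  if (cfg$trainable_shift)
    shapes[["shift"]] <- c(S, 1L)
  list(layY = layY, nY = nY, latent = latent, layers = layers, shapes = shapes)
}

#' Count trainable parameters
#'
#' Constructs the model's parameter shapes from a configuration and counts
#' all trainable scalars, with an itemized per-component breakdown so that
#' any mismatch against an expected total can be localized.
#'
#' @param config An [allegro_config()].
#' @return Integer total; attribute `"breakdown"` holds a data.frame with
#'   one row per parameter tensor (`name`, `rows`, `cols`, `count`).
#' @examples
#' cfg <- allegro_preset("li3po4")
#' count_parameters(cfg)  # 9058
#' @export
count_parameters <- function(config) {
  plan <- .model_plan(config)
  nm <- names(plan$shapes)
  bd <- data.frame(name = nm,
                   rows = vapply(plan$shapes, `[`, 0L, 1L),
                   cols = vapply(plan$shapes, `[`, 0L, 2L),
                   row.names = NULL)
  bd$count <- bd$rows * bd$cols
  total <- sum(bd$count)
  structure(total, breakdown = bd)
}

#' Construct a model with freshly initialized weights
#'
#' All weight matrices are drawn from the uniform distribution with unit
#' variance (`U(-sqrt(3), sqrt(3))`); forward passes scale every linear map
#' by `1/sqrt(fan-in)` so activations stay O(1). Construction is
#' deterministic given the seed.
#'
#' @param config An [allegro_config()].
#' @param seed Integer RNG seed recorded in the model.
#' @return An object of class `"allegro_model"`.
#' @export
allegro_model <- function(config, seed = 1L) {
  plan <- .model_plan(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  params <- list()
  for (nm in names(plan$shapes)) {
    sh <- plan$shapes[[nm]]
    params[[nm]] <- if (nm == "basis.freq") {
      matrix(seq_len(sh[1L]) * pi, sh[1L], 1L)
    } else if (nm == "shift") {
      matrix(config$mu, sh[1L], 1L)
    } else {
      matrix(stats::runif(prod(sh), -sqrt(3), sqrt(3)), sh[1L], sh[2L])
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  structure(list(config = config, plan = plan, params = params, seed = seed),
            class = "allegro_model")
}

#' @export
print.allegro_model <- function(x, ...) {
  cat("<allegro_model ", x$config$n_layers, " layer(s), l_max=",
      x$config$ell_max, ", ", x$config$parity, ", ",
      sum(vapply(x$params, length, 0L)), " parameters>\n", sep = "")
  invisible(x)
}

.nonlin <- function(tape, h, kind) if (kind == "silu") nd_silu(tape, h) else h

.mlp <- function(tape, h, weights, nonlin) {
  for (k in seq_along(weights)) {
    h <- nd_scale(tape, nd_matmul(tape, h, weights[[k]]),
                  1 / sqrt(nrow(nd_val(weights[[k]]))))
    if (k < length(weights)) h <- .nonlin(tape, h, nonlin)
  }
  h
}

# Batched forward pass over the directed edges of one or more systems.
# edges: list(i, j (global atom indices), rvec (E x 3)), atoms: codes, frame
# index per atom. Returns tape + nodes of interest.
.forward <- function(model, codes, frame_of_atom, n_frames, edge_i, edge_j,
                     rvec_init, complex_step = NULL, env_scale = 1,
                     keep = FALSE) {
  cfg <- model$config; plan <- model$plan
  neq <- cfg$n_equivariant
  S <- length(cfg$species)
  tape <- tape_new()
  P <- lapply(model$params, function(m) nd_leaf(tape, m))
  rvec_val <- rvec_init
  if (!is.null(complex_step)) rvec_val <- rvec_val + 1i * complex_step
  rvec <- nd_leaf(tape, rvec_val)
  n_atom <- length(codes)
  E <- nrow(rvec_val)
  r <- nd_norm3(tape, rvec)
  u <- nd_envelope(tape, r, cfg$radial)
  freq <- if (cfg$radial$trainable) P[["basis.freq"]] else NULL
  B <- nd_radial(tape, r, cfg$radial, freq)
  onehot <- cbind(diag(S)[codes[edge_i], , drop = FALSE],
                  diag(S)[codes[edge_j], , drop = FALSE])
  tb_w <- P[grep("^two_body\\.", names(P))]
  x <- nd_mulvec(tape, .mlp(tape, nd_cbind(tape, onehot, B), tb_w, "silu"), u)
  latent <- plan$latent
  Yb <- lapply(0:cfg$ell_max, function(l) nd_sph(tape, rvec, l))
  embed_cols <- function(b) ((b - 1L) * neq + 1L):(b * neq)
  w0 <- .mlp(tape, x, P["embed.L0"], "linear")
  V <- lapply(seq_len(plan$nY), function(b)
    nd_chanouter(tape, nd_cols(tape, w0, embed_cols(b)), Yb[[b]], neq))
  inv_sqrt_nn <- 1 / sqrt(max(cfg$avg_num_neighbors, 1e-12))
  inter <- if (keep) list(w0 = nd_val(w0), layers = list()) else NULL
  for (L in seq_len(cfg$n_layers)) {
    lay <- plan$layers[[L]]
    wL <- .mlp(tape, x, P[sprintf("embed.L%d", L)], "linear")
    Aedge <- vector("list", plan$nY)
    for (b in seq_len(plan$nY)) {
      contrib <- nd_chanouter(tape, nd_cols(tape, wL, embed_cols(b)), Yb[[b]], neq)
      A <- nd_scale(tape, nd_rowsum_by(tape, contrib, edge_i, n_atom), inv_sqrt_nn)
      lin <- function(z) {
        if (L == 1L)
          z <- nd_scale(tape, nd_blockmm(tape, z, P[[sprintf("env_linear.%d", b)]],
                                         2L * (b - 1L) + 1L), 1 / sqrt(neq))
        z
      }
      A <- lin(A)
      Ae <- nd_rows(tape, A, edge_i)
      if (env_scale != 1) {
        # scale the contribution of every environment atom except the paired
        # neighbor itself (the k = j term), so env_scale = 0 reduces each
        # pair to its isolated-dimer featurization
        self <- lin(nd_scale(tape, contrib, inv_sqrt_nn))
        Ae <- nd_add(tape, nd_scale(tape, self, 1 - env_scale),
                     nd_scale(tape, Ae, env_scale))
      }
      Aedge[[b]] <- Ae
    }
    paths <- lay$paths
    Tp <- vector("list", nrow(paths))
    for (p in seq_len(nrow(paths))) {
      if (!paths$retained[p] && !paths$scalar[p]) next
      Tp[[p]] <- nd_tp(tape, V[[paths$i1[p]]], Aedge[[paths$i2[p]]],
                       paths$l1[p], paths$l2[p], paths$l_out[p], neq)
    }
    sc <- which(paths$scalar)
    xin <- do.call(nd_cbind, c(list(tape, x), Tp[sc]))
    lat_w <- P[sprintf("latent.L%d.W%d", L, seq_along(cfg$latent_hidden))]
    xnew <- nd_mulvec(tape, .mlp(tape, xin, lat_w, cfg$latent_nonlin), u)
    x <- nd_scale(tape, nd_add(tape, x, xnew), 1 / sqrt(2))
    if (L < cfg$n_layers) {
      oi <- lay$out_irreps
      Vnew <- vector("list", nrow(oi))
      for (r2 in seq_len(nrow(oi))) {
        sel <- which(paths$retained & paths$l_out == oi$l_out[r2] &
                       paths$p_out == oi$p_out[r2])
        W <- P[[sprintf("mix.L%d.%d", L, r2)]]
        dm <- 2L * oi$l_out[r2] + 1L
        mcols <- function(m) ((m - 1L) * neq + 1L):(m * neq)
        per_m <- lapply(seq_len(dm), function(m) {
          stacked <- do.call(nd_cbind, c(list(tape),
                                         lapply(Tp[sel], function(t) nd_cols(tape, t, mcols(m)))))
          nd_scale(tape, nd_matmul(tape, stacked, W), 1 / sqrt(length(sel) * neq))
        })
        Vnew[[r2]] <- do.call(nd_cbind, c(list(tape), per_m))
      }
      V <- Vnew
    }
    if (keep)
      inter$layers[[L]] <- list(w = nd_val(wL), x = nd_val(x),
                                V = lapply(V, nd_val),
                                A = lapply(Aedge, nd_val))
  }
  out_w <- P[sprintf("output.W%d", seq_len(length(cfg$output_hidden) + 1L))]
  e_pair <- .mlp(tape, x, out_w, cfg$output_nonlin)
  sp <- cfg$sigma_pair[cbind(codes[edge_i], codes[edge_j])]
  e_atom_sum <- nd_scale(tape, nd_rowsum_by(tape, nd_mulvec(tape, e_pair, sp),
                                            edge_i, n_atom), inv_sqrt_nn)
  scaled <- nd_mulvec(tape, e_atom_sum, cfg$sigma[codes])
  if (cfg$trainable_shift) {
    scaled <- nd_add(tape, scaled, nd_rows(tape, P[["shift"]], codes))
    mu_atom <- rep(0, n_atom)
  } else {
    mu_atom <- cfg$mu[codes]
  }
  e_frame <- nd_add(tape, nd_rowsum_by(tape, scaled, frame_of_atom, n_frames),
                    matrix(.rowsum_by(matrix(mu_atom), frame_of_atom, n_frames),
                           n_frames, 1L))
  list(tape = tape, params = P, rvec = rvec, e_pair = e_pair,
       e_atom = e_atom_sum, e_frame = e_frame, intermediates = inter)
}

# forces from the rvec gradient: F_a = sum_{e: i=a} g_e - sum_{e: j=a} g_e
.forces_from_rvec_grad <- function(g, edge_i, edge_j, n_atom) {
  .rowsum_by(g, edge_i, n_atom) - .rowsum_by(g, edge_j, n_atom)
}

#' Predict energy, pairwise decomposition, and forces
#'
#' Runs the model on one configuration and returns the full energy breakdown
#' with forces computed as the exact negative gradient of the total energy
#' (reverse-mode differentiation through the whole network).
#'
#' @param model An [allegro_model()].
#' @param system An [atomic_system()].
#' @return List with `e_system` (eV), `e_atom` (per-atom energies including
#'   shift, eV), `e_pair` (per directed pair, eV), `pairs` (i, j indices),
#'   and `forces` (N x 3, eV/Angstrom).
#' @export
predict_energy_forces <- function(model, system) {
  cfg <- model$config
  codes <- species_codes(species_map(cfg$species), system$species)
  nl <- build_neighbor_list(system, cfg$r_cut)
  n <- n_atoms(system)
  if (length(nl$i) == 0L) {
    mu <- if (cfg$trainable_shift) model$params[["shift"]][codes, 1L] else cfg$mu[codes]
    return(list(e_system = sum(mu), e_atom = mu,
                e_pair = numeric(0), pairs = cbind(i = integer(0), j = integer(0)),
                forces = matrix(0, n, 3L)))
  }
  fw <- .forward(model, codes, rep(1L, n), 1L, nl$i, nl$j, nl$rvec)
  tape_backward(fw$tape, fw$e_frame, 1)
  g <- fw$rvec$grad
  mu <- if (cfg$trainable_shift) model$params[["shift"]][codes, 1L] else cfg$mu[codes]
  list(e_system = as.numeric(nd_val(fw$e_frame)),
       e_atom = cfg$sigma[codes] * as.numeric(nd_val(fw$e_atom)) + mu,
       e_pair = as.numeric(nd_val(fw$e_pair)),
       pairs = cbind(i = nl$i, j = nl$j),
       forces = .forces_from_rvec_grad(g, nl$i, nl$j, n))
}

#' Pair energies E_ij of one configuration
#'
#' @inheritParams predict_energy_forces
#' @return data.frame with columns `i`, `j`, `r`, `e_pair` (eV). The pair
#'   energies are direction-dependent: `E_ij != E_ji` in general.
#' @export
pair_energies <- function(model, system) {
  pr <- predict_energy_forces(model, system)
  nl <- build_neighbor_list(system, model$config$r_cut)
  data.frame(i = pr$pairs[, "i"], j = pr$pairs[, "j"], r = nl$r,
             e_pair = pr$e_pair)
}

# ---- presets ---------------------------------------------------------------

#' Published hyperparameter presets
#'
#' Architectural configurations matching the published training setups:
#' `"li3po4"` (1 layer, 1 even-parity feature channel, l_max 1, two-body MLP
#' 32-64, latent MLP 64, output hidden 32, 8 Bessel, p = 48, cutoff 4 A,
#' species Li/P/O), `"ag"` (as li3po4 but 16-32/32 MLPs, single species),
#' `"qm9_1layer"` (1 layer, l_max 3, 256 channels, two-body MLP
#' 128-256-512-1024, latent 1024x3, output hidden 128, p = 6, cutoff 10 A,
#' species H/C/N/O/F, trainable per-species shifts), and `"qm9_3layer"`
#' (3 layers, l_max 2, otherwise as the 1-layer QM9 model).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [allegro_config()].
#' @return An [allegro_config()].
#' @export
allegro_preset <- function(name = c("li3po4", "ag", "qm9_1layer", "qm9_3layer"),
                           ...) {
  name <- match.arg(name)
  args <- switch(name,
    li3po4 = list(species = c("Li", "P", "O"), r_cut = 4.0, n_layers = 1L,
                  ell_max = 1L, n_equivariant = 1L,
                  two_body_hidden = c(32L, 64L), latent_hidden = 64L,
                  output_hidden = 32L, envelope_p = 48),
    ag = list(species = "Ag", r_cut = 4.0, n_layers = 1L, ell_max = 1L,
              n_equivariant = 1L, two_body_hidden = c(16L, 32L),
              latent_hidden = 32L, output_hidden = 32L, envelope_p = 48),
    qm9_1layer = list(species = c("H", "C", "N", "O", "F"), r_cut = 10.0,
                      n_layers = 1L, ell_max = 3L, n_equivariant = 256L,
                      two_body_hidden = c(128L, 256L, 512L, 1024L),
                      latent_hidden = c(1024L, 1024L, 1024L),
                      output_hidden = 128L, envelope_p = 6,
                      trainable_shift = TRUE),
    qm9_3layer = list(species = c("H", "C", "N", "O", "F"), r_cut = 10.0,
                      n_layers = 3L, ell_max = 2L, n_equivariant = 256L,
                      two_body_hidden = c(128L, 256L, 512L, 1024L),
                      latent_hidden = c(1024L, 1024L, 1024L),
                      output_hidden = 128L, envelope_p = 6,
                      trainable_shift = TRUE))
  over <- list(...)
  args[names(over)] <- over
  do.call(allegro_config, args)
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are a documented JSON container holding the full
#' configuration, the flat parameter arrays (shape + column-major values at
#' full precision), and the construction seed.
#'
#' @param model An [allegro_model()].
#' @param path File path.
#' @return `path` (save) or the reconstructed model (load).
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  obj <- list(
    format = "allegror-checkpoint-1",
    seed = model$seed,
    config = list(
      species = cfg$species, r_cut = cfg$r_cut, n_layers = cfg$n_layers,
      ell_max = cfg$ell_max, n_equivariant = cfg$n_equivariant,
      two_body_hidden = cfg$two_body_hidden, latent_hidden = cfg$latent_hidden,
      output_hidden = cfg$output_hidden, parity = cfg$parity,
      latent_nonlin = cfg$latent_nonlin, output_nonlin = cfg$output_nonlin,
      n_basis = cfg$radial$n_basis, envelope_p = cfg$radial$envelope_p,
      trainable_basis = cfg$radial$trainable,
      avg_num_neighbors = cfg$avg_num_neighbors,
      mu = cfg$mu, sigma = cfg$sigma, sigma_pair = as.vector(cfg$sigma_pair),
      trainable_shift = cfg$trainable_shift, path_mode = cfg$path_mode),
    params = lapply(model$params, function(m)
      list(dim = dim(m), values = as.vector(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "allegror-checkpoint-1"))
    .stopf("not an allegror checkpoint: %s", path)
  cc <- obj$config
  S <- length(cc$species)
  cfg <- allegro_config(
    species = cc$species, r_cut = cc$r_cut, n_layers = cc$n_layers,
    ell_max = cc$ell_max, n_equivariant = cc$n_equivariant,
    two_body_hidden = cc$two_body_hidden, latent_hidden = cc$latent_hidden,
    output_hidden = cc$output_hidden, parity = cc$parity,
    latent_nonlin = cc$latent_nonlin, output_nonlin = cc$output_nonlin,
    n_basis = cc$n_basis, envelope_p = cc$envelope_p,
    trainable_basis = cc$trainable_basis,
    avg_num_neighbors = cc$avg_num_neighbors,
    mu = cc$mu, sigma = cc$sigma, sigma_pair = matrix(cc$sigma_pair, S, S),
    trainable_shift = cc$trainable_shift, path_mode = cc$path_mode)
  model <- allegro_model(cfg, seed = obj$seed)
  for (nm in names(obj$params))
    model$params[[nm]] <- matrix(obj$params[[nm]]$values,
                                 obj$params[[nm]]$dim[1L],
                                 obj$params[[nm]]$dim[2L])
  model
}
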