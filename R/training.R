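# Joint energy/force loss, target normalization, and the Adam training loop
# with on-plateau scheduling and an exponential moving average of the
# weights.
#
# The force term of the loss needs d/dtheta of the predicted forces, i.e. a
# mixed second derivative of the energy. It is obtained exactly (to machine
# precision) with a complex-step directional derivative: the forward+backward
# pass is re-run at positions displaced by i*h*v, where v is the
# force-residual direction, and the imaginary part of the parameter gradient
# divided by h is the required derivative. No second-order tape is needed.

#' Loss configuration
#'
#' `L = lambda_e/B * sum_b ((E_hat_b - E_b) / N_b^per_atom)^2
#'    + lambda_f/(3*N_tot) * sum |F_hat - F|^2`
#' where `B` is the number of frames in the batch and `N_tot` the total atom
#' count of the batch (per-batch means, not per-frame means). With
#' `per_atom = TRUE` the energy residual of each frame is divided by its atom
#' count before squaring.
#'
#' @param lambda_e,lambda_f Energy and force weights (>= 0, not both 0).
#' @param per_atom Use the per-atom energy MSE form.
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(lambda_e = 1, lambda_f = 1000, per_atom = FALSE) {
  if (lambda_e < 0 || lambda_f < 0 || (lambda_e == 0 && lambda_f == 0))
    .stopf("loss weights must be >= 0 and not both zero")
  structure(list(lambda_e = lambda_e, lambda_f = lambda_f,
                 per_atom = isTRUE(per_atom)), class = "loss_config")
}

#' Joint energy/force loss
#'
#' @param e_pred,e_ref Numeric vectors of predicted / reference total
#'   energies (eV), one per frame.
#' @param f_pred,f_ref Matrices of predicted / reference forces, frames
#'   concatenated row-wise (eV/Angstrom).
#' @param n_per_frame Integer vector of atom counts per frame.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
joint_loss <- function(e_pred, e_ref, f_pred, f_ref, n_per_frame, cfg) {
  B <- length(e_ref)
  if (length(e_pred) != B) .stopf("energy shape mismatch")
  de <- e_pred - e_ref
  if (cfg$per_atom) de <- de / n_per_frame
  loss <- cfg$lambda_e / B * sum(de^2)
  if (cfg$lambda_f > 0) {
    if (is.null(f_pred) || is.null(f_ref)) .stopf("force labels required")
    if (!all(dim(f_pred) == dim(f_ref))) .stopf("force shape mismatch")
    if (nrow(f_pred) != sum(n_per_frame)) .stopf("force/atom count mismatch")
    loss <- loss + cfg$lambda_f / (3 * sum(n_per_frame)) * sum((f_pred - f_ref)^2)
  }
  loss
}

#' Target normalization for fixed chemical composition
#'
#' Sets the per-species shift `mu_Z` (identical across species) to the mean
#' per-atom potential energy over all training frames, and the per-species
#' scale `sigma_Z` to the root-mean-square of the force components over the
#' training set. This keeps the potential size-extensive.
#'
#' @param dataset List of labelled [atomic_system()]s.
#' @param species Character vector of species the stats are reported for
#'   (default: all species present).
#' @return List (`NormStats`) with `mu`, `sigma` (named per species) and
#'   `avg_num_neighbors = NA` (set separately from a cutoff).
#' @export
fit_norm_fixed_composition <- function(dataset, species = NULL) {
  if (!length(dataset)) .stopf("empty dataset")
  if (any(vapply(dataset, function(s) is.null(s$energy), TRUE)))
    .stopf("all frames need energy labels")
  species <- species %||% unique(unlist(lapply(dataset, `[[`, "species")))
  mu <- mean(vapply(dataset, function(s) s$energy / n_atoms(s), 0))
  fcomp <- unlist(lapply(dataset, function(s) s$forces))
  if (is.null(fcomp)) .stopf("all frames need force labels")
  sigma <- sqrt(mean(fcomp^2))
  if (sigma <= 0) .stopf("degenerate force labels (all zero): sigma_Z undefined")
  list(mu = stats::setNames(rep(mu, length(species)), species),
       sigma = stats::setNames(rep(sigma, length(species)), species),
       avg_num_neighbors = NA_real_)
}

#' Target normalization by composition regression
#'
#' For variable chemical composition: solves the least-squares system
#' `[N_config,Z] mu = [E_config]` for per-species shifts `mu_Z`, where
#' `N_config,Z` counts atoms of each species per frame. Rank-deficient
#' composition matrices fall back to the pseudo-inverse (minimum-norm
#' solution) with a warning. `sigma_Z` is the force-component RMS as in
#' [fit_norm_fixed_composition()] (or 1 if no forces are present).
#'
#' @inheritParams fit_norm_fixed_composition
#' @return List (`NormStats`) as in [fit_norm_fixed_composition()].
#' @export
fit_norm_composition_regression <- function(dataset, species = NULL) {
  if (!length(dataset)) .stopf("empty dataset")
  if (any(vapply(dataset, function(s) is.null(s$energy), TRUE)))
    .stopf("all frames need energy labels")
  species <- species %||% unique(unlist(lapply(dataset, `[[`, "species")))
  counts <- t(vapply(dataset, function(s)
    vapply(species, function(z) sum(s$species == z), 0), numeric(length(species))))
  counts <- matrix(counts, ncol = length(species))
  e <- vapply(dataset, `[[`, 0, "energy")
  sv <- svd(counts)
  rank <- sum(sv$d > 1e-10 * max(sv$d))
  if (rank < length(species)) {
    warning("composition matrix is rank-deficient; using pseudo-inverse")
    dinv <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
    mu <- sv$v %*% (dinv * crossprod(sv$u, e))
  } else {
    mu <- qr.solve(counts, e)
  }
  fcomp <- unlist(lapply(dataset, function(s) s$forces))
  sigma <- if (is.null(fcomp)) 1 else sqrt(mean(fcomp^2))
  if (sigma <= 0) .stopf("degenerate force labels (all zero): sigma_Z undefined")
  list(mu = stats::setNames(as.numeric(mu), species),
       sigma = stats::setNames(rep(sigma, length(species)), species),
       avg_num_neighbors = NA_real_)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Frames per batch (`Inf` = full batch).
#' @param max_epochs Maximum number of epochs.
#' @param max_time Wall-time budget in seconds (`Inf` = none).
#' @param scheduler_patience Epochs without validation improvement before
#'   the learning rate is multiplied by `scheduler_factor`.
#' @param scheduler_factor On-plateau decay factor in (0, 1].
#' @param lr_floor Training stops when the learning rate drops below this.
#' @param stop_patience Epochs without validation improvement before early
#'   stop.
#' @param ema_decay Exponential-moving-average weight for evaluation and the
#'   final model.
#' @param val_fraction Fraction of frames held out for validation.
#' @param seed Seed for the train/validation split and per-epoch shuffling
#'   (epoch seeds are derived as `seed + epoch`).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.005, batch_size = Inf,
                         max_epochs = 200L, max_time = Inf,
                         scheduler_patience = 25L, scheduler_factor = 0.5,
                         lr_floor = 1e-5, stop_patience = 1000L,
                         ema_decay = 0.99, val_fraction = 0.1, seed = 1L) {
  if (learning_rate <= 0) .stopf("learning_rate must be > 0")
  if (scheduler_factor <= 0 || scheduler_factor > 1)
    .stopf("scheduler_factor must be in (0, 1]")
  if (ema_decay < 0 || ema_decay >= 1) .stopf("ema_decay must be in [0, 1)")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = as.integer(max_epochs), max_time = max_time,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_factor = scheduler_factor, lr_floor = lr_floor,
                 stop_patience = as.integer(stop_patience),
                 ema_decay = ema_decay, val_fraction = val_fraction,
                 seed = as.integer(seed)), class = "train_config")
}

# concatenated batch structure for a set of frames
.assemble_batch <- function(cfg, frames) {
  smap <- species_map(cfg$species)
  codes <- integer(0); frame_of_atom <- integer(0)
  edge_i <- integer(0); edge_j <- integer(0); rvec <- NULL
  e_ref <- numeric(length(frames)); n_per <- integer(length(frames))
  f_ref <- NULL; at0 <- 0L
  for (b in seq_along(frames)) {
    sys <- frames[[b]]
    n <- n_atoms(sys)
    nl <- build_neighbor_list(sys, cfg$r_cut)
    codes <- c(codes, species_codes(smap, sys$species))
    frame_of_atom <- c(frame_of_atom, rep(b, n))
    edge_i <- c(edge_i, nl$i + at0); edge_j <- c(edge_j, nl$j + at0)
    rvec <- rbind(rvec, nl$rvec)
    e_ref[b] <- sys$energy %||% NA_real_
    n_per[b] <- n
    f_ref <- rbind(f_ref, sys$forces %||% matrix(NA_real_, n, 3L))
    at0 <- at0 + n
  }
  list(codes = codes, frame_of_atom = frame_of_atom, n_frames = length(frames),
       edge_i = edge_i, edge_j = edge_j,
       rvec = rvec %||% matrix(0, 0L, 3L),
       e_ref = e_ref, f_ref = f_ref, n_per = n_per, n_atoms = at0)
}

# loss + exact parameter gradient on one assembled batch
.loss_and_grad <- function(model, batch, loss_cfg, want_grad = TRUE) {
  cfg <- model$config
  if (length(batch$edge_i) == 0L) {
    # no pairs anywhere in the batch: predictions reduce to the shifts
    mu <- if (cfg$trainable_shift) model$params[["shift"]][, 1L] else cfg$mu
    e_pred <- as.numeric(.rowsum_by(matrix(mu[batch$codes]),
                                    batch$frame_of_atom, batch$n_frames))
    f_pred <- matrix(0, batch$n_atoms, 3L)
    loss <- joint_loss(e_pred, batch$e_ref, f_pred, batch$f_ref, batch$n_per,
                       loss_cfg)
    if (!want_grad)
      return(list(loss = loss, e_pred = e_pred, f_pred = f_pred))
    grads <- lapply(model$params, function(p) 0 * p)
    if (cfg$trainable_shift) {
      de <- e_pred - batch$e_ref
      if (loss_cfg$per_atom) de <- de / batch$n_per^2
      ce <- 2 * loss_cfg$lambda_e / batch$n_frames * de
      for (b in seq_len(batch$n_frames)) {
        at <- which(batch$frame_of_atom == b)
        for (z in batch$codes[at])
          grads[["shift"]][z, 1L] <- grads[["shift"]][z, 1L] + ce[b]
      }
    }
    return(list(loss = loss, grad = grads, e_pred = e_pred, f_pred = f_pred))
  }
  fw <- .forward(model, batch$codes, batch$frame_of_atom, batch$n_frames,
                 batch$edge_i, batch$edge_j, batch$rvec)
  e_pred <- as.numeric(nd_val(fw$e_frame))
  tape_backward(fw$tape, fw$e_frame, matrix(1, batch$n_frames, 1L))
  g_rvec <- fw$rvec$grad
  f_pred <- .forces_from_rvec_grad(g_rvec, batch$edge_i, batch$edge_j,
                                   batch$n_atoms)
  loss <- joint_loss(e_pred, batch$e_ref, f_pred, batch$f_ref, batch$n_per,
                     loss_cfg)
  if (!want_grad)
    return(list(loss = loss, e_pred = e_pred, f_pred = f_pred))
  pnames <- names(model$params)
  # energy term: backward seeded with the per-frame residual coefficients
  de <- e_pred - batch$e_ref
  if (loss_cfg$per_atom) de <- de / batch$n_per^2
  ce <- 2 * loss_cfg$lambda_e / batch$n_frames * de
  tape_backward(fw$tape, fw$e_frame, matrix(ce, batch$n_frames, 1L))
  grads <- lapply(pnames, function(nm) {
    g <- fw$params[[nm]]$grad
    if (is.null(g)) 0 * model$params[[nm]] else g
  })
  names(grads) <- pnames
  # force term: complex-step directional derivative of the energy gradient
  if (loss_cfg$lambda_f > 0 && batch$n_atoms > 0 && length(batch$edge_i) > 0) {
    v <- 2 * loss_cfg$lambda_f / (3 * sum(batch$n_per)) *
      (f_pred - batch$f_ref)
    dir <- v[batch$edge_j, , drop = FALSE] - v[batch$edge_i, , drop = FALSE]
    h <- 1e-100
    fwc <- .forward(model, batch$codes, batch$frame_of_atom, batch$n_frames,
                    batch$edge_i, batch$edge_j, batch$rvec,
                    complex_step = h * dir)
    tape_backward(fwc$tape, fwc$e_frame, matrix(1, batch$n_frames, 1L))
    for (nm in pnames) {
      g <- fwc$params[[nm]]$grad
      if (!is.null(g)) grads[[nm]] <- grads[[nm]] - Im(g) / h
    }
  }
  list(loss = loss, grad = grads, e_pred = e_pred, f_pred = f_pred)
}

# evaluation metrics on a set of frames
.eval_metrics <- function(model, frames, loss_cfg) {
  batch <- .assemble_batch(model$config, frames)
  lg <- .loss_and_grad(model, batch, loss_cfg, want_grad = FALSE)
  list(loss = lg$loss,
       e_mae = mean(abs(lg$e_pred - batch$e_ref) / batch$n_per),
       f_mae = mean(abs(lg$f_pred - batch$f_ref)))
}

.with_params <- function(model, params) { model$params <- params; model }

#' Train a model
#'
#' Adam with the standard defaults (beta1 0.9, beta2 0.999, eps 1e-8, no
#' weight decay), per-epoch reshuffling with derived seeds, an on-plateau
#' learning-rate scheduler driven by the validation loss, and an exponential
#' moving average of the weights used for validation and for the returned
#' model. Training is deterministic in 64-bit arithmetic given the seed.
#'
#' @param model An [allegro_model()].
#' @param dataset List of labelled [atomic_system()]s.
#' @param tcfg A [train_config()].
#' @param lcfg A [loss_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (EMA weights), `raw_model` (last raw weights),
#'   and `log` (data.frame: epoch, lr, train_loss, val_loss, val_e_mae
#'   (eV/atom), val_f_mae (eV/A)).
#' @export
train <- function(model, dataset, tcfg = train_config(),
                  lcfg = loss_config(), verbose = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tcfg$seed)
  n <- length(dataset)
  if (n < 2L) .stopf("need at least 2 frames")
  n_val <- max(1L, round(tcfg$val_fraction * n))
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  train_idx <- idx[-seq_len(n_val)]
  pnames <- names(model$params)
  mom1 <- lapply(model$params, function(p) 0 * p)
  mom2 <- lapply(model$params, function(p) 0 * p)
  ema <- model$params
  lr <- tcfg$learning_rate
  best_val <- Inf; since_best <- 0L; since_decay <- 0L
  t0 <- Sys.time(); step <- 0L
  vm0 <- .eval_metrics(model, dataset[val_idx], lcfg)
  log <- data.frame(epoch = 0L, lr = lr, train_loss = NA_real_,
                    val_loss = vm0$loss, val_e_mae = vm0$e_mae,
                    val_f_mae = vm0$f_mae)
  for (epoch in seq_len(tcfg$max_epochs)) {
    set.seed(tcfg$seed + epoch)
    ord <- sample(train_idx)
    bs <- if (is.finite(tcfg$batch_size)) tcfg$batch_size else length(ord)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0
    for (bt in batches) {
      batch <- .assemble_batch(model$config, dataset[bt])
      lg <- .loss_and_grad(model, batch, lcfg)
      if (!is.finite(lg$loss))
        .stopf("loss diverged (non-finite) at epoch %d; last finite state kept in the returned model", epoch)
      step <- step + 1L
      for (nm in pnames) {
        g <- lg$grad[[nm]]
        mom1[[nm]] <- 0.9 * mom1[[nm]] + 0.1 * g
        mom2[[nm]] <- 0.999 * mom2[[nm]] + 0.001 * g^2
        m_hat <- mom1[[nm]] / (1 - 0.9^step)
        v_hat <- mom2[[nm]] / (1 - 0.999^step)
        model$params[[nm]] <- model$params[[nm]] -
          lr * m_hat / (sqrt(v_hat) + 1e-8)
        ema[[nm]] <- tcfg$ema_decay * ema[[nm]] +
          (1 - tcfg$ema_decay) * model$params[[nm]]
      }
      ep_loss <- ep_loss + lg$loss * length(bt)
    }
    ep_loss <- ep_loss / length(ord)
    vm <- .eval_metrics(.with_params(model, ema), dataset[val_idx], lcfg)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = ep_loss, val_loss = vm$loss,
                                 val_e_mae = vm$e_mae, val_f_mae = vm$f_mae))
    if (verbose)
      message(sprintf("epoch %4d lr %.2g train %.4g val %.4g f_mae %.4g",
                      epoch, lr, ep_loss, vm$loss, vm$f_mae))
    if (vm$loss < best_val - 1e-12) {
      best_val <- vm$loss; since_best <- 0L; since_decay <- 0L
    } else {
      since_best <- since_best + 1L; since_decay <- since_decay + 1L
    }
    if (since_decay >= tcfg$scheduler_patience) {
      lr <- lr * tcfg$scheduler_factor; since_decay <- 0L
    }
    if (lr < tcfg$lr_floor || since_best >= tcfg$stop_patience ||
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > tcfg$max_time)
      break
  }
  list(model = .with_params(model, ema), raw_model = model, log = log)
}
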