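# Loss functions, target normalization, and the optimization loop.

test_that("joint loss reproduces direct formula substitution", {
  cfg <- loss_config(lambda_e = 2, lambda_f = 5, per_atom = FALSE)
  # perfect predictions give zero
  f <- matrix(rnorm(6), 2)
  expect_equal(joint_loss(c(1, 2), c(1, 2), f, f, c(1, 1), cfg), 0)
  # 1-frame, 2-atom batch with hand-picked residuals
  e_hat <- 3; e_ref <- 1
  f_hat <- rbind(c(1, 0, 0), c(0, 2, 0))
  f_ref <- rbind(c(0, 0, 0), c(0, 0, 1))
  manual <- 2 / 1 * (3 - 1)^2 + 5 / (3 * 1 * 2) * (1 + 4 + 1)
  expect_equal(joint_loss(e_hat, e_ref, f_hat, f_ref, 2, cfg), manual)
  # per-atom form divides the energy residual by N before squaring
  cfg2 <- loss_config(lambda_e = 2, lambda_f = 5, per_atom = TRUE)
  manual2 <- 2 / 1 * ((3 - 1) / 2)^2 + 5 / (3 * 1 * 2) * 6
  expect_equal(joint_loss(e_hat, e_ref, f_hat, f_ref, 2, cfg2), manual2)
  # the two forms agree when N = 1
  f1 <- matrix(rnorm(3), 1); f0 <- matrix(0, 1, 3)
  expect_equal(joint_loss(2, 1, f1, f0, 1, loss_config(3, 7, FALSE)),
               joint_loss(2, 1, f1, f0, 1, loss_config(3, 7, TRUE)))
  # the default weighting is 1000 on forces, 1 on total energies
  dflt <- loss_config()
  expect_equal(dflt$lambda_f, 1000)
  expect_equal(dflt$lambda_e, 1)
  expect_error(loss_config(0, 0), "not both zero")
  expect_error(joint_loss(c(1, 2), 1, f1, f0, 1, dflt), "mismatch")
})

test_that("fixed-composition normalization matches its definitions", {
  one <- atomic_system(rep("A", 5), matrix(rnorm(15), 5), energy = 10,
                       forces = matrix(0.5, 5, 3))
  ns <- fit_norm_fixed_composition(list(one))
  expect_equal(unname(ns$mu["A"]), 2)
  expect_equal(unname(ns$sigma["A"]), 0.5)
  # two-frame synthetic set with known moments
  f1 <- matrix(c(1, -1, 2, 0, 0, 1), 2)
  f2 <- matrix(c(0, 3, -2, 1, 0, 0), 2)
  d <- list(atomic_system(c("A", "B"), matrix(rnorm(6), 2), energy = 4, forces = f1),
            atomic_system(c("A", "B"), matrix(rnorm(6), 2), energy = -2, forces = f2))
  ns <- fit_norm_fixed_composition(d)
  expect_equal(unname(ns$mu["B"]), mean(c(4 / 2, -2 / 2)))
  expect_equal(unname(ns$sigma["A"]), sqrt(mean(c(f1, f2)^2)))
  # degenerate all-zero forces are rejected
  z <- atomic_system("A", matrix(0, 1, 3), energy = 1, forces = matrix(0, 1, 3))
  expect_error(fit_norm_fixed_composition(list(z)), "degenerate")
})

test_that("composition regression recovers generating coefficients", {
  set.seed(41)
  mu_true <- c(A = -3.2, B = 1.7)
  mk <- function(na, nb, noise = 0)
    atomic_system(c(rep("A", na), rep("B", nb)), matrix(rnorm(3 * (na + nb)), na + nb),
                  energy = na * mu_true["A"] + nb * mu_true["B"] + noise)
  # exactly linear energies: exact recovery
  d <- list(mk(1, 2), mk(3, 1), mk(2, 2), mk(4, 0))
  ns <- fit_norm_composition_regression(d, species = c("A", "B"))
  expect_equal(unname(ns$mu), unname(mu_true), tolerance = 1e-10)
  # zero-mean noise: recovery within standard least-squares error bounds
  dn <- lapply(1:60, function(k) mk(sample(1:5, 1), sample(1:5, 1),
                                    noise = rnorm(1, sd = 0.05)))
  nsn <- fit_norm_composition_regression(dn, species = c("A", "B"))
  X <- t(vapply(dn, function(s) c(sum(s$species == "A"), sum(s$species == "B")),
                numeric(2)))
  se <- 0.05 * sqrt(diag(solve(crossprod(X))))
  expect_true(all(abs(nsn$mu - mu_true) < 5 * se))
  # single species reduces to the mean per-atom energy
  ds <- list(atomic_system(rep("A", 2), matrix(rnorm(6), 2), energy = 6),
             atomic_system(rep("A", 4), matrix(rnorm(12), 4), energy = 8))
  nss <- fit_norm_composition_regression(ds, species = "A")
  expect_equal(unname(nss$mu["A"]), qr.solve(matrix(c(2, 4)), c(6, 8))[1])
  # rank deficiency falls back to the pseudo-inverse with a warning
  dr <- list(mk(1, 1), mk(2, 2), mk(3, 3))
  expect_warning(fit_norm_composition_regression(dr, species = c("A", "B")),
                 "rank-deficient")
})

test_that("loss gradient matches finite differences on a small model", {
  data <- fix_lj_dataset(4)
  cfg <- allegro_config(species = "X", r_cut = 2.5, n_layers = 1, ell_max = 1,
                        n_equivariant = 1, two_body_hidden = c(3, 4),
                        latent_hidden = 4, output_hidden = 2,
                        avg_num_neighbors = 2, mu = -0.2, sigma = 0.4)
  m <- allegro_model(cfg, seed = 17)
  batch <- allegror:::.assemble_batch(cfg, data)
  for (lcfg in list(loss_config(1, 0), loss_config(1, 10, per_atom = TRUE))) {
    lg <- allegror:::.loss_and_grad(m, batch, lcfg)
    set.seed(18)
    for (nm in names(m$params)) {
      k <- sample(length(m$params[[nm]]), 1)
      h <- 1e-6
      mp <- m; mp$params[[nm]][k] <- mp$params[[nm]][k] + h
      mm <- m; mm$params[[nm]][k] <- mm$params[[nm]][k] - h
      fd <- (allegror:::.loss_and_grad(mp, batch, lcfg, want_grad = FALSE)$loss -
               allegror:::.loss_and_grad(mm, batch, lcfg, want_grad = FALSE)$loss) / (2 * h)
      expect_lt(abs(fd - lg$grad[[nm]][k]) / max(abs(fd), 1e-4), 1e-6)
    }
  }
})

test_that("per-atom energy loss is invariant to replicating extensive frames", {
  # the model is exactly extensive, so the per-atom energy residual of an
  # m-fold replicated frame is unchanged
  cfg <- allegro_config(species = "X", r_cut = 2.5, n_layers = 1, ell_max = 1,
                        n_equivariant = 1, two_body_hidden = c(4, 6),
                        latent_hidden = 6, output_hidden = 4,
                        avg_num_neighbors = 2, mu = -0.2, sigma = 0.4)
  m <- allegro_model(cfg, seed = 19)
  cell <- diag(3) * 3.0
  base <- atomic_system(c("X", "X"), rbind(c(0, 0, 0), c(1.45, 1.4, 1.5)),
                        cell = cell, pbc = rep(TRUE, 3))
  e_ref_per_atom <- -0.31
  lcfg <- loss_config(1, 0, per_atom = TRUE)
  losses <- sapply(1:2, function(mrep) {
    grid <- as.matrix(expand.grid(0:(mrep - 1), 0:(mrep - 1), 0:(mrep - 1)))
    pos <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r)
      sweep(base$positions, 2, -as.numeric(grid[r, ] %*% cell))))
    sys <- atomic_system(rep("X", 2 * nrow(grid)), pos, cell = mrep * cell,
                         pbc = rep(TRUE, 3),
                         energy = e_ref_per_atom * 2 * nrow(grid))
    batch <- allegror:::.assemble_batch(cfg, list(sys))
    allegror:::.loss_and_grad(m, batch, lcfg, want_grad = FALSE)$loss
  })
  expect_equal(losses[1], losses[2], tolerance = 1e-9)
})

test_that("training reduces the loss and is bit-reproducible under a seed", {
  data <- fix_lj_dataset(24)
  ns <- fit_norm_fixed_composition(data)
  ann <- average_neighbor_count(data, 2.5)
  cfg <- allegro_config(species = "X", r_cut = 2.5, n_layers = 1, ell_max = 1,
                        n_equivariant = 1, two_body_hidden = c(8, 16),
                        latent_hidden = 16, output_hidden = 8, envelope_p = 6,
                        avg_num_neighbors = ann, mu = ns$mu, sigma = ns$sigma)
  m <- allegro_model(cfg, seed = 5)
  tcfg <- train_config(learning_rate = 0.005, max_epochs = 12, seed = 2,
                       scheduler_patience = 10)
  lcfg <- loss_config(lambda_e = 1, lambda_f = 1, per_atom = TRUE)
  r1 <- train(m, data, tcfg, lcfg)
  expect_lt(min(r1$log$train_loss, na.rm = TRUE),
            r1$log$train_loss[2])
  expect_lt(r1$log$val_loss[nrow(r1$log)], r1$log$val_loss[1])
  # identical seed: bit-for-bit identical trajectory and final weights
  r2 <- train(m, data, tcfg, lcfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model$params, r2$model$params)
  # energy-only training still runs and learns
  r3 <- train(m, data, train_config(max_epochs = 6, seed = 3),
              loss_config(lambda_e = 1, lambda_f = 0, per_atom = TRUE))
  expect_lt(r3$log$val_e_mae[nrow(r3$log)], r3$log$val_e_mae[1])
})
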