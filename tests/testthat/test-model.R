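# The pair-energy network: embeddings, symmetry, locality, forces, counting.

test_that("pair energies vanish smoothly at the cutoff and depend on order", {
  m <- fix_model(n_layers = 1, ell_max = 1)
  rc <- m$config$r_cut
  # E_ij -> 0 smoothly as r -> r_cut (envelope factors through the latents)
  rs <- rc - c(0.5, 0.1, 0.02, 1e-3, 1e-6)
  e <- sapply(rs, function(r) {
    pair_energies(m, atomic_system(c("A", "B"), rbind(c(0, 0, 0), c(r, 0, 0))))$e_pair[1]
  })
  expect_lt(abs(e[5]), 1e-12)
  expect_true(abs(e[3]) > abs(e[4]) && abs(e[4]) > abs(e[5]))
  # identical (Zi, Zj, r) gives identical embeddings/pair energies
  p1 <- pair_energies(m, atomic_system(c("A", "B"), rbind(c(0, 0, 0), c(1.7, 0, 0))))
  p2 <- pair_energies(m, atomic_system(c("A", "B"), rbind(c(2, 1, -1), c(2, 1, 0.7))))
  expect_equal(p1$e_pair[1], p2$e_pair[1], tolerance = 1e-12)
  # swapping an asymmetric species pair changes the result
  expect_false(isTRUE(all.equal(p1$e_pair[1], p1$e_pair[2])))
  # species not in the map errors
  expect_error(predict_energy_forces(m, atomic_system("Zr", matrix(0, 1, 3))),
               "species")
})

test_that("E_ij != E_ji for generic asymmetric environments", {
  m <- fix_model(n_layers = 2, ell_max = 1)
  sys <- fix_env()
  pe <- pair_energies(m, sys)
  ij <- which(pe$i == 1 & pe$j == 2)
  ji <- which(pe$i == 2 & pe$j == 1)
  expect_false(isTRUE(all.equal(pe$e_pair[ij], pe$e_pair[ji])))
})

test_that("total energy is E(3)-invariant and forces are equivariant", {
  m <- fix_model(n_layers = 2, ell_max = 2)
  sys <- fix_cluster(5, seed = 22)
  pr <- predict_energy_forces(m, sys)
  set.seed(23)
  for (k in 1:25) {
    rot <- random_rotation(inversion_prob = 0.5)
    tr <- rnorm(3)
    sys2 <- atomic_system(sys$species,
                          allegror:::rot_apply_vec(rot, sys$positions) +
                            matrix(tr, 5, 3, byrow = TRUE))
    pr2 <- predict_energy_forces(m, sys2)
    expect_lt(abs(pr2$e_system - pr$e_system) / abs(pr$e_system), 1e-10)
    expect_lt(max(abs(pr2$forces - allegror:::rot_apply_vec(rot, pr$forces))),
              1e-10 * max(abs(pr$forces)))
  }
})

test_that("relabeling atoms permutes forces and preserves the energy exactly", {
  m <- fix_model()
  sys <- fix_cluster(6, seed = 24)
  pr <- predict_energy_forces(m, sys)
  set.seed(25)
  for (k in 1:5) {
    perm <- sample(6)
    pr2 <- predict_energy_forces(m, atomic_system(sys$species[perm],
                                                  sys$positions[perm, ]))
    # exact up to float summation order (edges are re-sorted by atom label)
    expect_equal(pr2$e_system, pr$e_system, tolerance = 1e-13)
    expect_equal(pr2$forces, pr$forces[perm, ], tolerance = 1e-12)
  }
})

test_that("strict locality: atoms outside the cutoff leave E_ij bit-identical", {
  m <- fix_model()
  sys <- fix_cluster(5, seed = 26)
  pr <- pair_energies(m, sys)
  set.seed(27)
  for (k in 1:5) {
    far <- c(10, -12, 15)[sample(3)] + rnorm(3)
    sys2 <- atomic_system(c(sys$species, "B"), rbind(sys$positions, far))
    pr2 <- pair_energies(m, sys2)
    keep <- pr2$i <= 5 & pr2$j <= 5
    expect_identical(pr2$e_pair[keep], pr$e_pair)
  }
})

test_that("energy is size-extensive under supercell replication", {
  m <- fix_model(n_layers = 1, ell_max = 1)
  cell <- diag(3) * 3.4
  base <- atomic_system(c("A", "B"), rbind(c(0.1, 0, 0), c(1.7, 1.6, 1.8)),
                        cell = cell, pbc = rep(TRUE, 3))
  e1 <- predict_energy_forces(m, base)$e_system
  for (mrep in 2:3) {
    grid <- as.matrix(expand.grid(0:(mrep - 1), 0:(mrep - 1), 0:(mrep - 1)))
    pos <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r)
      sweep(base$positions, 2, -as.numeric(grid[r, ] %*% cell))))
    spc <- rep(base$species, nrow(grid))
    em <- predict_energy_forces(m, atomic_system(spc, pos, cell = mrep * cell,
                                                 pbc = rep(TRUE, 3)))$e_system
    expect_lt(abs(em - mrep^3 * e1) / abs(mrep^3 * e1), 1e-12)
  }
})

test_that("energy is continuous as a neighbor crosses the cutoff", {
  m <- fix_model(n_layers = 2, ell_max = 1)
  rc <- m$config$r_cut
  # a cluster where one approaching atom crosses r_cut of the others
  base <- rbind(c(0, 0, 0), c(1.2, 0.4, 0), c(0.4, 1.3, 0.2))
  e_of <- function(x) predict_energy_forces(
    m, atomic_system(c("A", "B", "A", "B"), rbind(base, c(x, 0, 0))))$e_system
  # no jump at the crossing: values straddling r_cut agree to o(h)
  expect_lt(abs(e_of(rc - 1e-7) - e_of(rc + 1e-7)), 1e-6)
  expect_lt(abs(e_of(rc - 1e-4) - e_of(rc + 1e-4)), 1e-3)
  # for an isolated dimer the energy is exactly constant beyond r_cut
  e_dim <- function(x) predict_energy_forces(
    m, atomic_system(c("A", "B"), rbind(c(0, 0, 0), c(x, 0, 0))))$e_system
  expect_lt(abs(e_dim(rc - 1e-7) - e_dim(rc + 1e-7)), 1e-6)
  expect_identical(e_dim(rc + 1e-9), e_dim(rc + 1))
})

test_that("forces match central finite differences", {
  m <- fix_model(n_layers = 2, ell_max = 2)
  sys <- fix_cluster(4, seed = 28)
  pr <- predict_energy_forces(m, sys)
  h <- 1e-5
  for (a in 1:4) for (d in 1:3) {
    p1 <- sys$positions; p1[a, d] <- p1[a, d] + h
    p2 <- sys$positions; p2[a, d] <- p2[a, d] - h
    fd <- -(predict_energy_forces(m, atomic_system(sys$species, p1))$e_system -
              predict_energy_forces(m, atomic_system(sys$species, p2))$e_system) / (2 * h)
    expect_lt(abs(fd - pr$forces[a, d]), 1e-6)
  }
})

test_that("systems with no pairs reduce to the per-species shifts", {
  m <- fix_model()
  sys <- atomic_system(c("A", "B", "A"),
                       rbind(c(0, 0, 0), c(10, 0, 0), c(0, 20, 0)))
  pr <- predict_energy_forces(m, sys)
  expect_equal(pr$e_system, sum(m$config$mu[c(1, 2, 1)]))
  expect_equal(pr$forces, matrix(0, 3, 3))
})

test_that("parameter counting matches a by-hand degenerate enumeration", {
  cfg <- allegro_config(species = "X", r_cut = 3, n_layers = 1, ell_max = 0,
                        n_equivariant = 1, two_body_hidden = 1,
                        latent_hidden = 1, output_hidden = 1, n_basis = 1,
                        avg_num_neighbors = 1)
  # two-body (2*1+1)x1 = 3; embed L0, L1: 1 each; env_linear: 1;
  # latent (1 + 1 scalar path) x 1 = 2; output 1x1 + 1x1 = 2  => 10
  total <- count_parameters(cfg)
  expect_equal(as.integer(total), 10L)
  bd <- attr(total, "breakdown")
  expect_equal(sum(bd$count), 10)
  expect_setequal(bd$name, c("two_body.W1", "embed.L0", "embed.L1",
                             "env_linear.1", "latent.L1.W1", "output.W1",
                             "output.W2"))
  # the constructed model carries exactly the counted scalars
  model <- allegro_model(cfg, seed = 1)
  expect_equal(sum(vapply(model$params, length, 0L)), 10L)
})

test_that("model construction is deterministic and checkpoints round-trip", {
  cfg <- allegro_preset("li3po4", avg_num_neighbors = 4, mu = c(-1, -2, -3))
  m1 <- allegro_model(cfg, seed = 99)
  m2 <- allegro_model(cfg, seed = 99)
  expect_identical(m1$params, m2$params)
  sys <- atomic_system(c("Li", "P", "O"),
                       rbind(c(0, 0, 0), c(1.8, 0, 0), c(0.8, 1.5, 0)))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m1, path)
  m3 <- load_checkpoint(path)
  expect_identical(predict_energy_forces(m3, sys)$e_system,
                   predict_energy_forces(m1, sys)$e_system)
  expect_identical(m3$params, m1$params)
})

test_that("SE(3) mode runs and stays rotation-invariant", {
  cfg <- allegro_config(species = c("A", "B"), r_cut = 3, n_layers = 2,
                        ell_max = 1, n_equivariant = 2,
                        two_body_hidden = c(6, 8), latent_hidden = 8,
                        output_hidden = 4, parity = "SE3",
                        avg_num_neighbors = 3)
  m <- allegro_model(cfg, seed = 31)
  sys <- fix_cluster(4, seed = 32)
  pr <- predict_energy_forces(m, sys)
  rot <- random_rotation()
  pr2 <- predict_energy_forces(
    m, atomic_system(sys$species, allegror:::rot_apply_vec(rot, sys$positions)))
  expect_equal(pr2$e_system, pr$e_system, tolerance = 1e-10)
})
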