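# MD driver and structural/kinetic observables.

test_that("a zero-force configuration at rest stays static", {
  lj <- toy_potential_spec("lennard_jones", epsilon = 0.5, sigma = 1.0,
                           r_cut = 3, truncate = FALSE)
  sys <- atomic_system(c("X", "X"), rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)))
  traj <- velocity_verlet(sys, toy_potential(lj), dt = 0.5, n_steps = 20)
  expect_equal(traj$frames[[21]]$positions, sys$positions, tolerance = 1e-12)
  expect_equal(max(msd(traj)$msd), 0, tolerance = 1e-20)
})

test_that("LJ dimer oscillation matches the harmonic period to 2 percent", {
  lj <- toy_potential_spec("lennard_jones", epsilon = 0.5, sigma = 1.0,
                           r_cut = 3, truncate = FALSE)
  r0 <- 2^(1 / 6)
  sys <- atomic_system(c("X", "X"), rbind(c(0, 0, 0), c(r0 + 0.005, 0, 0)))
  traj <- velocity_verlet(sys, toy_potential(lj), dt = 0.25, n_steps = 1200,
                          masses = 10)
  sep <- sapply(traj$frames, function(f) f$positions[2, 1] - f$positions[1, 1])
  # analytic second derivative of LJ at the minimum
  k <- 4 * 0.5 * (156 * r0^(-14) - 42 * r0^(-8))
  period_th <- 2 * pi * sqrt((10 / 2) / (k * allegror:::.EVA_AMU))
  up <- which(diff(sign(sep - r0)) > 0)
  period_obs <- mean(diff(up)) * 0.25
  expect_lt(abs(period_obs - period_th) / period_th, 0.02)
})

test_that("NVE with model forces conserves energy; berendsen controls T", {
  data <- fix_lj_dataset(1, n_atoms = 5, seed = 61)
  cfg <- allegro_config(species = "X", r_cut = 2.5, n_layers = 1, ell_max = 1,
                        n_equivariant = 1, two_body_hidden = c(8, 16),
                        latent_hidden = 16, output_hidden = 8,
                        avg_num_neighbors = 2, mu = -0.5, sigma = 0.3)
  m <- allegro_model(cfg, seed = 62)
  traj <- velocity_verlet(data[[1]], model_potential(m), dt = 0.25,
                          n_steps = 400, masses = 20,
                          velocities = "maxwell", temperature = 60, seed = 63)
  drift <- max(abs(traj$energies$total - traj$energies$total[1])) /
    abs(traj$energies$total[1])
  expect_lt(drift, 1e-4)
  # berendsen drives the temperature toward the target
  trj <- velocity_verlet(data[[1]], toy_potential(fix_lj()), dt = 0.5,
                         n_steps = 600, masses = 20, thermostat = "berendsen",
                         temperature = 120, tau = 20,
                         velocities = "maxwell", seed = 64)
  tail_T <- mean(utils::tail(trj$energies$temperature, 100))
  expect_gt(tail_T, 40)
})

test_that("RDF is flat for an ideal gas and peaked for a crystal", {
  set.seed(65)
  frames <- lapply(1:30, function(k)
    atomic_system(rep("X", 40), matrix(runif(120, 0, 8), ncol = 3),
                  cell = diag(3) * 8, pbc = rep(TRUE, 3)))
  g <- rdf(frames, r_max = 3.9, bin_width = 0.3)
  # sampling tolerance from bin counts: relative sd ~ 1/sqrt(mean count)
  counts <- 40 * (39 / 8^3) * 4 * pi * g$r^2 * 0.3 * 30
  expect_true(all(abs(g$g - 1) < 5 / sqrt(counts)))
  # perfect simple-cubic crystal: peaks exactly at a and a*sqrt(2)
  a <- 2.0
  sc <- generate_dataset(generator_spec(1, 27, "X", mode = "sc", a = a,
                                        jitter = 0, seed = 1))[[1]]
  gc <- rdf(sc, r_max = 2.95, bin_width = 0.05)
  occupied <- gc$r[gc$g > 0]
  dist_to_shell <- apply(abs(outer(occupied, c(a, a * sqrt(2), a * sqrt(3)), "-")),
                         1, min)
  expect_true(all(dist_to_shell < 0.05))
  # single frame, single pair: exactly one occupied bin
  pair <- atomic_system(c("X", "X"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                        cell = diag(3) * 10, pbc = rep(TRUE, 3))
  gp <- rdf(pair, r_max = 3, bin_width = 0.1)
  expect_equal(sum(gp$g > 0), 1)
  # estimator guard: r_max beyond half the cell under minimum image
  expect_error(rdf(pair, r_max = 6), "half the minimum cell")
  expect_error(rdf(fix_cluster(3), r_max = 2), "periodic")
})

test_that("ADF peaks at the tetrahedral angle and normalizes to 1", {
  tet <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tsys <- atomic_system(c("P", "O", "O", "O", "O"), tet)
  a <- adf(tsys, "P", cutoff = 2, bin_width = 1)
  expect_equal(a$angle[which.max(a$density)], 109.5)
  expect_equal(sum(a$density * 1), 1, tolerance = 1e-12)
  expect_equal(sum(a$density > 0), 1)
  # linear triatomic: single peak at 180 degrees
  lin <- atomic_system(c("C", "O", "O"),
                       rbind(c(0, 0, 0), c(1.2, 0, 0), c(-1.2, 0, 0)))
  al <- adf(lin, "C", cutoff = 1.5, bin_width = 2)
  expect_equal(al$angle[which.max(al$density)], 179)
  # neighbor-species filter works
  mix <- atomic_system(c("P", "O", "O", "H"),
                       rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)))
  ao <- adf(mix, "P", cutoff = 2, neighbor_species = "O", bin_width = 1)
  expect_equal(sum(ao$density > 0), 1)
  # observables invariant under rigid rotation of every frame
  rot <- random_rotation()
  a2 <- adf(atomic_system(tsys$species,
                          allegror:::rot_apply_vec(rot, tet)), "P", cutoff = 2,
            bin_width = 1)
  expect_equal(a2$density, a$density, tolerance = 1e-12)
})

test_that("MSD: static zero, ballistic t^2, random-walk diffusion", {
  stat <- lapply(1:6, function(k) atomic_system(rep("X", 3), matrix(1:9, 3)))
  expect_equal(max(msd(stat)$msd), 0)
  v <- c(0.3, -0.1, 0.2)
  bal <- lapply(0:8, function(t) atomic_system("X", matrix(v * t, 1)))
  mm <- msd(bal)
  expect_equal(mm$msd, sum(v^2) * mm$time_fs^2, tolerance = 1e-12)
  # seeded lattice random walk: MSD slope = a^2 per step (3D walk)
  set.seed(66)
  nwalk <- 80; nstep <- 160; a <- 0.7
  pos <- matrix(0, nwalk, 3)
  frames <- vector("list", nstep + 1)
  frames[[1]] <- atomic_system(rep("X", nwalk), pos)
  for (t in seq_len(nstep)) {
    ax <- sample(3, nwalk, TRUE); dir <- sample(c(-1, 1), nwalk, TRUE)
    pos[cbind(seq_len(nwalk), ax)] <- pos[cbind(seq_len(nwalk), ax)] + a * dir
    frames[[t + 1]] <- atomic_system(rep("X", nwalk), pos)
  }
  mw <- msd(frames, origin_stride = 10)
  fit <- stats::coef(stats::lm(msd ~ 0 + time_fs, data = mw[mw$time_fs <= 40, ]))
  expect_lt(abs(fit - a^2) / a^2, 0.15)
  # species filter errors when empty
  expect_error(msd(frames, species = "Q"), "no atoms")
})

test_that("receptive-field arithmetic separates local from message passing", {
  expect_equal(receptive_field(6, 6, "message_passing"), 36)
  expect_equal(neighbor_volume_ratio(36, 6), 216)
  for (nl in c(1, 3, 6, 12))
    expect_equal(receptive_field(nl, 6, "strictly_local"), 6)
  expect_equal(receptive_field(1, 4.5, "message_passing"), 4.5)
  expect_error(receptive_field(0, 6), "n_layers")
})
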