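# Shared fixtures, built in code at test time.

# small random cluster with two species
fix_cluster <- function(n = 5, seed = 42, scale = 1.4, species = c("A", "B")) {
  set.seed(seed)
  atomic_system(rep(species, length.out = n),
                matrix(stats::rnorm(3 * n, sd = scale), n, 3))
}

# fixed compact 4-atom environment: every pair well inside a 3 A cutoff
fix_env <- function(species = c("A", "A", "B", "A"))
  atomic_system(species, rbind(c(0, 0, 0), c(1.2, 0.4, -0.3),
                               c(-0.5, 1.0, 0.7), c(0.8, -0.9, 0.6)))

# tiny two-species model with generic settings
fix_model <- function(n_layers = 2, ell_max = 2, n_equivariant = 2,
                      seed = 7, r_cut = 3.0, latent_nonlin = "silu",
                      latent_hidden = 16) {
  cfg <- allegro_config(species = c("A", "B"), r_cut = r_cut,
                        n_layers = n_layers, ell_max = ell_max,
                        n_equivariant = n_equivariant,
                        two_body_hidden = c(8, 16),
                        latent_hidden = latent_hidden, output_hidden = 8,
                        latent_nonlin = latent_nonlin,
                        avg_num_neighbors = 3,
                        mu = c(-1, -2), sigma = c(0.5, 0.8))
  allegro_model(cfg, seed = seed)
}

# truncated-LJ toy potential matching a 2.5 A cutoff
fix_lj <- function(r_cut = 2.5, truncate = TRUE)
  toy_potential_spec("lennard_jones", epsilon = 0.5, sigma = 1.0,
                     r_cut = r_cut, truncate = truncate, envelope_p = 6)

# labelled LJ cluster dataset (the training fixture at reduced size)
fix_lj_dataset <- function(n_frames, n_atoms = 4, seed = 123, box = 3.2)
  generate_dataset(generator_spec(n_frames = n_frames, n_atoms = n_atoms,
                                  species = "X", box = box, pbc = FALSE,
                                  min_dist = 0.9, seed = seed),
                   fix_lj())

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(max(abs(b)), 1e-300), tol)
}
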