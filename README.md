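# allegror

Strictly local, E(3)-equivariant neural-network interatomic potentials in
pure R — an implementation of the Allegro architecture together with the
verification machinery its theory invites: exact-gradient forces, an atomic
cluster expansion (ACE) oracle for the layer recursion, a body-order probe,
and the molecular-dynamics observables used to validate trained potentials.

## Who this is for and what it does

Machine-learning interatomic potentials map atomic configurations (species +
Cartesian coordinates, possibly periodic) to a total energy and per-atom
forces. Message-passing networks achieve high accuracy but propagate
information over `n_layers * r_cut`, which frustrates spatial-decomposition
parallelism; strictly local models keep the receptive field at `r_cut`
regardless of depth. Allegro is a strictly local *and* equivariant design:
it decomposes the energy into directed pair energies

    E_system = sum_i sigma_Zi * E_i + mu_Zi,      E_i = sum_{j in N(i)} sigma_ZiZj * E_ij / sqrt(<N>)

and computes each `E_ij` from two interacting latent tracks carried by the
ordered pair *(i, j)*: an invariant scalar track `x^{ij,L}` and an
equivariant track `V^{ij,L}_{n,l,p}` whose blocks transform as irreducible
representations of O(3) (rotation order `l`, parity `p`). Each layer embeds
the chemical environment of atom *i* as a learned-weight spherical-harmonic
density projection, combines it with `V` through Wigner-3j tensor products
over all symmetry-allowed coupling paths, routes the scalar outputs back
into `x` through a latent MLP gated by a smooth cutoff envelope, and mixes
the equivariant path outputs per irrep. Forces are the exact negative
gradient `F_i = -dE/dr_i`, computed by reverse-mode differentiation, so the
force field is energy-conserving by construction.

The package implements every piece at desk scale, with no external data:

- `irreps_core`: real spherical harmonics, real-basis Wigner 3j tensors,
  Wigner D matrices, tensor products and path enumeration
  (`sph_harmonics()`, `wigner_3j()`, `tensor_product()`).
- `radial_basis`: Bessel basis with the polynomial cutoff envelope and
  zero-mean/unit-variance normalization (`radial_basis_spec()`).
- `system_io`: atomic systems, periodic multi-image neighbor lists,
  extended-XYZ reading/writing (`build_neighbor_list()`, `read_extxyz()`).
- `model_core`: the network itself (`allegro_config()`, `allegro_model()`,
  `predict_energy_forces()`, `count_parameters()`, JSON checkpoints).
- `training`: joint energy/force loss, target normalization, Adam with
  on-plateau scheduling and EMA weights (`train()`).
- `synthetic_data`: seeded Lennard-Jones / Morse reference data with
  analytic labels (`generate_dataset()`, `toy_labels()`).
- `ace_oracle`: brute-force ACE descriptors and the neighbor-tuple
  expansion of the layer recursion (`ace_B_density()`, `ace_B_tuples()`,
  `allegro_expand()`, `body_order_probe()`).
- `md_eval`: velocity-Verlet MD, RDF/ADF/MSD observables, receptive-field
  arithmetic (`velocity_verlet()`, `rdf()`, `adf()`, `msd()`,
  `receptive_field()`).

A thin command-line front end (`inst/exec/allegror`) exposes `synth`,
`predict`, `md`, `analyze`, `neighbors`, `convert`, `count`, and `verify`.

## Worked example

Train a small model on 200 smoothly truncated Lennard-Jones clusters (four
atoms each, generated with analytic energy/force labels), then predict and
run NVE dynamics (about a minute on one CPU):

```r
library(allegror)

pot  <- toy_potential_spec("lennard_jones", epsilon = 0.5, sigma = 1.0,
                           r_cut = 2.5, truncate = TRUE)
data <- generate_dataset(
  generator_spec(n_frames = 200, n_atoms = 4, species = "X", box = 3.2,
                 min_dist = 0.9, seed = 123), pot)

norm <- fit_norm_fixed_composition(data)
cfg  <- allegro_config(
  species = "X", r_cut = 2.5, n_layers = 1, ell_max = 1, n_equivariant = 1,
  two_body_hidden = c(32, 64), latent_hidden = 64, output_hidden = 32,
  envelope_p = 6, avg_num_neighbors = average_neighbor_count(data, 2.5),
  mu = norm$mu, sigma = norm$sigma)

fit <- train(allegro_model(cfg, seed = 5), data,
             train_config(learning_rate = 0.005, batch_size = 50,
                          max_epochs = 80, scheduler_patience = 20,
                          scheduler_factor = 0.5, seed = 1),
             loss_config(lambda_e = 1, lambda_f = 1, per_atom = TRUE))

test <- generate_dataset(
  generator_spec(n_frames = 1, n_atoms = 4, species = "X", box = 3.2,
                 min_dist = 1.0, seed = 999), pot)[[1]]
pred <- predict_energy_forces(fit$model, test)
traj <- velocity_verlet(test, model_potential(fit$model), dt = 0.25,
                        n_steps = 1000, masses = 20,
                        velocities = "maxwell", temperature = 60, seed = 2)
```

Output of this exact script:

```
validation force MAE: 1.654 (init) -> 0.111 eV/A (epoch 80)
validation energy MAE: 0.0407 eV/atom
held-out frame: reference E = -0.0998 eV, predicted E = -0.2894 eV
max force component error: 0.152 eV/A (force scale 0.28 eV/A)
NVE drift over 1000 steps: 0.0018 (relative)
```

Reading it: the validation force mean absolute error drops 15-fold from its
random-initialization value, i.e. the model has genuinely learned the toy
potential energy surface; the held-out energy is off by the expected
~0.04 eV/atom; and the total energy in a microcanonical run drifts only at
the integrator's O(dt^2) level — the operational signature that the forces
are an exact gradient of the energy.

Architecture arithmetic is exactly reproducible from the published
hyperparameter presets:

```r
count_parameters(allegro_preset("li3po4"))      # 9058
count_parameters(allegro_preset("qm9_1layer"))  # 7375237
count_parameters(allegro_preset("qm9_3layer"))  # 17926533
receptive_field(6, 6, "message_passing")        # 36 (volume ratio 216)
receptive_field(6, 6, "strictly_local")         # 6
```

`count_parameters()` also returns an itemized per-tensor breakdown
(attribute `"breakdown"`) so any counting discrepancy can be localized to a
specific weight matrix.

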