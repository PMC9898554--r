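# Seeded synthetic reference data from analytic toy potentials, so that every
# other module is testable without any external dataset. Labels are exact:
# energies are pairwise lattice/cluster sums and forces are the analytic
# negative gradients, optionally smoothly truncated with the same polynomial
# envelope as the model's radial basis so that the toy ground truth is itself
# strictly local.

#' Toy pair-potential specification
#'
#' @param kind `"lennard_jones"` or `"morse"`.
#' @param epsilon,sigma LJ well depth (eV) and length (Angstrom); scalar or
#'   S x S per-species-pair matrix.
#' @param d_e,a,r_e Morse depth (eV), stiffness (1/Angstrom), equilibrium
#'   distance (Angstrom); scalar or S x S matrices.
#' @param species Character vector naming the species the (matrix-valued)
#'   parameters refer to; optional for scalar parameters.
#' @param r_cut Interaction cutoff (Angstrom).
#' @param truncate If `TRUE`, pair energies are multiplied by the smooth
#'   polynomial envelope so that energy and forces vanish smoothly at
#'   `r_cut`; if `FALSE` the potential is simply cut (discontinuously) at
#'   `r_cut`.
#' @param envelope_p Envelope exponent used when `truncate = TRUE`.
#' @param r_floor Hard floor on distances; overlapping atoms below it raise
#'   an error (default `0.1` Angstrom).
#' @return An object of class `"toy_potential_spec"`.
#' @export
toy_potential_spec <- function(kind = c("lennard_jones", "morse"),
                               epsilon = 1, sigma = 1,
                               d_e = 1, a = 1.5, r_e = 1.5,
                               species = NULL, r_cut = 3,
                               truncate = TRUE, envelope_p = 6,
                               r_floor = 0.1) {
  kind <- match.arg(kind)
  if (any(c(epsilon, sigma, d_e, a, r_e) <= 0)) .stopf("parameters must be positive")
  structure(list(kind = kind, epsilon = epsilon, sigma = sigma,
                 d_e = d_e, a = a, r_e = r_e, species = species,
                 r_cut = as.numeric(r_cut), truncate = isTRUE(truncate),
                 envelope_p = envelope_p, r_floor = r_floor),
            class = "toy_potential_spec")
}

.pair_param <- function(par, zi, zj) {
  if (is.matrix(par)) par[cbind(zi, zj)] else rep(par, length(zi))
}

# phi(r) and phi'(r) per pair
.toy_phi <- function(spec, r, zi, zj) {
  if (spec$kind == "lennard_jones") {
    eps <- .pair_param(spec$epsilon, zi, zj)
    sig <- .pair_param(spec$sigma, zi, zj)
    sr6 <- (sig / r)^6
    phi <- 4 * eps * (sr6^2 - sr6)
    dphi <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
  } else {
    de <- .pair_param(spec$d_e, zi, zj)
    aa <- .pair_param(spec$a, zi, zj)
    re <- .pair_param(spec$r_e, zi, zj)
    ex <- exp(-aa * (r - re))
    phi <- de * (1 - ex)^2 - de
    dphi <- 2 * de * aa * ex * (1 - ex)
  }
  if (spec$truncate) {
    esp <- radial_basis_spec(1L, spec$r_cut, spec$envelope_p)
    u <- envelope(r, esp)
    du <- .envelope_grad(r, esp)
    list(phi = phi * u, dphi = dphi * u + phi * du)
  } else {
    list(phi = phi, dphi = dphi)
  }
}

#' Analytic energy and forces from a toy potential
#'
#' Pairwise sum of the analytic potential over all pairs within the cutoff;
#' forces are the exact analytic negative gradient.
#'
#' @param system An [atomic_system()].
#' @param spec A [toy_potential_spec()].
#' @return The system with `energy` and `forces` fields set.
#' @export
toy_labels <- function(system, spec) {
  nl <- build_neighbor_list(system, spec$r_cut)
  n <- n_atoms(system)
  if (length(nl$i) == 0L) {
    system$energy <- 0
    system$forces <- matrix(0, n, 3L)
    return(system)
  }
  if (any(nl$r < spec$r_floor))
    .stopf("atoms closer than the hard floor %.3g A", spec$r_floor)
  if (is.matrix(spec$epsilon) || is.matrix(spec$sigma) ||
      is.matrix(spec$d_e) || is.matrix(spec$a) || is.matrix(spec$r_e)) {
    if (is.null(spec$species)) .stopf("matrix parameters require spec$species")
    zz <- species_codes(species_map(spec$species), system$species)
  } else zz <- rep(1L, n)
  pp <- .toy_phi(spec, nl$r, zz[nl$i], zz[nl$j])
  system$energy <- 0.5 * sum(pp$phi)  # each pair appears in both orientations
  # dE/drvec_e = 0.5 * phi'(r) * rhat; F_a = sum_{e:i=a} g - sum_{e:j=a} g
  g <- 0.5 * pp$dphi / nl$r * nl$rvec
  system$forces <- .rowsum_by(g, nl$i, n) - .rowsum_by(g, nl$j, n)
  system
}

#' Synthetic-dataset generator specification
#'
#' @param n_frames Number of configurations.
#' @param n_atoms Atoms per frame.
#' @param species Character vector recycled to `n_atoms` (e.g.
#'   `c("Li","Li","Li","P","O","O","O","O")` for a 3:1:4 composition).
#' @param box Cubic box edge (Angstrom). With `pbc = TRUE` this is the
#'   periodic cell; otherwise atoms are placed in the box without imaging.
#' @param pbc Single logical: fully periodic or fully open boundaries.
#' @param min_dist Minimum allowed interatomic distance (Angstrom, > 0).
#' @param jitter Gaussian displacement amplitude (Angstrom) applied to
#'   lattice modes (and to `"random"` mode after placement if positive).
#' @param mode `"random"` (rejection-sampled liquid-like), `"sc"` or
#'   `"fcc"` (perturbed crystals; `n_atoms` must fit the lattice),
#'   `"dimer_scan"` (two atoms at a scanned distance grid).
#' @param a Lattice constant for crystal modes (Angstrom).
#' @param vacancies Number of atoms removed from crystal modes.
#' @param scan_range Distance range for `"dimer_scan"`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param max_tries Rejection-sampling retry budget per atom.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_frames, n_atoms, species = "X", box = 6,
                           pbc = FALSE, min_dist = 0.8, jitter = 0.1,
                           mode = c("random", "sc", "fcc", "dimer_scan"),
                           a = 2.0, vacancies = 0L,
                           scan_range = c(0.85, 2.0), seed = 1L,
                           max_tries = 200L) {
  mode <- match.arg(mode)
  if (min_dist <= 0) .stopf("min_dist must be > 0")
  structure(list(n_frames = as.integer(n_frames), n_atoms = as.integer(n_atoms),
                 species = as.character(species), box = as.numeric(box),
                 pbc = isTRUE(pbc), min_dist = min_dist, jitter = jitter,
                 mode = mode, a = a, vacancies = as.integer(vacancies),
                 scan_range = scan_range, seed = as.integer(seed),
                 max_tries = as.integer(max_tries)),
            class = "generator_spec")
}

.min_image_dist_ok <- function(pos, cand, box, pbc, min_dist) {
  if (!nrow(pos)) return(TRUE)
  d <- sweep(pos, 2L, cand)
  if (pbc) d <- d - box * round(d / box)
  all(rowSums(d^2) >= min_dist^2)
}

.lattice_sites <- function(mode, a, n_target, box_cells = NULL) {
  ncell <- ceiling((n_target / if (mode == "fcc") 4 else 1)^(1 / 3))
  grid <- as.matrix(expand.grid(0:(ncell - 1), 0:(ncell - 1), 0:(ncell - 1))) * a
  sites <- if (mode == "fcc") {
    basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0)) * a
    do.call(rbind, lapply(seq_len(nrow(grid)), function(k)
      sweep(basis, 2L, -grid[k, ])))
  } else grid
  list(sites = sites, cell = diag(3) * ncell * a)
}

#' Generate a labelled synthetic dataset
#'
#' Deterministic under the spec's seed; every frame honors the
#' minimum-distance constraint exactly and carries analytic energy/force
#' labels from [toy_labels()].
#'
#' @param gen A [generator_spec()].
#' @param pot A [toy_potential_spec()] used for labelling (omit with
#'   `pot = NULL` to generate unlabelled frames).
#' @return List of [atomic_system()]s.
#' @export
generate_dataset <- function(gen, pot = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(gen$seed)
  species <- rep(gen$species, length.out = gen$n_atoms)
  frames <- vector("list", gen$n_frames)
  for (f in seq_len(gen$n_frames)) {
    if (gen$mode == "dimer_scan") {
      r <- gen$scan_range[1L] + (f - 1) / max(gen$n_frames - 1, 1) *
        diff(gen$scan_range)
      sys <- atomic_system(rep(gen$species, length.out = 2L),
                           rbind(c(0, 0, 0), c(r, 0, 0)))
    } else if (gen$mode %in% c("sc", "fcc")) {
      lat <- .lattice_sites(gen$mode, gen$a, gen$n_atoms + gen$vacancies)
      if (nrow(lat$sites) < gen$n_atoms + gen$vacancies)
        .stopf("lattice too small for requested atom count")
      keep <- seq_len(gen$n_atoms + gen$vacancies)
      if (gen$vacancies > 0L)
        keep <- sort(sample(keep, gen$n_atoms))
      pos <- lat$sites[keep, , drop = FALSE] +
        matrix(stats::rnorm(3L * gen$n_atoms, sd = gen$jitter), ncol = 3L)
      sys <- atomic_system(species, pos, cell = lat$cell, pbc = rep(TRUE, 3L))
    } else {
      if (gen$min_dist > gen$box * (if (gen$pbc) 0.5 else sqrt(3)))
        .stopf("min_dist %.3g infeasible in box %.3g", gen$min_dist, gen$box)
      pos <- matrix(0, 0L, 3L)
      for (atom in seq_len(gen$n_atoms)) {
        placed <- FALSE
        for (t in seq_len(gen$max_tries)) {
          cand <- stats::runif(3L, 0, gen$box)
          if (.min_image_dist_ok(pos, cand, gen$box, gen$pbc, gen$min_dist)) {
            pos <- rbind(pos, cand); placed <- TRUE; break
          }
        }
        if (!placed)
          .stopf("rejection sampling failed after %d tries (atom %d, frame %d)",
                 gen$max_tries, atom, f)
      }
      sys <- atomic_system(species, pos,
                           cell = if (gen$pbc) diag(3) * gen$box else NULL,
                           pbc = rep(gen$pbc, 3L))
    }
    frames[[f]] <- if (is.null(pot)) sys else toy_labels(sys, pot)
  }
  frames
}

#' Symmetry-transformed copies of a labelled configuration
#'
#' Produces rotated, inverted, translated, and atom-permuted copies with
#' consistently transformed labels: the energy is unchanged, forces are
#' rotated/negated/permuted along with the positions. These are the test
#' inputs for equivariance checks.
#'
#' @param system A labelled [atomic_system()].
#' @param seed Seed for the random rotation/translation/permutation.
#' @return Named list of [atomic_system()]s (`identity`, `rotation`,
#'   `inversion`, `translation`, `permutation`); each carries a
#'   `"transform"` attribute describing the operation.
#' @export
symmetry_variants <- function(system, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(system$energy) || is.null(system$forces))
    .stopf("system must carry energy and force labels")
  if (any(system$pbc)) .stopf("symmetry variants are defined for open boundaries")
  n <- n_atoms(system)
  rot <- random_rotation()
  tr <- stats::rnorm(3L)
  perm <- sample.int(n)
  mk <- function(pos, forces, species, what, meta) {
    s <- atomic_system(species, pos, energy = system$energy, forces = forces)
    attr(s, "transform") <- c(list(type = what), meta)
    s
  }
  list(
    identity = mk(system$positions, system$forces, system$species, "identity", list()),
    rotation = mk(rot_apply_vec(rot, system$positions),
                  rot_apply_vec(rot, system$forces), system$species,
                  "rotation", list(R = rot$R)),
    inversion = mk(-system$positions, -system$forces, system$species,
                   "inversion", list()),
    translation = mk(sweep(system$positions, 2L, -tr), system$forces,
                     system$species, "translation", list(t = tr)),
    permutation = mk(system$positions[perm, , drop = FALSE],
                     system$forces[perm, , drop = FALSE],
                     system$species[perm], "permutation", list(perm = perm)))
}
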