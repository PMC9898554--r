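# Minimal molecular-dynamics driver (velocity Verlet, NVE or Berendsen
# rescaling) and the structural/kinetic observables used for validating
# potentials: radial distribution function, angular distribution function,
# and mean-square displacement; plus the receptive-field arithmetic that
# separates strictly local models from message-passing ones.
#
# Units: Angstrom, eV, fs, amu. The conversion constant 1 eV/A / amu
# = 0.0096485 A/fs^2 fixes accelerations and kinetic energies.

.EVA_AMU <- 0.00964853322  # (eV/Angstrom)/amu in Angstrom/fs^2
.KB_EV <- 8.617333262e-5   # Boltzmann constant, eV/K

#' Potential adapters
#'
#' Wrap a trained model or a toy potential as the `function(system) ->
#' list(energy, forces)` interface the MD driver consumes.
#'
#' @param model An [allegro_model()].
#' @return A potential function.
#' @export
model_potential <- function(model) {
  function(system) {
    pr <- predict_energy_forces(model, system)
    list(energy = pr$e_system, forces = pr$forces)
  }
}

#' @rdname model_potential
#' @param spec A [toy_potential_spec()].
#' @export
toy_potential <- function(spec) {
  function(system) {
    lab <- toy_labels(system, spec)
    list(energy = lab$energy, forces = lab$forces)
  }
}

#' Velocity-Verlet molecular dynamics
#'
#' Integrates Newton's equations with velocity Verlet. With
#' `thermostat = "none"` (NVE) the total energy is conserved up to the
#' integrator's O(dt^2) error, which is the operational test that the
#' forces are an exact gradient. `"berendsen"` rescales velocities toward a
#' target temperature with time constant `tau`.
#'
#' @param system Starting [atomic_system()].
#' @param potential A `function(system) -> list(energy, forces)`; see
#'   [model_potential()] / [toy_potential()].
#' @param dt Time step (fs).
#' @param n_steps Number of steps.
#' @param thermostat `"none"` or `"berendsen"`.
#' @param temperature Target temperature (K) for the thermostat or for
#'   Maxwell-Boltzmann initial velocities.
#' @param tau Berendsen time constant (fs).
#' @param masses Per-atom masses (amu), recycled; default 1.
#' @param velocities Initial velocities (N x 3, Angstrom/fs); `"maxwell"`
#'   draws them from the Maxwell-Boltzmann distribution at `temperature`
#'   (seeded), and `"zero"` starts at rest.
#' @param seed Seed for `"maxwell"` initial velocities.
#' @param record_every Store every k-th frame.
#' @return An object of class `"md_trajectory"`: list with `frames`
#'   (positions are kept unwrapped for displacement observables), `energies`
#'   (data.frame: step, time_fs, potential, kinetic, total, temperature),
#'   `dt`, `record_every`, `thermostat`.
#' @export
velocity_verlet <- function(system, potential, dt, n_steps,
                            thermostat = c("none", "berendsen"),
                            temperature = 300, tau = 100,
                            masses = 1, velocities = c("zero", "maxwell"),
                            seed = 1L, record_every = 1L) {
  thermostat <- match.arg(thermostat)
  n <- n_atoms(system)
  m <- rep(masses, length.out = n)
  if (is.character(velocities)) {
    velocities <- match.arg(velocities)
    v <- if (velocities == "zero") matrix(0, n, 3L) else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
      matrix(stats::rnorm(3L * n, sd = sqrt(.KB_EV * temperature * .EVA_AMU / m)),
             n, 3L)
    }
  } else v <- matrix(velocities, n, 3L)
  wrap <- function(sys) {
    if (!any(sys$pbc)) return(sys)
    frac <- sys$positions %*% solve(sys$cell)
    sys$positions <- (frac - floor(frac)) %*% sys$cell
    sys
  }
  pos <- system$positions
  ev <- potential(wrap(system))
  if (any(!is.finite(ev$forces))) .stopf("non-finite forces at step 0")
  ke <- function(v) sum(0.5 * m * rowSums(v^2)) / .EVA_AMU
  frames <- list(); en <- NULL
  record <- function(step) {
    sys <- system; sys$positions <- pos
    sys$energy <- ev$energy; sys$forces <- ev$forces
    frames[[length(frames) + 1L]] <<- sys
    k <- ke(v)
    en <<- rbind(en, data.frame(step = step, time_fs = step * dt,
                                potential = ev$energy, kinetic = k,
                                total = ev$energy + k,
                                temperature = 2 * k / (3 * n * .KB_EV)))
  }
  record(0L)
  for (s in seq_len(n_steps)) {
    a <- ev$forces / m * .EVA_AMU
    v_half <- v + 0.5 * dt * a
    pos <- pos + dt * v_half
    sysn <- system; sysn$positions <- pos
    ev <- potential(wrap(sysn))
    if (any(!is.finite(ev$forces))) .stopf("non-finite forces at step %d", s)
    v <- v_half + 0.5 * dt * (ev$forces / m * .EVA_AMU)
    if (thermostat == "berendsen") {
      tcur <- 2 * ke(v) / (3 * n * .KB_EV)
      if (tcur > 0)
        v <- v * sqrt(1 + dt / tau * (temperature / tcur - 1))
    }
    if (s %% record_every == 0L) record(s)
  }
  structure(list(frames = frames, energies = en, dt = dt,
                 record_every = record_every, thermostat = thermostat),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory ", length(x$frames), " frames, dt=", x$dt, " fs, ",
      x$thermostat, ">\n", sep = "")
  invisible(x)
}

.traj_frames <- function(traj) {
  if (inherits(traj, "md_trajectory")) traj$frames
  else if (inherits(traj, "atomic_system")) list(traj)
  else traj
}

#' Radial distribution function
#'
#' Pair-density estimator: per-frame histograms of interatomic distances,
#' normalized by the ideal-gas shell count `N * rho * 4 pi r^2 dr` at each
#' frame's density, averaged over frames; an ideal gas gives `g(r) = 1`.
#' Requires periodic frames; `r_max` may not exceed half the smallest cell
#' dimension (minimum-image validity).
#'
#' @param traj An [md_trajectory()] result, a list of systems, or a single
#'   [atomic_system()].
#' @param r_max Maximum distance (Angstrom).
#' @param bin_width Bin width (Angstrom; default 0.05).
#' @param species_a,species_b Optional species filter for the pair
#'   (defaults: all-atom RDF).
#' @param discard Number of leading frames discarded as equilibration.
#' @return data.frame with `r` (bin centers) and `g`.
#' @export
rdf <- function(traj, r_max, bin_width = 0.05, species_a = NULL,
                species_b = NULL, discard = 0L) {
  frames <- .traj_frames(traj)
  if (discard > 0L) frames <- frames[-seq_len(min(discard, length(frames)))]
  if (!length(frames)) .stopf("no frames")
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  gsum <- numeric(length(centers))
  for (sys in frames) {
    if (!any(sys$pbc)) .stopf("rdf requires periodic frames")
    min_width <- min(sapply(1:3, function(a) 1 / sqrt(sum(solve(sys$cell)[, a]^2))))
    if (r_max > min_width / 2 + 1e-9)
      .stopf("r_max %.3g exceeds half the minimum cell dimension %.3g",
             r_max, min_width / 2)
    nl <- build_neighbor_list(sys, r_max)
    sel_a <- if (is.null(species_a)) rep(TRUE, length(nl$i)) else
      sys$species[nl$i] %in% species_a
    sel_b <- if (is.null(species_b)) rep(TRUE, length(nl$j)) else
      sys$species[nl$j] %in% species_b
    rr <- nl$r[sel_a & sel_b]
    na <- if (is.null(species_a)) n_atoms(sys) else sum(sys$species %in% species_a)
    nb <- if (is.null(species_b)) n_atoms(sys) else sum(sys$species %in% species_b)
    vol <- abs(det(sys$cell))
    h <- graphics::hist(rr, breaks = breaks, plot = FALSE)$counts
    shell <- 4 * pi * centers^2 * diff(breaks)
    ideal <- na * (nb / vol) * shell
    gsum <- gsum + ifelse(ideal > 0, h / ideal, 0)
  }
  data.frame(r = centers, g = gsum / length(frames))
}

#' Angular distribution function
#'
#' Distribution of the angle j-i-k over triplets with a central atom of
#' `central_species` and two distinct neighbors within `cutoff` (each
#' unordered neighbor pair counted once), as a probability density over
#' [0, 180] degrees (integrates to 1).
#'
#' @param traj As in [rdf()].
#' @param central_species Chemical symbol of the central atom.
#' @param cutoff Neighbor cutoff (Angstrom).
#' @param neighbor_species Optional species filter for the two neighbors.
#' @param bin_width Bin width in degrees.
#' @param discard Leading frames discarded as equilibration.
#' @return data.frame with `angle` (degrees, bin centers) and `density`
#'   (1/degree).
#' @export
adf <- function(traj, central_species, cutoff, neighbor_species = NULL,
                bin_width = 1, discard = 0L) {
  frames <- .traj_frames(traj)
  if (discard > 0L) frames <- frames[-seq_len(min(discard, length(frames)))]
  if (!length(frames)) .stopf("no frames")
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  counts <- numeric(length(centers))
  for (sys in frames) {
    nl <- build_neighbor_list(sys, cutoff)
    for (ci in which(sys$species == central_species)) {
      ee <- which(nl$i == ci)
      if (!is.null(neighbor_species))
        ee <- ee[sys$species[nl$j[ee]] %in% neighbor_species]
      if (length(ee) < 2L) next
      for (a in seq_len(length(ee) - 1L)) for (b in (a + 1L):length(ee)) {
        v1 <- nl$rvec[ee[a], ]; v2 <- nl$rvec[ee[b], ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        bin <- min(findInterval(ang, breaks, all.inside = TRUE), length(centers))
        counts[bin] <- counts[bin] + 1
      }
    }
  }
  tot <- sum(counts * diff(breaks))
  if (tot == 0) .stopf("no triplets found")
  data.frame(angle = centers, density = counts / tot)
}

#' Mean-square displacement
#'
#' `MSD(dt) = < |r(t0 + dt) - r(t0)|^2 >` averaged over atoms (optionally
#' filtered by species) and over multiple time origins spaced by
#' `origin_stride` recorded frames. Positions must be unwrapped (the MD
#' driver records unwrapped coordinates).
#'
#' @param traj An [md_trajectory()] or list of frames.
#' @param species Optional species filter.
#' @param origin_stride Spacing between time origins, in recorded frames.
#' @return data.frame with `time_fs` and `msd` (Angstrom^2).
#' @export
msd <- function(traj, species = NULL, origin_stride = 1L) {
  frames <- .traj_frames(traj)
  nf <- length(frames)
  if (nf < 2L) .stopf("need at least 2 frames")
  dt <- if (inherits(traj, "md_trajectory")) traj$dt * traj$record_every else 1
  sel <- if (is.null(species)) seq_len(n_atoms(frames[[1L]])) else
    which(frames[[1L]]$species %in% species)
  if (!length(sel)) .stopf("species filter matches no atoms")
  pos <- lapply(frames, function(f) f$positions[sel, , drop = FALSE])
  lags <- seq_len(nf - 1L)
  out <- vapply(lags, function(lag) {
    origins <- seq(1L, nf - lag, by = origin_stride)
    mean(vapply(origins, function(t0)
      mean(rowSums((pos[[t0 + lag]] - pos[[t0]])^2)), 0))
  }, 0)
  data.frame(time_fs = c(0, lags * dt), msd = c(0, out))
}

#' Receptive field of an interatomic potential
#'
#' For atom-centered message passing, information propagates layer by layer,
#' so the effective cutoff is `n_layers * r_cut`; a strictly local model's
#' receptive field stays `r_cut` regardless of depth. The companion
#' volume ratio `(r_eff/r_cut)^3` counts how many more atoms' states a
#' parallel worker must access in the message-passing case.
#'
#' @param n_layers Number of layers (>= 1).
#' @param r_cut Local cutoff radius (Angstrom).
#' @param architecture `"message_passing"` or `"strictly_local"`.
#' @return Effective cutoff radius (Angstrom).
#' @examples
#' receptive_field(6, 6, "message_passing")  # 36
#' receptive_field(6, 6, "strictly_local")   # 6
#' neighbor_volume_ratio(36, 6)              # 216
#' @export
receptive_field <- function(n_layers, r_cut,
                            architecture = c("message_passing", "strictly_local")) {
  architecture <- match.arg(architecture)
  if (n_layers < 1L) .stopf("n_layers must be >= 1")
  if (r_cut <= 0) .stopf("r_cut must be > 0")
  if (architecture == "message_passing") n_layers * r_cut else r_cut
}

#' @rdname receptive_field
#' @param r_eff Effective cutoff radius (Angstrom).
#' @export
neighbor_volume_ratio <- function(r_eff, r_cut) (r_eff / r_cut)^3
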