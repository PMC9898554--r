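# Atomic configurations, species encoding, periodic neighbor lists, and
# extended-XYZ reading/writing. Internal units are Angstrom and eV throughout;
# atom indices are 1-based in R but written 0-based nowhere (extended-XYZ has
# no indices).

#' Atomic configuration
#'
#' @param species Character vector of chemical symbols (length N).
#' @param positions N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell Optional 3 x 3 matrix of lattice row-vectors (Angstrom);
#'   required iff any `pbc` flag is `TRUE`.
#' @param pbc Logical length-3 periodic-boundary flags.
#' @param energy Optional total energy (eV).
#' @param forces Optional N x 3 matrix of forces (eV/Angstrom).
#' @return An object of class `"atomic_system"`.
#' @export
atomic_system <- function(species, positions, cell = NULL,
                          pbc = c(FALSE, FALSE, FALSE),
                          energy = NULL, forces = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  n <- nrow(positions)
  if (n < 1L) .stopf("system must contain at least one atom")
  species <- as.character(species)
  if (length(species) != n) .stopf("species/positions length mismatch")
  pbc <- as.logical(pbc)
  if (length(pbc) != 3L) .stopf("pbc must have length 3")
  if (any(pbc) && is.null(cell)) .stopf("periodic system requires a cell")
  if (!any(pbc)) cell <- NULL
  if (!is.null(cell)) {
    cell <- matrix(as.numeric(cell), 3L, 3L)
    if (abs(det(cell)) < 1e-10) .stopf("cell is singular")
  }
  if (!is.null(forces)) {
    forces <- matrix(as.numeric(forces), ncol = 3L)
    if (nrow(forces) != n) .stopf("forces shape must match positions")
  }
  if (!is.null(energy)) energy <- as.numeric(energy)[1L]
  structure(list(species = species, positions = positions, cell = cell,
                 pbc = pbc, energy = energy, forces = forces),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat("<atomic_system ", nrow(x$positions), " atoms [",
      paste(unique(x$species), collapse = ","), "]",
      if (any(x$pbc)) " periodic" else "",
      if (!is.null(x$energy)) sprintf(" E=%.6g eV", x$energy) else "",
      ">\n", sep = "")
  invisible(x)
}

n_atoms <- function(system) nrow(system$positions)

#' Species map (one-hot encoding order)
#'
#' Fixes a stable, ordered bijection between chemical symbols and one-hot
#' dimensions.
#'
#' @param symbols Character vector of chemical symbols (order preserved,
#'   duplicates dropped).
#' @return An object of class `"species_map"`.
#' @export
species_map <- function(symbols) {
  symbols <- unique(as.character(symbols))
  structure(list(symbols = symbols), class = "species_map")
}

species_codes <- function(map, species) {
  codes <- match(species, map$symbols)
  if (anyNA(codes))
    .stopf("species not in map: %s",
           paste(unique(species[is.na(codes)]), collapse = ", "))
  codes
}

one_hot <- function(map, species) {
  codes <- species_codes(map, species)
  S <- length(map$symbols)
  m <- matrix(0, length(codes), S)
  m[cbind(seq_along(codes), codes)] <- 1
  m
}

# integer shift ranges needed per periodic axis so that every image within
# r_cut is enumerated (supports cells smaller than 2 * r_cut)
.shift_ranges <- function(cell, pbc, r_cut) {
  n <- c(0L, 0L, 0L)
  if (!is.null(cell)) {
    inv <- solve(cell)
    for (a in 1:3) if (pbc[a]) {
      width <- 1 / sqrt(sum(inv[, a]^2))  # perpendicular plane spacing
      n[a] <- as.integer(ceiling(r_cut / width))
    }
  }
  n
}

#' Build a directed neighbor list
#'
#' Contains exactly the directed pairs `(i, j, shift)` with
#' `0 < |r_j - r_i + shift %*% cell| < r_cut` (strict inequality; pairs
#' exactly at the cutoff contribute zero through the envelope anyway). Both
#' orientations `(i, j)` and `(j, i)` are stored because the pairwise
#' energies of the model are direction-dependent. Cells smaller than
#' `2 * r_cut` are handled by explicit multi-image shift enumeration.
#'
#' @param system An [atomic_system()].
#' @param r_cut Cutoff radius (Angstrom, > 0).
#' @return An object of class `"neighbor_list"`: list with integer vectors
#'   `i`, `j`, integer matrix `shift`, displacement matrix `rvec`
#'   (`r_j - r_i + shift %*% cell`), and distances `r`.
#' @export
build_neighbor_list <- function(system, r_cut) {
  if (!is.numeric(r_cut) || r_cut <= 0) .stopf("r_cut must be > 0")
  pos <- system$positions
  n <- nrow(pos)
  rng <- .shift_ranges(system$cell, system$pbc, r_cut)
  shifts <- as.matrix(expand.grid(s1 = -rng[1L]:rng[1L], s2 = -rng[2L]:rng[2L],
                                  s3 = -rng[3L]:rng[3L]))
  ii <- jj <- integer(0); sh <- NULL; rv <- NULL
  for (s in seq_len(nrow(shifts))) {
    off <- if (is.null(system$cell)) c(0, 0, 0) else
      as.numeric(shifts[s, ] %*% system$cell)
    zero_shift <- all(shifts[s, ] == 0L)
    # displacement from every i to every j under this shift
    dx <- outer(pos[, 1L], pos[, 1L], function(a, b) b - a) + off[1L]
    dy <- outer(pos[, 2L], pos[, 2L], function(a, b) b - a) + off[2L]
    dz <- outer(pos[, 3L], pos[, 3L], function(a, b) b - a) + off[3L]
    d2 <- dx^2 + dy^2 + dz^2
    keep <- d2 < r_cut^2
    if (zero_shift) diag(keep) <- FALSE
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx)) {
      ii <- c(ii, idx[, 1L]); jj <- c(jj, idx[, 2L])
      sh <- rbind(sh, matrix(rep(as.integer(shifts[s, ]), each = nrow(idx)),
                             ncol = 3L))
      rv <- rbind(rv, cbind(dx[idx], dy[idx], dz[idx]))
    }
  }
  if (is.null(rv)) {
    rv <- matrix(numeric(0), 0L, 3L)
    sh <- matrix(integer(0), 0L, 3L)
  }
  ord <- order(ii, jj, sh[, 1L], sh[, 2L], sh[, 3L])
  structure(list(i = ii[ord], j = jj[ord],
                 shift = sh[ord, , drop = FALSE],
                 rvec = rv[ord, , drop = FALSE],
                 r = sqrt(rowSums(rv[ord, , drop = FALSE]^2)),
                 n_atoms = n, r_cut = r_cut),
            class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat("<neighbor_list ", length(x$i), " directed pairs, ", x$n_atoms,
      " atoms, r_cut=", x$r_cut, " A>\n", sep = "")
  invisible(x)
}

#' Average neighbor count of a dataset
#'
#' Arithmetic mean of per-atom neighbor counts over all atoms of all frames;
#' the constant by which the model normalizes its neighbor sums.
#'
#' @param dataset List of [atomic_system()]s (a single system is accepted).
#' @param r_cut Cutoff radius (Angstrom).
#' @return Scalar mean neighbor count.
#' @export
average_neighbor_count <- function(dataset, r_cut) {
  if (inherits(dataset, "atomic_system")) dataset <- list(dataset)
  if (!length(dataset)) .stopf("empty dataset")
  tot_pairs <- 0; tot_atoms <- 0
  for (sys in dataset) {
    nl <- build_neighbor_list(sys, r_cut)
    tot_pairs <- tot_pairs + length(nl$i)
    tot_atoms <- tot_atoms + n_atoms(sys)
  }
  tot_pairs / tot_atoms
}

# ---- extended-XYZ ----------------------------------------------------------

# tokenize a key=value comment line, honoring double quotes
.extxyz_parse_comment <- function(line) {
  out <- list(); i <- 1L; n <- nchar(line)
  chars <- strsplit(line, "")[[1L]]
  while (i <= n) {
    while (i <= n && chars[i] == " ") i <- i + 1L
    if (i > n) break
    j <- i
    while (j <= n && chars[j] != "=" && chars[j] != " ") j <- j + 1L
    if (j > n || chars[j] != "=") { i <- j + 1L; next }  # bare token; skip
    key <- paste(chars[i:(j - 1L)], collapse = "")
    j <- j + 1L
    if (j <= n && chars[j] == "\"") {
      k <- j + 1L
      while (k <= n && chars[k] != "\"") k <- k + 1L
      val <- if (k > j + 1L) paste(chars[(j + 1L):(k - 1L)], collapse = "") else ""
      i <- k + 1L
    } else {
      k <- j
      while (k <= n && chars[k] != " ") k <- k + 1L
      val <- paste(chars[j:(k - 1L)], collapse = "")
      i <- k
    }
    out[[key]] <- val
  }
  out
}

#' Read an extended-XYZ file
#'
#' Reads the ase-dialect extended-XYZ format: per-frame header keys
#' `Lattice` (9 numbers, row-vectors), `Properties` (e.g.
#' `species:S:1:pos:R:3:forces:R:3`), `energy`, and `pbc`. Files without a
#' lattice yield non-periodic systems.
#'
#' @param path File path.
#' @return List of [atomic_system()]s.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1L) .stopf("malformed atom count at line %d", ln)
    if (ln + 1L + nat > length(lines) + 1L)
      .stopf("truncated frame at line %d", ln)
    hdr <- .extxyz_parse_comment(lines[ln + 1L])
    props <- strsplit(hdr$Properties %||% "species:S:1:pos:R:3", ":")[[1L]]
    if (length(props) %% 3L != 0L) .stopf("malformed Properties key")
    pnames <- props[seq(1L, length(props), 3L)]
    pwidth <- as.integer(props[seq(3L, length(props), 3L)])
    body <- lines[(ln + 2L):(ln + 1L + nat)]
    toks <- strsplit(trimws(body), "[ \t]+")
    ncol_expect <- sum(pwidth)
    if (any(lengths(toks) != ncol_expect))
      .stopf("inconsistent column count in frame starting line %d", ln)
    tab <- do.call(rbind, toks)
    col <- 1L; fields <- list()
    for (k in seq_along(pnames)) {
      fields[[pnames[k]]] <- tab[, col:(col + pwidth[k] - 1L), drop = FALSE]
      col <- col + pwidth[k]
    }
    if (is.null(fields$species) || is.null(fields$pos))
      .stopf("frame lacks species/pos properties")
    cell <- NULL; pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(hdr$Lattice)) {
      cl <- as.numeric(strsplit(trimws(hdr$Lattice), "[ \t]+")[[1L]])
      if (length(cl) != 9L) .stopf("malformed Lattice key")
      cell <- matrix(cl, 3L, 3L, byrow = TRUE)
      pbc <- c(TRUE, TRUE, TRUE)
      if (!is.null(hdr$pbc))
        pbc <- toupper(strsplit(trimws(hdr$pbc), "[ \t]+")[[1L]]) %in% c("T", "TRUE")
    }
    frames[[length(frames) + 1L]] <- atomic_system(
      species = as.character(fields$species),
      positions = apply(fields$pos, 2L, as.numeric),
      cell = cell, pbc = pbc,
      energy = if (!is.null(hdr$energy)) as.numeric(hdr$energy) else NULL,
      forces = if (!is.null(fields$forces))
        apply(fields$forces, 2L, as.numeric) else NULL)
    ln <- ln + 2L + nat
  }
  frames
}

#' Write systems to an extended-XYZ file
#'
#' @param systems An [atomic_system()] or list thereof.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(systems, path) {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  num <- function(x) sprintf("%.17g", x)
  out <- character(0)
  for (sys in systems) {
    n <- n_atoms(sys)
    keys <- character(0)
    if (!is.null(sys$cell))
      keys <- c(keys, paste0("Lattice=\"",
                             paste(num(as.vector(t(sys$cell))), collapse = " "), "\""))
    props <- "species:S:1:pos:R:3"
    if (!is.null(sys$forces)) props <- paste0(props, ":forces:R:3")
    keys <- c(keys, paste0("Properties=", props))
    if (!is.null(sys$energy)) keys <- c(keys, paste0("energy=", num(sys$energy)))
    if (any(sys$pbc))
      keys <- c(keys, paste0("pbc=\"", paste(ifelse(sys$pbc, "T", "F"),
                                             collapse = " "), "\""))
    rows <- sapply(seq_len(n), function(a) {
      line <- paste(c(sys$species[a], num(sys$positions[a, ])), collapse = " ")
      if (!is.null(sys$forces))
        line <- paste(c(line, num(sys$forces[a, ])), collapse = " ")
      line
    })
    out <- c(out, as.character(n), paste(keys, collapse = " "), rows)
  }
  writeLines(out, path)
  invisible(path)
}
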