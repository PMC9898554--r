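Package: allegror
Title: Strictly Local Equivariant Neural-Network Interatomic Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Allegro family of strictly local, pairwise-decomposed,
    E(3)-equivariant many-body interatomic potentials in pure R: the algebra of
    O(3) irreducible representations (real spherical harmonics, Wigner 3j
    coupling, tensor products), Bessel radial bases with smooth polynomial
    cutoff envelopes, periodic neighbor lists and extended-XYZ input/output,
    the full per-pair two-track (scalar/equivariant) network with exact
    reverse-mode forces, joint energy/force training with Adam, synthetic
    Lennard-Jones and Morse reference data, brute-force atomic-cluster-expansion
    and feature-expansion oracles for verifying the layer recursion and body
    order, and a minimal molecular-dynamics driver with radial/angular
    distribution and mean-square-displacement observables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: graphics, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), ggplot2, withr
Config/testthat/edition: 3
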