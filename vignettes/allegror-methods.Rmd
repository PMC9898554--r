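---
title: "Methods: a strictly local equivariant pair-energy potential in R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a strictly local equivariant pair-energy potential in R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allegror)
```

This vignette records the model, its assumptions, and — explicitly — every
numerical convention and design decision that the architecture's published
description leaves open. Nothing stated here as an empirical result goes
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## The model

The potential energy of a configuration is decomposed into per-atom and
then into *directed pair* energies,

$$E_\mathrm{system} = \sum_i \sigma_{Z_i} E_i + \mu_{Z_i}, \qquad
  E_i = \frac{1}{\sqrt{\langle|\mathcal N|\rangle}}
        \sum_{j \in \mathcal N(i)} \sigma_{Z_i Z_j}\, E_{ij},$$

where $\mathcal N(i)$ is the set of neighbors within a fixed cutoff
$r_\mathrm{cut}$, $\mu_Z,\sigma_Z$ are per-species shift/scale constants,
and $\langle|\mathcal N|\rangle$ is the average neighbor count of the
training data. $E_{ij}$ depends only on the environment of the *center*
atom $i$, so $E_{ij} \neq E_{ji}$ by design, and perturbing any atom outside
$\mathcal N(i)$ leaves $E_{ij}$ bit-identical — the strict locality that
makes the receptive field $r_\mathrm{cut}$ independent of network depth
(`receptive_field()`), in contrast to the $n_\mathrm{layers} \cdot
r_\mathrm{cut}$ of atom-centered message passing.

Each ordered pair carries two latent tracks. The scalar track starts from a
two-body embedding

$$x^{ij,0} = \mathrm{MLP}_\mathrm{two\text{-}body}\!\left(
  \mathrm{1Hot}(Z_i)\,\|\,\mathrm{1Hot}(Z_j)\,\|\,B(r_{ij})\right)
  \cdot u(r_{ij}),$$

with $B$ the normalized enveloped Bessel basis and $u$ the polynomial
cutoff envelope. The equivariant track starts as weighted spherical
harmonics of the pair direction, $V^{ij,0}_{n,\ell,p} = w^{ij,0}_{n,\ell,p}
Y_{\ell}(\hat r_{ij})$, with weights given by a linear projection of
$x^{ij,0}$. Each layer $L$ then:

1. projects the previous scalars of every pair $ik$ to environment weights
   $w^{ik,L}$ (a single bias-free matrix, no hidden layer);
2. forms the embedded environment $A_i = \sum_{k}\, w^{ik,L}
   Y(\hat r_{ik}) / \sqrt{\langle|\mathcal N|\rangle}$ — a learned-weight
   atomic-density projection, the "density trick" applied to a per-pair
   model;
3. takes the channel-wise tensor product $V^{ij,L-1} \otimes A_i$ over
   *all* symmetry-allowed coupling paths
   $(\ell_1,p_1)\times(\ell_2,p_2)\to(\ell_o,p_1p_2)$ with $\ell_o \le
   \ell_\mathrm{max}$, using real-basis Wigner-3j tensors;
4. concatenates the scalar ($0^+$) path outputs after $x^{ij,L-1}$, applies
   the latent MLP, multiplies by $u(r_{ij})$, and updates the scalar track
   residually;
5. mixes the non-final layer's path outputs per output irrep with a learned
   linear map over (path, channel).

The pair energy is a bias-free MLP on the final scalars,
$E_{ij} = \mathrm{MLP}_\mathrm{output}(x^{ij,N})$, and forces are the exact
reverse-mode gradient $F_a = -\nabla_a E_\mathrm{system}$. Because every
term of $x^{ij,L}$ carries at least one envelope factor and all linear maps
are bias-free, $E_{ij} \to 0$ smoothly as $r_{ij}\to r_\mathrm{cut}$, and
the total energy is smooth as atoms enter or leave each other's cutoff
spheres.

## Conventions in the equivariant algebra

The published description fixes neither the spherical-harmonic convention
nor the component ordering; the package adopts, consistently everywhere:

- components ordered $m = -\ell,\dots,\ell$ (sine components first), **no
  Condon–Shortley phase**;
- *component normalization*: each $\ell$-block of $Y_\ell(\hat u)$ has
  squared norm $2\ell+1$ on unit input, so individual components are O(1).
  Concretely the $\ell=1$ block is $\sqrt3\,(y, z, x)$;
- parity bookkeeping $p = (-1)^\ell$ for harmonics, $p_o = p_1 p_2$ for
  products; an SE(3) mode (`parity = "SE3"`) simply leaves the parity index
  unset everywhere;
- path ordering is lexicographic in $(\ell_1,p_1,\ell_2,p_2,\ell_o,p_o)$,
  and every path-dependent sum uses this order, making runs reproducible to
  the bit.

The real-basis Wigner-3j tensors are obtained by solving the rotational
equivariance constraint directly (null space of the constraint stacked over
a fixed set of generic rotations, with Wigner-D matrices built from the
package's own harmonics), normalized to orthonormal output slices with a
deterministic sign. This construction cannot drift out of phase with the
harmonic convention; orthogonality, recovery of the dot and cross product,
and tensor-product equivariance to $10^{-10}$ are asserted in the test
suite for all $\ell \le 4$. A closed-form complex-basis construction with
an explicit change of basis would be equivalent; the constraint solution
was chosen because it is self-consistent by construction.

All arithmetic is 64-bit. R has no native 32-bit floating type, so no
reduced-precision mode is offered; all tolerances in the test suite are
stated for 64-bit arithmetic.

## Radial basis and normalization

$b_n(r) = \sqrt{2/r_c}\,\sin(n\pi r/r_c)/r$ with the envelope
$u(x) = 1 - \tfrac{(p+1)(p+2)}{2}x^p + p(p+2)x^{p+1} -
\tfrac{p(p+1)}{2}x^{p+2}$, which satisfies $u(0)=1$ and
$u=u'=u''=0$ at the cutoff; smaller $p$ decays sooner. The enveloped basis
is affinely rescaled per function to zero mean and unit variance with $r$
uniform on $(0, r_c]$, computed once by a fixed $2^{20}$-point midpoint
quadrature and cached. This realizes the stated goal that all internal
quantities enter with approximately zero mean and unit variance; the
specific sampling measure is this package's choice. Trainable Bessel
frequencies are supported (`trainable_basis = TRUE`) with the normalization
constants frozen at the initial frequencies; the published configurations
all use eight non-trainable functions.

## Internal normalization and initialization

Every learned linear map scales its output by $1/\sqrt{\mathrm{fan~in}}$;
neighbor sums and the per-atom energy sum divide by
$\sqrt{\langle|\mathcal N|\rangle}$; path mixing divides by
$\sqrt{n_\mathrm{paths} \cdot n_\mathrm{channels}}$; the residual update is
$x \mapsto (x + \mathrm{new})/\sqrt2$ (the variance-preserving additive
choice; widths always match because the latent MLP's output width equals
the scalar latent width). Weights are initialized i.i.d. from the uniform
distribution with unit variance, $U(-\sqrt3,\sqrt3)$, deterministically
under the model seed.

MLP nonlinearities (SiLU by default) are applied *between* layers, not
after the last listed one. A consequence worth making explicit: a latent
MLP with a single hidden width (as in the small fixed-composition presets)
consists of one matrix and is therefore linear, which makes those models
finite-body-order — consistent with the published observation that models
whose only nonlinearities sit in the two-body MLP remain accurate. The
deeper latent stacks of the large-molecule presets contain interior SiLUs
and are genuinely nonlinear.

## Parameter accounting

`count_parameters()` constructs the full set of weight-tensor shapes and
sums them, returning an itemized breakdown. Three conventions, not fixed by
the architecture's prose, had to be resolved; the package resolves them so
that the three published totals (9058; 7,375,237; 17,926,533) are
reproduced *exactly*, which is a strong joint constraint — the system of
three counts pins down all three choices:

1. there are $N_\mathrm{layers}+1$ environment-weight projections: one for
   the initial equivariant embedding plus one per layer;
2. the embedded environment of the *first* layer passes through a per-irrep
   channel-mixing linear ($n_\mathrm{eq}^2$ weights per harmonic irrep);
   later layers do not;
3. equivariant path mixing exists at every layer except the last (whose
   equivariant output feeds nothing), with output irreps pruned to those
   that can still couple down to a scalar within the remaining layers
   (backward reachability through the harmonic irreps);

plus: all MLPs are bias-free, and the per-species energy shifts count as
trainable parameters only in the variable-composition presets (where they
are fit by composition regression and refined by training), adding exactly
$S$ parameters there. The Open Question about "1 feature of even parity"
with $\ell_\mathrm{max}=1$ is immaterial for counting: with harmonic-parity
irreps the E(3) and SE(3) bookkeepings give identical shapes at
$\ell_\mathrm{max}\le 1$, so both interpretations yield 9058.

## Forces and training gradients

Forces come from a small reverse-mode tape (R environments recording
backward closures); the per-edge displacement vectors are leaves, so one
backward pass yields $\partial E/\partial \vec r_{ij}$ for every edge and
$F_a$ by scatter-add. The finite-difference check (max deviation
$<10^{-6}$ eV/Å at $h=10^{-5}$ Å) and the NVE drift bound are the
operational arbiters, both in the acceptance tests.

The force term of the joint loss needs
$\partial^2 E/\partial\theta\,\partial r$. Rather than a second-order tape,
the engine is *complex-step safe*: running the identical forward+backward
pass at positions displaced by $\mathrm i h v$ (with $v$ the force-residual
direction and $h = 10^{-100}$) and taking $\mathrm{Im}(\cdot)/h$ of the
parameter gradients yields the exact directional derivative with no
subtractive cancellation — machine-precision second-order information from
first-order code. The gradient check against finite differences of the
total loss (relative error $<10^{-6}$, in practice $\sim10^{-8}$) covers
this path.

Training uses Adam ($\beta_1=0.9$, $\beta_2=0.999$, $\epsilon=10^{-8}$, no
weight decay), per-epoch reshuffling with derived seeds (`seed + epoch`),
an on-plateau scheduler driven by the validation loss of the EMA weights,
and an exponential moving average of the parameters for validation and the
returned model. The loss follows the stated forms exactly: per-batch means
(energy term divided by the number of frames, force term by
$3\sum_b N_b$), with the per-atom variant dividing each frame's energy
residual by its atom count before squaring. Batches of variable-size
systems are assembled by concatenation with per-frame offsets. The EMA
weights are used for the plateau signal (the raw-weight alternative is a
one-line change; the log records validation metrics of the EMA model).

## Synthetic data: what it emulates and what it does not

The generator produces liquid-like random clusters or boxes (rejection
sampling under a minimum-distance constraint), perturbed simple-cubic/FCC
crystals (optionally with vacancies), and dimer distance scans, labelled
analytically by Lennard-Jones or Morse pair potentials. Labels are exact
gradients by construction, and the toy potentials are *smoothly truncated
with the same envelope family as the model's radial basis*, so the ground
truth is itself strictly local and learnable to near-zero error — which is
what makes the learning smoke test meaningful: failure to learn indicates a
defect in the model or optimizer, not an expressivity gap.

What the toys do not emulate: electronic effects, charge transfer,
long-range electrostatics, many-body reference interactions (the labels
are pairwise), or realistic phonon spectra. Passing tests on these data
therefore demonstrate the *mechanics* (symmetry, conservation, locality,
optimization) and say nothing about accuracy on ab-initio labels.

Study conditions of the learning test, chosen once: 200 frames of 4-atom
truncated-LJ clusters ($\epsilon=0.5$ eV, $\sigma=1$ Å, $r_c=2.5$ Å,
$p=6$, box 3.2 Å, minimum distance 0.9 Å, seed 123), the small
fixed-composition architecture (1 layer, $\ell_\mathrm{max}=1$, 1 channel,
two-body MLP 32–64, latent 64, output hidden 32), per-atom loss with unit
energy and force weights, Adam at $5\times10^{-3}$, batch 50, 80 epochs.
The acceptance criterion is a $\ge 5\times$ drop of the validation force
MAE from its initialization value; the observed drop is well above that.

## Theory oracles

Two independent routes are kept genuinely independent:

- **ACE**: `ace_B_density()` builds body-ordered scalar descriptors by
  iterated couplings of the density projection $A_{znl}$; `ace_B_tuples()`
  computes the same quantities as explicit sums over neighbor tuples
  (exponential cost, hard-capped with an explicit error). Their agreement
  to $10^{-10}$ for $\nu\le3$ is the bilinearity ("density trick")
  identity. The radial–chemical basis is the package's enveloped Bessel
  basis times a species indicator; the correspondence is
  convention-agnostic as long as both routes share it.
- **Recursion vs expansion**: `allegro_expand()` evaluates the layer
  recursion's equivariant features as the explicit neighbor-tuple sum,
  using the environment weights and mixing matrices the model itself
  computed, and must match the recursive features to $10^{-9}$ (budgeted to
  $L\le2$, $\le4$ neighbors). The summation convention inside the tuple
  expansion (which layer's weights attach to which tuple index, where the
  first layer's channel mixer folds in) is resolved exactly by requiring
  this equality.
- **Body order**: `body_order_probe()` scales the contribution of every
  environment atom *except the paired neighbor* by $t$, so $t=0$ reduces
  the pair to its isolated-dimer featurization, and fits $E_{ij}(t)$ by
  polynomials of increasing degree. With linear embedding/latent MLPs the
  response is a polynomial of degree $2^L-1$ under this probe (degree 1 for
  one layer, 3 for two), recovered at machine precision; with an interior
  SiLU no tested degree fits. The probe's default scaling grid extends to
  $t=4$: over a narrow range any smooth response is numerically
  polynomial, and the wide range is what separates exact polynomials
  (residual $\sim10^{-14}$) from approximated smooth ones (residual
  $\gtrsim10^{-10}$); the threshold sits between at $10^{-11}$.

## Neighbor lists, units, and I/O

Distances use a strict comparison $r < r_\mathrm{cut}$ (pairs exactly at
the cutoff contribute zero through the envelope, so inclusion is
immaterial); both orientations of every pair are stored; cells smaller than
$2 r_\mathrm{cut}$ are handled by explicit integer-shift enumeration, with
the shift range derived from perpendicular plane spacings. Units are fixed:
Å, eV, fs, amu (1 eV/Å / amu = 0.0096485 Å/fs²). Extended-XYZ follows the
ase dialect (`Lattice`, `Properties`, `energy`, `pbc` keys); checkpoints
are a documented JSON container (configuration + flat parameter arrays at
17 significant digits + seed), chosen over a binary format so that models
remain diffable, portable text.

## Observables

The RDF estimator normalizes per-frame histograms by ideal-gas shell counts
at the frame's density and averages over frames (default bin 0.05 Å);
`r_max` beyond half the smallest cell dimension is an error. The ADF counts
each unordered pair of distinct neighbors of a central atom once — the
triplet-selection convention is noted in the function documentation since
double-counting conventions differ across codes — and returns a density on
[0°, 180°] integrating to 1. The MSD averages over atoms and multiple time
origins with a configurable stride, on unwrapped coordinates (the MD driver
records them; wrapped input without image bookkeeping is rejected by
construction). An equilibration-discard parameter is available on RDF/ADF.
The MD driver offers NVE (where total-energy conservation is the test of
gradient exactness) and Berendsen velocity rescaling; fancier thermostats
are out of scope.

## Problem sizes in the test suite

Chosen to exercise every code path at desk scale: clusters of 4–6 atoms;
models with 1–3 layers, $\ell_\mathrm{max}\le2$, 1–2 channels in the
property tests; 100 random-cell trials against the brute-force neighbor
oracle (4–16 atoms, skewed cells, multi-image cutoffs); 200 frames for the
learning test; 1000 NVE steps for the conservation bound; 200 random E(3)
operations for the symmetry suite. The full suite runs in about a minute on
one CPU.

## Known limitations

- Pure-R execution: fine for the desk-scale systems above (milliseconds per
  force call on a few atoms), not for production MD.
- No 32-bit mode (R lacks the type); no GPU or multi-process execution.
- `sigma_pair` per-species-pair scales are supported as fixed constants
  only, and trainable per-species shifts are the only trainable
  normalization parameters.
- The tuple-expansion and ACE-tuple oracles are exponential by design and
  hard-capped; they are verification tools, not production descriptors.
- Trainable Bessel frequencies keep their normalization constants frozen at
  initialization.
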