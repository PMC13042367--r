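---
title: "Conformational ensembles by iterative geometry resampling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensembles by iterative geometry resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `dynfold`, the parameters that
matter, the numerical conventions, and the design choices that were made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The geometry representation

Each residue pair carries four binned probability distributions: the
Cβ–Cβ distance *d* and the orientations ω, θ (dihedrals) and φ (planar
angle), in the binning popularised by distogram-based structure
prediction: 36 uniform 0.5 Å distance bins over [2, 20) Å, 24 periodic
15° bins for each dihedral, 12 bins for φ, each map closed by a terminal
catch-all ("no contact") bin. Two conventions are worth making explicit:

* **The catch-all bin is categorical, not ordinal.** Gaussian smoothing
  operates on the in-range bins only (circular wrap for ω/θ, reflection
  for *d*/φ) and never moves mass into or out of the catch-all; the full
  vector is renormalised afterwards. Whether the upstream method smooths
  across that bin is not documented anywhere we could verify, so the
  exclusion is this package's own convention.
* **Virtual Cβ.** Glycine (and idealised chain building generally) uses
  the standard tetrahedral Cβ construction from N, Cα, C, rescaled to a
  Cα–Cβ length of exactly 1.522 Å so that the bonded energy of an ideal
  chain is numerically zero.

## Restraint-based folding

Distributions become spline potentials −log((p + ε)/(p_ref + ε))
(natural cubic through bin centers; ε = 1e-4). For orientations the
reference is uniform over the in-range mass. For distances the reference
is the probability of the *terminal in-range bin*, which anchors the
potential to zero at the no-contact boundary; beyond 19.75 Å the
restraint applies no force. The alternative — referencing the catch-all
mass itself — inverts the well of any pair whose no-contact mass exceeds
its in-range peak (every contact of a 50/50 two-state mixture), so that
convention is unusable for multi-modal inputs. Distance and ω restraints
are built once per unordered pair; θ and φ in both directions; pairs
enter only if their contact probability (1 − catch-all mass) reaches a
gate of 0.05 (configurable; the gating threshold is not documented
upstream).

The degrees of freedom are Cartesian coordinates of the five backbone
atoms per residue, not torsions: gradients stay local and chain
regularity is enforced by harmonic bond/angle/improper terms (force
constants 100 Å⁻², 20 rad⁻², 20 rad⁻²), soft-sphere sterics (threshold
3 Å, k = 10, residue separation ≥ 2) and a peptide ω-planarity penalty
(k = 10, weight 0.5). Two L-BFGS stages run with restraint weights
AtomPair/Dihedral/Angle = 5/4/4 then 4/1/1, at most 1000 iterations per
stage. The stated 1e-4 convergence tolerance is applied as the
projected-gradient tolerance (`pgtol`); the upstream minimizer's
tolerance semantics are not restated anywhere, so this mapping is a
declared convention. Initial chains use random torsions (φ uniform in
the L-amino-acid half-plane, ψ unrestricted), so independent seeds give
independent basins of attraction. Chirality is selected by the
orientation restraints (dihedrals flip sign in a mirror image), and a CB
improper torsion keeps the L-configuration of the local frame.

## The decay-and-smooth sampler

One iteration: (i) compute the one-hot geometries realised by the latest
structure; (ii) for every pair and map whose distribution has L∞ norm
below 0.5, remove half of the mass at the realised bin, renormalise and
smooth (σ = 1 bin by default); distributions at or above 0.5 are returned
bit-identically, making sharp geometries exact fixed points; (iii)
generate the next conformation by restrained minimization. Iteration
stops when the largest absolute per-bin change across all pairs and maps
drops below 0.01 (the norm is not specified upstream; the L∞ reading is
the strictest common one and is configurable), or at a 200-iteration cap
(motivated by published trajectories converging around step 155).

Two design choices deserve explanation:

* **Each step minimizes two candidates** — a continuation of the previous
  structure and a fresh random-torsion chain — and keeps the lower-energy
  result. Pure cold restarts never satisfy the 0.01 criterion on
  two-state mixtures: every fold realises different bins, so the decay
  keeps moving and per-iteration changes plateau around 0.02–0.05
  indefinitely. Pure continuation converges but cannot cross between
  basins. The two-candidate step reproduces the published narrative of a
  system that first explores its starting basin, then escapes once that
  basin's restraints have decayed away: the warm candidate dominates
  while the basin is deep, and the cold candidate wins exactly when the
  alternative basin has become energetically preferable.
* **Chains.** How many independent sampling chains to run per geometry
  set is not documented; the package defaults to 1 and the acceptance
  experiment uses 4, emulating parallel runs from multiple starts. Chain
  histories are concatenated without deduplication.

After sampling, structures with energy above Q3 + IQR (quartiles by
linear interpolation) are discarded. Energies are comparable across an
ensemble because each is the final two-stage total under its own
iteration's restraints; early sharp-restraint folds score deeply
negative, late folds on flattened distributions do not, so the filter
mostly removes frustrated intermediates.

## What the synthetic fixtures emulate — and what they do not

`make_toy_states()` builds ideal poly-alanine backbones (glycine at the
hinge to exercise the virtual-Cβ path): a single helix, a helix hairpin,
and a two-state "hinge" — a helical hairpin domain with a 16-residue
C-terminal helix arm that switches between two packed poses when the
hinge residue's (φ, ψ) rotate symmetrically (±100°, 80° ± 40° at the
default angle of 60). The default fixture (L = 44) separates the states
by 9.3 Å Cα RMSD with clash-free geometry and near-equal contact counts,
i.e. energetically equivalent basins.

A geometric caveat discovered while designing the fixture: a featureless
two-helix "V" cannot serve as a two-state benchmark, because its two
bent states are related by a 180° rotation about the straight arm's axis
— optimal superposition collapses their RMSD to a few Å no matter how
far the arm swings (exactly 0 for an idealised planar V). The hairpin
domain exists to break that symmetry.

`mix_geometries()` converts states into smoothed one-hot mixtures
(default σ = 0.75 bins). At σ = 0.75 the centre weight of the discrete
Gaussian is ≈ 0.55, so pairs identical across states stay above the 0.5
stability threshold, while split pairs fall well below it — the property
the sampler relies on. At σ = 1 the centre weight is ≈ 0.40 and even
state-invariant pairs would decay; the mixture default was chosen
accordingly (the sampler's own smoothing σ remains 1).

The mixtures emulate the *output shape* of a geometry-predicting network
— smoothed, possibly multi-peaked per-pair distributions — not its
failure modes: there is no miscalibration, no correlated noise between
maps, no length-dependent sharpening, and the toy states are ideal
helices rather than loops and strands. Passing the two-state experiments
therefore demonstrates that the sampling loop extracts alternative
conformations that are genuinely encoded in multi-modal distributions;
it says nothing about the quality of any particular predictor's maps on
real proteins.

## Evaluation stack: conventions

* All RMSD/TM computations use Cα atoms under the supplied residue mask.
* TM-score is normalised by the (masked) reference length with
  d0 = 1.24 (L − 15)^⅓ − 1.8, floored at 0.5 Å; pairwise filtering uses
  the symmetrised min(TM(a,b), TM(b,a)). The score is maximised over
  superpositions seeded from full-, half-, quarter-length and all
  7-residue windows with iterative close-residue refinement.
* Mean reference structures come from iterative superpose-to-mean cycles
  (tolerance 1e-6 Å). Note a small subtlety verified in the tests: for a
  reference of two copies displaced ±d at one residue, the converged
  mean differs from the exact midpoint by a sub-1e-3 re-fitting
  residual, which is a property of superposition itself.
* Amide hydrogens are placed geometrically in the C(i−1)–N–Cα plane,
  opposite the angle bisector, |N–H| = 1.01 Å; residue 1 and prolines
  are undefined.
* The RDC alignment tensor is fitted by least squares to
  ensemble-averaged direction-cosine products (one shared tensor across
  conformers, the "ensemble fit" convention); fitting per conformer and
  averaging couplings is the other defensible reading and was not
  chosen. Q = RMS(D_exp − D_calc)/RMS(D_exp).
* The minimum cross-entropy geometry loss floors predicted probabilities
  at 1e-8.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
fixtures: random 6–16-residue backbones for metric oracles, a 30-residue
helix-hairpin for single-state recovery (best of 10 seeds), and the
44-residue two-state hinge for the sampling experiments (4 chains, cap
200, plus a 50-fold baseline). These sizes were chosen as the smallest
at which each property is non-trivial. Every stochastic step (torsion
initialisation, chain seeding) derives from a single integer seed;
identical seeds reproduce identical ensembles bit for bit.

## Known limitations

* The physical energy is a deliberately simple stand-in: no hydrogen
  bonding, no Ramachandran statistics beyond the harmonic frame terms,
  no side chains beyond Cβ. It keeps backbones regular and clash-free;
  it does not rank near-native conformations the way a full force field
  would.
* The coarse minimizer is good enough on 44-residue toys that 50
  independent cold folds of a 50/50 two-state mixture typically reach
  *both* reference basins a handful of times — a single-basin collapse
  of the no-iteration baseline, sometimes expected of such protocols on
  real proteins, does not occur at this problem size. The iterative
  sampler's advantage here is coverage *with* convergence and far higher
  ensemble diversity, not exclusive access to the second state.
* Multi-chain PDBs, insertion codes and mmCIF are out of scope; NMR
  restraints are consumed as plain residue-pair lists, not NEF/CYANA
  dialects.
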