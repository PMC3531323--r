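---
title: "Perturbation maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `esimap`, the parameters that
matter, the numerical choices, and the reasoning behind design decisions
that were genuinely open. It is the companion to the README's worked
example.

## The method in one paragraph

A protein's electrostatic "hot-spots" are clusters of like-charged residues
whose summed field resists perturbation: removing one of several co-located
charges rescales the local potential, while removing an isolated charge
erases it. `esimap` quantifies this by (i) building a *perturbation family*
— the parent structure plus N perturbed members: alanine-scan charge
neutralizations, conformational snapshots, or homologue models; (ii)
solving the linearized Poisson–Boltzmann equation (LPBE) for the parent and
every member on one shared grid centred on the parent, so the fields are
node-aligned; and (iii) averaging a per-node similarity between the parent
potential and each member potential into an electrostatic similarity index
(ESI) field, which is then summarized over surface shells and projected
onto residues for rendering.

## Structure preparation

Formal charges are the majority protonation state at the working pH under a
model-pKa table (Asp 3.65, Glu 4.25, His 6.30, Cys 8.3, Tyr 10.1, Lys
10.53, Arg 12.48, N-terminus 8.0, C-terminus 3.1). At the default pH 7.4
this charges Asp/Glu (−1) and Lys/Arg (+1) and leaves His, Cys and Tyr
neutral; no fractional charges are used. Each residue's formal charge is
split evenly over its canonical charged-group atoms (Asp OD1/OD2, Glu
OE1/OE2, Lys NZ, Arg NH1/NH2); the ESI method depends on where the monopole
sits, not on a full force-field charge distribution, and this keeps the
parameter set self-contained. When those atoms are missing — coarse or
synthetic structures — the charge falls back to CB, then CA. Radii are
per-element Bondi vdW radii. Termini are charged by default (+1/−1); for a
single chain they cancel in the net charge, so published integer net
charges are reproduced either way. Cystines are not detected; Cys is simply
neutral at pH 7.4. Unknown residue types get zero charge and a warning
rather than an error, so hetero-groups do not abort a run.

The alanine scan enumerates residues with nonzero formal charge — at pH 7.4
that excludes His by construction — and for each target removes the
side-chain atoms beyond CB, renames the residue ALA and re-assigns
parameters. No rotamer rebuilding is attempted: truncation at CB is the
standard approximation for charge-neutralization scans, and the backbone is
untouched.

## The solver

The discretized problem is
∇·(ε∇φ) − κ̄²φ = −4π ℓ_B ρ, with φ in kT/e, lengths in Å and
ℓ_B = e²/(4πε₀k_BT) ≈ 560.4 Å at 298.15 K (the vacuum Bjerrum length; the
familiar ~7.1 Å Bjerrum length of water is ℓ_B/ε).

* **Grid.** Odd node counts ≥ 33 per axis; the centre is the parent's
  geometric centre and the same `grid_spec` is reused for every family
  member. Production grids of 129³ with lengths that leave well over 10 Å
  of solvent margin are typical; the package warns below 10 Å.
* **Charges.** Trilinear spreading to the 8 enclosing nodes; the grid total
  equals the molecular net charge to rounding error.
* **Dielectric.** Protein dielectric 20 (appropriate for charge-mutation
  electrostatics of highly charged proteins, where a low value of 2
  over-polarizes), solvent 78.57. The low-dielectric region is the
  solvent-excluded volume: the union of vdW spheres dilated by the 1.4 Å
  probe (equivalently, spheres of radius r+probe) and then eroded by the
  probe — a morphological closing evaluated on the grid, with the erosion
  implemented by shifted-mask dilation of the complement. Face dielectrics
  on the stencil are harmonic means of the node values, the standard
  treatment for discontinuous coefficients.
* **Salt.** Default 0 mM. When nonzero, κ̄² = 8π ℓ_B n_ion (Å⁻²) in the
  ion-accessible region (outside vdW + a 2 Å Stern layer), zero inside;
  κ̄²/ε_solvent reproduces the Debye length (≈ 7.9 Å at 150 mM, 298.15 K).
* **Boundary.** Dirichlet values from the sum of single-sphere
  Debye–Hückel potentials of all atomic charges (the multiple-sphere
  boundary condition used across the APBS ecosystem).
* **Linear solve.** Jacobi-preconditioned conjugate gradients on the
  symmetric 7-point system (Rcpp), relative residual ≤ 1e−6, max 10,000
  iterations, zero interior initial guess. Non-convergence is an error that
  reports the residual, never a silent result.

Against a point charge in a homogeneous 78.57 dielectric the solver tracks
the Coulomb law within a few percent in the shell between 4 node spacings
and a quarter box length, with the error shrinking monotonically from 33³
to 65³ to 129³; with 150 mM salt it tracks the screened Debye–Hückel form
(the oracle comparison disables the Stern layer, which the analytic
solution does not model). Those checks run in the test suite and the
acceptance script.

## The similarity index

The per-node similarity of two potential values is the local Hodgkin index
2ab/(a² + b²) ∈ [−1, 1]. The published form of this family of indices is a
signed similarity, which matches the reported ESI colour ranges that extend
below zero for homologue families (−0.10…0.40) while perturbation maps
live high in the scale (0.5…0.9); an unsigned index could not produce
negative values. Where the exact per-node expression in the source work was
not recoverable (the equation is typeset as an image), the local Hodgkin
form was adopted as the natural member of that lineage; this is the
package's most consequential interpretation and is stated here openly.

Two numerical details:

* **Near-zero guard.** When both |a| and |b| < ε₀ = 1e−4 kT/e the pair
  scores 1: identically negligible potentials are "similar", and the guard
  prevents 0/0 noise at far-field nodes. The guard deliberately breaks
  strict sign anti-symmetry for negligible fields; the identity and
  anti-identity unit tests therefore use fields bounded away from ε₀.
* **Scale robustness.** The index is invariant when parent *and* members
  are rescaled by one positive factor, not when one side is rescaled alone;
  the property tests assert exactly that.

ESI(i,j,k) is the mean of the local index over the N members; N is the
family size (for a 23-model homologue family, N = 23). Member order only
permutes a floating-point summation, so fields agree to 1e−12, not
bit-exactly. An optional PIPSA-style "skin" mask restricts the comparison
to a shell σ…σ+δ beyond the vdW surface (defaults 3 Å and 4 Å); the default
is the whole grid.

## Surface summaries and projection

`region_summary()` reports statistics over nodes in a shell around a
residue selection, between `offset` and `offset + width` beyond the
selection's vdW surface (defaults 2 Å and 5 Å), excluding nodes buried
near the rest of the molecule. `project_to_atoms()` samples the field by
trilinear interpolation at points displaced outward from the structure's
centre through each atom, at vdW radius + 1.4 Å — "the potential just
outside the surface", which is what surface-coloured figures display —
and aggregates per residue by the mean (median optional). Rendering
conventions worth recording: potential surfaces are usually saturated at
±5 kT/e, isopotential contours drawn at ±1.5 kT/e, perturbation-map ESI
displayed on 0.5–0.7–0.9 and homologue ESI on −0.10–0.15–0.40 scales.

For the *hot-spot contrast* (cluster vs dispersed charges) the analysis
shell is 0–2 Å beyond the vdW surface, bracketing the 1.4 Å projection
offset. This is deliberate: the perturbation-resistance signal is a local
deficit around the removed charge and decays within a few Å; averaged over
the default 2–7 Å shell it is diluted to the noise level, while the
immediate surface shell — the one the projections actually sample — retains
it. The same contrast, with the same sign, appears in the per-residue
projected ESI.

## Sequence-side clustering

Pairwise identity = matching non-gap positions / columns where at least one
row is non-gap. Charge similarity = count of columns where both rows are in
{K,R} or both in {D,E}; gaps and ambiguity codes (B, Z, X) never count.
Functional faces come from the reference structure's frame: with mx the
mean x over all atoms, a residue is on the negative-x face if any atom has
x ≤ mx − 5 Å and on the positive-x face if any atom has x > mx + 5 Å
(strict); a residue qualifying for both — possible only for very extended
residues — is demoted to "neither" with a warning so the faces stay
disjoint. Alignment columns are selected through the reference row's
non-gap positions, mapped 1:1 and in order to structure residues.

Counts are turned into distances by d = 1 − c_ij / max(c_ii, c_jj):
normalizing by the larger self-count keeps d ∈ [0, 1] and removes sequence
length and net-charge effects, consistent with the observation that net
charge has little effect on charge-position clustering. Identity matrices
use d = 1 − s. Clustering is complete-linkage `stats::hclust` — the
default of the R clustering route this emulates; the original linkage is
not verifiable — with deterministic label-order tie-breaking, and trees are
exported as Newick via `ape`.

## Synthetic fixtures: what they emulate, and what they do not

The generators produce poly-alanine-like pseudo-residues (N, CA, C, O, CB)
with formal charges realised by residue naming, on a straight chain
(3.8 Å CA spacing) or scattered on a sphere:

* `make_hotspot_fixture()` places a `cluster_size`-charge acidic patch
  (≤ 8 Å diameter) and `n_dispersed` isolated acidic charges (pairwise
  ≥ 15 Å) on a 16 Å sphere with a neutral scaffold. All charges are acidic
  (net −10 for 5+5), which is the *hard* case for hot-spot detection: the
  shared-sign background raises the similarity at perturbed sites, so a
  detected contrast is conservative. The geometry is deterministic.
* `make_synthetic_family()` builds gapless homologue families with charges
  conserved at chosen columns and re-drawn uniformly from {−1, +1}
  elsewhere, emitting matching structures and alignment. For clustering
  tests, two *clades* are built by drawing two independent conserved
  layouts plus per-member noise columns. A single clade with fully
  i.i.d.-scrambled members was rejected: such a "group" has no internal
  cohesion, so no clustering method can be required to keep it together at
  the top split, and individual scrambled members can match the conserved
  layout by chance.

What the fixtures do **not** emulate: real protein geometry (no rotamers,
no packing), dipolar and higher-multipole charge distributions, hydrogens,
conformational coupling between sites, and homology-model error. Passing
tests on these fixtures therefore demonstrates the *mechanism* — solver
correctness, similarity bookkeeping, perturbation-resistance detection,
charge-position clustering — not performance on real structures, which
additionally needs prepared crystal structures as inputs.

## Problem sizes and determinism

The test suite and the acceptance script run the point-charge oracles at
65³, the hot-spot scan (11 LPBE solves) at 65³, the 23-member family
normalization at 33³ (the N-bookkeeping it checks is
resolution-independent), and the refinement study at 33³/65³/129³. These
sizes were chosen so a full run completes in minutes on one CPU while
keeping the oracle shells well inside the boundary. All stochastic steps
derive from a single seed; solver output is floating-point deterministic on
one machine, and fixture PDBs are byte-identical across reruns.

## Known limitations

* The LPBE only (no nonlinear PB); at the default 0 mM the distinction is
  moot.
* Single-level grids, no focusing; accuracy near the molecular surface is
  limited by the node spacing.
* The molecular surface is a grid-sampled morphological closing, not an
  analytic SES triangulation; on coarse grids (spacing larger than the
  probe) the closing degenerates toward the probe-inflated surface.
* Energies (solvation or binding free energies) are out of scope: the
  package computes potentials and similarity maps.
* The per-node ESI formula is an interpretation (see above); alternative
  normalizations would change absolute ESI values but not the
  perturbation-resistance ranking that defines hot-spots.
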