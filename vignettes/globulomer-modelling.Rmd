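---
title: "Building and analysing annular amyloid-beta globulomer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing annular amyloid-beta globulomer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globulomeR)
```

## The modelling problem

Soluble amyloid-beta (Aβ) globulomers are roughly spherical 12-mer
oligomers that appear early in Aβ aggregation and are more neurotoxic
than mature fibrils. Because they are small, transient and
heterogeneous, no experimental atomic structure exists; candidate
structures are instead built computationally by packing copies of the
β-strand–loop–β-strand Aβ(17–42) unit into an annulus and asking which
packings are energetically plausible and how they behave dynamically.

globulomeR implements that construction and its analysis end to end:

1. **Building blocks.** A U-bend Aβ(17–42) monomer (two antiparallel
   strands, residues 17–25 and 31–42, joined by the turn
   Ser26–Asn27–Lys28–Gly29–Ala30), or a dimer made by stacking two
   monomers in register at ~4.7 Å — the canonical β-sheet spacing.
2. **Annular replication.** The block is aligned with its strand axis
   parallel to z, placed so every chain's centre of mass sits at a
   10 Å core radius with the N-terminal strand facing outward, and
   replicated by rotation about z: 12-fold for monomer blocks, 6-fold
   for dimer blocks (12 peptides either way).
3. **Self-rotation scan.** Every block is rotated in place about its
   own strand axis in 5° steps, enumerating 72 candidates per block
   type with different core/interface chemistry.
4. **Screening.** Each candidate is scored with a coarse surrogate
   energy and ranked; low-scoring candidates are the models carried
   into trajectory analysis.

Downstream metrics quantify the resulting ensembles: RMSD/Rg
free-energy landscapes, per-residue RMSF, convex-hull sphericity,
region-resolved solvent-accessible surface area (SASA), sidechain
contact and hydrogen-bond maps, salt-bridge counts, a reference-based
dimer-detection rule with PCA clustering of dimer configurations, and
Boltzmann/Metropolis population estimates over pooled conformers.

## The synthetic template and what it does (not) emulate

Production studies of this system derive the monomer from NMR fibril
models and relax assemblies with solvated molecular dynamics. This
package is self-contained instead: `make_hairpin_template()` generates
an idealized hairpin, and `make_synthetic_trajectory()` generates
perturbed ensembles, so every stage runs and is testable without
external structures or MD.

The template is deliberately minimal:

* Strands run along a common axis at 3.4 Å rise per residue with an
  alternating pleat, so consecutive alpha-carbons sit 3.8 Å apart; the
  turn is a planar six-step horseshoe of the same step length whose
  turning angle is solved so the loop exactly bridges the 10 Å
  inter-strand separation. Every peptide bond lands near 1.33 Å.
* Backbone N, C and O are placed from the local chain tangent with
  offsets chosen to give N–CA 1.46 Å, CA–C 1.52 Å and C=O 1.23 Å;
  carbonyl oxygens point along the sheet normal, as in a stacked
  β-sheet.
* Sidechains are single pseudo-atom stubs (`CB`) at the sidechain
  centre-of-mass distance (2.4 Å by default), alternating sides within
  the hairpin plane. The contact, salt-bridge and dimer definitions all
  operate on sidechain centres of mass, which is exactly what the stubs
  represent. Glycine carries no stub. The Lys28Ala mutation
  (`mutate_lys28ala()`) renames residue 28, truncates its stub to the
  alanine centre distance (1.53 Å), and thereby removes its surrogate
  charge.
* With a 10 Å strand separation the hairpin's radial extent is about
  10 Å, so a 12-fold annulus at the 10 Å core radius has an outer
  diameter near 40 Å — the right overall size class for a globulomer.

Synthetic trajectories add independent per-coordinate Gaussian noise of
standard deviation σ to every frame after the first (so the expected
per-atom fluctuation is σ√3, a closed form the tests exploit), plus an
optional rigid outward per-chain drift that emulates a relaxing,
swelling assembly. What the generator does **not** emulate: correlated
backbone motion, secondary-structure rearrangement, solvent effects or
realistic force-field energetics. Passing tests therefore demonstrate
that the machinery measures what it claims to measure on controlled
inputs — not that the synthetic ensembles reproduce solution behaviour.

## The screening score

The original pre-screen minimised each candidate under an implicit
solvent model before comparing energies — a coarse filter whose job is
ranking, not absolute energies. globulomeR keeps that contract with a
documented surrogate (`assembly_energy()`):

* **van der Waals**: Lennard-Jones 12-6 on element-based σ/ε, smoothly
  switched off between 10 and 12 Å, with the repulsion clamped below
  0.8 Å so coincident atoms in unminimised rigid packings score a large
  finite penalty.
* **Electrostatics**: Debye-screened Coulomb (default screening length
  10 Å) on surrogate charges of ±1 e placed on the sidechain centres of
  Glu22/Asp23 (−) and Lys28 (+) — the residues whose electrostatics
  matter for this system — and zero elsewhere.
* **Bonded**: harmonic deviations of the reduced topology's bond
  lengths from the template constants (k = 100 kcal mol⁻¹ Å⁻²); zero
  for rigidly built assemblies by construction.
* **Solvation**: γ·SASA(hydrophobic) − δ·SASA(polar) with
  γ = 0.025 and δ = 0.005 kcal mol⁻¹ Å⁻², the order-of-magnitude
  convention for surface-area solvation terms; carbon and sulfur count
  as hydrophobic, nitrogen and oxygen as polar. Both coefficients are
  free parameters of the score.

Absolute values in kcal/mol are **not** comparable to any published
implicit-solvent energies; only the ordering and shape of score
profiles carry meaning.

Unminimised rigid annuli at a 10 Å core radius interpenetrate at the
core — the construction squeezes a ~10 Å-wide hairpin into ~5 Å of arc
at the inner radius — so raw candidate scores are dominated by clash
noise. `relax_assembly()` therefore provides the analogue of the
per-candidate minimisation step: a deterministic line search over a
symmetric radial expansion of all blocks (0–8 Å), optionally followed
by greedy per-block rigid moves. Relaxed screening
(`screen_candidates(relax = TRUE)`) reproduces the qualitative
behaviour the construction is known for: the monomer-based scan profile
is much more rugged than the dimer-based one, because a dimer block
carries half of its interfaces as a fixed, pre-formed sheet contact
while every interface of a monomer-based annulus changes with the scan
angle.

## Metric definitions and numerical choices

* **RMSD** (`rmsd_to_ref()`): minimum over rigid superpositions via the
  optimal least-squares rotation (SVD with a determinant correction),
  computed on the backbone by default. The fitting selection is a
  package choice; it is configurable.
* **Rg** (`radius_of_gyration()`): mass-weighted RMS distance from the
  centre of mass, over heavy atoms by default.
* **RMSF** (`rmsf_and_average()`): frames are superposed onto a running
  mean (three fit–average passes), RMSF is taken over alpha-carbons,
  and residues are banded low/medium/high at 3 and 6 Å.
* **Sphericity** (`sphericity()`): the surface area Sₚ and volume Vₚ of
  the convex hull of heavy atoms give Φ = π^(1/3)·(6Vₚ)^(2/3)/Sₚ, the
  classical sphericity: Φ ∈ (0, 1] by the isoperimetric inequality and
  Φ = 1 exactly for a sphere. The reported diameter Dₚ is the
  equal-volume sphere diameter, under which Φ = 6Vₚ/(Dₚ·Sₚ). The hull
  is built by an incremental algorithm in compiled code; degenerate
  (coplanar) inputs are an error rather than a silent zero. A convex
  hull slightly overestimates the envelope of a ring-like assembly
  relative to a solvent-excluded surface, which is acceptable because
  Φ is used comparatively (shape change over time).
* **SASA** (`sasa_atoms()`, `sasa_by_region()`): Shrake–Rupley sphere
  sampling with a 1.4 Å probe and 960 points per atom (golden-section
  spiral), element-based van der Waals radii. Region totals follow the
  reporting partition N-terminal 17–26 / turn 27–30 / C-terminal 31–42;
  the template-geometry partition (strands 17–25 and 31–42, turn 26–30)
  is kept as a distinct, separately accessible convention rather than
  reconciled, since both appear in the literature. Per-chain values and
  assembly totals are both emitted.
* **Secondary structure** (`secondary_structure()`): a reduced
  hydrogen-bond-pattern assignment. A backbone hydrogen bond requires
  donor–acceptor distance < 3.5 Å and a donor–H⋯acceptor angle at the
  (inferred) hydrogen > 120°; the amide hydrogen is reconstructed along
  the bisector of N→C(prev) and N→CA when absent, so heavy-atom inputs
  work. Ladders of non-local bonds mark strand, an i→i+4 bond marks
  helix, a >70° bend in the CA trace marks turn, else coil. This is a
  simplification of DSSP, adequate for population-level summaries on
  idealized geometry.
* **Salt bridges** (`salt_bridges()`): Asp23/Glu22 carboxylate-proxy
  centre within 4.0 Å of the Lys28 amine-proxy centre. No cutoff is
  stated in the source material for this count; 4 Å is the community
  convention and the parameter is configurable.
* **Contacts and hydrogen bonds** (`contact_hbond_map()`): sidechain
  contact below 6.0 Å between sidechain centres of mass; frequencies
  are averaged over frames **and** over unordered chain pairs, so they
  live in [0, 1] (on a 12-chain assembly this dilutes adjacent-pair
  signal by the number of chain pairs — a documented convention, not a
  bug). Per-frame averages are reported rather than last-frame
  snapshots.
* **Landscapes** (`landscape()`): 2-D histogram over (backbone RMSD,
  Rg); free energy −kT·ln(occupancy) with k = 0.0019872 kcal mol⁻¹ K⁻¹
  and T = 330 K by default (the elevated sampling temperature of the
  reference simulations), shifted so the minimum is zero. Empty bins
  are absent from the result, never reported as zero free energy.

## Dimer detection and populations

`build_reference_dataset()` samples an isolated-dimer ensemble into
paired lists of C-terminal (residues 31–42) sidechain contact counts
and interpeptide interaction energies — 5000 entries by default. The
call rule (`is_dimer()`) draws `n_draws = 3000` references with
replacement and succeeds per draw when the candidate pair has more
C-terminal contacts than the reference **or** a strictly lower
interaction energy (ties fail — the conservative reading of "more
favourable"); the pair is a dimer when over 75 % of draws succeed.
Draws are seeded, so calls are reproducible, and the exact binomial
form of the rule is used as a test oracle. `count_dimers()` evaluates
candidate chain pairs per frame — by default only pairs whose minimum
inter-atom distance is below 12 Å, which bounds cost and avoids
scoring far-apart pairs whose interaction energy of exactly zero would
compare favourably against a positive-valued synthetic reference set;
an exhaustive mode is available. Conflicts are resolved by greedy
matching on success fraction so each chain joins at most one dimer: a
tetramer of two touching dimers reports as two pairs, mirroring how
tetramers are described as dimer-of-dimer associations.

`pca_cluster_dimers()` superposes configurations, projects onto the
first two principal components of the coordinate covariance (the
coordinate-PCA reading; a distance-feature PCA would be an equally
defensible unstated alternative), k-means-clusters the scores with a
seeded start, and reports cluster medoids.

`estimate_populations()` defaults to Boltzmann weighting of pooled
conformer energies at 330 K, with energies shifted by the pool minimum
for numerical stability. Because the original "in-house Monte Carlo"
population procedure is unspecified, a Metropolis sampler over
conformer indices is provided as the literal Monte Carlo reading; the
two agree within Monte Carlo error on any pool, which the tests assert.
The default pool shape (6 models × 500 conformers = 3000) matches the
reference analysis; mutant models are excluded from pooling and shown
as "/" in `population_report()`, since their energies are not
comparable to the wild-type ensemble.

## Design decisions that were genuinely open

* **Stacking direction.** "Stacking on top of each other in register"
  is implemented as a rigid translation perpendicular to both the
  strand axis and the inter-strand separation — the direction in which
  stacked β-sheets hydrogen-bond — so matched residues sit directly
  above one another.
* **Block rotation.** In the 6-fold scan the dimer rotates as one rigid
  unit about the dimer's common strand axis through its centre of mass
  ("each building block is self-rotated"), not each monomer about its
  own axis.
* **Chain placement.** Every chain's centre of mass is placed exactly
  at the core radius (for a dimer block the block centre then sits
  slightly inside it); this makes the radius contract exact and
  testable per chain.
* **β-strand axis.** Operationally the principal axis of the block's
  alpha-carbons, sign fixed toward increasing residue number of the
  C-strand.
* **Scan ties.** Candidates with equal scores keep their angle order;
  no automatic "distinct morphology" selection is attempted — choosing
  representatives is left to the user.
* **Hydrogen-bond angle convention.** The angle criterion is applied at
  the hydrogen (donor–H⋯acceptor > 120°), the standard geometric
  criterion this family of definitions abbreviates.
* **Sphericity formula.** The classical Φ above is adopted; it is the
  unique standard shape index satisfying the stated properties
  (range (0, 1], equality at the sphere).

## Problem sizes and limitations

The package's own demonstration scale: templates of 125 atoms, 12-chain
assemblies of 1500 atoms, scans of 72 candidates, trajectories of tens
to hundreds of frames, reference sets of hundreds to 5000 entries.
`run_pipeline()` with default settings completes on one CPU in minutes;
the test suite uses reduced sizes (documented per test) with fixed
seeds throughout.

Known limitations: the surrogate score is not a force field and its
absolute scale is meaningless; synthetic reference energies are
positive (clash-dominated noise around an idealized packing) where
solution dimer references would be negative, which is why the proximity
pre-filter in `count_dimers()` matters; the secondary-structure rules
are a DSSP reduction tuned for idealized ladders; and convex-hull
sphericity ignores cavities. None of these affect the package's
contracts — threshold behaviour, invariances, closed-form recoveries
and directional trends — which is what the test suite pins down.
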