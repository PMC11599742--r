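---
title: "Annular lipid analysis of membrane-protein crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annular lipid analysis of membrane-protein crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annulipid)
```

## The problem

Microbial rhodopsins (MRs) -- seven-transmembrane-helix retinal proteins such
as bacteriorhodopsin -- are resolved in the PDB at resolutions where the
first shell of lipids around the protein, the *annular* lipids, becomes
visible as ordered hydrocarbon fragments in the electron density. Those
fragments carry quantitative information: how tightly chains pack against the
hydrophobic surface, where along the bilayer normal they bind, which crevices
of an oligomer they occupy, and how many of them a given crystallization
route preserves. `annulipid` turns those questions into reproducible
computations on deposited coordinates:

1. **Component classification.** Depositors model lipid fragments under
   three-letter chemical-component codes (`OLC`, `L2P`, `SQU`, ...). The
   package ships a curated dictionary of 39 codes observed across MR entries
   and classifies each into a lipid class (archaeal diphytanyl, linear acyl,
   carotenoid, squalene, detergent, sugar headgroup, small amphiphile,
   unknown). Chain geometry (methyl-branched vs linear) is detected directly
   from coordinates via a carbon--carbon bond graph.
2. **Partition and selection.** Structures (PDB or mmCIF, parsed with
   `bio3d`) are partitioned into protein / retinal / lipid / solvent / other
   HET sets, and a small selection grammar reproduces printed atom
   selections, including numeric name ranges such as `C12-C21`.
3. **Superposition and membrane frame.** Structures are aligned on backbone
   N, CA, C, O atoms plus retinal (Kabsch SVD solver, cross-checked against
   an independent quaternion solver), and each structure receives a membrane
   frame: a unit normal, a z-origin at the bilayer median, and
   hydrophobic--hydrophilic boundary depths.
4. **Annular statistics.** The annular shell is the set of lipid residues
   with any heavy atom within 5 Å of the protomer; lipid-to-surface packing
   is summarised as the mean ± sd of each lipid atom's nearest protein
   heavy-atom distance; lipids in oligomers are classified as
   inner-compartment, inter-protomer, or peripheral.
5. **Depth profiles.** Depths of proximal lipid carbons (and of noble-gas
   atoms from pressure-derivatized structures) are histogrammed across the
   bilayer and their modes detected.
6. **Census.** Lipid fragments are counted per class and divided by the
   protomer count with exact rational arithmetic (`2/3`, `10/3`), and a
   simple budget converts a per-protomer count into the number of molecules
   to place around a predicted trimer: `3 × (per_protomer + extra)`.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| shell cutoff | 5.0 | Å | delimits the first (annular) lipid layer around a protomer |
| contact cutoff (location) | 4.5 | Å | a protomer "touches" a lipid below this nearest-atom distance |
| proximity cutoff (depth profile) | 5.0 | Å | reuses the shell cutoff: only annular atoms enter the profile |
| depth bin width | 2.0 | Å | resolves bilayer leaflet structure without fragmenting the histogram |
| smoothing window | 3 | bins | minimal smoothing that removes single-bin noise maxima |
| C--C bond threshold | 1.9 | Å | covers the 1.53 Å bond plus refinement noise, excludes 1--3 pairs (≥ 2.5 Å) |

All cutoffs are inclusive at the boundary (a lipid at exactly the cutoff is
a member); this makes results deterministic and documentable.

## Definitions left open by common practice, and the choices made

* **"Hydrophobic surface of the protein."** The default target set for
  nearest-distance statistics is *all protein heavy atoms*. A variant
  restricted to apolar atoms (C, S) is available via `apolar_only = TRUE`,
  and both can be reported side by side; the sample vs population standard
  deviation convention is likewise switchable (`sd_type`), with the sample
  (n−1) form as default.
* **Altloc resolution.** One conformer per atom is kept: highest occupancy
  wins, ties go to altloc `A`. Multi-model files keep the first model.
  Hydrogens are retained in the atom table but flagged and excluded from all
  geometry.
* **Location rule.** A lipid is *inner-compartment* when it contacts ≥ 2
  protomers **and** its centroid, projected on the membrane plane, falls
  inside the polygon of protomer centroids; *inter-protomer* when it
  contacts ≥ 2 protomers outside that polygon; *peripheral* otherwise. This
  geometric rule reproduces the qualitative placements described for
  trimeric bacteriorhodopsin (glycolipids in the central compartment,
  bridging lipids fastening adjacent protomers).
* **Membrane normal.** The principal axis of the helical C-alpha atoms
  (equivalently, the smallest-moment inertia axis of a 7-TM bundle). The
  sign is fixed deterministically.
* **Boundary fallback.** Published boundary planes come from dedicated
  hydrophobic-boundary methods and are accepted as input. When absent, a
  transparent slab estimator slides a 24--36 Å window along the normal and
  maximises (hydrophobic − polar) residue counts, with Kyte--Doolittle > 0
  defining hydrophobic. On synthetic bundles with a known belt the estimate
  lands within ±2 Å; it is a fallback, not a replacement for the dedicated
  methods.

## Numerical design

* **Two superposition solvers.** The production Kabsch solver (SVD of the
  3×3 cross-covariance, with the determinant correction for proper
  rotations) is validated against an independent Horn quaternion solver
  (principal eigenvector of the 4×4 key matrix); the test suite requires
  agreement to 1e-9 over 1,000 random instances. Degenerate inputs (< 3
  atoms, collinear sets) raise typed errors rather than returning unstable
  transforms.
* **Nearest-neighbour distances.** The production path uses a uniform-grid
  cell list with an expanding Chebyshev-ring search; a brute-force O(N·M)
  oracle is kept alongside. Both paths evaluate the winning atom pair with
  the same floating-point expression, so their outputs are required to be
  *bit-identical*, not merely close.
* **Mode detection.** Histogram counts are smoothed with a centred moving
  average (window shrinks at the edges), local maxima are taken with
  plateaus resolved to the lower depth, and zero-level maxima are excluded.
  An all-zero histogram yields an empty mode list; an empty depth vector
  yields an all-zero histogram, not an error.
* **Exact rationals.** Per-protomer census values are reduced fractions of
  integers, so `per_protomer × n_protomers` reconstructs the totals exactly.

## The synthetic-scene generator

Real MR coordinates are large and external; the generator builds fully
specified scenes in which every downstream quantity has a known ground
truth.

* **Protein.** Ideal alpha-helical C-alpha spirals (rise 1.5 Å/residue,
  100°/residue, spiral radius 2.3 Å), seven helices (default) on an
  8.5 Å-radius wheel, antiparallel, with approximate backbone N/C/O
  positions and a C-beta pseudo-atom; residues are hydrophobic inside the
  declared membrane belt and polar outside so the hydropathy-based boundary
  estimator sees realistic input. A 12-atom retinal arc sits inside the
  bundle. Trimers are generated by exact C3 rotations at 15 Å protomer-axis
  radius; the helix wheel is rotated by 3° so that the inner compartment of
  the trimer is narrow enough for an axis lipid to touch all three
  protomers at the 4.5 Å contact cutoff.
* **Lipids.** Chains are ideal hydrocarbons (1.27 Å rise, alternating
  lateral offset giving 1.54 Å bonds; methyl branches every 4th carbon for
  the phytanyl pattern). Peripheral and inter-protomer chains are placed by
  moving *each carbon* along its outward horizontal ray until its
  nearest-protein distance equals the target d0 exactly (1-D bisection to
  1e-12 Å); per-atom Gaussian jitter is added afterwards. This prioritises
  exact distance ground truth over chemically ideal bonds: a calibrated
  chain is slightly deformed, which is why branch-geometry tests use the
  ideal chains from `make_lipid_chain()` directly. Inner-compartment lipids
  stay centred on the C3 axis and record their geometry-determined minimum
  distance instead.
* **Depth mixtures.** Noble-gas atoms take depths from a declared Gaussian
  mixture (e.g. three components: bilayer core plus two flanking layers);
  short 3-carbon lipid fragments can likewise be planted with
  mixture-drawn depths to emulate the depth concentration of annular lipid
  atoms. Fragment centres are truncated to the protein's z-extent so each
  fragment has a surface to attach to; the histogram admits only depths
  within the boundaries in any case.
* **Determinism.** A scene spec includes its seed; identical specs produce
  byte-identical PDB fixtures and ground-truth JSON sidecars.

What the generator does **not** emulate: real side-chain rotamers, B-factor
and occupancy noise, partial/ambiguous density (every planted fragment is
complete), crystal-contact artefacts, and curvature of real bilayers.
Passing the synthetic suite therefore demonstrates the correctness of the
geometry and statistics, not robustness to the modelling ambiguities of
real depositions -- those are exercised by the reference comparisons
against deposited entries, which require the coordinate files to be
available locally.

## Problem sizes in the test suite

The shipped tests run entirely on generated data: bundles of 7×24 residues
(monomer ≈ 850 atoms, trimer ≈ 2,600), mixtures of 1,000--3,000 gas atoms,
100-replicate mode-recovery sweeps (≈ 1,000 lipid fragment carbons each),
1,000-instance solver cross-checks, and a handful of deposited-entry
comparisons that activate when the entries are present under
`tests/testthat/pdb_entries/`.

## Known limitations

* Fragments are counted as deposited; multi-residue lipids are not merged
  into molecules, and no headgroup chemistry is modelled.
* The census treats "no lipid residues present" as zero; it cannot
  distinguish a delipidated structure from one whose lipids were simply not
  modelled.
* The slab boundary estimator assumes a single membrane-spanning domain
  with a roughly axial normal.
* Assembly expansion currently generates point-symmetry (C3) or
  user-supplied operators; it does not read crystallographic REMARK 350
  instructions.
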