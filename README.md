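# annulipid

Quantitative analysis of **annular lipids** — the first shell of lipid
molecules in direct contact with a membrane protein's hydrophobic surface —
in crystal structures of microbial rhodopsins (bacteriorhodopsin and its
relatives). High-resolution entries of these seven-transmembrane-helix
proteins routinely contain ordered hydrocarbon fragments of the surrounding
lipids; this package is for structural biologists who want to turn those
fragments into numbers: packing distances, bilayer-depth profiles, shell
membership, oligomer locations, and per-protomer censuses.

## What it computes

* **Component dictionary.** Lipid and amphiphile fragments are deposited
  under three-letter chemical-component codes; `annulipid` ships a curated
  table of 39 codes observed in rhodopsin entries (`22B` … `UND`) with a
  lipid class for each (`archaeal_diphytanyl`, `linear_acyl`, `carotenoid`,
  `isoprenoid_squalene`, `detergent`, `sugar_headgroup_fragment`,
  `small_amphiphile_or_cryo`), plus coordinate-based detection of
  methyl-branched (phytanyl) vs linear chains.
* **Packing distance.** For a lipid selection with atoms *i = 1…n*, the
  summary is the mean ± sd of the per-atom nearest protein heavy-atom
  distances,
  *d̄ = (1/n) Σᵢ minⱼ ‖xᵢ − yⱼ‖*,
  the metric used to compare how native and non-native chains fit the
  protein surface.
* **Annular shell.** Lipid residues with ≥ 1 heavy atom within 5 Å
  (inclusive) of the protomer's protein heavy atoms.
* **Membrane frame and depth profiles.** Kabsch superposition on backbone +
  retinal atoms, a membrane normal from the helical C-alpha principal axis,
  a z-origin at the bilayer median, and histograms of lipid-carbon or
  noble-gas atom depths between the hydrophobic–hydrophilic boundaries,
  with mode detection.
* **Oligomer locations.** Lipids classified as `inner_compartment`,
  `inter_protomer`, or `peripheral` from protomer contacts (4.5 Å) and the
  membrane-plane projection of their centroid.
* **Census and budget.** Fragments per lipid class divided by the protomer
  count in exact rational arithmetic ("2/3 S-TGA-1 per protomer"), and the
  trimer placement budget `3 × (per_protomer + extra)` — e.g. 28 fragments
  per protomer plus one retinal-site molecule gives 87.
* **Synthetic scenes.** A deterministic generator of C3-symmetric helix
  bundles with lipids planted at exact nearest-surface distances and
  noble-gas atoms drawn from Gaussian depth mixtures, so the entire
  pipeline is testable without downloads.

## Worked example

```r
library(annulipid)

sp <- scene_spec(seed = 42, trimer = TRUE,
  lipids = list(
    list(class = "linear_acyl",         location = "peripheral",        d0 = 4.0, jitter = 0.3),
    list(class = "archaeal_diphytanyl", location = "inner_compartment", d0 = 4.0, branched = TRUE),
    list(class = "linear_acyl",         location = "inter_protomer",    d0 = 4.0)),
  gas = list(weights = c(1,1,1)/3, means = c(-10, 0, 10), sds = c(2,2,2), n = 1500))
scene <- build_scene(sp)

part <- partition_structure(scene$structure)
extract_shell(scene$structure, protomer_chains = "A", cutoff = 5)
#> annular shell at 5.0 A: 3 lipid residues
#>  chain resname resno insert         lipid_class min_distance n_atoms_within
#>      A     LFA  1001                linear_acyl     3.589242             16
#>      A     LFA  1003                linear_acyl     4.000000             16
#>      A     L2P  1002        archaeal_diphytanyl     4.179466             12
```

All three planted lipids touch protomer A within 5 Å; the jitter-free
inter-protomer chain (resno 1003) sits at exactly its planted 4.0 Å, while
the jittered peripheral chain approaches to 3.59 Å.

```r
nearest_surface_distances(part$lipid, part$protein)
#> nearest-surface distance: 4.24 +/- 0.34 A over 52 lipid atoms

classify_location(subset(scene$structure$atoms, resno == 1002 & het),
                  scene$structure, scene$frame)
#> location: inner_compartment (contacts: A,B,C; in-plane axis distance 0.00 A)
```

The mean of 4.24 Å over all 52 lipid atoms is pulled above the planted
4.0 Å by chain carbons that face away from the surface; the glycolipid on
the three-fold axis contacts all three protomers and is labelled
inner-compartment.

```r
gas <- subset(scene$structure$atoms, resname == "AR")
depth_histogram(depths_of(gas, scene$frame), scene$frame, bin_width = 2)
#> <depth_histogram> 1499 atoms in 16 bins over [-16.0, 16.0] A
#>   modes at depth: -9.0, 1.0, 9.0 A

lipid_census(scene$structure, n_protomers = 3)
#> lipid census for SYN1 (3 protomers): 3 lipid fragments
#>   archaeal_diphytanyl          1 total  (1/3 per protomer)
#>   linear_acyl                  2 total  (2/3 per protomer)
#>   other het residues: AR x1500

trimer_lipid_budget(28)
#> [1] 87
```

The three detected depth modes sit within one bin width of the planted
mixture means (−10, 0, +10 Å); one of the 1,500 gas atoms fell outside the
boundaries and is excluded.

A command-line front end over the same functions (subcommands `census`,
`shell`, `distances`, `zprofile`, `align`, `locate`, `simulate`) ships at
`system.file("cli/annulipid.R", package = "annulipid")`.

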