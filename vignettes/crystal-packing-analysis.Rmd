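---
title: "Crystal packing analysis with pixkit: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crystal packing analysis with pixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixkit)
```

# The problem

The lattice energy of a molecular crystal — the energy released when gas-phase
molecules assemble into the crystal — can be partitioned into pairwise
molecule–molecule interactions. In pairwise schemes the lattice energy is half
the sum, over one reference molecule, of its interaction energies with every
symmetry-generated neighbor:

$$E_\mathrm{latt} = \tfrac{1}{2}\sum_{i} E_\mathrm{pair}(0, i),$$

the half compensating for double counting each contact. Programs that
partition interaction energies into Coulombic, polarization, dispersion and
repulsion components need a substantial amount of crystallographic machinery
around them: complete, ordered molecules; hydrogen atoms at realistic
internuclear positions; an enumeration of the symmetry-related neighbors with
compact labels; and bookkeeping that connects energy tables back to symmetry
operations. `pixkit` implements that machinery, plus an *indicative* analysis
that flags the probably-important contacts before any quantum-chemical energy
is computed, and a pixel-sum Coulomb demonstrator operating on
electron-density cubes.

`pixkit` deliberately computes **no** quantum-chemical energies and does not
implement the polarization/dispersion/repulsion parameterization of full
energy-partitioning models; those parameters are not derivable from the
sources this package is built against. Energy breakdowns are *consumed* (from
whitespace tables) rather than produced, except for the Coulombic pixel sum.

# Molecule completion under symmetry

A CIF gives the asymmetric unit (AU) and the space-group operations. Whole
molecules are grown by breadth-first search: starting from an AU site, images
of all sites under all operations and nearby lattice translations are added
whenever they fall within covalent bonding distance
($d < r_\mathrm{cov,1} + r_\mathrm{cov,2} + 0.40$ Å) of an atom already in
the molecule. Atoms that land on an existing atom (special positions —
inversion centres, rotation axes) are *coincident* and dropped, the earlier
generator winning; the coincidence tolerance is 0.15 Å, larger than
refinement noise and much smaller than any bond. If growth escapes a ±4-cell
neighborhood the structure is polymeric and completion aborts with the
bridging bond named. Each connected set of AU sites yields one residue, so
Z′ > 1 structures come out as multiple molecules; no residue-count cap is
imposed here (a two-molecule limit applies only to Pixel-format export, where
the 200-atom capacity is also enforced).

Hydrogen positions refined from X-ray data sit systematically ~0.1 Å too
close to their heavy atom because the electron density maximum is displaced
into the bond. `normalize_h()` slides each H along its existing X–H direction
to neutron-derived internuclear targets (defaults C–H 1.089, N–H 1.015,
O–H 0.993, B–H 1.180 Å, user-overridable). Heavy atoms never move, the
direction is preserved to 1e-12, and the operation is a fixed point on
already-normalized molecules. Structures without hydrogen skip the step with
a message.

# Pair enumeration and ORTEP codes

All symmetry-related neighbors of each reference molecule within a
mass-weighted-centroid cutoff (default 20 Å) are enumerated. Centroids
transform affinely, so images are generated in fractional space and distances
measured through the metric tensor; the translation search bound is
`ceiling(cutoff / min interplanar spacing) + 1` per axis, which provably
covers arbitrarily skewed cells. Each image gets an ORTEP-type code: three
digits (unit-cell translations + 5) followed by the two-digit operation
number, so `55501` is the identity image with no translation. Two caveats are
worth stating loudly:

* operation numbers are **this package's** numbering — the order of
  operations in the parsed CIF. Other software may number differently.
* a scan of a small cell at a large cutoff can legitimately need |t| > 4,
  which the three-digit convention cannot express; such rows keep their
  integer translation columns and an `NA` code string.

Pairs with the same unordered residue pair and the same centroid distance
(within 1e-4 Å) are grouped as one symmetry orbit; the group size is the
multiplicity used by half-sum accounting. Mutually inverse images (e.g.
translations +**a** and −**a**) land in the same group and
`invert_pair_code()` recovers the exact inverse relation.

# Indicative structure analysis

Before any expensive energy calculation, geometry alone indicates which
contacts matter:

* **Hydrogen bonds**: an intermolecular H⋯acceptor distance inside the sum of
  the van der Waals radii indicates a bond, with donor and acceptor elements
  restricted to {N, O, S, F, Cl} and a D–H⋯A angle of at least 120°. The
  distance criterion is the defining one; the element and angle filters are
  conventional minimal additions and are configurable. Radii are Bondi-style
  (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, F 1.47, Cl 1.75 Å).
* **H-bond energies** are estimated by a simple exponential,
  $E(d) = -A e^{-B d}$ in the H⋯A distance. The defaults are anchored at
  $E(1.7\,\text{Å}) = -30$ and $E(2.2\,\text{Å}) = -10$ kJ/mol, giving
  $B = \ln 3 / 0.5 \approx 2.197\,\text{Å}^{-1}$ and $A \approx 1257$ kJ/mol.
  These are order-of-magnitude calibrations for moderate O–H⋯O bonds, exposed
  in `hbond_model()`; they are this package's defaults, not constants from
  any published program. Bonds weaker than 10 kJ/mol (strictly) draw a
  warning.
* **Contact fractions**: the fraction of a molecule's atoms closer than the
  vdW-radius sum + 1 Å to any atom of a partner. The +1 Å margin makes the
  fraction a useful dispersion-contact proxy; margin 0 recovers the strict
  overlap criterion used for H-bond indication.
* **1D motifs**: molecules linked into infinite chains (via H-bonds) or
  stacks (via contact fractions ≥ 0.30) drive anisotropic, needle-like
  growth. Detection works on the quotient graph of residues under symmetry:
  a closed walk whose composed operation is a pure lattice translation
  t ≠ 0 is a 1D motif with direction = primitive reduction of t and period =
  walk length. A pure-translation contact is a period-1 stack; two screw
  operations composing to +**b** give a period-2 chain; an inversion dimer
  composes to zero translation and is correctly *not* a motif.
* **Driver list**: the union of H-bonded pairs and pairs with contact
  fraction ≥ 0.20, ranked by strongest H-bond then contact fraction — the
  pairs whose energies are worth computing first, particularly for Z′ > 2
  structures where whole-crystal calculations are unavailable.

When per-pair total energies are supplied, the half-sum estimate above is
evaluated per reference residue and averaged over residues.

## Thresholds

| parameter | default | unit | role |
|---|---|---|---|
| centroid cutoff | 20 | Å | pair scan limit |
| bond slack | 0.40 | Å | covalent connectivity |
| coincidence tolerance | 0.15 | Å | special-position dedup |
| contact margin | 1.0 | Å | vdW contact fraction |
| stack threshold | 0.30 | — | contact fraction for a stack edge |
| driver threshold | 0.20 | — | contact fraction for a driver entry |
| weak H-bond threshold | 10 | kJ/mol | warning limit |
| matching tolerance | 0.01 | Å | centroid ↔ table row matching |

The stack and driver thresholds are unstated in the literature this package
follows; 0.30/0.20 were chosen once so that a pure translation stack with
one-third of its atoms in contact qualifies while incidental brushing
contacts do not, and they are ordinary arguments, not constants.

# Density cubes and the pixel Coulomb sum

Gaussian-format cubes are read/written with Bohr→Å conversion (density to
e/Å³). *Condensation* at level *n* merges n×n×n grid blocks into single
pixels: charge −∑ρ·dV (electrons negative), position the charge-weighted
mean of the block's voxel centers (geometric center for zero-charge blocks).
Edge remainders form smaller blocks so total charge is conserved exactly —
to 1e-10 e in the acceptance tests. Charge-weighted positions preserve each
block's dipole moment exactly, which is why the Coulomb energy is stable
across condensation levels for well-separated molecules; position convention
is a documented choice, not a claim of equivalence to any particular
program. Nuclei carry +Z or user-supplied valence charges, so the
total-charge invariant is checkable for both all-electron and
valence-density cubes.

The Coulomb energy between two clouds is the direct double sum
$E = K \sum_{i \in A}\sum_{j \in B} q_i q_j / r_{ij}$ over pixels and nuclei,
with $K = e^2 N_A / (4\pi\varepsilon_0 \cdot 1\,\text{Å}) \approx
1389.35$ kJ Å mol⁻¹ e⁻². Pairs closer than `r_min` (default 0.5 Å) are
skipped and counted as clashes — near-contacts between point pixels are
unphysical at condensed resolution and silently huge, so skipping with a
report is the transparent choice. The O(N²) inner loop is compiled (Rcpp);
at n = 1 on fine grids the sum spans ~10¹⁰ pairs.

# What the synthetic fixtures do and do not establish

All test inputs are generated in code:

* **Seven toy crystals** cover the symmetry situations the machinery must
  handle: P1 single site, an inversion dimer in P−1, a P2₁/c molecular
  crystal, a centrosymmetric molecule with half its atoms in the AU and one
  atom *on* the inversion centre, a 2₁-screw hydrogen-bond chain, a
  translation stack, and a Z′ = 4 cell. Every fixture ships with a
  ground-truth pair list computed at generation time by an independent
  brute-force path (atom-by-atom supercell expansion with centroids
  recomputed from transformed atoms), so a regression in the production
  enumeration cannot silently update the expectation. Cells are built with
  interplanar spacings ≥ ~8.5 Å so a ±3-supercell oracle provably covers a
  25 Å scan.
* **Gaussian-blob cubes** have closed-form pairwise Coulomb energies (the
  erf formula; a point charge is a zero-width Gaussian), giving an analytic
  oracle for the pixel sum. The 0.1% erf criterion is checked on
  *non-overlapping dipolar* clouds: for overlapping diffuse clouds the
  neutral–neutral penetration energy is a small difference of ~K/R-sized
  terms, and a point-pixel lattice sum carries an O(h²) near-field
  quadrature error of order 1% at the enforced ≥6 voxels/σ resolution —
  a property of the pixel model itself, not an implementation defect. The
  dipolar configuration tests the same code path (condensation, pruning,
  pairwise kernel, constant) on an energy the model can actually represent
  to 0.1%.
* **Tripalmitin** (glycerol esterified with three C16 chains, C₅₁H₉₈O₆,
  155 atoms) is built from idealized internal coordinates as the capacity
  test for the 200-atom format limit. Only topology and counts are
  asserted — the conformation is an extended idealization, not the crystal
  conformation.

Green tests therefore establish: correctness of the symmetry/enumeration/
bookkeeping machinery against independent oracles, exact charge accounting,
and pixel-sum electrostatics faithful to analytic multipole interactions.
They do **not** establish agreement with any published lattice energy —
those require quantum-chemical densities and database structures that are
out of scope by design; fixtures emulate symmetry situations, not real
compounds' geometry or energetics.

# Numerical choices

* Cartesian frame: **a** along x, **b** in the xy-plane; fractional
  coordinates as read.
* Symmetry-operation translations are stored reduced to [0, 1) with the raw
  integer part kept separately, so strings like `"2-z"` round-trip and ORTEP
  codes decompose cleanly into reduced operation + cell shift. Parsed
  translations snap to the nearest 1/24 within 1e-6.
* Space groups are recognized by operator list only; the Hermann–Mauguin
  name is carried as metadata and never trusted (a handful of common groups
  can be *generated* from a name when a CIF lacks the loop).
* Occupancy < 1 sites are accepted at parse time with a warning; molecule
  completion refuses them unless overridden.
* Centroid↔row matching is greedy nearest-distance with a 0.01 Å default
  tolerance (numeric noise is orders below; genuine mismatches are orders
  above). Energy-component closure is checked to 0.15 kJ/mol, reflecting
  one-decimal rounding in printed tables.
* Degenerate inputs: empty scans warn and return empty tables; tables
  without a total-energy line warn and carry `NA`; under-resolved Gaussian
  grids (< 6 voxels per σ) are an error in the generator.

# Resolved design questions

* **SHELXL → CSD normalization** canonicalizes the known tag variants
  (symmetry loop spellings, space-group name tags) and recovers a missing
  name from the operator list where possible; anything unrecognized becomes
  a warning, not a failure. The exact rewrite list of the original tooling
  is unpublished, so this is documented as a best-effort superset.
* **Symmetry reduction for export**: `pixkit complete` writes completed
  molecules to a P1 cell. Choosing a minimal retained operator subset (or a
  non-standard setting) the way specific GUIs do is not claimed; P1 is the
  unambiguous lossless route.
* **Energy tables**: the whitespace-table dialect (column order, the `toto`
  total-energy label, comment prefixes) is configurable because the
  reference layout exists only as a screenshot in the literature; the
  default dialect is this package's own canonical table.

# Limitations

* No polarization, dispersion or repulsion energies; no quantum chemistry;
  no wavefunction handling.
* No CSD access, no mmCIF/PDB, no modulated or magnetic structures, no
  disorder resolution beyond refusal/override.
* Motif detection enumerates closed walks up to period 4 by default; exotic
  longer-period motifs need the parameter raised.
* The pixel Coulomb sum is a demonstrator: quadratic cost, no Ewald
  summation, no cell-periodic electrostatics.
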