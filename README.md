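# pixkit

Crystal packing analysis for molecular crystals: the crystallographic
machinery that surrounds pairwise lattice-energy partitioning.

## Who this is for

Crystallographers and computational chemists who analyse intermolecular
interactions in small-molecule crystal structures — hydrogen bonding versus
dispersion stacking, which contacts drive needle growth, which pair energies
are worth computing — and who need reproducible plumbing between CIF files,
symmetry-generated molecular pairs, and spreadsheet-ready interaction-energy
tables.

## What it computes

In pairwise schemes the lattice energy is half the sum of one reference
molecule's interactions with every symmetry-generated neighbor,

E_latt = ½ Σᵢ E_pair(0, i),

and everything here serves that accounting:

- **CIF I/O** (CSD and SHELXL dialects), symmetry-operation parsing, and a
  SHELXL→CSD normalizer (`pixkit convert-cif`).
- **Molecule completion** across space-group symmetry, including half
  molecules on inversion centres and atoms on special positions (coincident
  images are dropped automatically); polymers are detected and refused.
- **Neutron H normalization**: hydrogens slid along their X–H bonds to
  neutron-derived internuclear lengths (C–H 1.089, N–H 1.015, O–H 0.993,
  B–H 1.180 Å by default).
- **Pair enumeration** within a mass-weighted-centroid cutoff (default 20 Å)
  with ORTEP-type symmetry codes — three digits of unit-cell translation + 5,
  then the operation number, so `55501` is the identity image — plus
  translation to standard `x, y, z` strings, orbit multiplicities, and
  matching against external centroid-distance lists with error reporting.
- **Indicative structure analysis**: hydrogen bonds flagged inside the van
  der Waals radii with exponential energy estimates, van der Waals contact
  fractions (vdW sum + 1 Å criterion), 1D chain/stack motif detection in the
  symmetry quotient graph, weak H-bond warnings, a ranked driver list of
  pairs worth computing, and the half-sum lattice-energy estimate when pair
  energies are supplied.
- **Electron-density cubes**: Gaussian-format read/write, condensation of
  n×n×n voxel blocks into charge pixels (charge conserved exactly), pruning,
  and a compiled pixel-sum Coulomb energy between two clouds
  (K ≈ 1389.35 kJ Å mol⁻¹ e⁻²).
- **Energy-table reporting**: parse PixelC-style whitespace `.MLP` tables
  (`toto` = lattice energy), annotate rows with symmetry codes by centroid
  matching, verify the half-sum against `toto`, and write
  spreadsheet-compatible CSV.

No quantum chemistry is performed and no polarization/dispersion/repulsion
model is fitted; energy breakdowns are consumed, not produced (except the
Coulombic pixel sum).

## Worked example

The bundled `screw_chain` fixture is a small hydroxy compound whose O–H
points at the 2₁-screw image of its acceptor oxygen:

```r
library(pixkit)
fx <- make_toy_crystal("screw_chain")
print(indicative_analysis(fx$structure))
```

```
Indicative structure analysis
  88 pairs in centroid scan
  strongest hydrogen bonds:
    O2-H1...O1  1.827 A  -22.7 kJ/mol  code 54502
    O2-H1...O1  1.827 A  -22.7 kJ/mol  code 55502
  highest vdW contact fractions:
    code 54502  0.75 / 0.75
    code 55502  0.75 / 0.75
  1D motif: hydrogen-bond chain along (0 1 0), period 2
  1D motif: vdW contact stack along (0 1 0), period 2
```

Reading: the screw images at codes `54502`/`55502` (operation 2 with cell
shifts −**b** and 0 — each the other's inverse) accept a 1.83 Å hydrogen
bond worth about −23 kJ/mol by the exponential estimate; composing the screw
operation with itself gives a net +**b** translation, so the bonds link
molecules into an infinite period-2 chain along **b** — the classic signature
of a growth-driving 1D motif. The same pairs also exceed the 0.30 contact
fraction, so the chain is simultaneously a van der Waals stack.

The pair table itself, spreadsheet-ready:

```r
mols <- lapply(complete_molecules(fx$structure), normalize_h)
tab  <- pair_multiplicities(enumerate_pairs(fx$structure, mols, 12))
cat(write_pairs_csv(head(tab, 5)))
```

```
ref,neighbor,code,standard_symop,distance_A,multiplicity
1,1,54502,"-x, -1/2+y, -z",4.300,2
1,1,55502,"-x, 1/2+y, -z",4.300,2
1,1,54501,"x, -1+y, z",8.600,2
1,1,56501,"x, 1+y, z",8.600,2
1,1,45501,"-1+x, y, z",9.000,2
```

## Command line

```sh
PIXKIT=$(Rscript -e 'cat(system.file("cli/pixkit", package = "pixkit"))')
Rscript $PIXKIT pairs IN.cif --cutoff 20 -o pairs.csv
Rscript $PIXKIT indicative IN.cif
Rscript $PIXKIT convert-cif SHELXL.cif -o CSD.cif
Rscript $PIXKIT annotate run.mlp IN.cif -o table.csv
Rscript $PIXKIT condense IN.cube -n 4 -o pixels.csv
Rscript $PIXKIT coulomb A.cube B.cube --shift 8,0,0
```

Exit codes: 0 success, 1 usage error, 2 data error; warnings go to stderr
prefixed `pixkit WARNING:`.

## Vignette

`vignettes/crystal-packing-analysis.Rmd` documents the models, every tunable
parameter with units and rationale, what the synthetic fixtures do and do not
establish, and the numerical conventions (coordinate frame, translation
reduction, tolerances, degenerate-input behavior).
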