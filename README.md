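# kihscan

Locate, analyze and visualize coiled-coil (CC) interfaces in protein
structures from their defining structural signature: **knobs-into-holes
(KIH) packing**. A *knob* is a side chain projecting from one α-helix
that inserts into a *hole* formed by four side chains of an adjacent
helix. `kihscan` detects these interactions with structural criteria
alone, assembles complementary KIH interfaces into coiled coils of
**any order** — open bundles and cyclic α-helical barrels alike — and
assigns the canonical a-to-g heptad register to every participating
helix.

The package is written for structural biologists and protein designers
who want to extract CC geometry (oligomer state, topology,
parallel/antiparallel orientation, helix crossing angles, per-knob
packing angles, sequence registers) from PDB or mmCIF coordinate files,
as tidy tables, plain-text reports and PyMOL scripts.

## The method in brief

1. **Helix assignment.** Per-residue α-helix labels come from a classic
   DSSP output file, or from an internal Kabsch–Sander-style assigner:
   the amide H is rebuilt from the preceding peptide plane and the
   electrostatic hydrogen-bond energy
   `E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol marks a
   bond at `E < −0.5`; residues supported by two consecutive i→i+4
   turns are helical. Maximal H-runs of ≥ 7 residues become helix
   segments, optionally grown by the *helix extension* dial.
2. **Knobs and holes.** Each residue's side chain is reduced to the
   unweighted centroid of its heavy atoms from CB outward (CA for
   glycine). A residue is a knob into another helix when its center
   lies within the *packing cutoff* (default 7 Å, dial 6–8 Å) of at
   least four side-chain centers there; the four nearest form its hole.
   Knobs are typed 1–4 by insertion depth via the packing angle between
   the CA→side-chain and CA→hole-center vectors.
3. **Assembly.** Two helices form a CC interface when knobs are
   reciprocated (each knob sits in the other's hole) and at least three
   knobs cross the interface. Helices are nodes, interfaces edges:
   every connected component of ≥ 2 helices is one coiled coil, with
   no cap on the number of helices; a cycle in the component marks an
   α-helical barrel.
4. **Register.** Knob spacings of 3 and 4 residues anchor the heptad:
   spacing 3 ⇒ `a…d`, spacing 4 ⇒ `d…a`; the majority-consistent phase
   propagates letters over the whole segment (`letter(i+7) = letter(i)`),
   and disagreeing anchors are reported as conflicts.

A Crick-parameterised generator (`crick_backbone()`) builds idealised
parallel/antiparallel dimers, bundles and Cn barrels with pseudo
side chains, so the entire test surface runs without any downloads.

## Worked example

```r
library(kihscan)

# an idealised parallel dimer, 28 residues per helix
s <- crick_backbone(crick_params(n_helices = 2, n_res = 28))
result <- kihscan(s)          # defaults: cutoff 7 A, extension 0
result
#> <kih_result> 2 helix segment(s), 10 knob(s), 1 coiled coil(s)
#>   CC 1: order 2, open, helices [1, 2]

glance(result)
#> # A tibble: 1 x 7
#>   n_helices n_knobs n_coiled_coils max_order n_cyclic cutoff extension
#>       <int>   <int>          <int>     <int>    <int>  <dbl>     <int>
#> 1         2      10              1         2        0      7         0

head(tidy(result, "knobs"), 3)
#> # A tibble: 3 x 7
#>   knob  knob_helix hole_helix hole            max_distance packing_angle knob_type
#>   <chr>      <int>      <int> <chr>                  <dbl>         <dbl>     <int>
#> 1 A|11           1          2 B|11+B|12+B|...         6.47          26.1         3
#> 2 A|15           1          2 B|15+B|11+B|...         6.47          44           3
#> 3 A|18           1          2 B|18+B|19+B|...         6.47          26.1         3
```

The knob table says: residue 11 of chain A is a knob of helix 1
packing into the four-residue hole `B|11, B|12, B|15, B|8` on helix 2,
with all four hole centers within 6.47 Å and a packing angle of 26°
(type 3, core-pointing). Knobs fall on the a/d heptad positions and
alternate 3- and 4-residue spacings along each helix — the signature of
a canonical parallel dimer. The text report adds the aligned register
string:

```
coiled coil 1: order 2, topology open
  helix 1: chain A residues 2-27 (26 aa)
  helix 2: chain B residues 2-27 (26 aa)
  pair 1-2: parallel, interhelix angle 22.5 deg, 10 knobs, 13 complementary
  helix 1 sequence/register:
    AAAAAAAAAAAAAAAAAAAAAAAAAA
    bcdefgabcdefgabcdefgabcdef
```

`render_outputs(result, "outdir", pymol = TRUE)` writes the report, a
`.pml` PyMOL script (helices coloured, knobs as sticks, one selection
per register letter), and JSON/CSV tables;
`autoplot(result, "pair_angles")` and
`autoplot(result, "packing_angles")` draw the interface-geometry
histograms. A thin command-line wrapper is installed under
`exec/kihscan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","kihscan.R",package="kihscan"))')" \
    -f structure.pdb -c 7.0 -e 0 -o outdir --json --csv --pymol
```

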