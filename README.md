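# bfhc

Topological **B**ay / **F**jord / **H**arbor / **C**anyon (BFHC) indices and
fused-ring topology classification for polycyclic aromatic hydrocarbons
(PAHs), computed directly from raw Cartesian coordinates.

## What it computes, for whom

PAH carcinogenicity is governed largely by rim concavities and ring-fusion
pattern: bay-type pockets steer metabolism toward DNA-reactive
diol-epoxides. For QSAR and toxicology work this package turns a structure
archive (plain XYZ or Gaussian-input Cartesian blocks, C/H only) into a
feature table of:

- **BFHC counts** — concave rim regions defined by the path
  X–(sp²C)ₖ–Y between two outer-rim carbons across k consecutive
  ring-junction carbons: k = 2 Bay (4-atom path), k = 3 Fjord (5), k = 4
  Harbor (6), k = 5 Canyon (7). Single junctions are *fissures*
  (reported, not indexed).
- **Fused-ring topology** — `linear` (acene-type straight fusion),
  `angular` (cata-condensed, bent or branched), `peri-condensed` (any
  carbon in ≥ 3 rings).
- A validated metadata schema carrying the seven-level ordinal
  carcinogenicity scheme (–, ±, L, LM, M, HM, H → 0…6), log P and
  log Iball (stored and cross-checked, never computed).

The pipeline is: distance matrix → covalent-radii bond perception
(r_C = 0.76 Å, r_H = 0.31 Å, tolerance 0.40 Å, all configurable) →
degree-based atom typing → minimum-cycle-basis ring perception → perimeter
boundary walk → junction-run motif detection with a geometric validity
filter. An independent brute-force path-enumeration oracle and an idealized
benzenoid/helicene geometry builder with ground-truth connectivity back the
test suite. See `vignettes/bfhc-methods.Rmd` for the full model.

## Worked example

```r
library(bfhc)

res <- bfhc_compute(canonical("benzo[c]phenanthrene")$molecule)
res
#> <bfhc_result> benzo[c]phenanthrene: C18H12  B=0 F=1 H=0 C=0  angular

cat(report_motifs(res$motifs, "table"), sep = "\n")
#> kind	path_indices	endpoint_distance	passed_geometry
#> fissure	1-3-4	2.5534	TRUE
#> fissure	7-9-12	2.5534	TRUE
#> fissure	15-14-17	2.5534	TRUE
#> fjord	10-11-8-6-5	3.4117	TRUE
```

Benzo[c]phenanthrene ([4]helicene) carries a single fjord: a 5-atom rim
path (0-based atom indices `10-11-8-6-5`) whose three interior atoms are
ring-junction carbons, its endpoints 3.41 Å apart through space (inside the
4.5 Å validity cap). The three fissures are the isolated junction carbons
elsewhere on the rim. The molecule has 6 boundary junction carbons in
total, and the boundary decomposition conserves them —
`fissure + 2·B + 3·F + 4·H + 5·C = 3 + 3×1 = 6`:

```r
cnt <- res$motifs$counts
cnt[["fissure"]] + 2*cnt[["bay"]] + 3*cnt[["fjord"]] +
  4*cnt[["harbor"]] + 5*cnt[["canyon"]] == res$motifs$n_boundary_junction
#> TRUE
```

Whole-file workflow and CLI:

```r
tab <- bfhc_compute_files(c("phenanthrene.xyz", "pyrene.xyz"))
write_pah_table(tab, "bfhc_table.csv")
cross_validate(read_pah_table("bfhc_table.csv"), structure_dir = ".")
```

```sh
Rscript inst/cli/bfhc.R generate --compound hexahelicene -o hexahelicene.xyz
Rscript inst/cli/bfhc.R compute hexahelicene.xyz -o table.csv
Rscript inst/cli/bfhc.R summarize --table table.csv
```

A 15-compound synthetic example table (structural fields computed by this
package, curated fields invented placeholders) ships at
`inst/extdata/pah_table_synthetic.csv`.

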