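---
title: "Methods: detecting Bay, Fjord, Harbor and Canyon regions in PAHs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting Bay, Fjord, Harbor and Canyon regions in PAHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfhc)
```

## The problem

Polycyclic aromatic hydrocarbons (PAHs) are fused systems of aromatic rings
built from carbon and hydrogen only. Their carcinogenic potency is strongly
structure-dependent: concave pockets on the molecular rim — the classic *bay
region* of phenanthrene and its deeper relatives — steer metabolic activation
toward DNA-reactive diol-epoxides, and the overall ring-fusion pattern
(linear acene chains versus angular or clustered systems) modulates
reactivity. This package computes a family of four concavity descriptors
plus a fused-ring topology class directly from raw Cartesian coordinates, so
that a structure archive can be turned into a QSAR-ready feature table with
no manual annotation.

A concave region is a path along the rim of the fused system between two
outer-rim carbons X and Y:

| index | path | atoms | junction carbons between X and Y |
|-------|------|-------|-----------------------------------|
| Bay (B) | X–C–C–Y | 4 | 2 |
| Fjord (F) | X–C–C–C–Y | 5 | 3 |
| Harbor (H) | X–C–C–C–C–Y | 6 | 4 |
| Canyon (C) | X–C–C–C–C–C–Y | 7 | 5 |

The interior carbons are *junction* (ring-fusion) carbons, members of at
least two rings and hence hydrogen-free; X and Y are rim carbons in exactly
one ring, typically hydrogen-bearing sp² centers. A single junction carbon
between two rim carbons is a *fissure* (reported, but not one of the four
indices); runs of six or more junctions are reported as *extended*.

## From coordinates to a typed graph

Bonds are perceived from the pairwise distance matrix with a covalent-radii
threshold: atoms $i, j$ are bonded iff
$0 < d_{ij} \le r_i + r_j + \tau$. Defaults are $r_\mathrm{C} = 0.76$ Å,
$r_\mathrm{H} = 0.31$ Å and tolerance $\tau = 0.40$ Å — standard single-bond
covalent radii, giving a C–C cutoff of 1.92 Å that accepts aromatic bonds
(≈1.40 Å) and rejects the shortest non-bonded contacts in idealized
geometries (second-neighbor carbons sit at ≈2.42 Å). All three values are
configurable because the appropriate slack depends on how distorted the
input geometries are. Two guards protect crowded inputs: H–H bonds are
forbidden outright (in-fjord hydrogens can approach each other well inside
any plausible threshold), and the perceived graph is validated against PAH
chemistry — every hydrogen must end with degree 1 on a carbon, every carbon
with degree 2, 3 or 4. Violations are errors naming the offending atoms, on
the view that a silently wrong graph is worse than a refusal.

Atom types follow from degree alone: degree-2 carbons are labeled `sp`,
degree-3 `sp2` (or `sp2-H` with a hydrogen neighbor), degree-4 `sp3`.
Disconnected carbon skeletons are rejected by default; `allow_fragments`
switches to per-fragment processing, and the molecule-level results then
come from the largest fused component (with a warning), since a single
topology label for several disjoint ring systems is otherwise undefined.

## Ring perception

Rings are a minimum cycle basis of the carbon skeleton (the
smallest-set-of-smallest-rings in its standard formulation), computed with
Horton's algorithm: candidate cycles are built from BFS shortest paths
through every vertex–edge pair, then a greedy GF(2) elimination over the
edge space keeps the $|E| - |V| + 1$ shortest independent ones. BFS
neighbors are visited in ascending index order, so the basis is
deterministic. For planar fused benzenoids the basis coincides with the
hexagonal faces, which is the property everything downstream relies on.
Basis cycles larger than `max_ring_size` (default 7) abort the analysis:
5-, 6- and 7-membered rings are in scope, macrocycles are not. Ring
*membership* — in how many basis rings a carbon sits — drives both the
junction flags and the peri-condensed test; systems containing non-hexagonal
rings are flagged so that class labels framed in benzene-ring terms can be
read with care.

## Boundary walk and motif detection

Boundary edges are exactly the ring edges contained in one basis ring; for a
simply connected fused system they form a single closed walk, which is
traversed with deterministic tie-breaks (start at the smallest atom index).
Interior carbons (e.g. the two central atoms of pyrene) have no boundary
edge and are excluded; substituent carbons outside all rings are recorded as
decorations on their anchor rim atom. Systems whose boundary splits into
several cycles (coronoid holes, or ring systems linked by a non-fused single
bond) stop with an explicit error — concavities spanning such links are out
of scope.

Detection is then a run-length scan: rotate the cyclic walk to start on a
rim carbon, take maximal runs of consecutive junction carbons, and map run
length $k = 1, 2, 3, 4, 5$ to fissure, Bay, Fjord, Harbor, Canyon. The
motif path is the run plus its two rim flanks. This topological rule is
exact on idealized geometries and insensitive to the out-of-plane
distortions of helicenes, which is why geometry enters only as a *validity
filter*: endpoints must be non-bonded and within
`geometry_max_distance` (default 4.5 Å) through space. The default cap is
an interpretation — deep but genuine pockets such as the hexahelicene canyon
span 4.0 Å between their stacked terminal carbons, while anything much
wider is no longer a pocket; disabling the filter reproduces pure-topology
counts, and motifs failing it are retained in the report with
`passed_geometry = FALSE` but excluded from counts. The endpoint policy
defaults to `any` (substituent-bearing flanks count, since rim positions
are only *typically* hydrogen-bearing); `hydrogen-only` drops motifs whose
flanks carry no hydrogen.

Every detector claim is cross-checked against an independent oracle,
`brute_force_motifs()`: enumerate all simple paths of 3–7 atoms over the
boundary-edge subgraph with junction interiors and non-adjacent rim
endpoints, deduplicate reversals. The two implementations share no code
path — one is an ordered walk plus run-length encoding, the other is
generic path enumeration — and must agree exactly on every fixture and on
randomized polyhexes. A conservation law ties the decomposition together:
fissures $+ 2B + 3F + 4H + 5C + \sum(\text{extended runs})$ equals the
number of junction carbons on the boundary, because every boundary junction
belongs to exactly one maximal run.

## Topology classification

A molecule is **peri-condensed** iff some carbon belongs to three or more
rings. Otherwise it is cata-condensed and subdivided by the inner dual
graph (one node per ring, edges between rings sharing a bond):
**linear** iff the dual is a simple path and the angle at each internal
ring's centroid between its two fused neighbors is at least
`linear_angle_threshold` (default 170°); **angular** otherwise, including
branched duals such as triphenylene. On an idealized lattice acenes give
exactly 180° and kinks 120°, so any threshold strictly between those values
separates them robustly; 170° leaves slack for mildly relaxed real
geometries. Single rings are linear by convention.

## What the synthetic generator emulates — and what it does not

`build_benzenoid()` places carbons on an ideal hexagonal lattice
(C–C 1.40 Å, C–H 1.09 Å), merging coincident vertices only between cells
joined by fusion edges, and emits the *intended* adjacency alongside the
coordinates, so bond perception is tested against ground truth rather than
assumed. Helicene specs use a rise of 0.8 Å per cell: large enough that
hexahelicene's lattice-coincident terminal rings end up 4.0 Å apart (far
outside the 1.92 Å bond cutoff), small enough that intra-ring bonds stay
within it (the longest distorted bond is ≈1.61 Å). Benzo[c]phenanthrene is
built with the same spiral policy: on a strictly planar lattice its fjord
hydrogens would sit ≈0.5 Å apart and ≈1.6 Å from the opposite flank carbon,
a geometrically degenerate input no real molecule exhibits.

`random_polyhex()` grows connected polyhexes by uniform frontier addition
under two rejection rules: no enclosed empty cell (coronoid holes have two
boundary cycles), and no *meta* cell pair with both common neighbor cells
empty — that pattern (five or more rings wrapping an empty hexagon) places
two rim carbons one bond length apart and is not realizable as a planar
molecule; the real compounds either close the ring or twist into helicenes,
which the library covers explicitly.

The generator therefore emulates topology faithfully but geometry only
ideally: no bond-length alternation, no relaxation, no out-of-plane
distortion beyond the uniform spiral, no heteroatoms, and substitution
limited to methyl groups. A green test suite establishes that the
*algorithms* are correct on their stated domain; it does not establish
robustness to poorly optimized real-world coordinates beyond what the
configurable radii/tolerance provide.

## Dataset conventions

The metadata table stores one row per compound: identifiers, C/H counts,
the four BFHC counts, the topology class, a seven-level ordinal
carcinogenicity label (–, ±, L, LM, M, HM, H, encoded 0–6 in that order),
and two curated physicochemical fields (log P, log Iball) that this package
stores and validates but never computes. The historical alias `+` is
resolved to `LM` on ingest and logged. The source scheme is ambiguous about
`L`: one reading lists it as "low", another folds it into
"non-carcinogenic"; labels are stored verbatim, the seven-level order is
canonical for encoding, and `collapse_L_to_negative = TRUE` switches to the
alternative reading rather than resolving the ambiguity silently. The
canonical interchange format is UTF-8 CSV; the deposited spreadsheet should
be exported to CSV once for ingestion (no spreadsheet reader is bundled).
`cross_validate()` recomputes every structural field from the structures
and reports discrepancies without ever overwriting recorded values: the
deposit is the reference, mismatches are findings.

## Known limitations

- Coronoids (ring systems with holes) and macrocycles are rejected, not
  analysed.
- Concave regions spanning a non-fused single bond (binaphthyl-type) are
  out of scope; such molecules are processed per fused component.
- No bond orders, Kekulé structures, aromaticity energetics, or electronic
  descriptors.
- The deposited reference table and structure archive are not
  redistributable here; dataset reconciliation against the published counts
  requires a one-time download, and the corresponding acceptance check
  remains red in offline environments by design.
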