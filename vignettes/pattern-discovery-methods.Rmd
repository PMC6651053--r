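---
title: "Grid-based discovery of conserved 3D amino-acid patterns: model and design notes"
author: "Pattern3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based discovery of conserved 3D amino-acid patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Pattern3D)
```

## The problem and the model

Given a set of protein structures, Pattern3D enumerates every local
arrangement of at least four residues, groups arrangements of identical
amino-acid composition into *3D-patterns*, and splits each pattern into
conformational *clusters* by rigid-body RMSD. The central premise is
that a conserved spatial arrangement of residues can be functionally
meaningful even when it has no sequence signature: the residues of one
site may come from scattered, differently ordered positions of each
protein's sequence. The method is therefore entirely geometric — no
binding-site annotation, ligand, or sequence alignment enters the
computation, and co-crystallized ions or ligands are deliberately
ignored at parse time (they are to be *rediscovered* as conserved
arrangements, not consumed as input).

### Residue representation

Each residue is reduced to two representative points: its Cα and the
unweighted centroid of its side-chain heavy atoms (atoms other than N,
CA, C, O, OXT and hydrogens). Glycine, which has no side chain, uses
its Cα as centroid. Spatial membership — which residues "surround" a
grid coordinate — is decided by the side-chain centroid alone, because
the side chain is what a residue presents chemically to a site;
backbone-only depositions (common at low resolution) are rejected by
`filterSidechainless()` since without side chains the arrangement
cannot be characterised. The RMSD between sites uses both points per
residue, so relative side-chain orientation contributes to the
distance, not just residue position. A Cα-only convention would
consider two sites identical even if every side chain pointed in
opposite directions; an all-atom convention would make glycine
ill-defined and tie the result to rotamer detail that the method does
not try to model. These are package conventions: the choice of
representative atoms is a genuinely open design point, isolated in
`representativePoints()` so that benchmark deviations can be attributed
to it.

### The grid of virtual coordinates

Per chain, the bounding box of the representative points is filled with
a lattice of spacing `st`; a lattice point is retained iff ≥ 4 residues
lie within `rt` of it. Two numerical choices matter:

* **Anchoring and padding.** The lattice is anchored at the
  bounding-box minimum corner and padded on every axis by
  `ceiling(rt/st) * st` — the search radius rounded *up to a whole
  number of steps*. Padding guarantees that surface sites are reachable
  (a site centered just outside the box is still covered by a retained
  point). Rounding the pad to whole steps makes the lattices at
  different `rt` (and at `st/2`) nested sublattices of one lattice
  anchored at the box minimum. Two useful invariants then hold exactly,
  and are tested: retention is monotone in `rt`, and every site found
  at spacing `st` is found at spacing `st/2`. Anchoring to the box
  (rather than to absolute space) also makes the whole computation
  exactly translation-equivariant.
* **Tolerance.** All distance comparisons use a `1e-9` Å slack so that
  points planted exactly at radius `rt` are not lost to floating-point
  rounding.

### Displaced zones

With `dt > 0` each retained point expands into seven two-center zones:
center pairs displaced ±`dt` along the three coordinate axes and the
four body diagonals (unit length). A residue belongs to a zone if it is
within `rt` of *either* center, giving seven elliptical search volumes
that catch elongated arrangements no single sphere can hold. The
axis-plus-body-diagonal construction is the package's reading of a
seven-zone expansion; it is isolated behind `expandZones()` so it can
be swapped without touching enumeration. Note an important asymmetry:
zones are only expanded around *retained* points, so an elongated
arrangement is discoverable only where the central point itself gathers
four residues — elongated sites in otherwise empty space are invisible
by construction.

### Sites, signatures, deduplication

Any (zone) neighbourhood with ≥ 4 residues is a site; there is no upper
size limit because `rt` bounds site size naturally. Adjacent grid
points typically see the same residues, so sites with identical residue
sets are deduplicated per chain, keeping the first in (grid index,
zone) order. Chains of homo-oligomers are processed independently and
cross-chain duplicates are kept — each chain is a separate observation
of the arrangement. Sites are canonicalized to composition signatures
(`"3C1H"`, `"1D1G1L1Q"`): counts of one-letter codes in strict
alphabetical order, independent of residue order and sequence position.

### Superposition and clustering

Two same-signature sites are compared by the minimum RMSD over all
type-preserving residue bijections, each evaluated with closed-form
least-squares superposition (SVD with determinant correction; proper
rotations only, since a mirror image of a chiral site is not the same
site). The correspondence search is exhaustive over within-type
permutations while the largest same-type group has ≤ 6 residues
(≤ 720 permutations per group); beyond that an iterated greedy
assignment refines a centroid-distance-ranked initial pairing, and the
result is flagged `exhaustive = FALSE`. In practice sites of 4–10
residues stay comfortably in the exhaustive regime.

Clustering is greedy and incremental, in deterministic order
(submission order of structures, then chain, then grid index, then
zone): a site joins the first cluster of its signature whose
*reference* site (the cluster's founder) it matches within `rmsdt`,
else it founds a new cluster. Comparing against the reference rather
than against all members is the literal incremental rule; it is cheap,
deterministic, and its border behaviour is testable by replay (every
member within `rmsdt` of its reference; every founder beyond `rmsdt`
of all earlier references). The trade-off is order dependence at the
margins: a site near the threshold may join or found depending on
submission order. Site discovery itself is per-structure independent,
so only cluster numbering — never pattern membership or coverage — can
change with submission order.

### Coverage statistics

For each pattern, `PCv = 100 · InProt / n_submitted`, where structures
that parsed but yielded no sites (for example backbone-only models)
stay in the denominator — a pattern absent from them is genuinely not
covered there. For each cluster,
`CCv = 100 · (distinct structures among cluster members) / (distinct
structures containing the pattern)`. The cluster-coverage denominator
is the pattern's protein set, which makes CCv "how much of the
pattern's spread this conformation explains": a cluster spanning one of
three pattern-bearing structures has CCv 33.3. Percentages are rounded
to one decimal for display; raw fractions are kept internally.

## Tunable parameters

| parameter | meaning | unit | typical |
|---|---|---|---|
| `st` | lattice spacing; exploration density | Å | 0.8–2 |
| `rt` | search radius; bounds site size | Å | 3 (small motifs) – 5 (larger sites) |
| `dt` | zone displacement; 0 = spherical only | Å | 0–2 |
| `rmsdt` | clustering threshold | Å | 2–4.5 |
| `mc` | minimum PCv shown | % | 0–80 |

Small `rt` finds small, tight motifs (metal-coordination sites); large
`rt` finds bigger surface patches but inflates the combinatorics.
Permissive `rmsdt` merges conformationally different sites into one
cluster (false positives); strict `rmsdt` fragments genuinely conserved
arrangements across clusters.

## What the synthetic generator emulates — and what it does not

`makeStructures()` plants rigid-body-transformed copies of a motif
template (uniform random rotation, random translation, optional
Gaussian per-point jitter) among isolated decoy residues, and writes
them as standard PDB with a single pseudo side-chain atom placed
exactly at the intended centroid. This decouples geometric ground truth
from side-chain chemistry: recovery tests verify the grid, enumeration,
superposition and clustering machinery, *not* stereochemical realism.
Decoys are kept out of search range of the planted copies and of each
other, so the fixtures have unambiguous expected outcomes. Real
structures differ in ways the generator deliberately does not model:
dense contiguous packing (every grid point retained, enormous raw site
counts), correlated backbone geometry, missing atoms and alternate
conformations. Passing the recovery suite therefore demonstrates
correctness of the method's mechanics under controlled conditions, not
benchmark-level agreement on real depositions.

Two purpose-built sets emulate published-style benchmark topologies in
miniature, and are labelled synthetic throughout:

* `makeC3H1Fixture()` builds a chain whose sequence contains the
  zinc-finger C-x(8)-C-x(5)-C-x(3)-H motif exactly once, with the three
  cysteines and the histidine forming a compact spatial cluster
  (pairwise ≤ 6 Å) and all spacer residues on a distant line where no
  four residues share a search sphere. Discovery at St 0.8 / Rt 3 then
  finds exactly the 3C1H site, and the structural sites can be checked
  for concordance against `scanPrositeC3H1()` on the sequence.
* `makeTwoConformerSet()` builds three structures sharing a compact
  `1D1G1L1Q` arrangement (twice in one structure), plus one elongated
  conformer of the same composition reachable only through a displaced
  zone; three anchor residues perpendicular to its long axis retain the
  central grid point while staying outside the capturing zone, and one
  isolated corner residue pins the bounding-box minimum so the block
  can be placed exactly on the lattice. At St 2 / Rt 5 / Dt 2 /
  RMSDt 4.5 / Mc 80 this reproduces the expected topology: PCv 100, a
  four-site cluster at CCv 100 with member RMSDs < 2.5 Å, and a
  single-site second cluster at CCv 33.3. The elongated conformer was
  chosen so that its minimal RMSD to the compact one, over all residue
  correspondences, exceeds 5 Å — notably, two arrangements that each
  fit a 5 Å sphere can never exceed ≈ 3.5 Å, so a second conformational
  cluster at RMSDt 4.5 *requires* the zone mechanism.

## Degenerate inputs and edge behaviour

* Structures that fail to parse are logged and skipped; structures that
  parse but lose all residues to the side-chain filter are kept in the
  coverage denominator with zero sites.
* Chains with fewer than four residues, or whose residues never gather
  four within `rt`, produce empty grids and no sites.
* Collinear point sets still superpose (the SVD route returns a valid
  minimiser); fully degenerate covariance falls back to the identity
  sign.
* `rmsdt = Inf` collapses each signature into a single cluster;
  `dt = 0` searches spherical neighbourhoods only.
* Multi-model files keep model 1; alternate locations keep blank/'A';
  selenomethionine maps to M; other non-standard residues are dropped
  with a warning.

## Problem sizes used in the test and acceptance runs

The shipped suites run entirely on generated structures, sized so the
full pipeline (parse → grid → enumerate → superpose → cluster → graph)
is exercised end-to-end in seconds: 5–13 structures per run, 6–30
residues per structure, grids of `1e4`–`1e5` lattice points, and 20
seeded replicates for the recovery-rate estimate. These sizes were
chosen to make every expected count exactly derivable by construction
or by the brute-force oracles shipped with the tests; scaling to real
depositions changes runtime, not code paths.

## Known limitations

* Patterns are equivalence classes of *identical* composition; sites
  built from chemically similar but non-identical residues (D↔E, K↔R)
  are different patterns by construction.
* No accessibility or druggability assessment: a conserved arrangement
  may be buried.
* The greedy first-fit-versus-reference comparator can mis-assign
  borderline sites relative to a best-of-members comparator; only
  sites within a hair of `rmsdt` are affected.
* Grid anchoring, the seven-zone geometry and the two-point RMSD
  convention are declared package conventions. Absolute counts (raw
  site totals in particular) are sensitive to them, which is why the
  validation suite checks recovery, concordance and conservation
  identities rather than absolute enumeration totals.
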