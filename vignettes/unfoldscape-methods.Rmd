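---
title: "Methods: landscape, surface and network analysis of unfolding intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape, surface and network analysis of unfolding intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldscape)
```

`unfoldscape` analyses conformational ensembles of partially unfolded
proteins: it locates intermediate states on two-dimensional free-energy
maps, characterises their secondary structure, hydrogen bonding and exposed
hydrophobic surface, and summarises their internal communication as a
residue network. This vignette is the package's own account of those
methods — the models and their assumptions, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Containers and units

Structures and trajectories are plain R lists (`Structure`, `Trajectory`)
holding an atom table and frame coordinates. All internal coordinates are
in nm; PDB input/output converts from/to Ångström, and surface areas are
reported in Å² because that is how patch sizes are conventionally quoted.
Residues are indexed 1..n internally — R and its structural ecosystem
(bio3d) are 1-based, so a 0-based internal convention would invite
off-by-one errors — while the author/PDB numbering is carried alongside and
used in every report.

Van der Waals radii are not hard-coded: two element-keyed tables ship as
plain text (`vdw_radii_bondi.tsv` for all-atom structures,
`vdw_radii_united.tsv` with inflated heavy-atom radii for
hydrogen-free crystal structures) and any custom table can be supplied.
Surface areas depend directly on these radii, so they must be explicit and
swappable. When hydrogens are absent, surface analysis runs on heavy atoms
with the united-atom radii and hydrogen-bond detection falls back to
donor–acceptor geometry (the backbone amide hydrogen, which is needed for
directional mainchain counts and secondary-structure assignment, is
reconstructed geometrically — 0.1 nm from N along the bisector of the
N−C(prev) and N−Cα directions, i.e. opposite the preceding carbonyl).

## Order parameters

Four per-frame order parameters coordinate all downstream analyses:

* **RMSD** (nm) after least-squares superposition on Cα atoms;
* **ρ**, the fraction of native side-chain contacts: a native pair is a
  residue pair (|i−j| ≥ 3) whose minimum side-chain heavy-atom distance is
  ≤ 0.55 nm in the reference structure, and ρ is the fraction of those
  pairs still within the cutoff in a frame;
* **Q**, the same ratio over all-heavy-atom residue contacts;
* **SASA** (nm²) by Shrake–Rupley dot quadrature.

The minimum sequence separation of 3 excludes contacts that are present in
any conformation and would otherwise compress the dynamic range of ρ and Q.
ρ versus Q is the minimal consistent split between a side-chain-only and an
all-heavy-atom contact definition; both scopes are configurable, and
residue-pair (not atom-pair) counting is used throughout. Glycine
contributes no side-chain atoms and is silently excluded from ρ.

The dot surface uses a deterministic Fibonacci lattice with 960 dots per
atom by default. At that density the area of an isolated sphere is exact to
well under 1 % and two-sphere overlaps agree with the closed-form spherical
cap solution to ~1 %; densities below 32 are refused as unreliable. The
lattice is fixed in the laboratory frame, so areas are rotation-invariant
only to quadrature error (≈0.5 %), which the tests account for.

## Free-energy maps, basins and barriers

Frames are histogrammed on a 20×20 grid over an order-parameter pair; the
free energy of cell *i* is ΔA(i) = −RT ln(p_i/p_ref) with R =
8.314×10⁻³ kJ/(mol·K) and the reference chosen as the maximum-probability
cell (ties broken lexicographically, so maps are deterministic). Bin
ranges default to the data range with the maximum edge folded into the last
bin; unoccupied cells carry `Inf`, never a numeric sentinel. A conservation
identity — exp(−ΔA/RT) equals the empirical count ratio exactly — is
asserted in the tests, which pins the estimator to its definition rather
than to any particular sampled landscape.

Basin populations are compared through `basin_delta_a()`, which counts
frames inside inclusive order-parameter windows and returns
−RT ln(n_b/n_a). Aggregating windows rather than single cells makes the
estimate exactly binomial in the frame counts, so the two-state recovery
test can use a principled 3-standard-error band instead of an arbitrary
tolerance.

Barriers between cells are defined as minimax path barriers: over all
8-connected paths through occupied cells, the smallest achievable maximum
ΔA, minus ΔA at the start. This discrete surrogate is exhaustively
testable (the suite enumerates all simple paths on random 4×4 grids) and
deterministic; it is implemented as threshold growth with BFS connectivity
rather than path enumeration.

Melting curves count frames whose RMSD falls in the unfolded window
(default 0.3–0.9 nm, inclusive) per temperature. `fit_tm()` min-max
normalizes the curve and fits a two-parameter logistic by `stats::nls`,
refusing flat curves, curves that never cross 0.5, and fitted midpoints
outside the data range. Noiseless midpoints are recovered to well under
0.1 K and σ = 0.02 noise leaves the midpoint within 1 K at 20 temperatures.

## Secondary structure and transition events

Assignment follows the Kabsch–Sander scheme: the electrostatic
hydrogen-bond energy E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)
kcal/mol (distances in Å) defines a bond when E < −0.5 kcal/mol. Helices
require two consecutive n-turns (n = 3, 4, 5) and strands come from
parallel/antiparallel bridge patterns with |i−j| ≥ 3; the 8-state alphabet
is reduced to three (H, G, I → H; E, B → E; rest → C) because the analyses
only distinguish helix, strand and coil. α-helix assignment takes
precedence over bridges. Sequence-adjacent "bonds" are excluded (they are
covalently constrained), chain breaks (C−N > 0.25 nm) interrupt turn
patterns, prolines never donate, and chains shorter than three residues are
coil. On hen-egg lysozyme the per-residue agreement with the mdtraj DSSP
implementation is ~98 %; ideal templates agree exactly.

Transition events compare each residue's native label with its modal label
across the ensemble: H→C, E→C, C→E and H→E are the four event classes,
everything else is `unchanged`, and modal ties resolve to `unchanged` so
that event calling is conservative. Propensities are computed from
per-frame labels (not block averages); they are frame-order invariant by
construction.

## Hydrogen bonding and HDX concordance

The geometric criterion is donor–acceptor (N/O···N/O) distance ≤ 0.35 nm,
plus an H–D–A angle ≤ 30° whenever hydrogens are present; heavy-atom-only
structures use the distance term alone for protein–solvent counts. The
H–D–A convention (rather than D–H···A) is used and documented; at 30° the
two differ little for near-linear bonds. Mainchain N−H···O=C counts always
apply the angle term with reconstructed amide hydrogens, because a
distance-only count on a helix picks up the i→i+3 ladder as well and
triples the count; with directionality an n-residue ideal helix yields
exactly n−4 bonds. Counts are a function of the geometry set, not record
multiplicity: duplicated solvent records at identical positions are
deduplicated.

Segment-level protein–solvent hydrogen bonding mirrors HDX-MS comparisons:
segments come from a BED-like TSV with a protection class (`more`, `less`,
`unknown`), counts are averaged per frame and across independent
trajectories, and a terminal-residue normalization restricts each segment
to seven terminal residues — resolved as the first 4 plus the last 3
(configurable to 3+4; the protocol's "3–4 on each side" is ambiguous and a
fixed default keeps results deterministic). Segments shorter than seven
residues are excluded with an explicit marker, not an error. Concordance
reports how many less-protected segments exceed the more-protected class
mean, using strict inequality so ties never inflate agreement.

## Hydrophobic patch detection

Carbon and sulfur atoms are nonpolar; nitrogen, oxygen and phosphorus are
polar; hydrogens inherit their bonded heavy atom's class (bond inferred by
nearest heavy atom in the residue). Dots are generated on nonpolar atoms at
r_vdw + probe (probe 0.14 nm, the water probe — numerically equal to, but
distinct from, the polar expansion radius, and both configurable). A dot
survives if it lies outside every other atom's accessible sphere, polar
spheres being additionally inflated by the 0.14 nm polar expansion; that
masking is what makes a patch "contiguously hydrophobic" rather than merely
exposed. Exposed atoms are nodes and accessible-sphere overlap (center
distance < r_i + r_j + 2·probe) defines adjacency; connected components are
patches. Sphere-overlap adjacency is a deterministic, testable surrogate
for contiguity on the dot surface itself.

Ranking keeps the top five patches by area and then applies the 300 Å²
significance threshold — in that order, so at most five patches are ever
significant. Total surface hydrophobicity is the significant-patch sum.
EHSC attributes each contributing residue's patch area to that residue's
transition-event class; fractions sum to one. IVL exposure counts distinct
Ile/Val/Leu residues with positive significant-patch area. Motif residue
sets (e.g. GroES-like binding motifs) are an explicit input file and never
inferred from sequence patterns, which are not machine-resolvable reliably.

The patch pipeline is validated against an oracle that shares no code with
it: `make_patch_phantom()` builds layouts with planted patch groups and
computes each group's exposed area by latitude–longitude quadrature with an
independent occlusion loop. The default planar phantom uses 0.32 nm atom
spacing so that next-nearest columns fall outside the adjacency reach and a
polar stripe splits the grid into exactly two patches; measured areas agree
with the oracle to well under 2 %.

## Contacts and communication networks

Contact maps use Cα distances at 7 Å by default (a minimum-heavy-atom mode
exists, and outputs record which metric was used); frequencies are
fractions of frames in contact, and pairs are classified native/non-native
against the native structure's map at the same cutoff. Persistent
non-native pairs default to a 0.5 frequency threshold, aligned with the
network module's interaction rule.

The commute time CT(i,j) is the population variance of the Cα–Cα distance
over frames — the δ(ij) term in its definition is the time-mean of d(ij),
making CT a variance. It is accumulated in one pass on distances shifted by
the first frame's values, which removes the catastrophic cancellation a raw
sum-of-squares accumulator suffers (rigid trajectories give exactly zero).
The pathway threshold 0.1 applies to the max-normalized CT matrix; a raw
(Å²) mode exists because a unitless threshold on raw variances would be
length-scale dependent. Residues are neighbors when their time-averaged
minimum heavy-atom distance is below 3.6 Å and interact when a ≤ 3.9 Å
heavy-atom contact (a standard non-bonded reach) persists in at least half
the frames.

Pathways grow greedily: seed with the interacting pair of minimal CT,
repeatedly append the residue interacting with at least one member and
within the CT threshold of *every* member (ties broken toward the lowest
CT sum, then the lowest residue index), retire members from the pool, and
discard pathways shorter than three residues. The growth conditions are
re-checked independently in the tests, and on a two-domain fixture
intra-domain commute times are strictly below inter-domain ones.
Communication efficiency is the node degree over the union of neighbor and
interaction edges. Networks export to GraphML (igraph); GEXF has no writer
in the supported stack and the format argument errors on anything else.

## Synthetic data: what it shows and what it does not

The generators are pure functions of their seed. Backbone templates are
built by natural-extension placement with standard bond geometry: the ideal
helix (φ = −57°, ψ = −47°), an extended coil (φ = −120°, ψ = 130°; a lone
extended chain has no bridge partner and is coil by construction), and an
antiparallel strand pair whose partner strand is a 2-fold rotation about
the sheet normal with its register fixed by a deterministic geometric
search placing amide H / carbonyl O pairs at hydrogen-bond distance.
Planted-event ensembles give each segment its own spatially isolated chain
and swap templates between native and intermediate frames; chain termini
are natively coil, so segment-level event calls aggregate per-residue
events by majority. Two-state ensembles draw frames i.i.d. from two
conformers with Gaussian coordinate noise (σ = 0.02 nm — small relative to
the ~1.4 nm separation of the basins, as in a well-separated
folded/unfolded projection) at the study conditions of populations 0.8/0.2,
400 K and 50,000 frames.

Noise is applied per-atom in Cartesian space with no bonded-geometry
repair: the order parameters and estimators, not the physics, are under
test. Consequently a passing suite demonstrates correctness of the
estimators and detection rules on data with known truth; it does not
demonstrate that real unfolding intermediates are sampled correctly, that
force-field artefacts are absent, or that the synthetic basins resemble a
real protein's landscape. Analyses of real ensembles inherit all the usual
sampling caveats.

## Problem sizes, determinism and limitations

The test suite and the acceptance script run at deliberately desk-scale
sizes — 50,000 frames for the two-state recovery (binomial 3σ ≈ 0.11
kJ/mol on a 4.61 kJ/mol gap), 12–16-residue templates, 4×4 grids for
exhaustive barrier enumeration, 50-water boxes for brute-force
hydrogen-bond checks — chosen so every oracle can be exhaustive or
closed-form. All randomness is seeded; ties (reference cells, pathway
growth, altloc selection at equal occupancy, modal labels) break by fixed
deterministic rules.

Known limitations: mmCIF input, protonation prediction and ligand handling
are out of scope; XTC trajectories are not readable (DCD and multi-model
PDB are); the DSSP reduction does not distinguish turns or π-helices from
coil; patch areas depend on the radii set and dot density, both of which
are configurable precisely because published patch figures rarely state
them; and weighted-histogram reweighting across temperatures is not
implemented — each map is a single-temperature histogram.
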