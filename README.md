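# unfoldscape

Structural analysis of partially unfolded protein ensembles in R.

Large (α/β)₈ TIM-barrel proteins often unfold through compact intermediates
that expose contiguous hydrophobic surface — the signal a chaperonin such as
GroEL recognises. Characterising those intermediates from conformational
ensembles requires a chain of analyses that are usually scattered over
several tools: projecting trajectories onto order parameters, carving
free-energy basins out of 2-D histograms, assigning secondary structure,
scoring hydrogen bonding against hydrogen–deuterium-exchange protection,
finding exposed hydrophobic patches, and mapping residue communication.
`unfoldscape` implements that chain as one tested R package, aimed at
computational structural biologists who have an ensemble (multi-model PDB or
DCD) and want reproducible intermediate-state analysis.

## The models at the core

**Free-energy contour maps.** Frames are projected onto pairs of order
parameters — RMSD to the native structure, the fraction of native side-chain
contacts ρ (minimum side-chain distance ≤ 0.55 nm), the all-heavy-atom
fraction of native contacts Q, or SASA — and histogrammed on a 20×20 grid.
The free energy of cell *i* relative to the most probable cell is

ΔA(i) = −RT ln(p_i / p_ref),  R = 8.314×10⁻³ kJ/(mol·K).

Basins are extracted with inclusive order-parameter windows; barriers
between basins are minimax path barriers over the occupied-cell graph
(8-connectivity). Melting curves count frames whose RMSD lies in an
unfolded window (default 0.3–0.9 nm) per temperature, and Tm is the
midpoint of a least-squares logistic fit to the 0–1-normalized curve.

**Secondary structure and transition events.** A Kabsch–Sander
implementation assigns H/E/C per residue from backbone hydrogen-bond
patterns (electrostatic energy model, bond when E < −0.5 kcal/mol, amide
hydrogens reconstructed when absent), cross-checkable against mdtraj's DSSP.
Each residue's modal ensemble label versus its native label yields one of
four transition events — helix→coil, strand→coil, coil→strand, helix→strand
— or `unchanged`.

**Hydrophobic patches.** A dot surface (Fibonacci lattice, 960 dots/atom)
is built on nonpolar atoms at radius r_vdw + probe; polar atoms' occluding
spheres are inflated by a polar expansion radius (0.14 nm) so nonpolar
surface bordering polar atoms is masked. Exposed atoms are grouped by
accessible-sphere overlap into contiguous patches; the top five patches of
≥ 300 Å² are significant. Patch area is attributed to transition-event
classes (EHSC), and Ile/Val/Leu exposure is reported.

**Communication networks.** The commute time CT(i,j) is the time-variance
of the Cα–Cα distance (Å²); residues are neighbors below a time-averaged
3.6 Å minimum distance and interact when a ≤ 3.9 Å heavy-atom contact
persists in ≥ 50 % of frames. Pathways grow greedily on the interaction
graph under a normalized CT threshold of 0.1 and export to GraphML.

**Synthetic data.** Every stage is exercisable without simulation data:
generators build ideal helices/strand pairs/coils, two-state hopping
ensembles with prescribed populations, planar surface phantoms with an
independent numerical patch oracle, ensembles with planted transition
events, and distance processes with exactly imposed moments.

## Worked example

```r
library(unfoldscape)

# two-state synthetic ensemble: 80 % folded / 20 % unfolded at 400 K
sim <- make_two_state_trajectory(populations = c(0.8, 0.2), n_frames = 5000,
                                 temperature = 400, seed = 1)
nc    <- native_contacts(sim$conformer_a, "sidechain")
rms   <- rmsd_series(sim$trajectory, sim$conformer_a)
rho_v <- rho(sim$trajectory, nc)

fes <- build_map(rms, rho_v, temperature = 400, axis_names = c("rmsd_nm", "rho"))
fes
#> FreeEnergyMap 20x20 (rmsd_nm vs rho), T = 400 K, ref cell (1, 17), 5000 points

basin_delta_a(rms, rho_v,
              window_a = list(x = c(0, 0.3),      y = c(0, 1)),
              window_b = list(x = c(0.3001, 10),  y = c(0, 1)),
              temperature = 400)
#> [1] 4.442   # kJ/mol; the planted populations imply -RT ln 0.25 = 4.610

# planted transition events are recovered from the assigned labels
ue <- make_unfolding_ensemble(c("alpha_to_beta", "unchanged"), seed = 1)
ev <- classify_transition_events(assign_secondary_structure(ue$native),
                                 ss_matrix(ue$trajectory))
table(ev$event)
#> alpha_to_coil  beta_to_coil  coil_to_beta alpha_to_beta     unchanged
#>             4             0             0             6            14

# hydrophobic patches on a phantom surface with a known decomposition
ph <- make_patch_phantom()
find_patches(ph$structure)
#> PatchSet: 2 patch(es)
#>   areas (A^2): 420.5, 419.3
```

The 4.44 kJ/mol gap is the free-energy difference between the folded and
unfolded basins estimated from 5,000 frames; it converges to the
closed-form 4.61 kJ/mol as the frame count grows (the acceptance run uses
50,000). The event table shows the remodeled segment called
`alpha_to_beta` at its interior residues, with termini (natively coil)
left `unchanged`. The phantom's two planted patches are recovered with
areas within 1 % of its independent numerical oracle.

A YAML-driven end-to-end run (stages `simulate`, `fes`, `extract`, `ss`,
`hbonds`, `patches`, `ehsc`, `contacts`, `network`, `melt`) is available as
`run_pipeline()`, or from a shell via
`Rscript inst/scripts/run_pipeline.R --config cfg.yaml --stages simulate,fes --out out/`.
Every run writes a JSON manifest with all parameters and the seed.

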