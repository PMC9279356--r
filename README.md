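# ckitraj

Trajectory analysis of Cyclin/Cdk/CKI trimer dynamics in R.

Cip/Kip inhibitors (p21, p27, p57) fold onto Cyclin/Cdk dimers and block
the kinase active site with a short 3₁₀ helix.  Phosphorylation of a
buried tyrosine in that helix (p27 Y88 and equivalents) destabilises the
bound state, can eject the helix, and partially restores kinase activity.
`ckitraj` is the analysis layer for studying such systems from
molecular-dynamics output — it does not run MD, it interrogates
trajectories:

* **Structure I/O** — multi-model PDB trajectories with a frame→ns
  mapping, per-atom parameter tables (TSV), and an atom-selection
  mini-grammar (`"chain C and name CA"`).
* **Superposition / RMSD** — Kabsch best-fit (proper rotations only),
  Cα RMSD series, separate fit/report selections, 25 ns equilibration
  trimming.
* **Hydrogen-bond networks** — geometric detection (donor–acceptor
  ≤ 3.0 Å, D–H–A ≥ 135°, heavy atoms N/O/F), lifetime fractions,
  1 ns bound-episode classification, persistent intermolecular networks
  at the 0.5 lifetime-fraction threshold.
* **Secondary structure** — DSSP from Kabsch–Sander backbone H-bond
  energies (E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN), bond below
  −0.5 kcal/mol), full H/G/I/E/B/T/S/C code set, per-residue
  class fractions over a trajectory.
* **Solvent accessibility** — LCPO (linear combinations of pairwise
  overlaps) per-atom SASA, side-chain residue series,
  accessible/buried classification, kernel density estimates.
* **Collective variables** — mass-weighted COM distances, ejection-event
  detection with per-system baselines, dissociation timing/rates,
  two-distance kinase-activity calls
  (inactive / partially_active / active), k-means conformer extraction
  with real centroid frames.
* **Interface energetics** — per-residue decomposition of
  receptor–ligand binding energy under a declared screened
  molecular-mechanics model (exact share conservation; ±2 kcal/mol
  reporting filter).  Not MM-PBSA: outputs carry a mandatory
  model-provenance header.
* **Toy accelerated MD** — boost ΔV = (E−V)²/(α+E−V) with the analytic
  force scale α²/(α+E−V)², BAOAB Langevin dynamics, exp(ΔV/kT)
  reweighting, boost-parameter estimation, transition counting.
* **Conservation** — aligned-FASTA position mapping through gaps,
  phospho-site presence/absence with clade summaries, S/T-P motif scans.
* **Synthetic data** — a trimer-trajectory generator that plants
  machine-readable ground truth (contact schedules, helix masks,
  ejection frames, burial schedules) so every stage is testable without
  external data.

## Worked example

Generate a synthetic trimer with a planted ejection at frame 80, then
recover the persistent contact network, the ejection event and the
probe-residue burial schedule:

```r
library(ckitraj)

gen <- make_toy_trimer(
  toy_trimer_config(n_frames = 120, helix_fraction = 1, ejection_frame = 80L),
  seed = 1
)
man <- gen$manifest

persistent_network(gen$trajectory, threshold = 0.5)
#>   donor_chain donor_resid acceptor_chain acceptor_resid chain_pair
#> 1           C          14              A            101        A-C
#> 2           C          15              B            102        B-C
#> 3           C          16              A            103        A-C
#>   lifetime_fraction longest_episode_ns is_bound
#> 1         0.9000000               10.8     TRUE
#> 2         0.7500000                9.0     TRUE
#> 3         0.5583333                6.7     TRUE
```

Exactly the three planted persistent contacts survive the 0.5 threshold
(the five planted transients, fractions 0.05–0.3, are filtered out); each
has a > 1 ns episode, so all are classified bound.

```r
cv <- com_distance_series(gen$trajectory, man$selections$helix_segment,
                          man$selections$pocket)
detect_ejection(cv, baseline_window_ns = 3, delta_A = 5, sustain_ns = 2)$events
#>       type onset_ns sustained
#> 1 ejection      7.9      TRUE
```

Frame 80 at 0.1 ns/frame is time 7.9 ns: the detected onset matches the
planted ejection frame exactly, and the excursion is sustained to the end
of the run.

```r
s <- residue_sasa_series(gen$trajectory, "C", man$exposure$resid)
classify_accessibility(s)$fraction_accessible
#> [1] 0.4
```

The probe residue's solvent-accessible fraction recovers the planted 40%
exposure schedule exactly (buried frames report ~0 Å² inside the burial
cage; exposed frames ~113 Å², the full expanded sphere).

The same pipeline runs from one JSON config:

```sh
Rscript -e 'ckitraj::cli()' simulate --out fixture --seed 1 --frames 120
Rscript -e 'ckitraj::cli()' run-all --config config.json --out results/
```

producing RMSD series, the persistent network table, secondary-structure
fractions, SASA/accessibility series, CV events, the energy decomposition
with ranked contributors, cluster labels, and a run manifest in which
every parameter is tagged `paper` (mirrors a published setting) or
`assumed`.

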