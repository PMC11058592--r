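---
title: "Methods: loop-state populations, flexibility statistics and EVB energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-state populations, flexibility statistics and EVB energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopshift)
```

## The problem this package addresses

Protein tyrosine phosphatases (PTPs) carry a mobile catalytic loop — the
WPD-loop — that must close over the active site for catalysis. The loop
interconverts among at least three conformational states (closed, open and
a further "wide-open" state), moving on the order of 10 Å between the
extremes. Sequence changes on or near the loop (for instance, grafting
loop residues from one PTP onto another) can shift the equilibrium
populations of these states and thereby tune or abolish activity without
touching the chemical step itself.

`loopshift` implements the trajectory-ensemble analyses with which such
population shifts are established and explained from multi-replica
molecular-dynamics-style data:

1. **State classification** — per-frame Cα-RMSD of the loop to each
   reference conformation, argmin-with-cutoff labelling, population
   histograms and cutoff fractions.
2. **Flexibility statistics** — per-replica, per-residue RMSF; between-
   variant ΔRMSF; two-sided t-tests with replicas as the statistical
   unit; Benjamini–Hochberg control at a 5% false discovery rate.
3. **Interaction-network differences** — per-frame hydrogen-bond /
   contact / salt-bridge detection, state-conditioned occupancies, and
   ranked occupancy differences between variants.
4. **EVB/LRA energetics** — free-energy profiles along the energy-gap
   coordinate of a two-state empirical valence bond model from λ-mapping
   windows, and linear-response per-residue electrostatic contributions.
5. **A seeded synthetic-data generator** that produces every input above
   with known ground truth, so each stage is testable end to end.

## State classification

Every frame is superposed on a reference structure over a *fit* selection
and the RMSD is measured over a *measure* selection. The default fit set
is all non-loop Cα atoms and the default measure set the loop Cα atoms;
superposing on the scaffold rather than the loop isolates loop motion
from global tumbling. The fit/measure labels are echoed into output
attributes so downstream tables are self-describing.

Labelling is argmin-then-threshold: a frame is assigned the state whose
reference is nearest, provided that RMSD is within the state's cutoff;
otherwise it is `other`. Exact ties resolve by the fixed priority closed
> open > wide_open, making the rule deterministic and auditable. The
per-state cutoffs default to 1.5 Å for all three states — the same
threshold used for the "fraction of frames within 1.5 Å of the closed
reference" stability statistic — and are mandatory, echoed configuration
rather than hidden constants. `other` frames are excluded from all
state-conditioned statistics.

Histograms use a 0.16 Å bin width with edges anchored at 0, so bin
boundaries are identical across runs and variants. Cutoff fractions are
inclusive (`rmsd <= cutoff`) and reported per replica and pooled.

Population uncertainty is always quantified **between replicas**: the
pooled fraction is the frame-weighted mean and its standard error is the
between-replica standard deviation divided by the square root of the
number of replicas. Frames within a replica are autocorrelated, so
frame-level binomial errors would be wildly optimistic; replica-level
errors absorb the autocorrelation without needing to estimate it.

The productive-closure analysis summarises each steered replica by the
mean loop RMSD-to-closed and the mean centre-of-mass distance between a
catalytic side chain and its coordination target over a terminal window
(defaulting to the frames spanning the last 5 ns), then applies joint
cutoffs. The distance cutoff separating productive from non-productive
side-chain conformations is a required configuration value — it encodes a
structural judgement, not a universal constant.

## Flexibility statistics

RMSF is computed per replica with a two-pass mean-structure alignment:
frames are superposed (on the fit selection, by default the non-loop Cα
set) to the raw mean structure, the mean is recomputed from the aligned
frames, and the frames are aligned once more before
`RMSF_i = sqrt(mean_f |r_i(f) − <r_i>|²)` is evaluated. Under isotropic
per-axis Gaussian noise of width σ the estimator concentrates at σ√3,
which the test suite uses as a closed-form oracle.

ΔRMSF is the difference of replica means (positive = more flexible in
variant A). Significance testing uses one two-sided test per residue with
the per-replica RMSF values as the two samples — replicas, not frames,
are the exchangeable unit. Welch's unequal-variance test is the default
because nothing guarantees equal variances across sequence variants;
Student's pooled test is available for exactness checks against the
textbook statistic. Benjamini–Hochberg is applied across **all** residues
tested (m = number of residues), not a pre-filtered subset, at a default
FDR of 5%; flags are derived from `stats::p.adjust(method = "BH")`
q-values, which makes the step-up rule exactly `q <= fdr`. The structure
projection writes each significant residue's ΔRMSF into the PDB
temperature-factor column and 0 elsewhere, so viewers colour
"no significant difference" as neutral.

## Interaction networks

Detection criteria are deliberately simple and fully geometric. A
hydrogen bond requires donor–acceptor heavy-atom distance ≤ 3.5 Å and,
when hydrogens are present, a D–H···A angle ≥ 135°; a heavy-atom-only
mode (distance criterion alone) supports hydrogen-free reduced models and
is recorded in output metadata. Proline's backbone nitrogen is never a
donor — it has no amide hydrogen. Pairs inside one residue are reported
only when exactly one partner is a backbone atom, and backbone–backbone
pairs fewer than three residues apart are suppressed as covalently
enforced geometry. Contacts are residue pairs with any heavy
sidechain–sidechain distance ≤ 4.5 Å; oppositely charged groups within
4.0 Å are flagged as salt bridges.

Occupancy is the fraction of a state's frames in which an interaction is
detected, tabulated per replica. Between-variant differences are pooled
(frame-weighted) occupancy deltas, ranked by magnitude with a
deterministic tie-break on the canonical key. Keys are ordered by
(chain, residue index) of the lower partner and compare **by position**,
carrying both variants' residue names, so a loop substitution still joins
across variants. This occupancy-difference layer is a transparent,
oracle-checkable replacement for machine-learned feature-importance
scoring of interaction networks: every network change it reports is an
explicit difference of two measured occupancies with a replica-level
spread.

## EVB and LRA energetics

The estimator consumes per-frame diabatic energies `(E1, E2)` from a
ladder of λ-mapping windows (51 evenly spaced windows by default, the
standard protocol scale) and never touches force fields. The mapping
potential is the linear mixture `E_m = (1−λ)E1 + λ(E2 + α)`; the
adiabatic ground state is the lower eigenvalue of the 2×2 Hamiltonian
with constant coupling `H12`. Free energies between adjacent windows use
Zwanzig exponential averaging with a max-shift overflow guard, reported
in both directions as an overlap diagnostic; the profile along the gap
coordinate `x = E1 − (E2 + α)` (reactant at negative x) follows the
standard umbrella reconstruction, combining overlapping windows by count
weighting. WHAM-style self-consistent weighting is deliberately out of
scope; count weighting is transparent and adequate for well-overlapped
ladders.

Numerical choices that matter:

- **80 gap bins** by default, with bins entered by fewer than 10 frames
  dropped. Reading extrema off bin centres biases the barrier by
  O(bin width²); at 80 bins, together with a **three-point quadratic
  refinement** of each extremum, this discretisation bias falls below the
  seed-to-seed spread of the estimator at the default sampling (1,000
  samples per window), while per-bin occupancy stays comfortably above
  the minimum count.
- A barrier must stand **0.25 kcal/mol proud** of both flanking minima to
  count; sampled profiles ripple at the bin level, and without a
  prominence guard that ripple would masquerade as a barrier on
  barrierless (strongly coupled) surfaces. Profiles with no qualifying
  interior maximum raise an explicit no-barrier error rather than
  returning a fabricated number.
- Temperature defaults to 298 K; kT enters only through the estimator.

LRA per-residue electrostatic contributions use the endpoint half-sum
`½(⟨u^TS − u^RS⟩_RS + ⟨u^TS − u^RS⟩_TS)`, with the perturbation energy
evaluated under both charge sets on both endpoint ensembles, scaled by an
internal dielectric constant (default 4) that is recorded in the output.
The functional is exactly additive: summing per-residue contributions
equals applying it to per-frame totals, which the suite asserts to 1e-10.

## What the synthetic generator emulates — and what it does not

The generator builds a rigid helical Cα scaffold (optionally with
backbone N/C/O, Cβ and one side-chain tip atom per residue) whose loop
residues are displaced along a smooth arc: zero displacement for the
closed reference, half scale for open, and the full ~10 Å scale for
wide-open, matching the displacement magnitude of the motivating system.
A discrete-state Markov chain drives which reference each frame is built
from — so ground-truth labels are exact and stationary distributions are
available in closed form by eigen-analysis — and frames add independent
per-atom Gaussian noise (default σ = 0.3 Å per axis; per-residue
overrides plant flexibility differences). Interactions are planted by
placing partner atoms at hydrogen-bonding geometry with a prescribed
per-frame probability. Diabatic-energy ladders come from parallel
Metropolis chains on harmonic diabats (default k = 100 kcal/mol/Å²,
minima ±0.5, H12 = 2 kcal/mol), for which a dense-grid evaluation of the
ground surface is an independent barrier oracle. The default ensemble
scale — 15 replicas × 5,000 frames, 100 ps apart — mirrors the study
conditions the analyses target.

One generator helper, `simulate_rmsf_replicates()`, draws per-replica
RMSF values directly from the estimator's exact sampling law under
isotropic noise (`RMSF² = σ²·χ²₍₃₍F−1₎₎/F`). This is the distribution the
full coordinate pipeline produces on a rigid scaffold (asserted by the
suite), and it makes large statistical calibrations — hundreds of
simulated 282-residue cohorts for FDR control — affordable.

Because frames are generated at the analysis stride, jitter is
uncorrelated between frames by construction; state autocorrelation comes
only from the Markov chain. Real trajectories differ in ways that matter
for interpretation: correlated solvent-damped dynamics, anisotropic and
state-dependent fluctuations, conformational states that are not rigid
templates, and hydrogen-bond geometry coupled to its surroundings.
Passing tests therefore demonstrate that the *estimators* are correct and
calibrated under their stated assumptions, not that those assumptions
hold for any particular force field or protein.

## Problem sizes used by the test and acceptance suites

Where a check concerns statistical calibration at scale, the suite runs
the full 15 × 5,000-frame preset (state recovery and population errors).
Checks whose power is already overwhelming at smaller sizes use reduced
ensembles chosen as the package's own trade-off between coverage and
runtime: 15 × 1,500 frames for the planted 0.7-vs-0.3 population-shift
separation, 2 × 120-frame cohorts (20–50 seeds) for planted-bond
recovery, 100–200 simulated cohorts for FDR calibration, and 20 seeded
51-window ladders at 1,000 samples per window for barrier recovery.

## Known limitations

- No periodic-boundary handling: inputs are assumed whole molecules.
- Binary trajectory formats (DCD/XTC/NetCDF) are not read; multi-model
  PDB and the package's tabular text format are the interfaces.
- Insertion codes are rejected rather than resolved.
- π-stacking and cation–π interactions are not detected.
- The EVB layer estimates free energies from supplied diabatic energies;
  computing those energies, or fitting H12/α to experiment, is out of
  scope.
- Markov state modelling and kinetic rate extraction are deliberately
  absent; the package quantifies *populations*, not rates.
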