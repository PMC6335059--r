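---
title: "Quantifying channel asymmetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying channel asymmetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(secasym)
```

`secasym` analyses molecular trajectories of the SecY translocon for
signatures of nucleotide-dependent asymmetry between the cytoplasmic and
exterior cavities that flank the pore ring. This vignette is the package's
account of the science behind each stage: the models, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic ground
truths do and do not establish.

## Coordinate conventions

All analyses work in a channel frame whose origin is the unweighted centroid
of the pore-ring residues (recomputed per frame; the selection is
configurable because different structures justify seeding from four pore
isoleucines or from the full six-residue ring) and whose axis is the
laboratory +z, with the cytoplasmic side at z > 0. The user is expected to
have aligned the membrane normal with z beforehand, as is standard for
membrane-protein simulations. Coordinates are Angstrom, times picoseconds,
energies kcal/mol. Residue indices follow the source file (1-based) and all
residue windows are inclusive closed intervals. No periodic-boundary imaging
is applied by any operator: inputs must be pre-imaged, which keeps every
operator a pure function of the coordinates it is given.

## Secondary structure and the degree of folding

Assignment uses the Kabsch–Sander electrostatic hydrogen-bond model on
backbone N, H, C, O atoms:

$$E = q_1 q_2 \, f \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right), \qquad
q_1 q_2 = 0.084\,e^2,\; f = 332\ \mathrm{kcal\,\mathring{A}/(mol\,e^2)},$$

with a bond iff E < −0.5 kcal/mol. Amide hydrogens are rebuilt at 1.01 Å
from N, opposite the bisector of the C(prev)–N and CA–N directions; the
first residue of a chain and prolines have no donor, and sequence-adjacent
pairs (|i − j| < 2) are never bonded. An n-turn at residue i (n = 3, 4)
means the carbonyl of i accepts from the amide of i + n; two consecutive
4-turns make residues i+1..i+4 α-helical (H), two consecutive 3-turns make
i+1..i+3 3₁₀-helical (G) with H taking precedence, residues inside isolated
turns are T, and everything else is C. Only these four labels are
implemented — the labels that occur for a short substrate confined inside
the channel. β-bridges and sheets, π-helix, bends and the rest of the
8-state machine are deliberately out of scope: an extended strand threading
the pore has no partner strand to pair with.

The *degree of folding* of a nine-residue cavity window is the fraction of
residue–frame pairs labelled {H, G, T}. Whether isolated turns count as
"folded" is genuinely open; they are included by default because a
hydrogen-bonded turn is the nucleus of helix formation and excluding it
(`folded = c("H", "G")`) mostly rescales both cavities equally. An
alternative normalisation (fraction of frames with ≥ 1 structured residue)
was considered and rejected: it saturates near 1 for any persistent helix
and so compresses exactly the asymmetry the statistic exists to measure.
Replicate windows are compared with Student's two-sample t-test (two-tailed)
by default, matching common practice for small equal-design replicate
groups; Welch is available. Two groups that are each exactly constant are
rejected as an error rather than reported as p = 0 — with zero variance the
t statistic is undefined and any finite answer would be an artifact.

## Channel geometry

The pore profile is the classic sphere-probe construction: at each axial
step the in-plane centre c maximising the clearance
$f(c) = \min_i(\lVert c - x_i \rVert - vdw_i)$ is found, walking from z = 0
outwards and seeding each step with the previous optimum. The maximiser is
Nelder–Mead restarted from five deterministic seeds (the walk seed and four
0.5 Å jitters); simulated annealing, the historical choice, buys nothing on
this 2-D piecewise-smooth objective, and the brute-force 0.1 Å grid search
kept in the test suite is the arbiter of correctness. The z-grid step is
fixed at 0.5 Å — the same partition the trapezoidal volume integration
uses — and volumes are integrated per side over |z| ≤ 6.5 Å, i.e.
13 intervals per side with half-weighted endpoints. Two failure modes are
made explicit rather than visual: a probe whose optimum runs to the 15 Å
trust-region boundary has escaped the wall and is flagged `burst` with its
radius capped, and a z-level whose seed lies inside an atom is reported as
radius 0 with a warning (an occluded channel, not an error).

Contacts use the standard heavy-atom convention (element ≠ H) with a 0.3 nm
cutoff, averaged over the window's residues within each frame and then over
frames.

## Water dynamics

Waters are assigned to 24 slices of 0.5 nm in a 5 × 5 × 12 nm prism centred
on the pore ring, by their position at the first analysed frame. Membership
is *not* re-evaluated as particles drift: re-binning mid-window would make
the per-slice MSD a statistic of a changing population and so ill-defined.
Particles that leave the prism are kept by default (`censor_leavers` drops
them; with it, a slice's n reflects only never-leaving particles).
Per-slice MSD uses every frame as a time origin (overlapping origins, the
standard estimator), and the final 25 ps of the curve is fitted by linear
least squares on (log t, log MSD); A is the slope. The log–log fit is
deterministic and convex where a nonlinear fit of k·t^A needs starting
values and can stall; on synthetic power laws both agree to machine
precision, and the exactness tests pin that down.

The estimator's sampling noise matters for interpretation: a single slice
of 200 particles over 100 frames carries an irreducible sd of about 0.06 on
A, dominated by the few effective origins at the longest lags. Per-condition
exponents are therefore reported as slice/replicate averages (the acceptance
script uses 24 slices × 200 particles × 3 replicates, which brings the
error below 0.01), and per-slice values are interpreted against their
s.e.m., never as point estimates.

## Mechanics

The elastic network is the standard Cα anisotropic network model: springs of
constant γ between nodes within 15 Å, Hessian blocks −γ ΔxΔxᵀ/d², diagonal
minus the row sum. A connected, non-degenerate structure has exactly six
zero modes; more flags a disconnected or collinear input. The per-residue
deformation energy of a mode v is
$e_i = \sum_{j: d_{ij} \le c} \gamma [(v_i - v_j)\cdot(x_i - x_j)/d_{ij}]^2$
summed over the first three non-trivial modes, each normalised to unit
length so the fields are comparable across structures; per-structure
normalisation to a unit maximum is optional (the cross-state alternative is
a flag away, but per-structure is the default because the mode amplitudes
of two different structures have no common physical scale in an ENM).
This pairwise distance-distortion form measures motion relative to
neighbours, so rigid translations and rotations carry exactly zero energy —
one of the package's invariant tests.

Spin-label analyses mirror what simulations can actually be compared
against: the per-frame distance between the unweighted centroids of the two
nitroxide ON groups, summarised by a Gaussian KDE (Silverman bandwidth) on a
fixed 0.01 nm grid, its argmax (modal distance) and its full width at half
height. For a Gaussian ensemble FWHH → 2.3548 σ, the identity the tests
exercise at n = 5000 within the KDE's bandwidth broadening. Degenerate
(single-valued) ensembles are flagged and their FWHH reported as the
bandwidth-limited minimum; multimodal ensembles are flagged and the width
refers to the peak containing the mode only. Rotamer-library prediction and
DEER time-trace processing are out of scope.

Passage times track the signed axial offset of the substrate-region centre
of mass relative to the pore-ring centre of mass; the passage time is the
first frame time at which the offset has changed sign and reached the exit
offset (default 5 Å) in magnitude. The crossing test is inclusive
(≥, with a 1e−9 Å tolerance) so that exact closed-form fixtures — a linear
ramp crossing at a frame time — are scored on that frame. Records that
never qualify are "did not pass" and are excluded from group comparisons
with their count reported, rather than imputed: at desk scale there is no
defensible censoring model for them.

## Differential HDX

Per peptide and exposure time, Δ = mean(ATP) − mean(ADP) in Da with pooled
standard error. Significance demands both |Δ| > 0.9 Da (the fixed rule) and
|Δ| > t₀.₀₀₅,df · SE (the per-peptide 99% CI); Δ > 0 is deprotected. The
0.9 Da constant can be replaced by `compute_threshold()`, a Houde-style
global pooled-SE threshold t₁₋α/₂,df · mean(SE); on a homoscedastic table
with σ = 0.2 Da and triplicates this evaluates near
qt(0.995, 4) · 0.2 · √(2/3) ≈ 0.75 Da (slightly below it in sample, since
E[s] < σ at n = 3). The threshold is global across timepoints by default;
nothing in the rule's statement forces a per-timepoint version, and a
global threshold is the conservative reading. Analysis is peptide-level
only — no back-exchange correction, no residue-level subtraction.

## The synthetic-data generators

The generators are first-class, tested code, and their defaults are the
study conditions: triplicate HDX tables over 0.25/1/5/30 min, nine-residue
cavity windows, the 24-slice prism, the 31-snapshot schedule
(500, 502, …, 910, 1000 ns), α at φ/ψ = −57/−47 and 3₁₀ at −49/−26 with
ideal bond geometry, coil dihedrals sampled from the extended region so no
helical hydrogen bond can form.

Fractional Brownian baths are synthesised per particle by circulant
embedding (Davies–Harte) of fractional Gaussian noise, with H fixed by each
particle's initial slice — particles do not change regime mid-run, which is
what makes 2H an exact per-slice ground truth. Channel walls are laid on
the *envelope* surface ρ(z) = (r₀ + vdw + s|z|)/√(1 − s²): a sphere probe
touches a sloped wall obliquely, so tiling the naive surface of revolution
would systematically understate the profile by the cone's cosine factor.
At the waist of an asymmetric channel the two sides' target spheres
overlap; wall atoms strictly inside the union are pruned, because the
requested kinked profile is not otherwise realisable by any sphere probe
(the residual deviation, ~0.1 Å at the waist, is below the discretisation
contract of half the atom spacing).

What the generators do *not* emulate bounds what green tests mean: the
water baths have no hydrogen bonding, density structure or rotational
dynamics; backbones have no side chains beyond the residue name; channel
walls are rigid and frozen; HDX noise is Gaussian and homoscedastic;
passage ramps have no barrier recrossing statistics. Passing tests
establish that the *estimators* recover known truths at desk scale — they
say nothing about force fields or sampling of the original simulations.

## Orchestration and problem sizes

`run_pipeline()` composes the stages over a two-state synthetic bundle
(ATP-like: 10-fold exterior excess of imposed helix content, a cytoplasmic
wall slope of 0.4 Å/Å, exterior-side H = 0.35; ADP-like: symmetric) and
reports per-stage asymmetry tests plus provenance (config hash, seed,
package version). Stages fail independently; a failed stage is recorded in
the report, not propagated. Identical configurations reproduce identical
outputs byte for byte, which the suite asserts by comparing serialized
reports.

Test and acceptance problem sizes are chosen so the whole battery runs in
minutes on one core while keeping every tolerance honest to the estimator
noise at that size: 12-residue backbones, channels of a few thousand wall
atoms, baths of 200 particles per slice over 100 frames (three replicates
for headline exponents), 5000-member label ensembles, 1000-peptide HDX
tables. Raw p-values are reported throughout, as is conventional for this
kind of replicate-level analysis; an optional Bonferroni column is off by
default.

## Known limitations

The package analyses trajectories; it does not produce them. Force-field
choices, thermostats, equilibration, steering forces and homology modelling
are upstream concerns recorded at most as configuration metadata. The pore
profiler assumes an approximately axis-aligned channel (its in-plane search
follows a drifting centre but the slicing plane is fixed); strongly tilted
or branched pores need realignment first. DCD/XTC binary trajectories are
not read natively — convert to multi-model PDB or the plain-text xyztraj
dialect. The HDX module classifies; it does not model exchange kinetics.
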