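---
title: "Membrane orientation and lipid-contact analysis of GPI-anchored three-finger proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane orientation and lipid-contact analysis of GPI-anchored three-finger proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luorient)
```

## The model

A GPI-anchored three-finger (Ly6/uPAR) protein in a planar bilayer has, to a
good approximation, three slow collective coordinates: how high it floats
above the membrane, how the head-to-central-loop axis pitches, and how the
molecule rolls about that axis. `luorient` reduces a trajectory to this
(Z, α, β) triad per frame and derives distribution statistics, a principal
component decomposition, and typed lipid-contact lifetimes from it.

The underlying assumptions, all of which the implementation checks or makes
explicit:

- the bilayer is planar and stays normal to the box z-axis, so the membrane
  normal is (0, 0, 1) and no per-frame surface fitting is performed;
- leaflet identity is static on the simulated timescale: lipids are assigned
  to leaflets once, from the phosphorus z-coordinates of the first frame,
  and the assignment is frozen (per-frame re-sorting would flip-flop on
  transient z-crossings while real flip is negligible over microseconds);
- the protein is a connected molecule that may straddle the periodic box;
  it is unwrapped before any centre-of-mass or vector computation, while
  membrane atoms stay wrapped;
- centres of mass are mass-weighted everywhere. The COM height uses the
  amino-acid atoms only: glycans and the GPI anchor are bookkept as separate
  moiety classes and excluded.

## The angle pair and the disambiguation vector

α is simply 90° minus the angle between the head→loop-II vector **A** and the
normal. β is built from the loop-III→loop-I vector **B** through a
three-branch rule switched on the signs of B_z and F_z, where **F** resolves
which hemisphere the molecule rolled into.

Two non-obvious consequences of the rule shaped the implementation:

1. **F must complete the frame.** Writing unit body axes a ∥ **A**,
   b ∥ **B**, n = a × b, the rule evaluates to cos ∠(**B**, **Z**) = sin β in
   *all three* branches; the branch index is carried entirely by the sign of
   F_z. The only body vector whose z-sign, together with (a_z, b_z),
   determines the orientation is the sheet normal n. The package therefore
   defaults to `f_vector = "sheet_normal"` (unit **A** × **B**); `"a"` and a
   custom two-group definition remain available as overrides for matching
   other conventions. With F = **A** the rule cannot even represent a
   loop-down pose with negative α and β near −90°, which anchored
   three-finger proteins visit routinely.
2. **The admissible domain is sin²α + sin²β ≤ 1.** Because a_z = sin α and
   b_z = sin β with a ⊥ b, extreme rolls (β → ±90°) are only reachable at
   small tilts and vice versa. `pose_protein()` rejects poses outside the
   domain, and the synthetic generator projects its stochastic draws onto it
   (shrinking |sin β| onto the boundary) and clamps |α| at 89.9° away from
   the gimbal pole, where β is undefined. Observed extremes in real
   three-finger systems respect the domain comfortably (large |β| occurs at
   small |α| and the largest |α| at β near 0°/180°).

Ties at B_z = 0 with F_z < 0 take the middle branch, exactly as the
inequalities are written, which places the seam of the circle at ±180° and
keeps the rule continuous everywhere off the poles (verified by a 1° grid
sweep in the acceptance suite).

## Distribution statistics

Histograms are probability-normalised (not densities), with default bin
widths of 0.05 nm for Z, 2° for α and 4° for β — fine enough to resolve the
narrowest modes typically reported (SD ≈ 0.13 nm, ≈ 4°) — and β is binned on
the half-open circle (−180°, 180°].

Mode fitting is a univariate Gaussian mixture with k = 1..3 unequal-variance
components, maximum likelihood via EM (delegated to `mclust`, whose
model-based hierarchical initialisation is deterministic, so no random
restarts are needed; the `seed` argument guards any residual tie-breaking).
k is chosen by minimal BIC — deliberately conservative, matching the
at-most-trimodal description of these systems; AIC would overcount shoulders.
Each mode is reported as median ± SD (median = mean for a normal) with its
weight; weights below 0.25 are flagged "low-population", an explicit,
configurable stand-in for the convention of parenthesising minor modes.

β is recentred before fitting: the centre of the longest empty arc of the
angular distribution is found, and the data are shifted so that arc contains
the wrap point (`shifted = wrap(x − offset + 180)`, making offset = 180 the
identity; near-uniform data return the identity). The inverse shift is exact,
and fits agree across recenterings to well under half a degree. Without this,
a single mode straddling ±180° would be split in two.

`pearson()` is the plain product-moment correlation, provided for
linker-length-versus-height style comparisons across proteins.

## Backbone PCA

The superposition removes only the in-plane rigid motions: each frame is
fitted to the reference by the least-squares rotation about z plus an x/y
translation (2D Procrustes via the 2×2 cross-covariance SVD, reflection
excluded); z passes through untouched. Rise, pitch and roll relative to the
membrane therefore survive the fit and dominate the leading components. The
covariance of the 3N backbone coordinate vector is unweighted — backbone
atoms have near-uniform masses and an unweighted covariance keeps
eigenvalues in nm² of coordinate variance; trace conservation is asserted to
1e-9. Tied extreme projections resolve to the lowest frame index.

## The synthetic generator

The generator exists so that every stage has an exact oracle. It emulates:

- a static planar patch of bead lipids (default 6×6 per leaflet, 0.8 nm
  spacing, 4 nm between phosphate planes) with headgroup z-jitter of SD
  0.05 nm per lipid per frame — the headgroup moves as a unit so planted
  contact geometry stays margin-separated;
- a rigid mock three-finger protein whose (Z, α, β) paths follow
  mixture-of-Gaussian targets realised as Ornstein–Uhlenbeck processes
  (relaxation time 5 ns at a 1 ns frame spacing) with seeded Markov switching
  between wells (stationary occupancy = the mixture weights, default
  per-frame switch probability 0.005) — autocorrelated series that look like
  MD without simulating physics; β is propagated on the circle;
- optional planted residue–lipid contacts: dedicated probe residues
  (Lys, Ser/Tyr hydroxyl, Tyr ring, Asp, Leu) are placed within the relevant
  cutoff of a chosen lipid bead in an exact, seeded random subset of frames
  and parked far above the membrane otherwise, beyond every cutoff plus a
  0.2 nm margin. Probe residues are excluded from the orientation groups, so
  planting never perturbs the (Z, α, β) ground truth. A planted hydrophobic
  contact creates two simultaneous atom pairs by construction (its detected
  lifetime is twice the planted presence fraction), which is what the
  report's "two simultaneous contacts" rule needs exercising.

The default orientation settings are the published behaviour of Lynx1 —
unimodal COM height 1.43 ± 0.21 nm, tilt modes −31.5 ± 8.7° (weight 0.8) and
0.7 ± 6.5° (weight 0.2, low-population), rotation modes −121.6 ± 8.6° and
−47.9 ± 7.2° at equal weight. The minor-mode weights are not published; 0.2
was chosen once as "minor but clearly visible" and sits below the 0.25
low-population flag, and equal β weights reflect that neither rotation mode
is parenthesised in the source table.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: membrane undulations and thickness fluctuations,
protein internal dynamics (the mock is rigid), glycan/GPI conformational
sampling, water, and any coupling between height, tilt and contacts. Tests
against it validate the *measurement* pipeline, not force-field biology.

## Contact analysis

Atoms are annotated from residue + atom names by shipped, swappable tables:
formal charge groups (Lys/Arg cationic, Asp/Glu anionic, phosphate anionic,
choline cationic; His neutral), hydrogen-bond donors and acceptors, aromatic
rings, and the sign of the atomic lipophilicity constant (carbons are
lipophilic unless adjacent to polar/charged groups) used for hydrophobic
contacts in the molecular-hydrophobic-potential sense. The numeric criteria
are standard MD-analysis conventions, all configurable: hydrogen bond at
donor–acceptor ≤ 0.35 nm with H–donor–acceptor ≤ 30° (when a donor has no
resolvable hydrogens — united-atom or bead topologies — the distance
criterion alone applies); ion–ion at ≤ 0.45 nm between opposite charged
groups; ion–dipole at ≤ 0.40 nm; π–cation at cation–centroid ≤ 0.60 nm
within 45° of the ring normal; hydrophobic at ≤ 0.45 nm between
positive-lipophilicity atoms.

Relative lifetime divides accumulated per-frame counts by the frame count,
per lipid class and in total, so several simultaneous partners push it above
one. The report applies the published thresholds (polar ≥ 10%, π–cation
≥ 5%, hydrophobic: ≥ 2 simultaneous and total > 200%) and precedence:
residues with qualifying ionic contacts absorb their hydrogen-bond listing;
the π–cation column is independent (a residue may appear there *and* under
hydrogen bonds, as published tables do); the hydrophobic column takes only
residues absent everywhere else. Emphasis tiers (bold at ≥ 50%, underline at
≥ 75%) apply to the polar columns.

One bookkeeping constraint: lipid residue numbers are assumed unique among
lipids (protein and lipid residues are distinguished by moiety class, so
protein/lipid number collisions are harmless).

## Problem sizes and numerical tolerances

The test and acceptance suites use sizes chosen to make their statistics
decisive while staying desk-scale: 1000 random pose triads for the
round-trip identity (recovered to < 1e-6, typically 1e-13), a 1°×1° grid
(129,600 evaluations) for branch continuity and circle coverage, 100
replicates of 2000 draws for bimodal mode recovery (≥ 95% required), and
1000-frame fixtures for exact planted-lifetime recovery. Histogram
normalisation is asserted to 1e-12, eigen-orthonormality and trace
conservation to 1e-9. Pose round trips are exact only in double precision;
DCD files store single-precision ångströms, so file round trips are asserted
at 1e-5 nm instead.

## Known limitations

- Planar bilayers only; no curved or vesicle membranes.
- Trajectory input is DCD (plus PDB/GRO topologies); XTC/TPR are not parsed.
- The head/loop-tip residue groups must be supplied per protein; shipped
  mock groups are for the synthetic template only. Reproducing published
  per-protein numbers requires the original residue-group definitions and
  deposited trajectories, and agreement further depends on matching the
  original F-vector convention (see the `f_vector` override) and the exact
  contact criteria of the original analysis software, which are not public.
- Whether the published COM group included hydrogens is unknown; the package
  uses all atoms of the amino-acid selection the caller provides, so either
  convention is expressible through the selection.
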