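# luorient

Orientation and lipid-contact analysis of GPI-anchored three-finger
(Ly6/uPAR) proteins from molecular dynamics trajectories.

Ly6/uPAR proteins carry a compact disulfide-stabilised β-structural core (the
"head") with three protruding loops ("fingers") and are tethered to the outer
membrane leaflet by a glycosylphosphatidylinositol (GPI) anchor. Whether the
anchor pre-orients the receptor-binding loops relative to the membrane is a
question answered by post-processing long MD trajectories. `luorient`
implements that post-processing for anyone running such simulations: it
reduces a trajectory to the three coarse state variables of an anchored
three-finger protein and classifies its lipid contacts.

## The state triad

For a planar bilayer with membrane normal **Z** = (0, 0, 1):

- **Z (rise, nm)** — the z-distance from the mass-weighted centre of mass of
  the protein's amino-acid atoms to the mean z of the upper-leaflet lipid
  phosphorus atoms (leaflets are assigned once, from the first frame).
- **α (pitch, deg)** — with **A** the vector from the head-group COM to the
  central-loop (loop II) tip COM, α = 90° − ∠(**A**, **Z**) ∈ [−90°, 90°].
  α > 0: the head dips toward the membrane; α < 0: the central loop does.
- **β (roll, deg)** — with **B** the loop III → loop I vector and **F** a
  hemisphere disambiguator (default: the β-sheet normal, unit **A** × **B**):

  β = 90° − ∠(**B**, **Z**) if F_z ≥ 0;
  β = 90° + ∠(**B**, **Z**) if B_z ≥ 0 and F_z < 0;
  β = −270° + ∠(**B**, **Z**) if B_z < 0 and F_z < 0;

  mapped into (−180°, 180°]. β ≈ −90°: loop I down; +90°: loop III down;
  0°: ventral side down; ±180°: dorsal side down. Note the rule implies
  cos ∠(**B**, **Z**) = sin β in every branch, so admissible poses satisfy
  sin²α + sin²β ≤ 1.

On top of the triad the package provides probability histograms (1D and α/β
2D), uni/bi/trimodal Gaussian mode fits (BIC-selected, circular-aware for β),
backbone PCA after xy-only superposition, and typed protein–lipid contact
lifetimes (ionic/ion–dipole, hydrogen bond, π–cation, hydrophobic by atomic
lipophilicity) rendered as a tiered residue report. A synthetic rigid-body
trajectory generator with exact ground truth makes every stage testable
without simulation data.

## Worked example

Generate a synthetic 2 µs-like trajectory (2000 frames, 1 ns apart) whose
orientation processes emulate a unimodally floating, loop-down protein, then
recover its state distributions:

```r
library(luorient)

spec <- synthetic_spec(n_frames = 2000)        # Lynx1-like defaults
sim  <- generate_trajectory(spec, seed = 11)
os   <- orientation_series(sim$trajectory, sim$groups)
summary(os)
#> Orientation series: mock3f - 2000 frames
#>                min   median     max     sd
#> Z_nm         0.683    1.450   2.109  0.209
#> alpha_deg  -56.546  -30.297  15.145 12.484
#> beta_deg  -152.591 -120.056 -28.471 37.421

fit_modes(os$Z_nm, seed = 1)
#> Gaussian mode fit: k = 1 ( n = 2000 )
#>   mode 1: 1.447 +- 0.208  (weight 1.00)

fit_modes(os$alpha_deg, seed = 1)
#> Gaussian mode fit: k = 2 ( n = 2000 )
#>   mode 1: -31.287 +- 8.765  (weight 0.91)
#>   mode 2: -0.102 +- 5.921  (weight 0.09)  [low-population]

fit_modes(os$beta_deg, seed = 1, circular = TRUE)
#> Gaussian mode fit: k = 2 ( n = 2000 )
#>   mode 1: -125.371 +- 8.070  (weight 0.65)
#>   mode 2: -48.406 +- 6.552  (weight 0.35)
```

The fits recover the generator's settings (COM height 1.43 ± 0.21 nm; tilt
modes −31.5° and 0.7° with the minor mode flagged low-population; rotation
modes −121.6° and −47.9°). Contact analysis on a fixture with planted
contacts:

```r
sim <- generate_trajectory(synthetic_spec(n_frames = 100,
          Z = list(means = 2.0, sds = 0.01, weights = 1),
          alpha = list(means = 0, sds = 1, weights = 1),
          beta  = list(means = 0, sds = 1, weights = 1)), seed = 5)
plan <- data.frame(resno = c(51, 55, 52), type = c("ionic", "hbond", "pication"),
                   fraction = c(0.8, 0.55, 0.06))
sim  <- plant_contacts(sim, plan, seed = 9)
contact_report(contact_timelines(sim$trajectory))
#> Ionic/ion-dipole: __**K51**__
#> Hydrogen bonds:   **S55**
#> Pi-cation:        Y52
#> Hydrophobic:      -
```

Lifetimes are recovered exactly (0.80, 0.55, 0.06); emphasis tiers mark
lifetimes ≥ 50% (bold) and ≥ 75% (bold + underline).

For real data, point the same functions at your files:

```r
top    <- load_topology("system.pdb")
traj   <- load_trajectory(top, "production.dcd", stride = 10)
groups <- read_groups("groups.yaml", topology = top)   # head/loop-tip residues
os     <- orientation_series(traj, groups)
```

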