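# secasym

Trajectory analysis of ATP-driven asymmetry across the SecY protein-conducting
channel.

During post-translational translocation, an unfolded pre-protein threads
through the SecY channel, driven by the SecA ATPase. A Brownian-ratchet view
of this process predicts that the nucleotide state of SecA biases where
transient secondary structure can form around the pore ring — the hydrophobic
constriction separating the cytoplasmic and exterior (periplasmic) cavities —
and thereby rectifies the substrate's diffusion into net forward transport.
Testing that prediction requires a battery of trajectory analyses: per-residue
secondary-structure assignment inside each cavity, cavity geometry and
volumes, water dynamics along the channel axis, substrate–channel contacts,
local chain mechanics, spin-label distance distributions, passage kinetics,
and differential hydrogen–deuterium exchange. `secasym` implements that
battery as a tested, reusable R package, together with synthetic-data
generators that give every stage a known ground truth at desk scale.

## Methods at a glance

* **Secondary structure** — Kabsch–Sander electrostatic hydrogen-bond
  criterion, `E = 0.084 · 332 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol
  with a bond iff `E < −0.5`; labels H (α-helix, paired i→i+4 turns),
  G (3₁₀-helix, paired i→i+3 turns), T (isolated turn), C (none).
  The *degree of folding* of a nine-residue cavity window is the fraction of
  residue–frame pairs labelled {H, G, T}, compared between cavities by a
  two-tailed two-sample t-test.
* **Channel geometry** — sphere-probe pore profile: at each 0.5 Å axial step
  the largest sphere centred in that plane touching no atom,
  `r(z) = max_c min_i (|c − x_i| − vdw_i)`; cavity volumes by the trapezoidal
  rule over π r(z)² for 6.5 Å on either side of the pore ring; contacts as
  heavy-atom inter-residue distances < 0.3 nm.
* **Water dynamics** — a 5 × 5 × 12 nm prism centred on the pore ring is cut
  into 24 slices of 0.5 nm; per-slice ensemble MSD with sliding origins is
  fitted over its final 25 ps to `MSD(t) = k t^A`; A = 1 is free diffusion,
  A < 1 subdiffusion.
* **Mechanics** — Cα anisotropic elastic network (cutoff 15 Å); per-residue
  deformation energy `Σ_j γ[(v_i − v_j)·(x_i − x_j)/d_ij]²` summed over the
  first three non-trivial modes; spin-label centroid distances summarised by
  KDE modal distance and full width at half height (2.3548 σ for a
  Gaussian); passage times from the signed axial offset of the substrate
  relative to the pore-ring centre of mass.
* **Differential HDX** — per-peptide ΔD = mean(ATP) − mean(ADP); significant
  iff |Δ| > 0.9 Da *and* |Δ| exceeds the per-peptide 99% confidence
  interval; Δ > 0 deprotected, Δ < 0 protected.
* **Synthetic data** — ideal helical/coil backbones from internal
  coordinates; channel-shaped atom clouds with analytic pore profiles;
  water baths with position-dependent fractional Brownian dynamics (MSD
  exponent = 2H by construction); mirrored/tandem 18-mer substrates from a
  9-residue seed; glycine-window scans; spin-label ensembles and steered
  passage ramps; replicate HDX uptake tables.

## Worked example

Profile an asymmetric hourglass channel (waist 3 Å, cytoplasmic wall opening
at 0.4 Å/Å) and integrate its cavity volumes:

```r
library(secasym)
ch <- build_channel("asymmetric-hourglass", r0 = 3, slope_cyt = 0.4, slope_ext = 0)
profile <- pore_profile(ch, origin = c(0, 0, 0))
profile
#> Channel profile: 27 steps, z in [-6.5, 6.5] A, radius 3.00-5.60 A
v <- cavity_volumes(profile)
cat(sprintf("v_cyt = %.1f A^3, v_ext = %.1f A^3, ratio = %.2f\n",
            v$v_cyt, v$v_ext, v$cyt_over_ext))
#> v_cyt = 391.2 A^3, v_ext = 184.6 A^3, ratio = 2.12
```

The analytic ratio for this shape is 2.117, recovered to 0.2%. Assign
secondary structure to an ideal 12-residue α-helix — the interior is
labelled H, the chain ends cannot complete the paired-turn pattern:

```r
assign_ss(build_backbone(12, "alpha"))[, 1]
#>   1   2   3   4   5   6   7   8   9  10  11  12
#> "C" "H" "H" "H" "H" "H" "H" "H" "H" "H" "H" "C"
```

Recover a sub-diffusive band imposed on the four central water slices
(H = 0.35, so the ground-truth exponent is 0.70):

```r
Hfun <- function(z) if (abs(z) < 10) 0.35 else 0.5
trajs <- lapply(1:3, function(r)
  build_bath(2400, box = c(50, 50, 120), H = Hfun, D = 0.1, dt = 0.5,
             n_frames = 100, seed = r))
prof <- slice_exponent_profile(trajs, prism_spec(), window = 25)
head(subset(prof, abs(z_mid) <= 15), 8)
#>    slice z_mid A_mean  A_sem n_rep n_waters
#> 10     9 -12.5  1.004 0.0581     3    100.7
#> 11    10  -7.5  0.587 0.0501     3    102.7
#> 12    11  -2.5  0.712 0.0607     3     99.3
#> 13    12   2.5  0.701 0.0319     3     97.0
#> 14    13   7.5  0.685 0.0389     3    100.3
#> 15    14  12.5  0.980 0.0121     3     94.0
```

`run_pipeline(default_config(seed = 1))` composes the stages into a full
two-state (ATP-like vs ADP-like) asymmetry report; see the methods vignette
(`vignettes/channel-asymmetry.Rmd`) for the model behind each stage and the
meaning of every tunable.

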