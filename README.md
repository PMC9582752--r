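# gtkit

Analysis toolkit for GH57-family 4-α-glucanotransferase (4-α-GTase,
EC 2.4.1.25) studies. These enzymes drive maltooligosaccharide
disproportionation in hyperthermophilic archaea: they cleave an α-1,4 bond,
hold the donor-side fragment as a covalent glycosyl-enzyme intermediate, and
resolve it onto a sugar acceptor (transglycosylation) or onto water
(hydrolysis). Characterising them combines structural modelling, docking,
steady-state kinetics and product profiling — gtkit implements the
quantitative side of that workflow, end to end, for structural biologists
and enzymologists working on glucanotransferases:

* **Structure I/O** — fixed-column PDB / multi-model PDB / minimal PDBQT
  reading and writing, reference-ligand (acarbose-style) annotation with
  subsite moiety maps, alanine-truncation mutant structures, and Vina-style
  docking-box configs (30 Å cube on the active-site anchor atom).
* **Pose geometry** — the substrate positional coordinate
  s = (centroid(pose) − origin) · û, where û is the unit vector between the
  C4A/C1 axis anchors and the origin is the N4A projection onto that axis;
  a greedy sub-ångström atom match (globally shortest pair, matched if
  d < 1 Å, both atoms removed, repeat); subsite calibration and assignment;
  minimum residue–ligand contact distances.
* **Kinetics** — Lineweaver–Burk fits (1/v = KM/Vmax · 1/[S] + 1/Vmax) with
  kcat = Vmax/[E] conversion and catalytic efficiencies kcat/KM,
  iodine-assay unit conversion, transglycosylation factors
  (activity with acceptor / activity without), and specific growth rates
  k = d ln N/dt over the exponential window.
* **Subsite simulator** — mass-action disproportionation over nine binding
  subsites (−6…−1, +1…+3; cleavage between −1 and +1), register weights as
  affinity products, glycosyl-enzyme intermediates, deterministic (ODE) and
  exact stochastic (Gillespie) engines, with presets contrasting the GH57
  acceptor-side binding mode with a +2-hindered GH77-like mode.
* **Synthetic data** — seeded generators for docked poses, reference
  ligands, Michaelis–Menten datasets and growth curves with ground truth,
  so every stage is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for the usual figures,
and pipe-friendly pipeline stages (`run_analyze_poses()`,
`run_fit_kinetics()`, `run_simulate()`, `run_gen_fixtures()`) with a thin
CLI wrapper in `inst/cli/gt-pipeline.R`.

## Worked example

```r
library(gtkit)

# a toy acarbose-like reference spanning subsites -1..+3, plus docked poses
ref   <- gen_reference_ligand(n_moieties = 4, spacing = 4, seed = 1)
poses <- gen_poses(ref, n_poses = 3, displacement_along_axis = c(0, -2, -6),
                   jitter_sd = 0.2, seed = 1)
pose_metrics(poses, ref)
#> # A tibble: 3 × 7
#>   ligand model score n_heavy_atoms positional_coordinate match_percent subsite
#>   <chr>  <int> <dbl>         <int>                 <dbl>         <dbl> <chr>
#> 1 ligand     1 -10              20                  4.04           100 +2
#> 2 ligand     2  -9.9            20                  2.02            30 +1
#> 3 ligand     3  -9.8            20                 -2.04            15 -1
```

The undisplaced pose matches the reference perfectly (100%) and sits at the
reference's own centroid coordinate (+4 Å, midway between the +1 and +2
centroids at +2 and +6 Å); the poses displaced by −2 and −6 Å land on the
calibrated +1 and −1 subsite centroids and are assigned accordingly, their
match percentage collapsing as they leave the reference's footprint.

```r
# acceptor kinetics at the 0.32-10 mM design, 0.097 mg/ml enzyme, 76,002 Da
d <- gen_mm_dataset(km = 0.86, kcat = 2635)
fit_lineweaver_burk(d, enzyme_concentration = 0.097, enzyme_molar_mass = 76002)
#> Lineweaver-Burk fit: KM = 0.86 mM, Vmax = 3363 (n = 6, R^2 = 1.0000)
#>   kcat = 2635 min^-1, kcat/KM = 3063.95 min^-1 mM^-1

transglycosylation_factor(27.4, 1.5)$factor   # activity with / without acceptor
#> [1] 18.26667

g <- gen_growth_curve(k = 0.493, sample_times = seq(1, 8, 1))
fit_growth_rate(g)
#> Specific growth rate k = 0.493 h^-1 (window 1-8 h, n = 8, R^2 = 1.0000)
```

The double-reciprocal fit recovers the generating Michaelis constant
(0.86 mM) and turnover number (2,635 min⁻¹) exactly on noiseless data, and
the efficiency kcat/KM ≈ 3,064 min⁻¹ mM⁻¹ follows; the transglycosylation
factor 27.4/1.5 rounds to 18.3-fold.

```r
# disproportionation of 10 mM maltopentaose, GH57 acceptor-side preset
sim <- simulate_disproportionation(c(G5 = 10), subsite_profile("GH57_PSGT"),
                                   duration = 2)
head(product_profile(sim, at_time = 2), 5)
#> # A tibble: 5 × 3
#>   species amount fraction
#>   <chr>    <dbl>    <dbl>
#> 1 G4      1.16     0.353
#> 2 G6      1.07     0.326
#> 3 G3      0.457    0.139
#> 4 G7      0.408    0.124
#> 5 G8      0.0925   0.0282
```

After two minutes the released G4/G3 and their paired transfer products
G6/G7 dominate while free glucose and maltose stay near zero — the GH57
signature. Swapping in `subsite_profile("GH77_contrast")` (steric hindrance
at +2) makes glucose the dominant early product instead.

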