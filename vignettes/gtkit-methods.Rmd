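---
title: "Methods: pose geometry, acceptor kinetics and the subsite simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose geometry, acceptor kinetics and the subsite simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtkit)
```

gtkit analyses the catalytic behaviour of GH57-family
4-α-glucanotransferases (4-α-GTases, EC 2.4.1.25). These enzymes cleave an
α-1,4 bond of a maltooligosaccharide donor, hold the donor-side fragment as
a covalent glycosyl-enzyme intermediate, and resolve it either onto a sugar
acceptor (transglycosylation/disproportionation) or onto water (hydrolysis).
The package implements three quantitative layers around this chemistry:
geometry of docked acceptor poses relative to a reference inhibitor,
steady-state acceptor kinetics and growth rates, and a mechanistic
subsite-binding simulator. Every input can be synthesised with known ground
truth, so the whole pipeline is testable without downloads.

## Docking-pose geometry

The active-site groove is modelled as a one-dimensional axis through the
bound inhibitor (acarbose in the real system). `build_binding_axis()` takes
the unit vector between the two axis anchor atoms (C4A → C1 by convention)
and places the coordinate origin at the orthogonal projection of the origin
anchor (N4A, the atom linking the −1 and +1 moieties) onto that line.

Two per-pose scores follow:

* **Positional coordinate** (`positional_coordinate()`): the signed
  projection of the pose's heavy-atom centroid onto the axis, in Å.
  Negative values lie toward the donor subsites, positive toward the
  acceptor subsites. The quantity is linear — translating a pose by *t*
  along the axis shifts it by exactly *t* — and invariant under any rigid
  motion applied jointly to pose and reference; both properties are tested.
* **Greedy sub-ångström match** (`greedy_match_percent()`): all pose ×
  reference heavy-atom distances are computed; the globally shortest
  remaining pair is accepted as a match when its distance is strictly below
  1 Å, both atoms are removed, and the loop repeats. The loop stops as soon
  as the shortest remaining distance reaches the threshold, because no
  later pair can be shorter — identical output to exhausting all pose
  atoms, fewer steps. The percentage denominator is the pose's heavy-atom
  count. Equal distances are broken lexicographically on (pose index,
  reference index), which makes results independent of atom input order;
  the whole procedure is checked against an independent brute-force replay
  of the sorted-pair removal rule, and its match count is verified never to
  exceed the optimal bipartite matching under the same cap. Note the
  procedure is coordinate-greedy, not topology-aware: it is not a
  symmetry-corrected RMSD and can under-match relative to the optimum.

`calibrate_subsites()` turns the reference's moiety annotation into a map
from subsite to axis coordinate (the moiety centroid's projection), and
requires the map to be monotone increasing in the order …, −2, −1, +1, +2,
… — a non-monotone result almost always means the axis anchors were swapped
and is rejected. `assign_subsite()` maps a pose coordinate to the nearest
calibrated centroid, with a 2 Å default cutoff before reporting
"unassigned" and donor-side preference on exact ties; the study system has
well-separated centroids (≈ 4 Å spacing), so the tie rule is a formality.

Contact distances (`min_residue_ligand_distance()`) are minimum heavy-atom
distances from a residue's side chain to the ligand, CA being used (and
flagged) for glycine. Side-chain-only is a choice: the aromatic stacking
interactions of interest (Y181, F185, W219 in the study system) are
side-chain contacts. Reported values are not validated against the study's
printed distances, whose exact atom-pair convention is unstated.

Alanine-mutant structures (`make_alanine_mutant()`) delete the target
residue's side chain beyond CB, keeping N, CA, C, O, CB and OXT; glycine is
rejected. `emit_docking_config()` writes the grid-box convention used for
the docking runs: a 30 Å cube centred on the origin anchor atom, with
exhaustiveness 100 and 20 modes by default.

## Acceptor kinetics, transglycosylation factors, growth rates

Initial velocities v([S]) at acceptor concentrations 0.32–10 mM are fitted
by the **Lineweaver–Burk** double-reciprocal regression (ordinary least
squares of 1/v on 1/[S]; intercept = 1/Vmax, slope = KM/Vmax), because that
is the reported method of the study being reproduced; `fit_michaelis_menten()`
provides the statistically preferable direct nonlinear fit as a
cross-check. On noiseless Michaelis–Menten data the reciprocal transform is
exact, so recovery is exact for any ≥ 3-point design; under multiplicative
noise the double-reciprocal fit over-weights low-velocity points — a known
bias, which is why the direct fit exists.

Turnover numbers need the molar enzyme concentration:
kcat = Vmax / E with E (µM) = 10⁶ × (mg/ml) / (Da). The study system's
values, 0.097 mg/ml and 76,002 Da, give E = 1.276 µM; they are arguments,
not constants, and the velocity unit (µM·min⁻¹) must be supplied by the
user's calibration — the assay's mapping from amylose degradation to molar
product is not derivable from an absorbance trace alone. For the iodine
assay, `absorbance_to_specific_activity()` converts ΔA₆₆₀ through an
explicit calibration slope (µg amylose per absorbance unit, a required
input) into mg amylose·min⁻¹·mg enzyme⁻¹; negative ΔA₆₆₀ is clipped to zero
and flagged. The transglycosylation factor is the ratio of activity with
acceptor to activity without, with first-order SD propagation.

Specific growth rates are the slope of ln(density) on time inside the
exponential window. When no window is given, the package selects the
longest contiguous window of ≥ 4 points with log-linear R² ≥ 0.99 (ties to
the earlier window), with one amendment: windows that are flat in log space
(lag or stationary plateaus) never qualify as "exponential", because a flat
segment is fitted exactly by a zero-slope line and would otherwise win as
the longest window with k = 0. A completely flat curve still returns k = 0.
The rule is a reproducible stand-in for the judgement call "exponential
portion"; it can retain one boundary point on either side of the true
exponential phase, so automatic-window estimates are approximate while
explicit-window fits on exact exponentials are exact.

## The subsite-binding simulator

The binding site is modelled as nine subsites, −6…−1 (donor side) and
+1…+3 (acceptor side), with the scissile bond between −1 and +1. A
`subsite_profile()` holds one nonnegative affinity per subsite and three
rate constants:

| parameter | units | GH57 preset | meaning |
|---|---|---|---|
| affinities −6…−2 | – | 0.3 | permissive donor subsites |
| affinity −1 | – | 1 | must be occupied for cleavage |
| affinities +1,+2,+3 | – | 3 | strong acceptor subsites |
| `cleavage_rate` | min⁻¹·(weight·mM)⁻¹ | 0.003 | catalysis per bound register |
| `transfer_rate` | min⁻¹·mM⁻¹ | 1 | intermediate → glucan acceptor |
| `hydrolysis_rate` | min⁻¹ | 0.05 | intermediate → water |

No numerical affinities exist in the source study — only orderings (KM
glucose > maltose > maltotriose; no +2 hindrance in GH57; little free
glucose or maltose early). The preset encodes those orderings once; all
simulator claims are therefore ordering-based, never value-based. The
`GH77_contrast` preset inverts the family contrast: affinity 0 at +2
(steric hindrance) and a strong donor side, which forces productive
placements of maltopentaose to put a single glucose on +1, so glucose
dominates the early products — the observed family difference.

`enumerate_registers()` lists contiguous placements of a chain on the
array, non-reducing end toward the donor side; a pNP label occupies the
slot distal of the reducing-end glucose. Placements fully inside the array
are always enumerated; placements overhanging +3 (at most one unit by
default — the acceptor-side extent beyond +3 is attested only once in the
source system) are enumerated only when productive, and donor-side overhang
only when the chain exceeds the array. Overhanging units contribute neutral
weight 1, a register's weight being the product of its occupied-subsite
affinities. A placement is productive when glucose units occupy both −1 and
+1.

The reaction network is mass action. Cleavage flux of species S through
productive register r is `cleavage_rate · [S] · w(r)` — binding
equilibration is assumed fast relative to catalysis, so registers are
populated in proportion to their weights and enzyme saturation is not
modelled. Cleavage releases the acceptor-side fragment (with the pNP label
when present) and creates an enzyme-held donor fragment, which is resolved
at `transfer_rate · w⁺(A) · [A]` onto acceptor A (product length = donor +
acceptor, keeping A's label; w⁺ is the +1…+3 affinity product covered by
A) or at `hydrolysis_rate` onto water, whose activity is folded into the
constant. Every reaction conserves glucose units and pNP groups exactly —
with one bookkeeping exception: tracked lengths are capped (20 glucose
units, 12 for pNP species by default) and transfer products beyond the cap
are truncated into the cap bin, leaking the excess units; a warning is
emitted whenever the leak exceeds 10⁻⁹ of the total. At the study's
initial-reaction scale (10 mM maltopentaose, 2 min) the leak through the
default caps is ~2×10⁻¹¹ of total units; runs designed to probe
conservation itself should raise the caps so truncation cannot bind.

Two engines share the network. The deterministic engine integrates the
ODEs with `deSolve::lsoda` at rtol 10⁻¹⁰ / atol 10⁻¹², which holds the
conservation drift below 10⁻⁹ over the scales above. The stochastic engine
is an exact Gillespie direct-method simulation on molecule counts, seeded
and reproducible, with bilinear propensities scaled by `omega` (molecules
per mM) so that a run started from `omega ×` the deterministic
concentrations estimates the same trajectories; at ≥ 10⁵ molecules the two
agree within Poisson error (tested at 3 standard errors).

One structural consequence worth stating: disproportionation is symmetric.
Each maltotetraose released from maltopentaose is paired with a transfer
product (2 G5 → G4 + G6), so G6 necessarily tracks G4 early on; the
qualitative signature of the GH57 preset is that G4 and G3 rank far above
G2 and G1, not that products longer than the substrate are absent.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its arguments including the seed.

* `gen_reference_ligand()` builds an acarbose-like ligand of equally spaced
  moieties along +x with anchors arranged so the axis and origin are known
  in closed form (moiety *i* sits at `spacing·(i−1) − spacing/2`); it gives
  exact expectations for the calibration and projection code but has no
  sugar chemistry, rings, or realistic bond geometry.
* `gen_poses()` emulates a docking run's output shape (20 modes by default)
  as rigid translations along the axis ± uniform random rotation ± isotropic
  Gaussian jitter, with the generating displacement kept as ground truth and
  placeholder scores. Real docking poses have correlated, internally
  flexible deviations and physically meaningful energies; passing tests
  here validate the geometry pipeline, not any docking engine.
* `gen_mm_dataset()` draws v([S]) from the Michaelis–Menten curve at the
  0.32–10 mM design with multiplicative Gaussian noise (CV-parameterised —
  appropriate for a positive-valued assay); real iodine-assay errors are
  not exactly multiplicative-normal.
* `gen_growth_curve()` is lag → exponential → hard cap with multiplicative
  noise; real cultures decelerate smoothly into stationary phase.

## Problem sizes and numerical choices

The shipped tests run at desk scale: ~1,000 random point sets (5–40 atoms)
for the greedy-match oracle equivalence, 200 noise replicates for the
kinetics recovery study, simulations of 2 minutes from 10 mM substrate, and
a stochastic run of 10⁵ molecules — sizes chosen so the full suite
completes in well under a minute per file while every property is exercised
far from its trivial regime. Ties in the greedy matcher, the subsite
assigner (donor side wins) and the growth-window search (earlier window
wins) are all deterministic, so repeated runs are bitwise identical;
stochastic trajectories are reproducible from their seed.

## Limitations

* Pose analysis is purely geometric: no scoring-function evaluation, no
  symmetry-corrected RMSD, no re-docking.
* The kinetics module carries velocity units symbolically; absolute kcat
  values are only as good as the supplied enzyme concentration, molar mass
  and velocity calibration.
* The simulator has no cyclisation or α-1,6 branching chemistry, no
  temperature dependence, and no enzyme saturation; affinities are
  qualitative encodings, so only orderings — not absolute product
  percentages — are meaningful outputs.
* The automatic growth window is a heuristic; report the window it chose
  (`glance()` does) alongside k.
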