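---
title: "Analysing hyperthermal ion tracks in water: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing hyperthermal ion tracks in water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiolyze)
```

## The physical setting

A carbon ion with a kinetic energy between roughly 175 eV and 2.8 keV
crossing liquid water sits in the adiabatic (nuclear stopping) regime:
it is too slow to ionise water, so all of its energy goes into nuclear
motion — translation, rotation, vibration, and, when enough energy lands
in one molecule, dissociation. The dominant products are hyperthermal H
atoms and OH groups, with isolated O atoms from complete dissociation of
a single molecule. These fragments carry most of the transferred energy
(the binding costs, about 5.0 eV for the first hydrogen and a further
4.4 eV for the second, are a 5–10% correction at most) and act as
secondary projectiles.

`radiolyze` implements the post-processing that turns such trajectories
into quantitative observables:

* **trajectory IO** — a fixed extended-XYZ dialect with per-frame box,
  time, projectile index and optional velocity and electron-population
  columns, plus CSV manifests grouping files into ensembles;
* **kinematics** — unit conversions ($\tfrac12 m v^2$ with speeds in
  Bohr/fs, energies in eV), cumulative energy-loss profiles versus
  projectile position, and the final kinetic energy with an explicit
  `stopped` / `exited` / `indeterminate` trichotomy;
* **species census** — minimum-image neighbour search under the cutoff
  convention (1.2 Å for all pairs, 0.8 Å for H–H), coordination numbers
  $Z_X(Y)$, and the taxonomy that maps them to species (water, hydroxyl,
  hydronium, peroxide oxygen, isolated H and O, H₂, bridging H);
* **event analysis** — segmentation of loss profiles into discrete
  collision events with elastic (restored) excursions separated from net
  inelastic transfers, census-based channel assignment, and trajectory
  classification;
* **charge states** — labels for fragments from summed per-atom electron
  populations (neutral ≥ 0.9 e, cation-like ≤ 0.4 e on a hydrogen);
* **ensemble statistics** — averaged species curves, final-energy
  histograms, nuclear stopping power, and fragment production spacings;
* **synthetic tracks** — an event-kinematic generator that emits
  trajectories with this statistical structure plus exact ground-truth
  event logs, so that every analysis stage is testable end to end.

## The synthetic generator: what it emulates and what it does not

The generator is deliberately *event-kinematic*, not force-based. The
analysis consumes only positions, velocities, energies and populations,
so a faithful force field is unnecessary; what must be right is the
statistical structure of the data. A track is built as follows:

1. A slab of rigid water molecules (default 128 in a cubic box of side
   15.736 Å, doubled along x to make vacuum; ~0.98 g/cm³) is placed by
   random sequential addition with hard contact limits (O–O > 2.5 Å,
   intermolecular O–H > 1.4 Å, H–H > 1.0 Å). These limits keep the bond
   graph of the random slab identical to that of an ideal one under the
   census cutoffs.
2. The projectile enters along x. Dissociative encounter positions are
   drawn with exponential gaps; each encounter is a single dissociation
   (transfer uniform in 25–50 eV) or a complete one (100–150 eV) per the
   channel mix. Transfers are capped at the remaining kinetic energy; a
   capped transfer below the binding cost dissociates nothing and simply
   dumps the residue. A transient elastic excursion (about 15–30 eV,
   fully restored within 0.2 fs) is painted around each event so that
   peak/restoration logic in the detector is exercised.
3. Between encounters a continuous loss rate drains the projectile —
   the model of vibrational/rotational excitation along the path.
4. Fragments take the transfer minus binding as kinetic energy, split in
   inverse proportion to their masses by default (hyperthermal H, slower
   heavy fragments). H fragments fly straight an order of magnitude
   farther than O/OH fragments, which scatter and stop within ~3 Å —
   the mean-free-path asymmetry the analysis should detect.
5. Electron populations are *painted*, not computed: 0.7 e per bound H
   (6.6 e on a bound O, i.e. valence counting), 0.95 e on fast free
   hydrogens, 0.3 e on slow ones. This exercises the charge-state module
   against known truth.
6. The event log records every transfer; the ledger
   $E_0 = E_\text{final} + \sum \text{transfers} + \text{continuous}$
   closes to better than $10^{-6}$ eV on every track by construction,
   and the test suite asserts it.

Features of real first-principles data the generator does **not**
emulate: thermal motion of the bath (water is static between events),
hydrogen-bond network structure, recombination chemistry (peroxide
formation, H₃O⁺/H₃O₂⁻ pairs, C–H abstraction), backscattering, and
electronic effects of any kind. Passing tests therefore demonstrate that
the *analysis* is correct and internally consistent on data with the
right statistics — not that the generator predicts new chemistry.

## Calibration of the per-speed defaults

The printed production rates at the two extreme speeds pin down the
encounter statistics. Every single dissociation produces one H and one
OH; every double produces two H and no OH. If encounters occur every
$d$ Å with double fraction $q$,

$$ \frac{1}{d_\mathrm{H}} = \frac{1 + q}{d}, \qquad
   \frac{1}{d_\mathrm{OH}} = \frac{1 - q}{d}. $$

One H per 5 Å and one OH per 7 Å at the lowest speed give
$d = 5.83$ Å and a 5/6 : 1/6 mix; one H per 20 Å and one OH per 30 Å at
the highest give $d = 24$ Å and 4/5 : 1/5. Intermediate speeds are
linearly interpolated (`speed_defaults()`). This is calibration to the
reported rates, not prediction.

The continuous loss rate is set to $0.0026\,E_0$ eV/Å — about 4% of the
projectile energy shed over the slab, consistent with "a small fraction"
lost in non-dissociative transits, and with the kinematic expectation
that quasi-elastic energy transfer per unit path grows roughly linearly
with projectile energy. With these defaults the four-speed stopping
curve peaks at the keV end (where the large continuous term dominates)
while the 175 eV ensemble deposits a larger *fraction* of its energy and
is the only one with fully stopped projectiles — the qualitative
behaviour the ensemble statistics are meant to surface.

## Numerical and design choices

* **Cutoff presets.** The census convention (1.2 Å everywhere, 0.8 Å
  H–H) cannot register a peroxide O–O bond (~1.47 Å), yet peroxide
  oxygen is part of the taxonomy. Two presets resolve this: `standard`
  for coordination censuses, and `peroxide` (O–O 1.7 Å) as the default
  for molecular formula labelling. A hydrogen within the cutoff of two
  oxygens is *not* tie-broken; $Z_H(O) = 2$ is a legitimate bridging
  label.
* **Minimum image and unwrapped coordinates.** Positions are stored
  unwrapped; every distance goes through the minimum-image convention on
  the orthorhombic box (the vacuum-extended box is just a larger edge).
  The neighbour kernel is a C++ cell list, checked in the test suite
  against a brute-force enumeration of all 27 periodic images.
* **Event detection thresholds** (`event_params()`) are invented, since
  the original analysis reads events off plots: a discrete step must
  rise at more than 25 eV/Å locally and net at least 10 eV, so the
  smallest dissociative transfer (25 eV) always registers while
  sub-10 eV ripple never does. Transfers are measured as plateau
  differences, so restored excursions contribute `peak`, not `transfer`;
  all inter-event drift is emitted as continuous segments, making the
  sum of all rows telescope exactly to the terminal loss.
* **Channel assignment** trusts the census over the profile: a discrete
  event is a single (double) dissociation when its creation window shows
  one H and one OH (two H and one isolated O). Isolated-H and isolated-O
  cumulative counts are the reliable counters; OH production counts only
  persistent arrivals at hydroxyl coordination from a bound state, which
  excludes two single-frame artefacts (the transient OH moment of an
  asynchronously resolving double dissociation, and an O radical
  drifting past a hydrogen).
* **Stopping definition.** `stopped` means kinetic energy below 1 eV
  sustained for at least 50 fs inside the slab; the exit buffer is 2 Å
  beyond the downstream face. Directed motion ends where the energy
  falls to the stop threshold. Truncated runs are flagged
  `indeterminate` and excluded from histograms with a count.
* **Stopping power** is the ensemble mean of deposited energy over slab
  width, with stopped trajectories contributing their full initial
  energy; the slab width is the water region only, not the vacuum.
* **Spacings** pool trajectories: total in-slab track length divided by
  total cumulative creations, with a bootstrap over trajectories for the
  confidence interval. Pooling matters — per-track ratios are biased for
  short stopped tracks, while the pooled ratio is consistent.
* **Seeds.** All generation is reproducible from integer seeds. Derived
  per-track seeds are drawn through `sample.int()` from the base-seeded
  generator rather than by seed arithmetic: structured seed sequences
  (e.g. `base + 7919 k` for small `k`) were observed to give collectively
  correlated Mersenne–Twister streams.
* **x-axis convention.** Profiles use the projectile x displacement, not
  path length; for the forward-peaked tracks generated here the two are
  identical, and for real data the difference is small.

## Problem sizes

The test suite and the acceptance script use ensembles of 200 tracks for
spacing estimates (the low-speed slab at its natural 15.736 Å, the
high-speed one elongated to 150 Å so each track hosts several
encounters), 72-track ensembles per speed for the stopping curve —
mirroring the 6 × 6 entry grid × 2 snapshot protocol — and 150-track
pairs for the width comparison of final-energy histograms. Module tests
run on 20-molecule slabs. These sizes put the statistical checks at 2–4
bootstrap standard errors of resolution and complete on a desktop in a
few minutes.

## Known limitations

Charge labels for oxygen fragments are reported as raw populations only
(no threshold table exists for O). The census counts species over the
whole box, which matches ensemble-averaged curves but would differ from
a near-track count in a large box. Backscattered projectiles are handled
by the analysis (profiles keep time order) but never produced by the
generator. The `h_mobility_factor` asymmetry is qualitative; no claim is
made about absolute secondary ranges. Event detection assumes low-noise
profiles; for noisy input the jump-slope threshold would need raising,
at the cost of missing small transfers.
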