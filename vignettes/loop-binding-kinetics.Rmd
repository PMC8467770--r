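---
title: "Quantifying two-site loop binding kinetics from MD trajectories"
author: "loopkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-site loop binding kinetics from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopkin)
```

## The problem

Several single-pass membrane receptors — EpCAM is the motivating example —
carry a short, intrinsically flexible loop (the thyroglobulin or "TY"
loop, ~21–26 residues) that detaches from the protein body and rebinds
reversibly at more than one intramolecular site. On the microsecond
timescales accessible to all-atom molecular dynamics, these binding and
unbinding events occur many times, so the trajectories themselves contain
enough events to estimate rate constants by *direct counting*: simply
measure how long the loop stays bound and how long it waits between
binding events. `loopkin` implements that analysis end to end for the
two-competing-site case, and — because rate estimates from finite,
discretely sampled trajectories are easy to get subtly wrong — ships a
ground-truth simulator so every stage can be validated against known
kinetics.

## The model

### Contact statistics

Two complementary contact definitions are used.

* **Loop-center contact ratio** (per residue): in each frame, compute the
  geometric center of all heavy atoms of the loop; residue $i$ is "in
  contact" when the distance from that center to residue $i$ is at most a
  cutoff $d_c$. The contact ratio $r_i$ is the fraction of frames with the
  contact present, reported at $d_c \in \{6.5, 8.0, 12.0\}$ Å. This is a
  coarse, whole-loop localisation statistic: binding sites show up as
  local maxima of $r_i$ along the sequence.
* **Residue–residue contact ratio** (per pair): loop residue $i$ and
  target residue $j$ are in contact in a frame when *any* two of their
  heavy atoms are within 4.5 Å. Averaged over frames this gives the
  contact map; restricted to the frames of one bound state it gives
  state-conditioned maps (e.g. which site residues the loop actually
  grips while bound).

Two conventions the package fixes explicitly, since either choice is
defensible: a frame counts as a contact when the distance is $\le$ the
cutoff (not $<$; ties at the boundary are contacts), and all distance
criteria use heavy atoms only, with an `include_hydrogens` switch for the
4.5 Å pair criterion. The residue endpoint of the center-based definition
is the residue's heavy-atom geometric center, symmetric with the loop
center; a nearest-heavy-atom endpoint is available
(`endpoint = "nearest"`). Residues of the loop itself (optionally plus
`k` sequence neighbours) are excluded from profiles, where contacts are
trivially persistent.

### Three states and dwell times

Each frame is classified into one of three states: **OPEN**, **SITE_A**
(bound at the first site) or **SITE_B** (bound at the second). A frame is
bound at a site when at least 3 loop residues are each in 4.5 Å
residue–residue contact with the site (`min_contact_residues`,
configurable). The classification reuses the 4.5 Å pair criterion rather
than the center-based cutoff: the residue-count rule is itself phrased in
terms of residue contacts, and the pair criterion is the sharper of the
two definitions.

Frames qualifying for both sites at once are resolved deterministically:
the site with more contacting loop residues wins; an exact tie keeps the
previous frame's bound label (hysteresis, preserving continuity of an
ongoing event), or OPEN at the start of a replica. Such frames are
vanishingly rare when the sites are well separated, but the rule must be
total for the state sequence to be a pure function of the input.

Dwells are maximal constant-label runs *within one replica*: independent
trajectories are hard boundaries and no run may span them. Runs touching
a replica's first or last frame are flagged **censored** — their true
duration is only bounded below. No smoothing is applied and single-frame
events are kept (`--min-event-frames` exists but defaults to 1): the
plain direct-counting estimator uses the runs as observed.

### Rate constants by direct counting

$$k_\mathrm{off} = \frac{1}{\text{mean survival time}}, \qquad
  k_\mathrm{on} = \frac{N_\mathrm{Av}\, v_\mathrm{eff}}{t_\mathrm{on}}$$

where the mean survival time averages the bound dwell durations of a
site, $t_\mathrm{on}$ is the mean unbound waiting time behind that
site's association events, and $v_\mathrm{eff}$ is the *effective
volume* — simulation box volume minus protein volume — explored by the
single tethered partner. The $k_\mathrm{on}$ arrangement is the unique
one with units $\mathrm{M^{-1}s^{-1}}$; equivalently
$k_\mathrm{on} = 1/(t_\mathrm{on} C_\mathrm{eff})$ with the effective
concentration $C_\mathrm{eff} = 1/(N_\mathrm{Av} v_\mathrm{eff})$, so
that $k_\mathrm{on} C_\mathrm{eff}$ is the observed pseudo-first-order
association rate $1/t_\mathrm{on}$.

Three estimator conventions are deliberate choices, each switchable:

* **Censored dwells are included** in the mean survival time by default.
  The plain direct-counting estimator pools every observed run; excluding
  boundary-truncated runs (`include_censored = FALSE`) removes events
  that are on average *longer* than typical and is only preferable when
  dwells approach the replica length.
* **Waiting-time scope**: the waiting time behind an association event at
  site X is the full maximal non-X interval that terminates in an X
  entry — time bound at the *other* site counts as waiting, because each
  association event needs exactly one waiting time and the loop cannot
  bind X while bound elsewhere. `scope = "open_only"` restricts to the
  OPEN portion instead. Trailing intervals that never terminate in an
  event are right-censored and excluded.
* **Pooling**: events are pooled across replicas for point estimates, and
  the bootstrap resamples *events*, not replicas — this matches the
  event-level estimator; with only ~5 replicas a replica-level bootstrap
  would be far too coarse.

Confidence intervals are percentile bootstrap over events (default
10,000 resamples, seeded). The bootstrap is applied to the mean dwell
(or waiting) time and mapped through the monotone transform to the rate
scale, which is equivalent to bootstrapping the rate directly.

### Effective volume

$v_\mathrm{eff}$ is the box volume minus the protein volume, the latter
estimated by van-der-Waals-sphere voxelisation: a cubic grid (0.5 Å
default spacing) spans the molecule and each voxel whose center falls
inside any atom's vdW sphere (H 1.20, C 1.70, N 1.55, O 1.52, S/P 1.80 Å;
unknown elements fall back to carbon) contributes its volume, averaged
over at most 100 evenly spaced frames. On the toy scaffold, halving the
grid to 0.25 Å moves the estimate by well under 2%; for a single atom
the voxelised volume matches $\tfrac43\pi r^3$ to ~1% at 0.25 Å spacing.
A `veff_liters` override bypasses estimation entirely (useful when the
solvent box is known but not stored in the trajectory).

## The synthetic ground truth

Validation needs data with *known* kinetics. The generator works at two
levels.

**Discrete level** — a three-state continuous-time Markov chain with OPEN
as the hub: exponential waiting times drawn by inverse-CDF on a seeded
generator, exact jump simulation, then subsampling at the frame interval
(frame $i$ records the state at time $i\,\Delta t$, emulating snapshot
sampling). Direct site-to-site jumps are forbidden by default, matching
the three-state picture in which the loop must release before rebinding;
a `k_exchange` flag enables them for robustness tests. The continuous
event log is returned alongside the discretised labels, so
discretisation bias itself is measurable. For the hub model the
stationary occupancies have the closed form
$\pi \propto (1,\; k_{on,A}/k_{off,A},\; k_{on,B}/k_{off,B})$, which the
test suite checks against long-run occupancies.

**Coordinate level** — a toy system: 40 one-heavy-atom scaffold residues
on a 25 Å ring, two 4-residue pockets on opposite sides (50 Å apart),
and an 8-residue loop chain. When bound, 4 loop residues sit 2.5 Å from
the pocket residues (well inside 4.5 Å); when open, the loop is strung
through the ring center, ≥ 20 Å from both pockets. Isotropic Gaussian
noise (σ = 0.5 Å by default) perturbs every atom in every frame. The
margin arithmetic is what makes the test sharp but fair: with both
endpoints jittered, pair distances fluctuate with sd ≈ 0.7 Å around
2.5 Å, so the 4.5 Å criterion sits almost 3 sd away — label recovery is
≥ 99.9% at σ = 0.5 and exact at σ = 0. The generator refuses σ ≥ 1.5 Å
(a third of the cutoff) or pockets closer than 15 Å, where states would
no longer be separable. What the toy system deliberately does *not*
emulate: realistic loop conformational sampling, intermediate/partial
binding poses, force-field energetics, solvent. Passing the recovery
tests therefore demonstrates that the *measurement* pipeline is unbiased
on well-separated states — not that state definitions are unambiguous on
real proteins, where the choice of cutoff and threshold genuinely
matters.

### The study-scale preset

`paper_scale_preset()` mirrors the reference sampling design — 5
replicas × 2500 frames at 200 ps (500 ns each, 12,500 frames per
system) — with rates chosen once as the validation operating point:
$k_{on} = 2.5\times10^8\,\mathrm{s^{-1}}$ per site (2 ns mean open
time), $k_{off,A} = 1.6\times10^8\,\mathrm{s^{-1}}$ (6.25 ns dwell,
~31 frames) and $k_{off,B} = 2.5\times10^8\,\mathrm{s^{-1}}$ (4 ns
dwell, 20 frames). The logic: every dwell mean stays at or above 20
frames, the regime where discretisation bias of direct counting remains
small (events shorter than a frame are missed, and sub-frame open
intervals merge adjacent dwells), while each system still produces
~170 events per site — enough for direct counting to resolve rates to
well under 15%. Site B unbinds faster than site A, mirroring the typical
weaker second site.

## Problem sizes in the validation suite

Test and validation workloads are sized for a laptop-class single core:
the parameter-recovery study runs 20 study-scale systems (12,500 frames
each) through the full coordinate-level pipeline with 1000-replicate
bootstrap CIs; bootstrap coverage calibration uses 500 outer replicates
of 200 exponential events with 1000 resamples each; oracle-equivalence
fixtures are 50 residues × 200 frames, where the naive $O(N^2)$ recount
is still exact and fast. The package default of 10,000 bootstrap
replicates applies to interactive analyses; the validation suite's 1000
is ample for 95% intervals of a mean.

## Numerical and degenerate-input conventions

* Zero events for a site is an explicit error ("no events"), never
  $k_\mathrm{off} = 0$; a single event yields a point estimate with an
  undefined, flagged CI.
* Identical resampled durations give a zero-width CI (degenerate but
  correct percentile bootstrap).
* All randomness (CTMC jumps, coordinate noise, bootstrap) flows from
  one master seed; replica $r$ uses `seed + r`, coordinate noise
  `seed + 1000 + r`. Reruns are bit-identical.
* Distances are plain Euclidean: the toy systems are non-periodic and
  the analysis assumes whole-molecule (unwrapped) coordinates. Periodic
  minimum-image handling is out of scope and documented as such.
* Frame order is irrelevant to contact ratios (they are frame averages);
  dwell extraction of course depends on order, which is why replica
  boundaries are first-class.

## Known limitations

* Rate constants from direct counting are only as good as the state
  definition; misclassification near the contact threshold biases short
  dwells. The σ-margin analysis above quantifies this for the toy
  system only.
* Discretisation bias: $k_\mathrm{off}$ estimates degrade as the frame
  interval approaches the mean dwell; keep
  $\Delta t \lesssim \bar\tau/20$.
* Censoring treatment is the pragmatic pooled estimator, not a
  likelihood-based survival model; with few, long events a parametric
  exponential fit with censoring (e.g. via `survival`) would be
  preferable.
* XTC trajectories are not read; convert to DCD upstream.
* The effective-volume voxelisation ignores solvent-excluded cavities
  (union of vdW spheres, no probe rolling); for $v_\mathrm{eff}$ this
  distinction is negligible against the box volume.
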