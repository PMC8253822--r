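---
title: "Quantifying sarcomere architecture from traced myofilaments"
author: "sarcopack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcomere architecture from traced myofilaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcopack)
```

## The problem

Cryo-electron tomography of striated muscle yields two complementary kinds
of data about sarcomeres: traced filament centerlines (thin, actin-based
filaments and thick, myosin-based filaments, exported from a segmentation
tool as ordered 3D point lists) and the tomographic density itself.
`sarcopack` implements the quantitative analyses that turn these into
architecture measurements:

* **packing statistics** — for every point along a filament, the closest
  point of every neighboring filament, characterized by its distance $d$
  and the unsigned acute angle $\theta$ between the local tangents, binned
  into a 2D histogram. A peak at small $\theta$ (below 10°) marks
  equidistant, nearly parallel filaments; the interfilament spacing is the
  mean of the distances in bins whose occupancy exceeds two-thirds of the
  peak maximum, contiguous with the first (smallest-distance) local
  maximum. Local reference frames $(e_1, e_2, e_3)$ — $e_2$ the tangent,
  $e_1$ toward the nearest parallel neighbor, $e_3 = e_1 \times e_2$ —
  align all neighbor offsets into a packing heatmap whose symmetry reveals
  the lattice: six-fold for the hexagonal thick-filament lattice, with
  thin filaments at the trigonal positions at $a/\sqrt{3}$ from three
  thick filaments.
* **subtomogram averaging and polarity** — cubic subvolumes extracted
  every half actin rise (1.38 nm) along each thin filament, with zxz Euler
  angles $(\varphi, \theta, \psi)$ initialized from the local tangent so
  the centerline lies along the subvolume z axis and $\varphi$, the
  in-plane angle, randomized on a 30° grid. Constrained alignment
  (masked normalized cross-correlation, axial shifts limited to 1.38 nm)
  and averaging produce a thin-filament map de novo; aligning every
  subvolume against a reference and its 180°-flipped copy and comparing
  the per-filament score samples with an unpaired Student's t-test
  ($\alpha = 0.05$) assigns each filament's polarity or leaves it
  unassigned.
* **sarcomere metrics** — with polarity known, barbed-end-facing gaps
  locate Z-disks, pointed-end encounters locate M-lines, and the maximal
  axial interpenetration of opposite-polarity pointed ends is the
  thin-filament overlap, also expressed as a percentage of the flanking
  sarcomere length. Refined subunit poses give the helical rise (mean
  axial spacing), twist (signed circular mean of consecutive in-plane
  rotation differences) and repeat length; a cylindrical-annulus
  azimuthal profile comparison measures tropomyosin azimuthal shifts
  between averages.

Everything is exercised end-to-end on synthetic geometry and synthetic
density, so no real tomogram is required.

## The synthetic generators and what they emulate

`build_lattice()` places parallel straight filaments along +x on a
hexagonal lattice (constant `spacing_a`, default 45.1 nm, the neonatal
cardiomyocyte thick-filament spacing) with thin filaments at trigonal
sites. Disorder enters as a *rigid* lateral Gaussian offset per filament
(`jitter_sd`), matching the packing analysis's premise of equidistant,
nearly parallel filaments while perturbing the spacings. Extra thin
filaments outside the trigonal positions come in two modes:

* uniform interstitials at `interstitial_density` per unit cell, rejected
  within 10 nm of any filament axis (`min_clearance`; thin/thick filament
  diameters of roughly 8 and 18 nm imply steric exclusion), with a bounded
  retry budget;
* a *calibrated* mode (`pair_fraction`) in which trigonal thin filaments
  receive a companion at a planted distance drawn from
  N(`pair_distance_mean`, `pair_distance_sd`) — default 15.5 ± 1.4 nm, the
  measured nearest-thin spacing in neonatal cardiomyocytes. The distance
  is drawn once and only the azimuth is retried under the steric
  constraints, so rejection cannot bias the planted distribution, and a
  companion must stay `pair_exclusion` (20 nm) away from every thin
  filament other than its anchor so that the planted distance really is
  its nearest-neighbor distance. A small fraction (up to 2%) of anchors in
  overcrowded spots may remain unpaired.

`build_sarcomere()` adds the longitudinal register: sarcomeres of length
1800 nm by default (neonatal sarcomere length 1.8 ± 0.2 µm), a
filament-free Z-disk gap (`z_disk_width`, default 120 nm, within the
observed 100–140 nm), thick filaments spanning the A-band (absent from the
I-band, default width 270 nm within the observed 240–300 nm), and thin
filaments emanating barbed-end-first from both Z-disk faces. Thin lengths
are Gaussian (sd 50 nm, emulating the known length variability within a
sarcomere) truncated at the M-region reach; one filament per
half-sarcomere is pinned to the maximal reach so the planted
`overlap_length` is realised exactly — the generator-level measurement
`planted_overlap()` recovers it identically before any analysis runs.

`render_filament_density()` is the forward model standing in for the
tomogram: soft-sphere (Gaussian) actin subunit densities at helical
positions — rise 2.76 nm, twist −167.0° per subunit, 13 subunits per
35.88 nm repeat — plus two continuous tropomyosin tubes at 3.9 nm radius
following the long-pitch twist, additive Gaussian noise to a requested
SNR, and an optional missing-wedge filter (off by default; the wedge
geometry is not analyzed quantitatively here). One modelling point
deserves emphasis: a single-start helix of featureless spheres with
tropomyosin on the subunit line is exactly mirror-symmetric — a 180°
rotation about a transverse axis equals an in-plane rotation, and polarity
would be undetectable *by construction*. The default tropomyosin azimuth
of 60° places the strands in the groove off the subunit line, which is
also how polarity is read in real data: from the position of the actin
subunits relative to the two tropomyosin strands. What the generator does
not emulate: myosin heads and thick-filament backbone density, CTF and
dose effects, membranes, curvature of filaments at the sarcomere scale,
and Z-disk density. Tests passing on this geometry therefore validate the
estimators' correctness, not their robustness to those real-data effects.

## Numerical choices that matter

* **Spacing estimator.** Bin widths default to 0.5 nm in $d$ and 1° in
  $\theta$. Desk-scale histograms are overdispersed because every filament
  pair contributes a block of nearly identical distances, so peak finding
  runs on a 5-bin moving average, a candidate first-shell peak must
  dominate the smoothed marginal within ±4 nm (`min_shell_separation` —
  distinct shells in these lattices are ≥10 nm apart) and must reach 20%
  of the tallest bin (`min_peak_fraction`, so an isolated close pair in a
  jittered network cannot masquerade as a shell), and the two-thirds
  occupancy window is taken on the smoothed marginal; the mean and sd are
  then computed over the raw distance observations in that window. On a
  jitter-free lattice all mass sits in one bin and the estimates are
  exact.
* **Alignment.** Scores are masked normalized cross-correlation under a
  soft cylindrical mask (default radius 8 nm) about the pose axis.
  Searches are grids: global in-plane $\varphi$ (default 10° steps) or
  local perturbation of all three Euler angles; translations are integer
  voxels, axially limited to 1.38 nm and transversally to a configurable
  voxel bound. Shifts are scored as absolute offsets from the subvolume
  box center and the refined position is center + shift, so repeated
  rounds cannot accumulate drift. The working reference is low-passed to
  2.5 nm between rounds, which suppresses interpolation artifacts feeding
  back into the alignment; the divergence guard errors after three rounds
  of mean-score decrease, with a 0.02 tolerance because scores legitimately
  dip as the reference sharpens. Late local-refinement rounds should
  tighten the shift bounds (per-round overrides in the schedule): a 1.38 nm
  axial shift plus a compensating in-plane rotation maps the helix onto
  its half-rise register and would smear polarity out of the average.
* **Polarity statistics.** The default design scores every subvolume
  against both references (as the alignment literature describes). The
  two score samples then share noise realisations, which makes the
  pooled-variance unpaired t-test *conservative* on polarity-free input —
  the realised false-call rate is far below $\alpha$. With
  `assign_polarity(split = TRUE)` the subvolumes of each filament are
  split into disjoint halves scored against the two references, the
  samples are independent, and the nominal size $\alpha$ is realised
  exactly; this is the configuration under which the type-I property is
  demonstrated. Degenerate cases are guarded: fewer than two subvolumes,
  or identical score samples, yield p = 1 and no call.
* **Helix estimator.** Twist is the signed circular mean of consecutive
  $\Delta\varphi$, wrapped to (−180°, 180°] — robust to noise excursions
  across ±180° where naive unwrapping injects 360° jumps. The subunits
  per repeat is the smallest $n \le 28$ whose closure residual
  $|\mathrm{wrap}(n \cdot \mathrm{twist})|$ is within 15°
  (for −167.0° that is $n = 13$, residual 11°; a pure argmin would prefer
  $n = 28$ with residual 4°, which does not describe the crossover
  repeat), falling back to the argmin when nothing closes.
* **Tropomyosin shift.** The azimuthal profile at the tropomyosin radius
  is sampled with the azimuth unwound along the axis at the long-pitch
  rate $(\mathrm{twist}+180)/\mathrm{rise}$, so each strand contributes at
  a fixed profile angle; the annulus extends outward only, because inner
  radii pick up actin density common to both maps and bias the
  correlation toward zero. The 180° two-strand ambiguity is resolved to
  the smaller absolute shift.
* **Coordinates.** Lengths in nm, angles in degrees; generated networks
  run along +x; subtomogram references put the filament axis along +z.
  Density arrays are indexed `[ix, iy, iz]` with the voxel center at its
  coordinate. Order-relative polarity (+1: pointed end at the last
  centerline point) flips together with point order in
  `unify_directions()`, so the physical pointed-end direction is
  preserved.

## A worked desk-scale example

```{r lattice, eval = FALSE}
net <- build_lattice(lattice_spec(spacing_a = 45.1, jitter_sd = 3.8,
                                  n_a = 14, n_b = 14,
                                  trigonal_occupancy = 0, seed = 1))
h <- near_neighbor_histogram(resample_network(net, 3), "thick", "thick",
                             d_max = 60)
estimate_spacing(h)
#> spacing: 45.08 +/- 2.22 nm (n = 13104, peak at 45.75 nm)
```

```{r sarcomere, eval = FALSE}
net <- build_sarcomere(sarcomere_spec(sarcomere_length = 1650,
                                      overlap_length = 281,
                                      n_sarcomeres = 2, seed = 1),
                       lattice_spec(n_a = 4, n_b = 4, seed = 1))
annotate_sarcomeres(net)
#> sarcomere_annotation: 3 Z-disks, 2 M-lines
#>   sarcomere lengths (nm): 1650, 1650
#>   M-line at 822 nm: overlap 281 nm (17%)
#>   M-line at 2475 nm: overlap 281 nm (17%)
```

The problem sizes used throughout the tests and the acceptance script are
desk-scale by design: ~200–900 filaments for packing statistics, 32³
voxel subvolumes at 0.684 nm/voxel (the binning-2 pixel size of the
source data; 64³/128³ remain available via configuration), tens of
subvolumes per filament for polarity, and 500 filaments × 20 subvolumes
for the type-I simulation.

## Known limitations

* The de novo cylinder-start iteration converges to a helically
  symmetric map at SNR ≥ 1 but, at desk scale (a handful of straight
  filaments), its absolute register and polarity purity are not
  guaranteed — symmetry breaking is noise-seeded, exactly as in the
  full-scale procedure, where vastly more subvolumes make the attractor
  reliable.
* With exact tangents from synthetic straight filaments, local all-Euler
  refinement adds interpolation-noise-driven tilt jitter rather than
  information; it earns its keep on traced centerlines with tracing
  error. The recommended synthetic-data schedule is global-$\varphi$
  rounds, optionally followed by one tight local round.
* The overlap at an M-line is reported as the *maximum* interpenetration
  over bridging opposite-polarity pairs (the per-pair distribution is also
  returned); other reductions (quantiles, means) are trivial to compute
  from it but change the number reported.
* One-sided Z-disks at the ends of a network are corrected by half the
  mean barbed-end gap of the interior disks; with a single Z-disk no
  correction is possible and the position carries a half-gap bias.
* Filament centerlines are inputs; no tracing from density is provided.
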