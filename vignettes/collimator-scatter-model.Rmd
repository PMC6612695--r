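---
title: "Modelling collimator-scattered protons in spot-scanning delivery"
author: "pbscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collimator-scattered protons in spot-scanning delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Low-energy pencil-beam-scanning (PBS) proton fields have wide spots, so
shallow targets are often treated through a nozzle-mounted applicator: a
plastic energy absorber that degrades the beam to short ranges, plus a
patient-specific brass collimator that trims the lateral penumbra.
Analytical dose engines usually assume the brass absorbs every proton it
intercepts.  In reality a population of protons clips the aperture edge,
scatters in the brass, loses energy, and still reaches the patient.
These *collimator-scattered* protons deposit extra physical dose — mostly
near the surface — and, because they are slower, they carry a higher
linear energy transfer (LET), which raises the question of an additional
biological (RBE) penalty.

`pbscatter` is a desk-scale Monte Carlo study of exactly this question.
It plans and transports collimated spot-scanning fields onto rectangular
targets in a water phantom, splits every voxel tally into a scattered (S)
and an unscattered (US) channel, and quantifies the physical
(dose), radiological (dose-averaged LET, \(LET_d\)) and biological (RBE)
impact of the S channel over a systematic sweep of target range, SOBP
width and field size.

## Geometry and conventions

The coordinate frame is right-handed with \(+z\) along the beam and the
origin at the centre of the water surface.  The fixed stations are: a
4-cm absorber plastic slab, a 1-cm air gap, a 2- or 4-cm brass collimator
whose exit face sits 6 cm above the water (9 cm above the isocenter),
and the isocenter at 3 cm depth.  Targets with maximum range \(R \le
10\) cm use the 2-cm collimator (that configuration tops out at a 10-cm
range); deeper targets use the 4-cm one.  All interfaces work in cm;
phantom voxels are half-open boxes \([ih, (i+1)h)\) with zero-based
indexing in the kernel and 1-based indexing in R.

A target is the rectangular box `R<range>_S<sobp>_FS<field>`: distal edge
at depth \(R\), proximal edge at \(R - S\), square field of side
\(FS\) at the isocenter.  The canonical sweep crosses
\(R \in \{5,10,15,20\}\) cm, \(S \in \{5,10\}\) cm and
\(FS \in \{2,4,8,16\}\) cm.  The combination \(R=5,S=10\) is geometrically
impossible (the proximal edge would sit above the surface), so the sweep
has 28 members.

The collimator opening is set per axis by back-projecting the field edge
at the *proximal* target plane through the virtual source (one
scanning-magnet distance upstream of the isocenter, different for x and
y) onto the collimator exit face.  For an unperturbed Gaussian penumbra
the 50%-dose point travels along this geometric edge ray, so the rule
covers the proximal field edge with half the prescribed dose without any
iterative dose calibration; a transported self-check in the test suite
confirms the delivered 50% isodose lands within 1.5 mm of the field
edge.  The walls are straight (parallel to z).

## Single-proton physics

*Stopping power* is the Bethe formula without shell or density
corrections (water I = 75 eV), tabulated on a 400-point logarithmic grid
from 0.1 to 300 MeV with log-log interpolation; CSDA ranges are the
cumulative trapezoid of \(1/S\).  This is accurate to a few percent
against published water tables over the therapeutic range, which is
sufficient because the model is anchored to printed range calibration
points rather than absolute dosimetry.  Brass is Cu70/Zn30 at
8.52 g/cm^3; air is at NTP.

*The absorber* is the one calibrated element.  The nozzle is
characterised by three (beam energy, residual range in water) anchor
points: 74.9 MeV -> 0.5 cm, 142.5 MeV -> 10 cm, 192.4 MeV -> 20 cm.
A single energy-independent water-equivalent thickness (WET) is fitted
to the three anchors by least squares (4.26 cm), and the absorber
plastic density is then set so the physical 4-cm slab reproduces that
WET (1.085 g/cm^3).  The three anchors are reproduced within
+-0.17 cm — the anchors are not exactly consistent with any single WET,
and one honest fitted constant is preferable to per-energy fudges.

*Multiple Coulomb scattering* uses Highland's parameterisation of the
projected angle.  The logarithmic correction term is evaluated on the
full thickness of the material slab being crossed, not on the
condensed-history step, which makes the accumulated angular variance
independent of the step size (a property the test suite checks by
halving all step caps).  *Energy straggling* is Bohr's Gaussian with
sigma proportional to \(\sqrt{\rho\,(Z/A)\,\ell}\).  *Nuclear
interactions* remove fluence: the weight decays with a removal length of
85 g/cm^2 in every material, and removed weight deposits nothing.
Below 1 MeV a proton stops and deposits its remaining energy locally
(sub-millimetre residual range).

Step lengths are the minimum of a per-material cap (5 mm air, 2 mm
absorber, 1 mm brass and water), 5% of the residual range, and the exact
distance to the next boundary, including the four lateral aperture
planes inside the collimator slab — edge-grazing trajectories are the
heart of this problem and may not be blurred by boundary overshoot.
Positions advance along the pre-deflection direction; the deflection is
applied after the advance (small-angle convention).

## Source model and planning

The printed beam data are three in-air 1-sigma spot sizes at the
isocenter: 11.7 mm at 74.9 MeV for both collimator configurations,
6.0 mm at 142.5 MeV (2-cm) and 5.3 mm at 192.4 MeV (4-cm).  Between the
anchors, \(\sigma^2(E)\) is interpolated along the shape of the
absorber-scattering contribution computed by the package's own
deterministic Fermi-Eyges march (\(\sigma^2 = a + c\,M_{iso}(E)\), exact
at both anchors).  This choice is physical — the spot size of a heavily
degraded beam is scattering-dominated and convex in energy — whereas a
linear interpolation overestimates mid-energy spot sizes.

Each spot is sampled as uncorrelated Gaussians in transverse position
and angle around the deterministic spot ray (tilt \(x_{iso}/\)SAD per
axis; SAD 200 cm in x, 240 cm in y), with 0.6% relative energy
dispersion.  The two Gaussian widths per energy are fixed by (i) the
anchor sigma at the isocenter after subtracting the Fermi-Eyges
scattering contribution and (ii) a configured 20% sigma growth between
collimator exit and isocenter.  At the lowest energies the scattering
contribution alone exceeds what the growth split allows; the angular
term is then dropped and the position width is set to match the
isocenter anchor exactly, which takes priority.  A collimator-free
transported verification in the test suite reproduces all three anchors
within 2%.

Energy layers descend from \(R\) to \(R-S\) in 5-mm water-equivalent
steps, refined to 2.5 mm where pristine peaks are narrow (residual
ranges below 6 cm and the first centimetre below the distal edge) —
without the refinement the SOBP ripple exceeds 3%.  Ranges below the
0.5-cm deliverable minimum clip to 0.5 cm.  The spot map is a 5-mm
square grid reaching one spacing beyond the field edge, identical for
all layers, with uniform weights within a layer: the collimator, not
edge-enhanced weighting, shapes the penumbra.

Layer weights come from a nonnegative least-squares fit of per-layer
central-axis depth-dose columns to a flat 2-Gy plateau (fit window 2-3 mm
inside the SOBP edges, and below no shallower than 0.7 cm, which the
minimum range cannot dose).  Each column is measured by a fast
pre-simulation of a single on-axis spot (2000 histories per layer),
scoring laterally integrated dE/dz *within the spot-map window* — an
exact finite-map coverage treatment that is robust to the heavy lateral
tails which defeat Gaussian-moment approximations — times an analytic
aperture-erosion factor: the collimator clips the field at its exit
plane and the clipped edge only migrates toward the axis through the
angular spread and in-water scattering.  Delivered unscattered
target doses land within 2% of the 2-Gy prescription across the sweep,
with SOBP flatness of 0.5-3%.

## Tallies and the two channels

A proton is tagged *collimator-scattered* the first time a transport
step runs through brass, and the tag never clears; protons scattered
only in the absorber are not tagged.  Every in-phantom step deposits
\(\varepsilon\) into the voxels it crosses by exact path-length
splitting (Amanatides-Woo traversal, no midpoint bias), accumulating
per channel and per batch both \(\sum\varepsilon\) and
\(\sum L\,\varepsilon\), where \(L\) is the unrestricted electronic
stopping power of *water* at the mid-step energy — the phantom is water,
matching the convention of scoring LET against the tracking medium.
The dose-averaged LET of a voxel (or any voxel region) is then

\[ LET_d \;=\; \frac{\sum_n \sum_s L_{sn}\,\varepsilon_{sn}}
                   {\sum_n \sum_s \varepsilon_{sn}}, \]

with the merged S+US channel built from the channel sums, so channel
additivity of dose and the LET mixture identity hold to machine
precision on every run; a 100-history run with a full step log is
re-aggregated independently in the tests and must agree voxel by voxel.

Histories are striped over (by default) 4 batches, giving voxel- and
region-level standard errors.  A voxel is *low-statistics* when some
batch never touched it or its batch relative error exceeds 0.35 —
roughly the "at least ten independent contributions" rule — and
voxel-level LET analyses exclude such voxels: at desk-scale statistics a
single stopping history can deposit a hundredth of a gray in one voxel,
which would otherwise masquerade as a high-dose, high-LET point.

## RBE model and evaluation points

RBE uses the LQ-based variable model of McNamara et al. (2015):

\[ RBE = \frac{1}{2D}\Big(\sqrt{(\alpha/\beta)^2
        + 4D(\alpha/\beta)\,RBE_{max} + 4RBE_{min}^2D^2}
        - \alpha/\beta\Big) \]

with \(RBE_{max} = 0.99064 + 0.35605\,LET_d/(\alpha/\beta)\) and
\(RBE_{min} = 1.1012 - 0.0038703\sqrt{\alpha/\beta}\,LET_d\).  The
\(\sqrt{\alpha/\beta}\) form in \(RBE_{min}\) is the model's published
form.  The model is pluggable: swapping the RBE function changes only
the RBE fields of the metrics record.  D is the local per-fraction total
physical dose (S+US).  \(\alpha/\beta\) is 3 Gy at the surface
evaluation point and 10 Gy at the target center.

The evaluation points follow the study convention: \(z_s = 5\) mm as the
representative surface depth, \(z_c = R - S/2\) as the target-center
depth (the SOBP mid-depth; "target center" has no printed formula), and
\(x_s\) the x-position of the maximum scattered dose at \(z_s\) (ties
break toward smaller |x|, then negative x).  Because single-voxel values
are noisy at desk scale, "points" are small symmetry-respecting
regions: the center averages over a box of half-width
\(\min(FS/4, 2)\) cm and +-3 mm in depth; the surface profile is
averaged over a central y strip and x-mirror-symmetrised before the peak
search; LET and RBE at the peak use a +-1-voxel window around the
maximising column.  Peak dose keeps the single (mirrored) column to
preserve its "maximum" semantics.  All scattered-dose metrics are
percentages of the unscattered dose at the target center.

The voxel-cloud analysis (scattered dose vs LET increase) lists every
reliable voxel with \(D^S > 0.01\) Gy; its two-region summary — the
largest LET increase among voxels with \(D^S > 0.08\) Gy, and the
largest \(D^S\) among voxels with an LET increase above 1 keV/um — is
restricted to positions receiving at least 15% of the target-center dose
(0.3 Gy), the same reliability scope applied to all LET statements of
the study.

## The study harness

`run_study()` executes plan, transport, tally and evaluation for every
geometry.  Per-geometry seeds are `base_seed * 1000 + index`, and every
history owns a counter-based random stream keyed by `(seed, history
index)`, so any subset of the sweep reproduces bitwise regardless of
execution order.  The acceptance profile uses 2-mm voxels and
\(2.5\times10^5\) histories for the smallest fields, scaled by
\(\max(1, FS/8)\) — larger fields receive more protons, as the
underlying study did, moderating the growth of per-voxel error with
field size.  The full sweep takes five to fifteen minutes on one core
depending on the host; the "fast" profile (2e5 histories, no single
geometry above a minute) is for interactive work.  The dedicated voxel-level
LET analysis of the reference geometry R15_S5_FS8 runs at \(10^6\)
histories with exact x/y mirror pooling, which halves voxel noise
without touching any expectation.

## What the model does and does not emulate

The transport reproduces the features that drive the question: realistic
range-energy behaviour through the calibrated absorber, energy-dependent
spot sizes, edge-grazing through straight brass walls with exact lateral
boundary crossings, punch-through of the highest energies through the
thinner collimator, and the depth- and field-size structure of the
scattered channel (surface-peaked edge lines; concave field-size
dependence with a central overlap peak for small fields and
growing wall incidence for large ones).

It deliberately omits: secondary protons and heavier products of nuclear
reactions (removed weight simply vanishes), neutron and photon
transport, elastic nuclear large-angle tails beyond Highland's Gaussian,
patient geometries, and any TPS-style double-Gaussian halo.  The
omissions bias the absolute scattered fractions somewhat low for
geometries whose scatter is dominated by rare large-angle events (the
shallow-range, mid-size fields sit near 2.8% where the published floor
is 3%), and leave the small-field central overlap a little high relative
to the published 2.6% ceiling; both sit within ~1 percentage point.
Passing tests therefore demonstrate the mechanism and its scaling, not
sub-percent dosimetric agreement with a general-purpose Monte Carlo.

## Numerical choices worth knowing

* Energy grid 0.1-300 MeV, 400 log points; interpolation error ~0.1%.
* Transport cut 1 MeV; terminal energy deposits locally with the
  water stopping power at the terminal energy as its LET.
* Boundary crossings push 1e-7 cm into the downstream region (half-open
  slabs); the self-consistency of `locate()` with the kernel is tested
  against an independent slab oracle on random points.
* Histories are hard-capped at 1e5 steps (runaway protection).
* The NNLS fit rejects identically zero depth-dose matrices with a
  diagnostic listing the layer ranges; a single-layer plan falls back to
  matching the prescription at the distal reference bin.
* Batch count 4: enough for region-level standard errors; voxel-level
  error estimates are themselves noisy and are used only for
  reliability filtering, never as precise uncertainties.
* Grids serialise to a plain-text header-plus-table format
  (`write_grids()`/`read_grids()`), round-tripping to 1e-7.

## Known limitations

Beyond the physics omissions above: the aperture-erosion factor in
planning treats the collimator clip as acting at the exit plane with
Gaussian migration, which is a few-percent approximation for the
smallest fields; the in-air sigma between anchors follows the package's
own scattering model rather than measured data; and the evaluation-point
regionalisation trades a small systematic smoothing of sharp peaks for
statistical stability — both conventions are fixed, documented here, and
identical for every geometry, so sweep-level comparisons are unaffected.
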