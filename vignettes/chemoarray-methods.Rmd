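---
title: "Modelling p2- and p6-symmetric chemosensory array lattices"
author: "chemoarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling p2- and p6-symmetric chemosensory array lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoarray)
```

## The system and the question

Bacterial chemosensory arrays are extended two-dimensional lattices of
chemoreceptors, the histidine kinase CheA and the coupling protein CheW,
assembled on the inner membrane. The building block is the
core-signalling unit (CSU): two receptor trimers-of-dimers (ToDs)
bridged by one CheA dimer and two "core" CheW monomers. CSUs
interconnect through six-membered baseplate rings about 30 nm beneath
the membrane. Two architectures are possible over the *same* universal
hexagonal receptor arrangement:

* **p6**: CSUs at three orientations (0/120/240 degrees) close
  alternating (A.P5/W)~3~ rings; additional "flanking" CheW monomers on
  the otherwise bare receptors can fill the interstitial (W)~6~ rings.
* **p2**: all CSUs parallel; rings can only be completed by flanking
  CheW, producing two-fold symmetric (A.P5/W/W)~2~ rings, with CheA
  dimers in parallel stripes.

This package builds coarse-grained pseudo-atom models of both
architectures, analyses the baseplate as a docking-site contact graph
(interface classes, ring taxonomy, per-CSU census, receptor-to-kinase
connectivity), classifies rendered or simulated density as p2 or p6 by
rotational self-similarity, and provides the curved-membrane machinery
(sphere fitting, membranogram projection) plus a synthetic tomogram
generator, so every stage is testable without any external data.

## Coarse-grained geometry

The published structural work fixes stoichiometry and connectivity but
not numeric coarse-grained coordinates, so the canonical geometry is
derived entirely from the lattice constant *a* (default 126 Å, the
value that produces an intact baseplate):

* six-membered baseplate rings sit on a hexagonal lattice of spacing
  *a*;
* ToD centres sit on the dual honeycomb vertices; the nearest ToD-ToD
  distance is *a*/√3, and the two ToDs of a CSU are such neighbours;
* each ring member (CheA.P5 or CheW) sits at the midpoint between its
  ring centre and the ToD whose receptor dimer binds it, i.e. on a
  circle of radius *a*/(2√3) ≈ 36.4 Å around the ring centre.

This construction guarantees that the p2 and p6 tilings decorate the
identical receptor point set, which is the hexagonal universality the
models must reproduce. The membrane plane is *z* = 0 and the baseplate
sits at *z* = −300 Å (30 nm, configurable). CheA's P3 dimerisation site
occupies the CSU two-fold axis; P4, the ATP lid and the end of the
P2-P3 linker are abstract point sites placed along the axis-to-P5
directions at fixed fractions, which is all the neighbour-distance
analysis needs. The P1/P2 domains are represented only through the
linker-anchor site.

Each P5/W site carries two docking half-sites, SUB1 and SUB2, whose
bearings point at the two adjacent ring vertices (±60° from the radial
direction); SUB1 faces the counter-clockwise neighbour. Interface
classification is then purely local:

| class | pairing | location |
|-------|---------------------------|---------------------------------|
| I     | P5.SUB1 -- W.SUB2         | intra-CSU                       |
| II    | P5.SUB2 -- W.SUB1         | inter-CSU                       |
| III   | W.SUB1 -- W.SUB2          | CheW/CheW (inter-CSU)           |

With flanking CheW owned by the CSU whose receptor binds it, interior
CSUs of fully occupied lattices of either symmetry count 2× I, 4× II
and 4× III — the published census — while the two architectures
distribute those interfaces differently across ring types (p6:
I/II alternate in (A.P5/W)~3~, III exclusively in (W)~6~; p2: all three
classes, each twice, in every (A.P5/W/W)~2~ ring).

## Contact graph and rings

`build_contact_graph()` pairs free half-sites greedily by docking-point
distance. Matched half-sites are *exactly* coincident by construction;
the nearest non-partner docking points are the two half-sites facing a
vacant flanking slot, *a*/4 apart. The default cutoff is therefore
*a*/10 — any value comfortably below *a*/4 gives the same graph. (A
cutoff of exactly *a*/4 would bridge vacant flanking slots and
fabricate rings in unoccupied lattices, which is why the default sits
well below that geometric threshold.)

Because every ring member has exactly two half-sites, the classified
ring graph has maximum degree two and decomposes into simple cycles
(complete rings — all chordless by construction) and open paths
(PARTIAL records). This makes ring enumeration exact and linear; an
independent igraph-based cycle search cross-checks it in the tests.

Receptor-to-kinase connectivity counts the receptor-to-baseplate
binding as one interface, which reproduces the published hop counts:
in p2, every receptor of an interior ToD is within two interfaces of a
CheA.P5 (multiset {1,2,2}); in p6 the flanking-CheW-bound receptor
terminates in a CheA-free ring and is reported `Inf` (unreachable)
rather than some large number — ring-mediated paths are the only ones
traversed.

"Interior" CSUs are those whose owned ring members (including their
flanking CheWs) have every half-site paired. This is deliberately a
*local* criterion: it is exactly what the per-CSU census needs, but it
does not guarantee that every ring the CSU touches is complete (a
flank's ring may continue into the patch boundary). The connectivity
tests therefore assert ring-composition properties, not ring
completeness.

## Rendering and symmetry classification

`render_baseplate()` splats normalised Gaussians at the in-plane site
positions. Two weight sets are provided:

* `render_weights_ring_layer` (default): receptor tips and P5/W members
  at equal mass, CheA body excluded — the baseplate plane as seen in
  tomographic top views. With these weights both architectures are
  *exactly* periodic with the 126 Å ring lattice, so the
  autocorrelation estimator returns the lattice constant identically
  for p2 and p6.
* `render_weights_chea`: adds P4/P3 and gives P5 extra mass. This
  compositional contrast (CheA-containing versus CheW-only ring
  positions) is precisely what distinguishes the architectures, and is
  what the classifier and the volume simulator use.

`autocorrelation_periodicity()` normalises the FFT autocorrelation by
the overlap area of the finite frame, so a true lattice translation
scores near 1 regardless of patch size while pseudo-translations (e.g.
the half-period shift that partially exchanges receptor and ring
sublattices, which scores ≈0.6) fall away; significance is defined
relative to the strongest off-origin peak (default 0.8), making the
estimator self-calibrating. Sub-pixel refinement is separable quadratic
interpolation around the nearest significant peak.

The classifier scores mean Pearson correlations between the image and
its rotations (orders 2, 3, 6; bilinear interpolation) on a disc of
radius 1.5 *a* about candidate ring centres. Candidate centres are
found by annulus contrast (high density on the member circle at
*a*/(2√3), low at the centre) and then pinned to the hexagonal ring
lattice inferred from the image's own autocorrelation, choosing the
lattice phase with the best median contrast — individual contrast peaks
alone are unreliable because receptor trimers form local pseudo-3-fold
motifs and p2 has two-fold axes between rings. The decision statistic
contrasts genuine high-order evidence, median min(C3, C6), against the
two-fold evidence not explained by it, median (C2 − min(C3, C6)); the
patch is called P6 or P2 only when one exceeds the other by a margin
(default 0.15 correlation units), and AMBIGUOUS otherwise — explicit
abstention beats silent misclassification on noisy patches. Two-fold
similarity itself is high for *both* architectures (every CSU centre is
a two-fold axis), which is the structural reason symmetrised
subtomogram averages could hide a p2 form. Images are pre-smoothed
(default *a*/16 ≈ 8 Å) before scoring: white noise attenuates Pearson
correlations, and matched filtering restores them without moving the
rotation centres.

All thresholds (margin, significance fraction, pre-smoothing width) are
algorithm parameters reported in the `symmetry_report` / CLI output, as
no quantitative symmetry scores exist in the literature to calibrate
against.

## Curved membranes

`map_to_sphere()` wraps a planar model onto a sphere by azimuthal
equidistant projection about the patch centre (placed at the north
pole), preserving each site's depth along the local normal and rotating
half-site bearings into the tangent frame. Arc lengths are preserved at
the membrane radius; the baseplate layer is correspondingly compressed
by (R−300)/R — a genuine curvature effect, ≈1% at the default
minicell-like radius of 1530 Å used in the examples and tests.

`fit_sphere()` is an algebraic least-squares solve followed by a
geometric fixed-point refinement of the orthogonal residuals, and is
accurate on partial caps (the minicell situation); recovery is unbiased
to <0.5% over seeds at 10 Å point noise. On simulated volumes the
membrane points are segmented as bright voxels in a z window
(`bright_points()`), because the baseplate layer is nearly as dense as
the membrane shell and would bias the fit inward. Very shallow caps
constrain the radius weakly — the end-to-end tests therefore use
patches several lattice constants wide, and the projection depth is not
taken from the nominal 300 Å but found by sweeping the normal offset
for the density peak below the membrane (`find_baseplate_offset()`),
the membranogram exploration that also tolerates a few percent of
radius error.

`template_match()` is exhaustive FFT-accelerated normalised
cross-correlation over a coarse orientation grid (default 12°, in-plane
× out-of-plane; the identity-only setting suffices for the isotropic
fixtures). In a simulated minicell volume, matching a cropped
baseplate-ring template reproduces the published picture: an intense
response at the inner membrane plus a peak layer at the configured
baseplate depth (within one voxel).

## Synthetic data

`simulate_volume()` renders membrane shell (Gaussian radial profile,
FWHM = membrane thickness, amplitude 3), receptor rods (mass 0.02 per
Å of length, σ 8 Å) and baseplate blobs (CheA-contrasted weights scaled
to peak amplitude 2, σ 10 Å) into a voxel grid, then adds white
Gaussian noise scaled to the signal RMS and finally applies a hard
Fourier missing-wedge mask (components whose out-of-plane angle exceeds
90° − wedge half-angle are zeroed; the zero-frequency term is kept, so
the mean is preserved). The amplitude ordering membrane > blobs > rods
is a deliberate construction — the membrane is always the densest
feature, as in tomograms. The simulator reproduces what the analysis
stages need (geometry, contrast, noise, wedge anisotropy) and nothing
more: no contrast transfer function, no dose weighting, no
tilt-dependent noise, no neural denoising. Passing tests on it
demonstrate the analysis logic, not performance on real tomograms.

Stochastic flanking-CheW occupancy uses a keyed 32-bit hash of
(seed, CSU id, ToD id) rather than R's global stream, so a site's
occupancy is reproducible independently of evaluation order. Volume
noise derives its `set.seed()` value from the global seed and a stage
label. `make_fixture_suite()` writes the documented fixture set
(planar models, occupancy sweep, spherical volumes, noise ladder) with
MD5 checksums; identical seeds give identical checksums.

## Problem sizes and numerical choices

The default analyses run on desk-scale fixtures: censuses and
connectivity on 6×6 unit-cell patches (108 CSUs for p6), periodicity on
8×8 patches rendered at 2 Å/pixel, classification robustness on 3×3 to
5×5 patches at 3 Å/pixel across 20 seeded poses, and end-to-end volume
recovery on ≈100³-voxel volumes at 8 Å/voxel — sizes where every
documented property is exercised in seconds to a couple of minutes.
Degenerate inputs fail loudly: coplanar points for the sphere fit,
discs exceeding the image frame, aperiodic models in unit-cell
reduction, out-of-bounds projection vertices (masked, never zeroed),
and distance ties in half-site pairing (broken towards the lowest site
id).

## Known limitations

* One architecture per model: no mixed p2/p6 domains, grain boundaries
  or defects — the phase-competition question is outside the scope.
* The coarse-grained sites carry no atomic detail; analyses relying on
  residue-level geometry (beyond the abstract linker-anchor/ATP-lid
  distances) are not supported.
* The minicell curvature reported for the real data cannot be
  recomputed here (its measurement inputs are not published); the
  package instead validates its curvature estimator by parameter
  recovery on simulated point clouds and volumes.
* Interface energetics, signalling kinetics and cooperativity are not
  modelled; the connectivity metrics are purely structural.
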