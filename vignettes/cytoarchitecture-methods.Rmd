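---
title: "Quantifying 3D cytoarchitecture from segmented EM volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D cytoarchitecture from segmented EM volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cochlear inner hair cells (IHCs) are strongly polarised sensory cells: one
lateral face of the flask-shaped cell body is visibly flatter than the
other, afferent terminals cluster on that flattened face, and the
infranuclear cytoplasm carries an extensive network of ER-like membrane
sheets and mitochondria that is concentrated on the same side. At electron
tomography resolution, small (~37 nm) vesicles are tethered to these
membranes and to each other by thin filamentous links whose lengths differ
systematically between cellular contexts.

cytoarch3d re-implements the quantitative machinery needed to measure this
kind of organisation from *segmented* 3D EM data (serial block-face SEM
stacks with anisotropic voxels, electron tomograms with near-isotropic
voxels): shape asymmetry, hemisphere partitioning, point-counting
stereology, membrane-sheet assembly and size classification, organelle
association and distance statistics, and tether morphometry. Because the
kind of data the methods were developed on is not publicly deposited, the
package treats synthetic data generation as a first-class module: every
analysis can be validated by parameter recovery against volumes with
complete planted ground truth.

# Coordinate conventions

A `label_volume` is a 3D integer array indexed `[z, y, x]` with a strictly
positive per-axis voxel size in nm and a label table mapping every label to
a semantic class. z is the sectioning axis. The cell's longitudinal
(apex-base) axis is the in-plane y axis: in a typical acquisition each
section image contains the full length of the cell, and successive sections
march across the cell's width. Consequently:

* the flattened/rounded (and modiolar/pillar) hemisphere split is a split
  in x, guided by a per-section dynamic centre line;
* the anterior/posterior split is a split in z at the cell's mid-section;
* the infranuclear region is a y-range (below the nucleus' basal pole),
  while the 3-µm peri-nuclear window used for partial-volume stereology is
  a z-range of sections (1.5 µm either side of the nucleus' z midline - 60
  sections at a 50 nm cutting pitch).

All public interfaces speak physical nanometres, 0-based voxel-centre
coordinates; voxel indices never cross module boundaries. Distances between
objects use a voxel-box convention: per axis, voxels `i` and `j` contribute
`max(0, |i-j|-1) * pitch`, so touching voxels (face, edge or corner) have a
gap of exactly 0 and one empty voxel between two objects reads as one
pitch. Ribbon positions are the one exception: distances are taken from the
ribbon's approximate centre (its voxel centroid), because that is how such
measurements are reported.

# Cell frame

`dynamic_centre_line()` places one point per section: the in-plane area
centroid of the cell mask, smoothed with a 5-section moving average. No
formula for a "dynamic centre line" is standard; the centroid is the
simplest choice that responds to the asymmetry of the cell (a bulge pulls
the line towards itself), and both the definition and the smoothing window
are exposed. `partition_hemispheres()` assigns a voxel to the positive or
negative hemisphere by comparing its x coordinate with the centre line of
its own section; the two masks always partition the cell mask exactly.

`flatness_profile()` quantifies side asymmetry the way it is done on
section images: on the widest section, a line parallel to the cell's long
axis is placed tangent to the maximal lateral extent of each side, and the
mean boundary-to-line distance is computed in depth bands below the neck
(defaults 1-4, 5-7 and 7-11 µm, scaled down proportionally when a cell is
shorter). The anchoring of the tangent line is a documented assumption -
"tangent at maximal lateral extent" - since only the geometric idea, not an
algebraic definition, is standard. The side with the smaller mean deviation
is the flattened side; ties are flagged. The neck itself is detected as the
minimal cross-sectional area above the nucleus, with a manual override.

# Point-counting stereology

`make_point_grid()` builds systematic grids: whole-cell mode places a
200 nm lattice in-plane on sections 200 nm apart; partial mode places a
grid on *every* section of the peri-nuclear window. The in-plane spacing in
published work of this kind is implied rather than stated, so it is exposed
as configuration with 200 nm as the default. Grid origins are systematic
uniform random (seeded) to remove alignment bias with the voxel raster; a
fixed half-spacing offset mode provides seedless reproducibility.

`classify_points()` gives each point the class of its containing voxel
(cytoplasm, membrane, mitochondrion, ...); since labels are mutually
exclusive, "organelle wins over cytoplasm" needs no tie-break. Terminals
are external boutons and count as not-in-cell. `volume_fraction()` is the
classical estimator: the volume fraction of a structure equals the fraction
of in-cell points hitting it, with the binomial standard error
`sqrt(p(1-p)/n)`. On analytic solids the estimator is unbiased and its
error shrinks as the spacing shrinks; the test suite verifies both on a
sphere-in-cube phantom.

# Membrane sheet assembly

Membranes appear in single sections as thin strands.
`extract_strands()` finds one strand per in-plane 8-connected component of
the membrane class and measures its length as the geodesic diameter of the
pixel set (longest shortest path through 8-neighbour steps weighted by
their physical length) - for a one-pixel-wide curve this is the polyline
arc length. `link_strands()` implements the assembly rule: strands in
*adjacent* sections that lie directly above each other (in-plane pixel
overlap of at least `overlap_min`, default 1 pixel) belong to one putative
sheet; sheets are connected components of this graph. "Directly above" has
no printed tolerance, so the overlap threshold is configurable and a
centroid-distance alternative (<= 100 nm) is provided for sensitivity
analysis. A strand missing on one section and resuming on the next does
not bridge the gap - the rule is strictly adjacent-section.

`sheet_area()` applies the tube model: strands are representative tubes of
radius 50 nm, half the section gap. Two area conventions are emitted and
always labelled: `sheet_face` (strand length x section gap, the face area
of the implied sheet; the default) and `tube_surface` (2 pi r x length).
Published total-area figures in this domain are not derivable from the
printed text alone, so both conventions are reported rather than resolved;
for the size *classification* the choice is immaterial because the two
differ by a constant factor.

`classify_sheets()` reproduces the three-class structure of the sheet-size
distribution: a handful of very large sheets (Type 1), a small flat-portion
population of intermediate sheets (Type 2), and a large steep-portion
population of very small sheets (Type 3). The `largest_gap` method sets the
Type 1 boundary at the largest log-area gap among the top order statistics
(at most `max_type1` = 6 sheets, accepted only if the gap exceeds
`min_gap_log` = 1, i.e. an e-fold area jump). The Type 2/3 boundary between
the flat and the steep region uses the same order-statistic principle:
because the flat portion is small by definition, the transition shows up as
the dominant gap among the top order statistics of the post-Type-1
remainder (searched over the top `max(12, 2%)` ranks, accepted at half the
Type 1 gap requirement). A global two-segment piecewise-linear elbow fit
was evaluated for this boundary and rejected: with a handful of flat points
against thousands of steep ones, the least-squares breakpoint is dominated
by the curvature of the steep segment and lands well inside the small-sheet
population; it is retained only as a fallback when no convincing gap exists
(populations that genuinely blend into "part of a single distribution").
Manual thresholds are supported;
degenerate inputs (all areas equal) yield a single flagged class with no
Type 1. Classification is monotone in area by construction.

# Organelle association and distance statistics

`mito_membrane_association()` measures, per mitochondrion, the minimal
surface-to-surface gap to any membrane strand. The association criterion in
the source imaging work is visual ("no visible gap"); the operational
default here is one in-plane voxel (19 nm), configurable and echoed in the
output. The association fraction is monotone in the threshold. With a sheet
classification available, each mitochondrion also reports how many sheet
types it touches; `mito_density_per_type()` counts only single-type
mitochondria (multi-type ones cannot be attributed) divided by the type's
total area. `ribbon_to_sheet_distances()` reports, per ribbon and sheet
type, the distance from the ribbon centre to the nearest sheet voxel
surface; a type with no sheets yields a missing value, never an infinity.
All nearest-distance code paths are tested for exact equality against
brute-force all-pair search on small volumes, with anisotropy handled by
scaling voxel indices by the per-axis pitch.

`terminal_distribution()` assigns terminal centres to hemispheres through
the cell frame and reports per-pair counts plus the terminal farthest from
the basal pole along the longitudinal axis (whether "farthest" should be
measured along the curved cell axis is unstated in the source literature;
the straight axis is used and documented). `region_membrane_share()`
reports a sub-region's share of cytoplasm volume and of total sheet area,
attributing each sheet by the fraction of its voxels inside the region.

`run_group_tests()` wraps the standard toolkit - Welch/paired t, one-way
ANOVA, Kruskal-Wallis - and adds a Games-Howell post hoc (pairwise
Welch-type statistics against the studentized range distribution), which no
installed package provides. Games-Howell is the only multiple-comparison
layer applied, matching the reporting conventions of the field; its
implementation is validated against an independent reference computation on
a frozen fixture.

# Tomogram-scale tether morphometry

`measure_link()` measures a tether (a thin filamentous link) surface to
surface: the voxel skeleton is ordered along its principal axis; the
primary `length_nm` is the extent of that ordered skeleton along the
principal direction plus one voxel (half a voxel per end compensates the
clipping of the end voxels at the structure surfaces), and the raw
polyline arc length is emitted alongside (`length_arc_nm`; an upper bound,
inflated by rasterisation zig-zag on oblique lines). Whether published
tether lengths were measured straight or along the filament is not stated;
the planted tethers are straight, where the two conventions coincide up to
discretisation. Endpoints resolve to the structures touching the tether;
context follows from the endpoint kinds, with vesicle-vesicle links within
100 nm of a ribbon surface assigned to the ribbon context (an operational
cutoff, configurable). Unattached second ends are flagged, and such links
carry no context.

`vesicle_diameters()` uses the equivalent-sphere diameter
`d = 2 (3V / 4 pi)^(1/3)` from the voxel volume; sub-2-voxel objects are
flagged unreliable. `compare_contexts()` reports per-context means +/- SE
and Games-Howell pairwise comparisons, naming the shortest context.

# The synthetic generators

`generate_cell_volume()` builds a flask-shaped cell in nm space and
rasterises it onto the anisotropic grid, so all planted truths are exact in
nm. The cross-section is a per-side superellipse (a boxier exponent on the
flattened side); the flatness contrast that the profile metric actually
measures is planted as per-side longitudinal bulge amplitudes whose ratio
is `flatness_contrast` - a cross-section exponent alone cannot produce a
controlled deviation along the cell's length. Membrane sheets are planted
as stacks of thin in-plane strand curves on consecutive sections with
bounded per-section jitter (guaranteeing the in-plane overlap that the
linkage rule needs) and a 1-voxel exclusion shell (guaranteeing that
distinct sheets never merge). Mitochondria are grown as compact connected
blobs through free cytoplasm from seeds adjacent to a strand (with
probability `p_mito_association`, default 0.96) or well clear of one;
voxel-exact growth drives each hemisphere's membrane+mitochondria volume
fraction to its target (defaults 0.23 flattened / 0.16 rounded, 0.21
anterior / 0.19 posterior) within +/-0.01. Those four printed fractions are
mutually inconsistent as a single cell's plant (the two pairs average 0.195
and 0.20 - they come from different cell cohorts), so the generator honours
the flattened/rounded pair exactly and applies the anterior/posterior
offset around the flattened/rounded mean. Ribbons are spheres near the
basolateral membrane; each receives a dedicated nearest Type 3 sheet at a
lognormally drawn distance (mean 515 nm by default; lognormal because
distances are positive and the implied spread is large relative to the
mean), with clearance constraints keeping other Type 3 sheets farther.
Terminals are surface boutons placed on the flattened hemisphere
independently with probability `p_flat_terminal` (default 0.63, the ratio
of the printed per-side means) - placement is deliberately binomial, which
is what the recovery tests assume.

Cell dimensions are order-of-magnitude choices (no numeric cell geometry is
printed in the motivating work) and fully configurable; the defaults are a
15 µm wide, 10 µm deep cell with an 11 µm infranuclear region at
19 x 19 x 50 nm voxels. The test suite and the acceptance script run on
proportionally scaled cells (3-5 µm wide) with the same voxel geometry,
probabilities and planted fractions, chosen so one cell holds a few
thousand grid points and a full analysis runs in seconds; the planted
*conditions* (fractions, probabilities, distances, tether lengths, vesicle
diameters) are never scaled.

`generate_tomogram_volume()` emulates a 2 nm isotropic tomogram: an RER
slab over one half of the field with a mitochondrion facing it, and a
ribbon with its vesicle pool in the other half, separated laterally by more
than the ribbon-context cutoff. Tethers are straight rasterised segments
whose endpoints lie exactly on the analytic surfaces of their structures,
so the planted surface-to-surface length is exact. Per-context lengths are
drawn lognormal with means equal to the printed values (30.9, 52.9, 45.4,
22.3, 26.8 nm) and standard deviations recovered from the printed standard
errors at the printed n; the whole length sample is drawn *before*
placement and each drawn length is then placed with geometry-only retries -
re-drawing on placement failure would select against long tethers in
crowded regions and bias the planted means low. Vesicle diameters are
normal, 37.3 nm (RER pool) and 36.3 nm (ribbon pool), sd 5 nm.

What the generators deliberately do not emulate: EM texture, imaging noise
and PSF, segmentation errors, membrane curvature in z, curved tethers, and
real cells' biological covariance between features. Passing recovery tests
therefore demonstrates that the measurement code is correct and unbiased on
geometry it understands - not that it is robust to segmentation noise in
real data, which should be assessed per dataset.

# Numerical choices and degenerate inputs

* Grid spacing below the voxel size is refused (sub-voxel point counting is
  meaningless).
* A TIFF stack without a voxel size in its sidecar is an error, never a
  silent default; MRC voxel sizes come from the header and conflicting
  sidecars are rejected.
* Measurement CSVs refuse unit-less numeric columns and sort rows
  deterministically, so identical inputs produce byte-identical files.
* An empty section inside a cell's z-range aborts the centre line with the
  section named; empty regions and absent organelle classes are explicit
  errors rather than zeros or infinities.
* All stochastic stages require a seed; a fixed seed reproduces volumes and
  pipeline outputs bit for bit.
* The hemisphere-fraction plant tolerance is +/-0.01; the mitochondria fill
  stops within 0.15% of each quadrant's voxel target.

# Known limitations

* The strand-length estimator (geodesic diameter) overestimates the length
  of a thick strand by roughly its half-thickness at each end; at the
  default 2-pixel thickness this stays well inside the 10% tolerance used
  for area recovery.
* Type 1/2/3 classification assumes the three size scales are separated in
  log area; heavily overlapping mixtures will not split cleanly (the
  degenerate flag covers only the fully equal case).
* The per-cell flat-majority probability of terminal placement is fixed by
  the binomial model at `P(Bin(16, 0.63) >= 9) ~ 0.80`; consequences for
  multi-cell laterality detection rates follow from that law and cannot be
  tightened without changing the placement model itself.
* `measure_link()` assumes tethers are simple (non-branching) filaments;
  branching tethers would need a true skeletonisation step.
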