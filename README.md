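# cytoarch3d

Quantitative 3D cytoarchitecture analysis of segmented volume-EM data,
motivated by the strongly polarised organisation of cochlear inner hair
cells (IHCs): one lateral face of the flask-shaped cell is flatter than the
other, afferent terminals and an infranuclear network of ER-like membrane
sheets and mitochondria concentrate on that flattened face, and at
tomography resolution ~37 nm vesicles hang off the membranes and off each
other on 20-55 nm filamentous tethers.

The package takes **segmented label volumes** (multi-page TIFF + JSON
sidecar, or MRC; integer labels over anisotropic voxels, e.g.
19 × 19 × 50 nm for serial block-face SEM) and provides, as tidyverse-style
functions returning tibbles:

* **Cell frame** — dynamic centre line (per-section area centroid,
  smoothed), exact hemisphere partitions (flattened/rounded and
  modiolar/pillar in x, anterior/posterior in z), flatness profiles
  (mean boundary deviation from a tangent line in depth bands below the
  neck), infranuclear extent and the 3-µm peri-nuclear window.
* **Point-counting stereology** — systematic uniform random grids
  (200 nm whole-cell pattern, every-section partial pattern), per-point
  classification against the labels, and the volume-fraction estimator
  `V_V = P_hit / P_total` with binomial standard errors.
* **Membrane sheet assembly** — per-section strands (8-connected in-plane
  components, geodesic-diameter lengths), the adjacent-section linkage rule
  ("directly above" = in-plane pixel overlap ≥ 1), tube-model surface areas
  (r = 50 nm), and Type 1/2/3 size classification from the sorted log-area
  distribution.
* **Spatial statistics** — mitochondrion–membrane association (voxel-box
  surface gaps, threshold = one in-plane voxel), per-type mitochondrial
  densities, ribbon-centre-to-nearest-sheet distances per type, terminal
  hemisphere distributions, sub-region volume/area shares, and group tests
  (Welch/paired t, ANOVA, Kruskal–Wallis, Games–Howell post hoc).
* **Tomogram morphometry** — tether lengths measured surface-to-surface by
  context (mito–RER, vesicle–RER, vesicle–vesicle at the RER or ribbon,
  vesicle–ribbon), equivalent-sphere vesicle diameters, and between-context
  comparisons.
* **Synthetic generators** — cell-scale and tomogram-scale label volumes
  with complete planted ground truth (hemisphere fractions, sheet mixtures,
  association probabilities, distances, tether lengths), so every stage is
  testable by parameter recovery. Defaults are the study conditions:
  fractions 0.23/0.16 and 0.21/0.19, p(flat terminal) = 0.63,
  p(association) = 0.96, ribbon–Type-3 distance 515 nm, tether lengths
  30.9/52.9/45.4/22.3/26.8 nm, vesicle diameters 37.3/36.3 nm.

`run_pipeline()` orchestrates simulate → frame → stereology → sheets →
stats → tomo with one config and one seed, writing deterministic CSV tables
and a JSON manifest; `inst/scripts/cytoarch3d` is a thin command-line
wrapper. See the methods vignette (`vignettes/cytoarchitecture-methods.Rmd`)
for the models, conventions and design decisions.

## Worked example

Simulate a scaled-down cell (3–5 µm cells keep everything interactive;
planted probabilities and fractions are the full study conditions), then
recover what was planted:

```r
library(cytoarch3d)
library(dplyr)

params <- cell_gen_params(
  cell_width_um = 5, cell_depth_um = 4, infranuclear_um = 4,
  nucleus_um = 2.5, neck_um = 1.5, n_terminals = 8, n_ribbons = 4,
  ribbon_type3_distance_sd_nm = 250, terminal_radius_nm = 400,
  sheet_area_mixture = list(
    counts = c(3L, 8L, 60L), mean_area_um2 = c(4, 0.8, 0.08),
    sdlog = c(0.2, 0.2, 0.4)
  ),
  seed = 1
)
sim <- generate_cell_volume(params)
frame <- cell_frame(sim$volume)

# hemisphere volume fractions by point-counting stereology
pts <- classify_points(
  make_point_grid(sim$volume, offset = "sur", seed = 1),
  sim$volume, frame
)
volume_fraction(filter(pts, infranuclear), by = "hemi_fr")
#> # A tibble: 2 × 5
#>   hemi_fr   n_points_count n_hits_count fraction_frac se_frac
#>   <chr>              <int>        <int>         <dbl>   <dbl>
#> 1 flattened           3439          785         0.228 0.00716
#> 2 rounded             3518          555         0.158 0.00615

# sheet assembly and size classes
strands <- extract_strands(sim$volume)
sheets  <- sheet_area(link_strands(strands), strands, sim$volume)
tidy(classify_sheets(sheets))
#> # A tibble: 3 × 6
#>   class n_sheets_count mean_area_um2 se_area_um2 total_area_um2 area_fraction_frac
#>   <chr>          <int>         <dbl>       <dbl>          <dbl>              <dbl>
#> 1 Type1              3        3.97        0.370           11.9               0.490
#> 2 Type2              8        0.864       0.0307           6.91              0.284
#> 3 Type3             60        0.0912      0.00468          5.47              0.225

# mitochondrion-membrane association
association_summary(mito_membrane_association(sim$volume))
#> # A tibble: 1 × 3
#>   n_mito_count associated_frac se_frac
#>          <int>           <dbl>   <dbl>
#> 1           99           0.990  0.0100
```

The flattened hemisphere carries a 0.228 ± 0.007 membrane+mitochondria
volume fraction against 0.158 ± 0.006 on the rounded side (planted:
0.23/0.16); the planted 3/8/60 sheet-size mixture is recovered exactly; and
99% of the 99 mitochondria sit in contact with a membrane strand (the
realised plant for this seed's Bernoulli(0.96) draws).

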