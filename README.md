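# bunchmetric

Phenotyping grape bunches from 3D point clouds. Bunch weight, size and
volume are yield- and quality-relevant traits, but a bunch is an awkward
object to measure: an irregular, self-occluding aggregate of dozens of
berries. `bunchmetric` implements a complete measurement pipeline for
multi-view depth-camera scans of a single bunch:

1. **Segmentation** — crop a raw single-view cloud to the working volume,
   then extract the bunch by curvature-seeded region growing: per-point
   normals and surface variation `λ_min / (λ_1+λ_2+λ_3)` come from the
   eigendecomposition of each point's k-neighborhood covariance; regions
   grow from low-curvature seeds while the normal angle to the current
   seed stays below a threshold.
2. **Registration** — merge 12 turntable views (30° steps about the
   vertical axis) into one 360° model `P_0`: PCA frames (`Cov(X,Y,Z) =
   UΣVᵀ`) give a coarse alignment, point-to-point ICP with an SVD
   closed-form update refines it, consecutive triples merge into quarter
   models and then into one cloud, followed by voxel-grid downsampling and
   moving-least-squares smoothing (local plane fit minimizing
   `Σ ⟨n,p_i⟩−D)² θ(‖p_i−q‖)` with `θ(d)=exp(−d²/h²)`) to remove the
   doubled-surface ghosting of imperfect registration.
3. **Size** — length, width, height as coordinate extents in the bunch's
   own PCA frame.
4. **Volume** — five estimators: bounding cylinder `V = π r² h` (GM), 3D
   convex hull (CH), 3D alpha-shape (Delaunay tetrahedra filtered by
   circumsphere radius ≤ α, AS), voxel occupancy `V = Σ k³` (VB), and
   Poisson indicator-function surface reconstruction (PB): oriented
   samples are splatted through a Gaussian filter into a vector field
   `V⃗`, the Poisson equation `Δχ̃ = ∇·V⃗` is solved on a regular grid, and
   the isosurface is extracted as a watertight triangle mesh whose volume
   is the signed-tetrahedron sum `V = |Σ (1/6)(v₁×v₂)·v₃|`.

A synthetic scanner generates bunches of known geometry (spherical
berries, irregular lobed envelope, turntable views with occlusion, sensor
noise, background board and outliers) together with a Monte-Carlo
union-of-spheres volume oracle that plays the role of the physical
water-displacement measurement, so every stage can be validated against
ground truth. A packaged 16-sample reference table of published size
errors and per-method volumes supports exact reproduction of its summary
statistics and method comparison (regression R²).

All coordinates are centimetres internally; volumes are cm³.

## Worked example

```r
library(bunchmetric)

# a 60-berry synthetic bunch and its reference volume
bunch <- generateBunch(bunchSpec(berryCount = 60, seed = 14))
truth <- trueVolume(bunch, samples = 1e6, seed = 14)
truth$volume
#> [1] 535.1623

# 12 turntable views, 30 degrees apart, 2 mm sensor noise
views <- scanViews(bunch, scanSpec(seed = 114))

# merge, smooth, measure
merged <- mergeViews(lapply(views, function(v) v$cloud))
model <- mlsSmooth(downsampleCloud(merged$cloud, 0.3), mlsParams())
report <- measureAll(model, alpha = 1.6, voxelEdge = 0.2,
                     vTrue = truth$volume, sampleId = "demo")
report
#> VolumeReport 'demo'
#>   size: l 9.71  w 8.81  h 17.13 cm
#>   V_true = 535.16 cm^3
#>   V_GM = 1268.05 cm^3
#>   V_CH = 850.08 cm^3
#>   V_AS = 714.14 cm^3
#>   V_VB = 122.05 cm^3
#>   V_PB = 594.48 cm^3
```

The bounding cylinder (GM) more than doubles the true volume because it
counts all inter-berry space; the convex hull (CH) still bridges every
concavity; the alpha-shape (AS) follows the envelope more closely; the
voxel count (VB) on a surface-only cloud measures the occupied shell, far
below the solid volume; the Poisson surface (PB) is closest to the truth,
and slightly above it because the closed surface cannot see interstitial
crevices — the same ordering the published comparison reports.

The published 16-sample table is reproduced with:

```r
summarizeTable1()$summary["v_pb", "Mean"]
#> [1] 746.77
summarizeTable1()$r2
#>     gm     ch     as     vb     pb
#> 0.5843 0.6522 0.7609 0.3074 0.9922
```

A command-line interface mirroring the pipeline stages is installed at
`exec/bunchmetric` (`synth`, `segment`, `register`, `measure`, `evaluate`,
`reproduce-table1`, `run`).

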