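# canopy3d

Extract canopy structure — per-leaf areas, vertical leaf area density (LAD)
profiles, leaf area index (LAI), and leaf inclination angles — from
multi-station terrestrial lidar point clouds of a crop canopy, with a
virtual scanner that generates fully ground-truthed synthetic scans for
validation.

## Who this is for

Plant-phenotyping and canopy-ecology researchers working with
high-resolution terrestrial laser scans (millimeter range resolution,
millimeter point spacing) of individual plants or small canopies, who need
leaf-level structure rather than whole-canopy gap-fraction summaries.

## What it computes

Stations scanned around the canopy are co-registered by point-to-point
**ICP** (iterative closest point): alternate nearest-neighbor
correspondence assignment with the closed-form least-squares rigid update
(SVD of the cross-covariance, reflection-corrected),

```
argmin_{R,t} Σᵢ ‖ R sᵢ + t − gᵢ ‖²,   RᵀR = I, det R = +1,
```

with distance-based and median-based outlier trimming for partial overlap.

Each labeled leaf is triangulated by principal-axes projection: fit the
least-squares plane, denoise heights by quadratic moving-least-squares,
Delaunay-triangulate the projection (a fast Bowyer–Watson triangulation in
C++), and lift faces back to 3-D. Then

* one-sided leaf area `A = Σ_faces ½‖(v₁−v₀)×(v₂−v₀)‖`,
* `LAD_k = (Σ face areas in layer k) / (footprint × layer thickness)` with
  20 cm layers,
* `LAI = Σ_k LAD_k · thickness ≡ (total leaf area) / footprint`,
* leaf inclination at a point `θ = acos|n_z| ∈ [0°, 90°]`, the zenith angle
  of the upward-folded surface normal,
* `MAPE = (100/n) Σ |estimate − truth| / truth` for leaf-area validation.

The virtual scanner casts beams on a regular angular grid from three
stations 120° apart at 5 m range (zenith span 94° ± 13°, ~2 mm spacing,
1 mm range noise along the beam), keeps first returns only (occlusion),
and labels each return with the leaf it hit. Scenes are parametric curved
leaves with closed-form normals and quadrature-exact areas, so every
downstream estimate can be scored against truth.

## Worked example

```r
library(canopy3d)
report <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

The pipeline logs each stage to stderr:

```
simulate: 30 leaves, seed 1
register: station 2 -> 1, rmsd 0.002 m, 25 iterations
register: station 3 -> 1, rmsd 0.0019 m, 29 iterations
mesh: 30 leaves with enough points
traits: 30 leaves, LAI 2.07, leaf-area MAPE 1.20%
```

and returns (and writes to `run1/report.json`) the run summary:

```r
report$mape_leaf_area   # 1.20  -- mean abs. % error of the 30 leaf areas
report$lai              # 2.07  -- m^2 m^-2 over the 0.19 m^2 footprint
head(report$per_leaf)   # leaf_id, area, centroid_z, n_faces,
                        # mean/std inclination, true_area
```

Here the registration RMSD (~2 mm) is the residual point-to-point distance
after aligning stations; the MAPE says reconstructed leaf areas are within
a couple of percent of the generator's true areas; `run1/lad.csv` holds the
20 cm LAD profile whose integral is the LAI. Per-station clouds, the merged
registered cloud, per-leaf meshes (ASCII PLY) and the ground truth are all
left in `run1/`.

The same stages are available from a shell:

```sh
Rscript inst/cli/canopy3d.R run --out run1 --seed 1
Rscript inst/cli/canopy3d.R simulate --out scans --seed 7
Rscript inst/cli/canopy3d.R mesh scans/station1.ply --batch-out meshes
Rscript inst/cli/canopy3d.R traits meshes --footprint 0.19
```

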