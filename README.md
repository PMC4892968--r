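# tracemap

Reconstruction and atlas normalization of serial-section neuroanatomical
tracer data.

## What it is for

Retrograde tracer studies of cortical connectivity produce, per animal, a
rostrocaudal stack of stained 2D section images plus plotted coordinates of
labeled neurons and injection sites. Individual sections are rigidly
misaligned and locally deformed, and the whole stack is affinely distorted
relative to any reference brain, so results from different animals cannot be
compared directly. `tracemap` converts such a stack into a 3D volume
registered to a labeled reference template and carries every plotted point
into template stereotaxic space with a cortical-area assignment, nominal and
normalized cortical depth, and accuracy statistics. It is aimed at
neuroanatomy labs who want archival, manually plotted material expressed in
a common atlas frame.

The pipeline has three stages, each exposed as ordinary R functions and
composed by `run_pipeline()`:

1. **Iterative affine reconstruction** — alternating 3D affine registration
   of the reference to the stack (yielding a "virtual reference" section per
   plane) and 2D rigid registration of each section to its virtual
   reference, driven by joint-histogram mutual information
   (`affine_reconstruction()`, `register_rigid_2d()`).
2. **Deformable reconstruction** — each section warped toward the average of
   its neighbors by Gaussian-regularized additive demons, removing
   uncorrelated per-section distortion while monotonically decreasing the
   between-section mean-squared difference (`deformable_reconstruction()`).
3. **Template coregistration** — resampling to 0.075 mm isotropic with a
   1-voxel median filter, 3D affine MI registration, then multi-resolution
   deformable registration driven by local correlation plus a landmark
   point-set attraction (equal weights), the practical counterpart of a
   CC + point-set-expectation objective (`normalize_to_template()`).

All stages are stored as *forward point maps* in a transform chain
(`map_point_through_chain()`, JSON round-trip via `write_chain_json()`);
registration outputs that are naturally resampling maps are inverted by
fixed-point iteration (`invert_field()`). Cell records get their area by
label lookup with a nearest-cortical-structure fallback (`assign_area()`),
and their depth from a Laplace-equation potential with streamline-integrated
thickness (`solve_depth()`), 0 at the pial surface, 1 at the gray/white
border, 0.5 defining the mid-thickness surface.

A first-class synthetic phantom (`make_phantom()`) generates a parcellated
hemispherical-shell template, a distorted section stack with known
ground-truth transforms, and planted cells/injections, so that every stage —
and the whole pipeline — is testable against ground truth without real
histology. The assessment module reproduces the standard validation battery:
per-injection Euclidean discrepancies against expert coordinates
(`discrepancy_table()`, with a packaged 17-injection coordinate table
shipped as `load_injection_table()`), Pearson correlation of per-area
percentages (`percentage_agreement()`), and sparse-connection concordance
(`sparse_concordance()`).

## Worked example

Recompute the recorded injection-site discrepancies from the packaged
coordinate table, then run a complete synthetic study:

```r
library(tracemap)

tab <- load_injection_table()
dt  <- discrepancy_table(tab)
round(range(dt$table$discrepancy_mm), 2)
#> [1] 0.01 1.36
round(dt$mean_mm, 3)
#> [1] 0.603
```

The mean recomputed discrepancy between automated and expert injection-site
coordinates is 0.6 mm — the scale of disagreement one should expect between
a registration-based and an expert-based localization of the same deposits.

```r
study <- run_phantom_study(phantom_config(seed = 7))
study$scores[c("median_injection_error_mm", "cell_area_accuracy",
               "percentage_r")]
#> $median_injection_error_mm
#> [1] 0.05810742
#>
#> $cell_area_accuracy
#> [1] 0.9688889
#>
#> $percentage_r
#> [1] 0.9978945
```

On the default phantom (64³ template, 32 distorted sections, 3 injections,
900 cells) the full pipeline localizes injection centers to 0.06 mm median
error, returns 96% of cells to their true area, and reproduces the true
per-area percentage profile with r > 0.99. The run takes on the order of a
minute on one CPU.

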