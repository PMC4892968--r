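---
title: "Reconstructing and normalizing serial-section tracer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and normalizing serial-section tracer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retrograde tracer experiments produce, per animal, a rostrocaudally ordered
stack of stained 2D sections plus the plotted coordinates of labeled neurons
and injection sites on those sections. Sections cut from free-floating tissue
are individually translated, rotated and locally deformed, and the whole
stack is affinely distorted relative to any reference brain. To compare
cases, every plotted point must be expressed in the stereotaxic frame of a
labeled 3D template, with a cortical-area assignment and a laminar-style
depth coordinate. `tracemap` implements that pipeline end to end, together
with a synthetic phantom that makes each stage verifiable against known
ground truth.

## The transform model

All spatial stages are *forward point maps* stored in a transform chain. A
section point $(s, x, y)$ is mapped by

1. a per-section 2D rigid transform (rotation + translation about the
   section center),
2. an optional per-section 2D displacement field,
3. lifting to 3D at the section's nominal rostrocaudal plane
   ($\mathrm{AP} = \mathrm{origin} + (s-1)\,\Delta$, with $\Delta$ the
   apparent section thickness); obliquity of sectioning is carried entirely
   by the global affines,
4. the reconstruction affine (stack space to template space, from stage 1),
5. a template-space affine correction and a template-space 3D displacement
   field (stage 3).

Registration algorithms naturally output *pull* (resampling) maps; those are
converted to forward maps by fixed-point displacement-field inversion
(tolerance 0.01 voxel, at most 50 iterations; lookups are clamped to the
field domain, where the displacement would otherwise read as zero and break
the contraction). Chains serialize to JSON at full floating-point precision,
so a reloaded chain reproduces mapped points bit for bit.

Conventions: axes are (ML, AP, DV) in mm; voxel indices are 0-based with
world coordinates at voxel centers, $\mathrm{world} = \mathrm{origin} +
\mathrm{index} \times \mathrm{spacing}$. The packaged injection-coordinate
table keeps AP signs exactly as printed in its source atlas convention
(negative values rostral to the interaural line); the package applies no
sign conversion of its own.

## Stage 1: iterative affine reconstruction

Given the reference template and the raw stack, the pipeline alternates
(i) a 12-parameter 3D affine registration between the current stack volume
and the reference, after which the reference is resliced at every section
plane to yield each section's *virtual reference*, and (ii) a 2D rigid
registration of each section to its virtual reference. Both registrations
maximize joint-histogram mutual information (bin count capped so the joint
histogram stays populated — about 8 samples per occupied bin row — because
no Parzen smoothing is applied; only the ranking of candidate transforms
matters for optimization). The optimizer is Nelder-Mead followed by a
deterministic compass (pattern) search, which we found necessary because
simplex steps stall on the jagged fine-scale structure of sampled MI; a
coarse rotation sweep at the lowest pyramid level protects against the
rotational local optima of ring-like section images. The loop runs up to 10
iterations (middle of the 8–12 range typical for this procedure) and stops
early when the mean per-section MI improves by less than `tol` (default
1e-3); a drop of more than 10% aborts with a diagnostic, and a 2D
registration that fails to beat its initialization returns the
initialization flagged with a warning.

## Stage 2: deformable reconstruction

Uncorrelated per-section distortions are reduced by warping every section
toward the unweighted average of its immediate neighbors (radius 1 on either
side; edge sections use the neighbors they have), all sections updating
simultaneously from the previous iteration's images. The warp model is
additive demons with Gaussian field regularization ($\sigma$ = 2 voxels),
standing in for diffeomorphic machinery: the contract of this stage is the
warp's effect (smoothness of the stack), not a particular algorithm, and
invertibility is enforced by a displacement-gradient check (< 1) with
automatic regularization increase. The summed mean-squared intensity
difference between consecutive sections is monitored; an update that would
increase it is reverted and the stage stops, making the stage monotone by
construction. Eight iterations are the default; each section-to-target warp
takes three demons sub-steps per iteration (a single first-order step can
move at most half a voxel, too little to absorb realistic per-section
distortion within eight iterations).

## Stage 3: coregistration with the template

Both the reconstructed volume and the template are resampled to an isotropic
working resolution of 0.075 mm and median-filtered once with a 1-voxel
radius (labels are resampled nearest-neighbour and never filtered). A 3D
affine MI registration is followed by multi-resolution (3-level) additive
demons driven by the local intensity difference plus, when landmark sectors
are supplied, a point-set attraction force: each fixed-side landmark voxel
is pulled toward the nearest same-label point of the moving side, the
forces capped at one voxel per iteration, splatted into the update and
smoothed with the field. Intensity and landmark terms carry equal weight by
default. This is the practical counterpart of combining a windowed
cross-correlation metric with a point-set expectation (PSE) metric; the PSE
reported in diagnostics is the symmetric mean nearest-neighbour distance
between labeled point sets, averaged over labels (the exact form used by
other toolchains is unpublished, so this definition is stated and tested as
a pseudo-metric in its own right). Landmark volumes are converted to point
sets by taking labeled voxel centers, subsampled to at most 2,000 points per
label with a deterministic stride. The tested guarantee is behavioural:
with landmarks enabled the final landmark PSE is never higher than with
landmarks disabled (paired runs), and never higher than after the affine
stage alone — the latter enforced by a trust-region safeguard that halves
the deformable field (down to zero, i.e. the affine-only alignment) if an
update would worsen the landmark term; in practice the safeguard engages
only on nearly-converged problems where the deformable stage has little
left to do.

## Cortical depth

The parcellation's cortex voxels form the domain of a Laplace problem with
potential 0 on pial-adjacent and 1 on white-matter-adjacent boundaries
(6-connectivity; Neumann conditions at grid faces), solved by SOR to a
residual below 1e-4. Streamlines of the potential gradient are integrated
from each voxel in both directions (RK2, 0.25-voxel steps); a streamline
terminates when its nearest voxel leaves the cortex mask, with the exit
refined by bisection so the surface sits at the half-voxel interface —
this placement is what makes a 5-voxel slab measure exactly 5 voxel
spacings thick. Thickness is the total streamline length, normalized depth
the pial-side fraction; the mid-thickness voxel set collects voxels whose
normalized depth is within half a voxel (scaled by local thickness) of 0.5.
Streamline failures near sharp label corners fall back to the potential
itself as normalized depth and inherit the nearest successful voxel's
thickness; the count is reported. Points outside the brain are assigned
nominal and normalized depth 0; points in the subjacent white matter get
normalized depth 1 and, as the package's own convention, a nominal depth
equal to the thickness at the nearest cortical voxel (the gray/white border
depth) — the mapping rule only specifies the normalized value, so the
nominal clamp is documented here.

Points mapped outside the cortical delineation are assigned to the nearest
cortical voxel by Euclidean distance (ties to the smaller label id), capped
at 1 mm by default: the source procedure states no cap, but an unbounded
fallback can produce absurd assignments for badly mapped points, so beyond
the cap a point is retained but flagged unassigned and excluded from
summaries. Per-area summaries exclude cells in the injected area (intrinsic
label cannot be separated from passive uptake near the deposit), so the
injected area's percentage is undefined by construction and flagged `NA`.

## The phantom: what it emulates and what it does not

The generator builds a hemispherical shell "cortex" (inner radius 1.9 mm,
outer 2.8 mm) around a white-matter core on a 64³ grid of 0.12 mm voxels,
subdivided into 6 equal azimuthal sectors about the AP axis, with three
landmark sectors on the shell. Intensity is an area-dependent mean plus a
smooth radial profile and seeded smooth noise, giving the similarity metrics
gradients to exploit. Sections are cut coronally every 0.24 mm (twice the
in-plane spacing, mirroring the anisotropy between scan resolution and
apparent section thickness in the real workflow) and perturbed by drawn
per-section rigid jitter (SD 0.25 mm, 0.03 rad), smooth random per-section
deformations (RMS 0.12 mm, 1 mm smoothness, redrawn if the displacement
gradient reaches 0.5 — the distortions remain invertible by construction),
and a global affine (scales in [0.95, 1.05], shears to 0.03, rotations to
0.05 rad). These magnitudes were chosen once as representative of the small
compression, stretching and bending that free-floating sections suffer.
Cells are planted analytically on the shell: uniform azimuth within an
area, latitude uniform in ±1.2 rad, normalized depth uniform in [0.2, 0.8],
per-area counts multinomial with weights decaying in angular distance from
the injected area; injections are voxel neighborhoods (0.25 mm radius) at
mid-depth. Plotted coordinates are produced by the *inverse* ground-truth
chain, including the quantization of each cell onto its nearest section —
exactly as a plotted neuron loses sub-section AP position in reality.

Every phantom output is a pure function of the configuration and its seed
(one RNG stream per generation stage at fixed seed offsets). Azimuthal
sector boundaries contain the AP axis, so section quantization alone cannot
flip an area assignment; that mirrors coronal sectioning against area
borders that run orthogonal to the cut, and it means the phantom does not
probe errors across borders parallel to the sectioning plane. Other real
features the phantom does not emulate: tears and missing tissue, staining
inhomogeneity, true cytoarchitectonic texture, inter-individual shape
variability, and a parcellation with hundreds of areas whose widths approach
the registration error. Passing the phantom battery therefore demonstrates
the machinery's correctness and its accuracy under representative geometric
distortion, not the field error rate on real histology.

The subject-side landmark volume is produced by carrying the template
landmark sectors through the ground-truth global affine into stack space —
the phantom's analogue of hand-drawing landmark sectors on a reconstruction,
idealized in that it omits per-section distortion of the drawings.

## Problem sizes and numerical choices

The default validation sizes were chosen as the smallest at which each
quantity is stable: the full study runs the 64³ phantom (32 sections of
64×64) through all three stages; unit tests use a 32³ phantom; the depth
oracles use a 16×16×11 slab and a 64³ shell of 2–3 mm radius at 0.1 mm
voxels. MI optimization subsamples volumes to roughly 50k voxels per
evaluation — beyond that the MI surface does not change materially, the
cost does. Ties in area assignment break toward the smaller label id; the
rigid optimizer breaks restarts deterministically (fixed sweep order);
everything that draws random numbers takes an explicit seed. Degenerate
inputs are handled as stated contracts: constant images yield MI 0 with a
warning, windowed correlation with no valid windows raises
`MetricUndefined`, mismatched landmark inventories raise
`LandmarkMismatch`, a non-invertible requested resampling raises
`ContractViolation`.

## Known limitations

The demons stages are first-order and not guaranteed diffeomorphic (only
gradient-checked); large real distortions may require a stronger model. The
assessment of laminar position stops at normalized depth — layer thickness
varies between areas and with curvature, which a depth fraction cannot
capture. The nearest-structure fallback and the discrete parcellation make
binary area decisions near borders that are genuinely gradual in tissue.
Expert percentage tables reported as ranges are scored at interval
midpoints. Percentage correlations are reported both with and without
zero-zero pairs, since whether such pairs belong in the comparison is a
judgment call; both numbers are computed so the reader can apply either
convention.
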