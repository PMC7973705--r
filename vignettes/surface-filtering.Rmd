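---
title: "Shrinkwrap surface filtering: method, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkwrap surface filtering: method, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Printing a fractured hemipelvis directly from a Hounsfield-threshold
segmentation is slow and fragile: the threshold keeps cancellous interior
structure and cortical walls of wildly varying thickness, which an FDM
printer has to fill and support. What a surgeon needs for plate pre-bending
is only the cortical *surface*, as a thin shell of even wall thickness, with
the fracture lines still open so the model can be reduced like the real
bone. `bonewrap` builds that shell.

The method is a constrained shrinkwrap. A sphere `S` (the *surface model*)
is initialized around the segmented model `M` and alternately shrunk and
remeshed until it adheres to `M`; extra stages handle the two places where a
pure closest-point wrap fails: concavities deeper than their rim is wide
(the acetabular cup) and narrow fracture gaps.

## The pipeline

1. **Offset wrap (phase 1).** Each vertex `s` of `S` moves to
   `s + (lambda - O) * dir`, where `dir` is the unit direction to its
   closest point on `M` and `lambda` the distance: it lands exactly on the
   offset-`O` level set of `M`. After each shrink the surface is remeshed
   (below) to restore uniform vertex distribution. Three iterations are run;
   the remesh of the *last* iteration is skipped. The skip matters: over a
   wide concavity the closest-point map is discontinuous across the medial
   axis, so neighbouring vertices land far apart and faces stretch —
   exactly the "large faces over the cup" that the next stage needs to see.
   A remesh would erase them (post-remesh edges are on the order of the
   remesh voxel, far below the 20 mm separation threshold), and the
   projection stage would never trigger.
2. **Separation.** Faces with an edge longer than `E_T` are split off into a
   subset `S_sub`; the remainder keeps the boundary vertices, and the
   correspondence is recorded for reattachment.
3. **Subdivision.** `S_sub` is Loop-subdivided until every edge is at most
   `E_S`. Interior vertices use the standard Loop masks; boundary midpoints
   are linear and the original boundary vertices stay *fixed*, so the
   separation interface is preserved. Midpoints inserted on interface edges
   are recorded, and at reattachment the neighbouring faces of the remainder
   are split against the same midpoints — the merged mesh stays
   edge-manifold instead of acquiring hanging nodes.
4. **Projection.** From every vertex of the subdivided subset a ray is cast
   along its inward normal. A hit at distance `lambda` is kept when
   `P_min < lambda < P_max` and when its isolation distance `d_i` — the
   nearest-neighbour distance among *all* hits passing the window, computed
   before any pruning, so the result is order-independent — is below `D`.
   Kept vertices move to their hit point; this is what carries the surface
   to the bottom of the cup. Isolated hits are typically rays that slipped
   into a narrow fissure; pruning them keeps the wrap out of the fracture
   gaps.
5. **Adhesion wrap (phase 2).** Seven shrink+remesh iterations at offset 0
   smooth the projection artefacts and close the remaining distance. Here
   the *final* remesh is kept: gap deletion needs the remeshed vertex
   distribution. A final bare shrink would put every vertex exactly on `M`
   (distance 0), the deletion threshold could never trigger, and fracture
   lines would never open.
6. **Gap deletion.** Vertices farther than `G` from `M` are deleted with
   their faces. Over a fracture gap the remeshed surface bridges the void,
   its mid-gap vertices exceed `G`, and the bridge falls away — the fissure
   stays visible. The result is an open (non-solid) surface.
7. **Solidification.** Every vertex is copied to `s + n * T` along its
   outward normal; the copied faces keep their winding (outer skin), the
   original faces are reversed (inner skin, carrying the anatomical surface
   used for plate bending), and each boundary edge is closed with two
   triangles between the rim and its offset copy. Boundary *pinch* vertices
   (two loops touching at a point, which gap deletion can produce) are
   duplicated per face-fan first; otherwise the closure would create a
   4-valent edge. Offset fold-overs at high-curvature vertices raise a
   warning, not an error. The result is watertight and consistently
   oriented.

## Parameters

| name | symbol-style meaning | default | unit |
|---|---|---|---|
| `offset` | phase-1 offset between `S` and `M` | 15 | mm |
| `edge_threshold` | edge length routing a face to projection | 20 | mm |
| `subdiv_edge` | maximal edge after Loop subdivision | 5 | mm |
| `proj_min`, `proj_max` | open window for projection ray length | 0, 100 | mm |
| `prune_dist` | maximal isolation distance of an accepted hit | 2 | mm |
| `gap` | deletion threshold after the final wrap | 1 | mm |
| `thickness` | shell thickness of solidification | 0.8 | mm |
| `phase1_iters`, `phase2_iters` | wrap iterations | 3, 7 | — |
| `remesh_voxel` | remeshing grid resolution | 2.5 | mm |
| `sphere_margin`, `sphere_edge` | initial sphere radius factor, edge | 1.2, 8 | —, mm |

The first eight are the established defaults for hemipelvis models. The
projection window is stated in its source as the pair "`P_max`, `P_min` =
0 mm, 100 mm"; only the reading `P_min = 0`, `P_max = 100` yields a
non-degenerate strict window, so that is what the package uses. The
remeshing resolution is not stated anywhere; the default of
`subdiv_edge / 2` keeps remeshed edges finer than the subdivision target. It
is exposed in `filter_config()` like everything else. The initial-sphere
parameters only need to enclose the target; results are insensitive to
them because the first shrink lands on the offset level set regardless.

Segmentation uses a lower cutoff of 300 HU by default, the midpoint of the
200–350 HU band appropriate for cortical bone; CT scans of PLA prints are
segmented with a window of about −900 to −200 HU instead. Manual editing is
replaced by 26-connected component selection (largest or seeded);
26-connectivity keeps thin diagonal cortical walls in one piece where
6-connectivity would fragment them.

## Remeshing

Remeshing samples a distance field of the current surface on a regular grid
(`remesh_voxel` spacing, grid padded beyond the bounding box) and extracts
an isosurface with marching tetrahedra (six tetrahedra per cube around a
fixed diagonal, shared-edge vertex welding, orientation from the field
gradient). Two field variants are used:

* **Closed input** (every pipeline intermediate): a *signed* field — unsigned
  distance from a BVH closest-point query, sign from ray-crossing parity per
  grid row — marched at level 0. This reconstructs the surface itself, with
  only interpolation error on smooth areas, which matters because the
  deletion threshold `G` = 1 mm is tighter than the voxel diagonal.
* **Open input**: the unsigned distance *band* at half a voxel diagonal is
  marched and the connected component nearest the input is kept, which keeps
  the operation well defined for sheets with boundary. The band sheet sits
  half a diagonal off the input; inside the pipeline this bias would be
  corrected by the next shrink anyway, but no pipeline stage actually
  remeshes an open surface.

Distances are clamped a little above the extraction level (the far field
does not influence the isosurface), which keeps the field computation fast
at fine resolutions. Edge interpolation weights are clamped to [0.1, 0.9]
— when the level passes very close to a grid node this suppresses sliver
triangles at a position cost of at most a tenth of a voxel; grid nodes
exactly on the level are nudged by 1e-9; parity rays carry a deterministic
sub-millivoxel jitter so they cannot graze mesh edges exactly. There is no
randomness anywhere in the pipeline: identical inputs and configuration
give byte-identical outputs.

## The phantoms

Patient CTs cannot ship with a package, so the generator builds the
geometry the pipeline exists for, with known ground truth:

* **Cup shell** (`make_cup_shell()`): a hollow spherical cortical shell
  (default outer radius 44 mm, wall 3 mm, 1000 HU on a 40 HU soft-tissue
  background, Gaussian noise SD 20 HU) with a cylinder-walled cup recessed
  into its top and optional fracture fissures — slabs of background HU
  cutting through the shell away from the cup. `cup_rim_width` is the
  rim-to-axis distance of the opening (half-width). The defaults — 26 mm
  half-width, 28 mm depth — match adult acetabular proportions (about 52 mm
  socket diameter and 28 mm depth) and put the phantom in the regime where
  closest-point wrapping must fail: from above the opening the nearest
  surface is always the rim, and with a 15 mm offset the phase-1 wrap stops
  a full cup depth short of the floor. The opening is also wide enough that
  the medial-axis jump of the shrink map stretches faces beyond the 20 mm
  separation threshold, so the projection stage engages exactly as it does
  over a real acetabulum.
* **Sphere shell** (`make_sphere_shell()`): the convex control; its ground
  truth is an icosphere with vertices exactly at the nominal radius.

The intensity model is deliberately simple: two tissue classes plus
Gaussian noise. It does not emulate partial-volume ramps at submillimetre
walls, beam hardening or metal artefacts, and the fissures are planar slabs
rather than irregular fracture surfaces. Passing the phantom suite
therefore shows the geometry processing is correct under CT-like contrast;
it does not certify segmentation quality on artefact-laden clinical scans,
which is why the workflow keeps the overlay verification step against the
original CT.

## Fracture gaps and the deletion bound

Gap deletion can only sever a bridge whose mid-gap *vertices* exceed `G`.
That gives a geometric validity bound: a fissure of width `w` is guaranteed
open when `w > 2 * (G + remesh voxel diagonal)`. Below that bound the wrap
can ratchet into the slot — each remesh rounds the rim crease slightly
inward, the next shrink anchors the rounded part to the slot wall — until
every vertex is within `G` of a wall and nothing is deleted. With the
default 2.5 mm remesh voxel the bound asks for gaps wider than about
10.7 mm; a 3 mm fissure is therefore exercised in the tests with a 0.25 mm
remesh voxel (diagonal 0.43 mm, bound 2.9 mm) on a proportionally smaller
fissured phantom, where the gap stays open and, for contrast, a fill-based
segmentation of the same phantom seals it. On clinical models the practical
mitigation is the same: lower `remesh_voxel` (and accept the longer run
time) when fracture gaps are narrow.

## Validation metrics

`landmark_register()` is the closed-form least-squares rigid alignment
(SVD of the landmark cross-covariance, proper rotation enforced). Printed
models are 1:1, so scale estimation is off by default and available behind
`allow_scaling`. `surface_distance()` then measures, for every vertex of
the (transformed) query mesh, the closest distance to the reference
surface — a directed measure, recorded as such — and summarizes it as MAD,
STD and MAX with the vertex count and the registration RMS, the layout of
the printed-model validation table. Landmarks come from plain `x y z` text
files; anatomical choice of landmarks is user input.

## Problem sizes

The test suite runs the phantoms at 1.4–2.2 mm voxels and the fissure
phantom at 20 mm outer radius; the acceptance script regenerates the
default 44 mm phantom at 1 mm voxels and runs the full pipeline on it.
These sizes were chosen so the whole suite re-runs comfortably on a single
CPU while keeping every stage in its operating regime (separation
triggered, projections accepted and pruned, gaps deleted).

## Known limitations

* Solidification can fold over where two cortical walls lie closer together
  than `thickness`; the package warns (it does not fail), mirroring the
  known imprecision of thin iliac-fossa regions.
* Volumes are treated as axis-aligned; gantry-tilted or obliquely oriented
  acquisitions must be resampled upstream.
* The DICOM reader covers uncompressed little-endian single-frame CT
  series only.
* Component selection replaces manual editing; bones fused to their
  neighbours by bridging voxels above the threshold will need a seeded
  selection or a higher cutoff.
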