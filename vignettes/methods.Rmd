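---
title: "molcloud: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molcloud: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcloud)
```

This vignette documents the science behind each module, the conventions the
package commits to, and the places where a genuinely open design choice was
made — in enough detail that a user can decide whether those choices match
their data. It states no empirical result that the test suite does not
itself compute.

## The point-cloud data model

A molecule is a set of `N` points with `M` alternative conformations,
stored as an `M × N × 3` array in Å, plus an `N`-row metadata table.
Conformations are indexed **1-based**, the natural R convention; geometry
operations act on the `current` conformation (default: the first) unless
told otherwise. Units are Å everywhere; user-facing angles are degrees
(converted to radians internally).

Masses (Da) and van der Waals radii (Å) come from an internal table
covering H, C, N, O, S and P — the elements that dominate protein
structures. Anything else degrades gracefully to mass 0 and radius 1.7 Å
with a warning rather than failing, so nonstandard HETATM records do not
abort a pipeline; selections can always exclude them afterwards.

### Superposition

Optimal rigid superposition uses the SVD of the coordinate cross-covariance
with a determinant sign correction, so only proper rotations are returned.
A reflection can fit two mirror-image clouds exactly, but mirror fits are
physically meaningless for chiral biomolecules; the test suite verifies
with a brute-force rotation search that the returned proper-rotation fit of
a chiral cloud onto its mirror image is genuinely nonzero and still optimal
within the proper rotations sampled.

### RMSF reference

RMSF is computed about each point's **mean position** across all
conformations (the standard definition), not about the first conformation.
With two conformations separated by `d` this gives `d/2` per point. RMSD
and RMSF are unweighted by default; RMSD offers explicit mass weighting.
Per-point RMSF has no meaningful mass weighting and offers none.

## File formats

**PDB.** Fixed-column ATOM/HETATM records; MODEL/ENDMDL blocks become
conformations; ANISOU/CONECT are ignored. Alternate locations keep the
first encountered altLoc per atom (with a warning) — deterministic and
common practice. Insertion codes are kept in their own metadata column so
selections remain lossless. Coordinates are written at 3 decimals, which
bounds the round-trip error at 5×10⁻⁴ Å; coordinates ≥ 10⁴ Å cannot be
represented in the fixed columns and raise an overflow error rather than
writing a corrupt file.

**OpenDX.** Text "gridpositions / gridconnections" scalar fields with
axis-aligned voxels only; values are ordered with the last (z) axis varying
fastest. The `origin` is the **center of the first voxel** — the common
molecular convention. Off-by-half-voxel bugs are the main hazard when
exchanging maps between packages, which is why the convention is asserted
in the I/O tests (voxel `(i,j,k)` is centered at `origin + (i−1)·delta`).

## Density simulation and contouring

Each point contributes an isotropic 3D Gaussian. The kernel width
convention is

> σ = `sigma_per_resolution` × resolution, default 0.5 (σ = resolution/2).

There is no universal convention linking "resolution" to Gaussian width
(σ = R/2, R/(2√2) and Fourier-criterion variants are all in circulation),
so the factor is an explicit parameter of `kernel_spec()` rather than a
hidden constant; users matching maps simulated by other software should set
it accordingly. Kernels are normalised so the map integral (Σ values ×
voxel volume) equals the total amplitude — point masses by default, or 1
per point in uniform mode. The grid pads the bounding box by 3σ per side
and kernels are truncated at 4σ; the ±3σ truncation leaves ≥ 99% of each
kernel's weight inside the grid (erf bound), which is what the 1% integral
tolerance in the tests reflects. `voxel_size > resolution` is rejected as
undersampling.

Thresholding uses a **strictly greater-than** comparison everywhere
(`value > isovalue`), making voxel counts deterministic; voxels exactly at
the isovalue are excluded. One consequence, measured by the fixture tests:
contouring an analytic Gaussian blob at the isovalue that should enclose
the σ-sphere undershoots the continuum sphere volume by about 6% at
voxel = σ/4 (boundary voxels fall out of the strict comparison), within the
a-priori voxelization bound of surface area × half a voxel diagonal. Tests
therefore compare discrete volumes against a brute-force voxel-center
oracle exactly, and against continuum values only within that bound.

### Isovalue from mass

The contour level consistent with a protein's mass is found by targeting an
enclosed volume of mass × specific volume, with the specific volume
defaulting to **1.21 Å³/Da** (≈ 0.73 cm³/g, the standard protein partial
specific volume), configurable. The published resolution-dependent
correction to this volume is not reproduced here — the primary source for
this package does not specify it — so the resolution argument is accepted
and logged for provenance but only enters through the simulation kernel
when maps are generated in-package. This deviation is deliberate and
documented rather than guessed at. The search bisects over the sorted
unique voxel values and reports the achieved volume and its relative error,
so the quantization of the answer is always visible to the caller.

## Symmetric assembly

All five regular polyhedra are generated with centroid at the origin and
every edge scaled to the requested length (verified to 10⁻⁹); "deformable
scaffold" means the polyhedron can be rescaled freely while subunits stay
aligned to its vertices, which is how candidate assemblies at different
sizes are enumerated against experimental observables.

The vertex local frame is not dictated by the geometry, so the package
commits to a deterministic convention: **z points from the vertex toward
the scaffold centroid, x toward the lowest-index edge neighbour (projected
orthogonal to z), y completes a right-handed frame**. The lowest-index rule
also resolves the tie at symmetric vertices. Subunit orientations are
intrinsic z-y-z Euler angles in degrees, applied about the subunit
centroid, either per vertex or "in concert" (the same local rotation
everywhere). In-concert placement makes all copies mutually congruent,
which the tests verify by pairwise superposition.

Cyclic Cn multimers place copy *i* at angle 2πi/n on a circle and rotate it
by the same angle about z, so the flattened assembly has exact Cn symmetry
(rotating by 2π/n and cyclically permuting subunits reproduces it; asserted
for n = 2…8). Flattening remaps chain identifiers A, B, C, … (single
characters up to 62 subunits, then two-character identifiers with a
warning) and conserves point count and mass exactly.

Super-coarse-grained generators: ellipsoid surfaces use Fibonacci-sphere
points scaled by the semiaxes — fast and quasi-uniform on the sphere, with
a known mild density distortion on strongly elongated ellipsoids that is
accepted and documented rather than corrected; volume sampling is seeded
rejection sampling, uniform by construction. Sphere chains space centers at
2r(1 − overlap), the standard overlapping-sphere parameterisation of a
linear chain of globular subunits.

## Collision cross section

CCS is computed by the **projection approximation**: the mean over
uniformly random orientations (normalised Gaussian quaternions, seeded) of
the projected shadow area of the union of atom+probe disks, rasterised on a
2D grid of `raster` Å (default 0.2; counting cells whose center falls in a
disk). The PA is self-contained and dependency-free but systematically
underestimates trajectory-method CCS for large molecules because it ignores
multiple scattering; a multiplicative `calibration` factor (default 1.0) is
exposed so users can match published scales. The standard error of the
mean over orientations is attached to every result. Default probes: 1.0 Å
for CCS (helium-like), 1.4 Å for SASA and lattice accessibility (water);
every run logs its resolved parameters.

SASA is Shrake–Rupley with a deterministic golden-spiral point set, so an
isolated atom's area is exactly 4π(r + probe)² and results are
reproducible without a seed.

## Solvent-accessible paths

A cubic lattice (default spacing 1 Å, margin 10 Å) is laid over the
structure; a node is accessible iff its distance to every atom is at least
vdw + probe. Accessible nodes are 26-connected with Euclidean edge weights
and shortest paths are computed with Dijkstra's algorithm (via igraph; an
independent exhaustive Dijkstra oracle in the test suite confirms
optimality exactly on small lattices). Endpoints snap to the nearest
accessible node within `snap_cutoff` (default 5 Å), ties broken by lattice
node index; equal-length path ties inside the graph search follow igraph's
deterministic traversal, which is stable for a fixed graph. A buried
endpoint and a disconnected endpoint pair raise distinct errors — the
latter is precisely the "infeasible cross-link" verdict.

Two geometric facts shape the tests. First, a 26-connected lattice path can
exceed the Euclidean distance by up to ≈ 12.8% in the worst direction; for
generic oblique directions such as (3,2,2) the overhead is under 9%, which
is the bound the free-space tests use. Second, path length is
non-increasing as the probe shrinks *only under identical endpoint
snapping* (shrinking the probe grows the accessible set), so the
monotonicity test constructs endpoints whose snapped nodes are provably
identical across the probe sweep. The lattice spacing, probe and snapping
defaults are engineering choices of this package, not values taken from a
published protocol, and should be reported alongside any derived
cross-link feasibility claim.

## Synthetic data

The fixture generators produce everything the test surface needs, with all
randomness flowing through explicit seeds and no global RNG state touched.
`make_toy_polymer()` emulates the *scale* of protein geometry — 1.5 Å
helical rise with 100° twist per residue on a 2.3 Å radius, or 3.8 Å
virtual-bond steps — but none of its chemistry: no bonds, rotamers,
sequence or packing. A green test on these fixtures establishes that the
geometric and numerical machinery is correct at protein-like length scales;
it does not establish accuracy against experimental CCS, SASA or
cross-link data for real proteins. `make_gaussian_blob_map()` is analytic,
which is what makes the density inverse problems exactly checkable.

## Known limitations

- PA-CCS needs external calibration to compare with trajectory-method or
  experimental values.
- Density maps are axis-aligned; no skewed cells, no MRC/CCP4 I/O, no
  Fourier-space sharpening.
- The lattice path is a lower bound on cross-linker span; it models no
  linker flexibility or statistics.
- No torsion-space manipulation, trajectory streaming or periodic boundary
  handling; assemblies are built, not scored against experimental data.
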