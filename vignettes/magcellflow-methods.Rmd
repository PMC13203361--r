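---
title: "Modeling remote magnetic guidance of SPION-magnetized cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling remote magnetic guidance of SPION-magnetized cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`magcellflow` models a microfluidic assay for the remote magnetic control of
living cells loaded with superparamagnetic iron oxide nanoparticles
(SPIONs): a dilute suspension of magnetized cells flows through a shallow
rectangular chamber while a cylindrical permanent magnet beside the chamber
pulls the fluorescent cell plume sideways. The package provides the forward
physics (field, force balance, plume transport), a synthetic
fluorescence-video generator with ground-truth masks, a classical
segmentation/descriptor pipeline, and an inverse calibration that turns a
measured lateral deflection back into an estimated SPION loading per cell.
This vignette documents the model, its assumptions, the tunable parameters,
and the design decisions that were genuinely open.

## The physical model

**Magnet field.** The magnet is an axially magnetized cylinder (diameter and
height 10 mm, remanence $B_r = 1.3$ T by default) with its axis in the
chamber mid-plane, perpendicular to the flow. Outside the magnet the field
is computed from the equivalent two-disk magnetic-charge model: surface
charge $\pm B_r/\mu_0$ on the end faces, integrated by Gauss–Legendre
quadrature in the squared radius and a midpoint rule in azimuth (32 nodes
each by default). The closed-form on-axis expression
$$B_z(z) = \frac{B_r}{2}\!\left[\frac{z+L}{\sqrt{(z+L)^2+R^2}} -
\frac{z}{\sqrt{z^2+R^2}}\right]$$
is kept as an independent oracle; the quadrature agrees with it to better
than $10^{-6}$ relative for $z \in [1, 50]$ mm and with the point-dipole
limit to 1% beyond ten magnet diameters. An exact axisymmetric evaluation
would need complete elliptic integrals; the quadrature is simpler to verify
and amply accurate at chamber distances (at least 5 mm from the near face).
$\nabla|B|$ is obtained by central differences with a step of
$\min(0.1\,\mathrm{mm}, h/2)$ for grid spacing $h$; the medium (an aqueous
physiological solution) is non-magnetic, so $\nabla|B| = \mu_0\nabla|H|$.
Whether the north face points at the chamber is irrelevant — only $|H|$ and
$\nabla|H|$ enter the force — so the sign convention (magnetization toward
the chamber) is arbitrary and documented here.

**Cell magnetization.** All of a cell's internalized magnetic material is
treated as one equivalent sphere of diameter $d_\mathrm{mag}$ conserving the
total core volume: $d_\mathrm{mag} = d_\mathrm{core} N^{1/3}$ with
$d_\mathrm{core} = 10$ nm, so $10^6$ SPIONs correspond to 1.0 µm and
$4 \times 10^6$ to 1.6 µm. The particle magnetization that multiplies
$\nabla|H|$ in the force law is dimensionally a magnetic moment; it is
implemented as the saturated moment $m = M_s \frac{\pi}{6} d_\mathrm{mag}^3$
with $M_s = 4.8 \times 10^5$ A/m (bulk magnetite) by default. Near a 1.3 T
magnet the cores are essentially saturated, so no field-dependent
(Langevin) magnetization is modeled; $M_s$ is exposed in the configuration
for sensitivity work.

**Force balance.** Magnetophoresis against Stokes drag,
$\vec F_\mathrm{mag} + \vec F_\mathrm{drag} = 0$ with
$\vec F_\mathrm{mag} = m \nabla|B|$ and
$\vec F_\mathrm{drag} = -6\pi\eta r_p(\vec v_p - \vec v_f)$, gives the
terminal cell velocity
$\vec v_p = \vec v_f + \vec F_\mathrm{mag}/(6\pi\eta r_p)$. The drag radius
$r_p$ is the hydrodynamic cell radius (5 µm), not the magnetic-sphere
radius. Buoyancy is ignored: the analysis concerns the horizontal
projection of the motion. At the flow axis (12 mm from the magnet face) the
slip is about 0.06 mm/s for $d_\mathrm{mag} = 1.6$ µm — commensurate with
the 0.2–0.5 mm/s working flow speeds, which is what makes the deflection
controllable by either knob.

**Plume transport.** The chamber (32 × 14 mm, 175 µm high) is reduced to
its 2-D mid-plane with uniform plug flow $(dU_x, 0)$; the camera sees the
depth-averaged horizontal behavior, and the height is kept as metadata
only. Cell concentration obeys an advection–diffusion equation with the
magnetophoretic velocity field, solved by a conservative first-order upwind
finite-volume scheme with explicit central diffusion (positivity-preserving
and easy to verify against a method-of-characteristics oracle). Boundary
conditions: Dirichlet $c = 1$ mol/m³ on a 2 mm inlet band centred on the
flow axis (the multi-channel inlet manifold of the physical chip is not
modeled geometrically), upwind outflow at the far end, no-flux side walls.
Mass bookkeeping (change per step vs. influx − outflux) closes to machine
precision and is asserted at $10^{-6}$ relative in the tests.

Because the slip field converges into the magnet-side wall and the walls
are no-flux, concentration near that wall exceeds the inlet value — this
accumulation zone is the quantity of interest in the magnet-repositioning
study, so no upper bound on $c$ is imposed (a bound at the inlet value
holds, and is tested, only for divergence-free plug-flow transport).

**Lagrangian twin.** Single-cell trajectories integrate
$\dot{\vec x} = \vec v_p(\vec x)$ with fixed-step classical Runge–Kutta and
bilinear velocity interpolation. The plume ridge and a trajectory released
at the plume centre agree within one grid cell at the magnet station; this
Euler–Lagrange consistency is a standing test.

## Numerical parameters

| Parameter | Default | Why |
|---|---|---|
| Grid spacing $h$ | 0.1 mm (0.2 mm in tests/acceptance) | resolves the 2 mm plume; halving $h$ changes the station drift by < 3% |
| Time step | $0.5\times$ the advective–diffusive stability bound | explicit scheme; a user `dt` above the bound is rejected naming the admissible value |
| Transient length | 180 s | the 0–3 min observation window of the recordings; the plume is established at the magnet station (x = 25 mm) from ~125 s at 0.2 mm/s |
| Effective diffusivity $D$ | $10^{-10}$ m²/s | regularization and plume-width realism; the Stokes–Einstein value for a 10 µm cell is orders of magnitude smaller, and the plume width is insensitive to $D$ well below the advective scale |
| Quadrature order | 32 × 32 per disk | $10^{-9}$ relative on-axis error at 1 mm; cost is amortized by caching the field grid per placement |

The choice of a *fixed finite* transient matters for the accumulation
measurements: with the default saturated-moment slip the backward (upstream)
slip along the wall never exceeds $dU_x$, so the wall pile has no stagnation
point and creeps slowly toward the outlet. At the 3-minute mark the pile
sits near the magnet and tracks magnet repositioning almost 1:1; run far
past the observation window it saturates against the outlet and the
Eulerian centroid stops responding. The Lagrangian wall-arrival point
tracks a 1 mm magnet shift at 0.99:1 at any time. A related geometric
limitation: when the magnet is placed within a couple of millimetres of the
outlet (the 5 mm repositioning case), the accumulation centroid is clipped
by the chamber end and its transmission ratio is bounded near 0.4 however
strong the coupling: in that configuration the accumulation zone is simply
squeezed into the chamber end.

## Synthetic videos

The generator renders concentration snapshots into fluorescence-like
frames: bilinear resampling to the pixel grid, intensity
$\mathrm{background} + \mathrm{gain}\cdot c$, Poisson shot noise, Gaussian
read noise (sd 50 counts), clipping to 16 bits. Defaults: 22.5 × 12 mm²
field of view at 50 px/mm, placed flush against the magnet-side wall (the
region of most pronounced magnetic displacement), 50 fps capability with
analysis frames on a ~30 s cadence across the 3-minute transient. The gain
(1500 counts per mol/m³) keeps the full accumulation range ($c$ up to ~40)
inside the 16-bit range so the response stays linear at high loadings.
Reported acquisition geometries for this assay are mutually inconsistent
(a ~100 × 100 pixel field versus fixed 22.5 × 12 mm² frames); both are
expressible through the camera model, and the frame-extent description is
the default. Ground-truth masks are pixels whose
noiseless signal exceeds 10% of the gain; they are independent of the noise
realization, which the tests assert.

The generator emulates: plume geometry and motion, shot/read noise,
background offset, saturation. It does not emulate: optical PSF blur,
photobleaching, focus drift, cell-to-cell loading heterogeneity, flow
pulsation, or annotation error. Passing recovery tests therefore show the
pipeline is consistent and noise-robust under these conditions, not that it
reproduces the accuracy attainable (or the failure modes present) on real
recordings.

## Segmentation and descriptors

Segmentation is a pluggable contract (`frame -> binary mask`,
deterministic). The trained neural segmentation of the original workflow
cannot be rebuilt without its recordings, so the default backend is
classical: threshold at 10% of the robust peak signal (0.999 quantile)
above the median background, then the largest connected component. Two
design decisions deserve a note:

* **Fraction-of-peak rather than Otsu.** On fluorescence frames where
  background vastly outnumbers foreground, the Otsu split lands inside the
  plume's intensity ramp (IoU ≈ 0.78 against the ground-truth masks and a
  ~3-pixel centroid bias); the 10%-of-peak rule matches the ground-truth
  convention (IoU ≈ 0.9996 noiseless, ≈ 0.97 at default noise). An Otsu
  backend remains available (`otsu_backend()`), and both are invariant to a
  constant intensity offset.
* **Intensity-weighted centroids.** Fluorescence intensity is proportional
  to concentration, so the intensity-weighted centroid inside the mask is
  the pixel-space twin of the concentration-weighted centroid the transport
  module reports; plain binary centroids of the skewed deflected plume are
  several pixels biased. Binary weighting is available as an option.

Descriptors per frame: centroid (px and mm), signed lateral drift toward
the magnet relative to a reference (the no-field run when available,
otherwise the mean of the first three frames, taken before appreciable
deviation), deflection angle $\arctan(\mathrm{drift}/x)$ from the drift and
the downstream centroid distance (a mask principal-axis angle would measure
plume shape rather than displacement), mask area, and centroid displacement
rate. Quality control excludes frames with mask area below the minimum
observed flow area, centroid discontinuity larger than one channel width
(default 2 mm, the inlet-band width — the source does not define the width
numerically) between consecutive valid frames, or IoU against ground truth
below an optional threshold; no default is claimed for that threshold on
frames without ground truth, since none is defined for real data.
Summaries report mean, SD and coefficient of variation per descriptor, per
replicate and pooled.

For drift *measurement* (as opposed to general descriptor extraction) the
analysis is restricted to a narrow region of interest around the
magnet-axis station, mirroring the fixed station at which the calibration
records its deflections; the minimum-area floor there is pixel-count-based
(50 px) because noise-speckle component size scales with pixels, not
physical area.

## Inverse calibration

The calibration maps loading to simulated station drift on a grid of
$\{10^4, 10^5, 5\times10^5, 10^6, 5\times10^6\}$ SPIONs/cell with a
monotone (Hyman-filtered) cubic interpolant in $\log_{10}$ loading —
loadings span three decades, and monotonicity is a modeling assumption the
build step enforces (non-monotone simulated drifts abort with an error,
since they signal a broken scenario). The grid extends one decade below the
lowest studied loading so that noisy measurements at $10^5$ are inverted
rather than pinned to the grid floor. Estimation inverts the curve by root
finding ($10^{-9}$ round-trip accuracy in log-loading); drifts outside the
curve range are clipped to the range ends and flagged. Estimates below
$10^5$ SPIONs/cell are flagged not reliable — below that threshold the
magnetic displacement approaches the detection limit set by noise and flow
variability. A forward-fit mode (minimize $|d_\mathrm{sim}(L) -
d_\mathrm{meas}|$ over $L$, with a pluggable forward model) is provided as
a cross-check of simulation-based estimation; how the original
simulation-column estimates were fitted is not documented, so this mode is
a stand-in, not a claim of equivalence.

The recovery study closes the loop: simulate at a nominal loading, render
with noise, measure, invert, and report the approximation error
$(\mathrm{est} - \mathrm{nom})/\mathrm{nom} \times 100\%$ (magnitudes
reported, signed values retained). With default noise and five seeds the
mean error is ≈ 0% at $5\times10^6$ (drift above the curve ceiling), 2–3%
at $10^6$, 3–5% at $5\times10^5$ and ~7% at $10^5$, growing monotonically
as loading decreases; at $10^4$ and below the outputs are flagged
non-applicable. These numbers characterize the synthetic pipeline only —
real-video errors are dominated by effects the generator does not model.

## Problem sizes

The package defaults (0.1 mm grid, 180 s transient, 50 px/mm camera) are
used for analysis runs. The test suite and the acceptance script run the
same scenarios on a 0.2 mm grid with the same transient — the station
drifts change by under 3% between the two spacings, which the grid
convergence test asserts — and the recovery study uses five noise seeds per
loading.

## Known limitations

* Single magnet, mid-plane 2-D, plug flow: no z-resolved profile, no
  multi-magnet arrays, no turbulence or pump pulsation.
* No cell–cell magnetic interaction, chaining, sedimentation, or
  cytoskeletal mechanics; the saturated-moment model ignores the
  magnetization curve.
* The accumulation-centroid transmission measure is meaningful within the
  finite observation window and away from the outlet (see above).
* The segmentation default is tuned to the generator's own ground-truth
  convention; a learned backend should be plugged in for real recordings,
  and segmentation scores reported for learned models on real recordings
  cannot be reproduced without those recordings.
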