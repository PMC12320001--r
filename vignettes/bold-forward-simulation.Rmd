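---
title: "Forward modelling of BOLD-type signal decay with boldsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modelling of BOLD-type signal decay with boldsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldsim)
```

## The model

The transverse MRI signal of a tissue voxel decays faster when the voxel
contains magnetic-susceptibility perturbers — deoxygenated blood vessels,
myelinated axons, iron-laden cells, contrast microspheres. Each perturber
with susceptibility difference $\Delta\chi$ distorts the local field $B_0$
by a dipole pattern; diffusing water spins accumulate phase
$\Delta\Phi = \gamma\,\Delta B_z\,\Delta t$ in that inhomogeneous field, and
the voxel signal is the magnitude of the summed transverse magnetization,
$S_j = |\sum_i M_{xy,j}(p_i)|$. `boldsim` simulates this chain end to end,
so that the susceptibility-attributable relaxation rates
$\Delta R_2$ (spin echo), $\Delta R_2^*$ (gradient echo) and their
difference $\Delta R_2' = \Delta R_2^* - \Delta R_2$ can be predicted from
the microstructure.

A simulation method is assembled from independent choices, named by a
hyphenated selector such as `3D-CTN-CYL-ANA-MC`:

* **Dimensionality** — `2D` (a plane through the voxel) or `3D`. 2D voxels
  with randomly *oriented effective field directions* per cylinder reproduce
  the field-offset statistics of randomly oriented 3D cylinders at a
  fraction of the cost.
* **Space** — `CTN` continuous (analytic geometry, field evaluated at exact
  positions) or `GRD` gridded ($N$ elements per side, element centers at
  $(i + \tfrac12)W/N$).
* **Perturber** — `CYL` infinite cylinders, `SPH` spheres (3D only, no
  orientation, zero internal field), or `VAN` a custom discretized label
  mask supplied by the user.
* **Field** — `ANA` closed-form dipole expressions, or `FFT` convolution
  with the spatial-domain dipole kernel
  $G(\mathbf r) = \frac{1}{4\pi}\frac{3z^2 - r^2}{r^5}$ (zeroed at
  $r = 0$).
* **Diffusion** — `MC` Monte Carlo random walks in continuous space, or
  `DD` deterministic convolution of the magnetization grid with a diffusion
  kernel (2D gridded only).

Compatibility rules are enforced by `parse_method_name()`: FFT needs a 3D
gridded voxel, custom masks need FFT, DD needs a 2D gridded voxel, spheres
need 3D.

## Field calculation

For a cylinder at angle $\theta$ to the field, the offset is
$B_0\Delta\chi\,(3\cos^2\theta - 1)/6$ inside and
$B_0\Delta\chi\,(R/r)^2\cos(2\varphi)\sin^2\theta / 2$ outside; for a
sphere, $0$ inside and $B_0\Delta\chi\,(R/r)^3(3\cos^2\theta - 1)/3$
outside. Multi-perturber fields are exact superpositions. $\Delta\chi$ is
dimensionless SI; literature ppm-cgs values convert via
`ppm_cgs_to_si()` ($\chi_{SI} = 4\pi\chi_{cgs}$), e.g. 0.3 ppm cgs for
deoxygenated blood and $-0.15$ ppm cgs for myelin.

The FFT path computes
$\Delta B_z = \mathcal F^{-1}\{\mathcal F\{\chi\}\,\mathcal F\{G\}\}B_0$
on a zero-padded grid. Three numerical choices matter:

* **Padding.** A kernel of width $M$ acting on an $N$-wide map needs
  $N + M - 1$ padded width to avoid wrap-around; that is the `pad = "full"`
  default. `pad = 0` deliberately keeps the circular wrap, emulating a
  voxel surrounded by copies of itself.
* **Kernel periodization.** Along a `pad = 0` axis the sources are
  effectively tiled, so the kernel is summed over the corresponding
  periodic images. Without this the kernel truncates the dipole tail: a
  through-voxel cylinder's interior field came out ~9% low in our tests;
  with periodization, interior agreement with the closed form is at the
  percent level. A cylinder along a periodic axis thereby becomes *exactly*
  infinite.
* **The zero-frequency term** is whatever the FFT of the spatial kernel
  yields; no analytic override is applied. Lorentz-correction conventions
  differ between toolchains, so all validation is against the analytic
  oracle rather than absolute constants.
* **Partial-volume maps.** Binary center-containment voxelization leaves a
  jagged boundary whose spurious dipoles dominate the near-surface error
  (~12% at two elements from a sphere's surface, independent of radius).
  `discretize_voxel(..., subsample = s)` averages the susceptibility over
  $s^{ndim}$ subpoints per element; with $s = 4$ the maximum interior error
  drops to ~1%. Labels (compartments, walls) remain center-based.

We recommend at least 6 grid elements across the smallest perturber's
diameter; `check_sampling()` warns otherwise.

## Diffusion

**Monte Carlo.** Spin positions are continuous regardless of the voxel
representation. Per step, each axis displacement is drawn from
$\mathcal N(0,\, 2D\Delta t)$; positions wrap periodically onto $[0, W)$.
A step whose endpoint lies in a different compartment is a wall crossing:
permeation succeeds with the wall's permeation probability (one Bernoulli
draw per attempted crossing), otherwise steps are redrawn until one stays
in the starting compartment (cap 100, then the spin rests for that step;
occurrences are counted). Wall crossing is detected by comparing endpoint
compartment labels — sub-step chord excursions that re-enter within one
step are ignored, which is consistent at the recommended step sizes. For a
direct perturber-to-perturber transition inside overlapping geometry the
crossing probability is the minimum of the two walls' values. The field is
sampled at the step's endpoint.

**Deterministic diffusion** replaces the walkers by one transverse/
longitudinal magnetization value per grid element; each step convolves the
grids with a separable 1D kernel (applied along both axes, equivalent to
the 2D product kernel) under periodic boundary conditions. Two kernels are
provided: a sampled Gaussian with $\sigma = \sqrt{2D\Delta t}$, and the
lattice-exact discrete analogue $D_k = e^{-t} I_{k - N_{hw}}(t)$ with
$t = (\sigma/\Delta x)^2$, whose untruncated sum is exactly 1. Both are
renormalized to unit sum after truncation — conservation takes precedence
over matching the continuous tail. The printed Gaussian form we started
from lacked a negative sign in the exponent; a Gaussian requires it and the
implementation uses $\exp(-x^2/2\sigma^2)$. The default half-width spans
$\max(5, \lceil 3.5\sigma/\Delta x\rceil)$ elements, so a well-resolved
kernel has at least 11 taps.

Impermeable perturbers are handled by a per-step correction that returns
any kernel weight crossing the EV/IV tissue boundary to its source element:
for $p$ in class $c$,
$M'(p) = \mathrm{conv}(M\,\mathbb 1_c)(p) + M(p)\,\mathrm{conv}(\mathbb 1_{\bar c})(p)$,
which conserves each class's total exactly (to $10^{-12}$ per step in the
tests). Only fully permeable or fully impermeable walls exist in this
backend; intermediate probabilities are rejected.

**The under-resolution hazard.** The kernel width in elements is
$\sigma/\Delta x$. Holding $N$ fixed while the voxel (and vasculature)
grows shrinks the kernel toward a delta: `kernel_effective_length()` drops
to 1–3 and the apparent diffusion effect silently vanishes — the spin-echo
$\Delta R_2$ collapses toward its static-dephasing value of zero. The only
remedy is to scale $N$ with $W$. Monte Carlo is immune because its
positions are continuous.

## Sequences and signal

RF pulses are hard rotations by flip angle $\alpha$ about an axis given in
polar coordinates (x-pulse: $(\pi/2, 0)$; y-pulse: $(\pi/2, \pi/2)$),
right-hand rule. A pulse scheduled at step $j$ acts at time $j\Delta t$,
after that step's diffusion/precession update and just before the signal is
read out. This convention makes a refocusing pulse at step $TE/2/\Delta t$
split the phase history exactly in half, so a spin echo with $D = 0$
refocuses to machine precision — the defining property of the static
dephasing regime. `build_sequence()` provides GE (90°x), SE (+180°y at
$TE/2$) and ASE (refocusing displaced by `tau_shift`); arbitrary pulse
trains go through `custom_sequence()`.

Between pulses the update is
$M_{xy} \leftarrow M_{xy}\,e^{i\gamma\Delta B_z\Delta t}\,e^{-\Delta t/T_2(p)}$,
with per-compartment $T_2$ resolved from the current label (spins that
permeate change relaxation environment). Longitudinal magnetization relaxes
as $M_z \leftarrow 1 + (M_z - 1)e^{-\Delta t/T_1(p)}$; the printed source
form $[e^{-\Delta t/T_1} - 1]$ cannot relax toward equilibrium and is
treated as a typo. Absent relaxation times mean no decay, and there is no
hidden blood-$T_2$ default — intravascular relaxation must be configured
explicitly.

## Rate analysis

`compute_dr2()` uses the single-echo-time estimator
$-\ln(|S_{pert}|/|S_{ref}|)/TE$, where the reference is the same simulation
with $\Delta\chi = 0$ (same seed, same geometry), so that everything except
the susceptibility effect cancels exactly. A multi-TE fit is out of scope.
`radius_sweep()` regenerates fresh voxels per radius at fixed CBV — the
voxel width is scaled to keep the perturber count roughly constant — and
reports per-repeat and aggregated GE/SE/$\Delta R_2'$ rates. The
characteristic result is the Boxerman-style curve: SE rates peak at
capillary-scale radii (diffusion narrowing) while GE rates rise to a
static-dephasing plateau.

## Random geometry generation

Perturbers are added one at a time until the Monte-Carlo-estimated union
volume fraction (a fixed cloud of $10^5$ test points) first reaches the
target CBV; the realization closer to the target (with or without the last
perturber) is kept, and a >10% relative miss is an error rather than a
silent bias. 3D cylinder axes are uniform on the sphere and pass through a
uniform point in the enclosing sphere of radius $W\sqrt3/2$ — a stated
choice, since the cited generation procedure is not restated in our source
material — which gives a uniformly distributed CBV across the voxel. 2D
cylinders draw $\cos\theta$ uniform on $[-1, 1]$, matching the angle
distribution between a fixed field and uniformly random 3D axes. Overlap is
allowed (union CBV semantics); every generator is a pure function of its
seed.

## What the synthetic fixtures emulate

`make_fixture()` provides deterministic study voxels:

* `gm_cylinders_2d`: cortical grey matter — 1 µm-radius cylinders at
  CBV 0.02, blood $\Delta\chi$ 0.3 ppm cgs, $D = 10^{-3}$ mm²/s, SE
  $TE = 70$ ms. We chose $W = 0.1$ mm (about 64 vessels) and a gridded
  default of $N = 400$, i.e. 8 elements across a vessel diameter — the
  6-element minimum with margin; $\Delta t = 0.2$ ms keeps
  $\sigma/\Delta x = 2.5$ so the DD kernel spans 19 taps.
* `wm_axons_2d`: a toy white-matter bundle — jittered-hexagonal
  hard-circle packing, diameters 0.4–3.5 µm, myelin $-0.15$ ppm cgs,
  axon volume fraction targeting 0.5 (an override with that documented
  default, since no value is stated in our source material), plus 1% CBV
  vessels with random effective field directions. This replaces an external
  axon-packing tool; externally generated packings import via the
  `cylinder2d` CSV. It reproduces the character, not the statistics, of
  real bundles (no g-ratio or sheath substructure).
* `single_cylinder_3d` / `single_sphere_3d`: the analytic oracles for the
  FFT path.
* `toy_mask_3d`: a minimal custom mask exercising the VAN pipeline.

What passing tests on these fixtures do **not** show: real microvascular
trees branch and curve, axon packings are denser and correlated, and blood
$\Delta\chi$ varies with oxygenation along the vascular tree. The fixtures
validate the numerics, not the biology.

## Numerical choices and degenerate inputs

* Element centers at $(i + \tfrac12)W/N$, voxel spans $[0, W)$, matching
  the periodic wrap.
* Containment uses $r \le R$ for labels/walls; the field expressions use
  the outside form at exactly $r = R$ (continuous there).
* The one-step pulse-ordering question (RF before vs after the step's
  evolution) was resolved in favour of after, which is the only ordering
  consistent with both a refocusing pulse at step $TE/2/\Delta t$ and exact
  static-dephasing refocusing; the alternatives differ by $O(\Delta t)$.
* DD relaxation/precession is applied after the convolution within each
  step (same $O(\Delta t)$ equivalence class as relax-then-diffuse), kept
  identical to the MC ordering so the two backends agree exactly at
  $D = 0$.
* $D = 0$ skips motion and caches the static field; $\Delta\chi = 0$
  short-circuits the field to zero by linearity.
* A perturber smaller than a grid element discretizes to nothing — a
  warning, not an error.
* Seeds: one user seed per run, expanded into per-component child streams
  (geometry, placement, walk) so adding a component does not perturb the
  others.

## Problem sizes used in the shipped checks

The validation suite runs at desk scale, chosen as the smallest sizes whose
statistical power supports each claim: $10^4$–$10^5$ Monte Carlo spins,
$N = 64$–$128$ FFT grids, the $N = 400$ grey-matter grid, ten-seed
cross-method comparisons, and six-radius sweeps at 3000 spins. The physics
does not change at larger sizes; dispersions shrink as
$1/\sqrt{N_{spins}}$ (verified in the tests).

## Known limitations

2D-only deterministic diffusion; no intermediate permeability in DD; no
flow/advection, slice profiles, $B_1$ inhomogeneity or imaging/diffusion
gradient waveforms; no background macroscopic gradients, chemical exchange
or Lorentz-correction variants; spheres have no 2D variant. Custom masks
rely entirely on the quality of the supplied labels — the FFT field is then
the only field option, and no analytic inside-term is added for them.

## A worked example

```{r example, eval = FALSE}
fx <- make_fixture("gm_cylinders_2d", seed = 1)
seq_se <- build_sequence("SE", te = fx$config$te, dt = fx$config$dt)
cfg <- sim_config("2D-CTN-CYL-ANA-MC", fx$spec, seq_se,
                  perturbers = fx$perturbers, D = fx$config$D,
                  nspins = 10000, seed = 1)
sig <- run_simulation(cfg)
ref <- fx$perturbers; ref$dchi <- 0
sig0 <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", fx$spec, seq_se,
                                  perturbers = ref, D = fx$config$D,
                                  nspins = 10000, seed = 1))
signal_dr2(sig, sig0)  # delta-R2 (SE) in 1/s
plot(sig)
```
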