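---
title: "Quantitative transmission ultrasound tomography with paraxtomo: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paraxtomo methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paraxtomo)
```

## The imaging problem

Transmission ultrasound tomography rotates a plane-wave source and an
opposing receiver array around the object in a water bath, records the
transmitted complex field at a ladder of working frequencies, and estimates
two quantitative tissue maps: the speed of sound $c(\mathbf{x})$ (m/s) and
the attenuation slope (dB m$^{-1}$ MHz$^{-1}$). Both are carried by the
complex *object function*

$$\gamma(\mathbf{x}) \;=\; \Big(\frac{c_0}{c(\mathbf{x})} - 1\Big)
  \;-\; i\,\frac{\alpha_{dB}(\mathbf{x})}{f_j}\,
  \frac{c_0}{2\pi \cdot 8.686},$$

where $c_0$ is the water-bath speed, $\alpha_{dB}$ the attenuation in dB/m
at the working frequency $f_j$, and $8.686 = 20/\ln 10$ converts nepers to
decibels. Under the $e^{-i\omega t}$ time convention used throughout,
non-negative attenuation means $\mathrm{Im}\,\gamma \le 0$ and forward
propagation decays. Attenuation is stored as a slope and assumed linear in
frequency, so $\alpha_{dB}$ at $f_j$ is the slope times $f_j$ in MHz; a
consequence worth noting is that $\mathrm{Im}\,\gamma$ is then the same at
every working frequency, which is what makes warm-starting across
frequencies trivial (see below).

Soft tissues differ from water by roughly $\pm 10\%$ in speed; bone is the
stress case, with a cortical shell near twice the water speed and a large
impedance mismatch that historically wrecks transmission reconstructions of
everything around it.

## Forward model: one-way split-step marching

The forward engine (`propagate()`, `simulate_dataset()`) assumes the
dominant part of the field travels forward along the source-receiver axis
and marches a transverse complex field slab by slab: per slab of thickness
$\Delta z$ a spectral diffraction operator, then the thin phase screen
$\exp(-i k_0 \gamma \Delta z)$, with $k_0 = \omega/c_0$. Design choices:

* **Wide-angle spectral step** (default): phase
  $\exp(-i\Delta z\sqrt{k_0^2 - |k_t|^2})$ for propagating components;
  evanescent components ($|k_t| > k_0$) get a decaying real exponential
  rather than truncation, keeping the operator continuous. A Fresnel
  (parabolic) variant is retained because Gaussian-beam diffraction has a
  closed form there, which the tests use as an oracle.
* **Strang (symmetric) splitting** (default): half screen, diffraction,
  half screen. This is second-order accurate in $\Delta z$; the test suite
  asserts that halving the axial step changes receiver data by well under
  0.5% RMS on the standard phantom. First-order splitting is available as a
  config option.
* **View handling**: for a view at azimuth $\theta$ the *medium* is rotated
  into a fixed source-to-receiver frame by bilinear resampling, keeping the
  propagation axis grid-aligned. The resampling operator has an exact
  adjoint (weight scatter), which the gradient uses.
* **Absorbing boundary**: the transverse grid is zero-padded and an
  absorbing layer with a raised-cosine absorption *profile per metre* is
  applied as $\exp(-\sigma(y)\,\Delta z)$ each slab. Because the profile is
  physical (units 1/m over a physical width), the absorption is invariant
  under grid refinement — specifying the window as a per-slab amplitude
  mask instead couples the boundary to the discretization and shows up as a
  percent-level data inconsistency between grids. For the same reason,
  simulations on a $2\times$ finer grid must scale the `pad`/`taper` voxel
  counts by two to hold the physical margin fixed; the reference
  experiments do this.
* **Sampling guard**: grids coarser than 4 points per wavelength in water
  are rejected, never silently accepted.

Receiver records are bilinear samples of the exit-plane field at the
element centres, row-major, giving the complex vector of length
$N_R = \text{rows}\times\text{cols}$ per (frequency, view, level).

## Inversion: adjoint-state Polak–Ribière NCG with frequency hopping

The objective is the L2 data misfit
$J(\gamma) = \tfrac12\sum_{f,\theta,l}\lVert \hat d(\gamma) - d \rVert^2$
over all views and levels at the working frequency. The unknowns are
$\mathrm{Re}\,\gamma$ and $\mathrm{Im}\,\gamma$ jointly (a flag freezes the
imaginary part for SOS-only studies). The gradient is assembled as the
Wirtinger derivative with respect to $\bar\gamma$ and exposed as the two
real fields.

One accepted NCG iteration costs exactly **five forward-problem
equivalents**: two for the gradient (stored forward march plus
reverse-marched adjoint, correlated slab by slab), two for the Jacobian
(tangent march alongside a forward march), and one residual check of the
candidate. The step length is the single exact minimizer of the quadratic
model, $\alpha = -\langle g, d\rangle / \lVert J d\rVert^2$ — no multi-point
line search — which is what makes the five-solve budget exact; a candidate
that fails to decrease $J$ is halved (each re-check adds one solve) and
repeated failure ends the stage. $\beta_{PR}$ is clipped at zero and a
steepest-descent restart fires every 20 iterations by default; the restart
period is configurable because on a nearly quadratic problem (the
linearized-data test) periodic restarts destroy the finite-termination
property of conjugate gradients.

Both the tangent and adjoint marches reuse the forward operators and the
exact adjoint of the view rotation, so the adjoint identity
$\langle J\delta\gamma, w\rangle = \langle \delta\gamma, J^{T}w\rangle$
holds to near machine precision; the suite asserts it at $10^{-8}$ along
with central finite-difference checks at $10^{-4}$ in 2D and 3D.

**Frequency hopping.** Reconstruction starts from a time-of-flight
estimate at the lowest frequency (0.35 MHz by default) and walks up the
ladder, warm-starting each stage from the previous image. The state is
carried between stages as the physical $(c, \text{slope})$ volumes and
re-encoded into $\gamma$ at each stage's frequency; with the slope
convention above this makes the imaginary part frequency-consistent by
construction and avoids any ad hoc rescaling. Per-stage iteration budgets
default to 15 at 0.35 MHz, 10 at 0.4–0.8 MHz and 5 at 0.9–1.3 MHz —
weighting the low frequencies where the basin of attraction is widest; the
right schedule is an open research question and everything is
configurable. There is no explicit regularization: the ladder itself is
the implicit regularizer (a Tikhonov hook exists, off by default).

**Time-of-flight initialization.** Arrival delays come from the unwrapped
phase of the lowest-frequency records *relative to a simulated water-bath
reference shot*. The reference shot matters: a finite source aperture puts
Fresnel edge-diffraction structure across the whole receiver array at 0.35
MHz, and referencing against an ideal plane-wave phase mistakes that
structure for medium delays. Referencing against the water shot — the
computational analogue of a scanner's blank calibration scan — cancels it
exactly. Delays then feed straight-ray slowness tomography solved by a
damped SART sweep with Gaussian post-smoothing.

## Reflection imaging

The reflection mode operates at ~4 MHz on 2D axial planes with a
monostatic synthetic-aperture linear array (the hardware's three rotating
beam-formed transceivers are not documented in enough detail to emulate).
Travel times solve the eikonal equation $|\nabla\phi| = n$,
$n = c_0/c$, by Gauss–Seidel fast sweeping with first-order upwind
differences (in C++). Fast sweeping was chosen over fast marching as the
first-arrival solver: it needs no priority queue, is robust in
high-contrast maps, and converges in a handful of passes; rays integrating
$\tfrac{d}{ds}(n \tfrac{d\mathbf{r}}{ds}) = \nabla n$ with classical RK4
are retained for the Snell-invariant and consistency property tests. The
Born echo simulator delays each scatterer by the two-way eikonal time
through the *true* medium, with reflectivity over two-way geometric
spreading and attenuation accumulated along the straight element-scatterer
chord (a deliberate simplification — the dB-arithmetic test uses a
homogeneous attenuation where the chord is the ray). Delay-and-sum then
beamforms the analytic traces with eikonal delays through the *provided*
speed map; passing a uniform water map gives the uncorrected baseline that
the mislocalization experiment beats.

## Postprocessing

Fusion is the voxelwise linear combination
$I = \alpha\,\mathrm{SoS} + \beta\,\mathrm{Atten} + \gamma_w\,\mathrm{Refl}$
with defaults $\alpha = 1000$, $\beta = 100$, $\gamma_w = 6$; the weights
are unit-dependent by nature and the volumes are fused in native units.
Bone isolation thresholds the attenuation image (Otsu by default), opens
with a spherical element (radius 2 voxels) and keeps the largest connected
component — that last step is a guard against disconnected false positives
and can be switched off. SOS-interval segmentation uses non-overlapping
intervals centred on the tabulated tissue speeds; skin and the trabecular
bone interior overlap other classes in SOS alone and are therefore not in
the default table. ROI statistics use 6 mm discs by default, batched over
slices 2 mm apart, with unbiased SD.

## The synthetic phantoms, and what passing tests do not show

Phantoms are (elliptic-)cylindrical regions with speeds and slopes from a
shipped tissue table (fat 1437, muscle 1571, cartilage 1664, ligament
1690 m/s; cortical shell 2900 m/s over a 1600 m/s low-attenuation
interior). Region boundaries are rasterized with partial-volume coverage
(a $4\times4$ subvoxel grid) so that grids of different resolution
discretize the *same* continuous object — with binary voxel masks, the
coarse and fine grids disagree at the percent level in the data and that
mismatch masquerades as a reconstruction bias. Water $c_0$ defaults to
1500 m/s and is configurable, as is the attenuation unit convention.

The generators emulate the geometry and contrast regime of knee imaging,
not its anatomy: no speckle, no density or elastic-mode physics (the model
is scalar in $\gamma$), no transducer directivity or electronics, and
noise only as optional seeded complex Gaussian at a stated SNR. Passing
the recovery tests therefore demonstrates the correctness and conditioning
of the *algorithm chain* under its own physics — including the
inverse-crime guard of simulating on a $2\times$ finer grid — but says
nothing about robustness to real-scanner calibration, aperture or tissue
effects outside that model.

## Reference experiment conditions

Chosen once, as the package's desk-scale study conditions:

* Inversion grid $64^2$ at 0.35 mm (22.4 mm field); simulation on the
  $2\times$ finer $128^2$ grid; 36 views over 360°; 56 receivers at
  0.35 mm pitch; protocol 0.35/0.5/0.7/1.0 MHz with 15/10/10/10
  iterations, time-of-flight start. The top frequency keeps the grid above
  4 points per wavelength.
* Recovery ROIs are 2.5 mm discs at the centres of the 3 mm-radius tissue
  discs. A reconstruction of a sharp disc carries Gibbs-type over- and
  undershoot in a ring of about one PSF width inside its boundary, so ROIs
  are sized to sit inside that ring, mirroring how tabulated ROI
  measurements are taken "well within" a tissue.
* The bone experiment places the soft-tissue ROIs two wavelengths (of the
  final 1 MHz stage) outside the shell; nothing is asserted inside the
  bone, where the scalar one-way model is not trusted.
* The PSF experiment widens the transverse grid to $64\times128$ and the
  array to 116 elements so the scattering aperture, seen from a centred
  point target, reaches the ±60° that the $\lambda/\sqrt 2$
  diffraction-limit figure presumes; it reconstructs a +10 m/s single-voxel
  perturbation at 1 MHz on the *same* grid as the simulation, because at
  Born-level amplitudes the point response is a property of the
  reconstruction operator and inter-grid discretization differences would
  swamp the signal.
* The quadratic NCG-versus-least-squares check runs on a 25-unknown
  instance with condition number ≈ 40 and a $10^{-8}$ perturbation
  amplitude: small enough that forward-model nonlinearity sits below the
  $10^{-6}$ comparison tolerance, large enough that double-precision
  residual rounding does too.

## Numerical edge cases and limitations

* `extract_sos_attenuation()` rejects $\mathrm{Re}\,\gamma \le -1$
  (non-physical speed) naming the voxel; NCG candidates are projected to
  $\mathrm{Re}\,\gamma > -0.9$, $\mathrm{Im}\,\gamma \le 0$ before the
  residual check, so monotone descent is asserted on the projected
  iterates.
* Ladder frequencies must land on DFT bins in chirp emulation; mismatch is
  an error, not rounding.
* The eikonal solver seeds the exact solution in a two-voxel ball around
  the source to tame the point-source singularity of first-order upwind
  schemes; errors are $O(h)$ along diagonals, and the consistency tests
  budget in voxel units.
* Speed-of-sound accuracy inside and immediately behind the cortical shell
  is not claimed anywhere; the paraxial screen handles the transmitted
  phase but not shear conversion or reverberation.
* The frequency-domain pipeline is primary; the chirp/time-domain path
  exists as an emulation layer for deriving frequency records and
  time-of-flight data, not as a full time-domain solver.
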