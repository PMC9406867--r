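---
title: "Modelling MRI heating risk for metallic orthopaedic implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MRI heating risk for metallic orthopaedic implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantheat)
```

## The problem

Patients carrying passive metallic prostheses (hip, knee, shoulder
arthroplasty) are increasingly referred for MRI. Two field sources heat them
in complementary ways. The radiofrequency (RF) transmit field deposits power
directly in tissue; the implant perturbs the field and can concentrate
specific absorption rate (SAR) near its surface, so the scanner's whole-body
SAR display is not a self-reliant safety parameter. The switched
gradient-coil (GC) fields, in the kHz band, induce eddy currents *inside* the
bulk metal; the Joule heat then diffuses into surrounding tissue, and is
largest when the implant sits far from the imaging region, where the
gradient fields are strongest.

`implantheat` implements both exposure channels as a reusable pipeline:
sequence-level stress descriptors, configuration-level field averages,
eddy-current power via a Q-matrix quadratic form, bioheat temperature
scaling, and a three-tier risk classification per scenario (scenario =
pulse sequence × configuration, where a configuration is the coil, subject,
imaging region and implant).

## RF channel

### Calibration and factorisation

Full-wave solvers provide, at nominal coil drive, the complex transmit
sensitivity $B_1^+(\mathbf x)$ and the nominal SAR map. A scaling factor
$\beta_C$ re-normalises the drive so that a hard pulse of length
$\Delta t = 1\,$ms produces a $90^\circ$ flip angle, defined as the
maximiser of the free-induction-decay signal magnitude

$$\max_{\beta_C}\Bigl|\int_V \sin\bigl(\beta_C\,|B_1^+|\,\gamma\,\Delta t\bigr)\,
e^{i\varphi^+}\,dv\Bigr|,$$

integrated over a 50 mm central axial slab intersected with the body mask
(air excluded — an interpretation choice; the slab volume is not otherwise
specified). The search uses a dense bracket (expanded $\times 2$ until the
maximum is interior) plus bounded 1-d refinement; exact ties resolve to the
smallest $\beta_C$, and an identically-vanishing objective (antipodal
phases) returns the smallest bracketed value with a warning.

The TR-averaged SAR then factorises as $\psi_S\,\xi_C(\mathbf x)$ with
$\xi_C = \beta_C^2\,\mathrm{SAR}^C$ a property of the configuration alone,
and the *sequence RF stress index*

$$\psi_S = \frac{1}{TR}\sum_i r_i\,T_i
\Bigl(\frac{\alpha_i}{\alpha_{90}}\frac{\Delta t}{T_i}\Bigr)^2,$$

where $r_i \ge 1$ is the energy ratio of the modulated pulse relative to a
hard pulse. When only console-declared $B_{1,\mathrm{rms}}^+$ is available
(as in the published sequence table), the provably identical route
$\psi_S = (\gamma\,\Delta t\,B_{1\mathrm{rms}}/(\pi/2))^2$ is used; the
identity is enforced as a property test at $10^{-10}$ relative error.
$\gamma$ is the proton value ($2\pi \times 42.577$ MHz/T) and the
$90^\circ$/1 ms reference is a fixed constant, not configuration.

### Spatial and temporal averages

Whole-body averages are mass-weighted means of $\xi_C$; the regulatory
"maximum 10 g SAR" is computed with a deterministic centred-cube scheme
(simplified IEC 62704-1 style): for each voxel, the smallest grid-aligned
centred cube whose in-mask mass reaches 10 g, clipped at the grid boundary
with growth continuing along valid directions. Whether the reference work
used cubical or arbitrarily-shaped 10 g regions is unknowable from the text;
the cube scheme is documented as a tolerance source. Note one consequence of
the clipping rule exercised by the tests: near a boundary the stopping cube
can be slightly *smaller* than the interior 10 g cube, so a boundary hotspot
can average marginally higher than the same hotspot deep in the object.

Temporal averaging follows the 6-minute IEC window: for sequences shorter
than $T_{IEC} = 360$ s the 6-minute average is the TR average scaled by
$T_S/T_{IEC}$. The 10 s IEC average is represented by the TR average, valid
because clinical TR ≪ 10 s ≪ sequence duration.

## GC channel

### Eddy currents and the Q matrix

Neglecting the skin effect (conservative at kHz frequencies in cm-scale
implants), the current density induced in the implant is linear in the
applied field, so three unit solutions suffice: $\hat{\mathbf J}_i$, the
response at 1 Hz to a 1 T uniform field along axis $i$. The solver freezes
the gradient-coil field at its implant-barycentre value (the uniform-field
assumption that makes three solutions sufficient), writes the source field
as $\mathbf E_A = -\partial_t \mathbf A$ with
$\mathbf A = \tfrac12 \mathbf B \times (\mathbf x - \mathbf x_0)$, and
solves the charge-conservation problem
$\nabla\cdot\sigma(\mathbf E_A - \nabla\varphi) = 0$ with zero normal
current on the implant surface by a finite-volume discretisation. The
pure-Neumann system is pinned at one cell (the current field is
gauge-invariant, which is tested by shifting $\mathbf x_0$); single-voxel
protrusions carry zero through-current along axes where both faces are
boundary faces. Against the conducting-sphere closed form the
volume-averaged power converges from a few percent below at 24 voxels per
diameter.

Field coefficients $B_{k,i}$ (field component $i$ at the barycentre per
unit gradient of coil $k$) default to the ideal-gradient model with its
lowest-order concomitant terms — z-coil $(-x/2, -y/2, z)$, x-coil
$(z, 0, x)$, y-coil $(0, z, y)$ — because the pipeline only ever consumes
barycentre values; a user-supplied $3\times3$ matrix is the escape hatch
for measured or simulated coil models. Superposition
$\mathbf J_k = \sum_i B_{k,i}\hat{\mathbf J}_i$ and volume averaging give
the $3\times3$ symmetric positive-semidefinite matrix $Q_V$, and the
deposited power density is the spectral quadratic form

$$p = D\,\frac{1}{2\sigma}\sum_f f^2\, G(f)^H Q_V\, G(f),$$

with $D$ the duty cycle and $G(f)$ the peak-phasor Fourier coefficients of
one TR of the gradient waveform (DC discarded; harmonics retained until
99.9 % of the $f^2$-weighted energy or 100 kHz, whichever first — the
quasi-static validity bound). For TR-varying sequences the
maximum-intensity TR is replicated, a deliberately conservative
simplification. For EPI sequences the frequency-encoding train is assigned
to each Cartesian axis in turn and the worst case reported.

CoCrMo electrical conductivity is not published in the source material;
the default is $1.16\times10^6$ S/m (handbook value), with a titanium
preset ($5.95\times10^5$ S/m) for comparative use. Both are overridable
and logged in reports.

## Thermal channel

A single unit-power Pennes solve per implant,
$\rho c\,\partial_t\vartheta = \nabla\cdot(k\nabla\vartheta) - w\vartheta
+ q$ with $q = 1$ W/m³ inside the metal, scales linearly to any scenario:
$\vartheta = p\,\hat\vartheta$. Defaults emulate bone-like gel
($k = 0.3$ W/m/K, $w = 600$ W/m³/K, $\rho = 1000$ kg/m³,
$c = 2500$ J/kg/K); the metal region uses CoCrMo handbook thermal values
($k = 14$, $\rho = 8300$, $c = 450$, zero perfusion), again overridable.
Backward-Euler stepping (unconditionally stable, $\Delta t \le 0.5$ s) and
a direct steady-state solve are both preconditioned-conjugate-gradient
based; the linear systems are SPD and CG with Jacobi preconditioning at
$10^{-10}$ relative residual proved far faster than sparse factorisation
at $10^5$–$10^6$ unknowns in this environment.

**Boundary condition.** The outer box is padded around the implant. A
Dirichlet $\vartheta = 0$ boundary at a practical margin depresses the
$w = 0$ solution by $\sim a/R$ (tens of percent), which is incompatible
with validating against the infinite-medium heated-sphere closed form
(surface rise $qa^2/3k$ within 3 %). The default is therefore a
monopole-matched Robin ("open") boundary,
$\partial_n\vartheta + \vartheta\,(\mathbf x\cdot\hat n)/|\mathbf x|^2 = 0$,
exact for the far-field $1/r$ decay on any surface; `"dirichlet"` and
`"adiabatic"` remain options. With physiological perfusion the decay
length $\sqrt{k/w} \approx 2$ cm makes the choice nearly irrelevant at a
5 cm margin; for the perfusion-free verification problems it is decisive.
This is the package's one deviation from the otherwise-adopted design
baseline, made so that a green closed-form test is meaningful.

The end-of-sequence metric $\vartheta$ interpolates the per-step domain
maximum at $T_S$; the steady metric $\vartheta_\infty$ comes from the
direct linear solve (cross-checked against long time-stepping in the
tests). Modelling note: power is applied as a constant average over the
sequence, per-TR structure having been averaged upstream.

## Risk tiers

RF, per scenario with TR averages $S_{wb}, S_{10g}$ and 6-minute averages:
tier 3 (attention) if any of $S^{TIEC}_{wb} > K_1$, $S_{wb} > 2K_1$,
$S^{TIEC}_{10g} > K_2^{eff}$, $S_{10g} > 2K_2^{eff}$; tier 2 (warning) if
instead $S_{wb} > K_1$ or $S_{10g} > K_2^{eff}$ (a repetition or extension
could escalate); tier 1 otherwise. $K_1 = 2$, $K_2 = 10$ W/kg (local-coil
limits, adopted deliberately although a body coil is simulated, to absorb
implant field perturbations); the knee doubles $K_2$. GC: tier 3 if
$\vartheta$ exceeds 2 °C (hip/shoulder; 39 °C limit over a 37 °C trunk
baseline) or 3 °C (knee; 36 °C limb baseline); tier 2 if only
$\vartheta_\infty$ exceeds it. Equality with a limit is read as compliant
(strict inequalities escalate) — the boundary convention is not specified
by the standards text paraphrased here, so it is a logged, configurable
choice. Combining the two local-SAR limits yields the admissible
configuration-index threshold
$\xi^*_{10g,S} = \min(2, T_{IEC}/T_S)\,K_2^{eff}/\psi_S$, constant in
$T_S$ below $T_{IEC}/2$.

## Synthetic fixtures: what they do and do not establish

The fixtures module synthesizes every input: an ASTM-like gel phantom
(440 × 178 × 1190 mm, σ = 0.47 S/m, εr = 80; the height exceeds the
standard box so the phantom stays centred while the implant moves across
imaging regions), sphere/cylinder/capsule implant geometries, the seven
reference sequences with their published TR, duration, flip angle and
B1+ rms (gradient trains are *representative*, derived from
matrix/FOV/bandwidth under 40 mT/m and 200 T/m/s defaults — the published
study does not print waveform amplitudes, so absolute GC powers for the
named sequences are not recoverable and are exercised by closed-form and
oracle tests instead), and seeded smooth B1+/SAR surrogates with an
optional implant-adjacent hotspot.

The surrogates are explicitly non-physical: they carry no RF scattering,
no implant-wavelength resonance, no realistic coil. A green pipeline test
therefore establishes that calibration, averaging, limit checking and
classification are correct *given* field maps — not that the package
predicts the fields themselves, which remain the province of full-wave
solvers whose outputs can be imported through the voxel-field container.
Imaging-region offsets along the body axis (head 0, shoulder 0.25, chest
0.45, abdomen 0.60, pelvis 0.75, femur 0.95, knee 1.25 m) are declared
package assumptions; the published figure is graphical only.

Two published stress-index entries (the EPI sequences, ψ printed as
1.3 × 10⁻⁵ and 1.6 × 10⁻⁵ at an identical printed B1+ rms of 0.02 µT) are
rounding-limited at the source and deliberately not targeted; the five
other entries reproduce within 5 %.

## Numerical choices

* Pulse energy ratios: midpoint quadrature at 8192 samples; the
  apodized-sinc value is validated against an independent trapezoid rule
  at doubled resolution to 10⁻⁴.
* Gradient spectra: power-of-two FFT of one TR at ≤ 1 µs target sampling
  (capped at 2²¹ samples); Parseval and time-shift invariance are property
  tests.
* Calibration: bracket `[0, 4·(π/2)/(γΔt·median|B1|)]`, 1024-point grid,
  `optimize()` refinement; validated against a 10⁻⁶-step grid search to
  10⁻⁵ relative.
* Eddy/thermal linear algebra: Jacobi-preconditioned CG at 10⁻¹⁰ relative
  residual, deterministic ordering; sparse Cholesky only for the small
  eddy systems.
* Degenerate inputs signal errors rather than guessing: zero-B1 slabs,
  empty masks, sub-10 g objects, zero-ψ thresholds, perfusion-free
  adiabatic steady states, inconsistent ϑ∞ < ϑ.

## Known limitations

Single-channel RF drive only (no pTx); no skin effect, magnetostatic
force or vibration; no combined RF+GC thermal superposition (the two
channels are assessed separately — published evidence indicates their
worst-case implant positions do not coincide); no anatomical perfusion
heterogeneity or thermoregulation; no vendor CAD or DICOM ingestion. The
scenario counts of the source study are not reproducible here because
they depend on unpublished full-wave field values; the printed worst-case
values are used as inputs to worked examples instead.
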