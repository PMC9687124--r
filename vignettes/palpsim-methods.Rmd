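---
title: "Simulating abdominal palpation and learning a real-time stress surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating abdominal palpation and learning a real-time stress surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`palpsim` is a desk-scale toolkit for studying how manual abdominal
palpation loads the liver, and for replacing the expensive finite-element
computation of that loading with a neural-network surrogate that answers in
a fraction of a second. This vignette explains the models, the numerical
choices and the limitations; the README shows the worked example.

## The physical problem

During an abdominal examination the examiner presses two fingers into the
abdominal wall above the liver. The quantity of clinical interest here is
the maximum principal stress $\sigma_3$ (the largest eigenvalue of the
Cauchy stress tensor) on the *edge of the liver* — the region a clinician
hunts for — as a function of where and how hard the fingers press. A
finite-element simulation of one palpation is far too slow for interactive
training feedback, so the pipeline is: simulate a modest number of
palpation locations offline, then train a multilayer perceptron mapping
(palpation $x$, $y$, contact force) to the full $\sigma_3$ field over the
liver-edge region of interest (ROI), and serve that surrogate in real time
against a force-plate input.

## The synthetic phantom

Real anatomies come from segmented CT; this package instead generates a
parametric phantom so that every geometric control is explicit and
testable: a rectangular block of lumped abdominal soft tissue ("flesh")
with an ellipsoidal liver and a few cylindrical rib bars embedded near the
skin. The default block is 80 × 80 × 60 mm at 5 mm voxels
(3072 hexahedral elements), with the liver ellipsoid (semi-axes
30 × 26 × 18 mm) centred at depth 30 mm and three rib bars running along
$x$ over the superior half of the liver — the inferior-anterior liver edge
is left uncovered, as the costal margin leaves the real liver edge. The
coordinate convention is: $x$–$y$ is the palpation (skin) plane, $z$ is
depth, $z = 0$ the fixed bottom face. All node and element indices in the
R API are 1-based, following R convention; the VTK files use the 0-based
indices their format requires.

The block depth matters: a 15 mm indentation must remain a moderate
fraction of the tissue thickness, otherwise the deformation under the
fingertips outruns what a 5 mm mesh can represent. This is why the phantom
is deeper than it is wide relative to the liver.

Voxel meshes of segmented shapes have jagged surfaces, so the package
includes Taubin $\lambda/\mu$ pair smoothing restricted to free-surface
nodes (volume-conserving by construction of the $\mu$ back-step, guarded
by a positive-Jacobian check). The default phantom's free surface is
already planar, so smoothing defaults to 0 iterations; the operation exists
for jagged geometries and is exercised on staircase meshes in the tests.

The ROI is defined geometrically: the liver edge is taken as the curve
where the liver surface touches its inferior-anterior supporting plane
(outward normal $(0, 1, 1)/\sqrt{2}$), and the ROI consists of the liver
elements owning a liver-surface facet whose centroid lies within a band
(default 16 mm) of that plane. On the default phantom this yields 80
elements, the same order of magnitude as the few-hundred-element ROI a
segmented liver yields. The band rule is a stand-in: no published
geometric criterion reproduces a particular ROI element count exactly.

## Constitutive models

All quantities use the mm–kg–ms unit system, in which stresses are GPa and
forces kN; forces are converted to N only at reporting boundaries.

**Liver — Ogden visco-hyperelasticity.** The long-term response is the
Ogden strain-energy density in principal stretches,
$$\Psi_\infty = \sum_p \frac{\mu_p}{\alpha_p}\left(
  \lambda_1^{\alpha_p} + \lambda_2^{\alpha_p} + \lambda_3^{\alpha_p} - 3
\right),$$
applied to the isochoric stretches
$\bar\lambda_i = J^{-1/3}\lambda_i$ and complemented by a quadratic
volumetric penalty $U(J) = \tfrac{K}{2}(J-1)^2$. The published liver card
is silent on the volumetric treatment; the bulk modulus is derived from
the Poisson ratio $\nu = 0.49$ and the ground-state shear modulus
$\mu_0 = \tfrac12\sum_p \mu_p\alpha_p$ as
$K = 2\mu_0(1+\nu)/(3(1-2\nu))$. The third Ogden pair has negative
$\mu_p$ and $\alpha_p$; it is applied verbatim and the net ground-state
stiffness is verified positive. Rate dependence enters through the
hereditary integral on the second Piola–Kirchhoff stress,
$$S(t) = S_\infty + \int_0^t G(t-T)\,\frac{\partial E_{dev}(T)}{\partial T}\,dT,
\qquad G(t) = \sum_i G_i e^{-t/\tau_i},$$
with $E$ the Green–Lagrange strain. The three-term relaxation series is
integrated by the standard per-term exponential recurrence
$$h_i \leftarrow e^{-\Delta t/\tau_i} h_i +
  G_i \frac{\tau_i}{\Delta t}\left(1 - e^{-\Delta t/\tau_i}\right)
  \Delta E_{dev},$$
which is exact for strain that is linear over a step; direct trapezoidal
quadrature of the convolution is retained as a test oracle. The decay
constants $\tau_i = 10, 10^2, 10^3$ carry no published unit; they are
interpreted in the solver time unit (ms), which makes the relaxation act
on the same scale as the 25 ms palpation ramp. Note that
$G(0) \approx 1.0 \times 10^{-4}$ GPa exceeds $\mu_0 \approx 6.5 \times
10^{-7}$ GPa by two orders of magnitude: on palpation time scales the
liver's transient stiffness is dominated by the viscoelastic overstress,
which is characteristic of this material model.

**Flesh — nearly incompressible neo-Hookean.** The lumped abdominal tissue
card gives density, bulk modulus (2 GPa, i.e. water-like
incompressibility), a shear modulus and a damping coefficient. The card's
originating commercial material model is not publicly specified; the
package interprets it as deviatoric neo-Hookean stress
$(G/J)\,\mathrm{dev}(\bar B)$ plus the volumetric pressure $K(J-1)$. The
damping coefficient is applied as mass-proportional damping in the time
integrator (see below). `flesh_stress()` additionally exposes an optional
Newtonian viscous term $damping \times G \times \mathrm{dev}(D)$ for
quasi-static API use; the solver does not add it on top of the integrator
damping, to avoid counting the same physical dissipation twice.

**Ribs — von Mises plasticity with linear hardening.** Small-strain
radial-return with hardening modulus $H = E E_t/(E - E_t)$, so the
uniaxial post-yield stress–total-strain slope equals the tangent modulus
$E_t$.

## The explicit solver

The solver is explicit central-difference dynamics on one-point-quadrature
hexahedra with Flanagan–Belytschko-style viscous hourglass control,
written in C++ for speed. Choices that required judgement:

* **Contact.** The fingertips are rigid capsules (a sphere of radius
  10 mm continued upward by a cylindrical shaft, two of them 22 mm
  apart — dimensions chosen as plausible adult fingertip defaults). Contact
  is node-on-analytic-surface penalty: any free node inside a capsule
  receives $k_{pen} \times$ penetration along the outward normal,
  frictionless. All free nodes (not only initial surface nodes) are
  candidates: at 15 mm indentation the surface sheet can fold around the
  tip, and the material that then carries the finger is interior to the
  original surface. The penalty stiffness defaults to
  $0.5\,K_{flesh} h$ (with $h$ the mean element size); doubling it
  changes peak forces by under half a percent.
* **Adaptive time stepping.** The reference-configuration stable step
  $\Delta t = 0.9\,\min_e h_e/c_e$ (dilatational wave speed
  $c_e = \sqrt{(K + 4G/3)/\rho}$) is re-limited during the run: every 20
  steps each element's current minimum dimension ($h_e$ times its
  smallest principal stretch) and, for liver elements, the current
  tangent of the Ogden stress (which grows exponentially as the
  $\alpha_p = -10.96$ term engages under compression) are used to shrink
  the step when needed. A contact-spring limit
  $\Delta t < \sqrt{m_{min}/k_{pen}}$ is also enforced. Without these
  re-limits the final millimetres of a 15 mm indentation destabilize the
  fixed-step integration.
* **Damping.** Mass-proportional damping with the flesh card's
  coefficient (0.4 per ms) keeps the quasi-static ramp free of structural
  ringing; the energy ledger verifies that the dynamics stay quasi-static
  (kinetic energy stays a small fraction of external work).
* **Selective mass scaling.** Optionally, elements whose stable step is
  below a target are given extra mass so the whole mesh can run at that
  target. The palpation sweep and the acceptance runs use a 5 × 10⁻³ ms
  target, which adds ~73% artificial mass but changes stamp forces by
  under 1% (the indentation is quasi-static, so inertia is negligible);
  the flag is off by default elsewhere.
* **Energy ledger.** External work (contact force × indentation rate),
  kinetic, internal ($\int \sigma\!:\!D$), contact-spring and dissipated
  (damping + hourglass) energies are tracked; runs abort if kinetic
  energy exceeds ten times external work, and tests require the ledger to
  close within 2%.
* **Boundary conditions.** The bottom face is fixed, the simplest support
  for a block phantom. `crop_model()` retains elements whose
  centroid lies in a box and fixes the nodes on newly exposed cut faces,
  so removed material acts as rigid far-field support.
* **Quadrature.** One-point quadrature with hourglass control was chosen
  for speed; correctness is established against a plain-R quasi-static
  assembly of the same elements, single-element patch tests and the
  energy ledger, rather than by a full-quadrature twin.

## The sweep and the surrogate

The study design is fixed: a 5 × 5 training grid of palpation locations
over the liver-region bounding rectangle (inset 5 mm) plus 3 off-grid
held-out locations; 15 mm indentation ramped linearly over 25 ms (a
linear ramp is the simplest schedule consistent with the stated depth and
duration); output
at the six stamps 0, 5, 10, 15, 20, 25 ms. That yields 25 × 6 = 150
training records and 18 held-out records. Each record holds
$(x, y, F, t)$ and the $\sigma_3$ vector over the ROI, where $F$ is the
finger contact force in N.

The surrogate is a multilayer perceptron
$3 \to 64 \to 128 \to 256 \to 512 \to |ROI|$ with positive-linear
(`max(0, x)`) hidden activations and a linear output layer; the
power-of-two hidden widths are defaults and fully configurable. Training
is full-batch gradient descent with momentum 0.9 and an adaptive learning
rate: ×1.05 after an improving epoch, step rejected (weights restored,
momentum reset) and rate ×0.7 after an epoch that worsens the MSE by more
than 4%. These are the classical constants of the variable-learning-rate
momentum recipe. Inputs are min–max normalized to [0, 1] and outputs
standardized by their pooled mean and standard deviation, fitted on the
training partition only. Up to 20 000 epochs with early stop at a
normalized MSE of 10⁻⁶. Initialization is a seeded scaled-uniform draw,
making training bit-reproducible.

Fit is reported as the pooled coefficient of determination in percent,
$$Fit = 100\left(1 - \frac{\sum_k (y_k - \hat y_k)^2}
  {\sum_k (y_k - \bar y)^2}\right),$$
pooled over all held-out records and ROI elements; per-element fits are
returned diagnostically. Pooling into one number summarizes the whole
held-out stress field, at the cost of being dominated by the
largest-variance elements — hence the per-element breakdown.

## Real-time serving

The hardware platform (a plate on four corner force sensors with a
projector) is replaced by software: `resolve_contact()` recovers the
contact point as the force-weighted centroid of the corner coordinates —
the static moment-balance (centre-of-pressure) solution, which is exact
for a rigid plate on four supports — and the total force as the corner
sum. `split_corner_forces()` is the bilinear inverse used by the stream
synthesizer and the round-trip tests. Predicted $\sigma_3$ fields are
rendered by filling each ROI element's plan-view footprint with a
diverging colour map (blue–white–red, neutral at zero when the display
range straddles zero),
with the display range chosen from the data since stress magnitudes are
anatomy-specific. Rendering is a pure function, so frames are
byte-reproducible.

## Problem sizes and scale

Segmented-anatomy abdomen models run to hundreds of thousands of
elements and hours per palpation on HPC hardware. This package's default
phantom is 3072 elements and one palpation takes tens of seconds on one
CPU; the full 28-location sweep plus training completes in well under
half an hour. These sizes are the package's chosen desk-scale study
conditions, stated here once so all documentation and acceptance runs
agree.

Stress magnitudes scale accordingly: the desk phantom's liver sits closer
to the skin than a real liver, so peak $\sigma_3$ values on the ROI are of
order 10⁻⁴ GPa rather than the few-kPa range a full anatomy produces, and
contact forces at full 15 mm indentation are of order 2 kN (the flesh card
is a 4 MPa rubber). Such magnitudes are anatomy-specific and are treated
as data, not targets.

## Known limitations

* **Crop invariance does not transfer to desk scale.** In a full-size
  anatomy a reduced model can be cut many contact-widths away from the
  palpation site, where removing material barely changes the contact
  force. In an 80 mm phantom with near-incompressible flesh every
  admissible cut plane lies inside the indenter's pressure bulb, and
  fixing the cut nodes stiffens the response at the percent level — tens
  of newtons on a ~1.8 kN peak, as the acceptance run measures and
  reports. `crop_model()` reproduces the *procedure*; the near-perfect
  invariance attainable at full scale is not reachable in a phantom this
  small.
* The phantom is a block, not an anatomy: no skin/fat layering, no
  curved abdominal wall, no respiratory motion, no tumour variants.
  A surrogate that interpolates well here shows the pipeline works, not
  that it generalizes over anatomical variation.
* Node-on-analytic-surface penalty contact is simpler than
  segment-to-segment contact; at extreme indentation the folded surface
  is carried by interior-node contact, which is robust but first-order.
* The rib model is small-strain; rib rotations under deep palpation are
  moderate in the default phantom but the model would not be adequate for
  rib-dominated loading.
* Training is full-batch on 150 records; the adaptive-rate schedule is
  deterministic but can plateau on materially different datasets, in
  which case the learning-rate constants (exposed in `train_config()`)
  need retuning.
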