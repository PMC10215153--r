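---
title: "A quasi-static virtual knee simulator for femoral component malrotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-static virtual knee simulator for femoral component malrotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`kneelax` simulates a total knee arthroplasty (TKA) joint mounted in a
six-degree-of-freedom joint motion simulator, as a quasi-static rigid-body
problem. Two rigid bodies articulate: the femur carrying a single-radius
cruciate-retaining (CR) femoral component, and the tibia carrying a tray and
a dished polyethylene insert. The machine's DOF architecture is respected
exactly: the femur can flex--extend and adduct--abduct only; the tibia can
translate in three directions and rotate about its long axis. Every test
prescribes the flexion angle and drives each remaining DOF either to a
displacement or to a target generalized load (0 N / 0 N mm for an
unconstrained DOF, or the test load).

Three structures connect the bodies:

* a **multifiber ligament system** -- a five-bundle superficial medial
  collateral ligament (sMCL, wrapped around the proximal-medial tibia), a
  five-bundle lateral collateral ligament (LCL) and a three-bundle posterior
  cruciate ligament (PCL). The cruciate-substituting structures released
  during TKA (ACL, ALL, POL, deep MCL) are absent.
* **component-on-insert contact**, evaluated by inferior--superior (IS)
  penetration testing between the femoral condyles and the insert's
  articular surface, with a penalty force law.
* applied test loads (posterior drawer force, varus--valgus and
  internal--external torques).

An equilibrium is a joint state in which every load-controlled DOF's
internal generalized load balances its target.

### Fiber force law

Each bundle is a one-dimensional nonlinear elastic point-to-point spring
with stiffness $k$ (N per unit strain) and slack length $l_0$, using the
standard quadratic-toe/linear law of knee ligament modelling:

$$
f(\varepsilon) \;=\;
\begin{cases}
0, & \varepsilon \le 0\\[2pt]
k\,\varepsilon^2 / (4\varepsilon_t), & 0 < \varepsilon \le 2\varepsilon_t\\[2pt]
k\,(\varepsilon - \varepsilon_t), & \varepsilon > 2\varepsilon_t
\end{cases}
$$

with toe transition strain $\varepsilon_t = 0.03$. The law is continuous,
C1 at $\varepsilon = 2\varepsilon_t$, and non-decreasing; both properties are
asserted by tests. The paper-style parameterisation is by *reference strain*
$\varepsilon_r = (l_r - l_0)/l_0 \times 100\%$, the strain at the reference
pose (full extension): the packaged table stores $(k, \varepsilon_r)$ per
bundle, the reference length $l_r$ is *measured* on the synthetic geometry
at the reference pose (wrapped length for the sMCL), and
$l_0 = l_r / (1 + \varepsilon_r/100)$ is back-computed. This preserves the
tabulated strain field on any surrogate geometry.

### Bundle augmentation and stiffness

The packaged table holds the final bundle set: the `am`/`mp` collateral
bundles and the middle PCL bundle are augmentation products, with insertions
midway between their neighbours' insertions and reference strains equal to
the neighbours' mean. `augment_bundles()` reproduces this construction and
the tests verify the interpolated strains against the tabulated values.
Because the tabulated stiffnesses are already the final calibrated values,
the default model takes every bundle's stiffness from the table (the middle
PCL, absent from it, receives its neighbours' mean).
`calibrate_stiffness()` implements the distraction-conservation rule --
uniform per-ligament scaling so the augmented set's total tension at a
distracted pose equals the original set's -- and is available via
`knee_model(stiffness = "recalibrated")` for deriving models from
uncalibrated sources.

A fixed 5 mm distraction cannot engage the PCL bundles (a bundle with
$\varepsilon_r \approx -28\%$ needs roughly 40% elongation), so the
calibration pose is found adaptively: the smallest inferior distraction that
puts every bundle of the ligament above 1% strain.

### Ligament wrapping

All sMCL bundles wrap the proximal-medial tibia. Wrapping follows the
single-optimized-point model: if the straight fiber intersects the wrap
surface, the path is routed through one via point on the surface, chosen to
minimise total length subject to neither sub-segment penetrating. The via
point is found by projected-gradient descent on the mesh (warm-started
across solver iterations), with a vertex grid-search fallback. The tibia
surrogate's proximal segment is a *convex* capped surface of revolution
(plateau rim flaring to the shaft) precisely so that the single-via-point
model is exact -- on a non-convex flare no single via point can be
penetration-free, which manifests as line contact in reality.

Because the wrap surface is part of the tibia, a wrapped fiber's insertion
pull and via-point reaction combine: the net force on the tibia is the
tension along the via-to-femur segment acting at the via point, exactly
equal, opposite and collinear with the femoral reaction. This is the only
resolution consistent with action--reaction and with the energy gradient
(`generalized_loads()` is verified against finite differences of the total
elastic energy).

### Contact

Contact is evaluated on a grid of sample points on each insert compartment
(21 x 11 per compartment by default). The component condyle meshes are
expressed in the tibia frame and a vertical ray is cast per sample point;
the penetration depth is the IS overlap. Per-point force is
`penalty_stiffness * depth * area` along the component's local surface
normal, scaled so its IS component equals the penalty pressure times the
tributary area -- making the force system the exact gradient of the IS
penalty energy in the tibial translations. Surface normals are
barycentrically interpolated from area-weighted vertex normals so the force
field is continuous across mesh facets (facet-wise constant normals produce
moment jumps larger than the solver tolerance and limit-cycle the
iteration). The medial/lateral split is by the sample point's side of the
insert midline; the two compressive components sum to the net IS force
exactly. Friction (mu = 0.04) enters only as a regularised Coulomb term
against a prescribed sliding direction; at a converged static equilibrium
with no prescribed sliding it contributes nothing.

Default penalty stiffness is 100 N/mm per mm^2. Under conforming contact
this keeps penetration well below 0.1 mm up to 1500 N of compression. In
deep flexion the engaged PCL presses the condyles against the posterior
dish lip; such edge contact concentrates load on a narrow strip and IS-ray
penetration there can reach ~0.3 mm at ~800 N. This is a property of edge
loading under the linear penalty, not of the conforming articulation, and
is reported per solution as `max_penetration_mm`.

## The synthetic geometry

No implant or bone surfaces are distributed with the study, so the
geometry module generates parametric surrogates (all dimensions
configurable, defaults resembling a mid-size conforming CR design):

* **Femoral component**: two toroidal condyles; single sagittal radius
  24 mm, coronal radius 20 mm, centres 46 mm apart. The single-radius
  design puts the condylar centre line on the flexion axis, which is also
  where the collateral femoral insertions sit -- making the collaterals
  near-isometric through flexion, the design's signature property.
* **Insert**: two dished compartments (sagittal radius 24.4 mm, coronal
  21 mm) separated by an intercondylar eminence; dish low points placed so
  the reference pose seats the condyles at zero penetration. The 0.4 mm
  sagittal clearance expresses a conforming CR insert; a closed-form
  restraint estimate (tangential capacity $\le N \tan\phi$ with centre
  offset $\le c\sin\phi$) shows that centimetre-scale clearances cannot
  reproduce sub-millimetre drawer laxity under a 100 N load with
  ligament-driven compression of order 100 N, so a conforming dish is the
  only surrogate consistent with the reported laxity envelope.
* **Femur surrogate**: posterior condylar prongs plus shaft. The native
  posterior condyle axis (PCA) is twisted 4 degrees internally relative to
  the flexion axis -- the condylar asymmetry that external component
  rotation corrects for. With the mechanically aligned baseline (3 degrees
  external), the flexion gap stays slightly medial-tight, as in a native
  varus-tendency knee; the internal (1.5) and external (4.5) conditions
  bracket it.
* **Tibia surrogate**: convex capped surface of revolution; its proximal
  band is the sMCL wrap surface.
* **Ligament insertions**: literature-plausible surrogate sites stored in
  the parameter file -- femoral epicondyles on the flexion axis with a
  +/-4 mm anterior-posterior fan, a distal anteromedial tibial footprint
  for the sMCL, the fibular head for the LCL, and notch/posterior-fossa
  sites for the PCL placed so the PCL is ~28% slack in extension and
  engages near 60 degrees of flexion, reproducing the anatomical
  slack-in-extension/taut-in-flexion pattern that the tabulated reference
  strains imply. The PCL is the knee's posterior restraint in late flexion;
  in mid flexion restraint comes from dish conformity plus the compressive
  preload of the collateral reference strains.

Component placement measures both PCAs (posterior-most vertex of each
condylar half about the sagittal midplane split), then rotates the
component about the femoral proximal--distal axis through the femoral PCA
midpoint until its PCA sits at the condition's external angle. External
rotation for a right knee moves the *lateral* condyle posteriorly and the
medial condyle anteriorly (the surgical sense; at 90 degrees of flexion
this is what makes an externally rotated component ride varus).

### What the surrogate does and does not emulate

The surrogate reproduces: the DOF architecture and control modes; the
tabulated ligament stiffnesses and reference strains with midpoint
augmentation; sMCL wrapping; single-radius CR articulation with a
conforming insert; the PCA-referenced malrotation protocol; and the
passive-laxity load protocol. It does not reproduce: any commercial
implant's actual surfaces or any patient's bone geometry (so absolute forces and laxities
are surrogate-scale, not patient predictions); patellofemoral mechanics and
muscle loads; capsule and released ligaments; viscoelasticity; deformable
polyethylene. Passing the laxity-bound checks on this geometry shows the
*machinery* reproduces the study's envelope on a consistent surrogate, not
that it predicts any individual knee.

## The solver

Quasi-static root finding on the free DOFs: damped Newton with a
finite-difference Jacobian, Broyden rank-1 updates between refreshes, step
caps (2 mm / 2 deg; 0.25 mm on IS, whose conforming-contact force range
spans < 0.1 mm), backtracking line search on the tolerance-scaled residual
norm, and automatic Jacobian refresh on stagnation. Convergence requires
every free-DOF residual within 0.5 N (forces) or 50 N mm (moments); the
contract is asserted for every reported solution. Finite-difference steps
(0.05 deg / 0.02 mm / 0.01 mm IS) are sized to average over contact-mesh
facets. Continuation: neutral flexion proceeds in <= 15 degree increments,
each solution seeding the next; laxity loads ramp in 4 equal increments
from the neutral solution, passing the Jacobian along. There is no
randomness anywhere; repeated runs are byte-identical.

Energy consistency ties the pieces together: along a frictionless loading
sweep, the work done by the applied torque matches the gain in total
elastic (ligament + contact penalty) energy within 2%, which exercises the
wrapped-fiber force resolution, the contact gradient and the generalized-
load projection at once.

## The study pipeline

`run_study()` reproduces the full experiment: three malrotation conditions
x (neutral flexion + posterior drawer 100 N, varus/valgus +/-8 N m,
internal/external +/-4 N m) x flexion 0/15/30/60/90 degrees -- 90 reported
equilibria (plus continuation substeps). Kinematics are converted to the
Grood--Suntay joint coordinate system relative to the reference pose
(varus, tibial external rotation and anterior translation positive for a
right knee; the figure-caption polarity conventions). Laxity is the
absolute coordinate difference between the loaded and neutral equilibria at
the same flexion angle; condition curves can be expressed relative to the
baseline neutral trajectory. On one CPU the full study runs in roughly ten
minutes; `scripts/acceptance.R` recomputes the three headline quantities
(maximum posterior laxity, neutral AP spread, varus/valgus laxity spread)
from scratch.

## Numerical choices and degenerate inputs

* Moments are reported about the femoral PCA midpoint at the reference
  pose; any fixed centre is self-consistent.
* The JCS translations are solved exactly in the (flexion axis, floating
  axis, tibial long axis) basis, so pose round trips are exact to 1e-9;
  |adduction| = 90 degrees is a gimbal error.
* Crossing parity against the (closed) wrap surface distinguishes an
  insertion inside the surface (error) from tangential grazing
  (disambiguated by jittered chords); tangent chords on a faceted surface
  legitimately dip through facets by O(L^2/8R), so sub-segment clearance
  tolerates grazing spans up to 1.5 mm.
* Mesh degeneracies: a single-condyle mesh (no intercondylar gap) is
  rejected by `compute_pca()`; zero-length PCA axes are rejected by
  `align_component()`; an empty articular sample region is a contact error;
  dislocation (no contact, all fibers slack) aborts the solve.

## Known limitations

* One surrogate subject; no statistical spread across geometries.
* The 60-degree internal/external laxity slice is a near-tie between the
  internal and external torque directions (the overall internal > external
  ordering is clear); the balance there is sensitive to the PCL engagement
  angle.
* Edge loading of the posterior dish lip in deep flexion concentrates
  penalty penetration (see Contact above).
* Flexion beyond 90 degrees, weight-bearing load profiles and the physical
  simulator's control electronics are out of scope.
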