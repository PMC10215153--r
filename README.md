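# kneelax

Quasi-static simulation of total knee arthroplasty (TKA) laxity under
femoral component malrotation.

## The problem

During mechanically aligned TKA the femoral component is rotated externally
by about 3° relative to the femur's posterior condyle axis (PCA). Surgical
error of ±1.5° around that target changes how the collateral ligaments load
the joint and how the knee moves — effects that are expensive to measure on
a physical joint motion simulator. `kneelax` is a digital twin of that
experiment: a six-degree-of-freedom, mixed force/displacement-controlled
knee rig in software, for biomechanics researchers who want to study
alignment–kinematics–ligament interactions on a reproducible synthetic
knee.

## The model

Two rigid bodies articulate under quasi-static equilibrium:

* **DOF architecture** (as in servo-hydraulic knee simulators): the femur
  flexes–extends and adducts–abducts; the tibia translates in AP/ML/IS and
  rotates about its long axis. Flexion is prescribed; every other DOF is
  driven to a target generalized load (0 for unconstrained DOFs).
* **Multifiber ligaments**: a wrapped five-bundle superficial MCL, a
  five-bundle LCL and a three-bundle PCL. Each bundle is a nonlinear
  spring with the quadratic-toe/linear law

  `f(ε) = 0 (ε≤0); k ε²/(4ε_t) (0<ε≤2ε_t); k (ε−ε_t) (ε>2ε_t)`,  ε_t = 0.03,

  parameterised by stiffness `k` (N/ε) and reference strain
  `ε_r = (l_r − l_0)/l_0 × 100 %` at full extension. Bundle augmentation
  (3→5 collaterals, 2→3 PCL) uses midpoint insertions and mean reference
  strains; the sMCL wraps the proximal-medial tibia through a single
  optimized via point.
* **Contact**: inferior–superior penetration testing of the femoral
  condyles against the dished insert, penalty pressure `100·depth` N/mm²,
  friction µ = 0.04 (regularised Coulomb, zero at static equilibrium).
* **Kinematics**: Grood–Suntay joint coordinates relative to the extended
  reference pose (varus, tibial external rotation, anterior translation
  positive; right knee).

Laxity is the absolute kinematic difference between the loaded equilibrium
(100 N posterior drawer, ±8 N m varus–valgus, ±4 N m internal–external)
and the neutral-flexion equilibrium at the same flexion angle. Because no
implant or bone surfaces are distributed with the study, the geometry
module generates parametric surrogates (single-radius condyles, conforming
dished insert, bone bodies with a native condylar twist); see the methods
vignette (`vignettes/malrotation-model.Rmd`) for every modelling decision.

## Worked example

```r
library(kneelax)

geom  <- make_knee_geometry()                 # synthetic right-knee TKA
model <- knee_model(geom, "external")         # 4.5 deg external rotation
sol   <- solve_equilibrium(model, dof_spec(fe = 0))
sol
#> <knee_equilibrium: fe 0.0 deg, converged in 10 iterations>
#> # A tibble: 1 × 6
#>      fe     vv    ie     ap    ml      is
#>   <dbl>  <dbl> <dbl>  <dbl> <dbl>   <dbl>
#> 1     0 0.0596 0.235 0.0603 0.225 0.00575
```

The tibble is the equilibrium pose in Grood–Suntay coordinates: at full
extension the externally rotated knee settles 0.06° varus, 0.24° externally
rotated, essentially centred (ap/ml in mm). `glance()` summarises the
solve — residuals within the 0.5 N / 50 N mm tolerances, the
ligament-driven compartment forces and the peak contact penetration:

```r
glance(sol)
#> # A tibble: 1 × 9
#>   converged iterations max_force_residual_N max_moment_residual_Nmm ...
#> 1 TRUE              10                0.472                    28.0
```

The full experiment — internal/baseline/external × {neutral, posterior,
varus, valgus, internal, external} × 0/15/30/60/90° flexion — is one call:

```r
study <- run_study(study_config())    # 90 reported equilibria
glance(study)                          # headline laxity numbers
autoplot(study, "laxity")              # laxity envelopes per test
autoplot(study, "kinematics", dof = "vv")
write_study_csvs(study, "results/")    # kinematics/laxity/tensions/... CSVs
```

`tidy(study, "laxity")` returns the per-condition laxity table;
`compartment_deltas(study)` gives the medial/lateral compressive-force
changes relative to the baseline alignment.

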