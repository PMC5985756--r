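---
title: "Methods: electro-mechano-fluidic simulation of the left ventricle and aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electro-mechano-fluidic simulation of the left ventricle and aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardioemf` implements a weakly coupled electro-mechano-fluidic (EMF) model
of the left ventricle (LV) and aorta at desk scale: electrophysiology
drives active contraction, quasi-static finite elasticity against a lumped
arterial afterload produces wall kinematics, and those kinematics move a
finer fluid mesh on which a stabilized finite-element Navier-Stokes solver
computes intracavitary and aortic hemodynamics. The coupling is strictly
one-way: the flow solution never feeds back on the mechanics. This
vignette records the model equations, the numerical choices, and the
reasoning behind the design decisions that were genuinely open.

## Synthetic anatomy

Patient anatomies are replaced by parametric shapes: a truncated-ellipsoid
LV (endocardial semi-axes `long_axis` = 45 mm, `short_axis` = 26 mm, wall
thickness 10 mm, basal truncation at 0.3 of the long axis) whose basal
disk is closed by a one-element valve layer split into aortic and mitral
sectors, an apical elastic cushion cap, and a cylindrical aorta with an
optional Gaussian-profile coarctation whose throat area is
`(1 - severity)` times the nominal lumen area. The default dimensions give
an end-diastolic cavity volume near 90 ml before inflation, a normal
child/adolescent LV consistent with the clinical presets shipped with the
package. Every downstream stage is geometry-agnostic, so the idealized
shapes exercise exactly the code paths a patient mesh would.

Only the cushion bottom carries the `dirichlet` tag; the ventricular
base — wall rim and valve tops — carries a named `rim` tag. Which
constraint the rim receives depends on the question being asked. The
passive (end-diastolic pressure-volume) fit leaves it free, matching the
full anatomy where fixation happens at remote clipped artery rims while
the base floats; clamping it would cost roughly a third of the cavity's
passive compliance. The beating simulation clamps it
(`em_context(..., dirichlet_tags = c("dirichlet", "rim"))`): the
isolated-LV anatomy lacks the atrium and aorta that tether the base
during contraction, and without that tether the stiff basal valve plate
snaps through under apical activation — a pathology of the truncated
geometry, not of the heart.

Meshes are built from structured hexahedral parameter grids split into six
tetrahedra per cell along the main diagonal (a conforming template on
structured grids); parametric degeneracies on the axis and at the apex are
collapsed and removed. Generation is fully deterministic given the
parameters; the seed is recorded in the manifest attached to every mesh.

The fluid mesh is deliberately *non-conformal*: it is regenerated from the
same analytic cavity at `refinement` times finer resolution and its
surface is mildly Laplacian-smoothed (2 sweeps, factor 0.1, outlet ring
fixed), emulating the smoothed-and-remeshed blood pool a patient pipeline
would produce. A remesher for arbitrary extracted surfaces is neither
available nor needed for the idealized shapes.

Fibers follow a rule-based transmural helix: the angle rotates linearly
with wall depth from -60 degrees (endocardium) to +60 degrees
(epicardium), with the sheet direction transmural. The full
Laplace-Dirichlet rule-based construction would add machinery without
changing what the material law consumes (a transmurally rotating
orthonormal frame). At the apex pole the circumferential direction is
undefined; elements within about twenty degrees of the axis are flagged
and receive no active tension (their frames are arbitrary continuations,
and tensioning them produces a non-physical frustrated state that stalls
the solver without affecting any global metric).

## Electrophysiology

Activation is the first-arrival solution of the anisotropic eikonal
equation with squared conduction velocities (defaults 0.6/0.4/0.2 m/s
along fiber/sheet/normal) assembled into the tensor `V`; distances are
measured in the metric `sqrt(d' V^{-1} d)`. The solver is a fixed-point
(fast-iterative) method on the simplicial mesh: each vertex is updated
from the opposite faces of its incident elements, minimizing over
face-interior, edge and vertex characteristic paths (the Kuhn-simplex
update solved in closed form), with Jacobi sweeps until the largest update
drops below 1e-3 ms. The default source is a single apical patch at t = 0,
the un-personalized choice.

The reaction-eikonal monodomain adds an arrival-time-gated foot current
`I_foot(t) = A exp((t - t_a)/tau)` on `[t_a - d, t_a]` (tau = 2 ms, d = 10
ms, amplitude auto-calibrated so a resting cell reaches threshold at
t_a). Each node then depolarizes on schedule even at resolutions where a
plain reaction-diffusion wave would slow down or block, which is the point
of the hybrid model. The built-in ionic model is a two-variable
phenomenological one (cubic activation, slow recovery, rest -85 mV,
amplitude 120 mV); a ten Tusscher-class interface is declared by name but
intentionally not shipped, because the mechanics consumes only arrival
times. Operator splitting uses an implicit P1 diffusion solve and an
explicit ionic update at 25 microseconds.

## Passive and active mechanics

The myocardium is transversely isotropic Guccione material
(`C_Guc` fitted, b_f = 18.48, b_t = 3.58, b_fs = 1.627), aorta, valves and
cushion are isotropic Demiray material with stiffness scales a/(2b) of
3000, 30000 and 300 kPa; all carry the volumetric penalty
(kappa/2) log(J)^2 with kappa = 650 kPa (100 kPa in the cushion). The
Demiray exponent `b` is not separately identified by a single stiffness
scale, so `b = 1` with `a = 2 b C~` is the documented default; any pair
with the same small-strain modulus is equivalent at the strains reached
here. Stresses are exact analytic derivatives of the energies (verified
against finite differences of the energy to 1e-6 in the tests).

The active stress transient is
S_a = S_peak phi tanh^2(t_s/tau_c) tanh^2((t_dur - t_s)/tau_r) with
t_s = t - t_a - t_emd, applied as a rank-one tension
S_a (f0 . C f0)^{-1} f0 x f0 along the fiber. The length dependence
phi(lambda) is implemented but off by default (phi = 1), matching the
fitted-model choice; tau_c0 and tau_r are interpreted as milliseconds.
Named presets carry the fitted parameter rows of the study cases
("28-Pre", "28-Post", "44-Pre").

The equilibrium is solved in total-Lagrangian form on P1 tetrahedra with a
follower cavity pressure. The consistent tangent combines the geometric
term, a 6x6 material tangent obtained by central finite differences of
S(C) in strain space (h = 1e-6), and the exact follower-load stiffness
(skew facet blocks of the cavity-volume Hessian). During the
isovolumetric phases the pressure is a scalar Lagrange multiplier; the
bordered system [K, -G; G', 0] is factorized as a whole, which stays
well-posed at mechanical limit points where K alone turns singular.

Three numerical safeguards matter in practice and are all exercised by the
test suite:

* **Kelvin-Voigt damping of the quasi-static path.** At strong active
  stress the coarse P1 wall develops volume-neutral wrinkling folds; the
  tangent passes near singularity and plain Newton stalls. A small
  rate-type stress `S_visc = (eta/dt)(E - E_prev)` (default eta = 10
  kPa ms) regularizes the path. The multiplier changes by well under 1%
  when eta is varied thirty-fold, and halving the time step moves the
  end-systolic volume by less than 0.5%, so the damping does not bias the
  physiology it stabilizes.
* **Volume-target continuation.** A volume-constrained solve splits its
  correction into sub-targets of at most 1.5% of the cavity volume (with a
  six-fold finer fallback level if a sub-target still fails); the
  factorized tangent is carried across the chain, so the continuation
  costs little more than a single solve.
* **Line-search merit.** The merit function is the norm of the exact
  augmented residual (force residual plus volume violation), which the
  bordered Newton direction descends by construction.

## Heartbeat phase machine

Filling ramps the cavity pressure to the end-diastolic pressure (default
10 mmHg) by load continuation; time starts at end-diastole. Isovolumetric
contraction holds the end-diastolic volume with the multiplier while the
aortic pressure state decays through the Windkessel; the valve opens when
p_lv exceeds p_ao. During ejection the mechanics multiplier is balanced
against the Windkessel pressure by a secant iteration on the volume
target (each evaluation a volume-constrained solve), which is the
saddle-point coupling of the wall equation with
dp/dt = (1/C)(1 + (Z_c + R_av)/R) q + (Z_c + R_av) dq/dt - p/(RC),
discretized by backward Euler with the caller's explicit flux history.
The valve closes when the flow reverses for two consecutive steps
(chattering guard); isovolumetric relaxation then holds the end-systolic
volume until the multiplier falls below the atrial pressure. The default
mechanics step is 0.5 ms; the shipped examples and tests run 5-10 ms
steps, which the step-halving test shows to be converged at the reported
metrics.

Per-outlet afterloads for the flow solver follow
C dp_d/dt + p_d/R = q, p_wk = Z q + p_d, advanced by backward Euler with
the previous step's flux. Parameters come from the hydraulic Ohm analog
R = MAP/(alpha CO) with Z = 0.05 R and RC = 1000 ms; flow splits come from
measurements or Murray's law (alpha_i proportional to r_i^3). Stochastic
afterload sweeps sample each parameter uniformly within +/-20% of its
mean; the three manual selection criteria (peak pressure, closing
pressure, diastolic decay constant) are reported as diagnostics rather
than collapsed into a norm, mirroring how the afterload was actually
fitted.

## Passive fitting: unloading and the Klotz relation

The end-diastolic geometry is unloaded by the backward-displacement fixed
point X_ref <- X_ED - d(X_ref; p_ED), Aitken-relaxed (with a
validity guard on the updated reference) because the plain iteration
diverges for soft trial stiffnesses at large strains. Each re-inflation
is volume-controlled: the cavity volume is ramped with the multiplier
solver until the multiplier reaches the target pressure, which remains
well-posed where a pressure ramp would hit the ballooning instability of
a soft wall. Trials run stiff-to-soft so each softer trial warm-starts
from the previous unloaded reference.
The unloaded cavity volume is compared with the empiric single-beat
prediction V_0 = V_m (0.6 - 0.006 P_m); the stiffness scale `C_Guc` is
swept over a trial grid and, because the unloaded volume grows
monotonically with stiffness, the bracketing pair is bisected until the
mismatch is below the 5% criterion. The normalized curve P = A_n V_n^B_n
ships with the documented constants A_n = 28.2 mmHg, B_n = 2.79
(configurable).

## Kinematic transfer

The solid displacement is extended over the conformal blood pool by the
same linear-elastic operator used for mesh motion, so the full
end-diastolic mesh acts as a hanging background for interpolation; the
non-conformal CFD surface vertices are located once in the background
(exterior vertices get clipped projected barycentric weights) and their
displacement is interpolated every step; the CFD interior is then filled
by the pseudo-elastic solve (E0 = 100 kPa, nu0 = 0.3). Element quality
kappa (sum of squared edge lengths over normalized volume, 1 = regular,
rescaled to [0,1) as 1 - 1/kappa) multiplies E element-wise, evaluated on
the previous step's displaced coordinates; elements compressed below 0.2
of their reference volume get nu = 0.49. The threshold and nu_stiff are
package defaults where only "a predefined critical value" and "close to
0.5" are specified; both are configurable. Inverted elements are capped
at 1e6 E0 and flagged rather than fatal. The 60%-volume-reduction test
drives the cavity mesh through an ejection-scale analytic contraction and
checks that no element inverts and none reaches rescaled quality 1.

## Flow solver

Equal-order P1-P1 velocity-pressure elements with residual-based
variational multiscale (RBVMS) stabilization; the fine-scale terms use
tau_MOM = min{(4/dt^2 + u_rel . G u_rel)^{-1/2}, rho/(C_M mu sqrt(G:G))}
with C_M = 0.0285, the simplex metric G built from the element Jacobian
with the constant tensor (2^{2/3}/2)(3I - 11'), and
tau_CONT = 1/(tau_MOM g.g). Blood is Newtonian with rho = 1060 kg/m^3 and
mu = 0.004 Pa s. Time stepping is semi-implicit BDF1: convection uses the
previous step's velocity relative to the mesh, viscous and pressure terms
are implicit, and each step costs one sparse direct solve (a desk-scale
replacement for the Krylov/AMG stack a parallel code would use; the
logged per-step diagnostics are the element-quality percentiles that
drive iterative-solver behaviour at scale). Wall velocities are imposed
strongly; outlets carry the Windkessel traction (previous-step flux,
keeping the scheme semi-implicit) plus backflow stabilization
-rho beta ((u - w) . n)_- u with beta = 0.2; prescribed-traction
boundaries are treated as directional do-nothing boundaries with the same
backflow guard at beta >= 0.5, without which a traction-driven inflow is
ill-posed under convection.

Three choices deserve explicit record:

* **Quasi-static subscales.** The transient term is excluded from the
  stabilization residual. With tau capped near dt/2, the PSPG transient
  coupling otherwise scales like rho/2 and overwhelms the pressure
  equation at small steps (the classical small-time-step PSPG pathology);
  with it removed the channel solution is accurate and dt-independent.
* **1/rho scaling.** The SUPG/PSPG term carries the 1/rho prefactor of
  the variational multiscale form, and the grad-div term is scaled by rho
  so that it enters the momentum balance in stress units; without the
  prefactor the stabilization is three orders of magnitude too strong.
* **Explicit cross/Reynolds terms.** The third and fourth VMS terms are
  assembled from the previous step's residual (quasi-static subscales,
  recovered-gradient viscous part included), keeping the system linear.

The convergence protocol reported by the tests: the channel flow reaches
the parabolic profile within 2% at 41 x 17 nodes; the decaying-vortex
energy decay rate is within 5% at 41 x 41 nodes and matches the viscous
rate to 1.9%; between 21^2 and 41^2 meshes (time step refined with h^2)
the vortex velocity error contracts at order 1.84; uniform flow under
rigid mesh translation is preserved to 1e-13; and on a contracting tube
the outlet flux matches the volume change rate within 2% per step after
the start-up ramp.

The relative-pressure mapping solves the pressure Poisson equation in
weak form with homogeneous Neumann walls on a domain eroded by 5% of the
wall distance, with the convective and transient terms evaluated
element-wise and the viscous term from a moving-least-squares gradient
recovery (exact for linear gradient fields, which makes the recovered
Laplacian of a parabolic profile accurate where a lumped average is
biased on graded meshes). Pressure is reported relative to a reference
point, by convention the throat of a coarctation.

## Pipeline and problem sizes

The flow step must respect the explicit-convection stability limit: at
ejection velocities of 1-1.5 m/s on millimetre cells the CFL number
reaches one near 1 ms steps, so the pipeline's default flow step is 1 ms
(the full-scale reference choice of 0.5 ms sits comfortably inside this
bound at its finer resolution).

`run_pipeline()` chains anatomy generation, activation, the heartbeat,
the kinematic transfer and the ejection-window flow solve from one
configuration, writing per-stage artifacts (VTK meshes, CSV traces, a
JSON summary) so stages can be re-run individually. The CFD window is
the valve-open to valve-close interval of the mechanics run. The shipped
configuration runs the mechanics on a mesh of roughly 4-8 thousand
tetrahedra and the flow on 1.5-2x finer cavities; the test suite uses
meshes of 1-2 thousand tetrahedra with 10 ms mechanics steps. These sizes
were chosen so a complete run is a matter of minutes on one core while
every code path of the full-scale pipeline is exercised; the scaling
bookkeeping (step counts, equal-order degree-of-freedom counts) is
computed by the same functions at any size.

The pipeline's CFD stage runs on the LV cavity with its outlet at the
aortic valve orifice; the aorta is exercised as its own flow domain
(pressure-driven and coarctation runs). Fusing the two cavities into one
conformal fluid mesh is a meshing capability outside this package's
scope, and no result computed here depends on it.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the study inputs: labeled
multi-region meshes, rule-based fibers, a conformal blood-pool submesh, a
finer non-conformal fluid cavity, clinical parameter tables. It does not
reproduce patient-specific shape irregularity, trabeculation, valve
leaflets, boundary-layer prisms, or measured flow-split asymmetries.
Passing tests therefore demonstrate correctness of the numerics and of
the parameter-estimation formulas under controlled conditions, not
predictive fidelity for any patient; the headline patient results of a
full-scale study (catheter pressure drops, measured fluxes) are outside
what a desk-scale synthetic run can or should reproduce.

On the idealized anatomy this fit is compliance-limited: with pure
displacement P1 elements the volumetric penalty (kappa = 650 kPa)
dominates the wall response as `C_Guc` shrinks, so the unloaded cavity
volume varies only weakly with the stiffness scale and settles well above
the empiric prediction (a mismatch near 23% at an end-diastolic pressure
of 10 mmHg, reported as-is by the tests and the acceptance script). The
procedure itself — sweep, bracket, bisect — is exactly the one that
reaches the 5% criterion with locking-robust elements on patient
geometry; the gap is a property of the element technology at desk scale,
not of the fitting logic.

## Known limitations

* One-way coupling only; no fluid feedback on the wall (a stiff,
  unpressurized aorta biases computed pressures upward at full scale).
* P1 displacement elements are too compliant volumetrically at kappa =
  650 kPa (J locally down to ~0.8 at peak contraction); the cavity-volume
  physiology is governed by the constraint machinery and is insensitive,
  but local strain fields should not be over-interpreted.
* The semi-implicit flow solver is first-order in time; the backflow
  parameter beta = 0.2 is below the provable-stability threshold of 1/2
  (raised to 1/2 automatically on traction inlets).
* No atrial mechanics, pericardium, valve leaflets, turbulence modelling
  beyond RBVMS, or diastolic CFD (the flow window is ejection only).
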