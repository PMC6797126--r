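---
title: "Methods: tape-based AD and Radau collocation for movement trajectory optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tape-based AD and Radau collocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tapetraj)
```

This vignette documents the models, numerical methods and design decisions
behind `tapetraj`. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The algorithmic-differentiation engine

### Recording

`record(fn, x0)` evaluates `fn` at the nominal point `x0` with an
operator-overloaded numeric type. Every elementary operation appends a node
(operation tag, parent ids, nominal value) to a tape. The supported
operation set is deliberately **closed and smooth**: `+ - * / ^ neg sqrt exp
log sin cos tan tanh atan`. Non-smooth primitives (`abs`, `min`, `max`,
`floor`) raise an error at recording time: exact Hessians require twice
continuously differentiable model functions, so any conditional behaviour
must be smoothed upstream (here with hyperbolic tangents, see §4).

Comparisons encountered during recording are evaluated numerically and their
outcomes stored as the tape's *branch signature*. A recorded graph is only
valid while those outcomes hold; `replay()` re-evaluates every recorded
comparison and raises a hard error on any mismatch rather than silently
re-taping. All model functions shipped with the package are branch-free.

### Sweeps

With local partial derivatives attached to each node, a forward sweep
propagates an input-side seed to `J ẋ` and a reverse sweep propagates an
output-side seed to `Jᵀ ȳ`; the identity `⟨ȳ, J ẋ⟩ = ⟨Jᵀ ȳ, ẋ⟩` is tested
on 200 random tapes at `1e-12` relative. Full Jacobians use `n` forward
sweeps when `n ≤ m`, else `m` reverse sweeps; seeding is dense per
column/row (graph-coloring sparsity exploitation is out of scope). For the
NLP callbacks, tapes are evaluated at many points at once (nodes hold one
value per mesh interval) and batches of seeds are propagated through a
level-grouped execution plan in single matrix operations — this is an
implementation detail with no effect on values.

Exact second derivatives use **forward-over-reverse**: `record_vjp()`
re-interprets a tape with overloaded inputs, performs the reverse
accumulation in overloaded arithmetic (recording the reverse sweep itself),
and the resulting vector-Jacobian-product tape is then differentiated by
forward sweeps. `emit_source()` exports any tape as flat single-assignment R
source implementing replay, forward and reverse sweeps; numerical agreement
with the interpreter is the contract, not the textual form.

### Finite-difference comparator

`fd_jacobian()` implements forward differences with step `h = 1e-6` on the
scaled variables (`n + 1` evaluations, counted), matching common NLP-solver
defaults; central differences are available as the higher-accuracy oracle
used in tests.

## 2. Rigid-body dynamics

Both mechanical models are planar kinematic trees evaluated by a generic
pass written against the closed smooth operation set, so the same code runs
on doubles, on complex numbers (the tests differentiate the energies by
complex step to build an independent Lagrangian-form oracle) and on the
tape. Inverse dynamics uses Jourdain's principle: one acceleration pass plus
one unit-velocity pass per coordinate,

`T_k = Σ_b [ m_b (a_b + a_off) · J_bk + I_b α_b Jrot_bk ] − Σ_j F_j · J_jk`,

with `a_off = (A, g)` combining gravity and the prescribed horizontal base
acceleration `A(t)` as a pseudo-force (the pendulum's balance perturbation).

* **Pendulum chain**: `ndof` uniform rods, total height 1.7 m and mass
  70 kg split equally — the torques this produces stay well inside the
  ±1000 N·m bounds. The perturbation is a half-sine backward pulse, peak
  2 m/s² and duration 0.2 s, a representative support-surface translation;
  neither value is prescribed by the task definition, so both are
  configuration parameters chosen once.
* **Gait skeleton**: 10 coordinates (pelvis x/y/tilt, hips, knees, ankles,
  lumbar), 8 segments with anthropometry representative of a 75-kg adult
  generic model. The segment values, muscle attachment points and contact
  constants are a synthetic fixture constructed in code — no quantitative
  claim rests on them, and the acceptance checks are structural
  (dimensions, tolerances, invariants), not anthropometric.

## 3. Muscle model

Activation dynamics follow the activation-rate formulation: the rate
`da/dt = s_da u_da` (`s_da = 100`) is box-bounded through two path
inequalities `0 ≤ s_da u_da + a/τ_d` and `s_da u_da + a/τ_a ≤ 1/τ_a` with
`τ_a = 15` ms, `τ_d = 60` ms, so activation rises no faster than `(1−a)/τ_a`
and falls no faster than `−a/τ_d`.

Contraction dynamics are implicit with the normalized tendon force `F_t`
(bounded `[0, 5]`) as a state and its scaled rate `u_dFt` (`s_dFt = 100`) as
a control. The curve set is a standard twice-differentiable family:
exponential tendon force–length (`kT = 35`, constants 0.200/0.995/0.250),
sum-of-three-Gaussians active force–length, logistic-type force–velocity
(`v_max = 10 l_opt/s`), exponential passive curve (`kpe = 4`, `e0 = 0.6`)
and a small fiber damping (0.1 on the normalized fiber velocity). All
constants are arguments of `muscle_params()` and can be overridden. Fiber
length is recovered from the invertible tendon curve with a
constant-thickness pennation model (`l_M sin α` constant); tendon velocity
follows from the force-rate state through the tendon-curve slope. The
residual

`r = a f_act f_v + f_pas + β ṽ_M − F_t / cos α`

vanishes exactly at fiber–tendon equilibrium and is C² in all arguments.
Tendon slack lengths of the fixture are calibrated so that at the neutral
standing pose each muscle–tendon length equals `l_T,slack + l_opt cos α` —
a convenient normalization that keeps all muscles in a physiological
operating range.

### Polynomial muscle–tendon geometry

Exact via-point lengths are sampled on dense grids over the walking joint
ranges (121 points for 1-dof muscles, 26² for 2-dof) with reference moment
arms by complex-step differentiation. `fit_polynomials()` solves a joint
least-squares problem stacking length rows and moment-arm rows
(`MA = −∂l/∂q`, with the moment-arm rows weighted twice as heavily since
they enter the joint torques directly) and selects the lowest total order at
which *both* the length RMS and every moment-arm RMS meet the 3 mm
tolerance, capped at order 9; requiring the moment-arm RMS too (rather than
length only) is a deliberate choice — with a length-only criterion the
low-order fits can carry several-mm moment-arm errors. At order 9 a fit that still misses the tolerance is an error naming
the worst muscle. Left and right legs share geometry, so right-side fits
are cloned onto left-side coordinates.

## 4. Smoothed compliant contact

Each foot carries two spheres (heel r = 3.5 cm, forefoot r = 3.0 cm,
plane-strain stiffness `k = 2e6 N/m^1.5`, dissipation `c = 2 s/m`, dynamic
friction 0.8, viscous friction 0.5). The normal force is the compliant law
`k δ^{3/2} (1 + 1.5 c δ̇)` with two smoothing devices:

* the positive part of the penetration is `dp = (δ + sqrt(δ² + ε²))/2` with
  `ε = 1e-5` m — C∞, exact to ~0.01% at 5 mm penetration, and decaying the
  airborne leakage far below `1e-6` N one radius above ground;
* the dissipation term is gated by `tanh(300 δ)` and the friction sign by
  `tanh(50 v_x)`, the hyperbolic-tangent replacements for the conditional
  branches of the underlying contact model.

The smooth positive part is used for the magnitude (a tanh gate there would
distort the force at millimetre penetrations by ~10%), tanh for the genuine
conditionals. Both choices keep all force components C², which the tests
verify by step-halving of second differences across touchdown.

## 5. Transcription

`transcribe(ocp, N, make_radau(3))` lays out, per mesh interval: the mesh
state, `d = 3` collocation states at the Radau IIA abscissae
(0.155051, 0.644949, 1), the piecewise-constant controls, and slack
variables for the inequality path constraints; the free final time (when
present) is one appended parameter. Equality rows per interval:

* `n_x · d` collocation rows (differentiation-matrix form of the stiffly
  accurate Radau IIA scheme, exact for polynomials of degree `d`);
* `n_x` continuity rows identifying the next mesh state with the
  interval-end collocation state;
* the equality path constraints — pendulum torque rows, Hill residuals,
  skeleton torque rows — imposed **once per interval** at the interval-end
  collocation state.

Inequality path constraints (the activation-rate bounds) are imposed once
per interval at the mesh state and converted to equalities with bounded
slacks. This layout — continuity rows plus per-interval path constraints —
is the one consistent with the dimension bookkeeping of both problem
families; imposing path equalities at every collocation point, with no
continuity rows, reproduces the pendulum counts too (the two layouts
coincide numerically for `d = 3` when the path-equality count equals the
coordinate count) but not the walking counts, and it leaves the mesh states
dynamically decoupled.

Because the state derivatives are controls (implicit formulation), the
collocation dynamics `ẋ = f(x, u, p)` are **affine**; the transcription
requires this and assembles the collocation/continuity/inequality/boundary
Jacobian blocks as constant sparse matrices (plus the bilinear free-time
coupling `h = t_f/N`). Only the path-equality block and the objective
integrand are taped, recorded once and evaluated vectorized across
intervals. Scaling follows the problem definitions: pendulum `s_q = 3`,
`s_t = 0.2`, `s_T = 500` (velocities scale by `s_q/s_t`, accelerations by
`s_q/s_t²`); walking variables are scaled by the largest bound magnitude so
all scaled variables live in `[−1, 1]`.

The walking objective is normalized by distance travelled; since the
prescribed-speed equality ties that distance to `1.33 t_f`, the
normalization is written as `/(1.33 t_f)` inside the integrand. This is
exact on the feasible set and keeps the objective separable per interval,
which the exact-Hessian assembly exploits (a global post-map would couple
all variables through a dense rank-one block).

## 6. The interior-point solver

`ip_solve()` is a monotone-barrier primal-dual method: Newton directions
from the sparse KKT system (Matrix sparse LU), fraction-to-boundary rule
(`τ = max(0.99, 1−μ)`), an ℓ1 merit line search whose penalty weight is set
from the directional derivative, plus a filter-style acceptance (strict
infeasibility decrease, or barrier decrease at comparable infeasibility)
that avoids Maratos rejections near the solution. Numerical safeguards:

* primal regularization `δ_w` grows geometrically until the direction is a
  descent direction (inertia is not available from the sparse LU);
* dual regularization `δ_c = 1e-8 √μ` vanishes with the barrier parameter —
  a fixed `δ_c` floors the attainable feasibility at `δ_c‖y‖` — and is
  raised adaptively when near-dependent constraint rows make the equality
  multipliers explode;
* the barrier parameter follows `μ ← min(0.2 μ, μ^{1.5})` once the scaled
  KKT error of the subproblem falls below `10 μ`; convergence is declared at
  scaled KKT error `≤ 1e-6` (the NLP relative error tolerance used
  throughout).

The limited-memory mode keeps 6 damped BFGS pairs in compact form and
applies them through a bordered solve (Woodbury identity) against the same
sparse KKT factorization. Exact Hessians assemble per-interval blocks from
forward-over-reverse sweeps of the integrand and path-equality tapes, seeded
only on input dimensions that are ancestors of an output.

## 7. Problem sizes, initial guesses, determinism

Mesh sizes default to 25 intervals (2–6 dof pendulums), 50 (7–9), 100
(10 dof); the walking problem is examined at a reduced mesh in the test
suite (10 intervals for the half cycle) and the transcription's constraint
bookkeeping is additionally checked at 50 intervals. Initial guesses are
deterministic: the pendulum starts from all-zero scaled variables; walking
starts from a kinematic sweep of the half cycle — the pelvis advances at the
prescribed speed at a slightly crouched height, the stance foot stays flat
and stationary on the ground, the swing foot travels one stride with a small
lift, leg angles follow from two-link inverse kinematics, velocities from
finite differences of the pose sequence, activations are 0.1 and tendon
forces at static equilibrium (solved per muscle by bisection). A purely
static standing pose swept forward was examined first and rejected: with
the feet sliding it is dominated by friction-inconsistent torque residuals,
and lifted clear of the ground it sits in a region where the constraint
linearization is inconsistent (no contact gradient), both of which stall
the solver. Seeded
perturbation guesses draw uniformly within 10% of the scaled bound widths.
Identical seeds and options reproduce identical iterate sequences; solution
fingerprints (trajectories rounded to `1e-3` in scaled units, then hashed)
define when two runs found the same optimum, and the benchmark harness
excludes fingerprint mismatches from its ratio statistics, reporting how
many were excluded.

Walking objective weights are `w1 = 1` (cubed activations, the dominant
fatigue-like term), `w2 = 1` (squared trunk excitation), `w3 = 0.05`
(squared scaled accelerations) with a `0.001` penalty on the rate controls
against singular arcs; only the ordering of magnitudes is meaningful.

## 8. What the synthetic fixtures do and do not show

The generator-side fixtures (pendulum parameters, gait anthropometry, muscle
roster and paths, contact constants, perturbation pulse) emulate the
*structure* of the corresponding biomechanical problems — dimensions,
coupling patterns, smoothness, scaling — not any specific subject or
laboratory condition. Passing tests therefore demonstrate correctness of
derivatives, transcription bookkeeping, constraint satisfaction and solver
behaviour on problems of this class; they do not validate the fixture
values against experimental movement data, and quantities that depend on
hardware (CPU-time ratios) or on unavailable experimental data (tracking
accuracy) are reported informationally by the benchmark harness, never
asserted.

## 9. Known limitations

* The interior-point solver is a compact implementation. All nine balance
  problems converge to the full 1e-6 tolerance with it, but on the strongly
  nonconvex walking problem it reaches primal near-feasibility only: at the
  optimum several contact spheres graze the ground, the constraint Jacobian
  is nearly rank-deficient and the equality multipliers become effectively
  unbounded, a degeneracy regime that industrial interior-point codes handle
  with machinery (adaptive barrier strategies, inertia-controlled
  factorizations, specialised restoration) that is out of scope here. The
  walking acceptance test runs the solve under a bounded iteration budget
  and reports the convergence assertion honestly.
* Inverse dynamics costs one kinematic pass per coordinate (Jourdain
  assembly), fine for planar chains up to ~10 dof; recursive O(n)
  algorithms are out of scope.
* Sparse Jacobian seeding is dense per block; graph coloring is a non-goal.
* Forward dynamics integration exists only as a test oracle; the implicit
  collocation formulation makes inverse dynamics the core path.
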