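---
title: "A multibody elbow model for medial collateral ligament deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multibody elbow model for medial collateral ligament deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(elbowmbs)
```

## The question the model answers

The medial collateral ligament (MCL) complex is the primary medial
stabiliser of the elbow. Its anterior bundle (AB, medial epicondyle to
the sublime tubercle) and posterior bundle (PB, medial epicondyle to the
medial olecranon) can be injured in isolation or together. `elbowmbs`
simulates a passive flexion protocol on a rigid multibody elbow under
four ligament states — intact, isolated AB deficiency, isolated PB
deficiency, and complete MCL deficiency — and compares joint kinematics,
articular contact, and the loads carried by the remaining ligaments.

The forearm is held fully pronated with the hand resting on a plate
(a soft six-degree-of-freedom spring to ground), the humerus rides a
vertical prismatic joint, and flexion is produced by driving the humeral
head 345 mm downward over 40 s. Constant stabilising muscle tensions of
40 N (triceps) and 20 N (brachialis) act throughout; no external valgus
torque is ever applied. Kinematics are decomposed in a clinical joint
coordinate system and sampled every 2 degrees of flexion from 50 to 130
degrees (40 samples per condition), and the conditions are compared by
one-way ANOVA with Tukey–Kramer pairwise tests at p <= 0.01.

## Model components

### Articular contact

The humeral cartilage (trochlea and capitellum) is discretized into
elements of approximately 5 x 5 mm. Each element exerts a normal force
on the opposing cartilage (sigmoid notch of the ulna; radial head dish)
through a modified Hertzian law

  F_c = k_c * delta^n + B_c(delta) * delta_dot,

with penetration delta (mm). The damping coefficient ramps as a cubic
smoothstep from 0 at first touch to `Bmax` at penetration `dmax`, so
contact forces are continuous when elements make or break contact.
Defaults: k_c = 126 N/mm (ulnohumeral), 105 N/mm (radiohumeral), n = 1,
Bmax = 2 Ns/mm, dmax = 0.1 mm.

`foundation_stiffness()` exposes the elastic-foundation route to the
contact stiffness: a thin incompressible-ish cartilage layer of combined
thickness h gives pressure-per-deformation `(1-nu) E / ((1+nu)(1-2nu) h)`,
which times the 25 mm^2 element area yields a per-element stiffness.
With the standard material values (E = 0.7 MPa, nu = 0.495, h = 4 mm)
the formula gives 147.8 N/mm. The calibrated 126/105 N/mm defaults stem
from prior model-to-experiment tuning and are deliberately not derived
from the formula; both paths are exposed and neither is reconciled to
the other.

### Ligaments

Each complex is a set of tension-only bundles (3 MCL-AB, 3 MCL-PB,
3 LUCL, 3 RCL, 2 annular; 14 in total) with the quadratic-toe /
linear force-strain law (`bundle_elastic_force()`), toe parameter
eps_l = 0.03, and a 0.5 Ns/mm parallel damper. The LUCL wraps around the
radial head (sphere primitive) and the annular bundles encircle it
(cylinder primitive) so their lines of action stay anatomical; the MCL
bundles run straight. Zero-load lengths are set from the generated
geometry at the reference pose through per-complex reference strains —
a reproducible stand-in for cadaver-specific zero-load-length protocols.

Per-bundle stiffness parameters are calibration values, chosen once so
that the intact simulation produces per-complex peak strains in the
0.10–0.50 band and AB peak loads exceeding PB peak loads, and so that
either MCL bundle alone maintains medial stability (the isolated
deficiencies must be mild while the complete deficiency is not). They
are configuration defaults, not tissue ground truth.

### Bodies, joints, drive

Humerus: prescribed (prismatic, vertical). Ulna, radius: free 6-DOF
rigid bodies. Hand: spherical wrist joint to the radius (position
eliminated), orientation free, tied to ground by the plate bushing
(1 N/mm translational, 0.1 N mm/deg rotational — soft stabilisation).
Gravity acts on the forearm segments (ulna 0.80 kg, radius 0.40 kg,
hand 0.45 kg, standard anthropometric scale); an interosseous membrane
and a distal radioulnar tie (30 N/mm) keep the forearm working as a
unit. The membrane is on by default: the modelled protocol relies on
the forearm moving as one pronated unit, and without a distal tie the
two bones scissor unphysically.

### The quasistatic solve

At 8.6 mm/s the drive is quasi-static: inertial and damping forces are
orders of magnitude below the elastic ones. The solver therefore
advances the prescribed displacement in increments (default 120) and
solves each step as a static equilibrium of the 15 free coordinates by
minimising the total potential (contact + ligament strain energy +
constant-tension muscle potential + gravity + bushing) with analytic
gradients; a step is accepted when the generalized-force residual is
below 1e-3 N. Around contact make/break and the medial-opening
snap-through the solver halves the drive increment adaptively and, if a
quasi-Newton stage stalls near a fold, follows the softest Hessian
eigenmode downhill — the standard continuation trick for snap-through.
Rates (penetration, ligament lengthening) are recovered by finite
differences between accepted steps and included in the reported forces.
A dynamic mode (`deSolve`-based stiff integration, `dynamic_settle()`)
cross-checks equilibria.

Degenerate inputs are handled explicitly: separated contacts carry zero
force; slack bundles carry zero force regardless of the damper (a
ligament cannot push); a wrap whose chord clears the primitive falls
back to the straight segment; sub-element surfaces collapse to a single
element with a warning.

### Kinematics

Anatomical frames are built from landmarks (trans-epicondylar flexion
axis on the humerus; long axes on ulna and radius), and relative poses
are decomposed Grood–Suntay-style: flexion about the humeral axis,
varus–valgus about the floating axis, axial rotation about the distal
long axis; translations are projections on the same triad. Signs follow
the clinical convention for a right arm: positive = internal rotation,
valgus, superior, anterior, medial. The decomposition warns near gimbal
lock (|varus-valgus| near 90 degrees) and `compose_jcs()` inverts it
exactly, which the round-trip tests exercise on random poses.

Flexion resampling uses the half-open grid [50, 130) at 2-degree
spacing, which yields exactly the 40 samples per condition the
statistical procedure expects; a closed grid would give 41. Local
flexion reversals during snap-through are handled by interpolating on
the monotone non-decreasing envelope of the flexion history.

### Statistics

`one_way_anova()` computes the classical between/within decomposition
from the defining formulas; `tukey_kramer()` computes the studentized
range statistic with the Kramer unequal-n correction and takes p-values
from R's studentized range distribution. Pairwise comparisons are
restricted to each deficiency against intact. The 40 grid points of a
condition are serially correlated along the flexion arc; treating them
as independent samples (as the protocol prescribes) overstates
significance, and every report carries that caveat.

## The synthetic elbow

No subject geometries are distributed with the protocol, so
`generate_elbow()` builds a parametric right elbow from a seed:

- trochlea: a grooved spool about the trans-epicondylar axis (cosine
  groove, lips at `trochlea_radius` + cartilage), with the groove
  spiralling laterally by `groove_spiral` (3.5 mm/rad) beyond 80 degrees
  of arc, the total travel saturating smoothly at `groove_spiral_max`
  (4 mm) so the track straightens again toward terminal flexion;
- sigmoid notch: the congruent concave spool, offset by the articular
  clearance (0.15 mm), wrapping 190 degrees (the long olecranon /
  coronoid hook is what lets the seated joint resist axial tilt);
- capitellum: a sphere sector; radial head: the matching concave dish;
- a 14-bundle attachment atlas placed qualitatively (epicondylar
  origins, sublime-tubercle/olecranon/supinator-crest insertions) with
  small seeded scatter, since bundle-level attachment coordinates are
  not available anywhere;
- landmarks sufficient to construct all anatomical frames.

The groove spiral is the key functional feature. Anatomically the
trochlear track is oblique, which is why the carrying angle changes
with flexion. Here it means that beyond ~80 degrees the congruent track
steers the forearm laterally while the plate holds the hand, so a
valgus/internal-rotation load develops on the medial soft tissues
without any applied valgus torque — the same boundary-condition-induced
loading as the in-vitro protocol. With the MCL intact the joint tracks
within a couple of degrees; with both bundles sectioned the medial side
opens, and the ulna pivots about the intact lateral column
(radiocapitellar contact plus LUCL/RCL): large internal rotation, large
lateral translation, medial contact loss, preserved radiocapitellar
contact, partial reduction toward terminal flexion — and no complete
dislocation.

Default study conditions: initial flexion 49 degrees, carrying angle
12 degrees, 345 mm / 40 s drive, 120 drive increments, elbow-to-wrist
distance `ulna_length - 25` mm. The initial flexion default sits a few
degrees above the drive's nominal geometry so that soft-tissue settling
and the deficiency-induced reconfiguration still leave every condition
covering the full 50–130 degree analysis window; the windowed analysis
is insensitive to the exact starting angle.

What the generator deliberately does **not** emulate: subject-specific
bone shape (and hence any of the printed per-specimen kinematic or
pressure magnitudes), the joint capsule and the full muscle complement,
deformable cartilage, and pronation–supination freedom (the forearm is
built fully pronated). Passing tests therefore show that the
implementation reproduces the *mechanistic pattern* of MCL deficiency —
severity ordering, load redistribution, medial contact loss with a
preserved lateral column, absence of complete dislocation — on a
controlled geometry, not that it predicts any individual's joint.

## Numerical choices

- Continuation with 120 drive increments keeps flexion resolution under
  ~1 degree per step; tests and the acceptance analysis use this size,
  which resolves the 2-degree sampling grid comfortably.
- Contact sector edges (notch rim, dish rim) are tapered by a short
  smoothstep window so the energy stays C1 when elements cross a rim.
- Rotations use incremental rotation vectors, rebased every accepted
  step; gradients carry the exact SO(3) chart correction.
- Equilibrium tolerance 1e-3 N (forces) with torques scaled by 1/100 mm;
  the plate statics oracle reproduces its closed form to 0.1%.
- Ties in flexion resampling resolve by averaging (`ties = mean`), and
  only the monotone envelope of flexion is interpolated.
- "Dislocation candidate" is defined at two levels: per step, a whole
  compartment separated beyond `separation_bound` (10 mm default) is
  flagged in the trace while the run continues; per scenario, the flag
  requires loss of contact on more than 90% of a compartment's elements
  over a contiguous flexion span exceeding 10 degrees. Neither fires in
  the four calibrated study conditions: the joint distracts medially but
  never dislocates.

## Known limitations

- The synthetic articulation is smooth and symmetric apart from the
  groove spiral; real notches are less congruent at the extremes of
  flexion, so absolute contact areas and pressures are only
  order-of-magnitude realistic (intact peaks sit in the literature's
  0.5–5 MPa range).
- Single-primitive wrapping (sphere/cylinder per bundle) approximates
  the lateral-side lines of action; multi-obstacle wrapping is not
  implemented.
- The quasistatic solver reports equilibria; rate-dependent phenomena
  (the damper terms) only shape the reported forces, not the path.
- The ANOVA treats serially correlated flexion samples as independent,
  by protocol fidelity, as noted above.
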