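---
title: "Simulating monoflagellate pullers in shear flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating monoflagellate pullers in shear flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promaswim)
```

# The model

`promaswim` simulates an idealised monoflagellated swimmer — a "virtual
promastigote" patterned on *Leishmania mexicana* — in Newtonian Stokes flow.
The swimmer is a prolate ellipsoidal body (major/minor axes 11 and 3.5 um by
default) with a flagellum of fixed arclength L = 13 um attached at the
swimmer-frame origin `x0`. The flagellar centerline beats as a prescribed
planar travelling wave,

$$x_1 = \xi,\qquad
  x_2(\xi, t) = A\left[\sin\!\left(\tfrac{2\pi}{\lambda}\xi + 2\pi f t\right)
  - \sin(2\pi f t)\right],\qquad x_3 = 0,$$

with amplitude A = 1.8 um, wavelength lambda = 13 um and frequency
f = 28 Hz. The subtraction pins the base to the body for all time; the wave
travels tip-to-base, which makes the swimmer a hydrodynamic puller (the
reversed wave gives the morphologically identical pusher). The parameter
bound `xi_star` is recomputed at every instant so the centerline arclength
is exactly L: the beat stores no length in the flagellum.

At micrometre scales inertia is negligible and the flow obeys the
incompressible Stokes equations. The swimmer is force- and torque-free
(neutrally buoyant); background flows are linear shears, either bulk
(`u_b = gamma_d (x2, 0, 0)`) or wall-bounded
(`u_b = gamma_d (0, -x1, 0)`, vanishing on the no-slip plane `x1 = 0`).

# Surface construction

The surface is one watertight triangulated mesh built in three patches:

* the body spheroid, meshed on polar rings equispaced in meridian
  arclength, with a circular hole around the flagellar pole;
* the flagellar tube of radius 0.25 um, with circular cross-sections
  erected on the planar-curve normal and binormal of the centerline (the
  beat is planar, so no frame twist arises) and a fan-capped distal tip;
* a zipper band joining the hole ring (2 n_c vertices) to the proximal
  tube ring (n_c vertices).

The flagellar radius is not a measured quantity; 0.25 um (a typical
axonemal scale) is the default and configurable. Stitching the tube
directly into a hole in the body surface — rather than overlapping two
closed surfaces — gives Euler characteristic 2 and exactly two triangles
per edge at every beat phase, which the test suite asserts. All quads are
split by a centre vertex into four triangles; together with azimuthal node
sets symmetric under reflection through the beat plane this makes the
discrete surface mirror-symmetric, so planar configurations stay planar to
solver precision rather than drifting at mesh-asymmetry order.

Tube nodes are material points: they sit at fixed fractions of arclength
and fixed azimuth, with positions found by inverting the arclength map by
Newton iteration on a Gauss-Legendre quadrature grid. Beat velocities are
central finite differences of node positions over `dt_frac` of a beat
period (default 1e-3); the suite verifies second-order convergence in
`dt_frac`.

Refinement levels 0/1/2 give roughly 290/660/2700 elements; level 1 is the
default working resolution (about 644 elements) and level 0 is used for
phase-plane sweeps where thousands of solves are needed.

# Boundary-element formulation

The disturbance velocity is represented by a single-layer potential over
the swimmer surface,
$$u_d(x) = \frac{1}{8\pi\mu}\int_S G(x, y)\, q(y)\, dS(y),$$
with G either the free-space Oseen tensor or the Blake image system for a
no-slip plane wall. Because the beat is kinematically prescribed and
volume-conserving to mesh tolerance, the double-layer term of the boundary
integral representation need not be assembled; the density q is a
viscosity-scaled traction whose surface integrals give the hydrodynamic
load exactly. The interior-pressure null vector of the single-layer
operator (a density along the surface normal) is removed by rank-one
deflation, which selects the member of the solution family with zero
normal moment without biasing the rigid-body velocities.

Discretisation is piecewise-constant (BEM0) with collocation at element
centroids. Self-element integrals use a Duffy-type polar split at the
collocation point (3 subtriangles x 8x8 Gauss-Legendre, the radial
Jacobian cancelling the 1/r singularity); neighbouring elements within 1.5
diameters are integrated by recursive four-way subdivision to depth 3; all
other pairs use a 7-point degree-5 triangle rule. The mobility system
appends the six rigid-body unknowns (U, Omega) and the force/torque
balance rows and is solved densely by LU. The wall variant adds the Blake
image correction, whose singularity sits at the mirrored source and is
handled by the same subdivision criterion applied to the mirrored
collocation point.

Verification in the test suite: Stokes drag on a sphere to 2% at ~300
elements with monotone mesh convergence, advection of a force-free sphere
by uniform flow, rotation at half the vorticity in shear, Jeffery's
rotation-rate formula for a passive prolate spheroid to 2%, machine-level
vanishing of the Blake velocity on the wall plane, Lorentz reciprocity of
the image system, and exact affinity of (U, Omega) in the shear rate.

# Time stepping and reduced dynamics

Trajectories advance by Heun's explicit trapezoidal method; orientations
are unit quaternions updated by the quaternion exponential of the angular
velocity and renormalised each step. The default step is one hundredth of
a beat period. Near a passive wall a run halts when the surface comes
within 2 nm of the boundary.

Phase averaging freezes the configuration and averages (U, Omega) over
equispaced beat phases (20 by default). Two exact properties of Stokes
flow make sweeps cheap, and both are verified rather than assumed:

* the response is affine in the shear rate, so solves at gamma = 0 and 1
  determine every shear rate;
* at frozen orientation the zero-shear swim contribution is
  theta-independent in the swimmer frame, so one assembly per beat phase
  serves all orientations through rotated right-hand sides.

The bulk reduced system is the single clockwise angle theta between the
swimmer axis and the flow axis; the wall reduced system is (theta, h) with
h the separation of `x0` from the wall. In both, positive shear gives
thetadot > 0 away from boundaries. Near-wall configurations whose surface
would cross the wall at any sampled phase are flagged geometrically
invalid via the support function of the beat-swept surface; the default
wall grid is bounded away from the wall by roughly a beat amplitude, below
which phase averaging is unreliable.

Rotation periods integrate d(theta)/thetadot over a periodic cubic
interpolant; the effective Jeffery aspect ratio r is fitted to periods at
several shear rates through T = (2 pi / gamma)(r + 1/r), inverting each
point in closed form and polishing by least squares. Saddles of the wall
field are found by damped multistart Newton iteration on a tensor
(periodic-in-theta, natural-in-h) cubic interpolant and classified by
finite-difference Jacobian eigenvalues; separatrices integrate the stable
manifold backward in time from small displacements along the stable
eigenvector.

# The repulsive wall

Steric wall repulsion acts per unit area along the outward wall normal,
$$f_{wall}(s) = g\,\frac{\mu}{T_d}\,\frac{e^{-s/l}}{1 - e^{-s/l}},$$
with g = 1250, decay length l = 0.2 um and T_d the beat period. The
density is integrated element-wise over the surface at centroid
separations — consistent with the piecewise-constant traction space — and
enters the solve as a rigid-body external load; the swimmer is not
deformed. Hybrid long-time runs near a repulsive wall step the full
boundary-element system whenever the surface is within three decay
lengths (0.6 um) of the wall and integrate the phase-averaged reduced
system otherwise: repulsion is negligible beyond a few decay lengths,
while phase averaging is unreliable within a beat amplitude of the wall,
and the full solver covers the overlap.

# A documented inconsistency, and speed matching

With the beat parameters above taken literally, the virtual promastigote
swims at about 14-16 um/s in free space: the phase-averaged velocity at
frozen orientation is 15.9 um/s (mesh levels 0 and 1 agree to 0.5%, and
an independent resistive-force estimate gives the same scale), and the
net displacement over one stepped beat — which includes the yaw wobble of
the attachment point — gives 14.2 um/s. Speeds of 1.5-2 um/s — the scale usually quoted for this
morphology, and the scale at which a wall saddle appears near shear rates
of order 1/s — correspond to exactly one tenth of this, i.e. to beat
frequency 2.8 Hz instead of 28 Hz: by Stokes linearity and kinematic
scaling, every active velocity component is exactly proportional to f
while the passive shear response is f-independent. The package therefore
keeps the literal defaults, and exposes the exact identity through
`scale_swim_speed()`: rescaling the swim components of a stored phase
field reproduces, without new solves, the reduced dynamics of the same
swimmer at any beat frequency. Wall phase-plane analyses that presume a
slow swimmer (free-space speed ~1.6 um/s) are run on fields rescaled by
0.1 and say so explicitly. Equivalently, the fixed-point structure of the
fast swimmer at shear rate 10 gamma is identical to that of the slow
swimmer at gamma up to a uniform rate factor of 10.

For the slow-matched swimmer the wall system at gamma = 1 1/s has a saddle
(real eigenvalues of opposite sign) with separation h* of a few
micrometres, sitting within a few degrees of theta = pi/2 modulo the
mirror; under shear reversal it maps to 2 pi - theta* exactly, which the
suite checks. The critical shear is operationalised as the smallest rate
at which h* drops below one beat amplitude A (the configuration-space
floor of reliable phase averaging): the printed criterion is qualitative,
so the threshold is an explicit, documented knob.

# Numerical choices and problem sizes

Orientation sweeps use 36 angles x 20 phases at level 1 for
aspect-ratio fits, and 24 x 12-ish grids at level 0 for wall fields; the
test suite uses smaller grids (12-16 angles, 6-10 phases, level 0) chosen
to resolve the quantities they assert while keeping the default run at
desk scale. Body-scale sweeps hold the flagellum and beat fixed and scale
both body axes; the mesh topology is fixed per refinement level, so
scaled bodies refine naturally. The hybrid wall runs use dt of 1/60 of a
beat period during full-solver segments.

Known limitations: the beat is kinematically prescribed (no
elastohydrodynamics); the beat plane is the shear plane (planar reduced
dynamics; out-of-plane rotations are not explored); no Brownian motion,
inertia, or swimmer-swimmer interactions; a single planar boundary. The
synthetic study conditions emulate idealised morphology and a clean
single-harmonic beat — real promastigote beats are irregular, their
bodies asymmetric, and midgut rheology non-Newtonian, so passing tests
demonstrate correctness of the model's numerics, not fidelity of the
model to in-vivo swimming.
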