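---
title: "Receptor-mediated nanoparticle wrapping: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-mediated nanoparticle wrapping: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npwrap)
```

## The model

`npwrap` simulates the early, receptor-driven stage of nanoparticle uptake
by an endothelial cell.  A rigid sphere of radius $a$, uniformly coated
with ligands at density $\xi_l$, sits above a cell whose surface is an
axisymmetric, inextensible, bending-elastic membrane (bending modulus $B$,
far-field tension $T_0$) resting on the cytoplasm, modeled as a
Kelvin--Voigt foundation: a spring of stiffness $K = E/a$ in parallel with
a damper $M = \mu/a$, acting vertically.  Ligands bind membrane receptors
(density $\xi_r$) and the bonds act as linear springs (stiffness $\kappa$,
rest length $\lambda$) pointing towards the particle center.  A screened
contact repulsion $(\gamma/l)(1/l + 1/\tau)e^{-l/\tau}$ prevents
interpenetration.  Active cytoskeletal forces are outside the model, which
therefore describes only the first seconds to a minute of uptake.

Three coupled problems are advanced in time:

1. **Bond kinetics.** The local bond density obeys
   $\partial_t \xi_b = K_f(\xi_l-\xi_b)(\xi_r-\xi_b) - K_d \xi_b$ with a
   Bell dissociation rate
   $K_d = K_d^{(0)} \exp\{\kappa |l-\lambda| x_b / k_B T\}$: both
   stretched and compressed bonds break faster.  With the geometry frozen
   over a step this is a constant-coefficient Riccati equation; the
   update uses its closed-form solution (`advance_bond_density()`), which
   preserves the admissible interval $[0, \min(\xi_l,\xi_r)]$ for any
   step size and is evaluated in an overflow-safe form (the Bell factor
   can reach $e^{700}$).

2. **Membrane equilibrium.** Force balances tangential and normal to the
   membrane, with thin-plate moment relations, reduce to two equations
   for the inclination $\theta(s)$ and tension $T(s)$, driven by the
   bond, repulsion and foundation stresses.  The transverse shear is
   $V = -B(\theta'' + \cos\theta\,\theta'/r - \sin\theta\cos\theta/r^2)$,
   independent of the Poisson ratio, which enters only the edge
   condition $M_s = 0$.  Because $s$ is material arc length of an
   inextensible sheet, $R' = \cos\theta$ and $Z' = \sin\theta$.
   Boundary conditions: $\theta = \theta'' = 0$ and $R = 0$ on the axis;
   $Z = 0$, $M_s = 0$ and $T\cos\theta - V\sin\theta = T_0$ at the outer
   edge $s_{max}$ (20 particle radii by default).

3. **Particle balance.** The elevation $Z_0$ solves the implicit vertical
   balance between an optional applied force $F_v$ and the integrated
   vertical components of bond and repulsion stresses.  Both components
   carry $\cos\alpha$ ($\alpha$ = bond angle from the vertical); membrane
   wrapped past the equator contributes with its signed measure
   $2\pi R\cos\theta\,ds$.

### Penetration depth

The depth is tied to the wrapping geometry.  With a spherical contact
zone of radius $a + \lambda$ joining a flat outer membrane, the particle
elevation and wrapping angle satisfy $Z_0 = (a+\lambda)\cos\alpha$, so

$$ d \;=\; a\,(1 - \cos\alpha) \;=\; a\left(1 - \frac{Z_0}{a+\lambda}\right). $$

$d = 0$ at the initial elevation $Z_0 = a + \lambda$, $d = a$ at
equatorial wrapping and $d = 2a$ at full engulfment; $d/(2a) = 1$ defines
"internalized".  Simulated wrap angles agree with this mapping (e.g.
$\alpha = 127^\circ$ measured on a snapshot where the metric gives
$d/(2a) = 0.86$, against $a(1-\cos\alpha)/(2a) = 0.80$).  The
alternative reading of $d$ as the raw descent $(a+\lambda) - Z_0$ is
inconsistent with $d = a(1-\cos\alpha)$ and overstates the depth by the
factor $(a+\lambda)/a$, which reaches $2\times$ for a 20 nm particle.

## Unit system

All internal arithmetic is nondimensional: lengths in units of $a$,
densities in $\xi_l$, times in the viscoelastic time $\mu/E$ (about 1 s),
stresses in $\sigma^* = \xi_l k_B T / x_b \approx 10^4\,$Pa — the stress a
fully bound patch exerts at the thermal elongation $k_B T/(\kappa x_b)$.
The solver coefficients are the dimensionally consistent reductions:
bending $B/(\sigma^* a^3)$, foundation $E/\sigma^*$, tension
$T_0/(\sigma^* a)$, repulsion $\gamma/(\sigma^* a^2)$, and the combined
bond-stress/Bell coefficient $C_K = \kappa a x_b / k_B T$.

A caution for anyone comparing with the original tabulation of "typical
values" of these groups: the printed definitions each carry an extra
factor $1/\kappa$ and are therefore not pure numbers (they equal the
consistent values divided by the numeric value of $\kappa$ in N/m,
i.e. appear $100\times$ larger).  We verified by direct experiment that
scaling the three mechanical resistances up by factors of 2–100 relative
to the consistent reduction suppresses internalization at *every* particle
radius, so the consistent set — under which the reported phenomenology
(fast wrapping over seconds, size-dependent feasibility) does occur — is
used throughout.  `nondimensionalize()` still reports the conventional
group values for reference.

## Discretization and solver

* **Grid.** Material arc length is discretized with the graded law
  $\Delta s = 0.04\,a/g(s)$, $g(s) = 1 + 10e^{-s^2/2a^2}$: ten times finer
  under the particle than at the far edge ($\approx 816$ nodes for
  $s_{max} = 20a$).  A desk-scale mode (`coarse = TRUE`: spacing doubled,
  $s_{max} = 10a$, 284 nodes) is used for parameter sweeps; refining from
  it to the production grid changes the final depth of a reference run by
  about 1%, well inside the 5% reproducibility band we target.

* **Box scheme.** The equilibrium equations are integrated as a
  first-order system in $(\theta, \theta', \theta'', T, R, Z)$ at cell
  midpoints with compact two-point stencils.  Solving the projected
  force-balance pair for the highest derivatives gives
  $T' = -(\cos\theta\,A_0 + \sin\theta\,B_0)$ and
  $B\theta''' = \cos\theta\,B_0 - \sin\theta\,A_0$ with determinant $-B$,
  always invertible.  Nodal collocation with a centered tension stencil
  is *exactly singular* at the flat state (odd–even decoupling of $T$);
  the box form has no spurious modes and is second order on the graded
  mesh.

* **Implicit step.** Each time step first advances the bond field in
  closed form with frozen geometry (the splitting order used in the
  source model), then solves membrane shape, tension and particle
  elevation together by one damped Newton iteration on the full
  unknown vector (arrow-sparse Jacobian: block-bidiagonal shape rows
  plus one dense particle row/column, assembled by finite differences
  over a graph coloring of the sparsity pattern, factorized by sparse LU
  with row equilibration).  The factorization is reused across steps
  while contraction stays fast.  The vertical damper is discretized
  backward-Euler against the previous time level, so the only time
  derivative in the mechanics is unconditionally stable.

* **Adaptive step.** $\Delta t \le 2\Delta t_{prev}$, capped at 0.05 time
  units, halved until no *growing* bond density changes by more than 2%
  of its local value (with a $10^{-3}\xi_l$ reference floor) or
  $0.02\,\xi_l$ absolute.  Early steps come out at $10^{-7}$–$10^{-6}$
  time units, late steps at the 0.05 cap, matching the magnitudes the
  source reports.  Decaying densities are exempt: bonds expelled from the
  contact zone die at the Bell rate (up to $10^7$ per time unit), their
  decay is integrated exactly by the closed form, and throttling the
  global step to that rate would freeze the simulation.

* **Snap-through.** As wrapping passes the equator the smooth equilibrium
  branch repeatedly folds (the neck between the wrapped zone and the
  outer membrane reorganizes).  At a fold the Newton iteration either
  stalls or converges onto a mesh-scale-oscillatory branch, recognized
  by the second difference of $\theta$ exceeding 0.35 rad (resolved necks
  stay below ~0.15; spurious branches exceed 0.7).  Such steps are
  rejected and dt is refined; if only rough solutions remain at the dt
  floor, the fold is traversed by a damped episode — implicit micro-steps
  with a temporary rotational dashpot on $\theta$ — followed by one exact,
  dashpot-free implicit step across the episode duration, so every state
  in the recorded trajectory satisfies the unmodified equations.  If no
  smooth post-snap solution exists the run is reported as `arrested`
  (wrapping front stuck at the fold), which is treated as terminal
  equilibrium.

* **Tolerances.** Newton accepts at a residual max-norm of $10^{-9}$
  (stress units) with $10^{-10}$ on the particle balance; a stagnated
  iterate below $10^{-6}$ is accepted in stiff steps because the
  attainable floor scales as $(E/\sigma^*)/\Delta t$ in double precision.
  The run ends when $d/(2a)$ changes by less than $10^{-4}$ (relative,
  with a 0.01 floor) over a one-time-unit window, or at `t_max` (60 time
  units by default; equilibria are typically reached well before 40).

## Initial conditions and what the simulations emulate

Runs start from a flat membrane, tension $T_0$, the particle resting one
bond length above the surface ($Z_0 = a+\lambda$), and a weak triangular
seed $\xi_b(s,0) = 0.01\,\xi_l(1 - 5s/a)$ for $s < 0.2a$ — the state of a
particle freshly captured by a few bonds.  Because early bond formation
is fast, the seed's precise shape is quickly forgotten.  The defaults are
the best-estimate values for anti-ICAM-1-coated particles on inflamed
endothelium (Table of `default_parameters()`): these are the study
conditions for every experiment in the package.  The model represents a
passive, axisymmetric, single-particle encounter; it does not emulate
receptor depletion by neighboring particles, membrane reservoirs and
stretching, cytoskeletal remodeling, or flow — so agreement of the tests
with the model says nothing about those aspects of real uptake.

## Numerical choices that were genuinely open

* Poisson ratio $\nu = 0.5$ (incompressible bilayer); it only enters the
  edge moment condition and is exposed as a parameter.
* Tension is initialized to $T_0$ and its sign is never constrained.
* The gap floor ($10^{-4} a$) below which the repulsion law is continued
  linearly (keeping its slope) exists only so that interpenetrating
  Newton iterates feel a smooth, strong restoring stress instead of a
  $1/l^2$ singularity with a dead zone.
* The step cap of 0.05 time units bounds the backward-Euler damper error
  near equilibrium, where the bond criterion alone would let the step
  grow without limit.
* Desk-scale problem sizes: sweeps run on the coarse grid and stop at the
  internalization crossing when only the crossing time is needed; the
  reference single run uses the production grid law.

## Known limitations

* The tabulated nondimensional "typical values" of the source cannot be
  reproduced from its own dimensional parameters (see *Unit system*);
  with the consistent reduction the binding drive is 1–2 orders above
  the mechanical resistances, so wrapping is strong, and the size
  selectivity of internalization is weaker than reported: in our sweeps
  small particles down to 20 nm still internalize (bending slows but
  does not stop them), the upper feasibility boundary falls near 50–60 nm
  rather than 110 nm, and the internalization time grows with the bond
  formation time with a coefficient of order ten above a viscous floor of
  about 1.5 time units, rather than purely proportionally with
  coefficient ~25 — the dynamics here are cytoplasm-limited rather than
  bond-limited.  The acceptance tests assert the source's printed values
  for these quantities and deliberately stay red where the consistent
  model disagrees.
* Beyond $d/(2a) \approx 1$–1.2 the neck reorganizes through repeated
  snap-through events; integration there relies on the traversal
  procedure above, and deeply engulfed states (neck closure,
  scission) are outside the model.
* The Kelvin–Voigt foundation is attached: membrane lifted above the
  plane is pulled back down.  This is as printed in the source equations,
  but it means the "cytoplasm" also acts as glue, which matters at the
  neck.
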