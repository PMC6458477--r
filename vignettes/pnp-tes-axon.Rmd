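---
title: "Electrodiffusion modelling of transcranial stimulation at a node of Ranvier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrodiffusion modelling of transcranial stimulation at a node of Ranvier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pnpaxon)
```

## The model

`pnpaxon` simulates how a weak, externally applied electric field — the kind
delivered by transcranial electrical stimulation (TES/tDCS) — polarizes the
membrane of a myelinated axon at a node of Ranvier, and what that does to
voltage-gated channel states, transmembrane ionic flux and intracellular
calcium.

Four ion species (Na\\(^+\\), K\\(^+\\), Ca\\(^{2+}\\), Cl\\(^-\\)) obey the
Nernst–Planck equation on the intracellular and extracellular regions,

\\[ \partial_t n_i + \nabla\cdot F_i = 0, \qquad
   F_i = -D_i\,(\nabla n_i + n_i \alpha_i \nabla\phi), \qquad
   \alpha_i = z_i F/(RT), \\]

with the electric potential set self-consistently by the Poisson equation
over the whole domain (including the membrane, which carries no mobile
ions),

\\[ \nabla\cdot(\varepsilon \nabla\phi) = -F \textstyle\sum_i z_i n_i . \\]

The domain is a 2D Cartesian slice, 4 µm long and 2 µm high: intracellular
space below (half-height 0.434 µm, the lower edge is the axon midline),
membrane above it, extracellular space on top.  The membrane is 0.406 µm
thick (myelin) except at the central 1 µm node of Ranvier, where it thins
to 5 nm and the extracellular space dips down to it.  Transmembrane
transport happens only on the nodal membrane, as a flux boundary condition
of Hodgkin–Huxley form on both faces of the thin membrane (mass leaves one
region and enters the other, never created): per ion,

\\[ f_i = \frac{g_i\,p_i(m,n,h)\,(V - E_i)}{z_i F}, \qquad
   V = \phi_I - \phi_E, \\]

with open probabilities \\(m^3h\\) (Na), \\(n^4\\) (K), \\(m\\) (Ca — the
calcium channel shares the activation gate), and a passive chloride leak.
Reversal potentials \\(E_i\\) are Nernst potentials recomputed from the
local concentrations at every membrane site and outer step.  The gates
follow the classic rate equations \\(\dot g = \alpha_g(V)(1-g) -
\beta_g(V)g\\), integrated per site with `lsoda` capped at the inner step
(0.0005 ms).

TES enters purely through the boundary: the left extracellular edge is held
at 0 V until `t_tes_on` (2 ms) and at 0.1 V afterwards; the right edge is
grounded; the extracellular top edge pins all concentrations at their bulk
values (a reservoir); every other boundary is closed.

## Membrane kinetics: the rate registry

The exact rate constants behind the reference model are not part of its
printed description, so the package carries them in a single
config-overridable registry.  The defaults are the classic squid-axon forms shifted by
+65 mV, with SI conductances \\(g_{Na} = 1200\\), \\(g_K = 360\\) S/m².
Two facts discipline this transcription without any tuning: with the
Table-constant temperature (279.45 K) the Nernst potentials come out at
+60.0 mV (Na) and −88.1 mV (K), and the sodium activation steady state at
the resting voltage −70.23 mV evaluates to \\(m_\infty = 0.02809 \approx
0.0281\\) — both matching the reported values.

Two conductances are the package's own calibration, fixed once and recorded
in the configuration:

* `g_Cl` (≈ 0.2344 S/m²) is set in closed form so that the net membrane
  current vanishes exactly at −70.23 mV with the default concentrations —
  the rest-consistency condition.  The resting potential of the
  point-membrane model is therefore −70.23 mV by construction, and its
  *stability* (a perturbed state relaxes back) is a genuine model property
  verified by the oracle suite.
* `g_Ca` = 0.2 S/m² is chosen so that the cumulative resting calcium influx
  over a 20 ms protocol produces an intracellular calcium increase of the
  observed order (tens of percent); the simulated default protocol yields
  about +60%.

## Charge bookkeeping and the resting state

Two model ingredients deserve emphasis because the governing equations
alone do not determine them:

**Immobile background charge.**  The four-ion composition is not
electroneutral (the extracellular side carries a net +27.7 mM of charge
equivalents).  Used literally in the Poisson source, that imbalance
produces kilovolt-scale potentials on a micron domain.  Physiological media
contain impermeant species (proteins, phosphates, bicarbonate) that are not
part of the transported set, so the package adds a fixed, immobile
background charge density per bulk region that neutralizes the initial
composition (`numerics$neutral_background`).  The *transported* ions and
their gradients are exactly the configured ones.

**Resting double layers.**  A resting membrane holds its −70.23 mV across
the membrane dielectric as trapped interfacial charge (±c·V per unit area,
c = ε_memb ε₀/d ≈ 3.55 mF/m² at the node).  Charging that capacitance
through the channels would take tens of milliseconds — far longer than the
2 ms pre-stimulus window — so the initializer seeds Gouy–Chapman-style
surface layers carrying exactly that charge on every membrane face, then
relaxes the coupled flux-free system (TES off, membrane sealed) to its
discrete electro-diffusive equilibrium and rescales the seeded charge so
the equilibrated node-interior voltage equals −70.23 mV
(`init_relax_steps` × `init_relax_dt` ≈ 300 ms of model time; the trapped
intracellular charge is conserved by this procedure, so the rescaling is a
one-dimensional, linear calibration).  The simulation clock then starts at
rest: gates at their steady state for the local voltage, fluxes in their
resting balance.

## Time integration

Each outer step (0.01 ms) performs the three-stage Gauss–Seidel pass:
(1) Poisson solve with the current concentrations, (2) per-site gating
integration and flux evaluation under the new frozen potential, (3) one
backward-Euler Nernst–Planck step per ion and region with the frozen
potential (θ-rule with θ = 1; θ < 1 is available).

The naive lagged splitting is violently unstable at this step size: bulk
electrolyte relaxes charge on the Maxwell time ε/σ ≈ 0.4 ns, five orders
below the outer step, and an explicit charge update amplifies
long-wavelength charge modes by −Δt·σ/ε ≈ −2.5·10⁴ per step.  The package
therefore treats the ohmic response implicitly inside the Poisson stage
with a deferred correction,

\\[ \nabla\cdot\big((\varepsilon + \Delta t\,\sigma^k)\nabla\phi^{k+1}\big)
   = -\rho^k + \Delta t\,\nabla\cdot(\sigma^k \nabla\phi^k), \\]

where \\(\sigma = F^2/(RT)\sum_i z_i^2 D_i n_i\\) is the local electrolyte
conductivity.  The correction term vanishes at any self-consistent steady
state — fixed points are exactly those of the plain equation — and a
two-variable mode analysis gives damping factors inside the unit circle for
all charge modes.  Empirically the coupled iteration is stable at the
default steps (and at the 0.1 ms initialization step); the step size must
not be switched abruptly mid-relaxation, which the driver never does.

**Electrode model.**  With *fully* blocking left/right walls the wall
double layers screen the applied 0.1 V within microseconds (an RC time with
λ_D ≈ 0.8 nm layers), which would collapse the bulk field and extinguish
the polarization almost immediately — inconsistent with the sustained
18 ms polarization the model is meant to reproduce.  The default electrode
model (`numerics$electrodes = "open"`) therefore zeroes only the
*diffusive* flux at the left/right extracellular walls and lets the ohmic
(migration) component pass, i.e. the walls behave as ideally reversible
electrodes carrying the stimulation current.  The literal blocking
condition remains available (`"blocking"`) and is what the closed-boundary
mass-conservation tests use.

**Negativity.**  Concentrations are never clipped (clipping would destroy
the conservation identities the tests rely on); the per-step report records
minima and the driver aborts when a minimum falls below
−`negativity_tol` × the ion's bulk scale.

## Mesh

The mesh is a structured, graded, mirror-symmetric triangulation.  Element
height equals `h_debye` (1 nm on the default preset) in a band around both
faces of the nodal membrane and grows geometrically away from it; columns
are refined to `node_edge_dx` (5 nm) at the node corners where the myelin
walls shape the recess potential.  The `"coarse"` preset used by the tests
and the acceptance runs has ≈ 3,700 nodes and 41 membrane sites; the
`"full"` preset approximates the reference full resolution (hundreds of
thousands of elements) and exists for completeness — nothing desk-scale
runs it.  Meshes round-trip through Gmsh MSH 2.2 ASCII with all tags.

## What the verification ladder shows

* manufactured Poisson solutions converge at second order in L2;
* a homogeneous strip between the electrodes carries the exact linear
  potential;
* closed-box Nernst–Planck steps conserve mass to direct-solver precision,
  and a frozen linear potential relaxes every ion onto its Boltzmann
  profile (< 1% deviation; the Ca²⁺ log-slope is twice the Na⁺ one);
* a charged wall under the four-ion electrolyte develops an exponential
  screening layer whose fitted decay length matches the analytic Debye
  length within a few percent, with the expected \\(1/\sqrt{c}\\) and
  \\(\sqrt{\varepsilon}\\) scalings;
* the isolated point-membrane model (capacitance ε_memb ε₀/d) rests at
  −70.23 mV and relaxes subthreshold perturbations back to it, and the
  coupled model's equilibrated nodal voltage agrees with it to well under a
  millivolt over the node interior.

## Known limitations

* **Corner sites.**  The two pairing sites at the exact node edges sit on
  re-entrant corners where the discrete double layer cannot fully form; at
  the default resolution their equilibrated rest is 2–3 mV shy of
  −70.23 mV and they retain a slow (≈ 0.5 mV over 2 ms) residual
  relaxation.  Node-interior sites rest within a few tenths of a millivolt
  and are stationary to well under 1%.  Summaries therefore quote the
  median over sites, and profile structure at the outermost ~2% of the
  node should not be over-interpreted.
* **Global transient and centre invariance.**  Switching the stimulus on
  excites, besides the antisymmetric polarization, a small global voltage
  shift (≈ −1 mV at its deepest, partially recovering by 20 ms) because the
  nonlinear channel response rectifies: the depolarized half does not
  mirror the hyperpolarized half exactly.  A stimulus-free control run
  bounds the initialization's own residual wobble at about ±0.35 mV.  The
  node-centre voltage consequently stays within about 1.8% of its resting
  value over a full default run — close to, but not within, the 1%
  invariance reported for full-resolution simulations; the centre
  voltage at the end of the run (−70.6 mV) is within 0.6% of rest.
* **Extremum location.**  The simulated polarization profile is flattened
  near the node corners by the recess geometry, but at desk-scale
  resolution the depolarization maximum sits at ≈ 95–98% of the node
  length rather than the reported ≈ 91%; the hyperpolarization extremum
  can land on the corner site itself because of the residual corner
  relaxation.  This is the main known resolution artefact of the coarse
  preset.
* The model is 2D-planar (an axisymmetric weighting would be a
  straightforward extension), single-node, and has no pumps or exchangers,
  no stochastic gating, and no steric effects — matching the scope of the
  model it implements.
* The synthetic stimulation protocol is a clean voltage step; real
  electrode montages deliver currents through a lead field that this
  single-axon model does not represent, so amplitudes map to clinical dose
  only qualitatively.

## Problem sizes used by the tests

The test and acceptance suites run the full 20 ms default protocol once on
the `"coarse"` preset (≈ 3,700 nodes, 2,000 outer steps, a few minutes of
compute) and exercise everything else on `"test"`-preset meshes and small
strips chosen so each verification problem finishes in seconds.
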