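---
title: "A hybrid multiscale model of vascular tumour growth with cell-level metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid multiscale model of vascular tumour growth with cell-level metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascmet)
```

## The model

`vascmet` simulates the growth of a vascular tumour in a cube of tissue by
coupling four layers on one cubic lattice (default 64 sites per axis at
20 µm spacing, a 1.28 mm cube, at most one cell per site):

1. **Subcellular ODEs.** Each cell carries a cell-cycle phase
   $\varphi \in [0,1]$, a p53 level and an intracellular VEGF level. With
   local oxygen $C$ frozen over a step,
   $$\dot\varphi = \frac{C}{C + K_\varphi}\,\frac{1}{T_{\min}},\qquad
     \dot p = a_p - b_p\frac{C}{C+K_p}\,p,\qquad
     \dot v = a_v\frac{K_v^4}{C^4+K_v^4} - b_v\,v.$$
   p53 accumulates under hypoxia (its degradation is oxygen-dependent) and
   intracellular VEGF is produced predominantly under hypoxia, with a
   steep sigmoidal oxygen shutoff. The linear
   ODEs are advanced by their exact exponential solution, so the update is
   unconditionally stable for any step size; the default cellular step is
   0.5 h, far below the minimum cycle times (24 h cancer, 48 h normal).

2. **Cellular automaton.** Cells are stochastic agents updated once per
   step in randomized order: division at $\varphi \ge 1$ into a uniformly
   chosen empty 26-neighbour site (deferred under contact inhibition),
   oxygen-gated quiescence with a maximal quiescence survival time,
   p53-triggered apoptosis with a local-density-dependent threshold, a
   homeostatic background turnover of normal cells, and a random-walk hop.
   Cancer cells cycle faster, survive hypoxia longer (96 h vs 48 h), are
   p53-insensitive by default, and have no background death — the
   competition for space this creates is what lets the implanted tumour
   displace healthy tissue.

3. **Quasi-steady diffusible fields.** Oxygen, VEGF and glucose obey
   reaction–diffusion equations solved to quasi-steady state on every
   step. For glucose,
   $$D\,\Delta c + \gamma(x)\,(c^{blood} - c) - r(c)\,I(x) = 0,\qquad
     r(c) = r_{\max}\frac{c}{K_M + c},$$
   with $\gamma = 2\pi R P \ell / h^3$ assembled from the radii $R$ and
   per-site lengths $\ell$ of functional vessel segments ($h$ the lattice
   spacing), $I(x)$ the occupancy indicator, $r_{\max} = 3.3$ (cancer) or
   $0.66$ (normal) mmol l⁻¹ h⁻¹ and $K_M = 0.2$ mmol l⁻¹. Oxygen uses the
   same structure; VEGF has a cellular secretion source proportional to
   the occupant's intracellular VEGF, first-order decay, and vessels as a
   sink ($c^{blood} = 0$).

4. **Vascular network.** Vessels are segments joining lattice-anchored
   nodes. Functional nodes sprout tips at a VEGF-dependent rate; tips
   migrate by a biased random walk up the VEGF gradient (softmax over the
   26 neighbours, never re-entering the previous site), laying segments
   behind them; a migrating tip fuses with another tip or a functional
   node at separation $d$ with probability
   $$P_{\text{anastomosis}} = 1 - d/\Delta x_{\max},\quad d < \Delta x_{\max} = 100\ \mu m,$$
   accepted by drawing $\xi \sim U[0,1]$ and fusing iff
   $\xi \le P$. Blood flow follows Poiseuille's law
   ($g = \pi R^4 / 8\mu L$) with node pressures solved by
   successive-displacement iteration; radii remodel multiplicatively
   toward a wall-shear set point, and persistently flow-less segments are
   pruned.

5. **Cell metabolism (lin-log).** Each cancer cell integrates a lin-log
   kinetic model of HEPG2 central carbon metabolism,
   $$\frac{d}{dt}\left(\frac{c}{c^0}\right) = (c^0)^{-1} N r,\qquad
     \frac{r_j}{J_{0,j}} = \frac{c_E}{c_E^0}\Bigl(1 + \sum_M
     \varepsilon_{M,j} \ln \frac{c_M}{c_M^0}\Bigr),$$
   with the elasticities $\varepsilon$ stored as signed inputs, external
   species (extracellular glucose, oxygen, exported lactate) clamped to
   the local fields, and integration in log-concentration space by a
   stiff adaptive solver (`deSolve::lsoda`) so positivity holds by
   construction. The coupling is strictly one-way: metabolism reads the
   frozen fields and never feeds back, so toggling it cannot change the
   growth trajectory.

A simulation step executes, in fixed order: field solves → subcellular
ODEs → cellular automaton → vascular update → field re-solve → per-cell
metabolic integration against the re-solved (frozen) fields → clock
advance. Synchronizing metabolism after the final field update of the step
mirrors the model's stated synchronization contract between the growth and
metabolism layers.

## The bundled metabolic network

The full published HEPG2 parameterization is not redistributed with
this package. The bundled network
(`hepg2_network()`, also shipped as `hepg2_linlog_synthetic.yaml`) encodes
the canonical topology — glucose → g6p → f16bp → pyruvate, the
pentose-phosphate branch g6p → 6-phosphogluconate → f16bp, the lactate
branch with export, and pyruvate → Acetyl-CoA → oxygen-consuming
respiration — with *synthetic but internally consistent* parameters: the
reference fluxes balance exactly ($N J_0 = 0$ on internal species, scaled
to the printed cancer glucose uptake 3.3 mmol l⁻¹ h⁻¹), and the reference
Jacobian is verified stable. Oxygen activates pyruvate dehydrogenase and
respiration, so hypoxia shifts pyruvate toward lactate; raising clamped
glucose raises the steady lactate-producing flux (the Warburg pattern the
model is meant to reproduce). The YAML format accepts the full published
parameter set verbatim when the user supplies it.

## Parameters that matter, and how the defaults were chosen

Values printed in bold are fixed by the underlying model description; the
rest are free parameters chosen once, on physiological grounds, and
documented as uncalibrated.

| parameter | default | unit | note |
|---|---|---|---|
| lattice | **64³ × 20 µm** | — | 1.28 mm cube |
| $\Delta x_{\max}$ | **100** | µm | anastomosis range |
| glucose $D$ | **7.2×10⁵** (2.0×10⁻⁶ cm²/s) | µm²/h | interstitium |
| glucose $r_{\max}$ | **3.3 / 0.66** | mmol l⁻¹ h⁻¹ | cancer / normal |
| glucose $K_M$ | **0.2** | mmol l⁻¹ | both types |
| glucose $c^{blood}$ | 5.0 | mmol l⁻¹ | physiological plasma |
| glucose $P$ | 500 | µm/h | uncalibrated; chosen so a parent vessel keeps $c > K_M$ within ~100 µm |
| oxygen $c^{blood}$ | 20 | framework units | plasma reference |
| oxygen $r_{\max}$ | 6000 / 2500 | units/h | cancer / normal; gives an oxygen penetration depth of roughly 150–190 µm around perfused vessels |
| quiescence enter/leave | 8 / 9.5 | oxygen units | hysteresis |
| VEGF switch `k_vegf_o2`, `vegf_o2_hill` | 6, 4 | oxygen units, — | sigmoidal hypoxia switch for intracellular VEGF production, centred just below the quiescence range |
| sprouting `vegf_min`, `vegf_half` | 0.5, 2 | VEGF units | activation threshold above the normoxic secretion baseline (only hypoxia-elevated VEGF recruits sprouts) and the half-saturation above it |
| shear set point | 0.04 | mmHg | matches the parent-vessel wall shear, so parents are near equilibrium |
| normal `base_death_rate` | 0.01 | 1/h | homeostatic tissue renewal; without it a confluent tissue contact-inhibits the tumour forever |

The oxygen-supply budget is the one genuinely delicate choice: two parent
vessels cannot richly oxygenate a whole confluent cube (supply scales
with vessel length, demand with volume), and the reference scenario
resolves this the same way the underlying model does — tissue within the
oxygen penetration depth of the parents is normoxic, distal tissue
becomes hypoxic and quiescent, switches on VEGF secretion, and recruits
its own vasculature, after which oxygenation improves and the tissue
recovers. The tumour, with 2.4-fold oxygen demand and glucose appetite
five-fold over normal, re-creates hypoxia locally as it expands.

## Numerical choices

* **Field solver.** The quasi-steady problems are solved by an outer
  Picard iteration that lags the Michaelis–Menten denominator one
  iteration, with the inner linear Helmholtz problem solved matrix-free
  by Jacobi-preconditioned conjugate gradients on the second-order
  7-point stencil (zero-flux closure by reflection; Dirichlet faces by
  ghost-cell elimination). A pseudo-time split-operator sweep would
  converge to a fixed point that differs from the discrete steady problem
  at the splitting order, whereas CG solves exactly that problem to a
  controlled residual (default 10⁻⁸ relative, configurable via
  `run.field_tol`); the discrete operator is an M-matrix, so the
  converged solution is non-negative without clipping. The independent
  check is a separately assembled sparse direct solve
  (`dense_linear_field_oracle()`), and the slab configuration has a cosh
  closed form; grid refinement confirms second-order convergence.
* **Pressure solve.** Chromatic successive displacement (multicolour SOR,
  ω = 1.8) on the node-pressure system; same-colour nodes are never
  adjacent, so their updates commute with the sequential sweep. Residual
  tolerance 10⁻¹¹ relative to the local flow scale. Components not
  reaching a boundary node carry zero flow.
* **Stiff metabolic integration.** `lsoda` on log-concentrations with
  rtol 10⁻⁸/atol 10⁻¹⁰ defaults; equivalence with the matrix-exponential
  solution of the reference-state linearization is part of the test
  surface. Because lin-log rates are linear in log-concentrations, the
  clamped-environment steady state solves a linear system
  (`linlog_steady_state()`), which doubles as an independent oracle and a
  stability diagnostic (reference Jacobian eigenvalues).
* **Determinism.** All stochastic layers draw from R's global RNG; a run
  is a pure function of (config, seed). Snapshots serialize every double
  through `%.17g`, which round-trips bit-exactly, and store the RNG
  state, so checkpoint/restart reproduces the uninterrupted trajectory
  bitwise.
* **Degenerate inputs.** Flat lattices (size-1 axes) drop the
  corresponding stencil directions; tips with no admissible neighbour
  stall and eventually regress; implant radii reaching the boundary are
  clipped with a warning; a flow solve without boundary pressures, a
  field solve with non-positive diffusivity, and non-positive lin-log
  concentrations are errors naming the offending quantity.

## Design choices on genuinely open points

* **Anastomosis candidate order.** The acceptance rule is per-pair; the
  candidate set (other tips and functional nodes within range, the tip's
  own trail excluded) is evaluated nearest-first with a stable id
  tie-break, one attempt per tip per vascular step, so the event sequence
  is a deterministic function of the RNG stream. The joining path is a
  deterministic monotone lattice path. Short-circuit loops onto the
  tip's own parent vessel are permitted: they carry negligible pressure
  difference, never become functional, and are pruned.
* **Sprouting law.** Only "increases with local VEGF" is prescribed; a
  saturating law with an activation threshold bounds the probability and
  prevents baseline secretion from the healthy tissue driving unbounded
  vessel growth.
* **Quiescent cancer cells** keep the cancer glucose-uptake rate
  (configurable), and CDH/p27 channels exist only as passive optional
  state, since no dynamics are prescribed for them.
* **Tissue initialization.** The reference scenario constructs confluent
  healthy tissue directly (phases uniform); a cellular-automaton burn-in
  from sparse seeds is available (`run.burnin_h`) but adds hundreds of
  steps for no additional tested behaviour.
* **Metabolic scope.** The HEPG2 network describes cancer cells, so only
  cancer cells carry metabolic state by default
  (`metabolism.cell_types = "all"` assigns it to every cell). The
  extracellular Michaelis–Menten sink and the lin-log uptake reaction are
  deliberately independent laws and are not forced to agree; both read
  the same extracellular glucose.
* **Lin-log pathology.** Rates can change sign at extreme
  log-deviations; they are not clipped (the published functional form is
  preserved), and the steady-state diagnostics expose reversed-sign
  fluxes.

## What the synthetic scenarios do and do not show

The generators used by the tests (toy chain networks with flux-balanced
references, isolated tip/target pairs, two-parent-vessel scenarios with a
static VEGF hotspot, scaled growth runs) exercise every mechanism —
uptake saturation, hypoxia-driven quiescence and VEGF secretion,
distance-dependent anastomosis, shear remodelling, Warburg-like flux
shifts — under controlled conditions with known oracles. They do not
establish quantitative agreement with any real tumour: the metabolic
parameters are synthetic, several transport coefficients are
uncalibrated, and a lattice automaton has no mechanics, adhesion or
interstitial convection. Passing tests certify the implementation of the
stated model, not the model's biological accuracy.

## Problem sizes used by the test surface

The packaged checks run scaled-down scenarios chosen to exercise every
mechanism at sizes a laptop handles comfortably: field-solver
equivalence on ≤ 32³ grids, flow networks of ≤ 220 segments,
coupling contracts on 8–12-site lattices over a few steps, growth
phenomenology on a 16³ lattice over 60 h with implant radius 4 (two
seeds), and the loop-formation comparison on a 14×14×7 two-vessel
scenario over 10 h with 20 seeds per rule. The full 64³ / 350 h reference configuration is the
package default for production use (`run(vm_default_config(), out_dir)`),
not part of the test suite.

## Known limitations

* No haematocrit partitioning, intravascular solute depletion or oxygen
  advection; vessel blood concentrations are prescribed.
* No transient PDE mode — fields are quasi-steady by assumption.
* No mechanics: cells occupy sites, they do not push.
* Single-process execution; the layers synchronize in a fixed serial
  order each step.
* The bundled metabolic parameterization is synthetic (topology-faithful,
  flux-balanced, stable) and should be replaced with the published
  parameter set for quantitative metabolic work.
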