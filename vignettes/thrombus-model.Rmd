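---
title: "A multi-constituent continuum model of thrombus deposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-constituent continuum model of thrombus deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombosim)
```

## The model

Blood is treated as a single-phase linear fluid coupled to a rigid,
stationary thrombus phase. A scalar field $\phi \in [0,1]$ — the volume
fraction of deposited platelets — ties the two together: the fluid obeys
incompressible momentum balance with stress
$\mathbf{T} = -p\mathbf{I} + \mu_f(\nabla \mathbf{v} + \nabla\mathbf{v}^T)$,
mixture density $\rho_f = \rho_{f0}(1-\phi)$, and a resistance force
$-C_2\, f(\phi)\, \mathbf{v}$ exerted by the deposit, with the hindrance
function $f(\phi) = \phi(1 + 6.5\phi)$. The coefficient
$C_2 = 2\times10^9\,\mathrm{kg\,m^{-3}s^{-1}}$ corresponds to densely
packed particles of the platelet hydraulic diameter
($2.78\,\mu\mathrm{m}$); the equivalent Darcy permeability of a dense
deposit ($\phi = 0.9$) is $\mu_f / (C_2 f(\phi)) \approx
2.8\times10^{-13}\,\mathrm{m^2}$.

Ten species are tracked. Seven advect and diffuse (free resting and
activated platelets RP, AP; ADP; thromboxane A2 (TxA2); prothrombin;
thrombin; antithrombin III), governed by conservative
convection–diffusion–reaction equations; three are deposited states
(RP_d, AP_d, AP_s) that evolve only through local reactions —
deposited platelets never advect. Platelet diffusivity is shear-enhanced,
$D = 1.58\times10^{-13} + 6.0\times10^{-13}\,\dot\gamma\ \mathrm{m^2/s}$
with $\dot\gamma$ the shear-rate magnitude in $\mathrm{s^{-1}}$ (the slope
coefficient carries the units that make this dimensionally consistent, as
in the empirical sources it descends from); the chemical species use
constant diffusivities.

### Activation

Resting platelets activate chemically when the weighted agonist number
$$\Omega = \sum_j w_j \frac{[a_j]}{a_{j,\mathrm{crit}}}, \qquad
  j \in \{\mathrm{ADP}, \mathrm{TxA2}, \mathrm{thrombin}\}$$
reaches 1, at rate $k_{apa} = \Omega / t_{ct}$ ($t_{ct} = 1$ s), and
mechanically at rate $k_{spa} = 1/t_{ct,spa}$ with the empirical
characteristic time $t_{ct,spa} = 4.0\times10^{6}\,\tau^{-2.3}$ ($\tau$ in
dyne/cm²). Both rates are capped at $\ln(100)/t_{act}$ — at most 99% of
platelets can activate within the physical activation time
$t_{act} = 0.5$ s (the slow end of the reported 0.1–0.5 s range; the cap
is then $9.21\,\mathrm{s^{-1}}$). Weights and thresholds:
$w = (1, 3.3, 30)$ and $a_\mathrm{crit} = (1.0, 1.2, 0.1)\times10^6$ in
nmol/m³ (thrombin in U/m³). Each activation event releases
$\lambda_j = 2.4\times10^{-8}$ nmol ADP per platelet; activated platelets
synthesize TxA2 at $s_{pj} = 9.5\times10^{-12}$ nmol/PLT/s, and TxA2 is
cleared first-order with a 30 s half-life (ADP is not degraded). The
synthesis and clearance constants are inherited from the platelet-kinetics
lineage this model builds on, since they are not legible in the source
tables.

### Thrombin and its inhibition

Thrombin is produced from prothrombin on procoagulant platelet membranes:
free and deposited activated platelets at
$\phi_{at} = 3.69\times10^{-15}$, deposited resting platelets at
$\phi_{rt} = 6.5\times10^{-16}$ (both in m³ nmol⁻¹ PLT⁻¹ U s⁻¹), with
$\varepsilon = 9.11\times10^{-3}$ nmol/U converting thrombin units to the
prothrombin and antithrombin budgets. Free *resting* platelets are
deliberately excluded from the generation term: at these SI coefficient
values their inclusion would have resting, heparinized blood generate
$\sim 4\times10^5$ U m⁻³ s⁻¹ of thrombin, driving the background
$\Omega$ above the activation threshold everywhere and igniting the whole
domain within one transit time — behaviour incompatible with the localized
thrombin and activated-platelet fields the model is meant to produce.
Restricting generation to procoagulant (activated or surface-adherent)
membranes keeps resting blood resting while leaving the intra-thrombus
generation, which dominates by orders of magnitude, untouched.

Inhibition follows the heparin-template kinetics: heparin binds
antithrombin III ($K_{AT} = 1.0\times10^5$ nmol/m³) and thrombin
($K_T = 3.5\times10^4$ nmol/m³), and the ternary complex reacts at
$k_{1,T} = 13.333\,\mathrm{s^{-1}}$. Under rapid-equilibrium occupancy
this gives the first-order neutralization rate
$$\Gamma = \frac{k_{1,T}[H]\,[AT]\,T'/(\alpha K_{AT} K_T)}
  {1 + [AT]/K_{AT} + T'/K_T + [AT]\,T'/(\alpha K_{AT} K_T)}\ /\ T',$$
with $T' = \varepsilon[TB]$ and $\alpha = 1$. At the default heparin level
$[H] = 1.0\times10^5$ nmol/m³ and plasma ATIII this yields
$\Gamma \approx 37\,\mathrm{s^{-1}}$: free thrombin lives $\sim$30 ms and
acts within a micrometre-scale halo of its source. Both benchmark
scenarios run with this heparin level; it is configurable per scenario.

### Deposition, propagation, embolization

Free platelets adhere to reactive walls through surface fluxes
$-S\,k_{rpd,b}[RP]$ and $-S\,k_{apd,b}[AP]$, where
$S = 1 - N_s/\mathrm{PLT}_{s,max}$ is the free fraction of the surface
($\mathrm{PLT}_{s,max} = 7\times10^{10}$ PLT/m²) and the three material
coefficients $(k_{rpd,b}, k_{apd,b}, \tau_{emb,b})$ characterize the
surface: injured vessel wall $(4\times10^{-5}, 4\times10^{-4}, 1.0)$,
healthy endothelium $(0, 0, -)$, titanium alloy
$(10^{-20}, 10^{-5}, 0.1)$. The contact-activation fraction $\theta = 1$
routes all depositing resting platelets directly to the activated
deposited state, releasing their ADP load.

Once a cell's deposited fraction exceeds the propagation threshold
$\phi_{prop}$ (default 0.2 — low enough that nascent deposits propagate,
high enough to avoid unconditional growth; exposed in the configuration),
deposition propagates to every fluid cell sharing a face with it at rates
$k_{rpd} = k_{ra} A_{int}/V$ and $k_{apd} = k_{aa} A_{int}/V$, where
$A_{int}$ is the shared interface area, $V$ the receiving cell volume, and
$k_{ra} = 3\times10^{-6}$, $k_{aa} = 3\times10^{-5}$ m/s the
platelet–thrombus aggregation velocities. Bulk deposition is
packing-limited by $\psi = \max(0, 1 - C_{dep}/\mathrm{PLT}_{max})$ with
$\mathrm{PLT}_{max} = \mathrm{PLT}_{s,max}/\mathrm{Dia}_{PLT} =
2.518\times10^{16}$ PLT/m³, so $\phi \le 1$ always. The volumetric
packing limit as the ratio of the printed surface capacity to the platelet
diameter is itself a modelling commitment (the quantity is typeset
illegibly in the source), exposed as an override.

Shear clears deposits. The embolization frequency used here is
$$f_{emb}(\tau;\tau_c) = \tfrac{1}{2}\dot\gamma\;
  \frac{\tau}{\tau_c}\,\bigl(1 - e^{-0.0095\,\tau}\bigr),$$
the slip velocity of the ambient flow at the mid-height of a surface
platelet ($\dot\gamma\,\mathrm{Dia}_{PLT}/2$) normalized by the platelet
diameter, scaled by the excess of the acting shear stress over the
characteristic embolization stress ($\tau_{emb} = 30$ dyne/cm² for bulk
thrombus, the material $\tau_{emb,b}$ for wall-bonded deposits) and by the
empirical non-adhesion fraction $1 - e^{-0.0095\tau}$. The exact printed
body of this law is not legible in the source material, so the functional
form is a design choice of this package (and is pluggable through
`embolization_rate(law = ...)`). The prefactor is pinned by a regime
argument rather than by fitting: with it, the injured-wall platelet layer
equilibrates *below* the propagation threshold under resting inflow
(blocking every agonist must prevent occlusion) while strongly activated
deposition exceeds it (the unblocked vessel must occlude); the
$\dot\gamma$-free alternatives fail one side or the other. In the coupled
driver the erosion shear of a cell is the *interface* shear — the largest
shear-rate magnitude among the cell and its fluid face-neighbours —
because a deposit's surface is exposed to the free-stream shear even as
its interior is Brinkman-damped; without this, growing deposits bury
themselves away from erosion and growth becomes unconditional.

Embolized platelets return to the free stream in their activation state;
the stabilization pathway ($f_{stb} = 0$) is carried but inert, so
deposition equilibrates with shear clearance rather than hardening.

## Numerics

Structured staggered (MAC) grids, planar or axisymmetric, with per-axis
graded spacings and blocked cells for non-rectangular domains. The flow is
solved as quasi-steady (Reynolds numbers are $\sim 10^{-2}$–$10$;
the vessel benchmark gives $Re = \rho U D/\mu \approx 0.015$, which we
report as computed even though it disagrees with the value printed
alongside the source geometry): a pressure-correction iteration with
first-order upwind convection, central diffusion, the resistance sink
taken implicitly (stable for arbitrarily dense deposits), and
under-relaxation; convergence requires both the normalized mass residual
and the momentum update to fall below tolerance. The flow is re-solved on
a fixed cadence (2 s of simulated time) and whenever $\max|\Delta\phi|$
since the last solve exceeds 0.02; solves warm-start from the previous
state.

Species transport is explicit conservative finite-volume upwinding with
central diffusion; the step size is set from the per-cell
advective+diffusive stability bound (CFL number 0.8, cap 20 ms) and steps
land exactly on output and flow-update times, which makes checkpointed
restarts replay the uninterrupted trajectory bitwise. Reactions use
donor-bounded (Patankar-type) transfer amounts computed from start-of-step
values: every platelet inter-conversion is written as an explicit transfer
between states, so platelet count is conserved to machine precision and no
state can go negative regardless of local stiffness (activation is capped
at $9.2\,\mathrm{s^{-1}}$, inhibition at $\Gamma \approx 37\,
\mathrm{s^{-1}}$, both well-resolved at millisecond steps). Transport
undershoots are clamped at zero and counted; benchmark runs report zero
clamp events. The model contains no randomness: identical inputs produce
bitwise-identical trajectories.

Occlusion is detected geometrically — some streamwise station is fully
spanned by cells with $\phi \ge \phi_{occ}$ (default 0.2, configurable;
the hydraulic criterion, flow rate below 1% of its initial value at fixed
driving pressure, is computed alongside and logged). Morphometrics use the
same threshold: height is the maximal wall-normal extent of the
above-threshold region, length its streamwise extent, volume the
$\phi$-weighted integral (with the $2\pi$ factor on axisymmetric grids).

A note on "zero" velocity inside deposits: the Brinkman screening length
$\sqrt{\mu_f/(C_2 f(\phi))}$ is $\approx 0.5\,\mu$m at $\phi = 0.9$, so
the surface cell of a deposit carries a residual shear layer, and the
interior seepage is $|\nabla p| / (C_2 f(\phi))$ — about 0.25% of the mean
inlet velocity per unit of unobstructed pressure gradient. Inside an
occlusive plug under the benchmark pressure drive the interior speed is
below 1% of the open-vessel mean, which is the sense in which the deposit
interior is stagnant.

## The benchmark scenarios

**Injured vessel (axisymmetric).** A 0.06 mm diameter, 0.5 mm long vessel
perfused at a mean velocity of 800 µm/s by a fixed pressure difference
(12.4 Pa, sized by the Hagen–Poiseuille relation, so the flow collapses
as the lumen occludes). Healthy endothelium everywhere except a 30 µm
injured segment centred mid-vessel (the injured length is not reported;
30 µm spans the injection site with a few mesh faces at the default
resolution). A 3 µm pipette port at the segment centre can hold ADP at a
fixed tip concentration of $10^9$ nmol/m³ (1 mM, within the range
perfused in the source experiments), exchanged diffusively through the
port area; the near-wall concentration then crosses the activation
threshold within seconds. Inlet platelet counts are rodent values
($6\times10^{14}$ resting, 1% activated). Default mesh: 40 axial × 10
radial cells (mesh scale 0.25 of the 160 × 40 base), at which a full
occlusion run takes seconds and occlusion times are mesh-robust (36–41 s
between mesh scales 0.25 and 0.5).

**Wall micro-crevice (planar).** A 0.9 mm window of a channel of
half-height 1.5 mm (symmetry plane on top), with a 0.125 mm deep crevice
of length 0.075 or 0.137 mm sunk into the floor 0.3 mm from the inlet;
fully developed inlet profile with mean 0.0173 m/s; all wetted walls
titanium alloy; human platelet counts ($2.5\times10^{14}$ resting,
$10^{13}$ activated). The 0.1 mm channel depth of the source experiment is
recorded but unused: the problem is solved at the mid-depth plane. The
mesh is graded (near-wall spacing 12.5 µm at the default mesh scale 0.25)
and the crevice edges snap to cell faces, so the effective crevice length
is mesh-quantized.

## What the scaled-down 2D runs do and do not show

The six agonist-blocking vessel runs reproduce the observed *ordering*
exactly: ADP-injected occludes first, no-injection and TxA2-blocked are
indistinguishable, ADP-blocked and thrombin-blocked are progressively
slower, and blocking all agonists prevents occlusion through the full
1200 s horizon. The *absolute* occlusion times are compressed roughly
eightfold relative to the in-vivo-calibrated reference (∼41 s vs ∼380 s
for the uninjected case). The compression is not a resolution artifact
(times vary <15% across mesh scales); it follows from the axisymmetric
reduction: the thrombus is an annular ring constricting the entire
cross-section, so all near-wall fluid contacts the reactive deposit and
the thrombin/ADP halo enriches activated platelets at the growth front far
more than around a localized three-dimensional mound, which fresh blood
can bypass laterally. The same effect elongates the ring axially, raising
the length:height ratio of the growing deposit (≈5.7 on average) above
the ≈2.5 reported for the mound. These quantities are reported as
computed.

In the crevice, the model reproduces the signature spatial pattern:
deposition concentrates at the crevice lips and the downstream corner
leads the upstream corner at every output time. The long-crevice
comparison is only partially reproduced: the deeper vortex penetration of
the 0.137 mm crevice is resolved (bottom-wall shear ∼20× the short
crevice's), but at ∼0.03 dyne/cm² the erosion law is negligible in both
cavities, and the larger sheltered volume of the long crevice accumulates
more agonist, so its *total* deposit at 450 s is larger rather than
smaller; per unit crevice length the short crevice does deposit faster.
Resolving this comparison most likely requires the original (unpublished)
erosion law, which the wall coefficients were fitted against.

## Worked example

```{r vessel, eval = FALSE}
sc <- build_vessel_scenario()            # ADP injected at the injury site
res <- run_simulation(sc, t_end = 1200)
res$occlusion_time                       # ~41 s at mesh scale 0.25
tail(res$morphometrics)

## the blocking panel
tab <- blocking_experiment(build_vessel_scenario(inject_adp = FALSE))
tab[order(tab$occlusion_time), ]
```

## Limitations

Beyond the 2D reductions discussed above: blood is single-phase (no
red-cell-induced platelet margination, no haematocrit dependence of the
near-wall excess); no von Willebrand factor pathway, so very-high-shear
device regimes are out of scope; fibrin/factor-XIII stabilization is
carried as a rate constant set to zero; surface chemistry is entirely
three coefficients per material; the propagation threshold and occlusion
threshold are model constants (0.2) rather than measured quantities. The
propagation threshold acts as a bifurcation parameter: in the uninjected
vessel benchmark, $\phi_{prop} = 0.1$ occludes at ~14 s, 0.2 at ~41 s,
and at 0.5 erosion holds the front below threshold and the vessel never
occludes within 600 s. The occlusion threshold is benign by comparison:
detected times at $\phi_{occ} = 0.1$ and 0.2 agree within 1%, while 0.5
waits for the slow late-stage packing of the ring (~160 s). The suite
exercises this sensitivity.
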