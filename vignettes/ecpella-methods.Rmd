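---
title: "Model, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecpella)
```

## The circulation model

`ecpella` is a closed-loop 0-D (lumped-parameter) model of the adult
circulation under combined mechanical support. The state is the vector of
ten compartment volumes: four cardiac chambers (LA, LV, RA, RV) and six
vascular compartments (systemic artery, capillary, vein; pulmonary artery,
capillary, vein). Vascular pressures are linear, `P = V / C`. Chamber
pressures blend the end-systolic and end-diastolic pressure–volume
relations,

$$P(V,t) = a(t)\,E_{es}(V - V_0) + \big(1 - a(t)\big)\,\alpha\big(e^{\beta V} - 1\big),$$

with the normalized activation $a(t) \in [0,1]$. This activation-weighted
blend is the de-facto standard closure for time-varying-elastance models:
at peak activation the chamber sits on its ESPVR, in diastole on its EDPVR,
and `elastance_waveform()` reports the equivalent instantaneous elastance
$E(t) = E_{min} + a(t)(E_{es} - E_{min})$, whose peak is exactly $E_{es}$.

**Activation waveform.** The source model does not state a shape for
$E(t)$, so we use the double-Hill activation
$h(x) \propto \frac{(x/\tau_1)^{n_1}}{1 + (x/\tau_1)^{n_1}} \cdot
\frac{1}{1 + (x/\tau_2)^{n_2}}$ with $\tau_1 = 0.30$, $n_1 = 1.32$,
$\tau_2 = 0.51$, $n_2 = 21.9$ on the normalized activation window,
numerically normalized to peak 1. It is continuous and $C^1$, produces
physiological pressure waveforms, and is cheap to tabulate. Cycle phase 0
is ventricular activation onset. Ventricular activation occupies 0.63 of
the cycle (at 80 bpm this places end-systole near 0.3·√T ≈ 0.26 s);
atrial activation (window 0.20) starts at phase 0.82 so the atrial kick
peaks just before the next ventricular contraction.

**Valves** are unidirectional Bernoulli orifices in series with a linear
resistance: $\Delta P = R\,Q + \frac{\rho}{2 (kA)^2} Q^2$ with $Q$ in mL/s,
$A$ in cm², $\Delta P$ in mmHg and $k^2 = 1333.22$ (the dyn/cm² per mmHg
conversion). The characteristic impedances $R_{SZ0}$ and $R_{PZ0}$ sit in
series with the aortic and pulmonary valves. Flow is zero whenever the
gradient is adverse; there is no regurgitation, no inertance, no
pericardium and no septal interaction.

**Devices.** VA-ECMO is an ideal flow source from the systemic-vein
compartment to the systemic artery. The Impella pump withdraws from the LV
and returns to the systemic artery; its flow solves the per-level
head–capacity quadratic $\Delta P = a - bQ - cQ^2$ at the instantaneous
head SAP − LVP, clamped at the zero-head capacity for adverse heads. LV
suction is *defined* as LAP reaching 0 mmHg; for LAP < 0 the nominal flow
is reduced by `limiter_gain` (default 1 (L/min)/mmHg — only the direction
of this "added resistance" is stated by the source, not its magnitude) per
mmHg below zero. VV-ECMO only switches the arterial saturation used in the
oxygen-delivery equation

$$\mathrm{DO_2} = 1.34 \cdot 10 \cdot Hb \cdot SaO_2 \cdot (CO + Q_{impella})
 + 1.34 \cdot 10 \cdot Hb \cdot 1.0 \cdot Q_{vaecmo}.$$

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `HR` | bpm | 80 | the scenarios' fixed heart rate |
| LV `E_es` | mmHg/mL | 0.4 (failure) / 1.6 (normal) | scenario-defining contractility |
| RV `E_es` | mmHg/mL | 0.5 (LVF) / 0.2 (BVF, BVF_PH) / 1.6 (normal) | scenario-defining |
| SVR | WU | 11.7 (failure) / 17 (normal) | scenario-defining; split 5/79/14/2% over Zc/artery/capillary/vein |
| PVR | WU | 0.8 / 6.0 (PH) | scenario-defining; split 5/60/25/10%; $R_{PZ0}$ scales linearly with PVR (Zc scale = PVR/0.8) |
| `dt` | s | 2e-4 | fixed integration step; halving it changes settled CO/SAP/LAP by < 0.5% |
| `decimation` | – | 5 | one stored sample per ms |
| `limiter_gain` | (L/min)/mmHg | 1.0 | suction throttle slope |
| `v_floor` | mL | 1.0 | outflow throttle floor (negative-volume guard) |
| Hb, SaO2 | g/dL, – | 10, 0.40/0.80 | the hypoxaemia scenario with/without VV-ECMO |

1 Wood unit = 1 mmHg·min/L = 0.06 mmHg·s/mL; conversions are centralized in
`wu_to_mmhg_s_ml()` / `mmhg_s_ml_to_wu()` and the preset loader verifies
that the element sums reproduce the scenario's printed Wood-unit totals.

## Calibration of unprinted constants

The individual R/C/E constants behind the scenario-defining totals are not
published, so they are *calibrated defaults*, documented in the preset
files, chosen once against three targets in this order:

1. element sums equal the stated SVR/PVR Wood-unit totals;
2. the NORMAL preset lands in the physiological gate (CO 4–6 L/min, mean
   arterial pressure 70–110 mmHg, atrial pressures 0–15 mmHg);
3. the headline behaviour of the pulmonary-hypertension protocol — the
   suction-limited Impella ceiling below 1.6 L/min at every VA-ECMO flow —
   is reproduced.

The main consequences of (3): a right-shifted RV diastolic curve
($V_0 = 40$ mL, EDPVR $0.9(e^{0.0178 V} - 1)$: near-empty below ~40 mL at
sub-mmHg filling pressures, ~115 mL at 6 mmHg), a gentle atrial kick
(atrial $E_{es}$ 0.12–0.45 mmHg/mL), moderate venous compliance
(25 mL/mmHg) and a stiff pulmonary arterial tree (C_PA 2 mL/mmHg). With
these diastolic curves a "normal" RV $E_{es}$ of 0.4–0.5 mmHg/mL cannot
produce a normal cardiac output, so the NORMAL preset uses RV
$E_{es} = 1.6$; the LVF scenario keeps its stated 0.5.

**Per-scenario operating volumes.** All *parameters* are shared across the
failure presets (only $E_{es}$, PVR and the PVR-scaled $Z_c$ differ); the
*initial volume state* is per-preset: NORMAL 803, LVF 702, BVF 646, BVF_PH
460 mL of stressed volume. Volaemia is a patient state, not a circuit
parameter: chronic LV failure presents congested (the left-sided pool holds
~350 mL above baseline), while acute RV pressure overload does not carry
that surplus. One shared volume cannot simultaneously congest the LVF left
heart and keep BVF_PH venous pressure low enough for the suction-limited
ceiling; the per-preset states are therefore part of the documented
scenario definitions.

**Impella head–capacity table.** The per-level coefficients follow pump
affinity scaling from a P9 curve with 120 mmHg shut-off head and 3.70 L/min
zero-head flow (Impella-CP class; speed fraction $(L+9)/18$ for levels
1–9, so $a_L = 120\,s^2$, $b_L = s$, $c_L = 8.5$). The table ships as CSV
and can be replaced wholesale with manufacturer data.

## Numerics

* **Integrator**: fixed-step explicit RK4 at `dt` = 0.2 ms (C++). The
  stiffest couplings (valve conductances into elastic chambers) have time
  constants ≳ 2 ms, comfortably inside the stability region; a
  step-halving test pins settled CO/SAP/LAP to < 0.5%.
* **Determinism**: there is no randomness anywhere; identical
  configurations give bit-identical series.
* **Activation lookup**: when the cardiac period is an integer number of
  half-steps (true for the defaults) the four activation waveforms are
  tabulated once per cycle; otherwise they are evaluated directly. Both
  paths use the same function, and the pure-R `circulation_rhs()` is
  property-tested against the C++ right-hand side to 1e-10.
* **Negative-volume guard**: outflows from a compartment are scaled by
  `clamp(V / v_floor, 0, 1)` (default floor 1 mL). This keeps the explicit
  scheme robust when the Impella empties the LV; it acts on the *source*
  side of each flow so volume conservation is exact by construction.
* **Blow-up guard**: any pressure beyond ±500 mmHg aborts with the channel
  and time in the message.
* **Steady-state extraction**: analysis windows end 2 s before each setting
  change and span 4 complete onset-aligned beats; a segment is flagged
  non-converged when beat-mean SAP varies more than 1% across the window
  (the 1% figure is this package's choice; the source only requires "a
  steady state").
* **PV-loop analytics**: stroke work by the shoelace rule on the ordered
  samples; the loop-closure check accepts a gap up to one sample's travel
  or 5% of the loop extent (nearly-settled beats); inside the beat pipeline
  complete fixed-period beats are treated as closed by wrap-around. PVA
  adds the potential energy between ESPVR and EDPVR from $V_0$ to the
  end-systolic (minimum-loop) volume, trapezoid-integrated on a 0.1 mL
  grid; end-systolic volumes at or below $V_0$ give PE = 0 with a warning.
* **CO** is the mean trans-aortic-valve flow, so "zero CO under total
  support" is literal; total systemic flow = CO + Impella + VA-ECMO.
* **Suction reporting**: a setting is flagged when any beat in its
  extraction window touches LAP ≤ 0.

## What the tests do and do not establish

The protocol tests run at reduced settling (10–30 s instead of 100/50 s)
with the convergence flag as the gate; the acceptance script re-runs at
full settling when any flag fails. Green trend tests establish the model's
qualitative behaviour — monotone LAP unloading by Impella, monotone total
systemic flow in VA-ECMO, suction capping in pulmonary hypertension,
VV-ECMO's DO2 augmentation — under *this* calibration; they do not
establish quantitative agreement with any patient data, and the absolute
flows and pressures of the failure scenarios are not comparable to the
source figures (whose element-level constants are unpublished).

## Known limitations

* **LVEDP versus VA-ECMO in LVF.** The source reports that raising VA-ECMO
  flow *lowers* LVEDP in LVF (preload reduction dominating) while raising
  it in BVF and BVF+PH. This model reproduces the BVF/BVF_PH direction and
  the relative ordering (RV failure strengthens the rise), but in LVF the
  afterload effect still dominates and LVEDP rises. The mechanism is
  structural here: once VA-ECMO has drained the right heart, the RV becomes
  a near-isovolumic pressure source whose standing pressure — at any
  residual right-atrial pressure achievable with a conserved, physiological
  volume state — meets or exceeds the baseline ejecting pulmonary pressure,
  so the left-sided pool cannot decompress below baseline. Calibrations
  spanning RV diastolic stiffness, RV $V_0$ 10–50 mL, atrial-kick strength,
  venous compliance 20–70 mL/mmHg and stressed volume 560–1290 mL did not
  flip the sign without breaking the (graded) suction-ceiling bound. The
  corresponding acceptance test is left failing on purpose.
* No baroreflex, force–frequency or relaxation-loading effects; heart rate
  is fixed.
* No valve regurgitation, inertances, pericardial constraint or septal
  interaction.
* VA-ECMO is ideal (no drainage insufficiency, no VAV flow diversion or
  differential-oxygenation physiology); the oxygen model is a single global
  DO2 number, not regional delivery.
* The Impella table is a class-shaped default, not manufacturer data.
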