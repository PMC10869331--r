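# ecpella

A closed-loop, zero-dimensional (lumped-parameter) simulator of the adult
circulation under combined mechanical circulatory support — VA-ECMO plus an
Impella-class percutaneous LV pump ("ECPELLA"), with VV-ECMO as an
oxygenation add-on. It is aimed at computational physiologists and
intensive-care researchers who want to explore, on a desk, how pump settings
interact with ventricular function, ventricular loading and global oxygen
delivery in cardiogenic shock.

## The model

Systemic and pulmonary circulations are 5-element resistance–capacitance
networks (characteristic impedance `R_Z0`, arterial / capillary / venous
resistances and compliances). The four cardiac chambers are time-varying
elastance elements: pressure blends a linear end-systolic relation (ESPVR,
slope `E_es`, intercept `V0`) with an exponential end-diastolic relation
(EDPVR, `P = α(e^{βV} − 1)`) weighted by a normalized double-Hill activation
`a(t)`,

    P(V, t) = a(t) · E_es (V − V0) + (1 − a(t)) · α (e^{βV} − 1).

Valves are unidirectional orifices obeying `ΔP = R·Q + ρ/(2(kA)²)·Q²`
(Bernoulli). The state is the ten compartment volumes; flows follow the loop
LV → aorta → systemic artery/capillary/vein → RA → RV → pulmonary
artery/capillary/vein → LA → LV, so total volume is conserved exactly.

Devices:

* **VA-ECMO** — ideal constant flow from the systemic veins to the systemic
  artery (0–5 L/min).
* **Impella** — axial pump from LV to systemic artery; flow solves a
  per-level (P0–P9) head–capacity quadratic `ΔP = a − bQ − cQ²` at the
  instantaneous head SAP − LVP. LV suction is defined as LAP reaching
  0 mmHg; below 0 the flow is throttled linearly (the suction limiter).
* **VV-ECMO** — raises the arterial saturation of the native-lung pathway;
  no haemodynamic effect.

Global oxygen delivery:

    DO2 = 1.34 · 10 · Hb · SaO2 · (CO + Q_impella) + 1.34 · 10 · Hb · 1.0 · Q_vaecmo   [mL O2/min]

Integration is fixed-step explicit RK4 at 0.2 ms (C++ core), with beat
segmentation, steady-state window extraction (ending 2 s before each
setting change), PV-loop analytics (stroke work by the shoelace rule,
pressure–volume area by trapezoid integration between ESPVR and EDPVR) and
the four protocol sweeps over VA-ECMO flow × Impella level in
left-ventricular failure (LVF), biventricular failure (BVF) and BVF with
pulmonary hypertension (BVF_PH).

## Worked example

```r
library(ecpella)
sc   <- scenario_preset("NORMAL")
ts   <- simulate_scenario(sc, duration = 30)          # 30 s, devices off
snap <- extract_steady_snapshots(ts, n_beats = 4)[[1]]
round(summarize_snapshot(snap), 2)
#>   impella_level vaecmo_flow converged   CO total_systemic_flow mean_AP mean_RAP
#> 1             0           0         1 4.72                4.72   81.52     5.32
#>   mean_LAP LVEDP Q_impella Q_vaecmo   SW_LV   SW_RV PVA_LV  PVA_RV suction
#> 1     10.5 12.01         0        0 6104.84 1411.81 9358.6 1506.96       0
```

A healthy baseline: cardiac output 4.7 L/min, mean arterial pressure
82 mmHg, right/left atrial pressures 5.3 / 10.5 mmHg, LV stroke work
6105 mmHg·mL with a pressure–volume area of 9359 mmHg·mL. With devices off,
total systemic flow equals CO.

```r
global_do2(Hb = 10, SaO2 = 0.8, CO = 1, Q_impella = 2, Q_vaecmo = 4)
#> [1] 857.6
```

A protocol sweep (here the BVF + pulmonary hypertension grid, reduced
settling) and its suction-limited Impella ceiling:

```r
p3 <- run_protocol(3, overrides = list(settle_initial = 10, settle_per_level = 10))
max_impella_flow(p3)   # per-VA-ECMO-flow maximum achieved Impella flow, L/min
```

At the reference settling (100 s initial, 50 s per level) the ceiling is
1.51 L/min at VA-ECMO 0, falling to 0.99 L/min at 5 L/min — below the
1.6 L/min bound at every VA-ECMO flow, because rising Impella support
collapses the left atrium (LAP → 0) and the suction limiter caps the pump.

## Command line

```sh
Rscript inst/cli/ecpella.R simulate CONFIG.json --out outdir
Rscript inst/cli/ecpella.R sweep --protocol 3 --out outdir
Rscript inst/cli/ecpella.R do2 --hb 10 --sao2 0.8 --co 1 --impella 2 --vaecmo 4
Rscript inst/cli/ecpella.R validate CONFIG.json
```

(Once installed, the same script lives at
`system.file("cli", "ecpella.R", package = "ecpella")`.)

## Scenario presets

JSON files under `inst/extdata/presets/` (NORMAL, LVF, BVF, BVF_PH) carry
the full circuit, chamber, device and initial-state definition; the Impella
head–capacity table is `inst/extdata/hq_curves.csv` (replace it with
manufacturer data via `default_hq_table(path=)`). The methods vignette
(`vignettes/ecpella-methods.Rmd`) documents every calibrated constant and
the reasoning behind it.
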