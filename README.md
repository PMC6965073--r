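# mtp06

Dynamical-systems analysis of early afterdepolarizations (EADs) in the
ten Tusscher–Panfilov 2006 (TP06) human ventricular myocyte model.

EADs — secondary depolarizations of the action-potential plateau — trigger
lethal arrhythmias in the long-QT syndromes. This package is for cardiac
electrophysiology modellers who want to study *why* a ventricular myocyte
model produces EADs, not just whether it does. It implements the
mid-myocardial (M) cell version of TP06 (19 ODEs; ms / mV / mM / pA-per-pF
units) with the membrane equation

    dV/dt = I_stim − (I_Na + I_CaL + I_Kr + I_Ks + I_to + I_K1
                      + I_pK + I_bNa + I_bCa + I_NaK + I_NCX + I_pCa)

plus two modified variants: **mTP06a** (g_Ks ×0.4, g_Kr ×1.5, SR uptake
P_up ×0.6 — realistic repolarization reserve and SR load, but no EADs) and
**mTP06b** (additionally τ_f, τ_f2 halved and g_CaL ×2 — the EAD-competent
cell). On top of the ionic model it provides:

* paced simulation with per-beat AP features (V_min, V_max, APD₉₀), EAD
  detection (plateau oscillations ≥200 ms after the AP peak) and behavior
  classification — no-EAD, fast-repolarizing EADs (fR), repolarization
  failure (RF), local response;
* equilibrium location (V_E1–V_E3), eigenvalue stability, one-parameter
  branch continuation with Hopf bisection, limit-cycle shooting with
  Floquet multipliers, spontaneous-oscillation (SO) detection;
* the two slow-fast decompositions that explain EAD initiation and
  termination: the xs²-parameterized fast subsystem (I_Ks activation as
  the slow variable) and the Ca_SR-parameterized voltage-clamped fast
  subsystem (spontaneous SR Ca²⁺ release);
* voltage-clamp pulse-train simulation, spontaneous SR-release detection,
  and the bifurcation structure of the intracellular Ca²⁺ subsystem
  versus clamped V_m, P_up, NCX activity and g_CaL;
* two-parameter phase diagrams of paced behavior with warm-started sweeps
  and overlays of the non-paced bifurcation curves.

## Worked example

Basal APD₉₀ of the mTP06b cell at 1 Hz, and the EAD threshold under
I_Kr reduction (the LQT2 condition) at 0.2 Hz:

```r
library(mtp06)

params <- build_parameters("mTP06b", fix_Ki = TRUE)
run <- simulate_paced(params, make_pacing(1000), n_beats = 1800)
print(run)
#> Paced simulation: 1800 beats at CL 1000 ms  
#>   last beat: V_min -86.2 mV, V_max 29.8 mV, APD90 333.2 ms, EAD extrema 0

lqt2 <- build_parameters("mTP06b", overrides = list(gKr = 0.6),
                         fix_Ki = TRUE)
ead <- simulate_paced(lqt2, make_pacing(5000), n_beats = 20,
                      stop = "converge")
print(ead)
#> Paced simulation: 20 beats at CL 5000 ms  
#>   last beat: V_min -86.5 mV, V_max 40.7 mV, APD90 659.6 ms, EAD extrema 1
classify_behavior(ead)
#> [1] "fR"
```

Reading: at control I_Kr the cell repolarizes in 333 ms with no plateau
oscillations; with g_Kr at 60% of control the plateau carries an EAD
oscillation and APD₉₀ roughly doubles, but the AP still repolarizes before
the next stimulus (fast-repolarization type). The dynamical explanation — a
stabilized depolarized quasi-equilibrium of the xs²-parameterized fast
subsystem that transiently traps the trajectory — is computed by
`fast_subsystem()` / `quasi_branch()` / `overlay_trajectory()`; see the
vignette `vignettes/ead-dynamics.Rmd`.

The non-paced cell's equilibria behind these behaviors:

```r
eps <- find_equilibria(lqt2)
sapply(eps, function(e) c(V = round(e$state[["V"]], 1),
                          stable = e$stability$stable))
#>         [,1]  [,2] [,3]
#> V      -86.3 -44.4 -6.2
#> stable   1.0   0.0  0.0
```

Three equilibria; only the resting one is stable, and the depolarized one
(V_E3) is the organizing center of the EAD dynamics.

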