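---
title: "Dynamical analysis of phase-2 EADs in modified TP06 ventricular myocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical analysis of phase-2 EADs in modified TP06 ventricular myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtp06)
```

## The model and the problem

Early afterdepolarizations (EADs) are secondary depolarizations of the
cardiac action potential (AP) plateau that can trigger lethal arrhythmias in
the long-QT syndromes. `mtp06` implements the mid-myocardial (M) cell
version of the ten Tusscher–Panfilov 2006 (TP06) human ventricular myocyte
model — 19 ordinary differential equations for the membrane potential
$V_m$, eleven voltage-gated channel gates, the Ca$^{2+}$-dependent L-type
channel gate, the fraction of closed SR release channels, and the Na$^+$,
K$^+$ and Ca$^{2+}$ concentrations of the myoplasm, the dyadic subspace and
the sarcoplasmic reticulum (SR) — together with the dynamical-systems
toolbox needed to explain when and why that model produces EADs.

The membrane equation is

$$\frac{dV_m}{dt} = I_{stim} - (I_{Na} + I_{CaL} + I_{Kr} + I_{Ks} + I_{to}
 + I_{K1} + I_{pK} + I_{bNa} + I_{bCa} + I_{NaK} + I_{NCX} + I_{pCa}),$$

in ms / mV / mM / pA-per-pF units, with external concentrations fixed at
$[K^+]_o = 5.4$, $[Na^+]_o = 140$ and $[Ca^{2+}]_o = 2.0$ mM. The equations
and constants were transcribed from the public CellML encoding of the
M-cell model (the code-version constants, e.g. the 562/240/80 form of the
$\tau_{f2}$ curve and $V_{rel} = 0.102\,\mathrm{ms}^{-1}$).

Two modified parameterisations are built in (`build_parameters()`):

* **mTP06a** — $g_{Ks} \times 0.4$, $g_{Kr} \times 1.5$, $P_{up} \times
  0.6$. This matches the experimentally observed mild response of human
  myocytes to $I_{Ks}$ block and brings the paced SR Ca$^{2+}$ content down
  from the original model's 3–4 mM to the 1.3–2.6 mM range, but it does not
  produce EADs.
* **mTP06b** — mTP06a plus halved voltage-dependent $I_{CaL}$ inactivation
  time constants ($\tau_f$, $\tau_{f2}$) and doubled $g_{CaL}$. This is the
  EAD-competent cell used for almost all analyses.

All scaling knobs (`gKs`, `gKr`, `gCaL`, `Pup`, `NCX`, `tau_fL`, ...) are
expressed as *normalized* values — ratios to the active variant's control —
and applied multiplicatively, matching how the source study reports them.

### Which inactivation gate is halved?

TP06 has two voltage-dependent $I_{CaL}$ inactivation gates ($f$, $f_2$).
"Halving the inactivation time constant" is ambiguous between $f$ only,
$f_2$ only, or both. We apply the halving to **both** gates and expose
per-gate overrides (`tau_f`, `tau_f2`). The choice was settled empirically:
with both gates halved the EAD onset under $g_{Kr}$ reduction at 0.2 Hz
falls at a normalized $g_{Kr}$ of 0.771; with $f$ only it falls near 0.73,
and with $f_2$ only no EADs form at all. Only the both-gates reading
reproduces the reference behavior.

## Conventions that matter

* **$K_i$ fixed at 140 mM.** The model's free-running K$^+$ balance makes
  the autonomous system degenerate (a conserved-charge continuum of
  equilibria) and, more subtly, couples slow $K_i$ drift into the EAD
  threshold. All bifurcation-type analyses fix $K_i$; we adopt the same
  convention for the critical-point and rate-switch pacing protocols, where
  it also reproduces the reference results decisively (e.g. critical
  $g_{Kr}$ 0.771 fixed vs 0.761 free). `fix_Ki = FALSE` remains available.
* **$Na_i$ free in paced runs, fixed at 6 mM** for the slow-fast and
  voltage-clamp analyses. Slow $Na_i$ drift is the mechanism behind the
  bradycardia-induced EADs, so pacing must leave it free.
* **Stimulus: 60 pA/pF for 1 ms**, depolarising, with its charge carried in
  the K$^+$ balance. Without that bookkeeping $K_i$ drains by >10 mM over a
  30-minute paced run and the dynamics drift qualitatively.
* **Initial conditions.** Gates start on their steady-state curves at the
  resting potential; concentrations default to the CellML resting values
  for the original variant and to a low-SR-load resting set ($Ca_{SR} =
  1.5$ mM, $Ca_i = 10^{-4}$ mM, $Ca_{ss} = 2\times 10^{-4}$ mM, $Na_i = 10$
  mM, $K_i = 140$ mM) for the $P_{up}$-reduced variants. This matters: the
  $g_{Kr}$-reduced mTP06b cell is bistable, and pacing it from the original
  model's high SR load ($Ca_{SR} = 4.27$ mM) lands it in an EAD attractor
  that the reference protocols never visit.
* **Solver.** `deSolve::lsoda` over a compiled C right-hand side, relative
  tolerance $10^{-8}$ (the study's stated tolerance) and per-variable
  absolute tolerances ($10^{-11}$ for $Ca_i$, $Ca_{ss}$). Halving the
  tolerances changes converged APD$_{90}$ by well under 0.5 ms and no
  critical value or EAD index we checked.

## Paced simulation and EAD classification

`simulate_paced()` integrates beat-by-beat (fine output sampling around the
stimulus), extracting per-beat features as it goes: the phase-4 minimum
$V_{min}$, the early phase-2 maximum $V_{max}$, APD$_{90}$ (measured from
the stimulus to 90% repolarisation of the amplitude above the beat's own
preceding $V_{min}$, across later beats if repolarisation is deferred), and
the local extrema of plateau oscillations. An oscillation counts as an EAD
when it occurs 200 ms or later after the AP peak, before repolarisation to
rest (−75 mV), with at least 1 mV prominence — the floor suppresses
integrator ripple while keeping the ~5–30 mV EADs of this cell
(configurable via `feature_options()`).

Runs stop on a fixed beat budget, at the beat-to-beat convergence criterion
(relative change of $V_{min}$, $V_{max}$ and APD$_{90}$ each below
$10^{-3}$), or at the first EAD-bearing beat. `classify_behavior()` pools
the last ten stimuli into one of four labels:

* `no_EAD` — regular APs, no plateau oscillations;
* `fR` (fast repolarisation) — EADs with APD$_{90} \le 5$ s;
* `RF` (repolarisation failure) — EADs or a depolarised plateau that the
  cell does not leave on its own (APD$_{90} > 5$ s or unresolved);
* `local_response` — the cell is trapped above −40 mV between stimuli *and
  quiescent there*: stimulus-evoked deflections decay straight back to the
  stable depolarised equilibrium.

The quiescence clause is a deliberate revision of a draft rule that also
required the stimulus-evoked overshoot to stay below 0 mV: a 60 pA/pF,
1-ms stimulus by itself deflects $V_m$ by up to +60 mV, so an
overshoot-based test can never fire from a depolarised equilibrium near
0 mV. Trapped-and-oscillating states are RF; trapped-and-quiet states are
local responses. This keeps the phase-diagram boundary between the two
aligned with the Hopf set of the non-paced cell, which is the dynamical
content of the distinction.

## Equilibria, branches and limit cycles

At any equilibrium every gate sits exactly on its steady-state curve, so
the equilibrium problem reduces to at most six slow unknowns ($V_m$,
$Na_i$, $K_i$, $Ca_i$, $Ca_{ss}$, $Ca_{SR}$) minus whatever is fixed.
`find_equilibria()` exploits this twice over: for each membrane potential
on a scan ladder it equilibrates the clamped subsystem (a damped Newton
iteration in log-concentration space, with the free-$Na_i$ balance solved
by an outer bracket-and-bisect — the direct Newton direction lies along the
very slow $Na_i$ manifold and stalls), then bisects sign changes of the
total membrane current in $V_m$. This yields the up-to-three equilibria
$V_{E1} < V_{E2} < V_{E3}$ with scaled residuals below $10^{-10}$.

Stability comes from the eigenvalues of a central finite-difference
Jacobian over the free variables. The *spiral* annotation used in the
slow-fast analysis is a convention we fix as follows: an equilibrium is a
spiral sink/source when a complex eigenvalue pair either leads the spectrum
or decays at most four times faster than the slowest real mode. (The
EAD-period pair of the depolarised quasi-equilibrium sits below two or
three near-neutral real modes; trajectories visibly spiral at its
~180-ms period, which is what the annotation is meant to capture.)

Limit cycles are located by single shooting with the period as an unknown
and a pinned-coordinate phase anchor, seeded either from simulation (the
seed is taken in the orbit's quiet phase, where closure error is least
sensitive to phase) or from the Hopf normal form (equilibrium plus a small
displacement along the critical eigenvector, period $2\pi/\omega$). Because
the SR-release orbits are relaxation-type — a sub-millisecond period error
moves a large Ca$^{2+}$ spike — the period is pre-refined by a grid search
before Newton. Floquet multipliers come from a central-difference monodromy
at tightened tolerance; the trivial multiplier within $10^{-3}$ of 1 is the
convergence gate. One honest limitation: the strongly unstable orbits of
the clamped Ca$^{2+}$ subsystem between its Neimark–Sacker points carry
multipliers of $10^2$–$10^4$, beyond what single shooting can resolve a
unit multiplier against; the gate is verified on the mildly unstable
EAD-period quasi-limit cycles instead, which are the orbits the slow-fast
argument actually uses.

## The two slow-fast decompositions

`fast_subsystem("xs", ...)` freezes the $I_{Ks}$ activation gate (as the
open probability $xs^2$, the diagram axis), $Na_i$ (6 mM) and $Ca_{SR}$
(0.5 mM, or 1.5 mM for the $g_{Kr}$-reduced mTP06b cell, the values reached
just before the first EAD). `quasi_branch()` then continues the fast
subsystem's equilibria and locates the Hopf point; `overlay_trajectory()`
projects a full-system trajectory (with the same $Na_i$/$Ca_{SR}$ frozen)
onto the $(xs^2, V_m)$ plane and reports *trapping*: the dwell time within
2 mV of the stable depolarised quasi-equilibrium before the trajectory
crosses the steady-state $xs^2$ curve (threshold 100 ms; conclusions are
robust to doubling either constant). Trapping — present only in the
$g_{Kr}$-reduced mTP06b cell — is the EAD mechanism: accelerated $I_{CaL}$
inactivation turns the depolarised quasi-equilibrium into a spiral sink,
$g_{Kr}$ reduction widens its stable $xs^2$ range, and slow $I_{Ks}$
activation carries the cell along it until escape, which terminates the
EADs.

`fast_subsystem("CaSR", ...)` clamps $V_m$ and treats $Ca_{SR}$ as the
parameter of the Ca$^{2+}$-handling fast subsystem (free: the
Ca$^{2+}$-dependent gate, the release-channel pool, $Ca_{ss}$, $Ca_i$; the
voltage gates equilibrate at the clamped potential and are kept as states,
which is equivalent at the equilibria and simpler). Its subcritical Hopf
point gives the $Ca_{SR}$ threshold for spontaneous SR release: during a
clamp pulse train the raised-$P_{up}$ cell refills past the Hopf value and
releases; the control cell never reaches it.

## Voltage clamp and release detection

`simulate_clamped()` drives the $Na_i$/$K_i$-fixed cell through 1-s steps
from −85 to −10 mV at 0.5 Hz (configurable). `detect_release_events()`
flags spontaneous SR Ca$^{2+}$ releases as drops of at least 5% of
$Ca_{SR}$ within 100 ms accompanied by a $Ca_i$ rise; events within the
window around a pulse onset are flagged pulse-triggered and excluded from
spontaneous counts (the forward-looking drop detector can fire up to one
window early, so the exclusion interval extends a window before each
onset). `ca_bifurcation_vs_vm()` scans the clamped potential, bisects the
two Hopf points bounding the unstable range, and `hb_locus()` traces how
that range widens with $P_{up}$, reduced NCX activity or raised $g_{CaL}$.

## Phase diagrams

`sweep_plane()` classifies the paced cell on a two-parameter grid with
warm-started initial conditions along each line (full convergence at the
first point, a fixed budget thereafter), mirroring the sweep protocol under
which the reference results were obtained; ascending/descending traversal
disagreements are flagged `bistable` rather than averaged.
`overlay_bifurcation()` merges non-paced curves (Hopf locus, spontaneous
oscillation onset/offset) and computes containment statistics such as the
fraction of the spontaneous-oscillation region labeled RF. Defaults are
desk-scale (coarse grids with optional boundary refinement); the study's
exhaustive 0.001-step scans are reproduced only where a printed critical
value is checked.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at desk scale, chosen so the whole
suite completes in minutes while still exercising every printed quantity it
checks: 30-minute pre-paces for converged paced states, 0.001/0.002-step
warm-started scans only across the onset neighbourhoods, 10-minute clamp
trains, 21-point slow-fast branches, and a 6×3 phase-diagram grid. The
generator defaults themselves (stimulus, tolerances, convergence criterion,
clamp protocol) are the study conditions, not tuned quantities.

## What the synthetic checks do and do not show

Constructed voltage traces (piecewise-linear upstroke, exponential
repolarisation, superimposed damped oscillations) verify the feature
extractor against closed-form APD$_{90}$ and oscillation counts; they
emulate idealised AP shapes, not the model's full waveform diversity
(notch-and-dome shapes, alternans), which the simulation-based tests cover.
All results here are properties of one deterministic ionic model under the
stated conventions; agreement with the reference values validates the
transcription and the analysis machinery, not the model's fidelity to real
human myocytes — single-cell EADs, a one-compartment SR with steady-state
buffering, and no late Na$^+$ current or beta-adrenergic signalling
dynamics are all built-in limitations.

## Known limitations

* The Supplementary beta-adrenergic scaling table of the source study is
  not shipped; `beta_as_scalings()` carries the printed folds only, which
  reproduces the LQT1 beta-stimulation thresholds approximately (within
  2 pp at 50% $g_{Ks}$, worse for the normal cell).
* One knife-edge printed value (the 172nd-stimulus EAD onset after a CL
  1 s → 3 s switch at normalized $g_{Kr}$ = 0.721) is not reproduced: this
  transcription places the CL-3 s EAD boundary at $g_{Kr} \approx 0.720$,
  about 0.1% below the operating point, and the corresponding run settles
  into an EAD-free steady state. The companion indices (74th and 51st at
  CL 4 s and 5 s) reproduce within ±1.
* Homoclinic points are flagged heuristically (period blow-up with saddle
  approach), matching their descriptive use; no rigorous homoclinic
  continuation is attempted.
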