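---
title: "cardpes: model, calibration and virtual PES methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardpes: model, calibration and virtual PES methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Patients with heart failure (HF) are vulnerable to reentrant ventricular
arrhythmias triggered by tightly coupled premature beats: a premature wave
front that encroaches on the repolarizing tail of the preceding wave takes
off from an elevated potential (elevated TOP), propagates slowly, and can
block and break in heterogeneous tissue. Chronic amiodarone (AM) is known
clinically to prevent such induction, and monophasic-action-potential
recordings in patients attribute this to *post-repolarization
refractoriness* (PRR = ERP − APD): with AM, the earliest possible premature
beat arises only after full repolarization, with a normal upstroke.

`cardpes` implements a minimal human ventricular action-potential model,
disease (HF) and drug (AM, d-sotalol) parameterizations calibrated to
clinical targets, virtual programmed electrical stimulation (PES, S1×8 +
S2–S4) in cells, 1-D cables and 2-D monodomain sheets with imposed APD
gradients, and a classifier for the reentry outcome of each 2-D run.

## The ionic model

The membrane carries six currents over four state variables
(v, h, w, ca_d):

* **I_Na** `= g_na · m∞(v)³ · h · (v − e_na)` — instantaneous cubed
  activation (midpoint −40 mV), a single inactivation gate h with
  steady-state availability `h∞(v) = 1/(1 + exp((v − (eh_mid +
  eh_shift))/kh))` and a voltage-dependent time constant
  `tau_h = tauh_scale · (1 + ca_alpha·ca_d) · tau_h0(v)`.
* **I_Ca,L** `= g_cal · d∞(v) · w · (v − e_ca)` — a Gaussian activation
  window centred near −17 mV (active roughly −30 to −5 mV) gated by the slow
  inactivation variable w (`tau_w`, voltage-independent).
* **I_Kr, I_Ks, I_K1, I_to** — instantaneously gated potassium currents:
  I_Kr an activation×rectification bump spanning the dome and early phase 3,
  I_Ks a plateau-activated sigmoid, I_K1 an inward-rectifier confined below
  about −50 mV that anchors the resting potential at e_K = −88 mV and
  steepens terminal repolarization, I_to a depolarized-activated transient
  outward surrogate shaping the peak/early dome.

The action potential mechanism: I_Na fires the upstroke and closes within a
millisecond (`tau_h0 < 1 ms` above −30 mV); the membrane settles into a
low dome near −12 mV where the I_Ca,L window current balances the potassium
currents; the dome decays as w inactivates, and once the balance tips,
I_Kr and then I_K1 complete repolarization. APD is therefore governed by the
K/Ca,L balance in the dome and by the w memory, which also produces APD rate
adaptation (incomplete w recovery at short diastolic intervals shortens the
next APD) and the progressive S1→S4 APD decrease under PES.

Excitability recovery is governed by h: `tau_h0(v)` is an asymmetric bump
peaking (≈7 ms in control) near −72 mV, with a flat-topped (quartic)
depolarized flank that keeps the wavefront foot slow-inactivating down to
≈−40 mV and a narrow Gaussian hyperpolarized flank so diastolic recovery
at −88 mV is fast. Class-I drug effects scale this whole curve
(`tauh_scale`), shift availability (`eh_shift`), or reduce `g_na`. The
diastolic-calcium scalar `ca_d` integrates |I_Ca,L| with gain `ca_gain` and
decays at `ca_decay`; it slows h recovery multiplicatively
(`1 + ca_alpha·ca_d`), a reduced surrogate for the calcium dependence of
sodium-channel recovery. This continuous form is the integrated equivalent
of a per-beat increment plus inter-beat exponential decay.

All equations are integrated with the forward Euler method (`dt` 0.001 ms in
0-D/1-D, 0.01 ms in 2-D), gates clipped to [0, 1]; tissue is an isotropic
monodomain with a 5-point Laplacian, no-flux boundaries, `dx` 0.01 cm (1-D)
or 0.02 cm (2-D) and diffusion coefficient 0.001 cm²/ms. Every simulation
starts from v = −88 mV, gates at their steady states at −88 mV, and
`ca_d = 0`.

### Shape constants and what was fitted to what

The underlying published model equations are not public; this package is a
constrained reconstruction. The voltage-curve *shape constants* (midpoints,
slopes, the tau_h0 bump, tau_w, the window location) were fixed once during
development by fitting the model's steady-state behaviour to the printed
clinical calibration/validation values across all variants simultaneously
(control APD 288 ms at BCL 1000 and ~242 ms at BCL 400; HF APD 320 ms; AM
cell APD 298 ms at BCL 400 and +32% at BCL 1000; DS APD 265 ms; upstroke
velocities 245/205/180 mV/ms; HF CV −13%). They are thereafter never
touched. The *variant parameters* (conductance scale factors, g_na, uniform
K scales, tauh_scale) are produced by the calibration module at run time;
`default_control_params()` stores the converged control values so variants
can be built quickly, and every stored value can be re-derived with
`calibrate = TRUE`.

## Variants

* **Control** — calibrated to cell APD 288 ms (BCL 1000) and dV/dt_max
  245 mV/ms.
* **HF** — peak-current reductions I_Ks −58%, I_K1 −41%, I_to −44%,
  I_Ca,L −25%; g_na reduced to match dV/dt_max = 180 mV/ms from failing
  human tissue. In this reconstruction the calibrated g_na factor is ≈0.7
  (the original model reported −39%; the exact factor depends on the
  model's dV/dt–g_na relation, which the printed values do not pin down).
* **AM1–AM8** — all combinations of three binary axes:
  `k1_block` (I_K1 −64% in addition to I_Ks −39%, I_Kr −55%),
  `dvdt_reduced` (upstroke target 205 instead of 245 mV/ms), and
  `avail_shift` (−10.8 mV availability shift). The blocked potassium
  conductances are then scaled uniformly to reach APD 298 ms at BCL 400,
  and (g_na, tauh_scale) are solved simultaneously so the S1 dV/dt_max hits
  its target and the mean PRR over S2–S4 is 8 ms; a second K-scale /
  (g_na, tauh) pass leaves the finished variant on all three targets at
  once. The clinically anchored scale factors were reported as ≈1.4 (with
  I_K1 block) and ≈1.45 (without); this reconstruction converges to ≈1.52
  and ≈1.36 respectively — same magnitude, reversed ordering, reflecting
  its different I_K1 share of repolarization — and its calibrated
  tauh_scale values span ≈12–32 against the reported 12.8–22.7. Variant
  index = 1 + 4·k1_block + 2·dvdt_reduced + avail_shift (the original
  AM1–AM8 labels are not tied to printed axes, so comparisons are
  per-axes, not per-label).
* **AM′** — the same AM variants with `tauh_scale` overwritten to 2.0
  (matching DS), not re-calibrated: isolates the role of slowed I_Na
  recovery.
* **DS (d-sotalol)** — I_Kr −23% (fine-tuned within ±3 percentage points to
  APD 265 ms at BCL 400) and `tauh_scale` ×2.0.
* **HF+drug** — effects assumed independent: conductance factors multiply,
  availability shifts add, tauh factors multiply. Drug deltas are calibrated
  on the control base and composed onto HF without re-calibration.

## Calibration machinery

All searches are bisections on brackets whose monotonicity is asserted
first (APD decreasing in the K scale, dV/dt_max increasing in g_na, PRR
increasing in tauh_scale), with explicit residual reports. Tolerances:
0.5 ms (APD targets), 2 mV/ms (dV/dt_max), 1 ms (mean PRR) — chosen below
the reporting precision of the clinical targets. The (g_na, tauh_scale)
solve nests the g_na bisection inside an outer geometric bisection on
tauh_scale. The PRR target "≈8 ms" is interpreted as the mean over S2–S4 in
the single cell (the clinical measurements were RV values; whether the
original calibration used cell or cable context is ambiguous — cable PRR is
reported but not constrained).

## Virtual PES

Eight S1 beats at BCL 400 ms (2-ms, −30 µA/cm² stimuli; C_m = 1 µF/cm² so
pA/pF and µA/cm² coincide), then for S2, S3, S4 in turn the coupling
interval is scanned upward in 1-ms increments (5 ms in 2-D) from the
preceding beat's APD minus 50 ms (guaranteed sub-refractory) until capture;
the ERP is the first capturing interval, and the next premature beat stacks
on the response delivered at its ERP. Capture criteria: peak I_Na more
negative than −100 µA/cm² (cell; strict inequality) or propagation along
the entire tissue (1-D/2-D). Conventions chosen where the protocol leaves
them open: coupling intervals are referenced to the preceding stimulus
onset; PRR_n = ERP_n − APD_{n−1}; DI_n = activation_n − *undisturbed*
repolarization_{n−1} (negative for encroaching beats); APD thresholds
−30/−75 mV with linear interpolation; cell dV/dt_max is computed from the
membrane currents (identical to dv/dt outside the stimulus window and free
of the stimulus artifact inside it). In cables (5 cm, stimulated over
0.1 cm at one end) measurements are taken at the midpoint; the takeoff
potential of a propagating beat is the minimum potential at the recording
site in the 12 ms before its local activation. The 1-D/2-D ERP search
advances the base state incrementally and brackets the capture transition
with 4-ms (1-D) or 5-ms (2-D) trials before refining at the protocol
increment, so the reported ERP is still the first capturing interval at
that increment.

## 2-D sheets and the APD gradient

`build_gradient_sheet()` interpolates each node's parameters between a
corner (control) and a centre (HF or HF+drug) model along tent
("pyramidic") blends — g_Ca,L vertically, the potassium conductances
horizontally — so the longest APD occurs near the centre and the
bottom-left/top-right corners are exactly control. g_na and the drug
kinetics parameters (tauh_scale, eh_shift) blend along the horizontal tent
with the potassium conductances so the corners remain drug-free; the
original description specifies the gradients only for the conductances.
The APD gradient of a run is (APD_max − APD at the lower-left corner)
divided by the distance between those sites, in ms/cm, computed from the
final S1 APD map — the difference-per-distance reading consistent with the
printed units.

PES is delivered from a 0.1 × 0.1 cm bottom-left footprint, ERPs determined
at that site with 5-ms increments, and the simulation continues for 2 s
after the last premature beat at full scale.

### Reduced-scale mode

The full experiments (16–24 cm sheets, 2-s horizons, dt 0.01 ms) are a
documented long-running mode (`run_scenario("table1"/"table2")`). The test
suite uses a reduced geometry chosen once: 2-cm sheets (2.5 cm for the
HF+DS centre, whose block line needs slightly more room to fragment away
from the boundary) at dx 0.01 cm — the 1-D spacing, kept because this
reconstruction's wavefront falls below its discrete propagation limit at
coarser grids — dt 0.02 ms (inside the 2-D diffusion stability bound of
0.025 ms), 2 S1 beats, 3 premature beats, and a 0.5-s post-stimulus
horizon. At this scale a full reentrant circuit does not fit (the
wavelength is comparable to the domain), so the reduced assertions target
the mechanism: with an HF centre the premature wave front blocks and
fragments in the long-APD core (wave break: transient interior phase
singularities); with an HF+AM centre no reentrant re-excitation occurs
(zero rotations, zero extra beats); with the slowed I_Na recovery removed
(HF+AM′, HF+DS) the fragmenting block reappears. What passes at reduced
scale therefore demonstrates the front–tail mechanism and its drug
modulation, not the sustained VT/VF end states of the full-scale tables.

## Reentry classification

Phase is obtained per node by time-delay embedding,
`atan2(V(t−τ) − V*, V(t) − V*)` with V* = −40 mV and τ = 8 ms; phase
singularities are plaquettes with winding ±2π. Wave break = singularities
present in at least 3 frames; rotations are counted as the unwrapped phase
advance at a probe node beside the singularity trajectory divided by 2π;
extra beats are re-excitations of the stimulus site after its stimulated
response; "sustained" means activity persists to the horizon. Labels:
`none`, `eb(n)`, `vt`, `vfvt` (sustained single-rotor with cycle length
< 150 ms), `nsvf` (self-terminating multi-rotor), `vf` (sustained
multi-rotor, mean concurrent singularities > 1.5). These operational
definitions and thresholds are documented assumptions (the source tables
give no operational definitions), verified exactly on synthetic rigidly
rotating phase fields; exact label-for-label reproduction of the published
outcome tables is not promised.

## Numerical choices and degenerate inputs

* Forward-Euler APD agrees with an adaptive stiff ODE solution of the same
  right-hand side to < 1 ms, and halving dt changes APD by < 0.5 ms.
* Tissue kernels tabulate the voltage-dependent terms at 0.02 mV resolution
  with linear interpolation.
* Gates are clipped to [0, 1] after each step; non-finite or |v| > 200 mV
  states abort with the offending time (and node).
* Strongly potassium-blocked cells can have APD approaching the BCL; pacing
  windows extend 300 ms past the last stimulus so the final beat's APD is
  still measured.
* ERP scans abort with a protocol error if no capture occurs within 600 ms.
* The stimulated end segment (0.1 cm) exceeds the space constant
  (≈0.08 cm), which a point stimulus would not.

## Known limitations

No pumps or exchangers, no intracellular calcium cycling beyond the scalar
`ca_d`, no late sodium current, no separate slow inactivation gate, no
Markov drug-binding states, no anisotropy or patient geometry; most gates
are instantaneous, so fine voltage-clamp details are out of scope. The
model is a calibrated reconstruction: printed calibration and validation
targets pin its behaviour, not equation identity with the original. The
HF+AM combination assumes independent, multiplicative effects. The
diastolic-calcium surrogate reproduces rate-dependent accumulation
qualitatively (strong accumulation at 3 Hz, near-baseline levels at
BCL 2000 ms); its quantitative match to reported accumulation factors is
approximate.
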