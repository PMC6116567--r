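---
title: "neohaem: model, assumptions and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neohaem: model, assumptions and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neohaem)
```

## Scope and intent

`neohaem` is a deliberately reduced, three-state lumped-parameter model of
cerebral haemodynamics and oxygen metabolism in the preterm neonate. Its
purpose is qualitative and mechanistic: to reproduce the *sign patterns*
and relative magnitudes of stimulus-evoked fNIRS responses (adult-like
hyperemia versus the inverted deoxyhaemoglobin-increasing response), the
steady-state autoregulation behaviour of the immature brain, and to
support least-squares estimation of stimulus amplitudes from measured
traces. It is not a biochemically detailed brain-energy-metabolism model:
glycolysis, pH buffering, adenosine pools, membrane potentials, venous
compliance dynamics and pulsatile flow are all out of scope, and no claim
is made that simulated traces agree quantitatively with any particular
instrument's measurements.

## State variables and closure equations

The dynamic state is `(mu, O2t, a)`:

* `mu` — vascular smooth-muscle tone, dimensionless in [-1, 1]; positive
  tone constricts. It relaxes with time constant `tau_mu` towards a
  *saturating* function of the stimulus,
  \[
  \frac{d\mu}{dt} = \frac{\tanh(\eta) - \mu}{\tau_\mu}, \qquad
  \eta = R_P\!\left(\frac{P_a}{P_{a,n}}-1\right)
       + R_C\!\left(1-\frac{\mathrm{PaCO_2}}{\mathrm{PaCO_2}_n}\right)
       + R_O\!\left(\frac{\mathrm{O2t}}{\mathrm{O2t}_n}-1\right)
       + R_u\,(1-u).
  \]
  The signs encode: pressure up constricts (myogenic), CO2 up dilates,
  tissue O2 down dilates, demand up dilates (neurovascular coupling). The
  tanh saturation is what produces an autoregulation plateau flanked by
  pressure-passive tails; because `mu` is bounded, so is the radius
  excursion, `r = r_n (1 - k_r \mu)\, m`, with `m` an externally imposed
  modulation (1 % vasoconstriction is `m = 0.99`).
* `O2t` — tissue O2 concentration (mM). Capillary-to-tissue transport is
  linear in the volume-averaged capillary saturation
  `S_c = (SaO2 + SvO2)/2`:
  \[
  \frac{d\,\mathrm{O2t}}{dt} = \kappa\!\left[D_{O2}\,(S_c\,[\mathrm{Hbtot}]
  - \sigma\,\mathrm{O2t}) - \mathrm{CMRO_2}\right],
  \qquad
  \mathrm{CMRO_2} = \mathrm{CMRO_2}_n\,(1 + k_m (u-1))\,
  \frac{g(\mathrm{O2t})}{g(\mathrm{O2t}_n)},
  \]
  with `g(x) = x/(x + K_mO2)` a Michaelis–Menten limitation. Venous
  saturation is the instantaneous Fick balance
  `SvO2 = SaO2 - CMRO2/(CBF [Hbtot])`; if it would fall below zero the
  simulation *stops with an error* rather than clipping — a negative
  venous saturation means the parameterisation or stimulus has left the
  model's domain of validity.
* `a` — oxidised fraction of the CuA centre of cytochrome-c-oxidase,
  balancing O2-dependent oxidation against demand-driven reduction:
  `da/dt = k_CuA [ g/g_n (1-a) - k_red u a ]`. The observable oxCCO signal
  is `a [CCO]_tis` in uM.

Flow follows a Poiseuille-type quartic conductance with the intracranial
pressure as effective downstream pressure,
`CBF = K_flow r^4 (P_a - P_ic)`. Blood volume has a static venous
compartment and an arterial compartment scaling with `r^2`:
`V_blood = V_{blood,n} (f_art (r/r_n)^2 + 1 - f_art)`. Tissue haemoglobin
observables weight arterial and venous saturations by their volumes;
change signals are referenced to the mean of the first 10 s (pre-stimulus
baseline) of each run.

### Units

Flows are ml 100g⁻¹ min⁻¹ and metabolic rates umol 100g⁻¹ min⁻¹
throughout (time integration is in seconds internally; the minute-based
rates are converted once inside the right-hand side). `[Hbtot]` is stored
in mM of *haem units* — one O2 binding site per haem, no factor 4. This
convention is deliberate: with the tabulated normal values it yields
baseline oxygen extraction fractions of about 0.22 (preterm) and 0.36
(adult), which are physiologically sensible, whereas tetramer units would
make extraction implausible. Clinical haemoglobin in g/dL is converted by
`g/dL * 10 / 64500 * 4 * 1000` mM (`subject_overrides()`).

## Parameters

Subject/population fields (per preset): normal flow `CBF_n`, metabolic
rate `CMRO2_n`, arterial and intracranial pressures `P_a_n`, `P_ic_n`,
haemoglobin `Hbtot`, blood volume fraction `V_blood_n`, CCO pool
`CCO_tis`, normal oxidised fraction `CuA_frac_n`. The two population
presets (`adult`, `preterm`) ship as JSON under `inst/extdata/presets/`
and are validated against their reference values on load; `neonate1` and
`neonate2` are the preterm preset with subject haemoglobin (17.08 and
9.70 g/dL) and baseline SpO2 (0.95; and 0.935, the midpoint of the
recorded 92–95 % range) applied.

Shared closure constants, with defaults chosen once:

| parameter | default | units | role |
|---|---|---|---|
| `tau_mu` | 5 | s | tone relaxation time |
| `R_P` | 3 (adult), 10 (preterm) | – | myogenic gain; the large preterm value gives the very narrow pressure range over which flow is held |
| `R_C`, `R_O` | 1, 1 | – | CO2 and tissue-O2 reactivity gains |
| `R_u` | 1.5 | – | demand-to-tone gain (drives functional hyperemia) |
| `k_r` | 0.12 | – | maximal fractional radius excursion |
| `k_m` | 0.15 | – | demand-to-CMRO2 gain; demand moves metabolism weakly but the vasculature strongly, so dilation normally outruns consumption and HHb falls |
| `K_mO2` | 0.005 | mM | O2 limitation constant |
| `O2t_n` | 0.024 | mM | normal tissue O2 |
| `k_CuA` | 0.5 | s⁻¹ | CuA redox relaxation rate |
| `tau_O2` | 2 | s | tissue O2 pool time constant (sets `kappa`) |
| `SaO2_n`, `PaCO2_n` | 0.96, 40 | –, mmHg | baseline inputs |
| `f_art` | 0.25 | – | arterial fraction of blood volume |

`calibrate()` solves the remaining constants exactly so the baseline state
is an equilibrium: `K_flow` from the flow anchor; `k_red = (1 -
a_n)/a_n`; and the O2-transport pair `(D_O2, sigma)` from the single
balance equation plus one convention — the tissue-side back-pressure at
baseline equals half the capillary drive (`sigma O2t_n = S_{c,n}
[Hbtot]/2`), leaving the other half as the diffusion gradient that
sustains `CMRO2_n`. `kappa` then sets the linearised O2 pool time constant
to `tau_O2`. This one-line convention is the only arbitrary choice in the
calibration; it fixes the split between diffusive conductance and
gradient, to which the stimulus-evoked responses are insensitive (the
calibration re-absorbs any rescaling).

## Stimulus model

The haemodynamic response function is the classical difference of two
gamma densities (unit rate; shapes `peak_time + 1` and
`undershoot_time + 1`, undershoot weight 0.35) convolved with the stimulus
boxcar. Because the kernel integral has a closed form in the gamma CDF,
the convolution is evaluated exactly — no numerical quadrature. The result
is renormalised to unit peak on the evaluation grid, so amplitudes always
denote *peak* excursions: `beta = 7` is exactly a 7 mmHg pressure dip and
`gamma = 0.01` exactly a 1 % radius reduction, whatever the stimulus
duration. The default peak time of 5 s encodes the steeply rising response
of the neonatal studies; onset and duration are per-scenario (10 s blocks
for the somatosensory studies, 20 s for the visual ones, 60 s total).

Sign convention: positive `beta` is a pressure *decrease*. The rat group
that showed a pressure *rise* is encoded with `beta = -1.5`; the printed
formula's sign and the described physiology disagree for that group, and
the physiology (a 1.5 mmHg rise accompanying hyperemia) was kept.

## Scenario registry

Six runnable scenarios pair the published stimulus amplitudes with
presets: `kozberg_bp_rise` (alpha 2, 1.5 mmHg pressure rise),
`kozberg_no_hyperemia` (no demand change, 1 % constriction, 0.18 mmHg
dip), `roche_labarbe` (alpha 0.5), `usz_neonate1` (alpha 0.7),
`usz_neonate2` (alpha 0.7 with CBF clamped) and `usz_neonate2_bp`
(additionally a 7 mmHg dip). The rat scenarios run on the generic preterm
human preset — the animals are age-equivalent to human newborns and the
model is a human-neonate model; this is an approximation, not a claim
about rat physiology. The CBF clamp substitutes the normal flow in the
oxygen transport and in the reported `CBF` *only*; tone, radius and blood
volume keep evolving, which is what lets total haemoglobin rise while flow
is held.

## Autoregulation behaviour

`autoregulation_curve()` computes steady-state flow over a pressure grid.
Both presets pass exactly through their (normal pressure, normal flow)
anchor and show pressure-passive tails. A caveat worth knowing: with the
preterm myogenic gain `R_P = 10` the tone response *over-compensates*
near the anchor — the normalised slope there is about -0.1/mmHg, so the
curve dips below the normal flow before rejoining the passive branch, and
the plateau width measured with the 0.01/mmHg slope criterion is zero
(against roughly 130 mmHg for the adult preset). The qualitative
statement "the preterm plateau is far narrower than the adult one" holds;
the local shape of the preterm curve around the anchor should not be
over-interpreted. At pressures so low that even the fully dilated bed
cannot deliver the baseline oxygen demand the model has no equilibrium and
the curve raises the oxygen-supply-exhausted error naming the pressure —
the default grids avoid that region.

## Synthetic traces

`make_fixture()` resamples a forward simulation to the measurement rate
(default 1 Hz, the typical block-averaged presentation) and adds
independent Gaussian noise per channel with standard deviation
`noise_fraction x max |dHbO2|`, referencing the level to the scenario's
own peak so a given fraction means the same relative corruption in every
scenario. The generator reproduces: the sampling rate, block-averaged
smoothness and amplitude scale of stimulus-evoked traces. It does *not*
emulate physiological noise (Mayer waves, cardiac and respiratory bands),
motion artefacts, drifts or channel cross-talk — so a green recovery test
establishes correctness of the estimation machinery under the stated noise
model, not robustness to real instrument noise. Seeds are mandatory and
scoped: the global RNG state is saved and restored around every draw.

## Fitting

`fit_amplitudes()` minimises the equally-weighted sum of squared
differences, in uM, over whichever of `dHbO2`, `dHHb`, `dHbT` the traces
contain, the model being linearly interpolated onto the measurement times.
The search is bounded (`alpha` in [0, 5], `beta` in [-10, 10], `gamma` in
[0, 0.05]) and derivative-free — Brent on the interval for one free
amplitude, Nelder–Mead on a logistic box transform otherwise — with three
starts (the template amplitudes plus two seeded uniform draws) and the
best local optimum retained. The surface is smooth and low-dimensional;
global search would be wasted effort. Equal channel weights are a declared
default (the objective the original studies used is not recorded); a
weights argument is deliberately *not* exposed until a use case demands
one.

Every fit reports an identifiability diagnostic: the condition number of
the numerical residual Jacobian at the optimum, with `flat_direction` set
above 1e4. In this closure, demand and pressure amplitudes acting on
*total haemoglobin alone* are nearly — but not exactly — collinear: both
drive tone through the same HRF time course, but `beta` additionally
perturbs flow directly and `alpha` perturbs metabolism, and both feed
tissue O2 back into tone with slightly different shapes. The HbT-only
Jacobian columns end up about 1.3 degrees apart (condition ~200): badly
conditioned, an order of magnitude worse than the full-channel fit, yet
below the 1e4 flag threshold, which is calibrated for *exact* flat
directions (for instance with the tissue-O2 feedback disabled, `R_O = 0`,
the degeneracy is exact and the flag trips). Users fitting HbT-only data
should inspect `jacobian_condition`, not just the flag.

## Numerical choices

* **Integration**: adaptive Dormand–Prince 5(4) in compiled code,
  relative tolerance 1e-8, absolute 1e-10, steps clipped to the output
  grid (default 0.1 s). At these tolerances the scheme is effectively
  converged: halving the tolerances changes simulated peaks by less than
  one part in 1e10, so the step-halving acceptance oracle is satisfied
  with margin. Inputs are interpolated linearly between grid samples. The
  state bounds (`mu` in [-1, 1], `O2t >= 0`, `a` in [0, 1]) are invariant
  sets of the dynamics, so no projection is needed.
* **Steady states**: damped Newton from the baseline state (deterministic
  by construction), residual tolerance 1e-10, numerical Jacobian. During
  iteration the venous saturation is floored at zero so the solver can
  traverse oxygen-infeasible intermediate iterates; strict feasibility is
  re-verified at the converged root, and an infeasible root raises the
  oxygen-supply error. An independent oracle — long time-integration to
  equilibrium — agrees with the Newton solution to better than 1e-9 in the
  test suite.
* **Degenerate inputs**: zero-amplitude stimuli reproduce the equilibrium
  to under 1e-6 uM; timelines must open with >= 10 s of baseline so the
  change signals have a defined zero; pressure excursions below the
  intracranial pressure, or any state driving `SvO2 < 0`, abort with an
  error carrying the simulation time.

## Known limitations

* **Two-parameter amplitude recovery at realistic noise is partly
  ill-posed.** With 5 % peak-referenced noise at 1 Hz over 60 s, the
  Cramér–Rao bound through this forward model gives sd(alpha) ~ 0.1 and
  sd(beta) ~ 0.5 mmHg. Recovering a 7 mmHg pressure dip is easy;
  recovering a 0.18 mmHg dip to 10 % (±0.018 mmHg) is impossible by more
  than an order of magnitude, and the corresponding acceptance experiment
  is expected — and observed — to fail for those cells (pass fraction
  ~0.3 against a 0.9 requirement). The demand amplitude alone, with the
  pressure amplitude fixed, is recovered within 10 % in over 90 % of
  fits. This is an identifiability property of the stated experiment, not
  an optimiser deficiency: the fits reach the global optimum of their
  objective (zero-noise fits recover amplitudes to 1e-4).
* The preterm autoregulation curve over-compensates locally (see above).
* Simulated absolute magnitudes (tens of uM for strong stimuli) reflect
  the simple two-compartment volume model and haem-unit convention; only
  signs, orderings and relative changes should be compared against
  plotted experimental data, whose numerical values are not reproduced
  here.
* Venous volume is static; post-stimulus undershoots arising from venous
  compliance (balloon effect) are not modelled, and no undershoot
  matching is attempted.
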