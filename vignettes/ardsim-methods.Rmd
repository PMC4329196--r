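---
title: "Simulating lung recruitment maneuvers in ARDS: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating lung recruitment maneuvers in ARDS: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ardsim` simulates mechanically ventilated patients with acute
respiratory distress syndrome (ARDS) in order to compare lung
recruitment maneuvers — transient elevations of airway pressure meant to
reopen collapsed alveoli — and to ask how much positive end-expiratory
pressure (PEEP) is needed to keep the reopened lung open. This vignette
describes the model, its assumptions, the numerical choices, and the
calibration procedure, and states what the synthetic test data do and do
not establish about real patients.

## The lung model

The lung is divided into `N = 100` alveolar compartments in parallel
behind a shared series (anatomical) dead space of 150 ml. Compartment
`i` has a pressure–volume law

$$P_{alv,i} = P_{ext,i} + k_i V_i + k_{3,i} V_i^3,$$

where `V_i` is the volume above the unstressed volume, `k_i` is the
compartment stiffness (cm H2O/ml) and `P_ext,i` an extrinsic pressure
that lumps superimposed tissue weight and surface-tension effects into a
single offset. The cubic term makes compartments stiffen as they
inflate; its scale is set so that whole-lung dynamic compliance falls by
roughly a third as operating pressures climb from baseline to the
40–45 cm H2O range, the behaviour a PEEP staircase elicits in a
recruitable ARDS lung. Airflow into an open compartment follows
$\dot V_i = (P_{aw} - P_{alv,i})/R_{aw,i}$ with airway resistance
`R_aw,i`, making each compartment a first-order
resistance–compliance element with a mechanical time constant of a few
hundred milliseconds.

**Recruitment** is time-dependent: a collapsed compartment carries a
threshold opening pressure `TOP_i` and an opening time constant
`tau_c,i`. While the airway pressure exceeds `TOP_i` an opening timer
accumulates; when it reaches `tau_c,i` the compartment opens (volume
starts from zero and fills through its airway resistance). If the
airway pressure falls to or below `TOP_i` the timer resets. Under tidal
ventilation this reset rule means a compartment whose TOP lies between
PEEP and peak inspiratory pressure can only open if its `tau_c` fits
inside a single inspiration, whereas once PEEP itself exceeds the TOP
the timer accumulates across breaths — which is precisely why a PEEP
staircase recruits slow-opening units that brief inspiratory pressure
excursions cannot.

**Derecruitment** is evaluated once per breath at end-expiration as a
cliff-edge event: an open compartment whose end-expiratory alveolar
pressure is below its closing pressure `TOP_i - d_close` collapses
instantly and its volume is discarded. The closing offset `d_close`
(one global value per patient, default 15 cm H2O) places closing
pressures well below opening pressures, producing the open/closed
hysteresis that makes post-maneuver PEEP selection matter: recruitment
gained at 40–60 cm H2O can be retained at 10–16 cm H2O, but not at 5.

**Heterogeneity.** Per-compartment parameters are described by a small
set of distribution hyper-parameters rather than 100 free values, since
four blood-gas targets cannot identify hundreds of parameters. TOPs
follow a Gaussian truncated to [0, 60] cm H2O whose mean is solved so
that the fraction of compartments with closing pressure above the
baseline PEEP of 5 cm H2O equals the patient's collapsed fraction; this
anchors the printed "% collapsed" to the physics, and the baseline open
set is exactly the set maintainable at baseline PEEP. Stiffness,
extrinsic pressure and the two resistances scatter around their means
with fixed relative spreads; opening time constants are log-normal.
Draws are quantile-stratified (the `i`-th compartment takes the
`(i - 0.5)/N` quantile) with seeded pairing permutations, so a
hyper-parameter vector maps deterministically to a lung and calibration
objectives are smooth.

## Gas exchange

Alveolar gas is computed per compartment from the steady-state
ventilation/perfusion mass balance: oxygen delivered by alveolar
ventilation equals oxygen taken up by end-capillary blood
($\dot V_A (P_IO_2 - P_AO_2)/863 = 10\,\dot Q\,(Cc'O_2 - C\bar vO_2)$),
and likewise for CO2 elimination. Both balances are solved by
vectorised bisection (each side is monotone). End-capillary blood
equilibrates fully with alveolar gas; collapsed compartments pass mixed
venous blood through unchanged, so shunt is an emergent property of the
recruitment state rather than a dialled parameter. Blood chemistry uses
the Kelman rational-polynomial oxyhaemoglobin dissociation curve with
Bohr/temperature shifts, and whole-blood CO2 content from
Henderson–Hasselbalch along a blood buffer line (buffer value
25 mmol/l/pH) with a Douglas-type haemoglobin/saturation correction
carrying the Haldane effect. Mixing always happens in contents, never
tensions; arterial and venous tensions are recovered by numerically
inverting the content relations.

Perfusion distributes across compartments in proportion to vascular
conductance, modulated by three factors:

* **Hypoxic pulmonary vasoconstriction (HPV):** a sigmoid conductance
  reduction with half-effect at an alveolar PO2 of 40 mmHg, slope
  8 mmHg, floor 0.3 — collapsed compartments keep a substantial share
  of flow, as ARDS shunt fractions demand. HPV can be switched off,
  which the shunt-recovery tests use.
* **Distension:** conductance falls as `1/(1 + c_d (V/V_s)^2)`, so
  highly inflated compartments shed perfusion. This creates alveolar
  dead space at high pressure and reproduces the transient PaCO2 rise
  when ventilator pressures climb.
* **A conductance gradient toward high-TOP regions** (`q_grad`):
  dependent, atelectasis-prone lung regions receive a disproportionate
  share of pulmonary blood flow, which is why measured venous admixture
  in ARDS can exceed the anatomical collapsed fraction. The gradient
  is a fitted per-patient parameter.

The whole-body loop closes through the Fick principle at fixed cardiac
output: venous O2 content is arterial minus `VO2/(10 CO)` and venous
CO2 content is arterial plus `RQ VO2/(10 CO)`. The simulator treats
cardiac output as constant throughout; consequences of high
intrathoracic pressure for venous return and right-ventricular function
are outside the model's scope, as is any overdistension injury.

## Ventilation protocols

Protocols are segment lists of pressure-controlled square waves: airway
pressure is PEEP plus driving pressure during the inspiratory fraction
of each cycle and PEEP during expiration (instant transitions make
peak-pressure accounting unambiguous). Three maneuvers are built in:

* **MRS** (maximal recruitment strategy): 2-minute tidal steps with a
  fixed driving pressure of 15 cm H2O while PEEP climbs
  5, 10, …, 45 cm H2O, then a titration phase descending from
  25 cm H2O in 5 cm H2O steps of 5 minutes to the end-maneuver PEEP
  (an off-grid end point such as 16 cm H2O is appended exactly).
* **SI** (sustained inflation): a single breath-free CPAP hold,
  40 cm H2O for 40 s.
* **PRM** (prolonged recruitment maneuver): driving pressure stepping
  15 → 20 → 25 cm H2O every 2 minutes over a fixed PEEP of 15 cm H2O.

Every maneuver is wrapped in a pre-RM stage (PEEP 10, driving pressure
15) and a post-RM stage at the end-maneuver PEEP. Stage durations are
not dictated by the maneuver definitions; the defaults are 5 minutes
pre and 20 minutes post, both configurable. Patient-specific
ventilation rate, inspiratory fraction and FiO2 are held at their
calibrated values through all protocols.

## Numerics

Within a breath the engine exploits the structure of the model: under a
piecewise-constant airway pressure each open compartment relaxes
exponentially toward its phase equilibrium volume, so each phase is
integrated with an exponential update linearised at the equilibrium
(exact for the linear part of the PV law; the cubic correction only
shifts the equilibrium, found by vectorised Newton iteration). A
generic explicit sub-stepped integrator (`step_mechanics`, default
sub-step 10 ms) is kept for oracle tests — the engine's update agrees
with the refined explicit solution to well under 0.5%. Breaths whose
settings, recruitment state and volumes repeat are served from a cache.

Gas exchange is quasi-steady once per breath. The mixed venous pool
relaxes toward its Fick steady state with a 30 s mixing time constant,
so minute-scale PaO2 transients after PEEP changes are resolved; CO2
equilibrates more slowly because its elimination is flow-dominated,
which is also why the steady-state solver accelerates the venous CO2
fixed point by geometric-series extrapolation (the O2 channel is never
extrapolated — it couples to the steep region of the HPV sigmoid and
overshooting oscillates). During CPAP holds there are no breaths:
per-compartment alveolar stores (compartment volume plus a 15 ml
resident gas volume) are depleted by ongoing perfusion, so a 40 s
sustained inflation produces the physiological mild fall of alveolar
PO2 rather than an instantaneous collapse to venous tensions.
Compartments that open within a breath are exempt from that breath's
derecruitment check — they have not yet completed an expiration and
would otherwise be discarded before ever filling.

Units: mechanics in cm H2O and ml; compliance is reported per mbar
with the working convention 1 mbar = 1 cm H2O (a ~2% conventional
error). Tensions are mmHg and contents ml/dl.

## Calibration

Stage one fits eleven parameters (ventilation rate, inspiratory
fraction, RQ, VO2, collapsed fraction, TOP spread, mean stiffness, mean
extrinsic pressure, mean airway resistance, distension coefficient and
perfusion gradient) to the four static targets PvO2, PvCO2, Qs/Qt and
PaO2 measured at the calibration conditions (driving pressure 15 over
PEEP 5), minimising equally weighted squared relative errors. The
search is a small differential-evolution run inside physiological box
bounds, seeded from a Latin hypercube centred on the record's reported
values, followed by a Nelder–Mead polish. Because several
collapsed-fraction/perfusion-gradient combinations produce the same
venous admixture, a weak penalized-calibration prior pulls the
collapsed fraction and VO2 toward the record's reported values; the
weight is small enough that the blood-gas targets dominate wherever
they are informative.

Stage two fixes the static parameters and fits the log-normal
`tau_c` hyper-parameters and the closing offset `d_close` to a dynamic
PaO2-versus-time reference under a PEEP 5 → 15 → 5 schedule, by
Nelder–Mead on the mean squared PaO2 error with a penalty if the static
targets degrade by more than 10% summed relative error. The reference
series the package ships against is synthetic
(`generate_dynamic_reference`): piecewise-exponential PaO2 relaxation
with a 300 s rise constant after PEEP increases, a 120 s fall constant
after decreases (derecruitment is closer to cliff-edge than
recruitment), and 2 mmHg Gaussian measurement noise. These constants
were chosen once as representative of minute-scale oxygenation
responses to PEEP steps in ARDS; they are inputs defining the study
conditions, not tuned quantities.

The five calibrated patients are shipped as a plain-text fixture of
fitted hyper-parameters (with checksums), so simulations and tests do
not re-run the optimizer; `scripts/refit_presets.R` regenerates the
fixture end to end.

## What the synthetic data can and cannot show

The synthetic dynamic reference emulates only the gross shape of a
PaO2 response to PEEP steps — exponential approach, asymmetric time
constants, measurement noise. It does not carry breath-by-breath
variability, measurement artefacts, spontaneous breathing efforts, or
the inter-patient diversity of real recruitment dynamics. Passing the
stage-two recovery tests therefore shows that the optimizer can
identify time-constant distributions from data of this shape at this
noise level — not that the fitted `tau_c` values of any real patient
would be recovered. Similarly, the static calibration can only be as
identifiable as four blood-gas values allow: heterogeneity parameters
beyond the collapsed fraction (e.g. the TOP spread) remain close to
their initialisation and should be read as modelling choices, not
measurements.

## Problem sizes and determinism

Reference patients use 100 compartments; engine-level tests use 20–50
compartments with stiffness, airway resistance and the stiffening
volume scale rescaled so that whole-lung compliance, time constants and
dimensionless stiffening are unchanged. Calibration tests use reduced
evaluation budgets (tens to a few hundred objective evaluations);
preset fixtures were produced at budget 600 per patient. All sampling
is quantile-stratified or seeded, every optimizer stage records its
seed, and the engine itself adds no randomness, so identical seeds and
configurations reproduce results bit for bit.

## Reporting conventions

The maneuver-level oxygenation benefit `delta_po2` is computed on the
PaO2/FiO2 ratio: the maximum breath-wise ratio during and after the
maneuver minus the mean ratio over the last minute of the pre-RM stage.
Since FiO2 is held constant within a protocol this differs from a raw
PaO2 difference only by the constant factor 1/FiO2; the ratio scale is
the one on which ARDS severity and maneuver efficacy are conventionally
discussed. `P_peak` is the mean of the per-compartment maximum alveolar
pressures over the most pressurised 20% of compartments, taken over the
entire maneuver.

## Consequences of the timer-reset rule

The opening-timer reset (any excursion of airway pressure to or below a
compartment's TOP zeroes its timer) has two consequences worth knowing.
First, maneuvers that raise only the *driving* pressure over a modest
PEEP — the PRM pattern — can only recruit compartments whose opening
time constant fits inside a single inspiration, because every
expiration resets the timers of compartments whose TOP exceeds PEEP.
With the fitted closing offsets the collapsed compartments' TOPs all
exceed a PEEP of 15 cm H2O, so the simulated PRM produces a much
smaller oxygenation benefit than sustained-pressure maneuvers; its
ranking below the MRS is robust, but its absolute benefit should be
read as a lower bound under this recruitment rule. Second, the same
mechanism limits what a dynamic PaO2 reference with PEEP steps to
15 cm H2O can reveal about the `tau_c` distribution: the stage-two fit
then constrains mostly the closing offset, and the time-constant
hyper-parameters stay near their defaults. The stage-two recovery test
therefore uses a schedule whose raised-PEEP phase exceeds the
recruitable compartments' TOPs (PEEP 25), under which the time-constant
scale is identifiable and recovered within 25%.

## Known limitations

* Fixed cardiac output; no venous-return or right-heart coupling.
* No overdistension injury, inflammation or outcome modelling —
  `P_peak` (mean of the per-compartment pressure maxima over the most
  pressurised 20%) is reported as a barotrauma surrogate only.
* Acid–base is a fixed buffer line (no metabolic compensation).
* The exact compartment-level constitutive equations of the underlying
  physiology are reconstructions from stated principles (monotone
  stiffening PV law, sigmoid HPV, conductance-weighted perfusion); the
  forms are documented here and parameterized so alternatives can be
  substituted.
* Pressure-dependent airway resistance is available as an optional
  mechanism but off by default.
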