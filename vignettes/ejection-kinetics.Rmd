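---
title: "Models and methods for phage DNA-ejection population kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for phage DNA-ejection population kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ejectkin)
```

## The system and the measurements

Bacteriophage lambda packages its 48.5 kbp genome at near-crystalline
density; the resulting interstrand repulsion and bending stress pressurize
the capsid and drive DNA ejection once the tail binds the *E. coli* outer
membrane receptor LamB. The packaged genome can sit in two mechanical
states. In the *fluid-like* state (high temperature, low Mg2+ screening of
interstrand repulsion) the interstrand sliding friction is low and every
virion ejects essentially immediately after receptor binding — ejections
are *synchronized*, finishing on the ~10 s timescale of single-genome
translocation. In the *solid-like* state (low temperature, high Mg2+) a
substantial friction barrier delays the initiation of ejection by a
stochastic, sometimes minutes-long lag — ejections are *desynchronized*.
The boundary between the states is the transition temperature `T*`, itself
a function of MgCl2 concentration.

Three instruments observe this population kinetics:

* **ITC.** Titrating phage into excess LamB produces an exothermic
  differential-power (DP) transient, the heat flow (ucal/s) of the ejecting
  population. Synchronized ejections pile their heat into a sharp early
  peak; desynchronized ejections spread it into a slow second peak.
  Below `T*` the DP curve is bimodal; above it, unimodal.
* **Time-resolved SAXS.** The diffraction peak of the ordered intracapsid
  DNA (q between 0.18 and 0.32 1/A) has an area proportional to the number
  of still-filled capsids; its decay rate is the ejection-event rate, and
  the temperature dependence of the slow-population rate follows an
  Arrhenius law whose activation energy measures the friction barrier.
* **Light scattering.** The bulk intensity decays as capsids empty, but
  ejected genomes persist briefly as compact condensates that still
  scatter, so LS systematically overestimates the ejection timescale.

The package implements the full analysis chain for each observable plus a
per-virion stochastic generator that renders all three signals from one set
of ejection events, so every analysis stage can be verified against ground
truth.

## The EMG deconvolution model

Each exothermic DP peak is modelled as an exponentially modified Gaussian

$$f(t) = \frac{a}{2b}\,
  \exp\!\left(\frac{c^2}{2b^2} + \frac{d-t}{b}\right)
  \left[\operatorname{erf}\!\left(\frac{t-d}{c\sqrt2}
  - \frac{c}{\sqrt2\,b}\right) + 1\right],$$

with area $a$, exponential damping time $b$, Gaussian width $c$ and
position $d$; $b = 0$ is a symmetric Gaussian. The component moments are
$\mu = d + b$, $s^2 = c^2 + b^2$,
$\gamma = 2b^3 / (c^2+b^2)^{3/2}$, and the central ejection time is
reported as the Pearson (second skewness law) median
$\mu - s\gamma/3$. The Pearson median is an approximation; `emg_stats()`
is checked against CDF inversion (`emg_median_exact()`) and agrees within
3% for skewness below 0.5, while for damping-dominated components
($b \gg c$, $\gamma \to 2$) it reads systematically earlier than the exact
median — it is used throughout because it is the estimator the headline
medians are defined by.

Numerically, the naive formula overflows through $\exp(c^2/2b^2)$ for small
$b$; `emg_value()` evaluates through the scaled complementary error
function $\mathrm{erfcx}$, switches to a pure exponential tail where
$\mathrm{erfc} \to 2$, uses an asymptotic series for $\mathrm{erfcx}$ at
large argument, and falls back to the Gaussian limit for
$b < 10^{-6} c$.

### Model selection and its failure modes

`fit_dp_curve()` fits one- and two-component sums by Levenberg–Marquardt
least squares (parameter bounds $b, c \in [0.1, 500]$ s, $d$ inside the
trace span) from a deterministic start grid: the two largest maxima of a
Savitzky–Golay-smoothed trace, plus variants, plus damping-dominated
second-component starts ($b_2 \in \{40, 60, 90\}$ s). The damping starts
matter: without them the optimizer can settle in a local optimum where the
fast component swallows the onset of the slow population (visibly higher
residual, biased medians and areas).

In `auto` mode the bimodal model is reported only when all three hold:

1. it is preferred by AICc;
2. the components are *resolved*: their Pearson medians differ by more
   than $\max(c_1, c_2)$ **and** by at least two-fold;
3. the minor component carries more than 2% of the total area.

The resolution test deliberately uses medians rather than the positions
$d$. For a population delayed by an exponential law, lateness lives in the
damping term $b$, so two cleanly separated populations can fit with nearly
identical $d$ (in the default 22 °C scenario, $d = 7.9$ vs $10.5$ s while
the medians are 9.2 vs 28.8 s); a $d$-based gap criterion would force
unimodal calls on clearly bimodal curves. The two-fold requirement encodes
the physics: synchronized ejection is translocation-limited (~10 s),
desynchronized ejection is initiation-delay-limited (tens of seconds to
minutes); a "second component" within a factor two of the first is a shape
correction, not a population. Populations are labelled fast/slow by median,
and the reported uncertainty of each median is the component width $c$.

## The synthetic-data generator

`simulate_ejection_times()` draws, for each virion, a state (fluid with
probability `phi_fast`), a start time — uniform on $[0, 2]$ s for fluid
virions (mixing plus portal opening; the portal barrier is small), or
exponential for solid virions (the minimal memoryless model consistent
with the first-order log-linear decay of the SAXS peak area) — and a fixed
translocation duration of 10 s.

Two modes set the exponential mean. *Arrhenius mode* (used for SAXS
scenarios) takes rate $k(T) = A e^{-E_a / k_B T}$ with defaults
$E_a = 1.2\times10^{-19}$ J/virion and $A$ chosen so that
$k(25\,°C) = 0.01$ s$^{-1}$ ($E_a$ recovery does not depend on $A$).
*Table mode* (used for ITC scenarios) reads the mean delay and `phi_fast`
from `condition_defaults()`. The two modes coexist because the calorimetric
slow medians lengthen with temperature (30 s at 22 °C to 45 s at 32 °C)
while the scattering rates speed up with temperature; the generator makes
both behaviours available rather than forcing one picture.

### Rendering

Each ejecting virion releases `dH_per_virion_J` (default $10^{-15}$ J — an
order-of-magnitude choice; absolute per-virion enthalpies are not pinned
by published axes) with a rise-then-fall rate profile over the
translocation window: translocation speeds up as intracapsid friction
falls with decreasing packing density, then slows as the driving pressure
drops. The profile is a Beta(8, 4) density over the window (mode at ~70%
of the window). Two considerations fix this shape: it places the fitted
fast-population Pearson median at ~9 s, consistent with the ~10 s
translocation time; and it is only mildly skewed, so the fluid-population
DP hump stays representable by a single EMG — strongly skewed profiles
leave a structural residual that the bimodal fit latches onto, splitting
pure-fluid traces into spurious pairs.

The per-bin heat is accumulated from exact increments of the cumulative
Beta profile, the population sum is convolved with a discretely normalized
exponential instrument response (time constant 3.5 s), and i.i.d. Gaussian
noise is added. Area is conserved by construction: the noise-free integral
equals (titrated count) × `dH_per_virion_J` to well within 0.1%.

The `n_virions` simulated events (default $10^5$) statistically represent
a titration of titer × volume virions (defaults $10^{12}$ pfu/mL ×
2.69 uL = $2.69\times10^9$); each rendered event carries the heat of
`n_titrated / n_virions` virions, so amplitudes sit on the real instrument
scale (peaks of a few times $10^{-2}$ ucal/s). At $10^5$ events the
event-sampling fluctuation of the trace shape lies below the instrument
noise; this is also the problem size used by the tests and the acceptance
script (SAXS series use 5000 virions per temperature, which keeps the full
frame-fitting chain fast while the ln-area slopes stay accurate).

LS traces count still-filled capsids plus a condensate term: a completed
ejection contributes weight $w$ (default 0.5) decaying with
`ls_relax_tau_s` (default 250 s, the diffusive relaxation of the ejected
coil) — the mechanism by which LS overestimates the ejection time. SAXS
frames are a fixed-center Gaussian DNA peak (center 0.25 1/A, width
0.015 1/A) whose area tracks the ordered intracapsid DNA, plus a local
linear background and a known linear combination of component backgrounds
(TM buffer, oPOE detergent, LamB).

### Calibration of `condition_defaults()`

The per-condition table is calibrated, once, so that the default scenario
reproduces the landmark numbers the simulator is meant to emulate: fast
median ~10 s at all temperatures; slow medians ~30 / ~45 / ~55 s at
22 °C, 32 °C and 37 °C / 20 mM; fast-population area fractions 100% at
5 mM and ~10% at ≥ 20 mM (37 °C); and baseline-return times ~20 s (fast
peak) and ~250 s (slow peak, 22 °C). Because the Pearson median of a
damping-dominated EMG sits near one third of the exponential mean plus the
pulse position, the slow means come out substantially longer than the
medians they produce (54 s at 22 °C, 97 s at 32 °C, 126 s at
37 °C / 20 mM). The fluid share below `T*` at 10 mM is not quantified by
any published number; it is fixed at 0.12, which yields a fast peak
roughly twice the height of the slow one and the ~20 s fast return.
Above `T*` the residual solid share is 1% (10 mM) to 0.5% (42 °C), small
enough that the model-selection rules report the single dominant
population. The DP noise sigma (1e-4 ucal/s) is the remaining scale
parameter and is set jointly with the slow means by the two
baseline-return landmarks: the return time of an exponentially decaying
component crosses the 2-sigma detection band at
$t \approx d + b\,\ln(h/2\sigma)$, so the 20 s and 250 s landmarks pin the
noise level once amplitudes and means are fixed.

These defaults were chosen against the landmark set and then frozen; all
headline metrics sit well inside their bands across independent seeds.

### What the generator does not emulate

Real titrations carry baseline drift, injection (mixing/pressure-volume)
transients, non-Gaussian and correlated noise, per-virion variation in
genome length and translocation speed, receptor-binding kinetics at finite
LamB excess, and partial or arrested ejections. Passing the recovery suite
therefore demonstrates that the analysis chain is correct and unbiased
under the stated stochastic model — not that it is robust to every
instrument pathology. The delay law is exponential by construction, so the
survival-curve and log-linearity checks validate internal consistency, not
the biological delay distribution.

## ITC processing

Controls (phage into buffer, buffer into LamB, buffer into buffer) are
linearly resampled onto the sample grid and combined as
`sample - (phage_into_buffer + buffer_into_lamb - buffer_into_buffer)`;
the buffer-into-buffer heat appears in both single controls and is added
back once. Baseline and noise sigma are the median and MAD of the 20 s of
samples before injection — robust and estimator-explicit, since published
work does not state one. Exothermic deflections are stored as positive
released heat flow. Integration is trapezoidal with 1 cal = 4.184 J and no
smoothing; the per-virion enthalpy divides by titer × volume.
`detect_equilibration()` reports the earliest time after the global
extremum at which the signal stays within `noise_k` sigma of baseline for
`hold_window` seconds (defaults 2 and 10 s), returning the trace end
flagged censored when the signal never settles. Both the baseline and
sigma can be overridden so the detector can run on noise-free fitted
component curves using the parent trace's noise estimate, which is how the
per-population return times are computed.

## Transition-temperature detection

`fit_two_segment()` scans breakpoints on a 0.1 °C grid and fits two
*independent* weighted lines on either side (weights $1/\mathrm{SE}^2$
when SEs are available). The segments are deliberately not constrained to
meet: the enthalpy change at the transition appears as a discontinuity,
and the unconnected fit is the default (a connected hinge variant is
available). The SSE is piecewise constant between sampled temperatures, so
the optimum is a plateau; its midpoint (first + last + grid step)/2 is
reported, which makes noise-free recovery exact to the grid step when the
true vertex lies between samples. A transition is flagged significant when
the slopes have opposite signs and each slope's |t| exceeds 2 — a
pragmatic rule, since no significance test accompanies the published
landmark temperatures. `tstar_vs_mg()` assembles `T*` against MgCl2 and
flags saturation when consecutive values differ by less than 1 °C.

## SAXS reduction

Backgrounds are fitted by non-negative least squares over the peak flanks
(q in [0.10, 0.17] and [0.33, 0.40] 1/A — the window itself is excluded;
the flank choice is this package's, as no fit region is published), with a
free constant offset so the flank residual is zero-mean. The DNA peak is a
Gaussian plus line over [0.18, 0.32] 1/A with area
amplitude × width × sqrt(2π); amplitudes below 2 sigma of the fit
residuals (or negligible against the intensity scale) are flagged
peak-absent with zero area. Rates are ordinary least squares slopes of
ln(area) against time, split at 20 s into the synchronized (fast) and
desynchronized (slow) regimes; the split is exposed as a parameter since
it is an empirical choice. The Arrhenius fit regresses ln k on 1/T
(kelvin, T = °C + 273.15 exactly) and reports
$E_a = -\mathrm{slope} \times k_B$, also expressed in units of $k_B T$ at
a reference temperature.

## Light scattering

`normalize_intensity()` maps the trace to
$\Delta I(t) = (I(t) - I_\mathrm{final}) / (I_\mathrm{initial} -
I_\mathrm{final})$ with the endpoints taken as 3-sample window means
(robust to endpoint noise; no published definition exists). A
single-exponential with offset is fitted alongside — the offset is
included because the long-time plateau of a condensate-contaminated decay
need not be exactly zero. `differentiate_decay()` differentiates the fit
analytically by default; the numeric fallback uses central differences on
a Savitzky–Golay-smoothed series (window 11, order 3).
`scale_to_itc()` multiplies $-d\Delta I/dt$ by phage count and per-virion
heat into ucal/s for overlay on a DP curve; the scaled overlay integrates
back to the total released heat, which is the conservation check.

## Known limitations

* The Pearson median underestimates the true median for heavily damped
  components ($\gamma \to 2$); all medians reported here are Pearson
  medians by definition of the metric.
* Model selection near the resolution boundary (minor share ~2%, median
  ratio ~2) can flip between unimodal and bimodal on different noise
  realizations; the reported fast metrics are stable across the flip, the
  slow ones exist only for bimodal calls.
* Breakpoint estimates are quantized to midpoints of the inter-sample
  intervals; with 2 °C sampling the best achievable accuracy is ±1 °C.
* At most two EMG components are fitted; mixtures of three or more
  populations are out of scope, as are stretched- or multi-exponential LS
  decay models and any low-q capsid form-factor analysis.
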