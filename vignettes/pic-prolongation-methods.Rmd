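---
title: "Estimating PIC-induced prolongation of motor-unit discharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating PIC-induced prolongation of motor-unit discharge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picmetrics)
```

## The problem

Spinal motoneurons carry dendritic persistent inward currents (PICs):
monoamine-facilitated depolarizing currents that both amplify and prolong the
response to excitatory synaptic input. The prolongation produces an
onset–offset hysteresis — a motor unit (MU) recruited at some torque keeps
discharging until the drive falls well below its recruitment level — and,
when inhibitory control of the PIC is constrained, that hysteresis degrades
force steadiness. `picmetrics` implements the discharge-pattern analyses used
to quantify this behaviour in humans from decomposed high-density surface EMG
(HDsEMG) spike trains and ankle-torque recordings, together with a simulator
that provides analytic ground truth for every metric.

The analyses operate on three contraction paradigms, all expressed in percent
of maximum voluntary torque (%MVT):

* **sombrero** — a triangular ramp (10 → 30 → 10 %MVT at 3 %MVT/s)
  superimposed on a 10 %MVT stabilization hold (10 s plateaus before and
  after);
* **hold** — a constant 10 %MVT contraction matched in duration to the
  sombrero, used as its control;
* **ramp** — a plain 0 → 30 → 0 %MVT triangle, the classical paradigm for
  paired-MU PIC estimation.

## Discharge-rate smoothing

Instantaneous discharge rate is the reciprocal of each inter-spike interval
(ISI), reported at the later spike of the pair. The continuous rate estimate
is an epsilon-insensitive (L1 soft-margin) support vector regression of rate
on time with a radial-basis kernel, evaluated on a uniform 2048 Hz grid from
recruitment (first spike) to derecruitment (last spike), with no
extrapolation beyond that interval.

Numerical choices:

* **Kernel length-scale 1 s** — the paradigms evolve on a seconds timescale
  (3 %MVT/s ramps, 10 s plateaus); a 1 s length-scale smooths ISI noise
  without flattening the ramp response. Regularization weight `C = 10`,
  tube half-width `epsilon = 0.1` pps. All three are exposed and recorded in
  `model_params`.
* **Training abscissa at the ISI midpoint.** A reciprocal-ISI sample
  estimates the mean rate over its interval, i.e. the instantaneous rate near
  the interval's centre. Fitting the curve against the later-spike time would
  lag it by half an ISI, which biases paired-MU hysteresis estimates by
  roughly `2 x (rate slope) x ISI/2` (about 0.3 pps under ramp conditions);
  fitting at the midpoint removes this bias while the reported sample times
  keep the conventional later-spike attribution.
* **Fallback** — with fewer than 4 rate samples the smoother degrades to
  linear interpolation and flags the result; duplicate sample times are
  rejected as degenerate.

```{r svr-example}
train <- spike_train(seq(0, 6, by = 0.1), unit_id = "u1")
sm <- svr_smooth(instantaneous_rates(train))
range(sm$rate)
```

## Paired-MU delta-F

Delta-F quantifies PIC magnitude for a higher-threshold *test* unit as the
change in a lower-threshold *reporter* unit's smoothed rate between the
test's recruitment and derecruitment:
`deltaF = reporter_rate(t_rec_test) - reporter_rate(t_derec_test)`, so
hysteresis gives positive values. The per-test value is the mean over all
surviving reporter pairs. Three exclusion criteria guard the estimate:

1. rate–rate correlation `r^2 <= 0.7` (the strict inequality `> 0.7` is
   required to keep a pair) — the common-drive screen;
2. recruitment time difference `< 1 s` — the reporter's own PIC must be fully
   activated before the test unit turns on;
3. reporter smoothed-rate range `< 0.5` pps while the test unit is active —
   a saturated reporter cannot report drive changes.

Reporter eligibility is any unit recruited before the test unit whose
smoothed support covers both test landmarks; the `r^2` is computed on the two
curves resampled to a common 2048 Hz grid over the test-active span.
Exclusion reasons are recorded per pair (checked in the order recruitment
difference, `r^2`, range) and results are invariant to reporter ordering.

## Sombrero classification and sustained discharge

For superimposition trials, units are classified from the command's analytic
segment windows (never inferred from torque):

* **brim** — recruited before the ramp window (during plateau one);
* **button** — recruited in the centre ramp, maintained discharge ends
  before plateau two;
* **cap** — recruited in the centre ramp, maintained discharge continues
  past the start of plateau two;
* **other** — recruited during plateau two (rare; excluded from the three
  named classes).

*Maintained discharge* ends at the first spike followed by a gap of at least
1 s (a gap of exactly 1 s terminates it, since maintained discharge is
defined by ISIs strictly below 1 s), or at the last spike.

*Sustained discharge* of a ramp-recruited unit is the signed time its
maintained discharge continues past its **theoretical derecruitment**: the
first instant after peak torque at which torque falls back to the unit's
recruitment torque (a unit with identical recruitment and derecruitment
torque sustains for 0 s). On simulated data the crossing is computed
analytically on the noiseless command; on measured data it is found on the
50 Hz-filtered torque with linear interpolation, and a trial whose torque
never falls back to the recruitment level is flagged `no_crossing` rather
than silently assigned the trial end.

The per-trial *proportion of sustained units* is the number of cap units
sustaining more than 2 s divided by the number of units recruited in the
ramp. Ramp-recruited literally means cap + button, and that is the default
denominator; a cap + brim denominator is also provided because both readings
circulate, and the choice is recorded in the call.

## Torque processing and steadiness

Raw torque (2048 Hz) is low-pass filtered at 50 Hz with a fifth-order
Butterworth filter. The filter is applied zero-phase (forward–backward) so
landmark torques are not lag-shifted; a single-pass mode with the textbook
−3 dB cutoff semantics is available via `zero_phase = FALSE`. The 125 ms
centred moving average mimics the visual-feedback conditioning; edges are
truncated so constants are preserved exactly.

Force steadiness is the coefficient of variation CV = 100·sd/mean of %MVT
torque in a window (sample SD, the default of mainstream statistics tools),
and the per-trial steadiness degradation is ΔCV = CV(plateau two) −
CV(plateau one). Plateau windows come from the command breakpoints, are
shared between a sombrero and its matched hold, and are trimmed by 0.5 s per
end (configurable) to avoid ramp-transition transients; whether CV should use
raw, 50 Hz-filtered or feedback-averaged torque is not standardized, and the
package defaults to the 50 Hz-filtered signal.

## MUAP matching across trials

Per-unit MUAP templates are estimated by spike-triggered averaging (±25 ms
windows, windows clipped at the record edge dropped, fewer than 10 usable
spikes flagged low-confidence) on the 13×5 electrode grid. Cross-trial
similarity is the maximum over time lags (±5 ms) of the normalized inner
product of the mean-subtracted channel×time representations; channels marked
absent in either template are excluded pairwise, with at least 75% of the
grid required in common. Spatial (row/column) shifting is not searched by
default: templates are compared channel-aligned. Matching is greedy in
descending correlation (unit-id tie-break, making it order-independent),
one-to-one within each trial pair, accepting only correlations strictly
above 0.8; accepted pairs are chained across trials under a single MU
identifier. Peak-over-lag was chosen over zero-lag cosine similarity because
small alignment offsets between trials are expected and should not destroy a
match.

## Statistical summaries

Mixed models are a thin, logged delegation to `lme4`: fixed factors with all
interactions, a centred numeric trial covariate, and a participant random
intercept; per-factor p-values come from likelihood-ratio tests of the full
model against the model without the factor (and its interactions), and
estimated marginal means with Tukey-adjusted pairwise contrasts come from
`emmeans`. Cohen's d uses the classical pooled-SD formula. Singular fits are
reported with a warning, never silently dropped.

## The simulator

The generator realizes the minimal mechanism that produces the measured PIC
signatures with analytically known ground truth — a drive-domain hysteresis
offset rather than conductance dynamics:

* unit *i* is recruited at the first instant the command drive reaches its
  threshold `theta_i`;
* once recruited, its effective drive is `drive + Delta_i * length_factor`,
  so it is derecruited only when `drive < theta_i - Delta_i * length_factor`
  (or at the command end — such units are recorded as censored);
* while active its mean rate is
  `rate_min + gain_i * (drive + Delta_i * length_factor - theta_i)`; PIC
  activation is instantaneous at recruitment;
* spikes are drawn by time-rescaling a gamma renewal process (shape
  `1/isi_cv^2`) through the integrated rate, so rate changes take effect
  within one ISI; `isi_cv = 0` gives deterministic ISIs;
* every train carries a spike at the exact recruitment instant and a
  terminal spike at the end of the active interval — the generator's
  definition of first/last discharge, which makes landmark recovery exact on
  noiseless runs;
* ground truth records thresholds, effective hysteresis, gains, exact event
  times, categories and twitch parameters; the true delta-F of a pair is
  `gain_reporter * Delta_test * length_factor` (the reporter's own offset
  cancels between the two landmarks).

Default study conditions, chosen once to represent a low-effort dorsiflexion
paradigm: 20 units; thresholds 1–28 %MVT skewed toward low values
(`theta_i = min + range * (exp(a i/n) - 1)/(exp(a) - 1)`, shape `a = 3`);
recruitment rate 8 pps (typical of human tibialis anterior at threshold);
gain 1.5 pps/%MVT (recruitment-to-30 %MVT rate ranges of roughly 8–25 pps);
hysteresis 2 %MVT; ISI CV 0.15 (within the 0.1–0.2 band reported for tonic
human MU discharge); torque noise 0.3 %MVT, white noise low-passed at 10 Hz;
EMG SNR 15 dB. Muscle length enters as a pure scaling of the hysteresis:
long/mid/short = 0.7/1.0/1.5.

Torque is twitch summation: each spike train is convolved with
`P (t/Tc) exp(1 - t/Tc)` (peak `P` at contraction time `Tc`), twitch
amplitudes growing geometrically with threshold rank (ratio 25) and
contraction times shrinking 90 → 30 ms — the size principle. The %MVT scale
is set either by pinning the mean plateau torque to the commanded level
(`scale = "track"`, default, so measured recruitment torques sit near
thresholds) or by an analytic steady-state calibration at a 100 %MVT drive
(`scale = "calibrate"`). Tracking is open-loop; an optional plateau-two
drive renormalization (`renormalize_plateau2 = TRUE`) lowers the common
drive in the second plateau until the expected noiseless pool torque matches
plateau one, emulating the compensatory reduction in descending drive a
participant must produce when cap units keep adding force — this is what
makes brim units discharge slower in plateau two, as observed.

Synthetic EMG assigns each unit a biphasic Gaussian-windowed wavelet
(per-unit frequency and width) scaled across the grid by a spatial Gaussian
(SD 1.2 electrode pitches) at a per-unit centre; the record is the template
train plus white noise at the stated SNR. Templates are separable
(time × space), which is sufficient for validating the matching pipeline but
is not a volume-conductor model.

### What the simulator does and does not emulate

It reproduces the discharge-level signatures — onset/offset hysteresis,
prolonged descending-limb discharge, cap units, torque ripple from unfused
high-threshold twitches — under controlled ground truth. It does not model
conductance-based PIC dynamics (no activation time constant by default, no
voltage dependence), muscle biomechanics, closed-loop visual tracking, EMG
volume conduction, or decomposition errors (missed/merged spikes). Passing
recovery tests on this generator therefore validates the *estimators* under
the stated assumptions; it does not certify performance against
decomposition artefacts in real HDsEMG.

## Validation experiments

The packaged experiment drivers fix the validation conditions (sizes chosen
to finish in minutes on one core):

* `run_delta_f_recovery()` — 30 ramp trials of 20-unit pools, gain 1.5,
  hysteresis 2 (true delta-F 3.0 pps), ISI CV 0.1: the blind pipeline
  estimate must land within 0.5 pps of truth, and within 0.3 pps of zero on
  zero-hysteresis pools. Units never derecruited before the command end are
  excluded: delta-F is undefined without a derecruitment instant.
* `run_classification_recovery()` — 20 noiseless sombreros with per-unit
  hysteresis uniform on 0–4 %MVT: labels must match ground truth exactly.
* `run_sustained_correctness()` — sustained durations against the analytic
  event-time oracle: 0 s for zero-hysteresis units, command-end minus
  descending-crossing for programmed caps, to sample precision.
* `run_matching_fidelity()` — 3 trials, 15 units, 15 dB: at least 90% of
  true pairs recovered, no merges between units 6 or more electrodes apart.
* `run_length_effects()` — 20 matched seeds per condition: ΔCV(sombrero) >
  ΔCV(hold), and delta-F, descending duration, cap counts and sustained
  proportions all larger at short (1.5) than long (0.7) length scaling.
* `run_lmm_calibration()` — 50 coverage replicates (true plateau effect
  −2 pps, participant SD 0.5, 12 participants) and 200 null replicates:
  95% CI coverage at least 90%, LRT type-I rate within 0.02–0.09.
* `plateau_response_ratio()` with `perturbation_pool_config()` — identical
  0.5 s, 1 %MVT drive pulses in each plateau of a sombrero. The response is
  the integrated extra discharge of the units already active at pulse onset,
  so with equal gains the ratio reduces to the active-count ratio. The probe
  pool uses a near-uniform threshold spread with strong effective hysteresis
  (the short-muscle regime), in which cap units outnumber brim units and the
  same input drives more than twice the pool output in plateau two.

## Known limitations

* Delta-F precision degrades for test units recruited close to the ramp peak
  (few surviving reporters, short active spans for the `r^2` screen).
* The SVR hyperparameters are package defaults on the paradigm timescale,
  not fitted values; strongly different paradigms (fast ramps, ballistic
  contractions) warrant re-tuning.
* The open-loop torque model cannot reproduce participant overcorrection
  dynamics; the plateau-two drive renormalization is a static surrogate.
* Greedy matching is order-independent and adequate at the observed
  correlation separations, but it is not a globally optimal assignment.
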