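---
title: "Models and methods: IRI scaling of cue-reward learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: IRI scaling of cue-reward learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irilearn)
```

## The scientific question

In Pavlovian trace conditioning, a brief cue (0.25 s tone) predicts a
reward delivered 1 s later, and animals express learning as anticipatory
licking between cue and reward. Trial-based learning theories assume that
what matters is the number of cue-reward pairings. The alternative this
package is built around is a *rate* rule: the amount learned per reward
scales proportionally with the inter-reward interval (IRI), so that
learning over a fixed duration of conditioning is independent of how many
trials it contains. `irilearn` provides the machinery to pose and test
that question end to end on synthetic data: schedule generation across a
20-fold range of intertrial intervals (ITIs), ground-truth behavioral and
photometric data synthesis, learned-trial detection, dopamine-response
quantification, three candidate learning models, and the model-comparison
and regression layer.

Throughout, the nominal IRI of a protocol is

$$\mathrm{IRI} = \frac{\text{mean ITI} + 4.25\ \mathrm{s}}{p(\text{reward})},$$

where 4.25 s is the trial block: 1.25 s from cue onset to reward (0.25-s
cue + 1-s trace) plus a 3-s consumption period. Under continuous
reinforcement the IRI equals the inter-cue interval (ICI); partial
reinforcement lengthens the IRI while leaving ITI and ICI untouched,
which is what makes it diagnostic between cue-rate and reward-rate rules.

## Schedules

`build_schedule()` draws per-trial ITIs i.i.d. uniform on mean ± 20%
(protocol-configurable) and schedules the consumption period on every
trial, rewarded or not, so partial reinforcement does not perturb the
ICI. Two conventions required a decision:

* **A leading ITI precedes every trial, including trial 1.** The
  protocols do not state whether the first cue of a session is preceded
  by an interval; a leading draw makes "ITIs experienced before trial
  L + 1" equal L + 1 and matches the simulated time-to-learn formula
  `L * 4.25 + (L + 1) * mean_ITI`. A `pre_session_delay` field overrides
  it where a fixed pre-period is wanted.
* **Between-session time carries no modeled duration.** Sessions are
  concatenated on a single conditioning-time axis, because every elapsed
  -time quantity in the analyses sums conditioning time only.

Distractor cues are an exponential renewal process confined to the
inter-trial gaps, and background rewards of a second identity are placed
sequentially, each a uniform mean ± 20% interval from the previous reward
delivery; impossible packings raise an error rather than silently
degrading.

## Synthetic behavior and photometry

`gen_licks()` emulates the features the analyses consume, not mouse
behavior in general: Poisson baseline licking (default 0.5 Hz),
an anticipatory-window rate that steps (optionally ramps) from baseline
to 4 Hz at a planted change-point trial, and a stereotyped post-reward
consumption bout whose contact gaps are under 500 ms by construction so
the ITI-rate analysis can excise it. The defaults mirror the learner
phenotype of the study system: ~4 Hz asymptotic cue-evoked licking above
a low spontaneous rate, with an abrupt transition. What the generator
does *not* emulate — slow within-session satiety drifts, spout-holding
artifacts, inter-animal rate heterogeneity — bounds what passing tests
can say about real data: they validate the analysis pipeline's
correctness and calibration, not biological effect sizes.

`gen_photometry()` renders a 470-nm channel as baseline plus event-locked
transients (difference-of-exponentials kernel, 0.05-s rise / 0.5-s decay
so most of the transient falls inside the 0.5-s analysis windows), a slow
artifact shared with the 405-nm isosbestic channel, and independent
noise; the isosbestic channel carries no event transients. Amplitude
trajectories are caller-supplied per-trial sequences so tests can plant
steps, sigmoids, or a reward-first/cue-later pattern. Amplitudes are
expressed in dF/F percentage points of baseline, which keeps ground truth
directly comparable with the analysis output.

## Learned-trial detection

The detector is the cumulative-sum geometry used for behavior, dopamine
cue responses, and omission dips alike. With per-trial responses $x_i$
and $S_i = \sum_{j\le i} x_j$ (and $S_0 = 0$), a diagonal runs from the
origin to $(n, S_n)$; the vertical distance $d_i$ between diagonal and
curve is scanned and the learned trial is the *first* trial whose
unsigned distance is within 75% of the maximum. If the diagonal lies
below the curve there — responding was decreasing, which happens when
post-learning licking tapers — the diagonal endpoint is re-anchored at
that trial's cumsum point and the scan repeats until the diagonal lies
above the curve at the detected trial.

Numerical and geometric choices:

* Distances are vertical, not perpendicular: the axes carry different
  units, and perpendicular distance would change with axis scaling.
* Ties at the 75% threshold resolve to the earliest trial, and the
  threshold comparison carries a 1e-12 slack so exact-tie geometries
  (the 20-zeros/20-fives example lands exactly on the threshold) are
  stable.
* A series whose cumsum never dips below the diagonal has no
  positive-going inflection and is flagged degenerate, with a
  scale-relative tolerance (1e-10 of the cumsum magnitude) so a
  numerically flat series from repeated decimals is degenerate too.
* The re-anchoring loop is capped at n iterations; reaching the cap, or
  failing to shrink the anchor, is degenerate.
* The diagonal's start anchor is (0, 0). Anchoring at the first point
  instead shifts sharp-step detections by one trial; the endpoint anchor
  is exposed (`end_anchor`) because the dopamine learned trial anchors at
  1.5x the behavioral learned trial.

One property deserves emphasis because it shapes the tests: on a clean
step at trial $c$, the distance rises linearly until $c - 1$, so the
first-within-75% rule fires near $0.75\,(c-1)$ — by design it marks the
onset of the rise, earlier than the change point itself (the worked
example detects trial 15 for a step beginning at trial 21). The
max-distance reading (`threshold_frac = 1`) is the consistent estimator
of the change point, so ground-truth recovery checks run the detector at
`threshold_frac = 1`, while the 75% default is pinned by its exact
worked-example geometry. Both are the same algorithm; the fraction is a
tunable with default 0.75.

Learner classification (≥ 0.5-Hz session-mean increase in cue lick rate
in at least two sessions), trial-1 alignment to the first consumed
reward (5-s window; disabled for partial reinforcement where omission
trials must be counted), rewards-to-learn, and total conditioning time to
learn follow the definitions above with no further free parameters.

## Dopamine quantification

dF/F is the session-wide isosbestic correction: ordinary least squares of
the 470-nm on the 405-nm channel, then
$100\,(F_{470} - \hat F)/\hat F$. Responses are baseline-subtracted
trapezoidal AUCs on the native ~120-Hz grid with half-open windows:
0.5 s after cue onset versus 0.5 s before (cue); 0.5 s after the first
lick following reward delivery — or delivery itself if a contact spans
it, or no lick arrives within the 3-s consumption horizon — versus the
same trial's pre-cue baseline (reward); and a 2-s window starting 1.25 s
after cue onset versus a 2-s pre-cue baseline (omission dips, whose
kinetics are slower and broader). Peaks are window maxima minus the
baseline mean. Per-animal normalization divides by the mean of the three
largest reward responses, measured in the 0.5-s window for cue/reward
responses and in the 2-s post-first-lick window for omission responses so
numerator and denominator share a window. The reward-response baseline is
taken as the trial's pre-cue window rather than re-measured at the lick
anchor; the definition is anchored to the cue-aligned trial structure.

## Learning models

All three simulators consume the same event schedules, simulate the full
ITI at their native time step, and emit a per-trial association quantity
whose first threshold crossing is the model's learned trial.

**Microstimulus TDRL** (dt = 0.25 s): each cue or reward launches a
memory trace decaying by `d` per step; `m` Gaussian basis functions
(width 0.08) centered evenly on (0, 1] of trace height, amplitude
-weighted by the trace, form the state features. Value is linear in the
features, updated by TD errors with accumulating eligibility traces
(decay 0.99). Defaults are the best-fitting sweep combination
(threshold 0.3, alpha 0.1, gamma 0.99, m 3, d 0.9). The per-trial
quantity is the maximum value between cue onset and reward time. The
scaled variant replaces alpha with `1 - exp(-k IRI)` (k = 3e-4 fits
behavior best over the experimentally motivated range).

**SOP** (dt = 0.25 s): cue and reward nodes hold element fractions in
inactive (I), primary active (A1) and refractory (A2) states; stimulus
presentation moves `p1 * I` into A1, decay moves `pd1 * A1` to A2 and
`pd2 * A2` back to I every step. The association grows with A1-cue/A1
-reward overlap and shrinks with A1-cue/A2-reward overlap; after
learning, cues push reward elements I to A2 in proportion to the
association (the conditioned-response pathway, confined to the reward
node). Fraction conservation holds to machine precision by construction
and is asserted in tests.

**ANCCR** (dt = 0.2 s): the retrospective predecessor representation
`M_<-cr` (average cue eligibility at reward times) updates at rewards
with the IRI-scaled learning rate
$\alpha = 1 - (1 - \alpha_0)^{\mathrm{IRI}/dt}$; baseline
representations update every dt with rate $\alpha_0$; eligibility traces
decay exponentially with time constant `T = k * IRI`. The prospective
association follows from the Bayes'-rule normalization
`M_->cr = M_<-cr * M_<-r- / M_<-c-`, and the net contingency is the
w-weighted combination of prospective and retrospective contingencies,

$$\mathrm{NC} = w\,(M_{\to cr} - M_{\leftarrow r-}) +
  (1-w)\,(M_{\leftarrow cr} - M_{\leftarrow c-}),$$

with w = 0.5 and best-fit threshold 0.4, alpha0 = 4e-5, k = 0.5. The
construction of NC beyond the retrospective update and Bayes conversion
follows the published companion model this framework derives from; the
tests pin only the behaviors asserted for it here — threshold crossing,
inverse-proportional trials-to-learn versus IRI, near-constant total
conditioning time, and no crossing for independent cue/reward streams.
Two numerical choices: the baseline-rate division is floored at 1e-6 to
avoid early-session blowup, and the per-dt baseline updates between
events are computed with exact geometric-sum closed forms (an algebraic
identity with the literal per-dt loop, asserted against it in tests),
which makes the simulator event-driven and fast.

Why the models separate: ANCCR's cue-reward update happens once per
reward, so its learning per unit *time* is IRI-invariant and its
trials-to-learn fall as 1/IRI at constant total conditioning time.
TDRL's updates happen every time step regardless of spacing, so its
trials-to-learn are roughly spacing-independent and its conditioning time
grows with ITI; SOP shows a genuine but sub-proportional spacing effect
through A2-pool recovery. These categorical signatures — not exact
trial counts — are what the test suite asserts.

## Model comparison and scaling

Simulated conditions mirror the experimental exposure: 800, 400, 88, 48
and 16 trials for the 30/60/300/600/3,600-s ITI groups, 20 iterations
each. Scoring uses the residual sum of squares of log10 trials-to-learn
against the observed group means; the reference aggregation computes each
iteration's RSS against those means and averages (a per-condition-means
strategy is available, since the original aggregation is ambiguous).
Censored iterations (no crossing) contribute the simulated trial count
plus one, preserving rank against models that do learn. AIC is
`2k + n ln(meanRSS)` with the conservative `k = 0` default, and relative
weights are `exp(-0.5 (AIC - AIC_min))`. Printed AIC magnitudes depend on
per-animal data this package does not ship, so they are not asserted;
the weight formula applied to reported AIC pairs is.

The scaling layer is ordinary least squares of log10 trials on log10 IRI
(base 10 throughout: the reported intercept is only consistent with
base-10 logs), with predictions `10^(intercept + slope log10 IRI)`. The
two-group dopamine "fit" is the exact line through two points. Fitted to
the four main-group means the slope is -1.06 with R^2 = 0.9992, and the
reported coefficient pairs reproduce the printed predictions at printed
precision, with one exception: the dopamine coefficients give 17.75
rewarded trials at IRI 128.5 s where 17.8 is printed — the published
coefficients are themselves rounded — so that value is held to printed
precision rather than rounding equality.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full 20-iteration,
four-condition model contrast (about a minute per model in pure R, the
ANCCR event-driven form in seconds), 1,000-series detector/oracle
equivalence, and 50-cohort change-point recovery; these sizes were chosen
to hold sampling error well inside the asserted bands while keeping a
complete run in the minutes range. Every stochastic stage takes an
explicit integer seed, schedules carry all simulator randomness (the
models themselves are deterministic), and reruns with the same
configuration are byte-identical, which the pipeline tests assert.

## Known limitations

* The synthetic generators are calibration fixtures, not behavioral or
  photometric models; effect sizes on real recordings will differ.
* The SOP conditioned-response strength is taken proportional to the
  association with unit gain; the literature leaves this mapping loose.
* The ANCCR dopamine proxy (net contingency at events, plus an innate
  meaningfulness of 1 at rewards) supports qualitative ordering only; no
  claim is made about waveforms.
* Identity-specific versus general IRI under background rewards is
  implemented as counting same-identity rewards versus all rewards; with
  partial generalization between reward identities (as sweet liquids
  show) the effective IRI lies between the two.
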