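---
title: "Modelling internal and external exploration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling internal and external exploration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dialexplore` implements a complete analysis pipeline for a sequential
multiple-option decision task in which an agent repeatedly chooses between
three actions: *internal exploration* (remove one decoy dial of a revealed
option, making its payoff more certain), *external exploration* (reveal a
new option elsewhere in the environment), and *accept* (end the trial and
collect the chosen option's true-dial points net of the exploration costs
incurred). This vignette explains the models, the tunable parameters, the
synthetic-data generator, and the design decisions taken where the design
was genuinely open. It states no empirical result beyond what the package's
tests and the acceptance script themselves compute.

## The task

Nine option slots each hold four integer dial values drawn uniformly from 1
to 100. Exactly one dial per option — unknown to the decision maker — is the
true payoff. One option is revealed at the start of a trial; each internal
or external exploration costs one point; at most three internal
explorations are allowed per option (the true dial is never removed, so a
removal always reduces outcome uncertainty) and at most eight external
explorations per trial. All of these are `task_config()` parameters.

Choices about representation that the task description leaves open:

* **Dial distribution.** Uniform integers on [1, 100]: a natural "points"
  scale; configurable.
* **Payoff.** `net_gain = true-dial points − cumulated cost`. The cost
  display is part of the task; the payoff formula is the obvious accounting.
* **Internal removal.** Sampled uniformly from the non-removed, non-true
  dials. Removing the true dial would destroy the outcome rather than
  de-noise it, contradicting the action's purpose.
* **External reveal.** Uniform over hidden positions; the choice model does
  not use box identity.

## Decision values and the choice model

Three value functions summarize a trial state:

* internal exploration value — the greatest product of mean point and
  dial SD over revealed options, `max(point × SD)`: exploration is worth
  most for options that are both rewarding and uncertain;
* external exploration value — the mean point of *all nine* options, hidden
  included (the on-screen "environment average");
* accept value — the mean point of the best revealed option.

Two open points and how they are resolved:

* **SD divisor.** Population SD (divisor *n*), so a one-dial option has SD
  exactly 0 rather than an undefined sample SD.
* **Environment average.** `fixed_at_trial_start` by default: hidden and
  revealed options contribute their original four-dial means, so the value
  is a trial-level constant, matching its role as a trial-level display;
  `recomputed_each_phase` is available for sensitivity analysis.

The choice model is a 10-parameter multinomial logit with accept as the
reference category: two linear log-odds equations (internal vs accept;
external vs accept), each with an intercept and the four predictors
(the three values and the cumulated cost), sharing one trinomial
probability model. Predictors are z-scored *within participant* with the
population SD (`standardize_predictors()`): the group coefficient scale
(≈ 2–5) is only plausible per SD of a predictor, not per raw point, and
scaling can be disabled for sensitivity runs by fitting raw columns.

Fitting (`fit_mle()`) maximizes the trinomial log-likelihood minus a ridge
penalty of `1e-6 · ‖β‖²`. The penalized objective is strictly convex, so
the optimizer's restarts are a safeguard rather than a necessity; the ridge
guarantees a finite optimum under quasi-separation (e.g. a participant who
never externally explores). The analytic gradient is used with BFGS;
likelihoods are computed with a log-sum-exp shift and are stable for
|linear predictor| up to ≈ 700. Predicted-choice accuracy breaks
probability ties by the fixed order internal, external, accept.

## Model comparison

Alternative value definitions live in a registry
(`value_registry()`: 4 internal × 3 external × 3 accept definitions);
`enumerate_model_family()` takes their Cartesian product, optionally
crossed with including cost, deduplicated, with the best-fit trio always
first — the same construction by which a family of order 10² arises (e.g.
5 × 4 × 3 × 2 = 120). The exact composition of any published 120-variant
family is not reconstructible from a main text, so the registry is a
configurable stand-in, extensible through a YAML/JSON config
(`family_config()`).

Per participant and variant, goodness of fit is `BIC = k ln n − 2 logL`
and log model evidence is approximated as −BIC/2 (standard practice).
Random-effects Bayesian model selection (`bms_exceedance()`) uses the
variational Dirichlet scheme: responsibilities
`u_nk ∝ exp(L_nk + ψ(α_k) − ψ(Σα))`, concentration updates
`α_k = α₀ + Σ u_nk`, default `α₀ = 1`, tolerance 1e-6, cap 10,000
iterations. Exceedance probabilities — each model's posterior probability
of being the most frequent — are Monte-Carlo estimates from 10⁶ Dirichlet
draws by default; the variational posterior is deterministic given the
evidence, and the Monte-Carlo step is seeded by the caller. Per-participant
best-model counts break exact BIC ties toward the first variant id — a
documented, deterministic rule.

## Parameter recovery

`parameter_recovery()` draws each synthetic participant's generating
10-vector from Normal(group values, `0.5·|β| + 0.2`), simulates a
100-trial session, refits, and reports the Pearson correlation between
generating and recovered values per parameter. The group-level centre
(`default_group_betas()`) uses strong own-value weights, strong negative
accept-value weights on both exploration branches, and negative cost
weights; the two intercepts (0.45, 0.90) — which no group table pins down —
were fixed once so that a simulated group lands near a 30/40/30 split of
internal/external/accept decisions, matching the behavioural conditions the
pipeline emulates.

One subtlety matters for recovery studies. The generating agent must place
its raw values on the standardized scale its coefficients refer to. With
*running* within-session statistics, the effective scale drifts early in
the session, and — worse — the recorded session's own moments differ from
the agent's by sampling error, which multiplies into the large value
coefficients and contaminates the recovered intercepts. The default is
therefore a *two-pass* design: an unrecorded calibration session fixes the
agent's standardization moments (`calibrate_norm_stats()`), the recorded
session standardizes against them, and the refit standardizes the emitted
table with those same moments (`standardize_with()`), so generating and
recovered parameters live on one scale. The running-statistics mode remains
available (`standardization = "running"`).

Even so, recovery precision is bounded by Fisher information: with
coefficients this large, most phases are nearly deterministic, and a
~330-event session yields per-parameter standard errors of roughly 0.2–0.6
(verified against an independent multinomial fitter, which agrees with our
estimator to all printed digits). For parameters whose generating
dispersion is small under the `0.5·|β| + 0.2` rule (the intercepts and the
cross-value terms near 0.45), the signal-to-noise ratio is near 1 and the
across-participant correlation typically lands around 0.7–0.9, varying by
realization; the minimum over the ten parameters is the pipeline's headline
recovery statistic and is recomputed from scratch by
`scripts/acceptance.R`.

## Behavioural statistics

`group_coefficient_tests()` runs one-sample t tests (df = n−1, two-sided)
on each coefficient across participants, flagging zero-variance columns.
`sliding_window_curves()` ranks each participant's decision phases by one
value into 30 equal-count classes — "probability classes" is read as
quantile bins; the alternative (equal-width) reading would leave extreme
bins nearly empty, defeating the stated purpose of stabilizing estimates —
with remainder events assigned to the lowest classes and stable tie order,
then slides an 11-class window (30 − 11 + 1 = 20 levels), excludes the
third decision type within each window, and averages the two-way choice
proportions across participants without weighting. Participants with fewer
events than classes are skipped, not padded.

## The synthetic imaging study

`generate_study()` builds the full study the imaging pipeline needs: per
participant, a generating beta, a 100-trial session with onsets (phase
onsets advance by RT + ISI within trials and RT + outcome + ITI at
accepts; RTs are truncated normals, floor 0.3 s, with per-decision moments
3.76/1.56, 2.75/1.19, 3.06/1.50 s; ISI 1–3 s, outcome 1–3 s, ITI 3–6 s),
and three ROI BOLD series with planted codes:

* **IPS** — `invariant_internal`: every event drives the region by
  `gain · z(internal value)`, regardless of the impending decision;
* **ACC** — `invariant_external`: `gain · z(external value)`;
* **mPFC** — `flexible_chosen`: `gain · z(chosen value) −
  suppression · z(best alternative)`, a general decision-value code.

Events are impulses at decision onset convolved with a two-gamma HRF
(gamma shapes 6 and 16, undershoot ratio 1/6, peak-normalized, 0 at t = 0)
on a 0.1 s grid, sampled at TR = 2 s, plus AR(1) noise (coefficient 0.3).
The per-participant gain is
`gain·(1 + 0.4·z(proportion of the corresponding decision)) + N(0, 1)`,
which plants both between-participant heterogeneity and a brain–behaviour
association of realistic size. The white-noise SD (4) and gain SD (1) were
fixed once so that the group peak t statistics at n = 24 land in the low
single digits — the range typical of event-locked ROI value signals —
rather than the implausibly large values a noise-free forward model
produces. True empirical signal-to-noise is unknowable from any text, so
these are calibration knobs of the generator, not estimates.

What the generator deliberately does *not* emulate: volumetric images and
preprocessing artefacts, physiological noise structure beyond AR(1),
RT-long neural epochs (impulses by default; boxcars would add a
RT-correlated confound), and session breaks. Passing tests therefore show
that the *pipeline* recovers what was planted under fair noise — not that
real data contain these codes.

## The time-course pipeline

`epoch_betas()` interpolates each tr-sampled ROI series onto an
event-relative grid (cubic spline; window −5 to 13 s, 0.01 s step by
default so sub-TR peak times are expressible) and, at each grid time,
regresses the amplitudes across events on the standardized regressors plus
an intercept by OLS. The epoch GLM regresses raw amplitudes rather than
HRF-convolved predictors — the point of the time-course approach is to be
free of waveform assumptions. Epochs of temporally close events overlap
and are used as-is; the pre-onset part of the window means slow components
can surface before the nominal onset. Edge events whose epoch leaves the
sampled span are dropped with a warning; participants whose event subset
cannot support the design (fewer events than regressors + intercept, or a
rank-deficient design) are skipped with a warning, and a group analysis
requires at least three estimable participants.

Peak estimation is leave-one-subject-out: for each left-out participant,
the peak of the remaining participants' mean course is taken as the signed
extremum (largest |β|, carrying its sign, so negative deflections are
genuine negative peaks); the LOSO times are averaged. The procedure runs
once per participant — n iterations for n participants. The peak window is
the full width at half maximum of the (signed) group course, with the two
half-maximum crossings linearly interpolated and clipped (flagged) at the
search-window edge if a crossing is absent. The per-participant peak size
is the mean beta inside the FWHM window — a formula-free "size of the
peak" made explicit — tested against zero by a one-sample t test and
supplemented by a JZS Bayes factor (Cauchy prior, scale √2/2, numeric
integration). Decision-conditioned analyses enter the three values
simultaneously within each impending-decision subset and adjust the three
decision-wise p values per region × signal by Benjamini–Hochberg; the
chosen/unchosen framing recodes each event's values as the value matching
the impending decision versus the best remaining alternative. An optional
filter drops the first of repeated internal explorations of the same
option, for signals that ramp over repeated sampling. The 3 × 3 × 3
region-by-decision-by-signal ANOVA is a fixed-effects analysis over the
27 cells per participant (interaction df 8; error df 27(n−1), i.e. 621 at
n = 24).

## Problem sizes and determinism

The shipped analyses and tests use 24 participants × 100 trials for the
behavioural and recovery studies (the study's own scale), a 12 × 60
session grid for the 72-variant comparison driver, and the full n = 24
synthetic imaging study for the planted-dissociation checks; unit tests
use smaller constructed fixtures. Every stochastic component draws from
R's global stream, so a single `set.seed()` (or `generate_study()`'s
`master_seed`) reproduces any result bit-for-bit; manifests record seeds
and configurations.

## Known limitations

* The likelihood treats all three actions as available at every phase;
  the simulator renormalizes over legal actions when a cap binds. Caps
  bind rarely under realistic parameters (the external cap essentially
  never), so the approximation is benign, but extreme parameter regimes
  could make it visible.
* BIC's −BIC/2 evidence approximation ignores posterior curvature
  differences between variants; no free-energy evidence is provided, and
  protected exceedance probabilities are not implemented.
* The deposited-data ingestion (`reproduce_osf()`) requires a
  user-supplied column mapping because the deposit's internal layout is
  not fixed by any schema this package can rely on; it never downloads.
* Recovery precision under the documented design is information-bounded,
  as discussed above; correlations near 0.8 for the weakest parameters
  should be read with that in mind.
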