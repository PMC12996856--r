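---
title: "Quantifying child–caregiver prosodic synchrony: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying child-caregiver prosodic synchrony: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

During free play, a young child and a caregiver continuously adapt their
voices to one another: pitch, loudness, voice quality and spectral balance
rise and fall in loosely coordinated patterns.  `dyadsync` quantifies this
*prosodic synchrony* from diarized audio — per-second speaker labels plus
frame-level acoustic low-level descriptors — and asks how it is modulated by
parenting stress (PSI total score), caregiver role (mother vs father) and
time, in a repeated-measures design where every child is recorded with both
caregivers at two timepoints (four sessions per child).

Two distinctions organize the whole pipeline:

* **Coordination vs similarity.** Two speakers can *sound alike* (similar
  acoustic distributions) without *coordinating* (moment-to-moment temporal
  dependence).  Only the latter is synchrony in the dynamical sense.  The
  permutation layer below exists to separate the two.
* **Predictability vs stability.** Within coordination, sequentially
  predictable patterning (diagonal structure of a recurrence plot) differs
  from persistence in shared states (vertical structure).  The two composite
  ratios DET/REC and LAM/DET are the pipeline's dependent variables because
  they index exactly this balance.

## From audio annotations to paired time series

`build_series()` converts one session's segment table (1 s labels CHI / ADU
/ SIL / BOTH) and frame table into two aligned matrices of 500 ms windows,
one per speaker.  A speaker's window is the arithmetic mean of that
speaker's frames when the diarization says they vocalize; concurrent
vocalization (BOTH) contributes the same frames to both series; windows are
half-open `[t, t + 0.5)`.  Maximal runs of joint silence of at least 25 s
are removed (`remove_long_silence()`), after aggregation, from both series
simultaneously so pairing is preserved.  Each speaker × feature vector is
then robustly scaled, `(x - median)/IQR`, with type-7 quantiles, per
session, using the speaker's vocalized windows only (`robust_scale()`).

**The silence placeholder.** Windows in which a speaker is silent receive a
placeholder value interpreted on the scaled scale, by default −4.  The
placeholder stands in for the low-level descriptors of a silent audio
segment, which are extreme relative to speech (near-zero loudness, undefined
pitch), so it belongs in the far tail of the scaled speech distribution.  A
center-of-distribution placeholder (e.g. 0) makes speech and silence
windows spuriously recurrent: in development experiments it saturated the
recurrence rate near 0.8 and buried every planted effect.  The value is
configurable per feature.

## Cross-recurrence quantification

For each feature, the two scaled window series are delay-embedded
(`embed_series()`, dimension m = 3, delay τ = 3 windows) and compared by a
fixed Euclidean radius ε = 1.5 on the scaled scale — the standard settings
for vocal interaction data at this temporal grain.  The cross-recurrence
plot `M[i, j] = 1{‖a_i − c_j‖ ≤ ε}` is the full rectangular matrix with no
line-of-identity exclusion and no Theiler window: the two series come from
distinct systems, so self-simultaneous matches are signal, not artifact.

**Orientation.** The caregiver indexes the rows and the child the columns.
Recurrence rate and all diagonal metrics are orientation-symmetric; vertical
lines are not — with this orientation LAM and TT measure the *caregiver
remaining in the child's state*, which is the reading of "trapping" this
package adopts.

Metrics (`crqa_metrics()`, Rcpp fast path in `crqa()`): REC (density of
recurrent points), DET (share of recurrent points on diagonal lines of
length ≥ 2), LAM (share on vertical lines ≥ 2), the composite ratios
DET/REC and LAM/DET, mean and maximal diagonal length (L, Lmax), trapping
time (TT), and Shannon entropies of the diagonal and vertical line-length
distributions in nats.  Minimum line lengths (2) and the entropy base are
conventional defaults; they are declared, not estimated.  A plot with no
recurrent points, or no diagonal structure, or a zero-IQR input has
undefined ratios and is flagged `unstable` — never silently zeroed.  The
compiled engine is checked for exact equality against an independent
brute-force double-loop oracle in the test suite.

`stability_filter()` then enforces the completeness rule of the modeling
stage: subjects must contribute all four sessions, and a feature is retained
only if its ratios are defined in every session of every retained subject.

## The inferential cascade

For each retained feature × ratio, `synchrony_lmm()` fits the
random-intercept model

y_ij = β₀ + β₁·psi_std + β₂·father + β₃·T2 + b_i + e_ij,

with the dependent variable and the caregiver-specific PSI z-scored within
whatever data enter the fit, so that every resample standardizes itself.
Estimation is exact maximum likelihood via the profiled likelihood: given
the variance ratio θ = σ_b²/σ_e², GLS estimates and the profiled deviance
are closed-form, leaving a one-dimensional optimization.  ML is used for
every likelihood-ratio comparison (REML likelihoods of models with different
fixed effects are not comparable); REML is available for final reporting.
Term p-values use a between–within residual df, `N − J − (p − 1)`, whose
type-I calibration at the study's design is verified by simulation in the
tests.  When `check_assumptions()` flags the fit (Shapiro–Wilk on residuals
and on empirical-Bayes intercepts; a Breusch–Pagan-type score test),
`cr2_inference()` provides CR2 bias-reduced-linearization cluster-robust
standard errors with Satterthwaite degrees of freedom, applied to the
marginal regression so its validity does not lean on the modelled
covariance.

The speed of the fitter is a design constraint, not a convenience: the
resampling layers refit the model 10⁵–10⁶ times inside routine validation
runs.  lme4 plays the role of independent oracle in the test suite
(log-likelihood, coefficients and variance components are compared on the
same data), never the production path.

**Sensitivity** (`loso_bootstrap()`): for each left-out subject the full and
baseline (no-stress) models are refit and the LRT statistic is calibrated by
a parametric bootstrap under the fitted baseline, the bootstrap budget
divided evenly across folds.  Empirical p-values use the add-one convention,
so the resolution floor is `1/(share + 1)` — a budget of 1000 draws over 26
folds resolves p ≈ 0.025, which matters when gating at 0.05.  The
distribution-level p (`p_dist`) tests H₀: mean fold-level p ≥ 0.05 by a
percentile bootstrap over folds; the choice of test is declared here because
only its verbal definition is standard.

**Specificity** (`permutation_specificity()`): the adult's window order is
uniformly permuted in every session (`permute_alignment()`), which exactly
preserves each speaker's marginal distribution — their individual speech
characteristics — while destroying dyadic temporal alignment.  CRQA and the
models are recomputed per permutation replicate; the permuted X² and
stress-term |t| provide empirical specificity p-values (add-one), and the
mean permuted LRT p (`p_rand`) shows whether significance *vanishes* under
permutation.  Window-level permutation is the literal reading of shuffling
feature vectors; it also destroys within-speaker temporal structure, so the
child series is left untouched by default (permuting one partner suffices
to break the dyad) and a `both = TRUE` option exists.  A permuted session
whose ratio becomes undefined is re-permuted up to three times before the
replicate is dropped; with a hundred-plus sessions per study, dropping a
replicate on any single unstable session would discard nearly all
replicates.

**Selection** (`sequential_gates()`): models pass four gates in order —
overall significance (p-ANOVA and its distribution-level test), temporal
specificity (significance vanishes under permutation *and* the observed X²
is extreme against the permutation null), a significant stress term, and
specificity of the stress effect.  Family-wise error of the cascade is
quantified by `fwe_simulation()`, Monte Carlo over independent null models
drawing uniform p-values per gate; the independence closed form
`1 − (1 − Πα)ⁿ` is the oracle the simulation must reproduce.  With 32
models and two 0.05 gates this probability is ≈ 0.077, printed as 0.08 at
two decimals.  `bonferroni_threshold()` and `power_simulation()` round out
the error-control toolkit.

## The synthetic-data generator

No recordings ship with the package; `simulate_study()` generates complete
studies with known ground truth so that every stage can be validated
end-to-end.  The generator is a *stand-in world*: nothing is claimed about
the true mechanism of child–caregiver coupling, only that the generator
realizes, controllably, the phenomena the pipeline must detect.

Design (per session):

* **Turn-taking**: a four-state Markov chain over CHI / ADU / SIL / BOTH at
  1 s resolution, tuned to a lively play interaction (frequent overlap,
  short silences, ~2 s dwell in speaking states).
* **Child prosody**: piecewise-constant heavy-tailed "register" levels
  (sinh-normal, dwell of several seconds) plus window-level noise.  The
  registers are the shared states of the dyad.
* **Coupling** (`coupling_strength` κ): the caregiver alternates between
  engagement stretches — tracking the child's last vocalized value and
  holding the child's current register — and disengaged stretches following
  an independent fast-mixing heavy-tailed process.  The engaged fraction is
  κ/(1+κ); κ = 0 removes all moment-to-moment dependence while leaving
  both speakers' marginals realistic.
* **Stress pathway**: parenting stress, caregiver role and a subject
  intercept act on the dyad's register turnover rate,
  `rate = base · exp(−η)`.  Slower turnover — interactions that linger in
  prosodic configurations — raises recurrence and determinism and lowers
  LAM/DET, reproducing the direction of the stress findings the pipeline
  targets (more recurrent, more predictable, less laminar-relative-to-
  deterministic coordination under stress).

Why this mechanism and not, say, lag-1 linear dependence with a switching
sign?  Because development experiments showed that at the fixed analysis
settings (m = 3, τ = 3, ε = 1.5, 500 ms windows) an embedded-point match
requires roughly 3.5 s of compatibly voiced, value-matched trajectory, and
window-level linear coupling of that kind contributes only O(1/W) to the
recurrence rate — it is essentially invisible to CRQA.  Register holding by
the caregiver is the minimal mechanism that produces supra-threshold
diagonal and vertical structure whose strength responds monotonically to κ
and whose balance responds to the turnover rate.

Calibration of defaults (done once, then frozen): with 26 subjects and
10-minute sessions, `stress_effect = 0.8` and `caregiver_effect = 1.2`
place the planted fixed effects near −0.2 (stress) and −0.3 (caregiver) on
the standardized LAM/DET scale, the magnitudes the inferential stage is
expected to resolve; at 300 s sessions (used by the heavier acceptance
simulations to stay inside time budgets) `stress_effect = 1.6` restores
b ≈ −0.2.  PSI totals are drawn from a truncated Normal(80, 20) with 0.75
test–retest correlation — plausible scenery, not a target.

`simulate_null_study()` forces κ, stress and caregiver effects to zero for
type-I calibration.  `simulate_similarity_study()` generates *general
similarity without coordination*, and its construction is instructive about
what the permutation surrogate can and cannot distinguish.  The child
carries a slow sinusoidal drift; the adult's windows are drawn iid from the
*marginal* of the same drift process (the sinusoid evaluated at iid
phases), so the two speakers' distributions match while the adult's series
is as close to window-exchangeable as the 1 s diarization granularity
allows; the similarity world's labeling is memoryless and overlap-free.
Stress modulates the rate of iid heavy excursions in the adult's prosody —
a purely marginal property.  Three earlier variants were rejected in
development, each for leaking a genuine temporal signature into a world
meant to contain none: a phase-locked shared drift (shared phase *is*
alignment), stress-modulated drift share (it alters the adult's own
autocorrelation, which window permutation also destroys), and multi-second
turn dwells (adult silence runs form recurrence blocks whose weight
interacts with the stress-modulated marginal).  The surviving leak — the
two identical-mask windows inside each labeled second — keeps the
specificity gate's false-attribution rate slightly above its nominal
floor, which the discriminant-validity test accounts for.

What the generator does **not** emulate: real acoustic descriptor ranges or
their cross-correlations, openSMILE numerics, diarization errors,
developmental change in the child's vocal repertoire, or any audio.  A green
test therefore establishes that the pipeline's logic and calibration are
sound under a controllable world with the right qualitative structure — not
that any empirical effect exists in real dyads.

## Numerical and reproducibility choices

* Quantiles are type 7 (linear interpolation) everywhere an IQR is taken.
* Entropies are in nats; minimum line lengths are 2.
* Empirical p-values always use the add-one convention and cannot be 0.
* Degenerate inputs (zero IQR, empty recurrence, all-silent sessions) are
  flagged and propagate as `unstable`/`degenerate`, never as silent zeros.
* All randomness flows through a deterministic seed tree
  (`derive_seed(master, stage, replicate)`, 32-bit safe), so stages are
  independently rerunnable and `run_pipeline()` is byte-reproducible for a
  given configuration and seed.
* The JZS correlation Bayes factor (`bayes_cor()`) uses a stretched-beta
  prior on ρ with scale 1/3 and computes the marginal likelihood by nested
  adaptive quadrature; an independent fine-grid quadrature oracle checks it
  in the tests.  BF > 10 is a reporting filter, not a multiplicity
  correction.  Normality gating is Shapiro–Wilk at α = 0.05 on either
  variable, with Blom-offset inverse-normal rank transformation applied to
  both.
* The test–retest ICC is the two-way consistency single-measure ICC(3,1)
  with the F-based confidence interval.

## Known limitations

* The single-random-intercept model ignores caregiver-by-child random
  slopes; with four observations per subject, richer random structures are
  not estimable anyway.
* The between–within df rule is an approximation; it is validated by
  simulation at the designs used here, not in general.
* Window-level permutation destroys within-speaker autocorrelation along
  with dyadic alignment; block permutation would preserve the former but is
  not implemented because the window-level scheme is the literal
  specification of the surrogate used.
* The generator's register mechanism is one of many worlds consistent with
  the pipeline's obligations; parameter estimates from real data should not
  be interpreted through its specifics.
* No command-line binary is shipped: the exported functions and
  `run_pipeline()` are the interface, which suits an R-native analysis
  workflow.
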