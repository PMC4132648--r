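---
title: "The event-based model: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The event-based model: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmr)
```

## The model

The event-based model (EBM) describes disease progression as a fixed
sequence of *N* events, each the transition of one biomarker from a
"normal" to an "abnormal" distribution. A subject at stage *k* has exactly
the first *k* events of the sequence. Given per-biomarker measurement
densities under the two states, the likelihood of a candidate sequence
marginalises each subject's unknown stage with a uniform prior over the
*N* + 1 stages; the uniform prior deliberately injects no information about
any subject's disease severity. The fitted object delivers three things:
the maximum-likelihood ordering, a posterior over orderings (visualised as
a positional variance diagram), and a per-subject stage.

The model's key assumptions, all of which the synthetic generator encodes
and the limitations section revisits:

* a single event ordering is shared by the whole population;
* biomarker measurements are conditionally independent given the stage;
* each biomarker's two states are adequately described by normal
  distributions;
* measurements are complete — subjects with missing biomarker values are
  rejected (or dropped in the reader's lenient mode), not imputed.

## Event distributions

Each biomarker's density pair is a two-component normal mixture fitted to
**all** subjects jointly, because in sporadic disease neither labelled group
is pure: a sizeable fraction of cognitively normal (CN) elderly subjects are
presymptomatic cases, and the patient (AD) group contains misdiagnoses. The
diagnostic labels enter only twice:

* **Initialisation.** The normal component starts at the CN group's
  mean/SD, the abnormal at the AD group's, and the mixing weight at the CN
  fraction of the cohort. This makes the fit deterministic.
* **Constraint.** The normal component's SD may not exceed the CN group's
  sample SD, and the abnormal component's may not exceed the AD group's — a
  weak guard against physically unrealistic solutions when the two states
  overlap heavily. We read the constraint as pairing the normal component
  with the CN group and the abnormal with the AD group, the natural pairing.

Fitting is expectation–maximisation with the constraint enforced by
projection at each M-step (the SD estimate is clipped at its bound). Because
the component mean and SD separate in the M-step objective and that
objective is unimodal in the SD, the clipped update is still the exact
constrained maximiser, so the observed-data log-likelihood is non-decreasing
across iterations; the fit stores its full likelihood trace and the test
suite asserts monotonicity. Iteration stops when the log-likelihood gain
falls below `tol = 1e-8` (cap `max_iter = 10000`; EM converges slowly when a
mixing weight approaches 0 or 1, and a tight cap would return mid-trajectory
parameters). Degenerate inputs (all values identical, a component's spread
collapsing to zero) are errors, not silent repairs. If the converged
components sit on the wrong side of each other relative to the biomarker's
declared direction of abnormality, they are relabelled with a warning.

Two further numerical choices: densities are floored at `1e-300` before
taking logs, so extreme outliers yield very unlikely — never infinitely
unlikely — observations (the floor is unreachable for any realistic value);
and the mixing weight is used only for fitting and for descriptive cut
points, never in the sequence likelihood, which conditions on event status
(the uniform stage prior plays the weight's role there).

The descriptive cut point for a biomarker is the value between the component
means where the mixture posterior probability of abnormality is 0.5, found
by root-finding on the log-density difference; sensitivity and specificity
against the labels can be reported alongside. The model itself never uses
cut points — they exist for comparison with threshold-based conventions.

## Sequence inference

The sequence log-likelihood is evaluated entirely in the log domain:
cumulative log-sums over positions give every stage's log-likelihood in
O(*JN*), and a log-sum-exp folds in the uniform stage prior. A brute-force
linear-space evaluation exists in the test suite as an independent oracle
(agreement to 1e-10 relative).

**Search.** From each of `n_starts = 10` random permutations, greedy ascent
evaluates all N(N−1)/2 pairwise position swaps and moves to the best
strictly improving one, breaking ties by the lexicographically first pair;
the best local optimum across starts is returned. On problems small enough
to enumerate (N ≤ 5) the result equals the exhaustive argmax on every seeded
instance we test. A fit where every swap leaves the likelihood exactly
unchanged is flagged as fully degenerate rather than pretending an ordering
was learned.

**Uncertainty.** A Metropolis chain over permutations proposes swapping two
uniformly chosen positions — a symmetric proposal, so the acceptance
probability is the bare likelihood ratio. Retained samples are summarised as
the positional variance matrix: entry (event, position) is the fraction of
samples placing that event there; rows and columns sum to one by
construction. Display orders the rows by the maximum-likelihood sequence,
greyscale 0 → white to 1 → black. Package defaults are 10,000 retained
samples after 1,000 burn-in — enough for a stable diagram on the problem
sizes here; the counts are arguments, and long production chains are a
matter of patience, not code. When the posterior concentrates on a single
ordering the chain may reject every proposal; that is reported as a
diagnostic warning (acceptance rate 0) and is expected behaviour at strong
separation, not a failure. A single seed governs each run and is recorded
in the result.

**Bootstrap cross-validation.** `bootstrap_sequences()` re-estimates the
mixtures *and* the ML sequence on `B = 100` (default) subject resamples and
aggregates the B orderings into a positional variance matrix. Each replicate
draws its RNG substream deterministically from the master seed, so enlarging
B extends rather than reshuffles the replicate set. Resampling is plain
(unstratified) bootstrap of subjects; a stratified-by-diagnosis option
exists but is off by default since nothing in the method requires group
sizes to be preserved. A resample that cannot support the constrained fit
(fewer than two CN or two AD subjects, or a spreadless biomarker) is redrawn
with a message; more than 50% redraws aborts. Because every replicate sees
only a resample, these diagrams are systematically more diffuse than the
MCMC diagrams on the full data — the test suite asserts exactly that
relation on synthetic cohorts.

## Staging and its longitudinal consistency

Under a fixed sequence, a subject's stage is the argmax over k of the stage
likelihood (uniform prior), with exact ties resolved to the **lowest**
stage so severity is never inflated by ambiguity. The full normalised stage
posterior is returned alongside; the point stage is a summary, not the
model's whole opinion of the subject.

For longitudinal data we flag a subject as inconsistent only when the
follow-up stage *drops* below baseline by more than the sequence's own
uncertainty at that stage. The uncertainty band is this package's
operationalisation (labelled as such): the band half-width at stage k is the
smallest window of contiguous positions around k over which the positional
variance mass of the event at position k reaches `band_mass` (default
0.95). A near-certain sequence gives band 0 — any drop is flagged; a blurred
diagram widens the tolerance. Progression or stability is always consistent.

## Stage-based evaluation

`stage_distribution()` tabulates per-diagnosis stage proportions (columns
sum to one). `classify_by_stage()` sweeps every threshold t = 0..N+1,
classifying stage ≥ t as positive, and reports the sweep plus the report at
the balanced-accuracy-maximising threshold — lowest threshold on ties,
favouring sensitivity, since the intended use is early detection. Balanced
accuracy is exactly (sensitivity + specificity)/2. AUC is computed from the
sweep's ROC points by the trapezoid rule, which is identical (to rounding)
to the Mann–Whitney rank statistic with half-credit for ties; the test suite
asserts the identity. Cohort construction for conversion analyses
(follow-up windows, censoring) is the caller's concern: the module takes a
binary outcome vector and is window-agnostic, and the stage table export is
designed so a survival package can consume it directly.

## The synthetic generator

`simulation_scenario()` defines the study conditions the package is
validated under; `generate_cohort()` draws from them with a known truth
sidecar. Defaults, and why:

* **14 events**, matching a realistic multi-modal event set (3 CSF, 3
  cognitive, 6 volumetric, 2 atrophy-rate markers).
* **Group sizes 100 CN / 130 MCI / 70 AD** (J = 300), a typical
  observational-cohort profile.
* **Component separation 2 pooled SDs** between normal and abnormal means
  (per-event means/SDs and direction are all overridable).
* **Contamination 1/3**: a third of CN-labelled subjects are presymptomatic,
  drawn from nonzero stages — 75% over stages 1–3 and 25% over stages 4–6,
  i.e. early (CSF-type) events only, which is how presymptomatic controls
  actually present.
* **Misdiagnosis 0.1**: a modest fraction of AD-labelled subjects are drawn
  from stage 0.
* **Stage profiles**: uncontaminated CN at stage 0; MCI on a triangular bump
  over stages 1..N−1 peaking mid-course; correctly diagnosed AD mostly at
  the final stage (0.6) with the remainder tapering over the three stages
  before it — the end-stage pile-up a staged AD cohort shows.

Noise is independent across biomarkers given the stage — exactly the
model's own conditional-independence assumption. That is deliberate and is
also the generator's main departure from real data, where biomarkers within
a modality are correlated given stage; passing the recovery tests therefore
demonstrates correctness of the machinery under the model's assumptions,
not robustness to their violation. Events are binary by construction (no
sigmoid trajectories), and follow-up visits resample all biomarkers at the
advanced stage rather than evolving the previous noise.

## What recovery is — and is not — achievable at the default separation

With the generating (oracle) distributions plugged in, the sequence search
recovers the true 14-event ordering essentially exactly (Kendall tau ≈ 1)
on default-sized cohorts, and at J = 3000 the full pipeline reaches tau ≈
0.93. At the default J = 300, however, the binding constraint is the
mixture estimation itself: a five-parameter normal mixture whose components
sit 2 pooled SDs apart is weakly identified from 300 pooled observations,
and the constrained MLE's sampling variance (occasionally including
near-coincident component solutions that the weak SD bound cannot exclude)
scrambles the ordering signal of the affected biomarkers. The acceptance
suite measures a median tau of ~0.7 over 10 seeds under these conditions;
we report that number as computed rather than tightening the scenario to
flatter it. Fits that achieve even higher mixture likelihood (multi-start
EM) recover the ordering *worse*, confirming this is a property of the
estimator under these conditions, not of the optimiser. Real multi-modal
cohorts typically show larger effect sizes (d ≈ 2.5–3 for the strongest
markers), where recovery is correspondingly stronger.

## Problem sizes used by the tests and acceptance script

The test suite exercises small cohorts (5–6 events, 90–240 subjects) for
unit and property checks, exhaustive enumeration up to N = 5, MCMC chains of
50,000 samples for distributional checks, bootstrap with B = 10–25, and the
default 14-event, 300-subject scenario across 10 seeds for end-to-end
recovery — sizes chosen so the whole suite runs in a couple of minutes while
every property remains sharply testable. The acceptance script uses the
same scenario sizes and derives all of its seeds from the single `--seed`
argument.

## Known limitations

* One ordering for everyone: heterogeneous subpopulations blur the
  positional variance diagram rather than being modelled (no mixtures of
  orderings).
* No missing data; no covariate-adjusted or nonparametric event
  distributions.
* MCMC positional variance understates total uncertainty (the mixture
  parameters are held fixed), while bootstrap diagrams overstate it; read
  them as the two ends of a bracket.
* The longitudinal consistency band is a declared operationalisation of
  sequence uncertainty, not a canonical definition.
* Stages are discrete; no fractional staging or transition-time modelling.
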