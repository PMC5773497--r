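---
title: "subfieldRSA: models, design decisions and limitations"
author: "subfieldRSA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{subfieldRSA: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subfieldRSA)
```

## What the package models

subfieldRSA is a simulation and inference pipeline for multivoxel
pattern-similarity (PS) analyses of hippocampal subfield data. The paradigm
it emulates is a two-phase episodic memory experiment: at encoding,
participants tour two virtual houses (the *spatial contexts*) across a
series of 20 videos (the *episodic contexts*), each video placing 10 unique
objects in one house. At test, all 200 studied objects plus 52 new objects
are presented one at a time, without any context, across 4 scanner runs of
63 trials, with "remember" / "feels familiar" / "new" judgments; a post-scan
test probes memory for each object's house. The scientific question is
whether trial-wise activity patterns in CA1 and CA23DG (combined
CA2/CA3/dentate gyrus) carry information about the retrieved episodic and
spatial context — and in which direction.

The pipeline runs: design and behavior simulation → trial-wise voxel
patterns per ROI (optionally through a BOLD forward model and a
least-squares-single GLM) → z-threshold outlier exclusion → a
trial-by-trial Pearson correlation matrix → between-run, eligibility-gated
condition-labeled trial pairs → random-intercept mixed models compared by
chi-squared likelihood-ratio tests (LRTs) → three robustness controls.

## The generative pattern model

For an old trial $t$ showing an object from video $v$ in house $h$, the
voxel pattern is

$$x_t = a\,H_h + b\,c_t\,V_v + \varepsilon_t,$$

with $H_h, V_v$ independent standard-normal latent voxel vectors (one per
house, one per video), $\varepsilon_t$ iid noise with SD $\sigma$, and a
loading $c_t$ that encodes the ROI's coding regime:

* **integrative** (CA1-like, pattern completion): $c_t = 1$, so same-video
  trials share the video signal and correlate positively;
* **separative** (CA23DG-like, pattern separation): the $n$ items of a
  video receive zero-sum loadings with $\sum c = 0$, $\sum c^2 = n$, so the
  mean same-video loading product is $-1/(n-1)$ and same-video trials
  *anti*-correlate relative to different-video/same-house trials;
* **null**: $b$ is effectively 0.

New trials are pure noise. The implied large-voxel-limit expected Pearson
correlations, with $D = a^2 + b^2 + \sigma^2$, are $(a^2 + b^2\rho_c)/D$
for same-video pairs ($\rho_c = 1$ or $-1/(n-1)$), $a^2/D$ for
different-video/same-house pairs, and 0 across houses
(`expectedSimilarity()`); the Monte-Carlo tests validate the generator
against these closed forms.

Two generator decisions are worth flagging. First, for even $n$ the
zero-sum loadings are $\pm 1$ (half the items $+1$, half $-1$): this
satisfies the zero-sum constraints *exactly* and keeps per-trial variance
uniform, so the closed form is exact rather than approximate; odd $n$ falls
back to centered, rescaled Gaussian loadings. Second, the default house
amplitude is $a = 0$: the empirical finding this pipeline is designed to
reproduce includes *null* spatial-context effects in every ROI, so the
default study conditions carry an episodic (video) signal ($b = 0.6$,
$\sigma = 1$) but no spatial (house) signal. Setting $a > 0$ produces
graded spatial effects for users who want them.

The default behavioral parameters are the published group rates: remember
hit rate 0.68, familiar hit rate 0.25, correct rejection rate 0.90. The
overall spatial source hit rate of 0.71 is a *marginal* rate, so it is
decomposed here into conditionals (free parameters): 0.79 after "remember",
0.55 after "familiar", 0.50 (chance) after misses, giving
$0.68 \cdot 0.79 + 0.25 \cdot 0.55 + 0.07 \cdot 0.50 \approx 0.71$ and
preserving the observed source-memory advantage for recollected items.
Reaction times are log-normal (location $\log 1.2$, scale 0.4), truncated
to the 3 s response window — a right-skewed shape typical of recognition
RTs; no RT distribution was reported, so these are the package's own
defaults.

## Trial layout decisions

How old items were distributed across the four test runs was not specified
in the source experiment. The generator stratifies old trials so each run
carries an approximately equal share (±1) from each house; this keeps
between-run pair counts balanced across conditions and subjects. This is a
documented guess, and the only consequence of changing it is the
distribution of per-condition pair counts.

## Single-trial estimation and outlier exclusion

The least-squares-single (LSS) design per trial has two task regressors —
the target trial's HRF-convolved stick and one regressor carrying *all
other trials* of the run — plus optional nuisance columns, Legendre drift
(order 2) and an intercept. Sticks are convolved with a peak-normalized
double-gamma HRF (delays 6/16 s, dispersions 1/1 s, ratio 1/6, 32 s
support) at 0.1 s microtime and sampled at the TR grid; onsets are not
locked to the TR. ITIs are jittered uniformly on a 0.5 s grid over 2–8 s.

One numerical subtlety: "noiseless data implies exact recovery" is *not*
true of LSS in general. Because heterogeneous other-trial betas are
represented by a single shared regressor, they leak into the target
estimate through the intercept and drift columns unless every trial
response is an identical shifted copy. Exact recovery (verified to machine
precision in the tests) requires TR-locked onsets (stimulus + ITI a
multiple of the TR), full HRF support within the run, and a driftless fit;
the realistic jittered case is instead held to an estimated-vs-true beta
correlation criterion (> 0.8 at the default noise SD of 0.5 and drift
amplitude 1; the pilot value is ≈ 0.93).

Outlier exclusion z-scores a per-trial beta summary (mean over voxels by
default, maximum absolute value as an alternative) within each run and
flags $|z|$ above a threshold, default 0.75 within the reported 0.7–0.85
range. On normal-like summaries this two-sided rule excludes
$2\Phi(-0.75) \approx 45\%$ of trials — far more than the ~10% reported
for the original data, whose exact exclusion statistic cannot be
reverse-engineered from its description. Both the threshold and the
summary statistic are therefore exposed as configuration; the default
simply follows the stated rule, and all downstream machinery is indifferent
to the exclusion rate beyond pair counts.

## Pair construction and models

Pairs are (i) between-run only, (ii) restricted to old trials with a
correct "remember" response *and* correct house source memory, and (iii)
purged of outlier-excluded trials. Conditions partition old-old pairs:
same video (implying same house), different video/same house, different
house. Similarity is raw Pearson $r$ (a Fisher-z flag exists;
the analysis choice follows the convention of reporting untransformed
PS values). The spatial contrast drops same-video pairs so that any
same-house effect is attributable to spatial context alone. RT differences
are absolute values; each object is tested once, so same-object pairs
cannot occur structurally.

All models are fitted by **maximum likelihood** (not REML), which is
required for valid fixed-effect LRTs. The omnibus test compares
`similarity ~ roi * condition * hemisphere + (1 | subject)` against the
same model without the three-way interaction (2 df with 2 ROIs × 3
conditions × 2 hemispheres). Condition contrasts are 1-df LRTs with a
random subject intercept, treatment-coded with the less-similar-context
condition as reference so a positive coefficient means higher similarity
for the shared context. Pair-level observations are treated as
conditionally independent given the subject intercept — mirroring the
published model; pairs sharing a trial are in fact dependent, which this
model (deliberately) ignores. Convergence uses a bounded-variance
parameterization with up to three seeded restarts; singular (boundary)
fits are accepted, as usual for near-zero variance components. Dunlap's
correction is used for paired-design effect sizes:
$d = t\sqrt{2(1-r)/n}$.

## Controls

* **Matched subsampling**: per subject × ROI × hemisphere cell, the
  condition with the fewest pairs sets the count $m$; $m$ pairs are drawn
  without replacement from every other condition and the omnibus model is
  refitted; the summary is the fraction of replicates significant at
  $\alpha$. Sampled indices are kept sorted, so when counts are already
  equal every replicate reproduces the full table verbatim and the
  statistic is exactly invariant. All subjects are resampled independently
  in every replicate. The standalone function defaults to 1000 replicates;
  the pipeline default is 100, a runtime choice for routine use.
* **Influential voxels**: voxels are ranked by mean absolute response,
  by response SD, or by the mean squared pair difference over the two
  episodic conditions (interpreting the compressed phrasing as the mean
  over those pairs of $(\beta_{iv} - \beta_{jv})^2$); the top 5 are
  dropped per subject (ties to the lowest index) and the contrast is
  refitted from the pruned similarity structure.
* **RT covariate**: the "random effect of the reaction-time difference"
  is implemented as a by-subject random slope of `rt_diff`; a
  fixed-covariate fallback (with a warning) handles zero-variance RT
  differences.

## Problem sizes and calibration checks

The shipped checks run at deliberately chosen scales: 23 simulated
subjects and 100-voxel ROIs for study-scale runs (matching the reported
sample size), 100 seeded replicates for sign recovery of the subfield
dissociation, 1000 direct null simulations for LRT calibration (rejection
rate required within [0.03, 0.07] at $\alpha = 0.05$), and Monte-Carlo
similarity checks at 100 and 1000 voxels against the closed forms within
3 SE of independent replicate means (replicate counts are kept moderate so
the $O(1/n_\text{voxels})$ small-sample bias of Pearson $r$ stays well
inside the band).

## What passing tests do and do not show

The generator produces iid Gaussian noise, exchangeable voxels and
latent context vectors that are exactly orthogonal in expectation. Real
fMRI data have spatially and temporally autocorrelated noise, motion
artifacts, vascular and susceptibility structure, and context signals of
unknown geometry; the BOLD forward model here adds only polynomial drift
and white noise, and omits prewhitening on the analysis side accordingly.
Passing tests therefore certify the *machinery* — counts, filters, model
algebra, calibration, robustness logic — not the biological claim. Whether
real CA1/CA23DG effects reflect amplitude differences or
correlation-structure differences is not resolvable with this generator,
which fixes only the similarity structure.

## Worked example

```{r example, eval = FALSE}
cfg <- defaultPipelineConfig(nSubjects = 23)
bundle <- runPipeline(cfg, seed = 1, verbose = TRUE)
makeReport(bundle)
```

The report tabulates behavioral rates, the omnibus interaction, every
ROI × hemisphere × contrast LRT with its direction, condition-mean
similarities, and control summaries. Under the default regimes the
episodic contrast is positive in left CA1, negative in left CA23DG, and
null elsewhere, with null spatial contrasts throughout — the qualitative
dissociation the pipeline is designed to recover.
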