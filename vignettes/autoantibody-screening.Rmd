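---
title: "Two-phase autoantibody screening and diagnostic modelling with seroscreen"
author: "seroscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase autoantibody screening and diagnostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Protein-microarray autoantibody studies in rheumatoid arthritis (RA)
proceed in two phases. Phase I probes a small number of sera on a
genome-scale array (tens of thousands of recombinant proteins printed
in duplicate, with printing-buffer, human IgG/IgM, biotin-BSA, BSA and
GST control spots) and calls candidate autoantigens. Phase II re-probes
a full case/control cohort on a small focused array carrying only the
candidates, evaluates each antibody as a diagnostic marker, and
combines them in a classifier. `seroscreen` implements both phases plus
the surrounding plumbing: GenePix-style file I/O, a synthetic-cohort
generator with ground truth, and an orchestrated pipeline.

## Signals, quality control and hit calling

The analysis channel is the 532 nm foreground/background pair; the net
signal of a spot is `max(fg - bg, 1)`. The floor of 1 fluorescence unit
is a deliberate numerical choice: scanned medians can dip below local
background, and a positive floor keeps `log10` transforms defined
downstream without affecting any spot that carries real signal.

Duplicate printing gives each protein two spots. Aggregation reports,
per probe:

* `net` — mean of the two floored net signals;
* `rpd` — relative percentage difference, `|a−b| / ((a+b)/2) × 100`,
  the within-array reproducibility metric (the literature names this
  quantity without defining it; the symmetric-mean form used here is the
  standard one);
* `snr` — mean over duplicates of `(fg − bg) / bg_sd`, the GenePix
  convention for signal-to-noise using the per-spot background SD.

Spots with negative GenePix flags are excluded; a probe with one usable
spot is reported as `single` (RPD undefined), with none as `missing` —
never as zero, which would silently fabricate a measurement.

Array QC (`qc_array`) checks two fractions over protein spots only:
foreground within [1000, 24000] and duplicate RPD strictly below 30%,
each required to reach 0.90. These ranges describe the anti-GST quality
scan of a fully tagged array, which is what `simulate_qc_profile`
emulates; serum arrays are sparser and are not expected to satisfy the
in-range criterion.

Hit calling (`call_hits`) declares a probe reactive for a sample when
*both* duplicates are present on the serum array and *no* duplicate of
the probe is present on either the blank or the
secondary-antibody-only array. "Present" is not defined in the
literature we follow; we use net signal ≥ 3 background SDs (the
configurable `presence_z`), a common array-positivity heuristic.
Candidate selection then requires, in at least `min_case_positive = 2`
hit-positive cases, SNR **strictly** above 13 and net signal
**strictly** above 2.5× the pooled-control net (both phrased as
"higher/more than", hence strict), and tolerates at most
`max_control_positive = 0` hit-positive healthy controls. The frequency
rule is our own: published criteria state the thresholds but not how
many samples had to agree.

## Phase II diagnostics

* **Cutoffs.** Seropositivity cutoff = mean + 2 SD of healthy-control
  intensities (SD with n−1). Positivity is strict (`> cutoff`); tie
  handling at the cutoff is unstated in the sources, and a strict rule
  keeps a degenerate constant-control cutoff from calling every control
  positive.
* **ROC.** AUC is the Mann–Whitney concordance (ties count ½), computed
  by midranks, which agrees *exactly* with the exhaustive pairwise count
  — the test suite asserts bitwise equality against a brute-force oracle
  on hundreds of random tied instances. The 95% CI uses the DeLong
  placement-variance estimator, cross-checked against an independent
  implementation; the original analyses only state "nonparametric", so
  the specific interval estimator is a documented choice.
* **Prevalence.** Percentages are rounded half-up to one decimal, the
  rendering used in clinical tables (banker's rounding would disagree on
  exact halves). Subgroup comparisons use Fisher's exact test when any
  expected 2×2 cell is below 5, otherwise chi-square with continuity
  correction, and record which test ran.
* **Clinical correlation.** Spearman by default; Pearson only when both
  members of a pair pass a Shapiro–Wilk screen at α = 0.05 — the source
  analyses list both tests without a selection rule, so the rule is
  ours and is recorded per cell. Pairs are formed with pairwise
  deletion; cells with fewer than 3 pairs are reported missing and
  excluded from the Bonferroni factor, which multiplies by the number of
  tests actually performed.
* **Embedding.** `embed_cohort` is a thin, seeded contract over t-SNE.
  We run exact gradients (`theta = 0`): at cohort scale the cost is
  negligible and the Barnes–Hut tree is not robust to duplicate
  profiles. An input with zero variance across samples has no
  neighbourhood structure; it embeds to the origin rather than erroring,
  so degenerate inputs survive. Coordinates carry no scale guarantee.

Two open choices are worth naming. The specificity denominator of the
panel report pools healthy and disease controls (n = 261 at study
scale), switchable to healthy-only — published per-antibody
specificities are consistent with the pooled denominator. Cases with
unrecorded disease duration are excluded from early/established
contrasts rather than imputed.

## The classifier

Features are `log10` net intensities of the candidate antigens,
z-standardized with training-set statistics. The SVM uses the RBF
kernel; `(C, γ)` comes from a grid search maximising mean out-of-fold
AUROC over stratified four-fold cross-validation, ties broken toward
smaller `C` then smaller `γ`. The default lattice is powers of two,
`C ∈ 2^{−5..15}`, `γ ∈ 2^{−15..3}`, at step 2 in the exponent — the
usual coarse grid; only the optimum of the original analysis is
published, not its lattice.

Feature ranking follows kernel RFE: with the SVM fitted on the current
feature set, compute `J = ½ Σᵢⱼ αᵢαⱼyᵢyⱼK(xᵢ,xⱼ)` on the support
vectors, recompute `J` for each feature with that feature's column
removed from the kernel while holding `α` fixed, and eliminate the
feature with the smallest `|ΔJ|` (ties to the lowest column index). For
the RBF kernel the reduced kernel is obtained in closed form,
`K^{(−f)} = K ⊙ exp(γ D_f)` with `D_f` the squared per-feature
differences, so each round is cheap; one feature is eliminated per
round. A constant feature leaves every pairwise distance unchanged and
is provably eliminated first — the suite checks this analytic null, an
independent brute-force recomputation of the first elimination, and the
γ→0 limit where the `|ΔJ|` ordering approaches the linear-SVM `w²`
ordering.

The feature count `k` is the argmax of mean out-of-fold AUROC along the
elimination path (ties to the smallest `k`); RFE runs once on the full
training set and the folds only score the path. Nesting RFE inside each
fold is the main alternative; the single-run variant is what the
published description implies, and we document it as the primary
reproducibility risk of this design.

The decision threshold is the smallest out-of-fold score achieving
specificity ≥ 0.90 among training controls (out-of-fold, not
resubstitution, scores — the final model would otherwise look
optimistically separable). The threshold is then applied unchanged to
final-model scores on the held-out set. All data-dependent choices —
standardization, grid search, RFE, `k`, threshold — see training data
only; the tests include a canary asserting that perturbing held-out
rows cannot change the trained model. For marker comparisons at matched
specificity, a combination of markers is called positive when **any**
member is positive; the sources compare combined markers without
defining the rule, and the any-positive rule is the clinical convention
for parallel testing.

One solver subtlety: libsvm orients binary decision values toward the
class that appears first in the training data, not toward a fixed
factor level. The trained model therefore stores an orientation sign
read from the fitted object, and the explicit kernel decision function
(used for serialization-independent scoring) applies it, so larger
scores always mean "more case-like".

## What the synthetic cohort emulates

`sim_config()` defaults describe one fixed study condition, mirroring a
two-phase RA cohort: 182 RA cases of which 48 ACPA-negative, 103
healthy controls, 158 disease controls (48 AS, 47 SLE, 31 SS, 32 OA),
200 antigens printed in duplicate of which 15 informative, plus
pooled-control, blank and secondary-only reference arrays.

Intensities are log10-normal: fluorescence spanning 1000–24,000 on the
QC array and strictly positive skewed serum signal make a log-normal
model the natural choice; per-antigen null means are drawn from
`[1.0, 1.35]` log10 units with SD 0.18, over a background of
300 ± 40 units. Reactivity is patient-structured: each case reacts to
one "primary" informative antigen with a shift of 1.8 log10 units
(lognormal-like magnitude noise, CV 0.3) and to each remaining
informative antigen with probability 0.05; ACPA-negative cases react at
all with probability 0.6 and at half the shift, which reproduces the
heterogeneity in which ACPA-negative profiles overlap the control
groups; early cases (duration < 2 y) gain extra reactivity and a small
boost on a designated early-antigen subset; disease controls
cross-react sparsely (probability 0.03 per antigen, attenuated).
Clinical covariates (ESR, RF, IgG strongly; CRP, DAS28, joint counts
weakly) load on a latent factor shared with the antibody burden at
strength 0.5.

Two defaults deserve their rationale spelled out. First, the effect
size: the screening gates tie "present" (net ≥ 3·bg_sd) and "selected"
(SNR > 13, i.e. net > 13·bg_sd) to the *same* background-SD scale, so
an antigen absent in every healthy control can only qualify in cases if
the case shift exceeds log10(13/3) ≈ 0.64 decades plus several
between-sample SDs. A shift below ~1 decade therefore cannot produce
recoverable candidates under these gates for any choice of the other
parameters; 1.8 decades (a ~60-fold response, typical of genuine array
seropositivity) makes recovery robust. Second, disease-control
cross-reactivity: without it, control decision scores are nearly
degenerate and the 90th-percentile threshold order statistic becomes
unstable, so held-out specificity would swing widely around its target;
sparse attenuated cross-reactions give the control score distribution a
continuous upper tail and centre held-out specificity near 0.90.

What the generator does **not** emulate: spatial artifacts (gradients,
scratches), batch effects between arrays, isotype cross-talk, true
biological correlation structure between antigens, and the long-tailed
titre distributions of real autoantibodies. Passing tests on this
cohort therefore demonstrates that the *pipeline logic* recovers planted
structure under realistic noise — not that the thresholds would perform
identically on real serum data.

## Problem sizes and runtimes

The test suite and acceptance script run the full study-scale cohort
(200 antigens, 443 serum arrays, ~186,000 spots) through screening and
modelling in roughly 15 seconds per seed on one CPU; the planted-signal
property is asserted over three seeds, and smaller cohorts (60 antigens,
~90 arrays) exercise the file-based pipeline and determinism checks.
These sizes were chosen so that the whole suite completes in about a
minute while every stage still runs at realistic dimensionality.

## Known limitations

* Background correction is per-spot local background; block-level
  alternatives are not implemented.
* No cross-array normalization is applied by default (none is described
  for the workflow we implement); `build_intensity_matrix` operates on
  raw net signals.
* RFE is run once on the training set rather than nested per fold (see
  above).
* The DeLong interval is asymptotic and degenerates for separable
  groups (interval collapses at the boundary); small-sample exact
  intervals are out of scope.
* The classifier is an RBF SVM by design; no alternative learners are
  provided.
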