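---
title: "Pooled rare-allele screening: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled rare-allele screening: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The screening problem

Early detection of a cryptic invasion — for example, barred tiger salamander
(BTS) alleles introgressing into an endangered California tiger salamander
(CTS) population — requires genotyping thousands of individuals at a panel of
diagnostic SNPs. poolscreen implements a group-testing shortcut: tissue from
up to 15 individuals is pooled, and each pool is run on a 96 x 96
endpoint-fluorescence SNP array. Each sealed reaction reads out one pool at
one diagnostic SNP as a pair of intensities, the X channel reporting the
native allele and the Y channel the non-native allele. Detecting one
heterozygous individual in a pool of 15 means resolving a non-native allele
fraction — the *rare-allele ratio* (RARatio) — of

$$\mathrm{RARatio} = \frac{het + 2 \cdot homBTS}{2n} = \frac{1}{30}$$

against a background of zero. A chip carries up to 90 pools plus six
controls (two homozygous-native, two homozygous-non-native, two no-template)
and scores 48 SNPs in duplicate, so every (pool, SNP) combination has a
same-chip technical replicate.

## Background structure and control correction

Endpoint fluorescence has a nonzero floor even where the allele is absent.
In homozygous controls this background varies far more between SNP assays
(a plausible consequence of uneven multiplex pre-amplification) than between
chip runs (imager and master-mix drift). `variance_decomposition()`
quantifies both with one-way fixed-effects ANOVA and
$\eta^2 = SS_{between}/SS_{total}$; separate one-way tests are used rather
than a two-way model because each factor is interpreted marginally, and with
a single factor $\eta^2$ equals partial $\eta^2$.

Correction is deliberately coarse: `estimate_background()` pools all assays
and replicates of a chip's homozygous controls into one scalar per channel
(the mean absent-allele intensity), and `apply_correction()` subtracts that
scalar from every reaction on the chip. Per-assay backgrounds are *not*
estimated here — the per-assay classifiers absorb assay-level structure, and
a per-chip scalar is all that is needed to make chips comparable. Corrected
intensities are not clipped at zero, since clipping would distort the
class-conditional distributions the classifiers learn. No-template controls
are excluded from estimation and reserved for sanity checks.

## Per-assay classifiers

`train_assay_classifier()` fits one random forest per SNP (500 trees, one
candidate feature per split, no depth limit — the defaults of the
randomForest package) on exactly two features: the X and Y intensities of a
reaction. No engineered ratios or angles are added; with two features and
assay-specific models, the forest can represent any boundary the data
support. Training data are pools of known composition at RARatios 0, 1/30
and 1/15, split 50/50 at the pool level (both replicates of a pool stay on
one side, stratified by presence class; odd counts floor the training side).
Out-of-bag (OOB) error is taken from the training half, the standard bagging
estimate. Assays are dropped when OOB error exceeds 5% *or* hold-out
sensitivity falls below 90%; values exactly at a threshold are retained
(strict inequalities). Call confidence is the winning-class vote fraction,
which lies in [0.5, 1] by construction.

Predictive values are estimated in closed form: with a uniform prior, a
correctness proportion with $t$ true and $f$ false outcomes has posterior
$\mathrm{Beta}(t+1, f+1)$, whose median and central 95% interval
`posterior_call_probability()` reports. For a binomial proportion this
coincides with an MCMC proportion test up to Monte-Carlo error, so no
sampler is involved.

## Replicate concordance, triage and validation

Before calling, `filter_replicate_pairs()` removes discordant technical
replicates. The absolute between-replicate difference is computed per
channel over the whole run batch, and a pair is removed when it exceeds
mean + 1 SD of that distribution in either channel. The mean + 1 SD form
keeps the rule scale-free; a pure 1-SD-above-zero variant is exposed via
`method = "sd_only"`, and the batch (rather than per-chip) scope is the
default because difference distributions are stable across chips. Dropping
the pair in both channels on a single-channel exceedance is conservative:
dubious reactions are discarded, not half-trusted.

Triage then follows a strict state machine (`triage_pools()`): a true
heterozygous pool should be Het in *both* replicates, so single-replicate
Hets are dismissed as the expected false-positive signature, and only
both-replicate Hets make a pool SUSPECT. Suspects are re-assayed on an
independent chip (`resolve_suspect()`): no repeat both-replicate Het refutes
the detection, a repeat confirms it (with a directive to genotype the
constituent individuals); if the suspect assay's re-assay pair was itself
concordance-filtered, the pool stays suspect with a needs-rerun flag rather
than being silently resolved.

Amplicon validation (`assess_amplicon_pool()`) counts allele reads per
locus. Presence requires at least 3 non-native reads by default — there is
no canonical threshold for this step, and 3 guards against index-hopping
noise while a true 1/30 pool at depth 579 is expected to show
$\lfloor 579/30 \rfloor = 19$. Non-native reads at 100% of assayed loci
raise a contamination flag: a genuinely introgressed pool carries non-native
alleles at only a subset of diagnostic loci, so an every-locus signal
indicates contamination with non-native control DNA. Loci with zero depth
are excluded from the fraction and block nothing by themselves.

## Design mathematics

* `detection_probability(L, s)` $= 1 - (1-s)^L$: the chance of catching a
  single hybrid whose pool is screened at $L$ informative loci with
  per-locus sensitivity $s$. The hybrid sits in exactly one pool (pooling is
  by pond of origin), so pool counts cancel; $L$ should be the number of
  retained assays at which the hypothesized hybrid is non-native.
* `backcross_fraction(f0, g)` $= f_0 \cdot 0.5^g$: expected non-native
  ancestry after $g$ generations of backcrossing to pure natives. The
  package returns generations and leaves calendar arithmetic to the caller.
* `evaluate_accuracy_model()` regresses call correctness on RARatio,
  dilution and zygosity (scaled) plus pool type, with hybrid and assay
  identifiers entered as categorical covariates. This fixed-effects logistic
  form approximates a binomial GLMM with those ids as random effects; the
  inferential targets are the fixed-effect signs and significance, for which
  the approximation is adequate and dependency-light. Complete separation is
  detected and flagged rather than silently reported.

## The synthetic generator and its calibration

No laboratory dataset ships with the package, so `generator_config()`
defines a synthetic model rich enough to exercise every pipeline stage:

| parameter | default | meaning |
|---|---|---|
| `background_mean` | 0.10 | mean absent-allele intensity (arbitrary units) |
| `signal_full` | 1.00 | mean intensity at allele fraction 1 |
| `assay_baseline_sd` | 0.060 | between-assay SD of background |
| `chip_offset_sd` | 0.018 | between-chip SD of background |
| `noise_sd` | 0.012 | within-reaction SD |
| `signal_exponent` | 1 | response shape in allele fraction (linear default) |

A channel's mean is background plus additive assay and chip effects plus a
linear ramp to `signal_full` in its allele fraction; draws are truncated at
zero because raw fluorescence is nonnegative. The exponent exists because
endpoint PCR chemistry may saturate, but no nonlinearity is assumed by
default. Training pools alternate between ratio 0 and the positive ratios so
the presence classes stay balanced — training pools are constructed by
mixing DNA, so balance is a design choice, and the classifiers use no
reweighting.

Two consequences of this calibration are worth stating plainly, because the
test suite computes both:

* **Separability at 1/30 is good but not perfect.** The Y-channel gap
  between an all-native pool and a 1/30 pool is $0.9/30 = 0.03$ against
  reaction noise of 0.012, giving a single-channel AUC of
  $\Phi(0.03/(0.012\sqrt{2})) \approx 0.96$ and a two-channel Bayes error
  near 4% for the hardest class. Retained assays therefore sit around 95-98%
  hold-out accuracy on synthetic screens, and an all-native screen shows a
  percent-scale, not permille-scale, Het-call rate. Real panels whose
  chemistry separates 1/30 more cleanly will do better; passing tests on
  this preset demonstrate pipeline correctness, not an upper bound on assay
  quality.
* **Zero-truncation couples chips to assays.** With assay SD 0.060 on a
  background of 0.10, a few percent of assays have near-zero mean
  background; truncation then biases each chip's pooled control mean by an
  amount that depends on the chip effect, leaving small residual per-chip
  shifts (SD roughly 0.004) in corrected intensities. This pushes clean-assay
  OOB error toward the 5% filter boundary, so on synthetic panels the
  OOB filter trims some healthy assays along with deliberately degraded
  ones. The between-assay $\eta^2$ of synthetic backgrounds follows the
  variance components, $0.06^2/(0.06^2+0.018^2+0.012^2) \approx 0.885$
  (measured 0.86-0.93 across seeds), with chip-level $\eta^2 \approx 0.08$
  — an assay-to-chip ratio above 5 in every run.

What the generator does *not* emulate: PCR kinetics, primer competition,
saturation, inter-locus dependence within a pool beyond composition, DNA
quantity variation between tissue punches, and plate-position effects.
Passing tests therefore certify the statistical pipeline, not the wet-lab
protocol.

## Problem sizes and determinism

The shipped tests use scaled-down screens chosen to be representative while
keeping the suite quick: variance decomposition on 13 chips x 55 assays with
duplicated controls; classifier end-to-end runs on 20 assays x 4 training
chips of 90 pools; planted-truth filter recovery on 20 assays (4 degraded,
10x noise) x 6 chips over 5 seeds; an all-native field screen of 387 pools
x 31 assays; Monte-Carlo cross-checks at $10^5$ replicates; and coefficient
recovery for the accuracy regression at n = 3000 over 100 replicates. Every
stochastic step takes an explicit integer seed, and all generators are pure
functions of (configuration, seed): identical inputs reproduce identical
records, splits, forests and calls. Two chips simulated from one
configuration share reaction noise by construction (so they differ only
through chip effects, which makes chip-effect tests exact);
`simulate_training_run()` varies the reaction seed per chip to emulate truly
independent runs.

## Known limitations

* The intensity model is additive-Gaussian with zero-truncation; real
  endpoint chemistry is multiplicative in places and saturates near full
  signal.
* The concordance threshold (mean + 1 SD) removes a fixed ~15% tail per
  channel whatever the data quality; with very clean replicates this is
  conservative.
* `evaluate_accuracy_model()` is a fixed-effects approximation; with few
  hybrids or assays and strong grouping, a true mixed model (e.g. lme4)
  gives better-calibrated standard errors.
* Individual-level follow-up genotyping of confirmed pools is represented
  only as a directive in the triage output.
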