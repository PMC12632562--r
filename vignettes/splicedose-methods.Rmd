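---
title: "Models and methods behind splicedose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicedose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedose)
library(dplyr)
```

splicedose analyses the two measurable consequences of SRSF2-class
spliceosome hotspot mutations in leukemia models: dysregulated
alternative splicing (shifted cassette-exon inclusion, with its
sequence-level signature in exonic splicing enhancer motifs) and altered
drug sensitivity (to replication-checkpoint kinase inhibitors, read out as
DSS, GR metrics, and IC50). This vignette explains the statistical models,
the tunable parameters, the synthetic-data generator used to validate every
stage, and the numerical choices made where the design was open.

## Percent spliced in and the Beta-Binomial model

For one event in one library, the observable evidence is a pair of junction
read counts: `inclusion_reads` supporting the included isoform and
`exclusion_reads` supporting the skipped isoform. We model inclusion reads
as Binomial(n, Ψ) where Ψ (percent spliced in) is the inclusion fraction.
With a conjugate Beta(a, b) prior, the posterior is
Beta(inclusion + a, exclusion + b); `estimate_psi()` reports the posterior
mean and central 95% interval. The default prior (1, 1) is uniform: with no
reads the estimate is 0.5 with an interval spanning (0.025, 0.975), and any
read depth pulls the posterior toward the empirical ratio.

This two-proportion junction-evidence model deliberately replaces
isoform-aware read-assignment machinery (transcript-length-weighted
generative models used by splicing quantifiers such as MISO): the
downstream decision rule acts only on ΔΨ and a Bayes factor, both of which
are functions of inclusion/exclusion evidence. Where effective-length
differences matter, counts can be rescaled before the Beta update; the
package treats that as a pre-processing concern.

Replicate libraries within a condition are pooled by summing counts before
testing. The comparison the pipeline is built for is one mutant clone
against one isogenic control, each with a single library; the pooling rule
is recorded in the output metadata (`attr(calls, "pooled")`) so multi-library
users can see it.

## The Savage-Dickey Bayes factor

Differential inclusion is tested as H1: Ψ_mut ≠ Ψ_wt against the point
null H0: Ψ_mut = Ψ_wt. Both Ψ get independent Uniform(0, 1) priors. The
induced prior on Δ = Ψ_mut − Ψ_wt is triangular on [−1, 1] with density
exactly 1 at Δ = 0, so the Savage-Dickey density ratio reduces to

BF10 = p_prior(Δ = 0) / p_post(Δ = 0) = 1 / p_post(Δ = 0),

and the posterior density of Δ at zero is the value at 0 of the convolution
of the two Beta posteriors — equivalently the overlap integral
∫ f_mut(ψ) f_wt(ψ) dψ. `bayes_factor()` evaluates that integral by the
trapezoid rule on a uniform grid (default 1001 points), which makes every
reported BF exactly reproducible. The grid refuses inputs whose posterior
is narrower than two grid cells (counts in the millions at the default
grid) rather than returning a silently under-resolved value; raising
`grid_size` resolves them.

The stochastic cross-check (`method = "mc"`) estimates the same overlap by
importance sampling from an equal mixture of the two Beta posteriors with
weight 2·f_a·f_b/(f_a + f_b). The weight is bounded by twice the smaller
density, which keeps the estimator's relative error small even for strongly
separated posteriors where naive density-averaging collapses. Any
density-at-a-point Monte Carlo estimate still degrades when the posteriors
are essentially disjoint (BF beyond ~10^6 at 10^6 draws), so the
equivalence checks sample count pairs from the regime the test is used in:
inclusion fractions in (0.1, 0.9), true differences up to ±0.3 — the
planted effect size of the validation design — and depths up to 100.

Events are called significant when |ΔΨ| ≥ 0.10 *and* BF ≥ 5, both
inclusive; these are the thresholds the package is built around, exposed as
`delta_threshold` and `bf_threshold`. ΔΨ is the difference of posterior
means (mutant minus wild-type); an alternative would be to threshold a
credible-interval bound, which would be more conservative at low depth —
the posterior-mean rule was chosen because the evidence requirement is
already carried by the Bayes factor. Under the validation conditions
(200 events, half planted at |ΔΨ| = 0.3, depth 200), calling at (0.10, 5)
achieves sensitivity ≥ 0.9 with a false-discovery proportion ≤ 0.1; the
acceptance script recomputes both.

## SSNG enhancer motifs, enrichment, and metagenes

SRSF2's RNA-binding preference is summarized by the SSNG consensus
(S = C or G, N = any base, then G); the hotspot mutations shift affinity
from GGNG-class toward CCNG-class variants, so exons gaining inclusion in
mutants should be CCNG-rich and exons losing inclusion GGNG-rich.
`count_motifs()` scans every 4-nt window, counting overlapping occurrences
(the simpler convention with clean additivity; a non-overlapping count
would depend on scan direction) and never matching windows that contain N.

`mean_enrichment()` totals each variant's occurrences inside the exon
intervals (flanks excluded) of the increased- and decreased-inclusion sets
and reports their ratio. A pseudocount (default 1) is added to both
numerator and denominator, always rather than only when a total is zero,
so the estimator is continuous in the counts; per-exon-normalized rates
are also emitted for sets of unequal size, since "mean count per exon"
and "total count" differ exactly by the set-size ratio. Percentile
bootstrap intervals (resampling exons with replacement within each set)
are available for the ratio.

`metagene_profile()` anchors two windows per cassette exon — at the 3′
splice site (exon start) and the 5′ splice site (exon end) — and totals
motif *start* positions per nucleotide offset. Window sizes default to 50
exonic + 50 intronic nt per anchor (25 + 25 in the pipeline defaults, to
fit the simulated flanks); they are free parameters because published
metagenes rarely state them. The profile is log2((inc + 1)/(dec + 1)) per
offset, exactly antisymmetric under swapping the sets. Confidence bands
are percentile bootstrap (B = 1000 by default, seed required): BCa offers
second-order accuracy but needs jackknife acceleration estimates per
position, and at per-position counts of a few dozen the percentile
interval's calibration is adequate — the null-coverage check in the test
suite measures it at ~0.95.

## Dose-response scoring

`normalize_viability()` divides raw well signal by the mean vehicle (DMSO)
signal of the same sample/drug context. Viability above 1 (stimulation) is
kept; negative raw signal is clamped to viability 0 so that inhibition
stays within [0, 100] and the DSS integrand is well-defined.

**DSS.** The drug sensitivity score integrates inhibition above an
activity threshold t (default 10%) over log10 concentration and normalizes
by the maximal achievable area:

DSS = 100 · A / ((100 − t) · (log10 Cmax − log10 Cmin)),

with A the trapezoidal integral of max(0, inhibition − t) and threshold
crossings located exactly on the piecewise-linear curve (not at grid
points). This makes the score 0 for inactive drugs, 100 for complete
inhibition everywhere, exactly 50 for a linear 0→100 ramp at t = 0, and
monotone in pointwise inhibition. Published DSS variants differ in
normalization details; absolute scores from other implementations are
comparable only in ordering, which is what the group contrasts use.

**GR metrics.** When cell counts at treatment start (x0) and end are
available, GR(c) = 2^(log2(x(c)/x0)/log2(x_ctrl/x0)) − 1 removes the
confounding of division rate with drug effect — essential here because the
splicing mutation itself slows growth. GR is 1 for no effect, 0 for
cytostasis, negative for cytotoxicity, and requires a growing control
(x_ctrl > x0; anything else is an error, not a number). GR50 comes from a
bounded sigmoid fit in log-concentration; it is undefined (NA) when
GR_inf ≥ 0.5.

**4PL / IC50.** `fit_4pl()` fits viability = bottom +
(top − bottom)/(1 + (c/ec50)^hill) by bounded Levenberg-Marquardt
(minpack.lm) on replicate-level points — fitting means would understate
noise — with three deterministic starts (EC50 at the quartiles of the
tested log-range) and bounds top ∈ [0.5, 1.5], bottom ∈ [0, 1],
hill ∈ [0.3, 5], EC50 within the tested range ± 2 log units. A flat model
competes by AIC; if it wins (flat or rising curves), the fit is flagged
`no_response` and IC50 is undefined rather than extrapolated. The reported
`ic50_abs` is the absolute 50%-of-control crossing, the quantity potency
ranges are quoted in; the relative EC50 (inflection) is also in the
coefficients. The absolute IC50 must fall inside the tested range extended
one log unit, else it is NA.

**Group statistics.** `compare_groups()` is the two-sided Mann-Whitney U
test, with the p-value obtained by full enumeration of rank assignments for
combined n ≤ 12 (the size regime of the patient-group contrasts; 924
assignments at worst) and the tie-corrected normal approximation above
that. `regress_vaf_dss()` is ordinary least squares of score on variant
allele frequency with a t-test on the slope. `anova_tukey()` is one-way
ANOVA on log10 potency (where fold-changes are additive) with Tukey HSD
pairwise adjustment.

## VAF and mutant-allele copy number

`compute_vaf()` is the exact read ratio alt/(alt + ref) (4 decimals);
zero-depth samples are flagged undefined. `infer_allele_copies()` rounds
the VAF to integer percent and bins it: 0 → 0 copies, 1–33% → 1,
34–66% → 2, 67–100% → 3 on a triploid locus. The bins are bounded above by
k/total, so a sample whose true VAF sits exactly at k/total (k < total)
lies on a bin edge: at 2/3, binomial noise at any depth splits calls
between 2 and 3 copies, and rounding decides. The generalization to other
ploidies (copies = ⌈percent · total/100⌉ after rounding) preserves the
triploid ranges exactly and is an extrapolation beyond the setting the rule
was defined for, marked as such in the documentation.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted ground
truth (`sim_config()` + `sim_*()`), which is what the test suite and the
acceptance script run on. The defaults are the study conditions the
generators emulate:

- **Splicing**: 200 events over the five classes (CE, RI, MXE, A5SS,
  A3SS), wild-type Ψ drawn uniformly from [0.2, 0.8], half the events
  planted with |ΔΨ| = 0.3 (sign random, flipped where the unit interval
  would truncate it, so the planted effect is always fully realized), one
  library per condition, and a fixed 200 reads per event — the "mean depth"
  parameter is honored degenerately as a constant because the downstream
  statistics depend only on the per-event totals.
- **Sequences**: exons of 100 nt with 100-nt flanks, uniform A/C/G/T
  background (per-variant background expectation (L−3)/256 ≈ 0.38
  occurrences per 100-nt exon), CCNG planted at 3 motifs/exon in
  increased-inclusion exons and GGNG at 3/exon in decreased ones — about
  a three-fold class-level excess over background, the size of effect the
  enrichment statistics are meant to detect. Planted motifs are Poisson in
  number, rejection-sampled to never overlap each other (keeping truth
  counts unambiguous) and never straddle a splice site.
- **Dose-response**: five concentrations in equal log-steps from 1 nM to
  10 µM (the canonical five-point screening series), three replicate wells
  plus six DMSO wells, 4PL truth (top 1, bottom 0, EC50 0.1 µM, hill 1),
  additive Gaussian noise with sd 0.02 of the control signal on an
  arbitrary luminescence scale so normalization is exercised.
- **Amplicon**: Binomial(10000, VAF) alt reads, the depth regime of
  targeted amplicon sequencing.

Each generator consumes an RNG stream derived from the master seed and a
stable label, so identical configs give byte-identical outputs and adding
one output never perturbs another.

What the simulations do *not* emulate: overdispersion beyond binomial in
junction counts (biological replicates of real clones vary more), mappability
and GC structure in sequence background, plate-position and edge effects in
viability, batch effects, and alignment artifacts. Passing the recovery and
calibration checks therefore demonstrates correctness of the statistics
under their own model assumptions, not robustness to every failure mode of
real data.

## Validation problem sizes

The shipped checks use: 200 events at depth 200 for call recovery; 50
sampled count pairs (depths 10–100) with 10^6 Monte-Carlo draws for the
Bayes-factor cross-check; 400 exons per set for enrichment direction and
800–1000 per set for the planted metagene; 30 replicate null datasets ×
100 positions × 400 bootstrap draws for interval calibration; and 100
noisy curves for EC50 recovery. These sizes were chosen so each check is
decisively powered (3+ standard errors from its pass boundary) while the
whole suite stays desk-scale.

## Known limitations

- The Bayes factor assumes independent uniform priors per condition; an
  empirical-Bayes prior across events would share strength but break the
  per-event reproducibility contract.
- Pooling replicates discards within-condition overdispersion; with many
  libraries per condition a hierarchical model would be preferable.
- Intron-retention events are tested on the same junction-evidence model
  as cassette exons; coverage-based RI quantification is out of scope.
- DSS absolute values are implementation-specific across the published
  variants; compare orderings, not magnitudes, across implementations.
- The copy-number rule is a deterministic binning of a point estimate; it
  does not propagate the binomial uncertainty of the VAF.

```{r example, eval = FALSE}
# end-to-end run on synthetic data
report <- run_pipeline(sim_config(seed = 1), out_dir = "splicedose_out")
```
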