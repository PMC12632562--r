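# splicedose

Hotspot mutations in the splicing factor SRSF2 (P95H/L/R), recurrent in
myeloid leukemias, shift the protein's RNA-binding preference from
GGNG-class toward CCNG-class exonic splicing enhancer motifs. That single
biochemical change has two measurable consequences in cell models and
patient samples: genome-wide shifts in cassette-exon inclusion, and
increased sensitivity to inhibitors of the ATR–CHK1–WEE1 replication
checkpoint. `splicedose` is an R package for quantifying both, written for
computational biologists analysing isogenic-clone RNA-seq and ex vivo
drug-screen data — and for anyone who wants the underlying statistics
(Bayes-factor differential PSI, motif metagenes with bootstrap bands,
DSS/GR/IC50 scoring) as tested, reusable functions.

Everything operates on plain data frames and returns tibbles, so stages
chain with the pipe; a seeded synthetic-data generator with planted ground
truth makes every stage testable without external data.

## What it computes

**Differential splicing.** Per-sample inclusion Ψ of an event with
inclusion/exclusion junction counts *k*, *m* is modelled as
Beta-Binomial: Ψ | data ~ Beta(k + a, m + b). Differential inclusion
between mutant and wild-type is tested with a Savage–Dickey Bayes factor:
under independent Uniform(0,1) priors the prior density of ΔΨ at 0 is 1,
so

&nbsp;&nbsp;&nbsp;&nbsp;BF₁₀ = 1 / p(ΔΨ = 0 | data) = 1 / ∫ f_mut(ψ) f_wt(ψ) dψ,

evaluated deterministically on a grid (a mixture importance-sampling
Monte-Carlo route provides an independent cross-check). Events are called
at |ΔΨ| ≥ 0.10 and BF ≥ 5, summarized by event class (CE, RI, MXE, A5SS,
A3SS) and by mutant-allele-dosage groups.

**ESE motif enrichment.** Counts of the 16 SSNG 4-mer variants
(S ∈ {C,G}) in exons with increased vs decreased inclusion; mean
enrichment = (count_inc + 1)/(count_dec + 1) per variant or per S-S class,
and positional metagene profiles log₂(inc/dec) around both splice sites
with percentile-bootstrap 95% bands.

**Dose-response.** DMSO normalization; drug sensitivity score
DSS = 100·A/((100−t)(log₁₀Cmax−log₁₀Cmin)) with A the thresholded
inhibition area over log-concentration; growth-rate-corrected
GR(c) = 2^(log₂(x/x₀)/log₂(x_ctrl/x₀)) − 1 with GR₅₀ from a bounded
sigmoid fit; bounded-parameter 4PL fits with absolute IC₅₀; Mann–Whitney
(exact by enumeration for small groups), VAF-vs-DSS regression, and
one-way ANOVA with Tukey correction.

**Genotyping.** VAF from amplicon ref/alt counts and mutant-allele copy
number on a triploid locus by the integer-percent bins 0 | 1–33 | 34–66 |
67–100 → 0/1/2/3 copies.

## Worked example

```r
library(splicedose)

cfg <- sim_config(n_events = 200, delta_psi = 0.3, read_depth = 200, seed = 101)
sim <- sim_splicing(cfg)
calls <- diff_splicing(sim$counts, sim$samples, events = sim$events)
dplyr::filter(calls, significant) |> head(3)
#> # A tibble: 3 × 8
#>   event_id event_class psi_wt psi_mut delta_psi bayes_factor significant direction
#>   <chr>    <chr>        <dbl>   <dbl>     <dbl>        <dbl> <lgl>       <chr>
#> 1 EV00002  CE           0.317   0.644     0.327   501979370. TRUE        increased
#> 2 EV00011  A3SS         0.807   0.495    -0.312   601439568. TRUE        decreased
#> 3 EV00012  CE           0.475   0.228    -0.248      126827. TRUE        decreased

summarize_by_class(calls, sim$events)
#> # A tibble: 5 × 3
#>   event_class n_increased n_decreased
#>   <chr>             <int>       <int>
#> 1 CE                    9          13
#> 2 RI                    8          11
#> 3 MXE                  10          13
#> 4 A5SS                  7           8
#> 5 A3SS                 12          10
```

Each significant row is an event whose posterior-mean inclusion moved by at
least 10 percentage points between conditions with a Bayes factor of at
least 5 — e.g. `EV00002` gains ~33 percentage points of inclusion in the
mutant with overwhelming evidence. The class table counts significant calls
by event type and direction; with the default generator settings
(planted effects in half the events, uniform over classes and signs) calls
spread roughly evenly, mirroring how real mutant-vs-control comparisons are
summarized.

Dose-response scoring on a simulated five-point curve:

```r
curve <- normalize_viability(sim_dose_response(sim_config(seed = 2))$viability)
compute_dss(curve)
#> # A tibble: 1 × 7
#>   sample_id drug    dss activity_threshold log10_cmin log10_cmax n_conc
#>   <chr>     <chr> <dbl>              <dbl>      <dbl>      <dbl>  <int>
#> 1 S001      drugA  46.4                 10         -9         -5      5
glance(fit_4pl(curve))
#> # A tibble: 1 × 7
#>       ic50_abs         ec50  hill no_response     rss   aic     n
#>          <dbl>        <dbl> <dbl> <lgl>         <dbl> <dbl> <int>
#> 1 0.0000000935 0.0000000926  1.04 FALSE       0.00277 -121.    15
```

A DSS of 46 on the 0–100 scale marks a clearly active drug; the fitted
absolute IC₅₀ of ~0.94e-7 M recovers the planted EC₅₀ (0.1 µM) to within
a few percent on this noisy five-point curve.

The whole pipeline, end to end, with provenance sidecars and a JSON run
report:

```r
report <- run_pipeline(sim_config(seed = 1), out_dir = "splicedose_out")
```

A thin CLI wrapper with the same stages ships in `inst/cli/splicedose`.

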