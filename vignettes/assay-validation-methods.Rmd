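---
title: "Validating and monitoring a somatic hotspot panel: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and monitoring a somatic hotspot panel: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayqc)
```

Clinical laboratories that run amplicon-based somatic variant panels (50-gene
hotspot assays on benchtop sequencers, typically from 1–10 ng of FFPE DNA)
must characterize the assay before use — expected allele frequencies of
engineered control mixtures, the limit of detection, run-acceptance metric
cutoffs, concordance with the single-gene assays being replaced — and then
monitor every clinical run against a characterized quality-control material.
`assayqc` implements that workflow end to end, together with a seeded
binomial read-count simulator so every stage can be exercised and tested
without sequencing data. This vignette records the models, the tunable
parameters, and the design decisions taken where published practice leaves
the details open.

## Mixture expectations

Control materials are built by mixing DNA from characterized cancer cell
lines (here colon HCT116, pancreatic MIA-PaCa-2, lung H1975, melanoma
SK-MEL-28, with normal placental DNA as a diluent). If component $i$ enters
the mixture with DNA mass fraction $w_i$, carries the variant at allele
frequency $f_i$ (percent) and contributes templates at the locus with copy
weight $\hat c_i$, the expected variant allele frequency (VAF) of the mix is

$$E[f] \;=\; \frac{\sum_i w_i\, \hat c_i\, f_i}{\sum_i w_i\, \hat c_i}.$$

Design decisions behind this formula:

* **Copy weights are binary.** $\hat c_i = 1$ for a copy-neutral locus and
  $0$ for a homozygous deletion (the line contributes no DNA there, which
  *raises* the expected VAF of the remaining carriers). MIA-PaCa-2's
  homozygous *CDKN2A* deletion is the motivating case: a homozygous
  *CDKN2A* variant diluted into MIA-PaCa-2 stays at 100 % at any mixing
  ratio, because every template present carries it. Extension to arbitrary
  integer copy numbers would only change $\hat c_i$; it is deliberately out
  of scope because mass-fraction mixing of near-diploid lines reproduces
  the characterization tables without it.
* **Absent means wild type.** A locus missing from a component's profile is
  frequency 0 at normal copy state, so wild-type components dilute the
  expectation — this is what makes an equal four-line mix of a single
  heterozygous carrier (e.g. 52.4 %) come out at 13.1 %.
* **A "1:k" serial dilution is mix fraction $1/k$**, i.e. the mix ends up
  as one part in $k$ total. This convention reproduces the diluent-borne
  germline expectations (55.8 % diluted 1:2 gives 27.9 %, 1:3 gives
  37.2 %); the union of loci includes variants private to the diluent, so
  germline SNPs of the diluent appear and rise toward their pure frequency
  as dilution increases.
* **Reporting rounds half-to-even to one decimal** (`round_pct()`, base R
  `round()`); all internal arithmetic is full precision. A small number of
  published expected cells in this field round half up or were computed
  from unrounded instrument values; the package does not chase individual
  rounding artifacts.

The test suite checks this model two ways: exact reproduction of the
characterization tables shipped with the package, and agreement with a
brute-force template-sampling oracle (draw $10^6$ templates, choose a
component with probability $\propto w_i \hat c_i$, then a variant allele
with probability $f_i/100$) within three Monte-Carlo standard deviations
across random mixtures.

## Limit of detection

The LoD procedure mirrors standard dilution-series practice: replicate
libraries at each nominal expected VAF, a call-acceptance policy
(`call_policy()`: minimum depth 200, minimum quality 300, maximum strand
bias 0.79, minimum frequency 4 %, all inclusive bounds), and per-level
detection rates. `estimate_lod()` returns the smallest level whose
detection rate meets the required rate (default 1.0, i.e. detected in
100 % of replicates) *and* whose every higher level also meets it; the
second clause prevents a non-monotone series — sampling noise can produce
one — from returning a spuriously low LoD. With the published replicate
rates (90 % detection near 3 %, 100 % at and above 4 %) the estimator
returns 4 %.

Note that a 4 % frequency threshold applied to a variant whose true VAF is
exactly 4 % is a coin flip: at depth 2000 the exact binomial tail
$P(\hat f \ge 4\,\% \mid p = 0.04, d = 2000)$ is about 0.52, and the
simulator reproduces this (it is one of the package's calibration checks).
Observed 100 % detection at the 4 % level therefore implies the caller's
internal detection threshold sits below the reporting threshold; the
package keeps the two ideas separate (simulator emits everything, the
policy gates detection).

`linearity()` (ordinary least squares of observed on expected plus Pearson
r) is the companion check that a dilution series tracks the equality line.

## Run-acceptance cutoffs

Historical run metrics (per-base coverage, Q20 base counts, call quality,
strand bias) are summarized as $\bar x \pm z\,s$ bounds on a scale where
the metric is acceptably normal. `derive_cutoff()`:

* gates raw samples with the Shapiro–Wilk test (`stats::shapiro.test`,
  $\alpha = 0.05$); with `transform = "auto"` it falls back to the log10
  scale — call quality is the canonical case of a metric that is lognormal
  rather than normal — and records the transform in the rule;
* accepts summary statistics directly (skipping the gate), because
  published characterizations often state only mean and SD;
* takes `z` explicitly or derives it from a confidence level (two-sided by
  default). `z` is explicit-first because published cutoff tables mix
  conventions (two-sided 1.96 at 95 %, one-sided 2.326 at 99 %) and a rule
  must reproduce the bound actually in force;
* carries a per-rule rounding policy (nearest integer, significant
  figures, decimals) since reported cutoffs mix all three.

Bounds are inclusive — a run exactly at its cutoff passes — so the
historical mean itself always passes its own rule. `evaluate_run()` reports
a per-rule verdict with an explicit `MISSING` state (missing metric fails
the run) and `write_cutoff_json()` round-trips rule sets through the JSON
parameter files variant-caller plugins consume.

## Concordance with orthogonal assays

`score_concordance()` scores per *sample* over the queried gene set: a
sample is reference-positive if any queried gene is positive in the
single-gene results, test-positive if any panel call in those genes passes
the active policy. This per-sample accounting is the reading under which a
55-specimen comparison with one discordant sample yields 96.7 % sensitivity
(29/30) and 100.0 % specificity (25/25); the discordant case is a variant
present below the 4 % policy threshold, which scores — correctly — as a
false negative of the panel, not as a missing sample. An `hgvs_level` mode
additionally requires the coding change to match, for stricter audits.
`correlate_frequencies()` handles replicate and paired-material
comparisons; absent-in-one variants default to 0 % (`union_zero_fill`)
because paired scatter plots of call sets legitimately include near-zero
points, with an `intersection` mode available.

## Artifact flagging

Three independent, individually configurable predicates annotate recurrent
false or non-somatic calls: germline SNPs with global minor allele
frequency above 0.01 (the common-SNP convention; thresholds are
configuration, not claims), calls within 5 bp of every covering amplicon
boundary (`END_OF_AMPLICON`; positions covered by no amplicon get
`OFF_TARGET` instead), and calls within or adjacent to a reference
homopolymer run of length at least 4 — the characteristic error mode of
semiconductor sequencing. Run lengths 4 and 5 bp edge distance are package
defaults chosen where published practice names the classes but not the
parameters. `apply_blacklist()` flags exact variant keys from a curated
list without destroying data: flagged calls keep all fields and only leave
the `reportable()` view.

## QC-material monitoring

`characterize_baseline()` establishes per-variant mean, sample SD (n−1
denominator, standard clinical-QC practice), CV and ±2SD/±3SD limits from
at least 10 consecutive runs of the QC material (a run missing any
expected variant is excluded and reported — an incomplete run is evidence
of a problem, not data). `lj_evaluate()` bands each monitored run's
deviation $(x - \bar x)/s$: within 2SD in control, 2–3SD warning (1~2s~),
beyond 3SD reject (1~3s~); an expected variant absent from a run rejects
the run outright. `lj_series()` assembles the Levey-Jennings chart table
(plot method included) and optionally applies the Westgard multi-rules
2~2s~ (two consecutive excursions beyond the same 2SD limit) and R~4s~
(consecutive deviations spanning more than 4 SD) as advisory flags; rules
beyond the 2SD/3SD bands are opt-in because routine monitoring of this
material uses the plain bands.

A statistical point worth recording: control limits **estimated** from
$n = 10$ baseline runs do not give the textbook 0.27 % false-rejection
rate. The monitored deviation behaves like $\sqrt{1 + 1/n}\,t_{n-1}$, so
with $n = 10$ the per-evaluation probability of exceeding "3SD" is about
1.9 % — estimation error roughly doubles the nominal false-alarm rate.
The package's calibration checks therefore separate the two questions:
control-*rule* calibration is tested against analytically derived limits
(true means, binomial SD at the nominal depth, with the simulator's depth
pinned at that nominal value so the analytic SD is exactly the generative
SD), where the measured false-alarm rate is well under 1 % and a +3.5 SD
mean shift is flagged within one run of its changepoint in essentially
every replicate; baseline-*estimation* quality is tested as parameter
recovery (estimated means within 3 standard errors of truth in ≥95 % of
simulated characterizations). Laboratories wanting the nominal error rate
in routine use should either extend the baseline beyond 10 runs or accept
the modest inflation.

## The simulator: what it emulates, and what it does not

`simulate_run()` draws per-locus depth (lognormal, CV 0.3 by default;
negative binomial available), binomial alternate-read counts at the true
VAF adjusted by a per-read error rate, lognormal per-call quality (log10
mean 3.65, SD 0.45) and truncated-Gaussian strand bias (0.7 ± 0.04), and
Gaussian run-level metrics. Presets encode the two library types the
package targets: `"frozen"` at mean depth 2000 and `"ffpe"` at 1300 with
C:G>T:A deamination artifacts injected at 1–3 % VAF at 2 % of susceptible
sites per run — deliberately below the 4 % policy so FFPE noise does not
perturb detection statistics. The depth means are the realistic operating
points for barcoding seven libraries on one chip; the *spread* (CV 0.3)
and the artifact rates are modelling choices stated here as such, since
per-locus depth distributions are rarely published. All randomness flows
from a mandatory seed with per-run sub-streams, so identical configurations
are bit-for-bit reproducible.

What the simulator does **not** model — and therefore what passing tests do
not demonstrate about real data: PCR amplification bias and
amplicon-specific depth structure, sequence-context error models
(homopolymer length effects are flagged downstream, not generated),
read-level artifacts requiring alignment, library-preparation inter-run
variability beyond the binomial floor (real QC materials show CVs above
the binomial prediction; the baseline machinery estimates whatever
variance is present, but the simulator's runs are binomially tight), and
tumor heterogeneity. The package validates the *statistical machinery* of
assay QC; it does not substitute for wet-lab verification of any
particular assay.

## Numerical and degenerate-input conventions

Frequencies are percent (0–100) end to end; VCF fractions convert at the
boundary. Positions are 1-based internally; BED input (0-based half-open)
converts on read and back-converts exactly on write. Zero baseline SD with
a discrepant observation maps to an infinite deviation and rejection
(never NaN). Zero-depth simulated loci are emitted as explicit `NO_DEPTH`
calls rather than dropped. Cutoff ties pass. Degenerate correlation inputs
(fewer than 3 points, zero variance) are errors, not NA propagation. The
mixture formula refuses loci where every component is deleted ("no
template"), naming the locus.

## Problem sizes used in the shipped checks

The package's own test battery runs at desk scale, chosen so the full
suite completes in well under a minute while keeping every statistical
assertion comfortably powered: 50 random mixtures against a $10^6$-template
oracle; 100 seeded QC characterizations of 8 variants × 10 runs for
parameter recovery; 100 null runs and 100 drift replicates for
control-chart calibration; 20 seeds × 10 replicates for the binomial-tail
detection check; 1000 loci for simulator SD calibration.
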