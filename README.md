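# assayqc

Validation and routine run quality control for amplicon-based somatic
hotspot sequencing panels — the workflow a clinical laboratory runs when it
brings a multi-gene NGS assay (e.g. a 50-gene cancer hotspot panel on a
benchtop sequencer) into service and then keeps it in control with an FFPE
quality-control material sequenced in every run.

## What it computes

**Mixture expectations.** Control materials are DNA mixtures of
characterized cell lines. With mass fractions $w_i$, per-line allele
frequencies $f_i$ (percent) and copy weights $\hat c_i$ (1 for a
copy-neutral locus, 0 for a homozygous deletion), the expected variant
allele frequency is

$$E[f] = \frac{\sum_i w_i \hat c_i f_i}{\sum_i w_i \hat c_i},$$

with serial "1:k" dilution into a characterized diluent handled as a
two-component mixture at fraction $1/k$. The copy-aware weights matter:
a homozygous variant diluted into a line that has the locus deleted stays
at 100 % at any ratio.

**Limit of detection.** Replicate detection rates per nominal VAF level
under a call-acceptance policy (depth ≥ 200, quality ≥ 300, strand bias
≤ 0.79, frequency ≥ 4 %), and the LoD as the smallest level detected at
the required rate (default 100 %) with every higher level also passing.

**Run-acceptance cutoffs.** $\bar x \mp z s$ bounds on historical run
metrics, with a Shapiro–Wilk normality gate and automatic log10 fallback
(call quality is lognormal), per-rule rounding policy, inclusive-bound run
evaluation, and JSON round-tripping of the rule sets.

**Concordance and artifacts.** Per-sample sensitivity/specificity against
orthogonal single-gene assay results, Pearson correlation of paired call
sets, and independent artifact predicates (high-MAF germline SNP,
amplicon-edge, homopolymer) plus a non-destructive blacklist.

**Levey-Jennings monitoring.** Per-variant baseline (mean, SD, CV,
±2SD/±3SD limits) of the QC material over ≥10 runs, per-run control status
(in control / 2SD warning / 3SD reject / missing variant), chart tables
and plots, and opt-in Westgard 2~2s~/R~4s~ multi-rules.

**Simulator.** A seeded binomial read-count simulator (lognormal depth,
FFPE deamination-artifact preset, run-metric models) generates profiles,
runs, dilution series and drift scenarios so the whole pipeline is
testable without sequencing data.

## Worked example

```r
library(assayqc)

## expected VAFs of the equal four-line validation mixture
profiles <- validation_profiles("frozen")
mix      <- equal_mix()
expected <- mixture_profile(profiles[profiles$line != "PLACENTA", ], mix)
expected
#> <expected VAF profile> 37 locus/loci
#>    chrom      pos ref alt gene vtype expected_pct
#> 1  chr10 43613843   C   T  RET   SNV         41.5
#> 2  chr10 43615612   A   G  RET   SNV         11.3
#> ...

## a 1:2 dilution into placental DNA halves the distance to the diluent --
## its germline ATM variant (55.8 %) appears at 27.9 %
diluted <- serial_dilute(expected, profiles[profiles$line == "PLACENTA", ], 1/2)
round_pct(diluted$expected_pct[diluted$pos == 108138003])
#> [1] 27.9

## run-acceptance cutoffs from historical metric summaries
rules <- shipped_cutoff_rules()
rules
#> <cutoff rules> 4 rule(s)
#> <cutoff> coverage: lower bound 200 (= 1231 - 1.96 * 526)
#> <cutoff> q20_bases: lower bound 2e+07 (= 2.5e+07 - 1.96 * 2.4e+06)
#> <cutoff> quality_log10: lower bound 300 (= 3.65 - 2.576 * 0.45, log10 scale)
#> <cutoff> strand_bias: upper bound 0.79 (= 0.7 + 2.326 * 0.04)
evaluate_run(list(coverage = 1850, q20_bases = 2.4e7,
                  quality_log10 = 4100, strand_bias = 0.71), rules)
#>         metric    value  side   bound verdict
#>       coverage 1.85e+03 lower 2.0e+02    PASS
#>      q20_bases 2.40e+07 lower 2.0e+07    PASS
#>  quality_log10 4.10e+03 lower 3.0e+02    PASS
#>    strand_bias 7.10e-01 upper 7.9e-01    PASS
#> overall: PASS

## concordance with single-gene assay results for 55 clinical specimens
score_concordance(clinical_calls(), clinical_reference(),
                  genes = c("KRAS", "EGFR", "BRAF"))
#> <concordance> 55 samples over genes KRAS/EGFR/BRAF (gene_level)
#> TP FP TN FN
#> 29  0 25  1
#> sensitivity 96.7 %, specificity 100.0 %

## characterize a simulated QC material over 10 runs, then monitor run 11
truth <- qc_truth()
qc_profile <- expected_profile(data.frame(truth[, 1:5],
                                          expected_pct = truth$mean_pct))
cfg   <- simulator_config(seed = 1, preset = "ffpe")
runs  <- simulate_runs(qc_profile, cfg, 10)
baseline <- characterize_baseline(lapply(runs, `[[`, "calls"), truth)
new_run  <- simulate_run(qc_profile, cfg, seed = 99, run_id = "clinical_run_11")
lj_evaluate(new_run$calls, baseline)
#>  chrom       pos  ref alt   gene vtype mean_pct sd_pct observed_pct deviation_sd      status
#>   chr7 140453136    T   A   BRAF   SNV    17.83   0.86        19.38         1.80  IN_CONTROL
#>   ...
#>   chr3 178952085    A   G PIK3CA   SNV     8.81   0.47        10.04         2.58 WARNING_2SD
#>   chr3  41266134 ACTT   A CTNNB1   DEL    11.97   0.92        11.54        -0.46  IN_CONTROL
#> run verdict: accept
```

The sensitivity of 96.7 % is 29/30 reference-positive samples: the single
discordance carries its variant below the 4 % frequency policy, so it
scores as a false negative of the panel. The Levey-Jennings verdict accepts
the monitored run because no variant exceeds 3SD and none is missing; the
2.5SD excursion is a 1~2s~ warning, not a rejection.

A thin CLI mirrors these stages
(`assayqc expect|lod|cutoffs|run-check|baseline|monitor|concordance|flag|simulate`,
see `inst/exec/assayqc`).

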