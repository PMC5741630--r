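# rayregen

Quantitative analysis of zebrafish fin-ray regeneration scored ray by ray.

## The problem

When regeneration of an amputated zebrafish fin is transiently blocked
(e.g. by inhibiting FGF or Wnt/β-catenin signaling), the fin becomes
"dormant": rays keep the competence to regenerate but do not resume growth
on their own. Re-injuring individual rays of such dormant fins — even with
minor epidermal or skin wounds that remove no skeletal tissue — can
re-initiate regeneration, and non-injured rays lying next to regenerating
rays frequently start growing too ("bystander regeneration").

Two statistical questions follow, and this package answers both from a
plain table of scored rays:

1. **Do wounded rays regenerate more often than non-injured ones?**
   Group regeneration fractions compared with a Pearson χ² test on a 2×2
   table.
2. **Is the growth of non-injured rays spatially clustered along the fin,
   or could it be spontaneous and independent?** Each analyzed ray is coded
   1 (growth) or 0 (no growth); a regenerating ray whose existing neighbors
   are all 0 is an *isolated* regenerator (the "010" pattern), and its
   complement is a *bystander*. The observed isolated frequency is compared
   with a Monte Carlo null built from N random rearrangements of the same
   multiset of 1s and 0s, with

   p = (r + 1) / (N + 1),

   where r is the number of rearrangements with an isolated frequency
   strictly lower than the observed one. Low p means regenerating rays
   cluster next to each other more than chance allows.

The package also implements the scoring protocol's eligibility rules
(escapers — uninjured rays in which the blockade failed — are excluded, as
is any ray directly adjacent to an escaper, a re-amputated, or an
epidermally wounded ray), a closed-form expectation of the isolated
frequency under random arrangement (an analytic cross-check of the null),
and a synthetic-data generator with a nearest-neighbor contagion model so
that every stage — filters, encoding, statistics, test — can be validated
against ground truth.

## Worked example

Simulate a cohort of 61 fish under the default contagion model, then run
the full analysis (the CLI wraps `cmd_simulate()` / `cmd_analyze()`; the
same can be done in R):

```sh
Rscript inst/cli/rayregen simulate --seed 11 --out demo
Rscript inst/cli/rayregen analyze --input demo/rays.tsv \
    --iterations 10000 --seed 11 --out demo_report
```

`demo_report/analyze_report.txt`:

```
ray regeneration report (schema 1.0)
input: rays.tsv (md5 de4bbebf6669d31d3ac2e28d7dfce3b6)
outcome: regen_7dpi

group regeneration fractions:
  noninjured       249/876 regenerating (28.4%)
  epidermal_wound  50/61 regenerating (82.0%)

chi-square comparisons:
  epidermal_wound_vs_noninjured X2 = 75.245, df = 1, p = 4.16e-18

bystander fraction: 96.4% of 249 regenerating rays

Monte Carlo clustering test:
  observed isolated freq 0.0361, null mean 0.5699
  N = 10000, r = 0, ties = 0, p = 9.999e-05 (mode pooled)
```

Reading the numbers: 28.4% of analyzable non-injured rays regenerated, but
82.0% of epidermally wounded rays did (χ² p ≈ 4×10⁻¹⁸) — wounding induces
regeneration. Among the regenerating non-injured rays, 96.4% grew next to
another regenerating ray; only 3.6% were isolated, against a null
expectation of 57% isolated, so no random rearrangement came close and the
permutation p-value is at its floor, 1/10001.

The test can also be replicated from summary counts alone — the composition
of the analyzed list (e.g. 142 regenerating / 409 not) and the observed
isolated frequency:

```sh
Rscript inst/cli/rayregen mc-test --ones 142 --zeros 409 \
    --observed 0.05 --iterations 10000 --seed 1
# observed isolated ('010') frequency: 0.0500
# null mean: 0.5533 (N = 10000 iterations, mode = pooled)
# r (null < observed): 0; ties: 0
# p = (r + 1)/(N + 1) = 9.999e-05
```

## Package layout

- `R/ray_records.R` — ray-score table format, validation, TSV/CSV I/O
- `R/eligibility.R` — escaper flagging and the exclusion rules defining
  analyzable rays
- `R/adjacency.R` — binary encoding, isolated/bystander statistics,
  neighbor-association rate, regeneration fractions, χ² tests
- `R/monte_carlo.R` — permutation null, closed-form expectation,
  (r+1)/(N+1) p-value, end-to-end clustering test
- `R/synthetic_data.R` — contagion-model generator with ground-truth
  labels, power/size sweeps
- `R/cli.R`, `inst/cli/rayregen` — orchestration and command-line entry
  points
- `vignettes/bystander-regeneration.Rmd` — model, assumptions, design
  choices, limitations
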