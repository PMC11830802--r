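# vntrproxy

Toolkit for linking a polymorphic intronic variable number tandem repeat
(VNTR) to nearby GWAS SNPs, built around the *TERT* intron 6 VNTR
(38-bp unit; Short alleles 24–27 copies, Long alleles 40.5–66.5 copies).
The locus is invisible to standard short-read genotyping, so working with
it requires a chain of proxies: repeat counting on long reads, a
read-depth classifier for short-read cohorts, a two-SNP tag haplotype,
and a biallelic pseudo-marker for imputation. `vntrproxy` implements that
entire chain, the downstream molecular readouts (splice-junction event
classification, G-quadruplex scoring) and the association layer, together
with a seeded synthetic-data generator so every stage can be validated by
parameter recovery.

## What it computes

- **Repeat decomposition** — `count_repeat_copies()` tiles a known unit
  greedily from the best-matching seed (copies at 0.5 resolution,
  Hamming-mismatch budget per window, terminal half-copy detection);
  `infer_repeat_unit()` finds the period p maximizing the self-agreement
  `mean(s[i] == s[i+p])` and reports the per-column majority consensus in
  the array's phase. `classify_allele()` binarizes at 34 copies (the
  midpoint of the empirical 27 → 40.5 gap); `check_mendelian()` verifies
  trio transmission.
- **Coverage classifier** — median read depth in consecutive 50-bp
  windows over the 2290-bp VNTR interval, flank-normalized, fed to an
  L2-regularized logistic model (damped IRLS, gradient norm < 1e-8,
  seeded k-fold cross-validation) that separates Short/Short from
  Long-carrier samples. Depth in the repeat scales with
  (c1 + c2) / (2 · 27), the combined copy number over the reference.
- **Tag haplotype** — MAF > 5% screen, per-marker chi-square scan of
  phased haplotype counts against the Short/Long class (χ² = n·r² on 2×2
  tables), then an exhaustive pair search maximizing Cohen's kappa; the
  winning single haplotype (rs56345976-A/rs33961405-G in the default
  panels) maps to Long, all others to Short. `ld_r2()` gives
  D²/(pA qA pB qB) from haplotype counts.
- **Imputation** — the binarized VNTR becomes a biallelic S/L
  pseudo-marker at chr5:1,275,400 in a phased reference panel;
  `impute_biallelic()` copies it into targets by k-nearest-haplotype
  voting (Hamming distance over a marker window, exp(−d) weights), scored
  by genotype concordance and the chance-corrected IQS
  (Po − Pc)/(1 − Pc).
- **Splice quantification** — exon4–exon5 junction reads classified by
  coordinate rules into canonical, INS1 (donor 38 bp into intron 4),
  INS1b (480 bp) and unspliced (≥ 20 bp intrusion); sub-threshold reads
  are excluded from totals. Plus intron-retention and gel-densitometry
  full-length-fraction helpers.
- **G-quadruplex scoring** — run-length per-base scores (G-run of length
  k scores +min(k, 4), C-runs negative), sliding window means, and
  threshold-merged tract calls.
- **Association models** — additive dosages, VNTR/SNP haplotype counts
  (Short-C reference), OLS and logistic fits with covariates, conditional
  fits, genotype × 5-year-age-group interactions, permutation p-values,
  exact/approximate Wilcoxon–Mann–Whitney tests, and the CFSE doublings
  formula −ln(final/start)/ln 2.

## Worked example

`run_demo()` exercises the full chain on synthetic data under one seed:

```r
library(vntrproxy)
metrics <- run_demo(seed = 1, out_prefix = "demo")
```

which writes `demo_report.txt`:

```
vntrproxy demo (seed 1, 600 individuals)
repeat counting: 27-copy allele -> 27.0 copies; 40.5 -> 40.5; inferred period 38 bp
coverage classifier CV: AUC 1.000, sens 1.000, spec 1.000
tag pair rs33961405/rs56345976: kappa 0.973, agreement 0.993
LD r2 with VNTR: rs2242652 0.685, rs10069690 0.476
imputation: concordance 0.9933, IQS 0.9847
splice fractions: canonical (CC) 68.4%, INS1b (TT) 6.9%
G4 tracts: 24 copies -> 1, 66.5 copies -> 1
expression model Long-T beta -15.02 TPM; rLTL Short-C beta -0.0558 (p_int 0.988)
```

Reading the lines in order: the repeat counter recovers the synthesized
copy numbers exactly and the de novo inference finds the 38-bp unit; the
depth classifier separates Long carriers cleanly under cross-validation;
the exhaustive pair search recovers the planted rs56345976/rs33961405 tag
haplotype with kappa 0.97; the generator reproduces its LD targets
(0.62/0.48) within sampling error; half-panel imputation of the
pseudo-marker reaches 99.3% concordance; the junction-read classifier
recovers the configured canonical (CC) and INS1b (TT) mixtures; tract
counts are reported for a Short and a Long allele; and the regression
layer returns the haplotype effect estimates for this seed, with their
sampling noise (the generating values are −24.18 TPM and −0.049).

A command-line wrapper for the common one-off tasks lives at
`inst/cli/vntrproxy.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vntrproxy.R", package = "vntrproxy"))')" \
  count-repeats --fasta alleles.fa --out calls
```

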