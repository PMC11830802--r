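---
title: "Methods: proxying an intronic VNTR with tags, depth profiles and imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proxying an intronic VNTR with tags, depth profiles and imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrproxy)
```

## The problem

The *TERT* intron 6 VNTR is a 38-bp tandem repeat whose alleles fall into
two well-separated classes — Short (24–27 copies) and Long (40.5–66.5
copies). The Long class travels with the intron 4 GWAS alleles
rs2242652-A (r² ≈ 0.62 in European-ancestry panels) and rs10069690-T
(r² ≈ 0.48), and the repeat itself expands a G-quadruplex-forming array
implicated in *TERT* splicing. Because the repeat cannot be genotyped
from short reads directly, analyses proceed through proxies: repeat
counting on long-read sequence, a read-depth classifier, a two-SNP tag
haplotype, and imputation of a biallelic pseudo-marker. This vignette
records how each stage is modeled here, the parameters that matter, and
the design choices that were genuinely open.

## Synthetic data: what is emulated

Every input is generated in-package from explicit seeded configurations;
no external data are consumed.

**Haplotype panels.** A `population_config` couples VNTR allele classes
(copy number, frequency) with SNP allele frequencies and pairwise LD
targets. Haplotypes are drawn hierarchically: first the VNTR copy number
from its class frequencies, then each SNP allele conditional on the
haplotype's Short/Long class using the four-haplotype table solved from
(p~Long~, p~alt~, r²): with D = sqrt(r² · p~L~ q~L~ p~B~ q~B~),
P(alt | Long) = p~B~ + D/p~L~ and P(alt | Short) = p~B~ − D/q~L~.
Targets above the algebraic maximum
D~max~ = min(p~L~ q~B~, q~L~ p~B~) are rejected at configuration time
with the feasible bound. Because each SNP is conditioned on the VNTR
only, the configured pairwise LD with the VNTR is matched exactly in
expectation, while SNP–SNP LD is whatever the shared dependence induces.
This is deliberately simpler than a coalescent model: the studies this
package mirrors report pairwise r² with the VNTR, and that is the
quantity the generator controls. No recombination is modeled within the
interval, which is also what makes the trio generator's Mendelian check
exact.

The `ceu_population()` preset splits the 83.3% Short mass 0.25/0.30/0.45
over 24/25.5/27 copies so the Short-class mean is 25.8; Long is a single
40.5-copy allele at 16.7%. The `yri_population()` preset puts 80% on
Short (mean 27.0) and 20% on Long with the 66.5-copy allele at 2.5%
population frequency, giving the Long-class mean of 43.75. LD targets for
the tag pair are set high (0.92) in the European-like preset — the tag
haplotype is a near-perfect proxy there — and lower (0.6) in the
African-like preset, where all four VNTR/rs10069690 haplotypes are
common; cohort simulations that need the full haplotype design (e.g. the
tumor-expression cohort) therefore draw from the African-like preset.

**Sequences.** `synthesize_vntr_allele()` concatenates exact unit copies
(a fractional .5 copy is the first 19 bases of the unit, consistent with
the 40.5/66.5 allele naming; the source material does not state which
half) between fixed 300-bp non-repetitive flanks, then applies i.i.d.
substitutions at a configurable rate. The flanks are fixed rather than
random so sequence fixtures are reproducible without extra seeds; they
are built with no G-runs (so they contribute no G4 signal), no
periodicity in the 10–60 bp range, and boundary bases that differ from
the unit's terminal bases — without that last property the array phase
would be genuinely ambiguous by one base (see below).

**Coverage.** Per-base depth over the 2290-bp interval is drawn
negative-binomially with mean `mean_depth` outside the repeat and
`mean_depth · (c1 + c2)/(2 · 27)` inside it (27 = reference copies),
variance μ + φμ²; the profile is the median within consecutive 50-bp
windows, matching how depth profiles are extracted from alignments with
windowed-median tools. Dispersion φ defaults to 0.1; no noise model is
stated for the real data, so this is an assumption, and φ = 0 returns the
noise-free expectation (used by the dosage-ratio tests). Summarizing
medians over per-base draws, rather than drawing one value per window,
matters: the median of 50 overdispersed bases has far less sampling noise
than a single window-level draw, and it is the former that corresponds to
the real pipeline. Per-base depths are drawn independently; real
positional autocorrelation (reads cover ~100 bp) would inflate window
noise somewhat, so the classifier's near-perfect synthetic AUC should be
read as "the windowed-median signal is strong", not as a claim about any
particular real dataset.

**Junction reads.** Reads are aligned-block tuples, not sequences. Each
read's category is multinomial from its genotype's event mixture;
sub-threshold intrusion reads (1–19 bp into the intron) are generated on
top with probability 0.02 and must be excluded by the classifier. The
default mixtures fix canonical at 68.3/63.8/57.3% and INS1b at 0/3.8/7.0%
across CC/CT/TT — the reported per-genotype fractions — while INS1
(3/2.5/2%) and unspliced (the remainder) are free parameters chosen to
respect the reported qualitative trends (INS1 decreasing, unspliced
increasing).

**Cohorts.** Phenotypes are linear: intercept + Σ effect·count +
covariates + Gaussian noise. The tumor-expression default
(`bl_cohort_spec()`) uses n = 78, intercept 59.7 TPM, haplotype effects
−12.2/−15.92/−24.18 TPM (Short-T/Long-C/Long-T vs the Short-C reference),
ages uniform 1–15, residual SD 45 TPM — chosen so single-cohort standard
errors (~10 TPM) match the borderline p-values reported at that sample
size. The telomere-length default (`ukb_cohort_spec()`) uses a Short-C
effect of −0.049 per copy in Z units, an age trend of −0.0025/year, ages
38–73, three smoking categories, residual SD 0.95 — back-calculated so
that the implied standard error at biobank scale reproduces the reported
test statistic's order of magnitude. Gaussian noise and uniform ages are
idealizations; passing recovery tests shows estimator correctness, not
robustness to real residual structure.

## Repeat decomposition

`count_repeat_copies()` anchors at the minimum-Hamming-distance window
(leftmost on ties), then tiles in unit steps both ways. A window counts
as a copy at Hamming distance ≤ 4 (default; ~10% of a 38-bp unit). An
isolated failing window is bridged — counted, with its mismatches charged
to purity — when the next in-phase window passes; without bridging, a
single 5-substitution window (probability ~0.1% per window at a 2% rate)
would truncate the array and the ≤ 0.5-copy accuracy guarantee would fail
for long alleles. Terminal half-copies are detected only at array ends
(leading 19 unit bases on the right, trailing 19 on the left, mismatch
budget ⌊4/2⌋ = 2), which keeps the counter strand-coherent: counting the
reverse complement with the reverse-complemented unit returns identical
copies. A sequence with no full-unit window is scanned once more for a
bare leading half (the 0.5-copy degenerate case); otherwise copies = 0
with an empty span.

`infer_repeat_unit()` scores each candidate period by global
self-agreement, takes the smallest period within 0.02 of the maximum
(this collapses harmonics — a p-periodic array is also 2p-periodic — and
resolves degenerate inputs such as homopolymers to the smallest
admissible period, with a note), then restricts to the longest matched
run (gaps ≤ max(4, p/8) filled, so isolated substitutions do not split
the span but flank noise does not chain into it) and takes per-column
majorities. The consensus phase is canonicalized by greedy tiling: the
array-start rotation tiles one more full copy than any other rotation, so
the rotation maximizing full-copy count (ties: fewer mismatches, then
leftmost) is reported. When noise mutates the array's first or last base,
the phase becomes intrinsically ambiguous — the sequence is equally well
described by a rotation — which bounds round-trip unit recovery at 2%
noise to roughly 97% of replicates; the period is still recovered, and
the tests assert exactly that (period always; unit in ≥ 90% of seeds,
rotations otherwise).

The Short/Long threshold is 34 copies, the midpoint of the empirical
27 → 40.5 gap; the binarization is reported with the threshold used, and
copy numbers inside the gap are flagged `intermediate` rather than
silently classified.

## Coverage classifier

Features are the 46 per-window medians divided by the mean of the windows
fully outside the array (flank normalization — genome-wide depth does not
exist for synthetic profiles). The model is a binomial logistic
regression with an unpenalized intercept and ridge penalty (default 1),
fit by damped Newton iterations with step halving to a gradient norm
below 1e-8 (cap 200 iterations, error on non-convergence). "Multimodal"
descriptions of such classifiers are read as binomial here: the task is
two-class. Cross-validation uses seeded fold assignment and pools
held-out predictions into a single report (sensitivity, specificity, F,
rank-statistic AUC with midrank ties). A 60/40 train/test split utility
is provided to mirror the usual partition. At the study-like operating
point (depth 30, φ = 0.1, n = 600, European-like genotype frequencies)
held-out AUC is ≥ 0.98, mirroring the real-data report.

## Tag haplotype and imputation

The proxy search screens markers at MAF > 5% (strict inequality) and by
per-marker chi-square on phased 2×2 haplotype counts (χ² = n·r², a
property the tests assert), then searches all candidate pairs and all
four haplotype→Long assignments exhaustively, maximizing Cohen's kappa
against the true class; ties break by agreement, then inter-marker
distance, then lexicographic ids. This replaces a random-forest
importance ranking: at the ~1500-marker scale involved, the exhaustive
search is cheap and directly optimizes the quantity the proxy is
validated with, at the cost of never modeling interactions beyond the
pair itself. An unsupervised clustering cross-check of coverage profiles
against haplotypes is subsumed by direct kappa validation against
simulated truth.

Imputation encodes the binarized VNTR as an S/L pseudo-marker at
chr5:1,275,400 and copies it into target haplotypes by k-nearest
reference haplotypes (Hamming distance over the `window` markers nearest
the pseudo-marker position; k = 10, window = 40 by default, clamped and
truncated with warnings), voting with weights exp(−d) and ties broken by
reference order — fully deterministic. A recombination-aware hidden-state
model would be the production choice; the transparent kNN engine keeps
the evaluation desk-scale while preserving what is actually being tested:
the pseudo-marker encoding and its scoring. IQS is implemented as
chance-corrected genotype concordance (the kappa form) over the 3×3
genotype table — the published score it reconstructs is defined by
citation rather than formula in the source material, and the kappa form
is the standard reading. Note that "target = reference implies
concordance 1" holds when the window's marker haplotypes determine the
VNTR class (the regime the invariant describes); with very few markers,
colliding SNP haplotypes of opposite class put an intrinsic ceiling below
1 regardless of engine.

## Splice quantification

Local coordinates put 0 at the exon 4 donor; intron 4 occupies [0, L)
with cryptic donors at 38 (INS1) and 480 (INS1b) bp. A junction is a
consecutive block pair gap running from a donor offset to exon 5's start,
exact by default (`slack = 0`; a slack parameter exists for noisy
aligners). Precedence INS1b > INS1 > canonical > unspliced resolves reads
matching several patterns — the definitions alone do not order them.
"Unspliced" is interpreted as intron-intruding reads (≥ 20 bp) that are
neither INS1 nor INS1b, *excluding* canonical junction reads; the
alternative literal reading ("total between the exons minus INS1/INS1b")
would count canonical reads as unspliced and is inconsistent with
separately reported canonical fractions. Every read maps to exactly one
of the five outcomes (including `excluded`), and the generator/classifier
round trip recovers mixtures within multinomial error at 2·10⁵ reads.

## G-quadruplex scoring

Per-base scores follow the run-length scheme (G-run of length k scores
+min(k, 4) per base, C-runs the negative; A/T zero), giving the
antisymmetry scores(revcomp(s)) = −reverse(scores(s)) that the tests
assert. Window means (default window 25, threshold 1.2 — the customary
defaults of this scoring family; both exposed) are merged into maximal
tracts when above-threshold windows overlap or touch. For pure consensus
arrays the per-window means stay above the default threshold across the
whole array, so merged-tract counts are small and monotone in copy number
rather than proportional to it; published per-allele G4 copy numbers
likely count motifs rather than merged tracts, so only monotonicity and
oracle equality are asserted, never absolute counts.

## Association layer

Design matrices are built from named cohort columns with complete-case
filtering. Linear fits go through QR-based OLS, logistic fits through
IRLS maximum likelihood; both re-emit tidy (term, β, SE, stat, p) tables,
reject rank-deficient designs naming the collinear columns, and flag
(quasi-)separation. Haplotype coding counts the four VNTR/SNP haplotypes
per individual (always summing to 2) and drops the Short-C reference from
designs. Conditional fits add one marker column (perfect collinearity is
an error); the genotype × age interaction bins age left-closed into
5-year groups anchored at the cohort minimum and adds a single ordinal
product term (a categorical coding was the alternative; the ordinal
choice matches a trend-test reading and keeps one interaction degree of
freedom). Permutation p-values permute the genetic column only, with the
add-one rule (1 + #exceed)/(n + 1). The rank-sum test enumerates all
assignments exactly for nA + nB ≤ 12 and otherwise uses the
tie-corrected, continuity-corrected normal approximation. Two-sided tests
throughout; raw p-values by default, with a Benjamini–Hochberg helper
that is opt-in.

## Problem sizes and tolerances in the test suite

The suite runs at deliberately desk-scale sizes chosen to keep every
stochastic assertion's sampling error far from its tolerance: 5,000
haplotypes for LD calibration (±0.05 around targets), 600 samples for the
classifier operating point, 2·10⁵ reads per genotype for splice recovery
(3 multinomial SDs), 500 replicate n = 78 cohorts for effect-size
recovery (mean β̂ within 1.5 TPM; 95% CI coverage within 95% ± 2%), one
n = 10⁵ cohort for the telomere effect (±0.005), 1,000 trios, and 500
seeded trials for the 2%-noise counting guarantee. Replicate seeds are
spaced (large multipliers) rather than consecutive: consecutive
Mersenne-Twister seedings proved noticeably correlated across replicates
in coverage experiments.

## Known limitations

- LD is controlled pairwise against the VNTR only; SNP–SNP LD is
  induced, not configured, and no recombination or coalescent structure
  exists.
- Coverage noise is independent per base; real depth is autocorrelated
  and subject to mappability structure the generator does not model.
- The splice generator emits 1–2 block reads with exact junction
  coordinates; soft-clipping, alignment slack and multi-intron reads are
  out of scope (the classifier's `slack` parameter exists but defaults
  to 0).
- Absolute G4 tract counts depend on (window, threshold) and on the
  merge convention; only relative statements are supported.
- Imputation is a deterministic kNN vote, adequate for panel-encoding
  evaluation but not a production imputation engine.
- De novo unit phase is ambiguous by one base when array-terminal bases
  are mutated; the period is unaffected.
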