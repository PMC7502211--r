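---
title: "Methods: allele-specific expression and methylation calling without parental genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression and methylation calling without parental genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeallele)
library(dplyr)
```

This vignette is the package's account of its statistical machinery: what
the two callers assume, why each threshold has the value it has, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open.

## The ASE model

The expression arm starts from per-SNP allelic read counts (the
ASEReadCounter output shape) for heterozygous SNPs in diploid individuals
sampled from several genetically distinct colonies in two reproductive
statuses. The obstacle is that without parental genomes there is no way to
phase ref/alt bases across SNPs onto physical alleles: a reference base at
one SNP may sit on either haplotype. The pipeline therefore:

1. **annotates** SNPs with genes (1-based inclusive containment, strand
   ignored; SNPs in overlapping genes count for each);
2. **filters** SNPs with total coverage < 10 reads or a zero count for
   either allele (a zero suggests a mis-called homozygous site);
3. **pools** replicate individuals per colony × status, summing each SNP's
   ref and alt counts;
4. **allocates** per SNP the larger pooled count to "allele 1";
5. **aggregates** allele-1/allele-2 totals per gene × colony × status;
6. **tests** each gene with a quasibinomial logistic regression and
7. **classifies** genes at q < 0.05 (BH) and mean allelic proportion
   > 0.65.

### Why pooling precedes allocation

The allocation rule `max/min` is a rectifier: applied to pure noise it
inflates the apparent proportion above 0.5. Applied independently to each
replicate it rectifies three noisy draws per SNP per group instead of one,
and under realistic overdispersion (intra-class correlation around 0.1)
the allocated proportion of a truly balanced gene climbs to ~0.65 — the
exact value of the classification threshold, which then no longer protects
against mis-allocation. Pooling replicates first (one allocation decision
per SNP per group, using the aggregate evidence) keeps null allocated
proportions near 0.58 and restores the threshold's guard band. Biologically
this is also the right unit: the ref/alt identity of a site is a property
of the SNP, not of the individual sequenced.

### The gene-level test

For the aggregated rows of one gene, allele-1 successes out of total
allelic reads are modelled as

$$\operatorname{logit}(\pi) = \mu + \text{status} + \text{colony},
\qquad \operatorname{Var} = \varphi\, \pi(1-\pi)/n .$$

Covariates use **sum-to-zero contrasts**, so the intercept $\mu$ is the
grand-mean logit proportion rather than a reference-cell mean; the
gene-level hypothesis is $\mu = 0$, i.e. $\pi = 0.5$. Which coefficient
defines the call was an open choice — the intercept was chosen because the
classification is a per-gene bias call, not a status contrast; status and
colony remain in the model so systematic group differences do not inflate
the dispersion. The dispersion $\varphi$ is the Pearson χ² over the
residual degrees of freedom, **floored at 1** (standard quasi-likelihood
practice; no under-dispersion credit keeps the test conservative), and the
p-value uses a *t* reference with the residual df. Degenerate inputs fall
back deterministically: zero residual df → intercept-only refit; a single
row or complete separation (every row pure allele 1) → exact two-sided
binomial test of the pooled counts.

With 6 groups and 4 parameters the residual df is 2, which makes the test
noticeably conservative at the null (empirical type-I ≈ 0.02–0.03 at
nominal 0.05 in the test suite's 2,000-gene simulation). This is inherent
to quasi-likelihood with few groups, not a bug; the test suite asserts
non-anti-conservativeness rather than exact calibration.

### Thresholds

| parameter | default | meaning / rationale |
|---|---|---|
| `min_coverage` | 10 reads | below this, per-SNP proportions are too noisy and mis-called heterozygotes common |
| `min_colonies` | 2 of 3 | a gene must be observed in ≥ 2 colonies for at least one status to be testable |
| `q_threshold` | 0.05 | BH FDR across the tested-gene set only (not all annotated genes) |
| `prop_threshold` | 0.65 | guard band against allocation bias: a balanced gene's allocated proportion at coverage 10 is ≈ 0.62 in expectation, so 0.65 sits above the null bulk while far below real strong bias |

## The ASM model

The methylation arm consumes epireads — per-read strings of C (methylated)
/ T (unmethylated) states over consecutive CpGs, indexed against the
chromosome's ordered CpG list — pooled per reproductive group. A sliding
window of `window = 3` CpGs (step 1 CpG) is tested wherever every window
CpG has ≥ `min_cpg_coverage = 10` observing reads; only chromosomes on an
allow-list (in the original assembly, the 18 placed linkage groups) are
scanned.

Per window two models are fit:

* **single profile:** both alleles share one per-CpG methylation rate
  vector; the ML rate at CpG $j$ is the observed methylated fraction
  $m_j/n_j$;
* **two profiles:** reads come from a 50:50 mixture of two per-CpG
  Bernoulli profiles. The mixture is fit by EM over reads
  (E-step: per-read allele responsibilities; M-step:
  responsibility-weighted rates). Mixing is fixed at 0.5 — the diploid
  expectation — even though inputs are pooled individuals; a free-mixing
  option exists (`mixing = NA`) but is off by default because the merged
  group is treated as the unit and the target is allele-level asymmetry.

The statistic is $\Lambda = 2(\ell_2 - \ell_1) \ge 0$, referred to
$\chi^2_w$ (the $w$ added profile parameters). For mixtures this reference
is approximate; simulations at intermediate methylation (the hardest null)
show empirical window-level type-I close to nominal (≈ 0.05–0.07 at
coverage 15), and the BH correction across windows governs the actual call
rate. Windows with q < 0.05 that overlap or abut in CpG-index space merge
into regions; a region reports the **minimum member p and q** (q is not
recomputed at region level — the FDR statement is per window, matching a
per-window corrected p-value design), and intervals are emitted BED-style
0-based half-open.

### Numerical choices

* Rates are clamped to $[10^{-6}, 1 - 10^{-6}]$ so log-likelihoods stay
  finite at pure columns.
* EM stops when the log-likelihood gain drops below $10^{-8}$ or after 500
  iterations (non-convergence is flagged and the best LL used).
* Restarts (default 5): a split initialisation (reads partitioned at the
  mean per-read methylation), the single-profile point — which guarantees
  $\ell_2 \ge \ell_1$, since EM never decreases the likelihood from the
  nested null — and seeded random profiles. Each restart index derives its
  own seed, so the best-of-restarts likelihood is non-decreasing in the
  number of restarts.
* Allocation ties (`ref == alt`) keep the reference count on allele 1;
  ties are symmetric so orientation invariance is unaffected.
* Reads partially covering a window contribute only their observed CpGs to
  both models.

## What the generators emulate — and what they do not

`simulate_ase_counts()` reproduces the *statistical* structure the ASE
caller assumes: colonies × statuses × replicates, Poisson coverage,
per-gene allelic proportion, beta-binomial overdispersion (intra-class
correlation `overdispersion_rho`, settable per gene), whole gene × colony
dropout, and — crucially — per-SNP randomization of which physical allele
carries the reference base, so synthetic data contain the same labelling
ambiguity as real data and only allocation can recover bias.

`simulate_epireads()` draws reads for allelically methylated regions from
two per-CpG profiles at a set mixing fraction and for null regions from a
single profile (default: the midpoint of the two profiles — an
intermediate-methylation null, which is the hardest case for the mixture
test). Every state is flipped with `conversion_error = 0.05`, the assumed
bisulfite conversion error floor. Each region sits on its own chromosome
so the sliding window never straddles two regions; reads span all CpGs of
their region unless `partial_read_rate` trims ends.

Neither generator emulates alignment artifacts, reference mapping bias,
SNP-calling error, linked SNPs within reads, spatial methylation
autocorrelation beyond the profile, or allele-specific splicing. Passing
recovery tests on these simulations therefore demonstrates that the
estimators and decision rules work when the modelled assumptions hold —
not that real libraries satisfy those assumptions.

## Problem sizes used for validation

The recovery simulations are sized to be decisive yet quick: 300 genes
(150 at proportion 0.85 without overdispersion, 150 unbiased at
ρ = 0.1 — the overdispersed null being the stress case for the call rule)
for the ASE arm, and 40 regions of 12 CpGs at 15 reads per CpG (8 true
epiallele regions at profiles 0.9 vs 0.1) for the ASM arm, plus 500
independent null windows for calibration and 2,000 replicate genes for the
GLM's type-I behaviour. With only 8 true regions, recall has a granularity
of 0.125 and single borderline regions (e.g. an unlucky allele draw among
15 reads, or noise-heavy windows with likelihood ratios near the BH cut)
move it by a step across seeds.

## Known limitations

* Allele 1 is "the more expressed allele per gene", not a phased
  haplotype; the method cannot distinguish parent-of-origin effects from
  genotype-linked (cis) effects, and genes with opposing SNP-level biases
  are diluted rather than detected (no allele-specific splicing).
* The χ² reference for the mixture LR is asymptotic and approximate; the
  per-window FDR is controlled empirically by BH, but region-level FDR is
  not separately controlled (a region inherits its best window's q).
* The epiread caller assumes exactly two epialleles at 50:50; pooled
  samples with more than two segregating epialleles violate this and
  reduce power.
* The hypergeometric overlap p-value depends entirely on the declared
  universe; the package requires the caller to supply one rather than
  defaulting silently.
* GO terms are used exactly as annotated (no ancestor propagation),
  matching a flat custom-database workflow.
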